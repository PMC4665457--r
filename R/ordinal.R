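## posterior ROC areas for two paired ordinal tests with verification
## bias, and a generic two-sample ordinal AUC from Dirichlet category
## probabilities

#' Tie-corrected ordinal ROC area kernel
#'
#' @description For category distributions `alpha` (diseased) and
#'   `beta` (non-diseased) over the same ordered categories (ascending
#'   suspicion of disease), the ROC area is the Mann-Whitney
#'   probability with half-credit for ties,
#'   `A = P[Y > X] + P[Y = X] / 2 = sum_{i>j} alpha_i beta_j +
#'   sum_i alpha_i beta_i / 2`.
#'
#' @param alpha,beta probability vectors of equal length `K`, or
#'   n x K matrices of draws (rows sum to 1).
#' @return a matrix with columns `strict` (`P[Y > X]`), `ties`
#'   (`P[Y = X]`) and `auc` (`strict + ties / 2`), one row per draw.
#' @examples
#' ordinalRocArea(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2))
#' @export
ordinalRocArea <- function(alpha, beta) {
  if (!is.matrix(alpha)) alpha <- matrix(alpha, 1L)
  if (!is.matrix(beta)) beta <- matrix(beta, 1L)
  stopifnot(ncol(alpha) == ncol(beta), nrow(alpha) == nrow(beta))
  K <- ncol(alpha)
  ## cumBeta[, i] = P[X < i]
  cumBeta <- cbind(0, t(apply(beta, 1L, cumsum))[, -K, drop = FALSE])
  if (K == 2L) cumBeta <- cbind(0, beta[, 1L])
  strict <- rowSums(alpha * cumBeta)
  ties <- rowSums(alpha * beta)
  cbind(strict = strict, ties = ties, auc = strict + ties / 2)
}

## row/column marginal aggregation of K^2 cell vectors (t1 major)
.rowAgg <- function(x, K) {
  vapply(seq_len(K), function(i) rowSums(x[, ((i - 1) * K + 1):(i * K),
                                            drop = FALSE]),
         numeric(nrow(x)))
}
.colAgg <- function(x, K) {
  vapply(seq_len(K), function(j) rowSums(x[, seq(j, K^2, by = K),
                                            drop = FALSE]),
         numeric(nrow(x)))
}

#' ROC areas of two ordinal tests from one parameter draw
#'
#' @description Bayes' theorem converts the marginal disease
#'   probabilities and outcome probabilities into the category
#'   distributions of each test within the diseased and non-diseased
#'   classes, `alpha_i = phi_i. theta_i. / sum(phi theta)` and
#'   `beta_i = (1 - phi_i.) theta_i. / sum((1 - phi) theta)`, from
#'   which the tie-corrected ROC area follows for any `K`.
#'
#' @param theta joint cell probabilities: length-`K^2` vector or
#'   n x `K^2` matrix (t1-major cell order), rows summing to 1.
#' @param phiRow `P(D = 1 | T1 = i)`: length-`K` vector or n x K
#'   matrix.
#' @param phiCol `P(D = 1 | T2 = i)`, same shape.
#' @return a list with matrices `alpha1`, `beta1`, `alpha2`, `beta2`
#'   (n x K) and vectors `A1`, `A2` of ROC areas.
#' @export
ordinalRocFromParameters <- function(theta, phiRow, phiCol) {
  if (!is.matrix(theta)) theta <- matrix(theta, 1L)
  if (!is.matrix(phiRow)) phiRow <- matrix(phiRow, 1L)
  if (!is.matrix(phiCol)) phiCol <- matrix(phiCol, 1L)
  K <- ncol(phiRow)
  stopifnot(ncol(theta) == K^2, ncol(phiCol) == K)
  thRow <- .rowAgg(theta, K)
  thCol <- .colAgg(theta, K)
  classDist <- function(phi, th) {
    num1 <- phi * th
    num0 <- (1 - phi) * th
    t1 <- rowSums(num1); t0 <- rowSums(num0)
    if (any(t1 == 0) || any(t0 == 0)) {
      stop("degenerate class: all mass on one disease status",
           call. = FALSE)
    }
    list(alpha = num1 / t1, beta = num0 / t0)
  }
  d1 <- classDist(phiRow, thRow)
  d2 <- classDist(phiCol, thCol)
  list(alpha1 = d1$alpha, beta1 = d1$beta,
       alpha2 = d2$alpha, beta2 = d2$beta,
       A1 = unname(ordinalRocArea(d1$alpha, d1$beta)[, "auc"]),
       A2 = unname(ordinalRocArea(d2$alpha, d2$beta)[, "auc"]))
}

#' Posterior ROC areas of two paired ordinal tests
#'
#' @description Samples `theta ~ Dirichlet(m)` over the `K^2` cells
#'   and, independently, the marginal disease probabilities
#'   `phi_i. ~ beta(s_i., r_i.)` and `phi_.i ~ beta(s_.i, r_.i)` from
#'   the row/column-aggregated verified counts; each draw is mapped
#'   through [ordinalRocFromParameters()] and the ROC areas `A1`,
#'   `A2` and their difference `d = A1 - A2` are summarized.
#'
#' @param table an [OrdinalVerificationTable-class].
#' @param prior a [PriorSpec-class].
#' @param nDraws number of draws (default 55000).
#' @param seed integer seed (required).
#' @return a posterior summary data.frame with rows `A1`, `A2`, `d`;
#'   attribute `draws` holds the [DrawMatrix-class].
#' @export
ordinalAnalysis <- function(table, prior = priorSpec(),
                            nDraws = 55000L, seed) {
  stopifnot(is(table, "OrdinalVerificationTable"), nDraws >= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  K <- table@K
  h <- hyperParameters(table, prior)
  if (length(h$note)) {
    message("zero-cell substitutions: ", paste(h$note, collapse = "; "))
  }
  aRow <- .rowAgg(matrix(h$a, 1L), K); bRow <- .rowAgg(matrix(h$b, 1L), K)
  aCol <- .colAgg(matrix(h$a, 1L), K); bCol <- .colAgg(matrix(h$b, 1L), K)
  if (any(c(aRow, bRow, aCol, bCol) == 0)) {
    stop("a row or column has no verified subjects in one disease ",
         "class; its marginal beta posterior is improper", call. = FALSE)
  }
  set.seed(seed)
  theta <- .rdirichlet(nDraws, h$d)
  rbetaMat <- function(a, b) {
    vapply(seq_along(a),
           function(i) stats::rbeta(nDraws, a[i], b[i]),
           numeric(nDraws))
  }
  phiRow <- rbetaMat(aRow, bRow)
  phiCol <- rbetaMat(aCol, bCol)
  roc <- ordinalRocFromParameters(theta, phiRow, phiCol)
  dmat <- cbind(A1 = roc$A1, A2 = roc$A2, d = roc$A1 - roc$A2)
  out <- summarizeDraws(dmat)
  attr(out, "draws") <- drawMatrix(dmat, seed = as.integer(seed))
  out
}

#' Posterior AUC from two independent Dirichlet category distributions
#'
#' @description Draws the diseased and non-diseased category
#'   probability vectors from independent Dirichlet distributions with
#'   the given (possibly fractional) positive hyperparameters, and
#'   summarizes the tie-corrected ROC area `auc = P[Y > X] +
#'   P[Y = X] / 2` together with its strict (`A1`) and tie (`A2`)
#'   components.  Because the kernel is bilinear in the two
#'   independent vectors, the posterior mean of `auc` equals the
#'   plug-in AUC at the Dirichlet mean vectors.
#'
#' @param aDiseased,aNondiseased positive hyperparameter vectors of
#'   equal length over the same ordered categories (ascending
#'   suspicion of disease).
#' @param nDraws number of draws (default 55000).
#' @param seed integer seed (required).
#' @return a posterior summary data.frame with rows `A1`, `A2`, `auc`;
#'   attributes `draws` ([DrawMatrix-class]) and `plugin` (the
#'   deterministic plug-in `c(strict, ties, auc)` at the mean
#'   vectors).
#' @examples
#' aucFromDirichletCounts(c(2, 3, 10), c(10, 3, 2), nDraws = 2000,
#'                        seed = 5)
#' @export
aucFromDirichletCounts <- function(aDiseased, aNondiseased,
                                   nDraws = 55000L, seed) {
  if (length(aDiseased) != length(aNondiseased)) {
    stop("hyperparameter vectors must have equal length", call. = FALSE)
  }
  if (any(aDiseased <= 0) || any(aNondiseased <= 0)) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(seed)
  p <- .rdirichlet(nDraws, aDiseased)
  q <- .rdirichlet(nDraws, aNondiseased)
  roc <- ordinalRocArea(p, q)
  dmat <- cbind(A1 = roc[, "strict"], A2 = roc[, "ties"],
                auc = roc[, "auc"])
  out <- summarizeDraws(dmat)
  attr(out, "draws") <- drawMatrix(dmat, seed = as.integer(seed))
  attr(out, "plugin") <- drop(ordinalRocArea(
    aDiseased / sum(aDiseased), aNondiseased / sum(aNondiseased)))
  out
}
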