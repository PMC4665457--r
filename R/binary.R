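## conjugate Monte Carlo posterior for two paired binary tests under
## MAR verification, and the derived accuracy quantities

## Dirichlet draws via normalized gammas; the gamma rate constant
## cancels after normalization, so rate 1 is used
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha,
              each = n), rate = 1), nrow = n)
  g / rowSums(g)
}

#' Sample the joint posterior for two binary tests
#'
#' @description Under the missing-at-random assumption, the posterior
#'   of the conditional disease probabilities is `phi_ij ~ beta(a_ij,
#'   b_ij)` per cell and the joint outcome probabilities `theta` are
#'   `Dirichlet(d)`, with hyperparameters from [hyperParameters()].
#'   The marginal disease probabilities `phi_1.` (given test 1
#'   positive) etc. are, by default, sampled as independent betas on
#'   the row/column-aggregated counts — the construction the accuracy
#'   formulas for single tests use; `marginals = "derived"` instead
#'   computes them from the joint `(phi, theta)` of the same draw.
#'
#' @param table a [BinaryVerificationTable-class].
#' @param prior a [PriorSpec-class].
#' @param nDraws number of Monte Carlo draws (default 45000).
#' @param seed integer seed (required).
#' @param marginals `"independent"` (default) or `"derived"`.
#' @return a [DrawMatrix-class] with columns `phi00, phi01, phi10,
#'   phi11, theta00, ..., theta11, phi0., phi1., phi.0, phi.1`.
#' @seealso [binaryAccuracyAnalysis()], [accuracyFromParameters()]
#' @export
sampleBinaryPosterior <- function(table, prior = priorSpec(),
                                  nDraws = 45000L, seed,
                                  marginals = c("independent",
                                                "derived")) {
  marginals <- match.arg(marginals)
  stopifnot(is(table, "BinaryVerificationTable"), nDraws >= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  h <- hyperParameters(table, prior)
  if (length(h$note)) {
    message("zero-cell substitutions: ", paste(h$note, collapse = "; "))
  }
  set.seed(seed)
  a <- as.vector(t(h$a)); b <- as.vector(t(h$b))   # cell order 00,01,10,11
  phi <- vapply(1:4, function(k) stats::rbeta(nDraws, a[k], b[k]),
                numeric(nDraws))
  theta <- .rdirichlet(nDraws, h$d)
  colnames(phi) <- paste0("phi", .BINARY_CELLS)
  colnames(theta) <- paste0("theta", .BINARY_CELLS)
  if (marginals == "independent") {
    ## aggregated counts from the (possibly zero-fixed) hyperparameters
    s0. <- a[1] + a[2]; s1. <- a[3] + a[4]
    r0. <- b[1] + b[2]; r1. <- b[3] + b[4]
    s.0 <- a[1] + a[3]; s.1 <- a[2] + a[4]
    r.0 <- b[1] + b[3]; r.1 <- b[2] + b[4]
    marg <- cbind(`phi0.` = stats::rbeta(nDraws, s0., r0.),
                  `phi1.` = stats::rbeta(nDraws, s1., r1.),
                  `phi.0` = stats::rbeta(nDraws, s.0, r.0),
                  `phi.1` = stats::rbeta(nDraws, s.1, r.1))
  } else {
    th0. <- theta[, 1] + theta[, 2]; th1. <- theta[, 3] + theta[, 4]
    th.0 <- theta[, 1] + theta[, 3]; th.1 <- theta[, 2] + theta[, 4]
    marg <- cbind(
      `phi0.` = (phi[, 1] * theta[, 1] + phi[, 2] * theta[, 2]) / th0.,
      `phi1.` = (phi[, 3] * theta[, 3] + phi[, 4] * theta[, 4]) / th1.,
      `phi.0` = (phi[, 1] * theta[, 1] + phi[, 3] * theta[, 3]) / th.0,
      `phi.1` = (phi[, 2] * theta[, 2] + phi[, 4] * theta[, 4]) / th.1)
  }
  drawMatrix(cbind(phi, theta, marg), seed = seed)
}

## normalize user input (2x2 matrix / named or plain length-4 vector /
## n x 4 matrix) to an n x 4 matrix in cell order 00, 01, 10, 11
.asCellMatrix <- function(x, what) {
  if (is.matrix(x) && identical(dim(x), c(2L, 2L))) {
    x <- matrix(as.vector(t(x)), 1L)
  } else if (!is.matrix(x)) {
    if (length(x) != 4L) {
      stop(sprintf("'%s' must have 4 cells", what), call. = FALSE)
    }
    x <- matrix(as.numeric(x), 1L)
  }
  if (ncol(x) != 4L) {
    stop(sprintf("'%s' must have 4 columns (cells 00,01,10,11)", what),
         call. = FALSE)
  }
  x
}

.asMargMatrix <- function(x, what) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), 1L)
  if (ncol(x) != 2L) {
    stop(sprintf("'%s' must have 2 columns (levels 0, 1)", what),
         call. = FALSE)
  }
  x
}

#' Accuracy quantities from the model parameters
#'
#' @description Deterministic map from one (or many) parameter draws to
#'   the accuracy measures.  With `pd = sum(phi_ij theta_ij)` the
#'   probability of disease:
#'   * `tpf1 = phi1. theta1. / (phi1. theta1. + phi0. theta0.)` and
#'     `fpf1 = (1 - phi1.) theta1. / (1 - phi1. theta1. - phi0. theta0.)`
#'     (analogously `tpf2`, `fpf2` with the column marginals);
#'   * believe-the-positive: `tpfbp = (phi11 theta11 + phi01 theta01 +
#'     phi10 theta10) / pd`, `fpfbp` with `1 - phi` in the numerator
#'     over `1 - pd`;
#'   * believe-the-negative: `tpfbn = phi11 theta11 / pd`,
#'     `fpfbn = (1 - phi11) theta11 / (1 - pd)`.
#'
#' @param phi per-cell disease probabilities: 2x2 matrix, length-4
#'   vector (cell order 00, 01, 10, 11) or n x 4 matrix of draws.
#' @param theta joint outcome probabilities, same shapes; rows sum to 1.
#' @param phiMarg1 `P(D=1 | Y1 = 0)` and `P(D=1 | Y1 = 1)`: length-2
#'   vector or n x 2 matrix.
#' @param phiMarg2 same for test 2.
#' @return a matrix (one row per draw) with columns `tpf1, fpf1, tpf2,
#'   fpf2, tpfbp, fpfbp, tpfbn, fpfbn, pd`.
#' @examples
#' accuracyFromParameters(phi = rep(0.5, 4), theta = rep(0.25, 4),
#'                        phiMarg1 = c(0.5, 0.5),
#'                        phiMarg2 = c(0.5, 0.5))
#' @export
accuracyFromParameters <- function(phi, theta, phiMarg1, phiMarg2) {
  phi <- .asCellMatrix(phi, "phi")
  theta <- .asCellMatrix(theta, "theta")
  m1 <- .asMargMatrix(phiMarg1, "phiMarg1")
  m2 <- .asMargMatrix(phiMarg2, "phiMarg2")
  if (any(phi < 0 | phi > 1) || any(m1 < 0 | m1 > 1) ||
      any(m2 < 0 | m2 > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(theta) - 1) > 1e-8)) {
    stop("theta rows must sum to 1", call. = FALSE)
  }
  th0. <- theta[, 1] + theta[, 2]; th1. <- theta[, 3] + theta[, 4]
  th.0 <- theta[, 1] + theta[, 3]; th.1 <- theta[, 2] + theta[, 4]
  pd <- rowSums(phi * theta)
  if (any(pd <= 0 | pd >= 1)) {
    stop("degenerate prevalence: P[D=1] must lie strictly in (0, 1)",
         call. = FALSE)
  }
  pd1 <- m1[, 2] * th1. + m1[, 1] * th0.
  pd2 <- m2[, 2] * th.1 + m2[, 1] * th.0
  out <- cbind(
    tpf1 = m1[, 2] * th1. / pd1,
    fpf1 = (1 - m1[, 2]) * th1. / (1 - pd1),
    tpf2 = m2[, 2] * th.1 / pd2,
    fpf2 = (1 - m2[, 2]) * th.1 / (1 - pd2),
    tpfbp = (phi[, 4] * theta[, 4] + phi[, 2] * theta[, 2] +
             phi[, 3] * theta[, 3]) / pd,
    fpfbp = ((1 - phi[, 4]) * theta[, 4] + (1 - phi[, 2]) * theta[, 2] +
             (1 - phi[, 3]) * theta[, 3]) / (1 - pd),
    tpfbn = phi[, 4] * theta[, 4] / pd,
    fpfbn = (1 - phi[, 4]) * theta[, 4] / (1 - pd),
    pd = pd)
  out
}

## split a posterior DrawMatrix into its parameter blocks
.drawBlocks <- function(dm) {
  d <- draws(dm)
  list(phi = d[, paste0("phi", .BINARY_CELLS), drop = FALSE],
       theta = d[, paste0("theta", .BINARY_CELLS), drop = FALSE],
       m1 = d[, c("phi0.", "phi1."), drop = FALSE],
       m2 = d[, c("phi.0", "phi.1"), drop = FALSE])
}

#' Posterior analysis of binary paired-test accuracy
#'
#' @description Samples the conjugate posterior, maps every draw
#'   through [accuracyFromParameters()] and summarizes.  This is the
#'   full verification-bias-corrected analysis for two paired binary
#'   tests: individual true/false positive fractions plus the
#'   believe-the-positive and believe-the-negative combined rules.
#'
#' @inheritParams sampleBinaryPosterior
#' @return a posterior summary data.frame (see [summarizeDraws()])
#'   with rows `tpf1, fpf1, tpf2, fpf2, tpfbp, fpfbp, tpfbn, fpfbn,
#'   pd`; attribute `draws` holds the accuracy [DrawMatrix-class].
#' @examples
#' tab <- binaryTable(s = c(3, 9, 12, 14), r = c(18, 13, 9, 4),
#'                    u = c(10, 9, 8, 7))
#' binaryAccuracyAnalysis(tab, nDraws = 5000, seed = 11)
#' @export
binaryAccuracyAnalysis <- function(table, prior = priorSpec(),
                                   nDraws = 45000L, seed,
                                   marginals = c("independent",
                                                 "derived")) {
  dm <- sampleBinaryPosterior(table, prior, nDraws, seed,
                              marginals = match.arg(marginals))
  bl <- .drawBlocks(dm)
  acc <- accuracyFromParameters(bl$phi, bl$theta, bl$m1, bl$m2)
  out <- summarizeDraws(acc)
  attr(out, "draws") <- drawMatrix(acc, seed = dm@seed)
  out
}
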