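## generator of verification-bias data with the structure the
## estimators assume: multinomial outcomes, cell-conditional disease,
## MAR verification

#' Generator specification constructor
#'
#' @param design `"binary"` or `"ordinal"`.
#' @param theta joint outcome probabilities (length 4 for binary in
#'   cell order `00, 01, 10, 11`, else `K^2` t1-major); must sum to 1.
#' @param phi conditional disease probability per cell.
#' @param v verification probability per cell; a scalar is recycled.
#'   Verification depends only on the test outcomes, never on disease
#'   status (missing at random by construction).
#' @param n number of subjects.
#' @param seed integer seed.
#' @param K ordinal levels (ignored for binary).
#' @return a validated [GeneratorSpec-class].
#' @export
generatorSpec <- function(design = c("binary", "ordinal"), theta, phi,
                          v, n, seed, K = 3L) {
  design <- match.arg(design)
  K <- if (design == "binary") 2L else as.integer(K)
  nc <- if (design == "binary") 4L else K^2
  if (length(v) == 1L) v <- rep(v, nc)
  if (length(phi) == 1L) phi <- rep(phi, nc)
  new("GeneratorSpec", design = design, K = K,
      theta = as.numeric(theta), phi = as.numeric(phi),
      v = as.numeric(v), n = as.integer(n), seed = as.integer(seed))
}

#' Generate a verification-bias table
#'
#' @description For each subject: the joint outcome cell is drawn from
#'   `theta` (multinomial), disease from `Bernoulli(phi_cell)` and
#'   verification from `Bernoulli(v_cell)` independently of disease
#'   given the cell; `s` counts verified diseased, `r` verified
#'   non-diseased, `u` unverified subjects.
#'
#' @param spec a [GeneratorSpec-class].
#' @return a [BinaryVerificationTable-class] or
#'   [OrdinalVerificationTable-class].
#' @examples
#' sp <- generatorSpec("binary", theta = rep(0.25, 4),
#'                     phi = c(0.14, 0.41, 0.57, 0.78), v = 0.6,
#'                     n = 1000, seed = 3)
#' generateTable(sp)
#' @export
generateTable <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nc <- length(spec@theta)
  m <- drop(stats::rmultinom(1L, spec@n, spec@theta))
  nver <- stats::rbinom(nc, m, spec@v)
  s <- stats::rbinom(nc, nver, spec@phi)
  r <- nver - s
  u <- m - nver
  if (spec@design == "binary") {
    binaryTable(s = s, r = r, u = u)
  } else {
    ordinalTable(K = spec@K, s = s, r = r, u = u)
  }
}

## true accuracy quantities implied by a binary generator spec; the
## marginal disease probabilities are derived coherently from the
## joint truth
.binaryTruth <- function(spec) {
  th <- spec@theta; ph <- spec@phi
  th0. <- th[1] + th[2]; th1. <- th[3] + th[4]
  th.0 <- th[1] + th[3]; th.1 <- th[2] + th[4]
  m1 <- c((ph[1] * th[1] + ph[2] * th[2]) / th0.,
          (ph[3] * th[3] + ph[4] * th[4]) / th1.)
  m2 <- c((ph[1] * th[1] + ph[3] * th[3]) / th.0,
          (ph[2] * th[2] + ph[4] * th[4]) / th.1)
  acc <- drop(accuracyFromParameters(ph, th, m1, m2))
  c(stats::setNames(ph, paste0("phi", .BINARY_CELLS)),
    stats::setNames(th, paste0("theta", .BINARY_CELLS)),
    acc)
}

#' Parameter-recovery experiment
#'
#' @description Generates one table from the spec, runs the posterior
#'   analysis, and reports for each parameter (per-cell `phi` and
#'   `theta`, and for binary designs the derived accuracy quantities)
#'   the truth, the posterior mean and sd, the central 95% interval
#'   and whether it covers the truth.  Looping this over seeds gives
#'   the frequentist coverage of the Bayesian intervals under the
#'   model's own data-generating process.
#'
#' @param spec a [GeneratorSpec-class] (binary design).
#' @param prior a [PriorSpec-class].
#' @param nDraws posterior draws per replicate (default 4000).
#' @param seed integer seed for the posterior sampling (the table uses
#'   `spec@seed`).
#' @return a data.frame with columns `parameter, truth, postMean,
#'   postSd, lower, upper, covered`; attribute `table` holds the
#'   generated table.
#' @export
recoveryExperiment <- function(spec, prior = priorSpec(),
                               nDraws = 4000L, seed) {
  stopifnot(is(spec, "GeneratorSpec"))
  if (spec@design != "binary") {
    stop("recovery experiments are implemented for the binary design",
         call. = FALSE)
  }
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  tab <- generateTable(spec)
  if (any(tab@s + tab@r == 0)) {
    stop("generated table has a cell with no verified subjects; ",
         "increase n or v, or choose a zeroFix policy explicitly",
         call. = FALSE)
  }
  dm <- sampleBinaryPosterior(tab, prior, nDraws, seed,
                              marginals = "derived")
  bl <- .drawBlocks(dm)
  acc <- accuracyFromParameters(bl$phi, bl$theta, bl$m1, bl$m2)
  all <- cbind(bl$phi, bl$theta, acc)
  truth <- .binaryTruth(spec)
  sm <- summarizeDraws(all[, names(truth)])
  out <- data.frame(parameter = names(truth), truth = unname(truth),
                    postMean = sm$mean, postSd = sm$sd,
                    lower = sm$q2.5, upper = sm$q97.5)
  out$covered <- out$lower <= out$truth & out$truth <= out$upper
  attr(out, "table") <- tab
  out
}
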