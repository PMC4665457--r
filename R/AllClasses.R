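#' @import methods
NULL

.BINARY_CELLS <- c("00", "01", "10", "11")

## counts must be whole, non-negative numbers (stored as numeric for
## convenience with jsonlite round-trips)
.checkCounts <- function(x, what) {
  if (any(!is.finite(x))) {
    return(sprintf("%s contains non-finite counts", what))
  }
  if (any(x < 0)) {
    return(sprintf("%s contains negative counts", what))
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    return(sprintf("%s contains non-integer counts", what))
  }
  TRUE
}

#' Virtual parent of the verification-bias count tables
#'
#' @description Parent class of [BinaryVerificationTable-class] and
#'   [OrdinalVerificationTable-class].  Both record, for every joint
#'   outcome cell of two paired tests, how many verified subjects were
#'   diseased (`s`), how many verified subjects were non-diseased (`r`),
#'   and how many subjects were never referred to the gold standard
#'   (`u`); the cell total is `m = s + r + u`.
#'
#' @seealso [binaryTable()], [ordinalTable()], [loadTable()]
#' @exportClass VerificationTable
setClass("VerificationTable", representation("VIRTUAL"))

#' Paired binary tests with partial gold-standard verification
#'
#' @description Counts for two binary tests \eqn{Y_1, Y_2 \in \{0, 1\}}
#'   cross-classified over the four joint outcome cells.  Slot matrices
#'   are 2x2 with rows indexed by \eqn{Y_1} and columns by \eqn{Y_2}
#'   (dimnames `"0"`, `"1"`).
#'
#' @slot s 2x2 matrix, verified diseased counts \eqn{s_{ij}}.
#' @slot r 2x2 matrix, verified non-diseased counts \eqn{r_{ij}}.
#' @slot u 2x2 matrix, unverified counts \eqn{u_{ij}}.
#'
#' @seealso [binaryTable()], [cellTotals()], [hyperParameters()]
#' @exportClass BinaryVerificationTable
setClass("BinaryVerificationTable",
  contains = "VerificationTable",
  representation(s = "matrix", r = "matrix", u = "matrix"))

setValidity("BinaryVerificationTable", function(object) {
  for (nm in c("s", "r", "u")) {
    x <- slot(object, nm)
    if (!is.numeric(x) || !identical(dim(x), c(2L, 2L))) {
      return(sprintf("slot '%s' must be a numeric 2x2 matrix", nm))
    }
    ok <- .checkCounts(x, sprintf("slot '%s'", nm))
    if (!isTRUE(ok)) return(ok)
  }
  if (sum(object@s + object@r) == 0) {
    return("no verified subjects in any cell (all s + r are zero)")
  }
  TRUE
})

#' Paired ordinal tests with partial gold-standard verification
#'
#' @description Counts for two ordinal tests \eqn{T_1, T_2 \in \{1,
#'   \dots, K\}} over the \eqn{K^2} joint outcome cells.  Cells are
#'   stored row-major with \eqn{T_1} as the slower index: cell
#'   \eqn{c = (i - 1) K + j} holds the subjects with \eqn{T_1 = i, T_2
#'   = j}.
#'
#' @slot K integer, number of ordinal levels per test (>= 2).
#' @slot s,r,u numeric vectors of length `K^2`: verified diseased,
#'   verified non-diseased and unverified counts per cell.
#'
#' @seealso [ordinalTable()], [ordinalAnalysis()], [imputeIPW()]
#' @exportClass OrdinalVerificationTable
setClass("OrdinalVerificationTable",
  contains = "VerificationTable",
  representation(K = "integer", s = "numeric", r = "numeric",
                 u = "numeric"))

setValidity("OrdinalVerificationTable", function(object) {
  K <- object@K
  if (length(K) != 1L || is.na(K) || K < 2L) {
    return("K must be a single integer >= 2")
  }
  for (nm in c("s", "r", "u")) {
    x <- slot(object, nm)
    if (length(x) != K^2) {
      return(sprintf("slot '%s' must have length K^2 = %d", nm, K^2))
    }
    ok <- .checkCounts(x, sprintf("slot '%s'", nm))
    if (!isTRUE(ok)) return(ok)
  }
  if (sum(object@s + object@r) == 0) {
    return("no verified subjects in any cell (all s + r are zero)")
  }
  TRUE
})

#' Prior specification for the beta/Dirichlet posteriors
#'
#' @description The improper prior (density proportional to the
#'   reciprocal of each parameter) gives posteriors `beta(s, r)` for
#'   the conditional disease probabilities and `Dirichlet(m)` for the
#'   joint outcome probabilities; the uniform prior adds one to every
#'   hyperparameter.  `zeroFix` governs cells whose `s` or `r` count is
#'   zero under the improper prior: `"error"` (default) refuses to sample
#'   from the improper posterior, `"add_one"` replaces only the
#'   offending zero entries by one (the workaround used for extreme
#'   verification bias, where no double-negative subject is verified).
#'
#' @slot kind `"improper"` or `"uniform"`.
#' @slot zeroFix `"error"` or `"add_one"`.
#'
#' @seealso [priorSpec()], [hyperParameters()]
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(kind = "character", zeroFix = "character"))

setValidity("PriorSpec", function(object) {
  if (!object@kind %in% c("improper", "uniform")) {
    return("kind must be 'improper' or 'uniform'")
  }
  if (!object@zeroFix %in% c("error", "add_one")) {
    return("zeroFix must be 'error' or 'add_one'")
  }
  TRUE
})

#' Labelled Monte Carlo draws of posterior quantities
#'
#' @slot draws numeric matrix, one row per draw and one named column
#'   per quantity; column names are unique.
#' @slot seed integer seed the draws were generated from.
#'
#' @seealso [summarizeDraws()], [sampleBinaryPosterior()]
#' @exportClass DrawMatrix
setClass("DrawMatrix",
  representation(draws = "matrix", seed = "integer"))

setValidity("DrawMatrix", function(object) {
  cn <- colnames(object@draws)
  if (is.null(cn) || anyDuplicated(cn)) {
    return("draws must have unique column names")
  }
  if (!is.numeric(object@draws)) return("draws must be numeric")
  TRUE
})

#' Inverse-probability-weighted ("selected") table
#'
#' @description The result of [imputeIPW()]: each cell's verified
#'   counts scaled by the reciprocal of that cell's verification rate,
#'   so that the imputed table carries no verification bias
#'   (`u` is identically zero).  Counts are fractional unless
#'   `rounding = "nearest"` was requested.
#'
#' @slot design `"binary"` or `"ordinal"`.
#' @slot K integer, levels per test (2 for binary, coded 0/1).
#' @slot t1,t2 integer test values per cell.
#' @slot s,r numeric imputed diseased / non-diseased counts per cell.
#' @slot m numeric original cell totals.
#' @slot rounding `"none"` or `"nearest"`.
#'
#' @seealso [imputeIPW()], [expandRecords()]
#' @exportClass ImputedTable
setClass("ImputedTable",
  representation(design = "character", K = "integer",
                 t1 = "integer", t2 = "integer",
                 s = "numeric", r = "numeric", m = "numeric",
                 rounding = "character"))

setValidity("ImputedTable", function(object) {
  n <- length(object@s)
  if (length(object@r) != n || length(object@m) != n ||
      length(object@t1) != n || length(object@t2) != n) {
    return("cell vectors must have equal length")
  }
  if (!object@rounding %in% c("none", "nearest")) {
    return("rounding must be 'none' or 'nearest'")
  }
  if (object@rounding == "none" &&
      any(abs(object@s + object@r - object@m) > 1e-9)) {
    return("s + r must equal m per cell (rounding = 'none')")
  }
  TRUE
})

#' Bayesian logistic risk-score model
#'
#' @description Posterior draws of the logistic-regression coefficients
#'   \eqn{logit P[D = 1 | T_1, T_2] = b_1 + b_2 T_1 + b_3 T_2} fitted
#'   to imputed per-patient records, together with the posterior-median
#'   risk score of every observed covariate pattern.  The risk score
#'   \eqn{RS(Y) = P[D = 1 | Y]} is monotone in the likelihood ratio, so
#'   its ROC area measures the combined accuracy of the two tests.
#'
#' @slot coefDraws numeric matrix of retained draws, columns `b1`,
#'   `b2`, `b3`.
#' @slot acceptanceRate Metropolis acceptance rate over retained draws.
#' @slot riskByPattern data.frame with columns `t1`, `t2`, `risk`
#'   (posterior median), one row per observed pattern.
#' @slot seed integer seed.
#'
#' @seealso [fitLogistic()], [combinedAuc()]
#' @exportClass RiskScoreModel
setClass("RiskScoreModel",
  representation(coefDraws = "matrix", acceptanceRate = "numeric",
                 riskByPattern = "data.frame", seed = "integer"))

setValidity("RiskScoreModel", function(object) {
  if (ncol(object@coefDraws) != 3L) {
    return("coefDraws must have 3 columns (b1, b2, b3)")
  }
  rk <- object@riskByPattern$risk
  if (any(rk <= 0 | rk >= 1)) return("risk scores must lie in (0, 1)")
  TRUE
})

#' Specification of the synthetic verification-bias generator
#'
#' @description Defines the data-generating process the estimators
#'   assume: joint test outcomes are multinomial with cell
#'   probabilities `theta`, disease is Bernoulli with cell-conditional
#'   probability `phi`, and verification is Bernoulli with
#'   cell-conditional probability `v` independent of disease given the
#'   outcome cell (missing at random).
#'
#' @slot design `"binary"` or `"ordinal"`.
#' @slot K integer levels per test (2 for binary).
#' @slot theta numeric cell probabilities (length 4 or `K^2`, sum 1).
#' @slot phi numeric conditional disease probabilities per cell.
#' @slot v numeric verification probabilities per cell.
#' @slot n integer number of subjects.
#' @slot seed integer seed.
#'
#' @seealso [generatorSpec()], [generateTable()], [recoveryExperiment()]
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(design = "character", K = "integer", theta = "numeric",
                 phi = "numeric", v = "numeric", n = "integer",
                 seed = "integer"))

setValidity("GeneratorSpec", function(object) {
  if (!object@design %in% c("binary", "ordinal")) {
    return("design must be 'binary' or 'ordinal'")
  }
  nc <- if (object@design == "binary") 4L else object@K^2
  if (length(object@theta) != nc || length(object@phi) != nc ||
      length(object@v) != nc) {
    return(sprintf("theta, phi, v must each have length %d", nc))
  }
  if (abs(sum(object@theta) - 1) > 1e-8) return("theta must sum to 1")
  if (any(object@theta < 0) || any(object@phi < 0 | object@phi > 1) ||
      any(object@v < 0 | object@v > 1)) {
    return("probabilities must lie in [0, 1]")
  }
  if (object@n < 1L) return("n must be >= 1")
  TRUE
})
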