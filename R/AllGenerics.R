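#' Verified diseased counts per cell
#'
#' @param x a verification table.
#' @return the `s` counts (2x2 matrix for binary, vector for ordinal).
#' @export
setGeneric("diseasedCounts", function(x) standardGeneric("diseasedCounts"))

#' Verified non-diseased counts per cell
#'
#' @param x a verification table.
#' @return the `r` counts.
#' @export
setGeneric("nondiseasedCounts",
           function(x) standardGeneric("nondiseasedCounts"))

#' Unverified counts per cell
#'
#' @param x a verification table.
#' @return the `u` counts.
#' @export
setGeneric("unverifiedCounts",
           function(x) standardGeneric("unverifiedCounts"))

#' Cell totals m = s + r + u
#'
#' @param x a verification table.
#' @return the `m` totals, same shape as the counts.
#' @export
setGeneric("cellTotals", function(x) standardGeneric("cellTotals"))

#' Posterior hyperparameters under a prior specification
#'
#' @description Returns the beta pairs `(a, b)` for the per-cell
#'   conditional disease probabilities and the Dirichlet vector `d`
#'   for the joint outcome probabilities.  Improper prior: `(a, b, d)
#'   = (s, r, m)`; uniform prior: `(s + 1, r + 1, m + 1)`.  Under the
#'   improper prior, cells with a zero `s` or `r` count make the beta
#'   posterior improper; `prior@zeroFix = "add_one"` replaces only the
#'   offending zero entries by one and records the substitution.
#'
#' @param table a [BinaryVerificationTable-class] or
#'   [OrdinalVerificationTable-class].
#' @param prior a [PriorSpec-class], default `priorSpec()`.
#' @return a list with elements `a`, `b` (shape of the table's counts),
#'   `d` (Dirichlet vector in cell order), and `note` (character vector
#'   describing any zero-cell substitutions, length 0 if none).
#' @examples
#' tab <- binaryTable(s = c(3, 9, 12, 14), r = c(18, 13, 9, 4),
#'                    u = c(10, 9, 8, 7))
#' hyperParameters(tab)              # improper: a = s, b = r, d = m
#' hyperParameters(tab, priorSpec("uniform"))
#' @export
setGeneric("hyperParameters",
           function(table, prior = priorSpec())
             standardGeneric("hyperParameters"))

#' Inverse-probability-weighting imputation
#'
#' @description Converts a verification-biased table into an unbiased
#'   "selected" table by scaling each cell's verified counts by the
#'   reciprocal of that cell's verification rate:
#'   `s' = s * m / (s + r)`, `r' = r * m / (s + r)`, `u' = 0`.
#'
#' @param table a verification table; every cell needs `s + r > 0`.
#' @param rounding `"none"` (default, fractional counts) or
#'   `"nearest"` (half away from zero, for record expansion).
#' @return an [ImputedTable-class].
#' @examples
#' tab <- ordinalTable(K = 3,
#'   s = c(8, 26, 51, 43, 81, 94, 117, 140, 208),
#'   r = c(101, 105, 83, 67, 72, 40, 41, 30, 4),
#'   u = c(2, 18, 62, 14, 83, 67, 63, 40, 108))
#' imputeIPW(tab)              # 8 -> 8 * 111/109 = 8.147 etc.
#' @export
setGeneric("imputeIPW",
           function(table, rounding = c("none", "nearest"))
             standardGeneric("imputeIPW"))
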