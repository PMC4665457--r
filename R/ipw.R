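## inverse-probability-weighting imputation and per-patient record
## expansion

## round half away from zero (all counts are non-negative here);
## base round() would round to even
.roundHalfUp <- function(x) floor(x + 0.5)

.imputeCore <- function(s, r, m, t1, t2, K, design, rounding) {
  ver <- s + r
  if (any(ver == 0)) {
    stop("verification rate undefined (no verified subjects) in ",
         "cell(s) ", paste(which(ver == 0), collapse = ", "),
         call. = FALSE)
  }
  sp <- s * m / ver
  rp <- r * m / ver
  if (rounding == "nearest") {
    sp <- .roundHalfUp(sp)
    rp <- .roundHalfUp(rp)
  }
  new("ImputedTable", design = design, K = as.integer(K),
      t1 = as.integer(t1), t2 = as.integer(t2),
      s = sp, r = rp, m = m, rounding = rounding)
}

#' @describeIn imputeIPW binary table; cells carry test values 0/1.
#' @export
setMethod("imputeIPW", "BinaryVerificationTable",
  function(table, rounding = c("none", "nearest")) {
    rounding <- match.arg(rounding)
    m <- cellTotals(table)
    .imputeCore(as.vector(t(table@s)), as.vector(t(table@r)),
                as.vector(t(m)),
                t1 = c(0L, 0L, 1L, 1L), t2 = c(0L, 1L, 0L, 1L),
                K = 2L, design = "binary", rounding = rounding)
  })

#' @describeIn imputeIPW ordinal table; cells carry test values
#'   `1..K`.
#' @export
setMethod("imputeIPW", "OrdinalVerificationTable",
  function(table, rounding = c("none", "nearest")) {
    rounding <- match.arg(rounding)
    ij <- .ordinalCellIndex(table@K)
    .imputeCore(table@s, table@r, cellTotals(table),
                t1 = ij$t1, t2 = ij$t2, K = table@K,
                design = "ordinal", rounding = rounding)
  })

setMethod("show", "ImputedTable", function(object) {
  cat(sprintf(
    "ImputedTable (%s design, %d cells, rounding = %s)\n",
    object@design, length(object@s), object@rounding))
  tab <- rbind(`s'` = object@s, `r'` = object@r, m = object@m)
  colnames(tab) <- paste0("(", object@t1, ",", object@t2, ")")
  print(tab)
  invisible(object)
})

#' Imputed counts as a data.frame
#'
#' @param x an [ImputedTable-class].
#' @return a data.frame with columns `t1, t2, s, r, m`.
#' @export
imputedCounts <- function(x) {
  stopifnot(is(x, "ImputedTable"))
  data.frame(t1 = x@t1, t2 = x@t2, s = x@s, r = x@r, m = x@m)
}

#' Convert an imputed table back into a verification table
#'
#' @description Only meaningful for integer (rounded) imputed counts;
#'   the result has `u` identically zero, so downstream analyses treat
#'   it as fully verified.
#'
#' @param x an [ImputedTable-class] with `rounding = "nearest"`.
#' @return a [BinaryVerificationTable-class] or
#'   [OrdinalVerificationTable-class].
#' @export
asVerificationTable <- function(x) {
  stopifnot(is(x, "ImputedTable"))
  if (x@rounding != "nearest") {
    stop("integer counts required: impute with rounding = 'nearest'",
         call. = FALSE)
  }
  if (x@design == "binary") {
    binaryTable(s = x@s, r = x@r, u = rep(0, 4))
  } else {
    ordinalTable(K = x@K, s = x@s, r = x@r, u = rep(0, x@K^2))
  }
}

#' Expand an imputed table into per-patient records
#'
#' @description Emits one record per (rounded) imputed count:
#'   `s'_c` diseased and `r'_c` non-diseased records with the cell's
#'   test values, suitable for the logistic risk-score fit.
#'
#' @param imputed an [ImputedTable-class] with `rounding = "nearest"`.
#' @return a data.frame with integer columns `t1`, `t2` and disease
#'   indicator `d`.
#' @seealso [fitLogistic()]
#' @export
expandRecords <- function(imputed) {
  stopifnot(is(imputed, "ImputedTable"))
  if (imputed@rounding != "nearest") {
    stop("record expansion needs integer counts: impute with ",
         "rounding = 'nearest'", call. = FALSE)
  }
  nc <- length(imputed@s)
  d <- rep(rep(c(1L, 0L), nc), times = as.vector(rbind(imputed@s,
                                                       imputed@r)))
  t1 <- rep(rep(imputed@t1, each = 2L), times = as.vector(rbind(
    imputed@s, imputed@r)))
  t2 <- rep(rep(imputed@t2, each = 2L), times = as.vector(rbind(
    imputed@s, imputed@r)))
  data.frame(t1 = t1, t2 = t2, d = d)
}

#' Write an imputed table to JSON
#'
#' @param x an [ImputedTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImputedTable <- function(x, path) {
  stopifnot(is(x, "ImputedTable"))
  obj <- list(design = x@design, K = x@K, t1 = x@t1, t2 = x@t2,
              s = x@s, r = x@r, m = x@m,
              u = rep(0, length(x@s)), rounding = x@rounding)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
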