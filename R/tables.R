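## constructors, accessors, I/O and hyperparameters for the
## verification-bias count tables

.asBinaryMatrix <- function(x, what) {
  if (is.matrix(x)) {
    if (!identical(dim(x), c(2L, 2L))) {
      stop(sprintf("'%s' must be a 2x2 matrix", what), call. = FALSE)
    }
    m <- x
  } else if (length(x) == 4L) {
    ## cell order 00, 01, 10, 11 (y1 major)
    m <- matrix(as.numeric(x), 2L, 2L, byrow = TRUE)
  } else {
    stop(sprintf("'%s' must be a 2x2 matrix or a length-4 vector ",
                 what), call. = FALSE)
  }
  dimnames(m) <- list(y1 = c("0", "1"), y2 = c("0", "1"))
  storage.mode(m) <- "double"
  m
}

#' Build a binary verification table
#'
#' @param s,r,u verified-diseased, verified-non-diseased and unverified
#'   counts: 2x2 matrices (rows = test 1, columns = test 2, level order
#'   0, 1) or length-4 vectors in cell order `00, 01, 10, 11`.
#' @return a validated [BinaryVerificationTable-class].
#' @examples
#' # CT (test 1) and MRI (test 2) for lung cancer risk
#' tab <- binaryTable(s = c(3, 9, 12, 14), r = c(18, 13, 9, 4),
#'                    u = c(10, 9, 8, 7))
#' cellTotals(tab)
#' @export
binaryTable <- function(s, r, u = 0 * s) {
  obj <- new("BinaryVerificationTable",
             s = .asBinaryMatrix(s, "s"),
             r = .asBinaryMatrix(r, "r"),
             u = .asBinaryMatrix(u, "u"))
  obj
}

#' Build an ordinal verification table
#'
#' @param K number of ordinal levels per test (>= 2).
#' @param s,r,u numeric vectors of length `K^2` in row-major order with
#'   test 1 as the slower index (cell `c = (i - 1) * K + j` holds
#'   subjects with `T1 = i, T2 = j`).
#' @return a validated [OrdinalVerificationTable-class].
#' @export
ordinalTable <- function(K, s, r, u = 0 * s) {
  new("OrdinalVerificationTable", K = as.integer(K),
      s = as.numeric(s), r = as.numeric(r), u = as.numeric(u))
}

#' Prior specification constructor
#'
#' @param kind `"improper"` (default) or `"uniform"`.
#' @param zeroFix `"error"` (default) or `"add_one"`; see
#'   [PriorSpec-class].
#' @return a [PriorSpec-class].
#' @export
priorSpec <- function(kind = c("improper", "uniform"),
                      zeroFix = c("error", "add_one")) {
  new("PriorSpec", kind = match.arg(kind), zeroFix = match.arg(zeroFix))
}

#' @describeIn diseasedCounts binary table
#' @export
setMethod("diseasedCounts", "BinaryVerificationTable",
          function(x) x@s)
#' @describeIn diseasedCounts ordinal table
#' @export
setMethod("diseasedCounts", "OrdinalVerificationTable",
          function(x) x@s)
#' @describeIn nondiseasedCounts binary table
#' @export
setMethod("nondiseasedCounts", "BinaryVerificationTable",
          function(x) x@r)
#' @describeIn nondiseasedCounts ordinal table
#' @export
setMethod("nondiseasedCounts", "OrdinalVerificationTable",
          function(x) x@r)
#' @describeIn unverifiedCounts binary table
#' @export
setMethod("unverifiedCounts", "BinaryVerificationTable",
          function(x) x@u)
#' @describeIn unverifiedCounts ordinal table
#' @export
setMethod("unverifiedCounts", "OrdinalVerificationTable",
          function(x) x@u)
#' @describeIn cellTotals binary table
#' @export
setMethod("cellTotals", "BinaryVerificationTable",
          function(x) x@s + x@r + x@u)
#' @describeIn cellTotals ordinal table
#' @export
setMethod("cellTotals", "OrdinalVerificationTable",
          function(x) x@s + x@r + x@u)

setMethod("show", "BinaryVerificationTable", function(object) {
  m <- cellTotals(object)
  cat("BinaryVerificationTable (2 binary tests, partial verification)\n")
  cat(sprintf("  total subjects: %d   verified: %d   unverified: %d\n",
              sum(m), sum(object@s + object@r), sum(object@u)))
  tab <- rbind(`s (D=1)` = as.vector(t(object@s)),
               `r (D=0)` = as.vector(t(object@r)),
               `u (V=0)` = as.vector(t(object@u)),
               m = as.vector(t(m)))
  colnames(tab) <- paste0("(", c("0,0", "0,1", "1,0", "1,1"), ")")
  print(tab)
  invisible(object)
})

setMethod("show", "OrdinalVerificationTable", function(object) {
  m <- cellTotals(object)
  cat(sprintf(
    "OrdinalVerificationTable (K = %d, %d cells, partial verification)\n",
    object@K, object@K^2))
  cat(sprintf("  total subjects: %d   verified: %d   unverified: %d\n",
              sum(m), sum(object@s + object@r), sum(object@u)))
  tab <- rbind(`s (D=1)` = object@s, `r (D=0)` = object@r,
               `u (V=0)` = object@u, m = m)
  ij <- .ordinalCellIndex(object@K)
  colnames(tab) <- paste0("(", ij$t1, ",", ij$t2, ")")
  print(tab)
  invisible(object)
})

## (t1, t2) values per cell in storage order
.ordinalCellIndex <- function(K) {
  list(t1 = rep(seq_len(K), each = K), t2 = rep(seq_len(K), times = K))
}

#' Read a verification table from JSON or CSV
#'
#' @description The JSON schema is
#'   `{"design":"binary","s":[[s00,s01],[s10,s11]],"r":...,"u":...}`
#'   for binary tables (nested rows indexed by test 1), and
#'   `{"design":"ordinal","K":3,"s":[...],"r":[...],"u":[...]}` with
#'   length-`K^2` arrays in row-major test-1-major order for ordinal
#'   tables.  A CSV file needs columns `y1, y2, s, r, u` (binary) or
#'   `t1, t2, s, r, u` (ordinal, one row per cell).
#'
#' @param path path to a `.json` or `.csv` file.
#' @param design `"auto"` (default; from the JSON `design` field or the
#'   CSV column names), `"binary"` or `"ordinal"`.
#' @return a validated verification table.
#' @seealso [writeTable()]
#' @export
loadTable <- function(path, design = c("auto", "binary", "ordinal")) {
  design <- match.arg(design)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(.loadTableCSV(path, design))
  }
  obj <- jsonlite::fromJSON(path)
  if (design == "auto") {
    design <- obj$design
    if (is.null(design)) stop("JSON lacks a 'design' field", call. = FALSE)
  }
  if (design == "binary") {
    tab <- binaryTable(s = .jsonBinaryCounts(obj$s, "s"),
                       r = .jsonBinaryCounts(obj$r, "r"),
                       u = .jsonBinaryCounts(obj$u, "u"))
  } else if (design == "ordinal") {
    tab <- ordinalTable(K = obj$K, s = obj$s, r = obj$r, u = obj$u)
  } else {
    stop("unknown design: ", design, call. = FALSE)
  }
  tab
}

.jsonBinaryCounts <- function(x, what) {
  if (is.null(x)) stop("JSON lacks the '", what, "' field", call. = FALSE)
  m <- as.matrix(x)
  if (!identical(dim(m), c(2L, 2L))) {
    stop("'", what, "' must be a nested 2x2 array", call. = FALSE)
  }
  m
}

.loadTableCSV <- function(path, design) {
  df <- utils::read.csv(path)
  binaryCols <- all(c("y1", "y2") %in% names(df))
  if (design == "auto") design <- if (binaryCols) "binary" else "ordinal"
  need <- c(if (design == "binary") c("y1", "y2") else c("t1", "t2"),
            "s", "r", "u")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (design == "binary") {
    idx <- df$y1 * 2 + df$y2 + 1          # cell order 00,01,10,11
    s <- r <- u <- numeric(4)
    s[idx] <- df$s; r[idx] <- df$r; u[idx] <- df$u
    binaryTable(s = s, r = r, u = u)
  } else {
    K <- max(df$t1, df$t2)
    idx <- (df$t1 - 1) * K + df$t2
    s <- r <- u <- numeric(K^2)
    s[idx] <- df$s; r[idx] <- df$r; u[idx] <- df$u
    ordinalTable(K = K, s = s, r = r, u = u)
  }
}

#' Write a verification table to JSON
#'
#' @param table a verification table.
#' @param path output path.
#' @return `path`, invisibly.  `loadTable(writeTable(x, p))` reproduces
#'   the counts exactly.
#' @export
writeTable <- function(table, path) {
  if (is(table, "BinaryVerificationTable")) {
    obj <- list(design = "binary",
                s = unname(table@s), r = unname(table@r),
                u = unname(table@u))
  } else {
    obj <- list(design = "ordinal", K = table@K,
                s = table@s, r = table@r, u = table@u)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.hyperCore <- function(s, r, m, prior, cellLabel) {
  note <- character(0)
  if (prior@kind == "uniform") {
    return(list(a = s + 1, b = r + 1, d = m + 1, note = note))
  }
  a <- s; b <- r
  zero <- which(a == 0 | b == 0)
  if (length(zero)) {
    if (prior@zeroFix == "error") {
      stop("improper posterior: zero verified count in cell(s) ",
           paste(cellLabel[zero], collapse = ", "),
           " (use zeroFix = 'add_one' or the uniform prior)",
           call. = FALSE)
    }
    for (z in zero) {
      if (a[z] == 0) {
        a[z] <- 1
        note <- c(note, sprintf("s[%s]: 0 -> 1", cellLabel[z]))
      }
      if (b[z] == 0) {
        b[z] <- 1
        note <- c(note, sprintf("r[%s]: 0 -> 1", cellLabel[z]))
      }
    }
  }
  list(a = a, b = b, d = m, note = note)
}

#' @describeIn hyperParameters binary table; `d` is ordered
#'   `(m00, m01, m10, m11)`.
#' @export
setMethod("hyperParameters", "BinaryVerificationTable",
  function(table, prior = priorSpec()) {
    m <- cellTotals(table)
    h <- .hyperCore(as.vector(t(table@s)), as.vector(t(table@r)),
                    as.vector(t(m)), prior, .BINARY_CELLS)
    out <- list(a = .asBinaryMatrix(h$a, "a"),
                b = .asBinaryMatrix(h$b, "b"),
                d = stats::setNames(h$d, .BINARY_CELLS),
                note = h$note)
    out
  })

#' @describeIn hyperParameters ordinal table; `a`, `b`, `d` are
#'   length-`K^2` vectors in cell order.
#' @export
setMethod("hyperParameters", "OrdinalVerificationTable",
  function(table, prior = priorSpec()) {
    m <- cellTotals(table)
    .hyperCore(table@s, table@r, m, prior,
               as.character(seq_len(table@K^2)))
  })
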