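#' Construct a DrawMatrix
#'
#' @param draws numeric matrix with unique column names (one column per
#'   quantity, one row per draw).
#' @param seed integer seed the draws came from.
#' @return a [DrawMatrix-class].
#' @export
drawMatrix <- function(draws, seed = NA_integer_) {
  new("DrawMatrix", draws = draws, seed = as.integer(seed))
}

#' Extract the draw matrix
#' @param x a [DrawMatrix-class].
#' @return the numeric matrix of draws.
#' @export
draws <- function(x) {
  stopifnot(is(x, "DrawMatrix"))
  x@draws
}

setMethod("show", "DrawMatrix", function(object) {
  cat(sprintf("DrawMatrix: %d draws of %d quantities (seed %s)\n",
              nrow(object@draws), ncol(object@draws),
              ifelse(is.na(object@seed), "unset", object@seed)))
  cat("  quantities:", paste(colnames(object@draws), collapse = ", "),
      "\n")
  invisible(object)
})

## batch-means standard error of the mean: 50 equal batches, remainder
## draws dropped; draws here are iid so this plays the role of the
## usual MCMC "MC error" column without autocorrelation machinery
.mcError <- function(x, batches = 50L) {
  n <- length(x)
  b <- n %/% batches
  if (b < 1L) stop("fewer draws than batches", call. = FALSE)
  bm <- colMeans(matrix(x[seq_len(b * batches)], nrow = b))
  stats::sd(bm) / sqrt(batches)
}

#' Summarize posterior draws
#'
#' @description Posterior mean, standard deviation, Monte Carlo error
#'   (batch means, 50 batches) and type-7 quantiles (2.5%, 50%, 97.5%)
#'   per quantity — the columns of the usual MCMC node-statistics
#'   table.
#'
#' @param x a [DrawMatrix-class] or a numeric matrix with named
#'   columns; at least 100 draws.
#' @return a data.frame with one row per quantity and columns `mean`,
#'   `sd`, `mcError`, `q2.5`, `median`, `q97.5`; attribute `nDraws`.
#' @examples
#' set.seed(1)
#' x <- cbind(u = runif(10000))
#' summarizeDraws(x)
#' @export
summarizeDraws <- function(x) {
  m <- if (is(x, "DrawMatrix")) x@draws else x
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (nrow(m) < 100L) {
    stop("need at least 100 draws to summarize", call. = FALSE)
  }
  qs <- t(apply(m, 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE))
  out <- data.frame(
    mean = colMeans(m),
    sd = apply(m, 2L, stats::sd),
    mcError = apply(m, 2L, .mcError),
    q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
    row.names = colnames(m))
  stopifnot(all(out$q2.5 <= out$median & out$median <= out$q97.5))
  attr(out, "nDraws") <- nrow(m)
  out
}

#' Format a posterior summary as an aligned text table
#'
#' @param summary a data.frame from [summarizeDraws()].
#' @param digits significant digits, default 4.
#' @return a character vector of lines (header + one line per
#'   quantity) with columns Mean, SD, Error, 2.5%, Median, 97.5%.
#' @export
formatSummaryTable <- function(summary, digits = 4) {
  num <- vapply(seq_len(nrow(summary)), function(i) {
    formatC(unlist(summary[i, c("mean", "sd", "mcError", "q2.5",
                                "median", "q97.5")]),
            digits = digits, format = "g", width = 10)
  }, character(6))
  header <- c("Mean", "SD", "Error", "2.5%", "Median", "97.5%")
  lines <- c(
    paste0(formatC("Parameter", width = -12),
           paste(formatC(header, width = 10), collapse = " ")),
    vapply(seq_len(nrow(summary)), function(i) {
      paste0(formatC(rownames(summary)[i], width = -12),
             paste(num[, i], collapse = " "))
    }, character(1)))
  lines
}
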