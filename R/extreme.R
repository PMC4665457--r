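## accuracy measures that remain estimable under extreme verification
## bias (no double-negative subject is verified): detection and false
## referral probabilities and the BP:BN ratios

#' Extreme-verification-bias quantities from the model parameters
#'
#' @description When no all-negative subject is verified, the disease
#'   prevalence — and hence TPF/FPF — is not estimable, but the
#'   detection probabilities `DP = P[test positive, D = 1]`, the false
#'   referral probabilities `FRP = P[test positive, D = 0]` and the
#'   ratios of the believe-the-positive to believe-the-negative rule's
#'   true and false positive fractions are.  Since `DP = rho * TPF`
#'   and `FRP = (1 - rho) * FPF`, the unknown prevalence `rho` cancels
#'   in those ratios.
#'
#' @inheritParams accuracyFromParameters
#' @return a matrix (one row per draw) with columns `dp1, dp2, frp1,
#'   frp2, ratioTpf, ratioFpf, ratioDp, ratioFrp` where
#'   `dp1 = theta1. phi1.`, `frp1 = (1 - phi1.) theta1.`,
#'   `ratioTpf = (theta11 phi11 + theta10 phi10 + theta01 phi01) /
#'   (theta11 phi11)`, `ratioFpf` is the analogous ratio with
#'   `1 - phi`, and `ratioDp = dp1/dp2`, `ratioFrp = frp1/frp2`
#'   compare the two tests (each equals the corresponding TPF or FPF
#'   ratio, the prevalence cancelling).
#' @export
extremeBiasFromParameters <- function(phi, theta, phiMarg1, phiMarg2) {
  phi <- .asCellMatrix(phi, "phi")
  theta <- .asCellMatrix(theta, "theta")
  m1 <- .asMargMatrix(phiMarg1, "phiMarg1")
  m2 <- .asMargMatrix(phiMarg2, "phiMarg2")
  th1. <- theta[, 3] + theta[, 4]
  th.1 <- theta[, 2] + theta[, 4]
  bnT <- theta[, 4] * phi[, 4]
  bnF <- theta[, 4] * (1 - phi[, 4])
  ## degenerate cells leave the dp/frp components estimable; only the
  ## affected ratio becomes NaN
  if (any(bnT == 0)) {
    warning("degenerate cell: theta11 * phi11 = 0, ratioTpf undefined",
            call. = FALSE)
    bnT[bnT == 0] <- NaN
  }
  if (any(bnF == 0)) {
    warning("degenerate cell: theta11 * (1 - phi11) = 0, ",
            "ratioFpf undefined", call. = FALSE)
    bnF[bnF == 0] <- NaN
  }
  dp1 <- th1. * m1[, 2]
  dp2 <- th.1 * m2[, 2]
  frp1 <- (1 - m1[, 2]) * th1.
  frp2 <- (1 - m2[, 2]) * th.1
  cbind(
    dp1 = dp1, dp2 = dp2, frp1 = frp1, frp2 = frp2,
    ratioTpf = (bnT + theta[, 3] * phi[, 3] + theta[, 2] * phi[, 2]) /
      bnT,
    ratioFpf = (bnF + theta[, 3] * (1 - phi[, 3]) +
                theta[, 2] * (1 - phi[, 2])) / bnF,
    ratioDp = dp1 / dp2,
    ratioFrp = frp1 / frp2)
}

#' Naive point estimates under extreme verification bias
#'
#' @description Direct count ratios, valid when all subjects positive
#'   on at least one test are verified: `dp1 = (s11 + s10) / m..`,
#'   `frp2 = (r11 + r01) / m..`, `ratioTpf = (s11 + s10 + s01) / s11`,
#'   `ratioFpf = (r11 + r10 + r01) / r11`, etc.  A warning is issued
#'   if the table does not have the extreme-bias structure (all
#'   unverified mass in the double-negative cell).
#'
#' @param table a [BinaryVerificationTable-class].
#' @return a named numeric vector `dp1, dp2, frp1, frp2, ratioTpf,
#'   ratioFpf`.
#' @examples
#' tab <- binaryTable(s = c(0, 9, 12, 14), r = c(0, 13, 9, 4),
#'                    u = c(21, 0, 0, 0))
#' naiveExtremeEstimates(tab)    # ratioTpf 35/14, ratioFpf 26/4
#' @export
naiveExtremeEstimates <- function(table) {
  stopifnot(is(table, "BinaryVerificationTable"))
  s <- table@s; r <- table@r; u <- table@u
  if (sum(u) != u["0", "0"]) {
    warning("table does not have extreme-bias structure ",
            "(unverified subjects outside the double-negative cell); ",
            "naive estimates may be biased")
  }
  mdd <- sum(cellTotals(table))
  s11 <- s["1", "1"]; s10 <- s["1", "0"]; s01 <- s["0", "1"]
  r11 <- r["1", "1"]; r10 <- r["1", "0"]; r01 <- r["0", "1"]
  if (s11 == 0 || r11 == 0) {
    stop("s11 or r11 is zero: BP:BN ratios undefined", call. = FALSE)
  }
  c(dp1 = (s11 + s10) / mdd,
    dp2 = (s11 + s01) / mdd,
    frp1 = (r11 + r10) / mdd,
    frp2 = (r11 + r01) / mdd,
    ratioTpf = (s11 + s10 + s01) / s11,
    ratioFpf = (r11 + r10 + r01) / r11)
}

#' Posterior analysis under extreme verification bias
#'
#' @description Samples the conjugate posterior (zero cells handled by
#'   the prior's `zeroFix` policy) and summarizes the detection
#'   probabilities, false referral probabilities and BP:BN ratios.
#'   For the heavy-tailed `ratioFpf` the posterior median is the
#'   preferred point estimate; both are reported.
#'
#' @inheritParams sampleBinaryPosterior
#' @param nDraws number of draws (default 55000).
#' @return a posterior summary data.frame with rows `dp1, dp2, frp1,
#'   frp2, ratioTpf, ratioFpf, ratioDp, ratioFrp`; attribute `draws`
#'   holds the [DrawMatrix-class].
#' @examples
#' tab <- binaryTable(s = c(0, 9, 12, 14), r = c(0, 13, 9, 4),
#'                    u = c(21, 0, 0, 0))
#' extremeBiasAnalysis(tab, priorSpec(zeroFix = "add_one"),
#'                     nDraws = 5000, seed = 7)
#' @export
extremeBiasAnalysis <- function(table, prior = priorSpec(),
                                nDraws = 55000L, seed) {
  dm <- sampleBinaryPosterior(table, prior, nDraws, seed)
  bl <- .drawBlocks(dm)
  ex <- extremeBiasFromParameters(bl$phi, bl$theta, bl$m1, bl$m2)
  out <- summarizeDraws(ex)
  attr(out, "draws") <- drawMatrix(ex, seed = dm@seed)
  out
}
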