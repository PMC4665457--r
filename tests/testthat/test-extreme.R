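test_that("naive extreme-bias estimates reproduce the count ratios exactly", {
  est <- naiveExtremeEstimates(lungExtremeTable())
  expect_equal(est[["ratioTpf"]], 35 / 14)  # = 2.5
  expect_equal(est[["ratioFpf"]], 26 / 4)   # = 6.5
  expect_equal(est[["dp1"]], 26 / 82)
  expect_equal(est[["dp2"]], 23 / 82)
  expect_equal(est[["frp1"]], 13 / 82)
  expect_equal(est[["frp2"]], 17 / 82)
})

test_that("naive estimates warn when the design is not extreme-bias", {
  expect_warning(naiveExtremeEstimates(lungTable()), "extreme-bias")
})

test_that("perfect disease prediction gives zero false referral", {
  expect_warning(
    out <- extremeBiasFromParameters(phi = rep(1, 4),
                                     theta = c(0.1, 0.2, 0.3, 0.4),
                                     phiMarg1 = c(1, 1),
                                     phiMarg2 = c(1, 1)),
    "ratioFpf")
  expect_equal(unname(out[1, "dp1"]), 0.7)   # = theta1.
  expect_equal(unname(out[1, "frp1"]), 0)
})

test_that("plug-in at the extreme-bias posterior means matches direct arithmetic", {
  # zero-fixed hyperparameter means for the extreme-bias lung table
  s <- c(1, 9, 12, 14); r <- c(1, 13, 9, 4); m <- c(21, 22, 21, 18)
  phi <- s / (s + r); th <- m / sum(m)
  phi1 <- c((s[1] + s[2]) / (s[1] + s[2] + r[1] + r[2]),
            (s[3] + s[4]) / (s[3] + s[4] + r[3] + r[4]))
  phi2 <- c((s[1] + s[3]) / (s[1] + s[3] + r[1] + r[3]),
            (s[2] + s[4]) / (s[2] + s[4] + r[2] + r[4]))
  out <- extremeBiasFromParameters(phi, th, phi1, phi2)
  expect_equal(unname(out[1, "dp1"]), (39 / 82) * (26 / 39))  # = 26/82 = 0.317
  expect_equal(round(unname(out[1, "dp1"]), 3), 0.317)
  # ratioFpf at the means reduces to the count ratio 26/4
  expect_equal(unname(out[1, "ratioFpf"]),
               (4 / 82 + 9 / 82 + 13 / 82) / (4 / 82))
  expect_equal(unname(out[1, "ratioFpf"]), 6.5)
})

test_that("per-draw identities and bounds hold across the posterior", {
  tab <- lungExtremeTable()
  dm <- suppressMessages(sampleBinaryPosterior(
    tab, priorSpec(zeroFix = "add_one"), nDraws = 5000, seed = 9))
  d <- draws(dm)
  cells <- c("00", "01", "10", "11")
  ex <- extremeBiasFromParameters(d[, paste0("phi", cells)],
                                  d[, paste0("theta", cells)],
                                  d[, c("phi0.", "phi1.")],
                                  d[, c("phi.0", "phi.1")])
  th1. <- d[, "theta10"] + d[, "theta11"]
  th.1 <- d[, "theta01"] + d[, "theta11"]
  # dp + frp exhausts the marginal positivity probability
  expect_equal(ex[, "dp1"] + ex[, "frp1"], th1., tolerance = 1e-12)
  expect_equal(ex[, "dp2"] + ex[, "frp2"], th.1, tolerance = 1e-12)
  expect_true(all(ex[, "ratioTpf"] >= 1))
  expect_true(all(ex[, "ratioFpf"] >= 1))
  expect_true(all(ex[, c("dp1", "dp2", "frp1", "frp2")] >= 0 &
                  ex[, c("dp1", "dp2", "frp1", "frp2")] <= 1))
})

test_that("DP = rho * TPF and FRP = (1 - rho) * FPF per draw", {
  dm <- sampleBinaryPosterior(lungTable(), nDraws = 2000, seed = 21,
                              marginals = "derived")
  d <- draws(dm)
  cells <- c("00", "01", "10", "11")
  phi <- d[, paste0("phi", cells)]; theta <- d[, paste0("theta", cells)]
  m1 <- d[, c("phi0.", "phi1.")]; m2 <- d[, c("phi.0", "phi.1")]
  acc <- accuracyFromParameters(phi, theta, m1, m2)
  ex <- extremeBiasFromParameters(phi, theta, m1, m2)
  rho <- acc[, "pd"]
  expect_equal(ex[, "dp1"], rho * acc[, "tpf1"], tolerance = 1e-10)
  expect_equal(ex[, "frp1"], (1 - rho) * acc[, "fpf1"],
               tolerance = 1e-10)
  # prevalence cancels in the cross-test ratios
  expect_equal(ex[, "ratioDp"], acc[, "tpf1"] / acc[, "tpf2"],
               tolerance = 1e-10)
  expect_equal(ex[, "ratioFrp"], acc[, "fpf1"] / acc[, "fpf2"],
               tolerance = 1e-10)
})

test_that("the FPF ratio posterior is right-skewed on the extreme-bias table", {
  sm <- suppressMessages(extremeBiasAnalysis(
    lungExtremeTable(), priorSpec(zeroFix = "add_one"),
    nDraws = 20000, seed = 33))
  expect_gt(sm["ratioFpf", "mean"], sm["ratioFpf", "median"])
})

test_that("degenerate double-positive cells are flagged with NaN ratios", {
  expect_warning(
    a <- extremeBiasFromParameters(phi = c(0.5, 0.5, 0.5, 0),
                                   theta = rep(0.25, 4),
                                   phiMarg1 = c(0.5, 0.5),
                                   phiMarg2 = c(0.5, 0.5)),
    "ratioTpf")
  expect_true(is.nan(a[1, "ratioTpf"]))
  expect_warning(
    b <- extremeBiasFromParameters(phi = c(0.5, 0.5, 0.5, 1),
                                   theta = rep(0.25, 4),
                                   phiMarg1 = c(0.5, 0.5),
                                   phiMarg2 = c(0.5, 0.5)),
    "ratioFpf")
  expect_true(is.nan(b[1, "ratioFpf"]))
})
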