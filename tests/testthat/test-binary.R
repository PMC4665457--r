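## independent arithmetic oracle: plug-in accuracy at the posterior
## hyperparameter mean ratios, written out longhand
pluginOracle <- function(s, r, m) {
  phi <- s / (s + r)                 # cell order 00, 01, 10, 11
  th <- m / sum(m)
  pd <- sum(phi * th)
  list(
    tpfbn = phi[4] * th[4] / pd,
    fpfbn = (1 - phi[4]) * th[4] / (1 - pd),
    tpfbp = (phi[4] * th[4] + phi[2] * th[2] + phi[3] * th[3]) / pd,
    fpfbp = ((1 - phi[4]) * th[4] + (1 - phi[2]) * th[2] +
             (1 - phi[3]) * th[3]) / (1 - pd))
}

test_that("posterior sampler recovers the conjugate moments", {
  dm <- sampleBinaryPosterior(lungTable(), nDraws = 20000, seed = 101)
  d <- draws(dm)
  expect_lt(abs(mean(d[, "theta11"]) - 25 / 116), 0.005)  # Dirichlet mean
  expect_lt(abs(mean(d[, "phi1."]) - 26 / 39), 0.005)     # beta(26, 13)
  expect_lt(abs(mean(d[, "phi11"]) - 14 / 18), 0.005)
  expect_equal(rowSums(d[, paste0("theta", c("00", "01", "10", "11"))]),
               rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("symmetric parameters give the symmetric accuracy values", {
  acc <- accuracyFromParameters(phi = rep(0.5, 4), theta = rep(0.25, 4),
                                phiMarg1 = c(0.5, 0.5),
                                phiMarg2 = c(0.5, 0.5))
  expect_equal(unname(acc[1, "pd"]), 0.5)
  expect_equal(unname(acc[1, "tpfbp"]), 0.75)
  expect_equal(unname(acc[1, "fpfbp"]), 0.75)
  expect_equal(unname(acc[1, "tpfbn"]), 0.25)
  expect_equal(unname(acc[1, "fpfbn"]), 0.25)
})

test_that("plug-in at the lung-cancer posterior means matches direct arithmetic", {
  s <- c(3, 9, 12, 14); r <- c(18, 13, 9, 4); m <- c(31, 31, 29, 25)
  orc <- pluginOracle(s, r, m)
  acc <- accuracyFromParameters(
    phi = s / (s + r), theta = m / sum(m),
    phiMarg1 = c((s[1] + s[2]) / (s[1] + s[2] + r[1] + r[2]),
                 (s[3] + s[4]) / (s[3] + s[4] + r[3] + r[4])),
    phiMarg2 = c((s[1] + s[3]) / (s[1] + s[3] + r[1] + r[3]),
                 (s[2] + s[4]) / (s[2] + s[4] + r[2] + r[4])))
  expect_equal(unname(acc[1, "tpfbn"]), orc$tpfbn)
  expect_equal(unname(acc[1, "tpfbp"]), orc$tpfbp)
  expect_equal(unname(acc[1, "fpfbn"]), orc$fpfbn)
  expect_equal(unname(acc[1, "fpfbp"]), orc$fpfbp)
  # the values themselves, to 4 decimals
  expect_equal(round(unname(acc[1, "tpfbn"]), 4), 0.3660)
  expect_equal(round(unname(acc[1, "tpfbp"]), 4), 0.9166)
  expect_equal(round(unname(acc[1, "fpfbn"]), 4), 0.0884)
  expect_equal(round(unname(acc[1, "fpfbp"]), 4), 0.5774)
  expect_equal(round(unname(acc[1, "tpf1"]), 4), 0.6754)
})

test_that("an uninformative test has tpf = fpf = its positivity rate", {
  for (p in c(0.2, 0.5, 0.9)) {
    th <- c(0.1, 0.2, 0.3, 0.4)
    acc <- accuracyFromParameters(phi = c(0.3, 0.4, 0.5, 0.6),
                                  theta = th,
                                  phiMarg1 = c(p, p),
                                  phiMarg2 = c(0.2, 0.7))
    expect_equal(unname(acc[1, "tpf1"]), th[3] + th[4])
    expect_equal(unname(acc[1, "fpf1"]), th[3] + th[4])
  }
})

test_that("per-draw accuracy invariants hold across the posterior", {
  dm <- sampleBinaryPosterior(lungTable(), nDraws = 5000, seed = 5)
  d <- draws(dm)
  cells <- paste0("phi", c("00", "01", "10", "11"))
  acc <- accuracyFromParameters(d[, cells],
                                d[, sub("phi", "theta", cells)],
                                d[, c("phi0.", "phi1.")],
                                d[, c("phi.0", "phi.1")])
  expect_true(all(acc >= 0 & acc <= 1))
  # BP sums strictly more non-negative mass than BN
  expect_true(all(acc[, "tpfbp"] >= acc[, "tpfbn"]))
  expect_true(all(acc[, "fpfbp"] >= acc[, "fpfbn"]))
})

test_that("uniform-prior results equal improper-prior results on the +1 table", {
  tab <- lungTable()
  inc <- binaryTable(s = tab@s + 1, r = tab@r + 1, u = tab@u - 1)
  a <- binaryAccuracyAnalysis(tab, priorSpec("uniform"), nDraws = 2000,
                              seed = 31)
  b <- binaryAccuracyAnalysis(inc, priorSpec("improper"), nDraws = 2000,
                              seed = 31)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("with complete verification the BN plug-in equals the naive estimator", {
  s <- c(5, 7, 9, 11); r <- c(12, 10, 8, 6)
  tab <- binaryTable(s = s, r = r, u = rep(0, 4))
  h <- hyperParameters(tab)
  phi <- as.vector(t(h$a)) / (as.vector(t(h$a)) + as.vector(t(h$b)))
  th <- unname(h$d) / sum(h$d)
  acc <- accuracyFromParameters(phi, th, phiMarg1 = c(0.5, 0.5),
                                phiMarg2 = c(0.5, 0.5))
  # tpfbn = phi11 theta11 / pd = s11 / sum(s) when m = s + r
  expect_equal(unname(acc[1, "tpfbn"]), s[4] / sum(s))
})

test_that("independent seeds agree within Monte Carlo error", {
  tab <- lungTable()
  a <- binaryAccuracyAnalysis(tab, nDraws = 20000, seed = 71)
  b <- binaryAccuracyAnalysis(tab, nDraws = 20000, seed = 72)
  tol <- 4 * sqrt(a$mcError^2 + b$mcError^2)
  expect_true(all(abs(a$mean - b$mean) <= tol))
})

test_that("derived-marginal construction is coherent with the joint", {
  dm <- sampleBinaryPosterior(lungTable(), nDraws = 1000, seed = 13,
                              marginals = "derived")
  d <- draws(dm)
  lhs <- d[, "phi1."] * (d[, "theta10"] + d[, "theta11"])
  rhs <- d[, "phi10"] * d[, "theta10"] + d[, "phi11"] * d[, "theta11"]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("degenerate prevalence is refused", {
  expect_error(
    accuracyFromParameters(phi = rep(0, 4), theta = rep(0.25, 4),
                           phiMarg1 = c(0.5, 0.5),
                           phiMarg2 = c(0.5, 0.5)),
    "prevalence")
})
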