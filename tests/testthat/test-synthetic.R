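## the generator's default study conditions: equally likely joint
## outcomes, disease probability rising with test positivity,
## outcome-dependent verification
defaultSpec <- function(n, seed, v = 0.6) {
  generatorSpec("binary", theta = rep(0.25, 4),
                phi = c(0.14, 0.41, 0.57, 0.78), v = v, n = n,
                seed = seed)
}

test_that("complete verification leaves no unverified subjects", {
  tab <- generateTable(defaultSpec(500, seed = 2, v = 1))
  expect_true(all(unverifiedCounts(tab) == 0))
  expect_equal(diseasedCounts(tab) + nondiseasedCounts(tab),
               cellTotals(tab))
  expect_equal(sum(cellTotals(tab)), 500)
})

test_that("zero verification yields a degenerate table and is refused", {
  # all mass lands in u, so no posterior exists; the table-level
  # invariant (some verified subjects) rejects it
  expect_error(generateTable(defaultSpec(100, seed = 2, v = 0)),
               "no verified")
})

test_that("large-sample verified fractions recover the generating probabilities", {
  spec <- defaultSpec(1e5, seed = 31)
  tab <- generateTable(spec)
  s <- as.vector(t(diseasedCounts(tab)))
  r <- as.vector(t(nondiseasedCounts(tab)))
  m <- as.vector(t(cellTotals(tab)))
  # disease rate among verified equals phi (MAR: verification carries
  # no information about disease within a cell)
  expect_true(all(abs(s / (s + r) - spec@phi) < 0.02))
  # verification rate equals v in every cell
  expect_true(all(abs((s + r) / m - 0.6) < 0.02))
})

test_that("cell totals are multinomial(n, theta)", {
  spec <- generatorSpec("binary", theta = c(0.1, 0.2, 0.3, 0.4),
                        phi = rep(0.5, 4), v = 1, n = 1e5, seed = 17)
  tab <- generateTable(spec)
  m <- as.vector(t(cellTotals(tab)))
  gof <- chisq.test(m, p = spec@theta)
  expect_gt(gof$p.value, 0.001)
})

test_that("the ordinal generator fills a K^2 grid", {
  th <- rep(1 / 9, 9)
  spec <- generatorSpec("ordinal", K = 3, theta = th,
                        phi = seq(0.1, 0.9, length.out = 9), v = 0.7,
                        n = 5000, seed = 23)
  tab <- generateTable(spec)
  expect_s4_class(tab, "OrdinalVerificationTable")
  expect_length(tab@s, 9)
  expect_equal(sum(cellTotals(tab)), 5000)
})

test_that("95% credible intervals cover the truth in at least 90 of 100 replicates", {
  spec0 <- defaultSpec(5000, seed = 0)
  pars <- paste0("phi", c("00", "01", "10", "11"))
  hits <- matrix(NA, 100, length(pars), dimnames = list(NULL, pars))
  for (k in 1:100) {
    spec <- defaultSpec(5000, seed = 5000 + k,
                        v = c(0.3, 0.5, 0.8, 1.0))
    rec <- recoveryExperiment(spec, nDraws = 2000, seed = 6000 + k)
    hits[k, ] <- rec$covered[match(pars, rec$parameter)]
  }
  expect_true(all(colSums(hits) >= 90))
})

test_that("outcome-independent verification leaves the verified-only estimate unbiased", {
  # constant v: the naive (verified-only) tpf and the corrected
  # posterior mean agree within posterior uncertainty
  for (k in 1:5) {
    spec <- defaultSpec(5000, seed = 300 + k, v = 0.5)
    tab <- generateTable(spec)
    s <- as.vector(t(diseasedCounts(tab)))
    naive <- (s[3] + s[4]) / sum(s)
    sm <- binaryAccuracyAnalysis(tab, nDraws = 2000, seed = 400 + k)
    expect_lt(abs(naive - sm["tpf1", "mean"]), 3 * sm["tpf1", "sd"])
  }
})

test_that("the posterior corrects the direction of verification bias", {
  # verify every double positive but few others: the verified-only
  # tpf estimate overshoots; the model-based posterior mean should be
  # closer to the truth in most replicates
  spec0 <- generatorSpec("binary", theta = rep(0.25, 4),
                         phi = c(0.14, 0.41, 0.57, 0.78),
                         v = c(0.2, 0.2, 0.2, 1), n = 5000, seed = 1)
  truth <- veribayes:::.binaryTruth(spec0)[["tpf1"]]
  closer <- vapply(1:100, function(k) {
    spec <- generatorSpec("binary", theta = spec0@theta,
                          phi = spec0@phi, v = spec0@v, n = 5000,
                          seed = 700 + k)
    tab <- generateTable(spec)
    s <- as.vector(t(diseasedCounts(tab)))
    naive <- (s[3] + s[4]) / sum(s)
    sm <- binaryAccuracyAnalysis(tab, nDraws = 1000, seed = 800 + k)
    abs(sm["tpf1", "mean"] - truth) < abs(naive - truth)
  }, logical(1))
  expect_gte(sum(closer), 80)
})

test_that("recovery experiments refuse unverifiable cells", {
  spec <- defaultSpec(20, seed = 8, v = 0.05)
  expect_error(recoveryExperiment(spec, nDraws = 500, seed = 9),
               "no verified|verified subjects")
})
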