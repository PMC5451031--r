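# Normality gate, Welch/Mann-Whitney selection, chi-squared / Fisher,
# Bonferroni thresholds and term enrichment.

test_that("Bonferroni thresholds are alpha over m", {
  expect_equal(bonferroniThreshold(6), 0.05 / 6)
  expect_equal(bonferroniThreshold(13), 0.05 / 13)
  expect_equal(bonferroniThreshold(1), 0.05)
  expect_equal(bonferroniThreshold(16), 0.003125)
  expect_error(bonferroniThreshold(0), ">= 1")
  ## strictly decreasing in m
  ms <- 1:30
  expect_true(all(diff(vapply(ms, bonferroniThreshold, numeric(1))) < 0))
})

test_that("the normality gate accepts normal and rejects skewed samples", {
  set.seed(10)
  pass <- vapply(1:40, function(i) normalityGate(rnorm(1000)), logical(1))
  expect_gte(mean(pass), 0.9)
  fail <- vapply(1:40, function(i) normalityGate(rexp(1000)), logical(1))
  expect_true(all(!fail))
  expect_false(normalityGate(rep(3, 50)))       # degenerate SD
  expect_error(normalityGate(rnorm(5)), "at least 8")
  ## the plain K-S variant is exposed too
  expect_false(normalityGate(rexp(1000), method = "ks"))
})

test_that("Mann-Whitney U matches exact enumeration and wilcox.test", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)          # 2 / 20 arrangements
  expect_equal(mw$method, "exact")
  ## identical samples: p = 1
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 1)

  ## random small layouts, with and without ties, against the oracle
  set.seed(20)
  for (i in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- if (i %% 2) rnorm(na + nb) else sample(1:4, na + nb, TRUE)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(mannWhitneyU(a, b)$p, oracle_mwu_p(a, b),
                 tolerance = 1e-12)
  }
  ## tie-free layouts also agree with R's exact Wilcoxon
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(mannWhitneyU(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  ## large samples switch to the tie-corrected normal approximation
  set.seed(3)
  big <- mannWhitneyU(rnorm(300), rnorm(300) + 0.4)
  expect_equal(big$method, "normal-approximation")
  expect_lt(big$p, 0.001)
})

test_that("compareNumeric gates into Welch t or Mann-Whitney", {
  set.seed(30)
  a <- rnorm(200, 10); b <- rnorm(200, 10.1)
  r <- compareNumeric(a, b, "normal_feature", m = 6)
  expect_equal(r$test, "welch_t")
  expect_equal(r$threshold, 0.05 / 6)

  a2 <- rlnorm(300); b2 <- rlnorm(300, 0.8)
  r2 <- compareNumeric(a2, b2, "skewed_feature", m = 6)
  expect_equal(r2$test, "mann_whitney_u")
  expect_true(r2$significant)
  expect_equal(r2$median_a, median(a2))

  ## paper-scale log-normal shift is detected with power >= 0.9 at n = 500
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rlnorm(500, log(28913), 0.9)
    y <- rlnorm(500, log(21629), 0.9)
    compareNumeric(x, y, m = 6)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(compareNumeric(numeric(0), 1:3), "non-empty")
})

test_that("chi-squared matches the hand formula and falls back to Fisher", {
  r <- compareCategorical(213, 1301, 1004, 3451, "signal_peptide", m = 1)
  expect_equal(r$pct_a, 16.4)
  expect_equal(r$pct_b, 29.1)
  expect_equal(r$test, "chi_squared")
  ## hand Pearson: sum (O - E)^2 / E over the 2 x 2 table
  tab <- matrix(c(213, 1301 - 213, 1004, 3451 - 1004), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(r$statistic, 80.25, tolerance = 1e-3)

  r0 <- compareCategorical(50, 100, 50, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  rf <- compareCategorical(0, 10, 10, 10)
  expect_equal(rf$test, "fisher_exact")
  expect_equal(rf$p, fisher.test(matrix(c(0, 10, 10, 0), 2,
                                        byrow = TRUE))$p.value)

  expect_error(compareCategorical(5, 3, 1, 10), "exceed")

  ## random 2 x 2 tables: statistic equals the hand formula
  set.seed(41)
  for (i in 1:20) {
    k1 <- sample(20:80, 1); n1 <- 100; k2 <- sample(20:80, 1); n2 <- 120
    rr <- compareCategorical(k1, n1, k2, n2)
    tt <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    EE <- outer(rowSums(tt), colSums(tt)) / sum(tt)
    expect_equal(rr$statistic, sum((tt - EE)^2 / EE), tolerance = 1e-12)
  }
})

test_that("term enrichment is a one-tailed hypergeometric with Bonferroni inflation", {
  background <- sprintf("g%03d", 1:100)
  query <- background[1:10]
  ann <- rbind(
    data.frame(term = "all_query", gene = query),
    data.frame(term = "flat", gene = background[seq(1, 100, 2)]),
    data.frame(term = "background_only", gene = background[60:90]),
    data.frame(term = "partial", gene = c(query[1:8], background[11:20])))
  res <- termEnrichment(query, background, ann)
  expect_equal(res$term[1], "all_query")
  flat <- res[res$term == "flat", ]
  expect_gt(flat$p, 0.2)
  ## raw p equals the closed-form hypergeometric tail
  part <- res[res$term == "partial", ]
  expect_equal(part$p, oracle_hyper_p(8, 18, 100, 10), tolerance = 1e-12)
  expect_equal(part$p_bonferroni, min(1, 4 * part$p))
  expect_true(all(diff(res$p_bonferroni) >= 0))
  expect_error(termEnrichment(c("zzz"), background, ann), "subset")
})

test_that("null comparisons reject at close to the nominal rate", {
  ## 200 seeded null draws; rejection count within the binomial 99% band
  rej <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    compareNumeric(rlnorm(100, log(1000), 0.7),
                   rlnorm(100, log(1000), 0.7), m = 1)$significant
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})
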