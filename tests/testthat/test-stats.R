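test_that("enrichment test reproduces the Poisson-rate arithmetic exactly", {
  # n = 7 query bases: mu = 4000 / 4^7 = 4000/16384
  et <- enrichment_test(nSearched = 50, nFound = 0, nTemplateBases = 7)
  expect_equal(et$mu, 0.244140625, tolerance = 1e-15)
  expect_equal(et$pTrial, 1 - exp(-0.244140625), tolerance = 1e-15)
  # no templates found: upper tail at zero is 1
  expect_equal(et$pValue, 1)

  # exact binomial-sum oracle
  p <- et$pTrial
  oracle <- sum(vapply(40:100, function(k) {
    choose(100, k) * p^k * (1 - p)^(100 - k)
  }, 1.0))
  et2 <- enrichment_test(nSearched = 100, nFound = 40, nTemplateBases = 7)
  expect_equal(et2$pValue, oracle, tolerance = 1e-12)

  expect_error(enrichment_test(0, 0, 7), "nSearched")
  expect_error(enrichment_test(10, 11, 7), "nFound")
  expect_error(enrichment_test(10, 1, 6), "nTemplateBases")
})

test_that("enrichment p-value is monotone in nFound and nTemplateBases", {
  pv <- vapply(0:30, function(f) enrichment_test(30, f, 8)$pValue, 1.0)
  expect_true(all(diff(pv) <= 1e-12))  # non-increasing in nFound
  pn <- vapply(7:14, function(n) enrichment_test(50, 5, n)$pValue, 1.0)
  expect_true(all(diff(pn) <= 1e-12))  # non-decreasing in query length
})

test_that("enrichment test is calibrated under the null", {
  # cohorts of untemplated insertions in random references: rejection at
  # alpha = 0.05 should stay near nominal
  nCohorts <- 60L
  nSearched <- 25L
  set.seed(881)
  plants <- plant_insertions(nCohorts * nSearched, 5L, seed = 881,
                             templated = FALSE)
  found <- vapply(plants, function(pl) {
    qu <- build_template_query(pl$call)
    scan_templates(qu, pl$reference, pl$call)$nCandidates > 0L
  }, TRUE)
  rej <- vapply(seq_len(nCohorts), function(i) {
    f <- sum(found[seq.int((i - 1L) * nSearched + 1L, i * nSearched)])
    enrichment_test(nSearched, f, 7L)$pValue < 0.05
  }, TRUE)
  # allow 3 SE above the nominal 5% for the reduced cohort count
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / nCohorts))
})

test_that("junction_profile implements the two profile axes", {
  calls <- data.frame(offset = c(-2L, -1L, 0L, 3L))
  pr <- junction_profile(calls)
  expect_equal(pr$meanMhNoInsertion, 1.0)
  expect_equal(pr$fracInsertion2to15, 0.25)

  blunt <- data.frame(offset = c(0L, 0L, 0L))
  prb <- junction_profile(blunt)
  expect_equal(prb$meanMhNoInsertion, 0)
  expect_equal(prb$fracInsertion2to15, 0)

  # 16 bp and 1 bp insertions are outside the 2-15 window
  edge <- data.frame(offset = c(2L, 15L, 16L, 1L))
  expect_equal(junction_profile(edge)$fracInsertion2to15, 0.5)

  empty <- junction_profile(data.frame(offset = integer(0L)))
  expect_identical(empty$nJunctions, 0L)
  expect_true(is.na(empty$meanMhNoInsertion))
})

test_that("compare_frequency is symmetric under identical groups", {
  d <- data.frame(sample = paste0("s", 1:8),
                  group = rep(c("A", "B"), each = 4L),
                  batch = rep(c("b1", "b2"), 4L),
                  nSvs = rep(c(10L, 12L, 9L, 11L), 2L),
                  coverage = rep(c(100, 110, 95, 105), 2L))
  cmp <- compare_frequency(d, "A", "B")
  expect_lt(abs(cmp$logRateRatio), 0.05)
  expect_gt(cmp$pValue, 0.5)
  expect_equal(cmp$rateRatio, exp(cmp$logRateRatio))
})

test_that("compare_frequency recovers a planted 5-fold rate ratio from cohorts", {
  ratios <- c(); pvals <- c()
  for (seed in 1:6) {
    cfg <- sim_config(seed = seed, genomeLength = 3e6,
                      target = c(1400001L, 1600000L), nSamplesPerGroup = 6L,
                      meanCoverage = 6, svRatePerHaplotype = c(A = 0.5, B = 2.5))
    sim <- simulate_cohort(cfg)
    counts <- data.frame(
      sample = sim$samples$sample, group = sim$samples$group,
      batch = sim$samples$batch,
      nSvs = as.integer(count_svs_per_sample(sim$calls, sim$samples)),
      coverage = vapply(sim$samples$sample, function(s) {
        compute_coverage(sim$molecules[sim$molecules$sample == s, ],
                         sim$targets)$coverage
      }, 1.0)
    )
    cmp <- compare_frequency(counts, "A", "B")
    ratios <- c(ratios, cmp$rateRatio)
    pvals <- c(pvals, cmp$pValue)
  }
  expect_gt(exp(mean(log(ratios))), 3)
  expect_lt(exp(mean(log(ratios))), 8)
  expect_gte(mean(pvals <= 0.01), 5 / 6)
})

test_that("null p-values are approximately uniform and type I error is controlled", {
  # 20 samples per group: the size at which the Wald test's asymptotic
  # calibration holds (small cohorts are slightly liberal; see vignette)
  set.seed(99)
  nSim <- 120L
  pv <- vapply(seq_len(nSim), function(i) {
    n <- 40L
    cov <- exp(rnorm(n, log(100), 0.1))
    d <- data.frame(sample = paste0("s", 1:n),
                    group = rep(c("A", "B"), each = n / 2L),
                    batch = rep(c("b1", "b2"), n / 2L),
                    nSvs = rnbinom(n, size = 10, mu = 0.2 * cov),
                    coverage = cov)
    compare_frequency(d, "A", "B")$pValue
  }, 1.0)
  expect_gte(mean(pv > 0.01), 0.95)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort-level type I error at the planted null is controlled", {
  # rate ratio 1: p > 0.01 in at least 95% of seeded cohort runs
  pv <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = 5000L + s, genomeLength = 3e6,
                      target = c(1400001L, 1600000L), nSamplesPerGroup = 6L,
                      meanCoverage = 5, svRatePerHaplotype = c(A = 1, B = 1))
    sim <- simulate_cohort(cfg)
    counts <- data.frame(
      sample = sim$samples$sample, group = sim$samples$group,
      batch = sim$samples$batch,
      nSvs = as.integer(count_svs_per_sample(sim$calls, sim$samples)),
      coverage = vapply(sim$samples$sample, function(x) {
        compute_coverage(sim$molecules[sim$molecules$sample == x, ],
                         sim$targets)$coverage
      }, 1.0))
    compare_frequency(counts, "A", "B")$pValue
  }, 1.0)
  expect_gte(mean(pv > 0.01), 0.95)
})

test_that("compare_frequency falls back to Poisson or a large dispersion on equidispersed data", {
  set.seed(7)
  cov <- rep(100, 12)
  d <- data.frame(sample = paste0("s", 1:12),
                  group = rep(c("A", "B"), each = 6L),
                  batch = "b1",
                  nSvs = rpois(12, 20),
                  coverage = cov)
  cmp <- suppressWarnings(compare_frequency(d, "A", "B"))
  expect_true(cmp$modelUsed == "poisson_fallback" || cmp$theta > 50)
  # same qualitative inference as a plain Poisson GLM
  pfit <- stats::glm(nSvs ~ group + offset(log(coverage)), data = d,
                     family = stats::poisson())
  pp <- stats::coef(summary(pfit))["groupB", 4L]
  expect_equal(cmp$pValue > 0.01, pp > 0.01)
})

test_that("confounded batches are dropped with a flag and exposure scaling cancels", {
  d <- data.frame(sample = paste0("s", 1:8),
                  group = rep(c("A", "B"), each = 4L),
                  batch = rep(c("b1", "b2"), each = 4L),
                  nSvs = c(5L, 7L, 6L, 4L, 25L, 30L, 28L, 27L),
                  coverage = rep(100, 8))
  expect_warning(cmp <- compare_frequency(d, "A", "B"), "confounded")
  expect_true(cmp$batchDropped)

  # exposure equivariance: doubling coverage and counts together leaves
  # the log rate ratio essentially unchanged
  d1 <- d; d1$batch <- rep(c("b1", "b2"), 4L)
  c1 <- compare_frequency(d1, "A", "B")
  d2 <- d1; d2$nSvs <- 2L * d1$nSvs; d2$coverage <- 2 * d1$coverage
  c2 <- compare_frequency(d2, "A", "B")
  expect_lt(abs(c1$logRateRatio - c2$logRateRatio), 0.05)

  # zero-count group flags instability
  d0 <- d1; d0$nSvs[d0$group == "A"] <- 0L
  expect_warning(withCallingHandlers(
    compare_frequency(d0, "A", "B"),
    warning = function(w) {
      if (!grepl("zero total", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }), "zero total")
})

test_that("per-size enrichment uses the initial query length for each stratum", {
  summ <- data.frame(insertSize = c(1L, 1L, 4L, 4L, 8L),
                     nTemplateBases = c(7L, 7L, 8L, 8L, 10L),
                     found = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  enr <- enrichment_by_size(summ)
  expect_equal(enr$nTemplateBases, c(7L, 8L, 10L))
  expect_equal(enr$nSearched, c(2L, 2L, 1L))
  expect_equal(enr$nFound, c(1L, 2L, 0L))
  direct <- enrichment_test(2, 1, 7)
  expect_equal(enr$pValue[1L], direct$pValue)
})
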