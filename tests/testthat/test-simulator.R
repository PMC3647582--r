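dr33_config <- function(n = 2000, seed = 20260926, or = 0.176 / 0.076)
  cohort_config(f = 0.076, p0 = 0.10, or_stratum = or,
                n_cases = n, n_controls = n, seed = seed)

test_that("cohorts are a pure function of seed and replicate index", {
  cfg <- dr33_config(n = 500)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, replicate = 2)))
  cfg2 <- dr33_config(n = 500, seed = 1)
  expect_false(identical(a, simulate_cohort(cfg2)))
  # the generator leaves the caller's RNG stream untouched
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
  # record counts are exact
  expect_equal(table(a$status)[["case"]], 500)
  expect_equal(table(a$status)[["control"]], 500)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(0, 0.1, 2, 10, 10, 1), "\\(0, 1\\]")
  expect_error(cohort_config(0.5, 1.1, 2, 10, 10, 1), "\\(0, 1\\)")
  expect_error(cohort_config(0.5, 0.1, -2, 10, 10, 1), "positive")
  expect_error(cohort_config(0.5, 0.1, 2, 0, 10, 1), "integer")
})

test_that("estimates reduce hand-built cohorts to their 2x2 tables", {
  cohort <- data.frame(
    status = rep(c("case", "control"), c(10, 10)),
    stratum = "risk-diplotype",
    carrier = rep(c("yes", "no", "yes", "no"), c(3, 7, 8, 2)))
  est <- estimate_ors(cohort)
  expect_equal(est$overall$or, 6 / 56, tolerance = 1e-12)
  expect_equal(est$overall$p, 11720 / 167960, tolerance = 1e-12)
  # all cases in the risk stratum: stratified equals overall
  expect_equal(est$stratum$or, est$overall$or)
  expect_error(estimate_ors(cohort[cohort$status == "case", ]),
               "at least one")
})

test_that("a null stratum effect leaves the cohort at the background rate", {
  cfg <- cohort_config(f = 0.076, p0 = 0.10, or_stratum = 1,
                       n_cases = 20000, n_controls = 20000, seed = 5)
  cohort <- simulate_cohort(cfg)
  case_rate <- mean(cohort$carrier[cohort$status == "case"] == "yes")
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(case_rate - 0.10), 3 * se)
  est <- estimate_ors(cohort)
  expect_lt(abs(log(est$overall$or)), 3 * sqrt(sum(1 / unlist(
    est$overall$table[c("a", "b", "c", "d")]))))
})

test_that("large cohorts recover the exact mixing OR, not the linear one", {
  cfg <- dr33_config(n = 200000, seed = 8)
  est <- estimate_ors(simulate_cohort(cfg))
  se_log <- sqrt(sum(1 / unlist(est$overall$table[c("a", "b", "c", "d")])))
  expect_lt(abs(log(est$overall$or) - log(mixing_or(0.076, 0.10, cfg$or_stratum))),
            3 * se_log)
  # stratum-restricted analysis recovers the generative stratum OR
  se_log_s <- sqrt(sum(1 / unlist(est$stratum$table[c("a", "b", "c", "d")])))
  expect_lt(abs(log(est$stratum$or) - log(cfg$or_stratum)), 3 * se_log_s)
})

test_that("stratum log-OR is recovered across replicates without bias", {
  cfg <- cohort_config(f = 0.076, p0 = 0.10, or_stratum = 0.176 / 0.076,
                       n_cases = 20000, n_controls = 20000, seed = 314)
  logors <- vapply(1:100, function(k)
    log(estimate_ors(simulate_cohort(cfg, replicate = k))$stratum$or),
    numeric(1))
  se <- sd(logors) / sqrt(length(logors))
  expect_lt(abs(mean(logors) - log(cfg$or_stratum)), 3 * se)
})

test_that("the linear dilution prediction tracks simulated cohort ORs", {
  # moderate stratum effects: model error plus MC noise stays within 0.02
  for (or_s in c(1.1, 1.3, 1.5)) {
    cfg <- cohort_config(f = 0.076, p0 = 0.10, or_stratum = or_s,
                         n_cases = 1e6, n_controls = 1e6, seed = 17)
    est <- estimate_ors(simulate_cohort(cfg))
    expect_lt(abs(est$overall$or - dilute_or(or_s, 0.076)), 0.02)
  }
})

test_that("Monte-Carlo rejection rates behave like a valid test", {
  sp <- power_spec(400, 400)
  cfg0 <- cohort_config(f = 1, p0 = 0.10, or_stratum = 1,
                        n_cases = 400, n_controls = 400, seed = 2)
  ep <- empirical_power(cfg0, sp, replicates = 400)
  expect_lte(ep$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_length(ep$rejections, 400)
  expect_equal(ep$power, mean(ep$rejections))
})

test_that("empirical power cross-validates the exact engine", {
  # an all-stratum cohort is the two-binomial design the engine assumes
  sp <- power_spec(400, 400)
  cfg <- cohort_config(f = 1, p0 = 0.10, or_stratum = 2.5,
                       n_cases = 400, n_controls = 400, seed = 99)
  exact <- fisher_power_exact(sp, 0.10, case_freq_from_or(0.10, 2.5))
  ep <- empirical_power(cfg, sp, replicates = 500)
  expect_lt(abs(ep$power - exact),
            3 * sqrt(exact * (1 - exact) / 500))
})

test_that("cohorts round-trip through TSV", {
  cfg <- dr33_config(n = 50)
  cohort <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(cohort, path)
  expect_identical(read_cohort_tsv(path), cohort)
})
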