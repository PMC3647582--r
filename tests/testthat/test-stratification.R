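test_that("dilution and concentration reproduce the DR3/3 arithmetic", {
  expect_equal(concentrate_or(1.1, 0.076), 0.176 / 0.076, tolerance = 1e-12)
  expect_equal(round(concentrate_or(1.1, 0.076), 1), 2.3)
  expect_equal(concentrate_or(1.1, 0.38), 0.48 / 0.38, tolerance = 1e-12)
  expect_equal(dilute_or(2.3, 0.076), 1.0988, tolerance = 1e-12)
  # trivial limits
  expect_equal(dilute_or(3.7, 1.0), 3.7)
  expect_equal(dilute_or(1.0, 0.2), 1.0)
  expect_equal(concentrate_or(1.0, 0.42), 1.0)
  expect_equal(concentrate_or(1.5, 1.0), 1.5)
})

test_that("infeasible or invalid inputs are rejected", {
  expect_error(concentrate_or(0.9, 0.076), "infeasible")
  expect_error(dilute_or(2, 0), "\\(0, 1\\]")
  expect_error(dilute_or(2, 1.2), "\\(0, 1\\]")
  expect_error(dilute_or(-1, 0.5), "positive")
  expect_error(concentrate_or(-0.1, 0.5), "positive")
})

test_that("dilute and concentrate are exact inverses over a grid", {
  for (f in c(0.02, 0.076, 0.38, 0.8, 1)) {
    for (x in c(0.2, 1, 1.5, 2.3158, 10, 400)) {
      expect_equal(dilute_or(concentrate_or(dilute_or(x, f), f), f),
                   dilute_or(x, f), tolerance = 1e-12)
      expect_equal(concentrate_or(dilute_or(x, f), f), x, tolerance = 1e-12)
    }
  }
})

test_that("concentration is monotone in or_all and in f", {
  f <- 0.076
  ors <- concentrate_or(seq(1.01, 3, length.out = 50), f)
  expect_true(all(diff(ors) > 0))
  fs <- seq(0.05, 1, length.out = 40)
  expect_true(all(diff(concentrate_or(1.5, fs)) < 0))   # or_all > 1
  expect_true(all(diff(concentrate_or(0.99, fs)) > 0))  # protective flips
})

test_that("odds conversion between frequencies and ORs is self-consistent", {
  expect_equal(case_freq_from_or(0.10, 1.0), 0.10)
  expect_equal(case_freq_from_or(0.10, 1.1), 0.11 / 1.01, tolerance = 1e-12)
  expect_equal(case_freq_from_or(0.10, 0.176 / 0.076), 0.2046512,
               tolerance = 1e-6)
  for (p0 in c(0.01, 0.1, 0.5, 0.9)) {
    for (or in c(0.3, 1, 1.1, 2.3158, 12)) {
      p1 <- case_freq_from_or(p0, or)
      expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), or, tolerance = 1e-12)
    }
  }
})

test_that("the ratio convention scales the frequency directly", {
  expect_equal(case_freq_from_or(0.10, 1.1, convention = "ratio"), 0.11)
  expect_error(case_freq_from_or(0.4, 3, convention = "ratio"), "infeasible")
})

test_that("exact frequency mixing sits just below the linear model", {
  expect_equal(mixing_or(0.3, 0.2, 1.0), 1.0)
  expect_equal(mixing_or(1.0, 0.2, 1.7), 1.7, tolerance = 1e-12)
  or_dr33 <- concentrate_or(1.1, 0.076)
  expect_equal(mixing_or(0.076, 0.10, or_dr33), 1.08916, tolerance = 1e-5)
  expect_lt(mixing_or(0.076, 0.10, or_dr33), dilute_or(or_dr33, 0.076))
  # the two models agree near the null
  for (or in seq(1.0, 1.2, by = 0.02))
    expect_lt(abs(dilute_or(or, 0.076) - mixing_or(0.076, 0.10, or)), 0.005)
})

test_that("multi-stratum dilution generalises the single-stratum model", {
  expect_equal(dilute_or_multi(2.3158, 0.076), dilute_or(2.3158, 0.076))
  expect_equal(dilute_or_multi(c(2, 1.5), c(0.1, 0.2)),
               0.1 * 2 + 0.2 * 1.5 + 0.7)
  expect_error(dilute_or_multi(c(2, 2), c(0.6, 0.5)), "sum")
  expect_error(dilute_or_multi(c(2, 2), 0.5), "length")
})

test_that("or_curve emits feasible pairs and drops the rest with a notice", {
  cur <- or_curve(0.076, 1.1)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$or_stratum, 0.176 / 0.076, tolerance = 1e-12)
  expect_equal(or_curve(1.0, 1.5)$or_stratum, 1.5)
  expect_equal(or_curve(0.5, 1.0)$or_stratum, 1.0)
  expect_message(cur2 <- or_curve(c(0.05, 0.5), c(0.9, 1.2)), "infeasible")
  expect_equal(nrow(cur2), 3L)  # (0.05, 0.9) omitted
  expect_error(or_curve(numeric(0), 1.1), "non-empty")
})

test_that("scenarios solve the missing OR and round-trip through JSON", {
  sc <- stratum_scenario("DR3/3", f = 0.076, p0 = 0.10, or_all = 1.1)
  expect_equal(sc$or_stratum, 0.176 / 0.076, tolerance = 1e-12)
  sc2 <- stratum_scenario("x", f = 0.38, p0 = 0.10, or_stratum = 1.2632)
  expect_equal(sc2$or_all, dilute_or(1.2632, 0.38))
  expect_error(stratum_scenario("x", f = 0.5, p0 = 0.1), "at least one")
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  back <- read_scenario_json(path)
  expect_equal(back, sc)
})
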