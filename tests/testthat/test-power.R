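test_that("power_spec validates its fields", {
  sp <- power_spec(2000, 2000)
  expect_s3_class(sp, "power_spec")
  expect_equal(sp$alternative, "two.sided")
  expect_error(power_spec(0, 10), "integer")
  expect_error(power_spec(10, 10, alpha = 1.2), "\\(0, 1\\)")
  expect_error(power_spec(10, 10, tail_mass_tolerance = 0.01), "alpha / 100")
})

test_that("exact power equals full double-binomial enumeration", {
  cases <- list(
    list(n1 = 10, n2 = 10, p0 = 0.10, p1 = 0.90),
    list(n1 = 15, n2 = 8, p0 = 0.30, p1 = 0.70),
    list(n1 = 25, n2 = 25, p0 = 0.10, p1 = 0.45),
    list(n1 = 12, n2 = 20, p0 = 0.50, p1 = 0.50))
  for (cs in cases) {
    for (alt in c("two.sided", "greater")) {
      sp <- power_spec(cs$n1, cs$n2, alpha = 0.05, alternative = alt)
      expect_equal(fisher_power_exact(sp, cs$p0, cs$p1),
                   oracle_power(cs$n1, cs$n2, 0.05, cs$p0, cs$p1, alt),
                   tolerance = 1e-10)
    }
  }
})

test_that("the conditional rejection rule is valid: size never exceeds alpha", {
  for (n in c(10, 50, 400)) {
    for (alpha in c(0.01, 0.05)) {
      sp <- power_spec(n, n, alpha = alpha)
      expect_lte(fisher_power_exact(sp, 0.10, 0.10), alpha)
    }
  }
  expect_lte(fisher_power_exact(paper_design(), 0.10, 0.10), 0.05)
})

test_that("power increases with effect size along the OR path", {
  sp <- power_spec(300, 300)
  pows <- vapply(c(1, 1.3, 1.7, 2.2, 3, 4.5), function(or)
    fisher_power_exact(sp, 0.10, case_freq_from_or(0.10, or)), numeric(1))
  expect_true(all(diff(pows) >= -1e-9))
})

test_that("power increases with sample size up to discreteness", {
  p1 <- case_freq_from_or(0.10, 2)
  for (n in c(25, 60, 150)) {
    pw_n <- fisher_power_exact(power_spec(n, n), 0.10, p1)
    pw_2n <- fisher_power_exact(power_spec(2 * n, 2 * n), 0.10, p1)
    expect_gte(pw_2n, pw_n - 0.01)
  }
})

test_that("normal approximation reproduces its closed form and the engine", {
  sp <- paper_design()
  # diluted cohort effect, OR 1.1: concordant direction gives 0.1495 and
  # the discordant direction adds 0.0020; single-direction arithmetic is
  # the conventional 0.149
  closed_form <- local({
    d <- 0.108911 - 0.10
    pbar <- (0.108911 + 0.10) / 2
    sd0 <- sqrt(pbar * (1 - pbar) * 2 / 2000)
    sd1 <- sqrt((0.108911 * 0.891089 + 0.10 * 0.90) / 2000)
    z <- qnorm(0.975)
    pnorm((d - z * sd0) / sd1) + pnorm((-d - z * sd0) / sd1)
  })
  expect_equal(fisher_power_normal(sp, 0.10, 0.108911), closed_form,
               tolerance = 1e-12)
  expect_lt(abs(fisher_power_normal(sp, 0.10, 0.108911) - 0.149), 0.005)
  expect_equal(fisher_power_normal(sp, 0.10, 0.10), 0.05, tolerance = 1e-3)
  expect_gt(fisher_power_normal(sp, 0.10, 0.2046512), 0.999)
  # exact and asymptotic agree at this sample size on the study scenarios
  for (p1 in c(0.108911, 0.11, 0.2046512, 0.231579))
    expect_lt(abs(fisher_power_exact(sp, 0.10, p1) -
                  fisher_power_normal(sp, 0.10, p1)), 0.03)
})

test_that("allele mode doubles the number of Bernoulli trials", {
  sp10 <- power_spec(10, 12)
  sp20 <- power_spec(20, 24)
  expect_equal(fisher_power_exact(sp10, 0.1, 0.5, mode = "allele"),
               fisher_power_exact(sp20, 0.1, 0.5, mode = "carrier"),
               tolerance = 1e-12)
})

test_that("stratified power report contrasts the two designs", {
  sc <- stratum_scenario("DR3/3", f = 0.076, p0 = 0.10, or_all = 1.1)
  sp <- power_spec(500, 500)
  rep <- stratified_power_report(sc, sp)
  expect_equal(rep$analysis, c("unstratified", "stratified"))
  expect_equal(rep$or, c(1.1, 0.176 / 0.076), tolerance = 1e-12)
  expect_gt(rep$power_exact[2], rep$power_exact[1])
  # vacuous stratification: identical rows
  sc1 <- stratum_scenario("all", f = 1, p0 = 0.10, or_all = 1.5)
  rep1 <- stratified_power_report(sc1, sp)
  expect_equal(rep1$power_exact[1], rep1$power_exact[2], tolerance = 1e-12)
  # null effect: both rows at or below alpha
  sc0 <- stratum_scenario("null", f = 0.076, p0 = 0.10, or_all = 1)
  rep0 <- stratified_power_report(sc0, sp)
  expect_true(all(rep0$power_exact <= sp$alpha))
  # post-hoc stratification shrinks the case group
  repf <- stratified_power_report(sc, sp, stratified_n = "fraction")
  expect_equal(repf$n_cases, c(500L, 38L))
  expect_lt(repf$power_exact[2], rep$power_exact[2])
})
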