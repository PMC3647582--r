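#' Specify a Fisher-exact power computation
#'
#' @param n_cases,n_controls group sizes (subjects per group).
#' @param alpha significance level, in (0, 1).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}, matching \code{\link{fisher_exact}}.
#' @param tail_mass_tolerance binomial probability mass allowed to be
#'   truncated from each sampling distribution when windowing the outcome
#'   enumeration; must be far below \code{alpha} (at most
#'   \code{alpha / 100}). Default 1e-12, i.e. the reported power is exact
#'   to ~2e-12.
#' @return An object of class \code{"power_spec"}.
#' @examples
#' power_spec(2000, 2000, alpha = 0.05)
#' @export
power_spec <- function(n_cases, n_controls, alpha = 0.05,
                       alternative = c("two.sided", "less", "greater"),
                       tail_mass_tolerance = 1e-12) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  check_fraction(alpha, "alpha")
  alternative <- match.arg(alternative)
  check_positive(tail_mass_tolerance, "tail_mass_tolerance")
  if (tail_mass_tolerance >= alpha / 100)
    stop("tail_mass_tolerance must be < alpha / 100", call. = FALSE)
  structure(list(n_cases = n_cases, n_controls = n_controls, alpha = alpha,
                 alternative = alternative,
                 tail_mass_tolerance = tail_mass_tolerance),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("Fisher power spec: %d cases vs %d controls, alpha = %g (%s)\n",
              x$n_cases, x$n_controls, x$alpha, x$alternative))
  invisible(x)
}

spec_group_sizes <- function(spec, mode) {
  ## "carrier": one binary observation per subject (dominant coding);
  ## "allele": two chromosomes per subject, 2n Bernoulli trials.
  mult <- if (mode == "allele") 2L else 1L
  c(spec$n_cases * mult, spec$n_controls * mult)
}

#' Exact power of Fisher's exact test for two binomial samples
#'
#' Power under the unconditional sampling model -- exposed-case counts
#' \eqn{A \sim Bin(n_1, p_1)} and exposed-control counts
#' \eqn{C \sim Bin(n_2, p_0)} drawn independently -- of the conditional
#' (Fisher) rejection rule at level \code{alpha}. This is the construction
#' behind standard exact power software for Fisher's test.
#'
#' The joint outcome space is enumerated over binomial windows carrying at
#' least \code{1 - tail_mass_tolerance} of each margin's mass. Within each
#' conditional margin \eqn{s = a + c} the rejection region is a pair of
#' tails of the hypergeometric support, located once per margin from the
#' shared p-value rule in \code{\link{fisher_exact}}; the loop is over
#' margins, not tables, which keeps group sizes of several thousand in the
#' sub-second range.
#'
#' @param spec a \code{\link{power_spec}}.
#' @param p0 control (group 2) exposure probability, in (0, 1).
#' @param p1 case (group 1) exposure probability, in (0, 1).
#' @param mode \code{"carrier"} (default; one observation per subject) or
#'   \code{"allele"} (2n chromosomes per group).
#' @return Power in [0, 1].
#' @examples
#' fisher_power_exact(power_spec(10, 10), p0 = 0.10, p1 = 0.90)
#' @export
fisher_power_exact <- function(spec, p0, p1, mode = c("carrier", "allele")) {
  stopifnot(inherits(spec, "power_spec"))
  mode <- match.arg(mode)
  check_fraction(p0, "p0")
  check_fraction(p1, "p1")
  n <- spec_group_sizes(spec, mode)
  n1 <- n[1]; n2 <- n[2]
  tol <- spec$tail_mass_tolerance
  aw <- stats::qbinom(c(tol / 2, 1 - tol / 2), n1, p1)
  cw <- stats::qbinom(c(tol / 2, 1 - tol / 2), n2, p0)
  la <- stats::dbinom(aw[1]:aw[2], n1, p1, log = TRUE)
  lc <- stats::dbinom(cw[1]:cw[2], n2, p0, log = TRUE)
  power <- 0
  for (s in (aw[1] + cw[1]):(aw[2] + cw[2])) {
    supp <- max(0L, s - n2):min(s, n1)
    lp <- stats::dhyper(supp, n1, n2, s, log = TRUE)
    pv <- hyper_pvalues(lp, spec$alternative)
    ## attainable p-values are rationals that can equal alpha exactly;
    ## compare with relative slack so such tables reject regardless of
    ## float noise in the tail accumulation
    rej <- supp[pv <= spec$alpha * (1 + 1e-9)]
    rej <- rej[rej >= aw[1] & rej <= aw[2] &
               (s - rej) >= cw[1] & (s - rej) <= cw[2]]
    if (length(rej))
      power <- power +
        sum(exp(la[rej - aw[1] + 1L] + lc[s - rej - cw[1] + 1L]))
  }
  min(power, 1)
}

#' Normal-approximation power for two proportions
#'
#' Asymptotic cross-check of \code{\link{fisher_power_exact}}: the
#' two-sample z-test for proportions with the null standard error pooled
#' and the alternative standard error unpooled. Two-sided power sums both
#' rejection directions.
#'
#' @inheritParams fisher_power_exact
#' @return Approximate power in [0, 1].
#' @examples
#' fisher_power_normal(power_spec(2000, 2000), p0 = 0.10, p1 = 0.108911)
#' @export
fisher_power_normal <- function(spec, p0, p1, mode = c("carrier", "allele")) {
  stopifnot(inherits(spec, "power_spec"))
  mode <- match.arg(mode)
  check_fraction(p0, "p0")
  check_fraction(p1, "p1")
  n <- spec_group_sizes(spec, mode)
  n1 <- n[1]; n2 <- n[2]
  d <- p1 - p0
  pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
  sd0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  sd1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n2)
  switch(spec$alternative,
    two.sided = {
      z <- stats::qnorm(1 - spec$alpha / 2)
      stats::pnorm((d - z * sd0) / sd1) + stats::pnorm((-d - z * sd0) / sd1)
    },
    greater = {
      z <- stats::qnorm(1 - spec$alpha)
      stats::pnorm((d - z * sd0) / sd1)
    },
    less = {
      z <- stats::qnorm(1 - spec$alpha)
      stats::pnorm((-d - z * sd0) / sd1)
    })
}

#' Power report for a stratification scenario
#'
#' The central comparison of the pipeline: power of the unstratified design
#' (effect diluted to the cohort-level odds ratio) against the stratified
#' design (cases ascertained from the risk stratum, effect at the
#' within-stratum odds ratio). By default both rows keep the full
#' \code{spec} sample sizes -- the stratified row describes a cohort
#' *enriched* to the stratum; \code{stratified_n = "fraction"} instead
#' shrinks the case group to \code{f * n_cases}, describing post-hoc
#' stratification of an existing cohort.
#'
#' @param scenario a \code{\link{stratum_scenario}} with \code{or_all} set.
#' @param spec a \code{\link{power_spec}}.
#' @param convention odds-ratio-to-frequency conversion passed to
#'   \code{\link{case_freq_from_or}}.
#' @param stratified_n \code{"full"} (default) or \code{"fraction"}; see
#'   Details.
#' @param mode passed to the power engines.
#' @return A data frame with one row per analysis (\code{"unstratified"},
#'   \code{"stratified"}) and columns \code{n_cases}, \code{n_controls},
#'   \code{or}, \code{p0}, \code{p1}, \code{power_exact},
#'   \code{power_normal}.
#' @examples
#' sc <- stratum_scenario("DR3/3", f = 0.076, p0 = 0.10, or_all = 1.1)
#' stratified_power_report(sc, power_spec(2000, 2000))
#' @export
stratified_power_report <- function(scenario, spec,
                                    convention = c("odds", "ratio"),
                                    stratified_n = c("full", "fraction"),
                                    mode = c("carrier", "allele")) {
  stopifnot(inherits(scenario, "stratum_scenario"),
            inherits(spec, "power_spec"))
  convention <- match.arg(convention)
  stratified_n <- match.arg(stratified_n)
  mode <- match.arg(mode)
  ors <- c(unstratified = scenario$or_all, stratified = scenario$or_stratum)
  rows <- lapply(names(ors), function(an) {
    or <- ors[[an]]
    sp <- spec
    if (an == "stratified" && stratified_n == "fraction") {
      n_strat <- max(1L, as.integer(round(scenario$f * spec$n_cases)))
      sp <- power_spec(n_strat, spec$n_controls, spec$alpha,
                       spec$alternative, spec$tail_mass_tolerance)
    }
    p1 <- case_freq_from_or(scenario$p0, or, convention)
    data.frame(analysis = an, n_cases = sp$n_cases,
               n_controls = sp$n_controls, or = or, p0 = scenario$p0,
               p1 = p1,
               power_exact = fisher_power_exact(sp, scenario$p0, p1, mode),
               power_normal = fisher_power_normal(sp, scenario$p0, p1, mode))
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario$name
  attr(out, "convention") <- convention
  out
}
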