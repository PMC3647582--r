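#' Configure the synthetic case-control cohort generator
#'
#' The generative model mirrors the stratified-susceptibility hypothesis:
#' a binary risk-TCR carrier marker sits at the background frequency
#' \code{p0} in every control and in cases outside the risk HLA diplotype,
#' and is enriched (within-stratum odds ratio \code{or_stratum}) only in
#' cases carrying the risk diplotype, a fraction \code{f} of all cases.
#' Sampling is conditional on case-control status; population prevalence is
#' not modelled because the design never identifies it.
#'
#' @param f fraction of cases in the risk diplotype stratum, in (0, 1].
#' @param p0 background carrier frequency, in (0, 1).
#' @param or_stratum within-stratum carrier odds ratio (> 0); the case
#'   carrier frequency in the risk stratum is
#'   \code{case_freq_from_or(p0, or_stratum)}.
#' @param n_cases,n_controls cohort sizes.
#' @param seed integer seed; together with the replicate index it fully
#'   determines the cohort (see \code{\link{simulate_cohort}}).
#' @param control_f fraction of controls labelled as risk-diplotype, for
#'   realism of the stratum column only -- the control carrier frequency is
#'   \code{p0} in every stratum. Defaults to \code{f}.
#' @return An object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(f, p0, or_stratum, n_cases, n_controls, seed,
                          control_f = f) {
  check_fraction(f, "f", open_lower = TRUE, closed_upper = TRUE)
  check_fraction(p0, "p0")
  check_positive(or_stratum, "or_stratum")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  seed <- check_count(seed, "seed", min = 0L)
  check_fraction(control_f, "control_f", open_lower = TRUE,
                 closed_upper = TRUE)
  structure(list(f = f, p0 = p0, or_stratum = or_stratum,
                 p1 = case_freq_from_or(p0, or_stratum),
                 n_cases = n_cases, n_controls = n_controls,
                 seed = seed, control_f = control_f),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Cohort config: %d cases / %d controls; f = %.4g, p0 = %.3g, stratum OR = %.4g (p1 = %.4g); seed = %d\n",
    x$n_cases, x$n_controls, x$f, x$p0, x$or_stratum, x$p1, x$seed))
  invisible(x)
}

#' Simulate a case-control cohort
#'
#' Case stratum membership is Bernoulli(\code{f}); carrier status is
#' Bernoulli(\code{p1}) for risk-stratum cases and Bernoulli(\code{p0})
#' otherwise (including all controls). The RNG stream is seeded with
#' \code{seed + replicate - 1} and the caller's RNG state is untouched, so
#' replicate k of a run is reproducible in isolation, independent of
#' execution order.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param replicate replicate index (>= 1) for stream splitting.
#' @return A data frame with \code{n_cases + n_controls} rows and columns
#'   \code{status} ("case"/"control"), \code{stratum}
#'   ("risk-diplotype"/"other"), \code{carrier} ("yes"/"no").
#' @examples
#' cfg <- cohort_config(f = 0.076, p0 = 0.10, or_stratum = 2.3,
#'                      n_cases = 100, n_controls = 100, seed = 7)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  replicate <- check_count(replicate, "replicate")
  with_seed(config$seed + replicate - 1L, {
    case_risk <- stats::rbinom(config$n_cases, 1L, config$f) == 1L
    case_p <- ifelse(case_risk, config$p1, config$p0)
    case_carrier <- stats::rbinom(config$n_cases, 1L, case_p) == 1L
    ctrl_risk <- stats::rbinom(config$n_controls, 1L, config$control_f) == 1L
    ctrl_carrier <- stats::rbinom(config$n_controls, 1L, config$p0) == 1L
    data.frame(
      status = rep(c("case", "control"),
                   c(config$n_cases, config$n_controls)),
      stratum = ifelse(c(case_risk, ctrl_risk), "risk-diplotype", "other"),
      carrier = ifelse(c(case_carrier, ctrl_carrier), "yes", "no"),
      stringsAsFactors = FALSE)
  })
}

#' Overall and stratified association estimates from a cohort
#'
#' The two analyses the dilution argument contrasts. The overall table
#' pools all cases against all controls; the stratified table restricts
#' cases to the risk diplotype stratum and keeps all controls (the carrier
#' background is stratum-independent in controls).
#'
#' @param cohort a data frame as returned by \code{\link{simulate_cohort}}.
#' @param alternative passed to \code{\link{fisher_exact}}.
#' @return A list of class \code{"cohort_estimates"} with elements
#'   \code{overall} and \code{stratum}, each holding \code{table}
#'   (a \code{\link{contingency_table}}), \code{or} and \code{p}.
#' @export
estimate_ors <- function(cohort, alternative = "two.sided") {
  need <- c("status", "stratum", "carrier")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns status, stratum, carrier", call. = FALSE)
  is_case <- cohort$status == "case"
  if (!any(is_case) || !any(!is_case))
    stop("cohort must contain at least one case and one control",
         call. = FALSE)
  carrier <- cohort$carrier == "yes"
  risk <- cohort$stratum == "risk-diplotype"
  one <- function(case_sel) {
    tab <- contingency_table(
      sum(case_sel & carrier), sum(case_sel & !carrier),
      sum(!is_case & carrier), sum(!is_case & !carrier))
    list(table = tab, or = odds_ratio(tab),
         p = fisher_exact(tab, alternative))
  }
  structure(list(overall = one(is_case), stratum = one(is_case & risk)),
            class = "cohort_estimates")
}

#' @export
print.cohort_estimates <- function(x, ...) {
  for (nm in c("overall", "stratum"))
    cat(sprintf("%-8s OR = %.4g, Fisher p = %.3g\n",
                nm, x[[nm]]$or, x[[nm]]$p))
  invisible(x)
}

#' Monte-Carlo power of the chosen analysis
#'
#' Simulates \code{replicates} cohorts from \code{config} (replicate k uses
#' seed \code{config$seed + k - 1}) and reports the fraction in which the
#' chosen analysis rejects at \code{spec$alpha}. Cross-validates
#' \code{\link{fisher_power_exact}} empirically and, with
#' \code{analysis = "stratified"}, quantifies the post-hoc stratified
#' design the exact engine does not cover (random stratum case count).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param spec a \code{\link{power_spec}}; supplies \code{alpha} and the
#'   sidedness (cohort sizes come from \code{config}).
#' @param replicates number of Monte-Carlo replicates.
#' @param analysis \code{"overall"} or \code{"stratified"}.
#' @return A list of class \code{"empirical_power"} with \code{power}, the
#'   logical \code{rejections} vector, \code{replicates}, \code{analysis},
#'   \code{alpha} and the Monte-Carlo standard error \code{se}.
#' @export
empirical_power <- function(config, spec, replicates,
                            analysis = c("overall", "stratified")) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "power_spec"))
  replicates <- check_count(replicates, "replicates")
  analysis <- match.arg(analysis)
  part <- if (analysis == "overall") "overall" else "stratum"
  rejections <- vapply(seq_len(replicates), function(k) {
    est <- estimate_ors(simulate_cohort(config, replicate = k),
                        alternative = spec$alternative)
    est[[part]]$p <= spec$alpha
  }, logical(1))
  pw <- mean(rejections)
  structure(list(power = pw, rejections = rejections,
                 replicates = replicates, analysis = analysis,
                 alpha = spec$alpha,
                 se = sqrt(pw * (1 - pw) / replicates)),
            class = "empirical_power")
}

#' @export
print.empirical_power <- function(x, ...) {
  cat(sprintf(
    "Empirical power (%s analysis): %.4f (MC se %.4f, %d replicates, alpha %g)\n",
    x$analysis, x$power, x$se, x$replicates, x$alpha))
  invisible(x)
}

#' Read / write cohorts as TSV
#'
#' One subject per row, columns \code{status}, \code{stratum},
#' \code{carrier}, keeping fixtures diffable.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("status", "stratum", "carrier")
  if (!all(need %in% names(df)))
    stop("expected columns status, stratum, carrier", call. = FALSE)
  df[need]
}
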