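#' Odds-ratio dilution and concentration under HLA stratification
#'
#' When a risk allele acts only within one HLA-diplotype stratum holding a
#' fraction \code{f} of cases, the cohort-wide odds ratio is modelled as the
#' case-fraction-weighted linear mixture
#' \deqn{OR_{all} = f \, OR_{stratum} + (1 - f).}
#' \code{dilute_or} applies the model forward; \code{concentrate_or} inverts
#' it, recovering the within-stratum odds ratio that an unstratified analysis
#' has diluted. The linear mixture is a stated model, not an identity of
#' probability theory; \code{\link{mixing_or}} gives the exact cohort odds
#' ratio under carrier-frequency mixing so the approximation error is always
#' inspectable.
#'
#' @param or_stratum within-stratum odds ratio (> 0).
#' @param or_all cohort-level odds ratio; must exceed \code{1 - f} for the
#'   inversion to be feasible.
#' @param f fraction of cases carrying the risk diplotype, in (0, 1].
#' @return A numeric odds ratio (vectorised over its first argument).
#' @examples
#' concentrate_or(1.1, 0.076)  # 2.3158: a diluted 1.1 hides a stratum OR of 2.3
#' dilute_or(2.3, 0.076)       # 1.0988
#' @export
dilute_or <- function(or_stratum, f) {
  check_fraction(f, "f", open_lower = TRUE, closed_upper = TRUE)
  check_positive(or_stratum, "or_stratum")
  f * or_stratum + (1 - f)
}

#' @rdname dilute_or
#' @export
concentrate_or <- function(or_all, f) {
  check_fraction(f, "f", open_lower = TRUE, closed_upper = TRUE)
  check_positive(or_all, "or_all")
  if (any(or_all <= 1 - f))
    stop("or_all <= 1 - f: infeasible dilution under the linear model ",
         "(the stratum OR would be non-positive)", call. = FALSE)
  (or_all - (1 - f)) / f
}

#' Multi-stratum generalisation of the dilution model
#'
#' \eqn{OR_{all} = \sum_i f_i OR_i + (1 - \sum_i f_i)}, with the remainder of
#' the cohort at the null. Reduces to \code{\link{dilute_or}} for one stratum.
#'
#' @param or_strata vector of within-stratum odds ratios (> 0).
#' @param f vector of case fractions, same length, with \code{sum(f) <= 1}.
#' @return The cohort-level odds ratio under the linear mixture.
#' @export
dilute_or_multi <- function(or_strata, f) {
  if (length(or_strata) != length(f))
    stop("or_strata and f must have the same length", call. = FALSE)
  check_positive(or_strata, "or_strata")
  if (any(f <= 0) || sum(f) > 1 + 1e-12)
    stop("stratum fractions must be positive and sum to at most 1",
         call. = FALSE)
  sum(f * or_strata) + (1 - sum(f))
}

#' Case carrier frequency implied by an odds ratio
#'
#' Converts an odds ratio against a control carrier frequency \code{p0} into
#' the corresponding case carrier frequency. Two conventions are supported:
#' \describe{
#'   \item{\code{"odds"}}{the exact inversion of the odds ratio,
#'     \eqn{p_1 = OR\,p_0 / (1 - p_0 + OR\,p_0)}. This is the generative
#'     truth used by the cohort simulator.}
#'   \item{\code{"ratio"}}{frequency scaling, \eqn{p_1 = OR \, p_0},
#'     i.e. the odds ratio applied as a risk ratio. At small \code{p0} the
#'     two nearly coincide; power calculators are routinely fed frequencies
#'     obtained this way, and the published power figures this package
#'     reproduces are recovered under this convention (see the methods
#'     vignette).}
#' }
#'
#' @param p0 control carrier frequency, in (0, 1).
#' @param or odds ratio (> 0).
#' @param convention \code{"odds"} (default) or \code{"ratio"}.
#' @return Case carrier frequency in (0, 1).
#' @examples
#' case_freq_from_or(0.10, 1.1)                       # 0.108911
#' case_freq_from_or(0.10, 1.1, convention = "ratio") # 0.11
#' @export
case_freq_from_or <- function(p0, or, convention = c("odds", "ratio")) {
  convention <- match.arg(convention)
  check_fraction(p0, "p0")
  check_positive(or, "or")
  if (convention == "odds") {
    or * p0 / (1 - p0 + or * p0)
  } else {
    p1 <- or * p0
    if (any(p1 >= 1))
      stop("or * p0 >= 1: frequency-scaling convention infeasible",
           call. = FALSE)
    p1
  }
}

#' Exact cohort odds ratio under carrier-frequency mixing
#'
#' The generative counterpart of \code{\link{dilute_or}}: cases in the risk
#' stratum (case fraction \code{f}) carry the allele at \eqn{p_1} implied by
#' \code{or_stratum}, remaining cases at the background \code{p0}; the pooled
#' case frequency is \eqn{p_c = f p_1 + (1-f) p_0} and the exact cohort odds
#' ratio is \eqn{odds(p_c)/odds(p_0)}. Slightly below the linear prediction
#' for \code{or_stratum} > 1; the two agree as the effect approaches the
#' null.
#'
#' @inheritParams dilute_or
#' @param p0 control carrier frequency, in (0, 1).
#' @return The exact cohort-level odds ratio.
#' @examples
#' mixing_or(0.076, 0.10, 2.3158)  # 1.0892, vs dilute_or's 1.1000
#' @export
mixing_or <- function(f, p0, or_stratum) {
  check_fraction(f, "f", open_lower = TRUE, closed_upper = TRUE)
  check_fraction(p0, "p0")
  check_positive(or_stratum, "or_stratum")
  p1 <- case_freq_from_or(p0, or_stratum)
  pc <- f * p1 + (1 - f) * p0
  (pc / (1 - pc)) / (p0 / (1 - p0))
}

#' Stratified-vs-unstratified odds-ratio curve
#'
#' For each case fraction and each cohort-level odds ratio on a grid,
#' computes the within-stratum odds ratio recovered by stratification.
#' Infeasible pairs (\code{or_all <= 1 - f}) are omitted with a notice.
#'
#' @param f_values case fractions, each in (0, 1].
#' @param or_all_grid cohort-level odds ratios.
#' @return A data frame with columns \code{f}, \code{or_all},
#'   \code{or_stratum}, one row per feasible pair.
#' @examples
#' or_curve(c(0.076, 0.38), seq(1.0, 2.0, by = 0.25))
#' @export
or_curve <- function(f_values, or_all_grid) {
  if (length(f_values) == 0L || length(or_all_grid) == 0L)
    stop("f_values and or_all_grid must be non-empty", call. = FALSE)
  check_fraction(f_values, "f_values", open_lower = TRUE, closed_upper = TRUE)
  check_positive(or_all_grid, "or_all_grid")
  grid <- expand.grid(f = f_values, or_all = or_all_grid,
                      KEEP.OUT.ATTRS = FALSE)
  feasible <- grid$or_all > 1 - grid$f
  if (any(!feasible))
    message(sum(!feasible), " infeasible (f, or_all) pair(s) omitted")
  grid <- grid[feasible, , drop = FALSE]
  grid$or_stratum <- concentrate_or(grid$or_all, grid$f)
  rownames(grid) <- NULL
  grid
}

#' Define a stratification scenario
#'
#' Bundles a stratum label, the case fraction of the risk diplotype, the
#' background carrier frequency, and one of the two odds ratios; the missing
#' one is solved from the linear dilution model.
#'
#' @param name stratum label, e.g. \code{"DR3/3"}.
#' @param f fraction of cases carrying the diplotype, in (0, 1].
#' @param p0 control carrier frequency, in (0, 1).
#' @param or_stratum within-stratum odds ratio (optional).
#' @param or_all cohort-level odds ratio (optional). Exactly one of
#'   \code{or_stratum} / \code{or_all} may be omitted.
#' @return An object of class \code{"stratum_scenario"} with both odds
#'   ratios populated.
#' @examples
#' stratum_scenario("DR3/3", f = 0.076, p0 = 0.10, or_all = 1.1)
#' @export
stratum_scenario <- function(name, f, p0, or_stratum = NULL, or_all = NULL) {
  check_fraction(f, "f", open_lower = TRUE, closed_upper = TRUE)
  check_fraction(p0, "p0")
  if (is.null(or_stratum) && is.null(or_all))
    stop("supply at least one of or_stratum, or_all", call. = FALSE)
  if (is.null(or_stratum)) or_stratum <- concentrate_or(or_all, f)
  if (is.null(or_all)) or_all <- dilute_or(or_stratum, f)
  check_positive(or_stratum, "or_stratum")
  check_positive(or_all, "or_all")
  structure(list(name = as.character(name), f = f, p0 = p0,
                 or_stratum = or_stratum, or_all = or_all),
            class = "stratum_scenario")
}

#' @export
print.stratum_scenario <- function(x, ...) {
  cat("Stratification scenario:", x$name, "\n")
  cat(sprintf("  case fraction f  : %.4g\n", x$f))
  cat(sprintf("  control freq p0  : %.4g\n", x$p0))
  cat(sprintf("  cohort OR        : %.4g\n", x$or_all))
  cat(sprintf("  stratum OR       : %.4g\n", x$or_stratum))
  invisible(x)
}

#' Read / write a scenario as flat JSON
#'
#' Keys \code{name}, \code{f}, \code{p0}, and one or both of
#' \code{or_stratum}, \code{or_all}.
#'
#' @param path file path.
#' @return For \code{read_scenario_json}, a
#'   \code{\link{stratum_scenario}}.
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stratum_scenario(name = x$name, f = x$f, p0 = x$p0,
                   or_stratum = x$or_stratum, or_all = x$or_all)
}

#' @rdname read_scenario_json
#' @param scenario a \code{\link{stratum_scenario}}.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "stratum_scenario"))
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
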