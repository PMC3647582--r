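#' Power of an indirect association test through a tag SNP
#'
#' When the causal variant is not typed and the test is carried by a tag in
#' linkage disequilibrium with it, the squared correlation \eqn{r^2} scales
#' the information of the sample: the indirect test at sample size \eqn{n}
#' behaves like the direct test at effective size \eqn{r^2 n}. The engine
#' is run at \code{floor(r2 * n)} per group (floored at 1); \code{r2 = 0}
#' carries no information and returns \code{alpha} by convention.
#'
#' @param r2 squared tag-causal correlation, in [0, 1].
#' @param spec a \code{\link{power_spec}} describing the full design.
#' @param p0,p1 control and case exposure probabilities at the causal
#'   variant.
#' @param mode passed to \code{\link{fisher_power_exact}}.
#' @return Power in [0, 1].
#' @examples
#' sp <- power_spec(2000, 2000)
#' attenuated_power(0.3, sp, p0 = 0.10, p1 = 0.20)  # = exact power at 600/600
#' @export
attenuated_power <- function(r2, spec, p0, p1, mode = c("carrier", "allele")) {
  stopifnot(inherits(spec, "power_spec"))
  mode <- match.arg(mode)
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 < 0 || r2 > 1)
    stop("r2 must be a single value in [0, 1]", call. = FALSE)
  if (r2 == 0) return(spec$alpha)
  n1 <- max(1L, as.integer(floor(r2 * spec$n_cases)))
  n2 <- max(1L, as.integer(floor(r2 * spec$n_controls)))
  eff <- power_spec(n1, n2, spec$alpha, spec$alternative,
                    spec$tail_mass_tolerance)
  fisher_power_exact(eff, p0, p1, mode)
}

#' Summarise array coverage of a set of variants
#'
#' Mean \eqn{r^2} and the fraction of variants tagged at or above a
#' threshold -- the two summary statistics of genotyping-array coverage
#' that decide whether an indirect (array) design can stand in for direct
#' resequencing.
#'
#' @param r2_values numeric vector of squared correlations in [0, 1].
#'   Missing values are not imputed: they are dropped and reported in
#'   \code{n_missing}.
#' @param threshold coverage threshold, in [0, 1]; default 0.8, the
#'   conventional "well tagged" cutoff.
#' @param label free-text label carried through to the output.
#' @return A data frame row: \code{label}, \code{n}, \code{n_missing},
#'   \code{mean_r2}, \code{threshold}, \code{fraction_ge_threshold}.
#' @examples
#' coverage_summary(c(0.1, 0.3, 0.9, 0.8), threshold = 0.8)
#' @export
coverage_summary <- function(r2_values, threshold = 0.8, label = "coverage") {
  if (!is.numeric(r2_values))
    stop("r2_values must be numeric", call. = FALSE)
  n_missing <- sum(is.na(r2_values))
  r2 <- r2_values[!is.na(r2_values)]
  if (length(r2) == 0L)
    stop("r2_values contains no non-missing entries", call. = FALSE)
  if (any(r2 < 0 | r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  check_fraction(threshold, "threshold", open_lower = FALSE,
                 closed_upper = TRUE)
  data.frame(label = label, n = length(r2), n_missing = n_missing,
             mean_r2 = mean(r2), threshold = threshold,
             fraction_ge_threshold = mean(r2 >= threshold))
}

#' Read a per-SNP r-squared table
#'
#' TSV with header columns \code{snp_id} and \code{r2}.
#'
#' @param path file path.
#' @return A data frame with columns \code{snp_id} (character) and
#'   \code{r2} (numeric; NA allowed, validated to [0, 1] otherwise).
#' @export
read_r2_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "r2") %in% names(df)))
    stop("expected columns snp_id and r2", call. = FALSE)
  bad <- !is.na(df$r2) & (df$r2 < 0 | df$r2 > 1)
  if (any(bad))
    stop("r2 out of [0, 1] at row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  df[c("snp_id", "r2")]
}

#' Draw a synthetic tag-SNP coverage set
#'
#' Beta-distributed \eqn{r^2} values emulating exon-SNP coverage by a
#' genome-wide genotyping array. The default shapes (0.0582, 0.1358) give a
#' U-shaped distribution -- variants are typically either well tagged or
#' essentially untagged -- with mean 0.30 and a 25\% mass at
#' \eqn{r^2 \ge 0.8}, the coverage profile reported for TCR V-gene exon
#' SNPs on the classic T1D GWAS arrays.
#'
#' @param n number of variants; default 322, the size of the surveyed
#'   TRAV/TRBV exon SNP set.
#' @param shape1,shape2 Beta shape parameters.
#' @param seed integer seed; the draw is a pure function of the arguments.
#' @return Numeric vector of length \code{n} in [0, 1].
#' @export
simulate_r2_coverage <- function(n = 322, shape1 = 0.0582, shape2 = 0.1358,
                                 seed = 1) {
  n <- check_count(n, "n")
  check_positive(c(shape1, shape2), "shape parameters")
  with_seed(seed, stats::rbeta(n, shape1, shape2))
}
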