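#!/usr/bin/env Rscript
# Odds-ratio dilution under HLA-diplotype stratification: how a modest
# cohort-wide OR of 1.1 conceals a substantial within-stratum effect, and
# the stratified-vs-unstratified OR curve over a grid of cohort ORs.

suppressPackageStartupMessages(library(stratpower))
dir.create("results", showWarnings = FALSE)

p0 <- 0.10
scenarios <- list(
  stratum_scenario("DR3/3", f = 0.076, p0 = p0, or_all = 1.1),
  stratum_scenario("DR3/4-DQB1*03:02", f = 0.38, p0 = p0, or_all = 1.1))

tab <- do.call(rbind, lapply(scenarios, function(s)
  data.frame(scenario = s$name, f = s$f, or_all = s$or_all,
             or_stratum = s$or_stratum,
             or_stratum_2sf = signif(s$or_stratum, 2),
             or_mixing_check = mixing_or(s$f, s$p0, s$or_stratum))))
write.table(tab, "results/stratified_ors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

curve <- or_curve(c(0.076, 0.38), seq(1.0, 2.0, by = 0.05))
curve$scenario <- c("DR3/3", "DR3/4-DQB1*03:02")[match(curve$f, c(0.076, 0.38))]
write.table(curve, "results/or_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Concentration of a cohort OR of 1.1 by diplotype stratification:\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("  %-18s f = %.3f: stratum OR %.4f (reported %.2g)\n",
              tab$scenario[i], tab$f[i], tab$or_stratum[i],
              tab$or_stratum_2sf[i]))
cat("\nThe rarer the risk diplotype, the stronger the concealed effect:",
    "\nDR3/3 (7.6% of cases) hides a 2.3-fold OR inside a cohort-wide 1.1.\n")
cat("Exact frequency-mixing cross-check (cohort OR implied by the stratum",
    sprintf("OR):\n  DR3/3 %.4f, DR3/4 %.4f -- the linear model overstates the cohort OR\n",
            tab$or_mixing_check[1], tab$or_mixing_check[2]),
    " by < 0.012 here.\n")
cat("\nCurve written to results/or_curve.tsv (",
    nrow(curve), "feasible grid points ).\n")
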