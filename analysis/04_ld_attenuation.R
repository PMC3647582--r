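#!/usr/bin/env Rscript
# Indirect testing through imperfect tag SNPs: r-squared scales the
# effective sample size, so array-based (GWAS) designs surrender part or
# all of the stratified design's power when coverage of the TCR V-gene
# exons is poor. A synthetic coverage set calibrated to the reported
# array profile (mean r2 0.3; 25% of SNPs at r2 >= 0.8) quantifies the
# typical loss.

suppressPackageStartupMessages(library(stratpower))
dir.create("results", showWarnings = FALSE)

spec <- power_spec(2000, 2000, alpha = 0.05)
designs <- list(
  "stratified DR3/3" = case_freq_from_or(0.10, concentrate_or(1.1, 0.076)),
  "stratified DR3/4-DQB1*03:02" =
    case_freq_from_or(0.10, concentrate_or(1.1, 0.38)),
  "unstratified (cohort OR 1.1)" = case_freq_from_or(0.10, 1.1))

grid <- seq(0, 1, by = 0.1)
att <- do.call(rbind, lapply(names(designs), function(nm)
  data.frame(design = nm, r2 = grid,
             n_eff_per_group = pmax(1, floor(grid * 2000)),
             power = vapply(grid, attenuated_power, numeric(1),
                            spec = spec, p0 = 0.10, p1 = designs[[nm]]))))
write.table(att, "results/ld_attenuation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

r2 <- simulate_r2_coverage(n = 322, seed = 20260926)
summ <- coverage_summary(r2, threshold = 0.8, label = "synthetic array coverage")
write.table(summ, "results/coverage_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(as.list(summ), "results/coverage_summary.json",
                     auto_unbox = TRUE, digits = NA)

cat("Power of each design when tested indirectly through a tag SNP:\n\n")
cat(sprintf("  %-4s %s\n", "r2", paste(sprintf("%-29s", names(designs)),
                                       collapse = " ")))
for (r in grid) {
  row <- att[abs(att$r2 - r) < 1e-9, ]
  cat(sprintf("  %.1f  %s\n", r,
              paste(sprintf("%-29s", sprintf("%5.1f%% (n_eff %4d)",
                                             100 * row$power,
                                             row$n_eff_per_group[1])),
                    collapse = " ")))
}
at03 <- att[abs(att$r2 - 0.3) < 1e-9, ]
cat(sprintf("\nSynthetic coverage set (n = %d): mean r2 = %.3f, %.0f%% of SNPs at r2 >= %.1f.\n",
            summ$n, summ$mean_r2, 100 * summ$fraction_ge_threshold,
            summ$threshold))
cat(sprintf("At the mean coverage (r2 = 0.3, n_eff 600/group) the DR3/3 design still\n"))
cat(sprintf("rejects almost surely (%.1f%%), but the weaker DR3/4 stratified effect\n",
            100 * at03$power[at03$design == "stratified DR3/3"]))
cat(sprintf("falls to %.1f%% and the unstratified design to %.1f%%: only well-tagged\n",
            100 * at03$power[at03$design == "stratified DR3/4-DQB1*03:02"],
            100 * at03$power[at03$design == "unstratified (cohort OR 1.1)"]))
cat("(r2 >= 0.8) variants -- about a quarter of the coverage set -- keep\n")
cat("useful power, which argues for direct sequencing of the TCR loci.\n")
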