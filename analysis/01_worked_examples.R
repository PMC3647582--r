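#!/usr/bin/env Rscript
# Worked 2x2 examples: the two rat V-beta-13 depletion experiments.
# Depleting V-beta-13+ T cells protects against both poly I:C- and
# virus-triggered diabetes; these tables exercise the Fisher core on
# real printed counts.

suppressPackageStartupMessages(library(stratpower))
dir.create("results", showWarnings = FALSE)

tables <- list(
  "poly I:C trigger, anti-Vb13 vs control" = contingency_table(2, 18, 34, 6),
  "KRV trigger, anti-Vb13 vs control" = contingency_table(3, 7, 8, 2))

rows <- do.call(rbind, lapply(names(tables), function(nm) {
  t <- tables[[nm]]
  data.frame(experiment = nm, a = t$a, b = t$b, c = t$c, d = t$d,
             or = odds_ratio(t),
             or_ci_lower = odds_ratio_ci(t)[["lower"]],
             or_ci_upper = odds_ratio_ci(t)[["upper"]],
             p_two_sided = fisher_exact(t, "two.sided"),
             p_one_sided_less = fisher_exact(t, "less"))
}))

write.table(rows, "results/worked_examples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_tables_tsv(tables, "results/worked_example_tables.tsv")

cat("Rat depletion experiments, Fisher exact results:\n")
for (i in seq_len(nrow(rows)))
  cat(sprintf("  %-40s OR = %.3f, two-sided p = %.3g, one-sided p = %.3g\n",
              rows$experiment[i], rows$or[i], rows$p_two_sided[i],
              rows$p_one_sided_less[i]))
cat("\nThe second experiment's one-sided p (0.035) matches the printed",
    "0.03 at two\ndecimals; its two-sided p is 0.070. Protection is",
    "decisive (p < 1e-7) in the\nlarger first experiment.\n")
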