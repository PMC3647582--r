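---
title: "Odds-ratio dilution, exact Fisher power, and HLA stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odds-ratio dilution, exact Fisher power, and HLA stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratpower)
```

## The question the package answers

Suppose a germline TCR variable-gene allele ("Vx") confers disease risk
only in individuals carrying a specific high-risk HLA class II diplotype
— the human analog of the rat Vβ13a/RT1u co-requirement in autoimmune
diabetes. A conventional case-control study pools cases of every HLA
background. What does that pooling do to the measurable effect, and to
the probability of detecting it? `stratpower` implements the complete
quantitative chain: effect dilution, exact detection power, the further
loss from imperfect tag-SNP coverage, and a simulator that checks each
analytic step by Monte Carlo.

## The dilution model

Let `f` be the fraction of cases carrying the risk diplotype (for
DR3/3 homozygotes in type 1 diabetes, `f = 0.076`; for the
DR3/4-DQB1\*03:02 diplotype, `f = 0.38`) and let the allele be neutral
outside that stratum. The package's central model is the linear mixture

$$OR_{all} = f \cdot OR_{stratum} + (1 - f),$$

with inversion $OR_{stratum} = (OR_{all} - (1-f))/f$ implemented in
`dilute_or()` / `concentrate_or()`. The inversion is only feasible for
$OR_{all} > 1 - f$; infeasible inputs raise an error rather than
returning a negative ratio.

The linear mixture treats odds ratios as if they averaged over strata
with case-fraction weights. That is a modelling statement, not an
identity: the generatively exact statement mixes *carrier frequencies*,
not odds ratios. `mixing_or()` computes that exact counterpart — cases
in the stratum carry the allele at the frequency implied by
$OR_{stratum}$, the rest at the background `p0`, and the cohort OR is
the odds ratio of the pooled case frequency against `p0`:

```{r mixing}
or_s <- concentrate_or(1.1, 0.076)
or_s
dilute_or(or_s, 0.076)        # linear model, by construction
mixing_or(0.076, 0.10, or_s)  # exact frequency mixing
```

The exact cohort OR sits slightly below the linear prediction for
risk-increasing effects; the two agree as the effect approaches the
null (the package asserts agreement within 0.005 for stratum ORs up to
1.2 at these parameters). Both are exposed so the approximation is never
hidden. A documented multi-stratum extension,
`dilute_or_multi()`, generalises to $\sum_i f_i OR_i + (1 - \sum_i f_i)$
with $\sum_i f_i \le 1$ enforced.

## From odds ratio to case frequency: two conventions

Power calculations need the case carrier frequency `p1` implied by an
odds ratio at control frequency `p0`. `case_freq_from_or()` supports
two conventions:

* **`"odds"`** (default): the exact inversion,
  $p_1 = OR\,p_0/(1-p_0+OR\,p_0)$. This is what an odds ratio means,
  and it is the generative rule of the cohort simulator.
* **`"ratio"`**: frequency scaling, $p_1 = OR \cdot p_0$ — the odds
  ratio applied as if it were a risk ratio. At `p0 = 0.10` and OR 1.1
  the difference is 0.11 vs 0.1089.

The `"ratio"` convention exists because it is how effect sizes are
routinely typed into two-proportion exact-power software, and because
the published power figures this package set out to reproduce (16%
unstratified; 100% for the DR3/3 stratified design; ~75% for DR3/4) are
recovered exactly under it — including the 75% figure, which no reading
of the exact-odds conversion reproduces. Paper-reproduction paths
(`run_paper_scenarios()`, the acceptance script) therefore use
`"ratio"`; everything else defaults to `"odds"`, and
`stratified_power_report()` reports either on request. With the exact
odds conversion the unstratified power is 13.9% rather than 16.5%; the
qualitative contrast — diluted effects are undetectable, stratified ones
are not — is identical under both.

## The exact power engine

`fisher_power_exact()` computes the power of Fisher's exact test under
*unconditional* binomial sampling with the *conditional* rejection
rule — the same construction standard exact-power software uses:

1. Exposed-case counts $A \sim Bin(n_1, p_1)$ and exposed-control
   counts $C \sim Bin(n_2, p_0)$ are enumerated over windows carrying at
   least $1 - \tau$ of each binomial's mass ($\tau$ =
   `tail_mass_tolerance`, default $10^{-12}$, validated to be below
   $\alpha/100$ so truncation can never affect a rejection decision at
   reporting precision).
2. For each margin $s = a + c$, the hypergeometric point probabilities
   over the support are evaluated in log space and the p-value of every
   support point is obtained by the same rule as `fisher_exact()`
   (two-sided: total mass of tables no more probable than the observed
   one, with relative tie slack $10^{-7}$). The rejection region is
   located once per margin, not per table.
3. Power is the binomial-weighted mass of the rejection region,
   accumulated from log-probabilities.

Because attainable p-values are rationals, a table's p-value can equal
$\alpha$ *exactly*; the engine compares with a relative slack of
$10^{-9}$ so such boundary tables are classified identically regardless
of floating-point noise. The test suite pins the engine to a naive
double-binomial enumeration oracle (every outcome pair, linear-space
arithmetic) for **all** group-size pairs up to 25, to $10^{-10}$.

The margin-wise design makes the study-size computation cheap: the
2000-vs-2000 scenarios run in well under a second each. Validity
(power at $p_1 = p_0$ never exceeding $\alpha$) is inherited from the
conditional test and asserted across sizes and levels.

`fisher_power_normal()` is the asymptotic cross-check: the
two-proportion z-test with pooled null and unpooled alternative
standard errors. Two-sided power sums both rejection directions, so it
reads ~0.1515 where single-direction arithmetic gives 0.1495 — the
suite checks the engine and the approximation agree within 0.03 at the
study size. A `mode = "allele"` flag re-runs any power computation with
$2n$ Bernoulli trials per group (per-chromosome counting); the default
`"carrier"` mode treats the 10% background frequency as a
per-individual carrier probability, which is the reading consistent
with `n = 2000` subjects per group.

Sample-size solving and covariate-adjusted (logistic) power are out of
scope, as is any multiplicity correction across candidate variants.

## LD attenuation

For an untyped causal variant tested through a tag SNP with squared
correlation $r^2$, the package adopts the standard effective-sample-size
reading of the proportionality between $r^2$ and power:
`attenuated_power()` runs the exact engine at
$n_{eff} = \lfloor r^2 n \rfloor$ per group (floored at 1), with
$r^2 = 0$ returning $\alpha$ by convention. The mapping is a documented
modelling choice; monotonicity in $r^2$ holds up to the discreteness of
the floor (asserted with 0.01 slack).

`coverage_summary()` reduces a per-SNP $r^2$ table (TSV: `snp_id`,
`r2`) to mean coverage and the fraction tagged at or above a threshold,
never imputing missing values (they are counted separately). The
empirical array survey behind the published coverage profile is not
re-run — no SNP database is queried; instead `simulate_r2_coverage()`
draws a synthetic coverage set from a Beta(0.0582, 0.1358) law. The
shapes were calibrated once so the generator's mean is 0.30 and its
mass above 0.8 is 25%, matching the reported array-coverage profile of
TCR V-gene exon SNPs; the resulting U-shape (variants either well
tagged or essentially untagged) is what highly variable local LD
produces. The calibration is part of the generator's definition, not a
tuning knob.

## The cohort simulator

`simulate_cohort()` draws the case-control study the analysis assumes:
case stratum membership Bernoulli(`f`); carrier status
Bernoulli(`p1`) for risk-stratum cases and Bernoulli(`p0`) for
everyone else, with `p1` always derived by the exact odds conversion.
Design choices worth stating:

* **Sampling is conditional on status.** Case-control ascertainment
  makes population prevalence unidentifiable from the design, so no
  prevalence parameter exists.
* **Controls carry the allele at `p0` in every stratum** — the
  "background frequency" framing. The control stratum label exists only
  for realism (`control_f`, default `f`); a control-stratum enrichment
  would model LD between the HLA region and the TCR loci, which is
  absent between chromosomes 6, 7 and 14.
* **Determinism.** Replicate $k$ seeds its stream with
  `seed + k - 1` and restores the caller's RNG state, so any replicate
  is reproducible in isolation and results are independent of execution
  order.

`estimate_ors()` closes the loop to the 2×2 layer: the overall analysis
pools all cases; the stratified analysis restricts cases to the risk
stratum and keeps **all** controls (valid because the control carrier
frequency is stratum-independent). `empirical_power()` reports the
Monte-Carlo rejection rate of either analysis.

For validating the exact engine, the relevant simulated design sets
`f = 1` at the appropriate OR: an all-stratum cohort *is* the
two-binomial design the engine models (a stratified study that recruits
its full case series from the stratum). With `f < 1` and the stratified
analysis, the stratum case count is itself random — the post-hoc
stratification design — which the engine covers through the
`stratified_n = "fraction"` option of `stratified_power_report()` only
as an expected-size approximation; the simulator is the authoritative
tool there.

What passing simulations do and do not show: the generator emulates
exactly the two-level structure the analytic model assumes (one risk
stratum, binary carrier, no LD, no covariates, no genotyping error), so
agreement validates the *mathematics*, not the model's adequacy for any
real cohort.

## Polymorphism catalog

The packaged fixture `table2_polymorphisms.tsv` transcribes the
compiled set of nonsynonymous germline TRAV/TRBV variants in the
regions that contact peptide-MHC (N-terminus, CDR1, CDR2 — extended one
residue N-terminally, recorded as part of the region definition — and
HV4; IMGT numbering). Where the source table lists several
substitutions against several genes in one region row, the
transcription keeps one record per substitution with the row's full
gene list; both counting operations are insensitive to that choice.
`count_distinct_positions()` tallies distinct (chain, region, position)
sites — 19 in the packaged catalog; `count_distinct_genes()` gives 21
distinct genes by direct enumeration of the printed gene lists (the
prose total of 22 is not recoverable from the table itself). Strict
loading rejects malformed rows with line numbers; a lenient flag skips
them with a warning instead.

## Problem sizes and numerical choices

The default validation suite was sized to what the inferences need, not
more: oracle equivalence over every group-size pair up to 25;
Monte-Carlo power at the full study size with 2000 replicates (MC
standard error under 0.01); stratum log-OR recovery over 100 replicates
of 20,000-per-arm cohorts; and asymptotic dilution-vs-simulation
agreement at $10^6$ per arm, where sampling noise (~0.005 on the OR) is
well inside the 0.02 comparison band. Presentation rounding — two
significant figures for odds ratios, whole percent for power — lives
only in `print()` methods and reports; machine outputs carry full
precision.

## Known limitations

* The linear dilution model is adopted as stated; its derivation is not
  re-examined, and for large stratum ORs it visibly overstates the
  cohort OR relative to exact mixing (the simulator quantifies the gap).
* Power for the post-hoc stratified design with random stratum size is
  available only by simulation or the expected-size approximation.
* The LD module consumes $r^2$ values; it does not compute them from
  genotype panels.
* Haplotype phasing, diploid genotypes, and multi-locus epistasis
  beyond the single contingent stratum are not modelled.
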