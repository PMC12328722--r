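---
title: "Recurrence statistics for trio cohorts: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence statistics for trio cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The null model

Every test in this package reduces to one construction. Over the space
of *possible* variants — every site in a gene of a given class (coding
SNV `CS`, coding indel `CI`, intronic SNV `IS`, intronic indel `II`),
with a per-generation mutation rate and a deleteriousness score — the
mutational target of an observed variant is the total rate mass at or
above its score. If de novo events land on sites with probability
proportional to the mutation rate (the null), the ratio of the variant
target to the whole-gene target is uniform on (0, 1]. A gene's evidence
is the sum of `K` uniform residuals, an Irwin–Hall variable given `K`;
`K` is Poisson with intensity `lambda = sum_t mu_{g,t} N_t`, where
gene targets are normalized to sum to 1 per class genome-wide and `N_t`
is the cohort-wide count of qualifying class-`t` events. Because the
statistic is undefined at `K = 0`, only the conditional tail
probability `Pr(y | K >= 1) = Pr(y) / (1 - e^{-lambda})` is uniform
under the null; both are reported and ranking uses the conditional one.

Compound heterozygous configurations repeat the construction in squared
space: a configuration's target is `max(mu_{g,vM}, mu_{g,vD})^2` (the
max demands *both* alleles be deleterious; one deleterious allele may
mean carrier status), uniform relative to `mu_g^2`. The Poisson
intensity conditions on each proband's observed maternal and paternal
rare-variant counts per class, `lambda^c = sum_{tM,tD} mu_{g,tM}
mu_{g,tD} sum_j n_{M,tM,j} n_{D,tD,j}`. Conditioning is the point: the
count of *rare* inherited variants per genome depends on fine-scale
population structure, which is hopeless to model, while the positions
of very rare variants are mutation-rate-driven.

The individual-level test rescales a configuration's squared target
against the whole genome (the probability that a random configuration
anywhere is at least as surprising), takes the minimum over a proband's
`K` configuration-carrying genes, and uses the order-statistic form
`Pr = 1 - (1 - y)^K` mixed over `K ~ Poisson(lambda~)`. The mixture has
the closed form `(1 - e^{-lambda y}) / (1 - e^{-lambda})`, which equals
the truncated sum exactly (a geometric–Poisson identity; a unit test
verifies this against direct summation).

## Tunable parameters

* **Possible-space filters** (`genome_filters()`): rate-model quality
  flag required; popmax allele frequency `< 0.01` for SNV classes and
  `<= 0.001` for indel classes (dimensionless frequencies; indel space
  is count-approximated from standing variation so it uses the tighter
  bound stated for it); splice-score floor `0.05` for intronic classes
  (only the lowest-scoring intronic variants are disregarded — the
  floor is a configurable choice, set well below the 0.5 "high
  impact" convention because lower-scoring splice variants still
  validate at a non-negligible rate), no floor for coding classes.
  Observed variants are subjected to the same floors as the sites; an
  event outside the possible space neither contributes a residual nor
  counts toward `N_t`. This symmetry is essential for calibration.
* **Indel rate proxy**: indels lack a per-site rate model, so possible
  indels are binned on their score rounded to the nearest hundredth and
  cumulative *counts* act as rate mass, normalized per class at the
  genome level like every other class.
* **Irwin–Hall evaluation** (`irwin_hall_sf()`): the exact alternating
  series up to `K_switch = 30`, the normal approximation (mean `K/2`,
  variance `K/12`) above. At `K = 30` the two agree to better than
  `1e-3` absolute, while by `K = 80` the series itself loses accuracy
  to cancellation — the switch is placed where both regimes are good.
  The series is evaluated with Kahan-compensated summation and
  reflected through the symmetry point `K/2` so tails are always
  computed from the small-argument side.
* **Mixture truncation** (`poisson_mixture_pvalue()`): the Poisson sum
  stops when the remaining tail mass is below `1e-12`; since the
  survival function is bounded by 1, the truncation error is bounded by
  that mass.
* **Cauchy combination**: unweighted across coding-SNV predictors;
  boundary p-values are clamped to `[1e-15, 1 - 1e-15]`. `p = 1`
  (a gene whose only event sits at its lowest possible score) is a
  legitimate value and is clamped silently inside the pipelines.
* **Constraint weights** (`constraint_weights()`): genes sorted
  ascending by constraint, ten equal bins (remainder spread over the
  first bins, stable sort by value then gene id for reproducibility),
  weight = 10 × fraction of dominant-disease genes in the bin. The
  dominant-disease denominator counts only constraint-scored genes, so
  the mean weight over scored genes is exactly 1; unscored genes get
  weight 1 and do enter the BH list.

## Design choices where the design was open

* **Score ties**: "score >= score(v)" includes the variant's own rate,
  so targets are strictly positive; with discrete scores the null ratio
  is stochastically larger than uniform, i.e. the test errs
  conservative. Ties are never randomized.
* **Bonferroni denominator**: the number of genes actually tested
  (`K >= 1` in at least one predictor run) in the current run.
* **Predictor gaps**: a gene with no scores under one coding-SNV
  predictor is dropped from that predictor's run only; its Cauchy
  combination runs over the remaining predictors.
* **CH intensity over class pairs**: `lambda^c` sums over all 16 class
  pairs with positive gene mass, whether or not a pair contributed an
  observed configuration — the expected count must not condition on the
  observed pair types, or the null intensity would be biased downward.
* **Multiple configurations per gene** (individual test): the
  minimum-target configuration is kept, matching the at-most-one-
  configuration-per-gene assumption (`n_M n_D mu_g^2 << 1`); dropped
  configurations are logged. The cohort CH test keeps all
  configurations, which under dense toy genomes makes it measurably
  conservative (see Limitations).
* **Homozygous configurations** are admitted only for probands passing
  the consanguinity gate (parent–parent kinship < 0.15, parent–child
  kinship within 0.5 ± 0.075, at least one supporting parent–child IBD
  region each, no parent–parent IBD segment over 3 Mb); a homozygous
  allele in a consanguineous trio likely descends from a single
  ancestral mutation, violating allele independence.
* **Unphasable doubly-heterozygous sites** are excluded from both
  configurations and parental counts rather than guessed.
* **Threshold boundaries** in trio ingestion are strict inequalities
  exactly as stated (depth > 10, GQ > 20, alternate depth > 4, allele
  fraction > 0.2, caller posterior > 0.7, "over 150" de novo calls).
* **Meta-analysis stores residual lists**, not just their sums: sums
  would suffice mathematically, but lists keep the Irwin–Hall
  evaluation at the combined `K` exact under any future statistic and
  allow bounded-precision audit. Summaries are serialized at 17
  significant digits so export/import round-trips bit-exactly, and an
  order-independent fingerprint of the possible-variant space (gene ×
  class × predictor totals and score-grid digests) refuses combination
  across mismatched spaces.

## What the simulator emulates, and what it does not

`synthetic_cohort_spec()` generates genes as bags of sites: per-site
SNV rates log-normal (median 1e-8 per generation, sdlog 1, spanning
roughly two orders of magnitude as basepair-resolution rate models do);
coding-SNV predictor scores uniform marginals coupled at rho = 0.6
through a Gaussian copula (so the Cauchy combination is exercised under
the dependence it claims to handle); splice and coding-indel scores
uniform on their scales. De novo counts per proband are Poisson around
78.3 SNVs and 9.5 indels genome-wide, split between coding and
intronic space by a coding fraction of 0.025; inherited rare-variant
counts are negative binomial (size 20) to mimic population-structure
overdispersion, which the CH tests neutralize by conditioning. Spike-ins
place events in the top score quantile of a target gene and return
truth labels.

Default genes carry 150/40/400/80 possible `CS`/`CI`/`IS`/`II` sites.
Real genes have orders of magnitude more possible variants; finite site
counts leave a discreteness bias of about `1/(2·sites)` per event
(plus hundredth-rounding ties for indel classes), always in the
conservative direction. At the default sizes this keeps the de novo
calibration KS distance near 0.015 at 2,000 genes — passing tests here
bound the *analytic* machinery, and real data, being closer to
continuous, will only be better calibrated. What the simulator does not
model: nucleotide context, linkage between sites, phenotypes, caller
error modes beyond the configured filter-failure fractions, and
X-chromosome inheritance.

Problem sizes used by the test suite (chosen as the smallest cohorts at
which the distributional claims are sharp): null calibration at 2,000
genes × 300 trios (de novo) and 500 probands (individual CH test);
spike-in recovery over 20 seeded replicates of 5 carriers among 300
trios; oracle equivalence on 3-gene toy genomes with ~2,000 near-equal-
rate sites per gene against 1e6-replicate site-level resampling;
squared-target uniformity over 1e5 simulated pairs.

## Known limitations

* The cohort CH test is conservative when several configurations of one
  gene occur in one individual (dependent residuals); at realistic
  densities (`n_M n_D mu_g^2 << 1`) the effect is small, but it is
  visible on dense synthetic genomes.
* Autosomes only; no mosaicism model; no gain-of-function positional
  clustering test.
* The indel count proxy assumes standing indel variation traces the
  indel mutation rate — reasonable for very rare variants, untested for
  common ones (which the MAF filters exclude anyway).
* Gene assignment is taken from the input annotation; variants in
  overlapping genes are counted once per assigned gene id.
* With discrete score scales (hundredth-rounded indel bins) the
  conditional p-values are super-uniform rather than uniform; reported
  significance is never anti-conservative on this account.
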