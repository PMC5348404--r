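---
title: "Methods: stage-stratified expression statistics and binding-specificity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-stratified expression statistics and binding-specificity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bindspec implements two linked analyses from biomarker-driven cancer drug
discovery: stage-stratified expression statistics with permutation
empirical p-values, and a virtual-screening cascade built around a
binding-site specificity statistic. This vignette records the models, the
parameters that matter, the numerical choices, and the design decisions
taken where more than one defensible construction existed.

## The expression model

Expression values enter as a genes × samples table of non-negative,
RPKM-like quantities with per-sample stage (normal, I–IV) and group
(e.g. ancestry cohort) labels. Analyses run on the scale
`log2(x + pseudocount)`; the pseudocount defaults to 1 so that a zero
stays a zero and fold changes read directly in log2 units. The zero
handling is a convention, not a fitted choice — `log2_transform()` exposes
it because public RPKM matrices differ in how they were offset.

Three statistics are computed per gene, always within a single group:

* **One-way stage ANOVA.** The classical between/within mean-square ratio
  with its F-distribution p-value. It assumes homoscedastic, roughly
  Gaussian log-scale noise and independent samples. Degenerate input — all
  values identical, so both sums of squares vanish and F is 0/0 — raises
  an explicit error rather than returning a silent NaN.

* **Planned stage contrast.** A single-degree-of-freedom contrast on stage
  means (default Stage I vs normal, weights `c(normal = -1, I = 1)`),
  using the pooled within-group mean square from the *full* one-way model
  as the error term, with a two-sided t test on the within degrees of
  freedom. Pooling follows from running the contrast inside the one-way
  ANOVA; it borrows strength from all stages rather than subsetting to the
  two contrasted ones. The weight vector is configurable because the
  appropriate contrast depends on the staging question.

* **Permutation empirical p-value.** `n_perm` (default 1000) shuffles of
  the stage labels over the samples — sampling without replacement, i.e. a
  label permutation — each recomputing F, with

  `p_emp = #{ F_perm > f_obs } / n_perm`.

  The inequality is strict: permuted statistics tying the observed one do
  not count as exceedances, so `p_emp = 0` is a possible (and for
  overwhelming effects, expected) outcome. An add-one smoothed estimator
  `(1 + #{F ≥ f_obs}) / (1 + n_perm)`, which cannot return 0, is available
  behind `smooth = TRUE` and off by default. Permutations stay within the
  analyzed group; stage labels are never shuffled across groups, matching
  the per-group design of the analysis.

Numerical note: a permutation that happens to reproduce the observed
grouping recomputes F along a different floating-point path, so exact
mathematical ties can land on either side of `f_obs` by rounding error.
The comparison therefore uses a relative tolerance of 1e-9 when counting
exceedances; without it, sampled p-values are biased upward by roughly
half the tie probability, which the exhaustive-enumeration test on
6-sample toys detects immediately.

`run_group_analysis()` fans a master seed out to one derived seed per
(gene, group) pair (multiplicative-congruential step, kept inside 32-bit
range), so results are independent of evaluation order and reproducible
pair by pair.

**Proportion tests.** Two-by-two tables (rows = groups, columns = trait
present/absent) are summarized by the sample odds ratio `ad/bc` — with
`Inf`/`0`/`NaN` for zero-cell patterns rather than an arbitrary
continuity correction — and Fisher's exact two-sided p-value, summing the
point probabilities of all tables with the observed margins that do not
exceed the observed table's probability. The p-value is delegated to
`stats::fisher.test()`, which implements exactly that convention; the
odds ratio is computed directly because `fisher.test()` reports the
conditional-MLE estimate, which differs from `ad/bc`.

## The screening cascade

`run_screen()` executes four stages, each recorded in a survivor ledger
(input count, survivor count; survivors never increase and each stage's
input equals the previous stage's survivors):

1. **Similarity.** Compounds are parsed and canonicalized through Open
   Babel (ChemmineOB), then fingerprinted in-package: every simple
   heavy-atom path of 1–7 atoms is labelled by its element/bond-order
   sequence (direction-canonicalized) and hashed into a 1024-bit set; both
   parameters are configurable. Similarity is the Tanimoto coefficient
   `|a∧b| / |a∨b|`, and the retention threshold (default 0.6) is
   *inclusive*. The linear-path family mirrors the default of the Open
   Babel toolchain; the package's own implementation exists because the
   analysis needs defined behavior down to single-atom molecules (a
   single atom sets its length-1 path bit) and an enumerable oracle for
   tests. A light lexical validator runs before Open Babel, which
   otherwise silently repairs some malformed SMILES (e.g. `"C("` parses
   as methane); unbalanced brackets and unpaired ring closures are
   rejected with the offending token named.

2. **Dockability.** A compound survives if at least one of its docked
   poses has binding energy at or below a ceiling, default −5.0 kcal/mol —
   a conventional "binds at all" cutoff for docking scores; it is a
   configuration knob, not a fitted constant. Poses arrive as a canonical
   TSV (`compound_id, pose_id, x, y, z, energy_kcal_mol`) or as
   multi-model Vina-style PDBQT, from which each model's energy is taken
   from its `REMARK VINA RESULT` line and its center of mass (COM) is the
   mass-weighted mean of atom coordinates over standard atomic masses
   (a geometric-center mode exists behind a flag; molecular-mechanics
   packages compute mass-weighted COMs, so that is the default).

3. **Binding regions and specificity.** Pose COMs are partitioned by
   deterministic energy-ordered leader clustering: poses are processed by
   ascending energy (ties broken by compound then pose id), each joining
   the first cluster whose representative — its founding, lowest-energy
   pose — lies within the cutoff (default 4.0 Å), else founding a new
   cluster. Clusters are numbered 1..K by ascending representative
   energy, so cluster 1 is the deepest region. Leader clustering is
   standard docking-pose practice, is order-stable given the defined
   sort, and in the well-separated regime coincides with single-linkage
   connected components (a property the tests assert). Per compound, the
   representative energy in each region it reaches is the minimum member
   energy; `E1 ≤ E2` are the two lowest, `ΔE_r = E2 − E1` the specificity
   gap, and `A = (E1 + E2)/2` the energy level. Compounds reaching a
   single region have no gap; they are flagged and excluded from the
   statistical batch rather than assigned a fictitious unbound reference
   energy, which would silently dominate the ranking.

4. **Rule of five.** Violations are counted over MW > 500 Da, logP > 5,
   H-bond donors > 5, acceptors > 10. Donors are O–H/N–H hydrogens and
   acceptors are N+O counts — the original rule's conventions, chosen for
   reproducibility over pharmacophore typing. MW sums standard atomic
   masses over the explicit-hydrogen graph. logP is a deliberately coarse
   per-element additive scheme whose contribution table ships in the
   package (`logp_contributions()`): carbon and halogens positive, N/O
   strongly negative. It ranks hydrophobicity for filtering; it is not a
   calibrated partition-coefficient predictor, and the table is exposed
   precisely so the additivity is auditable. The violation allowance
   defaults to 1 (the original heuristic flags compounds with ≥ 2
   out-of-range properties); strict mode is `max_violations = 0`.

### Significance of the specificity gap

The test conditions the gap `M = ΔE_r` on the energy level `A`, in the
spirit of MA-plot-style conditional testing: for each compound, the null
center and spread are the median and `1.4826 × MAD` of `M` over the
window of the nearest 10% of the batch by `A` (at least 50 records, or
the whole batch if smaller; both floored at `epsilon = 1e-8` to survive
degenerate batches), and the reported standardized statistic is
`z = (M − center)/spread`.

The p-value, however, is *not* a normal tail. A null gap is the spacing
between the two smallest of a compound's per-region minima, and spacings
of order statistics are exponential-tailed: under a normal-tail reading
of z the background tail is underestimated by orders of magnitude, and
in simulation the planted-screen false-discovery rate collapses (the
package's test suite measures this directly — with a normal tail the
empirical FDR at q < 0.05 sits around 0.4 against a target of ≤ 0.1,
with no loss of sensitivity either way). The default one-sided p is
therefore an exponential tail calibrated by the local median:

`p = 2^(−M / median)`,

which gives exactly p = 0.5 to a gap equal to its local null median, is
strictly decreasing in `M` at fixed `A`, is invariant to global energy
translation of the batch, and in the 20-seed planted-screen benchmark
attains sensitivity ≥ 0.9 with FDR ≤ 0.1 at q < 0.05. The normal-tail
variant is retained behind `tail = "normal"` for comparison. Multiple
testing is Benjamini–Hochberg across the batch; raw p-values are emitted
alongside q. Candidates are ranked by (q, then larger gap first), with
ties in representative energies across regions resolved by cluster id
for reproducibility.

The minimum batch size for null estimation defaults to 20 multi-region
compounds; smaller batches error rather than return unstable estimates.
Whether sub-pocket regions should form a second, finer clustering level
is not resolvable from the available description of the original
procedure; the package exposes a single cutoff and notes that a
hierarchical two-level clustering would be a faithful alternative.

## What the generators emulate — and what they do not

`sim_expression()` draws each cell as `2^(baseline + shift + latent +
noise)`: a per-gene log2 baseline `N(baseline_log_mean = 5,
baseline_log_sd = 1)`, per-cell log2 noise `N(0, noise_sd = 1)`
(multiplicative on the raw scale), additive per-(group, stage) log2
shifts for planted genes, and, for anti-correlated pairs, a shared
per-sample latent factor with coefficient `a = noise_sd *
sqrt(|rho|/(1−|rho|))` and opposite signs, which yields marginal log2
correlation `rho`. The log2-normal form matches the scale on which
RPKM-style stage profiles are analyzed; the latent-factor coupling is
phenomenological, not a causal regulation model. Defaults (5 stages ×
10 samples per stage per group, two groups) mirror a modest cohort.

`sim_poses()` places K binding sites (default 4 — screening studies
typically map several candidate regions) on a well-separated grid
(pairwise ≥ 5 × scatter SD, and at least 10 Å), scatters each pose's COM
isotropically (`site_scatter_sd = 1` Å), and draws energies
`N(background_energy_mean = −7, background_energy_sd = 0.2)` kcal/mol.
Poses visit sites round-robin from a random rotation so every compound
reaches several regions. For the `specific_fraction` (default 0.05) of
compounds, all poses at one designated site are deepened by
`planted_gap` (default 3 kcal/mol ≈ 10× the background spread of
per-region minima gaps), so the planted gap is recoverable but not
trivially separable. The generator does not model pose geometry inside a
site, receptor flexibility, or correlated docking-score errors.

`sim_library()` emits a reference scaffold (a synthetic quinoline
carbohydrazide stand-in echoing aromatic-plus-hydrazide inhibitor
chemistry — not any real compound), analogs built by appending 1–
`decoration_depth` small substituent tokens (halogens only terminally,
keeping valences ordinary), and decoys decorated from an unrelated
aliphatic/ether scaffold family. This yields a graded similarity ladder
spanning the 0.6 threshold — by design some analogs fall below it — and
decoys far beneath it. Real chemical space is vastly more diverse; a
passing screen here shows the cascade's mechanics and threshold
semantics, not performance on a real vendor library.

Every generator is a pure function of its configuration and seed, and
every planted structure (effect table, site assignment, specificity
flag, family label) is returned as a truth table the tests consume.

## Problem sizes and verification

The test suite validates each operation against an independent oracle:
hand sums of squares and `stats::anova(stats::lm(...))` for the F
statistic; exhaustive enumeration over all 20 label assignments of
6-sample toys for the permutation p; brute-force hypergeometric
enumeration for Fisher's p; hand path enumeration (ethane vs ethanol)
for the fingerprint; Open Babel's own MW for the mass sums; explicit
summation over the shipped table for logP additivity; single-linkage
connected components and planted truth for clustering; and planted truth
tables for the specificity test and the full cascade.

Calibration and recovery run at deliberately moderate sizes chosen to
make the statistical checks sharp while keeping the suite quick: the
null permutation calibration uses 2,000 genes × 50 samples × 1,000
permutations (type-I error at α = 0.05 within 0.05 ± 0.015 and
Kolmogorov–Smirnov uniformity of the empirical p distribution); the
clustering and planted-screen benchmarks use 20 simulation seeds each
(exact two-site recovery; sensitivity ≥ 0.9 and FDR ≤ 0.1 at q < 0.05
for 5 planted specifics among 100 compounds). `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

## Known limitations

* The permutation engine recomputes F from group sums, which assumes the
  classical one-way layout; multi-factor designs are out of scope.
* The exponential-tail null for `ΔE_r` is calibrated by the local median
  only; a heavy-tailed *planted* background (e.g. bimodal site depths)
  would call for a two-parameter tail.
* logP is a coarse ranking descriptor; do not interpret its absolute
  values.
* Leader clustering guarantees exact site recovery only in the
  well-separated regime (inter-site distance > 2×cutoff + ~6×scatter);
  overlapping regions merge or fragment, as any single-cutoff method
  must.
* The cascade's stage order (similarity → dockability → specificity →
  rule-of-five) is the package default; the specificity and
  drug-likeness filters commute in principle and the configuration keeps
  them independent.
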