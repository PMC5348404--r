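# bindspec

Stage-stratified gene-expression statistics and binding-specificity
virtual screening, in one tidyverse-native R package.

The package serves computational groups working on target-driven cancer
drug discovery — the motivating setting is a Rho-family GTPase (RHOA)
upregulated in one patient population of gastric cancer but not another —
and implements the two computational arms such a program needs:

1. **Expression arm.** For a gene measured across tumor stages (normal,
   I–IV) within a patient group: one-way ANOVA across stages, a planned
   stage contrast (e.g. Stage I vs normal, on pooled within-group error),
   and a label-permutation empirical p-value

   `p_emp = Pr(F > f_obs) = #{ F_perm > f_obs } / n_perm`,

   where each of the `n_perm` permutations shuffles the stage labels over
   the samples (sampling without replacement) and recomputes the classical
   F statistic. Exact two-by-two proportion tests (sample odds ratio
   `ad/bc` plus Fisher's exact two-sided p) compare trait frequencies,
   such as mutation carriers, between two groups.

2. **Screening arm.** A filter cascade over a compound library:
   Tanimoto path-fingerprint similarity to a reference inhibitor
   (inclusive threshold, default 0.6) → dockability (≥ 1 docked pose at or
   below an energy ceiling) → binding-region specificity → Lipinski
   rule-of-five. Docked-pose centers of mass are clustered into binding
   regions by deterministic energy-ordered leader clustering (4 Å cutoff);
   for each compound, `E1` and `E2` are the two lowest per-region
   representative (minimum) binding energies and

   `ΔE_r = E2 − E1 ≥ 0`

   is its specificity gap — a compound that binds one region much more
   deeply than any other is region-specific. Significance of `ΔE_r` is
   assessed against an empirical conditional null estimated locally along
   the energy level `A = (E1 + E2)/2` across the screened batch, with
   Benjamini–Hochberg FDR control.

3. **Synthetic-data module.** Generators for stage-annotated expression
   matrices (planted stage/group effects, anti-correlated gene pairs),
   compound libraries (reference + graded analogs + decoys) and docking
   pose tables (Gaussian site scatter, planted specificity gaps), each
   emitting the planted truth so every statistical claim in the package is
   validated against a known ground truth.

## Worked example

Expression arm, on synthetic data with a planted Stage-I effect (up for a
RHOA-like gene, down for its anti-correlated partner) in one group only:

```r
library(bindspec)

effects <- tibble::tibble(
  gene_id = c("RHOA_like", "RHOB_like"), group = "asian",
  stage = "I", log2_shift = c(2.5, -2.5))
pairs <- tibble::tibble(gene1 = "RHOA_like", gene2 = "RHOB_like", rho = -0.8)

ds <- sim_expression(n_genes = 50, samples_per_stage = 12,
                     effects = effects, anticorr_pairs = pairs, seed = 7) |>
  log2_transform()
run_expression(ds, genes = c("RHOA_like", "RHOB_like"), n_perm = 1000, seed = 17)
#>     gene_id     group f_obs p_anova contrast_estimate p_contrast p_empirical direction
#> 1 RHOA_like     asian 3.363 0.01560             3.646    0.00272       0.016        up
#> 2 RHOA_like caucasian 0.120 0.97496             0.366    0.73181       0.974        up
#> 3 RHOB_like     asian 3.691 0.00986            -2.869    0.00120       0.004      down
#> 4 RHOB_like caucasian 0.271 0.89528             0.440    0.61333       0.908        up
```

The planted genes are significant (stage ANOVA, Stage-I contrast and
permutation p all small) in the `asian` group only, with the planted
up/down directions; in the other group all p-values are null-like.

Screening arm, on the packaged demonstration configuration (121-compound
synthetic library, simulated poses with a 3 kcal/mol specificity gap
planted in a subset of compounds):

```r
rep <- run_screen(demo_screen_config(seed = 1))
rep$ledger
#>   stage        n_in n_out
#> 1 similarity    121    31
#> 2 dockability    31    31
#> 3 specificity    31     5
#> 4 lipinski        5     5
rep$candidates
#>   compound_id top_cluster_id    e1    e2 delta_e            p           q
#> 1 ANA0044                  1 -10.2 -7.07    3.10 9.81e-09     2.10e-07
#> 2 ANA0021                  2 -10.2 -7.16    3.03 1.45e-08     2.10e-07
#> ...
```

31 of 121 compounds clear the 0.6 Tanimoto threshold, all are dockable,
and exactly the five compounds carrying the planted specificity gap
(`delta_e ≈ 3` kcal/mol against a ~0.1 kcal/mol background) survive the
specificity and rule-of-five stages. `autoplot(rep)` draws the survivor
funnel, `plot_specificity(rep$specificity)` the gap-versus-energy-level
view, and `tidy()`/`glance()` return the candidate table and one-row
summary.

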