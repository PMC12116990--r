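# microguild

Guild-based analysis of longitudinal (repeated-measures) microbiome
cohorts, with the surrounding statistical toolkit such studies need:
subject-aware co-abundance clustering, stratified permutation tests,
subject-adjusted ordination, a multi-omics screening cascade, and
guild–metabolite association.

## The scientific problem

In short dietary-intervention studies, every participant is sampled
repeatedly (here: study days −5, 0, 2, 4 and 10 around a supplement
phase), and inter-individual differences in the gut microbiome dwarf any
treatment effect — samples cluster by person, not by timepoint. Every
analysis in this package is therefore built around the subject:

* **Guild inference.** Gut bacteria operate as co-abundant functional
  groups ("guilds"). Prevalent features (present in ≥ 20% of samples) are
  correlated pairwise with the *within-subject* (repeated-measures)
  correlation

  *r* = Σᵢₜ (xᵢₜ − x̄ᵢ)(yᵢₜ − ȳᵢ) / √(Σ (xᵢₜ − x̄ᵢ)² · Σ (yᵢₜ − ȳᵢ)²),

  which removes between-person level differences before asking whether
  two organisms co-vary over time. The correlation distance 1 − *r* is
  clustered with Ward's criterion (Ward.D2), and the tree is cut from the
  top by sequential PERMANOVA (9999 permutations): a node splits only if
  its two clades differ significantly (p ≤ α, default α = 0.001);
  otherwise its members form one guild.
* **Stratified PERMANOVA.** Community-level day contrasts use a pseudo-F
  on Bray–Curtis / Jaccard / z-scored Euclidean distances, with
  permutations restricted to *within each subject* — the correct null for
  a repeated-measures design.
* **Adjusted PCoA (aPCoA).** Ordination after projecting subject identity
  out of the Gower-centered distance kernel, so timepoint structure
  becomes visible despite dominant subject effects.
* **Screening cascade.** Per feature: repeated-measures one-way ANOVA →
  Benjamini–Hochberg across features (q ≤ 0.25) → Friedman + Nemenyi
  (and/or Dunnett-versus-baseline) post-hocs to localize the affected
  days. Two-timepoint comparisons gate on Shapiro–Wilk normality to pick
  paired *t* versus exact Wilcoxon signed-rank.
* **Association.** Metabolite concentrations are regressed on
  arcsine-square-root (AST) transformed guild abundance with a subject
  random intercept (profile-likelihood ML), Wald tests, BH across all
  (guild, analyte) pairs.
* **Synthetic cohorts.** A seeded generator plants co-abundance blocks,
  feature-specific subject fingerprints, transient treatment effects and
  guild-coupled metabolites — with the ground truth returned — so every
  stage can be validated by recovery tests.

## Worked example

Simulate the default cohort (27 subjects × 5 timepoints, 120 features in
10 planted blocks of 8 plus 40 background singletons) with one guild
transiently suppressed at days 2 and 4, then run the full chain:

```r
library(microguild)

sim <- simulate_abundance(cohort_design(seed = 42), guild_spec(),
                          effect_spec(list(`1` = c(0, 0, -2, -2, 0))))
flt  <- filter_prevalent(sim$table)            # prevalence >= 20%
D    <- correlation_distance_matrix(flt$table, sim$metadata)
part <- cut_tree_to_guilds(ward_tree(D), D, alpha = 0.001,
                           n_permutations = 999, seed = 42)
max(part)
#> [1] 13
gt  <- guild_abundance(flt$table, part)
scr <- screen_features(gt, sim$metadata, baseline = "0")
head(scr[order(scr$bh_q), c("feature_id", "screen_p", "bh_q",
                            "nemenyi_p_2", "nemenyi_p_4", "nemenyi_p_10")], 3)
#>    feature_id screen_p     bh_q nemenyi_p_2 nemenyi_p_4 nemenyi_p_10
#> 4     guild_4 2.05e-07 2.67e-06    6.94e-12    4.94e-10        0.974
#> 8     guild_8 1.80e-02 7.82e-02    9.14e-01    5.65e-04        0.867
#> 11   guild_11 1.69e-02 7.82e-02    1.83e-01    1.41e-01        0.667
```

The suppressed planted block is recovered as `guild_4`: its screen q-value
passes the q ≤ 0.25 gate, and the Nemenyi post-hoc localizes the change to
days 2 and 4 (p ≈ 7e-12 and 5e-10 versus day 0) with recovery by day 10
(p = 0.97) — the transient signature that was planted. The community-level
view agrees:

```r
Ds <- sample_distance(gt, "bray_curtis")
pairwise_stratified_permanova(Ds, sim$metadata, baseline = "0",
                              n_permutations = 999, seed = 42)
#>   contrast pseudo_F     p n_samples
#> 1  0 vs -5     1.09 0.198        54
#> 2   0 vs 2     2.47 0.004        54
#> 3   0 vs 4     2.72 0.005        54
#> 4  0 vs 10     1.48 0.113        54
```

Only the day-2 and day-4 contrasts differ from baseline under
subject-stratified permutation. The a-priori power calculation used to
size such a cohort:

```r
required_n(effect_size_f = 0.3, alpha = 0.05, target_power = 0.85,
           m = 4, corr_among_rm = 0.5, nonsphericity = 1)
#> $n
#> [1] 19
#> $achieved_power
#> [1] 0.8627598
```

A complete run (simulate → filter → guilds → screen → ordinate →
associate, with a reproducibility manifest) is one call —
`run_pipeline(config, out_dir)` — or one shell command via the thin CLI in
`inst/scripts/microguild.R`.

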