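---
title: "Methods: guild-based longitudinal microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild-based longitudinal microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microguild)
```

This vignette documents the statistical models behind `microguild`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed. It
states no empirical result that the test suite does not itself compute.

## Study setting and data model

The package targets longitudinal dietary-intervention cohorts in which
every subject is sampled at a handful of ordered timepoints (the default
design: 27 subjects at study days −5, 0, 2, 4 and 10, with sex recorded as
a binary covariate). Abundance data are compositional — features ×
samples, each sample column summing to 1 — and the dominant source of
variation is the subject, not the treatment. Three invariants are enforced
at the boundary (`read_abundance_table`, `as_sample_metadata`): no missing
cells, no duplicate ids, and unique (subject, timepoint) pairs. Missing
timepoints are handled downstream by complete-case logic in each test, not
by imputation, because the statistical procedures here all have natural
complete-case forms and imputation would manufacture within-subject
structure that the stratified tests then treat as real.

## Guild inference

**Prevalence filter.** A feature is *prevalent* when it is present
(abundance strictly > 0) in at least `ceiling(min_prevalence * n_samples)`
samples; `min_prevalence` defaults to 0.20. The filter report records the
kept features' share of total abundance, since the analysis is only
credible when the prevalent set carries almost all of the community.

**Within-subject correlation.** Co-abundance is measured by the
repeated-measures correlation — the correlation of deviations from each
subject's own means. This is deliberate: across-subject (pooled Pearson)
correlation is inflated by stable inter-individual differences, and the
point of guild analysis in a repeated-measures cohort is to find organisms
that move *together over time within a person*. A `method = "pearson"`
flag exposes the pooled alternative, because the choice between the two is
a genuine analytical fork and downstream users may want the comparison.
Features with zero within-subject variance have no defined correlation;
they are assigned r = 0 (distance 1) with a warning rather than dropped,
keeping the distance matrix complete while being conservative — an
uninformative feature ends up maximally distant from nothing and close to
nothing.

**Tree and cut.** The correlation distance 1 − r (range [0, 2]) is
clustered agglomeratively with the Ward criterion on squared distances
(the `ward.D2` convention; the variant is recorded so runs are
comparable). From the root, each node's two clades are compared by
PERMANOVA on the corresponding submatrix of the feature–feature distance
matrix — the only distance structure available at that level — treating
features as observations and clade membership as the grouping. If the
clades differ (p ≤ α, default 0.001, 9999 permutations), recursion
continues into both children; otherwise the node's members form one guild.
Nodes of fewer than three members cannot be tested and stop the descent.
Each node test draws its permutations from an RNG stream derived from
(seed, node id), so the partition is invariant to traversal order.

Two consequences of this stopping rule are worth stating plainly. First,
a clade with no internal structure — however large — becomes a *single*
guild; the procedure cannot, by construction, resolve a set of mutually
uncorrelated features into singletons, because that would require
rejecting a true null. Recovery tests on synthetic data therefore show
near-clean recovery of planted co-abundant blocks while unstructured
background features coalesce into a small number of residual guilds; a
partition-wide agreement score (such as the adjusted Rand index against a
truth in which background features are singletons) is bounded well below 1
by this behaviour alone. Second, the significance rule is `p <= alpha`,
not `p < alpha`: with the add-one permutation estimator
p = (1 + b)/(1 + m), the smallest attainable p at m permutations is
1/(1 + m), so a strict inequality would be unsatisfiable whenever
1/(1 + m) equals α (e.g. α = 0.001 with m = 999) and the cut would always
return one guild.

**PERMANOVA.** The one-way pseudo-F is computed from squared distances
(`SS_total = Σ_{i<j} d²_ij / N`; `SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d²`),
with significance by label permutation and the add-one estimator so p is
never 0. With `strata`, labels are permuted only within each stratum —
within each subject for the sample-level tests — which is the exchangeable
null for repeated measures. An `exact = TRUE` mode enumerates every
distinct relabeling (two-group designs, or any within-stratum
arrangement), used by the test suite to verify the sampled estimator
against complete enumeration.

## Screening cascade

The per-feature screen is a repeated-measures one-way ANOVA with subject
as block (the classical two-way-without-replication F). A
`block_subject = FALSE` flag gives the plain one-way ANOVA, since the
original description of this kind of screen is ambiguous about blocking;
the blocked form is the default because it matches the design. BH
adjustment runs across features within one table (one omic layer, one
contrast family), and features passing q ≤ 0.25 receive post-hocs:

* **Friedman/Nemenyi** — within-subject mid-ranks; the tie-corrected
  statistic `Q = (k−1) Σ_j (R_j − n(k+1)/2)² / Σ_{ij} (r_{ij} − (k+1)/2)²`
  against χ²(k−1), then standardized mean-rank differences against the
  studentized range (q/√2 convention, infinite df) for each timepoint
  pair.
* **Dunnett versus baseline** — paired t statistics for each day against
  day 0, adjusted by the equicorrelated (ρ = ½) multivariate-t reference,
  integrated by seeded Monte Carlo (default 1e5 draws; the Monte Carlo
  error on an adjusted p is a few 1e-3, and the adjusted p is clamped to
  be at least the raw p, which the exact distribution guarantees).
* **Two-timepoint comparisons** gate on Shapiro–Wilk (Royston AS R94) at
  0.05: normal-looking paired differences use the paired t, otherwise the
  Wilcoxon signed-rank with its exact null distribution for n ≤ 25 (zero
  differences dropped; no Pratt correction) and the
  continuity-corrected normal approximation above. All tests are
  two-sided throughout, as nothing in the setting justifies a direction.

**Power.** The a-priori repeated-measures ANOVA power follows G*Power's
within-factors conventions: noncentrality λ = f²·n·m·ε/(1 − ρ),
df₁ = (m−1)ε, df₂ = (n−1)(m−1)ε, power = P(F' > F_crit) under the
noncentral F. `required_n` scans n upward and reports the first n meeting
the target together with the power achieved there.

## Ordination and community-level testing

Bray–Curtis and Jaccard (presence = abundance > 0, no pseudocount)
dissimilarities are computed by `vegan`; the z-scored Euclidean metric
(per-feature z-scores across samples, zero-variance features dropped with
a warning) serves protein- and metabolite-profile data. PCoA
Gower-centers the squared distances and eigendecomposes; axes with
negative eigenvalues are reported and discarded — no Lingoes/Cailliez
correction by default, because the analyses this package mirrors plot raw
PCoA, and a corrected ordination would not be comparable. The adjusted
variant (aPCoA) projects the covariate's indicator space out of the
kernel, `E = (I − H) G (I − H)`, leaving coordinates exactly orthogonal to
the subject space; a single-level covariate reduces identically to plain
PCoA. Pairwise day contrasts run the stratified PERMANOVA on the two days'
samples only; subjects contributing fewer than two samples to a contrast
are dropped with a warning; BH across day-pairs is off by default
(per-pair raw p is what such studies report) and available by flag.

## Guild–metabolite association

For each (guild, analyte) pair the model is
`conc = β₀ + β₁·AST(guild share) + u_subject + ε` with
`u ~ N(0, σ²_u)`, fit by maximum likelihood profiled to the variance
ratio λ = σ²_u/σ²_e. The profile is optimized in one dimension on
log λ (tolerance 1e-8) with the λ = 0 boundary (OLS) always evaluated as
a candidate, so the returned likelihood can never fall below the OLS
solution; subject blocks are inverted in closed form. Inference is a
two-sided Wald test with normal reference on the slope, and BH runs across
all pairs fit in one call. Both raw p and q are reported, since the
significance convention for this analysis in the literature is not fixed.
This is a deliberate reimplementation of the Maaslin2-style model (linear
link, AST-transformed abundance, subject random effect) rather than a
wrapper, keeping the pipeline self-contained; Maaslin2's other
normalization options are out of scope.

## The synthetic-data generator

`simulate_abundance` draws, for feature g (block k) in sample (i, t),

log x = μ_g + u_{g,i} + √ρ·z_{k,i,t}·σ_f + √(1−ρ)·ε_{g,i,t}·σ_f + δ_k(t) + s_{i,t}

then exponentiates and closes each sample to sum 1. Here ρ
(`within_guild_corr`, default 0.7) is the latent within-block correlation;
δ_k(t) are per-timepoint log-fold-changes with the baseline entry pinned
to 0 (the default effect shape is a transient change at days 2 and 4
reverting by day 10); s_{i,t} is a whole-sample intercept (σ = 0.3)
absorbed by closure. One deliberate departure from the simplest additive
formulation: the subject effect u_{g,i} is drawn *per feature and
subject* (σ_u default 1), not shared across features — a subject effect
common to all features is an additive constant on the log scale of every
feature in a sample and cancels exactly under closure, which would leave
samples with no subject fingerprint at all, contradicting the defining
empirical feature of such cohorts (samples cluster by subject in
Bray–Curtis space). Defaults: 120 features as 10 blocks of 8 plus 40
background singletons — a reduced scale chosen so the full pipeline runs
in seconds in tests; the realistic scale (~1500 features, ~170 guilds) is
a configuration, not a test default. σ_f = 1 reflects day-scale
natural-log abundance fluctuations of roughly e-fold, consistent with
published dense longitudinal microbiome series.

Two properties of the generator matter for interpreting recovery tests.
The closure plus the multiplicative subject fingerprints attenuate the
*observed* abundance-scale within-block correlation well below the latent
ρ (at the defaults, to roughly 0.3), so recovery operates in a
weak-signal regime harder than the latent parameter suggests. And because
effect sizes for guild suppression are not empirically anchored, the
defaults (|log-fold-change| ≈ 2 at the affected days) are chosen for
testability, not realism. What passing tests show is therefore that the
pipeline recovers planted co-abundance blocks, transient effects and a
planted guild–metabolite coupling under controlled conditions emulating
the design — not that it would recover any particular real-data result.
Features of real data the generator does not emulate: sequencing zeros
and depth variation (counts mode with Poisson sampling at a stated depth
is available but not the default), taxonomic correlation structure beyond
blocks, and diet-driven covariates.

Randomness is organized as one global seed feeding a named RNG stream per
component (abundance / metabolites / outcomes / each tree-cut node / each
pipeline stage), so adding a component never perturbs another's draws,
and any stage can be re-run in isolation from the manifest's recorded
derived seeds.

`simulate_metabolites` produces analytes linear in the AST-transformed
share of one target guild with subject intercepts and residual noise,
truncated at zero (concentrations cannot be negative; truncation is the
recorded rule, not censoring). `simulate_paired_outcome` produces
(baseline, follow-up) pairs with a fixed shift for exercising the
normality-gated paired tests.

## Numerical choices and degenerate inputs

* Permutation p-values always use (1 + b)/(1 + m); exact enumeration
  includes the identity, so the two coincide at full coverage.
* All-zero sample pairs under Bray–Curtis are given distance 0 with a
  warning (0/0 otherwise).
* Degenerate paired data (all differences zero) return p = 1 with an
  explicit flag rather than an error, since screening loops must survive
  constant features.
* `benjamini_hochberg` delegates to `stats::p.adjust`; `shapiro_wilk` to
  `stats::shapiro.test`; Ward clustering to `stats::hclust` — these are
  the reference implementations of the exact algorithms intended, and the
  test suite pins them against independent oracles (hand step-up
  arithmetic, an external reference value, a brute-force Lance–Williams
  agglomerator).
* The Friedman statistic is computed in its tie-corrected form directly
  (the base-R implementation omits the mid-rank tie correction) and is
  verified against `stats::friedman.test` on tie-free data.

## Validation strategy and problem sizes

The test suite validates each engine against an independent oracle at
small n (full enumeration for permutation tests and the exact Wilcoxon;
Lance–Williams for Ward; `lme4` ML for the random-intercept fit;
`vegan::adonis2` for the pseudo-F), then checks operating characteristics
by simulation at the cohort's own dimensions: type-I error of the paired
gate, Friedman, stratified PERMANOVA and the association null within
0.05 ± 0.02 (500–1000 replicates each), empirical FDR of the screen at
q ≤ 0.25 (100 replicates), silhouette improvement of subject-adjusted over
raw ordination (10 cohorts), end-to-end guild recovery (10 cohorts,
999 permutations per node), and planted-coupling recovery as the
top-ranked association (50 cohorts). These sizes keep the full suite
around a minute of compute while leaving each band's Monte Carlo error
well inside the asserted tolerance.

## Known limitations

* The tree-cut cannot split clades the PERMANOVA cannot distinguish, so
  unstructured features aggregate into residual guilds (see above); guild
  counts are only comparable between runs with the same α and m.
* The node-level PERMANOVA tests a split suggested by the same distances
  it is tested on; the procedure inherits the selection bias of all
  cluster-then-test schemes, and α is best read as a tuning knob for
  granularity rather than a calibrated error rate.
* The Wald test in the association model is asymptotic; with few subjects
  its p-values are approximate, and the BH family covers only the pairs
  in one call.
* Dunnett adjustment is Monte Carlo, not quadrature: adjusted p-values
  carry seed-dependent jitter of a few 1e-3.
* The generator's compositional closure induces weak negative dependence
  among all features; planted "independent" background features are
  therefore only approximately independent on the observed scale.
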