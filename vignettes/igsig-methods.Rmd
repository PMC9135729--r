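---
title: "Integral genomic signature modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integral genomic signature modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsig)
```

# The modeling problem

Given a labeled pharmacogenomic cohort (cell lines with expression profiles,
somatic mutations and per-drug response measurements) and a large *unlabeled*
reference cohort, igsig builds a per-drug model that scores new subjects for
likely sensitivity or resistance. The design premise is the opposite of the
usual feature-pruning instinct: correlated genomic features are deliberately
*kept* — and extra redundancy is even manufactured, via overlapping
multi-level expression features — because when a model crosses datasets
(different platforms, library preparations, sequencing depths), individual
features drop out, and a redundant signature degrades gracefully where a
minimal one collapses. The price of redundancy, score inflation, is paid back
by an explicit redundancy penalty estimated from feature co-occurrence in the
unlabeled reference cohort.

# Pipeline

## Binary featurization

Expression matrices (linear scale, genes × subjects) are quantile-normalized
(`quantile_normalize()`, via limma; ties receive the mean of their tied-rank
targets). For each gene we add 1 to every value, take the trimmed mean across
subjects (`trim_frac = 0.10` from each end, so the 10% largest and smallest
values are excluded), and form per-subject log2 fold changes
`fc = log2(x + 1) − log2(tm + 1)`. Adding 1 *before* both the trimmed mean and
the ratio keeps the transform monotone and finite at zero expression. Genes
whose fold-change SD falls below the 20th percentile of all gene SDs
(inclusive lower quantile, linear interpolation) are discarded; SDs are
computed on all genes first, then filtered.

Each surviving gene yields up to twelve *overlapping* binary features:
`Up_Levelk` contains the subjects with `fc > mu + k·sd` and `Down_Levelk`
those with `fc < mu − k·sd`, k = 1..6, with strict inequalities. A subject at
+2.5 SD is a member of levels 1 and 2. Mutation catalogs contribute a feature
per recurrently mutated gene (`gene_min = 2` subjects) and per recurrent
hotspot (`hotspot_min = 3` subjects); silent and unclassifiable variants are
ignored. These recurrence floors are package choices (the downstream
5-subject prevalence rule dominates them in practice). Features are written
and read as GMT text (`feature_id`, description, member subjects), with the
id grammar `<gene>__<kind>` so the gene is recoverable for the gene-level
selection filters.

## Response labelling

Drug response enters as Act Area (area above the dose-response curve) and/or
AUC, each derivable from the other as `1 − value`. A drug is worth modeling
only when outstanding responders exist: the AUC distribution must be
negatively skewed (moment skewness g1 < 0) and the cohort must contain more
than `min_sensitive = 20` sensitive subjects. Sensitivity cutoffs come from
the waterfall construction: Act Area values are sorted ascending, and the
cutoff sits at the point of maximal perpendicular distance to the chord
joining the first and last points (leftmost index on ties; an all-equal
vector is an error). Perpendicular rather than vertical distance is the
standard elbow construction; for monotone sorted sequences the two rarely
disagree on the argmax. The resistance cutoff is `median(ActArea) − MAD`,
with the raw (unscaled) MAD by default and the 1.4826-scaled variant behind
a flag. Labels are strict: above the sensitivity cutoff → sensitive, below
the resistance cutoff → resistant, between → intermediate.

## Feature weighting

For the sensitive direction the cohort is ranked by Act Area descending (AUC
descending for the resistant direction; metric ties broken by subject id in
C-locale order). Each feature's member set is scored by the weighted
Kolmogorov–Smirnov running sum used by gene-set enrichment analysis: hits
advance the sum by `|metric|^p / Σ_hits |metric|^p` (exponent p = 1), misses
retreat by `1/(N − n_pos)`, and the enrichment score ES is the signed
deviation of maximal absolute value. Features covering fewer than
`min_pos = 5` cohort subjects, or the whole cohort, are not tested.

Significance is calibrated by permutation: `B = 2000` random member sets of
the same size give a null ES distribution, shared across all features of
equal size through a cache whose entries are seeded deterministically by
(cohort size, set size) — results are therefore independent of feature
evaluation order and identical with caching disabled. The normalized score
is `NES = ES / mean(ES_random)` over same-sign null scores, and the p-value
is the add-one tail estimate `(1 + #[ES_random ≥ ES]) / (1 + B)`. False
discovery rates use Storey q-values with π0 estimated at λ = 0.5
(Benjamini–Hochberg available by config). Selection keeps positively
enriched features with `q < 0.1`, then applies two gene-level plausibility
filters to expression features: a gene with an Up feature at q < 0.1 *and* a
Down feature at q < 0.3 (or vice versa) is contradictory and loses all its
expression features; and a gene-side significant only at Level 1, with no
higher level reaching q < 0.3, is treated as noise. The second rule reads an
ambiguous "more than" in its source description as "less than" — the only
reading under which the rule removes noise rather than well-supported genes;
the 0.3 threshold is configurable.

The feature weight ω is the NES by default. NES normalizes enrichment across
features of very different prevalence; raw ES is available by config for
sensitivity analysis.

To guard against overfitting when training subjects are themselves scored,
`loo_weight_table()` recomputes ES/NES for the features containing a given
subject on the cohort with that subject removed (null distributions at
`(N−1, n_pos−1)` from the same cache, generated from the full ranked metric
less its last element). Feature *selection* stays frozen on full-cohort
statistics so every subject sees the same significant set. Because held-out
evaluation never consumes these scores, `train_model()` computes them only
when `config$loo = TRUE`.

## Redundancy penalty and the signature score

Feature co-occurrence is estimated on the unlabeled reference cohort as the
Otsuka–Ochiai (binary cosine) coefficient
`K_ij = |S_i ∩ S_j| / sqrt(|S_i||S_j|)` over the model's significant
features. The similarity matrix is clustered with Ward-D2 linkage on the
distance `1 − K` (clustering sees the raw K; the 0.1 floor below applies
only in the penalty sum). Correlated feature groups are extracted by an
adaptive dendrogram cut: the tree is cut at a fraction of its maximal merge
height set by `cut_depth` (default 2 → 0.90; deeper values cut lower and
yield finer clusters), and clusters smaller than `min_cluster_size = 40` are
dissolved into singletons. Two implementation choices matter here. First,
features with identical reference membership are collapsed before clustering
and always share a label — including when their cluster is dissolved — so
exact duplicates can never be separated. Second, cluster size counts
*distinct membership profiles*, which makes every clustering decision
invariant under k-fold feature cloning. Features absent from the reference
cohort cannot be assessed for co-occurrence and fall back to singleton
clusters with penalty 1.

For a subject x carrying present features P, each feature i ∈ P is penalized
by the summed similarity of its same-cluster companions in P:
`ε_i = Σ_{j∈P, cluster(j)=cluster(i)} K'_ij`, where `K'` zeroes entries
below the 0.1 floor (self-similarity stays 1). ε runs from 1 (no redundancy)
to |P| (all features identical). With `ε̄_T` the trimmed mean of the present
penalties (trim = 0.3) and `n` the **total** number of significant features
in the model, the effective feature number is `EFN = n / ε̄_T` and the score
is

  score(x) = Σ_{i∈P} (ω_i / ε_i) / EFN .

`n` is the model's feature count, not the subject's: the score scales with
how much of the signature a subject carries, while k-fold duplication of
every feature provably cancels (each ε scales by k, the per-feature
effective weights shrink by k but appear k times, and ε̄_T scales by k). The
trimmed mean uses a mass-based fractional trim — `trim·n` observations'
worth of mass removed from each end, boundary observations fractionally
weighted — rather than the classical floor(trim·n) rule, because only the
fractional version is *exactly* invariant under replication (the two
coincide whenever trim·n is integral). Sensitive and resistant scores are
computed separately from their own weight tables; subjects carrying no
significant features score 0.

## Training, application, evaluation

`train_model()` chains eligibility, labelling, both weighting directions,
and the similarity model (built once over the union of both directions'
significant features; optional drug-target ablation removes all features of
listed genes before weighting). `apply_model()` carries only the training
weights to a new cohort: subject features are intersected with the model's
(features missing from the new feature space contribute nothing), and the
penalty can be re-estimated against a different reference cohort — e.g. a
tumor-type-restricted one — without touching the weights. Models serialize
to JSON (weights, cluster assignments, the significant features' reference
memberships, config, provenance) at 17 significant digits, so doubles
round-trip bit-exactly and `apply(load(save(m)))` equals `apply(m)`.

Evaluation treats sensitive subjects as positives and pools intermediate
with resistant as negatives; AUROC is the tie-corrected rank statistic and
the reported cutpoint maximizes Youden's J (both via pROC). Benchmarking
uses label-stratified 80/20 train/test splits, five repeats, sensitive
fractions balanced within one subject per class. `composite_score()`
combines several models' standardized sensitive scores by a logistic fit on
the provided labels (unweighted mean by config); the combination rule is a
package choice, as no canonical one exists for this method family.

# The synthetic cohort generator

`simulate_cohort()` draws log2 expression from a block-exchangeable Gaussian
model: `n_blocks = 10` blocks of `block_size = 15` genes with within-block
correlation `rho = 0.5`, remaining genes independent. A latent responder
state ties genotype to response: each subject is a responder with probability
`activation_rate = 0.15`, and within responders each of the
`n_causal_blocks = 5` causal blocks activates independently with probability
`coactivation = 0.8`. Activation shifts the block's log2 expression by
`expr_shift = 3` and adds `effect_size × noise_sd` to Act Area per active
block (`effect_size = 1.5`, `noise_sd = 0.10`, baseline 0.05, clamped to
[0, 1]); AUC is `1 − ActArea`. Sparse passenger mutations
(`mutation_rate = 0.004` per gene-subject) and two recurrent hotspots are
added independently of response unless `mutation_effect > 0`. An independent
reference cohort (`n_reference = 200`) is drawn from the same law. The
coupled causal blocks are the point: they reproduce the many-correlates-of-
one-phenotype redundancy the method exploits, both across genes within a
block and across the overlapping expression levels of each shifted gene; the
3-log2-unit shift makes responders detectable at several levels at once, the
way a distinct cellular state separates on an expression array. Defaults
were fixed from these considerations, not fitted.

What the generator does *not* emulate: count-based noise (negative binomial
dispersion, library-size effects), batch structure beyond random membership
dropout, copy-number or fusion features, and confounded clinical covariates.
Passing tests on synthetic cohorts therefore demonstrate the statistical
machinery — recovery of planted signal, FDR calibration, redundancy
tolerance — not performance on any real platform.

`corrupt_cohort()` deletes each (feature, subject) membership independently
with a given probability, emulating per-sample detection loss during
cross-dataset transfer; empty features disappear.

# Numerical choices and degenerate inputs

* Strict inequalities at every level/label boundary; boundary ties are
  measure-zero on continuous data.
* Ranking ties broken by subject id (radix order); leftmost index on tied
  running-sum maxima and waterfall distances.
* All-zero hit weights in the K-S sum (possible when the ranking metric is
  zero for every member) fall back to equal increments `1/n_pos`.
* A degenerate permutation null (same-sign mean ≈ 0) leaves NES undefined;
  the feature is dropped with a warning.
* Constant response vectors: skewness undefined (warning, ineligible);
  waterfall errors.
* Empty weight tables are valid (warning; such a direction scores 0), but
  training fails only when both directions are empty.
* Cohorts of ≤ 2 subjects cannot be left-one-out corrected (error); fold
  changes need ≥ 3 subjects.

# Problem sizes used in the shipped checks

The test-suite benchmark trains on 300 subjects and evaluates on 100
(5 seeds, 600 genes, B = 2000 permutations); null calibration uses
150-subject cohorts with 200 features at B = 500 over 20 seeds; the K-S and
waterfall oracles enumerate cohorts of up to 8 subjects exhaustively and 500
random vectors respectively. `scripts/acceptance.R` reruns the benchmark,
the null calibration (5 seeds) and a 3-fold duplication audit from a single
command-line seed.

# Known limitations

* The adaptive dendrogram cut is a deliberately simple stand-in for
  fully dynamic branch-by-branch cluster detection; its `cut_depth`
  fractions are heuristic, and very unbalanced trees may merge groups a
  dynamic method would split (the penalty floor limits the damage).
* Storey's π0 at a single λ is slightly conservative for small feature sets;
  switch to BH if the tested family is tiny.
* The logistic composite assumes roughly monotone score-response
  relationships and needs labels; use the mean combiner otherwise.
* Eligibility, waterfall cutoffs and weighting all assume a single
  measurement per subject per drug; replicate measurements must be collapsed
  upstream.
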