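---
title: "Inferring microbial co-occurrence networks with compositionality-aware significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial co-occurrence networks with compositionality-aware significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebootnet)
```

## The problem

Marker-gene surveys report *relative* abundances: each sample's taxon
counts are divided by the sample total, so they sum to one. This closure
makes the entries of a sample mutually dependent — when one organism
blooms, every other relative abundance must fall — and naive correlation
analysis of such data reports associations that reflect the sum
constraint rather than ecology. `rebootnet` infers signed co-occurrence
(positive) and co-exclusion (negative) networks between microbial clades
across many subjects while explicitly discounting this compositional
artifact.

Nodes of the inferred network are *(clade, body site)* features: the same
genus observed in two habitats is two nodes, so the network can express
both within-habitat partnerships and cross-habitat correspondences.

## The inference pipeline

The pipeline (`run_pipeline()`) mirrors the standard design for this
class of analysis:

1. **Input and filtering** (`read_count_table()`, `filter_rare_taxa()`,
   `flag_suspect_samples()`): taxa must be supported by at least 2
   sequences in at least 2 samples (defaults; configurable). A sample is
   *suspect* when its most abundant taxon carries fewer than 1% of the
   sequences that taxon reaches in the sample where it peaks. This
   compares against the taxon's **global maximum** — the sentence
   defining the rule also admits a within-sample reading, so the
   threshold and the comparison are both exposed as parameters.
2. **Clade aggregation** (`aggregate_clades()`): every ancestor of an
   observed lineage (family, order, … up to domain) is added as the sum
   of its terminal descendants, so associations can be detected between
   whole clades, not only terminal phylotypes. Aggregation and
   normalization commute (dividing by the per-sample leaf total rescales
   ancestors by the same factor), so either order is valid; both are
   supported and property-tested.
3. **Composite matrix** (`build_composite()`): rows are
   `lineage@body_site` features, columns are subject–visit points (a
   subject sampled twice contributes two columns). Rows whose zero (or
   missing) fraction strictly exceeds 2/3 are dropped — the boundary row
   is kept. Missing body-site observations are `NA` and are dropped
   pairwise downstream, with a minimum of 10 jointly observed columns
   per scored pair.
4. **Ensemble scoring** (`candidate_edges()`): Pearson and Spearman
   correlations plus Bray–Curtis and symmetrized Kullback–Leibler
   dissimilarities. Each measure nominates its top- and bottom-ranking
   edges (defaults 1,000 each) in its native ordering; measures are
   never mixed on a common scale. Pairs of lineages in
   ancestor/descendant relation are excluded *within* a body site
   (their values are arithmetically dependent through aggregation) but
   allowed across sites.
5. **ReBoot significance** (`reboot_edges()`): described below.
6. **GBLM compendium** (`gblm_compendium()`): described below.
7. **Merging** (`assemble_network()`): evidence from every
   (method × dataset) source is combined per edge with Simes' method,
   corrected across edges with Benjamini–Hochberg–Yekutieli, and
   filtered to q ≤ 0.05, at least two supporting sources, and a
   non-zero direction vote.
8. **Network statistics** (`degree_stats()`, `mcl_cluster()`,
   `network_modularity()`, enrichment tests) and **distance
   annotation** (`annotate_edges()`).

Dataset labels (e.g. two clinical centers) partition the data into
independent evidence sets that only meet again at the merge — systematic
center differences therefore weaken support counts instead of creating
artifact edges.

## ReBoot: permutation–renormalization with a bootstrap

For each candidate edge the scheme builds two distributions:

* a **bootstrap** of the observed score (columns resampled with
  replacement), giving a confidence distribution around the observed
  association, and
* a **null** in which one member of the pair (the lexicographically
  second feature; a symmetric option is available) is permuted across
  samples, after which every sample of that feature's body-site block is
  renormalized back to its constant sum at the terminal-phylotype level
  and clade features re-derived as sums over their terminal descendants.

Permutation destroys any real association; renormalization reintroduces
the sum constraint. The null therefore carries exactly the association
that compositionality alone would produce. The p-value is an upper-tail
pooled-variance z-test of the bootstrap mean against the null
distribution — the paper-trail statistic "jointly pooled standard
deviation" admits several formalizations, and the two-sample pooled
z-test on the distribution means is the one implemented; it is isolated
in `pooled_z_pvalue()` so alternatives can be swapped.

Bray–Curtis and Kullback–Leibler are intrinsically robust to closure, so
their nulls are plain permutations summarized as a point null
(`point_null_pvalue()` compares the bootstrap to the permutation mean).

P-values are then **tail-adjusted** (`tail_adjust()`) so that oriented
p < 0.5 always means co-presence and p > 0.5 exclusion — for
dissimilarities the tail flips because a *low* score means co-presence.
Edges whose observed score falls outside the central 95% bootstrap
interval are unstable and removed (`stability_filter()`), and a
leave-one-out influence check (`influence_check()`) automates the
removal of associations driven by a single extreme sample, replacing
any manual curation step with a reproducible rule.

### What the renormalized null does and does not correct

The package's operating-characteristics suite (`reboot_null_fpr()`,
`reboot_power()`) makes the scheme's scope explicit. On synthetic data
with no planted associations and one dominant high-variance taxon:

* For pairs **involving the confounder**, the observed correlation is
  strongly negative purely through closure. The renormalized null mean
  tracks that bias almost exactly, so the test stays near its nominal
  level, while a naive (non-renormalized) permutation null sits at zero
  and calls essentially every such pair a spurious co-exclusion.
* For **background pairs**, closure also induces a *positive* bias (all
  passive taxa share the denominator the confounder inflates). This
  bias survives single-row permutation regardless of renormalization —
  both nulls sit near zero there, and the two tests behave identically.
  No single-row permutation scheme can remove it; it is a known
  limitation, and it is why the FPR suite evaluates the test where
  compositionality acts: all tested pairs are half
  confounder-involving, half background.

The suite's default conditions are 50 taxa, 200 samples, sequencing
depth 10,000, 100 permutations and bootstraps per edge, and 20
simulation replicates; the full pipeline defaults to 1,000 resampling
iterations per edge. The confounder emulates a moderately dominant
signature taxon — median share near 10% of the community with
several-fold swings between subjects (log-normal with log-sd 1.2).
Under an extreme dominant organism (the 1–97% range that the most
skewed gut communities reach) the background-pair bias overwhelms any
permutation test; the suite documents this rather than hiding it.

## Generalized boosted linear models

The second, complementary evidence channel fits one sparse linear model
per (source site, target site, target clade): the target's relative
abundance is predicted from the source site's features. Safeguards
against this very high-dimensional regression:

* **Prefilter** (`prefilter_sources()`): only sources with nominally
  significant Spearman correlation (p < 0.05) against the target enter;
  when source and target site coincide, the target and all its
  ancestors/descendants are excluded so a clade is never "predicted"
  from abundances it is arithmetically part of.
* **Component-wise L2 boosting** (`boost_linear()`): starting from the
  intercept, each round fits every candidate predictor alone to the
  current residuals and commits a fraction ν = 0.1 of the best
  coefficient. The iteration count (50, 100, or 150) is chosen by
  10-fold cross-validation on held-out RMSE (`cv_select()`); AUC for
  binary targets fitted by the logistic variant (`boost_logistic()`).
  The learning rate is not dictated by the source material; 0.1 is the
  conventional choice for component-wise boosting and is configurable.
* **Quality rules**: AUCs below 0.5 are reflected (`model_quality()`),
  the reported score is the minimum of cross-validated and nominal, and
  continuous models must achieve a positive adjusted R²
  (`adjusted_r2()`, the standard 1 − (1 − R²)(n − 1)/(n − p − 1)
  penalty with p the number of selected predictors).
* **Significance** (`gblm_significance()`): the model is refit on 20
  bootstrap resamples (discarded if the observed adjusted R² leaves the
  central 90% interval) and on 20 permutations of the target with
  sample-wise renormalization — the same compositional null idea as
  ReBoot — and the bootstrap distribution is z-tested against the null
  with pooled variance.

A retained model is whole-model evidence; the merge, however, operates
on clade pairs. Each model's p-value is attributed to its
(target, selected source) pairs with the coefficient sign as direction —
an explicit design choice, since the evidence-attribution step is
underdetermined; when several models touch the same pair the strongest
evidence wins.

## Merging evidence

Oriented p-values cannot be Simes-combined directly (a strong exclusion
has p near 1, which Simes would read as "no evidence"). Each oriented p
is therefore folded to a two-sided p₂ = 2·min(p, 1 − p) — making strong
exclusions exactly as significant as strong co-presences — while the
direction is carried separately and resolved by consensus vote over
sources (sum of ±1; ties are indeterminate and removed). p₂ is clamped
below at machine-epsilon scale so that boundary values produced by
floating-point rounding of extreme z-scores keep, rather than lose,
their significance.

Absent evidence is absent: an edge that was not a surviving candidate
in a source contributes no p-value (never an imputed p = 1), and
support counts only the sources actually present. The
Benjamini–Hochberg–Yekutieli correction is used because the ten
evidence networks are anything but independent. A strict
dataset-intersection variant (`intersect_datasets = TRUE`) is available
for sensitivity analysis.

## Network statistics

* **Degree distribution** (`degree_stats()`): the power-law exponent is
  fitted by least squares on the log-log degree histogram — the
  regression-line convention, chosen deliberately over
  maximum-likelihood exponent estimation to match how such slopes are
  conventionally reported alongside an adjusted R²; at least five
  distinct non-zero degrees are required.
* **Markov clustering** (`mcl_cluster()`): self-loop weight 1 per node
  (standard regularization), expansion–inflation iterations to a
  max-element-change tolerance of 1e-6 (cap 100 rounds), clusters read
  off as connected components of the converged flow matrix — so
  clusters always refine graph components. `scan_inflation()` selects
  the inflation by maximizing modularity and assesses it against 100
  edge-reassigned random networks.
* **Modularity** (`network_modularity()`): Q = Σ_c (e_cc − a_c²).
* **Path length** (`average_path_length()`): mean over connected pairs
  only; a single summary number presumes a giant component, so
  cross-component pairs are excluded rather than imputed.
* **Enrichment** (`node_set_enrichment()`, `group_pair_enrichment()`):
  observed edge counts against 1,000 random equal-size node sets (or
  edge-reassigned networks), with the +1-corrected empirical p (never
  exactly zero; the floor is 1/(n_iter + 1)) and a Bonferroni
  multiplier. The number of tests behind that multiplier is ambiguous
  in the source description; one test per (group × category) is the
  default and the multiplier is configurable.

## Distances

Phylogenetic distances are patristic path lengths on a user-supplied
newick tree (missing branch lengths are an error, never defaulted);
distances between internal clades are the median over all cross pairs
of descendant leaves. Functional distances are Jaccard distances on
binary gene-family profiles after removing families present in fewer
than 10% of genomes — the boundary is inclusive (exactly 10% is kept),
and presence counting is used since the profiles are binary.
`annotate_edges()` joins both onto the network for the
relatedness-vs-function comparison; lineages missing from a distance
source are flagged, never silently dropped.

## The synthetic-data generator

`simulate_counts()` produces the ground-truth testbed: per-taxon
log-normal absolute abundances (log-mean spread 1, per-sample log-sd
0.7), planted positive/negative pairs sharing a latent Gaussian factor
at a stated correlation, an optional dominant high-variance confounder
(above), multinomial counts at fixed depth (column sums equal depth
exactly), a three-level lineage hierarchy, and an optional multi-site
mode in which a shared per-subject factor couples sites. Ground truth
is defined on the **absolute** (latent) abundances, because that is the
signal the pipeline aims to recover despite closure.

What it does *not* emulate: realistic taxon-abundance distributions
fitted to real surveys, overdispersion beyond the log-normal-multinomial
compound, chimeras or classification noise, or longitudinal
autocorrelation. Passing tests therefore demonstrate correctness of the
machinery and its operating characteristics under a clean compositional
model, not performance on any particular real cohort.

## Numerical choices and degenerate inputs

* Correlation of a zero-variance vector is undefined: such scores are
  excluded from ranking; degenerate resampling draws are dropped and an
  edge loses its p-value (with a reason code) when more than 10% of its
  draws are non-finite or a pooled standard deviation is zero.
* KLD uses a pseudocount of 1e-6 (added, then renormalized);
  Bray–Curtis needs none.
* Dissimilarity of a zero-sum vector is an error, as is a zero-sum
  sample at normalization (reported by name).
* Every stochastic routine takes a seed; per-edge seeds are derived by
  hashing the master seed with the edge identity, so edge-level results
  are independent of edge order and of which other edges are processed.
* Candidate ties at the ranking cut are broken lexicographically by
  feature id, making candidate lists deterministic.

## Problem sizes used in the test suite

The shipped tests run the resampling machinery at 40–100 iterations on
matrices of 5–50 taxa and 20–200 samples, and the
operating-characteristics suite at its stated default conditions
(20 replicates, 100 iterations); the pipeline defaults remain 1,000
iterations per edge. These sizes were chosen so the full suite
exercises every code path at meaningful statistical resolution while
remaining convenient to run routinely.

## Known limitations

* Single-row permutation cannot remove shared-denominator bias among
  taxa not involved in the permutation (above); with an extremely
  dominant, highly variable organism, background associations remain
  inflated under any of the implemented nulls.
* The per-(target, source) attribution of whole-model GBLM p-values is
  a modelling convention; alternative attributions (e.g. refitting
  per-coefficient significance) would change GBLM evidence weights.
* MCL cluster extraction by connected components of the converged flow
  matrix merges overlapping attractor systems instead of splitting
  ties; this is the common reading and keeps partitions well-defined.
* The suspect-sample rule's global-maximum reading is one of two
  defensible interpretations of its defining sentence; the alternative
  (within-sample fraction) can be obtained by preprocessing externally.
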