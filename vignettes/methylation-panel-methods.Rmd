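---
title: "Building tissue-of-origin methylation panels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building tissue-of-origin methylation panels: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methorigin)
```

## The problem

Cancers of unknown primary are metastatic tumours whose originating organ
cannot be identified by standard workup. DNA methylation is strongly
tissue-specific and largely preserved through transformation, so the
methylation profile of a tumour carries a readable signature of its tissue
of origin. methorigin implements the full arc of building such a
classifier: reduce hundreds of thousands of array CpGs to a compact panel
of a few hundred highly discriminative sites, train a multiclass
classifier on the panel, and quantify new clinical specimens with targeted
bisulfite sequencing of just those sites — an assay cheap enough to run
where methylation arrays are not available.

All quantities are methylation beta values: the fraction of methylated
signal at a CpG, in [0, 1].

## The selection pipeline

**Stage 1 — differential filter.** For each CpG, a one-way ANOVA compares
mean beta across the tumour classes; CpGs with a significant F test are
followed up with Tukey's honest significant difference post hoc test. A
probe becomes a candidate when some class separates from *every* other
class with Tukey-adjusted p below `alpha` and an absolute group-mean
difference above `delta` (defaults 0.01 and 0.2). This is the
`one_vs_all` reading of "differentially methylated in at least one class";
an `any_pair` criterion is available for sensitivity analysis, and
`one_vs_all` candidates are provably a subset of `any_pair` candidates.
Two details are deliberate:

* tests run on beta values directly, not M-values, because the effect-size
  threshold `delta` is a beta-scale quantity;
* the Tukey–Kramer standard error is used so unbalanced cohorts are
  handled correctly; thresholds are per-probe with no across-probe
  multiplicity correction (the downstream forest, not the p-value, decides
  what enters the panel).

Missing values are handled per probe by complete-case analysis; a probe
where any class drops below two usable samples is flagged unevaluable and
cannot pass.

**Stage 2 — forest-guided selection.** A random forest (500 trees, node
size 1, `mtry = floor(sqrt(p))`, recomputed whenever the feature count
changes) is trained on the candidates and every CpG is scored by
permutation importance — the mean rise in a tree's out-of-bag error when
the CpG's values are shuffled among that tree's OOB samples ("mean
decrease in accuracy"). Candidates are then re-visited in importance order
and accepted only if retraining the forest on the enlarged set strictly
lowers the OOB error (`min_improve` adds an optional noise floor; the
default 0 is the literal strict-decrease rule). The procedure is run
several times (default five) with different forest seeds; each run
contributes its top `per_run_top` CpGs, the contributions are unioned, a
forest is retrained on the union, and the final panel is the top `final_k`
of the re-ranked union.

Because no random-forest package is part of the supported dependency set,
the forest is implemented in the package itself (C++ via Rcpp): CART-style
gini trees on bootstrap samples, with OOB votes, OOB error and
per-tree permutation importance. All randomness flows from one
`std::mt19937` seeded from R with hand-rolled bounded draws, so forests
are bit-reproducible across platforms — a property the forward-selection
trace tests rely on.

Two genuinely open design points and how they were resolved:

* *Where does a run's top-`k` come from?* Either from the run's full
  candidate importance ranking, or only from its forward-selected kept
  set. The default is the full ranking (`per_run_source = "ranking"`):
  kept sets saturate quickly (OOB error hits zero after a few dozen
  informative CpGs) and are typically far smaller than `per_run_top`, so
  kept-only contribution could never produce the observed behaviour of
  multi-run unions in which every run contributes a full top list and the
  union lands strictly between `per_run_top` and `n_runs * per_run_top`.
  The kept-set variant remains available via the flag.
* *What varies between runs?* Only the forest seed (`base_seed + run`).
  Re-randomising the train/validation split per run would leak validation
  samples into selection.

**Panel-size sweep.** `sweep_panel_size()` trains a classifier on the top
k probes for a ladder of k (default 50–300) and reports validation
accuracy; k beyond the available ranking is skipped with a warning. On
synthetic cohorts whose planted signal involves fewer CpGs than 200, the
ranking is capped by the candidate pool, so the upper rungs of the ladder
are unreachable — the sweep then documents that the largest available
panel is no worse than the top-50 panel.

## The classifier

Three algorithms share one interface: the internal random forest
(probability = fraction of tree votes), and lasso / elastic-net
multinomial logistic regression via glmnet (probability = softmax of the
linear predictors). Lasso is definitionally the elastic net at mixing 1.
For the penalised fits the mixing parameter defaults to 0.5 — the
conventional midpoint, since nothing in the problem fixes it — and the
penalty strength is chosen by 5-fold cross-validated multinomial deviance
with stratified, seeded folds. Features are standardised inside the fit;
coefficients are reported on the beta scale. The predicted class is the
argmax of the per-class probabilities; exact ties resolve to the
lexicographically first class and are flagged, so predictions are
deterministic.

Per-probe training means are stored in the model. They are the default
imputation for probes a new platform lacks (`harmonize_to_panel()`):
class-agnostic, so imputation can dilute but never manufacture a class
signal. Every imputed cell is recorded in the output's provenance
attribute. Models serialise to a single versioned JSON file with numbers
written at 17 significant digits, so a save/load round trip reproduces
predictions bitwise; loaders refuse unversioned files and newer major
versions.

## Quantifying sequencing panels

Targeted bisulfite sequencing yields per-CpG methylated/unmethylated read
counts (Bismark coverage format; both 0- and 1-based dialects are parsed,
normalising to the 1-based forward-strand cytosine used by array
manifests). Reads reported on the reverse-strand cytosine (position + 1)
are summed into the forward CpG, since CpG methylation is symmetric and
the training beta values are strand-merged array values. Beta is exactly
M / (M + U) for probes whose merged coverage reaches `min_coverage`
(default 10, a standard floor for targeted panels; set 1 for no filter —
no coverage threshold is inherent to the method). Below-threshold probes
become missing and flow through the same training-mean imputation as
platform dropout.

## Annotation

Panel composition is summarised with the Illumina conventions: Island
inside a CpG island, Shore within 2 kb of an island edge, Shelf within
2–4 kb, OpenSea beyond, with boundary distances inclusive toward the
nearer category. Gene regions are strand-aware: TSS200 within 200 bp
upstream of a transcription start site (TSS included), TSS1500 at
201–1500 bp, then containment in 5'UTR, first exon, 3'UTR or gene body;
multi-gene hits resolve by the priority TSS200 > TSS1500 > 5'UTR >
FirstExon > 3'UTR > Body. Promoter-level summaries can be formed by
collapsing TSS200 + TSS1500; both granularities are reported. BED input
(0-based half-open) is converted to internal 1-based inclusive intervals
at the module boundary.

## The synthetic world

`simulate_methylation()` generates cohorts with known ground truth so
every stage is testable without controlled-access array data. Its
defaults are a stated world, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_classes` × `samples_per_class` | 8 × 40 | a mid-sized multi-cancer cohort |
| `n_probes` | 5000 | enough background for type-I-error checks |
| `informative_per_class` | 20 | compact class signatures, disjoint across classes |
| `effect_delta` | 0.35 | a clearly supra-threshold shift (filter threshold is 0.2) |
| `precision` | 30 | beta-noise SD ≈ 0.09 at beta 0.5, shrinking at the extremes |
| `bimodal_mix` | 0.4 | 60% low (≈0.15) / 40% high (≈0.85) baselines, the global bimodality of array data |

Noise is beta-distributed with a mean/precision parameterisation —
bounded and heteroscedastic like real array values. Sequencing coverage is
Poisson with a floor of one read, the simplest defensible model. The
generator also emits a synthetic manifest with evenly spaced coordinates,
island intervals and gene models so annotation is exercisable.

What the generator does *not* emulate: probe cross-reactivity and SNP
artefacts, batch effects, FFPE deamination damage, incomplete bisulfite
conversion, tumour purity gradients, and correlated CpG blocks (planted
probes are independent). A green recovery test therefore establishes that
the pipeline machinery is correct, not that any particular accuracy will
be attained on real cohorts.

## Numerical choices and degenerate inputs

* ANOVA with zero within- and between-group variance (a constant probe) is
  undefined and reported `NA`/non-candidate; zero within-group variance
  with separated means saturates to F = Inf, p = 0, and Tukey q = Inf.
* Importance ties break by (score desc, probe id asc) — deterministic
  across platforms.
* Stratified splits use per-class `ceiling(frac * n)` clamped so both
  partitions keep at least one sample; classes of size one are an error.
* Undefined 0/0 evaluation ratios (e.g. PPV of a never-predicted class)
  are `NA`, never 0.
* Row percentages of empty confusion-matrix rows stay zero and the rows
  are flagged rather than silently renormalised.
* One user seed fans out to per-stage seeds by a small string hash of the
  stage name, keeping every stage independently reproducible.

## Known limitations

* The forest grows fully (node size 1) with no depth cap; on much larger
  cohorts than the panels here, selection cost grows roughly linearly in
  candidates × runs.
* Probabilities are not calibrated and there is no reject option: the
  argmax is always called, as in the underlying procedure.
* The elastic-net mixing parameter is fixed (not cross-validated); only
  the penalty strength is tuned.
* `min_coverage` discards rather than down-weights shallow CpGs; a
  beta-binomial treatment of coverage is out of scope.
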