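---
title: "Deleteriousness-based CNV pathogenicity classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deleteriousness-based CNV pathogenicity classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpatho)
```

## The problem

Copy number variants (CNVs) — deletions ("loss") and duplications ("gain")
of genomic segments, typically longer than 50 bp — are classified clinically
on the ACMG five-tier scale: benign, likely benign, uncertain significance,
likely pathogenic, pathogenic. Manual classification integrates gene
content, dosage-sensitivity evidence and variant-level deleteriousness
scores, and is slow and inconsistent across laboratories. `cnvpatho`
implements a supervised approach: each CNV is summarized by a numeric
feature vector whose construction is *aware of the deleteriousness
direction of every score*, and gradient-boosted tree classifiers are
trained on curated, labelled CNV corpora — separately for loss and gain
CNVs, and separately as a five-tier and as a binary (benign vs pathogenic)
task.

## Direction-aware feature annotation

All coordinates are handled internally as 0-based half-open intervals, so
the CNV length feature is exactly `end - start`; 1-based inclusive source
tables (GFF3-like CNV exports) are converted at parse time. Whether source
CNV tables are 1-based is a convention choice made here, not a property of
any particular database export. Chromosome names are compared after
stripping a leading `chr`.

A **feature registry** is an ordered list of feature definitions. Each
definition names its aggregation kind and data source:

* **max** — for scores where *higher is more deleterious* (pLI, REVEL,
  GERP++ RS, Episcore, CADD, conservation scores, ...), the feature is the
  maximum over records overlapping the CNV.
* **min** — for scores where *lower is more deleterious* (LOEUF, SIFT,
  FATHMM, PROVEAN, RVIS, CDTS, ...), the minimum.
* **mean** — for direction-less scores (GHIS, GDI), the arithmetic mean.
* **count** — attribute features: the number of overlapping records of a
  kind (gene biotypes, UTRs, OMIM/Morbid genes, cCRE classes,
  haploinsufficiency/triplosensitivity genes per dosage score
  0/1/2/3/40/NA, and sites whose categorical predictor call equals a given
  code, e.g. `LRT_pred_D`).
* **length** — the CNV span itself.

Gene-level scores aggregate once per overlapping gene; site-level scores
once per overlapping position. "Overlap" for counting is any shared base
pair: no fractional threshold is applied, matching how gene-content counts
behave in comparable interval annotators (the threshold would be a registry
option if a sensitivity analysis needed one). The aggregation direction is
*declared* in the registry and never inferred from data; direction-aware
aggregation is the central modelling idea, so it must be explicit and
testable.

The default registry has exactly 79 entries: 1 length, 24 max-aggregated,
10 min-aggregated, 2 mean-aggregated, 7 genomic-element counts, 6 cCRE
class counts, 12 dosage counts and 17 categorical-prediction counts. The
anchor features (pLI, REVEL, GERP++ RS, Episcore; LOEUF, SIFT, FATHMM;
GHIS; the UTR/biotype/OMIM/Morbid counts; the six cCRE classes; the
SIFT/LRT/PolyPhen2 call counts) are fixed by the scheme; the remaining
score columns are a declared package default drawn from standard ANNOVAR /
dbNSFP rosters and are fully user-overridable through a registry config
file (`load_feature_registry()`).

**Missingness.** A CNV overlapping no scored record yields a *missing*
aggregation value — never a silent 0, since a true score of 0 is
informative. Missing cells are filled by per-feature medians
(`fit_impute()` / `apply_impute()`). Medians are fitted on the training
partition only and applied unchanged to held-out data; fitting on the full
data would leak label-correlated information through the imputation
constants. A feature entirely missing in training imputes to 0 with a
warning rather than failing, which keeps small synthetic runs usable.

## Corpus curation

Per-source inclusion filters (`apply_source_filter()`):

| source | retained rows | label |
|---|---|---|
| ClinVar | five-tier significance and review status among the accepted curation levels | as labelled |
| dbVar | pathogenic / likely pathogenic records | as labelled |
| ClinGen dosage regions | haploinsufficiency or triplosensitivity score 3 or 40 | score 3 → pathogenic (HI → loss, TS → gain); score 40 → benign |
| DGV gold standard | at least 2000 samples tested | benign |
| DECIPHER | observations > 0 and population frequency > 1% | benign |
| gnomAD SV | DEL/DUP, FILTER PASS, AF > 1%, AN > 2000 | benign |

Each excluded row is attributed to the first rule it fails, so the
curation report conserves counts exactly. A ClinGen region that qualifies
on both dosage sides emits one CNV per qualifying score.

The non-redundant merge (`merge_nonredundant()`) applies, in order: a
[50 bp, 5 Mb] length filter; removal of **both** members of every
same-type pair with reciprocal overlap ≥ 70% and conflicting
pathogenicity; removal of identical-coordinate same-type CNVs carrying
more than one distinct label. "Conflicting" means one member in
{benign, likely benign} and the other in {pathogenic, likely pathogenic};
uncertain significance conflicts with neither side, which keeps VUS
records usable. Removing both members (rather than privileging a source)
is deterministic and conservative; conflict pairs are decided over the
post-length-filter set in a single pass, with no cascading re-evaluation,
so the outcome cannot depend on scan order. Validation-set deduplication
(`dedup_validation()`) additionally keeps the *shorter* member of any
same-type pair at ≥ 90% reciprocal overlap (equal lengths break the tie by
record id), then applies the length filter. Loss and gain records are
never compared with each other anywhere in curation.

## Models

Classifiers are XGBoost ensembles: binary logistic for benign vs
pathogenic, softmax for the five-tier task, always one model per CNV type.
Binary models train only on benign and pathogenic rows. Datasets are split
70/30, stratified by class; class imbalance is otherwise left untouched
(no resampling), with an optional class-weight flag deliberately off by
default.

The tuned hyperparameters are `eta`, `gamma`, `max_depth`,
`min_child_weight`, `subsample` and `nrounds`; everything else stays at
the XGBoost defaults. `tune_hyperparameters()` samples configurations from
declared bounds (eta log-uniform in [0.01, 0.3]; gamma in [0, 5];
max_depth in {2..10}; min_child_weight in [1, 10]; subsample in [0.5, 1];
nrounds in {50..1000}) and selects the trial maximizing the mean
cross-validated objective under stratified k-fold CV (10 folds by
default). The sampler is seeded *random search*: with six loosely coupled
dimensions and tree ensembles that are robust over wide hyperparameter
plateaus, random search is a strong, fully reproducible baseline, and it
keeps the package dependency-free; the search bounds and trial budget are
user-facing knobs. The tuning objective is mean one-vs-rest AUC (binary:
AUC of the pathogenic probability) — chosen because the evaluation of the
five-tier model is itself reported per class as one-vs-rest AUC, so tuning
and reporting optimize the same quantity.

Training is single-threaded and seeded, which makes feature matrices,
splits, fitted models and prediction tables byte-reproducible under a
fixed seed. Each trained model stores its imputation medians and a
fingerprint of the feature columns; predicting on a matrix with different
columns is an error rather than a silent misalignment. Predicted labels
are the probability argmax with ties broken toward the more pathogenic
class (clinical conservatism, and deterministic).

## Evaluation conventions

* AUC is computed from midranks (equivalently U/(n1·n0) of the
  Mann-Whitney statistic, and the trapezoidal area under the empirical ROC
  curve), so it is invariant under strictly increasing score transforms
  and well-defined under ties.
* Multiclass AUC is one-vs-rest per class from that class's predicted
  probability; the single summary "accuracy" of the five-tier model is
  plain top-1 accuracy.
* Balanced accuracy is (sensitivity + specificity)/2, per class.
* Metrics with a zero denominator (e.g. precision with no predicted
  positives) are reported as 0 with an explicit `degenerate` flag instead
  of raising, so batch comparison tables over many classes never abort.
* `external_report()` builds the same report shape from another tool's
  predicted labels, enabling side-by-side comparison tables
  (`compare_models()`) without that tool's scores.

## Interpretation

SHAP attributions come from the exact TreeSHAP algorithm of the fitted
ensemble; additivity (per-row attributions + base value = margin output)
is asserted in the test suite at 1e-6 relative tolerance. Features are
ranked by the sum of absolute attributions over all rows (and classes),
ties broken by registry order. Dependence plots pair each feature value
with its attribution; the sign-change threshold is estimated by sorting by
feature value, smoothing attributions with a running median (window 51 —
wide enough to suppress single-point sign flips, narrow enough to track
genuine transitions) and interpolating the first zero crossing; the
estimate is reported absent when the smoothed attribution never changes
sign. A defined estimator replaces eyeballing and makes the output
testable.

Group statistics follow nonparametric practice: each non-benign tier is
compared against the benign reference with a two-sided Mann-Whitney U
test; the U statistic uses midranks, with the p-value exact by full
enumeration when the pooled sample size is at most 12 (valid under ties)
and a tie-corrected, continuity-corrected normal approximation otherwise.
Kruskal-Wallis across all tiers delegates to `stats::kruskal.test`, with
post hoc pairwise comparisons Bonferroni-multiplied by k(k−1)/2 and capped
at 1.

The differential top-feature analysis for heat maps ranks features by
Mann-Whitney p between benign and pathogenic groups on transformed values
(an absolute-median-difference ranking is available as an option — the
two-group statistic behind "differential analysis" is a design choice
here, and the nonparametric test is consistent with the rest of the
module). The transform is the signed offset log,
sign(x)·log10(|x| + 1): count features are legitimately 0 (the offset
keeps 0 mapped to 0) and several deleteriousness scores are legitimately
negative (GERP++ RS, PROVEAN), which a plain log10 cannot represent. Rows
whose selected features are all 0 are removed before rendering.

Genomic-element proportions per CNV group count overlapped genes in five
categories — pseudogene, OMIM gene, Morbid gene, RNA gene, protein-coding
gene — normalized to sum to 1 per group; a gene contributes to every
category it satisfies.

## The synthetic data generator

`fixture_spec()` / `generate_bundle()` / `generate_cnv_set()` build a toy
genome (default 2 chromosomes × 10 Mb — large enough to place the default
record counts without crowding, small enough for brute-force oracle
checks), an annotation bundle and a labelled CNV set. The generator
emulates the statistical structure the classifier assumes:

* pathogenic CNVs are longer — per-class lengths are log-normal around
  20 kb times `length_ratio^(rank/4)`, rank 0 (benign) to 4 (pathogenic),
  default ratio 4, clipped to [50 bp, 5 Mb];
* pathogenic CNVs overlap disease genes — with probability
  `morbid_enrichment · rank/4` a CNV is centred on a random morbid gene
  (default 0.8, so most pathogenic CNVs carry the effect and the planted
  signal is individually recoverable rather than diluted across
  placement noise);
* deleterious calls cluster in disease genes — categorical predictor
  calls inside morbid genes are "D" with probability raised by
  `site_D_rate_shift` (default 0.3).

Gene- and site-level *numeric* scores are uniform in their documented
ranges (pLI, SIFT, REVEL in [0,1]; LOEUF in [0,9]; GERP++ RS in [−5,6];
etc.) and independent of the flags, and the OMIM flag is drawn
independently of the Morbid flag. Both choices are deliberate toy
simplifications: they keep the planted morbid-overlap signal attributable
to the morbid-gene count itself instead of smearing it over dozens of
correlated proxies, which is what makes "SHAP recovers the planted
features" a sharp, testable property. Effects are monotone across the five
tiers so the five-tier ordering is learnable.

All randomness flows from one seed through a derived stream per track
(seed combined with a track-name hash), so regenerating one track never
perturbs another and results are identical across platforms.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic annotation density or score
correlation structure (real constraint scores are strongly correlated;
real Morbid genes are a subset of OMIM genes), population-genetic length
and frequency spectra, breakpoint effects, segmental-duplication artifacts,
reference-assembly quirks, or inter-database label noise. Performance
numbers on synthetic data validate the machinery (the planted signal is
recovered, a null signal is not invented), not clinical accuracy.

`generate_raw_db_tables()` emits one table per source dialect containing
known numbers of rows on each side of every curation predicate, a planted
conflicting 75–90% overlap pair, an identical-coordinate multi-label pair,
out-of-range lengths and a validation table with a concordant ≥ 90% pair —
together with a manifest of expected counts that the curation tests check
exactly.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data:
binary models at 2,000 CNVs per class (held-out AUC of the planted signal,
permuted-label null in [0.45, 0.55], SHAP recovery of the planted
features), five-tier models at the generator's default class counts
(400/100/150/150/400 per CNV type), oracle equivalence on a ≤ 200-record
bundle with over 100 random CNVs, and exact Mann-Whitney enumeration up to
pooled size 10. These sizes were chosen so that each property is measured
with comfortable margin while a full run stays interactive on one CPU.

Numerical conventions collected in one place: empty aggregation = missing
(imputed later), never 0; prediction ties break pathogenic-ward;
keep-shorter ties break by record id; conflicting overlap pairs remove
both members; degenerate metrics report 0 with a flag; reciprocal overlap
across chromosomes is 0, not an error; exact Mann-Whitney below pooled
size 13, tie-corrected normal approximation above.

## Known limitations

Breakpoint-level effects, nested or multi-allelic structural variants, TAD
boundaries and constrained coding regions are out of scope, as is parsing
the real database release formats (readers accept clean TSV/BED/GFF3
exports; liftOver-style coordinate harmonization is assumed done
upstream). Random-search tuning explores the declared bounds but is not a
model-based optimizer; with a large trial budget the distinction is minor
for tree ensembles, but the trial count is the user's lever. The default
79-feature roster beyond the anchor features is a documented stand-in
pending a site-specific registry.
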