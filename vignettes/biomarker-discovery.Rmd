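---
title: "Secreted miRNA biomarker discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secreted miRNA biomarker discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomir)
```

## The problem

Neurotoxic chemicals degrade neuronal morphology (neurite length and count,
cell density) before and sometimes without overt loss of viability (ATP).
microRNAs secreted into culture supernatant by stressed neurons are candidate
fluid biomarkers of that decline. `secretomir` implements the complete
analytical workflow for such a screen: dose-response analysis of the apical
endpoints to pick, per chemical, a *low* concentration (morphology degraded,
viability intact) and a *high* concentration (both degraded); qPCR-array
profiling of secreted miRNAs at those two concentrations against paired
vehicle controls; and downstream pathway and target analyses that turn the
significant miRNAs into testable biological hypotheses.

Because raw screen data and the commercial annotation databases behind such
studies are not redistributable, every stage is exercised on synthetic data
with planted ground truth. The generators are first-class, tested code: each
returns its truth (spiked miRNA indices, planted pathway, Hill means)
alongside the data so that recovery is measurable.

## Apical endpoints and concentration selection

Well-level endpoint values are normalized per plate to percent of the
same-plate vehicle mean (`normalize_percent_of_control()`), which removes
between-plate gain differences and makes plates poolable; normalization is
idempotent. Each tested concentration is compared with vehicle by Dunnett's
many-to-one procedure (`dunnett_test()`): pooled-variance t statistics with
family-wise adjusted two-sided p-values from the joint distribution of the
maximum absolute statistic.

The adjusted p-value is computed by seeded Monte-Carlo integration of the
max-|t| null (10^5 draws, memoised per design), rather than table lookup:
this is exact up to Monte-Carlo error at arbitrary numbers of groups and
unequal n, and fully reproducible. With a single treated group the procedure
reduces exactly to the classic pooled two-sample t test, and the simulated
family-wise error rate at four null groups of six wells is within
Monte-Carlo error of the nominal 5% (the acceptance script recomputes it).
Two-sided tests are retained even though only decreases are screened; the
20%-decrease screen supplies the directionality.

`select_concentrations()` implements the screening rule: *low* is the
smallest tested concentration with an ATP decrease of at most 20% and a
statistically significant neurite decrease of at least 20%; *high* is the
smallest concentration at or above it with significant decreases of at
least 20% in both ATP and a neurite endpoint. When no concentration meets
the high rule the maximum tested concentration is selected — the behavior
appropriate for microtubule-targeting agents whose viability stays intact
across the tested range. When no concentration meets the low rule the
chemical is reported with an explicit "no qualifying low concentration"
outcome rather than a silent fallback; a negative control should end the
workflow here. Two details the underlying procedure leaves open were
resolved as follows: the 20% screens use means pooled across plates (after
per-plate normalization the plates are exchangeable, and pooled means are
the quantity the Dunnett test models), and "significant decrease >= 20%"
requires both the magnitude screen and the adjusted p < .05 — magnitude
alone is not accepted.

## Ct processing and differential expression

Threshold-cycle values at or above the detection limit (default Ct 35) are
capped at the limit and flagged censored (`cap_detection_limit()`). Plate
normalization is mean-centered: the per-plate mean is computed over
non-censored entries only, and every entry's normalized expression is
`plate mean - raw Ct`, so higher values mean higher expression. A plate is
taken to be the array card holding all samples of one compound treatment,
so treated and control samples share their plate mean and plate-level
shifts cancel exactly in the paired contrasts. Censored entries participate
in downstream tests at the capped value — a conservative attenuation — and
every differential record carries its censored fraction so consumers can
filter.

Per miRNA and exposure, the fold change is `2^(mean treated - mean
control)` on the normalized (cycle) scale — one cycle is a 2-fold change —
and a paired t test is run on the per-pair differences (treated replicate
*i* versus control replicate *i* on the same plate; the pairing key is the
replicate index, which is how the generator and the sample sheet define
biological pairing). Degenerate rows (zero variance of differences) report
p = 1 when the mean difference is also zero, and the smallest representable
positive p with a flag otherwise.

A miRNA is called significant for an exposure when the fold change is at
least 1.5 or at most 0.67 **and** the unadjusted p is below .01. Storey
q-values (fixed lambda = 0.5, no smoother, pi0 floored at 1/m; below 10
p-values pi0 is fixed at 1) and Benjamini-Hochberg adjusted p-values are
computed within each exposure and carried in the output, but deliberately
not used for the call: the multiplicity risk of the unadjusted threshold is
mitigated downstream by requiring convergent pathway-level signal.
Down-regulation is reported both as the ratio and implicitly as its
reciprocal magnitude via the log2 scale.

With three biological replicate pairs the paired t has two degrees of
freedom, and p < .01 demands |t| > 9.92. This makes the joint filter very
conservative: at a true 4-fold change (|log2 FC| = 2) and per-sample noise
of 0.5 cycles the per-exposure sensitivity is only about 0.23, while the
magnitude of recovered effects is essentially unbiased (the acceptance
script computes both). That stringency is a property of the design being
modeled, not of the implementation; users with more replicates regain power
rapidly.

## Clustering

Significant miRNAs are clustered on their log2 fold-change profiles across
exposures (log2 keeps up- and down-regulation symmetric; untested exposures
are imputed as 0 = no change and recorded). Distances are Euclidean,
linkage is UPGMA, and rows are sorted lexicographically first so distance
ties break deterministically. Clusters come from a dynamic tree cut
(`dynamic_tree_cut()`): the sorted merge heights are scanned for
cluster-separating gaps (next height exceeding the previous by more than a
gap factor); each qualifying gap is a candidate cut and the candidate
yielding the most clusters of at least `min_cluster_size` leaves wins, with
ties going to the coarsest cut. Leaves in undersized clusters are
unassigned (label 0). Defaults `min_cluster_size = 3`, `deep_split = 1`
(gap factor 2.0) were chosen so that a few dozen significant miRNAs can
plausibly resolve into about four groups; the gap-factor ladder
(2.6, 2.0, 1.6, 1.3, 1.15 for `deep_split` 0-4) was calibrated so that the
default neither fragments homogeneous profiles nor misses four planted
centroids at within-group noise a third of the between-group separation.
Both parameters are exposed in the configuration.

## Pathway enrichment

miRNA signaling is sparsely represented in curated pathway collections, so
direct enrichment of miRNAs is biased. Two complementary bias corrections
are implemented, both using the exact upper-tail hypergeometric probability
(`hypergeom_upper()`, computed in log space via `phyper`):

* **Method 1** tests the miRNAs' *gene targets* in each pathway over a
  universe restricted to genes with at least one miRNA association in the
  supplied target network (genes unknown to any miRNA are excluded from
  the ontology at the universe level). Its weakness is the
  disproportionate contribution of miRNAs with many targets.
* **Method 2** transforms each pathway into the set of miRNAs with at
  least one target gene in it and tests the significant miRNAs in that set
  over the universe of all network miRNAs. It is insensitive to target
  counts but can boost miRNAs with few targets.

BH adjustment is applied within each method across pathways, and a pathway
is accepted only when *both* adjusted values fall below .01; accepted
pathways are ranked by the Fisher-combined (cumulative) p of the two
methods, with a reporting subset of the top 20 pathways at raw p < .001 in
both. The two methods share the same data, so Fisher's independence
assumption does not strictly hold; the combined value is used as a ranking
score, and acceptance rests on the within-method BH intersection rather
than on the combined p's nominal calibration. The Method 2 universe is the
network's miRNAs by default and can be overridden to the assay panel.

For cluster-level analysis, `pathway_union_enrichment()` tests each cluster
miRNA's targets against each pathway over the Method 1 universe and
combines the per-miRNA p-values by Fisher's method; a pathway qualifies at
p < .05 provided at least one cluster miRNA actually targets it. The
pathways significant for every cluster (`common_pathways()`) are the
workflow's "commonly enriched" output. With a single miRNA and a single
pathway, the union test, Method 1, and a direct hypergeometric test
coincide — a tested invariant.

## Target prioritization and cascades

From the significant miRNAs, `select_validated_targets()` keeps the union
of targets with *validated* evidence. `filter_neuro_targets()` then applies
the annotation funnel: keep genes present in the neurological annotation
catalog; drop genes with no disease-biomarker and no canonical-pathway
association; drop genes associated with only one specific condition.
"Multiple diseases and/or functions" is operationalized as at least two
distinct terms across the biomarker and canonical-pathway categories, since
no numeric threshold is standard. The funnel only removes genes, and every
stage's survivor count is recorded.

Each surviving target's expression direction is predicted from repression
logic: every supporting miRNA votes opposite to its own direction, weighted
by |log2 FC| (the weighted sum reduces to `-sum(log2 FC)`); a zero sum is
ambiguous. Conflicting-miRNA resolution by weighted voting is this
package's choice — the manual curation step it replaces is not an
algorithm. The funnel takes all significant miRNAs and reports per-target
direction, rather than pre-restricting to down-regulated miRNAs.

`trace_cascades()` enumerates all simple directed paths (default at most 4
edges, configurable) between two seed sets in a signed interaction graph,
deterministically ordered, and `merge_cascades()` unions them into one
network with per-node annotation flags. Path enumeration is exhaustive, so
seed sets and depth should be kept moderate.

## The synthetic generators

`gen_ct_matrix()` emulates a 754-feature array-card experiment: per-miRNA
baselines (mean Ct 28, between-miRNA sd 2), one card per compound treatment
carrying a Normal plate shift (sd 0.5), replicate noise (sd 0.5 cycles, the
package's default for a quantity the assay literature rarely reports —
configurable), and spiked treatment effects applied on the Ct scale as
`-log2_effect` so generator truth is directly comparable to pipeline fold
changes. Right-censoring arises only from values crossing the detection
limit; no separate missingness mechanism is simulated. Three paired
biological replicates per treatment is the default design.

`gen_apical()` draws well values around four-parameter Hill means over
0.1-100 uM with multiplicative noise (CV 0.1) and log-normal per-plate
scale factors, vehicle wells at 100%. `gen_target_network()` draws
per-miRNA out-degrees from a truncated power law (default exponent 2.5 on
4-30 targets) with 60% of edges tagged validated.
`gen_pathway_ontology()` plants one pathway containing a configured
fraction (default 0.8) of the spiked miRNAs' target union; the planted
pathway's size is drawn from the configured range, enlarged only as far as
the range's maximum allows. The default scenario (2000 genes, 200 miRNAs,
50 pathways of 25-120 genes, 12 spiked miRNAs) was sized so that a planted
pathway at overlap 0.8 is recoverable as rank 1 by the dual enrichment
while an unplanted one is not — the acceptance script measures both rates.

What the generators do **not** emulate: amplification curves and primer
efficiency, extraction spike-in controls, non-Normal heavy-tailed Ct noise,
correlated miRNA co-regulation, and the literature structure of real
pathway collections. Passing recovery tests therefore demonstrates the
correctness and calibration of the machinery under the stated statistical
model, not performance on real screens.

## Determinism and problem sizes

Every generator is a pure function of its configuration including the seed.
The pipeline forks one run seed into named substreams (`stage_seed()`), so
adding a stage never perturbs another stage's draws, and a repeated run
with the same seed is byte-identical — a tested contract. Simulation-based
checks in the test suite use 100 seeds for null calibration and spike
recovery (200-feature panels), 100 seeds for planted-pathway recovery, 50
for clustering recovery, and 10^4 Monte-Carlo runs for the Dunnett
family-wise error rate; the acceptance script uses 20-50 seeds per
quantity. These sizes are the package's own balance between statistical
resolution and a test suite that stays pleasant to run.

## Known limitations

* The paired design at n = 3 makes the unadjusted p < .01 filter severe
  (see above); sensitivity numbers from the synthetic model should be read
  as properties of that design.
* Fisher combination across the two enrichment methods ignores their
  dependence; it is used for ranking only.
* The dynamic tree cut is a deterministic gap-scan variant; it does not
  reproduce every behavior of adaptive branch-joining implementations.
* The cascade tracer is exhaustive and exponential in the worst case;
  depth defaults to 4.
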