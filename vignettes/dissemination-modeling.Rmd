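---
title: "Modeling clonal dissemination across tumor sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal dissemination across tumor sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneseed)
```

## The problem

A cancer sampled at several anatomical sites is a set of overlapping cell
populations. Every somatic mutation marks the clone in which it arose and
all of that clone's descendants, so the variant allele fractions (VAFs) of
thousands of mutations measured across sites jointly constrain (i) how many
clones there are, (ii) how they descend from one another, and (iii) which
of them physically moved between sites. `cloneseed` carries out that
inference for deeply sequenced multi-site tumor/normal pairs and classifies
the *mode*, *direction* and *relative timing* of dissemination.

This vignette documents the model, the tunable parameters, the synthetic
data generator used for validation, and the numerical and design choices a
user or reviewer should know about.

## From reads to cancer cell fractions

Somatic candidates are filtered per sample with two acceptance routes:

* **standard**: tumor and normal coverage ≥ 15×, tumor VAF ≥ 5%, normal
  VAF < 1% (strict);
* **relaxed** (for several-hundred-fold depth, where a few contaminating
  reads in the normal — e.g. circulating tumor cells — would otherwise veto
  a true call): tumor VAF ≥ 15%, both coverages ≥ 100×, normal VAF ≤ 5%
  (inclusive), and tumor VAF at least 4× the normal VAF.

The relaxed route is an *alternative* (logical OR), not a replacement, and
both routes require the mapping-quality gate (applied upstream of this
package, carried as a flag). Both boundaries are implemented exactly as
inclusive/strict as written above; the test suite pins the full truth table
against a brute-force transcription of the rules.

A passing mutation's VAF is converted to a cancer cell fraction,

$$\mathrm{CCF} = \mathrm{VAF}\cdot
  \frac{\rho\,\mathrm{CN} + (1-\rho)\cdot 2}{\rho\, m},$$

with tumor purity $\rho$ (an input, estimated upstream from copy-number
fits or histopathology), locus total copy number $\mathrm{CN}$ from the
segment covering the locus, and multiplicity $m$ (mutated copies per
cell). Multiplicity is estimated deterministically as the $m \in
\{1..\mathrm{CN_{major}}\}$ whose expected clonal VAF is nearest the
observation, provided it is within a tolerance band (`multiplicity_band`,
default 0.1 VAF units); otherwise $m = 1$. On 2:1 and 1:1 segments the
major allele count is 1 and $m = 1$ always. This nearest-expectation rule
replaces a fully probabilistic timing model on purpose: it is
deterministic, transparent, and adequate at the depths this pipeline
targets; no claim is made that it reproduces a Bayesian timing posterior.

CCF estimates are capped at `ccf_cap` (default 1.5) rather than truncated
to 1, so that inflated estimates remain visible. A mutation is *subclonal*
in a sample when CCF < `clonal_threshold` (default 0.9; the literature
says "approximately 1" and gives no number — 0.9 leaves three-ish standard
deviations of CCF noise at 600× depth between a truncal and an 0.8-prevalence
clone). Clonal mutations on gained segments are timed against the gain:
multiplicity ≥ 2 means the mutation predates the gain (`clonal_early`),
multiplicity 1 that it followed it (`clonal_late`); without a gain the
distinction is undefined. Patient-level clonality follows the
all-samples rule: *clonal* iff clonal in ≥ 1 sample **and** detected in
every tumor sample. Detection ("presence") is deliberately more sensitive
than discovery: a mutation is present in a sample if it passed the filters
there *or* has ≥ 2 alt reads at ≥ 1% VAF (`rescue_min_alt`,
`rescue_min_vaf`) — presence/absence calls must not inherit the discovery
thresholds, or shared clones would be mistaken for private ones.

## Clustering mutations into clones

Mutations are clustered on their joint CCF vector across all samples of
the patient. Exactly repeated profiles (which is what noise-free data
produces) are grouped directly. Otherwise a Gaussian mixture with diagonal
covariance is fitted for $k = 1..k_{max}$ (default 12: the largest clone
numbers reported for deeply sequenced HGSC, plus headroom) and the order
is chosen by BIC. Two numerical choices matter here:

* **Variance regularization.** A clone absent from a sample sits at CCF
  ≈ 0 there with almost no spread. Degenerate near-zero variances let the
  likelihood grow without bound and push BIC toward absurdly large $k$;
  the mixture is therefore fitted with a conjugate prior on the component
  variances (`mclust::priorControl`), which removes the degeneracy without
  affecting well-separated structure.
* **Post-merging.** Components whose centers are closer than `merge_tol`
  (default 0.1, max-norm) are merged — they are not distinguishable clones
  at realistic noise levels. Clusters below `min_cluster_size` (default 3,
  matching the smallest cluster size used in practice for this kind of
  modeling) are merged into the nearest center within `merge_tol` or
  dropped.

Missing entries (mutation not observed in a sample) enter as CCF 0:
at several-hundred-fold depth, absence of supporting reads *is* evidence
of prevalence ≈ 0. Cluster centers, clipped to [0, 1], are the clone
prevalences used downstream; the arithmetic mean is used as the center
statistic.

## Clone trees and parsimony

All rooted trees over the clusters are enumerated such that, within
`sum_tolerance` (default 0.05 prevalence units — the models in this field
are routinely adjusted by a few percent to admit a consistent tree), in
every sample each parent's prevalence covers each child's and the sum of
children does not exceed the parent (the pigeonhole constraint). The root
must be a cluster with prevalence ≥ `root_threshold` (default 0.9)
everywhere; if none exists the patient cannot have a single-origin model
over all samples and the pipeline (a) re-tests the origin (below) and (b)
falls back to enumerating models per site pair, flagging the report as
pairwise-modeled. Enumeration is exact — a depth-first parent assignment
with sum-rule pruning, checked against a brute-force oracle in the tests —
and is cheap for the clone numbers deep sequencing supports (≤ 9); a cap
(`max_trees`, default 20000) guards degenerate inputs.

Among consistent trees, selection is by parsimony: fewer branching nodes
first (linear over branched evolution), then fewer implied disseminated
clones (one seeding clone over several), then a deterministic
lexicographic tie-break on the parent map. Where several models remain
genuinely equivalent the tie-break is arbitrary by construction, which is
acceptable because the dissemination mode depends only on the ancestry
relations among disseminated clones, and those are shared by the tied
models in all cases we generate.

## Origin, mode, direction, timing

**Origin.** If some pair of sites shares not a single filtered mutation,
the tumors at those sites arose independently: the patient is flagged
`polyclonal_origin`, the sites are partitioned into sharing components,
and each component is modeled as a separate cancer (dissemination is still
assessed within multi-site components).

**Designation and mode.** On the selected tree the root is the *initial*
clone; non-root clones present (any sample of the site above
`presence_threshold`, default 0.02 CCF — the smallest prevalence
distinguishable from noise at ~600×) at ≥ 2 sites are *disseminated*;
single-site clones are *local*. If no subclone is shared across sites, the
initial clone itself did the seeding (dissemination before subclonal
development). One disseminated clone ⇒ *monoclonal*; several on one
root-to-leaf path ⇒ *monophyletic polyclonal*; at least two on separate
branches ⇒ *polyphyletic polyclonal*.

**Direction.** A disseminated clone's origin is the site where its mean
prevalence is smallest — a clone expands where it lands while the seeding
population stays minor — provided the two smallest site prevalences differ
by more than `direction_margin` (default 0.05, i.e. clearly outside
prevalence noise); ties, and the initial clone at ≈ 1 everywhere, are
*undetermined*.

**Timing.** A clone's mutation time is its cumulative root-lineage
mutation count divided by that of the latest developed clone (the clone
with the most cumulative mutations), so the latest clone sits at 1. "The
mutations of a clone" here always means the inherited lineage set, not the
private set — this makes the normalizer coherent and bounds the statistic
in [0, 1]. The dissemination interval is the mutation-time span between
first and last disseminated clone for monophyletic cancers; for
polyphyletic cancers, where branched clones do not share a lineage scale,
it is the largest fraction of modeled mutations unique to either of two
mutually non-ancestral disseminated clones (the "two most divergent"
operationalized as the maximizing pair).

## The synthetic cohort generator

Because multi-site patient sequencing data of this kind cannot be publicly
deposited, validation runs on simulated patients whose ground truth is
known by construction. The generator emulates the study conditions of a
disseminated-HGSC cohort:

* 23 patients by default — 6 monoclonal, 11 monophyletic-polyclonal and
  5 polyphyletic-polyclonal cancers plus one patient with a polyclonal
  cancer origin (two locus-disjoint cancers on disjoint site sets, with
  dissemination between the two extraovarian sites);
* 3–9 clones per cancer; private mutation counts Poisson (mean 40 per
  clone, floor 3 so every simulated clone is detectable in principle);
* 2–3 sites, 3–7 samples per patient (multi-region samples of one site
  share the site's prevalence vector; an optional multiplicative jitter
  exists and is off by default), purity uniform on 0.40–0.90, ~670× mean
  depth, binomial read noise, 0.1% error rate in the matched normal
  (safely below the 1% contamination filter);
* prevalences allocated per site by stick-breaking from the root down, so
  the sum rule holds *exactly* by construction; disseminated clones get
  positive prevalence at every site with the designated origin site scaled
  by a factor drawn from 0.25–0.45 (origin ≤ 0.5 × destination, making
  direction recoverable); sibling disseminated clones get different origin
  sites so their prevalence profiles cross and no chain can absorb them;
  all non-root prevalences stay below 0.88, keeping the clonal range
  (≥ 0.9) truncal-only. A monophyletic chain shares a single origin site —
  one seeding route — since nothing constrains per-clone origins of a
  chain and a shared route is the simplest consistent choice.

What the generator does **not** emulate: copy-number evolution along the
tree (segments are per-sample static, diploid 2:1 unless gains are
injected via `gain_chroms`), mutational signature processes, sequence-level
artifacts, and spatial heterogeneity within a tumor region beyond the
optional jitter. Passing the recovery tests therefore demonstrates the
pipeline's correctness under binomial read noise at realistic depth,
purity and clone structure — not robustness to segmentation error, subclonal
copy number, or caller-specific artifacts in real data.

## Validation results the package computes

The test suite and `scripts/acceptance.R` recompute, from scratch, at
problem sizes chosen to keep a desk-scale run comfortable (e.g. 30
noise-free patients per mode, 100 noisy patients, 100 random matrices for
the enumeration oracle, a 23-patient cohort run twice for byte-level
determinism):

* exact agreement of the somatic filters with a brute-force truth table;
* CCF back-transformation of noise-free data to the generating prevalences
  within 1e-9;
* set-equality of tree enumeration with brute-force enumeration;
* 100% dissemination-mode recovery on noise-free patients, and ≥ 90% mode /
  ≥ 95% direction recovery under binomial noise at 600×;
* exact equality of the patient-level clonal set with the simulated
  truncal set on noise-free data;
* byte-identical cohort outputs across reruns.

Cohort medians (clones per cancer, fraction disseminated, first
dissemination time, monophyletic interval) are reported with bootstrap
95% CIs (B = 1000; the CI method for medians is a plain percentile
bootstrap). On synthetic cohorts these are recovery diagnostics of the
generator's own settings, not reproductions of any published cohort.

## Known limitations

* Clone numbers are under-recovered relative to truth when deep local
  subclones are simulated at low prevalence — they fall below the
  discovery filters, exactly as they would in real data. Mode and
  direction calls are insensitive to this.
* The Gaussian-mixture surrogate for CCF clustering assumes near-Gaussian
  CCF noise, which holds at several-hundred-fold depth but not for shallow
  data.
* The pairwise-site fallback reports per-pair models but no reconciled
  multi-site tree; such patients are flagged rather than resolved.
* Mutation time is proportional to calendar time only under a constant
  mutation rate and division time; it should be read as mutational
  diversity, not as a clock.
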