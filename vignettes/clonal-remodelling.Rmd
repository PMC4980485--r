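---
title: "Inferring treatment-induced clonal remodelling from paired tumour samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring treatment-induced clonal remodelling from paired tumour samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaldrift)
library(dplyr)
```

## The problem

Oestrogen-receptor-positive (ER+) breast tumours treated with a neoadjuvant
aromatase inhibitor (NAI) for roughly four months are under strong selective
pressure: subclones differ in their susceptibility to oestrogen deprivation,
so the clonal composition of the tumour at surgical resection can differ
dramatically from the composition at the baseline biopsy. `clonaldrift`
quantifies that remodelling from somatic variant read counts in matched
baseline and surgical samples (plus a matched normal), and classifies each
case into one of four genomic patterns: collision tumours (two genomically
independent tumours in one site), clonally simple and treatment stable,
clonally complex and treatment stable, and clonally complex and treatment
dynamic.

## The model, stage by stage

**Somatic filtering.** A variant call with at least 10x coverage in both
tumour and normal is kept as somatic when a binomial log-likelihood ratio
exceeds 3. The LLR compares a somatic model -- the normal sample at the
sequencing error rate $e$ and the tumour at its maximum-likelihood allele
fraction $\hat f = \max(v/d, e)$ -- against the better of two germline
explanations: heterozygous (both samples at fraction $0.5$) and wild type
(both at $e$). All three likelihoods are binomial and natural logs are used.
The error-rate constant is exposed as a parameter (default $e = 0.001$, a
typical Illumina substitution rate); binomial coefficients cancel between
hypotheses. Note one consequence of the three-hypothesis design: as the
tumour VAF approaches 50% over a clean normal, the somatic and heterozygous
likelihoods converge and the LLR falls again, so the statistic is monotone
in variant reads only while the wild-type model is the best alternative.

**Copy-number-neutral masking.** VAF clustering assumes diploid heterozygous
loci, where a clone at cellular prevalence $q$ in a sample of purity $p$
yields an expected VAF of $pq/2$. A locus is retained iff its copy number is
within 0.25 of 2 in *every* sample of the case (the same margin sciClone's
`copyNumberMargins` applies); loci not covered by a segment default to copy
number 2, and overlapping segments with contradictory copy numbers raise an
error rather than being resolved silently.

**Purity and correction.** Purity is twice the median VAF of the founder
cluster, clamped to 1. With a clustering in hand the founder is the cluster
detected in all samples whose worst-sample median VAF is highest; without
one, the upper mode of a kernel-smoothed VAF histogram (fixed bandwidth
0.02, comparable to binomial VAF noise at ~100x) stands in, with the founder
median taken over all VAFs from just below the mode upward. The kernel route
is honest about its limits: a subclone within about one bandwidth of the
founder in a given sample biases it low, which is why the pipeline always
estimates purity from the fitted clusters. VAFs are corrected by removing
the normal-cell read mass from the reference count,
$r' = \max(0,\, r - (1-p)(r+v))$, the unique linear rule that maps a founder
heterozygous variant (raw VAF $p/2$) to 50%. Corrected reference counts are
rounded half-up to integers so that Fisher's exact test downstream receives
counts; published descriptions of this correction do not say whether
fractional pseudo-counts were carried instead, so integer rounding is this
package's documented choice. Purity is always estimated per core, never pooled:
purity is a property of the specimen, and the cohort's specimens ranged
from 12% to 100% tumour content.

**Temporal classification.** Each baseline x surgical core pair is tested
with a two-sided Fisher's exact test on the purity-corrected 2x2 table of
(reference, variant) reads by time point, defined conventionally as the sum
of hypergeometric probabilities no larger than the observed table's. Calls
with $p < 0.05$ are retained as changed; there is no multiple-testing
correction by default, mirroring per-variant retention at $p<0.05$, with a
Benjamini-Hochberg option available. Significant calls with both corrected
VAFs at or above 10% are enriched/depleted by direction; a significant call
below 10% corrected VAF in the other time point becomes baseline- or
surgical-specific provided it has at least one variant-supporting RNA read
in its own time point, and degrades to enriched/depleted with a flag when
only the RNA requirement fails. The 10% rule is applied to *corrected* VAFs
(consistent with the correction step that precedes it; the alternative
reading -- raw VAFs -- is not used). Across multiple cores the minimum p
with a majority-vote direction is reported; the aggregation rule is this
package's choice, since only the pairwise comparisons themselves are
prescribed.

**Clustering.** Copy-number-neutral VAFs are clustered jointly across all
$S$ samples of a case with an $S$-dimensional binomial mixture fitted by EM
for $K = 1..k_{max}$ (default 10), 10 seeded restarts each, model selection
by BIC. A binomial (not beta-binomial) component likelihood matches the
generator's noise model and keeps the M-step closed form; overdispersion is
a noted extension. Initialisation is quantile-spaced per sample with seeded
jitter; posteriors below 0.8 are flagged as outliers but retained; clusters
with fewer than 5 members are dissolved and their members reassigned
(singleton pseudo-clones otherwise masquerade as rare subclones). Cases
with fewer than 10 variants are flagged `manual`, mirroring the cohort's
three unclusterable cases. Two numerical details: component means are
clamped to $[10^{-6}, 0.75]$ (copy-number-neutral VAFs cannot meaningfully
exceed 0.5 plus noise), and the BIC scan stops after two consecutive
increases, which in practice scans to about the selected $K$ plus two.
The per-fit log-likelihood trace is exposed and is non-decreasing, which
the tests assert. A case where some cluster pair differs by less than 0.05
VAF in every sample is flagged `low_separation` (the qualitative
"insufficient separation" situation), without claiming equivalence to the
original exclusion rule.

**Clone trees.** Cluster medians, corrected for purity, convert to cellular
prevalences via $q = \min(1, 2\,\mathrm{VAF}/p)$; clusters whose corrected
median VAF falls below the ~1% detection limit in a sample get prevalence 0
there rather than a noisy raw estimate. Rooted trees over clusters are
enumerated exhaustively (bounded at 10 clusters) from the founder -- the
cluster at least as prevalent as every other in every sample -- and kept
when they satisfy the sum rule (a parent's prevalence is at least the sum
of its children's) in every sample within a tolerance of 0.05 plus the
binomial standard error of the cluster prevalence; a pure hard constraint
rejects true trees at finite depth. Feasible trees are ordered by total
violation mass ("slack"), with ties broken by a label-invariant canonical
form so that relabelling clusters can never change which tree ranks first.
Downstream numbers use the first tree; alternatives are retained in the
result object.

**Collision detection.** Two evidence classes: `disjoint_variants` when no
cluster is detectable in both a baseline and a surgical sample, and
`no_feasible_tree` when shared clusters exist but no single-origin tree
satisfies the sum rule (including the case where no cluster dominates every
sample, so no founder exists -- the signature of a cryptic second tumour
whose cluster rises above every other at surgery). Cases with one time
point are explicitly `not_evaluable`.

**Instability index and patterns.** Exclusive clone fractions (prevalence
minus children's prevalences, clipped at 0 and renormalised to sum to 1
over tumour cells) are averaged across cores within each time point, with
clones absent from a core contributing 0. The clonal instability index is
the mean absolute difference between the pre- and post-treatment fractions
over the union of clones detected at either time point. This makes the two
printed interpretations exact: an unchanged monoclonal tumour scores 0 and
two completely unrelated one-clone tumours score 1. Exclusive fractions
(rather than cellular prevalences) are used precisely because they produce
those endpoints; whether the original "clonal percentages" were exclusive
or cumulative is ambiguous in published accounts, so this is a documented
design choice, as is averaging across cores (versus designating one). Patterns follow the index
with the 0.1 cutoff inclusive on the stable side -- so an index of 0.097 is
complex-but-stable -- and a `manual_pattern` column consumed verbatim
carries expert assignments for cases outside automated inference (ploidy
shifts, unresolvable cluster structure). Fractions here are over tumour
cells after purity correction; normal-cell admixture is already divided
out.

## What the synthetic generator emulates, and what it does not

`simulate_phylogeny()` plants a rooted clone tree (two disjoint trees for
collisions) with per-sample exclusive fractions; because exclusive
fractions are non-negative and sum to 1, the sum rule holds by
construction. Scenarios fix the character of the baseline-to-surgery shift:

* `stable` -- every clone moves by at most 0.05;
* `dynamic` -- a dominant subclone (0.60-0.85) collapses below 0.04 while a
  rare one (0.01-0.03) expands above 0.55, the near-complete subclone
  replacement archetype;
* `emergent` -- one leaf clone below the ~1% VAF detection limit at baseline
  dominates the surgical sample;
* `collision` -- two clone sets sharing no variants, one per time point;
* `monoclonal` -- a single founder at fraction 1 throughout.

`simulate_reads()` draws depths Poisson around the configured mean (DNA
floored at one read), variant reads binomially at
$\mathrm{VAF} = p_s\,q_{cs}/2$ perturbed by a 0.1% per-allele error, matched
normal reads at the error rate alone, and RNA support reads analogously at
the RNA depth. Purities default to the observed 12-100% range. Multi-core
time points can jitter fractions with a Dirichlet perturbation
(concentration 50 by default), emulating the spatial heterogeneity seen in
concurrent biopsies.

The generator deliberately omits: overdispersion beyond binomial,
copy-number aberrations at variant loci (segments are written as diploid),
mapping artefacts, allele-specific expression (RNA VAF equals DNA VAF in
expectation), and read-level (FASTQ/BAM) structure. Passing recovery tests
on this generator therefore demonstrates correctness of the inference
machinery under its stated model, not robustness to every artefact of real
sequencing data.

## Study conditions used by the recovery suite

The seeded benchmark runs 100 cases -- scenarios cycling through stable,
dynamic, emergent and collision, 2-5 clones, 35 variants per clone, mean
depth 150x, purities drawn from 0.3-1, and phylogeny/purity draws rejected
until every clone pair's expected VAFs separate by at least 0.1 in some
sample (unresolvable planted clusters would make recovery ill-posed). It
asserts: the clone count recovered in at least 90% of cases, at least 95%
mean assignment accuracy, at least 90% of purity estimates within 0.05,
the planted tree in the feasible set in at least 95% of non-collision
cases with recovered K, the planted instability index within 0.07 in at
least 90% of cases, and the planted pattern (collision included) in at
least 90%. The exact-test oracle sweep covers every 2x2 table with total
at most 200 through one representative per margin-symmetry orbit (about
1.4 million tables checked directly) plus explicit symmetry checks, and
the LLR filter is compared against direct likelihood evaluation on the
full grid of tumour-by-normal count configurations with depth at most 30.
These sizes keep the whole suite around two to three minutes on one CPU.

## Known limitations

* The binomial mixture understates variance on real data; a beta-binomial
  component is the natural extension.
* Tree enumeration is exact but exponential; it is bounded at 10 clusters,
  comfortably above the 5-6 clusters resolvable from ~100x whole-genome
  VAFs.
* The kernel-mode purity estimator needs a resolvable founder mode; prefer
  the cluster-hint route (the pipeline default) or supply purity.
* Ploidy shifts and complex copy-number change defeat the diploid model by
  design; such cases should arrive with a `manual_pattern`.
* There is no shell entry point: users drive the package from R
  (`run_case()`, `run_cohort()`), as with the clustering and tree packages
  whose roles it fills.
```{r session}
sessionInfo()
```
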