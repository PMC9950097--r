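---
title: "Methods: CNV, ROH and mosaicism screening from SNP-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV, ROH and mosaicism screening from SNP-array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscreen)
```

This vignette is the package's account of its methods: the signal model
behind the six-state CNV caller, the mosaic and ROH screens, the
permutation machinery, the parameters that matter, and the design
decisions taken where more than one reasonable choice existed. It also
states what the synthetic-data generator does and does not emulate, and
the problem sizes the test suite and acceptance script run at.

## Signal model

A genotyping array reports, per marker and sample, a total-intensity
log-ratio (LRR, log2 of observed over expected intensity at the
marker's genotype cluster) and the B-allele fraction (BAF). Under
normal diploidy LRR is centred at zero and BAF clusters at 0, 1/2 and 1
with Hardy–Weinberg weights at the marker's population B-allele
frequency (PFB). Copy-number changes move both: deletions depress LRR
and empty the heterozygous band; duplications raise LRR and split the
het band to thirds (CN3) or quarters (CN4); copy-neutral LOH empties
the het band at unchanged LRR; a mosaic change present in a cell
fraction $f$ splits the het band to $0.5 \pm d$ with

$$d_\text{loss} = \frac{f/2}{2-f}, \qquad d_\text{gain} = \frac{f/2}{2+f},
\qquad d_\text{CN-LOH} = \frac{f}{2},$$

which invert to $f = 4d/(1+2d)$ (loss), $f = 4d/(1-2d)$ (gain,
capped at 1; $d = 1/6$ is a constitutional trisomy with bands at 1/3
and 2/3) and $f = 2d$. When the accompanying LRR shift is inside a
dead zone of $\pm 0.02$ the direction is reported as `unknown` and the
loss/gain bracket is returned with its midpoint as point estimate —
arm-scale events with visibly split BAF but no LRR displacement are
exactly the hard case this screen exists for.

## What the generator emulates

`simulate_cohort()` draws genotypes per marker from Hardy–Weinberg
proportions at the PFB, BAF from the genotype cluster means plus
Gaussian cluster noise (clamped to $[0,1]$), and LRR as Gaussian noise
around the copy-number state mean, with three structured artifacts:

* a GC wave, `gc_wave_amplitude * (gc_frac - mean gc)`, on a smooth
  low-frequency GC field in $[0.3, 0.7]$;
* a constant per-batch intensity offset (two batches, offsets drawn
  with SD `batch_shift_sd`);
* uniform BAF outliers at rate `outlier_rate`, recorded as no-calls.

Planted events rewrite the affected slice: CN0 markers lose their
genotype signal entirely (uniform BAF, no-call genotype); CN1 and ROH
force hemizygous/homozygous calls; CN3/CN4 draw allele counts
binomially; mosaic events displace each het marker's BAF to
$0.5 \pm d$ with a random band sign per marker.

Default noise levels — `lrr_sd = 0.2`, `baf_sd = 0.03`,
`outlier_rate = 0.005`, `gc_wave_amplitude = 0.1`,
`batch_shift_sd = 0.1` — are conventional magnitudes for a modern
genotyping array; no published per-array values were available to copy,
so they were fixed once for testability and are exposed in
`noise_model()`.

The generator does **not** emulate: linkage disequilibrium between
markers (genotypes are independent given the PFB), family structure,
allele-specific probe biases, spatially autocorrelated noise beyond the
GC wave, or raw two-channel intensities (except what
`compute_lrr_baf()` needs for its own tests). Consequences: passing
tests show the pipeline recovers events and calibrates inference under
the *assumed* signal model; they do not certify behaviour under probe-
level artifacts absent from that model. The LD-pruning and
HWE-filtering steps are exercised on independent genotypes, where their
expected action is "remove little, at the type-I rate" — their
behaviour under real LD is validated only structurally (the duplicated-
marker and threshold-monotonicity tests).

## Quality control

Per-sample metrics restrict windows exactly as defined: `lrr_sd` over
LRR values in $[-2, 2]$ (so true CNVs do not inflate the noise
estimate) and `het_baf_sd` over BAF in $[0.15, 0.85]$. A sample fails
when either metric exceeds the cohort mean by more than three cohort
SDs of that metric, or its call rate is at or below 0.95. The
three-SD screen is read as a *cohort-level* outlier rule, and it is
applied in a single pass; re-screening after exclusions shifts the
cohort statistics slightly, so a `reference` argument allows idempotent
re-runs against frozen statistics.

Marker QC applies call rate > 0.95, a Hardy–Weinberg *exact* test
(mid-p off; monomorphic markers define p = 1) at p > 1e-5, and — when
sex is known — Fisher's exact test on missingness by sex and an
allele-count chi-square (Fisher fallback when any expected count is
below 5) on frequency by sex, both at p > 1e-4. The HWE implementation
uses the standard two-term recurrence over heterozygote counts and is
tested against a full log-multinomial enumeration oracle.

Relatedness uses the method-of-moments IBD decomposition from observed
IBS counts and allele frequencies, with negative moment estimates
truncated to zero and renormalized; `pi_hat = P(IBD=2) + P(IBD=1)/2`.
Ancestry PCA standardizes each marker by its binomial SD before the
decomposition.

## Intensity correction

Order of operations: principal-component correction first, then GC
adjustment, following the upstream narrative of quality/batch effects
being removed before wave adjustment.

The PCA is fitted on copy-stable probes (flagged stable *and* below the
90th percentile of cross-sample LRR variance). Each probe's LRR is then
regressed across samples on the retained component scores and replaced
by its residual. One guard matters in small cohorts: a component whose
three largest squared sample loadings sum above 0.35 is *private* to a
handful of samples — in practice a large rare CNV, not a quality or
batch effect — and regressing it out would both erase the carriers'
events and leak them, with flipped sign, into every other sample at the
same probes. Such components are excluded from the regression. The
threshold sits well above the loading concentration of a pure-noise
component for realistic cohort sizes and well below that of a
single-carrier component; cohort-level effects (batch halves, quality
gradients) spread their mass across many samples and are untouched.

GC adjustment is per-sample (a pooled flag exists): a linear (or
optionally spline) regression of LRR on local GC fraction, fitted only
on markers with $|LRR| < 0.5$ so that real CNVs do not pull the wave
estimate, then subtracted everywhere. A constant GC track makes the
step a warned no-op.

## The CNV HMM

Six states: CN0, CN1, CN2 (reference), CN2-LOH, CN3, CN4, with default
LRR means $(-3.0, -0.66, 0.0, 0.0, +0.40, +0.68)$ — conventional
log2-scale values for one through four copies (the CN0 mean is largely
a placeholder for "signal collapsed"; its SD is wide at 1.0). BAF
emissions are state-specific cluster mixtures with Hardy–Weinberg
weights at the marker's PFB and censored-Gaussian clusters: interior
BAF values take the Gaussian density, values clamped at exactly 0 or 1
take the censored tail mass; every state additionally carries a uniform
outlier component with weight 0.01 so no single corrupt marker can veto
a state. CN0 emits uniform BAF.

Transitions decay with inter-marker distance:
$P(i \to j) = \pi_j\, \rho_{\max}(1 - e^{-d/D})$ off-diagonal, with the
diagonal absorbing the remainder; $D = 100$ kb, $\rho_{\max} = 0.5$,
and priors heavily favouring CN2 (0.995 before normalization). At
$d = 0$ the matrix is the identity; at large $d$ the rows approach the
priors scaled by $\rho_{\max}$.

Decoding is exact Viterbi per chromosome (autosomes only). Because the
sticky transitions bias the decoded runs toward late entry and early
exit, each raw segment's boundaries are re-anchored at the maximum-sum
interval of the per-probe emission log-likelihood ratio (called state
vs CN2) through the segment's core, within a 20-probe window and never
crossing a neighbouring segment. This removes a systematic 2–5 probe
edge trim at moderate SNR and is the same estimator used for mosaic
breakpoints.

Confidence is the emission-only log10 likelihood ratio of the called
state against CN2 summed over the segment's probes. Post-processing, in
order: probe-count and confidence filtering (CN0 at ≥ 3 probes, other
states at ≥ 15, confidence ≥ 10, CN2-LOH routed out of the CNV list),
merging of same-copy-number neighbours when the inter-call gap is
*strictly* less than 20% of the smaller call's length (probe counts
recounted from the map, confidence recomputed, iterated to a fixed
point; a tie at exactly 20% does not merge), and centromere splitting
with the two sides re-anchored at the flanking probes, re-scored, and
re-filtered (confidence is recomputed after merging — whether the
reference tools do so is unstated, and recomputation is the
self-consistent choice).

## Mosaic screen

Per chromosome arm, the SD and IQR of het-band BAF (values strictly
inside 0.15–0.85) summarize band splitting; arms with fewer than 50 het
markers (long ROH arms) are reported absent rather than scored, which
keeps constitutional autozygosity out of the mosaic cloud. Outlier
arms exceed the cohort median by more than five MADs in either
statistic — a robust stand-in for what is otherwise a visual call on
the SD/IQR scatter; the multiplier is exposed.

Flagged chromosomes are scanned with a two-state HMM on the folded
values $y = |BAF - 0.5|$ over het markers: the neutral state emits a
half-Gaussian at zero with SD $\sigma$, the mosaic state a folded
Gaussian at a band deviation $d$ profiled over a grid (0.02–0.30, step
0.01, best total Viterbi likelihood; afterwards $d$ is re-estimated as
the mean $y$ over the decoded run). $\sigma$ comes from the cohort's
non-outlier arms, or off-chromosome hets for a single sample — never
from the scanned chromosome itself, which a large event would
contaminate. Transitions use the same distance-decay family as the CNV
HMM but stickier ($D = 1$ Mb, $\rho_{\max} = 0.2$): the targets are
arm-scale events and the per-marker evidence at small $d$ is weak.
Decoded mosaic runs shorter than 25 het markers are dropped, short
neutral interruptions are bridged, and boundaries are refined by the
maximum-sum log-likelihood-ratio interval, constrained never to cross
an inter-het gap above 1 Mb (otherwise a refinement can jump a
centromere). Breakpoints are reported at the outermost het markers.

## Runs of homozygosity

Markers are prepared by a MAF ≥ 1% filter and LD pruning to pairwise
$r^2 \le 0.30$ (the generic pruning presets 50-SNP window, 5-SNP step
are shared with the ancestry prep at $r^2 \le 0.2$). Runs are then
grown greedily left to right and must satisfy all five criteria: span
≥ 1 Mb; ≥ 100 markers; at least one marker per 50 kb; at most one
heterozygote per Mb of span, with a floor of one; and no inter-marker
gap above 1 Mb (runs split at such gaps). The sliding-window internals
of the reference tool are deliberately *not* emulated — the five
textual criteria are the specification, and an independent post-hoc
validator re-checks every emitted segment directly against the
genotypes. Missing genotypes neither break a run nor count as
heterozygous (a `missing_breaks` flag gives the stricter reading).
Segments start and end at homozygous markers.

The region scan counts case and control carriers per marker: seed
regions are maximal runs with ≥ 10 case carriers, extended outward
while ≥ 7 cases still overlap and the control-carrier count never
exceeds its maximum over the seed (that is the operational reading of
"a new control appears"); separately, maximal runs with ≥ 7 cases and
zero controls are reported when not already inside a seed region.
Reported coordinates are pruned-marker boundaries.

## Permutation inference

All case-control contrasts share one engine: statistics are computed
from per-sample event summaries, phenotype labels are permuted
preserving group sizes, and empirical p-values use the
$(r+1)/(n+1)$ estimator, which is never exactly zero. Burden contrasts
(rate, carrier proportion, mean total span, mean event size — the mean
size being a ratio of sums, so samples without events do not dilute it)
are one-sided for case enrichment. The segmental scan's statistic at
each marker is the case carrier count minus the control count scaled by
the case/control ratio; EMP1 is pointwise and EMP2 compares each
marker's observed statistic against the *genome-wide maximum* per
permutation, the standard max-statistic family-wise correction, so
EMP2 ≥ EMP1 everywhere by construction. CNV burden uses a strict
size cut (calls of exactly the threshold length are excluded).

Known-locus annotation matches any overlap with a direction-compatible
locus by default; a reciprocal-overlap threshold is configurable since
no overlap rule is prescribed anywhere authoritative. The packaged
locus table carries recurrent NAHR-mediated loci (22q11.21, 16p11.2
proximal/distal, 15q13.3, 1q21.1, ...) with hg19 coordinates.

## Numerical choices and degenerate inputs

* BAF exactly 0/1 is handled by censored cluster mass, keeping
  likelihood ratios finite; degenerate PFB is avoided at generation
  (truncated to [0.01, 0.99]).
* Viterbi ties break toward the lower state index (deterministic).
* Monomorphic markers define HWE p = 1; a marker with missing clusters
  is flagged unusable rather than guessed.
* Single-sample cohorts cannot be screened (cohort statistics
  undefined) and error out rather than silently passing.
* All stochastic code paths take explicit integer seeds and restore the
  caller's RNG state; identical seeds give byte-identical signal files.

## Problem sizes

The test suite and the acceptance script run, by choice, at a scaled
cohort: 3,000-marker maps over two 30-Mb chromosomes (50 markers/Mb)
with 60 samples for CNV recovery; 1,000 replicates of 200 permutations
for null-uniformity; 25 replicates at the full 136/97 sample split for
burden power; and a 24,000-marker map (200 markers/Mb, the density
regime of a modern 780k array scaled to two chromosomes) for mosaic
recovery, where an 85%-of-arm event at band deviation 0.05 carries
roughly 2,500 het markers. These sizes keep every stage's statistical
behaviour in the regime the methods assume — in particular, boundary
resolution and pruning stability both degrade qualitatively below a few
dozen samples or a few tens of markers per Mb, which is a property of
the estimators, not of the implementation.

## Known limitations

* No sex-chromosome CNV calling (the screen reports X/Y aneuploidy
  instead); no trio or de-novo analysis; no EM re-training of HMM
  parameters (they are fixed and configurable).
* Mosaic fractions above ~0.75 push the split bands outside the
  0.15–0.85 het window and are intentionally out of reach of the BAF
  screen; they look like constitutional events and are the CNV/LOH
  caller's job.
* The private-component guard in the PC correction protects rare
  events; a CNV shared identically by a large fraction of the cohort
  would instead be treated as an artifact — at which point it is no
  longer "rare" and burden inference on it is moot.
* Real-data idiosyncrasies (probe-specific bias, LD, population
  stratification within cohorts) are outside the generator's model, as
  described above.
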