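---
title: "Models and design choices behind panelval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind panelval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

`panelval` characterises the analytical performance of a targeted
tumor sequencing panel: a filter-cascade caller for base substitutions
and indels, a matched-normal copy-number caller, a clipped-read
rearrangement caller, and the validation computations (sensitivity
versus depth, purity dilution limit of detection, orthogonal-assay
concordance) that a clinical validation study performs on them. This
vignette explains the models, the parameters that matter, and the
choices made where the design was genuinely open.

## The count model for sequencing evidence

Read-level data are deliberately abstracted to stranded count records.
Every decision the SNV/indel cascade makes depends only on the alt and
reference counts per strand, the total depth and the matched-normal
counts, so per-read simulation would add cost without adding
discriminating power. The generator draws, per site with true allele
fraction $m$:

* depth $D \sim \mathrm{Poisson}(\bar d)$ (or fixed, for titration
  experiments at exact depth),
* alt count $a \sim \mathrm{Binomial}(D, m)$,
* forward alt count $\sim \mathrm{Binomial}(a, s)$ with strand
  probability $s = 0.5$ by default ($s$ is a knob for exercising the
  strand-bias gate),
* a matched normal generated identically with $m$ replaced by the
  background error rate (default $10^{-3}$).

Depth titration uses hypergeometric downsampling — drawing the target
number of reads without replacement from the site's original read
multiset — so the expected allele fraction is preserved exactly at
every depth.

**What this does not emulate:** base-quality structure, PCR
duplicates, mapping artefacts, FFPE deamination damage, and local
assembly for indels. Passing simulation benchmarks therefore
demonstrates that the *decision rules* behave as specified under the
stated sampling model, not that the upstream alignment and assembly
of a production pipeline reach that model's ideal.

## The filter cascade and its boundaries

The cascade's gates are named constants in `call_thresholds()`:
minimum depth 30 (depth exactly 30 passes — the requirement is "not
less than"), matched-normal allele fraction at most 0.03 (the bound is
read as an allowed maximum, so 0.03 itself passes), strand fraction
within $[0.1, 0.9]$, and a strict MAF cut ($> 1\%$, $> 0.5\%$ at
hotspots). Two boundary decisions deserve comment:

* The strand-bias test is skipped below 2 alt reads: a single read
  always has fraction 0 or 1, so the test would be vacuous noise.
* The "empirically increased requirement" for repeat-tract indels is
  quantified here as MAF $\ge 2\%$ and $\ge 8$ alt reads (both
  configurable); no published values exist for this rule, so the
  defaults were chosen once as a plausible doubling of the headline
  MAF cut plus an absolute read floor, and are exercised but not
  tuned by any benchmark.

Fraction comparisons are performed in scaled-integer arithmetic
(`a * 10^9` versus `D * round(t * 10^9)`), so thresholds with up to
nine decimals compare exactly and a site at MAF exactly 1% can never
drift across the strict cut through floating-point division.

The beta-binomial posterior $P(p > \varepsilon \mid a, D)$ under a
Beta(1, 99) prior (Beta(5, 95) at hotspots) is advisory output only.
The published, reproducible gates are the four threshold rules; a
posterior gate would add an unpublished degree of freedom, so it is
reported (VCF `POSTERIOR` INFO field) but never decides a call.

## Copy number

The per-target log2 ratio uses library-size normalisation
($\log_2\frac{t_i/T}{n_i/N}$); bins with zero normal coverage are
masked, not imputed, because a ratio against nothing is not evidence.
GC bias is removed by subtracting per-stratum medians (20 equal-width
GC strata, global-median fallback below 5 bins per stratum) computed
over putatively neutral bins — by default all unmasked bins, relying
on the median's robustness while amplified targets are a minority of
the panel.

Segmentation is an agglomerative merge under a Gaussian BIC,
$\mathrm{RSS}/\sigma^2 + \lambda k \log n$ with $\lambda = 2$. The
textbook profiled-variance form $n\log(\mathrm{RSS}/n)$ cannot start
an agglomerative pass (at one bin per segment the RSS is identically
zero and every first merge has infinite relative cost), so the noise
scale is held fixed at a robust estimate from first differences,
$\hat\sigma = \mathrm{median}|\Delta x| / (0.6745\sqrt2)$. A merge is
accepted when it raises the RSS by less than
$\lambda\hat\sigma^2\log n$; ties break to the leftmost pair and
segments never cross chromosomes, making the result deterministic.
The estimate assumes jumps are sparse among neighbouring bins; for
re-segmenting derived profiles whose differences are all true jumps
(e.g. segment means), pass the original scale through the `sigma`
argument — idempotence holds at fixed scale.

Amplification calling inverts the purity mixing identity
$\mathrm{CN_{obs}} = p\,\mathrm{CN_t} + 2(1-p)$, reporting
$\mathrm{CN_t} = (2 \cdot 2^{\bar\ell} - 2(1-p))/p$ per segment. A
segment is called amplified when the inferred tumor copy number
reaches the threshold (default 4 copies, compared within half a copy
to absorb estimation noise) **and** the observed segment ratio clears
a detectability floor, `min_log2 = 0.3`. The floor carries the
biology of the dilution experiment: a 4-copy amplification diluted to
20% tumor content sits at $\log_2(1.2) \approx 0.263$, inside the
band where capture noise and GC-correction residue live, and no
purity correction can rescue a signal that never rose above the
noise. Purity correction alone would make the call threshold
purity-invariant and the low-purity dropout unobservable — with the
floor, the dilution series reproduces the expected behaviour: all
five fixture amplifications called at 50% purity, the 4-copy gene
(AKT1 in the fixture) lost at 20%. The fixture's copy numbers are a
modelling choice (the cell line's true values are not published): the
four high-level genes at 10 copies, AKT1 at the lowest amplified
level so it is the first to fall below detection.

## Rearrangements

Breakpoint evidence comes from two sources. A soft-clipped read marks
a junction exactly at its clip boundary ($\mathrm{pos}$ for left
clips, $\mathrm{pos} + \mathrm{aligned\ length}$ for right clips;
minimum clip 10 bp). Discordant pairs — different chromosomes, outer
span over 2 kb, or same-direction mates — mark both sides
approximately by each mate's junction-facing end. The 2 kb span is
measured as outer distance (leftmost start to rightmost end), the
natural reading of a span rule for paired reads. The phrase that
discordant candidates "are filtered" was taken as *kept* (filtered
in), the only reading consistent with the subsequent keep rule.

Evidence sharing chromosomes and orientations on both sides is
clustered by single linkage within a 50 bp window (processed in
sorted order, hence deterministic), and junction geometry classifies
the event: different chromosomes — translocation; equal orientations
— inversion; opposite orientations with the left-retaining side at
the lower coordinate and a gap over 2 kb — long deletion; the
reversed arrangement — tandem duplication. Calls need one side in a
baited region; support thresholds (3 split reads or 5 discordant
pairs) are config-exposed defaults chosen once at the level
production SV callers use, as no published values exist for them.

## Validation engine

Sensitivity curves bin truth variants by *true* MAF into the three
reporting bins, with edges $(0, 0.10]$, $(0.10, 0.20)$ and
$[0.20, 1]$ (edge membership is unstated in the conventions the bins
come from; the choice keeps the bins a partition and puts each
boundary with its printed label). Sensitivity is averaged over
downsampling replicates (default 10) with the s.e.m. across
replicates as the error bar. The plateau depth is the first grid
depth within `epsilon = 0.002` of the grid maximum — tight enough
that a curve must be flat to 0.2 percentage points before it counts
as saturated.

Concordance tables are exact count arithmetic. One convention needs
care: when every compared sample is NGS-positive and the orthogonal
assay confirms calls, the confirmed fraction is a positive predictive
value, which clinical validation reports sometimes label
"specificity". `concordance(..., paper_mode = TRUE)` reproduces that
labelling while always emitting both definitions explicitly.

## Problem sizes and determinism

The shipped test-suite and acceptance computations use a toy panel of
282 regions across 19 genes, truth sets of a few hundred to ~1,700
sites, coverage around 500–2000× and 10 replicates — sizes at which
every benchmarked quantity is stable to well under its tolerance
(binomial miss probabilities at the benchmarks are below $10^{-16}$
per site at 500×, and the dilution dropout is reproduced in 20/20
seeds in exploratory runs). All generators are deterministic given a
seed; a run seed fans out to per-stage child seeds via the documented
Lehmer-style map in `derive_seed()`, so any stage can be re-run in
isolation and the full pipeline is bit-reproducible under a fixed
configuration.

## Known limitations

* Counts, not reads: mapping ambiguity, strandedness artefacts tied
  to sequence context, and assembly failure modes for long indels are
  outside the model.
* The cell-line MAF spectrum (truncated Beta(1.2, 12), ~97.5% of mass
  below 30%) reproduces a summary statistic of pooled cancer cell
  lines, not their full mixture structure; pools are emulated as
  replicate draws rather than explicit 2–10 line mixtures.
* The hotspot catalog shipped in `inst/extdata` is illustrative; real
  deployments must supply their own.
* Fusion breakpoints are recovered to clustering-window resolution;
  no split-read realignment to base-pair-exact junctions is
  attempted, and no transcript-frame annotation is made.
* Deletion/LOH calling and allele-specific copy number are out of
  scope; the copy-number caller targets amplifications.
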