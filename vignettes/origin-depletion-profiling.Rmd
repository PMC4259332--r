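---
title: "Profiling replication of an origin-depleted chromosome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling replication of an origin-depleted chromosome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oritrack)
```

## The problem

Budding yeast initiates DNA replication at discrete, well-mapped origins
(ARS elements) licensed by the origin recognition complex (ORC). A chromosome
VI derivative in which seven confirmed left-arm origins were deleted
nevertheless grows normally and, by BrdU-IP replication profiling under
hydroxyurea (HU), initiates replication at non-canonical loci near the deleted
origins — despite strongly reduced ORC binding there. `oritrack` packages the
computational side of that analysis as a reusable, tested pipeline:

1. a **genome model** of chromosomes, ARS annotations and the seven-origin
   deletion-edit table, with coordinate maps between edited and reference
   frames;
2. a **synthetic data generator** for probe-level Orc2 ChIP and BrdU-IP
   log2-ratio tracks on a reference-designed tiling array;
3. **robust track conditioning**: Tukey biweight centring and a 50 bp
   Hodges–Lehmann pseudomedian sliding window;
4. **normalization and comparison**: background-region normalization of BrdU
   tracks and wild-type minus mutant difference tracks;
5. **peak analysis**: initiation/binding peak calling and classification as
   canonical, residual (non-canonical, near a deleted origin), or novel, plus
   ORC-depletion detection on difference tracks.

The real arrays behind the published figures are deposited in GEO; their
reanalysis is out of scope here. The package instead ships a generator whose
defaults encode the study conditions, so every downstream guarantee is checked
against planted truth.

## Coordinate conventions and the deletion table

Internally every interval is 1-based and fully closed; BED files (0-based
half-open) are converted at the I/O boundary by `rtracklayer`. The deletion
table ([`ori7_edits()`]) stores the published per-origin coordinate ranges.
Two of its printed bp totals are not reproduced by inclusive arithmetic
(`end - start + 1`): ARS600 prints 15,292 where the coordinates give 15,392,
and ARS606 prints 434 where they give 435. Five of seven rows are exactly
consistent with the inclusive convention, so that convention is used
throughout; the printed values are retained verbatim as an attribute and are
never silently "fixed". Half-open arithmetic would fit ARS606 but break
ARS605, so no single convention explains both discrepancies.

`apply_edits()` flags origins deleted, computes post-edit chromosome lengths
(reference − removed + replacement; the 34 bp loxP scar is enforced, cassette
lengths for LEU2/ADE2/KanMX are typical values since the study does not print
them) and returns a block coordinate map. The map is injective and
order-preserving on mapped positions; replacement-cassette positions map to
`NA` ("non-reference"), and removed reference positions are absent from its
image. Because the tiling array is designed against the reference sequence,
all simulation and analysis stays in reference coordinates; the map exists for
interpreting edited-genome positions.

## The synthetic-data generator

### What it emulates

* **Array geometry** — 50-mer probes tiled every 8 bp (42 bp overlap between
  consecutive probes), both strands collapsed to one forward-coordinate probe
  set, covering chromosomes III, VI and XII.
* **ORC ChIP** — Gaussian peaks of sd 125 bp (half the 250 bp average
  sonication fragment size) and default amplitude 2.0 log2 units at each
  origin, over a flat background (0.3 log2) with i.i.d. Gaussian probe noise
  (sd 0.1 log2). A deleted origin keeps `residual_fraction` (default 0.3) of
  its amplitude — residual ORC binding on the flanking sequence.
* **BrdU-IP under HU** — a deterministic fork model: an origin firing at time
  `fire_time` with per-cell probability `efficiency` replicates all positions
  within `fork_speed * (t_total - fire_time)` of its midpoint; with origins
  independent, the replicated fraction is
  `f(x) = 1 - prod_i (1 - eff_i * reach_i(x))`, and the probe value is
  `background + brdu_gain * f + noise`. Defaults: 60 min labelling in 200 mM
  HU, fork speed 0.1 kb/min (HU-stalled forks travel ~6 kb in an hour),
  `brdu_gain` 2.0.
* **Reference-designed probes vs mutant DNA** — probes overlapping a removed
  span report background plus noise only in the edited genotype: the mutant
  has no DNA for them to hybridize.
* **Residual initiation near deleted origins** — modelled as `k = 3`
  sub-origins jittered within ±2 kb of the deleted origin midpoint, each
  carrying `residual_fraction * efficiency / k`. Jittered positions are
  reflected to just outside the removed span (offset preserved relative to the
  span boundary): only sequence that still exists in the mutant can initiate,
  and without the reflection the 15 kb ARS600 deletion would swallow its own
  sub-origins and mask their signal entirely.

Origin loci outside the deletion table (ARS602.5, ARS603.1, ARS607–609 and
the chromosome III origins) are approximate, and firing
efficiencies/times/amplitudes are simulator parameters — plausible values
chosen once, not measurements. Confirmed efficient origins fire at release;
late/dormant origins (ARS609, ARS316) at 30 min.

### What it does not emulate

Dye chemistry, whole-genome amplification bias, probe GC effects,
converging-fork interactions (fork travel under HU is short relative to
inter-origin spacing, so passive replication between origins is negligible),
and strand-specific signal. The left-telomere cross-hybridization artifact is
available only as an opt-in additive bump (`telomere_artifact`). Passing
recovery benchmarks on these synthetic tracks therefore demonstrates that the
processing chain is correct and well-calibrated for signals of this shape and
noise level — not that it would be free of artifacts on real arrays.

### Reproducibility

Each track derives an RNG stream from the base seed, the assay, the
chromosome and a digest of the genome's edit table. Identical seed and
configuration give bit-identical tracks; a genome with no edits is
bit-identical to the reference genotype (so a zero-edit "mutant" run equals
the wild-type run exactly), while any real edit decorrelates the two
genotypes' arrays, as independent hybridizations would be.

## Robust conditioning

**Tukey biweight centring.** Each track is centred by a redescending
M-estimator of location: IRLS with bisquare weights, tuning constant `c = 5`
in units of the MAD (scaled by 1.4826, fixed at its initial value), iterated
to `1e-8`. A zero MAD falls back to the median. This reproduces the
"biweight mean-adjusted" log2 ratios produced by standard tiling-array
software; the constant and tolerance are exposed as arguments.

**Pseudomedian smoothing.** The 50 bp sliding window is interpreted as a
window in genomic bp centred on each probe's start — about 7 probes at the
default design — not as 50 probes (~400 bp), which would visibly over-smooth
250 bp-scale ORC peaks. Within each window the filter takes the
Hodges–Lehmann pseudomedian: the median of all Walsh averages
`(x_i + x_j)/2`, `i ≤ j`, self-pairs included, with the even-count median
defined as the midpoint of the central pair. Windows shrink at chromosome
edges; the filter is applied once, anchored on probe starts (the original
study does not state the anchor or iteration count). It is shift- and
scale-equivariant and removes a single spiked probe outright whenever its
window holds at least five probes. Correctness is defined by — and tested
against — a brute-force per-window enumeration oracle; the vectorized
implementation groups windows by probe count and sorts Walsh-average rows in
bulk.

**Order of operations** mirrors the processing description of the assay:
biweight centring per track, then the pseudomedian window, then (BrdU only)
background normalization.

## Normalization and differencing

BrdU tracks are normalized by subtracting the unweighted mean of probes whose
start lies in the known unreplicated regions under 200 mM HU (chrIII
184–192 kb, chrVI 80–86 kb, chrXII 845–870 kb; kb endpoints expanded to
closed bp intervals), making peak heights comparable across data sets. The
recomputed background mean is zero to numerical precision and the operation
is idempotent; the subtracted constant is recorded in track metadata. ORC
tracks are not background-normalized — the unreplicated-region argument
applies to BrdU enrichment, not ChIP ratios — they are only centred and
smoothed. Differential tracks require identical probe designs and never
interpolate; mismatched positions are an error naming the first offending
coordinate.

## Peak calling and classification

Peaks are local maxima (plateaus report their leftmost probe) at or above
`min_height`, selected greedily by height subject to a 1 kb minimal summit
separation, with half-height bounds defining extent. The default threshold is
`5 * noise_scale(track)` where the noise scale is the MAD of probe-value
differences at a lag of one smoothing window, divided by √2. Two deliberate
choices here:

* **Lagged-difference noise estimation** rather than whole-track MAD: under
  HU roughly 40% of chromosome VI is replicated, so a whole-track MAD
  conflates biological signal with noise and over-estimates the threshold
  (missing genuine residual peaks); lagged differencing cancels slowly varying
  signal, and a lag of one window keeps the two probes of a pair independent
  after smoothing.
* **Five sigma** rather than three: a smoothed 30–40k-probe chromosome
  contains thousands of effectively independent local maxima, so a 3-sigma
  cut admits several spurious calls per track, while 5 sigma keeps the
  family-wise expected false-call count well below one — required for the
  unedited chromosome III control to stay clean.

Classification measures the summit-to-locus-interval distance (zero inside
the locus; for a deleted origin the locus is its removed span, the per-origin
coordinate range the study prints). The nearest origin within 5 kb decides
the label — `canonical` if intact, `residual` if deleted, `novel` if none —
with ties broken toward the closer locus midpoint, then lexicographically.
The 5 kb radius is far below inter-origin spacing on chromosome VI and is
configurable. `detect_depletion()` applies the same caller to the wild-type
minus mutant ORC difference track, annotates peaks with the nearest deleted
origin and reports deleted origins lacking a depletion peak as explicit
misses.

## Numerical and degenerate-input choices

* Empty value vectors, non-finite values, non-increasing positions,
  out-of-bounds or overlapping edits, and unknown origin names are validation
  errors, not warnings.
* A constant track yields no peaks (no strict local maximum) and a zero noise
  scale; thresholds of zero are honoured literally.
* Peak summits are reported at probe-start coordinates (the track anchor);
  the recovery benchmark converts summits to probe-midpoint coordinates
  before comparing with planted origin midpoints, since the generator
  evaluates signal at probe midpoints — a half-probe (24.5 bp) frame shift
  that would otherwise dominate the summit-error statistic.
* The Gaussian ORC peak is truncated at six standard deviations, so
  noiseless wild-type and mutant signals are exactly equal away from deleted
  origins.

## The recovery benchmark and problem sizes

`recovery_study()` is the package's own planted-truth check: at default
configuration it simulates, conditions and analyses chromosomes VI and III
for both genotypes over independent seeds (20 by default, ~15 s total) and
measures intact-origin recall and mean summit error on ORC tracks, deletion
recovery on the WT−mutant difference, residual BrdU recovery near deleted
origins, and false depletion calls on the unedited chromosome III control.
The test suite runs the same study at full chromosome scale; unit tests use
small toy chromosomes (tens of kb) so the whole suite stays fast. The
acceptance script (`scripts/acceptance.R`) recomputes all of these quantities
from scratch at a caller-supplied seed, plus a 10⁵-cell per-cell Monte-Carlo
cross-check of the analytic replicated-fraction formula.

## Known limitations

* The fork model's rectangular per-origin replication profile ignores fork
  stalling variance, so BrdU peaks have plateau tops; summit positions within
  a plateau are noise-determined, which is why origin assignment uses a 5 kb
  radius rather than exact summits.
* The generator's parameters are stylized: origin efficiencies, amplitudes
  and the residual fraction are uniform defaults rather than per-origin
  measurements, and loci outside the deletion table are approximate.
* `detect_depletion()` assumes the difference is wild-type minus mutant;
  inverted inputs yield no peaks rather than an error.
* No statistical significance model (FDR, Poisson background) is attached to
  peaks, matching the visual peak assessment of the original analysis.

## A worked example

```{r example, eval = FALSE}
library(oritrack)

report <- run_pipeline(run_config(outdir = tempfile("oritrack"), seed = 1))
subset(report$summary, status == "deleted")

rs <- recovery_study(n_seeds = 5, seed = 1)
rs$intact_recall
rs$mean_summit_error_steps
```

The per-origin summary lists, for each of the seven deleted origins, the
height of its ORC-depletion peak in the wild-type minus mutant difference
track and the position and label of the strongest BrdU peak within 5 kb —
`residual` for all seven at the default residual fraction.
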