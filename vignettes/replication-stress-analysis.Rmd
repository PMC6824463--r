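---
title: "Origin firing under checkpoint control: models and methods"
author: "RepliFire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Origin firing under checkpoint control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepliFire)
```

# The problem

When budding yeast cells meet replication stress (hydroxyurea depleting
dNTPs, or an alkylating agent such as MMS), the intra-S-phase checkpoint
blocks the firing of origins that would normally initiate later in
S-phase. Strains carrying checkpoint-blind alleles of the firing factors
(the *sld3-A dbf4-A* genotype) fire essentially all licensed origins under
stress. RepliFire implements the computational side of asking what that
global de-repression does to the genome: copy-number replication profiling
with a peak and fired-origin caller, replication-normalized damage (γH2A)
mapping stratified by the transcriptional orientation of origin-flanking
gene pairs, quantitative fitness analysis (QFA) of genome-wide genetic
screens, and plasmid-loss / catenane statistics. A built-in simulator
generates every input with known ground truth, so each stage is testable
without external data.

# The origin-firing simulator

`buildGenome()` lays out a compact genome (default one 1-Mb chromosome,
1-kb bins, 40 origins). Origin positions sit on a grid jittered uniformly
by ±20% of the mean spacing: perfectly regular spacing is both unrealistic
(real inter-origin distances are broadly dispersed) and statistically
degenerate — with a regular grid, removing origins often leaves the median
nearest-neighbour distance pinned at exactly one spacing, which would make
on/off comparisons uninformative. Each origin carries a `t_rep` (its mean
replication time in an unperturbed S-phase, drawn uniformly on 15–40 min)
and, optionally, a flanking gene pair placed 3 kb away in a prescribed
orientation (convergent, codirectional, divergent).

`simulateCellPopulation()` simulates cells independently. Under HU or MMS,
origins permitted to fire do so at the moment of release (t = 0): the
arrest is modelled as a single synchronous snapshot, which is the simplest
model that reproduces origin-centred copy-number bumps. An origin is
permitted at its base probability (default 0.9) if the checkpoint is off
or its `t_rep` is below the cutoff (default 27.5 min, the conventional
early/late split; equality counts as early), otherwise it fires at the
suppressed probability (default 0.02). Forks travel at 1.5 kb/min but at
most `maxForkTravel` (default 10 kb) — in HU forks move slowly and travel
on the order of ten kilobases in 90 min. Neither the fork speed nor the
HU travel cap is a measured quantity here; they are stated model defaults,
and peak widths respond to them monotonically (a tested property). In the
unperturbed regime firing times are exponential with mean `t_rep`, and an
origin reached by an incoming fork before its own firing time is passively
replicated: it does not count as actively fired (standard licensing
logic). Firing is drawn by inversion (`runif(n) < p`), so for a fixed seed
the simulation is monotone-coupled across firing probabilities and fork
geometries — the monotonicity invariants hold exactly, not just in
expectation.

`sampleReads()` draws per-bin counts: Poisson(depth) for the G1 library
and Poisson(depth × (1 + replicated fraction)) for the S library. Both
libraries share the same mean depth — an idealisation that matters for
normalization (below).

What the generator deliberately does **not** emulate: sequence content and
mappability (inputs are binned coverage by contract), dNTP-pool dynamics
and checkpoint-kinase kinetics, fork stalling/reversal mechanics,
replication–transcription collisions as a mechanism (orientation effects
are injected phenomenologically), and plate/position effects in colony
growth. Tests passing on these simulations therefore validate the
*analysis machinery*, not biological claims about real data.

# Copy-number profiles and normalization

`computeCopyNumber()` forms the per-bin S/G1 ratio. Three normalization
modes are offered because the right choice depends on what is known about
the libraries:

* `"mode"` (default for real data): scale both tracks to equal totals,
  then divide by the mode of the ratio histogram so the unreplicated
  background sits at 1.0. This is only identifiable when a substantial
  fraction of the genome is unreplicated. When most of the genome is
  partially replicated (e.g. a checkpoint-off population where nearly
  every origin fired), the histogram mode sits inside the replicated mass,
  not at the background, and anchoring mis-calibrates the whole profile.
* `"total"`: equal-totals scaling only; a partially replicated genome
  deflates the background below 1 by the mean replicated fraction.
* `"none"`: the raw ratio. Correct when the libraries are depth-matched —
  which tracks from `sampleReads()` are by construction. Simulation-driven
  analyses in this package therefore run with `normalize = "none"`.

`fourierSmooth()` low-passes each chromosome: linear interpolation across
missing bins, mirror padding (even extension, so no wrap-around
discontinuity and the chromosome mean is preserved exactly), FFT,
zeroing of every component with wavelength below the cutoff, inverse FFT,
un-padding, re-flagging of missing bins. The default cutoff is 20 kb,
matched to the width of an HU replication bubble (2 × 10 kb fork travel)
and safely below the mean origin spacing (25 kb) so adjacent origins stay
separable. A per-chromosome end mask is available for excluding
telomere-proximal bins rather than hard-coding their removal.

**A documented bias.** A brick-wall filter applied to a feature whose
width is comparable to the cutoff wavelength distorts the feature apex
(Gibbs phenomenon): for a 20-kb box at a 20-kb cutoff the apex overshoots
by ~18%. Consequently the fired fraction estimated as
`smoothed copy number − 1` at the origin bin is a *biased* readout —
multiplicatively inflated — while the raw (unsmoothed) ratio is unbiased
but noisy. At screening depth (30 reads/bin) the per-origin error of any
estimator has a hard floor: even an oracle that pools the entire 21-bin
replication bubble has a standard error of ≈ 0.08 in fired-fraction
units. The package documents this rather than hiding it: the ≥20%-fired
*call* is robust (the bias is multiplicative, so thresholding still
separates fired from unfired origins with ~95% accuracy at screening
depth), but per-origin fired *fractions* at depth 30 should be treated as
having ~0.1 absolute uncertainty. Deep libraries or averaging over origin
sets recover accuracy.

# Peaks, fired origins, distances, widths

A replication peak is a local maximum of the smoothed profile where the
per-bin derivative changes sign from plus to minus and *keeps its sign* —
strictly positive over the window before the change point, strictly
negative after — for more than 3 kb on each side. Flat stretches do not
keep a sign, so short bumps on a flat background are rejected;
zero-derivative plateaus are allowed only at the top, where the apex is
the plateau-midpoint bin. Chromosome-terminal windows shorter than the
persistence span cannot host a peak. The test suite checks the vectorized
caller against a literal brute-force scan of this definition on hundreds
of randomized piecewise-linear profiles; they must agree exactly.

`callFiredOrigins()` reads the smoothed copy number at each annotated
origin bin, converts it to a fired fraction (`clamp(cn − 1, 0, 1)`; under
a two-state replicated/unreplicated population the copy number is
1 + fired fraction), and flags origins fired in at least 20% of cells.
Whether to read the raw or smoothed profile at the origin was an open
choice; the smoothed value is used, consistent with peak calling, and the
bias analysis above applies. `interoriginDistances()` and `peakWidths()`
(FWHM above the copy-number baseline of 1.0, linear interpolation,
valley-truncation flagged) summarise the geometry.

# Damage mapping

`normalizeChip()` scales IP and control to equal totals and divides with a
pseudocount; `normalizeByReplication()` divides the resulting ratio by the
local amount of replication (smoothed copy number − 1), flooring at 0.05
fraction-of-cells — bins below the floor become missing, never infinite.
Missing propagates; aggregation reports n.

`classifyOriginGeneContext()` finds the nearest gene wholly left and
wholly right of each origin (within 20 kb). Replication proceeds outward
from the origin, so the left gene meets its fork head-on iff transcribed
toward the origin ("+" on the left, "−" on the right). Both head-on =
convergent; any other complete pair is nonconvergent; origins inside gene
bodies or missing a flank are unclassified and excluded from binning.
Orientation has a built-in symmetry (flipping every strand maps convergent
pairs into the divergent subcase and leaves codirectional pairs
nonconvergent) which the tests exercise.

`binnedDamageByTrep()` averages the normalized damage over ±2 kb around
each origin (the window is configurable; a per-origin window mean was
chosen over a peak value as the more noise-tolerant statistic) and
tabulates mean ± SEM per `t_rep` bin and orientation class. On simulations
that inject extra damage only at convergent-context origins, with an
enrichment growing in `t_rep`, the convergent class shows a positive trend
across bins while the nonconvergent trend is statistically
indistinguishable from zero (sign test across seeds).

# Quantitative fitness analysis

`fitGrowthCurve()` fits the logistic solution
$g(t) = K g_0 e^{rt} / (K + g_0(e^{rt} - 1))$ by Levenberg–Marquardt with
multi-start initialisation. Residuals are taken on the **log scale**:
colony-density error is multiplicative, and log-scale least squares is the
maximum-likelihood fit under the lognormal noise model used throughout. A
raw-scale fit lets the saturation plateau dominate and inflates the error
on the fitness statistic roughly tenfold. Degenerate cultures return
`converged = FALSE` (never an exception) and count as dead (F = 0).

Fitness follows the QFA convention, fixed here explicitly because the
defining formulas are conventionally cited rather than restated:
MDP = log2(K/g0) (maximum doubling potential, doublings) and
MDR = (r/ln 2)(1 − g0/K) (maximum doubling rate, doublings/day — the
maximal instantaneous doubling rate of the fitted logistic, attained at
inoculation); F = MDP × MDR, averaged over replicates (four in the
standard design). Any monotone variant of these forms changes absolute F
but not the ranking that drives interaction calling.

The population model regresses mean query fitness on mean control fitness
across all genes with a Huber-weighted robust fit, so genuine interactions
do not drag the "equal growth" line. GIS = mean query fitness − model
prediction; significance is a two-sided one-sample t-test of the
replicate-level query fitness against the prediction, BH-adjusted. The
exact test behind the original screens is not restated in the sources this
package follows; t-test + BH is the documented substitute, and its type-I
behaviour is checked by simulation (null screens yield zero BH discoveries
at q < 0.05 in ~95% of seeds, as expected from Simes-type global-null
behaviour). A hit must be significant **and** fall in the top quartile of
|GIS| over all screened genes (inclusive of ties): the effect-size filter
reads "top 25% of gene deletions that significantly enhance/suppress" as
two conditions, which keeps recall high when only a few dozen genes
interact, while significance alone controls the error rate.
`complexEnrichment()` is a hypergeometric upper tail over a cyc2008-style
catalog restricted to the screened universe; `crossScreenCompare()` pairs
GIS across two screens (Spearman correlation, enhancer/suppressor overlap
and Jaccard).

The growth-curve generator places the controlled noise at the fitness
level (replicate fitness sd 0.05 in the standard screen conditions) and
renders curves with small (0.2%) density noise, so the dispersion the
screen statistics see is the prescribed one rather than an artefact of
curve fitting; baseline control fitness is N(30, 3), giving r ≈ 2/day so
cultures saturate within the 5-day, 4-hourly observation design and K is
identifiable.

# Plasmid loss and catenanes

The loss rate per generation is 100 × (1 − RMP^(1/G)) with RMP the
selective/nonselective colony ratio and G the (known, not estimated)
number of nonselective generations; RMP = 0 returns exactly 100.
`lossRateWithCI()` adds a percentile bootstrap over binomial resampling.
`simulatePlasmidCounts()` inverts the formula to generate counts, and the
round trip is unbiased to well under half a percentage point at 1000
colonies. Catenane distributions are discrete weights over the catenane
number n; the median is the smallest n whose cumulative weight reaches 0.5
(discrete, not interpolated — band counts are integers by nature), checked
against a cumulative-sum oracle on a thousand random distributions.
`compareCatenation()` reports the difference of medians with a multinomial
bootstrap at a stated effective molecule count.

# Numerical choices and problem sizes

* Coordinates are 1-based closed inside the package (the native R and
  GRanges convention); bedGraph's 0-based half-open convention is handled
  at the IO boundary only.
* Missing data propagate as `NA` through every normalization; no step
  clamps or invents values. Aggregations ignore missing and report n.
* Ties: `t_rep` equal to the cutoff is early; plateau apexes take the
  midpoint bin (integer division); hit-calling quantile boundaries are
  inclusive.
* Test and acceptance problem sizes — a 1-Mb genome with 40 origins,
  500-cell populations, depth 30, 400-gene screens with 4 replicates,
  50–100 seed replicates for calibration claims — were chosen as the
  smallest sizes at which the binomial/Poisson error bands are tight
  enough for the stated checks to be meaningful on a single CPU in
  seconds to tens of seconds each.

# Known limitations

* Modal anchoring of copy number is unidentifiable when most of the
  genome replicates; use depth-matched libraries (or external ploidy
  calibration) in that regime.
* The smoothed single-bin fired-fraction readout carries the feature-scale
  filter bias discussed above; treat per-origin fractions at low depth as
  approximate, and the ≥20% flags as the robust output.
* The brick-wall filter rings near sharp discontinuities; with noisy real
  profiles the raw maximum always dominates, but on adversarial noiseless
  square inputs the smoothed profile can locally overshoot.
* The unperturbed-regime firing-time model (exponential around `t_rep`)
  is a convenience, not a calibrated timing program.
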