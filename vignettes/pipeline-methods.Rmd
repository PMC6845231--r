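---
title: "Methods: simulation-verified calcium imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-verified calcium imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcifly)
```

## Scope and rationale

`calcifly` implements the analysis chain used for in vivo two-photon
recordings of *Drosophila* medulla interneurons (Mi1, Tm3, T4/T5) probed with
full-field ON/OFF flashes and moving bright/dark edges, together with the
associated statistics and a ΔΔCt module for qRT-PCR quantification. Because
no raw imaging data are distributed with studies of this kind (results are
summary tables), every stage is validated against a synthetic-movie
generator with exact ground truth: the generator encodes what the analysis
assumes about the data, and the test suite checks that each stage recovers
the generating parameters.

## The response model

A cell's noiseless response to a maintained contrast step of matching
polarity is

$$r(t) \;=\; \underbrace{\bigl(1 - e^{-t/\tau_\mathrm{rise}}\bigr)}_{\text{rise}}
\Bigl[\, A_\mathrm{tr}\, D(t) \;+\; A_\mathrm{pl}\,\bigl(1 - D(t)\bigr) \Bigr],
\qquad
D(t) = e^{-\max(0,\, t - t_\mathrm{hold})/\tau_\mathrm{tr}},$$

a fast rise to a transient peak $A_\mathrm{tr}$ (ΔF/F units) that, after a
short hold $t_\mathrm{hold}$, relaxes with $\tau_\mathrm{tr}$ onto a
sustained plateau $A_\mathrm{pl}$ — the canonical ON-cell shape whose
transient has settled onto the plateau within about 2 s. Defaults are
$\tau_\mathrm{rise} = 0.1$ s, $\tau_\mathrm{tr} = 0.8$ s,
$t_\mathrm{hold} = 0.5$ s; all are per-cell parameters. The hold term is a
deliberate numerical choice: it gives the kernel an exact, flat maximum equal
to $A_\mathrm{tr}$, so that "peak ΔF/F" is well defined on a 10 Hz grid and
parameter recovery does not depend on where grid samples fall on a cusp.
Epochs of non-matching contrast leave the trace at zero (rectification).

A moving edge triggers the same kernel as a transient event (no plateau
term) when the edge crosses the cell's receptive-field center: within an
edge epoch the onset is delayed by
$(\text{projection of the RF center on the motion axis} + \text{span}/2) /
\text{speed}$, and the transient relaxes freely into the following gray
epoch — a passing edge, unlike a maintained flash, leaves only indicator
decay behind. Direction tuning multiplies the edge amplitude by
$\max(0, \cos(\theta - \theta_\mathrm{pref}))$ for cosine-rectified cells.

### The two-receptor block model

Visual drive reaches these cells through a glutamate-gated (GluClα) and a
GABA-gated (Rdl) chloride conductance; bath-applied picrotoxin blocks both,
and point-mutant alleles render one channel block-insensitive. The
generator models this with per-channel block fractions
$b_\mathrm{glu}, b_\mathrm{gaba} \in [0,1]$, forced to 0 by the matching
insensitive flag. Two gain modes exist:

* **scalar** (default): one gain
  $g = w_\mathrm{glu}(1-\hat b_\mathrm{glu}) +
  w_\mathrm{gaba}(1-\hat b_\mathrm{gaba})$ scales the whole response, with
  cell-level receptor weights $w_\mathrm{glu} + w_\mathrm{gaba} = 1$
  (default 0.6/0.4).
* **per-component**: $(1-\hat b_\mathrm{glu})$ scales the transient
  component $A_\mathrm{tr} D(t)$ and $(1-\hat b_\mathrm{gaba})$ the plateau
  component $A_\mathrm{pl}(1-D(t))$. This is the minimal decomposition in
  which a GluClα-insensitive allele restores the full step response and an
  Rdl-insensitive allele the full plateau — the step/plateau dissociation
  the pharmacogenetics is designed to expose. It is a phenomenological toy,
  not a biophysical claim; both components see the same rise kinetics.

Setting both insensitive flags restores $g = 1$ at any block level (full
rescue), a property the tests assert.

## Movie synthesis

`render_movie()` rasterizes each cell as a disc of intensity
$F_\mathrm{base}(1 + r(t))$ on a uniform background, then applies, per
frame: an integer-pixel translation from a random walk whose steps are
rounded $\mathcal N(0, \sigma_\mathrm{walk})$ draws and which *reflects* at
±`max_shift_px` (default 8 px) — brain motion oscillates about a rest
position; an unbounded walk would drift out of any finite search radius and
out of the field of view, which no usable recording does; Poisson photon
noise at `photon_gain` expected counts per fluorescence unit (0 disables
shot noise, giving the deterministic limit used by the recovery oracles);
and additive Gaussian read noise. The first frame is always at rest
(shift 0,0) and identical configuration + seed gives a bit-identical movie.
The matching label mask marks discs at their rest positions; all unlabeled
pixels form the background region.

What the generator does **not** emulate: optics (PSF blur, bleaching,
z-drift), dendritic morphology, neuropil contamination beyond a uniform
background, non-rigid or sub-pixel motion, and correlated noise. Passing
tests therefore certify the *analysis logic* — windows, baselines, filters,
formulas — under the stated noise model, not robustness to every artifact of
real recordings.

## Motion correction

The reference is the pixel-wise maximum projection of the first 30 frames.
When motion is present during that window, projecting raw frames smears the
template and biases every subsequent estimate by the smear's offset;
`register()` therefore first aligns the reference frames to frame 1
(`prealign_reference = TRUE`), keeping the template sharp and anchored.
Each frame's shift is the integer translation within ±10 px (default)
maximizing the normalized cross-correlation of the overlapping regions; the
implementation evaluates the exhaustive search exactly via FFT cross-terms
plus integral-image moments, and ties break toward the smaller shift norm,
then row-major order. Correction applies the negated shift with the frame
median as border fill (neutral for max projections and ROI means).
Sub-pixel and non-rigid registration are out of scope; the integer model
matches the generator and admits an exact recovery oracle (the tests demand
≥ 99% exact agreement with ground truth on noisy movies).

## Traces, resampling, ΔF/F

ROI traces are per-frame means over the ROI's pixels minus the mean over
the background region (region-mean background; the estimator is not further
specified in this kind of protocol and region-mean commutes with the linear
operations downstream). Traces are linearly interpolated onto a 10 Hz grid
whose phase locks to each epoch onset — linear interpolation is
shape-preserving and exact on affine signals, and onset-locking makes every
"500 ms window" contain exactly 5 samples regardless of the native frame
clock (10–15 Hz). Each epoch instance becomes a segment with up to 2 s of
pre-onset context; trial averages pool segments of the same flash kind or
the same direction × contrast.

Two baseline conventions are supported, recorded in the result:

* `whole_trace_mean` (flash convention): $F_0$ is the mean of the full
  native trace, computed before segmentation. The resulting ΔF/F has zero
  mean over the recording by construction. Note the consequence for
  parameter recovery: if the true response is $r(t)$, the measured trace is
  $(r - \bar r)/(1+\bar r)$ — a protocol-dependent compression (about 20%
  for alternating 5 s flashes). Absolute amplitudes under this convention
  are therefore comparable *within* a protocol, not across protocols.
* `gray_last_second` (edge convention): $F_0$ is the mean over the last
  second of the gray epoch preceding each stimulus epoch. When a recording
  starts with a gray baseline this convention recovers response amplitudes
  on their natural scale, which is why the recovery harness in the tests
  uses a flash protocol with a leading gray epoch and this mode when it
  checks `step ≈ amp_transient`.

ROIs whose $F_0$ is not positive are excluded with a warning rather than
producing unbounded or sign-flipped ΔF/F.

## ROI inclusion rules

Three rules, intersection semantics, shipped as named presets
(`mi1_pharma`, `unpaired`, `t4t5`, `iglusnfr`):

1. *stimulus correlation*: Pearson r between the trial-averaged ΔF/F and a
   ±1 contrast square wave must exceed 0. The square wave is the minimal
   formalization of "the stimulus" for a flash protocol; the rule is
   undefined (an error) for edge data.
2. *pre-stimulus noise*: the s.d. of the 2 s window before the onset of
   visual stimulation must not exceed 0.2 ΔF/F. The rule rejects
   high-variance (noisy) ROIs.
3. *response threshold*: peak |ΔF/F| of the trial-averaged response must
   reach 0.5. "Peak" rather than mean, matching the intent of selecting
   well-responding ROIs.

Experiments expecting a full loss of response disable the response
threshold via an explicit policy flag — never automatically, so a policy
fully determines the analysis. In paired pharmacology, inclusion is decided
on the pre-drug recording and the identical ROI ids are carried to the
post-drug recording without re-filtering (`pair_rois()`).

## Metrics and direction selectivity

On the trial-averaged 10 Hz traces: **step** = epoch peak minus the mean of
the 5 pre-onset samples (negative values allowed — suppression is real);
**plateau** = mean of the last 5 epoch samples minus the same baseline;
**integral** = plain sum of the 50 epoch samples of a 5 s epoch, no
baseline subtraction (a seconds-scaled variant, ×0.1, exists but is not the
default); **edge amplitude** = step on gray-referenced edge segments,
computed per ROI *before* any peak alignment. Population edge traces are
displayed after circularly shifting each ROI's trace so its peak lands on
the median peak index.

Direction tuning takes the 8 direction-indexed amplitudes: PD is the
direction of the maximal response (ties toward the smaller angle), ND the
response 180° away, DSI = (PD − ND)/PD, flagged undefined when the PD
response is not positive. For a cosine-rectified cell with an on-grid
preference the idealized amplitudes give DSI = 1 exactly; through the full
pipeline the measured ND is zero only up to the indicator tail of the
preceding epoch (about 10⁻³–10⁻² ΔF/F for centered receptive fields with
2 s gray intervals), so end-to-end checks use a 0.01 band around 1 rather
than exact equality.

Group summaries average ROIs within each fly first, then report mean and
SEM across flies — every fly contributes equally regardless of ROI count
(assertable by duplicating ROIs). Post-drug metrics are normalized to the
*pre-drug group mean* of the same genotype; the per-genotype (rather than
per-fly) denominator is a documented choice where the convention is
ambiguous. The oocyte summary divides the agonist-evoked peak current under
antagonist by the mean post-washout peak.

## Statistics

Two-tailed Student t tests (pooled variance for unpaired data; Welch is
available but non-default, since the classical test is the stated
procedure); one-way ANOVA with all pairwise t tests and Bonferroni–Holm
adjustment; unbalanced two-way ANOVA with Type II sums of squares (the
standard choice when the interaction is not the focus; the interaction is
included whenever all cells are nonempty and dropped with a warning
otherwise) followed by Tukey–Kramer comparisons of the cell means using the
studentized-range distribution with per-pair harmonic cell sizes; and the
Lilliefors normality test with a seeded Monte Carlo null (default 10,000
replicates) instead of table lookup — exact at any n and reproducible.
Omnibus fits, Holm adjustment and Type II SS are delegated to `stats::aov`,
`stats::p.adjust` and `car::Anova`; the Lilliefors statistic and the
Tukey–Kramer assembly are implemented here and cross-checked in the tests
against `nortest::lillie.test` and `stats::TukeyHSD` respectively.
Significance annotations follow `*` p<0.05, `**` p<0.01, `***` p<0.001.

## ΔΔCt quantification

Technical replicates are averaged per (condition, biological replicate,
gene); the percent transcript difference is
$100 \cdot 2^{(\Delta Ct_\mathrm{ND} - \Delta Ct_\mathrm{D})}$ with
$\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$, computed per
biological replicate of the disrupted condition against the control's mean
ΔCt and summarized as mean ± SEM over biological replicates. An
efficiency-corrected (Pfaffl-style) mode uses per-gene efficiencies
$E^{\Delta Ct}$ and collapses to the base-2 formula at $E = 2$; the shipped
defaults are the measured efficiencies 1.91 (GluClα) and 1.96 (GAPDH2).
For presentation, values are normalized to the wild-type mean. A
standard-curve helper estimates $E = 10^{-1/\mathrm{slope}}$ from dilution
series. Amplification-curve processing (threshold calling) is instrument
software and out of scope.

## Problem sizes and numerical choices

The simulation studies in the tests and analysis scripts use sizes chosen
to give stable statistics while staying light: registration on a 600-frame
64×64 movie with 8 cells (photon gain 100, walk sd 1 px, reflection at
8 px, search radius 10 px); pharmacology on 8 flies × 30 ROIs × 4
conditions with ΔF/F noise sd 0.05 per native sample (a realistic scale
for averaged two-photon data) and 7 flash trials; direction tuning on 50
isotropic + tuned cells over 3 edge repetitions; 10,000 Monte Carlo
replicates for Lilliefors calibration and 2,000 null simulations for the
ANOVA→Holm chain. Degenerate inputs are defined, not silent: zero-variance
frames register at (0,0) with a warning, zero-variance traces fail the
correlation rule, empty backgrounds skip subtraction with a warning,
nonpositive $F_0$ excludes the ROI, identical paired samples make the t
test error, and a nonpositive PD response flags the DSI undefined.

## Known limitations

Integer-pixel rigid registration only; one background region per recording;
the drug model is linear in the two conductances with no dynamics; the
edge-response delay model assumes a punctate receptive field; trial counts
and epoch orderings are taken from the protocol object, so recordings must
be synchronized to a known protocol. The whole-trace-mean ΔF/F convention
compresses amplitudes protocol-dependently, as derived above — comparisons
across baseline conventions should use the gray-referenced mode.
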