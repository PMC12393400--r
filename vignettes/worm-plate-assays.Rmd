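---
title: "Models and methods behind wormassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormassays)
library(dplyr)
```

`wormassays` quantifies the plate assays used to characterize
*C. elegans* neurotransmission mutants: salt chemotaxis, swimming
(thrashing), roaming, lawn aversion, and intersectional reporter mapping
of co-transmitting neurons, plus the normality-gated statistics used to
compare genotypes. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices made where the methods
left room.

## The salt-gradient model

A chemotaxis plate carries a NaCl gradient built by pipetting drops of
5 M NaCl onto one marked point of the agar and letting them diffuse. The
model treats each drop as an instantaneous point source spreading
laterally through an agar sheet of uniform depth $d$. The concentration
(mM) at distance $r$ cm from the peak, $t_i$ seconds after drop $i$ of
$N_i$ moles, is

$$c(t_i, r) = \frac{10^6\,N_i}{4 \pi d D t_i}\, e^{-r^2/(4 D t_i)},$$

and the plate-level prediction superposes the drops on the 50 mM NGM
baseline:

$$C(r) = C_o + \sum_{i=1}^{n} c(t_i, r).$$

The $10^6$ factor converts mol/cm$^3$ to mM; all lengths are cm
internally and mm at the I/O boundary. $D = 1.590 \times 10^{-5}$
cm$^2$/s is the diffusion coefficient of NaCl in aqueous medium.

Assumptions worth knowing:

* **Unbounded plane.** The kernel ignores the plate wall, so a little
  mass diffuses "off plate". At the standard drop ages the missing mass
  is negligible near the peak; the model is not corrected at the wall.
* **Instantaneous sources, no evaporation.** Drop soak-in time and agar
  drying are not modeled.
* **Agar depth.** $d$ is the one geometric unknown of a poured plate; we
  default to 0.35 cm, a typical pour for a 50 mm plate, and expose it in
  `plate_model()`.
* **Drop timing.** The first drop is applied within a 20–24 h window
  before the assay; `standard_salt_schedule()` uses the midpoint, 22 h,
  with the later drops at 5 h and 2 h. Elapsed times are measured to
  assay start, and the gradient is evaluated at assay start (the model's
  own time parameter lets you evaluate at any other instant).

With these defaults the model predicts about 85 mM at the peak and
about 57 mM at the plate center, 12.5 mm away:

```{r gradient}
plate <- plate_model()
sched <- standard_salt_schedule()
predict_concentration(sched, plate, r_cm = c(0, 1.25))
```

`predict_field()` evaluates the same model on a Cartesian grid (origin
at the plate center, peak at `(12.5, 0)` mm) for plotting and for the
track simulator; `r` in the kernel is always distance from the *peak*,
not from the plate center. Measured gradients are mapped to mM with
`calibrate_conductivity()`, an affine two-point calibration through the
50 mM and 100 mM reference plates; it is exact at the references and
extrapolates linearly.

Mass conservation is a good model check: integrating
$c(t_i, r)\,2\pi r$ over the plane and multiplying by $d/10^6$ must
recover $N_i$ exactly; the test suite holds this to a relative error of
$10^{-6}$ by adaptive quadrature.

## Simulated chemotaxis tracks

Real assays film 8 worms per plate at 3.75 fps for 7 minutes after
placing them at the plate center. The simulator
(`simulate_chemotaxis_tracks()`) emulates the tracker's export so that
the whole analysis pipeline can be exercised end to end with a known
ground truth:

* constant-speed run-and-tumble motion: heading diffuses with Gaussian
  noise (`heading_noise`, rad/$\sqrt{s}$) and reorients uniformly at
  random ("pirouettes") at baseline rate `pirouette_rate`;
* klinokinesis: the per-step pirouette probability is scaled by
  $\max(0,\, 1 - \beta\, \widehat{dC/dt})$, where $\widehat{dC/dt}$ is
  the concentration derivative the worm experiences, exponentially
  smoothed with time constant `sensory_timescale_s`. Worms climbing the
  gradient pirouette less, which is the classical mechanism for salt
  chemotaxis. `beta = 0` gives an unbiased walk;
* reflection at the plate wall, so positions never leave the plate;
* detection gaps: each detected frame starts a gap with probability
  `gap_prob`; gap lengths are geometric with mean `mean_gap_frames`.
  Gaps keep the track id (re-detection resumes it), matching how
  per-worm tracks are interrupted and resumed; the
  `split_on_redetect = TRUE` dialect instead opens a new id per
  detection bout, for robustness testing. A gap that reaches the last
  frame is exactly a worm leaving the camera field and never returning.

Defaults (`worm_params()`): speed 0.15 mm/s, heading noise
0.7 rad/$\sqrt{s}$, pirouette rate 0.25 /s, sensory timescale 1 s —
adult-crawl scale values from the *C. elegans* locomotion literature.
Frame count is `round(duration * frame_rate)` with frames indexed from 0
at assay start. Everything is deterministic given `seed`.

Two cautions about what the simulator does *not* emulate: worm-worm
collisions and track identity swaps (the analyzer trusts track ids),
and posture — worms are points. Passing tests on simulated tracks
validates the *analysis arithmetic*, not the tracker.

A note on checking that `beta = 0` is unbiased: the mean *change in
distance to the peak* is a biased measure for a pure random walk
(diffusion increases the expected distance to any fixed point), so the
suite instead tests the mean displacement *projected onto the peak
direction*, which is exactly zero in expectation for an unbiased walk.

## The chemotaxis outcome statistic

The outcome for each worm is its mean Euclidean distance (mm) from the
salt peak, averaged over every frame of the assay's final minute. Two
rules matter:

* **Carry-forward imputation.** When a track is interrupted, the last
  available position is repeated until re-detection
  (`impute_carry_forward()`). Frames before the first detection are
  excluded, never back-filled; a worm last seen before the window still
  contributes through the terminal carry-forward of its last position.
* **Window mapping.** Assay $t = 0$ is the first recorded frame; the
  final minute is the closed interval $[T - 60, T]$ mapped to frame
  indices, i.e. 225 frames at 3.75 fps and $T = 420$ s.

`plate_summary()` weights worms equally (one mean per worm, then the
plate mean), and reports how many tracks were excluded for having no
usable frame at all. Distances are plate-plane Euclidean distances; no
correction for the agar surface curvature is applied.

```{r outcome}
field <- predict_field(sched, plate, grid_spacing_mm = 1)
tracks <- simulate_chemotaxis_tracks(field, n_worms = 8,
                                     worms = worm_params(beta = 2),
                                     seed = 1)
plate_summary(tracks)$plate
```

## Thrashing, roaming, aversion

**Thrashing** (`count_thrashes()`): a thrash is one reversal of the
midbody bend direction. The counter registers a reversal each time the
angle, having moved at least `hysteresis_rad` (default 10°) from the
running extremum, turns back. On a clean sinusoid this reproduces human
extremum counting exactly (two thrashes per cycle: a 1 Hz swimmer scores
120/min); on noisy signals the hysteresis gate suppresses micro-reversals
that an observer would never score. Counts are normalized to the
1-minute scoring window.

**Roaming** (`roaming_squares()`): the assay scores the number of
3 × 3 mm grid squares a worm's 16-hour excursion traverses. Since only
the trail is observed, "squares traversed" is read as *distinct squares
visited* (set semantics); consecutive track points are joined by
straight segments and every cell a segment passes through is credited
(an exact grid-traversal walk, not point sampling), so coarse temporal
sampling cannot skip cells. A boundary-crossing count is available via
`count = "crossings"`. The grid is anchored at the plate center by
default; `origin_mm` re-anchors an arbitrary overlay.

**Aversion** (`aversion_ratio()`): the per-frame ratio of worms outside
the bacterial lawn to all worms on the plate, over a 20 h recording at
1 frame/min. The scalar plate summary is the time-average of the
per-frame ratio (`aversion_summary()`), with the terminal-frame ratio as
an option — the reduction from 1,200 frames to one number is not pinned
down by the assay description, and the time-average is the stabler
choice.

## Mapping co-transmitting neurons

Intersectional labeling puts a recombinase (or one half of split-GFP)
under the promoter of one transmitter locus and a conditional reporter
at a second locus: fluorescence appears only in cells expressing *both*.
`labeled_neurons()` models this as a plain AND gate over each neuron's
expressed-locus set — split-GFP and FLP-on cassettes get the same
semantics, and the gate is symmetric in its two loci (it models
expression overlap, not which construct glows).

`tally_cotransmission()` counts a neuron as co-transmitting when at
least one cross labels it (union, no double counting) and reports
counts and integer percentages per anatomical category (sensory,
interneuron, motor), per region (head, tail, midbody, pharynx), and
overall. Tallies operate on individual neurons, not classes. Empty
strata report `NA`, never a division by zero.

The bundled table (`fig6_coexpression()`, also shipped as
`inst/extdata/fig6_coexpression.tsv`) transcribes only the printed
reporter identifications — e.g. the five cholinergic/glutamatergic
neurons AFDL, AFDR, M5, DVA, PVN and the GABA/glutamate pharyngeal
neuron I2L. It is a worked example, not an atlas: genome-wide tallies
require a user-supplied table covering all 302 neurons, and the bundled
fixture's totals are not nervous-system totals. Where the printed
identification names a class without laterality (SMD, PDE, ADF, HSN)
the fixture keeps one record under that name.

Expression in this framework is evidence of co-transmission *capacity*,
not proof of co-release — a neuron can express a vesicular transporter
without synthesizing the matching transmitter.

## Group statistics

`compare_groups()` implements the routing scheme used across all the
assays:

1. **Gate:** Shapiro–Wilk on every group at $\alpha = 0.05$
   (`normality_gate()`). Routing is parametric only if *all* groups
   pass — the conservative aggregation, since the family is shared by
   the whole comparison. Groups need $n \ge 3$; zero-variance groups are
   rejected with an explicit error.
2. **Two groups:** Student's *t* (parametric) or Mann–Whitney
   (nonparametric). The Mann–Whitney p is computed by full enumeration
   of all $\binom{n_1+n_2}{n_1}$ assignments whenever
   $n_1 + n_2 \le 12$ — exact even under ties, which are handled by
   mid-ranks — and by the tie-corrected normal approximation with
   continuity correction otherwise.
3. **Three or more:** one-way ANOVA with Dunnett's test against the
   designated control (parametric), or Kruskal–Wallis with Dunn's
   mean-rank *z* tests against the control (nonparametric). Dunn p
   values are Holm-adjusted across comparisons; Prism's default
   adjustment differs in general and no equivalence is claimed.
   `route = "unequal_variance"` selects Welch's heteroscedastic ANOVA
   with pairwise Welch *t* tests vs control (Holm) — an approximation
   to the Brown–Forsythe/Dunnett-T3 combination some comparisons use.

All tests are two-sided. `significance_stars()` applies the
figure-legend convention (`****` < 0.0001 … `NS`). Fitted comparisons
support `tidy()` (post-hoc table), `glance()` (omnibus row) and
`autoplot()` (jittered points with mean ± SD, the panel style of the
assay figures).

```{r stats}
set.seed(1)
d <- tibble::tibble(
  genotype = rep(c("wt", "mutA", "mutB"), each = 12),
  thrashes = c(rnorm(12, 95, 10), rnorm(12, 90, 10), rnorm(12, 40, 15))
)
fit <- compare_groups(d, thrashes, genotype, control = "wt")
glance(fit)
tidy(fit)
```

The suite calibrates the routed pipeline's type-I error on Gaussian
nulls (3 groups of 10, 5,000 simulations) and requires the rejection
rate to sit within 0.05 ± 0.01.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use 200 worms per condition
for the chemotaxis gain sweep, 5,000 replicates for the type-I
calibration, and exhaustive enumeration up to $n_1 + n_2 = 12$ for the
Mann–Whitney oracle — sizes at which the Monte-Carlo noise is well below
the effects being asserted while a full run stays comfortably
interactive. Quadrature tolerances are $10^{-10}$ relative (asserted at
$10^{-6}$); the field interpolator used by the simulator is bilinear on
a 1 mm grid, well below the millimetre scale of the gradient's
curvature. All simulators take integer seeds and are bit-reproducible
across runs.

## Known limitations

* The diffusion kernel ignores the plate wall and evaporation; predicted
  absolute concentrations inherit the uncertainty in agar depth.
* The track simulator validates analysis code, not trackers; identity
  swaps and collisions are out of scope.
* The roaming count interprets "squares traversed" as distinct squares;
  if a protocol scores repeated entries, use `count = "crossings"`.
* Dunn post-hoc adjustment is Holm; results can differ in the last digit
  from software using other multiplicity schemes.
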