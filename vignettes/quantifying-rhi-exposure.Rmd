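---
title: "Quantifying repetitive head impact exposure with bsetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repetitive head impact exposure with bsetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsetr)
```

## The measurement problem

Repetitive head impact (RHI) exposure in American-style football (ASF) is
poorly captured by any single metric. Helmet sensors count hits but measure
head kinematics unreliably, and peak accelerations are a less stable proxy
for tissue loading than the brain's mechanical response itself. The
measurement approach implemented here characterizes exposure by three
jointly observed properties of every documented impact:

* **frequency** — how many confirmed head impacts a player position
  sustains per game;
* **magnitude** — the brain-tissue maximum principal strain (MPS, %)
  associated with the impact condition, obtained from physical
  reconstructions of exemplar impacts combined with finite-element
  modelling, and consumed here purely as lookup tables;
* **interval** — the real time between successive impacts, reconstructed
  from the game clock with stop-time correction.

These are combined into a single cumulative index, BSE/T (brain strain
exposure per time), computed per position-game:

$$
\mathrm{BSE/T} \;=\; \frac{\sum_{m=1}^{5} f_m \, s_m \, w_m}{\sum_m f_m},
$$

where $f_m$ is the impact frequency in MPS magnitude category $m$,
$s_m \in \{1,\dots,5\}$ is the category's severity weight, and
$w \in \{4,3,2,1\}$ is the interval weight of the time interval in which
those impacts were experienced (shorter intervals weigh more). The index is
bounded in $[1, 20]$ for any non-empty game and is undefined — deliberately
not zero — for a game with no scorable impacts, since 0 lies outside the
attainable range and would corrupt averages.

## Category schemes

All category schemes are half-open on the left of each upper bound, which
turns the integer-labelled published bands (e.g. "8–16.9%") into true
partitions of the continuous scales:

| scale | bands | weights |
|---|---|---|
| MPS magnitude (%) | [0,8), [8,17), [17,26), [26,35), [35,100] | severity 1–5 |
| interval (min) | [0,15), [15,31), [31,91), [91,∞) | interval 4–1 |
| collision velocity (m/s) | [0,2), [2,4.5), [4.5,7), [7,9.5), [9.5,∞) | — |
| fall velocity (m/s) | [0,2), [2,4), [4,6), [6,8), [8,∞) | — |

Closing each level on the left at its nominal lower bound is the convention
consistent with the one printed worked value in the source material for the
reconstruction velocities (the "low collision" midrange 3.25 m/s is the
midpoint of the interval (2.0, 4.5)), and it is applied uniformly to all
four schemes. The clinically motivated annotations of the magnitude bands
(e.g. moderate ≈ 50% concussion risk) are carried as metadata strings on
`magnitude_categories()` and never used in computation.

## The BSE/T weighting ambiguity

The verbal definition of the index — frequency per magnitude category times
severity, "then multiplied by the time interval in which those impacts were
experienced" — is ambiguous between two readings, and both are implemented:

* **per-impact** (default): every impact contributes
  $s(\text{its magnitude}) \times w(\text{its own interval category})$;
  the contributions are summed and divided by total frequency. This uses
  all information in the data and degrades gracefully when a category's
  impacts straddle interval bands.
* **category-mean**: per magnitude category,
  $f_m \times s_m \times w(\text{category of the mean interval of that
  category's impacts})$; five terms summed and divided by total frequency.
  This is the literal five-term reading.

The two modes agree exactly whenever all impacts of a magnitude category
share one interval category (which is the common case in short games), and
outputs always label the mode used (`bset_mode`).

## Intervals from the game clock

Stamps are countdown clock readings (quarter, MM:SS remaining). The
conversion to real minutes is:

1. clock time elapsed between consecutive analysis-set impacts (countdown
   arithmetic across quarters);
2. multiplication by the game's **stop factor** — total broadcast duration
   over total game-clock time (≥ 1), computed per game from
   `game_meta()`;
3. addition of fixed real-time paddings for every period boundary the pair
   straddles: 2 min at the Q1/Q2 and Q3/Q4 breaks, 12 min at halftime,
   5 min before overtime. The paddings are wall-clock quantities and are
   therefore added *after* the stop-factor multiplication.

The first impact of a game is assigned the interval from kickoff (Q1, full
clock) under the same rules. The source material is silent on this point,
so an alternative mode (`first_impact = "exclude"`) drops the first impact
from interval-weighted scoring; the kickoff rule is the default because it
keeps single-impact games scorable. "Time of play" is taken as the
game-clock reading (`clock_duration_min`), not ball-in-play time. Ties in
clock time keep file order (stable sort), making intervals deterministic.

## Exemplar strain lookup

Impacts are assigned MPS through an exemplar table: a representative
impact per condition (event type × velocity level × head location, per
position) was physically reconstructed and simulated once, and its strain
is assigned to every impact in that condition. The bundled default table
carries the published per-position × per-event means plus per-position
event-collapsed means. Because the full 249-condition table was never
printed, lookups fall back from specific to collapsed keys:

```
exact (position, event, velocity level, head location)
  → (position, event)
  → (position, collapsed over events)
  → (event, collapsed over positions)
  → error
```

The position-collapsed step sits ahead of the cross-position step because
the source prints exactly that column; trying it first keeps the fallback
within the position before borrowing across positions.
Every assignment records which step matched (`mps_provenance`), so
fallback use is auditable.

Two bundled cells deserve note: the WR-helmet mean is typeset with a
garbled confidence bound in the source and is bundled as 22.5; the
DB-helmet mean is printed on the wrong scale ("0.242") and is *not*
bundled — DB helmet lookups fall back to the DB collapsed mean (21.1) and
say so in their provenance. Both cells can be overridden with a custom
`exemplar_table()`.

The viscoelastic utility `shear_modulus()` implements the shear-relaxation
law $G(t) = G_\infty + (G_0 - G_\infty)e^{-\beta t}$ with the bundled
constants of the four viscoelastic brain components
(`brain_materials()`); no finite-element computation is attempted or
needed anywhere in the package.

## Velocity estimation

Collision velocities come from a planar projective homography (direct
linear transform, total least squares for > 4 correspondences) mapping
image pixels to field meters via field lines of known spacing, then
distance over elapsed time across the 3–5 pre-impact frames. A full 3-D
camera model is deliberately not used: the calibration object is the flat
field, for which a homography is exact.

Fall velocities are a two-step resultant: the horizontal part subtracts a
static scene marker's apparent motion (camera panning) from the head's
apparent motion per frame and averages the relative velocity vectors; the
vertical part finite-differences the measured head-to-ground distances.
Whether the original workflow finite-differenced or used a ballistic model
is not documented; finite differencing is the default because the distances
are measured across frames, and a free-fall mode (`mode = "ballistic"`) is
provided as an explicit alternative, asserted as neither's provenance.

Head locations collapse eight 45° azimuthal sectors into five named
locations plus crown. The mirror identity (an impact at azimuth $a$ and at
$360° - a$ land in the same location) is made exact by folding the azimuth
to $[0°, 180°]$ before sectoring, with fold-scale sector edges belonging
to the sector above — this also realizes the documented convention that
22.5° belongs to the front boss.

## The synthetic generator

`generate_game()`/`generate_season()` emulate the *statistical structure*
of the observed positional exposure, not any real game:

* per-game confirmed counts are negative-binomial with the published
  per-position means and SDs (e.g. DL 22.1 ± 8.5), degrading to Poisson
  when underdispersed;
* magnitude mixes are the published per-game frequencies by magnitude
  level, normalized — the closest printed approximation to the true mixes,
  which were only ever shown graphically. They are approximations and are
  not acceptance-tested against the source;
* MPS values are uniform within the assigned category band, floored and
  capped at the observed exemplar range 4.6–50.6%;
* event kinds follow the collapsed documented mix (helmet 49%, shoulder
  23%, ground 13%, hip/thigh 2%, other 13%); arrivals are homogeneous over
  game-clock time (uniform quarter and clock draws);
* suspected impacts and pile-ups appear at the per-position documented
  rates and are excluded from scoring, as in real logs;
* stop factors are drawn N(3.1, 0.15) truncated at 1 — about a 3.1-hour
  broadcast for 60 clock minutes, a typical professional game; the source
  gives no per-game durations.

The default mode draws magnitudes directly, bypassing velocity and
location, because the magnitude mixes are the generator's natural
parameterization; a `"reconstruction"` mode instead draws velocity levels
and locations and routes through the exemplar table, exercising the full
pipeline. Child seeds are drawn deterministically from the master seed, so
seasons are byte-reproducible.

What passing tests on synthetic data do *not* show: the generator has no
play structure, no within-game clustering of impacts (arrivals are
uniform), independent draws of magnitude and interval, and no
opponent or score effects. Recovery of generator parameters by the
pipeline validates the pipeline's arithmetic, not the realism of any
particular game.

## Statistics

Positional comparisons use the tie-corrected Kruskal–Wallis H test
(delegated to `stats::kruskal.test`, with group mean ranks reported),
Dunn's post hoc z tests with the tie-corrected standard error and
Bonferroni adjustment over all $k(k-1)/2$ pairs, and Pearson contingency
analysis with per-cell adjusted standardized residuals
$z = (O-E)/\sqrt{E(1-r/N)(1-c/N)}$ and a Bonferroni family over all
$r \times c$ cells (the most conservative reading; the original family
was not documented). Tie correction is always applied because per-game
impact counts are small, heavily tied integers. The all-tied degenerate
case is reported as $H = 0$, $p = 1$ rather than NaN. Dunn's test is
implemented in-package and is cross-checked in the test suite against an
exhaustive permutation oracle on three groups of three.

## Numerical and reporting conventions

* Presentation rounding follows the published tables: per-game means to
  1 decimal, average-career projections to the nearest integer,
  record-games projections to 1 decimal, with halves rounded away from
  zero (`round_half_up()`); all computation uses unrounded values, and
  per-season estimates are the *unrounded* per-game mean × 16.
* p-values display as "<0.001" below that floor but are stored at full
  precision.
* Homography fitting rejects (near-)collinear correspondences by singular
  value ratio; reprojection residuals are always reported.
* The exemplar reconstruction velocity for a condition with ≥ 4 impacts is
  the midrange of the level's nominal bounds; the open-ended top level has
  no midrange, so the mean of observed speeds is used there, with a
  warning.

## Problem sizes used in the checks

The bundled verification runs use a 10,000-game single-position synthetic
season for mean recovery (Monte-Carlo SE ≈ 0.085 impacts/game) and a
300-game eight-position season for recovering the positional frequency
ordering; both finish in about a minute on one core and were chosen to
make Monte-Carlo error small relative to the parameter gaps being
recovered.

## Known limitations

* No absolute BSE/T anchor exists in the source material (only mean ranks
  were published), so the index is verified through hand-traced worked
  examples and its attainable bounds [1, 20].
* The bundled exemplar table is coarse (position × event type); users
  with their own reconstruction data should supply a full-resolution
  `exemplar_table()`.
* The headline omnibus statistics of the original 32-game study depend on
  unpublished raw logs and are reproduced here only in shape (df, test
  machinery), not in value.
* The package scores exposure; it makes no claim of predicting concussion
  or long-term neurological outcome from BSE/T.
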