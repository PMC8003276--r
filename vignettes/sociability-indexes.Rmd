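---
title: "Measuring and predicting sociability from indoor localization traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and predicting sociability from indoor localization traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxisoc)
```

## The setting and the data model

proxisoc analyzes coarse-grained indoor localization traces of residents of
assisted-care facilities — typically people living with Alzheimer's disease
in village-style care homes, where promoting social contact is part of the
therapy. A proximity-based localization system reports, every 10 seconds,
the *place* (a cluster of antennas: a private room, an apartment common
area, a public place such as the cafeteria or gym) where each resident is.
One day is therefore a discrete grid of $|T| = 8640$ slots of 10 s, and a
resident's day trace is a sequence of place identifiers with gaps where the
wearable could not be read (residents are prone to losing or rejecting the
bracelet). Gaps are kept as missing and never imputed: an unknown position
is never counted as co-location, and the denominator of every daily index
stays the full 8640-slot grid.

A resident is *active* on a day when their position can be tracked
throughout the day; operationally we require a fraction
`coverage_threshold` (default 0.8) of non-missing slots. The default
tolerates a lost bracelet of up to ~4.8 h; it is configurable because
facilities differ in how aggressively they re-tag residents.

## The Relational Index family

The raw pairwise Relational Index of residents $i, j$ on day $d$ is the
fraction of slots they spend in the same place,
$\widetilde{RI}^d_{i,j} = \sum_t V^d_{i,j}(t) / |T|$, where $V$ is the
binary co-location vector. Raw co-location overstates sociability for
residents who *wander* — walk aimlessly through the facility, brushing past
others for seconds at a time. Two successive filters remove such fortuitous
contact:

1. a **centred moving median** of window $k = 5$ slots (50 s), which erases
   interactions shorter than 20 s while also closing sub-20 s gaps inside a
   genuine interaction. The first $\lfloor k/2 \rfloor$ values cannot centre
   a window and are copied unchanged; we mirror that rule at the trailing
   boundary for symmetry. Larger windows are counter-productive: they
   aggregate distinct contacts into spurious long interactions, which is
   why a small window plus a separate duration pass is used;
2. a **minimum-duration filter** that zeroes every remaining run of ones
   shorter than 60 s. "Shorter than" is strict: a run of exactly six slots
   (60 s) survives. The pass is a run-length scan, independent of the
   median.

The filtered pairwise index $RI^d_{i,j}$ is the mean of the filtered
vector. The **Individual RI** is the mean of *squared* pairwise values over
the other active residents. The square is deliberate: six hours spent with
one companion and twelve half-hour encounters both sum to a pairwise total
of 0.25, but the mean of squares values the first twelve times higher —
strong bonds matter more than passing through crowded rooms. The
**Community RI** is the plain mean of Individual RIs over the active set.

For the three day slots used throughout (morning 8–12, noon 12–15,
afternoon 15–20), the **time-specific** pairwise index restricts the *raw*
co-location vector to the slot window (the defining formula is written on
$V$, not on the filtered vector; a switch `use_filtered_for_slots` applies
the filters first, default off). The **Time-Specific Adjusted RI** then
shifts the slot value towards 1 or 0 according to whether the relationship
helped or hurt resident $i$'s overall day:
$\Delta = RI^d_{i,j,\hat T} - RI^d_i$, $\gamma = 1 - RI^d_{i,j,\hat T}$
when $\Delta \ge 0$ and $\gamma = RI^d_{i,j,\hat T}$ otherwise, giving
$\widehat{RI} = RI^d_{i,j,\hat T} + \gamma\Delta \in [0,1]$. Note that
$\Delta$ compares a slot-level pairwise index with a daily mean-of-squares
individual index; the two live on different scales, but the definition is
applied exactly as stated because its two worked examples (0.3 vs 0.2
rewarding to 0.37; 0.05 vs 0.2 penalizing to 0.0425) pin the formula down
unambiguously. The individual and community aggregates of the adjusted
index are plain means (not means of squares), the individual one dividing
by $|A_d| - 1$.

```{r adjusted}
adjusted_pair_ri(0.3, 0.2)
adjusted_pair_ri(0.05, 0.2)
```

## The Popularity Index and its smoothing

Hourly attendance $n^d_p(h)$ counts *distinct* active residents seen in
place $p$ for at least one slot during hour $h$. The hourly granularity is
the anti-crossing device: walking across the piazza once still counts as
one attendance that hour, but cannot be inflated by ten-second re-entries.
The Popularity Index of a place averages attendance over the 18 awake
hours $D = \{6, \dots, 23\}$ and normalizes by the active-set size:
$PI^d_p = \sum_{h \in D} n^d_p(h) / (|A_d| \cdot |D|) \in [0,1]$ — the
expected fraction of the community found in the place during an awake hour.

Daily PI series are noisy; to read trends we treat them as discretized
samples of a smooth popularity curve and fit a penalized cubic B-spline
(`mgcv`, `bs = "ps"`) with a **first-order difference penalty**, so a large
penalty $\lambda$ shrinks the fit towards a constant and strong noise
peaks are flattened without chasing them. $\lambda$ is chosen by
generalized cross-validation when not supplied — no fixed basis dimension
has to be picked (one basis function per observed day, capped at 120 for
long series). Penalization discourages but cannot guarantee
nonnegativity, so tiny negative fitted values are clipped to zero. (Cubic
B-splines are $C^2$, not $C^3$; the package uses cubic splines
regardless, which is what the smoothing needs.) Records with
$PI < 0.01$ are discarded before model fitting — such values indicate no
ongoing event in the place; the comparison is strict, so exactly 0.01 is
kept.

## Feature encodings and the two predictors

Both predictors consume encodings chosen to let a small network
interpolate:

* **hour**: linear map of the awake window, $(t - 21600)/64800$, so
  6 A.M. $\to$ 0, 5 P.M. $\to 0.6\overline{1}$, midnight $\to$ 1. The
  encoding is deliberately not circular: 1 A.M. is socially nothing like
  11 P.M.;
* **season**: a triangular fuzzy 4-vector (spring, summer, autumn, winter)
  anchored at the equinoxes/solstices, linear in between; components sum
  to 1 with at most two nonzero, and the encoding is continuous across New
  Year, unlike a day-of-year scalar;
* **temperature**: $[0, 40]\,^\circ$C mapped linearly onto $[0,1]$, values
  outside clipped with a warning;
* **weather** and **place**: one-hot;
* **walk predisposition**: facilities derive this from movement metrics;
  here it is defined as the standardized mean walked-distance proxy per
  day slot supplied with the covariates (the synthetic generator produces
  it; z-scored over the generated period).

The **community sociability model** regresses the Community Time-Specific
Adjusted RI of a day slot on workday flag, season, temperature, walk
predisposition and the slot indicator: a feed-forward network with four
hidden layers of 128 ReLU units, MSE loss, Adam, a 70/30 train/test
split. Two representation choices were open. The season input could be 3
neurons (a categorical with a reference level) or the fuzzy 4-vector; the
default is the fuzzy vector, consistent with the popularity model, with
`season_style = "onehot3"` as the literal alternative. The slot indicator
is a 3-level categorical and is encoded one-hot rather than as a single
scalar neuron.

The **place-popularity model** first maps the place one-hot block onto a
3-dimensional latent space (a linear embedding learned jointly), then
concatenates the 9 remaining encoded values — 12 inputs to the hidden
stack. Its output neuron uses a Leaky ReLU during training (no dead
gradient) and a ReLU at inference (popularity is nonnegative). The hidden
stack is selected by grid search over first-layer width {16, 64, 256},
per-layer scaling factor {0.5, 1}, and depth 1–5. The naive grid has
$3 \times 2 \times 5 = 30$ cells, but the scaling factor is inert at depth
1; deduplicating leaves exactly **27 distinct configurations**, which is
the count the grid is usually quoted at. Ties in test MSE break in
enumeration order. The default stack 64–32–16 is the selected
configuration of that grid.

Training uses minibatch Adam (batch 32, learning rate $10^{-3}$ by
default), early stopping on a 10% validation slice of the training split
with patience 20 epochs, restoring the best weights. A single seed governs
the split, initialization, and shuffling; training is reproducible to
floating-point determinism on one thread. The networks are implemented in
the package directly with dense matrix algebra — at these sizes (tens of
thousands of parameters, $10^3$–$10^5$ records) nothing more is needed.

## The synthetic village

No localization data of real residents can be shipped, so the package
includes an agent-based generator whose defaults mirror the facility the
methods were developed for: 64 residents, apartments of 8 private rooms
with a shared common area, 8 public places. A day is a fixed routine —
night (0–6) in the private room, shared apartment lunch (12–13) and dinner
(18–19), two scheduled one-hour public activities (10–11, 16–17) rotating
through the public places, and free half-hour blocks in which a resident
dwells in the apartment common area with a covariate-modulated
probability. About 10% of residents wander: during free and activity
windows they hop between public places every 10–30 s, generating exactly
the brief fortuitous co-locations the continuity filter targets. Disjoint
cross-apartment friendship clusters share the activity-attendance draw, so
friends arrive together. A per-day sociability multiplier links attendance
to the covariates (warmer, sunnier, non-working days are more social), and
a bracelet-loss process blanks a contiguous 1–6 h stretch for a resident
with probability 0.03 per day.

Because every decision is a Bernoulli draw with known probability, common
dwells always start at the block start, and the wanderers' per-slot place
distribution is uniform over their roaming set, the expected raw
co-location fraction of every pair has a closed form, which the generator
serializes as ground truth with each run (exact when bracelet loss is
disabled, which is how the convergence test runs; with loss enabled the
expectations are conditional on full coverage). The ground-truth Community
RI is the plug-in value computed from the expected pairwise fractions — a
deliberate approximation, since the mean of squares of noisy values
exceeds the square of their means.

Two properties were designed in rather than hoped for. All randomness of a
day is drawn in fixed-size blocks before any behaviour is realized, so a
sweep of the global `sociability` multiplier (or of the contact-duration
knob `common_dwell_slots`) under a fixed seed changes decisions
monotonically — co-location vectors only gain ones — and the Community RI
responds monotonically. And each day derives its own seed from the
configuration seed, so any day can be regenerated in isolation,
byte-identically.

The **lockdown scenario** closes all public places from `lockdown_start`:
activities are cancelled (those windows become room time), common-area
visits shrink to short solitary stretches, and wanderers pace the
apartment common area. From `lockdown_phase2_start` residents settle into
apartment cohabitation: longer and likelier common dwells. This
reproduces the period pattern observed in practice: the popularity of
public places collapses, apartment-area popularity barely moves (hourly
distinct attendance is insensitive to visit length), and community
sociability dips before recovering above its pre-closure level as
flatmates become each other's only company. An `isolated_resident` preset
zeroes one resident's propensities for isolation-detection demonstrations.

A record-level generator (`simulate_ri_records()`) bypasses the agents
entirely: it draws covariates and computes the target from a known smooth
logistic response plus Gaussian noise ($\sigma = 0.02$ by default). This
is the parameter-recovery benchmark: with 365 days (1095 day-slot
records, the volume a year of observation yields), the sociability model
is expected to reach a test MAE within $2\sigma$. The published errors of
the original deployment (MAE 0.025 for sociability, 0.012 for popularity)
were measured on private facility data and are not reproducible from
synthetic traces; the recovery bound is the substitute criterion.

What the generator does *not* emulate: realistic human mobility between
scheduled blocks, caregiver–resident interactions (traces carry no role
labels), heterogeneous per-resident daily rhythms, localization noise
other than missingness, or epidemic dynamics. Passing tests demonstrate
that the indexes, filters and predictors do what they claim on data with
known structure — not that the generator's social world is faithful to any
particular facility.

## Numerical and testing choices

* The moving median of a binary vector is computed as a running window sum
  compared against $(k+1)/2$ (C++); tests cross-check it against the
  compiled running median in `stats::runmed` (`endrule = "keep"` matches
  the boundary-copy rule) and the duration filter against an independent
  run-length-encoding scan.
* Multiple detections in one 10 s slot (multi-tagging) resolve to the last
  record in file order — deterministic and order-stable.
* Slot indexing is 1-based and half-open in time: slot $t$ covers
  $[(t-1)\cdot 10\,\mathrm{s}, t\cdot 10\,\mathrm{s})$; midnight belongs
  to the next day.
* Pairs with an inactive member are excluded from every aggregate, as the
  active-set restriction in each definition requires.
* Degenerate inputs fail loudly: empty peer sets, empty active sets, day
  slots with no slots, even median windows, non-finite training data.
* Test problem sizes are chosen to exercise the full pipeline while
  keeping the suite quick: the synthetic invariants run on a 16-resident
  village, the scenario check on the full 64-resident village over 182
  days, oracle equivalence on 1000 random day-length vectors, and
  predictor recovery on 1095 records.

## Known limitations

* The Relational Index measures co-presence, not interaction; a silent
  room of residents scores as sociable as a lively one.
* The adjusted index mixes scales in $\Delta$ (slot-level pairwise vs
  daily mean-of-squares individual); it is implemented as defined.
* The PI model predicts hourly normalized attendance; mapping a
  multi-hour day slot to its midpoint hour in the prediction table is a
  package choice (configurable via the slot table).
* Smoothing assumes one observation per day on a regular grid; irregular
  gaps are treated as consecutive days.
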