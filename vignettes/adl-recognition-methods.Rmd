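---
title: "Recognising activities of daily living from ambient sensors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising activities of daily living from ambient sensors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlsense)
```

## The problem

Activities of daily living (ADL) — sleeping, grooming, toileting, getting
ready for bed, cooking, eating, watching TV, seated activity — are core
indicators of functional and cognitive health, and notoriously hard to
assess by questionnaire. A non-intrusive alternative instruments a home
with one ambient sensor box per room (temperature, humidity, luminescence,
passive infrared, acceleration, sampled at 0.2 Hz) and infers the
occupant's activities from the sensor stream. `adlsense` implements two
knowledge-driven classifiers for this setting — a rule-based
forward-chaining inference engine (RBI) and a circadian activity rhythm
classifier (CAR) — alongside two trained baselines (Gaussian naive Bayes,
random forest), with the packet model, preprocessing, a synthetic home
simulator and epoch-level evaluation around them.

## Data model and preprocessing

A data packet carries date, timestamp, sensor node number (the room),
supply voltage, a status word with even-parity error handling, a handshake
word for frame-collision detection, and the eight ambient values (the
acceleration block contributes node magnitude plus the three axes). The
original system transmits binary frames; since that wire format is not
published, the package defines a documented comma-separated record with
ISO-8601 date/time as its serialization. Parity is computed over all 16
bits of the status word (the bit width is a package choice — the field
convention, not a published constant); the handshake word is only checked
for equality with a fixed constant, as collision handling proper is
hardware behaviour. A packet is *lost* if its 5 s grid slot between a
node's first and last transmission is empty or its record is rejected;
reliability is `100·captured/(captured+lost)`.

Preprocessing follows the two classical sorting passes: a stable bucket
sort stratifies packets by room (the node number carries the room), and a
stable least-significant-digit radix sort (two 16-bit counting passes over
seconds-since-first-packet) orders each bucket chronologically.
Stability matters: it is what lets the bucket order survive the time sort,
and it is exercised against a comparison-sort oracle in the tests.

Sorted samples are composed into **ambient value matrices** `S_i`:
maximal runs of chronologically consecutive non-null samples from one
room, stored channels × time. Two readings of *null* are supported:

* `"grid"` — only a missing or rejected sample is null. This is the
  strictest reading and the low-level default, but it makes every
  room-day a single giant segment on a healthy link, which cannot carry
  per-activity labels (three different bathroom activities per day would
  collapse into one unit).
* `"occupancy"` — additionally, a present sample whose passive-infrared
  value is below a threshold (default 0.05 V) is null. The PIR channel
  reads ≈ 0 V in an empty room, so an inactive sample is a zero sample;
  under this reading segments coincide with occupancy episodes, which is
  the unit on which per-activity classification is meaningful. The
  classification pipeline uses this rule.

Two bounded tolerances are package choices: a segment terminates after
12 h regardless (bounding matrix size), and the pipeline bridges up to 2
missing grid samples inside a run (`gap_tolerance = 2`). The latter keeps
isolated transmission losses (≈ 0.5% of packets) from shattering long
activities — without it a seven-hour sleep episode fragments into ~20
pieces and no duration rule could ever fire. Runs of ≥ 3 consecutive
losses are rare enough at this loss rate to be negligible.

## The rule-based inference (RBI) classifier

The engine has three parts: a database of facts (the sorted segment
summaries, derived intermediate facts, and previously classified ADL as
historical facts), a rule repository over named behavioural parameters
`P_1..P_j`, and a forward-chaining loop. Rules are conjunctions of
threshold predicates over segment summaries — per-channel mean, SD, min,
max, least-squares slope, plus duration, room and clock time of the
segment start — with comparators `> ≥ = ≤ ≠ <`. A parser resolves every
parameter reference up front into a lookup table indexed by conclusion
and by referenced channel, reporting unknown parameters, comparators,
duplicate ids and empty conjunctions as parse errors.

Chaining repeatedly fires every rule whose premises hold, adding fact
conclusions to the segment's fact set and collecting ADL conclusions,
until quiescence or an iteration cap (default 10; the per-activity
iteration depth of the original deployment is unspecified, so a global
cap is used). The fact set grows monotonically and is bounded, so the
loop terminates even without the cap. Conflict resolution — the strategy
itself being open — orders fired rules by must-level first, then
priority, then predicate count (specificity), then rule id, and each
segment receives at most one final label. Historical facts persist only
within one subject's run, so nothing leaks across subjects.

Design choices worth flagging:

* The deployed rule values are unpublished. The shipped repository
  (`inst/extdata/default_rules.yaml`) encodes the behavioural statements
  that are domain facts — cooking only in the kitchen (a top-level *must*
  rule), humidity rise for grooming, a minimum sleeping duration,
  mealtime and evening clock windows — with every threshold a named,
  documented, tunable parameter.
* Equality on continuous summaries means agreement within the
  `equality_tolerance` parameter (default 0.5 channel units, about one
  noise SD); exact floating-point equality would never fire.
* One label per segment. Whether the original engine emitted concurrent
  labels is unstated; the single-label reading matches one-occupant homes.

## The circadian activity rhythm (CAR) classifier

CAR needs no training data. It exploits the observation that a person's
behaviour during the daily cycle falls into regular patterns: the same
activity recurs at a similar clock time with a similar sensor shape.

1. **Standardization.** Each segment is z-transformed per channel to
   `|(x − mean)/SD|`, removing person- and home-specific levels and
   scales. The sample SD (n−1) is used throughout — a convention choice.
   A zero-variance channel maps to zeros and is flagged.
2. **Emphasis.** The temporal centroid `E = Σ t·s_t / Σ s_t` locates the
   signal mass within the segment. The normalizer is read as `Σ s_t`
   (making the emphasis dimensionally a time); the alternative reading —
   dividing by the sample count — is not a centroid and is therefore not
   the default. An all-zero channel has undefined emphasis and cannot
   anchor a pattern.
3. **Candidate gating.** A segment is a potential ADL pattern if its
   room, duration and emphasis clock time fall inside at least one ADL's
   behavioural windows (shared with the rule repository's parameter file).
4. **CAR maps.** Candidates are grouped greedily across days: a candidate
   joins the closest map with the same room, emphasis clock time within
   60 min, and root-mean-square profile distance ≤ 0.5 on standardized
   profiles resampled to 64 points; otherwise it founds a new map. The
   three thresholds are package defaults — none are published. Every
   candidate lands in exactly one map.
5. **Smoothing.** Map profiles pass through the Gaussian broad-band
   filter `w(i) = exp(−i²/(2·SD⁴))/(SD²√(2π))`, truncated at
   `|i| ≤ 4·SD²` and renormalized to unit sum (with edge renormalization,
   so constants are preserved). The filter index is read as the position
   within the resampled profile, not as a segment index within the day —
   the reading under which "suppressing sensor fluctuation outliers"
   makes sense.
6. **Allotment.** Each map is scored against each ADL's windows on median
   clock time, median duration, room and duration relative to the longest
   co-occurring map (sleeping must be the dominant nightly pattern);
   the best-scoring ADL is allotted to the whole map. Maps outside all
   windows stay unlabelled and are reported, never force-assigned.

Under noise, profiles of short low-amplitude activities differ enough
across days that maps may stay small or singleton; that costs nothing in
accuracy (singleton maps are still scored against the windows) and the
cross-day merging becomes exact as noise decreases — the regime in which
the one-map-per-activity property is asserted in the tests.

## Trained baselines

The baselines see the recording at a coarser "dataset" granularity:
fixed 15-min windows (96/day), each attributed to the room with the
highest mean PIR and summarised by the same channel statistics as
segments. This granularity reconciles the order-of-magnitude gap between
the few-per-day activity events the ad-hoc classifiers retrieve and the
tens-of-thousands of datasets a windowed trained classifier consumes. A
window is labelled with the ADL covering ≥ 50% of it, else `"none"`.
The feature vector (per-channel mean/SD/min/max/slope, duration, room
one-hot, sine/cosine clock encoding, missingness masks) is the package's
documented choice — no feature set is published for this system.

Gaussian naive Bayes is implemented in the package (per-class Gaussian
likelihood per feature, floored variances, class priors, argmax
posterior) and cross-checked in the tests against an independent
implementation. The random forest contract — bootstrap per tree, no
pruning, `⌈√p⌉` features per split, majority vote — is exactly the
algorithm of the `randomForest` package, which the package delegates tree
growing to; the vote over individual tree predictions is aggregated in
the package so that ties break toward the smallest class index,
deterministically under a seed.

## Evaluation

Metrics are computed per 5 s epoch (the sampling period): the time axis
is discretized, every epoch labelled from the truth and the predicted
events, and a one-vs-rest confusion accumulated per ADL —
sensitivity `100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)`, macro means
unweighted over the eight ADL, metrics with empty denominators reported
as undefined. Whether the original metrics were event- or time-based is
unstated; the epoch reading is adopted because it is insensitive to how
predictions fragment, and an event-level count (a truth event is correct
when same-ADL predictions cover ≥ 50% of it — the matching rule again
being a package choice) is provided separately.

Ground-truth journals merge an electronic protocol-device log with a
paper log book: same-ADL overlaps fuse to their envelope; different-ADL
overlaps resolve in the device log's favour (it has trustworthy
timestamps) with the conflict counted. Predictions shorter than 20 s are
removed (strictly less: a 20 s prediction survives), the simple threshold
that suppresses the spurious one-sample segments noise produces.
Leave-one-out cross-validation trains on all subjects but one and
predicts the held-out subject, with a guard that refuses any fold whose
training set contains the test subject. Activity maps render events as a
day × time-of-day grid (5-min cells) for visual inspection of circadian
regularity.

## The synthetic home

No recordings are distributable, so the simulator defines the study
conditions: ten rooms/sensor boxes, 0.2 Hz, 20 days per subject by
default, eight ADL with one occurrence per day each. Schedules draw each
activity at its preferred clock time plus day-to-day jitter, modelled as
a stationary AR(1) process (ρ = 0.4) whose stationary SD is the nominal
jitter (15 min by default): schedules drift slowly rather than jump, so
start times are positively autocorrelated across days — the circadian
regularity CAR exploits — while the realized start-time SD still equals
the nominal value. A per-subject habitual shift (SD 10 min) adds
inter-subject variability. Getting ready for bed is anchored immediately
before sleeping. The single occupant cannot overlap activities; later
events shift past earlier ones. Ground truth is journalized at the
sensing resolution (5 s), and activities truncated by the recording
boundary are dropped rather than half-recorded.

Rendering adds, per room: sinusoidal diurnal baselines per channel, each
event's channel signature in its own room only (documented constants:
kitchen temperature +3 °C and humidity +2 g/m³ rises for cooking,
bathroom humidity ramps/pulses of different magnitude for grooming vs
toileting, living-room luminescence flicker for TV, small acceleration
pulses for meals and seated activity — the principle is domain fact, the
magnitudes are package choices), an elevated PIR level during occupancy
(0.3 V asleep, 0.8–1 V active), i.i.d. Gaussian channel noise
(temperature 0.15 °C, humidity 0.15 g/m³, luminescence 4 lx, PIR 0.02 V,
acceleration 0.05 m/s²), and independent packet loss at 0.47%. One
master seed drives three named substreams (schedule, render, loss), so
each stage is independently reproducible.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: multi-occupant homes and visitors, pets,
sensor drift and failure, activities outside the eight-label vocabulary,
unmodelled occupancy (the occupant is "nowhere" between events),
mislogged or forgotten journal entries, and room-to-room heat/humidity
coupling. Perfect benchmark scores on synthetic data certify the
pipeline's correctness under its own assumptions, not field performance;
the deployment reference table shipped with the package shows the
performance level this class of system reaches on real homes.

## Problem sizes and numerical choices

The shipped benchmark simulates 4 subjects × 7 days (≈ 4.8 M packets)
and the noise-free property runs 2 subjects × 5 days — sizes chosen so
the whole suite runs in well under a minute per scenario on a single
CPU while still exercising every pipeline stage at full sampling rate.
Other conventions: sample SD (n−1) everywhere; least-squares channel
slopes in units per minute; circular clock arithmetic for time-of-day
distances and means; radix keys as 32-bit seconds offsets (two 16-bit
passes); variance floors of 1e-6 in naive Bayes; ties in votes and
conflict resolution broken deterministically (smallest class index,
lexicographic rule id).

## Known limitations

The default rule repository and behavioural windows are written for the
default simulated routine; a real deployment would re-parameterize them
(they are one YAML file). The CAR map similarity thresholds are not
adaptive; strongly variable routines (jitter ≫ 1 h) degrade map merging
before they degrade candidate gating. The RBI engine evaluates rules per
segment and cannot express inter-segment sequencing beyond historical
facts. Baseline windows assume a single occupied room per window.
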