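# adlsense

Recognition of activities of daily living (ADL) from ambient home sensor
streams.

`adlsense` is for researchers and engineers working on non-intrusive,
sensor-based assessment of everyday functioning — sleeping, grooming,
toileting, getting ready for bed, cooking, eating, watching TV and seated
activity — from a wireless home sensor system: one sensor box per room,
each sampling temperature (°C), humidity (g/m³), luminescence (lx),
passive infrared (V) and acceleration (m/s², four values) at 0.2 Hz, and
transmitting parity-checked data packets to a central unit.

The package provides the full chain:

* **Packets** — the data-packet model (date, timestamp, node number,
  supply voltage, status word with even-parity error handling, handshake
  word, eight ambient channel values), delimited-text serialization,
  integrity-checked log readers and acquisition/reliability statistics.
* **Synthetic home** — a simulator that draws circadian ADL schedules
  (preferred clock time + slowly drifting AR(1) jitter) and renders them
  into per-room sensor streams with diurnal baselines, activity
  signatures, Gaussian noise and transmission loss. It stands in for
  private home recordings and gives every classifier a known ground
  truth.
* **Preprocessing** — stable bucket sort by room, LSD radix sort by time,
  and composition of maximal non-null sample runs into ambient value
  matrices `S_i` (channels × time), the classification unit.
* **RBI** — a rule-based forward-chaining inference classifier: a fact
  base, a YAML rule repository over named behavioural parameters
  `P_1..P_j`, rules `Rule_k = (S₁ > P₁) ∧ (S₂ = P₂) ∧ …` evaluated on
  segment summaries, iterated fact derivation until quiescence, and
  conflict resolution (must-level, priority, specificity).
* **CAR** — a circadian activity rhythm classifier: per-segment absolute
  z-standardization `|(S_i − S̄_i)/SD|`, temporal emphasis
  `E_i = Σ t·s_t / Σ s_t`, behavioural-window candidate gating, greedy
  cross-day grouping of similar patterns into CAR maps `D_j`, a Gaussian
  broad-band filter `w(i) = exp(−i²/(2·SD⁴)) / (SD²·√(2π))`, and ADL
  allotment by occurrence time and relative duration. No training data
  needed.
* **Baselines** — Gaussian naive Bayes (written here) and a random forest
  (bootstrap, unpruned trees, √p feature subsets, majority vote with
  smallest-index tie break) on fixed 15-min window features.
* **Evaluation** — journal merging, the 20 s false-positive threshold,
  leave-one-out cross-validation with a leakage guard, per-ADL epoch
  sensitivity/specificity `100·TP/(TP+FN)`, `100·TN/(TN+FP)` with
  unweighted macro means, event-level outcome counts, and day × time
  activity maps.

## Worked example

```r
library(adlsense)

home <- home_config(n_days = 5)
sim  <- simulate_subject(1, home, seed = 3)      # schedule -> sensors -> loss
cls  <- classify_subject(sim$stream, home, subject = 1)

cm <- confusion_metrics(cls$car, sim$truth,
                        span_start = home$origin,
                        span_end = home$origin + 5 * 86400)
print(cm)
```

```
                   adl    tp fp    tn fn sensitivity specificity
              sleeping 20761  0 65639  0         100         100
              grooming   916  0 85484  0         100         100
             toileting   435  0 85965  0         100         100
 getting_ready_for_bed   648  0 85752  0         100         100
               cooking  2211  0 84189  0         100         100
                eating  1962  0 84438  0         100         100
           watching_tv  5081  0 81319  0         100         100
       seated_activity  3556  0 82844  0         100         100
mean: sensitivity 100.00%, specificity 100.00%
```

Each row is a one-vs-rest confusion over 5 s epochs of the 5-day
recording: under the default simulation the rhythm classifier recovers
every activity epoch of this subject. With `plot(activity_map(cls$car,
n_days = 5))` the same result becomes the familiar day-by-time activity
map, one coloured band per recurring activity.

A full comparison of all four classifiers on a fresh multi-subject
simulation:

```r
run_benchmark(n_subjects = 4, n_days = 7, seed = 1)
```

```
Synthetic benchmark: 4 subjects x 7 days (seed 1)
Acquisition: loss_pct: 0.47, reliability_pct: 99.53
RBI  mean sensitivity  99.99%  mean specificity 100.00%
CAR  mean sensitivity  99.99%  mean specificity 100.00%
NB   mean sensitivity  92.68%  mean specificity  99.24%
RF   mean sensitivity  81.97%  mean specificity  99.75%
Events: 220 total; RBI correct 220 (missed 0); CAR correct 220 (missed 0)
```

The ad-hoc classifiers exploit structure (rooms, durations, circadian
timing) the windowed training-based baselines only see indirectly, which
is why they lead on macro sensitivity.

## Layout

```
R/                    packets, synthetic_home, preprocess, rbi, car,
                      baselines, evaluate, benchmark
inst/extdata/         default_rules.yaml (behavioural knowledge),
                      deployment reference tables (plain text)
inst/cli/adlsense.R   thin command-line front end (simulate / sort /
                      classify-rbi / classify-car / evaluate / activity-map)
vignettes/            methods vignette: model, assumptions, parameters
tests/testthat/       unit, property and acceptance tests
scripts/acceptance.R  headline-number reproduction (see above)
```
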