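---
title: "From beacon logs to school contact networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From beacon logs to school contact networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolcontacts)
```

## The measurement model

Proximity sensors ("motes") worn by students transmit a beacon every 20
seconds and log every beacon they hear: the sender's id, the time, and
the received signal strength (RSSI). Signal strength is a noisy proxy
for distance; a cut at −80 dB corresponds to roughly 3 m face-to-face —
a distance relevant to droplet transmission of respiratory infections.
This package treats those raw directed records as the primary data and
derives everything else from three simple, explicitly stated rules:

* **Thresholding is per record.** A record survives iff its RSSI is at
  least the threshold. Combining directions happens afterwards. (The
  alternative — thresholding a per-tick aggregate — would couple the
  two motes' noise; we keep the rule that can be applied in a single
  pass over a log.)
* **A pair-tick is evidence of proximity in that tick.** Under the
  default `union` rule one surviving direction suffices; the `mutual`
  rule requires both. Union is the default because mote flash memories
  lose data asymmetrically (battery pulls, corruption), and a lost
  direction should not erase an observed contact. The `mutual` option
  is retained for sensitivity analyses.
* **Contacts accumulate as `x/3` minutes per `x` recordings.** Each
  recording stands for one continuous 20-second contact, so durations
  are tick counts × 20 s, reported in minutes.

An *encounter* is a maximal run of consecutive pair-ticks
(`max_gap_ticks = 0`; a positive value bridges short dropouts but the
duration always counts observed ticks). A *cumulative contact* sums a
pair's ticks over the day. The day's *contact network* keeps
student–student contacts whose cumulative minutes **strictly exceed**
the threshold (default 5 minutes). Strictness matters because exact
5-minute totals (15 recordings) occur on the tick grid; "ignore
contacts of at most the threshold" gives clean semantics for threshold
sweeps. Network nodes are the students retaining at least one edge, so
the reported `n` responds to the threshold, and staff or stationary
motes never enter student networks.

## Statistics

Given the weighted network (weights `w_ij` in minutes):

* density `δ = 2m / (n(n−1))`;
* degree `k_i`, strength `s_i = Σ_j w_ij`, and the per-student mean
  contact duration `s_i / k_i`. School-level summaries report the
  across-student mean, sd, and standard error (`sd/√n`) of each. Note
  the summary column `s` is the mean of *per-student mean durations*,
  not total strength — both are available from `node_metrics()`;
* binary local clustering on the thresholded graph (`CC_i = 0` for
  degree < 2); weights are deliberately not used here, matching the
  convention for this measure in deployment studies;
* edge overlap `O_ij = n_ij / (k_i − 1 + k_j − 1 − n_ij)`, defined as 0
  when the denominator vanishes (two pendant endpoints). Averaged in
  weight bins it shows whether long contacts sit inside clique-like
  groups;
* contact matrices: edges between groups normalised per pair of
  students, `M[g,h] = e_{gh} / (n_g n_h)` off the diagonal and
  `M[g,g] = e_{gg} / (n_g(n_g−1)/2)` on it;
* time-binned degree: distinct partners per student per 3-minute bin,
  averaged over all tagged students (absent students count zero, so
  quiet bins read low).

**Modularity.** For an externally given partition `c` (grades or
classrooms — community *detection* is deliberately out of scope),

$$Q = \frac{1}{2W}\sum_{ij}\left(w_{ij} - \frac{s_i s_j}{2W}\right)\mathbf{1}[c_i = c_j].$$

Both the weighted and the binarized variant are exposed
(`weighted = FALSE`), because reported modularity values in the
literature do not always state which was used; the two coincide when
all weights are equal. Threshold sweeps rebuild the network at
`t = 0, 10, 20, …` recordings (10 recordings = 3 min 20 s), drop nodes
isolated by the cut, and flag points whose surviving partition has
fewer than two communities — scores there are not meaningful.

**Power-law fits.** Encounter durations are tick-quantised, so their
exponent is estimated with the exact discrete likelihood,
`P(X = x) = x^{-α} / ζ(α, x_{min})`, where the Hurwitz zeta function is
evaluated by Euler–Maclaurin summation (accurate to ~1e−12 for the
relevant α). Cumulative contact minutes use the continuous Pareto MLE.
When `x_min` is not supplied it is scanned over candidate values and
chosen by minimal Kolmogorov–Smirnov distance between the tail and the
fitted model. Two numerical notes: (i) for discrete data the KS
distance compares the two right-continuous step CDFs at the observed
atoms; (ii) on data that are a *clean* power law throughout, every
candidate tail fits and the scan's choice of `x_min` is noise-driven —
fits with known `x_min` are the right tool for exponent-recovery
checks. Degenerate samples (constant values, or no candidate leaving
50 tail points) raise a fit error rather than a number.

## The synthetic school-day generator

The generator exists so the full pipeline — including its statistical
behaviour — can be exercised without a deployment. It emulates:

* a school of `n_grades × classrooms_per_grade × class_size` students
  (default 4 × 2 × 12 = 96; deliberately smaller than real deployments
  of 141–327 students so that simulations stay fast, which scales down
  degree and density but preserves the structural contrasts of
  interest);
* a period schedule (defaults: five class periods, two 15-minute
  breaks, a 45-minute lunch, 8:30–15:00) with two regimes: **cohort**
  (a classroom shares every class period — elementary/middle school)
  and **individualized** (every student draws a grade-mixed room each
  period — US high school);
* per-pair contact as an alternating renewal process: geometric idle
  gaps (encounter-start probability per tick: `p_start = 0.2` in
  classrooms, `p_start_common = 0.02` in break/lunch rooms,
  `p_start_lunch` separable so crowded hallways can coexist with
  seated cafeterias) and encounter durations drawn from a discrete
  power law with exponent `duration_exponent = −2.5`, clipped at the
  period end. Successive encounters of a pair are separated by at
  least one out-of-range tick, so sampled encounters coincide with the
  maximal runs the ingest reconstructs;
* brief background meetings between students in *different* common
  rooms during breaks/lunch (`p_background = 0.002` per pair-tick);
* a Gaussian RSSI model (−65 ± 5 dB in range, −90 ± 5 dB out of range,
  emitted only when `emit_far = TRUE`) and an optional per-record drop
  probability for asymmetric data loss;
* lunch groups: by default consecutive grade pairs share a cafeteria
  room, reflecting staggered lunch scheduling in lower-level schools;
  the composition is a config knob because real pairings vary.

Two presets bundle these choices: `school_scenario("elementary")`
(cohort, quiet common rooms) and `school_scenario("highschool")`
(individualized, one shared cafeteria, crowded hallways with
`p_start_common = 0.1` and seated lunch at 0.02). The parameter values
were chosen once, on first principles: the encounter-duration exponent
−2.5 matches the steep heavy tails reported for face-to-face encounter
durations in sensor studies (cumulative *contact* durations are much
shallower, around −1 to −1.5, and emerge here from aggregation rather
than being imposed); classroom duty cycles (~30% of class time within
3 m of a given classmate) give classmate contacts on the order of an
hour; common-room rates make break/lunch contacts mostly sub-5-minute.
Under these conditions the elementary scenario lands at grade
modularity ≈ 0.7 with clustering ≈ 0.8, and the high-school scenario at
grade modularity ≈ 0 with pronounced break-time degree spikes — the
contrast the analysis is designed to expose.

What the generator does *not* emulate: spatial movement and radio
physics (co-location is room-level and binary), multi-day variation,
teacher/staff interaction patterns (non-students can be present but
emit nothing), clock drift (all motes share the tick grid, as real
deployments approximate with stationary synchronisation motes), and
room-capacity effects beyond the per-room contact rates. Passing tests
on synthetic data therefore validate the *processing* — thresholds,
segmentation, accumulation, statistics — and the qualitative
regime contrast, not any claim about real schools' parameter values.

## Determinism

Every stage draws from a stream seeded deterministically from
`config$seed` (separate offsets for roster, schedule, and log, so
regenerating one stage does not shift another). Identical configs and
seeds reproduce byte-identical logs and pipeline outputs; arguments are
forced before seeding so lazy evaluation cannot interleave streams.

## Problem sizes and expectations in the test-suite

The suite simulates schools of 30–96 students (tens of seconds in
total) and checks, among others: exact agreement of modularity with a
brute-force evaluation of its defining sum on all random graphs up to 8
nodes (tolerance 1e−12, weighted and binary, plus an igraph
cross-check); exact recovery of planted in-range pair-ticks through the
RSSI threshold; recovery of the planted duration exponent within ±0.15
from ≥ 20,000 simulated encounters and within ±0.05 from 50,000 pure
power-law draws with known `x_min`; a cohort-vs-individualized grade
modularity contrast of at least 0.2 (≥ 0.5 vs ≤ 0.3); and monotone
growth of Q while a threshold sweep removes only inter-block edges of a
planted two-block network. A comparison against the deployed-school
reference tables is included but requires the deposited network files,
which cannot ship with the package; without them that check reports a
failure rather than silently passing.

## Known limitations

* The contact-duration distribution of a synthetic school is a mixture
  (many brief cross-class contacts, a heavy classmate mode), so a
  single global power-law exponent summarises it only roughly — as is
  equally true of real school data.
* The discrete MLE's `x_min` scan caps candidates at 200
  quantile-spaced values for large samples; exponents far above α ≈ 8
  are outside the optimizer's bracket.
* `read_network()` accepts edge-list CSV, Pajek and GraphML; other
  formats (GML, graph6) should be converted externally.
* Modularity against overlapping or hierarchical partitions, and any
  form of community detection, are out of scope by design.
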