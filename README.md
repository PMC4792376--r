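# schoolcontacts

Weighted contact networks of school students from wireless
proximity-sensor (mote) beacon logs — and everything needed to analyse
them the way school-deployment studies do: encounter segmentation,
cumulative daily contacts, network summary statistics, mixing matrices,
modularity against grade and classroom partitions, and power-law fits to
contact-duration distributions. A synthetic school-day generator makes
the entire pipeline reproducible and testable without access to a sensor
deployment.

The package is aimed at infectious-disease modellers and network
epidemiologists working with proximity-sensor data (TelosB-style motes,
RFID badges) from schools or comparable closed settings.

## What it computes

Motes transmit a beacon every `tick_seconds` (20 s) and log who they
hear, when, and at what signal strength (RSSI). The processing chain is:

1. **RSSI threshold** — keep records with RSSI ≥ −80 dB (≈ 3 m
   face-to-face), applied per record.
2. **Pair-ticks** — map timestamps to tick indices
   (`floor(t / tick_seconds)`) and collapse the two directions of a pair
   into one observation per tick (union rule by default; a `mutual` rule
   requiring both directions is available).
3. **Encounters** — maximal runs of consecutive ticks for a pair; each
   recording stands for a continuous 20-second contact.
4. **Cumulative contacts** — per pair and day, `x` recordings = `x/3`
   minutes of aggregated contact time.
5. **Contact network** — undirected graph on students, edge weight
   `w_ij` = cumulative minutes, edges kept when `w_ij` strictly exceeds
   a 5-minute threshold.

On that network the package computes density `δ = 2m / n(n−1)`, per-node
degree `k_i`, strength `s_i = Σ_j w_ij`, binary local clustering `CC_i`,
the edge overlap ratio

```
O_ij = n_ij / (k_i − 1 + k_j − 1 − n_ij),   n_ij = |N(i) ∩ N(j)|,
```

grade/classroom contact matrices (edges per pair of students), degree
histograms, 3-minute time-binned average degree, and weighted
Newman–Girvan modularity against an *externally given* partition
(grades or classrooms — never inferred):

```
Q = (1/2W) Σ_ij ( w_ij − s_i s_j / 2W ) · 1[c_i = c_j]
```

with threshold sweeps in steps of 10 recordings. Encounter and contact
duration distributions are fitted with maximum-likelihood power laws
`P(w) ~ w^β` (discrete fits through the Hurwitz zeta function for
tick-quantised durations, continuous Pareto fits for cumulative minutes,
`x_min` chosen by minimal Kolmogorov–Smirnov distance).

## Worked example

Simulate an elementary-style school (4 grades × 2 classrooms × 12
students, cohort schedules, grade-paired lunches) and analyse its day:

```r
library(schoolcontacts)

cfg      <- school_scenario("elementary", seed = 7)
roster   <- generate_roster(cfg)
schedule <- generate_schedule(cfg, roster)
log      <- simulate_beacon_log(cfg, roster, schedule)
ing      <- ingest_beacon_log(log, roster)          # -80 dB, union rule
net      <- build_network(ing$contacts, roster, threshold_minutes = 5)

net
#> <contact_network> 96 nodes, 585 edges, total weight 45529.3 min (> 5 min contacts)

glance(net)
#>       n     m delta     d  d_sd  d_se     s  s_sd  s_se    cc cc_sd  cc_se
#>      96   585 0.128  12.2  1.06 0.108  78.3  6.42 0.655 0.832 0.134 0.0136

modularity_score(net, network_partition(net, "grade"))
#> [1] 0.7426759

fit_power_law(ing$encounters$n_ticks, discrete = TRUE, xmin = 1)
#> <power_law_fit> discrete MLE: beta = -2.525 (alpha = 2.525), x_min = 1, KS = 0.0013, tail n = 82093 of 82093
```

Reading: 96 students keep 585 contacts stronger than 5 minutes
(density 0.128); a student has on average 12.2 such contacts of 78
minutes each, with high local clustering (0.83). The grade partition
explains the network strongly (Q = 0.74, typical of cohort-scheduled
schools), and observed encounter durations recover the generator's
power-law exponent (−2.5). The same pipeline accepts recorded data:
`read_beacon_log()` / `read_roster()` for raw logs, or `read_network()`
for prebuilt edge lists, Pajek `.net` (with `.clu` partitions) and
GraphML files. `run_pipeline()` executes every stage and writes all
tables as CSV.

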