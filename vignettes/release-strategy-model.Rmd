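---
title: "A spatial Monte Carlo model of egg-parasitoid release strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial Monte Carlo model of egg-parasitoid release strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trichosim)
```

## The system and the question

The sugarcane borer *Diatraea saccharalis* is the key lepidopteran pest of
sugarcane in the Americas; its larvae bore galleries in the stalk.  The egg
parasitoid *Trichogramma galloi* is mass-released against it: a wasp lays
into freshly laid borer eggs, the embryo is killed, and about a week later
new wasps emerge from the parasitized egg.  The operational protocol is
three weekly releases of 50,000 wasps per hectare.  `trichosim` implements a
stochastic, spatially explicit simulation of this system to ask which knob
matters more: the *density* of wasps per release, or the *number* of weekly
releases.

## Model structure

The field is a square lattice of 1 m² cells (default 1000 × 1000 = 100 ha,
chosen large enough that insects effectively never reach the border; the
engine still logs boundary contacts so that scaled-down grids are
observable).  Time advances in daily steps at a constant mean temperature
(default 30 °C).

**Development.**  Immature stages develop by linear degree-day
accumulation: a stage with thermal constant $K$ and lower development
threshold $T_T$ gains $E = \max(0, T - T_T)$ degree-days per day and molts
on the day its accumulation crosses $K$ under the nearest-day convention: a
final development day more than half filled counts as complete, so the
stage lasts $\max(1, \lceil K/E - 1/2\rceil)$ whole days (equivalently, the
day-by-day accumulator molts at $K - E/2$).  This discretization matters: it
reproduces the reference event timing of the system — first F1 emergence,
and hence the first release, on day 36 — where always rounding up would
push every generation later by one day per stage.  The engine precomputes
these integer durations; their equivalence with day-by-day accumulation is
exercised in the test suite against a per-individual simulator.  The borer
passes through egg → larva → pupa → adult (4, 23 and 6 days at 30 °C with
the default constants); the parasitoid has a single immature stage inside
the host egg (8 days at 30 °C).  Surplus energy at a molt is discarded.  Immatures suffer no mortality other than
parasitism of eggs — the model isolates the parasitoid's effect.

**Adults.**  Adult life spans are Normal (borer 8.60 ± 0.95 d, wasp
8.9 ± 0.7 d), sampled once at emergence, rounded to whole days and floored
at one day.  Sex is assigned binomially at emergence (proportion female
0.46 and 0.89 respectively).  Only females reproduce; both sexes count
toward the release trigger.

**Reproduction.**  A female's expected daily output declines exponentially
with her oviposition age $\alpha$ (days since laying began):

$$o_\alpha = \lambda\left[e^{-\eta\alpha} - e^{-\eta(\alpha+1)}\right],$$

which telescopes to the lifetime total $\lambda$.  For the borer the
lifetime total defaults to the net reproductive rate 84 divided by the
proportion female (λ ≈ 182.6 eggs); reading the 84 as raw eggs instead is a
configuration switch (`fecundity_mode = "total"`).  Laying starts after a
2.16-day pre-oviposition period, rounded up to whole days.  For the wasp
the same schedule with λ = θ = 57 gives the daily *attack capacity*.  The
rhythm constant η is not fixed by the published life-table sources; the
default η = 0.33 puts roughly 90% of lifetime output in the first seven
laying days, consistent with a strongly front-loaded oviposition rhythm,
and both species' values are configurable (the wasp inherits the borer's
rhythm unless overridden).  Realized daily eggs are Poisson draws with mean
$o_\alpha$ (a deterministic rounding mode is available); summed over the
females in a cell this is a single Poisson draw in the summed mean.

**Movement.**  Borers disperse without preferred direction: a daily
distance drawn from an exponential kernel $D_d = e^{-\beta d}$ (β = 0.2 per
m) truncated at the species' maximum daily distance (50 m), in a uniformly
random direction; the x/y components are rounded to whole cells and
destinations are clipped at the grid edge (with a logged boundary contact).
Wasps search: each examines every cell within its 10 m action radius and
moves to one with probability proportional to that cell's count of
unparasitized host eggs; when the disk holds no eggs the wasp falls back to
the undirected kernel, reusing β = 0.2 with its daily displacement capped
at the action radius.  Host density means unparasitized eggs only — the
one host stage the wasp uses, and parasitized eggs never rejoin the
attackable pool (no superparasitism).

**Attack.**  Parasitism is local: after moving, the wasps in a cell pool
their daily capacities $o_\alpha$ (θ-scaled), a Poisson count is drawn, and
that many of the cell's eggs are parasitized, capped by availability;
unused capacity is forfeited.  Eggs are removed uniformly at random without
replacement across the cell's egg age classes (sequential hypergeometric
draws, oldest class first in the draw order).  A parasitized egg restarts
degree-day accumulation for the wasp's immature stage; on completion each
yields 2 adult wasps.

**Arrivals and releases.**  Each day one Bernoulli trial with probability
φ = 0.01 brings a new mated adult female borer to a uniformly random cell.
The simulation starts with four mated females at the central cell.  Wasp
releases start the first day the adult borer population reaches a threshold
τ and repeat at weekly intervals; with the default τ = 5 (the first
adult beyond the four founders, i.e. the first F1 emergence) the first
release lands on day 36 under default conditions.  Released wasps number
`density_per_ha × release-area hectares`, spread multinomially over the
release area — by default the bounding box of the cells holding eggs on the
first day any eggs existed, the most literal reading of "where the first
eggs are reported"; a centred square of configurable side is the
reproducible alternative.  Releases are all-female by default (mass-reared
*Trichogramma* releases are female-biased); applying the 0.89 sex ratio
instead is a switch.  Released wasps are placed on the release day and
become active (searching, attacking, ageing) the following day.

## The daily cycle and its randomness

The within-day event order is fixed: (1) development and molting, including
wasp emergence from completed parasitized-egg batches; (2) adult deaths;
(3) movement (borers undirected, wasps host-directed); (4) parasitism;
(5) oviposition; (6) background arrival; (7) trigger check and release;
(8) recording.  The order was chosen so that newly laid eggs become
attackable the following day and released wasps act from the next day; it
is documented in the engine source and changing it is deliberately not a
runtime option.

The engine represents eggs as per-cell age-class cohorts, larvae and pupae
as molt schedules, and adults as individuals.  All stochastic draws follow
a fixed, documented protocol (per-group binomial sex splits in ascending
cell order, per-individual life spans in creation order, distance deviates
before angle deviates, and so on).  Because of that protocol, a brute-force
simulator that tracks every insect — and every egg — as its own record
reproduces the engine's daily series *bit for bit* under the same seed.
That representation-invariance check, run on a 12 × 12 grid, is part of the
test suite; it is the strongest correctness guarantee in the package, since
it exercises development, movement, search, parasitism, releases and
bookkeeping simultaneously.

Replicate $i$ of a scenario uses seed `base_seed + i - 1`; two scenarios
run with the same base seed therefore share random streams replicate by
replicate (common random numbers), which makes scenario contrasts paired
and considerably tightens fold and dominance comparisons.  Everything is
reproducible: identical configuration and seed give byte-identical CSV
output.

## Scenario analysis

`run_release_matrix()` runs the standard protocol (3 × 50,000 ha⁻¹),
its density variants (3 × 100,000 and 3 × 200,000) and its frequency
variants (4 × 50,000 and 5 × 50,000) with common random numbers and
summarizes: mean final larval count, fold reduction versus the standard
protocol at the end of the horizon, and a negative-growth flag — the sign
of the ordinary least-squares slope of `log(mean larvae + 1)` from the
first release day to the horizon.  `summarize_replicates()` gives daily
means with a Normal-approximation 95% band (`mean ± z·SE`; a percentile
bootstrap is the alternative, since the published description fixes only
"95% confidence interval").  `ratio_n()` tracks the modified-to-standard
ratio of mean larval populations over time, with days of zero standard
mean emitted as `NA` rather than numbers.  Fold reductions default to the
final-day larval means; the time-averaged post-release alternative can be
computed from the summary series.

```{r example}
cfg <- scenario_fixture("desk")
mx <- run_release_matrix(cfg, base_seed = 1)
mx$table
plot_scenario(mx$results[c("3x50k", "5x50k")])
```

## Problem sizes

Three bundled tiers share one model: `smoke` (10 × 10 cells, 20 days, one
replicate) runs in well under a second and is used for interface and
reproducibility tests; `desk` (200 × 200 cells = 4 ha, 150 days, 10
replicates) is the package's scenario-comparison setting, sized so a full
five-scenario matrix with common random numbers completes in minutes on one
CPU; `field` (1000 × 1000 = 100 ha, 150 days, 20 replicates) reproduces the
reference geometry.  Scenario contrasts (folds, dominance, curve shape) are
properties of the dynamics rather than of the absolute area, but absolute
population sizes do scale with the grid, so desk-scale numbers should be
read as contrasts, not field counts.

## Numerical choices and degenerate inputs

* Stage durations use the nearest-day closed form
  `max(1, ceiling(K / (T − T_T) − 1/2))`; a stage whose threshold meets or
  exceeds the running temperature never completes (callers of
  `stage_duration()` get an error; the engine treats the stage as
  absorbing).
* Distances are sampled continuously by inverse CDF on the truncated
  kernel and discretized once, at displacement, by rounding the x/y
  components to whole cells (half-to-even).
* Poisson means for cell-level draws are accumulated in double precision
  in a fixed (creation) order, so cohort-level and individual-level
  summation agree exactly.
* The release trigger arms only once the pest is reported in the field
  (the first eggs exist): before that, the first-egg release area is not
  defined, so a count threshold met early — e.g. by a background arrival
  on day 1 — defers the first release to the first oviposition day rather
  than aborting the run.  Calling `apply_release()` directly with an empty
  area is still an error (degenerate input).
* With zero founders and zero immigration the empty state is absorbing;
  with `n_releases = 0` the model collapses to pure pest growth, which is
  geometric (net reproductive rate ≫ 1) — both are tested properties.
* The daily conservation audit (births + arrivals + releases − deaths −
  parasitism must explain every day's population change) runs by default
  and aborts with diagnostics on any bookkeeping imbalance.

## What the desk-scale runs do and do not show

The desk setting keeps every mechanism of the full model — phenology,
search, parasitism, the trigger, weekly release schedules — on a 25× smaller
area.  Release totals scale with the release area, so absolute larval
counts are not field predictions; the quantities that transfer are the
*contrasts*: fold reductions between protocols, the dominance of more
releases over denser releases at equal or smaller total numbers, and the
sign of the post-release growth rate.  Two constants the published
life-table sources do not pin down (the trigger τ and the rhythm η) were
fixed once at their defaults before any scenario comparisons were run and
are surfaced in the configuration; conclusions that depend strongly on
either would need field calibration.

One structural property of the model deserves emphasis.  At a constant
temperature with deterministic degree-day development, host generations
stay synchronized: the egg-to-egg cycle is 36 days at the defaults, and
host eggs exist only in discrete waves (roughly days 39–55 and 75–98 for
the second and third generations) separated by egg-free windows of about
three weeks.  Wasp adults live ~9 days and their immatures need 8 days, so
no release placed inside an egg-free window — nor the in-field offspring
of earlier releases — can survive to the next wave.  Release schedules
that differ only within such a window therefore produce nearly identical
outcomes under this model, and scenario contrasts should be interpreted
with that in mind.  Field populations are desynchronized by temperature
variation and continuous immigration, mechanisms this model deliberately
leaves out; see the README for how this property shows up in the
package's scenario comparisons.

The model also excludes crop phenology, humidity and rainfall,
density-dependent immature mortality, host-stage preference and
functional-response refinements, and economic cost layers.  It is a
strategy-comparison instrument, not a forecasting tool.
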