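---
title: "Modeling genetic population suppression and sterile-male fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genetic population suppression and sterile-male fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitsim)
```

## The modeling problem

Sterile-insect-style programs suppress a pest population by releasing
individuals whose matings or offspring are reproductive dead ends.  The four
systems compared here differ in what is released and where the dead end
falls:

* **pgSIT** releases eggs; all surviving adults are sterile males (released
  females die during the embryo/larval stages), so their matings waste wild
  females' single mating.
* **RIDL** releases adult males carrying a dominant lethal; all their
  offspring die at the end of the pupal stage, after consuming larval
  resources.
* **fsRIDL** releases eggs carrying a female-specific dominant lethal;
  transgenic females die before pupation, carrier males are fully fertile
  and pass the transgene on.
* **IIT** releases adult males whose *Wolbachia* infection makes every
  mating with an uninfected female cytoplasmically incompatible; low-level
  irradiation (used to neutralize the risk of accidentally releasing
  infected females) roughly halves their adult longevity.

Two mechanisms drive suppression: interception of female matings (weighted
by male mating competitiveness `c`) and, for egg releases, competition for
larval resources by doomed immature forms.  Which mechanism dominates
changes over the course of a program, which is why the model resolves life
stages, genotypes and mating structure explicitly.

## Population model

The model follows an *Aedes aegypti*-like population through egg, larval,
pupal and adult stages on a daily time step, with overlapping generations.
State is held per genotype-by-sex class and day-of-age within each juvenile
stage; adult females are indexed by their own genotype **and** their mate's,
because each female mates exactly once, on emergence, and retains that
male's genetic material for life.

Each day, in order:

1. **Egg laying.** Every mated-female class lays `beta` eggs per female,
   thinned by the cross's viable-egg fraction and distributed over offspring
   classes by the inheritance cube.  Sterile-sired and incompatible-sired
   matings contribute no egg input at all: eggs that can never hatch have no
   modeled resource effect, because density dependence acts only at the
   larval stage.
2. **Survival.** Juveniles survive with probability `1 - mu_aqua`; larvae
   additionally survive with the Deredec-form factor
   `(alpha / (alpha + L))^(1/T_L)`, where `L` is the day's total larval
   count across *all* genotypes, doomed classes included — this is the
   resource-competition channel exploited by egg releases.  Adults survive
   with probability `1 - omega * mu_ad` (clamped to [0, 1]).
3. **Aging and promotion.** Final-age eggs hatch, final-age larvae pupate,
   final-age pupae emerge.  Doomed classes are removed at the stage exit
   their lethality specifies: fsRIDL females and pgSIT released females at
   the larva-to-pupa transition, RIDL offspring at the pupa-to-adult
   transition, so that both consume larval resources in full.
4. **Mating.** Each newly emerged female picks a mate genotype `m` with
   probability `c_m M_m / sum_k c_k M_k` over the current adult males and
   joins the mated pool permanently.  If no effective males exist
   (`sum c_k M_k = 0`) she waits in a non-laying unmated class and retries
   daily — necessary for near-elimination endgames.

Scheduled releases are applied at the end of their day: released eggs sit
at age 1 overnight, released adult males join the mating pool from the next
day.

The same code path serves a deterministic mode (expected values, real
counts) and a stochastic mode (Poisson egg numbers, binomial survival,
multinomial mate choice and offspring assignment, integer counts).  The
stochastic mode is what makes *elimination* — the reproducing population
hitting exactly zero — a well-defined event; we count an individual as
reproducing if it is a fertile female of any genotype (at any stage) or a
male of a genotype that can sire viable offspring, so fsRIDL carrier males
keep a population "alive" but pgSIT, RIDL and IIT males do not.

### Ordering conventions

The daily order above — laying before adult survival, mating after
emergence, laying from the next day — is one of several defensible
conventions; it is fixed here because the equilibrium calibration below is
exact under it, and it is documented so results are reproducible.

## Calibration

Life-history defaults are `beta = 20` eggs/female/day, `mu_ad = 0.123`,
stage durations 5/6/4 days (egg/larva/pupa), `Rm = 1.1` per generation and
`N_F_eq = 10000` adult females — standard values for this modeling
framework, all overridable through `life_history()`.  Two derived
parameters make the wild equilibrium exact:

* `mu_aqua` solves `(beta / (2 mu_ad)) (1 - mu_aqua)^(T_E+T_L+T_P) = Rm`:
  density-independent juvenile survival is whatever gives the stated
  growth rate absent density dependence.  The closed form is
  `mu_aqua = 1 - (2 mu_ad Rm / beta)^(1/(T_E+T_L+T_P))`.
* Stationarity then forces the larval factor to cancel the growth excess:
  `alpha / (alpha + L_eq) = 1 / Rm`, i.e. `alpha = L_eq / (Rm - 1)` with
  `L_eq` the equilibrium larval total.  No iterative solve is needed, and
  the deterministic model started from the calibrated state is a fixed
  point to machine precision (the test suite holds it to < 0.1% over a
  year, and it is in fact exact).

```{r calibration}
cal <- calibrate_equilibrium(life_history(N_F_eq = 1000))
cal
```

## The comparative experiment

`compare_interventions()` reruns the four systems plus a no-intervention
baseline under identical per-realization random streams: weekly releases
for six months, 200 eggs per wild adult for the egg systems, 10 adult males
per wild adult for the adult systems, with cube-default fitness values
(pgSIT `c = 0.78`; RIDL/fsRIDL `c = 0.05`; IIT `c = 1`, `omega = 2`).
"Per wild adult" uses the pre-intervention equilibrium total (males plus
females), fixed for every event; a `baseline = "females"` switch exists
because the convention is genuinely ambiguous.

The shipped problem size is deliberately a tenth of the full study — 1,000
equilibrium females and 100 realizations over 200 days — chosen so the
whole comparison runs in about a minute and a half on one CPU while
exercising the identical code path; `full_scale = TRUE` assembles the
10,000-female, 2,000-realization configuration for cluster use.

```{r compare, eval = FALSE}
cmp <- compare_interventions(scale_factor = 0.1, n_realizations = 100,
                             horizon = 200, seed = 1)
cmp$table
```

Two qualitative expectations are encoded as tests: egg-release systems
suppress fastest in the first three weeks (their larvae hit the
density-dependent bottleneck immediately), and pgSIT attains the highest
elimination probability.  A caveat worth stating plainly: at this scale and
with `Rm = 1.1`, fixed-size 10:1 adult-male releases sterilize so large a
fraction of matings that RIDL and IIT also eliminate the scaled population,
so the day-180 ranking of the *middle* systems (fsRIDL vs RIDL vs IIT) is
not the one seen in full-scale published comparisons of this kind.  The
middle ordering is sensitive to the per-generation growth rate: with a
growth rate of several per generation, 90% mating interception no longer
guarantees collapse, the larval-competition channel gains relative weight,
and IIT's halved longevity becomes the binding constraint.  We keep
`Rm = 1.1` as the documented default rather than tuning it, and treat the
middle ordering as scale- and growth-rate-dependent; the elimination-sweep
monotonicities (below) are the robust claims.

`parameter_sweep()` maps elimination probability over male competitiveness
and adult lifespan reduction `r` (converted to a hazard multiplier
`omega = 1/(1-r)`, since halving mean lifespan under geometric survival is
approximately doubling the daily hazard).  Tests assert the monotone
trends — elimination probability non-decreasing in `c`, non-increasing in
`r` — on a coarse 3x3 grid at small population size, within Monte Carlo
slack; the published-scale thresholds (~25% competitiveness, ~75% lifespan
reduction) are qualitative expectations at full scale, not desk-scale
targets.

## Mate-competition statistics

The competition assay puts `n_wt` fertile and `n_test` sterile males in a
cage with virgin females; each female mates once (she is refractory on the
assay's timescale), so her brood hatches at `h0` if she found a fertile
male and at `h_sterile` (default 0) otherwise.  The expected hatch rate is

    h_mix = h0 * n_wt / (n_wt + c n_test) + h_sterile * c n_test / (n_wt + c n_test)

and inverting it gives the Fried competitiveness index

    c = (n_wt / n_test) * (h_ctrl - h_mix) / (h_mix - h_sterile).

With the printed mean hatch rates of the assay — 47.9% for one wild plus
one sterile male against the 85.1% two-wild-male baseline — the index is
78%:

```{r fried}
fried_index(h_mix = 0.479, h_ctrl = 0.851, n_wt = 1, n_test = 1)
```

The two-wild-male control is the default baseline because it holds male
density constant and so isolates competition from the dilution effect of
simply removing a fertile male; the one-wild-male control (87.6% in the
same assay) is selectable and yields a different index — the two are
reported separately, never averaged.  `estimate_competitiveness()` pools
hatch counts (total hatched / total laid) within each stratum before
inverting — a mean of ratios would weight small broods erratically — and
bootstraps over replicates for a percentile CI.  A calibration caveat: with
only five replicates the percentile bootstrap is anti-conservative; in our
synthetic-coverage experiments the nominal 95% CI covers the truth for
about 87% of assays.  We document this rather than substitute a different
interval type, and recommend >= 10 replicates where coverage matters.

## Interval-censored survival

Longevity assays inspect vials every third day, so a death is only known to
lie in a 3-day window `(last seen alive, first seen dead]`; survivors are
right-censored at study end.  The survival curve estimator is the standard
nonparametric MLE for such data: probability mass can sit only on the
*Turnbull intervals* (maximal intersections of the observation intervals),
and the masses are found by self-consistency (EM) iteration, whose
log-likelihood is non-decreasing and which we run to a 1e-8 mass tolerance.
Exact death times are supported as zero-width intervals, and when the data
are exact-or-right-censored the estimator collapses to the Kaplan–Meier
product-limit curve (asserted to 1e-8 against `survival::survfit`).

Within a Turnbull interval the survival function is not identified; we
report the lower/upper envelope (`survival_band()`) and, for point
summaries, place each interval's mass at its midpoint.  The median is the
smallest day at which the fitted survival drops to 0.5 or below, with a
record-level bootstrap (default 10,000 repetitions) for its SD and
percentile CI.  On a 3-day grid the midpoint convention quantizes the
median to half-grid values, so recovery tests use a ±3-day tolerance around
the generating median.

Group comparison uses a permutation test on the integrated absolute
difference between the two fitted curves over the pooled finite observation
window, with group labels reshuffled.  This replaces the generalized
log-rank machinery sometimes used for interval-censored comparisons: the
permutation analogue is exactly specified, distribution-free and
seed-reproducible.  Its power is limited when the integration window
extends far beyond the last death (the censored-tail plateau contributes
noise), which is why the packaged examples use a couple of hundred
individuals per group.

## Synthetic data: what it does and does not show

`gen_competition_assay()` draws each female's mate from the one-mating
model, egg counts as Poisson (mean 30 per female per cage-night — the
true laying distribution is not specified by the assay design, so Poisson
is the minimal documented choice) and hatches as binomial, with optional
beta-binomial overdispersion (off by default; replicate-level SDs in real
assays suggest extra-binomial variance, but no mechanism is specified, so
the default stays minimal).  `gen_interval_survival()` draws exponential or
Weibull death times and grids them onto the inspection schedule.

Passing recovery tests against these generators shows the estimators invert
the models they assume; it does not validate those models against real
cages or vials — real assays have female-level laying heterogeneity,
possible remating beyond the refractory window, and batch effects that the
generators deliberately omit.  Similarly, the population model's passing
tests certify internal consistency (exact equilibrium, conservation,
stochastic/deterministic agreement within Monte Carlo error) and the
stated comparative properties at desk scale, not field realism: no spatial
structure, migration, seasonality or temperature dependence is modeled, and
egg diapause — biologically important for egg-release logistics — has no
dynamic role.

## Numerical notes

* Calibration is closed-form; the only failure mode is
  `2 mu_ad Rm / beta > 1`, reported as "no root for mu_aqua".
* Stochastic runs use R's global RNG, seeded per realization by a
  deterministic perturbation of the base seed, so ensembles are
  reproducible and different systems share realization streams.
* Turnbull-interval computation shifts half-open left endpoints by a third
  of the smallest endpoint gap, turning interval containment into closed
  interval comparisons without floating-point ties.
* Degenerate inputs are first-class: zero males (females queue unmated),
  empty release schedules, `n_boot = 0` (point estimates only), all-equal
  hatch rates (index 0), and heavy censoring (median reported
  unestimable) all have defined behavior and tests.
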