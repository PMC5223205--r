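---
title: "Detecting simultaneous regime shifts in flood-pulse hydrology and fish assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting simultaneous regime shifts in flood-pulse hydrology and fish assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodshift)
```

## The problem

Large tropical rivers rise and fall once a year. In the central Amazon this
flood pulse — roughly ten metres of stage change at the Manaus gauge —
structures everything in the floodplain: habitat area, food supply, fish
reproduction and mortality. When the hydrological regime changes abruptly
(after an extreme drought, say), the fish assemblage of a floodplain lake
may change abruptly with it. `floodshift` implements a complete analytical
chain to ask, from daily stage records and standardised catch records,
three questions:

1. did the hydrology shift, and when;
2. did the assemblage shift, and when, along which taxonomic or
   functional axes;
3. do the two shifts share the same response shape and timing — the
   signature of an extrinsically (environmentally) driven regime shift —
   or not.

## Flood-pulse cycles and hydrological metrics

A day of the pulse belongs to one of four seasons defined by two stage
thresholds (defaults 20 m and 26 m, the conventional values for the Negro
River at Manaus): *dry* strictly below the low threshold, *flood* strictly
above the high one, and in the closed band between them *rising* or
*receding* by the direction of stage change. The band is split by
direction, so no level is unlabelled; a flat day inherits the previous
day's direction, and the first day of a series takes the sign of the next
change. A *cycle* runs from one upward crossing of the low threshold to
the day before the next, so each cycle holds one rising limb, one peak,
one receding limb and the dry season that follows. Because daily gauge
noise can jitter around the threshold, a crossing only opens a new cycle
after the stage has receded at least 0.5 m below the threshold
(`hysteresis_m`); on a 10 m pulse this is physically negligible but it
prevents one pulse from being split in two.

Seven metrics describe each cycle: amplitude, minimum and maximum stage,
and the day counts of the four seasons. Cycles missing more than a
configurable fraction of days (default 5%) are flagged unusable and carry
missing values rather than biased metrics. The metric columns are
z-scored across cycles before ordination.

## Assemblage structure

Catches are converted to CPUE (individuals per m² of gillnet per cycle),
the standard guard against unequal sampling effort between cycles. Species
are kept as *common* when their CPUE exceeds 0.01 individuals/m² in at
least one cycle; the maximum-over-cycles rule is the most inclusive of the
plausible aggregation rules and is configurable. Three views of structure
are computed:

* **taxonomic** — square-root transform, Bray–Curtis dissimilarity,
  principal coordinates (classical scaling). Negative eigenvalues are
  reported but not corrected; their magnitude share is typically a few
  percent and no downstream quantity uses them.
* **life-history** — species CPUE aggregated into the five strategy
  groups (equilibrium-small/large, intermediate-small,
  periodic-large/small), Hellinger transform, centred PCA.
* **trophic** — the same with four consumer levels (1 herbivores and
  detritivores, 1.5 omnivores, 2 invertivores and planktivores, 3
  piscivores).

Axis retention uses the broken-stick rule, with the scree elbow available
as a secondary check; when they disagree the broken stick wins, since the
elbow heuristic has no null model behind it.

Strategy labels can be supplied by the user (the canonical path — such
groupings are partly expert judgement) or suggested from the five
life-history traits. The suggestion works on the two gradients that define
the strategy triangle rather than on raw PCA axes, whose rotation depends
on species composition: the fecundity-versus-parental-care contrast
(z-scores of log fecundity minus care score) and body size (z of log
maximum SL). Ward clustering splits the species into five groups on that
plane; ordered along the fecundity–care contrast they are named
equilibrium, equilibrium, intermediate, periodic, periodic, and within
each pair the group whose median SL exceeds `sl_cut_mm` (default 250 mm)
is the large form. Trophic levels are assigned from volumetric diet
proportions with a 0.6 dominance threshold (configurable; the level
definitions are categorical in origin and name no cutoff).

The before/after effect of a disturbance on group abundance is tested by a
repeated-measures ANOVA with cycles as subjects, period (before/after) as
the between-subject factor and functional group as the within-subject
factor; the period-by-group interaction is the quantity of interest and
per-group Welch contrasts accompany it. Degrees of freedom follow this
explicit design.

## STARS: sequential t-test regime-shift detection

The detector is a one-pass online algorithm. The scale of a detectable
shift comes from the whole series: `sigma_l^2` is the average sample
variance of all `l`-point windows, and
`diff = t_crit * sqrt(2 sigma_l^2 / l)` with `t_crit` the two-sided
Student critical value at the chosen significance on `2l - 2` degrees of
freedom. The first `l` points seed the current regime; each later point
deviating from the current regime mean (over the most recent
`min(l, regime length)` points) by more than `diff` becomes a candidate,
and the Regime Shift Index accumulates its normalised exceedances over the
following up-to-`l` points. A negative partial sum kills the candidate —
this is what makes a lone outlier harmless — while a window that stays
positive confirms the shift, which then starts a new regime. There is no
retroactive adjustment; the pass is deterministic.

Two design choices deserve note. First, a window truncated by the series
end may still confirm, but only when it covers at least half the cut-off
length (`min_support`, configurable). Without this guard the final two or
three points of a series — whose confirmation windows hold only a handful
of values — generate abundant spurious shifts in pure noise (about 30% of
white-noise series of length 30 at significance 0.01; with the guard,
2–3%), while genuinely recent shifts with several supporting years are
still found. Second, prewhitening (removing lag-1 autocorrelation with an
OLS-estimated coefficient, first value scaled by `1 - alpha` so constants
stay constant) is available and recommended for stochastic series, but it
is not applied by default inside `stars()`: on a series whose
autocorrelation is dominated by a large deterministic step, the OLS
estimate of `alpha` is inflated by the regime contrast itself and the
filter largely removes the very signal being sought — a known caveat of
the method.

Missing cycles are simply absent points; windows count available points,
and confirmations whose window spans a label gap are flagged.

## Response-function models and selection

Seven mean shapes describe how a series moves through a (fixed) change
point `tau`: constant (`null`), `linear`, abrupt level change
(`step_mean`), two free linear segments (`linear_linear`), trend then
plateau (`linear_stable`), plateau then trend (`stable_linear`), and a
logistic transition (`sigmoid`, centre and slope free, slope bounded below
at 0.1 year to keep it distinct from a pure step). Segments are allowed to
be discontinuous at `tau`; continuity is an assumption the data need not
grant. `tau` comes from STARS and is not an estimated parameter; a
`free_tau` option profiles it over interior years for sensitivity checks.

Fitting is Gaussian maximum likelihood. Linear-in-parameter families are
solved in closed form by (generalised) least squares; the sigmoid profiles
its centre and slope by bounded multi-start optimisation (five centres
spread over the series) with its linear parameters solved in closed form
at each step. Three error structures are available: independent, AR(1)
(correlation `phi^|i-j|`, `phi` profiled on a grid and polished), and
AR(1) with a separate variance on each side of `tau`. The AR(1) likelihood
is evaluated in O(n) through the closed-form tridiagonal inverse of the
correlation matrix; a dense multivariate-normal evaluation is used as an
independent oracle in the tests. An exact interpolation (residuals
numerically zero) leaves nothing for variance or correlation parameters to
fit; all exact fits receive one common capped log-likelihood so that they
dominate every inexact fit and are ranked among themselves purely by
parameter count.

Models are ranked by AICc with `k` counting every estimated quantity —
mean parameters, each variance, and `phi` when fitted — uniformly across
families. Selection applies the standard parsimony convention for
effectively equivalent models: among all fits within 2 AICc units of the
minimum, the one with fewest parameters is selected. The families are
heavily nested (a segment with zero slope is a step; two matching segments
are a line), so the strict AICc minimum lands on a richer family whose
extra parameter chases noise in roughly 10–15% of cases per nested
competitor; the parsimony band restores the simpler shape unless the
richer one earns its keep. `rule = "min"` gives the strict minimum, and
the comparison table always reports ΔAICc relative to the minimum.

If the best model's residuals exceed the ±1.96/√n lag-1 autocorrelation
band, every family is refitted with AR(1) errors and re-ranked — the
two-pass treatment of temporally correlated residuals.

## Missing-cycle sweep

The robustness check for a single missing cycle imputes every value from
the observed minimum to the observed maximum in steps of 0.001 (endpoints
inclusive, final step truncated at the maximum), reruns the full selection
at each value, and reports each family's winning share. Ties within 1e-9
AICc are counted fractionally so shares always sum to one.

## Driver inference

A biological shift is called *extrinsic* when the environmental and
biological series show similar response functions and coincident shift
timing (within one cycle — two adjacent labels describe the same event
when a survey gap separates them); otherwise the report reads "internal or
unmeasured driver", a dichotomy that deliberately does not distinguish
internal dynamics from unmeasured external forcing. Similarity is judged
at the response-type level by default: all segmented and sigmoid families
describe an abrupt transition and count as one "shift" type, against
"trend" (linear) and "none" (null). Requiring identical family names
instead (`family_match = "exact"`) makes concordance hostage to the AICc
churn among nested segmented fits described above: two series that both
stepped at the same cycle would be called discordant whenever one side's
selection lands on a neighbouring segmented shape, which happens in a
substantial minority of draws even at strong signal-to-noise. Both the
exact and the type comparison are reported.

## The synthetic generators

The generators exist so that every stage of the pipeline can be exercised
against known truth without any field data.

`gen_hydrograph()` builds a quasi-sinusoidal annual pulse between a
year-specific minimum and maximum plus daily Gaussian noise (0.05 m).
Defaults emulate the Negro River at Manaus: minima near 18 m, amplitudes
near 10 m, so every pulse crosses both season thresholds. Interannual
variability matters: minima and amplitudes are jittered between years
(0.3 m and 0.5 m sd), so the default regime change (+2 m amplitude,
−1.5 m minimum) is an abrupt contrast of roughly four interannual
standard deviations rather than a caricature. The new regime takes effect
with the pulse of the change year; year-start minima follow one year
later, so each cycle sits entirely in one regime. Because the rising limb
of the hand-over cycle still starts from the old minimum, a single cycle
carries intermediate day-count metrics — a regime hand-over is not
instantaneous in every metric, and that is true of real hydrographs too.

`gen_community()` draws per-species Poisson counts with expected CPUE =
baseline × group response × shared lognormal group-year effect (AR(1) on
the log scale), so CPUE re-estimation is exactly the inverse of
generation in expectation. The default composition mirrors a surveyed
Amazon floodplain assemblage: 97 common species in the five strategies
(12, 3, 18, 29, 35) plus 99 rare species seeded below the common-CPUE
threshold, trophic levels spread 26:21:26:24. Trait and diet tables come
from strategy and trophic archetypes with multiplicative lognormal
within-cluster noise.

What the generators do **not** emulate: observation error in effort,
species-specific catchability, seasonal (within-cycle) dynamics,
immigration pulses, or the heavy right tail of real abundance
distributions. Green tests therefore demonstrate that the machinery
recovers known structure under a fair stochastic model of the study
design, not that any particular field dataset will behave as cleanly.

## Numerical choices and problem sizes

* PCA axis signs are fixed (largest-magnitude loading positive) so runs
  are reproducible across platforms; PCoA axis signs likewise from scores.
* Constant columns are dropped (with a warning) before a scaled PCA;
  zero-variance metric columns z-score to zero with a warning.
* All-zero rows map to all-zero rows in the Hellinger transform, and a
  pair of all-zero profiles has Bray–Curtis distance 0 (identical
  emptiness), both with warnings.
* AR(1) estimates are clamped to (−0.99, 0.99); the sigmoid slope is
  bounded below at 0.1 year; `phi` is profiled on a 0.15-spaced grid then
  polished by golden-section search.
* The test suite and the acceptance script use 200 replicates for each
  operating-characteristic experiment (detection, false positives, family
  recovery), 50 seeds for the end-to-end reproduction on a 30-cycle
  hydrograph, and series of length 30 for the recovery studies — sizes at
  which the Monte-Carlo standard error of a proportion is under 0.04.

## Known limitations

* STARS here detects mean shifts only; variance- and correlation-shift
  variants exist in the literature but are not used by this pipeline.
* Some response shapes are intrinsically hard to tell apart at realistic
  signal-to-noise and series length. In particular, a continuous
  decline-then-plateau (`linear_stable`) with a four-standard-deviation
  total contrast over thirty points is mistaken for a plain linear trend
  or a smooth sigmoid in roughly a quarter of simulated draws — not an
  estimation defect but a statement about the data: several shapes
  describe such a trajectory almost equally well. Interpretations that
  hinge on the distinction between neighbouring segmented shapes should
  lean on the missing-value sweep and on `free_tau` sensitivity checks
  rather than on a single AICc ranking.
* The AR(1) correlation uses observation order, not calendar spacing, so
  a gap of two missing cycles is treated as one step of correlation; with
  the short, nearly-complete series this pipeline targets the difference
  is immaterial, but heavily gapped series deserve a proper
  continuous-time model.
* The RM-ANOVA assumes sphericity in the within-cycle factor; with few
  groups and the interaction as the headline quantity this is the
  conventional design, but no sphericity correction is applied.
* Suggested life-history labels presume all five strategies are present;
  assemblages missing a strategy should use expert labels.
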