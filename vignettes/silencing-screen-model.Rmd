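---
title: "Modelling a pooled silencing-loss screen for long-lived mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a pooled silencing-loss screen for long-lived mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencescreen)
```

## The screen being modelled

A pooled library of barcoded yeast deletion strains carries a `URA3`
reporter at a silenced mating-type locus.  Transcriptional silencing at
that locus decays late in a mother cell's replicative life -- typically
after she has completed 70--100% of her divisions -- at which point `URA3`
turns on and 5-fluoroorotic acid (5-FOA) becomes toxic.  Growing the pool
with and without 5-FOA and comparing barcode abundances therefore enriches
for mutants that keep dividing (and keep silencing) longer than wild type.
A parallel control library carries the same reporter at a locus that stays
silent at any age, so strains that derepress the reporter for
age-*independent* reasons (chromatin, expression or uracil-pathway defects)
light up in both libraries and can be removed as false positives.

`silencescreen` provides the whole pipeline in silico: seeded library
generators with planted effects, the pooled-culture simulator, the
two-channel array readout with the classification rule (negative log2
Cy5:Cy3 ratio at both sampling days and below -2.3 at the late day), the
control filter, and the dissection/reproductive-span statistics used to
validate individual hits.

## Strain model

Each strain is described by:

* `mean_lifespan` $L$ -- mean number of daughters per mother (generations);
* `lifespan_cv` -- coefficient of variation of the per-mother lifespan.
  Per-mother lifespans are drawn from a gamma distribution with mean $L$
  and the given CV, rounded to the nearest integer.  The gamma is a
  pragmatic choice: nonnegative, right-skewed, two parameters, and a good
  description of published replicative-lifespan curves.  Published screens
  report only mean lifespans, so the default CV of 0.35 is a modelling
  choice typical of dissection data, not a measured value.
* a silencing-loss window `[loss_frac_lo, loss_frac_hi]`, default
  $[0.7, 1.0]$: a mother of lifespan $\ell$ derepresses at a division drawn
  uniformly from $\{\lceil 0.7\,\ell\rceil, \dots, \ell\}$.  The ceiling at
  the lower edge makes a 30-generation mother's earliest loss division 21,
  which is what makes the classic "$2^{21}$--$2^{30}$ daughters under
  5-FOA" envelope come out exactly.
* an optional `silencing_defect` flag: loss occurs at *any* division with
  constant probability (default 0.2 per division).  These are the planted
  false positives the control library exists to catch; 0.2 is a free
  synthetic parameter chosen to make stochastic derepression clearly
  earlier than age-dependent derepression.

## Population dynamics and the two silencing clocks

`clone_envelope()` gives the closed-form bound: an unselected clone doubles
to $2^{L}$ cells; under 5-FOA it is halted at the loss generation $g$ with
$2^{g}$ cells.

The simulator (`new_pool()`, `step_generation()`, `reseed()`,
`run_screen()`) implements two per-strain silencing clocks.

**Per-mother clock (`clock = "reset"`).**  Every cell draws its own
lifespan and loss division; each division advances the mother's age and
produces a rejuvenated, silenced, age-0 daughter; under 5-FOA a cell that
has derepressed completes no further divisions and is removed at the next
step.  Cohorts are aggregated by (age, dividing/doomed/stopped) with
age-indexed transition probabilities computed from the joint
(lifespan, loss) distribution, so a 3762-strain, 16-day run stays at desk
scale.  In the deterministic limit (CV 0, collapsed loss window) this clock
reproduces `clone_envelope()` *exactly* at the loss generation, which is
how the simulator is validated against the closed form.

**Heritable-derepression clock (`clock = "inherit"`).**  The silencing
clock counts divisions since the founding lineage: in a synchronously
doubling clone every cell's pedigree depth equals elapsed generations, so
the whole clone derepresses together at its drawn loss generation $g$,
reaches $2^{g}$ cells, and is removed by 5-FOA as a unit.  The unselected
culture doubles without constraint.  The expected per-strain abundance
under selection is then simply $2^{t}\,P(g \ge t)$.

Why two clocks?  The per-mother clock is the mechanistically literal
reading of replicative aging (daughters *are* rejuvenated).  But it cannot
produce a usable screen signal, for a quantitative reason worth recording:
in an exponentially growing, rejuvenating pool the age distribution is
geometric -- a fraction $\sim 2^{-a}$ of cells have age $a$ -- so the only
cells 5-FOA can kill (mothers past 70% of their lifespan) are an
$E[2^{-D}] \approx 10^{-4}$ sliver of the pool per generation.  The
growth-rate difference between a wild-type and a +40% lifespan strain is
then below $10^{-4}$ log2 units per generation, and no sampling schedule
can turn that into a $-2.3$ log2 separation.  The printed screen envelope
("a clone doubles to $2^{21}$--$2^{30}$ and is halted") instead describes
clone-coherent derepression -- heterochromatin decay marching with the
lineage's cumulative divisions and inherited by daughters.  The
`"inherit"` clock realises that picture, reproduces the envelope at the
population level, and yields the day-6/day-16 contrast the classifier
needs.  It is the default for the end-to-end run
(`run_config(clock = "inherit")`); the `"reset"` clock remains the default
for the low-level stepping functions and for the oracle-equivalence tests.

**Calibration of generations per day.**  The schedule's
`generations_per_day` converts culture days into divisions; it is a free
calibration constant (real pooled cultures sit mostly in saturation, so
the effective division rate is far below the rich-media maximum of ~10
doublings/day).  Under the heritable clock the late sample is informative
only if it falls at or just past the wild-type loss window.  With the
default of 3 generations/day the day-6 sample sits at 18 divisions --
before the $[21, 30]$ window of a 30-generation strain opens, so ratios
hover near zero -- and the day-16 sample at 48 divisions, past the
wild-type window but at the closing edge of a +40% strain's $[29, 42]$
window.  That is precisely the regime the published ratio projections
depict: the bulk of strains collapsed to a common depleted level, hits
retaining signal at the late day only.  At 10 generations/day both samples
would land beyond every strain's window and the selected pool would be
extinct; the simulator reports such extinction as an explicit error naming
the day.

**Reseeding.**  Serial reseeding is modelled either as an exact rescale of
all cohorts (expected mode -- it provably leaves relative abundances
untouched) or as a multinomial draw of the target size over every cohort
(stochastic mode), which adds genuine bottleneck drift and can drive small
pools extinct under selection.

## Array readout and classification

Barcode intensities are `scale * abundance * exp(eps)` with
`eps ~ N(0, (noise_sd_log2 * ln 2)^2)` per channel and barcode -- purely
multiplicative log-normal noise, the dominant behaviour of two-colour
arrays away from the detection floor.  Intensities below $10^{-6}$ of the
per-sample median are floored so extinct strains give finite ratios.  The
default `noise_sd_log2 = 0.25` per channel gives ratio noise of
$0.25\sqrt{2} \approx 0.35$ log2 units.

Dye orientation: the *unselected* culture is labelled Cy5 (numerator) and
the *selected* culture Cy3 (denominator).  This is the only assignment
under which a strain enriched by counter-selection -- a long-lived
candidate -- has a *negative* log2 Cy5:Cy3 ratio, matching the sign
convention of the published classification rule.

Ratios are median-centred per array (rank order preserved).  A strain is
classified long-lived when its ratio is strictly negative at both sampling
days and strictly below the threshold (default $-2.3$) at the late day.
The control filter flags any strain whose control-library day-16 ratio
deviates from zero by more than `control_tolerance` (default 1.0 log2
units -- no numeric criterion is published, so this is an exposed
parameter) and strips flagged strains of their classification; it can only
remove hits, never add them.

## Validation statistics

* `summarize_rls()`: mean, median (even-sized samples interpolate between
  the two central order statistics), maximum, and the survivor curve of a
  dissection dataset.
* `flank8_select()`: the eight data points flanking the 50% lifespan point,
  read as the four sorted values at-or-below the median position and the
  four above it (ties resolved by sorted index, i.e. toward the median).
  The source procedure does not define sidedness or tie handling; an
  alternative eight-nearest-by-value rule is available via
  `method = "nearest"`.
* `mann_whitney_u()`: $U$ with $U_x + U_y = n_x n_y$; the exact mode
  enumerates all $\binom{n_x+n_y}{n_x}$ group assignments (valid under
  ties), the approximation uses the tie-corrected normal with continuity
  correction; `auto` switches to exact when both groups have at most 10
  points -- which covers the eight-point procedure.  All p-values are
  two-sided; the source reports only inequalities, so sidedness is a
  package convention.
* `repro_cessation_day()`: last day with progeny followed by two
  progeny-free days; later progeny resets the rule; windows too short to
  show two empty days yield right-censoring.
* `build_repro_curve()`: day-by-day fraction of non-sterile adults still
  producing progeny, computed as a product-limit survivor so censoring
  cannot make the curve increase.  Matricide kills a still-reproducing
  mother, so matricide worms are right-censored at their death day by
  default (`matricide = "drop"` reproduces the stricter convention of
  excluding them; censoring is the less biased choice since exclusion
  discards exactly the longest reproducers).
* `logrank_test()`: the standard one-degree-of-freedom Mantel-Cox
  chi-square on cessation events with matricide and end-of-observation as
  censoring, written directly from the O--E table (and cross-checked in the
  test suite against `survival::survdiff`).

## Synthetic data: what it does and does not emulate

The generators reproduce the *structure* of the study -- a 3762-strain
library with 52 planted long-lived strains at +40% lifespan (mirroring the
published hit count and effect size), ~2% stochastic silencing defectives,
paired ±5-FOA cultures sampled at days 6 and 16, 40-mother dissection sets,
25-worm reproduction sets with sterile worms and late-onset matricide.
They do not emulate: transformation attrition of the starting collection,
probe chemistry or cross-hybridization (one TAG per strain), UPTAG/DOWNTAG
redundancy, nutrient or chronological-aging biology, brood sizes, or any
molecular mechanism behind the planted labels.  Passing tests therefore
demonstrate that the *analysis machinery* behaves correctly on data with
known truth, not that real cultures obey the model.

## Numerical choices and problem sizes

Lifespan distributions are truncated where the gamma upper tail falls
below $10^{-12}$ and renormalised; expected-count dynamics are exact within
that truncation.  Transition tables are cached per unique parameter set, so
the library collapses to a handful of strain groups and the full-scale
expected-mode run (3762 strains, 16 days, 3 generations/day, both
reporters, both conditions) completes in about a second.  The test suite
exercises stochastic modes on pools of $10^2$--$10^5$ cells, Monte-Carlo
moment checks at $10^4$--$10^5$ draws, and exact Mann-Whitney enumeration up
to $\binom{16}{8}$ splits; everything runs in well under a minute on one
CPU.  Seeds: every generator is a pure function of (parameters, seed); the
end-to-end run derives one sub-seed per stochastic stage from the base seed
and writes them to its manifest, so reruns are byte-identical.

## Known limitations

* The heritable-derepression clock is an idealisation at the opposite pole
  from full rejuvenation; real silencing inheritance is partial and noisy.
  The truth lies between the two implemented clocks, and the screen signal
  exists only toward the heritable end.
* Expected-count mode treats strains with identical parameters as
  exchangeable (their expected trajectories coincide); strain-level
  variability at the array stage comes from hybridization noise.
* The per-division defect rate, control tolerance, array noise and
  generations/day are free parameters with documented defaults, not
  measured quantities.
* A worked end-to-end example with concrete numbers is in the README; the
  acceptance script (`scripts/acceptance.R`) recomputes those quantities
  from scratch.

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_paper_screen(cfg, out_dir = "screen_run")
res$report
```
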