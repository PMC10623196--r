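---
title: "Methods: a Markov cohort cost-effectiveness model for myopia control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for myopia control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myopiacea)
```

## The decision problem

A cohort of 10-year-old children with myopia can be managed with single-vision
lenses (SVLs, the traditional approach) or with one of a dozen interventions
that slow progression: low-dose atropine (0.05%, 0.01%), defocus-modifying
spectacle designs (DIMS, HALs, BSLs, PALs), contact-lens modalities
(orthokeratology, daily-disposable, multifocal soft, rigid gas-permeable),
outdoor activity, and repeated low-level red light therapy. Each carries an
annual cost (direct care plus caretakers' lost productivity) and an annual
treatment effect: fewer diopters of spherical-equivalent (SER) progression
and fewer millimeters of axial elongation (AL) than the untreated comparator.
The question is which strategy delivers benefit at acceptable incremental
cost over a 5-year horizon, evaluated from a societal perspective in 2022
Hong Kong prices.

## Model structure and assumptions

The cohort moves through three severity states defined on the SER axis:
low (−0.50 to −2.99 D), moderate (−3.00 to −5.99 D) and high (−6 D and
beyond). Three structural assumptions shape the transition matrix:

1. **Irreversibility.** Myopia does not regress; the matrix is
   upper-triangular and the high state is absorbing.
2. **Severity-linked progression.** Each state carries a progression
   category (slow / intermediate / rapid), reflecting that progression
   accelerates with severity.
3. **Treatment slows transitions.** The untreated cohort progresses at
   0.81 D/yr (the comparator's placebo-arm estimate); a strategy with annual
   SER benefit $e$ progresses at $\max(0,\ 0.81 - e)$. The reference
   strategy itself progresses at the full untreated rate (its stored −0.81
   "effect" is the progression itself on the benefit scale, not a reduction).

The per-cycle probability of leaving a transient state is the net annual
progression divided by the state's band width (2.5 D for low, 3.0 D for
moderate), optionally scaled by a per-category multiplier and capped at 1:

$$p(\text{state} \to \text{next}) = \min\!\left(1,\ \frac{\text{rate} \times m_\text{category}}{\text{band width}}\right)$$

This rule is a package design decision: the source analysis derived its
transition probabilities from annual progression rates in supplementary
material that is not publicly available, so we use the simplest geometric
rule consistent with that description, make the multipliers configurable
(defaults 1), and serialize the rule into every run manifest so alternative
calibrations are reproducible. Band boundaries are placed at −3.00 and
−6.00 D so the bands are contiguous with widths 2.5 and 3.0 D (the printed
−2.99/−5.99 are inclusive decimal endpoints of the same bands).

The starting distribution defaults to (0.70, 0.25, 0.05) over (low,
moderate, high). This is a documented placeholder standing in for
prevalence estimates that the source analysis cites but does not print;
it is fully configurable and every analysis function takes it from the
`model_spec`.

## Costs, effects and accrual

- **Cost accrual.** Costs accrue at 6 annual events (cycles 0–5 inclusive
  of the 5-year horizon): annual cost plus the expected adverse-event cost,
  each discounted at 3%/yr via $(1+r)^{-t}$. A lens-replacement surcharge
  (spectacle and contact-lens modalities only) is charged on the expected
  fraction newly entering high myopia each cycle, since lenses must be
  re-made at that point; the baseline fixture sets the replacement
  component to 0 because its published annual totals already bundle
  replacement.
- **Effect accrual.** Effects accrue undiscounted: total benefit = annual
  benefit × 6. The choice of 6 events and no effect discounting is forced
  by internal consistency of the published base case, where every
  effectiveness value is exactly six times its annual input — impossible
  under 3% effect discounting. Costs remain discounted at 3%.
- **Sign convention.** SER effects are benefit-positive as printed; AL
  effects are printed raw (negative = slowed elongation) and negated once,
  in `annual_benefit()`. So atropine 0.05% (raw −0.30 mm/yr) has AL benefit
  +0.30 and the comparator (raw +0.41 mm/yr elongation) has benefit −0.41,
  giving the incremental 4.26 mm over 6 events.
- **Currency.** Everything is stored in HK$; US$ at the 7.85 peg is a
  presentation-layer conversion, rounded only in `_disp` columns.

### Model mode vs table mode

The published per-strategy total costs are not recoverable from the annual
costs under any uniform accrual convention (their total/annual ratios range
from 5.18 to 6.34), because the underlying cost-aggregation internals are
unavailable. The engine therefore has two modes: **model mode** computes
totals from the cohort engine as described above, and **table mode** takes
total and incremental costs verbatim from the packaged published-results
fixture (`hk2022_base_case()`) while still accruing effectiveness from the
annual inputs — the mode used to verify ICER arithmetic against published
figures. The fixture transcribes the source verbatim, including its
internal inconsistencies, each flagged in a `note` column (a
daily-disposable incremental-cost variant carried in `incr_cost_hkd_alt`,
an atropine 0.05% total that conflicts with its own incremental and US$
columns, and four AL effectiveness cells that are not 6× their annual
inputs).

## Incremental analysis

ICERs are reported against the single common SVL comparator, matching the
source's convention; sequential ICERs along the frontier are computed
separately (`sequential_icers()`) because they, not the common-reference
ratios, are the switch points of the optimal strategy. Dominance uses
strict inequalities: strongly dominated means some strategy is cheaper
*and* more effective (ties on effectiveness resolve by cost alone);
extended dominance is removed by the standard convex-hull sweep requiring
strictly increasing sequential ICERs. Cost-saving ICERs are reported as
negative numbers, never reclassified. `who_classify()` applies the strict
GDP thresholds (HK$382,377 and 3× that).

## Sensitivity analysis

**Deterministic.** `one_way_dsa()` pins one parameter (a strategy's annual
cost, an annual effect, or the discount rate over 0–6%) to each end of its
published sensitivity range and reruns the base case; `tornado()` does this
for every parameter and ranks by the target strategy's ICER spread.

**Probabilistic.** Costs draw from Gamma distributions moment-matched to
mean and range; effects draw from Normals. The published ranges and CIs
carry no distribution parameters, so both are interpreted as central 95%
intervals: SD = width/3.92, Gamma shape = mean²/SD², scale = SD²/mean
(which preserves the mean exactly). Effect draws are deliberately not
truncated — several CIs cross zero, and a negative drawn benefit (treatment
worse than the comparator) is meaningful. Parameters are drawn
independently across strategies and across cost/effect, as no correlation
structure is documented. For the SER outcome the drawn effect also drives
progression; for AL, progression keeps base-case SER rates since AL has no
band structure of its own. Each iteration runs the full cohort engine.
CEAC winners maximize NMB per iteration with deterministic tie-breaking
(lower cost, then label), so the curves sum to exactly 1 at every threshold.
The default grid is HK$0–78,500 in HK$3,925 steps (US$0–10,000 in $500
steps). The default 1000 iterations finish in a few seconds; the test suite
uses 10,000 draws for moment-recovery checks and 10,000 simulated
individuals for the engine oracle.

## What the synthetic generator does and does not emulate

`generate_strategy_set()` reproduces the *statistical shape* of the baseline
table: Gamma-style cost ranges in the thousands of HK$, Normal effect CIs of
a fraction of a diopter, a reference strategy whose "effect" is its own
progression, and optionally planted structure (a strictly dominated pair, or
a frontier chain with increasing sequential ICERs) that downstream analyses
must recover exactly. It does not emulate real-data features such as
correlated costs and effects, age-dependent progression, treatment
discontinuation or rebound after stopping, or heterogeneous adherence — so
green tests certify the arithmetic and the recovery of planted structure,
not the clinical realism of any particular parameter set.

## Numerical choices and degenerate inputs

- Row sums of transition matrices are enforced to 1 within 1e−12; occupancy
  conservation is asserted at 1e−9 in tests.
- Zero progression yields the identity matrix; absurd rates cap transition
  probabilities at 1; negative net progression is floored at 0.
- Degenerate cost ranges or zero-width CIs collapse to point masses; a PSA
  with all-fixed distributions reproduces the base case exactly, and its
  CEAC is a step function switching at the frontier's sequential ICERs.
- Zero incremental effectiveness makes the ICER undefined (`NA`), and such
  ties are resolved on cost alone.
- Hull sweeps treat collinear points as extended-dominated (sequential
  ICERs must strictly increase), so measure-zero ties resolve
  deterministically.

## Known limitations

The transition rule and start distribution are documented stand-ins for
unavailable internals, so model-mode totals (e.g. SVLs HK$32,853) differ
from the published totals (HK$34,320), and the model-mode PSA places the
outdoor-to-atropine crossover at a lower willingness-to-pay than the
published analysis; table mode exists precisely to separate verifiable ICER
arithmetic from these unverifiable internals. The model has no pathologic
myopia state, no quality-of-life weighting, no rebound after treatment
cessation, and no age dependence of progression. Costs are Hong Kong 2022
charges and do not generalize to other settings without a new parameter
file.
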