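---
title: "Methods: cost-utility modelling from reconstructed survival curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility modelling from reconstructed survival curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(survcua)
```

## The decision problem

The package evaluates whether a new, expensive oncology treatment (here a
Trop-2 antibody–drug conjugate for previously treated metastatic
triple-negative breast cancer) is worth its price relative to single-agent
chemotherapy, from a healthcare-system perspective. The published evidence
is two pairs of Kaplan–Meier curves (progression-free and overall survival,
one pair per arm) with number-at-risk tables; patient-level data are not
available. The analysis chain is therefore: reconstruct pseudo
individual-patient data from the curves, extrapolate survival over a
10-year horizon, simulate a three-state cohort, attach discounted costs and
utilities, and interrogate the result with sensitivity, scenario and
price-threshold analyses.

## Pseudo-IPD reconstruction

`reconstruct_ipd()` implements the iterative interval-allocation scheme for
inverting a digitized product-limit curve given the at-risk table. Within
each inter-risk-time interval the algorithm guesses the number of censored
subjects, spreads their censoring times uniformly across the interval,
derives integer event counts at each curve coordinate so the running
product-limit estimate tracks the digitized values, and iterates the
censoring count until the implied number at risk at the next risk time
matches the table. Conventions:

* A curve lacking an explicit (0, 1) anchor has one prepended, matching the
  product-limit convention; digitization jitter that raises survival by at
  most 1e-6 is flattened, larger rises are rejected with the row index.
* Ties between an event time and a risk-table time keep the subject in the
  risk set at that time (the standard risk-set definition: at risk means
  observed time ≥ t), so the event is allocated to the following interval.
* Censoring times are reported at interval midpoints; subjects outliving
  the last coordinate are censored there.
* When an arm-level event total is supplied, censoring in the final
  interval is rebalanced until the reconstructed event count matches it;
  when it is not, the counts implied by the curve drops are used unchanged,
  since arm-level totals are not always published. Both modes are exposed.
* If the table demands more subjects at risk than the curve drops permit
  (shortfall beyond the integer-rounding slack of 2), reconstruction is
  infeasible and errors rather than silently adjusting.

The fidelity criterion used throughout the tests is a maximum absolute
survival deviation of 0.02 between the input curve and the KM refit of the
reconstruction, with implied at-risk counts within ±2 of the table, for
arms of 100+ subjects. These thresholds are the package's own choice,
consistent with the accuracy this class of algorithms reports on published
oncology curves; the reconstruction literature fixes no single criterion.

## Survival extrapolation

`fit_survival()` fits the seven standard parametric families by maximum
likelihood (via `flexsurv`), and `fit_fracpoly()` fits fractional
polynomials of order 1 and 2. The fractional polynomials act on the
log-hazard scale,

$$\log h(t) = \beta_0 + \beta_1\, g_{p_1}(t)\; [+\; \beta_2\, g_{p_2}(t)],$$

with $g_p(t) = t^p$ for $p \ne 0$, $g_0(t) = \ln t$, and $t^{p}\ln t$ for a
repeated power — the dominant convention in survival-extrapolation
practice; the model class itself does not fix the scale. The powers are
searched over the standard grid $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$
(unordered pairs with repeats for order 2) and the grid-best model by AIC
is returned.

Numerical choices:

* Survival for the fractional polynomials has no closed form, so
  $S(t) = \exp(-H(t))$ with $H$ computed by trapezoid quadrature on a fixed
  one-day grid. The first day is subdivided geometrically down to
  $10^{-3}$ of a day because the log/power bases are singular at the
  origin; mass below that point is ignored (it is $O(10^{-5})$ of a day's
  hazard). A refinement test pins the quadrature error below 1e-4 in
  survival units against a 10× finer grid.
* Coefficients are optimized by Nelder–Mead polished with BFGS, from a
  method-of-moments-style start ($\beta_0 = \log(\text{events}/\text{person-time})$,
  slopes 0) plus deterministically jittered restarts (two per grid
  candidate, five for the selected powers). A failed family returns a
  `cua_fitfail` object carrying the diagnostics — never a silent fallback.
* `k` counts regression coefficients only; the chosen powers are reported
  but not counted as free parameters in AIC/BIC. This matches common
  practice for fractional polynomials; counting them would add a constant
  +2/+4 to every candidate within an order and not change the within-order
  ranking, but it would penalize the class against the standard families —
  a judgment call, made once and documented here.
* `select_model()` ranks ascending by AIC, reporting BIC alongside; exact
  ties go to the family with fewer parameters, then lexicographic name.
  There is no automated analogue of visual inspection; the ranking object
  and `plot()` method support it interactively.

Subgroups for which only hazard ratios are published are handled under
proportional hazards: `adjust_by_hazard_ratio()` returns
$S_{\mathrm{sub}}(t) = S(t)^{\mathrm{HR}}$. The default subgroup HRs in the
`subgroup` preset are synthetic placeholders — real subgroup HRs are study
inputs, not package constants.

## Cohort engine

The model has three states (progression-free, progressed, dead), 28-day
cycles and a 10-year horizon, giving `floor(10 × 365.25 / 28) = 130`
cycles; time is internally in months of 365.25/12 days with exact day
arithmetic at cycle boundaries. Transition probabilities come from the
fitted curves as described in the README. Two structural points deserve
emphasis:

* **Death split (calibration).** The conditional death probability derived
  from OS applies identically in both alive states, and progression is the
  excess of PFS attrition over death, floored at zero. This guarantees the
  cohort's alive fraction equals the fitted OS at every boundary, and makes
  the Markov trace equal the partitioned-survival trace cycle-by-cycle
  whenever the curves do not cross (machine precision; tested at 1e-9).
  The published analyses this package generalizes report materially
  different Markov and PSM results on identical curves, implying their
  transition derivation was not OS-calibrated; since that derivation is
  never specified in print, the package takes calibration as the default
  (it is the only choice whose behaviour can be verified exactly) and
  provides `pd_excess_mortality`, a multiplier on the progressed-state
  death hazard, to deliberately break the tie when structural divergence
  is the object of study.
* **Clamping.** Fitted PFS above fitted OS is clamped to OS and counted;
  cycles where the progression floor binds (PFS attrition slower than
  death) are flagged, because calibration and structural equivalence are
  exact only without them. Once OS reaches zero the remaining cycles are
  absorbing.

No half-cycle correction is applied by default — payoffs accrue on
start-of-cycle occupancy, which keeps the calibration invariants exact; a
trapezoid (life-table) correction is available behind `half_cycle = TRUE`.

## Economics

All costs are USD, per the reference input table: per-cycle drug
acquisition (3,635.34 experimental / 402.23 control), post-progression
therapy (585.62 / 1,332.77) mixed with best supportive care (807.68) by the
post-progression treatment probability (0.51 / 0.71), monitoring unit
costs, seven grade ≥3 adverse events with risks, management costs and
disutilities, end-of-life care (2,330.28), utilities 0.85 (PFS) and 0.52
(PD), and a 4.5% annual discount rate applied continuously at cycle-start
times, $(1+r)^{-t/365.25}$.

Accrual conventions, chosen where the source material is silent:

* Drug cost accrues while progression-free (treatment to progression); the
  price factor and the assistance-program pattern apply to the experimental
  drug only. The assistance program is a repeating paid, paid, free, free
  pattern from cycle 1 — the only reading jointly consistent with the
  published base-case, assistance-program and negotiated-price tables.
* Adverse events occur once, in cycle 1, as a risk-weighted cost and a
  one-cycle risk-weighted utility decrement.
* Monitoring is a routine blood test every cycle, imaging every 2 cycles
  and a bone scan every 3 cycles, in both alive states; unit costs are
  published but frequencies are not, so the schedule is configurable.
* Post-progression treatment and BSC costs are treated as per-cycle
  amounts while in PD ("per patient" labels in published tables are
  ambiguous); a one-off-at-entry mode (`posttx_mode = "at_entry"`) is
  provided.
* Reported tables round half-up to 2 decimals; internal arithmetic is full
  precision. The ICER identity ICER × ΔE = ΔC is maintained to 1e-6.

The negotiated-price scenario multiplies drug acquisition cost by
1800/9399 (the post-negotiation vial price over the list vial price),
leaving every other parameter unchanged. Dominance labels replace the ICER
whenever the incremental QALYs are non-positive or the increments have
opposite beneficial signs.

## Uncertainty and pricing

* **DSA.** Each parameter in the reference range table is set to its lower
  and upper bound (95% CIs where published, otherwise ±25%; discount rate
  3–5%; utility bounds clamped to [0, 1]) with the rest at base; entries
  are sorted by tornado width. Evaluation failures are flagged, not
  dropped.
* **PSA.** Gamma for costs, beta for probabilities and utilities, moment
  matched with mean = base and sd = (high − low)/3.92 regardless of how
  the bounds were derived (the source specifies the distributions but no
  sd rule). Beta moments that are infeasible shrink the sd to 95% of the
  feasible bound with a recorded warning; draws are guarded against float
  underflow at the support endpoints. Survival-curve parameters are held
  fixed — the PSA covers the economic parameters only, matching the scope
  of the published input table; this understates total decision
  uncertainty and is a documented limitation.
* **CEAC.** The probability of cost-effectiveness at WTP λ is the fraction
  of draws with positive net monetary benefit λΔE − ΔC; ties count as not
  cost-effective.
* **Threshold.** Bisection on the price factor to |ICER(f*) − WTP| ≤ 0.01
  USD/QALY, with an f-interval backstop of 1e-12 so the ICER tolerance is
  the binding criterion; infeasibility (ICER above WTP even as f → 0) and
  already-cost-effective-at-list are returned as flags, not errors.

## The synthetic trial generator

`synthetic_trial_default()` emulates the evidence shape of a two-arm
registration trial in this indication: 132 vs 131 subjects, Weibull event
times with the experimental arm at longer medians (PFS 5.7 vs 2.8 months,
OS 13.6 vs 9.4 months — within the few-months range typical of
later-line disease), exponential dropout at 1%/month, administrative
cutoff at 24 months, and a number-at-risk grid every 2 months. PFS and OS
share the Weibull shape within an arm so the latent curves never cross.
These defaults are fixed once; they are the study conditions under which
every end-to-end property is tested.

What the generator does *not* emulate: per-subject correlation between
progression and death times (endpoints are simulated marginally),
non-proportional or delayed treatment effects, cure fractions, and
digitization error beyond the product-limit discretization itself.
Passing round-trip and recovery tests therefore demonstrate correctness of
the machinery under clean censoring mechanisms, not robustness to
real-world digitization noise.

## Problem sizes and tolerances used in the tests

Parameter recovery uses n = 500 per family with ~20% random censoring and
a 15% relative-error criterion (absolute for parameters whose true value
is 0, e.g. the generalized-gamma shape at its log-normal special case);
the reconstruction round trip uses n = 150 with the 0.02 / ±2 fidelity
bounds; KM consistency is checked against a brute-force product-limit
oracle on 50 random datasets; the PSA contracts run at 1,000 iterations.
Trace conservation, OS calibration and Markov–PSM equivalence are asserted
at 1e-9 over all 130 cycles.

## Known limitations

* Pseudo-IPD reconstruction is approximate by nature; event counts are
  integers and censoring within intervals is assumed uniform.
* The headline totals of any specific published analysis depend on that
  trial's digitized coordinates, which are not shipped here; the package
  reproduces published incremental arithmetic exactly and the full
  pipeline on synthetic stand-ins.
* Background all-cause mortality is not added to the extrapolated OS
  hazard; over a 10-year horizon in a population with median OS under
  15 months this is negligible, but it matters for longer horizons.
* No microsimulation, tunnel states, correlated PSA draws, or value of
  information.
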