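---
title: "Model and methods: genotype-specific gynecologic cancer prevention in Lynch syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decision problem

Women carrying a pathogenic variant in one of the mismatch-repair genes
*MLH1*, *MSH2*, *MSH6* or *PMS2* (Lynch syndrome) face substantially
elevated lifetime risks of endometrial cancer (EC; 11.8% to 48.9% by age
75, depending on the gene) and ovarian cancer (OC; 3.0% to 17.4%).
Management options span annual surveillance (pelvic examination with
endometrial biopsy for EC; transvaginal ultrasound with CA-125 for OC),
risk-reducing hysterectomy with bilateral salpingo-oophorectomy (hyst-BSO)
at various ages, and a two-stage approach — hysterectomy with bilateral
salpingectomy (hyst-BS) at 40 with oophorectomy deferred to the natural
menopause age of 50 — that trades residual ovarian-cancer risk against a
decade of preserved ovarian function.  `lynchcea` implements an
annual-cycle Markov cohort model that evaluates twelve such strategies per
gene on discounted quality-adjusted life-years (QALYs) and lifetime
direct medical costs (2020 USD, health-system perspective), selecting the
optimal strategy as the most effective one whose incremental
cost-effectiveness ratio (ICER) stays below a willingness-to-pay of
$100,000 per QALY.

## States and within-cycle mechanics

The cohort enters healthy at age 25 and cycles annually to age 75.
States: healthy (uterus and ovaries intact); post-hyst-BSO, split by
whether the ovaries were removed before 50 (the early-menopause subgroup
carries the premenopausal utility weight until 50 and, in sensitivity
analyses, an all-cause mortality multiplier through the end of the model);
post-hyst-BS with ovaries retained; two transient undetected-cancer
states; six stage-specific diagnosed cancer states (local / regional /
distant for each site); and four absorbing death states (EC, OC,
surgical, other).

Within a cycle events resolve in a fixed order: (1) all-cause death from
the life table, (2) scheduled surgery (mortality 0.17%, complication
probability 3%), (3) cancer onset, (4) detection, (5) stage-specific
cancer death for already-diagnosed (prevalent) cancers.  Surgery and
onset do not co-occur in a cycle: a cycle that begins with a scheduled
operation contributes no onset that year.  The alternative (onset of
retained-organ cancers after surgery within the same cycle) changes the
two-stage arm's OC incidence by roughly +0.4 pp and was not adopted; the
adopted order errs by about −0.15 pp against the reference results, and
order effects at annual granularity are second-order throughout.

Without surveillance, onset leads directly to a diagnosed state with the
no-intervention stage distribution.  Under surveillance (annual, 100%
adherence, from its start age until the first positive result or
surgery), a true positive is diagnosed with the more favorable
surveillance stage distribution; a false negative moves to an undetected
state and is diagnosed the following cycle with the no-intervention
distribution (the screen-missed cancer presents symptomatically); a
false positive — probability one minus the product of the two test
specificities among the cancer-free — triggers an immediate hyst-BSO with
full surgical cost, mortality, complication risk and utility decrement.
After hyst-BSO both cancer risks are zero; after hyst-BS the EC risk is
zero and the OC risk persists, multiplied by the salpingectomy risk
ratio (1.0 in the base case).  One diagnosed cancer precludes the other.
Cancer states are absorbing until death; the annual cancer-specific death
probability is `1 − RS^(1/5)` from the stage's five-year relative
survival, applied on top of all-cause mortality.

## Calibration

Published penetrance estimates give cumulative incidences; the engine
needs annual onset probabilities inside a competing-risk model.  Each
site's cumulative-incidence curve is specified by anchors `(age, CI)`;
piecewise-constant conditional probabilities
`p = 1 − ((1−CI_1)/(1−CI_0))^(1/(a_1−a_0))` seed the schedule, and a
deterministic fixed-point iteration rescales each inter-anchor interval
by the ratio of target to modeled incidence gain until every anchor is
met to 1e-4 absolute (natural-history cohort, both sites competing,
alternated until jointly converged).  This replaces the visual-fit
calibration of the reference analysis with a reproducible procedure.

The bundled anchor file is a **synthetic reconstruction**: the original
age-specific incidence tables live in an unavailable supplement, and a
single age-75 anchor with flat onset from 30 is demonstrably wrong (it
would put ~14% of MSH2 carriers' EC before age 40, whereas the published
arm outcomes imply 2.26%).  Interior anchors are therefore back-derived
from the published strategy-arm incidences — in an arm with surgery at
age X and no surveillance, cumulative diagnosed incidence equals the
natural-history cumulative incidence at X — with the age-75 totals from
the published risk table.  Consequences: natural-history incidence is
exact at the anchor ages and interpolated by constant hazards between
them; the curve between 50 and 75 has no interior support and is flatter
than true penetrance curves, which decelerate after 60.  Users with the
supplement can supply a denser anchor file.

When the lifetime-risk parameter moves (one-way scans, PSA draws), the
stored anchors rescale on a proportional-hazards basis
(`CI' = 1 − (1−CI)^k`, `k = log(1−r_new)/log(1−r_old)`).  One-way scans
recalibrate fully; the PSA uses the same one-pass analytic rescale on the
calibrated schedules, which reproduces the new target exactly in the
absence of competing risks; at a +72% risk jump (far beyond a typical
draw) the property tests bound its pointwise error at 5% and the modeled
cumulative-incidence error at 3% relative.

## Outcome accounting

**Discounting.** Costs and QALYs discount at 3%/year from model entry
(`t = age − 25`).

**QALY accrual.** State occupancies at each age are weighted by state
utilities: healthy utility declines linearly from 1.00 at 25 to 0.82 at
75 (only the endpoints of the age-adjusted schedule are published; linear
interpolation is the simplest monotone reconstruction, and the absolute
QALY level inherits its uncertainty); post-surgical utilities
(premenopausal hyst-BSO 0.90 until age 50, postmenopausal 1.00, hyst-BS
1.00) act as multipliers on the age-adjusted healthy utility — treating
0.90 as an absolute value would place a 45-year-old after surgery
*above* an intact 60-year-old; diagnosed-cancer utilities (EC 0.83/0.83/
0.59, OC 0.75/0.75/0.59 by stage) are absolute state values, matching the
magnitudes of whole-state utilities in their source (the published table
lists them under a "decrement" header but they are plainly positive
utilities).  The default accrual convention is **cycle-end membership**:
each cycle contributes the utility of the state occupied at its end,
discounted at the cycle-end time.  A trapezoidal variant (half weight on
the first and last occupancy rows) is available; it values the same
trajectory about `0.5·u(25) − 0.5·u(75)·disc(50) ≈ 0.45` QALYs higher.
The cycle-end default was chosen because it reproduces all ten published
QALY cells within ±0.05 while the trapezoid misses all of them by
+0.4 to +0.5; both are recognized half-cycle conventions and the source
names the correction without the variant.  One-off decrements apply at
the event cycle: −0.0008 per screen, and per operation −0.025
(complication-free) or −0.0425 (with complication), weighted by the
complication flow.

**Costs.** Per cycle, discounted: surveillance encounters ($1,920 for
the first round, $1,376 thereafter, per woman screened), surgery
($8,922 hysterectomy with or without BSO — scheduled or false-positive
triggered; $6,155 stage-two oophorectomy), complications ($8,276 per
event), and phase-of-care cancer costs — stage-specific initial cost in
the diagnosis cycle, continuing annual cost while alive in a cancer
state, and end-of-life cost replacing the continuing cost in the cycle
of cancer-specific death (deaths from other causes do not trigger it).

**Life-years** are undiscounted and half-cycle corrected
(trapezoidal over the 51 occupancy rows).

## Cost-effectiveness ranking

Strategies sort by discounted cost (ties broken by higher QALYs, then
stable input order).  Strictly dominated options (at least as costly, no
more effective) are removed first; extendedly dominated options (whose
ICER against the next cheaper frontier member exceeds that of a more
effective strategy) are removed iteratively, so frontier ICERs are
non-decreasing.  The optimal strategy at a willingness-to-pay threshold
is the most effective frontier member whose ICER does not exceed it; the
cheapest frontier member qualifies unconditionally.

## Sensitivity analyses

**One-way / threshold.** The full strategy comparison re-runs at each
grid value of one parameter; switches in the optimum are refined by
bisection to 0.005 parameter units by default.

**PSA.** All parameters with a published sampling family are drawn
independently: beta for probabilities, gamma for costs, normal for
utilities and for parameters published with normal ranges.  Published
ranges are read as 95% intervals (SD = range/3.92, method of moments,
mean at base case); a beta made infeasible by that variance — or a mean
on the 0/1 boundary, as for the salpingectomy risk ratio — falls back to
a normal with SD = 10% of base.  Draws clamp to legal domains
(probabilities and utilities to [0,1], costs to ≥0, lifetime risks to
≤0.99) and stage-distribution triplets renormalize to sum to one.  No
correlation structure is imposed.  The oophorectomy all-cause mortality
ratio is varied only deterministically (no published distribution).
The acceptability curve reports, at each willingness-to-pay grid point,
the fraction of draws in which each strategy is optimal; draws are fully
reproducible under the specification seed.

## The synthetic world, and what a green test establishes

Three inputs of the reference analysis are not reproducible offline and
are replaced by declared stand-ins: (1) the women's national life table —
a Gompertz–Makeham fixture `qx = A + B·exp(C·age)` with `A = 0,
B = 5.5e-5, C = 0.08`, giving ~4e-4 at 25, 3e-3 at 50 and 2.2e-2 at 75
(slightly heavier late mortality than the 2016 US female table: survival
25→75 of 0.76 vs ~0.79, so life-years run ~0.3 low); a real two-column
age/qx file can be substituted; (2) the age shape of cancer risk
(synthetic anchors above); (3) the age-utility schedule (linear between
published endpoints).  Green base-case tests therefore establish that the
mechanics, accounting and ranking reproduce the reference outcomes *given
these stand-ins* — QALY cells to ±0.05, costs to ±1.6%, incidence and
mortality to ±0.15 pp, identical optimal strategies and dominance labels,
ICERs to ±11%.

They do not establish fine-margin equivalence.  Two published threshold
locations (the MSH2 hyst-BSO-40 → 35 flip at early-menopause utility
0.95, and the MSH2 oophorectomy-mortality switch at RR 1.24–1.32, found
here at ~1.17) sit inside the ±0.02-QALY band that the reconstructed
utility and risk curves cannot pin down, and the PSA optimal-strategy
fractions depend strongly on the unstated range-to-SD convention: under
the documented 95%-interval reading, the early-menopause utility SD of
0.046 alone places ~32% of MSH2 draws on the 2-stage side of the
base-case switch point, versus 12% reported.  The corresponding
acceptance tests are left failing rather than fitted, with modal
strategies all reproduced.

## Numerical choices and degenerate inputs

Calibration tolerance 1e-4 absolute per anchor, iteration caps 200 per
site and 10 joint rounds, onset probabilities clamped to [0, 0.99];
zero-risk targets yield identically zero schedules; an all-zero modeled
interval reseeds from the closed form.  Transition rows are validated to
sum to one within 1e-12 and cohort mass is conserved within 1e-9 over
the trace.  Frontier ties: cost ties break toward higher QALYs, exact
double ties keep input order.  Threshold bisection assumes one switch
per bracketing grid interval; a third optimum appearing inside a bracket
resolves to the boundary nearest the lower label.  Degenerate PSA ranges
(low = high) become point masses, and a PSA built entirely of point
masses reproduces the base case exactly.

## Known limitations

Only gynecologic outcomes are modeled (no colorectal or other
Lynch-spectrum cancers); no family-history or variant-level risk
modifiers; cancer states have no cure or remission; occult cancers found
at surgery are not modeled, so the published risk-reducing-surgery stage
distribution for OC is carried but unused by the base-case mechanics;
costs are 2020 USD from a US health-system perspective with no
inflation machinery; and the absolute QALY scale depends on the
reconstructed age-utility schedule, so cross-study QALY comparisons
should lean on differences rather than levels.
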