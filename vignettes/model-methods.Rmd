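---
title: "Decision-analytic methods behind lynchcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-analytic methods behind lynchcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchcea)
```

## The question the model answers

Lynch syndrome (LS) is an autosomal-dominant cancer-predisposition syndrome
caused by germline mutations in the DNA mismatch repair (MMR) genes *MLH1*,
*MSH2*, *MSH6* and *PMS2*. Universal screening offers a genetic work-up to
every newly diagnosed colorectal cancer (CRC) patient; when a patient is
confirmed as an LS proband, their first-degree relatives are offered
targeted testing for the family-specific mutation, and confirmed carriers
are offered biennial colonoscopic surveillance from age 20. The payer
question is whether the money spent on detecting probands and relatives is
justified by the discounted life-years the relatives gain.

`lynchcea` models this for the Taiwan setting: a registry-sized cohort of
13,534 incident CRC patients, each with four first-degree relatives, LS
prevalence of 2.3% among CRC patients and 0.227% in the population, and a
Referent comparator in which the only screening is the national biennial
fecal immunochemical test (FIT) programme at ages 50–69 with 21.4%
participation.

Four active strategies are compared with that Referent:

1. **IHC + BRAF**: immunohistochemistry for the four MMR proteins; tumours
   with MLH1 loss get BRAF V600E reflex testing (BRAF-positive indicates a
   sporadic, methylation-driven deficiency and stops the work-up);
   remaining implicated genes are sequenced.
2. **IHC**: as above without the BRAF filter.
3. **MSI**: microsatellite-instability testing; MSI-high tumours have all
   four genes sequenced.
4. **Direct sequencing** of all four genes in every accepting patient.

## Mutation spectrum (sample-size-weighted pooling)

The spectrum of causal genes among Chinese LS families is estimated by
pooling published per-study mutation counts: for gene $g$,

$$\hat p_g = \frac{\sum_{s \in S_g} x_{sg}}{\sum_{s \in S_g} n_s},$$

where $S_g$ is the set of studies that assayed gene $g$. A study that did
not assay a gene contributes to neither numerator nor denominator — an
assayed zero is evidence, a missing assay is not. The four pooled
proportions are then renormalised to sum to one under the assumption that
LS is caused solely by these genes. With the shipped study table this
yields 58% / 25% / 11% / 6% for *MLH1* / *MSH2* / *MSH6* / *PMS2*:

```{r spectrum}
mmr_study_counts() |>
  pooled_gene_proportions() |>
  normalize_proportions() |>
  round(4)
```

## The simulated population

`simulate_cohort()` draws patient LS status Bernoulli(0.023), assigns
causal genes from the spectrum, and gives each patient exactly four
relatives in the base case (a Poisson(4) count is used only inside the
probabilistic sensitivity analysis, where the relative count is an
uncertain parameter). Relatives of LS patients inherit the family mutation
with probability 1/2 (dominant inheritance); relatives of non-LS patients
are carriers at the population prevalence with genes drawn from the
spectrum. Relative ages are Normal(35, 12) truncated to [18, 80] via the
inverse CDF; the truncation bounds are a modelling choice to avoid
children and implausible elderly entrants in a cascade-testing programme.

The closed-form expectation
$n\pi m/2 + n(1-\pi)m\pi_{pop} = 742.6 \approx 743$ mutation-carrying
relatives serves as the analytic oracle for the generator and is verified
by Monte Carlo in the test suite.

What the generator does *not* emulate: pedigree structure beyond a flat
list of first-degree relatives, age/sex structure of the probands,
households shared between patients, and any correlation between a family's
uptake decisions. Tests that pass on this synthetic population therefore
validate the model arithmetic and its internal consistency, not the
external epidemiology of any real registry.

## Screening decision trees

Assay behaviour is parameterised by sensitivity (probability an affected
patient's causal gene is implicated) and specificity (per-assay, or per
sequenced gene for the panel). Two modelling choices matter:

* **False-positive IHC presents as MLH1 loss.** Sporadic MMR-deficient
  tumours are overwhelmingly MLH1-methylated, which is exactly the
  population the BRAF reflex test exists to filter out. Without this
  choice Strategy 1 would have nothing to gain from BRAF testing.
* **False-positive probands still trigger the cascade.** A non-LS patient
  whose sequencing reports a mutation (at $1-\mathrm{spec}$ per clean
  gene) is counselled and their relatives are contacted, counselled and
  tested at full cost; those relatives carry mutations only at the
  population rate. This is why sequencing-everyone detects the most
  probands and the most cost, disproportionately.

Relative-side uptake is a chain of independent Bernoulli gates: contact →
counseling (52%) → testing given counseling (95%) → surveillance adoption
given detection (79%). The targeted single-site family-mutation assay is
treated as perfect by default (its sensitivity/specificity are
configurable).

## Natural history of a carrier relative

Each carrier is propagated through annual cycles from entry age to a
lifetime horizon of age 100 with a within-cycle event order of background
death → surveillance → CRC incidence → cancer death. There is no
half-cycle correction; a survived year is credited at the year's end with
discount factor $(1+r)^{-t}$, $r = 3\%$ for both life-years and costs.

* **Incidence** follows an age-banded annual-risk curve for carriers,
  multiplied by $1 - 0.59$ under colonoscopic surveillance (from the
  surveillance start age onwards).
* **Stage at diagnosis** depends on the surveillance mode: the no-screening
  distribution (21.2/27.8/31.8/19.2% for stages 1–4), the FIT
  distribution (48.2/20.9/23.7/7.2%) during FIT-screened person-years
  (ages 50–69), or the colonoscopy distribution. The latter is constructed
  by mixing the no-screening distribution with a point mass on Stage 1,
  choosing the smallest mixing weight that raises expected five-year
  survival by 20% (`adjust_stage_distribution()`); the weight is capped at
  one when the target is unattainable.
* **Cancer mortality** uses the constant annual cause-specific probability
  $1 - s^{1/5}$ that reproduces the stage's five-year survival $s$ after
  five cycles. The hazard applies for ten years after diagnosis — the
  five-year calibration is simply extended through years 6–10 — after
  which the person is cured. Cancer and background mortality act as
  independent competing hazards.
* **Second primaries** occur at 1.6%/year from the cycle after the first
  diagnosis, in both the ill and cured states, up to a lifetime maximum of
  two CRC episodes. The second cancer starts a fresh stage/mortality clock
  (replacing, not stacking with, the first cancer's hazard) and its stage
  is drawn from the colonoscopy distribution for everyone, on the grounds
  that CRC survivors receive colonoscopic follow-up as standard care.
* **Costs.** Lifetime treatment cost is charged as a single discounted
  lump sum at diagnosis (stage-specific; the second episode is scaled by a
  stage-specific multiplier). Surveillance costs accrue only in the well
  state: colonoscopy every two years (plus the complication risk charged
  as its expected cost per procedure), or FIT every two years in ages
  50–69 with the follow-up colonoscopy after a positive FIT charged at the
  FIT-positive rate. Charging expectations rather than drawing
  complication events leaves every mean unchanged and removes nuisance
  variance from strategy comparisons.

Undetected carriers follow Referent behaviour: FIT participation is a
per-person trait drawn once (21.4%), not a per-round coin flip. Detected
carriers who decline colonoscopy (21%) are assumed to follow the FIT
programme with certainty.

Two engines share this model. `expected_outcomes()` propagates the full
state-probability vector (well; ill by episode × stage × years since
diagnosis; cured; dead) and is deterministic; the mass is checked to be
conserved to 1e-10 per cycle. `simulate_relatives()` is the
individual-level microsimulation; it consumes a fixed block of uniforms
per person per cycle regardless of state, so evaluations of different
strategies under the same seed are driven by identical random streams.
This common-random-number coupling means an undetected carrier contributes
*exactly* zero to a strategy-vs-Referent difference, which is what makes
per-carrier incremental life-years estimable at realistic cohort sizes.
The test suite requires the two engines to agree within three standard
errors at $n = 10^4$–$2\times10^4$ replicates.

## Economics

Three payer cost categories are tracked per strategy: detecting probands
(offering/counseling plus assay costs), detecting relatives (contact,
counseling, single-site tests), and surveillance plus treatment for the
relatives. Per-carrier averages divide by **all** carrier relatives,
detected or not — the only convention under which per-carrier cost times
the carrier count reproduces the total cost, an identity the tests
enforce. ICERs are computed against the Referent and against the previous
strategy in the conventional ordering; a non-positive life-year gain
raises a dominance flag instead of a ratio. WHO willingness-to-pay
categories use GDP per capita ($21,308): strictly below one GDP per
life-year is *highly cost-effective*, between one and three times
(inclusive at both ends, per the quoted wording's strict `<` for
"highly") *cost-effective*, above three *not cost-effective*.

## Sensitivity analyses

The PSA assigns beta distributions to probabilities, gamma to costs,
lognormal to the relative risk $1-\text{risk reduction}$ (a sampled
relative risk above one maps to zero reduction), and Poisson to the
per-patient relative count. Where only low/high bounds are stated for a
parameter, distributions are moment-matched to mean = base value and
sd = (high − low)/3.92, i.e. the bounds are read as a 95% interval;
parameters without bounds default to a 20% coefficient of variation. Each
draw samples a configuration, re-validates it, simulates a fresh cohort
and evaluates all strategies with common random numbers; the
cost-effectiveness acceptability curve reports, per threshold $\lambda$,
the fraction of draws with positive net monetary benefit
$\lambda\,\Delta E - \Delta C$.

The tornado analysis perturbs one parameter at a time to its bounds,
holding the rest at base values, and recomputes the Strategy 1 ICER from
replicate-averaged per-carrier costs and life-years under common seeds
(the ICER of the averages, not an average of noisy per-replicate ratios).
Reimbursement-fee cost parameters are deliberately excluded from the
default bounds: the payer's fee schedule is treated as fixed.

## Parameter provenance and placeholders

Every rate printed in the motivating epidemiology for Taiwan is a
base-case default and is listed in `default_config()`'s documentation.
Fields whose published values live only in supplementary material are
shipped as documented placeholders and flagged in
`default_config()$provenance$placeholder`: assay operating
characteristics (IHC 0.83/0.89, MSI 0.85/0.90, sequencing 0.94 with
per-gene specificity 0.998), assay and procedure costs (colonoscopy $76;
sequencing $1,000 per gene, preserving the stated 8.5:1 sequencing:MSI
price ratio), stage-specific five-year survival (0.86/0.74/0.55/0.12),
the carrier incidence curve (age-banded annual risks accumulating to
roughly a one-in-three lifetime risk by 70), background mortality (a
Gompertz–Makeham curve shaped to an East-Asian life table), the BRAF
positivity rates (0.68 sporadic, 0.01 in LS), and the FIT positivity rate
(0.05). Base-case results that depend on these placeholders — the ICER
levels themselves — are therefore indicative, not reproductions of any
published table; the structural results (cost ordering across strategies,
accounting identities, direction and rough size of life-year gains) are
robust to them. All placeholders are overridable through a YAML/JSON file
via `load_config()`.

## Numerical choices and problem sizes

Cycle length is one year with no half-cycle correction. Ages are floored
to integers for hazard lookups. Stage draws use the inverse CDF so that
coupled streams remain comparable across stage distributions. Replicate
seeds in scripted runs are spaced widely apart to keep Mersenne–Twister
streams well separated. The shipped test suite runs the full pipeline at
reduced cohort sizes (600–6,000 patients) for speed, and at the full
13,534-patient size where a published count is at stake (the 743 expected
carriers, verified over hundreds to a thousand replicate cohorts); the
microsimulation-vs-expectation checks use 10,000–20,000 replicate
lifetimes. These sizes are the package's own verification choices and can
be scaled up freely.

## Known limitations

* Only colorectal cancer is modelled; extracolonic LS tumours
  (endometrial, ovarian, gastric) are out of scope, as is any
  quality-of-life weighting — effects are life-years, not QALYs.
* The proband's own surveillance benefit is not counted; only the
  relative side of the cascade generates life-years.
* The colonoscopy stage-shift construction (mixing toward Stage 1 to hit
  a survival-uplift target) is a documented stand-in for the original
  stage-shift derivation, which is not fully specified in the public
  record.
* Variants of uncertain significance are not modelled as a distinct
  category; they are folded into assay specificity.
* The cohort has no pedigree or household structure, and uptake gates are
  independent across relatives of one proband.
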