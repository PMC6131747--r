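---
title: "Co-calibrating delirium severity instruments: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-calibrating delirium severity instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

The DRS-R-98, the MDAS, and the CAM-S all produce a sum score for the
severity of a delirium assessment, but each on its own metric: the
instruments rate different symptom sets, with different category
definitions (0--3 for DRS-R-98 and MDAS, 0--2 for the CAM features), so
a DRS-R-98 of 15 and an MDAS of 15 do not mean the same thing.  When
the same patients are rated with all three instruments on the same
hospital days -- a *common-person* design -- and several symptom
domains are rated by more than one instrument -- *common items* -- item
response theory can place all instruments on one latent severity
metric, after which integer scores translate between instruments
through their test characteristic curves.

`delharm` implements that workflow: a graded-response-model (GRM)
engine with per-parameter constraints, Haebara characteristic-curve
linking, a four-step co-calibration pipeline, and the derived reporting
artifacts (information and reliability curves, item-person maps,
factor-score correlations, sum-score crosswalk tables).

## Measurement model

Each assessment carries a latent severity $\theta$, identified by a
standard-normal population distribution (mean 0, variance 1).  An item
with $K$ ordered categories follows the graded response model on the
*logistic* metric,

$$P(y \ge k \mid \theta) = \mathrm{logit}^{-1}(\lambda\theta - \tau_k),
\qquad k = 1, \dots, K-1,$$

with slope (loading) $\lambda$ and strictly ordered thresholds
$\tau_1 < \dots < \tau_{K-1}$.  Binary items make this the
two-parameter logistic model.  No 1.7 scaling constant is applied
anywhere; external parameter sets on a probit-type metric must be
rescaled explicitly before comparison.  The IRT location form is
$a = \lambda$, $b_k = \tau_k / \lambda$ (`fa_to_irt()`), the latent
level at which category $k$ or higher is reached with probability one
half.

Estimation is marginal maximum likelihood by EM.  The E-step evaluates
each assessment's posterior over a fixed quadrature grid (61 equally
spaced nodes on $[-6, 6]$, standard-normal weights normalized to sum to
one); the M-step maximizes each item's expected complete-data
log-likelihood by BFGS on an unconstrained reparameterization of the
thresholds (the leading threshold plus log-differences, or, around
fixed thresholds, exponential steps away from them and a stick-breaking
map between them).  Because each M-step starts from the current values,
the marginal log-likelihood is non-decreasing by construction; the test
suite asserts increments above $-10^{-8}$.  Convergence is declared
when the largest absolute parameter change falls below `tol` (default
$10^{-4}$).  Missing ratings simply drop out of an assessment's
likelihood product (missing-at-random ignorability), and an assessment
with no observed items has likelihood one and posterior equal to the
prior, so `eap_scores()` returns mean 0, SD 1 for it.

Two degenerate-data rules keep constrained refits well defined: a
boundary category that no one used gets an infinite sentinel threshold
($P = 0$ for that category) and is excluded from estimation; an item
whose observed responses all fall in one category is flagged, its slope
set to `NA`, and it is excluded from the likelihood and from scoring.

The 61-node rectangular rule is deliberate rather than adaptive: the
integrands are smooth posterior kernels that vanish at $\pm 6$, for
which equally spaced rules converge super-algebraically.  The suite
checks that the marginal log-likelihood and EAP scores match 2001-point
dense-grid integration to $10^{-6}$ and $10^{-4}$ and that moving from
49 to 101 nodes changes the log-likelihood by less than $10^{-6}$.

## The four-step pipeline

```{r}
library(delharm)
specs <- bundled_instruments()
study <- simulate_study(generator_config(seed = 42))
model <- run_pipeline(study$data, specs)
```

1. **Shared items, dichotomized** (`step1_shared()`).  Ratings are
   collapsed to absent/present at each item's dichotomization cut --
   cut 1 ("not present" vs "any symptom") everywhere except sleep/wake
   disturbance, which uses cut 2 ("not present or mild" vs "moderate or
   severe") because mild sleep disturbance is near-universal in
   hospitalized older adults.  A 2PL model is fitted per instrument to
   its items in the seven symptom domains rated by all three
   instruments (attention, disorganized thinking, orientation,
   perceptual disturbance, psychomotor disturbance, sleep/wake,
   memory).  At the item level that is 8 DRS-R-98 items, 7 MDAS items,
   and 8 CAM-S items, since the DRS-R-98 and CAM-S rate psychomotor
   agitation and retardation separately while the MDAS pools them.
2. **All items, shared parameters fixed** (`step2_all_items()`).  Each
   instrument's full dichotomized item set is fitted with the shared
   items' $\lambda, \tau$ held (bit-identically) at their step-1
   values, so the non-shared items are estimated on the metric the
   shared items established.
3. **Haebara linking** (`step3_link()`).  The MDAS and CAM-S metrics
   are mapped onto the DRS-R-98 metric by the affine transform
   $\theta_{\mathrm{ref}} = A\,\theta_{\mathrm{target}} + B$ minimizing
   the weighted integrated squared difference between anchor items'
   response curves, with target parameters transformed as
   $\lambda' = \lambda / A$, $\tau' = \tau + \lambda' B$.  The anchor
   lists are instrument-specific: six domains for the MDAS
   (disorganized thinking, orientation, perceptual disturbance,
   sleep/wake, delusions, memory -- delusions is a two-instrument
   anchor; the MDAS attention and psychomotor-activity items are
   excluded because their content maps imperfectly onto the DRS-R-98
   counterparts) and seven for the CAM-S (attention, disorganized
   thinking, orientation, perceptual disturbance, psychomotor
   agitation, sleep/wake, psychomotor retardation).  The criterion is
   the common non-symmetric form (evaluated on the reference metric
   only); `symmetric = TRUE` adds the mirror term.  Optimization runs
   over $(\log A, B)$ -- positivity of $A$ by construction -- with
   Nelder--Mead from the identity plus a BFGS polish.
4. **Polytomous recalibration** (`step4_polytomous()`).  The original
   0--3 / 0--2 ratings are refitted per instrument with every item's
   slope and *one* threshold fixed at the linked values and the
   remaining thresholds free.  The fixed threshold is the one at the
   item's dichotomization cut: the binary parameter carried through
   steps 1--3 is, by construction, the cut-point threshold, so for
   sleep/wake items the fixed threshold is $\tau_2$ and $\tau_1$ is
   freely estimated.  Reading "first threshold" literally would equate
   a parameter estimated for the moderate-or-worse event with the
   mild-or-worse threshold; `fix_first = TRUE` provides that behavior
   for comparison.  This two-stage design exists because the higher
   categories are rare: their thresholds are estimated only after the
   slopes and cut thresholds are anchored.

The CAM-S short form is not calibrated separately: it is a reduced
score, so it is scored from the long-form calibration restricted to its
four items (`short_forms` argument).

EAP factor scores, information and reliability curves
(`reliability_report()`, with reliability $I/(I+1)$), item-person maps
(`item_person_map()`, flagging categories located more than 4 SD above
the latent mean), factor-score correlations (`score_correlations()`),
and integer crosswalks (`crosswalk()`) all derive from the harmonized
parameters.  Crosswalks invert the source instrument's test
characteristic curve by bisection (tolerance $10^{-6}$, truncated and
flagged beyond $\pm 6$ SD) and report target expectations raw and
rounded half-up -- half-up rather than banker's rounding so that
crosswalked scores never alternate direction across adjacent inputs,
with the raw value always retained alongside.  Curves are tabulated on
$\theta \in [-3, 6]$ in steps of 0.01, covering the range over which a
low-severity hospital sample spreads against high item thresholds.

## What the synthetic-data generator emulates

No public delirium co-calibration data set exists, so the package
ships a generator (`simulate_study()`) reproducing the design features
the pipeline relies on, with defaults chosen once to mirror a
prospective hospital cohort:

* **Clustered daily assessments.** 352 persons contribute 1--15 rated
  days.  Lengths of stay are drawn from a geometric distribution
  truncated at 15 days with success probability 0.3 (mean about 3.3
  rated days), yielding roughly 1178 assessments in expectation.  A
  uniform distribution on 1--15 would triple that total; short stays
  dominate real hospital data.
* **Latent severity.** $\theta_{pd} = u_p + e_{pd}$ with
  $u_p \sim N(0, \rho)$ and $e_{pd} \sim N(0, 1-\rho)$, so the
  marginal variance is exactly 1 (matching the models' identification)
  and the within-person correlation is $\rho$ (default 0.5 -- a
  placeholder for an unreported quantity, not an estimate; an AR(1)
  option exists).  The calibration steps treat assessments as
  independent, as the analysis they mirror does for point estimates.
* **Common-person, common-item structure.** All instruments are rated
  on identical person-days from the same $\theta$, and anchor-domain
  items share generating parameters across instruments, so the true
  between-instrument link is the identity and linking recovery is
  testable.
* **Severity skew and high thresholds.** Cognitive domains get the
  lowest first thresholds; psychotic and behavioral domains start 2+ SD
  above the mean; several domains place their top category beyond 4 SD
  ($b = \tau/\lambda > 4$), so expected sum scores sit near the low
  values typical of hospital cohorts, observed maxima fall short of the
  theoretical maxima, and the item-person map has categories to flag.
  Three-category CAM items take a domain's first and third base
  thresholds ("marked" is a moderate-to-severe rating), except the
  cut-2 sleep item, which keeps the first two so every anchor's cut
  threshold is identical across instruments.
* **Missingness** is completely at random at rate 0.02 -- the simplest
  mechanism consistent with administrative set-to-missing codes.
  The CAM-S acute-onset/fluctuation feature is included as a binary
  item in the all-items models and the long-form sum score (it is
  never an anchor); a configuration without it just omits the item
  from the spec.

What the generator does **not** emulate: rater effects and inter-rater
disagreement, dementia subgroups, informative dropout (sicker patients
staying longer), cross-loadings or residual dependence among items,
and any systematic difference between instrument metrics beyond an
affine transform.  Passing recovery tests on these data therefore
shows that the estimation and linking machinery is correct under the
model's own assumptions -- it does not validate the unidimensional GRM
as a description of real delirium ratings.  The residual diagnostic
(`residual_diagnostics()`, observed-vs-implied polychoric correlations
summarized as an RMSR) is the in-package check pointing at that
assumption; fit indices tied to a specific weighted-least-squares
estimator are out of scope.

## Numerical and design notes

* Problem sizes in the test suite were chosen to make the checks sharp
  at desk scale: dense-grid oracles use up to 4 items and 50
  assessments against a 2001-point grid; pipeline recovery runs 10
  replicates of a 600-person (~2000-assessment) study and bounds the
  mean absolute bias of $\lambda$ below 0.1 and of estimable $\tau$
  below 0.15; linking recovery re-estimates 25 replicate calibration
  pairs with a planted 0.5-SD group shift; crosswalk/TCC agreement is
  checked against Monte-Carlo sum-score means at five severities.
* The sign convention is $\lambda \ge 0$ at the solution (higher
  $\theta$ = more severe).  Fits start at $\lambda = 1$ with
  marginal-proportion threshold starts, which makes negative-slope
  solutions unreachable in practice for monotone severity data.
* Polychoric correlations use the two-step estimator (thresholds from
  margins, then 1-D likelihood over the correlation).  Model-implied
  correlations put the logistic residual variance $\pi^2/3$ on the
  latent-response scale, consistent with the engine's logit link; the
  bivariate-normal copula is an approximation under a logistic data
  model, and the under-truth RMSR (~0.03--0.05) reflects that
  approximation as well as sampling noise.
* Sum scores are missing whenever any item is missing, so severity is
  never silently understated; an opt-in prorated mode (mean observed
  item score scaled to the item count, flagged in the output) exists
  for users who need a score for every assessment.
* Serialization (`write_model_json()`, `write_params_json()`) encodes
  infinite sentinel thresholds as `"+inf"`/`"-inf"` strings; report
  tables regenerate identically from a serialized model.

## Known limitations

Cluster-robust standard errors for the repeated daily assessments are
not provided -- point estimates only.  Differential item functioning
across subgroups, multidimensional models, and alternative linking
criteria (Stocking--Lord, mean/mean, mean/sigma) are out of scope.
Parameter values estimated here live on the logistic metric and are
comparable to published probit-metric loadings only up to a scale
factor.
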