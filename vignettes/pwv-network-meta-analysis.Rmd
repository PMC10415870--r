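---
title: "Methods: Bayesian network meta-analysis of PWV change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis of PWV change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Pulse wave velocity (PWV, m/s) is a noninvasive marker of arterial
stiffness: the faster a pressure wave travels along the aorta, the
stiffer the vessel wall.  Randomized trials of antidiabetic drugs often
report the within-arm change in PWV from baseline to end of treatment
(ΔPWV), with negative change meaning improvement.  Because most trials
compare only one drug class against placebo or against one other class,
no single trial answers the question "which class improves arterial
stiffness most?".  A network meta-analysis (NMA) answers it by combining
direct and indirect evidence across a connected comparison graph.

`pwvnma` implements the full pipeline for this problem on arm-level
aggregate data: data validation, change-score SD imputation, pairwise
meta-analysis, a Bayesian random-effects consistency NMA with a
purpose-built Gibbs sampler, SUCRA ranking, loop and global
inconsistency assessment, and a synthetic-network generator with known
truth.  This vignette records the model, the default settings, and the
design decisions, in enough detail that each could be re-derived or
challenged.

## Data model

The unit of input is one trial arm: `study_id`, `treatment` (one of
seven codes: `placebo`, `GLP1RA`, `SGLT2i`, `DPP4i`, `TZD`, `SU`,
`metformin`), the number analysed `n`, the change-score mean and SD in
m/s, optional baseline/final means and SDs, a `population` label, and
the treatment duration in weeks.  Validation enforces the invariants the
downstream methods require — at least two distinct treatments per study,
`n ≥ 2`, a positive change SD or the pair of SDs needed to impute one,
durations of at least 12 weeks (the inclusion window of the compiled
dataset), and a comparison graph in which every treatment is reachable
from the reference — and reports all violations together with row
numbers.

The package ships `pwv_trials()`, arm summaries of 18 published
randomized trials (10 placebo-controlled, 8 head-to-head; 36 arms, all
two-arm) spanning six drug classes and placebo, with populations of
pre-T2DM, T1DM, T2DM, coronary artery disease, chronic heart failure and
NAFLD.  The pre-T2DM/T1DM/T2DM studies (15 of 18) form the
abnormal-glucose-metabolism (AGMD) subgroup used by `filter_agmd()`.
Values are stored exactly as compiled from the trial reports, including
two quirks kept deliberately:

* one trial (Kolwelter) is labelled `DPP4i` although its agent,
  empagliflozin, is an SGLT-2 inhibitor.  The default keeps the label so
  analyses track the compiled network; `reclassify_kolwelter = TRUE`
  flips it.  The network's edge set is identical either way.
* one control arm (Bjornstad) reports a ΔPWV of +4.1 ± 1.6 m/s over 12
  weeks, an implausibly large deterioration that makes its
  placebo–metformin contrast −5.2 m/s with SE 0.43.  This single arm
  dominates the between-trial heterogeneity estimate and, through it,
  the metformin effect and the entire ranking (see *Limitations*).
  The value is retained as compiled; no outlier handling is applied by
  default.

## Change-score SD imputation

When a trial reports baseline and final SDs but not the change SD,
`sd_change()` uses

$$SD_{change} = \sqrt{SD_b^2 + SD_f^2 - 2\rho\, SD_b SD_f},$$

with pre/post correlation ρ defaulting to 0.5, the conventional
conservative choice when the correlation is unknown: it reproduces the
arm SD when baseline and final SDs are equal, and errs toward wider
(not narrower) standard errors for typical positive correlations above
0.5.  Range and interquartile-range conversions use the standard
divisors 6 and 1.35 (`sd_from_range()`, `sd_from_iqr()`).  The shipped
dataset reports every change SD directly, so no imputation fires on it;
`sensitivity_corr()` provides a what-if sweep over ρ ∈ {0.3, 0.5, 0.7}
that re-imputes every imputable arm and reports the shift in each pooled
direct comparison.

`build_contrasts()` turns arms into within-trial contrasts against the
study's baseline arm (the reference treatment when present, otherwise
the trial's own control arm, stored last): MD = difference of change
means, SE = $\sqrt{sd_k^2/n_k + sd_b^2/n_b}$.

## Pairwise meta-analysis

`pool_pairwise()` pools each direct comparison with an inverse-variance
random-effects model using the DerSimonian–Laird between-trial variance
(delegated to `metafor::rma(method = "DL")`), reporting Cochran's Q,
I², the Q-test p-value and a two-level heterogeneity flag: *mild* when
p ≥ 0.1 and I² ≤ 50%, *investigate* otherwise.  DL is the conventional
moment estimator for this setting; no REML alternative is exposed
because the pairwise stage is descriptive here.  Comparisons reported in
both orientations are sign-aligned to the orientation of their first
occurrence before pooling, so each unordered pair yields one row (the
shipped network has 11 edges).  `funnel_data()` centres every study on
its own comparison's fixed-effect mean — the comparison-adjusted funnel
convention — so all edges share a common zero.

## The Bayesian consistency model

`fit_nma()` estimates the arm-based hierarchical normal model

$$y_{ik} \sim N(\mu_i + \delta_{ik},\; sd_{ik}^2/n_{ik}),$$

where $y_{ik}$ is the observed change mean of arm $k$ in study $i$ and
the arm sampling variances are treated as known.  The baseline arm of
each study has $\delta \equiv 0$; other arms receive trial-specific
effects

$$\delta_{ik} \sim N(d_{t(i,k)} - d_{t(i,b)},\; \tau^2),$$

with basic effects $d$ expressed against the reference (placebo,
$d_{ref} \equiv 0$) — the consistency parameterization, which makes
every contrast an exact difference of basic effects in every posterior
draw.  Multi-arm studies use the exchangeable joint normal with
$\tau^2/2$ off-diagonal covariance.  Priors: $N(0, \text{precision }
10^{-4})$ on every baseline $\mu_i$ and basic effect $d_k$, and
$\tau \sim U(0, 5)$ m/s.

Two prior-specification choices deserve a note.  A variance of $10^{-4}$
on effects would be a near-point-mass at zero, which contradicts the
intent of a vague prior; the package therefore uses precision $10^{-4}$
(variance $10^4$), the standard BUGS-style vague normal.  Likewise the
between-trial SD prior is the standard $U(0,5)$; 5 m/s is far above any
plausible heterogeneity for ΔPWV, so the bound is not informative in
practice.  Both are configurable (`effect_prior_precision`, `tau_max`)
for sensitivity analyses, including the literal near-point-mass reading.

A contrast-based likelihood (`likelihood = "contrast"`), which collapses
each two-arm study to its MD and SE and drops the baselines, is provided
as a cross-check; for two-arm data it agrees with the arm-based model
within Monte-Carlo error (tested).

### Sampling

All conditionals except τ are conjugate normals, so the sampler is plain
Gibbs with one slice-sampling step:

* $\mu_i$ and (for two-arm studies) $\delta_i$ update in vectorized
  blocks across studies; multi-arm studies draw their $\delta_i$ vector
  from the joint-normal conditional via a small Cholesky solve.
* the basic-effect block $d$ is drawn jointly from its multivariate
  normal conditional.  Its precision is $A/\tau^2 + p_0 I$ with $A$
  fixed by the design, so $A$ is eigendecomposed once and each
  iteration costs only matrix–vector products — no per-iteration
  factorization.
* τ has a nonstandard full conditional under the uniform prior
  ($\propto \tau^{-m} e^{-Q/2\tau^2}$ on $(0,5)$) and is updated by a
  stepping-out/shrinkage slice sampler.
* with `tau_fixed = 0` the δ's are exactly coupled to $d$, so the
  sampler switches to the collapsed conditional of $d$ given $\mu$;
  this common-effect limit is the bridge to the frequentist
  fixed-effect WLS network estimate, with which it agrees to within
  0.05 m/s on the shipped data (tested against an independent `lm()`
  oracle).

Defaults follow the compiled analysis protocol: 3 chains, 20,000
burn-in, 80,000 retained iterations, thinning 1.  Chains start from
overdispersed states ($d, \mu$ at 0/+1/−1; τ at 1, 0.1, 2.5) and
convergence is declared only if split-R̂ < 1.05 for every monitored
parameter (all $d_k$ and τ); the fit errors otherwise
(`on_nonconvergence = "warn"` downgrades this for simulation studies
where occasional slow chains are scored, not trusted individually).
Effective sample sizes come from `coda`.  Only $d$ and τ are retained by
default; `keep_mu = TRUE` stores the baselines.  A scalar seed makes the
entire fit bit-reproducible.  The sampler was additionally validated
against an independent Gibbs implementation (JAGS) on a small network:
posterior means and τ agree within Monte-Carlo error (tested).

The full default schedule on the 18-trial network runs in well under a
minute on one CPU core.  The test suite uses shorter schedules chosen so
that Monte-Carlo error is an order of magnitude below the checked
tolerances: 3 × (3,000 + 12,000) for the reproduction checks, 2 ×
(500–1,500 + 2,000–8,000) for unit tests, and 2 × (600 + 2,400) per
replicate inside the 200-replicate recovery study.

## Ranking

`sucra()` ranks all treatments — reference included — within each
posterior draw, most-negative-first by default (`direction = "lower"`),
since lower ΔPWV means greater stiffness reduction.  Ties are broken by
a uniformly random permutation within the tied set, which keeps the
treatment × rank probability matrix doubly stochastic (a degenerate
deterministic tie-break would not).  SUCRA is the surface under the
cumulative ranking curve,

$$\mathrm{SUCRA}_k = \frac{1}{a-1}\sum_{j=1}^{a-1} F_k(j),$$

1 for a treatment certain to be best, 0 for certain worst; across
treatments it averages exactly 0.5, which the tests assert as an exact
identity.

## Inconsistency

Indirect evidence can contradict direct evidence only around cycles, so
`enumerate_loops()` lists every chordless cycle of length 3 or 4 in the
comparison graph (longer chordless cycles do not occur in networks of
this size; the shipped network has four triangles and two
quadrilaterals).  For each loop, `loop_if()` pools the direct evidence
on every edge with a loop-common between-trial variance (method of
moments over the loop's multi-study edges, the convention of the
standard loop-inconsistency routines), sums the pooled estimates around
the oriented cycle, and reports the absolute inconsistency factor, its
SE by variance addition, a zero-truncated 95% CI, and a two-sided normal
p-value with p < 0.05 flagged.

`global_inconsistency()` is a two-stage design-by-treatment interaction
Wald test for two-arm designs: pool each design, then test the pooled
design means against the best-fitting consistent basic effects, χ² with
(designs − basic effects) degrees of freedom.  The shared τ² is
estimated by method of moments *within designs* (the
unrelated-design-means model), not from the consistency fit: estimating
it from the consistency model would absorb genuine between-design
disagreement into heterogeneity and destroy the test's power — in the
package's power simulation the rejection rate collapses from ≈ 0.95 to
the nominal 0.05 if τ² is taken from the consistency fit.  A loop-free
network has zero interaction degrees of freedom; the test then raises an
error rather than returning a vacuous p = 1.

Detection power is geometry-bound.  With a planted offset of five
contrast-SEs, rejection rates across the shipped network's designs range
from ≈ 0.68 (SGLT2i–placebo, thin indirect evidence) to ≈ 0.96
(metformin–placebo, two direct trials plus three independent indirect
routes).  The packaged power experiment plants the offset on the
metformin–placebo design for exactly that reason: it demonstrates the
test where the network actually carries enough evidence to confront
direct with indirect estimates.  A planted offset on a sparsely
connected edge is intrinsically hard to detect and no global test will
fix that.

## Synthetic networks with known truth

`simulate_network()` generates arm-level datasets under the same
hierarchical model the estimator assumes: per study, a baseline mean
drawn uniformly (default −0.5 to 0.5 m/s, matching the spread of control
-arm change means in the shipped data), a trial effect
$\delta_i \sim N(d_t - d_b + \text{offset}, \tau^2)$, and observed arm
means with sampling variance $sd^2/n$.  Arm SDs are drawn uniformly on
0.3–3.5 m/s and arm sizes on 13–97, the ranges spanned by the shipped
trials.  Three designs are available: the shipped network's exact 18
treatment pairs (`example_geometry`, the default), a round-robin star, and
a random connected graph.  The generating truth defaults to the frozen
posterior of the shipped analysis (`sim_defaults()`: basic effects
−0.67 … −1.44 m/s, τ = 1.43) so that simulations probe the estimator
under conditions like those it actually faces.  An
`inconsistency_offset` plants a consistency violation on named edges for
power studies.  Output passes `validate_trials()` unchanged, and the
truth travels with the tibble as an attribute (`sim_truth()`).

What the generator deliberately does *not* emulate: publication bias or
small-study effects, non-normal outcome distributions, measurement-error
differences between PWV devices, duration or population covariates, and
multi-arm trials (all generated studies are two-arm, like all shipped
trials).  Passing recovery tests therefore shows the estimator is
correct *under its own assumptions* — it says nothing about robustness
to model violations in real data.

`score_recovery()` summarizes replicated fits against the truth (bias,
RMSE, 95%-CrI coverage per treatment).  In the packaged 200-replicate
study at the default geometry, coverage is statistically compatible with
the nominal 0.95 for every treatment and for τ.  At 200 replicates the
binomial noise on a coverage proportion is ≈ ±1.5%, so individual
treatments can and occasionally do graze the boundaries of a fixed
acceptance band even under perfect calibration; a 400-replicate
diagnostic run showed 0.95–0.97 coverage throughout.

## Numerical and degenerate-input choices

* Arm variances are treated as known ($sd^2/n$); no sampling step for
  them.
* The $d$-block eigendecomposition is computed once per fit; eigenvalues
  are clipped at zero against roundoff.
* `sd_change()` allows the degenerate zero only at equal SDs with ρ = 1;
  downstream contrast building rejects non-positive SEs.
* Self-contrasts summarize to exactly (0, 0, 0); the reference column of
  the draw matrix is identically zero rather than sampled.
* Single-study edges report Q = 0, I² = 0, p = 1 and a *mild* flag.
* Empty AGMD subsets, disconnected networks, unknown treatment codes and
  duplicate arms are errors with row numbers, not warnings.
* Rank ties (exactly equal posterior draws, possible only in contrived
  inputs) are broken uniformly at random rather than by index order.

## Limitations

* **One arm dominates the shipped analysis.**  The Bjornstad control
  arm's +4.1 m/s change makes its trial an extreme outlier; the
  between-trial SD posterior concentrates around 1.4 m/s, every credible
  interval crosses zero, and metformin — the outlier trial's active
  arm — takes the most negative posterior mean and the top SUCRA rank.
  Analyses of these data should always be read next to a sensitivity
  analysis excluding or correcting that arm.  The two flagged
  quadrilateral loops trace to the same tension between a few very
  precise trials (Stakos, deBoer) and the rest of the network.
* The model assumes normal aggregate effects with known arm variances;
  trials with n per arm near the lower bound (13) strain both
  assumptions.
* SUCRA is a rank summary, not an effect size: treatments separated by
  far less than their interval widths can still be strictly ordered.
* The global test's power depends on where inconsistency sits in the
  graph (see above); non-rejection on a sparse network is weak evidence
  of consistency.
* Heterogeneity is a single network-wide τ; comparison-specific
  heterogeneity is not modelled.
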