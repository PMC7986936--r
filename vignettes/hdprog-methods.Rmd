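---
title: "Modelling regional brain atrophy around Huntington's disease motor onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional brain atrophy around Huntington's disease motor onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Huntington's disease (HD) gene carriers lose regional brain volume for a
decade or more around the clinical onset of motor symptoms. Longitudinal
volumetric studies of this period produce, per subject, a handful of
irregularly available annual measurements of many regional volumes, and the
scientific questions are hierarchical: what is each subject's trajectory,
how do trajectories differ between converters and controls, how does the
genetic burden (CAG-repeat length) modulate them, and do they predict motor
and cognitive decline?

`hdprog` implements a two-level Bayesian state-space treatment of this
design. Time is expressed in years relative to motor conversion (the first
clinical rating of unequivocal motor signs defines $t = 0$; controls are
aligned at the age-matched time point), and volumes are expressed as
percentages of the cohort mean volume at diagnosis, so 100 is the
cohort-typical volume at $t = 0$.

## The subject-level model

Each subject's 55 regional volumes are driven by 28 latent atrophy states
$x(t)$ through a linear state equation and a linear observation model:

$$\frac{dx}{dt} = A\,x(t) + C\,u(t,\theta_u), \qquad
  y(t) = g\big(x(t)\big) + \varepsilon,$$

where $A$ collects self-connections (and optionally interregional edges),
$u$ is an exogenous input with sensitivities $C$, and
$\varepsilon \sim \mathcal N(0, e^{-\gamma} I)$ with a single estimated log
noise precision $\gamma$ shared across the 55 volume columns. Bilateral
symmetry is assumed: the 25 cortical region pairs each share one latent
state that predicts both hemisphere columns, the caudate and the putamen
are each one bilateral state observed in two columns, and global white
matter is a single state — $25 + 1 + 1 + 1 = 28$ states for
$50 + 2 + 2 + 1 = 55$ columns. (Whether the original analyses treated the
striatal hemispheres exactly this way is not documented; this is the only
mapping consistent with both counts, and the package states it rather than
asserts it.)

Four candidate forms describe progression:

| form | dynamics | closed form |
|---|---|---|
| `constant_rate` | $A=0$, $u = c_0$ | $x(t) = x_0 + c_0 t$ |
| `quadratic_rate` | $A=0$, $u = c_0 + c_1 t$ | $x(t) = x_0 + c_0 t + \tfrac{c_1}{2}t^2$ |
| `dynamic` | $A = \mathrm{diag}(a_i)$, no input | $x_i(t) = x_{0i} e^{a_i t}$ |
| `dynamic_sigmoid` | diagonal $A$ plus logistic input | RK4, step 0.05 y |

Self-connections are parameterized as $a_i = -e^{\lambda_i}$ with
$\lambda_i$ unconstrained, which enforces decay (negative
self-connections) by construction and puts the prior on a log-rate scale.
The sigmoid input is the logistic
$u(t) = 1/(1 + e^{-(t - t_0)/\tau})$; an error-function transition would be
an equally defensible reading, but the logistic is used throughout.
With interregional edges the full linear system is solved through the
eigendecomposition of $A$; the sigmoid form is integrated by fixed-step
RK4 (0.05 years) forward and backward from the anchor $t = 0$, where
$x(0) = x_0$ exactly for every form.

## Subject-level inversion (variational Laplace)

`fit_subject()` maximizes the variational free energy
$F = \mathbb E_q[\log p(y\mid\theta)] - \mathrm{KL}(q \,\|\, p)$ over a
Gaussian posterior $q(\theta)$, by Gauss–Newton ascent with
Levenberg–Marquardt damping; steps are accepted only when they increase
$F$, so the trace is nondecreasing by construction. Log noise precisions
(one for volumes, one for behavioural channels when present, because the
two live on different scales) are updated by damped Newton steps with their
own Laplace factors. Convergence is declared when $|\Delta F| < 10^{-3}$
for 4 consecutive iterations (maximum 128); a fit that exhausts its
iterations is returned with `converged = FALSE`, never silently. For
linear-in-parameter forms the Jacobian is the exact design matrix and $F$
equals the analytic log marginal likelihood (this is tested to $10^{-6}$
against the conjugate solution); for the diagonal dynamic form derivatives
are analytic; the sigmoid and edged forms use compiled batched finite
differences.

Priors are deliberate choices on the volume % scale (the study data they
would be tuned to are not public):
$x_0 \sim \mathcal N(100, 10^2)$,
$\lambda \sim \mathcal N(\log 0.01, 1)$ (decade-plausible decay
magnitudes), $c_0 \sim \mathcal N(0,1)$, $c_1 \sim \mathcal N(0, 0.5^2)$,
$t_0 \sim \mathcal N(0, 2^2)$, $\log\tau \sim \mathcal N(0, 0.5^2)$, edge
weights $\mathcal N(0, 0.1^2)$, behavioural weights $\mathcal N(0,1)$ with
intercept $\mathcal N(50, 50^2)$, and log noise precisions
$\mathcal N(0,1)$ (volumes) and $\mathcal N(0,2^2)$ (behaviour). All are
exposed through `prior_spec()`.

## The group level (parametric empirical Bayes)

Subject posteriors are embedded in a second-level linear model
$\theta_s = B\,x_s + \xi_s$ over the design row $x_s$ with columns, in
fixed order: overall mean, diagnostic group ($+1$ HD / $-1$ control),
CAG-repeat length (z-scored over HD; controls enter at the column centre,
so the group column absorbs the group mean difference), gender
($\pm 1$, centred), age at conversion (z-scored, then orthogonalized with
respect to the CAG column — the two are strongly correlated because longer
repeats convert younger), TIV (z-scored) and centred site indicators.
Whether covariates should be scaled before orthogonalization is not
documented anywhere authoritative; z-scoring first is this package's
declared convention, chosen so effect magnitudes are comparable across
covariates when they are later thresholded.

The between-subject (random-effects) precision is a single estimated
scalar $\lambda_q$ on the *prior-scaled* metric: the random-effects
variance of parameter $j$ is $\sigma_{0j}^2/(16\,\lambda_q)$. A literal
isotropic precision would be dimensionally meaningless across parameters
living on scales from $\sim 100$ (% volume) to $\sim -5$ (log decay); the
prior-scaled form preserves the "one scalar, expectation one-sixteenth of
the first-level prior variance" convention parameterwise. The scalar is
estimated by maximizing the second-level free energy with a standard
normal prior on its log. First-level uncertainty propagates exactly
through the Gaussian likelihood summaries, so subjects with more visits
(tighter posteriors) weigh more.

**Iterated inversion.** The hierarchical free energy of *nonlinear* forms
is sensitive to where the subject-level Laplace approximation is
linearized: a subject whose true decay sits far from the initial prior
mean is summarized by a Gaussian likelihood expanded around a
prior-shrunk posterior, which misrepresents the evidence the hierarchy
assigns to group predictions far from that point. `hdprog()` therefore
re-inverts every subject under the PEB-implied empirical prior (group
prediction $B x_s$ with the random-effects plus propagated effect
covariance) and re-estimates the group model — `eb_passes = 2` by
default, the scheme recommended for PEB pipelines in the neuroimaging
literature. Group-level priors always remain the original model priors.

## Model comparison, reduction and averaging

Candidate models are compared by their total group free energy
(differences are log Bayes factors; `posterior_model_probs()` is a softmax
under equal model priors). Bayesian model reduction computes, without
refitting, the evidence of any reduced group model in which selected
(parameter, covariate) effects are switched off — implemented as prior
variance collapsed to $10^{-8}$ rather than exactly 0, the safe limit for
the linear algebra. `bma_average()` searches the on/off family (greedy
batch search by default, exhaustive enumeration for small searches — the
two agree on small problems and the choice is recorded in the result) and
reports, per entry, the evidence-weighted probability $P_p$ of being "on",
an evidence-weighted average estimate, and the surviving mask at
$P_p > 0.95$. Since no record states whether the original reduction search
was exhaustive or automatic, both are provided.

## The synthetic cohort

Because the original cohort is private, the package ships a generator
whose defaults *are* the published design, so that every stage of the
pipeline is testable:

* 49 converters + 49 age-matched controls; 3–7 annual visits placed
  uniformly among window alignments that include the conversion year;
  visit-count law $(0.14, 0.14, 0.07, 0.04, 0.61)$ over $3\ldots7$ with
  mean 5.84 (the published HD mean; 61% with 7 scans matches the
  published 30 of 49), control law with mean $\approx 6.07$ (published
  control means are reported inconsistently as 6.06 and 6.08; the
  generator targets "about 6.1" and leaves it there).
* CAG-repeat marginal: a discretized truncated normal on $39\ldots50$
  with $(\mu,\sigma) = (43.2423, 3.4367)$, calibrated once so the
  discretized mean and sd equal the published 43.67 and 2.77; age at
  conversion $\mathcal N(44.59, 9.28^2)$ truncated to $[28, 66]$; a
  Gaussian copula with correlation $-0.85/0.985$ (discretization
  attenuates Pearson correlations by $\approx 1.5\%$) reproduces the
  published CAG–onset-age correlation of $-.85$.
* Region-specific exponential atrophy
  $a_i = -(d_i + s_i\,(\mathrm{CAG} - 42))$ for HD subjects. Striatal
  decays are anchored so the subject at the mean CAG (43.67) loses
  exactly 18.7% (putamen) and 15.4% (caudate) of baseline volume per
  decade; cortical decays are graded by lobe (occipital 8%/decade >
  parietal 6% > frontal/temporal/limbic 3%, white matter 5%) following
  the published spatial ordering; controls decay 1% per decade (the
  published bound is "below 3%"). CAG slopes are concentrated in
  striatal, occipital and parietal states. Group volume offsets at
  $t = 0$ (putamen $-8$, caudate $-7$, occipital/parietal $-3$, rest
  $-2$ % points) express the published "largest striatal, widespread
  cortical" difference pattern; their exact magnitudes are not printed
  anywhere and are generator choices.
* Measurement noise is i.i.d. Gaussian, sd 1.0 % point (unreported in
  the source; chosen so subject-level recovery is nontrivial but
  achievable, and exposed in the config).
* Behavioural channels: TMS and SDMT scores are weighted sums of the
  latent states plus an intercept and noise (sd 5 points), clipped to
  $[0, 100]$ *after* noise because the rescaled scale is bounded by
  construction. Weight supports follow the regions the study associates
  with each score; weights are scaled once so the noise-free reference
  subject worsens by 57.80 (TMS) and 16.78 (SDMT) points over the decade
  $[-6, 4]$.

What the generator does **not** emulate: scanner/site intensity effects
beyond an additive covariate, informative missingness (visit counts are
completely at random), registration or segmentation error structure,
non-Gaussian heavy-tailed noise, and real biological heterogeneity beyond
the CAG-linear decay law. A green test therefore establishes that the
pipeline recovers the stated statistical structure at realistic sizes and
noise — not that it would behave identically on the original images.

## Numerical choices

* RK4 fixed step 0.05 years for the sigmoid form (final partial step
  adjusted to land on targets); trajectories match an independent
  fine-step oracle to $<10^{-6}$ over the full window.
* Finite-difference steps $10^{-4}$ (relative at the subject level).
* "Switched off" prior variance $10^{-8}$; between-subject precision
  search on $\log\lambda_q \in [-4, 6]$, golden-section tolerance 0.1.
* The nonhierarchical decade-loss summary fits per-subject OLS lines
  (hemispheres pooled) and reports $-10\,\hat b_1 / \hat v(-6) \times
  100$, anchored at the fitted volume extrapolated to the study window
  start. On noise-free exponential decay of the putamen magnitude this
  convention is within 1 percentage point of the closed form
  $100(1 - e^{10a})$ for every admissible visit placement; anchoring at
  the subject's first visit instead would overshoot by up to +1.6
  points. The residual $\approx -0.4$ point linearization gap is part of
  the summary's definition, not a bug.
* Behavioural readout fitting: the generator shares one readout across
  subjects, so the fitted brain–behaviour model is an empirical-Bayes
  ridge regression of pooled HD scores on the subjects' fitted latent
  states (28 weights + intercept, weight prior $\mathcal N(0,1)$, noise
  variance by marginal likelihood). Subject-level fitting of per-subject
  weights is supported by the machinery but is not identifiable from 3–7
  visits and is not used for the headline metrics.

## Known limitations

* **Exponential vs. linear decline is near-unidentifiable at published
  effect sizes.** With decays of at most $\sim 2\%$/year observed through
  windows of at most 6 years, the largest deviation of an exponential
  from its best-fitting line is $\approx 0.25$ % point — a quarter of the
  measurement noise — so the `constant_rate` and `dynamic` forms are
  separated by structural (prior and complexity) terms rather than by
  trajectory shape. The package's model selection reliably recovers the
  default dynamic generator, but a cohort generated from the
  constant-rate model is *also* attributed to the dynamic form: at these
  magnitudes that attribution is a property of any total-evidence
  comparison under these priors, not an implementation defect.
* **Interregional-edge sensitivity is Occam-limited.** An edge preset
  adds $\sim 50$ subject parameters and so hundreds of group-level effect
  entries, each costing evidence when unused; physiologically plausible
  edge strengths produce far less likelihood gain than that cost. The
  package therefore reproduces the published *null* result (no evidence
  for interregional spread) robustly, but could not detect plausible true
  spread either — a power statement worth remembering when interpreting
  that null.
* **SDMT readout underestimation.** The SDMT channel's weaker
  signal-to-noise leaves a $\approx -2$ point bias in its fitted decade
  change even with exactly known states; the reported metric sits at the
  lower edge of its calibration band.
* The leave-one-out covariate prediction is essentially perfect on the
  synthetic world (the published analysis misclassified 1 of 98): the
  generator's group separation is cleaner than real data, and the LOO
  numbers should be read as an upper bound.
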