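---
title: "Modelling skill change and the initial-skill boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling skill change and the initial-skill boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(skillbound)
library(dplyr)
```

## The problem

Robot-guided (haptic) motor training moves a trainee's hand along a
reference movement so they can learn it through proprioception. It does not
help everyone: trainees who are already accurate tend to stagnate or get
slightly worse, while initially inaccurate trainees improve. If that
dependence is real, a single number — a boundary on the *initial* error —
can predict, before any training, whether a new trainee is likely to
respond. This package estimates that boundary from before/after training
data and uses it to classify prospective trainees.

The motivating task is drawing a 10 cm-radius circle in 2 s, counter-
clockwise from the 12 o'clock position, without visual feedback. Skill on
each trial is summarised by two errors against the reference movement:

- **Position error** $E_p = \mathrm{mean}_t\,\lvert r_h(t) - r\rvert$, the
  mean absolute deviation of the hand's distance from the workspace centre
  ($r_h$) from the target radius ($r = 0.10$ m).
- **Velocity error** $E_v = \mathrm{mean}_t\,\lVert \mathbf{v}_h(t) -
  \mathbf{v}(t)\rVert$, the mean deviation of the hand velocity from the
  target's tangential velocity ($\lVert\mathbf{v}\rVert = 0.3762$ m/s).

Both are averaged over a 1.46 s evaluation window that starts when the hand
leaves a 3 cm-diameter start zone centred at 12 o'clock. A trial-level
display score is also computed, $100\,(E_{max} - ERR(t))/E_{max}$ averaged
over the window, with $E_{max}$ equal to the target radius, so a perfect
trial scores 100 and a hand held at the centre scores 0.

## The reference movement

The scoring reference is the constant-speed circle: peripheral speed
0.3762 m/s, one full revolution in $2\pi r / 0.3762 \approx 1.67$ s,
resting at the start point afterwards. We deliberately do *not* ramp the
reference speed inside the metric computation, for two reasons. First, the
velocity error is defined against a constant target speed — with ramps
included, a stationary hand would not give the clean identity
$E_v = 0.3762$ m/s. Second, the constant speed and the circumference pin
the moving segment to about 1.67 s, which is consistent with the
evaluation window always ending before the reference stops. The 0.2 s
acceleration/deceleration period of the guidance robot is kept in
`target_spec()` as metadata but plays no role in scoring. Instantaneous
error matches hand and reference by *elapsed time*, not nearest point, so
the score penalises timing as well as shape.

Numerical choices in the metrics stage: hand velocity is estimated by
central finite differences at the native sample rate (one-sided at the
ends), with no smoothing — at 500 Hz the discretisation error on the
circle is below 0.1% and a smoothing filter can be applied upstream by
users who need one. The window end is inclusive of the last sample with
$t \le t_s + 1.46$; time averages are arithmetic means over window samples
(sampling is assumed uniform). Scores are not clamped at 0: errors larger
than $E_{max}$ give negative instantaneous scores, keeping the metric
affine; clamp only for display.

## The four models of skill change

With $y$ a per-trial error, $x \in \{0, 1\}$ the session indicator
(before/after training), $j$ indexing subjects:

$$y \sim \mathcal{N}(\alpha + \beta x,\ \sigma^2)$$

| Model | Intercept | Slope | Interpretation |
|---|---|---|---|
| 1 pooled | shared $\alpha$ | shared $\beta$ | training affects everyone equally, regardless of initial skill |
| 2 varying slope | shared $\alpha$ | $\beta_j$ | individual effects, unpredictable from initial skill |
| 3 varying intercept | $\alpha_j$ | shared $\beta$ | initial skill varies, effect uniform |
| 4 varying intercept and slope | $\alpha_j$ | $\beta_j$ | effect depends on the individual and their initial skill |

Model 4 adds the coupling that makes prediction possible:

$$\beta_j \sim \mathcal{N}(\mu_\beta, \sigma_\beta^2), \qquad
  \alpha_j \sim \mathcal{N}(\theta\,\beta_j + \gamma,\ \sigma_\alpha^2).$$

A non-zero $\theta$ says skill change is linearly related to initial
skill; with $\theta < 0$, subjects whose initial error $\alpha_j$ exceeds
$\gamma$ have negative expected slopes (they improve), so $\gamma$ *is*
the decision boundary, estimated jointly with everything else — no post
hoc regression of fitted slopes on fitted intercepts is needed.

### Priors

Scalar fixed effects and hypermeans get vague normals specified by
precision, $\mathcal{N}(0, \tau = 10^{-5})$ (SD $\approx 316$), the BUGS
convention for "essentially flat on the data scale". All SDs
($\sigma, \sigma_\alpha, \sigma_\beta$) get half-Cauchy(5) priors — the
scale is in the metric's units, so 5 is effectively flat for metre-scale
errors; `prior_config()` exposes it. $\theta$ and $\gamma$ get flat
priors; the MCMC backend realises them as uniforms on $\pm 100$, wide
relative to $|\theta| \approx 1$ and $|\gamma| \le 0.2$, and the bound is
configurable. Observations enter per trial (both sessions stacked long),
and excluded trials never enter the likelihood.

### Inference

`fit_skill_model()` has two backends. The default, `method = "mcmc"`,
uses JAGS (Gibbs/slice sampling): these are conditionally conjugate
Gaussian hierarchies that JAGS samples efficiently, and draws are exactly
reproducible given a seed (per-chain RNG seeds derive from the fit seed).
Defaults are 4 chains × 2000 draws after 1000 warmup; R-hat and effective
sample size are reported, and R-hat > 1.01 raises a warning rather than an
error. `method = "vi"` is a mean-field Gaussian variational approximation
(ADVI-style: scale parameters log-transformed, ELBO maximised by Adam with
reparameterised Monte Carlo gradients computed from the analytic gradient
of the log joint). As usual for mean-field VI it matches posterior means
well and understates posterior spread; use it for quick exploration and
MCMC for intervals. The per-draw, per-observation log-likelihood needed by
WAIC is computed in R from the draws.

## Model selection and the boundary

`compute_waic()` follows the standard two-pass estimator on the deviance
scale, $\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, so smaller
is better. `loso_waic()` refits every candidate model once per held-out
subject and reports the mean ± SD of WAIC across folds; WAIC is computed
on each training fold (model fitness per refit), not on the held-out
subject, which the leave-one-subject-out loop already exercises through
classification. `derive_boundary()` summarises the $\gamma$ posterior by
its mean and the 94% highest-density interval (equal-tailed available via
`prior_config(interval_method = "eti")`), and flags whether the $\theta$
and $\gamma$ intervals exclude zero.

`loso_classification()` predicts each held-out subject from the boundary
fitted to the others: predicted to improve iff their first-session mean
error lies strictly above the fold's $\gamma$ (a tie counts as decline — an
arbitrary but documented convention, softened by a proximity flag raised
whenever the initial mean falls inside the credible interval). The
*actual* label is a strict decrease of the session mean; no significance
criterion is applied, since session means over ~15 trials are stable at
the noise levels considered. Accuracy is reported over classified
subjects, with the count of skipped (failed-fold) subjects alongside, and
the F-measure is F1 with "improve" as the positive class.
`assign_groups()` crosses the position and velocity boundaries into the
red (above both), blue (above velocity only), green (above position only)
and none (below both) groups.

## The synthetic-data generator

There is no deposited dataset for this design, so `generate_metric_dataset()`
emulates the study conditions directly from the generative model: 20
subjects × 2 sessions × 15 trials, $\beta_j \sim \mathcal{N}(\mu_\beta,
\sigma_\beta^2)$, $\alpha_j = \theta\beta_j + \gamma + \varepsilon$, trial
noise $\sigma_{obs}$. Position-scale defaults are $\theta = -1$,
$\gamma = 0.019$ m, $\mu_\beta = -0.002$, $\sigma_\beta = 0.006$,
$\sigma_\alpha = 0.002$, $\sigma_{obs} = 0.005$ — chosen once to match the
printed boundary scale and the qualitative geometry (most subjects above
the boundary improve, a few below it decline). Velocity-scale defaults are
the same structure scaled by the ratio of the two printed boundaries
(0.175/0.019 ≈ 9.2). Trials can be flagged "excluded" (movement left the
safe area) with a configurable rate; excluded trials are emitted flagged
rather than dropped, so the bookkeeping — excluded trials still count
towards the 15-trial session total — is testable.

`generate_trajectory()` optionally produces full circle drawings: the hand
moves on a circle of radius $b\,r$ with angular progression scaled by a
speed factor, plus isotropic Gaussian kinematic noise; $b$ is derived from
the subject's latent error so the metric stage recovers
$E_p \approx \alpha_j + \beta_j\,\mathrm{session}$ exactly in the
noise-free case. This is deliberately the simplest mechanism that lets
latents be dialed in; it makes no biomechanical claims. The generator also
assumes a single shared $\sigma_{obs}$ across subjects (as the likelihood
does); real trial noise is likely heteroscedastic across subjects, so
passing tests show the *procedure* works where its assumptions hold, not
that the assumptions hold for any particular lab's data. Within-session
learning curves are likewise not modelled.

## A small worked run

Problem sizes here are kept small for a fast build; study-scale runs (20
subjects, 4 chains × 2000 draws, full 20-fold LOSO) are the package
defaults.

```{r fit, message = FALSE, warning = FALSE}
cfg <- generator_config(n_subjects = 10, trials_per_session = 10, seed = 1)
data <- as_skill_data(generate_metric_dataset(cfg))

fit <- fit_skill_model(
  data, model = 4,
  config = fit_config(chains = 2, iter = 1000, warmup = 500, seed = 1)
)
boundary <- derive_boundary(fit)
boundary
```

```{r boundary-plot}
autoplot(boundary)
```

```{r compare, message = FALSE, warning = FALSE}
cmp <- loso_waic(
  data, models = 1:4,
  config = fit_config(chains = 2, iter = 600, warmup = 300, seed = 1)
)
tidy(cmp)
```

```{r classify, message = FALSE, warning = FALSE}
cls <- loso_classification(
  data, config = fit_config(chains = 2, iter = 600, warmup = 300, seed = 1)
)
glance(cls)
cls$confusion
```

## Design choices that were genuinely open

- **Equivalence of the nested models.** With $\theta \equiv 0$, model 4's
  intercept hierarchy is exactly model 3's with $\mu_\alpha$ renamed
  $\gamma$, but the slope structures still differ (varying vs shared). The
  nesting check therefore uses slope-homogeneous data
  ($\sigma_\beta = 0$), where the two posteriors must agree within Monte
  Carlo error — and do.
- **WAIC scale.** Deviance scale ($-2 \cdot$ elpd) so "smaller is better"
  and magnitudes line up with the conventional reporting of this analysis.
- **Sampler choice.** Gibbs sampling (JAGS) in place of Hamiltonian
  samplers: for these conditionally conjugate Gaussian hierarchies it is
  fast, exact-seeded, and needs no reparameterisation; the variational
  backend covers the fast-approximation role.
- **Which subjects count in accuracy.** Folds whose fit fails skip their
  subject with a warning; the report carries both the number classified
  and the number skipped so the denominator is always explicit.
- **Per-fold vs pooled boundary.** Classification uses each fold's own
  boundary (the held-out subject never influences it); the pipeline also
  writes the all-subject boundary, which is what one would deploy.

## Limitations

The linear coupling $\alpha = \theta\beta + \gamma$ is the simplest model
that yields a boundary; a curved relation, session-order effects, or
heteroscedastic subjects would need the extended models this package does
not implement. Classification accuracy on synthetic data is an upper bound
for practice: it inherits the generator's assumptions (shared noise, exact
linear coupling, no trial-order learning). And a boundary estimated from
~20 subjects carries real uncertainty — that is why every classification
carries the proximity flag and the credible interval rather than the point
boundary alone.
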