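---
title: "Observer models, fitting and inference in avbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models, fitting and inference in avbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avbci)
library(dplyr)
```

`avbci` models how observers localise synchronous audiovisual signals when
a precue directs attention to one modality and a postcue selects the
modality to report. This vignette is the package's account of the science:
the generative model, the model space, how the likelihood and the
group-level selection work, what the synthetic-data generators emulate, and
the numerical choices that a user may want to question.

## The generative model and the observer

On each trial an auditory source $S_A$ and a visual source $S_V$ are drawn
from three azimuths ($-9°, 0°, +9°$). The observer receives noisy internal
samples

$$x_A \sim N(S_A, \sigma_A^2), \qquad x_V \sim N(S_V, \sigma_V^2),$$

and holds a central spatial prior $N(\mu_P = 0, \sigma_P^2)$. Under the
causal-inference account the observer entertains two structures: a common
cause ($C = 1$), under which both samples reflect one location, and
independent causes ($C = 2$). The posterior probability of a common cause
combines a prior $P_{common}$ with the marginal likelihoods of the sample
pair under each structure; both marginals are Gaussian convolutions of the
noise with the spatial prior and are evaluated in closed form (in log
space, so extreme samples do not underflow).

Conditional on the structure, estimates are precision-weighted averages:

- fused: $\hat S_{AV} = \dfrac{x_A/\sigma_A^2 + x_V/\sigma_V^2 +
  \mu_P/\sigma_P^2}{1/\sigma_A^2 + 1/\sigma_V^2 + 1/\sigma_P^2}$
- segregated: $\hat S_{A} = \dfrac{x_A/\sigma_A^2 +
  \mu_P/\sigma_P^2}{1/\sigma_A^2 + 1/\sigma_P^2}$ (and analogously for
  vision).

The reported modality is read out by **model averaging**: the final
estimate is the fused and the task-relevant segregated estimate weighted by
the posterior probabilities of their structures. Other decision functions
(model selection, probability matching) are deliberately out of scope.
Forced fusion is the $P_{common} = 1$ special case, which the test suite
asserts to machine precision.

Responses are discrete: the observer presses the button nearest the final
estimate. Bin edges sit at the midpoints ($\pm 4.5°$); exact ties — a
measure-zero event — break toward the centre button.

## The 2 × 3 model space

Prestimulus attention and poststimulus report can act through different
mechanisms, and the model space crosses them:

| | report fixed | report free | BCI readout |
|---|---|---|---|
| attention fixed | FF, 3 params | FF, 5 | BCI, 4 |
| attention free | FF, 5 | FF, 9 | BCI, 6 |

"Free" means the sensory standard deviations $\sigma_A, \sigma_V$ take
separate values per attention (or report) level; the spatial prior
$\sigma_P$ is always shared, and BCI adds $P_{common}$. In the forced
fusion column report can only act by changing noise; in the BCI column it
acts through the late readout, with no report-specific noise at all. The
observer is modelled as *self-consistent*: the condition-specific
$\sigma$ governs both the generative draw and the observer's own inversion,
since a single condition-specific noise parameter is the natural reading of
the design and is standard in this literature.

A diagnostic consequence, which the tests exploit: a report effect produced
by the BCI readout *grows with audiovisual disparity* (greater disparity
favours independent causes, which weights the segregated, task-relevant
estimate more), while an attention effect produced by noise changes shifts
the weight index without a disparity interaction.

## Likelihood and fitting

The internal samples are not observable, so predicted response
distributions marginalise over them: 10,000 sample pairs per design cell
are simulated, pushed through the observer, and binned into the three
buttons; the data likelihood is multinomial in the per-cell button counts,
summed in log across the 36 cells. Two numerical choices matter:

- **Common random numbers.** One standard-normal draw matrix is generated
  per fit and reused at every parameter evaluation, scaled by the current
  $\sigma$. The likelihood surface is then an exactly deterministic,
  almost-everywhere-smooth function of the parameters, which a
  Nelder–Mead simplex can optimise; refitting with the same seed
  reproduces the optimum bit-identically. The draw seed ignores the model
  variant, so all six models fitted to one dataset share their Monte-Carlo
  noise and their likelihoods are directly comparable.
- **Probability floor.** Finite simulation can leave a button with zero
  mass; probabilities are floored at $10^{-6}$ before the log. The
  multinomial coefficient is omitted (constant in the parameters), so
  absolute log likelihoods are comparable within this convention only.

Optimisation is performed in transformed space ($\log \sigma$,
$\mathrm{logit}\,P_{common}$) to enforce bounds without a constrained
optimiser, initialised from the best point of a coarse factorial grid
($\sigma_A \in \{2,4,8,16\}$, $\sigma_V \in \{0.5,1,2,4\}$,
$\sigma_P \in \{5,10,20,40\}$ degrees, $P_{common} \in \{0.2,0.5,0.8\}$).
For variants with level-specific sigmas the grid is taken over *base*
values expanded equally across levels rather than the full per-level
factorial: the latter would cost hundreds of thousands of likelihood
evaluations for the 9-parameter model while adding nothing but symmetric
copies of the same starting regions, since the simplex separates the
levels from the data within a few dozen iterations. If the simplex ends
below the best grid point, the fit is flagged `converged = FALSE` and the
best-so-far parameters are returned.

An independent **quadrature oracle** backs the simulated likelihood:
`predict_response_probs(..., method = "quadrature")` integrates the
deterministic sample-to-button map over the bivariate Gaussian by
stratification in probability space, with the outermost stratum on each
side subdivided so the far tails are represented rather than truncated.
The two routes share no code path beyond the estimate formulas' algebra
(the quadrature runs through the pure-R estimate functions, the simulation
through the compiled kernel) and agree within Monte-Carlo error across the
design.

Goodness of fit is the coefficient of determination against a
uniform-guessing null, $R^2 = 1 - \exp(-\tfrac{2}{n}(l(\hat\beta) -
l(0)))$, scaled by its maximum attainable value given discrete responses,
$\max(R^2) = 1 - \exp(\tfrac{2}{n} l(0))$; it can be negative for a model
worse than guessing and is reported unclipped.

## Model evidence and group-level selection

`bic_scores()` reports three conventions side by side, because the
literature is inconsistent about constants: the Schwarz log-evidence
approximation $\log L - \tfrac{k}{2}\ln n$ (used for all selection in this
package), the textbook $-2\log L + k \ln n$, and $-\log L + k\ln n$. All
three rank models identically; `rel_bic` tables are reported relative to
the BCI attention-free model with the sign convention that the reference
is 0 and smaller is better.

Group selection treats the generating model as a random effect across
participants: a variational Dirichlet posterior over model frequencies
(stopping when the change in $\alpha$ falls below $10^{-6}$, cap $10^4$
iterations), exceedance probabilities by $10^6$ Dirichlet draws under a
fixed seed (with the exact regularised-incomplete-beta form available for
two models, used as a cross-check in the tests), and the Bayesian omnibus
risk from the free-energy comparison of the frequency model against the
null of equal frequencies, $BOR = 1/(1 + e^{F_1 - F_0})$. Protected
exceedance probabilities blend toward chance,
$pEP = EP (1 - BOR) + BOR/K$.

## Weight indices

The audiovisual weight index locates a report (or a decoded location)
between the congruent-condition anchors of its auditory and visual
locations: 1 means purely visual, 0 purely auditory. The scaling
denominators are pooled over attention × report conditions (and runs, for
decoded values) across participants, which stabilises a quantity that
would otherwise put per-participant noise in a denominator;
per-participant denominators remain available behind a flag for
sensitivity analysis. Indices are not clipped to $[0,1]$ — sampling noise
legitimately pushes cell means outside, and clipping would bias the
factorial contrasts. Indices are averaged over location pairs within each
absolute disparity (9°, 18°), giving the 2 × 2 × 2 participant table that
the permutation tests consume.

## Decoding

Multivoxel patterns are decoded run-wise with a linear $\nu$-SVR (LIBSVM,
$C = 1$, $\nu = 0.5$, never tuned), trained on the congruent conditions of
the training runs under leave-one-run-out cross-validation and applied to
every condition of the held-out run. Scaling statistics never cross folds.
The named "image scaling" of the source toolbox is ambiguous between
per-pattern and per-voxel statistics; both are implemented
(`scaling = "pattern"` is the default, matching the common reading), plus
a whole-matrix variant. The choice matters in a way the synthetic
generator makes precise: per-voxel and whole-matrix scaling are affine, so
a noise-free linear spatial code decodes exactly and a planted audiovisual
weight of 0.7 is recovered to machine precision; per-pattern min–max is
mildly nonlinear in the encoded location and biases the recovered weight
by a few hundredths (0.73 for a true 0.7 in the test conditions) — within
the tolerance of the ground-truth checks, but worth knowing when absolute
index values matter.

## Permutation inference

Group effects on the weight tables are tested without parametric
assumptions by exhaustive sign permutation: all $2^n$ assignments of signs
to participant effects (4,096 at $n = 12$), the observed assignment
included so $p \ge 2^{-n}$; Monte-Carlo flips with a seed take over beyond
$n = 20$. Factorial contrasts use ±1 coding (V and high disparity
positive) scaled so a main effect is a plain mean difference. Effect sizes
are the observed mean minus the permutation-null mean; the null mean is
exactly zero under full enumeration but is computed, not assumed. The 95%
CI is a bias-corrected percentile bootstrap over participants ($10^4$
resamples) — the CI construction is an interpretation, isolated behind the
function's arguments, since a nonparametric effect-size CI has no single
canonical form.

## Synthetic data: what it does and does not emulate

The generators produce balanced factorial trial tables (pseudo-randomised
within run from per-participant, per-run substreams of one master seed, so
adding participants never perturbs earlier ones), discrete responses from
any observer in the model space, and voxel patterns whose amplitude is
linear in an effective location $s^\* = w \cdot vloc + (1 - w) \cdot
aloc$ with Gaussian amplitude noise. `sample_observer_population()` draws
per-participant true parameters from ranges typical of audiovisual
localisation fits (auditory noise 3.5–7°, visual noise 1–2.5°, attended
modality 1.3–1.8× more precise, prior 9–16°, $P_{common}$ 0.45–0.75).

What is *not* emulated — and therefore what passing tests do not show
about real data: response lapses and wrong-keypad confusions (excluded
before analysis in practice; a lapse rate is exposed but defaults to 0),
response times, serial dependencies between trials, attentional switching
costs beyond the noise parameters, and any fMRI realism beyond a linear
spatial code with independent Gaussian amplitude noise (no spatial
correlation, drift, or hemodynamic structure). Ground-truth recovery here
demonstrates that the pipeline is correct, not that real cortical codes
are linear.

## Problem sizes and runtime

The recovery studies run at the study's own conditions — 12 participants,
84 trials per design cell (6 per run × 14 runs). Two settings are
resolution knobs rather than study conditions and are set for single-CPU
runtimes of minutes: parameter recovery fits with the published 10,000
simulated samples per cell, while the 6 × 6 model-recovery confusion
(432 fits) uses 1,500 samples, a 2⁴ starting grid and a 150-iteration
simplex cap — spot checks against the full settings select the same models.
The quadrature oracle uses 501 strata per dimension, giving bin-probability
errors well below the Monte-Carlo tolerance it is checking.

## Known limitations

- The simulation-based likelihood is piecewise constant in the parameters
  at the resolution of single samples crossing a bin edge; the common
  random numbers make this deterministic but not differentiable, which is
  why the optimiser is a simplex and why `n_sim` trades precision for
  time.
- $\sigma_P$ is weakly identified when $P_{common}$ is moderate and the
  locations span only 18°; its recovery correlation is accordingly low,
  and conclusions about the spatial prior should not lean on it.
- The 9-parameter forced-fusion variant is frequently indistinguishable
  from its 5-parameter nested version when the planted report effect on
  noise is small; the model-recovery confusion matrix reports this
  honestly rather than hiding it.
- Group-level selection assumes participants are exchangeable; there is no
  hierarchical parameter estimation (a non-goal).
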