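# avbci

Bayesian causal inference modelling of audiovisual spatial localisation
under prestimulus attention and poststimulus report cueing.

## The problem

When a sound and a flash occur together, observers must decide — implicitly
— whether the two signals came from one source (and should be fused,
weighted by their reliabilities) or from separate sources (and should be
kept apart). In pre/postcueing ventriloquist paradigms, observers are cued
*before* the stimulus to attend to audition or vision, and *after* the
stimulus to report the perceived auditory or visual location with one of
three buttons. Attention and report can shape the percept through two very
different computational routes: attention can change the sensory noise that
enters fusion, while the reported modality can change which spatial
estimate is read out late, after the causal structure of the signals has
been inferred.

`avbci` implements the full modelling pipeline that separates those routes,
for researchers in multisensory perception and model-based cognitive
neuroscience:

- **Observer models.** The Bayesian causal inference (BCI) observer
  receives internal samples `x_A ~ N(S_A, σ_A²)`, `x_V ~ N(S_V, σ_V²)` and
  a central spatial prior `N(μ_P, σ_P²)`. It infers the posterior
  probability of a common cause by Bayes' rule, forms a reliability-weighted
  fused estimate and modality-specific segregation estimates, and reads out
  the task-relevant modality by *model averaging*:
  `Ŝ_A = p(C=1|x) Ŝ_AV,C=1 + (1 − p(C=1|x)) Ŝ_A,C=2`. Forced fusion (FF)
  is the special case `P_common = 1`. Six variants form a 2 (attention:
  σ fixed/free) × 3 (report: FF fixed / FF free / BCI readout) model space
  with 3, 5, 5, 9, 4 and 6 free parameters.
- **Fitting.** Discrete 3-button responses are fitted per participant by a
  simulation-based multinomial likelihood (internal samples binned at the
  button midpoints), maximised by a grid-initialised Nelder–Mead simplex
  under common random numbers. Goodness of fit is reported as a scaled
  coefficient of determination against the uniform-guessing null; model
  evidence is approximated by the Schwarz criterion `logL − (k/2) ln n`.
- **Model selection.** Group-level random-effects Bayesian model selection:
  variational Dirichlet posterior over model frequencies, exceedance
  probabilities, Bayesian omnibus risk (BOR), and protected exceedance
  probabilities `pEP = EP·(1 − BOR) + BOR/K`.
- **Weight indices.** The behavioural audiovisual weight index
  `w_AV = (reported_incongruent(A=X,V=Y) − congruent(X)) / (congruent(Y) −
  congruent(X))` (1 = purely visual, 0 = purely auditory), with scaling
  denominators pooled over attention × report conditions across
  participants, and its neural analogue `nw_AV` computed from decoded
  locations.
- **Decoding.** Leave-one-run-out linear support-vector regression (LIBSVM
  via e1071, C = 1, ν = 0.5, untuned) trained on audiovisual congruent
  patterns, decoding congruent (accuracy via Fisher-z Pearson correlations)
  and incongruent conditions (input to `nw_AV`).
- **Inference.** Exhaustive sign-permutation tests (2ⁿ assignments; 4,096
  at n = 12) on factorial contrasts of the weight tables, with effect sizes
  relative to the permutation null and bootstrap CIs.
- **Synthetic data.** Generators for the factorial design, for discrete
  responses from any observer in the model space, and for multivoxel
  patterns whose spatial code mixes the auditory and visual locations with
  a known ground-truth weight — so every stage is testable against ground
  truth.

## Worked example

Simulate a BCI observer with attention-dependent noise at the standard
study size (3 × 3 locations × 2 × 2 cues, 6 trials/cell/run, 14 runs =
3,024 trials), fit two competing models, and compare them:

```r
library(avbci)
library(dplyr)

spec <- design_spec(n_trials_per_condition = 6, n_runs = 14)
truth <- observer_params("BCI-att_free",
  sigma_a = c(attA = 4.5, attV = 6), sigma_v = c(attA = 1.5, attV = 1.1),
  sigma_p = 12, p_common = 0.6)
trials <- make_design(spec) |> simulate_observer(truth, seed = 2)

fit <- fit_model(trials, "BCI-att_free", seed = 7)
fit
#> <avbci fit> BCI-att_free: logL = -965.5, scaled R2 = 0.888, k = 6, n = 3024
tidy(fit)
#> # A tibble: 6 x 2
#>   term         estimate
#>   <chr>           <dbl>
#> 1 sigma_a.attA    4.70
#> 2 sigma_a.attV    6.69
#> 3 sigma_v.attA    1.65
#> 4 sigma_v.attV    1.16
#> 5 sigma_p        12.1
#> 6 p_common        0.542
```

The fitted sensory noise is close to the generating values (4.5, 6, 1.5,
1.1), the causal prior is recovered at 0.54 (truth 0.6), and the model
explains 89% of the explainable variation in the discrete responses
(`scaled R2`). The weight-index analysis shows the signature dissociation —
the report effect grows with audiovisual disparity, the attention effect
does not:

```r
w <- weight_index(trials)
w |> group_by(report, disparity) |> summarise(w = mean(w), .groups = "drop")
#> # A tibble: 4 x 3
#>   report disparity     w
#>   <chr>      <dbl> <dbl>
#> 1 A              9 0.401
#> 2 A             18 0.179
#> 3 V              9 1.02
#> 4 V             18 1.02
```

The auditory-report index drops from 0.40 to 0.18 as disparity doubles
(segregation takes over), while the visual-report index stays near 1.
With several participants, `weight_effects_table()` runs the exhaustive
sign-permutation tests over all factorial effects.

The full pipeline (simulate → fit all six variants → group model selection
→ weight indices → decoding → permutation stats) is one call:

```r
cfg <- pipeline_config(n_participants = 12, seed = 1)
manifest <- run_pipeline(cfg, "out/")  # writes CSV/JSON per stage
```

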