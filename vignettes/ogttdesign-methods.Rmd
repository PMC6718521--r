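---
title: "Modeling glucose-insulin-incretin dynamics and designing ingestion patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glucose-insulin-incretin dynamics and designing ingestion patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttdesign)
```

## The model

`ogttdesign` implements an eight-state ODE model of the response of blood
glucose and four hormones to oral glucose ingestion. The states are the
glucose amount in the intestine $Intest_G$ [g], the incretins $GIP$ and
$GLP1$ [pM], the absorbed glucose pool $A_{GutG}$ [g], blood glucose $G$
[mg/dL], insulin $I$ [pM], C-peptide $CP$ [pM], and a dimensionless
"effective insulin" $X$ representing insulin action at target organs:

$$
\begin{aligned}
\dot{Intest_G} &= v_1 - v_6, &
\dot{GIP} &= v_2 + v_3, &
\dot{GLP1} &= v_4 + v_5, &
\dot{A}_{GutG} &= v_6 - v_7,\\
\dot{G} &= v_7/V + v_8 - v_9, &
\dot{I} &= v_{10} - v_{11}, &
\dot{CP} &= v_{10} - v_{12}, &
\dot{X} &= v_{11}/k_{11} - v_{13}.
\end{aligned}
$$

Ingestion ($v_1$, piecewise constant in g/min) fills the intestinal pool;
saturating absorption ($v_6$) feeds the absorbed pool, which appears in
blood ($v_7$, divided by the volume-like constant $V$ to convert g/min into
(mg/dL)/min). Hepatic glucose production ($v_8$) is inhibited by $X$;
uptake ($v_9 = k_9 G X$) is bilinear in glucose and insulin action.
Incretin secretion ($v_2$, $v_4$) is driven by intestinal glucose and each
incretin relaxes to its basal level ($v_3$, $v_5$ — these are *signed*
relaxation fluxes, negative above basal). Insulin and C-peptide share one
secretion flux,

$$v_{10} = k_{10}\,(G + a\,GIP + b\,G\,GIP + c\,GLP1 + d\,G\,GLP1),$$

whose four coupling coefficients encode independent ($a$, $c$) and
glucose-cooperative ($b$, $d$) incretin action. A *model structure* fixes a
subset of $\{a,b,c,d\}$ to zero, or removes the GLP-1 equation entirely
(then the system has 7 states and loses $k_4$, $k_5$, $L_4$, $GLP1(0)$).

### Steady-state closure

The pre-ingestion state is assumed stationary, which determines
$k_9, k_{11}, k_{12}, k_{13}$ and the basal levels $GIP_B$, $GLP1_B$ from
the free parameters and initial levels (see `close_parameters()`). This
closure is exact: with zero ingestion, the right-hand side at the initial
state is the zero vector to machine precision, and a 480-min zero-ingestion
simulation stays flat to solver tolerance — both are asserted in the test
suite for 1,000 random admissible parameter draws. The full model estimates
18 kinetic parameters and 6 initial levels; everything else is derived.

## Simulation

Two integrators are provided and cross-checked against each other:

* **Fixed-step forward Euler** (compiled): used wherever determinism and
  tight inner loops matter. The objective of the pattern optimizer is
  evaluated at a 0.01-min step during search and re-evaluated at a
  conservative 0.001-min step for reported values. The step must divide every ingestion-event boundary, so
  the grid never straddles a flux discontinuity; the 0.5-min bolus windows
  align exactly by construction.
* **Adaptive `lsoda`** (via `deSolve`), integrated segment-wise between
  event boundaries so discontinuous forcing is handled exactly.

Off-grid sampling interpolates linearly; at the default steps the
interpolation error is negligible relative to measurement noise. The
solver does not clamp negative states by default — a `floor_at_zero`
option exists for deliberately coarse steps — because silent clamping
would hide stiffness artifacts; instead, non-finite states abort with the
failing time attached.

## Synthetic subjects

Real measurements are replaced by a generator that emulates the
six-condition design: doses of 25/50/75 g delivered as a 0.5-min bolus or
a 2-h continuous ingestion (`standard_protocols()`), sampled on a default
grid of 12 times spanning 0–240 min, denser early. Three bundled
ground-truth subjects (`fixture_subject()`) carry the structures
`GLP1-free, a=0`, `b=c=0`, and `a=c=d=0`, so recovery tests target
realistic sparse structures. Their parameter values are fixture choices
tuned once for physiological plausibility (fasting glucose ~90 mg/dL
peaking ~145 mg/dL at ~35 min under a 50-g bolus, return to baseline
within 4 h, dose-monotone peaks, incretin peaks within ~30 min); they are
not estimates of any real person.

Measurement noise is Gaussian per series with SD equal to a fraction
(default 0.05) of that series' simulated range, clipped at zero —
consistent with the normal-residual assumption under which the AIC
comparison below is derived. The generator does **not** emulate assay
error structure, interstitial sensor delays, between-day physiological
drift, or correlated residuals; passing recovery tests therefore shows
identifiability under the model's own assumptions, not robustness to real
human data.

## Fitting

The objective is the min–max-normalized residual sum of squares

$$RSS = \sum_i \sum_k \sum_t
\left[\frac{x^{sim}_{i,k}(t) - x^{exp}_{i,k}(t)}
{\max_t x^{exp}_{i,k}(t) - \min_t x^{exp}_{i,k}(t)}\right]^2$$

over conditions, species and times, with one shared parameter set per
subject (the subject's physiology is assumed constant across conditions).
Excluded conditions contribute nothing; a flat series (max = min) is a
validation error naming the series.

Parameters are searched on a log scale. Kinetic parameters get the
scale-free default bounds $[10^{-4}, 10^{4}]$; initial levels are bounded
by 0.1–10 times the fasting (earliest) measurements, and the unobserved
$X(0)$ by $[0.1, 10]$.

`fit_subject()` runs, per trial:

1. a self-adaptive evolutionary-programming (EP) search (log-normal
   mutation scales, stochastic q-tournament survival, no crossover),
2. Levenberg–Marquardt polish (`minpack.lm`) of the best EP candidates,
   exploiting the least-squares structure of the objective,
3. a second EP phase re-seeded with the polished optimum (memetic step),
   polished again,
4. coordinate-subset basin hops: a few parameters are kicked log-normally
   and re-polished, keeping improvements,
5. a final Nelder–Mead simplex descent.

A pure EP-plus-simplex pipeline needs cluster scale to be reliable on
this landscape (think population 5000 × 5000 generations × 40 trials);
the desk-scale defaults here (population 200, 80 generations, 2 trials)
buy the missing global power back with the LM-based memetic steps, which
are dramatically cheaper per unit of progress on a least-squares
objective. A candidate whose
integration blows up is given a soft barrier graded by the blow-up time,
so the refiner sees a slope back toward the feasible region rather than a
flat plateau. All stages are deterministic given the settings seed.

## Model selection

Candidate structures are all $2^4$ on/off combinations of $\{a,b,c,d\}$,
optionally extended by the four structurally GLP-1-free variants — a
systematic enumeration, not a transcription of any published candidate
table. Each candidate is fitted to the identical data and scored by

$$AIC = N \log RSS + 2K$$

(natural log), where $N$ is the number of data points and $K$ counts every
estimated quantity, *including* free initial levels (full model:
$18 + 6 = 24$); this convention is recorded in the output so comparisons
are internally consistent. Ties are broken by smaller $K$, then candidate
order, and the tie-break is recorded. Mixing GLP-1-free candidates with
GLP-1-containing ones on data that include GLP-1 measurements changes $N$
(the GLP-1-free model cannot predict that series), so `select_model()`
warns and the two families are best compared in separate rounds, matching
how such selections are run in practice.

AIC's $2K$ penalty distinguishes nested candidates only when each
candidate's RSS is within about $2/N$ (relative) of its true minimum —
roughly half a percent here. Reaching that accuracy with independent
desk-scale fits for ~20 candidates is not affordable, so
`select_model()` defaults to *lattice warm-starting*: the richest
structure in each family is fitted with the full global pipeline, and
every reduced candidate is LM-refined from the solutions of its
already-fitted supersets. For the candidates that decide the selection —
those whose zeroed coefficients are already near zero in the richer fit —
this lands essentially at their optimum; candidates missing a genuinely
needed term stall at a high RSS and lose regardless. Fully independent
per-candidate fitting remains available via `warm_start = FALSE`.

## Pattern optimization

The inverse problem: distribute a fixed total (default 50 g) in integer
grams over the 13 slots $\{0, 5, \ldots, 60\}$ min, with at least 1 g at
0 min, minimizing the simulated peak of glucose ($G_{Max}$) or insulin
($I_{Max}$) over $T = 480$ min. The feasible set is astronomically large
(spreading the 49 free grams over 14 categories gives
$62!/(49!\,13!) = \binom{62}{13} \approx 8.3\times10^{12}$ patterns;
the 13-slot count proper is $\binom{61}{12}$), so the search is again
evolutionary programming, with the operators specific to this problem:

* **Initialization**: the bolus pattern, the (1 g @ 0, 49 g @ 60) split,
  and random patterns (1 g pinned at 0, the rest multinomial over all
  slots).
* **Mutation**: remove 1 g at slot 0; L times, move 1 g between uniformly
  chosen slots if the source has one; add 1 g back at slot 0. Total mass
  and the first-slot floor are conserved by construction. L anneals from
  20 down by 1 every 25 generations. "The source contains a gram" is read
  as *at least* 1 g (slots may empty); the strict reading is available via
  `source_rule = "more_than_1"`.
* **Selection**: each of the 2N parents+children meets M = N/5 random
  opponents; its score is the number of opponents with strictly larger
  objective; the top N by score survive. Score ties are broken by smaller
  objective, then insertion order — the tie-break is our choice (the
  construction is silent on it) and makes seeded runs exactly
  reproducible. No crossover: recombining two patterns under the fixed
  total-mass constraint has no natural operator.
* The incumbent best is tracked globally across mutations (elitist), so
  the best-objective trace is non-increasing, and the final value is
  re-evaluated at the 0.001-min step.

An exhaustive enumeration oracle (`enumerate_patterns()`) covers small
instances; the suite checks that the EP attains the enumerated minimum on
reduced problems, and that the optimized 50-g pattern beats both the bolus
and the 1-h continuous schedule on the fixture subjects.

## Numerical choices and limitations

* Default problem sizes (fitting population 200 × 80 × 2 trials; optimizer
  100 × 100 × 2; Euler steps 0.05 min for fitting, 0.01/0.001 min for
  optimization) are the package's desk-scale choices; every full-scale
  setting is reachable through the settings objects.
* The GLP-1-free variant is a structural removal (7 states), not a pinned
  constant, so AIC parameter counts are unambiguous. Internally the
  compiled core carries a dormant zero row for the GLP-1 state; the
  placeholder Michaelis constant is 1 so the dormant flux is well-defined.
* The closure requires strictly positive initial levels; zero or negative
  values are domain errors, not silent fixes.
* Identifiability is practical, not structural: distinct parameter sets
  can produce near-identical trajectories, which is why recovery criteria
  are stated on trajectories and peaks rather than parameter values.
* No glucagon, free-fatty-acid or autonomic extensions; no sensor-delay
  modeling; no real-valued dose patterns; no confidence intervals (point
  estimates only, as in the procedure this package implements).

## A worked pipeline

```{r pipeline, eval = FALSE}
truth <- fixture_subject("A")
dataset <- generate_dataset(truth, noise = 0.05, seed = 1)
fit <- fit_subject(dataset, truth$structure, fit_settings(seed = 2))
opt <- optimize_pattern(fit$subject, "glucose_peak",
                        pattern_settings(seed = 3))
tidy(opt)          # the optimized pattern as time_min / grams
glance(opt)        # objective value and search bookkeeping
autoplot(opt)
```

`run_pipeline()` chains the stages and writes every artifact (dataset,
subject JSONs, AIC table, pattern TSVs, trajectory CSVs) with the seed and
a configuration hash embedded.
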