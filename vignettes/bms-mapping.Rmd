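---
title: "Voxel-wise Bayesian model selection maps for M/EEG: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise Bayesian model selection maps for M/EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsmaps)
```

# The problem

Given epoched M/EEG data from a group of subjects and two or more competing
hypotheses about how experimental conditions order the evoked response
amplitudes, we want maps — over the scalp and peristimulus time, or over
source space — of how probable each hypothesis is for a randomly chosen
member of the population. `bmsmaps` implements the full chain:

1. **Scalp-time volumes.** Each trial's channels x time data are interpolated
   onto a regular scalp grid; the third voxel axis is peristimulus time.
2. **Per-voxel model evidence.** At every voxel, each candidate model is a
   Bayesian GLM whose single effect regressor encodes the model's
   condition weights. Variational Bayes (VB) yields the free energy `F`,
   used as the approximate log model evidence.
3. **Group inference.** At every voxel, a random-effects (RFX) Dirichlet
   model over group model frequencies is inverted from the
   subjects x models evidence matrix.
4. **Maps and clusters.** Posterior probability maps (PPMs) and exceedance
   probability maps (EPMs) are thresholded and reduced to cluster tables
   with extents and peaks.

# The per-voxel evidence model

At one voxel the amplitude of trial $i$ is modelled as
$y_i = x_i \beta + \mu + \varepsilon_i$, $\varepsilon_i \sim N(0, \lambda^{-1})$,
where $x_i$ is the model's covariate weight for the trial's condition after
mean-centring and unit-variance scaling, and $\mu$ is an intercept. Priors
are $\beta, \mu \sim N(0, s_0^{-1})$ and $\lambda \sim \text{Gamma}(a_0, b_0)$
with weakly informative defaults $s_0 = a_0 = b_0 = 10^{-3}$ (configurable in
`vb_priors()`; the defaults matter little beyond $n \approx 20$ trials).

Inference uses a mean-field factorisation $q(\beta, \mu)\,q(\lambda)$
optimised by coordinate ascent. The free energy

$$F = \mathbb{E}_q[\log p(y \mid \theta)] - \mathrm{KL}(q \,\|\, p)$$

is a lower bound on the log model evidence that tightens monotonically: the
bound equals the log evidence exactly when the KL term vanishes, and every
update increases $F$ (the test suite asserts non-decrease to $10^{-8}$).
On 20-trial problems the converged bound sits within about 0.05 nats of the
exact evidence (computed by marginalising the coefficients analytically and
integrating the noise precision numerically), so model comparisons based on
$F$ are effectively comparisons of log evidence. Convergence is declared
when $\Delta F < 10^{-4}$ nats (default), within 128 iterations.

Two numerical points. First, the coordinate updates are solved in the
eigenbasis of $X^\top X$, so thousands of voxels sharing one design are fit
simultaneously as elementwise vector operations; a full 21-subject,
32 x 32 x 80-voxel, two-model run takes on the order of a minute. Second,
errors are modelled as independent across trials; no autoregressive or
spatial coefficient priors are used. Spatial regularisation is applied
afterwards instead, by smoothing each log-evidence image with a mask-aware
Gaussian kernel (default FWHM 1 voxel per axis; the smoothing
renormalises by the smoothed mask so edge voxels average in-mask
neighbours only).

## Why the effect regressor is variance-scaled

The competing condition-weight vectors (for the four-condition
attention-by-prediction design: Opposition `[1, 2, 2, 3]` and Interaction
`[1, 4, 2, 3]` over UP, AP, UU, AU) have different norms after centring
(`[-1, 0, 0, 1]` vs `[-1.5, 1.5, -0.5, 0.5]`). Under a fixed coefficient
prior, a larger regressor norm means a larger effective complexity penalty,
so at pure-noise voxels the smaller-norm model would win systematically —
we measured a null posterior model probability of 0.88 instead of 0.5
before scaling. `build_design()` therefore scales the centred covariate to
unit sample variance (disable with `scale = FALSE`), which equalises the
Occam penalty and centres the null log Bayes factor on zero. Model
selection then compares the *patterns*, which is the scientific question.

# Group-level random-effects inference

Group model frequencies $r$ carry a Dirichlet prior
$\mathrm{Dir}(\alpha_0)$, each subject's generating model is a draw from
$r$, and subjects contribute their per-model log evidences. The variational
fixed point iterates

$$u_{nk} = \exp\!\big(\log p(y_n \mid m_k) + \psi(\alpha_k) - \psi(\textstyle\sum_j \alpha_j)\big),
\quad \beta_k = \sum_n \frac{u_{nk}}{\sum_j u_{nj}}, \quad \alpha = \alpha_0 + \beta,$$

until $\max|\Delta\alpha| < 10^{-6}$ (cap $10^4$ iterations). $u$ rows are
computed in the log domain with the per-row maximum subtracted — exact, by
shift invariance of the update — so decisive evidences cannot overflow.
$\alpha_0$ defaults to all ones (no models seen a priori). The bookkeeping
identity $\sum\alpha = \sum\alpha_0 + N$ holds at every voxel and is
asserted after every run.

From the converged $\alpha$:

* **PPM**: $\bar r_k = \alpha_k / \sum_j \alpha_j$, the probability that
  model $k$ generated a randomly selected subject's data.
* **EPM**: $\varphi_k = P(r_k > r_j\ \forall j \ne k \mid \alpha)$. For two
  models this is the closed Beta form
  $\varphi_1 = P(\mathrm{Beta}(\alpha_1, \alpha_2) > \tfrac12)$; for more,
  Dirichlet Monte Carlo with a fixed seed ($10^6$ draws by default, standard
  errors reported).

Note that PPMs and EPMs are *different* numbers even with two models:
$\alpha = [3, 1]$ gives $\bar r_1 = 0.75$ but $\varphi_1 = 1 - 0.5^3 = 0.875$.
Statements that the two coincide for two models conflate the expected
frequency with the probability of exceedance; `bmsmaps` computes both
literally and reports them separately.

Fixed-effects alternatives are provided for comparison:
`group_bayes_factor()` multiplies per-subject Bayes factors (log domain)
and is driven arbitrarily far by a single outlier (nine subjects at +1 nat
and one at −50 give a log GBF of −41), whereas the RFX posterior keeps
$\bar r_1 > 0.5$ — the motivation for random effects at the group level.
`bayes_factor_to_posterior()` maps the conventional strong-evidence
landmark BF = 20 to $20/21 \approx 0.952$.

# The synthetic-data generator

`simulate_group()` emulates the four-condition study design with known
ground truth. Channels sit on a regular 8 x 8 grid over the unit square
(64 channels, mirroring a 64-electrode montage); trial amplitude at channel
$c$, sample $t$ is

$$\text{intercept} + \text{effect\_size} \times w_k(\text{condition})
  \times g(c)\, h(t) + N(0, \text{noise\_sd}^2),$$

with $g$ an indicator over a 2 x 2 block of effect channels and $h$ a
boxcar over a 10-sample window — i.i.d. Gaussian trial noise, exactly the
likelihood the evidence model assumes. The voxel-space ground truth is
derived from the interpolation geometry: effect voxels are those whose
barycentric support lies entirely inside the effect channels (a contiguous
~4 x 4 to 5 x 5 spatial blob on a 32 x 32 grid, times the effect window);
voxels with partial support form a recorded halo and are excluded from
null-voxel checks. Each subject has an independent child random stream
derived from the root seed, so adding subjects never perturbs earlier ones.
Default group size is 21 subjects.

What the generator does *not* emulate: realistic ERP waveform shapes,
volume conduction, correlated sensor noise, artifacts, or source-space
geometry. Passing tests therefore demonstrate the statistical machinery
under its own assumptions, not performance on real recordings. Effect size
and noise defaults (1 and 1) are chosen for test power, not physiological
realism.

`simulate_log_evidences()` skips the GLM stage entirely: each subject's
generating model is drawn from stated frequencies and that model's log
evidence exceeds the others' by draws centred on `evidence_scale`, with
1-nat jitter per entry — a direct fixture for the group-level update.

# Maps, thresholds and clusters

`threshold_map()` uses strict inequality (probabilities *exceeding* the
threshold), matching the usual display conventions: 75% for scalp-time
maps, 50% for source maps. `extract_clusters()` labels connected
components under face (6, default), face+edge (18) or face+edge+corner
(26) connectivity, drops clusters below a minimum extent (the conventional
16, or 0 to keep everything), and reports extents $K_E$ and peaks with a
deterministic lexicographic tie-break. Source-space images that code
out-of-support voxels as NaN are repaired with `sanitize_source_map()`
(NaN to zero, count reported) before evidence mapping.

# Known limitations, measured

Two behaviours of the method itself — not implementation defects, both
reproduced by the acceptance script — deserve attention.

**Null overconfidence.** At a pure-noise voxel the two models' free
energies differ by a random amount of order 1 nat (the difference of two
correlated quadratic forms; it does not shrink with trial count). Across
21 subjects the RFX fixed point amplifies these fluctuations: the
per-voxel null PPM is centred on 0.5 but has a standard deviation of about
0.19, and roughly a third of null voxels exceed 0.6. Even the exact
hierarchical posterior (computed by assignment enumeration at small $N$)
has a null standard deviation of about 0.12 — the dispersion is inherent
to unprotected RFX model selection, which is why later literature
introduced protected exceedance probabilities (deliberately out of scope
here). Consequence: a planted heterogeneous effect whose PPM ceiling is
modest (a 14/7 split caps the PPM at $15/23 \approx 0.652$) cannot be
isolated from null fluctuation by thresholding alone; cluster tables over
such maps must be read with this in mind.

**Weak-evidence VB bias.** Against exact enumeration of the assignment
posterior ($N \le 4$, two models), the fixed point's $\bar r_1$ agrees to
better than 0.02 when per-subject evidence differences are decisive
(about 10 nats) but can deviate by up to about 0.08 when they are weak
(under 1 nat) — mean-field overconfidence. Group-level conclusions from
near-uninformative evidence matrices should not be over-read.

**Sampling limits on frequency recovery.** With 50 subjects whose
generating models are drawn at frequencies [0.7, 0.3] and 3-nat evidence,
the recovered $\bar r_1$ is centred on the truth (mean about 0.72) but the
binomial variability of the assignments alone gives it a standard
deviation of at least 0.065; about three quarters of seeds land within
±0.1 of the true frequency. No estimator that respects the data can beat
the binomial floor.

# Numerical and design choices

* Grid size defaults to 32 x 32 (the conventional scalp raster);
  interpolation is piecewise-linear barycentric on a Delaunay triangulation
  of the channel layout, exact at channels, bounded by the channel range,
  no extrapolation beyond the hull (masked, NaN on disk, explicit logical
  mask in memory).
* A −100..400 ms epoch at 200 Hz yields 101 time slices; the time axis is
  stored as the third NIfTI dimension with the sampling interval as its
  voxel size.
* Evidence-image smoothing defaults to FWHM 1 voxel per axis
  ($\sigma = \text{FWHM}/\sqrt{8\ln 2}$), applied to scalp-time and source
  images alike; set `smooth_fwhm = 0` to disable.
* Problem sizes used by the test suite and acceptance script — 12 x 12
  grids with 4-subject groups for unit checks, one full 21-subject
  32 x 32 x 80 run for the end-to-end map — were chosen so the whole suite
  completes in a few minutes while still exercising every code path at the
  study's full spatial scale once.
* The pipeline runner (`run_pipeline()`) drives
  simulate/images/evidence/RFX/maps from one validated config, writes a
  manifest with checksums and seeds for every stage, and reloads the
  expensive evidence stage when an identical configuration has already
  produced it. A thin command-line wrapper (`inst/cli/bmsmaps.R`) exposes
  the same stages as subcommands.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_group(n_subjects = 21, assignments = rep(c(1, 2), c(14, 7)),
                      effect_size = 1.5, noise_sd = 1, seed = 11)
images <- lapply(sim$datasets, build_scalp_time_volumes)
maps <- evidence_maps(images, list(opposition_model(), interaction_model()))
result <- voxelwise_bms(maps)
glance(result)
mean(result$ppm[1, sim$truth$effect_region])   # ~ 15/23 = 0.652
bms_report(result, threshold = 0.6, min_size = 16)$clusters
autoplot(result, model = "Opposition", threshold = 0.5)
```

The blob average lands on the analytic fixed point for a 14/7 split
($\alpha = [15, 8]$, PPM $15/23$), which the single-voxel `rfx_update()`
reproduces independently on the realised evidence matrix.
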