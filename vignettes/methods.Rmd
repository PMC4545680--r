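---
title: "Models and methods behind painconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind painconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painconn)
```

painconn re-implements, as a tested pipeline, the analysis chain of an
empathy-for-pain experiment in which adults judged whether photographed
hands and feet were in painful situations while skin conductance and fMRI
were recorded: signal-detection scoring of the binary judgments,
event-related GLMs of the skin-conductance and region-level BOLD signals,
bilinear dynamic causal modelling (DCM) of a three-region network (anterior
insular cortex, AIC; extrastriate body area, EBA; lateral prefrontal
cortex, LPFC), random-effects and family-level Bayesian model selection,
bootstrap group inference, and a Monte Carlo cluster-extent threshold.
Because no subject-level data are available, a synthetic-data generator
reproduces the study design with known ground truth, so every stage of the
pipeline has a recovery test.

## The experimental design the generator emulates

Each synthetic subject completes 4 runs of 64 trials. The 8 trial types
(left/right x hand/foot x painful/nonpainful) each occur 8 times per run at
a fixed 5.5-s stimulus onset asynchrony (2.5 s of stimulus and response
window, 3 s of fixation), padded by 30-s fixation at both ends of the run,
which is long enough for both electrodermal and hemodynamic responses to
return to baseline. Counterbalancing is implemented by walking a seeded
Eulerian circuit on the complete directed graph (with self-loops) over the
8 types: the 63 within-run transitions then use 63 *distinct* ordered type
pairs, the closest a 64-trial run can come to "every type preceded and
followed by every type equally often". The study states the
counterbalancing goal but not a construction; the Eulerian realisation is
this package's choice. Inter-trial jitter is not modelled: the published
design used a fixed 5.5-s SOA and so do we.

## Behavior: equal-variance signal detection

Responses are generated from (and scored by) the equal-variance Gaussian
observer. With sensitivity $d'$ and criterion $c$ (distance from the
neutral point), a painful trial is judged painful with probability
$\Phi(d'/2 - c)$ and a nonpainful trial with probability
$\Phi(-d'/2 - c)$. Scoring inverts the observed rates:
$d' = \Phi^{-1}(H) - \Phi^{-1}(F)$, the bias is the density ratio at the
criterion $\beta = f_s(\lambda)/f_n(\lambda) = \exp[(z_F^2 - z_H^2)/2]$,
and $c = -(z_H + z_F)/2$. We parameterise the generator by $c$ and derive
$\beta$, since one free parameter suffices. Hit/false-alarm rates of
exactly 0 or 1 make the naive formula infinite; the package reproduces the
naive formula by default and offers the standard $1/(2N)$ correction as an
option, since the original analysis does not state any correction. Trials
without a recorded button press are excluded from both numerator and
denominator, with the count reported.

The default control-group population ($d' = 3.03$, $c = -0.04$) matches
the group-mean hit and false-alarm rates printed for controls (0.94/0.07),
and the ASD offsets ($-0.77$ on $d'$) reproduce the printed ASD rates
(0.85/0.11).

## Skin conductance: canonical-response GLM

Phasic skin-conductance responses are modelled as a linear time-invariant
system: a trial with amplitude $a$ adds $a \cdot h(t - t_{\text{onset}})$,
where $h$ is a canonical impulse response. The original analysis delegates
the response function to its analysis toolbox; here $h$ is a gamma-family
curve $t^{k-1} e^{-t/\theta}$ with peak normalised to 1 at a configurable
latency (default 3.5 s, shape 3), which has the characteristic fast rise
and slow decay. The two-regressor analysis convolves "all images" (every
onset) and "painful images" (painful onsets only) with $h$, so the painful
coefficient measures arousal specific to pain over and above the common
response — mirroring the BOLD design below. Single-trial amplitudes are
estimated by the iterated model in which one trial at a time receives its
own column next to "all other images" and "all other painful images".

Both data and design are band-pass filtered with a first-order Butterworth
filter, 0.01–0.12 Hz, before ordinary least squares. The filter is applied
forward and backward (zero phase); the original paper does not state phase
handling, and a causal single pass would shift the regressors against the
data. Because a GLM is equivariant under any common linear filtering of
data and design, noise-free amplitudes are recovered through the filter —
a property the tests assert at 5%. Normalisation ("nondimensional" betas)
is z-scoring of each run's filtered trace, making betas invariant to
electrode-gain rescaling; normalising betas instead of traces would only
change the scale convention. Traces default to 100 Hz (the acquisition
rate of 2000 Hz is supported but needlessly slow for simulation); a slow
sinusoid-plus-trend drift is injected by the generator since the band-pass
step exists precisely because real traces drift.

## Region-level BOLD GLM

Event regressors are delta trains at the onsets convolved with a
double-gamma canonical HRF (peak 6 s, undershoot 16 s, ratio 1/6) on a
16-bins-per-TR microtime grid (156.25 ms at TR 2.5 s) and sampled at the
volume times; 165 volumes per run. The same two-event parameterisation is
used as for skin conductance, and the package also provides the separate
painful/nonpainful parameterisation to demonstrate that the
painful-images coefficient of one equals the painful-minus-nonpainful
contrast of the other to numerical precision (a reparameterisation
identity, asserted at 1e-8). Trial-wise skin-conductance amplitudes enter
as a parametric modulator: mean-centred within run (preventing
collinearity with "all images"), placed as scaled deltas at the onsets,
and convolved identically. Six motion-like covariates can be appended.
Fitting is plain OLS per region — no autocorrelation whitening, a
documented simplification acceptable at region scale. Multivoxel regions
are summarised by the principal eigenvariate: the leading
singular-vector time course of the centred data, scaled by the singular
value over $\sqrt{n}$ and sign-aligned with the mean series.

## The dynamic causal model

Neural dynamics follow the bilinear state equation
$\dot{x} = (A + u_2 B)\,x + C u$, with $u_1$ ("all images") driving EBA in
every model and $u_2$ ("painful images") modulating connectivity. The
leading diagonals of $A$ and $B$ are log-scale parameters: the effective
self-connection under pain is $-0.5\,e^{A_{ii} + B_{ii}}$ Hz, so negative
diagonal $B$ entries attenuate self-inhibition — disinhibition, the
operational index of increased regional gain (interoceptive precision in
the source study's interpretation). Each region's neural state drives a
balloon-type hemodynamic model (signal decay 0.65 s$^{-1}$,
autoregulation 0.41 s$^{-1}$, transit time 0.98 s, stiffness 0.32, resting
extraction 0.34, venous volume fraction 0.04 — literature defaults, fixed
rather than estimated to keep desk-scale inversion identifiable), and the
BOLD observation uses the classic three-term expression. Integration is
fourth-order Runge-Kutta on the 156.25-ms microtime grid; against an
independent fine-step solver the sampled output agrees to better than
$10^{-3}$ relative error.

The experimental inputs are unit boxcars over the 2.5-s stimulus window by
default. Single-bin "stick" inputs are available (`input_duration = 0`),
but a 156-ms stick carries roughly one sixteenth of the modulatory energy
of the epoch during which the stimulus is actually on screen, and with it
the self-connection modulations are close to unidentifiable at realistic
noise; the boxcar matches the stimulus duration and is the package
default.

The model space contains eight variants: painful images modulate no
self-connections (models 1–4) or all three (models 5–8), crossed with no /
forward (AIC, EBA to LPFC) / backward (LPFC to AIC, EBA) / reciprocal
extrinsic modulation. The direct AIC–EBA links and the driving input are
never modulated; all six extrinsic fixed connections and three
self-connections are always present in $A$.

### Inversion

`invert_dcm()` maximises the Laplace free energy — accuracy minus
complexity — by Gauss-Newton/EM with a Levenberg-Marquardt trust region:
candidate steps are accepted only if the free energy increases, so the
iteration trace is monotone by construction; when no step helps, the
scheme stops (observed to coincide with a flat optimum of the objective).
Priors are zero-mean Gaussians, variance 1/16 for extrinsic fixed
connections, log-scale self terms and modulatory entries, 1/4 for driving
gains. Initialisation is at the prior mean and the Jacobian is computed by
forward differences on the compiled integrator, making fits deterministic
given data and priors. Observation noise is one precision per region,
updated in closed form ($\lambda_r = N/\mathrm{RSS}_r$) inside each
accepted step. Noise-free data are recovered essentially exactly from
zero-centred priors; at the study's noise level (signal-to-noise ratio 2)
the self-modulation posteriors are strongly shrunk toward the prior, but
their across-subject ordering is preserved, which is what group inference
uses.

Each run is fitted separately ("four DCMs for the four sessions") and a
subject's log evidence is the sum of run free energies. Session posteriors
are combined parameter-wise; the default is the plain average. Two
alternatives are implemented and were measured to be worse at recovering
ground truth: softmax-of-evidence session weights saturate onto a single
run (free energies differ across runs by tens of log-units from noise
alone), and precision weighting inherits the miscalibration of the
per-session Laplace covariances at flat optima.

## Model and family selection

Random-effects Bayesian model selection treats each subject's best model
as a draw from population frequencies $r \sim \mathrm{Dir}(\alpha_0)$,
updated by the standard variational scheme (uniform prior counts,
occupancy updates to relative tolerance $10^{-8}$); exceedance
probabilities come from $10^6$ seeded Dirichlet draws. Family-level
inference (models 1–4, "no intrinsic modulation", versus 5–8) corrects for
family size through the prior (counts $1/s_f$, giving families equal
mass). The variational update is unreliable under non-uniform prior
counts — with uninformative evidence its fixed point concentrates on the
smaller family although the exact posterior equals the prior — so family
quantities are computed by Gibbs sampling of the exact hierarchical model
(alternately sampling subject assignments and frequencies) and
aggregating the frequency samples over families. With uninformative
evidence this yields 0.5/0.5 for families of sizes 6 and 2, as it should.

## Group statistics

The group-difference test follows the published resampling recipe: pool
both groups, draw surrogate groups of the original sizes, compute the
two-sample $t$, repeat 10,000 times, and report
$p = (b + 1)/(B + 1)$ where $b$ counts surrogate statistics at least as
extreme (two-sided by default) as the observed one. The printed recipe
("selected randomly ... from the whole group") is ambiguous between label
permutation and independent resampling with replacement; both are
implemented, with permutation — which has exact null guarantees — as the
default and the mode recorded in the result. One-sample $t$ tests,
Pearson correlations, the Fisher-$z$ test for the difference of two
independent correlations, and Bonferroni correction wrap the standard
closed forms.

## Cluster-extent threshold

The whole-volume correction simulates null statistic maps: draw white
Gaussian noise, smooth with an 8-mm FWHM Gaussian (separable kernel,
truncated at 4 SD, reflecting boundaries), renormalise to unit variance,
threshold at the per-voxel critical value, and tabulate contiguous
cluster sizes (face connectivity by default). The printed procedure
leaves four choices open, all explicit in `cluster_sim_config()`:

* **Grid of the null noise.** The default simulates directly on the 2-mm
  resampled grid (120 x 120 x 80 for the study's 240-mm field of view and
  40 slices), because in the actual analysis images were resampled to
  2 mm *before* the 8-mm smoothing — the null field should live where the
  statistic maps live. Simulating on the 64 x 64 x 40 acquisition grid
  with trilinear resampling is available.
* **Sidedness.** Two-sided thresholding ($|z| \ge 1.96$ at
  $\alpha = 0.05$) by default, since group contrasts were tested in both
  directions; one-sided is available.
* **Extent probability.** The default tallies *all* null clusters across
  iterations and takes the fraction at least $k$ voxels large, choosing
  the smallest $k$ below the corrected level. The per-iteration
  *maximum* cluster size (a familywise calibration) is available as an
  option; it yields thresholds several times larger and is not what
  produced the published value.
* **Connectivity.** 6, 18 or 26; measured to change the threshold by only
  a few voxels.

Under the defaults, 1000 iterations yield an extent threshold of about
113 resampled voxels (seed-to-seed spread of a few voxels), matching the
published criterion of 120 contiguous resampled voxels. The full-volume
run takes roughly two and a half minutes on one core.

## The synthetic cohort and what passing tests show

`generate_group()` draws per-subject true parameters around control-group
means (sensitivity 3.03; skin-conductance amplitudes 0.5 and 0.05 uS;
self-modulations $-0.4$ on the log scale for all three regions, matching
the reported disinhibition of all regions under the winning model; traits
EQ 42, TAS-20 40) with between-subject spreads, and applies ASD offsets
(defaults: $-0.77$ sensitivity, $-0.5$ further AIC self-modulation, lower
overall but higher pain-specific skin conductance, lower EQ, higher
TAS-20). Extrinsic couplings are fixed across subjects at moderate values
(0.05–0.15 Hz); only the self-modulations vary. All draws derive from one
seed, so the same seed reproduces the same cohort bit for bit.

The generator produces data exactly matching the analysis assumptions:
Gaussian white observation noise, a shared canonical response shape, no
motion, no scanner drift, no serial correlation, and a population that
really does follow model 8. Passing recovery tests therefore demonstrate
the internal consistency and correctness of the implementation — that the
estimators recover what the generative model planted, at the study's
sample sizes and noise levels — not that the original biological
conclusions are correct, and not robustness to the many ways real data
violate these assumptions.

Problem sizes used by the test-suite and acceptance computations (chosen
as representative desk-scale analogues of the study): 20 subjects for
model-recovery and selection checks, 15 per group for group-difference
power, 500 replicates for type-I calibration, 1000 iterations for the
cluster simulation, and $10^5$ trials for behavioral rate convergence.

## Numerical choices and limitations

Ties, degenerate inputs and tolerances: extreme rates error under the
naive formulas and are corrected only on request; zero-variance inputs to
the statistics error rather than returning NaN; the bilinear system must
be stable at rest (all eigenvalues of the zero-input Jacobian negative)
and the integrator aborts with a diagnostic on divergence, which can
happen for strongly disinhibited draws whose pain-on dynamics are
transiently unstable. The inversion is a local optimiser: it is
deterministic, monotone in free energy, and can in principle stop at a
local optimum; random restarts are not enabled by default. Hemodynamic
parameters are not estimated. No voxelwise whole-brain analysis of real
images, no slice-timing/realignment/normalisation, no unequal-variance
signal detection, no stochastic or two-state DCM, and no protected
exceedance probabilities.
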