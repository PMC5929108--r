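---
title: "From effective to functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From effective to functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdcm)
```

## The scientific question

Resting-state fMRI reliably shows an *anticorrelation* between the core
default network (cDN: PCC, aMPFC, bilateral angular gyrus) and two
task-positive systems, the salience network (SN) and the dorsal attention
network (DAN). Correlation is symmetric, so it cannot say *which network
drives which*. This package implements the full modelling chain needed to
ask that question with directed (effective) connectivity: a generative
model from coupling rates to observable spectra, a Bayesian inversion, a
hierarchical group model, and the network-level statistics that rank the
three systems.

## The generative model

Neuronal activity in $n$ regions follows a linear stochastic differential
equation

$$\dot x(t) = A\,x(t) + v(t),$$

where $A$ (Hz) is the effective connectivity matrix — entry $A_{ij}$ is
the influence of region $j$ on the rate of change of region $i$ (column =
source, row = target; every reader and writer in the package asserts this
orientation). Diagonal entries are self-inhibition and must be negative;
stability requires every eigenvalue of $A$ to have negative real part.
The endogenous fluctuations $v$ have power-law spectra
$g_v(\omega) = \alpha\,\omega^{-\beta}$ (with $\omega = 2\pi f$ in rad/s;
$\beta = 0$ is white noise, $\beta = 1$ is the 1/f form typical of
spontaneous cortical activity). Each region's activity is observed through
a linearised balloon model — vasodilatory signal, inflow, venous volume,
deoxyhaemoglobin — reduced to a single convolution kernel $k(t)$ with
transfer function $K(\omega)$, plus additive observation noise with its
own (by default white) spectrum.

In the frequency domain the whole chain is one formula, the predicted
cross-spectral density (CSD):

$$G_y(\omega) = H(\omega)\,G_v(\omega)\,H(\omega)^* + G_e(\omega),
\qquad H(\omega) = K(\omega)\,(i\omega I - A)^{-1}.$$

Two closed-form checks pin the conventions down and are enforced in the
tests: a single region with $A = -a$, $\beta = 0$ and unit kernel has the
Lorentzian spectrum $\alpha/(a^2+\omega^2)$, and for any stable $A$ the
spectral integral $\frac{1}{2\pi}\int G\,d\omega$ equals the stationary
covariance solving $A\Sigma + \Sigma A^\top + \alpha I = 0$. Functional
connectivity (FC) is defined as the normalised cross-covariance at zero
lag, i.e. the Pearson correlation implied by (or computed from) the CSD.

The mapping from $A$ to FC is *degenerate*: it symmetrises and densifies.
A one-way connection produces a symmetric correlation, and regions with no
direct coupling can be strongly correlated through common input. That is
why anticorrelation cannot identify directionality, and why inversion of
the generative model is needed.

## The synthetic cohort

No subject data are distributable, so the package generates cohorts with
the statistical structure the analysis assumes: 15 regions in three
networks (4 cDN, 5 SN, 6 DAN, the packaged `load_region_fixture()` table
with MNI coordinates), 170 retained volumes at TR = 2 s per subject, 1/f
endogenous fluctuations, haemodynamic convolution, white observation
noise, and per-subject Gaussian variation (sd 0.05 Hz) of the off-diagonal
couplings around a group template.

The template's six between-network means are the reported values of the
three-network system: SN→cDN $-0.13$, DAN→cDN $-0.10$, cDN→SN $0.02$,
cDN→DAN $0.02$, SN→DAN $0.03$, DAN→SN $0.02$ Hz. Within-network coupling
and self-inhibition are free design constants; we use 0.1 Hz and
$-0.8$ Hz. These were chosen once, on stability grounds: with $m$ regions
in a network, the network's uniform mode has growth rate
`self + (m-1) * within`, so a 6-region network with within-coupling
0.2 Hz would need self-inhibition stronger than $-1$ Hz to be stable at
all. The pair (0.1, $-0.8$) leaves a spectral margin of about 0.36 Hz, so
subject-level perturbations at sd 0.05 Hz remain stable essentially
always (draws are rejected and resampled otherwise). With these choices
the model FC reproduces the target phenomenon — cDN↔(SN, DAN) block
correlations near $-0.4$, positive within-network blocks — which the
tests assert both for the analytic FC and for simulated cohorts.

Noise amplitudes are not reported quantities; we fix the endogenous
amplitude at $\alpha_v = 1$, $\beta_v = 1$ and the observation spectrum at
$\alpha_e = 0.005$ (white), giving a BOLD signal-to-noise ratio of about
10 in standard deviation — comfortable for eigenvariate summaries of
clean resting-state data. What the synthetic cohort does *not* emulate:
spatial preprocessing, motion artefacts, physiological confounds,
inter-site variation, or the twin structure of real cohorts. Passing
tests therefore demonstrate correctness of the machinery and
recoverability under the model's own assumptions, not robustness to the
full messiness of empirical fMRI.

Numerical integration uses Euler steps at `dt_sim = 0.1` s with a 64 s
burn-in — about 20-fold oversampling of the 0.25 Hz band. Euler
discretisation biases the fastest modes by a few percent at these rates;
the generator–estimator consistency test bounds the end-to-end effect.
The spectral synthesis of power-law noise zeroes the DC bin (nuisance
regression in resting-state pipelines removes ultraslow drift anyway).

## Spectral estimation and inversion

The data feature is the complex CSD, estimated with a multivariate
autoregressive (MAR) model fit by least squares and evaluated on a grid
of 64 linear bins from the fundamental frequency to 0.25 Hz. MAR order 8
is the default — on 170-volume series it gives smooth, stable spectra;
for long benchmark series order 16 resolves the 1/f divergence better
(the order is a setting, and ill-conditioned fits fall back to ridge with
a warning).

Inversion is variational Laplace: a Gaussian posterior over the parameter
vector (210 off-diagonal couplings, 15 self log-factors realised as
$-0.5\,e^\theta$ so diagonals stay negative, log-scalings of the two
spectral laws, and per-region transit-time deviations of the balloon
model; 225 intrinsic connectivity parameters in total) is updated by
Gauss–Newton ascent on the free energy $F = \text{accuracy} -
\text{complexity}$, with Levenberg–Marquardt damping and central
finite-difference Jacobians (step $10^{-4}$). Steps are accepted only if
they raise $F$, so the reported trajectory is monotone; the log-precision
hyperparameter of the observation model is profile-optimised under a
guard that never lets its update lower the objective. Convergence is
declared when $F$ changes by less than 0.01 over four consecutive
accepted steps (128 iterations maximum). The group pipeline uses a
looser profile ($\Delta F < 0.1$, 48 iterations) because its statistics
average over subjects and are insensitive to the slow tail of
single-subject ascent.

Two observation-model choices deserve justification:

* **Per-frequency weighting.** Residuals between data and predicted CSD
  are scaled by the mean diagonal magnitude of the data CSD at each
  frequency. Spectral estimates have sampling error roughly proportional
  to the spectrum itself (chi-squared, few degrees of freedom per bin);
  an unweighted Gaussian likelihood lets the huge low-frequency bins
  dominate and, in our benchmarks, destroys parameter recovery
  (correlation with truth 0.01 unweighted versus above 0.9 weighted on
  the 3-node benchmark). A single shared log-precision hyperparameter
  then scales the weighted residuals.
* **Priors.** Couplings have zero-mean priors with variance 1/64; when a
  functional connectivity matrix is supplied, connections with
  $|r| < 0.1$ are shrunk to 1/512 (functional connectivity furnishing
  priors on effective connectivity). Self-connection log-factors get
  variance 1/16 — wide enough to reach the $-0.8$ Hz regime of the
  template from the $-0.5$ Hz parameterisation centre at under two prior
  standard deviations; spectral and transit parameters get 1/64. The
  observation-noise exponent is fixed (white) by a zero prior variance.

## Group level: BMR, greedy search, BMA, PEB

Bayesian model reduction computes, in closed form, the posterior and
evidence of any model whose prior is a more precise (nested) version of
the full prior — switching a connection off means pinning it to mean 0
with variance $10^{-8}$. The greedy search sweeps all single-connection
prunings, jointly applies those whose evidence change is nonnegative
(falling back to the best single pruning when the joint model is worse),
and stops when every remaining pruning costs evidence. Accepting
$\Delta F \ge 0$ rather than $> 0$ matters in one edge case: when the
posterior equals the prior (uninformative data), every pruning changes
the evidence by exactly zero and parsimony should win, so flat parameters
are pruned and ties in the final ranking favour the smaller model. The
best 256 models (default) are combined by Bayesian model averaging with
softmax evidence weights and Gaussian moment matching. Model scores store
masks and evidence changes only; reduced posteriors are recomputed on
demand (they are closed-form), which keeps thousands of scored models
cheap in memory.

Parametric empirical Bayes treats the 225 intrinsic parameters as random
between-subject effects: $\theta_i = (x_i^\top \otimes I)\beta +
\varepsilon_i$, $\varepsilon_i \sim N(0, e^{-\lambda} Q)$ with a single
identity component $Q$. Every subject enters through its full posterior —
mean *and* covariance — so uncertain subjects are down-weighted; the
between-subject log-precision $\lambda$ is optimised on the hierarchical
free energy. The design matrix's first column is the group mean;
covariates are mean-centred and collinear designs are rejected. The
pipeline then runs search, averaging and retention on the group
posterior, mirroring the first-level-then-PEB-then-BMR ordering of
standard group spectral analyses. Retention converts a
with-versus-without evidence comparison per connection into a posterior
probability $1/(1+e^{\Delta F})$, thresholded at 0.95.

## Network statistics

A Bayesian contrast $c$ over the posterior $N(M, \Sigma)$ has expectation
$\mu = c^\top M$ and variance $\sigma^2 = c^\top \Sigma c$; for example,
with $P = 6$ the mean of the first four parameters is the contrast
$c = [0.25, 0.25, 0.25, 0.25, 0, 0]^\top$. Between-network cells are
equal-weight contrasts over all connections from one network to another,
so every cell carries an uncertainty and a posterior probability, not
just a point value.

Hierarchy strength ranks the networks:
$$\mathrm{score}(\text{net}) = \sum_{j \ne \text{net}}
\left|\overline{A}_{j \leftarrow \text{net}}\right| -
\sum_{j \ne \text{net}} \left|\overline{A}_{\text{net} \leftarrow j}\right|,$$
the *sum* of unsigned efferent cells minus the sum of unsigned afferent
cells. A sum rather than a mean is used deliberately: the worked
three-network arithmetic that serves as this package's exactness check
(SN $0.03 + |-0.13| - 0.02 - 0.02 = 0.12$, DAN $0.07$, cDN $-0.19$) is a
sum, although the same quantity is sometimes described as a difference of
averages; with equal counts the two differ only by the factor 2, and
`form = "mean"` exposes the averaged version.

Clustering describes each region by its concatenated afferent row and
efferent column (self entry excluded), uses correlation distance and
average linkage — choices the underlying analyses leave open; they are
surfaced as options — and cuts at $k = 2$. On the default template both
the coupling matrix and its implied FC split into the same two modes,
cDN versus SN ∪ DAN, with adjusted Rand index 1 between the partitions.

```{r hierarchy-example}
reported <- network_averages(rbind(c(NA, -0.13, -0.10),
                                   c(0.02, NA, 0.02),
                                   c(0.02, 0.03, NA)),
                             networks = c("cDN", "SN", "DAN"))
hierarchy_strength(reported)
```

## Problem sizes, determinism and limitations

The shipped test suite and examples run the complete chain at the study's
own scale — 20 subjects, 15 regions, 170 volumes — for the end-to-end
recovery check, a 3-node, 2048-sample benchmark for quantitative
parameter recovery (signs of all couplings at or above 0.1 Hz, and
correlation with truth at least 0.9), and systems up to $n = 10$ for the
Lyapunov equivalence property. Every stochastic step takes an explicit
integer seed (cohorts derive subject seeds as master + index), inversion
itself is deterministic given data and priors, and identical
configurations reproduce bit-identical cohorts and artifact hashes.

Known limitations: the neuronal model is linear (no bilinear or two-state
variants, resting state only); the haemodynamics are linearised, with
only transit time free per region, which is an identifiability choice for
short series rather than a physiological claim; subject-level estimates
on 170 volumes are individually noisy (correlations with subject truth
around 0.3) and the scientific claims live at the group level, where PEB
sharpens them; and the hierarchy score orders *net senders versus net
receivers* among these three networks — it is not a statement about
cortical hierarchy in the laminar sense. The interface is the R API plus
`scripts/acceptance.R`; pipeline stages exchange plain CSV/JSON so any
stage can be driven or audited externally.
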