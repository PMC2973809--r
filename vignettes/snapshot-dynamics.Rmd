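---
title: "Reconstructing gene-expression dynamics from pairwise snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-expression dynamics from pairwise snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(snapdyn)
```

## The problem

Single-molecule RNA FISH counts individual mRNA molecules in fixed single
cells. Fixation makes each cell a *snapshot*: one unknown time point of a
hidden trajectory. When two transcripts are probed simultaneously in the
same cells, the joint distribution of the two counts carries information
about the *dynamics* that generated them — a cell cycle, a metabolic
cycle, or stochastic switching between expression states — even though no
cell is ever observed twice. snapdyn implements the reconstruction of such
dynamics from collections of pairwise snapshot measurements, together
with simulators that generate data of exactly this form, so every claim
the package makes can be checked against a known ground truth.

Two intrinsic limitations shape everything below. First, snapshots carry
no clock: the period of a cycle and the direction of time around it are
unidentifiable in principle, so all errors are measured after quotienting
out a global time shift and a time reflection. Second, in the bursty
regime the data reduce to pairwise means and covariances, so only model
families with few enough parameters are identifiable at all; the package
makes this precise with an explicit degrees-of-freedom calculator.

## Two regimes, two models

**Continuous regime.** When many transcription bursts contribute to each
count, counts fluctuate approximately normally about a smooth mean
trajectory. The model (`continuous_cycle_model()`) is harmonic:
$$\mu_i(t) = \mu_{0,i} + A_i \cos(2\pi t/T + \phi_i),$$
with per-gene Gaussian noise of standard deviation $\sigma_i$ about the
mean. The period $T$ is a pure convention (we use $T = 1$) and the phase
sign convention is $\cos(2\pi t/T + \phi)$ throughout. A pair observation
$(x_i, x_j)$ taken at an unknown uniform time has likelihood
$$P(x_i, x_j) = \frac{1}{T}\int_0^T
  N\!\left(x_i; \mu_i(t), \sigma_i\right)
  N\!\left(x_j; \mu_j(t), \sigma_j\right)\,dt .$$
`fit_continuous()` maximizes the summed log of this quantity over all
observations.

**Bursty regime.** When counts are dominated by at most one recent burst,
the informative content of a count is binary — burst present or absent —
and the model (`burst_cycle_model()`) describes the burst probability
along the cycle as a truncated Fourier series
$$p_i(t) = \bar p_i + \textstyle\sum_h a_{i,h}\cos(2\pi h t/T + \phi_{i,h}),$$
clipped to $[0,1]$ during simulation. Global transcriptional noise enters
as a single cell-wide multiplicative factor $G$ (mean 1, standard
deviation $\sigma_G$) applied to all burst probabilities of a cell; it is
the *sharing* of one factor per cell that converts global noise into
between-gene covariance. The amplitude-locked sub-family
$p_i(t) = \bar p_i(1 + \cos(2\pi t/T + \phi_i))$ describes genes whose
expression nearly vanishes somewhere along the cycle — the shape seen for
metabolically cycling genes — and has a single free parameter per gene
(its phase) once $\bar p_i$ is pinned to the data.

**Switching.** `switch_model()` describes synchronous stochastic jumps of
all genes among $S$ discrete states with probabilities $P_s$ and
per-state burst probabilities $q_{i,s}$. Snapshot data constrain only the
occupancies and the $q_{i,s}$, never the switching kinetics.

## Moments, identifiability, and rank

All bursty-regime inference runs through the cycle- or state-averaged
moments. Conditional on the hidden time (and global factor), burst
indicators of different genes are independent, so the between-gene
indicator covariance equals the covariance of the burst probabilities:
for one harmonic $c_{ij} = \tfrac12 a_i a_j \cos(\phi_i - \phi_j)$, and
with global noise
$c_{ij} = \sigma_G^2\,\bar p_i \bar p_j +
(1+\sigma_G^2)\,\tfrac12 a_i a_j \cos(\phi_i - \phi_j)$.
`exact_moments()` evaluates these closed forms (which, like the model
algebra, ignore clipping) or, on request, a quadrature path that honours
clipping: a fine uniform time grid (trapezoidal, hence spectrally
accurate for these periodic integrands) combined with generalized
Gauss–Laguerre nodes for the gamma-distributed global factor, which is
exact for the unclipped second moments. The two paths agree to near
machine precision whenever clipping never triggers; when it does
(large $G$ tails), the quadrature path is the honest one and is validated
against simulation in the test suite.

The covariance rank identifies the dynamical complexity: $2H$ for a cycle
with $H$ harmonics, $+1$ with global noise, $S-1$ for an $S$-state
switch. `dof_report()` turns this into identifiability accounting: a
single-harmonic cycle over $N$ genes has $N(1+2H) - 1$ parameters (one
overall phase is unidentifiable) against $N$ means plus
$\min(rN - r(r-1)/2,\ N(N-1)/2)$ covariance constraints at rank $r$. The
cap matters for small $N$: with fewer than five genes even the
single-harmonic free-amplitude model is under-constrained by pairwise
data, which is why `fit_cycle_bursty()` refuses such configurations and
suggests locking the amplitudes.

## Estimation pipeline in the bursty regime

1. **Thresholding** (`compute_thresholds()`): each gene's binary
   threshold defaults to the pooled median of its counts (lower median on
   ties), with a burst defined as a count *strictly* above threshold. In
   strongly bursty data most medians are zero.
2. **Moment estimation** (`estimate_moments()`): per-gene burst
   frequencies $\hat p_i$ pooled over every pair probing gene $i$;
   per-pair covariances $\hat c_{ij}$ from within-pair means (each pair's
   estimate stays self-contained; the pooled $\hat p$ is what the MLE
   pins — the two coincide asymptotically). The sampling variance of
   $\hat c_{ij}$ uses the leading Bernoulli-coincidence term
   $\hat r(1-\hat r)/M$; corrections of order $1/M$ from estimating the
   means are neglected, which is accurate exactly in the
   rare-coincidence regime the method targets, and is validated against
   a 1000-fold resampling experiment in the tests. Zero-coincidence
   pairs are floored at $0.25/M^2$ (a quarter of one count) so their
   likelihood stays finite.
3. **Fitting** (`fit_cycle_bursty()`, `fit_switch()`): the means are
   pinned to $\hat p$ exactly (mean estimates are far more precise than
   covariance estimates), and the Gaussian likelihood of the observed
   covariances is maximized by bounded quasi-Newton ascent from 10
   random restarts by default. In this regime the landscape is benign —
   the fraction of restarts reaching the best optimum is reported and is
   typically above 80%. Amplitudes are bounded to
   $[0, \min(\hat p_i, 1-\hat p_i)]$ so fitted probabilities stay in
   $[0,1]$ without invoking the clipping the closed forms ignore;
   $\sigma_G$ is optimized on a log scale with its lower bound
   ($e^{-8}$) reported as zero.

For a 2-state switch the state-1 occupancy $P_1$ must be supplied
(pairwise data leave exactly one parameter free); $q_{i,2}$ is then
eliminated exactly through the pinned mean. Note that for $P_1 \ne 1/2$
the pairwise moments still admit two mirrored solutions
($\delta \to -\delta$); both the MLE and the PCA route resolve the tie by
reporting the labeling in which state 1 is the more active one.

## PCA with diagonal completion

The diagonal of the estimated covariance (each gene's indicator variance
over the hidden phase) is not measurable from pairwise data.
`pca_complete()` starts from a zero diagonal, eigendecomposes, rebuilds
the diagonal from the top-$r$ reconstruction, and iterates to
convergence; off-diagonal entries are never modified, and unmeasured
pairs are imputed as zero (unbiased under no signal) with a count
reported. For a 2-state switch the exact covariance is
$P_1(1-P_1)\delta\delta^\top$ with $\delta = q_{\cdot,1} - q_{\cdot,2}$,
so the converged principal eigenvector inverts algebraically to the full
switch model (`switch_from_pca()`). `infer_complexity()` thresholds the
spectrum at 5 times the median absolute eigenvalue (with a $10^{-8}$
relative floor against numerical zeros) to suggest candidate model
families; the heuristic presumes the signal rank is well below the
number of genes, its design regime.

## Finding the continuous-regime optimum

The continuous-regime likelihood has frequent local maxima, almost always
reflecting wrong phase assignments. `init_phases()` builds full parameter
starts: baselines at per-gene sample means, amplitudes and noise levels
at half the per-gene standard deviation, and phases from the pairwise
Pearson correlation matrix $\hat\rho$ (for harmonic dynamics
$\hat\rho_{ij} \approx \cos(\phi_i - \phi_j)$) by two routes — (a)
magnitudes $|\phi_i| = \arccos\hat\rho_{ri}$ relative to a reference gene
(signs unresolved; two reference choices give two starts), and (b) the
phases maximizing $\sum_{i<j}\hat\rho_{ij}\cos(\phi_i-\phi_j)$, seeded by
the top two eigenvectors of $\hat\rho$ and refined by local ascent.
Route (b) generally lands in the global basin; the package's evaluation
(below) checks that heuristic starts match true-parameter starts. The
optimizer is L-BFGS-B with the analytic gradient of the quadrature
likelihood (implemented in C++), amplitude and noise bounds
($A_i \ge 0$, $\sigma_i \ge 10^{-3}$), convergence at `factr = 1e7`, and
phases wrapped to $[0, 2\pi)$ afterwards.

Numerical choices: the likelihood quadrature defaults to 128 uniform time
points with log-sum-exp stabilization; 64 points are indistinguishable
for single-harmonic fitting and are used in the large replicated
experiments. The zero-flooring of simulated counts is ignored by the
Gaussian likelihood — a documented approximation whose bias is small
unless a mean trajectory sits within a couple of noise standard
deviations of zero.

## Error metrics

The continuous reconstruction error is
$$\Delta^2 = \frac1N \sum_i
  \frac{\frac1T\int_0^T [\hat\mu_i(t) - \mu_i(t)]^2 dt}
       {\langle \mu_i \rangle^2},$$
minimized over the global shift and reflection. Normalization by the
squared mean level $\langle\mu_i\rangle^2$ (rather than by the variance
of $\mu_i(t)$) makes $\Delta$ dimensionless and well-defined for
non-oscillating genes; the choice affects absolute values, not
orderings. For single-harmonic models the integral and the optimal shift
are evaluated in closed form. The switch analogue weights squared
probability errors by state occupancy, normalizes by each gene's
state-to-state variation, averages over genes, and minimizes over state
relabelings.

## What the simulators emulate — and what they do not

The generators define the study conditions used in all tests.
`sample_cycle_params()` draws $A_i = 5(1+u)$, $\mu_{0,i} = A_i(1+u')$
(positivity with amplitudes comparable to baselines), phases uniform,
noise uniform on $(0, 5]$ — noise comparable to the smallest amplitudes.
`sample_burst_cycle_params()` draws $\bar p_i \sim U(0.05, 0.35)$, the
range typical of median-thresholded FISH data, with free amplitudes
$a_i = \bar p_i(0.5 + 0.5u)$ keeping unclipped probabilities inside
$[0,1]$. Switch draws are uniform on $[0,1]$, optionally with a floor on
$|q_{i,1}-q_{i,2}|$ so every gene is informative. Burst indicators can be
dressed into counts with geometric burst sizes (mean 8) to exercise
thresholding. Each simulated cell draws a fresh uniform time
independently for every pair, matching the independent-pairs design of
real pairwise FISH experiments.

Real data differ in ways the simulators deliberately omit: measurement
noise and probe efficiency, false-positive/negative spot calls,
ambiguous spots, nascent transcripts, cell-to-cell waveform variation
beyond a global factor, and non-harmonic cycle shapes. Passing tests
therefore demonstrate correctness of the inference machinery under its
own assumptions, not robustness to those artefacts. The gamma choice for
the global factor $G$ is likewise a convention: the moment formulas
depend only on its mean and variance, so the choice affects simulation
tails (and the rare clipping events they trigger) but not the fitted
moments.

## Evaluation design

The replicated experiments in the test suite run at scales chosen to
exercise the published trends while remaining quick to reproduce:

* continuous recovery on a $3\times3$ grid, $N \in \{2,4,8\}$ genes and
  $M \in \{30,100,300\}$ observations per pair, 20 replicates per cell;
  mean $\Delta$ is required to decrease along each axis *marginally*
  (averaging over the other factor) — cell-by-cell strictness over 180
  stochastic fits would test noise, not the method — and heuristic
  starts must match true-parameter starts within 10% in mean $\Delta$;
* switch recovery at 6 genes, $M = 10^4$, strong state separation:
  both the MLE and the PCA route must achieve mean
  $\Delta_{\rm switch} < 0.2$, with MLE no worse than PCA by more than
  10% (the two are expected to perform within a few percent of each
  other);
* global-noise recovery at $\sigma_G = 0.55$, $M = 10^4$, 20 replicates,
  mean estimate within $\pm 0.2$ — the residual downward bias of a few
  percent comes from clipping of the gamma tail and is expected;
* Monte-Carlo oracle agreement of all closed-form moments at
  $10^5$ samples per draw, 20 draws per family, within 3 standard
  errors (block-estimated with 100 blocks);
* cluster synchrony: clusters of 4–6 genes with phase jitter
  $\le 0.3$ rad must test significant ($p < 0.05$) in every one of 20
  replicates, while a random-phase cluster must never fall below the
  family-wise Bonferroni level $0.05/20$ and must keep a median p-value
  above 0.1 — under the null its p-values are uniform (a property
  KS-tested separately), so demanding $p \ge 0.05$ in all 20 replicates
  would reject a correct implementation most of the time.

## Cluster synchrony

For amplitude-locked fits, the activity of a gene cluster $j$ is the
mean-normalized average burst probability
$Q_j(t) = \frac{1}{N_j}\sum_{i\in j} p_i(t)/\bar p_i
        = \frac{1}{N_j}\sum_{i\in j} [1 + \cos(2\pi t/T + \phi_i)]$.
The normalization is forced by two requirements: perfect synchrony must
drive the minimum of $Q_j$ to zero, and clusters of equal size must be
comparable regardless of expression level. The minimum over the cycle
has the closed form $1 - R_j/N_j$ with
$R_j = |\sum_{i\in j} e^{i\phi_i}|$ (the phase resultant), which the
package uses instead of a time grid — grids are kept only for plotting
curves. `min_activity_pvalue()` compares an observed minimum against
Monte-Carlo draws of i.i.d. uniform phases with the add-one correction
$(k+1)/(n_{mc}+1)$.

## Known limitations

* Only the single-harmonic continuous family is implemented; higher
  harmonics in the bursty regime are rejected as unidentifiable from
  pairwise data rather than fitted with external constraints (triplet
  likelihood terms are out of scope).
* Switch fitting covers $S = 2$; larger $S$ requires constraints beyond
  pairwise data.
* The Gaussian covariance likelihood and the $\hat r(1-\hat r)/M$
  variance are leading-order approximations, excellent when coincident
  bursts are rare (the target regime) and progressively cruder as burst
  probabilities approach 1/2 with large amplitudes.
* Closed-form moments ignore clipping; simulators honour it. Fits of
  strongly clipped models (large $\sigma_G$ together with large
  $\bar p$) inherit a small systematic bias.
* Model selection is left to the rank heuristic plus prior knowledge; a
  thin leave-one-out utility (`holdout_loglik()`) supports comparing
  continuous-regime fits but no automatic selection is attempted.
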