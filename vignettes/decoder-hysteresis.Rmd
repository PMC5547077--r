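---
title: "Latent neural dynamics, decoder hysteresis, and electrode loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent neural dynamics, decoder hysteresis, and electrode loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbmi)
```

## The problem

Intracortical brain-machine interfaces decode a user's intended cursor
movement from spiking activity on a chronically implanted electrode array.
Arrays degrade: over months to years, electrodes stop yielding spikes, and
decoders retrained on the surviving channels perform progressively worse.
`dynbmi` implements a family of decoders built around a latent linear
dynamical system (LDS) of the motor-cortical population, and in particular
the *hysteresis* idea: the population dynamics are a property of the
circuit, not of the particular electrodes sampled from it, so a dynamics
model identified years earlier — when many more electrodes were available —
can be remembered and reused to constrain decoder training on today's
degraded recording.

## The model

Binned threshold-crossing counts $y_k \in \mathbb{Z}^E_{\ge 0}$ (15 ms,
non-overlapping bins) are modeled as noisy linear observations of a
low-dimensional latent neural state $s_k \in \mathbb{R}^d$:

$$ s_k = M s_{k-1} + n_k, \qquad y_k = P s_k + r_k, $$

with $n_k \sim \mathcal{N}(0, N)$, $r_k \sim \mathcal{N}(0, R)$, $N$ and
$R$ diagonal, and $s_1 \sim \mathcal{N}(\pi_1, S_1)$. Because the diagonal
$R$ carries all private variability, every correlation across electrodes
must flow through the latent state. One modeling note: the linear-Gaussian
model is zero-mean while spike counts have a positive baseline, so
`em_fit()` centers the counts on their training mean and stores that mean
with the parameters; decoders subtract it before filtering. This is the
same role the mean parameter plays in the factor-analysis initialization.

**Identification.** `em_fit()` maximizes the marginal likelihood by EM:
the E-step is exact Kalman smoothing (Rauch-Tung-Striebel, implemented in
compiled code with an information-form measurement update so the per-bin
cost is $O(Ed^2)$), the M-step is the closed-form update with $N$ and $R$
projected to diagonal. Initialization is factor analysis (EM with a PCA
warm start, 200 iterations): loadings and uniquenesses seed $(P, R)$, the
factor scores seed $(\pi_1, S_1, N)$, and the lag-one regression of the
scores seeds $M$. Convergence is declared when the relative log-likelihood
change falls below `1e-6`, with a 500-iteration cap; both are package
choices — no canonical stopping rule exists for this model class. An
optional steady-state E-step (`opts$steady_state = TRUE`) freezes the
filter and smoother gains once the predicted state covariance has
converged; on stationary sessions it reproduces the exact smoothed means
to ~1e-11 at a fraction of the cost, and the long sweeps below use it.

**Decoding.** The neural state is inferred causally with the steady-state
Kalman filter, $s_k = M s_{k-1} + K(y_k - PM s_{k-1})$, where the gain `K`
is the fixed point of the gain recursion (`steady_state_gain()`, iterated
to `1e-12`). Kinematics are read out linearly with a bias,
$\hat{x}_k = L_s [s_k; 1]$, with $L_s$ the least-squares solution on the
training block. The displayed position blends 2.5% of the decoded position
with 97.5% of the integrated decoded velocity
($\alpha = 0.975$, `blend_position()`), which anchors the cursor in the
workspace without letting position noise dominate.

## The decoder family

* **NDF** — dynamics, observation model and readout all fit fresh on
  today's data.
* **HNDF** — the dynamics process $(M, N)$ is remembered from a historical
  fit; constrained EM (`em_fit_constrained()`) re-estimates only
  $(P, R, \pi_1, S_1)$ on today's spikes. The returned $(M, N)$ are
  bit-identical to the remembered values.
* **MNDF** — when electrode identities persist, the observation process
  $(P, R)$ is also remembered (restricted to surviving electrodes); no EM
  at all, only the readout is refit.
* **FIT-KF** — a kinematic-state Kalman filter on
  $(p_x, p_y, v_x, v_y, 1)$ trained on intention-transformed kinematics:
  reach velocities are rotated toward the prompted target (magnitude
  preserved) and velocities inside the target's acceptance window are
  zeroed. Window containment is closed ($|dx| \le w/2$ and
  $|dy| \le w/2$, default $w = 4$ cm); zero velocities outside the window
  are left unchanged since their rotation is undefined. With intention
  estimation off this is the plain velocity Kalman filter baseline.
* **OLE** — least squares from causally Gaussian-smoothed counts
  (100 ms s.d., kernel truncated at $4\sigma$, renormalized over the
  available past during ramp-in) to kinematics.

Offline decoding resets the decoded position to the true hand position at
the first bin of every trial, so position error cannot accumulate across
trials; the FIT-KF's internal position state is reset the same way, and
OLE positions are integrated from decoded velocity between resets.

## Offline metrics

`velocity_correlation()` computes per-axis Pearson correlations at lags of
15-90 ms (15 ms steps) and reports the per-axis mean at the best lag; one
shared lag is chosen for both axes by maximizing the absolute mean
correlation, and positive lag means the decoded (neural) trace leads the
kinematics. `position_error()` is the mean Euclidean position error at
the error-minimizing lag. Paired decoder comparisons
(`compare_decoders()`) use the two-sided Wilcoxon signed-rank test, exact
below 25 pairs, with scores paired within seed. Closed-loop metric
definitions (targets per minute, success rate, acquire time excluding the
hold period) are provided by `closed_loop_metrics()` for trial logs; no
synthetic user model is included, so the package does not claim to
reproduce closed-loop performance numbers.

## Electrode ranking and the loss protocol

`estimate_spiking_distribution()` builds, per electrode, the empirical
count distributions on the support $\{0, 1, 2, 3, 4, 5^+\}$ conditioned on
the prompted target. Every bin from target onset to trial end contributes
to that trial's condition; the center prompt is its own condition. The
marginal $p_Y$ is defined as the $p_X$-mixture of the conditionals (with
$p_X$ empirical over trials), which keeps the distributions exactly
consistent when trials have unequal lengths. Mutual information
$I(X,Y) = H(Y) - H(Y|X)$ is reported in bits ($0\log 0 = 0$); electrodes
are dropped most informative first (`drop_order()`, ties broken by
electrode index) — the worst case for a decoder.

## Dynamics analyses

`eigenmodes()` decomposes $\tilde{M} = (M - I)/\Delta t$, the first-order
continuous-time approximation of the dynamics: a complex pair
$\sigma \pm i\omega$ is a rotational mode at $\omega/2\pi$ Hz with decay
time constant $-1/\sigma$. All downstream mode arithmetic uses a real
block basis (columns $\mathrm{Re}\,v$, $\mathrm{Im}\,v$ per pair) so
decoded velocities stay exactly real. `max_frequency()` applies a 20 ms
time-constant screen: a mode decaying faster than that dies out before
completing any oscillation.

`mode_contributions()` diagonalizes the decoder's dynamics, rotates the
inferred states into eigen-coordinates, and decodes velocity separately
through each mode's readout columns. Each mode's raw contribution $r_v$
is its mean decoded speed in cm/s; we use the mean rather than the summed
speed because the normalizing regularizer is itself a speed: shares are
$r_v / (\sum r_v + 10\ \mathrm{cm/s})$, where the 10 cm/s guards against
small overall decoded speeds after severe electrode loss. The per-mode
velocities sum to the total decoded velocity (minus bias) to within 1e-9,
a change-of-basis identity asserted in the test suite. By default the
analyses are run on held-out data.

`rotational_share()` splits the contribution between rotational and
purely decaying modes. A complex pair only counts as rotational if its
time constant passes the same 20 ms screen: estimated matrices generically
have complex eigenvalues, and a "rotation" that dies within one 15 ms bin
is dynamically a decay. Setting `min_time_constant_s = 0` recovers the
raw complex/real split.

`jpca_r2_ratio()` measures how rotational the condition-averaged
population trajectories themselves are: PSTHs (16 conditions — 8 outward
reaches and 8 returns, aligned at trial start) are smoothed with a 25 ms
Gaussian, restricted to the 200-500 ms epoch, projected on the top 6
principal components, and the Euler state derivative is regressed on the
state with an unconstrained matrix and with the best skew-symmetric
matrix (solved by explicit normal equations over the 15 free parameters).
The ratio $R^2_\mathrm{skew} / R^2_\mathrm{best} \in [0, 1]$ is 1 exactly
when the best linear dynamics are already skew. Trials shorter than the
epoch raise an error rather than silently truncating.

## The synthetic ground truth

No public recordings accompany this problem, so `synth_config()` /
`make_ground_truth()` / `generate_session()` define a fully specified
stand-in with a known answer. The generator emulates:

* a 20-dimensional latent state: 2 *drive* dimensions with a fast (80 ms)
  decay receiving a per-trial constant input aligned to the prompted
  target direction; decaying rotation blocks at 0.5, 1.0, 1.5, 2.0 and
  2.5 Hz (500 ms time constant), constructed so the imaginary parts of
  $(M-I)/\Delta t$ equal $2\pi f$ exactly; and real decay modes
  (50-400 ms) filling the remainder. The true LDS is autonomous between
  inputs; the target-aligned drive is an extension needed to make
  kinematics decodable at all, with weak random couplings into the
  rotational blocks so rotations are condition-dependent;
* a center-out-and-back task: 8 radial targets on a 12 cm circle, center
  and radial prompts alternating, ~500 prompts of ~0.72 s each, cursor
  velocity read out from the drive dimensions at 17 cm/s per unit state
  plus 0.5 cm/s measurement noise, positions integrated with a reset to
  the center at each radial prompt;
* heterogeneous electrode informativeness: per-electrode signal gains are
  log-normal (median 0.3 counts/bin per unit state, `sdlog` 0.8) on
  random unit loading directions (drive dimensions up-weighted 1.5x),
  baselines uniform over 7-60 Hz, and per-electrode observation noise at
  the Poisson-like level (variance = baseline). Counts are linear-Gaussian
  draws rounded and clipped at zero, which keeps the generating process
  inside the fitted model class except for the rounding;
* determinism: one seed fixes the ground truth and the session; the
  session draw uses an offset stream so the same truth can emit
  independent "historical" and "today" sessions.

Noise scales were calibrated once so that a full-array NDF reaches a
held-out velocity correlation of roughly 0.85-0.9 — the regime reported
for real full-array recordings — and were not revisited afterwards. What
the generator does **not** emulate: Poisson spiking, non-stationarities
within a session, neural adaptation, curved reaches, or any closed-loop
feedback; passing the electrode-loss properties here shows the pipeline
reproduces the phenomenology under the stated linear-Gaussian conditions,
not that it would do so on any particular animal's data.

## The electrode-loss experiment

`run_loss_experiment()` is the desk-scale analogue of the array-degradation
study: per seed, a fresh ground truth; a historical full-array session
whose EM fit provides the remembered dynamics; a second session on which
electrodes are dropped most-informative-first; and, per drop count, each
decoder trained on the 80% contiguous split and scored on the held-out
20%. For dynamical decoders the sweep also records the fitted dynamics'
maximum screened eigenfrequency and the rotational share of the decoded
output. The acceptance-level runs use 10 seeds, the default drop grid
$\{0, 20, 40, 60, 70, 80\}$ of 96 electrodes, the steady-state E-step,
and an EM cap of 100 iterations; dropping 80 leaves fewer electrodes
than the 20 latent dimensions and is reported as `NA` by design.

Three qualitative properties of the original degradation phenomenology
are asserted by the test suite on this experiment: (1) the hysteresis
decoder matches or beats the fresh fit on held-out velocity correlation
at 60+ electrodes dropped in at least 8 of 10 seeds, while the fresh
fit's median declines monotonically (Spearman rank correlation with drop
count negative); (2) the maximum eigenfrequency of re-learned dynamics
regresses negatively on the number of electrodes dropped; (3) the
rotational contribution to decoded output declines more shallowly for
the hysteresis decoder — per-seed slopes compared with the paired
Wilcoxon signed-rank test, the test family used for all paired decoder
comparisons here, with the per-seed direction count reported alongside.

## Numerical choices and degenerate inputs

* Innovation-form measurement updates use the matrix-inversion lemma with
  diagonal $R$; covariances are re-symmetrized every step.
* M-step variances are floored at `1e-10` to keep $N$, $R$ invertible.
* Rank-deficient least-squares designs (readout, OLE, FIT-KF) raise an
  error by default; an explicit ridge can be supplied and is recorded on
  the fitted object.
* Zero-variance electrodes make factor analysis (and hence EM) impossible
  and are reported by index.
* Defective dynamics matrices (eigenvector condition below `1e-10`) raise
  an error in `eigenmodes()` advising a small jitter.
* The session container is a versioned JSON file written with 17
  significant digits, which round-trips doubles bit-exactly and makes
  writes byte-deterministic; the trial table is also exportable as CSV.

## Known limitations

The hysteresis comparison inherits every idealization of the generator:
in particular, the remembered dynamics here really are the dynamics of
today's population, which is the hypothesis under test, not a property of
arrays in general. The MNDF additionally assumes stable electrode
identities, which the package enforces by label matching but cannot
verify. Closed-loop performance is out of scope: offline velocity
correlation is known to be an unreliable predictor of closed-loop control.
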