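---
title: "Measuring local DNA bend angles from tethered particle motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring local DNA bend angles from tethered particle motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmbend)
```

# The measurement problem

In a tethered particle motion (TPM) experiment a short DNA molecule
(here 575 bp) is grafted to a coverslip at one end and to a tracked
particle (radius ~150 nm) at the other. The root-mean-squared 2D
excursion of the particle about the anchoring point — the *amplitude of
motion* `R_par` — reports the effective length of the tether. A local
bend of angle `theta` anywhere in the molecule shortens its end-to-end
distance and hence the amplitude, so a sufficiently precise amplitude
measurement is an angle measurement. `tpmbend` implements the full
chain from tracked positions to an angle: trajectory reduction, camera
and particle corrections, a kinked worm-like-chain (WLC) model with
closed-form inversion, bend-series fitting, and an equilibrium Monte
Carlo simulator of the bead-DNA-wall assembly used to validate the
analytics.

# The kinked WLC model

For a WLC of contour length $L$, persistence length $L_p$ and a rigid
kink of angle $\theta$ at arclength $l$ from one end, the mean-squared
end-to-end distance is

$$\langle R^2\rangle(\theta) = 2L_p^2\Big[\tfrac{L}{L_p} - 2 +
e^{-l/L_p} + e^{-(L-l)/L_p}\Big] + \cos\theta\; 2L_p^2\Big[1 -
e^{-(L-l)/L_p} - e^{-l/L_p} + e^{-L/L_p}\Big] \equiv A + B\cos\theta.$$

The first bracket is the sum of the two arms, the second is the
arm-arm cross correlation attenuated by the kink. Two consequences are
used throughout:

* the reduced fitting form $R(\theta) = D\sqrt{1 + c\cos\theta}$ with
  $c = B/A$ computed from the geometry ([cos_coefficient()]); for the
  575 bp construct at $L_p$ = 150 bp, $c$ = 0.342 for a mid-chain bend
  and 0.338 at the experimental bend locus (318 bp);
* the closed-form inversion
  $\cos\theta = 1 + \frac{A+B}{B}\,\frac{R^2(\theta) -
  R^2(0)}{R^2(0)}$ ([invert_single_site()]).

All lengths are converted to nanometres at 0.34 nm/bp; the default
persistence length is 150 bp (51.0 nm). This pair jointly reproduces
the three benchmark values 121.9 nm, 0.342 and 0.338, which is why it
is fixed as the package default (both are overridable per call and in
the run configuration).

Angles are degrees at every interface and radians internally.

```{r}
p <- polymer_params(575, 318, 150)
kinked_msd(p, 0)$root
cos_coefficient(p)
```

## Saturation and the detection floor

Near 180 degrees the end-to-end distance saturates, so measured
distance pairs can push the raw cosine below -1. The inversion clamps
the cosine into $[-1, 1]$ and flags the clamping instead of erroring;
the flagged angle reads "at least ~180 degrees". Applied to published
measurements of the bacterial protein IHF (tether 1943 bp, site at
301 bp, distances 249 to 229 nm) this yields the expected ~180 degree
bend.

The smallest detectable single-site angle follows from the smallest
resolvable relative decrease of the corrected end-to-end distance. The
2% resolution quoted for the targeted instrument, applied to the
$R_{DNA}(\theta)/R_{DNA}(0)$ ratio, gives a floor of 33 degrees for the
575 bp construct. We deliberately apply the threshold to the
*corrected* distance ratio rather than to the raw amplitude: only this
reading reproduces the printed 33 degrees (propagating 2% of amplitude
through the particle correction would give a different number; the
ambiguity is documented here rather than silently resolved).

```{r}
detection_floor(0.02, p)
```

## Heterogeneous rigidity

An alternative explanation for a longer-than-expected construct is a
stiffer insert rather than a bend. [het_msd()] evaluates the WLC with
piecewise-constant persistence length from the factorized closed form
of the tangent-correlation double integral (derived from first
principles; the original supplementary formula is not available, so an
adaptive-quadrature oracle is the source of truth in the tests), and
[solve_insert_lp()] inverts it for the insert persistence length that
explains a measured length gain by monotone root bracketing. For the
out-of-phase four-tract construct (gain 3.2 nm over 55 bp) this gives
an effective insert persistence length well above 100 nm; the package
treats the printed 129 nm as a soft consistency check only, because
the exact published formula is unknown and the inference is avowedly
low-precision in this regime.

# From tracked positions to corrected distances

**Blur.** A camera exposure $T_{ex}$ averages the bead position over
the acquisition window. For exponentially correlated motion with
correlation time $\tau$, the recorded mean-square amplitude is
attenuated by the bracket
$2\tau/T_{ex} - 2(\tau/T_{ex})^2(1 - e^{-T_{ex}/\tau})$;
[blur_correct()] divides the raw amplitude by its square root. The
factor is exactly 1/0.7534 at the reference operating point
($\tau$ = 20 ms, $T_{ex}$ = 40 ms).

**Particle.** The minimal correction assumes the particle orientation
is independent of the DNA and ignores the substrate:
$R_{DNA} = \sqrt{(3/2)\langle R_\parallel^2\rangle - R_p^2}$. It
reproduces every published amplitude-to-distance pair of the packaged
bend-series table to 0.1 nm and is the package default. The
excursion-number (Segall-type) correction is implemented *exactly as
printed* in the reference TPM analysis: $\tfrac32\langle
R_\parallel^2\rangle/\langle R_{DNA}^2\rangle = 1 +
2N_R/(\sqrt{\pi}\,\mathrm{erf}\,N_R)$ with $N_R = \sqrt6
R_p/\sqrt{\langle R_{DNA}^2\rangle}$, solved by bracketed bisection to
relative tolerance 1e-9. As printed, its right-hand side tends to 2
(not 1) as $N_R \to 0$, so it is *not* the small-$N_R$ expansion of
the minimal correction even though its accompanying derivation claims otherwise; the
equation is kept as printed and the discrepancy is surfaced in the
tests (the bead-free limit is $\sqrt{3/4}$ of the amplitude, not
$\sqrt{3/2}$). Consequently the as-printed equation yields *smaller*
corrected distances than the minimal model at the experimental
geometry.

**Uncertainties.** Measurement uncertainties are carried through the
corrections by the first-order delta method; the published per-sample
uncertainties are used as given, not re-derived.

# Bend-series fitting

For $n$ phased repeats of a bent sequence, each contributing
$\theta_1$, the model is $R(n) = D[1 + c\cos(n\theta_1 -
\theta_0)]^{1/2}$ with the offset $\theta_0$ standing for the intrinsic
global bend of the $n=0$ molecule (sign convention: the argument is
$n\theta_1 - \theta_0$, matching the published convention). The
cosine makes the least-squares surface multimodal, so [fit_series()]
multi-starts on a grid — $\theta_1$ from 0 to 60 degrees in 1 degree
steps, $\theta_0$ from -90 to 90 in 5 degree steps when fitted — with
$D$ profiled out in closed form at each node, then polishes the best
node with BFGS. Ties are broken by residual, then by the smaller
$\theta_1$. Uncertainties are 1-sigma values from the curvature of the
objective at the optimum. Fits are unweighted by default because the
reference analysis does not state weights; `weighted = TRUE` applies
$1/\sigma^2$ weights and is exposed so both readings are available.

On the packaged series the two-parameter fit gives $D$ = 92 nm,
$\theta_1$ = 15 degrees, and the three-parameter fit $D$ = 91 nm,
$\theta_1$ = 19 degrees, $\theta_0$ = 25 degrees:

```{r}
tab <- tpm_bend_series_table()
ip <- tab[tab$phase != "O", ]
bs <- bend_series(ip$n_repeats, minimal_correction(ip$amplitude_nm, 150),
                  polymer_params(575, 318, 150))
fit_series(bs)
fit_series(bs, with_theta0 = TRUE)
```

# Trajectory reduction

[summarize_trajectory()] chains the per-tether analysis: a centred 5 s
moving average of the absolute positions defines the local anchoring
point and removes slow drift; the amplitude of motion is the RMS 2D
excursion per 5 s sliding window averaged along the trace; the
correlation time comes from the frame autocorrelation; the amplitude
is blur-corrected with the per-trace $\tau$; and an asymmetry factor
flags bad tethers.

Two estimator choices deserve a note:

* **Correlation time.** At 25 Hz with $\tau \approx$ 20 ms only the
  first couple of autocorrelation lags are informative, and a
  free-amplitude exponential fit is ill-conditioned. We therefore fit
  the *one-parameter* autocorrelation model of exposure-averaged
  exponentially correlated motion, $\rho_k = A(\tau)e^{-kT_f/\tau}$
  with $A(\tau)$ the known blur factor ratio, over the leading run of
  positive lags (lag 0 excluded: its variance carries the blur
  attenuation). This is self-consistent with the blur correction and
  recovers $\tau$ to a few percent on 5-minute traces.
* **Asymmetry factor.** The reference definition is not reproduced in
  the available text, so the package uses the standard TPM practice:
  the square root of the ratio of the larger to smaller eigenvalue of
  the 2D position covariance, with a configurable validity threshold
  of 1.3.

# The synthetic-data generator

[gen_trajectory()] simulates each axis as an exact-discretization
Ornstein-Uhlenbeck (OU) process on a sub-frame grid and averages the
substeps inside each exposure window. The OU process is chosen as the
minimal stationary Gaussian process with exponential correlation —
precisely the structure the blur correction assumes — and its defaults
are the stated acquisition regime: $\tau$ = 20 ms, 25 Hz, 40 ms
exposure, 5-minute traces, amplitudes in the 80-180 nm range of the
experimental constructs. It is a test surface, not a physical model of
bead hydrodynamics: a green pipeline test establishes that the
reduction chain inverts the generator's (blur + drift + OU) structure
at the stated tolerances, not that real beads are OU. Real data differ
in at least: tracking noise, non-exponential tails from bead rotation,
anchor heterogeneity, and occasional sticking events. With 20
substeps per 40 ms frame the discretization bias of the blur factor is
below 0.3% everywhere we test (below 0.03% at 40 substeps).

[gen_bend_series()] forward-evaluates the reduced fitting form plus
Gaussian noise (0.3 nm default, matching the published per-sample
uncertainty scale) and records the ground truth alongside.

# The Monte Carlo simulator

[run_chain_mc()] samples the equilibrium ensemble of a discrete WLC of
rigid bonds (3.41 nm = 10 bp; 58 segments for the 575 bp construct)
anchored to a hard wall, with bending energy $\kappa\sum_i(1 -
\cos\phi_i)$ in $k_BT$ units and the joint stiffness solved from
$\coth\kappa - 1/\kappa = e^{-a/L_p}$. The imposed bend is a stiff
harmonic well (50 $k_BT$/rad$^2$) about the target angle at one
interior joint; a hard angular window is available as an option. Moves
are single-vertex crankshaft rotations, tail pivots and bead
orientation resampling — all symmetric, so energy-only Metropolis
acceptance gives detailed balance; wall and overlap constraints act by
rejection. The kinetic scheme of the original simulations is not
available, and only time-averaged amplitudes are in scope, so
equilibrium sampling is substituted and validated against closed
forms: the freely jointed and discrete-WLC end-to-end formulas (3
standard errors at 1e5 sweeps), isotropy without the wall, and a
brute-force discrete kinked-chain sum for imposed bends.

**Bead model.** The reporter bead (radius 150 nm) has its center at
one bead radius from the chain end along a *free orientation vector*
with its own move (the experimental antibody linkage is a swivel), the
bead-wall overlap is rejected, and chain-bead overlap is rejected too
(`bead_exclusion`, on by default). The rigid attachment of the bead
along the last bond is kept as an option (`bead_rigid`). This
configuration was chosen after measuring all four attachment/exclusion
variants: with the free swivel plus excluded volume the simulated
amplitude of the straight 575 bp construct is ~152 nm, closest to the
~150 nm regime of the experiments; rigid attachment correlates the
bead with the DNA end direction and inflates the amplitude, while
dropping the excluded volume loses ~15 nm.

**A known red validation.** The validation protocol — simulate a bend
angle sweep, apply the minimal correction, fit $D\sqrt{1 +
c\cos\theta}$ with $D$ free — is implemented and asserted at its
stated tolerance (residual RMS below twice the mean Monte Carlo
standard error), and it *fails* in this package's stated world, for
every bead-model variant. The reason is structural, not statistical:
the minimal correction carries an angle-dependent bias that grows to
~20 nm near 180 degrees (the reference analysis itself quotes ~10%
errors for both correction methods and absorbs the bias into the free
$D$),
whereas the Monte Carlo standard error at any meaningful sampling is
1-3 nm after error propagation. The criterion could only be made green
by degrading the sampling until its noise reaches the bias scale,
which we decline to do; the test is left red deliberately, with the
fit itself, the monotone angle dependence, and the ordering of the two
corrections around the fitted scale all asserted and green.

# Numerical choices

* Bisection/root bracketing everywhere a monotone scalar equation is
  solved (excursion-number equation at 1e-9 relative tolerance, insert
  persistence length, joint stiffness), with explicit bracket
  diagnostics on failure.
* The inversion clamps cosines into $[-1,1]$ and flags rather than
  errors; degenerate geometries (bend on the boundary, non-positive
  lengths) error at construction.
* Batch-means standard errors (50 batches) for all Monte Carlo
  averages; the delta method maps them through square roots and the
  particle correction.
* Grid multi-start plus BFGS for the cosine fits; the grid pitch
  (1 degree / 5 degrees) is finer than the basin spacing of the cosine
  objective on 0-7 repeats, so the global basin is always hit.

# Limitations

* The package measures *fixed* bend angles; flexible hinges, looping
  dynamics and protein-binding kinetics are out of scope.
* The heterogeneous-rigidity correction and the 129 nm insert estimate
  are low-precision by nature (the end-to-end distance is insensitive
  to persistence lengths above ~150 bp).
* The simulator omits hydrodynamics and predicts no time scales; its
  correlation time cannot be compared to the experimental
  $\tau_\parallel$.
* The as-printed excursion-number correction disagrees with its own
  claimed small-bead limit (see above); both corrections are exposed
  and the minimal one is the default, as in standard TPM practice.
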