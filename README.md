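# tpmbend

Measurement of local DNA bend angles — intrinsic (e.g. phased A-tracts)
or protein-induced (e.g. IHF) — from Tethered Particle Motion (TPM)
experiments.

In TPM a short DNA (here 575 bp) tethers a ~150 nm tracked particle to
a coverslip; the root-mean-squared 2D excursion of the particle about
its anchoring point, the amplitude of motion R<sub>exp∥</sub>, reports
the effective tether length. A local bend of angle θ at arclength *l*
shortens the molecule according to a kinked worm-like chain (WLC):

    ⟨R²⟩(θ) = 2Lp²[L/Lp − 2 + e^(−l/Lp) + e^(−(L−l)/Lp)]
            + cos θ · 2Lp²[1 − e^(−(L−l)/Lp) − e^(−l/Lp) + e^(−L/Lp)]
            = A + B cos θ,

so that R(θ) = D √(1 + c·cos θ) with c = B/A, and, for a single site,

    cos θ = 1 + (A+B)/B · (R²(θ) − R²(0)) / R²(0).

The package implements the full analysis chain:

* **wlc model** — `kinked_msd()`, `cos_coefficient()`,
  `invert_single_site()` (with cosine clamping at saturation),
  `detection_floor()`, plus a heterogeneous-rigidity WLC
  (`het_msd()`, `solve_insert_lp()`);
* **corrections** — camera-blur correction `blur_correct()`, the
  minimal particle correction `minimal_correction()`, the
  excursion-number (Segall-type) correction `segall_correction()`, and
  batch processing `correct_table()`;
* **bend-series fitting** — `fit_series()` (multi-start nonlinear least
  squares of D√(1 + c cos(nθ₁ − θ₀))), `per_insert_angles()`;
* **simulator** — `run_chain_mc()` / `angle_sweep()`, an Rcpp
  Metropolis sampler of a wall-tethered discrete WLC with reporter
  bead, validated against closed forms;
* **trajectory reduction** — `summarize_trajectory()` (anchor and
  drift, amplitude, correlation time, asymmetry filter);
* **synthetic data** — `gen_trajectory()` (blurred, drifting
  Ornstein–Uhlenbeck bead motion) and `gen_bend_series()`, with ground
  truth attached;
* **CLI** — `tpm_main()` with subcommands (`correct`, `fit-series`,
  `invert-angle`, `detection-floor`, `simulate`, `process-traj`,
  `synth`, `reproduce-paper`); an executable wrapper ships in
  `inst/cli/tpmbend`.

## Worked example

The packaged measurement table holds the blur-corrected amplitudes of
motion for 575 bp constructs carrying 0–7 phased CA₆CGG tracts. The
minimal particle correction converts them to DNA end-to-end distances,
and the reduced kinked-WLC form is fitted to extract the per-tract
bend angle:

```r
library(tpmbend)

tab <- tpm_bend_series_table()
ip  <- tab[tab$phase != "O", ]                  # in-phase series
bs  <- bend_series(ip$n_repeats,
                   minimal_correction(ip$amplitude_nm, 150),
                   polymer_params(575, 318, 150))
fit_series(bs)
#> Kinked-WLC bend-series fit
#>   D      = 92.1 +/- 1.3 nm
#>   theta1 = 15.2 +/- 1.4 deg
#>   cosine coefficient c = 0.338, residual RMS = 2.41 nm

fit_series(bs, with_theta0 = TRUE)
#> Kinked-WLC bend-series fit
#>   D      = 91.4 +/- 1.2 nm
#>   theta1 = 18.9 +/- 3.3 deg
#>   theta0 = 25.2 +/- 18.8 deg
#>   cosine coefficient c = 0.338, residual RMS = 2.11 nm
```

θ₁ is the bend per tract: ~15° when the intrinsic global bend θ₀ of
the n = 0 molecule is pinned to zero, ~19° when θ₀ is fitted (the
offset soaks up the construct's own curvature). D is the amplitude
scale of the reduced form, left free to absorb the residual bias of
the particle correction.

A single-site protein-induced bend, from published IHF measurements
(1943 bp tether, binding site at 301 bp, end-to-end distance dropping
from 249 to 229 nm):

```r
invert_single_site(229, 249, polymer_params(1943, 301, 150))
#> bend angle: 180 degrees  [cosine clamped: saturation]
```

The smallest single-site angle detectable at the instrument's 2%
distance resolution:

```r
detection_floor(0.02, polymer_params(575, 318, 150))
#> [1] 32.51309      # i.e. ~33 degrees
```

And a simulated tethered bead with a 90° mid-chain kink:

```r
p <- chain_params(58, bend_angle = 90)    # 58 x 3.41 nm = 575 bp
run_chain_mc(p, n_sweeps = 2e4, burn_in = 2000, seed = 1)
#> TPM simulation: R_par = 141.72 +/- 0.95 nm (18000 samples, 74% accepted)
```

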