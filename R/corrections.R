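#' Correct a tracked amplitude of motion for camera blur
#'
#' Finite exposure averages the bead position over the acquisition window,
#' shrinking the apparent excursion. For a stationary signal with
#' exponential positional correlation (time constant `tau`), the recorded
#' mean-square amplitude is attenuated by the factor
#' \deqn{2\frac{\tau}{T_{ex}} - 2\left(\frac{\tau}{T_{ex}}\right)^2
#'   \left(1 - e^{-T_{ex}/\tau}\right),}
#' so the true amplitude is the raw one times the inverse square root of
#' that bracket. The factor is always >= 1 and tends to 1 as
#' \eqn{T_{ex}/\tau \to 0}.
#'
#' @param amplitude_raw recorded RMS amplitude of motion, nm.
#' @param tau positional correlation time \eqn{\tau_\parallel}, ms (> 0).
#' @param exposure camera exposure \eqn{T_{ex}}, ms (> 0); 40 ms for the
#'   25 Hz acquisition this workflow targets.
#' @return Blur-corrected amplitude(s), nm.
#' @examples
#' blur_correct(100, tau = 20, exposure = 40)
#' @export
blur_correct <- function(amplitude_raw, tau, exposure = 40) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("tau must be > 0")
  if (any(!is.finite(exposure)) || any(exposure <= 0))
    stop("exposure must be > 0")
  if (any(amplitude_raw < 0)) stop("amplitude_raw must be >= 0")
  amplitude_raw / sqrt(blur_attenuation(tau, exposure))
}

# variance attenuation bracket of exposure-averaged exponentially
# correlated motion; equals Var(window mean)/Var(instantaneous)
blur_attenuation <- function(tau, exposure) {
  x <- tau / exposure
  2 * x - 2 * x^2 * (1 - exp(-1 / x))
}

#' Minimal particle correction
#'
#' Converts a blur-corrected 2D amplitude of motion into a DNA end-to-end
#' distance assuming the particle and the DNA are statistically
#' independent and ignoring the substrate:
#' \eqn{R_{DNA} = \sqrt{(3/2)\langle R_\parallel^2\rangle - R_p^2}}.
#'
#' @param amplitude blur-corrected RMS amplitude \eqn{R_{exp\parallel}}, nm.
#' @param bead_radius particle radius \eqn{R_p}, nm (150 by default).
#' @return DNA end-to-end distance(s), nm.
#' @examples
#' minimal_correction(149.7, 150)   # 105.4 nm
#' @export
minimal_correction <- function(amplitude, bead_radius = 150) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    stop("amplitude must be > 0")
  if (any(bead_radius < 0)) stop("bead_radius must be >= 0")
  arg <- 1.5 * amplitude^2 - bead_radius^2
  if (any(arg <= 0))
    stop("bead dominates signal: (3/2) amplitude^2 <= bead_radius^2")
  sqrt(arg)
}

# RHS of the excursion-number equation: 1 + 2 N / (sqrt(pi) erf N)
segall_rhs <- function(n_r) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  ifelse(n_r == 0, 2, 1 + 2 * n_r / (sqrt(pi) * erf(n_r)))
}

# forward model: amplitude implied by a given <R_DNA^2> under the
# excursion-number correction (used by tests and the simulator protocol)
segall_forward <- function(r_dna, bead_radius) {
  msq <- r_dna^2
  n_r <- sqrt(6) * bead_radius / sqrt(msq)
  sqrt(msq * segall_rhs(n_r) / 1.5)
}

#' Excursion-number (Segall) particle correction
#'
#' Solves for \eqn{\langle R_{DNA}^2\rangle} in
#' \deqn{\frac{3}{2}\frac{\langle R_\parallel^2\rangle}
#'   {\langle R_{DNA}^2\rangle} = 1 +
#'   \frac{2N_R}{\sqrt{\pi}\,\mathrm{erf}(N_R)}, \qquad
#'   N_R = \sqrt{6}\,R_p/\sqrt{\langle R_{DNA}^2\rangle},}
#' the particle/substrate correction derived for long Gaussian tethers,
#' extrapolated to the semiflexible regime by identifying
#' \eqn{2LL_p} with \eqn{\langle R_{DNA}^2\rangle}. Solved by bracketed
#' bisection to relative tolerance `tol`.
#'
#' @param amplitude blur-corrected RMS amplitude, nm (> 0).
#' @param bead_radius particle radius, nm (>= 0).
#' @param tol relative tolerance of the root.
#' @return DNA end-to-end distance(s) \eqn{\sqrt{\langle R_{DNA}^2\rangle}},
#'   nm.
#' @export
segall_correction <- function(amplitude, bead_radius = 150, tol = 1e-9) {
  if (any(!is.finite(amplitude)) || any(amplitude <= 0))
    stop("amplitude must be > 0")
  if (any(bead_radius < 0)) stop("bead_radius must be >= 0")
  vapply(amplitude, function(a) {
    lhs_minus_rhs <- function(msq)
      1.5 * a^2 / msq - segall_rhs(sqrt(6) * bead_radius / sqrt(msq))
    # f is decreasing in msq: +Inf at 0+, negative for large msq
    lo <- 1e-8; hi <- max(1.5 * a^2, (a + bead_radius)^2) * 10
    if (lhs_minus_rhs(lo) < 0 || lhs_minus_rhs(hi) > 0)
      stop(sprintf(paste0(
        "no sign change bracketing the excursion-number equation ",
        "(amplitude = %.3g, bead_radius = %.3g, f(lo) = %.3g, f(hi) = %.3g)"),
        a, bead_radius, lhs_minus_rhs(lo), lhs_minus_rhs(hi)))
    sqrt(uniroot(lhs_minus_rhs, c(lo, hi), tol = tol * a^2)$root)
  }, numeric(1))
}

#' Batch-correct a table of TPM measurements
#'
#' Applies, per row, the blur correction (when raw amplitudes and
#' correlation times are present) followed by the chosen particle
#' correction, and propagates the amplitude uncertainty to the end-to-end
#' distance by the first-order delta method.
#'
#' @param rows a data frame with columns `amplitude_nm` (blur-corrected)
#'   or `amplitude_raw_nm` + `tau_ms`, and optionally `sample`,
#'   `n_trajectories`, `uncertainty_nm`.
#' @param method `"minimal"` or `"segall"`.
#' @param bead_radius particle radius, nm.
#' @param exposure camera exposure, ms (used only for raw amplitudes).
#' @return The input data frame with columns `r_dna_nm` and (when
#'   `uncertainty_nm` is present) `r_dna_uncertainty_nm` appended. Rows
#'   whose correction fails get `NA` and the failure message in a
#'   `correction_error` column.
#' @examples
#' correct_table(tpm_bend_series_table())
#' @export
correct_table <- function(rows, method = c("minimal", "segall"),
                          bead_radius = 150, exposure = 40) {
  method <- match.arg(method)
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("rows must be a non-empty data frame")
  out <- rows
  if (is.null(out$amplitude_nm)) {
    if (is.null(out$amplitude_raw_nm) || is.null(out$tau_ms))
      stop("need amplitude_nm, or amplitude_raw_nm together with tau_ms")
    out$amplitude_nm <- blur_correct(out$amplitude_raw_nm, out$tau_ms,
                                     exposure)
  }
  correct1 <- switch(method,
                     minimal = function(a) minimal_correction(a, bead_radius),
                     segall = function(a) segall_correction(a, bead_radius))
  res <- lapply(out$amplitude_nm, function(a)
    tryCatch(list(r = correct1(a), err = NA_character_),
             error = function(e) list(r = NA_real_,
                                      err = conditionMessage(e))))
  out$r_dna_nm <- vapply(res, `[[`, numeric(1), "r")
  errs <- vapply(res, `[[`, character(1), "err")
  if (any(!is.na(errs))) out$correction_error <- errs
  if (!is.null(out$uncertainty_nm)) {
    # delta method: dR_DNA/dR_par, analytic for minimal, numeric for segall
    slope <- if (method == "minimal") {
      1.5 * out$amplitude_nm / out$r_dna_nm
    } else {
      h <- 1e-3
      (vapply(out$amplitude_nm + h, function(a)
        tryCatch(correct1(a), error = function(e) NA_real_), numeric(1)) -
          out$r_dna_nm) / h
    }
    out$r_dna_uncertainty_nm <- abs(slope) * out$uncertainty_nm
  }
  out
}

#' Packaged phased A-tract bend-series measurements
#'
#' The blur-corrected amplitudes of motion of the 575 bp constructs
#' carrying 0 to 7 phased CA6CGG tracts (plus the four-tract out-of-phase
#' control), with trajectory counts, measurement uncertainties and the
#' published end-to-end distances obtained with the minimal correction at
#' a 150 nm particle radius.
#'
#' @return A data frame with columns `sample`, `n_repeats`, `phase`
#'   (`"P"` in phase, `"O"` opposition, `""` none), `n_trajectories`,
#'   `amplitude_nm`, `uncertainty_nm`, `r_dna_published_nm`.
#' @export
tpm_bend_series_table <- function() {
  path <- system.file("extdata", "bend_series_6A.csv", package = "tpmbend",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
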