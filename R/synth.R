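#' Parameters of the synthetic bead-trajectory generator
#'
#' The test-surface model of tethered-bead motion: an Ornstein-Uhlenbeck
#' (OU) process per axis - the minimal stationary Gaussian process with
#' the exponential positional correlation that the blur correction
#' assumes. Defaults emulate the targeted acquisition regime: 20 ms
#' correlation time, 25 Hz recording, 40 ms exposure, 5 min traces.
#'
#' @param tau positional correlation time, ms (> 0).
#' @param stationary_std per-axis stationary standard deviation, nm (the
#'   true 2D amplitude of motion is `stationary_std * sqrt(2)`).
#' @param frame_rate recording rate, Hz.
#' @param exposure camera exposure, ms (<= frame interval).
#' @param n_substeps sub-frame discretization of the exposure window.
#' @param duration trace length, seconds.
#' @param anchor true anchor position, nm (length 2).
#' @param drift_velocity linear drift, nm/s (length 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(tau = 20, stationary_std = 100, frame_rate = 25,
                      exposure = 40, n_substeps = 20, duration = 300,
                      anchor = c(0, 0), drift_velocity = c(0, 0),
                      seed = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  if (n_substeps < 1) stop("n_substeps must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  frame_ms <- 1000 / frame_rate
  if (exposure > frame_ms + 1e-9)
    stop("exposure cannot exceed the frame interval")
  structure(list(tau = tau, stationary_std = stationary_std,
                 frame_rate = frame_rate, exposure = exposure,
                 n_substeps = as.integer(n_substeps), duration = duration,
                 anchor = anchor, drift_velocity = drift_velocity,
                 seed = seed), class = "ou_params")
}

# exact-discretization stationary OU series: x_k = phi x_{k-1} + w_k
ou_series <- function(n, phi, sigma) {
  innov <- rnorm(n, sd = sigma * sqrt(1 - phi^2))
  innov[1L] <- rnorm(1L, sd = sigma)  # start in the stationary law
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate a blurred, drifting synthetic bead trajectory
#'
#' Simulates each axis as an exact-discretization OU process on a
#' sub-frame grid; every recorded frame is the mean of the substeps
#' falling inside the exposure window (camera blur), after which the
#' linear drift and anchor offset are added. With `tau` = 20 ms and a
#' 40 ms exposure the recorded RMS amplitude is attenuated to 75.3% of
#' the true one, exactly the bracket factor the blur correction inverts.
#'
#' @param params an [ou_params()] object.
#' @return A [tpm_trajectory()] with attribute `truth` (list: amplitude,
#'   tau, anchor, drift_velocity).
#' @examples
#' traj <- gen_trajectory(ou_params(duration = 30, seed = 1))
#' @export
gen_trajectory <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  frame_ms <- 1000 / params$frame_rate
  n_frames <- floor(params$duration * 1000 / frame_ms)
  nsub <- params$n_substeps
  dt <- frame_ms / nsub   # substeps tile the whole frame interval
  n_exposed <- max(1L, round(nsub * params$exposure / frame_ms))
  phi <- exp(-dt / params$tau)
  blur_mean <- function() {
    z <- ou_series(n_frames * nsub, phi, params$stationary_std)
    zm <- matrix(z, nrow = nsub)
    colMeans(zm[seq_len(n_exposed), , drop = FALSE])
  }
  times <- (seq_len(n_frames) - 1L) * frame_ms / 1000
  x <- blur_mean() + params$anchor[1L] + params$drift_velocity[1L] * times
  y <- blur_mean() + params$anchor[2L] + params$drift_velocity[2L] * times
  traj <- tpm_trajectory(times, x, y, particle_id = "synthetic",
                         frame_rate = params$frame_rate,
                         exposure = params$exposure)
  attr(traj, "truth") <- list(
    amplitude = params$stationary_std * sqrt(2),
    tau = params$tau, anchor = params$anchor,
    drift_velocity = params$drift_velocity)
  traj
}

#' Generate a noisy bend series with known ground truth
#'
#' Forward-evaluates the reduced kinked-WLC form
#' \eqn{R(n) = D\sqrt{1 + c\cos(n\theta_1 - \theta_0)}} (with `c` from
#' the geometry) and adds Gaussian noise, recording the truth alongside.
#'
#' @param D amplitude scale, nm.
#' @param theta1 per-repeat bend angle, degrees.
#' @param theta0 intrinsic global angle, degrees.
#' @param geometry a [polymer_params()] object.
#' @param n_values repeat counts.
#' @param noise_sd Gaussian noise on R(n), nm.
#' @param seed integer seed, or `NULL`.
#' @return A [bend_series()] with attribute `truth` (list: D, theta1,
#'   theta0).
#' @examples
#' gen_bend_series(92, 15, 0, polymer_params(575, 318, 150), seed = 1)
#' @export
gen_bend_series <- function(D, theta1, theta0 = 0,
                            geometry = polymer_params(575, 318, 150),
                            n_values = 0:7, noise_sd = 0.3, seed = NULL) {
  stopifnot(inherits(geometry, "polymer_params"))
  if (!is.null(seed)) set.seed(seed)
  c_coef <- cos_coefficient(geometry)
  r <- reduced_form(n_values, D, theta1, theta0, c_coef) +
    rnorm(length(n_values), sd = noise_sd)
  bs <- bend_series(n_values, pmax(r, 1e-6), geometry,
                    sigma = rep(max(noise_sd, 1e-12), length(n_values)))
  attr(bs, "truth") <- list(D = D, theta1 = theta1, theta0 = theta0)
  bs
}
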