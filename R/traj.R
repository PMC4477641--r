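#' A tracked bead trajectory
#'
#' Time-stamped 2D positions of one tethered bead, with the acquisition
#' settings needed downstream (frame rate for lag conversion, exposure
#' for blur correction).
#'
#' @param times time stamps, seconds, strictly increasing.
#' @param x,y bead positions, nm.
#' @param particle_id label for the tether.
#' @param frame_rate acquisition rate, Hz.
#' @param exposure camera exposure, ms.
#' @return An object of class `tpm_trajectory`.
#' @export
tpm_trajectory <- function(times, x, y, particle_id = "p1",
                           frame_rate = 25, exposure = 40) {
  if (length(times) != length(x) || length(times) != length(y))
    stop("times, x and y must have equal length")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), particle_id = particle_id,
                 frame_rate = frame_rate, exposure = exposure,
                 drift_corrected = FALSE, anchor = NULL),
            class = "tpm_trajectory")
}

#' @export
print.tpm_trajectory <- function(x, ...) {
  cat(sprintf("TPM trajectory '%s': %d frames, %.1f s at %g Hz%s\n",
              x$particle_id, length(x$times),
              diff(range(x$times)), x$frame_rate,
              if (x$drift_corrected) " (drift-corrected)" else ""))
  invisible(x)
}

# centered moving average with truncated edges
running_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the anchoring point and remove drift
#'
#' Averages the absolute positions over a centered window (5 s by
#' default) to follow the anchoring point of the tether through slow
#' stage drift, and re-expresses the positions relative to that local
#' anchor. The global anchor estimate is the overall mean position.
#'
#' @param traj a [tpm_trajectory()].
#' @param window averaging window, seconds; the trace must last at least
#'   twice this.
#' @return A list: `traj` (drift-corrected trajectory), `anchor` (global
#'   mean position, nm), `local_anchor` (per-frame anchor path, matrix).
#' @export
estimate_anchor_and_drift <- function(traj, window = 5) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  duration <- diff(range(traj$times))
  if (duration < 2 * window)
    stop(sprintf("trajectory too short: %.1f s < 2 x %.1f s window",
                 duration, window))
  half <- max(1L, round(window * traj$frame_rate / 2))
  ax <- running_mean(traj$x, half)
  ay <- running_mean(traj$y, half)
  out <- traj
  out$x <- traj$x - ax
  out$y <- traj$y - ay
  out$drift_corrected <- TRUE
  out$anchor <- c(x = mean(traj$x), y = mean(traj$y))
  list(traj = out, anchor = out$anchor,
       local_anchor = cbind(x = ax, y = ay))
}

#' Amplitude of motion of a drift-corrected trajectory
#'
#' Root-mean-squared 2D excursion from the anchor,
#' \eqn{\sqrt{\langle x^2 + y^2\rangle}}, computed over a sliding window
#' and averaged along the trace.
#'
#' @param traj a drift-corrected [tpm_trajectory()].
#' @param window sliding window, seconds.
#' @return Amplitude of motion, nm.
#' @export
amplitude_of_motion <- function(traj, window = 5) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  if (length(traj$x) == 0L) stop("empty trajectory")
  if (!traj$drift_corrected)
    warning("trajectory is not drift-corrected; interpreting positions ",
            "as relative to the anchor")
  r2 <- traj$x^2 + traj$y^2
  half <- max(1L, round(window * traj$frame_rate / 2))
  mean(sqrt(running_mean(r2, half)))
}

#' Positional correlation time of a tethered bead
#'
#' Estimates \eqn{\tau_\parallel} from the per-axis positional
#' autocorrelation of the recorded (exposure-averaged) frames. For an
#' exponentially correlated signal averaged over windows of length
#' \eqn{T_{ex}} spaced by the frame interval \eqn{T_f}, the frame
#' autocorrelation at lag \eqn{k \ge 1} is
#' \deqn{\rho_k(\tau) = A(\tau)\,e^{-kT_f/\tau}, \quad
#'   A = \frac{(\tau/T_{ex})^2 (e^{T_{ex}/\tau}-1)(1-e^{-T_{ex}/\tau})}
#'        {2\tau/T_{ex} - 2(\tau/T_{ex})^2(1 - e^{-T_{ex}/\tau})},}
#' so `tau` is obtained by a one-parameter least-squares fit of this
#' model over the leading run of positive empirical lags up to
#' `max_lag` (lag 0 is excluded: its variance carries the blur
#' attenuation). The two axis estimates are averaged.
#'
#' @param traj a drift-corrected [tpm_trajectory()] with >= 500 frames.
#' @param max_lag maximal lag entering the fit, ms.
#' @return A list: `tau_ms` (two-axis average), `tau_axis` (per-axis
#'   estimates), `ok` (`FALSE` when the autocorrelation does not decay,
#'   i.e. no usable positive lags).
#' @export
estimate_tau <- function(traj, max_lag = 200) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  n <- length(traj$x)
  if (n < 500L) stop("need at least 500 frames to estimate tau")
  t_frame <- 1000 / traj$frame_rate
  t_ex <- min(traj$exposure, t_frame)
  k_max <- max(1L, floor(max_lag / t_frame))
  model_rho <- function(tau, k) {
    x <- tau / t_ex
    amp <- x^2 * (exp(1 / x) - 1) * (1 - exp(-1 / x)) /
      blur_attenuation(tau, t_ex)
    amp * exp(-k * t_frame / tau)
  }
  fit_axis <- function(z) {
    rho <- as.numeric(acf(z, lag.max = k_max, plot = FALSE,
                          demean = TRUE)$acf)[-1L]
    if (rho[1L] <= 0) return(NA_real_)
    pos <- which(rho > 0)
    run <- pos[seq_len(which.max(c(diff(pos) != 1L, TRUE)))]
    k <- run
    sse <- function(log_tau)
      sum((rho[run] - model_rho(exp(log_tau), k))^2)
    opt <- optimize(sse, interval = log(c(t_frame / 50, 100 * t_frame)))
    exp(opt$minimum)
  }
  taus <- c(x = fit_axis(traj$x), y = fit_axis(traj$y))
  ok <- all(is.finite(taus)) && all(taus > 0) &&
    all(taus < 90 * t_frame)    # hit the upper bracket: no clean decay
  list(tau_ms = if (ok) mean(taus) else NA_real_, tau_axis = taus, ok = ok)
}

#' Asymmetry factor of the excursion cloud
#'
#' Square root of the ratio of the larger to the smaller eigenvalue of
#' the 2D position covariance: 1 for isotropic motion, large for beads
#' tethered by more than one molecule or stuck anisotropically. Standard
#' TPM quality filter.
#'
#' @param traj a drift-corrected [tpm_trajectory()] with >= 100 frames.
#' @param threshold validity cutoff on the factor.
#' @return A list: `factor`, `valid` (`factor <= threshold`).
#' @export
asymmetry_factor <- function(traj, threshold = 1.3) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  if (length(traj$x) < 100L) stop("need at least 100 frames")
  cv <- var(cbind(traj$x, traj$y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= 0)
    stop("degenerate position covariance: no 2D excursion")
  f <- sqrt(ev[1L] / ev[2L])
  list(factor = f, valid = f <= threshold)
}

#' Reduce a raw trajectory to a blur-corrected amplitude summary
#'
#' Chains the full per-tether analysis: anchor estimation and drift
#' removal, amplitude of motion, correlation time, blur correction of the
#' amplitude with the per-trace correlation time, and the asymmetry
#' quality flag.
#'
#' @param traj a raw [tpm_trajectory()].
#' @param window anchor/amplitude window, seconds.
#' @param max_lag maximal autocorrelation lag for the tau fit, ms.
#' @param asymmetry_threshold validity cutoff for [asymmetry_factor()].
#' @return A `traj_summary` list: `particle_id`, `anchor`,
#'   `amplitude_raw`, `tau_parallel`, `amplitude`, `asymmetry`, `valid`,
#'   `errors` (character vector of stage failures, empty when clean).
#' @export
summarize_trajectory <- function(traj, window = 5, max_lag = 200,
                                 asymmetry_threshold = 1.3) {
  stopifnot(inherits(traj, "tpm_trajectory"))
  errors <- character(0)
  note <- function(stage, e) sprintf("%s: %s", stage, conditionMessage(e))
  anchor <- c(x = NA_real_, y = NA_real_)
  amp_raw <- tau <- amp <- asym <- NA_real_
  valid <- FALSE
  dc <- tryCatch(estimate_anchor_and_drift(traj, window),
                 error = function(e) { errors <<- c(errors,
                   note("anchor", e)); NULL })
  if (!is.null(dc)) {
    anchor <- dc$anchor
    amp_raw <- tryCatch(amplitude_of_motion(dc$traj, window),
                        error = function(e) { errors <<- c(errors,
                          note("amplitude", e)); NA_real_ })
    tf <- tryCatch(estimate_tau(dc$traj, max_lag),
                   error = function(e) { errors <<- c(errors,
                     note("tau", e)); list(tau_ms = NA_real_, ok = FALSE) })
    tau <- tf$tau_ms
    if (!isTRUE(tf$ok))
      errors <- c(errors, "tau: autocorrelation does not decay cleanly")
    amp <- if (is.finite(amp_raw) && is.finite(tau) && tau > 0)
      blur_correct(amp_raw, tau, traj$exposure) else amp_raw
    af <- tryCatch(asymmetry_factor(dc$traj, asymmetry_threshold),
                   error = function(e) { errors <<- c(errors,
                     note("asymmetry", e)); list(factor = NA_real_,
                                                 valid = FALSE) })
    asym <- af$factor
    valid <- isTRUE(af$valid)
  }
  structure(list(particle_id = traj$particle_id, anchor = anchor,
                 amplitude_raw = amp_raw, tau_parallel = tau,
                 amplitude = amp, asymmetry = asym, valid = valid,
                 errors = errors), class = "traj_summary")
}

#' @export
print.traj_summary <- function(x, ...) {
  cat(sprintf(
    "tether %s: R_raw = %.1f nm, tau = %.1f ms, R = %.1f nm, %s\n",
    x$particle_id, x$amplitude_raw, x$tau_parallel, x$amplitude,
    if (x$valid) sprintf("valid (asymmetry %.2f)", x$asymmetry)
    else sprintf("flagged (asymmetry %.2f)", x$asymmetry)))
  if (length(x$errors))
    cat("  stage failures:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Read trajectories from CSV
#'
#' Accepts a single-particle file (columns `t_s`, `x_nm`, `y_nm`) or a
#' long-format multi-particle file with an additional `particle_id`
#' column.
#'
#' @param path CSV path.
#' @param frame_rate,exposure acquisition settings attached to each
#'   trajectory.
#' @return A list of [tpm_trajectory()] objects, named by particle.
#' @export
read_trajectories <- function(path, frame_rate = 25, exposure = 40) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns t_s, x_nm, y_nm")
  ids <- if ("particle_id" %in% names(df)) df$particle_id else "p1"
  split_df <- split(df, ids)
  out <- lapply(names(split_df), function(id) {
    d <- split_df[[id]]
    tpm_trajectory(d$t_s, d$x_nm, d$y_nm, particle_id = id,
                   frame_rate = frame_rate, exposure = exposure)
  })
  setNames(out, names(split_df))
}
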