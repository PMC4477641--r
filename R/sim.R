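#' Configuration of the tethered bead-DNA Monte Carlo simulator
#'
#' The DNA is discretized as `n_segments` rigid bonds of length
#' `segment_length` (3.41 nm = 10 bp by default); the joint stiffness
#' `kappa` (kBT) is solved from the persistence length through the
#' discrete-WLC relation \eqn{\langle\cos\phi\rangle = \coth\kappa -
#' 1/\kappa = e^{-a/L_p}}. An optional bend is imposed at one interior
#' joint by a stiff harmonic well about the target angle (or a hard
#' angular window). The chain is anchored to a hard wall at the origin
#' and carries a reporter bead whose center sits at the bead radius from
#' the chain end along a free orientation vector (a swivel, so bead and
#' DNA orientations decorrelate as the minimal particle correction
#' assumes, up to the wall and excluded-volume constraints).
#'
#' @param n_segments number of bonds (>= 2).
#' @param segment_length bond length, nm.
#' @param persistence_length target persistence length, nm.
#' @param bend_vertex interior joint index (1 .. n_segments-1) carrying
#'   the imposed bend; `NULL` for none (the middle joint is used when a
#'   `bend_angle` > 0 is given without a vertex).
#' @param bend_angle imposed bend angle, degrees in `[0, 180]`.
#' @param bead_radius reporter bead radius, nm.
#' @param wall logical; enforce the impenetrable substrate.
#' @param bead logical; attach the reporter bead.
#' @param bend_stiffness harmonic well stiffness, kBT/rad^2.
#' @param bead_exclusion reject chain configurations that penetrate the
#'   bead sphere (on by default; the large bead reshapes the accessible
#'   chain conformations appreciably).
#' @param bead_rigid attach the bead rigidly along the last bond
#'   direction instead of the free swivel.
#' @param hard_bend use a hard angular window instead of the harmonic
#'   well.
#' @param hard_tol half-width of the hard window, degrees.
#' @return An object of class `chain_params`.
#' @examples
#' chain_params(58, bend_angle = 90)    # the 575 bp construct, 90 deg kink
#' @export
chain_params <- function(n_segments, segment_length = 3.41,
                         persistence_length = 51, bend_vertex = NULL,
                         bend_angle = 0, bead_radius = 150, wall = TRUE,
                         bead = TRUE, bend_stiffness = 50,
                         hard_bend = FALSE, hard_tol = 2,
                         bead_exclusion = TRUE, bead_rigid = FALSE) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be >= 2")
  if (segment_length <= 0) stop("segment_length must be > 0")
  if (bend_angle < 0 || bend_angle > 180)
    stop("bend_angle must lie in [0, 180] degrees")
  if (is.null(bend_vertex) && bend_angle > 0)
    bend_vertex <- n_segments %/% 2L
  if (!is.null(bend_vertex)) {
    bend_vertex <- as.integer(bend_vertex)
    if (bend_vertex <= 0L || bend_vertex >= n_segments)
      stop("bend_vertex must be an interior joint: 0 < vertex < n_segments")
  }
  if (persistence_length <= 0) stop("persistence_length must be > 0")
  structure(list(
    n_segments = n_segments, segment_length = segment_length,
    persistence_length = persistence_length,
    kappa = kappa_from_lp(persistence_length, segment_length),
    bend_vertex = bend_vertex, bend_angle = bend_angle,
    bead_radius = bead_radius, wall = isTRUE(wall), bead = isTRUE(bead),
    bend_stiffness = bend_stiffness, hard_bend = isTRUE(hard_bend),
    hard_tol = hard_tol, bead_exclusion = isTRUE(bead_exclusion),
    bead_rigid = isTRUE(bead_rigid)), class = "chain_params")
}

#' Discretization helpers for the simulated tether
#'
#' `kappa_from_lp()` solves the discrete-WLC relation
#' \eqn{\coth\kappa - 1/\kappa = e^{-a/L_p}} for the joint stiffness;
#' `lp_from_kappa()` is its inverse; `mean_cos_from_kappa()` is the
#' Langevin function \eqn{\coth\kappa - 1/\kappa}.
#'
#' @param lp persistence length, nm.
#' @param a bond length, nm.
#' @param kappa joint stiffness, kBT.
#' @return A numeric scalar.
#' @export
kappa_from_lp <- function(lp, a) {
  target <- exp(-a / lp)
  if (target <= 0) stop("a/lp too large for a meaningful discretization")
  uniroot(function(k) mean_cos_from_kappa(k) - target,
          lower = 1e-6, upper = 1e6, tol = 1e-12)$root
}

#' @rdname kappa_from_lp
#' @export
lp_from_kappa <- function(kappa, a) -a / log(mean_cos_from_kappa(kappa))

#' @rdname kappa_from_lp
#' @export
mean_cos_from_kappa <- function(kappa) {
  ifelse(kappa < 1e-8, kappa / 3,
         ifelse(kappa > 20, 1 - 1 / kappa,   # coth(k) ~ 1 for large k
                1 / tanh(kappa) - 1 / kappa))
}

#' Discrete worm-like chain mean-squared end-to-end distance
#'
#' Closed form for a freely rotating / discrete-WLC chain of `N` bonds of
#' length `a` with bond-angle correlation `p` per joint:
#' \deqn{\langle R^2\rangle = Na^2\left[\frac{1+p}{1-p} -
#'   \frac{2p(1-p^N)}{N(1-p)^2}\right],}
#' the reference the simulator is validated against (`p = coth kappa -
#' 1/kappa`; `p = 0` recovers the freely jointed chain `N a^2`).
#'
#' @param N number of bonds.
#' @param a bond length, nm.
#' @param p per-joint mean cosine, in `[0, 1)`.
#' @return Mean-squared end-to-end distance, nm^2.
#' @export
discrete_wlc_r2 <- function(N, a, p) {
  if (p == 0) return(N * a^2)
  N * a^2 * ((1 + p) / (1 - p) - 2 * p * (1 - p^N) / (N * (1 - p)^2))
}

#' Build an initial chain state
#'
#' Constructs a straight chain tilted slightly off the wall normal so all
#' vertices have z > 0 and the bead clears the wall, whatever the imposed
#' bend (the bend well relaxes during burn-in).
#'
#' @param params a [chain_params()] object.
#' @param tilt_deg tilt of the chain axis from the wall normal, degrees.
#' @return A `chain_state` list: `vertices` ((n_segments+1) x 3 matrix,
#'   anchor at the origin) and `bead_center` (length-3 vector or `NULL`).
#' @export
build_chain <- function(params, tilt_deg = 10) {
  stopifnot(inherits(params, "chain_params"))
  if (tilt_deg < 0 || tilt_deg >= 90) stop("tilt_deg must be in [0, 90)")
  n <- params$n_segments; a <- params$segment_length
  dir <- c(sin(tilt_deg * pi / 180), 0, cos(tilt_deg * pi / 180))
  vertices <- outer(0:n, dir * a)
  colnames(vertices) <- c("x", "y", "z")
  bead_center <- NULL
  if (params$bead) {
    bead_center <- vertices[n + 1L, ] + params$bead_radius * dir
    if (bead_center[3] < params$bead_radius)
      stop("infeasible geometry: bead cannot clear the wall")
  }
  structure(list(vertices = vertices, bead_center = bead_center,
                 params = params), class = "chain_state")
}

#' Run the tethered-chain Metropolis sampler
#'
#' Samples the equilibrium ensemble of the tethered chain with
#' single-vertex crankshaft moves, tail pivots and bead orientation
#' resampling (symmetric proposals, energy-only Metropolis acceptance;
#' wall and bead-wall overlap rejected outright) and returns the amplitude of motion of the reporter: the RMS
#' 2D distance of the bead center (or chain end) from the anchor,
#' \eqn{R_{sim\parallel} = \sqrt{\langle x^2 + y^2\rangle}}. Standard
#' errors come from batch means over 25 batches.
#'
#' @param params a [chain_params()] object.
#' @param n_sweeps total Monte Carlo sweeps (one sweep = one attempted
#'   crankshaft per interior vertex plus `n_pivot` pivots).
#' @param burn_in sweeps discarded before recording (< `n_sweeps`).
#' @param seed integer seed; the run is fully reproducible.
#' @param step_crank,step_pivot proposal half-widths, radians.
#' @param n_pivot pivots per sweep (default `max(4, n_segments %/% 3)`);
#'   pivots are the only moves that displace the chain end, so they set
#'   the mixing rate of the end-to-end observables.
#' @return A `sim_result` list: `r_parallel`, `stderr`, `r2_3d_mean`,
#'   `r2_3d_stderr`, `n_samples`, `acceptance_rate`, `final_state`.
#'   A warning is raised if the acceptance rate falls below 1%.
#' @examples
#' \donttest{
#' p <- chain_params(58, bend_angle = 0)
#' run_chain_mc(p, n_sweeps = 20000, burn_in = 2000, seed = 1)
#' }
#' @export
run_chain_mc <- function(params, n_sweeps = 1e5, burn_in = 2000, seed = 1,
                         step_crank = 1.0, step_pivot = 0.6,
                         n_pivot = NULL) {
  stopifnot(inherits(params, "chain_params"))
  n_sweeps <- as.integer(n_sweeps); burn_in <- as.integer(burn_in)
  if (!(n_sweeps > burn_in && burn_in >= 0L))
    stop("need n_sweeps > burn_in >= 0")
  n_pivot <- n_pivot %||% max(4L, params$n_segments %/% 3L)
  state <- build_chain(params)
  set.seed(seed)
  bead_dir0 <- if (params$bead) {
    (state$bead_center - state$vertices[params$n_segments + 1L, ]) /
      params$bead_radius
  } else c(0, 0, 1)
  raw <- .mc_run(state$vertices, params$segment_length, params$kappa,
                 if (is.null(params$bend_vertex)) -1L else params$bend_vertex,
                 params$bend_angle, params$bend_stiffness,
                 params$hard_bend, params$hard_tol, params$bead_radius,
                 params$wall, params$bead,
                 params$bead && params$bead_exclusion,
                 isTRUE(params$bead_rigid), n_sweeps, burn_in,
                 step_crank, step_pivot, as.integer(n_pivot),
                 bead_dir0, 5L)
  if (raw$acceptance_rate < 0.01)
    warning(sprintf(
      "Monte Carlo acceptance rate %.2f%% is below 1%%: %s",
      100 * raw$acceptance_rate,
      "consider smaller proposal steps or a feasibility check"))
  bm_par <- batch_means(raw$rpar2)
  bm_3d <- batch_means(raw$r2_3d)
  r_par <- sqrt(bm_par$mean)
  structure(list(
    r_parallel = r_par,
    stderr = bm_par$se / (2 * r_par),    # delta method for the sqrt
    r2_par_mean = bm_par$mean, r2_par_stderr = bm_par$se,
    r2_3d_mean = bm_3d$mean, r2_3d_stderr = bm_3d$se,
    n_samples = length(raw$rpar2),
    acceptance_rate = raw$acceptance_rate,
    final_state = raw$vertices,
    params = params), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "TPM simulation: R_par = %.2f +/- %.2f nm (%d samples, %.0f%% accepted)\n",
    x$r_parallel, x$stderr, x$n_samples, 100 * x$acceptance_rate))
  invisible(x)
}

# batch-means standard error of the mean of a correlated series
batch_means <- function(x, n_batches = 25L) {
  n_batches <- min(n_batches, length(x))
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1L) * b + 1L):(i * b)]),
                  numeric(1))
  list(mean = mean(x[seq_len(n_batches * b)]),
       se = sd(means) / sqrt(n_batches))
}

#' Sweep the imposed bend angle and tabulate amplitudes of motion
#'
#' Runs [run_chain_mc()] at each angle of `theta_list` (seeding each run
#' deterministically from `seed`) and returns the simulated amplitudes,
#' ready for the validation protocol: correct with
#' [minimal_correction()], then fit \eqn{D\sqrt{1 + c\cos\theta}} with
#' `D` free.
#'
#' @param params a [chain_params()] object (its `bend_angle` is
#'   overridden per run; a mid-chain `bend_vertex` is used if unset).
#' @param theta_list bend angles, degrees in `[0, 180]`.
#' @param n_sweeps,burn_in,seed passed to [run_chain_mc()].
#' @param ... further arguments to [run_chain_mc()].
#' @return A data frame: `theta_deg`, `r_parallel_nm`, `stderr_nm`,
#'   `acceptance_rate`.
#' @export
angle_sweep <- function(params, theta_list, n_sweeps = 1e5,
                        burn_in = 2000, seed = 1, ...) {
  stopifnot(inherits(params, "chain_params"))
  if (any(theta_list < 0) || any(theta_list > 180))
    stop("theta values must lie in [0, 180] degrees")
  rows <- lapply(seq_along(theta_list), function(i) {
    th <- theta_list[i]
    p <- params
    p$bend_angle <- th
    if (is.null(p$bend_vertex)) p$bend_vertex <- p$n_segments %/% 2L
    res <- run_chain_mc(p, n_sweeps = n_sweeps, burn_in = burn_in,
                        seed = seed + 1000L * i, ...)
    data.frame(theta_deg = th, r_parallel_nm = res$r_parallel,
               stderr_nm = res$stderr,
               acceptance_rate = res$acceptance_rate)
  })
  do.call(rbind, rows)
}
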