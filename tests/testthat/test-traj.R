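test_that("anchor estimation removes drift and recovers the anchor", {
  # pure linear drift, zero noise: interior residuals vanish
  t_s <- seq(0, 60, by = 0.04)
  drift <- tpm_trajectory(t_s, 3 * t_s + 10, -2 * t_s + 5)
  dc <- estimate_anchor_and_drift(drift, window = 5)
  mid <- seq(200, length(t_s) - 200)
  expect_lt(max(abs(dc$traj$x[mid])), 1e-9)
  expect_lt(max(abs(dc$traj$y[mid])), 1e-9)
  # constant position: anchor equals it, residuals are zero
  const <- tpm_trajectory(t_s, rep(12, length(t_s)), rep(-7, length(t_s)))
  dcc <- estimate_anchor_and_drift(const)
  expect_equal(unname(dcc$anchor), c(12, -7))
  expect_equal(max(abs(dcc$traj$x)), 0)
  # zero-drift synthetic tether: anchor close to truth
  traj <- gen_trajectory(ou_params(anchor = c(50, -30), duration = 120,
                                   seed = 5))
  a <- estimate_anchor_and_drift(traj)$anchor
  expect_lt(abs(a["x"] - 50), 10)
  expect_lt(abs(a["y"] + 30), 10)
  expect_error(estimate_anchor_and_drift(
    tpm_trajectory(seq(0, 4, by = 0.04), rnorm(101), rnorm(101))),
    "too short")
})

test_that("amplitude of motion measures the RMS 2D excursion", {
  set.seed(8)
  n <- 6000
  traj <- tpm_trajectory(seq(0, by = 0.04, length.out = n),
                         rnorm(n, sd = 90), rnorm(n, sd = 90))
  dc <- estimate_anchor_and_drift(traj)$traj
  expect_equal(amplitude_of_motion(dc), 90 * sqrt(2), tolerance = 0.02)
  const <- tpm_trajectory(seq(0, by = 0.04, length.out = 500),
                          rep(0, 500), rep(0, 500))
  const$drift_corrected <- TRUE
  expect_equal(amplitude_of_motion(const), 0)
})

test_that("correlation time is recovered from blurred frames", {
  traj <- gen_trajectory(ou_params(tau = 20, duration = 300, seed = 13))
  dc <- estimate_anchor_and_drift(traj)$traj
  est <- estimate_tau(dc)
  expect_true(est$ok)
  expect_equal(est$tau_ms, 20, tolerance = 0.15)
  # per-axis estimates agree (same tau by construction)
  expect_lt(abs(diff(est$tau_axis)) / est$tau_ms, 0.5)
  # white noise: no positional correlation beyond one frame
  set.seed(14)
  wn <- tpm_trajectory(seq(0, by = 0.04, length.out = 4000),
                       rnorm(4000, sd = 50), rnorm(4000, sd = 50))
  wn$drift_corrected <- TRUE
  estw <- estimate_tau(wn)
  expect_true(!estw$ok || estw$tau_ms < 40)   # below one frame interval
  expect_error(estimate_tau(tpm_trajectory(1:100 / 25, rnorm(100),
                                           rnorm(100))),
               "500 frames")
})

test_that("asymmetry factor flags anisotropic excursion clouds", {
  set.seed(15)
  n <- 5000
  iso <- tpm_trajectory(seq_len(n) / 25, rnorm(n, sd = 80),
                        rnorm(n, sd = 80))
  iso$drift_corrected <- TRUE
  af <- asymmetry_factor(iso)
  expect_equal(af$factor, 1, tolerance = 0.05)
  expect_true(af$valid)
  aniso <- tpm_trajectory(seq_len(n) / 25, rnorm(n, sd = 160),
                          rnorm(n, sd = 80))
  af2 <- asymmetry_factor(aniso)
  expect_equal(af2$factor, 2, tolerance = 0.15)
  expect_false(af2$valid)
  oned <- tpm_trajectory(seq_len(n) / 25, rnorm(n, sd = 100),
                         rnorm(n, sd = 0.01))
  af3 <- asymmetry_factor(oned)
  expect_gt(af3$factor, 100)
  expect_false(af3$valid)
})

test_that("summarize chains the full per-tether reduction", {
  # blurred tether: raw amplitude attenuated, corrected one recovered
  true_amp <- 100 * sqrt(2)
  traj <- gen_trajectory(ou_params(tau = 20, stationary_std = 100,
                                   duration = 300, seed = 17))
  s <- summarize_trajectory(traj)
  expect_length(s$errors, 0)
  expect_true(s$valid)
  expect_lt(s$amplitude_raw, 0.80 * true_amp)
  expect_gt(s$amplitude_raw, 0.70 * true_amp)
  expect_equal(s$amplitude, true_amp, tolerance = 0.03)
  expect_gte(s$amplitude, s$amplitude_raw)
  # effectively unblurred acquisition: no inflation beyond noise
  fast <- gen_trajectory(ou_params(tau = 20, exposure = 1, n_substeps = 40,
                                   duration = 300, seed = 18))
  sf <- summarize_trajectory(fast)
  expect_equal(sf$amplitude / sf$amplitude_raw, 1, tolerance = 0.03)
  # stuck bead: tiny amplitude, stage errors recorded rather than thrown
  set.seed(19)
  stuck <- tpm_trajectory(seq(0, by = 0.04, length.out = 3000),
                          rnorm(3000, sd = 1), rnorm(3000, sd = 1))
  ss <- summarize_trajectory(stuck)
  expect_lt(ss$amplitude_raw, 5)
})

test_that("trajectory CSV round trip preserves particles", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(t_s = rep(seq(0, 19.96, by = 0.04), 2),
                   x_nm = rnorm(1000), y_nm = rnorm(1000),
                   particle_id = rep(c("a", "b"), each = 500))
  write.csv(df, tmp, row.names = FALSE)
  trajs <- read_trajectories(tmp)
  expect_named(trajs, c("a", "b"))
  expect_length(trajs$a$x, 500)
  expect_identical(trajs$b$particle_id, "b")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(u = 1), bad, row.names = FALSE)
  expect_error(read_trajectories(bad), "t_s")
})
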