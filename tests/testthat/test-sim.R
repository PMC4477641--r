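# unit tests run at reduced chain sizes and sweep counts; the full-scale
# equilibrium checks live in test-acceptance.R

test_that("build_chain constructs a feasible initial state", {
  p <- chain_params(58, segment_length = 3.41)
  st <- build_chain(p)
  bonds <- diff(st$vertices)
  expect_equal(sqrt(rowSums(bonds^2)), rep(3.41, 58), tolerance = 1e-12)
  expect_true(all(st$vertices[, "z"] >= 0))
  expect_equal(unname(st$vertices[1, ]), c(0, 0, 0))
  expect_gte(st$bead_center[3], p$bead_radius)
  # a fully folded imposed bend still admits the same feasible start
  p180 <- chain_params(58, bend_angle = 180)
  expect_silent(build_chain(p180))
  expect_error(chain_params(58, bend_vertex = 58, bend_angle = 90),
               "interior")
  expect_error(chain_params(1), "n_segments")
})

test_that("runs are reproducible under a fixed seed", {
  p <- chain_params(12, wall = FALSE, bead = FALSE)
  a <- run_chain_mc(p, n_sweeps = 2000, burn_in = 200, seed = 9)
  b <- run_chain_mc(p, n_sweeps = 2000, burn_in = 200, seed = 9)
  expect_identical(a$r_parallel, b$r_parallel)
  expect_identical(a$final_state, b$final_state)
  c_ <- run_chain_mc(p, n_sweeps = 2000, burn_in = 200, seed = 10)
  expect_false(identical(a$r_parallel, c_$r_parallel))
})

test_that("free chain equilibrium matches discrete closed forms", {
  a <- 3.41
  # near-freely-jointed: persistence length well below the bond length
  p_fjc <- chain_params(20, segment_length = a, persistence_length = 0.75,
                        wall = FALSE, bead = FALSE)
  pj <- mean_cos_from_kappa(p_fjc$kappa)
  expect_lt(pj, 0.05)
  res <- run_chain_mc(p_fjc, n_sweeps = 3e4, burn_in = 2000, seed = 21)
  # 4 sigma at this reduced sweep count: batch-means errors run ~30%
  # optimistic here (the full-scale 3-sigma checks are in acceptance)
  expect_lt(abs(res$r2_3d_mean - discrete_wlc_r2(20, a, pj)),
            4 * res$r2_3d_stderr)
  # semiflexible chain at the DNA persistence length
  p_wlc <- chain_params(20, segment_length = a, persistence_length = 51,
                        wall = FALSE, bead = FALSE)
  pj2 <- mean_cos_from_kappa(p_wlc$kappa)
  res2 <- run_chain_mc(p_wlc, n_sweeps = 3e4, burn_in = 2000, seed = 22)
  expect_lt(abs(res2$r2_3d_mean - discrete_wlc_r2(20, a, pj2)),
            4 * res2$r2_3d_stderr)
})

test_that("kappa/persistence-length conversion is consistent", {
  for (lp in c(10, 51, 150)) {
    k <- kappa_from_lp(lp, 3.41)
    expect_equal(lp_from_kappa(k, 3.41), lp, tolerance = 1e-6)
  }
  expect_equal(discrete_wlc_r2(30, 2, 0), 30 * 4)
})

test_that("free chain excursions are isotropic without the wall", {
  p <- chain_params(20, wall = FALSE, bead = FALSE)
  res <- run_chain_mc(p, n_sweeps = 3e4, burn_in = 2000, seed = 23)
  se <- sqrt(res$r2_par_stderr^2 + (2 / 3 * res$r2_3d_stderr)^2)
  expect_lt(abs(res$r2_par_mean - 2 / 3 * res$r2_3d_mean), 4 * se)
})

test_that("imposed bend matches the discrete kinked-chain oracle", {
  N <- 30; a <- 3.41
  p <- chain_params(N, segment_length = a, persistence_length = 51,
                    bend_vertex = N %/% 2, bend_angle = 90,
                    wall = FALSE, bead = FALSE)
  res <- run_chain_mc(p, n_sweeps = 4e4, burn_in = 4000, seed = 31)
  # mean cosine of the harmonic bend well (solid-angle weighted)
  k <- p$bend_stiffness; th <- pi / 2
  wgt <- function(phi) sin(phi) * exp(-k / 2 * (phi - th)^2)
  m_b <- integrate(function(phi) cos(phi) * wgt(phi), 0, pi)$value /
    integrate(wgt, 0, pi)$value
  pj <- mean_cos_from_kappa(p$kappa)
  oracle <- brute_discrete_kinked_r2(N, a, pj, N %/% 2, m_b)
  expect_lt(abs(res$r2_3d_mean - oracle), 4 * res$r2_3d_stderr)
})

test_that("hard bend window behaves like its window-averaged kink", {
  N <- 20; a <- 3.41
  p <- chain_params(N, segment_length = a, persistence_length = 51,
                    bend_vertex = N %/% 2, bend_angle = 30,
                    wall = FALSE, bead = FALSE,
                    hard_bend = TRUE, hard_tol = 2)
  res <- run_chain_mc(p, n_sweeps = 4e4, burn_in = 6000, seed = 33)
  lo <- 28 * pi / 180; hi <- 32 * pi / 180
  m_b <- (cos(lo) + cos(hi)) / 2   # solid-angle mean of cos on the window
  pj <- mean_cos_from_kappa(p$kappa)
  oracle <- brute_discrete_kinked_r2(N, a, pj, N %/% 2, m_b)
  expect_lt(abs(res$r2_3d_mean - oracle), 4 * res$r2_3d_stderr)
})

test_that("full-geometry amplitude decreases with the imposed bend", {
  p <- chain_params(58)
  sw <- angle_sweep(p, c(0, 90, 180), n_sweeps = 1.5e4, burn_in = 2000,
                    seed = 41)
  expect_equal(nrow(sw), 3L)
  gaps <- -diff(sw$r_parallel_nm)
  ses <- sqrt(sw$stderr_nm[-1]^2 + sw$stderr_nm[-3]^2)
  expect_true(all(gaps > ses))
  single <- angle_sweep(p, 45, n_sweeps = 3000, burn_in = 500, seed = 42)
  expect_equal(nrow(single), 1L)
  expect_error(angle_sweep(p, c(-5, 90)), "theta")
})

test_that("batch-means stderr shrinks as one over sqrt of sweeps", {
  p <- chain_params(10, wall = FALSE, bead = FALSE)
  sweeps <- c(2e3, 2e4, 2e5)
  ses <- vapply(sweeps, function(n)
    run_chain_mc(p, n_sweeps = n, burn_in = 500, seed = 51)$r2_3d_stderr,
    numeric(1))
  slope <- coef(stats::lm(log(ses) ~ log(sweeps)))[2]
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.7)
})
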