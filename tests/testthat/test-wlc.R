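test_that("kinked closed form reproduces the reference construct values", {
  # straight 575 bp tether at Lp = 150 bp: the canonical 121.9 nm
  expect_equal(kinked_msd(geom_mid(), 0)$root, 121.9, tolerance = 5e-4)
  # rigid-rod limit: two 100 nm arms at 90 degrees, law of cosines
  rigid <- polymer_params(200, 100, 2e6, unit = "nm")
  expect_equal(kinked_msd(rigid, 90)$root, sqrt(2) * 100,
               tolerance = 1e-3)
  # fully folded mid-bend at 51 nm persistence length, against the
  # independent quadrature oracle
  p <- polymer_params(575, 575 / 2, 51 / 0.34)
  got <- kinked_msd(p, 180)
  expect_equal(got$mean_square, quad_kinked_msd(195.5, 97.75, 51, 180),
               tolerance = 1e-5)
  expect_equal(got$root, sqrt(got$mean_square))
})

test_that("kinked_msd validates inputs", {
  p <- geom_mid()
  expect_error(kinked_msd(p, -1), "theta")
  expect_error(kinked_msd(p, 181), "theta")
  expect_error(kinked_msd(p, NaN), "theta")
  expect_error(polymer_params(575, 0, 150), "bend_position")
  expect_error(polymer_params(575, 575, 150), "bend_position")
  expect_error(polymer_params(-1, 10, 150), "contour_length")
  expect_error(polymer_params(575, 300, -5), "persistence_length")
})

test_that("cosine coefficient matches the reduced fitting forms", {
  expect_equal(round(cos_coefficient(geom_mid()), 3), 0.342)
  expect_equal(round(cos_coefficient(geom_exp()), 3), 0.338)
  # rigid limit with a mid-chain bend: 2l(L-l)/(l^2+(L-l)^2) = 1
  rigid <- polymer_params(200, 100, 2e6, unit = "nm")
  expect_equal(cos_coefficient(rigid), 1, tolerance = 1e-4)
})

test_that("kinked_msd has the right limits and monotonicity", {
  thetas <- seq(0, 180, by = 30)
  # rigid-rod limit, off-center bend so the 180-degree value stays finite
  rigid <- polymer_params(200, 60, 2e6, unit = "nm")
  locos <- 60^2 + 140^2 + 2 * 60 * 140 * cos(thetas * pi / 180)
  expect_equal(kinked_msd(rigid, thetas)$mean_square, locos,
               tolerance = 1e-3)
  # Gaussian limit: <R^2> -> 2 L Lp
  gauss <- polymer_params(5100, 2550, 51, unit = "nm")
  expect_equal(kinked_msd(gauss, 0)$mean_square / (2 * 5100 * 51), 1,
               tolerance = 0.03)
  # strictly decreasing in theta for assorted geometries
  set.seed(11)
  for (i in 1:8) {
    L <- runif(1, 50, 800)
    p <- polymer_params(L, runif(1, 0.05, 0.95) * L,
                        runif(1, 10, 120), unit = "nm")
    ms <- kinked_msd(p, seq(0, 180, by = 10))$mean_square
    expect_true(all(diff(ms) < 0))
  }
})

test_that("closed forms agree with the quadrature oracle on random inputs", {
  set.seed(42)
  for (i in 1:10) {
    L <- runif(1, 80, 500)
    l <- runif(1, 0.1, 0.9) * L
    lp <- runif(1, 20, 80)
    theta <- runif(1, 0, 180)
    p <- polymer_params(L, l, lp, unit = "nm")
    expect_equal(kinked_msd(p, theta)$mean_square,
                 quad_kinked_msd(L, l, lp, theta),
                 tolerance = 1e-4)
  }
})

test_that("single-site inversion inverts and clamps correctly", {
  # IHF literature case: raw cosine below -1, clamped to 180 degrees
  ihf <- invert_single_site(229, 249, geom_ihf())
  expect_true(ihf$clamped)
  expect_lt(ihf$cos_theta_raw, -1)
  expect_equal(ihf$theta_deg, 180)
  # no change in end-to-end distance: zero angle
  none <- invert_single_site(105.4, 105.4, geom_exp())
  expect_equal(none$theta_deg, 0)
  expect_false(none$clamped)
  # four phased tracts: 60.1 degrees total, 15.0 per tract
  four <- invert_single_site(98.5, 105.4, geom_exp())
  expect_equal(four$theta_deg, 60.082, tolerance = 1e-4)
  expect_equal(four$theta_deg / 4, 15.02, tolerance = 1e-3)
  expect_error(invert_single_site(100, 0, geom_exp()), "r_straight")
  expect_error(invert_single_site(-1, 100, geom_exp()), "r_bent")
})

test_that("inversion round-trips the closed form", {
  for (geom in list(geom_mid(), geom_exp(), geom_ihf())) {
    r0 <- kinked_msd(geom, 0)$root
    thetas <- c(1, 15, 60, 90, 135, 179)
    rb <- kinked_msd(geom, thetas)$root
    inv <- invert_single_site(rb, r0, geom)
    expect_equal(inv$theta_deg, thetas, tolerance = 1e-8)
    expect_false(any(inv$clamped))
  }
})

test_that("detection floor reproduces the 2 percent threshold", {
  expect_equal(round(detection_floor(0.02, geom_exp())), 33)
  expect_equal(detection_floor(0, geom_exp()), 0)
  expect_equal(detection_floor(0.05, geom_exp()), 52.113, tolerance = 1e-4)
  # independent of the absolute distance by construction: compare with an
  # explicit inversion at two scales
  for (r0 in c(50, 250)) {
    inv <- invert_single_site(0.98 * r0, r0, geom_exp())
    expect_equal(detection_floor(0.02, geom_exp()), inv$theta_deg,
                 tolerance = 1e-10)
  }
  expect_error(detection_floor(1, geom_exp()), "rel_change")
  expect_error(detection_floor(-0.1, geom_exp()), "rel_change")
})

test_that("unit conversion is consistent between bp and nm interfaces", {
  a <- polymer_params(575, 318, 150, unit = "bp")
  b <- polymer_params(575 * 0.34, 318 * 0.34, 51, unit = "nm")
  expect_equal(kinked_msd(a, 45)$mean_square, kinked_msd(b, 45)$mean_square)
  custom <- polymer_params(575, 318, 150, rise_per_bp = 0.32)
  expect_false(isTRUE(all.equal(kinked_msd(custom, 0)$root,
                                kinked_msd(a, 0)$root)))
})
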