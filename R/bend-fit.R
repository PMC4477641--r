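#' Assemble a bend series
#'
#' A bend series pairs the number `n` of phased bent repeats inserted in a
#' construct with the corrected end-to-end distance of that construct,
#' together with the tether geometry needed to compute the reduced-form
#' cosine coefficient.
#'
#' @param n_values repeat counts (distinct, >= 0).
#' @param r_dna corrected end-to-end distances, nm (> 0).
#' @param geometry a [polymer_params()] object for the construct.
#' @param sigma optional 1-sigma uncertainties, nm.
#' @return An object of class `bend_series`.
#' @examples
#' tab <- tpm_bend_series_table()
#' ip <- tab[tab$phase != "O", ]
#' bend_series(ip$n_repeats, minimal_correction(ip$amplitude_nm, 150),
#'             polymer_params(575, 318, 150))
#' @export
bend_series <- function(n_values, r_dna, geometry, sigma = NULL) {
  stopifnot(inherits(geometry, "polymer_params"))
  n_values <- as.numeric(n_values)
  if (length(n_values) != length(r_dna))
    stop("n_values and r_dna must have equal length")
  if (anyDuplicated(n_values)) stop("n_values must be distinct")
  if (any(n_values < 0)) stop("n_values must be >= 0")
  if (any(!is.finite(r_dna)) || any(r_dna <= 0)) stop("r_dna must be > 0")
  if (!is.null(sigma) && (length(sigma) != length(r_dna) || any(sigma < 0)))
    stop("sigma must match r_dna and be >= 0")
  structure(list(n_values = n_values, r_dna = r_dna, sigma = sigma,
                 geometry = geometry),
            class = "bend_series")
}

# model prediction R(n) = D sqrt(1 + c cos(n theta1 - theta0)), angles deg
reduced_form <- function(n, D, theta1, theta0, c_coef) {
  arg <- 1 + c_coef * cos((n * theta1 - theta0) * pi / 180)
  D * sqrt(pmax(arg, 0))
}

#' Fit the reduced kinked-WLC form to a bend series
#'
#' Least-squares fit of \eqn{R(n) = D\sqrt{1 + c\cos(n\theta_1 -
#' \theta_0)}} where the cosine coefficient `c` comes from the series
#' geometry via [cos_coefficient()]. The cosine makes the objective
#' multimodal, so the fit multi-starts on a grid over `theta1` (0-60
#' degrees, 1 degree steps) and, when `with_theta0`, over `theta0` (-90 to
#' 90, 5 degree steps); `D` is profiled out in closed form at each grid
#' node and the best node is polished by a quasi-Newton step. Ties are
#' broken by the lower residual, then the smaller `theta1`.
#'
#' @param data a [bend_series()] object with at least 3 points (4 when
#'   `with_theta0`).
#' @param with_theta0 also fit the intrinsic global angle `theta0`
#'   (otherwise fixed at 0).
#' @param weighted use `1/sigma^2` weights (requires `sigma` in `data`).
#'   Unweighted by default.
#' @return A `bend_fit` list: `amplitude_D`, `theta1`, `theta0`, standard
#'   errors `se_D`, `se_theta1`, `se_theta0` (from the local curvature of
#'   the objective), `residual_rms` (nm), `converged`, `c_coef`,
#'   `fitted`, `data`.
#' @examples
#' tab <- tpm_bend_series_table()
#' ip <- tab[tab$phase != "O", ]
#' bs <- bend_series(ip$n_repeats, minimal_correction(ip$amplitude_nm, 150),
#'                   polymer_params(575, 318, 150))
#' fit_series(bs)                     # D ~ 92 nm, theta1 ~ 15 deg
#' fit_series(bs, with_theta0 = TRUE) # D ~ 91 nm, theta1 ~ 19, theta0 ~ 25
#' @export
fit_series <- function(data, with_theta0 = FALSE, weighted = FALSE) {
  stopifnot(inherits(data, "bend_series"))
  m <- length(data$n_values)
  n_par <- if (with_theta0) 3L else 2L
  if (m < n_par + 1L)
    stop(sprintf("need at least %d points for a %d-parameter fit",
                 n_par + 1L, n_par))
  if (weighted && is.null(data$sigma))
    stop("weighted fit requires sigma in the series")
  w <- if (weighted) 1 / data$sigma^2 else rep(1, m)
  c_coef <- cos_coefficient(data$geometry)
  n <- data$n_values; R <- data$r_dna

  profile_ssr <- function(theta1, theta0) {
    f <- sqrt(pmax(1 + c_coef * cos((n * theta1 - theta0) * pi / 180), 0))
    D <- sum(w * f * R) / sum(w * f^2)
    c(ssr = sum(w * (R - D * f)^2), D = D)
  }
  grid <- expand.grid(theta1 = seq(0, 60, by = 1),
                      theta0 = if (with_theta0) seq(-90, 90, by = 5) else 0)
  prof <- mapply(profile_ssr, grid$theta1, grid$theta0)
  ord <- order(prof["ssr", ], grid$theta1)
  best <- ord[1L]
  start <- c(D = prof["D", best], theta1 = grid$theta1[best],
             theta0 = if (with_theta0) grid$theta0[best] else NULL)

  obj <- function(p)
    sum(w * (R - reduced_form(n, p[1L], p[2L],
                              if (with_theta0) p[3L] else 0, c_coef))^2)
  opt <- optim(start, obj, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  p <- opt$par
  # canonical branch: (theta1, theta0) and (-theta1, -theta0) are equivalent
  if (p[2L] < 0) {
    p[2L] <- -p[2L]
    if (with_theta0) p[3L] <- -p[3L]
  }
  resid <- R - reduced_form(n, p[1L], p[2L],
                            if (with_theta0) p[3L] else 0, c_coef)
  dof <- m - n_par
  s2 <- opt$value / max(dof, 1L)
  # 1-sigma from the curvature of the (weighted) SSR surface
  se <- tryCatch(sqrt(diag(2 * s2 * solve(opt$hessian))),
                 error = function(e) rep(NA_real_, n_par))
  structure(list(
    amplitude_D = unname(p[1L]),
    theta1 = unname(p[2L]),
    theta0 = if (with_theta0) unname(p[3L]) else 0,
    se_D = se[1L], se_theta1 = se[2L],
    se_theta0 = if (with_theta0) se[3L] else 0,
    residual_rms = sqrt(mean(resid^2)),
    converged = opt$convergence == 0L,
    c_coef = c_coef,
    fitted = reduced_form(n, p[1L], p[2L],
                          if (with_theta0) p[3L] else 0, c_coef),
    data = data), class = "bend_fit")
}

#' @export
print.bend_fit <- function(x, ...) {
  cat("Kinked-WLC bend-series fit\n")
  cat(sprintf("  D      = %.1f +/- %.1f nm\n", x$amplitude_D, x$se_D))
  cat(sprintf("  theta1 = %.1f +/- %.1f deg\n", x$theta1, x$se_theta1))
  if (x$theta0 != 0 || x$se_theta0 != 0)
    cat(sprintf("  theta0 = %.1f +/- %.1f deg\n", x$theta0, x$se_theta0))
  cat(sprintf("  cosine coefficient c = %.3f, residual RMS = %.2f nm\n",
              x$c_coef, x$residual_rms))
  invisible(x)
}

#' Per-insert bend angles by the single-site inversion
#'
#' Applies [invert_single_site()] to each construct of a bend series
#' against a reference construct (typically `n = 0`) and divides the
#' recovered total angle by the repeat count, yielding one per-insert
#' angle estimate per construct.
#'
#' @param data a [bend_series()] object.
#' @param reference_n repeat count of the reference (straight) construct.
#' @return A list: `table` (data frame with `n`, `theta_total`,
#'   `theta_per_insert`, `clamped`), `mean`, `sd` of the per-insert
#'   angles.
#' @examples
#' tab <- tpm_bend_series_table()
#' keep <- tab$sample %in% c("6An0", "6An4P", "6An6P", "6An7P")
#' bs <- bend_series(tab$n_repeats[keep],
#'                   minimal_correction(tab$amplitude_nm[keep], 150),
#'                   polymer_params(575, 318, 150))
#' per_insert_angles(bs)   # mean ~15 deg, sd ~2 deg
#' @export
per_insert_angles <- function(data, reference_n = 0) {
  stopifnot(inherits(data, "bend_series"))
  iref <- which(data$n_values == reference_n)
  if (length(iref) != 1L)
    stop(sprintf("reference n = %s not present in the series", reference_n))
  r0 <- data$r_dna[iref]
  keep <- data$n_values > reference_n
  if (!any(keep)) stop("no constructs beyond the reference to invert")
  inv <- invert_single_site(data$r_dna[keep], r0, data$geometry)
  per <- inv$theta_deg / data$n_values[keep]
  list(table = data.frame(n = data$n_values[keep],
                          theta_total = inv$theta_deg,
                          theta_per_insert = per,
                          clamped = inv$clamped),
       mean = mean(per), sd = sd(per))
}
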