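#' Polymer geometry of a tethered DNA with one bend locus
#'
#' Bundles the contour length \eqn{L}, the position \eqn{l} of the bend
#' measured from the anchored end, and the persistence length \eqn{L_p}.
#' Lengths may be given in base pairs or nanometres; everything is stored in
#' nanometres internally using the helical rise (0.34 nm/bp for B-DNA).
#'
#' @param contour_length total contour length \eqn{L} (> 0).
#' @param bend_position distance \eqn{l} of the bend from the anchored end,
#'   strictly inside `(0, contour_length)`.
#' @param persistence_length tangent-correlation decay length \eqn{L_p}
#'   (> 0). Default 150 bp (51 nm), the value appropriate for B-DNA at
#'   physiological ionic strength in this workflow.
#' @param unit `"bp"` or `"nm"`; unit of the three lengths above.
#' @param rise_per_bp helical rise in nm/bp used for the conversion.
#'
#' @return An object of class `polymer_params` with fields `L_nm`, `l_nm`,
#'   `lp_nm` and `rise_per_bp`.
#' @examples
#' polymer_params(575, 318, 150)            # the 575 bp construct
#' polymer_params(195.5, 97.75, 51, unit = "nm")
#' @export
polymer_params <- function(contour_length, bend_position,
                           persistence_length = 150,
                           unit = c("bp", "nm"), rise_per_bp = 0.34) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(contour_length), length(contour_length) == 1L,
            is.numeric(bend_position), length(bend_position) == 1L,
            is.numeric(persistence_length), length(persistence_length) == 1L,
            is.numeric(rise_per_bp), rise_per_bp > 0)
  if (!is.finite(contour_length) || contour_length <= 0)
    stop("contour_length must be finite and > 0")
  if (!is.finite(bend_position) || bend_position <= 0 ||
      bend_position >= contour_length)
    stop("bend_position must lie strictly inside (0, contour_length)")
  if (!is.finite(persistence_length) || persistence_length <= 0)
    stop("persistence_length must be finite and > 0")
  f <- if (unit == "bp") rise_per_bp else 1
  structure(
    list(L_nm = contour_length * f,
         l_nm = bend_position * f,
         lp_nm = persistence_length * f,
         rise_per_bp = rise_per_bp),
    class = "polymer_params")
}

#' @export
print.polymer_params <- function(x, ...) {
  cat(sprintf(
    "Tethered DNA geometry: L = %.1f nm, bend at l = %.1f nm, Lp = %.1f nm\n",
    x$L_nm, x$l_nm, x$lp_nm))
  invisible(x)
}

#' Bend model parameters for a phased-repeat construct
#'
#' Holds the angles of the kinked-WLC reduced fitting forms: the total bend
#' `theta`, the per-repeat angle `theta1`, the intrinsic global angle
#' `theta0` and the amplitude scale `D` of
#' \eqn{R(n) = D\sqrt{1 + c\cos(n\theta_1 - \theta_0)}}.
#'
#' @param theta total bend angle, degrees in `[0, 180]` (or `NA`).
#' @param theta1 per-repeat bend angle, degrees.
#' @param theta0 intrinsic global bend angle, degrees.
#' @param n_repeats number of phased repeats (>= 0).
#' @param amplitude_D amplitude scale in nm (> 0 when set).
#' @return An object of class `bend_model`.
#' @export
bend_model <- function(theta = NA_real_, theta1 = NA_real_,
                       theta0 = 0, n_repeats = 0L, amplitude_D = NA_real_) {
  if (!is.na(theta) && (theta < 0 || theta > 180))
    stop("theta must lie in [0, 180] degrees")
  if (n_repeats < 0) stop("n_repeats must be >= 0")
  if (!is.na(amplitude_D) && amplitude_D <= 0)
    stop("amplitude_D must be > 0 when set")
  structure(list(theta = theta, theta1 = theta1, theta0 = theta0,
                 n_repeats = as.integer(n_repeats),
                 amplitude_D = amplitude_D),
            class = "bend_model")
}

# internal: package an <R^2> value as an msd_result
msd_result <- function(mean_square) {
  if (any(!is.finite(mean_square)) || any(mean_square < 0))
    stop("mean-square end-to-end distance must be finite and >= 0")
  structure(list(mean_square = mean_square, root = sqrt(mean_square)),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat("WLC end-to-end distance\n")
  cat("  <R^2> =", format(x$mean_square, digits = 6), "nm^2\n")
  cat("  root  =", format(x$root, digits = 6), "nm\n")
  invisible(x)
}
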