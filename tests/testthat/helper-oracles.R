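# Independent quadrature oracles for the WLC closed forms.
#
# The mean-squared end-to-end distance of a chain with tangent
# correlation K(s, s') is the double integral of K over [0, L]^2. For a
# (possibly heterogeneous) WLC, K = exp(-|phi(s) - phi(s')|) with
# phi(s) = int_0^s du / Lp(u); a kink at arclength l multiplies K by
# cos(theta) for pairs straddling l. The oracle integrates numerically
# by composite Simpson on blocks split at the kink and at persistence-
# length discontinuities, so the only non-smooth line is the diagonal.

simpson_weights <- function(a, b, n) {
  stopifnot(n %% 2L == 1L, n >= 3L)
  h <- (b - a) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  list(x = seq(a, b, length.out = n), w = w * h / 3)
}

quad_block <- function(sa, sb, ta, tb, phi_fun, n = 601L) {
  if (sa == ta && sb == tb) {
    # diagonal block: phi is linear inside a block (constant Lp), so the
    # square integral of K(|s-t|) reduces to the smooth 1D integral
    # 2 int_0^D (D - u) K(u) du, avoiding the ridge along the diagonal
    D <- sb - sa
    g <- simpson_weights(0, D, n)
    integrand <- (D - g$x) * exp(-(phi_fun(sa + g$x) - phi_fun(sa)))
    return(2 * sum(g$w * integrand))
  }
  gs <- simpson_weights(sa, sb, n)
  gt <- simpson_weights(ta, tb, n)
  K <- exp(-abs(outer(phi_fun(gs$x), phi_fun(gt$x), "-")))
  as.numeric(gs$w %*% K %*% gt$w)
}

# uniform WLC with one kink of angle theta (degrees) at arclength l
quad_kinked_msd <- function(L, l, lp, theta, n = 601L) {
  phi <- function(u) u / lp
  same <- quad_block(0, l, 0, l, phi, n) + quad_block(l, L, l, L, phi, n)
  cross <- quad_block(0, l, l, L, phi, n)
  same + 2 * cos(theta * pi / 180) * cross
}

# piecewise-constant persistence length, no kink
quad_het_msd <- function(L, insert_start, insert_length, lp_flank,
                         lp_insert, n = 601L) {
  breaks <- sort(unique(pmin(pmax(
    c(0, insert_start, insert_start + insert_length, L), 0), L)))
  lp_of <- function(u)
    ifelse(u >= insert_start & u < insert_start + insert_length,
           lp_insert, lp_flank)
  phi <- function(u) {
    vapply(u, function(s) {
      below <- pmin(breaks[-1], s) - pmin(breaks[-length(breaks)], s)
      mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
      sum(pmax(below, 0) / lp_of(mids))
    }, numeric(1))
  }
  total <- 0
  m <- length(breaks) - 1L
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (breaks[i + 1L] > breaks[i] && breaks[j + 1L] > breaks[j])
      total <- total + quad_block(breaks[i], breaks[i + 1L],
                                  breaks[j], breaks[j + 1L], phi, n)
  }
  total
}

# brute-force discrete kinked chain: a^2 sum_ij prod of per-joint factors
brute_discrete_kinked_r2 <- function(N, a, p, bend_joint, cos_theta) {
  tot <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) { tot <- tot + 1; next }
    lo <- min(i, j); hi <- max(i, j)
    joints <- lo:(hi - 1L)               # joints crossed between bonds
    f <- prod(ifelse(joints == bend_joint, cos_theta, p))
    tot <- tot + f
  }
  a^2 * tot
}

# the geometries used throughout
geom_mid <- function() polymer_params(575, 575 / 2, 150)
geom_exp <- function() polymer_params(575, 318, 150)
geom_ihf <- function() polymer_params(1943, 301, 150)
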