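# Radial building blocks: normalized Slater-type functions and their
# closed-form electrostatic potentials and moments.
#
# Spherical density component (core or valence), unit charge:
#   D(r) = zeta^(n+3) / (4*pi*(n+2)!) * r^n * exp(-zeta*r)
#   with  int D(r) 4 pi r^2 dr = 1
# Deformation radial function for angular momentum l:
#   R_l(r) = zeta^(n+3) / (n+2)! * r^n * exp(-zeta*r)
#   with  int R_l(r) r^2 dr = 1
# The kappa / kappa' expansion-contraction scaling of the Hansen model,
# kappa^3 rho(kappa r), is absorbed exactly by replacing zeta with
# kappa*zeta: the normalization prefactor is form-invariant.

# validate a data.frame of Slater terms (columns c, n, zeta)
.check_slater_terms <- function(df, what) {
  if (!is.data.frame(df) || !all(c("c", "n", "zeta") %in% names(df)))
    stop(what, ": Slater terms need columns c, n, zeta")
  if (any(df$zeta <= 0)) stop(what, ": Slater exponents must be positive")
  if (any(df$n < 0 | df$n != round(df$n)))
    stop(what, ": radial powers n must be non-negative integers")
  if (nrow(df) > 0 && abs(sum(df$c) - 1) > 1e-8)
    stop(what, ": coefficients must sum to 1 (density normalized to one ",
         "electron); got ", sum(df$c))
  invisible(df)
}

# density of a normalized spherical Slater sum at radii r (unit charge)
.slater_sphere_density <- function(r, terms) {
  out <- numeric(length(r))
  for (k in seq_len(nrow(terms))) {
    n <- terms$n[k]; z <- terms$zeta[k]
    N <- z^(n + 3) / (4 * pi * gamma(n + 3))
    out <- out + terms$c[k] * N * r^n * exp(-z * r)
  }
  out
}

# electrostatic potential at radii r of a normalized spherical Slater sum
# carrying unit charge; closed form via regularized incomplete gammas:
#   phi(r) = P(n+3, z r)/r + z * Q(n+2, z r)/(n+2)
.slater_sphere_potential <- function(r, terms) {
  out <- numeric(length(r))
  for (k in seq_len(nrow(terms))) {
    n <- terms$n[k]; z <- terms$zeta[k]
    x <- z * r
    inner <- stats::pgamma(x, n + 3) / r
    outer_ <- z * stats::pgamma(x, n + 2, lower.tail = FALSE) / (n + 2)
    # r -> 0 limit: z/(n+2)
    inner[r == 0] <- 0
    out <- out + terms$c[k] * (inner + outer_)
  }
  out
}

# radial factor g_l(r) of the potential generated by a density
# F(r) * y_lm(Omega) with F the unit-normalized deformation radial
# function (power n, exponent z):
#   phi(r, Omega) = 4*pi/(2l+1) * y_lm(Omega) * g_l(r)
#   g_l(r) = r^-(l+1) int_0^r F s^(l+2) ds + r^l int_r^inf F s^(1-l) ds
# Requires n >= l so both incomplete-gamma shapes are positive.
.slater_defo_potential_radial <- function(r, l, n, z) {
  if (n < l) stop("deformation radial power n must be >= l")
  x <- z * r
  A <- gamma(n + l + 3) / (gamma(n + 3) * z^l)
  B <- z^(l + 1) * gamma(n + 2 - l) / gamma(n + 3)
  g <- A * stats::pgamma(x, n + l + 3) / r^(l + 1) +
    B * stats::pgamma(x, n + 2 - l, lower.tail = FALSE) * r^l
  g[r == 0] <- if (l == 0L) z / (n + 2) else 0
  g
}

# l-th radial moment int r^l F(r) r^2 dr of the unit-normalized
# deformation radial function (closed form)
.slater_defo_radial_moment <- function(l, n, z) {
  gamma(n + l + 3) / (gamma(n + 3) * z^l)
}

#' Closed-form Coulomb integral of two 1s Slater clouds
#'
#' Electron-electron Coulomb repulsion integral between two spherical
#' exponential densities \eqn{\rho(r) = (\alpha^3/8\pi) e^{-\alpha r}}
#' (each carrying unit charge) with equal exponents, centered a distance R
#' apart:
#' \deqn{J(R) = 1/R - e^{-\alpha R}(1/R + 11\alpha/16 + 3\alpha^2 R/16 +
#'   \alpha^3 R^2/48)}
#' This is the textbook two-center 1s-1s Coulomb integral and serves as an
#' independent analytic reference for the exact pair-energy integrator.
#'
#' @param alpha exponent of the density (inverse bohr); corresponds to a
#'   1s orbital exponent of alpha/2.
#' @param R separation in bohr.
#' @return energy in hartree for unit charges (multiply by q1*q2).
#' @export
slater_1s_coulomb <- function(alpha, R) {
  1 / R - exp(-alpha * R) *
    (1 / R + 11 * alpha / 16 + 3 * alpha^2 * R / 16 + alpha^3 * R^2 / 48)
}
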