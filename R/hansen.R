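#' Construct a Hansen-Coppens pseudoatom
#'
#' Represents one atom's electron density in the multipole pseudoatom
#' formalism:
#' \deqn{\rho(r) = P_c \rho_c(r) + P_v \kappa^3 \rho_v(\kappa r) +
#'   \sum_{l=0}^{l_{max}} \kappa'^3 R_l(\kappa' r)
#'   \sum_m P_{lm} y_{lm}(\theta,\phi)}
#' where \eqn{\rho_c}, \eqn{\rho_v} are spherical core and valence
#' densities (normalized sums of Slater terms, one electron each),
#' \eqn{R_l} are unit-normalized Slater radial functions and
#' \eqn{y_{lm}} are density-normalized real spherical harmonics. The
#' multipole populations are defined in the atom's local coordinate frame.
#'
#' @param Z nuclear charge (positive integer).
#' @param Pc,Pv core and valence populations (electrons).
#' @param kappa,kappap dimensionless valence and deformation
#'   expansion-contraction parameters.
#' @param core,valence data.frames of Slater terms with columns `c`, `n`,
#'   `zeta` (coefficients summing to 1; zeta in inverse bohr).
#' @param def list of deformation levels; each element is a list with
#'   fields `l`, `n`, `zeta` and `P`, a numeric vector of 2l+1
#'   populations ordered m = -l..l. At most one element per l.
#' @param lmax highest angular momentum retained (default: highest l
#'   present in `def`, or 0).
#' @return object of class `hansen_atom`.
#' @export
hansen_atom <- function(Z, Pc, Pv, kappa = 1, kappap = 1,
                        core = data.frame(c = numeric(), n = integer(),
                                          zeta = numeric()),
                        valence = core, def = list(), lmax = NULL) {
  stopifnot(Z == round(Z), Z > 0, kappa > 0, kappap > 0, Pc >= 0, Pv >= 0)
  if (Pc + Pv > Z + 2)
    stop("Pc + Pv = ", Pc + Pv, " exceeds sanity bound Z + 2")
  if (Pc > 0 && nrow(core) == 0) stop("Pc > 0 requires core Slater terms")
  if (Pv > 0 && nrow(valence) == 0)
    stop("Pv > 0 requires valence Slater terms")
  if (nrow(core)) .check_slater_terms(core, "core")
  if (nrow(valence)) .check_slater_terms(valence, "valence")
  ls <- vapply(def, function(d) as.integer(d$l), integer(1))
  if (anyDuplicated(ls)) stop("duplicate deformation level l")
  for (d in def) {
    if (length(d$P) != 2L * d$l + 1L)
      stop("deformation l = ", d$l, " needs ", 2 * d$l + 1, " populations")
    if (d$zeta <= 0) stop("deformation zeta must be positive")
    if (d$n < d$l) stop("deformation radial power n must be >= l")
  }
  if (is.null(lmax)) lmax <- if (length(ls)) max(ls) else 0L
  if (lmax < 0L) stop("lmax must be >= 0")
  structure(list(Z = as.integer(Z), Pc = Pc, Pv = Pv,
                 kappa = kappa, kappap = kappap,
                 core = core, valence = valence, def = def,
                 lmax = as.integer(lmax)),
            class = "hansen_atom")
}

# effective Slater terms with kappa scaling folded into the exponents
.kappa_scaled_valence <- function(atom) {
  v <- atom$valence
  if (nrow(v)) v$zeta <- v$zeta * atom$kappa
  v
}
.kappa_scaled_def <- function(atom) {
  lapply(atom$def, function(d) {
    d$zeta_eff <- d$zeta * atom$kappap
    d
  })
}

#' Evaluate a pseudoatom electron density
#'
#' Evaluates the Hansen-Coppens electron density of one atom at points in
#' space. The multipole populations stored in the atom are interpreted in
#' the local frame given by `frame` (local -> global rotation); the atom
#' sits at `origin`.
#'
#' @param atom a [hansen_atom()].
#' @param points numeric 3-vector or n x 3 matrix of evaluation points
#'   (bohr, global coordinates).
#' @param origin position of the nucleus (bohr).
#' @param frame 3x3 rotation whose columns are the local axes expressed in
#'   global coordinates (identity by default).
#' @param plm optional per-l population list overriding the populations
#'   stored in `atom$def` (e.g. populations already rotated to the global
#'   frame, in which case `frame` should stay the identity).
#' @return electron density values, e/bohr^3 (electrons positive).
#' @export
eval_density <- function(atom, points, origin = c(0, 0, 0),
                         frame = diag(3), plm = NULL) {
  p <- matrix(points, ncol = 3)
  d <- sweep(p, 2, as.numeric(origin))
  dl <- d %*% frame                 # coordinates in the local frame
  r <- sqrt(rowSums(dl^2))
  out <- numeric(nrow(p))
  if (atom$Pc > 0)
    out <- out + atom$Pc * .slater_sphere_density(r, atom$core)
  if (atom$Pv > 0)
    out <- out + atom$Pv * .slater_sphere_density(r, .kappa_scaled_valence(atom))
  for (dd in .kappa_scaled_def(atom)) {
    if (!is.null(plm) && dd$l + 1L <= length(plm)) dd$P <- plm[[dd$l + 1L]]
    if (all(dd$P == 0)) next
    N <- dd$zeta_eff^(dd$n + 3) / gamma(dd$n + 3)
    Fr <- N * r^dd$n * exp(-dd$zeta_eff * r)
    ang <- numeric(nrow(p))
    ok <- r > 0
    for (j in seq_along(dd$P)) {
      m <- j - dd$l - 1L
      if (dd$P[j] == 0) next
      ang[ok] <- ang[ok] +
        dd$P[j] * density_normalized_ylm(dd$l, m, dl[ok, , drop = FALSE])
    }
    out <- out + Fr * ang
  }
  out
}

#' Atomic multipole moments of a pseudoatom
#'
#' Closed-form real multipole moments of the total atomic charge density
#' (nucleus + electrons, electrons negative), in the traceless real
#' (Racah-normalized) convention: Q_00 is the net atomic charge in e, the
#' l = 1 block is the dipole vector in e*bohr ordered (mu_y, mu_z, mu_x),
#' and generally block l holds
#' \eqn{Q_{lm} = \int \rho_{charge}(r) r^l S_{lm}(\hat r) d^3r} with S_lm
#' the Racah real harmonics, ordered m = -l..l.
#'
#' Moments are reported in the same frame in which the populations are
#' expressed (the atom's local frame unless they were rotated first).
#'
#' @param atom a [hansen_atom()].
#' @param plm optional replacement population list (per-l list as in
#'   [rotate_multipoles()]); defaults to the populations in `atom$def`.
#' @return object of class `atomic_moments`: list with `lmax`, `q` (list
#'   of per-l Racah moment vectors) and `charge`.
#' @export
atomic_moments <- function(atom, plm = NULL) {
  lmax <- atom$lmax
  def <- .kappa_scaled_def(atom)
  if (!is.null(plm)) {
    for (li in seq_along(def)) {
      l <- def[[li]]$l
      if (l + 1L <= length(plm)) def[[li]]$P <- plm[[l + 1L]]
    }
  }
  q <- lapply(0:lmax, function(l) numeric(2L * l + 1L))
  p00 <- 0
  for (dd in def) {
    if (dd$l == 0L) { p00 <- dd$P[1]; }
    if (dd$l > lmax || all(dd$P == 0)) next
    radial <- .slater_defo_radial_moment(dd$l, dd$n, dd$zeta_eff)
    f <- .density_norm_factor(dd$l, seq(-dd$l, dd$l))
    if (dd$l == 0L) next  # handled through the net charge below
    # electrons carry negative charge; convert orthonormal-Y moments to
    # the Racah convention
    racah <- sqrt(4 * pi / (2 * dd$l + 1))
    q[[dd$l + 1L]] <- -dd$P * f * radial * racah
  }
  # net charge: nucleus minus all spherical electron counts;
  # the l = 0 deformation term integrates to exactly P00 electrons
  q[[1]][1] <- atom$Z - atom$Pc - atom$Pv - p00
  structure(list(lmax = lmax, q = q, charge = q[[1]][1]),
            class = "atomic_moments")
}
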