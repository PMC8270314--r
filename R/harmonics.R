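#' @importFrom pracma legendre
NULL

# package-level cache for quadrature-derived tables (rotation bases,
# multipole interaction constants)
.pa_cache <- new.env(parent = emptyenv())

# conversion factors f(l, |m|) between wavefunction-normalized real
# spherical harmonics Y_lm and density-normalized harmonics y_lm:
#   y_lm = f(l,|m|) * Y_lm,   with  int |y_lm| dOmega = 2  (l > 0)
#   y_00 = 1/(4*pi)
# Values are 2 / int|Y_lm|dOmega, precomputed to full double precision.
.DENSITY_NORM_F <- list(
  `0` = 2.8209479177387814e-01,
  `1` = c(6.5147001587055986e-01, 6.5147001587055986e-01),
  `2` = c(6.5552906573015968e-01, 6.8646842464782665e-01,
          6.8646842464782665e-01),
  `3` = c(6.5613423947691962e-01, 7.0087745306882732e-01,
          6.9189513695864069e-01, 7.1929123343438506e-01),
  `4` = c(6.5620995534266469e-01, 7.0847466992954489e-01,
          6.9879558002116671e-01, 7.0616251710906353e-01,
          7.4899845670137033e-01)
)

# f(l, m): density/wavefunction normalization ratio; m may be signed
.density_norm_factor <- function(l, m) {
  .DENSITY_NORM_F[[as.character(l)]][abs(m) + 1L]
}

# Wavefunction-normalized (orthonormal) real spherical harmonics without
# the Condon-Shortley phase, evaluated on unit vectors.
#
# u: n x 3 matrix of unit vectors. Returns a length-n vector.
.real_sph_Y <- function(l, m, u) {
  if (abs(m) > l) stop("|m| must be <= l")
  u <- matrix(u, ncol = 3)
  ct <- pmin(1, pmax(-1, u[, 3]))
  am <- abs(m)
  if (l == 0L) return(rep(1 / sqrt(4 * pi), nrow(u)))
  # pracma::legendre returns (l+1) x n matrix of P_l^m, MATLAB phase
  # convention (includes Condon-Shortley); strip the (-1)^m factor.
  P <- pracma::legendre(l, ct)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  Plm <- (-1)^am * P[am + 1L, ]
  if (am == 0L) {
    N <- sqrt((2 * l + 1) / (4 * pi))
    return(N * Plm)
  }
  N <- sqrt(2 * (2 * l + 1) / (4 * pi) *
              factorial(l - am) / factorial(l + am))
  phi <- atan2(u[, 2], u[, 1])
  if (m > 0) N * Plm * cos(am * phi) else N * Plm * sin(am * phi)
}

#' Real spherical harmonics in density normalization
#'
#' Evaluates the real spherical harmonic \eqn{y_{lm}} in the density
#' normalization used by the Hansen-Coppens pseudoatom model:
#' \eqn{\int |y_{lm}| d\Omega = 2} for \eqn{l > 0}, and
#' \eqn{y_{00} = 1/(4\pi)}. In this convention a deformation population
#' P_lm directly measures the number of electrons moved between the
#' positive and negative lobes of the harmonic.
#'
#' Negative m selects the sine-type (imaginary-part) harmonic, positive m
#' the cosine type; the Condon-Shortley phase is not used, so
#' \eqn{y_{11} \propto +x/r}.
#'
#' @param l integer, 0 <= l.
#' @param m signed integer, |m| <= l.
#' @param direction numeric 3-vector or n x 3 matrix of directions (need
#'   not be normalized).
#' @return numeric vector of harmonic values (1/steradian).
#' @examples
#' density_normalized_ylm(0, 0, c(0, 0, 1))  # 1/(4*pi)
#' density_normalized_ylm(1, 0, c(0, 0, 1))  # dipole "z" lobe maximum
#' @export
density_normalized_ylm <- function(l, m, direction) {
  if (l < 0L || abs(m) > l) stop("require 0 <= |m| <= l")
  u <- matrix(direction, ncol = 3)
  nrm <- sqrt(rowSums(u^2))
  if (any(nrm == 0)) stop("zero direction vector")
  u <- u / nrm
  .density_norm_factor(l, m) * .real_sph_Y(l, m, u)
}

# Fixed, well-spread direction set (Fibonacci sphere) used to solve for
# spherical-harmonic rotation matrices by least squares.
.rotation_dirs <- function(k = 64L) {
  key <- paste0("dirs", k)
  if (!is.null(.pa_cache[[key]])) return(.pa_cache[[key]])
  i <- seq_len(k) - 0.5
  z <- 1 - 2 * i / k
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  u <- cbind(r * cos(ga * i), r * sin(ga * i), z)
  .pa_cache[[key]] <- u
  u
}

# Pseudoinverse of the design matrix B[k, m'] = Y_lm'(u_k), cached per l.
.rotation_basis_pinv <- function(l) {
  key <- paste0("pinvB", l)
  if (!is.null(.pa_cache[[key]])) return(.pa_cache[[key]])
  u <- .rotation_dirs()
  B <- sapply(seq(-l, l), function(m) .real_sph_Y(l, m, u))
  B <- matrix(B, nrow = nrow(u))
  pinv <- solve(crossprod(B), t(B))
  .pa_cache[[key]] <- pinv
  pinv
}

# Rotation matrix D(l, R) for orthonormal real spherical harmonics:
#   Y_lm(R^T u) = sum_m' D[m', m] Y_lm'(u)
# so that a vector of coefficients in the Y basis transforms as v' = D v
# when the density is rotated by R. Solved exactly (to numerical
# precision) by projection on a fixed direction set; avoids transcribing
# recursion tables for the real-harmonic Wigner matrices.
.sph_rotation_Y <- function(l, R) {
  if (l == 0L) return(matrix(1, 1, 1))
  u <- .rotation_dirs()
  v <- u %*% R                       # rows are (R^T u_k)^T
  Tm <- sapply(seq(-l, l), function(m) .real_sph_Y(l, m, v))
  .rotation_basis_pinv(l) %*% matrix(Tm, nrow = nrow(u))
}

#' Rotate multipole populations between frames
#'
#' Transforms density-normalized multipole populations P_lm under a proper
#' rotation of the atom (or of its local coordinate frame). Blocks of equal
#' l transform independently; the Euclidean norm of the wavefunction-scaled
#' coefficients within each l block is preserved.
#'
#' @param plm list of population vectors, one element per l starting at
#'   l = 0; element for angular momentum l has length 2l+1, ordered
#'   m = -l, ..., +l (sine-type harmonics first).
#' @param rotation 3x3 proper rotation matrix (det = +1).
#' @return list of rotated population vectors of the same shape.
#' @export
rotate_multipoles <- function(plm, rotation) {
  rotation <- as.matrix(rotation)
  if (!isTRUE(all.equal(crossprod(rotation), diag(3), tolerance = 1e-8)))
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("improper rotation (det = -1): chirality-inverting operations ",
         "on multipole populations are not supported")
  out <- plm
  for (li in seq_along(plm)) {
    l <- li - 1L
    p <- plm[[li]]
    if (length(p) != 2L * l + 1L)
      stop("population block for l = ", l, " must have length ", 2 * l + 1)
    if (l == 0L || all(p == 0)) next
    f <- .density_norm_factor(l, seq(-l, l))
    D <- .sph_rotation_Y(l, rotation)
    out[[li]] <- as.numeric((D %*% (f * p)) / f)
  }
  out
}

# Rotate a moment vector expressed in the orthonormal-Y convention
# (used internally when aligning multipole moments with the pair axis).
.rotate_Y_coeffs <- function(q, l, R) {
  if (l == 0L) return(q)
  as.numeric(.sph_rotation_Y(l, R) %*% q)
}

# Rotation taking unit vector a onto unit vector b (Rodrigues formula).
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  Vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + Vx + Vx %*% Vx / (1 + c0)
}
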