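# Independent numerical oracle for pairwise Coulomb energies between
# pseudoatoms, deliberately built from different machinery than the
# package: hard-coded density-normalized harmonic polynomials (l <= 2),
# cumulative-trapezoid Poisson integrals on a fine radial mesh with
# linear interpolation, and a fixed midpoint product grid for the
# electron-electron integral. Agreement with the package therefore
# cross-validates conventions, normalizations and closed forms.

# density-normalized real spherical harmonics, explicit Cartesian forms
oracle_ylm <- function(l, m, u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  r2 <- x^2 + y^2 + z^2
  if (l == 0) return(rep(1 / (4 * pi), nrow(u)))
  if (l == 1) {
    v <- switch(as.character(m), `-1` = y, `0` = z, `1` = x)
    return(v / sqrt(r2) / pi)
  }
  if (l == 2) {
    return(switch(as.character(m),
      `-2` = 0.75 * (2 * x * y) / r2 / 2,      # (3/8) * 2xy/r^2
      `-1` = 0.75 * y * z / r2,
      `0` = (3 * sqrt(3) / (8 * pi)) * (3 * z^2 / r2 - 1),
      `1` = 0.75 * x * z / r2,
      `2` = 0.375 * (x^2 - y^2) / r2))
  }
  stop("oracle only supports l <= 2")
}

# decompose a pseudoatom (hansen_atom + global-frame populations) into
# radial components: spherical rows (weight, n, zeta) with unit-charge
# normalization folded into `weight`, and deformation levels
oracle_components <- function(h, plm) {
  sph <- data.frame(weight = numeric(), n = integer(), zeta = numeric())
  add <- function(P, terms, scale) {
    for (k in seq_len(nrow(terms)))
      sph[nrow(sph) + 1L, ] <<- c(P * terms$c[k], terms$n[k],
                                  terms$zeta[k] * scale)
    invisible(NULL)
  }
  if (h$Pc > 0) add(h$Pc, h$core, 1)
  if (h$Pv > 0) add(h$Pv, h$valence, h$kappa)
  def <- lapply(h$def, function(d) {
    P <- if (!is.null(plm) && d$l + 1L <= length(plm)) plm[[d$l + 1L]] else d$P
    list(l = d$l, n = d$n, zeta = d$zeta * h$kappap, P = P)
  })
  list(sph = sph, def = def)
}

# radial mesh Poisson solutions by cumulative trapezoid
.oracle_mesh <- local({
  r <- seq(1e-6, 40, length.out = 24001)
  list(r = r, h = r[2] - r[1])
})
.cumtrapz <- function(y, h) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2)) * h
}

# potential generated by one pseudoatom's electron cloud, evaluated at
# points relative to its nucleus; returns a function(points)
oracle_potential_fn <- function(h, plm) {
  comp <- oracle_components(h, plm)
  r <- .oracle_mesh$r; hstep <- .oracle_mesh$h
  # spherical: phi(r) = 4*pi*( (1/r) int_0^r F s^2 ds + int_r^inf F s ds )
  Fs <- numeric(length(r))
  for (k in seq_len(nrow(comp$sph))) {
    n <- comp$sph$n[k]; z <- comp$sph$zeta[k]
    N <- z^(n + 3) / (4 * pi * gamma(n + 3))
    Fs <- Fs + comp$sph$weight[k] * N * r^n * exp(-z * r)
  }
  c1 <- .cumtrapz(Fs * r^2, hstep)
  c2tot <- .cumtrapz(Fs * r, hstep)
  phi_sph <- 4 * pi * (c1 / r + (c2tot[length(r)] - c2tot))
  defs <- lapply(comp$def, function(d) {
    N <- (d$zeta)^(d$n + 3) / gamma(d$n + 3)
    Fr <- N * r^d$n * exp(-d$zeta * r)
    i1 <- .cumtrapz(Fr * r^(d$l + 2), hstep)
    i2 <- .cumtrapz(Fr * r^(1 - d$l), hstep)
    g <- i1 / r^(d$l + 1) + (i2[length(r)] - i2) * r^d$l
    list(l = d$l, P = d$P, g = g)
  })
  function(points) {
    p <- matrix(points, ncol = 3)
    rr <- sqrt(rowSums(p^2))
    out <- stats::approx(r, phi_sph, xout = rr, rule = 2)$y
    for (d in defs) {
      if (all(d$P == 0)) next
      gv <- stats::approx(r, d$g, xout = rr, rule = 2)$y
      ang <- numeric(length(rr))
      for (j in seq_along(d$P)) {
        m <- j - d$l - 1L
        if (d$P[j] == 0) next
        ang <- ang + d$P[j] * oracle_ylm(d$l, m, p)
      }
      out <- out + (4 * pi / (2 * d$l + 1)) * gv * ang
    }
    out
  }
}

# electron density of one pseudoatom at points relative to its nucleus
oracle_density_fn <- function(h, plm) {
  comp <- oracle_components(h, plm)
  function(points) {
    p <- matrix(points, ncol = 3)
    rr <- sqrt(rowSums(p^2))
    out <- numeric(length(rr))
    for (k in seq_len(nrow(comp$sph))) {
      n <- comp$sph$n[k]; z <- comp$sph$zeta[k]
      N <- z^(n + 3) / (4 * pi * gamma(n + 3))
      out <- out + comp$sph$weight[k] * N * rr^n * exp(-z * rr)
    }
    for (d in comp$def) {
      if (all(d$P == 0)) next
      N <- (d$zeta)^(d$n + 3) / gamma(d$n + 3)
      Fr <- N * rr^d$n * exp(-d$zeta * rr)
      ang <- numeric(length(rr))
      for (j in seq_along(d$P)) {
        m <- j - d$l - 1L
        if (d$P[j] == 0) next
        ang <- ang + d$P[j] * oracle_ylm(d$l, m, p)
      }
      out <- out + Fr * ang
    }
    out
  }
}

# brute-force two-center interaction energy (hartree) on a fixed
# midpoint product grid centered on atom j. Formulated against the
# total (nucleus + electrons) potential of atom i, which is screened at
# long range, so no large-term cancellation spoils the grid accuracy:
#   E = Z_j phi_i(r_j) - int rho_ej(r) phi_i(r) d3r
oracle_pair_energy <- function(atom_i, atom_j,
                               nr = 360, nth = 110, nph = 96, rmax = 18) {
  rA <- atom_i$pos; rB <- atom_j$pos
  phieA <- oracle_potential_fn(atom_i$h, atom_i$plm)
  rhoB <- oracle_density_fn(atom_j$h, atom_j$plm)
  phitotA <- function(pts_global) {
    d <- sweep(matrix(pts_global, ncol = 3), 2, rA)
    atom_i$h$Z / sqrt(rowSums(d^2)) - phieA(d)
  }
  E <- atom_j$h$Z * phitotA(matrix(rB, 1))
  # quadratically graded radial midpoint grid (fine near the nucleus,
  # where the core density peaks)
  tg <- (seq_len(nr) - 0.5) / nr
  rg <- rmax * tg^2
  wrg <- 2 * rmax * tg / nr
  ctg <- -1 + (seq_len(nth) - 0.5) * 2 / nth
  phg <- (seq_len(nph) - 0.5) * 2 * pi / nph
  wct <- 2 / nth; wph <- 2 * pi / nph
  st <- sqrt(pmax(0, 1 - ctg^2))
  u <- cbind(rep(st, each = nph) * cos(rep(phg, nth)),
             rep(st, each = nph) * sin(rep(phg, nth)),
             rep(ctg, each = nph))
  # the nuclear 1/|r - rA| part of phitotA is an integrable singularity
  # that midpoint cells sample erratically; subtract an analytically
  # integrable Gaussian-screened model charge at the A nucleus
  # (int c*exp(-mu s^2)/s d3s = 2*pi*c/mu) and integrate the remainder
  mu <- 4
  c0 <- rhoB(matrix(rA - rB, 1))
  ZA <- atom_i$h$Z
  Een <- 2 * pi * c0 * ZA / mu
  for (k in seq_len(nr)) {
    pts <- u * rg[k]
    gl <- sweep(pts, 2, rB, "+")
    s2 <- rowSums(sweep(gl, 2, rA)^2)
    f <- rhoB(pts) * phitotA(gl) -
      ZA * c0 * exp(-mu * s2) / sqrt(s2)
    Een <- Een + sum(f) * rg[k]^2 * wrg[k] * wct * wph
  }
  as.numeric(E - Een)
}

# deterministic random toy pseudoatom (l <= 2) for property tests
random_toy_atom <- function() {
  Z <- sample(c(1L, 6L, 7L, 8L), 1)
  Pc <- if (Z > 2) 2 else 0
  Pv <- max(0.2, Z - Pc + stats::runif(1, -0.4, 0.4))
  zc <- stats::runif(1, 10, 16)
  zv <- stats::runif(1, 2.2, 5)
  kappa <- stats::runif(1, 0.9, 1.15)
  kappap <- stats::runif(1, 0.9, 1.25)
  def <- list(
    list(l = 1L, n = 2L, zeta = zv, P = round(stats::runif(3, -0.08, 0.08), 3)),
    list(l = 2L, n = 2L, zeta = zv, P = round(stats::runif(5, -0.05, 0.05), 3)))
  h <- hansen_atom(Z, Pc, Pv, kappa, kappap,
                   core = if (Pc > 0) data.frame(c = 1, n = 0L, zeta = zc)
                   else data.frame(c = numeric(), n = integer(),
                                   zeta = numeric()),
                   valence = data.frame(c = 1, n = 2L, zeta = zv),
                   def = def)
  list(h = h, plm = list(0, def[[1]]$P, def[[2]]$P))
}
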