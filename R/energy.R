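# Pairwise electrostatic energies.
#
# Hybrid evaluation: for atom pairs closer than a cutoff the full
# Coulomb integral between the two pseudoatom charge distributions is
# computed (closed-form electrostatic potential of one atom integrated
# against the electron density of the other on a convergence-controlled
# spherical quadrature grid); beyond the cutoff a Buckingham-type
# point-multipole expansion is used. The difference exact - multipole on
# the inner pairs is the charge-penetration contribution.

# ---- multipole interaction constants -------------------------------------
# Interaction of two point multipoles a distance R apart along +z:
#   E = sum q^A_{l1 m1} q^B_{l2 m2} K(l1 m1, l2 m2) / R^(l1+l2+1)
# with q in the orthonormal real spherical harmonic moment convention.
# K is obtained numerically, once, by expanding the irregular solid
# harmonic of one center in regular solid harmonics about the other
# (the projection on a unit sphere is exact because the potential is
# harmonic there); values are cached.
.multipole_K <- function(lmax = 4L) {
  key <- paste0("K", lmax)
  if (!is.null(.pa_cache[[key]])) return(.pa_cache[[key]])
  nt <- 64L; np <- 128L; R0 <- 10
  gl <- pracma::gaussLegendre(nt, -1, 1)
  phis <- 2 * pi * (seq_len(np) - 1) / np
  ct <- rep(gl$x, each = np)
  wt <- rep(gl$w, each = np) * (2 * pi / np)
  ph <- rep(phis, nt)
  st <- sqrt(pmax(0, 1 - ct^2))
  u <- cbind(st * cos(ph), st * sin(ph), ct)
  nbas <- (lmax + 1L)^2
  idx_l <- unlist(lapply(0:lmax, function(l) rep(l, 2 * l + 1)))
  Ybas <- matrix(0, nrow(u), nbas)
  k <- 0L
  for (l in 0:lmax) for (m in seq(-l, l)) {
    k <- k + 1L
    Ybas[, k] <- .real_sph_Y(l, m, u)
  }
  d <- cbind(u[, 1], u[, 2], u[, 3] - R0)
  dn <- sqrt(rowSums(d^2))
  K <- matrix(0, nbas, nbas)
  k2 <- 0L
  for (l2 in 0:lmax) for (m2 in seq(-l2, l2)) {
    k2 <- k2 + 1L
    f <- .real_sph_Y(l2, m2, d / dn) / dn^(l2 + 1)
    proj <- colSums(Ybas * (f * wt))
    K[, k2] <- proj * R0^(idx_l + l2 + 1) * (4 * pi / (2 * l2 + 1))
  }
  K[abs(K) < 1e-9] <- 0
  pw <- outer(idx_l, idx_l, "+") + 1
  .pa_cache[[key]] <- list(K = K, power = pw, lmax = lmax)
  .pa_cache[[key]]
}

# flatten per-l Racah moments to an orthonormal-Y coefficient vector in
# the frame whose z-axis is `axis` (unit 3-vector, global coords)
.moments_to_pair_frame <- function(mom, axis, lmax) {
  G <- .rotation_between(axis, c(0, 0, 1))
  out <- numeric((lmax + 1L)^2)
  k <- 0L
  for (l in 0:lmax) {
    q <- if (l <= mom$lmax) mom$q[[l + 1L]] else numeric(2 * l + 1)
    q <- q * sqrt((2 * l + 1) / (4 * pi))   # Racah -> orthonormal
    if (l > 0L && any(q != 0)) q <- .rotate_Y_coeffs(q, l, G)
    out[k + seq_len(2 * l + 1)] <- q
    k <- k + 2L * l + 1L
  }
  out
}

#' Buckingham multipole interaction energy of two pseudoatoms
#'
#' Point-multipole interaction energy between two sets of atomic
#' multipole moments, including every interaction-tensor term with
#' l_i <= lmax and l_j <= lmax (each term scaling as
#' R^-(l_i+l_j+1)). Exact for non-overlapping charge distributions in
#' the large-separation limit.
#'
#' @param moments_i,moments_j [atomic_moments()] objects (moments
#'   expressed in the global frame).
#' @param displacement 3-vector from atom i to atom j, bohr.
#' @return energy in hartree.
#' @export
multipole_pair_energy <- function(moments_i, moments_j, displacement) {
  R <- sqrt(sum(displacement^2))
  if (R == 0) stop("zero displacement between multipole sites")
  lmax <- max(moments_i$lmax, moments_j$lmax)
  tab <- .multipole_K(max(lmax, 4L))
  # both moment sets are expressed in one common frame with z along the
  # i -> j axis, the orientation the tensor K is tabulated for
  axis <- displacement / R
  qi <- .moments_to_pair_frame(moments_i, axis, tab$lmax)
  qj <- .moments_to_pair_frame(moments_j, axis, tab$lmax)
  sum(qi * ((tab$K / R^tab$power) %*% qj))
}

# closed-form electrostatic potential (positive sign) of one atom's
# electron density, with populations plm (global frame), at global points
.electron_potential <- function(h, plm, origin, points) {
  p <- matrix(points, ncol = 3)
  d <- sweep(p, 2, as.numeric(origin))
  r <- sqrt(rowSums(d^2))
  out <- numeric(nrow(p))
  if (h$Pc > 0) out <- out + h$Pc * .slater_sphere_potential(r, h$core)
  if (h$Pv > 0)
    out <- out + h$Pv * .slater_sphere_potential(r, .kappa_scaled_valence(h))
  ok <- r > 0
  for (dd in .kappa_scaled_def(h)) {
    P <- if (dd$l + 1L <= length(plm)) plm[[dd$l + 1L]] else dd$P
    if (all(P == 0)) next
    g <- .slater_defo_potential_radial(r, dd$l, dd$n, dd$zeta_eff)
    ang <- numeric(nrow(p))
    for (jm in seq_along(P)) {
      m <- jm - dd$l - 1L
      if (P[jm] == 0) next
      ang[ok] <- ang[ok] +
        P[jm] * density_normalized_ylm(dd$l, m, d[ok, , drop = FALSE])
    }
    out <- out + (4 * pi / (2 * dd$l + 1)) * g * ang
  }
  out
}

# deterministic orthonormal frame for the quadrature grid of a pair:
# z from atom B toward atom A, secondary axis taken from B's local frame
# so that the grid co-rotates rigidly with the structure
.pair_quad_frame <- function(rA, rB, frameB) {
  e3 <- rA - rB
  e3 <- e3 / sqrt(sum(e3^2))
  for (colref in c(3L, 1L, 2L)) {
    v <- frameB[, colref]
    e1 <- v - sum(v * e3) * e3
    nv <- sqrt(sum(e1^2))
    if (nv > 1e-6) { e1 <- e1 / nv; break }
  }
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Exact Coulomb interaction energy of two pseudoatoms
#'
#' Full electrostatic interaction between two total atomic charge
#' distributions (point nucleus plus Hansen-Coppens electron density):
#' nucleus-nucleus and nucleus-electron terms are closed-form; the
#' electron-electron term integrates the closed-form potential of one
#' cloud against the density of the other on a spherical product grid
#' whose radial and angular orders are doubled until the energy changes
#' by less than `tol`.
#'
#' @param atom_i,atom_j lists with fields `h` ([hansen_atom()]), `plm`
#'   (global-frame population list), `pos` (position, bohr) and `frame`
#'   (local frame matrix, used only to orient the quadrature grid
#'   deterministically; identity is fine).
#' @param tol convergence tolerance in hartree (default 1e-5).
#' @return energy in hartree, with attribute `"converged"`.
#' @export
exact_pair_energy <- function(atom_i, atom_j, tol = 1e-5) {
  rA <- as.numeric(atom_i$pos); rB <- as.numeric(atom_j$pos)
  R <- sqrt(sum((rA - rB)^2))
  if (R == 0) stop("coincident nuclei")
  hA <- atom_i$h; hB <- atom_j$h
  plmA <- atom_i$plm %||% list(); plmB <- atom_j$plm %||% list()
  frameB <- atom_j$frame %||% diag(3)
  E <- hA$Z * hB$Z / R
  E <- E - hA$Z * .electron_potential(hB, plmB, rB, rA)
  E <- E - hB$Z * .electron_potential(hA, plmA, rA, rB)

  haselecB <- hB$Pc > 0 || hB$Pv > 0 ||
    any(vapply(plmB, function(p) any(p != 0), logical(1)))
  haselecA <- hA$Pc > 0 || hA$Pv > 0 ||
    any(vapply(plmA, function(p) any(p != 0), logical(1)))
  if (!haselecA || !haselecB)
    return(structure(as.numeric(E), converged = TRUE))

  # center the electron-electron grid on the more compact density: the
  # integrand is then concentrated where the radial grid is densest and
  # the off-center potential factor stays smooth
  if (.min_zeta(hA) > .min_zeta(hB)) {
    tmp <- list(hA, plmA, rA)
    hA <- hB; plmA <- plmB; rA <- rB
    hB <- tmp[[1]]; plmB <- tmp[[2]]; rB <- tmp[[3]]
    frameB <- atom_i$frame %||% diag(3)
  }
  M <- .pair_quad_frame(rA, rB, frameB)
  zmin <- .min_zeta(hB)
  r0 <- 2.5 / zmin
  nr <- 24L; nt <- 10L
  Eee_prev <- NA_real_
  converged <- FALSE
  change <- NA_real_
  for (lev in 1:4) {
    Eee <- .ee_quadrature(hA, plmA, rA, hB, plmB, rB, M, r0, nr, nt)
    if (!is.na(Eee_prev)) change <- abs(Eee - Eee_prev)
    if (!is.na(change) && change <= tol) {
      converged <- TRUE
      break
    }
    Eee_prev <- Eee
    nr <- nr * 2L
    nt <- min(nt * 2L, 48L)
  }
  if (!converged)
    warning("electron-electron quadrature not converged to ", tol,
            " hartree (last change ", signif(change, 3), ")")
  structure(as.numeric(E + Eee), converged = converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.min_zeta <- function(h) {
  z <- c(h$core$zeta, h$valence$zeta * h$kappa,
         vapply(h$def, function(d) d$zeta * h$kappap, numeric(1)))
  if (!length(z)) 1 else min(z)
}

# electron-electron repulsion integral on a spherical product grid
# centered at B (radial: Gauss-Legendre mapped to (0, Inf); angular:
# Gauss-Legendre in cos(theta) x uniform phi)
.ee_quadrature <- function(hA, plmA, rA, hB, plmB, rB, M, r0, nr, nt) {
  np <- 2L * nt
  glr <- pracma::gaussLegendre(nr, 0, 1)
  t <- glr$x
  r <- r0 * t / (1 - t)
  wr <- glr$w * r0 / (1 - t)^2
  glt <- pracma::gaussLegendre(nt, -1, 1)
  phis <- 2 * pi * (seq_len(np) - 1) / np
  ct <- glt$x; wt <- glt$w * (2 * pi / np)
  st <- sqrt(pmax(0, 1 - ct^2))
  # angular points (unit sphere), then all radii
  ua <- cbind(rep(st, each = np) * cos(rep(phis, nt)),
              rep(st, each = np) * sin(rep(phis, nt)),
              rep(ct, each = np))
  wa <- rep(wt, each = np)
  na <- nrow(ua)
  pts <- matrix(0, na * nr, 3)
  w <- numeric(na * nr)
  for (k in seq_len(nr)) {
    rows <- (k - 1L) * na + seq_len(na)
    pts[rows, ] <- ua * r[k]
    w[rows] <- wa * wr[k] * r[k]^2
  }
  gpts <- pts %*% t(M)
  gpts <- sweep(gpts, 2, rB, "+")
  rho <- eval_density(hB, gpts, origin = rB, plm = plmB)
  phi <- .electron_potential(hA, plmA, rA, gpts)
  sum(w * rho * phi)
}

#' Point-charge electrostatic interaction energy
#'
#' Plain Coulomb sum over all inter-group atom pairs using atom-centered
#' point charges (the classical force-field model), with no cutoff.
#'
#' @param snapshot a `pa_snapshot`.
#' @param group_a,group_b disjoint integer atom-index vectors.
#' @param charges numeric per-atom charges (e), length = number of atoms.
#' @return energy in kJ/mol.
#' @export
point_charge_energy <- function(snapshot, group_a, group_b, charges) {
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  need <- union(group_a, group_b)
  bad <- need[is.na(charges[need])]
  if (length(charges) < max(need) || length(bad))
    stop("missing point charges for atom(s): ",
         paste(sort(bad), collapse = ", "))
  xa <- snapshot$xyz[group_a, , drop = FALSE] * BOHR_PER_ANGSTROM
  xb <- snapshot$xyz[group_b, , drop = FALSE] * BOHR_PER_ANGSTROM
  qa <- charges[group_a]; qb <- charges[group_b]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  if (any(d == 0)) stop("coincident atoms across groups")
  sum(outer(qa, qb) / d) * KJMOL_PER_HARTREE
}

#' Hybrid (exact/multipole) interaction energy between two atom groups
#'
#' For every inter-group atom pair, computes the Buckingham multipole
#' energy; pairs within `cutoff` angstrom additionally get the exact
#' Coulomb integral, the difference being the penetration contribution
#' E_pen. The pair energy entering the totals (`e_used`) is the exact
#' energy inside the cutoff and the multipole energy outside. Pair
#' orientation is canonicalized (lower atom index first) so results are
#' identical whichever group is passed first.
#'
#' @param param a `pa_param` (all atoms parametrized).
#' @param group_a,group_b disjoint integer atom-index vectors.
#' @param cutoff inner-region distance cutoff in angstrom (default 4.5).
#' @param tol exact-integral convergence tolerance, hartree.
#' @return object of class `pa_interaction`: list with `pairs`
#'   (data.frame: i, j, R in angstrom, e_exact, e_mult, e_pen, e_used in
#'   kJ/mol; e_exact is NA for outer pairs), `ees`, `epen` (totals,
#'   kJ/mol), `cutoff`.
#' @export
epmm_interaction <- function(param, group_a, group_b, cutoff = 4.5,
                             tol = 1e-5) {
  stopifnot(inherits(param, "pa_param"))
  group_a <- sort(unique(as.integer(group_a)))
  group_b <- sort(unique(as.integer(group_b)))
  if (!length(group_a) || !length(group_b)) stop("empty atom group")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b),
                                   collapse = ", "))
  xyz <- param$snapshot$xyz * BOHR_PER_ANGSTROM
  atoms_used <- union(group_a, group_b)
  mom <- vector("list", nrow(param$snapshot$atoms))
  for (i in atoms_used)
    mom[[i]] <- atomic_moments(param$hansen[[i]], plm = param$plm_global[[i]])
  pi_ <- rep(group_a, times = length(group_b))
  pj_ <- rep(group_b, each = length(group_a))
  res <- data.frame(i = pmin(pi_, pj_), j = pmax(pi_, pj_),
                    R = NA_real_, e_exact = NA_real_, e_mult = NA_real_,
                    e_pen = 0, e_used = NA_real_)
  res <- res[order(res$i, res$j), ]
  rownames(res) <- NULL
  for (k in seq_len(nrow(res))) {
    i <- res$i[k]; j <- res$j[k]
    disp <- xyz[j, ] - xyz[i, ]
    Rb <- sqrt(sum(disp^2))
    Rang <- Rb / BOHR_PER_ANGSTROM
    em <- multipole_pair_energy(mom[[i]], mom[[j]], disp)
    res$R[k] <- Rang
    res$e_mult[k] <- em * KJMOL_PER_HARTREE
    if (Rang <= cutoff) {
      ee <- exact_pair_energy(
        list(h = param$hansen[[i]], plm = param$plm_global[[i]],
             pos = xyz[i, ], frame = param$frames[[i]]$R),
        list(h = param$hansen[[j]], plm = param$plm_global[[j]],
             pos = xyz[j, ], frame = param$frames[[j]]$R),
        tol = tol)
      res$e_exact[k] <- as.numeric(ee) * KJMOL_PER_HARTREE
      res$e_pen[k] <- res$e_exact[k] - res$e_mult[k]
      res$e_used[k] <- res$e_exact[k]
    } else {
      res$e_used[k] <- res$e_mult[k]
    }
  }
  structure(list(pairs = res, ees = sum(res$e_used),
                 epen = sum(res$e_pen), cutoff = cutoff,
                 group_a = group_a, group_b = group_b),
            class = "pa_interaction")
}

#' Aggregate pair energies to residue or chain matrices
#'
#' Sums atom-pair energies into a groups-of-A by groups-of-B matrix at
#' residue or chain level. Marginal sums are exact: the sum over all
#' residue-pair entries equals the chain-chain totals equals the sum of
#' the atom-pair energies.
#'
#' @param interaction a `pa_interaction` from [epmm_interaction()].
#' @param snapshot the `pa_snapshot` the interaction was computed on.
#' @param level `"residue"` or `"chain"`.
#' @return object of class `pa_energy_matrix`: list with `level`,
#'   `row_labels`, `col_labels`, `ees`, `epen` (matrices, kJ/mol).
#'   Residue labels have the form `chain:resno:resname`.
#' @export
aggregate_energy <- function(interaction, snapshot,
                             level = c("residue", "chain")) {
  level <- match.arg(level)
  a <- snapshot$atoms
  lab <- if (level == "residue")
    paste(a$chain, a$resno, a$resid, sep = ":") else a$chain
  ga <- interaction$group_a; gb <- interaction$group_b
  rl <- unique(lab[ga]); cl <- unique(lab[gb])
  ees <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
  epen <- ees
  p <- interaction$pairs
  # pairs are stored with i < j; map back to (A, B) roles (groups are
  # disjoint, so membership is unambiguous)
  ia <- ifelse(p$i %in% ga, p$i, p$j)
  ib <- ifelse(p$i %in% ga, p$j, p$i)
  for (k in seq_len(nrow(p))) {
    r <- lab[ia[k]]; cc <- lab[ib[k]]
    if (!(r %in% rl) || !(cc %in% cl))
      stop("atom not mapped to an aggregation group")
    ees[r, cc] <- ees[r, cc] + p$e_used[k]
    epen[r, cc] <- epen[r, cc] + p$e_pen[k]
  }
  structure(list(level = level, row_labels = rl, col_labels = cl,
                 ees = ees, epen = epen),
            class = "pa_energy_matrix")
}

#' Write an energy matrix to CSV
#'
#' @param mat a `pa_energy_matrix`.
#' @param path output CSV path.
#' @param what `"ees"` or `"epen"`.
#' @return invisibly, `path`.
#' @export
write_energy_matrix_csv <- function(mat, path, what = c("ees", "epen")) {
  what <- match.arg(what)
  m <- mat[[what]]
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
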