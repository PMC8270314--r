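# Synthetic study systems: a toy parameter bank, small
# hydrogen-bonding complexes with known connectivity, snapshot
# ensembles with controlled positional jitter and scheduled
# hydrogen-bond presence, and analytic two-atom fixtures. Everything
# the pipeline consumes can be generated here deterministically, so all
# stages are testable without any external structure or databank.

# run expr with a fixed RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# idealized gas-phase geometries, angstrom
.GEOM_WATER <- rbind(O = c(0, 0, 0),
                     H1 = c(0.9572, 0, 0),
                     H2 = c(-0.2399872, 0.9266272, 0))
.GEOM_FORMAMIDE <- rbind(C = c(0, 0, 0),
                         O = c(1.224, 0, 0),
                         N = c(-0.7755, 1.1075, 0),
                         H = c(-0.5908, -0.9276, 0),
                         H1 = c(-0.3406, 2.0192, 0),
                         H2 = c(-1.7809, 1.0106, 0))
.GEOM_METHANOL <- rbind(C = c(0, 0, 0),
                        O = c(1.43, 0, 0),
                        HO = c(1.7346, 0.9104, 0),
                        H1 = c(-0.3633, 0, 1.0277),
                        H2 = c(-0.3633, -0.8900, -0.5139),
                        H3 = c(-0.3633, 0.8900, -0.5139))

.place <- function(geom, shift = c(0, 0, 0), rot = diag(3)) {
  sweep(geom %*% t(rot), 2, shift, "+")
}

.residue_block <- function(geom, elems, names, chain, resno, resid) {
  data.frame(name = names, elem = elems, resno = resno, resid = resid,
             chain = chain, stringsAsFactors = FALSE)
}

#' Generate the built-in toy pseudoatom bank
#'
#' A small transferable parameter bank covering every atom type of the
#' built-in toy molecules (water, a formamide-like peptide unit,
#' methanol, and two closed-shell monatomic ions). Populations are
#' chemically plausible single-Slater toys: each neutral molecule sums
#' exactly to zero net charge before any normalization, Li carries +1
#' and Cl -1. With `neutral_atoms = TRUE` every entry instead gets
#' Pv = Z - Pc (atomic charges all zero) while keeping its multipoles.
#'
#' @param neutral_atoms logical; use formally neutral per-atom
#'   populations.
#' @return a `pa_bank`.
#' @export
make_toy_databank <- function(neutral_atoms = FALSE) {
  sl <- function(c, n, zeta) data.frame(c = c, n = n, zeta = zeta)
  d1 <- function(n, zeta, P) list(l = 1L, n = n, zeta = zeta, P = P)
  d2 <- function(n, zeta, P) list(l = 2L, n = n, zeta = zeta, P = P)
  entries <- list(
    `O|H2` = list(Pc = 2, Pv = 6.2, kappa = 0.98, kappap = 1.05,
                  core = sl(1, 0L, 15.0), valence = sl(1, 2L, 4.4),
                  def = list(d1(2L, 4.4, c(0, 0.08, 0.05)),
                             d2(2L, 4.4, c(0, 0, -0.03, 0, 0)))),
    `H|O` = list(Pc = 0, Pv = 0.9, kappa = 1.15, kappap = 1.2,
                 core = sl(numeric(), integer(), numeric()),
                 valence = sl(1, 0L, 2.0),
                 def = list(d1(1L, 2.0, c(0, 0.12, 0)))),
    `C|HNO|p` = list(Pc = 2, Pv = 3.75, kappa = 1.01, kappap = 0.95,
                     core = sl(1, 0L, 11.0), valence = sl(1, 2L, 3.2),
                     def = list(d1(2L, 3.2, c(0, 0.05, -0.03)),
                                d2(2L, 3.2, c(0, 0, 0.1, 0, 0.02)))),
    `O|C` = list(Pc = 2, Pv = 6.35, kappa = 0.98, kappap = 1.0,
                 core = sl(1, 0L, 15.0), valence = sl(1, 2L, 4.4),
                 def = list(d1(2L, 4.4, c(0, 0.10, 0)),
                            d2(2L, 4.4, c(0, 0, -0.04, 0, 0)))),
    `N|CH2|p` = list(Pc = 2, Pv = 5.40, kappa = 0.99, kappap = 1.0,
                     core = sl(1, 0L, 13.0), valence = sl(1, 2L, 3.8),
                     def = list(d1(2L, 3.8, c(0, 0.06, 0.02)),
                                d2(2L, 3.8, c(0, 0, -0.05, 0, 0)))),
    `H|N` = list(Pc = 0, Pv = 0.775, kappa = 1.12, kappap = 1.2,
                 core = sl(numeric(), integer(), numeric()),
                 valence = sl(1, 0L, 2.0),
                 def = list(d1(1L, 2.0, c(0, 0.10, 0)))),
    `H|C` = list(Pc = 0, Pv = 0.95, kappa = 1.10, kappap = 1.2,
                 core = sl(numeric(), integer(), numeric()),
                 valence = sl(1, 0L, 2.1),
                 def = list(d1(1L, 2.1, c(0, 0.08, 0)))),
    `C|H3O` = list(Pc = 2, Pv = 3.85, kappa = 1.01, kappap = 0.95,
                   core = sl(1, 0L, 11.0), valence = sl(1, 2L, 3.2),
                   def = list(d1(2L, 3.2, c(0, 0.04, 0)))),
    `O|CH` = list(Pc = 2, Pv = 6.40, kappa = 0.98, kappap = 1.0,
                  core = sl(1, 0L, 15.0), valence = sl(1, 2L, 4.4),
                  def = list(d1(2L, 4.4, c(0, 0.07, 0.04)))),
    `LI|` = list(Pc = 2, Pv = 0, kappa = 1, kappap = 1,
                 core = sl(1, 0L, 5.0),
                 valence = sl(numeric(), integer(), numeric()),
                 def = list()),
    `CL|` = list(Pc = 10, Pv = 8, kappa = 1, kappap = 1,
                 core = sl(1, 0L, 12.0), valence = sl(1, 2L, 2.0),
                 def = list())
  )
  if (neutral_atoms) {
    for (key in names(entries)) {
      Z <- element_to_Z(sub("\\|.*$", "", key))
      entries[[key]]$Pv <- Z - entries[[key]]$Pc
      if (!nrow(entries[[key]]$valence))
        entries[[key]]$valence <- sl(1, 0L, 2.0)
    }
  }
  structure(list(name = "toybank",
                 version = if (neutral_atoms) "1.0n" else "1.0",
                 entries = entries),
            class = "pa_bank")
}

#' Build a toy complex
#'
#' Named synthetic complexes with chemically sensible geometry,
#' residue/chain labels exercising a two-chain "protein" plus ligand
#' layout, and connectivity:
#' \describe{
#'   \item{water_dimer}{two waters, chains A/B, linear hydrogen bond,
#'     O...O distance `d_oo` (default 2.9 angstrom).}
#'   \item{peptide_ligand_toy}{two chains (A, B) of two formamide
#'     "residues" each plus a methanol ligand (chain L, residue LIG)
#'     nestled between them.}
#'   \item{charged_contact_toy}{a Li+ / Cl- contact pair at
#'     `separation` (default 3.0 angstrom) across chains A/B, with one
#'     far-away neutral formamide spectator in each chain.}
#' }
#'
#' @param kind complex name.
#' @param d_oo water-dimer O...O distance, angstrom.
#' @param separation charged-contact distance, angstrom.
#' @return list with `snapshot` (a `pa_snapshot`), `bonds`
#'   (a `pa_bonds`) and `ensemble` (single-model `pa_ensemble`).
#' @export
make_complex <- function(kind = c("water_dimer", "peptide_ligand_toy",
                                  "charged_contact_toy"),
                         d_oo = 2.9, separation = 3.0) {
  kind <- match.arg(kind)
  if (kind == "water_dimer") {
    don <- .place(.GEOM_WATER)
    acc <- .acceptor_water_coords(don, d_da = d_oo, angle_dha = 170)
    atoms <- data.frame(
      name = c("O", "H1", "H2", "O", "H1", "H2"),
      elem = c("O", "H", "H", "O", "H", "H"),
      resno = c(1L, 1L, 1L, 1L, 1L, 1L),
      resid = "HOH",
      chain = c("A", "A", "A", "B", "B", "B"),
      stringsAsFactors = FALSE)
    xyz <- rbind(don, acc)
  } else if (kind == "peptide_ligand_toy") {
    ra <- function(th) {
      c <- cos(th); s <- sin(th)
      matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
    }
    blocks <- list(
      list(g = .place(.GEOM_FORMAMIDE, c(0, 0, 0)),
           chain = "A", resno = 1L, resid = "FOR"),
      list(g = .place(.GEOM_FORMAMIDE, c(6.5, 0, 0), ra(pi / 3)),
           chain = "A", resno = 2L, resid = "FOR"),
      list(g = .place(.GEOM_FORMAMIDE, c(0, 6.2, 0), ra(pi)),
           chain = "B", resno = 25L, resid = "FOR"),
      list(g = .place(.GEOM_FORMAMIDE, c(6.5, 6.2, 0), ra(-pi / 3)),
           chain = "B", resno = 26L, resid = "FOR"),
      list(g = .place(.GEOM_METHANOL, c(2.9, 3.1, 3.4)),
           chain = "L", resno = 1L, resid = "LIG"))
    elems <- list(c("C", "O", "N", "H", "H", "H"),
                  c("C", "O", "N", "H", "H", "H"),
                  c("C", "O", "N", "H", "H", "H"),
                  c("C", "O", "N", "H", "H", "H"),
                  c("C", "O", "H", "H", "H", "H"))
    names_ <- list(c("C", "O", "N", "HC", "HN1", "HN2"),
                   c("C", "O", "N", "HC", "HN1", "HN2"),
                   c("C", "O", "N", "HC", "HN1", "HN2"),
                   c("C", "O", "N", "HC", "HN1", "HN2"),
                   c("C", "O", "HO", "H1", "H2", "H3"))
    atoms <- do.call(rbind, lapply(seq_along(blocks), function(b)
      data.frame(name = names_[[b]], elem = elems[[b]],
                 resno = blocks[[b]]$resno, resid = blocks[[b]]$resid,
                 chain = blocks[[b]]$chain, stringsAsFactors = FALSE)))
    xyz <- do.call(rbind, lapply(blocks, function(b) b$g))
  } else {
    atoms <- data.frame(
      name = c("LI", "C", "O", "N", "HC", "HN1", "HN2",
               "CL", "C", "O", "N", "HC", "HN1", "HN2"),
      elem = c("LI", "C", "O", "N", "H", "H", "H",
               "CL", "C", "O", "N", "H", "H", "H"),
      resno = c(1L, rep(2L, 6), 1L, rep(2L, 6)),
      resid = c("CAT", rep("FOR", 6), "ANI", rep("FOR", 6)),
      chain = c(rep("A", 7), rep("B", 7)),
      stringsAsFactors = FALSE)
    xyz <- rbind(c(0, 0, 0),
                 .place(.GEOM_FORMAMIDE, c(-20, 0, 0)),
                 c(separation, 0, 0),
                 .place(.GEOM_FORMAMIDE, c(22, 16, 0)))
  }
  rownames(xyz) <- NULL
  atoms$serial <- seq_len(nrow(atoms))
  atoms$Z <- element_to_Z(atoms$elem)
  atoms$occ <- 1
  atoms <- atoms[, c("serial", "name", "elem", "Z", "resno", "resid",
                     "chain", "occ")]
  snap <- structure(list(atoms = atoms, xyz = unname(as.matrix(xyz)),
                         model = 1L), class = "pa_snapshot")
  bonds <- infer_connectivity(snap)
  ens <- make_ensemble_object(atoms, list(snap$xyz),
                              source = paste0("synthetic:", kind))
  list(snapshot = snap, bonds = bonds, ensemble = ens)
}

# coordinates of an acceptor water hydrogen-bonded to the donor water
# `don` (rows O, H1, H2): donor-acceptor distance d_da along the O-H1
# bond with a D-H...A angle of angle_dha degrees; the acceptor's
# hydrogens point away from the donor
.acceptor_water_coords <- function(don, d_da, angle_dha = 170) {
  O1 <- don[1, ]; H1 <- don[2, ]
  u <- H1 - O1; dh <- sqrt(sum(u^2)); u <- u / dh
  # in-plane perpendicular for tilting the acceptor off the bond axis
  p <- don[3, ] - O1
  p <- p - sum(p * u) * u
  p <- p / sqrt(sum(p^2))
  tilt <- (180 - angle_dha) * pi / 180
  w <- cos(tilt) * u + sin(tilt) * p     # H -> acceptor direction
  # law of cosines in the D-H-A triangle (angle at H = angle_dha)
  cth <- cos(angle_dha * pi / 180)
  t <- (2 * dh * cth + sqrt(4 * dh^2 * cth^2 - 4 * (dh^2 - d_da^2))) / 2
  A <- H1 + t * w
  bis <- .GEOM_WATER[2, ] + .GEOM_WATER[3, ]
  rot <- .rotation_between(bis / sqrt(sum(bis^2)), w)
  .place(.GEOM_WATER, A, rot)
}

#' Generate a synthetic snapshot ensemble
#'
#' Emulates the statistical structure of a snapshot ensemble extracted
#' from a molecular-dynamics trajectory: one shared topology, per-frame
#' iid Gaussian positional jitter, and optionally a hydrogen bond whose
#' presence follows a planted per-frame schedule. Scheduled frames place
#' the acceptor water in ideal bonded geometry (donor-acceptor 2.9
#' angstrom, D-H...A 170 degrees); unscheduled frames move it to a
#' donor-acceptor distance drawn uniformly from 4.5-5.5 angstrom (beyond
#' the default detection cutoff). Deterministic given `seed`.
#'
#' @param kind `"water_dimer"` (one scheduled acceptor) or
#'   `"alternating_acceptor"` (two acceptor waters with complementary
#'   schedules, emulating bonds that alternate with each other) or any
#'   [make_complex()] kind (plain jitter, no schedule).
#' @param n_snapshots number of frames.
#' @param sigma jitter standard deviation per coordinate, angstrom.
#' @param seed RNG seed (mandatory; generators never touch the global
#'   RNG state).
#' @param present logical mask of length `n_snapshots` (or a fraction,
#'   converted to the first `round(f*n)` frames present) for the
#'   scheduled hydrogen bond.
#' @param path optional output path; when given, the ensemble is also
#'   written as a multi-model PDB file.
#' @return a `pa_ensemble` (invisibly also written to `path` if given).
#' @export
make_ensemble <- function(kind = "water_dimer", n_snapshots = 100L,
                          sigma = 0.05, seed, present = 0.5,
                          path = NULL) {
  if (missing(seed)) stop("seed is mandatory for ensemble generation")
  if (is.numeric(present) && length(present) == 1L && !is.logical(present)) {
    stopifnot(present >= 0, present <= 1)
    present <- seq_len(n_snapshots) <= round(present * n_snapshots)
  }
  if (length(present) != n_snapshots)
    stop("schedule mask length must equal n_snapshots")

  if (kind == "alternating_acceptor") {
    base <- make_complex("water_dimer")
    atoms <- base$snapshot$atoms
    # add a second acceptor water, chain C, placed opposite the first
    extra <- data.frame(name = c("O", "H1", "H2"), elem = c("O", "H", "H"),
                        resno = 1L, resid = "HOH", chain = "C",
                        stringsAsFactors = FALSE)
    extra$serial <- nrow(atoms) + 1:3
    extra$Z <- element_to_Z(extra$elem)
    extra$occ <- 1
    atoms <- rbind(atoms, extra[, names(atoms)])
    donor_rows <- 1:3
    acc_rows <- list(4:6, 7:9)
  } else if (kind == "water_dimer") {
    base <- make_complex("water_dimer")
    atoms <- base$snapshot$atoms
    donor_rows <- 1:3
    acc_rows <- list(4:6)
  } else {
    base <- make_complex(kind)
    atoms <- base$snapshot$atoms
    donor_rows <- integer()
    acc_rows <- list()
  }
  don0 <- base$snapshot$xyz[1:3, , drop = FALSE]

  xyz <- .with_seed(seed, {
    lapply(seq_len(n_snapshots), function(k) {
      m <- matrix(0, nrow(atoms), 3)
      if (length(donor_rows)) {
        don <- don0 + matrix(stats::rnorm(9, 0, sigma), 3, 3)
        m[donor_rows, ] <- don
        for (ai in seq_along(acc_rows)) {
          on_duty <- if (kind == "alternating_acceptor")
            (ai == 1L) == present[k] else present[k]
          d_da <- if (on_duty) 2.9 else stats::runif(1, 4.5, 5.5)
          m[acc_rows[[ai]], ] <-
            .acceptor_water_coords(don, d_da = d_da, angle_dha = 170)
        }
      } else {
        m <- base$snapshot$xyz +
          matrix(stats::rnorm(3 * nrow(atoms), 0, sigma), nrow(atoms), 3)
      }
      m
    })
  })
  # two alternating acceptors must not collide when both are off-duty:
  # the off-duty one is shifted to the side
  if (kind == "alternating_acceptor") {
    for (k in seq_len(n_snapshots)) {
      off <- if (present[k]) 2L else 1L
      xyz[[k]][acc_rows[[off]], 3] <- xyz[[k]][acc_rows[[off]], 3] + 2.5
    }
  }
  ens <- make_ensemble_object(atoms, xyz,
                              source = paste0("synthetic:", kind,
                                              ":seed", seed))
  if (!is.null(path)) write_pdb_models(ens, path)
  invisible(ens)
}

#' Analytic two-atom Slater fixture
#'
#' Two spherical single-exponential pseudoatoms with a closed-form
#' pairwise Coulomb energy, for validating the exact integrator. Each
#' atom has a nucleus of charge `Z` and an electron cloud of `q`
#' electrons with density \eqn{(\alpha^3/8\pi) e^{-\alpha r}} (zero
#' electrons allowed: bare nuclei). The reference total interaction is
#' \deqn{E = Z^2/R - 2 Z q \phi(R) + q^2 J(R)}
#' with \eqn{\phi(R) = 1/R - e^{-\alpha R}(1/R + \alpha/2)} the cloud
#' potential and J the 1s-1s integral of [slater_1s_coulomb()].
#'
#' @param alpha cloud exponent, inverse bohr.
#' @param q electrons per cloud (0 for bare nuclei).
#' @param R separation, bohr.
#' @param Z nuclear charge (default 1).
#' @return list with `atom_i`, `atom_j` (inputs for
#'   [exact_pair_energy()]), `R`, and `reference` (list naming the
#'   closed form and its value in hartree).
#' @export
make_slater_fixture <- function(alpha, q, R, Z = 1L) {
  stopifnot(alpha > 0, R > 0, q >= 0)
  h <- if (q > 0)
    hansen_atom(Z, Pc = 0, Pv = q,
                valence = data.frame(c = 1, n = 0L, zeta = alpha))
  else hansen_atom(Z, Pc = 0, Pv = 0)
  phiR <- 1 / R - exp(-alpha * R) * (1 / R + alpha / 2)
  eref <- Z^2 / R - 2 * Z * q * phiR + q^2 * slater_1s_coulomb(alpha, R)
  list(atom_i = list(h = h, plm = list(), pos = c(0, 0, 0),
                     frame = diag(3)),
       atom_j = list(h = h, plm = list(), pos = c(0, 0, R),
                     frame = diag(3)),
       R = R,
       reference = list(
         formula = "Z^2/R - 2*Z*q*phi(R) + q^2*J_1s1s(alpha,R)",
         energy_hartree = eref))
}
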