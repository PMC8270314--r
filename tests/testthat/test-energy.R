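# Pairwise energies: exact integrals, multipole expansion, hybrid
# bookkeeping, point-charge model, aggregation.

KJ <- 2625.4996

test_that("exact pair energy reproduces elementary closed forms", {
  # bare nuclei: Coulomb's law
  fx <- make_slater_fixture(alpha = 2, q = 0, R = 1)
  expect_equal(as.numeric(exact_pair_energy(fx$atom_i, fx$atom_j)), 1)
  fx2 <- make_slater_fixture(alpha = 2, q = 0, R = 2)
  expect_equal(as.numeric(exact_pair_energy(fx2$atom_i, fx2$atom_j)), 0.5)
  # neutral spherical atoms at large separation: vanishing interaction
  fx3 <- make_slater_fixture(alpha = 2, q = 1, R = 16)
  expect_lt(abs(as.numeric(exact_pair_energy(fx3$atom_i, fx3$atom_j))),
            1e-6)
  # neutral H-like pair against the independent 1s-1s closed form
  for (par in list(c(2, 5), c(1.5, 3.5), c(3, 2.5))) {
    fx4 <- make_slater_fixture(alpha = par[1], q = 1, R = par[2])
    expect_equal(as.numeric(exact_pair_energy(fx4$atom_i, fx4$atom_j,
                                              tol = 1e-6)),
                 fx4$reference$energy_hartree, tolerance = 1e-5)
  }
  expect_error(exact_pair_energy(fx$atom_i, fx$atom_i), "coincident")
})

test_that("multipole energy matches closed-form point multipoles", {
  mq <- function(l0, vals) {
    q <- lapply(0:4, function(l) numeric(2 * l + 1))
    q[[l0 + 1]] <- vals
    structure(list(lmax = 4L, q = q, charge = q[[1]][1]),
              class = "atomic_moments")
  }
  # unit charges, 1 bohr
  expect_equal(multipole_pair_energy(mq(0, 1), mq(0, -1), c(0, 0, 1)), -1)
  # collinear dipoles head-to-tail: -2 mu1 mu2 / R^3
  expect_equal(multipole_pair_energy(mq(1, c(0, 1, 0)), mq(1, c(0, 1, 0)),
                                     c(0, 0, 10)), -2e-3)
  # parallel dipoles perpendicular to the axis: + mu1 mu2 / R^3
  expect_equal(multipole_pair_energy(mq(1, c(0, 0, 1)), mq(1, c(0, 0, 1)),
                                     c(0, 0, 10)), 1e-3)
  expect_error(multipole_pair_energy(mq(0, 1), mq(0, 1), c(0, 0, 0)),
               "zero displacement")
})

test_that("multipole energy agrees with the exact integral at long range", {
  set.seed(21)
  for (rep in 1:4) {
    ai <- random_toy_atom()
    aj <- random_toy_atom()
    ai$pos <- c(0, 0, 0)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    R <- runif(1, 25, 35)
    aj$pos <- R * u
    ai$frame <- aj$frame <- diag(3)
    mi <- atomic_moments(ai$h, plm = ai$plm)
    mj <- atomic_moments(aj$h, plm = aj$plm)
    em <- multipole_pair_energy(mi, mj, aj$pos - ai$pos)
    ee <- as.numeric(exact_pair_energy(ai, aj, tol = 1e-7))
    # relative agreement, floored by the exact integral's tolerance
    expect_lt(abs(em - ee), max(1e-3 * abs(ee), 5e-7))
  }
})

test_that("monopole-only multipole energy equals the point-charge model", {
  cx <- make_complex("charged_contact_toy")
  bank <- make_toy_databank()
  param <- suppressWarnings(transfer_parameters(cx$snapshot, cx$bonds, bank))
  i <- 1L; j <- 8L  # the Li+ / Cl- pair carries no multipoles
  mi <- atomic_moments(param$hansen[[i]], plm = param$plm_global[[i]])
  mj <- atomic_moments(param$hansen[[j]], plm = param$plm_global[[j]])
  disp <- (cx$snapshot$xyz[j, ] - cx$snapshot$xyz[i, ]) * 1.8897259886
  em <- multipole_pair_energy(mi, mj, disp) * KJ
  q <- net_atomic_charges(param)
  epc <- point_charge_energy(cx$snapshot, i, j, q)
  expect_equal(em, epc, tolerance = 1e-12)
  # +1/-1 at 1 bohr: one hartree of attraction in kJ/mol
  snap1 <- cx$snapshot
  snap1$xyz <- rbind(c(0, 0, 0), c(1 / 1.8897259886, 0, 0))
  snap1$atoms <- cx$snapshot$atoms[1:2, ]
  expect_equal(point_charge_energy(snap1, 1, 2, c(1, -1)), -2625.4996)
  # zero charges give exactly zero
  expect_equal(point_charge_energy(snap1, 1, 2, c(0, 0)), 0)
})

test_that("point-charge energy equals a hand-summed double loop", {
  xyz <- rbind(c(0, 0, 0), c(1.1, 0.3, -0.2), c(3.0, 1.0, 0.5),
               c(2.5, -1.5, 1.0))
  qs <- c(0.4, -0.4, 0.25, -0.25)
  snap <- structure(list(atoms = data.frame(
    serial = 1:4, name = "X", elem = "O", Z = 8L, resno = 1:4,
    resid = "XXX", chain = c("A", "A", "B", "B"), occ = 1),
    xyz = xyz, model = 1L), class = "pa_snapshot")
  ref <- 0
  for (i in 1:2) for (j in 3:4)
    ref <- ref + qs[i] * qs[j] /
      (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) * 1.8897259886)
  expect_equal(point_charge_energy(snap, 1:2, 3:4, qs), ref * KJ)
  expect_error(point_charge_energy(snap, 1:2, 3:4, c(1, NA, 1, 1)),
               "missing point charges.*2")
})

test_that("hybrid interaction splits inner/outer pairs at the cutoff", {
  cx <- make_complex("water_dimer")
  bank <- make_toy_databank()
  param <- transfer_parameters(cx$snapshot, cx$bonds, bank)
  inter <- epmm_interaction(param, 1:3, 4:6)
  # all pairs of the contact dimer are inside 4.5 A
  expect_true(all(inter$pairs$R <= 4.5))
  expect_true(all(is.finite(inter$pairs$e_exact)))
  # hydrogen-bonded dimer: attractive, with nonzero penetration on the
  # contact pairs
  expect_lt(inter$ees, 0)
  expect_true(any(inter$pairs$e_pen != 0))
  expect_equal(inter$ees, sum(inter$pairs$e_used))
  # cutoff 0 degenerates to the pure multipole sum
  i0 <- epmm_interaction(param, 1:3, 4:6, cutoff = 0)
  expect_equal(i0$ees, sum(i0$pairs$e_mult))
  expect_true(all(i0$pairs$e_pen == 0))
  expect_equal(i0$epen, 0)
  # groups beyond the cutoff have identically zero penetration
  far <- cx$snapshot
  far$xyz[4:6, ] <- far$xyz[4:6, ] + 10
  pfar <- transfer_parameters(far, infer_connectivity(far), bank)
  ifar <- epmm_interaction(pfar, 1:3, 4:6)
  expect_true(all(ifar$pairs$e_pen == 0))
  expect_identical(ifar$epen, 0)
  # group hygiene
  expect_error(epmm_interaction(param, 1:3, 3:6), "overlap")
})

test_that("interaction is symmetric in the group arguments bit-for-bit", {
  cx <- make_complex("water_dimer")
  bank <- make_toy_databank()
  param <- transfer_parameters(cx$snapshot, cx$bonds, bank)
  iab <- epmm_interaction(param, 1:3, 4:6)
  iba <- epmm_interaction(param, 4:6, 1:3)
  expect_identical(iab$pairs$e_used, iba$pairs$e_used)
  expect_identical(iab$ees, iba$ees)
  expect_identical(iab$epen, iba$epen)
  mab <- aggregate_energy(iab, cx$snapshot, "chain")
  mba <- aggregate_energy(iba, cx$snapshot, "chain")
  expect_identical(mab$ees, t(mba$ees))
})

test_that("aggregation conserves sums across levels and atom order", {
  cx <- make_complex("peptide_ligand_toy")
  bank <- make_toy_databank()
  param <- transfer_parameters(cx$snapshot, cx$bonds, bank)
  ga <- select_atoms(cx$snapshot, "A")
  gl <- select_atoms(cx$snapshot, "LIG")
  inter <- epmm_interaction(param, ga, gl)
  mres <- aggregate_energy(inter, cx$snapshot, "residue")
  mch <- aggregate_energy(inter, cx$snapshot, "chain")
  expect_equal(dim(mres$ees), c(2L, 1L))
  expect_equal(dim(mch$ees), c(1L, 1L))
  # single-residue groups give a 1x1 matrix equal to the pair total
  i11 <- epmm_interaction(param, select_atoms(cx$snapshot, "A:1"), gl)
  m11 <- aggregate_energy(i11, cx$snapshot, "residue")
  expect_equal(as.numeric(m11$ees), i11$ees)
  # conservation to 1e-9 relative
  expect_equal(sum(mres$ees), mch$ees[1, 1], tolerance = 1e-9)
  expect_equal(sum(mres$epen), mch$epen[1, 1], tolerance = 1e-9)
  expect_equal(sum(mres$ees), inter$ees, tolerance = 1e-9)
  # permuting atom order within the groups leaves the matrix unchanged
  i2 <- epmm_interaction(param, sample(ga), sample(gl))
  m2 <- aggregate_energy(i2, cx$snapshot, "residue")
  expect_equal(m2$ees, mres$ees)
})

test_that("pair energies are invariant under rigid motion", {
  bank <- make_toy_databank()
  cx <- make_complex("water_dimer")
  param <- transfer_parameters(cx$snapshot, cx$bonds, bank)
  i1 <- epmm_interaction(param, 1:3, 4:6)
  set.seed(17)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  s2 <- cx$snapshot
  s2$xyz <- sweep(cx$snapshot$xyz %*% t(A), 2, c(3.2, -1.1, 8.4), "+")
  p2 <- transfer_parameters(s2, infer_connectivity(s2), bank)
  i2 <- epmm_interaction(p2, 1:3, 4:6)
  expect_lt(max(abs(i1$pairs$e_used - i2$pairs$e_used)), 1e-6)
  expect_lt(max(abs(i1$pairs$e_pen - i2$pairs$e_pen)), 1e-6)
})
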