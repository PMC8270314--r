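# Hansen-Coppens pseudoatom model: harmonics, densities, frames,
# rotations, moments.

# fixed spherical product quadrature used by several tests
sph_quad <- function(nt = 200, np = 200) {
  gl <- pracma::gaussLegendre(nt, -1, 1)
  ph <- 2 * pi * (seq_len(np) - 1) / np
  ct <- rep(gl$x, each = np)
  w <- rep(gl$w, each = np) * (2 * pi / np)
  st <- sqrt(pmax(0, 1 - ct^2))
  list(u = cbind(st * cos(rep(ph, nt)), st * sin(rep(ph, nt)), ct), w = w)
}

toy_oxygen <- function() {
  hansen_atom(8, Pc = 2, Pv = 6.2, kappa = 0.97, kappap = 1.1,
              core = data.frame(c = 1, n = 0L, zeta = 15),
              valence = data.frame(c = 1, n = 2L, zeta = 4.4),
              def = list(list(l = 1L, n = 2L, zeta = 4.4,
                              P = c(0.02, -0.05, 0.03)),
                         list(l = 2L, n = 2L, zeta = 4.4,
                              P = c(0, 0.01, 0, -0.02, 0.015))))
}

test_that("density-normalized harmonics have the defining normalization", {
  q <- sph_quad(400, 400)
  expect_equal(density_normalized_ylm(0, 0, c(0.3, -2, 1)), 1 / (4 * pi))
  for (lm in list(c(1, 0), c(1, 1), c(2, 0), c(2, -2), c(3, 2), c(4, -4))) {
    y <- density_normalized_ylm(lm[1], lm[2], q$u)
    # |y| has kinks at nodal lines, so the quadrature converges slowly;
    # 1e-3 still cleanly separates the competing normalizations, which
    # differ by several percent or more
    expect_equal(sum(abs(y) * q$w), 2, tolerance = 1e-3)
  }
  # parity of the dipole harmonic
  expect_equal(density_normalized_ylm(1, 0, c(0, 0, 1)),
               -density_normalized_ylm(1, 0, c(0, 0, -1)))
  expect_error(density_normalized_ylm(1, 2, c(0, 0, 1)), "<=")
})

test_that("multipole populations rotate per l-block, preserving norms", {
  plm <- list(0.05, c(0.1, -0.2, 0.3), c(0.02, 0, -0.04, 0.01, 0.03))
  expect_equal(rotate_multipoles(plm, diag(3)), plm)
  set.seed(11)
  for (rep in 1:5) {
    A <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(A) < 0) A[, 1] <- -A[, 1]
    out <- rotate_multipoles(plm, A)
    expect_equal(out[[1]], plm[[1]])  # l = 0 invariant
    for (l in 1:2) {
      f <- pseudoatomES:::.density_norm_factor(l, seq(-l, l))
      expect_equal(sum((f * out[[l + 1]])^2), sum((f * plm[[l + 1]])^2),
                   tolerance = 1e-12)
    }
  }
  # rotating the populations is the same as rotating the density
  q <- sph_quad(40, 40)
  A <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(A) < 0) A[, 1] <- -A[, 1]
  out <- rotate_multipoles(plm, A)
  for (k in sample(nrow(q$u), 25)) {
    u <- q$u[k, ]
    dens0 <- function(p, u) sum(sapply(1:2, function(l)
      sum(p[[l + 1]] * sapply(seq(-l, l), function(m)
        density_normalized_ylm(l, m, matrix(u, 1))))))
    expect_equal(dens0(out, u), dens0(plm, as.numeric(t(A) %*% u)),
                 tolerance = 1e-10)
  }
  # 90 degree rotation about z turns an "x" dipole into a "y" dipole
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(rotate_multipoles(list(0, c(0, 0, 1)), Rz)[[2]],
               c(1, 0, 0), tolerance = 1e-12)
  expect_error(rotate_multipoles(plm, diag(c(1, 1, -1))), "improper")
})

test_that("pseudoatom density integrates to the electron count", {
  h <- toy_oxygen()
  q <- sph_quad(24, 48)
  gl <- pracma::gaussLegendre(120, 0, 1)
  r0 <- 1.5
  r <- r0 * gl$x / (1 - gl$x)
  wr <- gl$w * r0 / (1 - gl$x)^2
  tot <- 0
  for (k in seq_along(r))
    tot <- tot + sum(eval_density(h, q$u * r[k]) * q$w) * r[k]^2 * wr[k]
  expect_equal(tot, h$Pc + h$Pv, tolerance = 1e-6)
  # each l > 0 deformation level alone carries zero net charge
  h10 <- hansen_atom(8, 0.1, 0, core = data.frame(c = 1, n = 0L, zeta = 15),
                     def = list(list(l = 1L, n = 2L, zeta = 4,
                                     P = c(0.3, 0.5, -0.2)),
                                list(l = 2L, n = 2L, zeta = 4,
                                     P = c(0.1, 0.2, 0.3, 0.4, 0.5))))
  tot <- 0
  for (k in seq_along(r))
    tot <- tot + sum(eval_density(h10, q$u * r[k]) * q$w) * r[k]^2 * wr[k]
  expect_equal(tot, 0.1, tolerance = 1e-6)
  # null parameters give the null density
  h0 <- hansen_atom(1, 0, 0)
  expect_equal(eval_density(h0, rbind(c(1, 1, 1), c(0.2, 0, 0))), c(0, 0))
  # spherical atoms are frame-independent
  hs <- hansen_atom(8, 2, 6, core = data.frame(c = 1, n = 0L, zeta = 15),
                    valence = data.frame(c = 1, n = 2L, zeta = 4))
  A <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(A) < 0) A[, 1] <- -A[, 1]
  pts <- matrix(rnorm(15), 5)
  expect_equal(eval_density(hs, pts), eval_density(hs, pts, frame = A))
})

test_that("atomic moments match spatial quadrature of the density", {
  h <- toy_oxygen()
  m <- atomic_moments(h)
  expect_equal(m$charge, 8 - 2 - 6.2)
  # dipole vector: Q_1 blocks are (mu_y, mu_z, mu_x) = -int rho_e r dV
  q <- sph_quad(30, 60)
  gl <- pracma::gaussLegendre(150, 0, 1)
  r0 <- 1.5
  r <- r0 * gl$x / (1 - gl$x)
  wr <- gl$w * r0 / (1 - gl$x)^2
  mu <- c(0, 0, 0)
  for (k in seq_along(r)) {
    d <- eval_density(h, q$u * r[k])
    mu <- mu + colSums(q$u * d * q$w) * r[k]^3 * wr[k]
  }
  expect_equal(m$q[[2]], -mu[c(2, 3, 1)], tolerance = 1e-8,
               ignore_attr = TRUE)
  # neutral spherical atom: all moments vanish
  hs <- hansen_atom(8, 2, 6, core = data.frame(c = 1, n = 0L, zeta = 15),
                    valence = data.frame(c = 1, n = 2L, zeta = 4))
  ms <- atomic_moments(hs)
  expect_equal(ms$charge, 0)
  expect_true(all(vapply(ms$q, function(v) all(v == 0), logical(1))))
  # moments of rotated populations equal rotated moments (l = 1 block
  # rotates like the vector (y, z, x))
  set.seed(3)
  A <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(A) < 0) A[, 1] <- -A[, 1]
  plm <- list(0, c(0.02, -0.05, 0.03), c(0, 0.01, 0, -0.02, 0.015))
  mrot <- atomic_moments(h, plm = rotate_multipoles(plm, A))
  vec <- m$q[[2]][c(3, 1, 2)]          # to (x, y, z)
  vrot <- as.numeric(A %*% vec)
  expect_equal(mrot$q[[2]], vrot[c(2, 3, 1)], tolerance = 1e-10)
})

test_that("local frames follow the priority rules and co-rotate rigidly", {
  cx <- make_complex("water_dimer")
  # water O: z toward the lower-serial H (equal Z, near-equal lengths
  # decided by bond length then serial)
  fr <- build_local_frame(1, cx$snapshot, cx$bonds)
  dz <- cx$snapshot$xyz[fr$definition$z, ] - cx$snapshot$xyz[1, ]
  expect_equal(as.numeric(fr$R[, 3]), dz / sqrt(sum(dz^2)))
  expect_equal(det(fr$R), 1, tolerance = 1e-12)
  expect_equal(crossprod(fr$R), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # terminal H: z along its only bond, x reference borrowed from a
  # neighbor of the neighbor
  frh <- build_local_frame(2, cx$snapshot, cx$bonds)
  expect_equal(frh$definition$z, 1L)
  expect_equal(frh$definition$x, 3L)
  # rigid rotation of the snapshot rotates every frame matrix
  set.seed(5)
  A <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(A) < 0) A[, 1] <- -A[, 1]
  s2 <- cx$snapshot
  s2$xyz <- cx$snapshot$xyz %*% t(A)
  b2 <- infer_connectivity(s2)
  for (i in seq_len(6)) {
    f1 <- build_local_frame(i, cx$snapshot, cx$bonds)
    f2 <- build_local_frame(i, s2, b2)
    expect_equal(f2$R, A %*% f1$R, tolerance = 1e-10)
  }
  # isolated atom: identity frame with a warning
  iso <- cx$snapshot
  iso$xyz[4, ] <- c(50, 50, 50)
  bi <- suppressWarnings(infer_connectivity(iso))
  expect_warning(fi <- build_local_frame(4, iso, bi), "no bonded neighbor")
  expect_equal(fi$R, diag(3))
})

test_that("a single l=1 population reproduces the closed-form dipole", {
  # P10 = 0.1 on a toy H-type: dipole magnitude from the analytic
  # radial moment integral int r^l R_l(kp*zeta; r) r^2 dr
  P10 <- 0.1; zeta <- 2.2; kp <- 1.2; n <- 1L
  h <- hansen_atom(1, 0, 0.9, kappa = 1.1, kappap = kp,
                   valence = data.frame(c = 1, n = 0L, zeta = 2.2),
                   def = list(list(l = 1L, n = n, zeta = zeta,
                                   P = c(0, P10, 0))))
  m <- atomic_moments(h)
  radial <- gamma(n + 1 + 3) / (gamma(n + 3) * (zeta * kp))
  # mu_z = P * radial * int y_10 * cos(theta) dOmega
  #      = P * radial * (1/pi) * (4*pi/3) = P * radial * 4/3
  expect_equal(m$q[[2]][2], -P10 * radial * 4 / 3, tolerance = 1e-12)
  # and against direct numerical integration of z * rho_deformation
  q <- sph_quad(30, 60)
  gl <- pracma::gaussLegendre(150, 0, 1)
  r0 <- 2; r <- r0 * gl$x / (1 - gl$x); wr <- gl$w * r0 / (1 - gl$x)^2
  hdef <- hansen_atom(1, 0, 0, kappap = kp,
                      def = list(list(l = 1L, n = n, zeta = zeta,
                                      P = c(0, P10, 0))))
  muz <- 0
  for (k in seq_along(r))
    muz <- muz + sum(eval_density(hdef, q$u * r[k]) * q$u[, 3] * q$w) *
      r[k]^3 * wr[k]
  expect_equal(m$q[[2]][2], -muz, tolerance = 1e-9)
})
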