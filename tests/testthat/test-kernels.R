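test_that("the evolution matrix has the augmented structure", {
  m <- bench_model()
  G <- bm_generator(m, omega_A = 100, omega_B = -200, omega1 = 60)
  expect_equal(dim(G), c(7, 7))
  expect_equal(G[1, ], rep(0, 7))  # constant element stays 1

  # no exchange, no RF, on resonance: pure decoupled relaxation rates
  m0 <- exchange_model(k_ex = 0, p_B = 0.3, delta_A = 118, delta_delta = 0,
                       R1_A = 1.5, R2_A = 10, R1_B = 2.5, R2_B = 20)
  G0 <- bm_generator(m0, 0, 0, 0)
  ev <- sort(Re(eigen(G0[2:7, 2:7])$values))
  expect_equal(ev, sort(-c(10, 10, 1.5, 20, 20, 2.5)), tolerance = 1e-12)

  # without relaxation and RF, exchange conserves total z-magnetization:
  # the Mz columns of the z-block sum to zero
  mz <- exchange_model(k_ex = 300, p_B = 0.05, delta_A = 118,
                       delta_delta = -5, R1_A = 0, R2_A = 0, R2_B = 0)
  Gz <- bm_generator(mz, 50, -50, 0)
  expect_equal(Gz[4, 4] + Gz[7, 4], 0)
  expect_equal(Gz[4, 7] + Gz[7, 7], 0)
})

test_that("propagation matches identity, fixed-point and ODE oracles", {
  m <- bench_model()
  om <- angular_frequencies(m, bench_acq(), 113.7, 25)
  G <- bm_generator(m, om$omega_A, om$omega_B, om$omega1)
  M0 <- c(1, 0, 0, 1 - m$p_B, 0, 0, m$p_B)

  expect_equal(propagate_bm(G, M0, 0), M0)          # T = 0 is the identity
  expect_error(propagate_bm(G, M0, -1), ">= 0")
  expect_error(propagate_bm(G, c(2, rep(0, 6)), 1), "M0")

  # equilibrium is a fixed point when the RF is off (with or without
  # exchange)
  for (kex in c(0, 300)) {
    meq <- exchange_model(k_ex = kex, p_B = 0.05, delta_A = 118,
                          delta_delta = -5)
    Geq <- bm_generator(meq, 500, -1500, 0)
    Meq <- c(1, 0, 0, 0.95, 0, 0, 0.05)
    expect_equal(propagate_bm(Geq, Meq, 0.7), Meq, tolerance = 1e-12)
  }

  # element 0 stays 1 and the result matches a hand-rolled fixed-step RK4
  # integration of dM/dt = G M
  set.seed(7)
  mr <- random_model()
  omr <- angular_frequencies(mr, bench_acq(), 116.3, 25)
  Gr <- bm_generator(mr, omr$omega_A, omr$omega_B, omr$omega1)
  M0r <- c(1, 0, 0, 1 - mr$p_B, 0, 0, mr$p_B)
  Mt <- propagate_bm(Gr, M0r, 0.4)
  expect_equal(Mt[1], 1, tolerance = 1e-10)
  expect_equal(Mt, rk4_propagate(Gr, M0r, 0.4, dt = 1e-5),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("matrix kernel agrees with an independent adaptive ODE solver", {
  acq <- bench_acq()
  set.seed(11)
  for (i in 1:20) {
    m <- random_model()
    nu1 <- sample(c(10, 25, 100), 1)
    off <- runif(2, 106, 128)
    z <- zspec_matrix(m, acq, nu1, off)
    for (j in 1:2) {
      om <- angular_frequencies(m, acq, off[j], nu1)
      G <- bm_generator(m, om$omega_A, om$omega_B, om$omega1)
      M0 <- c(1, 0, 0, 1 - m$p_B, 0, 0, m$p_B)
      Mref <- lsoda_propagate(G, M0, acq$T_sat)
      expect_equal(z[j], Mref[4] / (1 - m$p_B), tolerance = 1e-6)
    }
  }
})

test_that("matrix kernel reduces to the exchange-free limits", {
  acq <- bench_acq()
  off <- bench_offsets()

  # vanishing minor population: coincides with the single-spin kernel
  m <- exchange_model(k_ex = 300, p_B = 1e-12, delta_A = 118,
                      delta_delta = -5, R1_A = 1.5, R2_A = 10)
  zm <- zspec_matrix(m, acq, 10, off)
  zn <- zspec_noex(1.5, 10, 118, acq, 10, off)
  expect_lt(max(abs(zm - zn)), 1e-6)

  m0 <- exchange_model(k_ex = 0, p_B = 1e-12, delta_A = 118,
                       delta_delta = -5, R1_A = 1.5, R2_A = 10)
  expect_lt(max(abs(zspec_matrix(m0, acq, 10, off) - zn)), 1e-8)

  # far off resonance the equilibrium start stays put
  expect_gte(zspec_matrix(bench_model(), acq, 10, 1118), 0.999)
})

test_that("benchmark residue shows its two dips at the state positions", {
  z <- zspec_matrix(bench_model(), bench_acq(), 10, bench_offsets())
  x <- bench_offsets()
  loc <- which(diff(sign(diff(z))) == 2) + 1
  dips <- x[loc][order(z[loc])][1:2]
  expect_equal(sort(dips), c(113, 118))   # ground at 118, minor at 118 - 5
  expect_lt(z[x == 118], z[x == 113])     # ground dip is the deeper one
})

test_that("analytical and matrix kernels agree across the benchmark grid", {
  acq <- bench_acq()
  off <- bench_offsets()
  spec <- validation_spec()
  worst <- 0
  for (i in seq_len(nrow(spec$residues))) {
    r <- spec$residues[i, ]
    m <- exchange_model(k_AB = 15, k_BA = 285, delta_A = r$delta_A,
                        delta_delta = r$delta_delta, R1_A = 1.5, R2_A = 10)
    for (nu1 in c(10, 100)) {
      d <- abs(zspec_baldwin(m, acq, nu1, off) -
                 zspec_matrix(m, acq, nu1, off))
      worst <- max(worst, max(d))
    }
  }
  # the spectral solution is exact, so the two independent numerical routes
  # (eigendecomposition vs scaling-and-squaring expm) agree to tight
  # precision, far inside the 0.01 band required of the analytical kernel
  expect_lt(worst, 1e-8)
})

test_that("kernel intensities stay within physical bounds", {
  acq <- bench_acq()
  off <- seq(106, 128, 0.5)
  set.seed(3)
  for (i in 1:10) {
    m <- random_model()
    for (f in list(function() zspec_matrix(m, acq, 25, off),
                   function() zspec_baldwin(m, acq, 25, off),
                   function() zspec_noex(m$R1_A, m$R2_A, m$delta_A, acq,
                                         25, off))) {
      z <- f()
      expect_true(all(z >= -1 & z <= 1))
    }
    expect_true(all(abs(zspec_matrix(m, acq, 10, c(1000, -800)) - 1) <= 1e-3))
  }
})

test_that("swapping the state labels leaves the physics unchanged", {
  acq <- bench_acq()
  off <- bench_offsets(0.5)
  m <- exchange_model(k_ex = 300, p_B = 0.05, delta_A = 118,
                      delta_delta = -5, R1_A = 1.5, R1_B = 2,
                      R2_A = 10, R2_B = 30)
  m_swap <- exchange_model(k_ex = 300, p_B = 1 - 0.05, delta_A = 113,
                           delta_delta = +5, R1_A = 2, R1_B = 1.5,
                           R2_A = 30, R2_B = 10)
  zA <- zspec_matrix(m, acq, 25, off, component = "A")
  zB <- zspec_matrix(m_swap, acq, 25, off, component = "B")
  expect_equal(zA, zB, tolerance = 1e-8)
})

test_that("R1rho reproduces its closed-form limits", {
  # no exchange: R1 cos^2(theta) + R2 sin^2(theta)
  m0 <- exchange_model(k_ex = 0, p_B = 0.05, delta_A = 118,
                       delta_delta = -5, R1_A = 1.5, R2_A = 10)
  w1 <- 2 * pi * 25
  for (omA in 2 * pi * 80.12 * c(0.5, 2, 5, -3)) {
    th <- atan2(w1, omA)
    expect_equal(
      r1rho_baldwin(m0, omA, omA - 2 * pi * 5 * 80.12, w1),
      1.5 * cos(th)^2 + 10 * sin(th)^2, tolerance = 1e-3)
  }
  # effective field along z far off resonance: R1rho -> R1
  expect_equal(r1rho_baldwin(m0, 1e7, 1e7, w1), 1.5, tolerance = 1e-6)
  expect_equal(r1rho_baldwin(m0, -1e7, -1e7, w1), 1.5, tolerance = 1e-6)
  expect_error(r1rho_baldwin(m0, 100, 100, 0), "omega1")

  # with exchange, on-resonance saturation of the ground state decays near
  # R2 + p_B * k_ex (fast-exchange-free slow limit sanity bound)
  m <- bench_model()
  r <- r1rho_baldwin(m, 1e-6, -2 * pi * 5 * 80.12, w1)
  expect_gt(r, m$R2_A)
  expect_lt(r, m$R2_A + m$k_ex)
})

test_that("no-exchange dip width grows monotonically with the RF field", {
  acq <- bench_acq()
  x <- seq(108, 128, 0.02)
  half_width <- vapply(c(10, 25, 50, 100), function(nu1) {
    z <- zspec_noex(1.5, 10, 118, acq, nu1, x)
    depth <- 1 - min(z)
    sum(z < 1 - depth / 2) * 0.02
  }, numeric(1))
  expect_true(all(diff(half_width) > 0))
})

test_that("B1 inhomogeneity averaging is a proper Gaussian quadrature", {
  acq <- bench_acq()
  m <- bench_model()
  off <- bench_offsets(0.5)
  plain <- zspec_baldwin(m, acq, 10, off)

  # degenerate distribution: bit-identical to the nominal profile
  fn <- function(nu1) zspec_baldwin(m, acq, nu1, off)
  expect_identical(apply_b1_inhomogeneity(fn, 10, 0, 11), plain)
  expect_identical(apply_b1_inhomogeneity(fn, 10, 0.1, 1), plain)

  # weights are normalized: a constant profile averages to itself exactly
  for (np in c(3, 11, 101))
    for (fs in c(0.05, 0.2, 0.5))
      expect_equal(apply_b1_inhomogeneity(function(nu1) rep(1, 4),
                                          10, fs, np), rep(1, 4),
                   tolerance = 1e-14)

  # quadrature is converged by 11 points
  z11 <- apply_b1_inhomogeneity(fn, 10, 0.1, 11)
  z101 <- apply_b1_inhomogeneity(fn, 10, 0.1, 101)
  expect_lt(max(abs(z11 - z101)), 1e-3)

  expect_error(apply_b1_inhomogeneity(fn, 10, 0.6, 11), "frac_sigma")
  expect_error(apply_b1_inhomogeneity(fn, 10, 0.1, 4), "odd")

  # the acquisition-level switch routes through the same averaging
  acq_b1 <- bench_acq(b1_frac_sigma = 0.1, b1_grid_points = 11)
  expect_equal(zspec_baldwin(m, acq_b1, 10, off), z11)
})

test_that("Z-spectra are mirror-symmetric under reflection about delta_A", {
  acq <- bench_acq()
  d <- seq(-8, 8, 0.5)
  m <- exchange_model(k_ex = 300, p_B = 0.05, delta_A = 118,
                      delta_delta = -5, R1_A = 1.5, R2_A = 10, R2_B = 25)
  m_ref <- exchange_model(k_ex = 300, p_B = 0.05, delta_A = 118,
                          delta_delta = +5, R1_A = 1.5, R2_A = 10, R2_B = 25)
  z <- zspec_matrix(m, acq, 25, 118 + d)
  z_ref <- zspec_matrix(m_ref, acq, 25, 118 - d)
  expect_equal(z, z_ref, tolerance = 1e-10)
})
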