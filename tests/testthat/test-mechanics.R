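test_that("aligned directors give zero tilt and zero splay", {
  bl <- tiny_bilayer(n_side = 3L, spacing = 8)
  lf <- assign_leaflets(bl$frames, bl$topology)
  s <- tilt_splay_samples(bl$frames, lf, bl$topology)
  expect_true(all(abs(s$tilts) < 1e-9))
  expect_true(all(abs(s$splays) < 1e-12))
  expect_gt(s$pair_filter_log[["accepted"]], 0L)
})

test_that("two symmetrically tilted lipids have splay -2 sin(a)/d", {
  # 2 lipids per leaflet at separation d = 8 A, tilted toward each other
  alpha <- 0.2; d <- 8
  coords <- array(NA_real_, c(12L, 3L, 1L))
  place <- function(base, x, y, zh, dir) {
    coords[base + 1L, , 1L] <<- c(x, y, zh)
    coords[base + 2L, , 1L] <<- c(x, y, zh) - dir
    coords[base + 3L, , 1L] <<- c(x, y, zh) - 6 * dir
  }
  dir1 <- c(sin(alpha), 0, cos(alpha))    # tilted toward +x
  dir2 <- c(-sin(alpha), 0, cos(alpha))   # tilted toward -x
  # P offsets chosen so the head points sit exactly d apart
  sa <- sin(alpha) / 2
  place(0L, 6 + sa, 8, 60, dir1); place(3L, 6 + d - sa, 8, 60, dir2)
  place(6L, 6 - sa, 8, 20, -dir1); place(9L, 6 + d + sa, 8, 20, -dir2)
  atoms <- data.frame(lipid_id = rep(1:4, each = 3L), species = "SYN",
                      atom_name = rep(c("P", "C2", "CT"), 4L))
  fs <- frame_series(coords, c(24, 16, 80), atoms, dt = 1)
  top <- topology_set(synthetic_lipid_topology())
  lf <- assign_leaflets(fs, top)
  s <- tilt_splay_samples(fs, lf, top, d_range = c(2, 12))
  expect_equal(length(s$splays), 2L)       # one pair per leaflet
  expect_equal(s$splays, rep(-2 * sin(alpha) / d, 2L), tolerance = 1e-6)
  expect_equal(sort(unique(round(s$tilts, 9))), alpha, tolerance = 1e-9)
})

test_that("independent small directors pass the weak-correlation filter", {
  gen <- make_lattice_membrane(n_lipids_per_leaflet = 64L, tilt_sigma = 0.1,
                               xy_sigma = 0.8, n_frames = 3L, seed = 23L)
  lf <- assign_leaflets(gen$frames, gen$topology)
  s <- tilt_splay_samples(gen$frames, lf, gen$topology)
  log <- s$pair_filter_log
  acc_frac <- log[["accepted"]] /
    (log[["accepted"]] + log[["rejected_angle"]])
  expect_gt(acc_frac, 0.95)   # angle filter nearly never trips at 0.1 rad
})

test_that("tilt modulus recovery and maximum-likelihood oracle agree", {
  kt <- 2.86e-20
  s <- sample_tilt_splay(kappa_tilt = kt, n = 1e5, seed = 41L)
  m <- fit_tilt_modulus(s, temperature = 303.15)
  expect_lt(rel_err(as.numeric(m$value), kt), 0.05)

  # brute-force ML on the same samples: p(theta) ~ sin(theta) exp(-k th^2/2kBT)
  # (optimized over k/kt so the tolerance is meaningful at the 1e-20 scale)
  kT <- kBT(303.15)
  nll <- function(ratio) {
    k <- ratio * kt
    Z <- integrate(function(t) sin(t) * exp(-k * t^2 / (2 * kT)),
                   0, pi / 2, rel.tol = 1e-10)$value
    sum(k * s$tilts^2 / (2 * kT)) + length(s$tilts) * log(Z)
  }
  ml <- kt * optimize(nll, interval = c(1 / 3, 3), tol = 1e-8)$minimum
  expect_lt(abs(as.numeric(m$value) - ml) / ml, 0.05)
})

test_that("tilt modulus in thermal units is set by the samples alone", {
  s <- sample_tilt_splay(n = 2e4, seed = 6L)
  m1 <- fit_tilt_modulus(s, temperature = 303.15)
  m2 <- fit_tilt_modulus(s, temperature = 2 * 303.15)
  # PMF scales with kBT, so the J value doubles while kBT units are fixed
  expect_equal(as.numeric(m2$value) / as.numeric(m1$value), 2,
               tolerance = 1e-6)
  expect_equal(as.numeric(m1$value) / kBT(303.15),
               as.numeric(m2$value) / kBT(2 * 303.15), tolerance = 1e-6)
})

test_that("bending rigidity recovery, symmetry and moment oracle", {
  kap <- 1.12e-19; apl <- 60.7
  s <- sample_tilt_splay(kappa = kap, n = 1e5, apl = apl, seed = 42L)
  b <- fit_bending_rigidity_rsf(s, temperature = 303.15, apl = apl)
  expect_lt(rel_err(as.numeric(b$value), kap), 0.05)
  # symmetric distribution: fitted linear term negligible vs quadratic scale
  expect_lt(abs(b$linear_term) * diff(b$fit_range),
            0.2 * kBT(303.15))
  # moment oracle: chi = kBT / var(S) within 2%
  chi_mom <- kBT(303.15) / var(s$splays)
  expect_lt(abs(as.numeric(b$chi) / chi_mom - 1), 0.02)
})

test_that("kappa estimate is invariant under z-rotation and leaflet exchange", {
  gen <- make_lattice_membrane(n_lipids_per_leaflet = 49L, tilt_sigma = 0.25,
                               xy_sigma = 1, n_frames = 10L, seed = 19L)
  lf <- assign_leaflets(gen$frames, gen$topology)
  s0 <- tilt_splay_samples(gen$frames, lf, gen$topology)

  # in-plane rotation: swap x and y (with the box edges), an exact
  # orthogonal transform of the xy plane under which tilt and splay are
  # scalar invariants
  fsr <- frame_series(gen$frames$coords[, c(2L, 1L, 3L), , drop = FALSE],
                      gen$frames$box[, c(2L, 1L, 3L), drop = FALSE],
                      gen$frames$atoms, dt = gen$frames$dt)
  lfr <- assign_leaflets(fsr, gen$topology)
  sr <- tilt_splay_samples(fsr, lfr, gen$topology)
  expect_equal(sort(sr$splays), sort(s0$splays), tolerance = 1e-9)
  expect_equal(sort(sr$tilts), sort(s0$tilts), tolerance = 1e-9)

  # leaflet exchange: mirror z about the box center
  mir <- gen$frames$coords
  mir[, 3L, ] <- gen$frames$box[1L, 3L] - mir[, 3L, ]
  fsm <- frame_series(mir, gen$frames$box, gen$frames$atoms,
                      dt = gen$frames$dt)
  lfm <- assign_leaflets(fsm, gen$topology)
  sm <- tilt_splay_samples(fsm, lfm, gen$topology)
  # a z-mirror flips the sign convention of every splay but not |S|, so the
  # (symmetric) PMF and the fitted modulus are unchanged
  expect_equal(sort(sm$splays), sort(-s0$splays), tolerance = 1e-9)
  expect_equal(sort(sm$tilts), sort(s0$tilts), tolerance = 1e-9)
  k0 <- as.numeric(fit_bending_rigidity_rsf(s0$splays)$value)
  km <- as.numeric(fit_bending_rigidity_rsf(sm$splays)$value)
  expect_lt(abs(km / k0 - 1), 0.02)
})

test_that("parameter recovery is unbiased over seeds (median < 5%)", {
  kt_err <- k_err <- numeric(8L)
  for (i in 1:8) {
    s <- sample_tilt_splay(n = 3e4, seed = 100L + i)
    kt_err[i] <- as.numeric(fit_tilt_modulus(s)$value) / 2.86e-20 - 1
    k_err[i] <- as.numeric(fit_bending_rigidity_rsf(s)$value) / 1.12e-19 - 1
  }
  expect_lt(abs(median(kt_err)), 0.05)
  expect_lt(abs(median(k_err)), 0.05)
})

test_that("area compressibility: closed form, recovery and degeneracy", {
  # analytic Gaussian oracle: fitted K_A = kBT/(a0 sigma^2) within 3%
  a0 <- 60.7; t0 <- 3.78; Tk <- 303.15
  sigma <- 0.15
  set.seed(77)
  x <- rnorm(1e5, 0, sigma)
  ser <- thickness_fluctuation_series(t0 * (1 - x), t0 = t0, a0 = a0,
                                      temperature = Tk)
  r <- area_compressibility(ser)
  ka_exact <- kBT(Tk) / (a0 * sigma^2) * phys_const$J_per_A2_to_mN_per_m
  expect_lt(rel_err(as.numeric(r$KA), ka_exact), 0.03)

  # generator round trip at the reference value, n = 1e4, within 10%
  ser2 <- sample_thickness_series(ka = 235, n = 1e4, seed = 5L)
  r2 <- area_compressibility(ser2)
  expect_lt(rel_err(as.numeric(r2$KA), 235), 0.10)
  expect_identical(r2$convention, "whole membrane")

  expect_error(area_compressibility(
    thickness_fluctuation_series(rep(3.78, 1000))), "degenerate")
})
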