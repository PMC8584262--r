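test_that("autocorrelation of a single cosine mode is a cosine", {
  n <- 128L; a <- 0.05; R <- 5
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  r <- matrix(rep(R + a * cos(2 * phi), 50L), 50L, byrow = TRUE)
  cs <- contour_series(r)
  xi <- angular_autocorrelation(cs)
  # R is the grand mean, so u = a cos(2 phi) exactly
  expect_equal(xi$xi, a^2 / 2 * cos(2 * xi$gamma), tolerance = 1e-10)
  # xi(0) equals the contour variance
  expect_equal(xi$xi[1L], mean((r - cs$R)^2), tolerance = 1e-12)
})

test_that("white-noise contours decorrelate away from zero lag", {
  set.seed(4)
  r <- matrix(5 + rnorm(400 * 128, 0, 0.01), 400L, 128L)
  xi <- angular_autocorrelation(contour_series(r))
  expect_gt(xi$xi[1L], 5e-5)
  expect_lt(max(abs(xi$xi[-1L])), xi$xi[1L] / 10)
})

test_that("FFT autocorrelation equals the double-loop computation", {
  set.seed(10)
  n <- 64L
  r <- matrix(5 + rnorm(6L * n, 0, 0.05), 6L, n)
  cs <- contour_series(r)
  xi <- angular_autocorrelation(cs)
  u <- r - cs$R
  brute <- sapply(seq_len(n), function(k) {
    mean(sapply(seq_len(6L), function(f) {
      mean(u[f, ] * u[f, ((seq_len(n) - 1L + (k - 1L)) %% n) + 1L])
    }))
  })
  expect_equal(xi$xi, brute, tolerance = 1e-12)
})

test_that("missing rays use pairwise-complete products", {
  set.seed(2)
  r <- matrix(5 + rnorm(20 * 64, 0, 0.05), 20L, 64L)
  r[3L, 10:12] <- NA
  xi <- angular_autocorrelation(contour_series(r))
  expect_true(all(is.finite(xi$xi)))
})

test_that("Legendre decomposition is orthogonal and re-synthesizes xi", {
  n <- 256L
  g <- 2 * pi * (seq_len(n) - 1L) / n
  xi <- structure(list(gamma = g,
                       xi = 0.4 * membramech:::legendre_poly(3L, cos(g)),
                       R = 1, temperature = 295.15),
                  class = "angular_autocorrelation")
  s <- spectrum_average(xi, 8L)
  expect_equal(s$B_l[s$modes == 3L], 0.4, tolerance = 1e-9)
  expect_lt(max(abs(s$B_l[s$modes != 3L])), 1e-9)

  const <- structure(list(gamma = g, xi = rep(2.5, n), R = 1,
                          temperature = 295.15),
                     class = "angular_autocorrelation")
  sc <- spectrum_average(const, 6L)
  expect_equal(sc$B_l[1L], 2.5, tolerance = 1e-9)
  expect_lt(max(abs(sc$B_l[-1L])), 1e-9)

  # random smooth xi: resynthesis from B_l reproduces it
  set.seed(5)
  B_true <- c(0.3, 0, 0.2, 0.1, 0.05, 0.02, 0.01)
  xi_r <- Reduce(`+`, lapply(0:6, function(l)
    B_true[l + 1L] * membramech:::legendre_poly(l, cos(g))))
  sr <- spectrum_average(structure(list(gamma = g, xi = xi_r, R = 1,
                                        temperature = 295.15),
                                   class = "angular_autocorrelation"), 10L)
  resynth <- Reduce(`+`, lapply(0:10, function(l)
    sr$B_l[l + 1L] * membramech:::legendre_poly(l, cos(g))))
  expect_equal(resynth, xi_r, tolerance = 1e-8)
  expect_error(spectrum_average(xi, 200L), "half the angular grid")
})

test_that("statistical spectrum recovers exponential amplitude means", {
  # i.i.d. exponential squared amplitudes per mode, synthesized directly
  set.seed(6)
  n <- 128L; nf <- 1000L
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  m_true <- c(4e-4, 2e-4, 1e-4)
  r <- matrix(0, nf, n)
  for (f in seq_len(nf)) {
    u <- 0
    for (k in 1:3) {
      amp <- sqrt(rexp(1L, 1 / m_true[k]))
      ph <- runif(1L, 0, 2 * pi)
      u <- u + 2 * amp * cos((k + 2L) * phi + ph)
    }
    r[f, ] <- 5 * (1 + u)
  }
  spec <- spectrum_statistical(contour_series(r), 8L)
  errs <- vapply(1:3, function(k)
    rel_err(spec$amplitude_mean[k + 2L], m_true[k]), numeric(1L))
  expect_lt(median(errs), 0.05)   # per-mode estimator sd is ~3% at 1000 frames
  expect_lt(max(errs), 0.10)
})

test_that("degenerate single-mode series falls back to the raw mean", {
  n <- 128L
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  r <- matrix(rep(5 * (1 + 0.02 * cos(3 * phi)), 60L), 60L, byrow = TRUE)
  spec <- spectrum_statistical(contour_series(r), 6L)
  expect_equal(spec$estimator[3L], "raw")
})

test_that("average and statistical spectra agree on equilibrium contours", {
  cs <- make_fluctuating_vesicle(kappa = 1.9e-19, n_frames = 1500L,
                                 seed = 77L)
  ss <- spectrum_statistical(cs, 15L)
  sa <- spectrum_average(angular_autocorrelation(cs), 15L)
  # compare at the Fourier level: predicted <|c_m|^2> from the per-l average
  # spectrum vs the directly measured Fourier amplitudes
  ks <- as.numeric(fit_bending_rigidity(ss, mode_range = c(3L, 12L))$kappa)
  ka <- as.numeric(fit_bending_rigidity(sa, mode_range = c(3L, 12L))$kappa)
  expect_lt(abs(ks / ka - 1), 0.10)
})

test_that("rigidity fit recovers exact model amplitudes and scales", {
  kap <- 1.9e-19; sb <- 10
  modes <- 0:24
  amp <- membramech:::ms_mode_variance(pmax(modes, 2L), kap, sb, 295.15)
  amp[modes < 2L] <- 1e-3
  spec <- structure(list(modes = modes, amplitude_mean = amp, R = 5,
                         temperature = 295.15, approach = "average"),
                    class = "fluctuation_spectrum")
  fit <- fit_bending_rigidity(spec, mode_range = c(3L, 20L))
  expect_lt(rel_err(as.numeric(fit$kappa), kap), 0.03)
  expect_lt(abs(fit$sigma_bar - sb), 1)

  # doubling all amplitudes halves the fitted kappa
  spec2 <- spec; spec2$amplitude_mean <- 2 * amp
  fit2 <- fit_bending_rigidity(spec2, mode_range = c(3L, 20L))
  expect_equal(as.numeric(fit2$kappa) / as.numeric(fit$kappa), 0.5,
               tolerance = 1e-6)

  # grid-search oracle over (kappa, sigma_bar)
  obs <- amp[modes >= 3 & modes <= 20]
  ms <- 3:20
  grid_k <- kap * seq(0.8, 1.2, length.out = 81L)
  grid_s <- seq(5, 15, length.out = 81L)
  best <- c(Inf, NA, NA)
  for (kk in grid_k) for (ss in grid_s) {
    pred <- membramech:::ms_mode_variance(ms, kk, ss, 295.15)
    err <- sum((log(obs) - log(pred))^2)
    if (err < best[1L]) best <- c(err, kk, ss)
  }
  expect_lt(abs(as.numeric(fit$kappa) / best[2L] - 1), 0.01)
})

test_that("fitted kappa is invariant to angular origin and frame order", {
  cs <- make_fluctuating_vesicle(kappa = 3e-19, n_frames = 400L, seed = 12L)
  k0 <- as.numeric(fit_bending_rigidity(spectrum_statistical(cs, 15L),
                                        mode_range = c(3L, 12L))$kappa)
  rot <- contour_series(cs$r[, c(40:256, 1:39)])
  k1 <- as.numeric(fit_bending_rigidity(spectrum_statistical(rot, 15L),
                                        mode_range = c(3L, 12L))$kappa)
  perm <- contour_series(cs$r[sample(400L), ])
  k2 <- as.numeric(fit_bending_rigidity(spectrum_statistical(perm, 15L),
                                        mode_range = c(3L, 12L))$kappa)
  expect_equal(k1, k0, tolerance = 1e-9)
  expect_equal(k2, k0, tolerance = 1e-9)
})

test_that("Parseval: mode powers sum to the contour variance", {
  cs <- make_fluctuating_vesicle(kappa = 1.9e-19, n_frames = 300L, seed = 3L)
  u <- (cs$r - cs$R) / cs$R
  for (f in c(1L, 150L)) {
    cf <- fft(u[f, ]) / cs$n_phi
    expect_equal(sum(Mod(cf)^2), mean(u[f, ]^2), tolerance = 1e-12)
  }
})

test_that("contour extraction: circle, off-center guess, ellipse mode", {
  n <- 120L
  d <- sqrt((row(matrix(0, n, n)) - 60.5)^2 + (col(matrix(0, n, n)) - 60.5)^2)
  img <- array(exp(-(d - 50)^2 / (2 * 1.5^2)), c(n, n, 1L))
  cs <- extract_contour(img, pixel_size = 0.1, n_phi = 128L)
  expect_lt(abs(cs$R - 5), 0.02)
  expect_lt(sd(cs$r), 0.02)

  cs2 <- extract_contour(img, pixel_size = 0.1, center_guess = c(50.5, 65.5),
                         n_phi = 128L)
  expect_lt(abs(cs2$R - cs$R), 0.005)
  expect_lt(max(abs(cs2$r - cs$r)), 0.1)

  th <- atan2(col(matrix(0, n, n)) - 60.5, row(matrix(0, n, n)) - 60.5)
  a <- 52; b <- 48
  rell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  img2 <- array(exp(-(d - rell)^2 / (2 * 1.5^2)), c(n, n, 1L))
  cs3 <- extract_contour(img2, pixel_size = 0.1, n_phi = 256L)
  phi <- 2 * pi * (0:255) / 256
  got <- 2 * mean(cs3$r[1L, ] * cos(2 * phi))
  want <- 2 * mean(0.1 * a * b /
                     sqrt((b * cos(phi))^2 + (a * sin(phi))^2) * cos(2 * phi))
  expect_lt(rel_err(got, want), 0.02)
})

test_that("render-extract-fit recovers kappa end to end", {
  errs <- sapply(1:3, function(s) {
    v <- make_fluctuating_vesicle(kappa = 1.9e-19, n_frames = 400L, seed = s,
                                  render = TRUE, pixel_size = 0.08,
                                  psf_sigma = 1.5, noise = 0.05)
    cs <- extract_contour(v$stack, pixel_size = 0.08, n_phi = 192L)
    fit <- fit_bending_rigidity(spectrum_statistical(cs, 14L),
                                mode_range = c(3L, 12L))
    as.numeric(fit$kappa) / 1.9e-19 - 1
  })
  expect_lt(abs(median(errs)), 0.10)
})
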