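test_that("isotherm files round-trip, with order invariance and dedup", {
  A <- seq(90, 33, length.out = 20L)
  p <- 80 * exp(-A / 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(area = A, pressure = p), path, row.names = FALSE)
  iso <- read_isotherm(path, composition = c(POPC = 1))
  expect_s3_class(iso, "isotherm")
  expect_equal(iso$area, sort(A, decreasing = TRUE))
  expect_equal(length(iso$area), 20L)

  # shuffled rows give the identical isotherm
  path2 <- withr::local_tempfile(fileext = ".csv")
  idx <- sample(20L)
  write.csv(data.frame(area = A[idx], pressure = p[idx]), path2,
            row.names = FALSE)
  iso2 <- read_isotherm(path2, composition = c(POPC = 1))
  expect_equal(iso2$area, iso$area)
  expect_equal(iso2$pressure, iso$pressure)

  # a duplicated area row is averaged away
  path3 <- withr::local_tempfile(fileext = ".tsv")
  A3 <- c(A, A[5L]); p3 <- c(p, p[5L] + 0.2)
  write.table(data.frame(A3, p3), path3, row.names = FALSE, sep = "\t")
  iso3 <- read_isotherm(path3, composition = c(POPC = 1))
  expect_equal(length(iso3$area), 20L)
  expect_equal(iso3$pressure[iso3$area == A[5L]], p[5L] + 0.1)

  expect_error(isotherm(A[1:5], p[1:5], c(X = 1)), ">= 10")
  expect_error(isotherm(A, p, c(X = 0.7, Y = 0.2)), "sum to 1")
})

test_that("APL at pressure interpolates and refuses to extrapolate", {
  iso <- make_isotherm("linear", A0 = 80, slope = 1, pi_max = 45)
  expect_equal(as.numeric(apl_at_pressure(iso, 33)), 47)
  exact <- isotherm(c(seq(90, 55, length.out = 12L), 50),
                    c(seq(0, 28, length.out = 12L), 33), c(X = 1))
  expect_equal(as.numeric(apl_at_pressure(exact, 33)), 50)
  expect_error(apl_at_pressure(iso, 60), "outside")

  # dense exponential isotherm: interpolation matches the analytic inverse
  iso2 <- make_isotherm("exponential", A0 = 80, k = 59, pi_max = 45,
                        n_points = 500L)
  expect_lt(rel_err(as.numeric(apl_at_pressure(iso2, 33)),
                    80 * exp(-33 / 59)), 0.001)
})

test_that("compressibility modulus matches closed forms", {
  iso <- make_isotherm("exponential", A0 = 80, k = 59, pi_max = 45,
                       n_points = 400L)
  r <- compressibility_modulus(iso, 33)
  expect_lt(rel_err(as.numeric(r$modulus), 59), 0.005)
  expect_equal(as.numeric(r$cs_raw), 1 / as.numeric(r$modulus),
               tolerance = 1e-9)

  lin <- make_isotherm("linear", A0 = 80, slope = 0.8, pi_max = 45,
                       n_points = 300L)
  rl <- compressibility_modulus(lin, 33)
  expect_lt(rel_err(as.numeric(rl$modulus), (80 - 0.8 * 33) / 0.8), 0.005)

  # noisy isotherm with smoothing stays within 5% of the closed form
  noisy <- make_isotherm("exponential", A0 = 80, k = 59, pi_max = 45,
                         n_points = 300L, noise_sigma = 0.1, seed = 9L)
  rn <- compressibility_modulus(noisy, 33, smooth = TRUE)
  expect_lt(rel_err(as.numeric(rn$modulus), 59), 0.05)
})

test_that("plateau detection trips on flat isotherms", {
  A <- c(seq(80, 60.01, length.out = 10L), 60 - 1e-8 * 1:5,
         seq(59.99, 40, length.out = 10L))
  p <- seq(0, 45, length.out = 25L)
  iso <- isotherm(A, p, c(X = 1))
  expect_error(compressibility_modulus(iso, p[12L]), "plateau")
})

test_that("ideal mixing is the weighted mean, with identity and boundaries", {
  a <- make_isotherm("exponential", A0 = 80, k = 59)
  b <- make_isotherm("exponential", A0 = 60, k = 200)
  same <- ideal_mixed_apl(list(a, a), c(0.5, 0.5))
  expect_equal(same$area, membramech:::interp_area(a, same$pressure))
  one <- ideal_mixed_apl(list(a, b), c(1, 0))
  expect_equal(one$area, membramech:::interp_area(a, one$pressure))

  c3 <- make_isotherm("linear", A0 = 70, slope = 0.5)
  mix <- ideal_mixed_apl(list(a, b, c3), c(0.5, 0.3, 0.2))
  at <- function(iso, p) membramech:::interp_area(iso, p)
  probe <- seq(2, 40, length.out = 10L)
  got <- approx(mix$pressure, mix$area, xout = probe)$y
  want <- 0.5 * at(a, probe) + 0.3 * at(b, probe) + 0.2 * at(c3, probe)
  expect_equal(got, want, tolerance = 1e-6)

  # permutation invariance of (component, fraction) pairs
  m1 <- ideal_mixed_apl(list(a, b, c3), c(0.5, 0.3, 0.2))
  m2 <- ideal_mixed_apl(list(c3, a, b), c(0.2, 0.5, 0.3))
  expect_equal(m1$area, m2$area, tolerance = 1e-12)
})

test_that("excess free energy vanishes for ideal mixtures", {
  a <- make_isotherm("exponential", A0 = 80, k = 59)
  b <- make_isotherm("exponential", A0 = 60, k = 200)
  mixed <- make_mixed_isotherm(list(a, b), c(0.8, 0.2), delta = 0)
  mr <- excess_free_energy(mixed, list(a, b), c(0.8, 0.2), pi_max = 33)
  expect_lt(max(abs(mr$dG_excess)), 0.1)

  # simplex vertex: X = (1, 0)
  mixed1 <- make_mixed_isotherm(list(a, b), c(1, 0), delta = 0)
  mr1 <- excess_free_energy(mixed1, list(a, b), c(1, 0), pi_max = 33)
  expect_lt(max(abs(mr1$dG_excess)), 0.1)
})

test_that("constant deviation gives the linear closed form", {
  a <- make_isotherm("exponential", A0 = 80, k = 59)
  b <- make_isotherm("exponential", A0 = 60, k = 200)
  cdev <- -3
  mixed <- make_mixed_isotherm(list(a, b), c(0.8, 0.2), delta = cdev)
  mr <- excess_free_energy(mixed, list(a, b), c(0.8, 0.2), pi_max = 33)
  pi0 <- attr(mr, "pi0")
  scale <- phys_const$NA_avogadro * phys_const$mNm_A2_to_J
  i30 <- which.min(abs(mr$pressure - 30))
  want <- scale * cdev * (mr$pressure[i30] - pi0)
  expect_lt(rel_err(mr$dG_excess[i30], want), 0.001)
})

test_that("curved deviation matches refined quadrature within 0.1%", {
  a <- make_isotherm("exponential", A0 = 80, k = 59, n_points = 400L)
  b <- make_isotherm("exponential", A0 = 60, k = 200, n_points = 400L)
  dev_fn <- function(p) -0.08 * p + 0.001 * p^2
  mixed <- make_mixed_isotherm(list(a, b), c(0.8, 0.2), delta = dev_fn)
  mr <- excess_free_energy(mixed, list(a, b), c(0.8, 0.2), pi_max = 33,
                           n_grid = 400L)
  pi0 <- attr(mr, "pi0")
  piN <- mr$pressure[nrow(mr)]
  # oracle: adaptive quadrature of the deviation integral
  want <- phys_const$NA_avogadro * phys_const$mNm_A2_to_J *
    integrate(dev_fn, pi0, piN, rel.tol = 1e-10)$value
  expect_lt(rel_err(mr$dG_excess[nrow(mr)], want), 0.001)
})

test_that("excess free energy is additive over pressure intervals", {
  a <- make_isotherm("exponential", A0 = 80, k = 59, n_points = 800L)
  b <- make_isotherm("linear", A0 = 62, slope = 0.4, n_points = 800L)
  dev_fn <- function(p) 0.05 * sin(p / 5)
  mixed <- make_mixed_isotherm(list(a, b), c(0.6, 0.4), delta = dev_fn)
  full <- excess_free_energy(mixed, list(a, b), c(0.6, 0.4), pi_max = 30,
                             pi0 = 2, n_grid = 1401L)
  head_part <- excess_free_energy(mixed, list(a, b), c(0.6, 0.4),
                                  pi_max = 16, pi0 = 2, n_grid = 701L)
  tail_part <- excess_free_energy(mixed, list(a, b), c(0.6, 0.4),
                                  pi_max = 30, pi0 = 16, n_grid = 701L)
  expect_equal(full$dG_excess[nrow(full)],
               head_part$dG_excess[nrow(head_part)] +
                 tail_part$dG_excess[nrow(tail_part)],
               tolerance = 1e-6)
})

test_that("inconsistent mixture composition is rejected", {
  a <- make_isotherm("exponential", A0 = 80, k = 59)
  b <- make_isotherm("exponential", A0 = 60, k = 200)
  mixed <- make_mixed_isotherm(list(a, b), c(0.8, 0.2))
  expect_error(excess_free_energy(mixed, list(a, b), c(0.5, 0.5)),
               "inconsistent")
})
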