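# Ground-truth generators for every analysis stage. Each generator is
# deterministic under a fixed seed (the caller's RNG state is restored on
# exit) and its defaults are the conditions of the reference POPC system:
# 324 lipids per leaflet, APL 60.7 A^2, thickness 3.78 nm, D 7.7 um^2/s,
# kappa 1.12e-19 J, kappa_tilt 2.86e-20 J, K_A 235 mN/m at 303.15 K for the
# bilayer analyses, and kappa 1.9e-19 J at 295.15 K for vesicle flicker.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Factor pair of n closest to square, preferring an even second factor
# (a periodic hexagonal lattice needs an even row count).
lattice_dims <- function(n) {
  divs <- which(n %% seq_len(n) == 0L)
  pairs <- cbind(divs, n / divs)
  pairs <- pairs[pairs[, 1L] <= pairs[, 2L], , drop = FALSE]
  even <- pairs[pairs[, 2L] %% 2L == 0L, , drop = FALSE]
  if (nrow(even) > 0L) pairs <- even
  best <- which.min(pairs[, 2L] - pairs[, 1L])
  c(nx = unname(pairs[best, 1L]), ny = unname(pairs[best, 2L]))
}

#' Synthetic lattice membrane with prescribed structure and dynamics
#'
#' Builds a bilayer of minimal three-atom lipids (P, C2, terminal carbon CT)
#' on jittered hexagonal leaflet lattices. The box cross-section realizes
#' the prescribed area per lipid exactly; P atoms sit at +/- thickness/2;
#' lipid positions evolve as independent 2D random walks with diffusion
#' coefficient `d_coeff` and receive per-frame rigid z jitter.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (>= 16; factorized into
#'   the closest-to-square lattice).
#' @param apl Area per lipid (angstrom^2).
#' @param thickness P-to-P bilayer thickness (angstrom).
#' @param z_sigma Per-frame rigid z jitter sd (angstrom).
#' @param xy_sigma Static lattice jitter sd (angstrom).
#' @param d_coeff Lateral diffusion coefficient (um^2/s).
#' @param tilt_sigma Angular jitter sd of the lipid director (radians).
#' @param n_frames Number of frames.
#' @param dt Frame interval (ns).
#' @param temperature Temperature (K).
#' @param seed RNG seed.
#' @return List: `frames` (a `frame_series`), `topology` (a `topology_set`),
#'   `leaflet_truth` (data frame lipid_id, leaflet), `params` (the inputs,
#'   including the realized lipid count).
#' @export
make_lattice_membrane <- function(n_lipids_per_leaflet = 324L, apl = 60.7,
                                  thickness = 37.8, z_sigma = 1,
                                  xy_sigma = 1.5, d_coeff = 7.7,
                                  tilt_sigma = 0, n_frames = 100L, dt = 0.1,
                                  temperature = 303.15, seed = 1L) {
  stopifnot(n_lipids_per_leaflet >= 16L, apl > 0, thickness > 0,
            n_frames >= 1L, dt > 0)
  top <- synthetic_lipid_topology()
  a <- sqrt(2 * apl / sqrt(3))            # hexagonal lattice constant
  if (a < max(top$vdw_radii))
    stop("area per lipid too small: lattice spacing below vdW contact")
  dims <- lattice_dims(n_lipids_per_leaflet)
  nx <- dims[["nx"]]; ny <- dims[["ny"]]
  n <- nx * ny
  Lx <- nx * a; Ly <- ny * a * sqrt(3) / 2  # Lx*Ly = n*apl exactly
  Lz <- thickness + 40

  with_seed(seed, {
    ii <- rep(seq_len(nx) - 1L, times = ny)
    jj <- rep(seq_len(ny) - 1L, each = nx)
    x0 <- (ii + 0.5 * (jj %% 2L)) * a
    y0 <- jj * a * sqrt(3) / 2
    nl <- 2L * n
    # static jitter, shared by both leaflets' layouts independently
    X0 <- c(x0, x0) + stats::rnorm(nl, 0, xy_sigma)
    Y0 <- c(y0, y0) + stats::rnorm(nl, 0, xy_sigma)
    leaflet <- rep(c("upper", "lower"), each = n)
    sgn <- ifelse(leaflet == "upper", 1, -1)

    D_A2ns <- d_coeff / phys_const$A2_per_ns_to_um2_per_s
    step_sd <- sqrt(2 * D_A2ns * dt)
    # directors: unit vectors near +/- z with angular jitter
    tilt_x <- stats::rnorm(nl, 0, tilt_sigma)
    tilt_y <- stats::rnorm(nl, 0, tilt_sigma)

    natoms <- 3L * nl
    coords <- array(NA_real_, c(natoms, 3L, n_frames))
    X <- X0; Y <- Y0
    z_head <- sgn * thickness / 2
    for (f in seq_len(n_frames)) {
      if (f > 1L) {
        X <- X + stats::rnorm(nl, 0, step_sd)
        Y <- Y + stats::rnorm(nl, 0, step_sd)
      }
      zj <- stats::rnorm(nl, 0, z_sigma)
      # director of each lipid (pointing from tail toward head)
      dx <- sin(tilt_x); dy <- sin(tilt_y)
      dz <- sgn * sqrt(pmax(0, 1 - dx^2 - dy^2))
      # P at the head, C2 1 A inward, CT 6 A inward along the director;
      # bilayer centered at Lz/2
      pz <- z_head + zj + Lz / 2
      ip <- seq(1L, 3L * nl, by = 3L)
      coords[ip, 1L, f] <- X;           coords[ip, 2L, f] <- Y
      coords[ip, 3L, f] <- pz
      coords[ip + 1L, 1L, f] <- X - dx; coords[ip + 1L, 2L, f] <- Y - dy
      coords[ip + 1L, 3L, f] <- pz - dz
      coords[ip + 2L, 1L, f] <- X - 6 * dx
      coords[ip + 2L, 2L, f] <- Y - 6 * dy
      coords[ip + 2L, 3L, f] <- pz - 6 * dz
    }
    atoms <- data.frame(
      lipid_id = rep(seq_len(nl), each = 3L),
      species = "SYN",
      atom_name = rep(c("P", "C2", "CT"), nl)
    )
    fs <- frame_series(coords, c(Lx, Ly, Lz), atoms, dt = dt,
                       temperature = temperature)
    list(frames = fs,
         topology = topology_set(top),
         leaflet_truth = data.frame(lipid_id = seq_len(nl),
                                    leaflet = leaflet),
         params = list(n_per_leaflet = n, apl = apl, thickness = thickness,
                       d_coeff = d_coeff, box = c(Lx, Ly, Lz), seed = seed))
  })
}

#' Synthetic tilt and splay samples at prescribed moduli
#'
#' Tilt angles follow the Boltzmann law `p(theta) ~ sin(theta)
#' exp(-kappa_tilt theta^2 / (2 kBT))` (Rayleigh proposal rejection
#' sampling); splays are Gaussian with variance `kBT/chi` where
#' `chi = kappa * apl / 2` is the pairwise splay modulus matching the
#' bilayer bending rigidity convention of [fit_bending_rigidity_rsf()].
#'
#' @param kappa Bilayer bending rigidity (J).
#' @param kappa_tilt Tilt modulus (J).
#' @param temperature Temperature (K).
#' @param n Number of samples of each kind (>= 100).
#' @param apl Area per lipid (angstrom^2) entering the splay convention.
#' @param seed RNG seed.
#' @return A `tilt_splay_samples` object.
#' @export
sample_tilt_splay <- function(kappa = 1.12e-19, kappa_tilt = 2.86e-20,
                              temperature = 303.15, n = 1e5, apl = 60.7,
                              seed = 1L) {
  if (n < 100) stop("need n >= 100")
  kT <- kBT(temperature)
  with_seed(seed, {
    sig <- sqrt(kT / kappa_tilt)
    tilts <- numeric(0)
    while (length(tilts) < n) {
      m <- ceiling(1.3 * (n - length(tilts)))
      th <- sig * sqrt(-2 * log(stats::runif(m)))   # Rayleigh
      keep <- th < pi / 2 & stats::runif(m) < sin(th) / th
      tilts <- c(tilts, th[keep])
    }
    chi <- kappa * apl / 2
    splays <- stats::rnorm(n, 0, sqrt(kT / chi))
    structure(list(tilts = tilts[seq_len(n)], splays = splays,
                   pair_filter_log = c(accepted = as.integer(n),
                                       rejected_distance = 0L,
                                       rejected_angle = 0L)),
              class = "tilt_splay_samples")
  })
}

#' Synthetic thickness-fluctuation series at prescribed compressibility
#'
#' Relative deviations `x = (t0 - t)/t0` are Gaussian with variance
#' `kBT / (a0 * K_A)` (unit-reconciled), so the thickness-PMF route
#' recovers `K_A` exactly in distribution.
#'
#' @param ka Area compressibility (mN/m).
#' @param a0 Area per lipid (angstrom^2).
#' @param t0 Equilibrium thickness (nm).
#' @param temperature Temperature (K).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return A `thickness_fluctuation_series`.
#' @export
sample_thickness_series <- function(ka = 235, a0 = 60.7, t0 = 3.78,
                                    temperature = 303.15, n = 1e4,
                                    seed = 1L) {
  stopifnot(ka > 0, a0 > 0, t0 > 0)
  ka_JA2 <- ka / phys_const$J_per_A2_to_mN_per_m
  sigma <- sqrt(kBT(temperature) / (a0 * ka_JA2))
  with_seed(seed, {
    x <- stats::rnorm(n, 0, sigma)
    thickness_fluctuation_series(t = t0 * (1 - x), t0 = t0, a0 = a0,
                                 temperature = temperature)
  })
}

#' Synthetic surface pressure--area isotherm
#'
#' Analytic isotherm `A(pi)` sampled on a pressure grid with optional
#' Gaussian area noise. The exponential form `A = A0 exp(-pi/k)` has
#' surface-elasticity modulus exactly `k` at every pressure; the linear
#' form `A = A0 - m pi` has modulus `(A0 - m pi)/m`.
#'
#' @param form `"exponential"`, `"linear"`, or `"tabulated"`.
#' @param A0 Area at zero pressure (angstrom^2).
#' @param k Exponential pressure constant (mN/m; the modulus).
#' @param slope Linear slope m (angstrom^2 per mN/m).
#' @param table For `"tabulated"`, a data frame with columns `pressure`,
#'   `area`.
#' @param pi_max Maximum pressure (mN/m).
#' @param n_points Number of points.
#' @param noise_sigma Gaussian area noise sd (angstrom^2).
#' @param composition Named mole fractions (default a single species).
#' @param temperature Temperature (K).
#' @param seed RNG seed.
#' @return An `isotherm`.
#' @export
make_isotherm <- function(form = c("exponential", "linear", "tabulated"),
                          A0 = 80, k = 59, slope = 0.8, table = NULL,
                          pi_max = 45, n_points = 200L, noise_sigma = 0,
                          composition = c(SYN = 1), temperature = 295.15,
                          seed = 1L) {
  form <- match.arg(form)
  if (form == "tabulated") {
    stopifnot(!is.null(table))
    p <- table$pressure; A <- table$area
  } else {
    p <- seq(0, pi_max, length.out = n_points)
    A <- switch(form,
                exponential = A0 * exp(-p / k),
                linear = A0 - slope * p)
  }
  with_seed(seed, {
    if (noise_sigma > 0) A <- A + stats::rnorm(length(A), 0, noise_sigma)
    isotherm(A, p, composition = composition, temperature = temperature)
  })
}

#' Synthetic mixed-monolayer isotherm with a prescribed deviation
#'
#' Builds the ideal mole-fraction-weighted mixture of the component
#' isotherms and adds the deviation `delta(pi)` (angstrom^2), so the excess
#' free energy of mixing has the closed form
#' `N_A int delta dpi` and vanishes identically for `delta = 0`.
#'
#' @param components List of single-component `isotherm`s.
#' @param fractions Mole fractions.
#' @param delta Function of pressure returning the area deviation
#'   (angstrom^2), or a single number for a constant deviation.
#' @param noise_sigma Gaussian area noise sd (angstrom^2).
#' @param names Species names for the composition (defaults taken from the
#'   components).
#' @param seed RNG seed.
#' @return An `isotherm` for the mixture.
#' @export
make_mixed_isotherm <- function(components, fractions, delta = 0,
                                noise_sigma = 0, names = NULL, seed = 1L) {
  if (is.numeric(delta)) { dconst <- delta; delta <- function(p) rep(dconst, length(p)) }
  ideal <- ideal_mixed_apl(components, fractions)
  A <- ideal$area + delta(ideal$pressure)
  if (is.null(names))
    names <- vapply(components, function(i) names(i$composition)[1L], "")
  comp <- stats::setNames(fractions, names)
  with_seed(seed, {
    if (noise_sigma > 0) A <- A + stats::rnorm(length(A), 0, noise_sigma)
    isotherm(A, ideal$pressure, composition = comp,
             temperature = components[[1L]]$temperature)
  })
}

#' Synthetic fluctuating quasi-spherical vesicle
#'
#' Draws equilibrium Helfrich / Milner-Safran fluctuations: per frame, the
#' equatorial Fourier coefficients `c_m` are complex Gaussians with variance
#' `V_m = sum_{l>=m} |Y_lm(pi/2,0)|^2 kBT/[kappa (l-1)(l+2)(l(l+1)+sigma_bar)]`
#' — the exact distribution of the equatorial section of independently drawn
#' spherical-harmonic amplitudes truncated at `l_max`. Frames are temporally
#' uncorrelated (equilibrium sampling) unless `frame_correlation` is set, in
#' which case successive coefficients follow an AR(1) process with that
#' correlation.
#'
#' @param kappa Bending rigidity (J).
#' @param sigma_bar Reduced tension (dimensionless).
#' @param R Vesicle radius (um); a warning is issued outside 1--50 um.
#' @param temperature Temperature (K).
#' @param n_frames Number of frames.
#' @param l_max Spherical-harmonic truncation degree.
#' @param n_phi Angular grid size.
#' @param frame_correlation AR(1) coefficient in `[0, 1)` for correlated
#'   frames (default 0: equilibrium, uncorrelated).
#' @param seed RNG seed.
#' @param render If TRUE, return a rendered image stack instead of contours.
#' @param pixel_size Pixel size (um) for rendering.
#' @param psf_sigma Gaussian rim cross-section sd (pixels).
#' @param noise Additive noise level (fraction of peak intensity).
#' @param img_size Image edge in pixels (default fits the vesicle).
#' @return A `contour_series`, or (render = TRUE) a list with `stack`
#'   (array), `contours` (the underlying `contour_series`), `center`,
#'   `pixel_size`.
#' @export
make_fluctuating_vesicle <- function(kappa = 1.9e-19, sigma_bar = 10, R = 5,
                                     temperature = 295.15, n_frames = 1200L,
                                     l_max = 30L, n_phi = 256L,
                                     frame_correlation = 0, seed = 1L,
                                     render = FALSE, pixel_size = 0.08,
                                     psf_sigma = 1.5, noise = 0,
                                     img_size = NULL) {
  stopifnot(kappa > 0, n_frames >= 1L, l_max >= 3L, n_phi >= 64L,
            frame_correlation >= 0, frame_correlation < 1)
  if (R < 1 || R > 50)
    warning("vesicle radius ", R, " um outside the typical 1-50 um range")
  Vm <- vapply(0:l_max, fourier_mode_variance, numeric(1L),
               kappa = kappa, sigma_bar = sigma_bar,
               temperature = temperature, l_max = l_max)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  cs <- with_seed(seed, {
    rmat <- matrix(NA_real_, n_frames, n_phi)
    nm <- l_max + 1L
    re <- matrix(stats::rnorm(n_frames * nm), n_frames, nm)
    im <- matrix(stats::rnorm(n_frames * nm), n_frames, nm)
    if (frame_correlation > 0) {
      a <- frame_correlation; b <- sqrt(1 - a^2)
      for (f in 2:n_frames) {
        re[f, ] <- a * re[f - 1L, ] + b * re[f, ]
        im[f, ] <- a * im[f - 1L, ] + b * im[f, ]
      }
    }
    cosm <- cos(outer(0:l_max, phi)); sinm <- sin(outer(0:l_max, phi))
    for (f in seq_len(n_frames)) {
      cm_re <- re[f, ] * sqrt(Vm / 2); cm_im <- im[f, ] * sqrt(Vm / 2)
      # m = 0 is real with full variance
      cm_re[1L] <- re[f, 1L] * sqrt(Vm[1L]); cm_im[1L] <- 0
      u <- as.numeric(cm_re %*% cosm - cm_im %*% sinm)
      u <- 2 * u - cm_re[1L] * cosm[1L, ]   # m = 0 counted once
      rmat[f, ] <- R * (1 + u)
    }
    rmat
  })
  if (any(cs <= 0))
    stop("fluctuations exceeded the vesicle radius; increase kappa")
  contours <- contour_series(cs, pixel_size = if (render) pixel_size else NA,
                             frame_interval = 1, temperature = temperature)
  if (!render) return(contours)

  if (is.null(img_size))
    img_size <- 2L * ceiling(1.25 * R / pixel_size / 2) * 2L
  cx <- (img_size + 1) / 2; cy <- cx
  stack <- array(0, c(img_size, img_size, n_frames))
  xpix <- row(matrix(0, img_size, img_size)) - cx
  ypix <- col(matrix(0, img_size, img_size)) - cy
  d <- sqrt(xpix^2 + ypix^2)
  ang <- (atan2(ypix, xpix)) %% (2 * pi)
  idx <- ang / (2 * pi) * n_phi            # fractional contour index
  i0 <- floor(idx); fr <- idx - i0
  i1 <- (i0 + 1L) %% n_phi
  noisy <- noise > 0
  rn <- if (noisy) with_seed(seed + 1L, stats::rnorm(img_size^2 * n_frames))
  for (f in seq_len(n_frames)) {
    rphi <- cs[f, ]
    rim <- (rphi[i0 + 1L] * (1 - fr) + rphi[i1 + 1L] * fr) / pixel_size
    img <- exp(-(d - rim)^2 / (2 * psf_sigma^2))
    if (noisy) {
      off <- (f - 1L) * img_size^2
      img <- img + noise * sqrt(img + 0.01) *
        matrix(rn[(off + 1L):(off + img_size^2)], img_size)
      img[img < 0] <- 0
    }
    stack[, , f] <- img
  }
  list(stack = stack, contours = contours, center = c(cx, cy),
       pixel_size = pixel_size)
}
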