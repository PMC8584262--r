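# Flicker-noise spectroscopy of quasi-spherical vesicles: radial contour
# series, angular autocorrelation, decomposition into Legendre (average
# approach) or Fourier (statistical approach) spectra, and the bending
# rigidity fit against the Helfrich / Milner-Safran equatorial spectrum
#   <|u_lm|^2> = kBT / [ kappa (l-1)(l+2) (l(l+1) + sigma_bar) ]
# with reduced tension sigma_bar as a nuisance parameter.

#' Construct a vesicle contour series
#'
#' @param r Matrix of radial positions, frames in rows and the uniform
#'   angular grid (`n_phi` angles over `[0, 2*pi)`) in columns, in um.
#'   `NA` marks missing rays.
#' @param pixel_size Pixel size in um (NA for synthetic contours).
#' @param frame_interval Frame interval in seconds.
#' @param temperature Temperature in kelvin.
#' @return Object of class `contour_series` with the grand-mean radius `R`.
#' @export
contour_series <- function(r, pixel_size = NA_real_, frame_interval = 1,
                           temperature = 295.15) {
  r <- as.matrix(r)
  if (ncol(r) < 64L) stop("need an angular grid of at least 64 rays")
  if (any(r <= 0, na.rm = TRUE)) stop("radial positions must be positive")
  structure(list(r = r, n_phi = ncol(r), n_frames = nrow(r),
                 R = mean(r, na.rm = TRUE),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 temperature = temperature),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour_series> %d frames x %d rays, R = %.3f um, T = %.2f K\n",
              x$n_frames, x$n_phi, x$R, x$temperature))
  invisible(x)
}

#' Angular autocorrelation of a contour series
#'
#' `xi(gamma) = < (r(phi+gamma,t) - R)(r(phi,t) - R) >` averaged over the
#' angular origin and over frames, on the contour's angular lags. Computed
#' by circular FFT correlation when complete, by pairwise-complete products
#' when rays are missing.
#'
#' @param contours A `contour_series`.
#' @return Object of class `angular_autocorrelation`: `gamma` (radians),
#'   `xi` (um^2, time mean), `xi_t` (per-frame matrix), `R`, `temperature`.
#' @export
angular_autocorrelation <- function(contours) {
  stopifnot(inherits(contours, "contour_series"))
  u <- contours$r - contours$R
  n <- contours$n_phi
  nf <- contours$n_frames
  if (stats::sd(as.numeric(u), na.rm = TRUE) < 1e-12 * contours$R)
    warning("degenerate (constant) contours; autocorrelation is zero")
  xi_t <- matrix(NA_real_, nf, n)
  for (f in seq_len(nf)) {
    uf <- u[f, ]
    if (anyNA(uf)) {
      for (k in seq_len(n)) {
        prod <- uf * uf[((seq_len(n) - 1L + (k - 1L)) %% n) + 1L]
        xi_t[f, k] <- mean(prod, na.rm = TRUE)
      }
    } else {
      xi_t[f, ] <- Re(stats::fft(Mod(stats::fft(uf))^2, inverse = TRUE)) / n^2
    }
  }
  structure(list(gamma = 2 * pi * (seq_len(n) - 1L) / n,
                 xi = colMeans(xi_t, na.rm = TRUE),
                 xi_t = xi_t,
                 R = contours$R,
                 temperature = contours$temperature),
            class = "angular_autocorrelation")
}

# log |Y_lm(pi/2, 0)|^2: squared spherical harmonic at the equator.
# P_lm(0) = 2^m pi^(-1/2) cos((l+m) pi/2) Gamma((l+m+1)/2) / Gamma((l-m)/2+1)
log_equatorial_weight <- function(l, m) {
  if ((l + m) %% 2L == 1L) return(-Inf)
  logP <- m * log(2) - 0.5 * log(pi) +
    lgamma((l + m + 1) / 2) - lgamma((l - m) / 2 + 1)
  logN2 <- log(2 * l + 1) - log(4 * pi) + lgamma(l - m + 1) - lgamma(l + m + 1)
  logN2 + 2 * logP
}

#' Equatorial spherical-harmonic weight
#'
#' `w_lm = |Y_lm(pi/2, 0)|^2`, the weight with which spherical-harmonic mode
#' `(l, m)` contributes to the equatorial Fourier mode `m`
#' (`sum_m w_lm = (2l+1)/(4*pi)` by the addition theorem).
#'
#' @param l Spherical-harmonic degree(s).
#' @param m Order (scalar).
#' @return Numeric vector of weights.
#' @export
equatorial_weight <- function(l, m) {
  vapply(l, function(li) exp(log_equatorial_weight(li, m)), numeric(1L))
}

# Milner-Safran mean-square amplitude per spherical-harmonic component.
ms_mode_variance <- function(l, kappa, sigma_bar, temperature) {
  kBT(temperature) / (kappa * (l - 1) * (l + 2) * (l * (l + 1) + sigma_bar))
}

# Predicted equatorial Fourier-mode variance <|c_m|^2> including the l >= m
# mode mixing, truncated at l_max.
fourier_mode_variance <- function(m, kappa, sigma_bar, temperature, l_max) {
  ls <- seq.int(max(2L, m), l_max)
  sum(equatorial_weight(ls, m) *
        ms_mode_variance(ls, kappa, sigma_bar, temperature))
}

# Gauss-Legendre nodes and weights on [-1, 1] (Golub-Welsch).
gauss_legendre_nodes <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b; J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (2 * e$vectors[1L, ]^2)[ord])
}

# Legendre polynomial P_l(x) by the Bonnet recursion, l >= 0.
legendre_poly <- function(l, x) {
  if (l == 0L) return(rep(1, length(x)))
  if (l == 1L) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:l) {
    p <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

#' Mode spectrum from the Legendre decomposition (average approach)
#'
#' The time-averaged autocorrelation is decomposed into Legendre
#' polynomials, `B_l = (2l+1)/2 int xi(gamma) P_l(cos gamma) d cos gamma`,
#' and the per-degree mean-square amplitude follows from the equatorial
#' addition theorem: `<|u_l|^2> = 4 pi B_l / ((2l+1) R^2)`.
#'
#' @param xi An `angular_autocorrelation`.
#' @param n_modes Highest degree to compute (must not exceed half the
#'   angular grid).
#' @return Object of class `fluctuation_spectrum` with `modes`,
#'   `amplitude_mean` (dimensionless), `B_l` (um^2), `approach = "average"`.
#' @export
spectrum_average <- function(xi, n_modes = 20L) {
  stopifnot(inherits(xi, "angular_autocorrelation"))
  n <- length(xi$gamma)
  if (n_modes > n / 2) stop("n_modes exceeds half the angular grid")
  # xi is a trigonometric polynomial on the angular grid, so xi(acos x) is a
  # Chebyshev series: Gauss-Legendre quadrature of xi(acos x) P_l(x) with
  # enough nodes is exact. Fourier cosine coefficients give the evaluator.
  cf <- Re(stats::fft(xi$xi)) / n
  mmax <- floor(n / 2)
  nodes <- gauss_legendre_nodes(ceiling((mmax + n_modes) / 2) + 2L)
  gam <- acos(nodes$x)
  xi_at <- rep(cf[1L], length(gam))
  for (m in seq_len(mmax)) {
    wgt <- if (m == n / 2) 1 else 2
    xi_at <- xi_at + wgt * cf[m + 1L] * cos(m * gam)
  }
  modes <- 0:n_modes
  B <- vapply(modes, function(l) {
    (2 * l + 1) / 2 * sum(nodes$w * xi_at * legendre_poly(l, nodes$x))
  }, numeric(1L))
  amp <- 4 * pi * B / ((2 * modes + 1) * xi$R^2)
  structure(list(modes = modes, amplitude_mean = amp, B_l = B,
                 amplitude_histograms = NULL,
                 R = xi$R, temperature = xi$temperature,
                 approach = "average"),
            class = "fluctuation_spectrum")
}

# Mean of an exponential law fitted to the histogram of squared amplitudes
# (weighted log-linear fit); falls back to the raw mean for degenerate input.
exp_histogram_mean <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 50L || stats::sd(v) < 1e-15 * max(mean(v), 1e-300))
    return(list(mean = mean(v), method = "raw", hist = NULL))
  h <- graphics::hist(v, breaks = 24L, plot = FALSE)
  if (sum(h$counts > 0) < 4L)
    return(list(mean = mean(v), method = "raw", hist = h))
  # Poisson regression of bin counts on bin centers: the histogram-based
  # maximum-likelihood fit of the exponential law, robust to sparse bins
  fit <- tryCatch(
    stats::glm(h$counts ~ h$mids, family = stats::poisson()),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit)) return(list(mean = mean(v), method = "raw", hist = h))
  slope <- stats::coef(fit)[[2L]]
  if (!is.finite(slope) || slope >= 0)
    return(list(mean = mean(v), method = "raw", hist = h))
  list(mean = -1 / slope, method = "exponential fit", hist = h)
}

#' Mode spectrum from per-frame Fourier amplitudes (statistical approach)
#'
#' Each frame's relative contour `(r - R)/R` is decomposed into a Fourier
#' series; per mode, the frequency histogram of squared amplitudes is fitted
#' with the equilibrium exponential law and the fitted mean is reported as
#' the mode's mean-square amplitude (falling back to the raw mean, with a
#' warning, below 50 frames or for degenerate histograms).
#'
#' @param contours A `contour_series`.
#' @param n_modes Highest Fourier mode to report.
#' @return Object of class `fluctuation_spectrum` with `modes`,
#'   `amplitude_mean` (`<|c_m|^2>`, dimensionless), `amplitude_histograms`,
#'   `approach = "statistical"`.
#' @export
spectrum_statistical <- function(contours, n_modes = 20L) {
  stopifnot(inherits(contours, "contour_series"))
  n <- contours$n_phi
  if (n_modes > n / 2) stop("n_modes exceeds half the angular grid")
  if (contours$n_frames < 50L)
    warning("fewer than 50 frames; using raw means instead of histogram fits")
  u <- (contours$r - contours$R) / contours$R
  # per-frame Fourier coefficients c_m = mean_j u_j exp(-i m phi_j)
  amp2 <- matrix(NA_real_, contours$n_frames, n_modes)
  for (f in seq_len(contours$n_frames)) {
    uf <- u[f, ]
    if (anyNA(uf)) uf[is.na(uf)] <- mean(uf, na.rm = TRUE)
    cf <- stats::fft(uf) / n
    amp2[f, ] <- Mod(cf[2:(n_modes + 1L)])^2
  }
  fits <- lapply(seq_len(n_modes), function(m) exp_histogram_mean(amp2[, m]))
  structure(list(modes = seq_len(n_modes),
                 amplitude_mean = vapply(fits, `[[`, 1, "mean"),
                 estimator = vapply(fits, `[[`, "", "method"),
                 amplitude_histograms = lapply(fits, `[[`, "hist"),
                 amplitude_samples = amp2,
                 R = contours$R, temperature = contours$temperature,
                 approach = "statistical"),
            class = "fluctuation_spectrum")
}

#' @export
print.fluctuation_spectrum <- function(x, ...) {
  cat("<fluctuation_spectrum>", x$approach, "approach, modes",
      min(x$modes), "..", max(x$modes), "\n")
  invisible(x)
}

#' Bending rigidity from a fluctuation spectrum
#'
#' Least-squares fit (in log amplitude) of the Milner-Safran spectrum over
#' `mode_range`, with the bending rigidity kappa and the reduced tension
#' sigma_bar as parameters. For an `average` spectrum the per-degree model
#' is used directly; for a `statistical` spectrum the model is the
#' equatorial Fourier variance including the spherical-harmonic mode mixing
#' `<|c_m|^2> = sum_{l>=m} w_lm <|u_l|^2>`.
#'
#' @param spectrum A `fluctuation_spectrum`.
#' @param R Vesicle radius (um); defaults to the spectrum's.
#' @param temperature Temperature (K); defaults to the spectrum's.
#' @param mode_range Integer pair, default `c(3, 20)` (modes 0--2 are
#'   size/translation/tension dominated, high modes noise dominated).
#' @param l_max_sum Truncation of the mode-mixing sum for the statistical
#'   model; default `max(mode_range) + 12`.
#' @return Object of class `rigidity_fit`: `kappa` (J), `kappa_se`,
#'   `sigma_bar`, `mode_range`, `approach`, `residuals`.
#' @export
fit_bending_rigidity <- function(spectrum, R = NULL, temperature = NULL,
                                 mode_range = c(3L, 20L), l_max_sum = NULL) {
  stopifnot(inherits(spectrum, "fluctuation_spectrum"))
  if (is.null(temperature)) temperature <- spectrum$temperature
  if (is.null(l_max_sum)) l_max_sum <- max(mode_range) + 12L
  sel <- spectrum$modes >= mode_range[1L] & spectrum$modes <= mode_range[2L]
  modes <- spectrum$modes[sel]
  if (length(modes) < 4L) stop("need at least 4 modes inside mode_range")
  obs <- spectrum$amplitude_mean[sel]
  if (any(obs <= 0))
    stop("non-positive mode amplitudes inside mode_range")

  shape <- function(sigma_bar) {
    # model amplitude for kappa = kBT (so model = shape / (kappa/kBT))
    if (spectrum$approach == "statistical")
      vapply(modes, fourier_mode_variance, numeric(1L),
             kappa = kBT(temperature), sigma_bar = sigma_bar,
             temperature = temperature, l_max = l_max_sum)
    else
      ms_mode_variance(modes, kBT(temperature), sigma_bar, temperature)
  }
  objective <- function(sigma_bar) {
    s <- log(shape(sigma_bar))
    resid <- log(obs) - s
    sum((resid - mean(resid))^2)   # kappa profiled out (log offset)
  }
  lmin <- mode_range[1L]
  lower <- -(lmin * (lmin + 1)) + 1e-6
  opt <- stats::optim(10, objective, method = "Brent",
                      lower = lower, upper = 1e6)
  sigma_bar <- opt$par
  s <- log(shape(sigma_bar))
  log_kappa <- mean(s - log(obs)) + log(kBT(temperature))
  kappa <- exp(log_kappa)
  resid <- log(obs) - (s + log(kBT(temperature)) - log_kappa)
  se <- kappa * stats::sd(resid) / sqrt(length(resid))
  if (!is.finite(kappa) || kappa <= 0)
    stop("non-positive fitted bending rigidity; residuals: ",
         paste(signif(resid, 3), collapse = ", "))
  structure(list(kappa = with_unit(kappa, "J"), kappa_se = se,
                 sigma_bar = sigma_bar, mode_range = mode_range,
                 approach = spectrum$approach, residuals = resid,
                 temperature = temperature),
            class = "rigidity_fit")
}

#' @export
print.rigidity_fit <- function(x, ...) {
  cat(sprintf(
    "<rigidity_fit> kappa = %.3e +/- %.1e J, sigma_bar = %.2f (%s, modes %d..%d)\n",
    x$kappa, x$kappa_se, x$sigma_bar, x$approach,
    x$mode_range[1L], x$mode_range[2L]))
  invisible(x)
}

# Bilinear interpolation of image `img` (matrix, x = rows) at points (x, y).
bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 1), nx - 1e-9)
  y <- pmin(pmax(y, 1), ny - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

#' Extract vesicle contours from an image stack
#'
#' Per frame the vesicle center is refined iteratively as the centroid of
#' the detected rim; along each of `n_phi` rays the rim is located at the
#' maximum of the radial intensity profile with three-point parabolic
#' subpixel refinement. Rays without a detectable rim are marked missing;
#' frames with more than 10 percent missing rays are dropped.
#'
#' @param stack 3D array `nx x ny x n_frames` of grayscale intensities (or a
#'   matrix for a single frame).
#' @param pixel_size Pixel size in um.
#' @param center_guess Initial center `c(x, y)` in pixel coordinates;
#'   default the intensity-weighted image centroid.
#' @param n_phi Number of rays (default 180).
#' @param frame_interval Frame interval in seconds.
#' @param temperature Temperature in kelvin.
#' @param radial_step Radial sampling step in pixels.
#' @param min_peak_frac Rim peaks below this fraction of the frame maximum
#'   are treated as missing.
#' @return A `contour_series` (r in um); dropped frames are reported in the
#'   `dropped_frames` attribute.
#' @export
extract_contour <- function(stack, pixel_size, center_guess = NULL,
                            n_phi = 180L, frame_interval = 1,
                            temperature = 295.15, radial_step = 0.5,
                            min_peak_frac = 0.2) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L, pixel_size > 0)
  nx <- dim(stack)[1L]; ny <- dim(stack)[2L]; nf <- dim(stack)[3L]
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  cosphi <- cos(phi); sinphi <- sin(phi)

  rows <- list(); dropped <- integer(0)
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    if (is.null(center_guess)) {
      w <- img - min(img)
      cx <- sum(row(img) * w) / sum(w); cy <- sum(col(img) * w) / sum(w)
    } else { cx <- center_guess[1L]; cy <- center_guess[2L] }
    imax <- max(img)
    r_px <- rep(NA_real_, n_phi)
    for (it in 1:30) {
      # radial window up to the nearest image border from the current center
      rho_max <- min(cx - 1, nx - cx, cy - 1, ny - cy) - 1
      if (rho_max < 4) break
      rho <- seq(2, rho_max, by = radial_step)
      X <- outer(cosphi, rho) + cx
      Y <- outer(sinphi, rho) + cy
      I <- matrix(bilinear(img, as.numeric(X), as.numeric(Y)), n_phi)
      pk <- max.col(I, ties.method = "first")
      val <- I[cbind(seq_len(n_phi), pk)]
      good <- pk > 1L & pk < length(rho) & val >= min_peak_frac * imax
      r_px <- rep(NA_real_, n_phi)
      if (any(good)) {
        g <- which(good)
        ia <- cbind(g, pk[g] - 1L); ib <- cbind(g, pk[g]); ic <- cbind(g, pk[g] + 1L)
        denom <- I[ia] - 2 * I[ib] + I[ic]
        delta <- ifelse(abs(denom) > 1e-12, 0.5 * (I[ia] - I[ic]) / denom, 0)
        delta <- pmin(pmax(delta, -1), 1)
        r_px[g] <- rho[pk[g]] + delta * radial_step
      }
      if (sum(good) < 3L) break
      # least-squares circle center through the detected rim points; robust
      # to rays lost on one side, unlike a plain rim centroid
      g <- which(good)
      rx <- cx + r_px[g] * cosphi[g]; ry <- cy + r_px[g] * sinphi[g]
      A <- cbind(2 * rx, 2 * ry, 1)
      sol <- stats::lm.fit(A, rx^2 + ry^2)$coefficients
      ncx <- sol[[1L]]; ncy <- sol[[2L]]
      shift <- sqrt((ncx - cx)^2 + (ncy - cy)^2)
      cx <- ncx; cy <- ncy
      if (shift < 0.01) break
    }
    if (mean(is.na(r_px)) > 0.1) {
      dropped <- c(dropped, f)
    } else {
      rows[[length(rows) + 1L]] <- r_px * pixel_size
    }
  }
  if (length(rows) == 0L) stop("no frame yielded a usable contour")
  if (length(dropped) > 0L)
    message("dropped ", length(dropped), " frame(s) with > 10% missing rays")
  cs <- contour_series(do.call(rbind, rows), pixel_size = pixel_size,
                       frame_interval = frame_interval,
                       temperature = temperature)
  attr(cs, "dropped_frames") <- dropped
  cs
}
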