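# Real-space fluctuation (RSF) mechanics: tilt and splay statistics pooled
# over lipids and frames, potential-of-mean-force (PMF) fits for the tilt
# modulus and bending rigidity, and the thickness-fluctuation route to the
# area compressibility coefficient.

#' Pool lipid tilt and splay samples from a frame series
#'
#' The lipid director is the unit vector from the tail point (midpoint of
#' terminal chain carbons) to the head point (midpoint of P and C2); tilt is
#' its angle to the leaflet normal (+z upper leaflet, -z lower). Neighbor
#' pairs come from the periodic xy Voronoi adjacency of head points within a
#' leaflet; the splay of a pair is the in-plane finite-difference divergence
#' `((d_j - d_i)_xy . e_ij) / |r_ij|` of the unit directors along the
#' inter-head axis. Pairs are accepted only when weakly correlated: head
#' separation within `d_range` and director angle below `max_angle`.
#'
#' @param fs A `frame_series`.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set`.
#' @param d_range Accepted head-point separation (angstrom), default 5--12.
#' @param max_angle Maximum angle between pair directors (degrees), default 60.
#' @param refs Optional precomputed [reference_points()].
#' @return Object of class `tilt_splay_samples`: `tilts` (radians), `splays`
#'   (1/angstrom), `pair_filter_log` (accepted / rejected counts).
#' @export
tilt_splay_samples <- function(fs, leaflets, topology,
                               d_range = c(5, 12), max_angle = 60,
                               refs = NULL) {
  if (is.null(refs)) refs <- reference_points(fs, topology)
  nf <- n_frames(fs)
  tilts <- list(); splays <- list()
  acc <- 0L; rej_d <- 0L; rej_a <- 0L
  cos_max <- cos(max_angle * pi / 180)

  for (side in c("upper", "lower")) {
    sgn <- if (side == "upper") 1 else -1
    idx <- match(leaflets$lipid_id[leaflets$leaflet == side], refs$lipid_id)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    for (f in seq_len(nf)) {
      d3 <- refs$head[idx, , f, drop = FALSE][, , 1L] -
            refs$tail[idx, , f, drop = FALSE][, , 1L]
      if (length(idx) == 1L) d3 <- matrix(d3, 1L, 3L)
      # head and tail points are stored wrapped; take the local difference
      for (d in 1:3) d3[, d] <- min_image(d3[, d], fs$box[f, d])
      len <- sqrt(rowSums(d3 * d3))
      if (any(len < 1e-9))
        stop("zero-length director for lipid ",
             refs$lipid_id[idx[which(len < 1e-9)[1L]]])
      u <- d3 / len                       # unit director, tail -> head
      tilts[[length(tilts) + 1L]] <- acos(pmin(1, pmax(-1, sgn * u[, 3L])))

      if (length(idx) >= 2L) {
        Lx <- fs$box[f, 1L]; Ly <- fs$box[f, 2L]
        heads <- refs$head[idx, 1:2, f, drop = FALSE][, , 1L]
        vor <- voronoi_periodic(heads, Lx, Ly)
        pairs <- voronoi_pairs(vor)
        if (nrow(pairs) > 0L) {
          ex <- min_image(heads[pairs[, 2L], 1L] - heads[pairs[, 1L], 1L], Lx)
          ey <- min_image(heads[pairs[, 2L], 2L] - heads[pairs[, 1L], 2L], Ly)
          d <- sqrt(ex^2 + ey^2)
          cosd <- rowSums(u[pairs[, 1L], , drop = FALSE] *
                          u[pairs[, 2L], , drop = FALSE])
          ok_d <- d >= d_range[1L] & d <= d_range[2L]
          ok_a <- cosd > cos_max
          keep <- ok_d & ok_a
          rej_d <- rej_d + sum(!ok_d)
          rej_a <- rej_a + sum(ok_d & !ok_a)
          acc <- acc + sum(keep)
          if (any(keep)) {
            i <- pairs[keep, 1L]; j <- pairs[keep, 2L]
            # leaflet-normal-aligned directors make the two leaflets symmetric
            v <- sgn * u
            s <- ((v[j, 1L] - v[i, 1L]) * ex[keep] +
                  (v[j, 2L] - v[i, 2L]) * ey[keep]) / d[keep]^2
            splays[[length(splays) + 1L]] <- s
          }
        }
      }
    }
  }
  structure(list(
    tilts = unlist(tilts),
    splays = if (length(splays) > 0L) unlist(splays) else numeric(0),
    pair_filter_log = c(accepted = acc, rejected_distance = rej_d,
                        rejected_angle = rej_a)
  ), class = "tilt_splay_samples")
}

#' @export
print.tilt_splay_samples <- function(x, ...) {
  cat("<tilt_splay_samples>", length(x$tilts), "tilts,",
      length(x$splays), "splays\n")
  cat("  pair filter:", paste(names(x$pair_filter_log),
                              x$pair_filter_log, collapse = ", "), "\n")
  invisible(x)
}

# Histogram-estimated PMF: -prefactor * log(density / jacobian), shifted to
# its minimum, returned on populated bin centers.
pmf_from_samples <- function(x, prefactor, jacobian = NULL, n_bins = NULL) {
  n <- length(x)
  if (is.null(n_bins)) n_bins <- max(30L, min(120L, floor(sqrt(n) / 2)))
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  dens <- h$density
  mids <- h$mids
  keep <- dens > 0
  dens <- dens[keep]; mids <- mids[keep]
  if (!is.null(jacobian)) dens <- dens / jacobian(mids)
  pmf <- -prefactor * log(dens)
  pmf <- pmf - min(pmf)
  data.frame(x = mids, pmf = pmf)
}

# Quadratic PMF fit on the bins within `cut` prefactor-units of the minimum.
# Returns the x^2 coefficient, its standard error, the fitted curve and the
# fit range; errors out if fewer than `min_bins` bins are available.
pmf_quadratic_fit <- function(pmf_df, prefactor, cut = 2, min_bins = 5L,
                              center = TRUE) {
  sel <- pmf_df$pmf <= cut * prefactor
  if (sum(sel) < min_bins)
    stop("fewer than ", min_bins, " populated PMF bins in the fit range")
  d <- pmf_df[sel, ]
  fit <- if (center) stats::lm(pmf ~ x + I(x^2), data = d)
         else stats::lm(pmf ~ I(x^2), data = d)
  co <- summary(fit)$coefficients
  a <- co["I(x^2)", "Estimate"]
  se <- co["I(x^2)", "Std. Error"]
  list(a = a, se = se, fit_range = range(d$x), n_bins = sum(sel),
       linear = if (center) co["x", "Estimate"] else 0,
      data = d)
}

#' Tilt modulus from the tilt-angle PMF
#'
#' The PMF is estimated as `-kBT log(p(theta)/sin(theta))` (the solid-angle
#' Jacobian is removed so the small-angle form is quadratic) and fitted with
#' `PMF = 1/2 kt theta^2 + c` on the bins within 2 kBT of the minimum.
#'
#' @param samples A `tilt_splay_samples` object or a numeric vector of tilt
#'   angles (radians); at least 1000 samples.
#' @param temperature Temperature in kelvin.
#' @return Object of class `modulus_result` with `value` (J), `uncertainty`
#'   (J, fit standard error), `pmf_curve`, `fit_range`.
#' @export
fit_tilt_modulus <- function(samples, temperature = 303.15) {
  th <- if (inherits(samples, "tilt_splay_samples")) samples$tilts
        else as.numeric(samples)
  if (length(th) < 1000L) stop("need >= 1000 tilt samples")
  kT <- kBT(temperature)
  pmf <- pmf_from_samples(th, prefactor = kT, jacobian = sin)
  qf <- pmf_quadratic_fit(pmf, prefactor = kT, center = FALSE)
  if (qf$a <= 0)
    stop("tilt PMF is not convex on the fit range; inspect pmf_curve")
  structure(list(
    value = with_unit(2 * qf$a, "J"),
    uncertainty = 2 * qf$se,
    pmf_curve = transform(pmf, pmf_kBT = pmf / kT),
    fit_range = qf$fit_range,
    kind = "tilt_modulus"
  ), class = "modulus_result")
}

#' Bending rigidity from the splay PMF (real-space fluctuation method)
#'
#' The splay PMF `-kBT log p(S)` is fitted with `1/2 chi S^2 + c`; the
#' quadratic coefficient `chi` (J angstrom^2) is the pairwise splay modulus.
#' Normalizing by the area per lipid gives the monolayer bending modulus
#' `kappa_m = chi / apl`, and the bilayer value is `kappa = 2 kappa_m`.
#'
#' @param samples A `tilt_splay_samples` object or numeric vector of splay
#'   values (1/angstrom); at least 1000 samples.
#' @param temperature Temperature in kelvin.
#' @param apl Area per lipid in angstrom^2 used for the normalization.
#' @return Object of class `modulus_result` with `value` the bilayer bending
#'   rigidity (J), `uncertainty`, `pmf_curve`, `fit_range`, and
#'   `chi` (J angstrom^2).
#' @export
fit_bending_rigidity_rsf <- function(samples, temperature = 303.15,
                                     apl = 60.7) {
  S <- if (inherits(samples, "tilt_splay_samples")) samples$splays
       else as.numeric(samples)
  if (length(S) < 1000L) stop("need >= 1000 splay samples")
  stopifnot(apl > 0)
  kT <- kBT(temperature)
  pmf <- pmf_from_samples(S, prefactor = kT)
  qf <- pmf_quadratic_fit(pmf, prefactor = kT, center = TRUE)
  if (qf$a <= 0)
    stop("splay PMF is not convex on the fit range; inspect pmf_curve")
  chi <- 2 * qf$a                         # J A^2
  structure(list(
    value = with_unit(2 * chi / apl, "J"),
    uncertainty = 2 * 2 * qf$se / apl,
    chi = with_unit(chi, "J A^2"),
    linear_term = qf$linear,
    pmf_curve = transform(pmf, pmf_kBT = pmf / kT),
    fit_range = qf$fit_range,
    kind = "bending_rigidity_rsf"
  ), class = "modulus_result")
}

#' @export
print.modulus_result <- function(x, ...) {
  cat(sprintf("<modulus_result> %s = %.3e +/- %.1e J\n", x$kind,
              x$value, x$uncertainty))
  invisible(x)
}

#' Construct a thickness-fluctuation series
#'
#' @param t Instantaneous membrane thickness per frame (nm).
#' @param t0 Equilibrium thickness (nm); defaults to `mean(t)`.
#' @param a0 Area per lipid (angstrom^2).
#' @param temperature Temperature in kelvin.
#' @return Object of class `thickness_fluctuation_series`.
#' @export
thickness_fluctuation_series <- function(t, t0 = NULL, a0 = 60.7,
                                         temperature = 303.15) {
  t <- as.numeric(t)
  stopifnot(all(t > 0), a0 > 0, temperature > 0)
  if (is.null(t0)) t0 <- mean(t)
  structure(list(t = t, t0 = t0, a0 = a0, temperature = temperature),
            class = "thickness_fluctuation_series")
}

#' Area compressibility from thickness fluctuations
#'
#' The relative thickness deviation `x = (t0 - t)/t0` is histogrammed and
#' its potential of mean force `PMF(x) = -(2 kBT / a0) log p(x)` is fitted
#' with the quadratic `K_A x^2 + C'` over the central bins; `K_A` is
#' converted from J/angstrom^2 to mN/m. The method probes whole-membrane
#' compressibility; per-leaflet readings are a historical convention and the
#' result metadata records the whole-membrane interpretation.
#'
#' @param series A `thickness_fluctuation_series` (at least 500 samples).
#' @return Object of class `ka_result`: `KA` (mN/m), `KA_se`, `offset`
#'   (C', J/angstrom^2), `pmf_points`, `fit_range`, `convention`.
#' @export
area_compressibility <- function(series) {
  stopifnot(inherits(series, "thickness_fluctuation_series"))
  t <- series$t
  if (length(t) < 500L) stop("need >= 500 thickness samples")
  if (stats::sd(t) < 1e-12 * series$t0)
    stop("degenerate thickness distribution (constant series)")
  x <- (series$t0 - t) / series$t0
  kT <- kBT(series$temperature)
  pref <- 2 * kT / series$a0              # J / A^2
  pmf <- pmf_from_samples(x, prefactor = pref)
  sel <- pmf$pmf <= 2 * pref
  if (sum(sel) < 5L) stop("fewer than 5 populated bins in fit range")
  d <- pmf[sel, ]
  fit <- stats::lm(pmf ~ x + I(x^2), data = d)
  co <- summary(fit)$coefficients
  ka_JA2 <- co["I(x^2)", "Estimate"]
  if (ka_JA2 <= 0) stop("thickness PMF is not convex on the fit range")
  conv <- phys_const$J_per_A2_to_mN_per_m
  structure(list(
    KA = with_unit(ka_JA2 * conv, "mN/m"),
    KA_se = co["I(x^2)", "Std. Error"] * conv,
    offset = co["(Intercept)", "Estimate"],
    pmf_points = d,
    fit_range = range(d$x),
    convention = "whole membrane"
  ), class = "ka_result")
}

#' @export
print.ka_result <- function(x, ...) {
  cat(sprintf("<ka_result> K_A = %.1f +/- %.1f mN/m (%s)\n",
              x$KA, x$KA_se, x$convention))
  invisible(x)
}
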