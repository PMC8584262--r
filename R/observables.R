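#' Area per lipid by periodic Voronoi tessellation
#'
#' For every frame and leaflet the lipid head points are projected onto the
#' xy plane and tessellated with periodic images; each lipid is assigned its
#' Voronoi cell area. The system value is the mean of a Gaussian fitted by
#' least squares to the histogram of all per-lipid areas (Freedman-Diaconis
#' binning); per-species values are arithmetic means. Per frame and leaflet
#' the cell areas must sum to the box cross-section (relative error < 1e-6),
#' which is asserted.
#'
#' @param fs A `frame_series`.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set`.
#' @param refs Optional precomputed [reference_points()].
#' @return Object of class `apl_result`: `system_apl` (angstrom^2),
#'   `system_apl_se` (Gaussian-fit standard error of the mean),
#'   `per_species` (data frame: species, mean, sd, n), `per_lipid_areas`
#'   (pooled vector), `fit` ("gaussian" or "moment fallback").
#' @export
area_per_lipid <- function(fs, leaflets, topology, refs = NULL) {
  if (is.null(refs)) refs <- reference_points(fs, topology)
  nf <- n_frames(fs)
  stopifnot(nf >= 1L)
  areas_all <- NULL
  species_all <- NULL
  for (side in c("upper", "lower")) {
    sel <- which(leaflets$leaflet == side &
                   leaflets$lipid_id %in% refs$lipid_id)
    idx <- match(leaflets$lipid_id[sel], refs$lipid_id)
    if (length(idx) < 3L)
      stop("need >= 3 lipids per leaflet for tessellation (", side, ")")
    for (f in seq_len(nf)) {
      Lx <- fs$box[f, 1L]; Ly <- fs$box[f, 2L]
      xy <- refs$head[idx, 1:2, f, drop = FALSE][, , 1L]
      vor <- tryCatch(voronoi_periodic(xy, Lx, Ly), error = function(e) {
        # duplicate/collinear seeds: jitter once and retry
        xy2 <- xy + matrix(stats::runif(length(xy), -1e-4, 1e-4), ncol = 2L)
        voronoi_periodic(xy2, Lx, Ly)
      })
      rel_err <- abs(sum(vor$areas) - Lx * Ly) / (Lx * Ly)
      if (rel_err > 1e-6)
        stop("Voronoi areas do not tile the box (relative error ",
             signif(rel_err, 3), ")")
      areas_all <- c(areas_all, vor$areas)
      species_all <- c(species_all, refs$species[idx])
    }
  }

  gf <- fit_gaussian_hist(areas_all)
  per_species <- do.call(rbind, lapply(split(areas_all, species_all),
    function(a) data.frame(mean = mean(a), sd = stats::sd(a), n = length(a))))
  per_species <- data.frame(species = rownames(per_species), per_species,
                            row.names = NULL)
  structure(list(
    system_apl = with_unit(gf$mean, "A^2"),
    system_apl_se = gf$se_mean,
    per_species = per_species,
    per_lipid_areas = areas_all,
    fit = gf$method
  ), class = "apl_result")
}

#' @export
print.apl_result <- function(x, ...) {
  cat(sprintf("<apl_result> system APL = %.2f +/- %.2f A^2 (%s fit)\n",
              x$system_apl, x$system_apl_se, x$fit))
  print(x$per_species)
  invisible(x)
}

# Least-squares Gaussian fit to a Freedman-Diaconis histogram of `values`.
# Falls back (with a warning) to the sample mean when the fit fails.
fit_gaussian_hist <- function(values) {
  if (length(values) < 10L || stats::sd(values) < 1e-9 * max(abs(values), 1)) {
    warning("too few or degenerate values for a histogram fit; ",
            "reporting the sample mean")
    s <- if (length(values) > 1L) stats::sd(values) else 0
    return(list(mean = mean(values), se_mean = s / sqrt(length(values)),
                sd = s, method = "moment fallback"))
  }
  bw <- 2 * stats::IQR(values) / length(values)^(1 / 3)
  if (bw <= 0) bw <- diff(range(values)) / 30
  breaks <- seq(min(values) - bw, max(values) + bw, by = bw)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  df <- df[df$y > 0, ]
  start <- list(A = max(df$y), mu = mean(values), s = stats::sd(values))
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
               start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian histogram fit did not converge; ",
            "falling back to sample mean +/- sd")
    return(list(mean = mean(values),
                se_mean = stats::sd(values) / sqrt(length(values)),
                sd = stats::sd(values), method = "moment fallback"))
  }
  cf <- summary(fit)$coefficients
  list(mean = cf["mu", "Estimate"], se_mean = cf["mu", "Std. Error"],
       sd = abs(cf["s", "Estimate"]), method = "gaussian")
}

#' Membrane thickness from leaflet atom planes
#'
#' Thickness is the difference between the mean z of the chosen reference
#' atoms (P, C1 or C2, with the sterol surrogate names taken from each
#' species' topology) in the upper and the lower leaflet, evaluated per
#' frame and averaged.
#'
#' @param fs A `frame_series`.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set`.
#' @param atom_tag One of `"P"`, `"C1"`, `"C2"`.
#' @return Object of class `mt_result`: `thickness` (nm, mean over frames),
#'   `sd` (nm), `per_frame` (nm), `atom_tag`.
#' @export
membrane_thickness <- function(fs, leaflets, topology,
                               atom_tag = c("P", "C1", "C2")) {
  atom_tag <- match.arg(atom_tag)
  at <- fs$atoms
  keep <- logical(nrow(at))
  for (sp in unique(at$species)) {
    nm <- topology[[sp]]$thickness_atoms
    if (!(atom_tag %in% names(nm)))
      stop("species '", sp, "' declares no atom for thickness tag '",
           atom_tag, "'")
    keep <- keep | (at$species == sp & at$atom_name == nm[[atom_tag]])
  }
  side <- leaflets$leaflet[match(at$lipid_id, leaflets$lipid_id)]
  iu <- which(keep & side == "upper")
  il <- which(keep & side == "lower")
  if (length(iu) == 0L || length(il) == 0L)
    stop("no '", atom_tag, "' atoms found in one of the leaflets")
  per_frame <- vapply(seq_len(n_frames(fs)), function(f) {
    (mean(fs$coords[iu, 3L, f]) - mean(fs$coords[il, 3L, f])) / 10  # A -> nm
  }, numeric(1L))
  structure(list(
    thickness = with_unit(mean(per_frame), "nm"),
    sd = stats::sd(per_frame),
    per_frame = per_frame,
    atom_tag = paste0("MT_", atom_tag, "-", atom_tag)
  ), class = "mt_result")
}

#' @export
print.mt_result <- function(x, ...) {
  cat(sprintf("<mt_result> %s = %.3f +/- %.3f nm\n", x$atom_tag,
              x$thickness, if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Lateral diffusion coefficient from the Einstein relation
#'
#' Head-point trajectories are unwrapped across the periodic boundaries,
#' the center-of-mass motion of each leaflet is subtracted, and the 2D mean
#' square displacement averaged over lipids and time origins is fitted with
#' a straight line over the given lag window; D = slope/4.
#'
#' @param fs A `frame_series` with at least 20 frames.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set`.
#' @param species Species to analyze, or `NULL` for all lipids.
#' @param fit_window Lag window as a fraction pair of the maximum lag
#'   (default 10--50 percent).
#' @param refs Optional precomputed [reference_points()].
#' @return Object of class `diffusion_result`: `D` (um^2/s), `D_se` (fit
#'   standard error), `msd` (data frame lag_ns, msd_A2), `fit_window`
#'   (lag indices used).
#' @export
lateral_diffusion <- function(fs, leaflets, topology, species = NULL,
                              fit_window = c(0.1, 0.5), refs = NULL) {
  nf <- n_frames(fs)
  if (nf < 20L) stop("need >= 20 frames for a diffusion estimate")
  stopifnot(length(fit_window) == 2L, fit_window[1L] < fit_window[2L],
            fit_window[1L] >= 0, fit_window[2L] <= 1)
  if (is.null(refs)) refs <- reference_points(fs, topology)
  nl <- length(refs$lipid_id)

  # unwrap xy tracks: nf x nl matrices
  X <- t(refs$head[, 1L, , drop = FALSE][, 1L, ])
  Y <- t(refs$head[, 2L, , drop = FALSE][, 1L, ])
  if (nl == 1L) { X <- matrix(refs$head[1L, 1L, ], ncol = 1L)
                  Y <- matrix(refs$head[1L, 2L, ], ncol = 1L) }
  for (f in 2:nf) {
    X[f, ] <- X[f - 1L, ] + min_image(X[f, ] - X[f - 1L, ], fs$box[f, 1L])
    Y[f, ] <- Y[f - 1L, ] + min_image(Y[f, ] - Y[f - 1L, ], fs$box[f, 2L])
  }
  # per-leaflet center-of-mass subtraction
  side <- leaflets$leaflet[match(refs$lipid_id, leaflets$lipid_id)]
  for (s in levels(side)) {
    cols <- which(side == s)
    if (length(cols) > 0L) {
      comx <- rowMeans(X[, cols, drop = FALSE])
      comy <- rowMeans(Y[, cols, drop = FALSE])
      X[, cols] <- X[, cols] - comx
      Y[, cols] <- Y[, cols] - comy
    }
  }
  if (!is.null(species)) {
    cols <- which(refs$species == species)
    if (length(cols) == 0L) stop("species '", species, "' not present")
    X <- X[, cols, drop = FALSE]; Y <- Y[, cols, drop = FALSE]
  }

  max_lag <- nf - 1L
  msd <- vapply(seq_len(max_lag), function(lag) {
    dX <- X[(1L + lag):nf, , drop = FALSE] - X[1L:(nf - lag), , drop = FALSE]
    dY <- Y[(1L + lag):nf, , drop = FALSE] - Y[1L:(nf - lag), , drop = FALSE]
    mean(dX * dX + dY * dY)
  }, numeric(1L))
  lags_ns <- seq_len(max_lag) * fs$dt

  i1 <- max(1L, ceiling(fit_window[1L] * max_lag))
  i2 <- floor(fit_window[2L] * max_lag)
  if (i2 <= i1) stop("fit window outside available lags")
  fit <- stats::lm(msd[i1:i2] ~ lags_ns[i1:i2])
  slope <- stats::coef(fit)[[2L]]                       # A^2 / ns
  se <- summary(fit)$coefficients[2L, 2L]
  conv <- phys_const$A2_per_ns_to_um2_per_s / 4
  structure(list(
    D = with_unit(slope * conv, "um^2/s"),
    D_se = se * conv,
    msd = data.frame(lag_ns = lags_ns, msd_A2 = msd),
    fit_window = c(i1, i2)
  ), class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> D = %.3f +/- %.3f um^2/s (lags %d..%d)\n",
              x$D, x$D_se, x$fit_window[1L], x$fit_window[2L]))
  invisible(x)
}

#' Leaflet interdigitation from mass-density overlap
#'
#' Per frame, mass-density profiles of the two leaflets are accumulated
#' along z and the interdigitation width is the integral of
#' `4*rho_u*rho_l / (rho_u + rho_l)^2` over z: the width of the region of
#' mass overlap (it equals L for identical rectangular profiles of support
#' L and 0 for disjoint profiles).
#'
#' @param fs A `frame_series`.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set` (atomic masses are taken from it).
#' @param n_bins Number of z bins over the box height (default 100).
#' @return Object of class `interdigitation_result`: `width` (angstrom,
#'   mean over frames), `sd`, `per_frame`, `profiles` (z, rho_upper,
#'   rho_lower of the last frame, amu/A^3).
#' @export
interdigitation <- function(fs, leaflets, topology, n_bins = 100L) {
  at <- fs$atoms
  mass <- numeric(nrow(at))
  for (sp in unique(at$species)) {
    rows <- at$species == sp
    mass[rows] <- topology[[sp]]$masses[at$atom_name[rows]]
  }
  side <- leaflets$leaflet[match(at$lipid_id, leaflets$lipid_id)]
  iu <- which(side == "upper"); il <- which(side == "lower")
  if (length(iu) == 0L || length(il) == 0L) stop("empty leaflet")
  per_frame <- numeric(n_frames(fs))
  prof <- NULL
  for (f in seq_len(n_frames(fs))) {
    Lz <- fs$box[f, 3L]
    edges <- seq(0, Lz, length.out = n_bins + 1L)
    dz <- edges[2L] - edges[1L]
    vol <- fs$box[f, 1L] * fs$box[f, 2L] * dz
    zu <- fs$coords[iu, 3L, f]; zl <- fs$coords[il, 3L, f]
    bu <- pmin(pmax(findInterval(zu, edges, rightmost.closed = TRUE), 1L), n_bins)
    bl <- pmin(pmax(findInterval(zl, edges, rightmost.closed = TRUE), 1L), n_bins)
    rho_u <- as.numeric(tapply(mass[iu], factor(bu, levels = seq_len(n_bins)),
                               sum, default = 0)) / vol
    rho_l <- as.numeric(tapply(mass[il], factor(bl, levels = seq_len(n_bins)),
                               sum, default = 0)) / vol
    z_mid <- (edges[-1L] + edges[-length(edges)]) / 2
    per_frame[f] <- density_overlap_width(z_mid, rho_u, rho_l)
    prof <- data.frame(z = z_mid, rho_upper = rho_u, rho_lower = rho_l)
  }
  structure(list(
    width = with_unit(mean(per_frame), "A"),
    sd = stats::sd(per_frame),
    per_frame = per_frame,
    profiles = prof
  ), class = "interdigitation_result")
}

#' Overlap width of two density profiles
#'
#' Trapezoidal integral of `4*rho_u*rho_l/(rho_u+rho_l)^2` over z, with the
#' integrand defined as zero where both densities vanish.
#'
#' @param z Grid positions (angstrom), equally or unequally spaced.
#' @param rho_u,rho_l Non-negative densities on `z`.
#' @return Overlap width in the units of `z`.
#' @export
density_overlap_width <- function(z, rho_u, rho_l) {
  stopifnot(length(z) == length(rho_u), length(z) == length(rho_l))
  s <- rho_u + rho_l
  integrand <- ifelse(s > 0, 4 * rho_u * rho_l / s^2, 0)
  sum(diff(z) * (integrand[-1L] + integrand[-length(integrand)]) / 2)
}

#' @export
print.interdigitation_result <- function(x, ...) {
  cat(sprintf("<interdigitation_result> width = %.2f +/- %.2f A\n",
              x$width, if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}
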