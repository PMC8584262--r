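# Langmuir pi-A isotherm analytics: area-per-lipid readout at a target
# surface pressure, the compressibility / surface-elasticity modulus, ideal
# mixing curves, and the excess free energy of mixing.

#' Construct a surface pressure--area isotherm
#'
#' @param area Mean molecular areas A (angstrom^2).
#' @param pressure Surface pressures pi (mN/m), same length as `area`.
#' @param composition Named numeric vector of mole fractions (must sum to 1).
#' @param temperature Subphase temperature (K).
#' @param collapse_pressure Optional collapse pressure (mN/m).
#' @param apl_sd Optional reported deviation of the APL values (angstrom^2),
#'   used in the error propagation of mixing free energies.
#' @return Object of class `isotherm`, points sorted by decreasing area with
#'   duplicate areas averaged.
#' @export
isotherm <- function(area, pressure, composition, temperature = 295.15,
                     collapse_pressure = NULL, apl_sd = NULL) {
  stopifnot(length(area) == length(pressure))
  if (any(pressure < 0)) stop("negative surface pressure")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("mole fractions must sum to 1")
  # average duplicated areas, then sort by decreasing area (compression order)
  key <- as.character(signif(area, 12))
  if (anyDuplicated(key)) {
    pressure <- as.numeric(tapply(pressure, key, mean))
    area <- as.numeric(tapply(area, key, mean))
  }
  ord <- order(area, decreasing = TRUE)
  area <- area[ord]; pressure <- pressure[ord]
  if (length(area) < 10L) stop("need >= 10 isotherm points")
  if (any(diff(pressure) < -0.5))
    warning("pressure is not monotone along compression (beyond 0.5 mN/m)")
  structure(list(area = area, pressure = pressure,
                 composition = composition, temperature = temperature,
                 collapse_pressure = collapse_pressure,
                 apl_sd = apl_sd),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat("<isotherm>", length(x$area), "points, pi",
      signif(min(x$pressure), 3), "..", signif(max(x$pressure), 3),
      "mN/m, A", signif(min(x$area), 4), "..", signif(max(x$area), 4),
      "A^2\n  composition:",
      paste(names(x$composition), signif(x$composition, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a two-column isotherm file
#'
#' Accepts comma-, tab- or whitespace-separated numeric tables (area in
#' angstrom^2, pressure in mN/m) with an optional header line.
#'
#' @param path File path.
#' @param composition Named mole-fraction vector.
#' @param temperature Temperature (K).
#' @param ... Passed to [isotherm()].
#' @return An `isotherm`.
#' @export
read_isotherm <- function(path, composition, temperature = 295.15, ...) {
  if (!file.exists(path)) stop("isotherm file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,\\s]+")[[1L]][1L])))
  df <- utils::read.table(path, header = has_header, sep = sep)
  if (ncol(df) < 2L) stop("expected two numeric columns in ", path)
  isotherm(as.numeric(df[[1L]]), as.numeric(df[[2L]]),
           composition = composition, temperature = temperature, ...)
}

#' Area per lipid at a target surface pressure
#'
#' Linear interpolation of A at `target_pi` (default 33 mN/m, the pressure
#' at which monolayer packing is conventionally compared with bilayers).
#'
#' @param iso An `isotherm`.
#' @param target_pi Target pressure (mN/m).
#' @return APL in angstrom^2.
#' @export
apl_at_pressure <- function(iso, target_pi = 33) {
  stopifnot(inherits(iso, "isotherm"))
  rng <- range(iso$pressure)
  if (target_pi < rng[1L] || target_pi > rng[2L])
    stop("target pressure ", target_pi, " mN/m outside recorded range [",
         signif(rng[1L], 4), ", ", signif(rng[2L], 4), "]")
  with_unit(stats::approx(iso$pressure, iso$area, xout = target_pi,
                          ties = mean)$y, "A^2")
}

#' Compressibility and surface-elasticity modulus of a monolayer
#'
#' The raw compressibility is `Cs = -(1/A) dA/dpi` (m/mN); the headline
#' value reported alongside it is the reciprocal modulus
#' `Cs^-1 = -A dpi/dA` (mN/m), the convention isotherm tables use for
#' "surface elasticity". The derivative is taken by central differences,
#' optionally after Savitzky-Golay smoothing of A(pi).
#'
#' @param iso An `isotherm`.
#' @param target_pi Pressure at which to evaluate (mN/m).
#' @param smooth Estimate the derivative with a Savitzky-Golay local
#'   polynomial filter (on a uniform pressure grid) instead of raw central
#'   differences; recommended for experimental isotherms.
#' @param sg_window Savitzky-Golay window length (odd); default the largest
#'   odd number up to 41 not exceeding a seventh of the record.
#' @param sg_order Savitzky-Golay polynomial order.
#' @return List of class `cs_result`: `modulus` (mN/m), `cs_raw` (m/mN),
#'   `area` (angstrom^2 at the target).
#' @export
compressibility_modulus <- function(iso, target_pi = 33, smooth = FALSE,
                                    sg_window = NULL, sg_order = 2) {
  stopifnot(inherits(iso, "isotherm"))
  rng <- range(iso$pressure)
  if (target_pi < rng[1L] || target_pi > rng[2L])
    stop("target pressure outside recorded range")
  # increasing pressure order for differencing
  ord <- order(iso$pressure)
  p <- iso$pressure[ord]; A <- iso$area[ord]
  n <- length(p)
  if (smooth) {
    # resample onto a uniform grid, then smoothed value and derivative from
    # the same local polynomial fit
    pu <- seq(p[1L], p[n], length.out = n)
    Au <- stats::approx(p, A, xout = pu, ties = mean)$y
    if (is.null(sg_window)) {
      sg_window <- min(41L, n %/% 7 * 2L + 1L)
      sg_window <- max(sg_window, sg_order + 2L + (sg_order %% 2L))
    }
    if (sg_window %% 2L == 0L) sg_window <- sg_window + 1L
    if (sg_window > n) sg_window <- (n - 1L) %/% 2L * 2L + 1L
    h <- pu[2L] - pu[1L]
    dAdp <- signal::sgolayfilt(Au, p = sg_order, n = sg_window, m = 1L,
                               ts = h)
    A <- signal::sgolayfilt(Au, p = sg_order, n = sg_window)
    p <- pu
  } else {
    dAdp <- numeric(n)
    dAdp[2:(n - 1L)] <- (A[3:n] - A[1:(n - 2L)]) / (p[3:n] - p[1:(n - 2L)])
    dAdp[1L] <- (A[2L] - A[1L]) / (p[2L] - p[1L])
    dAdp[n] <- (A[n] - A[n - 1L]) / (p[n] - p[n - 1L])
  }
  d_at <- stats::approx(p, dAdp, xout = target_pi, ties = mean)$y
  A_at <- stats::approx(p, A, xout = target_pi, ties = mean)$y
  if (abs(d_at) < 1e-9 * A_at)
    stop("phase transition plateau: dA/dpi vanishes at ", target_pi, " mN/m")
  cs_raw <- -(1 / A_at) * d_at            # 1/(mN/m)
  if (cs_raw <= 0)
    warning("negative compressibility at ", target_pi,
            " mN/m; isotherm is locally expanding")
  structure(list(modulus = with_unit(1 / cs_raw, "mN/m"),
                 cs_raw = with_unit(cs_raw, "m/mN"),
                 area = with_unit(A_at, "A^2"),
                 target_pi = target_pi),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> Cs^-1 = %.1f mN/m at pi = %.1f mN/m (A = %.1f A^2)\n",
              x$modulus, x$target_pi, x$area))
  invisible(x)
}

# Common pressure grid over the intersection of component ranges.
common_pressure_grid <- function(isos, n_grid = 400L, pi_max = NULL,
                                 pi_min = NULL) {
  lo <- max(vapply(isos, function(i) min(i$pressure), 1))
  hi <- min(vapply(isos, function(i) max(i$pressure), 1))
  if (!is.null(pi_max)) hi <- min(hi, pi_max)
  if (!is.null(pi_min)) lo <- max(lo, pi_min)
  if (hi <= lo) stop("empty common pressure range")
  seq(lo, hi, length.out = n_grid)
}

interp_area <- function(iso, p_grid) {
  stats::approx(iso$pressure, iso$area, xout = p_grid, ties = mean)$y
}

#' Ideal (non-interacting) mixed isotherm
#'
#' The theoretical mean molecular area of an ideal mixture is the
#' mole-fraction-weighted mean of the component areas at every pressure,
#' evaluated on the common pressure grid of the components.
#'
#' @param components List of 2 or 3 single-component `isotherm`s.
#' @param fractions Mole fractions (same length, summing to 1).
#' @param n_grid Number of grid points.
#' @return Data frame `pressure` (mN/m), `area` (angstrom^2).
#' @export
ideal_mixed_apl <- function(components, fractions, n_grid = 400L) {
  stopifnot(length(components) %in% 2:3,
            length(fractions) == length(components),
            abs(sum(fractions) - 1) < 1e-9)
  p <- common_pressure_grid(components, n_grid)
  A <- Reduce(`+`, Map(function(iso, x) x * interp_area(iso, p),
                       components, fractions))
  data.frame(pressure = p, area = A)
}

# Cumulative trapezoid along x.
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1L] + y[-length(y)]) / 2))
}

#' Excess free energy of mixing of a monolayer
#'
#' `dG_ex(pi) = N_A [ int A_mix dpi' - sum_k X_k int A_k dpi' ]`, the
#' integrals running from the lift-off pressure `pi0` to `pi` (trapezoidal
#' quadrature on a shared pressure grid), reported in J/mol. The deviation
#' is propagated linearly as the sum of the isotherms' APL deviations scaled
#' by `N_A (pi - pi0)`.
#'
#' @param mixed The measured mixed-monolayer `isotherm`.
#' @param components List of single-component `isotherm`s.
#' @param fractions Mole fractions of the components in the mixture.
#' @param pi_max Upper pressure limit (mN/m), default 33.
#' @param pi0 Lower integration limit; default the lift-off pressure, the
#'   first grid pressure above 0.5 mN/m common to all isotherms.
#' @param n_grid Number of quadrature points.
#' @return Object of class `mixing_result`: data frame `pressure`,
#'   `ideal_area`, `mixed_area`, `dG_excess` (J/mol), `dG_dev` (J/mol).
#' @export
excess_free_energy <- function(mixed, components, fractions, pi_max = 33,
                               pi0 = NULL, n_grid = 400L) {
  stopifnot(inherits(mixed, "isotherm"),
            length(components) %in% 2:3,
            length(fractions) == length(components),
            abs(sum(fractions) - 1) < 1e-9)
  comp_names <- names(mixed$composition)
  if (!is.null(comp_names) && length(comp_names) == length(fractions)) {
    declared <- as.numeric(mixed$composition)
    if (max(abs(sort(declared) - sort(fractions))) > 1e-6)
      stop("mixed isotherm composition is inconsistent with `fractions`")
  }
  isos <- c(list(mixed), components)
  p <- common_pressure_grid(isos, n_grid, pi_max = pi_max, pi_min = pi0)
  if (is.null(pi0)) {
    lift <- which(p > 0.5)
    if (length(lift) == 0L) stop("no pressures above the lift-off threshold")
    p <- p[lift[1L]:length(p)]
  }
  A_mix <- interp_area(mixed, p)
  A_comp <- lapply(components, interp_area, p_grid = p)
  A_ideal <- Reduce(`+`, Map(`*`, A_comp, fractions))
  I_mix <- cumtrapz(p, A_mix)
  I_ideal <- Reduce(`+`, Map(function(A, x) x * cumtrapz(p, A),
                             A_comp, fractions))
  # (mN/m * A^2) -> J, times Avogadro -> J/mol
  scale <- phys_const$NA_avogadro * phys_const$mNm_A2_to_J
  dG <- scale * (I_mix - I_ideal)
  sd_sum <- sum(vapply(isos, function(i)
    if (is.null(i$apl_sd)) 0 else i$apl_sd, 1))
  dev <- scale * sd_sum * (p - p[1L])
  structure(data.frame(pressure = p, ideal_area = A_ideal,
                       mixed_area = A_mix, dG_excess = dG, dG_dev = dev),
            pi0 = p[1L], units = "J/mol",
            class = c("mixing_result", "data.frame"))
}

#' @export
print.mixing_result <- function(x, ...) {
  last <- x[nrow(x), ]
  cat(sprintf(
    "<mixing_result> dG_ex(%.1f mN/m) = %.1f +/- %.1f J/mol (pi0 = %.2f)\n",
    last$pressure, last$dG_excess, last$dG_dev, attr(x, "pi0")))
  invisible(x)
}
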