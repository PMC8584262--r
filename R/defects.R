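# Hydrophobic defect analysis: occupancy grids of the leaflet surface
# (polar headgroup vs exposed acyl chain), the exposed-chain fraction F_exp,
# and the sphere-probe defect fraction as a function of probe radius.

#' Occupancy grid of a leaflet surface
#'
#' The box cross-section is divided into square cells of approximately
#' `spacing` angstrom. Atoms of the leaflet are processed from the bilayer
#' midplane outward; every cell whose center falls within an atom's
#' projected van der Waals disc takes that atom's class (head if the atom is
#' a headgroup atom, tail otherwise), the outermost covering atom winning
#' (ties: larger vdW radius, then lower atom index). Uncovered cells are
#' labeled empty.
#'
#' @param fs A `frame_series`.
#' @param leaflets A `leaflet_assignment`.
#' @param topology A `topology_set` (vdW radii are taken from it).
#' @param frame Frame index (default 1).
#' @param leaflet `"upper"` or `"lower"`.
#' @param spacing Target grid spacing in angstrom (default 0.5); the actual
#'   spacing divides the box edge exactly.
#' @return Object of class `surface_grid`: `grid` (integer matrix nx x ny,
#'   0 = empty, 1 = head, 2 = tail), `spacing_x`, `spacing_y` (angstrom),
#'   `leaflet`, `frame_index`.
#' @export
occupancy_grid <- function(fs, leaflets, topology, frame = 1L,
                           leaflet = c("upper", "lower"), spacing = 0.5) {
  leaflet <- match.arg(leaflet)
  at <- fs$atoms
  side <- leaflets$leaflet[match(at$lipid_id, leaflets$lipid_id)]
  sel <- which(side == leaflet)
  if (length(sel) == 0L) stop("no atoms in ", leaflet, " leaflet")

  is_head <- logical(nrow(at)); vdw <- numeric(nrow(at))
  for (sp in unique(at$species)) {
    rows <- at$species == sp
    is_head[rows] <- at$atom_name[rows] %in% topology[[sp]]$head_atoms
    vdw[rows] <- topology[[sp]]$vdw_radii[at$atom_name[rows]]
  }

  Lx <- fs$box[frame, 1L]; Ly <- fs$box[frame, 2L]
  nx <- max(1L, round(Lx / spacing)); ny <- max(1L, round(Ly / spacing))
  sx <- Lx / nx; sy <- Ly / ny
  grid <- matrix(0L, nx, ny)

  z <- fs$coords[sel, 3L, frame]
  dz <- abs(z - leaflets$midplane_z)
  # inner atoms first so outer atoms overwrite; vdW ties: larger radius and
  # lower index written later (they win)
  ord <- sel[order(dz, vdw[sel], -sel)]

  cx <- (seq_len(nx) - 0.5) * sx
  cy <- (seq_len(ny) - 0.5) * sy
  for (a in ord) {
    r <- vdw[a]
    ax <- fs$coords[a, 1L, frame]; ay <- fs$coords[a, 2L, frame]
    i0 <- floor((ax - r) / sx - 0.5); i1 <- ceiling((ax + r) / sx + 0.5)
    j0 <- floor((ay - r) / sy - 0.5); j1 <- ceiling((ay + r) / sy + 0.5)
    ii <- i0:i1; jj <- j0:j1
    dxv <- min_image(cx[(ii %% nx) + 1L] - ax, Lx)
    dyv <- min_image(cy[(jj %% ny) + 1L] - ay, Ly)
    hit <- outer(dxv^2, dyv^2, `+`) <= r^2
    if (any(hit)) {
      gi <- ((ii %% nx) + 1L)[row(hit)[hit]]
      gj <- ((jj %% ny) + 1L)[col(hit)[hit]]
      grid[cbind(gi, gj)] <- if (is_head[a]) 1L else 2L
    }
  }
  structure(list(grid = grid, spacing_x = sx, spacing_y = sy,
                 leaflet = leaflet, frame_index = frame),
            class = "surface_grid")
}

#' Build a surface grid directly from a label matrix
#'
#' Mainly for testing and for probing synthetic label fields.
#'
#' @param labels Integer matrix (0 empty, 1 head, 2 tail).
#' @param spacing Cell edge in angstrom (used for probe radii).
#' @return A `surface_grid`.
#' @export
surface_grid_from_matrix <- function(labels, spacing = 0.5) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  structure(list(grid = matrix(as.integer(labels), nrow(labels), ncol(labels)),
                 spacing_x = spacing, spacing_y = spacing,
                 leaflet = "synthetic", frame_index = NA_integer_),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  tab <- table(factor(x$grid, 0:2, c("empty", "head", "tail")))
  cat("<surface_grid>", nrow(x$grid), "x", ncol(x$grid), "cells (",
      signif(x$spacing_x, 3), "A ), leaflet", x$leaflet, "\n")
  print(tab)
  invisible(x)
}

#' Exposed acyl-chain fraction of a surface grid
#'
#' `F_exp` is the number of tail-labeled cells over the total cell count
#' (empty cells count in the denominator).
#'
#' @param grid A `surface_grid`.
#' @return Fraction in `[0, 1]`.
#' @export
exposed_fraction <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  mean(grid$grid == 2L)
}

# Periodic (circular) convolution of a 0/1 matrix with a disc of offsets.
# Returns, per cell, the number of marked cells within the disc around it.
periodic_disc_count <- function(mask, di, dj) {
  nx <- nrow(mask); ny <- ncol(mask)
  K <- matrix(0, nx, ny)
  K[cbind((di %% nx) + 1L, (dj %% ny) + 1L)] <- 1
  # correlation with a symmetric kernel == convolution
  out <- Re(stats::fft(stats::fft(mask) * stats::fft(K), inverse = TRUE)) /
    (nx * ny)
  round(out)
}

disc_offsets <- function(r, sx, sy) {
  mi <- floor(r / sx); mj <- floor(r / sy)
  g <- expand.grid(di = -mi:mi, dj = -mj:mj)
  g <- g[(g$di * sx)^2 + (g$dj * sy)^2 <= r^2, ]
  g
}

#' Sphere-probe defect fraction versus probe radius
#'
#' For each probe radius, a cell is a defect-candidate center if every cell
#' within that radius (periodic xy distance between cell centers) is
#' tail-labeled; the defect set is the union of the probe discs around all
#' centers, and the defect fraction is its share of the total surface.
#' Empty cells block the probe (they are not tail). Implemented by periodic
#' FFT convolution (morphological opening of the tail mask with the disc).
#'
#' @param grid A `surface_grid`.
#' @param radii Probe radii in nm (default 0.1 to 0.5 in 0.05 steps).
#' @return Object of class `defect_curve`: data frame `radius_nm`,
#'   `fraction`, plus attribute `f_exp`.
#' @export
probe_defect_fraction <- function(grid, radii = seq(0.1, 0.5, by = 0.05)) {
  stopifnot(inherits(grid, "surface_grid"), all(radii > 0))
  nx <- nrow(grid$grid); ny <- ncol(grid$grid)
  if (any(radii * 10 > min(nx * grid$spacing_x, ny * grid$spacing_y) / 4))
    stop("probe radius exceeds a quarter of the box")
  tail_mask <- (grid$grid == 2L) * 1
  fexp <- exposed_fraction(grid)
  fraction <- vapply(radii, function(r_nm) {
    r <- r_nm * 10                        # nm -> A
    off <- disc_offsets(r, grid$spacing_x, grid$spacing_y)
    if (nrow(off) <= 1L) {
      warning("probe radius ", r_nm,
              " nm is below the grid spacing; returning F_exp")
      return(fexp)
    }
    need <- nrow(off)
    cnt <- periodic_disc_count(tail_mask, off$di, off$dj)
    centers <- (cnt >= need) * 1
    if (!any(centers == 1)) return(0)
    covered <- periodic_disc_count(centers, off$di, off$dj) > 0
    mean(covered)
  }, numeric(1L))
  structure(data.frame(radius_nm = radii, fraction = fraction),
            f_exp = fexp, class = c("defect_curve", "data.frame"))
}
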