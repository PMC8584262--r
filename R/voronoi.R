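# Periodic 2D Voronoi tessellation by incremental half-plane clipping.
#
# Periodicity is realized by tiling the seeds over the 3x3 block of box
# images; each primary-image cell is obtained by clipping a generous starting
# square with the perpendicular bisectors of the seed and its neighbors,
# nearest first, stopping once the next bisector lies beyond the farthest
# cell vertex. For points in a periodic box this is exact, and the cell
# areas tile the box: their sum equals the box area.

#' Periodic Voronoi tessellation in the plane
#'
#' @param xy Numeric matrix `n x 2` of seed positions (angstrom); wrapped
#'   into the box internally.
#' @param Lx,Ly Box edge lengths (angstrom).
#' @return List with `areas` (numeric n, angstrom^2), `neighbors` (list of
#'   integer vectors: for each seed, the primary-image indices of the seeds
#'   sharing a cell edge, self-image adjacency excluded) and `n` the seed
#'   count.
#' @export
voronoi_periodic <- function(xy, Lx, Ly) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, Lx > 0, Ly > 0)
  n <- nrow(xy)
  if (n < 1L) stop("no seeds")
  xy[, 1L] <- xy[, 1L] - floor(xy[, 1L] / Lx) * Lx
  xy[, 2L] <- xy[, 2L] - floor(xy[, 2L] / Ly) * Ly

  # 3x3 tiling
  off <- as.matrix(expand.grid(dx = c(-1, 0, 1) * Lx, dy = c(-1, 0, 1) * Ly))
  ntile <- nrow(off)
  px <- rep(xy[, 1L], times = ntile) + rep(off[, 1L], each = n)
  py <- rep(xy[, 2L], times = ntile) + rep(off[, 2L], each = n)
  owner <- rep(seq_len(n), times = ntile)
  self_primary <- seq_len(n) + n * (which(off[, 1L] == 0 & off[, 2L] == 0) - 1L)

  scale <- max(Lx, Ly)
  tol <- 1e-9 * scale
  areas <- numeric(n)
  neighbors <- vector("list", n)

  for (i in seq_len(n)) {
    sx <- xy[i, 1L]; sy <- xy[i, 2L]
    d2 <- (px - sx)^2 + (py - sy)^2
    d2[self_primary[i]] <- Inf
    if (min(d2) < (1e-6)^2)
      stop("duplicate seeds in Voronoi input (seed ", i, ")")
    ord <- order(d2)

    # starting square slightly beyond half a box in each direction
    hx <- 0.51 * Lx; hy <- 0.51 * Ly
    V <- rbind(c(sx - hx, sy - hy), c(sx + hx, sy - hy),
               c(sx + hx, sy + hy), c(sx - hx, sy + hy))
    eids <- rep(0L, 4L)  # id of edge from vertex k to k+1; 0 = outer boundary
    rmax2 <- max((V[, 1L] - sx)^2 + (V[, 2L] - sy)^2)

    for (j in ord) {
      if (d2[j] / 4 > rmax2) break
      ux <- px[j] - sx; uy <- py[j] - sy
      mx <- (px[j] + sx) / 2; my <- (py[j] + sy) / 2
      s <- (V[, 1L] - mx) * ux + (V[, 2L] - my) * uy
      inside <- s <= tol * sqrt(d2[j])
      if (all(inside)) next
      if (!any(inside))
        stop("Voronoi cell vanished; degenerate seed configuration")
      nv <- nrow(V)
      newV <- matrix(NA_real_, nv + 2L, 2L)
      newE <- integer(nv + 2L)
      cnt <- 0L
      for (a in seq_len(nv)) {
        b <- if (a == nv) 1L else a + 1L
        if (inside[a]) {
          cnt <- cnt + 1L; newV[cnt, ] <- V[a, ]
          if (inside[b]) {
            newE[cnt] <- eids[a]
          } else {
            tt <- s[a] / (s[a] - s[b])
            cnt2 <- cnt + 1L
            newV[cnt2, ] <- V[a, ] + tt * (V[b, ] - V[a, ])
            newE[cnt] <- eids[a]
            newE[cnt2] <- j
            cnt <- cnt2
          }
        } else if (inside[b]) {
          tt <- s[a] / (s[a] - s[b])
          cnt <- cnt + 1L
          newV[cnt, ] <- V[a, ] + tt * (V[b, ] - V[a, ])
          newE[cnt] <- eids[a]
        }
      }
      V <- newV[seq_len(cnt), , drop = FALSE]
      eids <- newE[seq_len(cnt)]
      rmax2 <- max((V[, 1L] - sx)^2 + (V[, 2L] - sy)^2)
    }

    # shoelace area
    xs <- V[, 1L]; ys <- V[, 2L]
    areas[i] <- abs(sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)) / 2

    # adjacency from surviving edges of nonzero length
    nv <- nrow(V)
    nxt <- c(seq_len(nv)[-1L], 1L)
    elen2 <- (V[nxt, 1L] - xs)^2 + (V[nxt, 2L] - ys)^2
    keep <- eids > 0L & elen2 > (10 * tol)^2
    nb <- unique(owner[eids[keep]])
    neighbors[[i]] <- sort(setdiff(nb, i))
  }

  list(areas = areas, neighbors = neighbors, n = n)
}

# Unique unordered neighbor pairs (i < j) from a voronoi_periodic result.
voronoi_pairs <- function(vor) {
  pairs <- do.call(rbind, lapply(seq_len(vor$n), function(i) {
    js <- vor$neighbors[[i]]
    if (length(js) == 0L) return(NULL)
    cbind(pmin(i, js), pmax(i, js))
  }))
  if (is.null(pairs)) return(matrix(integer(0), 0L, 2L))
  unique(pairs)
}
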