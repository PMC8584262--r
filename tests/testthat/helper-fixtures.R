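# In-code fixtures shared across the suite.

# A hand-built bilayer of minimal 3-atom lipids: `n_side` lipids per leaflet
# on a square lattice, heads at +/- sep/2 around the box center.
tiny_bilayer <- function(n_side = 2L, spacing = 10, sep = 40, n_frames = 1L,
                         z_jitter = 0, seed = 1L) {
  set.seed(seed)
  n <- n_side^2
  g <- expand.grid(x = (seq_len(n_side) - 0.5) * spacing,
                   y = (seq_len(n_side) - 0.5) * spacing)
  Lx <- n_side * spacing; Ly <- Lx; Lz <- sep + 40
  nl <- 2L * n
  coords <- array(NA_real_, c(3L * nl, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    for (k in seq_len(nl)) {
      up <- k <= n
      base <- (k - 1L) %% n + 1L
      sgn <- if (up) 1 else -1
      zj <- if (z_jitter > 0) rnorm(1, 0, z_jitter) else 0
      zh <- Lz / 2 + sgn * sep / 2 + zj
      rows <- 3L * (k - 1L) + 1:3
      coords[rows[1L], , f] <- c(g$x[base], g$y[base], zh)
      coords[rows[2L], , f] <- c(g$x[base], g$y[base], zh - sgn * 1)
      coords[rows[3L], , f] <- c(g$x[base], g$y[base], zh - sgn * 6)
    }
  }
  atoms <- data.frame(lipid_id = rep(seq_len(nl), each = 3L),
                      species = "SYN",
                      atom_name = rep(c("P", "C2", "CT"), nl))
  list(frames = frame_series(coords, c(Lx, Ly, Lz), atoms, dt = 0.1),
       topology = topology_set(synthetic_lipid_topology()),
       truth = rep(c("upper", "lower"), each = n))
}

# Write a frame_series as a minimal multi-model PDB (text fixture).
write_pdb_fixture <- function(fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- fs$box[1L, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                     b[1L], b[2L], b[3L]), con)
  for (f in seq_len(dim(fs$coords)[3L])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (a in seq_len(nrow(fs$atoms))) {
      writeLines(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         a, fs$atoms$atom_name[a], fs$atoms$species[a],
                         fs$atoms$lipid_id[a],
                         fs$coords[a, 1L, f], fs$coords[a, 2L, f],
                         fs$coords[a, 3L, f]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Brute-force reference for the sphere-probe defect fraction.
brute_defect_fraction <- function(grid, radii_nm) {
  g <- grid$grid
  nx <- nrow(g); ny <- ncol(g)
  vapply(radii_nm, function(r_nm) {
    r <- r_nm * 10
    off <- membramech:::disc_offsets(r, grid$spacing_x, grid$spacing_y)
    if (nrow(off) <= 1L) return(mean(g == 2L))
    defect <- matrix(FALSE, nx, ny)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      ii <- ((i - 1L + off$di) %% nx) + 1L
      jj <- ((j - 1L + off$dj) %% ny) + 1L
      if (all(g[cbind(ii, jj)] == 2L)) defect[cbind(ii, jj)] <- TRUE
    }
    mean(defect)
  }, numeric(1L))
}

rel_err <- function(x, target) abs(x / target - 1)
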