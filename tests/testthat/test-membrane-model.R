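test_that("topology invariants are enforced", {
  expect_error(lipid_topology("X", head_atoms = c("P", "C2"),
                              tail_atoms = c("C2", "CT"),
                              p_atom = "P", c2_atom = "C2",
                              terminal_atoms = "CT"),
               "overlap")
  expect_error(lipid_topology("X", head_atoms = "C2", tail_atoms = "CT",
                              p_atom = "P", c2_atom = "C2",
                              terminal_atoms = "CT"),
               "not a head atom")
  expect_error(lipid_topology("X", head_atoms = c("P", "C2"),
                              tail_atoms = "CT", p_atom = "P",
                              c2_atom = "C2", terminal_atoms = "C99"),
               "terminal")
  top <- synthetic_lipid_topology()
  expect_s3_class(top, "lipid_topology")
  expect_setequal(names(top$vdw_radii), c("P", "C2", "CT"))
})

test_that("topology YAML config round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "POPC:",
    "  head_atoms: [P, C2]",
    "  tail_atoms: [C216, C316]",
    "  p_atom: P",
    "  c2_atom: C2",
    "  terminal_atoms: [C216, C316]",
    "  vdw_radii: {P: 1.9, C2: 1.7}"), path)
  tops <- read_topology(path)
  expect_s3_class(tops, "topology_set")
  expect_equal(tops$POPC$vdw_radii[["P"]], 1.9)
  expect_equal(tops$POPC$terminal_atoms, c("C216", "C316"))
})

test_that("native format round-trips exactly", {
  bl <- tiny_bilayer(n_side = 2L, n_frames = 2L)
  path <- withr::local_tempfile(fileext = ".mmf")
  write_frames_native(bl$frames, path)
  fs <- load_frames(path, bl$topology, format = "native")
  expect_equal(dim(fs$coords), dim(bl$frames$coords))
  expect_equal(fs$coords, bl$frames$coords, tolerance = 1e-12)
  expect_equal(fs$atoms, bl$frames$atoms)
  expect_equal(length(unique(fs$atoms$lipid_id)), 8L)
})

test_that("synthetic lattice round-trips through the native format", {
  gen <- make_lattice_membrane(n_lipids_per_leaflet = 16L, n_frames = 2L,
                               seed = 4L)
  path <- withr::local_tempfile()
  write_frames_native(gen$frames, path)
  fs <- load_frames(path, gen$topology, format = "native")
  expect_lt(max(abs(fs$coords - gen$frames$coords)), 1e-6)
})

test_that("unknown residues and atoms are named in errors", {
  bl <- tiny_bilayer()
  fs <- bl$frames
  fs$atoms$species[1:3] <- "XXX"
  path <- withr::local_tempfile()
  write_frames_native(fs, path)
  expect_error(load_frames(path, bl$topology), "XXX")
  fs2 <- bl$frames
  fs2$atoms$atom_name[2L] <- "QQ"
  path2 <- withr::local_tempfile()
  write_frames_native(fs2, path2)
  expect_error(load_frames(path2, bl$topology), "QQ")
})

test_that("PDB, GRO and XYZ readers recover coordinates", {
  bl <- tiny_bilayer(n_side = 2L, n_frames = 2L)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(bl$frames, pdb)
  fs <- load_frames(pdb, bl$topology, format = "pdb")
  expect_equal(dim(fs$coords)[3L], 2L)
  expect_lt(max(abs(fs$coords - bl$frames$coords)), 1e-3)  # %8.3f precision

  # cross-check the PDB reader against an independent parser if available
  if (requireNamespace("bio3d", quietly = TRUE)) {
    ref <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
    expect_equal(as.numeric(ref$xyz[1L, ]),
                 as.numeric(t(bl$frames$coords[, , 1L])), tolerance = 1e-3)
  }

  gro <- withr::local_tempfile(fileext = ".gro")
  con <- file(gro, "w")
  b <- bl$frames$box[1L, ] / 10
  for (f in 1:2) {
    writeLines("synthetic bilayer", con)
    writeLines(sprintf("%5d", nrow(bl$frames$atoms)), con)
    for (a in seq_len(nrow(bl$frames$atoms)))
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         bl$frames$atoms$lipid_id[a], "SYN",
                         bl$frames$atoms$atom_name[a], a,
                         bl$frames$coords[a, 1L, f] / 10,
                         bl$frames$coords[a, 2L, f] / 10,
                         bl$frames$coords[a, 3L, f] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1L], b[2L], b[3L]), con)
  }
  close(con)
  fsg <- load_frames(gro, bl$topology, format = "gro")
  expect_lt(max(abs(fsg$coords - bl$frames$coords)), 1e-2)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  con <- file(xyz, "w")
  writeLines(sprintf("%d", nrow(bl$frames$atoms)), con)
  writeLines(sprintf("box %g %g %g", bl$frames$box[1L, 1L],
                     bl$frames$box[1L, 2L], bl$frames$box[1L, 3L]), con)
  for (a in seq_len(nrow(bl$frames$atoms)))
    writeLines(sprintf("%s %.6f %.6f %.6f", bl$frames$atoms$atom_name[a],
                       bl$frames$coords[a, 1L, 1L],
                       bl$frames$coords[a, 2L, 1L],
                       bl$frames$coords[a, 3L, 1L]), con)
  close(con)
  fsx <- membramech:::read_frames_xyz(xyz, dt = 1, temperature = 300)
  expect_lt(max(abs(fsx$coords[, , 1L] - bl$frames$coords[, , 1L])), 1e-5)
})

test_that("reference points are minimum-image midpoints", {
  bl <- tiny_bilayer(n_side = 2L)
  refs <- reference_points(bl$frames, bl$topology)
  # head point = midpoint of P (z = zh) and C2 (z = zh - 1) for upper leaflet
  k <- which(refs$lipid_id == 1L)
  expect_equal(refs$head[k, 3L, 1L],
               mean(bl$frames$coords[1:2, 3L, 1L]))
  # single terminal atom: tail point is that atom
  expect_equal(refs$tail[k, , 1L], bl$frames$coords[3L, , 1L])

  # randomized coordinates: midpoint equals the coordinate mean elementwise
  set.seed(8)
  fs <- bl$frames
  fs$coords[, , 1L] <- fs$coords[, , 1L] +
    matrix(runif(length(fs$coords[, , 1L]), -2, 2), ncol = 3L)
  refs2 <- reference_points(fs, bl$topology)
  for (k in seq_along(refs2$lipid_id)) {
    rows <- which(fs$atoms$lipid_id == refs2$lipid_id[k])
    expect_equal(refs2$head[k, , 1L],
                 colMeans(fs$coords[rows[1:2], , 1L]), tolerance = 1e-9)
  }
})

test_that("reference points across the periodic boundary stay local", {
  bl <- tiny_bilayer(n_side = 2L)
  fs <- bl$frames
  # push lipid 1's P just below the x = 0 face so P and C2 straddle it
  fs$coords[1L, 1L, 1L] <- 0.2
  fs$coords[2L, 1L, 1L] <- fs$box[1L, 1L] - 0.4   # = -0.4 wrapped
  refs <- reference_points(fs, bl$topology)
  expect_equal(refs$head[1L, 1L, 1L], -0.1, tolerance = 1e-9)
})

test_that("leaflet assignment splits a bilayer and rejects a monolayer", {
  bl <- tiny_bilayer(n_side = 2L)
  lf <- assign_leaflets(bl$frames, bl$topology)
  expect_equal(sum(lf$leaflet == "upper"), 4L)
  expect_equal(sum(lf$leaflet == "lower"), 4L)
  expect_equal(as.character(lf$leaflet), bl$truth)

  mono <- bl$frames
  keep <- mono$atoms$lipid_id <= 4L
  mono <- frame_series(mono$coords[keep, , , drop = FALSE], mono$box[1L, ],
                       mono$atoms[keep, ], dt = mono$dt)
  expect_error(assign_leaflets(mono, bl$topology), "monolayer input")
})

test_that("leaflet assignment matches generator truth on a jittered bilayer", {
  gen <- make_lattice_membrane(n_lipids_per_leaflet = 36L, z_sigma = 1,
                               n_frames = 3L, seed = 12L)
  lf <- assign_leaflets(gen$frames, gen$topology)
  expect_equal(as.character(lf$leaflet), gen$leaflet_truth$leaflet)
})

test_that("leaflet assignment is invariant to z-translation and lipid order", {
  bl <- tiny_bilayer(n_side = 3L, z_jitter = 1, seed = 3L)
  lf <- assign_leaflets(bl$frames, bl$topology)

  shifted <- bl$frames
  shifted$coords[, 3L, ] <- shifted$coords[, 3L, ] + 7.3
  lf2 <- assign_leaflets(shifted, bl$topology)
  expect_equal(lf$leaflet, lf2$leaflet)

  perm <- sample(nrow(bl$frames$atoms))
  reordered <- frame_series(bl$frames$coords[perm, , , drop = FALSE],
                            bl$frames$box, bl$frames$atoms[perm, ],
                            dt = bl$frames$dt)
  lf3 <- assign_leaflets(reordered, bl$topology)
  expect_equal(lf3$leaflet[match(lf$lipid_id, lf3$lipid_id)], lf$leaflet)
})

test_that("wrapping preserves minimum-image distances (27-image oracle)", {
  set.seed(21)
  box <- c(18, 25, 31)
  pts <- cbind(runif(40, -30, 60), runif(40, -30, 60), runif(40, -30, 60))
  wrapped <- pts
  for (d in 1:3)
    wrapped[, d] <- pts[, d] - floor(pts[, d] / box[d]) * box[d]
  imgs <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  for (trial in 1:25) {
    ij <- sample(40, 2)
    a <- wrapped[ij[1L], ]; b <- wrapped[ij[2L], ]
    brute <- min(apply(imgs, 1L, function(s)
      sqrt(sum((a - b + s * box)^2))))
    expect_equal(membramech:::min_image_dist(a, b, box), brute,
                 tolerance = 1e-12)
  }
})
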