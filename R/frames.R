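#' Construct a frame series
#'
#' A `frame_series` is the package's container for a time-ordered set of
#' coordinate frames of a lipid assembly: an `n_atoms x 3 x n_frames` array of
#' coordinates (angstrom), per-frame orthorhombic box dimensions, the atom
#' labelling (lipid id, species, atom name) and the analysis temperature.
#' Coordinates are stored wrapped into the primary box image `[0, L)`.
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames` (angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param box Numeric matrix `n_frames x 3` of box edge lengths (angstrom), or
#'   a length-3 vector recycled over frames.
#' @param atoms Data frame with columns `lipid_id` (integer), `species`,
#'   `atom_name` (character), one row per atom.
#' @param dt Inter-frame time in nanoseconds.
#' @param temperature Temperature in kelvin.
#' @param wrap Wrap coordinates into the primary image (default TRUE).
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(coords, box, atoms, dt = 1, temperature = 303.15,
                         wrap = TRUE) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  n_atoms <- dim(coords)[1L]
  n_frames <- dim(coords)[3L]
  if (n_frames < 1L) stop("frame series must contain at least one frame")
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3L, byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3L, all(box > 0))
  stopifnot(is.data.frame(atoms), nrow(atoms) == n_atoms,
            all(c("lipid_id", "species", "atom_name") %in% names(atoms)))
  stopifnot(dt > 0, temperature > 0)
  atoms$lipid_id <- as.integer(atoms$lipid_id)
  atoms$species <- as.character(atoms$species)
  atoms$atom_name <- as.character(atoms$atom_name)
  if (wrap) {
    for (f in seq_len(n_frames)) {
      for (d in 1:3) {
        L <- box[f, d]
        coords[, d, f] <- coords[, d, f] - floor(coords[, d, f] / L) * L
      }
    }
  }
  structure(list(coords = coords, box = box, atoms = atoms,
                 dt = dt, temperature = temperature),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("<frame_series> ", dim(x$coords)[3L], " frames, ",
      dim(x$coords)[1L], " atoms, ",
      length(unique(x$atoms$lipid_id)), " lipids\n", sep = "")
  cat("  box (frame 1): ", paste(signif(x$box[1L, ], 5L), collapse = " x "),
      " A;  dt = ", x$dt, " ns;  T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

n_frames <- function(fs) dim(fs$coords)[3L]
n_atoms <- function(fs) dim(fs$coords)[1L]
lipid_ids <- function(fs) sort(unique(fs$atoms$lipid_id))

# Minimum-image displacement along one axis.
min_image <- function(d, L) d - round(d / L) * L

# Minimum-image distance between two 3D points under an orthorhombic box.
min_image_dist <- function(a, b, box) {
  d <- min_image(a - b, box)
  sqrt(sum(d * d))
}

## ---- native frame format -----------------------------------------------
## Plain-text, self-describing:
##   line 1: "membramech-frames 1"
##   line 2: "natoms N nframes M dt DT temperature T"
##   line 3: "atoms lipid_id species atom_name" header, then N label rows
##   per frame: "frame k box Lx Ly Lz" then N rows "x y z"

#' Write a frame series in the native plain-text format
#'
#' @param fs A `frame_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames_native <- function(fs, path) {
  stopifnot(inherits(fs, "frame_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("membramech-frames 1", con)
  writeLines(sprintf("natoms %d nframes %d dt %.17g temperature %.17g",
                     n_atoms(fs), n_frames(fs), fs$dt, fs$temperature), con)
  writeLines("atoms lipid_id species atom_name", con)
  writeLines(sprintf("%d %s %s", fs$atoms$lipid_id, fs$atoms$species,
                     fs$atoms$atom_name), con)
  for (f in seq_len(n_frames(fs))) {
    writeLines(sprintf("frame %d box %.17g %.17g %.17g", f,
                       fs$box[f, 1L], fs$box[f, 2L], fs$box[f, 3L]), con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       fs$coords[, 1L, f], fs$coords[, 2L, f],
                       fs$coords[, 3L, f]), con)
  }
  invisible(path)
}

read_frames_native <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "membramech-frames"))
    stop("not a native frame file: ", path)
  hdr <- strsplit(lines[2L], "\\s+")[[1L]]
  na <- as.integer(hdr[2L]); nf <- as.integer(hdr[4L])
  dt <- as.numeric(hdr[6L]); temp <- as.numeric(hdr[8L])
  if (nf < 1L) stop("frame count 0 in ", path)
  at0 <- 4L
  parts <- strsplit(lines[at0:(at0 + na - 1L)], "\\s+")
  atoms <- data.frame(
    lipid_id = as.integer(vapply(parts, `[[`, "", 1L)),
    species = vapply(parts, `[[`, "", 2L),
    atom_name = vapply(parts, `[[`, "", 3L)
  )
  coords <- array(NA_real_, c(na, 3L, nf))
  box <- matrix(NA_real_, nf, 3L)
  pos <- at0 + na
  for (f in seq_len(nf)) {
    bl <- strsplit(lines[pos], "\\s+")[[1L]]
    box[f, ] <- as.numeric(bl[4:6])
    block <- lines[(pos + 1L):(pos + na)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3L, byrow = TRUE)
    coords[, , f] <- m
    pos <- pos + na + 1L
  }
  frame_series(coords, box, atoms, dt = dt, temperature = temp)
}

## ---- standard coordinate formats ---------------------------------------

read_frames_pdb <- function(path, dt, temperature) {
  lines <- readLines(path)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst) > 0L)
    as.numeric(c(substr(cryst[1L], 7, 15), substr(cryst[1L], 16, 24),
                 substr(cryst[1L], 25, 33)))
  else stop("PDB file lacks a CRYST1 box record: ", path)
  if (length(model_starts) == 0L) model_starts <- 0L
  nf <- length(model_starts)
  # split atom lines per model
  idx <- which(atom_lines)
  if (length(idx) == 0L || nf == 0L) stop("frame count 0 in ", path)
  model_of <- findInterval(idx, model_starts)
  per_model <- split(idx, model_of)
  na <- length(per_model[[1L]])
  if (!all(vapply(per_model, length, 1L) == na))
    stop("PDB models have differing atom counts: ", path)
  first <- lines[per_model[[1L]]]
  atoms <- data.frame(
    lipid_id = as.integer(substr(first, 23, 26)),
    species = trimws(substr(first, 18, 21)),
    atom_name = trimws(substr(first, 13, 16))
  )
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf)) {
    ln <- lines[per_model[[f]]]
    coords[, 1L, f] <- as.numeric(substr(ln, 31, 38))
    coords[, 2L, f] <- as.numeric(substr(ln, 39, 46))
    coords[, 3L, f] <- as.numeric(substr(ln, 47, 54))
  }
  frame_series(coords, box, atoms, dt = dt, temperature = temperature)
}

read_frames_gro <- function(path, dt, temperature) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); atoms <- NULL
  pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    na <- as.integer(trimws(lines[pos + 1L]))
    ln <- lines[(pos + 2L):(pos + 1L + na)]
    if (is.null(atoms)) {
      atoms <- data.frame(
        lipid_id = as.integer(substr(ln, 1, 5)),
        species = trimws(substr(ln, 6, 10)),
        atom_name = trimws(substr(ln, 11, 15))
      )
    }
    # GRO stores nm; convert to angstrom. Velocities, if present, ignored.
    x <- as.numeric(substr(ln, 21, 28)) * 10
    y <- as.numeric(substr(ln, 29, 36)) * 10
    z <- as.numeric(substr(ln, 37, 44)) * 10
    bx <- as.numeric(strsplit(trimws(lines[pos + 2L + na]), "\\s+")[[1L]])[1:3] * 10
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- bx
    pos <- pos + 3L + na
  }
  if (length(frames) == 0L) stop("frame count 0 in ", path)
  coords <- array(unlist(frames), c(nrow(frames[[1L]]), 3L, length(frames)))
  frame_series(coords, do.call(rbind, boxes), atoms,
               dt = dt, temperature = temperature)
}

# XYZ with the box on the comment line as "box Lx Ly Lz" (angstrom) and atom
# records "NAME x y z". Lipid ids / species come from a sidecar labelling the
# caller supplies, or default to one species with atoms grouped sequentially.
read_frames_xyz <- function(path, dt, temperature, atoms = NULL) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); names1 <- NULL
  pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    na <- as.integer(trimws(lines[pos]))
    cm <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1L]]
    bi <- which(cm == "box")
    if (length(bi) == 0L) stop("XYZ comment line lacks 'box Lx Ly Lz': ", path)
    bx <- as.numeric(cm[bi + 1:3])
    ln <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + na)]), "\\s+")
    if (is.null(names1)) names1 <- vapply(ln, `[[`, "", 1L)
    m <- t(vapply(ln, function(p) as.numeric(p[2:4]), numeric(3L)))
    frames[[length(frames) + 1L]] <- m
    boxes[[length(boxes) + 1L]] <- bx
    pos <- pos + 2L + na
  }
  if (length(frames) == 0L) stop("frame count 0 in ", path)
  if (is.null(atoms))
    atoms <- data.frame(lipid_id = 1L, species = "XYZ", atom_name = names1)
  coords <- array(unlist(frames), c(nrow(frames[[1L]]), 3L, length(frames)))
  frame_series(coords, do.call(rbind, boxes), atoms,
               dt = dt, temperature = temperature)
}

#' Load a coordinate frame series
#'
#' Reads a multi-frame coordinate file, resolves every residue against the
#' declared topologies, and wraps coordinates into the primary box image.
#'
#' @param path Path to the file.
#' @param topology A `topology_set` declaring every species in the file.
#' @param format One of `"native"`, `"pdb"`, `"gro"`, `"xyz"` (default
#'   guessed from the file extension).
#' @param dt Inter-frame time (ns) for formats that do not store it.
#' @param temperature Temperature (K) for formats that do not store it.
#' @return A `frame_series`.
#' @export
load_frames <- function(path, topology, format = c("auto", "native", "pdb",
                                                   "gro", "xyz"),
                        dt = 1, temperature = 303.15) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro", xyz = "xyz", "native")
  }
  fs <- switch(format,
    native = read_frames_native(path),
    pdb = read_frames_pdb(path, dt, temperature),
    gro = read_frames_gro(path, dt, temperature),
    xyz = read_frames_xyz(path, dt, temperature)
  )
  check_against_topology(fs, topology)
  fs
}

check_against_topology <- function(fs, topology) {
  stopifnot(inherits(topology, "topology_set"))
  unknown <- setdiff(unique(fs$atoms$species), names(topology))
  if (length(unknown) > 0L)
    stop("residue name(s) not declared in topology: ",
         paste(unknown, collapse = ", "))
  for (sp in unique(fs$atoms$species)) {
    declared <- c(topology[[sp]]$head_atoms, topology[[sp]]$tail_atoms)
    an <- unique(fs$atoms$atom_name[fs$atoms$species == sp])
    bad <- setdiff(an, declared)
    if (length(bad) > 0L)
      stop("atom name(s) of species '", sp, "' not declared in topology: ",
           paste(bad, collapse = ", "))
  }
  invisible(fs)
}
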