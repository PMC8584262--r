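#' Per-lipid head and tail reference points
#'
#' The head point of a lipid is the midpoint between its phosphorus (P) and
#' C2 atoms; the tail point is the midpoint of the terminal carbon atoms of
#' its chains. Midpoints are formed under the minimum-image convention so a
#' pair straddling the periodic boundary does not produce a spurious point.
#'
#' @param fs A `frame_series`.
#' @param topology A `topology_set` covering every species in `fs`.
#' @return A list with elements `lipid_id` (integer vector, n), `species`
#'   (character, n), `head` and `tail` (numeric arrays `n x 3 x n_frames`,
#'   angstrom).
#' @export
reference_points <- function(fs, topology) {
  check_against_topology(fs, topology)
  ids <- lipid_ids(fs)
  nl <- length(ids)
  nf <- n_frames(fs)
  head <- array(NA_real_, c(nl, 3L, nf))
  tail <- array(NA_real_, c(nl, 3L, nf))
  species <- character(nl)

  at <- fs$atoms
  rows_of <- split(seq_len(nrow(at)), at$lipid_id)
  ip <- integer(nl); ic2 <- integer(nl)
  iterm <- vector("list", nl)
  for (k in seq_len(nl)) {
    rows <- rows_of[[as.character(ids[k])]]
    sp <- at$species[rows[1L]]
    species[k] <- sp
    top <- topology[[sp]]
    nm <- at$atom_name[rows]
    ip[k] <- rows[match(top$p_atom, nm)]
    ic2[k] <- rows[match(top$c2_atom, nm)]
    iterm[[k]] <- rows[match(top$terminal_atoms, nm)]
    if (is.na(ip[k]))
      stop("lipid ", ids[k], ": reference atom '", top$p_atom, "' missing")
    if (is.na(ic2[k]))
      stop("lipid ", ids[k], ": reference atom '", top$c2_atom, "' missing")
    if (anyNA(iterm[[k]]))
      stop("lipid ", ids[k], ": terminal atom(s) '",
           paste(top$terminal_atoms[is.na(match(top$terminal_atoms, nm))],
                 collapse = ","), "' missing")
  }
  it1 <- vapply(iterm, `[[`, 1L, 1L)
  nchain <- lengths(iterm)
  for (f in seq_len(nf)) {
    L <- fs$box[f, ]
    p <- fs$coords[ip, , f, drop = FALSE][, , 1L, drop = FALSE][, , 1L]
    c2 <- fs$coords[ic2, , f, drop = FALSE][, , 1L, drop = FALSE][, , 1L]
    if (nl == 1L) { p <- matrix(p, 1L); c2 <- matrix(c2, 1L) }
    for (d in 1:3) c2[, d] <- p[, d] + min_image(c2[, d] - p[, d], L[d])
    head[, , f] <- (p + c2) / 2
    t1 <- fs$coords[it1, , f, drop = FALSE][, , 1L, drop = FALSE][, , 1L]
    if (nl == 1L) t1 <- matrix(t1, 1L)
    tail[, , f] <- t1
    for (k in which(nchain > 1L)) {
      rel <- vapply(iterm[[k]], function(i)
        min_image(fs$coords[i, , f] - t1[k, ], L), numeric(3L))
      tail[k, , f] <- t1[k, ] + rowMeans(rel)
    }
  }
  list(lipid_id = ids, species = species, head = head, tail = tail)
}

#' Assign lipids to bilayer leaflets
#'
#' The bilayer midplane is fixed at the mean head-point z of the first
#' analyzed frame; lipids above it form the upper leaflet, lipids below the
#' lower. The assignment is held constant over the series; lipids whose head
#' point crosses the midplane in a later frame are flagged (in the `flagged`
#' element) but not reassigned, since flip-flop is not analyzed.
#'
#' @param fs A `frame_series`.
#' @param topology A `topology_set`.
#' @param refs Optional precomputed [reference_points()] output.
#' @return A list of class `leaflet_assignment`: `lipid_id`, `leaflet`
#'   (factor `upper`/`lower`), `midplane_z` (angstrom), `flagged`
#'   (lipid ids whose head crossed the midplane).
#' @export
assign_leaflets <- function(fs, topology, refs = NULL) {
  if (is.null(refs)) refs <- reference_points(fs, topology)
  nl <- length(refs$lipid_id)
  if (nl < 2L) stop("need at least 2 lipids to assign leaflets")
  z1 <- refs$head[, 3L, 1L]
  mid <- mean(z1)
  upper <- z1 > mid
  if (all(upper) || all(!upper)) stop("monolayer input")
  # flag midplane crossings in later frames, never reassign
  flagged <- integer(0)
  if (dim(refs$head)[3L] > 1L) {
    zall <- refs$head[, 3L, , drop = FALSE]
    crossed <- vapply(seq_len(nl), function(k) {
      any((zall[k, 1L, ] > mid) != upper[k])
    }, logical(1L))
    flagged <- refs$lipid_id[crossed]
  }
  structure(list(
    lipid_id = refs$lipid_id,
    leaflet = factor(ifelse(upper, "upper", "lower"),
                     levels = c("upper", "lower")),
    midplane_z = mid,
    flagged = flagged
  ), class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat("<leaflet_assignment> upper:", sum(x$leaflet == "upper"),
      " lower:", sum(x$leaflet == "lower"),
      " midplane z:", signif(x$midplane_z, 5), "A\n")
  if (length(x$flagged) > 0L)
    cat("  flagged midplane crossings:", length(x$flagged), "lipids\n")
  invisible(x)
}
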