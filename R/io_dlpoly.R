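#' Read a DL_POLY (classic) HISTORY trajectory
#'
#' Supports the formatted (text) HISTORY layout: a two-line header
#' (title; `levcfg imcon natms ...`), then per frame a `timestep` record,
#' three cell-vector lines when `imcon > 0`, and per atom a name record plus
#' a coordinate line, with velocity and force lines (levcfg 1/2) skipped.
#' Only orthorhombic periodic cells (imcon 1 or 2; off-diagonal cell terms
#' zero) or non-periodic frames (imcon 0) are accepted. Atom names are
#' reduced to element symbols by their leading letters and grouped into
#' molecules with `species_rule`.
#'
#' @param path File path.
#' @param max_frames Maximum number of frames to read (`Inf` for all).
#' @param species_rule Molecule template rule; see [default_species_rule()].
#' @return A [trajectory()] holding coordinates only.
#' @export
read_dlpoly_history <- function(path, max_frames = Inf,
                                species_rule = default_species_rule()) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("HISTORY file too short for a header")
  hdr <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(hdr) < 3L || anyNA(hdr[1:3]))
    stop("malformed HISTORY header record (expected: levcfg imcon natms)")
  imcon <- hdr[2]
  if (!imcon %in% c(0, 1, 2))
    stop("unsupported HISTORY cell type imcon=", imcon,
         " (only orthorhombic or non-periodic cells are readable)")
  i <- 3L
  frames <- list()
  truncated_at <- function(nread) {
    stop(sprintf(
      "truncated HISTORY file: last complete frame is %d", nread))
  }
  while (i <= length(lines) && length(frames) < max_frames) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    ts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tolower(ts[1]) != "timestep")
      stop(sprintf("expected a 'timestep' record at line %d", i))
    nat <- as.integer(ts[3])
    levcfg <- as.integer(ts[4])
    imcon_f <- as.integer(ts[5])
    if (is.na(nat) || is.na(levcfg) || is.na(imcon_f))
      stop(sprintf("malformed timestep record at line %d", i))
    if (!imcon_f %in% c(0, 1, 2))
      stop("unsupported cell type imcon=", imcon_f, " (triclinic?)")
    tstep <- suppressWarnings(as.numeric(ts[6]))
    nstep <- suppressWarnings(as.numeric(ts[2]))
    i <- i + 1L
    box <- NULL
    if (imcon_f > 0L) {
      if (i + 2L > length(lines)) truncated_at(length(frames))
      cell <- t(vapply(lines[i:(i + 2L)], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])[1:3], numeric(3)))
      if (!all(is.finite(cell))) truncated_at(length(frames))
      if (max(abs(cell[upper.tri(cell) | lower.tri(cell)])) > 1e-8)
        stop("unsupported triclinic cell (off-diagonal cell vector components)")
      box <- simulation_box(diag(cell), periodic = TRUE)
      i <- i + 3L
    }
    per_atom <- 2L + levcfg
    if (i + nat * per_atom - 1L > length(lines)) truncated_at(length(frames))
    rec <- lines[i:(i + nat * per_atom - 1L)]
    name_lines <- rec[seq(1L, by = per_atom, length.out = nat)]
    coord_lines <- rec[seq(2L, by = per_atom, length.out = nat)]
    el <- toupper(sub("([A-Za-z]+).*", "\\1",
                      vapply(strsplit(trimws(name_lines), "\\s+"),
                             `[`, "", 1L)))
    # HISTORY atom names carry forcefield decorations (OW, HW1, CT...);
    # the leading letter is the element for the O/H/C systems handled here
    el <- substr(el, 1L, 1L)
    xyz <- matrix(as.numeric(unlist(strsplit(trimws(coord_lines), "\\s+"))),
                  ncol = 3L, byrow = TRUE)
    if (!all(is.finite(xyz))) truncated_at(length(frames))
    grp <- match_molecule_blocks(el, species_rule, line_offset = i - 1L)
    if (is.null(box)) {
      span <- apply(xyz, 2L, function(v) max(diff(range(v)), 1))
      box <- simulation_box(span, periodic = FALSE)
    }
    atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], mol = grp$mol)
    tlab <- if (is.finite(tstep) && is.finite(nstep)) nstep * tstep else NULL
    frames[[length(frames) + 1L]] <-
      molecular_configuration(grp$species, box, atoms = atoms, time_ps = tlab)
    i <- i + nat * per_atom
  }
  if (!length(frames)) stop("no frames found in HISTORY file ", path)
  trajectory(frames)
}
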