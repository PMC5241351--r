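#' Molecule template rule for grouping flat atom lists
#'
#' Readers for XYZ and DL_POLY HISTORY files receive atoms as a flat list and
#' must group them into molecules. Grouping is greedy over contiguous atom
#' blocks: at each position the next `sum(template)` elements are compared,
#' as an unordered multiset, against each template in turn. The default rule
#' matches the package's minimal molecular templates: water = one O + two H,
#' alcohol = three C + one O + one H (united-atom methyl/methine carbons).
#'
#' @return Named list of named integer vectors (element -> count), tried in
#'   list order.
#' @export
default_species_rule <- function() {
  list(water = c(O = 1L, H = 2L),
       alcohol = c(C = 3L, O = 1L, H = 1L))
}

match_molecule_blocks <- function(elements, species_rule, line_offset = 0L) {
  n <- length(elements)
  species <- character(0)
  mol <- integer(n)
  i <- 1L
  m <- 0L
  while (i <= n) {
    matched <- FALSE
    for (sp in names(species_rule)) {
      tmpl <- species_rule[[sp]]
      k <- sum(tmpl)
      if (i + k - 1L > n) next
      block <- elements[i:(i + k - 1L)]
      tab <- table(factor(block, levels = names(tmpl)))
      if (all(tab == tmpl) && !anyNA(match(block, names(tmpl)))) {
        m <- m + 1L
        mol[i:(i + k - 1L)] <- m
        species[m] <- sp
        i <- i + k
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf(
        "cannot match a molecule template starting at atom line %d (element %s)",
        i + line_offset, elements[i]))
  }
  list(species = species, mol = mol)
}

parse_comment_metadata <- function(line) {
  out <- list()
  for (tok in strsplit(trimws(line), "\\s+")[[1]]) {
    if (!grepl("=", tok, fixed = TRUE)) next
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- kv[2]
  }
  out
}

#' Read an (extended) XYZ trajectory
#'
#' Standard multi-frame XYZ with key=value metadata on the comment line:
#' `box=Lx,Ly,Lz` gives the periodic orthorhombic box (Angstrom) and
#' `time=t` a frame time label (ps); unknown keys are ignored. Atoms are
#' grouped into molecules by `species_rule` (see [default_species_rule()]).
#' Files without a box are loaded with a non-periodic bounding box and a
#' warning.
#'
#' @param path File path.
#' @param species_rule Molecule template rule; see [default_species_rule()].
#' @param frame_interval_ps Frame spacing recorded on the trajectory (ps).
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, species_rule = default_species_rule(),
                     frame_interval_ps = 1) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("malformed atom count at line %d", i))
    if (i + 1L + nat > length(lines))
      stop(sprintf("truncated frame: expected %d atom lines after line %d",
                   nat, i + 1L))
    meta <- parse_comment_metadata(lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop(sprintf("malformed atom record at line %d", i + 1L + bad[1]))
    el <- toupper(vapply(toks, `[`, "", 1L))
    xyz <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3))),
                  ncol = 3L, byrow = TRUE)
    if (!all(is.finite(xyz)))
      stop(sprintf("non-numeric coordinates in frame starting at line %d", i))
    grp <- match_molecule_blocks(el, species_rule, line_offset = i + 1L)
    if (!is.null(meta$box)) {
      L <- as.numeric(strsplit(meta$box, ",", fixed = TRUE)[[1]])
      box <- simulation_box(L, periodic = TRUE)
    } else {
      warning("no box= metadata; using non-periodic bounding box")
      span <- apply(xyz, 2L, function(v) max(diff(range(v)), 1))
      box <- simulation_box(span, periodic = FALSE)
    }
    tlab <- if (!is.null(meta$time)) as.numeric(meta$time) else NULL
    atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        mol = grp$mol)
    frames[[length(frames) + 1L]] <-
      molecular_configuration(grp$species, box, atoms = atoms, time_ps = tlab)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in ", path)
  trajectory(frames, frame_interval_ps = frame_interval_ps)
}

#' Write an (extended) XYZ trajectory
#'
#' @param x A [trajectory()] or single [molecular_configuration()].
#' @param path Output file path.
#' @param digits Coordinate decimals (default 6).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, digits = 6) {
  if (inherits(x, "molecular_configuration")) x <- trajectory(list(x))
  stopifnot(inherits(x, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (fr in x$frames) {
    if (!is_atomistic(fr))
      stop("write_xyz requires atomistic configurations")
    meta <- sprintf("box=%s", paste(format(fr$box$edge_lengths, trim = TRUE,
                                           digits = 12), collapse = ","))
    if (!is.null(fr$time_ps)) meta <- paste0(meta, sprintf(" time=%g", fr$time_ps))
    writeLines(as.character(nrow(fr$atoms)), con)
    writeLines(meta, con)
    writeLines(sprintf(fmt, fr$atoms$element, fr$atoms$x, fr$atoms$y,
                       fr$atoms$z), con)
  }
  invisible(path)
}
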