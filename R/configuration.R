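#' Particle configuration of a binary water/alcohol mixture
#'
#' The unit of all structural analysis: a set of molecules, each labelled
#' `"water"` or `"alcohol"`, inside an orthorhombic [simulation_box()].
#' Two representations are supported:
#'
#' * **atomistic** — `atoms` is a data frame with one row per atom
#'   (`element`, `x`, `y`, `z`, `mol`), using minimal molecular templates:
#'   a water is one O and two H; an alcohol is one hydroxyl O, one hydroxyl
#'   H and three (united-atom) carbons. Hydrogen-bond detection and the
#'   carbon-presence occupancy rule need this form.
#' * **point mode** — `atoms` is `NULL` and `points` holds one reference
#'   point per molecule. Sufficient for segregation-only workflows, where
#'   the random-mixture null needs positions only; hydrogen-bond operations
#'   reject such input.
#'
#' @param species Character vector, one of `"water"`/`"alcohol"` per molecule.
#' @param box A [simulation_box()].
#' @param atoms Data frame (`element`, `x`, `y`, `z`, `mol`) or `NULL`.
#'   `mol` is the 1-based molecule index of each atom.
#' @param points Numeric matrix (n_molecules x 3) of reference points; required
#'   when `atoms` is `NULL`, derived from the oxygen positions otherwise.
#' @param time_ps Optional time label (ps).
#' @return An object of class `"molecular_configuration"`.
#' @export
molecular_configuration <- function(species, box, atoms = NULL, points = NULL,
                                    time_ps = NULL) {
  stopifnot(inherits(box, "simulation_box"))
  species <- as.character(species)
  if (!all(species %in% c("water", "alcohol")))
    stop("species labels must be 'water' or 'alcohol'")
  n_mol <- length(species)
  if (n_mol < 1L) stop("configuration must contain at least one molecule")

  if (is.null(atoms)) {
    points <- as.matrix(points)
    if (is.null(points) || nrow(points) != n_mol || ncol(points) != 3L)
      stop("point-mode configuration needs one 3D reference point per molecule")
    if (!all(is.finite(points))) stop("coordinates must be finite")
  } else {
    atoms <- as.data.frame(atoms)
    need <- c("element", "x", "y", "z", "mol")
    if (!all(need %in% names(atoms)))
      stop("atoms needs columns: ", paste(need, collapse = ", "))
    atoms$element <- toupper(as.character(atoms$element))
    atoms$mol <- as.integer(atoms$mol)
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
      stop("coordinates must be finite")
    if (!all(atoms$mol %in% seq_len(n_mol)))
      stop("atom molecule indices outside 1..n_molecules")
    validate_molecule_templates(atoms, species)
    if (is.null(points)) points <- oxygen_points(atoms, species)
  }
  structure(list(species = species, box = box, atoms = atoms,
                 points = points, time_ps = time_ps),
            class = "molecular_configuration")
}

validate_molecule_templates <- function(atoms, species) {
  el <- atoms$element
  mol <- atoms$mol
  nO <- tabulate(mol[el == "O"], length(species))
  nH <- tabulate(mol[el == "H"], length(species))
  nC <- tabulate(mol[el == "C"], length(species))
  w <- species == "water"
  if (any(nO[w] != 1L) || any(nH[w] != 2L) || any(nC[w] != 0L))
    stop("each water molecule must contain exactly one O and two H")
  a <- !w
  if (any(nO[a] != 1L) || any(nH[a] < 1L) || any(nC[a] != 3L))
    stop("each alcohol molecule must contain one O, at least one H and three C")
  invisible(NULL)
}

oxygen_points <- function(atoms, species) {
  ox <- atoms[atoms$element == "O", ]
  ox <- ox[order(ox$mol), ]
  as.matrix(ox[, c("x", "y", "z")])
}

#' @export
print.molecular_configuration <- function(x, ...) {
  n <- length(x$species)
  cat(sprintf("molecular_configuration: %d molecules (%d water, %d alcohol), %s\n",
              n, sum(x$species == "water"), sum(x$species == "alcohol"),
              if (is.null(x$atoms)) "point mode"
              else sprintf("%d atoms", nrow(x$atoms))))
  print(x$box)
  invisible(x)
}

#' @rdname molecular_configuration
#' @param config A `molecular_configuration`.
#' @export
is_atomistic <- function(config) !is.null(config$atoms)

#' @rdname molecular_configuration
#' @export
n_molecules <- function(config) length(config$species)

#' Ordered trajectory of configurations
#'
#' @param frames List of [molecular_configuration()] objects sharing molecule
#'   count and species labels.
#' @param frame_interval_ps Time between successive frames (ps).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(frames, frame_interval_ps = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (!all(vapply(frames, inherits, TRUE, "molecular_configuration")))
    stop("frames must be molecular_configuration objects")
  sp0 <- frames[[1L]]$species
  same <- vapply(frames, function(f) identical(f$species, sp0), TRUE)
  if (!all(same)) stop("all frames must share molecule count and species labels")
  stopifnot(is.numeric(frame_interval_ps), frame_interval_ps > 0)
  structure(list(frames = frames, frame_interval_ps = frame_interval_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames at %g ps/frame, %d molecules\n",
              length(x$frames), x$frame_interval_ps,
              length(x$frames[[1L]]$species)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

# trailing frames covering window_ps (all frames if shorter)
trailing_frames <- function(traj, window_ps = NULL, n_frames = NULL) {
  nf <- length(traj$frames)
  if (!is.null(n_frames)) {
    keep <- max(1L, nf - as.integer(n_frames) + 1L)
  } else if (!is.null(window_ps)) {
    k <- floor(window_ps / traj$frame_interval_ps)
    keep <- max(1L, nf - max(1L, k) + 1L)
  } else keep <- 1L
  traj$frames[keep:nf]
}
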