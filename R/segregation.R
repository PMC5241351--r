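#' Sub-box partition of a simulation box
#'
#' The segregation statistic divides the box into `n_boxes` equal cells
#' (default 1000 as a 10 x 10 x 10 grid). For scaled-down systems,
#' [auto_partition()] keeps the mean alcohol-per-cell occupancy comparable
#' by choosing `n_boxes = round(n_molecules / 3)` — the 3 molecules-per-cell
#' mean of the reference 3000-molecule / 1000-cell setting — on a grid as
#' near cubic as possible.
#'
#' @param n_boxes Total number of cells.
#' @param grid_shape Integer vector of three cell counts whose product is
#'   `n_boxes`; default the most cubic factorization.
#' @return An object of class `"partition_spec"`.
#' @export
partition_spec <- function(n_boxes = 1000L, grid_shape = NULL) {
  n_boxes <- as.integer(n_boxes)
  stopifnot(n_boxes >= 1L)
  if (is.null(grid_shape)) grid_shape <- near_cubic_grid(n_boxes)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (prod(grid_shape) != n_boxes)
    stop("product of grid_shape must equal n_boxes")
  structure(list(n_boxes = n_boxes, grid_shape = grid_shape),
            class = "partition_spec")
}

# most-cubic factorization of n into three integer factors
near_cubic_grid <- function(n) {
  best <- NULL
  best_spread <- Inf
  for (a in seq_len(floor(n^(1 / 3)) + 1L)) {
    if (n %% a) next
    m <- n %/% a
    for (b in seq_len(floor(sqrt(m)) + 1L)) {
      if (m %% b) next
      cc <- m %/% b
      dims <- sort(c(a, b, cc))
      spread <- dims[3] / dims[1]
      if (spread < best_spread) { best <- dims; best_spread <- spread }
    }
  }
  as.integer(best)
}

#' @rdname partition_spec
#' @param n_molecules System size used to scale the cell count.
#' @param target_occupancy Mean molecules per cell to preserve (default 3).
#' @export
auto_partition <- function(n_molecules, target_occupancy = 3) {
  partition_spec(max(1L, as.integer(round_half_up(
    n_molecules / target_occupancy))))
}

# flat cell index (1-based) for wrapped coordinates
cell_index <- function(xyz, box, part) {
  xyz <- wrap_coords(xyz, box)
  g <- part$grid_shape
  L <- box$edge_lengths
  ix <- pmin(floor(xyz[, 1] / (L[1] / g[1])), g[1] - 1)
  iy <- pmin(floor(xyz[, 2] / (L[2] / g[2])), g[2] - 1)
  iz <- pmin(floor(xyz[, 3] / (L[3] / g[3])), g[3] - 1)
  as.integer(ix + g[1] * (iy + g[2] * iz) + 1)
}

#' Per-cell molecule occupancy of a configuration
#'
#' A water molecule is counted in the single cell containing its oxygen
#' (its reference point in point mode). An alcohol is counted once in each
#' distinct cell containing at least one of its carbons — one to three
#' cells for a molecule straddling cell faces — or, in point mode, in the
#' cell of its reference point. Cells are half-open intervals
#' `[0, L/n)` over wrapped coordinates, so every atom maps to exactly one
#' cell.
#'
#' @param config A [molecular_configuration()] with a fully periodic box.
#' @param part A [partition_spec()].
#' @return List with integer vectors `water` and `alcohol` of per-cell
#'   counts (length `n_boxes`).
#' @export
count_occupancy <- function(config, part = partition_spec()) {
  stopifnot(inherits(config, "molecular_configuration"),
            inherits(part, "partition_spec"))
  check_uniform_periodicity(config$box)
  box <- config$box
  nb <- part$n_boxes
  if (is_atomistic(config)) {
    at <- config$atoms
    sp_at <- config$species[at$mol]
    w_o <- at$element == "O" & sp_at == "water"
    wat <- tabulate(cell_index(as.matrix(at[w_o, c("x", "y", "z")]), box,
                               part), nb)
    a_c <- at$element == "C" & sp_at == "alcohol"
    if (any(a_c)) {
      cells <- cell_index(as.matrix(at[a_c, c("x", "y", "z")]), box, part)
      # one count per (molecule, distinct cell) pair
      u <- unique(data.frame(mol = at$mol[a_c], cell = cells))
      alc <- tabulate(u$cell, nb)
    } else alc <- integer(nb)
  } else {
    cells <- cell_index(config$points, box, part)
    wat <- tabulate(cells[config$species == "water"], nb)
    alc <- tabulate(cells[config$species == "alcohol"], nb)
  }
  list(water = wat, alcohol = alc)
}

#' Occupancy distribution over an ensemble of per-cell counts
#'
#' N(x) is the fraction of (cell, configuration) pairs holding exactly `x`
#' molecules of the species, normalized over all cells of all
#' configurations.
#'
#' @param counts A single [count_occupancy()] result or a list of them.
#' @param species `"alcohol"` (default) or `"water"`.
#' @return An object of class `"occupancy_distribution"`: list with
#'   `fractions` (named numeric, names are occupancy counts), `n_boxes_total`
#'   and `species`.
#' @export
build_distribution <- function(counts, species = c("alcohol", "water")) {
  species <- match.arg(species)
  if (!is.null(counts$water) && !is.null(counts$alcohol)) counts <- list(counts)
  if (!length(counts)) stop("empty ensemble")
  per <- unlist(lapply(counts, `[[`, species), use.names = FALSE)
  tab <- tabulate(per + 1L)
  total <- length(per)
  fr <- tab / total
  names(fr) <- as.character(seq_along(tab) - 1L)
  structure(list(fractions = fr, n_boxes_total = total, species = species),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("occupancy_distribution (%s) over %d cell observations\n",
              x$species, x$n_boxes_total))
  print(round(x$fractions, 4))
  invisible(x)
}

#' @describeIn build_distribution Mean occupancy of a distribution.
#' @param dist An `"occupancy_distribution"`.
#' @export
occupancy_mean <- function(dist) {
  x <- as.numeric(names(dist$fractions))
  sum(x * dist$fractions)
}

#' Occupancy distribution of the random-mixture null ensemble
#'
#' Builds the ideal-mixing reference: `n_configs` independent random
#' arrangements of the same composition and box volume, reduced to a single
#' occupancy distribution. The default 2500 configurations put the sampling
#' noise floor of the non-ideality statistic well below 0.01. Point mode
#' (`atomistic = FALSE`) bins molecule reference points; atomistic mode
#' applies the carbon-presence rule to randomly oriented rigid alcohols and
#' should be used whenever the simulation side is atomistic, so both sides
#' of the statistic count presence the same way.
#'
#' @param spec A [mixture_spec()]; its `seed` drives the ensemble.
#' @param part A [partition_spec()].
#' @param n_configs Ensemble size (default 2500).
#' @param atomistic Apply the carbon rule to template alcohols.
#' @param species Species of the returned distribution.
#' @return An `"occupancy_distribution"` with attribute `seed`.
#' @export
sample_null_ensemble <- function(spec, part = partition_spec(),
                                 n_configs = 2500L, atomistic = FALSE,
                                 species = c("alcohol", "water")) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(part, "partition_spec"),
            n_configs >= 1L)
  species <- match.arg(species)
  box <- spec$box
  nb <- part$n_boxes
  n_a <- alcohol_count(spec)
  n_w <- spec$n_molecules - n_a
  n_sp <- if (species == "alcohol") n_a else n_w
  if (n_sp == 0L)
    return(structure(list(fractions = c(`0` = 1), n_boxes_total = nb * n_configs,
                          species = species), class = "occupancy_distribution",
                     seed = spec$seed))
  counts_per_cell <- withr::with_seed(spec$seed, {
    if (!atomistic) {
      # vectorized over the whole ensemble: uniform points, one cell each
      L <- box$edge_lengths
      total <- n_sp * n_configs
      xyz <- cbind(stats::runif(total, 0, L[1]), stats::runif(total, 0, L[2]),
                   stats::runif(total, 0, L[3]))
      cells <- cell_index(xyz, box, part)
      cfg <- rep(seq_len(n_configs), each = n_sp)
      tabulate((cfg - 1L) * nb + cells, nb * n_configs)
    } else {
      out <- integer(nb * n_configs)
      for (i in seq_len(n_configs)) {
        cfg <- gen_random_mixture_impl(spec, atomistic = TRUE)
        oc <- count_occupancy(cfg, part)
        out[((i - 1L) * nb + 1L):(i * nb)] <- oc[[species]]
      }
      out
    }
  })
  tab <- tabulate(counts_per_cell + 1L)
  fr <- tab / length(counts_per_cell)
  names(fr) <- as.character(seq_along(tab) - 1L)
  structure(list(fractions = fr, n_boxes_total = length(counts_per_cell),
                 species = species),
            class = "occupancy_distribution", seed = spec$seed)
}

#' Non-ideality between a simulated and a random occupancy distribution
#'
#' The segregation statistic: the root of the summed squared differences
#' between the two alcohol-occupancy distributions,
#' `sqrt(sum_x (N_s(x) - N_R(x))^2)`, taken over the union of observed
#' occupancy values with missing entries as zero. Zero means statistically
#' random mixing; larger values mean segregation.
#'
#' @param sim,null `"occupancy_distribution"` objects over the same species.
#' @return An object of class `"non_ideality_result"`: list with `value`,
#'   `sim_distribution`, `null_distribution`.
#' @export
non_ideality <- function(sim, null) {
  stopifnot(inherits(sim, "occupancy_distribution"),
            inherits(null, "occupancy_distribution"))
  if (!identical(sim$species, null$species))
    stop("distributions must be over the same species")
  support <- union(names(sim$fractions), names(null$fractions))
  ns <- ifelse(support %in% names(sim$fractions),
               sim$fractions[support], 0)
  nr <- ifelse(support %in% names(null$fractions),
               null$fractions[support], 0)
  structure(list(value = sqrt(sum((ns - nr)^2)),
                 sim_distribution = sim, null_distribution = null),
            class = "non_ideality_result")
}

#' @export
print.non_ideality_result <- function(x, ...) {
  cat(sprintf("non_ideality (%s occupancy): %.4f\n",
              x$sim_distribution$species, x$value))
  invisible(x)
}

#' Non-ideality of a trajectory against a matched random null
#'
#' Builds the simulation-side occupancy distribution from the trailing
#' frames of a trajectory (default: the last 2500, or all if fewer) and
#' compares it against a random-mixture null of matched composition, box
#' volume (taken from the final frame) and ensemble size. The null is
#' atomistic whenever the trajectory is, so the carbon-presence rule acts
#' on both sides.
#'
#' @param traj A [trajectory()].
#' @param part A [partition_spec()], or `NULL` to use [auto_partition()]
#'   on the molecule count.
#' @param n_frames Number of trailing frames for the simulation side.
#' @param n_null_configs Null ensemble size; defaults to the number of
#'   frames actually used, keeping the ensembles the same size.
#' @param seed Seed for the null ensemble.
#' @param species Species of the compared distributions.
#' @return A `"non_ideality_result"` with extra fields `n_frames`, `n_null`,
#'   `n_boxes`, `seed`.
#' @export
trajectory_non_ideality <- function(traj, part = NULL, n_frames = 2500L,
                                    n_null_configs = NULL, seed = 1L,
                                    species = c("alcohol", "water")) {
  stopifnot(inherits(traj, "trajectory"))
  species <- match.arg(species)
  frames <- trailing_frames(traj, n_frames = n_frames)
  last <- frames[[length(frames)]]
  if (is.null(part)) part <- auto_partition(length(last$species))
  if (is.null(n_null_configs)) n_null_configs <- length(frames)
  counts <- lapply(frames, count_occupancy, part = part)
  sim <- build_distribution(counts, species)
  pct <- 100 * sum(last$species == "alcohol") / length(last$species)
  null_spec <- mixture_spec(length(last$species), pct, box = last$box,
                            seed = seed)
  null <- sample_null_ensemble(null_spec, part, n_configs = n_null_configs,
                               atomistic = is_atomistic(last),
                               species = species)
  out <- non_ideality(sim, null)
  out$n_frames <- length(frames)
  out$n_null <- n_null_configs
  out$n_boxes <- part$n_boxes
  out$seed <- seed
  out
}
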