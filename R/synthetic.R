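#' Specification of a random binary mixture
#'
#' Describes the composition, box and seed of a synthetic water/alcohol
#' mixture. The alcohol count is `round(n_molecules * mole_percent / 100)`
#' with round-half-up, so e.g. 3000 molecules at 2.5 mol% gives exactly 75
#' alcohols. When no box is given, a cubic box is sized from the pure-liquid
#' molar volumes at 25 C (water 18.07, 2-propanol 76.92 cm3/mol), matching
#' the liquid density a simulation box of the same composition would have.
#'
#' @param n_molecules Total number of molecules.
#' @param alcohol_mole_percent Alcohol mole percentage in `[0, 100]`.
#' @param box A [simulation_box()], or `NULL` for the density-derived cube.
#' @param seed Integer seed; all generators are pure functions of (spec, seed).
#' @return An object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(n_molecules, alcohol_mole_percent, box = NULL,
                         seed = 1L) {
  stopifnot(n_molecules >= 1, alcohol_mole_percent >= 0,
            alcohol_mole_percent <= 100)
  if (is.null(box)) {
    box <- simulation_box(rep(mixture_box_edge(n_molecules,
                                               alcohol_mole_percent), 3L))
  }
  stopifnot(inherits(box, "simulation_box"))
  structure(list(n_molecules = as.integer(n_molecules),
                 alcohol_mole_percent = alcohol_mole_percent,
                 box = box, seed = as.integer(seed)),
            class = "mixture_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' @rdname mixture_spec
#' @export
alcohol_count <- function(spec) {
  as.integer(round_half_up(spec$n_molecules * spec$alcohol_mole_percent / 100))
}

# molecular volumes (A^3) from 25 C molar volumes: 18.07 / 76.92 cm3/mol
.VOL_WATER_A3 <- 18.07 / 6.02214076e23 * 1e24
.VOL_ALCOHOL_A3 <- 76.92 / 6.02214076e23 * 1e24

#' Cubic box edge for a mixture at liquid density
#'
#' @param n_molecules Total molecules.
#' @param alcohol_mole_percent Alcohol mole percentage.
#' @return Edge length in Angstrom.
#' @export
mixture_box_edge <- function(n_molecules, alcohol_mole_percent) {
  n_a <- round_half_up(n_molecules * alcohol_mole_percent / 100)
  v <- (n_molecules - n_a) * .VOL_WATER_A3 + n_a * .VOL_ALCOHOL_A3
  unname(v^(1 / 3))
}

# ideal rigid templates (A), molecule-local frames
water_template <- function() {
  a <- 104.5 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = 0.96 * c(sin(a), 0, cos(a)),
        H2 = 0.96 * c(-sin(a), 0, cos(a)))
}

alcohol_template <- function() {
  tet <- 109.47 * pi / 180
  o <- 1.43 * c(0, 0, 1)
  coh <- 108.5 * pi / 180
  h_dir <- c(sin(pi - coh), 0, -cos(pi - coh))  # angle C-O-H = 108.5 deg
  rbind(C2 = c(0, 0, 0),
        CB1 = 1.53 * c(sin(tet), 0, cos(tet)),
        CB2 = 1.53 * c(sin(tet) * cos(2 * pi / 3),
                       sin(tet) * sin(2 * pi / 3), cos(tet)),
        O = o,
        H = o + 0.96 * h_dir)
}

# n uniform rotations on SO(3) via normalized quaternions; returns 3x3xn
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4L * n), ncol = 4L)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- array(0, c(3L, 3L, n))
  R[1, 1, ] <- 1 - 2 * (y^2 + z^2); R[1, 2, ] <- 2 * (x * y - z * w)
  R[1, 3, ] <- 2 * (x * z + y * w)
  R[2, 1, ] <- 2 * (x * y + z * w); R[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  R[2, 3, ] <- 2 * (y * z - x * w)
  R[3, 1, ] <- 2 * (x * z - y * w); R[3, 2, ] <- 2 * (y * z + x * w)
  R[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  R
}

# build an atomistic configuration from molecule reference points; consumes
# RNG draws for orientations, so must be called inside the generator's seed
atomize_points <- function(points, species, box) {
  n <- length(species)
  R <- random_rotations(n)
  tw <- water_template()
  ta <- alcohol_template()
  counts <- ifelse(species == "water", nrow(tw), nrow(ta))
  total <- sum(counts)
  el <- character(total)
  xyz <- matrix(0, total, 3L)
  mol <- integer(total)
  pos <- 1L
  for (i in seq_len(n)) {
    tmpl <- if (species[i] == "water") tw else ta
    k <- nrow(tmpl)
    rot <- tmpl %*% t(R[, , i])
    xyz[pos:(pos + k - 1L), ] <- sweep(rot, 2L, points[i, ], `+`)
    el[pos:(pos + k - 1L)] <- substr(rownames(tmpl), 1L, 1L)
    mol[pos:(pos + k - 1L)] <- i
    pos <- pos + k
  }
  xyz <- wrap_coords(xyz, box)
  data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], mol = mol)
}

#' Generate a randomly mixed configuration
#'
#' Molecule reference points are uniform in the box — the random-mixture
#' null the segregation statistic is compared against. Steric overlap is
#' permitted: the statistic depends only on which sub-box each molecule
#' occupies. In atomistic mode each molecule is a rigid ideal-geometry
#' template with orientation uniform on SO(3) (quaternion sampling), so the
#' carbon-presence counting rule sees randomized orientations. Alcohol
#' molecules come first in the molecule ordering, then waters.
#'
#' @param spec A [mixture_spec()].
#' @param atomistic Build full minimal-template atoms (`TRUE`) or point-mode
#'   reference points only (`FALSE`, default).
#' @return A [molecular_configuration()].
#' @export
gen_random_mixture <- function(spec, atomistic = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  withr::with_seed(spec$seed, gen_random_mixture_impl(spec, atomistic))
}

gen_random_mixture_impl <- function(spec, atomistic) {
  n <- spec$n_molecules
  n_a <- alcohol_count(spec)
  species <- c(rep("alcohol", n_a), rep("water", n - n_a))
  L <- spec$box$edge_lengths
  pts <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]),
               stats::runif(n, 0, L[3]))
  if (atomistic) {
    atoms <- atomize_points(pts, species, spec$box)
    molecular_configuration(species, spec$box, atoms = atoms, points = pts)
  } else {
    molecular_configuration(species, spec$box, points = pts)
  }
}

#' Specification of planted alcohol clustering
#'
#' Ground truth for segregation tests: a `clustered_fraction` of the alcohol
#' molecules is placed as wrapped Gaussian displacements (sd `cluster_sigma`)
#' around `n_clusters` uniformly placed centers; everything else is uniform.
#'
#' @param n_clusters Number of cluster centers (>= 1).
#' @param cluster_sigma Gaussian displacement sd (Angstrom, > 0).
#' @param clustered_fraction Fraction of alcohols placed in clusters, in
#'   `[0, 1]`.
#' @return An object of class `"cluster_spec"`.
#' @export
cluster_spec <- function(n_clusters = 1L, cluster_sigma = 2,
                         clustered_fraction = 1) {
  stopifnot(n_clusters >= 1, cluster_sigma > 0,
            clustered_fraction >= 0, clustered_fraction <= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_sigma = cluster_sigma,
                 clustered_fraction = clustered_fraction),
            class = "cluster_spec")
}

#' Generate a configuration with planted alcohol clusters
#'
#' With `clustered_fraction = 0` this takes exactly the same random path as
#' [gen_random_mixture()], so the degenerate case is identical draw for draw.
#'
#' @param spec A [mixture_spec()].
#' @param cluster A [cluster_spec()].
#' @inheritParams gen_random_mixture
#' @return A [molecular_configuration()].
#' @export
gen_clustered_mixture <- function(spec, cluster, atomistic = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(cluster, "cluster_spec"))
  n_a <- alcohol_count(spec)
  n_cl <- as.integer(round_half_up(n_a * cluster$clustered_fraction))
  if (n_cl == 0L) return(gen_random_mixture(spec, atomistic))
  withr::with_seed(spec$seed, {
    n <- spec$n_molecules
    species <- c(rep("alcohol", n_a), rep("water", n - n_a))
    L <- spec$box$edge_lengths
    pts <- cbind(stats::runif(n, 0, L[1]), stats::runif(n, 0, L[2]),
                 stats::runif(n, 0, L[3]))
    centers <- cbind(stats::runif(cluster$n_clusters, 0, L[1]),
                     stats::runif(cluster$n_clusters, 0, L[2]),
                     stats::runif(cluster$n_clusters, 0, L[3]))
    assign <- rep_len(seq_len(cluster$n_clusters), n_cl)
    disp <- matrix(stats::rnorm(3L * n_cl, sd = cluster$cluster_sigma),
                   ncol = 3L)
    pts[seq_len(n_cl), ] <- wrap_coords(centers[assign, , drop = FALSE] + disp,
                                        spec$box)
    if (atomistic) {
      atoms <- atomize_points(pts, species, spec$box)
      molecular_configuration(species, spec$box, atoms = atoms, points = pts)
    } else {
      molecular_configuration(species, spec$box, points = pts)
    }
  })
}

#' Generate a trajectory of independent synthetic frames
#'
#' Convenience wrapper: `n_frames` independent draws from
#' [gen_clustered_mixture()] (or the random mixture when `cluster` is
#' `NULL`), with per-frame seeds derived as `seed + frame - 1`.
#'
#' @inheritParams gen_clustered_mixture
#' @param n_frames Number of frames.
#' @param frame_interval_ps Frame spacing (ps).
#' @return A [trajectory()].
#' @export
gen_mixture_trajectory <- function(spec, n_frames, cluster = NULL,
                                   atomistic = FALSE, frame_interval_ps = 1) {
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    sp_i <- spec
    sp_i$seed <- spec$seed + i - 1L
    frames[[i]] <- if (is.null(cluster)) gen_random_mixture(sp_i, atomistic)
      else gen_clustered_mixture(sp_i, cluster, atomistic)
    frames[[i]]$time_ps <- (i - 1) * frame_interval_ps
  }
  trajectory(frames, frame_interval_ps)
}
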