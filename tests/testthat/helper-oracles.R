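# Independent oracles: deliberately naive nested-loop implementations, kept
# separate from the package's vectorized code paths.

# minimum-image displacement for one pair, componentwise
mi_vec <- function(from, to, box) {
  d <- to - from
  for (k in 1:3) {
    if (box$periodic[k]) {
      L <- box$edge_lengths[k]
      d[k] <- d[k] - L * round(d[k] / L)
    }
  }
  d
}

# exhaustive all-pairs hydrogen-bond enumeration
oracle_hbonds <- function(config, criteria = hbond_criteria()) {
  at <- config$atoms
  box <- config$box
  found <- matrix(integer(0), ncol = 2)
  h_all <- which(at$element == "H")
  o_all <- which(at$element == "O")
  for (hi in h_all) {
    dmol <- at$mol[hi]
    doi <- o_all[at$mol[o_all] == dmol]
    p_h <- as.numeric(at[hi, c("x", "y", "z")])
    p_o <- as.numeric(at[doi, c("x", "y", "z")])
    for (ai in o_all) {
      if (at$mol[ai] == dmol) next
      p_a <- as.numeric(at[ai, c("x", "y", "z")])
      d_ha <- mi_vec(p_h, p_a, box)
      dist <- sqrt(sum(d_ha^2))
      if (dist >= criteria$h_acceptor_max_A) next
      d_ho <- mi_vec(p_h, p_o, box)
      ang <- acos(max(-1, min(1, sum(d_ha * d_ho) /
                                (dist * sqrt(sum(d_ho^2)))))) * 180 / pi
      in_band <- (ang >= criteria$angle_min_deg &&
                    ang <= criteria$angle_max_deg) ||
        ((360 - ang) >= criteria$angle_min_deg &&
           (360 - ang) <= criteria$angle_max_deg)
      if (in_band) found <- rbind(found, c(hi, ai))
    }
  }
  found
}

bond_key <- function(h, a) paste(h, a, sep = "->")

# nested-loop per-cell occupancy counter
oracle_occupancy <- function(config, part) {
  box <- config$box
  g <- part$grid_shape
  L <- box$edge_lengths
  cell_of <- function(p) {
    idx <- integer(3)
    for (k in 1:3) {
      x <- p[k] - floor(p[k] / L[k]) * L[k]
      idx[k] <- min(floor(x / (L[k] / g[k])), g[k] - 1)
    }
    idx[1] + g[1] * (idx[2] + g[2] * idx[3]) + 1
  }
  wat <- integer(part$n_boxes)
  alc <- integer(part$n_boxes)
  for (m in seq_along(config$species)) {
    if (is_atomistic(config)) {
      rows <- config$atoms[config$atoms$mol == m, ]
      if (config$species[m] == "water") {
        p <- as.numeric(rows[rows$element == "O", c("x", "y", "z")])
        wat[cell_of(p)] <- wat[cell_of(p)] + 1L
      } else {
        crows <- rows[rows$element == "C", ]
        cells <- unique(vapply(seq_len(nrow(crows)), function(j)
          cell_of(as.numeric(crows[j, c("x", "y", "z")])), 1))
        for (cl in cells) alc[cl] <- alc[cl] + 1L
      }
    } else {
      cl <- cell_of(config$points[m, ])
      if (config$species[m] == "water") wat[cl] <- wat[cl] + 1L
      else alc[cl] <- alc[cl] + 1L
    }
  }
  list(water = wat, alcohol = alc)
}

# direct two-histogram non-ideality
oracle_non_ideality <- function(fr_s, fr_r) {
  xs <- union(names(fr_s), names(fr_r))
  a <- sapply(xs, function(x) if (x %in% names(fr_s)) fr_s[[x]] else 0)
  b <- sapply(xs, function(x) if (x %in% names(fr_r)) fr_r[[x]] else 0)
  sqrt(sum((a - b)^2))
}

occ_dist <- function(fractions) {
  structure(list(fractions = fractions, n_boxes_total = NA_integer_,
                 species = "alcohol"),
            class = "occupancy_distribution")
}

# small dense atomistic mixture for oracle-equivalence runs
random_dense_config <- function(n_molecules, seed, edge = 12,
                                alcohol_pct = 30) {
  gen_random_mixture(mixture_spec(n_molecules, alcohol_pct,
                                  box = simulation_box(edge), seed = seed),
                     atomistic = TRUE)
}
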