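#' Orthorhombic simulation box
#'
#' Constructs the periodic (or open) orthorhombic box that every particle
#' configuration carries. Only orthorhombic geometry is supported: the
#' sub-box partitioning used by the segregation statistic presumes
#' axis-aligned rectangular cells, so triclinic cells are rejected at the
#' door rather than silently converted.
#'
#' @param edge_lengths Numeric vector of three positive edge lengths (Angstrom).
#' @param periodic Logical vector of three flags, recycled from length 1.
#'   Analyses that need an unambiguous wrapping rule require all-periodic or
#'   all-open boxes; mixed flags are stored but rejected by those consumers.
#' @return An object of class `"simulation_box"`.
#' @examples
#' simulation_box(c(30, 30, 30))
#' @export
simulation_box <- function(edge_lengths, periodic = TRUE) {
  edge_lengths <- as.numeric(edge_lengths)
  if (length(edge_lengths) == 1L) edge_lengths <- rep(edge_lengths, 3L)
  stopifnot(length(edge_lengths) == 3L, all(is.finite(edge_lengths)))
  if (any(edge_lengths <= 0)) stop("box edge lengths must be positive")
  if (length(periodic) == 1L) periodic <- rep(as.logical(periodic), 3L)
  stopifnot(length(periodic) == 3L, !anyNA(periodic))
  structure(list(edge_lengths = edge_lengths, periodic = periodic),
            class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("simulation_box: %.3f x %.3f x %.3f A, periodic = %s\n",
              x$edge_lengths[1], x$edge_lengths[2], x$edge_lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

is_fully_periodic <- function(box) all(box$periodic)

check_uniform_periodicity <- function(box) {
  if (!(all(box$periodic) || !any(box$periodic)))
    stop("mixed periodic flags are not supported by this operation")
  invisible(box)
}

#' Wrap coordinates into the primary box image
#'
#' Maps coordinates into `[0, L)` along each periodic axis; non-periodic axes
#' are left untouched.
#'
#' @param xyz Numeric matrix with 3 columns (Angstrom).
#' @param box A [simulation_box()].
#' @return Matrix of the same shape.
#' @export
wrap_coords <- function(xyz, box) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  for (k in 1:3) {
    if (box$periodic[k]) {
      L <- box$edge_lengths[k]
      xyz[, k] <- xyz[, k] - floor(xyz[, k] / L) * L
    }
  }
  xyz
}

#' Minimum-image displacement vectors
#'
#' Displacement `to - from` under the minimum-image convention for periodic
#' axes. Both arguments are recycled row-wise against each other.
#'
#' @param from,to Numeric matrices with 3 columns (Angstrom).
#' @param box A [simulation_box()].
#' @return Matrix of displacement vectors.
#' @export
minimum_image <- function(from, to, box) {
  from <- matrix(as.numeric(from), ncol = 3L)
  to <- matrix(as.numeric(to), ncol = 3L)
  n <- max(nrow(from), nrow(to))
  if (nrow(from) == 1L && n > 1L) from <- from[rep(1L, n), , drop = FALSE]
  if (nrow(to) == 1L && n > 1L) to <- to[rep(1L, n), , drop = FALSE]
  d <- to - from
  for (k in 1:3) {
    if (box$periodic[k]) {
      L <- box$edge_lengths[k]
      d[, k] <- d[, k] - round(d[, k] / L) * L
    }
  }
  d
}

row_norms <- function(m) sqrt(rowSums(m * m))
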