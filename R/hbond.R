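#' Geometric hydrogen-bond criterion
#'
#' A donor O-H ... acceptor O contact is a hydrogen bond when the angle at
#' the hydrogen lies between `angle_min_deg` and `angle_max_deg` and the
#' hydrogen-to-acceptor-oxygen separation is below `h_acceptor_max_A`.
#' The geometric angle lies in `[0, 180]` degrees, so the default 150-210
#' band — symmetric about linearity — is applied by folding: an angle `a`
#' is accepted when `a` or `360 - a` falls inside the band.
#'
#' @param angle_min_deg,angle_max_deg Angle band (degrees); defaults 150/210.
#' @param h_acceptor_max_A Maximum H...O separation (Angstrom); default 2.5,
#'   applied strictly (`<`).
#' @return An object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(angle_min_deg = 150, angle_max_deg = 210,
                           h_acceptor_max_A = 2.5) {
  stopifnot(angle_min_deg > 0, angle_min_deg <= 180,
            angle_max_deg >= 180, h_acceptor_max_A > 0)
  structure(list(angle_min_deg = angle_min_deg, angle_max_deg = angle_max_deg,
                 h_acceptor_max_A = h_acceptor_max_A),
            class = "hbond_criteria")
}

angle_in_band <- function(angle_deg, criteria) {
  (angle_deg >= criteria$angle_min_deg & angle_deg <= criteria$angle_max_deg) |
    ((360 - angle_deg) >= criteria$angle_min_deg &
       (360 - angle_deg) <= criteria$angle_max_deg)
}

#' Detect hydrogen bonds in a configuration
#'
#' Donors are every hydrogen of a water and the hydroxyl hydrogen of an
#' alcohol, with the covalent O-H assignment taken from the molecular
#' template, not inferred from distances. Acceptors are all oxygens of
#' other molecules. Distances and the three atoms of the angle use the
#' minimum-image convention (the acceptor is imaged relative to the
#' hydrogen). Each directed donor-H -> acceptor-O contact appears at most
#' once.
#'
#' @param config An atomistic [molecular_configuration()] (point-mode input
#'   is rejected).
#' @param criteria An [hbond_criteria()].
#' @return Data frame of class `"hbond_set"` with one row per bond:
#'   `donor_mol`, `acceptor_mol`, `donor_species`, `acceptor_species`,
#'   `h_atom`, `acceptor_atom`, `distance_A`, `angle_deg`.
#' @export
detect_hbonds <- function(config, criteria = hbond_criteria()) {
  stopifnot(inherits(config, "molecular_configuration"))
  if (!is_atomistic(config))
    stop("hydrogen-bond detection requires an atomistic configuration")
  check_uniform_periodicity(config$box)
  at <- config$atoms
  box <- config$box

  h_idx <- which(at$element == "H")
  o_idx <- which(at$element == "O")
  # oxygen of each molecule (templates have exactly one per molecule)
  o_of_mol <- integer(length(config$species))
  o_of_mol[at$mol[o_idx]] <- o_idx

  empty <- data.frame(donor_mol = integer(0), acceptor_mol = integer(0),
                      donor_species = character(0),
                      acceptor_species = character(0),
                      h_atom = integer(0), acceptor_atom = integer(0),
                      distance_A = numeric(0), angle_deg = numeric(0))
  class(empty) <- c("hbond_set", "data.frame")
  if (!length(h_idx) || length(o_idx) < 2L) return(empty)

  xyz <- as.matrix(at[, c("x", "y", "z")])
  nh <- length(h_idx)
  no <- length(o_idx)
  # all H x O pairs, chunked over hydrogens to bound memory
  res <- vector("list", 0L)
  chunk <- max(1L, floor(2e6 / no))
  for (start in seq(1L, nh, by = chunk)) {
    hs <- h_idx[start:min(start + chunk - 1L, nh)]
    m <- length(hs)
    hmat <- xyz[rep(hs, each = no), , drop = FALSE]
    amat <- xyz[rep(o_idx, m), , drop = FALSE]
    d_ha <- minimum_image(hmat, amat, box)
    dist <- row_norms(d_ha)
    hmol <- at$mol[rep(hs, each = no)]
    amol <- at$mol[rep(o_idx, m)]
    cand <- which(dist < criteria$h_acceptor_max_A & hmol != amol)
    if (!length(cand)) next
    hs_c <- rep(hs, each = no)[cand]
    ai_c <- rep(o_idx, m)[cand]
    d_do <- minimum_image(xyz[hs_c, , drop = FALSE],
                          xyz[o_of_mol[at$mol[hs_c]], , drop = FALSE], box)
    cosang <- rowSums(d_do * d_ha[cand, , drop = FALSE]) /
      (row_norms(d_do) * dist[cand])
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    keep <- angle_in_band(ang, criteria)
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      donor_mol = at$mol[hs_c[keep]], acceptor_mol = at$mol[ai_c[keep]],
      h_atom = hs_c[keep], acceptor_atom = ai_c[keep],
      distance_A = dist[cand][keep], angle_deg = ang[keep])
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$donor_species <- config$species[out$donor_mol]
  out$acceptor_species <- config$species[out$acceptor_mol]
  out <- out[order(out$h_atom, out$acceptor_atom),
             c("donor_mol", "acceptor_mol", "donor_species",
               "acceptor_species", "h_atom", "acceptor_atom", "distance_A",
               "angle_deg")]
  rownames(out) <- NULL
  class(out) <- c("hbond_set", "data.frame")
  out
}

#' Classify alcohol molecules by their hydrogen-bond partners
#'
#' An alcohol with at least one bond (as donor or acceptor) to another
#' alcohol is class `"PP"`; otherwise, with at least one bond to a water,
#' `"PW"`; otherwise `"none"`. The precedence PP > PW makes the classes
#' mutually exclusive and exhaustive, so percentages sum to exactly 100.
#'
#' @param bonds An `"hbond_set"` from [detect_hbonds()] on `config`.
#' @param config The same [molecular_configuration()].
#' @return Character vector (`"PP"`/`"PW"`/`"none"`) over alcohol molecules,
#'   named by molecule index.
#' @export
classify_alcohols <- function(bonds, config) {
  alc <- which(config$species == "alcohol")
  cls <- rep("none", length(alc))
  names(cls) <- alc
  if (nrow(bonds)) {
    pp <- unique(c(bonds$donor_mol[bonds$donor_species == "alcohol" &
                                     bonds$acceptor_species == "alcohol"],
                   bonds$acceptor_mol[bonds$donor_species == "alcohol" &
                                        bonds$acceptor_species == "alcohol"]))
    pw <- unique(c(bonds$donor_mol[bonds$donor_species == "alcohol" &
                                     bonds$acceptor_species == "water"],
                   bonds$acceptor_mol[bonds$donor_species == "water" &
                                        bonds$acceptor_species == "alcohol"]))
    cls[as.character(intersect(pw, alc))] <- "PW"
    cls[as.character(intersect(pp, alc))] <- "PP"
  }
  cls
}

per_frame_percent <- function(config, criteria) {
  cls <- classify_alcohols(detect_hbonds(config, criteria), config)
  n <- length(cls)
  if (n == 0L) stop("configuration contains no alcohol molecules")
  c(pct_PP = 100 * sum(cls == "PP") / n,
    pct_PW = 100 * sum(cls == "PW") / n,
    pct_none = 100 * sum(cls == "none") / n)
}

#' Trajectory-averaged hydrogen-bond classification
#'
#' Percentages of alcohol molecules in the P-P / P-W / no-bond classes,
#' averaged over the trailing frames of a trajectory (default: the frames
#' spanning the final 1 ns, or all frames if the trajectory is shorter).
#'
#' @param traj A [trajectory()] of atomistic frames.
#' @param criteria An [hbond_criteria()].
#' @param window_ps Length of the trailing analysis window (ps).
#' @return An object of class `"hbond_summary"`: list with `pct_PP`,
#'   `pct_PW`, `pct_none`, `n_alcohol`, `n_frames`.
#' @export
summarize_trajectory <- function(traj, criteria = hbond_criteria(),
                                 window_ps = 1000) {
  stopifnot(inherits(traj, "trajectory"))
  frames <- trailing_frames(traj, window_ps = window_ps)
  if (!length(frames)) stop("empty analysis window")
  pct <- vapply(frames, per_frame_percent, numeric(3), criteria = criteria)
  out <- as.list(rowMeans(pct))
  out$n_alcohol <- sum(frames[[1L]]$species == "alcohol")
  out$n_frames <- length(frames)
  structure(out, class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf(
    "hbond_summary over %d frame(s), %d alcohol molecules\n  P-P %.2f%%  P-W %.2f%%  no bonds %.2f%%\n",
    x$n_frames, x$n_alcohol, x$pct_PP, x$pct_PW, x$pct_none))
  invisible(x)
}
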