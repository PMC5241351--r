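#' Read a single-model PDB configuration
#'
#' Atom records are parsed with [bio3d::read.pdb()]; the CRYST1 record is
#' read directly (bio3d does not expose it) and must describe an orthorhombic
#' cell (all angles 90 degrees). Residue names map to species via
#' `residue_map`; unmapped residues are an error. A missing CRYST1 record
#' yields a non-periodic bounding box with a warning.
#'
#' @param path File path.
#' @param residue_map Named character vector residue -> species.
#' @return A [molecular_configuration()].
#' @export
read_pdb <- function(path,
                     residue_map = c(HOH = "water", WAT = "water",
                                     TIP = "water", IPA = "alcohol",
                                     IPL = "alcohol")) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  el <- toupper(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                       substr(trimws(at$elety), 1L, 1L), trimws(at$elesy)))
  # molecule = unique (chain, resno, insert) in order of appearance
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  mol <- match(key, unique(key))
  resid_by_mol <- toupper(at$resid[!duplicated(key)])
  species <- unname(residue_map[resid_by_mol])
  if (anyNA(species))
    stop("unmapped residue name(s): ",
         paste(unique(resid_by_mol[is.na(species)]), collapse = ", "))
  xyz <- cbind(at$x, at$y, at$z)
  if (length(cryst)) {
    f <- suppressWarnings(as.numeric(c(
      substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
      substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
      substr(cryst[1], 41, 47), substr(cryst[1], 48, 54))))
    if (anyNA(f)) stop("malformed CRYST1 record")
    if (any(abs(f[4:6] - 90) > 1e-6))
      stop("non-orthorhombic CRYST1 cell (angles != 90 degrees) is unsupported")
    box <- simulation_box(f[1:3], periodic = TRUE)
  } else {
    warning("no CRYST1 record; using non-periodic bounding box")
    span <- apply(xyz, 2L, function(v) max(diff(range(v)), 1))
    box <- simulation_box(span, periodic = FALSE)
  }
  atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      mol = mol)
  molecular_configuration(species, box, atoms = atoms)
}

#' Write a configuration as a PDB file
#'
#' Atom records are emitted through [bio3d::write.pdb()]; a CRYST1 record
#' carrying the orthorhombic box is prepended.
#'
#' @param config An atomistic [molecular_configuration()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(config, path) {
  stopifnot(inherits(config, "molecular_configuration"))
  if (!is_atomistic(config)) stop("write_pdb requires an atomistic configuration")
  at <- config$atoms
  resid <- ifelse(config$species[at$mol] == "water", "HOH", "IPA")
  # per-molecule atom name: element + index within molecule
  idx <- stats::ave(seq_len(nrow(at)), at$mol, FUN = seq_along)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$mol, resid = resid,
                   eleno = seq_len(nrow(at)),
                   elety = paste0(at$element, idx),
                   elesy = at$element, chain = "A")
  L <- config$box$edge_lengths
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   L[1], L[2], L[3], 90, 90, 90)
  writeLines(c(cryst, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}
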