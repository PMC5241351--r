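#' Hand-specified hydrogen-bond test geometries
#'
#' Each case is a tiny configuration built so that its hydrogen-bond count
#' under the default geometric criterion (donor O-H...acceptor O angle at H
#' within 150-210 degrees after folding about linearity, H...O distance
#' < 2.5 Angstrom) is known by construction. The expected count is attached
#' as attribute `"expected_bonds"`.
#'
#' Cases:
#' * `collinear-pair` — linear water-water bond, H...O = 1.80 A, 180 deg: 1 bond
#' * `angle-149` / `angle-151` — 1.80 A at 149 / 151 deg: 0 / 1 bonds
#' * `dist-2.49` / `dist-2.51` — collinear at 2.49 / 2.51 A: 1 / 0 bonds
#' * `pbc-wrapped-pair` — partners adjacent only through the periodic image
#'   of a 10 A box: 1 bond (0 if images are ignored)
#' * `alcohol-donor` — alcohol hydroxyl donating to a water: 1 bond
#' * `alcohol-acceptor` — water donating to an alcohol oxygen: 1 bond
#' * `trifurcated` — one water oxygen accepting from three donors: 3 bonds
#'
#' @param case_id One of the documented case names.
#' @return A [molecular_configuration()] with attribute `expected_bonds`.
#' @export
gen_hbond_toy <- function(case_id) {
  water_at <- function(o, h1, h2) {
    list(el = c("O", "H", "H"), xyz = rbind(o, h1, h2), species = "water")
  }
  # water with O at `o`, one H at o + 0.96*u, the other pointing along `v`
  water_dir <- function(o, u, v) {
    water_at(o, o + 0.96 * u / sqrt(sum(u^2)), o + 0.96 * v / sqrt(sum(v^2)))
  }
  alcohol_at <- function(o, h, c_near) {
    # three carbons strung out behind the hydroxyl, away from the action
    cc <- rbind(c_near, c_near + c(-1.0, -0.5, 0.8), c_near + c(-1.0, -0.5, -0.8))
    list(el = c("C", "C", "C", "O", "H"), xyz = rbind(cc, o, h),
         species = "alcohol")
  }
  assemble <- function(mols, box_edge = 20) {
    el <- unlist(lapply(mols, `[[`, "el"))
    xyz <- do.call(rbind, lapply(mols, `[[`, "xyz"))
    mol <- rep(seq_along(mols), vapply(mols, function(m) length(m$el), 1L))
    species <- vapply(mols, `[[`, "", "species")
    atoms <- data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        mol = mol)
    molecular_configuration(species, simulation_box(box_edge), atoms = atoms)
  }
  away1 <- c(0.6, 0.8, 0)    # acceptor H directions pointing off +x
  away2 <- c(0.6, -0.8, 0)
  back <- c(-0.6, 0.8, 0)
  donor_o <- c(8, 10, 10)
  donor_h <- c(8.96, 10, 10)

  pair_at_angle <- function(theta_deg, dist = 1.8) {
    phi <- (180 - theta_deg) * pi / 180
    acc_o <- donor_h + dist * c(cos(phi), sin(phi), 0)
    list(water_at(donor_o, donor_h, donor_o + 0.96 * back),
         water_dir(acc_o, away1, away2))
  }

  cfg <- switch(
    case_id,
    "collinear-pair" = {
      x <- assemble(pair_at_angle(180))
      structure(x, expected_bonds = 1L)
    },
    "angle-149" = structure(assemble(pair_at_angle(149)), expected_bonds = 0L),
    "angle-151" = structure(assemble(pair_at_angle(151)), expected_bonds = 1L),
    "dist-2.49" = structure(assemble(pair_at_angle(180, 2.49)),
                            expected_bonds = 1L),
    "dist-2.51" = structure(assemble(pair_at_angle(180, 2.51)),
                            expected_bonds = 0L),
    "pbc-wrapped-pair" = {
      # donor H at x = 9.96 in a 10 A box; acceptor O at x = 1.76, i.e.
      # 1.80 A away only through the periodic image
      o_d <- c(9.0, 5, 5); h_d <- c(9.96, 5, 5); o_a <- c(1.76, 5, 5)
      x <- assemble(list(water_at(o_d, h_d, o_d + 0.96 * back),
                         water_dir(o_a, away1, away2)), box_edge = 10)
      structure(x, expected_bonds = 1L)
    },
    "alcohol-donor" = {
      acc_o <- donor_h + 1.8 * c(1, 0, 0)
      x <- assemble(list(alcohol_at(donor_o, donor_h, c(7, 9.2, 10)),
                         water_dir(acc_o, away1, away2)))
      structure(x, expected_bonds = 1L)
    },
    "alcohol-acceptor" = {
      acc_o <- donor_h + 1.8 * c(1, 0, 0)
      oh <- acc_o + 0.96 * away1 / sqrt(sum(away1^2))
      x <- assemble(list(water_at(donor_o, donor_h, donor_o + 0.96 * back),
                         alcohol_at(acc_o, oh, acc_o + c(1.2, -0.9, 0))))
      structure(x, expected_bonds = 1L)
    },
    "trifurcated" = {
      o_a <- c(10, 10, 10)
      u <- list(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
      donors <- lapply(u, function(ui) {
        o_d <- o_a + 2.76 * ui
        water_at(o_d, o_a + 1.8 * ui, o_d + 0.96 * c(0, 0, 1))
      })
      a <- 104.5 / 2 * pi / 180
      acc <- water_at(o_a, o_a + 0.96 * c(sin(a), 0, cos(a)),
                      o_a + 0.96 * c(-sin(a), 0, cos(a)))
      structure(assemble(c(donors, list(acc))), expected_bonds = 3L)
    },
    stop("unknown toy case: ", case_id)
  )
  cfg
}

#' @rdname gen_hbond_toy
#' @export
hbond_toy_cases <- function() {
  c("collinear-pair", "angle-149", "angle-151", "dist-2.49", "dist-2.51",
    "pbc-wrapped-pair", "alcohol-donor", "alcohol-acceptor", "trifurcated")
}

#' Packaged reference tables
#'
#' Returns the packaged experimental/simulation reference tables shipped
#' with the package: `"table1"` — pressurization heats at 25.5 C, window
#' gradients and kinematic viscosities across the 2-propanol composition
#' range; `"table2"` — hydrogen-bond class percentages and non-ideality
#' values from mixture simulations. Entries a source does not report are NA.
#'
#' @param name `"table1"` or `"table2"`.
#' @return A data frame.
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, c("table1", "table2"))
  path <- system.file("extdata", paste0(name, ".csv"), package = "mesomix",
                      mustWork = TRUE)
  utils::read.csv(path)
}
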