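#' Side-arm bead specifications for the brush model
#'
#' Loads the per-species coarse-grained side-arm tables: one bead per tail
#' residue, with a block-wise charge assignment approximating the acidic
#' tail-domain composition, and the designated KSP serine beads that carry
#' an extra charge of -2 when phosphorylated. The packaged tables are
#' synthetic design inputs (defaults: NfL 143 beads net -25, NfM 510 beads
#' net -43, NfH 606 beads net -44 dephosphorylated; 0/13/44 phospho sites);
#' both files are plain TSV and fully overridable.
#'
#' @param charge_path TSV with columns `species`, `block_start`,
#'   `block_end`, `charge_per_bead`; defaults to the packaged table.
#' @param phospho_path TSV with columns `species`, `bead_index`; defaults to
#'   the packaged table.
#' @param phospho_charge Charge added at each phospho site when
#'   phosphorylated (default -2).
#' @return Named list (`NfL`, `NfM`, `NfH`), each with `n_beads`, `charge`
#'   (dephosphorylated per-bead charges) and `phospho_sites`.
#' @export
sidearm_specs <- function(charge_path = NULL, phospho_path = NULL,
                          phospho_charge = -2) {
  if (is.null(charge_path)) {
    charge_path <- system.file("extdata", "sidearm_charges.tsv",
                               package = "nfstoich", mustWork = TRUE)
  }
  if (is.null(phospho_path)) {
    phospho_path <- system.file("extdata", "sidearm_phospho.tsv",
                                package = "nfstoich", mustWork = TRUE)
  }
  blocks <- utils::read.delim(charge_path)
  phos <- utils::read.delim(phospho_path)
  specs <- lapply(split(blocks, blocks$species), function(bl) {
    n <- max(bl$block_end)
    charge <- numeric(n)
    for (k in seq_len(nrow(bl))) {
      charge[bl$block_start[k]:bl$block_end[k]] <- bl$charge_per_bead[k]
    }
    list(n_beads = n, charge = charge, phospho_sites = integer(0))
  })
  for (sp in names(specs)) {
    idx <- phos$bead_index[phos$species == sp]
    if (any(idx < 1 | idx > specs[[sp]]$n_beads)) {
      abort("phospho site outside the arm", class = "nfstoich_config_error")
    }
    specs[[sp]]$phospho_sites <- sort(as.integer(idx))
  }
  specs <- specs[c("NfL", "NfM", "NfH")]
  attr(specs, "phospho_charge") <- phospho_charge
  specs
}

#' Coarse rescaled side-arm tables for short exploratory runs
#'
#' Produces shorter arms with the same species length ordering and charge
#' density by keeping every bead at `round(seq(1, n, length.out = n*factor))`
#' with its original per-bead charge; phospho sites are remapped onto the
#' nearest retained bead. Net charge therefore scales roughly with `factor`.
#' Intended for reduced-size runs where the full 143/510/606-bead arms would
#' need far longer equilibration than the question at hand requires.
#'
#' @param specs Output of [sidearm_specs()].
#' @param factor Length scale in (0, 1].
#' @return A rescaled spec list of the same shape.
#' @export
scale_sidearms <- function(specs, factor) {
  stopifnot(factor > 0, factor <= 1)
  out <- lapply(specs, function(sp) {
    n_new <- max(3L, as.integer(round(sp$n_beads * factor)))
    keep <- unique(as.integer(round(seq(1, sp$n_beads, length.out = n_new))))
    sites <- if (length(sp$phospho_sites)) {
      n_sites <- max(0L, as.integer(round(length(sp$phospho_sites) * factor)))
      orig <- sp$phospho_sites[unique(as.integer(round(
        seq(1, length(sp$phospho_sites), length.out = max(n_sites, 1)))))]
      if (n_sites == 0) integer(0) else
        sort(unique(vapply(orig, function(s) which.min(abs(keep - s)), 1L)))
    } else integer(0)
    list(n_beads = length(keep), charge = sp$charge[keep], phospho_sites = sites)
  })
  attr(out, "phospho_charge") <- attr(specs, "phospho_charge")
  out
}

#' Configuration of the neurofilament side-arm brush simulation
#'
#' Geometry, interaction and run-length parameters of the coarse-grained
#' brush Monte Carlo. Lengths are in nm, energies in units of kBT. The
#' number of graft sites per backbone is the nearest integer to
#' `box_z / graft_interval` (31 at defaults); sites are spaced uniformly at
#' `box_z / n_sites` so that the axial period tiles exactly. The inverse
#' Debye length is computed from the ionic strength as
#' `kappa [1/nm] = sqrt(I [mol/L]) / 0.304`.
#'
#' @param stoichiometry Named or positional `(NfL, NfM, NfH)` mixture
#'   weights used to assign a species to each graft site.
#' @param phosphorylated Simulate the fully phosphorylated state?
#' @param box_z,box_xy Periodic box lengths (nm); z runs along the backbone.
#' @param graft_interval Nominal axial spacing of graft sites (nm).
#' @param n_backbones Number of parallel filament backbones (1 or 2).
#' @param backbone_separation Axis-to-axis distance for two backbones (nm).
#' @param backbone_radius Hard-cylinder radius of the filament core (nm).
#' @param bead_diameter,bond_length Bead hard-core diameter and fixed bond
#'   length (nm); one bead per residue.
#' @param ionic_strength Implicit-salt ionic strength (mM).
#' @param bjerrum_length Bjerrum length (nm).
#' @param cutoff Screened-Coulomb interaction cutoff (nm); the default
#'   2.5 nm is ~3 Debye lengths at 150 mM, where the screened pair energy
#'   of even doubly charged beads is below 0.05 kBT.
#' @param excluded_volume Hard-core repulsion between non-bonded beads.
#' @param backbone_exclusion Treat the backbones as hard cylinders for
#'   mobile beads (disable for free-chain reference runs).
#' @param sweeps_equil,sweeps_prod Equilibration and production sweeps (one
#'   attempted move per mobile bead per sweep).
#' @param sample_every Production sampling interval in sweeps.
#' @param arm_specs Side-arm tables from [sidearm_specs()] (or a rescaled
#'   version from [scale_sidearms()]).
#' @param species_assignment `"multinomial"` samples a species per graft
#'   site with probabilities proportional to the mixture; `"proportional"`
#'   fixes the per-species arm counts by largest-remainder quota and
#'   shuffles their placement, guaranteeing rare species are represented at
#'   small site counts.
#' @param seed Integer seed; fully determines the trajectory.
#' @return A list of class `brush_config`.
#' @export
brush_config <- function(stoichiometry = nf_targets(),
                         phosphorylated = FALSE,
                         box_z = 50, box_xy = 200,
                         graft_interval = 1.6,
                         n_backbones = 2,
                         backbone_separation = 45,
                         backbone_radius = 5,
                         bead_diameter = 0.6, bond_length = 0.6,
                         ionic_strength = 150,
                         bjerrum_length = 0.714,
                         cutoff = 2.5,
                         excluded_volume = TRUE,
                         backbone_exclusion = TRUE,
                         sweeps_equil = 500L, sweeps_prod = 1000L,
                         sample_every = 20L,
                         arm_specs = NULL,
                         species_assignment = c("multinomial", "proportional"),
                         seed = 1L) {
  species_assignment <- match.arg(species_assignment)
  stopifnot(box_z > 0, box_xy > 0, graft_interval > 0, backbone_radius > 0,
            bead_diameter > 0, bond_length > 0, ionic_strength > 0,
            n_backbones >= 1, length(stoichiometry) == 3,
            all(stoichiometry >= 0), sum(stoichiometry) > 0)
  if (is.null(names(stoichiometry))) names(stoichiometry) <- c("NfL", "NfM", "NfH")
  if (is.null(arm_specs)) arm_specs <- sidearm_specs()
  n_sites <- as.integer(round(box_z / graft_interval))
  if (n_sites < 1) abort("box too short for any graft site",
                         class = "nfstoich_config_error")
  mid <- box_xy / 2
  backbone_xy <- if (n_backbones == 1) {
    matrix(c(mid, mid), 1, 2)
  } else {
    cbind(mid + (seq_len(n_backbones) - (n_backbones + 1) / 2) *
            backbone_separation, rep(mid, n_backbones))
  }
  structure(list(
    stoichiometry = stoichiometry, phosphorylated = phosphorylated,
    box_z = box_z, box_xy = box_xy,
    graft_interval = graft_interval,
    n_sites = n_sites, site_spacing = box_z / n_sites,
    n_backbones = as.integer(n_backbones),
    backbone_separation = backbone_separation,
    backbone_radius = backbone_radius,
    backbone_xy = backbone_xy,
    bead_diameter = bead_diameter, bond_length = bond_length,
    ionic_strength = ionic_strength,
    kappa = sqrt(ionic_strength / 1000) / 0.304,
    bjerrum_length = bjerrum_length, cutoff = cutoff,
    excluded_volume = isTRUE(excluded_volume),
    backbone_exclusion = isTRUE(backbone_exclusion),
    sweeps_equil = as.integer(sweeps_equil),
    sweeps_prod = as.integer(sweeps_prod),
    sample_every = as.integer(sample_every),
    arm_specs = arm_specs,
    species_assignment = species_assignment,
    seed = as.integer(seed)
  ), class = "brush_config")
}

# interaction parameter list handed to the C++ core
.brush_params <- function(config, backbone_on = config$backbone_exclusion) {
  if (is.null(backbone_on)) backbone_on <- TRUE
  list(
    box_xy = config$box_xy, box_z = config$box_z,
    cutoff = config$cutoff,
    bead_diameter = config$bead_diameter,
    bond_length = config$bond_length,
    bjerrum_length = config$bjerrum_length,
    kappa = config$kappa,
    excluded_volume = config$excluded_volume,
    backbone_on = backbone_on,
    backbone_excl = config$backbone_radius + config$bead_diameter / 2,
    backbone_xy = config$backbone_xy
  )
}

# per-bead charges for one species under the configured phosphorylation state
.arm_charges <- function(config, species) {
  sp <- config$arm_specs[[species]]
  q <- sp$charge
  if (config$phosphorylated && length(sp$phospho_sites)) {
    pc <- attr(config$arm_specs, "phospho_charge")
    if (is.null(pc)) pc <- -2
    q[sp$phospho_sites] <- q[sp$phospho_sites] + pc
  }
  q
}
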