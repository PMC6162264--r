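# Sequence-based membrane-insertion energetics: Wimley-White whole-residue
# transfer free energies, helical-wheel hydrophobic moment, and Liu-Deber
# segmental hydrophobicity.

# Wimley-White whole-residue scales, kcal/mol. Interface scale: free energy of
# transfer from water to the POPC bilayer interface (Wimley & White 1996).
# Octanol scale: water-to-n-octanol transfer (Wimley, Creamer & White 1996).
# D, E and H carry explicit charged/neutral variants; positive values are
# unfavorable for partitioning out of water.
.ww_interface <- c(
  A = 0.17, R = 0.81, N = 0.42, C = -0.24, Q = 0.58, G = 0.01,
  I = -0.31, L = -0.56, K = 0.99, M = -0.23, F = -1.13, P = 0.45,
  S = 0.13, T = 0.14, W = -1.85, Y = -0.94, V = 0.07,
  `D-` = 1.23, D0 = -0.07, `E-` = 2.02, E0 = -0.01, H0 = 0.17, `H+` = 0.96
)

.ww_octanol <- c(
  A = 0.50, R = 1.81, N = 0.85, C = -0.02, Q = 0.77, G = 1.15,
  I = -1.12, L = -1.25, K = 2.80, M = -0.67, F = -1.71, P = 0.14,
  S = 0.46, T = 0.25, W = -2.09, Y = -0.71, V = -0.46,
  `D-` = 3.64, D0 = 0.43, `E-` = 3.63, E0 = 0.11, H0 = 0.11, `H+` = 2.33
)

# Liu-Deber relative hydrophobicity (RP-HPLC retention of model TM peptides,
# normalized to Gly = 0; values as distributed with the TM Finder server).
# Only the ordering of residues is exercised by this package's analyses.
.liu_deber <- c(
  A = 0.1, C = 1.4, D = -2.7, E = -2.6, F = 2.2, G = 0.0, H = -1.1,
  I = 3.1, K = -2.8, L = 2.8, M = 1.9, N = -1.6, P = -0.7, Q = -1.5,
  R = -2.0, S = -0.5, T = -0.3, V = 2.3, W = 1.5, Y = 0.6
)

KCAL_TO_KJ <- 4.184

#' Retrieve a bundled per-residue hydropathy scale
#'
#' Returns one of the whole-residue scales used for membrane-insertion
#' energetics, as a named numeric vector in kcal/mol (Wimley-White scales)
#' or relative units (Liu-Deber).
#'
#' @param name One of `"interface"` (Wimley-White water-to-interface),
#'   `"octanol"` (water-to-octanol), `"octanol_interface"` (their
#'   difference, i.e. the interface-to-octanol per-residue scale), or
#'   `"liu_deber"`.
#' @return Named numeric vector. The Wimley-White scales carry explicit
#'   charged/neutral variants `D-`, `D0`, `E-`, `E0`, `H0`, `H+`.
#' @export
hydropathy_scale <- function(name = c("interface", "octanol",
                                      "octanol_interface", "liu_deber")) {
  name <- match.arg(name)
  switch(name,
    interface = .ww_interface,
    octanol = .ww_octanol,
    octanol_interface = .ww_octanol - .ww_interface[names(.ww_octanol)],
    liu_deber = .liu_deber
  )
}

# Map plain residue letters to scale keys given protonation flags.
.residue_keys <- function(seq, protonation) {
  res <- strsplit(toupper(seq), "")[[1]]
  if (length(res) == 0L) stop("sequence must be nonempty")
  bad <- which(!res %in% c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  keys <- res
  keys[res == "D"] <- if (protonation$asp_charged) "D-" else "D0"
  keys[res == "E"] <- if (protonation$glu_charged) "E-" else "E0"
  keys[res == "H"] <- if (protonation$his_charged) "H+" else "H0"
  keys
}

#' Protonation-state flags for titratable residues
#'
#' @param asp_charged,glu_charged Treat Asp/Glu as charged (default `TRUE`,
#'   appropriate at neutral pH).
#' @param his_charged Treat His as protonated (default `FALSE`).
#' @return List of the three logical flags.
#' @export
protonation_state <- function(asp_charged = TRUE, glu_charged = TRUE,
                              his_charged = FALSE) {
  stopifnot(is.logical(asp_charged), is.logical(glu_charged),
            is.logical(his_charged))
  list(asp_charged = asp_charged, glu_charged = glu_charged,
       his_charged = his_charged)
}

# Per-residue values for a sequence on one of the WW scales (kcal/mol).
.per_residue <- function(seq, scale_name, protonation) {
  scale <- hydropathy_scale(scale_name)
  keys <- .residue_keys(seq, protonation)
  if (scale_name == "liu_deber") {
    # Liu-Deber has no protonation variants
    keys <- strsplit(toupper(seq), "")[[1]]
  }
  unname(scale[keys])
}

#' Whole-residue transfer free energy of a peptide segment
#'
#' Sums per-residue Wimley-White transfer free energies over a segment and
#' converts to kJ/mol. `scale = "interface"` gives the water-to-interface
#' free energy, `"octanol"` the water-to-octanol one, and
#' `"octanol_interface"` their difference (interface-to-octanol).
#'
#' @param seq Peptide sequence (one-letter codes, standard residues only).
#' @param scale Scale name as in [hydropathy_scale()].
#' @param protonation [protonation_state()] flags; the default treats
#'   Asp/Glu as charged.
#' @return Transfer free energy in kJ/mol (negative = favorable).
#' @examples
#' transfer_free_energy("SAFAGLGFLIVLALFQAGL", "interface") # approx -21.0
#' @export
transfer_free_energy <- function(seq, scale = "interface",
                                 protonation = protonation_state()) {
  sum(.per_residue(seq, scale, protonation)) * KCAL_TO_KJ
}

#' Interface-to-octanol transfer free energy
#'
#' The difference between water-to-octanol and water-to-interface transfer
#' free energies of a segment; negative values favor the transmembrane
#' (octanol-like) state over an interfacial location.
#'
#' @inheritParams transfer_free_energy
#' @return Free energy in kJ/mol; identically equal to
#'   `transfer_free_energy(seq, "octanol") - transfer_free_energy(seq, "interface")`.
#' @export
interface_to_octanol <- function(seq, protonation = protonation_state()) {
  transfer_free_energy(seq, "octanol", protonation) -
    transfer_free_energy(seq, "interface", protonation)
}

#' Helical-wheel hydrophobic moment
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed around
#' an ideal alpha-helical wheel (100 degrees per residue by default); a
#' measure of helix amphiphilicity. The default per-residue value is the
#' Wimley-White interface-to-octanol difference in kcal/mol.
#'
#' @inheritParams transfer_free_energy
#' @param scale Per-residue scale name (default `"octanol_interface"`).
#' @param delta_deg Helical twist per residue in degrees (default 100).
#' @return Non-negative moment magnitude (units of the scale, kcal/mol for
#'   the default).
#' @examples
#' hydrophobic_moment("SAFAGLGFLIVLALFQAGL") # approx 0.40
#' @export
hydrophobic_moment <- function(seq, scale = "octanol_interface",
                               delta_deg = 100,
                               protonation = protonation_state()) {
  h <- .per_residue(seq, scale, protonation)
  ang <- (seq_along(h) - 1L) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2)
}

#' Mean segmental hydrophobicity (Liu-Deber scale)
#'
#' Arithmetic mean of per-residue Liu-Deber hydrophobicity values over a
#' segment, with a transmembrane-propensity flag against a configurable
#' threshold.
#'
#' @param seq Peptide sequence.
#' @param threshold Mean-hydrophobicity threshold above which the segment is
#'   flagged as having transmembrane propensity (default 0.4).
#' @param scale Scale values (default the bundled Liu-Deber table).
#' @return List with `mean` (numeric) and `tm_propensity` (logical).
#' @export
segmental_hydrophobicity <- function(seq, threshold = 0.4,
                                     scale = hydropathy_scale("liu_deber")) {
  res <- strsplit(toupper(seq), "")[[1]]
  if (length(res) == 0L) stop("sequence must be nonempty")
  bad <- which(!res %in% names(scale))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  m <- mean(unname(scale[res]))
  list(mean = m, tm_propensity = m >= threshold)
}

#' Full segment energetics summary
#'
#' Convenience wrapper computing all transfer free energies, the hydrophobic
#' moment and the segmental hydrophobicity of one segment.
#'
#' @inheritParams transfer_free_energy
#' @return A one-row data.frame with columns `sequence`,
#'   `dG_WI_kJ_per_mol`, `dG_WO_kJ_per_mol`, `dG_IO_kJ_per_mol`,
#'   `hydrophobic_moment_kcal_per_mol`, `mean_liu_deber`, `asp_charged`.
#' @export
segment_energetics <- function(seq, protonation = protonation_state()) {
  wi <- transfer_free_energy(seq, "interface", protonation)
  wo <- transfer_free_energy(seq, "octanol", protonation)
  data.frame(
    sequence = seq,
    dG_WI_kJ_per_mol = wi,
    dG_WO_kJ_per_mol = wo,
    dG_IO_kJ_per_mol = wo - wi,
    hydrophobic_moment_kcal_per_mol =
      hydrophobic_moment(seq, protonation = protonation),
    mean_liu_deber = segmental_hydrophobicity(seq)$mean,
    asp_charged = protonation$asp_charged,
    stringsAsFactors = FALSE
  )
}
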