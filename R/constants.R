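# Physical constants (CODATA-ish values, units used throughout the package:
# energy kcal/mol, length Angstrom, mass amu, time fs, charge e, temperature K)

#' @keywords internal
.mbw <- list(
  kB        = 0.0019872041,     # kcal/mol/K
  coulomb   = 332.06371,        # kcal*A/mol/e^2
  kcal2md   = 4.184e-4,         # kcal/mol -> amu*A^2/fs^2
  hbar      = 15.178709,        # kcal*fs/mol  (hbar * N_A / 4184 * 1e15)
  amu_gmol  = 1.0,              # amu == g/mol
  avogadro3 = 0.6022140857,     # N_A * 1e-24  (molecules/A^3 per mol/cm^3)
  m_water   = 18.01528,         # g/mol
  mass_O    = 15.9994,
  mass_H    = 1.008,
  hard_floor = 0.3              # A; below this interatomic distance the
                                # potential is considered undefined
)

#' Box edge length of a cubic water box at a given density
#'
#' @param n_molecules number of water molecules
#' @param density mass density in g/cm^3
#' @return edge length in Angstrom
#' @examples
#' box_edge_for_density(256, 0.997)
#' @export
box_edge_for_density <- function(n_molecules, density) {
  stopifnot(n_molecules >= 1, density > 0)
  (n_molecules * .mbw$m_water / (density * .mbw$avogadro3))^(1 / 3)
}
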