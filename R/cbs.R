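# Complete-basis-set extrapolation and counterpoise arithmetic.  Pure
# operations on caller-supplied energies (no electronic structure here, and
# no HF/correlation split: callers choose what to extrapolate).

#' Two-point inverse-cubic extrapolation to the complete basis set limit
#'
#' Assumes the standard correlation-energy convergence `E_X = E_CBS + A/X^3`
#' for basis-set cardinal number X, so that two cardinals determine the
#' limit:
#' `E_CBS = (X_hi^3 E_hi - X_lo^3 E_lo) / (X_hi^3 - X_lo^3)`.
#' Exact for any series of that form (e.g. cardinals 3 and 4).
#'
#' @param x_lo,e_lo lower cardinal number (>= 2) and its energy.
#' @param x_hi,e_hi higher cardinal number and its energy.
#' @return extrapolated energy `E_CBS` (units follow the inputs).
#' @export
cbs_two_point <- function(x_lo, e_lo, x_hi, e_hi) {
  if (x_lo < 2 || x_hi < 2) stop("cardinal numbers must be >= 2")
  if (x_hi == x_lo) stop("cardinal numbers must differ (division by zero)")
  if (x_hi < x_lo) stop("x_hi must exceed x_lo")
  (x_hi^3 * e_hi - x_lo^3 * e_lo) / (x_hi^3 - x_lo^3)
}

#' Counterpoise-corrected interaction energy and BSSE estimate
#'
#' Pure arithmetic on supplied energies.  Sign convention: the corrected
#' interaction energy is
#' `E_int = E_complex - sum(monomers in the full cluster basis)` and the
#' basis-set superposition error estimate is
#' `BSSE = sum(monomers in full basis) - sum(monomers in own basis)`
#' (typically negative: ghost functions lower the monomer energies).
#'
#' @param e_complex energy of the complex in the full basis.
#' @param monomers_full_basis monomer energies computed in the full cluster
#'   basis (ghost functions present).
#' @param monomers_own_basis monomer energies in their own basis, same order.
#' @return list with `interaction` (corrected), `bsse`, and `uncorrected`
#'   (`e_complex - sum(monomers_own_basis)`).
#' @export
counterpoise_interaction <- function(e_complex, monomers_full_basis,
                                     monomers_own_basis) {
  if (length(monomers_full_basis) != length(monomers_own_basis))
    stop("one full-basis and one own-basis energy per monomer required")
  list(interaction = e_complex - sum(monomers_full_basis),
       bsse = sum(monomers_full_basis) - sum(monomers_own_basis),
       uncorrected = e_complex - sum(monomers_own_basis))
}
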