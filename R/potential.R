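# Potential stack: 1B + classical many-body baseline (permanent
# electrostatics, self-consistent induction, damped dispersion) + switched
# short-range 2B/3B terms.  The short-range terms can be the built-in
# Born-Mayer / Axilrod-Teller forms or fitted permutation-invariant terms
# swapped in by swap_terms().

#' Default parameter set of the truth water potential
#'
#' These constants define the synthetic "truth" model used throughout the
#' package.  They are chosen for physical plausibility (gas-phase monomer
#' geometry, a water-dimer minimum near O-O = 2.9 A with an interaction
#' energy of roughly -5 kcal/mol, 2B-dominant many-body expansion); they are
#' *not* a fit to real water and stand in for a coupled-cluster quality
#' reference.
#'
#' @return named list of parameters:
#' \describe{
#'   \item{qO, qH}{fixed atomic point charges (e)}
#'   \item{alphaO}{isotropic polarizability of the O site (A^3)}
#'   \item{thole_a}{Thole damping width for induction (A)}
#'   \item{C6, b_disp}{O-O dispersion coefficient (kcal/mol A^6) and
#'     Tang-Toennies damping range (1/A)}
#'   \item{A_bm, b_bm}{Born-Mayer short-range 2B repulsion (kcal/mol, 1/A)}
#'   \item{k3b}{Axilrod-Teller-Muto 3B prefactor (kcal/mol A^9)}
#'   \item{kbond, D_morse, r0}{O-H stretch: harmonic force constant
#'     (kcal/mol/A^2), Morse well depth (kcal/mol) and equilibrium length
#'     (A).  The stretch is a bounded Morse form whose expansion is the
#'     harmonic term plus the cubic anharmonic correction.}
#'   \item{kang, theta0}{harmonic HOH bend (kcal/mol/rad^2, rad)}
#'   \item{sw2_in, sw2_out, sw3_in, sw3_out}{quintic switching radii of the
#'     short-range 2B and 3B terms (A)}
#'   \item{cutoff}{periodic real-space atom-atom cutoff (A)}
#'   \item{ewald_tol}{target relative accuracy of the Ewald sum}
#'   \item{scf_tol, scf_maxit}{induced-dipole convergence (max norm of the
#'     dipole update, e*A) and iteration bound}
#' }
#' @export
default_water_params <- function() {
  list(qO = -0.84, qH = 0.42,
       alphaO = 1.444, thole_a = 1.6,
       C6 = 450.0, b_disp = 3.0,
       A_bm = 3.0e6, b_bm = 4.8,
       k3b = 1500.0,
       kbond = 1059.162, D_morse = 120.0, r0 = 0.9572,
       kang = 75.90, theta0 = 104.52 * pi / 180,
       sw2_in = 5.5, sw2_out = 7.5,
       sw3_in = 2.5, sw3_out = 4.5,
       cutoff = 9.0, ewald_tol = 1e-5,
       scf_tol = 1e-8, scf_maxit = 500L)
}

#' Construct the truth many-body water potential
#'
#' The "truth" potential plays the role of the coupled-cluster/CBS reference
#' level: a polarizable baseline (point charges + self-consistent induction +
#' damped dispersion) supplemented by switched short-range two-body
#' (Born-Mayer) and three-body (Axilrod-Teller-Muto) terms, plus a flexible
#' intramolecular 1B term that is zero at the reference monomer geometry.
#'
#' @param params parameter list; defaults from [default_water_params()].
#'   Partial lists are merged over the defaults.
#' @return an object of class `mbw_potential`.
#' @export
make_truth_potential <- function(params = list()) {
  p <- utils::modifyList(default_water_params(), params)
  if (p$kbond <= 0 || p$kang <= 0) stop("force constants must be positive")
  if (p$sw2_out <= p$sw2_in || p$sw3_out <= p$sw3_in)
    stop("switch outer radius must exceed inner radius")
  if (p$cutoff <= 0) stop("cutoff must be positive")
  if (p$alphaO < 0) stop("polarizability must be non-negative")
  structure(list(params = p,
                 level_tag = "truth",
                 distortion = c(eps_rep = 0, eps_disp = 0, eps_3b = 0),
                 fitted_2b = NULL, fitted_3b = NULL,
                 use_native_2b = TRUE, use_native_3b = TRUE),
            class = "mbw_potential")
}

#' Distortion specification for surrogate potentials
#'
#' Fractional scalings emulating the rung-dependent error of approximate
#' exchange-correlation functionals: `eps_rep` scales the short-range 2B
#' repulsion, `eps_disp` the dispersion coefficient, `eps_3b` the 3B term.
#'
#' @param eps_rep,eps_disp,eps_3b fractional scalings, each > -1.
#' @param label surrogate name.
#' @return a `mbw_distortion` list.
#' @export
distortion_spec <- function(eps_rep = 0, eps_disp = 0, eps_3b = 0,
                            label = "surrogate") {
  if (any(c(eps_rep, eps_disp, eps_3b) <= -1))
    stop("distortion scalings must be > -1 (terms keep their sign)")
  structure(list(eps_rep = eps_rep, eps_disp = eps_disp, eps_3b = eps_3b,
                 label = label), class = "mbw_distortion")
}

#' Construct a distorted surrogate potential
#'
#' Returns the truth potential with the short-range 2B repulsion scaled by
#' `(1 + eps_rep)`, the dispersion C6 by `(1 + eps_disp)` and the short-range
#' 3B term by `(1 + eps_3b)`.  Baseline electrostatics/induction and the 1B
#' term are unchanged, mimicking a functional whose many-body error lives in
#' the short-range 2B/3B representation.
#'
#' @param truth an `mbw_potential` (normally from [make_truth_potential()]).
#' @param spec an `mbw_distortion` from [distortion_spec()].
#' @return an `mbw_potential` tagged with the surrogate label.
#' @export
make_surrogate_potential <- function(truth, spec) {
  stopifnot(inherits(truth, "mbw_potential"), inherits(spec, "mbw_distortion"))
  pot <- truth
  pot$params$A_bm <- truth$params$A_bm * (1 + spec$eps_rep)
  pot$params$C6 <- truth$params$C6 * (1 + spec$eps_disp)
  pot$params$k3b <- truth$params$k3b * (1 + spec$eps_3b)
  pot$level_tag <- spec$label
  pot$distortion <- c(eps_rep = spec$eps_rep, eps_disp = spec$eps_disp,
                      eps_3b = spec$eps_3b)
  pot
}

#' Swap fitted short-range terms into a potential
#'
#' Realizes the hybrid construction: the base potential keeps its 1B term and
#' classical many-body baseline while the explicit short-range 2B and/or 3B
#' terms are replaced by fitted permutation-invariant terms.  Passing `NULL`
#' for a slot keeps the base's native term.
#'
#' @param base an `mbw_potential`.
#' @param two_body,three_body `mbw_fitted_term` objects from [fit_term()],
#'   or `NULL` to keep the base term.
#' @param label tag for the hybrid (default derived from the base tag).
#' @return an `mbw_potential` with the requested terms replaced.
#' @export
swap_terms <- function(base, two_body = NULL, three_body = NULL,
                       label = NULL) {
  stopifnot(inherits(base, "mbw_potential"))
  pot <- base
  for (tm in list(two_body, three_body)) {
    if (is.null(tm)) next
    if (!inherits(tm, "mbw_fitted_term")) stop("fitted terms must come from fit_term()")
    bs <- tm$basis_spec
    refs <- if (tm$order == 2L) c(base$params$sw2_in, base$params$sw2_out)
            else c(base$params$sw3_in, base$params$sw3_out)
    if (abs(bs$sw_in - refs[1]) > 1e-9 || abs(bs$sw_out - refs[2]) > 1e-9)
      stop(sprintf("switching radii of the fitted %dB term (%.2f, %.2f) do not match the base potential (%.2f, %.2f)",
                   tm$order, bs$sw_in, bs$sw_out, refs[1], refs[2]))
  }
  if (!is.null(two_body)) {
    if (two_body$order != 2L) stop("two_body term must have order 2")
    pot$fitted_2b <- two_body
    pot$use_native_2b <- FALSE
  }
  if (!is.null(three_body)) {
    if (three_body$order != 3L) stop("three_body term must have order 3")
    pot$fitted_3b <- three_body
    pot$use_native_3b <- FALSE
  }
  pot$level_tag <- if (!is.null(label)) label else {
    sw <- c(if (!is.null(two_body)) "2B", if (!is.null(three_body)) "3B")
    if (length(sw)) paste0("(", paste(sw, collapse = "+"), ")-", base$level_tag)
    else base$level_tag
  }
  pot
}

#' @export
print.mbw_potential <- function(x, ...) {
  cat(sprintf("<mbw_potential '%s': 2B %s, 3B %s%s>\n", x$level_tag,
              if (x$use_native_2b) "native" else "fitted",
              if (x$use_native_3b) "native" else "fitted",
              if (any(x$distortion != 0))
                sprintf("; distortion rep=%+.2f disp=%+.2f 3b=%+.2f",
                        x$distortion[1], x$distortion[2], x$distortion[3])
              else ""))
  invisible(x)
}

# parameters passed to the C++ kernel, with native-term flags
.cpp_params <- function(pot) {
  p <- pot$params
  p$use2b <- pot$use_native_2b
  p$use3b <- pot$use_native_3b
  p$scf_maxit <- as.integer(p$scf_maxit)
  p
}

.eval_core <- function(pot, cfg, do_forces) {
  box <- if (is.null(cfg$box_edge)) -1.0 else cfg$box_edge
  res <- water_eval_cpp(cfg$coords, box, .cpp_params(pot), do_forces)
  # fitted short-range terms evaluated in R (sum over molecule pairs/triples)
  if (!pot$use_native_2b && !is.null(pot$fitted_2b)) {
    ft <- .eval_fitted(pot$fitted_2b, cfg, do_forces)
    res$energy <- res$energy + ft$energy
    res$terms[["short_2b"]] <- ft$energy
    if (do_forces) res$forces <- res$forces + ft$forces
  }
  if (!pot$use_native_3b && !is.null(pot$fitted_3b)) {
    ft <- .eval_fitted(pot$fitted_3b, cfg, do_forces)
    res$energy <- res$energy + ft$energy
    res$terms[["short_3b"]] <- ft$energy
    if (do_forces) res$forces <- res$forces + ft$forces
  }
  res
}

#' Evaluate the total potential energy of a configuration
#'
#' For clusters all interactions are summed directly; for periodic
#' configurations pairwise terms use the minimum image convention within the
#' real-space cutoff and permanent electrostatics use the Ewald sum.
#'
#' @param potential an `mbw_potential`.
#' @param config an `mbw_config`.
#' @param terms if `TRUE`, return the named per-term breakdown instead of the
#'   bare total.
#' @return total energy in kcal/mol (scalar), or a named vector of term
#'   energies when `terms = TRUE`.
#' @export
evaluate_energy <- function(potential, config, terms = FALSE) {
  stopifnot(inherits(potential, "mbw_potential"), inherits(config, "mbw_config"))
  res <- .eval_core(potential, config, FALSE)
  if (terms) c(res$terms, total = res$energy) else res$energy
}

#' Evaluate analytic forces
#'
#' Negative gradient of [evaluate_energy()], including the induced-dipole
#' response through the variational (self-consistent) condition.
#'
#' @inheritParams evaluate_energy
#' @return `n_atoms x 3` matrix of forces in kcal/mol/A, with the total
#'   energy attached as attribute `"energy"`.
#' @export
evaluate_forces <- function(potential, config) {
  stopifnot(inherits(potential, "mbw_potential"), inherits(config, "mbw_config"))
  res <- .eval_core(potential, config, TRUE)
  structure(res$forces, energy = res$energy)
}

#' Solve the self-consistent induced dipoles
#'
#' Fixed-point iteration of the Thole-damped dipole equations to a residual
#' below `scf_tol` (max norm of the dipole update).  Non-convergence raises
#' an error carrying the smallest eigenvalue of the polarization matrix as a
#' diagnostic for a polarization catastrophe.
#'
#' @param config an `mbw_config`.
#' @param params parameter list as in [default_water_params()].
#' @return list with `dipoles` (`n_mol x 3`, e*A), `energy` (induction
#'   energy, kcal/mol) and `iterations`.
#' @export
solve_induced_dipoles <- function(config, params = default_water_params()) {
  pot <- make_truth_potential(params)
  res <- .eval_core(pot, config, FALSE)
  list(dipoles = res$dipoles, energy = unname(res$terms[["induction"]]),
       iterations = res$scf_iters)
}

#' Locally minimize a configuration under a potential
#'
#' L-BFGS-B minimization with analytic forces until the largest force
#' component falls below `gtol`.
#'
#' @param potential an `mbw_potential`.
#' @param config starting `mbw_config` (cluster).
#' @param gtol convergence threshold on the max abs force component
#'   (kcal/mol/A).
#' @param maxit iteration budget per L-BFGS-B restart.
#' @param restarts number of restarts before giving up.
#' @return the minimized `mbw_config`, with attributes `energy` (kcal/mol)
#'   and `max_force`.
#' @export
local_minimize <- function(potential, config, gtol = 1e-4, maxit = 500L,
                           restarts = 8L) {
  x0 <- as.vector(t(config$coords))
  shape <- function(x) configuration(matrix(x, ncol = 3, byrow = TRUE),
                                     config$elements, config$molecule,
                                     config$box_edge, validate = FALSE)
  fn <- function(x) tryCatch(evaluate_energy(potential, shape(x)),
                             error = function(e) 1e8)
  gr <- function(x) tryCatch(
    -as.vector(t(evaluate_forces(potential, shape(x)))),
    error = function(e) numeric(length(x)))
  e0 <- fn(x0)
  if (!is.finite(e0)) stop("non-finite starting energy")
  x <- x0
  # stage 1: damped steepest descent with a capped step keeps a strained
  # starting structure inside its own basin before the quasi-Newton polish
  e <- e0
  step <- 0.02
  for (k in 1:200) {
    g <- gr(x)
    gm <- max(abs(g))
    if (gm < gtol) break
    xn <- x - g * min(step / gm, 0.05)
    en <- fn(xn)
    if (en < e) { x <- xn; e <- en; step <- min(step * 1.2, 0.05) }
    else step <- step / 2
    if (step < 1e-6) break
  }
  mf <- max(abs(gr(x)))
  for (k in seq_len(restarts)) {
    if (mf < gtol) break
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    x <- opt$par
    mf <- max(abs(gr(x)))
  }
  if (mf >= gtol)
    stop(sprintf("minimization did not reach gtol = %g (max force %g)",
                 gtol, mf))
  out <- shape(x)
  out <- configuration(out$coords, out$elements, out$molecule, out$box_edge)
  attr(out, "energy") <- fn(x)
  attr(out, "max_force") <- mf
  out
}

#' Strip the explicit short-range terms from a potential
#'
#' Returns the potential with the short-range 2B and/or 3B terms disabled,
#' leaving the 1B term and the classical many-body baseline (permanent
#' electrostatics + induction + dispersion).  Used to form residual training
#' labels: a fitted short-range term should be trained on
#' `n-body(reference) - n-body(baseline_only(base))` so that
#' `baseline + fitted term` reproduces the reference (see [label_set()]).
#'
#' @param potential an `mbw_potential`.
#' @param two_body,three_body which short-range terms to strip.
#' @return an `mbw_potential`.
#' @export
baseline_only <- function(potential, two_body = TRUE, three_body = TRUE) {
  pot <- potential
  if (two_body) { pot$use_native_2b <- FALSE; pot$fitted_2b <- NULL }
  if (three_body) { pot$use_native_3b <- FALSE; pot$fitted_3b <- NULL }
  pot$level_tag <- paste0(potential$level_tag, "-baseline")
  pot
}

#' Point-charge Ewald sum for a periodic cubic box
#'
#' Real-space (erfc-screened, minimum image) + reciprocal + self terms for an
#' arbitrary neutral set of point charges.  Screening and reciprocal-space
#' extent are chosen automatically from the accuracy target.
#'
#' @param coords `n x 3` matrix (A).
#' @param charges numeric vector (e); must sum to ~0.
#' @param box_edge cubic box edge (A).
#' @param cutoff real-space cutoff (A), at most half the box edge.
#' @param tol target relative accuracy.
#' @param forces also return forces.
#' @return list with `energy` (kcal/mol) and, if requested, `forces`
#'   (kcal/mol/A), plus the chosen `alpha` and reciprocal extent `nmax`.
#' @export
ewald_energy <- function(coords, charges, box_edge, cutoff = box_edge / 2,
                         tol = 1e-6, forces = FALSE) {
  res <- ewald_cpp(as.matrix(coords), as.numeric(charges), box_edge, cutoff,
                   tol, forces)
  if (!forces) res$forces <- NULL
  res
}
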