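# Many-body expansion: per-subset cluster energies, recursive n-body terms
# via the alternating-sum (Moebius) equivalent, full decompositions and
# stratified (mixed-level) totals.

.subset_key <- function(subset) paste(sort(as.integer(subset)), collapse = ",")

# memoised raw subset energies at frozen in-cluster geometry
.subset_energy_env <- function(config, potential) {
  memo <- new.env(parent = emptyenv())
  function(subset) {
    key <- .subset_key(subset)
    val <- memo[[key]]
    if (is.null(val)) {
      val <- evaluate_energy(potential, subset_molecules(config, subset))
      memo[[key]] <- val
    }
    val
  }
}

#' Energy of a molecular sub-cluster at frozen geometry
#'
#' @param config an `mbw_config` cluster (non-periodic).
#' @param potential an `mbw_potential`.
#' @param subset molecule indices (non-empty, no duplicates).
#' @return energy in kcal/mol.
#' @export
subset_energy <- function(config, potential, subset) {
  if (!is.null(config$box_edge))
    stop("MBE subset energies are defined for non-periodic clusters")
  evaluate_energy(potential, subset_molecules(config, subset))
}

#' n-body energy of a molecule subset
#'
#' The n-body term is the part of the subset energy not explained by all
#' lower-order terms.  It is computed with the closed-form alternating sum
#' `E^nB(S) = sum over non-empty T subset of S of (-1)^(|S|-|T|) E(T)`,
#' which is the Moebius inversion of the recursive definition (both agree
#' identically).
#'
#' @inheritParams subset_energy
#' @param .energy_fn internal memoised energy closure.
#' @return the n-body energy in kcal/mol (n = length of `subset`).
#' @export
nbody_term <- function(config, potential, subset, .energy_fn = NULL) {
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("duplicate molecule indices")
  if (is.null(.energy_fn)) .energy_fn <- .subset_energy_env(config, potential)
  n <- length(subset)
  total <- 0
  for (k in seq_len(n)) {
    sgn <- (-1)^(n - k)
    combs <- utils::combn(subset, k)
    for (j in seq_len(ncol(combs)))
      total <- total + sgn * .energy_fn(combs[, j])
  }
  total
}

#' Full many-body decomposition of a cluster energy
#'
#' Enumerates every molecule subset up to `max_order`, computes the n-body
#' terms, and accumulates per-order sums.  With the `"in_cluster"` monomer
#' reference the sum of all order sums up to the full order equals the
#' interaction energy `E_N - sum E(monomer at frozen geometry)` exactly
#' (telescoping); with the `"isolated"` reference the 1B terms are monomer
#' deformation energies relative to the optimized monomer, matching the
#' definition of the 1B energy as the energy required to deform each molecule
#' from its equilibrium geometry.
#'
#' @param config an `mbw_config` cluster of N molecules.
#' @param potential an `mbw_potential`.
#' @param max_order highest order to enumerate (1..N).
#' @param reference monomer reference convention, `"in_cluster"` (default;
#'   1B terms are zero and the expansion reconstructs the interaction
#'   energy) or `"isolated"` (1B terms are deformation energies).
#' @param force allow full-order decompositions beyond 12 molecules (2^N
#'   subset blow-up guard).
#' @return an object of class `mbw_mbe` with `subset_energies`,
#'   `nbody_terms`, `order_sums`, `fractions` (per-order percentage of the
#'   reconstructed total), `max_order`, `reference`, `e_total` and
#'   `e_monomers`.
#' @export
mbe_decompose <- function(config, potential, max_order,
                          reference = c("in_cluster", "isolated"),
                          force = FALSE) {
  reference <- match.arg(reference)
  N <- n_molecules(config)
  if (max_order < 1L || max_order > N)
    stop("max_order must be between 1 and the number of molecules")
  if (N > 12L && max_order >= N && !force)
    stop("full-order decomposition beyond 12 molecules is refused unless force = TRUE")
  efn <- .subset_energy_env(config, potential)
  e_mono <- vapply(seq_len(N), function(i) efn(i), numeric(1))
  ref_1b <- if (reference == "isolated") {
    e_opt <- evaluate_energy(potential, reference_monomer())
    rep(e_opt, N)
  } else e_mono
  subset_energies <- list()
  nbody_terms <- list()
  order_sums <- stats::setNames(numeric(max_order),
                                paste0(seq_len(max_order), "B"))
  for (n in seq_len(max_order)) {
    combs <- utils::combn(N, n)
    for (j in seq_len(ncol(combs))) {
      s <- combs[, j]
      key <- .subset_key(s)
      subset_energies[[key]] <- efn(s)
      term <- if (n == 1L) e_mono[s] - ref_1b[s]
              else nbody_term(config, potential, s, .energy_fn = efn)
      nbody_terms[[key]] <- term
      order_sums[n] <- order_sums[n] + term
    }
  }
  total_rec <- sum(order_sums)
  structure(list(
    subset_energies = subset_energies, nbody_terms = nbody_terms,
    order_sums = order_sums,
    fractions = if (abs(total_rec) > 0) 100 * order_sums / total_rec
                else order_sums * NA,
    max_order = max_order, reference = reference,
    e_total = evaluate_energy(potential, config),
    e_monomers = e_mono, n_molecules = N),
    class = "mbw_mbe")
}

#' @export
print.mbw_mbe <- function(x, ...) {
  cat(sprintf("<mbw_mbe: %d molecules, orders 1..%d, reference %s>\n",
              x$n_molecules, x$max_order, x$reference))
  tab <- data.frame(order = names(x$order_sums),
                    energy_kcal_mol = unname(x$order_sums),
                    percent = unname(x$fractions))
  print(tab, row.names = FALSE, digits = 6)
  if (x$max_order == x$n_molecules)
    cat(sprintf("telescoping residual: %.3g kcal/mol\n", mbe_residual(x)))
  invisible(x)
}

#' Telescoping residual of a full-order decomposition
#'
#' For `max_order = N` the reconstruction
#' `sum_n order_sums[n]` must equal `E_N - sum_i reference_i` exactly; this
#' returns the difference (should be ~1e-12 kcal/mol).
#'
#' @param dec an `mbw_mbe` with `max_order == n_molecules`.
#' @return residual in kcal/mol.
#' @export
mbe_residual <- function(dec) {
  stopifnot(inherits(dec, "mbw_mbe"))
  if (dec$max_order != dec$n_molecules)
    stop("telescoping requires a full-order decomposition")
  interaction <- dec$e_total - sum(dec$e_monomers)
  onebody <- if (dec$reference == "isolated") dec$order_sums[1] else 0
  sum(dec$order_sums) - onebody - interaction
}

#' Stratified (mixed-level) cluster energy
#'
#' Evaluates each many-body order with its own potential ("level of
#' theory"): orders 1..`max_order` with the potentials in `levels`, all
#' higher orders with `levels$rest`.  With a single level for every order the
#' result collapses to that level's full decomposition total.
#'
#' @param config an `mbw_config` cluster of N molecules.
#' @param levels named list of `mbw_potential`s: entries `"1"`, `"2"`, ...
#'   up to `max_order` (a potential may be repeated), plus `"rest"` for
#'   orders above `max_order` (required when `max_order < N`).
#' @param max_order highest explicitly stratified order.
#' @param reference monomer reference convention (see [mbe_decompose()]).
#' @return list with `total` (the stratified reconstructed total, kcal/mol)
#'   and `order_sums` (per-order contributions, the `>max_order` tail
#'   collapsed into one entry).
#' @export
samba_energy <- function(config, levels, max_order,
                         reference = c("in_cluster", "isolated")) {
  reference <- match.arg(reference)
  N <- n_molecules(config)
  for (n in seq_len(max_order))
    if (is.null(levels[[as.character(n)]]))
      stop("missing level for order ", n)
  if (max_order < N && is.null(levels$rest))
    stop("missing 'rest' level for orders above max_order")
  pots <- unique(c(lapply(seq_len(max_order),
                          function(n) levels[[as.character(n)]]),
                   if (max_order < N) list(levels$rest)))
  decs <- lapply(pots, function(p)
    mbe_decompose(config, p, max_order, reference = reference))
  which_pot <- function(p) which(vapply(pots, identical, logical(1), p))[1]
  sums <- numeric(0)
  total <- 0
  for (n in seq_len(max_order)) {
    d <- decs[[which_pot(levels[[as.character(n)]])]]
    sums[paste0(n, "B")] <- d$order_sums[n]
    total <- total + d$order_sums[n]
  }
  if (max_order < N) {
    pr <- levels$rest
    dr <- decs[[which_pot(pr)]]
    # tail = (full reconstruction) - (orders <= max_order), without a full
    # 2^N enumeration: telescoping gives sum_all = E_N - sum E(monomers)
    # (+ 1B deformation under the isolated reference)
    full <- dr$e_total - sum(dr$e_monomers) +
      (if (reference == "isolated") dr$order_sums[1] else 0)
    tail <- full - sum(dr$order_sums)
    sums[paste0(">", max_order, "B")] <- tail
    total <- total + tail
  }
  list(total = total, order_sums = sums)
}

#' Write a decomposition report as a delimited table
#'
#' One row per subset: molecule indices, order, subset energy, n-body term
#' and the cumulative percentage of the reconstructed total.
#'
#' @param dec an `mbw_mbe`.
#' @param path output path (tab-separated).
#' @return the data frame, invisibly.
#' @export
write_mbe_table <- function(dec, path) {
  keys <- names(dec$nbody_terms)
  ord <- lengths(strsplit(keys, ","))
  tab <- data.frame(subset = keys, order = ord,
                    subset_energy = unlist(dec$subset_energies[keys]),
                    nbody_term = unlist(dec$nbody_terms[keys]))
  tab <- tab[order(tab$order, tab$subset), ]
  tot <- sum(dec$order_sums)
  tab$cumulative_percent <- if (abs(tot) > 0)
    100 * cumsum(tab$nbody_term) / tot else NA_real_
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
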