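# Structural observables: tetrahedral order parameter, bead-averaged q
# distributions and radial distribution functions, hexamer isomer tables.

#' Tetrahedral order parameter from four neighbor directions
#'
#' `q = 1 - 3/8 * sum_{j<k} (cos psi_jk + 1/3)^2` over the six angle pairs
#' formed by four neighbor directions seen from a central site.  q = 1 for a
#' perfect tetrahedral arrangement, 0 on average for random directions, and
#' the global minimum -3 when all four neighbors coincide in direction.
#'
#' @param dirs `4 x 3` matrix of neighbor direction vectors (not necessarily
#'   normalized).
#' @return scalar q.
#' @export
q_tet_from_vectors <- function(dirs) {
  stopifnot(nrow(dirs) == 4)
  u <- dirs / sqrt(rowSums(dirs^2))
  s <- 0
  for (j in 1:3) for (k in (j + 1):4)
    s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
  1 - 3 / 8 * s
}

#' Tetrahedral order parameter of a molecule in a configuration
#'
#' The four nearest oxygen neighbors of the central molecule's O atom are
#' found (minimum image for periodic systems, ties broken by molecule
#' index) and the six O-O-O angles at the central O enter the sum.
#'
#' @param config an `mbw_config` with at least 5 molecules.
#' @param center central molecule index.
#' @return scalar q.
#' @export
q_tet <- function(config, center) {
  nm <- n_molecules(config)
  if (nm < 5) stop("q_tet needs at least 4 neighbor molecules")
  o_idx <- 3L * (seq_len(nm) - 1L) + 1L
  ro <- config$coords[o_idx[center], ]
  others <- setdiff(seq_len(nm), center)
  d <- t(vapply(others, function(m)
    .min_image(config$coords[o_idx[m], ] - ro, config$box_edge), numeric(3)))
  r <- sqrt(rowSums(d^2))
  nb <- order(r)[1:4]                      # stable: ties broken by index
  q_tet_from_vectors(d[nb, , drop = FALSE])
}

#' Bead-averaged distribution of the tetrahedral order parameter
#'
#' q is computed for every molecule, frame and bead of a liquid trajectory
#' and histogrammed; the distribution is normalized to unit integral.
#'
#' @param traj an `mbw_trajectory` over a periodic water system.
#' @param bins bin edges over q (default `seq(-3, 1, by = 0.02)` restricted
#'   to the observed range is not applied; fixed edges keep overlays
#'   comparable).
#' @return an object of class `mbw_qdist` with `bin_edges`, `mids`,
#'   `density` (integrating to 1) and `n_samples`.
#' @export
q_tet_distribution <- function(traj, bins = seq(-1, 1, by = 0.02)) {
  if (!length(traj$frames)) stop("empty trajectory")
  tmpl <- traj$template
  if (!inherits(tmpl, "mbw_config"))
    stop("trajectory was not run on a water configuration")
  qs <- numeric(0)
  for (f in seq_along(traj$frames)) {
    box <- if (is.na(traj$box[f])) NULL else traj$box[f]
    arr <- traj$frames[[f]]
    for (s in seq_len(dim(arr)[1])) {
      cfg <- configuration(arr[s, , ], tmpl$elements, tmpl$molecule, box,
                           validate = FALSE)
      qs <- c(qs, vapply(seq_len(n_molecules(cfg)), function(m)
        q_tet(cfg, m), numeric(1)))
    }
  }
  qs <- pmin(pmax(qs, min(bins)), max(bins))
  h <- graphics::hist(qs, breaks = bins, plot = FALSE)
  structure(list(bin_edges = bins, mids = h$mids, density = h$density,
                 n_samples = length(qs)),
            class = "mbw_qdist")
}

#' @export
print.mbw_qdist <- function(x, ...) {
  cat(sprintf("<mbw_qdist: %d samples, mean q = %.3f, integral = %.6f>\n",
              x$n_samples, sum(x$mids * x$density * diff(x$bin_edges)),
              sum(x$density * diff(x$bin_edges))))
  invisible(x)
}

.pair_kind_idx <- function(cfg, pair_kind) {
  o <- which(cfg$elements == "O"); h <- which(cfg$elements == "H")
  switch(pair_kind,
         OO = list(a = o, b = o, same = TRUE),
         HH = list(a = h, b = h, same = TRUE),
         OH = list(a = o, b = h, same = FALSE),
         stop("pair_kind must be OO, OH or HH"))
}

#' Bead-averaged radial distribution function
#'
#' Same-bead pair distances (minimum image) are histogrammed over all frames
#' and beads and normalized by the ideal-gas shell counts at the frame
#' density.  Intramolecular pairs are excluded.  This is the standard PIMD
#' pair-correlation estimator; cross-bead pairs are not counted.
#'
#' @param traj an `mbw_trajectory` over a periodic water system.
#' @param pair_kind `"OO"`, `"OH"` or `"HH"`.
#' @param r_max maximum distance (default: half the smallest box edge).
#' @param dr bin width in A (default 0.05).
#' @return an object of class `mbw_rdf` with `r` (bin centers), `g`,
#'   `pair_kind`, `n_frames` and `density` (molecules/A^3).
#' @export
compute_rdf <- function(traj, pair_kind = "OO", r_max = NULL, dr = 0.05) {
  if (!length(traj$frames)) stop("empty trajectory")
  tmpl <- traj$template
  if (any(is.na(traj$box))) stop("RDF requires a periodic trajectory")
  Lmin <- min(traj$box)
  if (is.null(r_max)) r_max <- Lmin / 2
  if (r_max > Lmin / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge")
  idx <- .pair_kind_idx(list(elements = tmpl$elements), pair_kind)
  edges <- seq(0, r_max, by = dr)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + dr)
  counts <- numeric(length(edges) - 1L)
  n_obs <- 0L
  mol <- tmpl$molecule
  pairs <- NULL
  if (idx$same) {
    pr <- utils::combn(idx$a, 2L)
    keep <- mol[pr[1, ]] != mol[pr[2, ]]
    pairs <- pr[, keep, drop = FALSE]
  } else {
    pr <- as.matrix(expand.grid(idx$a, idx$b))
    keep <- mol[pr[, 1]] != mol[pr[, 2]]
    pairs <- t(pr[keep, , drop = FALSE])
  }
  vol_sum <- 0
  for (f in seq_along(traj$frames)) {
    L <- traj$box[f]
    arr <- traj$frames[[f]]
    for (s in seq_len(dim(arr)[1])) {
      x <- arr[s, , ]
      d <- x[pairs[1, ], , drop = FALSE] - x[pairs[2, ], , drop = FALSE]
      d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      r <- r[r < max(edges)]
      counts <- counts + tabulate(findInterval(r, edges), length(counts))
      n_obs <- n_obs + 1L
      vol_sum <- vol_sum + L^3
    }
  }
  V <- vol_sum / n_obs
  n_pairs <- ncol(pairs)
  mids <- edges[-length(edges)] + dr / 2
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / n_obs / (n_pairs * shell / V)
  structure(list(r = mids, g = g, pair_kind = pair_kind, n_frames = n_obs,
                 density = (length(tmpl$elements) / 3) / V),
            class = "mbw_rdf")
}

#' @export
print.mbw_rdf <- function(x, ...) {
  cat(sprintf("<mbw_rdf %s: %d bins to %.2f A, %d frame-beads>\n",
              x$pair_kind, length(x$r), max(x$r), x$n_frames))
  invisible(x)
}

#' Write an RDF or q distribution as a two-column delimited table
#'
#' @param x an `mbw_rdf` or `mbw_qdist`.
#' @param path output path.
#' @param meta named character vector written as `# key: value` header lines
#'   (ensemble, temperature, beads, potential tag, ...).
#' @return `path`, invisibly.
#' @export
write_distribution_table <- function(x, path, meta = character()) {
  hdr <- sprintf("# %s: %s", names(meta), meta)
  if (inherits(x, "mbw_rdf"))
    body <- sprintf("%.6f\t%.8f", x$r, x$g)
  else if (inherits(x, "mbw_qdist"))
    body <- sprintf("%.6f\t%.8f", x$mids, x$density)
  else stop("unsupported object")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Relative energies of hexamer isomers under a stack of potentials
#'
#' Each isomer is evaluated under every potential; per potential the
#' energies are shifted so the lowest isomer is zero.  When `parents` maps a
#' hybrid potential to its parent full potential, the per-isomer deviation
#' of relative energies from the parent is reported.
#'
#' @param potentials named list of `mbw_potential`s.
#' @param isomers named list of `mbw_config` clusters (normally locally
#'   minimized under a designated geometry-defining potential).
#' @param parents optional named character vector: `parents["hybrid"] =
#'   "parent"`.
#' @param force_tol geometries whose max force under the first potential
#'   exceeds this are flagged in the metadata (warning recorded, not
#'   raised).
#' @return data frame of relative energies (isomers x potentials) with
#'   attributes `deviations` (list of matrices per hybrid) and `metadata`.
#' @export
isomer_relative_energies <- function(potentials, isomers, parents = NULL,
                                     force_tol = 1e-3) {
  stopifnot(length(potentials) >= 1, length(isomers) >= 2)
  E <- sapply(potentials, function(pot)
    vapply(isomers, function(cfg) evaluate_energy(pot, cfg), numeric(1)))
  E <- matrix(E, nrow = length(isomers),
              dimnames = list(names(isomers), names(potentials)))
  rel <- sweep(E, 2L, apply(E, 2L, min))
  meta <- list(warnings = character())
  mf <- vapply(isomers, function(cfg)
    max(abs(evaluate_forces(potentials[[1]], cfg))), numeric(1))
  bad <- names(isomers)[mf > force_tol]
  if (length(bad))
    meta$warnings <- sprintf(
      "isomer '%s' max force %.3g exceeds tolerance %.1g (unminimized input?)",
      bad, mf[bad], force_tol)
  meta$max_forces <- mf
  devs <- NULL
  if (!is.null(parents)) {
    devs <- lapply(names(parents), function(h)
      rel[, h] - rel[, parents[[h]]])
    names(devs) <- names(parents)
  }
  out <- as.data.frame(rel)
  attr(out, "deviations") <- devs
  attr(out, "metadata") <- meta
  out
}
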