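# Generators for every input the pipeline needs: dimer/trimer training sets,
# hexamer templates, periodic liquid boxes and labeled energy sets.  All
# generators are deterministic under a fixed seed.

# run expr with a local RNG seeded at `seed`, restoring the caller's RNG
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# perturbed monomer about the reference geometry (sigma_r in A, sigma_a rad)
.perturbed_monomer <- function(sigma_r, sigma_a) {
  r1 <- 0.9572 + stats::rnorm(1, 0, sigma_r)
  r2 <- 0.9572 + stats::rnorm(1, 0, sigma_r)
  th <- 104.52 * pi / 180 + stats::rnorm(1, 0, sigma_a)
  h <- th / 2
  rbind(c(0, 0, 0),
        c(r1 * sin(h), 0, r1 * cos(h)),
        c(-r2 * sin(h), 0, r2 * cos(h)))
}

.random_unit <- function() {
  z <- stats::rnorm(3)
  z / sqrt(sum(z^2))
}

.place_random_monomer <- function(origin, sigma_r, sigma_a) {
  m <- .perturbed_monomer(sigma_r, sigma_a)
  sweep(m %*% t(.random_rotation()), 2L, origin, "+")
}

.min_intermolecular <- function(coords, mol, L = NULL) {
  n <- nrow(coords)
  best <- Inf
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (mol[i] == mol[j]) next
    d <- .min_image(coords[j, ] - coords[i, ], L)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

#' Sample a set of water dimers
#'
#' O-O distances are uniform in `r_range`, molecular orientations uniform on
#' the rotation group (quaternion sampling), and intramolecular geometries
#' are perturbed about the reference monomer by Gaussian displacements.
#' Configurations with any intermolecular atom-atom contact below 1.2 A are
#' rejected and resampled.
#'
#' @param n number of dimers.
#' @param r_range `c(min, max)` O-O distance range in A, `0 < min < max`.
#' @param seed integer seed (deterministic output).
#' @param sigma_r,sigma_a intramolecular perturbation widths (A for bonds,
#'   radians for the angle; defaults 0.02 A and 2 degrees).
#' @return list of `mbw_config` dimers.
#' @export
sample_dimer_set <- function(n, r_range, seed,
                             sigma_r = 0.02, sigma_a = 2 * pi / 180) {
  stopifnot(n >= 1)
  if (!(length(r_range) == 2 && r_range[1] > 0 && r_range[1] < r_range[2]))
    stop("r_range must satisfy 0 < min < max")
  .with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      repeat {
        r <- stats::runif(1, r_range[1], r_range[2])
        c1 <- .place_random_monomer(c(0, 0, 0), sigma_r, sigma_a)
        c2 <- .place_random_monomer(r * .random_unit(), sigma_r, sigma_a)
        coords <- rbind(c1, c2)
        if (.min_intermolecular(coords, rep(1:2, each = 3)) >= 1.2) break
      }
      out[[k]] <- configuration(coords)
    }
    out
  })
}

#' Sample a set of water trimers
#'
#' All three O-O pair distances fall in `r_range`; otherwise as
#' [sample_dimer_set()].
#'
#' @inheritParams sample_dimer_set
#' @return list of `mbw_config` trimers.
#' @export
sample_trimer_set <- function(n, r_range, seed,
                              sigma_r = 0.02, sigma_a = 2 * pi / 180) {
  stopifnot(n >= 1)
  if (!(length(r_range) == 2 && r_range[1] > 0 && r_range[1] < r_range[2]))
    stop("r_range must satisfy 0 < min < max")
  .with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      repeat {
        r12 <- stats::runif(1, r_range[1], r_range[2])
        r13 <- stats::runif(1, r_range[1], r_range[2])
        # third O in the xz plane at angle phi from O2 direction
        phi <- stats::runif(1, 0, pi)
        o2 <- c(r12, 0, 0)
        o3 <- r13 * c(cos(phi), 0, sin(phi))
        r23 <- sqrt(sum((o3 - o2)^2))
        if (r23 < r_range[1] || r23 > r_range[2]) next
        rot <- .random_rotation()     # random overall orientation
        os <- rbind(c(0, 0, 0), o2, o3) %*% t(rot)
        coords <- rbind(.place_random_monomer(os[1, ], sigma_r, sigma_a),
                        .place_random_monomer(os[2, ], sigma_r, sigma_a),
                        .place_random_monomer(os[3, ], sigma_r, sigma_a))
        if (.min_intermolecular(coords, rep(1:3, each = 3)) >= 1.2) break
      }
      out[[k]] <- configuration(coords)
    }
    out
  })
}

#' Build a periodic liquid water box
#'
#' Molecules are placed on a jittered cubic lattice with uniformly random
#' orientations inside a cubic box whose edge is set by the requested mass
#' density.  Placement is retried (bounded) until no intermolecular
#' atom-atom contact is below 1.5 A under the minimum image convention.
#'
#' @param n_molecules number of water molecules (>= 2).
#' @param density mass density in g/cm^3 (default 0.997, ambient liquid
#'   water).
#' @param seed integer seed.
#' @param max_retries placement retries before giving up.
#' @return a periodic `mbw_config`.
#' @export
build_liquid_box <- function(n_molecules, density = 0.997, seed,
                             max_retries = 200L) {
  stopifnot(n_molecules >= 2, density > 0)
  L <- box_edge_for_density(n_molecules, density)
  .with_seed(seed, {
    # checkerboard sites double the nearest-site spacing over a plain lattice
    n_side <- ceiling((2 * n_molecules)^(1 / 3))
    spacing <- L / n_side
    grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                  z = seq_len(n_side)))
    grid <- grid[rowSums(grid) %% 2L == 0L, , drop = FALSE]
    mol_ids <- rep(seq_len(n_molecules), each = 3L)
    for (attempt in seq_len(max_retries)) {
      sites <- grid[sample(nrow(grid), n_molecules), , drop = FALSE]
      centers <- (sites - 0.5) * spacing +
        matrix(stats::rnorm(3 * n_molecules, 0, 0.05 * spacing), ncol = 3)
      coords <- matrix(NA_real_, 3 * n_molecules, 3)
      ok <- TRUE
      for (m in seq_len(n_molecules)) {
        placed <- FALSE
        for (try in 1:50) {
          cand <- .place_random_monomer(centers[m, ], 0.01, pi / 180)
          rows <- seq_len(3 * (m - 1L))
          clash <- FALSE
          if (length(rows)) {
            for (a in 1:3) {
              d <- sweep(coords[rows, , drop = FALSE], 2L, cand[a, ])
              d <- d - L * round(d / L)
              if (min(rowSums(d^2)) < 1.5^2) { clash <- TRUE; break }
            }
          }
          if (!clash) {
            coords[3L * (m - 1L) + 1:3, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok && .min_intermolecular(coords, mol_ids, L) >= 1.5)
        return(configuration(coords, box_edge = L))
    }
    stop("could not place molecules without contacts below 1.5 A at this density")
  })
}

# O-atom skeletons of the low-lying hexamer isomers (A) and their hydrogen
# bond donor patterns (row i donates its first OH toward molecule donors[i];
# NA = point the OH away from the cluster center).  Documented geometric
# templates with nearest O-O near 2.8 A, meant as starting points for local
# minimization -- not literature coordinates.
.hexamer_skeletons <- function() {
  d <- 2.8
  cyc <- t(vapply(0:5, function(k)
    d * c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  tri <- function(z) {
    R <- d / sqrt(3)
    t(vapply(0:2, function(k)
      c(R * cos(2 * pi * k / 3), R * sin(2 * pi * k / 3), z), numeric(3)))
  }
  prism <- rbind(tri(0), tri(d))
  book <- rbind(c(0, 0, 0), c(d, 0, 0),
                c(0, d, 0), c(d, d, 0),
                c(0, d + d * cos(1.1 * pi / 3), d * sin(1.1 * pi / 3)),
                c(d, d + d * cos(1.1 * pi / 3), d * sin(1.1 * pi / 3)))
  cage <- rbind(c(0, 0, 2.6), c(0, 0, -2.6),
                c(1.95, 0, 0.45), c(-1.95, 0, 0.45),
                c(0, 1.95, -0.45), c(0, -1.95, -0.45))
  list(
    prism = list(os = prism, donors = cbind(c(2, 3, 1, 5, 6, 4),
                                            c(4, 5, 6, NA, NA, NA))),
    cage = list(os = cage, donors = cbind(c(3, 5, 4, 2, 6, 1),
                                          rep(NA, 6))),
    book = list(os = book, donors = cbind(c(2, 4, 1, 3, 3, 5),
                                          c(NA, NA, NA, 6, NA, NA))),
    cyclic = list(os = cyc, donors = cbind(c(2, 3, 4, 5, 6, 1),
                                           rep(NA, 6))))
}

# orient the reference monomer at `origin`: first OH along d1; if d2 given,
# rotate about d1 so the second OH leans toward d2 (both unit targets)
.oriented_monomer <- function(origin, d1, d2 = NULL) {
  ref <- reference_monomer()$coords
  b1 <- ref[2, ] / sqrt(sum(ref[2, ]^2))
  d1 <- d1 / sqrt(sum(d1^2))
  rot_align <- function(a, b) {          # rotation taking unit a to unit b
    v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    s <- sqrt(sum(v^2)); c_ <- sum(a * b)
    if (s < 1e-12) { if (c_ > 0) return(diag(3)) else return(diag(c(-1, -1, 1))) }
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  R1 <- rot_align(b1, d1)
  if (!is.null(d2)) {
    b2 <- as.vector(R1 %*% (ref[3, ] / sqrt(sum(ref[3, ]^2))))
    # project b2 and d2 off d1, rotate about d1 to align the projections
    p2 <- b2 - sum(b2 * d1) * d1
    q2 <- d2 / sqrt(sum(d2^2)); q2 <- q2 - sum(q2 * d1) * d1
    if (sqrt(sum(p2^2)) > 1e-8 && sqrt(sum(q2^2)) > 1e-8) {
      p2 <- p2 / sqrt(sum(p2^2)); q2 <- q2 / sqrt(sum(q2^2))
      ang <- atan2(sum(d1 * c(p2[2] * q2[3] - p2[3] * q2[2],
                              p2[3] * q2[1] - p2[1] * q2[3],
                              p2[1] * q2[2] - p2[2] * q2[1])), sum(p2 * q2))
      K <- matrix(c(0, -d1[3], d1[2], d1[3], 0, -d1[1], -d1[2], d1[1], 0),
                  3, 3, byrow = TRUE)
      R1 <- (diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K) %*% R1
    }
  }
  sweep(ref %*% t(R1), 2L, origin, "+")
}

#' Geometric templates of the low-lying water hexamer isomers
#'
#' Returns six-molecule clusters built from documented O-atom skeletons
#' (prism, cage, book, cyclic) with each molecule oriented according to a
#' hydrogen-bond donor pattern appropriate to the isomer (ring chains for
#' the cyclic/book motifs, double donors in the prism).  These are starting
#' points intended for local minimization under a chosen potential, not
#' literature geometries.
#'
#' @param isomer optional isomer name; omit for all templates.
#' @return a named list of `mbw_config` (or a single one if `isomer` given).
#' @export
hexamer_templates <- function(isomer = NULL) {
  sk <- .hexamer_skeletons()
  build <- function(tmpl) {
    os <- tmpl$os
    ctr <- colMeans(os)
    coords <- do.call(rbind, lapply(seq_len(nrow(os)), function(i) {
      j1 <- tmpl$donors[i, 1]
      d1 <- if (is.na(j1)) os[i, ] - ctr else os[j1, ] - os[i, ]
      j2 <- tmpl$donors[i, 2]
      d2 <- if (is.na(j2)) os[i, ] - ctr else os[j2, ] - os[i, ]
      if (sqrt(sum(d2^2)) < 1e-8) d2 <- NULL
      .oriented_monomer(os[i, ], d1, d2)
    }))
    configuration(coords)
  }
  all <- lapply(sk, build)
  if (is.null(isomer)) return(all)
  if (!isomer %in% names(all))
    stop("unknown hexamer isomer '", isomer, "'; known: ",
         paste(names(all), collapse = ", "))
  all[[isomer]]
}

#' Label configurations with n-body energies from a potential
#'
#' Computes the requested n-body quantity for every configuration with the
#' many-body expansion under the given potential, optionally adding seeded
#' Gaussian noise.  This produces the reference ("truth") and surrogate
#' energy sets the fitting module trains and validates on.
#'
#' @param configs list of `mbw_config` clusters.
#' @param potential an `mbw_potential`.
#' @param order `1`, `2`, `3` or `"total"`.  Order 2 requires dimers and
#'   order 3 trimers; order 1 labels are summed deformation energies relative
#'   to the optimized monomer.
#' @param noise_sigma Gaussian noise width in kcal/mol (>= 0).
#' @param seed integer seed for the noise draw.
#' @param baseline optional `mbw_potential` (normally
#'   `baseline_only(truth)`): the same n-body quantity computed with it is
#'   subtracted from every label, producing the residual a swappable
#'   short-range term should be fitted to.
#' @return an object of class `mbw_labeled_set` with `configs`, `energies`,
#'   `order`, `level_tag` and `noise_sigma`.
#' @export
label_set <- function(configs, potential, order, noise_sigma = 0,
                      seed = NULL, baseline = NULL) {
  stopifnot(noise_sigma >= 0)
  if (inherits(configs, "mbw_config")) configs <- list(configs)
  ord_chr <- as.character(order)
  if (!ord_chr %in% c("1", "2", "3", "total"))
    stop("order must be 1, 2, 3 or 'total'")
  one <- function(cfg, potential) {
    nm <- n_molecules(cfg)
    if (ord_chr %in% c("2", "3")) {
      need <- as.integer(ord_chr)
      if (nm != need)
        stop(sprintf("order %s labels require %d-molecule clusters (got %d)",
                     ord_chr, need, nm))
      nbody_term(cfg, potential, seq_len(nm))
    } else if (ord_chr == "1") {
      e_opt <- evaluate_energy(potential, reference_monomer())
      sum(vapply(seq_len(nm), function(i)
        evaluate_energy(potential, subset_molecules(cfg, i)) - e_opt,
        numeric(1)))
    } else evaluate_energy(potential, cfg)
  }
  energies <- vapply(configs, one, numeric(1), potential = potential)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "mbw_potential"))
    energies <- energies - vapply(configs, one, numeric(1),
                                  potential = baseline)
  }
  if (noise_sigma > 0)
    energies <- energies + .with_seed(seed, stats::rnorm(length(energies),
                                                         0, noise_sigma))
  structure(list(configs = configs, energies = energies,
                 order = if (ord_chr == "total") "total"
                         else as.integer(ord_chr),
                 level_tag = potential$level_tag, noise_sigma = noise_sigma),
            class = "mbw_labeled_set")
}

#' @export
print.mbw_labeled_set <- function(x, ...) {
  cat(sprintf("<mbw_labeled_set: %d configs, order %s, level '%s', noise %g>\n",
              length(x$configs), x$order, x$level_tag, x$noise_sigma))
  invisible(x)
}
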