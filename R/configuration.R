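# Configuration container: a set of water molecules (each O,H,H in fixed
# order), optionally in a periodic cubic box.

#' Construct a water configuration
#'
#' A configuration holds atomic coordinates partitioned into water molecules.
#' Each molecule must consist of three atoms in the fixed order O, H, H.
#' A positive `box_edge` marks the configuration as periodic (cubic box);
#' `NULL` marks an isolated cluster.
#'
#' @param coords numeric matrix `n_atoms x 3`, Angstrom.
#' @param elements character vector of atomic symbols ("O"/"H").  Defaults to
#'   the O,H,H pattern implied by the number of atoms.
#' @param molecule integer vector mapping each atom to its molecule id
#'   (1-based, consecutive).  Defaults to `rep(1:(n/3), each = 3)`.
#' @param box_edge cubic box edge in Angstrom, or `NULL` for a cluster.
#' @param validate check invariants (O,H,H ordering, intramolecular O-H
#'   distances < 2 A).
#' @return an object of class `mbw_config`.
#' @export
configuration <- function(coords, elements = NULL, molecule = NULL,
                          box_edge = NULL, validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n %% 3L != 0L) stop("atom count must be a multiple of 3 (O,H,H waters)")
  nmol <- n %/% 3L
  if (is.null(elements)) elements <- rep(c("O", "H", "H"), nmol)
  if (is.null(molecule)) molecule <- rep(seq_len(nmol), each = 3L)
  cfg <- structure(
    list(coords = coords, elements = as.character(elements),
         molecule = as.integer(molecule),
         box_edge = if (is.null(box_edge)) NULL else as.numeric(box_edge)),
    class = "mbw_config")
  if (validate) validate_config(cfg)
  cfg
}

#' Validate the invariants of a configuration
#'
#' Checks that every molecule id maps to exactly three atoms in O,H,H order,
#' that intramolecular O-H distances are below 2.0 A, that coordinates are
#' finite, and that `box_edge` (when present) is positive.
#'
#' @param cfg an `mbw_config`.
#' @return `cfg`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "mbw_config"))
  if (!all(is.finite(cfg$coords))) stop("non-finite coordinates")
  n <- nrow(cfg$coords)
  if (length(cfg$elements) != n || length(cfg$molecule) != n)
    stop("elements/molecule length mismatch")
  mols <- split(seq_len(n), cfg$molecule)
  for (idx in mols) {
    if (length(idx) != 3L)
      stop("molecule with ", length(idx), " atoms; each must be O,H,H")
    if (!identical(cfg$elements[idx], c("O", "H", "H")))
      stop("molecule atoms must be ordered O,H,H")
    ro <- cfg$coords[idx[1L], ]
    for (h in idx[2:3]) {
      d <- sqrt(sum((cfg$coords[h, ] - ro)^2))
      if (d >= 2.0)
        stop(sprintf("O-H distance %.3f A >= 2.0 A in molecule %d",
                     d, cfg$molecule[idx[1L]]))
    }
  }
  if (!is.null(cfg$box_edge) && cfg$box_edge <= 0) stop("box_edge must be > 0")
  invisible(cfg)
}

#' Number of molecules in a configuration
#' @param cfg an `mbw_config`.
#' @export
n_molecules <- function(cfg) nrow(cfg$coords) %/% 3L

#' @export
print.mbw_config <- function(x, ...) {
  cat(sprintf("<mbw_config: %d molecules (%d atoms)%s>\n",
              n_molecules(x), nrow(x$coords),
              if (is.null(x$box_edge)) ", cluster"
              else sprintf(", cubic box L = %.4f A", x$box_edge)))
  invisible(x)
}

#' Extract a sub-cluster of molecules at frozen geometry
#'
#' @param cfg an `mbw_config` (cluster or periodic; the subset is returned as
#'   a cluster at the frozen in-cluster geometry).
#' @param molecules integer vector of molecule ids.
#' @return an `mbw_config` cluster with the selected molecules, renumbered.
#' @export
subset_molecules <- function(cfg, molecules) {
  molecules <- as.integer(molecules)
  if (anyDuplicated(molecules)) stop("duplicate molecule indices")
  if (length(molecules) == 0L) stop("empty molecule subset")
  if (any(molecules < 1L | molecules > n_molecules(cfg)))
    stop("molecule index out of range")
  keep <- which(cfg$molecule %in% molecules)
  ord <- keep[order(match(cfg$molecule[keep], molecules), keep)]
  configuration(cfg$coords[ord, , drop = FALSE], cfg$elements[ord],
                rep(seq_along(molecules), each = 3L), box_edge = NULL,
                validate = FALSE)
}

#' Reference (equilibrium) water monomer geometry
#'
#' Gas-phase style geometry: r(OH) = 0.9572 A, HOH angle 104.52 degrees, O at
#' the origin, molecule in the xz plane with the bisector along +z.
#'
#' @return an `mbw_config` with one molecule.
#' @export
reference_monomer <- function() {
  r0 <- 0.9572; theta <- 104.52 * pi / 180
  h <- theta / 2
  coords <- rbind(c(0, 0, 0),
                  c(r0 * sin(h), 0, r0 * cos(h)),
                  c(-r0 * sin(h), 0, r0 * cos(h)))
  configuration(coords)
}

# rigid-body placement of the reference monomer: rotation matrix R, offset t
.place_monomer <- function(rot, trans) {
  m <- reference_monomer()$coords
  sweep(m %*% t(rot), 2L, trans, "+")
}

# uniform random rotation matrices via quaternions (Shoemake)
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum-image displacement matrix helper (rows minus vector), cluster if L NULL
.min_image <- function(d, L) {
  if (is.null(L)) return(d)
  d - L * round(d / L)
}

#' All O-O distances between distinct molecules
#' @param cfg an `mbw_config`.
#' @return numeric vector of pairwise O-O distances (minimum image if
#'   periodic).
#' @export
oo_distances <- function(cfg) {
  o_idx <- which(cfg$elements == "O")
  oc <- cfg$coords[o_idx, , drop = FALSE]
  nm <- nrow(oc)
  if (nm < 2L) return(numeric(0))
  out <- numeric(nm * (nm - 1L) / 2L)
  k <- 0L
  for (i in seq_len(nm - 1L)) for (j in seq.int(i + 1L, nm)) {
    d <- .min_image(oc[j, ] - oc[i, ], cfg$box_edge)
    k <- k + 1L
    out[k] <- sqrt(sum(d^2))
  }
  out
}
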