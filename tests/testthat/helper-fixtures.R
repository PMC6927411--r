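# shared fixtures; everything is generated in code

truth_pot <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- make_truth_potential()
    p
  }
})

# surrogate with moderate rung-2-like distortion
surrogate_pot <- function(scale = 1, label = "surrogate") {
  make_surrogate_potential(
    truth_pot(),
    distortion_spec(0.05 * scale, 0.05 * scale, 0.10 * scale, label))
}

# strictly pairwise-additive potential: no induction, no 3B term
pairwise_pot <- function() {
  baseline_only(make_truth_potential(list(alphaO = 0)),
                two_body = FALSE, three_body = TRUE)
}

# potential with only the 1B (intramolecular) term
onebody_pot <- function() {
  baseline_only(make_truth_potential(list(alphaO = 0, qO = 0, qH = 0,
                                          C6 = 0)))
}

# small random water cluster (n molecules in a loose ball), seeded
random_cluster <- function(n, seed, spread = 3.2) {
  set.seed(seed)
  repeat {
    centers <- matrix(rnorm(3 * n, 0, spread * n^(1 / 3) / 2), n, 3)
    coords <- do.call(rbind, lapply(seq_len(n), function(m)
      mbwater:::.place_random_monomer(centers[m, ], 0.01, pi / 180)))
    if (mbwater:::.min_intermolecular(coords, rep(seq_len(n), each = 3)) >= 2.2)
      return(configuration(coords))
  }
}

# independent recursive n-body evaluation (oracle for the Moebius form)
recursive_nbody <- function(config, potential, subset) {
  subset <- sort(as.integer(subset))
  e <- function(s) evaluate_energy(potential, subset_molecules(config, s))
  rec <- function(s) {
    if (length(s) == 1L) return(e(s))
    total <- e(s)
    for (k in seq_len(length(s) - 1L)) {
      cmb <- utils::combn(s, k)
      for (j in seq_len(ncol(cmb))) total <- total - rec(cmb[, j])
    }
    total
  }
  rec(subset)
}
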