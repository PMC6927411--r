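kcal_md <- 4.184e-4
kB <- 0.0019872041

test_that("normal-mode transform is orthogonal and exposes the frequencies", {
  expect_equal(normal_mode_matrix(1)$C, matrix(1, 1, 1))
  for (P in c(4, 32)) {
    nm <- normal_mode_matrix(P)
    expect_lt(max(abs(nm$C %*% t(nm$C) - diag(P))), 1e-12)
    set.seed(P)
    block <- array(rnorm(P * 2 * 3), c(P, 2, 3))
    modes <- normal_mode_transform(block)
    back <- normal_mode_transform(modes, inverse = TRUE)
    expect_lt(max(abs(back - block)), 1e-12)
    expect_lt(abs(sum(modes^2) - sum(block^2)), 1e-10)   # Parseval
  }
  # omega_k = 2/(beta_P hbar) sin(k pi/P)
  P <- 8; Tq <- 298.15
  om <- ring_polymer_frequencies(P, Tq)
  beta_P <- 1 / (P * kB * Tq)
  hbar <- 15.178709
  kidx <- normal_mode_matrix(P)$k_index
  expect_equal(om, 2 / (beta_P * hbar) * sin(kidx * pi / P),
               tolerance = 1e-12)
  expect_equal(om[1], 0)
})

test_that("ring-polymer initialization is seeded and thermally consistent", {
  box <- build_liquid_box(4, 0.997, seed = 5)
  spec <- simulation_spec("nvt", n_beads = 8, n_steps = 0, cutoff = 2.0,
                          seed = 11)
  s1 <- init_ring_polymer(box, spec)
  s2 <- init_ring_polymer(box, spec)
  expect_identical(s1$pu, s2$pu)
  expect_equal(dim(s1$u), c(8, 12, 3))
  # beads start at classical positions
  x <- mbwater:::.beads_of(s1)
  expect_lt(max(abs(x[1, , ] - box$coords)), 1e-10)
  expect_lt(max(abs(x[8, , ] - box$coords)), 1e-10)
  expect_error(init_ring_polymer(box, simulation_spec("nvt", cutoff = 9,
                                                      n_steps = 0)),
               "half the box")

  # drawn momenta variance -> m kB (P T) per mode dof (Monte-Carlo check)
  spec_big <- simulation_spec("nvt", n_beads = 16, n_steps = 0, cutoff = 2.0,
                              seed = 12, temperature = 298.15)
  sb <- init_ring_polymer(build_liquid_box(32, 0.997, seed = 6), spec_big)
  m_arr <- mbwater:::.mass_arr(sb)
  ratio <- mean(sb$pu^2 / m_arr) / (kB * kcal_md * 16 * 298.15)
  n_dof <- length(sb$pu)
  expect_lt(abs(ratio - 1), 4 / sqrt(n_dof))
})

test_that("one-bead NVE reproduces a reference classical velocity Verlet", {
  pot <- truth_pot()
  d0 <- sample_dimer_set(1, c(2.8, 2.9), seed = 3)[[1]]
  spec <- simulation_spec("nve", n_beads = 1, dt = 0.2, n_steps = 0, seed = 4)
  st <- init_ring_polymer(d0, spec)
  x <- d0$coords
  p <- matrix(st$pu[1, , ], ncol = 3)
  m <- ifelse(d0$elements == "O", 15.9994, 1.008)
  f <- evaluate_forces(pot, d0)
  for (i in 1:150) {
    p <- p + 0.1 * kcal_md * f
    x <- x + 0.2 * p / m
    f <- evaluate_forces(pot, configuration(x, validate = FALSE))
    p <- p + 0.1 * kcal_md * f
  }
  for (i in 1:150) st <- pimd_step(st, pot, spec)
  expect_lt(max(abs(mbwater:::.beads_of(st)[1, , ] - x)), 1e-12)
  expect_lt(max(abs(st$pu[1, , ] - p)), 1e-12)
})

test_that("free ring polymer moves ballistically with conserved mode energies", {
  zero <- model_potential(function(x, b) 0, function(x, b) x * 0)
  sys <- list(coords = matrix(c(0, 0, 0), 1, 3), masses = 2.5)
  spec <- simulation_spec("nve", n_beads = 8, dt = 0.5, n_steps = 0,
                          cutoff = 1, seed = 7, temperature = 100)
  st <- init_ring_polymer(sys, spec, thermal_spread = TRUE)
  e_mode_0 <- vapply(seq_len(8), function(k)
    sum(st$pu[k, , ]^2) / (2 * 2.5) +
      0.5 * 2.5 * st$omega[k]^2 * sum(st$u[k, , ]^2), numeric(1))
  u0 <- st$u[1, , ]
  p0 <- st$pu[1, , ]
  for (i in 1:400) st <- pimd_step(st, zero, spec)
  e_mode <- vapply(seq_len(8), function(k)
    sum(st$pu[k, , ]^2) / (2 * 2.5) +
      0.5 * 2.5 * st$omega[k]^2 * sum(st$u[k, , ]^2), numeric(1))
  expect_lt(max(abs(e_mode - e_mode_0)), 1e-10)
  expect_lt(max(abs(st$u[1, , ] - (u0 + 400 * 0.5 * p0 / 2.5))), 1e-8)
})

test_that("NVE ring-polymer Hamiltonian shows no secular drift", {
  pot <- truth_pot()
  d0 <- sample_dimer_set(1, c(2.8, 2.85), seed = 3)[[1]]
  spec <- simulation_spec("nve", n_beads = 8, dt = 0.2, n_steps = 0, seed = 1)
  st <- init_ring_polymer(d0, spec, thermal_spread = TRUE)
  for (i in 1:2000) st <- pimd_step(st, pot, spec)   # warm-up
  n <- 10000L
  es <- numeric(n)
  for (i in seq_len(n)) {
    st <- pimd_step(st, pot, spec)
    es[i] <- rp_estimators(st)$conserved
  }
  drift <- abs(stats::coef(stats::lm(es ~ seq_len(n)))[2]) * n / abs(mean(es))
  expect_lt(drift, 1e-5)
})

test_that("NVT sampling of a harmonic oscillator hits the finite-P quantum law", {
  Tq <- 298.15; m <- 1.008; omega <- 0.08
  k_md <- m * omega^2
  pot <- model_potential(
    energy = function(x, b) 0.5 * k_md * sum(x^2) / kcal_md,
    forces = function(x, b) -k_md * x / kcal_md)
  P <- 16
  omk <- ring_polymer_frequencies(P, Tq)
  ke_exact <- 3 * (kB * Tq / 2) * sum(omega^2 / (omk^2 + omega^2))
  spec <- simulation_spec("nvt", temperature = Tq, dt = 0.5, n_beads = P,
                          n_steps = 0, seed = 2, tau_thermo = 10, cutoff = 1)
  st <- init_ring_polymer(list(coords = matrix(0, 1, 3), masses = m), spec,
                          thermal_spread = TRUE)
  for (i in 1:1500) st <- pimd_step(st, pot, spec)
  n <- 40000L
  kp <- numeric(n); kv <- numeric(n)
  for (i in seq_len(n)) {
    st <- pimd_step(st, pot, spec)
    e <- rp_estimators(st)
    kp[i] <- e$ke_primitive; kv[i] <- e$ke_virial
  }
  blocks <- function(x, nb = 40) {
    bm <- tapply(x, rep(seq_len(nb), each = length(x) / nb), mean)
    c(mean = mean(bm), se = sd(bm) / sqrt(nb))
  }
  bp <- blocks(kp); bv <- blocks(kv)
  expect_lt(abs(bp["mean"] - ke_exact), 3 * bp["se"])
  expect_lt(abs(bv["mean"] - ke_exact), 3 * bv["se"])
  # the quantum value is far from classical: the estimators must tell them apart
  expect_gt(ke_exact, 1.25 * 1.5 * kB * Tq)
  expect_gt(bv["mean"], 1.5 * kB * Tq + 3 * bv["se"])
})

test_that("NPT decouples to NVT in the infinite-piston-mass limit", {
  pot <- make_truth_potential(list(cutoff = 2.4))
  box <- build_liquid_box(8, 0.997, seed = 3)
  spec_nvt <- simulation_spec("nvt", n_beads = 2, dt = 0.2, n_steps = 0,
                              cutoff = 2.4, seed = 4)
  spec_npt <- simulation_spec("npt", n_beads = 2, dt = 0.2, n_steps = 0,
                              cutoff = 2.4, seed = 4, tau_baro = 1e8)
  s1 <- init_ring_polymer(box, spec_nvt)
  s2 <- init_ring_polymer(box, spec_npt)
  for (i in 1:40) {
    s1 <- pimd_step(s1, pot, spec_nvt)
    s2 <- pimd_step_npt(s2, pot, spec_npt)
  }
  expect_lt(max(abs(mbwater:::.beads_of(s1) - mbwater:::.beads_of(s2))), 1e-10)
  expect_lt(abs(s2$box_edge - box$box_edge), 1e-10)
})

test_that("NPT ideal gas obeys the ideal-gas law with a conservative
           extended Hamiltonian", {
  zero <- model_potential(function(x, b) 0, function(x, b) x * 0)
  n <- 40; Tq <- 300; Pext <- 200
  set.seed(1)
  sys <- list(coords = matrix(runif(n * 3, 0, 12), n, 3),
              masses = rep(10, n), box_edge = 12)
  spec <- simulation_spec("npt", temperature = Tq, pressure = Pext, dt = 1.0,
                          n_beads = 1, n_steps = 0, cutoff = 1.0, seed = 2,
                          tau_thermo = 50, tau_baro = 400)
  st <- init_ring_polymer(sys, spec)
  vols <- c(); cons <- c()
  for (i in 1:20000) {
    st <- pimd_step_npt(st, zero, spec)
    if (i > 5000 && i %% 25 == 0) vols <- c(vols, st$box_edge^3)
    if (i %% 500 == 0) cons <- c(cons, rp_estimators(st)$conserved)
  }
  v_ideal <- (n + 1) * kB * Tq / (Pext * 1.458397e-5)
  expect_lt(abs(mean(vols) / v_ideal - 1), 0.05)
  drift <- abs(cons[length(cons)] - cons[1]) / abs(mean(cons))
  expect_lt(drift, 2e-3)
})

test_that("runs are reproducible, sized correctly and estimator-consistent", {
  pot <- make_truth_potential(list(cutoff = 2.4))
  box <- build_liquid_box(8, 0.997, seed = 8)
  spec0 <- simulation_spec("nvt", n_beads = 2, dt = 0.2, n_steps = 0,
                           cutoff = 2.4, seed = 5, stride = 10)
  t0 <- pimd_run(box, pot, spec0)
  expect_length(t0$frames, 1L)
  expect_lt(max(abs(t0$frames[[1]][1, , ] - box$coords)), 1e-10)

  spec <- simulation_spec("nvt", n_beads = 2, dt = 0.2, n_steps = 40,
                          cutoff = 2.4, seed = 5, stride = 10)
  tr1 <- pimd_run(box, pot, spec)
  tr2 <- pimd_run(box, pot, spec)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$scalars, tr2$scalars)
  expect_length(tr1$frames, 5L)   # n_steps/stride + 1
  # all estimators finite (pressure is intentionally NA in NVT runs)
  core <- tr1$scalars[, setdiff(names(tr1$scalars), "pressure")]
  expect_true(all(is.finite(unlist(core))))
  expect_true(all(is.na(tr1$scalars$pressure)))

  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr1, path)
  frames <- read_xyz(path, multi = TRUE)
  expect_length(frames, 5L * 2L)   # frames x beads
})

test_that("simulation specs round-trip through config text with defaults", {
  spec <- simulation_spec("npt", temperature = 310, n_beads = 8,
                          n_steps = 100, seed = 9)
  path <- withr::local_tempfile(fileext = ".cfg")
  save_config(spec, path)
  back <- load_config(path)
  expect_equal(unclass(back), unclass(spec))

  # empty config -> full protocol defaults
  writeLines(character(), path)
  d <- load_config(path)
  expect_equal(d$temperature, 298.15)
  expect_equal(d$pressure, 1.0)
  expect_equal(d$dt, 0.2)
  expect_equal(d$n_beads, 32L)
  expect_equal(d$cutoff, 9.0)

  writeLines("dt: -1", path)
  expect_error(load_config(path), "dt")
  writeLines("banana: 3", path)
  expect_error(load_config(path), "unknown config keys")
})

test_that("Ewald electrostatics match direct-sum oracles", {
  # two opposite charges approach the isolated Coulomb pair as the box grows
  e_pair <- -332.06371 / 2
  errs <- vapply(c(20, 40, 80), function(L)
    abs(ewald_energy(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, -1), L,
                     cutoff = L / 2, tol = 1e-8)$energy - e_pair),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)

  # rock-salt cube: Evjen-weighted direct lattice sum over expanding shells
  L <- 4.0
  xyz <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * (L / 2)
  q <- (-1)^rowSums(xyz / (L / 2))
  ew <- ewald_energy(xyz, q, L, cutoff = L / 2, tol = 1e-8)
  evjen <- function(nmax) {
    # Madelung constant of NaCl by Evjen's method (fractional boundary
    # charges), lattice spacing 1
    acc <- 0
    for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax) {
      if (i == 0 && j == 0 && k == 0) next
      w <- prod(ifelse(abs(c(i, j, k)) == nmax, 0.5, 1))
      acc <- acc + w * (-1)^(i + j + k) / sqrt(i^2 + j^2 + k^2)
    }
    -acc
  }
  M <- evjen(8)                       # ~1.747565 at this shell count
  e_ref <- -8 * M * 332.06371 / (L / 2) / 2
  expect_lt(abs(ew$energy - e_ref) / abs(e_ref), 1e-5)

  # rigid translation invariance (tight screening so that the exact-boundary
  # neighbor pairs at r == cutoff contribute below the comparison level)
  ew1t <- ewald_energy(xyz, q, L, cutoff = L / 2, tol = 1e-12)
  ew2t <- ewald_energy(sweep(xyz, 2, c(0.37, -1.2, 0.05), "+"), q, L,
                       cutoff = L / 2, tol = 1e-12)
  expect_lt(abs(ew2t$energy - ew1t$energy), 1e-9)
  expect_error(ewald_energy(xyz, q + 0.1, L), "neutral")
})
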