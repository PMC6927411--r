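# Normal-mode path-integral molecular dynamics.
#
# Convention: the isomorphic classical ring-polymer system carries the full
# physical potential on every bead and is sampled at temperature P*T, so the
# free ring-polymer normal-mode frequencies are
# omega_k = 2/(beta_P*hbar) * sin(k*pi/P) with beta_P = beta/P.  The
# reported kinetic temperature estimator divides the bead kinetic energy by
# the extra factor P so that it estimates the physical temperature T.
# Classical MD is the exact P = 1 special case.

#' Simulation specification
#'
#' Defaults follow the reference protocol for liquid water: T = 298.15 K,
#' P = 1 atm, dt = 0.2 fs, 32 beads, 9.0 A atom-atom cutoff.
#'
#' @param ensemble `"nvt"`, `"npt"` or `"nve"`.
#' @param temperature target temperature (K).
#' @param pressure target pressure (atm), NPT only.
#' @param dt time step (fs).
#' @param n_beads ring-polymer beads per atom (1 = classical).
#' @param n_steps number of integration steps.
#' @param cutoff periodic real-space cutoff (A); must not exceed half the box
#'   edge.
#' @param seed master seed; per-stream seeds for momenta etc. are derived
#'   from it.
#' @param stride trajectory output stride (steps).
#' @param tau_thermo centroid thermostat time constant (fs); internal modes
#'   use 1/omega_k.
#' @param tau_baro barostat time constant (fs).
#' @return a `mbw_sim_spec` list.
#' @export
simulation_spec <- function(ensemble = c("nvt", "npt", "nve"),
                            temperature = 298.15, pressure = 1.0,
                            dt = 0.2, n_beads = 32L, n_steps = 1000L,
                            cutoff = 9.0, seed = 1L, stride = 50L,
                            tau_thermo = 50, tau_baro = 500) {
  ensemble <- match.arg(tolower(ensemble[1]), c("nvt", "npt", "nve"))
  if (dt <= 0) stop("dt must be positive")
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(ensemble = ensemble, temperature = temperature,
                 pressure = pressure, dt = dt, n_beads = as.integer(n_beads),
                 n_steps = as.integer(n_steps), cutoff = cutoff,
                 seed = as.integer(seed), stride = as.integer(stride),
                 tau_thermo = tau_thermo, tau_baro = tau_baro),
            class = "mbw_sim_spec")
}

#' Parse a simulation spec from structured config text
#'
#' `key: value` lines; unknown keys are rejected, missing keys fall back to
#' the protocol defaults (see [simulation_spec()]).
#'
#' @param path file path.
#' @return a `mbw_sim_spec`.
#' @export
load_config <- function(path) {
  kv <- .parse_kv(readLines(path))
  known <- names(formals(simulation_spec))
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- lapply(kv, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  do.call(simulation_spec, args)
}

#' Serialize a simulation spec to structured config text
#' @param spec a `mbw_sim_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(spec, path) {
  writeLines(sprintf("%s: %s", names(unclass(spec)),
                     vapply(unclass(spec), format, "", digits = 17)), path)
  invisible(path)
}

# ---- normal modes ----------------------------------------------------------

#' Orthogonal normal-mode transformation matrix of a P-bead ring polymer
#'
#' Row 1 is the (scaled) centroid; the matrix is orthonormal so the
#' bead -> mode map `u = C x` and its inverse `x = t(C) u` round-trip
#' exactly and preserve sums of squares.
#'
#' @param P number of beads.
#' @return list with `C` (`P x P`) and `k_index` (DFT index of each row, used
#'   for the mode frequencies).
#' @export
normal_mode_matrix <- function(P) {
  C <- matrix(0, P, P)
  kidx <- integer(P)
  s <- 0:(P - 1)
  row <- 1L
  C[row, ] <- sqrt(1 / P); kidx[row] <- 0L; row <- row + 1L
  kmax_cos <- if (P %% 2L == 0L) P %/% 2L - 1L else (P - 1L) %/% 2L
  for (k in seq_len(kmax_cos)) {
    C[row, ] <- sqrt(2 / P) * cos(2 * pi * k * s / P)
    kidx[row] <- k; row <- row + 1L
    C[row, ] <- sqrt(2 / P) * sin(2 * pi * k * s / P)
    kidx[row] <- k; row <- row + 1L
  }
  if (P %% 2L == 0L) {
    C[row, ] <- sqrt(1 / P) * (-1)^s
    kidx[row] <- P %/% 2L
  }
  list(C = C, k_index = kidx)
}

#' Free ring-polymer normal-mode frequencies
#'
#' `omega_k = 2/(beta_P hbar) sin(k pi / P)` with `beta_P = beta/P`, in 1/fs.
#'
#' @param P number of beads.
#' @param temperature physical temperature (K).
#' @return numeric vector of length P, ordered as the rows of
#'   [normal_mode_matrix()] (first entry 0, the centroid).
#' @export
ring_polymer_frequencies <- function(P, temperature) {
  nm <- normal_mode_matrix(P)
  omega_P <- P * .mbw$kB * .mbw$kcal2md * temperature /
    (.mbw$hbar * .mbw$kcal2md)
  2 * omega_P * sin(nm$k_index * pi / P)
}

#' Transform a bead-resolved block to normal modes (or back)
#'
#' @param block array `P x n x 3` (or a `P x m` matrix).
#' @param inverse if `TRUE` apply the mode -> bead transform.
#' @return array/matrix of the same shape.
#' @export
normal_mode_transform <- function(block, inverse = FALSE) {
  dims <- dim(block)
  P <- dims[1]
  C <- normal_mode_matrix(P)$C
  M <- matrix(block, nrow = P)
  out <- if (inverse) crossprod(C, M) else C %*% M
  array(out, dims)
}

# ---- state -----------------------------------------------------------------

.system_info <- function(config) {
  if (inherits(config, "mbw_config")) {
    masses <- ifelse(config$elements == "O", .mbw$mass_O, .mbw$mass_H)
    list(coords = config$coords, masses = masses,
         box_edge = config$box_edge, template = config)
  } else {
    stopifnot(is.list(config), !is.null(config$coords), !is.null(config$masses))
    list(coords = as.matrix(config$coords), masses = as.numeric(config$masses),
         box_edge = config$box_edge, template = config)
  }
}

#' Initialize a ring-polymer state
#'
#' Beads start at the classical positions; normal-mode momenta are drawn
#' from the Maxwell-Boltzmann distribution of the isomorphic system (each
#' mode degree of freedom at k_B P T); thermostat and barostat states are
#' zeroed.  Deterministic under the spec seed.
#'
#' @param config an `mbw_config`, or a list with `coords`, `masses` and
#'   optionally `box_edge` for model systems.
#' @param spec a `mbw_sim_spec`.
#' @param thermal_spread if `TRUE`, the internal ring-polymer modes are also
#'   drawn from their exact free-ring-polymer Gaussian distribution instead
#'   of starting collapsed on the classical positions; reduces the initial
#'   equilibration transient.
#' @return an object of class `mbw_rp_state`.
#' @export
init_ring_polymer <- function(config, spec, thermal_spread = FALSE) {
  sys <- .system_info(config)
  n <- nrow(sys$coords)
  P <- spec$n_beads
  if (!is.null(sys$box_edge) && spec$cutoff > sys$box_edge / 2)
    stop(sprintf("cutoff %.2f A exceeds half the box edge %.2f A",
                 spec$cutoff, sys$box_edge / 2))
  nm <- normal_mode_matrix(P)
  Tsim <- P * spec$temperature
  kT <- .mbw$kB * .mbw$kcal2md * Tsim
  m3 <- rep(sys$masses, 3L)                    # length n*3 (atom-major per dim)
  omega <- ring_polymer_frequencies(P, spec$temperature)
  u <- array(0, c(P, n, 3))
  u[1, , ] <- sqrt(P) * sys$coords             # centroid row = sqrt(P)*mean
  drawn <- .with_seed(spec$seed, {
    pu <- array(stats::rnorm(P * n * 3, 0,
                             sqrt(kT * rep(rep(sys$masses, each = P), 3))),
                c(P, n, 3))
    du <- if (thermal_spread) {
      m_rep <- rep(rep(sys$masses, each = P), 3)
      om_rep <- rep(omega, n * 3)
      sd_u <- ifelse(om_rep > 0, sqrt(kT / m_rep) / pmax(om_rep, 1e-300), 0)
      array(stats::rnorm(P * n * 3, 0, sd_u), c(P, n, 3))
    } else NULL
    list(pu = pu, du = du)
  })
  pu <- drawn$pu
  if (!is.null(drawn$du)) u <- u + drawn$du
  tau <- ifelse(omega > 0, 1 / omega, spec$tau_thermo)
  Q <- kT * tau^2                              # per-mode NHC mass
  state <- structure(list(
    u = u, pu = pu, masses = sys$masses, n_atoms = n, n_beads = P,
    box_edge = sys$box_edge, omega = omega, C = nm$C,
    thermo = list(xi = rep(list(array(0, c(P, n, 3))), 4),
                  vxi = rep(list(array(0, c(P, n, 3))), 4),
                  Q = Q, kT = kT,
                  nc = max(1L, ceiling((spec$dt / 2) / (0.2 * min(tau))))),
    baro = list(v_eps = 0, W = NA_real_, xi = numeric(4), vxi = numeric(4)),
    step_count = 0L, temperature_target = spec$temperature,
    pressure_target = spec$pressure,
    template = sys$template, forces = NULL, epot = NULL),
    class = "mbw_rp_state")
  state$baro$W <- (3 * n + 3) * kT * spec$tau_baro^2
  state
}

# bead coordinate array (P,n,3) from mode array
.beads_of <- function(state) {
  P <- state$n_beads
  array(crossprod(state$C, matrix(state$u, nrow = P)),
        c(P, state$n_atoms, 3))
}

# forces (kcal/mol/A) and potential energies per bead.  `vir` is -dE/d(eps)
# under the barostat's centroid scaling (eps = ln L): for cluster-style
# potentials it equals sum(r.F); for periodic water it is computed by central
# difference (only when need_virial, i.e. NPT).
.forces_all <- function(potential, state, cutoff = NULL,
                        need_virial = FALSE) {
  x <- .beads_of(state)
  P <- state$n_beads
  F <- array(0, dim(x))
  V <- numeric(P)
  vir <- numeric(P)
  if (inherits(potential, "mbw_potential")) {
    pot <- potential
    if (!is.null(cutoff)) pot$params$cutoff <- cutoff
    tmpl <- state$template
    for (s in seq_len(P)) {
      cfg <- configuration(x[s, , ], tmpl$elements, tmpl$molecule,
                           state$box_edge, validate = FALSE)
      f <- evaluate_forces(pot, cfg)
      F[s, , ] <- f
      V[s] <- attr(f, "energy")
    }
    if (need_virial) {
      if (is.null(state$box_edge)) {
        for (s in seq_len(P)) vir[s] <- sum(x[s, , ] * F[s, , ])
      } else {
        xc <- apply(x, c(2, 3), mean)
        de <- 1e-4
        for (s in seq_len(P)) {
          ep <- em <- 0
          for (sgn in c(1, -1)) {
            fac <- exp(sgn * de) - 1
            cfg <- configuration(x[s, , ] + fac * xc, tmpl$elements,
                                 tmpl$molecule,
                                 state$box_edge * exp(sgn * de),
                                 validate = FALSE)
            e <- evaluate_energy(pot, cfg)
            if (sgn > 0) ep <- e else em <- e
          }
          vir[s] <- -(ep - em) / (2 * de)
        }
      }
    }
  } else if (inherits(potential, "mbw_model_potential")) {
    for (s in seq_len(P)) {
      f <- potential$forces(x[s, , ], state$box_edge)
      F[s, , ] <- f
      V[s] <- potential$energy(x[s, , ], state$box_edge)
      vir[s] <- sum(x[s, , ] * f)
    }
  } else stop("unsupported potential object")
  list(F = F, V = V, vir = vir,
       vir_valid = need_virial || inherits(potential, "mbw_model_potential"))
}

#' A model potential for the PIMD engine
#'
#' Wraps plain R energy/force functions (e.g. a harmonic oscillator or an
#' ideal gas) so they can be integrated like the water potentials.
#'
#' @param energy `function(x, box_edge)` returning kcal/mol for an `n x 3`
#'   coordinate matrix.
#' @param forces `function(x, box_edge)` returning the `n x 3` force matrix.
#' @return an `mbw_model_potential`.
#' @export
model_potential <- function(energy, forces) {
  structure(list(energy = energy, forces = forces),
            class = "mbw_model_potential")
}

# ---- thermostats -----------------------------------------------------------

# massive NHC half-step (Suzuki-Yoshida 3-term), acting on mode momenta.
# Returns scaled momenta and updated chain state.
.nhc_half <- function(pu, th, m_arr, dt2) {
  w <- c(1.351207191959657, -1.702414383919315, 1.351207191959657)
  kT <- th$kT
  Qarr <- array(th$Q, dim(pu))     # Q varies along the mode dimension
  KE2 <- pu^2 / m_arr
  scale <- array(1, dim(pu))
  vxi <- th$vxi; xi <- th$xi
  nc <- th$nc %||% 1L
  for (ic in seq_len(nc)) for (iw in w) {
    dts <- iw * dt2 / nc; dt4 <- dts / 2; dt8 <- dts / 4
    G <- (Qarr * vxi[[3]]^2 - kT) / Qarr
    vxi[[4]] <- vxi[[4]] + dt4 * G
    for (j in 3:1) {
      AA <- exp(-dt8 * vxi[[j + 1]])
      G <- if (j == 1) (KE2 - kT) / Qarr
           else (Qarr * vxi[[j - 1]]^2 - kT) / Qarr
      vxi[[j]] <- vxi[[j]] * AA^2 + dt4 * G * AA
    }
    s <- exp(-dts * vxi[[1]])
    scale <- scale * s
    KE2 <- KE2 * s^2
    for (j in 1:4) xi[[j]] <- xi[[j]] + dts * vxi[[j]]
    for (j in 1:3) {
      AA <- exp(-dt8 * vxi[[j + 1]])
      G <- if (j == 1) (KE2 - kT) / Qarr
           else (Qarr * vxi[[j - 1]]^2 - kT) / Qarr
      vxi[[j]] <- vxi[[j]] * AA^2 + dt4 * G * AA
    }
    G <- (Qarr * vxi[[3]]^2 - kT) / Qarr
    vxi[[4]] <- vxi[[4]] + dt4 * G
  }
  th$vxi <- vxi; th$xi <- xi
  list(pu = pu * scale, thermo = th)
}

# NHC energy term of the conserved quantity (md units)
.nhc_energy <- function(th, dims) {
  Qarr <- array(th$Q, dims)
  e <- 0
  for (j in 1:4)
    e <- e + sum(0.5 * Qarr * th$vxi[[j]]^2 + th$kT * th$xi[[j]])
  e
}

# ---- single steps ----------------------------------------------------------

# mass array recycled over (P,n,3)
.mass_arr <- function(state) {
  array(rep(state$masses, each = state$n_beads),
        c(state$n_beads, state$n_atoms, 3))
}

# exact free ring-polymer normal-mode evolution over dt
.free_rp_evolve <- function(state, dt) {
  om <- state$omega
  m_arr <- .mass_arr(state)
  u <- state$u; pu <- state$pu
  for (k in seq_along(om)) {
    if (om[k] == 0) {
      u[k, , ] <- u[k, , ] + dt * pu[k, , ] / m_arr[k, , ]
    } else {
      c_ <- cos(om[k] * dt); s_ <- sin(om[k] * dt)
      mo <- m_arr[k, , ] * om[k]
      u_new <- u[k, , ] * c_ + pu[k, , ] / mo * s_
      pu[k, , ] <- pu[k, , ] * c_ - mo * u[k, , ] * s_
      u[k, , ] <- u_new
    }
  }
  state$u <- u; state$pu <- pu
  state
}

#' Advance a ring-polymer state by one step (NVE/NVT)
#'
#' One step of the symmetric splitting: half thermostat, half momentum kick
#' with bead forces, exact free ring-polymer normal-mode evolution, half
#' kick, half thermostat.  In NVE mode the thermostats are disabled and the
#' ring-polymer Hamiltonian is conserved.
#'
#' @param state an `mbw_rp_state`.
#' @param potential an `mbw_potential` or `mbw_model_potential`.
#' @param spec a `mbw_sim_spec`.
#' @return the advanced state (with cached forces/energies).
#' @export
pimd_step <- function(state, potential, spec) {
  dt <- spec$dt
  kcal <- .mbw$kcal2md
  m_arr <- .mass_arr(state)
  thermostat <- spec$ensemble == "nvt"
  if (is.null(state$forces))
    state[c("forces", "epot", "vir", "vir_valid")] <-
      .forces_all(potential, state,
                  spec$cutoff)[c("F", "V", "vir", "vir_valid")]
  if (thermostat) {
    r <- .nhc_half(state$pu, state$thermo, m_arr, dt / 2)
    state$pu <- r$pu; state$thermo <- r$thermo
  }
  P <- state$n_beads
  Fm <- array(state$C %*% matrix(state$forces, nrow = P), dim(state$pu))
  state$pu <- state$pu + (dt / 2) * kcal * Fm
  state <- .free_rp_evolve(state, dt)
  ff <- .forces_all(potential, state, spec$cutoff)
  state$forces <- ff$F; state$epot <- ff$V; state$vir <- ff$vir
  state$vir_valid <- ff$vir_valid
  Fm <- array(state$C %*% matrix(state$forces, nrow = P), dim(state$pu))
  state$pu <- state$pu + (dt / 2) * kcal * Fm
  if (thermostat) {
    r <- .nhc_half(state$pu, state$thermo, m_arr, dt / 2)
    state$pu <- r$pu; state$thermo <- r$thermo
  }
  state$step_count <- state$step_count + 1L
  state
}

#' Advance a ring-polymer state by one NPT step
#'
#' Isotropic Martyna-type barostat coupled to the centroid mode: the box
#' edge and centroid coordinates are scaled together while internal modes
#' are unaffected.  The piston carries its own 4-link Nose-Hoover chain.
#' The instantaneous pressure is estimated from the bead-averaged virial.
#'
#' @inheritParams pimd_step
#' @return the advanced state.
#' @export
pimd_step_npt <- function(state, potential, spec) {
  if (is.null(state$box_edge)) stop("NPT requires a periodic system")
  dt <- spec$dt
  kcal <- .mbw$kcal2md
  m_arr <- .mass_arr(state)
  P <- state$n_beads; n <- state$n_atoms
  kT <- state$thermo$kT
  Pext_md <- spec$pressure * 1.458397e-5 * kcal # atm -> md energy / A^3
  W <- state$baro$W
  Qp <- kT * spec$tau_baro^2
  state$baro$Qp <- Qp
  if (is.null(state$forces) || !isTRUE(state$vir_valid))
    state[c("forces", "epot", "vir", "vir_valid")] <-
      .forces_all(potential, state, spec$cutoff,
                  need_virial = TRUE)[c("F", "V", "vir", "vir_valid")]
  # piston NHC: thermostat v_eps for dt/2 (mirrors .nhc_half, single dof)
  piston_nhc <- function(b, dt2, nc = 4L) {
    w <- c(1.351207191959657, -1.702414383919315, 1.351207191959657)
    KE2 <- W * b$v_eps^2
    for (ic in seq_len(nc)) for (iw in w) {
      dts <- iw * dt2 / nc; dt4 <- dts / 2; dt8 <- dts / 4
      b$vxi[4] <- b$vxi[4] + dt4 * (Qp * b$vxi[3]^2 - kT) / Qp
      for (j in 3:1) {
        AA <- exp(-dt8 * b$vxi[j + 1])
        Gj <- if (j == 1) (KE2 - kT) / Qp else (Qp * b$vxi[j - 1]^2 - kT) / Qp
        b$vxi[j] <- b$vxi[j] * AA^2 + dt4 * Gj * AA
      }
      sc <- exp(-dts * b$vxi[1])
      b$v_eps <- b$v_eps * sc
      KE2 <- KE2 * sc^2
      b$xi <- b$xi + dts * b$vxi
      for (j in 1:3) {
        AA <- exp(-dt8 * b$vxi[j + 1])
        Gj <- if (j == 1) (KE2 - kT) / Qp else (Qp * b$vxi[j - 1]^2 - kT) / Qp
        b$vxi[j] <- b$vxi[j] * AA^2 + dt4 * Gj * AA
      }
      b$vxi[4] <- b$vxi[4] + dt4 * (Qp * b$vxi[3]^2 - kT) / Qp
    }
    b
  }
  veps_kick <- function(state, dt2) {
    V <- state$box_edge^3
    KE2c <- sum(state$pu[1, , ]^2 / m_arr[1, , ])
    P_int <- (KE2c + sum(state$vir) * kcal) / (3 * V)  # convention-A
    G <- (3 * V * (P_int - P * Pext_md) + KE2c / n) / W
    state$baro$v_eps <- state$baro$v_eps + dt2 * G
    state
  }
  couple <- function(state, dt2) {
    a_fac <- (1 + 1 / n) * state$baro$v_eps
    state$pu[1, , ] <- state$pu[1, , ] * exp(-a_fac * dt2)
    state
  }
  r <- .nhc_half(state$pu, state$thermo, m_arr, dt / 2)
  state$pu <- r$pu; state$thermo <- r$thermo
  state$baro <- piston_nhc(state$baro, dt / 2)
  state <- veps_kick(state, dt / 2)
  state <- couple(state, dt / 2)
  Fm <- array(state$C %*% matrix(state$forces, nrow = P), dim(state$pu))
  state$pu <- state$pu + (dt / 2) * kcal * Fm
  # drift: scale centroid and box exponentially, then free-RP evolution
  ve <- state$baro$v_eps
  state$u[1, , ] <- state$u[1, , ] * exp(ve * dt)
  state$box_edge <- state$box_edge * exp(ve * dt)
  state <- .free_rp_evolve(state, dt)
  if (state$box_edge < 2 * spec$cutoff)
    stop("box collapsed below twice the cutoff")
  ff <- .forces_all(potential, state, spec$cutoff, need_virial = TRUE)
  state$forces <- ff$F; state$epot <- ff$V; state$vir <- ff$vir
  state$vir_valid <- ff$vir_valid
  Fm <- array(state$C %*% matrix(state$forces, nrow = P), dim(state$pu))
  state$pu <- state$pu + (dt / 2) * kcal * Fm
  state <- couple(state, dt / 2)
  state <- veps_kick(state, dt / 2)
  state$baro <- piston_nhc(state$baro, dt / 2)
  r <- .nhc_half(state$pu, state$thermo, m_arr, dt / 2)
  state$pu <- r$pu; state$thermo <- r$thermo
  state$step_count <- state$step_count + 1L
  state
}

# ---- estimators ------------------------------------------------------------

#' Energy/temperature estimators of a ring-polymer state
#'
#' @param state an `mbw_rp_state` with cached forces (after a step, or pass
#'   `potential` to compute them).
#' @param potential optional potential for a fresh force evaluation.
#' @param spec optional spec (cutoff).
#' @return list with `temperature` (K, physical estimator), `ke_primitive`
#'   and `ke_virial` (kcal/mol, quantum kinetic-energy estimators),
#'   `epot_mean` (mean bead potential energy, kcal/mol), `conserved`
#'   (kcal/mol, ring-polymer Hamiltonian + thermostat terms) and `pressure`
#'   (atm, periodic systems).
#' @export
rp_estimators <- function(state, potential = NULL, spec = NULL) {
  kcal <- .mbw$kcal2md
  if (is.null(state$forces)) {
    if (is.null(potential)) stop("state has no cached forces; pass potential")
    ff <- .forces_all(potential, state,
                      if (is.null(spec)) NULL else spec$cutoff)
    state$forces <- ff$F; state$epot <- ff$V; state$vir <- ff$vir
  state$vir_valid <- ff$vir_valid
  }
  m_arr <- .mass_arr(state)
  P <- state$n_beads; n <- state$n_atoms
  kB <- .mbw$kB
  Tphys <- state$temperature_target
  ke_md <- sum(state$pu^2 / m_arr) / 2
  temperature <- 2 * ke_md / (3 * n * P * kB * kcal) / P
  # spring energy (md): sum_k 1/2 m omega_k^2 u_k^2
  om2 <- state$omega^2
  spring_md <- 0
  for (k in seq_len(P)) if (om2[k] > 0)
    spring_md <- spring_md + 0.5 * om2[k] * sum(m_arr[k, , ] * state$u[k, , ]^2)
  spring <- spring_md / kcal
  ke_prim <- 1.5 * n * P * kB * Tphys - spring / P
  x <- .beads_of(state)
  xc <- apply(x, c(2, 3), mean)
  vir_c <- 0
  for (s in seq_len(P))
    vir_c <- vir_c - sum((x[s, , ] - xc) * state$forces[s, , ])
  ke_vir <- 1.5 * n * kB * Tphys + vir_c / (2 * P)
  conserved <- (ke_md + spring_md) / kcal + sum(state$epot) +
    .nhc_energy(state$thermo, dim(state$pu)) / kcal
  pressure <- NA_real_
  if (!is.null(state$box_edge)) {
    V <- state$box_edge^3
    if (!is.null(state$vir) && state$vir_valid %||% FALSE) {
      KE2c <- sum(state$pu[1, , ]^2 / m_arr[1, , ])
      P_int_md <- (KE2c + sum(state$vir) * kcal) / (3 * V)
      pressure <- P_int_md / P / (1.458397e-5 * kcal) # atm, physical
    }
    conserved <- conserved + state$baro$W * state$baro$v_eps^2 / 2 / kcal +
      state$pressure_target * 1.458397e-5 * P * V
    if (!is.null(state$baro$Qp))   # piston chain terms (after any NPT step)
      conserved <- conserved +
        sum(0.5 * state$baro$Qp * state$baro$vxi^2 +
              state$thermo$kT * state$baro$xi) / kcal
  }
  list(temperature = temperature, ke_primitive = ke_prim, ke_virial = ke_vir,
       epot_mean = mean(state$epot), conserved = conserved,
       pressure = pressure, spring_energy = spring)
}

# ---- full runs -------------------------------------------------------------

#' Run a path-integral MD simulation
#'
#' Initializes the ring polymer and advances `n_steps` steps of the
#' requested ensemble, recording bead-resolved frames and scalar estimators
#' every `stride` steps (plus the initial state).  Fully reproducible under
#' the spec seed.
#'
#' @param config starting `mbw_config` (periodic for NVT/NPT liquids) or
#'   model system list.
#' @param potential an `mbw_potential` or `mbw_model_potential`.
#' @param spec a `mbw_sim_spec`.
#' @param progress print progress every `progress` steps (0 = silent).
#' @return an object of class `mbw_trajectory`: `frames` (list of
#'   `P x n x 3` bead position arrays), `box` (per-frame box edge or NA),
#'   `scalars` (data frame of per-frame estimators), `spec`, `template`.
#' @export
pimd_run <- function(config, potential, spec, progress = 0) {
  state <- init_ring_polymer(config, spec)
  ff <- .forces_all(potential, state, spec$cutoff,
                    need_virial = spec$ensemble == "npt")
  state$forces <- ff$F; state$epot <- ff$V; state$vir <- ff$vir
  state$vir_valid <- ff$vir_valid
  stepper <- if (spec$ensemble == "npt") pimd_step_npt else pimd_step
  n_rec <- spec$n_steps %/% spec$stride + 1L
  frames <- vector("list", n_rec)
  box <- numeric(n_rec)
  scal <- vector("list", n_rec)
  rec <- 1L
  snap <- function(state, rec, step) {
    est <- rp_estimators(state)
    frames[[rec]] <<- .beads_of(state)
    box[rec] <<- if (is.null(state$box_edge)) NA_real_ else state$box_edge
    scal[[rec]] <<- data.frame(step = step, time_fs = step * spec$dt,
                               temperature = est$temperature,
                               epot_mean = est$epot_mean,
                               ke_primitive = est$ke_primitive,
                               ke_virial = est$ke_virial,
                               conserved = est$conserved,
                               pressure = est$pressure)
  }
  snap(state, rec, 0L)
  for (step in seq_len(spec$n_steps)) {
    state <- stepper(state, potential, spec)
    if (step %% spec$stride == 0L) {
      rec <- rec + 1L
      snap(state, rec, step)
    }
    if (progress > 0 && step %% progress == 0L)
      message(sprintf("step %d / %d (T = %.1f K)", step, spec$n_steps,
                      rp_estimators(state)$temperature))
  }
  structure(list(frames = frames[seq_len(rec)], box = box[seq_len(rec)],
                 scalars = do.call(rbind, scal[seq_len(rec)]),
                 spec = spec, template = state$template,
                 potential_tag = if (inherits(potential, "mbw_potential"))
                   potential$level_tag else "model",
                 final_state = state),
            class = "mbw_trajectory")
}

#' @export
print.mbw_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mbw_trajectory: %d frames, %d beads x %d atoms, %s, %s, %.1f fs>\n",
    length(x$frames), x$spec$n_beads, dim(x$frames[[1]])[2],
    toupper(x$spec$ensemble), x$potential_tag,
    max(x$scalars$time_fs)))
  invisible(x)
}

#' Write a bead-resolved trajectory as extended XYZ
#'
#' Frames are concatenated; each bead is written as its own frame with
#' `frame=` and `bead=` tags (plus box and mean potential energy) in the
#' comment line.
#'
#' @param traj an `mbw_trajectory` over an `mbw_config` template.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  tmpl <- traj$template
  if (!inherits(tmpl, "mbw_config"))
    stop("trajectory was not run on an mbw_config system")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    for (s in seq_len(dim(traj$frames[[f]])[1])) {
      cfg <- configuration(traj$frames[[f]][s, , ], tmpl$elements,
                           tmpl$molecule,
                           if (is.na(traj$box[f])) NULL else traj$box[f],
                           validate = FALSE)
      writeLines(as.character(nrow(cfg$coords)), con)
      writeLines(paste(.xyz_comment(cfg, traj$scalars$epot_mean[f]),
                       sprintf("frame=%d bead=%d", f, s)), con)
      writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", cfg$elements,
                         cfg$coords[, 1], cfg$coords[, 2], cfg$coords[, 3]),
                 con)
    }
  }
  invisible(path)
}
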