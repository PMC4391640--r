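#' Propagator settings
#'
#' Collects the numerical parameters of the surface-hopping engine. Defaults
#' follow the study protocol: 0.5 fs nuclear steps for 1 ps, 0.02 fs
#' electronic amplitude substeps, energy-based decoherence with
#' alpha = 0.1 hartree, uniform velocity rescaling on accepted hops, and
#' frustrated hops rejected with velocities unchanged.
#'
#' @param dt_fs nuclear time step (fs).
#' @param dt_electronic_fs electronic amplitude substep (fs); must divide the
#'   nuclear step evenly.
#' @param t_max_fs total simulation time (fs).
#' @param alpha decoherence parameter (hartree).
#' @param decoherence logical, apply the energy-based decoherence correction.
#' @param hopping logical, allow surface hops (disable for adiabatic runs).
#' @param rescaling velocity rescaling policy on accepted hops; only
#'   `"uniform"` is implemented (the full velocity vector is scaled).
#' @param frustrated policy for energetically forbidden upward hops; only
#'   `"keep-velocity"` is implemented (no reflection).
#' @param seed integer seed for the hopping random stream.
#' @return A list of class `propagator_settings`.
#' @export
propagator_settings <- function(dt_fs = 0.5, dt_electronic_fs = 0.02,
                                t_max_fs = 1000, alpha = 0.1,
                                decoherence = TRUE, hopping = TRUE,
                                rescaling = "uniform",
                                frustrated = "keep-velocity",
                                seed = 1) {
  if (dt_fs <= 0 || dt_electronic_fs <= 0 || t_max_fs <= 0) {
    stop("all times must be positive")
  }
  nsub <- dt_fs / dt_electronic_fs
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("dt_electronic_fs must divide dt_fs evenly")
  }
  rescaling <- match.arg(rescaling, "uniform")
  frustrated <- match.arg(frustrated, "keep-velocity")
  structure(list(dt_fs = dt_fs, dt_electronic_fs = dt_electronic_fs,
                 t_max_fs = t_max_fs, alpha = alpha,
                 decoherence = decoherence, hopping = hopping,
                 rescaling = rescaling, frustrated = frustrated,
                 nsub = as.integer(round(nsub)), seed = seed),
            class = "propagator_settings")
}

#' Tracked Hermitian diagonalization
#'
#' Diagonalizes a complex Hermitian matrix. Without a previous eigenvector
#' matrix the eigenvalues are returned ascending. With `U_prev`, column order
#' and phases are chosen to maximize continuity: columns are assigned greedily
#' by largest squared overlap with the previous columns and each column's
#' phase is fixed so the diagonal of `U_prev^H U` is real and positive.
#'
#' @param H complex Hermitian matrix.
#' @param U_prev optional previous unitary for order/phase tracking.
#' @param tol Hermiticity tolerance relative to the matrix scale.
#' @return list with `values` and unitary `vectors` such that
#'   `U^H H U` is diagonal.
#' @export
diagonalize_tracked <- function(H, U_prev = NULL, tol = 1e-10) {
  H <- as.matrix(H)
  if (!is.complex(H)) storage.mode(H) <- "complex"
  herm_err <- max(Mod(H - Conj(t(H))))
  if (herm_err > tol * max(1, max(Mod(H)))) {
    stop("matrix is not Hermitian (deviation ", format(herm_err), ")")
  }
  e <- .cx_eig_sym((H + Conj(t(H))) / 2)
  vals <- drop(e$values)
  U <- e$vectors
  if (!is.null(U_prev)) {
    S <- Conj(t(U_prev)) %*% U
    A <- Mod(S)^2
    n <- ncol(U)
    perm <- integer(n)
    taken_row <- rep(FALSE, n); taken_col <- rep(FALSE, n)
    for (k in seq_len(n)) {
      A2 <- A
      A2[taken_row, ] <- -1
      A2[, taken_col] <- -1
      idx <- arrayInd(which.max(A2), dim(A2))
      perm[idx[1]] <- idx[2]
      taken_row[idx[1]] <- TRUE
      taken_col[idx[2]] <- TRUE
    }
    U <- U[, perm, drop = FALSE]
    vals <- vals[perm]
    d <- diag(Conj(t(U_prev)) %*% U)
    ph <- ifelse(Mod(d) > 0, d / Mod(d), 1 + 0i)
    U <- sweep(U, 2, Conj(ph), "*")
  }
  list(values = vals, vectors = U)
}

# Spin-free (MCH) eigenbasis from the real multiplicity blocks, with
# per-block continuity tracking. Returns component-resolved energies and the
# real orthogonal matrix V over spin components (triplet Ms blocks shared).
mch_basis <- function(res, space, prev = NULL) {
  ns <- space$n_singlets; nt <- space$n_triplets
  Vs <- NULL; Vt <- NULL; Es <- NULL; Et <- NULL
  if (ns > 0) {
    es <- diagonalize_tracked(res$S_block, if (!is.null(prev)) prev$Vs)
    Es <- Re(es$values); Vs <- Re(es$vectors)
  }
  if (nt > 0) {
    et <- diagonalize_tracked(res$T_block, if (!is.null(prev)) prev$Vt)
    Et <- Re(et$values); Vt <- Re(et$vectors)
  }
  nc <- space$n_components
  V <- matrix(0, nc, nc)
  if (ns > 0) V[seq_len(ns), seq_len(ns)] <- Vs
  if (nt > 0) {
    idx <- ns + seq_len(3 * nt)
    V[idx, idx] <- kronecker(Vt, diag(3))
  }
  comp_E <- c(Es, if (nt > 0) rep(Et, each = 3))
  list(Vs = Vs, Vt = Vt, Es = Es, Et = Et, V = V, comp_values = comp_E)
}

#' One velocity-Verlet step
#'
#' Standard velocity-Verlet update of coordinates and velocities using a
#' gradient callback evaluated on the active surface at the start and end
#' points.
#'
#' @param coords,velocities current nuclear coordinates and velocities.
#' @param mass per-coordinate masses (atomic units).
#' @param gradient_fn function(coords) returning the potential gradient
#'   (hartree per coordinate unit) on the active surface.
#' @param dt time step (atomic time units).
#' @return list with updated `coords` and `velocities`.
#' @export
velocity_verlet_step <- function(coords, velocities, mass, gradient_fn, dt) {
  a0 <- -gradient_fn(coords) / mass
  x1 <- coords + velocities * dt + 0.5 * a0 * dt^2
  a1 <- -gradient_fn(x1) / mass
  list(coords = x1, velocities = velocities + 0.5 * (a0 + a1) * dt)
}

#' Substepped electronic amplitude propagation
#'
#' Advances the complex amplitudes over one nuclear step by unitary
#' integration of \eqn{i\hbar\,\partial c/\partial t = H(t)\,c} with the
#' Hamiltonian linearly interpolated between the step endpoints in the
#' quasi-diabatic propagation basis. Amplitudes are supplied and returned in
#' the diagonal (spin-mixed) basis of the respective endpoint.
#'
#' @param amplitudes complex amplitude vector in the diagonal basis at the
#'   start of the step.
#' @param H_start,H_end Hamiltonians (propagation basis) at the endpoints.
#' @param U_start,U_end diagonal-basis eigenvector matrices at the endpoints.
#' @param dt nuclear step (atomic time units).
#' @param dt_electronic substep (atomic time units); must divide `dt` evenly.
#' @return complex amplitude vector in the diagonal basis at the end point.
#' @export
propagate_amplitudes <- function(amplitudes, H_start, H_end, U_start, U_end,
                                 dt, dt_electronic) {
  nsub <- dt / dt_electronic
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("dt_electronic must divide dt evenly")
  }
  P <- .cx_step_propagator(as_cx(H_start), as_cx(H_end), dt, as.integer(round(nsub)))
  drop(Conj(t(U_end)) %*% (P %*% (U_start %*% amplitudes)))
}

as_cx <- function(M) {
  M <- as.matrix(M)
  if (!is.complex(M)) storage.mode(M) <- "complex"
  M
}

#' Fewest-switches hopping probabilities (population-flux variant)
#'
#' Apportions the loss of active-state population over one nuclear step to
#' the states whose populations grew. Probabilities are non-negative, sum to
#' at most 1, and are zero for the active state; they vanish whenever the
#' active population did not decrease.
#'
#' @param amplitudes_before,amplitudes_after complex amplitudes in the
#'   diagonal basis at the start and end of the step.
#' @param active_state index of the active diagonal state.
#' @param dt time step (unused by this variant; kept for interface parity
#'   with derivative-coupling formulations).
#' @return numeric probability vector.
#' @export
hop_probabilities <- function(amplitudes_before, amplitudes_after,
                              active_state, dt = NULL) {
  pb <- Mod(amplitudes_before)^2
  pa <- Mod(amplitudes_after)^2
  probs <- numeric(length(pb))
  loss <- pb[active_state] - pa[active_state]
  if (pb[active_state] <= 0 || loss <= 0) return(probs)
  gains <- pmax(pa - pb, 0)
  gains[active_state] <- 0
  tot <- sum(gains)
  if (tot <= 0) return(probs)
  probs <- (loss / pb[active_state]) * gains / tot
  probs[active_state] <- 0
  probs
}

#' Attempt a surface hop
#'
#' Draws a target state by comparing one uniform variate against the
#' cumulative hopping probabilities. Accepted hops conserve total energy by
#' uniform rescaling of the full velocity vector; energetically forbidden
#' upward hops are recorded as frustrated with velocities unchanged.
#'
#' @param active index of the active diagonal state.
#' @param probabilities vector from [hop_probabilities()].
#' @param energies diagonal-state potential energies (hartree).
#' @param velocities,mass nuclear velocities and masses.
#' @param u uniform(0,1) variate deciding the hop.
#' @return list with `active`, `velocities`, and `event` (NULL, or a list with
#'   `target`, `delta_e`, `frustrated`).
#' @export
attempt_hop <- function(active, probabilities, energies, velocities, mass, u) {
  cum <- cumsum(probabilities)
  target <- NA_integer_
  if (length(cum) > 0 && u < cum[length(cum)]) {
    target <- which(u < cum)[1]
  }
  if (is.na(target) || target == active) {
    return(list(active = active, velocities = velocities, event = NULL))
  }
  ekin <- 0.5 * sum(mass * velocities^2)
  delta_e <- energies[target] - energies[active]
  if (delta_e > ekin) {
    return(list(active = active, velocities = velocities,
                event = list(target = target, delta_e = delta_e,
                             frustrated = TRUE)))
  }
  fac <- if (ekin > 0) sqrt(max(0, 1 - delta_e / ekin)) else 1
  list(active = target, velocities = velocities * fac,
       event = list(target = target, delta_e = delta_e, frustrated = FALSE))
}

#' Energy-based decoherence correction
#'
#' Damps every non-active amplitude with the gap- and kinetic-energy-dependent
#' time constant \eqn{\tau_\beta = \frac{\hbar}{|E_\beta - E_{active}|}
#' \left(1 + \frac{\alpha}{E_{kin}}\right)} and rescales the active amplitude
#' so the total norm is restored. Degenerate states are left untouched
#' (tau -> infinity).
#'
#' @param amplitudes complex amplitudes in the diagonal basis.
#' @param energies diagonal-state energies (hartree).
#' @param active index of the active state.
#' @param kinetic_energy nuclear kinetic energy (hartree), must be positive.
#' @param dt time step (atomic time units).
#' @param alpha decoherence parameter (hartree).
#' @return corrected complex amplitude vector.
#' @export
apply_decoherence <- function(amplitudes, energies, active, kinetic_energy,
                              dt, alpha = 0.1) {
  if (kinetic_energy <= 0) stop("kinetic energy must be positive")
  norm0 <- sum(Mod(amplitudes)^2)
  gap <- abs(energies - energies[active])
  damp <- ifelse(gap > 0,
                 exp(-dt * gap / (1 + alpha / kinetic_energy)), 1)
  damp[active] <- 1
  out <- amplitudes * damp
  rest <- sum(Mod(out[-active])^2)
  pa <- Mod(out[active])^2
  if (pa > 0) {
    out[active] <- out[active] * sqrt(max(0, norm0 - rest) / pa)
  } else if (norm0 > 0 && sum(Mod(out)^2) > 0) {
    out <- out * sqrt(norm0 / sum(Mod(out)^2))
  }
  out
}

#' Run one surface-hopping trajectory
#'
#' Propagates a single trajectory on an LVC model: velocity-Verlet nuclear
#' motion on the active diagonal (spin-mixed) surface with Hellmann-Feynman
#' gradients, substepped electronic amplitude propagation in the
#' quasi-diabatic basis, energy-based decoherence, and fewest-switches
#' hopping with uniform velocity rescaling. Initial amplitudes are a pure
#' state on the diagonal state that best overlaps the assigned spin-free
#' excited state (delta-pulse excitation). When the model carries no SOC the
#' multiplicity blocks are diagonalized separately, so spin purity is exact.
#'
#' @param model an `lvc_model`.
#' @param coords,velocities initial nuclear coordinates and velocities.
#' @param initial_state spin-free index of the initially excited state.
#' @param settings a `propagator_settings`; its `seed` drives the hopping
#'   stream, so runs are deterministic.
#' @return Object of class `trajectory`: per-step snapshots (time, coords,
#'   velocities, diagonal energies, active diagonal state, MCH assignment,
#'   spectroscopic class, amplitude populations, total energy, norm), a hop
#'   event table, and `status` in `completed`/`crashed`.
#' @export
run_trajectory <- function(model, coords, velocities, initial_state,
                           settings = propagator_settings()) {
  stopifnot(inherits(model, "lvc_model"), inherits(settings, "propagator_settings"))
  space <- model$space
  nc <- space$n_components
  nm <- model$n_modes
  if (length(coords) != nm || length(velocities) != nm) {
    stop("initial condition does not match model dimensionality")
  }
  dt <- settings$dt_fs * units_au$fs_au
  nsteps <- as.integer(round(settings$t_max_fs / settings$dt_fs))
  mass <- model$mass
  rng <- local_rng(settings$seed)
  uvars <- rng$unif(nsteps)
  has_soc <- model$has_soc

  res0 <- evaluate_model(model, coords)
  mch0 <- mch_basis(res0, space)
  if (has_soc) {
    eig0 <- diagonalize_tracked(res0$H)
    U0 <- eig0$vectors; E0 <- eig0$values
  } else {
    U0 <- as_cx(mch0$V); E0 <- mch0$comp_values
  }
  # delta-pulse: diagonal state with maximal overlap with the assigned MCH state
  if (initial_state < 1 || initial_state > space$n_spin_free ||
      space$sf_multiplicity[initial_state] != 1L) {
    stop("initial_state must index a singlet spin-free state")
  }
  Urel0 <- Conj(t(as_cx(mch0$V))) %*% U0
  active <- which.max(Mod(Urel0[initial_state, ])^2)
  amps <- complex(nc); amps[active] <- 1 + 0i

  nrec <- nsteps + 1L
  rec_time <- numeric(nrec)
  rec_coords <- matrix(NA_real_, nrec, nm)
  rec_vel <- matrix(NA_real_, nrec, nm)
  rec_ediag <- matrix(NA_real_, nrec, nc)
  rec_active <- integer(nrec)
  rec_mch <- integer(nrec)
  rec_spect <- integer(nrec)
  rec_pop <- matrix(NA_real_, nrec, nc)
  rec_etot <- numeric(nrec)
  rec_norm <- numeric(nrec)
  hops <- list()
  status <- "completed"

  snapshot <- function(k, t_fs, x, v, E, U, mch, act, amps) {
    rec_time[k] <<- t_fs
    rec_coords[k, ] <<- x
    rec_vel[k, ] <<- v
    rec_ediag[k, ] <<- Re(E)
    rec_active[k] <<- act
    Urel <- Conj(t(as_cx(mch$V))) %*% U
    mc <- mch_assignment(Urel, act)
    rec_mch[k] <<- mc
    rec_spect[k] <<- spect_code(model, mch, mc)
    rec_pop[k, ] <<- Mod(amps)^2
    rec_etot[k] <<- Re(E[act]) + 0.5 * sum(mass * v^2)
    rec_norm[k] <<- sum(Mod(amps)^2)
  }
  snapshot(1L, 0, coords, velocities, E0, U0, mch0, active, amps)

  x0 <- coords; v0 <- velocities
  for (step in seq_len(nsteps)) {
    u_act <- U0[, active]
    g0 <- hf_gradient(res0, u_act)
    a0 <- -g0 / mass
    x1 <- x0 + v0 * dt + 0.5 * a0 * dt^2
    if (!all(is.finite(x1))) { status <- "crashed"; break }
    res1 <- evaluate_model(model, x1)
    mch1 <- mch_basis(res1, space, mch0)
    if (has_soc) {
      eig1 <- diagonalize_tracked(res1$H, U0)
      U1 <- eig1$vectors; E1 <- eig1$values
    } else {
      U1 <- as_cx(mch1$V); E1 <- mch1$comp_values
    }
    g1 <- hf_gradient(res1, U1[, active])
    v1 <- v0 + 0.5 * (a0 - g1 / mass) * dt

    P <- .cx_step_propagator(res0$H, res1$H, dt, settings$nsub)
    amps1 <- drop(Conj(t(U1)) %*% (P %*% (U0 %*% amps)))
    ekin <- 0.5 * sum(mass * v1^2)
    amps1d <- if (settings$decoherence && ekin > 0) {
      apply_decoherence(amps1, Re(E1), active, ekin, dt, settings$alpha)
    } else amps1

    if (settings$hopping) {
      probs <- hop_probabilities(amps, amps1d, active, dt)
      hop <- attempt_hop(active, probs, Re(E1), v1, mass, uvars[step])
      if (!is.null(hop$event)) {
        ev <- hop$event
        Urel1 <- Conj(t(as_cx(mch1$V))) %*% U1
        from_mch <- mch_assignment(Urel1, active)
        to_mch <- mch_assignment(Urel1, ev$target)
        from_sf <- model$comp_state[from_mch]
        to_sf <- model$comp_state[to_mch]
        soc <- NA_real_
        if (model$comp_mult[from_mch] != model$comp_mult[to_mch]) {
          soc <- mch_pair_soc(res1$H, mch1$V, model, from_mch, to_mch)
        }
        hops[[length(hops) + 1L]] <- list(
          time_fs = step * settings$dt_fs,
          from_diag = active, to_diag = ev$target,
          from_sf = from_sf, to_sf = to_sf,
          from_mult = model$comp_mult[from_mch],
          to_mult = model$comp_mult[to_mch],
          delta_e_ev = hartree_to_ev(ev$delta_e),
          soc_cm1 = soc, frustrated = ev$frustrated,
          geometry = x1
        )
        active <- hop$active
        v1 <- hop$velocities
      }
    }
    amps <- amps1d
    x0 <- x1; v0 <- v1; res0 <- res1; mch0 <- mch1; U0 <- U1; E0 <- E1
    snapshot(step + 1L, step * settings$dt_fs, x0, v0, E0, U0, mch0, active, amps)
  }

  nkeep <- if (status == "completed") nrec else step
  hop_df <- if (length(hops) > 0) {
    do.call(rbind, lapply(hops, function(h) {
      data.frame(h[setdiff(names(h), "geometry")], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(time_fs = numeric(0), from_diag = integer(0), to_diag = integer(0),
               from_sf = integer(0), to_sf = integer(0), from_mult = integer(0),
               to_mult = integer(0), delta_e_ev = numeric(0), soc_cm1 = numeric(0),
               frustrated = logical(0))
  }
  structure(list(
    time_fs = rec_time[seq_len(nkeep)],
    coords = rec_coords[seq_len(nkeep), , drop = FALSE],
    velocities = rec_vel[seq_len(nkeep), , drop = FALSE],
    energies_diag = rec_ediag[seq_len(nkeep), , drop = FALSE],
    active = rec_active[seq_len(nkeep)],
    mch_comp = rec_mch[seq_len(nkeep)],
    spect = rec_spect[seq_len(nkeep)],
    amp_pop = rec_pop[seq_len(nkeep), , drop = FALSE],
    energy_total = rec_etot[seq_len(nkeep)],
    norm = rec_norm[seq_len(nkeep)],
    hops = hop_df,
    hop_geometries = lapply(hops, `[[`, "geometry"),
    status = status,
    settings = settings,
    space = space
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %.1f fs, %d snapshots, %d hop events (%d frustrated), status %s\n",
              max(x$time_fs), length(x$time_fs), nrow(x$hops),
              sum(x$hops$frustrated), x$status))
  invisible(x)
}

# Hellmann-Feynman gradient of one diagonal surface: <u| dH/dx_m |u>
hf_gradient <- function(res, u) {
  vapply(res$dH, function(D) Re(Conj(u) %*% D %*% u)[1], numeric(1))
}

# total SOC magnitude (cm^-1) between the spin-free states underlying two MCH
# components of different multiplicity, summed over Ms sublevels
mch_pair_soc <- function(H, V, model, comp_a, comp_b) {
  Hm <- Conj(t(as_cx(V))) %*% H %*% as_cx(V)
  mult <- model$comp_mult
  if (mult[comp_a] == mult[comp_b]) return(NA_real_)
  s <- if (mult[comp_a] == 1L) comp_a else comp_b
  t3 <- if (mult[comp_a] == 3L) comp_a else comp_b
  # all Ms components of the triplet MCH state
  sf <- model$comp_state[t3]
  tcomp <- which(model$comp_state == sf & model$comp_mult == 3L)
  hartree_to_cm1(sqrt(sum(Mod(Hm[s, tcomp])^2)))
}

# spectroscopic class code of an MCH component:
# 1 = S0 closed shell, 2 = bright ppi*, 3 = dark npi*, 4 = triplet
spect_code <- function(model, mch, comp) {
  mult <- model$comp_mult[comp]
  if (mult == 3L) return(4L)
  sf <- model$comp_state[comp]
  if (sf == 1L) return(1L)
  ns <- model$space$n_singlets
  mu <- drop(t(mch$Vs[, sf]) %*% model$mu0[seq_len(ns), , drop = FALSE])
  classify_spectroscopic(sqrt(sum(mu^2)), multiplicity = 1L,
                         is_ground = FALSE, as_code = TRUE)
}
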