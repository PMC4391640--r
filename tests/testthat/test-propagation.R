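test_that("tracked diagonalization is unitary, diagonalizing and continuous", {
  # already-diagonal matrix with identity reference
  H <- diag(c(0.1, 0.25, 0.4)) + 0i
  e <- diagonalize_tracked(H, U_prev = diag(3) + 0i)
  expect_equal(Re(e$values), c(0.1, 0.25, 0.4))
  expect_equal(e$vectors, diag(3) + 0i, tolerance = 1e-14)

  # 2x2 closed form
  cc <- 0.0123
  e2 <- diagonalize_tracked(matrix(c(0, cc, cc, 0), 2, 2) + 0i)
  expect_equal(Re(e2$values), c(-cc, cc), tolerance = 1e-14)

  # random Hermitian 13x13
  set.seed(1)
  A <- matrix(complex(real = rnorm(169), imaginary = rnorm(169)), 13, 13)
  H13 <- (A + Conj(t(A))) / 2
  e13 <- diagonalize_tracked(H13)
  D <- Conj(t(e13$vectors)) %*% H13 %*% e13$vectors
  expect_lt(max(Mod(D - diag(diag(D)))), 1e-10)
  expect_lt(max(Mod(Conj(t(e13$vectors)) %*% e13$vectors - diag(13))), 1e-12)

  # continuity along a slowly varying path: diag(U_prev^H U) real positive
  m <- build_uracil_lvc_model()
  U_prev <- NULL
  for (s in seq(0, 2, by = 0.1)) {
    res <- evaluate_model(m, c(s, 0.3 * s, -0.2 * s))
    e <- diagonalize_tracked(res$H, U_prev)
    if (!is.null(U_prev)) {
      d <- diag(Conj(t(U_prev)) %*% e$vectors)
      expect_true(all(Re(d) > 0))
      expect_lt(max(abs(Im(d))), 1e-8)
    }
    U_prev <- e$vectors
  }
  expect_error(diagonalize_tracked(matrix(c(0, 1, 0, 0), 2, 2)), "Hermitian")
})

test_that("velocity-Verlet reproduces free, harmonic and time-reversed motion", {
  dt <- 0.5 * units_au$fs_au
  # free particle
  st <- velocity_verlet_step(c(1, 2), c(0.01, -0.02), c(100, 100),
                             function(x) c(0, 0), dt)
  expect_equal(st$coords, c(1, 2) + c(0.01, -0.02) * dt)
  expect_equal(st$velocities, c(0.01, -0.02))

  # harmonic oscillator vs analytic cosine over 1000 steps
  k <- 7.2e-4; mass <- 180
  nu <- sqrt(k / mass)
  x <- 1.3; v <- 0
  for (i in 1:1000) {
    st <- velocity_verlet_step(x, v, mass, function(q) k * q, dt)
    x <- st$coords; v <- st$velocities
  }
  t_end <- 1000 * dt
  n_periods <- t_end * nu / (2 * pi)
  expect_lt(abs(x - 1.3 * cos(nu * t_end)), 1e-3 * 1.3 * n_periods)

  # time reversal symmetry
  g <- function(q) 0.004 * q + 0.002
  f1 <- velocity_verlet_step(0.7, 0.015, 120, g, dt)
  f2 <- velocity_verlet_step(f1$coords, -f1$velocities, 120, g, dt)
  expect_equal(f2$coords, 0.7, tolerance = 1e-10)
  expect_equal(f2$velocities, -0.015, tolerance = 1e-10)
})

test_that("amplitude propagation is phase-exact, unitary and matches Rabi", {
  dt <- 0.5 * units_au$fs_au
  # constant diagonal H: pure phases
  E <- c(0.05, 0.21)
  H <- diag(E) + 0i
  c0 <- complex(real = c(0.6, 0.8))
  c1 <- propagate_amplitudes(c0, H, H, diag(2) + 0i, diag(2) + 0i, dt, dt / 25)
  expect_equal(c1, c0 * exp(-1i * E * dt), tolerance = 1e-12)

  # norm conservation along a random H path
  set.seed(2)
  amps <- c(1 + 0i, 0i, 0i)
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  H0 <- (A + Conj(t(A))) / 2 * 0.01
  U <- diag(3) + 0i
  for (i in 1:500) {
    B <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
    H1 <- H0 + (B + Conj(t(B))) / 2 * 5e-4
    amps <- propagate_amplitudes(amps, H0, H1, U, U, dt, dt / 25)
    H0 <- H1
  }
  expect_lt(abs(sum(Mod(amps)^2) - 1), 1e-9)

  # Rabi oscillation closed form: H = [[0, c], [c, 0]], P2(t) = sin^2(c t)
  cc <- 0.002
  Hr <- matrix(c(0, cc, cc, 0), 2, 2) + 0i
  amps <- c(1 + 0i, 0i)
  nstep <- 200
  for (i in seq_len(nstep)) {
    amps <- propagate_amplitudes(amps, Hr, Hr, diag(2) + 0i, diag(2) + 0i,
                                 dt, dt / 25)
  }
  expect_equal(Mod(amps[2])^2, sin(cc * nstep * dt)^2, tolerance = 1e-6)
})

test_that("hopping probabilities implement the population-flux prescription", {
  c0 <- complex(real = c(sqrt(0.7), sqrt(0.2), sqrt(0.1)))
  expect_equal(hop_probabilities(c0, c0, 1), rep(0, 3))
  # complete transfer limit
  p <- hop_probabilities(c(1 + 0i, 0i), c(0i, 1 + 0i), 1)
  expect_equal(p, c(0, 1))
  # general case: non-negative, sum <= 1, zero on the active state
  set.seed(8)
  for (k in 1:50) {
    a <- complex(real = rnorm(4), imaginary = rnorm(4))
    b <- complex(real = rnorm(4), imaginary = rnorm(4))
    a <- a / sqrt(sum(Mod(a)^2)); b <- b / sqrt(sum(Mod(b)^2))
    pr <- hop_probabilities(a, b, 2)
    expect_true(all(pr >= 0))
    expect_lte(sum(pr), 1 + 1e-12)
    expect_identical(pr[2], 0)
  }
  # growth apportioning: only gaining states receive probability
  a <- sqrt(c(0.5, 0.3, 0.2)) + 0i
  b <- sqrt(c(0.3, 0.5, 0.2)) + 0i
  pr <- hop_probabilities(a, b, 1)
  expect_equal(pr[3], 0)
  expect_equal(pr[2], (0.2 / 0.5), tolerance = 1e-12)
})

test_that("hop attempts conserve energy or are frustrated", {
  probs <- c(0, 0, 0)
  out <- attempt_hop(1, probs, c(0, 0.01, 0.02), c(0.01), 1000, u = 0.5)
  expect_identical(out$active, 1)
  expect_null(out$event)

  # accepted downward hop: kinetic energy increases by exactly -delta_e
  E <- c(0.10, 0.06)
  v <- c(0.003); mass <- 2000
  out <- attempt_hop(1, c(0, 1), E, v, mass, u = 0.5)
  expect_identical(out$active, 2L)
  ek0 <- 0.5 * mass * v^2
  ek1 <- 0.5 * mass * out$velocities^2
  expect_lt(abs((ek1 + E[2]) - (ek0 + E[1])), 1e-10)

  # forbidden upward hop: frustrated, velocities unchanged
  E <- c(0.0, 0.5)
  out <- attempt_hop(1, c(0, 1), E, v, mass, u = 0.5)
  expect_identical(out$active, 1)
  expect_true(out$event$frustrated)
  expect_identical(out$velocities, v)
})

test_that("energy-based decoherence damps with the stated time constant", {
  amps <- c(sqrt(0.8), sqrt(0.2)) + 0i
  # degenerate states are untouched
  out <- apply_decoherence(amps, c(0.1, 0.1), 1, 0.05, 20.67, alpha = 0.1)
  expect_equal(out, amps)
  # pure active state is a fixed point
  pure <- c(1 + 0i, 0i)
  expect_equal(apply_decoherence(pure, c(0, 0.2), 1, 0.03, 20.67), pure)
  # hand-computed damping factor: dE = 0.1, Ekin = 0.05, dt = 0.5 fs
  dt <- 0.5 * units_au$fs_au
  tau <- (1 / 0.1) * (1 + 0.1 / 0.05)
  fac <- exp(-dt / tau)
  out <- apply_decoherence(amps, c(0, 0.1), 1, 0.05, dt, alpha = 0.1)
  expect_equal(Mod(out[2]), Mod(amps[2]) * fac, tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  expect_error(apply_decoherence(amps, c(0, 0.1), 1, -0.1, dt), "positive")
})

test_that("trajectories conserve norm and are deterministic", {
  m <- build_uracil_lvc_model()
  w <- sample_wigner(model_modes(m), 2, seed = 21)
  set <- propagator_settings(t_max_fs = 50, seed = 5)
  t1 <- run_trajectory(m, w$coords[1, ], w$velocities[1, ], 3, set)
  t2 <- run_trajectory(m, w$coords[1, ], w$velocities[1, ], 3, set)
  expect_identical(t1, t2)
  expect_lt(max(abs(t1$norm - 1)), 1e-8)
  expect_equal(t1$status, "completed")
  expect_error(run_trajectory(m, w$coords[1, ], w$velocities[1, ], 5, set),
               "singlet")
})

test_that("a single-state model propagates adiabatically without hops", {
  sp <- make_state_space(1, 0)
  m <- new_lvc_model(sp, omega = c(0.007, 0.004), epsilon = 0,
                     kappa = matrix(c(0.01, 0.002), 1, 2))
  set <- propagator_settings(t_max_fs = 1000, seed = 2)
  tr <- run_trajectory(m, c(1, -0.5), c(0.001, 0), 1, set)
  expect_identical(nrow(tr$hops), 0L)
  drift <- abs(unname(stats::coef(stats::lm(tr$energy_total ~ tr$time_fs))[2])) * 1000
  expect_lt(drift, 1e-6)
})

test_that("spin purity is exact when all SOC constants vanish", {
  m <- build_uracil_lvc_model(list(eta_cm1 = 0))
  w <- sample_wigner(model_modes(m), 2, seed = 31)
  set <- propagator_settings(t_max_fs = 100, seed = 13)
  tr <- run_trajectory(m, w$coords[1, ], w$velocities[1, ], 3, set)
  trip_comp <- which(m$comp_mult == 3L)
  expect_true(all(tr$amp_pop[, trip_comp] == 0))
  expect_true(all(m$comp_mult[tr$mch_comp] == 1L))
  # diagonal and MCH assignments coincide when the bases are identical
  expect_identical(tr$active, tr$mch_comp)
})
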