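#' Harmonic normal-mode set
#'
#' Container for the vibrational modes used by the Wigner sampler. Modes may
#' live directly in the model's (possibly dimensionless) coordinates, in which
#' case the displacement matrix is the identity, or span full Cartesian space
#' through mass-weighted displacement vectors.
#'
#' @param x0 reference coordinates (length = coordinate dimension).
#' @param freq_au per-mode angular frequency in atomic units; all sampled
#'   frequencies must be positive. Use [normal_mode_set_cm1()] to construct
#'   from wavenumbers.
#' @param mass per-mode effective mass (atomic units).
#' @param displacements matrix (dimension x n_modes) of unit displacement
#'   vectors, orthonormal in mass-weighted coordinates; default identity.
#' @return An object of class `normal_mode_set`.
#' @export
normal_mode_set <- function(x0, freq_au, mass, displacements = NULL) {
  n_modes <- length(freq_au)
  if (length(mass) == 1) mass <- rep(mass, n_modes)
  if (length(mass) != n_modes) stop("mass must have one entry per mode")
  if (is.null(displacements)) displacements <- diag(length(x0))[, seq_len(n_modes), drop = FALSE]
  displacements <- as.matrix(displacements)
  if (nrow(displacements) != length(x0) || ncol(displacements) != n_modes) {
    stop("displacements must be (length(x0) x n_modes)")
  }
  structure(list(x0 = x0, freq = freq_au, mass = mass,
                 displacements = displacements, n_modes = n_modes),
            class = "normal_mode_set")
}

#' @param freq_cm1 per-mode harmonic wavenumbers (cm^-1).
#' @rdname normal_mode_set
#' @export
normal_mode_set_cm1 <- function(x0, freq_cm1, mass, displacements = NULL) {
  normal_mode_set(x0, cm1_to_hartree(freq_cm1), mass, displacements)
}

#' Read a plain-text frequencies/modes file
#'
#' Simple whitespace-delimited format: a header line `n_dim n_modes`, one line
#' with the reference coordinates, then per mode one line
#' `freq_cm1 mass d_1 ... d_ndim`.
#'
#' @param path file path.
#' @return A `normal_mode_set`.
#' @export
read_modes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- scan(text = lines[1], quiet = TRUE)
  ndim <- hdr[1]; nm <- hdr[2]
  x0 <- scan(text = lines[2], quiet = TRUE)
  if (length(x0) != ndim) stop("reference coordinate line has wrong length")
  freq <- numeric(nm); mass <- numeric(nm); disp <- matrix(0, ndim, nm)
  for (m in seq_len(nm)) {
    v <- scan(text = lines[2 + m], quiet = TRUE)
    if (length(v) != 2 + ndim) stop("mode line ", m, " has wrong length")
    freq[m] <- v[1]; mass[m] <- v[2]; disp[, m] <- v[-(1:2)]
  }
  normal_mode_set_cm1(x0, freq, mass, disp)
}

#' Sample the ground-state harmonic Wigner distribution
#'
#' Draws uncorrelated geometries and velocities from the Wigner function of
#' the vibrational ground state (0 K): per mode, Gaussian position with
#' variance \eqn{\hbar/(2 m \omega)} and Gaussian momentum with variance
#' \eqn{m \omega \hbar / 2}, mutually independent.
#'
#' @param modes a `normal_mode_set`; all frequencies must be positive.
#' @param n number of samples (>= 1).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return Object of class `wigner_samples`: list with matrices `coords` and
#'   `velocities` (n x dimension), the mode set, `n` and `seed`.
#' @export
#' @examples
#' nm <- normal_mode_set(0, 0.005, 200)
#' w <- sample_wigner(nm, 100, seed = 1)
sample_wigner <- function(modes, n, seed) {
  stopifnot(inherits(modes, "normal_mode_set"))
  if (n < 1) stop("n must be >= 1")
  if (any(modes$freq <= 0)) stop("all sampled frequencies must be positive")
  rng <- local_rng(seed)
  sd_q <- sqrt(1 / (2 * modes$mass * modes$freq))
  sd_p <- sqrt(modes$mass * modes$freq / 2)
  q <- sweep(matrix(rng$norm(n * modes$n_modes), n, modes$n_modes), 2, sd_q, "*")
  p <- sweep(matrix(rng$norm(n * modes$n_modes), n, modes$n_modes), 2, sd_p, "*")
  coords <- sweep(q %*% t(modes$displacements), 2, modes$x0, "+")
  vel <- sweep(p, 2, modes$mass, "/") %*% t(modes$displacements)
  structure(list(coords = coords, velocities = vel, modes = modes,
                 n = n, seed = seed),
            class = "wigner_samples")
}

#' Oscillator strength from excitation energy and transition dipole
#'
#' Length-gauge formula \eqn{f = (2/3)\,\Delta E\,|\mu|^2} in atomic units.
#'
#' @param delta_e excitation energy (hartree), must be positive.
#' @param dipole transition dipole vector (a.u.), or a matrix with one row
#'   per transition.
#' @return Dimensionless oscillator strength(s).
#' @export
#' @examples
#' oscillator_strength(0.25, c(1, 0, 0))  # 1/6
oscillator_strength <- function(delta_e, dipole) {
  if (any(delta_e <= 0)) stop("excitation energy must be positive")
  if (is.matrix(dipole)) {
    mu2 <- rowSums(dipole^2)
  } else {
    mu2 <- sum(dipole^2)
  }
  (2 / 3) * delta_e * mu2
}

#' Simulate a broadened absorption spectrum
#'
#' Sum of Gaussians, one per transition, centered at the excitation energy
#' with area proportional to the oscillator strength.
#'
#' @param conditions data frame with columns `energy_ev` and `f` (one row per
#'   transition), e.g. as produced by [excitation_table()].
#' @param fwhm Gaussian full width at half maximum (eV), must be positive.
#' @param grid energy grid (eV); default covers the lines plus 3 fwhm at
#'   resolution fwhm/20.
#' @return data frame with columns `energy_ev`, `intensity`; attribute
#'   `total_f` carries the summed oscillator strength. An empty condition
#'   list yields an empty spectrum with a warning.
#' @export
simulate_spectrum <- function(conditions, fwhm = 0.1, grid = NULL) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (is.null(conditions) || nrow(conditions) == 0) {
    warning("no transitions supplied; returning empty spectrum")
    return(structure(data.frame(energy_ev = numeric(0), intensity = numeric(0)),
                     total_f = 0))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(grid)) {
    lo <- min(conditions$energy_ev) - 3 * fwhm
    hi <- max(conditions$energy_ev) + 3 * fwhm
    grid <- seq(lo, hi, by = fwhm / 20)
  }
  intensity <- numeric(length(grid))
  norm <- 1 / (sigma * sqrt(2 * pi))
  for (i in seq_len(nrow(conditions))) {
    intensity <- intensity + conditions$f[i] * norm *
      exp(-(grid - conditions$energy_ev[i])^2 / (2 * sigma^2))
  }
  structure(data.frame(energy_ev = grid, intensity = intensity),
            total_f = sum(conditions$f))
}

#' Per-sample excitation energies and oscillator strengths
#'
#' Evaluates the model at every Wigner sample and tabulates, for each singlet
#' excited state, the vertical excitation energy out of the lowest spin-free
#' singlet eigenstate and the oscillator strength from the transformed
#' transition dipoles. This is the pool that the absorption spectrum and the
#' delta-pulse selection draw from.
#'
#' @param model an `lvc_model` whose first singlet is the closed-shell ground
#'   state.
#' @param samples a `wigner_samples` object.
#' @return data frame with columns `sample`, `state` (spin-free index),
#'   `label`, `energy_ev`, `f`.
#' @export
excitation_table <- function(model, samples) {
  ns <- model$space$n_singlets
  if (ns < 2) stop("model needs at least two singlet states")
  out <- vector("list", samples$n)
  for (k in seq_len(samples$n)) {
    res <- evaluate_model(model, samples$coords[k, ])
    es <- eigen(res$S_block, symmetric = TRUE)
    ord <- order(es$values)
    vals <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE]
    # transition dipoles rotated into the spin-free eigenbasis (Condon dipoles
    # of the diabats combined with the eigenvector of each adiabatic state)
    mu <- t(vecs) %*% res$dipoles[seq_len(ns), , drop = FALSE]
    de <- vals[-1] - vals[1]
    f <- oscillator_strength(de, mu[-1, , drop = FALSE])
    out[[k]] <- data.frame(sample = k, state = 2:ns,
                           label = model$space$sf_labels[2:ns],
                           energy_ev = hartree_to_ev(de), f = f)
  }
  do.call(rbind, out)
}

#' Select initial excited states by oscillator strength (delta-pulse)
#'
#' Given the pool of per-sample per-state excitation energies and oscillator
#' strengths, draws `n_traj` (sample, state) pairs with probability
#' proportional to the oscillator strength among the pairs whose excitation
#' energy lies inside the (inclusive) energy window. Selection is with
#' replacement, mirroring an instantaneous (delta-pulse) excitation whose
#' per-trajectory initial state is an independent draw.
#'
#' @param pool data frame as from [excitation_table()].
#' @param n_traj number of trajectories to select.
#' @param window optional inclusive energy window `c(E_lo, E_hi)` in eV.
#' @param seed integer seed.
#' @return data frame of initial conditions (columns of `pool` plus
#'   `traj_id`), with attribute `state_split` (named count per state label).
#' @export
select_initial_conditions <- function(pool, n_traj, window = NULL, seed = 1) {
  if (is.null(pool) || nrow(pool) == 0) stop("empty pool")
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] > window[2]) {
      stop("window must be c(E_lo, E_hi) with E_lo <= E_hi")
    }
    pool <- pool[pool$energy_ev >= window[1] & pool$energy_ev <= window[2], ]
  }
  pool <- pool[pool$f > 0, ]
  if (nrow(pool) == 0) {
    stop("no eligible (sample, state) pair inside the excitation window")
  }
  rng <- local_rng(seed)
  idx <- rng$sample_int(nrow(pool), n_traj, prob = pool$f, replace = TRUE)
  out <- pool[idx, , drop = FALSE]
  out$traj_id <- seq_len(n_traj)
  rownames(out) <- NULL
  split <- table(out$label)
  attr(out, "state_split") <- split
  out
}

# RNG helper: isolates package sampling from the global RNG state while
# remaining deterministic under a fixed integer seed.
local_rng <- function(seed) {
  if (is.null(seed)) stop("a seed is required for reproducible sampling")
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    fn()
  }
  list(
    norm = function(n) with_state(function() stats::rnorm(n)),
    unif = function(n = 1) with_state(function() stats::runif(n)),
    sample_int = function(n, size, prob = NULL, replace = FALSE) {
      with_state(function() sample.int(n, size, replace = replace, prob = prob))
    }
  )
}
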