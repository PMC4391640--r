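#' Construct a spin-component state space
#'
#' Enumerates the explicit spin components spanned by a set of singlet and
#' triplet electronic states. Components are ordered with all singlets first
#' (by energy index) followed by the triplets grouped by state with the
#' magnetic sublevel Ms ascending (-1, 0, +1). This ordering is fixed; all
#' Hamiltonians in the package use it.
#'
#' @param n_singlets number of singlet states (the first one is taken as the
#'   closed-shell ground state when present).
#' @param n_triplets number of triplet states; each contributes three spin
#'   components.
#' @return An object of class `state_space`: a list with counts and a
#'   data frame `components` (columns `multiplicity`, `state`, `ms`,
#'   `sf_index`, `label`).
#' @export
#' @examples
#' make_state_space(4, 3)  # 13 spin components
make_state_space <- function(n_singlets, n_triplets) {
  if (length(n_singlets) != 1L || length(n_triplets) != 1L ||
      is.na(n_singlets) || is.na(n_triplets) ||
      n_singlets < 0 || n_triplets < 0 ||
      n_singlets != round(n_singlets) || n_triplets != round(n_triplets)) {
    stop("n_singlets and n_triplets must be non-negative integers")
  }
  if (n_singlets == 0 && n_triplets == 0) {
    stop("state space must contain at least one state")
  }
  n_singlets <- as.integer(n_singlets)
  n_triplets <- as.integer(n_triplets)
  comp <- data.frame(
    multiplicity = integer(0), state = integer(0), ms = integer(0),
    sf_index = integer(0), label = character(0), stringsAsFactors = FALSE
  )
  if (n_singlets > 0) {
    comp <- rbind(comp, data.frame(
      multiplicity = 1L, state = seq_len(n_singlets), ms = 0L,
      sf_index = seq_len(n_singlets),
      label = paste0("S", seq_len(n_singlets) - 1L),
      stringsAsFactors = FALSE
    ))
  }
  if (n_triplets > 0) {
    tri <- expand.grid(ms = c(-1L, 0L, 1L), state = seq_len(n_triplets))
    tri <- tri[order(tri$state, tri$ms), ]
    comp <- rbind(comp, data.frame(
      multiplicity = 3L, state = tri$state, ms = tri$ms,
      sf_index = n_singlets + tri$state,
      label = sprintf("T%d(ms=%+d)", tri$state, tri$ms),
      stringsAsFactors = FALSE
    ))
  }
  rownames(comp) <- NULL
  structure(list(
    n_singlets = n_singlets,
    n_triplets = n_triplets,
    n_spin_free = n_singlets + n_triplets,
    n_components = n_singlets + 3L * n_triplets,
    components = comp,
    # spin-free labels: S0.. then T1..
    sf_labels = c(if (n_singlets > 0) paste0("S", seq_len(n_singlets) - 1L),
                  if (n_triplets > 0) paste0("T", seq_len(n_triplets))),
    sf_multiplicity = c(rep(1L, n_singlets), rep(3L, n_triplets))
  ), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state space: %d singlets + %d triplets = %d spin components\n",
              x$n_singlets, x$n_triplets, x$n_components))
  invisible(x)
}

# Ms replication weights for singlet-triplet SOC matrix elements: one total
# magnitude |eta| is split equally over the three Ms components with real
# positive coefficients, so sqrt(sum over Ms of |H|^2) = |eta|. With this
# (Condon-like) convention only the symmetric Ms combination couples to the
# singlet, which is the physically relevant single ISC channel of the pair.
.soc_ms_weights <- rep(1, 3) / sqrt(3)

#' Construct a linear vibronic coupling (LVC) model potential
#'
#' Low-level constructor. The diabatic Hamiltonian over spin components is
#' \deqn{H_{ii}(x) = \epsilon_i + \sum_m \kappa_{i,m} x_m + \sum_m \tfrac12 \omega_m x_m^2}
#' with the harmonic part common to all states, spin-free interstate couplings
#' \eqn{H_{ij} = \lambda^{(0)}_{ij} + \sum_m \lambda_{ij,m} x_m} between equal
#' multiplicities (equal Ms for triplets), and geometry-independent complex
#' SOC constants \eqn{\eta} between singlet components and triplet spin
#' components. Coordinates are dimensionless mass-frequency-scaled normal
#' coordinates when `mass = 1/omega` (the default of the builders), in which
#' case the classical oscillation angular frequency on any single surface
#' equals `omega`.
#'
#' @param space a `state_space`.
#' @param omega per-mode harmonic constants (hartree).
#' @param epsilon per spin-free state vertical energy at the reference
#'   geometry (hartree).
#' @param kappa matrix (n_spin_free x n_modes) of intrastate linear coupling
#'   constants (hartree per unit coordinate).
#' @param lambda array (n_spin_free x n_spin_free x n_modes) of linear
#'   interstate couplings; must be symmetric in the first two indices and zero
#'   between different multiplicities. Default all zero.
#' @param lambda0 constant interstate coupling matrix, same symmetry rules.
#' @param eta complex matrix (n_singlets x n_triplets) of SOC magnitudes in
#'   hartree. Default all zero.
#' @param mu0 matrix (n_spin_free x 3) of transition dipole vectors from the
#'   ground state at the reference geometry (atomic units); the ground-state
#'   row must be zero, triplet rows should be zero.
#' @param mass per-mode effective masses (atomic units); default `1/omega`.
#' @return An object of class `lvc_model`.
#' @export
new_lvc_model <- function(space, omega, epsilon, kappa,
                          lambda = NULL, lambda0 = NULL, eta = NULL,
                          mu0 = NULL, mass = NULL) {
  stopifnot(inherits(space, "state_space"))
  n_modes <- length(omega)
  nsf <- space$n_spin_free
  nc <- space$n_components
  if (is.null(mass)) {
    if (any(omega <= 0)) stop("default mass = 1/omega requires omega > 0")
    mass <- 1 / omega
  }
  if (any(mass <= 0)) stop("masses must be positive")
  if (length(epsilon) != nsf) stop("epsilon length must equal spin-free state count")
  kappa <- as.matrix(kappa)
  if (!all(dim(kappa) == c(nsf, n_modes))) {
    stop("kappa must be a (n_spin_free x n_modes) matrix")
  }
  if (is.null(lambda)) lambda <- array(0, c(nsf, nsf, n_modes))
  if (is.null(lambda0)) lambda0 <- matrix(0, nsf, nsf)
  if (!all(dim(lambda) == c(nsf, nsf, n_modes))) stop("lambda has wrong dimensions")
  if (!all(dim(lambda0) == c(nsf, nsf))) stop("lambda0 has wrong dimensions")
  if (is.null(eta) || space$n_singlets == 0L || space$n_triplets == 0L) {
    eta <- matrix(0 + 0i, space$n_singlets, space$n_triplets)
  } else {
    eta <- matrix(as.complex(eta), space$n_singlets, space$n_triplets)
  }
  mult <- space$sf_multiplicity
  for (m in seq_len(n_modes)) {
    lm <- matrix(lambda[, , m], nsf, nsf)
    if (max(abs(lm - t(lm))) > 0) stop("lambda slices must be symmetric")
    if (any(lm[outer(mult, mult, "!=")] != 0)) {
      stop("lambda may only connect states of equal multiplicity")
    }
  }
  if (max(abs(lambda0 - t(lambda0))) > 0) stop("lambda0 must be symmetric")
  if (any(lambda0[outer(mult, mult, "!=")] != 0)) {
    stop("lambda0 may only connect states of equal multiplicity")
  }
  if (is.null(mu0)) mu0 <- matrix(0, nsf, 3)
  mu0 <- as.matrix(mu0)
  if (!all(dim(mu0) == c(nsf, 3))) stop("mu0 must be (n_spin_free x 3)")

  comp <- space$components
  cs <- comp$sf_index
  # constant part of H: lambda0 replicated over equal-Ms pairs + SOC entries
  Hc <- matrix(0 + 0i, nc, nc)
  same_block <- outer(comp$multiplicity, comp$multiplicity, "==") &
    outer(comp$ms, comp$ms, "==")
  Hc[same_block] <- lambda0[cbind(cs[row(Hc)[same_block]], cs[col(Hc)[same_block]])]
  diag(Hc) <- 0
  if (space$n_singlets > 0 && space$n_triplets > 0) {
    w <- .soc_ms_weights
    for (i in seq_len(space$n_singlets)) {
      for (j in seq_len(space$n_triplets)) {
        if (eta[i, j] == 0) next
        tcomp <- which(comp$multiplicity == 3L & comp$state == j)  # ms -1,0,+1
        Hc[i, tcomp] <- eta[i, j] * w
        Hc[tcomp, i] <- Conj(eta[i, j] * w)
      }
    }
  }
  # per-mode linear parts: diag(kappa) + lambda slice replicated
  D <- vector("list", n_modes)
  for (m in seq_len(n_modes)) {
    Dm <- matrix(0 + 0i, nc, nc)
    lam_m <- matrix(lambda[, , m], nsf, nsf)
    Dm[same_block] <- lam_m[cbind(cs[row(Dm)[same_block]], cs[col(Dm)[same_block]])]
    diag(Dm) <- kappa[cs, m]
    D[[m]] <- Dm
  }

  structure(list(
    space = space, n_modes = n_modes,
    omega = omega, mass = mass,
    epsilon = epsilon, kappa = kappa,
    lambda = lambda, lambda0 = lambda0, eta = eta, mu0 = mu0,
    Hconst = Hc, Dlin = D,
    comp_state = cs, comp_mult = comp$multiplicity, comp_ms = comp$ms,
    has_soc = any(Mod(eta) > 0)
  ), class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  cat(sprintf("LVC model: %d singlets + %d triplets (%d components), %d modes, SOC %s\n",
              x$space$n_singlets, x$space$n_triplets, x$space$n_components,
              x$n_modes, if (x$has_soc) "on" else "off"))
  cat("vertical energies (eV):",
      paste(sprintf("%s %.2f", x$space$sf_labels, hartree_to_ev(x$epsilon)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Default parameters of the uracil-like LVC model
#'
#' Returns the default configuration of [build_uracil_lvc_model()] as a list,
#' so individual entries can be inspected or overridden. Reference vertical
#' energies are state-averaged multi-configurational benchmark values for the
#' diketo tautomer; SOC
#' magnitudes follow El-Sayed's rule with ~40 cm^-1 for character-changing
#' singlet-triplet pairs and ~4 cm^-1 for same-character pairs. Three
#' effective modes: a ppi*/npi* tuning mode, a vibronic coupling (ISC/IC
#' promoting) mode, and a ground-state-recovery mode.
#'
#' @return A named list of parameter groups (see [build_uracil_lvc_model()]).
#' @export
uracil_lvc_defaults <- function() {
  list(
    n_singlets = 4L, n_triplets = 3L,
    # S0, S1(npi*), S2(ppi*), S3, T1(ppi*), T2(npi*), T3(ppi*)
    epsilon_ev = c(0, 5.13, 7.04, 7.07, 4.00, 4.95, 5.86),
    omega_cm1 = c(1520, 880, 1210),
    # hartree per dimensionless normal coordinate; rows follow sf states
    kappa = matrix(c(
      #  tuning   coupling  recovery
       0.000,     0,  0.000,   # S0
       0.010,     0, -0.025,   # S1 npi*
      -0.015,     0,  0.000,   # S2 ppi*
      -0.010,     0,  0.000,   # S3
      -0.015,     0, -0.020,   # T1 ppi*
       0.008,     0, -0.028,   # T2 npi*
      -0.012,     0,  0.000    # T3 ppi*
    ), nrow = 7, byrow = TRUE),
    # linear interstate couplings on the coupling mode (hartree per unit q)
    lambda_pairs = list(
      list("S0", "S1", 0.0006), list("S0", "S2", 0.0001), list("S0", "S3", 0.0001),
      list("S1", "S2", 0.0050), list("S1", "S3", 0.0020), list("S2", "S3", 0.0060),
      list("T1", "T2", 0.0080), list("T1", "T3", 0.0030), list("T2", "T3", 0.0060)
    ),
    coupling_mode = 2L,
    # SOC magnitudes in cm^-1, rows S0..S3, columns T1..T3
    eta_cm1 = matrix(c(
       2,  8,  2,   # S0
      40,  4, 40,   # S1 npi* -> ppi* triplets (El-Sayed allowed)
       4, 40,  4,   # S2 ppi*
       4, 40,  4    # S3
    ), nrow = 4, byrow = TRUE),
    # transition dipoles from S0 (a.u.)
    mu0 = rbind(
      c(0, 0, 0),        # S0
      c(0.02, 0, 0),     # S1 dark npi*
      c(1.2, 0, 0),      # S2 bright ppi*
      c(0, 1.1, 0),      # S3 bright
      matrix(0, 3, 3)    # triplets
    )
  )
}

#' Build the default uracil-like LVC model
#'
#' Constructs a reduced-dimensional linear vibronic coupling model of the
#' diketo nucleobase with 4 singlets and 3 triplets (13 spin components) over
#' three effective modes. At the reference geometry all interstate couplings
#' vanish (they are linear in the coupling-mode displacement), so with SOC
#' disabled the configured vertical energies are exact eigenvalues there.
#'
#' @param config named list overriding entries of [uracil_lvc_defaults()].
#'   Recognised keys: `epsilon_ev`, `omega_cm1`, `kappa`, `lambda_pairs`,
#'   `coupling_mode`, `eta_cm1`, `mu0`, `n_singlets`, `n_triplets`.
#'   `eta_cm1` may be a single number (uniform scale, 0 disables SOC) or a
#'   full (n_singlets x n_triplets) matrix.
#' @return An `lvc_model`.
#' @export
#' @examples
#' m <- build_uracil_lvc_model()
#' res <- evaluate_model(m, c(0, 0, 0))
build_uracil_lvc_model <- function(config = list()) {
  def <- uracil_lvc_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  # replacement (not recursive-merge) semantics: a supplied key overrides the
  # default entirely, so e.g. lambda_pairs = list() disables all couplings
  p <- def
  p[names(config)] <- config
  space <- make_state_space(p$n_singlets, p$n_triplets)
  nsf <- space$n_spin_free
  n_modes <- length(p$omega_cm1)
  if (length(p$epsilon_ev) != nsf) {
    stop("configuration error: epsilon_ev must have ", nsf, " entries")
  }
  kappa <- as.matrix(p$kappa)
  if (!all(dim(kappa) == c(nsf, n_modes))) {
    stop("configuration error: kappa must be (", nsf, " x ", n_modes, ")")
  }
  lab <- space$sf_labels
  lambda <- array(0, c(nsf, nsf, n_modes))
  for (pr in p$lambda_pairs) {
    i <- match(pr[[1]], lab); j <- match(pr[[2]], lab)
    if (is.na(i) || is.na(j)) {
      stop("configuration error: unknown state label in lambda_pairs")
    }
    lambda[i, j, p$coupling_mode] <- pr[[3]]
    lambda[j, i, p$coupling_mode] <- pr[[3]]
  }
  eta_cm1 <- p$eta_cm1
  if (length(eta_cm1) == 1) {
    scale <- eta_cm1 / 40
    eta_cm1 <- def$eta_cm1 * scale
  }
  eta_cm1 <- matrix(eta_cm1, space$n_singlets, space$n_triplets)
  mu0 <- as.matrix(p$mu0)
  if (!all(dim(mu0) == c(nsf, 3))) {
    stop("configuration error: mu0 must be (", nsf, " x 3)")
  }
  new_lvc_model(
    space = space,
    omega = cm1_to_hartree(p$omega_cm1),
    epsilon = ev_to_hartree(p$epsilon_ev),
    kappa = kappa,
    lambda = lambda,
    eta = cm1_to_hartree(eta_cm1),
    mu0 = mu0
  )
}

#' Build a 1D two-state linear crossing model
#'
#' Validation fixture with a closed-form oracle: diabatic energies
#' \eqn{\pm k x} and a constant coupling `c`, so the adiabatic energies are
#' \eqn{\pm\sqrt{(kx)^2 + c^2}} and a single passage at constant velocity `v`
#' follows the Landau-Zener transition probability
#' \eqn{\exp(-2\pi c^2 / (\hbar v \cdot 2k))}.
#'
#' @param slope k > 0, diabatic slope magnitude (hartree/bohr).
#' @param coupling c >= 0, constant diabatic coupling (hartree). Spin-free if
#'   the multiplicities are equal, SOC-type otherwise.
#' @param mass nuclear mass (atomic units), must be positive.
#' @param multiplicities integer pair from {1, 3} for the two states.
#' @return An `lvc_model` with one mode and no harmonic term.
#' @export
build_two_state_crossing <- function(slope, coupling, mass,
                                     multiplicities = c(1, 1)) {
  if (slope <= 0) stop("slope must be positive")
  if (coupling < 0) stop("coupling must be non-negative")
  if (mass <= 0) stop("mass must be positive")
  if (!all(multiplicities %in% c(1, 3)) || length(multiplicities) != 2) {
    stop("multiplicities must be a pair from {1, 3}")
  }
  ns <- sum(multiplicities == 1)
  nt <- sum(multiplicities == 3)
  space <- make_state_space(ns, nt)
  # spin-free state 1 is +k x, state 2 is -k x; with mixed multiplicities the
  # singlet occupies slot 1 of the component ordering regardless of the order
  # of the multiplicities argument
  kap <- matrix(c(slope, -slope), 2, 1)
  lambda0 <- matrix(0, 2, 2)
  eta <- NULL
  if (ns == 2 || nt == 2) {
    lambda0[1, 2] <- lambda0[2, 1] <- coupling
  } else {
    eta <- matrix(complex(real = coupling), 1, 1)
  }
  new_lvc_model(space, omega = 0, epsilon = c(0, 0), kappa = kap,
                lambda0 = lambda0, eta = eta, mass = mass)
}

#' Evaluate an LVC model at a nuclear configuration
#'
#' Returns the electronic-structure bundle that the propagator consumes; this
#' is the provider contract an external quantum-chemistry adapter would have
#' to satisfy: the complex Hermitian Hamiltonian over spin components in the
#' model's quasi-diabatic basis, analytic gradients of the diabatic diagonal
#' per spin-free state, the analytic Hamiltonian derivative per mode (the
#' interstate-coupling information), and ground-to-excited transition dipoles.
#'
#' @param model an `lvc_model`.
#' @param coords numeric vector of nuclear coordinates, length `model$n_modes`.
#' @return Object of class `estruct`: list with `H` (complex Hermitian,
#'   hartree), `gradients` (n_spin_free x n_modes), `dH` (list of per-mode
#'   derivative matrices), `dipoles` (n_spin_free x 3, a.u.), `S_block` and
#'   `T_block` (real spin-free Hamiltonian blocks), `basis_tag = "diabatic"`.
#' @export
evaluate_model <- function(model, coords) {
  stopifnot(inherits(model, "lvc_model"))
  coords <- as.numeric(coords)
  if (length(coords) != model$n_modes) {
    stop("coords length ", length(coords), " does not match n_modes ",
         model$n_modes)
  }
  nc <- model$space$n_components
  nsf <- model$space$n_spin_free
  harm <- 0.5 * sum(model$omega * coords^2)
  # spin-free diagonal per state
  ediag <- model$epsilon + as.numeric(model$kappa %*% coords) + harm
  H <- model$Hconst
  for (m in seq_len(model$n_modes)) {
    # Dlin carries kappa on its diagonal, so only epsilon + the common
    # harmonic part is added below
    if (coords[m] != 0) H <- H + coords[m] * model$Dlin[[m]]
  }
  diag(H) <- diag(H) + (model$epsilon + harm)[model$comp_state]
  # spin-free blocks (real): singlet block and one triplet block (Ms-shared)
  sf_off <- model$lambda0 + apply_lambda(model$lambda, coords)
  Hsf <- sf_off
  diag(Hsf) <- ediag
  ns <- model$space$n_singlets
  S_block <- if (ns > 0) Hsf[seq_len(ns), seq_len(ns), drop = FALSE] else NULL
  T_block <- if (model$space$n_triplets > 0) {
    idx <- ns + seq_len(model$space$n_triplets)
    Hsf[idx, idx, drop = FALSE]
  } else NULL
  grad <- sweep(model$kappa, 2, model$omega * coords, "+")
  dH <- vector("list", model$n_modes)
  for (m in seq_len(model$n_modes)) {
    Dm <- model$Dlin[[m]]
    diag(Dm) <- diag(Dm) + model$omega[m] * coords[m]
    dH[[m]] <- Dm
  }
  structure(list(
    H = H, gradients = grad, dH = dH, dipoles = model$mu0,
    S_block = S_block, T_block = T_block, energies_diabatic = ediag,
    basis_tag = "diabatic"
  ), class = "estruct")
}

# sum over modes of lambda[,,m] * x_m
apply_lambda <- function(lambda, coords) {
  out <- matrix(0, dim(lambda)[1], dim(lambda)[2])
  for (m in seq_along(coords)) {
    if (coords[m] != 0) out <- out + lambda[, , m] * coords[m]
  }
  out
}

#' Normal-mode set of an LVC model
#'
#' Packages the model's modes for Wigner sampling: reference coordinates at
#' the origin, oscillation angular frequency `sqrt(omega/mass)` and the
#' effective masses.
#'
#' @param model an `lvc_model`.
#' @return A `normal_mode_set` (see [normal_mode_set()]).
#' @export
model_modes <- function(model) {
  normal_mode_set(
    x0 = rep(0, model$n_modes),
    freq_au = sqrt(model$omega / model$mass),
    mass = model$mass
  )
}
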