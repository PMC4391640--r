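# Shared fixtures: small models and hand-built trajectory objects.

# random LVC model over a mix of singlets/triplets, used for invariant sweeps
random_model <- function(n_singlets, n_triplets, n_modes = 2, seed = 1,
                         soc = TRUE) {
  set.seed(seed)
  space <- make_state_space(n_singlets, n_triplets)
  nsf <- space$n_spin_free
  omega <- runif(n_modes, 0.003, 0.008)
  lambda <- array(0, c(nsf, nsf, n_modes))
  mult <- space$sf_multiplicity
  for (m in seq_len(n_modes)) {
    L <- matrix(rnorm(nsf * nsf, sd = 0.002), nsf, nsf)
    L <- (L + t(L)) / 2
    L[outer(mult, mult, "!=")] <- 0
    diag(L) <- 0
    lambda[, , m] <- L
  }
  eta <- NULL
  if (soc && n_singlets > 0 && n_triplets > 0) {
    eta <- matrix(complex(real = rnorm(n_singlets * n_triplets, sd = 2e-4),
                          imaginary = rnorm(n_singlets * n_triplets, sd = 2e-4)),
                  n_singlets, n_triplets)
  }
  new_lvc_model(space, omega = omega,
                epsilon = sort(runif(nsf, 0, 0.3)),
                kappa = matrix(rnorm(nsf * n_modes, sd = 0.01), nsf, n_modes),
                lambda = lambda, eta = eta)
}

# minimal hand-scripted trajectory object for analysis-level tests
toy_trajectory <- function(space, time_fs, mch_sf, spect = NULL,
                           status = "completed", hops = NULL) {
  comp_of_sf <- vapply(mch_sf, function(s) {
    which(space$components$sf_index == s)[1]
  }, integer(1))
  if (is.null(spect)) spect <- rep(1L, length(time_fs))
  if (is.null(hops)) {
    hops <- data.frame(time_fs = numeric(0), from_diag = integer(0),
                       to_diag = integer(0), from_sf = integer(0),
                       to_sf = integer(0), from_mult = integer(0),
                       to_mult = integer(0), delta_e_ev = numeric(0),
                       soc_cm1 = numeric(0), frustrated = logical(0))
  }
  structure(list(time_fs = time_fs, active = comp_of_sf, mch_comp = comp_of_sf,
                 spect = spect, hops = hops, status = status, space = space,
                 norm = rep(1, length(time_fs))),
            class = "trajectory")
}

# hop-event row builder
hop_row <- function(time_fs, from_mult, to_mult, soc_cm1 = NA_real_,
                    delta_e_ev = 0, frustrated = FALSE) {
  data.frame(time_fs = time_fs, from_diag = 1L, to_diag = 2L, from_sf = 1L,
             to_sf = 2L, from_mult = from_mult, to_mult = to_mult,
             delta_e_ev = delta_e_ev, soc_cm1 = soc_cm1,
             frustrated = frustrated)
}
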