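.fit_forms <- c("mono_rise", "bi_rise", "mono_decay", "bi_decay")

.fit_model_fn <- function(form) {
  switch(form,
    mono_rise  = function(t, p) 1 - exp(-t / p[["tau1"]]),
    mono_decay = function(t, p) exp(-t / p[["tau1"]]),
    bi_rise    = function(t, p) 1 - p[["a"]] * exp(-t / p[["tau1"]]) -
                                (1 - p[["a"]]) * exp(-t / p[["tau2"]]),
    bi_decay   = function(t, p) p[["a"]] * exp(-t / p[["tau1"]]) +
                                (1 - p[["a"]]) * exp(-t / p[["tau2"]])
  )
}

#' Fit an exponential rise or decay to a population trace
#'
#' Unweighted nonlinear least squares of one of four saturating forms:
#' mono-rise \eqn{P(t) = 1 - e^{-t/\tau}}, biexponential rise
#' \eqn{P(t) = 1 - a e^{-t/\tau_1} - (1-a) e^{-t/\tau_2}}, and their mirrored
#' decay complements. Time zero is fixed at 0 (delta-pulse excitation).
#' Standard errors are the asymptotic ones from the scaled inverse of the
#' Gauss-Newton normal matrix at the optimum. Fits are started from a
#' log-spaced 3x3 grid of time-constant guesses to avoid local minima; for
#' biexponential forms the convention tau1 <= tau2 is enforced by relabelling.
#'
#' @param time_fs time grid (fs).
#' @param values population fractions in [0, 1], one per time point; at least
#'   3 points per free parameter are required.
#' @param form one of `"mono_rise"`, `"bi_rise"`, `"mono_decay"`, `"bi_decay"`.
#' @param start optional named list of starting values (`tau1`, `tau2`, `a`),
#'   replacing the grid start.
#' @return Object of class `fit_result`: `form`, `tau` (fs, named vector),
#'   `tau_se`, `a`, `a_se`, `rss`, `n`, `boundary` flag and the underlying
#'   `nls` fit.
#' @export
#' @examples
#' t <- seq(0, 1000, by = 2)
#' y <- 1 - exp(-t / 150)
#' fit_exponential(t, y, "mono_rise")
fit_exponential <- function(time_fs, values, form = .fit_forms, start = NULL) {
  form <- match.arg(form)
  npar <- if (grepl("^bi", form)) 3L else 1L
  if (length(time_fs) != length(values)) stop("time and values differ in length")
  if (length(values) < 3 * npar) stop("too few points for ", npar, " parameters")
  if (any(values < -1e-6) || any(values > 1 + 1e-6)) {
    stop("population values must lie in [0, 1]")
  }
  if (diff(range(values)) < 1e-12) {
    stop("degenerate input: trace is constant, no time constant is defined")
  }
  fn <- .fit_model_fn(form)
  tspan <- max(time_fs) - min(time_fs)
  tau_grid <- 10^seq(log10(tspan / 50), log10(5 * tspan), length.out = 3)
  starts <- if (!is.null(start)) {
    list(as.list(start))
  } else if (npar == 1L) {
    lapply(tau_grid, function(x) list(tau1 = x))
  } else {
    g <- expand.grid(tau1 = tau_grid, tau2 = tau_grid)
    g <- g[g$tau1 <= g$tau2, ]
    lapply(seq_len(nrow(g)), function(i) list(tau1 = g$tau1[i], tau2 = g$tau2[i], a = 0.5))
  }
  lower <- c(tau1 = tspan * 1e-5, tau2 = tspan * 1e-5, a = 0)[seq_len(npar)]
  upper <- c(tau1 = tspan * 1e4, tau2 = tspan * 1e4, a = 1)[seq_len(npar)]
  names(lower) <- names(upper) <- c("tau1", "tau2", "a")[seq_len(npar)]
  dat <- data.frame(t = time_fs, y = values)
  formula <- switch(form,
    mono_rise  = y ~ 1 - exp(-t / tau1),
    mono_decay = y ~ exp(-t / tau1),
    bi_rise    = y ~ 1 - a * exp(-t / tau1) - (1 - a) * exp(-t / tau2),
    bi_decay   = y ~ a * exp(-t / tau1) + (1 - a) * exp(-t / tau2)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-14) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("exponential fit did not converge for form '", form,
         "' from any starting point")
  }
  fit <- best$fit
  cf <- summary(fit)$coefficients
  est <- stats::setNames(cf[, "Estimate"], rownames(cf))
  se <- stats::setNames(cf[, "Std. Error"], rownames(cf))
  tau <- est[grep("^tau", names(est))]
  tau_se <- se[grep("^tau", names(est))]
  a <- if (npar == 3L) unname(est["a"]) else NA_real_
  a_se <- if (npar == 3L) unname(se["a"]) else NA_real_
  if (npar == 3L && tau[["tau1"]] > tau[["tau2"]]) {
    tau <- rev(tau); tau_se <- rev(tau_se)
    names(tau) <- names(tau_se) <- c("tau1", "tau2")
    a <- 1 - a
  }
  boundary <- any(abs(est - lower[names(est)]) < 1e-8 * pmax(1, abs(est))) ||
    any(abs(est - upper[names(est)]) < 1e-8 * abs(upper[names(est)]))
  structure(list(form = form, tau = tau, tau_se = tau_se, a = a, a_se = a_se,
                 rss = best$rss, n = length(values), boundary = boundary,
                 fit = fit), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  fmt <- function(v, s) {
    ifelse(v >= 1000, sprintf("%.2f +/- %.2f ps", v / 1000, s / 1000),
           sprintf("%.1f +/- %.1f fs", v, s))
  }
  cat(sprintf("%s fit (n = %d, rss = %.3g)%s\n", x$form, x$n, x$rss,
              if (x$boundary) " [parameter at bound]" else ""))
  for (k in seq_along(x$tau)) {
    cat(sprintf("  %s = %s\n", names(x$tau)[k], fmt(x$tau[k], x$tau_se[k])))
  }
  if (!is.na(x$a)) cat(sprintf("  a = %.3f +/- %.3f\n", x$a, x$a_se))
  invisible(x)
}

#' Fit one class column of a population trace
#'
#' @param trace a `population_trace`.
#' @param class name of the class column, or several names whose populations
#'   are summed before fitting (e.g. `c("S0", "T1")`).
#' @param form fit form, see [fit_exponential()].
#' @param ... passed to [fit_exponential()].
#' @return A `fit_result`.
#' @export
fit_population <- function(trace, class, form, ...) {
  missing <- setdiff(class, names(trace))
  if (length(missing) > 0) stop("unknown class column(s): ",
                                paste(missing, collapse = ", "))
  y <- rowSums(as.data.frame(trace)[, class, drop = FALSE])
  fit_exponential(trace$time_fs, y, form, ...)
}

#' Compare two exponential fits by a small-sample information criterion
#'
#' Computes AICc for both fits (Gaussian residual likelihood; parameter count
#' includes the residual variance) and reports which model it prefers. Both
#' fits are returned regardless of the preference.
#'
#' @param fit_a,fit_b `fit_result` objects on the same trace.
#' @param n_points number of points in the trace; default taken from the fits.
#' @return list with `preferred` (`"a"` or `"b"`), `aicc` (named vector) and
#'   both fits.
#' @export
compare_fits <- function(fit_a, fit_b, n_points = NULL) {
  if (is.null(n_points)) n_points <- fit_a$n
  if (fit_a$n != fit_b$n) stop("fits are not on the same trace")
  aicc <- function(f) {
    k <- length(f$tau) + (!is.na(f$a)) + 1  # + residual variance
    n <- n_points
    n * log(f$rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  va <- aicc(fit_a); vb <- aicc(fit_b)
  list(preferred = if (va <= vb) "a" else "b",
       aicc = c(a = va, b = vb), fit_a = fit_a, fit_b = fit_b)
}
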