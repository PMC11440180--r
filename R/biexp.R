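#' Amplitude-weighted mean fluorescence lifetime
#'
#' `tau_m = (a1 tau1 + a2 tau2) / (a1 + a2)`. Invariant under common
#' rescaling of the amplitudes.
#'
#' @param a1,a2 Non-negative component amplitudes (need not be normalized).
#' @param tau1_ns,tau2_ns Positive lifetimes in ns.
#' @return Mean lifetime in ns.
#' @examples
#' mean_lifetime(0.80, 0.36, 0.20, 0.89)  # 0.466
#' @export
mean_lifetime <- function(a1, tau1_ns, a2, tau2_ns) {
  if (any(c(a1, a2) < 0)) stop("amplitudes must be non-negative")
  if (any(c(tau1_ns, tau2_ns) <= 0)) stop("lifetimes must be positive")
  s <- a1 + a2
  if (any(s <= 0)) stop("amplitude sum must be positive")
  (a1 * tau1_ns + a2 * tau2_ns) / s
}

# Poisson deviance 2*sum(m - k + k*log(k/m)); bins with k = 0 contribute 2m.
poisson_deviance <- function(k, m) {
  m <- pmax(m, 1e-12)
  pos <- k > 0
  2 * (sum(m - k) + sum(k[pos] * log(k[pos] / m[pos])))
}

# Neyman weighted least squares with weights 1/max(k, 1)
wls_objective <- function(k, m) sum((k - m)^2 / pmax(k, 1))

# Pearson goodness of fit over bins with adequate expected counts (the
# usual validity condition); each such bin has unit expectation under a
# correct Poisson model, so near-empty tail bins neither inflate nor
# deflate the statistic.
pearson_chi2_reduced <- function(k, m, n_par, min_expected = 5) {
  use <- m >= min_expected
  if (sum(use) <= n_par) use <- m >= stats::quantile(m, 0.5)
  sum((k[use] - m[use])^2 / m[use]) / max(sum(use) - n_par, 1)
}

fit_objective_value <- function(objective, k, m) {
  if (objective == "mle") poisson_deviance(k, m) else wls_objective(k, m)
}

# Weighted NNLS solve of k ~ D %*% alpha with weights 1/max(k,1).
nnls_amplitudes <- function(D, k) {
  sw <- 1 / sqrt(pmax(k, 1))
  fit <- pracma::lsqnonneg(D * sw, k * sw)
  fit$x
}

#' Options for decay fitting
#'
#' @param objective `"mle"` for Poisson maximum likelihood (default; correct
#'   at TCSPC count levels) or `"wls"` for Neyman weighted least squares
#'   with weights `1/max(k, 1)`.
#' @param min_photons Minimum photons in a single decay for a per-channel
#'   fit (default 500).
#' @param min_photons_global Minimum total photons across channels for a
#'   global fit (default 2000).
#' @param multistart Try a grid of lifetime starting points when the first
#'   start fails to converge or lands on a bound.
#' @param refine Run a joint nonlinear polish of lifetimes and amplitudes
#'   after the separable (profiled) search.
#' @param trim_start_bins Number of leading time bins to drop before the
#'   fit (default 0; all bins used).
#' @param fit_t0 Also fit a shared shift of the IRF position (global fit
#'   only; default FALSE).
#' @return List of class `fit_options`.
#' @export
fit_options <- function(objective = c("mle", "wls"), min_photons = 500,
                        min_photons_global = 2000, multistart = TRUE,
                        refine = TRUE, trim_start_bins = 0L, fit_t0 = FALSE) {
  structure(list(
    objective = match.arg(objective),
    min_photons = min_photons,
    min_photons_global = min_photons_global,
    multistart = isTRUE(multistart),
    refine = isTRUE(refine),
    trim_start_bins = as.integer(trim_start_bins),
    fit_t0 = isTRUE(fit_t0)
  ), class = "fit_options")
}

#' Bi-exponential fit of a single decay curve
#'
#' Fits `F(t) ~ IRF (x) (alpha1 exp(-t/tau1) + alpha2 exp(-t/tau2))` to a
#' photon-count histogram. The search is separable: at fixed lifetimes the
#' amplitudes are solved by non-negative weighted least squares, and a 2-D
#' bounded quasi-Newton search runs over the log-lifetimes, followed by a
#' joint polish under the chosen objective. Returned lifetimes are ordered
#' `tau1 <= tau2` and amplitudes normalized to `a1 + a2 = 1`.
#'
#' @param curve A [decay_curve()] (or bare counts vector).
#' @param instrument An [instrument_model()].
#' @param options A [fit_options()].
#' @param start Optional list with `tau1_ns`, `tau2_ns` starting values.
#' @return Object of class `biexp_fit` with fields `a1`, `a2`, `tau1_ns`,
#'   `tau2_ns`, `tau_m_ns`, `scale`, `offset`, `chi2_reduced`, `n_photons`,
#'   `converged`.
#' @export
fit_biexponential <- function(curve, instrument, options = fit_options(),
                              start = list(tau1_ns = 0.4, tau2_ns = 2.0)) {
  if (!inherits(curve, "decay_curve")) curve <- decay_curve(curve, instrument$time)
  k_all <- curve$counts
  if (curve$total_photons < options$min_photons)
    stop(sprintf("insufficient signal: %d photons < min_photons = %d",
                 round(curve$total_photons), round(options$min_photons)))
  keep <- seq_along(k_all) > options$trim_start_bins
  k <- k_all[keep]

  profiled <- function(ltau) {
    E <- component_curves(exp(ltau), instrument)[keep, , drop = FALSE]
    alpha <- nnls_amplitudes(E, k)
    m <- drop(E %*% alpha)
    list(obj = fit_objective_value(options$objective, k, m), alpha = alpha)
  }
  lb <- log(0.05)
  ub <- log(10)
  run_start <- function(t1, t2) {
    stats::optim(log(c(t1, t2)), function(p) profiled(p)$obj,
                 method = "L-BFGS-B", lower = lb, upper = ub,
                 control = list(maxit = 200))
  }
  best <- run_start(start$tau1_ns, start$tau2_ns)
  if (options$multistart &&
      (best$convergence != 0 || any(abs(best$par - c(lb, ub)) < 1e-6))) {
    for (t2 in c(1, 2, 4)) {
      cand <- run_start(0.4, t2)
      if (cand$value < best$value) best <- cand
    }
  }
  taus <- exp(best$par)
  alpha <- profiled(best$par)$alpha
  converged <- best$convergence == 0

  if (options$refine) {
    # joint polish over (log tau1, log tau2, alpha1, alpha2)
    p0 <- c(best$par, pmax(alpha, 1e-8))
    fn <- function(p) {
      E <- component_curves(exp(p[1:2]), instrument)[keep, , drop = FALSE]
      fit_objective_value(options$objective, k, drop(E %*% p[3:4]))
    }
    pol <- stats::nlminb(p0, fn, lower = c(lb, lb, 0, 0),
                         upper = c(ub, ub, Inf, Inf),
                         control = list(iter.max = 200, eval.max = 400))
    if (is.finite(pol$objective) && pol$objective <= best$value + 1e-9) {
      taus <- exp(pol$par[1:2])
      alpha <- pol$par[3:4]
      converged <- pol$convergence == 0 || converged
    }
  }

  if (taus[1] > taus[2]) {  # enforce tau1 <= tau2
    taus <- rev(taus)
    alpha <- rev(alpha)
  }
  E <- component_curves(taus, instrument)[keep, , drop = FALSE]
  m <- drop(E %*% alpha)
  asum <- sum(alpha)
  if (asum <= 0) {
    a_norm <- c(NA_real_, NA_real_)
    tau_m <- NA_real_
    converged <- FALSE
  } else {
    a_norm <- alpha / asum
    tau_m <- mean_lifetime(a_norm[1], taus[1], a_norm[2], taus[2])
  }
  structure(list(
    a1 = a_norm[1], a2 = a_norm[2],
    tau1_ns = taus[1], tau2_ns = taus[2],
    tau_m_ns = tau_m,
    scale = sum(m), offset = 0,
    chi2_reduced = pearson_chi2_reduced(k, m, 4),
    n_photons = curve$total_photons,
    objective = options$objective,
    converged = converged
  ), class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "biexp_fit: a1 = %.3f tau1 = %.3f ns | a2 = %.3f tau2 = %.3f ns | tau_m = %.3f ns (chi2_red %.2f, %s photons)\n",
    x$a1, x$tau1_ns, x$a2, x$tau2_ns, x$tau_m_ns, x$chi2_reduced,
    format(round(x$n_photons))))
  invisible(x)
}

#' Bi-exponential fits of every spectral channel of one decay set
#'
#' Maps [fit_biexponential()] over the channels of a channel-by-bin count
#' matrix (e.g. one pixel or one cell of a [spectral_cube()]). Channels
#' below the photon threshold are reported as missing rows with a reason,
#' not errors.
#'
#' @param channel_decays Matrix (n_channels x n_bins) of counts, or a list
#'   of [decay_curve()]s.
#' @param instrument An [instrument_model()].
#' @param options A [fit_options()].
#' @return `data.frame` with one row per channel: `channel`,
#'   `wavelength_nm`, `n_photons`, `a1`, `a2`, `tau1_ns`, `tau2_ns`,
#'   `tau_m_ns`, `chi2_reduced`, `converged`, `reason`.
#' @export
fit_channel_series <- function(channel_decays, instrument,
                               options = fit_options()) {
  M <- as_channel_matrix(channel_decays, instrument)
  n_ch <- nrow(M)
  rows <- lapply(seq_len(n_ch), function(c) {
    base <- data.frame(
      channel = c,
      wavelength_nm = instrument$spectral$channel_centers_nm[c],
      n_photons = sum(M[c, ]),
      a1 = NA_real_, a2 = NA_real_, tau1_ns = NA_real_, tau2_ns = NA_real_,
      tau_m_ns = NA_real_, chi2_reduced = NA_real_, converged = FALSE,
      reason = NA_character_
    )
    if (sum(M[c, ]) < options$min_photons) {
      base$reason <- "below min_photons"
      return(base)
    }
    f <- fit_biexponential(M[c, ], instrument, options)
    base[c("a1", "a2", "tau1_ns", "tau2_ns", "tau_m_ns", "chi2_reduced")] <-
      f[c("a1", "a2", "tau1_ns", "tau2_ns", "tau_m_ns", "chi2_reduced")]
    base$converged <- f$converged
    base
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$reason)))
    stop("all channels below min_photons: nothing to fit")
  out
}

# Accept a matrix, a list of decay_curves, or a list of count vectors.
as_channel_matrix <- function(channel_decays, instrument) {
  if (is.list(channel_decays)) {
    channel_decays <- do.call(rbind, lapply(channel_decays, function(d) {
      if (inherits(d, "decay_curve")) d$counts else as.numeric(d)
    }))
  }
  M <- as.matrix(channel_decays)
  if (ncol(M) != instrument$time$n_bins ||
      nrow(M) != instrument$spectral$n_channels)
    stop(sprintf("channel decays must be %d channels x %d bins",
                 instrument$spectral$n_channels, instrument$time$n_bins))
  M
}
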