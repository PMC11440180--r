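#' Normalized component amplitudes from decay-associated spectra
#'
#' For each component the channel maximum `A_i = max_lambda a_i(lambda)` is
#' taken, and the triple is normalized: `a_i = A_i / (A1 + A2 + A3)`. This
#' is the relative-contribution readout of the three-component unmixing.
#'
#' @param a1,a2,a3 Non-negative per-channel amplitude spectra (free NAD(P)H,
#'   bound NAD(P)H, flavins).
#' @return Named numeric vector `c(a_free, a_bound, a_flavins)` summing to 1.
#' @examples
#' normalize_amplitudes(c(2, 1), c(1, 0.5), c(0, 1))
#' @export
normalize_amplitudes <- function(a1, a2, a3) {
  if (any(c(a1, a2, a3) < 0)) stop("amplitude spectra must be non-negative")
  A <- c(max(a1), max(a2), max(a3))
  if (sum(A) <= 0) stop("all component spectra are zero")
  out <- A / sum(A)
  names(out) <- c("a_free", "a_bound", "a_flavins")
  out
}

#' Mean NAD(P)H lifetime from the global-fit amplitudes
#'
#' Amplitude-weighted mean of the fixed free-NAD(P)H lifetime and the fitted
#' bound-NAD(P)H lifetime, excluding the flavin component:
#' `(a_free tau_free + a_bound tau_bound) / (a_free + a_bound)`.
#'
#' @param a_free,a_bound Non-negative normalized amplitudes.
#' @param tau_free_ns,tau_bound_ns Lifetimes in ns.
#' @return Mean NAD(P)H lifetime in ns.
#' @export
nadh_mean_lifetime <- function(a_free, a_bound, tau_free_ns, tau_bound_ns) {
  mean_lifetime(a_free, tau_free_ns, a_bound, tau_bound_ns)
}

#' Intensity-weighted mean emission wavelength of the flavin component
#'
#' `sum(lambda_i a3(lambda_i)) / sum(a3(lambda_i))`. Returns `NA` for an
#' all-zero spectrum (flavin component absent).
#'
#' @param flavin_spectrum Non-negative per-channel amplitudes.
#' @param spectral A [spectral_axis()].
#' @return Wavelength in nm, or `NA_real_` when the spectrum has zero sum.
#' @export
flavin_lambda_avg <- function(flavin_spectrum, spectral) {
  stopifnot(inherits(spectral, "spectral_axis"))
  if (length(flavin_spectrum) != spectral$n_channels)
    stop("flavin_spectrum length must equal n_channels")
  if (any(flavin_spectrum < 0)) stop("flavin_spectrum must be non-negative")
  s <- sum(flavin_spectrum)
  if (s <= 0) return(NA_real_)
  sum(spectral$channel_centers_nm * flavin_spectrum) / s
}

# Build the stacked design matrix for the global model. Data are stacked as
# channel blocks of n_bins; columns: free shape x E1, bound shape x E2, one
# column per flavin-free channel carrying E3 in its own block.
global_design <- function(E, basis, keep_bins) {
  n_bins <- sum(keep_bins)
  n_ch <- basis$spectral$n_channels
  fl <- which(basis$flavin_free_channels)
  A <- matrix(0, n_ch * n_bins, 2L + length(fl))
  A[, 1] <- kronecker(basis$free_spectrum, E[keep_bins, 1])
  A[, 2] <- kronecker(basis$bound_spectrum, E[keep_bins, 2])
  for (j in seq_along(fl)) {
    rows <- (fl[j] - 1L) * n_bins + seq_len(n_bins)
    A[rows, 2L + j] <- E[keep_bins, 3]
  }
  A
}

# Model matrix (n_ch x n_bins) from component curves and amplitudes
global_model_matrix <- function(E, basis, amp_free, amp_bound, a3) {
  outer(amp_free * basis$free_spectrum, E[, 1]) +
    outer(amp_bound * basis$bound_spectrum, E[, 2]) +
    outer(a3, E[, 3])
}

#' Global three-component fit of a multispectral decay set
#'
#' Simultaneously fits all spectral channels of one decay set (a pixel, a
#' binned pixel, or a cell-integrated measurement) with three components
#' whose lifetimes are shared across channels:
#' free NAD(P)H (lifetime fixed, spectrum fixed), bound NAD(P)H (lifetime
#' fitted within bounds, spectrum fixed), and flavins (lifetime fitted
#' within bounds, per-channel amplitudes free but zero below the wavelength
#' cutoff). The optimization is separable: at fixed lifetimes all
#' amplitudes enter linearly and are solved by non-negative weighted least
#' squares; a bounded 2-D search runs over the log-lifetimes; a joint
#' refinement under the chosen objective follows.
#'
#' @param channel_decays Matrix (n_channels x n_bins) of counts, or a list
#'   of per-channel [decay_curve()]s.
#' @param instrument An [instrument_model()].
#' @param basis A [component_basis()].
#' @param options A [fit_options()].
#' @return Object of class `global_fit` with the fitted lifetimes
#'   (`tau_bound_ns`, `tau_flavin_ns`), amplitude scalars (`amp_free`,
#'   `amp_bound`), the flavin amplitude spectrum (`flavin_spectrum`),
#'   channel maxima (`A1`, `A2`, `A3`), normalized amplitudes (`a_free`,
#'   `a_bound`, `a_flavins`), `ratio_free_bound`, `tau_m_nadh_ns`,
#'   `lambda_avg_flavin_nm`, `chi2_reduced`, and quality flags (`converged`,
#'   `at_bound`).
#' @export
fit_global <- function(channel_decays, instrument, basis,
                       options = fit_options()) {
  stopifnot(inherits(instrument, "instrument_model"),
            inherits(basis, "component_basis"))
  if (basis$spectral$n_channels != instrument$spectral$n_channels)
    stop("basis and instrument disagree on the number of spectral channels")
  if (max(basis$free_spectrum) <= 0 || max(basis$bound_spectrum) <= 0)
    stop("infeasible basis: fixed spectra are all zero")
  Y <- as_channel_matrix(channel_decays, instrument)
  if (sum(Y) < options$min_photons_global)
    stop(sprintf("insufficient signal: %d photons < min_photons_global = %d",
                 round(sum(Y)), round(options$min_photons_global)))

  keep <- seq_len(instrument$time$n_bins) > options$trim_start_bins
  y <- as.vector(t(Y[, keep, drop = FALSE]))  # channel blocks of kept bins
  fl <- which(basis$flavin_free_channels)
  n_ch <- nrow(Y)

  tb_b <- basis$tau_bound_bounds_ns
  tf_b <- basis$tau_flavin_bounds_ns
  lower <- log(c(tb_b[1], tf_b[1]))
  upper <- log(c(tb_b[2], tf_b[2]))
  if (options$fit_t0) {
    lower <- c(lower, -0.2)
    upper <- c(upper, 0.2)
  }

  inst_at <- function(dt0) {
    if (dt0 == 0) return(instrument)
    instrument_model(instrument$time, instrument$spectral,
                     irf_fwhm_ns = instrument$irf_fwhm_ns,
                     irf_t0_ns = instrument$irf_t0_ns + dt0,
                     wraparound = instrument$wraparound)
  }
  curves_at <- function(p) {
    dt0 <- if (options$fit_t0) p[3] else 0
    component_curves(c(basis$tau_free_ns, exp(p[1:2])), inst_at(dt0))
  }
  profiled <- function(p) {
    E <- curves_at(p)
    A <- global_design(E, basis, keep)
    alpha <- nnls_amplitudes(A, y)
    m <- drop(A %*% alpha)
    list(obj = fit_objective_value(options$objective, y, m), alpha = alpha, E = E)
  }

  run_start <- function(tb, tf) {
    p0 <- log(c(tb, tf))
    if (options$fit_t0) p0 <- c(p0, 0)
    stats::optim(p0, function(p) profiled(p)$obj, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = list(maxit = 200))
  }
  near_bound <- function(p) any(abs(p[1:2] - lower[1:2]) < 1e-4 |
                                abs(p[1:2] - upper[1:2]) < 1e-4)
  best <- run_start(2.0, 2.0)
  if (options$multistart && (best$convergence != 0 || near_bound(best$par))) {
    for (tb in c(1.0, 2.0, 3.5)) for (tf in c(0.8, 1.5, 3.0)) {
      cand <- run_start(tb, tf)
      better <- cand$value < best$value - 1e-9 ||
        (abs(cand$value - best$value) <= 1e-9 && cand$par[1] < best$par[1])
      if (better) best <- cand
    }
  }
  sol <- profiled(best$par)
  par <- best$par
  alpha <- sol$alpha
  converged <- best$convergence == 0

  if (options$refine) {
    # joint polish: (log tau_b, log tau_f, [dt0], amp_free, amp_bound, a3...)
    # with analytic gradients (numeric for the optional t0 shift)
    nf <- length(fl)
    np <- length(par)
    Yk <- Y[, keep, drop = FALSE]
    unpack <- function(p) {
      eg <- component_curve_grads(c(basis$tau_free_ns, exp(p[1:2])),
                                  inst_at(if (options$fit_t0) p[3] else 0))
      a3 <- a3_full(p[np + 2 + seq_len(nf)], fl, n_ch)
      M <- global_model_matrix(eg$E[keep, , drop = FALSE], basis,
                               p[np + 1], p[np + 2], a3)
      list(eg = eg, a3 = a3, M = M)
    }
    fn <- function(p) {
      fit_objective_value(options$objective, y, as.vector(t(unpack(p)$M)))
    }
    gr <- function(p) {
      s <- unpack(p)
      Dm <- if (options$objective == "mle") {
        2 * (1 - Yk / pmax(s$M, 1e-12))
      } else {
        -2 * (Yk - s$M) / pmax(Yk, 1)
      }
      Ek <- s$eg$E[keep, , drop = FALSE]
      dEk <- s$eg$dE[keep, , drop = FALSE]
      g <- numeric(length(p))
      g[1] <- p[np + 2] * sum(Dm * outer(basis$bound_spectrum, dEk[, 2]))
      g[2] <- sum(drop(Dm %*% dEk[, 3]) * s$a3)
      if (options$fit_t0) {  # numeric in the shift only
        e <- 1e-5
        g[3] <- (fn(`[<-`(p, 3, p[3] + e)) - fn(`[<-`(p, 3, p[3] - e))) / (2 * e)
      }
      g[np + 1] <- sum(Dm * outer(basis$free_spectrum, Ek[, 1]))
      g[np + 2] <- sum(Dm * outer(basis$bound_spectrum, Ek[, 2]))
      g[np + 2 + seq_len(nf)] <- drop(Dm %*% Ek[, 3])[fl]
      g
    }
    pol <- stats::nlminb(c(par, pmax(alpha, 0)), fn, gradient = gr,
                         lower = c(lower, rep(0, 2 + nf)),
                         upper = c(upper, rep(Inf, 2 + nf)),
                         control = list(iter.max = 300, eval.max = 600))
    if (is.finite(pol$objective) && pol$objective <= best$value + 1e-9) {
      par <- pol$par[seq_len(np)]
      alpha <- pol$par[np + seq_len(2 + nf)]
      converged <- pol$convergence == 0 || converged
    }
  }

  taus <- exp(par[1:2])
  amp_free <- alpha[1]
  amp_bound <- alpha[2]
  a3 <- a3_full(alpha[-(1:2)], fl, n_ch)
  E <- curves_at(par)
  M <- global_model_matrix(E, basis, amp_free, amp_bound, a3)
  n_free_par <- length(par) + 2L + length(fl)

  a_spec_free <- amp_free * basis$free_spectrum
  a_spec_bound <- amp_bound * basis$bound_spectrum
  norm <- normalize_amplitudes(a_spec_free, a_spec_bound, a3)
  at_bound <- near_bound(par)

  structure(list(
    amp_free = amp_free, amp_bound = amp_bound,
    flavin_spectrum = a3,
    tau_free_ns = basis$tau_free_ns,
    tau_bound_ns = taus[1], tau_flavin_ns = taus[2],
    t0_shift_ns = if (options$fit_t0) par[3] else 0,
    A1 = max(a_spec_free), A2 = max(a_spec_bound), A3 = max(a3),
    a_free = norm[["a_free"]], a_bound = norm[["a_bound"]],
    a_flavins = norm[["a_flavins"]],
    ratio_free_bound = if (norm[["a_bound"]] > 0)
      norm[["a_free"]] / norm[["a_bound"]] else NA_real_,
    tau_m_nadh_ns = if (norm[["a_free"]] + norm[["a_bound"]] > 0)
      nadh_mean_lifetime(norm[["a_free"]], norm[["a_bound"]],
                         basis$tau_free_ns, taus[1]) else NA_real_,
    lambda_avg_flavin_nm = flavin_lambda_avg(a3, basis$spectral),
    chi2_reduced = pearson_chi2_reduced(y, as.vector(t(M[, keep, drop = FALSE])),
                                        n_free_par),
    n_photons = sum(Y),
    objective = options$objective,
    converged = converged,
    at_bound = at_bound
  ), class = "global_fit")
}

a3_full <- function(a3_free, fl, n_ch) {
  a3 <- numeric(n_ch)
  a3[fl] <- a3_free
  a3
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf(
    paste0("global_fit: tau_bound = %.3f ns, tau_flavin = %.3f ns | ",
           "a_free/a_bound/a_flavins = %.3f/%.3f/%.3f (ratio %.2f) | ",
           "tau_m(NAD(P)H) = %.3f ns, lambda_avg(flavins) = %.1f nm\n"),
    x$tau_bound_ns, x$tau_flavin_ns, x$a_free, x$a_bound, x$a_flavins,
    x$ratio_free_bound, x$tau_m_nadh_ns, x$lambda_avg_flavin_nm))
  if (x$at_bound) cat("  [flag] a lifetime sits at its bound\n")
  if (!x$converged) cat("  [flag] optimizer did not report convergence\n")
  invisible(x)
}
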