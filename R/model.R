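#' Discrete Gaussian IRF weights on the time grid
#'
#' Integrates the Gaussian IRF density over each time bin and normalizes the
#' result to sum to 1. Used for display, for the numeric-convolution cross
#' check, and when exporting a synthetic instrument response; the fit core
#' uses the analytic Gaussian (x) exponential form instead.
#'
#' @param instrument An [instrument_model()].
#' @return Numeric vector of length `n_bins`, non-negative, summing to 1.
#' @export
make_gaussian_irf <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_model"))
  tx <- instrument$time
  sigma <- instrument$irf_sigma_ns
  if (sigma < tx$bin_width_ns / 50)
    stop("IRF sigma is below 1/50 of the bin width: unresolvable on this grid")
  edges <- c(0, seq_len(tx$n_bins)) * tx$bin_width_ns
  w <- diff(stats::pnorm(edges, mean = instrument$irf_t0_ns, sd = sigma))
  w / sum(w)
}

# Unit-amplitude exponentially modified Gaussian ("exGaussian"):
#   h(t) = 0.5 * exp(sigma^2/(2 tau^2) - (t - t0)/tau)
#              * erfc((sigma/tau - (t - t0)/sigma)/sqrt(2))
# Evaluated in the scaled-complementary-error-function (erfcx) form when the
# erfc argument is positive, which avoids overflow for tau << sigma.
exgauss <- function(t, tau, sigma, t0) {
  u <- (t - t0) / sigma
  r <- sigma / tau
  z <- (r - u) / sqrt(2)
  out <- numeric(length(t))
  pos <- z >= 0
  if (any(pos))   # erfcx(z) * exp(-u^2/2) == exp(r^2/2 - u r) * erfc(z)
    out[pos] <- 0.5 * erfcx_safe(z[pos]) * exp(-u[pos]^2 / 2)
  if (any(!pos))
    out[!pos] <- 0.5 * exp(r^2 / 2 - u[!pos] * r) * pracma::erfc(z[!pos])
  out
}

# pracma::erfcx returns NaN for z > ~26 (erfc underflow); switch to the
# asymptotic series 1/(z sqrt(pi)) * (1 - 1/(2z^2) + 3/(4z^4) - 15/(8z^6))
# there (relative error < 1e-11 at the switch point).
erfcx_safe <- function(z) {
  out <- numeric(length(z))
  big <- z > 25
  if (any(!big)) out[!big] <- pracma::erfcx(z[!big])
  if (any(big)) {
    zi2 <- 1 / z[big]^2
    out[big] <- (1 - zi2 / 2 * (1 - 3 / 2 * zi2 * (1 - 5 / 2 * zi2))) /
      (z[big] * sqrt(pi))
  }
  out
}

# Previous-pulse ("wraparound") tail of the exGaussian at repetition period
# T_ns: for t + kT (k >= 1) the Gaussian edge has fully passed, so each term
# is the pure exponential exp(sigma^2/(2 tau^2)) * exp(-(t - t0)/tau)
# * exp(-kT/tau); the sum over k is geometric.
exgauss_wrap_tail <- function(t, tau, sigma, t0, period_ns) {
  g <- exp(-period_ns / tau)
  exp(sigma^2 / (2 * tau^2)) * exp(-(t - t0) / tau) * g / (1 - g)
}

# Per-component unit-amplitude model curves at the bin centers.
# Returns an n_bins x n_components matrix.
component_curves <- function(lifetimes, instrument) {
  if (!is.null(instrument$irf_weights))
    return(component_curves_measured(lifetimes, instrument))
  t <- instrument$time$bin_centers_ns
  sigma <- instrument$irf_sigma_ns
  t0 <- instrument$irf_t0_ns
  vapply(lifetimes, function(tau) {
    v <- exgauss(t, tau, sigma, t0)
    if (instrument$wraparound)
      v <- v + exgauss_wrap_tail(t, tau, sigma, t0, instrument$time$period_ns)
    v
  }, numeric(instrument$time$n_bins))
}

# Discrete convolution path for a measured IRF: circular convolution of the
# per-bin IRF weights with the cell-averaged (optionally periodized)
# exponential. Cell averaging matches the binned nature of measured IRFs.
component_curves_measured <- function(lifetimes, instrument) {
  tx <- instrument$time
  n <- tx$n_bins
  bw <- tx$bin_width_ns
  w <- instrument$irf_weights
  lag <- (seq_len(n) - 1L) * bw
  fw <- stats::fft(w)
  vapply(lifetimes, function(tau) {
    # exponential averaged over lag cells centered on l*bw (cell 0 is half)
    full <- (tau / bw) * (exp(bw / (2 * tau)) - exp(-bw / (2 * tau))) *
      exp(-lag / tau)
    p <- full
    p[1] <- (tau / bw) * (1 - exp(-bw / (2 * tau)))
    if (instrument$wraparound) {
      g <- exp(-tx$period_ns / tau)
      p <- p + full * g / (1 - g)
    }
    Re(stats::fft(fw * stats::fft(p), inverse = TRUE)) / n
  }, numeric(n))
}

# d h / d log(tau) of the unit-amplitude exGaussian, wraparound included.
# With r = sigma/tau, u = (t - t0)/sigma:
#   dh/dr = (r - u) h - exp(-u^2/2)/sqrt(2 pi),  dh/dlogtau = -r dh/dr.
# Wrap tail w has d log w / d log tau = -r^2 + (t - t0)/tau + (T/tau)/(1 - g).
exgauss_dlogtau <- function(t, tau, sigma, t0, period_ns = NULL) {
  u <- (t - t0) / sigma
  r <- sigma / tau
  h <- exgauss(t, tau, sigma, t0)
  out <- -r * ((r - u) * h - exp(-u^2 / 2) / sqrt(2 * pi))
  if (!is.null(period_ns)) {
    g <- exp(-period_ns / tau)
    w <- exgauss_wrap_tail(t, tau, sigma, t0, period_ns)
    out <- out + w * (-r^2 + (t - t0) / tau + (period_ns / tau) / (1 - g))
  }
  out
}

# Curves and their log-lifetime derivatives, both n_bins x n_components.
# For a measured IRF the derivative falls back to central differences.
component_curve_grads <- function(lifetimes, instrument) {
  if (!is.null(instrument$irf_weights)) {
    e <- 1e-6
    dE <- (component_curves(lifetimes * exp(e), instrument) -
             component_curves(lifetimes * exp(-e), instrument)) / (2 * e)
    return(list(E = component_curves(lifetimes, instrument), dE = dE))
  }
  t <- instrument$time$bin_centers_ns
  sigma <- instrument$irf_sigma_ns
  t0 <- instrument$irf_t0_ns
  per <- if (instrument$wraparound) instrument$time$period_ns else NULL
  dE <- vapply(lifetimes, function(tau)
    exgauss_dlogtau(t, tau, sigma, t0, per),
    numeric(instrument$time$n_bins))
  list(E = component_curves(lifetimes, instrument), dE = dE)
}

#' IRF-convolved multi-exponential decay model
#'
#' Evaluates `sum_i a_i * IRF (x) exp(-t/tau_i)` at the bin centers using the
#' closed-form Gaussian-convolved exponential per component. With
#' `wraparound` enabled on the instrument, the tail of each component left
#' over from the previous laser pulse is added through the geometric factor
#' `exp(-T/tau) / (1 - exp(-T/tau))` applied to the pure-exponential part.
#'
#' @param amplitudes Non-negative per-component amplitudes.
#' @param lifetimes_ns Positive per-component lifetimes in ns (same length).
#' @param instrument An [instrument_model()].
#' @return Numeric vector of model values, one per time bin.
#' @examples
#' im <- instrument_model()
#' m <- model_decay(c(0.8, 0.2), c(0.37, 2.5), im)
#' @export
model_decay <- function(amplitudes, lifetimes_ns, instrument) {
  stopifnot(inherits(instrument, "instrument_model"))
  if (length(amplitudes) != length(lifetimes_ns) || length(amplitudes) < 1)
    stop("amplitudes and lifetimes_ns must have equal positive length")
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0))
    stop("all lifetimes must be positive")
  if (any(amplitudes < 0))
    stop("amplitudes must be non-negative")
  drop(component_curves(lifetimes_ns, instrument) %*% amplitudes)
}

#' Per-channel model decays for a spectral-temporal slice
#'
#' Channel c of the result equals [model_decay()] with amplitudes
#' `amplitude_spectra[, c]` and the shared `lifetimes_ns`. This is the
#' forward model of the global analysis: lifetimes shared across channels,
#' amplitudes wavelength-dependent.
#'
#' @param amplitude_spectra Matrix (n_components x n_channels) of
#'   non-negative amplitudes.
#' @param lifetimes_ns Per-component lifetimes (length n_components).
#' @param instrument An [instrument_model()].
#' @return Matrix (n_channels x n_bins) of model values.
#' @export
model_cube_slice <- function(amplitude_spectra, lifetimes_ns, instrument) {
  stopifnot(inherits(instrument, "instrument_model"))
  amplitude_spectra <- as.matrix(amplitude_spectra)
  if (ncol(amplitude_spectra) != instrument$spectral$n_channels)
    stop(sprintf("amplitude_spectra has %d columns but the spectral axis has %d channels",
                 ncol(amplitude_spectra), instrument$spectral$n_channels))
  if (nrow(amplitude_spectra) != length(lifetimes_ns))
    stop("rows of amplitude_spectra must match length(lifetimes_ns)")
  E <- component_curves(lifetimes_ns, instrument)  # n_bins x n_comp
  t(E %*% amplitude_spectra)                       # n_channels x n_bins
}

#' Brute-force numeric convolution of IRF and exponentials (test oracle)
#'
#' Discrete convolution of the sampled Gaussian IRF with sampled
#' exponentials on an oversampled grid, downsampled back to the bin centers.
#' Slow but assumption-free; retained as an independent cross check of the
#' analytic model.
#'
#' @param amplitudes,lifetimes_ns,instrument As in [model_decay()].
#' @param oversample Integer factor refining the IRF sampling relative to the
#'   bin width (default 10).
#' @return Numeric vector of length `n_bins`.
#' @export
numeric_convolved_decay <- function(amplitudes, lifetimes_ns, instrument,
                                    oversample = 10L) {
  tx <- instrument$time
  sigma <- instrument$irf_sigma_ns
  t0 <- instrument$irf_t0_ns
  dt <- tx$bin_width_ns / oversample
  n_rep <- if (instrument$wraparound) 12L else 1L
  t_out <- tx$bin_centers_ns
  # integration cells covering the IRF support
  edges <- seq(t0 - 10 * sigma, t0 + 10 * sigma, by = dt)
  a <- edges[-length(edges)]
  # periodized one-sided exponential (the decay law being convolved)
  f_per <- function(u, tau) {
    v <- 0
    for (k in seq_len(n_rep) - 1L) {
      uk <- u + k * tx$period_ns
      v <- v + exp(-uk / tau) * (uk >= 0)
    }
    v
  }
  # two-point Gauss-Legendre on [lo, hi] of g(s) * f(t - s)
  gl2 <- function(lo, hi, t, tau) {
    h <- (hi - lo) / 2
    mid <- (hi + lo) / 2
    s1 <- mid - h / sqrt(3)
    s2 <- mid + h / sqrt(3)
    h * (stats::dnorm(s1, t0, sigma) * f_per(t - s1, tau) +
           stats::dnorm(s2, t0, sigma) * f_per(t - s2, tau))
  }
  out <- numeric(tx$n_bins)
  for (i in seq_along(amplitudes)) {
    tau <- lifetimes_ns[i]
    # bulk: all cells, all output times at once
    val <- rowSums(gl2(matrix(a, tx$n_bins, length(a), byrow = TRUE),
                       matrix(a + dt, tx$n_bins, length(a), byrow = TRUE),
                       matrix(t_out, tx$n_bins, length(a)), tau))
    # the integrand has a kink at s = t (the k = 0 decay onset): split the
    # straddling cell there and integrate each smooth piece exactly enough
    for (j in seq_len(tx$n_bins)) {
      k <- findInterval(t_out[j], edges)
      if (k >= 1 && k <= length(a)) {
        lo <- a[k]
        hi <- a[k] + dt
        val[j] <- val[j] - gl2(lo, hi, t_out[j], tau) +
          gl2(lo, t_out[j], t_out[j], tau) +
          gl2(t_out[j], hi, t_out[j], tau)
      }
    }
    out <- out + amplitudes[i] * val
  }
  out
}
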