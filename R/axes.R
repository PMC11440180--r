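#' Time axis of a TCSPC measurement
#'
#' Describes the uniform time binning of a TCSPC histogram over one laser
#' period. At an 80 MHz repetition rate the period is 12.5 ns; the default
#' 256 ADC bins give a bin width of ~48.8 ps.
#'
#' @param n_bins Number of TCSPC time bins (>= 16).
#' @param period_ns Laser repetition period in nanoseconds.
#' @return An object of class `time_axis` with fields `n_bins`, `period_ns`,
#'   `bin_width_ns` and `bin_centers_ns`.
#' @examples
#' tx <- time_axis(256, 12.5)
#' tx$bin_width_ns
#' @export
time_axis <- function(n_bins = 256L, period_ns = 12.5) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 16L)
    stop("n_bins must be an integer >= 16")
  if (!is.finite(period_ns) || period_ns <= 0)
    stop("period_ns must be positive")
  bw <- period_ns / n_bins
  structure(
    list(
      n_bins = n_bins,
      period_ns = period_ns,
      bin_width_ns = bw,
      bin_centers_ns = (seq_len(n_bins) - 0.5) * bw
    ),
    class = "time_axis"
  )
}

#' Spectral axis of a multispectral detector
#'
#' The default grid mirrors a 16-channel multi-wavelength PMT spanning
#' 388.1 to 573.6 nm. The first and last values are channel CENTERS, so the
#' uniform spacing is (573.6 - 388.1)/15 ~= 12.37 nm; the nominal channel
#' bandwidth (12.5 nm) is kept as descriptive metadata only.
#'
#' @param n_channels Number of spectral channels.
#' @param range_nm Length-2 numeric: centers of the first and last channels.
#' @param channel_centers_nm Optional explicit centers (overrides `range_nm`).
#' @param bandwidth_nm Nominal per-channel bandwidth in nm (metadata).
#' @return An object of class `spectral_axis`.
#' @export
spectral_axis <- function(n_channels = 16L, range_nm = c(388.1, 573.6),
                          channel_centers_nm = NULL, bandwidth_nm = 12.5) {
  if (is.null(channel_centers_nm)) {
    n_channels <- as.integer(n_channels)
    if (is.na(n_channels) || n_channels < 2L)
      stop("n_channels must be an integer >= 2")
    channel_centers_nm <- seq(range_nm[1], range_nm[2], length.out = n_channels)
  } else {
    n_channels <- length(channel_centers_nm)
  }
  if (any(diff(channel_centers_nm) <= 0))
    stop("channel_centers_nm must be strictly increasing")
  structure(
    list(
      n_channels = n_channels,
      channel_centers_nm = as.numeric(channel_centers_nm),
      bandwidth_nm = bandwidth_nm
    ),
    class = "spectral_axis"
  )
}

#' Instrument model: axes plus IRF description
#'
#' Bundles the time axis, spectral axis and a Gaussian instrument response
#' function (IRF). The Gaussian sigma is `irf_fwhm_ns / (2 sqrt(2 ln 2))`.
#' `wraparound = TRUE` enables the incomplete-decay correction: at 80 MHz the
#' tail of a long-lived component from the previous pulse overlaps the
#' current window and is added via a geometric series factor.
#'
#' @param time A [time_axis()].
#' @param spectral A [spectral_axis()].
#' @param irf_fwhm_ns IRF full width at half maximum in ns (default 0.220).
#' @param irf_t0_ns IRF peak position on the time axis in ns; defaults to
#'   10% of the period.
#' @param wraparound Logical; apply the previous-pulse correction.
#' @param irf_weights Optional measured per-bin IRF weights (length
#'   `n_bins`); when supplied they override the analytic Gaussian model and
#'   decays are formed by discrete convolution instead.
#' @return An object of class `instrument_model`.
#' @examples
#' im <- instrument_model()
#' im$irf_sigma_ns
#' @export
instrument_model <- function(time = time_axis(), spectral = spectral_axis(),
                             irf_fwhm_ns = 0.220, irf_t0_ns = NULL,
                             wraparound = TRUE, irf_weights = NULL) {
  stopifnot(inherits(time, "time_axis"), inherits(spectral, "spectral_axis"))
  if (!is.finite(irf_fwhm_ns) || irf_fwhm_ns <= 0)
    stop("irf_fwhm_ns must be positive")
  if (is.null(irf_t0_ns)) irf_t0_ns <- 0.1 * time$period_ns
  if (irf_t0_ns < 0 || irf_t0_ns >= time$period_ns)
    stop("irf_t0_ns must lie in [0, period_ns)")
  if (!is.null(irf_weights)) {
    irf_weights <- as.numeric(irf_weights)
    if (length(irf_weights) != time$n_bins || any(irf_weights < 0) ||
        sum(irf_weights) <= 0)
      stop("irf_weights must be non-negative, length n_bins, positive sum")
    irf_weights <- irf_weights / sum(irf_weights)
  }
  structure(
    list(
      time = time,
      spectral = spectral,
      irf_fwhm_ns = irf_fwhm_ns,
      irf_t0_ns = irf_t0_ns,
      irf_sigma_ns = irf_fwhm_ns / (2 * sqrt(2 * log(2))),
      wraparound = isTRUE(wraparound),
      irf_weights = irf_weights
    ),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(
    "instrument_model: %d time bins over %.4g ns (%.1f ps/bin), %d channels %.1f-%.1f nm\n",
    x$time$n_bins, x$time$period_ns, 1000 * x$time$bin_width_ns,
    x$spectral$n_channels, min(x$spectral$channel_centers_nm),
    max(x$spectral$channel_centers_nm)))
  cat(sprintf("  IRF: Gaussian, FWHM %.0f ps (sigma %.1f ps) at t0 = %.3g ns; wraparound %s\n",
              1000 * x$irf_fwhm_ns, 1000 * x$irf_sigma_ns, x$irf_t0_ns,
              if (x$wraparound) "on" else "off"))
  invisible(x)
}

#' Single-channel photon-count decay histogram
#'
#' @param counts Non-negative photon counts, one per time bin.
#' @param time The [time_axis()] the counts live on.
#' @return An object of class `decay_curve` with `counts`, `time` and
#'   `total_photons`.
#' @export
decay_curve <- function(counts, time) {
  stopifnot(inherits(time, "time_axis"))
  counts <- as.numeric(counts)
  if (length(counts) != time$n_bins)
    stop("counts length must equal time$n_bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  structure(
    list(counts = counts, time = time, total_photons = sum(counts)),
    class = "decay_curve"
  )
}

#' Multispectral TCSPC image cube
#'
#' A 4-D photon-count histogram indexed (row, col, channel, time bin),
#' together with the instrument model that produced it.
#'
#' @param counts 4-D non-negative array, dims (rows, cols, n_channels, n_bins).
#' @param instrument An [instrument_model()] whose axes match `counts`.
#' @param pixel_size_um Physical pixel pitch in micrometres.
#' @param provenance Named list of free-text metadata.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(counts, instrument, pixel_size_um = 1,
                          provenance = list()) {
  stopifnot(inherits(instrument, "instrument_model"))
  d <- dim(counts)
  if (length(d) != 4L)
    stop("counts must be a 4-D array (rows, cols, channels, bins)")
  if (d[3] != instrument$spectral$n_channels || d[4] != instrument$time$n_bins)
    stop(sprintf("counts dims (%d channels, %d bins) do not match instrument (%d, %d)",
                 d[3], d[4], instrument$spectral$n_channels, instrument$time$n_bins))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(
    list(counts = counts, instrument = instrument,
         pixel_size_um = pixel_size_um, provenance = provenance),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("spectral_cube: %d x %d pixels, %d channels, %d bins, %.3g photons\n",
              d[1], d[2], d[3], d[4], sum(x$counts)))
  invisible(x)
}

#' Extract one pixel (or any spatial position) as a channel x bin matrix
#'
#' @param cube A [spectral_cube()].
#' @param row,col Spatial indices.
#' @return Numeric matrix (n_channels x n_bins).
#' @export
cube_pixel_decays <- function(cube, row, col) {
  stopifnot(inherits(cube, "spectral_cube"))
  m <- cube$counts[row, col, , , drop = TRUE]
  dim(m) <- c(cube$instrument$spectral$n_channels, cube$instrument$time$n_bins)
  m
}
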