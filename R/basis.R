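#' Fixed spectral shapes and lifetime constraints for the three components
#'
#' The global analysis fixes the emission spectra of free and bound NAD(P)H
#' (max-normalized shapes on the channel grid) and the free-NAD(P)H lifetime
#' (0.37 ns); the bound-NAD(P)H and flavin lifetimes are fitted within
#' bounds, and the flavin amplitude spectrum is free per channel but pinned
#' to zero below a wavelength cutoff (490 nm), where flavins do not emit.
#'
#' @param spectral A [spectral_axis()].
#' @param free_spectrum,bound_spectrum Non-negative per-channel shapes; max
#'   is normalized to 1. Defaults are synthetic log-normal bands peaking near
#'   475 nm (free) and 450 nm (bound), matching the solution-phase emission
#'   maxima of the two forms.
#' @param tau_free_ns Fixed free-NAD(P)H lifetime (default 0.37 ns).
#' @param tau_bound_bounds_ns Interval for the bound-NAD(P)H lifetime
#'   (default `c(0.5, 10)`).
#' @param tau_flavin_bounds_ns Interval for the flavin lifetime (default
#'   `c(0.3, 6)`, spanning quenched FAD to FMN).
#' @param flavin_zero_below_nm Channels with centers below this wavelength
#'   get a flavin amplitude fixed at exactly zero (default 490).
#' @return An object of class `component_basis`.
#' @examples
#' b <- component_basis(spectral_axis())
#' which(b$flavin_free_channels)
#' @export
component_basis <- function(spectral,
                            free_spectrum = NULL,
                            bound_spectrum = NULL,
                            tau_free_ns = 0.37,
                            tau_bound_bounds_ns = c(0.5, 10),
                            tau_flavin_bounds_ns = c(0.3, 6),
                            flavin_zero_below_nm = 490) {
  stopifnot(inherits(spectral, "spectral_axis"))
  if (is.null(free_spectrum) || is.null(bound_spectrum)) {
    sp <- generate_component_spectra(spectral, flavin_peak_nm = NA)
    if (is.null(free_spectrum)) free_spectrum <- sp$free
    if (is.null(bound_spectrum)) bound_spectrum <- sp$bound
  }
  norm_shape <- function(s, what) {
    s <- as.numeric(s)
    if (length(s) != spectral$n_channels)
      stop(sprintf("%s length must equal n_channels", what))
    if (any(s < 0) || max(s) <= 0)
      stop(sprintf("%s must be non-negative with a positive maximum", what))
    s / max(s)
  }
  chk_bounds <- function(b, what) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop(sprintf("%s must be a proper interval with positive lower end", what))
    b
  }
  if (tau_free_ns <= 0) stop("tau_free_ns must be positive")
  structure(
    list(
      spectral = spectral,
      free_spectrum = norm_shape(free_spectrum, "free_spectrum"),
      bound_spectrum = norm_shape(bound_spectrum, "bound_spectrum"),
      tau_free_ns = tau_free_ns,
      tau_bound_bounds_ns = chk_bounds(tau_bound_bounds_ns, "tau_bound_bounds_ns"),
      tau_flavin_bounds_ns = chk_bounds(tau_flavin_bounds_ns, "tau_flavin_bounds_ns"),
      flavin_zero_below_nm = flavin_zero_below_nm,
      flavin_free_channels = spectral$channel_centers_nm >= flavin_zero_below_nm
    ),
    class = "component_basis"
  )
}

#' @export
print.component_basis <- function(x, ...) {
  cat(sprintf(
    "component_basis: %d channels; tau_free fixed %.2f ns; tau_bound in [%.2g, %.2g] ns; tau_flavin in [%.2g, %.2g] ns; flavins free in %d channels >= %.0f nm\n",
    x$spectral$n_channels, x$tau_free_ns,
    x$tau_bound_bounds_ns[1], x$tau_bound_bounds_ns[2],
    x$tau_flavin_bounds_ns[1], x$tau_flavin_bounds_ns[2],
    sum(x$flavin_free_channels), x$flavin_zero_below_nm))
  invisible(x)
}

#' Load reference component spectra from CSV onto a channel grid
#'
#' Reads a CSV with columns `wavelength_nm`, `free_nadh`, `bound_nadh`,
#' linearly interpolates both spectra onto the channel centers, and
#' max-normalizes them. The packaged default
#' (`reference_spectra_synthetic_v1.csv`) is a synthetic stand-in built from
#' log-normal bands at the literature emission maxima, not a solution
#' measurement.
#'
#' @param path CSV file path; default is the packaged synthetic reference.
#' @param spectral A [spectral_axis()] to interpolate onto.
#' @return List with elements `free` and `bound` (per-channel, max 1).
#' @export
load_reference_spectra <- function(path = NULL, spectral = spectral_axis()) {
  if (is.null(path))
    path <- system.file("extdata", "reference_spectra_synthetic_v1.csv",
                        package = "multiflim", mustWork = TRUE)
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "free_nadh", "bound_nadh")
  if (!all(need %in% names(df)))
    stop("reference spectra CSV must have columns: ", paste(need, collapse = ", "))
  onto <- function(col) {
    y <- stats::approx(df$wavelength_nm, df[[col]],
                       xout = spectral$channel_centers_nm, rule = 2)$y
    y <- pmax(y, 0)
    y / max(y)
  }
  list(free = onto("free_nadh"), bound = onto("bound_nadh"))
}
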