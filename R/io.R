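CUBE_MAGIC <- "#MSFLIM-CUBE-1"

#' Write a spectral cube to the self-describing container
#'
#' Single text file: the first line carries a magic tag and a JSON header
#' (array dims, time/spectral axes, IRF parameters, pixel size, provenance);
#' the remaining lines hold the counts as a (rows x cols x channels) by
#' n_bins integer matrix in R array order (row index fastest). A `.gz`
#' suffix writes compressed.
#'
#' @param cube A [spectral_cube()].
#' @param path Output file path (conventionally `.stc` or `.stc.gz`).
#' @return `path`, invisibly.
#' @export
write_spectral_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  im <- cube$instrument
  header <- list(
    dims = dim(cube$counts),
    n_bins = im$time$n_bins, period_ns = im$time$period_ns,
    channel_centers_nm = im$spectral$channel_centers_nm,
    bandwidth_nm = im$spectral$bandwidth_nm,
    irf_fwhm_ns = im$irf_fwhm_ns, irf_t0_ns = im$irf_t0_ns,
    wraparound = im$wraparound,
    pixel_size_um = cube$pixel_size_um,
    provenance = cube$provenance
  )
  line <- paste(CUBE_MAGIC,
                jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(line, con)
  close(con)
  d <- dim(cube$counts)
  m <- matrix(as.integer(round(cube$counts)), d[1] * d[2] * d[3], d[4])
  data.table::fwrite(data.table::as.data.table(m), path, append = TRUE,
                     col.names = FALSE, sep = ",")
  invisible(path)
}

#' Read a spectral cube from the container format
#'
#' @param path File written by [write_spectral_cube()].
#' @return A [spectral_cube()].
#' @export
read_spectral_cube <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  line <- readLines(con, n = 1)
  close(con)
  if (!startsWith(line, CUBE_MAGIC))
    stop("not a spectral-cube container (bad magic line): ", path)
  header <- jsonlite::fromJSON(sub(paste0("^", CUBE_MAGIC, " "), "", line))
  d <- header$dims
  m <- as.matrix(data.table::fread(path, skip = 1L, header = FALSE))
  if (nrow(m) != prod(d[1:3]) || ncol(m) != d[4])
    stop("corrupted container: count matrix is ", nrow(m), " x ", ncol(m),
         " but header announces dims ", paste(d, collapse = " x "))
  im <- instrument_model(
    time = time_axis(header$n_bins, header$period_ns),
    spectral = spectral_axis(channel_centers_nm = header$channel_centers_nm,
                             bandwidth_nm = header$bandwidth_nm),
    irf_fwhm_ns = header$irf_fwhm_ns, irf_t0_ns = header$irf_t0_ns,
    wraparound = header$wraparound
  )
  prov <- header$provenance
  spectral_cube(array(as.numeric(m), dim = d), im,
                pixel_size_um = header$pixel_size_um,
                provenance = if (is.null(prov)) list() else as.list(prov))
}

#' Write an integer label mask
#'
#' `.tif`/`.tiff` paths are written as 16-bit grayscale TIFF (labels encoded
#' as value/65535, exact for labels up to 65535); `.csv` writes a plain
#' integer matrix.
#'
#' @param mask Integer matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask < 0) || any(mask != round(mask)))
    stop("mask must contain non-negative integers")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(mask) > 65535) stop("labels above 65535 cannot be TIFF-encoded")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else {
    data.table::fwrite(data.table::as.data.table(mask), path,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read an integer label mask written by [write_label_mask()]
#'
#' @param path `.tif`/`.tiff` or `.csv` path.
#' @return Integer matrix.
#' @export
read_label_mask <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  } else {
    as.matrix(data.table::fread(path, header = FALSE))
  }
}

#' Read measured IRF weights from CSV
#'
#' Expects columns `time_ns` and `weight`; weights are linearly interpolated
#' onto the instrument's bin centers (zero outside the measured range) and
#' normalized to sum to 1. The result can be passed to
#' [instrument_model()]'s `irf_weights` to replace the Gaussian IRF.
#'
#' @param path CSV path.
#' @param time A [time_axis()].
#' @return Numeric vector of per-bin weights summing to 1.
#' @export
read_irf_csv <- function(path, time = time_axis()) {
  df <- utils::read.csv(path)
  if (!all(c("time_ns", "weight") %in% names(df)))
    stop("IRF CSV must have columns time_ns, weight")
  w <- stats::approx(df$time_ns, df$weight, xout = time$bin_centers_ns,
                     yleft = 0, yright = 0)$y
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("IRF weights are all zero on the time grid")
  w / sum(w)
}

#' Default run configuration
#'
#' Nested key/value structure mirroring the YAML config consumed by the
#' command-line interface; every block is validated on load and unknown
#' keys are rejected.
#'
#' @return Named list with `instrument`, `basis`, `fit`, `io` and `report`
#'   blocks.
#' @export
default_run_config <- function() {
  list(
    instrument = list(n_bins = 256L, period_ns = 12.5, n_channels = 16L,
                      range_nm = c(388.1, 573.6), irf_fwhm_ns = 0.220,
                      irf_t0_ns = 1.25, wraparound = TRUE, irf_csv = NULL),
    basis = list(spectra_csv = NULL, tau_free_ns = 0.37,
                 tau_bound_bounds_ns = c(0.5, 10),
                 tau_flavin_bounds_ns = c(0.3, 6), cutoff_nm = 490),
    fit = list(objective = "mle", bin_parameter = 0L, min_photons = 500,
               min_photons_global = 2000, multistart = TRUE, refine = TRUE,
               seed = 1L),
    io = list(output_dir = "."),
    report = list(reference_group = "control", depth_bin_um = 10)
  )
}

#' Load and validate a run configuration
#'
#' @param path YAML file, or `NULL` for the defaults. Supplied keys override
#'   defaults; unknown blocks or keys raise an error.
#' @return Validated config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config block(s): ", paste(bad, collapse = ", "))
    for (blk in names(user)) {
      badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(badk))
        stop("unknown key(s) in block '", blk, "': ",
             paste(badk, collapse = ", "))
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    }
  }
  if (!cfg$fit$objective %in% c("mle", "wls"))
    stop("fit$objective must be 'mle' or 'wls'")
  cfg
}

#' Instrument model from a run configuration
#' @param config A config list from [load_run_config()].
#' @return An [instrument_model()].
#' @export
config_instrument <- function(config) {
  ic <- config$instrument
  tx <- time_axis(ic$n_bins, ic$period_ns)
  w <- if (!is.null(ic$irf_csv)) read_irf_csv(ic$irf_csv, tx) else NULL
  instrument_model(
    time = tx,
    spectral = spectral_axis(ic$n_channels, unlist(ic$range_nm)),
    irf_fwhm_ns = ic$irf_fwhm_ns, irf_t0_ns = ic$irf_t0_ns,
    wraparound = ic$wraparound, irf_weights = w
  )
}

#' Component basis from a run configuration
#' @param config A config list; @param instrument matching instrument.
#' @return A [component_basis()].
#' @export
config_basis <- function(config, instrument) {
  bc <- config$basis
  sp <- if (!is.null(bc$spectra_csv))
    load_reference_spectra(bc$spectra_csv, instrument$spectral)
  else
    generate_component_spectra(instrument$spectral)[c("free", "bound")]
  component_basis(instrument$spectral,
                  free_spectrum = sp$free, bound_spectrum = sp$bound,
                  tau_free_ns = bc$tau_free_ns,
                  tau_bound_bounds_ns = unlist(bc$tau_bound_bounds_ns),
                  tau_flavin_bounds_ns = unlist(bc$tau_flavin_bounds_ns),
                  flavin_zero_below_nm = bc$cutoff_nm)
}

#' Fit options from a run configuration
#' @param config A config list.
#' @return A [fit_options()].
#' @export
config_fit_options <- function(config) {
  fc <- config$fit
  fit_options(objective = fc$objective, min_photons = fc$min_photons,
              min_photons_global = fc$min_photons_global,
              multistart = fc$multistart, refine = fc$refine)
}

# Provenance block written next to every CLI output.
provenance_block <- function(config, seed) {
  list(package = "multiflim",
       version = as.character(utils::packageVersion("multiflim")),
       seed = seed, config = config)
}
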