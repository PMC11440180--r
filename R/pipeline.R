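#' Sliding-window spatial binning of a cube
#'
#' The decay at pixel p of the result is the sum of counts over the
#' (2b+1) x (2b+1) window centered at p, clipped at the image edges (partial
#' windows near borders; no photons are fabricated by padding). `b = 0` is
#' the identity. Binning 5 reproduces the 11 x 11 sliding window used at
#' acquisition-like photon levels.
#'
#' @param cube A [spectral_cube()].
#' @param bin_parameter Non-negative integer b.
#' @return A [spectral_cube()] of the same shape with window-summed counts.
#' @export
spatial_bin <- function(cube, bin_parameter) {
  stopifnot(inherits(cube, "spectral_cube"))
  b <- as.integer(bin_parameter)
  if (is.na(b) || b < 0) stop("bin_parameter must be a non-negative integer")
  if (b == 0L) return(cube)
  d <- dim(cube$counts)
  if (2L * b + 1L > min(d[1], d[2]))
    stop("binning window larger than the image")
  K <- d[3] * d[4]
  x <- array(cube$counts, dim = c(d[1], d[2], K))
  out <- array(0, dim = dim(x))
  i1 <- pmax(seq_len(d[1]) - b, 1L)
  i2 <- pmin(seq_len(d[1]) + b, d[1])
  j1 <- pmax(seq_len(d[2]) - b, 1L)
  j2 <- pmin(seq_len(d[2]) + b, d[2])
  for (k in seq_len(K)) {
    # summed-area table with a zero top row / left column
    S <- matrix(0, d[1] + 1L, d[2] + 1L)
    S[-1, -1] <- apply(apply(x[, , k], 2, cumsum), 1, cumsum) |> t()
    out[, , k] <- S[i2 + 1L, j2 + 1L] - S[i1, j2 + 1L] -
      S[i2 + 1L, j1] + S[i1, j1]
  }
  spectral_cube(array(out, dim = d), cube$instrument, cube$pixel_size_um,
                c(cube$provenance, list(spatial_bin = b)))
}

#' Per-pixel intensity-weighted mean emission wavelength
#'
#' For each pixel, `I_i` is the time-summed count in spectral channel i and
#' `lambda_avg = sum(lambda_i I_i) / sum(I_i)`. Pixels with zero total
#' counts are `NA`.
#'
#' @param cube A [spectral_cube()].
#' @return Numeric matrix (rows x cols) of wavelengths in nm.
#' @export
compute_lambda_avg_map <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$counts)
  I <- apply(cube$counts, c(1, 2, 3), sum)        # rows x cols x channels
  lam <- cube$instrument$spectral$channel_centers_nm
  num <- apply(sweep(I, 3, lam, "*"), c(1, 2), sum)
  den <- apply(I, c(1, 2), sum)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

# lambda_avg of one channel x bin count matrix
lambda_avg_of_decays <- function(M, spectral) {
  I <- rowSums(M)
  if (sum(I) <= 0) return(NA_real_)
  sum(spectral$channel_centers_nm * I) / sum(I)
}

#' Per-pixel global-fit parameter maps
#'
#' Applies [spatial_bin()] and then runs [fit_global()] at every pixel whose
#' binned decay holds at least `min_photons` photons. Unfitted pixels are
#' `NA`, never zero.
#'
#' @param cube A [spectral_cube()].
#' @param basis A [component_basis()].
#' @param bin_parameter Spatial binning b (window side 2b+1).
#' @param min_photons Minimum photons in a binned pixel decay to fit.
#' @param options A [fit_options()].
#' @param verbose Print progress every few hundred pixels.
#' @return Object of class `parameter_maps`: list of matrices `tau_m_nadh_ns`,
#'   `ratio_free_bound`, `a_flavins`, `tau_bound_ns`, `tau_flavin_ns`,
#'   `lambda_avg_nm`, `photon_count`, logical `fitted`, plus the instrument.
#' @export
fit_pixel_maps <- function(cube, basis, bin_parameter = 0L,
                           min_photons = 2000, options = fit_options(),
                           verbose = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  binned <- spatial_bin(cube, bin_parameter)
  d <- dim(binned$counts)
  instrument <- binned$instrument
  nm <- function() matrix(NA_real_, d[1], d[2])
  maps <- list(tau_m_nadh_ns = nm(), ratio_free_bound = nm(),
               a_flavins = nm(), tau_bound_ns = nm(), tau_flavin_ns = nm(),
               lambda_avg_nm = compute_lambda_avg_map(binned),
               photon_count = apply(binned$counts, c(1, 2), sum),
               fitted = matrix(FALSE, d[1], d[2]))
  todo <- which(maps$photon_count >= min_photons)
  if (!length(todo))
    warning("no pixel reaches min_photons; all maps are missing")
  for (n in seq_along(todo)) {
    ij <- arrayInd(todo[n], d[1:2])
    M <- cube_pixel_decays(binned, ij[1], ij[2])
    g <- try(fit_global(M, instrument, basis, options), silent = TRUE)
    if (inherits(g, "try-error")) next
    maps$tau_m_nadh_ns[ij] <- g$tau_m_nadh_ns
    maps$ratio_free_bound[ij] <- g$ratio_free_bound
    maps$a_flavins[ij] <- g$a_flavins
    maps$tau_bound_ns[ij] <- g$tau_bound_ns
    maps$tau_flavin_ns[ij] <- g$tau_flavin_ns
    maps$fitted[ij] <- TRUE
    if (verbose && n %% 200 == 0)
      message(sprintf("fit_pixel_maps: %d / %d pixels", n, length(todo)))
  }
  structure(c(maps, list(instrument = instrument,
                         bin_parameter = as.integer(bin_parameter))),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("parameter_maps: %d x %d px, %d fitted (b = %d)\n",
              nrow(x$fitted), ncol(x$fitted), sum(x$fitted), x$bin_parameter))
  invisible(x)
}

#' Cell-integrated global fits over a label mask
#'
#' For every label, the photon histograms of all member pixels are summed
#' into one multispectral decay set (fitting the sum is identical to
#' fitting the integrated cell signal) and [fit_global()] is run on it.
#' Labels below `min_photons_global` are skipped with a reason; an empty
#' mask yields an empty table.
#'
#' @param cube A [spectral_cube()].
#' @param label_mask Integer matrix of cell labels (0 = background), same
#'   spatial shape as the cube.
#' @param basis A [component_basis()].
#' @param options A [fit_options()].
#' @param phantom Optional [scene_phantom()]; its group and
#'   border-distance ground truth are joined onto the table.
#' @return A `data.frame` ("cell table") with one row per fitted cell:
#'   identity, photon accounting, every global-fit descriptor, the
#'   cell-level total-signal `lambda_avg_nm`, and `border_distance_um`.
#' @export
aggregate_cells <- function(cube, label_mask, basis,
                            options = fit_options(), phantom = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  label_mask <- as.matrix(label_mask)
  d <- dim(cube$counts)
  if (!all(dim(label_mask) == d[1:2]))
    stop("label mask shape does not match the cube's spatial shape")
  labels <- sort(unique(as.vector(label_mask)))
  labels <- labels[labels > 0]
  cm <- matrix(cube$counts, d[1] * d[2], d[3] * d[4])
  rows <- list()
  for (lb in labels) {
    px <- which(label_mask == lb)
    M <- matrix(colSums(cm[px, , drop = FALSE]), d[3], d[4])
    row <- data.frame(
      cell_id = lb,
      group = if (!is.null(phantom)) phantom$group_label else NA_character_,
      n_pixels = length(px),
      total_photons = sum(M),
      a_free = NA_real_, a_bound = NA_real_, a_flavins = NA_real_,
      ratio_free_bound = NA_real_, tau_bound_ns = NA_real_,
      tau_flavin_ns = NA_real_, tau_m_nadh_ns = NA_real_,
      lambda_avg_flavin_nm = NA_real_,
      lambda_avg_nm = lambda_avg_of_decays(M, cube$instrument$spectral),
      chi2_reduced = NA_real_, converged = FALSE, at_bound = NA,
      border_distance_um = NA_real_, reason = NA_character_
    )
    if (sum(M) < options$min_photons_global) {
      row$reason <- "below min_photons_global"
    } else {
      g <- fit_global(M, cube$instrument, basis, options)
      for (f in c("a_free", "a_bound", "a_flavins", "ratio_free_bound",
                  "tau_bound_ns", "tau_flavin_ns", "tau_m_nadh_ns",
                  "lambda_avg_flavin_nm", "chi2_reduced", "converged",
                  "at_bound"))
        row[[f]] <- g[[f]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(phantom) && nrow(out)) {
    idx <- match(out$cell_id, phantom$truth$cell_id)
    out$border_distance_um <- phantom$truth$border_distance_um[idx]
  }
  out
}

#' Distance from the spheroid border at each cell centroid
#'
#' Euclidean distance transform of the spheroid interior to its boundary
#' (via `EBImage::distmap`), evaluated at each cell's centroid and scaled to
#' micrometres.
#'
#' @param label_mask Integer cell-label matrix.
#' @param spheroid_mask Logical/0-1 matrix marking the spheroid foreground
#'   (one connected region).
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return `data.frame` with `cell_id` and `border_distance_um`.
#' @export
assign_border_distance <- function(label_mask, spheroid_mask,
                                   pixel_size_um = 1) {
  label_mask <- as.matrix(label_mask)
  spheroid_mask <- as.matrix(spheroid_mask) > 0
  if (!all(dim(label_mask) == dim(spheroid_mask)))
    stop("label and spheroid masks must have the same shape")
  dm <- EBImage::distmap(EBImage::Image(spheroid_mask * 1))
  dm <- as.matrix(EBImage::imageData(dm))
  labels <- sort(unique(as.vector(label_mask)))
  labels <- labels[labels > 0]
  out <- lapply(labels, function(lb) {
    px <- which(label_mask == lb, arr.ind = TRUE)
    cen <- pmax(round(colMeans(px)), 1)
    cen <- pmin(cen, dim(dm))
    data.frame(cell_id = lb,
               border_distance_um = dm[cen[1], cen[2]] * pixel_size_um)
  })
  do.call(rbind, out)
}
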