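#' Smooth synthetic emission spectra for the three components
#'
#' Log-normal band shapes (a standard phenomenological model for broad
#' fluorescence emission bands), max-normalized on the channel grid: free
#' NAD(P)H peaking at 475 nm, bound NAD(P)H at 450 nm, and flavins at
#' `flavin_peak_nm` (default 535 nm) with the shape truncated to exactly
#' zero below `flavin_cut_nm`.
#'
#' @param spectral A [spectral_axis()].
#' @param flavin_peak_nm Flavin emission maximum in nm; `NA` skips the
#'   flavin band (only `free` and `bound` are returned).
#' @param free_peak_nm,bound_peak_nm NAD(P)H emission maxima in nm.
#' @param flavin_cut_nm Wavelength below which the flavin shape is zero.
#' @param logwidth Log-domain Gaussian widths of the three bands.
#' @return List with per-channel shapes `free`, `bound`, `flavin`, each with
#'   maximum 1.
#' @export
generate_component_spectra <- function(spectral = spectral_axis(),
                                       flavin_peak_nm = 535,
                                       free_peak_nm = 475,
                                       bound_peak_nm = 450,
                                       flavin_cut_nm = 490,
                                       logwidth = c(free = 0.090,
                                                    bound = 0.085,
                                                    flavin = 0.080)) {
  stopifnot(inherits(spectral, "spectral_axis"))
  lam <- spectral$channel_centers_nm
  rng <- range(lam)
  peaks <- c(free_peak_nm, bound_peak_nm)
  if (!is.na(flavin_peak_nm)) peaks <- c(peaks, flavin_peak_nm)
  for (p in peaks)
    if (p < rng[1] || p > rng[2])
      stop("component peak lies outside the spectral range")
  band <- function(peak, w) {
    s <- exp(-log(lam / peak)^2 / (2 * w^2))
    s / max(s)
  }
  out <- list(free = band(free_peak_nm, logwidth[["free"]]),
              bound = band(bound_peak_nm, logwidth[["bound"]]))
  if (!is.na(flavin_peak_nm)) {
    flavin <- band(flavin_peak_nm, logwidth[["flavin"]])
    flavin[lam < flavin_cut_nm] <- 0
    if (max(flavin) <= 0) stop("flavin band entirely below the cutoff")
    out$flavin <- flavin / max(flavin)
  }
  out
}

# Median ground-truth parameters per treatment group: free/bound amplitude
# ratio, bound-NAD(P)H lifetime, normalized flavin amplitude, flavin
# lifetime, flavin emission peak.
group_parameter_table <- function() {
  data.frame(
    group = c("control", "rotenone", "3BP"),
    ratio_free_bound = c(2.7, 3.3, 2.65),
    tau_bound_ns = c(2.5, 2.1, 2.35),
    flavin_fraction = c(0.12, 0.076, 0.115),
    tau_flavin_ns = c(1.48, 1.85, 1.72),
    flavin_peak_nm = c(535, 543, 540)
  )
}

#' Convert (ratio, flavin fraction) ground truth to component amplitudes
#'
#' Returns scalars `(A1, A2, A3)` such that `A1/A2 = ratio` and
#' `A3/(A1+A2+A3) = flavin_fraction`, with `A2 = 1`. These are the channel
#' maxima of the three decay-associated spectra.
#'
#' @param ratio_free_bound Free/bound amplitude ratio.
#' @param flavin_fraction Normalized flavin amplitude in [0, 1).
#' @return Numeric vector `c(A1, A2, A3)`.
#' @export
amplitudes_from_truth <- function(ratio_free_bound, flavin_fraction) {
  if (flavin_fraction < 0 || flavin_fraction >= 1)
    stop("flavin_fraction must be in [0, 1)")
  A1 <- ratio_free_bound
  A2 <- 1
  A3 <- flavin_fraction / (1 - flavin_fraction) * (A1 + A2)
  c(A1, A2, A3)
}

#' Expected (noise-free) multispectral decay set for one ground truth
#'
#' Forward-models the channel-by-bin expected counts for a single set of
#' ground-truth parameters, scaled to a total photon count.
#'
#' @param truth List or one-row data.frame with `ratio_free_bound`,
#'   `tau_bound_ns`, `flavin_fraction`, `tau_flavin_ns`, and optionally
#'   `flavin_peak_nm` (default 535).
#' @param instrument An [instrument_model()].
#' @param basis A [component_basis()] supplying the fixed NAD(P)H shapes
#'   and the free-NAD(P)H lifetime.
#' @param total_photons Expected photons summed over channels and bins.
#' @return Matrix (n_channels x n_bins) of expected counts.
#' @export
expected_cell_decays <- function(truth, instrument, basis,
                                 total_photons = 5e5) {
  peak <- if (!is.null(truth$flavin_peak_nm)) truth$flavin_peak_nm else 535
  s3 <- generate_component_spectra(basis$spectral, flavin_peak_nm = peak,
                                   flavin_cut_nm = basis$flavin_zero_below_nm)$flavin
  A <- amplitudes_from_truth(truth$ratio_free_bound, truth$flavin_fraction)
  amp <- rbind(A[1] * basis$free_spectrum,
               A[2] * basis$bound_spectrum,
               A[3] * s3)
  M <- model_cube_slice(amp, c(basis$tau_free_ns, truth$tau_bound_ns,
                               truth$tau_flavin_ns), instrument)
  M * (total_photons / sum(M))
}

#' Scene phantom: label image plus per-cell ground truth
#'
#' @param cell_masks Integer label matrix (0 = background, cells = 1..n).
#' @param truth `data.frame` with one row per label: `cell_id`, `group`,
#'   `ratio_free_bound`, `tau_bound_ns`, `flavin_fraction`, `tau_flavin_ns`,
#'   `flavin_peak_nm`, `brightness`, `border_distance_um`.
#' @param group_label Scene-level group tag.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return Object of class `scene_phantom`.
#' @export
scene_phantom <- function(cell_masks, truth, group_label,
                          pixel_size_um = 1, spheroid_mask = NULL) {
  cell_masks <- as.matrix(cell_masks)
  labels <- sort(unique(as.vector(cell_masks)))
  labels <- labels[labels > 0]
  if (length(labels) && !identical(as.integer(labels), seq_along(labels)))
    stop("cell labels must be contiguous positive integers 1..n")
  if (!identical(sort(truth$cell_id), as.integer(labels)) &&
      length(labels) != nrow(truth))
    stop("ground truth must have one row per label")
  if (any(truth$flavin_fraction < 0 | truth$flavin_fraction > 1))
    stop("flavin_fraction must lie in [0, 1]")
  structure(list(
    shape = dim(cell_masks), cell_masks = cell_masks, truth = truth,
    group_label = group_label, pixel_size_um = pixel_size_um,
    spheroid_mask = spheroid_mask
  ), class = "scene_phantom")
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf("scene_phantom '%s': %d x %d px, %d cells\n",
              x$group_label, x$shape[1], x$shape[2], nrow(x$truth)))
  invisible(x)
}

# Pack n non-overlapping ellipses on a jittered grid; returns a label matrix.
pack_ellipse_cells <- function(n_cells, cell_radius_px = 4, gap_px = 3) {
  pitch <- 2 * cell_radius_px + gap_px
  per_side <- ceiling(sqrt(n_cells))
  side <- per_side * pitch + gap_px
  lab <- matrix(0L, side, side)
  xs <- row(lab)
  ys <- col(lab)
  placed <- 0L
  for (i in seq_len(per_side)) {
    for (j in seq_len(per_side)) {
      if (placed >= n_cells) break
      placed <- placed + 1L
      cx <- gap_px + cell_radius_px + (i - 1L) * pitch +
        stats::runif(1, -gap_px / 2, gap_px / 2)
      cy <- gap_px + cell_radius_px + (j - 1L) * pitch +
        stats::runif(1, -gap_px / 2, gap_px / 2)
      rx <- cell_radius_px * stats::runif(1, 0.8, 1.1)
      ry <- cell_radius_px * stats::runif(1, 0.8, 1.1)
      th <- stats::runif(1, 0, pi)
      dx <- xs - cx
      dy <- ys - cy
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      inside <- (u / rx)^2 + (v / ry)^2 <= 1
      lab[inside & lab == 0L] <- placed
    }
  }
  lab
}

# Multiplicative lognormal jitter with median `med` and coefficient of
# variation `cv`.
rlnorm_med <- function(n, med, cv) {
  if (cv <= 0) return(rep(med, n))
  sdlog <- sqrt(log(1 + cv^2))
  med * exp(stats::rnorm(n, 0, sdlog))
}

#' Phantom of a treated cell-culture field of view
#'
#' Non-overlapping elliptical cells on a dark background; per-cell
#' parameters are drawn from narrow lognormal distributions (default CV
#' 10%) centered on the group's median ground truth: control
#' (ratio 2.7, tau_bound 2.5 ns, flavin fraction 0.12, tau_flavin 1.48 ns),
#' rotenone (3.3, 2.1, 0.076, 1.85) and 3BP (2.65, 2.35, 0.115, 1.72).
#'
#' @param group_label `"control"`, `"rotenone"` or `"3BP"`.
#' @param n_cells Number of cells (>= 1).
#' @param seed RNG seed (mandatory; the phantom is reproducible).
#' @param cv Coefficient of variation of the per-cell parameter jitter.
#' @param brightness Expected photons per cell pixel.
#' @param cell_radius_px Nominal cell radius in pixels.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return A [scene_phantom()].
#' @export
make_group_scene <- function(group_label, n_cells, seed, cv = 0.10,
                             brightness = 200, cell_radius_px = 4,
                             pixel_size_um = 1) {
  grp <- group_parameter_table()
  if (!group_label %in% grp$group)
    stop("unknown group: ", group_label, " (expected one of ",
         paste(grp$group, collapse = ", "), ")")
  if (n_cells < 1) stop("n_cells must be >= 1")
  g <- grp[grp$group == group_label, ]
  set.seed(seed)
  lab <- pack_ellipse_cells(n_cells, cell_radius_px)
  truth <- data.frame(
    cell_id = seq_len(n_cells),
    group = group_label,
    ratio_free_bound = rlnorm_med(n_cells, g$ratio_free_bound, cv),
    tau_bound_ns = rlnorm_med(n_cells, g$tau_bound_ns, cv),
    flavin_fraction = pmin(rlnorm_med(n_cells, g$flavin_fraction, cv), 0.9),
    tau_flavin_ns = rlnorm_med(n_cells, g$tau_flavin_ns, cv),
    flavin_peak_nm = g$flavin_peak_nm,
    brightness = brightness,
    border_distance_um = NA_real_
  )
  scene_phantom(lab, truth, group_label, pixel_size_um)
}

#' Phantom of a tumor-spheroid cross section
#'
#' A disk of packed cells whose ground truth varies linearly with the
#' distance from the spheroid border over the first 80 micrometres: the
#' free/bound amplitude ratio decreases 5.3 -> 4.0, the flavin fraction
#' increases 0.125 -> 0.16, and the bound-NAD(P)H lifetime follows the
#' mean-lifetime gradient 0.84 -> 0.86 ns implied by those ratios
#' (`tau_bound = tau_m (ratio + 1) - 0.37 ratio`, i.e. 3.33 -> 2.82 ns).
#' Profiles are exactly linear (monotone by construction); depths beyond
#' 80 um hold the 80 um values. Default radius 85 um so recorded depths
#' cover the full 0-80 um range.
#'
#' @param radius_um Spheroid radius in micrometres (>= 80 to span the full
#'   depth range).
#' @param seed RNG seed.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param cell_radius_px Nominal cell radius in pixels.
#' @param brightness Expected photons per cell pixel; the default gives a
#'   cell-integrated signal of a few 1e4 photons, a typical two-photon
#'   autofluorescence level for small segmented cells.
#' @return A [scene_phantom()] with `border_distance_um` filled in.
#' @export
make_spheroid_scene <- function(radius_um = 85, seed = 1, pixel_size_um = 2,
                                cell_radius_px = 2, brightness = 4000) {
  set.seed(seed)
  r_px <- radius_um / pixel_size_um
  side <- ceiling(2 * r_px) + 5L
  ctr <- (side + 1) / 2
  pitch <- 2 * cell_radius_px + 2L
  lab <- matrix(0L, side, side)
  xs <- row(lab)
  ys <- col(lab)
  disk <- (xs - ctr)^2 + (ys - ctr)^2 <= r_px^2
  centers <- expand.grid(
    x = seq(cell_radius_px + 1, side - cell_radius_px, by = pitch),
    y = seq(cell_radius_px + 1, side - cell_radius_px, by = pitch)
  )
  centers$x <- centers$x + stats::runif(nrow(centers), -1, 1)
  centers$y <- centers$y + stats::runif(nrow(centers), -1, 1)
  d_ctr <- sqrt((centers$x - ctr)^2 + (centers$y - ctr)^2)
  # cells may touch the border (pixels clipped to the disk) so recorded
  # depths reach (close to) zero at the shell
  centers <- centers[d_ctr <= r_px - 1, ]
  if (nrow(centers) == 0) stop("radius too small to hold any cell")
  k <- 0L
  depth <- numeric(0)
  for (i in seq_len(nrow(centers))) {
    inside <- disk &
      (xs - centers$x[i])^2 + (ys - centers$y[i])^2 <= cell_radius_px^2
    if (!any(inside & lab == 0L)) next
    k <- k + 1L
    lab[inside & lab == 0L] <- k
    d_border_um <- max(r_px - sqrt((centers$x[i] - ctr)^2 +
                                   (centers$y[i] - ctr)^2), 0) * pixel_size_um
    depth <- c(depth, d_border_um)
  }
  f <- pmin(depth, 80) / 80
  ratio <- 5.3 + (4.0 - 5.3) * f
  tau_m <- 0.84 + (0.86 - 0.84) * f
  tau_bound <- tau_m * (ratio + 1) - 0.37 * ratio
  truth <- data.frame(
    cell_id = seq_len(k),
    group = "spheroid",
    ratio_free_bound = ratio,
    tau_bound_ns = tau_bound,
    flavin_fraction = 0.125 + (0.16 - 0.125) * f,
    tau_flavin_ns = 1.6,
    flavin_peak_nm = 535,
    brightness = brightness,
    border_distance_um = depth
  )
  scene_phantom(lab, truth, "spheroid", pixel_size_um, spheroid_mask = disk)
}

#' Simulate a multispectral TCSPC cube from a phantom
#'
#' Per pixel, the expected channel-by-bin counts are the forward model at
#' that pixel's cell ground truth scaled to the cell brightness; observed
#' counts are drawn independently Poisson. Background pixels receive only
#' the optional dark-count rate. Bit-identical for identical seeds.
#'
#' @param phantom A [scene_phantom()].
#' @param instrument An [instrument_model()].
#' @param basis A [component_basis()].
#' @param seed RNG seed (mandatory).
#' @param total_photon_budget Optional expected total photons over the whole
#'   cube; rescales all brightness values.
#' @param background_rate Expected dark counts per pixel (spread uniformly
#'   over channels and bins).
#' @return A [spectral_cube()]; provenance records the seed and realized
#'   expected budget, and a `budget_warning` flag when fewer than 10
#'   expected photons land on some cell pixel.
#' @export
simulate_cube <- function(phantom, instrument, basis, seed,
                          total_photon_budget = NULL, background_rate = 0) {
  stopifnot(inherits(phantom, "scene_phantom"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  lab <- phantom$cell_masks
  n_ch <- instrument$spectral$n_channels
  n_bins <- instrument$time$n_bins
  d <- dim(lab)
  bright <- phantom$truth$brightness
  if (!is.null(total_photon_budget)) {
    px_per_cell <- tabulate(lab[lab > 0], nbins = nrow(phantom$truth))
    expected <- sum(bright * px_per_cell) + background_rate * prod(d)
    bright <- bright * total_photon_budget / expected
  }
  # pixel x (channel, bin) working matrix; reshaped to 4-D at the end
  cm <- matrix(0, prod(d), n_ch * n_bins)
  if (background_rate > 0)
    cm[] <- stats::rpois(length(cm), background_rate / (n_ch * n_bins))
  budget_warning <- FALSE
  for (i in seq_len(nrow(phantom$truth))) {
    px <- which(lab == phantom$truth$cell_id[i])
    if (!length(px)) next
    if (bright[i] < 10) budget_warning <- TRUE
    M <- expected_cell_decays(phantom$truth[i, ], instrument, basis,
                              total_photons = bright[i])
    lam <- rep(as.vector(M), each = length(px))  # channel fastest, then bin
    cm[px, ] <- cm[px, ] +
      matrix(stats::rpois(length(lam), lam), nrow = length(px))
  }
  counts <- array(cm, dim = c(d[1], d[2], n_ch, n_bins))
  spectral_cube(counts, instrument, phantom$pixel_size_um,
                provenance = list(seed = seed, group = phantom$group_label,
                                  budget_warning = budget_warning))
}
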