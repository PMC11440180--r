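# Shared fixtures: default instrument/basis and photon-level helpers.

default_instrument <- function(...) instrument_model(...)

default_basis <- function(instrument = default_instrument()) {
  component_basis(instrument$spectral)
}

control_truth <- function() {
  list(ratio_free_bound = 2.7, tau_bound_ns = 2.5,
       flavin_fraction = 0.12, tau_flavin_ns = 1.48)
}

rotenone_truth <- function() {
  list(ratio_free_bound = 3.3, tau_bound_ns = 2.1,
       flavin_fraction = 0.076, tau_flavin_ns = 1.85)
}

# Poisson realization of one cell-integrated multispectral decay set
sim_cell_counts <- function(truth, instrument, basis, total_photons) {
  M <- expected_cell_decays(truth, instrument, basis, total_photons)
  matrix(stats::rpois(length(M), M), nrow(M))
}

# free-NADH solution-phase bi-exponential expected curve
free_nadh_curve <- function(instrument, total_photons = 1e5) {
  m <- model_decay(c(0.8, 0.2), c(0.36, 0.89), instrument)
  m * total_photons / sum(m)
}
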