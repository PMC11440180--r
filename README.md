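# multiflim

Analysis of **multispectral FLIM** (fluorescence lifetime imaging) data:
time-correlated single photon counting cubes recorded in many spectral
channels at a single two-photon excitation wavelength, where the
autofluorescence of **free NAD(P)H**, **protein-bound NAD(P)H** and
**flavins** (FAD/FMN) overlaps both in spectrum and in decay time. The
package is for microscopists and image analysts doing metabolic imaging of
cells and 3-D tumor spheroids who want the three pools disentangled per
pixel or per segmented cell.

## The method

Each decay set (a pixel, a binned pixel, or a cell-integrated measurement)
is a channel-by-time photon histogram `F(λ, t)`. Two fitters are provided:

**Per-channel bi-exponential fit** (exploratory):

    F(t) ~ IRF(t) ⊗ (a₁ e^(−t/τ₁) + a₂ e^(−t/τ₂)),
    τ_m = (a₁τ₁ + a₂τ₂)/(a₁ + a₂)

**Global three-component unmixing** (the core method): all channels fitted
simultaneously with lifetimes shared across channels,

    F(λ, t) ~ IRF(t) ⊗ Σᵢ aᵢ(λ) e^(−t/τᵢ),   i = 1..3

under the constraints that make the components identifiable: the free- and
bound-NAD(P)H spectra are fixed shapes (amplitudes free), τ_free = 0.37 ns
is fixed, τ_bound ∈ [0.5, 10] ns, and the flavin amplitudes a₃(λ) are free
per channel but exactly zero below 490 nm. From the fitted
decay-associated spectra the per-component channel maxima Aᵢ = max_λ aᵢ(λ)
give normalized contributions aᵢ = Aᵢ/(A₁+A₂+A₃), the free/bound amplitude
ratio, the NAD(P)H mean lifetime
(a_free·τ_free + a_bound·τ_bound)/(a_free + a_bound), and the
intensity-weighted mean emission wavelength of the flavin spectrum.

The IRF is a Gaussian (220 ps FWHM by default); component curves use the
closed-form Gaussian⊗exponential with an erfcx formulation and a
previous-pulse ("wraparound") correction for the 12.5 ns window at 80 MHz.
Fits are Poisson maximum likelihood by default, solved separably:
non-negative least squares for amplitudes inside a bounded search over the
log-lifetimes, then a joint gradient polish.

A photon-realistic simulator (treatment-group scenes and spheroid
phantoms with linear radial gradients), an imaging pipeline (sliding-window
binning, λ-average maps, cell aggregation over label masks, border
distances), and group statistics (median/IQR, Mann-Whitney U,
correlations, depth profiles) complete the workflow.

## Worked example

Simulate one cell-integrated decay set at the control-group parameter
medians (free/bound ratio 2.7, τ_bound 2.5 ns, flavin contribution 0.12,
τ_flavin 1.48 ns) with 5×10⁵ photons, and unmix it:

```r
library(multiflim)
im    <- instrument_model()
basis <- component_basis(im$spectral)

set.seed(42)
truth <- list(ratio_free_bound = 2.7, tau_bound_ns = 2.5,
              flavin_fraction = 0.12, tau_flavin_ns = 1.48)
M   <- expected_cell_decays(truth, im, basis, total_photons = 5e5)
Y   <- matrix(rpois(length(M), M), nrow(M))
fit <- fit_global(Y, im, basis)
fit
#> global_fit: tau_bound = 2.489 ns, tau_flavin = 1.484 ns |
#>   a_free/a_bound/a_flavins = 0.637/0.240/0.123 (ratio 2.66) |
#>   tau_m(NAD(P)H) = 0.949 ns, lambda_avg(flavins) = 536.3 nm
```

Every generating parameter is recovered within a few percent from a single
noisy realization: the bound-NAD(P)H lifetime (2.489 vs 2.5 ns), the flavin
lifetime (1.484 vs 1.48 ns), the free/bound ratio (2.66 vs 2.7) and the
flavin contribution (0.123 vs 0.12). The NAD(P)H mean lifetime of ~0.95 ns
and the flavin λ_avg of ~536 nm follow from those.

The solution-phase arithmetic is a one-liner — the mean lifetime of free
NADH from its published bi-exponential fit (80%/20% amplitudes, 0.36 and
0.89 ns):

```r
mean_lifetime(0.80, 0.36, 0.20, 0.89)
#> [1] 0.466
```

A command-line interface wraps the same functions
(`inst/cli/multiflim simulate | fit | report | irf-check`); cubes travel in
a self-describing text container, masks as 16-bit TIFF or CSV, tables as
CSV.

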