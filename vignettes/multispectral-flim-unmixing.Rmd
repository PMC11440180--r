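---
title: "Global three-component unmixing of multispectral FLIM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global three-component unmixing of multispectral FLIM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

Two-photon excitation of living cells at a single near-infrared wavelength
excites three endogenous fluorophore pools at once: free NAD(P)H, protein-
bound NAD(P)H, and oxidized flavins (FAD/FMN). A multispectral TCSPC
detector histograms photon arrival times in 16 spectral channels, so each
pixel of an image carries a channel-by-time photon-count cube `F(lambda, t)`.
The difficulty is that the three pools overlap both spectrally and
temporally; neither the spectrum alone nor a single-channel decay alone
separates them.

`multiflim` implements the two complementary analyses of such cubes:

1. **Per-channel bi-exponential fits.** Each channel's decay is fitted
   independently with
   `F(t) ~ IRF(t) (x) (a1 exp(-t/tau1) + a2 exp(-t/tau2))` and summarized by
   the amplitude-weighted mean lifetime
   `tau_m = (a1 tau1 + a2 tau2)/(a1 + a2)`. This is the exploratory view:
   with NAD(P)H alone, `tau_m(lambda)` falls with wavelength (the free form
   emits red of the bound form); a rise above ~500 nm betrays flavins.

2. **Global three-component unmixing.** All channels are fitted
   simultaneously with
   `F(lambda, t) ~ IRF(t) (x) sum_i a_i(lambda) exp(-t/tau_i)`, `i = 1..3`,
   where each component's lifetime is shared across channels. Identifiability
   comes from hard constraints: the free- and bound-NAD(P)H emission spectra
   are fixed shapes (only their overall amplitudes vary), the free-NAD(P)H
   lifetime is fixed at 0.37 ns, the bound lifetime is fitted inside
   [0.5, 10] ns, and the flavin component has free per-channel amplitudes
   that are pinned to exactly zero below 490 nm, where flavins do not emit,
   with its lifetime fitted inside [0.3, 6] ns (quenched FAD up to FMN).

The unmixing readout per decay set is: the channel maxima `A_i` of the three
decay-associated spectra, their normalized contributions
`a_i = A_i / (A1 + A2 + A3)`, the free/bound amplitude ratio (a glycolytic
vs oxidative proxy), the NAD(P)H mean lifetime
`(a_free tau_free + a_bound tau_bound)/(a_free + a_bound)`, the flavin
lifetime, and the intensity-weighted mean emission wavelength of the flavin
spectrum. Because the fixed NAD(P)H shapes are max-normalized, the fitted
amplitude scalars *are* the channel maxima, which makes the normalized
contributions well defined without further convention.

## The forward model and its numerics

The IRF is modeled as a Gaussian (default 220 ps FWHM, i.e. sigma =
FWHM / (2 sqrt(2 ln 2)) = 93.4 ps). Each component curve is the closed-form
Gaussian-convolved exponential

```
h(t) = 0.5 exp(sigma^2/(2 tau^2) - (t - t0)/tau)
           erfc((sigma/tau - (t - t0)/sigma)/sqrt(2)),
```

evaluated at the bin centers in the scaled-erfc (`erfcx`) form so it cannot
overflow when `tau << sigma`. At an 80 MHz repetition rate the 12.5 ns
window does not contain a long-lived decay completely, so by default the
previous-pulse tail is added through the geometric factor
`exp(-T/tau)/(1 - exp(-T/tau))` applied to the pure-exponential part
("wraparound", on by default; with it the model conserves periodic mass
independent of the IRF position). The analytic form is used for all
fitting; an independent brute-force numeric convolution (Gauss-Legendre
quadrature of the sampled Gaussian against the sampled exponential on a
10x-oversampled grid) is kept as a test oracle and agrees with the analytic
curves to better than one part in 1e4 across lifetimes of 0.2-6 ns.

A measured IRF can replace the Gaussian: per-bin weights from a two-column
CSV are convolved with cell-averaged periodized exponentials by FFT. The
resolution of that path is inherently the time bin, so the rising edge can
differ from the continuous-Gaussian model at the bin scale; lifetimes and
integrals are unaffected.

Defaults the data do not dictate and we had to choose:

* **Time binning**: 256 bins over 12.5 ns, standard TCSPC ADC settings;
  configurable.
* **IRF position** `t0`: 10% of the period (1.25 ns). A shared `t0` shift
  can be fitted (`fit_t0`), but is off by default; per-channel IRF color
  shift is not modeled.
* **Spectral grid**: the published 16-channel range 388.1-573.6 nm is
  inconsistent with 16 x 12.5 nm; we read 388.1 and 573.6 as the first and
  last channel *centers* (uniform spacing 12.367 nm) and keep 12.5 nm as
  descriptive bandwidth metadata only.
* **Background**: dark counts default to zero; the simulator can add them,
  and decays may be trimmed before the IRF rise (`trim_start_bins`).
* **Flavin lifetime model**: one shared exponential. Reported flavin "mean"
  lifetimes in the field sometimes imply a richer sub-model; with a single
  flavin exponential the fitted value plays that role, and we accept the
  tension rather than add an unidentifiable second flavin component.

## Fitting strategy

Both fitters use a separable search. At fixed lifetimes every amplitude
enters the model linearly, so amplitudes are solved by non-negative
weighted least squares (Lawson-Hanson NNLS, weights `1/max(k, 1)`); a
bounded quasi-Newton search then runs over the log-lifetimes only (2-D for
the global fit), followed by a joint polish of lifetimes and amplitudes
under the chosen objective with analytic gradients. The default objective
is the Poisson deviance `2 sum(m - k + k log(k/m))` — correct at TCSPC
count levels where Gaussian weighting is biased — with Neyman weighted
least squares available for parity with common practice. Multi-start grids
(tau_bound x tau_flavin in {1.0, 2.0, 3.5} x {0.8, 1.5, 3.0} ns; tau2 in
{1, 2, 4} ns per channel) are triggered when the first start fails to
converge or lands on a bound; ties prefer the smaller bound lifetime.
Lifetimes are reported ordered (`tau1 <= tau2`), results carry convergence
and at-bound flags, and fits refuse decays under 500 photons (2000 for the
global fit) rather than returning garbage.

Goodness of fit is reported as reduced Pearson chi-square computed over
bins with expected counts of at least 5 (the usual validity condition);
on correctly specified Poisson simulations at 1e5 photons its median is
within a few percent of 1.

## What the simulator emulates — and what it does not

The synthetic-data generator exists so that every stage is testable without
microscope data, at the parameter values the method was characterized at:

* **Emission spectra** are log-normal bands (standard fluorescence band
  phenomenology) peaking at 475 nm (free NAD(P)H), 450 nm (bound) and
  535 nm (flavins, truncated to zero below 490 nm). A synthetic reference
  CSV with these shapes ships with the package and is labelled synthetic;
  it stands in for solution-phase measurements.
* **Treatment groups** reproduce the published median parameters: control
  (free/bound ratio 2.7, tau_bound 2.5 ns, flavin contribution 0.12,
  tau_flavin 1.48 ns), rotenone (3.3, 2.1, 0.076, 1.85) and 3BP
  (2.65, 2.35, 0.115, 1.72), with modest red shifts of the flavin peak for
  the inhibitor groups (543 / 540 nm vs 535 nm; the magnitude of the
  published shift is not tabulated, so these are our choice). Per-cell
  parameters get lognormal jitter with 10% CV so that boxplots are
  non-degenerate; cells are non-overlapping ellipses on a jittered grid.
* **Spheroids** are disks of packed cells whose ground truth varies
  linearly with distance from the border over 0-80 um: ratio 5.3 -> 4.0,
  flavin contribution 0.125 -> 0.16, and tau_bound following the NAD(P)H
  mean-lifetime gradient 0.84 -> 0.86 ns implied by those ratios
  (tau_bound = tau_m (ratio + 1) - 0.37 ratio, i.e. 3.33 -> 2.82 ns).
  Depths beyond 80 um hold the 80 um values. The default spheroid radius
  (85 um at 2 um pixels) keeps cube simulation affordable while covering
  the full depth range; default cell brightness gives a few 1e4 photons
  per cell-integrated decay.
* **Noise** is exact per-bin Poisson sampling of the forward model,
  bit-reproducible per seed.

Not emulated: optical blur (PSF), depth-dependent scattering and
attenuation in spheroids, detector afterpulsing or pile-up, per-channel
IRF differences, and real segmentation errors (masks are ground truth).
Passing round trips therefore demonstrate that the estimator inverts its
own forward model at realistic photon budgets — a necessary condition —
not that it is robust to every instrumental imperfection of real cubes.

## Pixel and cell pipelines

Spatial binning sums counts over a (2b+1) x (2b+1) sliding window (b = 5,
an 11 x 11 window, mirrors acquisition practice); windows are clipped at
image edges rather than padded, so no photons are fabricated. Cell-level
analysis sums the histograms of all pixels of a mask label and fits the
sum — identical to fitting the integrated cell signal. Per-pixel parameter
maps run the same global model per (binned) pixel; unfitted pixels are NA,
never zero. The per-pixel intensity-weighted mean emission wavelength
`lambda_avg = sum(lambda_i I_i)/sum(I_i)` uses time-summed channel
intensities. Spheroid cells get a distance-to-border from the Euclidean
distance transform of the spheroid mask evaluated at the cell centroid
(the centroid is what segmentation pipelines export; the choice matters
little at cell sizes of a few pixels).

Group statistics use medians and interquartile ranges with two-sided
Mann-Whitney U tests against a reference group — the natural companions of
median/IQR reporting — with raw p-values by default (Holm correction by
flag), and Pearson correlation by default (Spearman by flag).

## Problem sizes used in the shipped checks

The test suite inverts noiseless decays exactly; runs 20-replicate Poisson
recoveries at 5e5 photons per cell-integrated decay (medians: tau_bound
within 5%, ratio within 10%, flavin contribution within 15%); separates
control from rotenone with 200 simulated cells per group at p < 1e-4;
round-trips a full spheroid cube (about 190 cells); and calibrates the
type-I error of the group test on 500 null replicates. These sizes were
chosen to give stable medians at interactive runtimes on one CPU.

## Known limitations

FAD is not distinguished from FMN, nor NADH from NADPH; the flavin pool is
one exponential with one spectrum per decay set. The Gaussian IRF is an
approximation (a 220 ps FWHM Gaussian has 93.4 ps RMS, slightly below the
~96 ps RMS quoted for real multi-anode PMTs, so real IRFs are mildly
non-Gaussian). Vendor binary formats (.sdt) are not parsed; cubes enter
through the package's text container or through code.
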