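---
title: "Quantifying calcium binding to lipid bilayers: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium binding to lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidion)
```

## What this package computes

Divalent calcium binds phospholipid membranes at several chemically distinct
sites — the phosphate group of all phospholipids, the *sn*-2 ester carbonyl
oxygens, and, in anionic membranes, the carboxylate of phosphatidylserine
(PS). Binding compresses the bilayer laterally, thickens it, reorients
headgroups, and displaces first-shell water. `lipidion` implements the
complete desk-side analysis chain for this problem:

1. **Charge scaling (ECC)** — the electronic-continuum correction for ionic
   force fields, plus the composition arithmetic (neutralization counts,
   nominal concentrations) needed to set up simulated systems.
2. **Bilayer structure** — area per lipid (APL) with block-averaged errors,
   number-density profiles along the membrane normal, phosphate-peak
   bilayer thickness, and P–N headgroup angle distributions.
3. **Ion binding** — radial distribution functions, first-shell coordination
   numbers in both directions (ions per lipid group; groups per adsorbed
   ion), the contact-based lipids-per-adsorbed-ion ratio, lipid hydration
   numbers, and bound-interval residence times.
4. **TDFS spectroscopy** — time-dependent fluorescence shift analysis:
   iterative-reconvolution decay fitting, time-resolved emission spectrum
   (TRES) reconstruction, log-normal peak fitting, the total shift
   Δν = ν(0) − ν(∞), and the integrated relaxation time
   τ = ∫₀^∞ C(t) dt with C(t) = (ν(t) − ν(∞))/Δν. A Langmuir–Freundlich
   isotherm fitter covers zeta-potential titrations.
5. **Synthetic generators with ground truth** for both the membrane and the
   TCSPC stages, so that every estimator above can be validated against
   known expectations.

## The electronic-continuum correction

Nonpolarizable force fields overestimate ion–lipid binding because they omit
electronic polarization. The ECC includes it in a mean-field way by scaling
ionic charges by `f = 1/sqrt(eps_el)`, with `eps_el` the electronic
(optical-frequency, n²) part of the solvent dielectric constant — about 1.78
for water, giving the conventional factor 0.75 and scaled charges +1.5 e
(Ca²⁺) and −0.75 e (Cl⁻):

```{r ecc}
f <- scaling_factor(1.78)
round(f, 2)
scale_charges(c(ca = +2, cl = -1), f = 0.75)
```

Lipid partial charges are deliberately *not* scaled by this package: scaling
is a property of a bare ion in the dielectric, and the arithmetic of the
reference systems only closes under that convention — 16 cations of +1.5 e
exactly neutralize 24 anionic lipids of −1 e:

```{r neutral}
composition(n_pc = 104, n_ps = 24, n_water = 4300)
```

Nominal salt concentrations are quoted per water molecule,
`c = (n_pairs/n_water) * 55.51 mol/L`. The 55.51 reference (pure-water
molarity) is a documented convention and is configurable.

## The synthetic membrane and what it does (not) emulate

There is no public trajectory archive for the reference systems, so the
generator is a first-class module that stands in for the MD engine. It
builds exactly the statistical structure the analyses consume, with known
expectations:

* two leaflets of `lipids_per_leaflet` (default 64) lipids on a jittered
  square lattice whose lateral box follows the APL schedule
  (`Lx = Ly = sqrt(N * APL)`), optionally with 12 PS per leaflet (the 4:1
  PC:PS mixture);
* per lipid: one phosphate P at |z| = 2.0 nm, choline N placed `d_pn`
  (0.45 nm) from P along a direction drawn from a truncated-normal tilt
  distribution about the outward leaflet normal (or isotropically, density
  ∝ sin Φ), two carbonyl O at 1.45/1.5 nm, and two carboxylate O at 2.1 nm
  for PS. The z-levels are configuration, chosen to reproduce the
  characteristic ordering carbonyl < phosphate < choline/carboxylate, not
  physical claims;
* Ca²⁺ ions follow a two-state bound/free Markov chain per ion with
  stationary bound probability `p_phos + p_carb + p_coo` and mean bound
  residence `mean_residence`; a bound ion sits on a shell of radius
  `bound_distance` (0.28 nm) around its site atom, a free ion is uniform in
  the water slab. The slab starts 0.5 nm above the outermost headgroup plane
  so that free species can never satisfy the 0.42 nm contact criterion;
* Cl⁻ and slab waters are uniform in the slab; optional first-shell waters
  are placed at fixed radii around carbonyl O and phosphate P;
* everything receives isotropic Gaussian jitter `noise_sd` (default
  0.02 nm).

The default `noise_sd` is small compared with real thermal disorder: in this
model the *mean* geometry (shell radii, plane separations) carries the
physics, and the jitter only prevents degenerate, exactly-coincident
distances. What the generator does **not** emulate: forces and energies,
acyl chains, membrane undulations, ion bridging of several lipids at once
(each bound ion is attached to one site), lipid flip-flop, and water
structure. Passing recovery tests therefore demonstrate correctness of the
*estimators* on data with known truth — not realism of the data.

### Ground truth with geometric cross terms

`expected_statistics()` returns the exact expectations for the generated
data. Two technical points matter:

* **Cross terms.** An ion bound 0.28 nm from a phosphate can also fall
  within the 0.33 nm coordination cutoff of the *same lipid's* carbonyl
  (the planes are only 0.5 nm apart), and a phosphate-shell water can enter
  the carbonyl hydration shell. These probabilities are computed by
  vectorized Monte Carlo over the exact single-lipid local geometry
  (2×10⁵ draws under a fixed internal RNG substream, standard error
  reported), so recovery tests are unbiased. Cross-*lipid* terms are
  neglected: the maximal reach (0.28 + 0.33 nm) is below the lattice
  spacing at realistic APL.
* **Autocorrelation-aware errors.** Time averages over the bound/free chain
  are correlated across frames; the standard error of a bound fraction uses
  the effective sample size `n (1 − ρ)/(1 + ρ)` with
  `ρ = exp(−dt (k_on + k_off))`.

## Structural estimators: numerical choices

* **Recentring.** Every frame is recentred on the (mass-weighted) lipid
  center of mass before z-binning; this removes box drift and is standard
  for membrane profiles. Leaflets are assigned by the sign of the recentred
  phosphate z; flip-flop is not modeled.
* **Bin grid.** Density-profile bins are centred on multiples of the bin
  width (default 0.1 nm), with one bin centred on the bilayer midplane, so
  that symmetrization maps bins onto bins exactly and the profile integral
  times the box area reproduces the atom count to machine precision.
* **Thickness.** Each leaflet's phosphate peak is refined by three-point
  parabolic interpolation around the maximal bin; the quoted uncertainty is
  one bin width (the peak-position estimation inaccuracy).
* **P–N angles** are measured against the *outward* leaflet normal, so a
  mean below 90° means headgroups point toward the water phase; cation
  adsorption raises headgroups (lowers the angle).
* **Block averaging** splits the series into 5 contiguous equal blocks by
  default (remainder dropped from the front); the SE is the standard
  deviation of block means over √(blocks), which exceeds the naive SE for
  positively autocorrelated series.

## Binding estimators: numerical choices

* Pair distances use the orthorhombic minimum-image convention (round-based)
  and are valid for separations below half the box in each dimension; the
  test suite checks every counting operation against an independent
  brute-force enumeration of the {−1, 0, 1} periodic images.
* Groups are represented by the atoms named in the density analyses:
  phosphate by its P atom, carbonyl by the two ester oxygens, carboxylate by
  its two oxygens — multi-atom groups count an ion (or water) once per
  group.
* The RDF reference density is the mean partner density over the whole box.
  Bilayer systems are inhomogeneous, so `g(r)` plateaus are not meaningful
  far from the interface; first-shell cutoffs may instead be supplied
  directly (the summary-table workflow uses the conventional 0.42 nm
  contact, 2.4 Å carbonyl and 3.35 Å phosphate hydration cutoffs).
* "Adsorbed" means: at least one binding-group atom within the 0.42 nm
  all-contacts cutoff in that frame. This is the only cutoff attached to
  ion–lipid contacts in the source data; an explicit z-threshold definition
  is a documented alternative the package does not implement.
* Coordination-number uncertainties are reported as SD over samples; block
  SEs can be formed by applying `block_average()` to the per-frame means.
* **Residence times.** Bound intervals are maximal runs of bound frames with
  unbound gaps up to `gap_tolerance` bridged. Intervals touching either
  trajectory end are flagged censored; `mean_ns` averages what was observed,
  while `mean_mle_ns` (total bound time over completed intervals — the
  censored-exponential MLE) is the unbiased choice for mean-residence
  estimation and is what the recovery tests use.

## TDFS: model and numerical choices

Decays are fitted as `counts ~ IRF ⊛ Σ αᵢ exp(−t/τᵢ)` under Neyman weights
`1/max(counts, 1)` (the floor avoids division by zero in empty channels).
The discrete convolution is evaluated by the exact channelwise recursion
`c_k = exp(−dt/τ) c_{k−1} + irf_k`. Given lifetimes, amplitudes solve a
weighted linear least-squares problem — negative amplitudes are allowed
because decays on the red edge of a relaxing band rise before decaying.
Lifetimes are optimized by Nelder–Mead from a deterministic multi-start
grid, so fits are reproducible. The default component selection is a
guarded cascade: a three-component fit, refined by a four-component attempt
that is accepted only when it reduces the weighted residual by at least 20%
while keeping well-separated lifetimes (ratio ≥ 1.15), bounded amplitudes
(Σ|αᵢ| ≤ 30 × peak counts), and a non-negative model over the window. An
unguarded fourth component tends to produce near-degenerate lifetime pairs
with large cancelling amplitudes on drifting-band data; the guards restrict
it to the regime where it captures real shape.

TRES reconstruction uses
`S(λ, t) = f_λ(t) · SS_λ / ∫₀^∞ f_λ(t) dt` with the integral evaluated
analytically (Σ αᵢτᵢ), so each wavelength's time-integrated intensity equals
its steady-state intensity exactly. Wavelengths convert to wavenumbers with
the λ² Jacobian applied to intensities. Peak positions ν(t) come from
Siano–Metzler log-normal fits; the symmetric limit is handled by a separate
pure-Gaussian candidate because the asymmetry gradient vanishes at b = 0.

ν(0) is a probe constant (Laurdan 23800 cm⁻¹, Dtmac 22750 cm⁻¹), not a fit
parameter. ν(∞) is the mean of ν(t) over the final 10% of the time window
(configurable), with a warning if that plateau still drifts. The integrated
relaxation time fits C(t) with up to three exponentials constrained to
ΣAᵢ = 1 with Aᵢ ≥ 0 (a relaxation correlation function is completely
monotone, so it is a non-negative mixture of decaying exponentials) and
lifetimes capped at three times the observation window (slower components
are indistinguishable from an offset), then integrates analytically
(τ = ΣAᵢτᵢ). The fit is restricted to the region where C(t) > 3% of its
initial amplitude, because below that the reconstructed peak positions carry
reconstruction error larger than the remaining signal, and the analytic tail
integral of the fitted exponentials is the better extrapolation. A trapezoid
fallback covers fit failures.

The synthetic TCSPC generator builds a drifting log-normal band
`S(ν, t) = LN(ν; ν(t)) E(t)` with `ν(t) = ν(∞) + Δν C(t)`, slices it at the
detection wavelengths (400–550 nm in 10 nm steps, as collected with a
>399 nm emission cutoff), converts to the wavelength domain, convolves with
a Gaussian IRF, scales each decay to the target peak count and applies
Poisson noise. Its defaults emulate a Laurdan-like measurement: Δν =
2000 cm⁻¹, single-exponential C(t) with τ = 1.5 ns, 4 ns fluorescence
lifetime, 3000 cm⁻¹ band FWHM, asymmetry 0.25, 15 ns window over 1024
channels, 0.1 ns IRF FWHM, 10⁴ peak counts. Because the sliced decays are
*not* exactly multi-exponential, the pipeline carries a small systematic
reconstruction error (a few tens of cm⁻¹ in ν(t)); the validation suite
verifies that Δν and τ are nevertheless recovered within the intrinsic
uncertainties of the method, 50 cm⁻¹ and 0.05 ns, averaged over 20 seeds at
10⁴ peak counts.

## Orchestration

`run_pipeline()` takes a validated config (programmatic list or YAML),
executes the requested stages (prep → simulate/load → structure → binding →
tdfs) on the trimmed analysis window, funnels every warning into the report,
and stamps it with a config hash and the seed, so identical config + seed
give identical reports. `make_table1()` condenses one or more reports into
the conventional summary layout (rows: bilayer × concentration; columns:
lipids per Ca²⁺, per-group coordination of adsorbed ions, hydration
numbers), rendering the carboxylate column as an em-dash for PS-free
systems. For R users the functions themselves are the interface; no shell
entry point is shipped.

## Problem sizes used by the validation suite

The test suite and the reproduction script run entirely from synthetic data
generated at run time. Typical sizes: bilayers of 8–64 lipids per leaflet
over 2–790 frames (the isotropic-angle check draws >10⁵ P–N samples);
counting oracles on 50 random frames of 150–500 atoms; 100 random
trajectories for mass conservation; 20 seeds × three occupancy levels for
binding recovery; 20 seeds of 16-wavelength, 512-channel TCSPC data for the
TDFS recovery. These sizes give the statistical power the 3-SE bands need
while keeping a full run in minutes on one core.

## Known limitations

* Orthorhombic boxes only; triclinic input is rejected.
* The generator's bound ions attach to a single lipid site, so
  multi-lipid bridging statistics (coordination numbers per adsorbed ion
  above 1 per group type) can only be exercised via hand-constructed
  configurations, not via the chain model.
* The RDF normalization assumes a homogeneous reference density; use
  explicit cutoffs for interfacial shells.
* The TDFS pipeline's multi-exponential representation of drifting-band
  decays is an approximation; its systematic error is validated to stay
  within the method's intrinsic uncertainty under the default synthetic
  conditions, and grows for bands that relax much faster than the IRF or
  drift far outside the detection window.
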