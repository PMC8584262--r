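---
title: "Membrane mechanics across three observation windows: models, estimators, and design choices"
author: "membramech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mechanics: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membramech)
```

# Scope

`membramech` characterizes lipid membranes through three complementary
observation windows:

1. **Coordinate frames** of a simulated bilayer: area per lipid (APL),
   membrane thickness (MT), leaflet interdigitation, lateral diffusion,
   real-space-fluctuation (RSF) bending and tilt moduli, thickness-fluctuation
   area compressibility, and hydrophobic defect probing.
2. **Langmuir monolayer isotherms**: APL at a reference surface pressure,
   the surface-elasticity (compressibility) modulus, and the excess free
   energy of mixing.
3. **Flicker-noise spectroscopy** of giant unilamellar vesicles (GUVs):
   bending rigidity from the thermal fluctuations of the equatorial contour.

Every estimator is paired with a deterministic synthetic generator that
produces inputs with known ground truth, so the whole pipeline is testable
without trajectories or microscope recordings.

# Coordinate-frame observables

## Data model and conventions

Coordinates are in angstrom, times in nanoseconds, temperatures in kelvin;
every public result carries an explicit unit tag because the downstream
conventions mix nm, Å², µm²/s, mN/m and J. Boxes are orthorhombic and all
distances use the minimum-image convention. A lipid's *head point* is the
midpoint of its P and C2 atoms (for sterols, the C3/C2 surrogates declared in
the topology); its *tail point* is the midpoint of the terminal chain
carbons; the *director* points from tail to head.

Leaflets are assigned once, from the sign of the head-point z against the
mean head z of the first analyzed frame, and held fixed; a lipid whose head
later crosses the midplane is flagged but never reassigned, since flip-flop
is outside the model. This is our convention — the assignment rule is not
part of the published protocols we implement.

## Area per lipid

Head points are projected to the xy plane and tessellated with a periodic
Voronoi construction: the seeds are tiled over the 3×3 block of box images
and each primary cell is cut from a starting square by perpendicular-bisector
half-planes, nearest seed first, stopping when the next bisector lies beyond
the farthest remaining vertex. This is exact for periodic point sets, and the
areas tile the box: the suite asserts `sum(areas) == Lx*Ly` to a relative
1e-6 on every frame. No installed package offers periodic tessellation with
areas and adjacency, which is why the construction is implemented here; the
same adjacency graph defines the neighbor pairs used for splay.

The system APL is the mean of a Gaussian fitted (least squares) to the
Freedman–Diaconis histogram of all per-lipid areas; species values are
arithmetic means. If the Gaussian fit cannot converge (degenerate or tiny
histograms) the sample mean ± sd is reported with a warning.

## Thickness, interdigitation, diffusion

MT is the difference of mean reference-atom heights between leaflets
(reported in nm for tags P, C1, C2). Interdigitation is the width of the
mass-overlap region, `w = ∫ 4 ρ_u ρ_l / (ρ_u + ρ_l)² dz`, on 100 z-bins by
default — the overlap functional equals the support length for identical
rectangular profiles and vanishes for disjoint ones. Lateral diffusion
unwraps the head-point tracks, subtracts each leaflet's center-of-mass
motion (the published analyses do not state which COM is removed; per-leaflet
is our choice), averages the 2D MSD over lipids and all time origins, and
takes `D = slope/4` on the 10–50% lag window — the window is standard
practice, the source protocols being silent on it.

# Real-space-fluctuation moduli

Tilt θ is the angle between the director and the leaflet normal (+z upper,
−z lower). Splay for a Voronoi-adjacent pair is the projected
finite-difference divergence

\[ S = \frac{(\hat d_j - \hat d_i)_{xy} \cdot \hat e_{ij}}{|r_{ij}|}, \]

accepted only for *weakly correlated* pairs: head separation within 5–12 Å
and director angle below 60°. The published method requires weak correlation
without printing a criterion; these cutoffs keep nearest neighbors and
reject strongly aligned contacts, and rejected counts are logged so the
filter is auditable.

The moduli come from quadratic fits to histogram potentials of mean force
(PMFs), using only bins within 2 thermal units of the PMF minimum (at least
5 bins) so that only the harmonic regime enters:

* tilt: `PMF(θ) = −kBT log[p(θ)/sin θ]` (the solid-angle Jacobian removed,
  otherwise the small-angle form is not quadratic), fitted as `½ κ_t θ²`;
* splay: `PMF(S) = −kBT log p(S)` fitted as `½ χ S²` with `χ` in J·Å².

**Splay modulus convention.** With S in 1/Å the quadratic coefficient χ
carries units of energy×area. We normalize by the area per lipid to obtain
the monolayer bending modulus, `κ_m = χ / a₀`, and report the bilayer value
`κ = 2 κ_m`. This convention is dimensionally forced once S is a spatial
divergence, uses the `apl` argument explicitly, and at the reference bilayer
values (κ ≈ 27 kBT, a₀ = 60.7 Å²) predicts splay fluctuations of rms
≈ 0.35 nm⁻¹, the magnitude RSF studies observe. The bilayer-vs-monolayer
reading of published tables is itself ambiguous; we treat tabulated κ as
bilayer values, which places them at the literature scale of tens of kBT.

## Area compressibility from thickness fluctuations

The relative thickness deviation `x = (t₀ − t)/t₀` is histogrammed and

\[ \mathrm{PMF}(x) = -\frac{2 k_B T}{a_0} \log p(x) = K_A x^2 + C' \]

is fitted over the central bins; K_A converts from J/Å² to mN/m. For
Gaussian x this reduces to `K_A = kBT/(a₀ σ²)` exactly, which the tests
verify. The printed form of the underlying relation typesets the deviation
with an instantaneous-thickness denominator; we use the equilibrium
denominator, which is the small-fluctuation-equivalent form that makes the
generator's `t = t₀(1 − x)` exactly invertible. The method is reported as a
whole-membrane K_A (the per-leaflet reading is historical), and the result
carries that tag.

# Hydrophobic defects

The leaflet surface is rasterized at ~0.5 Å; atoms are processed from the
bilayer midplane outward and each cell takes the class (polar head vs acyl
tail) of the outermost atom whose projected van der Waals disc covers it,
with deterministic tie-breaks (larger radius, then lower atom index).
Uncovered cells are *empty*: they count in the denominator and block probes,
a conservative choice that avoids scoring vacuum as hydrophobic defect.
`F_exp` is the tail fraction of the map. The sphere probe of radius r marks
a cell a defect-candidate center when every cell within r (periodic
distance) is tail; the defect set is the union of the probe discs — a
morphological opening, implemented by FFT convolution and verified bit-exact
against a brute-force double loop. Defect fraction is non-increasing in
probe radius by construction.

# Isotherm analytics

Isotherms are two-column records (Å², mN/m), sorted by decreasing area with
duplicate areas averaged. APL is read at 33 mN/m by default — the
monolayer–bilayer equivalence pressure; the published usage mixes 30 and
33 mN/m, so the pressure is an argument. The compressibility
`Cs = −(1/A) dA/dπ` is computed together with its reciprocal modulus
`Cs⁻¹ = −A dπ/dA` (mN/m), which is the tabulated "surface elasticity"
convention; both are returned. For noisy records the derivative comes from a
Savitzky–Golay local-polynomial *derivative* filter on a uniform pressure
grid with an adaptive window (up to 41 points, about a seventh of the
record). A short fixed window leaves the pointwise derivative dominated by
noise — with 0.1 Å² area noise a 7-point window yields worst-case modulus
errors near 70%, while the adaptive derivative filter stays within ~4%.

The excess free energy of mixing is

\[ \Delta G^{ex}_m(\pi) = N_A\left[\int_{\pi_0}^{\pi} A_{mix}\,d\pi' -
   \sum_k X_k \int_{\pi_0}^{\pi} A_k\,d\pi'\right], \]

by trapezoidal quadrature on a shared grid, reported in J/mol (the unit is
always printed; published tables are ambiguous between J/mol and kJ/mol
scales, and we do not guess). π₀ defaults to the lift-off pressure (first
grid pressure above 0.5 mN/m) since the integral's lower limit is not
defined in the source protocols. ΔG is identically zero for ideal mixtures,
linear in π for a constant area deviation, and additive over pressure
intervals — all asserted in the suite. The deviation is propagated linearly
as the sum of the components' APL deviations scaled by `N_A (π − π₀)`; the
published "sum of deviations" prescription is under-specified, so this
linear reading is our convention.

# Flicker-noise spectroscopy

## Fluctuation model

A quasi-spherical vesicle's shape fluctuations follow the Helfrich
(Milner–Safran) spectrum: spherical-harmonic amplitudes with

\[ \langle |u_{lm}|^2\rangle = \frac{k_B T}
   {\kappa\,(l-1)(l+2)\,[l(l+1)+\bar\sigma]}, \]

with reduced tension σ̄ as a nuisance parameter. The equatorial contour seen
in a microscope section mixes modes: the Fourier mode m of `(r − R)/R`
collects every degree l ≥ m with weight `w_lm = |Y_lm(π/2, 0)|²`
(`Σ_m w_lm = (2l+1)/4π`). The two published decompositions differ exactly
here:

* **average approach**: the time-mean angular autocorrelation
  `ξ(γ) = ⟨(r(φ+γ)−R)(r(φ)−R)⟩` is decomposed in Legendre polynomials,
  `ξ(γ)/R² = Σ_l σ_l² (2l+1)/(4π) P_l(cos γ)` by the addition theorem — so
  `B_l` yields the *per-degree* amplitude σ_l² directly and the fit model is
  the spectrum above;
* **statistical approach**: per frame, Fourier amplitudes are computed and
  each mode's squared-amplitude histogram is fitted with the equilibrium
  exponential law; the fit model is then the mode-mixed sum
  `⟨|c_m|²⟩ = Σ_{l≥m} w_lm σ_l²`.

Using the per-degree model on Fourier amplitudes would bias κ; the suite
checks that the two approaches agree within a few percent on equilibrium
synthetic vesicles. The Legendre coefficients are integrated by
Gauss–Legendre quadrature after evaluating ξ from its Fourier cosine
series — ξ(acos x) is a Chebyshev series, so the quadrature is exact at the
node counts used; a plain trapezoid on the angular grid loses the high
degrees.

The histogram estimator fits the exponential law by Poisson regression of
bin counts on bin centers, which remains unbiased with sparse bins; below 50
frames (or for degenerate histograms) it falls back to the raw mean with a
warning. The exact histogram functional behind the published statistical
approach lives in its methodological references, not the text; the
exponential law is the equilibrium distribution of squared Gaussian
amplitudes and is our reading.

Modes 0–2 are excluded by default (size, translation and tension dominate
them) and the default fit range is modes 3–20; higher modes are left out
because pixel noise and finite video integration time damp them. No
integration-time correction is applied — the affected modes are excluded by
the mode range instead, a documented limitation.

## Contour extraction

The rim is the brightest radial feature (fluorescent GUV sections), located
along each of n rays by the radial intensity maximum with three-point
parabolic subpixel refinement. The center is refined iteratively by a
least-squares circle fit through the detected rim points — robust when part
of the rim leaves the search range, where a plain rim centroid diverges.
Rays without a detectable peak are missing; frames with more than 10%
missing rays are dropped and logged.

# Synthetic generators

The generators' defaults are the reference study conditions: a bilayer of
648 minimal three-atom lipids (324 per leaflet) at APL 60.7 Å², P–P
thickness 3.78 nm, D 7.7 µm²/s and 303.15 K; RSF samples at κ = 1.12e-19 J
and κ_t = 2.86e-20 J; thickness series at K_A = 235 mN/m; vesicle contours
at κ = 1.9e-19 J, R = 5 µm and 295.15 K (the vesicle experiments run at
22 °C, the simulations at 30 °C — the two temperatures are deliberately
separate defaults). Every generator is bit-reproducible under a fixed seed
and restores the caller's RNG state.

The lattice membrane is a jittered hexagonal lattice whose box realizes the
requested APL exactly; lipids are rigid three-atom rods (P, C2, terminal
carbon) executing independent 2D random walks with per-frame z jitter.
It emulates the *statistics* the estimators consume — it has no inter-lipid
forces, no undulations, no protrusions, and its frames are temporally
uncorrelated where equilibrium sampling suffices (an AR(1) option exists for
stress testing). Passing recovery tests therefore validates the estimators
under their own assumptions; they do not certify behavior on force-field
artifacts such as correlated undulation modes.

The vesicle generator draws the equatorial Fourier coefficients directly as
complex Gaussians with variance `V_m = Σ_{l≥m} w_lm σ_l²` — exactly the
distribution of the equatorial section of independently drawn
spherical-harmonic amplitudes truncated at `l_max` (everything is Gaussian
and independent), at a fraction of the cost. Optional rendering draws a
Gaussian-profile rim on a dark background with Poisson-like noise for
end-to-end extraction tests.

# Numerical choices and degenerate inputs

* PMF fits: Freedman–Diaconis-scaled histograms, fit window within 2
  thermal units of the minimum, ≥5 bins, convexity required (else an error
  with the diagnostic curve).
* Voronoi: duplicate seeds raise an error; the APL driver jitters once
  (1e-4 Å) and retries before failing.
* Constant thickness series, all-one-leaflet inputs, empty stage lists, and
  extrapolation requests raise informative errors rather than returning
  numbers.
* Problem sizes in the suite — e.g. 8–60 frames for the 648-lipid membrane,
  1e4–1e5 fluctuation samples, 10–20 seeds per recovery median, 1200-frame
  contour series — were chosen so each estimator operates in the regime
  where its own statistical error is a few percent.

# Known limitations

* Orthorhombic boxes only; no triclinic support.
* The defect probe works on the projected 2D map, not the 3D void
  structure.
* The flicker fit reports tension only as a nuisance parameter; no
  integration-time correction.
* The lattice generator's diffusion subtracts leaflet COM motion, which
  removes 1/N of the per-lipid signal (≈0.5% at 200 lipids) — visible only
  below the tolerance of the recovery tests.
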