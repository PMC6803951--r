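---
title: "Models and methods: SWCNT film optics, defects and network packing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: SWCNT film optics, defects and network packing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swcntkit)
```

## What the package models

Laser nanowelding of single-walled carbon nanotube (SWCNT) scaffolds is
driven by *non-uniform* absorption of laser energy: point defects and open
tube ends absorb more strongly and shed heat poorly, so they form hot spots
where covalent inter-tube bonds form. `swcntkit` implements the desk-scale,
reproducible part of that story:

1. **Geometry** — pristine, defective and finite SWCNT models
   (`build_periodic_tube()`, `apply_defect()`, `build_finite_tube()`);
2. **Electronic structure** — a pi-orbital tight-binding (TB) model, band
   structures and chemical potentials (`band_structure()`,
   `chemical_potential()`);
3. **Optical response** — the Kubo-Greenwood complex sheet conductivity
   (`kubo_conductivity()`);
4. **Film optics** — normal-incidence reflection, transmission and
   absorption of a thin film, `A = 1 - |R|^2 - |T|^2` with
   `R = -sigma Z0 / (2 + sigma Z0)`, `T = 2 / (2 + sigma Z0)`
   (`film_absorption()`), plus spectrum analytics;
5. **Network packing** — random SWCNT networks in periodic boxes with
   contact detection, defect seeding and hot-spot temperature maps
   (`generate_network()` and friends);
6. **Coarse-grained bookkeeping** — bead-count manifests for the
   protein-polymer matrix and membrane systems (`cg_preset()`).

Molecular dynamics of the welding event itself (reactive force fields) and
of matrix formation / membrane piercing (MARTINI-class engines) are
deliberately out of scope: the package produces the geometric and optical
inputs those external engines consume.

## The tight-binding model, and what it can and cannot reproduce

The reference work behind this problem class uses a self-consistent
charge-transfer (SCC-DFTB) Hamiltonian. `swcntkit` instead uses an
**orthogonal nearest-neighbour pi-orbital model**: one p_z orbital per
carbon, hopping `gamma0 = 2.7 eV` (the standard graphene value), onsite
energy 0, bond cutoff 0.17 nm (midway between the first- and
second-neighbour shells at 0.142 and 0.246 nm). The choice is deliberate:

* it is dependency-free and fast enough for supercells of thousands of
  atoms on one CPU;
* it reproduces the features that drive the qualitative conclusions — the
  metal/semiconductor dichotomy (`(n - m) mod 3`), van Hove singularities
  and the associated absorption peaks, gap transparency of semiconducting
  tubes, Drude response of metallic ones, and new defect-induced states;
* it does **not** reproduce DFTB-grade absolute peak positions or
  magnitudes (e.g. peak absorptions of tens of percent at specific
  wavelengths). Quantitative spectra from this package must be read as
  model-level, property-faithful results, and the test suite checks
  properties, not DFTB numbers.

Two further simplifications are documented rather than hidden:

* **No geometry optimization.** Tubes are ideal rolled-graphene cylinders;
  vacancies are left unreconstructed and the Stone-Wales rotation is purely
  geometric (90 degrees about the bond midpoint in the local tangent plane,
  then a global rebond). Reproducible topology matters more to a TB model
  than sub-picometre coordinates. An optional harmonic spring relaxation
  (`relax_bonds()`) exists but is off by default everywhere.
* **No depolarization correction.** Perpendicular-polarization response
  uses bare matrix elements; transverse absorption is therefore known to be
  overestimated. Axial polarization (the default) is unaffected.

## The Kubo-Greenwood implementation

`kubo_conductivity()` evaluates, term by term,

    sigma(Omega) = 2 e^2 hbar / (i m_e^2 Scell Nk)
                   * sum_k sum_{n,m} P_nm P_mn / (E_n - E_m + Omega + i eta)
                   * (f(E_n) - f(E_m)) / (E_n - E_m)

with the spin degeneracy as the explicit factor 2 (never folded into
occupations). Numerical choices:

* **Momentum matrix.** `P -> (m_e/hbar) dH/dk`, evaluated analytically from
  the Bloch phases for the axial direction of periodic tubes; the
  commutator form `(m_e / i hbar)(r_i - r_j) H_ij` serves transverse
  directions and finite tubes. The two routes agree for axial periodic
  transport (a tested equivalence).
* **Intraband / degenerate limit.** The printed formula is 0/0 at
  `E_n = E_m`; pairs closer than 1e-9 eV use the analytic limit
  `df/dE`, which yields the standard eta-broadened Drude term. Because the
  conductivity sums `|P|^2` over degenerate subspaces (a unitary-invariant
  quantity, asserted by a rotation test), eigenvector tie-breaking is
  irrelevant.
* **Broadening.** `eta = 0.05 eV` by default (configurable); the response
  is finite for every `Omega > 0` whenever `eta > 0`, and `eta <= 0` is
  rejected. A Lorentzian of width eta has tails: at `4 eta` below a
  resonance the response is still ~1/17 of the peak, which bounds how
  "transparent" a semiconducting tube can look below its gap.
* **Electronic temperature.** Default 300 K; the chemical potential is
  solved at half filling by bisection to 1e-9 eV (electron-count residual
  below 1e-8 relative, tested).
* **k-convergence.** `tube_conductivity()` doubles the k-grid until the
  spectrum changes by less than 1% of its peak and records the count used.

## Sheet-conductivity normalization (Scell)

The film equations need a **2D sheet conductivity**, so each tube's response
is divided by the film area it occupies. Two conventions are wired in,
matching the two film geometries, both with a 0.5 nm wall-to-wall gap:

* side-illuminated parallel tubes: `Scell = period x (diameter + 0.5 nm)`;
* end-illuminated open-ended tubes: hexagonal packing cross-section,
  `Scell = sqrt(3)/2 (diameter + 0.5 nm)^2`.

This makes `sigma Z0` dimensionless. The normalization is stated
prominently because "area per tube in a film" is genuinely a modelling
choice; any other convention rescales spectra by a constant.

The single-sheet (vacuum-sheet-vacuum) equations are used as printed; no
transfer-matrix stack. Their validity requires thickness << wavelength, and
`reflection_transmission()` warns when `thickness >= lambda_min / 10`.
Recommended grids: 10-3000 nm for periodic-tube films, 100-3000 nm for the
~40 nm end-illuminated film; internally the grids are uniform in photon
energy.

A useful analytic anchor survives every modelling choice: for a purely real
sheet conductivity, `A(x) = 4x/(2 + x)^2` with `x = sigma Z0`, so
single-pass absorption can never exceed **50%**, attained at
`sigma Z0 = 2` (`max_real_sheet_absorption()`).

## Defects and the ring census

`apply_defect()` implements single vacancies (SV, one atom removed, three
2-coordinated neighbours left), double vacancies (DV, two bonded atoms
removed), Stone-Wales rotations (SW, atom count preserved; ring census
gains exactly two pentagons and two heptagons) and ordered MIXED lists.
`ring_census()` counts chordless cycles up to length 7; it is meaningful
when the periodic cell is at least two periods long, since in a one-period
cell a defect can overlap its own periodic image and short winding cycles
exist. Random site selection is seeded and avoids earlier defects by at
least two bond lengths where possible; closer placements warn unless
overridden.

## The network generator as the study-condition generator

`generate_network()` *is* the synthetic-data generator of the scaffold
study, and its defaults are the study conditions: 258 tubes of (4,4)
chirality, lengths uniform in 5-20 nm (rounded down to whole periods), a
65 x 45 x 40 nm periodic box, and a 0.34 nm van der Waals exclusion gap.
Tubes are rigid straight cylinders (5-20 nm is far below typical
persistence lengths); placement is random sequential insertion with
minimum-image distances; determinism is guaranteed under the seed.

What the generator emulates: random orientation/position disorder, the
surface-to-surface contact statistics, and close contacts in the 0.2-0.4 nm
window where welding defects are seeded. What it does not emulate: tube
bending, bundling/alignment correlations from van der Waals attraction
(only the hard exclusion is modelled), polydisperse chirality mixtures, and
the welding dynamics itself. Consequently, passing tests say the geometry
and bookkeeping are right, not that a real buckypaper looks like this.

Two bookkeeping notes, flagged rather than tuned away:

* With lengths uniform in 5-20 nm the expected atom count in the default
  box is about 2.05e5 (density ~33 kg/m^3), with small seed-to-seed spread;
  published counts for this configuration (~1.75e5 atoms) imply a mean tube
  length nearer 10.7 nm. The generator keeps the stated uniform range and
  reports what it built; `network_density()` is the closed-form `N m_C / V`
  either way.
* A printed density of 60 kg/m^3 for that same configuration is ~2x what
  its own atom count and box volume imply (29.8 kg/m^3); the package
  reports the computed value.

Hot spots (`hot_spot_map()`) assign each defect-site and open-end rim atom
a temperature factor drawn uniformly from [1.16, 1.20] - defective regions
run 16-20% hotter than pristine regions - and 1.0 elsewhere; the factors
export to the PDB B-factor column for visualization.

## Coarse-grained manifests

`cg_preset()` records the compositions of the matrix and membrane systems
as exact integer bead counts (SWCNT + albumin + water: 245,797 grains;
SWCNT + collagen + water: 236,325; SWCNT + chitosan + water: 229,064;
DPPC membrane: 8,450 lipids x 12 beads = 101,400), thermostat 310 K. The
12-bead DPPC topology (2 head + 2 glycerol + 2 x 4 tails) is the standard
coarse-grained mapping and exactly reconciles the membrane's lipid count
with its bead total. No coordinates and no dynamics: manifests are the
hand-off record to external CG engines, and reimplementing those engines
would be glue, not contribution.

## Reproducibility and problem sizes

Every stochastic stage (random defect sites, network packing, defect-kind
draws, hot-spot draws) takes an explicit seed, and the pipeline
(`run_pipeline()`) derives all stage seeds from one master seed; identical
configs produce identical summaries. The test suite validates the
zone-folding identity across all sixteen reference chiralities at 64
k-points (the largest, (23,6), has 2812 atoms per cell), runs the
brute-force Kubo oracle on 16-atom fixtures, and compares spatial-hash
contact detection against brute force on 50-tube networks - sizes chosen so
the full suite stays desk-scale while still exercising the largest
reference cells.

## Worked example

```{r example}
tube <- build_periodic_tube(swnt_chirality(13, 0))
bands <- band_structure(tube, tb_model(), nk = 48)
sigma <- kubo_conductivity(bands, kubo_config(seq(0.45, 12.4, by = 0.01)))
spectrum <- film_absorption(sigma, film_model("side"))
peaks <- find_absorption_maxima(spectrum)
bin_peaks(peaks)
wavelengths_at_level(spectrum, 0.05)

sw <- apply_defect(build_periodic_tube(swnt_chirality(13, 0), 2),
                   defect_spec("SW", rng_seed = 1))
ring_census(sw)[c("5", "7")]
```

## Known limitations

* No curvature corrections (sigma-pi rehybridization), so very small
  tubes' secondary gaps are absent; no excitons; no electron-phonon
  broadening beyond the constant eta.
* Perpendicular-polarization absorption lacks the depolarization
  correction and is overestimated.
* The ring census assumes cells long enough that no winding cycle is
  shorter than the largest counted ring.
* Network tubes are straight and monodisperse in chirality.
* Absolute absorption magnitudes are TB-model-level; only their structure
  (peak existence, gaps, trends under defects) should be compared across
  methods.
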