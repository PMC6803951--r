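# swcntkit

Atomistic models, tight-binding optics and network packing for single-walled
carbon nanotube (SWCNT) films — the in-silico toolbox behind laser
nanowelding of SWCNT scaffolds for tissue engineering.

## The problem

Branched SWCNT networks are welded into conductive 3D scaffolds by laser
irradiation. Welding happens at *hot spots*: point defects (single and
double vacancies, Stone–Wales rotations, mixed defects) and open tube ends
absorb laser energy more strongly than pristine regions and shed heat
poorly, running 16–20% hotter. Understanding which wavelengths a film of
given tubes absorbs — and how defects reshape that absorption — requires
three linked computations that this package provides to modellers of
nanotube optics and scaffold formation:

1. **Geometry.** Rolled-graphene SWCNT models indexed by chiral indices
   (n,m): diameter `d = a√(n²+m²+nm)/π` (a = 0.246 nm), translational cells
   of `4(n²+m²+nm)/gcd(2n+m, 2m+n)` atoms, point defects with verified ring
   topology, finite open-ended tubes, and random networks in periodic boxes.
2. **Electronic structure and optics.** A π-orbital tight-binding model
   (γ₀ = 2.7 eV) and the Kubo–Greenwood conductivity

   σ<sub>αβ</sub>(Ω) = (2e²ħ / i m²<sub>e</sub> S<sub>cell</sub>N<sub>k</sub>) Σ<sub>k</sub> Σ<sub>n,m</sub>
   [P<sub>nm</sub>P<sub>mn</sub> / (E<sub>n</sub>−E<sub>m</sub>+Ω+iη)] · [(f(E<sub>n</sub>)−f(E<sub>m</sub>)) / (E<sub>n</sub>−E<sub>m</sub>)]

3. **Film absorption.** For a thin current sheet in vacuum at normal
   incidence, `R = −σZ₀/(2+σZ₀)`, `T = 2/(2+σZ₀)` (Z₀ = 120π Ω) and
   `A = 1 − |R|² − |T|²`; maximum single-pass absorption is **50%**, at
   `σZ₀ = 2`.

Plus bead-count manifests for the coarse-grained protein–polymer matrix and
membrane systems that the welded scaffolds feed into.

## Worked example

```r
library(swcntkit)

ch <- swnt_chirality(11, 10)
print(ch)
#> SWCNT chirality (11,10): d = 1.4246 nm, T = 7.7519 nm, 1324 atoms/cell, semiconducting

census <- classify_chiralities()          # 16 commonly synthesized tubes
attr(census, "semiconductor_fraction")
#> [1] 0.6875                              # 11 of 16, ~69%

tube   <- build_periodic_tube(swnt_chirality(13, 0))
bands  <- band_structure(tube, tb_model(), nk = 48)
band_gap(tube)
#> [1] 0.7350993                           # eV; semiconducting

sigma    <- kubo_conductivity(bands, kubo_config(seq(0.45, 12.4, by = 0.01)))
spectrum <- film_absorption(sigma, film_model("side"))   # 0.5 nm tube gap
print(spectrum)
#> absorption spectrum: 1196 points, A_max = 0.1624 (16.2%) at 1512 nm

bin_peaks(find_absorption_maxima(spectrum))
#>   200-400   650-800  900-1150 1800-2400   outside
#>        12         2         1         0        14
```

The A_max printed above is the first interband (van Hove) peak of (13,0) in
this tight-binding model; a defective tube adds peaks on top of the
pristine ones (`apply_defect()`, then recompute). The network side:

```r
net <- generate_network(box = c(65, 45, 40), n_tubes = 258,
                        length_range = c(5, 20), chirality = c(4, 4), seed = 7)
net <- detect_contacts(net)               # surface gaps in [0.2, 0.4] nm
net <- seed_defects_at_contacts(net, seed = 8)
hs  <- hot_spot_map(net, seed = 9)        # rim/defect atoms 16-20% hotter
network_density(net)                      # closed-form N·m_C / V, kg/m^3
```

A thin CLI over the same functions lives in `inst/cli/swcntkit`
(`build-tube`, `bands`, `conduct`, `absorb`, `peaks`, `network`, `compose`,
`run`).

## Scope notes

The tight-binding model reproduces the metal/semiconductor dichotomy, van
Hove peak structure, gap transparency and defect-induced states, but not
the absolute peak positions/magnitudes of self-consistent (DFTB-grade)
Hamiltonians — see the methods vignette (`vignettes/swcnt-film-optics.Rmd`)
for the full list of modelling choices, conventions and limitations.
Reactive welding dynamics and coarse-grained membrane dynamics are out of
scope by design; the package produces the inputs those external engines
consume.
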