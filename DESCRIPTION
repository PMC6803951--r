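Package: swcntkit
Title: Atomistic Models, Tight-Binding Optics and Network Packing for
    Single-Walled Carbon Nanotube Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pristine and point-defective single-walled carbon
    nanotube (SWCNT) atomistic models (vacancies, Stone-Wales and mixed
    defects, finite open-ended tubes), computes their pi-orbital
    tight-binding band structure and Kubo-Greenwood complex optical
    conductivity, converts sheet conductivity to normal-incidence
    reflection, transmission and absorption spectra of thin SWCNT films,
    and analyses the spectra (absorption maxima, wavelength-range binning,
    level sets). Also packs random SWCNT networks into periodic boxes with
    contact detection, defect seeding at close contacts and hot-spot
    temperature maps, and keeps bead-count manifests for coarse-grained
    protein-polymer matrix and membrane systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
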