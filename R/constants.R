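# Physical constants and lattice parameters used throughout.
# Lengths in nm, energies in eV unless a function says otherwise.

.const <- list(
  a_nm      = 0.246,                 # graphene lattice constant
  acc_nm    = 0.246 / sqrt(3),       # C-C bond length, 0.142 nm
  cutoff_nm = 0.17,                  # bond cutoff: between 1st (0.142) and 2nd (0.246) shells
  kB_eV     = 8.617333262e-5,        # Boltzmann constant, eV/K
  hc_eVnm   = 1239.842,              # photon energy <-> wavelength conversion
  Z0_ohm    = 120 * pi,              # free-space wave impedance
  e2_hbar_S = 2.4341348073e-4,       # e^2/hbar in siemens
  mC_kg     = 12.011 * 1.66054e-27   # mass of one carbon atom
)
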