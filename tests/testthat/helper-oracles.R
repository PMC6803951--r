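# Independent oracles used across the test files.

# A 2-atom "dimer" fixture: two carbons 0.142 nm apart along z, no
# periodicity. The 2x2 tight-binding problem has closed-form eigenpairs.
make_dimer <- function() {
  st <- swcntkit:::new_swnt_structure(rbind(c(0, 0, 0), c(0, 0, 0.142)))
  swcntkit:::rebuild_bonds(st)
}

# Brute-force Kubo-Greenwood evaluation: plain loops over k-points and band
# pairs, finite-difference momentum matrix, and an independent SI unit chain
# (CODATA constants). Shares only the Hamiltonian builder and eigensolver
# with the production kernel; the derivative, occupation handling, pair sum
# and prefactor are all recomputed from scratch.
brute_kubo <- function(structure, model, omega_eV, eta, temperature, mu, scell_nm2, nk) {
  e_C <- 1.602176634e-19
  hbar <- 1.054571817e-34
  me <- 9.1093837015e-31
  kB_eV <- 8.617333262e-5
  Tlen <- structure$cell$period
  ks <- -pi / Tlen + (0:(nk - 1)) * 2 * pi / (Tlen * nk)
  fermi <- function(E) 1 / (1 + exp((E - mu) / (kB_eV * temperature)))
  dfermi <- function(E) {
    f <- fermi(E)
    -f * (1 - f) / (kB_eV * temperature)
  }
  sig <- rep(0 + 0i, length(omega_eV))
  h <- 3e-5          # central-difference step balancing truncation vs roundoff
  for (k in ks) {
    H <- swcntkit::tb_hamiltonian(structure, model, k)
    dH <- (swcntkit::tb_hamiltonian(structure, model, k + h) -
           swcntkit::tb_hamiltonian(structure, model, k - h)) / (2 * h)
    eg <- eigen(H, symmetric = TRUE)
    ord <- order(Re(eg$values))
    E <- Re(eg$values)[ord]
    C <- eg$vectors[, ord, drop = FALSE]
    v <- Conj(t(C)) %*% dH %*% C              # eV nm
    nb <- length(E)
    for (n in seq_len(nb)) for (m in seq_len(nb)) {
      P2 <- Mod(v[n, m])^2 * (me / hbar)^2 * (e_C * 1e-9)^2   # SI, (kg m/s)^2
      dE <- E[n] - E[m]
      occ <- if (abs(dE) < 1e-9) dfermi((E[n] + E[m]) / 2) else (fermi(E[n]) - fermi(E[m])) / dE
      occ <- occ / e_C                                         # 1/J
      for (io in seq_along(omega_eV)) {
        den <- (dE + omega_eV[io] + 1i * eta) * e_C            # J
        sig[io] <- sig[io] + P2 / den * occ
      }
    }
  }
  pref <- 2 * e_C^2 * hbar / (1i * me^2 * (scell_nm2 * 1e-18))
  pref * sig / nk
}
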