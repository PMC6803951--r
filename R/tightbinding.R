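#' Orthogonal pi-orbital tight-binding model
#'
#' One p_z orbital per carbon atom, onsite energy `onsite` and
#' nearest-neighbour hopping `-gamma0` for every bonded pair within
#' `cutoff`. Optionally the hopping scales with bond length as
#' `gamma0 * (0.142 / r)^scaling`, for strained geometries. This desk-scale
#' model captures the metal/semiconductor dichotomy and the van Hove
#' structure of nanotube optics; absolute peak positions differ from
#' self-consistent (DFTB-grade) Hamiltonians, as discussed in the methods
#' vignette.
#'
#' @param gamma0 nearest-neighbour hopping in eV (default 2.7, must be > 0).
#' @param onsite onsite energy in eV (default 0).
#' @param cutoff hopping/bond cutoff in nm; must stay below the
#'   second-neighbour distance (0.246 nm).
#' @param scaling distance-scaling exponent for the hopping (default 0).
#' @return An object of class `tb_model`.
#' @export
tb_model <- function(gamma0 = 2.7, onsite = 0, cutoff = .const$cutoff_nm,
                     scaling = 0) {
  if (gamma0 <= 0) stop("gamma0 must be positive", call. = FALSE)
  if (cutoff >= .const$a_nm) {
    stop("cutoff must stay below the second-neighbour distance (0.246 nm)", call. = FALSE)
  }
  structure(list(gamma0 = gamma0, onsite = onsite, cutoff = cutoff,
                 scaling = scaling), class = "tb_model")
}

#' @export
print.tb_model <- function(x, ...) {
  cat(sprintf("pi-orbital TB model: gamma0 = %.3f eV, onsite = %.3f eV, cutoff = %.3f nm\n",
              x$gamma0, x$onsite, x$cutoff))
  invisible(x)
}

# hopping per bond (positive magnitude), honouring optional distance scaling
.bond_hoppings <- function(structure, model) {
  if (model$scaling == 0) return(rep(model$gamma0, nrow(structure$bonds)))
  model$gamma0 * (.const$acc_nm / bond_lengths(structure))^model$scaling
}

# axial displacement (nm) per bond entry, periodic image included
.bond_dz <- function(structure) {
  z <- structure$positions[, 3]
  z[structure$bonds$j + 1L] + structure$bonds$sz - z[structure$bonds$i + 1L]
}

.accum_hermitian <- function(n, i0, j0, values) {
  H <- matrix(0 + 0i, n, n)
  lin <- j0 * n + i0 + 1L                       # 0-based (i,j) -> linear index
  re <- rowsum(Re(values), lin); im <- rowsum(Im(values), lin)
  at <- as.integer(rownames(re))
  H[at] <- complex(real = re[, 1], imaginary = im[, 1])
  H + Conj(t(H))
}

#' Tight-binding Bloch Hamiltonian at axial wavevector k
#'
#' Dimension = atom count. Bonded pairs contribute
#' `-gamma * exp(i k dz)` where `dz` is the axial displacement of the bond
#' including its periodic image shift, so the matrix is Hermitian by
#' construction. For non-periodic structures only `k = 0` is meaningful.
#'
#' @param structure an `swnt_structure` with bonds.
#' @param model a [tb_model()].
#' @param k axial wavevector in 1/nm.
#' @return Complex Hermitian matrix (eV).
#' @export
tb_hamiltonian <- function(structure, model = tb_model(), k = 0) {
  if (structure$cell$kind != "periodic_z" && k != 0) {
    stop("non-periodic structure: the Hamiltonian is only defined at k = 0", call. = FALSE)
  }
  n <- n_atoms(structure)
  b <- structure$bonds
  g <- .bond_hoppings(structure, model)
  dz <- .bond_dz(structure)
  H <- .accum_hermitian(n, b$i, b$j, -g * exp(1i * k * dz))
  diag(H) <- diag(H) + model$onsite
  H
}

# d/dk of the Bloch Hamiltonian (eV nm), analytic from the Bloch phases
.tb_dhamiltonian_dk <- function(structure, model, k) {
  n <- n_atoms(structure)
  b <- structure$bonds
  g <- .bond_hoppings(structure, model)
  dz <- .bond_dz(structure)
  .accum_hermitian(n, b$i, b$j, -g * (1i * dz) * exp(1i * k * dz))
}

#' Band structure over the 1D Brillouin zone
#'
#' Diagonalizes the Bloch Hamiltonian on a uniform `nk`-point grid over
#' `[-pi/T, pi/T)`. Finite (non-periodic) structures are handled Gamma-only
#' (`nk` is forced to 1). Eigenvalues are sorted ascending per k-point.
#'
#' @param structure an `swnt_structure` with bonds.
#' @param model a [tb_model()].
#' @param nk number of k-points (>= 1).
#' @param eigenvectors keep eigenvectors (needed for optical response)?
#' @param scell area per tube in nm^2, used to normalize sheet conductivity.
#'   Default: side-illuminated film convention, period x (diameter + 0.5 nm)
#'   for periodic tubes; hexagonal-packing cross-section per tube for finite
#'   tubes (see [film_model()]).
#' @return An object of class `swnt_bands`: list with `k` (1/nm), `energies`
#'   (nk x n matrix, eV), `vectors` (list of unitary matrices or NULL),
#'   `scell`, `structure`, `model`.
#' @export
band_structure <- function(structure, model = tb_model(), nk = 64L,
                           eigenvectors = TRUE, scell = NULL) {
  if (nk < 1 || nk != round(nk)) stop("nk must be a positive integer", call. = FALSE)
  periodic <- structure$cell$kind == "periodic_z"
  if (!periodic) nk <- 1L
  kgrid <- if (periodic) {
    Tlen <- structure$cell$period
    -pi / Tlen + (seq_len(nk) - 1L) * (2 * pi / Tlen) / nk
  } else 0
  n <- n_atoms(structure)
  energies <- matrix(NA_real_, nk, n)
  vectors <- if (eigenvectors) vector("list", nk) else NULL
  for (ik in seq_len(nk)) {
    H <- tb_hamiltonian(structure, model, kgrid[ik])
    e <- eigen(H, symmetric = TRUE, only.values = !eigenvectors)
    ord <- order(Re(e$values))
    energies[ik, ] <- Re(e$values)[ord]
    if (eigenvectors) vectors[[ik]] <- e$vectors[, ord, drop = FALSE]
  }
  if (is.null(scell)) {
    ch <- structure$provenance$chirality
    d <- if (!is.null(ch)) nt_diameter(ch) else 2 * nt_radius_of(structure)
    pitch <- d + 0.5
    scell <- if (periodic) structure$cell$period * pitch else sqrt(3) / 2 * pitch^2
  }
  structure(list(k = kgrid, energies = energies, vectors = vectors,
                 scell = scell, structure = structure, model = model),
            class = "swnt_bands")
}

#' @export
print.swnt_bands <- function(x, ...) {
  cat(sprintf("band structure: %d bands x %d k-points, E in [%.3f, %.3f] eV, Scell = %.3f nm^2\n",
              ncol(x$energies), nrow(x$energies), min(x$energies), max(x$energies), x$scell))
  invisible(x)
}

#' @export
plot.swnt_bands <- function(x, ...) {
  graphics::matplot(x$k, x$energies, type = "l", lty = 1, col = 1,
                    xlab = "k (1/nm)", ylab = "E (eV)", ...)
  invisible(x)
}

#' Export a band structure as CSV
#' @param bands an `swnt_bands` object.
#' @param path output CSV path (columns `k_invnm`, `E1`...).
#' @return `path`, invisibly.
#' @export
write_bands_csv <- function(bands, path) {
  df <- data.frame(k_invnm = bands$k, bands$energies)
  names(df) <- c("k_invnm", paste0("E", seq_len(ncol(bands$energies))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Analytic zone-folded band energies
#'
#' Reference spectrum of a pristine (n,m) tube from the graphene pi-band
#' dispersion `E = onsite +/- gamma0 |1 + exp(-i k.a1) + exp(-i k.a2)|`
#' restricted to the quantized circumferential lines. Independent of the
#' Hamiltonian machinery; used to validate direct diagonalization.
#'
#' @param chirality an [swnt_chirality()] or `c(n, m)`.
#' @param k axial wavevector in 1/nm.
#' @param model a [tb_model()] (only `gamma0` and `onsite` are used).
#' @return Sorted numeric vector of the `atoms_per_cell` band energies (eV).
#' @export
folded_band_energies <- function(chirality, k, model = tb_model()) {
  ch <- as_chirality(chirality)
  n <- ch$n; m <- ch$m
  a <- .const$a_nm
  a1 <- a * c(sqrt(3) / 2, 1 / 2)
  a2 <- a * c(sqrt(3) / 2, -1 / 2)
  b1 <- (2 * pi / a) * c(1 / sqrt(3), 1)
  b2 <- (2 * pi / a) * c(1 / sqrt(3), -1)
  dR <- .dR(n, m)
  t1 <- (2 * m + n) / dR
  t2 <- -(2 * n + m) / dR
  Nhex <- 2 * (n^2 + n * m + m^2) / dR
  K1 <- (-t2 * b1 + t1 * b2) / Nhex     # circumferential quantization vector
  K2 <- (m * b1 - n * b2) / Nhex        # axial reciprocal vector
  K2hat <- K2 / sqrt(sum(K2^2))
  mu <- 0:(Nhex - 1)
  kx <- mu * K1[1] + k * K2hat[1]
  ky <- mu * K1[2] + k * K2hat[2]
  f <- abs(1 + exp(-1i * (kx * a1[1] + ky * a1[2])) + exp(-1i * (kx * a2[1] + ky * a2[2])))
  sort(c(model$onsite - model$gamma0 * f, model$onsite + model$gamma0 * f))
}

#' Band gap of a periodic tube
#'
#' Minimal direct gap between the highest valence and lowest conduction
#' band (half filling) over the 1D Brillouin zone: coarse scan on `nk`
#' points followed by golden-section refinement around the scan minimum,
#' so metallic crossings between grid points are resolved.
#'
#' @param structure a pristine periodic `swnt_structure` (even atom count).
#' @param model a [tb_model()].
#' @param nk coarse scan size.
#' @param refine refine with [stats::optimize()]?
#' @return Gap in eV (~0 for metallic tubes).
#' @export
band_gap <- function(structure, model = tb_model(), nk = 16L, refine = TRUE) {
  stopifnot(structure$cell$kind == "periodic_z")
  n <- n_atoms(structure)
  if (n %% 2L) stop("band gap at half filling needs an even atom count", call. = FALSE)
  v <- n %/% 2L
  Tlen <- structure$cell$period
  gap_at <- function(k) {
    e <- sort(Re(eigen(tb_hamiltonian(structure, model, k),
                       symmetric = TRUE, only.values = TRUE)$values))
    e[v + 1L] - e[v]
  }
  kgrid <- -pi / Tlen + (seq_len(nk) - 1L) * (2 * pi / Tlen) / nk
  gaps <- vapply(kgrid, gap_at, numeric(1))
  if (!refine) return(min(gaps))
  i0 <- which.min(gaps)
  dk <- 2 * pi / (Tlen * nk)
  opt <- stats::optimize(gap_at, interval = c(kgrid[i0] - dk, kgrid[i0] + dk),
                         tol = 1e-6)
  min(min(gaps), opt$objective)
}

# Fermi-Dirac occupation, numerically safe for large |x|
.fermi <- function(E, mu, temperature) {
  x <- (E - mu) / (.const$kB_eV * temperature)
  ifelse(x > 0, exp(-x) / (1 + exp(-x)), 1 / (1 + exp(x)))
}

.fermi_deriv <- function(E, mu, temperature) {
  beta <- 1 / (.const$kB_eV * temperature)
  f <- .fermi(E, mu, temperature)
  -beta * f * (1 - f)
}

#' Chemical potential at half filling
#'
#' Solves `(1/Nk) sum_k sum_n 2 f((E_n(k) - mu)/kT) = N_atoms` (one pi
#' electron per carbon, spin factor 2 explicit) by bisection to 1e-9 eV.
#' For a particle-hole symmetric spectrum the result is the onsite energy.
#'
#' @param bands an `swnt_bands` object.
#' @param temperature electronic temperature in K (default 300).
#' @param n_electrons target electron count; default one per atom.
#' @return Chemical potential in eV, with attribute `"occupation_error"`
#'   (relative electron-count residual).
#' @export
chemical_potential <- function(bands, temperature = 300, n_electrons = NULL) {
  E <- bands$energies
  nk <- nrow(E)
  if (is.null(n_electrons)) n_electrons <- ncol(E)
  count <- function(mu) sum(2 * .fermi(E, mu, temperature)) / nk
  lo0 <- min(E) - 10; hi0 <- max(E) + 10
  if (count(lo0) > n_electrons || count(hi0) < n_electrons) {
    stop(sprintf("chemical potential not bracketed: N(mu=%.2f) = %.4f, N(mu=%.2f) = %.4f, target %d",
                 lo0, count(lo0), hi0, count(hi0), n_electrons), call. = FALSE)
  }
  # At low temperature a gapped spectrum makes count(mu) flat (to machine
  # precision) across the whole gap; return the midpoint of that plateau
  # (mid-gap convention), located by two bisections on the plateau edges.
  edge <- function(thresh) {
    lo <- lo0; hi <- hi0
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (count(mid) < thresh) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    (lo + hi) / 2
  }
  eps <- 1e-9 * n_electrons
  mu <- (edge(n_electrons - eps) + edge(n_electrons + eps)) / 2
  attr(mu, "occupation_error") <- abs(count(mu) - n_electrons) / n_electrons
  mu
}
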