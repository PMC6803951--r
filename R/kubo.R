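#' Configuration for the Kubo-Greenwood conductivity
#'
#' @param omega_eV photon-energy grid in eV; strictly increasing, positive.
#' @param eta phenomenological broadening in eV (> 0); default 0.05.
#' @param temperature electronic temperature in K; default 300.
#' @param polarization `"axial"` (E parallel to the tube axis, z),
#'   `"perpendicular"` (average of the two transverse responses), or one of
#'   `"x"`, `"y"`, `"z"`.
#' @return An object of class `kubo_config`.
#' @export
kubo_config <- function(omega_eV = seq(0.1, 10, by = 0.02), eta = 0.05,
                        temperature = 300, polarization = "axial") {
  if (eta <= 0) stop("eta must be positive: the response diverges at eta = 0", call. = FALSE)
  if (any(omega_eV <= 0) || is.unsorted(omega_eV, strictly = TRUE)) {
    stop("omega_eV must be a strictly increasing grid of positive energies", call. = FALSE)
  }
  polarization <- match.arg(polarization, c("axial", "perpendicular", "x", "y", "z"))
  structure(list(omega_eV = omega_eV, eta = eta, temperature = temperature,
                 polarization = polarization), class = "kubo_config")
}

.dir_index <- function(direction) {
  i <- match(direction, c("x", "y", "z"))
  if (is.na(i)) stop("direction must be one of 'x', 'y', 'z'", call. = FALSE)
  i
}

#' Momentum matrix in the eigenbasis (velocity units of eV nm)
#'
#' Returns `v = (hbar/m_e) P` in eV nm. For the axial direction of periodic
#' tubes the analytic k-derivative of the Bloch Hamiltonian is used,
#' `P -> (m_e/hbar) dH/dk`; for transverse directions (and all directions of
#' finite structures) the commutator form
#' `<i|P|j> = (m_e / i hbar) (r_i - r_j) H_ij` is used in the site basis.
#' The two routes agree for the axial direction of periodic tubes.
#'
#' @param bands an `swnt_bands` object with eigenvectors.
#' @param ik k-point index into `bands$k`.
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param form `"auto"` (k-derivative for periodic z, commutator otherwise),
#'   `"dk"` or `"commutator"`.
#' @return Complex Hermitian matrix in the eigenbasis, eV nm.
#' @export
momentum_matrix <- function(bands, ik = 1L, direction = "z", form = "auto") {
  if (is.null(bands$vectors)) stop("band structure was computed without eigenvectors", call. = FALSE)
  diri <- .dir_index(direction)
  st <- bands$structure
  periodic <- st$cell$kind == "periodic_z"
  form <- match.arg(form, c("auto", "dk", "commutator"))
  if (form == "auto") form <- if (periodic && diri == 3L) "dk" else "commutator"
  if (form == "dk" && !(periodic && diri == 3L)) {
    stop("the k-derivative form is only available for the axial direction of periodic tubes",
         call. = FALSE)
  }
  k <- bands$k[ik]
  C <- bands$vectors[[ik]]
  if (form == "dk") {
    M <- .tb_dhamiltonian_dk(st, bands$model, k)
  } else {
    n <- n_atoms(st)
    b <- st$bonds
    g <- .bond_hoppings(st, bands$model)
    p <- st$positions
    disp <- p[b$i + 1L, diri] - (p[b$j + 1L, diri] + if (diri == 3L) b$sz else 0)
    dz <- .bond_dz(st)
    # (1/i) (r_i - r_j) H_ij with the Bloch phase of each bond image
    M <- .accum_hermitian(n, b$i, b$j, (1 / 1i) * disp * (-g * exp(1i * k * dz)))
  }
  Conj(t(C)) %*% M %*% C
}

#' Complex sheet conductivity via the Kubo-Greenwood formula
#'
#' Implements, term by term, the band-pair sum
#' `sigma(Omega) = (2 e^2 hbar / (i m_e^2 Scell Nk)) * sum_k sum_{n,m}
#' P_nm P_mn / (E_n - E_m + Omega + i eta) * (f(E_n) - f(E_m))/(E_n - E_m)`
#' with the spin factor 2 explicit and the intraband / degenerate `0/0`
#' limit replaced by the analytic derivative `df/dE` (Drude-like term,
#' broadened by `eta`). The result is a 2D sheet conductivity in siemens:
#' the cell area `Scell` of the band structure normalizes one tube to its
#' share of film area, making `sigma * Z0` dimensionless.
#'
#' @param bands an `swnt_bands` with eigenvectors.
#' @param config a [kubo_config()].
#' @param mu chemical potential in eV; default solved at half filling via
#'   [chemical_potential()] at `config$temperature`.
#' @return An object of class `conductivity_spectrum`: `omega_eV`,
#'   `lambda_nm`, complex `sigma_S`, plus the configuration used.
#' @export
kubo_conductivity <- function(bands, config = kubo_config(), mu = NULL) {
  if (is.null(bands$vectors)) stop("band structure was computed without eigenvectors", call. = FALSE)
  if (is.null(mu)) mu <- chemical_potential(bands, config$temperature)
  dirs <- switch(config$polarization,
                 axial = "z", perpendicular = c("x", "y"),
                 x = "x", y = "y", z = "z")
  omega <- config$omega_eV
  eta <- config$eta
  nk <- nrow(bands$energies)
  acc <- complex(length(omega))
  degtol <- 1e-9
  for (ik in seq_len(nk)) {
    E <- bands$energies[ik, ]
    f <- .fermi(E, mu, config$temperature)
    dE <- outer(E, E, "-")
    df <- outer(f, f, "-")
    occ <- ifelse(abs(dE) < degtol,
                  .fermi_deriv(outer(E, E, "+") / 2, mu, config$temperature),
                  df / ifelse(abs(dE) < degtol, 1, dE))
    for (d in dirs) {
      v <- momentum_matrix(bands, ik, d)
      W <- Re(v * Conj(v)) * occ        # |v_nm|^2 (f_n - f_m)/(E_n - E_m)
      keep <- which(abs(W) > 0)
      if (!length(keep)) next
      Wk <- W[keep]; dEk <- dE[keep]
      for (io in seq_along(omega)) {
        acc[io] <- acc[io] + sum(Wk / (dEk + omega[io] + 1i * eta)) / length(dirs)
      }
    }
  }
  sigma <- (2 * .const$e2_hbar_S / 1i) * acc / (bands$scell * nk)
  structure(list(omega_eV = omega, lambda_nm = .const$hc_eVnm / omega,
                 sigma_S = sigma, eta = eta, temperature = config$temperature,
                 polarization = config$polarization, mu = mu,
                 scell = bands$scell, nk = nk,
                 provenance = bands$structure$provenance),
            class = "conductivity_spectrum")
}

#' @export
print.conductivity_spectrum <- function(x, ...) {
  cat(sprintf("sheet conductivity: %d energies in [%.2f, %.2f] eV, pol = %s, eta = %.3f eV\n",
              length(x$omega_eV), min(x$omega_eV), max(x$omega_eV),
              x$polarization, x$eta))
  cat(sprintf("  peak Re sigma = %.3e S at %.2f eV (sigma Z0 = %.3f)\n",
              max(Re(x$sigma_S)), x$omega_eV[which.max(Re(x$sigma_S))],
              max(Re(x$sigma_S)) * .const$Z0_ohm))
  invisible(x)
}

#' @export
plot.conductivity_spectrum <- function(x, ...) {
  graphics::plot(x$omega_eV, Re(x$sigma_S), type = "l",
                 xlab = expression(Omega ~ "(eV)"),
                 ylab = expression(Re ~ sigma ~ "(S)"), ...)
  graphics::lines(x$omega_eV, Im(x$sigma_S), lty = 2)
  graphics::legend("topright", legend = c("Re", "Im"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Export a conductivity spectrum as CSV
#' @param sigma a `conductivity_spectrum`.
#' @param path output CSV path (omega_eV, lambda_nm, re_sigma_S, im_sigma_S).
#' @return `path`, invisibly.
#' @export
write_sigma_csv <- function(sigma, path) {
  utils::write.csv(data.frame(omega_eV = sigma$omega_eV, lambda_nm = sigma$lambda_nm,
                              re_sigma_S = Re(sigma$sigma_S), im_sigma_S = Im(sigma$sigma_S),
                              polarization = sigma$polarization),
                   path, row.names = FALSE)
  invisible(path)
}

#' One-call conductivity of a tube with k-point convergence
#'
#' Doubles the k-grid from `nk_start` until the maximum change of `sigma`
#' falls below `tol_frac` of the spectrum peak, then returns the converged
#' spectrum. The number of k-points used is recorded in the output (`$nk`).
#'
#' @param structure a periodic `swnt_structure`.
#' @param model a [tb_model()].
#' @param config a [kubo_config()].
#' @param nk_start initial k-point count (doubled as needed).
#' @param tol_frac convergence tolerance as a fraction of the peak of
#'   `|sigma|`; default 0.01.
#' @param nk_max k-point cap.
#' @return A `conductivity_spectrum` (see [kubo_conductivity()]).
#' @export
tube_conductivity <- function(structure, model = tb_model(), config = kubo_config(),
                              nk_start = 16L, tol_frac = 0.01, nk_max = 256L) {
  nk <- nk_start
  prev <- NULL
  repeat {
    bands <- band_structure(structure, model, nk = nk)
    cur <- kubo_conductivity(bands, config)
    if (!is.null(prev)) {
      delta <- max(Mod(cur$sigma_S - prev$sigma_S)) / max(Mod(cur$sigma_S))
      if (delta < tol_frac || nk >= nk_max) {
        cur$nk_converged <- nk
        cur$nk_delta <- delta
        return(cur)
      }
    }
    prev <- cur
    nk <- 2L * nk
  }
}
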