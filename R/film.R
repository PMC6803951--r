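#' Thin-film geometry for absorption calculations
#'
#' Two film geometries are supported, both treated as a single infinitesimal
#' current sheet in vacuum (valid while the film is much thinner than the
#' wavelength):
#' * `"side"` - side-illuminated film of long parallel tubes; one tube
#'   occupies a film area of `period x (diameter + gap)`.
#' * `"end"` - end-illuminated film of short open-ended tubes standing
#'   normal to the film; one tube occupies the hexagonal-packing
#'   cross-section `sqrt(3)/2 (diameter + gap)^2`.
#'
#' @param geometry `"side"` or `"end"`.
#' @param gap_nm wall-to-wall inter-tube gap in nm (default 0.5).
#' @param thickness_nm film thickness in nm; used only to check the
#'   thin-film validity condition (`thickness < lambda_min / 10`), with a
#'   warning otherwise.
#' @return An object of class `film_model`.
#' @export
film_model <- function(geometry = c("side", "end"), gap_nm = 0.5,
                       thickness_nm = NULL) {
  geometry <- match.arg(geometry)
  structure(list(geometry = geometry, gap_nm = gap_nm,
                 thickness_nm = thickness_nm, Z0 = .const$Z0_ohm),
            class = "film_model")
}

#' Film area per tube (the conductivity normalization cell)
#'
#' @param film a [film_model()].
#' @param chirality tube chirality, for the diameter.
#' @param period_nm axial period in nm (side geometry only).
#' @return Area in nm^2.
#' @export
film_scell <- function(film, chirality, period_nm = NULL) {
  pitch <- nt_diameter(as_chirality(chirality)) + film$gap_nm
  if (film$geometry == "side") {
    if (is.null(period_nm)) stop("side geometry needs the axial period", call. = FALSE)
    period_nm * pitch
  } else {
    sqrt(3) / 2 * pitch^2
  }
}

#' Normal-incidence reflection and transmission of a conducting sheet
#'
#' `R = -sigma Z0 / (2 + sigma Z0)`, `T = 2 / (2 + sigma Z0)` with
#' `Z0 = 120 pi` ohm, elementwise over the photon-energy grid.
#'
#' @param sigma a `conductivity_spectrum` (sheet conductivity in siemens),
#'   or a complex vector of sheet conductivities.
#' @param film a [film_model()] (used for the thin-film validity warning).
#' @return List with complex `R`, `T` and the grids (`omega_eV`, `lambda_nm`).
#' @export
reflection_transmission <- function(sigma, film = film_model()) {
  if (inherits(sigma, "conductivity_spectrum")) {
    s <- sigma$sigma_S; omega <- sigma$omega_eV; lambda <- sigma$lambda_nm
  } else {
    s <- as.complex(sigma); omega <- NULL; lambda <- NULL
  }
  sz <- s * .const$Z0_ohm
  if (any(Mod(2 + sz) < 1e-12)) {
    stop("2 + sigma Z0 vanishes: nonphysical (negative-loss) sheet conductivity", call. = FALSE)
  }
  if (!is.null(film$thickness_nm) && !is.null(lambda) &&
      film$thickness_nm >= min(lambda) / 10) {
    warning(sprintf("thin-film condition violated: thickness %.1f nm >= lambda_min/10 = %.1f nm",
                    film$thickness_nm, min(lambda) / 10), call. = FALSE)
  }
  list(R = -sz / (2 + sz), T = 2 / (2 + sz), omega_eV = omega, lambda_nm = lambda)
}

#' Absorption spectrum from reflection and transmission
#'
#' `A = 1 - |R|^2 - |T|^2`, with the wavelength grid attached via
#' `lambda = 1239.842 / Omega` (nm, eV).
#'
#' @param rt output of [reflection_transmission()], or complex `R`.
#' @param T complex transmission (when `rt` is given as a bare vector).
#' @param omega_eV photon-energy grid (when not carried by `rt`).
#' @param provenance optional list recording where the spectrum came from.
#' @return An `absorption_spectrum`: `lambda_nm`, `omega_eV`, `A`, `R2`, `T2`.
#' @export
absorption <- function(rt, T = NULL, omega_eV = NULL, provenance = list()) {
  if (is.list(rt) && !is.null(rt$R)) {
    R <- rt$R; Tc <- rt$T
    if (is.null(omega_eV)) omega_eV <- rt$omega_eV
  } else {
    R <- rt; Tc <- T
  }
  if (length(R) != length(Tc)) stop("R and T grids do not match", call. = FALSE)
  R2 <- Mod(R)^2; T2 <- Mod(Tc)^2
  A <- 1 - R2 - T2
  lambda <- if (!is.null(omega_eV)) .const$hc_eVnm / omega_eV else NULL
  structure(list(lambda_nm = lambda, omega_eV = omega_eV, A = A, R2 = R2, T2 = T2,
                 provenance = provenance),
            class = "absorption_spectrum")
}

#' One-call film absorption from a conductivity spectrum
#' @param sigma a `conductivity_spectrum`.
#' @param film a [film_model()].
#' @return An `absorption_spectrum`.
#' @export
film_absorption <- function(sigma, film = film_model()) {
  rt <- reflection_transmission(sigma, film)
  absorption(rt, provenance = list(film = film, sigma = sigma$provenance,
                                   polarization = sigma$polarization))
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  imax <- which.max(x$A)
  cat(sprintf("absorption spectrum: %d points, A_max = %.4f (%.1f%%)",
              length(x$A), x$A[imax], 100 * x$A[imax]))
  if (!is.null(x$lambda_nm)) cat(sprintf(" at %.0f nm", x$lambda_nm[imax]))
  cat("\n")
  invisible(x)
}

#' @export
plot.absorption_spectrum <- function(x, ...) {
  if (!is.null(x$lambda_nm)) {
    graphics::plot(x$lambda_nm, x$A, type = "l", xlab = "wavelength (nm)",
                   ylab = "A", ...)
  } else {
    graphics::plot(seq_along(x$A), x$A, type = "l", xlab = "index", ylab = "A", ...)
  }
  invisible(x)
}

#' Export an absorption spectrum as CSV
#' @param spectrum an `absorption_spectrum`.
#' @param path output CSV path (lambda_nm, omega_eV, A, R2, T2).
#' @return `path`, invisibly.
#' @export
write_absorption_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(lambda_nm = spectrum$lambda_nm,
                              omega_eV = spectrum$omega_eV,
                              A = spectrum$A, R2 = spectrum$R2, T2 = spectrum$T2),
                   path, row.names = FALSE)
  invisible(path)
}

#' Locate absorption maxima
#'
#' Local maxima of `A` versus wavelength with at least the requested
#' absolute prominence (height above the higher of the two saddles
#' separating the peak from taller peaks).
#'
#' @param spectrum an `absorption_spectrum` (or list with `lambda_nm`, `A`).
#' @param prominence minimal absolute prominence in A units, in (0, 1);
#'   default 0.01.
#' @return data.frame with `lambda_nm` and `A`, sorted by wavelength.
#' @export
find_absorption_maxima <- function(spectrum, prominence = 0.01) {
  if (prominence <= 0 || prominence >= 1) stop("prominence must lie in (0, 1)", call. = FALSE)
  lam <- spectrum$lambda_nm
  A <- spectrum$A
  if (length(A) < 3L) stop("spectrum too short to locate maxima (need >= 3 points)", call. = FALSE)
  ord <- order(lam)
  lam <- lam[ord]; A <- A[ord]
  n <- length(A)
  ispk <- which(diff(sign(diff(A))) < 0) + 1L  # strict rise then fall/flat
  ispk <- ispk[A[ispk] > A[pmax(1L, ispk - 1L)] & A[ispk] >= A[pmin(n, ispk + 1L)]]
  keep <- vapply(ispk, function(i) {
    # walk out to the nearest higher point on each side; prominence is the
    # peak height above the higher of the two interval minima
    left <- A[seq_len(i - 1L)]
    right <- A[seq(i + 1L, n)]
    higherL <- which(left > A[i]); higherR <- which(right > A[i])
    minL <- if (length(higherL)) min(left[seq(max(higherL), i - 1L)]) else min(left)
    minR <- if (length(higherR)) min(right[seq_len(min(higherR))]) else min(right)
    (A[i] - max(minL, minR)) >= prominence
  }, logical(1))
  data.frame(lambda_nm = lam[ispk[keep]], A = A[ispk[keep]])
}

#' Count peaks per wavelength range
#'
#' Bins peak wavelengths into disjoint `[lo, hi)` intervals (boundary
#' inclusive on the left) plus an `outside` bucket. The default ranges are
#' the UV, visible, near-IR and far-IR windows where nanotube film
#' absorption maxima concentrate: 200-400, 650-800, 900-1150, 1800-2400 nm.
#'
#' @param peaks data.frame from [find_absorption_maxima()] (column
#'   `lambda_nm`), or a numeric vector of wavelengths.
#' @param ranges 2-column matrix or list of `c(lo, hi)` pairs, disjoint.
#' @return Named integer vector of counts, one per range plus `"outside"`.
#' @export
bin_peaks <- function(peaks,
                      ranges = list(c(200, 400), c(650, 800), c(900, 1150), c(1800, 2400))) {
  lam <- if (is.data.frame(peaks)) peaks$lambda_nm else as.numeric(peaks)
  rg <- do.call(rbind, lapply(ranges, function(r) sort(as.numeric(r))))
  ord <- order(rg[, 1])
  rg <- rg[ord, , drop = FALSE]
  if (nrow(rg) > 1 && any(rg[-1, 1] < rg[-nrow(rg), 2])) {
    stop("wavelength ranges overlap", call. = FALSE)
  }
  counts <- vapply(seq_len(nrow(rg)), function(i) sum(lam >= rg[i, 1] & lam < rg[i, 2]),
                   integer(1))
  names(counts) <- sprintf("%g-%g", rg[, 1], rg[, 2])
  c(counts, outside = length(lam) - sum(counts))
}

#' Wavelength intervals where absorption reaches a level
#'
#' Maximal wavelength intervals with `A >= level`, endpoints located by
#' linear interpolation between grid points.
#'
#' @param spectrum an `absorption_spectrum`.
#' @param level threshold in (0, 1), e.g. 0.5 for the 50% condition.
#' @return data.frame with `lambda_lo`, `lambda_hi` (nm); zero rows if the
#'   level is never reached.
#' @export
wavelengths_at_level <- function(spectrum, level = 0.5) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  ord <- order(spectrum$lambda_nm)
  lam <- spectrum$lambda_nm[ord]
  A <- spectrum$A[ord]
  above <- A >= level
  if (!any(above)) return(data.frame(lambda_lo = numeric(0), lambda_hi = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(seg) {
    i0 <- starts[seg]; i1 <- ends[seg]
    lo <- if (i0 == 1L) lam[1] else {
      lam[i0 - 1L] + (level - A[i0 - 1L]) / (A[i0] - A[i0 - 1L]) * (lam[i0] - lam[i0 - 1L])
    }
    hi <- if (i1 == length(lam)) lam[length(lam)] else {
      lam[i1] + (level - A[i1]) / (A[i1 + 1L] - A[i1]) * (lam[i1 + 1L] - lam[i1])
    }
    c(lo, hi)
  })
  out <- do.call(rbind, out)
  data.frame(lambda_lo = out[, 1], lambda_hi = out[, 2])
}

#' Maximum single-pass absorption over real sheet conductivities
#'
#' For a purely real (lossy) sheet, `A(x) = 4x / (2 + x)^2` with
#' `x = sigma Z0`; the maximum over `x >= 0` is 1/2, attained at
#' `sigma Z0 = 2`. This function finds the maximum numerically and returns
#' both the optimum and the analytic reference.
#'
#' @param interval search interval for `x = sigma Z0`.
#' @return List with `A_max`, `x_opt` (numerical), `A_max_analytic = 0.5`,
#'   `x_opt_analytic = 2`.
#' @export
max_real_sheet_absorption <- function(interval = c(0, 100)) {
  A_of <- function(x) {
    rt <- reflection_transmission(complex(real = x / .const$Z0_ohm))
    1 - Mod(rt$R)^2 - Mod(rt$T)^2
  }
  opt <- stats::optimize(A_of, interval = interval, maximum = TRUE, tol = 1e-12)
  list(A_max = opt$objective, x_opt = opt$maximum,
       A_max_analytic = 0.5, x_opt_analytic = 2)
}
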