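#' Chiral indices of a single-walled carbon nanotube
#'
#' A nanotube is indexed by the integer pair (n, m) defining the chiral
#' (rolling) vector `Ch = n a1 + m a2` on the graphene lattice. The pair
#' determines the tube diameter, the translational period along the axis,
#' the number of atoms in the translational cell and whether the tube is
#' metallic or semiconducting.
#'
#' @param n integer, `n >= 1`.
#' @param m integer, `0 <= m <= n` (the conventional irreducible wedge).
#' @return An object of class `swnt_chirality`.
#' @examples
#' ch <- swnt_chirality(11, 10)
#' nt_diameter(ch)
#' nt_atoms_per_cell(ch)
#' nt_metallicity(ch)
#' @export
swnt_chirality <- function(n, m) {
  if (length(n) != 1L || length(m) != 1L || !is.numeric(n) || !is.numeric(m) ||
      n != round(n) || m != round(m)) {
    stop("chiral indices (n, m) must be single integers", call. = FALSE)
  }
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L) stop("invalid chiral indices: n must be >= 1 (got n = ", n, ")", call. = FALSE)
  if (m < 0L || m > n) {
    stop("invalid chiral indices: need 0 <= m <= n (got n = ", n, ", m = ", m, ")",
         call. = FALSE)
  }
  structure(list(n = n, m = m), class = "swnt_chirality")
}

as_chirality <- function(x) {
  if (inherits(x, "swnt_chirality")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(swnt_chirality(x[1], x[2]))
  stop("cannot interpret as chiral indices: supply swnt_chirality() or c(n, m)",
       call. = FALSE)
}

#' @export
print.swnt_chirality <- function(x, ...) {
  cat(sprintf("SWCNT chirality (%d,%d): d = %.4f nm, T = %.4f nm, %d atoms/cell, %s\n",
              x$n, x$m, nt_diameter(x), nt_translation_period(x),
              nt_atoms_per_cell(x), nt_metallicity(x)))
  invisible(x)
}

#' @export
format.swnt_chirality <- function(x, ...) sprintf("(%d,%d)", x$n, x$m)

# gcd of the graphene sublattice combination entering the translational cell
.dR <- function(n, m) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  g(2L * n + m, 2L * m + n)
}

#' Nanotube diameter
#'
#' `d = a sqrt(n^2 + m^2 + n m) / pi` with `a = 0.246` nm.
#'
#' @param chirality an [swnt_chirality()] (or `c(n, m)`).
#' @return Diameter in nm.
#' @export
nt_diameter <- function(chirality) {
  ch <- as_chirality(chirality)
  .const$a_nm * sqrt(ch$n^2 + ch$m^2 + ch$n * ch$m) / pi
}

#' Translational period along the tube axis
#'
#' `T = sqrt(3) |Ch| / d_R` with `d_R = gcd(2n + m, 2m + n)`.
#'
#' @inheritParams nt_diameter
#' @return Period in nm.
#' @export
nt_translation_period <- function(chirality) {
  ch <- as_chirality(chirality)
  sqrt(3) * .const$a_nm * sqrt(ch$n^2 + ch$m^2 + ch$n * ch$m) / .dR(ch$n, ch$m)
}

#' Atoms in one translational cell
#'
#' `N = 4 (n^2 + m^2 + n m) / d_R`; always an even positive integer.
#'
#' @inheritParams nt_diameter
#' @return Integer atom count.
#' @export
nt_atoms_per_cell <- function(chirality) {
  ch <- as_chirality(chirality)
  as.integer(4L * (ch$n^2 + ch$m^2 + ch$n * ch$m) / .dR(ch$n, ch$m))
}

#' Metallic or semiconducting?
#'
#' Zone-folding rule: a tube is metallic iff `(n - m) mod 3 == 0`, else
#' semiconducting (curvature-induced mini-gaps are not modelled).
#'
#' @inheritParams nt_diameter
#' @return `"metallic"` or `"semiconducting"`.
#' @export
nt_metallicity <- function(chirality) {
  ch <- as_chirality(chirality)
  if ((ch$n - ch$m) %% 3L == 0L) "metallic" else "semiconducting"
}

#' A reference set of sixteen frequently synthesized chiralities
#'
#' Zigzag (m,0) with m = 13, 14, 16, 20, 23, 32; armchair (m,m) with
#' m = 4, 12, 15, 20; and chiral (11,10), (14,4), (12,6), (12,8), (23,6),
#' (9,4). Diameters span roughly 0.6-2 nm. Eleven of the sixteen are
#' semiconducting (about 69%), matching the roughly 2/3 semiconductor
#' fraction of as-synthesized nanotube material.
#'
#' @return A list of [swnt_chirality()] objects, length 16.
#' @export
common_chiralities <- function() {
  idx <- list(c(13, 0), c(14, 0), c(16, 0), c(20, 0), c(23, 0), c(32, 0),
              c(4, 4), c(12, 12), c(15, 15), c(20, 20),
              c(11, 10), c(14, 4), c(12, 6), c(12, 8), c(23, 6), c(9, 4))
  lapply(idx, function(p) swnt_chirality(p[1], p[2]))
}

#' Metallicity table for a set of chiralities
#'
#' @param chiralities list of [swnt_chirality()]; default [common_chiralities()].
#' @return data.frame with n, m, diameter_nm, period_nm, atoms_per_cell,
#'   metallicity; attribute `"semiconductor_fraction"` carries the fraction.
#' @export
classify_chiralities <- function(chiralities = common_chiralities()) {
  chiralities <- lapply(chiralities, as_chirality)
  df <- data.frame(
    n = vapply(chiralities, function(c) c$n, integer(1)),
    m = vapply(chiralities, function(c) c$m, integer(1)),
    diameter_nm = vapply(chiralities, nt_diameter, numeric(1)),
    period_nm = vapply(chiralities, nt_translation_period, numeric(1)),
    atoms_per_cell = vapply(chiralities, nt_atoms_per_cell, integer(1)),
    metallicity = vapply(chiralities, nt_metallicity, character(1)),
    stringsAsFactors = FALSE
  )
  attr(df, "semiconductor_fraction") <- mean(df$metallicity == "semiconducting")
  df
}
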