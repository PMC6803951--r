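#' @name swnt_structure
#' @title Atomistic SWCNT structure
#'
#' @description
#' The universal geometry container of the package: Cartesian coordinates in
#' nm (tube axis along z), per-atom element symbols, a bond list from a
#' distance cutoff, an optional periodic cell, and defect-site annotations.
#'
#' Bonds are stored as a data.frame with columns `i`, `j` (0-based atom
#' indices) and `sz` (z-shift in nm applied to atom `j` for bonds crossing
#' the periodic boundary; 0 for in-cell bonds). For short periodic cells the
#' bond list is a multigraph: the same atom pair may be bonded through two
#' different periodic images, and both bonds carry full weight in the
#' tight-binding Hamiltonian.
#' @keywords internal
NULL

new_swnt_structure <- function(positions, elements = NULL, bonds = NULL,
                               cell = list(kind = "none"), defects = list(),
                               provenance = list(), sublattice = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  if (is.null(elements)) elements <- rep("C", nrow(positions))
  structure(list(positions = positions, elements = elements, bonds = bonds,
                 cell = cell, defects = defects, provenance = provenance,
                 sublattice = sublattice),
            class = "swnt_structure")
}

#' Number of atoms in a structure
#' @param structure an `swnt_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$positions)

#' @export
print.swnt_structure <- function(x, ...) {
  celltxt <- switch(x$cell$kind,
    periodic_z = sprintf("periodic along z, T = %.4f nm", x$cell$period),
    box = sprintf("periodic box %.1f x %.1f x %.1f nm", x$cell$box[1], x$cell$box[2], x$cell$box[3]),
    none = "non-periodic")
  cat(sprintf("SWCNT structure: %d atoms, %d bonds, %s\n",
              n_atoms(x), if (is.null(x$bonds)) 0L else nrow(x$bonds), celltxt))
  if (!is.null(x$provenance$chirality)) {
    cat("  chirality:", format(x$provenance$chirality), "\n")
  }
  if (length(x$defects)) {
    kinds <- vapply(x$defects, function(d) d$kind, character(1))
    cat("  defects:", paste(kinds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.swnt_structure <- function(object, ...) {
  deg <- atom_degrees(object)
  bl <- bond_lengths(object)
  out <- list(
    n_atoms = n_atoms(object),
    n_bonds = nrow(object$bonds),
    degree_table = table(deg),
    bond_length_range = range(bl),
    radius_range = range(sqrt(object$positions[, 1]^2 + object$positions[, 2]^2)),
    defects = object$defects
  )
  class(out) <- "summary.swnt_structure"
  out
}

#' @export
print.summary.swnt_structure <- function(x, ...) {
  cat(sprintf("%d atoms, %d bonds\n", x$n_atoms, x$n_bonds))
  cat("coordination:"); print(x$degree_table)
  cat(sprintf("bond lengths: %.4f - %.4f nm\n", x$bond_length_range[1], x$bond_length_range[2]))
  cat(sprintf("radial range: %.4f - %.4f nm\n", x$radius_range[1], x$radius_range[2]))
  invisible(x)
}

#' @export
plot.swnt_structure <- function(x, ...) {
  p <- x$positions
  graphics::plot(p[, 3], atan2(p[, 2], p[, 1]) * nt_radius_of(x),
                 pch = 16, cex = 0.4, xlab = "z (nm)",
                 ylab = "unrolled circumference (nm)", asp = 1, ...)
  invisible(x)
}

nt_radius_of <- function(structure) {
  stats::median(sqrt(structure$positions[, 1]^2 + structure$positions[, 2]^2))
}

# ---- unit-cell generation (exact integer lattice bookkeeping) --------------

# Atoms of one translational cell of tube (n,m), as exact fractions of the
# circumference (u/6NC) and the period (w/6L). Graphene lattice points
# i*a1 + j*a2 + s*(a1+a2)/3 (s = 0, 1 for the A/B sublattices) are projected
# on the chiral and translation vectors; all arithmetic stays in integers so
# deduplication of periodic copies is exact.
.tube_cell_fractions <- function(ch) {
  n <- ch$n; m <- ch$m
  NC <- n^2 + n * m + m^2
  dR <- .dR(n, m)
  t1 <- (2L * m + n) / dR
  t2 <- -(2L * n + m) / dR
  L <- 3L * NC / dR^2          # |T|^2 / a^2, an integer

  corners_i <- c(0, n, t1, n + t1)
  corners_j <- c(0, m, t2, m + t2)
  is <- seq(min(corners_i) - 1L, max(corners_i) + 1L)
  js <- seq(min(corners_j) - 1L, max(corners_j) + 1L)
  g <- expand.grid(i = is, j = js)

  res <- lapply(0:1, function(s) {
    xi <- (3 * g$i + s) * (2 * n + m) + (3 * g$j + s) * (2 * m + n)   # / (6 NC)
    ze <- (3 * g$i + s) * (2 * t1 + t2) + (3 * g$j + s) * (2 * t2 + t1) # / (6 L)
    u <- xi %% (6 * NC)
    w <- ze %% (6 * L)
    keep <- !duplicated(u + (6 * NC) * w)
    data.frame(u = u[keep], w = w[keep], s = s)
  })
  res <- rbind(res[[1]], res[[2]])
  res <- res[!duplicated(res$u + (6 * NC) * res$w + 36 * NC * L * res$s), ]
  expected <- nt_atoms_per_cell(ch)
  if (nrow(res) != expected) {
    stop(sprintf("internal error: built %d atoms for (%d,%d), expected %d",
                 nrow(res), n, m, expected))
  }
  res$den_u <- 6 * NC
  res$den_w <- 6 * L
  res[order(res$w, res$u), ]
}

# Cartesian coordinates of one cell from the exact fractions.
.tube_cell_positions <- function(ch) {
  fr <- .tube_cell_fractions(ch)
  R <- nt_diameter(ch) / 2
  Tlen <- nt_translation_period(ch)
  phi <- 2 * pi * fr$u / fr$den_u
  z <- Tlen * fr$w / fr$den_w
  list(positions = cbind(x = R * cos(phi), y = R * sin(phi), z = z),
       sublattice = fr$s, period = Tlen)
}

# ---- bond detection --------------------------------------------------------

# All-pairs bond search with optional z-periodicity, chunked to bound memory.
# Returns data.frame(i, j, sz): 0-based indices; sz is the z-shift (nm)
# applied to atom j. In-cell bonds are listed once with i < j; bonds through
# the +T image are listed for every ordered pair, so a pair bonded through
# both images appears twice (a genuine multigraph edge).
find_bonds <- function(positions, cutoff = .const$cutoff_nm, period_z = NULL) {
  n <- nrow(positions)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), sz = numeric(0)))
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  c2 <- cutoff^2
  block <- max(64L, min(n, as.integer(2e6 / n)))
  res <- list(); ri <- 1L

  add_pairs <- function(ii, jj, sz) {
    if (length(ii)) {
      res[[ri]] <<- data.frame(i = ii - 1L, j = jj - 1L, sz = sz)
      ri <<- ri + 1L
    }
  }
  shifts <- if (is.null(period_z)) 0 else c(0, period_z)
  for (s in shifts) {
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(n, start + block - 1L)
      d2 <- (outer(x[rows], x, "-"))^2 + (outer(y[rows], y, "-"))^2 +
            (outer(z[rows], z + s, "-"))^2
      hit <- which(d2 <= c2, arr.ind = TRUE)
      ii <- rows[hit[, 1]]; jj <- hit[, 2]
      keep <- if (s == 0) ii < jj else ii != jj
      add_pairs(ii[keep], jj[keep], s)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(i = integer(0), j = integer(0), sz = numeric(0))
  rownames(out) <- NULL
  out
}

#' Coordination number of every atom
#' @param structure an `swnt_structure`.
#' @return integer vector of bond counts per atom (multigraph-aware).
#' @export
atom_degrees <- function(structure) {
  n <- n_atoms(structure)
  tabulate(c(structure$bonds$i, structure$bonds$j) + 1L, nbins = n)
}

#' Bond lengths of a structure
#' @param structure an `swnt_structure`.
#' @return numeric vector, nm, one entry per bond.
#' @export
bond_lengths <- function(structure) {
  p <- structure$positions; b <- structure$bonds
  d <- p[b$j + 1L, , drop = FALSE] - p[b$i + 1L, , drop = FALSE]
  d[, 3] <- d[, 3] + b$sz
  sqrt(rowSums(d^2))
}

rebuild_bonds <- function(structure, cutoff = .const$cutoff_nm) {
  period <- if (structure$cell$kind == "periodic_z") structure$cell$period else NULL
  structure$bonds <- find_bonds(structure$positions, cutoff, period)
  structure
}

# ---- builders --------------------------------------------------------------

#' Build a periodic single-walled nanotube
#'
#' Ideal rolled-graphene cylinder: atoms of `n_periods` translational cells
#' on a cylinder of the analytic diameter, periodic along z. No geometry
#' optimization is applied (see the methods vignette); an optional harmonic
#' relaxation is available via [relax_bonds()].
#'
#' @param chirality an [swnt_chirality()] or `c(n, m)`.
#' @param n_periods number of translational cells, `>= 1`.
#' @param bonds logical; set `FALSE` to skip bond detection (positions only).
#' @return An `swnt_structure`, periodic along z with period
#'   `n_periods * nt_translation_period(chirality)`.
#' @examples
#' tube <- build_periodic_tube(swnt_chirality(4, 4))
#' n_atoms(tube)  # 16
#' @export
build_periodic_tube <- function(chirality, n_periods = 1L, bonds = TRUE) {
  ch <- as_chirality(chirality)
  if (length(n_periods) != 1L || n_periods < 1 || n_periods != round(n_periods)) {
    stop("n_periods must be a positive integer", call. = FALSE)
  }
  n_periods <- as.integer(n_periods)
  cell <- .tube_cell_positions(ch)
  reps <- lapply(seq_len(n_periods) - 1L, function(k) {
    p <- cell$positions
    p[, 3] <- p[, 3] + k * cell$period
    p
  })
  pos <- do.call(rbind, reps)
  st <- new_swnt_structure(
    positions = pos,
    cell = list(kind = "periodic_z", period = n_periods * cell$period),
    provenance = list(chirality = ch, n_periods = n_periods, construction = "periodic"),
    sublattice = rep(cell$sublattice, n_periods)
  )
  if (bonds) st <- rebuild_bonds(st)
  st
}

#' Build a finite open-ended nanotube
#'
#' Stacks whole translational cells up to the requested length (rounded
#' DOWN to whole periods so the tube never exceeds the request), with no
#' periodicity. Open ends are left unterminated: rim atoms have
#' coordination 2 and are tagged as `open_end` defect sites.
#'
#' @param chirality an [swnt_chirality()] or `c(n, m)`.
#' @param length_nm requested tube length in nm; must be at least one period.
#' @return A non-periodic `swnt_structure` with an `open_end` entry in
#'   `$defects` listing the rim atoms.
#' @examples
#' tube <- build_finite_tube(swnt_chirality(4, 4), 2)   # 8 periods, 128 atoms
#' @export
build_finite_tube <- function(chirality, length_nm) {
  ch <- as_chirality(chirality)
  Tlen <- nt_translation_period(ch)
  if (length_nm < Tlen) {
    stop(sprintf("requested length %.3f nm is below one period (%.3f nm) of (%d,%d)",
                 length_nm, Tlen, ch$n, ch$m), call. = FALSE)
  }
  np <- as.integer(floor(length_nm / Tlen))
  cell <- .tube_cell_positions(ch)
  reps <- lapply(seq_len(np) - 1L, function(k) {
    p <- cell$positions
    p[, 3] <- p[, 3] + k * cell$period
    p
  })
  pos <- do.call(rbind, reps)
  st <- new_swnt_structure(
    positions = pos,
    cell = list(kind = "none"),
    provenance = list(chirality = ch, n_periods = np,
                      requested_length_nm = length_nm, construction = "finite"),
    sublattice = rep(cell$sublattice, np)
  )
  st <- rebuild_bonds(st)
  rim <- which(atom_degrees(st) < 3L) - 1L
  st$defects <- list(list(kind = "open_end", atoms = rim))
  st
}

#' Optional harmonic bond relaxation
#'
#' Steepest-descent relaxation with nearest-neighbour springs of natural
#' length 0.142 nm. OFF by default everywhere: the ideal rolled cylinder is
#' the reference geometry, and reproducible topology matters more to the
#' tight-binding model than sub-picometre coordinates.
#'
#' @param structure an `swnt_structure` with bonds.
#' @param k_spring spring constant (arbitrary energy units per nm^2).
#' @param step steepest-descent step (nm^2 per energy unit).
#' @param tol stop when the maximum force component falls below `tol`.
#' @param max_iter iteration cap.
#' @return The structure with relaxed coordinates (bonds recomputed).
#' @export
relax_bonds <- function(structure, k_spring = 1, step = 0.05, tol = 1e-4,
                        max_iter = 500L) {
  p <- structure$positions
  b <- structure$bonds
  r0 <- .const$acc_nm
  for (it in seq_len(max_iter)) {
    d <- p[b$j + 1L, , drop = FALSE] - p[b$i + 1L, , drop = FALSE]
    d[, 3] <- d[, 3] + b$sz
    len <- sqrt(rowSums(d^2))
    fpair <- k_spring * (len - r0) / len   # force magnitude / length
    fx <- d * fpair
    force <- matrix(0, nrow(p), 3)
    for (col in 1:3) {
      force[, col] <- force[, col] +
        as.vector(tapply(fx[, col], factor(b$i + 1L, levels = seq_len(nrow(p))), sum, default = 0)) -
        as.vector(tapply(fx[, col], factor(b$j + 1L, levels = seq_len(nrow(p))), sum, default = 0))
    }
    force[is.na(force)] <- 0
    if (max(abs(force)) < tol) break
    p <- p + step * force
  }
  structure$positions <- p
  rebuild_bonds(structure)
}
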