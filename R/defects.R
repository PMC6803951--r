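#' Point-defect specifications
#'
#' Four defect kinds are supported, the ones relevant to laser nanowelding
#' of nanotube scaffolds:
#' * `SV` - single vacancy: removes one atom, leaving three 2-coordinated
#'   neighbours (no reconstruction is applied).
#' * `DV` - double vacancy: removes two bonded atoms.
#' * `SW` - Stone-Wales defect: rotates one C-C bond by 90 degrees in the
#'   local tangent plane and rebonds, converting four hexagons into two
#'   pentagons and two heptagons.
#' * `MIXED` - an ordered list of non-MIXED specs applied sequentially.
#'
#' Atom and bond indices are 0-based throughout the package. When `site`
#' (or `bond`) is `NULL`, a valid site is drawn at random using `rng_seed`.
#'
#' @param kind one of `"SV"`, `"DV"`, `"SW"`, `"MIXED"`.
#' @param site 0-based atom index (SV/DV) or `NULL` for random.
#' @param bond 0-based row index into `structure$bonds` (SW) or `NULL`.
#' @param components list of non-MIXED `defect_spec`s (MIXED only).
#' @param rng_seed integer seed for random site selection.
#' @return An object of class `defect_spec`.
#' @examples
#' defect_spec("SV", site = 10)
#' defect_spec("MIXED", components = list(defect_spec("SW"), defect_spec("SV")),
#'             rng_seed = 1)
#' @export
defect_spec <- function(kind = c("SV", "DV", "SW", "MIXED"), site = NULL,
                        bond = NULL, components = NULL, rng_seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "MIXED") {
    if (is.null(components) || !length(components)) {
      stop("MIXED defect needs a non-empty list of component specs", call. = FALSE)
    }
    bad <- vapply(components, function(c) !inherits(c, "defect_spec") || c$kind == "MIXED",
                  logical(1))
    if (any(bad)) stop("MIXED components must be non-MIXED defect_spec objects", call. = FALSE)
  }
  structure(list(kind = kind, site = site, bond = bond,
                 components = components, rng_seed = rng_seed),
            class = "defect_spec")
}

#' @export
print.defect_spec <- function(x, ...) {
  if (x$kind == "MIXED") {
    cat("MIXED defect:", paste(vapply(x$components, function(c) c$kind, character(1)),
                               collapse = " + "), "\n")
  } else {
    loc <- if (!is.null(x$site)) paste(" at atom", x$site)
           else if (!is.null(x$bond)) paste(" at bond", x$bond) else " (random site)"
    cat(x$kind, "defect", loc, "\n", sep = "")
  }
  invisible(x)
}

# indices (0-based) of atoms currently tagged by any defect
.defect_atoms <- function(structure) {
  unique(unlist(lapply(structure$defects, function(d) d$atoms)))
}

# remap 0-based atom indices after removing `removed` (0-based): dropped
# atoms map to NA, the rest shift down.
.remap_after_removal <- function(idx, removed, n_before) {
  map <- rep(NA_integer_, n_before)
  keep <- setdiff(seq_len(n_before) - 1L, removed)
  map[keep + 1L] <- seq_along(keep) - 1L
  map[idx + 1L]
}

.remap_defects <- function(defects, removed, n_before) {
  lapply(defects, function(d) {
    if (!is.null(d$atoms)) {
      a <- .remap_after_removal(d$atoms, removed, n_before)
      d$atoms <- a[!is.na(a)]
    }
    d
  })
}

.bonded_neighbours <- function(structure, atom) {
  b <- structure$bonds
  sort(unique(c(b$j[b$i == atom], b$i[b$j == atom])))
}

.check_overlap <- function(structure, new_atoms, override) {
  prior <- .defect_atoms(structure)
  if (!length(prior) || !length(new_atoms)) return(invisible())
  p <- structure$positions
  d <- sqrt(outer(p[new_atoms + 1L, 1], p[prior + 1L, 1], "-")^2 +
            outer(p[new_atoms + 1L, 2], p[prior + 1L, 2], "-")^2 +
            outer(p[new_atoms + 1L, 3], p[prior + 1L, 3], "-")^2)
  if (min(d) < 2 * .const$acc_nm && !override) {
    warning("new defect lies within two bond lengths of an existing defect; ",
            "pass override = TRUE to silence", call. = FALSE)
  }
  invisible()
}

.random_interior_atom <- function(structure) {
  deg <- atom_degrees(structure)
  excl <- .defect_atoms(structure)
  cand <- which(deg == 3L) - 1L
  cand <- setdiff(cand, excl)
  if (!length(cand)) stop("no interior atoms left for defect placement", call. = FALSE)
  # keep clear of existing defects where possible
  if (length(excl)) {
    p <- structure$positions
    dmin <- apply(sqrt(outer(p[cand + 1L, 1], p[excl + 1L, 1], "-")^2 +
                       outer(p[cand + 1L, 2], p[excl + 1L, 2], "-")^2 +
                       outer(p[cand + 1L, 3], p[excl + 1L, 3], "-")^2), 1, min)
    far <- cand[dmin >= 2 * .const$acc_nm]
    if (length(far)) cand <- far
  }
  sample(cand, 1L)
}

.random_interior_bond <- function(structure) {
  deg <- atom_degrees(structure)
  b <- structure$bonds
  excl <- .defect_atoms(structure)
  cand <- which(deg[b$i + 1L] == 3L & deg[b$j + 1L] == 3L &
                !(b$i %in% excl) & !(b$j %in% excl))
  if (!length(cand)) stop("no interior bonds left for defect placement", call. = FALSE)
  sample(cand, 1L) - 1L
}

#' Apply a point defect to a structure
#'
#' Semantics per kind: SV removes exactly one atom; DV removes the site atom
#' and one bonded neighbour; SW keeps the atom count and rotates the bond by
#' 90 degrees about its midpoint in the local tangent plane of the cylinder,
#' after which bonds are rebuilt with the global cutoff (ring census gains
#' exactly two pentagons and two heptagons); MIXED applies its components in
#' order. Vacancies are left unreconstructed. Defect sites are recorded in
#' `$defects` and survive subsequent removals (indices are remapped).
#'
#' @param structure an `swnt_structure` with bonds.
#' @param spec a [defect_spec()].
#' @param override logical; silence the warning issued when the new defect
#'   lies within two bond lengths of an existing one.
#' @return The modified `swnt_structure`.
#' @examples
#' tube <- build_periodic_tube(swnt_chirality(20, 0), 3)
#' sw <- apply_defect(tube, defect_spec("SW", rng_seed = 7))
#' ring_census(sw)[c("5", "7")]
#' @export
apply_defect <- function(structure, spec, override = FALSE) {
  stopifnot(inherits(structure, "swnt_structure"), inherits(spec, "defect_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)

  if (spec$kind == "MIXED") {
    for (comp in spec$components) structure <- apply_defect(structure, comp, override)
    return(structure)
  }

  n0 <- n_atoms(structure)
  if (spec$kind %in% c("SV", "DV")) {
    site <- spec$site
    if (is.null(site)) site <- .random_interior_atom(structure)
    if (site < 0L || site >= n0) stop("defect site out of range: atom ", site, call. = FALSE)
    removed <- site
    if (spec$kind == "DV") {
      nb <- .bonded_neighbours(structure, site)
      if (!length(nb)) stop("DV site has no bonded neighbour", call. = FALSE)
      partner <- if (length(nb) == 1L) nb else sample(nb, 1L)
      removed <- c(site, partner)
    }
    neigh <- setdiff(unique(unlist(lapply(removed, .bonded_neighbours, structure = structure))),
                     removed)
    .check_overlap(structure, neigh, override)
    keep <- setdiff(seq_len(n0) - 1L, removed)
    structure$defects <- .remap_defects(structure$defects, removed, n0)
    tagged <- .remap_after_removal(neigh, removed, n0)
    structure$positions <- structure$positions[keep + 1L, , drop = FALSE]
    structure$sublattice <- structure$sublattice[keep + 1L]
    structure$elements <- structure$elements[keep + 1L]
    structure <- rebuild_bonds(structure)
    structure$defects <- c(structure$defects,
                           list(list(kind = spec$kind, atoms = tagged[!is.na(tagged)])))
    return(structure)
  }

  # SW: rotate a bond by 90 degrees in the tangent plane
  bidx <- spec$bond
  if (is.null(bidx)) bidx <- .random_interior_bond(structure)
  if (bidx < 0L || bidx >= nrow(structure$bonds)) {
    stop("SW bond index out of range: ", bidx, call. = FALSE)
  }
  b <- structure$bonds[bidx + 1L, ]
  deg <- atom_degrees(structure)
  if (deg[b$i + 1L] != 3L || deg[b$j + 1L] != 3L) {
    stop("SW defect requires an interior bond (both atoms 3-coordinated); ",
         "bond ", bidx, " touches the tube rim", call. = FALSE)
  }
  .check_overlap(structure, c(b$i, b$j), override)
  p <- structure$positions
  pi_ <- p[b$i + 1L, ]
  pj <- p[b$j + 1L, ]; pj[3] <- pj[3] + b$sz
  mid <- (pi_ + pj) / 2
  axis <- c(mid[1], mid[2], 0)              # surface normal of the cylinder
  axis <- axis / sqrt(sum(axis^2))
  rot90 <- function(v) {                    # Rodrigues, theta = 90 deg
    crossp <- c(axis[2] * v[3] - axis[3] * v[2],
                axis[3] * v[1] - axis[1] * v[3],
                axis[1] * v[2] - axis[2] * v[1])
    crossp + axis * sum(axis * v)
  }
  p[b$i + 1L, ] <- mid + rot90(pi_ - mid)
  newj <- mid + rot90(pj - mid)
  newj[3] <- newj[3] - b$sz
  p[b$j + 1L, ] <- newj
  structure$positions <- p
  structure <- rebuild_bonds(structure)
  structure$defects <- c(structure$defects,
                         list(list(kind = "SW", atoms = c(b$i, b$j))))
  structure
}

# ---- ring census -----------------------------------------------------------

#' Ring census of the bond graph
#'
#' Counts chordless cycles of length 3 up to `max_size` in the (simple) bond
#' graph: pristine tubes show hexagons only, a Stone-Wales defect adds
#' exactly two pentagons and two heptagons. The census is meaningful when
#' the periodic cell is long enough that no winding cycle is shorter than
#' `max_size` (two or more translational periods in practice).
#'
#' @param structure an `swnt_structure` with bonds.
#' @param max_size largest ring size counted (default 7).
#' @return Named integer vector of ring counts for sizes `3:max_size`.
#' @export
ring_census <- function(structure, max_size = 7L) {
  n <- n_atoms(structure)
  b <- structure$bonds
  key <- pmin(b$i, b$j) * n + pmax(b$i, b$j)
  uniq <- !duplicated(key)
  ei <- b$i[uniq]; ej <- b$j[uniq]
  adj <- vector("list", n)
  for (r in seq_along(ei)) {
    adj[[ei[r] + 1L]] <- c(adj[[ei[r] + 1L]], ej[r])
    adj[[ej[r] + 1L]] <- c(adj[[ej[r] + 1L]], ei[r])
  }
  edge_set <- new.env(hash = TRUE)
  for (r in seq_along(ei)) {
    assign(paste(min(ei[r], ej[r]), max(ei[r], ej[r])), TRUE, envir = edge_set)
  }
  has_edge <- function(a, bb) exists(paste(min(a, bb), max(a, bb)), envir = edge_set)

  counts <- integer(max_size)
  # enumerate cycles with their smallest vertex first; dedupe orientation by
  # requiring the second vertex to be smaller than the last
  for (v in 0:(n - 1L)) {
    path <- integer(max_size)
    dfs <- function(cur, depth) {
      for (w in adj[[cur + 1L]]) {
        if (w == v && depth >= 3L) {
          if (path[2] < path[depth]) {
            cyc <- path[1:depth]
            chordless <- TRUE
            for (ii in 1:(depth - 2L)) {
              jmax <- if (ii == 1L) depth - 1L else depth
              for (jj in (ii + 2L):jmax) {
                if (has_edge(cyc[ii], cyc[jj])) { chordless <- FALSE; break }
              }
              if (!chordless) break
            }
            if (chordless) counts[depth] <<- counts[depth] + 1L
          }
        } else if (depth < max_size && w > v && !(w %in% path[1:depth])) {
          path[depth + 1L] <<- w
          dfs(w, depth + 1L)
          path[depth + 1L] <<- 0L
        }
      }
    }
    path[1] <- v
    dfs(v, 1L)
  }
  stats::setNames(counts[3:max_size], as.character(3:max_size))
}
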