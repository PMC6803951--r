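# Random SWCNT network in a periodic box: rigid straight tubes placed by
# random sequential insertion with a surface-surface exclusion distance,
# close-contact detection (spatial hashing with a brute-force-equivalent
# guarantee), defect seeding at contacts, and hot-spot temperature maps.

#' Minimal distance between two line segments
#'
#' Closed-form clamped minimization (the standard segment-segment algorithm);
#' used for tube axes during packing so the cost stays independent of the
#' atom count.
#'
#' @param p1,u1,l1 base point, unit axis and length of segment 1.
#' @param p2,u2,l2 base point, unit axis and length of segment 2.
#' @return Minimal distance between the segments (same units as inputs).
#' @export
segment_distance <- function(p1, u1, l1, p2, u2, l2) {
  d1 <- u1 * l1; d2 <- u2 * l2
  r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (a <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > tiny) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# distance between tube axes i and j under minimum image: tries the 27
# periodic offsets of tube j (valid while tubes are shorter than half the
# box, which generate_network enforces); returns the distance and offset
.seg_dist_mi <- function(net, i, j) {
  ti <- net$tubes[[i]]; tj <- net$tubes[[j]]
  best <- Inf; boff <- c(0, 0, 0)
  for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
    off <- c(ox, oy, oz) * net$box
    d <- segment_distance(ti$base, ti$axis, ti$length, tj$base + off, tj$axis, tj$length)
    if (d < best) { best <- d; boff <- off }
  }
  list(dist = best, offset = boff)
}

new_swnt_network <- function(box, chirality, tubes = list(), seed = NULL,
                             exclusion_gap = 0.34) {
  structure(list(box = box, chirality = as_chirality(chirality), tubes = tubes,
                 structures = vector("list", length(tubes)),
                 contacts = NULL, defect_assignments = NULL,
                 exclusion_gap = exclusion_gap, seed = seed),
            class = "swnt_network")
}

#' @export
print.swnt_network <- function(x, ...) {
  cat(sprintf("SWCNT network: %d tubes %s in %.0f x %.0f x %.0f nm periodic box\n",
              length(x$tubes), format(x$chirality), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  %d atoms, density %.2f kg/m^3\n", network_atom_count(x), network_density(x)))
  if (!is.null(x$contacts)) cat(sprintf("  %d contacts detected\n", nrow(x$contacts)))
  if (!is.null(x$defect_assignments)) {
    cat(sprintf("  %d defects assigned\n", nrow(x$defect_assignments)))
  }
  invisible(x)
}

#' Generate a random SWCNT network in a periodic box
#'
#' Random sequential insertion: tube lengths uniform in `length_range`
#' (rounded down to whole translational periods), positions uniform in the
#' box, orientations uniform on the sphere. A candidate is rejected when its
#' surface comes closer than `exclusion_gap` (the van der Waals wall-to-wall
#' distance) to any placed tube under the minimum-image convention.
#' Deterministic under `seed`.
#'
#' @param box numeric length-3, box edges in nm (periodic in all directions).
#' @param n_tubes number of tubes to place.
#' @param length_range `c(min, max)` tube length in nm.
#' @param chirality tube chirality (one chirality per network).
#' @param exclusion_gap minimal allowed surface-surface gap in nm (default 0.34).
#' @param seed integer RNG seed (mandatory: placement is stochastic).
#' @param max_attempts insertion attempts per tube before giving up.
#' @return An `swnt_network`.
#' @export
generate_network <- function(box, n_tubes, length_range = c(5, 20),
                             chirality = c(4, 4), exclusion_gap = 0.34,
                             seed, max_attempts = 2000L) {
  if (missing(seed)) stop("seed is mandatory: network placement is stochastic", call. = FALSE)
  ch <- as_chirality(chirality)
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0))
  if (max(length_range) >= max(box)) {
    stop("box does not fit the tubes: longest tube must be shorter than the longest box edge",
         call. = FALSE)
  }
  if (max(length_range) >= min(box)) {
    # with tube midpoints wrapped into the box, +/-1 periodic images cover
    # every close approach while tubes stay shorter than the box edges
    warning("tubes longer than the shortest box edge: minimum-image distances may miss images",
            call. = FALSE)
  }
  set.seed(seed)
  Tlen <- nt_translation_period(ch)
  r <- nt_diameter(ch) / 2
  net <- new_swnt_network(box, ch, seed = seed, exclusion_gap = exclusion_gap)
  for (it in seq_len(n_tubes)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      L <- floor(stats::runif(1, length_range[1], length_range[2]) / Tlen) * Tlen
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # sample the midpoint uniformly in the box so no tube extends more
      # than L/2 beyond it; +/-1 minimum images are then exhaustive
      base <- stats::runif(3) * box - u * L / 2
      cand <- list(base = base, axis = u, length = L, radius = r,
                   n_periods = round(L / Tlen))
      ok <- TRUE
      for (jj in seq_along(net$tubes)) {
        tj <- net$tubes[[jj]]
        best <- Inf
        for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
          d <- segment_distance(base, u, L, tj$base + c(ox, oy, oz) * box,
                                tj$axis, tj$length)
          if (d < best) best <- d
        }
        if (best - 2 * r < exclusion_gap) { ok <- FALSE; break }
      }
      if (ok) {
        net$tubes <- c(net$tubes, list(cand))
        net$structures <- c(net$structures, list(NULL))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("failed to place tube %d of %d after %d attempts (%d placed so far)",
                   it, n_tubes, max_attempts, length(net$tubes)), call. = FALSE)
    }
  }
  net
}

#' Place a tube explicitly (no exclusion check)
#'
#' Direct placement API for constructing reference configurations; the
#' exclusion rule of [generate_network()] is deliberately not applied.
#'
#' @param net an `swnt_network`.
#' @param base base point (nm).
#' @param axis direction (normalized internally).
#' @param length_nm tube length in nm (rounded down to whole periods).
#' @return The network with the tube appended.
#' @export
place_tube <- function(net, base, axis, length_nm) {
  axis <- axis / sqrt(sum(axis^2))
  Tlen <- nt_translation_period(net$chirality)
  L <- floor(length_nm / Tlen) * Tlen
  net$tubes <- c(net$tubes, list(list(base = as.numeric(base), axis = as.numeric(axis),
                                      length = L, radius = nt_diameter(net$chirality) / 2,
                                      n_periods = round(L / Tlen))))
  net$structures <- c(net$structures, list(NULL))
  net
}

# rotation taking e_z to unit vector u
.rot_z_to <- function(u) {
  if (abs(u[3] - 1) < 1e-12) return(diag(3))
  if (abs(u[3] + 1) < 1e-12) return(diag(c(1, -1, -1)))
  v <- c(-u[2], u[1], 0)                      # e_z x u
  s <- sqrt(sum(v^2)); c_ <- u[3]
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Atomistic structure of one network tube
#'
#' Built lazily (finite open-ended tube, rotated onto the tube axis and
#' translated to its base point) and cached on the network object.
#'
#' @param net an `swnt_network`.
#' @param i tube index (1-based).
#' @return List `net` (with the structure cached) and `structure`.
#' @export
realize_tube <- function(net, i) {
  if (!is.null(net$structures[[i]])) {
    return(list(net = net, structure = net$structures[[i]]))
  }
  tb <- net$tubes[[i]]
  st <- build_finite_tube(net$chirality, tb$length + 1e-9)
  R <- .rot_z_to(tb$axis)
  st$positions <- st$positions %*% t(R) + matrix(tb$base, n_atoms(st), 3, byrow = TRUE)
  net$structures[[i]] <- st
  list(net = net, structure = st)
}

#' Total atom count of a network
#' @param net an `swnt_network`.
#' @return Integer atom count (from per-tube period counts; no realization).
#' @export
network_atom_count <- function(net) {
  ap <- nt_atoms_per_cell(net$chirality)
  sum(vapply(net$tubes, function(t) t$n_periods * ap, numeric(1)))
}

#' Mass density of the network
#'
#' Total carbon mass over box volume, `m_C = 12.011 x 1.66054e-27` kg.
#'
#' @param net an `swnt_network`.
#' @return Density in kg/m^3.
#' @export
network_density <- function(net) {
  V_m3 <- prod(net$box) * 1e-27
  network_atom_count(net) * .const$mC_kg / V_m3
}

# ---- contact detection -----------------------------------------------------

.contact_row <- function(net, i, j) {
  dm <- .seg_dist_mi(net, i, j)
  ri <- net$tubes[[i]]$radius; rj <- net$tubes[[j]]$radius
  data.frame(tube_i = i, tube_j = j, gap = dm$dist - ri - rj,
             off_x = dm$offset[1], off_y = dm$offset[2], off_z = dm$offset[3])
}

.brute_pairs <- function(net, thresh_gap) {
  n <- length(net$tubes)
  if (n < 2L) return(NULL)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    row <- .contact_row(net, i, j)
    if (row$gap <= thresh_gap) out[[length(out) + 1L]] <- row
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# spatial hash on points sampled along the axes. Guarantee: with sample
# spacing s and cell size c >= (axis distance threshold) + s, any pair of
# segments within the threshold shares a 3x3x3 cell neighbourhood, so the
# candidate set is a superset of the brute-force result.
.hash_pairs <- function(net, thresh_gap) {
  if (length(net$tubes) < 2L) return(NULL)
  rmax <- max(vapply(net$tubes, function(t) t$radius, numeric(1)))
  thresh <- thresh_gap + 2 * rmax          # axis-distance threshold
  s <- thresh / 2
  cell <- thresh + s
  ncell <- pmax(1L, as.integer(floor(net$box / cell)))
  if (any(ncell < 3L)) return(.brute_pairs(net, thresh_gap))
  cw <- net$box / ncell
  pts <- lapply(seq_along(net$tubes), function(i) {
    tb <- net$tubes[[i]]
    tt <- seq(0, tb$length, by = s)
    if (tt[length(tt)] < tb$length) tt <- c(tt, tb$length)
    p <- matrix(tb$base, length(tt), 3, byrow = TRUE) + outer(tt, tb$axis)
    p <- p %% matrix(net$box, nrow(p), 3, byrow = TRUE)
    cbind(floor(p[, 1] / cw[1]), floor(p[, 2] / cw[2]), floor(p[, 3] / cw[3]), i)
  })
  pts <- do.call(rbind, pts)
  pts[, 1:3] <- pmin(pts[, 1:3], matrix(ncell - 1L, nrow(pts), 3, byrow = TRUE))
  keyof <- function(cx, cy, cz) (cx * ncell[2] + cy) * ncell[3] + cz
  occ <- split(pts[, 4], keyof(pts[, 1], pts[, 2], pts[, 3]))
  occ <- lapply(occ, unique)
  cells <- as.numeric(names(occ))
  cz <- cells %% ncell[3]; rest <- (cells - cz) / ncell[3]
  cy <- rest %% ncell[2]; cx <- (rest - cy) / ncell[2]
  lookup <- new.env(hash = TRUE)
  for (ii in seq_along(cells)) assign(as.character(cells[ii]), occ[[ii]], envir = lookup)
  cand <- new.env(hash = TRUE)
  for (ii in seq_along(cells)) {
    here <- occ[[ii]]
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      nk <- keyof((cx[ii] + ox) %% ncell[1], (cy[ii] + oy) %% ncell[2],
                  (cz[ii] + oz) %% ncell[3])
      there <- lookup[[as.character(nk)]]
      if (is.null(there)) next
      for (a in here) for (b in there) {
        if (a < b) assign(paste(a, b), TRUE, envir = cand)
      }
    }
  }
  pairs <- ls(cand)
  out <- list()
  for (pp in pairs) {
    ij <- as.integer(strsplit(pp, " ", fixed = TRUE)[[1]])
    row <- .contact_row(net, ij[1], ij[2])
    if (row$gap <= thresh_gap) out[[length(out) + 1L]] <- row
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Detect close contacts between tubes
#'
#' Finds all unordered tube pairs whose minimal surface-surface gap lies in
#' `[d_min, d_max]` under the minimum-image convention, plus the realizing
#' atom pair of each contact. The default spatial-hash search returns
#' exactly the brute-force all-pairs result (asserted property).
#'
#' @param net an `swnt_network`.
#' @param d_min,d_max gap window in nm (defaults 0.2 and 0.4).
#' @param method `"hash"` (default) or `"brute"`.
#' @return The network with `$contacts` set: data.frame with tube indices,
#'   surface gap, periodic offset, and nearest atom pair (0-based indices
#'   into the realized tube structures) with its surface-surface distance.
#' @export
detect_contacts <- function(net, d_min = 0.2, d_max = 0.4,
                            method = c("hash", "brute")) {
  method <- match.arg(method)
  if (d_min >= d_max) stop("need d_min < d_max", call. = FALSE)
  rows <- if (method == "hash") .hash_pairs(net, d_max) else .brute_pairs(net, d_max)
  if (!is.null(rows)) rows <- rows[rows$gap >= d_min & rows$gap <= d_max, , drop = FALSE]
  if (is.null(rows) || !nrow(rows)) {
    net$contacts <- data.frame(tube_i = integer(0), tube_j = integer(0), gap = numeric(0),
                               off_x = numeric(0), off_y = numeric(0), off_z = numeric(0),
                               atom_i = integer(0), atom_j = integer(0),
                               atom_gap = numeric(0))
    return(net)
  }
  rows$atom_i <- NA_integer_; rows$atom_j <- NA_integer_; rows$atom_gap <- NA_real_
  for (rr in seq_len(nrow(rows))) {
    i <- rows$tube_i[rr]; j <- rows$tube_j[rr]
    res <- realize_tube(net, i); net <- res$net; si <- res$structure
    res <- realize_tube(net, j); net <- res$net; sj <- res$structure
    off <- c(rows$off_x[rr], rows$off_y[rr], rows$off_z[rr])
    pj <- sj$positions + matrix(off, n_atoms(sj), 3, byrow = TRUE)
    np <- .nearest_atom_pair(si$positions, pj)
    rows$atom_i[rr] <- np$i - 1L
    rows$atom_j[rr] <- np$j - 1L
    rows$atom_gap[rr] <- np$dist
  }
  rownames(rows) <- NULL
  net$contacts <- rows
  net
}

# nearest pair between two coordinate sets, prefiltered around the mutual
# closest region to keep the pair scan small
.nearest_atom_pair <- function(pi_, pj) {
  ci <- colMeans(pi_); cj <- colMeans(pj)
  besti <- 1L; bestj <- 1L; best <- Inf
  di <- sqrt(rowSums((pj - matrix(ci, nrow(pj), 3, byrow = TRUE))^2))
  j0 <- which.min(di)
  dj <- sqrt(rowSums((pi_ - matrix(pj[j0, ], nrow(pi_), 3, byrow = TRUE))^2))
  cut_i <- which(dj <= min(dj) + 1.5)
  for (a in cut_i) {
    d <- sqrt(rowSums((pj - matrix(pi_[a, ], nrow(pj), 3, byrow = TRUE))^2))
    b <- which.min(d)
    if (d[b] < best) { best <- d[b]; besti <- a; bestj <- b }
  }
  list(i = besti, j = bestj, dist = best)
}

#' Seed point defects at network contacts
#'
#' For every detected contact, one defect kind is drawn uniformly from
#' `defect_kinds` for each partner tube and applied at the contact's
#' nearest-atom site (for SW, at an interior bond incident to that atom).
#' A contact atom already consumed by a previous defect is skipped with a
#' warning. Deterministic under `seed`.
#'
#' @param net an `swnt_network` with contacts detected.
#' @param defect_kinds character vector from `c("SV", "DV", "SW")`.
#' @param seed integer RNG seed.
#' @return The network with modified tube structures and
#'   `$defect_assignments` (data.frame: contact, tube, kind, atom).
#' @export
seed_defects_at_contacts <- function(net, defect_kinds = c("SV", "DV", "SW"), seed) {
  if (is.null(net$contacts)) stop("run detect_contacts() first", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory: defect kinds are drawn at random", call. = FALSE)
  stopifnot(all(defect_kinds %in% c("SV", "DV", "SW")))
  set.seed(seed)
  assigns <- list()
  if (nrow(net$contacts)) for (rr in seq_len(nrow(net$contacts))) {
    for (side in c("i", "j")) {
      ti <- net$contacts[[paste0("tube_", side)]][rr]
      res <- realize_tube(net, ti); net <- res$net; st <- res$structure
      # nearest atom in the *current* structure to the contact's other tube
      other <- if (side == "i") net$contacts$tube_j[rr] else net$contacts$tube_i[rr]
      off <- c(net$contacts$off_x[rr], net$contacts$off_y[rr], net$contacts$off_z[rr])
      if (side == "j") off <- -off
      res2 <- realize_tube(net, other); net <- res2$net
      po <- res2$structure$positions + matrix(off, n_atoms(res2$structure), 3, byrow = TRUE)
      np <- .nearest_atom_pair(st$positions, po)
      site <- np$i - 1L
      if (site %in% .defect_atoms(st)) {
        warning(sprintf("contact %d, tube %d: atom %d already consumed by a defect; skipping",
                        rr, ti, site), call. = FALSE)
        next
      }
      kind <- if (length(defect_kinds) == 1L) defect_kinds else sample(defect_kinds, 1L)
      st2 <- tryCatch({
        if (kind == "SW") {
          deg <- atom_degrees(st)
          b <- st$bonds
          inc <- which((b$i == site | b$j == site) &
                       deg[b$i + 1L] == 3L & deg[b$j + 1L] == 3L)
          if (!length(inc)) stop("no interior bond at contact atom")
          apply_defect(st, defect_spec("SW", bond = inc[1] - 1L), override = TRUE)
        } else {
          apply_defect(st, defect_spec(kind, site = site), override = TRUE)
        }
      }, error = function(e) {
        warning(sprintf("contact %d, tube %d: %s; skipping", rr, ti, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      if (is.null(st2)) next
      net$structures[[ti]] <- st2
      assigns[[length(assigns) + 1L]] <- data.frame(contact = rr, tube = ti,
                                                    kind = kind, atom = site)
    }
  }
  net$defect_assignments <- if (length(assigns)) do.call(rbind, assigns) else
    data.frame(contact = integer(0), tube = integer(0), kind = character(0), atom = integer(0))
  net
}

#' Hot-spot temperature map
#'
#' Per-atom temperature factors (dimensionless multipliers of the base
#' temperature): defect-site atoms and open-end rim atoms absorb laser
#' energy more strongly and shed heat poorly, so they run hotter by a factor
#' drawn uniformly from `1 + overheat_range`; all other atoms stay at 1.
#'
#' @param net an `swnt_network` (defects assigned, if any).
#' @param overheat_range relative overheat window, default `c(0.16, 0.20)`.
#' @param seed integer RNG seed for the uniform draws.
#' @return List with `factors` (list of per-tube numeric vectors aligned
#'   with the realized structures) and the updated network (structures get
#'   realized as a side effect): `list(net, factors)`.
#' @export
hot_spot_map <- function(net, overheat_range = c(0.16, 0.20), seed = 1L) {
  set.seed(seed)
  factors <- vector("list", length(net$tubes))
  for (i in seq_along(net$tubes)) {
    res <- realize_tube(net, i); net <- res$net; st <- res$structure
    f <- rep(1, n_atoms(st))
    hot <- .defect_atoms(st)                      # includes open_end rims
    if (length(hot)) {
      f[hot + 1L] <- 1 + stats::runif(length(hot), overheat_range[1], overheat_range[2])
    }
    factors[[i]] <- f
  }
  list(net = net, factors = factors)
}

#' Export a whole network as XYZ or PDB
#'
#' Concatenates all realized tubes with coordinates wrapped into the box;
#' for PDB the hot-spot temperature factors go to the B-factor column.
#'
#' @param net an `swnt_network`.
#' @param path output path.
#' @param format `"xyz"` or `"pdb"` (default from extension).
#' @param temperature_factors optional result of [hot_spot_map()]`$factors`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = NULL, temperature_factors = NULL) {
  pos <- list(); bf <- list()
  for (i in seq_along(net$tubes)) {
    res <- realize_tube(net, i); net <- res$net
    p <- res$structure$positions %% matrix(net$box, n_atoms(res$structure), 3, byrow = TRUE)
    pos[[i]] <- p
    bf[[i]] <- if (is.null(temperature_factors)) rep(0, nrow(p)) else temperature_factors[[i]]
  }
  allp <- do.call(rbind, pos)
  st <- new_swnt_structure(allp, cell = list(kind = "box", box = net$box),
                           provenance = list(chirality = net$chirality))
  st$bonds <- data.frame(i = integer(0), j = integer(0), sz = numeric(0))
  write_structure(st, path, format, b_factor = unlist(bf))
}

#' Contact report as JSON
#' @param net an `swnt_network` with contacts.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_contacts_json <- function(net, path) {
  jsonlite::write_json(list(box_nm = net$box, n_tubes = length(net$tubes),
                            contacts = net$contacts,
                            defect_assignments = net$defect_assignments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
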