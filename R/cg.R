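# Bead-count bookkeeping for coarse-grained protein-polymer matrix and
# membrane systems: component manifests, exact integer totals, and JSON
# round-trips. Deliberately no coordinates and no dynamics - the manifests
# are the hand-off record for external coarse-grained engines.

#' A coarse-grained component
#'
#' @param name component name (e.g. `"SWCNT"`, `"albumin"`, `"water"`).
#' @param beads_per_molecule beads (grains) per molecule, positive integer.
#' @param n_molecules number of molecules, positive integer.
#' @return A list of class `cg_component` with the per-component bead total.
#' @export
cg_component <- function(name, beads_per_molecule, n_molecules) {
  for (v in list(beads_per_molecule, n_molecules)) {
    if (length(v) != 1L || !is.numeric(v) || v != round(v) || v <= 0) {
      stop("bead and molecule counts must be positive integers (component '", name, "')",
           call. = FALSE)
    }
  }
  structure(list(name = as.character(name),
                 beads_per_molecule = as.integer(beads_per_molecule),
                 n_molecules = as.integer(n_molecules),
                 total_beads = as.integer(beads_per_molecule * n_molecules)),
            class = "cg_component")
}

#' Compose a coarse-grained system manifest
#'
#' @param components list of [cg_component()]s.
#' @param box_nm numeric length-3 box dimensions in nm (optional).
#' @param temperature_K thermostat temperature, default 310 K.
#' @param allow_empty permit an empty component list (total 0)?
#' @return A `cg_manifest`: components, per-component totals, grand total,
#'   box and temperature.
#' @examples
#' compose_system(list(
#'   cg_component("SWCNT", 19827, 1),
#'   cg_component("albumin", 5194, 5),
#'   cg_component("water", 1, 200000)
#' ), box_nm = c(30, 30, 30))$total_beads  # 245797
#' @export
compose_system <- function(components, box_nm = NULL, temperature_K = 310,
                           allow_empty = FALSE) {
  if (!length(components)) {
    if (!allow_empty) {
      stop("empty component list (pass allow_empty = TRUE for a zero manifest)", call. = FALSE)
    }
    warning("composing an empty manifest (total 0 beads)", call. = FALSE)
  }
  stopifnot(all(vapply(components, inherits, logical(1), "cg_component")))
  totals <- vapply(components, function(c) c$total_beads, integer(1))
  structure(list(components = components,
                 component_totals = stats::setNames(totals,
                   vapply(components, function(c) c$name, character(1))),
                 total_beads = as.integer(sum(totals)),
                 box_nm = box_nm, temperature_K = temperature_K),
            class = "cg_manifest")
}

#' @export
print.cg_manifest <- function(x, ...) {
  cat("coarse-grained system manifest\n")
  for (c_ in x$components) {
    cat(sprintf("  %-10s %8d molecules x %6d beads = %9d\n",
                c_$name, c_$n_molecules, c_$beads_per_molecule, c_$total_beads))
  }
  cat(sprintf("  total beads: %d", x$total_beads))
  if (!is.null(x$box_nm)) cat(sprintf("   box %g x %g x %g nm", x$box_nm[1], x$box_nm[2], x$box_nm[3]))
  cat(sprintf("   T = %g K\n", x$temperature_K))
  invisible(x)
}

#' Lipid-membrane manifest
#'
#' A phospholipid bilayer patch of `n_lipids` coarse-grained DPPC molecules.
#' The default 12 beads per lipid is the standard coarse-grained DPPC
#' topology (2 head + 2 glycerol + 2 x 4 tail beads).
#'
#' @param n_lipids number of lipid molecules (default 8450).
#' @param beads_per_lipid beads per lipid (default 12).
#' @param expected_total optional declared total; a mismatch with
#'   `n_lipids * beads_per_lipid` raises an error.
#' @param box_nm membrane patch dimensions, default 50 x 50 x 4 nm.
#' @return A `cg_manifest`.
#' @examples
#' membrane_manifest()$total_beads  # 101400
#' @export
membrane_manifest <- function(n_lipids = 8450, beads_per_lipid = 12,
                              expected_total = NULL, box_nm = c(50, 50, 4)) {
  man <- compose_system(list(cg_component("DPPC", beads_per_lipid, n_lipids)),
                        box_nm = box_nm)
  if (!is.null(expected_total) && man$total_beads != expected_total) {
    stop(sprintf("membrane bead total %d does not match the declared total %d",
                 man$total_beads, expected_total), call. = FALSE)
  }
  man
}

#' Preset compositions of the matrix and membrane boxes
#'
#' Four presets: `"albumin-box"` (19,827 SWCNT + 25,970 albumin over five
#' molecules + 200,000 water grains, 30 nm box), `"collagen-box"` (19,827 +
#' 56,498 + 160,000), `"chitosan-box"` (19,827 + 9,237 chitosan + 200,000
#' water) and `"membrane"` (8,450 DPPC x 12 beads). All thermostatted at
#' 310 K.
#'
#' @param preset preset name.
#' @return A `cg_manifest`.
#' @export
cg_preset <- function(preset = c("albumin-box", "collagen-box", "chitosan-box",
                                 "membrane")) {
  preset <- match.arg(preset)
  box30 <- c(30, 30, 30)
  switch(preset,
    "albumin-box" = compose_system(list(
      cg_component("SWCNT", 19827, 1),
      cg_component("albumin", 5194, 5),
      cg_component("water", 1, 200000)), box_nm = box30),
    "collagen-box" = compose_system(list(
      cg_component("SWCNT", 19827, 1),
      cg_component("collagen", 56498, 1),
      cg_component("water", 1, 160000)), box_nm = box30),
    "chitosan-box" = compose_system(list(
      cg_component("SWCNT", 19827, 1),
      cg_component("chitosan", 9237, 1),
      cg_component("water", 1, 200000)), box_nm = box30),
    "membrane" = membrane_manifest())
}

#' Write / read a manifest as JSON (lossless round-trip)
#' @param manifest a `cg_manifest`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `cg_manifest` (read).
#' @export
write_manifest_json <- function(manifest, path) {
  comp <- lapply(manifest$components, function(c_) {
    list(name = c_$name, beads_per_molecule = c_$beads_per_molecule,
         n_molecules = c_$n_molecules)
  })
  jsonlite::write_json(list(components = comp, box_nm = manifest$box_nm,
                            temperature_K = manifest$temperature_K,
                            total_beads = manifest$total_beads),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  j <- jsonlite::read_json(path)
  comps <- lapply(j$components, function(c_) {
    cg_component(c_$name, c_$beads_per_molecule, c_$n_molecules)
  })
  man <- compose_system(comps, box_nm = if (!is.null(j$box_nm)) as.numeric(unlist(j$box_nm)),
                        temperature_K = as.numeric(j$temperature_K))
  if (!is.null(j$total_beads) && man$total_beads != j$total_beads) {
    stop(sprintf("manifest total %d disagrees with recomputed total %d (file %s)",
                 j$total_beads, man$total_beads, path), call. = FALSE)
  }
  man
}
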