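# Structure file I/O. XYZ carries metadata in the comment line as key=value
# tokens (unit, cell, chirality, defects); PDB carries the same metadata in
# REMARK 300 lines and per-atom temperature factors in the B-factor column.
# Coordinates are nm internally; PDB files are written in Angstrom as the
# format demands.

.meta_tokens <- function(structure) {
  tok <- c("swcntkit", "unit=nm")
  if (structure$cell$kind == "periodic_z") {
    tok <- c(tok, "cell=periodic_z", sprintf("period=%.9f", structure$cell$period))
  } else if (structure$cell$kind == "box") {
    tok <- c(tok, "cell=box", paste0("box=", paste(sprintf("%.6f", structure$cell$box), collapse = ",")))
  } else {
    tok <- c(tok, "cell=none")
  }
  ch <- structure$provenance$chirality
  if (!is.null(ch)) tok <- c(tok, sprintf("chirality=%d,%d", ch$n, ch$m))
  if (length(structure$defects)) {
    enc <- vapply(structure$defects, function(d) {
      paste0(d$kind, ":", paste(d$atoms, collapse = ","))
    }, character(1))
    tok <- c(tok, paste0("defects=", paste(enc, collapse = ";")))
  }
  tok
}

.parse_meta <- function(tokens) {
  kv <- strsplit(tokens[grepl("=", tokens, fixed = TRUE)], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  cell <- list(kind = "none")
  if (!is.na(vals["cell"])) {
    if (vals["cell"] == "periodic_z") {
      cell <- list(kind = "periodic_z", period = as.numeric(vals["period"]))
    } else if (vals["cell"] == "box") {
      cell <- list(kind = "box", box = as.numeric(strsplit(vals["box"], ",")[[1]]))
    }
  }
  prov <- list()
  if (!is.na(vals["chirality"])) {
    nm <- as.integer(strsplit(vals["chirality"], ",")[[1]])
    prov$chirality <- swnt_chirality(nm[1], nm[2])
  }
  defects <- list()
  if (!is.na(vals["defects"])) {
    for (enc in strsplit(vals["defects"], ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(enc, ":", fixed = TRUE)[[1]]
      atoms <- if (length(parts) > 1 && nzchar(parts[2])) {
        as.integer(strsplit(parts[2], ",")[[1]])
      } else integer(0)
      defects <- c(defects, list(list(kind = parts[1], atoms = atoms)))
    }
  }
  unit <- if (!is.na(vals["unit"])) vals["unit"] else "nm"
  list(cell = cell, provenance = prov, defects = defects, unit = unit)
}

#' Write a structure to XYZ or PDB
#'
#' XYZ: atom count, then a comment line with `key=value` metadata tokens
#' (unit, cell, chirality, defect tags), then `element x y z` rows in nm.
#' PDB: fixed-width ATOM records in Angstrom with metadata in REMARK 300
#' lines; `b_factor` (e.g. a hot-spot temperature factor) fills the B-factor
#' column.
#'
#' @param structure an `swnt_structure` with at least one atom.
#' @param path output file path.
#' @param format `"xyz"` or `"pdb"`; default inferred from the extension.
#' @param b_factor optional numeric vector (one per atom) written to the PDB
#'   B-factor column; ignored for XYZ.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = NULL, b_factor = NULL) {
  stopifnot(inherits(structure, "swnt_structure"))
  if (n_atoms(structure) == 0L) stop("refusing to write a structure with 0 atoms", call. = FALSE)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("xyz", "pdb"))
  p <- structure$positions
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(p)),
      paste(.meta_tokens(structure), collapse = " "),
      sprintf("%-2s %14.8f %14.8f %14.8f", structure$elements, p[, 1], p[, 2], p[, 3])
    )
    writeLines(lines, path)
  } else {
    if (is.null(b_factor)) b_factor <- rep(0, nrow(p))
    stopifnot(length(b_factor) == nrow(p))
    ang <- p * 10
    rem <- sprintf("REMARK 300 %s", .meta_tokens(structure))
    atom <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    (seq_len(nrow(p)) - 1L) %% 100000L,
                    paste0(" ", substr(structure$elements, 1, 2)),
                    "CNT", 1L, ang[, 1], ang[, 2], ang[, 3],
                    1, pmin(b_factor, 99.99), structure$elements)
    writeLines(c(rem, atom, "END"), path)
  }
  invisible(path)
}

#' Read a structure written by [write_structure()]
#'
#' Restores coordinates, elements, cell and defect tags; bonds are rebuilt
#' from the distance cutoff. Non-carbon elements are accepted with a warning
#' (the tight-binding model is parametrized for carbon).
#'
#' @param path file path (`.xyz` or `.pdb`).
#' @param format `"xyz"` or `"pdb"`; default inferred from the extension.
#' @param cutoff bond cutoff in nm for rebuilding the bond graph.
#' @return An `swnt_structure`.
#' @export
read_structure <- function(path, format = NULL, cutoff = .const$cutoff_nm) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("xyz", "pdb"))
  if (format == "xyz") {
    lines <- readLines(path)
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("malformed XYZ at line 1: expected atom count, got '", lines[1], "'",
                       call. = FALSE)
    if (length(lines) < n + 2L) {
      stop("malformed XYZ: header declares ", n, " atoms but file ends at line ",
           length(lines), call. = FALSE)
    }
    meta <- .parse_meta(strsplit(trimws(lines[2]), "\\s+")[[1]])
    rows <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
    bad <- which(vapply(rows, length, integer(1)) < 4L)
    if (length(bad)) {
      stop("malformed XYZ at line ", bad[1] + 2L, ": expected 'element x y z'", call. = FALSE)
    }
    elements <- vapply(rows, `[`, character(1), 1)
    pos <- suppressWarnings(t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))))
    if (anyNA(pos)) {
      stop("malformed XYZ at line ", which(is.na(rowSums(pos)))[1] + 2L,
           ": non-numeric coordinate", call. = FALSE)
    }
    if (meta$unit == "angstrom") pos <- pos / 10
  } else {
    pdb <- bio3d::read.pdb(path)
    pos <- matrix(pdb$xyz, ncol = 3, byrow = TRUE) / 10
    elements <- trimws(pdb$atom$elesy)
    elements[!nzchar(elements)] <- "C"
    rem <- grep("^REMARK 300 ", readLines(path), value = TRUE)
    meta <- .parse_meta(sub("^REMARK 300 ", "", rem))
  }
  if (any(elements != "C")) {
    warning("structure contains non-carbon elements; geometry kept, but the ",
            "tight-binding model is parametrized for carbon", call. = FALSE)
  }
  st <- new_swnt_structure(pos, elements = elements, cell = meta$cell,
                           defects = meta$defects, provenance = meta$provenance)
  rebuild_bonds(st, cutoff)
}
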