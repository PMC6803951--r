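#' Pipeline run configuration
#'
#' One validated document holding every stage default: tube set, spectra
#' jobs, tight-binding and broadening parameters, film geometry, peak
#' analysis windows, network packing parameters, coarse-grained presets and
#' the master seed. Unknown arguments are rejected. All stochastic stages
#' derive their seeds from `seed`.
#'
#' @param chiralities list of chiralities for the metallicity census.
#' @param spectra list of spectrum jobs; each a list with `chirality`,
#'   optional `defect` (a [defect_spec()]) and optional `n_periods`.
#' @param gamma0,eta,temperature tight-binding hopping (eV), broadening (eV)
#'   and electronic temperature (K).
#' @param omega_eV photon-energy grid for the optics (eV).
#' @param nk k-point count for band structures.
#' @param film_gap inter-tube wall gap in the film, nm.
#' @param peak_prominence minimal absolute prominence for peak detection.
#' @param peak_ranges wavelength windows for [bin_peaks()].
#' @param level absorption level for [wavelengths_at_level()].
#' @param sigma_source `"kubo"` or `"zero"` (dry run; all-transparent film).
#' @param network `NULL`, or a list with `box`, `n_tubes`, `length_range`,
#'   `chirality`, `exclusion_gap` (defaults are the scaffold-study
#'   conditions: 258 tubes of (4,4), 5-20 nm, 65 x 45 x 40 nm box).
#' @param cg_presets character vector of [cg_preset()] names.
#' @param seed master seed (mandatory).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(chiralities = common_chiralities(),
                            spectra = list(list(chirality = c(4, 4)),
                                           list(chirality = c(13, 0))),
                            gamma0 = 2.7, eta = 0.05, temperature = 300,
                            omega_eV = seq(0.45, 12.4, by = 0.01),
                            nk = 48L,
                            film_gap = 0.5,
                            peak_prominence = 0.01,
                            peak_ranges = list(c(200, 400), c(650, 800),
                                               c(900, 1150), c(1800, 2400)),
                            level = 0.5,
                            sigma_source = c("kubo", "zero"),
                            network = list(box = c(65, 45, 40), n_tubes = 258,
                                           length_range = c(5, 20),
                                           chirality = c(4, 4),
                                           exclusion_gap = 0.34),
                            cg_presets = c("albumin-box", "collagen-box",
                                           "chitosan-box", "membrane"),
                            seed = 1L) {
  sigma_source <- match.arg(sigma_source)
  if (!is.null(network)) {
    known <- c("box", "n_tubes", "length_range", "chirality", "exclusion_gap")
    extra <- setdiff(names(network), known)
    if (length(extra)) stop("unknown network config keys: ", paste(extra, collapse = ", "),
                            call. = FALSE)
    defaults <- list(box = c(65, 45, 40), n_tubes = 258, length_range = c(5, 20),
                     chirality = c(4, 4), exclusion_gap = 0.34)
    network <- utils::modifyList(defaults, network)
  }
  cfg <- list(chiralities = lapply(chiralities, as_chirality), spectra = spectra,
              gamma0 = gamma0, eta = eta, temperature = temperature,
              omega_eV = omega_eV, nk = as.integer(nk), film_gap = film_gap,
              peak_prominence = peak_prominence, peak_ranges = peak_ranges,
              level = level, sigma_source = sigma_source, network = network,
              cg_presets = cg_presets, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Tube census -> (tube, defect) spectra -> film absorption -> peak
#' analytics; random network packing with contact detection, defect seeding
#' and hot-spot map; coarse-grained manifests. Deterministic given the
#' config: all stage seeds derive from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, structures (XYZ), spectra
#'   (CSV), peak/contact reports and the summary (JSON) are written there.
#' @return A `pipeline_summary` list: `metallicity` (data.frame +
#'   semiconductor fraction), `spectra` (per job: peaks, peak-range counts,
#'   level intervals, A_max), `network` (contact count, density, atom count,
#'   hot-atom share) and `cg` (per-preset totals).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- tb_model(gamma0 = config$gamma0)

  census <- classify_chiralities(config$chiralities)

  film <- film_model("side", gap_nm = config$film_gap)
  spectra <- list()
  for (si in seq_along(config$spectra)) {
    job <- config$spectra[[si]]
    ch <- as_chirality(job$chirality)
    np <- if (!is.null(job$n_periods)) job$n_periods else 1L
    tube <- build_periodic_tube(ch, np)
    label <- sprintf("(%d,%d)%s", ch$n, ch$m,
                     if (!is.null(job$defect)) paste0("+", job$defect$kind) else "")
    if (!is.null(job$defect)) {
      d <- job$defect
      if (is.null(d$rng_seed)) d$rng_seed <- config$seed + si
      tube <- apply_defect(tube, d, override = TRUE)
    }
    if (config$sigma_source == "zero") {
      A <- absorption(rep(0 + 0i, length(config$omega_eV)),
                      rep(1 + 0i, length(config$omega_eV)),
                      omega_eV = config$omega_eV)
    } else {
      bands <- band_structure(tube, model, nk = config$nk,
                              scell = film_scell(film, ch, tube$cell$period))
      cfg <- kubo_config(config$omega_eV, eta = config$eta,
                         temperature = config$temperature)
      sig <- kubo_conductivity(bands, cfg)
      A <- film_absorption(sig, film)
      if (!is.null(out_dir)) {
        write_sigma_csv(sig, file.path(out_dir, sprintf("sigma_%02d.csv", si)))
      }
    }
    peaks <- find_absorption_maxima(A, config$peak_prominence)
    spectra[[label]] <- list(
      chirality = c(ch$n, ch$m),
      defect = if (!is.null(job$defect)) job$defect$kind,
      A_max = max(A$A),
      peaks = peaks,
      peak_counts = bin_peaks(peaks, config$peak_ranges),
      level_intervals = wavelengths_at_level(A, config$level)
    )
    if (!is.null(out_dir)) {
      write_absorption_csv(A, file.path(out_dir, sprintf("absorption_%02d.csv", si)))
      write_structure(tube, file.path(out_dir, sprintf("tube_%02d.xyz", si)))
    }
  }

  network_summary <- NULL
  if (!is.null(config$network)) {
    nw <- config$network
    net <- generate_network(nw$box, nw$n_tubes, nw$length_range, nw$chirality,
                            nw$exclusion_gap, seed = config$seed)
    net <- detect_contacts(net)
    net <- suppressWarnings(seed_defects_at_contacts(net, seed = config$seed + 1L))
    hs <- hot_spot_map(net, seed = config$seed + 2L)
    net <- hs$net
    fac <- unlist(hs$factors)
    network_summary <- list(
      n_tubes = length(net$tubes),
      atom_count = network_atom_count(net),
      density_kg_m3 = network_density(net),
      n_contacts = nrow(net$contacts),
      n_defects = nrow(net$defect_assignments),
      hot_atom_fraction = mean(fac > 1),
      mean_overheat = if (any(fac > 1)) mean(fac[fac > 1]) - 1 else 0
    )
    if (!is.null(out_dir)) {
      write_contacts_json(net, file.path(out_dir, "network_contacts.json"))
      write_network(net, file.path(out_dir, "network.pdb"),
                    temperature_factors = hs$factors)
    }
  }

  cg <- lapply(config$cg_presets, function(p) {
    man <- cg_preset(p)
    list(preset = p, total_beads = man$total_beads,
         components = as.list(man$component_totals))
  })
  names(cg) <- config$cg_presets

  summary <- list(
    package_version = as.character(utils::packageVersion("swcntkit")),
    seed = config$seed,
    metallicity = census,
    semiconductor_fraction = attr(census, "semiconductor_fraction"),
    spectra = spectra,
    network = network_summary,
    cg = cg
  )
  class(summary) <- "pipeline_summary"
  if (!is.null(out_dir)) {
    js <- summary
    js$metallicity <- census
    jsonlite::write_json(unclass(js), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  summary
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("pipeline summary (swcntkit", x$package_version, ")\n")
  tab <- table(x$metallicity$metallicity)
  cat(sprintf("  tubes: %d (%d semiconducting / %d metallic, %.0f%% semiconducting)\n",
              nrow(x$metallicity), tab[["semiconducting"]], tab[["metallic"]],
              100 * x$semiconductor_fraction))
  for (nm in names(x$spectra)) {
    s <- x$spectra[[nm]]
    cat(sprintf("  %s: A_max = %.4f, %d peaks, range counts [%s]\n",
                nm, s$A_max, nrow(s$peaks),
                paste(s$peak_counts, collapse = ", ")))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d tubes, %d atoms, %.1f kg/m^3, %d contacts, %d defects\n",
                x$network$n_tubes, x$network$atom_count, x$network$density_kg_m3,
                x$network$n_contacts, x$network$n_defects))
  }
  for (nm in names(x$cg)) {
    cat(sprintf("  CG %s: %d beads\n", nm, x$cg[[nm]]$total_beads))
  }
  invisible(x)
}
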