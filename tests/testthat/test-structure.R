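test_that("periodic tubes are 3-regular with graphene-like bond lengths", {
  for (nm in list(c(4, 4), c(13, 0), c(12, 6), c(11, 10))) {
    tube <- build_periodic_tube(swnt_chirality(nm[1], nm[2]))
    deg <- atom_degrees(tube)
    expect_true(all(deg == 3L))
    bl <- bond_lengths(tube)
    expect_true(all(abs(bl / 0.142 - 1) < 0.05))
    expect_identical(nrow(tube$bonds), as.integer(3L * n_atoms(tube) / 2L))
  }
})

test_that("atom count scales with the number of periods", {
  ch <- swnt_chirality(12, 6)
  for (np in c(1L, 2L, 3L)) {
    expect_identical(n_atoms(build_periodic_tube(ch, np, bonds = FALSE)),
                     np * nt_atoms_per_cell(ch))
  }
  expect_error(build_periodic_tube(ch, 0), "positive integer")
})

test_that("pristine bond graph is bipartite (A/B sublattices)", {
  skip_if_not_installed("igraph")
  tube <- build_periodic_tube(swnt_chirality(12, 6))
  g <- igraph::graph_from_edgelist(cbind(tube$bonds$i, tube$bonds$j) + 1L, directed = FALSE)
  expect_true(igraph::bipartite_mapping(g)$res)
  # the builder's own sublattice labels 2-colour every bond
  s <- tube$sublattice
  expect_true(all(s[tube$bonds$i + 1L] != s[tube$bonds$j + 1L]))
})

test_that("finite tubes round down to whole periods and tag open ends", {
  t40 <- build_finite_tube(swnt_chirality(4, 4), 40)
  expect_identical(n_atoms(t40), 162L * 16L)   # floor(40 / 0.246) periods
  expect_identical(t40$cell$kind, "none")
  rim <- t40$defects[[1]]
  expect_identical(rim$kind, "open_end")
  expect_true(all(atom_degrees(t40)[rim$atoms + 1L] == 2L))
  expect_true(all(atom_degrees(t40)[setdiff(seq_len(n_atoms(t40)) - 1L, rim$atoms) + 1L] == 3L))

  # single period: every atom sits on a rim
  t1 <- build_finite_tube(swnt_chirality(4, 4), 0.246)
  expect_identical(n_atoms(t1), 16L)
  expect_identical(sort(t1$defects[[1]]$atoms), 0:15)

  # chiral tube at 38 nm: whole-period count from the analytic period
  Tlen <- sqrt(3) * 0.246 * sqrt(252) / 6
  expect_identical(n_atoms(build_finite_tube(swnt_chirality(12, 6), 38)),
                   as.integer(floor(38 / Tlen)) * 168L)
  expect_identical(as.integer(floor(38 / Tlen)) * 168L, 5544L)

  expect_error(build_finite_tube(swnt_chirality(12, 6), 0.5), "below one period")
})

test_that("single vacancy removes one atom and leaves three dangling sites", {
  tube <- build_periodic_tube(swnt_chirality(15, 15), 2)
  sv <- apply_defect(tube, defect_spec("SV", site = 17L))
  expect_identical(n_atoms(sv), n_atoms(tube) - 1L)
  deg <- atom_degrees(sv)
  expect_identical(sum(deg == 2L), 3L)
  tagged <- sv$defects[[1]]$atoms
  expect_identical(sort(which(deg == 2L) - 1L), sort(tagged))
})

test_that("double vacancy removes two bonded atoms", {
  tube <- build_periodic_tube(swnt_chirality(15, 15), 2)
  dv <- apply_defect(tube, defect_spec("DV", site = 17L, rng_seed = 4))
  expect_identical(n_atoms(dv), n_atoms(tube) - 2L)
  expect_identical(dv$defects[[1]]$kind, "DV")
})

test_that("Stone-Wales rotation keeps the atom count and makes 2+2 odd rings", {
  tube <- build_periodic_tube(swnt_chirality(20, 0), 3)
  expect_identical(unname(ring_census(tube)), c(0L, 0L, 0L, 120L, 0L))
  sw <- apply_defect(tube, defect_spec("SW", bond = 100L))
  expect_identical(n_atoms(sw), n_atoms(tube))
  census <- ring_census(sw)
  expect_identical(census[["5"]], 2L)
  expect_identical(census[["7"]], 2L)
  expect_identical(census[["6"]], 116L)
  expect_true(all(atom_degrees(sw) == 3L))   # SW preserves 3-regularity
})

test_that("mixed defect applies components in order: two SW + one vacancy", {
  tube <- build_periodic_tube(swnt_chirality(15, 15), 4)
  mixed <- defect_spec("MIXED", components = list(
    defect_spec("SW", bond = 10L), defect_spec("SW", bond = 250L),
    defect_spec("SV", site = 150L)))
  out <- suppressWarnings(apply_defect(tube, mixed))
  expect_identical(n_atoms(out), n_atoms(tube) - 1L)
  census <- ring_census(out)
  expect_identical(census[["5"]], 4L)   # two disjoint 5-7-7-5 patterns
  expect_identical(census[["7"]], 4L)
  expect_identical(vapply(out$defects, function(d) d$kind, character(1)),
                   c("SW", "SW", "SV"))
})

test_that("SW on a rim bond of a finite tube is rejected", {
  tube <- build_finite_tube(swnt_chirality(4, 4), 1.0)
  rim_atom <- tube$defects[[1]]$atoms[1]
  rim_bond <- which(tube$bonds$i == rim_atom | tube$bonds$j == rim_atom)[1] - 1L
  expect_error(apply_defect(tube, defect_spec("SW", bond = rim_bond)), "interior bond")
})

test_that("defects closer than two bond lengths warn unless overridden", {
  tube <- build_periodic_tube(swnt_chirality(15, 15), 2)
  one <- apply_defect(tube, defect_spec("SV", site = 17L))
  nb <- swcntkit:::.bonded_neighbours(tube, 17L)[1]
  expect_warning(apply_defect(one, defect_spec("SV", site = nb)), "two bond lengths")
  expect_silent(apply_defect(one, defect_spec("SV", site = nb), override = TRUE))
})

test_that("random site selection is deterministic under rng_seed", {
  tube <- build_periodic_tube(swnt_chirality(20, 0), 3)
  a <- apply_defect(tube, defect_spec("SW", rng_seed = 42))
  b <- apply_defect(tube, defect_spec("SW", rng_seed = 42))
  c <- apply_defect(tube, defect_spec("SW", rng_seed = 43))
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
})

test_that("XYZ round-trip is lossless (coordinates, cell, defect tags)", {
  tube <- apply_defect(build_periodic_tube(swnt_chirality(13, 0), 2),
                       defect_spec("SV", site = 30L))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_structure(tube, path)
  back <- read_structure(path)
  expect_identical(n_atoms(back), n_atoms(tube))
  expect_lt(max(abs(back$positions - tube$positions)), 1e-7)
  expect_equal(back$cell$period, tube$cell$period, tolerance = 1e-8)
  expect_identical(back$defects[[1]]$kind, "SV")
  expect_identical(sort(back$defects[[1]]$atoms), sort(tube$defects[[1]]$atoms))
  expect_identical(back$provenance$chirality$n, 13L)
})

test_that("PDB round-trip preserves coordinates to 1e-4 nm and metadata", {
  tube <- build_periodic_tube(swnt_chirality(4, 4), 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tube, path, b_factor = rep(1.18, n_atoms(tube)))
  back <- read_structure(path)
  expect_identical(n_atoms(back), n_atoms(tube))
  expect_lt(max(abs(back$positions - tube$positions)), 1e-4 + 1e-12)
  expect_equal(back$cell$period, tube$cell$period, tolerance = 1e-8)
  expect_identical(back$provenance$chirality$m, 4L)
})

test_that("I/O edge cases: empty structure, foreign elements, malformed files", {
  tube <- build_periodic_tube(swnt_chirality(4, 4))
  empty <- tube
  empty$positions <- tube$positions[0, , drop = FALSE]
  expect_error(write_structure(empty, tempfile(fileext = ".xyz")), "0 atoms")

  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "swcntkit unit=nm cell=none",
               "C 0 0 0", "N 0 0 0.142"), path)
  expect_warning(st <- read_structure(path), "non-carbon")
  expect_identical(st$elements, c("C", "N"))

  writeLines(c("not_a_count", "x"), path)
  expect_error(read_structure(path), "line 1")
  writeLines(c("3", "comment", "C 0 0 0", "C 0 0 bad", "C 0 0 1"), path)
  expect_error(read_structure(path), "line 4")
})
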