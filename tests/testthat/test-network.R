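test_that("segment distance matches hand-computable configurations", {
  # parallel unit segments one apart
  expect_equal(segment_distance(c(0, 0, 0), c(0, 0, 1), 5, c(1, 0, 0), c(0, 0, 1), 5), 1,
               tolerance = 1e-12)
  # collinear, gap of 2 between end points
  expect_equal(segment_distance(c(0, 0, 0), c(0, 0, 1), 3, c(0, 0, 5), c(0, 0, 1), 3), 2,
               tolerance = 1e-12)
  # crossing perpendicular segments
  expect_equal(segment_distance(c(-1, 0, 0), c(1, 0, 0), 2, c(0, -1, 0.5), c(0, 1, 0), 2),
               0.5, tolerance = 1e-12)
})

test_that("constructed contacts land at the constructed gap", {
  r <- nt_diameter(swnt_chirality(4, 4)) / 2
  net <- swcntkit:::new_swnt_network(c(20, 20, 20), c(4, 4))
  net <- place_tube(net, c(5, 5, 5), c(0, 0, 1), 5)
  net <- place_tube(net, c(5 + 2 * r + 0.3, 5, 5), c(0, 0, 1), 5)
  net <- detect_contacts(net)
  expect_identical(nrow(net$contacts), 1L)
  expect_equal(net$contacts$gap, 0.3, tolerance = 1e-9)
  expect_lt(abs(net$contacts$atom_gap - 0.3), 0.005)   # realizing atom pair

  far <- swcntkit:::new_swnt_network(c(20, 20, 20), c(4, 4))
  far <- place_tube(far, c(5, 5, 5), c(0, 0, 1), 5)
  far <- place_tube(far, c(5 + 2 * r + 0.5, 5, 5), c(0, 0, 1), 5)
  far <- detect_contacts(far)
  expect_identical(nrow(far$contacts), 0L)
})

test_that("contacts are found across the periodic boundary", {
  r <- nt_diameter(swnt_chirality(4, 4)) / 2
  net <- swcntkit:::new_swnt_network(c(15, 15, 15), c(4, 4))
  net <- place_tube(net, c(0.1, 7, 7), c(0, 0, 1), 5)
  net <- place_tube(net, c(15 - 0.25 - 2 * r + 0.1, 7, 7), c(0, 0, 1), 5)
  net <- detect_contacts(net)
  expect_identical(nrow(net$contacts), 1L)
  expect_equal(net$contacts$gap, 0.25, tolerance = 1e-9)
})

test_that("the generator enforces the exclusion gap; explicit placement does not", {
  net <- generate_network(c(18, 18, 18), 25, c(4, 7), c(4, 4), seed = 5)
  # post-hoc brute-force check of the exclusion invariant
  gaps <- c()
  for (i in seq_len(length(net$tubes) - 1)) for (j in (i + 1):length(net$tubes)) {
    gaps <- c(gaps, swcntkit:::.seg_dist_mi(net, i, j)$dist - 2 * net$tubes[[i]]$radius)
  }
  expect_gte(min(gaps), 0.34)

  # direct construction may violate it
  r <- nt_diameter(swnt_chirality(4, 4)) / 2
  tight <- swcntkit:::new_swnt_network(c(20, 20, 20), c(4, 4))
  tight <- place_tube(tight, c(5, 5, 5), c(0, 0, 1), 5)
  tight <- place_tube(tight, c(5 + 2 * r + 0.2, 5, 5), c(0, 0, 1), 5)
  expect_equal(swcntkit:::.seg_dist_mi(tight, 1, 2)$dist - 2 * r, 0.2, tolerance = 1e-9)
})

test_that("spatial-hash contact detection equals brute force exactly", {
  net <- generate_network(c(18, 18, 18), 50, c(3, 6), c(4, 4), seed = 11)
  sorted <- function(d) {
    d <- d[order(d$tube_i, d$tube_j), c("tube_i", "tube_j", "gap"), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  for (win in list(c(0.2, 0.4), c(0.34, 0.6), c(0.34, 1.0))) {
    a <- detect_contacts(net, win[1], win[2], method = "hash")$contacts
    b <- detect_contacts(net, win[1], win[2], method = "brute")$contacts
    expect_identical(sorted(a), sorted(b))
  }
  # at least one window must be non-trivial for the comparison to bite
  wide <- detect_contacts(net, 0.34, 1.0, method = "brute")$contacts
  expect_gt(nrow(wide), 0L)
  expect_error(detect_contacts(net, 0.5, 0.4), "d_min < d_max")
})

test_that("network generation is deterministic under seed", {
  a <- generate_network(c(15, 15, 15), 12, c(3, 6), c(4, 4), seed = 21)
  b <- generate_network(c(15, 15, 15), 12, c(3, 6), c(4, 4), seed = 21)
  c <- generate_network(c(15, 15, 15), 12, c(3, 6), c(4, 4), seed = 22)
  expect_identical(a$tubes, b$tubes)
  expect_false(identical(a$tubes, c$tubes))
  expect_error(generate_network(c(15, 15, 15), 12, c(3, 6), c(4, 4)), "seed")
  expect_error(generate_network(c(10, 10, 10), 2, c(12, 15), c(4, 4), seed = 1),
               "does not fit")
})

test_that("density is the closed-form carbon mass over box volume", {
  net <- swcntkit:::new_swnt_network(c(10, 10, 10), c(4, 4))
  net <- place_tube(net, c(5, 5, 0), c(0, 0, 1), 10)
  n_at <- network_atom_count(net)
  expect_identical(n_at, 40 * 16)                      # floor(10/0.246) periods
  expect_equal(network_density(net),
               n_at * 12.011 * 1.66054e-27 / 1e-24, tolerance = 1e-12)

  empty <- swcntkit:::new_swnt_network(c(10, 10, 10), c(4, 4))
  expect_identical(network_density(empty), 0)

  # intensive: duplicating the contents in a doubled box leaves it unchanged
  dbl <- swcntkit:::new_swnt_network(c(20, 10, 10), c(4, 4))
  dbl <- place_tube(dbl, c(5, 5, 0), c(0, 0, 1), 10)
  dbl <- place_tube(dbl, c(15, 5, 0), c(0, 0, 1), 10)
  expect_equal(network_density(dbl), network_density(net), tolerance = 1e-12)
})

test_that("defect seeding consumes contact atoms and is seed-stable", {
  r <- nt_diameter(swnt_chirality(4, 4)) / 2
  net <- swcntkit:::new_swnt_network(c(20, 20, 20), c(4, 4))
  net <- place_tube(net, c(5, 5, 5), c(0, 0, 1), 5)
  net <- place_tube(net, c(5 + 2 * r + 0.3, 5, 5), c(0, 0, 1), 5)
  net <- detect_contacts(net)
  seeded <- seed_defects_at_contacts(net, defect_kinds = "SV", seed = 3)
  expect_identical(nrow(seeded$defect_assignments), 2L)  # one SV per partner
  atoms_before <- vapply(1:2, function(i) {
    n_atoms(realize_tube(net, i)$structure)
  }, numeric(1))
  atoms_after <- vapply(1:2, function(i) n_atoms(seeded$structures[[i]]), numeric(1))
  expect_identical(sum(atoms_before) - sum(atoms_after), 2)

  again <- seed_defects_at_contacts(net, defect_kinds = "SV", seed = 3)
  expect_identical(seeded$defect_assignments, again$defect_assignments)

  none <- detect_contacts(swcntkit:::new_swnt_network(c(20, 20, 20), c(4, 4)))
  none_seeded <- seed_defects_at_contacts(none, seed = 1)
  expect_identical(nrow(none_seeded$defect_assignments), 0L)
})

test_that("hot spots sit exactly on defect and rim atoms with 16-20% overheat", {
  net <- generate_network(c(18, 18, 18), 20, c(3, 6), c(4, 4), seed = 7)
  net <- detect_contacts(net, 0.34, 0.6)
  net <- suppressWarnings(seed_defects_at_contacts(net, seed = 8))
  hs <- hot_spot_map(net, seed = 9)
  for (i in seq_along(hs$factors)) {
    st <- hs$net$structures[[i]]
    f <- hs$factors[[i]]
    hot <- swcntkit:::.defect_atoms(st)
    expect_true(all(f[hot + 1L] >= 1.16 & f[hot + 1L] <= 1.20))
    expect_true(all(f[setdiff(seq_along(f) - 1L, hot) + 1L] == 1))
  }
  f_all <- unlist(hs$factors)
  hot_vals <- f_all[f_all > 1]
  expect_gt(length(hot_vals), 200)                 # every rim is hot
  expect_equal(mean(hot_vals), 1.18, tolerance = 0.005)  # uniform midpoint
})

test_that("the study-scale network packs 258 tubes into the 65x45x40 nm box", {
  net <- generate_network(c(65, 45, 40), 258, c(5, 20), c(4, 4), seed = 42)
  expect_identical(length(net$tubes), 258L)
  # atom count equals the closed form over the sampled whole-period lengths
  expected <- sum(vapply(net$tubes, function(t) t$n_periods * 16, numeric(1)))
  expect_identical(network_atom_count(net), expected)
  # uniform 5-20 nm lengths put the count near 2.05e5 atoms
  expect_gt(network_atom_count(net), 1.7e5)
  expect_lt(network_atom_count(net), 2.4e5)
  expect_equal(network_density(net),
               network_atom_count(net) * 12.011 * 1.66054e-27 / (65 * 45 * 40 * 1e-27),
               tolerance = 1e-12)
  # all wrapped midpoints inside the box; exclusion on a sample of pairs
  for (tb in net$tubes[1:20]) {
    mid <- (tb$base + tb$axis * tb$length / 2) %% c(65, 45, 40)
    expect_true(all(mid >= 0 & mid <= c(65, 45, 40)))
  }
  set.seed(1)
  for (p in sample(258, 40)) {
    q <- sample(setdiff(1:258, p), 1)
    expect_gte(swcntkit:::.seg_dist_mi(net, p, q)$dist - 2 * net$tubes[[p]]$radius, 0.34)
  }
})

test_that("whole-network export wraps coordinates into the box", {
  net <- generate_network(c(12, 12, 12), 6, c(3, 5), c(4, 4), seed = 13)
  hs <- hot_spot_map(net, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_network(hs$net, path, temperature_factors = hs$factors)
  back <- read_structure(path)
  expect_identical(n_atoms(back), as.integer(network_atom_count(net)))
  expect_true(all(back$positions >= -1e-3 & back$positions <= 12 + 1e-3))
  expect_identical(back$cell$kind, "box")
})
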