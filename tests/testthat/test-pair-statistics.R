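test_that("minimum-image distances equal brute force over all 27 periodic images", {
  set.seed(19)
  box <- c(21, 27, 33)
  ref <- cbind(runif(12, -10, 40), runif(12, -10, 40), runif(12, -10, 40))
  oth <- cbind(runif(25, -10, 40), runif(25, -10, 40), runif(25, -10, 40))
  fast <- bilayr:::pair_dist_matrix(ref, oth, box)
  brute <- brute_min_image_dist(ref, oth, box)
  expect_equal(fast, brute, tolerance = 1e-12)

  # lateral-only imaging (the thickness convention)
  fast_xy <- bilayr:::pair_dist_matrix(ref, oth, box, image = c(TRUE, TRUE, FALSE))
  brute_xy <- brute_min_image_dist(ref, oth, box, image = c(TRUE, TRUE, FALSE))
  expect_equal(fast_xy, brute_xy, tolerance = 1e-12)
})


test_that("ideal-gas RDF is unity and its shell integral matches the coordination count", {
  tr <- ideal_gas_traj()
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  waters <- select_atoms(tr$topology, role = "water_O")
  rdf <- radial_distribution(tr, heads, waters,
    window = c(0, 1), dr = 1, r_max = 14
  )
  inner <- rdf$g[rdf$r >= 2 & rdf$r <= 14]
  expect_lt(mean(abs(inner - 1)), 0.02)
  expect_true(all(rdf$g >= 0))

  cutoff <- 8
  coord <- coordination_number(tr, heads, waters, cutoff, window = c(0, 1))
  rho <- attr(rdf, "rho")
  analytic <- 4 / 3 * pi * cutoff^3 * rho
  expect_equal(attr(coord, "mean"), analytic, tolerance = 0.05)
  chk <- consistency_check_rdf_coordination(rdf, coord)
  expect_equal(chk$integral, chk$coordination, tolerance = 0.05)
})

test_that("a single isolated pair lands in one bin with the closed-form g value", {
  n <- 2
  P0 <- cbind(c(50, 58), c(50, 50), c(10, -10)) # two lipids, irrelevant
  wat <- tibble::tibble(name = "OH2", resname = "TIP3", resid = 3L)
  wc <- array(c(50 + 3.02, 50, 10), c(1, 3, 1)) # 3.02 A from the first headgroup
  tr <- micro_traj(array(P0, c(n, 3, 1)),
    box = c(100, 100, 100),
    extra_atoms = wat, extra_coords = wc
  )
  heads <- select_atoms(tr$topology, name = "P")[1]
  waters <- select_atoms(tr$topology, role = "water_O")
  rdf <- radial_distribution(tr, heads, waters, window = c(0, 1), dr = 0.1, r_max = 10)
  occupied <- which(rdf$n_pairs > 0)
  expect_length(occupied, 1)
  expect_equal(rdf$r[occupied], 3.05)
  rho <- 1 / 100^3
  expect_equal(rdf$g[occupied], 1 / (4 * pi * 3.05^2 * rho * 0.1))
})

test_that("coordination counts planted neighbors exactly and matches a brute-force recount", {
  set.seed(31)
  n <- 4
  box <- c(40, 40, 40)
  P0 <- cbind(c(8, 28, 8, 28), c(8, 8, 28, 28), c(5, 5, -5, -5))
  cutoff <- 4
  # 3 planted inside the cutoff and 2 outside, per reference atom
  wrows <- list()
  wcoords <- list()
  for (i in 1:n) {
    for (j in 1:3) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      wcoords[[length(wcoords) + 1]] <- P0[i, ] + runif(1, 1.5, cutoff - 0.2) * u
    }
    for (j in 1:2) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      wcoords[[length(wcoords) + 1]] <- P0[i, ] + runif(1, cutoff + 0.5, 6) * u
    }
  }
  nw <- length(wcoords)
  wat <- tibble::tibble(name = "OH2", resname = "TIP3", resid = n + seq_len(nw))
  wc <- array(t(do.call(rbind, wcoords)), c(3, nw, 1))
  wc <- aperm(wc, c(2, 1, 3))
  tr <- micro_traj(array(P0, c(n, 3, 1)), box = box, extra_atoms = wat, extra_coords = wc)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  waters <- select_atoms(tr$topology, role = "water_O")
  coord <- coordination_number(tr, heads, waters, cutoff, window = c(0, 1))
  expect_equal(attr(coord, "mean"), 3.0)

  # brute-force O(n^2) recount with explicit images
  D <- brute_min_image_dist(
    matrix(tr$coords[heads, , 1], ncol = 3),
    matrix(tr$coords[waters, , 1], ncol = 3), box
  )
  expect_equal(attr(coord, "mean"), sum(D <= cutoff) / length(heads))

  # zero neighbors anywhere -> 0
  coord0 <- coordination_number(tr, heads, waters, 1.0, window = c(0, 1))
  expect_equal(attr(coord0, "mean"), 0)
})

test_that("coordination is monotone nondecreasing in the cutoff", {
  spec <- small_spec(n_frames = 4)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  waters <- select_atoms(tr$topology, role = "water_O")
  cuts <- c(2, 3.5, 4.85, 6, 8)
  means <- vapply(
    cuts,
    function(cc) attr(coordination_number(tr, heads, waters, cc, window = c(0, 1)), "mean"),
    numeric(1)
  )
  expect_true(all(diff(means) >= 0))
})

test_that("raw RDF pair counts are symmetric under selection swap", {
  spec <- small_spec(n_frames = 3)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  ns <- select_atoms(tr$topology, role = "choline_N")
  r1 <- radial_distribution(tr, heads, ns, window = c(0, 1), dr = 0.2, r_max = 12)
  r2 <- radial_distribution(tr, ns, heads, window = c(0, 1), dr = 0.2, r_max = 12)
  expect_equal(r1$n_pairs, r2$n_pairs)
})

test_that("same-residue exclusion removes intra-lipid pairs only", {
  spec <- small_spec(n_frames = 3)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  ns <- select_atoms(tr$topology, role = "choline_N")
  with_self <- coordination_number(tr, heads, ns, 6.75, "none", window = c(0, 1))
  without_self <- coordination_number(tr, heads, ns, 6.75, "same_residue", window = c(0, 1))
  # every lipid's own choline N sits at pn_length < cutoff, so the difference
  # is exactly one pair per reference atom
  expect_equal(attr(with_self, "mean") - attr(without_self, "mean"), 1.0)
})

test_that("self-RDF excludes self pairs", {
  spec <- small_spec(n_frames = 2)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  rdf <- radial_distribution(tr, heads, heads, window = c(0, 1), dr = 0.5, r_max = 10)
  expect_equal(sum(rdf$n_pairs[rdf$r < 0.5]), 0)
})

test_that("pair statistics validate their inputs", {
  spec <- small_spec(n_frames = 2)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  waters <- select_atoms(tr$topology, role = "water_O")
  expect_error(
    radial_distribution(tr, heads, waters, window = c(0, 1), r_max = 100),
    "half the minimum box edge"
  )
  expect_error(radial_distribution(tr, integer(0), waters), "empty selection")
  expect_error(coordination_number(tr, heads, waters, -1), "cutoff")
  expect_error(
    radial_distribution(tr, heads, c(heads[1], waters)),
    "disjoint or identical"
  )
})

test_that("the RDF integral reproduces the hydration count within the bin tolerance", {
  spec <- small_spec(n_frames = 10, n_waters = 400, hydration_count = 5)
  tr <- generate_bilayer(spec)
  heads <- select_atoms(tr$topology, role = "headgroup_center")
  waters <- select_atoms(tr$topology, role = "water_O")
  # dr chosen so the 4.85 A cutoff falls on a bin edge
  rdf <- radial_distribution(tr, heads, waters, window = c(0, 1), dr = 0.05, r_max = 10)
  coord <- coordination_number(tr, heads, waters, 4.85, window = c(0, 1))
  chk <- consistency_check_rdf_coordination(rdf, coord)
  expect_lt(chk$relative_discrepancy, 0.02)

  # parameter mismatch is rejected
  coord_excl <- coordination_number(tr, heads, waters, 4.85, "same_residue", window = c(0, 1))
  expect_error(consistency_check_rdf_coordination(rdf, coord_excl), "exclusion")
})
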