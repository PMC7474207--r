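test_that("contact map obeys separation and the strict overlap boundary", {
  # 3 residues: no pair with j - i >= 3
  st3 <- make_helix_bundle(1, 8, 0, 10)
  st3$residues <- st3$residues[1:3, ]
  st3$atoms <- st3$atoms[st3$atoms$residue_index <= 3, ]
  expect_equal(nrow(build_contact_map(st3)), 0)

  # CA-only residues 1 and 5 along x; boundary at 1.24 * (1.70 + 1.70)
  lim <- 1.24 * (1.70 + 1.70)
  place <- function(d) {
    xyz <- rbind(c(0, 0, 0), c(0, 50, 0), c(0, 100, 0), c(0, 150, 0),
                 c(d, 0, 0))
    f <- tempfile(fileext = ".pdb")
    on.exit(unlink(f))
    suppressWarnings(read_pdb_calpha(write_mini_pdb(f, xyz)))
  }
  expect_equal(nrow(suppressWarnings(build_contact_map(place(lim + 0.01)))), 0)
  expect_equal(nrow(suppressWarnings(build_contact_map(place(lim - 0.01)))), 1)
})

test_that("contact map equals the brute-force oracle and grows with enlargement", {
  st <- make_helix_bundle(2, 10, 3, 10)
  map <- build_contact_map(st)
  oracle <- brute_force_contact_map(st)
  expect_equal(as.data.frame(map)[, c("i", "j")],
               oracle[, c("i", "j")], ignore_attr = TRUE)
  expect_equal(map$native_distance, oracle$native_distance, tolerance = 1e-12)

  counts <- vapply(c(1.0, 1.24, 1.5),
                   function(e) nrow(build_contact_map(st, enlargement = e)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("calpha fallback exists and no-heavy-atom structures are rejected", {
  st <- make_helix_bundle(2, 10, 3, 10)
  bare <- st
  bare$atoms <- bare$atoms[0, ]
  expect_error(build_contact_map(bare), "calpha")
  fb <- build_contact_map(st, method = "calpha", ca_cutoff = 7.5)
  expect_true(all(fb$native_distance < 7.5))
  expect_true(all(fb$j - fb$i >= 3))
})

test_that("build_topology instantiates the stated force-field parameters", {
  st <- make_helix_bundle(2, 10, 3, 10)
  map <- build_contact_map(st)
  topo <- build_topology(st, map)
  expect_equal(topo$contacts$sigma, map$native_distance / 2^(1 / 6))
  expect_equal(topo$contacts$eps, rep(1, nrow(map)))
  expect_equal(topo$bonds$r0, consecutive_ca_distances(st$residues))
  # native contact at 6.0 A -> sigma = 6 / 2^(1/6)
  toy <- two_bead_toy(r0 = 6)
  expect_equal(toy$contacts$sigma, 6 / 2^(1 / 6), tolerance = 1e-12)
  expect_equal(6 / 2^(1 / 6), 5.346, tolerance = 1e-3)

  # 2-residue chain: 1 bond, 0 chirality, 0 contacts
  st2 <- st
  st2$residues <- st2$residues[1:2, ]
  st2$atoms <- st2$atoms[st2$atoms$residue_index <= 2, ]
  t2 <- build_topology(st2, build_contact_map(st2))
  expect_equal(nrow(t2$bonds), 1)
  expect_equal(nrow(t2$chirality), 0)
  expect_equal(nrow(t2$contacts), 0)

  # deterministic rebuild
  expect_identical(build_topology(st, map), build_topology(st, map))

  # contact referencing an absent residue
  bad <- map
  bad$j[1] <- 999
  expect_error(build_topology(st, bad), "absent")
})

test_that("native pair energies hit the LJ landmarks", {
  toy <- two_bead_toy(r0 = 5)
  at <- function(r) energy_forces(toy, rbind(c(0, 0, 0), c(r, 0, 0)))
  mini <- at(5)
  expect_equal(mini$energy$native_lj, -1, tolerance = 1e-12)
  expect_equal(max(abs(mini$forces)), 0, tolerance = 1e-10)
  expect_equal(at(5 / 2^(1 / 6))$energy$native_lj, 0, tolerance = 1e-10)
  expect_equal(mini$energy$total,
               with(mini$energy, bonds + chirality + native_lj + repulsive +
                      pulling_springs),
               tolerance = 1e-10)
})

test_that("non-native repulsion is truncated and shifted at 4 A", {
  # 4 beads; pair (1, 4) is non-native with j - i = 3
  topo <- toy_topology(4)
  pos_at <- function(d) rbind(c(0, 0, 0), c(0, 60, 0), c(0, 120, 0),
                              c(d, 0, 0))
  expect_equal(energy_forces(topo, pos_at(4.0))$energy$repulsive, 0,
               tolerance = 1e-12)
  expect_equal(energy_forces(topo, pos_at(4.5))$energy$repulsive, 0,
               tolerance = 1e-12)
  e35 <- energy_forces(topo, pos_at(3.5))
  expect_gt(e35$energy$repulsive, 0)
  expect_gt(abs(e35$forces[4, 1]), 0)
  expect_error(energy_forces(topo, pos_at(0)), "coincident")
})

test_that("forces are the exact negative gradient (finite differences)", {
  fx <- bundle_fixture()
  set.seed(42)
  x <- ca_coords(fx$structure) +
    matrix(rnorm(3 * fx$topology$n_residues, sd = 0.35), ncol = 3)
  f <- energy_forces(fx$topology, x)$forces
  h <- 1e-6
  tot <- function(p) energy_forces(fx$topology, p)$energy$total
  picks <- rbind(c(1, 1), c(17, 2), c(36, 3), c(50, 1), c(72, 3))
  for (k in seq_len(nrow(picks))) {
    i <- picks[k, 1]; d <- picks[k, 2]
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num <- -(tot(xp) - tot(xm)) / (2 * h)
    expect_equal(f[i, d], num, tolerance = 1e-6)
  }
})

test_that("energy is invariant under rigid motions", {
  fx <- bundle_fixture()
  set.seed(3)
  x <- ca_coords(fx$structure) + matrix(rnorm(216, sd = 0.2), ncol = 3)
  e0 <- energy_forces(fx$topology, x)$energy$total
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  e1 <- energy_forces(fx$topology,
                      sweep(x %*% R, 2, c(12, -7, 3), "+"))$energy$total
  expect_equal(e0, e1, tolerance = 1e-8)
})

test_that("contact map and topology serialize losslessly", {
  st <- make_helix_bundle(2, 10, 3, 10)
  map <- build_contact_map(st)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(map, f)
  map2 <- read_contact_map(f, n_residues = nrow(st$residues))
  expect_equal(as.data.frame(map2), as.data.frame(map), tolerance = 1e-12,
               ignore_attr = TRUE)

  topo <- build_topology(st, map)
  fj <- withr::local_tempfile(fileext = ".json")
  write_topology(topo, fj)
  topo2 <- read_topology(fj)
  expect_equal(topo2$contacts$sigma, topo$contacts$sigma, tolerance = 1e-12)
  expect_equal(topo2$native_positions, unname(topo$native_positions),
               tolerance = 1e-12)
  e1 <- energy_forces(topo, ca_coords(st))$energy$total
  e2 <- energy_forces(topo2, ca_coords(st))$energy$total
  expect_equal(e1, e2, tolerance = 1e-10)
})
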