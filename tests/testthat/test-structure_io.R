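test_that("read_pdb_calpha reads a minimal file back verbatim", {
  f <- withr::local_tempfile(fileext = ".pdb")
  xyz <- rbind(c(1.234, 2.500, -3.750), c(4.004, 4.300, -2.100),
               c(6.804, 6.100, -0.450))
  write_mini_pdb(f, xyz)
  st <- read_pdb_calpha(f)
  expect_equal(nrow(st$residues), 3)
  expect_equal(unname(ca_coords(st)), xyz, tolerance = 1e-12)
  expect_equal(st$chain_id, "A")
  expect_error(read_pdb_calpha(f, chain = "Z"), "chain 'Z' not present")
})

test_that("altloc resolves to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  ALA A   2       4.500   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, f)
  st <- suppressWarnings(read_pdb_calpha(f))
  expect_equal(unname(ca_coords(st)[1, 1]), 1.0)
})

test_that("reader flags gaps, missing CA, and out-of-range requests", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   5       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, f)
  expect_warning(st <- read_pdb_calpha(f), "gap")
  expect_match(st$warnings, "gap", all = FALSE)
  expect_error(suppressWarnings(read_pdb_calpha(f, residue_range = c(90, 95))),
               "range")
  lines2 <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines2, f)
  expect_error(read_pdb_calpha(f), "without a CA")
})

test_that("PDB write/read round trip preserves coordinates to 3 decimals", {
  st <- make_helix_bundle(2, 10, 3, 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_calpha(st, f)
  st2 <- read_pdb_calpha(f)
  expect_equal(ca_coords(st2), ca_coords(st), tolerance = 1e-3)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
})

test_that("helix detector finds ideal helices and rejects extended chains", {
  one <- make_helix_bundle(1, 20, 0, 10)
  ann <- assign_helices(one)
  expect_equal(nrow(ann$segments), 1)
  expect_gte(ann$segments$end - ann$segments$start + 1, 16)

  ext <- straight_chain(20)
  expect_equal(sum(assign_helices(ext)$per_residue_helical), 0)

  expect_equal(nrow(assign_helices(straight_chain(4))$segments), 0)
})

test_that("detector matches generator ground truth across bundle sizes", {
  for (nh in c(2, 4, 5)) {
    for (len in c(10, 15)) {
      st <- make_helix_bundle(nh, len, 4, 10)
      ann <- assign_helices(st)
      expect_equal(nrow(ann$segments), nh)
      expect_equal(ann$segments$label, paste0("H", seq_len(nh)))
      agree <- mean(ann$per_residue_helical ==
                      st$helix_ground_truth$per_residue_helical)
      expect_gte(agree, 0.9)
    }
  }
})

test_that("make_helix_bundle geometry follows the ideal-helix oracle", {
  one <- make_helix_bundle(1, 10, 0, 10)
  # oracle from the stated construction: rise 1.5/res, 100 deg/res, r 2.3
  j <- 0:9
  xyz <- cbind(2.3 * cos(j * 100 * pi / 180), 2.3 * sin(j * 100 * pi / 180),
               1.5 * j)
  expect_equal(unname(ca_coords(one)), unname(xyz), tolerance = 1e-10)
  e2e <- end_to_end(one)
  expect_equal(e2e, sqrt(sum((xyz[10, ] - xyz[1, ])^2)))
  expect_lt(abs(e2e - 13.5), 1.0)  # dominated by the 9 x 1.5 A rise

  # consecutive spacing within 3.8 +/- 0.1 away from loop junctions
  st <- make_helix_bundle(3, 12, 4, 10)
  d <- consecutive_ca_distances(st$residues)
  seg <- st$helix_ground_truth$segments
  in_helix <- logical(length(d))
  for (s in seq_len(nrow(seg)))
    in_helix[seg$start[s]:(seg$end[s] - 1)] <- TRUE
  expect_true(all(abs(d[in_helix] - 3.8) <= 0.1))
})

test_that("bundle generation is deterministic and validates arguments", {
  a <- make_helix_bundle(4, 15, 4, 10, seed = 7, jitter = 0.1)
  b <- make_helix_bundle(4, 15, 4, 10, seed = 7, jitter = 0.1)
  expect_identical(ca_coords(a), ca_coords(b))
  c <- make_helix_bundle(4, 15, 4, 10, seed = 8, jitter = 0.1)
  expect_false(identical(ca_coords(a), ca_coords(c)))
  expect_error(make_helix_bundle(2, 10, 3, packing_distance = 4),
               "packing_distance")
})

test_that("2-helix bundle at 10 A packing forms inter-helix contacts", {
  st <- make_helix_bundle(2, 12, 3, 10)
  map <- build_contact_map(st)
  seg <- st$helix_ground_truth$segments
  h1 <- seq(seg$start[1], seg$end[1])
  h2 <- seq(seg$start[2], seg$end[2])
  inter <- map$i %in% h1 & map$j %in% h2
  expect_gte(sum(inter), 1)
})
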