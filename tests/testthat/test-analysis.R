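# morph fixture: linear interpolation from the native bundle to a straight
# chain, a deterministic stand-in for an unfolding trajectory
morph_frames <- function(structure, n_frames = 15) {
  x0 <- ca_coords(structure)
  x1 <- straight_chain(nrow(x0))
  lapply(seq(0, 1, length.out = n_frames), function(a) (1 - a) * x0 + a * x1)
}

test_that("helicity trace is exact on native frames and dies when extended", {
  fx <- bundle_fixture()
  frames <- morph_frames(fx$structure)
  tr <- helicity_trace(frames)
  native_frac <- mean(assign_helices(fx$structure)$per_residue_helical)
  expect_equal(tr$fraction_helical[1], native_frac)
  expect_equal(tr$fraction_helical[nrow(tr)], 0)
  # monotone within detector noise on the morph
  expect_true(all(diff(tr$fraction_helical) <= 0.1))
  expect_true(all(tr$fraction_helical >= 0 & tr$fraction_helical <= 1))
})

test_that("pair contact fractions are 1 at native and 0 for removed helices", {
  fx <- bundle_fixture()
  x0 <- ca_coords(fx$structure)
  seg <- fx$annotation$segments
  moved <- x0
  h1 <- seg$start[1]:seg$end[1]
  moved[h1, 1] <- moved[h1, 1] + 50
  Q <- helix_pair_contact_fraction(list(x0, moved), fx$map, fx$annotation)
  expect_true(all(Q[1, ] == 1))
  h1cols <- grepl("^H1:|:H1$", colnames(Q))
  expect_true(all(Q[2, h1cols] == 0))
  expect_true(all(Q[2, !h1cols] == 1))

  # morph: Q non-increasing per pair within tolerance
  Qm <- helix_pair_contact_fraction(morph_frames(fx$structure), fx$map,
                                    fx$annotation)
  expect_true(all(apply(Qm, 2, function(q) all(diff(q) <= 0.15))))
})

test_that("pairs without native contacts are absent, not 0/0", {
  fx <- bundle_fixture()
  ann <- fx$annotation
  # fabricate an extra 'helix' in the first loop: it has no tertiary contacts
  ann$segments <- rbind(ann$segments,
                        data.frame(label = "H9", start = 16, end = 19))
  Q <- helix_pair_contact_fraction(list(ca_coords(fx$structure)), fx$map, ann)
  expect_false(any(grepl("H9", colnames(Q))))
})

test_that("classify_state counts attached helices through max pairwise Q", {
  ann <- list(segments = data.frame(label = paste0("H", 1:5),
                                    start = seq(1, 81, by = 20),
                                    end = seq(15, 95, by = 20)))
  class(ann) <- "HelixAnnotation"
  pairs <- combn(paste0("H", 1:5), 2)
  qn <- paste0(pairs[1, ], ":", pairs[2, ])
  q_native <- setNames(rep(1, length(qn)), qn)
  s <- classify_state(q_native, ann)
  expect_equal(s$label, "five-helix")
  expect_equal(s$n_attached, 5)

  # H1 and H5 detached -> three-helix formed by H2-H4
  q <- q_native
  q[grepl("H1|H5", qn)] <- 0.1
  s3 <- classify_state(q, ann)
  expect_equal(s3$label, "three-helix")
  expect_equal(sort(s3$attached), c("H2", "H3", "H4"))

  s0 <- classify_state(setNames(rep(0.2, length(qn)), qn), ann)
  expect_equal(s0$label, "zero-helix")
  expect_equal(s0$n_attached, 0)
})

test_that("classify_state is invariant under helix relabeling", {
  ann <- list(segments = data.frame(label = paste0("H", 1:4),
                                    start = c(1, 21, 41, 61),
                                    end = c(15, 35, 55, 75)))
  class(ann) <- "HelixAnnotation"
  q <- c("H1:H2" = 0.9, "H2:H3" = 0.1, "H3:H4" = 0.8, "H1:H4" = 0.05,
         "H1:H3" = 0.02, "H2:H4" = 0.03)
  s <- classify_state(q, ann)
  # relabel helices by the permutation 1<->4, 2<->3
  perm <- c(H1 = "H4", H2 = "H3", H3 = "H2", H4 = "H1")
  qs <- strsplit(names(q), ":")
  names(q) <- vapply(qs, function(p)
    paste(sort(perm[p]), collapse = ":"), character(1))
  s2 <- classify_state(q, ann)
  expect_equal(sort(unname(perm[s$attached])), sort(s2$attached))
  expect_equal(s$label, s2$label)
})

test_that("intermediate_call applies hysteresis and reports detachments", {
  ann <- list(segments = data.frame(label = paste0("H", 1:3),
                                    start = c(1, 21, 41), end = c(15, 35, 55)))
  class(ann) <- "HelixAnnotation"
  nf <- 60
  ext <- seq(10, 128, length.out = nf)
  # H1:H2 breaks around frame 20; H2:H3 around frame 40; add flicker
  q12 <- c(rep(1, 15), 0.55, 0.45, 0.55, 0.45, rep(0.1, nf - 19))
  q23 <- c(rep(1, 39), rep(0.05, nf - 39))
  Q <- cbind("H1:H2" = q12, "H2:H3" = q23)
  ic <- intermediate_call(Q, ext, ann, q_smooth = 0, min_dwell = 3)
  expect_equal(ic$state_sequence, c("three-helix", "two-helix", "zero-helix"))
  expect_true(all(diff(ic$n_attached) <= 0))
  expect_lt(ic$detachment_extension["H1"], ic$detachment_extension["H2"])
})

test_that("unfolding events are located on constructed profiles", {
  x <- seq(0, 100, by = 1)
  lin <- data.frame(rc = x, free_energy = 0.2 * x)
  expect_equal(nrow(unfolding_events_from_pmf(lin)), 0)

  y <- 0.1 * x
  y[x >= 40 & x <= 45] <- y[x >= 40 & x <= 45] + (x[x >= 40 & x <= 45] - 40)
  one <- unfolding_events_from_pmf(data.frame(rc = x, free_energy = cummax(y)),
                                   min_rise = 3)
  expect_equal(nrow(one), 1)
  expect_true(one$rc >= 38 && one$rc <= 47)

  y2 <- 0.1 * x
  for (c0 in c(30, 70))
    y2[x >= c0 & x <= c0 + 4] <- y2[x >= c0 & x <= c0 + 4] +
      2 * (x[x >= c0 & x <= c0 + 4] - c0)
  two <- unfolding_events_from_pmf(data.frame(rc = x, free_energy = y2),
                                   min_rise = 3)
  expect_equal(nrow(two), 2)
  expect_true(all(diff(two$rc) > 0))
  expect_lt(abs(two$rc[1] - 32), 5)
  expect_lt(abs(two$rc[2] - 72), 5)
})
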