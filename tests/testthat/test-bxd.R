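# minimal constructor for synthetic per-box statistics
fake_stats <- function(df, kT = 0.3) {
  attr(df, "kT") <- kT
  class(df) <- c("BXDStats", "data.frame")
  df
}

test_that("box partitioning covers the range with half-open boxes", {
  cfg <- bxd_config(10, 25, box_width = 5)
  expect_equal(partition_boxes(cfg), c(10, 15, 20, 25))
  expect_warning(b <- partition_boxes(bxd_config(10, 23, box_width = 5)),
                 "truncated")
  expect_equal(b, c(10, 15, 20, 23))
  expect_error(bxd_config(10, 18, box_width = 5), "two boxes")
  expect_error(bxd_config(10, 25, box_width = -1))
})

test_that("free 1D diffusion hits both walls at equal rates", {
  cfg <- bxd_config(-2, 2, box_width = 2, events_per_box = 4000,
                    max_steps_per_box = 1e7)
  stats <- run_bxd(list(potential = "free", p = 0, x0 = -1), cfg,
                   langevin_params(kT = 0.3, gamma = 2, dt = 0.005), seed = 2)
  # wall hits come in correlated bursts, so Poisson errors do not apply;
  # use a block estimate of the up-lo difference instead
  log1 <- attr(stats, "hit_log")
  log1 <- log1[log1$box == 1, ]
  blocks <- cut(log1$time, breaks = 20)
  d_k <- tapply(ifelse(log1$wall == "upper", 1, -1), blocks, sum)
  d_k[is.na(d_k)] <- 0
  D <- sum(d_k)
  se <- sd(d_k) * sqrt(length(d_k))
  expect_lt(abs(D), 3 * se)
})

test_that("a linear potential biases hits downhill", {
  cfg <- bxd_config(1, 5, box_width = 2, events_per_box = 2000,
                    max_steps_per_box = 1e7)
  stats <- run_bxd(list(potential = "linear", p = 1.5, x0 = 1.5), cfg,
                   langevin_params(kT = 0.3, gamma = 2, dt = 0.005), seed = 3)
  expect_gt(stats$hits_lower[1], stats$hits_upper[1])
})

test_that("BXD runs are deterministic given the master seed", {
  cfg <- bxd_config(0, 2, box_width = 1, events_per_box = 300,
                    max_steps_per_box = 1e7)
  sys <- list(potential = "harmonic", p = 1, x0 = 0.4)
  s1 <- run_bxd(sys, cfg, seed = 5)
  s2 <- run_bxd(sys, cfg, seed = 5)
  expect_identical(attr(s1, "hit_log"), attr(s2, "hit_log"))
})

test_that("rate constants are hit counts over residence time", {
  st <- fake_stats(data.frame(
    box = 1:2, lo = c(0, 5), hi = c(5, 10),
    hits_upper = c(10, 0), hits_lower = c(5, 8),
    residence_time = c(5, 4),
    hits_first_half = c(7, 4), hits_second_half = c(8, 4)))
  r <- rates_from_stats(st)
  expect_equal(r$k_forward, 2)       # 10 hits in 5 tau
  expect_equal(r$k_backward, 2)      # 8 hits in 4 tau
  st2 <- st
  st2$residence_time <- st$residence_time * 2
  expect_equal(rates_from_stats(st2)$k_forward, 1)  # doubling time halves k
  st3 <- st
  st3$hits_upper[1] <- 0
  expect_error(rates_from_stats(st3), "more events")
})

test_that("PMF assembly anchors at zero and applies -kT log K", {
  r <- structure(data.frame(boundary = 5, k_forward = exp(1), k_backward = 1,
                            n_forward = 1000, n_backward = 1000),
                 box_centers = c(2.5, 7.5), kT = 0.3,
                 class = c("BXDRates", "data.frame"))
  pmf <- pmf_from_rates(r)
  expect_equal(pmf$free_energy, c(0, -0.3), tolerance = 1e-12)

  # detailed-balance identity: equal rates give a flat profile
  rf <- structure(data.frame(boundary = c(1, 2), k_forward = c(2, 3),
                             k_backward = c(2, 3), n_forward = c(50, 50),
                             n_backward = c(50, 50)),
                  box_centers = c(0.5, 1.5, 2.5), kT = 0.3,
                  class = c("BXDRates", "data.frame"))
  expect_equal(pmf_from_rates(rf)$free_energy, c(0, 0, 0))
  rf$k_backward[1] <- 0
  expect_error(pmf_from_rates(rf), "non-positive")
})

test_that("BXD error against the box-weight oracle shrinks with more events", {
  p1 <- langevin_params(kT = 0.3, gamma = 2, dt = 0.001)
  bounds <- seq(0, 2, by = 0.5)
  oracle <- box_weight_pmf(bounds, "harmonic", 1, kT = 0.3)
  err_at <- function(events, seeds) {
    G <- vapply(seeds, function(r)
      bxd_pmf(run_bxd(list(potential = "harmonic", p = 1, x0 = 0.2),
                      bxd_config(0, 2, 0.5, events, max_steps_per_box = 1e8),
                      p1, seed = r))$free_energy, numeric(4))
    mean(abs(G - oracle))
  }
  e_small <- err_at(500, 1:12)
  e_large <- err_at(2000, 1:12)
  expect_lt(e_large, e_small)
  expect_lt(err_at(2000, 101:112), 0.15)
})

test_that("halving the box width leaves the 1D PMF invariant", {
  params <- langevin_params(kT = 0.3, gamma = 2, dt = 0.001)
  sys <- list(potential = "harmonic", p = 1, x0 = 0.2)
  mean_pmf <- function(cfg, seeds) {
    rowMeans(vapply(seeds, function(r)
      bxd_pmf(run_bxd(sys, cfg, params, seed = r))$free_energy,
      numeric((cfg$rc_max - cfg$rc_min) / cfg$box_width)))
  }
  wide_cfg <- bxd_config(0, 2, 0.5, 1500, max_steps_per_box = 2e7)
  narrow_cfg <- bxd_config(0, 2, 0.25, 1500, max_steps_per_box = 2e7)
  wide <- mean_pmf(wide_cfg, 1:8)
  narrow <- mean_pmf(narrow_cfg, 11:18)
  g <- approx(seq(0.125, by = 0.25, length.out = 8), narrow,
              xout = seq(0.25, by = 0.5, length.out = 4))$y
  off <- g[1] - wide[1]
  expect_lt(max(abs(g - off - wide)), 0.15)
})

test_that("equilibration check flags drifting and sparse boxes", {
  st <- fake_stats(data.frame(
    box = 1:3, lo = c(0, 1, 2), hi = c(1, 2, 3),
    hits_upper = c(500, 550, 10), hits_lower = c(500, 550, 12),
    residence_time = c(10, 10, 10),
    hits_first_half = c(495, 1000, 11), hits_second_half = c(505, 100, 11)))
  chk <- equilibration_check(st)
  expect_equal(chk$status, c("pass", "fail", "insufficient data"))
})

test_that("starting outside the first box is rejected", {
  cfg <- bxd_config(0, 2, box_width = 1, events_per_box = 100)
  expect_error(run_bxd(list(potential = "free", p = 0, x0 = 1.5), cfg,
                       seed = 1), "first box")
})

test_that("an unreachable event quota errors naming the box", {
  cfg <- bxd_config(0, 2, box_width = 1, events_per_box = 5000,
                    max_steps_per_box = 200)
  expect_error(run_bxd(list(potential = "harmonic", p = 1, x0 = 0.5), cfg,
                       seed = 1), "box 1")
})
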