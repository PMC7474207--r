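#' Boxed-dynamics (BXD) configuration
#'
#' BXD splits the reaction coordinate (here the end-to-end distance) into
#' contiguous boxes in which the trajectory is locked; every attempted wall
#' crossing counts as a "hit" and is reflected in the reaction-coordinate
#' direction. After `events_per_box` hits (both walls pooled) the trajectory
#' is released through the upper wall and the sweep continues toward the
#' unfolded state. Defaults follow the production protocol: 5 A (0.5 nm)
#' boxes and 1000-2000 events per box.
#'
#' @param rc_min,rc_max reaction-coordinate range, A
#' @param box_width box width, A
#' @param events_per_box hit quota per box
#' @param max_steps_per_box safeguard against unreachable quotas
#' @param equil_events_per_box uncounted burn-in hits after entering a box
#'   (the trajectory arrives through the lower wall; counting immediately
#'   biases the early statistics toward that wall). Default 10% of
#'   `events_per_box`.
#' @return a `BXDConfig`
#' @export
bxd_config <- function(rc_min, rc_max, box_width = 5, events_per_box = 2000,
                       max_steps_per_box = 5e6,
                       equil_events_per_box = ceiling(events_per_box / 10)) {
  stopifnot(box_width > 0, events_per_box >= 2)
  if ((rc_max - rc_min) / box_width < 2)
    stop("range must cover at least two boxes")
  structure(list(rc_min = rc_min, rc_max = rc_max, box_width = box_width,
                 events_per_box = as.integer(events_per_box),
                 max_steps_per_box = max_steps_per_box,
                 equil_events_per_box = as.integer(equil_events_per_box)),
            class = "BXDConfig")
}

#' Partition the reaction coordinate into boxes
#'
#' Contiguous half-open intervals `[b_m, b_m+1)` covering
#' `[rc_min, rc_max)`; the last box is closed. A range that is not an
#' integer number of widths gets a truncated final box (with a warning).
#'
#' @param config a `BXDConfig`
#' @return numeric vector of box boundaries (length = boxes + 1)
#' @export
partition_boxes <- function(config) {
  if (config$box_width <= 0) stop("box width must be positive")
  b <- seq(config$rc_min, config$rc_max, by = config$box_width)
  if (tail(b, 1) < config$rc_max) {
    warning(sprintf("range not divisible by box width; final box [%g, %g] %s",
                    tail(b, 1), config$rc_max, "is truncated"),
            call. = FALSE)
    b <- c(b, config$rc_max)
  }
  b
}

#' Run a BXD sweep from the folded toward the unfolded state
#'
#' `system` is either a `GoTopology` (the reaction coordinate is the
#' end-to-end distance; supply `positions` with rc inside the first box) or
#' a 1D analytic system `list(potential =, p =, x0 =)` as in
#' [simulate_1d()]. Each box gets an independent seed derived from `seed`,
#' so boxes are reproducible in isolation.
#'
#' @param system `GoTopology` or 1D system description
#' @param config `BXDConfig`
#' @param params `LangevinParams`
#' @param seed master seed
#' @param positions starting coordinates (coarse-grained systems)
#' @return a `BXDStats`: per-box data.frame plus a hit log, the
#'   configuration and the thermostat in attributes
#' @export
run_bxd <- function(system, config, params = langevin_params(), seed = 1,
                    positions = NULL) {
  bounds <- partition_boxes(config)
  nbox <- length(bounds) - 1
  set.seed(seed)
  box_seeds <- sample.int(.Machine$integer.max, nbox)
  is_cg <- inherits(system, "GoTopology")
  if (is_cg) {
    if (is.null(positions)) positions <- system$native_positions
    rc0 <- end_to_end(positions)
    ct <- .cpp_topology(system)
  } else {
    rc0 <- system$x0
  }
  if (rc0 < bounds[1] || rc0 >= bounds[2])
    stop(sprintf("initial reaction coordinate %.2f not inside first box [%g, %g)",
                 rc0, bounds[1], bounds[2]))

  per_box <- vector("list", nbox)
  hit_log <- vector("list", nbox)
  x1d <- if (!is_cg) system$x0 else NULL
  pot <- if (!is_cg) .POTENTIALS[match.arg(system$potential,
                                           names(.POTENTIALS))] else NULL
  for (m in seq_len(nbox)) {
    release <- m < nbox
    if (is_cg) {
      r <- cpp_cg_bxd_box(ct, as.matrix(positions), params$kT, params$gamma,
                          params$dt, box_seeds[m], bounds[m], bounds[m + 1],
                          config$events_per_box, config$max_steps_per_box,
                          release, config$equil_events_per_box)
      positions <- r$positions
    } else {
      r <- cpp_bd1d_bxd_box(pot, system$p, x1d, params$kT, params$gamma,
                            params$dt, box_seeds[m], bounds[m], bounds[m + 1],
                            config$events_per_box, config$max_steps_per_box,
                            release, !params$overdamped, params$mass,
                            config$equil_events_per_box)
      x1d <- r$x
    }
    if (!r$quota_reached || (release && !r$released))
      stop(sprintf(paste0("box %d [%g, %g): event quota not reached within ",
                          "max_steps_per_box; increase max_steps_per_box, ",
                          "events or use smaller boxes"),
                   m, bounds[m], bounds[m + 1]))
    half <- r$residence_time / 2
    per_box[[m]] <- data.frame(
      box = m, lo = bounds[m], hi = bounds[m + 1],
      hits_upper = r$hits_upper, hits_lower = r$hits_lower,
      residence_time = r$residence_time,
      hits_first_half = sum(r$hit_time <= half),
      hits_second_half = sum(r$hit_time > half))
    hit_log[[m]] <- if (length(r$hit_time))
      data.frame(box = m, wall = ifelse(r$hit_wall == 1, "upper", "lower"),
                 time = r$hit_time) else NULL
  }
  stats <- do.call(rbind, per_box)
  attr(stats, "hit_log") <- do.call(rbind, hit_log)
  attr(stats, "config") <- config
  attr(stats, "kT") <- params$kT
  attr(stats, "final_positions") <- if (is_cg) positions else x1d
  class(stats) <- c("BXDStats", "data.frame")
  stats
}

#' Box-to-box rate constants from BXD statistics
#'
#' The rate of going from box m to box m+1 is the inverse mean time between
#' upper-wall hits in box m, `hits_upper(m) / residence_time(m)`; the
#' backward rate uses the lower-wall hits of box m+1.
#'
#' @param stats a `BXDStats`
#' @return a `BXDRates` data.frame: one row per interior boundary with
#'   forward/backward rates and hit counts
#' @export
rates_from_stats <- function(stats) {
  stopifnot(inherits(stats, "BXDStats"))
  if (any(stats$residence_time <= 0))
    stop("visited boxes must have positive residence time")
  n <- nrow(stats)
  if (n < 2) stop("need at least two boxes")
  m <- seq_len(n - 1)
  bad_f <- stats$hits_upper[m] == 0
  bad_b <- stats$hits_lower[m + 1] == 0
  if (any(bad_f | bad_b))
    stop(sprintf(paste0("zero hits on boundary %s; accumulate more events ",
                        "or use smaller boxes"),
                 paste(which(bad_f | bad_b), collapse = ", ")))
  rates <- data.frame(
    boundary = stats$hi[m],
    k_forward = stats$hits_upper[m] / stats$residence_time[m],
    k_backward = stats$hits_lower[m + 1] / stats$residence_time[m + 1],
    n_forward = stats$hits_upper[m],
    n_backward = stats$hits_lower[m + 1])
  attr(rates, "box_centers") <- (stats$lo + stats$hi) / 2
  attr(rates, "kT") <- attr(stats, "kT")
  class(rates) <- c("BXDRates", "data.frame")
  rates
}

#' Assemble the PMF from box-to-box rates
#'
#' The free-energy difference between neighbouring boxes follows from the
#' box-to-box equilibrium constant,
#' \eqn{\Delta G_{m-1,m} = -k_B T \ln(k_{m-1,m}/k_{m,m-1})}; the profile is
#' the cumulative sum anchored at zero in the first box. Standard errors
#' propagate the Poisson/binomial hit-count uncertainty
#' (\eqn{\mathrm{var}(\ln k) \approx 1/n}) through the log-ratio and
#' accumulate in quadrature.
#'
#' @param rates a `BXDRates`
#' @param kT thermal energy (default: recorded on `rates`)
#' @return a `PMFProfile` data.frame (rc, free_energy, stderr)
#' @export
pmf_from_rates <- function(rates, kT = attr(rates, "kT")) {
  stopifnot(inherits(rates, "BXDRates"))
  if (any(rates$k_forward <= 0 | rates$k_backward <= 0))
    stop("non-positive rate constant")
  dG <- -kT * log(rates$k_forward / rates$k_backward)
  se_b <- kT * sqrt(1 / rates$n_forward + 1 / rates$n_backward)
  pmf <- data.frame(rc = attr(rates, "box_centers"),
                    free_energy = c(0, cumsum(dG)),
                    stderr = c(0, sqrt(cumsum(se_b^2))))
  attr(pmf, "kT") <- kT
  class(pmf) <- c("PMFProfile", "data.frame")
  pmf
}

#' BXD PMF in one call
#' @param stats a `BXDStats`
#' @param kT thermal energy
#' @return a `PMFProfile`
#' @export
bxd_pmf <- function(stats, kT = attr(stats, "kT"))
  pmf_from_rates(rates_from_stats(stats), kT)

#' Check within-box equilibration
#'
#' Equilibrium inside each box is assumed by the rate formula and is tested
#' here by comparing first-half and second-half hit rates: a box whose
#' rates differ by more than `factor` is flagged `"fail"`, and boxes with
#' fewer than 40 hits are `"insufficient data"`.
#'
#' @param stats a `BXDStats`
#' @param factor maximum tolerated first/second-half rate ratio
#' @return data.frame (box, rate_first, rate_second, ratio, status)
#' @export
equilibration_check <- function(stats, factor = 2) {
  stopifnot(inherits(stats, "BXDStats"))
  r1 <- stats$hits_first_half / (stats$residence_time / 2)
  r2 <- stats$hits_second_half / (stats$residence_time / 2)
  ratio <- pmax(r1, r2) / pmin(r1, r2)
  total <- stats$hits_first_half + stats$hits_second_half
  status <- ifelse(total < 40, "insufficient data",
                   ifelse(is.finite(ratio) & ratio <= factor, "pass", "fail"))
  data.frame(box = stats$box, rate_first = r1, rate_second = r2,
             ratio = ratio, status = status)
}

#' Write BXD outputs (hit log, rates, PMF) as CSV
#' @param stats a `BXDStats`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_bxd_outputs <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(attr(stats, "hit_log"), file.path(dir, "hits.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  rates <- rates_from_stats(stats)
  write.table(as.data.frame(rates), file.path(dir, "rates.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  pmf <- pmf_from_rates(rates)
  out <- data.frame(rc_center = pmf$rc, G_eps = pmf$free_energy,
                    G_kJ_per_mol = eps_to_kJ_per_mol(pmf$free_energy),
                    stderr_eps = pmf$stderr)
  write.table(out, file.path(dir, "pmf.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}
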