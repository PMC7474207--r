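#' Select umbrella starting frames from a pulling trajectory
#'
#' For each requested window center, picks the stored pulling frame whose
#' end-to-end distance is closest to the center (the standard way of seeding
#' umbrella windows from a steered trajectory).
#'
#' @param trajectory `PullingTrajectory` with stored frames
#' @param centers window centers, A
#' @return list of starting states: each `list(center, positions, frame)`
#' @export
seed_windows_from_pulling <- function(trajectory, centers) {
  frames <- attr(trajectory, "frames")
  rc <- attr(trajectory, "frame_end_to_end")
  if (is.null(frames) || length(frames) == 0)
    stop("trajectory carries no frames; rerun with frame_stride > 0")
  lo <- min(rc)
  hi <- max(rc)
  bad <- centers < lo | centers > hi
  if (any(bad))
    stop(sprintf("window center(s) %s outside the trajectory range [%.1f, %.1f] A",
                 paste(round(centers[bad], 1), collapse = ", "), lo, hi))
  idx <- vapply(centers, function(cc) which.min(abs(rc - cc)), integer(1))
  if (anyDuplicated(idx))
    warning("multiple window centers map to the same frame ",
            "(coarse trajectory)", call. = FALSE)
  lapply(seq_along(centers), function(k)
    list(center = centers[k], positions = frames[[idx[k]]], frame = idx[k]))
}

#' Run one umbrella-sampling window
#'
#' Adds the harmonic bias \eqn{\frac{1}{2} k_{umb} (rc - center)^2} on the
#' end-to-end distance and samples the reaction coordinate at `stride`
#' after discarding `n_equil` steps (by default the first third, mirroring
#' the discard-first-third convention of the production windows).
#'
#' @param topology `GoTopology`
#' @param window starting state from [seed_windows_from_pulling()], or a
#'   `list(center =, positions =)`
#' @param k_umb umbrella constant, eps/A^2 (use [umbrella_k_to_reduced()]
#'   for physical-unit inputs)
#' @param params `LangevinParams`
#' @param n_steps total steps
#' @param n_equil discarded steps (default `n_steps / 3`)
#' @param stride sampling stride
#' @param seed window seed
#' @return an `UmbrellaWindow`: `list(center, k_umb, samples)`
#' @export
run_window <- function(topology, window, k_umb, params = langevin_params(),
                       n_steps = 2e5, n_equil = ceiling(n_steps / 3),
                       stride = 10, seed = NULL) {
  if (is.null(seed)) seed <- params$seed
  r <- cpp_cg_umbrella(.cpp_topology(topology), as.matrix(window$positions),
                       params$kT, params$gamma, params$dt, seed, k_umb,
                       window$center, n_steps, n_equil, as.integer(stride))
  structure(list(center = window$center, k_umb = k_umb,
                 samples = r$samples, positions = r$positions),
            class = "UmbrellaWindow")
}

#' Weighted histogram analysis (WHAM)
#'
#' Self-consistent unbiasing of umbrella-window histograms: iterates the
#' standard coupled equations for the unbiased bin probabilities and window
#' offsets until the maximum change of any offset falls below `tol`, then
#' reports \eqn{-k_B T \ln p} shifted so the minimum is zero.
#'
#' @param windows list of `UmbrellaWindow` objects
#' @param kT thermal energy, eps
#' @param bin_width histogram bin width, A. The default is the smaller of
#'   half the median window spacing and a quarter of the stiffest window's
#'   thermal width sqrt(kT/k_umb) — the bias potential must be close to
#'   constant across a bin, or the centre-point bias factor tilts the
#'   profile.
#' @param min_count bins with fewer pooled samples are dropped (they only
#'   add noise, and a noisy tail bin would corrupt the min-zero gauge)
#' @param tol convergence tolerance on the window offsets (eps)
#' @param max_iter iteration cap
#' @return a `WhamResult`: data.frame (rc, free_energy) with window offsets,
#'   iteration count and convergence in attributes
#' @export
wham <- function(windows, kT = 0.3, bin_width = NULL, min_count = 5,
                 tol = 1e-8, max_iter = 10000) {
  stopifnot(length(windows) >= 1)
  centers <- vapply(windows, function(w) w$center, numeric(1))
  ord <- order(centers)
  samples <- lapply(windows, function(w) w$samples)
  rng <- range(unlist(samples))
  if (is.null(bin_width)) {
    sp <- if (length(windows) > 1) median(diff(sort(centers))) / 2 else
      diff(rng) / 200
    kmax <- max(vapply(windows, function(w) w$k_umb, numeric(1)))
    if (kmax > 0) sp <- min(sp, sqrt(kT / kmax) / 4)
    bin_width <- max(sp, 1e-6)
  }
  edges <- seq(rng[1] - 1e-9, rng[2] + bin_width, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids)
  nw <- length(windows)
  H <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- findInterval(samples[[i]], edges, rightmost.closed = TRUE)
    b[b < 1] <- 1
    b[b > nb] <- nb
    H[i, ] <- tabulate(b, nb)
  }
  # adjacent windows must share at least one occupied bin
  if (nw > 1) {
    occ <- H[ord, , drop = FALSE] > 0
    for (k in seq_len(nw - 1)) {
      if (!any(occ[k, ] & occ[k + 1, ]))
        stop(sprintf(paste0("no histogram overlap between windows at %.2f ",
                            "and %.2f A; add windows or sample longer"),
                     centers[ord[k]], centers[ord[k + 1]]))
    }
  }
  n_i <- rowSums(H)
  h <- colSums(H)
  # bias factors c_ib = exp(-w_i(x_b)/kT)
  C <- exp(-outer(vapply(windows, function(w) w$k_umb, numeric(1)) / 2,
                  rep(1, nb)) *
             (matrix(rep(mids, each = nw), nw, nb) - centers)^2 / kT)
  f <- rep(1, nw)  # exp(f_i/kT) normalisation factors
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(n_i * f * C)
    p <- h / denom
    p[!is.finite(p)] <- 0
    f_new <- 1 / as.numeric(C %*% p)
    # fix the gauge on the first window
    f_new <- f_new / f_new[1]
    delta <- max(abs(kT * log(f_new / f)), na.rm = TRUE)
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }
  if (delta >= tol)
    stop(sprintf(paste0("WHAM did not converge in %d iterations ",
                        "(last offset change %.3g eps)"), max_iter, delta))
  p <- p / sum(p)
  keep <- p > 0 & h >= min_count
  G <- rep(NA_real_, nb)
  G[keep] <- -kT * log(p[keep])
  G <- G - min(G, na.rm = TRUE)
  out <- data.frame(rc = mids[keep], free_energy = G[keep])
  attr(out, "offsets") <- -kT * log(f)
  attr(out, "iterations") <- iter
  attr(out, "convergence") <- delta
  attr(out, "kT") <- kT
  attr(out, "bin_width") <- bin_width
  class(out) <- c("WhamResult", "PMFProfile", "data.frame")
  out
}

#' Bootstrap error bars for a WHAM PMF
#'
#' Resamples each window's sample set with replacement `n_boot` times,
#' recomputes the PMF and reports the per-bin standard deviation on the
#' grid of the point-estimate result.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap resamples
#' @param seed RNG seed for the resampling
#' @return the [wham()] result with a `stderr` column added
#' @export
wham_bootstrap <- function(windows, kT = 0.3, bin_width = NULL, n_boot = 200,
                           seed = 1, min_count = 5, tol = 1e-8,
                           max_iter = 10000) {
  base <- wham(windows, kT = kT, bin_width = bin_width, min_count = min_count,
               tol = tol, max_iter = max_iter)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, nrow(base))
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    gb <- tryCatch(
      wham(wb, kT = kT, bin_width = attr(base, "bin_width"),
           min_count = min_count, tol = tol, max_iter = max_iter),
      error = function(e) NULL)
    if (!is.null(gb)) {
      boots[b, ] <- approx(gb$rc, gb$free_energy, xout = base$rc,
                           rule = 1)$y
      # align gauge: minimise squared difference to the point estimate
      boots[b, ] <- boots[b, ] -
        mean(boots[b, ] - base$free_energy, na.rm = TRUE)
    }
  }
  base$stderr <- apply(boots, 2, sd, na.rm = TRUE)
  base
}
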