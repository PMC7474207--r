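#' Constant-velocity pulling protocol
#'
#' Elastic springs are attached to both termini: one spring anchors the
#' static terminus at its initial position, the other spring's anchor moves
#' at constant velocity along the initial N-to-C axis. Defaults follow the
#' standard coarse-grained protocol (spring 0.12 eps/A^2, 0.005 A/tau).
#'
#' @param spring_k spring constant, eps/A^2
#' @param velocity pulling velocity, A/tau
#' @param pulled_terminus `"C"` (default: C-terminal spring moves, N-terminal
#'   spring anchors) or `"N"`
#' @param total_extension anchor travel, A; default 1.05 x contour length
#'   (set at run time)
#' @return a `PullingProtocol`
#' @export
pulling_protocol <- function(spring_k = 0.12, velocity = 0.005,
                             pulled_terminus = c("C", "N"),
                             total_extension = NULL) {
  stopifnot(spring_k > 0, velocity >= 0)
  structure(list(spring_k = spring_k, velocity = velocity,
                 pulled_terminus = match.arg(pulled_terminus),
                 total_extension = total_extension),
            class = "PullingProtocol")
}

#' Run a constant-velocity pulling simulation
#'
#' Records time, end-to-end distance, moving-spring extension and tension
#' (positive when stretched, along the fixed pulling axis), and the
#' accumulated pulling work \eqn{W(t) = \sum F v_p \, dt}. The run ends when
#' the anchor displacement reaches `total_extension` (for `velocity = 0`,
#' supply `n_steps`).
#'
#' @param topology `GoTopology`
#' @param protocol `PullingProtocol`
#' @param params `LangevinParams`
#' @param seed replica seed (overrides `params$seed`)
#' @param positions starting coordinates, default native
#' @param stride recording stride (steps)
#' @param frame_stride coordinate-frame stride (steps); 0 disables frames
#' @param n_steps required when `velocity = 0`
#' @return a `PullingTrajectory`: data.frame (time, end_to_end,
#'   spring_extension, force, work) with frames and metadata in attributes
#' @export
run_pulling <- function(topology, protocol = pulling_protocol(),
                        params = langevin_params(), seed = NULL,
                        positions = NULL, stride = 200, frame_stride = 5000,
                        n_steps = NULL) {
  if (is.null(positions)) positions <- topology$native_positions
  if (is.null(seed)) seed <- params$seed
  total_ext <- protocol$total_extension
  if (is.null(total_ext))
    total_ext <- 1.05 * 3.8 * (topology$n_residues - 1)
  if (protocol$velocity > 0) {
    n_steps <- ceiling(total_ext / (protocol$velocity * params$dt))
  } else if (is.null(n_steps)) {
    stop("velocity is 0: supply n_steps")
  }
  r <- cpp_cg_pull(.cpp_topology(topology), as.matrix(positions), params$kT,
                   params$gamma, params$dt, seed, protocol$spring_k,
                   protocol$velocity, n_steps, as.integer(stride),
                   as.integer(frame_stride),
                   protocol$pulled_terminus == "C")
  tr <- data.frame(time = r$time, end_to_end = r$end_to_end,
                   spring_extension = r$spring_extension, force = r$force,
                   work = r$work)
  attr(tr, "frames") <- r$frames
  attr(tr, "frame_time") <- r$frame_time
  attr(tr, "frame_end_to_end") <- r$frame_end_to_end
  attr(tr, "final_positions") <- r$positions
  attr(tr, "protocol") <- protocol
  attr(tr, "params") <- params
  attr(tr, "seed") <- seed
  class(tr) <- c("PullingTrajectory", "data.frame")
  tr
}

#' Coordinate frames stored on a trajectory
#' @param trajectory a `PullingTrajectory`
#' @return list of n x 3 matrices
#' @export
trajectory_frames <- function(trajectory) attr(trajectory, "frames")

#' Accumulated pulling work from a force trace
#'
#' \eqn{W(t) = \sum_{s \le t} F_s \, v_p \, dt}; the free energy profile is
#' approximated by the work profile in the slow-pulling regime
#' (\eqn{\Delta G \approx \Delta W}, with \eqn{\Delta W \ge \Delta G} by the
#' second law).
#'
#' @param trace numeric force series (eps/A), or a data.frame with a `force`
#'   column and optionally an `end_to_end` column carried through
#' @param velocity pulling velocity, A/tau
#' @param dt time step between consecutive force samples, tau
#' @return numeric work series (or a data.frame when `trace` has
#'   `end_to_end`)
#' @export
work_from_force_trace <- function(trace, velocity, dt) {
  if (is.list(trace)) {
    force <- trace$force
    if (!is.null(trace$end_to_end) &&
        length(trace$end_to_end) != length(force))
      stop("force and end_to_end series have mismatched lengths")
    w <- cumsum(force * velocity * dt)
    out <- data.frame(work = w)
    if (!is.null(trace$end_to_end)) out$end_to_end <- trace$end_to_end
    return(out)
  }
  cumsum(trace * velocity * dt)
}

#' Detect rupture (unfolding-force) peaks on a force-extension curve
#'
#' Local maxima of the smoothed force-extension curve whose topographic
#' prominence exceeds `min_prominence`, ordered by extension. Rupture of a
#' packed helix state shows up as such a peak.
#'
#' @param trace data.frame with `end_to_end` (or `extension`) and `force`
#' @param smoothing_window running-mean window (samples, odd)
#' @param min_prominence minimum peak prominence, eps/A
#' @return data.frame (extension, peak_force); zero rows when no event
#' @export
detect_rupture_peaks <- function(trace, smoothing_window = 21,
                                 min_prominence = 0.5) {
  stopifnot(nrow(trace) > 0)
  x <- if (!is.null(trace$end_to_end)) trace$end_to_end else trace$extension
  f <- trace$force
  k <- max(1L, as.integer(smoothing_window))
  if (k %% 2 == 0) k <- k + 1L
  fs <- if (k > 1 && length(f) > k)
    as.numeric(stats::filter(f, rep(1 / k, k), sides = 2)) else f
  fs[is.na(fs)] <- f[is.na(fs)]
  n <- length(fs)
  if (n < 3) return(data.frame(extension = numeric(0),
                               peak_force = numeric(0)))
  is_max <- c(FALSE, fs[2:(n - 1)] > fs[1:(n - 2)] &
                fs[2:(n - 1)] >= fs[3:n], FALSE)
  peaks <- which(is_max)
  prom <- vapply(peaks, function(p) {
    higher_l <- which(fs[seq_len(p - 1)] > fs[p])
    lo_l <- if (length(higher_l)) min(fs[(max(higher_l) + 1):(p - 1)])
            else min(fs[seq_len(p)])
    higher_r <- which(fs[(p + 1):n] > fs[p]) + p
    lo_r <- if (length(higher_r)) min(fs[(p + 1):(min(higher_r) - 1)])
            else min(fs[p:n])
    fs[p] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(extension = x[peaks[keep]], peak_force = fs[peaks[keep]])
}
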