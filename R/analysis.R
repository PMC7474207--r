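#' Helicity versus extension along a trajectory
#'
#' Applies the Ca-geometry helix detector frame by frame and reports the
#' number and fraction of helical residues against the end-to-end distance,
#' the analysis behind helicity-vs-extension unfolding panels.
#'
#' @param trajectory `PullingTrajectory` (or any object whose frames are
#'   retrievable with [trajectory_frames()]), or a plain list of n x 3
#'   coordinate matrices
#' @param extensions end-to-end distances per frame; taken from the
#'   trajectory attributes when omitted
#' @param ... detector parameters passed to [assign_helices()]
#' @return a `HelicityTrace` data.frame (frame, extension, n_helical,
#'   fraction_helical)
#' @export
helicity_trace <- function(trajectory, extensions = NULL, ...) {
  frames <- if (is.list(trajectory) && !is.data.frame(trajectory))
    trajectory else trajectory_frames(trajectory)
  if (is.null(extensions))
    extensions <- if (is.data.frame(trajectory))
      attr(trajectory, "frame_end_to_end")
    else vapply(frames, end_to_end, numeric(1))
  n <- nrow(frames[[1]])
  nh <- vapply(frames, function(fr)
    sum(assign_helices(fr, ...)$per_residue_helical), numeric(1))
  out <- data.frame(frame = seq_along(frames), extension = extensions,
                    n_helical = nh, fraction_helical = nh / n)
  class(out) <- c("HelicityTrace", "data.frame")
  out
}

.helix_pairs <- function(map, annotation) {
  seg <- annotation$segments
  res_helix <- rep(NA_integer_, max(seg$end))
  for (s in seq_len(nrow(seg))) res_helix[seg$start[s]:seg$end[s]] <- s
  hi <- res_helix[map$i]
  hj <- res_helix[map$j]
  ok <- !is.na(hi) & !is.na(hj) & hi != hj
  list(contact_pair = cbind(pmin(hi, hj), pmax(hi, hj))[ok, , drop = FALSE],
       contacts = which(ok))
}

#' Per-helix-pair native contact fraction Q along a trajectory
#'
#' For every helix pair with at least one inter-helix native contact,
#' reports per frame the fraction of those contacts currently formed; a
#' contact counts as formed when its distance is below
#' `formed_factor` times the native distance. Pairs without native contacts
#' are absent from the result (not reported as 0/0).
#'
#' @param trajectory as in [helicity_trace()]
#' @param map `ContactMap` built from the same native structure
#' @param annotation `HelixAnnotation` (e.g. the generator ground truth)
#' @param formed_factor formedness cutoff as a multiple of native distance
#' @param min_seq_sep contacts between residues closer than this in sequence
#'   are excluded from the pair Q: contacts straddling a short loop behave
#'   like local structure and would otherwise keep "detached" neighbouring
#'   helices nominally in contact
#' @return matrix (frames x helix pairs) of Q values; pair labels like
#'   `"H1:H2"` as column names, native contact counts in
#'   `attr(, "n_contacts")`
#' @export
helix_pair_contact_fraction <- function(trajectory, map, annotation,
                                        formed_factor = 1.5,
                                        min_seq_sep = 10) {
  frames <- if (is.list(trajectory) && !is.data.frame(trajectory))
    trajectory else trajectory_frames(trajectory)
  sep_ok <- (map$j - map$i) >= min_seq_sep
  map_f <- map[sep_ok, , drop = FALSE]
  attr(map_f, "n_residues") <- attr(map, "n_residues")
  class(map_f) <- class(map)
  hp <- .helix_pairs(map_f, annotation)
  map <- map_f
  if (!nrow(hp$contact_pair))
    stop("no inter-helix native contacts between annotated helices")
  key <- paste0("H", hp$contact_pair[, 1], ":H", hp$contact_pair[, 2])
  groups <- split(hp$contacts, key)
  labels <- names(groups)
  Q <- matrix(NA_real_, length(frames), length(labels),
              dimnames = list(NULL, labels))
  ii <- map$i
  jj <- map$j
  lim <- formed_factor * map$native_distance
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    d <- sqrt(rowSums((xyz[jj, , drop = FALSE] -
                         xyz[ii, , drop = FALSE])^2))
    formed <- d < lim
    Q[f, ] <- vapply(groups, function(g) mean(formed[g]), numeric(1))
  }
  attr(Q, "n_contacts") <- vapply(groups, length, integer(1))
  Q
}

#' Classify the packed-helix state of one frame
#'
#' A helix is "attached" when its maximum contact fraction Q against any
#' other helix reaches `threshold`; the state label counts the attached
#' helices ("five-helix", "three-helix", ..., "zero-helix" when no pair
#' survives).
#'
#' @param q named Q values of one frame (names `"Ha:Hb"`), e.g. one row of
#'   [helix_pair_contact_fraction()]
#' @param annotation `HelixAnnotation`
#' @param threshold attachment threshold on max pairwise Q
#' @return list: `label`, `attached` (character vector of helix labels),
#'   `n_attached`
#' @export
classify_state <- function(q, annotation, threshold = 0.5) {
  helices <- annotation$segments$label
  members <- strsplit(names(q), ":", fixed = TRUE)
  per_helix <- vapply(helices, function(h) {
    involved <- vapply(members, function(m) h %in% m, logical(1))
    if (!any(involved)) return(-Inf)
    max(q[involved])
  }, numeric(1))
  attached <- helices[per_helix >= threshold]
  n <- length(attached)
  words <- c("zero", "one", "two", "three", "four", "five", "six", "seven")
  label <- paste0(words[min(n, length(words) - 1) + 1], "-helix")
  list(label = label, attached = attached, n_attached = n)
}

#' Per-frame state sequence and intermediate call for one replica
#'
#' Classifies every frame, applies an optional minimum dwell (in frames) to
#' suppress single-frame flicker around the attachment threshold, and
#' reports the surviving-helix sets, each helix's detachment extension (the
#' extension of the last crossing of its max-Q below the threshold) and
#' whether a three-helix intermediate was visited.
#'
#' @param Q frames x pairs matrix from [helix_pair_contact_fraction()]
#' @param extensions per-frame end-to-end distances
#' @param annotation `HelixAnnotation`
#' @param threshold attachment threshold
#' @param min_dwell minimum consecutive frames for a state to enter the
#'   compressed sequence
#' @param q_smooth running-mean window (frames) applied to Q before
#'   classification; suppresses quantisation flicker when a pair has few
#'   native contacts
#' @param hysteresis half-width of the two-threshold (Schmitt) band: a helix
#'   detaches when its max Q drops below `threshold - hysteresis` and only
#'   counts as re-attached above `threshold + hysteresis`, so fluctuation
#'   inside the band does not toggle the state
#' @param sequence how the canonical state sequence is built:
#'   `"last_crossing"` (default) counts a helix attached until its *final*
#'   detachment — transient re-binding episodes after a rupture (which this
#'   model shows, consistent with the helix recoil/refolding seen in
#'   reference trajectories) do not re-enter the sequence; `"dwell"` uses
#'   the raw per-frame classification compressed by `min_dwell`
#' @return an `IntermediateCall` list: per-frame `n_attached`, compressed
#'   `state_sequence`, `detachment_extension` per helix,
#'   `three_helix_visited`, `three_helix_set`
#' @export
intermediate_call <- function(Q, extensions, annotation, threshold = 0.5,
                              min_dwell = 5, q_smooth = 9,
                              hysteresis = 0.15,
                              sequence = c("last_crossing", "dwell")) {
  sequence <- match.arg(sequence)
  helices <- annotation$segments$label
  if (q_smooth > 1 && nrow(Q) > q_smooth) {
    k <- as.integer(q_smooth) + (as.integer(q_smooth) + 1) %% 2
    Qs <- apply(Q, 2, function(col) {
      s <- as.numeric(stats::filter(col, rep(1 / k, k), sides = 2))
      s[is.na(s)] <- col[is.na(s)]
      s
    })
    Q <- Qs
  }
  members <- strsplit(colnames(Q), ":", fixed = TRUE)
  lo <- threshold - hysteresis
  hi <- threshold + hysteresis
  per_frame <- matrix(FALSE, nrow(Q), length(helices),
                      dimnames = list(NULL, helices))
  for (h in seq_along(helices)) {
    involved <- vapply(members, function(m) helices[h] %in% m, logical(1))
    if (!any(involved)) next
    qmax <- apply(Q[, involved, drop = FALSE], 1, max)
    att <- qmax[1] >= lo
    for (f in seq_along(qmax)) {
      if (att && qmax[f] < lo) att <- FALSE
      else if (!att && qmax[f] > hi) att <- TRUE
      per_frame[f, h] <- att
    }
  }
  n_att <- rowSums(per_frame)
  nf <- nrow(per_frame)
  # final-detachment view: a helix counts attached until its last crossing
  last_att <- vapply(seq_along(helices), function(h) {
    att <- per_frame[, h]
    if (any(att)) max(which(att)) else 0L
  }, numeric(1))
  final_attached <- outer(seq_len(nf), last_att, "<=")
  n_att_final <- rowSums(final_attached)
  seq_src <- if (sequence == "last_crossing") n_att_final else n_att
  r <- rle(seq_src)
  keep <- r$lengths >= min_dwell | sequence == "last_crossing"
  seq_counts <- r$values[keep]
  seq_counts <- seq_counts[c(TRUE, diff(seq_counts) != 0)]
  words <- c("zero", "one", "two", "three", "four", "five", "six", "seven")
  state_sequence <- paste0(words[pmin(seq_counts, 7) + 1], "-helix")
  # detachment extension: last crossing below threshold per helix
  det <- vapply(seq_along(helices), function(h) {
    la <- last_att[h]
    if (la >= nf) return(NA_real_)
    extensions[la + 1]
  }, numeric(1))
  names(det) <- helices
  # surviving set while exactly three helices remain (must persist at least
  # min_dwell frames to count as a visited state)
  three_set <- character(0)
  i3 <- which(n_att_final == 3)
  if (length(i3) >= min_dwell) three_set <- helices[final_attached[i3[1], ]]
  structure(list(n_attached = n_att, n_attached_final = n_att_final,
                 state_sequence = state_sequence,
                 detachment_extension = det,
                 three_helix_visited = length(three_set) == 3,
                 three_helix_set = three_set),
            class = "IntermediateCall")
}

#' Locate unfolding events on a PMF (or work/force) profile
#'
#' Events are regions where the local slope over a running window exceeds
#' `min_rise` times the median local slope, the quantitative stand-in for
#' the "higher local increase" of the profile at the breaking of a packed
#' state. The same interface accepts force-extension traces
#' (columns renamed via `value_col`).
#'
#' @param pmf `PMFProfile` (or any data.frame on a uniform grid)
#' @param window slope window, in grid points (odd)
#' @param min_rise slope threshold as a multiple of the median slope
#' @param value_col column holding the profile (default `free_energy`)
#' @param x_col column holding the coordinate (default `rc`)
#' @return data.frame (rc, slope), one row per event, ordered by rc
#' @export
unfolding_events_from_pmf <- function(pmf, window = 3, min_rise = 3,
                                      value_col = "free_energy",
                                      x_col = "rc") {
  x <- pmf[[x_col]]
  y <- pmf[[value_col]]
  n <- length(x)
  if (n < window + 1) return(data.frame(rc = numeric(0), slope = numeric(0)))
  w <- max(1L, as.integer(window))
  half <- w %/% 2
  idx <- (1 + half):(n - half)
  slope <- (y[idx + half] - y[idx - half]) / (x[idx + half] - x[idx - half])
  med <- median(abs(slope))
  if (med <= 0) med <- mean(abs(slope))
  hot <- slope > min_rise * med
  if (!any(hot) || med == 0)
    return(data.frame(rc = numeric(0), slope = numeric(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values)
  out <- do.call(rbind, lapply(ev, function(k) {
    span <- starts[k]:ends[k]
    best <- span[which.max(slope[span])]
    data.frame(rc = x[idx[best]], slope = slope[best])
  }))
  out[order(out$rc), , drop = FALSE]
}
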