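#' Built-in van der Waals radii (Angstrom) for the overlap criterion
#'
#' Fixed element-to-radius map used when enlarging heavy-atom radii for
#' native-contact detection. Override entries (or supply additional elements)
#' through the `vdw` argument of [read_pdb_calpha()].
#'
#' @return named numeric vector of radii in Angstrom
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

.new_calpha_structure <- function(residues, atoms, chain_id, source,
                                  warnings = character(0)) {
  stopifnot(all(diff(residues$index) > 0))
  d <- consecutive_ca_distances(residues)
  if (length(d) && source != "synthetic" &&
      (any(d < 2.5) || any(d > 4.5))) {
    msg <- sprintf("%d consecutive Ca-Ca distance(s) outside 2.5-4.5 A",
                   sum(d < 2.5 | d > 4.5))
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }
  structure(list(residues = residues, atoms = atoms, chain_id = chain_id,
                 source = source, warnings = warnings),
            class = "CAlphaStructure")
}

#' Consecutive Ca-Ca distances of a residue table
#' @param residues the `residues` data.frame of a `CAlphaStructure`
#' @return numeric vector of n-1 distances, Angstrom
#' @export
consecutive_ca_distances <- function(residues) {
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (nrow(xyz) < 2) return(numeric(0))
  sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}

#' Extract Ca coordinates of a structure as an n x 3 matrix
#' @param structure a `CAlphaStructure`
#' @return numeric matrix, one row per residue, Angstrom
#' @export
ca_coords <- function(structure) {
  stopifnot(inherits(structure, "CAlphaStructure"))
  as.matrix(structure$residues[, c("x", "y", "z")])
}

#' @export
print.CAlphaStructure <- function(x, ...) {
  cat(sprintf("CAlphaStructure: %d residues, %d heavy atoms, chain %s (%s)\n",
              nrow(x$residues), nrow(x$atoms), x$chain_id, x$source))
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Read a PDB file at C-alpha resolution, retaining heavy atoms
#'
#' Parses `ATOM` records (HETATM ignored), resolves alternate locations to
#' the highest-occupancy conformer, drops hydrogens, and returns one Ca
#' interaction centre per residue together with the residue's heavy atoms
#' (which are needed only to build the native contact map by the overlap
#' criterion).
#'
#' @param path PDB file
#' @param chain chain identifier; default: first chain encountered
#' @param residue_range optional inclusive 1-based `c(first, last)` range of
#'   author residue numbers
#' @param vdw named element-to-radius map, see [default_vdw_radii()]
#' @return a `CAlphaStructure`
#' @export
read_pdb_calpha <- function(path, chain = NULL, residue_range = NULL,
                            vdw = default_vdw_radii()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  if (!length(lines)) stop("no ATOM records in ", path)

  fx <- function(a, b) substr(lines, a, b)
  atom_name <- trimws(fx(13, 16))
  altloc <- fx(17, 17)
  res_name <- trimws(fx(18, 20))
  chain_id <- fx(22, 22)
  res_seq <- as.integer(fx(23, 26))
  x <- as.numeric(fx(31, 38))
  y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(fx(77, 78))
  guess <- is.na(element) | element == ""
  # fall back on the first alphabetic character of the atom name
  element[guess] <- sub("^[0-9']*([A-Za-z]).*", "\\1",
                        toupper(atom_name[guess]))
  element <- toupper(element)

  if (is.null(chain)) chain <- chain_id[1]
  if (!any(chain_id == chain))
    stop(sprintf("chain '%s' not present (chains: %s)", chain,
                 paste(unique(chain_id), collapse = ", ")))
  keep <- chain_id == chain & element != "H" & element != "D"
  df <- data.frame(residue_index = res_seq, residue_name = res_name,
                   atom_name = atom_name, element = element,
                   x = x, y = y, z = z, occ = occ,
                   altloc = altloc)[keep, ]
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    df <- df[df$residue_index >= residue_range[1] &
               df$residue_index <= residue_range[2], ]
    if (!nrow(df)) stop("no residues in requested range")
  }
  # altloc: keep the highest-occupancy conformer per (residue, atom)
  key <- paste(df$residue_index, df$atom_name)
  df <- df[order(key, -df$occ), ]
  df <- df[!duplicated(paste(df$residue_index, df$atom_name)), ]
  df <- df[order(df$residue_index, df$atom_name), ]

  df$vdw_radius <- unname(vdw[df$element])
  unknown <- unique(df$element[is.na(df$vdw_radius)])
  if (length(unknown)) {
    warning("unknown element(s) ", paste(unknown, collapse = ","),
            "; using 1.70 A", call. = FALSE)
    df$vdw_radius[is.na(df$vdw_radius)] <- 1.70
  }

  idx <- sort(unique(df$residue_index))
  ca <- df[df$atom_name == "CA", ]
  missing_ca <- setdiff(idx, ca$residue_index)
  if (length(missing_ca))
    stop("residue(s) without a CA atom: ", paste(missing_ca, collapse = ", "))
  ca <- ca[match(idx, ca$residue_index), ]
  residues <- data.frame(index = idx, name = ca$residue_name,
                         x = ca$x, y = ca$y, z = ca$z)
  warnings <- character(0)
  if (any(diff(idx) != 1)) {
    msg <- sprintf("gap(s) in residue numbering after residue(s): %s",
                   paste(idx[which(diff(idx) != 1)], collapse = ", "))
    warnings <- msg
    warning(msg, call. = FALSE)
  }
  atoms <- df[, c("residue_index", "residue_name", "atom_name", "element",
                  "x", "y", "z", "vdw_radius")]
  rownames(atoms) <- NULL
  .new_calpha_structure(residues, atoms, chain, path, warnings)
}

#' Write a structure (all retained atoms) back to PDB
#'
#' @param structure a `CAlphaStructure`
#' @param path output file
#' @export
write_pdb_calpha <- function(structure, path) {
  stopifnot(inherits(structure, "CAlphaStructure"))
  a <- structure$atoms
  ch <- substr(ifelse(nzchar(structure$chain_id), structure$chain_id, "A"),
               1, 1)
  lines <- sprintf(
    "ATOM  %5d %-4s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
    a$residue_name, ch, a$residue_index, a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Annotate helices from Ca geometry
#'
#' A stand-in for hydrogen-bond based secondary-structure assignment that
#' works on Ca-only models: a 5-residue window starting at residue i is
#' helix-like when d(i, i+3) and d(i, i+4) fall inside characteristic
#' distance windows of compact (alpha/3-10/pi-like) helical geometry. Two
#' *consecutive* qualifying windows (the Ca analogue of DSSP's two
#' consecutive backbone H-bonds) mark all residues i..i+5 helical, and
#' contiguous helical runs of at least four residues become segments labeled
#' H1, H2, ... from the N-terminus.
#'
#' @param structure `CAlphaStructure` or n x 3 coordinate matrix
#' @param d13 inclusive window (A) for the i to i+3 Ca distance
#' @param d14 inclusive window (A) for the i to i+4 Ca distance
#' @param min_run minimum helical run length kept as a segment
#' @param spread mark the full i..i+5 span of two consecutive qualifying
#'   windows (default); `FALSE` marks only residue i of each qualifying
#'   window, which systematically clips helix C-termini
#' @return a `HelixAnnotation`: `segments` data.frame (label, start, end; 1-based
#'   residue offsets) and `per_residue_helical` logical vector
#' @export
assign_helices <- function(structure, d13 = c(4.5, 6.0), d14 = c(5.0, 6.8),
                           min_run = 4, spread = TRUE) {
  xyz <- if (inherits(structure, "CAlphaStructure")) ca_coords(structure)
         else as.matrix(structure)
  n <- nrow(xyz)
  helical <- rep(FALSE, n)
  if (n >= 5) {
    i <- seq_len(n - 4)
    d3 <- sqrt(rowSums((xyz[i + 3, , drop = FALSE] -
                          xyz[i, , drop = FALSE])^2))
    d4 <- sqrt(rowSums((xyz[i + 4, , drop = FALSE] -
                          xyz[i, , drop = FALSE])^2))
    ok <- d3 >= d13[1] & d3 <= d13[2] & d4 >= d14[1] & d4 <= d14[2]
    if (spread) {
      pair <- ok[-length(ok)] & ok[-1]
      for (w in which(pair)) helical[w:(w + 5)] <- TRUE
    } else {
      helical[i[ok]] <- TRUE
    }
  }
  runs <- rle(helical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_run
  segments <- data.frame(label = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  if (any(keep)) {
    segments <- data.frame(label = paste0("H", seq_len(sum(keep))),
                           start = starts[keep], end = ends[keep],
                           stringsAsFactors = FALSE)
    # residues in runs shorter than min_run are not part of any segment
    helical_seg <- rep(FALSE, n)
    for (s in seq_len(nrow(segments)))
      helical_seg[segments$start[s]:segments$end[s]] <- TRUE
  }
  structure(list(segments = segments, per_residue_helical = helical),
            class = "HelixAnnotation")
}

#' @export
print.HelixAnnotation <- function(x, ...) {
  cat(sprintf("HelixAnnotation: %d segment(s), %d/%d helical residues\n",
              nrow(x$segments), sum(x$per_residue_helical),
              length(x$per_residue_helical)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

.bundle_axis_positions <- function(n_helices, packing_distance) {
  if (n_helices == 1) return(matrix(0, 1, 2))
  if (n_helices == 2)
    return(rbind(c(-packing_distance / 2, 0), c(packing_distance / 2, 0)))
  r <- packing_distance / (2 * sin(pi / n_helices))
  ang <- 2 * pi * (seq_len(n_helices) - 1) / n_helices
  cbind(r * cos(ang), r * sin(ang))
}

#' Generate a synthetic C-alpha helix bundle
#'
#' Builds an idealized antiparallel helix bundle (rise 1.5 A/residue, 100
#' degrees/residue, helix radius 2.3 A) with near-extended loops connecting
#' consecutive helices, emulating the four/five-helix subdomain architecture
#' of mechanosensitive rod proteins. Pseudo heavy atoms (carbons) are placed
#' around each Ca, displaced toward the helix axis and toward the bundle
#' core, so that the van der Waals overlap criterion produces both
#' intra-helix (i, i+3) and inter-helix native contacts. These atoms are a
#' fixture-only stand-in for real side chains.
#'
#' @param n_helices number of helices (1-5 sensible)
#' @param helix_len residues per helix (>= 8)
#' @param loop_len residues per connecting loop
#' @param packing_distance distance between adjacent helix axes (A)
#' @param seed integer seed (used only when `jitter > 0`)
#' @param jitter optional Gaussian coordinate noise, sd in A
#' @return `CAlphaStructure` with the generator's ground-truth
#'   `HelixAnnotation` attached as `$helix_ground_truth`
#' @export
make_helix_bundle <- function(n_helices = 4, helix_len = 15, loop_len = 4,
                              packing_distance = 10, seed = 1, jitter = 0) {
  stopifnot(n_helices >= 1, helix_len >= 8, loop_len >= 0)
  helix_radius <- 2.3
  rise <- 1.5
  twist <- 100 * pi / 180
  if (packing_distance < 2 * helix_radius && n_helices > 1)
    stop("packing_distance must be at least 2 x helix radius (4.6 A)")

  axes <- .bundle_axis_positions(n_helices, packing_distance)
  coords <- list()
  kinds <- list()    # "helix" or "loop"
  hel_id <- list()
  dirs <- numeric(0) # per-residue helix direction (z sign), loops get 0
  gt_start <- integer(0)
  gt_end <- integer(0)
  idx <- 0
  zmax <- (helix_len - 1) * rise
  for (h in seq_len(n_helices)) {
    dir <- if (h %% 2 == 1) 1 else -1
    j <- 0:(helix_len - 1)
    ang <- j * twist
    hx <- axes[h, 1] + helix_radius * cos(ang)
    hy <- axes[h, 2] + helix_radius * sin(ang)
    hz <- if (dir == 1) j * rise else zmax - j * rise
    gt_start <- c(gt_start, idx + 1)
    gt_end <- c(gt_end, idx + helix_len)
    coords[[length(coords) + 1]] <- cbind(hx, hy, hz)
    kinds[[length(kinds) + 1]] <- rep("helix", helix_len)
    hel_id[[length(hel_id) + 1]] <- rep(h, helix_len)
    dirs <- c(dirs, rep(dir, helix_len))
    idx <- idx + helix_len

    if (h < n_helices && loop_len > 0) {
      # connect end of this helix to start of the next with an outward-
      # bulging quadratic arc so consecutive spacing stays reasonable
      p0 <- c(hx[helix_len], hy[helix_len], hz[helix_len])
      dir2 <- if ((h + 1) %% 2 == 1) 1 else -1
      q_ang <- 0
      q0 <- c(axes[h + 1, 1] + helix_radius * cos(q_ang),
              axes[h + 1, 2] + helix_radius * sin(q_ang),
              if (dir2 == 1) 0 else zmax)
      mid <- (p0 + q0) / 2
      radial <- mid[1:2]
      nr <- sqrt(sum(radial^2))
      radial <- if (nr > 1e-8) radial / nr else c(1, 0)
      zdir <- if (dir == 1) 1 else -1  # bulge past the connecting level
      nrm <- c(radial * 0.8, zdir * 0.6)
      nrm <- nrm / sqrt(sum(nrm^2))
      target_len <- 3.5 * (loop_len + 1)
      bez_len <- function(hh) {
        ctrl <- mid + hh * nrm
        tt <- seq(0, 1, length.out = 50)
        pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) +
          outer(tt^2, q0)
        sum(sqrt(rowSums(diff(pts)^2)))
      }
      hh <- 0
      while (bez_len(hh) < target_len && hh < 30) hh <- hh + 0.25
      ctrl <- mid + hh * nrm
      tt <- seq(0, 1, length.out = loop_len + 2)[2:(loop_len + 1)]
      pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) +
        outer(tt^2, q0)
      coords[[length(coords) + 1]] <- pts
      kinds[[length(kinds) + 1]] <- rep("loop", loop_len)
      hel_id[[length(hel_id) + 1]] <- rep(0, loop_len)
      dirs <- c(dirs, rep(0, loop_len))
      idx <- idx + loop_len
    }
  }
  xyz <- do.call(rbind, coords)
  kind <- unlist(kinds)
  hid <- unlist(hel_id)
  n <- nrow(xyz)
  if (jitter > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(rnorm(3 * n, sd = jitter), n, 3)
  }

  # pseudo heavy atoms: CA plus carbons displaced toward the helix axis
  # (+/- along the helix direction, giving i/i+3 intra-helix contacts) and
  # toward each packing neighbour (giving the inter-helix interface)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- xyz[i, ]
    if (hid[i] > 0) {
      ax <- axes[hid[i], ]
      inward_h <- c(ax - p[1:2], 0)
    } else {
      inward_h <- c(-p[1:2], 0)
    }
    nh <- sqrt(sum(inward_h^2))
    inward_h <- if (nh > 1e-8) inward_h / nh else c(1, 0, 0)
    dz <- c(0, 0, if (dirs[i] != 0) dirs[i] else 1)
    nb <- if (hid[i] > 0 && n_helices > 1) {
      h <- hid[i]
      others <- if (n_helices == 2) setdiff(1:2, h)
        else unique(c((h %% n_helices) + 1, ((h - 2) %% n_helices) + 1))
      lapply(others, function(o) {
        v <- c(axes[o, ] - axes[h, ], 0)
        v / sqrt(sum(v^2))
      })
    } else {
      iv <- c(-p[1:2], 0)
      nc <- sqrt(sum(iv^2))
      list(if (nc > 1e-8) iv / nc else c(1, 0, 0))
    }
    pos <- rbind(p,
                 p + 1.9 * inward_h + 0.8 * dz,
                 p + 1.9 * inward_h - 0.8 * dz,
                 do.call(rbind, lapply(nb, function(v) p + 2.6 * v)))
    nm <- c("CA", "CB1", "CB2", paste0("CD", seq_along(nb)))
    rows[[i]] <- data.frame(
      residue_index = i,
      residue_name = ifelse(kind[i] == "helix", "ALA", "GLY"),
      atom_name = nm, element = "C",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      vdw_radius = 1.70, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  residues <- data.frame(index = seq_len(n),
                         name = ifelse(kind == "helix", "ALA", "GLY"),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  st <- .new_calpha_structure(residues, atoms, chain_id = "A",
                              source = "synthetic")
  helical <- hid > 0
  st$helix_ground_truth <- structure(
    list(segments = data.frame(label = paste0("H", seq_len(n_helices)),
                               start = gt_start, end = gt_end,
                               stringsAsFactors = FALSE),
         per_residue_helical = helical),
    class = "HelixAnnotation")
  st
}

#' Write trajectory frames in plain XYZ format
#' @param frames list of n x 3 coordinate matrices
#' @param path output file
#' @param comment per-frame comment lines (recycled)
#' @export
write_xyz <- function(frames, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  comment <- rep_len(comment, length(frames))
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    writeLines(c(nrow(m), comment[k],
                 sprintf("CA %12.5f %12.5f %12.5f", m[, 1], m[, 2], m[, 3])),
               con)
  }
  invisible(path)
}
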