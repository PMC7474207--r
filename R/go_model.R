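#' Build a native contact map by the van der Waals overlap criterion
#'
#' A residue pair (i, j) with sequence separation `j - i >= min_sep` forms a
#' native contact when any heavy atom of i and any heavy atom of j overlap
#' once their van der Waals radii are enlarged by `enlargement` (strictly
#' `d < enlargement * (r_i + r_j)`). The contact's native distance is the
#' Ca-Ca distance in the input structure.
#'
#' For structures carrying no heavy atoms a Ca-distance fallback
#' (`method = "calpha"`, cutoff in A) is available; this criterion is a
#' pragmatic stand-in, not the overlap rule.
#'
#' @param structure a `CAlphaStructure`
#' @param enlargement radius enlargement factor
#' @param min_sep minimum sequence separation (`j - i`), i.e. pairs separated
#'   by at least `min_sep - 1` other residues
#' @param method `"overlap"` (default) or `"calpha"`
#' @param ca_cutoff Ca-Ca cutoff (A) for the fallback criterion
#' @return a `ContactMap`: data.frame (i, j, native_distance) with attributes
#'   `n_residues`, `method`
#' @export
build_contact_map <- function(structure, enlargement = 1.24, min_sep = 3,
                              method = c("overlap", "calpha"),
                              ca_cutoff = 7.5) {
  stopifnot(inherits(structure, "CAlphaStructure"))
  method <- match.arg(method)
  xyz <- ca_coords(structure)
  n <- nrow(xyz)
  dca <- as.matrix(stats::dist(xyz))

  if (method == "overlap") {
    if (is.null(structure$atoms) || nrow(structure$atoms) == 0)
      stop("structure has no heavy atoms; use method = \"calpha\" ",
           "(Ca-distance fallback) instead")
    at <- structure$atoms
    resmap <- match(at$residue_index, structure$residues$index)
    split_xyz <- split.data.frame(
      data.frame(x = at$x, y = at$y, z = at$z, r = at$vdw_radius), resmap)
    max_r <- max(at$vdw_radius)
    # atoms sit within a few A of their Ca; screen pairs by Ca distance
    reach <- vapply(seq_len(n), function(i) {
      a <- split_xyz[[as.character(i)]]
      if (is.null(a)) 0 else
        max(sqrt((a$x - xyz[i, 1])^2 + (a$y - xyz[i, 2])^2 +
                   (a$z - xyz[i, 3])^2))
    }, numeric(1))
    screen <- 2 * max(reach) + enlargement * 2 * max_r
    pairs <- which(upper.tri(dca) &
                     col(dca) - row(dca) >= min_sep &
                     dca < screen, arr.ind = TRUE)
    hit <- logical(nrow(pairs))
    if (nrow(pairs)) {
      for (p in seq_len(nrow(pairs))) {
        ai <- split_xyz[[as.character(pairs[p, 1])]]
        aj <- split_xyz[[as.character(pairs[p, 2])]]
        if (is.null(ai) || is.null(aj)) next
        d2 <- outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
          outer(ai$z, aj$z, "-")^2
        lim <- enlargement * outer(ai$r, aj$r, "+")
        hit[p] <- any(d2 < lim^2)
      }
    }
    pairs <- pairs[hit, , drop = FALSE]
  } else {
    pairs <- which(upper.tri(dca) &
                     col(dca) - row(dca) >= min_sep &
                     dca < ca_cutoff, arr.ind = TRUE)
  }
  map <- data.frame(i = unname(pairs[, 1]), j = unname(pairs[, 2]))
  map <- map[order(map$i, map$j), , drop = FALSE]
  map$native_distance <- dca[cbind(map$i, map$j)]
  rownames(map) <- NULL
  attr(map, "n_residues") <- n
  attr(map, "method") <- method
  attr(map, "min_sep") <- min_sep
  class(map) <- c("ContactMap", "data.frame")
  map
}

#' Write / read a contact map as tab-separated text
#' @param map a `ContactMap`
#' @param path file path
#' @export
write_contact_map <- function(map, path) {
  write.table(as.data.frame(map)[, c("i", "j", "native_distance")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @param n_residues chain length recorded on the re-read map
#' @export
read_contact_map <- function(path, n_residues) {
  map <- read.table(path, header = TRUE, sep = "\t")
  attr(map, "n_residues") <- n_residues
  attr(map, "method") <- "file"
  attr(map, "min_sep") <- if (nrow(map)) min(map$j - map$i) else 3L
  class(map) <- c("ContactMap", "data.frame")
  map
}

#' Instantiate the coarse-grained force field
#'
#' Assembles the complete structure-based topology from a native structure
#' and its contact map: harmonic pseudo-bonds between consecutive Ca beads at
#' their native lengths, a native-chirality term over each 4-residue window,
#' native contacts as Lennard-Jones wells with \eqn{\sigma_{ij}} chosen so
#' the minimum sits at the native pair distance
#' (\eqn{\sigma_{ij} = d_{ij}/2^{1/6}}) and a uniform well depth, and a
#' purely repulsive truncated-shifted Lennard-Jones term below `rep_cut` for
#' all remaining pairs with sequence separation at least `min_sep`.
#'
#' The chirality energy is \eqn{\frac{1}{2}\kappa (C_w - C_w^{nat})^2} with
#' \eqn{C_w} the signed triple product of the window's three bond vectors
#' normalised by the product of its native bond lengths.
#'
#' @param structure native `CAlphaStructure`
#' @param map `ContactMap` built from the same structure
#' @param bond_k bond spring constant, eps/A^2
#' @param chir_kappa chirality stiffness, eps
#' @param contact_eps uniform contact well depth, eps
#' @param rep_cut repulsive cutoff, A
#' @param rep_eps repulsive energy scale, eps
#' @param mass uniform bead mass (reduced)
#' @return a `GoTopology`
#' @export
build_topology <- function(structure, map, bond_k = 100, chir_kappa = 1,
                           contact_eps = 1, rep_cut = 4, rep_eps = 1,
                           mass = 1) {
  stopifnot(inherits(structure, "CAlphaStructure"),
            inherits(map, "ContactMap"))
  xyz <- ca_coords(structure)
  n <- nrow(xyz)
  if (nrow(map) && (max(map$j) > n || min(map$i) < 1))
    stop("contact map references residues absent from the structure")

  bl <- consecutive_ca_distances(structure$residues)
  bonds <- data.frame(i = seq_len(max(n - 1, 0)),
                      j = seq_len(max(n - 1, 0)) + 1,
                      r0 = bl, k = bond_k)

  chir <- data.frame(i = integer(0), c0 = numeric(0), norm = numeric(0))
  if (n >= 4) {
    iw <- seq_len(n - 3)
    c0 <- numeric(length(iw))
    nrm <- numeric(length(iw))
    for (w in iw) {
      b1 <- xyz[w + 1, ] - xyz[w, ]
      b2 <- xyz[w + 2, ] - xyz[w + 1, ]
      b3 <- xyz[w + 3, ] - xyz[w + 2, ]
      nrm[w] <- 1 / (sqrt(sum(b1^2)) * sqrt(sum(b2^2)) * sqrt(sum(b3^2)))
      c0[w] <- sum(b1 * c(b2[2] * b3[3] - b2[3] * b3[2],
                          b2[3] * b3[1] - b2[1] * b3[3],
                          b2[1] * b3[2] - b2[2] * b3[1])) * nrm[w]
    }
    chir <- data.frame(i = iw, c0 = c0, norm = nrm)
  }

  contacts <- data.frame(i = map$i, j = map$j,
                         native_distance = map$native_distance,
                         sigma = map$native_distance / 2^(1 / 6),
                         eps = rep(contact_eps, nrow(map)))
  min_sep <- attr(map, "min_sep")
  if (is.null(min_sep)) min_sep <- 3L

  structure(list(n_residues = n, bonds = bonds, chirality = chir,
                 chir_kappa = chir_kappa, contacts = contacts,
                 rep_cut = rep_cut, rep_eps = rep_eps,
                 min_sep = as.integer(min_sep), mass = mass,
                 native_positions = xyz),
            class = "GoTopology")
}

#' @export
print.GoTopology <- function(x, ...) {
  cat(sprintf(paste0("GoTopology: %d residues, %d bonds, %d chirality ",
                     "windows, %d native contacts\n"),
              x$n_residues, nrow(x$bonds), nrow(x$chirality),
              nrow(x$contacts)))
  invisible(x)
}

# 0-based arrays for the compiled engine
.cpp_topology <- function(topology) {
  stopifnot(inherits(topology, "GoTopology"))
  list(n = topology$n_residues,
       bond_i = topology$bonds$i - 1L, bond_j = topology$bonds$j - 1L,
       bond_r0 = topology$bonds$r0, bond_k = topology$bonds$k,
       chir_i = topology$chirality$i - 1L, chir_c0 = topology$chirality$c0,
       chir_kappa = rep(topology$chir_kappa, nrow(topology$chirality)),
       chir_norm = topology$chirality$norm,
       nat_i = topology$contacts$i - 1L, nat_j = topology$contacts$j - 1L,
       nat_sigma = topology$contacts$sigma, nat_eps = topology$contacts$eps,
       rep_cut = topology$rep_cut, rep_eps = topology$rep_eps,
       min_sep = topology$min_sep)
}

#' Energies and forces of the coarse-grained force field
#'
#' @param topology a `GoTopology`
#' @param positions n x 3 coordinate matrix (A)
#' @return list with `energy` (per-term breakdown in eps, including a
#'   `pulling_springs` slot, zero here, and `total`) and `forces`
#'   (n x 3, eps/A), the exact negative gradient of the reported energy
#' @export
energy_forces <- function(topology, positions) {
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (nrow(positions) != topology$n_residues)
    stop("positions do not match topology size")
  r <- cpp_energy_forces(.cpp_topology(topology), positions)
  energy <- list(bonds = r$bonds, chirality = r$chirality,
                 native_lj = r$native_lj, repulsive = r$repulsive,
                 pulling_springs = 0)
  energy$total <- r$bonds + r$chirality + r$native_lj + r$repulsive
  list(energy = energy, forces = r$forces)
}

#' Serialize / restore a topology as a single JSON document
#' @param topology a `GoTopology`
#' @param path file path
#' @export
write_topology <- function(topology, path) {
  x <- unclass(topology)
  x$native_positions <- unname(apply(x$native_positions, 1, c,
                                     simplify = FALSE))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$native_positions <- do.call(rbind, lapply(
    if (is.list(x$native_positions)) x$native_positions
    else asplit(x$native_positions, 1), as.numeric))
  x$bonds <- as.data.frame(x$bonds)
  x$chirality <- as.data.frame(x$chirality)
  x$contacts <- as.data.frame(x$contacts)
  class(x) <- "GoTopology"
  x
}
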