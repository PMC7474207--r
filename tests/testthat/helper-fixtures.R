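# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk except files the tests write
# themselves.

# minimal hand-written PDB text: one CA (and optional extra atoms) per residue
write_mini_pdb <- function(path, coords, chain = "A", extra = NULL,
                           occ = NULL, altloc = NULL) {
  n <- nrow(coords)
  lines <- character(0)
  serial <- 1
  for (i in seq_len(n)) {
    o <- if (is.null(occ)) 1 else occ[i]
    al <- if (is.null(altloc)) " " else altloc[i]
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA %sALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial, al, chain, i, coords[i, 1], coords[i, 2], coords[i, 3], o, 0))
    serial <- serial + 1
  }
  if (!is.null(extra)) {
    for (k in seq_len(nrow(extra))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, chain, extra$res[k], extra$x[k], extra$y[k], extra$z[k], 1, 0))
      serial <- serial + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# straight chain along x at given spacing
straight_chain <- function(n, spacing = 3.8)
  cbind(seq_len(n) * spacing - spacing, 0, 0)

# GoTopology assembled by hand (bypasses build_topology) for toy systems
toy_topology <- function(n, contacts = NULL, bonds = NULL, rep_cut = 4,
                         min_sep = 3) {
  structure(list(
    n_residues = n,
    bonds = if (is.null(bonds))
      data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                 k = numeric(0)) else bonds,
    chirality = data.frame(i = integer(0), c0 = numeric(0),
                           norm = numeric(0)),
    chir_kappa = 1,
    contacts = if (is.null(contacts))
      data.frame(i = integer(0), j = integer(0), native_distance = numeric(0),
                 sigma = numeric(0), eps = numeric(0)) else contacts,
    rep_cut = rep_cut, rep_eps = 1, min_sep = as.integer(min_sep), mass = 1,
    native_positions = straight_chain(n)), class = "GoTopology")
}

# two beads joined by one breakable native contact at distance r0
two_bead_toy <- function(r0 = 5, eps = 1) {
  topo <- toy_topology(2, contacts = data.frame(
    i = 1, j = 2, native_distance = r0, sigma = r0 / 2^(1 / 6), eps = eps))
  topo$native_positions <- rbind(c(0, 0, 0), c(r0, 0, 0))
  topo
}

# brute-force overlap-criterion contact map (independent of the package path)
brute_force_contact_map <- function(structure, enlargement = 1.24,
                                    min_sep = 3) {
  at <- structure$atoms
  xyz <- ca_coords(structure)
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < min_sep) next
      ai <- at[at$residue_index == i, ]
      aj <- at[at$residue_index == j, ]
      hit <- FALSE
      for (a in seq_len(nrow(ai))) {
        for (b in seq_len(nrow(aj))) {
          d <- sqrt(sum((c(ai$x[a], ai$y[a], ai$z[a]) -
                           c(aj$x[b], aj$y[b], aj$z[b]))^2))
          if (d < enlargement * (ai$vdw_radius[a] + aj$vdw_radius[b])) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      if (hit) out <- rbind(out, data.frame(
        i = i, j = j, native_distance = sqrt(sum((xyz[j, ] - xyz[i, ])^2))))
    }
  }
  out
}

# quadrature oracle for the two-bead pulling toy: -kT log Z(D) with
# Z(D) = int s^2 exp(-beta [k/4 (s^2+D^2) + V(s)]) * sinh(a)/a ds,
# a = beta k s D / 2 (anchors D apart, springs k on both beads)
two_bead_free_energy <- function(D, k = 0.12, kT = 0.3, r0 = 5, eps = 1) {
  beta <- 1 / kT
  V <- function(s) {
    s6 <- (r0 / 2^(1 / 6) / s)^6
    4 * eps * (s6^2 - s6)
  }
  lz <- vapply(D, function(d) {
    f <- function(s) {
      a <- beta * k * s * d / 2
      sh <- ifelse(a < 1e-8, 1, (1 - exp(-2 * a)) / (2 * a))  # sinh(a)/a*e^-a
      # fold e^{a} into the main exponent to avoid overflow
      s^2 * exp(-beta * (k / 4 * (s - d)^2 + V(s))) * sh
    }
    log(integrate(f, 0.5, d + 60, rel.tol = 1e-9,
                  subdivisions = 400L)$value)
  }, numeric(1))
  -kT * lz
}

# per-box Boltzmann log-weight PMF oracle on a 1D potential
box_weight_pmf <- function(bounds, potential = "harmonic", p = 1, kT = 0.3) {
  bz <- boltzmann_1d(potential, p, kT, lower = -Inf, upper = Inf)
  w <- vapply(seq_len(length(bounds) - 1), function(m)
    bz$interval_weight(bounds[m], bounds[m + 1]), numeric(1))
  -kT * (log(w) - log(w[1]))
}

# a 4-helix bundle plus everything derived from it, built once per test run
bundle_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- make_helix_bundle(4, 15, 4, 10, seed = 1)
      map <- build_contact_map(st)
      cache <<- list(structure = st, map = map,
                     topology = build_topology(st, map),
                     annotation = st$helix_ground_truth)
    }
    cache
  }
})
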