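#include "model.h"

#include <cmath>

using Rcpp::as;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

Topology parse_topology(const List& topo) {
  Topology t;
  t.n = as<int>(topo["n"]);
  t.bi = as<std::vector<int>>(topo["bond_i"]);
  t.bj = as<std::vector<int>>(topo["bond_j"]);
  t.br0 = as<std::vector<double>>(topo["bond_r0"]);
  t.bk = as<std::vector<double>>(topo["bond_k"]);
  t.ci = as<std::vector<int>>(topo["chir_i"]);
  t.c0 = as<std::vector<double>>(topo["chir_c0"]);
  t.ckappa = as<std::vector<double>>(topo["chir_kappa"]);
  t.cnorm = as<std::vector<double>>(topo["chir_norm"]);
  t.ni = as<std::vector<int>>(topo["nat_i"]);
  t.nj = as<std::vector<int>>(topo["nat_j"]);
  t.nsig = as<std::vector<double>>(topo["nat_sigma"]);
  t.neps = as<std::vector<double>>(topo["nat_eps"]);
  t.rep_cut = as<double>(topo["rep_cut"]);
  t.rep_eps = as<double>(topo["rep_eps"]);
  t.min_sep = as<int>(topo["min_sep"]);
  t.rep_sig = t.rep_cut / std::pow(2.0, 1.0 / 6.0);
  t.is_nat.assign((size_t)t.n * t.n, 0);
  for (size_t k = 0; k < t.ni.size(); ++k) {
    t.is_nat[(size_t)t.ni[k] * t.n + t.nj[k]] = 1;
    t.is_nat[(size_t)t.nj[k] * t.n + t.ni[k]] = 1;
  }
  return t;
}

void NeighborList::build(const Topology& topo, const std::vector<double>& x) {
  pi.clear();
  pj.clear();
  const double cut2 = (topo.rep_cut + skin) * (topo.rep_cut + skin);
  for (int i = 0; i < topo.n; ++i) {
    for (int j = i + topo.min_sep; j < topo.n; ++j) {
      if (topo.native(i, j)) continue;
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < cut2) {
        pi.push_back(i);
        pj.push_back(j);
      }
    }
  }
  ref = x;
}

bool NeighborList::stale(const std::vector<double>& x) const {
  if (ref.size() != x.size()) return true;
  const double lim2 = (skin * 0.5) * (skin * 0.5);
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i] - ref[i];
    double dy = x[i + 1] - ref[i + 1];
    double dz = x[i + 2] - ref[i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

EnergyTerms compute_forces(const Topology& topo, const std::vector<double>& x,
                           std::vector<double>& f, NeighborList& nl) {
  EnergyTerms e;
  f.assign((size_t)3 * topo.n, 0.0);

  // consecutive bond vectors are shared by the bond and chirality terms
  static thread_local std::vector<double> bv;
  bv.resize(topo.bi.size() * 3);

  // harmonic bonds: V = 1/2 k (r - r0)^2
  for (size_t b = 0; b < topo.bi.size(); ++b) {
    int i = topo.bi[b], j = topo.bj[b];
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    bv[3 * b] = dx;
    bv[3 * b + 1] = dy;
    bv[3 * b + 2] = dz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0)
      Rcpp::stop("coincident beads %d and %d (bond)", i + 1, j + 1);
    double dr = r - topo.br0[b];
    e.bonds += 0.5 * topo.bk[b] * dr * dr;
    double fac = -topo.bk[b] * dr / r;  // force on j along (j - i)
    f[3 * j] += fac * dx;
    f[3 * j + 1] += fac * dy;
    f[3 * j + 2] += fac * dz;
    f[3 * i] -= fac * dx;
    f[3 * i + 1] -= fac * dy;
    f[3 * i + 2] -= fac * dz;
  }

  // chirality: C = det(b1, b2, b3) / d0^3 over consecutive bond vectors,
  // V = 1/2 kappa (C - C_native)^2
  for (size_t w = 0; w < topo.ci.size(); ++w) {
    int i = topo.ci[w];
    const double* b1 = &bv[3 * (size_t)i];
    const double* b2 = b1 + 3;
    const double* b3 = b2 + 3;
    double c23[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                     b2[2] * b3[0] - b2[0] * b3[2],
                     b2[0] * b3[1] - b2[1] * b3[0]};
    double c31[3] = {b3[1] * b1[2] - b3[2] * b1[1],
                     b3[2] * b1[0] - b3[0] * b1[2],
                     b3[0] * b1[1] - b3[1] * b1[0]};
    double c12[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                     b1[2] * b2[0] - b1[0] * b2[2],
                     b1[0] * b2[1] - b1[1] * b2[0]};
    double det = b1[0] * c23[0] + b1[1] * c23[1] + b1[2] * c23[2];
    double C = det * topo.cnorm[w];
    double dC = C - topo.c0[w];
    e.chir += 0.5 * topo.ckappa[w] * dC * dC;
    double pref = -topo.ckappa[w] * dC * topo.cnorm[w];
    // dDet/db1 = b2 x b3, /db2 = b3 x b1, /db3 = b1 x b2; chain to atoms
    for (int d = 0; d < 3; ++d) {
      double g1 = pref * c23[d], g2 = pref * c31[d], g3 = pref * c12[d];
      f[3 * i + d] -= g1;
      f[3 * (i + 1) + d] += g1 - g2;
      f[3 * (i + 2) + d] += g2 - g3;
      f[3 * (i + 3) + d] += g3;
    }
  }

  // native contacts: full Lennard-Jones 4 eps [(s/r)^12 - (s/r)^6]
  for (size_t c = 0; c < topo.ni.size(); ++c) {
    int i = topo.ni[c], j = topo.nj[c];
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0.0)
      Rcpp::stop("coincident beads %d and %d (native contact)", i + 1, j + 1);
    double inv2 = 1.0 / r2;
    double s2 = topo.nsig[c] * topo.nsig[c] * inv2;
    double s6 = s2 * s2 * s2;
    double eps = topo.neps[c];
    e.native += 4.0 * eps * s6 * (s6 - 1.0);
    // dV/dr * 1/r = -24 eps (2 s12 - s6) / r^2
    double fac = 24.0 * eps * s6 * (2.0 * s6 - 1.0) * inv2;  // repulsive > 0
    f[3 * j] += fac * dx;
    f[3 * j + 1] += fac * dy;
    f[3 * j + 2] += fac * dz;
    f[3 * i] -= fac * dx;
    f[3 * i + 1] -= fac * dy;
    f[3 * i + 2] -= fac * dz;
  }

  // non-native repulsion: LJ with minimum at rep_cut, truncated there and
  // shifted up by eps so energy and force vanish continuously at the cutoff
  if (nl.stale(x)) nl.build(topo, x);
  const double cut2 = topo.rep_cut * topo.rep_cut;
  for (size_t p = 0; p < nl.pi.size(); ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2) continue;
    if (r2 <= 0.0)
      Rcpp::stop("coincident beads %d and %d (repulsion)", i + 1, j + 1);
    double inv2 = 1.0 / r2;
    double s2 = topo.rep_sig * topo.rep_sig * inv2;
    double s6 = s2 * s2 * s2;
    e.rep += 4.0 * topo.rep_eps * s6 * (s6 - 1.0) + topo.rep_eps;
    double fac = 24.0 * topo.rep_eps * s6 * (2.0 * s6 - 1.0) * inv2;
    f[3 * j] += fac * dx;
    f[3 * j + 1] += fac * dy;
    f[3 * j + 2] += fac * dz;
    f[3 * i] -= fac * dx;
    f[3 * i + 1] -= fac * dy;
    f[3 * i + 2] -= fac * dz;
  }

  return e;
}
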