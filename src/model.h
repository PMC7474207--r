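#ifndef GOPULL_MODEL_H
#define GOPULL_MODEL_H

#include <Rcpp.h>
#include <vector>

// Full coarse-grained force field: harmonic bonds, native-chirality term,
// native Lennard-Jones contacts, and truncated-shifted repulsion between all
// non-native pairs with sequence separation >= min_sep.
struct Topology {
  int n;
  // bonds (i, j) 0-based, native length r0, spring constant k (eps/A^2)
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  // chirality windows: residues (i, i+1, i+2, i+3); native signed triple
  // product c0 (already normalised), stiffness kappa, normalisation 1/d0^3
  std::vector<int> ci;
  std::vector<double> c0, ckappa, cnorm;
  // native contacts with LJ sigma (A) and well depth eps
  std::vector<int> ni, nj;
  std::vector<double> nsig, neps;
  // repulsion between non-native pairs, |i-j| >= min_sep
  double rep_cut, rep_eps, rep_sig;
  int min_sep;
  std::vector<char> is_nat;  // n*n lookup

  bool native(int i, int j) const { return is_nat[(size_t)i * n + j] != 0; }
};

struct EnergyTerms {
  double bonds = 0.0, chir = 0.0, native = 0.0, rep = 0.0, springs = 0.0;
  double total() const { return bonds + chir + native + rep + springs; }
};

Topology parse_topology(const Rcpp::List& topo);

// Verlet-style pair list for the short-range repulsion
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref;  // positions at last build (n*3)
  double skin;
  void build(const Topology& topo, const std::vector<double>& x);
  bool stale(const std::vector<double>& x) const;
};

// Forces accumulated into f (length 3n); returns energy breakdown.
// Throws Rcpp::exception on coincident beads.
EnergyTerms compute_forces(const Topology& topo, const std::vector<double>& x,
                           std::vector<double>& f, NeighborList& nl);

#endif
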