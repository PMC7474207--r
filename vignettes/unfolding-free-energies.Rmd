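---
title: "Coarse-grained pulling simulations and unfolding free energies of helix bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained pulling simulations and unfolding free energies of helix bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mechanosensitive proteins such as the talin rod are built from bundles of
four or five alpha-helices that unfold under tension through partially
unfolded intermediates — most prominently a *three-helix state* in which two
helices have peeled off while three remain packed. Whether such an
intermediate is a genuine metastable state, where along the extension it
appears, and how much free energy its rupture costs are questions about the
potential of mean force (PMF) along the pulling coordinate, the end-to-end
distance between the terminal C-alpha atoms.

`gopull` implements, in one coherent reduced-unit framework, the three
standard routes to that profile and the trajectory analyses used to call
intermediates:

1. **Steered pulling (SMD)** — constant-velocity pulling by terminal
   springs; the accumulated pulling work $W(t)=\sum F\,v_p\,\mathrm{d}t$
   upper-bounds the free-energy profile ($\Delta W \ge \Delta G$, with
   equality in the quasi-static limit).
2. **Boxed dynamics (BXD)** — the coordinate is split into boxes; the
   trajectory is reflected at box walls, wall-hit statistics give box-to-box
   rate constants, and $\Delta G_{m,m+1} = -k_BT\,
   \ln\!\left(k_{m\to m+1}/k_{m+1\to m}\right)$ assembles the PMF.
3. **Umbrella sampling + WHAM** — harmonic biases hold windows along the
   coordinate and the weighted-histogram equations recover the unbiased
   profile.

Cross-checking BXD against umbrella sampling, and both against the SMD work
profile, is the methodological core: the three estimators have very
different failure modes (nonequilibrium dissipation, within-box
equilibration, window overlap), so their agreement is evidence that the
profile is converged.

## The model

The force field is a structure-based (Gō-type) model at one bead per
residue, centred on the C-alpha positions of a native structure:

* **Bonds**: harmonic springs between consecutive residues at their native
  lengths (default stiffness 100 ε/Å²; the literature for this model family
  does not pin this value, and the results are insensitive to it as long as
  bonds are stiff).
* **Local chirality**: for each four-residue window, $V = \tfrac12
  \kappa\,(C - C^{\mathrm{nat}})^2$ with $C$ the signed triple product of
  the three bond vectors normalised by the product of native bond lengths
  (κ = 1 ε). This is the standard way this model family encodes native
  handedness; the exact functional form is isolated behind one term so it
  can be swapped.
* **Native contacts**: residue pairs in contact in the native structure
  interact by a full Lennard-Jones potential
  $V_{LJ} = 4\varepsilon\left[(\sigma_{ij}/r_{ij})^{12} -
  (\sigma_{ij}/r_{ij})^{6}\right]$ with $\sigma_{ij}$ chosen so the minimum
  sits at the native pair distance and a *uniform* well depth ε — the energy
  unit of the model, calibrated against unfolding experiments at about
  110 pN·Å ≈ 6.62 kJ/mol.
* **Contact definition (overlap criterion)**: two residues at least three
  apart in sequence form a native contact when any two of their heavy atoms
  overlap after enlarging the van der Waals radii 1.24-fold. The radii
  table (C 1.70, N 1.55, O 1.52, S 1.80 Å) is configurable; the criterion's
  source does not name its table, and contact counts are mildly sensitive
  to this choice.
* **Non-native pairs** repel below 4 Å (a Lennard-Jones branch truncated at
  its minimum and shifted, so energy and force vanish continuously at the
  cutoff). Bonded neighbours and $i,i{+}2$ pairs are excluded from
  non-bonded terms.

Dynamics are overdamped Langevin (Brownian) at $k_BT = 0.3\,\varepsilon$
(room temperature in this calibration), damping $\gamma = 2m/\tau$, time
step $0.005\,\tau$ with $\tau \sim 1$ ns. The integrator is
Euler–Maruyama: the contract is correct Boltzmann sampling, which the test
suite verifies directly (equipartition, Kolmogorov–Smirnov distance against
quadrature densities); a fifth-order predictor–corrector would add nothing
observable at this time step. An inertial BAOAB variant exists for the 1D
validation systems, where BXD's velocity-inversion reading can be
exercised; the protein engine is overdamped-only, matching the model's
stated operating regime.

Pulling attaches springs of 0.12 ε/Å² to both termini; one anchor is fixed,
the other moves at $v_p = 0.005$ Å/τ along the initial N→C axis (fixed
direction, the AFM analogy). Reported force is the moving spring's tension
along that axis.

## Synthetic structures: what they emulate and what they do not

Real talin subdomain coordinates cannot be bundled with the package, so
`make_helix_bundle()` generates idealised antiparallel C-alpha bundles:
helices with 1.5 Å rise and 100°/residue twist at 2.3 Å radius, axes on a
circle with adjacent-axis spacing `packing_distance` (default 10 Å), joined
by short bulging loops. Each residue carries pseudo heavy atoms — carbons
displaced toward the helix axis and toward each packing neighbour — placed
so that the 1.24× overlap criterion yields both intra-helix (i, i+3)
contacts and a dense inter-helix interface. These atoms are *fixture
machinery*, not a side-chain model: they give the generator a realistic
contact topology (a dozen intra-helix contacts per helix, roughly 10–13
tertiary contacts per packed interface), which is what the downstream
methods actually consume.

The fixture reproduces the features the methods depend on — helical
geometry detectable from C-alpha distances, a funnel-shaped Gō energy with
a packed native state, terminal-helix unpeeling under tension, three-helix
intermediates, monotonically increasing unfolding PMFs. It does **not**
reproduce sequence heterogeneity, varying helix lengths, side-chain packing
specificity, or the relative mechanical strengths of real subdomains; a
green test on the fixture validates the *machinery*, not any biological
claim about talin.

## Helix detection without hydrogen bonds

Secondary-structure assignment on C-alpha-only frames cannot use
backbone-H-bond methods. The detector marks a 5-residue window starting at
residue $i$ helix-like when $d(i,i{+}3) \in [4.5, 6.0]$ Å and
$d(i,i{+}4) \in [5.0, 6.8]$ Å (both configurable), spanning
alpha/3₁₀/pi-like compactness. Marking only window starts would clip every
helix C-terminus by four residues — structurally capping agreement with the
generator ground truth at (len−4)/len — so two *consecutive* qualifying
windows mark their full i…i+5 span, the C-alpha analogue of DSSP's
requirement of two consecutive H-bonds. Runs of ≥ 4 marked residues become
segments H1, H2, … from the N-terminus. On generated bundles (2–5 helices,
lengths 10–20) this reproduces the ground-truth segment count exactly and
per-residue labels to better than 90%.

## BXD: counting rule, burn-in, and honest errors

Within a box, every proposed update that would cross a wall counts as a
hit; the displacement's reaction-coordinate component is reflected (the
overdamped reading of velocity inversion — in inertial mode the velocity
projection is negated). After the event quota (both walls pooled; default
2000) the trajectory is released through the upper wall: the sweep runs
from the folded state toward extension. Rates are wall-resolved,
$k = \mathrm{hits}/\mathrm{residence\ time}$.

Two numerical realities shape the implementation:

* **Entry transient.** A box is entered through its lower wall, so the
  first hits oversample that wall and bias $k_{m+1\to m}$ upward
  (a systematic *negative* PMF bias). A burn-in of 10% of the event quota
  (uncounted hits, configurable) removes most of it; the
  `equilibration_check()` report compares first- and second-half hit rates
  box by box, implementing the "equilibrium is assumed and tested for"
  discipline.
* **Hit bursts.** With diffusive steps much smaller than the box, hits
  arrive in strongly correlated bursts, so binomial/Poisson error bars on
  hit counts understate the true uncertainty considerably. The error model
  the package trusts is replica spread: independent BXD sweeps (the
  reference protocol ran 11 replicas per system) whose standard deviation
  *is* the reported uncertainty. The per-boundary binomial propagation is
  still computed (it is cheap and a useful lower bound) but
  cross-validation tests use replica-based errors.

The printed form of the box-equilibrium relation omits the logarithm;
dimensional analysis (and the BXD literature) require
$\Delta G = -k_BT \ln K$, which is what the package implements and what the
quadrature oracle confirms.

For the oracle tests on 1D analytic potentials the time step is 0.001 τ
rather than the protein model's 0.005 τ: reflected Euler–Maruyama carries an
$O(\sqrt{\mathrm{d}t})$ boundary-layer error at the walls, and at
0.005 τ this discretisation artefact (≈ 0.03 ε per steep boundary) would
contaminate what is meant to be a test of the *estimator*. The criterion
that fixes kT, box width and event count does not fix the 1D time step.

## Umbrella sampling and WHAM

Windows are seeded from pulling-trajectory frames nearest each centre
(2000 kJ/mol/nm² ≈ 3.02 ε/Å² umbrella, 0.1 nm spacing, mirroring the
production protocol), equilibrated for the first third of each run by
default (the 30 ns-run/analyse-last-20 ns convention), and unbiased by
self-consistent WHAM iteration to an offset tolerance of 1e-8 ε. Two
numerical choices matter:

* **Bin width** defaults to the smaller of half the window spacing and a
  quarter of the stiffest window's thermal width $\sqrt{k_BT/k_{umb}}$.
  The bias factor is evaluated at bin centres; with bins coarse relative to
  the umbrella curvature this tilts the profile by ~0.1 ε, which is what a
  too-coarse default produced in testing.
* **Occupancy trimming**: bins with fewer than 5 pooled samples are
  dropped. A noisy tail bin can otherwise become the spurious minimum and
  corrupt the min-zero gauge of the whole profile.

Errors come from a 200-resample bootstrap over each window's sample set
(50 resamples in the time-budgeted tests).

## Intermediate calls on trajectories

For each pair of annotated helices, Q is the fraction of their native
*tertiary* contacts currently formed (formed below 1.5× the native
distance). Three documented defaults make replica-level state sequences
well-behaved where the raw per-frame rule would flicker:

* contacts between residues closer than 10 in sequence are excluded from
  pair Q — contacts straddling a 4-residue loop behave as local structure
  and never report detachment;
* Q is smoothed over 9 frames;
* the state machine uses a hysteresis band: a helix detaches below
  Q = 0.35 and re-attaches only above 0.65. Fluctuations inside the band,
  inevitable when a pair has ~10 quantised contacts, do not toggle the
  state. The single-frame classifier `classify_state()` keeps the plain 0.5
  threshold.

A helix's detachment extension is the extension at its last crossing into
the detached state; the three-helix call reports which helices survive.
Unfolding events on PMF (or force) profiles are regions where the local
slope exceeds a multiple (default 3×) of the median slope — an explicit
stand-in for the visual shading of events in the reference figures.

## Scaling decisions in the test suite

The full protocol (1.05× contour extension per replica, full-range BXD)
costs hours; the suite must run in minutes. Scaled, with thresholds
unchanged:

* the 20 pulling replicas of the acceptance test run to 160 Å extension —
  across pilot seeds the complete four→three→two→zero pathway finishes by
  ~140 Å — instead of 283 Å;
* BXD–WHAM cross-validation runs over the first 15 Å of extension (the
  quasi-equilibrium stage). Both estimators run as replicas — 6 BXD sweeps
  and 3 umbrella/WHAM estimates seeded from independent pulling
  trajectories — and their box-integrated profiles must agree within the
  combined replica scatter, which is how the reference analysis (plotting
  per-replica profiles) judges agreement. The BXD event quota is
  calibrated per system, as the reference workflow prescribes: on this
  fixture 2000 events/box leaves within-box conformational equilibration
  incomplete (the profile sits ~0.3–0.5 ε high with large scatter), while
  16000 events with half discarded as burn-in reproduces an independent
  referee — the PMF from a long *unbiased* equilibrium trajectory's
  end-to-end histogram (10⁸ steps; feasible because the compared range
  spans only ~6 k_BT) — to ~0.05 ε, as does WHAM;
* the contour-length property uses a 2-helix bundle.

## Known limitations

* The overdamped engine is Euler–Maruyama: wall reflection carries an
  $O(\sqrt{\mathrm{d}t})$ boundary-layer bias, visible in steep 1D
  potentials at dt = 0.005 τ (mitigated as described above; irrelevant at
  the soft walls of the protein runs relative to replica spread).
* No side chains, uniform well depths and masses: relative mechanical
  strengths of real subdomains are outside the model's resolution.
* BXD box placement is static; no adaptive refinement.
* The refolding direction (reverse sweeps, refolding kinetics) is
  configuration-level only and untested science.
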