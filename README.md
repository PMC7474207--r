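# gopull

Coarse-grained, structure-based (Gō-model) simulation of mechanical protein
unfolding, with three independent routes to the unfolding free-energy
profile along the end-to-end reaction coordinate:

* **steered pulling** (constant-velocity springs on the termini) with the
  accumulated pulling work `W(t) = Σ F·v_p·dt`, an upper bound on ΔG;
* **boxed dynamics (BXD)**: reflecting walls partition the coordinate into
  boxes, wall-hit statistics give box-to-box rate constants, and
  `ΔG = −k_B T · ln(k_forward / k_backward)` assembles the PMF;
* **umbrella sampling** with a weighted-histogram (WHAM) solver.

The intended audience is anyone studying mechanosensitive α-helical
proteins — e.g. talin rod subdomains, which unfold under force through
*three-helix intermediates* — and anyone who wants the three estimators in
one reduced-unit framework to cross-validate against each other.

## The model in brief

One bead per residue at the C-alpha position. Native contacts (residue
pairs whose heavy atoms overlap after a 1.24× enlargement of their van der
Waals radii, sequence separation ≥ 3) interact by a Lennard-Jones well of
uniform depth ε (≈ 110 pN·Å ≈ 6.62 kJ/mol) with its minimum at the native
distance; all other pairs repel below 4 Å. Harmonic bonds and a native
chirality term complete the potential. Dynamics are overdamped Langevin at
k_BT = 0.3 ε, damping γ = 2m/τ, time step 0.005 τ; pulling uses
0.12 ε/Å² springs at 0.005 Å/τ. See the methods vignette
(`vignettes/unfolding-free-energies.Rmd`) for everything tunable and why.

Structures come from PDB files (`read_pdb_calpha()`) or from the built-in
synthetic helix-bundle generator (`make_helix_bundle()`), which emulates
antiparallel 2–5-helix bundles so the whole pipeline is testable without
downloads.

## Worked example

Pull a synthetic 4-helix bundle apart and classify its unfolding pathway:

```r
library(gopull)

st   <- make_helix_bundle(n_helices = 4, helix_len = 15, loop_len = 4,
                          packing_distance = 10, seed = 1)
map  <- build_contact_map(st)            # 1.24x overlap criterion
topo <- build_topology(st, map)
topo
#> GoTopology: 72 residues, 71 bonds, 69 chirality windows, 107 native contacts

tr <- run_pulling(topo, pulling_protocol(total_extension = 160),
                  langevin_params(), seed = 7001,
                  stride = 2000, frame_stride = 4000)

detect_rupture_peaks(tr, smoothing_window = 21, min_prominence = 0.8)
#>   extension peak_force
#> 1  31.51902   1.082746

Q  <- helix_pair_contact_fraction(tr, map, st$helix_ground_truth)
ic <- intermediate_call(Q, attr(tr, "frame_end_to_end"),
                        st$helix_ground_truth)
paste(ic$state_sequence, collapse = " -> ")
#> "four-helix -> three-helix -> two-helix -> zero-helix"
round(ic$detachment_extension, 1)
#>    H1    H2    H3    H4
#> 114.7 114.7  89.4  52.7
ic$three_helix_set
#> "H1" "H2" "H3"
```

Reading: the bundle ruptures once near 32 Å extension with a ~1.1 ε/Å
(≈ 120 pN) force peak — helix H4 peels off first (detaching at 53 Å),
leaving a three-helix intermediate formed by H1–H3 that survives to ~90 Å;
by 115 Å the bundle is fully dissociated ("zero-helix"). The accumulated
pulling work for the 160 Å of anchor travel is 90.3 ε ≈ 598 kJ/mol, an
upper bound on the unfolding free energy at this pulling speed.

A PMF for the same fixture by BXD:

```r
cfg   <- bxd_config(10, 40, box_width = 5, events_per_box = 2000)
stats <- run_bxd(topo, cfg, langevin_params(), seed = 11)
bxd_pmf(stats)          # rc (A), free_energy (eps), stderr
equilibration_check(stats)
```

and by umbrella sampling seeded from the pulling run:

```r
starts <- seed_windows_from_pulling(tr, centers = seq(11, 25, by = 1))
wins <- lapply(seq_along(starts), function(i)
  run_window(topo, starts[[i]], k_umb = umbrella_k_to_reduced(2000),
             n_steps = 2e6, seed = 1000 + i))
wham_bootstrap(wins, kT = 0.3)
```

## Command line

```sh
inst/exec/gopull fixture --helices 4 --len 15 --seed 1 -o bundle.pdb
inst/exec/gopull pull bundle.json --velocity 0.005 --spring-k 0.12 \
    --replicas 20 --seed 7 -o pull/
inst/exec/gopull bxd bundle.json --box-width 5 --events 2000 --seed 3 -o bxd/
```

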