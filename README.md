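# nucmet

Analysis toolkit for how divalent cations shape ATP recognition and release
by a trimeric receptor. The package covers three connected computations:

1. **Metal–nucleotide coordination modes.** For a structure carrying ATP (or
   the non-hydrolyzable analog AMP-PNP) and a divalent ion, each phosphate
   group *s* ∈ {α, β, γ} is summarized by a soft-minimum *ion-coordination
   number* over its non-backbone oxygen–ion distances *d<sub>i</sub>*:

   *N*<sup>s</sup> = *R* / ln Σ<sub>i</sub> exp(*R*/*d<sub>i</sub>*),  *R* = 1000 Å

   computed with an overflow-safe log-sum-exp shift. *N*<sup>s</sup> is a
   smooth lower bound on the minimum oxygen–ion distance; values below
   3.2 Å mark direct coordination, and the *mode* (α, β, γ, αβ, …, αβγ,
   none — written `a`, `b`, `g`, …, `abg`, `none` in code) is the set of
   directly coordinating groups. A survey pipeline applies, in order, an
   X-ray/resolution filter (≤ 2.5 Å), sequence-redundancy elimination
   (70 % global-alignment identity), site extraction, concurrent-cation
   exclusion and mode classification, and emits an occurrence table with a
   per-entry audit log.

2. **ATP-dissociation trajectory analysis.** For three-subunit trajectory
   windows it computes per-subunit distance series **D1** (center of mass of
   ATP to center of mass of the binding-site residues T172/K63/K65/R281/R299,
   hydrogens excluded) and **D2** (γ-phosphorus to the ion), detects
   dissociation events (D1 > 12 Å, persistent by default), builds mean ± SEM
   event-count curves versus the interaction-scaling factor *S*, and fits

   *f*(*S*) = 3 / (1 + exp[*m*(*S* − *n*)])

   by Levenberg–Marquardt with multistart. Snapshot selections (dissociated
   state: D1 > 12 Å and D2 > 5 Å; acidic chamber: ion within 6 Å of the
   D158/E156/E111/E109 carboxylates) feed subunit-averaged 3D occupancy maps
   (cloud-in-cell deposition, Kabsch superposition of subunits, optional
   Gaussian smoothing, CCP4/MRC output).

3. **Solution speciation.** Equilibrium concentrations of free ATP, free
   cations and 1:1 metal–ATP complexes from stability constants
   (log₁₀ K: Mg 4.10, Ca 3.76, Na 0.83, K 1.17), plus the inverse problem of
   designing totals that realize target free-ATP and Mg-ATP concentrations.

Because cluster-scale molecular dynamics and a versioned structure database
are out of reach of a test suite, the package ships first-class synthetic
generators: structure fixtures with prescribed per-phosphate coordination
geometry (the spec is its own classification oracle) and three-subunit
trajectory ensembles whose escape statistics follow a ground-truth logistic
in *S*.

## Worked example

```r
library(nucmet)

# classify a structure's metal site
model <- make_structure_fixture(fixture_spec("bg", seed = 7))
site  <- extract_sites(model)[[1]]
ion   <- select_bound_metal(site, "MG")
classify_mode(site, ion)
#> coordination mode: bg  (N^a=4.172, N^b=2.300, N^g=2.300 A; threshold 3.20 A)

# dissociation curve and logistic fit from a simulated ensemble
spec <- ensemble_spec(n_replicas = 20, dt = 0.5, seed = 11)
fit  <- fit_logistic(dissociation_curve(simulate_ensemble(spec)))
fit
#> logistic_fit: m = 49.82, n = 0.4205 (C.C. = 0.9978)
```

The fitted slope and midpoint recover the generator's ground truth
(m = 58.6, n = 0.42) within the sampling error of 20 replicas per point;
the correlation coefficient between observed and fitted means exceeds 99 %.

The numbered scripts under `analysis/` run the full workflows — mini-survey
(`01`), binding-site geometry of the synthetic trimeric model (`02`),
dissociation curves and fits for the with- and without-ion conditions
(`03`), occupancy density maps (`04`), and solution speciation (`05`) —
writing their tables under `results/`.

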