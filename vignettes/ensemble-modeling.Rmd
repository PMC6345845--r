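---
title: "Coarse-grained ensemble modeling of flexible complexes against SAXS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained ensemble modeling of flexible complexes against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexsaxs)
```

## The problem

Large multi-protein complexes with long intrinsically disordered linkers
resist crystallography, NMR and cryo-EM alike: they are conformationally
heterogeneous by construction. Small-angle X-ray scattering (SAXS) measures
such systems in solution, but a SAXS curve is a rotationally averaged,
one-dimensional fingerprint — interpreting it structurally requires a pool
of physically plausible three-dimensional conformations to test against the
data. flexsaxs implements that workflow end to end:

1. represent the complex as **rigid bodies** (folded, crystallized domains,
   one bead per residue at the C-alpha position) joined by **flexible
   linker chains** of amino-acid beads;
2. sample conformations by **replica-exchange Metropolis Monte Carlo**
   (REMC), in solution or restrained to an implicit flat membrane;
3. compute a theoretical SAXS profile for every saved conformation with the
   **Debye formula**;
4. select single structures or a **minimum ensemble** — the smallest set of
   conformations whose weighted profile fits the measured curve within a
   reduced chi-square threshold;
5. characterize the accepted structures by **QT clustering** under a DRMS
   metric, and membrane-mode pools by per-residue **membrane contact
   probabilities** and extension (Dmax, Rg) statistics.

## The model

### Geometry

Every residue is one bead. Rigid bodies keep their internal geometry
exactly (moves act on the pose: rotation about the body centroid plus
translation); linker beads are free particles tied by bonded terms.
Internal units are Angstrom and kcal/mol throughout; membrane heights
quoted in nm elsewhere are 10x in Angstrom (the membrane surface sits at
z = 20 A = 2 nm by default). Linkers missing from crystal structures are
initialized in extended geometry — consecutive beads at the 3.8 A C-alpha
spacing, seated along the line between their anchors — rather than by
loop-modeling software; Monte Carlo relaxation takes care of the rest.

### Energy

The potential is deliberately minimal and fully configurable
(`energy_model()`):

* **Bonded** (linkers only): harmonic stretch `1/2 k_b (b - 3.8)^2`
  (k_b = 10 kcal/mol/A^2), harmonic bend about a typical C-alpha
  pseudo-angle of 2.12 rad (k_a = 5 kcal/mol/rad^2), and a weak cosine
  torsion `k_t (1 + cos phi)` (k_t = 0.2 kcal/mol). A collinear chain
  leaves the dihedral undefined; we take the trans convention (zero
  torsion energy) there, which makes the extended initial geometry
  torsion-relaxed.
* **Contacts**: a square well of depth `eps_ij` for pair distances inside
  8 A, with a finite steep repulsion below the 4 A excluded-volume radius
  (capped, so overlapping beads have a large but finite energy and the
  sampler never sees a singularity). The 20 x 20 well-depth table defaults
  to a simple two-level hydrophobicity rule — hydrophobic-hydrophobic
  pairs (0.30 kcal/mol) deeper than polar pairs (0.05) — and is fully
  user-replaceable from a whitespace-delimited text table
  (`read_contact_matrix()`). Results should always be reported together
  with the matrix used.
* **Electrostatics**: screened Debye-Hueckel,
  `332.0637 q_i q_j exp(-r/lambda_D) / (eps_r r)`, with integer formal
  charges at pH 7 (Asp/Glu -1, Lys/Arg +1, His neutral by default and
  configurable), Debye length 10 A (about 150 mM monovalent salt) and
  eps_r = 80.
* **Membrane** (membrane mode only): soft harmonic anchors
  `1/2 k (z_i - z_0)^2` on designated beads (k = 0.1 kcal/mol/A^2 by
  default — soft enough for z fluctuations of a few Angstrom at 300 K,
  which is the point of modeling a flexible lipid anchor); a
  per-residue-type Gaussian attraction of depth 0.05-0.25 kcal/mol within
  ~5 A of the plane standing in for statistical amino-acid/lipid
  interaction profiles (hydrophobics strongest, Lys/Arg intermediate for
  the headgroup attraction); and a steep half-space wall below the plane
  for impenetrability. The attraction's functional form and depths are
  configuration, not physics we claim to derive.

Exclusions: pairs within the same rigid body and directly bonded
neighbours contribute no nonbonded energy.

### Sampling

One sweep attempts one move per mobile degree of freedom: each rigid body
a random translation (default amplitude 1 A) or rotation about its
centroid (0.15 rad), each linker bead a local displacement or — when the
bead has a free tail on one side of its chain — a pivot of that tail
(0.3 rad). Moves are accepted with the Metropolis probability
`min(1, exp(-dE/kT))`. The default amplitudes give move acceptance around
10-40% on the toy systems shipped here.

Replica exchange runs a geometric temperature ladder between 300 and
500 K (the source protocol states endpoints and replica count, not the
spacing; geometric is the parallel-tempering default). Every 10 sweeps,
`n_replicas - 1` swap attempts are made between randomly chosen adjacent
ladder slots with the standard acceptance
`min(1, exp((beta_i - beta_j)(E_i - E_j)))`. Conformations are recorded
every `save_interval` sweeps from all replicas (solution default) or from
the lowest-temperature replica only (membrane default); the 32-trajectory
arithmetic of the solution protocol implies all replicas were saved there,
while the membrane protocol states room-temperature-only saving — both are
overridable. The reference protocols are pure bookkeeping here
(`plan_pool_size()`): 2 runs x 16 replicas x 5e6 sweeps / 1000 = 160,000
solution structures; 20 runs x 1 saved replica x 2.5e6 / 1000 = 50,000
membrane structures.

Each of the `n_runs` independent runs starts from a different randomized
conformation (all body poses redrawn) and its own RNG stream spawned from
the master seed, so pools are reproducible bit for bit.

For efficiency the Metropolis delta only re-evaluates terms touching moved
beads (unmoved-unmoved contributions cancel); the full energy is
recomputed at every save event, which also guards against numeric drift
and aborts on non-finite energies.

### SAXS profiles and fitting

`debye_intensity()` evaluates the exact orientation-averaged Debye double
sum with per-residue form factors (a single constant effective form factor
per bead by default; a per-residue or q-dependent table can be supplied).
Excluded-volume and hydration-shell corrections are deliberately omitted —
a documented limitation appropriate for bead models compared on relative
shape, not absolute intensity.

`chi2_fit()` uses the error-weighted chi-square with the intensity scale
`a` solved analytically from `d chi2/d a = 0`. Because published
goodness-of-fit values for this statistic are of order one, the headline
number reported is the **reduced** chi-square (divided by the number of
data points); the raw sum is kept alongside. Model profiles are aligned to
the target grid by linear interpolation in q; extrapolation is an error.

`guinier_fit()` fits `ln I = ln I0 - q^2 Rg^2/3` by (weighted) linear
regression, starting from the widest usable window and shrinking until
`q_max Rg <= 1.3` reaches a fixed point. Note the window limit is part of
the definition: for a homogeneous sphere the qRg <= 1.3 window biases the
fitted Rg about +1.8% relative to the exact `sqrt(3/5) R` — visible in our
own sphere checks, and inherent to the Guinier convention rather than a
defect of the fit.

### Selection

`rank_structures()` fits every pool profile individually (ascending
reduced chi-square, ties broken by pool id). `minimum_ensemble()` searches
sizes s = 1, 2, ... in order, exhaustively over equal-weight combinations
of a candidate pool pruned to the best 200 singles, and returns the first
size whose best combination reaches the acceptance threshold (default
reduced chi-square 1.5, between the ~1.2-1.3 values typically accepted and
the >= 1.8 regime treated as failure). The search is made cheap by a Gram
identity: with `u_k = sum(w I_exp I_k)` and `v_kl = sum(w I_k I_l)`, the
optimally rescaled equal-weight subset S has
`chi2 = sum(w I_exp^2) - (sum_{k in S} u_k)^2 / sum_{k,l in S} v_kl`, so
pair search over 200 candidates is a few milliseconds. Whether the
original analysis searched exhaustively is unstated; exhaustive search
over a pruned candidate set is the reproducible choice. An optional
non-negative-least-squares mode fits free weights per subset (a tiny
Lawson-Hanson active-set solver) as an extension beyond the equal-weight
definition.

One subtlety: with strictly equal weights the best chi-square is not
mathematically guaranteed monotone in s (a size-3 mean cannot reproduce
every 50/50 pair mixture). `minimum_ensemble()` therefore reports the best
combination over all sizes up to `max_size`, which restores the
"adding freedom never hurts" monotonicity and is what the search
semantics require anyway.

### Clustering

`drms()` is the root-mean-square difference of internal bead-pair
distances over a declared pair set — invariant to global rotation and
translation by construction. The default pair set is all inter-body pairs
(capturing the relative placement of the rigid bodies while ignoring
linker noise), subsampled to at most 5,000 pairs with a fixed seed for
tractable matrices; exactly which pairs enter the metric is a declared
parameter, since the reference analysis does not state its choice.
`qt_cluster()` is the classic quality-threshold procedure with cluster
*diameter* (maximum intra-cluster DRMS) as the quality measure: grow a
candidate from every remaining point by always adding the point that
increases the diameter least (ties: lowest id), commit the largest
candidate (ties: lowest seed id), repeat. Determinism of the tie-breaks is
part of the contract and is tested.

### Membrane analysis

`contact_probability()` counts, per bead, the fraction of saved
room-temperature conformations with z below a threshold z0, conventionally
scanned over 20-25 A (2-2.5 nm); values outside that window warn. Since
membrane-mode runs save the lowest-temperature replica only, the
probabilities refer to room-temperature structures. `extension_stats()`
reports exact order statistics, means and histograms of per-conformation
Dmax and Rg. When analyzing a finite run, we discard the first fifth of
the saved frames as burn-in before quoting contact probabilities: the
chains start from a randomized (or lifted reference) pose and the soft
anchors need a few thousand sweeps to settle.

## What the synthetic data emulate — and what they do not

No experimental scattering curves are bundled (none are publicly
deposited for the motivating system), so the `synthetic_data` functions
generate everything the tests exercise:

* `make_toy_complex()` builds a dumbbell: rigid bead clouds filling
  spheres, joined by a flexible linker, in a compact or extended reference
  geometry — the minimal system exhibiting the compact/extended dichotomy
  that makes minimum-ensemble analysis interesting. With
  `membrane_anchors = TRUE` the most peripheral bead of the first and last
  body carries a soft z-anchor (a lipid-anchored residue must be
  surface-exposed; an interior bead could never reach the plane past the
  excluded-volume wall).
* `synthesize_saxs()` adds Gaussian noise with
  `sigma(q) = alpha + beta I(q)` and records that sigma truthfully — the
  multiplicative-plus-floor stand-in for a beamline error model, which
  reproduces exactly the statistical structure the chi-square assumes
  (known per-point errors). With `alpha = beta = 0` no noise is added and
  unit errors are recorded, since zero errors would be degenerate in the
  chi-square.
* `two_state_fixture()` plants a known 50/50 two-structure truth in a
  200-structure pool of decoys with 1% multiplicative noise. Decoys are
  sampled around each truth state by seeded pose kicks whose translation
  always carries a radial component of at least half the kick scale
  (default scale 6 A, so radial offsets of 3-18 A) along the body
  separation axis: the orientation-averaged profile senses mainly the
  inter-body distance distribution, and purely tangential displacements
  would create profile-degenerate decoys that no method could reject.
  The pool's Rg range spans the compact-to-extended interval by
  construction.

Passing these tests shows the machinery is correct and well calibrated
(the generating ensemble scores reduced chi-square ~1 against its own
noisy data; the true pair is recovered in >= 18/20 seeded repetitions). It
does **not** show that real experimental curves — with inter-particle
structure factors, buffer-subtraction artifacts, hydration-shell contrast
and correlated errors — would be interpreted equally cleanly, nor that the
shipped contact matrix is a quantitatively accurate force field.

## Numerical choices and problem sizes

* Degenerate geometry: collinear dihedrals take the trans convention;
  acos arguments are clamped to [-1, 1]; bead separations below 0.1 A are
  evaluated at 0.1 A inside the (finite) repulsive core.
* Guinier fitting requires at least 5 usable points, drops non-positive
  intensities with a warning, and errors when `q_min Rg` already exceeds
  the limit.
* Ties everywhere (ranking, minimum-ensemble enumeration, QT growth and
  commitment) resolve to the lowest id, making every result reproducible.
* The test suite and the acceptance script run REMC at deliberately small
  problem sizes — a 72-bead dumbbell, 8 replicas, 1e5 sweeps for the
  membrane checks; a single restrained bead and 1e5 sweeps for the
  Boltzmann calibration — chosen so the full statistical checks
  (variance ratios, goodness-of-fit, 20-seed recovery) rerun from scratch
  in a few minutes on one core while leaving the protocol-scale runs to
  `plan_pool_size()` bookkeeping.

## Known limitations

* The contact and membrane interaction tables are simple documented
  defaults, not derived statistical potentials; quantitative energetics
  (binding constants, absolute contact probabilities away from anchors)
  should not be read off them.
* Form factors default to a single constant per bead; no excluded-volume
  or hydration corrections are applied to Debye profiles.
* Equal-weight minimum ensembles are a structural *representation* of the
  data, not the true conformational distribution — two structures fitting
  a curve proves heterogeneity, not a two-state landscape.
* The implicit membrane is a flat plane: no curvature, leaflet asymmetry
  or lipid specificity.

## A worked sketch

```{r example, eval = FALSE}
library(flexsaxs)

fx <- two_state_fixture(seed = 1)          # pool + noisy target + truth
im <- pool_intensities(fx$pool, fx$target$q)
ranked <- rank_structures(im, fx$target)   # no single structure fits
head(ranked, 3)
ens <- minimum_ensemble(im, fx$target, max_size = 2, chi2_accept = 1.5)
ens                                        # the planted pair, chi2 ~ 1

cs <- qt_cluster(drms_matrix(fx$pool), cutoff = 8)
glance(cs)
```
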