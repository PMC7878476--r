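---
title: "Models and methods behind xlinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xlinkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkr)
```

xlinkr implements the computational side of an integrative XL-MS study of
a multidomain, partially disordered protein: from cross-linker mass
accounting through contact maps, ensemble scoring, restraint-driven
compaction, hydrodynamic size, sequence electrostatics, NMR chemical shift
perturbations, and fluorescence-polarization binding models. This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## Cross-linker chemistry and mass accounting

Every mass the package reports is derived at run time from a table of
IUPAC monoisotopic atomic masses (`atomic_masses()`, ≥ 6 decimals), never
hard-coded. A chemistry is a `crosslinker_spec`: reactive residue sets,
bridge composition, waters lost on coupling, deuterium label count,
monolink product compositions, and a satisfaction distance bound.

* ADH joins carboxylate pairs (D/E × D/E) through a C6 dihydrazide bridge
  (C6H14N4O2) losing two waters: +138.090546 Da. Its hydrolyzed monolink
  (one hydrazide unreacted) is the cross-link shift plus one water,
  +156.101111 Da. The h8/d8 isotope pair differs by
  8 × (m(²H) − m(¹H)) = 8.050214 Da.
* DMTMM mediates a direct amide bond between lysine amines and
  carboxylates: empty bridge, one water lost, −18.010565 Da, and no
  monolink product.
* DSS adds C8H10O2 between two lysines (+138.068079 Da); its hydrolyzed
  monolink is +156.078644 Da, and an aminolyzed (+NH3) product computes to
  +155.094629 Da.

Two printed reference values disagree slightly with atomic-mass
arithmetic and are deliberately *not* asserted in tests: the DSS-d12
precursor delta (printed 12.07573 Da vs 12 × 1.0062767 = 12.075321 Da)
and the aminolyzed DSS monolink (printed 155.096428 Da vs our
155.094629 Da). We compute from atomic masses and document the
difference; which product the second mass corresponds to is not certain,
so both compositions are exposed as named entries without asserting an
assignment. The protein N-terminal amine is treated as DSS/DMTMM-reactive
only when `n_terminal_amine = TRUE` (off by default; reactivity of the
α-amine depends on pH and acetylation state).

Distance bounds: acid–acid 21 Å and acid–lysine 16 Å are the
chemistry-geometry criteria used throughout; the DSS bound is not
standardized in the same way, so it defaults to the common Cα–Cα
convention of 30 Å and is configurable.

## Cross-link tables, domains, and contact maps

Records use 1-based residue coordinates and an unordered-pair identity:
(a, b) ≡ (b, a), canonicalized by (protein, residue) order.
Deduplication groups by pair, chemistry and condition, so repeated
identifications across peptides and charge states collapse to one row
with a count — published cross-link tallies are counts of unique residue
pairs, and both the unique-pair and per-record counts are available.

The default DnaJB8 domain map is JD 1–82, G/F 83–139, S/T 140–169,
CTD 170–232. The G/F↔S/T boundary is not precisely annotated; the split
at 139/140 is marked approximate and configurable. Class labels are
alphabetically ordered (`"CTD–JD"`), making classification symmetric. A
putative helix (H5) or any other sub-feature can be supplied as an extra
interval table; annotations are only produced when configured, since the
feature's bounds are not established. Intra- vs intermolecular identity
of a link in an oligomer is genuinely ambiguous without a monomeric
control, so records default to `"ambiguous"`.

Covariation overlap uses a probability threshold of 0.7 and a ±2-residue
window by default: a cross-link overlaps the covariation signal if a
strong covarying pair lies within the window on both coordinates, in
either orientation. The window acknowledges that covariation and
cross-linking report on contacts at slightly different positions along
the sequence.

## Ensemble satisfaction scoring

The scoring model is deliberately simple: Euclidean distance between
designated atoms, compared inclusively (≤) against the chemistry bound.
The atom convention is not uniquely determined by the bounds themselves;
the default is Cα–Cα, which is robust for models lacking side-chain atoms
and consistent with the 21/16 Å magnitudes, with `CB` (falling back to CA
for glycine) and `terminal` (reactive side-chain terminal atom, falling
back CB → CA) as options. Models missing a linked residue score that link
FALSE and are flagged rather than dropped, so per-model counts remain
comparable across the ensemble.

`score_ensemble()` reports the per-model satisfied count, the per-link
fraction of models satisfying it, the histogram of satisfied counts
(whose mass always equals the number of models), and the argmax set of
best models (ties all reported). `threshold_sensitivity()` recomputes the
counts over a threshold grid as a robustness check; counts are
non-decreasing in the threshold by construction.

## Restraint-driven collapse

The collapse module reproduces the *logic* of restraint-guided structural
compaction — upper-bound restraints from cross-link chemistry pulling an
expanded chain into a compact state whose size can be compared with
solution measurements — with a transparent coarse-grained model rather
than a fragment-based all-atom protocol: one bead per residue, harmonic
bonds at 3.8 Å (the Cα virtual bond), soft-sphere repulsion of radius
σ = 4 Å between non-bonded beads, and flat-bottom restraints (zero inside
the bound, quadratic outside, weight 1 by default).

Minimization is a two-stage quasi-Newton (L-BFGS) descent with analytic
gradients: stage one turns repulsion off so restraints can pull the chain
past itself without topological traps; stage two restores repulsion to
resolve clashes. Seeded random restarts (default 5, Gaussian jitter of
3 Å on the start) escape trapped conformations and the best-energy
result is returned; the whole procedure is deterministic given the seed.
Rigid groups move only by exact translation and rotation (Rodrigues
formula), so their internal geometry is preserved to machine precision.

Numerical boundary behavior: an active restraint at the optimum sits
exactly on its flat-bottom edge, so satisfaction checks on minimizer
output allow 1e-6 Å of slack; the stopping rule is the minimizer's
machine-precision relative energy decrease rather than a loose gradient
threshold, which would otherwise park restrained distances a few 1e-6 Å
outside their bounds.

The expanded starting conformation is a gentle helix with 3.5 Å rise per
residue (end-to-end ≈ 3.5 Å × (N−1)) and 3.8 Å bond length; the small
lateral displacement avoids the degenerate collinear start in which all
forces are axial. Reference sizes from the original all-atom modeling of
DnaJB8 (collapse from R_h 9.27 nm / R_g 6.65 nm to 4.02 nm / 2.45 nm) are
reported for qualitative comparison only — they depend on the all-atom
force field and bead-shell hydrodynamics and are not targets for this
coarse model. How many restraints that modeling applied, and with what
weights, is not recorded; both are exposed as configuration here.

## Hydrodynamic size

Three complementary estimates:

* `radius_of_gyration()`: RMS deviation from the centroid, uniform
  weights (CA-only models carry no reliable masses). Internal units are
  Å; all outputs are nm with conversion only at the boundary.
* `kirkwood_rh()`: the Kirkwood double-sum approximation
  1/R_h = N⁻² Σ_{i≠j} 1/r_ij. This replaces rigorous bead-shell
  hydrodynamics: it carries no bead radius or hydration shell, so
  absolute values run below shell-model results for compact particles,
  but it is deterministic, exactly homogeneous of degree one under
  scaling, and rotation/translation invariant — the right properties for
  comparing conformations of the same chain.
* `mfk_hydrodynamic_radius()`: the empirical chain-length power law
  R_h = A·N^B with published coefficients (disordered A = 2.49 Å,
  B = 0.509; folded A = 4.75 Å, B = 0.29). The disordered regime
  reproduces the 3.98 nm estimate for N = 232 and is the default; the
  folded regime is provided for contrast.

## Sequence charge (NCPR)

`ncpr()` computes the sliding-window mean of per-residue charges with a
10-residue window by default (D/E = −1, K/R = +1, others 0). Histidine is
uncharged by default — the standard neutral-pH convention — with partial
charges (+0.1, +0.5) available for lower-pH scenarios. Window values are
reported at the window start (1-based) by default; centering is an
option. `charge_blocks()` extracts maximal same-sign runs above a
magnitude threshold, the objects whose complementarity (a basic face on
one domain vs an acidic face on another) underlies electrostatically
driven domain contacts.

## Chemical shift perturbations

Peak matching uses assignment keys when both lists share them; otherwise
greedy nearest-neighbour matching within a tolerance ellipse
((ΔH/0.05)² + (ΔN/0.5)² ≤ 1 by default), ascending by scaled distance,
each peak matched at most once. The combined CSP is the standard amide
form Δδ = √(Δδ_H² + (0.14·Δδ_N)²); the 0.14 nitrogen scaling is
convention, not derived, and is configurable.

Perturbed-residue calling supports two rules because titration reports
commonly use either: the mean CSP over non-proline residues (prolines
have no amide proton and are excluded), with strict > comparison, or a
fixed ppm threshold (e.g. 0.005 ppm). Published perturbed-peak counts are
not asserted in tests — they require the original peak data — but the
synthetic generator plants shifts with margins and the round trip
recovers exactly the planted set. `titration_series()` assembles
per-residue trajectories over a molar-ratio ladder (e.g. 0×, 0.125×,
0.25×, 0.5×, 1×, 2×) and flags non-monotonic trajectories, which in a
fast-exchange titration indicate matching errors or overlap.

## FP binding and competition

With tracer at 0.2 µM and affinities down to ~0.4 µM, the tracer is a
substantial fraction of the bound ligand, so the non-depleting hyperbola
is biased; the one-site model therefore uses the exact quadratic
mass-balance root throughout, and fits estimate (Kd, FP_min, FP_max) by
Levenberg–Marquardt with multistart initial guesses around the
half-signal concentration. Standard errors come from the fit covariance;
non-convergence sets a flag rather than raising.

The competition experiment — tracer preincubated with one partner at
fixed concentration, titrated with the second — is modeled by the full
two-competitor equilibrium, solved by damped fixed-point iteration to a
relative mass-balance residual below 1e-12. The solver reduces exactly to
the one-site result at zero competitor, and in the non-depleting limit
the apparent EC50 equals the Cheng–Prusoff form K₂(1 + [C]/K₁)
analytically. One identifiability note: a competition curve never visits
the fully free tracer state, so the free plateau is poorly constrained by
that curve alone; `fit_competition(fp_free = ...)` accepts the plateau
from the companion direct titration, which sharpens the K₂ estimate
markedly. The preincubated competitor concentration defaults to 3.125 µM
(the stated experimental concentration; a rounded 3 µM also appears in
summaries of the same experiment and can be configured).

An empirical ≥10-fold apparent-affinity shift reported for the
CTD-preincubated system exceeds what this simple competitive model
predicts at those concentrations (~1.7-fold); the package reports both
the mechanistic fit and the model-free apparent EC50 with the
Cheng–Prusoff reference so the discrepancy is visible rather than
absorbed, and deliberately does not guess a more elaborate mechanism
(e.g. avidity in oligomers).

The simulation noise model is additive Gaussian on mP with σ = 5 mP —
chosen once as typical triplicate plate-reader scatter — at the
experimental design: two-fold dilutions from a 150 µM top dose plus a
zero point, triplicate.

## Synthetic data and what the tests show

Every generator is a pure function of (seed, stage name): each stage
derives its own RNG stream, so adding a generator never perturbs another
stage's fixtures. Ground truth is always emitted alongside the data
(planted link labels, generating Kd, planted CSP set), enabling label
round-trip tests in every module.

The generators emulate the *statistical structure* each stage assumes —
self-avoiding compact chains (min pairwise distance 3.5 Å), Gaussian
coordinate jitter around one fold, true links sampled under the chemistry
bound and decoys beyond it with a 2 Å margin, exact-model FP curves with
Gaussian noise, uniform HSQC peak positions in amide ranges with planted
shifts. They do not emulate real-data pathologies: correlated
conformational changes, peptide-level detectability bias in MS, peak
overlap and exchange broadening in spectra, or plate-position effects in
FP. Passing tests therefore demonstrate correctness of the computations
under the stated models, not robustness to those pathologies.

Problem sizes were chosen to keep the full suite comfortably inside a
few minutes on one CPU while remaining statistically meaningful: 50-model
× 50-link oracle comparisons, 60-bead collapse instances (50 seeds),
100-seed parameter-recovery studies, 1000-trial set-operation checks.

## Known limitations

* Satisfaction scoring is Euclidean; solvent-accessible-surface path
  distances (Xwalk-style) are out of scope and would tighten the
  geometric criterion for buried pairs.
* The Kirkwood R_h underestimates shell-model values for compact
  particles; use it for relative comparisons.
* The collapse model has no secondary-structure or sidechain physics; it
  answers "do these restraints compact the chain, and by how much", not
  "what is the structure".
* Oligomeric avidity is not modeled in the binding module; apparent
  affinities in oligomerizing systems will deviate from the two-state
  models in ways the package surfaces but does not explain.
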