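# xlinkr

Integrative cross-linking mass spectrometry (XL-MS) restraint analysis for
multidomain and partially disordered proteins, motivated by chaperones such
as the Hsp40 co-chaperone DnaJB8, whose J-domain (JD) is regulated by an
electrostatic contact with its acidic C-terminal domain (CTD).

The package covers the computational chain that connects an XL-MS
experiment to structural and biophysical interpretation:

* **Cross-linker mass accounting.** Chemistries are defined by elemental
  composition and reaction stoichiometry, and every search-engine mass
  parameter is derived from IUPAC monoisotopic atomic masses: for a bridge
  of composition *B* losing *w* waters, the cross-link shift is
  Δm = m(*B*) − *w*·m(H₂O). Built-ins: ADH (adipic acid dihydrazide,
  D/E–D/E, +138.09055 Da, h8/d8 pair), DMTMM-mediated zero-length coupling
  (K–D/E, −18.010565 Da), and DSS (K–K, +138.068080 Da, h12/d12 pair),
  with monolink (single-ended) product masses and heavy/light deltas
  Δ = *n*·(m(²H) − m(¹H)).
* **Cross-link tables.** TSV reading/writing, deduplication to unique
  unordered residue pairs, domain classification (JD 1–82, G/F 83–139,
  S/T 140–169, CTD 170–232 by default), contact maps with per-class
  counts, condition comparison (e.g. 150 vs 285 mM NaCl), monolink
  frequency comparison, and overlap with covariation pair tables.
* **Ensemble satisfaction scoring.** A cross-link is satisfied by a model
  when the inter-residue distance is within the chemistry bound
  (acid–acid 21 Å, acid–lysine 16 Å, inclusive). Multi-model PDB ensembles
  are scored per model and per link, with the satisfied-count histogram
  and best-model report.
* **Restraint-driven collapse.** A bead-per-residue chain (bonds at
  3.8 Å, soft-sphere repulsion, optional rigid groups) is compacted under
  flat-bottom upper-bound restraints by a deterministic two-stage
  quasi-Newton minimization with seeded restarts.
* **Hydrodynamics.** Radius of gyration; the Kirkwood inverse-distance
  approximation 1/R_h = N⁻² Σ_{i≠j} 1/r_ij; and the Marsh–Forman-Kay
  empirical chain-length law R_h = A·N^B (disordered: A = 2.49 Å,
  B = 0.509; folded: A = 4.75 Å, B = 0.29), which predicts 3.98 nm for a
  232-residue disordered chain.
* **Sequence charge.** Net charge per residue (NCPR) sliding-window
  profiles and signed charge-block detection.
* **NMR chemical shift perturbation.** HSQC peak matching, combined CSP
  Δδ = √(Δδ_H² + (0.14·Δδ_N)²), perturbed-residue calling (mean rule
  excluding prolines, or a fixed ppm threshold), and titration-series
  trajectories.
* **FP binding models.** One-site binding with exact ligand depletion
  (quadratic mass balance), the two-competitor equilibrium behind
  preincubation competition experiments (damped fixed-point solve),
  fitting via Levenberg–Marquardt with multistart, and apparent-EC50
  reporting against the Cheng–Prusoff prediction K₂(1 + [C]/K₁).
* **Synthetic data.** Seeded generators for every input class — self-
  avoiding chains, jittered ensembles, planted true/decoy cross-links,
  noisy FP titrations, and peak lists with planted shifts — so the entire
  pipeline is testable without downloads, with ground-truth labels for
  round-trip checks.

## Worked example

```r
library(xlinkr)

xl_chemistries()$adh
#> <crosslinker_spec> adh
#>   reactive: {D,E} x {D,E}
#>   crosslink mass shift: 138.090546 Da
#>   monolinks: hydrolyzed = 156.101111 Da
#>   heavy/light delta: 8.050214 Da
#>   max distance: 21 A

# plant cross-links on a synthetic compact chain, score a jittered ensemble
ch    <- gen_chain(60, seed = 3)
links <- plant_crosslinks(ch, "dmtmm", n_true = 7, n_decoy = 7, seed = 3)
ens   <- gen_ensemble(ch, n_models = 50, jitter = 4, seed = 3)
score_ensemble(links, ens)
#> <xl_satisfaction> 50 model(s) x 14 link(s)
#>   best model 20: 8/14 links satisfied
```

The 7 planted-true links are geometrically satisfiable; the 4 Å coordinate
jitter degrades some of them per model, and the decoys (planted beyond the
16 Å bound + 2 Å margin) stay mostly unsatisfied — the best of 50 models
recovers 8 of 14.

```r
# fit a noisy FP titration generated at Kd = 4.4 uM
fit <- fit_one_site(gen_fp_curve(kd = 4.4, sigma = 5, seed = 1))
tidy(fit)
#> # A tibble: 3 × 3
#>   term   estimate std_error
#>   <chr>     <dbl>     <dbl>
#> 1 kd         4.94     0.342
#> 2 fp_min    52.1      1.49
#> 3 fp_max   202.       2.13
```

One simulated triplicate titration (0.2 µM tracer, two-fold series from
150 µM, σ = 5 mP) refits the dissociation constant to 4.9 ± 0.3 µM against
a generating truth of 4.4 µM; across many seeds the median recovery is
unbiased (see the acceptance script below).

```r
# collapse an expanded chain under the planted-link restraints
tl  <- links[links$planted_true, ]
res <- collapse_chain(build_expanded_chain(60),
                      restraint_set(tl$residue_a, tl$residue_b, 16),
                      seed = 1)
res
#> <xl_collapse> Rg 6.07 -> 5.15 nm; restraints satisfied: 100%
size_summary(res$chain)
#> # A tibble: 1 × 4
#>   n_residues rg_nm kirkwood_rh_nm mfk_rh_nm
#>        <int> <dbl>          <dbl>     <dbl>
#> 1         60  5.15           2.44      2.00
```

`autoplot()` methods render the contact map, the satisfaction histogram
and titration fits; `plot_ncpr()` and `plot_csp()` cover the charge and
CSP profiles.

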