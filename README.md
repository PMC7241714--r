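# maltriage

Tools for dissecting the substrate determinants of 3-methylaspartate
ammonia-lyase (MAL, EC 4.3.1.2), the Mg²⁺-dependent enzyme that
deaminates (2S,3S)-3-methylaspartate to mesaconate and is a candidate
scaffold for engineering the deamination of β-lysine and related amines.
The package is aimed at enzyme engineers and structural bioinformaticians
who dock candidate substrates into the MAL catalytic pocket and
characterise them kinetically, and it covers four stages of that
workflow:

1. **Docking-pose triage.** Docked poses are screened with a
   four-anchor distance filter: the distances from the pose to the
   catalytic lysine Nζ (K331), the glutamine side-chain amide N (Q329),
   the histidine ε-N (H194) and the catalytic Mg²⁺, taking for each
   oxygen-directed distance the shorter of the two carboxylate oxygens
   (two-fold carboxylate symmetry). A pose is *inside the pocket* when
   at least 3 of the 4 distances are strictly below 4 Å — in the
   reference crystal geometry the distances are 4.16, 3.08, 2.75 and
   2.2 Å, so the crystal substrate itself passes with exactly 3 of 4.
   In-pocket poses are ranked by the positional (no superposition) RMSD
   over the six-atom common scaffold — the Mg-facing carboxyl carbon,
   its two oxygens and the three following backbone carbons —

   minimised over the symmetry-equivalent mappings (carboxyl choice for
   dicarboxylic ligands, oxygen swap within a carboxylate), and the
   lowest-RMSD in-pocket pose is selected.
2. **Interaction fingerprints.** Receptor–ligand contacts per pocket
   residue, reduced to four categories with precedence
   hydrogen bond > ionic > hydrophobic > proximal, with set-algebra
   comparison (Jaccard index) against the natural-substrate reference
   fingerprint.
3. **Enzyme kinetics.** Beer–Lambert conversion of absorbance slopes to
   initial velocities; Michaelis–Menten fits
   (v = k꜀ₐₜ·S/(Kₘ+S)); global competitive
   (v = k꜀ₐₜ·S/(Kₘ(1+I/Kᵢ)+S)) and non-competitive
   (v = k꜀ₐₜ·S/((1+I/Kᵢ)(Kₘ+S))) inhibition fits across all inhibitor
   series at once; AICc-based model discrimination with an explicit
   "no inhibition" outcome; Lineweaver–Burk diagnostics; k꜀ₐₜ/Kₘ
   efficiencies and fold changes.
4. **ΔΔG scan post-processing.** Replicate stability-predictor runs are
   averaged per mutation and classified destabilizing/neutral at a
   1.6 kcal/mol threshold (twice the predictor's typical 0.8 kcal/mol
   error), with per-position saturation-scan summaries.

Seeded synthetic-data generators with known ground truth accompany every
stage, including an analytic catalytic-pocket fixture that reproduces the
reference crystal distances exactly by construction. The fixture is a
synthetic stand-in; `fetch_reference()` can download the real crystal
structure (PDB 1KKR) for users with network access.

## Worked example

```r
library(maltriage)

# pocket fixture + a labelled pose cloud: 40 in-pocket, 60 decoys
fx  <- make_pocket_fixture()
sim <- generate_poses(fx$reference, n_in_pocket = 40, n_decoys = 60, seed = 7)
triage_ligand(fx$receptor, sim$poses, fx$template, fx$reference,
              anchors = fx$anchors)
#> <mal_triage: 100 poses, 40% in pocket; selected pose: 71 (RMSD 0.01 A)>
```

The per-pose table carries the four anchor distances, the pass count
under the strict 4 Å rule and the symmetry-corrected scaffold RMSD:

```
  pose_id d_k331_c3 d_q329_o d_h194_o d_mg_o n_below_cutoff in_pocket scaffold_rmsd
1       1      4.14     3.16     2.68   2.28              3      TRUE         0.121
2       2      4.17     3.10     2.65   2.30              3      TRUE         0.102
3       3     17.29    22.33    20.36  20.03              0     FALSE        20.022
```

Pose 3 is a decoy: all four distances far exceed the cutoff. Poses 1–2
are small rigid perturbations of the reference and pass with 3 of 4, like
the crystal substrate itself.

Kinetics, on synthetic competitive-inhibition data at the
natural-substrate constants (k꜀ₐₜ 17.6 s⁻¹, Kₘ 1.0 mM) and Kᵢ 1.7 mM:

```r
d   <- generate_kinetics("competitive", kcat = 17.6, Km = 1.0, Ki = 1.7,
                         I_levels = c(0, 2, 5, 10), noise_cv = 0.02, seed = 7)
fit <- classify_inhibition(d)
fit
#> competitive inhibition fit: kcat 17.6, Km 0.97 mM, Ki 1.68 mM, global R2 0.9968
round(attr(fit, "aicc_table"), 1)
#>           none    competitive noncompetitive
#>          339.4           -6.9          372.7
```

The generating mechanism is recovered (AICc separates the three models by
hundreds of units at 2% noise) and the fitted constants land within a few
percent of the truth.

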