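---
title: "Methods: pose triage, fingerprints, kinetics and stability scans for MAL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose triage, fingerprints, kinetics and stability scans for MAL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maltriage)
```

3-methylaspartate ammonia-lyase (MAL) deaminates (2S,3S)-3-methylaspartate
using a catalytic Mg²⁺ and the base K331, which abstracts the proton from
carbon 3. Candidate alternative substrates (β-lysine, lysine, aspartate,
β-glutamate, 3-aminobutanoate, 2-aminoadipate) can be docked into the
catalytic pocket and assessed geometrically, interaction-wise,
kinetically and for mutational tolerance. This vignette documents the
models implemented here, the defaults and why they were chosen, and what
the synthetic data generators do and do not emulate.

## Pose triage

### The four-anchor distance filter

A docked pose is judged against four anchor atoms of the catalytic site:
K331 Nζ, the Q329 side-chain amide nitrogen, the H194 ε-nitrogen and the
Mg²⁺ ion. Distances are taken from, respectively, the ligand's
proton-abstraction carbon (K331) and the oxygens of the Mg-facing
carboxylate (Q329, H194, Mg). A carboxylate is symmetric under exchange
of its two oxygens, so each oxygen-directed distance is the minimum over
the two oxygens; for dicarboxylic ligands the carboxyl whose carbon lies
nearer the Mg anchor is taken as Mg-facing and recorded. A pose is
*in pocket* when at least `min_pass = 3` of the four distances are
**strictly** below `cutoff = 4` Å.

Strictness matters: in the reference crystal geometry the four distances
are 4.16, 3.08, 2.75 and 2.2 Å, so the crystal substrate itself scores
exactly 3 of 4 (4.16 ≥ 4). A non-strict rule would silently change the
count to the same 3, but a cutoff of exactly 4.16 would not; the strict
convention is documented and tested so the boundary behaviour is never
ambiguous.

### Symmetry-corrected scaffold RMSD

All ligands considered share a six-atom scaffold: the Mg-facing carboxyl
carbon, its two oxygens and the three backbone carbons that follow. The
RMSD between a pose and the reference substrate is computed positionally
— both sit in the receptor frame produced by docking, and no
superposition is ever applied, because the quantity of interest is *where
the pose sits in the pocket*, not its internal conformation. The RMSD is
minimised over the symmetry-equivalent mappings: the pose's carboxyl
choice (2 for dicarboxylic ligands) × the oxygen swap within the
carboxylate (2). The reference orientation is fixed to its own Mg-facing
carboxyl; permuting the reference oxygens is equivalent to permuting the
pose oxygens and adds nothing, which the test suite verifies against a
brute-force oracle that enumerates all 2×2×2 mappings.

Scaffold membership is declared per ligand in explicit templates
(`mal_template()`) rather than perceived from bonds. This avoids a
cheminformatics dependency, and the scaffold is small and unambiguous
enough that hand declaration is the more auditable choice. The
abstraction carbon is likewise template-declared: it is the first
backbone carbon after the Mg-facing carboxyl carbon (C3 in
3-methylaspartate, whose counterpart in β-lysine is C2).

### Selection and statistics

Among in-pocket poses the one with the lowest scaffold RMSD is selected.
Ties are broken by better (more negative) docking score, then lower pose
id — docking programs rarely produce exact RMSD ties, so the tie-break is
a determinism device, not a scientific statement. When no pose passes
the filter an explicit no-selection outcome is returned; an empty pose
set is an error. `percent_in_pocket()` is the plain fraction of
in-pocket poses and is invariant to pose order.

## Interaction fingerprints

Contacts between pocket residues and the ligand are reduced to four
categories, assigned per atom pair by the highest-precedence satisfied
rule:

| category | rule | default threshold |
|---|---|---|
| hydrogen_bond | both atoms N/O | ≤ 3.5 Å |
| ionic | oppositely charged group atoms | ≤ 4.0 Å |
| hydrophobic | both atoms apolar carbons | ≤ 4.5 Å |
| proximal | anything else | ≤ 5.0 Å |

Docked heavy-atom poses carry no hydrogens, so the hydrogen-bond rule is
distance-only; with explicit hydrogens a donor–H–acceptor angle term
would apply, but none of the inputs this package targets provide them.
Charge assignment is a residue/atom-name lookup (Asp/Glu carboxylates,
Lys Nζ, Arg guanidinium, Mg²⁺; His ring nitrogens behind an optional
flag since the protonation state is unknown without a pKa model), and
ligand charges come from the templates. This is deliberately far coarser
than full interaction calculators, which distinguish over a dozen
categories with atom-typed force-field terms; only presence/absence per
residue of the four categories discussed for the MAL pocket is claimed.
Water-mediated contacts are out of scope — a residue that only interacts
through a bridging water (Q73 in the MAL pocket) appears as proximal at
best, matching the behaviour of water-blind contact analysis.

Fingerprints are sets of (residue, category) pairs; comparison is exact
set algebra plus the Jaccard index, defined as 1 when both sets are
empty (two non-binders are identical, not incomparable).

## Kinetics

### Models and fitting

Michaelis–Menten: $v = k_{cat} S / (K_m + S)$. Competitive inhibition:
$v = k_{cat} S / (K_m (1 + I/K_i) + S)$. Non-competitive:
$v = k_{cat} S / ((1 + I/K_i)(K_m + S))$. The competitive form is the
standard one in which the inhibitor scales the apparent $K_m$; a
literal reading of some printed renderings of this equation places the
$(1+I/K_i)$ factor outside the denominator sum, which is dimensionally
wrong and is not implemented.

Inhibition fits are *global*: one $(k_{cat}, K_m, K_i)$ triple across
all inhibitor series simultaneously, which uses the data far more
efficiently than per-series apparent constants. Fitting is
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with positivity
bounds and starting values $K_m = \mathrm{median}(S)$,
$k_{cat} = 1.2\max(v)$, $K_i = \mathrm{median}(I_{>0})$ — crude but
inside the basin of attraction for any data that remotely follows the
model. Standard errors come from the Jacobian-based covariance at the
optimum ($\sigma^2 (J^\top J)^{-1}$); if a parameter is pinned at a
bound the covariance is rank-deficient and the standard errors are
reported as `NA` rather than failing the fit. 95% limits are
±1.96·se. Global R² is $1 - SS_{res}/SS_{tot}$ pooled over all points.

$K_i$ is bounded above at $10^8$ mM; a fit pinned there means the data
carry no inhibition signal and is flagged as such rather than reported
as a (meaningless) huge constant.

### Model discrimination

`classify_inhibition()` fits plain Michaelis–Menten (parameters shared
across all series), competitive and non-competitive, and selects by
smallest AICc ($k$ counts the residual variance). "none" is declared
when neither inhibition model beats plain Michaelis–Menten by more than
2 AICc units — the conventional "barely worth mentioning" threshold —
or when the winning fit sits at the $K_i$ bound. The classical
diagnostic is kept alongside: in double-reciprocal (Lineweaver–Burk)
coordinates competitive series share the y-intercept $1/k_{cat}$ and
non-competitive series the x-intercept $-1/K_m$, which
`lineweaver_burk()` tests with a relative-spread tolerance (default
$10^{-6}$; the noiseless algebra holds to machine precision).

Velocities are accepted in mM/min or, when the enzyme concentration is
supplied to `assay_spec()`, as turnover in s⁻¹; `rate_from_absorbance()`
applies Beer–Lambert ($v = \text{slope}/(\varepsilon \ell)$). Racemic
substrate stocks are the caller's responsibility: when only one
enantiomer is a substrate, the effective concentration is half the
nominal one, and no correction is applied silently.

## ΔΔG scan post-processing

Structure-based stability predictors are stochastic in their side-chain
sampling, so each mutation is run several times (five is conventional)
and averaged. The mean ΔΔG is classified destabilizing when strictly
above 1.6 kcal/mol — twice the predictor's typical 0.8 kcal/mol error —
and neutral otherwise; the boundary value itself is neutral (the
threshold is "clearly beyond the noise", and a value *at* twice the
error is not clearly beyond it). A "stabilizing" annotation at
mean ≤ −1.6 is available behind a flag, clearly marked as an extension
beyond the two-class scheme. The predictor itself is never executed;
only its tabular output is consumed, keeping the package tool-agnostic.

## Synthetic data: what it emulates, and what not

`make_pocket_fixture()` builds the catalytic pocket analytically: a
reference 3-methylaspartate with idealised bond lengths, anchor atoms
placed on single axes from their reference ligand atoms so that the four
anchor distances are met *exactly* (to machine precision, not by
optimisation), and the discussed pocket residues (Q172, T360, C361 and
the hydrophobic L384/F170/Y356 cluster) at hydrogen-bonding or
hydrophobic-contact range. It is a synthetic stand-in: tests passing on
it demonstrate that the geometry, filtering and fingerprint machinery
compute what they claim on a pocket with the published metrics — not
that a particular crystal structure reproduces those metrics.
`fetch_reference()` retrieves the real structure for that check when a
network is available.

`generate_poses()` emulates a docking program's output as rigid-body
perturbations: in-pocket poses rotate up to `rotation_max = 3°` about
the centroid and translate isotropically with
`translation_sigma = 0.1` Å; decoys are displaced 20 Å in random
directions. The defaults are set by a margin argument, not calibration:
the tightest in-pocket distance (Q329–O, 3.08 Å) leaves 0.92 Å to the
cutoff, a 3° rotation moves scaffold atoms at most ~0.15 Å, and a
translation beyond 0.7 Å is a >7σ event — so constructed labels are
deterministic for any seed. What this does **not** emulate: conformer
flexibility (poses are rigid copies of the reference geometry), scoring
landscapes, or borderline poses hovering at the cutoff; triage accuracy
on labelled synthetic sets is therefore a correctness check, not a
benchmark of discriminative power on real docking output. The published
per-ligand in-pocket percentages (81/80/78/55/68/90%) require re-running
an external docking program and are treated as an external benchmark,
not a test.

`generate_kinetics()` uses multiplicative Gaussian noise,
$v_{obs} = v(1 + e)$, $e \sim N(0, cv^2)$ with `cv = 0.02`, because
initial-velocity error in plate readers scales with signal; the substrate
grid default (1.25–15 mM, six points) mirrors the reference assay range.
`generate_ddg_table()` draws true effects from a declared two-component
mixture — neutral $N(0, 0.5)$, destabilizing $N(3, 1)$ kcal/mol — with
per-run noise 0.8 kcal/mol; the components are separated enough for
~97% expected label recovery at five runs, so a large accuracy drop
signals a code defect, not bad luck.

All generators consume an explicit integer seed and are pure functions
of their arguments.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes — 100-pose clouds, 25-seed kinetics recoveries (72 observations
per fit), 20-seed ΔΔG scans of three positions — chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo
fractions (e.g. ≥95% correct model classification) statistically
meaningful at their thresholds.

## Known limitations

* PDB parsing covers ATOM/HETATM/MODEL records with first-altloc
  selection; mmCIF, occupancy weighting, symmetry mates and hydrogens
  are out of scope.
* Fingerprints are four-category and distance-based; no π-stacking,
  halogen or carbonyl categories, no solvent.
* Kinetics covers initial-velocity analysis only: no progress-curve
  fitting, no substrate-inhibition, mixed or uncompetitive models.
* The scaffold RMSD presumes the ligand actually has the declared
  six-atom scaffold; ligands without a carboxylate cannot be triaged.
* Per-chain anchor distances on a real multi-chain crystal structure
  should be reported side by side (`resolve_anchors()` takes the chain
  explicitly); the package never assumes which chain a published
  measurement was made on.
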