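---
title: "Photo-switchable cross-linkers as molecular rulers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photo-switchable cross-linkers as molecular rulers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoruler)
```

## The scientific problem

Trimeric ATP-gated channels (P2X receptors) open by a rearrangement of their
six transmembrane helices. A bifunctional azobenzene cross-linker — two
maleimide-glycine arms on a 4,4'-azobenzene core — can be attached across
pairs of engineered cysteines and toggled with light between its *trans*
(extended) and *cis* (bent) configurations. Because the two configurations
span different distances, the linker acts as a light-operated molecular
ruler: if a cysteine pair can only be bridged in one configuration, light
drives the channel between conformations, and the wavelength that opens the
channel reports which structural state matches which isomer.

`photoruler` implements the full analysis around this idea:

1. a conformer ensemble of the reacted linker in fixed *cis* or *trans*
   (module `linker_model`),
2. pooled stereoisomer distance statistics with Gaussian fits
   (`distance_stats`),
3. inter-subunit anchor distances on trimeric structures (`structure_io`),
4. the compatibility statistic Δ = linker mean − structure distance and the
   predicted photoresponse polarity (`ruler_compat`),
5. HOLE-style pore-radius profiles with a backbone-only option
   (`pore_profile`),
6. cross-link combinatorics on concatenated trimers (`concatemer_logic`),
7. the electrophysiology fits used to quantify light-gated currents
   (`ephys_analysis`), and
8. deterministic synthetic fixtures for all of the above (`synthetic_data`).

## The linker model: a geometric surrogate

The reference analysis obtained end-to-end S–S distances of the free reacted
linker from explicit-solvent molecular dynamics. `photoruler` replaces the
force field with a *kinematic surrogate*: ideal small-molecule geometry
(aromatic C–C 1.39 Å, N=N 1.25 Å, amide C–N 1.33 Å, sp³ C–C 1.52 Å, C–S
1.81 Å; sp² angles 120°, sp³ 109.5°), rigid planar rings, and independent
torsion draws with hard-sphere rejection. This is a deliberate trade: the
surrogate is deterministic, dependency-free and fast (10⁵ conformers in
seconds), at the cost of ignoring solvation and torsional energetics. Its
accuracy target is therefore the *printed standard deviation* of the
reference distributions (±2.0 Å *trans*, ±4.6 Å *cis*), not the printed
means to higher precision.

Key geometric decisions, made once:

* **Azo configuration.** The C–N=N–C dihedral is fixed per isomer: 180° for
  *trans*, 10° for *cis*. Crystalline *cis*-azobenzene is non-planar with
  the C–N=N angle opened to ~122° and the phenyl rings twisted ~53° out of
  the C–N=N plane; a planar-ring *cis* reference is sterically impossible
  (every conformer clashes). The *cis* template therefore uses the
  crystallographic angle and twist reference, with the twist sampled ±30°
  and its sign randomized so both twist enantiomers are visited. *Trans*
  uses 114° at the azo nitrogens and a planar twist reference sampled ±10°.
* **Rotatable set.** Per arm: the phenyl twist, the aryl–N(amide) torsion,
  and the two glycine-arm torsions (C(O)–CH2 and CH2–N(ring)). Conjugated
  and sp³ torsions adjacent to planar groups are drawn from two lobes at
  0°/180° ± 30°; amide ω torsions are fixed *trans*; the azo dihedral never
  varies. A "thioether χ" torsion about the C–S bond would rotate nothing
  in a heavy-atom model (the sulfur is terminal and rigidly attached to the
  succinimide ring through its stereocentre), so it is not sampled.
* **Clash rule.** Atom pairs separated by more than three bonds clash when
  closer than 0.8 × the sum of their Bondi vdW radii. At cutoffs ≥ 0.9 the
  planar-anilide O⋯ortho-carbon contact (at 0.79 × the vdW sum in every
  conformation) rejects everything; 0.8 keeps the model permissive, emulating
  solvated flexibility.
* **Stereochemistry.** The two thioether-bearing succinimide carbons are
  stereocentres; the package labels the sign of the substituent
  signed-volume (S, carbonyl-side ring C, methylene-side ring C) as R (+)
  or S (−). The R/R ↔ S/S mirror identity is exact for *trans* when all
  torsions are negated along with the stereo swap; for *cis* the fixed
  +10° azo reference makes the frame weakly chiral, and the identity holds
  in distribution (the twist-sign randomization restores it).

With these choices the pooled ensembles (25,000 per stereoisomer, R/S
counted twice, n = 100,000) give a *trans* mean of ≈ 20.3 Å and a *cis* mean
of ≈ 12.8 Å — both inside the surrogate's stated tolerance around the
reference values of 21.7 and 16.0 Å. The *cis* shortfall is systematic and
understood: uniform two-lobe arm sampling visits folded states that the
solvated force field disfavours, pulling the mean down; it was left as-is
rather than re-weighted, because any re-weighting would amount to fitting
the answer.

```{r, eval = FALSE}
st <- free_linker_stats("trans", n_per_stereo = 25000, seed = 1)
fit_gaussian(st$distribution, "free-mean")
```

## Distance statistics

Pooling follows the reference weighting exactly: R/R + S/S + 2 × R/S.
Distances are binned at 0.2 Å with edges aligned to multiples of the bin
width, and a scaled normal is fitted by trust-region least squares
(`nls(algorithm = "port")`, tolerance 1e-8, 200 iterations). Two modes are
provided: `peak-mean` (the free-linker rule — mean pinned to the tallest
bin, ties to the lowest centre; SD and amplitude fitted) and `free-mean`
(all three parameters fitted, the fused-linker rule). The acceptance report
uses `free-mean`: the surrogate's histograms have broad flat tops on which
the tallest-bin rule alternates between two local maxima from seed to seed
(≈ 1.4 Å spread at n = 100,000), while the fitted mean is stable to
< 0.05 Å. Peak selection is appropriate for the much smoother reference MD
distributions; both estimators agree here to well within one standard
deviation.

## Structures, rulers and the compatibility statistic

`read_channel_pdb()` is a minimal fixed-column PDB reader (no R PDB parser
is available in the supported dependency set): ATOM records only, altloc
resolved by highest occupancy then alphabetically, insertion codes and
deposition order preserved, author numbering untouched. Horizontal mode
measures the same residue's anchor atom (default Cβ) across the three
adjacent chain pairs; vertical mode measures residue_a in chain *i* against
residue_b in chain *i*+1, where "clockwise" means file-order succession —
the data fix the orientation only up to the viewing convention, so the flip
is exposed everywhere. Glycine anchor sites use `reconstruct_cb()` (ideal
tetrahedral Cβ from N/CA/C).

Compatibility is operationalized as: match if |Δ| ≤ k·SD of the linker
distribution (k = 1 by default — this reproduces the published calls, e.g.
Δ = −0.1 vs SD 4.6 → match, Δ = −6.0 vs SD 2.0 → cannot span), `short` if
the linker falls short, `long` if it overshoots. The predicted opening
wavelength is a pure function of the four state × isomer labels: 525 nm if
*trans* matches open and *cis* matches closed, 365 nm for the reverse,
`none` otherwise. S–S means compared against Cβ–Cβ distances are flagged
approximate; a constant offset correction is available and defaults to 0.

## Pore profiles

At each axial position the package reports the radius of the largest sphere
centred in that plane that touches no atom's vdW sphere (Bondi radii:
C 1.70, N 1.55, O 1.52, S 1.80 Å — a slightly different dialect from HOLE's
own table). The in-plane centre is found by a deterministic coarse-grid
scan (0.5 Å, within 3 Å of the axis by default) plus step-halving
refinement to 0.1 Å, replacing HOLE's simulated annealing for
reproducibility; on analytic fixtures (cylinder, cone) the result is exact.
The `backbone` subset (N, CA, C, O) emphasizes global helix displacement
over side-chain detail. Because the centre search is a heuristic, the
backbone ≥ all-atom dominance holds pointwise only up to the refinement
resolution; tests assert it with a 0.1 Å allowance. The automatic axis is
the principal-component eigenvector with the isolated eigenvalue (the two
in-plane eigenvalues of a symmetric bundle are degenerate). The constriction
tie-break is the smallest z, and a pore is called open if the minimum radius
admits a Na⁺ ion (0.95 Å).

## Concatemer combinatorics

Concatemer labels like `OC/CO/CC` give, per concatenated subunit, the outer
(TM2 apex) and inner (intracellular TM2) site: C = cysteine, O = wild type.
A linker occupies exactly two cysteines; vertical links join outer(*i*) to
inner(*i*+1) under the clockwise convention shared with the structure
module, horizontal links join outer cysteines of adjacent subunits, intra
links join the two sites of one subunit and never gate. All maximal
site-disjoint arrangements are enumerated; the channel is predicted
light-gated if some arrangement bridges ≥ 2 interfaces with vertical links
(or ≥ 1 horizontal link in horizontal mode). Under the clockwise rule the
published pattern is reproduced (no gating for `OO/CO/OC`, `OC/OO/CO`,
`OO/OO/CC`; gating for `OC/CO/CC`, `CC/CC/CC`), and the counterclockwise
alternative contradicts it — the package's regression test of the
orientation inference.

## Electrophysiology fits

Hill (I = Imax·cⁿ/(EC50ⁿ + cⁿ)), single-exponential
(I = I₀ + A·exp(−t/τ), robust starts from a tail-plateau estimate and a
log-linear decay regression, with restarts on singular convergence),
relative current ((I_ATP+light − I_light)/I_ATP, with an exposed sign flag
because the verbal description and the formula disagree in one place),
desensitization ratio (|end|/|peak| within the application window), GHK
permeability ratios (bi-ionic monovalent, Lewis divalent, and dilution
forms; reversal potentials are junction-corrected by plain subtraction —
junction potentials are inputs, not computed), and all-points-histogram
Gaussian mixtures (least squares on 0.1 pA bins, means initialized at the
tallest well-separated smoothed-density peaks so rare conductance levels
are found, reported sorted; conductance = (level − baseline)/V_hold).
RT/F uses 295 K by default.

## What the synthetic data do and do not establish

Every fixture is a pure function of (parameters, seed):

* **Toy trimers** are poly-alanine two-helix bundles with exact C3 symmetry,
  labelled synthetic throughout. The presets are calibrated once to the
  stated gating geometry — closed: outer-site horizontal Cβ–Cβ ≈ 16.1 Å,
  vertical ≈ 19.7 Å, gate radius 0.33 Å; open: horizontal ≈ 24.7 Å,
  vertical ≈ 16.7 Å, gate radius 3.6 Å (≈ 7 Å entryway). Reaching the short
  open-state vertical distance requires the gating-hinge kink parameter (a
  tangential swing of the intracellular TM2 half); straight ideal helices
  cannot bring the sites closer than their ~20 Å axial separation, which is
  itself a faithful reflection of why the crystallographic open state is
  incompatible with the bent linker. A green test on these fixtures
  establishes that the measurement pipeline is correct, *not* that the
  deposited structures have these distances — the real-structure checks
  require the deposited files and are deliberately left red offline.
* **Dose–response fixtures** evaluate the Hill equation on seven
  half-decade concentrations centred on the EC50 (the "spanning the EC50
  region" precondition) with additive Gaussian noise; `n_cells` averages
  replicate noisy curves per point, emulating protocols where each point is
  a mean over several cells. Recovery tests use 5% per-cell noise and
  n_cells = 4; without averaging, the finite-sample skew of nonlinear-LS
  EC50 estimates is ≈ 2%, which is a property of the estimator, not a bug.
* **Single-channel records** are continuous-time Markov chains (Gillespie),
  sampled uniformly with Gaussian baseline noise; occupancies converge to
  the analytic stationary distribution. They contain no filtering artifacts,
  no drift and no flicker beyond the chain itself, so mixture-fit greens
  establish estimator correctness, not robustness to real patch-clamp
  pathologies.
* **Linker surrogate samples** are zero-truncated normal draws, used where a
  distance sample with known moments is needed.

## Known limitations

* The conformer sampler is energy-blind; its *cis* mean sits ~3 Å below the
  solvated-MD value (within the stated tolerance) and its histograms are
  flatter-topped than MD distributions.
* The pore profiler assumes a straight, axis-aligned pore; curved pathways
  and lipid occlusion are out of scope.
* GHK forms assume independent ion permeation; junction potentials must be
  supplied.
* The real deposited structures cannot be shipped; all structure-dependent
  numbers quoted here were computed on the calibrated synthetic stand-ins.
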