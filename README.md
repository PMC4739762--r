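# photoruler

Photo-switchable cross-linkers as molecular rulers for trimeric
channel gating.

## The problem

ATP-gated P2X receptors are trimeric ion channels whose pore opens by a
rearrangement of six transmembrane helices. A bifunctional azobenzene
cross-linker (two maleimide-glycine arms on a 4,4'-azobenzene core) bridges
pairs of engineered cysteines and photo-isomerizes between *trans*
(extended, ~21.7 Å S–S) and *cis* (bent, ~16.0 Å). Attached across an
inter-subunit cysteine pair, it becomes a light-operated molecular ruler:
the wavelength that opens the channel reports which channel state is
compatible with which linker configuration, and the compatibility statistic

    Δ = ⟨d_linker⟩ − d_structure,   match ⇔ |Δ| ≤ k·SD (k = 1)

turns ensemble distance distributions plus structural anchor distances into
testable gating predictions.

`photoruler` is for structural/channel biophysicists who want to run that
entire analysis reproducibly and offline: conformer ensembles of the reacted
linker, pooled stereoisomer distance statistics (n = 25,000 × {R/R, S/S} +
2 × 25,000 × R/S = 100,000), Cβ–Cβ ruler distances on trimeric PDB
structures, HOLE-style pore-radius profiles (backbone-only option),
cross-link combinatorics on concatenated trimers, and the standard
electrophysiology fits (Hill, single-exponential kinetics, GHK permeability
ratios, all-points-histogram Gaussian mixtures).

## Worked example

```r
library(photoruler)

# 1. linker reach in both light states (100,000 pooled conformers each)
st <- free_linker_stats("trans", n_per_stereo = 25000, seed = 1)
fit_gaussian(st$distribution, "free-mean")
#> gaussian_fit (free-mean): mean 20.33 A, sd 2.39 A, rss 0.000182, converged TRUE
sc <- free_linker_stats("cis", n_per_stereo = 25000, seed = 1)
fit_gaussian(sc$distribution, "free-mean")
#> gaussian_fit (free-mean): mean 12.82 A, sd 3.49 A, rss 5.98e-05, converged TRUE
```

The geometric sampler lands within one reference standard deviation of the
solvated-MD values (21.7 ± 2.0 and 16.0 ± 4.6 Å); see the vignette for why
the *cis* mean runs short.

```r
# 2. compatibility report for the vertical cysteine pair, using the
#    published free-linker statistics against closed/open anchor distances
rep_v <- ruler_report(
  linker_fits = list(cis = list(mean = 16.0, sd = 4.6),
                     trans = list(mean = 21.7, sd = 2.0)),
  structure_distances = c(closed = 20.8, open = 17.2))
rep_v
#>   state isomer linker_mean linker_sd structure_distance delta compatibility
#>  closed    cis        16.0       4.6               20.8  -4.8         short
#>    open    cis        16.0       4.6               17.2  -1.2         match
#>  closed  trans        21.7       2.0               20.8   0.9         match
#>    open  trans        21.7       2.0               17.2   4.5          long
#> predicted opening wavelength: 365 nm (k = 1 SD; ...)
```

The bent *cis* linker matches the open state and the extended *trans*
linker the closed state, so UV light (365 nm) is predicted to open the
channel — the observed polarity for the vertical cross-link.

```r
# 3. synthetic open-state trimer: ruler distances and pore profile
tri <- make_toy_trimer(toy_trimer_params("open"))
interchain_distances(tri, residue_pair_spec("horizontal", 328))
#>   pair distance
#> 1  A-B 24.72679
#> 2  B-C 24.72679
#> 3  C-A 24.72679
compute_profile(tri, "backbone", z_range = c(-12, 12))
#> pore_profile (backbone atoms): z in [-12.0, 12.0] A (step 0.25),
#> min radius 3.60 A at z = -0.50        # ~7.2 A open entryway

# 4. concatemer logic: two vertical linkers suffice to gate
predict_gating(enumerate_crosslinks("OC/CO/CC", "clockwise"), "vertical")
#> $light_gated TRUE  $max_interfaces 2  $required_interfaces 2
```

A command-line front end with the same operations ships in
`inst/cli/photoruler` (subcommands `linker-sample`, `diststats-fit`,
`ruler-measure`, `pore-profile`, `concat-predict`, `fixtures-trimer`).

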