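# contactr

Segmentation-free detection and quantification of sub-resolution membrane
contact sites — e.g. mitochondria–ER contacts (MERCs) — from two aligned
single-channel 3D fluorescence volumes (typically deconvolved 3D STED stacks
with 25 × 25 × 100 nm voxels).

**Who it is for.** Cell biologists and image analysts who have two
co-registered organelle channels and want voxel-level contact reconstructions
plus per-contact and per-cell morphometrics, without hand-tuned intensity
thresholds or per-channel segmentation.

## Method

The contact cleft (10–30 nm) is far below optical resolution, but at an
interface the blurred intensity of one channel falls exactly where the other
rises. Writing `L⁻[I] = max(−ΔI, 0)` for the negative part of the discrete
Laplacian of a channel `I`, the detector computes at every voxel `v` the
Spearman rank correlation over a centred `(2w+1)³` window `W(v)` (default
`w = 2`, 125 voxels, ~350 nm):

    ρ_lap(v) = ρ_s( L⁻[I_A], L⁻[I_B] | W(v) )
    ρ_int(v) = ρ_s( I_A, I_B | W(v) )

and retains `m(v) = −ρ_lap(v)` where both `ρ_lap(v) < 0` and `ρ_int(v) < 0`.
Rank correlation is invariant to strictly increasing intensity transforms, so
detection is threshold-free in intensity. The raw response is then cleaned by

1. a **bleed-through filter** (voxel intensity z-score ≥ 3 in both channels),
2. a **confidence map** — Fisher z-test `z = atanh(ρ)·√((n−3)/1.06)` at
   α = 0.05 and the minimum observable correlation
   `ρ_min = tanh((z_{1−α/2} + z_power)·√(1.06/(n−3)))` (≈ 0.324 at n = 125,
   power 0.95),
3. a **shadow filter** (third derivative must be zero in both channels or in
   neither),
4. 26-connected labelling with removal of contacts ≤ 2 voxels, and
5. a **vesicle filter**: contacts must touch a mitochondria component with
   ln(size) ≥ 9 and mean rescaled intensity ≥ 0.2.

Contacts are quantified by volume, geometric-mean response, eigenvalue shape
features (sphericity `λ3/λ1`, planarity `(λ2−λ3)/λ1`, anisotropy
`(λ1−λ2)/λ1`; they sum to 1), axial height, mitochondrial surface coverage in
non-overlapping `5k × 5k × k` sampling cubes, and per-cell Q95 large-contact
summaries; conditions are compared with two-sided Mann–Whitney tests on
per-cell means.

A phantom generator (anisotropic Gaussian PSF, 120/250 nm FWHM) produces all
test inputs: a two-sphere separation-sweep demonstration and a whole-volume
cell phantom with ground-truth contact masks, genuine mitochondria, and
vesicle decoys. See the methods vignette
(`vignettes/contact-detection-methods.Rmd`) for the model, parameter
rationale, and limitations.

## Worked example

```r
library(contactr)

spec <- phantom_spec("cell", seed = 1)   # 192 x 192 x 64 voxels, 2 true
ph   <- cell_phantom(spec)               # contacts + 5 vesicle decoys
res  <- detect_contacts(ph$pair)
res
#> contact_result
#>   stage voxel counts:
#>     response     718419
#>     bleedthrough 334
#>     confidence   180
#>     shadow       180
#>     min_size     180
#>     vesicle      180
#>   contacts: 4   rho_min: 0.3239
```

The raw rank-correlation response is permissive; the bleed-through and
confidence stages do the pruning. The surviving 180 voxels form the two
designed interfaces (the two 4-voxel entries are marginal fragments of the
same interfaces — the method does not merge proximate detections):

```r
res$contacts$features[, c("label", "volume", "gm_spearman", "sphericity",
                          "planarity", "anisotropy", "height_nm")]
#>   label volume gm_spearman sphericity planarity anisotropy height_nm
#> 1     1     80      0.4313     0.0161    0.5568     0.4271       300
#> 2     2     92      0.4037     0.0079    0.2741     0.7180       300
#> 3     3      4      0.3374     0.0000    0.0000     1.0000       100
#> 4     4      4      0.3580     0.0000    0.0000     1.0000       100
```

Near-zero sphericity with the weight split between planarity and anisotropy
is exactly right for thin, elongated ribbon-like contacts between a tubule
and an ellipsoid flank, extending over three 100-nm z-slices. Against the geometric
ground truth (2-voxel matching tolerance):

```r
contact_agreement(res$contacts, ph$truth$contact_mask)
#> $recall     0.948
#> $precision  0.989
```

All five vesicle decoys are removed. Writing every output (response TIFF,
contact mask, contact/window CSVs, JSON summary embedding the full parameter
set):

```r
write_outputs(res, "out/")
```

A thin command-line front end with the same parameters lives at
`inst/cli/contactr` (subcommands `detect`, `phantom`, `compare`).

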