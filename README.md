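# cryodenmod

Maximum-likelihood density modification of single-particle cryo-EM maps,
starting from two unmasked half-maps.

## The problem

A cryo-EM reconstruction is a set of complex Fourier terms F(hkl) estimated
from particle images. Agreement between two half-data-set reconstructions
(the Fourier shell correlation, FSC) measures the per-resolution-shell
accuracy of those terms; the resolution at which the half-map FSC falls to
0.143 — where the estimated correlation of the averaged map to the true map
falls to 1/2 — is the map's nominal resolution. High-resolution shells are
noisy, and that noise limits interpretability.

Density modification improves the terms by exploiting prior knowledge about
the *map*: solvent regions are nearly flat, macromolecule density values
follow a characteristic histogram, and (optionally) an atomic model predicts
the density locally. Because an error in one Fourier term spreads over the
whole map while the priors constrain specific regions, each term can be
re-estimated from the rest — provided errors are *local in Fourier space*
(uncorrelated between terms), which holds for unmasked reconstructions and
fails after real-space masking.

## What the package implements

- **Error model** (per resolution shell): FSC between half-maps; the
  expected-value weight `w = FSC * rms_low / rms_high`; complex error
  estimates `E = F_low - w F_high`; error variances from half-map
  differences.
- **Real-space likelihood**: flat-solvent Gaussian + K-component
  Gaussian-mixture macromolecule prior (fit by EM to the averaged map), and
  optionally a model-based target map with per-voxel uncertainty.
- **Map phasing + recombination**: a variance-preconditioned likelihood
  gradient step in Fourier space with an exact line search, recombined with
  the original terms by per-shell inverse-variance weights; iterated for a
  small number of cycles per half-map independently.
- **Ensemble targets**: shake-and-refine model ensembles per half-map, mean
  density and spread-based local sigma (3 Å atom radius, 3-model minimum
  coverage, 2/3-resolution sigma smoothing), combined with the
  density-modified half-map and calibrated against the independent half.
- **Diagnostics**: radial SD profiles and an error-locality verdict
  (local vs concentrated), reproducing the masking pathology on demand.
- **Plumbing**: MRC/CCP4 volume I/O (modes 0/1/2), PDB models (via bio3d),
  B-factor sharpening/blurring `exp(-B/(4d^2))`, half-map sharpening,
  spectral scaling, and a synthetic-scene generator with per-shell
  complex-normal noise.

## Worked example

```r
library(cryodenmod)

# a synthetic 64^3 scene: ~150-atom blob, 1.2 A voxels, nominal 3.5 A
model <- make_toy_model(150, "blob", box = 64 * 1.2, seed = 11)
scene <- make_scene(model, c(64, 64, 64), 1.2, d_min = 2.5,
                    noise_profile(3.5), seed = 1)

params <- denmod_params(resolution = 3.5, d_min = 2.5,
                        fraction_macromolecule =
                          mean(scene$solvent_mask_true$values))
res <- density_modify(scene$half_a, scene$half_b, params)

avg  <- with_values(scene$truth, (scene$half_a$values + scene$half_b$values) / 2)
orig <- fsc_curve(avg, scene$truth, 2.5, 20)
dm   <- fsc_curve(res$final, scene$truth, 2.5, 20)
c(original = mean_weak_shell_fsc(orig),
  density_modified = mean_weak_shell_fsc(dm, reference = orig))
#>         original density_modified
#>        0.1798955        0.7430655
```

The two numbers are the mean FSC-to-truth over the shells where the original
map is weak (FSC < 0.5, roughly 3.7–2.5 Å here): the original averaged map
carries little signal there (0.18), while the density-modified map recovers
most of it (0.74). `plot_fsc(list(original = orig, modified = dm))` draws the
curves; `res$ll_log` records the per-cycle line-search log-likelihoods
(non-decreasing within each cycle).

Adding a model-based target:

```r
tgt   <- build_half_targets(model, res, params, scene$half_a, scene$half_b)
res_m <- density_modify(scene$half_a, scene$half_b, params, target = tgt)
```

raises the weak-shell mean further (0.76 on this seed).

## Command line

A thin wrapper lives in `exec/cryodenmod`:

```sh
cryodenmod simulate --output-prefix scene --seed 7
cryodenmod denmod --half-a scene_half_a.mrc --half-b scene_half_b.mrc \
                  --resolution 3.5 --d-min 2.5 --output dm.mrc
cryodenmod fsc --map-a dm.mrc --map-b scene_truth.mrc --resolution 2.5 \
               --output fsc.csv
```

Every run writes a provenance JSON (parameters, seeds, input checksums,
package version).

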