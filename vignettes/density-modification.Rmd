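---
title: "Maximum-likelihood density modification of cryo-EM half-maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood density modification of cryo-EM half-maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodenmod)
```

## The model

A cryo-EM reconstruction supplies complex Fourier terms $F(hkl)$ whose errors
we take to be drawn, independently per term, from a complex normal
distribution — the central-limit consequence of averaging many per-image
observations. Within a resolution shell the relationship between two
reconstructions is then fully described by their complex correlation, which
for half-maps is the familiar FSC. Three shell quantities drive everything:

* $\mathrm{FSC} = \Re\sum F_{low}\overline{F}_{high} /
  (\mathrm{rms}_{low}\,\mathrm{rms}_{high}\,n)$,
* the expected-value weight $w = \mathrm{FSC}\cdot
  \mathrm{rms}_{low}/\mathrm{rms}_{high}$ (the Luzzati-style factor scaling
  one map's term to its expected value given the other), and
* the complex error estimate $E = F_{low} - w\,F_{high}$ against a
  truth-proxy map.

On the real-space side, the log-likelihood of a candidate map is a sum of
per-voxel terms: a Gaussian about the solvent mean where the map is solvent,
the log of a $K$-component Gaussian mixture (fit by EM to the averaged
half-maps) in the macromolecule region, and — where a model-based target is
available — a Gaussian about the target value with the target's local sigma.
Density modification alternates two steps per half-map: *map phasing*
(re-estimate the Fourier terms so the map better satisfies these
expectations) and *recombination* (an inverse-variance weighted average of
the map-phasing terms with the originals, per shell). The two half-maps are
processed independently and averaged at the end, so the usual half-map FSC
machinery remains valid downstream.

### Why errors must be local in Fourier space

Map phasing re-estimates one term from all the others through the regions
where the map is constrained (most powerfully, flat solvent). The
re-estimated term is useful to average with the original only if its error —
inherited from the *other* terms — is independent of the original term's
error. That holds when errors are uncorrelated between terms ("local in
Fourier space", hence global in real space). The package ships the
diagnostic used to check this premise: the radial profile of the estimated
error map's local standard deviation should be flat, and
`locality_diagnostic()` reports `local` when the inside/outside-mask SD
ratio lies within a factor $T$ (default 1.5 — our operationalisation of
"relatively constant", exposed as a parameter). Real-space masking is the
canonical way to break the premise; `apply_mask_corruption()` reproduces it,
and the diagnostic then reports `concentrated`.

### The single-term oracle

With exactly flat solvent, all terms perfect except one, and only that term
free, zeroing the solvent region determines the term exactly. The package
keeps this argument testable in its literal form: `phase_single_term()`
optimizes one coefficient (all others fixed) by gradient ascent with exact
line searches, and `brute_force_single_term()` does an exhaustive
amplitude-phase search of the same one-term problem. Both restore a
corrupted term to well under 1% on the bundled noise-free scenes.

The production step, `map_phase_step()`, is deliberately *not* a per-term
loop (that would cost $O(N_{terms} N_{grid})$): it moves all terms at once
along the likelihood gradient transformed to Fourier space. Note a fact that
shapes the design: if every term is free and run to convergence, gradient
flow on the flat-solvent objective converges to the projection of the map
onto densities unchanged in solvent, and a single corrupted term retains a
residual proportional to the macromolecule volume fraction. Recovery of
individual terms to high accuracy is therefore a property of the
*single-term* formulation (and of recombination anchoring the rest), not of
the full-gradient flow — which is why both paths exist and are tested
against each other for direction agreement.

## Numerical choices

* **Preconditioned gradient, one step length.** The raw gradient scales as
  $1/\sigma^2$, so a region with a tight sigma (a calibrated target, nearly
  flat solvent) has curvature orders of magnitude above the rest and a
  single step length stalls. We precondition by the per-voxel branch
  variance (diagonal Newton), making the natural step $\alpha\approx 1$
  everywhere, then find $\alpha$ by an exact line search (golden-section on
  the pointwise likelihood along the band-limited direction, bounded at 4).
  A per-shell step length was considered and rejected: the stiffness is
  spatial, not spectral, and after preconditioning a shared scalar step is
  within rounding of per-shell optima at these problem sizes. The line
  search never decreases the total log-likelihood; every cycle logs
  before/after values so the monotonicity is auditable from output alone.
* **F000 is held fixed** (the absolute offset is not determined by the
  priors), and the gradient is zeroed beyond the analysis resolution.
* **Error variances.** Original per-half shell variances come from
  $\langle|F_a-F_b|^2\rangle/2$. Map-phasing variances are scored
  *cross-half*: mp terms of half a against the original terms of half b,
  minus b's own variance. The more obvious mp-a/mp-b difference was tried
  first and is biased: the prior pushes both mp maps the same way, the
  common component cancels in the difference, and the recombination weights
  become overconfident (visibly degrading low-resolution shells). The
  cross-half estimator sees that common error because the reference errors
  are independent of it.
* **Target sigma calibration.** The ensemble spread is a lower bound on
  target error; all members share the starting model and the refinement
  target, so systematic error is invisible to the spread (measured 3–5×
  underestimates on desk scenes). `calibrate_target_sigma()` rescales sigma
  by one global factor so the mean squared target residual against the
  *opposite original half-map* (minus that half-map's own noise variance)
  matches the claimed variance; sigma is never shrunk. Accurate uncertainty
  specification is a stated prerequisite of the method, and this uses only
  independent data.
* **EM for the mixture prior**: quantile-spread means, equal weights, common
  sigma at start; relative log-likelihood tolerance $10^{-6}$, at most 1000
  iterations; sigmas floored at $10^{-6}\times$ the overall map SD. The fit
  is deterministic (no random restarts), so runs are reproducible without a
  seed.
* **Shells** are equal-width in $1/d^2$; a term exactly on an interior edge
  joins the higher-resolution shell; empty shells merge downward with a
  warning. Conventions chosen to be brute-force checkable, and checked.
* **B factors** follow $\exp(-B/(4d^2))$; `blur_by_resolution` applies
  $B = 10\times$ resolution to the final map. Half-map sharpening rescales
  each shell's rms to be proportional to $\max(\mathrm{FSC},0)$ (negative
  shells carry no usable signal and are zeroed), preserving total power.
  Spectral scaling takes an explicit per-shell target profile; a canonical
  smooth profile table ships in `inst/extdata/` rather than being computed
  from a reference structure — a documented simplification.
* **Cycles**: default 5 with a $10^{-4}$ relative stopping tolerance.
  Repeated cycling re-adjusts terms using already-adjusted terms and can
  correlate errors, so the count is deliberately small and configurable.
  Recombination keeps at least `recomb_floor` (default 0.05) weight on the
  originals.

## Ensemble targets

Per half-map: shake the supplied model (isotropic Gaussian displacements
with r.m.s. equal to the requested magnitude), refine each copy against that
half's density-modified map, and keep `n_models` (default 8) members. The
refinement is a simple gradient fit of atoms to local density — a stand-in
for full real-space refinement, adequate for desk-scale scenes — with a
per-step cap and a total-displacement cap from the start coordinates; the
cap plays the role of stereochemical restraints and prevents neighbouring
atoms from piling onto one peak. The target value/sigma are the per-voxel
mean and $(n-1)$-denominator SD over member densities; sigma is smoothed
with radius $2/3\times$ resolution and floored at 10% of its in-mask mean
(floor and divisor are our choices). Validity requires an atom within 3 Å in
at least 3 members. The target is then combined with the density-modified
half-map by inverse-variance weights, the half-map's local variance being
the smoothed half squared difference of the two density-modified half-maps
(smoothing radius = the resolution). Each half's target uses only its own
ensemble, preserving half-map independence.

The wrong-conformer control shows why this is reasonably safe against model
bias: build a two-state scene whose truth is conformer B, target the wrong
conformer A, and the density-modified map still correlates better with B in
the feature region — the original terms carry the B signal, and a map-phased
term must fit the *whole* likelihood, not just the target patch.

## The synthetic scene generator

`make_scene()` realizes the statistical structure the method assumes: truth
is a Gaussian-atom model density that is *exactly* constant (zero) outside
the molecular envelope, and each half-map adds independent, Hermitian,
per-term complex-normal noise whose per-shell SD follows a noise-to-signal
profile that grows exponentially in $1/d^2$, calibrated so the expected
half-map FSC $=1/(1+\sigma^2/\mathrm{rms}^2)$ crosses 0.143 at the nominal
resolution. A single scene seed deterministically derives sub-seeds for the
two halves, guaranteeing the independence contract. Two deliberate
idealisations: the truth is only *softly* band-limited (atom width matched
to the resolution, $B_{res} = 8 d_{min}^2$, leaving ~1–2% of power beyond
$d_{min}$) because a sharp Fourier truncation would ripple into the solvent
and destroy the exactly-flat premise; and soft masks use a 2-voxel cosine
taper since hard edges ring enough to confound the locality diagnostic's
tolerance.

Default conditions: $64^3$ grid, 1.2 Å voxels, a ~150-atom compact random
cluster ("blob", roughly half protein-interior atom density — a peptide-size
object), nominal resolution 3.5 Å, analysis to 2.5 Å, 20 shells. Small
enough that a full density-modification run takes seconds; rich enough for
meaningful shell statistics. What passing tests on these scenes does *not*
show: behaviour under masking applied during reconstruction, non-flat
solvent (lipid, disordered regions), spatially varying resolution, or
errors shared between half-maps — all listed limitations of the method
itself, not just of the scenes.

## Degenerate inputs and edge rules

Identical half-maps carry no error information: `density_modify()` warns and
runs prior-only modification (no recombination). All-non-positive FSC
aborts. Shells with zero reference rms flag `w` undefined and fall back to
$E = F_{low}$. Sigma of a constant solvent region floors to a positive
epsilon. The brute-force search widens its amplitude bounds once if the
optimum lands on the boundary, and returns the input coefficient when the
likelihood is flat in that term (tie rule: keep the original).

## Problem sizes used by the test-suite and acceptance script

Unit tests run on $8^3$–$32^3$ grids; the end-to-end properties use the
default $64^3$ scene with 5 replicates (FSC improvement, model-bias
control) and 20 replicates of a $32^3$ scene for the locality diagnostics —
sizes at which the whole suite completes in a few minutes on one CPU while
the shell statistics remain stable.

## Known limitations

The refinement stand-in has no stereochemistry beyond the displacement cap;
ensembles therefore under-explore conformations compared to restrained
refinement. Recombination weights are shell-constant (no per-term weights),
matching the shell resolution of the error model. Low-resolution shells can
dip slightly below their original FSC after recombination — the weighting is
honest but not provably optimal, and the floor on original weights is the
exposed control. Only orthogonal cells and single maps (no symmetry
averaging, no NCS targets) are supported.
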