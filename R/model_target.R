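# atomic-number weights for the elements that occur in desk-scale models
element_weight <- function(element) {
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, FE = 26)
  out <- z[toupper(element)]
  out[is.na(out)] <- 6
  unname(out)
}

#' Compute model-based density on a grid
#'
#' Each atom contributes an isotropic 3-D Gaussian whose mass is occupancy
#' times atomic number and whose width combines the atomic B value with an
#' overall resolution blur `B_res = 8 * d_min^2` (so amplitudes fall to about
#' exp(-2) at the resolution limit — an effectively band-limited map without
#' the solvent ripple a sharp Fourier truncation would add). Atoms outside the
#' grid are clipped with a warning.
#'
#' @param model An `atommodel`.
#' @param grid `mapgrid` template supplying dims/voxel/origin (values ignored).
#' @param d_min Resolution in Angstrom controlling the blur.
#' @return A `mapgrid` of model density (exactly zero away from all atoms).
#' @export
model_to_density <- function(model, grid, d_min) {
  a <- model$atoms
  b_eff <- a$b + 8 * d_min^2
  sigma <- sqrt(b_eff / (8 * pi^2))
  amp <- a$occ * element_weight(a$element) / (2 * pi * sigma^2)^1.5
  vals <- stamp_gaussians(grid, model_coords(model), amp, sigma)
  with_values(grid, vals)
}

# Sum per-atom Gaussians over local neighbourhoods (cutoff 4 sigma each).
stamp_gaussians <- function(grid, xyz, amp, sigma) {
  d <- map_dims(grid)
  out <- array(0, d)
  clipped <- FALSE
  for (i in seq_len(nrow(xyz))) {
    p <- (xyz[i, ] - grid$origin) / grid$voxel        # fractional grid coords
    cut <- 4 * sigma[i] / grid$voxel
    lo <- pmax(ceiling(p - cut), 0)
    hi <- pmin(floor(p + cut), d - 1)
    if (any(lo > hi) || any(p < -0.5) || any(p > d - 0.5)) {
      clipped <- TRUE
      next
    }
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - p[1]) * grid$voxel[1])^2
    dy2 <- ((iy - p[2]) * grid$voxel[2])^2
    dz2 <- ((iz - p[3]) * grid$voxel[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    g <- amp[i] * exp(-r2 / (2 * sigma[i]^2))
    g[r2 > (4 * sigma[i])^2] <- 0           # spherical cutoff: exact zeros beyond 4 sigma
    out[ix + 1, iy + 1, iz + 1] <- out[ix + 1, iy + 1, iz + 1] + g
  }
  if (clipped) warning("atom(s) outside the grid were clipped")
  out
}

# TRUE for voxels within `radius` A of any atom.
near_atom_mask <- function(grid, xyz, radius) {
  d <- map_dims(grid)
  out <- array(FALSE, d)
  for (i in seq_len(nrow(xyz))) {
    p <- (xyz[i, ] - grid$origin) / grid$voxel
    cut <- radius / grid$voxel
    lo <- pmax(ceiling(p - cut), 0)
    hi <- pmin(floor(p + cut), d - 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - p[1]) * grid$voxel[1])^2
    dy2 <- ((iy - p[2]) * grid$voxel[2])^2
    dz2 <- ((iz - p[3]) * grid$voxel[3])^2
    sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    out[ix + 1, iy + 1, iz + 1] <- out[ix + 1, iy + 1, iz + 1] | sph
  }
  out
}

#' Randomly perturb a model ("shaking")
#'
#' Displaces every atom by an isotropic Gaussian perturbation whose expected
#' r.m.s. total displacement equals `magnitude`. Identical seeds reproduce
#' identical output.
#'
#' @param model An `atommodel`.
#' @param magnitude Target r.m.s. displacement in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return An `atommodel`.
#' @export
shake_model <- function(model, magnitude, seed) {
  if (magnitude < 0) stop("magnitude must be non-negative")
  if (magnitude == 0) return(model)
  a <- model$atoms
  n <- nrow(a)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  s <- magnitude / sqrt(3)
  a$x <- a$x + stats::rnorm(n, 0, s)
  a$y <- a$y + stats::rnorm(n, 0, s)
  a$z <- a$z + stats::rnorm(n, 0, s)
  atom_model(a)
}

# seed helpers: set a temporary seed and restore the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# derive k sub-seeds (< 2^31) deterministically from one seed
split_seed <- function(seed, k) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, k)
}

# trilinear interpolation of map values at arbitrary Angstrom positions
interp_map <- function(m, xyz) {
  d <- map_dims(m)
  p <- sweep(sweep(xyz, 2, m$origin, "-"), 2, m$voxel, "/")
  p <- pmin(pmax(p, 0), matrix(rep(d - 1 - 1e-9, each = nrow(p)), nrow(p)))
  i0 <- floor(p)
  fr <- p - i0
  v <- m$values
  idx <- function(ox, oy, oz)
    v[cbind(i0[, 1] + 1 + ox, i0[, 2] + 1 + oy, i0[, 3] + 1 + oz)]
  c000 <- idx(0, 0, 0); c100 <- idx(1, 0, 0); c010 <- idx(0, 1, 0); c110 <- idx(1, 1, 0)
  c001 <- idx(0, 0, 1); c101 <- idx(1, 0, 1); c011 <- idx(0, 1, 1); c111 <- idx(1, 1, 1)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
    (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
    (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
    (c011 * (1 - fx) + c111 * fx) * fy * fz
}

#' Real-space gradient refinement of a model against a map
#'
#' Moves each atom up the local density gradient (estimated by central
#' differences of the trilinear interpolant) with backtracking step control, a
#' per-step displacement cap, and a total-displacement cap from the starting
#' coordinates (the stand-in for the stereochemical restraints of a full
#' real-space refinement, preventing neighbouring atoms from piling onto the
#' same density peak). The density-fit score (sum of interpolated density at
#' atom centres, occupancy-weighted) is non-decreasing across steps. A
#' deliberately simple fit, adequate for desk-scale scenes.
#'
#' @param model An `atommodel`.
#' @param half_map `mapgrid` target (typically a density-modified half-map).
#' @param steps Maximum number of steps.
#' @param max_shift Displacement cap per atom per step in Angstrom.
#' @param max_total Total displacement cap per atom from its starting
#'   position, Angstrom (`Inf` to disable).
#' @return An `atommodel` with attribute `score_trajectory`.
#' @export
local_refine <- function(model, half_map, steps = 20, max_shift = 0.25,
                         max_total = 0.6) {
  xyz <- model_coords(model)
  start <- xyz
  occ <- model$atoms$occ
  score <- function(pos) sum(occ * interp_map(half_map, pos))
  clip_total <- function(pos) {
    disp <- pos - start
    dn <- sqrt(rowSums(disp^2))
    over <- dn > max_total
    if (any(over))
      pos[over, ] <- start[over, ] + disp[over, ] * (max_total / dn[over])
    pos
  }
  h <- min(half_map$voxel) / 4
  traj <- numeric(0)
  s0 <- score(xyz)
  for (step in seq_len(steps)) {
    g <- matrix(0, nrow(xyz), 3)
    for (a in 1:3) {
      e <- matrix(0, nrow(xyz), 3); e[, a] <- h
      g[, a] <- (interp_map(half_map, xyz + e) - interp_map(half_map, xyz - e)) / (2 * h)
    }
    gn <- sqrt(rowSums(g^2))
    if (max(gn) == 0) break
    dirn <- g / pmax(gn, 1e-12)
    stepsize <- max_shift
    moved <- FALSE
    while (stepsize > max_shift / 64) {
      cand <- clip_total(xyz + dirn * pmin(gn * stepsize / max(gn), stepsize))
      s1 <- score(cand)
      if (s1 >= s0) {
        xyz <- cand; s0 <- s1; moved <- TRUE
        break
      }
      stepsize <- stepsize / 2
    }
    traj <- c(traj, s0)
    if (!moved) break
  }
  a <- model$atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  out <- atom_model(a)
  attr(out, "score_trajectory") <- traj
  out
}

#' Build an ensemble of models for one half-map
#'
#' Shakes a starting model `n_models` times (different derived seeds) and
#' refines each copy against the supplied density-modified half-map, mirroring
#' the construction of a per-half-map ensemble whose spread lower-bounds local
#' model uncertainty.
#'
#' @param model Starting `atommodel`.
#' @param half_map `mapgrid` used as the refinement target.
#' @param n_models Number of members (default 8).
#' @param shake_magnitude R.m.s. shake in Angstrom (default 0.5).
#' @param seed Integer seed.
#' @param refine_steps Steps of [local_refine()] per member.
#' @param source_half Identifier "a" or "b", recorded for provenance.
#' @return An `ensemble`: list with `models`, `source_half`,
#'   `shake_magnitude`, `seed`.
#' @export
make_ensemble <- function(model, half_map, n_models = 8, shake_magnitude = 0.5,
                          seed = 1, refine_steps = 10, source_half = "a") {
  if (n_models < 2) stop("an ensemble needs at least 2 members")
  seeds <- split_seed(seed, n_models)
  models <- lapply(seeds, function(s)
    local_refine(shake_model(model, shake_magnitude, s), half_map,
                 steps = refine_steps))
  structure(list(models = models, source_half = source_half,
                 shake_magnitude = shake_magnitude, seed = seed),
            class = "ensemble")
}

#' Construct a TargetMap
#' @param value,sigma `mapgrid`s of target density and local uncertainty.
#' @param mask Logical `mapgrid` of validity.
#' @param coverage Integer `mapgrid` of contributing-model counts (optional).
#' @return A `targetmap`.
#' @export
target_map <- function(value, sigma, mask, coverage = NULL) {
  stop_if_misaligned(value, sigma, "target value and sigma")
  stop_if_misaligned(value, mask, "target value and mask")
  structure(list(value = value, sigma = sigma, mask = mask,
                 coverage = coverage),
            class = "targetmap")
}

#' Ensemble-based target density with local uncertainty
#'
#' At each grid point, counts the ensemble members with an atom within
#' `atom_radius`; points covered by at least `min_models` members form the
#' validity mask. Inside it, the target value is the mean of the member
#' densities and the local uncertainty is their (n-1)-denominator standard
#' deviation, smoothed with radius `2/3 * d_min` and floored at 10% of the
#' mean in-mask sigma.
#'
#' @param e An `ensemble`.
#' @param grid `mapgrid` template.
#' @param d_min Resolution in Angstrom.
#' @param atom_radius Coverage radius in Angstrom (default 3).
#' @param min_models Minimum contributing members (default 3).
#' @param smooth_radius Sigma smoothing radius (default `2/3 * d_min`).
#' @return A `targetmap` with `coverage`.
#' @export
ensemble_density <- function(e, grid, d_min, atom_radius = 3, min_models = 3,
                             smooth_radius = 2 / 3 * d_min) {
  models <- e$models
  if (length(models) < min_models)
    stop("fewer ensemble members than min_models")
  dens <- lapply(models, function(mod) model_to_density(mod, grid, d_min)$values)
  cov <- array(0L, map_dims(grid))
  for (mod in models)
    cov <- cov + near_atom_mask(grid, model_coords(mod), atom_radius)
  mask <- cov >= min_models
  if (!any(mask)) stop("no grid points covered by enough models: no usable model information")
  n <- length(dens)
  mean_d <- Reduce(`+`, dens) / n
  var_d <- Reduce(`+`, lapply(dens, function(v) (v - mean_d)^2)) / (n - 1)
  sig <- smooth_map(with_values(grid, sqrt(var_d)), smooth_radius)$values
  floor_sig <- 0.1 * mean(sig[mask])
  sig <- pmax(sig, max(floor_sig, .Machine$double.eps))
  out <- target_map(with_values(grid, mean_d),
                    with_values(grid, sig),
                    with_values(grid, mask),
                    with_values(grid, cov))
  attr(out, "smooth_radius") <- smooth_radius
  out
}

#' Combine a model-based target with a density-modified half-map
#'
#' Estimates the local variance of the density-modified half-map as the
#' smoothed half squared difference between the two density-modified
#' half-maps (smoothing radius = the resolution of the original map), then
#' replaces the target value inside the mask by the inverse-variance weighted
#' average of model density and half-map, with the corresponding posterior
#' sigma. The mask still requires the minimum model coverage.
#'
#' @param t A `targetmap` from [ensemble_density()].
#' @param dm_half `mapgrid`: the density-modified half-map this target belongs
#'   to.
#' @param other_dm_half `mapgrid`: the other density-modified half-map.
#' @param resolution Nominal resolution of the original map in Angstrom
#'   (smoothing radius for the half-map uncertainty).
#' @return A `targetmap`.
#' @export
combine_target <- function(t, dm_half, other_dm_half, resolution) {
  stop_if_misaligned(dm_half, other_dm_half, "half-maps")
  stop_if_misaligned(t$value, dm_half, "target and half-map")
  diff2 <- (dm_half$values - other_dm_half$values)^2 / 2
  var_h <- pmax(smooth_map(with_values(dm_half, diff2), resolution)$values, 0)
  var_t <- t$sigma$values^2
  both_zero <- var_h <= 0 & var_t <= 0
  var_h[var_h <= 0] <- .Machine$double.eps
  var_t[var_t <= 0] <- .Machine$double.eps
  w_model <- (1 / var_t) / (1 / var_t + 1 / var_h)
  value <- w_model * t$value$values + (1 - w_model) * dm_half$values
  value[both_zero] <- t$value$values[both_zero]
  sigma <- sqrt(1 / (1 / var_t + 1 / var_h))
  out <- target_map(with_values(dm_half, value),
                    with_values(dm_half, sigma),
                    t$mask, t$coverage)
  attr(out, "halfmap_smooth_radius") <- resolution
  attr(out, "flagged_zero_variance") <- any(both_zero)
  out
}

#' Correlation between a map and model-based density
#'
#' Computes the correlation of the map with density calculated from the model
#' after setting all atomic B values to zero, over grid points within
#' `mask_radius` of any atom (a CC-mask-style map quality metric).
#'
#' @param m A `mapgrid`.
#' @param model An `atommodel`.
#' @param d_min Resolution for the model density, Angstrom.
#' @param mask_radius Mask radius in Angstrom (default 3).
#' @return Numeric correlation.
#' @export
map_model_correlation <- function(m, model, d_min, mask_radius = 3) {
  a <- model$atoms
  a$b <- 0
  dens <- model_to_density(atom_model(a), m, d_min)
  mask <- near_atom_mask(m, model_coords(model), mask_radius)
  if (!any(mask)) stop("empty correlation mask")
  stats::cor(m$values[mask], dens$values[mask])
}
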