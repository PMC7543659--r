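grid_template <- function(dims = c(24, 24, 24), voxel = 1.2) {
  map_grid(array(0, dims), voxel)
}

test_that("model density is a centred peak, linear in occupancy, additive", {
  g <- grid_template()
  ctr <- (map_dims(g) - 1) / 2 * g$voxel
  one <- atom_model(tibble::tibble(element = "C", x = ctr[1], y = ctr[2],
                                   z = ctr[3], b = 20, occ = 1))
  d1 <- model_to_density(one, g, 3)
  peak <- which(d1$values == max(d1$values), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(peak - 1) * g$voxel, ctr, tolerance = max(g$voxel))
  # radially symmetric about the atom: mirror symmetry along every axis
  flip <- rev(seq_len(map_dims(g)[1]))
  expect_equal(d1$values, d1$values[flip, flip, flip], tolerance = 1e-10)

  half <- one
  half$atoms$occ <- 0.5
  d05 <- model_to_density(half, g, 3)
  expect_equal(d05$values, d1$values / 2, tolerance = 1e-10)

  two <- atom_model(rbind(one$atoms, one$atoms))
  d2 <- model_to_density(two, g, 3)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-10)
})

test_that("atoms outside the grid are clipped with a warning", {
  g <- grid_template()
  far <- atom_model(tibble::tibble(element = "C", x = 500, y = 0, z = 0,
                                   b = 20, occ = 1))
  expect_warning(d <- model_to_density(far, g, 3), "clipped")
  expect_equal(max(abs(d$values)), 0)
})

test_that("shaking is seeded, unbiased in magnitude and identity at zero", {
  mod <- make_toy_model(500, "blob", box = 80, seed = 12)
  expect_identical(shake_model(mod, 0, 1), mod)
  s1 <- shake_model(mod, 0.5, 99)
  s2 <- shake_model(mod, 0.5, 99)
  expect_identical(s1$atoms, s2$atoms)
  disp <- sqrt(rowSums((model_coords(s1) - model_coords(mod))^2))
  expect_lt(abs(sqrt(mean(disp^2)) - 0.5) / 0.5, 0.1)
  s3 <- shake_model(mod, 0.5, 100)
  expect_false(identical(s3$atoms$x, s1$atoms$x))
})

test_that("local refinement walks an atom toward a density peak, monotonely", {
  g <- grid_template()
  ctr <- (map_dims(g) - 1) / 2 * g$voxel
  peak_model <- atom_model(tibble::tibble(element = "C", x = ctr[1],
                                          y = ctr[2], z = ctr[3], b = 20,
                                          occ = 1))
  dens <- model_to_density(peak_model, g, 3)

  displaced <- peak_model
  displaced$atoms$x <- displaced$atoms$x + 0.8
  ref <- local_refine(displaced, dens, steps = 20)
  d_before <- abs(displaced$atoms$x - ctr[1])
  d_after <- sqrt(sum((model_coords(ref) - ctr)^2))
  expect_lt(d_after, d_before)

  traj <- attr(ref, "score_trajectory")
  expect_true(all(diff(traj) >= -1e-12))

  # already at the optimum: no movement beyond tolerance
  at_peak <- local_refine(peak_model, dens, steps = 10)
  expect_lt(max(abs(model_coords(at_peak) - model_coords(peak_model))), 0.1)
})

test_that("ensemble density applies the coverage rule and uncertainty model", {
  g <- grid_template(c(28, 28, 28))
  base <- make_toy_model(12, "helix", box = 28 * 1.2, seed = 7)

  # identical members: sigma collapses to the floor, value = member density
  same <- structure(list(models = replicate(8, base, simplify = FALSE),
                         source_half = "a", shake_magnitude = 0, seed = 1),
                    class = "ensemble")
  t_same <- ensemble_density(same, g, 3)
  inm <- t_same$mask$values
  expect_equal(t_same$value$values[inm],
               model_to_density(base, g, 3)$values[inm], tolerance = 1e-10)
  expect_lt(diff(range(t_same$sigma$values[inm])), 1e-12)

  # a point near atoms in only 2 of 8 members is excluded from the mask
  outlier <- base
  outlier$atoms$x <- outlier$atoms$x + 12   # move the whole model far away
  two_cover <- structure(list(models = c(replicate(6, base, simplify = FALSE),
                                         list(outlier, outlier)),
                              source_half = "a", shake_magnitude = 0,
                              seed = 1),
                         class = "ensemble")
  t2 <- ensemble_density(two_cover, g, 3)
  cov <- t2$coverage$values
  only2 <- cov == 2
  expect_gt(sum(only2), 0)
  expect_true(all(!t2$mask$values[only2]))
  expect_true(all(cov[t2$mask$values] >= 3))

  # one displaced atom raises sigma only near that atom
  moved <- base
  moved$atoms$x[5] <- moved$atoms$x[5] + 2.5
  pair <- structure(list(models = c(replicate(4, base, simplify = FALSE),
                                    replicate(4, moved, simplify = FALSE)),
                         source_half = "a", shake_magnitude = 0, seed = 1),
                    class = "ensemble")
  tp <- ensemble_density(pair, g, 3, smooth_radius = 2)
  both <- rbind(base$atoms[5, ], moved$atoms[5, ])
  near <- cryodenmod:::near_atom_mask(g, cbind(both$x, both$y, both$z), 3 + 2)
  inm <- tp$mask$values
  hi <- tp$sigma$values > 2 * min(tp$sigma$values[inm])
  expect_true(all(which(hi & inm) %in% which(near)))
})

test_that("ensemble mask shrinks as min_models grows; member order is irrelevant", {
  g <- grid_template(c(28, 28, 28))
  base <- make_toy_model(12, "helix", box = 28 * 1.2, seed = 7)
  ens <- make_ensemble(base, model_to_density(base, g, 3), n_models = 6,
                       shake_magnitude = 1.5, seed = 3)
  sizes <- vapply(2:5, function(k)
    sum(ensemble_density(ens, g, 3, min_models = k)$mask$values), numeric(1))
  expect_true(all(diff(sizes) <= 0))

  perm <- ens
  perm$models <- perm$models[c(4, 2, 6, 1, 3, 5)]
  t1 <- ensemble_density(ens, g, 3)
  t2 <- ensemble_density(perm, g, 3)
  expect_equal(t1$sigma$values, t2$sigma$values, tolerance = 1e-12)
  expect_equal(t1$value$values, t2$value$values, tolerance = 1e-12)
})

test_that("target combination follows inverse-variance weighting", {
  sc <- small_scene()
  g <- sc$truth
  base <- sc$model
  dens <- model_to_density(base, g, 2.6)
  sig <- with_values(g, array(0.5, map_dims(g)))
  mask <- sc$solvent_mask_true
  t0 <- target_map(dens, sig, mask)

  # equal local variances -> simple mean (build half-maps whose smoothed
  # squared difference is exactly 2 * 0.5^2 so var_h = 0.5^2)
  delta <- 0.5 / sqrt(2)   # so smoothed (ha-hb)^2 / 2 equals sigma_t^2 = 0.25
  ha <- with_values(g, g$values + delta)
  hb <- with_values(g, g$values - delta)
  comb <- combine_target(t0, ha, hb, resolution = 3.2)
  inm <- mask$values
  expect_equal(comb$value$values[inm],
               (dens$values[inm] + ha$values[inm]) / 2, tolerance = 1e-6)

  # half-map variance huge -> model value wins
  ha2 <- with_values(g, g$values + 1e4)
  hb2 <- with_values(g, g$values - 1e4)
  comb2 <- combine_target(t0, ha2, hb2, resolution = 3.2)
  expect_lt(max(abs(comb2$value$values[inm] - dens$values[inm])), 1e-3)

  # the half-map uncertainty smoothing radius is the stated resolution
  expect_equal(attr(comb, "halfmap_smooth_radius"), 3.2)
})

test_that("combined target beats each source in mean squared error", {
  # Monte-Carlo over seeds: truth + independent noise as "model" and
  # "half-map" sources with matching variances
  sc <- small_scene()
  g <- sc$truth
  mask <- sc$solvent_mask_true
  inm <- mask$values
  set.seed(31)
  wins <- replicate(10, {
    n <- length(g$values)
    model_src <- with_values(g, g$values + stats::rnorm(n, 0, 0.02))
    ha <- with_values(g, g$values + stats::rnorm(n, 0, 0.03))
    hb <- with_values(g, g$values + stats::rnorm(n, 0, 0.03))
    t0 <- target_map(model_src, with_values(g, array(0.02, map_dims(g))), mask)
    comb <- combine_target(t0, ha, hb, resolution = 3.2)
    mse <- function(v) mean((v[inm] - g$values[inm])^2)
    mse(comb$value$values) <= min(mse(model_src$values), mse(ha$values))
  })
  expect_gte(mean(wins), 0.9)
})

test_that("map-model correlation is 1 against its own B0 density, -1 negated,
           and ~1/sqrt(2) at SNR 1", {
  g <- grid_template(c(28, 28, 28))
  mod <- make_toy_model(12, "helix", box = 28 * 1.2, seed = 8)
  b0 <- mod
  b0$atoms$b <- 0
  dens <- model_to_density(b0, g, 3)
  expect_equal(map_model_correlation(dens, mod, 3), 1, tolerance = 1e-6)
  neg <- with_values(dens, -dens$values)
  expect_equal(map_model_correlation(neg, mod, 3), -1, tolerance = 1e-6)

  mask <- cryodenmod:::near_atom_mask(g, model_coords(mod), 3)
  sd_sig <- stats::sd(dens$values[mask])
  set.seed(17)
  ccs <- replicate(8, {
    noisy <- with_values(dens, dens$values +
                           stats::rnorm(length(dens$values), 0, sd_sig))
    map_model_correlation(noisy, mod, 3)
  })
  n <- sum(mask)
  expect_lt(abs(mean(ccs) - 1 / sqrt(2)), 3 * 0.5 / sqrt(8 * n))
})
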