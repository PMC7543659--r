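test_that("map phasing is a fixed point at the prior mode", {
  sc <- flat_scene()
  prior <- flat_solvent_prior(sc)
  # truth already satisfies the flat-solvent expectation exactly
  f <- fft_map(sc$truth)
  lf <- evaluate_likelihood(sc$truth, prior)
  stepped <- map_phase_step(f, lf, sc$scheme, prior)
  expect_lt(max(Mod(stepped$terms - f$terms)), 1e-6 * max(Mod(f$terms)))
  expect_gte(attr(stepped, "ll_after"), attr(stepped, "ll_before"))
})

test_that("a single corrupted term is restored by iterated single-term phasing", {
  sc <- flat_scene()
  prior <- flat_solvent_prior(sc)
  hkl <- c(2, 1, 1)
  truth_f <- fft_map(sc$truth)
  true_val <- get_fourier_term(truth_f, hkl)
  corrupted <- corrupt_fourier_term(sc$truth, hkl, 5)
  fc <- fft_map(corrupted)

  est <- phase_single_term(fc, hkl, prior)
  expect_lt(Mod(est - true_val) / Mod(true_val), 0.01)

  # one full map-phasing gradient step also removes most of the corruption
  lf <- evaluate_likelihood(corrupted, prior)
  stepped <- map_phase_step(fc, lf, sc$scheme, prior)
  resid <- Mod(get_fourier_term(stepped, hkl) - true_val)
  resid0 <- Mod(get_fourier_term(fc, hkl) - true_val)
  expect_lt(resid / resid0, 0.25)
})

test_that("brute-force single-term search agrees with the gradient path and
           the Gaussian closed form", {
  sc <- flat_scene()
  prior <- flat_solvent_prior(sc)
  hkl <- c(2, 1, 1)
  true_val <- get_fourier_term(fft_map(sc$truth), hkl)
  fc <- fft_map(corrupt_fourier_term(sc$truth, hkl, 5))

  bf <- brute_force_single_term(fc, hkl, prior)
  est <- phase_single_term(fc, hkl, prior)
  expect_lt(Mod(bf - true_val) / Mod(true_val), 0.05)
  expect_lt(Mod(bf - est) / Mod(true_val), 0.05)

  # all-Gaussian likelihood: the optimum solves a 2x2 normal-equation system.
  # With (effectively) only the flat-solvent branch active, minimize
  # sum_M (rho0 + (2/N)(u ReE - v ImE))^2 over delta = u + i v.
  dims <- map_dims(sc$truth)
  n <- prod(dims)
  E <- cryodenmod:::phase_wave(dims, hkl)
  M <- !sc$solvent_mask_true$values
  A <- (2 / n) * Re(E)[M]
  B <- -(2 / n) * Im(E)[M]
  r0 <- corrupt_fourier_term(sc$truth, hkl, 5)$values[M]
  sol <- solve(matrix(c(sum(A^2), sum(A * B), sum(A * B), sum(B^2)), 2),
               c(-sum(A * r0), -sum(B * r0)))
  closed <- get_fourier_term(fc, hkl) + complex(real = sol[1],
                                                imaginary = sol[2])
  expect_lt(Mod(est - closed) / Mod(closed), 1e-6)

  # flat likelihood keeps the original value (tie rule)
  flat_prior <- prior
  flat_prior$solvent <- c(mean = 0, sd = 1e9)
  flat_prior$macro$sd <- 1e9
  tie <- brute_force_single_term(fc, hkl, flat_prior)
  expect_equal(as.complex(tie), get_fourier_term(fc, hkl))
})

test_that("recombination follows inverse-variance weighting with a floor", {
  sc <- small_scene()
  fa <- fft_map(sc$half_a); fb <- fft_map(sc$half_b)
  scheme <- sc$scheme
  so <- cryodenmod:::halfmap_error_stats(fa, fb, scheme)

  # infinite map-phasing variance: the original is returned
  sm_inf <- so
  sm_inf$sigma2_err <- rep(1e30, scheme$n_shells)
  out <- recombine(fa, fb, so, sm_inf, recomb_floor = 0)
  ok <- !is.na(scheme$index)
  expect_equal(out$terms[ok], fa$terms[ok], tolerance = 1e-10)

  # equal variances: arithmetic mean of the coefficients
  out2 <- recombine(fa, fb, so, so, recomb_floor = 0)
  expect_equal(out2$terms[ok], ((fa$terms + fb$terms) / 2)[ok],
               tolerance = 1e-10)

  # recomb_floor = 1 reproduces the original exactly
  sm0 <- so
  sm0$sigma2_err <- rep(0, scheme$n_shells)
  out3 <- recombine(fa, fb, so, sm0, recomb_floor = 1)
  expect_identical(out3$terms, fa$terms)
})

test_that("recombined error variance is no worse than either input", {
  # uncorrelated-error construction: truth + two independent noise draws
  sc <- small_scene()
  truth_f <- fft_map(sc$truth)
  scheme <- sc$scheme
  rms_sig <- cryodenmod:::shell_rms(truth_f, scheme)
  set.seed(77)
  better <- replicate(20, {
    seeds <- sample.int(1e6, 2)
    f1 <- fft_map(cryodenmod:::add_shell_noise(sc$truth, truth_f, scheme,
                                               0.8 * rms_sig, seeds[1]))
    f2 <- fft_map(cryodenmod:::add_shell_noise(sc$truth, truth_f, scheme,
                                               1.2 * rms_sig, seeds[2]))
    s1 <- cryodenmod:::halfmap_error_stats(f1, f2, scheme)  # overestimates each alone
    s1$sigma2_err <- (0.8 * rms_sig)^2
    s2 <- s1; s2$sigma2_err <- (1.2 * rms_sig)^2
    rec <- recombine(f1, f2, s1, s2, recomb_floor = 0)
    err <- function(f) mean(Mod(f$terms - truth_f$terms)[!is.na(scheme$index)]^2)
    err(rec) <= min(err(f1), err(f2)) + 1e-12
  })
  expect_gte(mean(better), 0.95)
})

test_that("density modification improves FSC to truth on weak shells", {
  sc <- default_scene(1)
  params <- default_params(sc)
  res <- density_modify(sc$half_a, sc$half_b, params)
  orig <- fsc_curve(half_average(sc), sc$truth, params$d_min, params$n_shells)
  dm <- fsc_curve(res$final, sc$truth, params$d_min, params$n_shells)
  expect_gte(mean_weak_shell_fsc(dm, reference = orig) -
               mean_weak_shell_fsc(orig), 0.05)
  # the line search never decreases the likelihood within a cycle
  expect_true(all(res$ll_log$ll_after >= res$ll_log$ll_before - 1e-6))
  # provenance records the inputs and parameters
  expect_equal(res$provenance$seed, params$seed)
  expect_match(res$provenance$input_checksums[["a"]], "^64x64x64")
})

test_that("degenerate inputs follow the documented paths", {
  sc <- flat_scene()
  params <- denmod_params(resolution = 4.5, d_min = 4, n_shells = 4,
                          n_cycles = 2,
                          fraction_macromolecule =
                            mean(sc$solvent_mask_true$values))
  # identical half-maps: warn and run prior-only modification
  expect_warning(res <- density_modify(sc$half_a, sc$half_b, params),
                 "identical")
  expect_s3_class(res, "denmodresult")

  # anti-correlated half-maps have FSC = -1 in every shell: abort
  set.seed(12)
  na <- with_values(sc$truth, array(stats::rnorm(16^3), c(16, 16, 16)))
  nb <- with_values(sc$truth, -na$values)
  expect_error(density_modify(na, nb, params), "no signal")
})

test_that("zero-noise scenes pass through density modification unharmed", {
  sc <- flat_scene()
  half_eps <- with_values(sc$half_b, sc$half_b$values *
                            (1 + 1e-9) + 1e-12)   # break exact identity only
  params <- denmod_params(resolution = 4.5, d_min = 4, n_shells = 4,
                          n_cycles = 2,
                          fraction_macromolecule =
                            mean(sc$solvent_mask_true$values))
  res <- density_modify(sc$half_a, half_eps, params)
  cc <- stats::cor(as.vector(res$final$values), as.vector(sc$truth$values))
  expect_gt(cc, 0.999)
})

test_that("blur and spectral scaling act on the final map as flagged", {
  sc <- default_scene(1)
  params <- default_params(sc)
  params$n_cycles <- 1
  res_plain <- density_modify(sc$half_a, sc$half_b, params)
  params$blur_by_resolution <- TRUE
  res_blur <- density_modify(sc$half_a, sc$half_b, params)
  fp <- fft_map(res_plain$final); fb <- fft_map(res_blur$final)
  s2 <- inv_d2_grid(fp)
  pick <- which(!is.na(res_plain$scheme$index) & Mod(fp$terms) > 1e-8)
  ratio <- Mod(fb$terms[pick]) / Mod(fp$terms[pick])
  expect_equal(ratio, exp(-blur_by_resolution_b(params$resolution) *
                            s2[pick] / 4), tolerance = 1e-6)

  params$blur_by_resolution <- FALSE
  params$spectral_scaling <- TRUE
  res_ss <- density_modify(sc$half_a, sc$half_b, params)
  prof <- default_spectral_profile(res_ss$scheme, params$resolution)
  got <- cryodenmod:::shell_rms(fft_map(res_ss$final), res_ss$scheme)
  k <- sum(got * prof) / sum(prof^2)
  expect_equal(got, k * prof, tolerance = 1e-6)
})

test_that("oracle equivalence: gradient and brute-force agree on the direction
           of change for corrupted terms", {
  sc <- flat_scene()
  prior <- flat_solvent_prior(sc)
  set.seed(42)
  hkls <- cbind(sample(1:3, 20, TRUE), sample(0:2, 20, TRUE),
                sample(0:2, 20, TRUE))
  agree <- vapply(seq_len(20), function(i) {
    hkl <- hkls[i, ]
    f0 <- get_fourier_term(fft_map(sc$truth), hkl)
    if (Mod(f0) < 1e-9) return(NA)
    fc <- fft_map(corrupt_fourier_term(sc$truth, hkl, 3))
    cur <- get_fourier_term(fc, hkl)
    g <- phase_single_term(fc, hkl, prior)
    b <- brute_force_single_term(fc, hkl, prior)
    Re(Conj(g - cur) * (b - cur)) > 0     # same direction of change
  }, logical(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.9)
})
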