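#' Parameters for density modification
#'
#' @param resolution Nominal resolution of the reconstruction in Angstrom
#'   (mandatory; sets smoothing radii and the blur-by-resolution B value).
#' @param d_min High-resolution limit of the analysis in Angstrom. Defaults to
#'   1 Angstrom finer than `resolution`, clamped at Nyquist when half-maps are
#'   supplied.
#' @param n_shells Number of resolution shells (default 20).
#' @param n_cycles Density-modification cycles (default 5).
#' @param fraction_macromolecule Expected macromolecule volume fraction for
#'   the solvent mask (default 0.25).
#' @param K Gaussian-mixture components of the macromolecule prior (default 3).
#' @param recomb_floor Minimum per-shell weight on the original terms during
#'   recombination, in `[0, 1]` (default 0.05).
#' @param blur_by_resolution Apply a final blur of B = 10 x resolution
#'   (default FALSE).
#' @param spectral_scaling Rescale the final map to the package's canonical
#'   amplitude profile (default FALSE).
#' @param seed Integer seed recorded in provenance.
#' @param stop_tol Relative log-likelihood change below which cycling stops
#'   early (default 1e-4).
#' @return A `denmodparams` list.
#' @export
denmod_params <- function(resolution, d_min = NULL, n_shells = 20,
                          n_cycles = 5, fraction_macromolecule = 0.25, K = 3,
                          recomb_floor = 0.05, blur_by_resolution = FALSE,
                          spectral_scaling = FALSE, seed = 1,
                          stop_tol = 1e-4) {
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (recomb_floor < 0 || recomb_floor > 1) stop("recomb_floor must be in [0, 1]")
  if (is.null(d_min)) d_min <- resolution - 1
  structure(list(resolution = resolution, d_min = d_min, n_shells = n_shells,
                 n_cycles = n_cycles,
                 fraction_macromolecule = fraction_macromolecule, K = K,
                 recomb_floor = recomb_floor,
                 blur_by_resolution = blur_by_resolution,
                 spectral_scaling = spectral_scaling, seed = seed,
                 stop_tol = stop_tol),
            class = "denmodparams")
}

# fast total-log-likelihood evaluator: precompute the branch partition once
ll_context <- function(prior, target, dims) {
  n <- prod(dims)
  in_target <- rep(FALSE, n)
  tv <- ts <- NULL
  if (!is.null(target)) {
    in_target <- as.vector(target$mask$values)
    tv <- as.vector(target$value$values)[in_target]
    ts <- pmax(as.vector(target$sigma$values)[in_target], prior$sigma_floor)
  }
  macro <- as.vector(prior$region_mask$values) & !in_target
  solv <- !as.vector(prior$region_mask$values) & !in_target
  # per-point branch variance, used to precondition the gradient direction:
  # target/solvent Gaussians use their sigma^2, the mixture its total variance
  comp <- prior$macro
  mix_mean <- sum(comp$weight * comp$mean)
  mix_var <- sum(comp$weight * (comp$sd^2 + comp$mean^2)) - mix_mean^2
  s_sd <- max(unname(prior$solvent["sd"]), prior$sigma_floor)
  var_eff <- numeric(n)
  if (any(in_target)) var_eff[in_target] <- ts^2
  var_eff[macro] <- max(mix_var, prior$sigma_floor^2)
  var_eff[solv] <- s_sd^2
  list(in_target = in_target, macro = macro, solv = solv, tv = tv, ts = ts,
       comp = comp,
       sigma_floor = prior$sigma_floor,
       s_mean = unname(prior$solvent["mean"]),
       s_sd = s_sd, var_eff = var_eff)
}

ll_total_ctx <- function(x, ctx) {
  total <- 0
  if (any(ctx$in_target))
    total <- total + sum(stats::dnorm(x[ctx$in_target], ctx$tv, ctx$ts, log = TRUE))
  if (any(ctx$macro)) {
    xm <- x[ctx$macro]
    dens <- 0
    for (k in seq_len(nrow(ctx$comp)))
      dens <- dens + ctx$comp$weight[k] *
        stats::dnorm(xm, ctx$comp$mean[k], max(ctx$comp$sd[k], ctx$sigma_floor))
    dens[dens <= 0] <- .Machine$double.xmin
    total <- total + sum(log(dens))
  }
  if (any(ctx$solv))
    total <- total + sum(stats::dnorm(x[ctx$solv], ctx$s_mean, ctx$s_sd, log = TRUE))
  total
}

#' One map-phasing step: move all Fourier terms up the likelihood gradient
#'
#' Preconditions the real-space likelihood gradient by the local branch
#' variance (a diagonal Newton scaling, so regions with very certain
#' expectations — e.g. a tight target sigma or near-flat solvent — do not
#' stall the step for everything else), transforms it to Fourier space,
#' zeroes it at the origin term (F000 is held fixed) and beyond the shell
#' scheme's resolution limit, and takes a step `F + alpha * FT[precond grad]`
#' with the scalar step length chosen by a line search that maximizes the
#' total log-likelihood along this direction. The step never decreases the
#' total log-likelihood; if the gradient is numerically zero the input is
#' returned and flagged as converged.
#'
#' @param f_cur `fouriermap` of the current map.
#' @param lf `likelihoodfield` evaluated at `ifft_map(f_cur)`.
#' @param scheme A `shellscheme`.
#' @param prior `densityprior` used to re-evaluate the likelihood during the
#'   line search.
#' @param target Optional `targetmap` (must match what produced `lf`).
#' @return A `fouriermap` with attributes `alpha`, `ll_before`, `ll_after`,
#'   `converged`.
#' @export
map_phase_step <- function(f_cur, lf, scheme, prior, target = NULL) {
  g <- lf$grad$values
  dims <- dim(g)
  n <- length(g)
  if (max(abs(g)) == 0) {
    attr(f_cur, "converged") <- TRUE
    attr(f_cur, "alpha") <- 0
    attr(f_cur, "ll_before") <- lf$total
    attr(f_cur, "ll_after") <- lf$total
    return(f_cur)
  }
  ctx <- ll_context(prior, target, dims)
  G <- stats::fft(array(as.vector(g) * ctx$var_eff, dims))
  G[is.na(scheme$index)] <- 0 + 0i          # band limit; F000 fixed
  dmap <- Re(stats::fft(G, inverse = TRUE)) / n
  m0 <- as.vector(ifft_map(f_cur)$values)
  d <- as.vector(dmap)
  sd_d <- stats::sd(d)
  if (sd_d == 0 || !is.finite(sd_d)) {
    attr(f_cur, "converged") <- TRUE
    attr(f_cur, "alpha") <- 0
    attr(f_cur, "ll_before") <- lf$total
    attr(f_cur, "ll_after") <- lf$total
    return(f_cur)
  }
  # the preconditioned step is dimensionless: beta ~ 1 is the Newton scale
  beta_hi <- 4
  obj <- function(b) ll_total_ctx(m0 + b * d, ctx)
  opt <- stats::optimize(obj, c(0, beta_hi), maximum = TRUE, tol = 1e-7 * beta_hi)
  ll0 <- ll_total_ctx(m0, ctx)
  beta <- if (opt$objective > ll0) opt$maximum else 0
  ll1 <- max(opt$objective, ll0)
  out <- f_cur
  out$terms <- f_cur$terms + beta * G
  attr(out, "alpha") <- beta
  attr(out, "ll_before") <- ll0
  attr(out, "ll_after") <- ll1
  attr(out, "converged") <- beta == 0
  out
}

# phase factor exp(+2 pi i hkl . x / n) over the grid, as a complex array
phase_wave <- function(dims, hkl) {
  ex <- exp(2i * pi * hkl[1] * (seq_len(dims[1]) - 1) / dims[1])
  ey <- exp(2i * pi * hkl[2] * (seq_len(dims[2]) - 1) / dims[2])
  ez <- exp(2i * pi * hkl[3] * (seq_len(dims[3]) - 1) / dims[3])
  outer(outer(ex, ey), ez)
}

#' Map-phasing estimate of a single Fourier term (all others fixed)
#'
#' The literal one-term definition of map phasing: with every other term
#' frozen, finds the complex value of the term at `hkl` that maximizes the
#' total log-likelihood of the map, by iterated gradient ascent with an exact
#' line search in the complex plane of that one coefficient. The Hermitian
#' mate at `-hkl` moves conjugately.
#'
#' @param f_cur `fouriermap`.
#' @param hkl Signed integer indices (must not be a self-conjugate term).
#' @param prior A `densityprior`.
#' @param target Optional `targetmap`.
#' @param max_iter,tol Iteration cap and relative convergence tolerance.
#' @return Complex: the optimized coefficient for `hkl`, with attribute
#'   `ll` (the total log-likelihood at the optimum).
#' @export
phase_single_term <- function(f_cur, hkl, prior, target = NULL,
                              max_iter = 60, tol = 1e-8) {
  dims <- dim(f_cur$terms)
  if (all(hkl_to_pos(hkl, dims) == hkl_to_pos(-hkl, dims)))
    stop("self-conjugate term: not supported")
  E <- phase_wave(dims, hkl)
  ReE <- as.vector(Re(E)); ImE <- as.vector(Im(E))
  n <- prod(dims)
  rho0 <- as.vector(ifft_map(f_cur)$values)
  ctx <- ll_context(prior, target, dims)
  ll_at <- function(delta)
    ll_total_ctx(rho0 + (2 / n) * (Re(delta) * ReE - Im(delta) * ImE), ctx)
  grad_at <- function(delta) {
    x <- rho0 + (2 / n) * (Re(delta) * ReE - Im(delta) * ImE)
    g <- grad_ctx(x, ctx)
    complex(real = sum(g * ReE), imaginary = -sum(g * ImE)) * (2 / n)
  }
  f0 <- get_fourier_term(f_cur, hkl)
  delta <- 0 + 0i
  ll_cur <- ll_at(delta)
  scale0 <- max(Mod(f0), sqrt(mean(Mod(f_cur$terms)^2)))
  for (iter in seq_len(max_iter)) {
    gam <- grad_at(delta)
    if (Mod(gam) == 0) break
    dirn <- gam / Mod(gam)
    obj <- function(t) ll_at(delta + t * dirn)
    t_hi <- 4 * scale0
    opt <- stats::optimize(obj, c(0, t_hi), maximum = TRUE, tol = 1e-9 * t_hi)
    if (opt$objective <= ll_cur) break
    delta <- delta + opt$maximum * dirn
    improved <- opt$objective - ll_cur
    ll_cur <- opt$objective
    if (improved < tol * (abs(ll_cur) + 1)) break
  }
  out <- f0 + delta
  attr(out, "ll") <- ll_cur
  out
}

# pointwise gradient of the log-likelihood (same branches as evaluate_likelihood)
grad_ctx <- function(x, ctx) {
  g <- numeric(length(x))
  if (any(ctx$in_target)) {
    xm <- x[ctx$in_target]
    g[ctx$in_target] <- (ctx$tv - xm) / ctx$ts^2
  }
  if (any(ctx$macro)) {
    xm <- x[ctx$macro]
    dens <- matrix(0, length(xm), nrow(ctx$comp))
    for (k in seq_len(nrow(ctx$comp)))
      dens[, k] <- ctx$comp$weight[k] *
        stats::dnorm(xm, ctx$comp$mean[k], max(ctx$comp$sd[k], ctx$sigma_floor))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    num <- numeric(length(xm))
    for (k in seq_len(nrow(ctx$comp))) {
      sk <- max(ctx$comp$sd[k], ctx$sigma_floor)
      num <- num + dens[, k] * (ctx$comp$mean[k] - xm) / sk^2
    }
    g[ctx$macro] <- num / tot
  }
  if (any(ctx$solv)) {
    xs <- x[ctx$solv]
    g[ctx$solv] <- (ctx$s_mean - xs) / ctx$s_sd^2
  }
  g
}

#' Brute-force single-term search (oracle)
#'
#' Exhaustive nested search over amplitude and phase of one Fourier term (all
#' others fixed) for the value maximizing the total log-likelihood. Intended
#' for small grids (<= 16^3) as an independent check of the gradient-based
#' map-phasing path. If the optimum lands on the amplitude boundary the
#' bounds are widened once and the search repeated; a second boundary hit is
#' an error. If the likelihood is flat in this term, the input value is
#' returned (tie rule: keep the original).
#'
#' @param f_cur `fouriermap` (small grids only).
#' @param hkl Signed integer indices.
#' @param prior A `densityprior`.
#' @param target Optional `targetmap`.
#' @param n_amp,n_phase Coarse grid resolution.
#' @param n_refine Number of local refinement passes.
#' @return Complex coefficient at the likelihood maximum.
#' @export
brute_force_single_term <- function(f_cur, hkl, prior, target = NULL,
                                    n_amp = 16, n_phase = 24, n_refine = 4) {
  dims <- dim(f_cur$terms)
  if (prod(dims) > 16^3 * 8) stop("brute-force search is restricted to small grids")
  E <- phase_wave(dims, hkl)
  ReE <- as.vector(Re(E)); ImE <- as.vector(Im(E))
  n <- prod(dims)
  rho0 <- as.vector(ifft_map(f_cur)$values)
  ctx <- ll_context(prior, target, dims)
  f0 <- get_fourier_term(f_cur, hkl)
  ll_of <- function(val) {
    delta <- val - f0
    ll_total_ctx(rho0 + (2 / n) * (Re(delta) * ReE - Im(delta) * ImE), ctx)
  }
  a_max <- 2.5 * max(Mod(f0), sqrt(mean(Mod(f_cur$terms)^2)))
  for (attempt in 1:2) {
    amps <- seq(0, a_max, length.out = n_amp)
    phis <- seq(0, 2 * pi, length.out = n_phase + 1)[-(n_phase + 1)]
    cand <- as.vector(outer(amps, exp(1i * phis)))
    lls <- vapply(cand, ll_of, numeric(1))
    if (max(lls) - min(lls) < 1e-9 * (abs(max(lls)) + 1)) {
      out <- f0
      attr(out, "flat") <- TRUE
      return(out)
    }
    best <- cand[which.max(lls)]
    on_boundary <- Mod(best) >= a_max - 1e-12
    if (!on_boundary) break
    if (attempt == 2) stop("optimum at widened search boundary")
    a_max <- 2 * a_max
  }
  # local refinement on a shrinking rectangular grid in the complex plane
  half <- a_max / n_amp
  for (pass in seq_len(n_refine)) {
    re <- Re(best) + seq(-half, half, length.out = 7)
    im <- Im(best) + seq(-half, half, length.out = 7)
    cand <- as.vector(outer(re, 1i * im, "+"))
    lls <- vapply(cand, ll_of, numeric(1))
    best <- cand[which.max(lls)]
    half <- half / 3
  }
  best
}

# empirical per-shell error variance of one map of a pair, from the half
# squared difference of the pair (signal cancels; errors are independent)
halfmap_error_stats <- function(f_a, f_b, scheme) {
  idx <- as.vector(scheme$index)
  keep <- !is.na(idx)
  d2 <- Mod(as.vector(f_a$terms) - as.vector(f_b$terms))[keep]^2
  n <- tabulate(idx[keep], nbins = scheme$n_shells)
  s2 <- rowsum_by(d2, idx[keep], scheme$n_shells) / pmax(n, 1) / 2
  out <- tibble::tibble(shell = seq_len(scheme$n_shells), n_terms = n,
                        sigma2_err = s2)
  attr(out, "scheme") <- scheme
  out
}

# per-shell mean squared difference of two Fourier maps (no halving)
shell_msd <- function(f_x, f_y, scheme) {
  idx <- as.vector(scheme$index)
  keep <- !is.na(idx)
  d2 <- Mod(as.vector(f_x$terms) - as.vector(f_y$terms))[keep]^2
  n <- tabulate(idx[keep], nbins = scheme$n_shells)
  rowsum_by(d2, idx[keep], scheme$n_shells) / pmax(n, 1)
}

# Error variance of the map-phasing estimates, scored cross-half: the
# map-phasing map of one half is compared against the ORIGINAL Fourier terms
# of the other half, whose errors are independent of it. This captures the
# shared bias the prior induces in both map-phasing maps, which cancels in
# their mutual difference and would otherwise make the recombination weights
# overconfident.
mp_error_stats <- function(f_mp_a, f_mp_b, f_orig_a, f_orig_b, stats_orig,
                           scheme) {
  v_a <- shell_msd(f_mp_a, f_orig_b, scheme) - stats_orig$sigma2_err
  v_b <- shell_msd(f_mp_b, f_orig_a, scheme) - stats_orig$sigma2_err
  s2 <- pmax((v_a + v_b) / 2, 1e-6 * stats_orig$sigma2_err)
  out <- tibble::tibble(shell = seq_len(scheme$n_shells),
                        n_terms = stats_orig$n_terms, sigma2_err = s2)
  attr(out, "scheme") <- scheme
  out
}

#' Recombine original and map-phasing Fourier terms
#'
#' Per-shell inverse-variance weighted average of the original and
#' map-phasing estimates. The weight on the originals never falls below
#' `recomb_floor`; shells where both variances are zero keep the original.
#' Terms beyond the shell scheme's resolution limit keep the original value.
#'
#' @param f_orig,f_mp Aligned `fouriermap`s.
#' @param stats_orig,stats_mp Tables carrying per-shell `sigma2_err` for each
#'   source (a `shellstats` or the output of the half-map difference
#'   estimator); `stats_orig` must carry the shell scheme.
#' @param recomb_floor Minimum weight on the originals (default 0.05).
#' @return A `fouriermap` with attribute `w_orig` (per-shell weights).
#' @export
recombine <- function(f_orig, f_mp, stats_orig, stats_mp, recomb_floor = 0.05) {
  stop_if_misaligned(f_orig, f_mp, "Fourier maps")
  scheme <- attr(stats_orig, "scheme")
  if (is.null(scheme)) stop("stats_orig must carry a shell scheme")
  s2o <- stats_orig$sigma2_err
  s2m <- stats_mp$sigma2_err
  w <- ifelse(s2o + s2m > 0, s2m / (s2o + s2m), 1)
  w <- pmin(pmax(w, recomb_floor), 1)
  warr <- array(1, dim(f_orig$terms))
  ok <- !is.na(scheme$index)
  warr[ok] <- w[scheme$index[ok]]
  out <- f_orig
  out$terms <- warr * f_orig$terms + (1 - warr) * f_mp$terms
  attr(out, "w_orig") <- w
  out
}

#' Maximum-likelihood density modification of two half-maps
#'
#' The full two-step pipeline: average the half-maps, derive the solvent mask
#' and density prior, estimate per-shell error variances from the half-map
#' differences, then for each half-map independently iterate (evaluate
#' likelihood, map-phasing gradient step, recombine with the original terms
#' using inverse-variance shell weights). The two density-modified half-maps
#' are averaged into the final map, optionally blurred by B = 10 x resolution
#' and/or rescaled to the canonical amplitude profile.
#'
#' Identical half-maps carry no error information: a warning is issued and a
#' prior-only modification (no recombination) is run. Half-maps whose FSC is
#' non-positive in every shell are rejected.
#'
#' @param half_a,half_b Aligned `mapgrid` half-maps.
#' @param params A `denmodparams`.
#' @param target Optional model-based target: a single `targetmap` used for
#'   both halves, or `list(a = , b = )` with one per half (preserving
#'   half-map independence).
#' @return A `denmodresult`: list with `final` (`mapgrid`), `dm_half_a`,
#'   `dm_half_b`, `cycle_stats` (per-cycle shell tables), `ll_log` (tibble of
#'   per-cycle line-search log-likelihoods), `stats_half` (input shell
#'   statistics), `prior`, `mask`, `params`, `provenance`.
#' @export
density_modify <- function(half_a, half_b, params, target = NULL) {
  stopifnot(inherits(params, "denmodparams"))
  stop_if_misaligned(half_a, half_b, "half-maps")
  d_min <- max(params$d_min, 2 * max(half_a$voxel) * 1.0000001)
  fa <- fft_map(half_a); fb <- fft_map(half_b)
  scheme <- make_shells(fa, d_min, params$n_shells)
  stats_half <- shell_stats(fa, fb, scheme)
  prior_only <- max(abs(half_a$values - half_b$values)) == 0
  if (prior_only) {
    warning("half-maps are identical: no error estimate; running prior-only modification")
  } else if (all(stats_half$fsc <= 0)) {
    stop("FSC non-positive in every shell: no signal to modify")
  }
  avg <- with_values(half_a, (half_a$values + half_b$values) / 2)
  mask <- solvent_mask(avg, params$fraction_macromolecule, params$resolution)
  prior <- fit_density_prior(avg, mask, params$K)
  t_a <- if (is.null(target)) NULL else if (inherits(target, "targetmap"))
    target else target$a
  t_b <- if (is.null(target)) NULL else if (inherits(target, "targetmap"))
    target else target$b
  stats_orig <- halfmap_error_stats(fa, fb, scheme)
  f_cur <- list(a = fa, b = fb)
  f_origs <- list(a = fa, b = fb)
  targets <- list(a = t_a, b = t_b)
  ll_log <- NULL
  cycle_stats <- vector("list", params$n_cycles)
  last_ll <- c(a = NA_real_, b = NA_real_)
  for (cyc in seq_len(params$n_cycles)) {
    f_mp <- list()
    for (h in c("a", "b")) {
      m <- ifft_map(f_cur[[h]], tol = 1e-6)
      lf <- evaluate_likelihood(m, prior, targets[[h]])
      stepped <- map_phase_step(f_cur[[h]], lf, scheme, prior, targets[[h]])
      f_mp[[h]] <- stepped
      ll_log <- rbind(ll_log, data.frame(
        cycle = cyc, half = h, ll_before = attr(stepped, "ll_before"),
        ll_after = attr(stepped, "ll_after"), alpha = attr(stepped, "alpha")))
    }
    stats_mp <- mp_error_stats(f_mp$a, f_mp$b, fa, fb, stats_orig, scheme)
    if (prior_only) {
      f_cur <- f_mp
    } else {
      for (h in c("a", "b"))
        f_cur[[h]] <- recombine(f_origs[[h]], f_mp[[h]], stats_orig, stats_mp,
                                params$recomb_floor)
    }
    cs <- shell_stats(f_cur$a, f_cur$b, scheme)
    cs$sigma2_mp <- stats_mp$sigma2_err
    cycle_stats[[cyc]] <- cs
    ll_now <- c(a = attr(f_mp$a, "ll_after"), b = attr(f_mp$b, "ll_after"))
    if (cyc > 1 && all(abs(ll_now - last_ll) <=
                       params$stop_tol * (abs(last_ll) + 1))) {
      cycle_stats <- cycle_stats[seq_len(cyc)]
      last_ll <- ll_now
      break
    }
    last_ll <- ll_now
  }
  f_final <- fa
  f_final$terms <- (f_cur$a$terms + f_cur$b$terms) / 2
  if (params$blur_by_resolution)
    f_final <- apply_b_factor(f_final, blur_by_resolution_b(params$resolution))
  if (params$spectral_scaling)
    f_final <- spectral_scale(f_final, scheme,
                              default_spectral_profile(scheme, params$resolution))
  final <- ifft_map(f_final, tol = 1e-6)
  structure(list(final = final,
                 dm_half_a = ifft_map(f_cur$a, tol = 1e-6),
                 dm_half_b = ifft_map(f_cur$b, tol = 1e-6),
                 cycle_stats = cycle_stats,
                 ll_log = tibble::as_tibble(ll_log),
                 stats_half = stats_half, prior = prior, mask = mask,
                 params = params, scheme = scheme,
                 provenance = list(
                   params = unclass(params), seed = params$seed,
                   input_checksums = c(a = map_checksum(half_a),
                                       b = map_checksum(half_b)),
                   package_version = as.character(utils::packageVersion("cryodenmod")))),
            class = "denmodresult")
}

map_checksum <- function(m) {
  sprintf("%dx%dx%d:%.10e:%.10e", map_dims(m)[1], map_dims(m)[2],
          map_dims(m)[3], mean(m$values), stats::sd(as.vector(m$values)))
}

#' @export
print.denmodresult <- function(x, ...) {
  cat(sprintf("<denmodresult> %d cycle(s); final map %s\n",
              length(x$cycle_stats),
              paste(map_dims(x$final), collapse = "x")))
  cat(sprintf("  input FSC(half) range: %.3f .. %.3f\n",
              min(x$stats_half$fsc), max(x$stats_half$fsc)))
  invisible(x)
}

#' Canonical amplitude profile for spectral scaling
#'
#' A smooth, resolution-relative target r.m.s. profile (shipped as a table in
#' `inst/extdata/spectral_profile.csv`, interpolated at the shell centres):
#' the amplitude spectrum decays smoothly with (resolution/d)^2 toward a
#' small high-frequency floor.
#'
#' @param scheme A `shellscheme`.
#' @param resolution Nominal resolution in Angstrom.
#' @return Numeric vector, one relative r.m.s. per shell.
#' @export
default_spectral_profile <- function(scheme, resolution) {
  path <- system.file("extdata", "spectral_profile.csv", package = "cryodenmod")
  tab <- utils::read.csv(path)
  mids <- (scheme$edges[-1] + scheme$edges[-length(scheme$edges)]) / 2
  x <- mids * resolution^2                 # (resolution / d)^2, dimensionless
  stats::approx(tab$x, tab$rel_rms, xout = pmin(pmax(x, min(tab$x)), max(tab$x)))$y
}

#' Fourier shell correlation curve between two maps
#'
#' Convenience wrapper: transforms both maps and computes shell statistics.
#'
#' @param map_a,map_b Aligned `mapgrid`s.
#' @param d_min Resolution limit in Angstrom.
#' @param n_shells Number of shells.
#' @return A `shellstats` tibble.
#' @export
fsc_curve <- function(map_a, map_b, d_min, n_shells = 20) {
  fa <- fft_map(map_a)
  shell_stats(fa, fft_map(map_b), make_shells(fa, d_min, n_shells))
}

#' Mean FSC over the shells where a reference curve is weak
#'
#' Helper for before/after comparisons: averages `fsc` over the shells where
#' the reference curve falls below `cutoff` (default 0.5) — the resolution
#' range where improvement is possible.
#'
#' @param stats A `shellstats`.
#' @param reference A `shellstats` on the same scheme supplying the weak-shell
#'   selection (defaults to `stats` itself).
#' @param cutoff FSC cutoff defining "weak" (default 0.5).
#' @return Numeric scalar (NA if no shell qualifies).
#' @export
mean_weak_shell_fsc <- function(stats, reference = stats, cutoff = 0.5) {
  weak <- reference$fsc < cutoff
  if (!any(weak)) return(NA_real_)
  mean(stats$fsc[weak])
}
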