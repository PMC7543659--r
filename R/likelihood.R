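#' Gaussian smoothing of a map
#'
#' Convolves the map with an isotropic Gaussian kernel of real-space standard
#' deviation `radius / 2` (so ~95% of the kernel mass lies within `radius`),
#' implemented as multiplication in Fourier space. Used for local-variance
#' masks and for smoothing uncertainty maps.
#'
#' @param m A `mapgrid`.
#' @param radius Smoothing radius in Angstrom.
#' @return A `mapgrid`.
#' @export
smooth_map <- function(m, radius) {
  if (radius <= 0) return(m)
  f <- fft_map(m)
  s2 <- inv_d2_grid(f)
  sigma <- radius / 2
  f$terms <- f$terms * exp(-2 * pi^2 * sigma^2 * s2)
  ifft_map(f, tol = 1e-6)
}

#' Estimate a macromolecule mask from smoothed local variance
#'
#' Marks the stated fraction of grid points having the highest smoothed local
#' variance of the (half-map-averaged) map; the macromolecule region varies on
#' the scale of the resolution while flat solvent does not. Smoothing radius
#' equals the resolution. Connectedness is not enforced.
#'
#' @param m_avg `mapgrid`, typically the average of the two half-maps.
#' @param fraction_macromolecule Fraction of the box expected to be
#'   macromolecule, in (0, 1).
#' @param resolution Nominal resolution in Angstrom (sets the smoothing
#'   radius).
#' @return A logical `mapgrid` (TRUE = macromolecule).
#' @export
solvent_mask <- function(m_avg, fraction_macromolecule, resolution) {
  if (fraction_macromolecule <= 0 || fraction_macromolecule >= 1)
    stop("fraction_macromolecule must lie in (0, 1)")
  if (stats::sd(as.vector(m_avg$values)) == 0)
    stop("map is constant: no density contrast to build a mask from")
  mu <- smooth_map(m_avg, resolution)
  m2 <- smooth_map(with_values(m_avg, m_avg$values^2), resolution)
  locvar <- pmax(m2$values - mu$values^2, 0)
  cut <- stats::quantile(locvar, probs = 1 - fraction_macromolecule,
                         names = FALSE, type = 1)
  with_values(m_avg, array(locvar >= cut, dim(locvar)))
}

#' Fit the density prior: flat solvent plus Gaussian-mixture macromolecule
#'
#' The solvent component is the (mean, SD) of values outside the mask. The
#' macromolecule component is a K-component 1-D Gaussian mixture fit to the
#' values inside the mask by expectation-maximization, initialized with
#' quantile-spread means, equal weights and a common SD. SDs are floored at
#' `1e-6` times the overall map SD.
#'
#' @param m_avg `mapgrid`, the average of the two half-maps.
#' @param mask Logical `mapgrid`, TRUE where the macromolecule is.
#' @param K Number of mixture components (default 3).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return A `densityprior`: list with `solvent` (mean, sd), `macro` tibble
#'   (weight, mean, sd), `region_mask`, `sigma_floor`, `em_converged`.
#' @export
fit_density_prior <- function(m_avg, mask, K = 3, max_iter = 1000, tol = 1e-6) {
  stop_if_misaligned(m_avg, mask, "map and mask")
  inside <- as.logical(mask$values)
  if (!any(inside) || all(inside)) stop("mask must be neither empty nor full")
  floor_sd <- 1e-6 * max(stats::sd(as.vector(m_avg$values)), .Machine$double.eps)
  sv <- as.vector(m_avg$values)[!inside]
  solvent <- c(mean = mean(sv), sd = max(stats::sd(sv), floor_sd))
  x <- as.vector(m_avg$values)[inside]
  fit <- fit_gmm_1d(x, K, max_iter, tol, floor_sd)
  structure(list(solvent = solvent, macro = fit$components,
                 region_mask = mask, sigma_floor = floor_sd,
                 em_converged = fit$converged, em_loglik = fit$loglik),
            class = "densityprior")
}

# 1-D Gaussian mixture by EM. Deterministic init: means at the (k)/(K+1)
# quantiles, equal weights, common sigma = sd(x).
fit_gmm_1d <- function(x, K, max_iter, tol, floor_sd) {
  n <- length(x)
  mu <- as.numeric(stats::quantile(x, probs = seq_len(K) / (K + 1), names = FALSE))
  sigma <- rep(max(stats::sd(x), floor_sd), K)
  wt <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      wt[k] * stats::dnorm(x, mu[k], sigma[k]), numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk <= 0] <- .Machine$double.eps
    wt <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- pmax(sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk), floor_sd)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("mixture EM did not converge; returning best fit")
  list(components = tibble::tibble(weight = wt, mean = mu, sd = sigma),
       converged = converged, loglik = ll)
}

#' @export
print.densityprior <- function(x, ...) {
  cat(sprintf("<densityprior> solvent: mean %.4g sd %.4g; %d-component macromolecule mixture\n",
              x$solvent["mean"], x$solvent["sd"], nrow(x$macro)))
  invisible(x)
}

#' Serialize prior parameters to a JSON string
#' @param prior A `densityprior`.
#' @return JSON character scalar (solvent and mixture parameters only).
#' @export
prior_to_json <- function(prior) {
  jsonlite::toJSON(list(solvent = as.list(prior$solvent),
                        macro = as.data.frame(prior$macro),
                        sigma_floor = prior$sigma_floor),
                   auto_unbox = TRUE, digits = NA)
}

#' Real-space log-likelihood of a map and its gradient
#'
#' Evaluates, at every grid point, the log-likelihood of the current density
#' and its derivative with respect to that density. Points inside the target
#' mask (when a target is given) use a Gaussian with the target value and
#' local sigma; macromolecule points outside it use the mixture prior; solvent
#' points use the solvent Gaussian. The total is the sum over all points.
#'
#' @param m `mapgrid` of current density.
#' @param prior A `densityprior`.
#' @param target Optional `targetmap` (see [ensemble_density()]); `NULL` for
#'   density modification without a model.
#' @return A `likelihoodfield`: list with `ll` (`mapgrid`), `grad`
#'   (`mapgrid`), `total` (scalar).
#' @export
evaluate_likelihood <- function(m, prior, target = NULL) {
  stop_if_misaligned(m, prior$region_mask, "map and prior mask")
  x <- as.vector(m$values)
  n <- length(x)
  ll <- numeric(n)
  grad <- numeric(n)
  in_target <- rep(FALSE, n)
  if (!is.null(target)) {
    stop_if_misaligned(m, target$value, "map and target")
    in_target <- as.vector(target$mask$values)
    if (any(in_target)) {
      tv <- as.vector(target$value$values)[in_target]
      ts <- pmax(as.vector(target$sigma$values)[in_target], prior$sigma_floor)
      xm <- x[in_target]
      ll[in_target] <- stats::dnorm(xm, tv, ts, log = TRUE)
      grad[in_target] <- (tv - xm) / ts^2
    }
  }
  macro <- as.vector(prior$region_mask$values) & !in_target
  solv <- !as.vector(prior$region_mask$values) & !in_target
  if (any(macro)) {
    comp <- prior$macro
    xm <- x[macro]
    dens <- matrix(0, length(xm), nrow(comp))
    for (k in seq_len(nrow(comp)))
      dens[, k] <- comp$weight[k] * stats::dnorm(xm, comp$mean[k],
                                                 max(comp$sd[k], prior$sigma_floor))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll[macro] <- log(tot)
    num <- numeric(length(xm))
    for (k in seq_len(nrow(comp))) {
      sk <- max(comp$sd[k], prior$sigma_floor)
      num <- num + dens[, k] * (comp$mean[k] - xm) / sk^2
    }
    grad[macro] <- num / tot
  }
  if (any(solv)) {
    ssd <- max(prior$solvent["sd"], prior$sigma_floor)
    xs <- x[solv]
    ll[solv] <- stats::dnorm(xs, prior$solvent["mean"], ssd, log = TRUE)
    grad[solv] <- (prior$solvent["mean"] - xs) / ssd^2
  }
  structure(list(ll = with_values(m, array(ll, dim(m$values))),
                 grad = with_values(m, array(grad, dim(m$values))),
                 total = sum(ll)),
            class = "likelihoodfield")
}
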