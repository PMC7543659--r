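#' Fourier transform of a map
#'
#' Computes the discrete Fourier transform of a `mapgrid`. Terms are stored on
#' the full complex grid with the Hermitian symmetry implied by a real map; the
#' term at index (0,0,0) equals the sum of map values (the F000 term). The
#' convention is `rho(x) = (1/N) * sum_h F(h) exp(+2 pi i h.x / n)`.
#'
#' @param m A `mapgrid`.
#' @return A `fouriermap` with fields `terms` (complex array), `voxel`, `origin`.
#' @export
fft_map <- function(m) {
  stopifnot(inherits(m, "mapgrid"))
  structure(list(terms = stats::fft(m$values), voxel = m$voxel, origin = m$origin),
            class = "fouriermap")
}

#' Inverse Fourier transform back to a map
#'
#' @param f A `fouriermap`. Must be Hermitian (its inverse transform real to
#'   numerical tolerance), otherwise an error is raised.
#' @param tol Relative tolerance on the residual imaginary part.
#' @return A `mapgrid`.
#' @export
ifft_map <- function(f, tol = 1e-8) {
  stopifnot(inherits(f, "fouriermap"))
  # Hermitian symmetry checked directly on the coefficients (robust even for
  # maps that are pure rounding noise, where the inverse transform's real and
  # imaginary parts are the same magnitude)
  d <- dim(f$terms)
  refl <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))
  mate <- Conj(f$terms[refl(d[1]), refl(d[2]), refl(d[3])])
  scale <- max(Mod(f$terms), .Machine$double.eps)
  if (max(Mod(f$terms - mate)) > tol * scale)
    stop("Fourier terms are not Hermitian: inverse transform is not real")
  v <- stats::fft(f$terms, inverse = TRUE) / length(f$terms)
  map_grid(array(Re(v), dim(f$terms)), f$voxel, f$origin)
}

#' @export
print.fouriermap <- function(x, ...) {
  d <- dim(x$terms)
  cat(sprintf("<fouriermap> %d x %d x %d terms, voxel %.4g x %.4g x %.4g A\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

# Signed integer frequency index along one axis (0, 1, ..., floor(n/2), -(n-1-floor(n/2)), ..., -1
# reinterpreted so that k = n/2 maps to +n/2 for even n).
signed_index <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k > n / 2, k - n, k)
}

#' Inverse-squared resolution of every Fourier term
#'
#' Returns `1/d^2` (Angstrom^-2) per term; 0 at the origin term (whose d is
#' undefined/infinite).
#'
#' @param f A `fouriermap`.
#' @return Numeric array aligned with `f$terms`.
#' @export
inv_d2_grid <- function(f) {
  d <- dim(f$terms)
  sx <- (signed_index(d[1]) / (d[1] * f$voxel[1]))^2
  sy <- (signed_index(d[2]) / (d[2] * f$voxel[2]))^2
  sz <- (signed_index(d[3]) / (d[3] * f$voxel[3]))^2
  outer(outer(sx, sy, "+"), sz, "+")
}

#' Resolution d (Angstrom) of every Fourier term
#' @param f A `fouriermap`.
#' @return Numeric array; `Inf` at the origin term.
#' @export
dspacing_grid <- function(f) {
  s2 <- inv_d2_grid(f)
  out <- 1 / sqrt(s2)
  out[s2 == 0] <- Inf
  out
}

#' Partition Fourier terms into resolution shells
#'
#' Shells are equal-width bins in `1/d^2` from 0 to `1/d_min^2`. Every
#' non-origin term with `d >= d_min` is assigned to exactly one shell; a term
#' falling exactly on an interior edge goes to the higher-resolution shell.
#' Empty shells are merged with their lower-resolution neighbour (with a
#' warning).
#'
#' @param f A `fouriermap`.
#' @param d_min High-resolution limit in Angstrom; must be at least twice the
#'   largest voxel edge (Nyquist).
#' @param n_shells Number of shells requested.
#' @return A `shellscheme`: list with `edges` (length `n_shells`+1 vector in
#'   Angstrom^-2), `n_shells`, `d_min`, and `index` (integer array aligned with
#'   the terms; `NA` for the origin term and terms beyond `d_min`).
#' @export
make_shells <- function(f, d_min, n_shells) {
  stopifnot(inherits(f, "fouriermap"))
  if (n_shells < 1) stop("n_shells must be at least 1")
  if (d_min < 2 * max(f$voxel))
    stop(sprintf("d_min (%.3g A) is below the Nyquist limit (%.3g A)",
                 d_min, 2 * max(f$voxel)))
  s2 <- inv_d2_grid(f)
  smax2 <- 1 / d_min^2
  edges <- seq(0, smax2, length.out = n_shells + 1)
  width <- smax2 / n_shells
  idx <- floor(s2 / width) + 1L          # ties at interior edges go up
  idx[idx > n_shells & s2 <= smax2 * (1 + 1e-12)] <- n_shells
  idx[s2 == 0 | s2 > smax2 * (1 + 1e-12)] <- NA_integer_
  # merge empty shells downward
  counts <- tabulate(idx[!is.na(idx)], nbins = n_shells)
  if (any(counts == 0)) {
    warning("empty resolution shell(s) merged with neighbour")
    keep <- which(counts > 0)
    remap <- cumsum(counts > 0)          # empty shell joins the shell below it
    remap[remap == 0] <- 1L
    idx[!is.na(idx)] <- remap[idx[!is.na(idx)]]
    edges <- c(0, edges[-1][keep])
    n_shells <- length(keep)
  }
  structure(list(edges = edges, n_shells = n_shells, d_min = d_min,
                 index = array(as.integer(idx), dim(f$terms))),
            class = "shellscheme")
}

#' @export
print.shellscheme <- function(x, ...) {
  cat(sprintf("<shellscheme> %d shells to d_min = %.3g A\n", x$n_shells, x$d_min))
  invisible(x)
}

# Project coefficients onto exact Hermitian symmetry (numerical hygiene for
# derived term arrays whose magnitude is comparable to FFT rounding noise).
hermitian_symmetrize <- function(terms) {
  d <- dim(terms)
  refl <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))
  (terms + Conj(terms[refl(d[1]), refl(d[2]), refl(d[3])])) / 2
}

# d range (A) of each shell as a two-column matrix (d_max = low-res edge).
shell_d_limits <- function(s) {
  lo <- s$edges[-length(s$edges)]
  hi <- s$edges[-1]
  cbind(d_max = ifelse(lo == 0, Inf, 1 / sqrt(lo)), d_min = 1 / sqrt(hi))
}

#' Per-shell FSC, amplitudes, weights and error variances for two maps
#'
#' For each resolution shell, computes the Fourier shell correlation
#' `fsc = Re sum(F_low conj(F_high)) / (rms_low rms_high n)`, the r.m.s.
#' amplitudes of each map, the expected-value weight `w = fsc * rms_low /
#' rms_high` that scales a term of the second map to its expected value given
#' the first, and the per-term residual error variance `sigma2_err =
#' rms_low^2 (1 - fsc^2)` implied by the complex-normal error model.
#'
#' @param f_low,f_high Aligned `fouriermap`s (by convention, the noisier map
#'   first; the second is treated as the truth proxy when forming `w`).
#' @param scheme A `shellscheme` from [make_shells()].
#' @return A `shellstats` tibble with columns `shell`, `d_max`, `d_min`,
#'   `n_terms`, `fsc`, `rms_low`, `rms_high`, `w`, `sigma2_err`, and a logical
#'   `w_defined` flag (FALSE where `rms_high` is zero).
#' @export
shell_stats <- function(f_low, f_high, scheme) {
  stop_if_misaligned(f_low, f_high, "Fourier maps")
  if (!identical(dim(scheme$index), dim(f_low$terms)))
    stop("shell scheme does not match the Fourier grid")
  idx <- as.vector(scheme$index)
  keep <- !is.na(idx)
  idx <- idx[keep]
  fl <- as.vector(f_low$terms)[keep]
  fh <- as.vector(f_high$terms)[keep]
  n <- tabulate(idx, nbins = scheme$n_shells)
  cross <- rowsum_by(Re(fl * Conj(fh)), idx, scheme$n_shells)
  p_low <- rowsum_by(Mod(fl)^2, idx, scheme$n_shells)
  p_high <- rowsum_by(Mod(fh)^2, idx, scheme$n_shells)
  rms_low <- sqrt(p_low / pmax(n, 1))
  rms_high <- sqrt(p_high / pmax(n, 1))
  denom <- sqrt(p_low * p_high)
  fsc <- ifelse(denom > 0, cross / denom, 0)
  w_defined <- rms_high > 0
  w <- ifelse(w_defined, fsc * rms_low / rms_high, NA_real_)
  dl <- shell_d_limits(scheme)
  out <- tibble::tibble(shell = seq_len(scheme$n_shells),
                        d_max = dl[, "d_max"], d_min = dl[, "d_min"],
                        n_terms = n, fsc = fsc,
                        rms_low = rms_low, rms_high = rms_high,
                        w = w, w_defined = w_defined,
                        sigma2_err = rms_low^2 * (1 - pmin(fsc, 1)^2))
  class(out) <- c("shellstats", class(out))
  attr(out, "scheme") <- scheme
  out
}

rowsum_by <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Convert a half-map FSC to full-map quantities
#'
#' A half-map shell correlation `fsc_half` implies a full (averaged) map FSC of
#' `2 fsc_half / (1 + fsc_half)` and an estimated shell correlation of the
#' averaged map to the true map of `sqrt(max(fsc_full, 0))`. The conventional
#' 0.143 half-map threshold therefore corresponds to a map-to-true correlation
#' of 0.5.
#'
#' @param fsc_half Numeric vector of half-map FSC values in (-1, 1].
#' @return A tibble with columns `fsc_half`, `fsc_full`, `c_ref`.
#' @export
half_to_full_correlation <- function(fsc_half) {
  if (any(fsc_half <= -1 | fsc_half > 1))
    stop("fsc_half must lie in (-1, 1]")
  fsc_full <- 2 * fsc_half / (1 + fsc_half)
  tibble::tibble(fsc_half = fsc_half, fsc_full = fsc_full,
                 c_ref = sqrt(pmax(fsc_full, 0)))
}

#' Apply a B factor (blur or sharpen) to Fourier terms
#'
#' Each term is multiplied by `exp(-B / (4 d^2))`; the origin term (undefined d)
#' is unchanged. Positive B blurs, negative B sharpens;
#' `apply_b_factor(B1)` then `apply_b_factor(B2)` equals
#' `apply_b_factor(B1 + B2)`.
#'
#' @param f A `fouriermap`.
#' @param B B value in Angstrom^2.
#' @return A `fouriermap`.
#' @export
apply_b_factor <- function(f, B) {
  s2 <- inv_d2_grid(f)
  f$terms <- f$terms * exp(-B * s2 / 4)
  f
}

#' Blur-by-resolution B value
#'
#' The default blurring applied to a final density-modified map: B equals ten
#' times the nominal resolution.
#'
#' @param resolution Nominal resolution in Angstrom.
#' @return B in Angstrom^2.
#' @export
blur_by_resolution_b <- function(resolution) 10 * resolution

#' Half-map sharpening
#'
#' Rescales each shell so the output r.m.s. amplitude is proportional to the
#' (non-negative part of the) half-map FSC in that shell, with one global
#' constant chosen to preserve total power. Shells with `fsc <= 0` are zeroed;
#' terms beyond the shell scheme's resolution limit are left unchanged.
#'
#' @param f `fouriermap` of the map to sharpen (typically the average of the
#'   two half-maps whose statistics are supplied).
#' @param stats `shellstats` computed from the two half-maps.
#' @return A `fouriermap`.
#' @export
half_map_sharpen <- function(f, stats) {
  scheme <- attr(stats, "scheme")
  if (is.null(scheme)) stop("stats must carry a shell scheme")
  cc <- pmax(stats$fsc, 0)
  if (all(cc <= 0)) stop("all shells have non-positive FSC: nothing to sharpen")
  cur <- shell_rms(f, scheme)
  p_in <- sum(stats$n_terms * cur^2)
  p_target <- sum(stats$n_terms * cc^2)
  k <- sqrt(p_in / p_target)
  scale_per_shell(f, scheme, ifelse(cur > 0, k * cc / cur, 0))
}

#' Rescale shells to a target amplitude profile
#'
#' Scales each shell so its r.m.s. amplitude matches the supplied profile up to
#' one global constant (chosen to preserve total power). Supports the
#' spectral-scaling option of the density-modification pipeline: the profile is
#' an explicit per-shell target rather than a computed reference spectrum.
#'
#' @param f A `fouriermap`.
#' @param scheme A `shellscheme`.
#' @param profile Non-negative numeric vector, one target r.m.s. per shell.
#' @return A `fouriermap`.
#' @export
spectral_scale <- function(f, scheme, profile) {
  if (length(profile) != scheme$n_shells)
    stop("profile length must equal the number of shells")
  if (any(profile < 0)) stop("profile must be non-negative")
  if (all(profile == 0)) stop("profile is identically zero")
  cur <- shell_rms(f, scheme)
  n <- tabulate(scheme$index[!is.na(scheme$index)], nbins = scheme$n_shells)
  p_in <- sum(n * cur^2)
  p_target <- sum(n * profile^2)
  k <- sqrt(p_in / p_target)
  scale_per_shell(f, scheme, ifelse(cur > 0, k * profile / cur, 0))
}

# r.m.s. amplitude per shell of one fouriermap.
shell_rms <- function(f, scheme) {
  idx <- as.vector(scheme$index)
  keep <- !is.na(idx)
  p <- rowsum_by(Mod(as.vector(f$terms))[keep]^2, idx[keep], scheme$n_shells)
  n <- tabulate(idx[keep], nbins = scheme$n_shells)
  sqrt(p / pmax(n, 1))
}

# multiply every assigned term by its shell's factor; unassigned non-origin
# terms are left untouched.
scale_per_shell <- function(f, scheme, factors) {
  fac <- array(1, dim(f$terms))
  ok <- !is.na(scheme$index)
  fac[ok] <- factors[scheme$index[ok]]
  f$terms <- f$terms * fac
  f
}

#' Write a shell-statistics table to CSV
#' @param stats A `shellstats` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shell_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
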