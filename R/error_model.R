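#' Estimate complex errors in Fourier terms by weighted subtraction
#'
#' Per term, `E = F_low - w * F_high` with the Luzzati-style weight `w` taken
#' from the term's resolution shell (so `w F_high` is the expected value of
#' `F_low` given `F_high` under the complex-normal model). The high-accuracy
#' map acts as the truth proxy; the error map is the real-space transform of
#' the per-term errors. Shells where `w` is undefined (`rms_high = 0`) keep
#' `E = F_low` and are flagged; terms beyond the shell scheme's resolution
#' limit are set to zero, as is the origin term.
#'
#' @param f_low,f_high Aligned `fouriermap`s.
#' @param stats `shellstats` computed from the same pair with [shell_stats()].
#' @return An `errormap`: list with `emap` (`mapgrid`), `eterms` (`fouriermap`)
#'   and `flagged_shells` (integer vector).
#' @export
error_terms <- function(f_low, f_high, stats) {
  stop_if_misaligned(f_low, f_high, "Fourier maps")
  scheme <- attr(stats, "scheme")
  if (is.null(scheme)) stop("stats must carry a shell scheme")
  w_shell <- ifelse(stats$w_defined, stats$w, 0)
  warr <- array(0, dim(f_low$terms))
  ok <- !is.na(scheme$index)
  warr[ok] <- w_shell[scheme$index[ok]]
  eterms <- f_low
  eterms$terms <- f_low$terms - warr * f_high$terms
  eterms$terms[!ok] <- 0 + 0i
  # flagged shells revert to E = F_low
  flagged <- which(!stats$w_defined)
  if (length(flagged)) {
    rev <- ok & (scheme$index %in% flagged)
    eterms$terms[rev] <- f_low$terms[rev]
  }
  eterms$terms <- hermitian_symmetrize(eterms$terms)
  structure(list(emap = ifft_map(eterms), eterms = eterms,
                 flagged_shells = flagged),
            class = "errormap")
}

#' @export
print.errormap <- function(x, ...) {
  cat("<errormap>\n"); print(x$emap); invisible(x)
}

#' Radial profile of local map variation
#'
#' Standard deviation of map values in concentric shells around the geometric
#' center of the box: the value for a shell from radius r1 to r2 is the SD over
#' all grid points whose distance from the center lies in [r1, r2). Shells are
#' equally spaced from 0 to half the smallest box edge. Empty shells are
#' reported as absent (`NA`), not zero.
#'
#' @param m A `mapgrid`.
#' @param n_shells Number of radial shells (>= 1).
#' @return A `radialprofile` tibble with columns `r_min`, `r_max` (Angstrom),
#'   `n`, `sd`.
#' @export
radial_sd_profile <- function(m, n_shells) {
  if (n_shells < 1) stop("n_shells must be at least 1")
  r <- center_distance(m)
  rmax <- min(map_dims(m) * m$voxel) / 2
  width <- rmax / n_shells
  idx <- pmin(floor(r / width) + 1L, n_shells + 1L)
  keep <- idx <= n_shells
  v <- as.vector(m$values)[keep]
  idx <- as.vector(idx)[keep]
  n <- tabulate(idx, nbins = n_shells)
  sds <- rep(NA_real_, n_shells)
  for (s in which(n >= 2)) sds[s] <- stats::sd(v[idx == s])
  out <- tibble::tibble(r_min = (seq_len(n_shells) - 1) * width,
                        r_max = seq_len(n_shells) * width,
                        n = n, sd = sds)
  class(out) <- c("radialprofile", class(out))
  out
}

#' Test whether estimated errors are local in Fourier space
#'
#' If errors are local in Fourier space they are global in real space, so an
#' estimated real-space error map should be about equally variable inside and
#' outside the macromolecule region. The diagnostic compares the SD of error
#' values inside the mask with the SD outside it (restricted to the same range
#' of centre radii, so the comparison is not confounded by the box corners) and
#' declares the errors "local" when the ratio lies within [1/T, T].
#'
#' @param e An `errormap` (or a `mapgrid` of error values).
#' @param macromolecule_mask Logical `mapgrid` aligned with the error map.
#' @param threshold Flatness tolerance T (default 1.5).
#' @return A list with `flatness_ratio`, `verdict` ("local" or
#'   "concentrated"), `sd_inside`, `sd_outside`.
#' @export
locality_diagnostic <- function(e, macromolecule_mask, threshold = 1.5) {
  emap <- if (inherits(e, "errormap")) e$emap else e
  stop_if_misaligned(emap, macromolecule_mask, "error map and mask")
  mask <- as.logical(macromolecule_mask$values)
  if (!any(mask) || all(mask)) stop("mask must be neither empty nor full")
  if (all(emap$values == 0)) stop("error map is identically zero: ratio undefined")
  r <- as.vector(center_distance(emap))
  v <- as.vector(emap$values)
  rr <- range(r[mask])
  outside <- !mask & r >= rr[1] & r <= rr[2]
  if (!any(outside)) stop("no points outside the mask in the mask's radial support")
  sd_in <- stats::sd(v[mask])
  sd_out <- stats::sd(v[outside])
  ratio <- sd_in / sd_out
  list(flatness_ratio = ratio,
       verdict = if (ratio >= 1 / threshold && ratio <= threshold)
         "local" else "concentrated",
       sd_inside = sd_in, sd_outside = sd_out)
}

#' Write a radial profile to CSV
#' @param profile A `radialprofile` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_radial_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
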