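#' Define a per-shell noise profile for synthetic half-maps
#'
#' The generator injects independent complex-normal noise per Fourier term
#' whose variance, relative to the signal power in the term's shell, grows
#' exponentially in 1/d^2 — the usual monotone loss of signal-to-noise with
#' resolution. The profile is calibrated so the expected half-map FSC,
#' `1 / (1 + sigma^2 / rms^2)`, crosses 0.143 at the nominal resolution.
#'
#' @param nominal_resolution Target FSC = 0.143 crossing in Angstrom.
#' @param vr0 Noise-to-signal variance ratio at zero spatial frequency
#'   (default 0.01).
#' @return A `noiseprofile`: list with `nominal_resolution`, `vr0`, `k` and
#'   the variance-ratio function `vr(s2)`.
#' @export
noise_profile <- function(nominal_resolution, vr0 = 0.01) {
  if (nominal_resolution <= 0) stop("nominal_resolution must be positive")
  vr_nom <- 1 / 0.143 - 1
  s2_nom <- 1 / nominal_resolution^2
  k <- log(vr_nom / vr0) / s2_nom
  structure(list(nominal_resolution = nominal_resolution, vr0 = vr0, k = k,
                 vr = function(s2) vr0 * exp(k * s2)),
            class = "noiseprofile")
}

#' Per-shell table of a noise profile
#' @param profile A `noiseprofile`.
#' @param scheme A `shellscheme`.
#' @return Tibble with `shell`, `d_mid`, `noise_to_signal_sd`, `expected_fsc`.
#' @export
profile_table <- function(profile, scheme) {
  mids <- (scheme$edges[-1] + scheme$edges[-length(scheme$edges)]) / 2
  vr <- profile$vr(mids)
  tibble::tibble(shell = seq_len(scheme$n_shells), d_mid = 1 / sqrt(mids),
                 noise_to_signal_sd = sqrt(vr), expected_fsc = 1 / (1 + vr))
}

#' Generate a procedural pseudo-atomic toy model
#'
#' Motifs: `"helix"` (a regular helical trace with exactly constant
#' consecutive-atom spacing), `"blob"` (a compact random cluster with a
#' minimum spacing, emulating a folded domain), and `"two_state"` (a blob
#' scaffold plus a six-atom local feature present in two alternative
#' conformations A and B, recorded via the altloc field and selectable with
#' [select_altloc()]).
#'
#' @param n_atoms Number of atoms (scaffold atoms for `two_state`).
#' @param motif One of `"helix"`, `"blob"`, `"two_state"`.
#' @param box Cubic box edge in Angstrom (model is kept in the central
#'   region).
#' @param seed Integer seed.
#' @return An `atommodel` centred at `box/2` in all three axes.
#' @export
make_toy_model <- function(n_atoms, motif = c("blob", "helix", "two_state"),
                           box, seed = 1) {
  motif <- match.arg(motif)
  if (n_atoms < 1) stop("n_atoms must be at least 1")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ctr <- rep(box / 2, 3)
  if (motif == "helix") {
    rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
    height <- (n_atoms - 1) * rise
    if (height > 0.8 * box) stop("box too small for a helix of this length")
    t <- seq_len(n_atoms) - 1
    xyz <- cbind(radius * cos(t * twist), radius * sin(t * twist),
                 t * rise - height / 2)
    xyz <- sweep(xyz, 2, ctr, "+")
    elem <- rep("C", n_atoms)
    alt <- rep("", n_atoms)
  } else {
    # compact random cluster: atoms at >= 1.4 A spacing inside a sphere whose
    # radius gives roughly half of protein-interior atom density
    r_sphere <- max((n_atoms / (4 / 3 * pi * 0.006))^(1 / 3), 3)
    if (2 * (r_sphere + 4) > box) stop("box too small for this many atoms")
    xyz <- matrix(NA_real_, n_atoms, 3)
    placed <- 0
    tries <- 0
    while (placed < n_atoms && tries < 200000) {
      tries <- tries + 1
      p <- stats::runif(3, -r_sphere, r_sphere)
      if (sum(p^2) > r_sphere^2) next
      if (placed > 0) {
        d2 <- colSums((t(xyz[seq_len(placed), , drop = FALSE]) - p)^2)
        if (min(d2) < 1.4^2) next
      }
      placed <- placed + 1
      xyz[placed, ] <- p
    }
    if (placed < n_atoms) stop("box too small for this many atoms at physical spacing")
    xyz <- sweep(xyz, 2, ctr, "+")
    elem <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
    alt <- rep("", n_atoms)
    if (motif == "two_state") {
      # anchor the two-state feature on the outermost scaffold atom
      rad <- rowSums(sweep(xyz, 2, ctr, "-")^2)
      anchor <- xyz[which.max(rad), ]
      u <- (anchor - ctr) / sqrt(max(sum((anchor - ctr)^2), 1e-9))
      perp1 <- normalize_perp(u)
      perp2 <- cross3(u, perp1)
      mk_branch <- function(dirn) {
        steps <- outer(seq_len(6) * 1.4, dirn)
        sweep(steps, 2, anchor + 0.7 * u, "+")
      }
      dir_a <- (u + 1.2 * perp1) / sqrt(1 + 1.44)
      dir_b <- (u - 1.2 * perp1 + 0.4 * perp2) / sqrt(1 + 1.44 + 0.16)
      xyz <- rbind(xyz, mk_branch(dir_a), mk_branch(dir_b))
      elem <- c(elem, rep("C", 12))
      alt <- c(alt, rep("A", 6), rep("B", 6))
    }
  }
  occ <- ifelse(alt == "", 1, 0.5)
  atom_model(tibble::tibble(element = elem, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], b = 20, occ = occ,
                            chain = "A", resno = seq_along(elem),
                            resid = "ALA", name = elem, altloc = alt))
}

normalize_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- v - sum(v * u) * u
  p / sqrt(sum(p^2))
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Generate a synthetic scene: truth map plus two noisy half-maps
#'
#' The ground-truth map is the model density (exactly zero — flat solvent —
#' outside the molecular envelope). Each half-map adds independent per-term
#' complex-normal noise, Hermitian-consistent, with per-shell standard
#' deviation set by the noise profile relative to the truth's shell r.m.s.;
#' the two half-maps use independently derived sub-seeds. Noise beyond the
#' scene's resolution limit is zero (the half-maps are band-limited), and the
#' F000 term carries no noise.
#'
#' @param model An `atommodel`.
#' @param dims Integer length-3 grid dimensions.
#' @param voxel Voxel size in Angstrom (scalar or length 3).
#' @param d_min Resolution limit of the scene in Angstrom.
#' @param profile A `noiseprofile` (or `NULL` for no noise).
#' @param seed Integer scene seed (sub-seeds for the two half-maps are derived
#'   from it).
#' @param n_shells Shell count used to impose the profile (default 20).
#' @return A `scene`: list with `truth`, `model`, `half_a`, `half_b`,
#'   `profile`, `profile_realized` (tibble), `solvent_mask_true`, `scheme`,
#'   `seed`.
#' @export
make_scene <- function(model, dims, voxel, d_min, profile, seed = 1,
                       n_shells = 20) {
  voxel <- rep_len(voxel, 3)
  if (d_min < 2 * max(voxel)) stop("profile/grid incompatible: d_min below Nyquist")
  template <- map_grid(array(0, dims), voxel)
  truth <- model_to_density(model, template, d_min)
  # envelope radius guarantees exact zeros outside (stamping cutoff is 4 sigma)
  sigma_max <- sqrt((max(model$atoms$b) + 8 * d_min^2) / (8 * pi^2))
  env_r <- 4 * sigma_max + max(voxel)
  mask_true <- with_values(template,
                           near_atom_mask(template, model_coords(model), env_r))
  ft <- fft_map(truth)
  scheme <- make_shells(ft, d_min, n_shells)
  if (is.null(profile)) {
    half_a <- truth; half_b <- truth
    ptab <- NULL
  } else {
    rms_sig <- shell_rms(ft, scheme)
    mids <- (scheme$edges[-1] + scheme$edges[-length(scheme$edges)]) / 2
    sd_shell <- sqrt(profile$vr(mids)) * rms_sig
    seeds <- split_seed(seed, 2)
    half_a <- add_shell_noise(truth, ft, scheme, sd_shell, seeds[1])
    half_b <- add_shell_noise(truth, ft, scheme, sd_shell, seeds[2])
    ptab <- profile_table(profile, scheme)
    ptab$signal_rms <- rms_sig
    ptab$noise_sd <- sd_shell
  }
  structure(list(truth = truth, model = model, half_a = half_a,
                 half_b = half_b, profile = profile, profile_realized = ptab,
                 solvent_mask_true = mask_true, scheme = scheme, seed = seed),
            class = "scene")
}

# truth + Hermitian complex-normal noise with given per-shell per-term SD
add_shell_noise <- function(truth, ft, scheme, sd_shell, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(ft$terms)
  white <- stats::fft(array(stats::rnorm(n), dim(ft$terms)))  # E|W|^2 = n per term
  sdarr <- array(0, dim(ft$terms))
  ok <- !is.na(scheme$index)
  sdarr[ok] <- sd_shell[scheme$index[ok]]
  noisy <- ft
  noisy$terms <- ft$terms + white * (sdarr / sqrt(n))
  ifft_map(noisy, tol = 1e-6)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> seed %d, %d atoms, grid %s\n", x$seed, n_atoms(x$model),
              paste(map_dims(x$truth), collapse = "x")))
  invisible(x)
}

#' Multiply both half-maps by a soft spherical mask
#'
#' Produces a deliberately pathological scene: real-space masking gives the
#' half-maps finite support, which correlates the errors of neighbouring
#' Fourier terms (errors become non-local in Fourier space). The truth map is
#' untouched. The mask is 1 inside `mask_radius`, falls to 0 over a cosine
#' taper two voxels wide, and is centred on the box centre.
#'
#' @param scene A `scene`.
#' @param mask_radius Radius in Angstrom.
#' @return A `scene` with masked half-maps and `masked = TRUE`.
#' @export
apply_mask_corruption <- function(scene, mask_radius) {
  box <- min(map_dims(scene$truth) * scene$truth$voxel)
  if (mask_radius > box) stop("mask radius exceeds the box")
  r <- center_distance(scene$truth)
  taper <- 2 * max(scene$truth$voxel)
  w <- ifelse(r <= mask_radius - taper, 1,
              ifelse(r >= mask_radius, 0,
                     0.5 * (1 + cos(pi * (r - (mask_radius - taper)) / taper))))
  scene$half_a <- with_values(scene$half_a, scene$half_a$values * w)
  scene$half_b <- with_values(scene$half_b, scene$half_b$values * w)
  scene$masked <- TRUE
  scene
}

# signed hkl -> 1-based array position
hkl_to_pos <- function(hkl, dims) {
  ((hkl %% dims) + dims) %% dims + 1
}

#' Read or replace a single Fourier term (with its Hermitian mate)
#'
#' @param f A `fouriermap`.
#' @param hkl Integer length-3 signed indices.
#' @param value Complex replacement for `set_fourier_term`.
#' @return `get_fourier_term`: the complex coefficient. `set_fourier_term`: a
#'   `fouriermap` with the term and its mate at `-hkl` replaced consistently.
#' @export
get_fourier_term <- function(f, hkl) {
  p <- hkl_to_pos(hkl, dim(f$terms))
  f$terms[p[1], p[2], p[3]]
}

#' @rdname get_fourier_term
#' @export
set_fourier_term <- function(f, hkl, value) {
  d <- dim(f$terms)
  p <- hkl_to_pos(hkl, d)
  q <- hkl_to_pos(-hkl, d)
  f$terms[p[1], p[2], p[3]] <- value
  if (!all(p == q)) f$terms[q[1], q[2], q[3]] <- Conj(value)
  f
}

#' Corrupt one Fourier term of a map
#'
#' Multiplies the term at `hkl` (and its Hermitian mate) by `factor`, e.g. 5
#' for a five-fold amplitude corruption.
#'
#' @param m A `mapgrid`.
#' @param hkl Integer length-3 signed indices.
#' @param factor Complex or real multiplier.
#' @return A `mapgrid`.
#' @export
corrupt_fourier_term <- function(m, hkl, factor = 5) {
  f <- fft_map(m)
  f <- set_fourier_term(f, hkl, factor * get_fourier_term(f, hkl))
  ifft_map(f)
}
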