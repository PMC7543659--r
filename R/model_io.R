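#' Construct an atomic model
#'
#' A light container for a set of atoms: element, position (Angstrom),
#' isotropic B (Angstrom^2), occupancy and identifiers, stored as a tibble.
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z`, `b`, `occ`
#'   and optionally `chain`, `resno`, `resid`, `name`, `altloc`.
#' @return An object of class `atommodel`.
#' @export
atom_model <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) < 1) stop("a model must contain at least one atom")
  for (col in c("chain", "resid", "name", "altloc"))
    if (!col %in% names(atoms)) atoms[[col]] <- ""
  if (!"resno" %in% names(atoms)) atoms$resno <- seq_len(nrow(atoms))
  if (!"b" %in% names(atoms)) atoms$b <- 20
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) || any(!is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0)) stop("B values must be non-negative")
  structure(list(atoms = atoms), class = "atommodel")
}

#' @export
print.atommodel <- function(x, ...) {
  cat(sprintf("<atommodel> %d atoms, %d residues\n", nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Number of atoms in a model
#' @param model An `atommodel`.
#' @return Integer.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Atom coordinates as a matrix
#' @param model An `atommodel`.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
model_coords <- function(model) {
  cbind(x = model$atoms$x, y = model$atoms$y, z = model$atoms$z)
}

#' Read an atomic model from a PDB file
#'
#' Reads all ATOM/HETATM records (via bio3d). Alternate-location identifiers
#' are preserved so that individual conformers can be selected afterwards with
#' [select_altloc()].
#'
#' @param path Path to a PDB file.
#' @return An `atommodel`.
#' @export
read_model <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) < 1) stop("no atoms in PDB file")
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  elem[is.na(elem) | trimws(elem) == ""] <- substr(trimws(a$elety[is.na(elem) | trimws(elem) == ""]), 1, 1)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  atom_model(tibble::tibble(
    element = trimws(elem), x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b), occ = ifelse(is.na(a$o), 1, a$o),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, resid = a$resid, name = trimws(a$elety), altloc = alt))
}

#' Write an atomic model (or ensemble) to a PDB file
#'
#' @param model An `atommodel`, or a list of them (written as a multi-model
#'   PDB).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  models <- if (inherits(model, "atommodel")) list(model) else model
  con <- file(path, "wt")
  on.exit(close(con))
  multi <- length(models) > 1
  for (i in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    a <- models[[i]]$atoms
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000,
      substr(ifelse(a$name == "", a$element, a$name), 1, 4),
      substr(a$altloc, 1, 1),
      substr(ifelse(a$resid == "", "ALA", a$resid), 1, 3),
      substr(ifelse(a$chain == "", "A", a$chain), 1, 1),
      a$resno %% 10000, a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select one alternate conformation from a model
#'
#' Keeps atoms whose altloc is blank or matches `altloc`; occupancies of the
#' selected conformer atoms are reset to 1.
#'
#' @param model An `atommodel`.
#' @param altloc Single character, e.g. `"A"`.
#' @return An `atommodel`.
#' @export
select_altloc <- function(model, altloc) {
  a <- model$atoms
  keep <- a$altloc == "" | a$altloc == altloc
  a <- a[keep, , drop = FALSE]
  a$occ[a$altloc == altloc] <- 1
  atom_model(a)
}
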