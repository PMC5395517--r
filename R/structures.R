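## Structure I/O, atom classification, solvent accessibility, rigid
## superposition and crystallographic quality filtering.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

#' Van der Waals radii used for solvent accessibility
#'
#' Bondi-style radii (in angstroms) for the elements that occur in
#' protein structures. Elements absent from the table fall back to a
#' configurable default (1.7 A) with a warning.
#'
#' @return Named numeric vector of radii in angstroms.
#' @export
vdw_radii <- function() {
  c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    B = 1.92, SI = 2.10)
}

new_structure <- function(id, atoms, provenance = list()) {
  stopifnot(is.data.frame(atoms))
  structure(list(id = id, atoms = atoms, provenance = provenance),
            class = "pm_structure")
}

#' @export
print.pm_structure <- function(x, ...) {
  tab <- table(x$atoms$record)
  cat("Structure", sQuote(x$id), "with", nrow(x$atoms), "atoms\n")
  cat(" ", paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CA"),
         two, one)
}

#' Coordinates of a structure as a matrix
#'
#' @param structure A `pm_structure`.
#' @param idx Optional atom indices (1-based).
#' @return Numeric matrix with one row per atom and columns x, y, z (A).
#' @export
coords <- function(structure, idx = NULL) {
  a <- structure$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

classify_record <- function(type, resname) {
  rec <- ifelse(type == "ATOM", "protein",
         ifelse(toupper(resname) %in% WATER_RESNAMES, "water", "ligand"))
  rec[is.na(rec)] <- "other"
  rec
}

#' Read a protein structure
#'
#' Parses a PDB (or mmCIF) file into an atom table. Records are
#' classified deterministically: `ATOM` rows become `protein`, `HETATM`
#' waters (HOH/WAT/...) become `water`, all other `HETATM` rows become
#' `ligand`. Hydrogens are retained but flagged. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' letter order).
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"` (default) or `"mmcif"`.
#' @param id Structure identifier; defaults to the file basename.
#' @return A `pm_structure`: list with `id`, `atoms` (data frame with
#'   serial, name, element, resname, resno, chain, x, y, z, record,
#'   occupancy, b, hydrogen) and `provenance`.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif"), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse ", sQuote(path), " as ", dialect,
                             ": ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no atoms in ", path)
  element <- toupper(at$elesy)
  bad <- is.na(element) | element == ""
  element[bad] <- guess_element(at$elety[bad])

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = element,
    resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    record = classify_record(at$type, at$resid),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    stringsAsFactors = FALSE)
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  # resolve alternate locations: keep highest occupancy, ties by altloc order
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name)
  if (any(duplicated(key))) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno,
                                     atoms$resname, atoms$name)), , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, at$eleno)), , drop = FALSE]
  }
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  new_structure(id %||% sub("\\.(pdb|cif|ent)$", "", basename(path)),
                atoms, provenance = list(path = path, dialect = dialect))
}

#' Write a structure to a PDB file
#'
#' @param structure A `pm_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    type = ifelse(a$record == "protein", "ATOM", "HETATM"),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = a$chain, resno = a$resno,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$occupancy, b = a$b, elesy = a$element)
  invisible(path)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Areas are computed over protein heavy atoms only: hydrogens, ligands
#' and waters are excluded both as probes and as occluders, so a bound
#' ligand does not mask the pocket it sits in. The spherical test-point
#' set is a deterministic Fibonacci lattice.
#'
#' @param structure A `pm_structure`.
#' @param probe Probe radius in angstroms (water, 1.4 A).
#' @param n_points Number of test points per atom sphere.
#' @param radii Named vector of element radii; defaults to [vdw_radii()].
#' @param fallback_radius Radius (A) for elements missing from `radii`.
#' @return Numeric vector, one entry per atom in the structure; `NA` for
#'   atoms not included in the calculation (hydrogens, non-protein).
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 960,
                      radii = vdw_radii(), fallback_radius = 1.7) {
  a <- structure$atoms
  sel <- which(a$record == "protein" & !a$hydrogen)
  if (length(sel) == 0) stop("no protein heavy atoms in structure ", structure$id)
  el <- a$element[sel]
  r <- unname(radii[el])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
            "; using fallback radius ", fallback_radius, " A")
    r[is.na(r)] <- fallback_radius
  }
  area <- rep(NA_real_, nrow(a))
  area[sel] <- .sasa_cpp(coords(structure, sel), r, probe, as.integer(n_points))
  area
}

#' Surface atoms of a structure
#'
#' Protein heavy atoms with solvent-accessible area at or above
#' `min_area`.
#'
#' @param structure A `pm_structure`.
#' @param min_area Area threshold in square angstroms.
#' @param sasa Optional precomputed result of [atom_sasa()].
#' @param ... Passed to [atom_sasa()] when `sasa` is not supplied.
#' @return Integer vector of atom indices (1-based).
#' @export
surface_atoms <- function(structure, min_area = 0.5, sasa = NULL, ...) {
  if (is.null(sasa)) sasa <- atom_sasa(structure, ...)
  which(!is.na(sasa) & sasa >= min_area)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' paired atoms, mapping `mobile` onto `reference`.
#'
#' @param mobile,reference `pm_structure` objects, or plain n x 3
#'   coordinate matrices.
#' @param pairing Two-column integer matrix of (mobile, reference) atom
#'   indices; defaults to the identity pairing when both have the same
#'   number of atoms.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length
#'   3) and `rmsd` (A, over the pairing after transform). The transform
#'   maps a mobile coordinate x to `rotation %*% x + translation`.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  X <- if (inherits(mobile, "pm_structure")) coords(mobile) else as.matrix(mobile)
  Y <- if (inherits(reference, "pm_structure")) coords(reference) else as.matrix(reference)
  if (is.null(pairing)) {
    if (nrow(X) != nrow(Y)) stop("pairing required when atom counts differ")
    pairing <- cbind(seq_len(nrow(X)), seq_len(nrow(Y)))
  }
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3) stop("need at least 3 atom pairs")
  X <- X[pairing[, 1], , drop = FALSE]
  Y <- Y[pairing[, 2], , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (svd(Xc)$d[2] < 1e-8) stop("degenerate pairing: points are (near-)collinear")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cy - R %*% cx)
  Xt <- sweep(Xc %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((Xt - Y)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, "+")
}

#' Crystallographic quality thresholds
#'
#' Bound sets used for dataset curation. `protein_centric`: resolution
#' 2.5 A or better, Rfree <= 0.3, DPI <= 0.5 A. `ligand_centric`:
#' resolution 2.7 A or better, ligand RSCC >= 0.9, ligand RSR <= 0.15,
#' ligand OWAB in [5, 50] A^2.
#'
#' @param set `"protein_centric"` or `"ligand_centric"`.
#' @return Named list of `c(lower, upper)` inclusive bounds.
#' @export
quality_thresholds <- function(set = c("protein_centric", "ligand_centric")) {
  set <- match.arg(set)
  if (set == "protein_centric")
    list(resolution = c(-Inf, 2.5), rfree = c(-Inf, 0.3), dpi = c(-Inf, 0.5))
  else
    list(resolution = c(-Inf, 2.7), rscc = c(0.9, Inf),
         rsr = c(-Inf, 0.15), owab = c(5, 50))
}

#' Read a crystallographic quality table
#'
#' Delimited text (TSV or CSV, autodetected) with a header row naming
#' quality fields; must include `structure_id`. Missing values stay
#' missing (`NA`), never silently zero.
#'
#' @param path File path.
#' @return Data frame of quality records.
#' @export
read_quality_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"structure_id" %in% names(df)) stop("quality table needs a structure_id column")
  df
}

#' Filter structures by crystallographic quality
#'
#' A record passes when every thresholded field is present and inside
#' its inclusive `c(lower, upper)` bound. A record missing a thresholded
#' field fails (and is reported via `message`).
#'
#' @param records Data frame with a `structure_id` column plus quality
#'   fields (resolution, rscc, rsr, owab, rfree, dpi).
#' @param thresholds Named list of `c(lower, upper)` bounds, e.g.
#'   [quality_thresholds()].
#' @return Character vector of passing `structure_id`s.
#' @export
quality_filter <- function(records, thresholds = quality_thresholds()) {
  stopifnot(is.data.frame(records), "structure_id" %in% names(records))
  unknown <- setdiff(names(thresholds), names(records))
  known_fields <- c("resolution", "rscc", "rsr", "owab", "rfree", "dpi")
  if (length(bad <- setdiff(names(thresholds), known_fields)))
    stop("unknown quality field(s): ", paste(bad, collapse = ", "))
  if (length(unknown))
    stop("quality field(s) absent from records: ", paste(unknown, collapse = ", "))
  pass <- rep(TRUE, nrow(records))
  for (f in names(thresholds)) {
    b <- thresholds[[f]]
    v <- records[[f]]
    miss <- is.na(v)
    if (any(miss & pass))
      message(sum(miss & pass), " record(s) missing ", f, ": failed")
    pass <- pass & !miss & v >= b[1] & v <= b[2]
  }
  records$structure_id[pass]
}
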