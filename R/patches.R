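## Binding-site patches: pharmacophore pseudocenters typed from residue
## and atom names, plus surface-atom shape points, built from a bound
## ligand (4 A rule) or from a detected cavity via the pseudo-ligand
## rule (0.3 A site size).

#' The five pharmacophore types
#' @return Character vector: donor, acceptor, anion, cation, hydrophobe.
#' @export
pharmacophore_types <- function() {
  c("donor", "acceptor", "anion", "cation", "hydrophobe")
}

# side-chain rules per residue; "group" entries are collapsed to one
# centroid pseudocenter per residue
SIDECHAIN_RULES <- list(
  ASP = list(list(atoms = c("OD1", "OD2"), type = "anion", group = TRUE)),
  GLU = list(list(atoms = c("OE1", "OE2"), type = "anion", group = TRUE)),
  LYS = list(list(atoms = "NZ", type = "cation", group = FALSE)),
  ARG = list(list(atoms = c("NE", "NH1", "NH2"), type = "cation", group = TRUE)),
  SER = list(list(atoms = "OG", type = "donor", group = FALSE),
             list(atoms = "OG", type = "acceptor", group = FALSE)),
  THR = list(list(atoms = "OG1", type = "donor", group = FALSE),
             list(atoms = "OG1", type = "acceptor", group = FALSE),
             list(atoms = "CG2", type = "hydrophobe", group = FALSE)),
  TYR = list(list(atoms = "OH", type = "donor", group = FALSE),
             list(atoms = "OH", type = "acceptor", group = FALSE)),
  ASN = list(list(atoms = "ND2", type = "donor", group = FALSE),
             list(atoms = "OD1", type = "acceptor", group = FALSE)),
  GLN = list(list(atoms = "NE2", type = "donor", group = FALSE),
             list(atoms = "OE1", type = "acceptor", group = FALSE)),
  TRP = list(list(atoms = "NE1", type = "donor", group = FALSE),
             list(atoms = "CB", type = "hydrophobe", group = FALSE),
             list(atoms = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                  type = "hydrophobe", group = TRUE)),
  ALA = list(list(atoms = "CB", type = "hydrophobe", group = FALSE)),
  VAL = list(list(atoms = c("CB", "CG1", "CG2"), type = "hydrophobe", group = FALSE)),
  LEU = list(list(atoms = c("CB", "CG", "CD1", "CD2"), type = "hydrophobe", group = FALSE)),
  ILE = list(list(atoms = c("CB", "CG1", "CG2", "CD1"), type = "hydrophobe", group = FALSE)),
  MET = list(list(atoms = c("CB", "CG", "CE"), type = "hydrophobe", group = FALSE)),
  PRO = list(list(atoms = c("CB", "CG", "CD"), type = "hydrophobe", group = FALSE)),
  PHE = list(list(atoms = "CB", type = "hydrophobe", group = FALSE),
             list(atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  type = "hydrophobe", group = TRUE))
)

STANDARD_AA <- c(names(SIDECHAIN_RULES), "GLY", "CYS", "HIS")

#' Type pharmacophore pseudocenters on protein atoms
#'
#' Rule-table typing of the five interaction types. Backbone N atoms
#' (except proline) are donors, backbone O atoms acceptors, terminal
#' OXT anions. Asp/Glu carboxylates and the Arg guanidinium collapse to
#' one centroid pseudocenter; Ser/Thr/Tyr hydroxyls type as both donor
#' and acceptor; aliphatic and aromatic side-chain carbons type as
#' hydrophobes with aromatic rings collapsed to their centroid (or kept
#' per atom with `ring_mode = "atoms"`). Histidine ring nitrogens type
#' as acceptors by default (neutral tautomers) or as a cation centroid
#' with `his_mode = "cation"`. Non-standard residues fall back to
#' element typing (N donor, O acceptor, C hydrophobe); unmatched atoms
#' are skipped.
#'
#' @param structure A `pm_structure`.
#' @param atom_subset Atom indices to type (1-based).
#' @param his_mode `"acceptor"` (neutral His) or `"cation"` (protonated).
#' @param ring_mode `"centroid"` or `"atoms"` for aromatic rings.
#' @return Data frame of pseudocenters: columns `x`, `y`, `z`, `ptype`,
#'   and a `source` list column of contributing atom indices.
#' @export
type_pharmacophores <- function(structure, atom_subset,
                                his_mode = c("acceptor", "cation"),
                                ring_mode = c("centroid", "atoms")) {
  his_mode <- match.arg(his_mode)
  ring_mode <- match.arg(ring_mode)
  a <- structure$atoms
  sub <- atom_subset[a$record[atom_subset] == "protein" & !a$hydrogen[atom_subset]]
  out_pos <- list(); out_type <- character(0); out_src <- list()
  emit <- function(pos, type, src) {
    out_pos[[length(out_pos) + 1L]] <<- pos
    out_type[length(out_type) + 1L] <<- type
    out_src[[length(out_src) + 1L]] <<- src
  }
  key <- paste(a$chain[sub], a$resno[sub], a$resname[sub])
  for (k in unique(key)) {
    idx <- sub[key == k]
    resname <- a$resname[idx[1]]
    std <- resname %in% STANDARD_AA
    for (i in idx) {
      nm <- a$name[i]
      pos <- c(a$x[i], a$y[i], a$z[i])
      if (std && nm == "N" && resname != "PRO") emit(pos, "donor", i)
      else if (std && nm == "O") emit(pos, "acceptor", i)
      else if (nm == "OXT") emit(pos, "anion", i)
    }
    if (std) {
      rules <- SIDECHAIN_RULES[[resname]]
      if (resname == "HIS") {
        rules <- if (his_mode == "acceptor")
          list(list(atoms = "ND1", type = "acceptor", group = FALSE),
               list(atoms = "NE2", type = "acceptor", group = FALSE))
        else
          list(list(atoms = c("ND1", "NE2"), type = "cation", group = TRUE))
      }
      for (rl in rules %||% list()) {
        hit <- idx[a$name[idx] %in% rl$atoms]
        if (!length(hit)) next
        grouped <- rl$group && !(rl$type == "hydrophobe" && ring_mode == "atoms")
        if (grouped) {
          emit(colMeans(cbind(a$x[hit], a$y[hit], a$z[hit])), rl$type, hit)
        } else {
          for (i in hit) emit(c(a$x[i], a$y[i], a$z[i]), rl$type, i)
        }
      }
    } else {
      # element fallback for non-standard residues
      for (i in idx) {
        pos <- c(a$x[i], a$y[i], a$z[i])
        el <- a$element[i]
        if (el == "N") emit(pos, "donor", i)
        else if (el == "O") emit(pos, "acceptor", i)
        else if (el == "C") emit(pos, "hydrophobe", i)
        # else skipped
      }
    }
  }
  if (!length(out_pos))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      ptype = character(0), source = I(list())))
  P <- do.call(rbind, out_pos)
  df <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3], ptype = out_type,
                   stringsAsFactors = FALSE)
  df$source <- out_src
  df
}

new_patch <- function(id, structure_id, origin, atoms, shape_points, pseudocenters) {
  stopifnot(nrow(shape_points) > 0)
  structure(list(id = id, structure_id = structure_id, origin = origin,
                 atoms = atoms, shape_points = shape_points,
                 pseudocenters = pseudocenters),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  tab <- table(factor(x$pseudocenters$ptype, levels = pharmacophore_types()))
  cat("patch", sQuote(x$id), "(origin:", x$origin$kind, ")\n")
  cat(" ", nrow(x$shape_points), "shape points;",
      nrow(x$pseudocenters), "pseudocenters (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = " "), ")\n")
  invisible(x)
}

build_patch <- function(structure, patch_atoms, id, origin, ...) {
  if (!length(patch_atoms))
    stop("empty patch: no surface protein atoms in range")
  new_patch(id = id, structure_id = structure$id, origin = origin,
            atoms = patch_atoms,
            shape_points = coords(structure, patch_atoms),
            pseudocenters = type_pharmacophores(structure, patch_atoms, ...))
}

#' Build a binding-site patch around a bound ligand
#'
#' Patch atoms are the surface protein atoms within `cutoff` of any
#' ligand heavy atom; shape points are their centers and pseudocenters
#' are typed on them.
#'
#' @param structure A `pm_structure`.
#' @param ligand_atoms Atom indices of the bound ligand.
#' @param cutoff Distance cutoff in angstroms (default 4.0).
#' @param surface Optional precomputed [surface_atoms()] result.
#' @param id Patch identifier.
#' @param ... Passed to [type_pharmacophores()].
#' @return A `patch`.
#' @export
patch_from_ligand <- function(structure, ligand_atoms, cutoff = 4.0,
                              surface = NULL, id = NULL, ...) {
  stopifnot(length(ligand_atoms) > 0)
  if (is.null(surface)) surface <- surface_atoms(structure)
  lig <- structure$atoms[ligand_atoms, , drop = FALSE]
  L <- as.matrix(lig[!lig$hydrogen, c("x", "y", "z"), drop = FALSE])
  S <- coords(structure, surface)
  keep <- vapply(seq_len(nrow(S)), function(i) {
    any((L[, 1] - S[i, 1])^2 + (L[, 2] - S[i, 2])^2 + (L[, 3] - S[i, 3])^2 <= cutoff^2)
  }, logical(1))
  build_patch(structure, surface[keep],
              id = id %||% paste0(structure$id, "_lig"),
              origin = list(kind = "ligand", source = ligand_atoms), ...)
}

#' Pseudo-ligand atoms of a cavity
#'
#' The surface protein atoms associated with a detected cavity, used in
#' place of a bound ligand: the tangent atoms of the cavity's alpha
#' spheres (or, for cavities parsed from fpocket output, the
#' pocket-lining atom serials) restricted to the surface atom set.
#'
#' @param structure A `pm_structure`.
#' @param cavity A `cavity`.
#' @param surface Optional precomputed [surface_atoms()] result.
#' @return Integer vector of atom indices.
#' @export
pseudo_ligand_atoms <- function(structure, cavity, surface = NULL) {
  if (is.null(surface)) surface <- surface_atoms(structure)
  cand <- if (!is.null(cavity$spheres$tangent)) unique(as.integer(cavity$spheres$tangent))
  else match(cavity$lining_serials, structure$atoms$serial)
  cand <- cand[!is.na(cand)]
  res <- intersect(cand, surface)
  if (!length(res))
    stop("cavity ", cavity$id, " has no surface-exposed atoms")
  sort(res)
}

#' Build a binding-site patch from a detected cavity
#'
#' Patch atoms are the surface protein atoms lying within `site_size`
#' of the cavity's pseudo-ligand atoms. At the default 0.3 A this is
#' effectively the pseudo-ligand set itself plus exact-overlap
#' neighbors; the patch grows monotonically with `site_size`.
#'
#' @param structure A `pm_structure`.
#' @param cavity A `cavity`.
#' @param site_size Distance in angstroms (default 0.3).
#' @param surface Optional precomputed [surface_atoms()] result.
#' @param id Patch identifier.
#' @param ... Passed to [type_pharmacophores()].
#' @return A `patch` with `origin$kind == "cavity"`.
#' @export
patch_from_cavity <- function(structure, cavity, site_size = 0.3,
                              surface = NULL, id = NULL, ...) {
  if (is.null(surface)) surface <- surface_atoms(structure)
  pl <- pseudo_ligand_atoms(structure, cavity, surface = surface)
  P <- coords(structure, pl)
  S <- coords(structure, surface)
  keep <- vapply(seq_len(nrow(S)), function(i) {
    any((P[, 1] - S[i, 1])^2 + (P[, 2] - S[i, 2])^2 + (P[, 3] - S[i, 3])^2 <= site_size^2)
  }, logical(1))
  build_patch(structure, union(pl, surface[keep]),
              id = id %||% paste0(cavity$id, "_patch"),
              origin = list(kind = "cavity", source = cavity$id), ...)
}

#' Serialize a patch to JSON
#'
#' @param patch A `patch`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  jsonlite::write_json(list(
    id = patch$id, structure_id = patch$structure_id, origin = patch$origin,
    atoms = patch$atoms,
    shape_points = unname(apply(patch$shape_points, 1, as.numeric, simplify = FALSE)),
    pseudocenters = lapply(seq_len(nrow(patch$pseudocenters)), function(i)
      list(position = as.numeric(patch$pseudocenters[i, c("x", "y", "z")]),
           ptype = patch$pseudocenters$ptype[i],
           source_atoms = patch$pseudocenters$source[[i]]))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patch from JSON written by [write_patch()]
#' @param path JSON path.
#' @return A `patch`.
#' @export
read_patch <- function(path) {
  js <- jsonlite::read_json(path)
  sp <- do.call(rbind, lapply(js$shape_points, as.numeric))
  colnames(sp) <- c("x", "y", "z")
  pc <- if (length(js$pseudocenters)) {
    P <- do.call(rbind, lapply(js$pseudocenters, function(p) as.numeric(p$position)))
    df <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                     ptype = vapply(js$pseudocenters, function(p) p$ptype, character(1)),
                     stringsAsFactors = FALSE)
    df$source <- lapply(js$pseudocenters, function(p) as.integer(unlist(p$source_atoms)))
    df
  } else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    ptype = character(0), source = I(list()))
  new_patch(js$id, js$structure_id, js$origin, as.integer(unlist(js$atoms)), sp, pc)
}
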