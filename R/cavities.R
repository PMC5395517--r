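## Alpha-sphere cavity detection, clustering, descriptors, linear
## scoring, recall-threshold calibration and fpocket interoperability.

new_alpha_spheres <- function(center, radius, tangent, apolar) {
  structure(list(center = center, radius = radius,
                 tangent = tangent, apolar = apolar),
            class = "alpha_spheres")
}

#' @export
print.alpha_spheres <- function(x, ...) {
  cat("alpha_spheres:", length(x$radius), "spheres, radius ",
      if (length(x$radius)) sprintf("%.2f-%.2f A", min(x$radius), max(x$radius))
      else "-", "\n")
  invisible(x)
}

#' @export
length.alpha_spheres <- function(x) length(x$radius)

subset_alpha_spheres <- function(sp, idx) {
  new_alpha_spheres(sp$center[idx, , drop = FALSE], sp$radius[idx],
                    if (!is.null(sp$tangent)) sp$tangent[idx, , drop = FALSE],
                    sp$apolar[idx])
}

APOLAR_ELEMENTS <- c("C", "S")

#' Compute alpha spheres of a structure
#'
#' One candidate sphere per tetrahedron of the Delaunay complex of
#' protein heavy-atom centers (its circumsphere, tangent to the four
#' atoms), filtered to radius within `[r_min, r_max]` and to the
#' empty-sphere invariant: no protein heavy atom strictly inside the
#' sphere. Tangent atoms with apolar elements (C, S) give each sphere
#' its apolar contact count (0-4).
#'
#' @param structure A `pm_structure` with at least 5 non-coplanar
#'   protein heavy atoms.
#' @param r_min,r_max Sphere radius window in angstroms. The defaults
#'   mirror a cavity-detection setup tuned for concise, ligandable
#'   pockets (minimum 3.0 A).
#' @return An `alpha_spheres` object: `center` (n x 3), `radius`,
#'   `tangent` (n x 4 atom indices into the structure), `apolar`
#'   (contact counts).
#' @export
compute_alpha_spheres <- function(structure, r_min = 3.0, r_max = 6.0) {
  prot <- which(structure$atoms$record == "protein" & !structure$atoms$hydrogen)
  if (length(prot) < 5) stop("need at least 5 protein heavy atoms")
  P <- coords(structure, prot)
  # deterministic perturbation for general position; spheres are
  # re-derived and re-validated on the unperturbed coordinates below
  n <- nrow(P)
  pert <- 1e-6 * matrix(sin(1e4 * seq_len(3 * n) + 0.7), ncol = 3)
  tets <- .delaunay_tets(P + pert)
  if (nrow(tets) == 0) stop("degenerate geometry: no tetrahedra from Delaunay complex")

  cs <- t(apply(tets, 1, function(v) circumsphere4(P[v, , drop = FALSE])))
  ok <- is.finite(cs[, 4]) & cs[, 4] >= r_min & cs[, 4] <= r_max
  tets <- tets[ok, , drop = FALSE]
  cs <- cs[ok, , drop = FALSE]
  if (nrow(cs)) {
    # empty-sphere invariant on original coordinates
    keep <- vapply(seq_len(nrow(cs)), function(i) {
      d2 <- (P[, 1] - cs[i, 1])^2 + (P[, 2] - cs[i, 2])^2 + (P[, 3] - cs[i, 3])^2
      !any(d2 < (cs[i, 4] - 1e-6)^2 - 1e-9)
    }, logical(1))
    tets <- tets[keep, , drop = FALSE]
    cs <- cs[keep, , drop = FALSE]
  }
  dimnames(cs) <- NULL
  # distinct tetrahedra of (near-)cospherical atoms can share one
  # circumsphere; keep each geometric sphere once
  if (nrow(cs) > 1) {
    key <- apply(round(cs, 6), 1, paste, collapse = "/")
    keep <- !duplicated(key)
    tets <- tets[keep, , drop = FALSE]
    cs <- cs[keep, , drop = FALSE]
  }
  tangent <- matrix(prot[tets], ncol = 4)
  apolar <- matrix(structure$atoms$element[tangent] %in% APOLAR_ELEMENTS, ncol = 4)
  new_alpha_spheres(cs[, 1:3, drop = FALSE], unname(cs[, 4]), tangent, rowSums(apolar))
}

# circumsphere of 4 points: c(x, y, z, radius); NA radius if degenerate
circumsphere4 <- function(Q) {
  A <- 2 * sweep(Q[2:4, , drop = FALSE], 2, Q[1, ])
  b <- rowSums(Q[2:4, , drop = FALSE]^2) - sum(Q[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, 3))
  c(ctr, sqrt(sum((Q[1, ] - ctr)^2)))
}

#' Cluster alpha spheres into cavities
#'
#' Single-linkage connected components of sphere centers at distance
#' `r`; components with fewer than `n_min` spheres are discarded.
#' Cavities are ordered by descending sphere count, ties by lowest
#' member sphere index.
#'
#' @param spheres An `alpha_spheres` object.
#' @param r Clustering distance (A).
#' @param n_min Minimum spheres per cavity.
#' @param structure_id Carried into each cavity.
#' @return List of `cavity` objects (`id`, `spheres`, `structure_id`).
#' @export
cluster_alpha_spheres <- function(spheres, r = 3.0, n_min = 3,
                                  structure_id = "structure") {
  m <- length(spheres)
  if (m == 0) return(list())
  d <- as.matrix(dist(spheres$center))
  comp <- integer(m)
  cid <- 0L
  for (i in seq_len(m)) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(d[v, ] <= r & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  keep <- which(sizes >= n_min)
  if (!length(keep)) return(list())
  first <- vapply(keep, function(k) min(which(comp == k)), integer(1))
  ord <- keep[order(-sizes[keep], first)]
  lapply(seq_along(ord), function(k) {
    idx <- which(comp == ord[k])
    structure(list(id = sprintf("%s_cav%d", structure_id, k),
                   spheres = subset_alpha_spheres(spheres, idx),
                   structure_id = structure_id),
              class = "cavity")
  })
}

#' @export
print.cavity <- function(x, ...) {
  cat("cavity", sQuote(x$id), "with", length(x$spheres), "alpha spheres\n")
  invisible(x)
}

#' Cavity descriptors
#'
#' Size, hydrophobicity and polarity descriptors of a cavity:
#' sphere count, mean sphere radius, hydrophobic fraction (spheres with
#' at least 3 apolar tangent contacts), polarity fraction (the
#' complement), and a seeded Monte-Carlo volume of the union of spheres.
#'
#' @param cavity A `cavity`.
#' @param mc_points Monte-Carlo sample size over the union's bounding
#'   box.
#' @param seed Integer seed for the volume sampling.
#' @return A `cavity_descriptors` list.
#' @export
cavity_descriptors <- function(cavity, mc_points = 1e5, seed = 1) {
  sp <- cavity$spheres
  m <- length(sp)
  stopifnot(m >= 1)
  hydro <- mean(sp$apolar >= 3)
  lo <- apply(sp$center, 2, min) - max(sp$radius)
  hi <- apply(sp$center, 2, max) + max(sp$radius)
  vol_box <- prod(hi - lo)
  inside <- with_seed(seed, {
    pts <- cbind(runif(mc_points, lo[1], hi[1]),
                 runif(mc_points, lo[2], hi[2]),
                 runif(mc_points, lo[3], hi[3]))
    hit <- rep(FALSE, mc_points)
    for (i in seq_len(m)) {
      d2 <- (pts[, 1] - sp$center[i, 1])^2 + (pts[, 2] - sp$center[i, 2])^2 +
        (pts[, 3] - sp$center[i, 3])^2
      hit <- hit | d2 <= sp$radius[i]^2
    }
    mean(hit)
  })
  structure(list(n_spheres = m, mean_radius = mean(sp$radius),
                 hydrophobic_fraction = hydro,
                 polarity_fraction = 1 - hydro,
                 mc_volume = inside * vol_box,
                 mc_points = mc_points, seed = seed),
            class = "cavity_descriptors")
}

#' Default cavity score weights
#'
#' Transparent linear scoring model over the five cavity descriptors.
#' The score increases with sphere count, Monte-Carlo volume and
#' hydrophobic fraction (bigger, more hydrophobic cavities rank
#' higher); magnitudes are package defaults, identified by
#' `weights_id`, and freely configurable. External fpocket scores carry
#' a different `weights_id`, so score thresholds are never mixed across
#' scoring models.
#'
#' @return List with `weights_id`, `intercept`, `center`, `scale`,
#'   `weights` (all named over the descriptor fields).
#' @export
cavity_score_weights <- function() {
  flds <- c("n_spheres", "mean_radius", "hydrophobic_fraction",
            "polarity_fraction", "mc_volume")
  list(weights_id = "pocketmap-linear-1",
       intercept = 10,
       center = setNames(c(25, 4.0, 0.5, 0.5, 300), flds),
       scale = setNames(c(20, 1.0, 0.25, 0.25, 250), flds),
       weights = setNames(c(4, 0.5, 2, -0.5, 4), flds))
}

#' Score a cavity
#'
#' Linear score over standardized descriptors:
#' `sum(w * (d - center) / scale) + intercept`.
#'
#' @param descriptors A `cavity_descriptors`.
#' @param weights A weight set as from [cavity_score_weights()].
#' @return A `cavity_score`: list with `value` and `weights_id`.
#' @export
cavity_score <- function(descriptors, weights = cavity_score_weights()) {
  flds <- names(weights$weights)
  d <- unlist(descriptors[flds])
  if (anyNA(d) || length(d) != length(flds))
    stop("descriptors missing field(s): ",
         paste(setdiff(flds, names(descriptors)), collapse = ", "))
  z <- (d - weights$center[flds]) / weights$scale[flds]
  structure(list(value = sum(weights$weights[flds] * z) + weights$intercept,
                 weights_id = weights$weights_id),
            class = "cavity_score")
}

#' @export
print.cavity_score <- function(x, ...) {
  cat(sprintf("cavity score %.3f [%s]\n", x$value, x$weights_id))
  invisible(x)
}

#' Match a detected cavity to a bound ligand
#'
#' The matching cavity is the one with the largest number of alpha
#' sphere centers within `contact` of any ligand heavy atom; ties go to
#' the larger cavity, then the lower cavity id. Returns `NULL` when no
#' cavity touches the ligand.
#'
#' @param cavities List of `cavity` objects.
#' @param structure The parent `pm_structure`.
#' @param ligand_atoms Atom indices of the ligand.
#' @param contact Contact distance (A).
#' @return The matching cavity id, or `NULL`.
#' @export
match_cavity_to_ligand <- function(cavities, structure, ligand_atoms,
                                   contact = 4.0) {
  stopifnot(length(ligand_atoms) > 0)
  lig <- structure$atoms[ligand_atoms, , drop = FALSE]
  lig <- lig[!lig$hydrogen, , drop = FALSE]
  L <- as.matrix(lig[, c("x", "y", "z")])
  if (!length(cavities)) return(NULL)
  counts <- vapply(cavities, function(cv) {
    ctr <- cv$spheres$center
    sum(vapply(seq_len(nrow(ctr)), function(i) {
      any(sqrt((L[, 1] - ctr[i, 1])^2 + (L[, 2] - ctr[i, 2])^2 +
                 (L[, 3] - ctr[i, 3])^2) <= contact)
    }, logical(1)))
  }, numeric(1))
  if (max(counts) == 0) return(NULL)
  sizes <- vapply(cavities, function(cv) length(cv$spheres), numeric(1))
  ids <- vapply(cavities, function(cv) cv$id, character(1))
  ord <- order(-counts, -sizes, ids)
  ids[ord[1]]
}

#' Calibrate a sensitivity score threshold
#'
#' Returns the largest threshold `t` such that at least `recall` of the
#' supplied true-site scores are at or above `t` (i.e. the
#' `ceiling(n * recall)`-th largest score). By construction the recall
#' at the returned threshold is at least `recall`.
#'
#' @param true_site_scores Scores of known (true) binding sites.
#' @param recall Required recall fraction (0 < recall <= 1).
#' @return The calibrated threshold.
#' @export
calibrate_score_threshold <- function(true_site_scores, recall = 0.95) {
  stopifnot(length(true_site_scores) > 0, recall > 0, recall <= 1)
  n <- length(true_site_scores)
  sort(true_site_scores, decreasing = TRUE)[ceiling(n * recall)]
}

#' Parse an fpocket output directory
#'
#' Reads the per-pocket info text plus `pockets/pocket<N>_vert.pqr`
#' (alpha sphere centers and radii) and `pockets/pocket<N>_atm.pdb`
#' (pocket-lining atom serials). Reported Score, Druggability Score and
#' Volume are carried verbatim; the conventional interop threshold
#' (Score >= 16.8, the value above which 95% of known ligand sites are
#' recovered) is applied only when `score_min` is given.
#'
#' @param directory Path to an fpocket `*_out` directory.
#' @param score_min Optional minimal reported Score; pockets below it
#'   are dropped.
#' @return List of records: `pocket` (number), `score`,
#'   `druggability_score`, `volume`, `cavity` (a `cavity` with sphere
#'   centers/radii and `lining_serials`).
#' @export
parse_fpocket_results <- function(directory, score_min = NULL) {
  info <- list.files(directory, pattern = "_info\\.txt$", full.names = TRUE)
  if (!length(info)) {
    warning("no *_info.txt found in ", directory, "; empty result")
    return(list())
  }
  lines <- readLines(info[1])
  recs <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\s*Pocket\\s+[0-9]+", ln)) {
      if (!is.null(cur)) recs[[length(recs) + 1]] <- cur
      cur <- list(pocket = as.integer(sub("^\\s*Pocket\\s+([0-9]+).*", "\\1", ln)))
    } else if (!is.null(cur) && grepl(":", ln)) {
      key <- tolower(trimws(sub(":.*", "", ln)))
      val <- suppressWarnings(as.numeric(trimws(sub(".*:", "", ln))))
      if (key == "score") cur$score <- val
      if (key == "druggability score") cur$druggability_score <- val
      if (key == "volume") cur$volume <- val
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1]] <- cur
  if (!length(recs)) stop("malformed fpocket info file: ", info[1])

  pdir <- file.path(directory, "pockets")
  out <- lapply(recs, function(rc) {
    if (is.null(rc$score)) stop("malformed fpocket info file (no Score): ", info[1])
    vert <- file.path(pdir, sprintf("pocket%d_vert.pqr", rc$pocket))
    atm <- file.path(pdir, sprintf("pocket%d_atm.pdb", rc$pocket))
    spheres <- NULL
    if (file.exists(vert)) {
      vl <- grep("^(ATOM|HETATM)", readLines(vert), value = TRUE)
      fields <- lapply(strsplit(trimws(vl), "\\s+"), function(f) {
        nf <- length(f)
        as.numeric(f[(nf - 4):nf]) # x y z charge radius
      })
      fm <- do.call(rbind, fields)
      spheres <- new_alpha_spheres(fm[, 1:3, drop = FALSE], fm[, 5],
                                   NULL, rep(NA_real_, nrow(fm)))
    }
    lining <- integer(0)
    if (file.exists(atm)) {
      al <- grep("^(ATOM|HETATM)", readLines(atm), value = TRUE)
      lining <- as.integer(substr(al, 7, 11))
    }
    cav <- structure(list(id = sprintf("fpocket_%d", rc$pocket),
                          spheres = spheres, structure_id = "fpocket",
                          lining_serials = lining),
                     class = "cavity")
    list(pocket = rc$pocket, score = rc$score,
         druggability_score = rc$druggability_score %||% NA_real_,
         volume = rc$volume %||% NA_real_, cavity = cav)
  })
  if (!is.null(score_min))
    out <- Filter(function(rc) rc$score >= score_min, out)
  out
}

#' Export a cavity as a pseudo-atom PDB plus JSON descriptors
#'
#' Sphere centers are written as HETATM pseudo-atoms (APS residues,
#' sphere radius in the B-factor column); descriptors go to a JSON
#' sidecar.
#'
#' @param cavity A `cavity`.
#' @param path Output PDB path (`.json` sidecar written next to it).
#' @param descriptors Optional `cavity_descriptors` to serialize.
#' @return Invisibly, the paths written.
#' @export
write_cavity <- function(cavity, path, descriptors = NULL) {
  sp <- cavity$spheres
  n <- length(sp)
  bio3d::write.pdb(file = path, type = rep("HETATM", n),
                   eleno = seq_len(n), elety = rep("APS", n),
                   resid = rep("APS", n), chain = rep("Z", n),
                   resno = seq_len(n),
                   xyz = as.numeric(t(sp$center)),
                   o = rep(1, n), b = sp$radius, elesy = rep("C", n))
  js <- sub("\\.pdb$", ".json", path)
  jsonlite::write_json(list(id = cavity$id, structure_id = cavity$structure_id,
                            n_spheres = n, descriptors = descriptors),
                       js, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(pdb = path, json = js))
}
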