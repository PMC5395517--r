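## Deterministic synthetic fixtures: toy "pocket proteins" (atom shells
## with carved, pharmacophore-lined cavities and placed pseudo-ligands),
## perturbed structure families, and labeled score rankings.

# residue/atom realization of each lining pharmacophore type; one
# single-atom residue per lining site so rule-table typing recovers the
# requested type exactly
LINING_ATOMS <- data.frame(
  type = c("donor", "acceptor", "anion", "cation", "hydrophobe"),
  resname = c("GLN", "GLN", "ASP", "LYS", "LEU"),
  name = c("NE2", "OE1", "OD1", "NZ", "CD1"),
  element = c("N", "O", "O", "N", "C"),
  stringsAsFactors = FALSE)

#' Specify a synthetic pocket
#'
#' Describes one carved pocket of a toy pocket protein: an invagination
#' along `mouth_direction` with the given depth and width, lined by
#' atoms realizing the requested pharmacophore types.
#'
#' @param center Pocket centroid (3-vector, A).
#' @param mouth_direction Unit 3-vector pointing from the pocket bottom
#'   towards its mouth.
#' @param depth,width Pocket dimensions in angstroms (both > 0).
#' @param lining_types Character multiset over donor, acceptor, anion,
#'   cation, hydrophobe; lining atoms cycle through it.
#' @return A `pocket_spec` list.
#' @export
pocket_spec <- function(center, mouth_direction, depth = 8, width = 7,
                        lining_types = c("donor", "acceptor", "hydrophobe")) {
  stopifnot(length(center) == 3, length(mouth_direction) == 3,
            depth > 0, width > 0, length(lining_types) >= 1)
  if (!all(lining_types %in% LINING_ATOMS$type))
    stop("unknown lining type(s): ",
         paste(setdiff(lining_types, LINING_ATOMS$type), collapse = ", "))
  u <- mouth_direction / sqrt(sum(mouth_direction^2))
  structure(list(center = as.numeric(center), mouth_direction = u,
                 depth = depth, width = width, lining_types = lining_types),
            class = "pocket_spec")
}

# deterministic Fibonacci lattice on a sphere
fib_sphere <- function(n, radius = 1) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (k - 0.5)
  radius * cbind(x = r * cos(th), y = r * sin(th), z = z)
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  tt <- pmin(1, pmax(0, (sweep(p, 2, a) %*% ab) / sum(ab^2)))
  sqrt(rowSums((p - (rep(1, nrow(p)) %o% a + tt %*% t(ab)))^2))
}

segment_segment_dist <- function(a1, b1, a2, b2) {
  # coarse but sufficient: sample each segment
  t1 <- seq(0, 1, length.out = 25)
  p1 <- rep(1, 25) %o% a1 + t1 %*% t(b1 - a1)
  min(vapply(seq_len(25), function(i) min(point_segment_dist(p1[i, , drop = FALSE], a2, b2)),
             numeric(1)))
}

#' Generate a toy pocket protein
#'
#' Builds a deterministic two-layer spherical shell of pseudo-residue
#' atoms, carves each requested pocket as a capsule-shaped invagination,
#' lines it with single-atom residues realizing the requested
#' pharmacophore types, and drops a small rigid pseudo-ligand into each
#' pocket. The ground-truth lining atom sets and pocket centers are
#' returned alongside the structure, so detection and patching can be
#' validated without any external data.
#'
#' @param n_atoms Approximate number of shell atoms before carving.
#' @param shell_radius Outer shell radius (A).
#' @param pockets List of [pocket_spec()] objects (may be empty).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param jitter Small positional noise (A) applied to shell atoms for
#'   geometric genericity.
#' @return A `pocket_protein` list: `structure` (a `pm_structure`),
#'   `pockets` (per pocket: `atoms` ground-truth lining indices,
#'   `serials`, `center`, `spec`), `ligand_atoms` (per pocket: indices
#'   of the placed pseudo-ligand), `seed`.
#' @export
make_pocket_protein <- function(n_atoms = 400, shell_radius = 15,
                                pockets = list(), seed = 1, jitter = 0.15) {
  if (inherits(pockets, "pocket_spec")) pockets <- list(pockets)
  # pockets must fit in the shell and not overlap
  caps <- lapply(pockets, function(p) {
    a <- p$center + p$mouth_direction * p$depth / 2
    b <- p$center - p$mouth_direction * p$depth / 2
    list(a = a, b = b, w = p$width)
  })
  if (length(caps) > 1) {
    for (i in seq_along(caps)[-1]) for (j in seq_len(i - 1)) {
      d <- segment_segment_dist(caps[[i]]$a, caps[[i]]$b, caps[[j]]$a, caps[[j]]$b)
      if (d < (caps[[i]]$w + caps[[j]]$w) / 2 + 2)
        stop("pockets ", j, " and ", i, " overlap")
    }
  }
  with_seed(seed, {
    n_out <- ceiling(0.6 * n_atoms)
    n_in <- n_atoms - n_out
    pts <- rbind(fib_sphere(n_out, shell_radius),
                 fib_sphere(max(n_in, 4), shell_radius - 2.6))
    pts <- pts + matrix(rnorm(length(pts), sd = jitter), ncol = 3)

    keep <- rep(TRUE, nrow(pts))
    for (cp in caps) {
      d <- point_segment_dist(pts, cp$a, cp$b)
      keep <- keep & d > cp$w / 2 + 1.2
    }
    pts <- pts[keep, , drop = FALSE]

    shell <- data.frame(name = "CB", element = "C", resname = "ALA",
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        type = "shell", stringsAsFactors = FALSE)

    lin_list <- list()
    for (pk in seq_along(pockets)) {
      p <- pockets[[pk]]
      u <- p$mouth_direction
      # two orthonormal vectors spanning the plane normal to the axis
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      n_rings <- max(2L, round(p$depth / 2.8))
      ax <- seq(-p$depth / 2, p$depth / 2 - 1, length.out = n_rings)
      rows <- list()
      ti <- 0L
      for (h in ax) {
        n_ring <- max(6L, round(pi * p$width / 3.0))
        ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring + 0.3 * h
        for (aa in ang) {
          ti <- ti + 1L
          typ <- p$lining_types[((ti - 1L) %% length(p$lining_types)) + 1L]
          la <- LINING_ATOMS[LINING_ATOMS$type == typ, ]
          pos <- p$center + h * u + (p$width / 2) * (cos(aa) * e1 + sin(aa) * e2)
          rows[[length(rows) + 1L]] <- data.frame(
            name = la$name, element = la$element, resname = la$resname,
            x = pos[1], y = pos[2], z = pos[3],
            type = paste0("pocket", pk), stringsAsFactors = FALSE)
        }
      }
      # bottom cap
      bot <- p$center - (p$depth / 2 + 1.2) * u
      for (k in 0:3) {
        ti <- ti + 1L
        typ <- p$lining_types[((ti - 1L) %% length(p$lining_types)) + 1L]
        la <- LINING_ATOMS[LINING_ATOMS$type == typ, ]
        off <- if (k == 0) c(0, 0, 0) else 2.6 * (cos(2 * pi * k / 3) * e1 + sin(2 * pi * k / 3) * e2)
        rows[[length(rows) + 1L]] <- data.frame(
          name = la$name, element = la$element, resname = la$resname,
          x = bot[1] + off[1], y = bot[2] + off[2], z = bot[3] + off[3],
          type = paste0("pocket", pk), stringsAsFactors = FALSE)
      }
      lin_list[[pk]] <- do.call(rbind, rows)
    }

    prot <- rbind(shell, if (length(lin_list)) do.call(rbind, lin_list))
    np <- nrow(prot)
    atoms <- data.frame(
      serial = seq_len(np), name = prot$name, element = prot$element,
      resname = prot$resname, resno = seq_len(np), chain = "A",
      x = prot$x, y = prot$y, z = prot$z, record = "protein",
      occupancy = 1, b = 0, hydrogen = FALSE, stringsAsFactors = FALSE)

    # pseudo-ligand: small rigid octahedral cluster at each pocket center
    lig_idx <- list()
    if (length(pockets)) {
      dirs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1), c(0.6, 0.6, 0.6))
      for (pk in seq_along(pockets)) {
        p <- pockets[[pk]]
        # scale the dummy ligand to roughly fill the pocket, like a
        # drug-like ligand does
        lig_r <- 0.3 * min(p$width, p$depth)
        lp <- sweep(lig_r * dirs, 2, p$center, "+")
        lig <- data.frame(
          serial = np + seq_len(nrow(lp)),
          name = paste0("C", seq_len(nrow(lp))), element = "C",
          resname = "LIG", resno = pk, chain = "X",
          x = lp[, 1], y = lp[, 2], z = lp[, 3], record = "ligand",
          occupancy = 1, b = 0, hydrogen = FALSE, stringsAsFactors = FALSE)
        lig_idx[[pk]] <- np + seq_len(nrow(lp))
        atoms <- rbind(atoms, lig)
        np <- nrow(atoms)
      }
    }
    rownames(atoms) <- NULL
    st <- new_structure(sprintf("synth_s%d", seed), atoms,
                        provenance = list(generator = "make_pocket_protein",
                                          seed = seed))
    gt <- lapply(seq_along(pockets), function(pk) {
      idx <- which(prot$type == paste0("pocket", pk))
      list(atoms = idx, serials = atoms$serial[idx],
           center = pockets[[pk]]$center, spec = pockets[[pk]])
    })
    structure(list(structure = st, pockets = gt, ligand_atoms = lig_idx,
                   seed = seed),
              class = "pocket_protein")
  })
}

#' Write a pocket-protein fixture to disk
#'
#' Writes the structure as a PDB file plus a JSON sidecar with the
#' ground truth (pocket atom serials, pocket centers, seed).
#'
#' @param x A `pocket_protein` from [make_pocket_protein()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pocket_fixture <- function(x, dir) {
  stopifnot(inherits(x, "pocket_protein"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(x$structure$id, ".pdb"))
  js <- file.path(dir, paste0(x$structure$id, ".json"))
  write_structure(x$structure, pdb)
  jsonlite::write_json(list(
    id = x$structure$id, seed = x$seed,
    pockets = lapply(x$pockets, function(p)
      list(serials = p$serials, center = p$center)),
    ligand_serials = lapply(x$ligand_atoms, function(i) x$structure$atoms$serial[i])
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = pdb, json = js))
}

#' Generate a family of perturbed structures
#'
#' Emulates an ensemble of structures of the same protein: each member
#' is the base structure plus i.i.d. Gaussian coordinate noise. Member 1
#' is the unperturbed base.
#'
#' @param base A `pm_structure`.
#' @param n_members Number of structures (including the base).
#' @param jitter_sd Per-coordinate noise standard deviation (A).
#' @param seed Integer seed.
#' @return List of `pm_structure` objects.
#' @export
make_structure_family <- function(base, n_members, jitter_sd = 0.3, seed = 1) {
  stopifnot(inherits(base, "pm_structure"), jitter_sd >= 0, n_members >= 1)
  with_seed(seed, {
    lapply(seq_len(n_members), function(k) {
      st <- base
      st$id <- sprintf("%s_m%d", base$id, k)
      if (k > 1 && jitter_sd > 0) {
        xyz <- coords(st) + matrix(rnorm(3 * nrow(st$atoms), sd = jitter_sd), ncol = 3)
        st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
      }
      st$provenance <- c(st$provenance, list(family_member = k, jitter_sd = jitter_sd))
      st
    })
  })
}

#' Generate a labeled score ranking
#'
#' Fixture feeding the retrieval metrics: `perfect` scores every
#' positive above every negative, `random` draws scores independent of
#' the labels, `graded` draws Gaussian scores with mean `mu_shift` for
#' positives and 0 for negatives.
#'
#' @param n Total items; `n_pos` of them positive (0 < n_pos < n).
#' @param n_pos Number of positives.
#' @param enrichment `"perfect"`, `"random"` or `"graded"`.
#' @param mu_shift Mean shift of positive scores for `"graded"`.
#' @param seed Integer seed.
#' @return A `ranking_fixture`: list with `scores`, `labels`
#'   (`"positive"`/`"negative"`), `seed`.
#' @export
make_labeled_ranking <- function(n, n_pos,
                                 enrichment = c("perfect", "random", "graded"),
                                 mu_shift = 1, seed = 1) {
  enrichment <- match.arg(enrichment)
  stopifnot(n_pos > 0, n_pos < n)
  with_seed(seed, {
    labels <- rep("negative", n)
    labels[sample.int(n, n_pos)] <- "positive"
    pos <- labels == "positive"
    scores <- switch(enrichment,
      perfect = ifelse(pos, 1 + runif(n), runif(n)),
      random = runif(n),
      graded = rnorm(n) + ifelse(pos, mu_shift, 0))
    structure(list(scores = scores, labels = labels, seed = seed),
              class = "ranking_fixture")
  })
}
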