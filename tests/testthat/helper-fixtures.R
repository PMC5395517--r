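# Shared fixtures (cached across tests: the generators are pure, so a
# cached object equals a fresh one) and brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

default_pocket_spec <- function(lining_types = c("donor", "acceptor", "hydrophobe")) {
  pocket_spec(center = c(0, 0, 11), mouth_direction = c(0, 0, 1),
              depth = 8, width = 7, lining_types = lining_types)
}

test_pocket_protein <- function(seed = 7) {
  cached(paste0("pp", seed),
         make_pocket_protein(pockets = list(default_pocket_spec()), seed = seed))
}

test_surface <- function(pp) {
  cached(paste0("surf", pp$seed), surface_atoms(pp$structure))
}

test_cavities <- function(pp) {
  cached(paste0("cavs", pp$seed),
         cluster_alpha_spheres(compute_alpha_spheres(pp$structure),
                               structure_id = pp$structure$id))
}

matched_cavity <- function(pp) {
  cavs <- test_cavities(pp)
  id <- match_cavity_to_ligand(cavs, pp$structure, pp$ligand_atoms[[1]])
  cavs[[which(vapply(cavs, function(c) c$id, character(1)) == id)]]
}

# minimal structure straight from an atom table
structure_from_atoms <- function(id, name, element, resname, xyz,
                                 record = "protein", resno = NULL) {
  n <- nrow(xyz)
  pocketmap:::new_structure(id, data.frame(
    serial = seq_len(n), name = name, element = element, resname = resname,
    resno = resno %||% seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    record = record, occupancy = 1, b = 0, hydrogen = FALSE,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built patch (for comparison-stage tests)
simple_patch <- function(id, shape, pc_pos = NULL, pc_type = NULL) {
  pcs <- if (is.null(pc_pos))
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               ptype = character(0), source = I(list()))
  else {
    d <- data.frame(x = pc_pos[, 1], y = pc_pos[, 2], z = pc_pos[, 3],
                    ptype = pc_type, stringsAsFactors = FALSE)
    d$source <- as.list(seq_len(nrow(d)))
    d
  }
  pocketmap:::new_patch(id, paste0("st_", id), list(kind = "ligand", source = 1L),
                        seq_len(nrow(shape)), shape, pcs)
}

rigid_transform_patch <- function(p, rotvec, translation, id = paste0(p$id, "_t")) {
  R <- pocketmap:::rotation_from_vector(rotvec)
  q <- p
  q$id <- id
  q$shape_points <- sweep(p$shape_points %*% t(R), 2, translation, "+")
  if (nrow(p$pseudocenters)) {
    pc <- as.matrix(p$pseudocenters[, c("x", "y", "z")]) %*% t(R)
    q$pseudocenters[, c("x", "y", "z")] <- sweep(pc, 2, translation, "+")
  }
  q
}

## ---- independent oracles ------------------------------------------------

# naive R double-sum Gaussian overlap
brute_overlap <- function(A, B, gamma, ta = NULL, tb = NULL) {
  pref <- (pi / (2 * gamma))^1.5
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (!is.null(ta) && ta[i] != tb[j]) next
    s <- s + exp(-(gamma / 2) * sum((A[i, ] - B[j, ])^2))
  }
  pref * s
}

# Mann-Whitney probability with ties counted one half
auroc_mw <- function(scores, positive) {
  cmp <- outer(scores[positive], scores[!positive],
               function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# reference DBSCAN by direct definition
brute_dbscan <- function(d, eps, min_samples) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    comp <- i
    repeat {
      grow <- unique(unlist(nb[comp[core[comp]]]))
      grow <- grow[core[grow]]
      new <- setdiff(grow, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    labels[comp] <- cid
  }
  for (i in which(!core)) {
    reach <- labels[nb[[i]][core[nb[[i]]]]]
    reach <- reach[reach != 0L]
    if (length(reach)) labels[i] <- min(reach)
  }
  labels
}

# naive average-linkage agglomeration: returns sorted merge heights
brute_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-1]) for (j in seq_len(i - 1)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Truchon-Bayly analytic BEDROC (independent formulation; agrees with
# the discrete-normalization implementation to O(1/N))
bedroc_analytic <- function(scores, positive, alpha) {
  N <- length(scores); n <- sum(positive)
  Ra <- n / N
  r <- which(positive[order(-scores)])
  rie <- sum(exp(-alpha * r / N)) / (n * (1 - exp(-alpha)) / (N * (exp(alpha / N) - 1)))
  rie * Ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# brute-force rigid-body RMSD minimization (oracle for superpose)
brute_min_rmsd <- function(X, Y) {
  obj <- function(par) {
    R <- pocketmap:::rotation_from_vector(par[1:3])
    Xt <- sweep(X %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((Xt - Y)^2)))
  }
  best <- Inf
  for (s in list(rep(0, 6), c(0.5, -0.3, 0.2, 1, -1, 1), c(-1, 1, 2, 0, 0, 0))) {
    o <- stats::optim(s, obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "HETATM    3  O   HOH A   2       5.000   5.000   5.000  1.00 20.00           O",
    "HETATM    4  C1  ATP A   3       8.000   2.000   1.000  1.00 15.00           C",
    "END")
  writeLines(lines, path)
  path
}

# continuous synthetic true-site score sets for threshold calibration
with_seed_scores <- function(seed) {
  set.seed(seed)
  switch(seed %% 3 + 1,
         rnorm(137, mean = 20, sd = 6),
         rexp(211, rate = 0.1),
         runif(163, 0, 50))
}

# Three synthetic protein targets, 15 structures each. Targets A and B
# carry the same pocket archetype (polar lining); target C carries a
# different, all-hydrophobe archetype. Full pipeline: detection ->
# cavity patches -> all-vs-all PatchScores -> conservation filter ->
# per-target DBSCAN -> cluster links.
three_target_experiment <- function() {
  cached("three_target", {
    archetype_AB <- pocket_spec(c(0, 0, 11), c(0, 0, 1), depth = 8, width = 7,
                                lining_types = c("donor", "acceptor", "cation"))
    archetype_C <- pocket_spec(c(0, 0, 11), c(0, 0, 1), depth = 6.5, width = 6,
                               lining_types = "hydrophobe")
    bases <- list(A = make_pocket_protein(pockets = list(archetype_AB), seed = 101),
                  B = make_pocket_protein(pockets = list(archetype_AB), seed = 202),
                  C = make_pocket_protein(pockets = list(archetype_C), seed = 303))
    patches <- list()
    targets <- character(0)
    for (tg in names(bases)) {
      base <- bases[[tg]]
      fam <- make_structure_family(base$structure, 15, jitter_sd = 0.2,
                                   seed = match(tg, names(bases)))
      for (st in fam) {
        st$id <- paste0(tg, "_", st$provenance$family_member)
        cavs <- cluster_alpha_spheres(compute_alpha_spheres(st),
                                      structure_id = st$id)
        id <- match_cavity_to_ligand(cavs, st, base$ligand_atoms[[1]])
        if (is.null(id)) next
        cav <- cavs[[which(vapply(cavs, function(c) c$id, character(1)) == id)]]
        surf <- surface_atoms(st)
        p <- tryCatch(patch_from_cavity(st, cav, surface = surf),
                      error = function(e) NULL)
        if (is.null(p)) next
        patches[[length(patches) + 1]] <- p
        targets <- c(targets, tg)
      }
    }
    sm <- all_vs_all(patches, target_labels = targets)
    cm <- binding_site_map(sm)
    lt <- cluster_link_table(cm, sm)
    list(similarity = sm, map = cm, link_table = lt,
         n_patches = length(patches), targets = targets)
  })
}
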