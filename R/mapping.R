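## Binding-site maps from similarity matrices: conservation filtering,
## within-target and global clustering (average-linkage hierarchical
## and DBSCAN), cluster-pair link tables and file exports (heat-map
## matrix, Circos-compatible karyotype/link files, JSON summary).

#' Conservation filter
#'
#' Retains a patch when at least `min_links` of its off-diagonal
#' PatchScores reach `threshold`, removing non-conserved,
#' information-poor patches. A single pass on the original matrix (the
#' rule is not iterated after removals).
#'
#' @param matrix A `similarity_matrix` (or square symmetric matrix with
#'   dimnames).
#' @param min_links Minimum number of qualifying links (default 5).
#' @param threshold PatchScore threshold (default 2.0).
#' @return Character vector of retained patch ids.
#' @export
conservation_filter <- function(matrix, min_links = 5, threshold = 2.0) {
  S <- if (inherits(matrix, "similarity_matrix")) matrix$scores else as.matrix(matrix)
  stopifnot(nrow(S) == ncol(S))
  diag(S) <- NA
  links <- rowSums(S >= threshold, na.rm = TRUE)
  rownames(S)[links >= min_links]
}

sim_subset <- function(sm, ids) {
  keep <- match(ids, sm$patch_ids)
  structure(list(patch_ids = sm$patch_ids[keep],
                 target_labels = sm$target_labels[keep],
                 scores = sm$scores[keep, keep, drop = FALSE],
                 params = sm$params),
            class = "similarity_matrix")
}

# feature rows: each patch is represented by its vector of PatchScores
# over the given column set (NA scores as 0 contribution)
score_features <- function(S, rows, cols) {
  F <- S[rows, cols, drop = FALSE]
  F[is.na(F)] <- 0
  F
}

#' Hierarchical clustering of binding sites
#'
#' Average-linkage agglomerative clustering on Euclidean distances
#' between PatchScore row vectors. At `level = "within_target"` each
#' target is clustered separately using only its own columns (local
#' structure); at `level = "global"` all retained patches are clustered
#' over all retained columns.
#'
#' @param matrix A `similarity_matrix` (typically already restricted to
#'   [conservation_filter()] survivors).
#' @param level `"global"` or `"within_target"`.
#' @param k Optional flat cluster count for a dendrogram cut.
#' @return For `"global"`: list with `hclust`, `order` (leaf order as
#'   patch ids) and optional `labels`. For `"within_target"`: a named
#'   list of such records, one per target (singleton targets yield a
#'   trivial record and a message).
#' @export
hierarchical_map <- function(matrix, level = c("global", "within_target"),
                             k = NULL) {
  level <- match.arg(level)
  sm <- matrix
  stopifnot(inherits(sm, "similarity_matrix"))
  one <- function(rows, cols) {
    ids <- sm$patch_ids[rows]
    if (length(rows) < 2) {
      message("singleton cluster set (", ids, "): trivial dendrogram")
      return(list(hclust = NULL, order = ids,
                  labels = if (!is.null(k)) setNames(1L, ids)))
    }
    F <- score_features(sm$scores, rows, cols)
    hc <- stats::hclust(dist(F), method = "average")
    hc$labels <- ids
    list(hclust = hc, order = ids[hc$order],
         labels = if (!is.null(k)) stats::cutree(hc, k = min(k, length(rows))))
  }
  if (level == "global") {
    one(seq_along(sm$patch_ids), seq_along(sm$patch_ids))
  } else {
    targets <- unique(sm$target_labels)
    setNames(lapply(targets, function(tg) {
      rows <- which(sm$target_labels == tg)
      one(rows, rows)
    }), targets)
  }
}

#' DBSCAN clustering of binding sites
#'
#' Density-based clustering with noise on the same feature space as
#' [hierarchical_map()]: Euclidean distances between PatchScore row
#' vectors. A core point has at least `min_samples` neighbors within
#' `eps` (itself included); clusters are the connected components of
#' core points at distance `eps`, border points join the
#' lowest-numbered reachable core cluster, and everything else is noise
#' (label 0). The core partition is independent of input order.
#'
#' @param matrix A `similarity_matrix`.
#' @param eps Neighborhood radius (default 7, consistent with
#'   PatchScore row-vector distances).
#' @param min_samples Minimum neighborhood size for a core point
#'   (default 10).
#' @param rows,cols Optional row/column subsets (indices into the
#'   matrix) for per-target clustering.
#' @return Integer labels per (subset) patch: 0 = noise, clusters
#'   numbered from 1 in order of their lowest member index.
#' @export
dbscan_map <- function(matrix, eps = 7.0, min_samples = 10,
                       rows = NULL, cols = NULL) {
  S <- if (inherits(matrix, "similarity_matrix")) matrix$scores else as.matrix(matrix)
  rows <- rows %||% seq_len(nrow(S))
  cols <- cols %||% rows
  F <- score_features(S, rows, cols)
  n <- nrow(F)
  d <- as.matrix(dist(F))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in nb[[v]]) {
        if (labels[u] == 0L) {
          labels[u] <- cid
          if (core[u]) queue <- c(queue, u)
        }
      }
    }
  }
  # border points reachable from several clusters: lowest cluster id
  for (i in which(!core & labels != 0L)) {
    reach <- unique(labels[nb[[i]][core[nb[[i]]]]])
    reach <- reach[reach != 0L]
    if (length(reach)) labels[i] <- min(reach)
  }
  labels
}

#' Build a binding-site cluster map
#'
#' The full mapping stage: conservation filtering, per-target DBSCAN
#' cluster labels, per-target and global average-linkage dendrograms,
#' and the global heat-map leaf order.
#'
#' @param matrix A `similarity_matrix` over all patches.
#' @param min_links,link_threshold Conservation filter parameters
#'   (default: at least 5 PatchScores >= 2.0).
#' @param eps,min_samples DBSCAN parameters (default 7 and 10).
#' @param k Optional flat cut count for the hierarchical labels.
#' @return A `cluster_map`: `retained_ids`, `per_target_labels` (data
#'   frame patch_id / target / cluster, cluster 0 = noise),
#'   `global_order`, `dendrograms` (`global` + `within_target`),
#'   `parameters`.
#' @export
binding_site_map <- function(matrix, min_links = 5, link_threshold = 2.0,
                             eps = 7.0, min_samples = 10, k = NULL) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  retained <- conservation_filter(matrix, min_links, link_threshold)
  if (length(retained) < 2) stop("fewer than 2 patches retained by the conservation filter")
  sm <- sim_subset(matrix, retained)

  targets <- unique(sm$target_labels)
  lab <- do.call(rbind, lapply(targets, function(tg) {
    rows <- which(sm$target_labels == tg)
    cl <- dbscan_map(sm, eps = eps, min_samples = min_samples, rows = rows)
    data.frame(patch_id = sm$patch_ids[rows], target = tg, cluster = cl,
               stringsAsFactors = FALSE)
  }))
  lab <- lab[match(sm$patch_ids, lab$patch_id), ]
  rownames(lab) <- NULL

  dendro <- list(global = hierarchical_map(sm, "global", k = k),
                 within_target = hierarchical_map(sm, "within_target", k = k))
  structure(list(retained_ids = sm$patch_ids,
                 per_target_labels = lab,
                 global_order = dendro$global$order,
                 dendrograms = dendro,
                 parameters = list(min_links = min_links,
                                   link_threshold = link_threshold,
                                   eps = eps, min_samples = min_samples)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  nt <- length(unique(x$per_target_labels$target))
  ncl <- sum(tapply(x$per_target_labels$cluster, x$per_target_labels$target,
                    function(v) length(unique(v[v != 0]))))
  cat("cluster_map:", length(x$retained_ids), "retained patches,",
      nt, "target(s),", ncl, "DBSCAN cluster(s),",
      sum(x$per_target_labels$cluster == 0), "noise\n")
  invisible(x)
}

#' Cluster-pair link table
#'
#' One row per unordered pair of (target, cluster) groups with at least
#' one scored cross pair, carrying the maximum PatchScore between their
#' members; links at or above `highlight_threshold` are flagged (the
#' red-ribbon convention of circular binding-site maps). Noise patches
#' (cluster 0) are excluded.
#'
#' @param cluster_map A `cluster_map` (or its `per_target_labels` data
#'   frame).
#' @param matrix The `similarity_matrix` the labels came from.
#' @param highlight_threshold PatchScore highlight cutoff (default 2.0).
#' @return A `link_table` data frame: target_a, cluster_a, target_b,
#'   cluster_b, max_patch_score, highlighted, same_target.
#' @export
cluster_link_table <- function(cluster_map, matrix, highlight_threshold = 2.0) {
  lab <- if (inherits(cluster_map, "cluster_map")) cluster_map$per_target_labels
  else cluster_map
  lab <- lab[lab$cluster != 0, , drop = FALSE]
  S <- if (inherits(matrix, "similarity_matrix")) matrix$scores else as.matrix(matrix)
  grp <- paste(lab$target, lab$cluster, sep = "\r")
  groups <- unique(grp)
  rows <- list()
  if (length(groups) >= 2) {
    for (i in seq_along(groups)[-1]) for (j in seq_len(i - 1)) {
      mi <- match(lab$patch_id[grp == groups[i]], rownames(S))
      mj <- match(lab$patch_id[grp == groups[j]], rownames(S))
      cross <- S[mi, mj, drop = FALSE]
      if (all(is.na(cross))) next
      gi <- strsplit(groups[i], "\r")[[1]]; gj <- strsplit(groups[j], "\r")[[1]]
      ord <- order(c(groups[j], groups[i]))
      pair <- list(gj, gi)[ord]
      rows[[length(rows) + 1]] <- data.frame(
        target_a = pair[[1]][1], cluster_a = as.integer(pair[[1]][2]),
        target_b = pair[[2]][1], cluster_b = as.integer(pair[[2]][2]),
        max_patch_score = max(cross, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(target_a = character(0), cluster_a = integer(0),
                  target_b = character(0), cluster_b = integer(0),
                  max_patch_score = numeric(0))
  tab$highlighted <- tab$max_patch_score >= highlight_threshold
  tab$same_target <- tab$target_a == tab$target_b
  tab <- tab[order(tab$target_a, tab$cluster_a, tab$target_b, tab$cluster_b), ]
  rownames(tab) <- NULL
  class(tab) <- c("link_table", "data.frame")
  tab
}

#' Write binding-site map outputs
#'
#' Writes (1) the similarity matrix reordered by the global leaf order
#' plus its id list, for heat-map rendering, (2) a raster heat map
#' (PNG), (3) Circos-compatible karyotype and link files (targets as
#' outer segments, DBSCAN clusters as bands, highlighted links
#' flagged by color), and (4) a JSON summary with cluster sizes and
#' parameters. Text outputs are byte-stable given identical inputs.
#'
#' @param cluster_map A `cluster_map`.
#' @param link_table A `link_table`.
#' @param matrix The `similarity_matrix` (full or retained).
#' @param out_dir Output directory (created if needed).
#' @param png Also render the built-in raster heat map.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_map_outputs <- function(cluster_map, link_table, matrix, out_dir,
                              png = TRUE) {
  stopifnot(inherits(cluster_map, "cluster_map"))
  S <- if (inherits(matrix, "similarity_matrix")) matrix$scores else as.matrix(matrix)
  ord <- cluster_map$global_order
  if (!all(ord %in% rownames(S))) stop("id mismatch between cluster map and matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  M <- S[ord, ord]

  paths <- c(matrix = file.path(out_dir, "heatmap_matrix.tsv"),
             ids = file.path(out_dir, "heatmap_order.txt"),
             karyotype = file.path(out_dir, "circos_karyotype.txt"),
             links = file.path(out_dir, "circos_links.txt"),
             summary = file.path(out_dir, "map_summary.json"))
  utils::write.table(format(M, digits = 10, trim = TRUE), paths["matrix"],
                     sep = "\t", quote = FALSE, col.names = NA)
  writeLines(ord, paths["ids"])

  # Circos karyotype: one chromosome per target, band per cluster;
  # coordinates count patches
  lab <- cluster_map$per_target_labels
  targets <- sort(unique(lab$target))
  kar <- character(0)
  for (tg in targets) {
    sub <- lab[lab$target == tg, ]
    kar <- c(kar, sprintf("chr - %s %s 0 %d grey", tg, tg, nrow(sub)))
    off <- 0
    for (cl in sort(unique(sub$cluster[sub$cluster != 0]))) {
      n <- sum(sub$cluster == cl)
      kar <- c(kar, sprintf("band %s cl%d cl%d %d %d gpos50", tg, cl, cl, off, off + n))
      off <- off + n
    }
  }
  writeLines(kar, paths["karyotype"])

  lt <- as.data.frame(link_table)
  lnk <- if (nrow(lt)) sprintf(
    "%s %d %d %s %d %d color=%s,score=%.3f",
    lt$target_a, lt$cluster_a - 1L, lt$cluster_a,
    lt$target_b, lt$cluster_b - 1L, lt$cluster_b,
    ifelse(lt$highlighted, "red", "grey"), lt$max_patch_score) else character(0)
  writeLines(lnk, paths["links"])

  cl_sizes <- stats::aggregate(patch_id ~ target + cluster,
                               lab[lab$cluster != 0, ], length)
  jsonlite::write_json(list(
    retained = length(cluster_map$retained_ids),
    noise = sum(lab$cluster == 0),
    clusters = if (nrow(cl_sizes)) lapply(seq_len(nrow(cl_sizes)), function(i)
      list(target = cl_sizes$target[i], cluster = cl_sizes$cluster[i],
           size = cl_sizes$patch_id[i])) else list(),
    parameters = cluster_map$parameters
  ), paths["summary"], auto_unbox = TRUE, digits = NA)

  if (png) {
    paths <- c(paths, heatmap = file.path(out_dir, "heatmap.png"))
    grDevices::png(paths["heatmap"], width = 800, height = 800)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    graphics::image(t(M[rev(seq_len(nrow(M))), ]), axes = FALSE,
                    main = "PatchScore heat map",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    zlim = c(0, 4))
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(paths)
}
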