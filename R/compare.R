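## Pairwise patch comparison: Gaussian shape/color overlap, Tanimoto
## coefficients, multi-start rigid alignment maximizing the 3:1
## color:shape PatchScore, and all-against-all similarity matrices.

#' Gaussian overlap of two typed point sets
#'
#' Exact double sum of atom-centered Gaussian products,
#' `sum_ij delta(type_i, type_j) * (pi / (2 gamma))^(3/2) *
#' exp(-(gamma/2) d_ij^2)`. When `type_matched` is `TRUE` cross terms
#' are restricted to equal pharmacophore types; otherwise all pairs
#' contribute (shape overlap).
#'
#' @param points_a,points_b n x 3 coordinate matrices.
#' @param gamma Gaussian width parameter (1/A^2, > 0).
#' @param types_a,types_b Type labels per point (required when
#'   `type_matched`).
#' @param type_matched Restrict to equal-type cross terms.
#' @return Non-negative overlap value.
#' @export
gaussian_overlap <- function(points_a, points_b, gamma,
                             types_a = NULL, types_b = NULL,
                             type_matched = FALSE) {
  stopifnot(gamma > 0)
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  if (type_matched) {
    lv <- unique(c(types_a, types_b))
    ta <- match(types_a, lv); tb <- match(types_b, lv)
  } else {
    ta <- integer(nrow(A)); tb <- integer(nrow(B))
  }
  .gaussian_overlap_cpp(A, B, as.integer(ta), as.integer(tb),
                        gamma, isTRUE(type_matched))
}

#' Tanimoto coefficient from overlap values
#'
#' `T = o_ab / (o_aa + o_bb - o_ab)`, clipped into `[0, 1]` (clipping
#' is reported via `message`). Requires strictly positive self
#' overlaps.
#'
#' @param o_ab Cross overlap.
#' @param o_aa,o_bb Self overlaps.
#' @return Tanimoto value in `[0, 1]`.
#' @export
overlap_tanimoto <- function(o_ab, o_aa, o_bb) {
  if (o_aa <= 0 || o_bb <= 0) stop("non-positive self-overlap")
  t <- o_ab / (o_aa + o_bb - o_ab)
  if (t < 0 || t > 1) {
    message("overlap Tanimoto ", format(t), " clipped to [0,1]")
    t <- min(1, max(0, t))
  }
  t
}

# Rodrigues rotation from a rotation vector
rotation_from_vector <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# principal axes with a deterministic sign convention (det +1)
principal_axes <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  E <- eigen(crossprod(Pc) / max(1, nrow(P) - 1), symmetric = TRUE)$vectors
  for (j in 1:3) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  if (det(E) < 0) E[, 3] <- -E[, 3]
  E
}

patch_color_points <- function(p) {
  pc <- p$pseudocenters
  list(pos = as.matrix(pc[, c("x", "y", "z"), drop = FALSE]),
       type = match(pc$ptype, pharmacophore_types()))
}

#' Align two binding-site patches
#'
#' Finds the rigid transform of `b` maximizing the PatchScore
#' combination `3 * T_color + T_shape`, where both terms are Gaussian
#' overlap Tanimotos (color restricted to equal pharmacophore types).
#' Optimization is deterministic: starts are centroid-superposed
#' principal-axes alignments of the shape points and of the
#' pseudocenters (color carries three quarters of the objective weight,
#' so a color-based start is as informative as a shape-based one), each
#' with its three 180-degree axis flips; every start is refined by a
#' local Nelder-Mead search over the six rigid degrees of freedom and
#' the best result is kept. A start whose refined objective reaches the
#' maximum attainable value (4) short-circuits the remaining starts.
#'
#' @param a,b `patch` objects.
#' @param gamma_shape,gamma_color Gaussian widths (1/A^2); the color
#'   kernel is narrower so pharmacophore matches must be tighter.
#' @param n_starts Number of deterministic starts (1-8; starts
#'   alternate shape-based and color-based).
#' @param tol Relative convergence tolerance of the local search.
#' @param maxit Iteration cap per start.
#' @return An `alignment` object: `rotation`, `translation` (apply to
#'   `b` as `x %*% t(rotation) + translation`), `shape_tanimoto`,
#'   `color_tanimoto`, `patch_score` (= 3 color + 1 shape, in [0, 4]),
#'   `n_starts_used`, `converged`.
#' @export
align_patches <- function(a, b, gamma_shape = 0.3, gamma_color = 0.5,
                          n_starts = 8, tol = 1e-6, maxit = 300) {
  stopifnot(inherits(a, "patch"), inherits(b, "patch"))
  n_starts <- max(1L, min(8L, as.integer(n_starts)))
  As <- a$shape_points; Bs <- b$shape_points
  Ac <- patch_color_points(a); Bc <- patch_color_points(b)
  has_color <- nrow(Ac$pos) > 0 && nrow(Bc$pos) > 0

  o_aa_s <- .gaussian_overlap_cpp(As, As, integer(nrow(As)), integer(nrow(As)),
                                  gamma_shape, FALSE)
  o_bb_s <- .gaussian_overlap_cpp(Bs, Bs, integer(nrow(Bs)), integer(nrow(Bs)),
                                  gamma_shape, FALSE)
  o_aa_c <- o_bb_c <- 1
  if (has_color) {
    o_aa_c <- .gaussian_overlap_cpp(Ac$pos, Ac$pos, Ac$type, Ac$type, gamma_color, TRUE)
    o_bb_c <- .gaussian_overlap_cpp(Bc$pos, Bc$pos, Bc$type, Bc$type, gamma_color, TRUE)
    if (o_aa_c <= 0 || o_bb_c <= 0) has_color <- FALSE
  }
  cpos0 <- matrix(numeric(0), 0, 3)
  evaluate <- function(R, tr) {
    v <- .patch_objective_cpp(As, Bs,
                              if (has_color) Ac$pos else cpos0,
                              if (has_color) Bc$pos else cpos0,
                              if (has_color) Ac$type else integer(0),
                              if (has_color) Bc$type else integer(0),
                              gamma_shape, gamma_color,
                              o_aa_s, o_bb_s, o_aa_c, o_bb_c, has_color,
                              R, tr)
    list(objective = v[1], shape = v[2], color = v[3])
  }

  ca_s <- colMeans(As); cb_s <- colMeans(Bs)
  frames <- list(list(Ea = principal_axes(As), Eb = principal_axes(Bs),
                      ca = ca_s, cb = cb_s))
  if (has_color && nrow(Ac$pos) >= 3 && nrow(Bc$pos) >= 3)
    frames[[2]] <- list(Ea = principal_axes(Ac$pos), Eb = principal_axes(Bc$pos),
                        ca = colMeans(Ac$pos), cb = colMeans(Bc$pos))
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  # alternate shape-based and color-based starts, flip by flip
  starts <- list()
  for (fl in flips) for (fr in frames) {
    R0 <- fr$Ea %*% fl %*% t(fr$Eb)
    starts[[length(starts) + 1]] <- list(R0 = R0,
                                         t0 = as.numeric(fr$ca - R0 %*% fr$cb))
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  best <- NULL
  converged <- FALSE
  used <- 0L
  for (s0 in starts) {
    used <- used + 1L
    fn <- function(par) {
      R <- rotation_from_vector(par[1:3]) %*% s0$R0
      -evaluate(R, s0$t0 + par[4:6])$objective
    }
    # Nelder-Mead with fresh-simplex restarts: a single 6-dim simplex
    # can collapse prematurely on a curved ridge
    opt <- stats::optim(rep(0, 6), fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = tol))
    for (round in 1:3) {
      opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = tol))
      if (opt2$value < opt$value - 1e-9) opt <- opt2 else { opt <- opt2; break }
    }
    # gradient-based polish of the simplex optimum
    opt3 <- stats::optim(opt$par, fn, method = "BFGS",
                         control = list(maxit = 100, reltol = tol))
    if (opt3$value < opt$value) opt <- opt3
    R <- rotation_from_vector(opt$par[1:3]) %*% s0$R0
    tr <- s0$t0 + opt$par[4:6]
    ev <- evaluate(R, tr)
    if (is.null(best) || ev$objective > best$objective)
      best <- c(ev, list(rotation = R, translation = tr))
    if (opt$convergence == 0) converged <- TRUE
    if (best$objective >= 4 - 1e-6) break
  }
  structure(list(rotation = best$rotation, translation = best$translation,
                 shape_tanimoto = best$shape, color_tanimoto = best$color,
                 patch_score = best$objective, n_starts_used = used,
                 converged = converged),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("patch alignment: PatchScore %.3f (color %.3f, shape %.3f)%s\n",
              x$patch_score, x$color_tanimoto, x$shape_tanimoto,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' PatchScore of two patches
#'
#' `3 * color_tanimoto + 1 * shape_tanimoto` from the best alignment,
#' a continuous value between 0 (complete dissimilarity) and 4 (perfect
#' similarity). Computed once per unordered pair: arguments are
#' canonically ordered by patch id, so the score is exactly symmetric.
#'
#' @param a,b `patch` objects.
#' @param ... Passed to [align_patches()].
#' @return Numeric score in `[0, 4]`.
#' @export
patch_score <- function(a, b, ...) {
  if (is.character(b$id) && is.character(a$id) && b$id < a$id) {
    tmp <- a; a <- b; b <- tmp
  }
  align_patches(a, b, ...)$patch_score
}

#' All-against-all patch comparison
#'
#' Computes the symmetric matrix of PatchScores over every unordered
#' patch pair (plus self-alignments on the diagonal). Individual pair
#' failures are recorded as `NA`, not fatal. With `store` set, per-pair
#' results are appended to a TSV log as they complete and reloaded on
#' rerun, so an interrupted computation resumes where it stopped.
#'
#' @param patches List of `patch` objects with unique ids.
#' @param target_labels Optional per-patch target label (e.g. the
#'   protein the structure belongs to); defaults to the structure id.
#' @param store Optional path to an append-only per-pair score log.
#' @param verbose Log progress via `message`.
#' @param ... Passed to [align_patches()].
#' @return A `similarity_matrix`: `patch_ids`, `target_labels`,
#'   `scores` (symmetric, diagonal = self scores), `params`.
#' @export
all_vs_all <- function(patches, target_labels = NULL, store = NULL,
                       verbose = FALSE, ...) {
  stopifnot(length(patches) >= 2)
  ids <- vapply(patches, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("patch ids must be unique")
  if (is.null(target_labels))
    target_labels <- vapply(patches, function(p) p$structure_id, character(1))
  n <- length(patches)
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))

  done <- new.env(parent = emptyenv())
  if (!is.null(store) && file.exists(store)) {
    log <- utils::read.table(store, sep = "\t", header = FALSE,
                             col.names = c("a", "b", "score"),
                             stringsAsFactors = FALSE)
    for (r in seq_len(nrow(log)))
      assign(paste(log$a[r], log$b[r], sep = "\r"), log$score[r], envir = done)
  }
  record <- function(ia, ib, s) {
    if (!is.null(store))
      cat(sprintf("%s\t%s\t%.17g\n", ia, ib, s), file = store, append = TRUE)
  }
  ord <- order(ids)
  for (ii in seq_len(n)) {
    i <- ord[ii]
    for (jj in ii:n) {
      j <- ord[jj]
      key <- paste(ids[i], ids[j], sep = "\r")
      s <- if (exists(key, envir = done)) get(key, envir = done)
      else tryCatch({
        v <- patch_score(patches[[i]], patches[[j]], ...)
        record(ids[i], ids[j], v)
        v
      }, error = function(e) {
        warning("pair (", ids[i], ", ", ids[j], ") failed: ",
                conditionMessage(e))
        NA_real_
      })
      S[i, j] <- s; S[j, i] <- s
    }
    if (verbose) message("all_vs_all: ", ii, "/", n, " rows done")
  }
  structure(list(patch_ids = ids, target_labels = target_labels,
                 scores = S, params = list(...)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", length(x$patch_ids), "patches,",
      length(unique(x$target_labels)), "target(s)\n")
  off <- x$scores[upper.tri(x$scores)]
  if (length(off))
    cat(sprintf("  off-diagonal PatchScore: median %.2f, max %.2f, NA %d\n",
                stats::median(off, na.rm = TRUE), max(off, na.rm = TRUE),
                sum(is.na(off))))
  invisible(x)
}

#' Write a similarity matrix as delimited text plus JSON metadata
#'
#' @param sm A `similarity_matrix`.
#' @param path Output TSV path; a `.json` sidecar with target labels
#'   and parameters is written next to it.
#' @return Invisibly, the paths written.
#' @export
write_similarity_matrix <- function(sm, path) {
  utils::write.table(format(sm$scores, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  js <- sub("\\.(tsv|txt)$", "", path)
  js <- paste0(js, ".json")
  jsonlite::write_json(list(patch_ids = sm$patch_ids,
                            target_labels = sm$target_labels,
                            params = sm$params),
                       js, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(matrix = path, meta = js))
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#' @param path TSV path.
#' @return A `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  js <- paste0(sub("\\.(tsv|txt)$", "", path), ".json")
  meta <- if (file.exists(js)) jsonlite::read_json(js, simplifyVector = TRUE)
  else list(patch_ids = rownames(m), target_labels = rownames(m), params = list())
  structure(list(patch_ids = meta$patch_ids, target_labels = meta$target_labels,
                 scores = m, params = meta$params),
            class = "similarity_matrix")
}
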