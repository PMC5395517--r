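## Retrieval evaluation: ROC/AUROC, enrichment factor, BEDROC, and the
## query-against-database protocol with per-structure true-positive
## deduplication.

#' Construct a ranked list
#'
#' @param item_ids Item identifiers.
#' @param scores Numeric scores (higher = retrieved earlier).
#' @param labels `"positive"`, `"negative"` or `"ignored"`; ignored
#'   items are excluded from every metric.
#' @return A `ranked_list`.
#' @export
ranked_list <- function(item_ids, scores, labels) {
  stopifnot(length(item_ids) == length(scores),
            length(scores) == length(labels),
            all(labels %in% c("positive", "negative", "ignored")))
  structure(list(item_ids = item_ids, scores = as.numeric(scores),
                 labels = labels),
            class = "ranked_list")
}

ranked_kept <- function(ranked) {
  k <- ranked$labels != "ignored"
  list(scores = ranked$scores[k], pos = ranked$labels[k] == "positive")
}

#' ROC curve points
#'
#' Threshold sweep over the distinct scores with ties grouped (all tied
#' items enter together, producing a diagonal segment). Starts at
#' (0, 0) and ends at (1, 1); both coordinates are monotone
#' non-decreasing.
#'
#' @param ranked A `ranked_list` with at least one positive and one
#'   negative.
#' @return Two-column matrix of (fpr, tpr).
#' @export
roc_points <- function(ranked) {
  kp <- ranked_kept(ranked)
  P <- sum(kp$pos); N <- sum(!kp$pos)
  if (P == 0 || N == 0) stop("need at least one positive and one negative")
  o <- order(-kp$scores)
  s <- kp$scores[o]; y <- kp$pos[o]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- cumsum(y)[ends] / P
  fpr <- cumsum(!y)[ends] / N
  unname(rbind(c(0, 0), cbind(fpr, tpr)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of [roc_points()]; identical to the Mann-Whitney
#' probability that a random positive outscores a random negative, with
#' ties counted one half.
#'
#' @param ranked A `ranked_list`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(ranked) {
  rp <- roc_points(ranked)
  sum(diff(rp[, 1]) * (rp[-1, 2] + rp[-nrow(rp), 2]) / 2)
}

#' Enrichment factor at a fraction of the ranking
#'
#' Ratio of the positive rate in the top `m = ceiling(fraction * n)`
#' items (descending score, ties at the cutoff broken by stable input
#' order) to the positive rate in the whole list.
#'
#' @param ranked A `ranked_list` with at least one positive.
#' @param fraction Initial portion of the ranking (default 5%).
#' @return EF value; 1 means no enrichment.
#' @export
enrichment_factor <- function(ranked, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  kp <- ranked_kept(ranked)
  n <- length(kp$scores)
  P <- sum(kp$pos)
  stopifnot(P >= 1)
  m <- ceiling(fraction * n)
  top <- order(-kp$scores)[seq_len(m)] # stable for ties: input order
  (sum(kp$pos[top]) / m) / (P / n)
}

# exponentially weighted positive-rank sum used by bedroc()
bedroc_weight_sum <- function(ranks, alpha, n_total) {
  sum(exp(-alpha * ranks / n_total))
}

#' BEDROC: Boltzmann-enhanced discrimination ROC
#'
#' Exponentially down-weights late ranks so that early recognition of
#' positives dominates: the sum of `exp(-alpha * rank / N)` over
#' positive ranks, normalized to `[0, 1]` by its exact extremes (all
#' positives first, respectively last). Ranks come from a stable
#' descending-score sort, so tie order follows input order.
#'
#' @param ranked A `ranked_list`.
#' @param alpha Early-recognition weight (default 20: roughly the first
#'   8% of the ranking carries 80% of the weight).
#' @return BEDROC in `[0, 1]`: 1 for a perfect ranking, 0 for a fully
#'   inverted one.
#' @export
bedroc <- function(ranked, alpha = 20.0) {
  stopifnot(alpha > 0)
  kp <- ranked_kept(ranked)
  N <- length(kp$scores)
  n <- sum(kp$pos)
  if (n == 0 || n == N) stop("need at least one positive and one negative")
  ranks <- which(kp$pos[order(-kp$scores)])
  s <- bedroc_weight_sum(ranks, alpha, N)
  s_max <- bedroc_weight_sum(seq_len(n), alpha, N)
  s_min <- bedroc_weight_sum(N - n + seq_len(n), alpha, N)
  (s - s_min) / (s_max - s_min)
}

#' Run a retrieval experiment for one query patch
#'
#' Scores the query against every database patch, labels the result by
#' protein identity with per-structure deduplication (for each
#' structure sharing the query's identity only its best-scoring patch
#' counts as positive; its remaining patches are ignored, removing them
#' from both numerator and denominator), and computes AUROC, EF and
#' BEDROC.
#'
#' @param query A `patch` (must not be in `database`).
#' @param database List of `patch` objects.
#' @param identity_labels Protein identity per database patch.
#' @param query_identity The query's protein identity.
#' @param structure_ids Structure of origin per database patch;
#'   defaults to each patch's `structure_id`.
#' @param ef_fraction,bedroc_alpha Metric parameters.
#' @param ... Passed to [align_patches()].
#' @return List with `ranked` (a `ranked_list`) and `metrics`
#'   (`auroc`, `ef`, `bedroc`).
#' @export
run_retrieval <- function(query, database, identity_labels, query_identity,
                          structure_ids = NULL, ef_fraction = 0.05,
                          bedroc_alpha = 20, ...) {
  stopifnot(length(database) == length(identity_labels))
  if (is.null(structure_ids))
    structure_ids <- vapply(database, function(p) p$structure_id, character(1))
  if (!any(identity_labels == query_identity))
    stop("no database structures share the query identity: no positives")
  ids <- vapply(database, function(p) p$id, character(1))
  if (query$id %in% ids) stop("query patch must be excluded from the database")
  scores <- vapply(database, function(p) patch_score(query, p, ...), numeric(1))

  labels <- rep("negative", length(database))
  match_idx <- which(identity_labels == query_identity)
  for (sid in unique(structure_ids[match_idx])) {
    grp <- match_idx[structure_ids[match_idx] == sid]
    best <- grp[which.max(scores[grp])]
    labels[grp] <- "ignored"
    labels[best] <- "positive"
  }
  ranked <- ranked_list(ids, scores, labels)
  list(ranked = ranked,
       metrics = list(auroc = auroc(ranked),
                      ef = enrichment_factor(ranked, ef_fraction),
                      bedroc = bedroc(ranked, bedroc_alpha)))
}

#' Aggregate retrieval metrics over queries
#'
#' Mean and standard error over queries of AUROC, EF and BEDROC,
#' mirroring the usual per-target reporting (N, AUROC, EF, BEDROC).
#'
#' @param results List of [run_retrieval()] results (one per query).
#' @param n_database Database size to report as N.
#' @return One-row data frame.
#' @export
summarize_retrieval <- function(results, n_database = NULL) {
  get <- function(f) vapply(results, function(r) r$metrics[[f]], numeric(1))
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  au <- get("auroc"); ef <- get("ef"); bd <- get("bedroc")
  data.frame(n_queries = length(results),
             N = n_database %||% NA_integer_,
             auroc = mean(au), auroc_se = se(au),
             ef = mean(ef), ef_se = se(ef),
             bedroc = mean(bd), bedroc_se = se(bd))
}
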