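# hand-built similarity matrix with ids and target labels
sim_from_matrix <- function(S, targets = NULL) {
  ids <- paste0("p", seq_len(nrow(S)))
  dimnames(S) <- list(ids, ids)
  structure(list(patch_ids = ids,
                 target_labels = targets %||% rep("t1", nrow(S)),
                 scores = S, params = list()),
            class = "similarity_matrix")
}

block_matrix <- function(sizes, within = 4, cross = 0, diag_val = 4) {
  n <- sum(sizes)
  S <- matrix(cross, n, n)
  off <- 0
  for (s in sizes) {
    S[off + seq_len(s), off + seq_len(s)] <- within
    off <- off + s
  }
  diag(S) <- diag_val
  S
}

test_that("the conservation filter counts qualifying links once", {
  S <- block_matrix(c(3))
  expect_equal(length(conservation_filter(sim_from_matrix(S), min_links = 5)), 0)
  expect_equal(conservation_filter(sim_from_matrix(S), min_links = 2),
               paste0("p", 1:3))

  # patch 1 has exactly 5 links >= 2, patch 2 exactly 4
  S8 <- matrix(0, 8, 8); diag(S8) <- 4
  S8[1, 2:6] <- S8[2:6, 1] <- 2.5
  S8[2, 3:5] <- S8[3:5, 2] <- 2.1
  ret <- conservation_filter(sim_from_matrix(S8), min_links = 5, threshold = 2)
  expect_true("p1" %in% ret)
  expect_false("p2" %in% ret)

  expect_equal(conservation_filter(sim_from_matrix(S8), min_links = 5, threshold = 0),
               paste0("p", 1:8))

  # monotone in both parameters
  for (ml in c(2, 4, 6)) {
    a <- conservation_filter(sim_from_matrix(S8), ml, 2)
    b <- conservation_filter(sim_from_matrix(S8), ml + 1, 2)
    expect_true(all(b %in% a))
    c1 <- conservation_filter(sim_from_matrix(S8), ml, 1)
    c2 <- conservation_filter(sim_from_matrix(S8), ml, 2.5)
    expect_true(all(c2 %in% c1))
  }
})

test_that("average-linkage clustering matches a brute-force agglomeration", {
  sm <- sim_from_matrix(block_matrix(c(5, 5)))
  hm <- hierarchical_map(sm, "global")
  expect_setequal(hm$order, sm$patch_ids) # leaf order is a permutation
  top <- stats::cutree(hm$hclust, k = 2)
  expect_equal(length(unique(top[1:5])), 1)
  expect_equal(length(unique(top[6:10])), 1)
  expect_false(top[1] == top[6])

  # identical rows merge at height zero first
  expect_equal(min(hm$hclust$height), 0)

  set.seed(101)
  for (k in 1:5) {
    n <- sample(6:15, 1)
    F <- matrix(rnorm(n * 4), n)
    d <- dist(F)
    hc <- stats::hclust(d, method = "average")
    expect_equal(sort(hc$height), sort(brute_average_linkage_heights(d)),
                 tolerance = 1e-9)
  }
})

test_that("within-target clustering uses only same-target columns", {
  S <- block_matrix(c(4, 4), within = 3.5, cross = 1)
  sm <- sim_from_matrix(S, targets = rep(c("A", "B"), each = 4))
  wt <- hierarchical_map(sm, "within_target")
  expect_setequal(names(wt), c("A", "B"))
  expect_setequal(wt$A$order, paste0("p", 1:4))
  expect_equal(length(wt$A$hclust$height), 3)
})

test_that("DBSCAN matches the brute-force reference and its core definition", {
  # 12 near-identical rows and 3 remote outliers
  S <- block_matrix(c(12, 1, 1, 1), within = 4, cross = 0)
  S[13, 14] <- S[14, 13] <- 3.9 # outliers unlike the block AND each other
  sm <- sim_from_matrix(S)
  lab <- dbscan_map(sm, eps = 7, min_samples = 10)
  expect_equal(lab, c(rep(1L, 12), 0L, 0L, 0L))

  expect_equal(dbscan_map(sm, eps = 7, min_samples = 20), rep(0L, 15))

  # random symmetric score matrices: the feature rows are the score rows
  set.seed(57)
  for (k in 1:8) {
    n <- sample(8:15, 1)
    R <- matrix(runif(n * n, 0, 4), n)
    Ssym <- (R + t(R)) / 2; diag(Ssym) <- 4
    smk <- sim_from_matrix(Ssym)
    d <- as.matrix(dist(Ssym))
    eps <- runif(1, 2, 6)
    ms <- sample(2:5, 1)
    expect_equal(dbscan_map(smk, eps = eps, min_samples = ms),
                 brute_dbscan(d, eps, ms))
  }
})

test_that("dbscan_map on score rows is order independent and core-valid", {
  S <- block_matrix(c(12, 5), within = 4, cross = 0.3)
  sm <- sim_from_matrix(S)
  lab <- dbscan_map(sm, eps = 7, min_samples = 5)
  # permute input and compare partitions
  perm <- sample(seq_len(17))
  Sp <- S[perm, perm]
  smp <- sim_from_matrix(Sp)
  labp <- dbscan_map(smp, eps = 7, min_samples = 5)
  co <- outer(lab, lab, "==") & lab > 0
  cop <- outer(labp, labp, "==") & labp > 0
  expect_equal(cop, co[perm, perm], ignore_attr = TRUE)

  # post-hoc core check: every point with >= min_samples neighbors
  # within eps is clustered, and every cluster contains a core point
  d <- as.matrix(dist(S))
  core <- rowSums(d <= 7) >= 5
  expect_true(all(lab[core] != 0))
  for (cl in setdiff(unique(lab), 0L))
    expect_true(any(core[lab == cl]))
})

test_that("link tables carry max scores and highlight flags", {
  S <- block_matrix(c(11, 11), within = 4, cross = 0)
  S[1, 12] <- S[12, 1] <- 3.1
  sm <- sim_from_matrix(S, targets = rep(c("A", "B"), each = 11))
  cm <- binding_site_map(sm, min_links = 5, link_threshold = 2,
                         eps = 7, min_samples = 10)
  lt <- cluster_link_table(cm, sm)
  expect_equal(nrow(lt), 1)
  expect_equal(lt$max_patch_score, 3.1)
  expect_true(lt$highlighted)
  expect_false(lt$same_target)

  S[1, 12] <- S[12, 1] <- 1.9
  sm2 <- sim_from_matrix(S, targets = rep(c("A", "B"), each = 11))
  cm2 <- binding_site_map(sm2, min_links = 5, link_threshold = 1,
                          eps = 7, min_samples = 10)
  lt2 <- cluster_link_table(cm2, sm2)
  expect_false(lt2$highlighted[1])

  # three clusters -> three unordered pairs
  S3 <- block_matrix(c(11, 11, 11), within = 4, cross = 2.2)
  sm3 <- sim_from_matrix(S3, targets = rep(c("A", "B", "C"), each = 11))
  cm3 <- binding_site_map(sm3, min_links = 5, link_threshold = 2,
                          eps = 7, min_samples = 10)
  lt3 <- cluster_link_table(cm3, sm3)
  expect_equal(nrow(lt3), 3)
})

test_that("map outputs are consistent and byte-stable", {
  S <- block_matrix(c(11, 11), within = 4, cross = 0.5)
  S[1, 12] <- S[12, 1] <- 2.8
  sm <- sim_from_matrix(S, targets = rep(c("A", "B"), each = 11))
  cm <- binding_site_map(sm, min_links = 5, link_threshold = 2,
                         eps = 7, min_samples = 10)
  lt <- cluster_link_table(cm, sm)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths1 <- write_map_outputs(cm, lt, sm, d1, png = FALSE)
  paths2 <- write_map_outputs(cm, lt, sm, d2, png = FALSE)
  expect_equal(length(readLines(paths1["links"])), nrow(lt))
  for (key in names(paths1))
    expect_identical(readLines(paths1[key]), readLines(paths2[key]))

  M <- read.table(paths1["matrix"], sep = "\t", header = TRUE, row.names = 1,
                  check.names = FALSE)
  expect_equal(rownames(M), cm$global_order)
  expect_equal(as.matrix(M), sm$scores[cm$global_order, cm$global_order],
               tolerance = 1e-9, ignore_attr = TRUE)

  bad <- cm; bad$global_order <- c("nope", cm$global_order[-1])
  expect_error(write_map_outputs(bad, lt, sm, d1, png = FALSE), "id mismatch")
})
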