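regular_tetrahedron <- function(edge = 2) {
  rbind(c(0, 0, 0), c(edge, 0, 0), c(edge / 2, edge * sqrt(3) / 2, 0),
        c(edge / 2, edge * sqrt(3) / 6, edge * sqrt(6) / 3))
}

test_that("the tetrahedralization matches brute-force empty-circumsphere enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    P <- matrix(runif(36, 0, 10), ncol = 3)
    tt <- pocketmap:::.delaunay_tets(P)
    brute <- t(combn(12, 4))
    is_del <- apply(brute, 1, function(v) {
      cs <- pocketmap:::circumsphere4(P[v, ])
      if (!is.finite(cs[4])) return(FALSE)
      d2 <- rowSums(sweep(P, 2, cs[1:3])^2)
      all(d2 >= cs[4]^2 * (1 - 1e-9) | seq_len(12) %in% v)
    })
    expect_equal(unname(tt), unname(brute[is_del, , drop = FALSE]))
  }
})

test_that("a regular tetrahedron yields exactly its circumsphere", {
  tet <- regular_tetrahedron(2)
  # a 5th far atom satisfies the >= 5 atom precondition without
  # contributing a sphere in the radius window
  st <- structure_from_atoms("tet", rep("CB", 5), rep("C", 5), rep("ALA", 5),
                             rbind(tet, c(100, 100, 100)))
  sp <- compute_alpha_spheres(st, r_min = 0.5, r_max = 1.5)
  expect_equal(length(sp), 1)
  expect_equal(sp$radius, 2 * sqrt(6) / 4, tolerance = 1e-6)
  expect_equal(as.numeric(sp$center), colMeans(tet), tolerance = 1e-6)
  expect_equal(sp$apolar, 4) # four carbon tangent atoms

  # an atom at the centroid violates the empty-sphere invariant
  st2 <- structure_from_atoms("tet2", rep("CB", 6), rep("C", 6), rep("ALA", 6),
                              rbind(tet, colMeans(tet), c(100, 100, 100)))
  # the four sub-tetrahedra formed with the centroid atom have
  # circumradius 1.84, outside the window: nothing remains
  expect_equal(length(compute_alpha_spheres(st2, r_min = 0.5, r_max = 1.5)), 0)
})

test_that("every alpha sphere is empty and detection is rotation invariant", {
  pp <- test_pocket_protein()
  st <- pp$structure
  sp <- compute_alpha_spheres(st)
  prot <- coords(st, which(st$atoms$record == "protein" & !st$atoms$hydrogen))
  for (i in seq_len(length(sp))) {
    d <- sqrt(rowSums(sweep(prot, 2, sp$center[i, ])^2))
    expect_gte(min(d), sp$radius[i] - 1e-6)
  }
  expect_true(all(sp$radius >= 3.0 & sp$radius <= 6.0))

  R <- pocketmap:::rotation_from_vector(c(0.3, 0.9, -0.5))
  st2 <- st
  xyz <- sweep(coords(st) %*% t(R), 2, c(7, -2, 4), "+")
  st2$atoms$x <- xyz[, 1]; st2$atoms$y <- xyz[, 2]; st2$atoms$z <- xyz[, 3]
  sp2 <- compute_alpha_spheres(st2)
  expect_equal(length(sp2), length(sp))
  back <- sweep(sp2$center, 2, c(7, -2, 4)) %*% R
  expect_equal(sort(sp2$radius), sort(sp$radius), tolerance = 1e-5)
  # every back-rotated sphere coincides with one original sphere
  nn <- apply(back, 1, function(p)
    min(sqrt(rowSums(sweep(sp$center, 2, p)^2))))
  expect_lt(max(nn), 1e-4)
})

test_that("single-linkage clustering follows the distance and size rules", {
  mk <- function(centers) pocketmap:::new_alpha_spheres(
    centers, rep(3.5, nrow(centers)),
    matrix(1L, nrow(centers), 4), rep(2, nrow(centers)))

  two <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                  c(20, 0, 0), c(21, 0, 0), c(22, 0, 0)))
  cavs <- cluster_alpha_spheres(two, r = 3, n_min = 3)
  expect_equal(length(cavs), 2)

  chain <- mk(cbind(seq(0, by = 2.9, length.out = 5), 0, 0))
  cavs <- cluster_alpha_spheres(chain, r = 3, n_min = 3)
  expect_equal(length(cavs), 1)
  expect_equal(length(cavs[[1]]$spheres), 5)

  iso <- mk(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(length(cluster_alpha_spheres(iso, r = 3, n_min = 3)), 0)

  # output partitions the retained input: no sphere in two cavities
  pp <- test_pocket_protein()
  sp <- compute_alpha_spheres(pp$structure)
  cavs <- cluster_alpha_spheres(sp)
  all_centers <- do.call(rbind, lapply(cavs, function(c) c$spheres$center))
  expect_equal(nrow(all_centers), nrow(unique(all_centers)))
  sizes <- vapply(cavs, function(c) length(c$spheres), numeric(1))
  expect_true(all(diff(sizes) <= 0)) # ordered by descending size
})

test_that("Monte-Carlo volume matches closed forms for spheres", {
  one <- structure(list(id = "c1", structure_id = "s", spheres =
    pocketmap:::new_alpha_spheres(matrix(0, 1, 3), 2, matrix(1L, 1, 4), 2)),
    class = "cavity")
  v1 <- cavity_descriptors(one, mc_points = 1e6, seed = 1)$mc_volume
  expect_equal(v1, 4 / 3 * pi * 8, tolerance = 0.01)

  two <- one
  two$spheres <- pocketmap:::new_alpha_spheres(rbind(c(0, 0, 0), c(50, 0, 0)),
                                               c(2, 2), matrix(1L, 2, 4), c(2, 2))
  v2 <- cavity_descriptors(two, mc_points = 1e6, seed = 1)$mc_volume
  expect_equal(v2, 2 * 4 / 3 * pi * 8, tolerance = 0.015)

  coincident <- one
  coincident$spheres <- pocketmap:::new_alpha_spheres(rbind(c(0, 0, 0), c(0, 0, 0)),
                                                      c(2, 2), matrix(1L, 2, 4), c(2, 2))
  v3 <- cavity_descriptors(coincident, mc_points = 1e6, seed = 1)$mc_volume
  expect_equal(v3, 4 / 3 * pi * 8, tolerance = 0.01)

  # determinism and fraction bookkeeping
  d1 <- cavity_descriptors(one, seed = 42)
  d2 <- cavity_descriptors(one, seed = 42)
  expect_identical(d1, d2)
  expect_equal(d1$hydrophobic_fraction + d1$polarity_fraction, 1)
})

test_that("the linear cavity score behaves as documented", {
  pp <- test_pocket_protein()
  d <- cavity_descriptors(matched_cavity(pp), seed = 1)
  w0 <- cavity_score_weights()
  w0$weights[] <- 0; w0$intercept <- 5
  expect_equal(cavity_score(d, w0)$value, 5.0)

  w <- cavity_score_weights()
  d2 <- d; d2$n_spheres <- 2 * d$n_spheres
  expect_gt(cavity_score(d2, w)$value, cavity_score(d, w)$value)

  big_hydro <- d; big_hydro$n_spheres <- 60; big_hydro$mc_volume <- 500
  big_hydro$hydrophobic_fraction <- 0.9; big_hydro$polarity_fraction <- 0.1
  small_polar <- d; small_polar$n_spheres <- 6; small_polar$mc_volume <- 60
  small_polar$hydrophobic_fraction <- 0.1; small_polar$polarity_fraction <- 0.9
  expect_gt(cavity_score(big_hydro, w)$value, cavity_score(small_polar, w)$value)

  w_missing <- w; w_missing$weights <- w$weights[-1]
  d_short <- d; d_short$n_spheres <- NULL
  expect_error(cavity_score(d_short, w), "missing")
})

test_that("ligand matching picks the most-contacted cavity with documented ties", {
  pp <- test_pocket_protein()
  id <- match_cavity_to_ligand(test_cavities(pp), pp$structure, pp$ligand_atoms[[1]])
  cav <- matched_cavity(pp)
  # the matched cavity contains spheres near the planted pocket center
  d <- sqrt(rowSums(sweep(cav$spheres$center, 2, pp$pockets[[1]]$center)^2))
  expect_lte(min(d), pp$pockets[[1]]$spec$width / 2)

  far <- pp$structure$atoms$serial[pp$ligand_atoms[[1]]]
  stfar <- pp$structure
  stfar$atoms$x[pp$ligand_atoms[[1]]] <- 500
  expect_null(match_cavity_to_ligand(test_cavities(pp), stfar, pp$ligand_atoms[[1]]))

  mk_cav <- function(id, centers) structure(list(
    id = id, structure_id = "s",
    spheres = pocketmap:::new_alpha_spheres(centers, rep(3.5, nrow(centers)),
                                            matrix(1L, nrow(centers), 4),
                                            rep(2, nrow(centers)))), class = "cavity")
  lig_st <- structure_from_atoms("l", c("CB", "C1"), c("C", "C"), c("ALA", "LIG"),
                                 rbind(c(100, 100, 100), c(0, 0, 0)),
                                 record = c("protein", "ligand"))
  big <- mk_cav("big", rbind(matrix(rnorm(6, sd = 0.5), 2, 3), matrix(50, 6, 3)))
  small <- mk_cav("small", matrix(rnorm(6, sd = 0.5), 2, 3))
  # equal contact counts (2 each): larger cavity wins
  expect_equal(match_cavity_to_ligand(list(small, big), lig_st, 2), "big")
})

test_that("threshold calibration attains the requested recall", {
  expect_equal(calibrate_score_threshold(seq(10, 100, by = 10), 0.95), 10)
  expect_equal(calibrate_score_threshold(1:100, 0.95), 6)
  expect_equal(calibrate_score_threshold(c(5, 3, 9), 1.0), 3)

  set.seed(21)
  for (rec in c(0.5, 0.8, 0.95, 0.99)) {
    s <- rnorm(137)
    t <- calibrate_score_threshold(s, rec)
    expect_gte(mean(s >= t), rec)
  }
  # monotone: higher recall never raises the threshold
  s <- rnorm(200)
  ts <- vapply(seq(0.5, 1, by = 0.05), function(r)
    calibrate_score_threshold(s, r), numeric(1))
  expect_true(all(diff(ts) <= 0))
})

test_that("fpocket output directories parse with verbatim reported values", {
  dir <- system.file("extdata", "fpocket_mini", package = "pocketmap")
  recs <- parse_fpocket_results(dir)
  expect_equal(length(recs), 2)
  expect_equal(vapply(recs, function(r) r$score, numeric(1)), c(17.0, 16.0))
  expect_equal(recs[[1]]$druggability_score, 0.89)
  expect_equal(recs[[1]]$volume, 311.25)
  expect_equal(length(recs[[1]]$cavity$spheres), 6)
  expect_equal(recs[[1]]$cavity$spheres$radius[1], 3.40)
  expect_equal(recs[[1]]$cavity$lining_serials, c(3L, 7L, 11L, 15L))

  kept <- parse_fpocket_results(dir, score_min = 16.8)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]]$score, 17.0)

  empty <- withr::local_tempdir()
  expect_warning(res <- parse_fpocket_results(empty), "no \\*_info")
  expect_equal(length(res), 0)
})

test_that("the planted pocket is recovered across a 40-seed sweep", {
  hits <- vapply(1:40, function(sd) {
    pp <- make_pocket_protein(pockets = list(default_pocket_spec()), seed = sd)
    cavs <- cluster_alpha_spheres(compute_alpha_spheres(pp$structure),
                                  structure_id = pp$structure$id)
    !is.null(match_cavity_to_ligand(cavs, pp$structure, pp$ligand_atoms[[1]]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
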