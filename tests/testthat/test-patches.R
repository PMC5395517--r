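aa_structure <- function(resname, names, xyz, resno = NULL) {
  el <- substr(gsub("[0-9]", "", names), 1, 1)
  structure_from_atoms(paste0("aa_", resname[1]), names, el, resname, xyz,
                       resno = resno %||% rep(1, length(names)))
}

test_that("rule-table typing produces the documented pseudocenters", {
  # Asp side chain: one anion pseudocenter at the carboxylate centroid
  asp <- aa_structure(rep("ASP", 4), c("CB", "CG", "OD1", "OD2"),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1, 0), c(2.2, -1, 0)))
  pc <- type_pharmacophores(asp, 1:4)
  an <- pc[pc$ptype == "anion", ]
  expect_equal(nrow(an), 1)
  expect_equal(as.numeric(an[, c("x", "y", "z")]), c(2.2, 0, 0))
  expect_setequal(an$source[[1]], 3:4)

  # Lys NZ: single cation
  lys <- aa_structure(rep("LYS", 2), c("CE", "NZ"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  pc <- type_pharmacophores(lys, 1:2)
  expect_equal(pc$ptype[pc$x == 1.5], "cation")

  # Phe ring collapses to a single hydrophobe centroid (plus CB)
  ring <- 1.4 * cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  phe <- aa_structure(rep("PHE", 7), c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      rbind(c(5, 5, 5), sweep(ring, 2, c(10, 10, 10), "+")))
  pc <- type_pharmacophores(phe, 1:7)
  hyd <- pc[pc$ptype == "hydrophobe", ]
  expect_equal(nrow(hyd), 2) # CB + ring centroid
  centroid <- hyd[vapply(hyd$source, length, integer(1)) == 6, ]
  expect_equal(as.numeric(centroid[, c("x", "y", "z")]), c(10, 10, 10),
               tolerance = 1e-9)
  # per-atom ring mode keeps the six ring carbons
  pc_atoms <- type_pharmacophores(phe, 1:7, ring_mode = "atoms")
  expect_equal(sum(pc_atoms$ptype == "hydrophobe"), 7)

  # backbone N donor / O acceptor; Ser OG is a dual donor+acceptor
  ser <- aa_structure(rep("SER", 4), c("N", "O", "CB", "OG"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(1, 2, 0)))
  pc <- type_pharmacophores(ser, 1:4)
  og <- pc[pc$x == 1 & pc$y == 2, ]
  expect_setequal(og$ptype, c("donor", "acceptor"))
  expect_equal(sum(pc$ptype == "donor"), 2)   # backbone N + OG
  expect_equal(sum(pc$ptype == "acceptor"), 2) # backbone O + OG

  # His defaults to neutral acceptor nitrogens, switchable to cation
  his <- aa_structure(rep("HIS", 2), c("ND1", "NE2"),
                      rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(type_pharmacophores(his, 1:2)$ptype, c("acceptor", "acceptor"))
  expect_equal(type_pharmacophores(his, 1:2, his_mode = "cation")$ptype, "cation")

  # non-standard residues fall back to element typing
  het <- aa_structure(rep("XYZ", 3), c("N1", "O1", "C1"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  expect_equal(type_pharmacophores(het, 1:3)$ptype,
               c("donor", "acceptor", "hydrophobe"))

  # typing is deterministic
  pp <- test_pocket_protein()
  t1 <- type_pharmacophores(pp$structure, pp$pockets[[1]]$atoms)
  t2 <- type_pharmacophores(pp$structure, pp$pockets[[1]]$atoms)
  expect_identical(t1, t2)
})

test_that("ligand patches select surface atoms within the cutoff", {
  pp <- test_pocket_protein()
  surf <- test_surface(pp)
  p <- patch_from_ligand(pp$structure, pp$ligand_atoms[[1]], surface = surf)
  # the 4 A rule reaches only the planted pocket lining
  expect_true(all(p$atoms %in% pp$pockets[[1]]$atoms))
  expect_gt(nrow(p$shape_points), 5)
  # every pseudocenter's source atoms belong to the patch atom set
  expect_true(all(unlist(p$pseudocenters$source) %in% p$atoms))

  expect_error(patch_from_ligand(pp$structure, pp$ligand_atoms[[1]],
                                 cutoff = 0, surface = surf), "empty patch")
  p6 <- patch_from_ligand(pp$structure, pp$ligand_atoms[[1]], cutoff = 6,
                          surface = surf)
  expect_true(all(p$atoms %in% p6$atoms))
})

test_that("pseudo-ligand atoms are the surface-exposed sphere tangents", {
  pp <- test_pocket_protein()
  surf <- test_surface(pp)
  cav <- matched_cavity(pp)
  pl <- pseudo_ligand_atoms(pp$structure, cav, surface = surf)
  expect_true(all(pl %in% surf))
  expect_true(all(pl %in% unique(as.integer(cav$spheres$tangent))))
  # pocket-derived pseudo-ligand is dominated by the planted lining
  expect_gte(mean(pl %in% pp$pockets[[1]]$atoms), 0.5)

  # a cavity whose tangent atoms are all outside the surface set fails
  tangents <- unique(as.integer(cav$spheres$tangent))
  expect_error(pseudo_ligand_atoms(pp$structure, cav,
                                   surface = setdiff(surf, tangents)),
               "surface-exposed")
})

test_that("cavity patches follow the site-size rule", {
  pp <- test_pocket_protein()
  surf <- test_surface(pp)
  cav <- matched_cavity(pp)
  pl <- pseudo_ligand_atoms(pp$structure, cav, surface = surf)

  p0 <- patch_from_cavity(pp$structure, cav, site_size = 0, surface = surf)
  expect_setequal(p0$atoms, pl)
  pbig <- patch_from_cavity(pp$structure, cav, site_size = 1000, surface = surf)
  expect_setequal(pbig$atoms, surf)

  # monotone in site_size
  sizes <- c(0.1, 0.3, 0.6, 2, 5)
  patches <- lapply(sizes, function(s)
    patch_from_cavity(pp$structure, cav, site_size = s, surface = surf))
  for (i in seq_along(sizes)[-1])
    expect_true(all(patches[[i - 1]]$atoms %in% patches[[i]]$atoms))

  # ligand patch and cavity patch of the same pocket largely agree
  p_lig <- patch_from_ligand(pp$structure, pp$ligand_atoms[[1]], surface = surf)
  p_cav <- patch_from_cavity(pp$structure, cav, surface = surf)
  jac <- length(intersect(p_lig$atoms, p_cav$atoms)) /
    length(union(p_lig$atoms, p_cav$atoms))
  expect_gte(jac, 0.5)
})

test_that("patch construction commutes with rigid motion", {
  pp <- test_pocket_protein()
  st <- pp$structure
  R <- pocketmap:::rotation_from_vector(c(-0.7, 0.2, 1.1))
  tr <- c(3, -8, 5)
  st2 <- st
  xyz <- sweep(coords(st) %*% t(R), 2, tr, "+")
  st2$atoms$x <- xyz[, 1]; st2$atoms$y <- xyz[, 2]; st2$atoms$z <- xyz[, 3]

  sas1 <- atom_sasa(st, n_points = 480); sas2 <- atom_sasa(st2, n_points = 480)
  s1 <- surface_atoms(st, sasa = sas1); s2 <- surface_atoms(st2, sasa = sas2)
  p1 <- patch_from_ligand(st, pp$ligand_atoms[[1]], surface = s1)
  p2 <- patch_from_ligand(st2, pp$ligand_atoms[[1]], surface = s2)
  expect_equal(p1$atoms, p2$atoms)
  expect_equal(sweep(p1$shape_points %*% t(R), 2, tr, "+"), p2$shape_points,
               tolerance = 1e-6, ignore_attr = TRUE)
  pc1 <- as.matrix(p1$pseudocenters[, c("x", "y", "z")])
  pc2 <- as.matrix(p2$pseudocenters[, c("x", "y", "z")])
  expect_equal(sweep(pc1 %*% t(R), 2, tr, "+"), pc2,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(p1$pseudocenters$ptype, p2$pseudocenters$ptype)
})

test_that("patches serialize to JSON and back", {
  pp <- test_pocket_protein()
  p <- patch_from_ligand(pp$structure, pp$ligand_atoms[[1]],
                         surface = test_surface(pp))
  f <- withr::local_tempfile(fileext = ".json")
  write_patch(p, f)
  q <- read_patch(f)
  expect_equal(q$id, p$id)
  expect_equal(q$shape_points, p$shape_points, ignore_attr = TRUE)
  expect_equal(q$pseudocenters$ptype, p$pseudocenters$ptype)
  expect_equal(patch_score(p, q), 4, tolerance = 1e-3)
})
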