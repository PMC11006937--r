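test_that("elasticity matrix matches the isotropic closed form", {
  D0 <- elasticity_matrix(material("m", 1, 0))
  expect_equal(D0, diag(c(1, 1, 1, 0.5, 0.5, 0.5)))

  bone <- material("bone", 20490, 0.40)
  Db <- elasticity_matrix(bone)
  expect_equal(Db[1, 1], 20490 * (1 - 0.4) / ((1 + 0.4) * (1 - 2 * 0.4)))
  expect_equal(Db[1, 1], 43907.142857142855)
  expect_true(isSymmetric(Db))
  expect_true(all(eigen(Db, symmetric = TRUE, only.values = TRUE)$values > 0))

  expect_error(material("m", 1, 0.6), "nu")
  expect_error(material("m", 1, 0.5), "nu")
  expect_error(material("m", -1, 0.3), "positive")
})

test_that("element stiffness is symmetric, rank 6, and matches the first-principles oracle", {
  set.seed(7)
  mat <- test_material(E = 123, nu = 0.27)
  for (rep in 1:5) {
    coords <- unit_tet_mesh()$nodes + matrix(stats::rnorm(12, sd = 0.1), 4)
    if (det(cbind(1, coords)) < 0) coords <- coords[c(1, 3, 2, 4), ]
    Ke <- element_stiffness(coords, mat)
    expect_lt(max(abs(Ke - t(Ke))) / max(abs(Ke)), 1e-9)
    ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)  # rigid-body modes
    expect_equal(Ke, oracle_element_stiffness(coords, 123, 0.27),
                 tolerance = 1e-12)
  }
  # reference tet, E = 1, nu = 0 against the hand-built oracle
  expect_equal(element_stiffness(unit_tet_mesh()$nodes, material("m", 1, 0)),
               oracle_element_stiffness(unit_tet_mesh()$nodes, 1, 0))
  expect_error(
    element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            c(0.5, 0.5, 0)), mat),
    "degenerate")
})

test_that("assembly places element matrices at their DOFs and is symmetric", {
  mat <- list(bone = test_material())
  one <- unit_tet_mesh()
  K <- as.matrix(assemble_stiffness(one, mat))
  expect_equal(K, unname(as.matrix(element_stiffness(one$nodes, mat$bone))),
               tolerance = 1e-14)

  # two disconnected tets give a block-diagonal matrix
  two <- tet_mesh(rbind(one$nodes, one$nodes + 10),
                  rbind(1:4, 5:8))
  K2 <- as.matrix(assemble_stiffness(two, mat))
  expect_equal(K2[1:12, 13:24], matrix(0, 12, 12))
  expect_equal(K2[1:12, 1:12], K2[13:24, 13:24], tolerance = 1e-12)

  skull <- make_toy_skull()
  Ks <- assemble_stiffness(skull, default_materials())
  expect_lt(Matrix::norm(Ks - Matrix::t(Ks), "F") / Matrix::norm(Ks, "F"),
            1e-12)
  expect_error(assemble_stiffness(one, list(teeth = mat$bone)), "no material")
})

test_that("von Mises closed forms hold", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(3, 3, 3, 0, 0, 0)), 0)       # hydrostatic
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))  # pure shear
  S <- matrix(c(1, 2, 0, 2, 3, 0, 0, 0, -1), 3)
  expect_equal(von_mises(S), von_mises(c(1, 3, -1, 2, 0, 0)))
})

test_that("load_case enforces its invariants", {
  n <- 10L
  cons <- data.frame(node = 1:2, x = TRUE, y = TRUE, z = TRUE)
  pl <- data.frame(node = 5L, fx = 1, fy = 0, fz = 0)
  expect_s3_class(load_case(pl, cons, n), "load_case")
  expect_error(load_case(data.frame(node = 11L, fx = 1, fy = 0, fz = 0),
                         cons, n), "invalid node")
  expect_error(load_case(pl, cons[1, ], n), "at least 6")
  expect_error(
    load_case(data.frame(node = 1L, fx = 1, fy = 0, fz = 0), cons, n),
    "both loaded and constrained")
  # a zero force component on a constrained axis is allowed
  expect_s3_class(
    load_case(data.frame(node = 1L, fx = 0, fy = 0, fz = 0), cons, n),
    "load_case")
})

test_that("zero loads give a zero field and singular systems are diagnosed", {
  m <- unit_cube_mesh()
  mats <- list(bone = test_material())
  cons <- data.frame(node = m$node_sets$fixed_end, x = TRUE, y = TRUE,
                     z = TRUE)
  lc <- load_case(data.frame(node = integer(0), fx = numeric(0),
                             fy = numeric(0), fz = numeric(0)), cons,
                  nrow(m$nodes))
  sol <- solve_fem(m, mats, lc)
  expect_equal(max(abs(sol$displacements)), 0)
  expect_equal(max(sol$element_nodal_vm), 0)
  expect_equal(sol$strain_energy, 0)

  beam <- make_beam(2, 1, 1, 2, 1, 1)
  bad <- load_case(data.frame(node = nrow(beam$nodes), fx = 0, fy = 0,
                              fz = -1),
                   data.frame(node = 1:6, x = FALSE, y = FALSE, z = TRUE),
                   nrow(beam$nodes))
  expect_error(solve_fem(beam, mats, bad), "rigid-body")
})

test_that("uniform traction reproduces the exact constant stress field", {
  pt <- patch_test_case(sigma = 3.5)
  sol <- solve_fem(pt$mesh, list(bone = test_material()), pt$lc)
  expect_equal(sol$element_stress[, 1], rep(pt$sigma, nrow(pt$mesh$elements)),
               tolerance = 1e-12)
  expect_equal(max(abs(sol$element_stress[, 2:6])), 0, tolerance = 1e-12)
  expect_equal(sol$element_vm, rep(pt$sigma, nrow(pt$mesh$elements)),
               tolerance = 1e-12)
  expect_length(sol$element_nodal_vm, 4 * nrow(pt$mesh$elements))
})

test_that("solutions are linear, superposable, and in equilibrium", {
  m <- make_toy_skull()
  mats <- default_materials()
  sc1 <- build_bending_scenario(m, "anterior", "bilateral", 100)
  sc2 <- build_bending_scenario(m, "posterior", "unilateral_left", 60)
  s1 <- solve_fem(m, mats, sc1$load_case)

  # linearity: double the loads
  sc1d <- build_bending_scenario(m, "anterior", "bilateral", 200)
  s1d <- solve_fem(m, mats, sc1d$load_case)
  expect_equal(s1d$displacements, 2 * s1$displacements, tolerance = 1e-9)
  expect_equal(s1d$element_vm, 2 * s1$element_vm, tolerance = 1e-9)
  expect_equal(s1d$strain_energy, 4 * s1$strain_energy, tolerance = 1e-9)

  # superposition under shared constraints
  s2 <- solve_fem(m, mats, sc2$load_case)
  pl12 <- rbind(sc1$load_case$point_loads, sc2$load_case$point_loads)
  lc12 <- load_case(pl12, sc1$load_case$constraints, nrow(m$nodes))
  s12 <- solve_fem(m, mats, lc12)
  expect_equal(s12$displacements, s1$displacements + s2$displacements,
               tolerance = 1e-9)

  # global equilibrium: reactions balance applied loads per axis
  applied <- colSums(sc1$load_case$point_loads[, c("fx", "fy", "fz")])
  reacted <- colSums(s1$reactions[, c("rx", "ry", "rz")])
  expect_lt(max(abs(applied + reacted)), 1e-6)
})

test_that("the von Mises multiset is frame invariant", {
  set.seed(11)
  m <- make_beam(4, 1, 1, 4, 2, 2)
  mats <- list(bone = test_material())
  cons <- data.frame(node = m$node_sets$fixed_end, x = TRUE, y = TRUE,
                     z = TRUE)
  tip <- m$node_sets$free_end_tip
  pl <- data.frame(node = tip, fx = 0, fy = 0.2, fz = -1 / length(tip))
  sol <- solve_fem(m, mats, load_case(pl, cons, nrow(m$nodes)))

  R <- random_rotation()
  mr <- m
  mr$nodes <- m$nodes %*% t(R)
  fr <- as.matrix(pl[, c("fx", "fy", "fz")]) %*% t(R)
  plr <- data.frame(node = pl$node, fx = fr[, 1], fy = fr[, 2], fz = fr[, 3])
  solr <- solve_fem(mr, mats, load_case(plr, cons, nrow(m$nodes)))
  expect_equal(sort(solr$element_vm), sort(sol$element_vm),
               tolerance = 1e-6)
  expect_equal(solr$strain_energy, sol$strain_energy, tolerance = 1e-9)
})

test_that("sparse, dense and conjugate-gradient solutions agree", {
  m <- make_beam(3, 1, 1, 3, 1, 2)   # 96 nodes -> 288 DOFs
  expect_lte(3 * nrow(m$nodes), 300)
  mat <- test_material(E = 500, nu = 0.3)
  cons <- data.frame(node = m$node_sets$fixed_end, x = TRUE, y = TRUE,
                     z = TRUE)
  tip <- m$node_sets$free_end_tip
  pl <- data.frame(node = tip, fx = 0.1, fy = -0.3, fz = -1 / length(tip))
  lc <- load_case(pl, cons, nrow(m$nodes))

  u_sparse <- solve_fem(m, list(bone = mat), lc)$displacements
  u_dense <- dense_solve_displacements(m, mat, lc)
  expect_equal(u_sparse, u_dense, tolerance = 1e-9)

  u_cg <- solve_fem(m, list(bone = mat), lc, method = "cg")$displacements
  expect_equal(u_cg, u_dense, tolerance = 1e-8)
})
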