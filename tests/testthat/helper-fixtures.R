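# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# A single unit reference tetrahedron: (0,0,0),(1,0,0),(0,1,0),(0,0,1).
unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, nrow = 1L))
}

# Unit cube meshed into 6 tets.
unit_cube_mesh <- function() make_beam(1, 1, 1, 1, 1, 1)

# A small linear-elastic test material.
test_material <- function(E = 100, nu = 0.3) material("bone", E, nu)

# Independent element-stiffness oracle from first principles: linear shape
# functions on the tet give constant gradients (rows of inv([1 | X])[2:4,]);
# build B entry-by-entry and integrate Ke = V * t(B) D B directly. Shares
# no code with the implementation beyond the constitutive matrix formula,
# which is re-derived here too.
oracle_element_stiffness <- function(coords, E, nu) {
  A <- cbind(1, coords)
  V <- det(A) / 6
  G <- solve(A)[2:4, ]          # grad N_i in column i
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- G[1, i]
    B[2, c0 + 2] <- G[2, i]
    B[3, c0 + 3] <- G[3, i]
    B[4, c0 + 1] <- G[2, i]; B[4, c0 + 2] <- G[1, i]
    B[5, c0 + 2] <- G[3, i]; B[5, c0 + 3] <- G[2, i]
    B[6, c0 + 1] <- G[3, i]; B[6, c0 + 3] <- G[1, i]
  }
  V * t(B) %*% D %*% B
}

# Dense direct solve used as the oracle against the sparse path: assembles
# a dense stiffness from per-element matrices and solves the reduced system
# with base R's dense solver.
dense_solve_displacements <- function(mesh, mat, lc) {
  n <- nrow(mesh$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(mesh$elements))) {
    en <- mesh$elements[e, ]
    Ke <- oracle_element_stiffness(mesh$nodes[en, , drop = FALSE],
                                   mat$E, mat$nu)
    dofs <- rep(3 * (en - 1), each = 3) + rep(1:3, 4)
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  f <- numeric(3 * n)
  pl <- lc$point_loads
  for (k in seq_len(nrow(pl))) {
    f[3 * (pl$node[k] - 1) + 1:3] <-
      f[3 * (pl$node[k] - 1) + 1:3] + c(pl$fx[k], pl$fy[k], pl$fz[k])
  }
  cn <- lc$constraints
  fixed <- sort(unique(c(3 * (cn$node[cn$x] - 1) + 1,
                         3 * (cn$node[cn$y] - 1) + 2,
                         3 * (cn$node[cn$z] - 1) + 3)))
  free <- setdiff(seq_len(3 * n), fixed)
  u <- numeric(3 * n)
  u[free] <- solve(K[free, free], f[free])
  matrix(u, ncol = 3, byrow = TRUE)
}

# Uniaxial patch test on a block: uniform traction sigma on the x = L face
# via consistent (area-weighted) nodal loads, minimal supports elsewhere.
# The exact solution is a uniform stress field sigma_xx = sigma.
patch_test_case <- function(sigma = 1, nx = 2, ny = 2, nz = 2) {
  m <- make_beam(2, 1, 1, nx, ny, nz)
  fixed <- m$node_sets$fixed_end
  cons <- data.frame(node = fixed, x = TRUE, y = FALSE, z = FALSE)
  origin <- fixed[which.min(rowSums(m$nodes[fixed, ]^2))]
  cons$y[cons$node == origin] <- TRUE
  cons$z[cons$node == origin] <- TRUE
  cons$z[cons$node == fixed[which.max(m$nodes[fixed, 2])]] <- TRUE
  cons$y[cons$node == fixed[which.max(m$nodes[fixed, 3])]] <- TRUE
  tris <- boundary_triangles(m)
  xs <- matrix(m$nodes[tris, 1], ncol = 3)
  tip_tris <- tris[rowSums(xs == max(m$nodes[, 1])) == 3L, , drop = FALSE]
  areas <- apply(tip_tris, 1L, function(tr) {
    a <- m$nodes[tr[2], ] - m$nodes[tr[1], ]
    b <- m$nodes[tr[3], ] - m$nodes[tr[1], ]
    0.5 * sqrt(sum(crossprod_vec(a, b)^2))
  })
  f <- numeric(nrow(m$nodes))
  for (k in seq_len(nrow(tip_tris))) {
    f[tip_tris[k, ]] <- f[tip_tris[k, ]] + sigma * areas[k] / 3
  }
  loaded <- which(f > 0)
  pl <- data.frame(node = loaded, fx = f[loaded], fy = 0, fz = 0)
  list(mesh = m, lc = load_case(pl, cons, nrow(m$nodes)), sigma = sigma)
}

# Element mirror pairing of a bilaterally symmetric mesh, recovered
# geometrically: match element centroids under x -> -x.
mirror_element_map <- function(mesh, digits = 8) {
  cent <- (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
           mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
  key <- function(p) paste(round(p[, 1], digits), round(p[, 2], digits),
                           round(p[, 3], digits))
  match(key(cbind(-cent[, 1], cent[, 2], cent[, 3])), key(cent))
}

# Element centroids (for side splits).
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], ] + mesh$nodes[mesh$elements[, 2], ] +
   mesh$nodes[mesh$elements[, 3], ] + mesh$nodes[mesh$elements[, 4], ]) / 4
}

# A random rigid rotation matrix (deterministic given the seed in force).
random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

# INP text for a single unit tet with one node set; used by parser tests.
unit_tet_inp_lines <- function() {
  c("*NODE",
    "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0", "4, 0, 0, 1",
    "*ELEMENT, TYPE=C3D4",
    "1, 1, 2, 3, 4",
    "*NSET, NSET=tip",
    "4, 4")
}
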