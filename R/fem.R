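#' Isotropic linear-elastic material
#'
#' @param name material label (e.g. `"bone"`, `"teeth"`, `"keratin"`).
#' @param E Young's modulus in MPa (the pipeline works in mm / N / MPa;
#'   GPa inputs in configuration files are converted by a factor of 1000 at
#'   load time).
#' @param nu Poisson's ratio, `0 <= nu < 0.5`.
#' @return an object of class `fem_material`.
#' @export
material <- function(name, E, nu) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0) {
    stop("Young's modulus E must be a single positive number (MPa)")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu >= 0.5) {
    stop("Poisson's ratio nu must satisfy 0 <= nu < 0.5 ",
         "(the incompressible limit is unsupported)")
  }
  structure(list(name = as.character(name), E = E, nu = nu),
            class = "fem_material")
}

#' Default cranial material set
#'
#' Bone (E = 20.49 GPa, nu = 0.40, from extant alligator mandible data) and
#' teeth (E = 60.40 GPa, nu = 0.31, extant crocodile teeth), both isotropic
#' and homogeneous, expressed in MPa. Keratin has no default: rhamphotheca
#' runs must supply their own constants.
#'
#' @return named list of `fem_material`.
#' @export
default_materials <- function() {
  list(bone = material("bone", E = 20490, nu = 0.40),
       teeth = material("teeth", E = 60400, nu = 0.31))
}

#' Isotropic elasticity matrix
#'
#' The 6x6 constitutive matrix D relating Voigt stress
#' (xx, yy, zz, xy, yz, zx) to Voigt engineering strain for an isotropic
#' material. Symmetric positive definite for `0 <= nu < 0.5`.
#'
#' @param mat a `fem_material`.
#' @return a 6x6 numeric matrix, MPa.
#' @export
elasticity_matrix <- function(mat) {
  stopifnot(inherits(mat, "fem_material"))
  E <- mat$E; nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6L, 6L)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Shape-function gradients and volume for one tet: columns of `grads` are
# grad N_i (constant over the element). A = [1 | coords] is invertible iff
# the tet is non-degenerate; det(A) = 6 V.
.tet_gradients <- function(coords) {
  A <- cbind(1, coords)
  detA <- det(A)
  V <- detA / 6
  if (!is.finite(V) || abs(V) < .Machine$double.eps * 100) {
    stop("degenerate tetrahedron (zero volume)")
  }
  Ci <- solve(A)
  list(grads = Ci[2:4, , drop = FALSE], volume = V)
}

# Strain-displacement matrix B (6x12) of the constant-strain tetrahedron,
# Voigt order (xx, yy, zz, xy, yz, zx) with engineering shear strains.
.tet_B <- function(grads) {
  B <- matrix(0, 6L, 12L)
  for (i in 1:4) {
    bx <- grads[1L, i]; by <- grads[2L, i]; bz <- grads[3L, i]
    c0 <- 3L * (i - 1L)
    B[1L, c0 + 1L] <- bx
    B[2L, c0 + 2L] <- by
    B[3L, c0 + 3L] <- bz
    B[4L, c0 + 1L] <- by; B[4L, c0 + 2L] <- bx
    B[5L, c0 + 2L] <- bz; B[5L, c0 + 3L] <- by
    B[6L, c0 + 1L] <- bz; B[6L, c0 + 3L] <- bx
  }
  B
}

#' Element stiffness matrix of a constant-strain tetrahedron
#'
#' Ke = V * t(B) D B, with B the constant 6x12 strain-displacement matrix
#' from the linear shape-function gradients. Symmetric with exactly six
#' zero eigenvalues (the rigid-body modes).
#'
#' @param coords 4x3 matrix of node coordinates, mm.
#' @param mat a `fem_material`.
#' @return 12x12 stiffness matrix (N/mm); DOF order is (x,y,z) per node.
#' @export
element_stiffness <- function(coords, mat) {
  g <- .tet_gradients(as.matrix(coords))
  if (g$volume < 0) stop("element has negative volume; orient the mesh first")
  B <- .tet_B(g$grads)
  D <- elasticity_matrix(mat)
  g$volume * crossprod(B, D %*% B)
}

#' Load case: point loads and homogeneous displacement constraints
#'
#' @param point_loads numeric matrix or data frame with columns
#'   `node`, `fx`, `fy`, `fz` (N). May have zero rows.
#' @param constraints data frame with columns `node` and logical `x`, `y`,
#'   `z`: `TRUE` means zero prescribed displacement on that axis.
#' @param n_nodes number of mesh nodes, for index validation.
#' @return an object of class `load_case`.
#' @export
load_case <- function(point_loads, constraints, n_nodes) {
  pl <- as.data.frame(point_loads)
  if (nrow(pl) == 0L) {
    pl <- data.frame(node = integer(0), fx = numeric(0),
                     fy = numeric(0), fz = numeric(0))
  }
  stopifnot(all(c("node", "fx", "fy", "fz") %in% names(pl)))
  cn <- as.data.frame(constraints)
  stopifnot(all(c("node", "x", "y", "z") %in% names(cn)))
  pl$node <- as.integer(pl$node)
  cn$node <- as.integer(cn$node)
  if (nrow(pl) && (min(pl$node) < 1L || max(pl$node) > n_nodes)) {
    stop("point load references invalid node index")
  }
  if (nrow(cn) && (min(cn$node) < 1L || max(cn$node) > n_nodes)) {
    stop("constraint references invalid node index")
  }
  ndof <- sum(cn$x) + sum(cn$y) + sum(cn$z)
  if (ndof < 6L) {
    stop("load case has ", ndof, " constrained DOFs; at least 6 are needed ",
         "to suppress rigid-body motion")
  }
  # a node must not carry an applied force component on a constrained axis
  if (nrow(pl)) {
    for (ax in c("x", "y", "z")) {
      fcol <- paste0("f", ax)
      cons_nodes <- cn$node[cn[[ax]]]
      bad <- pl$node %in% cons_nodes & abs(pl[[fcol]]) > 0
      if (any(bad)) {
        stop("node ", pl$node[which(bad)[1L]], " is both loaded and ",
             "constrained on the ", ax, " axis")
      }
    }
  }
  structure(list(point_loads = pl, constraints = cn, n_nodes = n_nodes),
            class = "load_case")
}

# Constrained global DOF indices (x,y,z interleaved per node) of a load case.
.constrained_dofs <- function(lc) {
  cn <- lc$constraints
  dofs <- c(
    3L * (cn$node[cn$x] - 1L) + 1L,
    3L * (cn$node[cn$y] - 1L) + 2L,
    3L * (cn$node[cn$z] - 1L) + 3L)
  sort(unique(dofs))
}

# Global load vector (length 3N) of a load case.
.load_vector <- function(lc) {
  f <- numeric(3L * lc$n_nodes)
  pl <- lc$point_loads
  if (nrow(pl)) {
    base <- 3L * (pl$node - 1L)
    # accumulate: a node may receive several point loads (e.g. two muscles)
    for (k in seq_len(nrow(pl))) {
      f[base[k] + 1L] <- f[base[k] + 1L] + pl$fx[k]
      f[base[k] + 2L] <- f[base[k] + 2L] + pl$fy[k]
      f[base[k] + 3L] <- f[base[k] + 3L] + pl$fz[k]
    }
  }
  f
}

# Per-element D matrices keyed by material label.
.material_D <- function(mesh, materials) {
  labels <- unique(mesh$element_material)
  missing <- setdiff(labels, names(materials))
  if (length(missing)) {
    stop("no material supplied for label(s): ", paste(missing, collapse = ", "))
  }
  Ds <- lapply(materials[labels], elasticity_matrix)
  names(Ds) <- labels
  Ds
}

#' Assemble the global sparse stiffness matrix
#'
#' Sum of element stiffness contributions into a symmetric 3N x 3N sparse
#' matrix (N/mm), DOFs ordered (x,y,z) per node.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named list of `fem_material`, keyed by the labels in
#'   `mesh$element_material`.
#' @return a `Matrix::dgCMatrix`.
#' @export
assemble_stiffness <- function(mesh, materials) {
  ne <- nrow(mesh$elements)
  Ds <- .material_D(mesh, materials)
  ii <- integer(144L * ne)
  jj <- integer(144L * ne)
  xx <- numeric(144L * ne)
  pos <- 0L
  col_idx <- rep(1:12, each = 12L)
  row_idx <- rep(1:12, times = 12L)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    g <- .tet_gradients(mesh$nodes[en, , drop = FALSE])
    B <- .tet_B(g$grads)
    Ke <- g$volume * crossprod(B, Ds[[mesh$element_material[e]]] %*% B)
    dofs <- rep(3L * (en - 1L), each = 3L) + rep(1:3, times = 4L)
    rng <- pos + 1:144
    ii[rng] <- dofs[row_idx]
    jj[rng] <- dofs[col_idx]
    xx[rng] <- Ke
    pos <- pos + 144L
  }
  n <- 3L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' von Mises equivalent stress
#'
#' @param stress either a symmetric 3x3 stress tensor or a length-6 Voigt
#'   vector (xx, yy, zz, xy, yz, zx), MPa.
#' @return the scalar von Mises stress, MPa (non-negative).
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress)) {
    stopifnot(all(dim(stress) == c(3L, 3L)))
    s <- c(stress[1, 1], stress[2, 2], stress[3, 3],
           stress[1, 2], stress[2, 3], stress[3, 1])
  } else {
    stopifnot(length(stress) == 6L)
    s <- as.numeric(stress)
  }
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
       3 * (s[4]^2 + s[5]^2 + s[6]^2))
}

# Vectorised von Mises over rows of an ne x 6 Voigt stress matrix.
.von_mises_rows <- function(S) {
  sqrt(0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
              (S[, 3] - S[, 1])^2) +
       3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2))
}

#' Solve a linear-elastic load case
#'
#' Assembles the tet4 stiffness, eliminates constrained DOFs exactly (no
#' penalty terms, which would contaminate the trimmed peak statistic),
#' solves the reduced symmetric positive-definite system with a sparse
#' direct factorisation, and recovers element stresses (sigma = D B u,
#' constant per element), the element-nodal von Mises multiset (each
#' element's value replicated at its 4 corners, mirroring a commercial
#' solver's element-nodal report), reactions at constrained DOFs, and total
#' strain energy U = 0.5 * f.u over the applied loads.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named list of `fem_material`.
#' @param lc a `load_case`.
#' @param method `"direct"` (sparse Cholesky) or `"cg"` (conjugate
#'   gradients, relative residual 1e-10); both deterministic.
#' @return an object of class `fem_solution` with `displacements` (N x 3,
#'   mm), `element_stress` (ne x 6 Voigt, MPa), `element_vm` (ne),
#'   `element_nodal_vm` (4*ne), `strain_energy` (N.mm), and `reactions`
#'   (data frame node/rx/ry/rz, N).
#' @export
solve_fem <- function(mesh, materials, lc, method = c("direct", "cg")) {
  method <- match.arg(method)
  stopifnot(inherits(lc, "load_case"))
  if (lc$n_nodes != nrow(mesh$nodes)) {
    stop("load case was built for a different node count")
  }
  K <- assemble_stiffness(mesh, materials)
  f <- .load_vector(lc)
  fixed <- .constrained_dofs(lc)
  free <- setdiff(seq_len(3L * nrow(mesh$nodes)), fixed)

  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- if (method == "direct") {
    tryCatch(
      # CHOLMOD warns before erroring on an indefinite matrix; the error
      # carries the diagnosis, so the warning is redundant noise
      suppressWarnings(
        as.numeric(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE,
                                                  perm = TRUE),
                                 f[free], system = "A"))),
      error = function(e) {
        stop("stiffness matrix is singular on the free DOFs ",
             "(unsuppressed rigid-body mode): ", conditionMessage(e))
      })
  } else {
    .solve_cg(Kff, f[free])
  }
  u <- numeric(3L * nrow(mesh$nodes))
  u[free] <- uf

  ne <- nrow(mesh$elements)
  Ds <- .material_D(mesh, materials)
  S <- matrix(0, ne, 6L)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    g <- .tet_gradients(mesh$nodes[en, , drop = FALSE])
    B <- .tet_B(g$grads)
    ue <- u[rep(3L * (en - 1L), each = 3L) + rep(1:3, times = 4L)]
    S[e, ] <- Ds[[mesh$element_material[e]]] %*% (B %*% ue)
  }
  vm <- .von_mises_rows(S)

  r_full <- as.numeric(K %*% u) - f
  cn <- unique(lc$constraints$node)
  reactions <- data.frame(
    node = cn,
    rx = r_full[3L * (cn - 1L) + 1L],
    ry = r_full[3L * (cn - 1L) + 2L],
    rz = r_full[3L * (cn - 1L) + 3L])

  structure(list(
    displacements = matrix(u, ncol = 3L, byrow = TRUE),
    element_stress = S,
    element_vm = vm,
    element_nodal_vm = rep(vm, each = 4L),
    strain_energy = 0.5 * sum(f * u),
    reactions = reactions,
    load_case = lc,
    method = method), class = "fem_solution")
}

# Conjugate gradients on the reduced SPD system; Jacobi preconditioner.
.solve_cg <- function(A, b, tol = 1e-10, maxit = 50000L) {
  x <- numeric(length(b))
  if (all(b == 0)) return(x)
  d <- Matrix::diag(A)
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / b2 < tol) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradients did not converge; relative residual ",
       format(sqrt(sum(r^2)) / b2))
}

#' @export
print.fem_solution <- function(x, ...) {
  cat("fem_solution:", nrow(x$displacements), "nodes,",
      length(x$element_vm), "elements\n")
  cat("  max |u| =", format(max(abs(x$displacements))), "mm;",
      "peak element vm =", format(max(x$element_vm)), "MPa;",
      "U =", format(x$strain_energy), "N.mm\n")
  invisible(x)
}

#' Per-node averaged von Mises field
#'
#' Unweighted average of the element von Mises values over the elements
#' incident to each node; used only for smooth contour export, never for
#' the comparative statistics (which use the raw element-nodal multiset).
#'
#' @param mesh a `tet_mesh`.
#' @param solution a `fem_solution` on that mesh.
#' @return numeric vector, one value per node.
#' @export
nodal_von_mises <- function(mesh, solution) {
  n <- nrow(mesh$nodes)
  acc <- numeric(n)
  cnt <- numeric(n)
  idx <- as.vector(mesh$elements)  # column-major: node slot 1 of all
  val <- rep(solution$element_vm, times = 4L)  # elements, then slot 2, ...
  tab <- tapply(val, idx, sum)
  acc[as.integer(names(tab))] <- tab
  cnt_tab <- table(idx)
  cnt[as.integer(names(cnt_tab))] <- as.numeric(cnt_tab)
  ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
}
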