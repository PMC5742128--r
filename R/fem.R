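# Linear (P1) tetrahedral finite elements: shape-function gradients, stiffness
# assembly for scalar and tensor conductivity, boundary (Robin/Neumann) terms.

# Per-tet P1 basis gradients. Returns volumes (m) and g1..g4 (m x 3 each).
p1_gradients <- function(vertices, tets) {
  p1 <- vertices[tets[, 1], , drop = FALSE]
  e2 <- vertices[tets[, 2], , drop = FALSE] - p1
  e3 <- vertices[tets[, 3], , drop = FALSE] - p1
  e4 <- vertices[tets[, 4], , drop = FALSE] - p1
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c34 <- cross3(e3, e4)
  six_v <- rowSums(e2 * c34)           # 6 * signed volume (positive, oriented)
  g2 <- c34 / six_v
  g3 <- cross3(e4, e2) / six_v
  g4 <- cross3(e2, e3) / six_v
  g1 <- -(g2 + g3 + g4)
  list(vol = six_v / 6, g = list(g1, g2, g3, g4))
}

# sigma: either a numeric vector (per-tet isotropic) or a list of 6 per-tet
# component vectors s11,s22,s33,s12,s13,s23 (symmetric tensor).
assemble_stiffness <- function(vertices, tets, sigma = 1) {
  pg <- p1_gradients(vertices, tets)
  m <- nrow(tets)
  iso <- !is.list(sigma)
  if (iso) sigma <- rep_len(sigma, m)
  quad <- function(a, b) {
    if (iso) {
      sigma * rowSums(a * b)
    } else {
      s <- sigma
      s$s11 * a[, 1] * b[, 1] + s$s22 * a[, 2] * b[, 2] + s$s33 * a[, 3] * b[, 3] +
        s$s12 * (a[, 1] * b[, 2] + a[, 2] * b[, 1]) +
        s$s13 * (a[, 1] * b[, 3] + a[, 3] * b[, 1]) +
        s$s23 * (a[, 2] * b[, 3] + a[, 3] * b[, 2])
    }
  }
  ii <- jj <- xx <- vector("list", 16)
  k <- 0
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1
    ii[[k]] <- tets[, a]
    jj[[k]] <- tets[, b]
    xx[[k]] <- pg$vol * quad(pg$g[[a]], pg$g[[b]])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(vertices), 2))
}

# Consistent surface mass matrix for triangle faces (k x 3 idx) scaled by
# per-face coefficient alpha: integral over faces of alpha * u * v.
assemble_face_mass <- function(vertices, faces, alpha, n) {
  if (!nrow(faces)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(n, n)))
  A <- tri_areas(vertices, faces) * alpha
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- faces[, a]
    jj[[k]] <- faces[, b]
    xx[[k]] <- A * (if (a == b) 2 else 1) / 12
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Load vector for integral over faces of g * v with per-face constant g.
face_load <- function(vertices, faces, g, n) {
  f <- numeric(n)
  if (!nrow(faces)) return(f)
  w <- tri_areas(vertices, faces) * g / 3
  for (a in 1:3) {
    acc <- rowsum(w, faces[, a])
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }
  f
}

# Solve K u = f with Dirichlet values u[d] = ud by row/column elimination.
# Returns list(u, reaction) where reaction = (K u - f) restricted to d rows.
solve_dirichlet <- function(K, f, d, ud = 0) {
  n <- length(f)
  if (!length(d)) stop("singular system: no Dirichlet constraints")
  ud <- rep_len(ud, length(d))
  free <- setdiff(seq_len(n), d)
  u <- numeric(n)
  u[d] <- ud
  rhs <- f[free] - as.vector(K[free, d, drop = FALSE] %*% ud)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u[free] <- as.vector(Matrix::solve(Kff, rhs))
  reaction <- as.vector(K[d, , drop = FALSE] %*% u) - f[d]
  list(u = u, reaction = reaction)
}

#' Scalar field on a mesh
#'
#' One value per mesh vertex; \code{NA} outside the sub-region a solve was
#' restricted to. Dimensionless for the fiber-orientation machinery, volts
#' for electrical solves.
#'
#' @param values numeric vector, one per mesh vertex.
#' @param region region label the field was solved on (or \code{NULL} for a
#'   whole-mesh field).
#' @return object of class \code{scalar_field}.
#' @export
scalar_field <- function(values, region = NULL) {
  structure(list(values = values, region = region), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<scalar_field> %d values%s, range [%.4g, %.4g]\n", length(v),
              if (!is.null(x$region)) paste0(" on '", x$region, "'") else "",
              min(v), max(v)), sep = "")
  invisible(x)
}

# map patch faces into submesh vertex numbering
patch_faces_in_submesh <- function(sub, patch) {
  remap <- integer(max(sub$vertex_map))
  remap[sub$vertex_map] <- seq_along(sub$vertex_map)
  f <- patch$faces
  if (any(f > length(remap)) || any(remap[f] == 0))
    stop("patch does not lie on the region boundary")
  matrix(remap[f], ncol = 3)
}

#' Distance-surrogate Laplace solve on a nerve region
#'
#' Solves the Laplace equation on a single-connected region with the
#' potential clamped to 0 on the start surface and a uniform unit outflow
#' over the remainder of the region boundary. The resulting field is a
#' distance surrogate: it is non-positive and its minimum lies near the
#' point most distant from the start surface, which is how the target
#' surface of a nerve branch is located automatically.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region region label (must be single-connected).
#' @param start a \code{surface_patch} on the region boundary (the start
#'   surface Gamma_s); must be nonempty.
#' @return a \code{\link{scalar_field}} (values \code{NA} outside the region).
#' @export
solve_distance_surrogate <- function(mesh, region, start) {
  check_region(mesh, region)
  if (!patch_size(start)) stop("empty start surface")
  sub <- submesh(mesh, which(mesh$region == region))
  n <- nrow(sub$vertices)
  K <- assemble_stiffness(sub$vertices, sub$tets)

  bnd <- region_boundary(sub, region, "all")
  sf <- patch_faces_in_submesh(sub, start)
  key_of <- function(f) {
    fs <- t(apply(f, 1, sort.int))
    (as.numeric(fs[, 1]) * (n + 1) + fs[, 2]) * (n + 1) + fs[, 3]
  }
  is_start <- key_of(bnd$faces) %in% key_of(sf)
  neumann_faces <- bnd$faces[!is_start, , drop = FALSE]
  # -grad(phi).n = 1 on Gamma \ Gamma_s  =>  rhs contribution -area/3
  f <- face_load(sub$vertices, neumann_faces, -1, n)
  d <- sort(unique(as.vector(sf)))
  sol <- solve_dirichlet(K, f, d, 0)
  vals <- rep(NA_real_, nrow(mesh$vertices))
  vals[sub$vertex_map] <- sol$u
  scalar_field(vals, region)
}

#' Cauchy (Robin) coupling parameters for the orientation solve
#'
#' @param alpha_s,alpha_t coupling coefficients on the start and target
#'   surfaces (1/m; the external potential is 0 on Gamma_s and 1 on Gamma_t,
#'   insulating elsewhere). Both must be positive. Default 100, with larger
#'   values forcing a steeper fiber entry/exit angle at the surfaces.
#' @return object of class \code{cauchy_params}.
#' @export
cauchy_params <- function(alpha_s = 100, alpha_t = 100) {
  if (alpha_s <= 0 || alpha_t <= 0) stop("alpha_s and alpha_t must be > 0")
  structure(list(alpha_s = alpha_s, alpha_t = alpha_t), class = "cauchy_params")
}

#' Orientation-potential solve with Cauchy boundary conditions
#'
#' Solves the Laplace equation on a nerve region with a Robin (Cauchy)
#' boundary condition \eqn{-\nabla\phi\cdot n = \alpha(x)[\phi - \phi_e(x)]}
#' applied on the whole region surface, where \eqn{(\alpha,\phi_e)} is
#' \eqn{(\alpha_s, 0)} on the start surface, \eqn{(\alpha_t, 1)} on the
#' target surface and \eqn{(0,\cdot)} (natural/insulating) elsewhere. The
#' potential rises continuously from the start to the target surface; its
#' normalized gradient is the nerve-fiber orientation field.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region region label.
#' @param start,target nonempty, disjoint \code{surface_patch}es on the
#'   region boundary.
#' @param params a \code{\link{cauchy_params}}.
#' @return a \code{\link{scalar_field}} with values in approximately [0, 1].
#' @export
solve_orientation_potential <- function(mesh, region, start, target,
                                        params = cauchy_params()) {
  check_region(mesh, region)
  if (!patch_size(start) || !patch_size(target))
    stop("start and target surfaces must be nonempty")
  sub <- submesh(mesh, which(mesh$region == region))
  n <- nrow(sub$vertices)
  sf <- patch_faces_in_submesh(sub, start)
  tf <- patch_faces_in_submesh(sub, target)
  key <- function(f) {
    fs <- t(apply(f, 1, sort.int))
    (as.numeric(fs[, 1]) * (n + 1) + fs[, 2]) * (n + 1) + fs[, 3]
  }
  if (length(intersect(key(sf), key(tf))))
    stop("start and target surfaces overlap")
  K <- assemble_stiffness(sub$vertices, sub$tets)
  K <- K + assemble_face_mass(sub$vertices, sf, params$alpha_s, n) +
           assemble_face_mass(sub$vertices, tf, params$alpha_t, n)
  # rhs: integral over Gamma_t of alpha_t * phi_e * v with phi_e = 1
  f <- face_load(sub$vertices, tf, params$alpha_t, n)
  u <- as.vector(Matrix::solve(Matrix::forceSymmetric(K), f))
  vals <- rep(NA_real_, nrow(mesh$vertices))
  vals[sub$vertex_map] <- u
  scalar_field(vals, region)
}

#' Orientation field from a potential
#'
#' Evaluates the normed per-tet P1 gradient of the orientation potential,
#' \eqn{F = \nabla\phi / |\nabla\phi|}. Tets with a vanishing gradient
#' (below 1e-12) inherit the average direction of their face neighbours.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region region label the field lives on.
#' @param field a \code{\link{scalar_field}} solved on that region.
#' @return an \code{orientation_field}: unit 3-vectors, one per region tet
#'   (elements \code{vectors}, \code{tet_ids} (global ids), \code{region},
#'   \code{mesh}).
#' @export
orientation_from_potential <- function(mesh, region, field) {
  check_region(mesh, region)
  idx <- which(mesh$region == region)
  sub <- submesh(mesh, idx)
  u <- field$values[sub$vertex_map]
  if (anyNA(u)) stop("field not solved on region '", region, "'")
  pg <- p1_gradients(sub$vertices, sub$tets)
  grad <- pg$g[[1]] * u[sub$tets[, 1]] + pg$g[[2]] * u[sub$tets[, 2]] +
          pg$g[[3]] * u[sub$tets[, 3]] + pg$g[[4]] * u[sub$tets[, 4]]
  nrm <- sqrt(rowSums(grad^2))
  bad <- which(nrm < 1e-12)
  F_ <- grad / pmax(nrm, 1e-300)
  if (length(bad)) {
    adj <- interior_face_pairs(sub)
    nb <- split(c(adj[, 2], adj[, 1]), c(adj[, 1], adj[, 2]))
    for (pass in 1:10) {
      still <- integer(0)
      for (t in bad) {
        nbs <- setdiff(nb[[as.character(t)]], bad)
        if (length(nbs)) {
          v <- colMeans(F_[nbs, , drop = FALSE])
          nv <- sqrt(sum(v^2))
          if (nv > 1e-12) { F_[t, ] <- v / nv; next }
        }
        still <- c(still, t)
      }
      bad <- still
      if (!length(bad)) break
    }
    if (length(bad)) stop("orientation field degenerate on ", length(bad), " tets")
  }
  structure(list(vectors = F_, tet_ids = idx, region = region, mesh = mesh,
                 cache = new.env(parent = emptyenv())),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d unit vectors on region '%s'\n",
              nrow(x$vectors), x$region))
  invisible(x)
}
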