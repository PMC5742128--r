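# Automatic start/target surface determination for nerve branches:
# distance-surrogate solve -> extremal surface point -> geodesic patch.

#' Extremal (minimum-field) vertex on a surface
#'
#' The surface vertex with the minimal field value; with the distance
#' surrogate this approximates the surface point most distant from the start
#' surface. Ties are broken by the lowest vertex index.
#'
#' @param field a \code{\link{scalar_field}}.
#' @param surface a \code{surface_patch} (nonempty).
#' @return vertex index (parent mesh id).
#' @export
find_extremal_point <- function(field, surface) {
  verts <- patch_vertices(surface)
  if (!length(verts)) stop("empty surface")
  v <- field$values[verts]
  if (anyNA(v)) stop("field not defined on all surface vertices")
  verts[which.min(v)]
}

#' Automatic target surface of a nerve region
#'
#' Composition of the distance-surrogate solve, the extremal-point search and
#' a Dijkstra geodesic patch: the target surface consists of all boundary
#' triangles within \code{patch_radius} (surface graph distance) of the
#' approximated most distant point from the start surface.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region region label.
#' @param start start \code{surface_patch}.
#' @param patch_radius geodesic radius of the target patch (m), > 0.
#' @return a \code{surface_patch} with role \code{"target"}, disjoint from
#'   \code{start} (an error advises a smaller radius otherwise).
#' @export
find_target_surface <- function(mesh, region, start, patch_radius) {
  if (patch_radius <= 0) stop("patch_radius must be > 0")
  phi <- solve_distance_surrogate(mesh, region, start)
  bnd <- region_boundary(mesh, region, "all")
  far <- find_extremal_point(phi, bnd)
  target <- surface_geodesic_patch(mesh, bnd, far, patch_radius, role = "target")
  fkey <- function(f) {
    fs <- t(apply(f, 1, sort.int))
    paste(fs[, 1], fs[, 2], fs[, 3])
  }
  if (length(intersect(fkey(target$faces), fkey(start$faces))))
    stop("target patch overlaps the start surface; use a smaller patch_radius")
  target
}

#' Automatic start surface for a tube-like region
#'
#' For tube-like nerve volumes without a labeled sensory contact (the facial
#' nerve case): a seeded random boundary triangle serves as a temporary start
#' surface, a distance-surrogate solve locates the most distant surface
#' point (a tube end), and the geodesic patch around it becomes the
#' definitive start surface. Deterministic given the seed.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region tube-like region label.
#' @param patch_radius geodesic radius of the returned patch (m).
#' @param rng_seed integer seed for the random temporary surface element.
#' @return a \code{surface_patch} with role \code{"start"}.
#' @export
auto_start_surface_tube <- function(mesh, region, patch_radius, rng_seed = 1L) {
  bnd <- region_boundary(mesh, region, "all")
  if (!patch_size(bnd)) stop("region has no boundary")
  k <- with_seed(rng_seed, sample.int(patch_size(bnd), 1))
  tmp <- surface_patch(bnd$faces[k, , drop = FALSE], region,
                       bnd$normals[k, , drop = FALSE], "start", bnd$tet[k])
  phi <- solve_distance_surrogate(mesh, region, tmp)
  far <- find_extremal_point(phi, bnd)
  surface_geodesic_patch(mesh, bnd, far, patch_radius, role = "start")
}

# ---- point location and interpolation ---------------------------------------

# Uniform-grid bucket locator over tets; cells sized ~ mean tet scale.
build_locator <- function(vertices, tets) {
  lo <- apply(vertices, 2, min)
  hi <- apply(vertices, 2, max)
  p <- lapply(1:4, function(k) vertices[tets[, k], , drop = FALSE])
  bb_lo <- pmin(p[[1]], p[[2]], p[[3]], p[[4]])
  bb_hi <- pmax(p[[1]], p[[2]], p[[3]], p[[4]])
  # cell at least as large as any tet bbox: a tet covers <= 2 cells per axis
  hchar <- max(bb_hi - bb_lo) * 1.01
  nc <- pmax(1L, pmin(128L, as.integer(floor((hi - lo) / hchar))))
  cell <- (hi - lo) / nc
  cell[cell == 0] <- 1
  cidx <- function(x, k) pmin(nc[k] - 1L, pmax(0L, as.integer(floor((x - lo[k]) / cell[k]))))
  m <- nrow(tets)
  lo_i <- cbind(cidx(bb_lo[, 1], 1), cidx(bb_lo[, 2], 2), cidx(bb_lo[, 3], 3))
  hi_i <- cbind(cidx(bb_hi[, 1], 1), cidx(bb_hi[, 2], 2), cidx(bb_hi[, 3], 3))
  cells <- integer(0); tet_rep <- integer(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    xs <- if (cx) hi_i[, 1] else lo_i[, 1]
    ys <- if (cy) hi_i[, 2] else lo_i[, 2]
    zs <- if (cz) hi_i[, 3] else lo_i[, 3]
    cells <- c(cells, xs + nc[1] * (ys + nc[2] * zs))
    tet_rep <- c(tet_rep, seq_len(m))
  }
  pair <- unique(cbind(cells, tet_rep))
  bucket <- split(pair[, 2], pair[, 1])
  # barycentric transform: lambda_{2..4} = Tinv (x - p1)
  e <- cbind(p[[2]] - p[[1]], p[[3]] - p[[1]], p[[4]] - p[[1]])  # m x 9
  Tinv <- matrix(0, nrow(tets), 9)
  det3 <- e[, 1] * (e[, 5] * e[, 9] - e[, 8] * e[, 6]) -
          e[, 4] * (e[, 2] * e[, 9] - e[, 8] * e[, 3]) +
          e[, 7] * (e[, 2] * e[, 6] - e[, 5] * e[, 3])
  # columns of e: [e2x e2y e2z e3x e3y e3z e4x e4y e4z]; matrix M = [e2 e3 e4]
  # inverse via cofactors of M (column-major 3x3 per tet)
  M <- function(i, j) e[, (j - 1) * 3 + i]
  co <- function(i1, j1, i2, j2) M(i1, j1) * M(i2, j2) - M(i1, j2) * M(i2, j1)
  Tinv[, 1] <- co(2, 2, 3, 3) / det3; Tinv[, 4] <- -co(1, 2, 3, 3) / det3; Tinv[, 7] <- co(1, 2, 2, 3) / det3
  Tinv[, 2] <- -co(2, 1, 3, 3) / det3; Tinv[, 5] <- co(1, 1, 3, 3) / det3; Tinv[, 8] <- -co(1, 1, 2, 3) / det3
  Tinv[, 3] <- co(2, 1, 3, 2) / det3; Tinv[, 6] <- -co(1, 1, 3, 2) / det3; Tinv[, 9] <- co(1, 1, 2, 2) / det3
  list(lo = lo, nc = nc, cell = cell, bucket = bucket,
       p1 = p[[1]], Tinv = Tinv, tets = tets, vertices = vertices)
}

# barycentric coords of point x in tets ts (rows of locator arrays)
bary_in <- function(loc, ts, x) {
  dx <- x[1] - loc$p1[ts, 1]; dy <- x[2] - loc$p1[ts, 2]; dz <- x[3] - loc$p1[ts, 3]
  Ti <- loc$Tinv
  l2 <- Ti[ts, 1] * dx + Ti[ts, 4] * dy + Ti[ts, 7] * dz
  l3 <- Ti[ts, 2] * dx + Ti[ts, 5] * dy + Ti[ts, 8] * dz
  l4 <- Ti[ts, 3] * dx + Ti[ts, 6] * dy + Ti[ts, 9] * dz
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

locate_point <- function(loc, x, tol = 1e-9) {
  ci <- pmin(loc$nc - 1L, pmax(0L, as.integer(floor((x - loc$lo) / loc$cell))))
  id <- as.character(ci[1] + loc$nc[1] * (ci[2] + loc$nc[2] * ci[3]))
  cand <- loc$bucket[[id]]
  if (is.null(cand)) return(NULL)
  lb <- bary_in(loc, cand, x)
  worst <- apply(lb, 1, min)
  best <- which.max(worst)
  if (worst[best] >= -tol) list(tet = cand[best], bary = lb[best, ]) else NULL
}

#' Interpolate a vertex field at arbitrary points
#'
#' Barycentric P1 interpolation inside the containing tetrahedron, found by
#' a bucketed point-location search. Points within a small tolerance outside
#' an element face are snapped to it.
#'
#' @param mesh a \code{\link{tet_mesh}} (or a \code{unit_potential}, whose
#'   mesh and values are then used).
#' @param values numeric vertex field (omitted when \code{mesh} is a
#'   \code{unit_potential}).
#' @param points numeric matrix (k x 3) of query positions (m).
#' @param tol barycentric snap tolerance (default 1e-6 relative).
#' @return numeric vector of interpolated values.
#' @export
interpolate_at_points <- function(mesh, values, points, tol = 1e-6) {
  if (inherits(mesh, "unit_potential")) {
    if (missing(points)) { points <- values } else points <- points
    values <- mesh$field$values
    mesh <- mesh$mesh
  }
  points <- matrix(as.numeric(points), ncol = 3)
  loc <- mesh_locator(mesh)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    hit <- locate_point(loc, points[i, ], tol)
    if (is.null(hit))
      stop(sprintf("point outside mesh: (%.6g, %.6g, %.6g)",
                   points[i, 1], points[i, 2], points[i, 3]))
    b <- pmax(hit$bary, 0); b <- b / sum(b)
    out[i] <- sum(values[mesh$tets[hit$tet, ]] * b)
  }
  out
}

# cache a locator on the mesh via attribute-environment
mesh_locator <- function(mesh) {
  cache <- attr(mesh, "locator_cache")
  if (is.environment(cache) && !is.null(cache$loc)) return(cache$loc)
  loc <- build_locator(mesh$vertices, mesh$tets)
  if (is.environment(cache)) cache$loc <- loc
  loc
}
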