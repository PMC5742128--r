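#' Labeled tetrahedral mesh
#'
#' The central geometry container of the package: a conforming tetrahedral
#' mesh in which every tetrahedron carries a tissue-region label (e.g.
#' \code{"bone"}, \code{"saline"}, \code{"endolymph"}, \code{"nerve_target"}).
#' All solver stages (fiber-orientation Laplace solves, anisotropic Poisson
#' solves) operate on this structure. Coordinates are in meters (SI units are
#' used throughout the package).
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in meters.
#' @param tets integer matrix (m x 4) of 1-based vertex indices.
#' @param region character vector of length m: region label per tetrahedron.
#' @param orig_region optional character vector of original labels, kept when
#'   electrodes overwrite tissue labels so they can be restored exactly.
#' @param validate if \code{TRUE} (default) the mesh is checked for positive
#'   tet volumes (after consistent re-orientation), mesh conformity (every
#'   interior face shared by exactly 2 tets) and duplicate vertices.
#' @return an object of class \code{tet_mesh} with elements \code{vertices},
#'   \code{tets}, \code{region}, and optionally \code{orig_region}.
#' @export
tet_mesh <- function(vertices, tets, region, orig_region = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(tets) == 4)
  region <- as.character(region)
  if (length(region) != nrow(tets))
    stop("region must have one label per tetrahedron")
  if (min(tets) < 1 || max(tets) > nrow(vertices))
    stop("tet vertex indices out of range")

  m <- orient_tets(vertices, tets)
  mesh <- structure(
    list(vertices = vertices, tets = m, region = region,
         orig_region = orig_region),
    class = "tet_mesh",
    locator_cache = new.env(parent = emptyenv()))
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tets\n", nrow(x$vertices), nrow(x$tets)))
  tab <- sort(table(x$region), decreasing = TRUE)
  cat("regions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Signed volumes of tets (m^3); positive when (v2-v1, v3-v1, v4-v1) right-handed.
tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - a
  e2 <- vertices[tets[, 3], , drop = FALSE] - a
  e3 <- vertices[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

# Flip tets with negative signed volume so all volumes are positive.
orient_tets <- function(vertices, tets) {
  v <- tet_signed_volumes(vertices, tets)
  if (any(v == 0)) stop("degenerate (zero-volume) tetrahedra present")
  neg <- v < 0
  if (any(neg)) {
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
  }
  tets
}

#' Tetrahedron volumes
#' @param mesh a \code{tet_mesh}.
#' @return numeric vector of positive tet volumes in cubic meters.
#' @export
tet_volumes <- function(mesh) {
  abs(tet_signed_volumes(mesh$vertices, mesh$tets))
}

# Local faces of a tet, ordered so the face is opposite the excluded vertex.
.tet_face_local <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))

# All 4m faces: matrix with sorted vertex triples, owning tet, opposite vertex.
tet_face_table <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  f <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)],
             tets[, c(1L, 2L, 4L)], tets[, c(1L, 3L, 2L)])
  opp <- c(tets[, 1L], tets[, 2L], tets[, 3L], tets[, 4L])
  fs <- t(apply(f, 1L, sort.int))
  # 53-bit-safe numeric key for a sorted triple
  n <- nrow(mesh$vertices)
  key <- (as.numeric(fs[, 1]) * (n + 1) + fs[, 2]) * (n + 1) + fs[, 3]
  list(faces = f, sorted = fs, tet = rep.int(seq_len(m), 4L), opp = opp, key = key)
}

# Face census: for each unique face, how many tets share it and which.
face_census <- function(mesh, ft = tet_face_table(mesh)) {
  o <- order(ft$key)
  k <- ft$key[o]
  grp <- cumsum(c(TRUE, k[-1] != k[-length(k)]))
  cnt <- tabulate(grp)
  list(order = o, group = grp, count = cnt, ft = ft)
}

#' Validate a labeled tetrahedral mesh
#'
#' Checks positive tet volumes, conformity (every face incident to at most 2
#' tets; faces incident to 2 tets are interior, to 1 are boundary) and absence
#' of duplicated vertex coordinates (coincident vertices with distinct indices
#' make geometrically touching tets that claim no shared face, a classic
#' non-conformity in assembled label meshes).
#'
#' @param mesh a \code{tet_mesh}.
#' @return invisibly \code{TRUE}; otherwise an error naming offending entities.
#' @export
validate_mesh <- function(mesh) {
  v <- tet_signed_volumes(mesh$vertices, mesh$tets)
  if (any(v <= 0)) stop("non-positive tet volumes at tets: ",
                        paste(utils::head(which(v <= 0), 5), collapse = ", "))
  fc <- face_census(mesh)
  if (any(fc$count > 2)) {
    bad <- which(fc$count > 2)[1]
    rows <- fc$order[fc$group == bad]
    stop("nonconforming mesh: face {",
         paste(fc$ft$sorted[rows[1], ], collapse = ","),
         "} shared by ", fc$count[bad], " tets")
  }
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("nonconforming mesh: duplicated vertex coordinates (vertex ", dup,
         " coincides with an earlier vertex); tets touching through ",
         "coincident vertices share no face")
  }
  invisible(TRUE)
}

#' Regions present in a mesh
#' @param mesh a \code{tet_mesh}.
#' @return character vector of region labels.
#' @export
mesh_regions <- function(mesh) sort(unique(mesh$region))

check_region <- function(mesh, region) {
  missing <- setdiff(region, mesh$region)
  if (length(missing))
    stop("unknown region id(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Connected components of a region (face adjacency)
#'
#' Nerve volumes used for the fiber-orientation solves must form a single
#' connected region; this reports the face-adjacency components.
#'
#' @param mesh a \code{tet_mesh}.
#' @param region region label.
#' @return integer vector: component id per tet of the region (in region order).
#' @export
region_components <- function(mesh, region) {
  check_region(mesh, region)
  idx <- which(mesh$region == region)
  sub <- submesh(mesh, idx)
  adj <- interior_face_pairs(sub)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
  igraph::components(g)$membership
}

# Pairs of tets sharing an interior face (two-column matrix of tet ids).
interior_face_pairs <- function(mesh) {
  fc <- face_census(mesh)
  o <- fc$order
  cnt <- fc$count
  ends <- cumsum(cnt)
  two <- which(cnt == 2)
  if (!length(two)) return(matrix(integer(0), ncol = 2))
  r1 <- o[ends[two] - 1L]
  r2 <- o[ends[two]]
  cbind(fc$ft$tet[r1], fc$ft$tet[r2])
}

# Extract the submesh of the given tets (vertices renumbered). Keeps a map
# back to parent vertex / tet ids.
submesh <- function(mesh, tet_idx) {
  tets <- mesh$tets[tet_idx, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  structure(
    list(vertices = mesh$vertices[used, , drop = FALSE],
         tets = matrix(remap[tets], ncol = 4),
         region = mesh$region[tet_idx],
         vertex_map = used, tet_map = tet_idx),
    class = "tet_mesh")
}

# ---- surface patches ---------------------------------------------------------

#' Surface patch
#'
#' A set of boundary triangles of a region, with outward unit normals and a
#' role tag. Used for start/target surfaces of the fiber-orientation solves
#' (Gamma_s, Gamma_t), the outer saline surface and generic interfaces.
#'
#' @param faces integer matrix (k x 3) of vertex indices (parent mesh indices).
#' @param region owning region label.
#' @param normals numeric matrix (k x 3) of outward unit normals.
#' @param role one of \code{"start"}, \code{"target"}, \code{"outer_saline"},
#'   \code{"reference"}, \code{"generic"}.
#' @param tet integer vector: owning tet (in the parent mesh) per face.
#' @return object of class \code{surface_patch}.
#' @export
surface_patch <- function(faces, region, normals, role = "generic", tet = NULL) {
  faces <- matrix(as.integer(faces), ncol = 3)
  role <- match.arg(role, c("start", "target", "outer_saline", "reference", "generic"))
  structure(list(faces = faces, region = region, normals = normals,
                 role = role, tet = tet),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> %d triangles, region '%s', role '%s'\n",
              nrow(x$faces), x$region, x$role))
  invisible(x)
}

#' Number of triangles in a patch
#' @param patch a \code{surface_patch}.
#' @return integer count.
#' @export
patch_size <- function(patch) nrow(patch$faces)

#' Triangle areas of a patch
#' @param mesh a \code{tet_mesh}.
#' @param patch a \code{surface_patch} on that mesh.
#' @return numeric vector of areas (m^2).
#' @export
patch_areas <- function(mesh, patch) {
  tri_areas(mesh$vertices, patch$faces)
}

tri_areas <- function(vertices, faces) {
  if (!nrow(faces)) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE] - a
  c_ <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Vertices of a patch
#' @param patch a \code{surface_patch}.
#' @return sorted integer vector of vertex indices appearing in the patch.
#' @export
patch_vertices <- function(patch) sort(unique(as.vector(patch$faces)))

# outward normal for faces (k x 3 idx) with opposite (interior) points opp_pt
face_outward_normals <- function(vertices, faces, inside_pts) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE] - a
  c_ <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
             b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
             b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  n <- n / sqrt(rowSums(n^2))
  flip <- rowSums(n * (inside_pts - a)) > 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  n
}

# Shared internal: faces of tets in region A whose neighbor is in set B
# (or has no neighbor when B contains NA meaning "exterior").
region_faces <- function(mesh, region_a, neighbor_in) {
  ft <- tet_face_table(mesh)
  fc <- face_census(mesh, ft)
  o <- fc$order
  grp <- fc$group
  cnt <- fc$count
  rows1 <- o[cumsum(cnt) - cnt + 1]            # first row of each face group
  rows2 <- ifelse(cnt == 2, o[cumsum(cnt)], NA_integer_)
  t1 <- ft$tet[rows1]
  t2 <- ifelse(is.na(rows2), NA_integer_, ft$tet[rows2])
  r1 <- mesh$region[t1]
  r2 <- ifelse(is.na(t2), NA_character_, mesh$region[t2])
  # candidate (owner in A, neighbor satisfying predicate) in either orientation
  keep1 <- r1 == region_a & neighbor_in(r2)
  keep2 <- !is.na(r2) & r2 == region_a & neighbor_in(r1)
  own_rows <- c(rows1[keep1], rows2[keep2])
  own_tet <- c(t1[keep1], t2[keep2])
  faces <- ft$faces[own_rows, , drop = FALSE]
  opp <- ft$opp[own_rows]
  if (!nrow(faces)) {
    return(list(faces = faces, normals = matrix(numeric(0), ncol = 3),
                tet = integer(0)))
  }
  normals <- face_outward_normals(mesh$vertices, faces,
                                  mesh$vertices[opp, , drop = FALSE])
  list(faces = faces, normals = normals, tet = own_tet)
}

#' Interface between two regions
#'
#' All triangular faces with one incident tet in \code{region_a} and one in
#' \code{region_b}; normals point outward from \code{region_a}. This is how
#' the starting surface of a nerve branch (nerve volume in contact with the
#' sensory epithelium or endolymphatic space) is extracted.
#'
#' @param mesh a \code{tet_mesh}.
#' @param region_a,region_b region labels (must both be present).
#' @param role role tag for the returned patch.
#' @return a \code{surface_patch} owned by \code{region_a} (possibly empty).
#' @export
region_interface <- function(mesh, region_a, region_b, role = "generic") {
  check_region(mesh, c(region_a, region_b))
  rf <- region_faces(mesh, region_a,
                     function(r) !is.na(r) & r == region_b)
  surface_patch(rf$faces, region_a, rf$normals, role, rf$tet)
}

#' Boundary faces of a region
#'
#' Faces of \code{region} incident to no tet (exterior) or to a tet outside
#' the region, optionally restricted to a set of neighbor regions.
#'
#' @param mesh a \code{tet_mesh}.
#' @param region region label.
#' @param against \code{"all"} (default: any neighbor region or the exterior),
#'   \code{"exterior"} (faces with no neighboring tet), or a character vector
#'   of neighbor region labels.
#' @param role role tag for the returned patch.
#' @return a \code{surface_patch}.
#' @export
region_boundary <- function(mesh, region, against = "all", role = "generic") {
  check_region(mesh, region)
  pred <-
    if (identical(against, "all")) {
      function(r) is.na(r) | r != region
    } else if (identical(against, "exterior")) {
      function(r) is.na(r)
    } else {
      function(r) !is.na(r) & r %in% against
    }
  rf <- region_faces(mesh, region, pred)
  surface_patch(rf$faces, region, rf$normals, role, rf$tet)
}

# ---- surface geodesics -------------------------------------------------------

surface_edge_graph <- function(mesh, patch) {
  f <- patch$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(t(apply(e, 1, sort.int)))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  verts <- patch_vertices(patch)
  id <- integer(nrow(mesh$vertices))
  id[verts] <- seq_along(verts)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::add_edges(g, rbind(id[e[, 1]], id[e[, 2]]))
  igraph::E(g)$weight <- w
  list(graph = g, verts = verts, id = id)
}

#' Geodesic distances on a surface patch
#'
#' Dijkstra shortest-path distances over the surface edge graph (edge weight =
#' Euclidean edge length) from a set of source vertices.
#'
#' @param mesh a \code{tet_mesh}.
#' @param patch a \code{surface_patch}.
#' @param sources integer vector of vertex indices (parent mesh ids) on the patch.
#' @return numeric vector of distances, one per \code{patch_vertices(patch)},
#'   named by vertex index.
#' @export
surface_geodesic_distances <- function(mesh, patch, sources) {
  sg <- surface_edge_graph(mesh, patch)
  if (!all(sources %in% sg$verts)) stop("source vertex not on surface")
  d <- igraph::distances(sg$graph, v = sg$id[sources], algorithm = "dijkstra")
  d <- apply(d, 2, min)
  names(d) <- sg$verts
  d
}

#' Geodesic patch around a seed vertex
#'
#' Selects the triangles of a surface all of whose vertices lie within a given
#' geodesic (Dijkstra, edge-graph) distance of a seed vertex. Triangles
#' incident to the seed are always included, so the patch is nonempty even at
#' radius 0.
#'
#' @param mesh a \code{tet_mesh}.
#' @param surface a \code{surface_patch}.
#' @param seed_vertex vertex index (parent mesh id) on the surface.
#' @param radius geodesic radius in meters (>= 0).
#' @param role role tag for the returned patch.
#' @return a \code{surface_patch} (subset of \code{surface}).
#' @export
surface_geodesic_patch <- function(mesh, surface, seed_vertex, radius,
                                   role = "generic") {
  if (radius < 0) stop("radius must be >= 0")
  verts <- patch_vertices(surface)
  if (!(seed_vertex %in% verts)) stop("seed vertex not on surface")
  d <- surface_geodesic_distances(mesh, surface, seed_vertex)
  dist_of <- numeric(nrow(mesh$vertices))
  dist_of[as.integer(names(d))] <- d
  f <- surface$faces
  within <- dist_of[f[, 1]] <= radius & dist_of[f[, 2]] <= radius &
    dist_of[f[, 3]] <= radius
  incident <- f[, 1] == seed_vertex | f[, 2] == seed_vertex | f[, 3] == seed_vertex
  keep <- within | incident
  surface_patch(f[keep, , drop = FALSE], surface$region,
                surface$normals[keep, , drop = FALSE], role,
                surface$tet[keep])
}

#' Is a surface patch edge-connected?
#' @param mesh a \code{tet_mesh}.
#' @param patch a \code{surface_patch}.
#' @return logical.
#' @export
patch_is_connected <- function(mesh, patch) {
  if (!nrow(patch$faces)) return(FALSE)
  f <- patch$faces
  # triangles adjacent when sharing an edge
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- data.frame(tri = rep(seq_len(nrow(f)), 3),
                      key = c(ek(f[, 1], f[, 2]), ek(f[, 2], f[, 3]), ek(f[, 1], f[, 3])))
  sp <- split(edges$tri, edges$key)
  sp <- sp[lengths(sp) == 2]
  if (!length(sp) && nrow(f) > 1) return(FALSE)
  el <- do.call(rbind, sp)
  g <- igraph::make_empty_graph(n = nrow(f), directed = FALSE)
  if (length(sp)) g <- igraph::add_edges(g, t(el))
  igraph::components(g)$no == 1
}

#' Patch centroid (area-weighted)
#' @param mesh a \code{tet_mesh}.
#' @param patch a \code{surface_patch}.
#' @return numeric length-3 position (m).
#' @export
patch_centroid <- function(mesh, patch) {
  a <- patch_areas(mesh, patch)
  cen <- (mesh$vertices[patch$faces[, 1], , drop = FALSE] +
          mesh$vertices[patch$faces[, 2], , drop = FALSE] +
          mesh$vertices[patch$faces[, 3], , drop = FALSE]) / 3
  colSums(cen * a) / sum(a)
}
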