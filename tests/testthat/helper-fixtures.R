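# Shared fixtures (built once per run) and independent test oracles.

.fx <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

fx_cylinder <- function() {
  fixture("cyl", function() make_test_cylinder(length = 0.02, radius = 2e-3,
                                               resolution = 4))
}

fx_cyl_caps <- function() {
  fixture("cyl_caps", function() {
    cyl <- fx_cylinder()
    list(start = region_interface(cyl, "nerve", "start_marker", role = "start"),
         target = region_interface(cyl, "nerve", "target_marker", role = "target"))
  })
}

fx_cyl_field <- function() {
  fixture("cyl_field", function() {
    cyl <- fx_cylinder()
    caps <- fx_cyl_caps()
    phi <- solve_orientation_potential(cyl, "nerve", caps$start, caps$target)
    orientation_from_potential(cyl, "nerve", phi)
  })
}

fx_arc <- function() {
  fixture("arc", function() make_test_tube_arc(arc_radius = 8e-3,
                                               tube_radius = 2e-3,
                                               angle = pi, resolution = 3))
}

# homogeneous grounded sphere (R = 1 m, sigma = 1 S/m) with a central source
# sphere of radius ~0.2 m; unit current, monopolar ground on the outer surface
fx_sphere <- function() {
  fixture("sphere", function() {
    nvox <- 27L
    h <- 2 / nvox
    cs <- -1 + (seq_len(nvox) - 0.5) * h
    g <- expand.grid(x = cs, y = cs, z = cs)
    r <- sqrt(g$x^2 + g$y^2 + g$z^2)
    lab <- rep(NA_character_, nrow(g))
    lab[r <= 1] <- "medium"
    lab[r <= 0.2] <- "electrode_src"
    mesh <- voxel_to_tetmesh(array(lab, c(nvox, nvox, nvox)), h,
                             origin = c(-1, -1, -1))
    tens <- per_tet_conductivity(mesh, list(medium = 1, electrode_src = 1))
    up <- solve_unit_current(mesh, tens,
                             source_spec("electrode_src", "saline_surface"))
    list(mesh = mesh, up = up, h = h)
  })
}

fx_phantom <- function() fixture("phantom", function() make_phantom())

# a uniform +z orientation field over the cylinder's nerve region,
# constructed directly (bypasses the solver) for streamline unit tests
fx_uniform_field <- function(direction = c(0, 0, 1)) {
  cyl <- fx_cylinder()
  idx <- which(cyl$region == "nerve")
  v <- matrix(rep(direction / sqrt(sum(direction^2)), each = length(idx)),
              ncol = 3)
  structure(list(vectors = v, tet_ids = idx, region = "nerve", mesh = cyl,
                 cache = new.env(parent = emptyenv())),
            class = "orientation_field")
}

# ---- independent oracles -----------------------------------------------------

# O(V^2) Dijkstra over an explicit weighted edge list; deliberately written
# from scratch (no igraph) so it can serve as an oracle for the package's
# surface geodesics.
oracle_dijkstra <- function(n_vertices, edges, weights, sources) {
  dist <- rep(Inf, n_vertices)
  dist[sources] <- 0
  visited <- rep(FALSE, n_vertices)
  adj <- vector("list", n_vertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[k]))
  }
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (dist[u] + nb[r, 2] < dist[v]) dist[v] <- dist[u] + nb[r, 2]
      }
    }
  }
  dist
}

# surface edge list (local vertex numbering) of a patch; returns list with
# verts (parent ids), edges, weights
patch_edge_list <- function(mesh, patch) {
  f <- patch$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(t(apply(e, 1, sort)))
  verts <- sort(unique(as.vector(f)))
  id <- integer(nrow(mesh$vertices))
  id[verts] <- seq_along(verts)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(verts = verts, edges = cbind(id[e[, 1]], id[e[, 2]]), weights = w)
}

# geodesic distances of all patch vertices from a source vertex set, by the
# from-scratch Dijkstra
oracle_surface_distances <- function(mesh, patch, sources) {
  el <- patch_edge_list(mesh, patch)
  id <- match(sources, el$verts)
  stopifnot(!anyNA(id))
  d <- oracle_dijkstra(length(el$verts), el$edges, el$weights, id)
  names(d) <- el$verts
  d
}

# geodesic distances from a source vertex set measured through the region
# volume (all tet edges) -- the distance notion the surrogate solve
# approximates; from-scratch Dijkstra again
oracle_volume_distances <- function(mesh, region, sources) {
  sub <- vestim:::submesh(mesh, which(mesh$region == region))
  tt <- sub$tets
  e <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
             tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  e <- unique(t(apply(e, 1, sort)))
  w <- sqrt(rowSums((sub$vertices[e[, 1], , drop = FALSE] -
                     sub$vertices[e[, 2], , drop = FALSE])^2))
  src <- match(sources, sub$vertex_map)
  d <- oracle_dijkstra(nrow(sub$vertices), e, w, src[!is.na(src)])
  names(d) <- sub$vertex_map
  d
}

# brute-force point-in-tet interpolation over all tets (oracle for the
# bucketed locator)
oracle_interpolate <- function(mesh, values, p) {
  for (t in seq_len(nrow(mesh$tets))) {
    vid <- mesh$tets[t, ]
    A <- rbind(t(mesh$vertices[vid, ]), rep(1, 4))
    b <- c(p, 1)
    lam <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(lam) && all(lam >= -1e-9)) return(sum(values[vid] * lam))
  }
  NA_real_
}

# exhaustive multiplicative amplitude scan for the threshold search oracle
oracle_grid_threshold <- function(u, waveform, params, lo, hi, step_factor) {
  a <- lo
  while (a <= hi) {
    if (simulate_fiber(u, waveform, a, params)) return(a)
    a <- a * step_factor
  }
  Inf
}
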