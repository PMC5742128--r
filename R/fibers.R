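# Streamline-based nerve-fiber synthesis: seeding on the start surface,
# RK4 tracing through the per-tet orientation field, acceptance by target
# crossing, fiber-type assignment and node-of-Ranvier placement.

#' Random seed points on a surface patch
#'
#' Uniform sampling by area-weighted triangle selection followed by uniform
#' barycentric sampling within the selected triangle. Deterministic given the
#' seed.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param start a nonempty \code{surface_patch}.
#' @param n number of points (>= 1).
#' @param rng_seed integer seed.
#' @return n x 3 matrix of positions with attribute \code{"triangle"} (the
#'   patch triangle index of each point).
#' @export
seed_start_points <- function(mesh, start, n, rng_seed = 1L) {
  if (!patch_size(start)) stop("empty start patch")
  if (n < 1) stop("n must be >= 1")
  areas <- patch_areas(mesh, start)
  with_seed(rng_seed, {
    tri <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    a <- mesh$vertices[start$faces[tri, 1], , drop = FALSE]
    b <- mesh$vertices[start$faces[tri, 2], , drop = FALSE]
    c_ <- mesh$vertices[start$faces[tri, 3], , drop = FALSE]
    pts <- a + (b - a) * u + (c_ - a) * v
    attr(pts, "triangle") <- tri
    pts
  })
}

# tracing context for an orientation field (memoized on the field)
tracer_ctx <- function(field) {
  if (!is.null(field$cache$ctx)) return(field$cache$ctx)
  mesh <- field$mesh
  sub <- submesh(mesh, field$tet_ids)
  m <- nrow(sub$tets)
  fc <- face_census(sub)
  # neighbor[tet, local_face]; 0 on region boundary
  neighbor <- matrix(0L, m, 4)
  o <- fc$order; cnt <- fc$count; ends <- cumsum(cnt)
  two <- which(cnt == 2)
  row_tet <- function(r) ((r - 1L) %% m) + 1L
  row_lf <- function(r) ((r - 1L) %/% m) + 1L
  if (length(two)) {
    r1 <- o[ends[two] - 1L]; r2 <- o[ends[two]]
    neighbor[cbind(row_tet(r1), row_lf(r1))] <- row_tet(r2)
    neighbor[cbind(row_tet(r2), row_lf(r2))] <- row_tet(r1)
  }
  loc <- build_locator(sub$vertices, sub$tets)
  # mean edge length of region tets (step-size heuristic)
  ed <- 0
  for (pr in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    ed <- ed + mean(sqrt(rowSums((sub$vertices[sub$tets[, pr[1]], , drop = FALSE] -
                                  sub$vertices[sub$tets[, pr[2]], , drop = FALSE])^2)))
  }
  ctx <- list(sub = sub, loc = loc, neighbor = neighbor,
              F = field$vectors, mean_edge = ed / 6)
  field$cache$ctx <- ctx
  ctx
}

# global sorted-face key for local face lf of sub tet t
sub_face_key <- function(ctx, t, lf) {
  vloc <- ctx$sub$tets[t, .tet_face_local[lf, ]]
  v <- sort.int(ctx$sub$vertex_map[vloc])
  paste(v[1], v[2], v[3])
}

# walk from tet t to the tet containing x; returns tet id or NA (left region)
walk_to <- function(ctx, t, x, tol = 1e-10) {
  for (it in 1:400) {
    b <- bary_in(ctx$loc, t, x)
    k <- which.min(b)
    if (b[k] >= -tol) return(t)
    nb <- ctx$neighbor[t, k]
    if (nb == 0L) {
      hit <- locate_point(ctx$loc, x, tol = 1e-9)   # fallback: global search
      return(if (is.null(hit)) NA_integer_ else hit$tet)
    }
    t <- nb
  }
  hit <- locate_point(ctx$loc, x, tol = 1e-9)
  if (is.null(hit)) NA_integer_ else hit$tet
}

#' Trace a streamline through an orientation field
#'
#' Fixed-step fourth-order Runge-Kutta integration of \eqn{dx/ds = F(x)}
#' with \eqn{F} piecewise constant per tetrahedron (point location by tet
#' walking). The trace terminates when the trajectory leaves the nerve
#' region (the exit face is recorded and the polyline clipped to it) or when
#' \code{max_steps} is reached (flagged non-terminating).
#'
#' @param field an \code{orientation_field}.
#' @param seed numeric length-3 start position inside or on the boundary of
#'   the region.
#' @param step integration step (m); default 1/4 of the mean tet edge length.
#' @param max_steps step budget (default 10000).
#' @return list with \code{points} (polyline matrix), \code{exit_face}
#'   (global sorted vertex-triple key, or \code{NA} if non-terminating) and
#'   \code{terminated} (logical).
#' @export
trace_streamline <- function(field, seed, step = NULL, max_steps = 10000L) {
  ctx <- tracer_ctx(field)
  if (is.null(step)) step <- ctx$mean_edge / 4
  if (step <= 0) stop("step must be > 0")
  x <- as.numeric(seed)
  hit <- locate_point(ctx$loc, x, tol = 1e-7)
  if (is.null(hit)) stop("seed point is not inside the region")
  t <- hit$tet
  # nudge off the boundary along the local field direction
  x <- x + ctx$F[t, ] * (1e-6 * step)
  t2 <- walk_to(ctx, t, x)
  if (!is.na(t2)) t <- t2 else x <- as.numeric(seed)

  pts <- matrix(0, max_steps + 1L, 3)
  pts[1, ] <- x
  np <- 1L
  f_at <- function(xq, hint) {
    tq <- walk_to(ctx, hint, xq)
    if (is.na(tq)) NULL else ctx$F[tq, ]
  }
  for (s in seq_len(max_steps)) {
    k1 <- ctx$F[t, ]
    k2 <- f_at(x + 0.5 * step * k1, t); if (is.null(k2)) k2 <- k1
    k3 <- f_at(x + 0.5 * step * k2, t); if (is.null(k3)) k3 <- k2
    k4 <- f_at(x + step * k3, t);       if (is.null(k4)) k4 <- k3
    x1 <- x + (step / 6) * (k1 + 2 * k2 + 2 * k3 + k4)

    # advance through tets along segment x -> x1; stop at a boundary face
    crossed <- 0L
    repeat {
      crossed <- crossed + 1L
      if (crossed > 500L)
        return(list(points = pts[seq_len(np), , drop = FALSE],
                    exit_face = NA_character_, terminated = FALSE, steps = s))
      b0 <- bary_in(ctx$loc, t, x)
      b1 <- bary_in(ctx$loc, t, x1)
      if (min(b1) >= -1e-12) { x <- x1; break }
      neg <- which(b1 < -1e-12 & b1 < b0)
      if (!length(neg)) { x <- x1; break }
      svals <- (b0[neg]) / (b0[neg] - b1[neg])
      kix <- which.min(svals)
      scross <- max(0, min(1, svals[kix]))
      lf <- neg[kix]
      xc <- x + scross * (x1 - x)
      nb <- ctx$neighbor[t, lf]
      if (nb == 0L) {
        np <- np + 1L
        pts[np, ] <- xc
        return(list(points = pts[seq_len(np), , drop = FALSE],
                    exit_face = sub_face_key(ctx, t, lf),
                    terminated = TRUE, steps = s))
      }
      t <- nb
      x <- xc + (x1 - xc) * 1e-9   # nudge into the next tet
    }
    np <- np + 1L
    pts[np, ] <- x
  }
  list(points = pts[seq_len(np), , drop = FALSE], exit_face = NA_character_,
       terminated = FALSE, steps = max_steps)
}

patch_face_keys <- function(patch) {
  f <- patch$faces
  if (!nrow(f)) return(character(0))
  fs <- t(apply(f, 1, sort.int))
  paste(fs[, 1], fs[, 2], fs[, 3])
}

#' Generate an accepted fiber set for a nerve branch
#'
#' Repeatedly samples a random start point on the start surface and traces a
#' streamline through the orientation field; a trace is accepted only if it
#' terminates by crossing the target surface, otherwise a different start
#' point is drawn. Stops when \code{n} fibers are accepted or the attempt
#' budget is exhausted. Deterministic given the seed.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param region nerve branch region label.
#' @param field the branch \code{orientation_field}.
#' @param start,target start/target \code{surface_patch}es.
#' @param n requested fiber count (paper-style default for a full branch is
#'   400; smaller counts are typical for quick studies).
#' @param rng_seed integer seed.
#' @param max_attempts attempt budget (default \code{20 * n}).
#' @param step RK4 step (m); default 1/4 mean tet edge.
#' @return a \code{fiber_set}: list of fibers (each with \code{points},
#'   \code{seed}, \code{branch}, \code{type}, \code{nodes}), plus generation
#'   statistics.
#' @export
generate_fibers <- function(mesh, region, field, start, target, n,
                            rng_seed = 1L, max_attempts = 20L * n,
                            step = NULL) {
  if (n < 1) stop("n must be >= 1")
  tkeys <- patch_face_keys(target)
  fibers <- vector("list", n)
  accepted <- 0L
  attempts <- 0L
  seeds <- seed_start_points(mesh, start, max_attempts, rng_seed)
  tris <- attr(seeds, "triangle")
  while (accepted < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    sp <- seeds[attempts, ]
    tr <- tryCatch(trace_streamline(field, sp, step = step),
                   error = function(e) NULL)
    if (is.null(tr) || !tr$terminated) next
    if (!(tr$exit_face %in% tkeys)) next
    accepted <- accepted + 1L
    fibers[[accepted]] <- list(points = rbind(sp, tr$points),
                               seed = sp, seed_triangle = tris[attempts],
                               branch = region, type = NA_character_,
                               nodes = NULL)
  }
  if (accepted < n)
    stop(sprintf(paste0("fiber generation exhausted %d attempts with %d/%d ",
                        "accepted (acceptance rate %.2f)"),
                 attempts, accepted, n, accepted / attempts))
  structure(list(fibers = fibers, branch = region, seed = rng_seed,
                 stats = list(attempts = attempts,
                              rejections = attempts - accepted)),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers on branch '%s' (%d attempts)\n",
              length(x$fibers), x$branch, x$stats$attempts))
  invisible(x)
}

#' Default zone-conditional fiber-type distributions
#'
#' Irregular afferents innervate mainly the central zone of the sensory
#' epithelium, regular afferents mainly the periphery, and dimorphic
#' afferents all zones. The exact proportions are configuration, not
#' measurement; these defaults split each zone evenly between its dominant
#' type and dimorphic.
#'
#' @return list with \code{central} and \code{peripheral} named probability
#'   vectors over \code{c("regular", "irregular", "dimorphic")}.
#' @export
fiber_type_defaults <- function() {
  list(central = c(regular = 0, irregular = 0.5, dimorphic = 0.5),
       peripheral = c(regular = 0.5, irregular = 0, dimorphic = 0.5))
}

#' Assign fiber types by epithelial zone
#'
#' Classifies each fiber's start point as central or peripheral on the start
#' surface: a seed is central when the geodesic distance from its nearest
#' patch vertex to the patch's centroid-nearest vertex lies below the
#' \code{central_fraction} quantile of all patch vertex distances. The fiber
#' type is then drawn from the zone's configured distribution.
#'
#' @param fiber_set a \code{fiber_set}.
#' @param mesh a \code{\link{tet_mesh}}.
#' @param start the start \code{surface_patch} the fibers were seeded on.
#' @param central_fraction quantile in (0,1) splitting central from
#'   peripheral (default 0.5).
#' @param type_probabilities list as \code{\link{fiber_type_defaults}}.
#' @param rng_seed integer seed.
#' @return the \code{fiber_set} with per-fiber \code{type} and \code{zone}.
#' @export
assign_fiber_types <- function(fiber_set, mesh, start, central_fraction = 0.5,
                               type_probabilities = fiber_type_defaults(),
                               rng_seed = 1L) {
  if (central_fraction <= 0 || central_fraction >= 1)
    stop("central_fraction must be in (0,1)")
  for (zone in c("central", "peripheral")) {
    p <- type_probabilities[[zone]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9)
      stop("type probabilities for zone '", zone, "' must sum to 1")
  }
  cen <- patch_centroid(mesh, start)
  verts <- patch_vertices(start)
  vxyz <- mesh$vertices[verts, , drop = FALSE]
  cen_vertex <- verts[which.min(rowSums(sweep(vxyz, 2, cen)^2))]
  d <- surface_geodesic_distances(mesh, start, cen_vertex)
  thr <- stats::quantile(d, central_fraction, names = FALSE)
  dist_of <- d[match(verts, as.integer(names(d)))]
  with_seed(rng_seed, {
    for (i in seq_along(fiber_set$fibers)) {
      fb <- fiber_set$fibers[[i]]
      nearest <- which.min(rowSums(sweep(vxyz, 2, fb$seed)^2))
      zone <- if (dist_of[nearest] < thr) "central" else "peripheral"
      p <- type_probabilities[[zone]]
      fb$zone <- zone
      fb$type <- sample(names(p), 1, prob = p)
      fiber_set$fibers[[i]] <- fb
    }
  })
  fiber_set
}

#' Type-dependent internodal distances (placeholders)
#'
#' Node-of-Ranvier spacing per fiber type. These defaults are configuration
#' placeholders in a plausible myelinated-afferent range, not measured
#' human values; override per study.
#'
#' @return named numeric vector (m).
#' @export
internodal_defaults <- function() {
  c(regular = 350e-6, irregular = 250e-6, dimorphic = 300e-6)
}

#' Place nodes of Ranvier along a fiber
#'
#' Nodes at arc lengths \code{offset, offset + d, offset + 2d, ...} up to the
#' fiber length. A myelinated cable model needs at least two nodes.
#'
#' @param fiber a fiber (list with \code{points}).
#' @param internodal_distance node spacing d (m), > 0.
#' @param first_node_offset arc length of the first node (m), >= 0.
#' @return numeric vector of node arc lengths (m).
#' @export
place_nodes_of_ranvier <- function(fiber, internodal_distance,
                                   first_node_offset = 0) {
  if (internodal_distance <= 0) stop("internodal_distance must be > 0")
  if (first_node_offset < 0) stop("first_node_offset must be >= 0")
  L <- polyline_length(fiber$points)
  if (L < first_node_offset + internodal_distance)
    stop("fiber too short for myelinated model (length ", signif(L, 4),
         " m < offset + internodal distance)")
  seq(first_node_offset, L, by = internodal_distance)
}

#' Node positions of a fiber in 3-D
#' @param fiber a fiber with \code{points}.
#' @param nodes arc lengths from \code{\link{place_nodes_of_ranvier}}.
#' @return k x 3 matrix of node positions (m).
#' @export
fiber_node_points <- function(fiber, nodes) {
  polyline_point_at(fiber$points, nodes)
}

#' Tabular view of a fiber set
#' @param fiber_set a \code{fiber_set}.
#' @return a tibble with fiber id, branch, type, length and node count.
#' @export
fiber_table <- function(fiber_set) {
  tibble::tibble(
    fiber = seq_along(fiber_set$fibers),
    branch = fiber_set$branch,
    type = vapply(fiber_set$fibers, function(f) f$type, character(1)),
    length = vapply(fiber_set$fibers, function(f) polyline_length(f$points),
                    numeric(1)),
    n_nodes = vapply(fiber_set$fibers,
                     function(f) length(f$nodes %||% numeric(0)), integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fiber set as VTK PolyData lines
#'
#' Exports the fiber polylines as legacy VTK PolyData (one line per fiber)
#' for visual inspection; the tabular sidecar is
#' \code{\link{fiber_table}} written to CSV by the pipeline.
#'
#' @param fiber_set a \code{fiber_set}.
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
write_fibers_vtk <- function(fiber_set, path) {
  pts <- do.call(rbind, lapply(fiber_set$fibers, function(f) f$points))
  counts <- vapply(fiber_set$fibers, function(f) nrow(f$points), integer(1))
  offsets <- cumsum(c(0, counts[-length(counts)]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "nerve fibers", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(format(pts, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("LINES %d %d", length(counts),
                     length(counts) + sum(counts)), con)
  for (i in seq_along(counts)) {
    writeLines(paste(c(counts[i], offsets[i] + seq_len(counts[i]) - 1L),
                     collapse = " "), con)
  }
  invisible(path)
}
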