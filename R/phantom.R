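#' Specification of the synthetic inner-ear phantom
#'
#' Parameters of a deterministic, seeded phantom anatomy that reproduces the
#' topology the stimulation workflow assumes: a fluid endolymph labyrinth with
#' two ampulla-like cavities, a sensory-epithelium disc at the base of each
#' ampulla, one nerve branch per ampulla running from its epithelium to a
#' merged canal (IAC) region, all embedded in a bone sphere (default diameter
#' 5 cm) surrounded by a saline shell (default 1 cm thick). All lengths in
#' meters.
#'
#' The phantom is intentionally coarse: nerve tubes are millimetre-scale so
#' that a uniform voxelization resolves them with a practical tet budget. It
#' emulates topology and embedding, not anatomical scale of real nerve
#' branches.
#'
#' @param bone_diameter bone sphere diameter (m), default 0.05.
#' @param saline_thickness saline shell thickness (m), default 0.01.
#' @param voxel voxel edge length (m), default 2.5e-3.
#' @param branch_x lateral offset of each ampulla/nerve axis (m).
#' @param ampulla_radius radius of the ampullary endolymph cavities (m).
#' @param labyrinth_radius radius of the horizontal labyrinth tube (m).
#' @param nerve_radius nerve tube radius (m).
#' @param epithelium_radius,epithelium_thickness sensory-epithelium disc size (m).
#' @param iac_radius radius of the merged canal (IAC) tube (m).
#' @param seed RNG seed recorded with the phantom (generation is
#'   deterministic; the seed namespaces downstream random stages).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(bone_diameter = 0.05,
                         saline_thickness = 0.01,
                         voxel = 2.5e-3,
                         branch_x = 9e-3,
                         ampulla_radius = 5.5e-3,
                         labyrinth_radius = 4e-3,
                         nerve_radius = 4e-3,
                         epithelium_radius = 2.5e-3,
                         epithelium_thickness = 2.5e-3,
                         iac_radius = 5e-3,
                         seed = 1L) {
  spec <- list(bone_diameter = bone_diameter,
               saline_thickness = saline_thickness,
               voxel = voxel, branch_x = branch_x,
               ampulla_radius = ampulla_radius,
               labyrinth_radius = labyrinth_radius,
               nerve_radius = nerve_radius,
               epithelium_radius = epithelium_radius,
               epithelium_thickness = epithelium_thickness,
               iac_radius = iac_radius, seed = as.integer(seed))
  if (saline_thickness <= 0) stop("saline shell must have positive thickness")
  if (nerve_radius < 1.5 * voxel)
    stop("nerve tube radius below 1.5 voxels: tube may disconnect")
  structure(spec, class = "phantom_spec")
}

# ---- voxel painting helpers --------------------------------------------------

# A paint canvas: voxel-center coordinates plus a label vector painted in order.
voxel_canvas <- function(half_extent, voxel) {
  # round, not ceiling: voxel centers must sit on the half-integer grid so
  # region boundaries at voxel multiples never coincide with centers
  n <- max(2L, as.integer(round(2 * half_extent / voxel)))
  origin <- -n * voxel / 2
  cs <- origin + (seq_len(n) - 0.5) * voxel
  g <- expand.grid(x = cs, y = cs, z = cs, KEEP.OUT.ATTRS = FALSE)
  list(n = n, origin = rep(origin, 3), voxel = voxel,
       x = g$x, y = g$y, z = g$z,
       label = rep(NA_character_, n^3))
}

paint <- function(cv, lab, mask) { cv$label[mask] <- lab; cv }

mask_sphere <- function(cv, center, r) {
  (cv$x - center[1])^2 + (cv$y - center[2])^2 + (cv$z - center[3])^2 <= r^2
}

mask_cylinder_z <- function(cv, cx, cy, r, z0, z1) {
  (cv$x - cx)^2 + (cv$y - cy)^2 <= r^2 & cv$z >= z0 & cv$z <= z1
}

# capsule: all points within r of segment p0-p1
mask_capsule <- function(cv, p0, p1, r) {
  d <- p1 - p0
  L2 <- sum(d^2)
  t <- ((cv$x - p0[1]) * d[1] + (cv$y - p0[2]) * d[2] + (cv$z - p0[3]) * d[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  (cv$x - (p0[1] + t * d[1]))^2 + (cv$y - (p0[2] + t * d[2]))^2 +
    (cv$z - (p0[3] + t * d[3]))^2 <= r^2
}

canvas_to_mesh <- function(cv) {
  labels <- array(cv$label, dim = c(cv$n, cv$n, cv$n))
  voxel_to_tetmesh(labels, cv$voxel, origin = cv$origin)
}

# ---- phantom -----------------------------------------------------------------

#' Generate the synthetic labeled phantom anatomy
#'
#' Rasterizes the phantom described by a \code{\link{phantom_spec}} onto a
#' uniform voxel grid and converts it with \code{\link{voxel_to_tetmesh}}, so
#' the synthetic anatomy takes exactly the path real labeled volumes would.
#' The result contains regions \code{bone}, \code{saline}, \code{endolymph},
#' \code{nerve_target}, \code{nerve_neighbor}, \code{epithelium_target},
#' \code{epithelium_neighbor} and \code{IAC}. Both nerve branches are
#' single-connected, contact their epithelium disc and the endolymph, and
#' join the IAC.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a validated \code{\link{tet_mesh}} with attribute \code{"spec"}.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  rb <- spec$bone_diameter / 2
  rs <- rb + spec$saline_thickness
  bx <- spec$branch_x
  cv <- voxel_canvas(rs, spec$voxel)

  # embedding: saline shell with bone sphere inside
  cv <- paint(cv, "saline", mask_sphere(cv, c(0, 0, 0), rs))
  cv <- paint(cv, "bone", mask_sphere(cv, c(0, 0, 0), rb))

  # endolymph: two ampullary cavities joined by a horizontal labyrinth tube
  cv <- paint(cv, "endolymph",
              mask_capsule(cv, c(-bx, 0, 10e-3), c(bx, 0, 10e-3),
                           spec$labyrinth_radius) |
              mask_cylinder_z(cv, bx, 0, spec$ampulla_radius, 0, 10e-3) |
              mask_cylinder_z(cv, -bx, 0, spec$ampulla_radius, 0, 10e-3))

  # per-branch epithelium disc then nerve tube (nerve carves the cavity floor,
  # leaving an endolymph annulus in side contact with the nerve)
  zt <- spec$epithelium_thickness
  for (b in c(target = 1, neighbor = -1)) {
    nm <- if (b > 0) "target" else "neighbor"
    x0 <- b * bx
    cv <- paint(cv, paste0("epithelium_", nm),
                mask_cylinder_z(cv, x0, 0, spec$epithelium_radius, zt, 2 * zt))
    cv <- paint(cv, paste0("nerve_", nm),
                mask_cylinder_z(cv, x0, 0, spec$nerve_radius, -6e-3, zt) |
                mask_capsule(cv, c(x0, 0, -5e-3), c(b * 4e-3, 0, -14e-3),
                             spec$nerve_radius))
  }

  # merged canal region joining both nerves (painted last: truncates the
  # nerve ends so each nerve terminates on the IAC interface)
  cv <- paint(cv, "IAC",
              mask_capsule(cv, c(-6e-3, 0, -16e-3), c(6e-3, 0, -16e-3),
                           spec$iac_radius))

  # geometry collision check: labyrinth structures must stay inside the bone
  inner <- !is.na(cv$label) & !(cv$label %in% c("bone", "saline"))
  if (any(cv$x[inner]^2 + cv$y[inner]^2 + cv$z[inner]^2 > rb^2))
    stop("geometry collision: labyrinth structure exits the bone sphere")

  mesh <- canvas_to_mesh(cv)
  for (nerve in c("nerve_target", "nerve_neighbor")) {
    if (max(region_components(mesh, nerve)) > 1)
      stop("phantom nerve region '", nerve, "' is not single-connected")
  }
  attr(mesh, "spec") <- spec
  mesh
}

#' Straight-cylinder test fixture
#'
#' A voxelized straight tube labeled \code{nerve} with one-voxel-thick end
#' caps labeled \code{start_marker} and \code{target_marker}. The standard
#' fixture for validating the fiber-orientation solves and streamline tracing
#' on a geometry with a known axis.
#'
#' @param length tube length (m), caps included.
#' @param radius tube radius (m).
#' @param resolution number of voxels across the tube radius (>= 2).
#' @param axis tube axis direction (need not be unit length). The default
#'   +z aligns with the voxel grid; a tilted axis gives a staircase lateral
#'   boundary, the honest setting for discretization-convergence studies
#'   (grid-aligned tubes admit exactly linear solves).
#' @return a validated \code{\link{tet_mesh}}; attribute \code{"axis"} holds
#'   the unit tube axis and \code{"voxel"} the voxel size.
#' @export
make_test_cylinder <- function(length = 0.02, radius = 2e-3, resolution = 4,
                               axis = c(0, 0, 1)) {
  if (resolution < 2)
    stop("resolution too coarse for the tube radius (need >= 2 voxels)")
  h <- radius / resolution
  a <- axis / vnorm(axis)
  # grid bounding the tilted tube (plus one voxel margin)
  ext_lo <- pmin(0, a * length) - radius - h
  ext_hi <- pmax(0, a * length) + radius + h
  n <- as.integer(ceiling((ext_hi - ext_lo) / h))
  cs <- lapply(1:3, function(k) ext_lo[k] + (seq_len(n[k]) - 0.5) * h)
  g <- expand.grid(x = cs[[1]], y = cs[[2]], z = cs[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  zp <- g$x * a[1] + g$y * a[2] + g$z * a[3]          # axial coordinate
  rad2 <- (g$x - zp * a[1])^2 + (g$y - zp * a[2])^2 + (g$z - zp * a[3])^2
  inside <- rad2 <= radius^2 & zp >= 0 & zp <= length
  lab <- rep(NA_character_, nrow(g))
  lab[inside] <- "nerve"
  lab[inside & zp < h] <- "start_marker"
  lab[inside & zp > length - h] <- "target_marker"
  labels <- array(lab, dim = n)
  mesh <- voxel_to_tetmesh(labels, h, origin = ext_lo)
  if (max(region_components(mesh, "nerve")) > 1)
    stop("resolution too coarse for the tube radius (nerve disconnects)")
  attr(mesh, "axis") <- a
  attr(mesh, "voxel") <- h
  mesh
}

#' Curved tube-arc (torus-segment) test fixture
#'
#' A voxelized tube whose centerline is a circular arc in the x-y plane,
#' with marker caps at both arc ends. Used to validate the distance-surrogate
#' and start/target machinery on a curved nerve-like volume.
#'
#' @param arc_radius radius of the centerline arc (m).
#' @param tube_radius tube radius (m).
#' @param angle arc angle in radians (default \code{pi}: half torus).
#' @param resolution voxels across the tube radius (>= 2).
#' @return a validated \code{\link{tet_mesh}}.
#' @export
make_test_tube_arc <- function(arc_radius = 8e-3, tube_radius = 2e-3,
                               angle = pi, resolution = 3) {
  if (resolution < 2)
    stop("resolution too coarse for the tube radius (need >= 2 voxels)")
  h <- tube_radius / resolution
  ext <- arc_radius + tube_radius + h
  nxy <- ceiling(2 * ext / h)
  nz <- ceiling(2 * (tube_radius + h) / h)
  cxy <- -ext + (seq_len(nxy) - 0.5) * h
  cz <- -(tube_radius + h) + (seq_len(nz) - 0.5) * h
  g <- expand.grid(x = cxy, y = cxy, z = cz, KEEP.OUT.ATTRS = FALSE)
  theta <- atan2(g$y, g$x)
  rho <- sqrt(g$x^2 + g$y^2)
  in_tube <- theta >= 0 & theta <= angle &
    (rho - arc_radius)^2 + g$z^2 <= tube_radius^2
  th_cap <- 1.0 * h / arc_radius
  lab <- rep(NA_character_, nrow(g))
  lab[in_tube] <- "nerve"
  lab[in_tube & theta < th_cap] <- "start_marker"
  lab[in_tube & theta > angle - th_cap] <- "target_marker"
  labels <- array(lab, dim = c(nxy, nxy, nz))
  mesh <- voxel_to_tetmesh(labels, h,
                           origin = c(-ext, -ext, -(tube_radius + h)))
  if (max(region_components(mesh, "nerve")) > 1)
    stop("resolution too coarse for the tube radius (nerve disconnects)")
  attr(mesh, "voxel") <- h
  mesh
}
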