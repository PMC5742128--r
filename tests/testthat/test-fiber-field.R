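# Distance-surrogate and Cauchy orientation solves, extremal points,
# automatic start/target surfaces, orientation fields.

test_that("distance surrogate behaves like a distance field on a slender tube", {
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  phi <- solve_distance_surrogate(cyl, "nerve", caps$start)

  # Dirichlet condition exactly on the start surface
  sv <- patch_vertices(caps$start)
  expect_true(all(phi$values[sv] == 0))
  expect_true(all(phi$values[!is.na(phi$values)] <= 1e-12))

  # binned axial means decrease monotonically and follow the 1-D slender-tube
  # oracle (quadratic in z: A phi'(z) = -(P (L - z) + A))
  vals <- phi$values
  z <- cyl$vertices[, 3]
  ok <- !is.na(vals)
  bins <- cut(z[ok], breaks = seq(0, 0.02, by = 2e-3))
  mu <- tapply(vals[ok], bins, mean)
  expect_true(all(diff(mu) < 0))
  zc <- seq(1e-3, 0.019, by = 2e-3)
  fit <- lm(mu ~ zc + I(zc^2))
  expect_gt(summary(fit)$r.squared, 0.99)

  expect_error(solve_distance_surrogate(cyl, "nerve",
                                        surface_patch(matrix(integer(0), ncol = 3),
                                                      "nerve",
                                                      matrix(numeric(0), ncol = 3))),
               "empty")
})

test_that("extremal point lands near the antipode on a ball", {
  # voxel ball with a start patch at its north pole
  nv <- 11L; h <- 1e-3
  cs <- (seq_len(nv) - (nv + 1) / 2) * h
  g <- expand.grid(x = cs, y = cs, z = cs)
  lab <- rep(NA_character_, nrow(g))
  lab[sqrt(g$x^2 + g$y^2 + g$z^2) <= 5 * h] <- "nerve"
  ball <- voxel_to_tetmesh(array(lab, c(nv, nv, nv)), h,
                           origin = rep(-nv * h / 2, 3))
  bnd <- region_boundary(ball, "nerve")
  verts <- patch_vertices(bnd)
  north <- verts[which.max(ball$vertices[verts, 3])]
  start <- surface_geodesic_patch(ball, bnd, north, 2 * h, role = "start")
  phi <- solve_distance_surrogate(ball, "nerve", start)
  far <- find_extremal_point(phi, bnd)
  south <- verts[which.min(ball$vertices[verts, 3])]
  expect_lt(sqrt(sum((ball$vertices[far, ] - ball$vertices[south, ])^2)),
            2 * sqrt(3) * h)
})

test_that("extremal point selection handles linear and constant fields", {
  cyl <- fx_cylinder()
  bnd <- region_boundary(cyl, "nerve")
  verts <- patch_vertices(bnd)
  f <- scalar_field(-cyl$vertices[, 1])   # minimum at max x
  far <- find_extremal_point(f, bnd)
  expect_equal(cyl$vertices[far, 1], max(cyl$vertices[verts, 1]))
  # constant field: tie broken by lowest vertex index
  expect_equal(find_extremal_point(scalar_field(rep(1, nrow(cyl$vertices))), bnd),
               min(verts))
})

test_that("automatic target surface lands on the far cap and respects radii", {
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  r <- 2e-3
  tgt <- find_target_surface(cyl, "nerve", caps$start, patch_radius = r)
  # contained in the far cap plus an adjacent lateral ring
  zmin <- min(cyl$vertices[patch_vertices(tgt), 3])
  expect_gt(zmin, 0.019 - (r + 2 * attr(cyl, "voxel")))

  # tiny radius: triangles incident to the extremal vertex only
  tgt0 <- find_target_surface(cyl, "nerve", caps$start, patch_radius = 1e-9)
  phi <- solve_distance_surrogate(cyl, "nerve", caps$start)
  bnd <- region_boundary(cyl, "nerve")
  far <- find_extremal_point(phi, bnd)
  expect_true(all(apply(tgt0$faces, 1, function(f) far %in% f)))

  # start and target disjoint on the curved tube
  arc <- fx_arc()
  astart <- region_interface(arc, "nerve", "start_marker", role = "start")
  atgt <- find_target_surface(arc, "nerve", astart, patch_radius = 2e-3)
  key <- function(f) apply(f, 1, function(x) paste(sort(x), collapse = "-"))
  expect_length(intersect(key(atgt$faces), key(astart$faces)), 0)

  # radius so large the patch would swallow the start surface -> error
  expect_error(find_target_surface(cyl, "nerve", caps$start, patch_radius = 1),
               "smaller patch_radius")
})

test_that("auto start surface for a tube lands on a cap, deterministically", {
  cyl <- fx_cylinder()
  p1 <- auto_start_surface_tube(cyl, "nerve", patch_radius = 2e-3, rng_seed = 4)
  p2 <- auto_start_surface_tube(cyl, "nerve", patch_radius = 2e-3, rng_seed = 4)
  expect_identical(p1$faces, p2$faces)

  z <- cyl$vertices[patch_vertices(p1), 3]
  on_near <- all(z < 0.004)
  on_far <- all(z > 0.016)
  expect_true(on_near || on_far)

  # the subsequent target surface lands on the opposite cap
  tgt <- find_target_surface(cyl, "nerve", p1, patch_radius = 2e-3)
  zt <- cyl$vertices[patch_vertices(tgt), 3]
  if (on_near) expect_true(all(zt > 0.016)) else expect_true(all(zt < 0.004))
})

test_that("orientation potential rises from start to target with Cauchy BCs", {
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  phi <- solve_orientation_potential(cyl, "nerve", caps$start, caps$target)
  vals <- phi$values
  ok <- !is.na(vals)
  # soft maximum principle
  expect_gt(min(vals[ok]), -1e-6)
  expect_lt(max(vals[ok]), 1 + 1e-6)
  # binned axial means strictly increasing
  bins <- cut(cyl$vertices[ok, 3], breaks = seq(0, 0.02, by = 2e-3))
  expect_true(all(diff(tapply(vals[ok], bins, mean)) > 0))

  # alpha -> infinity approaches the Dirichlet limit
  phiD <- solve_orientation_potential(cyl, "nerve", caps$start, caps$target,
                                      cauchy_params(1e8, 1e8))
  expect_lt(max(abs(phiD$values[patch_vertices(caps$start)])), 1e-3)
  expect_lt(max(abs(1 - phiD$values[patch_vertices(caps$target)])), 1e-3)

  # swapping start and target maps phi -> 1 - phi
  phiS <- solve_orientation_potential(cyl, "nerve", caps$target, caps$start)
  expect_equal(phiS$values[ok], 1 - vals[ok], tolerance = 1e-9)

  expect_error(solve_orientation_potential(cyl, "nerve", caps$start, caps$start),
               "overlap")
})

test_that("orientation field is the normed gradient, aligned with the axis", {
  cyl <- fx_cylinder()
  # linear field phi = x: F = (1,0,0) everywhere
  fld <- orientation_from_potential(cyl, "nerve",
                                    scalar_field(cyl$vertices[, 1]))
  expect_true(all(abs(fld$vectors[, 1] - 1) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(fld$vectors^2)) - 1) < 1e-9))

  # solved cylinder field: unit norm, mean angle to the axis < 5 degrees
  f2 <- fx_cyl_field()
  expect_true(all(abs(sqrt(rowSums(f2$vectors^2)) - 1) < 1e-9))
  ang <- acos(pmin(1, abs(f2$vectors[, 3]))) * 180 / pi
  expect_lt(mean(ang), 5)
})

test_that("larger alpha steepens the fiber entry angle at the start surface", {
  # start/target patches that include a lateral ring make the entry-angle
  # dependence on alpha visible
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  start <- find_target_surface(cyl, "nerve", caps$target, patch_radius = 2e-3)
  start$role <- "start"
  target <- caps$target
  mean_entry_angle <- function(alpha) {
    phi <- solve_orientation_potential(cyl, "nerve", start, target,
                                       cauchy_params(alpha, alpha))
    fld <- orientation_from_potential(cyl, "nerve", phi)
    sub_ids <- match(start$tet, fld$tet_ids)
    inward <- -start$normals
    f <- fld$vectors[sub_ids, , drop = FALSE]
    mean(acos(pmin(1, pmax(-1, rowSums(f * inward)))))
  }
  angles <- vapply(c(1, 10, 100, 1000), mean_entry_angle, numeric(1))
  expect_true(all(diff(angles) < 0))
})
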