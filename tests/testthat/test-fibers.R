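# Streamline fiber synthesis, type assignment and node placement.

test_that("seed points are uniform by area and reproducible", {
  mesh <- tet_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         c(3, 1, 0)),
                   rbind(c(1, 2, 3, 4), c(2, 5, 3, 4)), c("a", "a"))
  bnd <- region_boundary(mesh, "a")
  # pick one triangle: a single-triangle patch keeps its sample inside
  p1 <- surface_patch(bnd$faces[1, , drop = FALSE], "a",
                      bnd$normals[1, , drop = FALSE])
  s <- seed_start_points(mesh, p1, 1, rng_seed = 1)
  A <- rbind(t(mesh$vertices[p1$faces[1, ], ]), rep(1, 3))
  lam <- qr.solve(A, c(s[1, ], 1))
  expect_true(all(lam > -1e-9))

  expect_identical(seed_start_points(mesh, p1, 5, rng_seed = 9),
                   seed_start_points(mesh, p1, 5, rng_seed = 9))
  expect_error(seed_start_points(mesh,
                                 surface_patch(matrix(integer(0), ncol = 3),
                                               "a", matrix(numeric(0), ncol = 3)),
                                 1), "empty")

  # two triangles with 3:1 area ratio: counts within the binomial 99% CI
  areas <- vestim:::tri_areas(mesh$vertices, bnd$faces)
  two <- order(areas)  # find one small and one large triangle
  big <- which.max(areas); small <- which.min(areas)
  ratio <- areas[big] / areas[small]
  p2 <- surface_patch(bnd$faces[c(big, small), , drop = FALSE], "a",
                      bnd$normals[c(big, small), , drop = FALSE])
  n <- 10000
  s2 <- seed_start_points(mesh, p2, n, rng_seed = 3)
  n_big <- sum(attr(s2, "triangle") == 1)
  pr <- areas[big] / (areas[big] + areas[small])
  ci <- qbinom(c(0.005, 0.995), n, pr)
  expect_gte(n_big, ci[1])
  expect_lte(n_big, ci[2])
})

test_that("streamlines follow the field and terminate on region exit", {
  cyl <- fx_cylinder()
  up_field <- fx_uniform_field(c(0, 0, 1))
  caps <- fx_cyl_caps()
  tkeys <- vestim:::patch_face_keys(caps$target)

  h <- attr(cyl, "voxel")
  seed <- c(0.1e-3, 0.1e-3, h + 1e-6)
  tr <- trace_streamline(up_field, seed, step = h / 2)
  expect_true(tr$terminated)
  expect_true(tr$exit_face %in% tkeys)   # straight up through the far cap
  L_expect <- (0.02 - h) - seed[3]
  expect_lt(abs(vestim:::polyline_length(tr$points) - L_expect), h / 2)
  # straight polyline: x/y constant
  expect_lt(max(abs(tr$points[, 1] - seed[1])), 1e-9)

  # radially outward field exits the lateral surface, not the caps
  out_field <- fx_uniform_field(c(1, 0, 0))
  tr2 <- trace_streamline(out_field, c(0, 0.1e-3, 0.01), step = h / 2)
  expect_true(tr2$terminated)
  expect_false(tr2$exit_face %in% tkeys)
  expect_gt(max(tr2$points[, 1]), 1.5e-3)

  # halving the step moves the exit point by less than one step
  fld <- fx_cyl_field()
  s3 <- c(0.3e-3, -0.2e-3, h + 1e-6)
  e1 <- trace_streamline(fld, s3, step = h / 2)
  e2 <- trace_streamline(fld, s3, step = h / 4)
  p1 <- e1$points[nrow(e1$points), ]
  p2 <- e2$points[nrow(e2$points), ]
  expect_lt(sqrt(sum((p1 - p2)^2)), h / 2)
})

test_that("fiber generation accepts only target-crossing traces, reproducibly", {
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  fld <- fx_cyl_field()
  fs <- generate_fibers(cyl, "nerve", fld, caps$start, caps$target, n = 60,
                        rng_seed = 21)
  expect_length(fs$fibers, 60)
  expect_gt(60 / fs$stats$attempts, 0.9)   # well-aligned field: high acceptance

  # every fiber starts on the start surface and ends on the target surface
  h <- attr(cyl, "voxel")
  z_start <- h; z_end <- 0.02 - h
  first_z <- vapply(fs$fibers, function(f) f$points[1, 3], numeric(1))
  last_z <- vapply(fs$fibers, function(f) f$points[nrow(f$points), 3], numeric(1))
  expect_true(all(abs(first_z - z_start) < 1e-9))
  expect_true(all(abs(last_z - z_end) < 1e-9))

  # bit-for-bit reproducible
  fs2 <- generate_fibers(cyl, "nerve", fld, caps$start, caps$target, n = 60,
                         rng_seed = 21)
  expect_identical(fs$fibers, fs2$fibers)

  # a target that the field cannot reach exhausts the attempt budget
  lateral <- region_boundary(cyl, "nerve", "exterior")
  expect_error(generate_fibers(cyl, "nerve", fx_uniform_field(c(0, 0, -1)),
                               caps$start, caps$target, n = 3,
                               max_attempts = 9),
               "acceptance rate")
})

test_that("fiber types follow the zone-conditional distributions", {
  cyl <- fx_cylinder()
  caps <- fx_cyl_caps()
  fld <- fx_cyl_field()
  fs <- generate_fibers(cyl, "nerve", fld, caps$start, caps$target, n = 400,
                        rng_seed = 33)

  # degenerate distributions are deterministic
  all_dim <- assign_fiber_types(fs, cyl, caps$start,
                                type_probabilities = list(
                                  central = c(regular = 0, irregular = 0, dimorphic = 1),
                                  peripheral = c(regular = 0, irregular = 0, dimorphic = 1)),
                                rng_seed = 1)
  expect_true(all(vapply(all_dim$fibers, function(f) f$type, character(1)) ==
                  "dimorphic"))

  zonal <- assign_fiber_types(fs, cyl, caps$start,
                              type_probabilities = list(
                                central = c(regular = 0, irregular = 1, dimorphic = 0),
                                peripheral = c(regular = 1, irregular = 0, dimorphic = 0)),
                              rng_seed = 1)
  types <- vapply(zonal$fibers, function(f) f$type, character(1))
  zones <- vapply(zonal$fibers, function(f) f$zone, character(1))
  expect_true(all(types[zones == "central"] == "irregular"))
  expect_true(all(types[zones == "peripheral"] == "regular"))

  # default config: zone-conditional frequencies within the multinomial 99% CI
  fs <- assign_fiber_types(fs, cyl, caps$start, rng_seed = 77)
  types <- vapply(fs$fibers, function(f) f$type, character(1))
  zones <- vapply(fs$fibers, function(f) f$zone, character(1))
  defaults <- fiber_type_defaults()
  for (zone in c("central", "peripheral")) {
    nz <- sum(zones == zone)
    for (ty in names(defaults[[zone]])) {
      k <- sum(types[zones == zone] == ty)
      ci <- qbinom(c(0.005, 0.995), nz, defaults[[zone]][[ty]])
      expect_gte(k, ci[1]); expect_lte(k, ci[2])
    }
  }

  expect_error(assign_fiber_types(fs, cyl, caps$start,
                                  type_probabilities = list(
                                    central = c(regular = 0.5, irregular = 0.2,
                                                dimorphic = 0.2),
                                    peripheral = c(regular = 0.5, irregular = 0,
                                                   dimorphic = 0.5))),
               "sum to 1")
})

test_that("nodes of Ranvier are placed arithmetically along the fiber", {
  straight <- list(points = rbind(c(0, 0, 0), c(0, 0, 1e-3)))
  expect_equal(place_nodes_of_ranvier(straight, 100e-6),
               seq(0, 1e-3, by = 100e-6))
  expect_equal(place_nodes_of_ranvier(straight, 300e-6,
                                      first_node_offset = 50e-6),
               c(50e-6, 350e-6, 650e-6, 950e-6))
  expect_error(place_nodes_of_ranvier(straight, 2e-3), "too short")

  # property: node count floor((L - offset)/d) + 1 for random L, d, offset
  set.seed(8)
  for (rep in 1:25) {
    L <- runif(1, 1e-3, 2e-2)
    d <- runif(1, 1e-4, 5e-4)
    off <- runif(1, 0, 4e-4)
    if (L < off + d) next
    fb <- list(points = rbind(c(0, 0, 0), c(0, 0, L)))
    nodes <- place_nodes_of_ranvier(fb, d, off)
    expect_equal(length(nodes), floor((L - off) / d + 1e-9) + 1)
    expect_true(all(diff(nodes) > 0))
    expect_true(all(nodes >= 0 & nodes <= L))
  }
})

test_that("fibers narrow with the tube on a tapering fixture", {
  # cone-ish tube: radius shrinks from 3 mm to 1.5 mm over 20 mm
  h <- 0.5e-3
  nr <- 8L; nz <- 40L
  cs <- (seq_len(2 * nr) - nr - 0.5) * h
  zs <- (seq_len(nz) - 0.5) * h
  g <- expand.grid(x = cs, y = cs, z = zs)
  rad <- 3e-3 - (1.5e-3) * g$z / 0.02
  lab <- rep(NA_character_, nrow(g))
  inside <- g$x^2 + g$y^2 <= rad^2
  lab[inside] <- "nerve"
  lab[inside & g$z < h] <- "start_marker"
  lab[inside & g$z > (nz - 1) * h] <- "target_marker"
  taper <- voxel_to_tetmesh(array(lab, c(length(cs), length(cs), nz)), h,
                            origin = c(-nr * h, -nr * h, 0))
  start <- region_interface(taper, "nerve", "start_marker", role = "start")
  target <- region_interface(taper, "nerve", "target_marker", role = "target")
  phi <- solve_orientation_potential(taper, "nerve", start, target)
  fld <- orientation_from_potential(taper, "nerve", phi)
  fs <- generate_fibers(taper, "nerve", fld, start, target, n = 80,
                        rng_seed = 10)
  spread_at <- function(zq) {
    xy <- t(vapply(fs$fibers, function(f) {
      i <- which.min(abs(f$points[, 3] - zq))
      f$points[i, 1:2]
    }, numeric(2)))
    sqrt(mean(rowSums(xy^2)))
  }
  spreads <- vapply(c(0.002, 0.010, 0.018), spread_at, numeric(1))
  expect_true(all(diff(spreads) < 0))
})
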