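# Conductivity tensors, unit-current Poisson solves and interpolation.

test_that("conductivity tensors have the nerve anisotropy structure", {
  cyl <- fx_cylinder()
  fld <- fx_uniform_field(c(0, 0, 1))
  table <- list(nerve = c(longitudinal = 0.3333, transversal = 0.0143),
                start_marker = 2.0, target_marker = 2.0)
  s <- per_tet_conductivity(cyl, table, list(nerve = fld))
  i <- which(cyl$region == "nerve")[1]
  expect_equal(c(s$s11[i], s$s22[i], s$s33[i]), c(0.0143, 0.0143, 0.3333))
  expect_equal(c(s$s12[i], s$s13[i], s$s23[i]), c(0, 0, 0))
  j <- which(cyl$region == "start_marker")[1]
  expect_equal(c(s$s11[j], s$s22[j], s$s33[j]), c(2, 2, 2))

  # sigma_l = sigma_t: isotropic regardless of direction
  s_iso <- per_tet_conductivity(cyl, list(nerve = c(longitudinal = 0.5,
                                                    transversal = 0.5),
                                          start_marker = 1, target_marker = 1),
                                list(nerve = fx_uniform_field(c(1, 1, 1))))
  expect_equal(s_iso$s11[i], 0.5); expect_equal(s_iso$s12[i], 0)

  # random direction: eigenvalues {sl, st, st}, principal eigenvector || F
  set.seed(5)
  for (rep in 1:5) {
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    fr <- fx_uniform_field(dirv)
    sr <- per_tet_conductivity(cyl, table, list(nerve = fr))
    M <- matrix(c(sr$s11[i], sr$s12[i], sr$s13[i],
                  sr$s12[i], sr$s22[i], sr$s23[i],
                  sr$s13[i], sr$s23[i], sr$s33[i]), 3, 3)
    eg <- eigen(M, symmetric = TRUE)
    expect_equal(sort(eg$values), sort(c(0.3333, 0.0143, 0.0143)),
                 tolerance = 1e-9)
    v1 <- eg$vectors[, which.max(eg$values)]
    expect_gt(abs(sum(v1 * dirv)), 1 - 1e-9)
  }

  expect_error(per_tet_conductivity(cyl, list(nerve = table$nerve,
                                              start_marker = 2),
                                    list(nerve = fld)),
               "no conductivity")
  expect_error(per_tet_conductivity(cyl, table, list()),
               "no orientation field")
})

test_that("unit-current solve is linear, conservative and SPD", {
  fx <- fx_sphere()
  up <- fx$up
  expect_equal(up$diagnostics$absorbed_current, 1, tolerance = 1e-6)
  expect_lt(up$diagnostics$residual, 1e-8)

  # doubling the current doubles the field everywhere
  tens <- per_tet_conductivity(fx$mesh, list(medium = 1, electrode_src = 1))
  up2 <- solve_unit_current(fx$mesh, tens,
                            source_spec("electrode_src", "saline_surface",
                                        current = 2))
  expect_equal(up2$field$values, 2 * up$field$values, tolerance = 1e-9)

  # stiffness matrix is symmetric positive semi-definite; PD after constraints
  cyl <- fx_cylinder()
  sub <- vestim:::submesh(cyl, which(cyl$region == "start_marker"))
  K <- vestim:::assemble_stiffness(sub$vertices, sub$tets)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-15)
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)
  caps <- fx_cyl_caps()
  n <- nrow(sub$vertices)
  Krob <- K + vestim:::assemble_face_mass(
    sub$vertices, vestim:::region_boundary(sub, "start_marker")$faces, 100, n)
  ev2 <- eigen(as.matrix(Krob), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev2), 0)
})

test_that("bipolar solve is antisymmetric for a symmetric dipole", {
  n <- 21L; h <- 13e-3 / n
  lab <- array("fluid", c(n, n, n))
  box <- voxel_to_tetmesh(lab, h, origin = rep(-n * h / 2, 3))
  box <- place_electrode(box, electrode("p", c(3e-3, 0, 0), 3.2e-3))
  box <- place_electrode(box, electrode("q", c(-3e-3, 0, 0), 3.2e-3))
  tens <- per_tet_conductivity(box, list(fluid = 1, electrode_p = 1e6,
                                         electrode_q = 1e6))
  up <- solve_unit_current(box, tens, source_spec("electrode_p", "electrode_q"))
  v <- up$field$values
  # mirror map x -> -x on the structured vertex grid
  key <- apply(round(box$vertices / h, 6), 1, paste, collapse = ",")
  mkey <- apply(round(cbind(-box$vertices[, 1], box$vertices[, 2],
                            box$vertices[, 3]) / h, 6), 1, paste, collapse = ",")
  mirror <- match(mkey, key)
  # phi(x) + phi(Mx) is approximately the constant active-electrode offset
  s <- v + v[mirror]
  expect_lt(stats::sd(s) / max(abs(v)), 0.02)

  # swapping active and reference electrodes mirrors the field
  up_sw <- solve_unit_current(box, tens, source_spec("electrode_q", "electrode_p"))
  expect_equal(up_sw$field$values, v[mirror], tolerance = 0.02 * max(abs(v)))
})

test_that("anisotropy elongates equipotentials along the fiber axis", {
  n <- 15L; h <- 1e-3
  cs <- (seq_len(n) - (n + 1) / 2) * h
  g <- expand.grid(x = cs, y = cs, z = cs)
  lab <- rep("bone", nrow(g))
  lab[g$x^2 + g$y^2 <= (3e-3)^2] <- "nerve"
  mesh <- voxel_to_tetmesh(array(lab, c(n, n, n)), h, origin = rep(-n * h / 2, 3))
  mesh <- place_electrode(mesh, electrode("s", c(0, 0, 0), 3.2e-3))
  idx <- which(mesh$region == "nerve")
  fldz <- structure(list(vectors = matrix(rep(c(0, 0, 1), each = length(idx)),
                                          ncol = 3),
                         tet_ids = idx, region = "nerve", mesh = mesh,
                         cache = new.env(parent = emptyenv())),
                    class = "orientation_field")
  tens <- per_tet_conductivity(mesh,
                               list(nerve = c(longitudinal = 0.3333,
                                              transversal = 0.0143),
                                    bone = 0.0139, electrode_s = 1e6),
                               list(nerve = fldz))
  up <- solve_unit_current(mesh, tens, source_spec("electrode_s", "saline_surface"))
  d <- 4e-3
  phi_axial <- interpolate_at_points(up, rbind(c(0, 0, d)))
  phi_trans <- interpolate_at_points(up, rbind(c(d, 0, 0)))
  expect_gt(phi_axial, phi_trans)
})

test_that("temporal scaling needs no re-solve", {
  fx <- fx_sphere()
  wf <- biphasic_waveform()
  f1 <- scale_potential(fx$up, wf, 1e-3, 100e-6)
  expect_equal(f1$values, -1e-3 * fx$up$field$values)
  expect_true(all(scale_potential(fx$up, wf, 1e-3, 1)$values == 0))
  f2 <- scale_potential(fx$up, wf, 2e-3, 100e-6)
  expect_equal(f2$values, 2 * f1$values)
})

test_that("interpolation reproduces P1 fields and matches brute-force search", {
  cyl <- fx_cylinder()
  vx <- cyl$vertices[, 1]
  pts <- rbind(c(0.3e-3, -0.4e-3, 0.011), c(-1e-3, 0.2e-3, 0.003))
  expect_equal(interpolate_at_points(cyl, vx, pts), pts[, 1], tolerance = 1e-12)

  # vertex location returns the vertex value
  vi <- 123
  expect_equal(interpolate_at_points(cyl, vx, cyl$vertices[vi, , drop = FALSE]),
               vx[vi], tolerance = 1e-12)

  # random interior points: match the exhaustive all-tet barycentric oracle
  set.seed(11)
  vals <- sin(1e3 * cyl$vertices[, 1]) + cos(0.5e3 * cyl$vertices[, 3])
  for (rep in 1:5) {
    p <- c(runif(1, -1e-3, 1e-3), runif(1, -1e-3, 1e-3), runif(1, 2e-3, 0.018))
    expect_equal(interpolate_at_points(cyl, vals, rbind(p)),
                 oracle_interpolate(cyl, vals, p), tolerance = 1e-9)
  }

  expect_error(interpolate_at_points(cyl, vx, rbind(c(1, 1, 1))),
               "outside mesh")
})
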