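# Quasistatic anisotropic volume-conductor solves: per-tet conductivity
# tensors, unit-current Poisson solve, temporal scaling by the stimulus.

#' Default tissue conductivities
#'
#' The standard conductivity set for inner-ear volume-conductor models
#' (S/m): bone 0.0139; nerve tissue anisotropic with 0.3333 longitudinal and
#' 0.0143 transversal; cochlear nerve 0.1738 (average of the two, used where
#' no fiber field is generated); perilymph/endolymph and scalae 2.0; the
#' embedding saline layer 2.0; electrode metal 1e6.
#'
#' @return named list; isotropic entries are scalars, anisotropic entries are
#'   \code{c(longitudinal=, transversal=)}.
#' @export
conductivity_defaults <- function() {
  list(bone = 0.0139,
       nerve = c(longitudinal = 0.3333, transversal = 0.0143),
       cochlear_nerve = 0.1738,
       scala = 2.0,
       endolymph = 2.0,
       perilymph = 2.0,
       saline = 2.0,
       electrode = 1e6)
}

#' Map mesh regions to conductivity entries
#'
#' Builds a per-region conductivity table from the defaults using naming
#' conventions: \code{nerve_*} regions are anisotropic nerve tissue,
#' \code{electrode_*} regions are metal, \code{epithelium_*} and \code{IAC}
#' are neural tissue at the isotropic nerve average, fixture marker regions
#' follow the nerve. Unmatched regions raise an error (every region present
#' must have a conductivity).
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param defaults base table (see \code{\link{conductivity_defaults}}).
#' @param overrides named list of per-region overrides.
#' @return named list: one entry per mesh region.
#' @export
region_conductivities <- function(mesh, defaults = conductivity_defaults(),
                                  overrides = list()) {
  out <- list()
  for (r in mesh_regions(mesh)) {
    out[[r]] <-
      if (!is.null(overrides[[r]])) overrides[[r]]
      else if (!is.null(defaults[[r]])) defaults[[r]]
      else if (startsWith(r, "nerve")) defaults$nerve
      else if (startsWith(r, "electrode")) defaults$electrode
      else if (startsWith(r, "epithelium")) defaults$cochlear_nerve
      else if (r == "IAC") defaults$cochlear_nerve
      else if (r %in% c("start_marker", "target_marker")) defaults$nerve
      else if (startsWith(r, "scala")) defaults$scala
      else stop("no conductivity for region '", r, "'")
  }
  out
}

#' Per-tet conductivity tensors
#'
#' Isotropic regions get \eqn{\sigma I}; anisotropic nerve regions get
#' \eqn{\sigma_t I + (\sigma_l - \sigma_t) F F^T} with \eqn{F} the per-tet
#' fiber orientation, so the principal eigenvector is the fiber direction
#' with eigenvalue \eqn{\sigma_l} and the two transversal eigenvalues are
#' \eqn{\sigma_t}.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param table per-region table from \code{\link{region_conductivities}}.
#' @param fields named list of \code{orientation_field}s, one per anisotropic
#'   region (an anisotropic region without a covering field is an error;
#'   an anisotropic entry for a region lacking a field falls back to the
#'   eigenvalue average only if \code{isotropic_fallback} is set).
#' @param isotropic_fallback if \code{TRUE}, anisotropic regions without an
#'   orientation field use the average of the two eigenvalues.
#' @return list of per-tet tensor component vectors
#'   (\code{s11,s22,s33,s12,s13,s23}).
#' @export
per_tet_conductivity <- function(mesh, table, fields = list(),
                                 isotropic_fallback = FALSE) {
  m <- nrow(mesh$tets)
  s <- list(s11 = numeric(m), s22 = numeric(m), s33 = numeric(m),
            s12 = numeric(m), s13 = numeric(m), s23 = numeric(m))
  for (r in mesh_regions(mesh)) {
    entry <- table[[r]]
    if (is.null(entry)) stop("no conductivity for region '", r, "'")
    idx <- mesh$region == r
    if (length(entry) == 1) {
      s$s11[idx] <- s$s22[idx] <- s$s33[idx] <- as.numeric(entry)
    } else {
      sl <- entry[["longitudinal"]]; st <- entry[["transversal"]]
      fld <- fields[[r]]
      if (is.null(fld)) {
        if (!isotropic_fallback)
          stop("anisotropic region '", r, "' has no orientation field")
        s$s11[idx] <- s$s22[idx] <- s$s33[idx] <- (sl + st) / 2
      } else {
        if (!identical(fld$region, r) || length(fld$tet_ids) != sum(idx))
          stop("orientation field does not cover region '", r, "'")
        F_ <- matrix(0, m, 3)
        F_[fld$tet_ids, ] <- fld$vectors
        d <- sl - st
        s$s11[idx] <- st + d * F_[idx, 1]^2
        s$s22[idx] <- st + d * F_[idx, 2]^2
        s$s33[idx] <- st + d * F_[idx, 3]^2
        s$s12[idx] <- d * F_[idx, 1] * F_[idx, 2]
        s$s13[idx] <- d * F_[idx, 1] * F_[idx, 3]
        s$s23[idx] <- d * F_[idx, 2] * F_[idx, 3]
      }
    }
  }
  s
}

#' Current source specification
#'
#' A unit current distributed uniformly over the active electrode region(s),
#' with either a reference electrode region clamped to 0 V (bipolar) or the
#' outer saline surface clamped to 0 V (monopolar, distant return).
#'
#' @param active character vector of active electrode region labels.
#' @param reference \code{"saline_surface"} or a reference region label.
#' @param current injected current (A), default 1 (unit current).
#' @return object of class \code{source_spec}.
#' @export
source_spec <- function(active, reference = "saline_surface", current = 1) {
  structure(list(active = active, reference = reference, current = current),
            class = "source_spec")
}

#' Solve the unit-current potential distribution
#'
#' P1 finite-element solve of the quasistatic Poisson equation
#' \eqn{-\nabla\cdot(\sigma\nabla\phi) = I_s} with the unit current
#' distributed uniformly over the active electrode tets
#' (\eqn{I_s = I/V_a}), a zero-flux condition on the outer boundary (bipolar)
#' and the reference at 0 V: all vertices of the reference electrode region
#' (bipolar) or all outer-surface vertices (monopolar).
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param tensors per-tet conductivity from \code{\link{per_tet_conductivity}}.
#' @param source a \code{\link{source_spec}}.
#' @return object of class \code{unit_potential}: \code{field} (volts per
#'   injected ampere), \code{mesh}, \code{source}, and \code{diagnostics}
#'   (residual norm, current balance at the reference).
#' @export
solve_unit_current <- function(mesh, tensors, source) {
  check_region(mesh, source$active)
  n <- nrow(mesh$vertices)
  K <- assemble_stiffness(mesh$vertices, mesh$tets, tensors)
  vol <- tet_volumes(mesh)
  act <- mesh$region %in% source$active
  Va <- sum(vol[act])
  if (Va <= 0) stop("active electrode region has zero volume")
  Is <- source$current / Va
  f <- numeric(n)
  w <- rep(vol[act] * Is / 4, 4L)
  acc <- rowsum(w, as.vector(mesh$tets[act, ]))
  f[as.integer(rownames(acc))] <- acc[, 1]

  if (identical(source$reference, "saline_surface")) {
    fc <- face_census(mesh)
    ext_rows <- fc$order[cumsum(fc$count)][fc$count == 1]
    d <- sort(unique(as.vector(fc$ft$faces[ext_rows, ])))
  } else {
    check_region(mesh, source$reference)
    d <- sort(unique(as.vector(mesh$tets[mesh$region == source$reference, ])))
  }
  sol <- solve_dirichlet(K, f, d, 0)
  res <- as.vector(K %*% sol$u) - f
  res[d] <- 0
  structure(list(field = scalar_field(sol$u),
                 mesh = mesh, source = source,
                 diagnostics = list(
                   residual = sqrt(sum(res^2)) / max(1e-300, sqrt(sum(f^2))),
                   absorbed_current = -sum(sol$reaction),
                   active_volume = Va)),
            class = "unit_potential")
}

#' @export
print.unit_potential <- function(x, ...) {
  cat(sprintf("<unit_potential> %d vertices, active {%s}, ref %s; balance %.4g A\n",
              length(x$field$values), paste(x$source$active, collapse = ","),
              x$source$reference, x$diagnostics$absorbed_current))
  invisible(x)
}

#' Scale a unit potential by the stimulus at time t
#'
#' Under the quasistatic assumption the potential at any instant is the
#' unit-current solution scaled by the instantaneous stimulus amplitude; no
#' re-solve is needed.
#'
#' @param unit a \code{\link{solve_unit_current}} result.
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param amplitude stimulus amplitude (A).
#' @param t time (s); outside the support the field is zero.
#' @return a \code{\link{scalar_field}} in volts.
#' @export
scale_potential <- function(unit, waveform, amplitude, t) {
  scalar_field(unit$field$values * amplitude * waveform_at(waveform, t))
}

# lumped access resistance implied by the FEM solution (V per A at 1 A)
access_resistance <- function(unit) {
  mesh <- unit$mesh
  act_v <- sort(unique(as.vector(mesh$tets[mesh$region %in% unit$source$active, ])))
  va <- mean(unit$field$values[act_v])
  vr <- if (identical(unit$source$reference, "saline_surface")) 0 else {
    ref_v <- sort(unique(as.vector(mesh$tets[mesh$region == unit$source$reference, ])))
    mean(unit$field$values[ref_v])
  }
  (va - vr) / unit$source$current
}
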