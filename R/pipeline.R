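# Configuration-driven end-to-end driver: phantom (or file) mesh ->
# fiber-orientation fields -> fibers -> electrodes -> unit potentials ->
# thresholds -> selectivity evaluation.

#' Scenario configuration
#'
#' Bundles every knob of an end-to-end stimulation study. Defaults describe
#' the phantom study: two instrumented nerve branches, four electrode
#' configurations scaled to the phantom resolution, the standard
#' cathodic-first biphasic pulse, and 50 fibers per branch.
#'
#' @param mesh a \code{\link{tet_mesh}}, a \code{\link{phantom_spec}}, or a
#'   path to a VTK file readable by \code{\link{read_mesh}}.
#' @param target_branch region label of the target nerve branch.
#' @param nontarget_branches region labels of instrumented non-target
#'   branches (fibers are generated for these too).
#' @param fibers_per_branch accepted fiber count per branch.
#' @param configurations subset of \code{c("monopolar", "axial",
#'   "transverse_parallel", "transverse_perpendicular")}.
#' @param electrode_diameter,standoff,separation electrode geometry (m);
#'   defaults are scaled to the phantom mesh resolution.
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param cauchy a \code{\link{cauchy_params}} for the orientation solves.
#' @param patch_radius geodesic radius used when a target surface must be
#'   found automatically (m); default 2x the nerve tube radius estimate.
#' @param conductivity_overrides named per-region overrides (S/m).
#' @param neuron named list of \code{\link{neuron_params}} per fiber type,
#'   default \code{\link{neuron_params_by_type}()}.
#' @param rel_tol threshold search tolerance.
#' @param floor_amplitude threshold bracketing floor (A).
#' @param level recruitment level reported (default 0.8).
#' @param seed master RNG seed; all stage streams derive from it.
#' @param out_dir optional output directory for stage artifacts.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(mesh = phantom_spec(),
                            target_branch = "nerve_target",
                            nontarget_branches = "nerve_neighbor",
                            fibers_per_branch = 50,
                            configurations = c("monopolar", "axial",
                                               "transverse_parallel",
                                               "transverse_perpendicular"),
                            electrode_diameter = 8e-3,
                            standoff = 8.75e-3,
                            separation = 10e-3,
                            waveform = biphasic_waveform(),
                            cauchy = cauchy_params(),
                            patch_radius = NULL,
                            conductivity_overrides = list(),
                            neuron = neuron_params_by_type(),
                            rel_tol = 0.01,
                            floor_amplitude = 1e-5,
                            level = 0.8,
                            seed = 1L,
                            out_dir = NULL) {
  configurations <- match.arg(configurations, several.ok = TRUE)
  structure(as.list(environment()), class = "scenario_config")
}

# start/target surfaces of a nerve branch: epithelium interface (fallback:
# endolymph) as start; IAC interface (fallback: automatic distance-surrogate
# target) as target.
branch_surfaces <- function(mesh, branch, patch_radius) {
  regs <- mesh_regions(mesh)
  parts <- list()
  for (e in c(regs[startsWith(regs, "epithelium")], "endolymph")) {
    if (!(e %in% regs)) next
    p <- region_interface(mesh, branch, e, role = "start")
    if (patch_size(p)) parts[[e]] <- p
  }
  if (!length(parts)) stop("no epithelium/endolymph contact for branch ", branch)
  start <- parts[[1]]
  if (length(parts) > 1) {
    start <- surface_patch(do.call(rbind, lapply(parts, function(p) p$faces)),
                           branch,
                           do.call(rbind, lapply(parts, function(p) p$normals)),
                           "start",
                           unlist(lapply(parts, function(p) p$tet)))
  }
  target <- NULL
  if ("IAC" %in% regs) {
    p <- region_interface(mesh, branch, "IAC", role = "target")
    if (patch_size(p)) target <- p
  }
  if (is.null(target))
    target <- find_target_surface(mesh, branch, start, patch_radius)
  # epithelium-only contact patch (if present): anchors the electrode frame
  epi_patch <- if (length(parts) && startsWith(names(parts)[1], "epithelium"))
    parts[[1]] else start
  list(start = start, target = target, epithelium = epi_patch)
}

#' Run a stimulation scenario end to end
#'
#' Executes the full workflow for every requested electrode configuration
#' and evaluates selectivity per configuration. Fully deterministic given the
#' config seed (up to direct-solver roundoff). When \code{out_dir} is set,
#' each stage's artifact is persisted (mesh as VTK, fibers and thresholds as
#' CSV, reports as JSON).
#'
#' @param config a \code{\link{scenario_config}}.
#' @return object of class \code{scenario_result}: per-configuration
#'   \code{selectivity_report}s, threshold tables, fiber sets and the mesh.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mesh <-
    if (inherits(config$mesh, "tet_mesh")) config$mesh
    else if (inherits(config$mesh, "phantom_spec")) make_phantom(config$mesh)
    else if (is.character(config$mesh)) read_mesh(config$mesh)
    else stop("config$mesh must be a tet_mesh, phantom_spec or file path")

  # validate conductivity coverage before any solve
  cond_table <- region_conductivities(mesh, overrides = config$conductivity_overrides)

  branches <- c(config$target_branch, config$nontarget_branches)
  check_region(mesh, branches)
  patch_radius <- config$patch_radius %||% {
    vol <- sum(tet_volumes(mesh)[mesh$region == config$target_branch])
    2 * sqrt(vol / (pi * 0.02))   # crude tube-radius estimate at ~2 cm length
  }

  fields <- list(); fiber_sets <- list(); surfaces <- list()
  for (b in branches) {
    surf <- branch_surfaces(mesh, b, patch_radius)
    phi <- solve_orientation_potential(mesh, b, surf$start, surf$target,
                                       config$cauchy)
    fields[[b]] <- orientation_from_potential(mesh, b, phi)
    fs <- generate_fibers(mesh, b, fields[[b]], surf$start, surf$target,
                          config$fibers_per_branch,
                          rng_seed = stage_seed(config$seed, paste0("fibers_", b)))
    fs <- assign_fiber_types(fs, mesh, surf$start,
                             rng_seed = stage_seed(config$seed, paste0("types_", b)))
    for (i in seq_along(fs$fibers)) {
      pars <- config$neuron[[fs$fibers[[i]]$type]]
      fs$fibers[[i]]$nodes <-
        place_nodes_of_ranvier(fs$fibers[[i]], pars$internodal_distance)
    }
    fiber_sets[[b]] <- fs
    surfaces[[b]] <- surf
  }

  # electrode frame at the target epithelium
  tsurf <- surfaces[[config$target_branch]]
  epi_centroid <- patch_centroid(mesh, tsurf$epithelium)
  tv <- colMeans(tsurf$epithelium$normals)  # outward from nerve, through the
                                            # epithelium into the fluid
  endo_idx <- mesh$region == "endolymph"
  ax <- if (any(endo_idx)) {
    vol <- tet_volumes(mesh)[endo_idx]
    cen <- (mesh$vertices[mesh$tets[endo_idx, 1], , drop = FALSE] +
            mesh$vertices[mesh$tets[endo_idx, 2], , drop = FALSE] +
            mesh$vertices[mesh$tets[endo_idx, 3], , drop = FALSE] +
            mesh$vertices[mesh$tets[endo_idx, 4], , drop = FALSE]) / 4
    colSums(cen * vol) / sum(vol) - epi_centroid
  } else c(1, 0, 0)
  configs <- standard_configurations(epi_centroid, tv, ax,
                                     diameter = config$electrode_diameter,
                                     standoff = config$standoff,
                                     separation = config$separation)
  configs <- configs[config$configurations]

  reports <- list(); thresholds <- list(); units <- list()
  for (cname in names(configs)) {
    cf <- configs[[cname]]
    m2 <- mesh
    for (el in cf$electrodes) m2 <- place_electrode(m2, el)
    tab2 <- region_conductivities(m2, overrides = config$conductivity_overrides)
    tensors <- per_tet_conductivity(m2, tab2, fields)
    roles <- vapply(cf$electrodes, function(e) e$role, character(1))
    active <- vapply(cf$electrodes[roles == "active"],
                     function(e) e$region, character(1))
    ref <- if (identical(cf$reference, "saline_surface")) "saline_surface"
           else cf$electrodes[[which(roles == "reference")[1]]]$region
    unit <- solve_unit_current(m2, tensors, source_spec(active, ref))
    units[[cname]] <- unit
    th <- lapply(branches, function(b)
      branch_thresholds(fiber_sets[[b]], unit, config$waveform, config$neuron,
                        rel_tol = config$rel_tol,
                        floor_amplitude = config$floor_amplitude))
    names(th) <- branches
    thresholds[[cname]] <- do.call(rbind, th)
    curves <- lapply(branches, function(b)
      recruitment_curve(th[[b]]$threshold, nrow(th[[b]]), branch = b))
    names(curves) <- branches
    reports[[cname]] <- selectivity_report(cname, config$target_branch,
                                           curves, config$waveform, unit,
                                           config$level)
  }

  result <- structure(list(reports = reports, thresholds = thresholds,
                           fiber_sets = fiber_sets, mesh = mesh,
                           config = config),
                      class = "scenario_result")
  if (!is.null(config$out_dir)) write_scenario_artifacts(result, config$out_dir)
  result
}

write_scenario_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(result$mesh, file.path(out_dir, "mesh.vtk"))
  ft <- do.call(rbind, lapply(result$fiber_sets, fiber_table))
  utils::write.csv(ft, file.path(out_dir, "fibers.csv"), row.names = FALSE)
  for (cname in names(result$thresholds)) {
    utils::write.csv(result$thresholds[[cname]],
                     file.path(out_dir, paste0("thresholds_", cname, ".csv")),
                     row.names = FALSE)
  }
  summ <- glance(result)
  utils::write.csv(summ, file.path(out_dir, "selectivity.csv"), row.names = FALSE)
  jsonlite::write_json(summ, file.path(out_dir, "selectivity.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  for (r in x$reports) print(r)
  invisible(x)
}

#' Summarise a scenario result
#' @param x a \code{scenario_result}.
#' @param ... unused.
#' @return tibble with one row per electrode configuration.
#' @exportS3Method generics::glance
glance.scenario_result <- function(x, ...) {
  do.call(rbind, lapply(x$reports, tidy))
}
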