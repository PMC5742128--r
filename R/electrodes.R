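# Virtual electrode geometry, placement by region relabeling, multi-electrode
# activate/deactivate bookkeeping, and stimulus waveforms.

#' Spherical virtual electrode
#'
#' @param id electrode identifier (string); the electrode's mesh region is
#'   labeled \code{electrode_<id>}.
#' @param center sphere center (m, length 3).
#' @param diameter sphere diameter (m), > 0.
#' @param role \code{"active"}, \code{"reference"} or \code{"inactive"}.
#' @return object of class \code{electrode}.
#' @export
electrode <- function(id, center, diameter, role = "active") {
  if (diameter <= 0) stop("diameter must be > 0")
  role <- match.arg(role, c("active", "reference", "inactive"))
  structure(list(id = as.character(id), center = as.numeric(center),
                 diameter = diameter, role = role,
                 region = paste0("electrode_", id)),
            class = "electrode")
}

#' Linear electrode array
#'
#' An ordered run of spherical contacts with a fixed pitch along a
#' direction, as in simple multi-contact array designs. Contacts are
#' individual \code{\link{electrode}}s (ids \code{<id>_1 ... <id>_n}) so
#' they can be activated and deactivated independently.
#'
#' @param id array identifier prefix.
#' @param start_center center of the first contact (m).
#' @param direction array direction (normalized internally).
#' @param n number of contacts (>= 1).
#' @param pitch center-to-center spacing (m); must exceed the diameter.
#' @param diameter contact diameter (m).
#' @param roles role per contact (recycled), default \code{"inactive"}.
#' @return list of \code{\link{electrode}}s.
#' @export
electrode_array <- function(id, start_center, direction, n, pitch, diameter,
                            roles = "inactive") {
  if (n < 1) stop("n must be >= 1")
  if (pitch <= diameter) stop("pitch must exceed the contact diameter")
  d <- direction / vnorm(direction)
  roles <- rep_len(roles, n)
  lapply(seq_len(n), function(k)
    electrode(paste0(id, "_", k),
              as.numeric(start_center) + (k - 1) * pitch * d,
              diameter, roles[k]))
}

#' Place an electrode into a labeled mesh
#'
#' Relabels all tets whose centroid lies inside the electrode sphere as
#' \code{electrode_<id>}; the original labels are retained so that
#' \code{\link{deactivate_electrode}} restores them exactly. The mesh must
#' resolve the electrode: the local tet scale (effective voxel pitch of the
#' captured neighbourhood) must be at most 1/3 of the electrode diameter,
#' otherwise an error advises regenerating the mesh at finer resolution.
#'
#' @param mesh a \code{\link{tet_mesh}}.
#' @param el an \code{\link{electrode}}.
#' @return the mesh with the electrode region added (and
#'   \code{orig_region} bookkeeping updated).
#' @export
place_electrode <- function(mesh, el) {
  cen <- (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
          mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4
  r <- el$diameter / 2
  inside <- (cen[, 1] - el$center[1])^2 + (cen[, 2] - el$center[2])^2 +
            (cen[, 3] - el$center[3])^2 <= r^2
  if (!any(inside))
    stop("electrode '", el$id, "' captures no tets (outside the mesh?)")
  if (any(startsWith(mesh$region[inside], "electrode_")))
    stop("electrode '", el$id, "' overlaps an existing electrode region")
  vol <- sum(tet_volumes(mesh)[inside])
  pitch <- (6 * vol / sum(inside) )^(1 / 3)   # effective voxel pitch
  if (pitch > el$diameter / 3)
    stop(sprintf(paste0("local tet size %.3g m exceeds 1/3 electrode diameter ",
                        "%.3g m; regenerate the mesh at finer resolution"),
                 pitch, el$diameter))
  if (is.null(mesh$orig_region)) mesh$orig_region <- mesh$region
  mesh$region[inside] <- el$region
  els <- attr(mesh, "electrodes")
  if (is.null(els)) els <- list()
  els[[el$id]] <- el
  attr(mesh, "electrodes") <- els
  mesh
}

#' Restore the tissue labels under an electrode
#'
#' Assigns the originally present region labels back to the tets of the
#' electrode region; other electrodes are untouched. Idempotent: a second
#' deactivation of the same electrode is a no-op.
#'
#' @param mesh a \code{\link{tet_mesh}} with a placed electrode.
#' @param id electrode id.
#' @return the mesh with the electrode's tets restored.
#' @export
deactivate_electrode <- function(mesh, id) {
  els <- attr(mesh, "electrodes")
  if (is.null(els[[id]])) stop("unknown electrode: ", id)
  reg <- paste0("electrode_", id)
  sel <- mesh$region == reg
  mesh$region[sel] <- mesh$orig_region[sel]
  els[[id]]$role <- "inactive"
  attr(mesh, "electrodes") <- els
  mesh
}

#' Electrode volume captured in the mesh
#' @param mesh a \code{\link{tet_mesh}}.
#' @param id electrode id.
#' @return relabeled volume (m^3).
#' @export
electrode_volume <- function(mesh, id) {
  sum(tet_volumes(mesh)[mesh$region == paste0("electrode_", id)])
}

#' Standard mono- and bipolar electrode configurations
#'
#' Builds the four canonical configurations at an ampullary nerve: a
#' monopolar electrode at a fixed standoff from the sensory epithelium along
#' its transverse axis (reference at the outer saline surface), and three
#' bipolar pairs centered at the monopolar position with dipole moments along
#' the canal-tangent (axial), the transverse axis (transverse-parallel,
#' active electrode closer to the epithelium) and the mutually perpendicular
#' direction (transverse-perpendicular). Defaults are the customary 200 um
#' spheres at 750 um standoff with 1 mm separation; pass scaled values for a
#' coarse phantom.
#'
#' @param epithelium_centroid centroid of the target sensory epithelium (m).
#' @param transverse_axis unit-ish vector from the epithelium toward the
#'   nerve-distal stimulation site (the electrode standoff direction).
#' @param axial_axis vector tangent to the semicircular canal; its component
#'   orthogonal to \code{transverse_axis} is used.
#' @param diameter electrode sphere diameter (m), default 200e-6.
#' @param standoff distance of the monopolar electrode from the epithelium
#'   centroid (m), default 750e-6.
#' @param separation intra-pair center distance (m), default 1e-3.
#' @return named list of configurations (\code{monopolar}, \code{axial},
#'   \code{transverse_parallel}, \code{transverse_perpendicular}); each is a
#'   list of \code{\link{electrode}}s plus a \code{reference} field
#'   (\code{"saline_surface"} for the monopolar case).
#' @export
standard_configurations <- function(epithelium_centroid, transverse_axis,
                                    axial_axis, diameter = 200e-6,
                                    standoff = 750e-6, separation = 1e-3) {
  tv <- as.numeric(transverse_axis)
  if (vnorm(tv) < 1e-12) stop("degenerate transverse axis")
  tv <- tv / vnorm(tv)
  ax <- as.numeric(axial_axis)
  ax <- ax - sum(ax * tv) * tv
  if (vnorm(ax) < 1e-12) stop("degenerate axial axis (parallel to transverse)")
  ax <- ax / vnorm(ax)
  pp <- c(tv[2] * ax[3] - tv[3] * ax[2],
          tv[3] * ax[1] - tv[1] * ax[3],
          tv[1] * ax[2] - tv[2] * ax[1])
  center <- as.numeric(epithelium_centroid) + standoff * tv
  h <- separation / 2
  list(
    monopolar = list(
      electrodes = list(electrode("mono", center, diameter, "active")),
      reference = "saline_surface"),
    axial = list(
      electrodes = list(
        electrode("ax_a", center + h * ax, diameter, "active"),
        electrode("ax_r", center - h * ax, diameter, "reference")),
      reference = "electrode"),
    transverse_parallel = list(
      electrodes = list(
        electrode("tp_a", center - h * tv, diameter, "active"),
        electrode("tp_r", center + h * tv, diameter, "reference")),
      reference = "electrode"),
    transverse_perpendicular = list(
      electrodes = list(
        electrode("tq_a", center + h * pp, diameter, "active"),
        electrode("tq_r", center - h * pp, diameter, "reference")),
      reference = "electrode"))
}

# ---- stimulus waveforms ------------------------------------------------------

#' Stimulus waveform as ordered constant phases
#'
#' @param phases data.frame/list with \code{duration} (s, > 0) and
#'   \code{amplitude} (relative, dimensionless) per phase.
#' @param name waveform name.
#' @return object of class \code{stimulus_waveform} with fields
#'   \code{duration} and \code{amplitude} vectors.
#' @export
stimulus_waveform <- function(phases, name = "custom") {
  dur <- as.numeric(phases$duration)
  amp <- as.numeric(phases$amplitude)
  if (any(dur <= 0)) stop("phase durations must be > 0")
  structure(list(duration = dur, amplitude = amp, name = name),
            class = "stimulus_waveform")
}

#' Charge-balanced biphasic waveform
#'
#' The canonical stimulus: two rectangular phases of equal duration and
#' opposite polarity separated by an interphase gap (default 200 us phases,
#' 30 us gap, cathodic phase first).
#'
#' @param phase_duration phase duration (s), > 0.
#' @param interphase_gap gap duration (s), >= 0.
#' @param cathodic_first logical; if \code{TRUE} (default) the first phase is
#'   negative.
#' @return a \code{\link{stimulus_waveform}}.
#' @export
biphasic_waveform <- function(phase_duration = 200e-6, interphase_gap = 30e-6,
                              cathodic_first = TRUE) {
  if (phase_duration <= 0) stop("phase_duration must be > 0")
  if (interphase_gap < 0) stop("interphase_gap must be >= 0")
  s <- if (cathodic_first) -1 else 1
  ph <- if (interphase_gap > 0) {
    list(duration = c(phase_duration, interphase_gap, phase_duration),
         amplitude = c(s, 0, -s))
  } else {
    list(duration = c(phase_duration, phase_duration), amplitude = c(s, -s))
  }
  stimulus_waveform(ph, name = if (cathodic_first) "biphasic_cathodic_first"
                               else "biphasic_anodic_first")
}

#' Evaluate a waveform
#'
#' Piecewise-constant evaluation w(t); 0 outside the support.
#'
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param t time(s) in seconds.
#' @return relative amplitude(s).
#' @export
waveform_at <- function(waveform, t) {
  edges <- c(0, cumsum(waveform$duration))
  idx <- findInterval(t, edges, left.open = FALSE)
  out <- numeric(length(t))
  inb <- t >= 0 & t < edges[length(edges)] & idx >= 1 &
    idx <= length(waveform$amplitude)
  out[inb] <- waveform$amplitude[idx[inb]]
  out
}

#' Waveform support duration
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @return total support (s).
#' @export
waveform_support <- function(waveform) sum(waveform$duration)
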