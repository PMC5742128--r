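# Per-fiber activation model: discrete myelinated-axon cable at the nodes of
# Ranvier driven by interpolated extracellular potentials, plus the threshold
# amplification-factor search.
#
# Default node kinetics: the CRRSS mammalian myelinated-node formulation
# (fast Na + leak at 37 C), a standard published model; all parameters are
# exposed and a closed-form "linear_sdc" (linear second-difference criterion)
# variant is available as an analytic oracle for the search machinery.

#' Neuron model parameters
#'
#' Electrical parameters of a myelinated fiber discretized at its nodes of
#' Ranvier. Node capacitance and axial internodal conductance are derived
#' from fiber diameter and internodal distance unless given explicitly.
#'
#' @param fiber_diameter outer fiber diameter (m). Axon diameter is taken as
#'   0.7 of it.
#' @param internodal_distance node spacing (m).
#' @param model \code{"active_cable"} (CRRSS node, default) or
#'   \code{"linear_sdc"} (closed-form linear second-difference criterion,
#'   used as a test oracle).
#' @param node_length nodal gap length (m), default 1.5 um.
#' @param c_m nodal membrane capacitance per area (F/m^2), default 0.025
#'   (2.5 uF/cm^2).
#' @param g_na,g_l maximal sodium / leak conductance per area (S/m^2),
#'   defaults 14450 and 1280.
#' @param e_na,e_l sodium / leak reversal potentials relative to rest (V),
#'   defaults 0.115 and -1e-5.
#' @param rho_axial axoplasmic resistivity (Ohm m), default 0.547.
#' @param v_rest resting membrane potential (V, absolute), default -0.080.
#' @param spike_threshold absolute membrane potential counted as a spike
#'   (V), default 0 (full depolarization overshoot).
#' @param temp_factor rate scaling factor (default 1: rates already at 37 C).
#' @param dt integration step (s), default 2e-6, implicit Euler.
#' @param tail simulated time appended after the stimulus support (s),
#'   default 1e-3.
#' @param sdc_drive_threshold activation-function threshold (A) of the
#'   \code{linear_sdc} variant.
#' @return object of class \code{neuron_params} with derived \code{c_node}
#'   (F) and \code{g_axial} (S).
#' @export
neuron_params <- function(fiber_diameter = 3e-6,
                          internodal_distance = 300e-6,
                          model = c("active_cable", "linear_sdc"),
                          node_length = 1.5e-6,
                          c_m = 0.025, g_na = 14450, g_l = 1280,
                          e_na = 0.115, e_l = -1e-5,
                          rho_axial = 0.547,
                          v_rest = -0.080, spike_threshold = 0,
                          temp_factor = 1,
                          dt = 2e-6, tail = 1e-3,
                          sdc_drive_threshold = 1e-9) {
  model <- match.arg(model)
  stopifnot(fiber_diameter > 0, internodal_distance > 0, node_length > 0,
            c_m > 0, g_na > 0, g_l > 0, rho_axial > 0, dt > 0,
            temp_factor > 0)
  d_axon <- 0.7 * fiber_diameter
  area <- pi * d_axon * node_length
  structure(list(fiber_diameter = fiber_diameter,
                 internodal_distance = internodal_distance,
                 model = model, node_length = node_length,
                 c_m = c_m, g_na = g_na, g_l = g_l,
                 e_na = e_na, e_l = e_l, rho_axial = rho_axial,
                 v_rest = v_rest, spike_threshold = spike_threshold,
                 temp_factor = temp_factor, dt = dt, tail = tail,
                 sdc_drive_threshold = sdc_drive_threshold,
                 node_area = area,
                 c_node = c_m * area,
                 g_axial = pi * d_axon^2 / (4 * rho_axial * internodal_distance)),
            class = "neuron_params")
}

#' Per-type neuron parameter defaults
#'
#' Regular, irregular and dimorphic afferents differ in caliber and
#' internodal spacing; these defaults pair the placeholder internodal
#' distances with diameters at the customary length-to-diameter ratio of
#' about 100.
#'
#' @param ... overrides forwarded to \code{\link{neuron_params}}.
#' @return named list of \code{neuron_params} per fiber type.
#' @export
neuron_params_by_type <- function(...) {
  spacing <- internodal_defaults()
  lapply(spacing, function(L)
    neuron_params(fiber_diameter = L / 100, internodal_distance = L, ...))
}

# CRRSS rate functions; v in volts relative to rest, rates in 1/s
crrss_rates <- function(v, k) {
  vm <- v * 1e3
  am <- 1e3 * (97 + 0.363 * vm) / (1 + exp((31 - vm) / 5.3))
  bm <- am / exp((vm - 23.8) / 4.17)
  bh <- 1e3 * 15.6 / (1 + exp((24 - vm) / 10))
  ah <- bh / exp((vm - 5.5) / 5)
  list(am = k * am, bm = k * bm, ah = k * ah, bh = k * bh)
}

# sealed-end second-difference matrix L (N x N): (L v)_i = v_{i-1}-2v_i+v_{i+1}
# with one-sided ends.
second_difference_matrix <- function(N) {
  L <- diag(-2, N)
  L[cbind(1:(N - 1), 2:N)] <- 1
  L[cbind(2:N, 1:(N - 1))] <- 1
  L[1, 1] <- -1
  L[N, N] <- -1
  L
}

#' Simulate one fiber under an extracellular stimulus
#'
#' Discrete cable model at the nodes of Ranvier: the transmembrane potential
#' obeys \eqn{C dV_n/dt = G_a (V_{n-1} - 2V_n + V_{n+1} + V_{e,n-1} -
#' 2V_{e,n} + V_{e,n+1}) - I_{ion}(V_n)} with sealed ends, where
#' \eqn{V_{e,n}(t) = A\, w(t)\, u_n} couples the unit-current extracellular
#' potentials \eqn{u_n} at the nodes through the waveform and amplitude.
#' Integration is fixed-step implicit Euler (gates by exponential Euler)
#' over the stimulus support plus a tail. A spike is any node's absolute
#' membrane potential crossing the spike criterion after stimulus onset.
#'
#' @param node_potentials unit-current extracellular potentials at the nodes
#'   (V per A), length >= 2.
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param amplitude stimulus amplitude (A): the amplification factor applied
#'   to the unit-current solution.
#' @param params a \code{\link{neuron_params}}.
#' @return logical: did the fiber spike?
#' @export
simulate_fiber <- function(node_potentials, waveform, amplitude, params) {
  u <- as.numeric(node_potentials)
  N <- length(u)
  if (N < 2) stop("need at least 2 nodes of Ranvier")
  if (params$model == "linear_sdc") {
    drive <- sdc_peak_drive(u, waveform, params)
    return(amplitude * drive >= params$sdc_drive_threshold)
  }
  out <- .cable_spike(u, waveform$duration, waveform$amplitude, amplitude,
                      params$dt, params$tail, params$c_node, params$g_axial,
                      params$node_area, params$g_na, params$g_l,
                      params$e_na, params$e_l, params$temp_factor,
                      params$spike_threshold - params$v_rest)
  if (out < 0) stop("cable model instability (|V| > 1 V); reduce dt")
  out == 1L
}

# Pure-R reference implementation of the same stepper (used to cross-check
# the compiled core on small problems).
r_cable_spike <- function(node_potentials, waveform, amplitude, params) {
  u <- as.numeric(node_potentials)
  N <- length(u)
  dt <- params$dt
  steps <- ceiling((waveform_support(waveform) + params$tail) / dt)
  L <- second_difference_matrix(N)
  A <- diag(params$c_node / dt, N) - params$g_axial * L
  Ainv <- solve(A)
  v <- numeric(N)
  r0 <- crrss_rates(0, params$temp_factor)
  m <- r0$am / (r0$am + r0$bm)
  h <- r0$ah / (r0$ah + r0$bh)
  vth <- params$spike_threshold - params$v_rest
  area <- params$node_area
  for (s in seq_len(steps)) {
    t1 <- s * dt
    ve <- (amplitude * waveform_at(waveform, t1)) * u
    r <- crrss_rates(v, params$temp_factor)
    sm <- r$am + r$bm
    m <- r$am / sm + (m - r$am / sm) * exp(-dt * sm)
    sh <- r$ah + r$bh
    h <- r$ah / sh + (h - r$ah / sh) * exp(-dt * sh)
    i_ion <- area * (params$g_na * m^3 * h * (v - params$e_na) +
                     params$g_l * (v - params$e_l))
    b <- (params$c_node / dt) * v - i_ion + params$g_axial * (L %*% ve)
    v <- as.vector(Ainv %*% b)
    if (any(!is.finite(v)) || max(abs(v)) > 1)
      stop("cable model instability (|V| > 1 V); reduce dt")
    if (max(v) >= vth) return(TRUE)
  }
  FALSE
}

# peak positive activating drive (A per unit amplitude) of the linear
# second-difference criterion: max over phases and nodes of
# g_axial * (w * second difference of u)_+
sdc_peak_drive <- function(u, waveform, params) {
  L <- second_difference_matrix(length(u))
  d2 <- as.vector(L %*% u)
  amps <- unique(waveform$amplitude)
  best <- 0
  for (a in amps) best <- max(best, max(a * d2))
  params$g_axial * best
}

#' Threshold amplification factor of a fiber
#'
#' Finds the smallest stimulus amplitude (multiple of the unit current, i.e.
#' a current in amperes) that elicits a spike: bracket by doubling from a
#' floor until a spike occurs, then bisect to the requested relative
#' tolerance. Fibers that do not spike at the ceiling are flagged
#' non-excitable (threshold \code{Inf}).
#'
#' @param node_potentials unit-current extracellular node potentials (V/A).
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param params a \code{\link{neuron_params}}.
#' @param rel_tol relative tolerance in (0, 0.1], default 0.01.
#' @param floor_amplitude bracketing floor (A), default 1e-5.
#' @param ceiling_factor search ceiling as a multiple of the floor,
#'   default 1e6.
#' @return object of class \code{threshold_result}: \code{threshold} (A; Inf
#'   when non-excitable), \code{converged}, \code{bracket} history.
#' @export
find_threshold <- function(node_potentials, waveform, params,
                           rel_tol = 0.01, floor_amplitude = 1e-5,
                           ceiling_factor = 1e6) {
  if (rel_tol <= 0 || rel_tol > 0.1) stop("rel_tol must be in (0, 0.1]")
  spikes <- function(a) simulate_fiber(node_potentials, waveform, a, params)
  hi <- floor_amplitude
  ceiling_amp <- floor_amplitude * ceiling_factor
  bracket <- numeric(0)
  while (!spikes(hi)) {
    bracket <- c(bracket, hi)
    hi <- hi * 2
    if (hi > ceiling_amp) {
      return(structure(list(threshold = Inf, converged = FALSE,
                            bracket = bracket),
                       class = "threshold_result"))
    }
  }
  lo <- if (length(bracket)) hi / 2 else 0
  while ((hi - lo) > rel_tol * hi) {
    mid <- (hi + lo) / 2
    if (spikes(mid)) hi <- mid else lo <- mid
    bracket <- c(bracket, mid)
  }
  structure(list(threshold = hi, converged = TRUE, bracket = bracket),
            class = "threshold_result")
}

#' Thresholds for all fibers of a branch
#'
#' Interpolates the unit-current potential at each fiber's nodes of Ranvier
#' and runs the threshold search per fiber. Per-fiber errors are recorded,
#' not fatal; results are independent of evaluation order.
#'
#' @param fiber_set a \code{fiber_set} with nodes placed (fibers without
#'   nodes get them placed at their type's default internodal distance).
#' @param unit a \code{unit_potential}.
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param params_by_type named list of \code{\link{neuron_params}} per fiber
#'   type (or a single \code{neuron_params} for all fibers).
#' @param rel_tol,floor_amplitude,ceiling_factor forwarded to
#'   \code{\link{find_threshold}}.
#' @return tibble: fiber id, branch, type, threshold (A), converged, error.
#' @export
branch_thresholds <- function(fiber_set, unit, waveform, params_by_type,
                              rel_tol = 0.01, floor_amplitude = 1e-5,
                              ceiling_factor = 1e6) {
  fibers <- fiber_set$fibers
  n <- length(fibers)
  thr <- rep(NA_real_, n); conv <- rep(FALSE, n); err <- rep(NA_character_, n)
  types <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fb <- fibers[[i]]
    type <- if (!is.na(fb$type)) fb$type else "dimorphic"
    types[i] <- type
    pars <- if (inherits(params_by_type, "neuron_params")) params_by_type
            else params_by_type[[type]]
    if (is.null(pars)) { err[i] <- paste0("no params for type ", type); next }
    res <- tryCatch({
      nodes <- fb$nodes %||% place_nodes_of_ranvier(fb, pars$internodal_distance)
      npts <- fiber_node_points(fb, nodes)
      up <- interpolate_at_points(unit, npts)
      find_threshold(up, waveform, pars, rel_tol, floor_amplitude,
                     ceiling_factor)
    }, error = function(e) e)
    if (inherits(res, "error")) { err[i] <- conditionMessage(res); next }
    thr[i] <- res$threshold
    conv[i] <- res$converged
  }
  tibble::tibble(fiber = seq_len(n), branch = fiber_set$branch, type = types,
                 threshold = thr, converged = conv, error = err)
}
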