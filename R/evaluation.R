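# Selectivity evaluation: recruitment curves, ROC/AUC over stimulus
# amplitude, 80%-activation amplitude, charge and energy per pulse.

#' Fiber recruitment curve
#'
#' The right-continuous non-decreasing step function
#' \eqn{recruitment(a) = \#\{thresholds \le a\}/N}: the ratio of activated
#' fibers of a branch at stimulus amplitude \eqn{a}. Non-excitable fibers
#' (infinite thresholds) stay in the denominator and never activate.
#'
#' @param thresholds numeric vector of per-fiber thresholds (A); \code{Inf}
#'   marks non-excitable fibers.
#' @param n_total denominator (defaults to \code{length(thresholds)}).
#' @param branch optional branch label.
#' @return object of class \code{recruitment_curve} with sorted finite
#'   thresholds and an evaluation closure accessible via
#'   \code{\link{recruitment_at}}.
#' @export
recruitment_curve <- function(thresholds, n_total = length(thresholds),
                              branch = NA_character_) {
  if (n_total < 1) stop("n_total must be >= 1")
  th <- sort(thresholds[is.finite(thresholds)])
  structure(list(thresholds = th, n_total = n_total, branch = branch),
            class = "recruitment_curve")
}

#' Evaluate a recruitment curve
#' @param curve a \code{recruitment_curve}.
#' @param a amplitude(s) (A).
#' @return recruitment ratio(s) in [0, 1].
#' @export
recruitment_at <- function(curve, a) {
  vapply(a, function(x) sum(curve$thresholds <= x), numeric(1)) / curve$n_total
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("<recruitment_curve>%s %d/%d excitable fibers, thresholds [%.4g, %.4g] A\n",
              if (!is.na(x$branch)) paste0(" ", x$branch) else "",
              length(x$thresholds), x$n_total,
              if (length(x$thresholds)) min(x$thresholds) else NA,
              if (length(x$thresholds)) max(x$thresholds) else NA))
  invisible(x)
}

#' Amplitude required for a recruitment level
#'
#' The smallest amplitude at which recruitment reaches \code{level}: the
#' \eqn{\lceil level \cdot N \rceil}-th order statistic of the thresholds
#' (the recruitment curve is a step function, so no interpolation).
#'
#' @param curve a \code{recruitment_curve}.
#' @param level recruitment ratio in (0, 1], default 0.8.
#' @return amplitude (A).
#' @export
amplitude_for_recruitment <- function(curve, level = 0.8) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  k <- ceiling(level * curve$n_total)
  if (k > length(curve$thresholds))
    stop(sprintf("recruitment level %.2f unattainable (max attainable %.3f)",
                 level, length(curve$thresholds) / curve$n_total))
  curve$thresholds[k]
}

#' ROC selectivity: area under the TPR-vs-FPR curve
#'
#' Sweeps the stimulus amplitude over all distinct thresholds; at each
#' amplitude the true positive rate is the target-branch recruitment and the
#' false positive rate is the recruitment of the maximally activated
#' non-target branch. The staircase is completed with (0,0) and (1,1) and
#' integrated by trapezoids. 1 means fully selective (all target fibers
#' activate before any non-target fiber), 0 fully anti-selective.
#'
#' @param target target-branch \code{recruitment_curve}.
#' @param nontargets list of non-target \code{recruitment_curve}s (>= 1).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(target, nontargets) {
  if (inherits(nontargets, "recruitment_curve")) nontargets <- list(nontargets)
  if (!length(nontargets)) stop("need at least one non-target curve")
  if (!length(target$thresholds)) stop("empty target curve")
  amps <- sort(unique(c(target$thresholds,
                        unlist(lapply(nontargets, function(c) c$thresholds)))))
  tpr <- recruitment_at(target, amps)
  fprs <- matrix(vapply(nontargets, function(c) recruitment_at(c, amps),
                        numeric(length(amps))), nrow = length(amps))
  fpr <- apply(fprs, 1, max)
  x <- c(0, fpr, 1)
  y <- c(0, tpr, 1)
  sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)]) / 2)
}

#' Charge per pulse
#'
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param amplitude stimulus amplitude (A), > 0.
#' @return list: \code{per_phase} (C, charge magnitude per polarity),
#'   \code{net} (C, charge-balance residual), \code{total_abs} (C).
#' @export
charge_per_pulse <- function(waveform, amplitude) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  q <- amplitude * waveform$amplitude * waveform$duration
  list(per_phase = stats::setNames(abs(q[waveform$amplitude != 0]), NULL),
       net = sum(q),
       total_abs = sum(abs(q)))
}

#' Energy per pulse
#'
#' \eqn{E = A^2 \int w(t)^2 dt \cdot R_{access}} with the lumped access
#' resistance read from the FEM solution: mean unit potential over the
#' active-electrode vertices minus the mean over the reference (0 for the
#' grounded saline surface) per injected ampere. This is a reporting
#' convention; alternative energy figures can be plugged in.
#'
#' @param waveform a \code{\link{stimulus_waveform}}.
#' @param amplitude stimulus amplitude (A).
#' @param unit a \code{unit_potential} for the configuration.
#' @return energy (J).
#' @export
energy_per_pulse <- function(waveform, amplitude, unit) {
  int_w2 <- sum(waveform$amplitude^2 * waveform$duration)
  amplitude^2 * int_w2 * access_resistance(unit)
}

#' Selectivity report of one electrode configuration
#'
#' @param configuration configuration name.
#' @param target_branch target branch label.
#' @param curves named list of per-branch \code{recruitment_curve}s
#'   (target first).
#' @param waveform the stimulus waveform used.
#' @param unit the configuration's \code{unit_potential} (optional, enables
#'   charge/energy).
#' @param level recruitment level for the amplitude figure (default 0.8).
#' @return object of class \code{selectivity_report} with \code{auc},
#'   \code{amplitude} (A for \code{level} target recruitment), charge and
#'   energy at that amplitude.
#' @export
selectivity_report <- function(configuration, target_branch, curves, waveform,
                               unit = NULL, level = 0.8) {
  target <- curves[[target_branch]]
  if (is.null(target)) stop("no curve for target branch ", target_branch)
  nont <- curves[names(curves) != target_branch]
  # an entirely non-excitable target has no ROC; report NA rather than fail
  auc <- if (length(target$thresholds)) roc_auc(target, nont) else NA_real_
  amp <- tryCatch(amplitude_for_recruitment(target, level),
                  error = function(e) NA_real_)
  chg <- if (!is.na(amp)) charge_per_pulse(waveform, amp) else NULL
  en <- if (!is.na(amp) && !is.null(unit)) energy_per_pulse(waveform, amp, unit)
        else NA_real_
  structure(list(configuration = configuration, target = target_branch,
                 curves = curves, auc = auc, level = level, amplitude = amp,
                 charge = chg, energy = en, waveform = waveform),
            class = "selectivity_report")
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf("<selectivity_report> %s (target %s): AUC %.3f, %.0f%% amplitude %s\n",
              x$configuration, x$target, x$auc, 100 * x$level,
              if (is.na(x$amplitude)) "unattainable"
              else sprintf("%.4g A", x$amplitude)))
  invisible(x)
}

#' Tidy a selectivity report
#' @param x a \code{selectivity_report}.
#' @param ... unused.
#' @return one-row tibble with the report's headline figures.
#' @exportS3Method generics::tidy
tidy.selectivity_report <- function(x, ...) {
  tibble::tibble(configuration = x$configuration, target = x$target,
                 auc = x$auc, level = x$level, amplitude = x$amplitude,
                 charge_per_phase = if (is.null(x$charge)) NA_real_
                                    else max(x$charge$per_phase),
                 energy = x$energy)
}

#' Recruitment curves as a long tibble
#' @param report a \code{selectivity_report}.
#' @return tibble (branch, amplitude, recruitment) tracing each step curve.
#' @export
recruitment_table <- function(report) {
  rows <- lapply(names(report$curves), function(b) {
    cur <- report$curves[[b]]
    th <- cur$thresholds
    tibble::tibble(branch = b, amplitude = th,
                   recruitment = seq_along(th) / cur$n_total)
  })
  do.call(rbind, rows)
}

#' Plot recruitment curves of a report
#'
#' Step plot of per-branch recruitment versus stimulus amplitude
#' (ggplot2 must be installed).
#'
#' @param report a \code{selectivity_report}.
#' @return a ggplot object.
#' @export
plot_recruitment <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- recruitment_table(report)
  ggplot2::ggplot(df, ggplot2::aes(x = amplitude, y = recruitment,
                                   colour = branch)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "stimulus amplitude (A)", y = "fiber recruitment",
                  title = report$configuration,
                  subtitle = sprintf("AUC %.3f", report$auc)) +
    ggplot2::theme_minimal()
}
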