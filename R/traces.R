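#' Voltage-step protocol
#'
#' Ordered constant-voltage segments of a voltage-clamp episode.
#'
#' @param segments Data frame with columns `duration_ms`, `voltage_mV`,
#'   `label` (labels unique within the protocol).
#' @param inter_episode_ms Optional interval between episodes, ms.
#' @return Object of class `voltage_protocol`.
#' @examples
#' voltage_protocol(data.frame(
#'   duration_ms = c(10000, 250), voltage_mV = c(-100, 50),
#'   label = c("prepulse", "test")))
#' @export
voltage_protocol <- function(segments, inter_episode_ms = NULL) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("duration_ms", "voltage_mV", "label") %in%
                  names(segments)))
  if (any(segments$duration_ms <= 0)) stop("segment durations must be > 0")
  if (anyDuplicated(segments$label)) stop("segment labels must be unique")
  structure(list(segments = segments,
                 inter_episode_ms = inter_episode_ms,
                 junction_corrected = FALSE),
            class = "voltage_protocol")
}

#' Current trace from a voltage-clamp sweep
#'
#' A uniformly sampled current recording stored as a tibble with
#' columns `time_ms` and `current`, carrying unit and metadata
#' attributes.
#'
#' @param current Numeric current samples (>= 2).
#' @param sampling_ms Sampling interval, ms (> 0).
#' @param unit Current unit string (e.g. `"uA"`, `"nA"`).
#' @param protocol Optional [voltage_protocol()].
#' @param metadata Named list (holding potential, cell id, ...).
#' @return Tibble of class `current_trace`.
#' @export
current_trace <- function(current, sampling_ms, unit = "uA",
                          protocol = NULL, metadata = list()) {
  if (sampling_ms <= 0) stop("`sampling_ms` must be > 0")
  if (length(current) < 2) stop("a trace needs at least 2 samples")
  if (!is.character(unit) || length(unit) != 1) {
    stop("`unit` must be declared as a single string")
  }
  metadata$junction_corrected <- metadata$junction_corrected %||% FALSE
  out <- tibble::tibble(
    time_ms = (seq_along(current) - 1) * sampling_ms,
    current = as.numeric(current))
  structure(out, class = c("current_trace", class(out)),
            sampling_ms = sampling_ms, unit = unit,
            protocol = protocol, metadata = metadata)
}

trace_meta <- function(trace) attr(trace, "metadata") %||% list()

#' A set of sweeps sharing a protocol with one varied parameter
#'
#' @param traces Named list of [current_trace()] objects.
#' @param varied_values Numeric value of the varied parameter per sweep
#'   (must be unique).
#' @param varied_param Name of the varied parameter, e.g.
#'   `"prepulse_mV"`, `"test_mV"` or `"interval_ms"`.
#' @return Object of class `sweep_set` (list with `traces`, `values`,
#'   `varied_param`).
#' @export
sweep_set <- function(traces, varied_values, varied_param) {
  stopifnot(length(traces) == length(varied_values))
  if (anyDuplicated(varied_values)) {
    stop("varied-parameter values must be unique across sweeps")
  }
  if (is.null(names(traces))) {
    names(traces) <- paste0("sweep_",
                            format(varied_values, trim = TRUE))
  }
  structure(list(traces = traces, values = as.numeric(varied_values),
                 varied_param = varied_param),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", length(x$traces), " sweeps varied by ",
      x$varied_param, ": ", paste(x$values, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Long-format view of a sweep set
#'
#' @param set A [sweep_set()].
#' @return Tibble with columns `sweep`, the varied parameter, `time_ms`,
#'   `current`.
#' @export
sweeps_to_tibble <- function(set) {
  stopifnot(inherits(set, "sweep_set"))
  purrr::map_dfr(seq_along(set$traces), function(i) {
    tr <- set$traces[[i]]
    out <- tibble::tibble(sweep = names(set$traces)[i],
                          time_ms = tr$time_ms, current = tr$current)
    out[[set$varied_param]] <- set$values[i]
    out[, c("sweep", set$varied_param, "time_ms", "current")]
  })
}

#' Subtract a scaled null trace (leak/capacitance correction)
#'
#' Off-line leak and capacitative-transient subtraction: a null trace
#' recorded at a voltage without ionic current is scaled up and
#' subtracted pointwise from the total current.
#'
#' @param trace,null_trace [current_trace()] objects of equal length
#'   and sampling interval.
#' @param scale Dimensionless scale factor applied to the null trace.
#' @return Corrected `current_trace`; metadata records the subtraction.
#' @export
subtract_scaled_null <- function(trace, null_trace, scale) {
  if (nrow(trace) != nrow(null_trace) ||
      !isTRUE(all.equal(attr(trace, "sampling_ms"),
                        attr(null_trace, "sampling_ms")))) {
    stop("trace and null trace must share length and sampling interval")
  }
  meta <- trace_meta(trace)
  meta$null_subtracted <- TRUE
  meta$null_scale <- scale
  current_trace(trace$current - scale * null_trace$current,
                attr(trace, "sampling_ms"), attr(trace, "unit"),
                attr(trace, "protocol"), meta)
}

#' Isolate the transient A-type current by prepulse subtraction
#'
#' The transient outward current is revealed by subtracting, at each
#' test voltage, the sweep conditioned at a depolarized prepulse (which
#' inactivates the A-type component) from the sweep conditioned at a
#' hyperpolarized prepulse (full availability); sustained currents
#' cancel in the difference.
#'
#' @param sweeps_hyper Sweep set conditioned at the hyperpolarized
#'   prepulse (e.g. -114 mV), varied by test voltage.
#' @param sweeps_depol Sweep set conditioned at the depolarized
#'   prepulse (e.g. -44 mV), matched test voltages.
#' @return A [sweep_set()] of difference traces.
#' @export
isolate_isa_by_prepulse_subtraction <- function(sweeps_hyper,
                                                sweeps_depol) {
  stopifnot(inherits(sweeps_hyper, "sweep_set"),
            inherits(sweeps_depol, "sweep_set"))
  miss_h <- setdiff(sweeps_depol$values, sweeps_hyper$values)
  miss_d <- setdiff(sweeps_hyper$values, sweeps_depol$values)
  if (length(miss_h) + length(miss_d) > 0) {
    stop("unmatched test voltages: ",
         if (length(miss_d)) paste("missing from depolarized set:",
                                   paste(miss_d, collapse = ", ")),
         if (length(miss_h)) paste(" missing from hyperpolarized set:",
                                   paste(miss_h, collapse = ", ")))
  }
  vals <- sweeps_hyper$values
  diffs <- purrr::map(seq_along(vals), function(i) {
    j <- match(vals[i], sweeps_depol$values)
    subtract_scaled_null(sweeps_hyper$traces[[i]],
                         sweeps_depol$traces[[j]], 1)
  })
  sweep_set(diffs, vals, sweeps_hyper$varied_param)
}

#' Peak conductance from peak current
#'
#' G_p = I_p / (V_c - V_rev); with current in nA (or uA) and voltage in
#' mV the result is in uS (or mS).
#'
#' @param i_peak Peak current.
#' @param v_command Command (test) voltage, mV.
#' @param v_rev Reversal potential, mV (default -90, the value in ND96
#'   bath solution).
#' @return Conductance in current-unit per mV.
#' @export
peak_conductance <- function(i_peak, v_command, v_rev = -90) {
  if (any(v_command == v_rev)) {
    stop("command voltage equals the reversal potential")
  }
  i_peak / (v_command - v_rev)
}

#' Peak of a test-pulse trace after a blanking period
#'
#' @param trace A [current_trace()] (or data frame with `time_ms`,
#'   `current`).
#' @param blank_ms Initial window to skip, ms (default 1, to avoid the
#'   residual capacitance artifact).
#' @return Maximum current after blanking.
#' @export
trace_peak <- function(trace, blank_ms = 1) {
  keep <- trace$time_ms >= blank_ms
  if (!any(keep)) keep <- rep(TRUE, nrow(trace))
  max(trace$current[keep])
}

#' Fractional recovery from a two-pulse protocol
#'
#' The residual current at the end of the first pulse is subtracted
#' from both peak currents and recovery is the ratio of the corrected
#' second-pulse peak to the corrected first-pulse peak:
#' (peak2 - residual1) / (peak1 - residual1).
#'
#' @param pulse1,pulse2 [current_trace()] objects for the conditioning
#'   and test pulses.
#' @param blank_ms Peak-detection blanking period, ms.
#' @param residual_window_ms Averaging window at the end of pulse 1 for
#'   the residual; the default 0 takes the final sample.
#' @return Fractional recovery (dimensionless).
#' @export
fractional_recovery <- function(pulse1, pulse2, blank_ms = 1,
                                residual_window_ms = 0) {
  tail_from <- max(pulse1$time_ms) - residual_window_ms
  residual1 <- mean(pulse1$current[pulse1$time_ms >= tail_from])
  peak1 <- trace_peak(pulse1, blank_ms)
  peak2 <- trace_peak(pulse2, blank_ms)
  if (peak1 <= residual1) {
    stop("first pulse has no inactivating component ",
         "(peak <= residual)")
  }
  (peak2 - residual1) / (peak1 - residual1)
}

#' Steady-state inactivation points from a prepulse-varied sweep set
#'
#' Normalizes each sweep's test-pulse peak by the peak at the most
#' hyperpolarized prepulse (I_max) to give the available fraction
#' I/I_max per prepulse voltage.
#'
#' @param sweeps [sweep_set()] varied by prepulse voltage (mV).
#' @param blank_ms Peak-detection blanking period, ms.
#' @return Tibble with columns `prepulse_mV`, `availability`.
#' @export
ssi_points <- function(sweeps, blank_ms = 1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (length(sweeps$traces) < 2) stop("need at least 2 sweeps")
  peaks <- vapply(sweeps$traces, trace_peak, numeric(1),
                  blank_ms = blank_ms)
  i_max <- peaks[which.min(sweeps$values)]
  if (i_max <= 0) stop("I_max (most hyperpolarized sweep peak) is <= 0")
  out <- tibble::tibble(prepulse_mV = sweeps$values,
                        availability = unname(peaks) / i_max)
  out[order(out$prepulse_mV), ]
}

#' Apply the liquid-junction-potential correction
#'
#' Shifts all command voltages by the calculated junction offset
#' (default -14.2 mV, the gluconate-based pipette value) and flags the
#' object as corrected; re-application errors.
#'
#' @param x A [voltage_protocol()], [sweep_set()] varied by a voltage,
#'   or numeric voltage vector.
#' @param offset_mV Junction potential, mV.
#' @return Corrected object of the same type.
#' @examples
#' apply_junction_correction(-100)  # -114.2
#' @export
apply_junction_correction <- function(x, offset_mV = -14.2) {
  if (is.numeric(x)) return(x + offset_mV)
  if (inherits(x, "voltage_protocol")) {
    if (isTRUE(x$junction_corrected)) {
      stop("protocol is already junction-corrected")
    }
    x$segments$voltage_mV <- x$segments$voltage_mV + offset_mV
    x$junction_corrected <- TRUE
    return(x)
  }
  if (inherits(x, "sweep_set")) {
    if (isTRUE(attr(x, "junction_corrected"))) {
      stop("sweep set is already junction-corrected")
    }
    if (!grepl("mV", x$varied_param)) {
      stop("sweep set is not varied by a voltage")
    }
    x$values <- x$values + offset_mV
    attr(x, "junction_corrected") <- TRUE
    return(x)
  }
  stop("unsupported object for junction correction")
}
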