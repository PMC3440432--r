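# Trajectory metrics: reduce a thrombin trace to the six thrombogram
# parameters (MaxL, TMaxL, MaxR, TMaxR, AUC, CT).

#' Thrombogram parameters of a thrombin trace
#'
#' * `MaxL` (nM): maximum of the trace; `TMaxL` (s): first time attaining it.
#' * `MaxR` (nM/s): maximum forward-difference rate on the reporting grid;
#'   `TMaxR` (s): left endpoint of the maximizing interval (ties broken
#'   earliest).
#' * `AUC` (uM*s): trapezoidal integral over the full reporting window.
#' * `CT` (s): clot time, the first time the trace reaches the 10 nM
#'   threshold; by default linearly interpolated within the first upward
#'   crossing, `NA` if the threshold is never reached.
#'
#' @param trace a `thrombin_timecourse`, or a numeric nM trace on a uniform
#'   grid (then `times` gives the grid, default 1 s from 0).
#' @param times time grid in seconds (ignored when `trace` is a time course).
#' @param ct_threshold_nM clot-time threshold (default 10 nM).
#' @param ct_method `"interpolate"` (default) or `"grid"` (first grid point
#'   at or above threshold).
#' @return a `thrombin_metrics` list with fields `MaxL_nM`, `TMaxL_s`,
#'   `MaxR_nM_per_s`, `TMaxR_s`, `AUC_uM_s`, `CT_s` (`NA` = not reached).
#' @examples
#' m <- compute_metrics(0.05 * (0:1200), times = 0:1200)
#' m$CT_s    # 200
#' m$AUC_uM_s
#' @export
compute_metrics <- function(trace, times = NULL, ct_threshold_nM = 10,
                            ct_method = c("interpolate", "grid")) {
  if (inherits(trace, "thrombin_timecourse")) {
    times <- trace$time
    ct_threshold_nM <- trace$config$ct_threshold_nM
    ct_method <- trace$config$ct_method
    trace <- trace$thrombin
  }
  ct_method <- match.arg(ct_method)
  if (length(trace) == 0L) stop("empty trace")
  if (is.null(times)) times <- seq_along(trace) - 1
  if (length(times) != length(trace)) stop("times/trace length mismatch")
  if (any(!is.finite(trace))) stop("non-finite values in trace")
  dt <- diff(times)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("non-uniform time grid")

  imax <- which.max(trace)
  MaxL <- trace[imax]
  TMaxL <- times[imax]
  if (length(trace) > 1L) {
    rates <- diff(trace) / dt
    MaxR <- max(rates)
    # earliest-tie rule, robust to float noise in differenced equal slopes
    ir <- which(rates >= MaxR - 1e-9 * max(abs(MaxR), 1e-300))[1]
    TMaxR <- times[ir]
    AUC <- sum((trace[-1] + trace[-length(trace)]) / 2 * dt) / 1000
  } else { MaxR <- 0; TMaxR <- times[1]; AUC <- 0 }

  CT <- NA_real_
  thr <- ct_threshold_nM
  if (trace[1] >= thr) CT <- times[1]
  else {
    below <- trace < thr
    cross <- which(below[-length(trace)] & !below[-1])
    if (length(cross)) {
      i <- cross[1]
      CT <- if (ct_method == "grid") times[i + 1]
      else times[i] + (thr - trace[i]) / (trace[i + 1] - trace[i]) * dt[i]
    }
  }
  structure(list(MaxL_nM = MaxL, TMaxL_s = TMaxL, MaxR_nM_per_s = MaxR,
                 TMaxR_s = TMaxR, AUC_uM_s = AUC, CT_s = CT),
            class = "thrombin_metrics")
}

#' @export
print.thrombin_metrics <- function(x, ...) {
  ct <- if (is.na(x$CT_s)) "not reached" else sprintf("%.1f s", x$CT_s)
  cat(sprintf(
    "MaxL %.3g nM @ %g s | MaxR %.3g nM/s @ %g s | AUC %.3g uM*s | CT %s\n",
    x$MaxL_nM, x$TMaxL_s, x$MaxR_nM_per_s, x$TMaxR_s, x$AUC_uM_s, ct))
  invisible(x)
}

#' Does a metric set exceed the control (more procoagulant)?
#'
#' "Exceeds" means strictly greater `MaxL`, `MaxR`, `AUC`, and strictly
#' *shorter* `CT`; a clot time that was never reached cannot exceed.
#'
#' @param metrics,control `thrombin_metrics` computed under identical
#'   configuration.
#' @return named logical vector with entries `CT`, `MaxL`, `MaxR`, `AUC`.
#' @export
exceeds_control <- function(metrics, control) {
  stopifnot(inherits(metrics, "thrombin_metrics"),
            inherits(control, "thrombin_metrics"))
  c(CT = !is.na(metrics$CT_s) &&
        (is.na(control$CT_s) || metrics$CT_s < control$CT_s),
    MaxL = metrics$MaxL_nM > control$MaxL_nM,
    MaxR = metrics$MaxR_nM_per_s > control$MaxR_nM_per_s,
    AUC = metrics$AUC_uM_s > control$AUC_uM_s)
}

as_metrics_row <- function(m, subject_id, pathway) {
  data.frame(subject_id = subject_id, pathway = pathway,
             MaxL_nM = m$MaxL_nM, TMaxL_s = m$TMaxL_s,
             MaxR_nM_per_s = m$MaxR_nM_per_s, TMaxR_s = m$TMaxR_s,
             AUC_uM_s = m$AUC_uM_s, CT_s = m$CT_s,
             stringsAsFactors = FALSE)
}
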