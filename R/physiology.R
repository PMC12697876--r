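#' Isosbestic-corrected dF/F
#'
#' Fits the 410 nm control channel onto the 470 nm signal channel by
#' ordinary least squares over the whole recording (`f470 ~ a + b * f410`)
#' and computes `dF/F = (f470 - fit) / fit`. The affine fit absorbs
#' bleaching drift and motion artifacts shared by the two channels. If
#' the control channel is constant (zero variance) the function falls back
#' to a baseline-percentile dF/F (`F0` = 10th percentile of `f470`) with a
#' warning.
#'
#' @param rec a [photometry_recording()].
#' @param baseline_percentile fallback `F0` percentile (0-1) used only
#'   when the control channel is degenerate.
#' @return A list of class `dff_trace`: `t_s`, `dff`, `fit_params`
#'   (intercept/slope or percentile F0), `sample_rate`, `event_times_s`,
#'   `method`.
#' @export
compute_dff <- function(rec, baseline_percentile = 0.1) {
  if (!inherits(rec, "photometry_recording"))
    stop("`rec` must be a photometry_recording", call. = FALSE)
  if (stats::var(rec$f410) > 0) {
    fit <- stats::lm.fit(cbind(1, rec$f410), rec$f470)
    pred <- drop(cbind(1, rec$f410) %*% fit$coefficients)
    dff <- (rec$f470 - pred) / pred
    params <- c(intercept = unname(fit$coefficients[1L]),
                slope = unname(fit$coefficients[2L]))
    method <- "isosbestic_affine"
  } else {
    warning("control channel has zero variance; using baseline-percentile dF/F",
            call. = FALSE)
    f0 <- stats::quantile(rec$f470, baseline_percentile, names = FALSE)
    dff <- (rec$f470 - f0) / f0
    params <- c(F0 = f0)
    method <- "percentile_baseline"
  }
  structure(list(t_s = rec$t_s, dff = dff, fit_params = params,
                 sample_rate = rec$sample_rate,
                 event_times_s = rec$event_times_s, method = method),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples @ %.1f Hz (%s correction)\n",
              length(x$dff), x$sample_rate, x$method))
  invisible(x)
}

#' Peri-event alignment of a dF/F trace
#'
#' Extracts a window around each event, baseline-subtracts each trial by
#' its pre-window mean, and stacks the trials into a matrix (rows =
#' trials). Trials whose window extends beyond the recording are dropped
#' and counted in the `n_dropped` attribute (with a message).
#'
#' @param dff a `dff_trace` (or supply `event_times_s`).
#' @param window_pre_s,window_post_s window extent before/after each
#'   event, in seconds (> 0).
#' @param event_times_s event times; default those stored on the trace.
#' @return Trial x time matrix of class `peri_event`, with attributes
#'   `time_s` (relative time axis), `n_dropped`, `sample_rate`.
#' @export
peri_event <- function(dff, window_pre_s = 2, window_post_s = 5,
                       event_times_s = dff$event_times_s) {
  if (!inherits(dff, "dff_trace")) stop("`dff` must be a dff_trace", call. = FALSE)
  check_scalar_num(window_pre_s, "window_pre_s", positive = TRUE)
  check_scalar_num(window_post_s, "window_post_s", positive = TRUE)
  sr <- dff$sample_rate
  npre <- round(window_pre_s * sr)
  npost <- round(window_post_s * sr)
  n <- length(dff$dff)
  rows <- list(); dropped <- 0L
  for (ev in event_times_s) {
    i0 <- which.min(abs(dff$t_s - ev))
    lo <- i0 - npre; hi <- i0 + npost
    if (lo < 1L || hi > n) { dropped <- dropped + 1L; next }
    seg <- dff$dff[lo:hi]
    rows[[length(rows) + 1L]] <- seg - mean(seg[seq_len(npre)])
  }
  if (dropped > 0L)
    message(dropped, " trial(s) dropped: window extends beyond the recording")
  if (!length(rows)) stop("no usable events within the recording", call. = FALSE)
  m <- do.call(rbind, rows)
  structure(m, time_s = (seq(-npre, npost)) / sr, n_dropped = dropped,
            sample_rate = sr, class = c("peri_event", "matrix", "array"))
}

#' Per-trial area under the peri-event curve
#'
#' Trapezoidal integral of the baseline-subtracted dF/F over a window of
#' relative time, one value per trial. Units: dF/F x seconds.
#'
#' @param peri a [peri_event()] matrix.
#' @param window_s length-2 numeric `c(from, to)` in seconds relative to
#'   the event; default the full post-event range.
#' @return Numeric vector, one AUC per trial.
#' @export
peri_event_auc <- function(peri, window_s = NULL) {
  if (!inherits(peri, "peri_event")) stop("`peri` must be a peri_event matrix", call. = FALSE)
  tt <- attr(peri, "time_s")
  window_s <- window_s %||% c(0, max(tt))
  keep <- which(tt >= window_s[1L] - 1e-12 & tt <= window_s[2L] + 1e-12)
  if (length(keep) < 2L) stop("empty AUC window", call. = FALSE)
  ts <- tt[keep]
  dt <- diff(ts)
  apply(peri[, keep, drop = FALSE], 1L, function(y)
    sum((y[-length(y)] + y[-1L]) / 2 * dt))
}

#' Paired-pulse ratio
#'
#' Ratio of the second evoked peak current to the first, computed on
#' amplitude magnitudes (inward currents at negative holding potentials
#' are rectified upstream).
#'
#' @param peak1,peak2 peak amplitudes (pA, magnitudes); `peak1 > 0`.
#'   Vectorized.
#' @param interstimulus_interval_ms optional ISI annotation
#'   (conventionally 50, 100 or 200 ms), returned alongside.
#' @return Numeric vector of ratios (PPR), or a data frame when the ISI
#'   is supplied.
#' @export
paired_pulse_ratio <- function(peak1, peak2, interstimulus_interval_ms = NULL) {
  if (any(!is.finite(peak1)) || any(peak1 <= 0))
    stop("`peak1` must be positive", call. = FALSE)
  if (length(peak2) != length(peak1))
    stop("`peak1` and `peak2` lengths differ", call. = FALSE)
  r <- abs(peak2) / peak1
  if (is.null(interstimulus_interval_ms)) return(r)
  data.frame(interstimulus_interval_ms =
               rep_len(interstimulus_interval_ms, length(r)),
             ppr = r)
}
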