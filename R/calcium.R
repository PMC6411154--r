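#' deltaF/F0 normalization
#'
#' Converts a raw fluorescence trace to deltaF/F0 with the session baseline
#' F0 estimated as a low percentile of the raw trace (default 10th), which
#' is robust to sparse positive transients.
#'
#' @param trace Raw fluorescence vector (length >= 2).
#' @param f0 Optional known baseline; when `NULL`, estimated from the
#'   trace.
#' @param probs Percentile (in `[0, 1]`) used for the F0 estimate.
#' @return Dimensionless deltaF/F0 vector with attribute `f0`.
#' @export
dff_normalize <- function(trace, f0 = NULL, probs = 0.1) {
  stopifnot(is.numeric(trace), length(trace) >= 2L)
  if (is.null(f0)) f0 <- quantile(trace, probs, names = FALSE)
  if (!is.finite(f0) || f0 <= 0) stopf("F0 estimate must be > 0 (got %g)", f0)
  out <- (trace - f0) / f0
  attr(out, "f0") <- f0
  out
}

#' Zero-phase low-pass filtering
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' ([signal::filtfilt()]), so the filter is zero-phase: transient onsets
#' and peaks are not shifted in time, which keeps decay-time estimates
#' unbiased. DC gain is 1.
#'
#' @param trace Numeric vector.
#' @param fps Sampling rate (samples/s).
#' @param cutoff_hz Cutoff frequency; must satisfy
#'   `0 < cutoff_hz < fps / 2`.
#' @param order Filter order.
#' @return Filtered vector, same length.
#' @export
lowpass <- function(trace, fps, cutoff_hz = 2, order = 4) {
  check_scalar_number(fps, "fps", lower = 0, strict_lower = TRUE)
  if (!(cutoff_hz > 0 && cutoff_hz < fps / 2)) {
    stopf("`cutoff_hz` must lie in (0, fps/2) = (0, %g)", fps / 2)
  }
  bf <- signal::butter(order, cutoff_hz / (fps / 2), type = "low")
  x <- as.numeric(trace)
  n <- length(x)
  # odd-reflection padding absorbs the filter's edge transients, so the
  # returned segment is free of startup artifacts (and DC is exact)
  pad <- min(n - 1, ceiling(10 * fps / cutoff_hz))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
  y[seq(pad + 1, pad + n)]
}

#' Detect calcium events on a normalized trace
#'
#' Events are contiguous excursions of the low-pass-filtered trace above a
#' noise-scaled threshold. The noise SD is estimated robustly (MAD x
#' 1.4826 by default) on the filtered trace so large events do not inflate
#' it; the threshold sits `threshold_sd` SDs above the filtered baseline
#' (its median). Excursion extent uses a lower release threshold
#' (`release_sd` SDs, hysteresis), which prevents a decaying tail from
#' re-crossing the detection threshold and being double counted; excursions
#' separated by fewer than `merge_gap` samples are merged for the same
#' reason. Conversely, one excursion can hold several transients riding on
#' each other's decay tails: an excursion is split wherever two local
#' maxima are separated by a dip of at least `split_sd` noise SDs below the
#' smaller of the two peaks (a prominence criterion), and each sub-segment
#' becomes a candidate event. Per event, the peak amplitude is the maximum
#' of the (unfiltered) deltaF/F0 trace within the event's segment, measured
#' above the trace median; the decay time tau is the time from the filtered
#' peak until the filtered trace first falls below 1/e of the peak (above
#' baseline). Events with `tau <= min_tau_s` are discarded.
#'
#' @param trace deltaF/F0 trace (see [dff_normalize()]).
#' @param fps Sampling rate (samples/s).
#' @param threshold_sd Detection threshold in noise SDs (default 6).
#' @param min_tau_s Minimum decay time in seconds (default 0.5, exclusive).
#' @param cutoff_hz Low-pass cutoff used for detection (default 2).
#' @param release_sd Hysteresis release threshold in noise SDs.
#' @param split_sd Minimum dip depth (noise SDs, below the smaller adjacent
#'   peak) for two local maxima in one excursion to count as separate
#'   events.
#' @param merge_gap Merge excursions separated by fewer than this many
#'   sub-threshold samples.
#' @param sd_method `"mad"` (robust, default) or `"sd"` (plain).
#' @param filtered Optional pre-filtered trace; computed internally when
#'   `NULL`.
#' @return data.frame of events ordered by onset: `onset_idx`, `onset_s`,
#'   `peak_idx`, `peak_s`, `amplitude`, `tau_s`.
#' @export
detect_events <- function(trace, fps, threshold_sd = 6, min_tau_s = 0.5,
                          cutoff_hz = 2, release_sd = 2, split_sd = 6,
                          merge_gap = 2, sd_method = c("mad", "sd"),
                          filtered = NULL) {
  sd_method <- match.arg(sd_method)
  stopifnot(is.numeric(trace), length(trace) >= 2L)
  if (release_sd > threshold_sd) stopf("`release_sd` must be <= `threshold_sd`")
  trace <- as.numeric(trace)
  if (is.null(filtered)) filtered <- lowpass(trace, fps, cutoff_hz)
  n <- length(trace)
  empty <- data.frame(onset_idx = integer(), onset_s = numeric(),
                      peak_idx = integer(), peak_s = numeric(),
                      amplitude = numeric(), tau_s = numeric())

  base <- median(filtered)
  noise_sd <- if (sd_method == "mad") mad(filtered) else sd(filtered)
  if (!is.finite(noise_sd) || noise_sd == 0) {
    warning("noise SD estimate is 0; no events detected", call. = FALSE)
    return(empty)
  }
  thr <- base + threshold_sd * noise_sd
  rel <- base + release_sd * noise_sd

  above <- filtered > rel
  # merge excursions separated by short sub-threshold gaps
  r <- rle(above)
  if (merge_gap > 0 && length(r$lengths) > 2L) {
    gap <- !r$values & r$lengths < merge_gap
    inner <- seq_along(gap) > 1L & seq_along(gap) < length(gap)
    r$values[gap & inner] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trace_base <- trace - median(trace)

  ev <- list()
  for (j in which(r$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    if (max(filtered[i1:i2]) <= thr) next  # never reaches detection threshold
    peaks <- split_excursion_peaks(filtered, i1, i2, thr,
                                   split_sd * noise_sd)
    # segment boundaries: the minimum between consecutive accepted peaks
    bounds <- i1 - 1L
    if (length(peaks) > 1L) {
      for (k in seq_len(length(peaks) - 1L)) {
        seg <- peaks[k]:peaks[k + 1L]
        bounds <- c(bounds, seg[which.min(filtered[seg])])
      }
    }
    bounds <- c(bounds, i2)
    for (k in seq_along(peaks)) {
      s1 <- bounds[k] + 1L; s2 <- bounds[k + 1L]
      pk <- peaks[k]
      peak_h <- filtered[pk] - base
      below <- which(filtered[pk:n] - base < peak_h / exp(1))
      if (!length(below)) next  # decay unresolved within the session
      tau <- (below[1] - 1L) / fps
      if (tau <= min_tau_s) next
      ev[[length(ev) + 1L]] <- data.frame(
        onset_idx = s1, onset_s = (s1 - 1L) / fps,
        peak_idx = pk, peak_s = (pk - 1L) / fps,
        amplitude = max(trace_base[s1:s2]), tau_s = tau)
    }
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out[order(out$onset_idx), , drop = FALSE]
}

# Accepted peak indices within one supra-threshold excursion: local maxima
# above `thr`, kept only if separated from every already-accepted neighbor
# by a dip at least `min_drop` below the smaller of the two peaks.
split_excursion_peaks <- function(filtered, i1, i2, thr, min_drop) {
  seg <- filtered[i1:i2]
  m <- length(seg)
  if (m < 3L) return(i1 - 1L + which.max(seg))
  is_max <- c(FALSE, seg[2:(m - 1)] > seg[1:(m - 2)] &
                seg[2:(m - 1)] >= seg[3:m], FALSE)
  # end samples can hold the maximum of the excursion
  is_max[1] <- seg[1] >= seg[2]
  is_max[m] <- seg[m] > seg[m - 1]
  cand <- which(is_max & seg > thr)
  if (!length(cand)) return(i1 - 1L + which.max(seg))
  cand <- cand[order(-seg[cand])]
  accepted <- cand[1]
  for (c in cand[-1]) {
    ok <- TRUE
    left <- accepted[accepted < c]
    right <- accepted[accepted > c]
    for (nb in c(if (length(left)) max(left),
                 if (length(right)) min(right))) {
      dip <- min(seg[min(c, nb):max(c, nb)])
      if (!(dip <= min(seg[c], seg[nb]) - min_drop)) ok <- FALSE
    }
    if (ok) accepted <- c(accepted, c)
  }
  i1 - 1L + sort(accepted)
}

#' Event score of a session
#'
#' Cumulative amplitude of the detected supra-threshold events: the sum of
#' event peak amplitudes, 0 for an eventless session.
#'
#' @param events Event data.frame from [detect_events()].
#' @return Non-negative scalar.
#' @export
event_score <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(0)
  sum(events$amplitude)
}

#' Classify a unit by its drug response
#'
#' Sign of the drug-minus-saline event-score difference: `"increasing"`
#' (> 0), `"decreasing"` (< 0), `"unaffected"` (= 0). The comparison is
#' exact by default; `tol` widens the unaffected band for real-valued
#' scores.
#'
#' @param score_saline,score_drug Non-negative event scores.
#' @param tol Half-width of the unaffected band (default 0).
#' @return One of `"increasing"`, `"decreasing"`, `"unaffected"`.
#' @export
classify_unit <- function(score_saline, score_drug, tol = 0) {
  stopifnot(score_saline >= 0, score_drug >= 0, tol >= 0)
  d <- score_drug - score_saline
  if (d > tol) "increasing" else if (d < -tol) "decreasing" else "unaffected"
}

#' Run the calcium event pipeline on paired sessions
#'
#' For every unit: deltaF/F0-normalize each session's raw trace, low-pass
#' filter, detect events, compute the per-session event scores, and
#' classify the unit by the sign of the drug-minus-saline difference.
#'
#' @param traces_saline,traces_drug Numeric matrices of raw fluorescence,
#'   one column per unit (same units, same order, same `fps`).
#' @param fps Sampling rate (samples/s).
#' @param cell_type Optional per-unit cell-type labels (recycled if length
#'   1).
#' @param ... Tuning parameters passed to [detect_events()]
#'   (`threshold_sd`, `min_tau_s`, `cutoff_hz`, ...).
#' @param f0_probs Percentile for the F0 estimate (see [dff_normalize()]).
#' @param tol Unaffected band half-width for [classify_unit()].
#' @return A list of class `calcium_analysis`:
#'   \describe{
#'     \item{summary}{data.frame per unit: `unit`, `cell_type`,
#'       `score_saline`, `score_drug`, `delta_score`, `class`;}
#'     \item{events}{data.frame of all events with `unit` and `session`
#'       columns.}
#'   }
#' @export
#' @examples
#' sim <- simulate_calcium(calcium_sim_config(n_units = 3, seed = 1))
#' res <- calcium_event_analysis(sim$traces$saline, sim$traces$drug,
#'                               fps = sim$fps)
#' res$summary
calcium_event_analysis <- function(traces_saline, traces_drug, fps,
                                   cell_type = NULL, ..., f0_probs = 0.1,
                                   tol = 0) {
  stopifnot(is.matrix(traces_saline), is.matrix(traces_drug),
            ncol(traces_saline) == ncol(traces_drug))
  units <- colnames(traces_saline)
  if (is.null(units)) units <- paste0("unit", seq_len(ncol(traces_saline)))
  if (is.null(cell_type)) cell_type <- NA_character_
  cell_type <- rep_len(as.character(cell_type), length(units))
  sessions <- list(saline = traces_saline, drug = traces_drug)
  all_events <- list()
  scores <- matrix(0, length(units), 2,
                   dimnames = list(units, names(sessions)))
  for (s in names(sessions)) {
    for (u in seq_along(units)) {
      dff <- dff_normalize(sessions[[s]][, u], probs = f0_probs)
      ev <- detect_events(dff, fps, ...)
      scores[u, s] <- event_score(ev)
      if (nrow(ev)) {
        ev$unit <- units[u]
        ev$session <- s
        all_events[[length(all_events) + 1L]] <- ev
      }
    }
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(onset_idx = integer(), onset_s = numeric(),
               peak_idx = integer(), peak_s = numeric(),
               amplitude = numeric(), tau_s = numeric(),
               unit = character(), session = character())
  rownames(events) <- NULL
  summary <- data.frame(
    unit = units, cell_type = cell_type,
    score_saline = scores[, "saline"], score_drug = scores[, "drug"],
    delta_score = scores[, "drug"] - scores[, "saline"],
    stringsAsFactors = FALSE, row.names = NULL)
  summary$class <- mapply(classify_unit, summary$score_saline,
                          summary$score_drug, MoreArgs = list(tol = tol))
  out <- list(summary = summary, events = events)
  class(out) <- "calcium_analysis"
  out
}

#' @export
print.calcium_analysis <- function(x, ...) {
  cat("calcium event analysis:", nrow(x$summary), "units,",
      nrow(x$events), "events\n")
  print(table(x$summary$class))
  invisible(x)
}

#' Cell-type by response-class association
#'
#' Contingency table of unit counts (cell type x class) and its Pearson
#' chi-squared test of independence (no continuity correction). Classes
#' with zero counts across all cell types are dropped before computing the
#' statistic, so df = (rows - 1) x (non-empty cols - 1).
#'
#' @param summary Unit summary data.frame with `cell_type` and `class`
#'   columns (see [calcium_event_analysis()]).
#' @param classes Class levels defining column order.
#' @return A list: `table` (counts), `statistic` (chi-squared), `df`, and
#'   `p_value`.
#' @export
population_association <- function(summary,
                                   classes = c("increasing", "decreasing",
                                               "unaffected")) {
  stopifnot(is.data.frame(summary),
            all(c("cell_type", "class") %in% names(summary)))
  types <- unique(summary$cell_type)
  if (length(types) < 2L) stopf("need >= 2 cell types")
  tab <- table(factor(summary$cell_type, levels = types),
               factor(summary$class, levels = classes))
  if (any(rowSums(tab) == 0L)) {
    stopf("cell type(s) with zero units: %s",
          paste(rownames(tab)[rowSums(tab) == 0L], collapse = ", "))
  }
  used <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(used) < 2L) {
    # every unit in one class: independence holds trivially
    return(list(table = tab, statistic = 0, df = 0, p_value = 1))
  }
  ct <- suppressWarnings(chisq.test(used, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = unname(ct$p.value))
}
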