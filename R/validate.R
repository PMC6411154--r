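#' Match detected events to planted ground truth
#'
#' One-to-one greedy matching of detected events against planted transient
#' onsets: truth entries are visited in onset order and matched to the
#' nearest unmatched detection whose peak lies within `tol_s` seconds of
#' the planted onset (transients rise instantaneously, so the planted
#' onset is the planted peak time).
#'
#' @param events Detected events from [detect_events()] (needs `peak_s`).
#' @param truth_onsets Numeric vector of planted onset times (s).
#' @param tol_s Matching tolerance in seconds.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall` (precision
#'   and recall are `NA` when undefined).
#' @export
match_events <- function(events, truth_onsets, tol_s = 0.5) {
  n_det <- if (is.null(events)) 0L else nrow(events)
  used <- logical(n_det)
  tp <- 0L
  for (o in sort(truth_onsets)) {
    if (n_det == 0L) break
    d <- abs(events$peak_s - o)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- n_det - tp
  fn <- length(truth_onsets) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (n_det > 0L) tp / n_det else NA_real_,
       recall = if (length(truth_onsets) > 0L) tp / length(truth_onsets)
                else NA_real_)
}
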