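#' Configuration for synthetic calcium recordings
#'
#' Describes paired saline/drug miniscope-style sessions: per unit, a raw
#' fluorescence trace sampled at `fps` holding Poisson-counted transients
#' with instantaneous rise and exponential decay, on a constant baseline
#' with Gaussian noise. Amplitudes and noise are expressed in deltaF/F0
#' units; the raw trace is `baseline_f * (1 + signal + noise)`.
#'
#' @param n_units Number of units (> 0).
#' @param fps Sampling rate in samples/s (default 20).
#' @param duration_s Session duration in seconds.
#' @param event_rate Named numeric, mean transient count per unit and
#'   session for the `saline` and `drug` sessions.
#' @param amplitude_mean Mean transient amplitude (deltaF/F0 units).
#' @param amplitude_cv Coefficient of variation of amplitudes; draws are
#'   truncated below at 5% of the mean.
#' @param decay_tau_s Exponential decay constant in seconds (> 0.5).
#' @param noise_sd Gaussian noise SD (deltaF/F0 units, >= 0; 0 gives a
#'   noise-free trace).
#' @param baseline_f Baseline fluorescence (arbitrary units, > 0).
#' @param seed Integer seed.
#' @return An object of class `calcium_sim_config`.
#' @seealso [simulate_calcium()]
#' @export
calcium_sim_config <- function(n_units = 10,
                               fps = 20,
                               duration_s = 60,
                               event_rate = c(saline = 2, drug = 2),
                               amplitude_mean = 0.2,
                               amplitude_cv = 0.1,
                               decay_tau_s = 1,
                               noise_sd = 0.02,
                               baseline_f = 100,
                               seed = 1L) {
  if (!is.numeric(n_units) || n_units < 1 || n_units != trunc(n_units)) {
    stopf("`n_units` must be a positive integer")
  }
  check_scalar_number(fps, "fps", lower = 0, strict_lower = TRUE)
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (duration_s * fps < 2) stopf("need duration_s * fps >= 2 samples")
  if (!setequal(names(event_rate), c("saline", "drug"))) {
    stopf("`event_rate` must be named 'saline' and 'drug'")
  }
  if (any(event_rate < 0)) stopf("event rates must be >= 0")
  check_scalar_number(amplitude_mean, "amplitude_mean",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(amplitude_cv, "amplitude_cv", lower = 0)
  check_scalar_number(decay_tau_s, "decay_tau_s", lower = 0.5,
                      strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(baseline_f, "baseline_f", lower = 0, strict_lower = TRUE)
  cfg <- list(n_units = as.integer(n_units), fps = fps,
              duration_s = duration_s,
              event_rate = event_rate[c("saline", "drug")],
              amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
              decay_tau_s = decay_tau_s, noise_sd = noise_sd,
              baseline_f = baseline_f, seed = as.integer(seed))
  class(cfg) <- "calcium_sim_config"
  cfg
}

#' Simulate paired-session calcium traces with planted transients
#'
#' Per unit and session, transient counts are Poisson with the session's
#' rate; onsets are uniform over `[0, duration_s - 3 * decay_tau_s]`,
#' snapped to the sample grid (so the planted amplitude is attained exactly
#' at the onset sample) with every planted transient completing within the
#' session; amplitudes are
#' Gaussian around `amplitude_mean` (truncated at 5% of the mean). The raw
#' trace is the baseline fluorescence modulated by the transient sum plus
#' Gaussian noise.
#'
#' @param config A [calcium_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{traces}{list of two numeric matrices (`saline`, `drug`), one
#'       column per unit, one row per sample (raw fluorescence).}
#'     \item{time}{time of each sample in seconds.}
#'     \item{fps}{sampling rate.}
#'     \item{truth}{data.frame of planted transients: `unit`, `session`,
#'       `onset_s`, `amplitude`, `tau_s`.}
#'     \item{config}{the config, echoed.}
#'   }
#' @export
#' @examples
#' sim <- simulate_calcium(calcium_sim_config(n_units = 2, seed = 3))
#' dim(sim$traces$saline)
simulate_calcium <- function(config) {
  if (!inherits(config, "calcium_sim_config")) {
    stopf("`config` must be a calcium_sim_config")
  }
  cfg <- config
  n <- floor(cfg$duration_s * cfg$fps)
  t <- (seq_len(n) - 1) / cfg$fps
  onset_max <- max(0, cfg$duration_s - 3 * cfg$decay_tau_s)
  units <- paste0("unit", seq_len(cfg$n_units))
  with_local_seed(cfg$seed, {
    truth <- list()
    traces <- list()
    for (session in c("saline", "drug")) {
      mat <- matrix(0, n, cfg$n_units, dimnames = list(NULL, units))
      for (u in seq_len(cfg$n_units)) {
        k <- rpois(1, cfg$event_rate[[session]])
        sig <- numeric(n)
        if (k > 0) {
          onsets <- sort(floor(runif(k, 0, onset_max) * cfg$fps) / cfg$fps)
          amps <- pmax(rnorm(k, cfg$amplitude_mean,
                             cfg$amplitude_cv * cfg$amplitude_mean),
                       0.05 * cfg$amplitude_mean)
          for (i in seq_len(k)) {
            idx <- t >= onsets[i]
            sig[idx] <- sig[idx] +
              amps[i] * exp(-(t[idx] - onsets[i]) / cfg$decay_tau_s)
          }
          truth[[length(truth) + 1L]] <- data.frame(
            unit = units[u], session = session, onset_s = onsets,
            amplitude = amps, tau_s = cfg$decay_tau_s,
            stringsAsFactors = FALSE)
        }
        noise <- rnorm(n, 0, cfg$noise_sd)
        mat[, u] <- cfg$baseline_f * (1 + sig + noise)
      }
      traces[[session]] <- mat
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(unit = character(), session = character(),
                 onset_s = numeric(), amplitude = numeric(),
                 tau_s = numeric(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(traces = traces, time = t, fps = cfg$fps, truth = truth,
         config = cfg)
  })
}
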