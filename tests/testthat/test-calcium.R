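# Calcium event pipeline: normalization, filtering, detection, scoring,
# classification, population association.

make_dff_trace <- function(onsets_s, amps, tau = 1, fps = 20, dur = 60,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(dur * fps) - 1) / fps
  sig <- numeric(length(t))
  for (i in seq_along(onsets_s)) {
    idx <- t >= onsets_s[i]
    sig[idx] <- sig[idx] + amps[i] * exp(-(t[idx] - onsets_s[i]) / tau)
  }
  sig + rnorm(length(t), 0, noise_sd)
}

test_that("deltaF/F0 normalization has the declared fixed points", {
  expect_equal(dff_normalize(rep(5, 10), f0 = 5), rep(0, 10),
               ignore_attr = TRUE)
  expect_equal(as.numeric(dff_normalize(c(5, 10), f0 = 5)), c(0, 1))
  expect_error(dff_normalize(c(-3, -2, -1)), "F0")
})

test_that("the percentile F0 estimate recovers the simulated baseline", {
  cfg <- calcium_sim_config(n_units = 1, event_rate = c(saline = 0, drug = 0),
                            noise_sd = 0.02, seed = 7)
  sim <- simulate_calcium(cfg)
  trace <- sim$traces$saline[, 1]
  f0 <- attr(dff_normalize(trace), "f0")
  # 10th percentile of Gaussian noise around the baseline: the estimate
  # targets baseline * (1 + qnorm(0.1) * noise_sd); allow 4 asymptotic SEs
  target <- cfg$baseline_f * (1 + qnorm(0.1) * cfg$noise_sd)
  n <- length(trace)
  se <- cfg$baseline_f * cfg$noise_sd *
    sqrt(0.1 * 0.9 / n) / dnorm(qnorm(0.1))
  expect_lt(abs(f0 - target), 4 * se)
})

test_that("the low-pass filter preserves DC and attenuates the stop band", {
  fps <- 20
  const <- rep(3.5, 200)
  expect_equal(lowpass(const, fps), const, tolerance = 1e-9)
  t <- (0:1199) / fps
  hi <- sin(2 * pi * 9 * t)
  lo <- sin(2 * pi * 0.1 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(lowpass(hi, fps)) / rms(hi), 0.05)
  expect_gt(rms(lowpass(lo, fps)) / rms(lo), 0.98)
  expect_error(lowpass(const, fps, cutoff_hz = 10), "fps/2")
  expect_error(lowpass(const, fps, cutoff_hz = 0), "fps/2")
})

test_that("a flat trace yields no events and a warning", {
  expect_warning(ev <- detect_events(rep(0, 100), fps = 20), "noise SD")
  expect_equal(nrow(ev), 0)
})

test_that("a noiseless planted transient is recovered exactly", {
  trace <- make_dff_trace(10, 1, tau = 1)
  # plain SD keeps the threshold finite on a noise-free trace
  ev <- detect_events(trace, fps = 20, sd_method = "sd")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 1, tolerance = 1e-9)
  expect_lt(abs(ev$tau_s - 1), 0.1)
  expect_lt(abs(ev$peak_s - 10), 0.25)
})

test_that("a noisy planted transient is recovered within noise tolerance", {
  noise_sd <- 0.02
  trace <- make_dff_trace(20, 0.2, tau = 1, noise_sd = noise_sd, seed = 5)
  ev <- detect_events(trace, fps = 20)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude - 0.2), 0.05 * 0.2 + 3 * noise_sd)
  expect_lt(abs(ev$tau_s - 1), 0.2)
})

test_that("fast transients fail the decay-time gate", {
  trace <- make_dff_trace(10, 1, tau = 0.2)
  ev <- detect_events(trace, fps = 20, sd_method = "sd")
  expect_equal(nrow(ev), 0)
  # the same transient passes once the gate is relaxed below its
  # filter-broadened decay time
  ev2 <- detect_events(trace, fps = 20, sd_method = "sd", min_tau_s = 0.05)
  expect_equal(nrow(ev2), 1)
})

test_that("event count is non-increasing in the detection threshold", {
  trace <- make_dff_trace(c(5, 15, 30, 45), c(0.1, 0.2, 0.3, 0.4),
                          noise_sd = 0.02, seed = 3)
  counts <- vapply(c(2, 4, 6, 8, 12, 20), function(th) {
    nrow(detect_events(trace, fps = 20, threshold_sd = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adding a supra-threshold transient never lowers the event score", {
  for (s in 1:10) {
    base <- make_dff_trace(c(10, 40), c(0.2, 0.25), noise_sd = 0.02,
                           seed = s)
    extra <- make_dff_trace(25, 0.3, noise_sd = 0)
    s0 <- event_score(detect_events(base, fps = 20))
    s1 <- event_score(detect_events(base + extra, fps = 20))
    expect_gte(s1, s0)
  }
})

test_that("event scores sum peak amplitudes", {
  expect_equal(event_score(NULL), 0)
  expect_equal(event_score(data.frame(amplitude = numeric())), 0)
  expect_equal(event_score(data.frame(amplitude = c(0.5, 1.5))), 2.0)
})

test_that("units classify by the sign of the score difference", {
  expect_equal(classify_unit(5, 3), "decreasing")
  expect_equal(classify_unit(0, 0), "unaffected")
  expect_equal(classify_unit(0, 0.2), "increasing")
  expect_equal(classify_unit(1, 1.05, tol = 0.1), "unaffected")
})

test_that("the paired-session pipeline is deterministic and self-consistent", {
  sim <- simulate_calcium(calcium_sim_config(n_units = 4, seed = 6))
  r1 <- calcium_event_analysis(sim$traces$saline, sim$traces$drug,
                               fps = sim$fps)
  r2 <- calcium_event_analysis(sim$traces$saline, sim$traces$drug,
                               fps = sim$fps)
  expect_identical(r1, r2)
  expect_equal(r1$summary$delta_score,
               r1$summary$score_drug - r1$summary$score_saline)
  # class always matches the sign of delta
  cls <- ifelse(r1$summary$delta_score > 0, "increasing",
                ifelse(r1$summary$delta_score < 0, "decreasing",
                       "unaffected"))
  expect_equal(r1$summary$class, cls)
})

test_that("population association reproduces hand-computed chi-squared values", {
  su <- data.frame(cell_type = rep(c("SST", "PKCd"), each = 10),
                   class = rep(c("increasing", "decreasing"), each = 10))
  res <- population_association(su)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  # identical row profiles: independence, statistic 0
  su2 <- data.frame(cell_type = rep(c("SST", "PKCd"), each = 4),
                    class = rep(c("increasing", "decreasing"), 4))
  expect_equal(population_association(su2)$statistic, 0)
  expect_error(population_association(data.frame(cell_type = "SST",
                                                 class = "increasing")),
               ">= 2 cell types")
})

test_that("chi-squared matches the direct-formula oracle on random tables", {
  set.seed(9)
  for (i in 1:20) {
    su <- data.frame(
      cell_type = sample(c("SST", "PKCd", "CEAm"), 60, replace = TRUE),
      class = sample(c("increasing", "decreasing", "unaffected"), 60,
                     replace = TRUE))
    res <- population_association(su)
    tab <- table(su$cell_type, su$class)
    expect_equal(res$statistic, naive_chisq(tab), tolerance = 1e-9)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
})

test_that("all-zero classes are dropped before the association test", {
  su <- data.frame(cell_type = rep(c("SST", "PKCd"), each = 6),
                   class = rep(c("increasing", "decreasing"), 6))
  res <- population_association(su)
  expect_equal(dim(res$table), c(2L, 3L))  # unaffected kept in the table
  expect_equal(res$df, 1)                  # but not in the statistic
})
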