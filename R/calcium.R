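# Pre/post-treatment calcium trace analysis (chemogenetic stimulation
# assay).  Traces are background-subtracted ROI intensities per frame; the
# pre-treatment average serves as F0 for the post-treatment response.

#' Baseline activity as dF/F_avg
#'
#' `(F - mean(F)) / mean(F)` on the background-subtracted trace.
#'
#' @param trace ROI intensity per frame.
#' @param background scalar or per-frame background to subtract (default 0,
#'   i.e. already subtracted).
#' @return dF/F_avg trace (mean exactly 0).
#' @export
baseline_activity <- function(trace, background = 0) {
  f <- trace - background
  m <- mean(f)
  if (m <= 0) stop("mean background-subtracted intensity must be positive")
  (f - m) / m
}

#' Post-treatment response relative to the pre-treatment baseline
#'
#' `response(t) = (F_post(t) - f0_pre) / f0_pre` with `f0_pre` the mean of
#' the background-subtracted pre-treatment trace.
#'
#' @param pre_trace,post_trace ROI intensities per frame.
#' @param background scalar or per-frame background for each trace.
#' @return list of class `treatment_response`: `response` trace,
#'   `f0_pre`, `mean_response`, `peak_response`.
#' @export
treatment_response <- function(pre_trace, post_trace, background = 0) {
  pre <- pre_trace - background
  post <- post_trace - background
  f0 <- mean(pre)
  if (f0 <= 0) stop("pre-treatment baseline must be positive after background subtraction")
  resp <- (post - f0) / f0
  structure(list(response = resp, f0_pre = f0,
                 mean_response = mean(resp), peak_response = max(resp)),
            class = "treatment_response")
}

#' Simulate a calcium trace with Poisson-timed transients
#'
#' Helper for property tests and the stimulated-versus-baseline comparison:
#' baseline level plus exponentially decaying transients at a given rate,
#' with Gaussian noise.
#'
#' @param n_frames trace length.
#' @param rate_per_min transient rate.
#' @param frame_interval s/frame.
#' @param baseline resting intensity.
#' @param transient_amp amplitude of each transient (fraction of baseline).
#' @param decay_s transient decay constant (s).
#' @param noise_sd Gaussian noise SD.
#' @return numeric trace.
#' @export
simulate_calcium_trace <- function(n_frames = 180, rate_per_min = 2,
                                   frame_interval = 1, baseline = 100,
                                   transient_amp = 0.8, decay_s = 3,
                                   noise_sd = 2) {
  tt <- (seq_len(n_frames) - 1) * frame_interval
  n_ev <- stats::rpois(1, rate_per_min * n_frames * frame_interval / 60)
  f <- rep(baseline, n_frames)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, max(tt)))
    for (o in onsets) {
      add <- ifelse(tt >= o, transient_amp * baseline * exp(-(tt - o) / decay_s), 0)
      f <- f + add
    }
  }
  pmax(f + stats::rnorm(n_frames, 0, noise_sd), 0)
}
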