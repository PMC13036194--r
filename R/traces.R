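# GCaMP6s-like fluorescence trace synthesis.

#' Calcium transient kernel
#'
#' Difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s by default,
#' GCaMP6s-like), sampled at the configured frame rate, normalized to unit
#' peak, truncated where the tail falls below 1e-3 of the peak.
#'
#' @param config A \code{\link{generator_config}}.
#' @return Numeric vector of kernel samples (first sample at event onset).
#' @export
calcium_kernel <- function(config) {
  dt <- 1 / config$frame_rate
  t_max <- config$kernel_decay_s * 8
  t <- seq(0, t_max, by = dt)
  k <- exp(-t / config$kernel_decay_s) - exp(-t / config$kernel_rise_s)
  k <- k / max(k)
  k[seq_len(max(which(k > 1e-3)))]
}

#' Synthesize a session's fluorescence trace matrix
#'
#' Each cell's trace is Gaussian noise around a zero baseline (traces emulate
#' background-scaled output of constrained matrix factorization, so dF rather
#' than dF/F is the downstream response measure) plus calcium transients: a
#' Poisson event train whose rate during each trial's 5-s lick window scales
#' linearly with the cell's gain for that trial's stimulus
#' (\code{event_rate_hz} events/s at unit gain), convolved with the
#' difference-of-exponentials kernel. The lick window opens at the trial's
#' first lick, or at trial onset for lick-less trials. A per-cell lognormal
#' day jitter models day-to-day response variability.
#'
#' @param trials Trial table.
#' @param licks Lick events (\code{trial_id}, \code{lick_time_s}).
#' @param gains Gain matrix, cells x stimuli, for this day.
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed.
#' @return Matrix cells x frames of fluorescence values.
#' @export
synthesize_traces <- function(trials, licks, gains, config,
                              seed = config$seed) {
  set.seed(seed)
  n_cells <- nrow(gains)
  fr <- config$frame_rate
  n_frames <- ceiling(session_duration_s(trials, config) * fr)
  kern <- calcium_kernel(config)
  traces <- matrix(rnorm(n_cells * n_frames, 0, config$noise_sd),
                   nrow = n_cells)
  jitter <- if (config$day_gain_jitter_sd > 0) {
    rlnorm(n_cells, 0, config$day_gain_jitter_sd)
  } else rep(1, n_cells)

  for (i in seq_len(nrow(trials))) {
    stim <- trials$stimulus[i]
    g_stim <- ifelse(stim == "NaCl-Force", config$cs_label, stim)
    if (!g_stim %in% colnames(gains))
      stop("no gains defined for stimulus: ", g_stim)
    lt <- licks$lick_time_s[licks$trial_id == trials$trial_id[i]]
    win_start <- if (length(lt)) min(lt) else trials$onset_s[i]
    rate <- config$event_rate_hz * gains[, g_stim] * jitter /
      config$response_gain_mean
    n_ev <- rpois(n_cells, rate * config$trial_s)
    cells <- which(n_ev > 0)
    for (cc in cells) {
      ev_t <- win_start + runif(n_ev[cc], 0, config$trial_s)
      ev_f <- floor(ev_t * fr) + 1L
      for (f0 in ev_f) {
        idx <- f0:min(f0 + length(kern) - 1L, n_frames)
        traces[cc, idx] <- traces[cc, idx] +
          config$event_amplitude * kern[seq_along(idx)]
      }
    }
  }
  rownames(traces) <- rownames(gains)
  traces
}
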