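# Lick behaviour simulation.

# Effective palatability score of a stimulus for one group on one day.
# CTA animals show a reduced CS score on post-conditioning days, scaled by
# the day's re-tuning strength (so extinction recovery tracks behaviour);
# NaCl-Force trials inherit the CS score.
effective_score <- function(stimulus, group, day, config) {
  lab <- ifelse(stimulus == "NaCl-Force", config$cs_label, stimulus)
  sc <- config$palatability_scores[lab]
  if (any(is.na(sc)))
    stop("missing palatability score for: ",
         paste(unique(lab[is.na(sc)]), collapse = ", "))
  if (group == "cta") {
    s <- retune_strength(config, day)
    if (s > 0) {
      is_cs <- lab == config$cs_label
      sc[is_cs] <- sc[is_cs] - s * (sc[is_cs] - config$cs_post_score)
    }
  }
  unname(sc)
}

#' Simulate per-trial lick events
#'
#' Draws per-trial lick counts from a negative binomial centred on each
#' stimulus's palatability score (mean licks per 5-s trial; the CS score is
#' reduced post-conditioning in the CTA group), then lays timestamps on a
#' jittered lick rhythm (default 8 Hz) starting shortly after trial onset.
#' Counts are capped at the number of rhythm cycles that fit in the trial.
#' Conditioning sessions are handled by \code{\link{simulate_conditioning_licks}}.
#'
#' @param trials Trial table from \code{\link{build_schedule}} (non-conditioning).
#' @param config A \code{\link{generator_config}}.
#' @param group \code{"control"} or \code{"cta"}.
#' @param day Day label (determines post-conditioning CS reduction).
#' @param seed Integer seed.
#' @return A data.frame with columns \code{trial_id}, \code{lick_time_s}
#'   (seconds, session clock); trials with zero licks contribute no rows.
#' @export
simulate_licks <- function(trials, config, group = "control",
                           day = "pretest1", seed = config$seed) {
  set.seed(seed)
  scores <- effective_score(trials$stimulus, group, day, config)
  max_licks <- floor(config$trial_s * config$lick_rate_hz)
  counts <- rnbinom(nrow(trials), size = config$lick_dispersion, mu = scores)
  counts[scores == 0] <- 0L
  counts <- pmin(counts, max_licks)
  period <- 1 / config$lick_rate_hz
  out <- lapply(seq_len(nrow(trials)), function(i) {
    n <- counts[i]
    if (n == 0L) return(NULL)
    latency <- runif(1, 0.05, 0.25)
    t <- trials$onset_s[i] + latency + (seq_len(n) - 1L) * period +
      runif(n, -0.3 * period, 0.3 * period)
    t <- sort(pmin(pmax(t, trials$onset_s[i]),
                   trials$onset_s[i] + config$trial_s - 1e-3))
    data.frame(trial_id = trials$trial_id[i], lick_time_s = t)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(trial_id = integer(), lick_time_s = numeric())
  rownames(out) <- NULL
  out
}

#' Simulate the conditioning-session lick record
#'
#' The conditioning session is a single access period truncated at the first
#' of \code{conditioning_cap_licks} licks (default 1,000) or
#' \code{conditioning_cap_min} minutes (default 20). Both groups lick avidly
#' in the first minute; thereafter control animals sustain a high rate while
#' CTA animals (ingesting LiCl) slow down with an exponentially decaying
#' rate, so most never reach the lick cap.
#'
#' @param config A \code{\link{generator_config}}.
#' @param group \code{"control"} or \code{"cta"}.
#' @param seed Integer seed.
#' @param onset_s Access-period start time (session clock).
#' @return data.frame(trial_id = 1, lick_time_s) of lick timestamps.
#' @export
simulate_conditioning_licks <- function(config, group, seed = config$seed,
                                        onset_s = config$session_start_s) {
  set.seed(seed)
  cap_s <- config$conditioning_cap_min * 60
  base_rate <- config$lick_rate_hz
  sustained <- if (group == "control") runif(1, 0.6, 0.9) else NA
  tau <- if (group == "cta") rlnorm(1, log(55), 0.35) else NA
  # piecewise activity: full rate for the first minute, then group-specific
  sec <- seq_len(ceiling(cap_s)) - 1L
  act <- ifelse(sec < 60, 1,
                if (group == "control") sustained else exp(-(sec - 60) / tau))
  n_per_s <- rpois(length(sec), base_rate * act)
  times <- unlist(lapply(which(n_per_s > 0), function(i) {
    sort(runif(n_per_s[i], sec[i], sec[i] + 1))
  }), use.names = FALSE)
  times <- times[times < cap_s]
  if (length(times) > config$conditioning_cap_licks)
    times <- times[seq_len(config$conditioning_cap_licks)]
  data.frame(trial_id = rep(1L, length(times)),
             lick_time_s = onset_s + times)
}
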