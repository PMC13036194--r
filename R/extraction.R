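# Trial-aligned dF extraction, responsiveness classification, tracked-cell
# filtering and per-animal response summaries.

#' Lick-anchored analysis windows for one trial
#'
#' The response window is the 5 s (\code{window_s}) from the trial's first
#' lick; the baseline window is the 5 s immediately before it. Trials without
#' licks anchor both windows to trial (shutter) onset instead — post-CTA
#' animals may refuse to lick the CS, and those trials must not vanish from
#' analysis. Frames are 0-based and windows half-open \code{[start, end)};
#' times are converted by \code{floor(t * frame_rate)}.
#'
#' @param onset_s Trial onset, seconds.
#' @param lick_times_s Lick timestamps of this trial (may be empty).
#' @param frame_rate Frames per second.
#' @param window_s Window length in seconds (default 5).
#' @param n_frames Total frames in the recording (for bounds checking).
#' @return List: \code{baseline} and \code{response} integer frame spans
#'   \code{c(start, end)} (0-based, half-open), \code{anchor}
#'   (\code{"lick"} or \code{"onset"}), \code{ok} (FALSE if the windows fall
#'   outside the recording).
#' @export
#' @examples
#' align_trial_window(95, 100.0, 10)$baseline  # c(950, 1000)
align_trial_window <- function(onset_s, lick_times_s, frame_rate,
                               window_s = 5, n_frames = Inf) {
  anchor <- if (length(lick_times_s) > 0) "lick" else "onset"
  t0 <- if (anchor == "lick") min(lick_times_s) else onset_s
  f0 <- floor(t0 * frame_rate)
  w <- round(window_s * frame_rate)
  baseline <- c(f0 - w, f0)
  response <- c(f0, f0 + w)
  ok <- baseline[1] >= 0 && response[2] <= n_frames
  list(baseline = baseline, response = response, anchor = anchor, ok = ok)
}

#' Compute dF statistics for one trace row and window pair
#'
#' \code{delta_plus} = max of the response window minus the mean of the
#' baseline window; \code{delta_minus} = min of the response window minus
#' the baseline mean; \code{baseline_sd} = sample SD of the baseline frames,
#' floored at \code{sd_floor} (protects noiseless synthetic traces). dF, not
#' dF/F: the traces are already background-scaled.
#'
#' @param trace Numeric vector, one cell's full-session trace.
#' @param baseline,response 0-based half-open frame spans.
#' @param sd_floor Lower bound for the baseline SD.
#' @return Named numeric: \code{delta_plus}, \code{delta_minus},
#'   \code{baseline_sd}.
#' @export
compute_delta <- function(trace, baseline, response, sd_floor = 0) {
  b <- trace[(baseline[1] + 1L):baseline[2]]
  r <- trace[(response[1] + 1L):response[2]]
  if (anyNA(b) || anyNA(r)) stop("NaN in analysis window")
  mb <- mean(b)
  c(delta_plus = max(r) - mb, delta_minus = min(r) - mb,
    baseline_sd = max(sd(b), sd_floor))
}

#' Classify a response as excited, suppressed or none
#'
#' A response is excited if \code{delta_plus >= 3 * baseline_sd} and
#' suppressed if \code{delta_minus <= -3 * baseline_sd} (inclusive
#' thresholds, "at least a +/- 3.0 SD change"). If both thresholds are met
#' the excited call wins; such dual-threshold cases are counted via the
#' \code{"both"} attribute by callers that log them.
#'
#' @param delta_plus,delta_minus,baseline_sd Values from
#'   \code{\link{compute_delta}}; vectorized.
#' @param threshold SD multiple (default 3).
#' @return Character vector in \code{c("excited", "suppressed", "none")}.
#' @export
classify_response <- function(delta_plus, delta_minus, baseline_sd,
                              threshold = 3) {
  exc <- delta_plus >= threshold * baseline_sd
  sup <- delta_minus <= -threshold * baseline_sd
  ifelse(exc, "excited", ifelse(sup, "suppressed", "none"))
}

#' Extract the per-trial response table of one session
#'
#' Applies \code{\link{align_trial_window}} / \code{\link{compute_delta}} /
#' \code{\link{classify_response}} to every cell x trial. The baseline SD
#' floor is \code{1e-6} times the trace dynamic range. Trials whose windows
#' fall outside the recording are excluded (count reported via the
#' \code{"excluded_trials"} attribute); dual-threshold responses are counted
#' in \code{"dual_threshold"}.
#'
#' @param session A session record (see \code{\link{generate_cohort}}).
#' @param window_s Analysis window length, seconds.
#' @param baseline_scope \code{"per_trial"} (default; SD from each trial's
#'   own baseline window) or \code{"session"} (SD pooled over all baseline
#'   windows of the session, per cell).
#' @return data.frame: \code{animal_id}, \code{group}, \code{day},
#'   \code{cell_id}, \code{trial_id}, \code{stimulus}, \code{delta_plus},
#'   \code{delta_minus}, \code{baseline_sd}, \code{class}, \code{anchor}.
#' @export
extract_responses <- function(session, window_s = 5,
                              baseline_scope = c("per_trial", "session")) {
  baseline_scope <- match.arg(baseline_scope)
  traces <- session$traces
  if (is.null(traces)) stop("session has no traces: ", session$animal_id,
                            " ", session$day)
  n_frames <- ncol(traces)
  fr <- session$frame_rate
  rng <- diff(range(traces))
  sd_floor <- 1e-6 * max(rng, 1e-12)
  trials <- session$trials
  rows <- vector("list", nrow(trials))
  excluded <- 0L
  for (i in seq_len(nrow(trials))) {
    lt <- session$licks$lick_time_s[session$licks$trial_id ==
                                      trials$trial_id[i]]
    w <- align_trial_window(trials$onset_s[i], lt, fr, window_s, n_frames)
    if (!w$ok) { excluded <- excluded + 1L; next }
    b <- traces[, (w$baseline[1] + 1L):w$baseline[2], drop = FALSE]
    r <- traces[, (w$response[1] + 1L):w$response[2], drop = FALSE]
    mb <- rowMeans(b)
    bsd <- pmax(apply(b, 1L, sd), sd_floor)
    rows[[i]] <- data.frame(
      animal_id = session$animal_id, group = session$group,
      day = session$day, cell_id = session$global_cell_ids,
      trial_id = trials$trial_id[i], stimulus = trials$stimulus[i],
      delta_plus = apply(r, 1L, max) - mb,
      delta_minus = apply(r, 1L, min) - mb,
      baseline_sd = bsd, anchor = w$anchor,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (baseline_scope == "session" && !is.null(out)) {
    pooled <- tapply(out$baseline_sd, out$cell_id,
                     function(x) sqrt(mean(x^2)))
    out$baseline_sd <- unname(pooled[out$cell_id])
  }
  dual <- sum(out$delta_plus >= 3 * out$baseline_sd &
                out$delta_minus <= -3 * out$baseline_sd)
  out$class <- classify_response(out$delta_plus, out$delta_minus,
                                 out$baseline_sd)
  rownames(out) <- NULL
  attr(out, "excluded_trials") <- excluded
  attr(out, "dual_threshold") <- dual
  out
}

#' Restrict a cohort to cells tracked on all imaging days
#'
#' Keeps, per animal, only the global cell IDs present in every imaging
#' session of that animal (the cross-day registration criterion). Animals
#' with zero tracked cells are dropped from cell-level analyses with a
#' warning.
#'
#' @param cohort A \code{taste_cohort}.
#' @return The cohort with traces and cell-ID lists subset to tracked cells;
#'   the \code{"tracked_counts"} attribute maps animal to retained count.
#' @export
filter_tracked <- function(cohort) {
  imaging <- Filter(function(s) s$day_kind != "conditioning",
                    cohort$sessions)
  animals <- unique(vapply(imaging, `[[`, "", "animal_id"))
  tracked <- list()
  for (aid in animals) {
    ids <- lapply(Filter(function(s) s$animal_id == aid, imaging),
                  `[[`, "global_cell_ids")
    tracked[[aid]] <- Reduce(intersect, ids)
    if (length(tracked[[aid]]) == 0L)
      warning("animal ", aid, " has no tracked cells; dropped")
  }
  cohort$sessions <- lapply(cohort$sessions, function(s) {
    if (s$day_kind == "conditioning") return(s)
    keep <- s$global_cell_ids %in% tracked[[s$animal_id]]
    s$global_cell_ids <- s$global_cell_ids[keep]
    if (!is.null(s$traces))
      s$traces <- s$traces[keep, , drop = FALSE]
    s
  })
  attr(cohort, "tracked_counts") <- vapply(tracked, length, 0L)
  cohort
}

#' Per-day averaged responses
#'
#' Averages the per-trial dF values to one response per cell, stimulus and
#' day ("one response value per cell and stimulus on a given day") and
#' classifies each averaged response against 3x the cell's mean baseline SD.
#'
#' @param responses Per-trial response table (\code{\link{extract_responses}}
#'   output, possibly row-bound over sessions).
#' @param threshold SD multiple for the day-level classification.
#' @return data.frame keyed by (\code{animal_id}, \code{group}, \code{day},
#'   \code{cell_id}, \code{stimulus}) with \code{mean_delta} (mean
#'   delta_plus), \code{mean_delta_minus}, \code{mean_baseline_sd},
#'   \code{n_trials}, \code{class}.
#' @export
response_means <- function(responses, threshold = 3) {
  key <- interaction(responses$animal_id, responses$day, responses$cell_id,
                     responses$stimulus, drop = TRUE)
  first <- !duplicated(key)
  out <- responses[first, c("animal_id", "group", "day", "cell_id",
                            "stimulus")]
  out$mean_delta <- as.numeric(tapply(responses$delta_plus, key,
                                      mean)[as.character(key[first])])
  out$mean_delta_minus <- as.numeric(tapply(responses$delta_minus, key,
                                            mean)[as.character(key[first])])
  out$mean_baseline_sd <- as.numeric(tapply(responses$baseline_sd, key,
                                            mean)[as.character(key[first])])
  out$n_trials <- as.integer(tapply(responses$trial_id, key,
                                    length)[as.character(key[first])])
  out$class <- classify_response(out$mean_delta, out$mean_delta_minus,
                                 out$mean_baseline_sd, threshold)
  rownames(out) <- NULL
  out
}

#' Per-animal responsiveness summaries
#'
#' For each animal, day and stimulus: the fraction of tracked cells whose
#' day-averaged response is perturbed (excited or suppressed), the mean
#' magnitude of significantly excited responses and of significantly
#' suppressed responses. An \code{"all"} row per animal/day gives the
#' fraction of cells perturbed by at least one stimulus and magnitudes
#' pooled over all significant cell x stimulus responses. Where no response
#' reaches significance the magnitude is \code{NA}, not zero.
#'
#' @param day_means \code{\link{response_means}} output.
#' @return data.frame: \code{animal_id}, \code{group}, \code{day},
#'   \code{stimulus} (or \code{"all"}), \code{n_cells},
#'   \code{fraction_perturbed}, \code{mean_excited}, \code{mean_suppressed}.
#' @export
summarize_responses <- function(day_means) {
  groups <- split(day_means,
                  interaction(day_means$animal_id, day_means$day,
                              drop = TRUE))
  out <- lapply(groups, function(g) {
    per_stim <- lapply(split(g, g$stimulus), function(gs) {
      data.frame(
        animal_id = gs$animal_id[1], group = gs$group[1], day = gs$day[1],
        stimulus = gs$stimulus[1], n_cells = nrow(gs),
        fraction_perturbed = mean(gs$class != "none"),
        mean_excited = mean_or_na(gs$mean_delta[gs$class == "excited"]),
        mean_suppressed =
          mean_or_na(gs$mean_delta_minus[gs$class == "suppressed"]),
        stringsAsFactors = FALSE)
    })
    cells <- split(g$class != "none", g$cell_id)
    all_row <- data.frame(
      animal_id = g$animal_id[1], group = g$group[1], day = g$day[1],
      stimulus = "all", n_cells = length(cells),
      fraction_perturbed = mean(vapply(cells, any, TRUE)),
      mean_excited = mean_or_na(g$mean_delta[g$class == "excited"]),
      mean_suppressed =
        mean_or_na(g$mean_delta_minus[g$class == "suppressed"]),
      stringsAsFactors = FALSE)
    rbind(do.call(rbind, per_stim), all_row)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

#' Extract and average responses for a whole cohort
#'
#' Convenience wrapper: tracked-cell filtering, per-session extraction on
#' imaging days, row-binding, and day-level averaging.
#'
#' @param cohort A \code{taste_cohort} (with traces).
#' @param ... Passed to \code{\link{extract_responses}}.
#' @return List: \code{trials} (per-trial table), \code{day_means}
#'   (\code{\link{response_means}}), \code{tracked_counts}.
#' @export
cohort_responses <- function(cohort, ...) {
  cohort <- filter_tracked(cohort)
  imaging <- Filter(function(s) !is.null(s$traces), cohort$sessions)
  per_trial <- do.call(rbind, lapply(imaging, extract_responses, ...))
  rownames(per_trial) <- NULL
  list(trials = per_trial, day_means = response_means(per_trial),
       tracked_counts = attr(cohort, "tracked_counts"))
}
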