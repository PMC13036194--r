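# Lickometer analytics.

#' Per-trial lick counts for a cohort
#'
#' Assigns each lick to the trial whose window \code{[onset, onset +
#' trial_s)} contains it; licks falling outside every trial window are
#' dropped and counted in the \code{"dropped_licks"} attribute.
#' Conditioning sessions are excluded (see
#' \code{\link{conditioning_metrics}}).
#'
#' @param cohort A \code{taste_cohort}.
#' @param trial_s Trial duration in seconds.
#' @return data.frame: \code{animal_id}, \code{group}, \code{day},
#'   \code{trial_id}, \code{stimulus}, \code{forced}, \code{licks}.
#' @export
trial_lick_counts <- function(cohort, trial_s = 5) {
  dropped <- 0L
  out <- lapply(Filter(function(s) s$day_kind != "conditioning",
                       cohort$sessions), function(s) {
    tr <- s$trials
    counts <- integer(nrow(tr))
    lt <- s$licks$lick_time_s
    idx <- findInterval(lt, tr$onset_s)
    in_win <- idx >= 1L
    in_win[in_win] <- lt[in_win] < tr$onset_s[idx[in_win]] + trial_s
    dropped <<- dropped + sum(!in_win)
    tab <- table(factor(idx[in_win], levels = seq_len(nrow(tr))))
    data.frame(animal_id = s$animal_id, group = s$group, day = s$day,
               trial_id = tr$trial_id, stimulus = tr$stimulus,
               forced = tr$forced, licks = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "dropped_licks") <- dropped
  out
}

#' Per-stimulus lick summaries
#'
#' Mean licks per trial for each animal, day and stimulus. Forced NaCl
#' trials carry the distinct \code{"NaCl-Force"} stimulus label, so forced
#' and unforced NaCl are summarized separately on extinction-format days.
#' Stimuli not presented on a day are absent rows, not zeros.
#'
#' @param trial_licks \code{\link{trial_lick_counts}} output.
#' @return data.frame: \code{animal_id}, \code{group}, \code{day},
#'   \code{stimulus}, \code{forced}, \code{mean_licks}, \code{n_trials}.
#' @export
lick_summary <- function(trial_licks) {
  key <- interaction(trial_licks$animal_id, trial_licks$day,
                     trial_licks$stimulus, drop = TRUE)
  first <- !duplicated(key)
  out <- trial_licks[first, c("animal_id", "group", "day", "stimulus",
                              "forced")]
  out$mean_licks <- as.numeric(tapply(trial_licks$licks, key,
                                      mean)[as.character(key[first])])
  out$n_trials <- as.integer(tapply(trial_licks$licks, key,
                                    length)[as.character(key[first])])
  rownames(out) <- NULL
  out
}

#' Conditioning-session drinking metrics
#'
#' First-minute lick count, mean licks per minute over the session window,
#' and the time (minutes) at which the lick cap was reached (\code{NA} if
#' it never was).
#'
#' @param session A conditioning session record.
#' @param cap_licks Lick cap (default 1,000).
#' @param session_min Session window in minutes used for the licks/min rate
#'   (default 20, the access limit).
#' @return data.frame with one row: \code{animal_id}, \code{group},
#'   \code{first_minute_licks}, \code{licks_per_min},
#'   \code{minutes_to_cap}, \code{total_licks}.
#' @export
conditioning_metrics <- function(session, cap_licks = 1000L,
                                 session_min = 20) {
  t0 <- session$trials$onset_s[1L]
  t <- session$licks$lick_time_s - t0
  n <- length(t)
  data.frame(
    animal_id = session$animal_id, group = session$group,
    first_minute_licks = sum(t < 60),
    licks_per_min = n / session_min,
    minutes_to_cap = if (n >= cap_licks) t[cap_licks] / 60 else NA_real_,
    total_licks = n,
    stringsAsFactors = FALSE)
}

#' Per-trial response magnitude vs lick count regression
#'
#' For every taste trial, the mean dF over tracked cells is paired with the
#' trial's lick count; an ordinary-least-squares line (response on licks)
#' is fitted pooled over animals and days of one group. Near-zero R-squared
#' here rules out response strength being a mere reflection of licking
#' amount.
#'
#' @param per_trial Per-trial response table
#'   (\code{\link{cohort_responses}}\code{$trials}).
#' @param trial_licks \code{\link{trial_lick_counts}} output.
#' @param group Group label.
#' @param exclude_stimuli Trials to leave out (default water rinses).
#' @return List: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}, and \code{points} (animal, day, trial, licks, mean dF).
#' @export
response_vs_licks <- function(per_trial, trial_licks, group,
                              exclude_stimuli = "water") {
  rt <- per_trial[per_trial$group == group &
                    !per_trial$stimulus %in% exclude_stimuli, ]
  key <- interaction(rt$animal_id, rt$day, rt$trial_id, drop = TRUE)
  first <- !duplicated(key)
  pts <- rt[first, c("animal_id", "day", "trial_id", "stimulus")]
  pts$mean_delta <- as.numeric(tapply(rt$delta_plus, key,
                                      mean)[as.character(key[first])])
  pts <- merge(pts,
               trial_licks[trial_licks$group == group,
                           c("animal_id", "day", "trial_id", "licks")],
               by = c("animal_id", "day", "trial_id"))
  if (nrow(pts) < 3L) stop("fewer than 3 points")
  if (sd(pts$mean_delta) == 0 || sd(pts$licks) == 0) {
    # degenerate fits: summary.lm's R^2 is 0/0 noise for constant response
    return(list(slope = 0, intercept = mean(pts$mean_delta), r_squared = 0,
                n = nrow(pts), points = pts))
  }
  fit <- suppressWarnings(lm(mean_delta ~ licks, data = pts))
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       n = nrow(pts), points = pts)
}

#' Paired comparison (classical paired t-test with effect size)
#'
#' @param values_pre,values_post Paired numeric vectors (length >= 2).
#' @return List: \code{t}, \code{df}, \code{p}, \code{cohens_d} (of the
#'   differences), \code{mean_diff}, \code{zero_variance} flag (when the
#'   differences have no variance, \code{p} is \code{NA}).
#' @export
paired_comparison <- function(values_pre, values_post) {
  if (length(values_pre) != length(values_post) || length(values_pre) < 2L)
    stop("need paired vectors of equal length >= 2")
  d <- values_post - values_pre
  if (sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1L, p = NA_real_, cohens_d = NA_real_,
                mean_diff = mean(d), zero_variance = TRUE))
  }
  tt <- stats::t.test(values_post, values_pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / sd(d), mean_diff = mean(d),
       zero_variance = FALSE)
}
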