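# Lickometer session schedules.

#' Build the trial table for one session
#'
#' Emits the brief-access lickometer schedule for a session of the given
#' kind. Pretest and posttest sessions present each of the 6 panel stimuli
#' once per block in pseudorandom order, alternating with water rinses, for 2
#' blocks: 12 stimulus trials and 12 water trials. Extinction sessions open
#' with 12 consecutive forced NaCl trials (labelled \code{"NaCl-Force"}, a
#' distinct stimulus in analysis) followed by one randomized block of each
#' taste interleaved with water. The conditioning session is a single access
#' period. Trials last \code{trial_s} seconds with an \code{iti_s} inter-trial
#' interval.
#'
#' @param day_kind One of \code{"pretest"}, \code{"posttest"},
#'   \code{"conditioning"}, \code{"extinction"}.
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed for the pseudorandom block orders.
#' @param n_blocks Number of stimulus blocks for pretest/posttest (default 2).
#' @param conditioning_stimulus Label of the single conditioning tastant
#'   (NaCl for controls, LiCl for the CTA group).
#' @param panel Stimulus labels to schedule (default the config's panel);
#'   allows degenerate panels without relaxing config validation.
#' @return A data.frame with columns \code{trial_id}, \code{stimulus},
#'   \code{onset_s}, \code{block}, \code{forced}.
#' @export
#' @examples
#' sched <- build_schedule("pretest", generator_config(), seed = 1)
#' table(sched$stimulus == "water")
build_schedule <- function(day_kind, config, seed = config$seed,
                           n_blocks = 2L,
                           conditioning_stimulus = "NaCl",
                           panel = names(config$stimulus_panel)) {
  validate_generator_config(config)
  if (!day_kind %in% c("pretest", "posttest", "conditioning", "extinction"))
    stop("unknown day_kind: ", day_kind)
  set.seed(seed)

  if (day_kind == "conditioning") {
    return(data.frame(trial_id = 1L, stimulus = conditioning_stimulus,
                      onset_s = config$session_start_s, block = 1L,
                      forced = TRUE, stringsAsFactors = FALSE))
  }

  if (day_kind %in% c("pretest", "posttest")) {
    stim_seq <- unlist(lapply(seq_len(n_blocks), function(b) sample(panel)))
    blocks <- rep(seq_len(n_blocks), each = length(panel))
    # alternate stimulus / water within each block
    stimulus <- as.vector(rbind(stim_seq, "water"))
    block <- rep(blocks, each = 2L)
    forced <- rep(FALSE, length(stimulus))
  } else { # extinction
    forced_stim <- rep("NaCl-Force", 12L)
    rand_stim <- as.vector(rbind(sample(panel), "water"))
    stimulus <- c(forced_stim, rand_stim)
    block <- c(rep(1L, 12L), rep(2L, length(rand_stim)))
    forced <- c(rep(TRUE, 12L), rep(FALSE, length(rand_stim)))
  }

  n <- length(stimulus)
  data.frame(
    trial_id = seq_len(n),
    stimulus = stimulus,
    onset_s = config$session_start_s +
      (seq_len(n) - 1L) * (config$trial_s + config$iti_s),
    block = block,
    forced = forced,
    stringsAsFactors = FALSE)
}

#' Duration in seconds of a session described by a trial table
#'
#' @param trials Trial table from \code{\link{build_schedule}}.
#' @param config A \code{\link{generator_config}}.
#' @return Scalar seconds, covering the last trial plus one ITI.
#' @export
session_duration_s <- function(trials, config) {
  max(trials$onset_s) + config$trial_s + config$iti_s
}
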