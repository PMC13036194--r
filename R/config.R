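# Generator configuration and deterministic seed substreams.

#' Default taste panel
#'
#' The six-stimulus brief-access panel plus the water rinse. Names are the
#' stimulus labels used throughout the package; values are concentration
#' strings (documentation only, never parsed).
#'
#' @return Named character vector of concentration strings.
#' @export
default_panel <- function() {
  c(sucrose   = "0.5 M",
    NaCl      = "0.3 M",
    citric    = "0.02 M",
    QHCl_high = "0.01 M",
    QHCl_low  = "0.03 mM",
    KCl       = "0.3 M")
}

#' The four basic tastes used for tuning and basic-taste decoding
#'
#' Sucrose, NaCl, citric acid and high-concentration quinine; the low-quinine
#' and KCl stimuli are excluded from 4-taste analyses.
#'
#' @return Character vector of length 4, in the fixed panel order used for
#'   tie-breaking.
#' @export
basic_tastes <- function() c("sucrose", "NaCl", "citric", "QHCl_high")

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration object describing a synthetic CTA
#' experiment: cohort size, session schedule constants, the latent
#' population-coding model (palatability + identity axes), GCaMP6s-like
#' transient kernel, lick behaviour, and the CTA re-tuning manipulation.
#'
#' Defaults describe a desk-scale cohort (4 animals/group x 50 cells,
#' >= 100 pooled cells per group) with strong palatability coding; schedule
#' constants (5-s trials, 60-s ITI, 2 blocks of 6 stimuli alternating with
#' water, 1,000-lick / 20-min conditioning cap) follow the brief-access
#' lickometer paradigm exactly. Animal and cell counts are configurable up to
#' experiment scale (7-8 animals, ~140 tracked cells per animal).
#'
#' @param n_animals_per_group Animals in each of the control and CTA groups.
#' @param n_cells_per_animal Tracked cells per animal (registration is
#'   perfect in synthetic cohorts unless degraded downstream).
#' @param frame_rate Imaging frame rate, frames/s.
#' @param stimulus_panel Named character vector of 6 taste stimuli
#'   (names = labels, values = concentration strings). Must contain exactly
#'   one \code{"NaCl"} (the CS) and one \code{"QHCl_high"} (the aversive
#'   reference).
#' @param palatability_scores Named numeric, mean licks per 5-s trial for
#'   every panel stimulus plus \code{"water"}; nonnegative.
#' @param identity_axes Named numeric, a latent identity coordinate per
#'   stimulus (water included) on an arbitrary 1-D chemical-identity axis.
#' @param accept_midpoint,accept_scale Logistic midpoint and scale (licks)
#'   mapping palatability scores to the latent acceptance coordinate (see
#'   \code{\link{acceptance_value}}).
#' @param tuning_noise_sd SD of the per-cell-per-stimulus lognormal tuning
#'   heterogeneity (0 = perfectly shared acceptance tuning).
#' @param palatability_weight,identity_weight Relative weight of the
#'   acceptance and identity components in each cell's gain.
#' @param aversive_pole_fraction Fraction of cells loading on the rejected
#'   (aversive) pole of the acceptance axis; the rest load on the accepted
#'   pole.
#' @param cell_tuning_sparsity Fraction in [0,1] of tracked cells that are
#'   taste-responsive; the remainder are near-silent on every stimulus.
#' @param response_gain_mean,response_gain_sd Mean and SD (dF units) of the
#'   per-cell gain scale factor.
#' @param identity_width Tuning width (identity-axis units) of the identity
#'   component.
#' @param kernel_rise_s,kernel_decay_s Rise and decay time constants (s) of
#'   the difference-of-exponentials calcium kernel (GCaMP6s-like).
#' @param event_rate_hz Transient event rate (events/s) during the lick
#'   window for a cell at unit gain; rate scales linearly with gain.
#' @param event_amplitude Fluorescence amplitude of a single transient.
#' @param noise_sd Gaussian noise SD added to every trace frame.
#' @param day_gain_jitter_sd SD of the per-cell, per-day lognormal gain
#'   jitter (0 disables day-to-day drift).
#' @param cta_retune_fraction Fraction in [0,1] of Q-best cells that gain CS
#'   sensitivity and of N-best cells that lose it after conditioning (CTA
#'   group only).
#' @param magnitude_preserving If \code{TRUE}, re-tuning conserves the pooled
#'   positive CS gain mass within 1\%, so population response magnitudes are
#'   unchanged by design.
#' @param cs_label,aversive_label Conditioned stimulus and aversive reference
#'   labels; must be panel members.
#' @param cs_post_score Post-conditioning CS palatability (licks/5 s) at full
#'   re-tuning strength, CTA group only.
#' @param lick_dispersion Negative-binomial size parameter of per-trial lick
#'   counts (smaller = more overdispersed).
#' @param lick_rate_hz Licking rhythm frequency, Hz.
#' @param trial_s,iti_s,session_start_s Trial duration, inter-trial interval
#'   and pre-session dead time, seconds.
#' @param conditioning_cap_licks,conditioning_cap_min Conditioning-session
#'   stop rule: whichever of this lick count or elapsed minutes comes first.
#' @param n_extinction_days Number of extra extinction-format test days after
#'   \code{posttest2} (0-2; \code{posttest2} itself always uses the
#'   extinction schedule with 12 forced NaCl trials).
#' @param extinction_recovery If \code{TRUE}, re-tuning strength and the CS
#'   lick deficit ramp back to baseline over the extinction days
#'   (full aversion on posttest1-2, none by the final day).
#' @param seed Integer master seed; expands deterministically into
#'   per-animal, per-day substreams (see \code{\link{substream_seed}}).
#' @return An object of class \code{taste_generator_config} (a validated
#'   named list).
#' @export
#' @examples
#' cfg <- generator_config(n_animals_per_group = 2, n_cells_per_animal = 10)
#' cfg$frame_rate
generator_config <- function(n_animals_per_group = 4L,
                             n_cells_per_animal = 50L,
                             frame_rate = 10,
                             stimulus_panel = default_panel(),
                             palatability_scores = c(
                               sucrose = 26, NaCl = 23, citric = 21,
                               QHCl_high = 4.6, QHCl_low = 24, KCl = 22,
                               water = 24),
                             identity_axes = c(
                               sucrose = 1, NaCl = 2.5, citric = 4,
                               QHCl_high = 5.5, QHCl_low = 5, KCl = 3,
                               water = 0),
                             accept_midpoint = 12,
                             accept_scale = 3,
                             tuning_noise_sd = 0.2,
                             aversive_pole_fraction = 0.3,
                             cell_tuning_sparsity = 0.8,
                             response_gain_mean = 1.0,
                             response_gain_sd = 0.5,
                             palatability_weight = 1.2,
                             identity_weight = 0.45,
                             identity_width = 0.6,
                             kernel_rise_s = 0.2,
                             kernel_decay_s = 1.5,
                             event_rate_hz = 3,
                             event_amplitude = 0.8,
                             noise_sd = 0.1,
                             day_gain_jitter_sd = 0.05,
                             cta_retune_fraction = 0.5,
                             magnitude_preserving = TRUE,
                             cs_label = "NaCl",
                             aversive_label = "QHCl_high",
                             cs_post_score = 5,
                             lick_dispersion = 20,
                             lick_rate_hz = 8,
                             trial_s = 5,
                             iti_s = 60,
                             session_start_s = 60,
                             conditioning_cap_licks = 1000L,
                             conditioning_cap_min = 20,
                             n_extinction_days = 0L,
                             extinction_recovery = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_animals_per_group = as.integer(n_animals_per_group),
    n_cells_per_animal = as.integer(n_cells_per_animal),
    frame_rate = frame_rate,
    stimulus_panel = stimulus_panel,
    palatability_scores = palatability_scores,
    identity_axes = identity_axes,
    accept_midpoint = accept_midpoint,
    accept_scale = accept_scale,
    tuning_noise_sd = tuning_noise_sd,
    aversive_pole_fraction = aversive_pole_fraction,
    cell_tuning_sparsity = cell_tuning_sparsity,
    response_gain_mean = response_gain_mean,
    response_gain_sd = response_gain_sd,
    palatability_weight = palatability_weight,
    identity_weight = identity_weight,
    identity_width = identity_width,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    event_rate_hz = event_rate_hz,
    event_amplitude = event_amplitude,
    noise_sd = noise_sd,
    day_gain_jitter_sd = day_gain_jitter_sd,
    cta_retune_fraction = cta_retune_fraction,
    magnitude_preserving = isTRUE(magnitude_preserving),
    cs_label = cs_label,
    aversive_label = aversive_label,
    cs_post_score = cs_post_score,
    lick_dispersion = lick_dispersion,
    lick_rate_hz = lick_rate_hz,
    trial_s = trial_s,
    iti_s = iti_s,
    session_start_s = session_start_s,
    conditioning_cap_licks = as.integer(conditioning_cap_licks),
    conditioning_cap_min = conditioning_cap_min,
    n_extinction_days = as.integer(n_extinction_days),
    extinction_recovery = isTRUE(extinction_recovery),
    seed = as.integer(seed))
  class(cfg) <- "taste_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "taste_generator_config"))
  if (cfg$n_animals_per_group < 1L || cfg$n_cells_per_animal < 1L)
    stop("cohort sizes must be positive")
  if (!is.numeric(cfg$frame_rate) || cfg$frame_rate <= 0)
    stop("frame_rate must be > 0")
  panel <- names(cfg$stimulus_panel)
  if (length(panel) != length(unique(panel)))
    stop("duplicate stimulus labels in panel")
  if (sum(panel == cfg$cs_label) != 1L)
    stop("panel must contain exactly one CS label (", cfg$cs_label, ")")
  if (sum(panel == cfg$aversive_label) != 1L)
    stop("panel must contain exactly one aversive label (",
         cfg$aversive_label, ")")
  all_stim <- c(panel, "water")
  for (field in c("palatability_scores", "identity_axes")) {
    miss <- setdiff(all_stim, names(cfg[[field]]))
    if (length(miss))
      stop(field, " missing entries for: ", paste(miss, collapse = ", "))
  }
  if (any(cfg$palatability_scores < 0))
    stop("palatability_scores must be nonnegative")
  for (field in c("cell_tuning_sparsity", "cta_retune_fraction",
                  "aversive_pole_fraction")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(field, " must lie in [0, 1]")
  }
  if (cfg$n_extinction_days < 0L || cfg$n_extinction_days > 2L)
    stop("n_extinction_days must be 0, 1 or 2")
  invisible(cfg)
}

#' Day labels of a synthetic experiment
#'
#' @param config A \code{\link{generator_config}}.
#' @return Character vector: 2 pretest days, the conditioning day, and
#'   2 + \code{n_extinction_days} post-test days.
#' @export
cohort_days <- function(config) {
  c("pretest1", "pretest2", "conditioning",
    paste0("posttest", seq_len(2L + config$n_extinction_days)))
}

#' Imaging day labels (all days except conditioning)
#' @inheritParams cohort_days
#' @return Character vector of days carrying trace matrices.
#' @export
imaging_days <- function(config) {
  setdiff(cohort_days(config), "conditioning")
}

day_kind <- function(day) {
  if (day %in% c("pretest1", "pretest2", "posttest1")) {
    if (day == "posttest1") "posttest" else "pretest"
  } else if (day == "conditioning") {
    "conditioning"
  } else {
    "extinction"
  }
}

# Re-tuning strength in [0,1] applied on each post-conditioning day.  Without
# extinction recovery the aversion persists at full strength; with recovery it
# peaks on posttest2 and ramps back to zero by the final extinction day.
retune_strength <- function(config, day) {
  if (!grepl("^posttest", day)) return(0)
  if (!config$extinction_recovery) return(1)
  n_post <- 2L + config$n_extinction_days
  idx <- as.integer(sub("posttest", "", day))
  profile <- switch(as.character(n_post),
                    "2" = c(1, 1),
                    "3" = c(0.85, 1, 0),
                    "4" = c(0.85, 1, 0.5, 0))
  profile[idx]
}

#' Deterministic seed substream derivation
#'
#' Expands a master seed into independent substreams keyed by animal index,
#' day index and purpose, via 32-bit modular mixing. Streams depend only on
#' their own key, so enlarging a cohort never perturbs the data of existing
#' animals or days.
#'
#' @param seed Integer master seed.
#' @param animal Animal index (0 = cohort-level stream).
#' @param day Day index (0 = day-independent stream).
#' @param purpose Small integer separating uses within one animal-day.
#' @return A positive integer < 2^31 suitable for \code{set.seed}.
#' @export
substream_seed <- function(seed, animal = 0L, day = 0L, purpose = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 %% m
  x <- (x + as.numeric(animal) * 69621 + as.numeric(day) * 16807 +
          as.numeric(purpose) * 7919) %% m
  as.integer((x * 48271) %% m) + 1L
}
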