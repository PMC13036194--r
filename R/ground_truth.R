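# Latent population-coding model: per-cell stimulus gains, stimulus-best
# ground-truth labels, and the CTA re-tuning manipulation.

unit_labels <- function() {
  c(sucrose = "S-Unit", NaCl = "N-Unit", citric = "C-Unit",
    QHCl_high = "Q-Unit")
}

# argmax over the 4 basic tastes with fixed panel-order tie-break
best_of_basic <- function(gains) {
  bt <- basic_tastes()
  sub <- gains[, bt, drop = FALSE]
  idx <- apply(sub, 1L, which.max) # which.max = first max, fixed-order ties
  unname(unit_labels()[bt[idx]])
}

#' Acceptance value of each stimulus
#'
#' Logistic map from mean licks per trial to an acceptance coordinate in
#' (0, 1): readily consumed stimuli sit near 1, the avoided high-quinine
#' stimulus near 0. The near-binary pattern (licked vs not licked) is the
#' dominant axis the population codes.
#'
#' @param scores Named numeric, mean licks per 5-s trial.
#' @param midpoint,scale Logistic midpoint and scale, in licks.
#' @return Named numeric in (0, 1).
#' @export
acceptance_value <- function(scores, midpoint = 12, scale = 3) {
  1 / (1 + exp(-(scores - midpoint) / scale))
}

#' Draw the pre-conditioning gain matrix for one animal
#'
#' Each cell combines an acceptance component (cells load on the accepted
#' pole — responding near-equally to every consumed stimulus — or, for an
#' \code{aversive_pole_fraction} minority, on the rejected pole, with
#' magnitudes balanced across poles) with a Gaussian identity-tuned component on the
#' latent identity axis. Gains are roughened by per-cell-per-stimulus
#' lognormal tuning heterogeneity; a (1 - \code{cell_tuning_sparsity})
#' fraction of cells is left essentially taste-silent; and a per-cell gamma
#' factor scales gains so the mean positive gain equals
#' \code{response_gain_mean}.
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed.
#' @return Nonnegative matrix, cells x stimuli (panel plus water).
#' @export
make_base_gains <- function(config, seed = config$seed) {
  set.seed(seed)
  stimuli <- c(names(config$stimulus_panel), "water")
  n <- config$n_cells_per_animal
  accept <- acceptance_value(config$palatability_scores[stimuli],
                             config$accept_midpoint, config$accept_scale)
  id_ax <- config$identity_axes[stimuli]

  u <- abs(rnorm(n))                              # acceptance loading
  avf <- config$aversive_pole_fraction
  pole <- ifelse(runif(n) < avf, 0, 1)
  # aversive-pole cells are fewer but individually stronger, so the
  # population-mean response is palatability-independent (no built-in
  # magnitude-lick coupling)
  bal <- if (avf > 0) (1 - avf) / avf else 1
  pal_part <- config$palatability_weight * u *
    outer(pole, accept) + config$palatability_weight * u * bal *
    outer(1 - pole, 1 - accept)
  pref <- runif(n, min(id_ax) - 0.5, max(id_ax) + 0.5)
  h <- abs(rnorm(n))                              # identity strength
  id_part <- config$identity_weight * h *
    exp(-(outer(pref, id_ax, "-"))^2 / (2 * config$identity_width^2))
  g <- pal_part + id_part
  g <- g * matrix(rlnorm(length(g), 0, config$tuning_noise_sd), nrow = n)
  # a (1 - sparsity) fraction of tracked cells is essentially taste-silent
  responsive <- runif(n) < config$cell_tuning_sparsity
  g <- g * ifelse(responsive, 1, 0.05)
  pos_mean <- mean(g[g > 0])
  if (is.finite(pos_mean) && pos_mean > 0) g <- g / pos_mean
  cv <- config$response_gain_sd / config$response_gain_mean
  shape <- 1 / cv^2
  m <- rgamma(n, shape = shape, rate = shape / config$response_gain_mean)
  g <- g * m
  dimnames(g) <- list(NULL, stimuli)
  g
}

#' Apply CTA re-tuning to a gain matrix
#'
#' Implements the conditioning manipulation on the ground-truth gains of a
#' CTA-group animal: a \code{cta_retune_fraction} of Q-best cells gains CS
#' sensitivity (their CS gain is raised to at least their quinine gain) and
#' the same fraction of N-best cells loses it (CS gain shrunk to 10\%).
#' With \code{magnitude_preserving}, raised CS gains are rescaled so the
#' pooled positive CS gain mass is exactly conserved, mirroring the absence
#' of population-level magnitude changes after conditioning. A partial
#' \code{strength} blends linearly between the pre and fully re-tuned gains
#' (conservation is strength-invariant).
#'
#' @param gains Pre-conditioning gain matrix (cells x stimuli).
#' @param best_pre Character vector of pre-conditioning unit labels
#'   (\code{\link{make_base_gains}} + \code{best_of_basic}).
#' @param config A \code{\link{generator_config}}.
#' @param strength Re-tuning strength in [0, 1].
#' @param seed Seed for selecting which cells re-tune (fixed per animal so
#'   the same cells re-tune on every post day).
#' @return Gain matrix of identical shape.
#' @export
apply_cta_retuning <- function(gains, best_pre, config, strength = 1,
                               seed = config$seed) {
  f <- config$cta_retune_fraction
  if (f < 0 || f > 1) stop("cta_retune_fraction out of [0, 1]")
  if (f == 0 || strength == 0) return(gains)
  cs <- config$cs_label
  av <- config$aversive_label
  post <- gains
  set.seed(seed)
  q_cells <- which(best_pre == "Q-Unit")
  n_cells <- which(best_pre == "N-Unit")
  q_sel <- sample_fraction(q_cells, f)
  n_sel <- sample_fraction(n_cells, f)

  post[q_sel, cs] <- pmax(post[q_sel, cs], post[q_sel, av])
  post[n_sel, cs] <- 0.1 * post[n_sel, cs]

  if (config$magnitude_preserving && length(q_sel)) {
    t_pre <- sum(gains[, cs])
    t_other <- sum(post[-q_sel, cs])
    raised <- sum(post[q_sel, cs])
    if (raised > 0 && t_pre > t_other) {
      post[q_sel, cs] <- post[q_sel, cs] * (t_pre - t_other) / raised
    }
  }
  (1 - strength) * gains + strength * post
}

sample_fraction <- function(idx, f) {
  k <- round(f * length(idx))
  if (k == 0L) return(integer())
  if (length(idx) == 1L) return(if (k >= 1L) idx else integer())
  sample(idx, k)
}

#' Ground truth for one synthetic animal
#'
#' Base gains, pre-conditioning stimulus-best labels, and the per-day gain
#' matrices (re-tuned on post-conditioning days for CTA animals, with
#' strength following the extinction-recovery profile when enabled).
#'
#' @param config A \code{\link{generator_config}}.
#' @param group \code{"control"} or \code{"cta"}.
#' @param animal_idx 1-based animal index within the group.
#' @return List with \code{animal_id}, \code{group}, \code{cell_ids},
#'   \code{base_gains}, \code{best_pre}, \code{gains_by_day} (imaging days
#'   only) and \code{retune_seed}.
#' @export
make_animal_truth <- function(config, group, animal_idx) {
  animal_id <- sprintf("%s%02d", ifelse(group == "control", "con", "cta"),
                       animal_idx)
  a_key <- animal_key(group, animal_idx)
  gains <- make_base_gains(config,
                           seed = substream_seed(config$seed, a_key, 0L, 1L))
  best <- best_of_basic(gains)
  retune_seed <- substream_seed(config$seed, a_key, 0L, 2L)
  days <- imaging_days(config)
  gains_by_day <- lapply(days, function(d) {
    s <- retune_strength(config, d)
    if (group == "cta" && s > 0) {
      apply_cta_retuning(gains, best, config, strength = s,
                         seed = retune_seed)
    } else {
      gains
    }
  })
  names(gains_by_day) <- days
  list(animal_id = animal_id, group = group,
       cell_ids = sprintf("%s_c%03d", animal_id,
                          seq_len(config$n_cells_per_animal)),
       base_gains = gains, best_pre = best,
       gains_by_day = gains_by_day, retune_seed = retune_seed)
}

# stable per-animal key: control animals 1..N, cta animals 1001..1000+N
animal_key <- function(group, animal_idx) {
  as.integer(animal_idx + ifelse(group == "cta", 1000L, 0L))
}
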