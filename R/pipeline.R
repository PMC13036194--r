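# End-to-end orchestration: generate -> extract -> tune -> geometry ->
# decode -> behaviour -> report.

# tiny FNV-1a hash of a deparsed object, for provenance stamping
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, then runs every analysis stage and
#' writes tidy CSV outputs plus a single JSON report: per-animal
#' responsiveness summaries, entropy means, PCoA coordinates and
#' CS-divergence series per group, the N-/Q-Unit tuning-shift table,
#' decoding results, behaviour summaries and the response-vs-lick
#' regression. Fully deterministic under a fixed seed; the effective
#' configuration and its hash are echoed into the report.
#'
#' @param config A \code{\link{generator_config}}.
#' @param out_dir Output directory (created; \code{NULL} = no files
#'   written, report returned only).
#' @param cohort Optional pre-built \code{taste_cohort} (skips generation).
#' @param stages Character subset of
#'   \code{c("extract", "tune", "geometry", "decode", "behavior")}.
#' @param decode_shuffles,decode_bootstraps Repetition counts for the
#'   decoding stage (kept modest by default; raise to 1000 for full runs).
#' @return The report, an invisible named list.
#' @export
run_cta_pipeline <- function(config = generator_config(), out_dir = NULL,
                             cohort = NULL,
                             stages = c("extract", "tune", "geometry",
                                        "decode", "behavior"),
                             decode_shuffles = 20L,
                             decode_bootstraps = 20L) {
  t_start <- Sys.time()
  if (is.null(cohort)) cohort <- generate_cohort(config)
  report <- list(
    manifest = list(
      package_version = as.character(utils::packageVersion("tastecoda")),
      seed = config$seed, config_hash = config_hash(unclass(config)),
      config = unclass(config)[setdiff(names(unclass(config)),
                                       c("stimulus_panel"))],
      stages = stages))
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                row.names = FALSE)
    }
  }
  groups <- unique(vapply(cohort$sessions, `[[`, "", "group"))
  days <- unique(vapply(Filter(function(s) s$day_kind != "conditioning",
                               cohort$sessions), `[[`, "", "day"))

  responses <- NULL
  if (any(c("extract", "tune", "geometry", "decode") %in% stages)) {
    responses <- tryCatch(cohort_responses(cohort),
                          error = function(e) stop("stage extract: ",
                                                   conditionMessage(e)))
    emit("day_means", responses$day_means)
    summ <- summarize_responses(responses$day_means)
    emit("response_summaries", summ)
    report$extract <- list(
      tracked_counts = as.list(responses$tracked_counts),
      fraction_perturbed = stats::aggregate(
        fraction_perturbed ~ group + day + stimulus, summ, mean))
  }

  trial_licks <- trial_lick_counts(cohort)
  lick_sum <- lick_summary(trial_licks)
  emit("lick_summary", lick_sum)

  if ("tune" %in% stages) {
    prof <- tryCatch({
      p <- tuning_profiles(responses$day_means)
      labels <- assign_best_stimulus(responses$day_means)
      shift <- tuning_shift_table(labels, responses$day_means)
      emit("tuning_profiles", p)
      emit("tuning_shift", shift$table)
      list(entropy_means = stats::aggregate(entropy ~ group + day, p, mean,
                                            na.rm = TRUE),
           ties = attr(labels, "ties"), shift = shift$table)
    }, error = function(e) stop("stage tune: ", conditionMessage(e)))
    report$tune <- prof
  }

  if ("geometry" %in% stages) {
    report$geometry <- tryCatch(lapply(setNames(groups, groups),
                                       function(g) {
      pv <- build_population_vectors(responses$day_means, group = g)
      emb <- pcoa(dist(pv), ndim = 2)
      licks_post <- lick_sum[lick_sum$group == g &
                               lick_sum$day == "posttest1", ]
      lick_means <- setNames(licks_post$mean_licks, licks_post$stimulus)
      oc <- orient_and_correlate(emb, lick_means, "posttest1")
      div <- cs_divergence(oc$embedding, days = setdiff(days, NULL))
      if (!is.null(out_dir)) {
        coords <- data.frame(object = oc$embedding$objects,
                             oc$embedding$coords[, 1:2] *
                               rep(oc$embedding$orientation[1:2],
                                   each = length(oc$embedding$objects)))
        emit(paste0("pcoa_", g), coords)
        emit(paste0("cs_divergence_", g), div)
      }
      list(eigenvalues = emb$eigenvalues, dim1_lick_r = oc$r,
           divergence = div)
    }), error = function(e) stop("stage geometry: ", conditionMessage(e)))
  }

  if ("decode" %in% stages) {
    report$decode <- tryCatch(lapply(setNames(groups, groups),
                                     function(g) {
      pre_days <- c("pretest1", "pretest2")
      obs <- assemble_observations(responses, "per_day_average",
                                   stimuli = NULL,
                                   days = days, group = g)
      id_res <- loocv_svm(obs$features, obs$labels, days = obs$days,
                          shuffles = decode_shuffles,
                          bootstraps = decode_bootstraps,
                          seed = config$seed)
      tr_obs <- assemble_observations(responses, "per_trial",
                                      stimuli = basic_tastes(),
                                      days = days, group = g)
      pre <- tr_obs$days %in% pre_days
      post <- tr_obs$days == "posttest1"
      p2p <- pre2post_svm(tr_obs$features[pre, , drop = FALSE],
                          tr_obs$labels[pre],
                          tr_obs$features[post, , drop = FALSE],
                          tr_obs$labels[post],
                          bootstraps = decode_bootstraps,
                          seed = config$seed)
      if (!is.null(out_dir))
        emit(paste0("confusion_pre2post_", g),
             as.data.frame(p2p$confusion$percent))
      list(identity_error = id_res$error_rate,
           identity_shuffled_mean_error =
             if (length(id_res$shuffled_accuracies))
               1 - mean(id_res$shuffled_accuracies) else NA,
           pre2post_accuracy = p2p$accuracy,
           pre2post_confusion_percent = p2p$confusion$percent)
    }), error = function(e) stop("stage decode: ", conditionMessage(e)))
  }

  if ("behavior" %in% stages) {
    report$behavior <- tryCatch({
      cond <- Filter(function(s) s$day_kind == "conditioning",
                     cohort$sessions)
      cm <- do.call(rbind, lapply(cond, conditioning_metrics))
      emit("conditioning_metrics", cm)
      reg <- if (!is.null(responses))
        lapply(setNames(groups, groups), function(g) {
          r <- response_vs_licks(responses$trials, trial_licks, g)
          r$points <- NULL
          r
        }) else NULL
      list(conditioning = cm, response_vs_licks = reg)
    }, error = function(e) stop("stage behavior: ", conditionMessage(e)))
  }

  report$manifest$elapsed_s <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 8,
                         force = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Thin wrapper used by the \code{inst/cli/tastecoda} script:
#' \code{tastecoda run-all --seed N --out DIR} (also \code{generate}, which
#' writes the cohort directory only).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
tastecoda_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: tastecoda <generate|run-all> [--seed N] [--out DIR] ",
            "[--animals N] [--cells N]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cfg <- generator_config(
    seed = as.integer(get_opt("--seed", "1")),
    n_animals_per_group = as.integer(get_opt("--animals", "4")),
    n_cells_per_animal = as.integer(get_opt("--cells", "30")))
  out <- get_opt("--out", "tastecoda-out")
  if (cmd == "generate") {
    write_cohort(generate_cohort(cfg), out)
    message("cohort written to ", out)
  } else if (cmd == "run-all") {
    run_cta_pipeline(cfg, out_dir = out)
    message("report written to ", file.path(out, "report.json"))
  } else {
    stop("unknown command: ", cmd)
  }
  invisible(0L)
}
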