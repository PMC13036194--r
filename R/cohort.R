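# Cohort generation and the on-disk cohort format.

#' Generate a complete synthetic cohort
#'
#' Builds control and CTA groups over the full session sequence (2 pretest
#' days, conditioning, 2 or more post-test days; \code{posttest2} onward use
#' the extinction schedule with 12 forced NaCl trials). Every animal x day
#' gets a trial table, lick events and — on imaging days — a synthesized
#' trace matrix, all driven by per-animal/per-day seed substreams of
#' \code{config$seed}, so adding animals or days never perturbs existing
#' ones. Ground truth (gains, stimulus-best labels, group assignment) is
#' retained for validation.
#'
#' @param config A \code{\link{generator_config}}.
#' @param groups Which groups to generate (default both).
#' @param keep_traces If \code{FALSE}, imaging-day traces are dropped after
#'   generation (schedule/licks only; saves memory for behaviour-only work).
#' @return An object of class \code{taste_cohort}: list with \code{config},
#'   \code{truth} (per animal, see \code{\link{make_animal_truth}}) and
#'   \code{sessions}, a list of session records (\code{animal_id},
#'   \code{group}, \code{day}, \code{trials}, \code{licks},
#'   \code{frame_rate}, \code{global_cell_ids}, \code{traces}).
#' @export
#' @examples
#' cfg <- generator_config(n_animals_per_group = 1, n_cells_per_animal = 5)
#' coh <- generate_cohort(cfg, groups = "control")
#' length(coh$sessions)
generate_cohort <- function(config, groups = c("control", "cta"),
                            keep_traces = TRUE) {
  validate_generator_config(config)
  days <- cohort_days(config)
  truth <- list()
  sessions <- list()
  for (group in groups) {
    for (a in seq_len(config$n_animals_per_group)) {
      tr <- make_animal_truth(config, group, a)
      truth[[tr$animal_id]] <- tr
      a_key <- animal_key(group, a)
      for (d_idx in seq_along(days)) {
        day <- days[d_idx]
        kind <- day_kind(day)
        sched_seed <- substream_seed(config$seed, a_key, d_idx, 3L)
        lick_seed <- substream_seed(config$seed, a_key, d_idx, 4L)
        trace_seed <- substream_seed(config$seed, a_key, d_idx, 5L)
        if (kind == "conditioning") {
          trials <- build_schedule("conditioning", config, seed = sched_seed,
                                   conditioning_stimulus =
                                     ifelse(group == "cta", "LiCl", "NaCl"))
          licks <- simulate_conditioning_licks(config, group,
                                               seed = lick_seed)
          traces <- NULL
        } else {
          trials <- build_schedule(kind, config, seed = sched_seed)
          licks <- simulate_licks(trials, config, group, day,
                                  seed = lick_seed)
          traces <- if (keep_traces) {
            synthesize_traces(trials, licks, tr$gains_by_day[[day]], config,
                              seed = trace_seed)
          } else NULL
        }
        sessions[[paste(tr$animal_id, day, sep = ".")]] <- list(
          animal_id = tr$animal_id, group = group, day = day,
          day_kind = kind, trials = trials, licks = licks,
          frame_rate = config$frame_rate,
          global_cell_ids = tr$cell_ids, traces = traces)
      }
    }
  }
  structure(list(config = config, truth = truth, sessions = sessions),
            class = "taste_cohort")
}

#' @export
print.taste_cohort <- function(x, ...) {
  grp <- vapply(x$sessions, `[[`, "", "group")
  cat("taste_cohort:", length(unique(names(x$truth))), "animals,",
      length(x$sessions), "sessions (",
      paste(names(table(grp)), table(grp), collapse = ", "), ")\n")
  invisible(x)
}

#' Write a cohort directory
#'
#' Lays the cohort out as delimited text: per animal/day a
#' \code{traces.csv} (cells x frames, first column the global cell ID), a
#' \code{trials.csv} and a \code{licks.csv}; plus \code{manifest.json}
#' (groups, animals, days, frame rate, seed) and \code{ground_truth.json}
#' (per-animal gains and stimulus-best labels) at the root.
#'
#' @param cohort A \code{taste_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  animals <- lapply(cohort$truth, function(tr)
    list(animal_id = tr$animal_id, group = tr$group,
         n_cells = length(tr$cell_ids)))
  manifest <- list(
    format = "tastecoda-cohort/1",
    frame_rate = cohort$config$frame_rate,
    seed = cohort$config$seed,
    days = cohort_days(cohort$config),
    animals = unname(animals))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  truth_out <- lapply(cohort$truth, function(tr) list(
    group = tr$group, cell_ids = tr$cell_ids, best_pre = tr$best_pre,
    stimuli = colnames(tr$base_gains),
    gains_by_day = lapply(tr$gains_by_day, function(g)
      unname(apply(g, 1L, function(r) round(unname(r), 6), simplify = FALSE)))))
  jsonlite::write_json(truth_out, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in cohort$sessions) {
    sdir <- file.path(dir, s$animal_id, s$day)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(s$trials, file.path(sdir, "trials.csv"), row.names = FALSE)
    write.csv(s$licks, file.path(sdir, "licks.csv"), row.names = FALSE)
    if (!is.null(s$traces)) {
      df <- data.frame(cell_id = s$global_cell_ids,
                       round(s$traces, 4), check.names = FALSE)
      colnames(df) <- c("cell_id", paste0("f", seq_len(ncol(s$traces))))
      write.csv(df, file.path(sdir, "traces.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir Cohort directory.
#' @return A \code{taste_cohort} (without generator ground truth unless
#'   \code{ground_truth.json} is present; \code{config} is \code{NULL} —
#'   the manifest carries frame rate and day list).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "tastecoda-cohort/1"))
    stop("not a tastecoda cohort directory: ", dir)
  sessions <- list()
  for (i in seq_len(nrow(manifest$animals))) {
    aid <- manifest$animals$animal_id[i]
    grp <- manifest$animals$group[i]
    for (day in manifest$days) {
      sdir <- file.path(dir, aid, day)
      if (!dir.exists(sdir)) next
      trials <- read.csv(file.path(sdir, "trials.csv"),
                         stringsAsFactors = FALSE)
      licks <- read.csv(file.path(sdir, "licks.csv"))
      tf <- file.path(sdir, "traces.csv")
      traces <- NULL
      cell_ids <- character()
      if (file.exists(tf)) {
        df <- read.csv(tf, check.names = FALSE, stringsAsFactors = FALSE)
        cell_ids <- df$cell_id
        traces <- as.matrix(df[, -1, drop = FALSE])
        dimnames(traces) <- NULL
        rownames(traces) <- cell_ids
      }
      sessions[[paste(aid, day, sep = ".")]] <- list(
        animal_id = aid, group = grp, day = day, day_kind = day_kind(day),
        trials = trials, licks = licks, frame_rate = manifest$frame_rate,
        global_cell_ids = cell_ids, traces = traces)
    }
  }
  structure(list(config = NULL, manifest = manifest, truth = NULL,
                 sessions = sessions),
            class = "taste_cohort")
}
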