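# SVM decoding protocols: observation assembly, palatability labelling,
# LOOCV with shuffled-label nulls and bootstraps, train-pre/test-post.

#' Assemble decoding observations from the response table
#'
#' Builds the feature matrix (one column per pooled tracked cell) and label
#' vector for decoding. In \code{per_day_average} mode each observation is a
#' stimulus x day population vector (per-day mean dF per cell). In
#' \code{per_trial} mode each observation is one stimulus presentation:
#' cells are pooled across animals by aligning same-rank presentations of a
#' stimulus within a day (every animal's k-th trial of that stimulus), and
#' ranks beyond the minimum shared count are dropped.
#'
#' @param responses \code{\link{cohort_responses}} output (or a compatible
#'   list with \code{trials} and \code{day_means}).
#' @param mode \code{"per_day_average"} or \code{"per_trial"}.
#' @param stimuli Stimulus set to decode (e.g. \code{\link{basic_tastes}});
#'   \code{NULL} uses every stimulus present on all requested days.
#' @param days Days to include.
#' @param group Group to pool.
#' @return List: \code{features} (matrix), \code{labels} (stimulus),
#'   \code{days} (day of each observation), \code{ids} (row labels).
#' @export
assemble_observations <- function(responses, mode = c("per_day_average",
                                                      "per_trial"),
                                  stimuli, days, group) {
  mode <- match.arg(mode)
  if (mode == "per_day_average") {
    dm <- responses$day_means
    if (!is.null(stimuli)) {
      miss <- setdiff(stimuli, unique(dm$stimulus[dm$group == group]))
      if (length(miss))
        stop("requested stimulus missing: ", paste(miss, collapse = ", "))
    }
    mat <- build_population_vectors(dm, group = group, stimuli = stimuli,
                                    days = days)
    obj <- attr(mat, "objects")
    return(list(features = unclass(mat)[, , drop = FALSE],
                labels = obj$stimulus, days = obj$day,
                ids = rownames(mat)))
  }
  tr <- responses$trials
  if (is.null(stimuli)) {
    per_day <- lapply(days, function(dd)
      unique(tr$stimulus[tr$day == dd & tr$group == group]))
    stimuli <- Reduce(intersect, per_day)
  }
  tr <- tr[tr$group == group & tr$stimulus %in% stimuli & tr$day %in% days, ]
  miss <- setdiff(stimuli, unique(tr$stimulus))
  if (length(miss))
    stop("requested stimulus missing: ", paste(miss, collapse = ", "))
  # presentation rank of each trial within animal x day x stimulus
  ord <- order(tr$animal_id, tr$day, tr$stimulus, tr$trial_id, tr$cell_id)
  tr <- tr[ord, ]
  key <- interaction(tr$animal_id, tr$day, tr$stimulus, tr$cell_id,
                     drop = TRUE)
  tr$occ <- stats::ave(tr$delta_plus, key, FUN = seq_along)
  animals <- unique(tr$animal_id)
  cells <- unique(tr$cell_id)
  rows <- list()
  for (day in days) {
    for (stim in stimuli) {
      sub <- tr[tr$day == day & tr$stimulus == stim, ]
      if (nrow(sub) == 0L) next
      n_occ <- min(tapply(sub$occ, sub$animal_id, max))
      for (k in seq_len(n_occ)) {
        v <- sub[sub$occ == k, ]
        feat <- setNames(v$delta_plus, v$cell_id)[cells]
        rows[[paste(stim, day, k, sep = "|")]] <-
          list(feat = feat, label = stim, day = day)
      }
    }
  }
  features <- do.call(rbind, lapply(rows, `[[`, "feat"))
  colnames(features) <- cells
  list(features = features,
       labels = vapply(rows, `[[`, "", "label"),
       days = vapply(rows, `[[`, "", "day"),
       ids = names(rows))
}

#' Binary palatability labels from lick behaviour
#'
#' A stimulus on a given day is labelled \code{"high"} if its cross-animal
#' mean lick count exceeds the median lick count over all of that day's
#' trials, else \code{"low"}; exact ties go to \code{"low"} and are counted
#' in the \code{"ties"} attribute.
#'
#' @param trial_licks Per-trial lick counts: data.frame with \code{day},
#'   \code{stimulus}, \code{licks} (see \code{\link{trial_lick_counts}}).
#' @param day Day label.
#' @return Named character vector (stimulus -> \code{"high"}/\code{"low"}).
#' @export
label_palatability <- function(trial_licks, day) {
  tl <- trial_licks[trial_licks$day == day, ]
  if (nrow(tl) == 0L) stop("no lick data for day ", day)
  med <- median(tl$licks)
  means <- tapply(tl$licks, tl$stimulus, mean)
  lab <- ifelse(means > med, "high", "low")
  attr(lab, "ties") <- sum(means == med)
  lab
}

confusion_matrix <- function(true, pred, classes = sort(unique(true))) {
  counts <- table(factor(true, classes), factor(pred, classes))
  pct <- sweep(counts, 1L, pmax(rowSums(counts), 1L), "/") * 100
  list(counts = unclass(counts), percent = unclass(pct))
}

run_loocv <- function(features, labels, cost) {
  n <- length(labels)
  preds <- character(n)
  for (i in seq_len(n)) {
    if (length(unique(labels[-i])) < 2L) {
      # degenerate fold (left-out obs was a singleton class)
      preds[i] <- labels[-i][1L]
      next
    }
    fit <- svm_train(features[-i, , drop = FALSE], labels[-i], cost = cost)
    preds[i] <- predict(fit, features[i, , drop = FALSE])
  }
  preds
}

# inner k-fold CV accuracy used when a cost grid is supplied
pick_cost <- function(features, labels, cost_grid, folds = 3L) {
  if (length(cost_grid) == 1L) return(cost_grid)
  n <- length(labels)
  fold <- rep_len(seq_len(folds), n)
  acc <- vapply(cost_grid, function(cc) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L) return(NA_real_)
      fit <- svm_train(features[tr, , drop = FALSE], labels[tr], cost = cc)
      mean(predict(fit, features[!tr, , drop = FALSE]) == labels[!tr])
    }, 0), na.rm = TRUE)
  }, 0)
  cost_grid[which.max(acc)]
}

#' Leave-one-out SVM decoding with shuffled-label null and bootstrap
#'
#' Each observation is predicted by a linear SVM trained on all others
#' (features standardized within each training fold). The shuffled-label
#' null permutes labels within each day (preserving day structure) and
#' reruns the full LOOCV, \code{shuffles} times; bootstrap repetitions
#' resample observations with replacement and rerun LOOCV on the resample.
#'
#' @param features Observations x features matrix.
#' @param labels Class labels.
#' @param days Optional day label per observation (shuffle stratum).
#' @param shuffles,bootstraps Repetition counts (0 disables).
#' @param seed Integer seed driving shuffle/bootstrap randomness.
#' @param cost Cost parameter; a vector is treated as a grid resolved once
#'   by inner 3-fold CV on the true-label data.
#' @return Object of class \code{decoding_result}: \code{protocol},
#'   \code{labels}, \code{predictions}, \code{accuracy}, \code{error_rate},
#'   \code{confusion} (counts and row percentages),
#'   \code{shuffled_accuracies}, \code{bootstrap_accuracies}, \code{cost}.
#' @export
loocv_svm <- function(features, labels, days = NULL, shuffles = 0L,
                      bootstraps = 0L, seed = 1L, cost = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  singletons <- names(which(table(labels) == 1L))
  if (length(singletons))
    warning("classes with a single observation (degenerate LOOCV fold): ",
            paste(singletons, collapse = ", "))
  cost <- pick_cost(features, labels, cost)
  preds <- run_loocv(features, labels, cost)
  acc <- mean(preds == labels)
  set.seed(seed)
  strata <- if (is.null(days)) rep(1L, n) else as.integer(factor(days))
  shuf <- vapply(seq_len(shuffles), function(r) {
    lab_s <- labels
    for (s in unique(strata)) {
      idx <- which(strata == s)
      lab_s[idx] <- labels[sample(idx)]
    }
    # null-model benchmark: models are *trained* on shuffled labels but
    # scored on predicting the true classes (scoring against the permuted
    # labels would add a permutation anti-correlation the benchmark lacks)
    mean(run_loocv(features, lab_s, cost) == labels)
  }, 0)
  boot <- vapply(seq_len(bootstraps), function(r) {
    idx <- sample(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    mean(run_loocv(features[idx, , drop = FALSE], labels[idx], cost) ==
           labels[idx])
  }, 0)
  structure(list(protocol = "loocv", labels = labels, predictions = preds,
                 accuracy = acc, error_rate = 1 - acc,
                 confusion = confusion_matrix(labels, preds),
                 shuffled_accuracies = shuf, bootstrap_accuracies = boot,
                 cost = cost),
            class = "decoding_result")
}

#' Train-pre / test-post SVM decoding
#'
#' Fits one linear SVM on all pre-conditioning observations and predicts
#' the post-conditioning observations, summarized as a confusion matrix of
#' true vs predicted stimulus with row-normalized percentages. Bootstrap
#' repetitions resample the post observations with replacement for
#' prediction-rate distributions.
#'
#' @param pre_features,pre_labels Training observations (pre-CTA days).
#' @param post_features,post_labels Test observations (post-CTA); columns
#'   (cells) must match the training features.
#' @param bootstraps Bootstrap repetitions over post observations.
#' @param seed Integer seed.
#' @param cost Cost parameter (or grid, resolved on the pre data).
#' @return A \code{decoding_result} with protocol \code{"pre2post"}.
#' @export
pre2post_svm <- function(pre_features, pre_labels, post_features,
                         post_labels, bootstraps = 0L, seed = 1L,
                         cost = 1) {
  if (ncol(pre_features) != ncol(post_features) ||
      !identical(colnames(pre_features), colnames(post_features)))
    stop("pre/post feature columns (cell sets) differ")
  cost <- pick_cost(pre_features, as.character(pre_labels), cost)
  fit <- svm_train(pre_features, pre_labels, cost = cost)
  preds <- predict(fit, post_features)
  post_labels <- as.character(post_labels)
  acc <- mean(preds == post_labels)
  set.seed(seed)
  n <- length(post_labels)
  boot <- vapply(seq_len(bootstraps), function(r) {
    idx <- sample(n, replace = TRUE)
    mean(preds[idx] == post_labels[idx])
  }, 0)
  structure(list(protocol = "pre2post", labels = post_labels,
                 predictions = preds, accuracy = acc,
                 error_rate = 1 - acc,
                 confusion = confusion_matrix(
                   post_labels, preds,
                   classes = sort(unique(c(post_labels, pre_labels)))),
                 shuffled_accuracies = numeric(),
                 bootstrap_accuracies = boot, cost = cost),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("decoding_result [", x$protocol, "]: accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy),
      if (length(x$shuffled_accuracies))
        sprintf(" (shuffled mean %.1f%%)",
                100 * mean(x$shuffled_accuracies)) else "", "\n", sep = "")
  invisible(x)
}
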