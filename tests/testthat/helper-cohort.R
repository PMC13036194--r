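# Shared fixtures: all synthetic, generated in code. The default shared
# cohort (3 animals/group x 20 cells) is built lazily once per test run and
# reused by the tuning / geometry / decoding / behaviour tests.

.tc_cache <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_animals_per_group = 2L, n_cells_per_animal = 10L,
                   seed = 11L)
  do.call(generator_config, utils::modifyList(defaults, args))
}

shared_config <- function() {
  generator_config(n_animals_per_group = 3L, n_cells_per_animal = 20L,
                   seed = 42L)
}

shared_cohort <- function() {
  if (is.null(.tc_cache$cohort))
    .tc_cache$cohort <- generate_cohort(shared_config())
  .tc_cache$cohort
}

shared_responses <- function() {
  if (is.null(.tc_cache$responses))
    .tc_cache$responses <- cohort_responses(shared_cohort())
  .tc_cache$responses
}

shared_trial_licks <- function() {
  if (is.null(.tc_cache$trial_licks))
    .tc_cache$trial_licks <- trial_lick_counts(shared_cohort())
  .tc_cache$trial_licks
}

# pooled ground-truth best-stimulus labels, named by global cell id
shared_truth_best <- function() {
  do.call(c, unname(lapply(shared_cohort()$truth, function(tr)
    stats::setNames(tr$best_pre, tr$cell_ids))))
}

# independent complete-linkage oracle: recompute every cluster pair distance
# as the max over member pairs of the ORIGINAL matrix at each step
naive_complete_linkage <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- max(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights[step] <- best_d
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    members[[step]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, members = members)
}

# canonical member sets of each merge of an hclust-style result
hclust_members <- function(hc) {
  n <- nrow(hc$merge) + 1L
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    mem <- integer()
    for (v in hc$merge[s, ])
      mem <- c(mem, if (v < 0) -v else out[[v]])
    out[[s]] <- sort(mem)
  }
  out
}
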