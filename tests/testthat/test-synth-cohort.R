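test_that("lick counts follow palatability and the CTA reduction", {
  cfg <- tiny_config()
  sched <- build_schedule("pretest", cfg, seed = 2)
  # zero palatability -> zero licks on every trial
  zero_cfg <- tiny_config(palatability_scores = stats::setNames(
    rep(0, 7), c(names(cfg$stimulus_panel), "water")))
  licks0 <- simulate_licks(sched, zero_cfg, seed = 3)
  expect_equal(nrow(licks0), 0L)
  # missing score errors
  cfg_miss <- cfg
  cfg_miss$palatability_scores <-
    cfg$palatability_scores[names(cfg$palatability_scores) != "KCl"]
  expect_error(simulate_licks(sched, cfg_miss, seed = 1), "missing palatability")
  # licks fall inside their trial windows, on an ~8 Hz rhythm
  licks <- simulate_licks(sched, cfg, seed = 4)
  for (tid in unique(licks$trial_id)) {
    lt <- licks$lick_time_s[licks$trial_id == tid]
    on <- sched$onset_s[sched$trial_id == tid]
    expect_true(all(lt >= on & lt < on + cfg$trial_s))
  }
})

test_that("post-conditioning CS licking drops for every CTA animal", {
  tl <- shared_trial_licks()
  cs <- tl[tl$stimulus == "NaCl" & tl$group == "cta", ]
  for (a in unique(cs$animal_id)) {
    pre <- cs$licks[cs$animal_id == a & cs$day == "pretest2"]
    post <- cs$licks[cs$animal_id == a & cs$day == "posttest1"]
    expect_lt(mean(post), mean(pre))
  }
  # control CS licking does not collapse
  con <- tl[tl$stimulus == "NaCl" & tl$group == "control", ]
  expect_gt(mean(con$licks[con$day == "posttest1"]), 10)
})

test_that("behavioural separation: high quinine is licked < 25% of sucrose", {
  for (seed in 1:3) {
    cfg <- tiny_config(seed = seed)
    coh <- generate_cohort(cfg, keep_traces = FALSE)
    tl <- trial_lick_counts(coh)
    pre <- tl[tl$day %in% c("pretest1", "pretest2"), ]
    expect_lt(mean(pre$licks[pre$stimulus == "QHCl_high"]),
              0.25 * mean(pre$licks[pre$stimulus == "sucrose"]))
  }
})

test_that("conditioning session obeys the 1,000-lick / 20-min stop rule", {
  cfg <- tiny_config()
  caps <- sapply(1:8, function(i) {
    con <- simulate_conditioning_licks(cfg, "control", seed = i)
    cta <- simulate_conditioning_licks(cfg, "cta", seed = i)
    expect_lte(nrow(con), cfg$conditioning_cap_licks)
    expect_true(all(con$lick_time_s - cfg$session_start_s <
                      cfg$conditioning_cap_min * 60))
    c(control = nrow(con) >= cfg$conditioning_cap_licks,
      cta = nrow(cta) >= cfg$conditioning_cap_licks)
  })
  # an animal that never slows records exactly 1,000 licks
  expect_true(all(caps["control", ]))
  expect_equal(nrow(simulate_conditioning_licks(cfg, "control", seed = 1)),
               cfg$conditioning_cap_licks)
  # CTA animals (LiCl) reach the cap less often than controls
  expect_lt(sum(caps["cta", ]), sum(caps["control", ]))
})

test_that("trace synthesis: silent gains give pure-noise traces; kernel sane", {
  cfg <- tiny_config(noise_sd = 0)
  sched <- build_schedule("pretest", cfg, seed = 1)
  licks <- simulate_licks(sched, cfg, seed = 2)
  g0 <- matrix(0, 3, 7,
               dimnames = list(NULL, c(names(cfg$stimulus_panel), "water")))
  tr <- synthesize_traces(sched, licks, g0, cfg, seed = 3)
  expect_true(all(tr == 0))
  k <- calcium_kernel(cfg)
  expect_equal(max(k), 1)
  expect_true(all(k >= 0))
  expect_gt(which.max(k), 1L)          # finite rise time
  expect_lt(k[length(k)], 0.01)        # decayed tail
})

test_that("extraction recovers configured gains (r > 0.8) at default SNR", {
  coh <- shared_cohort()
  resp <- shared_responses()
  dm <- resp$day_means[resp$day_means$day == "pretest2" &
                         resp$day_means$stimulus != "NaCl-Force", ]
  truth <- shared_cohort()$truth
  gains <- do.call(rbind, lapply(truth, function(tr) {
    g <- tr$gains_by_day[["pretest2"]]
    rownames(g) <- tr$cell_ids
    g
  }))
  idx <- cbind(match(dm$cell_id, rownames(gains)),
               match(dm$stimulus, colnames(gains)))
  expect_gt(cor(dm$mean_delta, gains[idx]), 0.8)
})

test_that("CTA re-tuning conserves pooled CS gain mass and alters cells", {
  cfg <- tiny_config(n_cells_per_animal = 40L, cta_retune_fraction = 1)
  g <- make_base_gains(cfg, seed = 9)
  best <- tastecoda:::best_of_basic(g)
  post <- apply_cta_retuning(g, best, cfg, strength = 1, seed = 10)
  expect_true(all(post >= 0))
  expect_equal(sum(post[, "NaCl"]), sum(g[, "NaCl"]), tolerance = 1e-9)
  expect_gt(sum(abs(post[, "NaCl"] - g[, "NaCl"])), 0)
  # partial strength also conserves (linear blend)
  half <- apply_cta_retuning(g, best, cfg, strength = 0.5, seed = 10)
  expect_equal(sum(half[, "NaCl"]), sum(g[, "NaCl"]), tolerance = 1e-9)
  # non-CS columns untouched
  expect_identical(post[, colnames(post) != "NaCl"],
                   g[, colnames(g) != "NaCl"])
  # fraction 0 -> identity
  cfg0 <- tiny_config(cta_retune_fraction = 0)
  expect_identical(apply_cta_retuning(g, best, cfg0, seed = 10), g)
})

test_that("control-group truth is identical on every day", {
  truth <- shared_cohort()$truth
  for (tr in truth) {
    if (tr$group != "control") next
    for (d in names(tr$gains_by_day))
      expect_identical(tr$gains_by_day[[d]], tr$base_gains)
  }
  # CTA truth differs on post days only
  cta <- Filter(function(tr) tr$group == "cta", truth)[[1]]
  expect_identical(cta$gains_by_day[["pretest1"]], cta$base_gains)
  expect_false(identical(cta$gains_by_day[["posttest1"]], cta$base_gains))
})

test_that("cohort round-trips through the on-disk format", {
  coh <- generate_cohort(tiny_config(n_cells_per_animal = 4L,
                                     n_animals_per_group = 1L))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$sessions), names(coh$sessions))
  s0 <- coh$sessions[["con01.pretest1"]]
  s1 <- back$sessions[["con01.pretest1"]]
  expect_equal(s1$trials, s0$trials)
  expect_equal(s1$licks$lick_time_s, s0$licks$lick_time_s)
  expect_equal(s1$global_cell_ids, s0$global_cell_ids)
  expect_equal(unname(s1$traces), unname(s0$traces), tolerance = 1e-3)
  expect_error(suppressWarnings(read_cohort(withr::local_tempdir())),
               "cannot open|manifest")
})
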