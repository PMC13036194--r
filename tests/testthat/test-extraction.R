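test_that("trial windows anchor to the first lick, falling back to onset", {
  w <- align_trial_window(95, 100.0, 10)
  expect_equal(w$baseline, c(950, 1000))
  expect_equal(w$response, c(1000, 1050))
  expect_equal(w$anchor, "lick")
  # no licks -> anchored at shutter onset
  w0 <- align_trial_window(60.0, numeric(), 10)
  expect_equal(w0$baseline, c(550, 600))
  expect_equal(w0$response, c(600, 650))
  expect_equal(w0$anchor, "onset")
  # first lick 2 s after onset: spans follow the lick, not the onset
  w2 <- align_trial_window(50, c(52.0, 52.4), 10)
  expect_equal(w2$response, c(520, 570))
  expect_equal(w2$baseline, c(470, 520))
  # out-of-bounds windows are flagged
  expect_false(align_trial_window(2, numeric(), 10, n_frames = 500)$ok)
  expect_false(align_trial_window(48, numeric(), 10, n_frames = 500)$ok)
})

test_that("compute_delta matches its arithmetic definition", {
  tr <- rep(1, 200)
  tr[101:150] <- c(4, rep(1, 48), 0.5)
  d <- compute_delta(tr, c(50, 100), c(100, 150), sd_floor = 1e-6)
  expect_equal(unname(d["delta_plus"]), 3.0)
  expect_equal(unname(d["delta_minus"]), -0.5)
  expect_equal(unname(d["baseline_sd"]), 1e-6) # constant baseline -> floor
  # constant trace
  d0 <- compute_delta(rep(2, 100), c(0, 50), c(50, 100), sd_floor = 1e-6)
  expect_equal(unname(d0["delta_plus"]), 0)
  expect_equal(unname(d0["delta_minus"]), 0)
  expect_error(compute_delta(c(rep(1, 50), NA), c(0, 25), c(25, 51)), "NaN")
})

test_that("dF is shift-invariant and scale-equivariant", {
  set.seed(1)
  for (i in 1:20) {
    tr <- rnorm(200, sd = runif(1, 0.1, 2)) + runif(1, -5, 5)
    b <- c(50, 100); r <- c(100, 150)
    d <- compute_delta(tr, b, r)
    ds <- compute_delta(tr + 3.7, b, r)
    expect_equal(ds, d, tolerance = 1e-12)
    cc <- runif(1, 0.5, 4)
    dm <- compute_delta(tr * cc, b, r)
    expect_equal(unname(dm), unname(d) * cc, tolerance = 1e-12)
    expect_identical(
      classify_response(dm["delta_plus"], dm["delta_minus"],
                        dm["baseline_sd"]),
      classify_response(d["delta_plus"], d["delta_minus"],
                        d["baseline_sd"]))
  }
})

test_that("classification thresholds are inclusive at +/- 3 SD", {
  expect_equal(classify_response(3, 0, 1), "excited")
  expect_equal(classify_response(2.9, -1, 1), "none")
  expect_equal(classify_response(0.5, -3.5, 1), "suppressed")
  # dual-threshold: excited wins
  expect_equal(classify_response(3.5, -3.5, 1), "excited")
  expect_equal(classify_response(c(3, 2.9), c(0, -3), c(1, 1)),
               c("excited", "suppressed"))
})

test_that("per-day stimulus means equal brute-force trial means", {
  resp <- shared_responses()
  dm <- resp$day_means
  tr <- resp$trials
  set.seed(5)
  pick <- dm[sample(nrow(dm), 50), ]
  for (i in seq_len(nrow(pick))) {
    sel <- tr$animal_id == pick$animal_id[i] & tr$day == pick$day[i] &
      tr$cell_id == pick$cell_id[i] & tr$stimulus == pick$stimulus[i]
    expect_identical(pick$mean_delta[i], mean(tr$delta_plus[sel]))
    expect_identical(pick$mean_delta_minus[i], mean(tr$delta_minus[sel]))
  }
})

test_that("tracked-cell filtering equals the brute-force intersection", {
  coh <- generate_cohort(tiny_config(n_cells_per_animal = 20L))
  # degrade the registry: drop a random 20% of cells per imaging session
  set.seed(99)
  coh$sessions <- lapply(coh$sessions, function(s) {
    if (is.null(s$traces)) return(s)
    keep <- runif(length(s$global_cell_ids)) > 0.2
    s$global_cell_ids <- s$global_cell_ids[keep]
    s$traces <- s$traces[keep, , drop = FALSE]
    s
  })
  filt <- filter_tracked(coh)
  imaging <- Filter(function(s) !is.null(s$traces), coh$sessions)
  for (aid in unique(vapply(imaging, `[[`, "", "animal_id"))) {
    expected <- Reduce(intersect,
                       lapply(Filter(function(s) s$animal_id == aid, imaging),
                              `[[`, "global_cell_ids"))
    got <- filt$sessions[[paste0(aid, ".pretest1")]]$global_cell_ids
    expect_setequal(got, expected)
    expect_equal(unname(attr(filt, "tracked_counts")[aid]),
                 length(expected))
  }
  # perfect registry retains everything
  clean <- filter_tracked(shared_cohort())
  expect_true(all(attr(clean, "tracked_counts") == 20L))
})

test_that("responsiveness summaries count perturbed cells correctly", {
  mk <- function(cell, stim, delta, sdv = 1) data.frame(
    animal_id = "a1", group = "g", day = "d1", cell_id = cell,
    stimulus = stim, mean_delta = delta, mean_delta_minus = 0,
    mean_baseline_sd = sdv, n_trials = 2L,
    class = classify_response(delta, 0, sdv), stringsAsFactors = FALSE)
  # 10 cells, 3 excited to NaCl -> fraction 0.3
  dm <- do.call(rbind, lapply(1:10, function(i)
    mk(paste0("c", i), "NaCl", ifelse(i <= 3, 5, 0.1))))
  s <- summarize_responses(dm)
  nacl <- s[s$stimulus == "NaCl", ]
  expect_equal(nacl$fraction_perturbed, 0.3)
  expect_equal(nacl$mean_excited, 5)
  expect_true(is.na(nacl$mean_suppressed))
  # all flat -> fraction 0, magnitudes undefined (NA, not zero)
  flat <- do.call(rbind, lapply(1:5, function(i) mk(paste0("c", i),
                                                    "sucrose", 0.1)))
  s0 <- summarize_responses(flat)
  expect_true(all(s0$fraction_perturbed == 0))
  expect_true(all(is.na(s0$mean_excited)))
})
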