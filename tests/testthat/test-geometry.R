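test_that("population vectors have the contracted shape and values", {
  resp <- shared_responses()
  pv <- build_population_vectors(resp$day_means, group = "control")
  # 7 stimuli common to all 4 imaging days x (3 animals x 20 cells)
  expect_equal(dim(pv), c(7L * 4L, 60L))
  expect_false("NaCl-Force" %in% attr(pv, "objects")$stimulus)
  # entries equal brute-force aggregation from the trial-level table
  tr <- resp$trials
  for (probe in list(c("sucrose", "pretest1"), c("QHCl_high", "posttest1"))) {
    cell <- colnames(pv)[5]
    sel <- tr$cell_id == cell & tr$stimulus == probe[1] & tr$day == probe[2]
    expect_equal(pv[paste(probe[1], probe[2], sep = "|"), cell],
                 mean(tr$delta_plus[sel]))
  }
  expect_error(build_population_vectors(resp$day_means, group = "ghost"),
               "no rows")
})

test_that("pcoa reproduces Euclidean geometry", {
  # two objects at distance 10 -> 1-D coordinates +/- 5
  d2 <- matrix(c(0, 10, 10, 0), 2)
  e2 <- pcoa(d2)
  expect_equal(sort(e2$coords[, 1]), c(-5, 5))
  # distances from a known 2-D point set are reproduced exactly
  set.seed(3)
  pts <- matrix(rnorm(16), ncol = 2)
  emb <- pcoa(as.matrix(dist(pts)))
  expect_lt(max(abs(dist(emb$coords) - dist(pts))) / max(dist(pts)), 1e-8)
  # recovered coordinates match the points up to rotation/reflection
  x <- scale(emb$coords[, 1:2], scale = FALSE)
  y <- scale(pts, scale = FALSE)
  sv <- svd(crossprod(y, x))
  rot <- sv$v %*% t(sv$u)
  expect_lt(sum((x %*% rot - y)^2), 1e-12)
  # agreement with the classical-scaling oracle (up to axis signs)
  cs <- stats::cmdscale(as.matrix(dist(pts)), k = 2)
  for (j in 1:2)
    expect_equal(unname(abs(emb$coords[, j])), unname(abs(cs[, j])),
                 tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(pcoa(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("scree rule finds the eigenvalue elbow, defaulting to 2", {
  expect_equal(tastecoda:::scree_dimension(c(10, 9, 1, 0.9, 0.8)), 2L)
  expect_equal(tastecoda:::scree_dimension(c(10, 2, 1.8, 1.7)), 1L)
  expect_equal(tastecoda:::scree_dimension(c(5, 4)), 2L)
  expect_equal(tastecoda:::scree_dimension(c(5)), 1L)
  # ambiguous (tied second differences) -> 2
  expect_equal(tastecoda:::scree_dimension(c(4, 3, 2, 1)), 2L)
})

test_that("euclidean_distance matches an elementwise oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(euclidean_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_error(euclidean_distance(1:2, 1:3), "dimension mismatch")
})

test_that("cs_divergence averages distances to the accepted set", {
  coords <- rbind("NaCl|d1" = c(0, 0), "sucrose|d1" = c(3, 4),
                  "KCl|d1" = c(0, 5), "QHCl_high|d1" = c(-6, -8),
                  "citric|d1" = c(0, 0), "QHCl_low|d1" = c(0, 0),
                  "water|d1" = c(0, 0))
  emb <- structure(list(coords = coords, eigenvalues = c(2, 1), d = 2L,
                        objects = rownames(coords), orientation = c(1, 1)),
                   class = "taste_pcoa")
  div <- cs_divergence(emb, days = "d1")
  expect_equal(div$mean_accepted_dist, mean(c(5, 5, 0, 0, 0)))
  expect_equal(div$dist_to_aversive, 10)
  # coincident CS and accepted stimuli -> 0
  div0 <- cs_divergence(emb, days = "d1",
                        accepted = c("citric", "QHCl_low", "water"))
  expect_equal(div0$mean_accepted_dist, 0)
  expect_error(cs_divergence(emb, days = "d1", accepted = "NaCl"), "empty")
  expect_error(cs_divergence(emb, days = "d2"), "not in embedding")
})

test_that("orientation flips dimension 1 toward positive lick correlation", {
  coords <- cbind(c(-3, -1, 1, 3), c(0, 0, 0, 0))
  rownames(coords) <- paste0(c("a", "b", "c", "d"), "|day")
  emb <- structure(list(coords = coords, eigenvalues = c(2, 1), d = 2L,
                        objects = rownames(coords),
                        orientation = c(1, 1)), class = "taste_pcoa")
  licks <- c(a = 30, b = 20, c = 10, d = 0)  # licks decrease along dim 1
  oc <- orient_and_correlate(emb, licks, "day")
  expect_equal(oc$r, 1)                      # after flipping
  expect_equal(oc$embedding$orientation[1], -1)
  expect_equal(unname(oc$dim1), c(3, 1, -1, -3))
  expect_equal(oc$slope * oc$dim1[["a"]] + oc$intercept, 30)
  # constant licks -> undefined correlation, reported as NA
  oc0 <- orient_and_correlate(emb, c(a = 5, b = 5, c = 5, d = 5), "day")
  expect_true(is.na(oc0$r))
  expect_error(orient_and_correlate(emb, c(a = 1, b = 2), "day"),
               "no lick means|fewer")
})

test_that("Lance-Williams complete linkage matches the naive oracle", {
  # 2 objects -> one merge at their distance
  hc2 <- lw_complete_linkage(matrix(c(0, 4, 4, 0), 2))
  expect_equal(hc2$height, 4)
  # points {0, 1, 10} on a line
  hc3 <- lw_complete_linkage(as.matrix(dist(c(0, 1, 10))))
  expect_equal(hc3$height, c(1, 10))
  expect_equal(hclust_members(hc3), list(c(1L, 2L), c(1L, 2L, 3L)))
  expect_error(lw_complete_linkage(matrix(0, 1, 1)), "at least 2")
  # random instances: identical merges and heights to the oracle,
  # and height sequence matches stats::hclust complete linkage
  set.seed(17)
  for (i in 1:25) {
    pts <- matrix(rnorm(16), ncol = 2)
    dm <- as.matrix(dist(pts))
    lw <- lw_complete_linkage(dm)
    oracle <- naive_complete_linkage(dm)
    expect_equal(lw$height, oracle$heights, tolerance = 1e-12)
    expect_identical(hclust_members(lw), oracle$members)
    expect_true(all(diff(lw$height) >= 0))
    hc <- stats::hclust(as.dist(dm), method = "complete")
    expect_equal(lw$height, hc$height, tolerance = 1e-12)
  }
})

test_that("embedding is equivariant under object permutation", {
  set.seed(4)
  pts <- matrix(rnorm(14), ncol = 2)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("o", 1:7)
  perm <- sample(7)
  e1 <- pcoa(dm, ndim = 2)
  e2 <- pcoa(dm[perm, perm], ndim = 2)
  d1 <- as.matrix(dist(e1$coords))
  d2 <- as.matrix(dist(e2$coords))[rownames(dm), rownames(dm)]
  expect_equal(d1, d2, tolerance = 1e-9)
})
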