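# Population geometry: pooled population vectors, principal coordinates
# analysis, Euclidean-distance trajectories and Lance-Williams clustering.

#' Pooled population vectors per stimulus and day
#'
#' One row per stimulus x day object; one column per tracked cell, pooled
#' across all animals of a group. Entries are the per-day mean dF of that
#' cell to that stimulus.
#'
#' @param day_means \code{\link{response_means}} output (tracked cells).
#' @param group Group label to pool (\code{NULL} = all rows).
#' @param stimuli,days Optional subsets; default everything present.
#' @return Numeric matrix with rownames \code{"<stimulus>|<day>"} and
#'   colnames the pooled global cell IDs.
#' @export
build_population_vectors <- function(day_means, group = NULL,
                                     stimuli = NULL, days = NULL) {
  d <- day_means
  if (!is.null(group)) d <- d[d$group == group, ]
  if (nrow(d) == 0L) stop("no rows for group: ", group)
  if (is.null(days)) days <- unique(d$day)
  if (is.null(stimuli)) {
    # default to stimuli present on every requested day (e.g. NaCl-Force
    # exists only on extinction-format days and is excluded from joint
    # embeddings unless asked for explicitly)
    per_day <- lapply(days, function(dd) unique(d$stimulus[d$day == dd]))
    stimuli <- Reduce(intersect, per_day)
  }
  d <- d[d$stimulus %in% stimuli & d$day %in% days, ]
  cells <- unique(d$cell_id)
  objects <- expand.grid(stimulus = stimuli, day = days,
                         stringsAsFactors = FALSE)
  mat <- matrix(NA_real_, nrow(objects), length(cells),
                dimnames = list(paste(objects$stimulus, objects$day,
                                      sep = "|"), cells))
  idx <- cbind(match(paste(d$stimulus, d$day, sep = "|"), rownames(mat)),
               match(d$cell_id, cells))
  mat[idx] <- d$mean_delta
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("missing stimulus-day means for ", nrow(bad),
         " cell entries (first: ", rownames(mat)[bad[1, 1]], " / ",
         cells[bad[1, 2]], ")")
  }
  attr(mat, "objects") <- objects
  mat
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres the squared distance matrix, eigendecomposes it, and
#' returns coordinates \eqn{V \Lambda^{1/2}} on the axes with positive
#' eigenvalues. Dimensionality is either fixed or chosen by the scree rule:
#' the elbow of the eigenvalue sequence, located at the largest second
#' difference, defaulting to 2 when the rule is ambiguous (ties or fewer
#' than 3 positive eigenvalues).
#'
#' @param d Distance matrix (symmetric, zero diagonal, nonnegative) or a
#'   \code{dist} object.
#' @param ndim Integer dimensionality, or \code{"scree"}.
#' @return Object of class \code{taste_pcoa}: \code{coords} (objects x all
#'   positive axes), \code{eigenvalues} (all, descending; negative ones
#'   reported but their axes discarded), \code{d} (chosen dimensionality),
#'   \code{objects} (labels), \code{orientation} (per-axis signs, all +1
#'   until \code{\link{orient_and_correlate}} flips dimension 1).
#' @export
#' @examples
#' pts <- cbind(c(0, 3), c(0, 4))
#' pcoa(as.matrix(dist(pts)))$coords  # 1-D, +/- 2.5
pcoa <- function(d, ndim = "scree") {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-10))
    stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("negative distances")
  n <- nrow(dm)
  b <- -0.5 * dm^2
  b <- sweep(b, 1L, rowMeans(b))
  b <- sweep(b, 2L, colMeans(b))
  # sequential sweeps give J (-D^2/2) J; symmetrize for eigen stability
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), nrow = length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("dim", seq_along(pos))
  ndim <- if (identical(ndim, "scree")) scree_dimension(ev[pos]) else
    min(as.integer(ndim), length(pos))
  structure(list(coords = coords, eigenvalues = ev, d = ndim,
                 objects = rownames(dm),
                 orientation = rep(1, length(pos))),
            class = "taste_pcoa")
}

# Scree elbow: index of the largest second difference of the (descending)
# positive eigenvalue sequence; 2 when ambiguous.
scree_dimension <- function(ev) {
  m <- length(ev)
  if (m < 3L) return(min(2L, m))
  s <- ev[1:(m - 2)] - 2 * ev[2:(m - 1)] + ev[3:m]
  top <- which(s == max(s))
  if (length(top) != 1L) return(2L)
  as.integer(top)
}

#' @export
print.taste_pcoa <- function(x, ...) {
  cat("taste_pcoa:", length(x$objects), "objects,",
      sum(x$eigenvalues > 0), "positive axes, chosen d =", x$d, "\n")
  invisible(x)
}

#' Euclidean distance between two coordinate vectors
#'
#' The square root of the summed squared coordinate differences, in the
#' embedding's arbitrary units.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar distance.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch")
  sqrt(sum((a - b)^2))
}

# coordinates (chosen d) of one stimulus|day object
object_coords <- function(embedding, stimulus, day) {
  lab <- paste(stimulus, day, sep = "|")
  i <- match(lab, embedding$objects)
  if (is.na(i)) stop("object not in embedding: ", lab)
  embedding$coords[i, seq_len(embedding$d)] *
    embedding$orientation[seq_len(embedding$d)]
}

#' CS divergence trajectory
#'
#' For each requested day, the arithmetic mean Euclidean distance (in the
#' chosen-dimensionality embedding) between the CS and each behaviourally
#' accepted stimulus, plus the companion distance from the CS to the
#' aversive reference (high quinine). Rising mean accepted distance after
#' conditioning, with a falling CS-quinine distance, is the geometric
#' signature of the acquired aversion; its reversal tracks extinction.
#'
#' @param embedding A \code{\link{pcoa}} result on stimulus x day objects.
#' @param days Day labels to evaluate.
#' @param cs_label Conditioned stimulus.
#' @param accepted Accepted-stimulus set; default every panel stimulus with
#'   high pretest licking except the CS, plus water.
#' @param aversive_label Aversive reference stimulus.
#' @return data.frame: \code{day}, \code{mean_accepted_dist},
#'   \code{dist_to_aversive}.
#' @export
cs_divergence <- function(embedding, days, cs_label = "NaCl",
                          accepted = c("sucrose", "KCl", "citric",
                                       "QHCl_low", "water"),
                          aversive_label = "QHCl_high") {
  accepted <- setdiff(accepted, c(cs_label, aversive_label))
  if (length(accepted) == 0L) stop("accepted set is empty")
  out <- lapply(days, function(day) {
    cs <- object_coords(embedding, cs_label, day)
    dists <- vapply(accepted, function(s)
      euclidean_distance(cs, object_coords(embedding, s, day)), 0)
    data.frame(day = day, mean_accepted_dist = mean(dists),
               dist_to_aversive = euclidean_distance(
                 cs, object_coords(embedding, aversive_label, day)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Orient dimension 1 by behaviour and correlate with licking
#'
#' Flips the sign of embedding dimension 1 if needed so that its correlation
#' with mean lick counts is positive (positive = appetitive), then reports
#' the Pearson correlation and simple-regression fit between the oriented
#' dimension-1 coordinate of every stimulus on one day and that stimulus's
#' mean licks.
#'
#' @param embedding A \code{\link{pcoa}} result on stimulus x day objects.
#' @param lick_means Named numeric: mean licks per trial per stimulus.
#' @param day Day label.
#' @return List: \code{embedding} (orientation updated), \code{dim1}
#'   (oriented values, named by stimulus), \code{licks}, \code{r},
#'   \code{slope}, \code{intercept}, \code{r_squared}. With constant licks
#'   \code{r} is \code{NA}.
#' @export
orient_and_correlate <- function(embedding, lick_means, day) {
  labs <- embedding$objects
  sel <- grepl(paste0("\\|", day, "$"), labs)
  stim <- sub("\\|.*$", "", labs[sel])
  if (length(stim) < 3L) stop("fewer than 3 stimuli on day ", day)
  miss <- setdiff(stim, names(lick_means))
  if (length(miss))
    stop("no lick means for: ", paste(miss, collapse = ", "))
  x <- embedding$coords[sel, 1L] * embedding$orientation[1L]
  y <- unname(lick_means[stim])
  if (sd(y) == 0) {
    return(list(embedding = embedding, dim1 = setNames(x, stim), licks = y,
                r = NA_real_, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  r <- cor(x, y)
  if (!is.na(r) && r < 0) {
    embedding$orientation[1L] <- -embedding$orientation[1L]
    x <- -x
    r <- -r
  }
  fit <- suppressWarnings(lm(y ~ x))  # exact fits are legitimate here
  list(embedding = embedding, dim1 = setNames(x, stim), licks = y, r = r,
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit))$r.squared)
}

#' Agglomerative clustering via the Lance-Williams update, complete linkage
#'
#' Successive nearest-pair merges where the dissimilarity of a merged
#' cluster \eqn{(ij)} to any other cluster \eqn{k} follows the
#' Lance-Williams recurrence with complete-linkage coefficients
#' (\eqn{\alpha_i = \alpha_j = 0.5}, \eqn{\beta = 0}, \eqn{\gamma = 0.5}),
#' i.e. the maximum pairwise dissimilarity. Ties break to the first pair in
#' row-major order.
#'
#' @param d Distance matrix or \code{dist} object (n >= 2 objects).
#' @return An \code{hclust}-compatible object (\code{merge}, \code{height},
#'   \code{order}, \code{labels}, \code{method = "complete"}).
#' @export
lw_complete_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 objects")
  labels <- rownames(dm)
  active <- rep(TRUE, n)
  id <- -(1:n)                 # hclust convention: negatives are singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(dm) <- Inf
  dm[lower.tri(dm)] <- Inf     # search upper triangle only
  work <- dm
  for (step in seq_len(n - 1L)) {
    pos <- which(work == min(work[active, active]), arr.ind = TRUE)
    pos <- pos[pos[, 1] < pos[, 2] & active[pos[, 1]] & active[pos[, 2]], ,
               drop = FALSE]
    i <- pos[1, 1]; j <- pos[1, 2]
    height[step] <- work[i, j]
    merge[step, ] <- sort_pair(id[i], id[j])
    for (k in which(active)) {
      if (k == i || k == j) next
      dik <- work[min(i, k), max(i, k)]
      djk <- work[min(j, k), max(j, k)]
      dnew <- 0.5 * dik + 0.5 * djk + 0.5 * abs(dik - djk)
      work[min(i, k), max(i, k)] <- dnew
    }
    active[j] <- FALSE
    work[j, ] <- Inf
    work[, j] <- Inf
    id[i] <- step
  }
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge, n), labels = labels,
                 method = "complete", call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

sort_pair <- function(a, b) {
  # hclust orders each merge row: singletons (negative) first, then by value
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) || (a > 0 && b < 0))
    c(b, a) else c(a, b)
}

dendrogram_order <- function(merge, n) {
  leaves <- function(row) {
    out <- integer()
    for (v in merge[row, ]) {
      out <- c(out, if (v < 0) -v else leaves(v))
    }
    out
  }
  leaves(n - 1L)
}
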