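# Breadth-of-tuning entropy and stimulus-best unit analysis.

#' Breadth-of-tuning entropy
#'
#' Entropy of a cell's response profile over \code{n} stimuli,
#' \deqn{H = -K \sum_i p_i \log_{10} p_i, \qquad K = 1/\log_{10}(n),}
#' the taste-literature convention (for the 4 basic tastes K = 1.661).
#' Responses are clipped at zero before normalizing to proportions
#' \code{p_i} (entropy considers positive responses only); \code{0 log 0}
#' is treated as 0. H is 0 for a cell responding to a single stimulus and 1
#' for equal responses to all.
#'
#' @param responses Numeric vector of mean dF values over the stimuli.
#' @return H in [0, 1], or \code{NA} if no response is positive (such cells
#'   are excluded from entropy means).
#' @export
#' @examples
#' taste_entropy(c(1, 0, 0, 0))    # 0
#' taste_entropy(c(2, 2, 2, 2))    # 1
taste_entropy <- function(responses) {
  p <- pmax(responses, 0)
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- p[p > 0] / tot
  k <- 1 / log10(length(responses))
  h <- -k * sum(p * log10(p))
  min(max(h, 0), 1)
}

#' Tuning profiles (entropy + best stimulus) per cell and day
#'
#' Computes, for every cell and day, the response vector over the 4 basic
#' tastes, its entropy, and the best (argmax) stimulus with ties broken by
#' the fixed panel order (sucrose, NaCl, citric, QHCl_high); ties are
#' counted in the \code{"ties"} attribute.
#'
#' @param day_means \code{\link{response_means}} output.
#' @param tastes Stimulus set (default \code{\link{basic_tastes}}).
#' @return data.frame: \code{animal_id}, \code{group}, \code{day},
#'   \code{cell_id}, one response column per taste, \code{entropy},
#'   \code{best_stimulus}, \code{unit} (S-/N-/C-/Q-Unit for basic tastes).
#' @export
tuning_profiles <- function(day_means, tastes = basic_tastes()) {
  sub <- day_means[day_means$stimulus %in% tastes, ]
  wide <- stats::reshape(
    sub[, c("animal_id", "group", "day", "cell_id", "stimulus",
            "mean_delta")],
    idvar = c("animal_id", "group", "day", "cell_id"),
    timevar = "stimulus", direction = "wide")
  resp_cols <- paste0("mean_delta.", tastes)
  missing <- setdiff(resp_cols, colnames(wide))
  if (length(missing))
    stop("missing stimuli in response table: ",
         paste(sub("mean_delta\\.", "", missing), collapse = ", "))
  rmat <- as.matrix(wide[, resp_cols])
  colnames(rmat) <- tastes
  n_max <- rowSums(rmat == apply(rmat, 1L, max))
  best <- tastes[apply(rmat, 1L, which.max)]
  out <- wide[, c("animal_id", "group", "day", "cell_id")]
  out <- cbind(out, as.data.frame(rmat))
  out$entropy <- apply(rmat, 1L, taste_entropy)
  out$best_stimulus <- best
  out$unit <- unname(unit_labels()[best])
  rownames(out) <- NULL
  attr(out, "ties") <- sum(n_max > 1L)
  out
}

#' Assign stimulus-best unit labels on a reference day
#'
#' Groups cells by their strongest response to the 4 basic tastes on the
#' reference day (default the second pre-conditioning test day), yielding
#' S-Unit / N-Unit / C-Unit / Q-Unit labels used for post-conditioning
#' tuning comparisons.
#'
#' @param day_means \code{\link{response_means}} output.
#' @param reference_day Day whose responses define the grouping.
#' @return data.frame: \code{animal_id}, \code{group}, \code{cell_id},
#'   \code{unit}; ties carried in the \code{"ties"} attribute.
#' @export
assign_best_stimulus <- function(day_means, reference_day = "pretest2") {
  ref <- day_means[day_means$day == reference_day, ]
  if (nrow(ref) == 0L) stop("reference day not present: ", reference_day)
  prof <- tuning_profiles(ref)
  out <- prof[, c("animal_id", "group", "cell_id", "unit")]
  attr(out, "ties") <- attr(prof, "ties")
  out
}

#' Post-conditioning tuning-shift table for N-Units and Q-Units
#'
#' Mean post-conditioning response of N-Units and Q-Units (labelled on the
#' reference day) to the CS and to quinine, split by experimental group:
#' the 2 x 2 x 2 comparison that dissociates re-tuning (Q-Units acquiring
#' and N-Units losing CS sensitivity in CTA animals) from unchanged quinine
#' tuning. Cell-level values are returned alongside for downstream tests.
#'
#' @param labels \code{\link{assign_best_stimulus}} output.
#' @param day_means \code{\link{response_means}} output.
#' @param post_day Post-conditioning day to quantify (default
#'   \code{"posttest1"}).
#' @param cs_label,aversive_label Stimulus labels.
#' @return List: \code{table} (group x unit x stimulus mean dF with cell
#'   counts; empty classes give \code{NA}), \code{cells} (per-cell rows).
#' @export
tuning_shift_table <- function(labels, day_means, post_day = "posttest1",
                               cs_label = "NaCl",
                               aversive_label = "QHCl_high") {
  post <- day_means[day_means$day == post_day &
                      day_means$stimulus %in% c(cs_label, aversive_label), ]
  merged <- merge(post, labels[, c("animal_id", "cell_id", "unit")],
                  by = c("animal_id", "cell_id"))
  cells <- merged[merged$unit %in% c("N-Unit", "Q-Unit"),
                  c("animal_id", "group", "cell_id", "unit", "stimulus",
                    "mean_delta")]
  combos <- expand.grid(group = unique(cells$group),
                        unit = c("N-Unit", "Q-Unit"),
                        stimulus = c(cs_label, aversive_label),
                        stringsAsFactors = FALSE)
  combos$n_cells <- NA_integer_
  combos$mean_response <- NA_real_
  for (i in seq_len(nrow(combos))) {
    sel <- cells$group == combos$group[i] & cells$unit == combos$unit[i] &
      cells$stimulus == combos$stimulus[i]
    combos$n_cells[i] <- sum(sel)
    combos$mean_response[i] <- mean_or_na(cells$mean_delta[sel])
  }
  list(table = combos, cells = cells)
}
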