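# Per-participant bias estimators and accuracy measures for the matched-pair
# continuous-report design. All estimators consume the trials of ONE
# participant; cross-participant aggregation happens in the pipeline, so the
# statistically unsound "average ratios across participants first" route
# cannot be invoked by accident.

# Split one participant's trials into aligned larger/smaller report vectors.
pair_align <- function(trials) {
  trials$context <- tolower(as.character(trials$context))
  if (length(unique(trials$participant_id)) > 1L) {
    stop_config("bias estimators take the trials of a single participant")
  }
  larger <- trials[trials$context == "larger", ]
  smaller <- trials[trials$context == "smaller", ]
  pairs <- sort(unique(trials$pair_id))
  if (anyDuplicated(larger$pair_id) || anyDuplicated(smaller$pair_id) ||
      !setequal(larger$pair_id, pairs) || !setequal(smaller$pair_id, pairs)) {
    stop_config("incomplete or duplicated matched pairs: each pair needs exactly ",
                "one 'larger' and one 'smaller' trial")
  }
  list(
    larger = larger$reported_size_px[match(pairs, larger$pair_id)],
    smaller = smaller$reported_size_px[match(pairs, smaller$pair_id)]
  )
}

check_positive_reports <- function(al) {
  if (any(al$larger <= 0) || any(al$smaller <= 0)) {
    stop_config("ratio-based bias requires strictly positive reported sizes")
  }
  al
}

#' Bias estimators for one participant
#'
#' Three ways to score the matched-pair bias from one participant's trials.
#' `bias_difference()` is the mean over pairs of (larger-context report minus
#' smaller-context report); because averaging and differencing commute it
#' equals the difference of the two context means exactly, and its null value
#' is 0 px. `bias_ratio_of_averages()` divides the mean larger-context report
#' by the mean smaller-context report; `bias_averaging_ratios()` averages the
#' per-pair ratios. Both ratio scores have null value 1 and, by Jensen's
#' inequality, exceed 1 in expectation under the null on noisy data — the
#' source of the inflated type-I error that [alpha_error()] quantifies.
#'
#' @param trials Data frame of one participant's trials in the experiment
#'   table schema: one `larger` and one `smaller` trial per `pair_id`.
#' @return A single numeric bias value (pixels for the difference score,
#'   dimensionless for the ratio scores).
#' @examples
#' t1 <- data.frame(participant_id = 1, pair_id = c(1, 1, 2, 2),
#'                  context = c("larger", "smaller", "larger", "smaller"),
#'                  true_size_px = c(48, 48, 29, 29),
#'                  reported_size_px = c(50, 46, 30, 28))
#' bias_difference(t1)        # (4 + 2)/2 = 3
#' bias_ratio_of_averages(t1) # 40/37
#' bias_averaging_ratios(t1)  # (50/46 + 30/28)/2
#' @export
bias_difference <- function(trials) {
  al <- pair_align(trials)
  mean(al$larger - al$smaller)
}

#' @rdname bias_difference
#' @export
bias_ratio_of_averages <- function(trials) {
  al <- check_positive_reports(pair_align(trials))
  mean(al$larger) / mean(al$smaller)
}

#' @rdname bias_difference
#' @export
bias_averaging_ratios <- function(trials) {
  al <- check_positive_reports(pair_align(trials))
  mean(al$larger / al$smaller)
}

#' Null reference value of a bias method
#'
#' @param method One of `"difference"`, `"ratio_of_averages"`,
#'   `"averaging_ratios"`.
#' @return 0 for the difference score, 1 for the ratio scores.
#' @export
bias_null_value <- function(method) {
  method <- match.arg(method, c("difference", "ratio_of_averages", "averaging_ratios"))
  if (method == "difference") 0 else 1
}

bias_fun <- function(method) {
  switch(match.arg(method, c("difference", "ratio_of_averages", "averaging_ratios")),
         difference = bias_difference,
         ratio_of_averages = bias_ratio_of_averages,
         averaging_ratios = bias_averaging_ratios)
}

#' Per-participant bias for a whole experiment table
#'
#' Applies one bias estimator participant-wise.
#'
#' @param table An experiment table (validated on entry).
#' @param method Bias estimator name; see [bias_null_value()].
#' @return Tidy data frame `participant_id, method, bias, null_value`, one
#'   row per participant, in order of first appearance.
#' @export
participant_bias <- function(table, method = "difference") {
  table <- validate_experiment_table(table)
  f <- bias_fun(method)
  ids <- unique(table$participant_id)
  vals <- vapply(ids, function(pid) f(table[table$participant_id == pid, ]),
                 numeric(1))
  data.frame(participant_id = ids, method = method, bias = vals,
             null_value = bias_null_value(method), row.names = NULL)
}

#' Accuracy of one participant's reports
#'
#' `mean_absolute_error()` is the mean over trials of |reported - true| in
#' pixels. `chance_mae()` is its empirical-chance counterpart: the responses
#' are re-paired with the true sizes of randomly chosen trials (a uniform
#' random permutation of the truths) and the MAE of that pairing is
#' returned. With `method = "derangement"` the permutation is resampled
#' until it has no fixed point; the default keeps fixed points (the
#' difference is O(1/n)).
#'
#' @param trials Data frame of one participant's trials (>= 1 trial for the
#'   MAE, >= 2 for the chance MAE).
#' @param seed Integer seed for the permutation draw, or `NULL`.
#' @param method `"permutation"` (default) or `"derangement"`.
#' @return MAE in pixels (a single number).
#' @export
mean_absolute_error <- function(trials) {
  if (nrow(trials) < 1L) stop_config("mean_absolute_error needs at least one trial")
  mean(abs(trials$reported_size_px - trials$true_size_px))
}

#' @rdname mean_absolute_error
#' @export
chance_mae <- function(trials, seed = NULL, method = c("permutation", "derangement")) {
  method <- match.arg(method)
  n <- nrow(trials)
  if (n < 2L) stop_config("chance_mae needs at least two trials to re-pair")
  perm <- with_seed(seed, {
    p <- sample.int(n)
    if (method == "derangement") {
      while (any(p == seq_len(n))) p <- sample.int(n)
    }
    p
  })
  mean(abs(trials$reported_size_px - trials$true_size_px[perm]))
}

#' Per-participant accuracy summary for a whole table
#'
#' One MAE and one chance-MAE draw per participant. Chance permutations are
#' drawn from per-participant seeds derived deterministically from `seed`
#' (participants keep their chance value if others are added or removed).
#'
#' @param table An experiment table.
#' @param seed Top-level integer seed fanned out per participant.
#' @inheritParams chance_mae
#' @return Data frame `participant_id, mae_px, chance_mae_px`.
#' @export
participant_accuracy <- function(table, seed = NULL,
                                 method = c("permutation", "derangement")) {
  method <- match.arg(method)
  table <- validate_experiment_table(table)
  ids <- unique(table$participant_id)
  res <- lapply(seq_along(ids), function(i) {
    sub <- table[table$participant_id == ids[i], ]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    c(mae = mean_absolute_error(sub),
      chance = chance_mae(sub, seed = sub_seed, method = method))
  })
  m <- do.call(rbind, res)
  data.frame(participant_id = ids, mae_px = m[, "mae"],
             chance_mae_px = m[, "chance"], row.names = NULL)
}
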