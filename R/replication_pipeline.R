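# The pre-planned analysis of the registered replication, end to end, on
# any balanced experiment table: accuracy-versus-chance test, difference-
# score bias t-test with Cohen's dz, JZS Bayesian t-test, posterior
# credible interval for mean bias, proportion of positively biased
# participants, and a rerun on the sanity subset (participants with MAE
# below a pixel threshold).

#' Run the pre-planned replication analysis
#'
#' Computes, in order: per-participant mean absolute error and one
#' chance-MAE draw each (responses re-paired with permuted true sizes);
#' a paired two-sided t-test of actual versus chance MAE; per-participant
#' bias (difference score by default — the registered choice; the ratio
#' estimators are available for comparison runs only via `bias_method`);
#' the two-sided one-sample t-test of bias against its null value with
#' Cohen's dz and 95% CI; the JZS Bayes factor from that t and n; the
#' Gibbs posterior for mean bias with its 95% credible interval; the
#' proportion of participants with bias above the null; and a rerun of the
#' bias t-test and Bayes factor on the subset with MAE strictly below
#' `sanity_threshold`. All randomness (chance permutations, posterior
#' sampling) fans out deterministically from `seed`.
#'
#' @param table An experiment table (validated on entry).
#' @param rscale Cauchy prior scale for the Bayesian t-test and posterior.
#' @param sanity_threshold MAE cutoff in pixels for the sanity subset.
#' @param n_iterations Posterior sampling iterations (>= 10,000).
#' @param seed Top-level integer seed.
#' @param bias_method Bias estimator; the pipeline default is the
#'   difference score.
#' @return Object of class `replication_report`; see Details for fields.
#' @details Fields: `n_participants`; `accuracy` (list: per-participant
#'   table, mean/SE of both MAEs, paired `one_sample_t` on actual - chance);
#'   `bias` (per-participant values, mean, se); `bias_test`
#'   (`one_sample_t`); `bayes` (`jzs_bf`); `posterior` (`jzs_posterior`);
#'   `prop_positive`; `sanity` (list with `threshold_px`, `n_retained`,
#'   `prop_retained`, and — when at least two participants survive —
#'   `bias_test`, `bayes`, `bias_mean`, `bias_se`; otherwise
#'   `available = FALSE`); `rscale`; `seed`.
#' @examples
#' tab <- generate_experiment(generator_config(40, bias_shift = 0.67, seed = 2))
#' rep <- run_replication_analysis(tab, n_iterations = 10000, seed = 2)
#' print(rep)
#' @export
run_replication_analysis <- function(table, rscale = sqrt(2) / 2,
                                     sanity_threshold = 25,
                                     n_iterations = 100000, seed = NULL,
                                     bias_method = "difference") {
  table <- validate_experiment_table(table)
  ids <- unique(table$participant_id)
  if (length(ids) < 2L) stop_config("the analysis needs at least 2 participants")

  acc <- participant_accuracy(table, seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  accuracy_test <- one_sample_t(acc$mae_px - acc$chance_mae_px, 0)

  pb <- participant_bias(table, method = bias_method)
  null_value <- bias_null_value(bias_method)
  bias_test <- one_sample_t(pb$bias, null_value)
  bayes <- jzs_bf10(bias_test$t, bias_test$n, rscale)
  posterior <- jzs_posterior(values = pb$bias, rscale = rscale,
                             n_iterations = n_iterations,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
  prop_positive <- mean(pb$bias > null_value)

  keep <- acc$participant_id[acc$mae_px < sanity_threshold]
  sanity <- list(threshold_px = sanity_threshold,
                 n_retained = length(keep),
                 prop_retained = length(keep) / length(ids))
  if (length(keep) >= 2L && stats::sd(pb$bias[pb$participant_id %in% keep]) > 0) {
    sb <- pb$bias[pb$participant_id %in% keep]
    sanity$available <- TRUE
    sanity$bias_mean <- mean(sb)
    sanity$bias_se <- stats::sd(sb) / sqrt(length(sb))
    sanity$bias_test <- one_sample_t(sb, null_value)
    sanity$bayes <- jzs_bf10(sanity$bias_test$t, sanity$bias_test$n, rscale)
  } else {
    sanity$available <- FALSE
  }

  structure(
    list(n_participants = length(ids),
         accuracy = list(per_participant = acc,
                         mae_mean = mean(acc$mae_px),
                         mae_se = stats::sd(acc$mae_px) / sqrt(nrow(acc)),
                         chance_mean = mean(acc$chance_mae_px),
                         chance_se = stats::sd(acc$chance_mae_px) / sqrt(nrow(acc)),
                         test = accuracy_test),
         bias = list(per_participant = pb,
                     mean = bias_test$mean, se = bias_test$se,
                     method = bias_method, null_value = null_value),
         bias_test = bias_test,
         bayes = bayes,
         posterior = posterior,
         prop_positive = prop_positive,
         sanity = sanity,
         rscale = rscale,
         seed = seed),
    class = "replication_report"
  )
}

#' Restrict a table to well-performing participants
#'
#' Keeps exactly the participants whose mean absolute error is strictly
#' below `threshold_px` (the boundary is excluded). May return an empty
#' table.
#'
#' @param table An experiment table.
#' @param threshold_px Positive MAE cutoff in pixels.
#' @return The subset of `table`, same schema.
#' @export
sanity_filter <- function(table, threshold_px = 25) {
  if (threshold_px <= 0) stop_config("`threshold_px` must be positive")
  table <- validate_experiment_table(table)
  ids <- unique(table$participant_id)
  mae <- vapply(ids, function(pid) {
    mean_absolute_error(table[table$participant_id == pid, ])
  }, numeric(1))
  table[table$participant_id %in% ids[mae < threshold_px], ]
}

#' Read and write experiment tables as CSV
#'
#' The on-disk schema is
#' `participant_id,pair_id,context,true_size_px,reported_size_px` with
#' context spelled `larger`/`smaller` (accepted case-insensitively and
#' normalized on load) and sizes as decimal pixels. Loading enforces every
#' experiment-table invariant and names the offending participant or
#' column on failure, so a round trip is the identity on valid tables.
#'
#' @param path CSV file path.
#' @param table An experiment table.
#' @return `read_trials_csv()`: the validated table. `write_trials_csv()`:
#'   `path`, invisibly.
#' @export
read_trials_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_experiment_table(raw)
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(table, path) {
  table <- validate_experiment_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a replication report to JSON
#'
#' Flattens every numeric summary of the report (plus the seed and
#' configuration) into a JSON record; per-participant tables and posterior
#' draws are omitted.
#'
#' @param report A `replication_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "replication_report"))
  tt <- function(x) list(t = x$t, df = x$df, p = x$p, mean = x$mean, se = x$se,
                         dz = x$dz, ci95_lo = x$ci95[1], ci95_hi = x$ci95[2])
  out <- list(
    n_participants = report$n_participants,
    accuracy = c(list(mae_mean = report$accuracy$mae_mean,
                      mae_se = report$accuracy$mae_se,
                      chance_mean = report$accuracy$chance_mean,
                      chance_se = report$accuracy$chance_se),
                 tt(report$accuracy$test)),
    bias = list(method = report$bias$method, mean = report$bias$mean,
                se = report$bias$se, null_value = report$bias$null_value),
    bias_test = tt(report$bias_test),
    bf10 = report$bayes$bf10,
    rscale = report$rscale,
    posterior = list(mean = report$posterior$mean,
                     cred_lo = report$posterior$ci95[1],
                     cred_hi = report$posterior$ci95[2],
                     n_iterations = report$posterior$n_iterations),
    prop_positive = report$prop_positive,
    sanity = if (isTRUE(report$sanity$available)) {
      c(list(threshold_px = report$sanity$threshold_px,
             n_retained = report$sanity$n_retained,
             prop_retained = report$sanity$prop_retained,
             bf10 = report$sanity$bayes$bf10),
        tt(report$sanity$bias_test))
    } else {
      list(threshold_px = report$sanity$threshold_px,
           n_retained = report$sanity$n_retained,
           available = FALSE)
    },
    seed = report$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
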