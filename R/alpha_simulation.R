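# Monte-Carlo type-I error of the one-sample t-test applied to each bias
# estimator under the null (no context shift). Repetitions are vectorized
# in chunks: all trials of a chunk of replicate experiments are drawn in one
# truncated-normal call, reshaped to (pairs x participants x reps), reduced
# to per-participant biases, and t-tested against the estimator's null
# value with the exact central t distribution.

#' Observed type-I error of a bias estimator's t-test
#'
#' Under the null (equal true sizes, no context shift, i.i.d. response
#' noise), repeatedly generates an experiment with `n_participants`,
#' computes the chosen per-participant bias, runs the two-sided one-sample
#' t-test against the estimator's null reference (0 px for the difference
#' score, 1 for the ratio scores), and records rejections at
#' `nominal_alpha`. The difference score keeps its nominal level; both
#' ratio scores inflate it — mildly for the ratio of averages at small n,
#' to the ceiling for averaging ratios — because Jensen's inequality puts
#' their null expectation above 1 while the t-test assumes it at 1.
#'
#' @param method Bias estimator: `"difference"`, `"ratio_of_averages"` or
#'   `"averaging_ratios"`.
#' @param n_participants Participants per simulated experiment.
#' @param reps Monte-Carlo repetitions (default 100,000).
#' @param nominal_alpha Intended significance level.
#' @param generator A [generator_config()] with `bias_shift = 0` supplying
#'   pair sizes, noise SD and truncation; its `n_participants` and `seed`
#'   are ignored in favor of the arguments here.
#' @param seed Integer seed.
#' @param chunk Repetitions drawn per vectorized block (memory knob, no
#'   effect on results at fixed seed and chunk).
#' @return Object of class `alpha_sim_result`: `alpha_hat` (rejection
#'   proportion), `mc_se` (binomial SE), `reps`, `method`,
#'   `n_participants`, `nominal_alpha`, `seed`.
#' @examples
#' alpha_error("difference", n_participants = 21, reps = 2000, seed = 1)
#' @export
alpha_error <- function(method = c("difference", "ratio_of_averages", "averaging_ratios"),
                        n_participants, reps = 100000, nominal_alpha = 0.05,
                        generator = generator_config(n_participants),
                        seed = NULL, chunk = 1000L) {
  method <- match.arg(method)
  if (!inherits(generator, "generator_config")) {
    stop_config("`generator` must be a generator_config()")
  }
  if (generator$bias_shift != 0) {
    stop_config("the type-I-error simulation is defined under the null: ",
                "`generator$bias_shift` must be 0")
  }
  if (reps < 1) stop_config("`reps` must be positive")
  nsub <- as.integer(n_participants)
  sizes <- generator$pair_designs$true_size_px
  k <- length(sizes)
  null_value <- bias_null_value(method)
  crit <- stats::qt(1 - nominal_alpha / 2, df = nsub - 1)

  n_rej <- with_seed(seed, {
    rej <- 0L
    done <- 0L
    while (done < reps) {
      m <- as.integer(min(chunk, reps - done))
      mu <- rep(sizes, times = nsub * m)          # pair fastest, then participant, rep
      dims <- c(k, nsub, m)
      L <- array(rnorm_trunc(mu, generator$noise_sd, generator$clip_min), dims)
      S <- array(rnorm_trunc(mu, generator$noise_sd, generator$clip_min), dims)
      # per-participant bias: (nsub x m) matrix
      b <- switch(method,
        difference = colSums(L - S) / k,
        ratio_of_averages = colSums(L) / colSums(S),
        averaging_ratios = colSums(L / S) / k)
      bbar <- colMeans(b)
      bsd <- sqrt(colSums(sweep(b, 2L, bbar)^2) / (nsub - 1))
      tstat <- (bbar - null_value) / (bsd / sqrt(nsub))
      rej <- rej + sum(abs(tstat) > crit)
      done <- done + m
    }
    rej
  })
  alpha_hat <- n_rej / reps
  structure(list(alpha_hat = alpha_hat,
                 mc_se = sqrt(alpha_hat * (1 - alpha_hat) / reps),
                 reps = as.integer(reps), method = method,
                 n_participants = nsub, nominal_alpha = nominal_alpha,
                 seed = seed),
            class = "alpha_sim_result")
}
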