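# print methods for the classed results

#' @export
print.one_sample_t <- function(x, ...) {
  cat(sprintf("One-sample t-test against %g\n", x$null_value))
  cat(sprintf("  n = %d, mean = %.4g (se %.4g)\n", x$n, x$mean, x$se))
  cat(sprintf("  t(%d) = %.3f, p = %.3g, dz = %.3f\n", x$df, x$t, x$p, x$dz))
  cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (Cauchy prior scale %.4f)\n", x$rscale))
  cat(sprintf("  t = %.4g, n = %d\n", x$t, x$n))
  cat(sprintf("  BF10 = %.6g  (log BF10 = %.4f)\n", x$bf10, x$log_bf10))
  invisible(x)
}

#' @export
print.jzs_posterior <- function(x, ...) {
  cat("JZS posterior for the mean\n")
  cat(sprintf("  %d retained iterations (burn-in %d), rscale %.4f\n",
              x$n_iterations, x$burn, x$rscale))
  cat(sprintf("  posterior mean %.4g, 95%% credible interval [%.4g, %.4g]\n",
              x$mean, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Two-sided one-sample t-test power: n = %d, d = %g, alpha = %g\n",
              x$n, x$d, x$alpha))
  cat(sprintf("  power = %.6f\n", x$power))
  invisible(x)
}

#' @export
print.bfda_result <- function(x, ...) {
  cat(sprintf("Fixed-n Bayes Factor Design Analysis (%s engine)\n", x$engine))
  cat(sprintf("  d = %g, n = %d, rscale %.4f, bounds [%g, %g]\n",
              x$d, x$n, x$rscale, x$lower_bound, x$upper_bound))
  if (x$engine == "mc") cat(sprintf("  reps = %d\n", x$reps))
  cat(sprintf("  P(BF10 >= %g)      = %.4f\n", x$upper_bound, x$p_upper))
  cat(sprintf("  P(BF10 <= %g)     = %.4f\n", x$lower_bound, x$p_lower))
  cat(sprintf("  P(inconclusive)  = %.4f\n", x$p_inconclusive))
  invisible(x)
}

#' @export
print.alpha_sim_result <- function(x, ...) {
  cat(sprintf("Type-I error of the %s bias t-test under the null\n", x$method))
  cat(sprintf("  n = %d participants, %d repetitions, nominal alpha %.3f\n",
              x$n_participants, x$reps, x$nominal_alpha))
  cat(sprintf("  observed alpha = %.4f (MC se %.5f)\n", x$alpha_hat, x$mc_se))
  invisible(x)
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("Replication analysis: %d participants, %s-score bias\n",
              x$n_participants, x$bias$method))
  cat(sprintf("  accuracy: MAE %.2f px (se %.2f) vs chance %.2f px (se %.2f); t(%d) = %.2f, p = %.3g\n",
              x$accuracy$mae_mean, x$accuracy$mae_se,
              x$accuracy$chance_mean, x$accuracy$chance_se,
              x$accuracy$test$df, x$accuracy$test$t, x$accuracy$test$p))
  cat(sprintf("  bias: M = %.3f (se %.3f); t(%d) = %.2f, p = %.3g, dz = %.3f\n",
              x$bias$mean, x$bias$se, x$bias_test$df, x$bias_test$t,
              x$bias_test$p, x$bias_test$dz))
  cat(sprintf("  BF10 = %.6g (rscale %.4f)\n", x$bayes$bf10, x$rscale))
  cat(sprintf("  posterior mean %.3f, 95%% credible interval [%.3f, %.3f]\n",
              x$posterior$mean, x$posterior$ci95[1], x$posterior$ci95[2]))
  cat(sprintf("  participants with bias > %g: %.1f%%\n",
              x$bias$null_value, 100 * x$prop_positive))
  if (isTRUE(x$sanity$available)) {
    cat(sprintf("  sanity subset (MAE < %g px): %d kept (%.1f%%); M = %.3f, t(%d) = %.2f, BF10 = %.6g\n",
                x$sanity$threshold_px, x$sanity$n_retained,
                100 * x$sanity$prop_retained, x$sanity$bias_mean,
                x$sanity$bias_test$df, x$sanity$bias_test$t,
                x$sanity$bayes$bf10))
  } else {
    cat(sprintf("  sanity subset (MAE < %g px): unavailable (%d participant(s) retained)\n",
                x$sanity$threshold_px, x$sanity$n_retained))
  }
  invisible(x)
}
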