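# Classical power analysis and fixed-n Bayes Factor Design Analysis for the
# one-sample design. Two BFDA engines: a Monte-Carlo engine that simulates
# effect-level data and evaluates the JZS Bayes factor per repetition, and a
# deterministic analytic engine that inverts the monotone map t -> BF10 at
# the evidence bounds and evaluates (non)central-t tail probabilities there.

#' Exact power of the two-sided one-sample t-test
#'
#' Power from the noncentral t distribution with df = n - 1 and
#' noncentrality `d * sqrt(n)`.
#'
#' @param n Sample size (>= 2).
#' @param d True standardized effect (Cohen's dz).
#' @param alpha Two-sided significance level.
#' @return Object of class `power_result`: list with `n`, `d`, `alpha`,
#'   `power`.
#' @examples
#' power_one_sample_t(90, 0.3)   # just above .80
#' @export
power_one_sample_t <- function(n, d, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_config("`n` must be a single integer >= 2")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_config("`alpha` must lie in (0, 1)")
  }
  q <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- d * sqrt(n)
  pow <- stats::pt(q, df = n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-q, df = n - 1, ncp = ncp)
  structure(list(n = as.integer(n), d = d, alpha = alpha, power = pow),
            class = "power_result")
}

#' Smallest n reaching a target power
#'
#' Bracket-and-bisect over integer n for the smallest sample size whose
#' exact noncentral-t power meets `target_power`. If the target does not
#' exceed `alpha`, n = 2 already suffices (the test's size is `alpha`).
#'
#' @inheritParams power_one_sample_t
#' @param target_power Required power, in (0, 1).
#' @param n_max Upper search bound guarding against unreachable targets.
#' @return Integer sample size.
#' @examples
#' required_n_power(d = 0.3)  # 90
#' @export
required_n_power <- function(d, alpha = 0.05, target_power = 0.80,
                             n_max = 1e7) {
  if (!is.numeric(target_power) || target_power <= 0 || target_power >= 1) {
    stop_config("`target_power` must lie in (0, 1)")
  }
  if (d == 0) stop_config("`d` must be nonzero (power never exceeds alpha at d = 0)")
  pow <- function(n) power_one_sample_t(n, d, alpha)$power
  if (target_power <= alpha) return(2L)
  lo <- 2L
  hi <- 4L
  while (pow(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop_config("target power unreachable below n_max = ", n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' t-statistic threshold for a Bayes-factor bound
#'
#' Inverts the strictly increasing map |t| -> BF10 at `bound`. The root may
#' not exist: at small n even t = 0 leaves BF10 above a sub-unit bound, and
#' at n = 2 the Bayes factor is bounded above so large bounds are never
#' reached. `NA` is returned in either case and the corresponding evidence
#' outcome has probability 0.
#'
#' @inheritParams jzs_bf10
#' @param bound Bayes-factor value to invert at.
#' @param t_max Upper end of the search bracket; BF10 still below a
#'   super-unit `bound` there is treated as unreachable.
#' @return The nonnegative t with BF10(t) = bound, or `NA_real_`.
#' @export
bf_threshold_t <- function(n, bound, rscale = sqrt(2) / 2, t_max = 5000) {
  f <- function(tt) log_jzs_bf10_scalar(tt, n, rscale) - log(bound)
  if (bound < 1 && f(0) > 0) return(NA_real_)
  if (bound >= 1 && f(t_max) < 0) return(NA_real_)
  stats::uniroot(f, interval = c(0, t_max), tol = 1e-9)$root
}

bfda_result <- function(p_upper, p_lower, p_inconclusive, mc_se, engine,
                        d, n, rscale, upper_bound, lower_bound, reps = NA_integer_,
                        seed = NULL) {
  structure(list(p_upper = p_upper, p_lower = p_lower,
                 p_inconclusive = p_inconclusive, mc_se = mc_se,
                 engine = engine, d = d, n = as.integer(n), rscale = rscale,
                 upper_bound = upper_bound, lower_bound = lower_bound,
                 reps = reps, seed = seed),
            class = "bfda_result")
}

check_bfda_args <- function(n, upper_bound, lower_bound, rscale) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_config("`n` must be a single integer >= 2")
  }
  if (!(lower_bound > 0 && lower_bound < 1 && upper_bound > 1)) {
    stop_config("bounds must satisfy 0 < lower_bound < 1 < upper_bound")
  }
  if (rscale <= 0) stop_config("`rscale` must be positive")
}

#' Fixed-n Bayes Factor Design Analysis
#'
#' For a one-sample design with `n` observations and true standardized
#' effect `d`, the probabilities that the JZS Bayes factor reaches the
#' upper evidence bound (BF10 >= `upper_bound`), the lower bound
#' (BF10 <= `lower_bound`), or stays between the two (inconclusive).
#' Boundary values count as meeting the bound.
#'
#' `bfda_fixed_n_mc()` simulates: per repetition, `n` draws from
#' `Normal(d, 1)`, the one-sample t statistic, and its Bayes factor; it
#' returns outcome proportions with binomial Monte-Carlo standard errors.
#' `bfda_fixed_n_analytic()` is the deterministic engine: it inverts the
#' monotone |t| -> BF10 map at the two bounds and evaluates central
#' (d = 0) or noncentral t tail probabilities at those thresholds
#' (`mc_se` = 0). The three probabilities sum to one by construction.
#'
#' @param d True standardized effect (0 under the null).
#' @param n Sample size per simulated experiment.
#' @param rscale Cauchy prior scale of the Bayes factor.
#' @param upper_bound,lower_bound Evidence bounds on BF10 (defaults 10 and
#'   0.1).
#' @param reps Monte-Carlo repetitions (>= 1,000).
#' @param seed Integer seed.
#' @return Object of class `bfda_result` with `p_upper`, `p_lower`,
#'   `p_inconclusive`, `mc_se` (named vector), and the configuration.
#' @examples
#' bfda_fixed_n_analytic(d = 0, n = 663)  # p_lower about .80
#' @export
bfda_fixed_n_mc <- function(d, n, rscale = sqrt(2) / 2,
                            upper_bound = 10, lower_bound = 0.1,
                            reps = 10000, seed = NULL) {
  check_bfda_args(n, upper_bound, lower_bound, rscale)
  if (reps < 1000) stop_config("`reps` must be at least 1,000")
  tstats <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      x <- stats::rnorm(n, mean = d, sd = 1)
      mean(x) / (stats::sd(x) / sqrt(n))
    }, numeric(1))
  })
  lbf <- log_jzs_bf10_vec(tstats, n, rscale)
  up <- lbf >= log(upper_bound)
  lo <- lbf <= log(lower_bound)
  p_up <- mean(up); p_lo <- mean(lo)
  p_in <- 1 - p_up - p_lo
  se <- function(p) sqrt(p * (1 - p) / reps)
  bfda_result(p_up, p_lo, p_in,
              mc_se = c(p_upper = se(p_up), p_lower = se(p_lo),
                        p_inconclusive = se(p_in)),
              engine = "mc", d = d, n = n, rscale = rscale,
              upper_bound = upper_bound, lower_bound = lower_bound,
              reps = as.integer(reps), seed = seed)
}

#' @rdname bfda_fixed_n_mc
#' @export
bfda_fixed_n_analytic <- function(d, n, rscale = sqrt(2) / 2,
                                  upper_bound = 10, lower_bound = 0.1) {
  check_bfda_args(n, upper_bound, lower_bound, rscale)
  t_up <- bf_threshold_t(n, upper_bound, rscale)
  t_lo <- bf_threshold_t(n, lower_bound, rscale)
  ncp <- d * sqrt(n)
  df <- n - 1
  p_up <- if (is.na(t_up)) 0 else {
    stats::pt(t_up, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-t_up, df, ncp = ncp)
  }
  p_lo <- if (is.na(t_lo)) 0 else {
    stats::pt(t_lo, df, ncp = ncp) - stats::pt(-t_lo, df, ncp = ncp)
  }
  bfda_result(p_up, p_lo, 1 - p_up - p_lo,
              mc_se = c(p_upper = 0, p_lower = 0, p_inconclusive = 0),
              engine = "analytic", d = d, n = n, rscale = rscale,
              upper_bound = upper_bound, lower_bound = lower_bound)
}

#' Smallest n meeting a BFDA outcome-probability target
#'
#' Searches (monotone bisection) for the smallest sample size at which the
#' probability of the chosen evidence outcome reaches `prob_target`. The
#' analytic engine defines the answer by default; the Monte-Carlo engine is
#' available for cross-checks but resolves required n only up to its
#' binomial noise.
#'
#' @param d True standardized effect.
#' @param side `"upper"` (probability of BF10 >= `upper_bound`) or
#'   `"lower"` (probability of BF10 <= `lower_bound`).
#' @param prob_target Required outcome probability, in (0, 1).
#' @param n_range Integer search bracket.
#' @param engine `"analytic"` or `"mc"`.
#' @inheritParams bfda_fixed_n_mc
#' @return Integer sample size.
#' @examples
#' bfda_required_n(d = 0.3, side = "upper", prob_target = 0.80)
#' @export
bfda_required_n <- function(d, side = c("upper", "lower"), prob_target = 0.80,
                            rscale = sqrt(2) / 2, upper_bound = 10,
                            lower_bound = 0.1, n_range = c(2L, 5000L),
                            engine = c("analytic", "mc"), reps = 10000,
                            seed = NULL) {
  side <- match.arg(side)
  engine <- match.arg(engine)
  if (prob_target <= 0 || prob_target >= 1) {
    stop_config("`prob_target` must lie in (0, 1)")
  }
  prob_at <- function(n) {
    r <- if (engine == "analytic") {
      bfda_fixed_n_analytic(d, n, rscale, upper_bound, lower_bound)
    } else {
      bfda_fixed_n_mc(d, n, rscale, upper_bound, lower_bound, reps = reps,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, n))
    }
    if (side == "upper") r$p_upper else r$p_lower
  }
  lo <- as.integer(n_range[1L]); hi <- as.integer(n_range[2L])
  if (prob_at(lo) >= prob_target) return(lo)
  if (prob_at(hi) < prob_target) {
    stop_config("probability target ", prob_target, " unreachable for side '",
                side, "' within n_range [", lo, ", ", hi, "]")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (prob_at(mid) >= prob_target) hi <- mid else lo <- mid
  }
  hi
}
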