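# One-sample t-test machinery: classical test with Cohen's dz, the JZS
# default Bayes factor (zero-centered Cauchy prior on the standardized
# effect), and a Gibbs sampler for the posterior of the mean under the same
# model.

#' One-sample t-test with Cohen's dz
#'
#' Standard two-sided one-sample t-test of `values` against `null_value`,
#' augmented with the standardized effect size dz = (mean - null)/sd, which
#' satisfies dz = t/sqrt(n).
#'
#' @param values Numeric sample (n >= 2, nonzero variance).
#' @param null_value Null constant tested against (0 for difference-score
#'   bias, 1 for ratio bias).
#' @return Object of class `one_sample_t`: list with `t`, `df`, `p`, `n`,
#'   `mean`, `sd`, `se`, `dz`, `ci95` (length-2), `null_value`.
#' @examples
#' one_sample_t(c(1, 2, 3))  # t = 2*sqrt(3)
#' @export
one_sample_t <- function(values, null_value = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop_config("one_sample_t needs n >= 2")
  if (stats::sd(values) == 0) stop_config("one_sample_t needs nonzero sample variance")
  ht <- stats::t.test(values, mu = null_value, alternative = "two.sided",
                      conf.level = 0.95)
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, n = n,
         mean = mean(values), sd = stats::sd(values),
         se = stats::sd(values) / sqrt(n),
         dz = (mean(values) - null_value) / stats::sd(values),
         ci95 = unname(ht$conf.int), null_value = null_value),
    class = "one_sample_t"
  )
}

# log integrand of the JZS alternative marginal over g, already divided by
# the null likelihood, in the bounded variable z = log(g): the integrand's
# width in z is O(1) for every t and n, so the adaptive integrator resolves
# it even when the g-space peak (near t^2/n) is extreme.
# The Cauchy(0, rscale) prior on the standardized effect is represented as
# delta | g ~ N(0, g), g ~ InvGamma(1/2, rscale^2/2).
jzs_log_integrand <- function(z, t, n, rscale) {
  g <- exp(z)
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  -0.5 * log1p(n * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
    log_null +
    0.5 * log(rscale^2 / 2) - lgamma(0.5) -
    1.5 * z - rscale^2 / (2 * g) +
    z                                    # jacobian dg = g dz
}

log_jzs_bf10_scalar <- function(t, n, rscale) {
  # locate the peak on a coarse z-grid, offset by its height so exp() never
  # overflows (BF can reach e^900), and integrate the two half-lines either
  # side of the peak
  z_hi <- 2 * log(abs(t) + 10) + 20
  zg <- seq(-40, z_hi, length.out = 513L)
  lg <- jzs_log_integrand(zg, t, n, rscale)
  C <- max(lg)
  z_peak <- zg[which.max(lg)]
  f <- function(z) exp(jzs_log_integrand(z, t, n, rscale) - C)
  q1 <- stats::integrate(f, lower = -Inf, upper = z_peak,
                         rel.tol = 1e-10, subdivisions = 500L)
  q2 <- stats::integrate(f, lower = z_peak, upper = Inf,
                         rel.tol = 1e-10, subdivisions = 500L)
  if (q1$message != "OK" || q2$message != "OK" || q1$value + q2$value <= 0) {
    stop_config("JZS quadrature failed to converge: ", q1$message, "/", q2$message)
  }
  if ((q1$abs.error + q2$abs.error) / (q1$value + q2$value) > 1e-6) {
    stop_config("JZS quadrature above the 1e-6 relative-error budget")
  }
  C + log(q1$value + q2$value)
}

#' JZS default Bayes factor for a one-sample t-test
#'
#' Evidence for a nonzero standardized effect over the point null, computed
#' from the sufficient statistics (t, n). The alternative places a
#' zero-centered Cauchy prior with scale `rscale` on the standardized
#' effect; the marginal likelihood is obtained by one-dimensional quadrature
#' over the normal-by-inverse-gamma mixture representation of that prior,
#' mapped to a bounded interval (relative integration error below 1e-6,
#' evaluated on the log scale so very large Bayes factors keep full
#' precision). BF10 > 1 favors the alternative.
#'
#' @param t Observed t statistic.
#' @param n Sample size (>= 2).
#' @param rscale Cauchy prior scale; the default `sqrt(2)/2` is the
#'   conventional "medium" width.
#' @return Object of class `jzs_bf`: list with `bf10`, `log_bf10`, `t`,
#'   `n`, `df`, `rscale`.
#' @examples
#' jzs_bf10(t = 5.83, n = 663)
#' @export
jzs_bf10 <- function(t, n, rscale = sqrt(2) / 2) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_config("`n` must be a single integer >= 2")
  }
  if (!is.numeric(rscale) || length(rscale) != 1L || rscale <= 0) {
    stop_config("`rscale` must be a single positive number")
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop_config("`t` must be a single finite number")
  }
  lb <- log_jzs_bf10_scalar(t, n, rscale)
  structure(list(bf10 = exp(lb), log_bf10 = lb, t = t, n = n,
                 df = n - 1, rscale = rscale),
            class = "jzs_bf")
}

#' @rdname jzs_bf10
#' @param values Raw sample; its t statistic against `null_value` is used.
#' @param null_value Null constant for the raw-values interface.
#' @export
jzs_bf10_values <- function(values, null_value = 0, rscale = sqrt(2) / 2) {
  tt <- one_sample_t(values, null_value)
  jzs_bf10(tt$t, tt$n, rscale)
}

# vectorized log BF over a t grid (internal; used by the MC design analysis)
log_jzs_bf10_vec <- function(t, n, rscale) {
  vapply(t, log_jzs_bf10_scalar, numeric(1), n = n, rscale = rscale)
}

#' Posterior of the mean under the JZS one-sample model
#'
#' Gibbs sampler for the model `y_i ~ N(mu, sigma^2)` with the JZS prior:
#' `mu | sigma^2, g ~ N(0, g * sigma^2)`, Jeffreys prior on `sigma^2`, and
#' `g ~ InvGamma(1/2, rscale^2/2)` (equivalently a Cauchy prior with scale
#' `rscale` on the standardized effect `mu/sigma`). The three full
#' conditionals are conjugate and sampled alternately; the first 10% of
#' iterations are discarded as burn-in. The location draws are returned in
#' the input's units (pixels, for bias values).
#'
#' @param values Numeric sample (n >= 2); or `NULL` when sufficient
#'   statistics are supplied.
#' @param rscale Cauchy prior scale.
#' @param n_iterations Retained sampling iterations (>= 10,000).
#' @param seed Integer seed, or `NULL`.
#' @param n,mean,sd Sufficient statistics, used when `values` is `NULL`.
#' @param keep_draws If `TRUE`, the retained location draws are attached as
#'   `$draws`.
#' @return Object of class `jzs_posterior`: `mean` (posterior mean of the
#'   location), `ci95` (central 95% credible interval), `median`,
#'   `n_iterations`, `burn`, `rscale`, `seed`, and optionally `draws`.
#' @examples
#' jzs_posterior(n = 663, mean = 1.34, sd = 5.922, n_iterations = 10000, seed = 1)
#' @export
jzs_posterior <- function(values = NULL, rscale = sqrt(2) / 2,
                          n_iterations = 100000, seed = NULL,
                          n = NULL, mean = NULL, sd = NULL,
                          keep_draws = FALSE) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(n) || is.null(mean) || is.null(sd)) {
    stop_config("supply `values` or all of `n`, `mean`, `sd`")
  }
  if (n < 2L) stop_config("jzs_posterior needs n >= 2")
  if (!is.finite(sd) || sd <= 0) stop_config("`sd` must be positive")
  if (n_iterations < 10000) {
    stop_config("`n_iterations` must be at least 10,000 for stable summaries")
  }
  burn <- as.integer(ceiling(n_iterations / 9))  # 10% of the total run
  total <- n_iterations + burn
  ss <- (n - 1) * sd^2
  draws <- with_seed(seed, {
    mu <- mean; sig2 <- sd^2; g <- 1
    out <- numeric(n_iterations)
    for (i in seq_len(total)) {
      prec <- n + 1 / g
      mu <- stats::rnorm(1L, n * mean / prec, sqrt(sig2 / prec))
      ssr <- ss + n * (mean - mu)^2 + mu^2 / g
      sig2 <- 1 / stats::rgamma(1L, (n + 1) / 2, rate = ssr / 2)
      g <- 1 / stats::rgamma(1L, 1, rate = (mu^2 / sig2 + rscale^2) / 2)
      if (i > burn) out[i - burn] <- mu
    }
    out
  })
  res <- list(mean = base::mean(draws),
              median = stats::median(draws),
              ci95 = unname(stats::quantile(draws, c(0.025, 0.975))),
              n_iterations = as.integer(n_iterations), burn = burn,
              rscale = rscale, seed = seed, n = as.integer(n))
  if (keep_draws) res$draws <- draws
  structure(res, class = "jzs_posterior")
}
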