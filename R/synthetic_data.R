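#' Default matched-pair stimulus designs
#'
#' The matched-pair design probes the same circle twice — once surrounded by
#' larger same-colored circles, once by smaller ones — with an identical true
#' probe size in both contexts. The default set spans 15 pairs with probe
#' sizes evenly spaced from 20 to 90 pixels (step 5 px), a stand-in for the
#' original stimulus set whose exact diameters are not published; the probe's
#' random initial diameter in the task was bounded at 15--95 px.
#'
#' @return A data frame with columns `pair_id` (integer 1..15) and
#'   `true_size_px` (probe diameter in pixels).
#' @examples
#' default_pair_designs()
#' @export
default_pair_designs <- function() {
  data.frame(pair_id = 1:15, true_size_px = seq(20, 90, by = 5))
}

#' Configuration for the synthetic experiment generator
#'
#' Bundles and validates every parameter of the trial-level generator. The
#' generator works at the response level: it injects a signed half-shift
#' `bias_shift` per context (larger context +shift, smaller context -shift)
#' plus i.i.d. Gaussian response noise, so the per-participant difference
#' score equals `2 * bias_shift` in the noise-free limit. `bias_shift = 0`
#' is the null hypothesis of the type-I-error simulations.
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param pair_designs Data frame of matched pairs as returned by
#'   [default_pair_designs()]: unique `pair_id`, positive `true_size_px`.
#' @param bias_shift Signed per-context half-shift in pixels; 0 under the null.
#' @param noise_sd Response-noise standard deviation in pixels (> 0). The
#'   default 21 px calibrates the expected mean absolute error to
#'   `21 * sqrt(2/pi)` (about 16.75 px), matching well-performing responders.
#' @param clip_min Lower truncation for reported sizes in pixels (> 0);
#'   violations are redrawn, keeping the noise distribution smooth. Ratio
#'   estimators require strictly positive reports.
#' @param seed Integer seed making the generated table reproducible, or
#'   `NULL` to use the current RNG stream.
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_experiment()], [read_generator_config()]
#' @export
generator_config <- function(n_participants,
                             pair_designs = default_pair_designs(),
                             bias_shift = 0,
                             noise_sd = 21,
                             clip_min = 1,
                             seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      n_participants < 1 || n_participants != round(n_participants)) {
    stop_config("`n_participants` must be a single positive integer")
  }
  if (!is.data.frame(pair_designs) ||
      !all(c("pair_id", "true_size_px") %in% names(pair_designs))) {
    stop_config("`pair_designs` needs columns `pair_id` and `true_size_px`")
  }
  if (anyDuplicated(pair_designs$pair_id)) {
    stop_config("`pair_designs$pair_id` must be unique")
  }
  if (any(pair_designs$true_size_px <= 0)) {
    stop_config("`true_size_px` must be strictly positive")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_config("`noise_sd` must be a single positive number")
  }
  if (!is.numeric(clip_min) || length(clip_min) != 1L || clip_min <= 0) {
    stop_config("`clip_min` must be strictly positive (ratio estimators need positive reports)")
  }
  if (!is.numeric(bias_shift) || length(bias_shift) != 1L || !is.finite(bias_shift)) {
    stop_config("`bias_shift` must be a single finite number")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         pair_designs = pair_designs[order(pair_designs$pair_id),
                                     c("pair_id", "true_size_px")],
         bias_shift = bias_shift,
         noise_sd = noise_sd,
         clip_min = clip_min,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config"
  )
}

# Draw `length(mu)` truncated-normal responses by redrawing violations.
rnorm_trunc <- function(mu, sd, lower) {
  x <- stats::rnorm(length(mu), mu, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rnorm(sum(bad), mu[bad], sd)
  }
  x
}

#' Generate a synthetic matched-pair experiment
#'
#' Simulates a balanced continuous-report experiment: every participant
#' contributes exactly one trial per (pair, context), with
#' `reported = true + bias_shift + noise` in the larger-group context and
#' `reported = true - bias_shift + noise` in the smaller-group context,
#' noise i.i.d. `Normal(0, noise_sd)` truncated below at `clip_min` by
#' redraw. Reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An experiment table: a data frame with columns `participant_id`,
#'   `pair_id`, `context` (`"larger"`/`"smaller"`), `true_size_px`,
#'   `reported_size_px`; `n_participants * n_pairs * 2` rows.
#' @examples
#' tab <- generate_experiment(generator_config(4, bias_shift = 1, seed = 1))
#' head(tab)
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_config("`config` must be created by generator_config()")
  }
  n <- config$n_participants
  pd <- config$pair_designs
  k <- nrow(pd)
  base <- data.frame(
    participant_id = rep(seq_len(n), each = 2L * k),
    pair_id = rep(rep(pd$pair_id, times = 2L), times = n),
    context = rep(rep(c("larger", "smaller"), each = k), times = n),
    true_size_px = rep(rep(pd$true_size_px, times = 2L), times = n)
  )
  shift <- ifelse(base$context == "larger", config$bias_shift, -config$bias_shift)
  base$reported_size_px <- with_seed(
    config$seed,
    rnorm_trunc(base$true_size_px + shift, config$noise_sd, config$clip_min)
  )
  base
}

#' Draw standardized effect-level samples
#'
#' The effect-level input for Bayes Factor Design Analysis: `n` i.i.d. draws
#' from `Normal(d, 1)`, i.e. observations on the standardized (Cohen's dz)
#' scale with true effect `d`.
#'
#' @param n Sample size (>= 2; a t-test is undefined below that).
#' @param d True standardized effect (0 under the null).
#' @param seed Integer seed, or `NULL`.
#' @return Numeric vector of length `n`.
#' @export
generate_effect_samples <- function(n, d = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_config("`n` must be an integer >= 2 (a t-test is undefined otherwise)")
  }
  with_seed(seed, stats::rnorm(n, mean = d, sd = 1))
}

#' Validate an experiment table
#'
#' Enforces the balanced-design invariants: required columns, contexts
#' limited to larger/smaller, strictly positive reported sizes, every
#' participant contributing exactly one trial per (pair, context) over a
#' common pair set, and identical true size across the two contexts of a
#' pair within participant.
#'
#' @param table A data frame in the experiment-table schema.
#' @return The validated table, invisibly normalized (context lower-case).
#' @export
validate_experiment_table <- function(table) {
  req <- c("participant_id", "pair_id", "context", "true_size_px", "reported_size_px")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop_config("experiment table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  table$context <- tolower(as.character(table$context))
  bad_ctx <- !table$context %in% c("larger", "smaller")
  if (any(bad_ctx)) {
    stop_config("invalid `context` token(s) at row(s) ",
                paste(utils::head(which(bad_ctx), 5L), collapse = ", "),
                " (expected 'larger' or 'smaller')")
  }
  if (any(!is.finite(table$reported_size_px)) || any(table$reported_size_px <= 0)) {
    stop_config("`reported_size_px` must be finite and strictly positive")
  }
  pairs <- sort(unique(table$pair_id))
  for (pid in unique(table$participant_id)) {
    sub <- table[table$participant_id == pid, ]
    tab <- table(factor(sub$pair_id, levels = pairs), sub$context)
    if (!all(dim(tab) == c(length(pairs), 2L)) || !all(tab == 1L)) {
      stop_config("unbalanced design for participant ", pid,
                  ": expected exactly one trial per (pair, context)")
    }
    ts <- tapply(sub$true_size_px, sub$pair_id, function(x) diff(range(x)))
    if (any(ts > 1e-9)) {
      stop_config("participant ", pid,
                  ": true size differs across contexts within a matched pair")
    }
  }
  invisible(table)
}

#' Read a generator configuration from YAML
#'
#' The YAML file mirrors the fields of [generator_config()]; `pair_designs`
#' is given as parallel lists `pair_id` and `true_size_px` (omitted fields
#' fall back to the defaults).
#'
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  pd <- if (!is.null(y$pair_designs)) {
    data.frame(pair_id = as.integer(y$pair_designs$pair_id),
               true_size_px = as.numeric(y$pair_designs$true_size_px))
  } else {
    default_pair_designs()
  }
  generator_config(
    n_participants = y$n_participants,
    pair_designs = pd,
    bias_shift = y$bias_shift %||% 0,
    noise_sd = y$noise_sd %||% 21,
    clip_min = y$clip_min %||% 1,
    seed = y$seed
  )
}
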