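test_that("trial tables round-trip through CSV with context normalization", {
  tab <- generate_experiment(generator_config(4, bias_shift = 0.5, seed = 1))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials_csv(tab, path)
  expect_identical(readLines(path, n = 1L),
                   "participant_id,pair_id,context,true_size_px,reported_size_px")
  back <- read_trials_csv(path)
  expect_equal(back$reported_size_px, tab$reported_size_px, tolerance = 1e-12)
  expect_equal(back$context, tab$context)

  # case-variant context tokens are accepted and normalized
  up <- tab
  up$context <- ifelse(up$context == "larger", "Larger", "SMALLER")
  write_trials_csv(up, path)
  expect_equal(read_trials_csv(path)$context, tab$context)
})

test_that("schema and balance violations are reported with their location", {
  tab <- generate_experiment(generator_config(3, seed = 2))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))

  write_trials_csv(tab[-1, ], path) |> expect_error("participant 1")
  bad <- tab
  bad$context[5] <- "weird"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_trials_csv(path), "row.* 5|context")
  utils::write.csv(tab[, -3], path, row.names = FALSE)
  expect_error(read_trials_csv(path), "missing column")
})

test_that("sanity filter keeps exactly the strict-threshold participants", {
  tab <- noise_free_table(3)
  offs <- c(10, 25, 40)
  for (i in 1:3) {
    sel <- tab$participant_id == i
    tab$reported_size_px[sel] <- tab$true_size_px[sel] + offs[i]
  }
  kept <- sanity_filter(tab, 25)
  expect_equal(unique(kept$participant_id), 1L)   # 25 sits on the boundary: excluded
  expect_equal(nrow(sanity_filter(noise_free_table(3), 25)),
               nrow(noise_free_table(3)))
})

test_that("pipeline is deterministic and internally consistent", {
  tab <- generate_experiment(generator_config(40, bias_shift = 1, seed = 3))
  r1 <- run_replication_analysis(tab, n_iterations = 10000, seed = 7)
  r2 <- run_replication_analysis(tab, n_iterations = 10000, seed = 7)
  expect_identical(r1$bias_test$t, r2$bias_test$t)
  expect_identical(r1$posterior$ci95, r2$posterior$ci95)
  expect_identical(r1$accuracy$chance_mean, r2$accuracy$chance_mean)

  # report consistency: BF from the report's own t and n; dz = t/sqrt(n)
  expect_equal(r1$bayes$bf10,
               jzs_bf10(r1$bias_test$t, r1$n_participants, r1$rscale)$bf10)
  expect_equal(r1$bias_test$dz, r1$bias_test$t / sqrt(r1$n_participants))
  expect_equal(r1$bias_test$df, r1$n_participants - 1L)
  expect_gte(r1$prop_positive, 0)
  expect_lte(r1$prop_positive, 1)
})

test_that("noise-free limit: vanishing bias and accuracy beating chance", {
  tab <- generate_experiment(generator_config(10, bias_shift = 0,
                                              noise_sd = 1e-6, seed = 5))
  r <- run_replication_analysis(tab, n_iterations = 10000, seed = 5)
  expect_equal(r$bias$mean, 0, tolerance = 1e-5)
  expect_equal(r$accuracy$mae_mean, 0, tolerance = 1e-5)
  expect_gt(r$accuracy$chance_mean, 0)
  expect_lt(r$accuracy$test$t, 0)              # actual error below chance error
  expect_lt(r$accuracy$test$p, 0.001)
})

test_that("sanity section degrades gracefully when every participant fails the cut", {
  tab <- generate_experiment(generator_config(5, noise_sd = 3, seed = 6))
  tab$reported_size_px <- tab$reported_size_px + 40   # MAE near 40 for everyone
  r <- run_replication_analysis(tab, sanity_threshold = 25,
                                n_iterations = 10000, seed = 6)
  expect_false(r$sanity$available)
  expect_equal(r$sanity$n_retained, 0L)
  expect_true(is.finite(r$bias_test$p))          # main analysis intact
})

test_that("pipeline recovers an injected bias of 1.34 px", {
  tab <- generate_experiment(generator_config(663, bias_shift = 0.67, seed = 11))
  r <- run_replication_analysis(tab, n_iterations = 10000, seed = 11)
  expect_lt(abs(r$bias$mean - 1.34), 3 * r$bias$se)
  expect_equal(r$bias_test$dz, r$bias$mean / r$bias_test$sd)
})

test_that("CI coverage over replicated small experiments is near 95%", {
  hits <- 0L
  n_rep <- 120L
  for (s in seq_len(n_rep)) {
    tab <- generate_experiment(generator_config(25, bias_shift = 0.67,
                                                noise_sd = 21, seed = 2000 + s))
    ci <- one_sample_t(participant_bias(tab)$bias, 0)$ci95
    hits <- hits + (ci[1] <= 1.34 && 1.34 <= ci[2])
  }
  cover <- hits / n_rep
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / n_rep))
})

test_that("reports serialize to JSON with every numeric field", {
  tab <- generate_experiment(generator_config(12, bias_shift = 0.5, seed = 13))
  r <- run_replication_analysis(tab, n_iterations = 10000, seed = 13)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_report_json(r, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_participants, 12L)
  expect_equal(j$bf10, r$bayes$bf10)
  expect_equal(j$bias_test$t, r$bias_test$t)
  expect_equal(j$posterior$cred_lo, r$posterior$ci95[1])
  expect_equal(j$seed, 13L)
})
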