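test_that("toy arithmetic: all three estimators on the two-pair participant", {
  toy <- toy_two_pair()
  expect_equal(bias_difference(toy), 3.0)                 # (4 + 2)/2
  expect_equal(bias_ratio_of_averages(toy), 40 / 37)
  expect_equal(bias_averaging_ratios(toy), (50 / 46 + 30 / 28) / 2)
})

test_that("identical reports in both contexts hit the null value of every estimator", {
  tab <- noise_free_table(1)
  expect_equal(bias_difference(tab), 0)
  expect_equal(bias_ratio_of_averages(tab), 1)
  expect_equal(bias_averaging_ratios(tab), 1)
  expect_equal(bias_null_value("difference"), 0)
  expect_equal(bias_null_value("ratio_of_averages"), 1)
  expect_equal(bias_null_value("averaging_ratios"), 1)
})

test_that("uniform per-context offsets reproduce the constructed bias", {
  tab <- noise_free_table(2, offset_larger = 2, offset_smaller = 0)
  expect_equal(bias_difference(tab[tab$participant_id == 1, ]), 2)
})

test_that("averaging then differencing equals differencing then averaging", {
  for (s in 1:5) {
    tab <- generate_experiment(generator_config(1, noise_sd = 15, seed = s))
    al <- ensemblebias:::pair_align(tab)
    # mathematical identity; agreement to summation round-off
    expect_equal(bias_difference(tab), mean(al$larger) - mean(al$smaller),
                 tolerance = 1e-12)
    expect_equal(bias_difference(tab), mean(al$larger - al$smaller),
                 tolerance = 1e-12)
  }
})

test_that("scaling one context scales the ratio of averages reciprocally", {
  for (s in 1:5) {
    k <- 0.5 + s / 4
    tab <- generate_experiment(generator_config(1, noise_sd = 10, seed = 40 + s))
    scaled <- tab
    sm <- scaled$context == "smaller"
    scaled$reported_size_px[sm] <- scaled$reported_size_px[sm] * k
    expect_equal(bias_ratio_of_averages(scaled),
                 bias_ratio_of_averages(tab) / k)
  }
})

test_that("single pair degeneracy: averaging ratios equals ratio of averages", {
  tab <- toy_two_pair()[1:2, ]
  expect_equal(bias_averaging_ratios(tab), bias_ratio_of_averages(tab))
})

test_that("Jensen ordering on noisy null tables: averaging ratios >= ratio of averages > 1", {
  tab <- generate_experiment(generator_config(800, bias_shift = 0, seed = 51))
  ar <- participant_bias(tab, "averaging_ratios")$bias
  ra <- participant_bias(tab, "ratio_of_averages")$bias
  expect_gt(mean(ar), mean(ra))
  expect_gt(mean(ar), 1)
  expect_gt(mean(ra), 1)
})

test_that("structural and domain errors are raised", {
  toy <- toy_two_pair()
  expect_error(bias_difference(toy[-1, ]), "incomplete")
  dup <- rbind(toy, toy[1, ])
  expect_error(bias_difference(dup), "duplicated|incomplete")
  neg <- toy
  neg$reported_size_px[2] <- -1
  expect_error(bias_ratio_of_averages(neg), "positive")
  expect_error(bias_averaging_ratios(neg), "positive")
  two <- rbind(toy, transform(toy, participant_id = 2L))
  expect_error(bias_difference(two), "single participant")
})

test_that("mean absolute error: perfect, constant-offset and noisy responders", {
  tab <- noise_free_table(1)
  expect_equal(mean_absolute_error(tab), 0)
  off <- tab
  off$reported_size_px <- off$true_size_px + 5
  expect_equal(mean_absolute_error(off), 5)
  # half-normal closed form: E|noise| = sd * sqrt(2/pi); large sizes keep
  # the truncation from biasing the noise
  big_pairs <- data.frame(pair_id = 1:15, true_size_px = seq(300, 370, by = 5))
  big <- generate_experiment(generator_config(2000, pair_designs = big_pairs,
                                              noise_sd = 21, seed = 61))
  expect_equal(mean_absolute_error(big), 21 * sqrt(2 / pi), tolerance = 0.01)
})

test_that("chance MAE matches the exhaustive permutation enumeration on a 3-trial toy", {
  toy <- data.frame(participant_id = 1L, pair_id = c(1L, 2L, 3L),
                    context = "larger", true_size_px = c(10, 20, 30),
                    reported_size_px = c(10, 20, 30))
  # oracle: average MAE over all 6 permutations of the truths
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  oracle <- mean(vapply(perms, function(p) {
    mean(abs(toy$reported_size_px - toy$true_size_px[p]))
  }, numeric(1)))
  expect_equal(oracle, 80 / 9)
  mc <- mean(vapply(1:4000, function(s) chance_mae(toy, seed = s), numeric(1)))
  expect_equal(mc, oracle, tolerance = 0.2)
  # permutation invariance under identical truths; positivity for identity-free pairings
  same <- transform(toy, true_size_px = 20, reported_size_px = 20)
  expect_equal(chance_mae(same, seed = 1), 0)
  expect_gt(chance_mae(toy, seed = 2, method = "derangement"), 0)
})

test_that("chance MAE exceeds actual MAE for a well-performing responder", {
  tab <- generate_experiment(generator_config(1, noise_sd = 5, seed = 71))
  actual <- mean_absolute_error(tab)
  chance <- mean(vapply(1:200, function(s) chance_mae(tab, seed = s), numeric(1)))
  expect_gt(chance, actual)
})

test_that("accuracy and bias table wrappers are deterministic and tidy", {
  tab <- generate_experiment(generator_config(5, seed = 81))
  acc <- participant_accuracy(tab, seed = 4)
  expect_named(acc, c("participant_id", "mae_px", "chance_mae_px"))
  expect_identical(acc, participant_accuracy(tab, seed = 4))
  pb <- participant_bias(tab, "ratio_of_averages")
  expect_named(pb, c("participant_id", "method", "bias", "null_value"))
  expect_true(all(pb$null_value == 1))
  expect_true(all(pb$bias > 0))
})
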