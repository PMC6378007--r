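test_that("the closed-form sphere distance CDF has its exact landmarks", {
  expect_equal(sphere_distance_cdf(0, 3), 0)
  expect_equal(sphere_distance_cdf(6, 3), 1)
  expect_equal(sphere_distance_cdf(1, 1), 15 / 32)
  expect_error(sphere_distance_cdf(7, 3), "domain")
  expect_equal(sphere_distance_cdf(7, 3, clamp = TRUE), 1)
})

test_that("Monte-Carlo sphere fractions match the closed form on a grid", {
  n <- 1e4
  for (R in c(2, 3, 4.23, 5, 6)) {
    for (sf in c(0.15, 0.3, 0.5, 0.8, 1.2)) {
      s <- sf * R
      res <- simulate_null(null_model_config(sphere_geometry(R),
                                             threshold_um = s, n_draws = n,
                                             seed = round(1000 * R + 100 * sf)))
      se <- max(res$mc_standard_error, sqrt(0.5 / n))
      expect_lt(abs(res$fraction_below_threshold - sphere_distance_cdf(s, R)),
                4 * se)
    }
  }
})

test_that("a threshold of the diameter captures every pair", {
  res <- simulate_null(null_model_config(sphere_geometry(3), threshold_um = 6,
                                         n_draws = 2000, seed = 1))
  expect_equal(res$fraction_below_threshold, 1)
})

test_that("the null fraction is scale equivariant", {
  a <- simulate_null(null_model_config(sphere_geometry(4), threshold_um = 2,
                                       n_draws = 2e4, seed = 99))
  b <- simulate_null(null_model_config(sphere_geometry(8), threshold_um = 4,
                                       n_draws = 2e4, seed = 99))
  expect_equal(a$fraction_below_threshold, b$fraction_below_threshold)
})

test_that("elongation reduces the close-pair fraction at equal volume", {
  # ellipsoid (6, 4, 2.6667) has the same volume as the sphere of radius 4
  r_eq <- (6 * 4 * 8 / 3)^(1 / 3)
  sp <- simulate_null(null_model_config(sphere_geometry(r_eq), n_draws = 4e4,
                                        seed = 5))
  el <- simulate_null(null_model_config(ellipsoid_geometry(6, 4, 8 / 3),
                                        n_draws = 4e4, seed = 6))
  se <- sqrt(sp$mc_standard_error^2 + el$mc_standard_error^2)
  expect_lt(el$fraction_below_threshold,
            sp$fraction_below_threshold + 4 * se)
  expect_lt(el$fraction_below_threshold, sp$fraction_below_threshold)
})

test_that("mask geometry agrees with the closed form for a spherical model", {
  m <- generate_nucleus_model(sphere_shape(4.23), seed = 2)
  res <- simulate_null(null_model_config(mask_geometry(m), n_draws = 2e4,
                                         seed = 3))
  expect_lt(abs(res$fraction_below_threshold - sphere_distance_cdf(2, 4.23)),
            4 * res$mc_standard_error)
})

test_that("the generator-ensemble background matches the sphere oracle", {
  bg <- background_interaction_rate(sphere_shape(4.23), copies = c(1, 1),
                                    n_models = 150, draws_per_model = 20,
                                    seed = 8)
  expect_lt(abs(bg$rate - sphere_distance_cdf(2, 4.23)),
            4 * bg$mc_standard_error)
})

test_that("data drawn from the null itself is rarely rejected", {
  # the reference must be much larger than each observed sample, otherwise
  # its own sampling error inflates the chi-squared statistic
  ref <- simulate_null(null_model_config(sphere_geometry(4.23), n_draws = 2e5,
                                         seed = 100))
  rejected <- 0
  for (i in 1:100) {
    obs <- simulate_null(null_model_config(sphere_geometry(4.23),
                                           n_draws = 5000, seed = 200 + i))
    cmp <- compare_to_null(obs$histogram, ref)
    rejected <- rejected + (cmp$p_value < 0.01)
  }
  expect_lte(rejected, 2)
})

test_that("strong observed colocalization is rejected against the null", {
  ref <- simulate_null(null_model_config(sphere_geometry(4.23), n_draws = 4e4,
                                         seed = 101))
  # construct 500 distances with 38.5% mass below 2 um vs the ~7.8% null
  d <- c(runif(193, 0.2, 1.9), runif(307, 2.5, 10))
  cmp <- compare_to_null(bin_distances(d), ref)
  expect_lt(cmp$p_value, 0.001)
})

test_that("comparison inputs are validated", {
  ref <- simulate_null(null_model_config(sphere_geometry(4.23), n_draws = 5000,
                                         seed = 1))
  expect_error(compare_to_null(bin_distances(numeric(0)), ref), "empty")
  other <- bin_distances(runif(50, 0, 5),
                         interaction_params(histogram_bins = 10))
  expect_error(compare_to_null(other, ref), "mismatch")
})

test_that("null distances concentrate a few um apart, with modal mass at 3-6 um", {
  res <- simulate_null(null_model_config(sphere_geometry(4.23), n_draws = 1e4,
                                         seed = 55))
  pr <- tidy(res$histogram)$proportion
  expect_gt(sum(pr[4:6]), 0.5)           # most pairs lie 3-6 um apart
  mean_d <- mean(res$min_distances)
  expect_lt(abs(mean_d - 4.36), 0.15)    # 36R/35 for a ball of radius 4.23
})
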