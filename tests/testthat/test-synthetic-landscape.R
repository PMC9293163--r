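test_that("generators are deterministic under a fixed seed", {
  s1 <- generate_climate_stack(seed = 11, n_rows = 15, n_cols = 15)
  s2 <- generate_climate_stack(seed = 11, n_rows = 15, n_cols = 15)
  expect_identical(s1$layers, s2$layers)

  tr <- scenario_truth(s1)
  expect_identical(sample_presences(s1, tr, 30, seed = 2),
                   sample_presences(s1, tr, 30, seed = 2))
  expect_identical(generate_crop_map(s1, seed = 3)$categories,
                   generate_crop_map(s1, seed = 3)$categories)
  expect_identical(generate_survey_table(survey_spec(), seed = 4),
                   generate_survey_table(survey_spec(), seed = 4))
  expect_identical(generate_tree_counts(seed = 5),
                   generate_tree_counts(seed = 5))
})

test_that("full mixing makes layers perfectly correlated", {
  st <- generate_climate_stack(seed = 1, n_rows = 20, n_cols = 20, mix = 1)
  v <- sapply(st$layers, function(m) as.vector(m))
  r <- cor(v)
  expect_true(all(abs(r) > 1 - 1e-10))
})

test_that("adjacent-cell roughness decreases monotonically with smoothness", {
  mad_adjacent <- function(st) {
    m <- st$layers[[1]]
    mean(abs(diff(m))) + mean(abs(t(diff(t(m)))))
  }
  mads <- sapply(c(0, 1, 2, 4, 8), function(s)
    mad_adjacent(generate_climate_stack(seed = 6, n_rows = 40, n_cols = 40,
                                        smoothness = s)))
  expect_true(all(diff(mads) < 0))
  expect_error(generate_climate_stack(seed = 1, smoothness = -1), "smoothness")
})

test_that("presence sampling enriches for truly suitable cells", {
  st <- generate_climate_stack(seed = 21, n_rows = 25, n_cols = 25)
  tr <- scenario_truth(st)
  s <- niche_suitability(st, tr)
  grid_mean <- mean(s$values, na.rm = TRUE)
  enriched <- vapply(1:100, function(i) {
    p <- sample_presences(st, tr, 200, seed = 1000 + i)
    v <- map_at_points(s, p)
    mean(v) > grid_mean
  }, logical(1))
  expect_true(all(enriched))
  expect_equal(nrow(sample_presences(st, tr, 5, seed = 1)), 5)
})

test_that("constant truth draws cells uniformly", {
  st <- generate_climate_stack(seed = 2, n_rows = 10, n_cols = 10)
  flat <- suitability_map(matrix(1, 10, 10), st$grid)
  p <- sample_presences(st, flat, 10000, seed = 3)
  cc <- cbind(floor(p$longitude) + 1, 10 - floor(p$latitude))
  counts <- table(factor(cc[, 1] + 10 * (cc[, 2] - 1), levels = 1:100 + 0))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("zero suitability cannot be sampled from", {
  st <- generate_climate_stack(seed = 2, n_rows = 5, n_cols = 5)
  zero <- suitability_map(matrix(0, 5, 5), st$grid)
  expect_error(sample_presences(st, zero, 5, seed = 1), "zero everywhere")
})

test_that("crop map categories match the requested proportions", {
  g <- raster_grid(15, 20)
  cm <- generate_crop_map(g, proportions = c(1, 1, 1) / 3, seed = 8)
  counts <- table(as.character(cm$categories))
  expect_true(all(abs(counts - 100) <= 1))

  all_suit <- generate_crop_map(g, proportions = c(1, 0, 0), seed = 8)
  expect_true(all(as.character(all_suit$categories) == "suitable"))
  expect_error(generate_crop_map(g, proportions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("survey tables follow the questionnaire schema", {
  tbl <- generate_survey_table(survey_spec(n_fields = 165), seed = 9)
  expect_equal(nrow(tbl), 165)
  expect_true(all(abs(tbl$pct_age_0_3 + tbl$pct_age_4_8 +
                      tbl$pct_age_gt8 - 100) < 1e-9))
  expect_true(all(tbl$attack %in% 0:1))
  expect_true(all(is.na(tbl$impact[tbl$attack == 0])))
  expect_true(all(tbl$impact[tbl$attack == 1] %in% 0:2))

  # extreme thresholds force rank 1 for every attacked field
  sp <- survey_spec(attack_intercept = 20,
                    attack_coef = c(suitability = 0),
                    impact_coef = c(suitability = 0),
                    impact_thresholds = c(-30, 30))
  tbl2 <- generate_survey_table(sp, seed = 10)
  expect_true(all(tbl2$impact == 1))
})

test_that("tree counts are clumped with dispersion-controlled skewness", {
  tc <- generate_tree_counts(n_trees = 59, seed = 12)
  expect_equal(nrow(tc), 59)
  expect_named(tc, c("males", "females", "copulae", "egg_clusters"))

  # Poisson limit: skewness of Poisson(10) is 1/sqrt(10)
  big <- generate_tree_counts(n_trees = 10000, means = c(males = 10),
                              dispersion = Inf, seed = 13)
  expect_equal(e1071::skewness(big$males, type = 1), 1 / sqrt(10),
               tolerance = 0.05 / (1 / sqrt(10)))

  # smaller dispersion => heavier clumping => larger skewness
  sk <- vapply(c(0.3, 1, 5, Inf), function(k)
    e1071::skewness(generate_tree_counts(n_trees = 5000,
                                         means = c(males = 10),
                                         dispersion = k, seed = 14)$males,
                    type = 1), numeric(1))
  expect_true(all(diff(sk) < 0))

  expect_error(generate_tree_counts(means = c(males = 0)), "> 0")
  expect_error(generate_tree_counts(dispersion = 0), "dispersion")
})

test_that("survey generator recovers its own ordinal coefficients", {
  sp <- survey_spec(n_fields = 5000, attack_intercept = 20,
                    impact_coef = c(suitability = -0.8))
  tbl <- generate_survey_table(sp, seed = 15)
  fit <- impact_ordinal(tbl, "suitability")
  expect_lt(abs(fit$coef - (-0.8)) / fit$se, 3)
})
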