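test_that("clumping statistics flag skewed counts and behave under negation", {
  x <- c(0, 0, 0, 0, 10)
  cs <- clumping_stats(x)
  expect_gt(cs$skewness, 1.5)
  expect_lt(cs$p, 0.05)
  expect_true(cs$W > 0 && cs$W <= 1)
  expect_equal(clumping_stats(-x)$skewness, -cs$skewness)

  set.seed(1)
  z <- rnorm(5000)
  cz <- clumping_stats(z)
  expect_gt(cz$W, 0.99)
  expect_lt(abs(cz$skewness), 0.1)

  expect_error(clumping_stats(rep(3, 10)), "undefined")
  expect_error(clumping_stats(c(1, 2)), "at least 3")
})

test_that("count correlations handle exact, null and degenerate cases", {
  x <- c(1, 3, 5, 7, 11, 2, 8)
  tbl <- data.frame(males = x, females = 2 * x, copulae = x,
                    egg_clusters = x)
  out <- count_correlations(tbl)
  expect_equal(out$r[out$pair == "males ~ females"], 1)
  expect_equal(nrow(out), 4)

  # degenerate: a constant column is flagged, not an error
  tbl2 <- data.frame(males = x, females = rep(2, 7), copulae = x,
                     egg_clusters = x)
  out2 <- count_correlations(tbl2)
  expect_true(is.na(out2$r[out2$pair == "males ~ females"]))
  expect_match(out2$note[out2$pair == "males ~ females"], "degenerate")

  # trees with zero copulae are dropped for the per-copula ratio pair
  tbl3 <- generate_tree_counts(n_trees = 59, seed = 2)
  out3 <- count_correlations(tbl3)
  ratio_row <- out3[out3$pair == "copulae ~ egg_clusters_per_copula", ]
  expect_equal(ratio_row$n, sum(tbl3$copulae > 0))

  # null distribution of r at n = 59: |r| below the 5% critical value ~95%
  set.seed(3)
  rcrit <- qt(0.975, 57) / sqrt(57 + qt(0.975, 57)^2)
  inside <- mean(replicate(1000, abs(cor(rnorm(59), rnorm(59))) < rcrit))
  expect_equal(inside, 0.95, tolerance = 0.02 / 0.95)
})

test_that("a constant covariate explains exactly nothing", {
  tbl <- generate_survey_table(survey_spec(n_fields = 120), seed = 4)
  tbl$flat <- 1
  out <- attack_logistic(tbl, "flat")
  expect_equal(out$chisq, 0, tolerance = 1e-8)
  expect_equal(out$D2, 0, tolerance = 1e-10)
  expect_equal(out$p, 1, tolerance = 1e-4)
})

test_that("binary logistic results match glm's likelihood-ratio test", {
  tbl <- generate_survey_table(survey_spec(n_fields = 200), seed = 5)
  out <- attack_logistic(tbl, "suitability")
  ref <- glm(attack ~ suitability, binomial, tbl)
  ref0 <- glm(attack ~ 1, binomial, tbl)
  expect_equal(out$chisq, deviance(ref0) - deviance(ref))
  expect_equal(out$D2, (deviance(ref0) - deviance(ref)) / deviance(ref0))
  expect_equal(out$df, 1L)
  expect_true(out$estimable)
})

test_that("perfect separation is reported as non-estimable", {
  tbl <- generate_survey_table(survey_spec(n_fields = 100), seed = 6)
  tbl$mirror <- tbl$attack
  out <- attack_logistic(tbl, "mirror")
  expect_false(out$estimable)
  expect_match(out$diagnostic, "separation")
  expect_true(is.na(out$p))
})

test_that("ordinal regression detects simulated effects and stays centered under the null", {
  sp_eff <- survey_spec(n_fields = 500, attack_intercept = 20,
                        impact_coef = c(suitability = 2))
  t_eff <- vapply(1:5, function(i)
    impact_ordinal(generate_survey_table(sp_eff, seed = 100 + i),
                   "suitability")$t, numeric(1))
  expect_true(all(t_eff > 3))

  # under the null t is ~N(0,1); the mean of 300 replicates has sd
  # 1/sqrt(300), so a 3-sigma band around 0 is |mean| < 0.17
  sp_null <- survey_spec(n_fields = 300, attack_intercept = 20,
                         impact_coef = c(suitability = 0))
  t_null <- vapply(1:300, function(i)
    impact_ordinal(generate_survey_table(sp_null, seed = 200 + i),
                   "suitability")$t, numeric(1))
  expect_lt(abs(mean(t_null)), 3 / sqrt(300))

  out <- impact_ordinal(generate_survey_table(sp_eff, seed = 7),
                        "suitability")
  expect_equal(out$df, 2L)            # two cumulative-logit thresholds
  expect_true(out$D2 >= 0 && out$D2 < 1)
})

test_that("non-attacked fields enter the impact model as rank 0", {
  tbl <- data.frame(area_ha = c(1, 2, 3, 4, 5, 6),
                    attack = c(0, 0, 1, 1, 1, 1),
                    impact = c(NA, NA, 0, 1, 2, 1),
                    suitability = c(0.1, 0.2, 0.5, 0.6, 0.9, 0.7))
  out <- suppressWarnings(impact_ordinal(tbl, "suitability"))
  expect_equal(out$n, 6)
  expect_error(impact_ordinal(data.frame(attack = c(1, 1),
                                         impact = c(1, 1),
                                         suitability = c(0.3, 0.4)),
                              "suitability"), "distinct impact ranks")
})

test_that("survey summaries count age compositions by hand-checkable rules", {
  tbl <- data.frame(region = c("A", "A", "B", "C"),
                    municipality = NA,
                    area_ha = c(0.7, 119, 10, 14.3),
                    pct_age_0_3 = c(100, 0, 30, 0),
                    pct_age_4_8 = c(0, 100, 50, 0),
                    pct_age_gt8 = c(0, 0, 20, 100),
                    attack = c(0, 1, 1, 0),
                    impact = c(NA, 1, 2, NA),
                    suitability = c(0.2, 0.8, 0.5, 0.4))
  s <- survey_summaries(tbl)
  expect_equal(s$n, 4)
  expect_equal(s$young_only, 1)
  expect_equal(s$moderate_only, 1)
  expect_equal(s$old_only, 1)
  expect_equal(s$no_old, 2)
  expect_equal(s$area_mean, mean(tbl$area_ha))
  expect_equal(s$area_min, 0.7)
  expect_equal(s$area_max, 119)
  expect_equal(as.vector(s$by_region[c("A", "B", "C")]), c(2, 1, 1))
  expect_equal(survey_summaries(tbl[0, ])$n, 0)
})

test_that("survey CSV validation enforces the schema", {
  f <- tempfile(fileext = ".csv")
  tbl <- generate_survey_table(survey_spec(n_fields = 20), seed = 8)
  write.csv(tbl, f, row.names = FALSE)
  back <- read_survey_table(f)
  expect_s3_class(back, "survey_table")
  expect_equal(nrow(back), 20)

  bad <- tbl; bad$pct_age_0_3 <- bad$pct_age_0_3 + 10
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_survey_table(f), "sum to 100")

  bad2 <- tbl; bad2$impact[bad2$attack == 0][1] <- 2
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_survey_table(f), "attack = 0")
})
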