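test_that("AUC follows the Mann-Whitney definition", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.4), c(1, 1, 0)), 1)          # separable
  expect_equal(auc_roc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)    # all tied
  # positives {0.9, 0.3}, negatives {0.8, 0.4}: 2 concordant of 4 pairs
  expect_equal(auc_roc(c(0.9, 0.3, 0.8, 0.4), c(1, 1, 0, 0)), 0.5)
  expect_error(auc_roc(c(1, 2), c(1, 1)), "both classes")
  expect_error(auc_roc(1:3, c(1, 0)), "length")
})

test_that("AUC equals brute-force pair counting on random instances", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    # discrete score support so ties actually occur
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(auc_roc(scores, labels), bf_auc(scores, labels))
  }
})

make_sep_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(presence = rep(c(1L, 0L), each = n),
             X = c(runif(n, 2, 3), runif(n, 0, 1)))
}

test_that("every algorithm separates well-separated one-variable data", {
  bg <- data.frame(X = runif(200, 0, 3))
  for (seed in 1:5) {
    dat <- make_sep_data(seed = seed)
    for (alg in c("GLM", "GAM", "ANN", "CTA", "MAXENT", "RF")) {
      run <- suppressWarnings(fit_single(alg, dat, seed = 400 + seed,
                                         background = bg))
      expect_false(run$failed)
      expect_gte(run$internal_auc, 0.95)
      expect_true(run$kept)
    }
  }
})

test_that("labels independent of the variables give chance-level AUC", {
  set.seed(88)
  aucs <- vapply(1:100, function(i) {
    dat <- data.frame(presence = rep(c(1L, 0L), each = 40),
                      X = rnorm(80), Y = rnorm(80))
    suppressWarnings(fit_single("GLM", dat, seed = i))$internal_auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05 / 0.5)
})

test_that("the same seed reproduces the same fitted run exactly", {
  dat <- make_sep_data(seed = 9)
  bg <- data.frame(X = runif(150, 0, 3))
  new <- data.frame(X = seq(0, 3, length.out = 50))
  for (alg in c("GLM", "GAM", "ANN", "CTA", "MAXENT", "RF")) {
    r1 <- suppressWarnings(fit_single(alg, dat, seed = 5, background = bg))
    r2 <- suppressWarnings(fit_single(alg, dat, seed = 5, background = bg))
    expect_identical(predict(r1, new), predict(r2, new))
    expect_identical(r1$internal_auc, r2$internal_auc)
  }
})

test_that("predictions are probabilities and failures are contained", {
  dat <- make_sep_data(seed = 2)
  r <- suppressWarnings(fit_single("GLM", dat, seed = 1))
  p <- predict(r, data.frame(X = seq(-50, 50, length.out = 100)))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_single("MAXENT", dat, seed = 1), NA,
               class = NULL)  # failure is flagged, not thrown
  rf <- fit_single("MAXENT", dat, seed = 1)  # no background supplied
  expect_true(rf$failed)
  expect_match(rf$message, "background")
  expect_error(predict(rf, dat), "failed run")
  expect_error(fit_single("GLM", dat[c(1:5, 61:65), ], seed = 1), ">= 10")
})

test_that("binarization uses the closed >= rule and conserves cells", {
  g <- raster_grid(2, 2)
  m <- suitability_map(matrix(c(0.551, 0.549, 0.55, NA), 2, 2), g)
  b <- binarize(m, 0.55)
  expect_equal(b$values[1, 1], 1)
  expect_equal(b$values[2, 1], 0)
  expect_equal(b$values[1, 2], 1)      # boundary value is suitable
  expect_true(is.na(b$values[2, 2]))   # nodata preserved
  expect_equal(sum(b$values == 1, na.rm = TRUE) +
               sum(b$values == 0, na.rm = TRUE),
               sum(!is.na(m$values)))
  const <- binarize(suitability_map(matrix(0.55, 2, 2), g), 0.55)
  expect_true(all(const$values == 1))
  expect_error(binarize(m, 0), "cutoff")
  expect_error(binarize(m, 1.2), "cutoff")
})

# one small ensemble reused by the remaining blocks
small_scenario <- local({
  stack <- generate_climate_stack(seed = 500, n_rows = 30, n_cols = 30)
  truth <- scenario_truth(stack)
  pres <- sample_presences(stack, truth, 80, seed = 501)
  part <- partition_cells(stack, build_envelope(stack, pres))
  res <- suppressWarnings(
    run_ensemble(stack, pres, part, n_iterations = 4, seed = 502))
  list(stack = stack, truth = truth, pres = pres, part = part, res = res)
})

test_that("the ensemble attempts iterations x algorithms runs and filters by AUC", {
  res <- small_scenario$res
  expect_equal(res$n_attempted, 4 * 6)
  expect_equal(nrow(res$runs), 24)
  expect_true(all(res$runs$internal_auc[res$runs$kept] > 0.7))
  expect_true(all(res$external_auc >= 0 & res$external_auc <= 1))
})

test_that("consensus and bound maps are probabilities with lower <= consensus <= upper", {
  res <- small_scenario$res
  ok <- !is.na(res$consensus$values)
  expect_true(all(res$consensus$values[ok] >= 0 &
                  res$consensus$values[ok] <= 1))
  expect_true(all(res$lower$values[ok] <= res$consensus$values[ok]))
  expect_true(all(res$consensus$values[ok] <= res$upper$values[ok]))
  expect_identical(is.na(res$consensus$values), !small_scenario$stack$mask)
})

test_that("ensembles are reproducible under the master seed", {
  s <- small_scenario
  res2 <- suppressWarnings(
    run_ensemble(s$stack, s$pres, s$part, n_iterations = 4, seed = 502))
  expect_identical(res2$consensus$values, s$res$consensus$values)
  expect_identical(res2$runs$internal_auc, s$res$runs$internal_auc)
})

test_that("a single kept run collapses the bounds onto the consensus", {
  s <- small_scenario
  res1 <- suppressWarnings(
    run_ensemble(s$stack, s$pres, s$part, n_iterations = 1,
                 algorithms = "GLM", bounds = "minmax", seed = 503))
  ok <- !is.na(res1$consensus$values)
  expect_identical(res1$lower$values[ok], res1$consensus$values[ok])
  expect_identical(res1$upper$values[ok], res1$consensus$values[ok])
})

test_that("permutation importance isolates the variables a model uses", {
  s <- small_scenario
  # strong monotone single-variable truth
  st <- generate_climate_stack(seed = 510, n_rows = 30, n_cols = 30)
  tr <- true_niche(0, c(BIO10 = 3))
  pres <- sample_presences(st, tr, 80, seed = 511)
  part <- partition_cells(st, build_envelope(st, pres))
  res <- suppressWarnings(
    run_ensemble(st, pres, part, vars = "BIO10", n_iterations = 2,
                 algorithms = c("GLM", "RF"), seed = 512))
  vc <- variable_contributions(res, st, seed = 513)
  expect_true(all(vc[, "BIO10"] > 80))
  expect_true(all(vc >= 0 & vc <= 100))

  # a variable outside the fit's inputs contributes exactly 0
  X <- as.matrix(data.frame(BIO10 = rnorm(100)))
  y <- rbinom(100, 1, plogis(2 * X[, 1]))
  run <- structure(list(algorithm = "GLM", seed = 1,
                        fit = nichecast:::fit_algorithm("GLM", X, y, seed = 1),
                        internal_auc = 1, kept = TRUE, failed = FALSE,
                        iteration = 1),
                   class = "model_run")
  fake <- list(vars = c("BIO10", "BIO15"),
               runs = data.frame(algorithm = "GLM"),
               models = list(run))
  vc2 <- variable_contributions(fake, st, seed = 514)
  expect_equal(unname(vc2["GLM", "BIO15"]), 0)
})

test_that("validation points are scored against the consensus", {
  g <- raster_grid(2, 2)
  fake <- list(consensus = suitability_map(matrix(c(1, 1, 0.2, NA), 2, 2), g),
               cutoff = 0.55)
  val <- occurrence_set(c(0.5, 0.5, 1.5), c(1.5, 0.5, 1.5))
  out <- validate_points(fake, val)
  expect_equal(out$n_high, 2)
  expect_equal(out$n_low, 1)
  expect_equal(out$points$suitability, c(1, 1, 0.2))

  all_high <- validate_points(fake, occurrence_set(c(0.5, 0.5), c(1.5, 0.5)))
  expect_equal(all_high$n_high, 2)
  expect_equal(all_high$n_low, 0)
})
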