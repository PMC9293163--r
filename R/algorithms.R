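## The six ensemble member algorithms. Each fit is wrapped in an `sdm_fit`
## object exposing a uniform predict() returning probabilities clipped to
## [0, 1]:
##   GLM    logistic regression with linear + quadratic terms
##   GAM    per-variable smoothing splines (mgcv, binomial)
##   ANN    one-hidden-layer feed-forward classifier (nnet, 5 units)
##   CTA    single classification tree (rpart, depth-limited)
##   RF     500-tree random forest
##   MAXENT L1-regularised logistic contrast of presences vs background
##          with linear + quadratic + pairwise-product features (the
##          standard MaxEnt-logistic equivalence)

#' The six ensemble member algorithms
#' @export
sdm_algorithms <- c("GLM", "GAM", "ANN", "CTA", "MAXENT", "RF")

maxent_features <- function(X) {
  p <- ncol(X)
  feats <- cbind(X, X^2)
  colnames(feats) <- c(colnames(X), paste0(colnames(X), "_sq"))
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    prod <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(prod) <- paste0(colnames(X)[pairs[1, ]], "_x_",
                             colnames(X)[pairs[2, ]])
    feats <- cbind(feats, prod)
  }
  feats
}

fit_algorithm <- function(algorithm, X, y, seed, background = NULL,
                          ann_size = 5, cta_maxdepth = 8, rf_ntree = 500) {
  algorithm <- match.arg(algorithm, sdm_algorithms)
  vars <- colnames(X)
  set.seed(seed)
  fit <- switch(algorithm,
    GLM = {
      df <- data.frame(presence = y, X)
      fm <- stats::as.formula(paste("presence ~",
        paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")))
      stats::glm(fm, family = stats::binomial(), data = df)
    },
    GAM = {
      df <- data.frame(presence = y, X)
      k <- pmin(5L, vapply(vars, function(v) length(unique(df[[v]])), 0L) - 1L)
      ## fixed-df regression splines: no smoothness-selection outer loop,
      ## which is unstable (and slow) under the quasi-separation typical of
      ## presence/pseudoabsence contrasts
      terms <- ifelse(k >= 3, sprintf("s(%s, k = %d, fx = TRUE)", vars, k),
                      vars)
      fm <- stats::as.formula(paste("presence ~", paste(terms, collapse = " + ")))
      mgcv::gam(fm, family = stats::binomial(), data = df)
    },
    ANN = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      net <- nnet::nnet(scale(X, ctr, scl), y, size = ann_size, decay = 0.01,
                        maxit = 300, trace = FALSE, entropy = TRUE)
      list(net = net, center = ctr, scale = scl)
    },
    CTA = {
      df <- data.frame(presence = factor(y), X)
      rpart::rpart(presence ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = cta_maxdepth,
                                                  cp = 0.001, xval = 0))
    },
    RF = randomForest::randomForest(X, factor(y), ntree = rf_ntree),
    MAXENT = {
      if (is.null(background) || nrow(background) < 10)
        stop("MAXENT requires background points (>= 10)")
      Xp <- X[y == 1, , drop = FALSE]
      Xall <- rbind(Xp, background[, vars, drop = FALSE])
      yall <- c(rep(1, nrow(Xp)), rep(0, nrow(background)))
      F <- maxent_features(as.matrix(Xall))
      ctr <- colMeans(F); scl <- apply(F, 2, stats::sd)
      scl[scl == 0] <- 1
      ## stratified folds: presences and background spread evenly, else a
      ## fold can end up with almost no presences and wreck the cv curve
      foldid <- integer(length(yall))
      for (cl in c(0, 1)) {
        idx <- which(yall == cl)
        foldid[idx] <- sample(rep_len(seq_len(4), length(idx)))
      }
      ## AUC as the cv criterion (deviance can select the null model on
      ## imbalanced presence/background data); the path is kept short since
      ## near-zero lambdas converge slowly under quasi-separation
      cv <- glmnet::cv.glmnet(scale(F, ctr, scl), yall, family = "binomial",
                              alpha = 1, foldid = foldid,
                              type.measure = "auc", nlambda = 20,
                              lambda.min.ratio = 0.01)
      list(cv = cv, center = ctr, scale = scl)
    })
  structure(list(algorithm = algorithm, fit = fit, vars = vars),
            class = "sdm_fit")
}

#' Predict suitability from a fitted ensemble member
#' @param object an \code{sdm_fit}.
#' @param newdata data frame or matrix holding the model's variables.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$vars, drop = FALSE])
  p <- switch(object$algorithm,
    GLM = stats::predict(object$fit, as.data.frame(X), type = "response"),
    GAM = as.numeric(stats::predict(object$fit, as.data.frame(X),
                                    type = "response")),
    ANN = as.numeric(stats::predict(object$fit$net,
                       scale(X, object$fit$center, object$fit$scale))),
    CTA = stats::predict(object$fit, as.data.frame(X))[, "1"],
    RF = stats::predict(object$fit, X, type = "prob")[, "1"],
    MAXENT = as.numeric(stats::predict(object$fit$cv,
               scale(maxent_features(X), object$fit$center,
                     object$fit$scale),
               s = "lambda.min", type = "response")))
  pmin(pmax(as.numeric(p), 0), 1)
}

## stratified split: returns logical vector, TRUE = first (larger) part
stratified_split <- function(labels, fraction) {
  take <- logical(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n1 <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
    take[sample(idx, n1)] <- TRUE
  }
  take
}

#' Fit one ensemble member with its own evaluation split
#'
#' Draws a fresh stratified split of the supplied data (default 75%
#' fitting / 25% internal evaluation), fits the requested algorithm on the
#' fitting part, and scores the internal AUC on the held-in evaluation
#' part. The run is kept for consensus building only if its internal AUC
#' strictly exceeds \code{auc_keep}. Fitting failures (e.g. convergence)
#' mark the run failed rather than aborting.
#'
#' @param algorithm one of GLM, GAM, ANN, CTA, MAXENT, RF.
#' @param data data frame with a 0/1 \code{presence} column (1 = presence,
#'   0 = pseudoabsence) and the predictor columns.
#' @param seed integer RNG seed for this run (split and fit).
#' @param background data frame of background-point predictor values,
#'   required by MAXENT only.
#' @param eval_fraction share of rows held in for internal evaluation.
#' @param auc_keep internal-AUC retention threshold (strict inequality).
#' @return a \code{model_run}: the fit, internal AUC, kept/failed flags.
#' @export
fit_single <- function(algorithm, data, seed, background = NULL,
                       eval_fraction = 0.25, auc_keep = 0.7) {
  if (!"presence" %in% names(data)) stop("data needs a 'presence' column")
  y <- data$presence
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 10)
    stop("need >= 10 points per class, got ", min(table(y)))
  vars <- setdiff(names(data), "presence")
  set.seed(seed)
  in_fit <- stratified_split(y, 1 - eval_fraction)
  run <- structure(list(algorithm = algorithm, seed = seed, fit = NULL,
                        internal_auc = NA_real_, kept = FALSE,
                        failed = FALSE, message = NULL),
                   class = "model_run")
  res <- tryCatch({
    X <- as.matrix(data[in_fit, vars, drop = FALSE])
    f <- fit_algorithm(algorithm, X, y[in_fit], seed = seed,
                       background = background)
    scores <- predict(f, data[!in_fit, vars, drop = FALSE])
    list(fit = f, auc = auc_roc(scores, y[!in_fit]))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    run$failed <- TRUE
    run$message <- conditionMessage(res)
  } else {
    run$fit <- res$fit
    run$internal_auc <- res$auc
    run$kept <- res$auc > auc_keep
  }
  run
}

#' @export
predict.model_run <- function(object, newdata, ...) {
  if (object$failed || is.null(object$fit))
    stop("cannot predict from a failed run")
  predict(object$fit, newdata)
}
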