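## Ensemble species distribution model: many iterations x six algorithms,
## an internal-AUC keep filter, cell-wise consensus and bound maps, and an
## external evaluation on a holdout drawn before any fitting.

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney identity: the probability that a random
#' positive scores above a random negative, with ties counted half. Exact,
#' no curve interpolation.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

map_extract <- function(map, points) {
  cc <- point_to_cell(map$grid, points$longitude, points$latitude)
  idx <- ifelse(is.na(cc$row), NA_integer_,
                cc$row + (cc$col - 1L) * map$grid$n_rows)
  map$values[idx]
}

#' Map values at point locations
#'
#' Looks up a single-layer map (e.g. a suitability map) at point
#' coordinates using the same point-in-cell rule as
#' \code{\link{extract_values}}; off-grid points yield NA.
#'
#' @param map a \code{suitability_map} (or any object with \code{grid} and
#'   \code{values}).
#' @param points data frame with \code{longitude}, \code{latitude}.
#' @return numeric vector of map values.
#' @export
map_at_points <- function(map, points) map_extract(map, points)

#' Run the full ensemble
#'
#' Workflow: thin presences to one per cell (optional), extract their
#' climate values, sample pseudoabsence and background points from the
#' envelope partition, hold out a stratified share (default 25%) of
#' presences and pseudoabsences for external evaluation, then for each
#' iteration fit all algorithms (each with its own fresh stratified
#' fit/evaluation split of the training pool and its own derived seed).
#' Runs with internal AUC strictly above \code{auc_keep} are averaged
#' cell-wise into the consensus map; the lower/upper bound maps are the
#' cell-wise 2.5th/97.5th percentiles of the kept-run predictions,
#' bracketed with the consensus so lower <= consensus <= upper holds at
#' every cell. Consensus and bounds are finally scored with the external
#' AUC on the holdout.
#'
#' @param stack a \code{climate_stack} restricted to the selected variables
#'   (or use \code{vars}).
#' @param presences an \code{occurrence_set} of training presences.
#' @param partition a \code{cell_partition} from
#'   \code{\link{partition_cells}}.
#' @param vars variable names used for fitting (default: all layers).
#' @param n_iterations iterations per algorithm (default 100; with the six
#'   default algorithms 600 model runs are attempted).
#' @param algorithms subset of GLM, GAM, ANN, CTA, MAXENT, RF.
#' @param split share of data kept for training; the complement is the
#'   external holdout (default 0.75).
#' @param auc_keep internal-AUC retention threshold (default 0.7, strict).
#' @param cutoff suitability threshold carried into the result (default
#'   0.55).
#' @param n_pseudoabsence,n_background pool sample sizes; defaults are one
#'   pseudoabsence per presence and ten background points per presence.
#' @param thin thin presences to one record per cell (default TRUE).
#' @param bounds \code{"percentile"} (2.5/97.5) or \code{"minmax"}.
#' @param keep_models retain fitted members for permutation importance
#'   (default TRUE).
#' @param seed master seed; per-run seeds are derived from it.
#' @return an \code{ensemble_result}: consensus/lower/upper
#'   \code{suitability_map}s, the per-run AUC table, external AUCs of the
#'   three maps, the kept models, and the sampling bookkeeping.
#' @export
run_ensemble <- function(stack, presences, partition,
                         vars = layer_names(stack),
                         n_iterations = 100, algorithms = sdm_algorithms,
                         split = 0.75, auc_keep = 0.7, cutoff = 0.55,
                         n_pseudoabsence = NULL, n_background = NULL,
                         thin = TRUE, bounds = c("percentile", "minmax"),
                         keep_models = TRUE, seed = 1) {
  bounds <- match.arg(bounds)
  algorithms <- match.arg(algorithms, sdm_algorithms, several.ok = TRUE)
  if (thin) presences <- thin_occurrences(stack, presences)
  pv <- suppressWarnings(extract_values(stack, presences))[, vars, drop = FALSE]
  ok <- stats::complete.cases(pv)
  pv <- pv[ok, , drop = FALSE]
  pres_coords <- data.frame(longitude = presences$longitude,
                            latitude = presences$latitude)[ok, , drop = FALSE]
  n_pres <- nrow(pv)
  if (n_pres < 10) stop("need >= 10 usable presences, got ", n_pres)
  pool_sizes <- table(as.character(partition$class))
  ## defaults per standard practice (1 pseudoabsence and 10 background
  ## points per presence), capped at what the partition can supply
  if (is.null(n_pseudoabsence))
    n_pseudoabsence <- min(n_pres, pool_sizes[["pseudoabsence"]])
  if (is.null(n_background))
    n_background <- min(10L * n_pres, pool_sizes[["background"]])

  set.seed(seed)
  seed_points <- sample.int(.Machine$integer.max, 1)
  seed_holdout <- sample.int(.Machine$integer.max, 1)
  run_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_iterations * length(algorithms)),
                      n_iterations, length(algorithms))

  pts <- sample_envelope_points(partition, n_background, n_pseudoabsence,
                                seed = seed_points)
  pav <- extract_values(stack, pts$pseudoabsence)[, vars, drop = FALSE]
  bgv <- extract_values(stack, pts$background)[, vars, drop = FALSE]

  data_all <- data.frame(presence = c(rep(1L, n_pres),
                                      rep(0L, nrow(pav))),
                         rbind(pv, pav))
  coords_all <- rbind(pres_coords,
                      pts$pseudoabsence[, c("longitude", "latitude")])
  set.seed(seed_holdout)
  in_train <- stratified_split(data_all$presence, split)
  bg_train <- stratified_split(rep(1L, nrow(bgv)), split)
  train_pool <- data_all[in_train, , drop = FALSE]
  holdout <- data_all[!in_train, , drop = FALSE]
  bg_pool <- as.data.frame(bgv[bg_train, , drop = FALSE])

  valid_idx <- which(stack$mask)
  cellmat <- as.data.frame(
    vapply(stack$layers[vars], function(m) m[valid_idx],
           numeric(length(valid_idx))))

  runs <- vector("list", n_iterations * length(algorithms))
  preds <- list()
  tab <- data.frame(algorithm = character(0), iteration = integer(0),
                    seed = integer(0), internal_auc = numeric(0),
                    kept = logical(0), failed = logical(0))
  k <- 0L
  for (it in seq_len(n_iterations)) {
    for (ai in seq_along(algorithms)) {
      k <- k + 1L
      run <- fit_single(algorithms[ai], train_pool,
                        seed = run_seeds[it, ai], background = bg_pool,
                        auc_keep = auc_keep)
      run$iteration <- it
      tab[k, ] <- list(algorithms[ai], it, run_seeds[it, ai],
                       run$internal_auc, run$kept, run$failed)
      if (run$kept) preds[[length(preds) + 1L]] <- predict(run, cellmat)
      runs[[k]] <- if (keep_models) run
                   else run[setdiff(names(run), "fit")]
    }
  }
  if (!length(preds))
    stop("no model run passed the AUC filter; run table:\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  P <- do.call(cbind, preds)
  consensus_v <- rowMeans(P)
  if (bounds == "percentile") {
    lower_v <- apply(P, 1, stats::quantile, probs = 0.025, names = FALSE)
    upper_v <- apply(P, 1, stats::quantile, probs = 0.975, names = FALSE)
  } else {
    lower_v <- apply(P, 1, min)
    upper_v <- apply(P, 1, max)
  }
  lower_v <- pmin(lower_v, consensus_v)
  upper_v <- pmax(upper_v, consensus_v)
  to_map <- function(v) {
    m <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
    m[valid_idx] <- v
    suitability_map(m, stack$grid)
  }
  consensus <- to_map(consensus_v)
  lower <- to_map(lower_v)
  upper <- to_map(upper_v)

  ## external AUC: map values at the holdout presence/pseudoabsence cells
  hold_coords <- coords_all[!in_train, , drop = FALSE]
  ext <- vapply(list(consensus = consensus, lower = lower, upper = upper),
                function(m) auc_roc(map_extract(m, hold_coords),
                                    holdout$presence),
                numeric(1))

  structure(list(grid = stack$grid, vars = vars,
                 consensus = consensus, lower = lower, upper = upper,
                 runs = tab, models = runs,
                 external_auc = ext, cutoff = cutoff,
                 n_presences = n_pres,
                 points = pts, holdout = holdout,
                 n_attempted = nrow(tab), n_kept = sum(tab$kept),
                 seed = seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result:", x$n_attempted, "runs attempted,", x$n_kept,
      "kept by the internal-AUC filter\n")
  cat("external AUC: consensus", round(x$external_auc["consensus"], 3),
      "| lower", round(x$external_auc["lower"], 3),
      "| upper", round(x$external_auc["upper"], 3), "\n")
  cat("cutoff:", x$cutoff, "\n")
  invisible(x)
}

#' Permutation variable contributions
#'
#' For each algorithm and each variable: predictions of each kept run on
#' the original cell values are compared with predictions after permuting
#' that variable's column; the contribution is
#' \code{1 - max(0, cor(original, permuted))}, averaged over the
#' algorithm's kept runs and reported in percent. A variable the model
#' ignores scores 0; a variable the model relies on entirely scores near
#' 100.
#'
#' @param result an \code{ensemble_result} with \code{keep_models = TRUE}.
#' @param stack the \code{climate_stack} predictions are evaluated on.
#' @param seed RNG seed for the permutations.
#' @param max_cells cap on evaluation cells (subsampled if exceeded).
#' @return matrix (algorithms x variables) of contributions in percent;
#'   algorithms with no kept runs are NA.
#' @export
variable_contributions <- function(result, stack, seed = 1,
                                   max_cells = 5000L) {
  vars <- result$vars
  valid_idx <- which(stack$mask)
  set.seed(seed)
  if (length(valid_idx) > max_cells)
    valid_idx <- sort(sample(valid_idx, max_cells))
  cellmat <- as.data.frame(
    vapply(stack$layers[vars], function(m) m[valid_idx],
           numeric(length(valid_idx))))
  perms <- lapply(vars, function(v) sample.int(nrow(cellmat)))
  names(perms) <- vars
  algs <- unique(result$runs$algorithm)
  out <- matrix(NA_real_, length(algs), length(vars),
                dimnames = list(algs, vars))
  for (alg in algs) {
    kept <- Filter(function(r) !is.null(r$fit) && r$kept && r$algorithm == alg,
                   result$models)
    if (!length(kept)) {
      message("no kept runs for ", alg, "; contributions reported missing")
      next
    }
    contrib <- matrix(0, length(kept), length(vars))
    for (i in seq_along(kept)) {
      p0 <- predict(kept[[i]], cellmat)
      for (j in seq_along(vars)) {
        pd <- cellmat
        pd[[vars[j]]] <- pd[[vars[j]]][perms[[vars[j]]]]
        p1 <- predict(kept[[i]], pd)
        r <- if (stats::sd(p0) == 0 || stats::sd(p1) == 0) 1
             else stats::cor(p0, p1)
        contrib[i, j] <- 1 - max(0, r)
      }
    }
    out[alg, ] <- 100 * colMeans(contrib)
  }
  out
}

#' Binarize a suitability map at a cutoff
#'
#' Cells with suitability greater than or equal to the cutoff are suitable
#' (closed rule, so a map constant at the cutoff is entirely suitable).
#'
#' @param map a \code{suitability_map}.
#' @param cutoff threshold in (0, 1), default 0.55.
#' @return a \code{suitability_map} of 0/1 values (nodata preserved).
#' @export
binarize <- function(map, cutoff = 0.55) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly inside (0, 1)")
  v <- ifelse(map$values >= cutoff, 1, 0)
  suitability_map(v, map$grid)
}

#' Score independent validation points against the consensus map
#'
#' @param result an \code{ensemble_result}.
#' @param validation an \code{occurrence_set} of a-posteriori records.
#' @param high_cutoff suitability threshold defining "highly suitable"
#'   (defaults to the ensemble's cutoff).
#' @return list with a per-point data frame (\code{suitability},
#'   \code{high}) and the counts above/below the cutoff.
#' @export
validate_points <- function(result, validation, high_cutoff = NULL) {
  if (is.null(high_cutoff)) high_cutoff <- result$cutoff
  s <- map_extract(result$consensus, validation)
  pts <- data.frame(longitude = validation$longitude,
                    latitude = validation$latitude,
                    suitability = s,
                    high = !is.na(s) & s >= high_cutoff)
  list(points = pts,
       n_high = sum(pts$high),
       n_low = sum(!pts$high & !is.na(s)),
       n_missing = sum(is.na(s)),
       cutoff = high_cutoff)
}
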