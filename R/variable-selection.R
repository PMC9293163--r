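## Collinearity filtering of candidate bioclimatic layers:
## Ward clustering of the 1 - |Pearson r| dissimilarity, tree cut at a
## distance threshold (0.3 <=> |r| > 0.7 merged), one representative per
## cluster, then an iterative variance-inflation-factor screen.

stack_value_matrix <- function(stack, sample_cells = NULL, seed = NULL,
                               max_cells = 50000L) {
  idx <- which(stack$mask)
  if (!is.null(sample_cells)) {
    idx <- sample_cells
  } else if (length(idx) > max_cells) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sort(sample(idx, max_cells))
  }
  vapply(stack$layers, function(m) m[idx], numeric(length(idx)))
}

#' Cluster candidate variables and pick representatives
#'
#' Computes the pairwise Pearson correlation of all layers over (a sample
#' of) valid cells, converts it to the dissimilarity d = 1 - |r| so that a
#' cut height of 0.3 corresponds to grouping variables correlated above
#' 0.7, agglomerates with Ward linkage, cuts the tree at \code{threshold},
#' and keeps one representative per cluster. A variable uncorrelated with
#' every other forms its own cluster and is kept as-is.
#'
#' The default representative is the cluster member whose min-max-rescaled
#' values have the largest variance, i.e. the variable that spreads
#' observations most widely across its own range; \code{force_keep} can
#' override the choice per cluster for reproducing a published set.
#'
#' @param stack a \code{climate_stack} with >= 2 layers.
#' @param sample_cells optional integer vector of cell indices to use; the
#'   default uses all valid cells up to \code{max_cells}, subsampled with
#'   \code{seed}.
#' @param threshold tree-cut height on the 1 - |r| scale (default 0.3).
#' @param force_keep character vector of variable names that must be chosen
#'   as their cluster's representative.
#' @param seed RNG seed for cell subsampling.
#' @param max_cells cap on cells used for correlations.
#' @return a \code{selection_report} with the correlation matrix, the
#'   \code{hclust} tree, cluster membership, representatives and the
#'   selected names (pre-VIF).
#' @export
select_variables <- function(stack, sample_cells = NULL, threshold = 0.3,
                             force_keep = NULL, seed = 1,
                             max_cells = 50000L) {
  if (length(stack$layers) < 2) stop("need at least two candidate layers")
  X <- stack_value_matrix(stack, sample_cells, seed, max_cells)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant layer(s), correlation undefined: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  d <- 1 - abs(r)
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  members <- stats::cutree(tree, h = threshold)
  spread <- apply(X, 2, function(v) stats::var((v - min(v)) / (max(v) - min(v))))
  reps <- vapply(split(names(members), members), function(vars) {
    forced <- intersect(force_keep, vars)
    if (length(forced) >= 1) return(forced[1])
    vars[which.max(spread[vars])]
  }, character(1))
  structure(list(correlation = r, distance = d, tree = tree,
                 clusters = members, representatives = unname(reps),
                 spread = spread, threshold = threshold,
                 selected = unname(reps), vif = NULL),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report:", length(x$clusters), "candidates ->",
      length(unique(x$clusters)), "cluster(s) at threshold", x$threshold, "\n")
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$vif)) {
    cat("VIF after filtering:\n")
    print(round(x$vif, 3))
  }
  invisible(x)
}

## VIF_i = 1 / (1 - R^2_i) from regressing column i on the others
vif_values <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(i) {
    fit <- stats::lm.fit(cbind(1, X[, -i, drop = FALSE]), X[, i])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, i] - mean(X[, i]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Variance-inflation-factor filter
#'
#' Computes each variable's VIF = 1/(1 - R^2) from regressing it on the
#' other variables (over z-scored values at the sampled cells) and
#' iteratively drops the largest-VIF variable while any VIF exceeds
#' \code{max_vif}. Perfectly collinear variables (infinite VIF) are dropped
#' immediately with a warning. All intermediate VIF tables are recorded.
#'
#' @param stack a \code{climate_stack}.
#' @param selected character vector of variable names entering the filter
#'   (e.g. \code{report$selected}), length >= 2.
#' @param max_vif retention threshold (default 5).
#' @param sample_cells,seed,max_cells as in \code{\link{select_variables}}.
#' @param report optional \code{selection_report} to update in place.
#' @return a \code{selection_report} with elements \code{vif} (final VIFs),
#'   \code{vif_steps} (list of intermediate VIF vectors), \code{dropped}
#'   and \code{selected} (the final names).
#' @export
vif_filter <- function(stack, selected, max_vif = 5, sample_cells = NULL,
                       seed = 1, max_cells = 50000L, report = NULL) {
  if (length(selected) < 2) stop("need at least two variables for VIF")
  X <- stack_value_matrix(stack, sample_cells, seed, max_cells)
  X <- scale(X[, selected, drop = FALSE])
  keep <- colnames(X)
  steps <- list()
  dropped <- character(0)
  repeat {
    v <- stats::setNames(vif_values(X[, keep, drop = FALSE]), keep)
    steps[[length(steps) + 1]] <- v
    if (any(is.infinite(v))) {
      worst <- names(v)[which(is.infinite(v))[1]]
      warning("perfect collinearity: dropping ", worst)
    } else if (max(v) > max_vif) {
      worst <- names(v)[which.max(v)]
    } else break
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
    if (length(keep) < 2) break
  }
  final <- stats::setNames(
    if (length(keep) >= 2) vif_values(X[, keep, drop = FALSE])
    else rep(1, length(keep)), keep)
  if (is.null(report))
    report <- structure(list(threshold = NA_real_), class = "selection_report")
  report$vif <- final
  report$vif_steps <- steps
  report$dropped <- dropped
  report$max_vif <- max_vif
  report$selected <- keep
  report
}
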