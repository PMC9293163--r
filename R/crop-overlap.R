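## Overlap of modelled pest suitability with a categorical crop-suitability
## map, summarised per category and tested with a one-way ANOVA plus
## Bonferroni-adjusted pairwise comparisons. Grid cells are treated as
## independent observations, as is conventional in this kind of overlap
## summary; spatial autocorrelation is not corrected for.

#' Summarize suitability within crop categories
#'
#' Pairs each crop-map cell with the pest suitability at the same location
#' (same grid, or nearest-neighbour lookup from the suitability grid with a
#' warning when grids differ); cells with nodata in either layer are
#' excluded pairwise.
#'
#' @param suitability a \code{suitability_map}.
#' @param crop a \code{crop_category_map}.
#' @return an \code{overlap_summary}: per-category n, mean and standard
#'   error, plus the paired per-cell values/categories for testing.
#' @export
overlay_summarize <- function(suitability, crop) {
  if (same_grid(suitability$grid, crop$grid)) {
    s <- as.vector(suitability$values)
  } else {
    warning("grids differ; resampling suitability to the crop grid by ",
            "nearest neighbour")
    ## crop-grid cell centers in column-major order, matching as.vector()
    s <- map_extract(suitability, cell_center(
      crop$grid,
      rep(seq_len(crop$grid$n_rows), crop$grid$n_cols),
      rep(seq_len(crop$grid$n_cols), each = crop$grid$n_rows)))
  }
  g <- as.character(crop$categories)
  keep <- !is.na(s) & !is.na(g)
  if (!any(keep)) stop("no overlapping valid cells between the two maps")
  s <- s[keep]; g <- factor(g[keep],
                            levels = c("suitable", "conditioned",
                                       "unsuitable"))
  g <- droplevels(g)
  per <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- s[g == lv]
    data.frame(category = lv, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(per) <- NULL
  structure(list(summary = per, values = s, categories = g),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' One-way ANOVA with Bonferroni pairwise post-hoc tests
#'
#' Fixed-effects one-way ANOVA across the groups, followed by all pairwise
#' two-sample pooled-variance t-tests with p-values multiplied by the
#' number of pairs (capped at 1).
#'
#' @param values numeric observations.
#' @param groups grouping factor; every group needs >= 2 values.
#' @return list with \code{F}, \code{df} (between, within),
#'   \code{p}, and a \code{pairwise} data frame (raw and Bonferroni p).
#' @export
anova_bonferroni <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with < 2 values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  a <- stats::anova(stats::lm(values ~ groups))
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    x <- values[groups == pairs[1, i]]
    y <- values[groups == pairs[2, i]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t = unname(tt$statistic), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs))
  }))
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]),
       p = a$`Pr(>F)`[1], pairwise = pw)
}

#' Crop-overlap analysis in one call
#'
#' Convenience wrapper: \code{\link{overlay_summarize}} followed by
#' \code{\link{anova_bonferroni}} on the per-cell values.
#'
#' @param suitability a \code{suitability_map}.
#' @param crop a \code{crop_category_map}.
#' @return the \code{overlap_summary} with an added \code{test} element.
#' @export
crop_overlap_test <- function(suitability, crop) {
  ov <- overlay_summarize(suitability, crop)
  ov$test <- anova_bonferroni(ov$values, ov$categories)
  ov
}
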