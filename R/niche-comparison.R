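## Niche contrast: climate at presence points vs randomized "no-record"
## points drawn from cells predicted unsuitable by both bound maps.

#' Sample sets of no-record points
#'
#' Eligible cells are valid cells that hold no presence record and whose
#' suitability falls below the cutoff in both the lower and the upper bound
#' map. Each of the \code{n_sets} sets samples exactly as many cells as
#' there are presence records, uniformly without replacement.
#'
#' @param stack a \code{climate_stack}.
#' @param presences an \code{occurrence_set}.
#' @param lower,upper bound \code{suitability_map}s from the ensemble.
#' @param cutoff suitability cutoff (default 0.55).
#' @param n_sets number of random sets (default 100).
#' @param seed integer RNG seed.
#' @return list of \code{occurrence_set}s (cell centers), length
#'   \code{n_sets}.
#' @export
sample_norecord_sets <- function(stack, presences, lower, upper,
                                 cutoff = 0.55, n_sets = 100, seed = 1) {
  cc <- point_to_cell(stack$grid, presences$longitude, presences$latitude)
  pres_idx <- stats::na.omit(cc$row + (cc$col - 1L) * stack$grid$n_rows)
  n_pres <- nrow(presences)
  eligible <- which(stack$mask &
                    !is.na(lower$values) & lower$values < cutoff &
                    !is.na(upper$values) & upper$values < cutoff)
  eligible <- setdiff(eligible, pres_idx)
  if (length(eligible) < n_pres)
    stop("eligible no-record pool (", length(eligible),
         " cells) smaller than the number of presences (", n_pres, ")")
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    cells <- sample(eligible, n_pres)
    rc <- arrayInd(cells, dim(stack$mask))
    ctr <- cell_center(stack$grid, rc[, 1], rc[, 2])
    occurrence_set(ctr$longitude, ctr$latitude, source = "no-record")
  })
}

#' Two-sample Student's t-test with pooled variance
#'
#' The classical equal-variance two-sample t-test with
#' df = n1 + n2 - 2 and a two-sided p-value, as used by
#' \code{\link{niche_ttests}}. Two identical samples give t = 0, p = 1;
#' zero pooled variance with unequal means gives an infinite t (p = 0),
#' reported as such.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  pooled_t(x, y)
}

pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  dm <- mean(x) - mean(y)
  df <- n1 + n2 - 2
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
  } else {
    t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Niche contrast t-tests per variable
#'
#' The no-record sets are reduced to a single comparison sample by
#' averaging the value vectors element-wise across sets
#' (\code{mode = "average"}, the default: set positions are random, so this
#' approximates the pooled no-record mean with reduced variance) or by
#' concatenating all sets (\code{mode = "pool"}). Each variable is then
#' compared between presences and the no-record sample by a two-sample
#' Student's t-test with pooled variance and df = n1 + n2 - 2.
#'
#' @param stack a \code{climate_stack}.
#' @param presences an \code{occurrence_set}.
#' @param sets list of no-record \code{occurrence_set}s from
#'   \code{\link{sample_norecord_sets}}.
#' @param vars variables to contrast (default: all layers).
#' @param mode \code{"average"} or \code{"pool"}.
#' @return data frame of class \code{niche_contrast}: per variable the
#'   presence mean/sd/quartiles, no-record mean/sd, t, df, two-sided p and
#'   the direction of preference.
#' @export
niche_ttests <- function(stack, presences, sets,
                         vars = layer_names(stack),
                         mode = c("average", "pool")) {
  mode <- match.arg(mode)
  pvals <- suppressWarnings(extract_values(stack, presences))[, vars,
                                                              drop = FALSE]
  pvals <- pvals[stats::complete.cases(pvals), , drop = FALSE]
  if (nrow(pvals) < 2) stop("need >= 2 presence points on valid cells")
  setvals <- lapply(sets, function(s)
    extract_values(stack, s)[, vars, drop = FALSE])
  nr <- if (mode == "average") Reduce(`+`, setvals) / length(setvals)
        else do.call(rbind, setvals)
  if (nrow(nr) < 2) stop("need >= 2 no-record points")
  rows <- lapply(vars, function(v) {
    x <- pvals[, v]; y <- nr[, v]
    tt <- pooled_t(x, y)
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(variable = v,
               presence_mean = mean(x), presence_sd = stats::sd(x),
               presence_min = q[1], presence_q25 = q[2],
               presence_median = q[3], presence_q75 = q[4],
               presence_max = q[5],
               norecord_mean = mean(y), norecord_sd = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p,
               direction = if (mean(x) > mean(y)) "higher"
                           else if (mean(x) < mean(y)) "lower" else "equal")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("niche_contrast", "data.frame")
  out
}
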