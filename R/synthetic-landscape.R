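## Synthetic-landscape generators. These emulate the statistical structure
## of the real inputs -- smooth climate fields, a logistic true niche,
## presence records sampled proportionally to true suitability, a
## three-category crop map, a farmer-survey table with a logit-linked attack
## process, and overdispersed per-tree counts -- so the whole pipeline can be
## exercised and its parameter recovery measured without any downloads.

## separable Gaussian blur with edge renormalisation
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  kern <- stats::dnorm(seq(-half, half), sd = sd)
  kern <- kern / sum(kern)
  blur1d <- function(x) {
    n <- length(x)
    padded <- c(rep(x[1], half), x, rep(x[n], half))
    stats::convolve(padded, rev(kern), type = "filter")
  }
  m <- t(apply(m, 1, blur1d))   # along rows
  apply(m, 2, blur1d)           # along columns
}

default_bioclim_names <- c("BIO3", "BIO7", "BIO10", "BIO15", "BIO18", "BIO19")
default_bioclim_ranges <- list(BIO3 = c(30, 60), BIO7 = c(20, 45),
                               BIO10 = c(15, 30), BIO15 = c(20, 90),
                               BIO18 = c(10, 200), BIO19 = c(50, 500))

#' Generate a synthetic climate stack
#'
#' Each layer is a smooth spatial field: seeded white noise low-pass
#' filtered with a Gaussian kernel of standard deviation \code{smoothness}
#' (in cells), then min-max rescaled to the layer's stated range. A mixing
#' weight \code{mix} in [0, 1] injects pairwise correlation by blending
#' every layer towards the first (weight 1 makes all layers perfectly
#' correlated).
#'
#' Default layer names are the six bioclimatic variables retained by the
#' pest-risk analysis this package supports (BIO3, BIO7, BIO10, BIO15,
#' BIO18, BIO19) with ranges typical of the Iberian Peninsula, so synthetic
#' and real configurations are interchangeable.
#'
#' @param seed integer RNG seed.
#' @param n_rows,n_cols grid dimensions.
#' @param n_vars number of layers (>= 2).
#' @param smoothness Gaussian kernel sd in cells (>= 0).
#' @param mix blending weight towards layer 1, in [0, 1].
#' @param names optional layer names.
#' @param ranges optional named list of c(min, max) per layer.
#' @param grid optional \code{raster_grid}; defaults to a unit-cell grid.
#' @return a \code{climate_stack}.
#' @export
generate_climate_stack <- function(seed, n_rows = 60, n_cols = 60,
                                   n_vars = 6, smoothness = 4, mix = 0,
                                   names = NULL, ranges = NULL, grid = NULL) {
  if (n_vars < 2) stop("n_vars must be >= 2")
  if (smoothness < 0) stop("smoothness must be >= 0")
  if (mix < 0 || mix > 1) stop("mix must lie in [0, 1]")
  if (is.null(names))
    names <- if (n_vars == 6) default_bioclim_names
             else paste0("VAR", seq_len(n_vars))
  if (is.null(ranges))
    ranges <- if (n_vars == 6) default_bioclim_ranges
              else stats::setNames(rep(list(c(0, 100)), n_vars), names)
  set.seed(seed)
  fields <- lapply(seq_len(n_vars), function(i)
    gaussian_blur(matrix(stats::rnorm(n_rows * n_cols), n_rows), smoothness))
  if (mix > 0 && n_vars > 1) {
    std <- function(m) (m - mean(m)) / stats::sd(m)
    base <- std(fields[[1]])
    for (i in 2:n_vars)
      fields[[i]] <- mix * base + (1 - mix) * std(fields[[i]])
  }
  layers <- lapply(seq_len(n_vars), function(i) {
    f <- fields[[i]]
    rng <- ranges[[names[i]]]
    if (is.null(rng)) rng <- c(0, 100)
    lo <- min(f); hi <- max(f)
    if (hi > lo) f <- (f - lo) / (hi - lo) else f[] <- 0.5
    rng[1] + f * (rng[2] - rng[1])
  })
  names(layers) <- names
  if (is.null(grid)) grid <- raster_grid(n_rows, n_cols)
  climate_stack(layers, grid)
}

#' Define a logistic true niche
#'
#' True suitability at a cell is
#' \code{plogis(intercept + sum(coef_i * z_i) + sum(quad_i * z_i^2))}
#' where \code{z_i} are the stack layers z-scored over valid cells, so
#' coefficients are comparable across variables with different units.
#'
#' @param intercept scalar intercept.
#' @param coef named numeric vector of linear coefficients (names must be
#'   layer names).
#' @param quad optional named numeric vector of quadratic coefficients.
#' @return object of class \code{true_niche}.
#' @export
true_niche <- function(intercept, coef, quad = NULL) {
  if (is.null(names(coef)) || any(names(coef) == ""))
    stop("'coef' must be a named vector")
  structure(list(intercept = intercept, coef = coef, quad = quad),
            class = "true_niche")
}

#' Evaluate a true niche over a stack
#' @param stack a \code{climate_stack}.
#' @param niche a \code{true_niche}.
#' @return a \code{suitability_map} of true suitabilities.
#' @export
niche_suitability <- function(stack, niche) {
  miss <- setdiff(names(niche$coef), layer_names(stack))
  if (length(miss)) stop("niche names a layer absent from the stack: ",
                         paste(miss, collapse = ", "))
  eta <- matrix(niche$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(niche$coef)) {
    v <- stack$layers[[nm]]
    z <- (v - mean(v[stack$mask])) / stats::sd(v[stack$mask])
    eta <- eta + niche$coef[[nm]] * z
    if (!is.null(niche$quad) && nm %in% names(niche$quad))
      eta <- eta + niche$quad[[nm]] * z^2
  }
  s <- stats::plogis(eta)
  s[!stack$mask] <- NA_real_
  suitability_map(s, stack$grid)
}

#' Sample presence records proportionally to true suitability
#'
#' Valid cells are drawn with replacement with probability proportional to
#' the true suitability surface; records are placed at cell centers. This
#' mirrors how a compiled occurrence data set over-represents climatically
#' favourable areas.
#'
#' @param stack a \code{climate_stack}.
#' @param truth a \code{true_niche} or \code{suitability_map}.
#' @param n number of records (>= 1).
#' @param seed integer RNG seed.
#' @param role role tag for the records.
#' @return an \code{occurrence_set} of \code{n} records.
#' @export
sample_presences <- function(stack, truth, n, seed, role = "train") {
  if (n < 1) stop("n must be >= 1")
  s <- if (inherits(truth, "true_niche")) niche_suitability(stack, truth)
       else truth
  p <- s$values[stack$mask]
  if (all(p == 0)) stop("true suitability is zero everywhere; cannot sample")
  idx_valid <- which(stack$mask)
  set.seed(seed)
  cells <- sample(idx_valid, n, replace = TRUE, prob = p)
  rc <- arrayInd(cells, dim(stack$mask))
  ctr <- cell_center(stack$grid, rc[, 1], rc[, 2])
  occurrence_set(ctr$longitude, ctr$latitude, source = "synthetic",
                 year = NA_integer_, role = role)
}

#' Generate a synthetic three-category crop-suitability map
#'
#' A smooth seeded field is thresholded by rank so the three categories
#' (suitable, conditioned, unsuitable) occupy the requested areal
#' proportions exactly (within one cell of rounding); level sets of a
#' smooth field give contiguous-looking regions.
#'
#' @param x a \code{climate_stack} or \code{raster_grid} defining the grid.
#' @param proportions numeric length 3 (suitable, conditioned, unsuitable),
#'   summing to 1.
#' @param seed integer RNG seed.
#' @param smoothness Gaussian kernel sd in cells.
#' @return a \code{crop_category_map}.
#' @export
generate_crop_map <- function(x, proportions = c(1, 1, 1) / 3, seed = 1,
                              smoothness = 6) {
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-8)
    stop("'proportions' must be three values summing to 1")
  grid <- if (inherits(x, "climate_stack")) x$grid else x
  mask <- if (inherits(x, "climate_stack")) x$mask
          else matrix(TRUE, grid$n_rows, grid$n_cols)
  set.seed(seed)
  f <- gaussian_blur(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                            grid$n_rows), smoothness)
  idx <- which(mask)
  n <- length(idx)
  ord <- idx[order(f[idx])]
  k1 <- round(proportions[1] * n)
  k2 <- round(proportions[2] * n)
  cats <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  cats[ord[seq_len(k1)]] <- "suitable"
  if (k2 > 0) cats[ord[k1 + seq_len(min(k2, n - k1))]] <- "conditioned"
  rest <- ord[-seq_len(min(k1 + k2, n))]
  if (length(rest)) cats[rest] <- "unsuitable"
  crop_category_map(cats, grid)
}

#' Specify a synthetic farmer survey
#'
#' Parameters of the survey data-generating process: field count, a
#' log-normal field-area distribution, an age-composition sampler (a
#' mixture of single-age-class fields and Dirichlet-mixed fields, since
#' real plantations are often uniform-aged), binary-logit attack
#' coefficients, and proportional-odds impact coefficients with two
#' thresholds.
#'
#' Coefficient vectors are named by covariate: \code{area_ha},
#' \code{pct_age_0_3}, \code{pct_age_4_8}, \code{pct_age_gt8},
#' \code{suitability}; missing names mean a zero coefficient.
#'
#' @param n_fields number of survey rows.
#' @param area_meanlog,area_sdlog log-normal parameters for area (ha).
#' @param pure_prob probability a field is 100% one age class.
#' @param pure_weights length-3 weights over the pure classes.
#' @param age_alpha Dirichlet concentration for mixed-age fields.
#' @param attack_intercept,attack_coef binary-logit attack model.
#' @param impact_coef proportional-odds covariate coefficients.
#' @param impact_thresholds two increasing cumulative-logit thresholds.
#' @return object of class \code{survey_spec}.
#' @export
survey_spec <- function(n_fields = 165,
                        area_meanlog = log(6), area_sdlog = 1,
                        pure_prob = 0.64,
                        pure_weights = c(42, 49, 14) / 105,
                        age_alpha = c(1.5, 1.5, 0.7),
                        attack_intercept = -0.5,
                        attack_coef = c(suitability = 0.8),
                        impact_coef = c(suitability = -0.8),
                        impact_thresholds = c(0, 1.5)) {
  stopifnot(n_fields >= 1, area_sdlog > 0,
            pure_prob >= 0, pure_prob <= 1,
            length(impact_thresholds) == 2,
            diff(impact_thresholds) > 0)
  structure(list(n_fields = n_fields, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, pure_prob = pure_prob,
                 pure_weights = pure_weights / sum(pure_weights),
                 age_alpha = age_alpha,
                 attack_intercept = attack_intercept,
                 attack_coef = attack_coef,
                 impact_coef = impact_coef,
                 impact_thresholds = impact_thresholds),
            class = "survey_spec")
}

lin_pred <- function(coef, df) {
  eta <- rep(0, nrow(df))
  for (nm in names(coef)) {
    if (!nm %in% names(df)) stop("coefficient names unknown covariate: ", nm)
    eta <- eta + coef[[nm]] * df[[nm]]
  }
  eta
}

#' Generate a synthetic farmer-survey table
#'
#' Rows follow the standard survey schema: region, area (ha), percentage
#' of the plantation in age classes 0-3 / 4-8 / >8 years (summing to 100),
#' beetle suitability at the field location, a Bernoulli attack indicator
#' drawn from a logistic model, and -- for attacked fields only -- an
#' ordinal impact rank (0 = no loss, 1 = <10\%, 2 = >=10\%) drawn from a
#' proportional-odds model. Impact is NA when attack = 0.
#'
#' @param spec a \code{survey_spec}.
#' @param suitability per-field beetle suitability in [0, 1]; recycled;
#'   drawn uniformly if NULL.
#' @param seed integer RNG seed.
#' @return a data frame of class \code{survey_table}.
#' @export
generate_survey_table <- function(spec, suitability = NULL, seed = 1) {
  set.seed(seed)
  n <- spec$n_fields
  area <- stats::rlnorm(n, spec$area_meanlog, spec$area_sdlog)
  pure <- stats::runif(n) < spec$pure_prob
  ages <- matrix(0, n, 3)
  which_pure <- sample.int(3, n, replace = TRUE, prob = spec$pure_weights)
  ages[cbind(which(pure), which_pure[pure])] <- 100
  n_mix <- sum(!pure)
  if (n_mix > 0) {
    g <- matrix(stats::rgamma(n_mix * 3, shape = rep(spec$age_alpha,
                                                     each = n_mix)), n_mix)
    ages[!pure, ] <- 100 * g / rowSums(g)
  }
  if (is.null(suitability)) suitability <- stats::runif(n)
  suitability <- rep_len(suitability, n)
  df <- data.frame(region = "synthetic", municipality = NA_character_,
                   area_ha = area,
                   pct_age_0_3 = ages[, 1], pct_age_4_8 = ages[, 2],
                   pct_age_gt8 = ages[, 3],
                   suitability = suitability)
  eta_a <- spec$attack_intercept + lin_pred(spec$attack_coef, df)
  df$attack <- stats::rbinom(n, 1, stats::plogis(eta_a))
  eta_i <- lin_pred(spec$impact_coef, df)
  th <- spec$impact_thresholds
  u <- stats::runif(n)
  p0 <- stats::plogis(th[1] - eta_i)
  p01 <- stats::plogis(th[2] - eta_i)
  impact <- ifelse(u <= p0, 0L, ifelse(u <= p01, 1L, 2L))
  df$impact <- ifelse(df$attack == 1L, impact, NA_integer_)
  df <- df[, c("region", "municipality", "area_ha", "pct_age_0_3",
               "pct_age_4_8", "pct_age_gt8", "attack", "impact",
               "suitability")]
  class(df) <- c("survey_table", "data.frame")
  df
}

#' Generate clumped per-tree counts
#'
#' Counts of individuals (or egg clusters) per tree drawn from a negative
#' binomial: a few trees accumulate most observations, as seen in
#' structured orchard sampling. Smaller \code{dispersion} (the size
#' parameter k) gives stronger clumping and larger skewness; the
#' \code{dispersion = Inf} limit is Poisson.
#'
#' @param n_trees number of trees (rows).
#' @param means named numeric vector of per-tree mean counts, one entry per
#'   count type (e.g. males, females, copulae, egg_clusters); all > 0.
#' @param dispersion negative-binomial size k (> 0; Inf = Poisson).
#' @param seed integer RNG seed.
#' @return data frame of class \code{tree_count_table}, one column per
#'   count type.
#' @export
generate_tree_counts <- function(n_trees = 59,
                                 means = c(males = 20, females = 20,
                                           copulae = 8, egg_clusters = 1.5),
                                 dispersion = 0.6, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (any(means <= 0)) stop("all means must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(names(means))) names(means) <- paste0("count", seq_along(means))
  set.seed(seed)
  cols <- lapply(means, function(mu) {
    if (is.infinite(dispersion)) stats::rpois(n_trees, mu)
    else stats::rnbinom(n_trees, size = dispersion, mu = mu)
  })
  df <- as.data.frame(cols)
  class(df) <- c("tree_count_table", "data.frame")
  df
}
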