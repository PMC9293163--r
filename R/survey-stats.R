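## Field (per-tree) clumping statistics and farmer-survey regressions:
## Shapiro-Wilk + skewness diagnostics of per-tree counts, Pearson
## correlations between count types, single-covariate binary logistic
## models of attack probability, and proportional-odds models of the
## perceived-impact rank.

#' Read a farmer-survey table from CSV
#'
#' Expected columns: \code{region, municipality, area_ha, pct_age_0_3,
#' pct_age_4_8, pct_age_gt8, attack, impact, suitability} (the last is
#' optional). Age percentages must sum to 100 within 0.5; a recorded
#' impact requires \code{attack = 1}.
#'
#' @param path CSV file path.
#' @return a data frame of class \code{survey_table}.
#' @export
read_survey_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_ha", "pct_age_0_3", "pct_age_4_8", "pct_age_gt8", "attack")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  tot <- df$pct_age_0_3 + df$pct_age_4_8 + df$pct_age_gt8
  bad <- which(abs(tot - 100) > 0.5)
  if (length(bad)) stop("age percentages do not sum to 100 at row ", bad[1])
  if (!all(df$attack %in% c(0, 1))) stop("attack must be 0/1")
  if ("impact" %in% names(df)) {
    bad <- which(!is.na(df$impact) & df$attack == 0 & df$impact != 0)
    if (length(bad))
      stop("non-zero impact recorded with attack = 0 at row ", bad[1])
  }
  class(df) <- c("survey_table", "data.frame")
  df
}

#' Clumping diagnostics for per-tree counts
#'
#' Shapiro-Wilk normality test (Royston approximation, as in
#' \code{shapiro.test}) and the sample skewness: g1 = m3 / m2^(3/2) plus
#' the small-sample adjusted G1. Strong positive skewness with rejected
#' normality indicates a clumped distribution -- a few trees accumulating
#' most observations.
#'
#' @param counts integer vector of per-tree counts, n >= 3, not all equal.
#' @return list with \code{W}, \code{p}, \code{skewness} (g1),
#'   \code{skewness_adj} (G1) and \code{n}.
#' @export
clumping_stats <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 3) stop("need at least 3 counts")
  if (stats::sd(counts) == 0)
    stop("all counts equal; Shapiro-Wilk W is undefined")
  sw <- stats::shapiro.test(counts)
  list(W = unname(sw$statistic), p = sw$p.value,
       skewness = e1071::skewness(counts, type = 1),
       skewness_adj = e1071::skewness(counts, type = 2),
       n = length(counts))
}

#' Pearson correlations among per-tree count types
#'
#' Tests the standard pairs: males-females, males-copulae,
#' copulae-egg_clusters, and copulae against egg clusters per copula
#' (the ratio is undefined on trees with zero copulae; those trees are
#' dropped for that pair and the drop is noted).
#'
#' @param table a \code{tree_count_table} with columns \code{males},
#'   \code{females}, \code{copulae}, \code{egg_clusters}.
#' @return data frame with pair, n, r, t, df, p and a note column
#'   (degenerate pairs are flagged, not errored).
#' @export
count_correlations <- function(table) {
  need <- c("males", "females", "copulae", "egg_clusters")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("tree count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  pairs <- list(c("males", "females"), c("males", "copulae"),
                c("copulae", "egg_clusters"),
                c("copulae", "egg_clusters_per_copula"))
  ratio <- ifelse(table$copulae > 0,
                  table$egg_clusters / table$copulae, NA_real_)
  dat <- cbind(as.data.frame(table), egg_clusters_per_copula = ratio)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- dat[[pr[1]]]; y <- dat[[pr[2]]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    note <- if (sum(!keep)) paste(sum(!keep), "row(s) dropped (undefined ratio)")
            else ""
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(pair = paste(pr, collapse = " ~ "), n = length(x),
                        r = NA_real_, t = NA_real_, df = NA_integer_,
                        p = NA_real_,
                        note = paste(note, "degenerate: correlation undefined")))
    }
    ct <- stats::cor.test(x, y)
    data.frame(pair = paste(pr, collapse = " ~ "), n = length(x),
               r = unname(ct$estimate), t = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value, note = note)
  }))
  rownames(out) <- NULL
  out
}

#' Binary logistic regression of attack on one covariate
#'
#' Maximum-likelihood logistic fit of the attack indicator on a single
#' covariate; reports the likelihood-ratio chi-square against the
#' intercept-only model (df = 1), the deviance explained
#' D2 = (null deviance - residual deviance) / null deviance, and the
#' two-sided chi-square p-value. Perfect separation is detected and
#' reported as non-estimable rather than returning runaway estimates.
#'
#' @param table a \code{survey_table}.
#' @param covariate name of the covariate column.
#' @return list with \code{chisq}, \code{df}, \code{D2}, \code{p},
#'   \code{coef}, \code{estimable} and, when non-estimable, a
#'   \code{diagnostic} message.
#' @export
attack_logistic <- function(table, covariate) {
  if (!covariate %in% names(table)) stop("unknown covariate: ", covariate)
  df <- data.frame(attack = table$attack, x = table[[covariate]])
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$attack)) < 2)
    stop("both attack outcomes must be present")
  fit <- suppressWarnings(stats::glm(attack ~ x, family = stats::binomial(),
                                     data = df))
  sep <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    all(abs(fit$fitted.values - df$attack) < 1e-8)
  chisq <- fit$null.deviance - fit$deviance
  out <- list(covariate = covariate,
              chisq = chisq, df = 1L,
              D2 = chisq / fit$null.deviance,
              p = stats::pchisq(chisq, 1, lower.tail = FALSE),
              coef = stats::coef(fit), n = nrow(df),
              estimable = !sep)
  if (sep) {
    out$diagnostic <- paste("perfect or quasi-perfect separation on",
                            covariate, "; estimates not interpretable")
    out$chisq <- out$D2 <- out$p <- NA_real_
  }
  out
}

#' Ordered (proportional-odds) logistic regression of impact on one covariate
#'
#' Cumulative-logit maximum-likelihood fit of the perceived-impact rank
#' (0 = no loss, 1 = <10\%, 2 = >=10\%) on a single covariate. All fields
#' enter: non-attacked fields count as rank 0 (no loss). Reports the Wald
#' t = coefficient / SE with a two-sided normal-approximation p-value, the
#' model df as the number of threshold parameters, and McFadden's deviance
#' explained D2.
#'
#' @param table a \code{survey_table}.
#' @param covariate name of the covariate column.
#' @return list with \code{t}, \code{df}, \code{D2}, \code{p},
#'   \code{coef}, \code{se}, \code{thresholds}, \code{n}.
#' @export
impact_ordinal <- function(table, covariate) {
  if (!covariate %in% names(table)) stop("unknown covariate: ", covariate)
  impact <- ifelse(is.na(table$impact) & table$attack == 0, 0L, table$impact)
  df <- data.frame(impact = impact, x = table[[covariate]])
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$impact)) < 2)
    stop("need >= 2 distinct impact ranks")
  df$impact <- factor(df$impact, ordered = TRUE)
  fit <- MASS::polr(impact ~ x, data = df, Hess = TRUE)
  null <- MASS::polr(impact ~ 1, data = df, Hess = TRUE)
  sm <- summary(fit)$coefficients
  tval <- sm["x", "t value"]
  list(covariate = covariate,
       t = tval, df = length(fit$zeta),
       D2 = 1 - fit$deviance / null$deviance,
       p = 2 * stats::pnorm(-abs(tval)),
       coef = unname(stats::coef(fit)["x"]), se = sm["x", "Std. Error"],
       thresholds = fit$zeta, n = nrow(df))
}

#' Descriptive survey summaries
#'
#' Counts of single-age-class fields (a field is "young-only" when 100% of
#' its area is 0-3 years old, within the 0.5 percentage-point tolerance),
#' fields with no old (>8 y) trees, area statistics, and per-region
#' tallies.
#'
#' @param table a \code{survey_table}.
#' @return list of counts and area statistics.
#' @export
survey_summaries <- function(table) {
  n <- nrow(table)
  if (n == 0)
    return(list(n = 0L, young_only = 0L, moderate_only = 0L, old_only = 0L,
                no_old = 0L, area_mean = NA_real_, area_se = NA_real_,
                area_min = NA_real_, area_max = NA_real_,
                by_region = table(character(0))))
  tol <- 0.5
  list(n = n,
       young_only = sum(table$pct_age_0_3 >= 100 - tol),
       moderate_only = sum(table$pct_age_4_8 >= 100 - tol),
       old_only = sum(table$pct_age_gt8 >= 100 - tol),
       no_old = sum(table$pct_age_gt8 <= tol),
       area_mean = mean(table$area_ha),
       area_se = stats::sd(table$area_ha) / sqrt(n),
       area_min = min(table$area_ha),
       area_max = max(table$area_ha),
       by_region = if ("region" %in% names(table)) table(table$region)
                   else table(character(0)))
}
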