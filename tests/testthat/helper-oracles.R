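# Shared fixtures and independent brute-force oracles.

# stack from named list of matrices on a unit-cell grid
make_stack <- function(layers, cellsize = 1) {
  d <- dim(layers[[1]])
  climate_stack(layers, raster_grid(d[1], d[2], cellsize = cellsize))
}

# standard synthetic scenario: optimum-shaped niche on a smooth landscape
scenario_truth <- function(stack) {
  vars <- layer_names(stack)
  true_niche(2.5,
             stats::setNames(c(-0.8, 0.6, 0.6, 0.4, -0.6, -0.5)[seq_along(vars)],
                             vars),
             quad = stats::setNames(rep(-1.2, length(vars)), vars))
}

# brute-force envelope partition: explicit loop over cells and variables
bf_partition <- function(stack, envelope) {
  g <- stack$grid
  lim <- envelope$limits
  cls <- matrix(NA_character_, g$n_rows, g$n_cols)
  for (r in seq_len(g$n_rows)) {
    for (cc in seq_len(g$n_cols)) {
      if (!stack$mask[r, cc]) next
      fails <- 0L
      for (i in seq_len(nrow(lim))) {
        v <- stack$layers[[lim$variable[i]]][r, cc]
        if (v < lim$min[i] || v > lim$max[i]) fails <- fails + 1L
      }
      cls[r, cc] <- if (fails == 0L) "background"
                    else if (fails == 1L) "excluded" else "pseudoabsence"
    }
  }
  cls
}

# brute-force AUC: count concordant pairs, ties worth 1/2
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force greedy Ward agglomeration (Lance-Williams update matching
# hclust's ward.D2): returns merge heights and the partition at height h
bf_ward <- function(d, h_cut) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d
  diag(D) <- Inf
  heights <- numeric(0)
  membership <- seq_len(n)
  repeat {
    if (length(active) == 1) break
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    hgt <- D[i, j]
    heights <- c(heights, hgt)
    if (hgt <= h_cut)
      membership[membership == membership[active[[j]][1]]] <-
        membership[active[[i]][1]]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in seq_along(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D[i, k] <- D[k, i] <- sqrt(((ni + nk) * D[i, k]^2 +
                                  (nj + nk) * D[j, k]^2 -
                                  nk * hgt^2) / (ni + nj + nk))
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    active <- active[-j]; sizes <- sizes[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  list(heights = sort(heights),
       membership = as.integer(factor(membership)))
}

# two columns with an exact sample correlation r (up to rounding)
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  xs <- as.numeric(scale(x)); zs <- as.numeric(scale(z))
  cbind(x = xs, y = r * xs + sqrt(1 - r^2) * zs)
}
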