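## Presence-only environmental envelope and landscape partition.
## The envelope is the per-variable [min, max] interval spanned by presence
## cells (closed intervals: boundary values count as inside, so every
## presence cell is inside its own envelope). Cells inside the envelope for
## every variable form the background pool; cells outside the interval for
## at least two variables form the pseudoabsence pool; cells failing exactly
## one variable belong to neither pool and are excluded.

#' Build a presence-only environmental envelope
#'
#' @param stack a \code{climate_stack}.
#' @param presences an \code{occurrence_set}; records on masked cells are
#'   dropped with a warning.
#' @param selected variable names the envelope is defined over (default:
#'   all layers).
#' @return an \code{envelope_model}: per-variable rows with \code{min} and
#'   \code{max} observed at presence cells.
#' @export
build_envelope <- function(stack, presences,
                           selected = layer_names(stack)) {
  miss <- setdiff(selected, layer_names(stack))
  if (length(miss)) stop("variables absent from the stack: ",
                         paste(miss, collapse = ", "))
  vals <- suppressWarnings(extract_values(stack, presences))
  vals <- vals[, selected, drop = FALSE]
  ok <- stats::complete.cases(vals)
  if (!any(ok)) stop("no usable presence records on valid cells")
  if (any(!ok))
    warning(sum(!ok), " presence record(s) on masked/off-grid cells dropped")
  vals <- vals[ok, , drop = FALSE]
  lim <- data.frame(variable = selected,
                    min = apply(vals, 2, min),
                    max = apply(vals, 2, max),
                    row.names = NULL)
  structure(list(limits = lim, n_presences = sum(ok)),
            class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat("envelope_model over", nrow(x$limits), "variable(s),",
      x$n_presences, "presence record(s)\n")
  print(x$limits)
  invisible(x)
}

#' Partition valid cells by envelope membership
#'
#' For every valid cell, counts the envelope variables whose value falls
#' strictly outside the closed interval [min, max]; classifies the cell as
#' \code{background} (0 failures), \code{excluded} (exactly 1) or
#' \code{pseudoabsence} (>= 2).
#'
#' @param stack a \code{climate_stack}.
#' @param envelope an \code{envelope_model} whose variables are all layers
#'   of the stack.
#' @return a \code{cell_partition}: matrices \code{n_failed} (integer) and
#'   \code{class} (character, background/excluded/pseudoabsence; NA on
#'   masked cells), plus the grid.
#' @export
partition_cells <- function(stack, envelope) {
  vars <- envelope$limits$variable
  miss <- setdiff(vars, layer_names(stack))
  if (length(miss)) stop("stack lacks envelope variable(s): ",
                         paste(miss, collapse = ", "))
  nf <- matrix(0L, stack$grid$n_rows, stack$grid$n_cols)
  for (i in seq_along(vars)) {
    m <- stack$layers[[vars[i]]]
    out <- (m < envelope$limits$min[i]) | (m > envelope$limits$max[i])
    nf <- nf + ifelse(out, 1L, 0L)
  }
  nf[!stack$mask] <- NA_integer_
  cls <- matrix(ifelse(nf == 0L, "background",
                ifelse(nf == 1L, "excluded", "pseudoabsence")),
                nrow = stack$grid$n_rows)
  structure(list(grid = stack$grid, n_failed = nf, class = cls),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat("cell_partition:\n")
  print(table(as.character(x$class), useNA = "ifany"))
  invisible(x)
}

#' Sample background and pseudoabsence points from a partition
#'
#' Uniform sampling without replacement within each pool; points are placed
#' at cell centers.
#'
#' @param partition a \code{cell_partition}.
#' @param n_background,n_pseudoabsence sample sizes (0 allowed).
#' @param seed integer RNG seed.
#' @return list with \code{background} and \code{pseudoabsence}, each an
#'   \code{occurrence_set} (source tag records the pool).
#' @export
sample_envelope_points <- function(partition, n_background,
                                   n_pseudoabsence, seed) {
  set.seed(seed)
  draw <- function(pool_name, n) {
    pool <- which(!is.na(partition$class) & partition$class == pool_name)
    if (n > length(pool))
      stop("requested ", n, " ", pool_name, " points but pool has only ",
           length(pool), " cells")
    cells <- if (n == 0) integer(0) else sample(pool, n)
    rc <- arrayInd(cells, c(partition$grid$n_rows, partition$grid$n_cols))
    ctr <- cell_center(partition$grid, rc[, 1], rc[, 2])
    occurrence_set(ctr$longitude, ctr$latitude, source = pool_name)
  }
  list(background = draw("background", n_background),
       pseudoabsence = draw("pseudoabsence", n_pseudoabsence))
}
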