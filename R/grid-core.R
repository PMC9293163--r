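#' Define a raster grid
#'
#' A grid describes the geometry shared by every raster in an analysis:
#' number of rows and columns, cell size, and the coordinates of the
#' lower-left corner. Cells are half-open intervals \code{[x, x + dx)} in
#' longitude and \code{[y, y + dy)} in latitude; row 1 is the northernmost
#' row and the grid is addressed row-major.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param xmin,ymin coordinates of the lower-left corner (degrees).
#' @param cellsize cell edge length (degrees); cells are square.
#' @param crs coordinate reference label, default \code{"WGS84"}.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(n_rows, n_cols, xmin = 0, ymin = 0,
                        cellsize = 1, crs = "WGS84") {
  stopifnot(n_rows >= 1, n_cols >= 1, cellsize > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         xmin = xmin, ymin = ymin, cellsize = cellsize,
         xmax = xmin + n_cols * cellsize, ymax = ymin + n_rows * cellsize,
         crs = crs),
    class = "raster_grid")
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Assemble a multi-layer climate stack
#'
#' Bundles named layers (matrices of identical shape) on a common grid and
#' derives the shared validity mask: a cell is valid only if it is non-NA in
#' every layer (union of per-layer nodata). Masked cells are set to NA in
#' all layers so the stack invariant -- each cell valid everywhere or
#' nowhere -- holds by construction.
#'
#' @param layers named list of numeric matrices, all \code{n_rows x n_cols}.
#' @param grid a \code{raster_grid}.
#' @return an object of class \code{climate_stack} with elements
#'   \code{grid}, \code{layers} and \code{mask} (logical matrix, TRUE =
#'   valid).
#' @export
climate_stack <- function(layers, grid) {
  if (length(layers) < 1) stop("at least one layer is required")
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    stop("all layers must be named")
  if (anyDuplicated(nms))
    stop("duplicate layer names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != grid$n_rows) || any(dims[2, ] != grid$n_cols))
    stop("layer dimensions do not match the grid (",
         grid$n_rows, " x ", grid$n_cols, ")")
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat("climate_stack:", length(x$layers), "layer(s),",
      x$grid$n_rows, "x", x$grid$n_cols, "cells,",
      sum(x$mask), "valid\n")
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Number of layers / layer names of a stack
#' @param stack a \code{climate_stack}.
#' @return character vector of layer names.
#' @export
layer_names <- function(stack) names(stack$layers)

#' Continuous suitability map
#'
#' A single raster of values in \code{[0, 1]} on a given grid; NA marks
#' nodata. Values outside the unit interval are rejected.
#'
#' @param values numeric matrix.
#' @param grid a \code{raster_grid}.
#' @return object of class \code{suitability_map}.
#' @export
suitability_map <- function(values, grid) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("suitability values must lie in [0, 1]")
  structure(list(grid = grid, values = values), class = "suitability_map")
}

#' Categorical crop-suitability map
#'
#' Three-category raster: \code{suitable}, \code{conditioned} (suitable only
#' under restrictions such as early-spring planting), \code{unsuitable};
#' NA marks nodata.
#'
#' @param categories character matrix with entries from the closed set
#'   above (NA = nodata).
#' @param grid a \code{raster_grid}.
#' @return object of class \code{crop_category_map}.
#' @export
crop_category_map <- function(categories, grid) {
  stopifnot(nrow(categories) == grid$n_rows, ncol(categories) == grid$n_cols)
  lev <- c("suitable", "conditioned", "unsuitable")
  vals <- as.character(categories)
  bad <- !is.na(vals) & !(vals %in% lev)
  if (any(bad))
    stop("unknown crop categories: ", paste(unique(vals[bad]), collapse = ", "))
  m <- matrix(vals, nrow = grid$n_rows)
  structure(list(grid = grid, categories = m), class = "crop_category_map")
}

#' Build an occurrence set from coordinates
#'
#' @param longitude,latitude numeric vectors of equal length (degrees).
#' @param source optional character vector of record provenance tags.
#' @param year optional integer vector.
#' @param role record role, \code{"train"} or \code{"validation"}; recycled.
#' @return a data frame of class \code{occurrence_set} with columns
#'   \code{longitude, latitude, source, year, role}.
#' @export
occurrence_set <- function(longitude, latitude, source = NA_character_,
                           year = NA_integer_, role = "train") {
  longitude <- as.numeric(longitude); latitude <- as.numeric(latitude)
  n <- length(longitude)
  if (length(latitude) != n) stop("longitude and latitude lengths differ")
  if (any(!is.finite(longitude)) || any(!is.finite(latitude)))
    stop("coordinates must be finite")
  if (any(latitude < -90 | latitude > 90))
    stop("latitude out of range [-90, 90] at row ",
         which(latitude < -90 | latitude > 90)[1])
  if (any(longitude < -360 | longitude > 360))
    stop("longitude out of plausible range at row ",
         which(longitude < -360 | longitude > 360)[1])
  role <- match.arg(role, c("train", "validation"))
  out <- data.frame(longitude = longitude, latitude = latitude,
                    source = rep_len(as.character(source), n),
                    year = rep_len(as.integer(year), n),
                    role = rep_len(role, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Read georeferenced occurrence records from CSV
#'
#' Expects a header with at least \code{longitude} and \code{latitude}
#' columns (optional \code{source}, \code{year}). Non-numeric or
#' out-of-range coordinates raise an error naming the offending row. The
#' number of records read is reported via a message.
#'
#' @param path CSV file path.
#' @param role role assigned to every record: \code{"train"} or
#'   \code{"validation"}.
#' @return an \code{occurrence_set}.
#' @export
read_occurrences <- function(path, role = "train") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("longitude", "latitude")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("occurrence CSV lacks column(s): ", paste(miss, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad))
      stop("non-numeric ", cn, " at row ", bad[1], ": '", raw[[cn]][bad[1]], "'")
    if (anyNA(v)) stop("missing ", cn, " at row ", which(is.na(v))[1])
    raw[[cn]] <- v
  }
  out <- occurrence_set(raw$longitude, raw$latitude,
                        source = if ("source" %in% names(raw)) raw$source else NA,
                        year = if ("year" %in% names(raw)) raw$year else NA,
                        role = role)
  message(nrow(out), " occurrence record(s) read from ", path,
          " (role = ", role, ")")
  out
}

## fractional index -> cell, half-open cells, row 1 = northernmost
point_to_cell <- function(grid, longitude, latitude) {
  col <- floor((longitude - grid$xmin) / grid$cellsize) + 1L
  row <- floor((grid$ymax - latitude) / grid$cellsize) + 1L
  ## a point exactly on the top/right outer edge belongs to the last cell
  row[latitude == grid$ymax] <- 1L
  col[longitude == grid$xmax & col == grid$n_cols + 1L] <- grid$n_cols
  inside <- row >= 1L & row <= grid$n_rows & col >= 1L & col <= grid$n_cols
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Coordinates of cell centers
#' @param grid a \code{raster_grid}.
#' @param row,col integer cell indices (row 1 = northernmost).
#' @return data frame with \code{longitude}, \code{latitude}.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(longitude = grid$xmin + (col - 0.5) * grid$cellsize,
             latitude = grid$ymax - (row - 0.5) * grid$cellsize)
}

#' Extract per-point layer values from a stack
#'
#' Each point is assigned to the cell containing it (half-open cells,
#' index by flooring the fractional offset). Points outside the grid extent
#' or on masked cells yield NA rows and are flagged, never silently
#' dropped.
#'
#' @param stack a \code{climate_stack}.
#' @param points an \code{occurrence_set} or data frame with
#'   \code{longitude}, \code{latitude}.
#' @return numeric matrix (points x layers) with attributes
#'   \code{"cell"} (row/col data frame), \code{"missing"} (integer indices
#'   of points that are off-grid or on masked cells).
#' @export
extract_values <- function(stack, points) {
  cc <- point_to_cell(stack$grid, points$longitude, points$latitude)
  n <- nrow(cc)
  idx <- ifelse(is.na(cc$row), NA_integer_,
                cc$row + (cc$col - 1L) * stack$grid$n_rows)
  out <- vapply(stack$layers, function(m) m[idx], numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1L,
                             dimnames = list(NULL, layer_names(stack)))
  masked <- !is.na(idx) & !stack$mask[idx]
  out[masked, ] <- NA_real_
  missing <- which(is.na(idx) | masked)
  if (length(missing) == n && n > 0)
    stop("all points fall outside the grid extent or on masked cells")
  if (length(missing))
    warning(length(missing), " point(s) off-grid or on masked cells; ",
            "returned as NA rows")
  attr(out, "cell") <- cc
  attr(out, "missing") <- missing
  out
}

#' Thin occurrences to one record per grid cell
#'
#' Standard practice before presence-only model fitting: duplicate records
#' in the same cell carry no extra climatic information and bias sampling
#' effort. The first record per occupied cell is kept.
#'
#' @param stack a \code{climate_stack} (supplies the grid).
#' @param points an \code{occurrence_set}.
#' @return the thinned \code{occurrence_set}.
#' @export
thin_occurrences <- function(stack, points) {
  cc <- point_to_cell(stack$grid, points$longitude, points$latitude)
  key <- paste(cc$row, cc$col)
  keep <- !duplicated(key) | is.na(cc$row)
  points[keep, , drop = FALSE]
}
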