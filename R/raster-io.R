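## Raster I/O: ESRI ASCII grid (.asc). Values are written with %.17g so a
## write/read cycle reproduces doubles exactly; nodata cells use the
## NODATA_value tag. Row 1 of the matrix is the northernmost row, matching
## the on-disk row order of the format.

write_asc <- function(values, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    sprintf("xllcorner %.17g", grid$xmin),
    sprintf("yllcorner %.17g", grid$ymin),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  for (r in seq_len(grid$n_rows))
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, as.is = TRUE,
                           col.names = c("key", "value"))
  key <- tolower(hdr$key)
  g <- as.numeric(hdr$value)
  names(g) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key)) stop("malformed .asc header in ", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- g[["nrows"]]; nc <- g[["ncols"]]
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == g[["nodata_value"]]] <- NA_real_
  list(values = m,
       grid = raster_grid(nr, nc, xmin = g[["xllcorner"]],
                          ymin = g[["yllcorner"]], cellsize = g[["cellsize"]]))
}

#' Read a stack of single-layer rasters
#'
#' All files must share the same grid; the stack mask is the union of the
#' per-layer nodata masks.
#'
#' @param paths character vector of .asc file paths.
#' @param names layer names, one per file (defaults to file basenames).
#' @return a \code{climate_stack}.
#' @export
read_raster_stack <- function(paths, names = NULL) {
  if (length(paths) < 1) stop("at least one raster path is required")
  if (is.null(names))
    names <- sub("\\.[^.]*$", "", basename(paths))
  if (length(names) != length(paths))
    stop("'names' must match 'paths' in length")
  rasters <- lapply(paths, read_asc)
  g <- rasters[[1]]$grid
  for (i in seq_along(rasters))
    if (!same_grid(g, rasters[[i]]$grid))
      stop("grid mismatch: ", paths[i], " differs from ", paths[1])
  layers <- lapply(rasters, `[[`, "values")
  names(layers) <- names
  climate_stack(layers, g)
}

#' Write a raster map to an ESRI ASCII grid
#'
#' Suitability maps are written as-is; crop category maps are written as
#' integer codes (1 = suitable, 2 = conditioned, 3 = unsuitable); cell
#' partitions as codes (1 = background, 2 = excluded, 3 = pseudoabsence);
#' climate stacks are written one file per layer (\code{path} is then
#' treated as a stem and \code{<stem>_<layer>.asc} files are produced).
#' Nodata cells are preserved. Values round-trip exactly.
#'
#' @param map a \code{suitability_map}, \code{crop_category_map},
#'   \code{cell_partition}, or \code{climate_stack}.
#' @param path output path (.asc).
#' @return the path(s) written, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "suitability_map")) {
    write_asc(map$values, map$grid, path)
  } else if (inherits(map, "crop_category_map")) {
    codes <- matrix(match(as.character(map$categories),
                          c("suitable", "conditioned", "unsuitable")),
                    nrow = map$grid$n_rows)
    write_asc(codes, map$grid, path)
  } else if (inherits(map, "cell_partition")) {
    codes <- matrix(match(as.character(map$class),
                          c("background", "excluded", "pseudoabsence")),
                    nrow = map$grid$n_rows)
    write_asc(codes, map$grid, path)
  } else if (inherits(map, "climate_stack")) {
    stem <- sub("\\.asc$", "", path)
    paths <- vapply(layer_names(map), function(nm) {
      p <- paste0(stem, "_", nm, ".asc")
      write_asc(map$layers[[nm]], map$grid, p)
      p
    }, character(1))
    return(invisible(paths))
  } else stop("unsupported map type: ", paste(class(map), collapse = "/"))
  invisible(path)
}

#' Read a suitability map from an ESRI ASCII grid
#' @param path .asc file path.
#' @return a \code{suitability_map}.
#' @export
read_suitability_map <- function(path) {
  r <- read_asc(path)
  suitability_map(r$values, r$grid)
}

#' Read a categorical crop-suitability map from an ESRI ASCII grid
#'
#' Integer codes 1, 2, 3 map to suitable, conditioned, unsuitable.
#'
#' @param path .asc file path.
#' @return a \code{crop_category_map}.
#' @export
read_crop_map <- function(path) {
  r <- read_asc(path)
  codes <- r$values
  bad <- !is.na(codes) & !(codes %in% 1:3)
  if (any(bad)) stop("crop map codes must be 1, 2, 3 or nodata")
  lev <- c("suitable", "conditioned", "unsuitable")
  cats <- matrix(lev[codes], nrow = r$grid$n_rows)
  crop_category_map(cats, r$grid)
}
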