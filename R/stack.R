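#' Construct a covariate stack
#'
#' A covariate stack is a set of named, co-registered single-band grids
#' sharing one geometry: north-up, row-major storage with row 1 the top
#' (largest y), values sampled at cell centers, and one missing-data mask
#' shared by all layers.
#'
#' @param layers Named list of numeric matrices, all with identical
#'   dimensions.
#' @param xmin,ymax Map coordinates of the grid's top-left corner.
#' @param cellsize Cell edge length in map units (square cells).
#' @param mask Logical matrix, `TRUE` where data are valid. Defaults to all
#'   valid.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, xmin = 0, ymax = NULL, cellsize = 1,
                            mask = NULL) {
  if (length(layers) == 0 || is.null(names(layers)) ||
      any(names(layers) == "") || anyDuplicated(names(layers))) {
    stop("layers must be a non-empty, uniquely named list", call. = FALSE)
  }
  dims <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !identical(dim(layers[[nm]]), dims)) {
      stop("layer '", nm, "' does not share the common grid dimensions",
           call. = FALSE)
    }
  }
  if (is.null(ymax)) ymax <- dims[1] * cellsize
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(mask), dims)) {
    stop("mask does not share the grid dimensions", call. = FALSE)
  }
  for (nm in names(layers)) layers[[nm]][!mask] <- NA_real_
  structure(list(layers = layers, nrow = dims[1], ncol = dims[2],
                 xmin = xmin, ymax = ymax, cellsize = cellsize, mask = mask),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat("covariate_stack:", x$nrow, "x", x$ncol, "cells,",
      length(x$layers), "layers, cellsize", x$cellsize, "\n")
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Layer names of a stack
#' @param stack A `covariate_stack`.
#' @export
stack_layers <- function(stack) names(stack$layers)

#' Cell-center coordinates of every grid cell
#'
#' @param stack A `covariate_stack` or `grid_map`.
#' @return Data.frame with `row`, `col`, `x`, `y` for all cells in row-major
#'   order.
#' @export
cell_centers <- function(stack) {
  g <- expand.grid(col = seq_len(stack$ncol), row = seq_len(stack$nrow))
  data.frame(row = g$row, col = g$col,
             x = stack$xmin + (g$col - 0.5) * stack$cellsize,
             y = stack$ymax - (g$row - 0.5) * stack$cellsize)
}

#' Covariate values of every cell as a data.frame
#'
#' @param stack A `covariate_stack`.
#' @param drop_missing Drop masked cells?
#' @return Data.frame with `row`, `col`, `x`, `y` and one column per layer.
#' @export
stack_to_df <- function(stack, drop_missing = TRUE) {
  cc <- cell_centers(stack)
  vals <- lapply(stack$layers, function(m) as.vector(t(m))) # row-major
  df <- cbind(cc, as.data.frame(vals))
  if (drop_missing) df <- df[as.vector(t(stack$mask)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' A single-band output grid
#'
#' Grid maps hold one derived surface (prediction, novelty distance, residual
#' or mask) on the same geometry conventions as [covariate_stack()]. `NA`
#' encodes missing cells; `units` records the value scale (e.g. `"log
#' percent"` vs `"percent"`).
#'
#' @param values Numeric matrix.
#' @param xmin,ymax,cellsize Geometry, as for [covariate_stack()].
#' @param units Free-text unit tag carried in metadata.
#' @return An object of class `grid_map`.
#' @export
grid_map <- function(values, xmin = 0, ymax = NULL, cellsize = 1,
                     units = "unknown") {
  stopifnot(is.matrix(values))
  if (is.null(ymax)) ymax <- nrow(values) * cellsize
  structure(list(values = values, nrow = nrow(values), ncol = ncol(values),
                 xmin = xmin, ymax = ymax, cellsize = cellsize, units = units),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("grid_map:", x$nrow, "x", x$ncol, "cells, units:", x$units, "\n")
  if (length(v)) cat("range:", format(range(v)), " missing:",
                     sum(!is.finite(x$values)), "\n")
  invisible(x)
}

#' Grid map derived from one stack layer
#' @param stack A `covariate_stack`.
#' @param layer Layer name.
#' @param units Unit tag for the resulting map.
#' @export
stack_layer_map <- function(stack, layer, units = "covariate") {
  if (!layer %in% names(stack$layers)) {
    stop("no such layer: ", layer, call. = FALSE)
  }
  grid_map(stack$layers[[layer]], xmin = stack$xmin, ymax = stack$ymax,
           cellsize = stack$cellsize, units = units)
}

same_geometry <- function(a, b) {
  isTRUE(a$nrow == b$nrow && a$ncol == b$ncol &&
         all.equal(c(a$xmin, a$ymax, a$cellsize),
                   c(b$xmin, b$ymax, b$cellsize)) == TRUE)
}

check_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop(what, " do not share grid geometry", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- plain-text raster I/O (ESRI ASCII grid + JSON sidecar) -----------------

write_asc <- function(values, xmin, ymax, cellsize, path, nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  yllcorner <- ymax - nr * cellsize
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(xmin, digits = 17)),
           paste("yllcorner", format(yllcorner, digits = 17)),
           paste("cellsize", format(cellsize, digits = 17)),
           paste("NODATA_value", nodata))
  body <- apply(values, 1, function(r) {
    r[!is.finite(r)] <- nodata
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  nodata <- vals[["nodata_value"]]
  body <- lapply(lines[6 + seq_len(nr)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, body)
  m[m == nodata] <- NA_real_
  list(values = m, xmin = vals[["xllcorner"]],
       ymax = vals[["yllcorner"]] + nr * vals[["cellsize"]],
       cellsize = vals[["cellsize"]])
}

#' Write / read a covariate stack as plain-text rasters
#'
#' One ESRI ASCII grid (`<layer>.asc`) per layer plus a `stack.json` sidecar
#' naming the layers and recording the shared geometry. All layers are
#' checked for identical geometry on read.
#'
#' @param stack A `covariate_stack`.
#' @param dir Directory to write into (created if needed).
#' @return `read_stack()` returns a `covariate_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_asc(stack$layers[[nm]], stack$xmin, stack$ymax, stack$cellsize,
              file.path(dir, paste0(nm, ".asc")))
  }
  sidecar <- list(format = "esri_ascii_grid", layers = names(stack$layers),
                  nrow = stack$nrow, ncol = stack$ncol, xmin = stack$xmin,
                  ymax = stack$ymax, cellsize = stack$cellsize)
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "stack.json"),
                                 simplifyVector = TRUE)
  layers <- list()
  geo <- NULL
  for (nm in sidecar$layers) {
    a <- read_asc(file.path(dir, paste0(nm, ".asc")))
    if (is.null(geo)) {
      geo <- a
    } else if (!isTRUE(all.equal(c(a$xmin, a$ymax, a$cellsize, dim(a$values)),
                                 c(geo$xmin, geo$ymax, geo$cellsize,
                                   dim(geo$values))))) {
      stop("layer '", nm, "' does not share the stack geometry", call. = FALSE)
    }
    layers[[nm]] <- a$values
  }
  mask <- Reduce(`&`, lapply(layers, is.finite))
  covariate_stack(layers, xmin = geo$xmin, ymax = geo$ymax,
                  cellsize = geo$cellsize, mask = mask)
}

#' Write / read a grid map as a plain-text raster
#' @param map A `grid_map`.
#' @param path Path of the `.asc` file.
#' @param units Unit tag to attach on read.
#' @export
write_grid_map <- function(map, path) {
  write_asc(map$values, map$xmin, map$ymax, map$cellsize, path)
}

#' @rdname write_grid_map
#' @export
read_grid_map <- function(path, units = "unknown") {
  a <- read_asc(path)
  grid_map(a$values, xmin = a$xmin, ymax = a$ymax, cellsize = a$cellsize,
           units = units)
}
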