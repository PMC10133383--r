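#' Environmental raster stack on a planar grid
#'
#' The basic spatial container of the package: a set of named environmental
#' layers sharing one regular grid and one missing-value mask. Geographic
#' space is treated as a planar grid (cell centers, no CRS math); real-world
#' rasters should be resampled to a common grid before import. Cells are
#' indexed row-major from the top-left; coordinates refer to cell centers.
#'
#' @param values a rows x cols x layers numeric array, or a list of equal-size
#'   matrices (one per layer). `NA` in any layer masks the cell in all layers.
#' @param layer_names character vector of unique layer names; defaults to
#'   `layer1`, `layer2`, ...
#' @param xmin,ymin coordinates of the grid's lower-left corner.
#' @param cellsize side length of a (square) cell.
#' @param crs optional free-text CRS tag, carried but never interpreted.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(values, layer_names = NULL, xmin = 0, ymin = 0,
                          cellsize = 1, crs = NULL) {
  if (is.list(values) && !is.array(values)) {
    dims <- dim(values[[1]])
    values <- array(unlist(values), dim = c(dims, length(values)))
  }
  if (length(dim(values)) == 2) values <- array(values, dim = c(dim(values), 1))
  stopifnot(length(dim(values)) == 3)
  nl <- dim(values)[3]
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_len(nl))
  if (anyDuplicated(layer_names)) stop("layer names must be unique")
  if (length(layer_names) != nl) stop("layer_names length must match layers")
  # shared mask: a cell missing in any layer is missing in all
  mask <- apply(!is.na(values), c(1, 2), all)
  if (any(!mask)) {
    for (k in seq_len(nl)) {
      v <- values[, , k]
      v[!mask] <- NA_real_
      values[, , k] <- v
    }
  }
  structure(list(values = values, layer_names = layer_names,
                 nrow = dim(values)[1], ncol = dim(values)[2],
                 xmin = xmin, ymin = ymin, cellsize = cellsize,
                 mask = mask, crs = crs),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d x %d grid, %d layer(s), %d valid cells\n",
              x$nrow, x$ncol, length(x$layer_names), sum(x$mask)))
  cat("  layers:", paste(x$layer_names, collapse = ", "), "\n")
  invisible(x)
}

n_layers <- function(stack) length(stack$layer_names)

#' Cell indexing helpers
#'
#' Cells are numbered row-major from the top-left cell (cell 1 = top-left).
#' `cell_from_xy` maps point coordinates to cell indices (`NA` outside the
#' grid); `xy_from_cell` returns cell-center coordinates; `cell_values`
#' extracts a cells x layers matrix of layer values.
#'
#' @param stack a [climate_stack].
#' @param x,y point coordinates.
#' @param cells integer cell indices.
#' @return see details above.
#' @name cells
NULL

#' @rdname cells
#' @export
cell_from_xy <- function(stack, x, y) {
  col <- floor((x - stack$xmin) / stack$cellsize) + 1
  ymax <- stack$ymin + stack$nrow * stack$cellsize
  row <- floor((ymax - y) / stack$cellsize) + 1
  # points exactly on the top or right edge belong to the edge cell
  col[x == stack$xmin + stack$ncol * stack$cellsize] <- stack$ncol
  row[y == stack$ymin] <- stack$nrow
  bad <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  idx <- (row - 1) * stack$ncol + col
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' @rdname cells
#' @export
xy_from_cell <- function(stack, cells) {
  row <- (cells - 1) %/% stack$ncol + 1
  col <- (cells - 1) %% stack$ncol + 1
  ymax <- stack$ymin + stack$nrow * stack$cellsize
  cbind(x = stack$xmin + (col - 0.5) * stack$cellsize,
        y = ymax - (row - 0.5) * stack$cellsize)
}

#' @rdname cells
#' @export
cell_values <- function(stack, cells) {
  row <- (cells - 1) %/% stack$ncol + 1
  col <- (cells - 1) %% stack$ncol + 1
  out <- vapply(seq_len(n_layers(stack)),
                function(k) stack$values[cbind(row, col, k)],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells))
  colnames(out) <- stack$layer_names
  out
}

# integer indices (row-major) of non-missing cells
valid_cells <- function(stack) {
  which(t(stack$mask))  # t(): row-major order
}

#' Crop a stack to a rectangular extent
#'
#' Keeps exactly the cells whose centers fall in the half-open extent
#' `[xmin, xmax) x [ymin, ymax)`. Layer order is preserved.
#'
#' @param stack a [climate_stack].
#' @param xmin,xmax,ymin,ymax extent bounds.
#' @return the cropped [climate_stack].
#' @export
crop_stack <- function(stack, xmin, xmax, ymin, ymax) {
  cs <- stack$cellsize
  xc <- stack$xmin + (seq_len(stack$ncol) - 0.5) * cs
  ymaxg <- stack$ymin + stack$nrow * cs
  yc <- ymaxg - (seq_len(stack$nrow) - 0.5) * cs
  keep_col <- which(xc >= xmin & xc < xmax)
  keep_row <- which(yc >= ymin & yc < ymax)
  if (!length(keep_col) || !length(keep_row))
    stop("crop extent contains no cell centers")
  vals <- stack$values[keep_row, keep_col, , drop = FALSE]
  climate_stack(vals, stack$layer_names,
                xmin = stack$xmin + (min(keep_col) - 1) * cs,
                ymin = ymaxg - max(keep_row) * cs,
                cellsize = cs, crs = stack$crs)
}

#' Pearson correlation matrix of stack layers
#'
#' Pairwise-complete Pearson correlations over non-missing cells. A constant
#' (zero-variance) layer is assigned correlation 0 against every other layer.
#'
#' @param stack a [climate_stack].
#' @return named layer x layer correlation matrix with unit diagonal.
#' @export
layer_correlations <- function(stack) {
  vc <- valid_cells(stack)
  m <- cell_values(stack, vc)
  nl <- ncol(m)
  const <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 || !is.finite(stats::sd(v, na.rm = TRUE)))
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  attr(r, "constant_layers") <- stack$layer_names[const]
  r
}

#' Remove highly correlated layers
#'
#' Implements the standard pre-modeling collinearity filter: layers are
#' dropped greedily until no retained pair has |Pearson r| above `threshold`
#' (default 0.80). At each step the pair with the highest |r| above threshold
#' is found and the member with the larger mean |r| against all other retained
#' layers is removed (tie: the later layer in stack order is dropped).
#'
#' @param stack a [climate_stack] with at least one layer.
#' @param threshold correlation magnitude above which a pair is redundant.
#' @return a list with `stack` (filtered) and `report`, a `correlation_report`
#'   holding the full correlation matrix, the removal order (data frame with
#'   the removed layer, its partner and their r at removal time), the retained
#'   names, flagged constant layers, and the threshold.
#' @export
filter_correlated <- function(stack, threshold = 0.80) {
  if (n_layers(stack) < 1) stop("stack has no layers")
  full_r <- layer_correlations(stack)
  r <- full_r
  keep <- stack$layer_names
  removals <- list()
  repeat {
    if (length(keep) < 2) break
    sub <- abs(r[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- vapply(pair, function(l) {
      others <- setdiff(keep, l)
      mean(abs(r[l, others]))
    }, numeric(1))
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else pair[which.max(match(pair, stack$layer_names))]
    removals[[length(removals) + 1]] <-
      data.frame(removed = drop, partner = setdiff(pair, drop),
                 r = r[pair[1], pair[2]], stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop)
  }
  removal_df <- if (length(removals)) do.call(rbind, removals)
    else data.frame(removed = character(), partner = character(), r = numeric())
  keep_idx <- match(keep, stack$layer_names)
  out <- climate_stack(stack$values[, , keep_idx, drop = FALSE], keep,
                       xmin = stack$xmin, ymin = stack$ymin,
                       cellsize = stack$cellsize, crs = stack$crs)
  report <- structure(list(correlations = full_r, removals = removal_df,
                           retained = keep,
                           constant_layers = attr(full_r, "constant_layers"),
                           threshold = threshold),
                      class = "correlation_report")
  list(stack = out, report = report)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> threshold |r| > %.2f: removed %d, retained %d\n",
              x$threshold, nrow(x$removals), length(x$retained)))
  if (nrow(x$removals)) print(x$removals)
  invisible(x)
}

#' Plain-text stack import/export
#'
#' Layers are stored as TSV matrices (one file per layer, `NA` for masked
#' cells) plus a JSON header with grid geometry; a deliberately simple format
#' because the analysis is grid-based and carries no CRS math.
#'
#' @param stack a [climate_stack].
#' @param dir directory to write to / read from.
#' @return `write_stack` returns `dir` invisibly; `read_stack` a
#'   [climate_stack].
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(layer_names = stack$layer_names, nrow = stack$nrow,
               ncol = stack$ncol, xmin = stack$xmin, ymin = stack$ymin,
               cellsize = stack$cellsize, crs = stack$crs)
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE,
                       digits = NA)
  for (k in seq_along(stack$layer_names)) {
    utils::write.table(stack$values[, , k],
                       file.path(dir, paste0(stack$layer_names[k], ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  vals <- lapply(meta$layer_names, function(nm) {
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")), sep = "\t"))
  })
  vals <- lapply(vals, function(m) {
    dimnames(m) <- NULL
    m
  })
  climate_stack(vals, meta$layer_names, xmin = meta$xmin, ymin = meta$ymin,
                cellsize = meta$cellsize, crs = meta$crs)
}
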