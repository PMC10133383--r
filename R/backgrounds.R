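# Background-region constructions. The choice of "available environment"
# is known to change background-similarity inference, so three definitions
# are provided: the minimum convex polygon of the occurrence points and the
# cells whose logistic habitat suitability exceeds 0.5 or 0.75. Regions are
# stored as cell index sets (authoritative for all sampling); polygon
# outlines are derived, cosmetic exports.

#' Background region
#'
#' @param method construction tag (`mcp`, `thresh50`, `thresh75`, `custom`).
#' @param cells integer vector of member cell indices (row-major; non-empty).
#' @param polygon optional outline vertex matrix (x, y).
#' @param lineage source lineage label.
#' @return a `background_region`.
#' @export
background_region <- function(method, cells, polygon = NULL,
                              lineage = NA_character_) {
  if (!length(cells)) stop("background region must contain at least one cell")
  structure(list(method = method, cells = as.integer(cells),
                 polygon = polygon, lineage = lineage),
            class = "background_region")
}

#' @export
print.background_region <- function(x, ...) {
  cat(sprintf("<background_region> method=%s lineage=%s cells=%d\n",
              x$method, x$lineage, length(x$cells)))
  invisible(x)
}

#' Minimum-convex-polygon background region
#'
#' The region is every non-missing cell whose center lies inside or on the
#' convex hull of the occurrence points. Degenerate inputs (fewer than three
#' distinct points, or collinear points) fall back to the bounding box of the
#' points buffered by one cell width.
#'
#' @param occ an [occurrence_set].
#' @param stack the parent [climate_stack].
#' @return a `background_region` with method `"mcp"`.
#' @export
mcp_region <- function(occ, stack) {
  pts <- unique(cbind(occ$x, occ$y))
  vc <- valid_cells(stack)
  ctr <- xy_from_cell(stack, vc)
  degenerate <- nrow(pts) < 3 || is_collinear(pts)
  if (degenerate) {
    buf <- stack$cellsize
    inside <- ctr[, 1] >= min(pts[, 1]) - buf & ctr[, 1] <= max(pts[, 1]) + buf &
              ctr[, 2] >= min(pts[, 2]) - buf & ctr[, 2] <= max(pts[, 2]) + buf
    hull <- cbind(x = c(min(pts[, 1]) - buf, max(pts[, 1]) + buf,
                        max(pts[, 1]) + buf, min(pts[, 1]) - buf),
                  y = c(min(pts[, 2]) - buf, min(pts[, 2]) - buf,
                        max(pts[, 2]) + buf, max(pts[, 2]) + buf))
  } else {
    h <- grDevices::chull(pts)
    hull <- pts[h, , drop = FALSE]
    colnames(hull) <- c("x", "y")
    inside <- in_convex_hull(ctr, hull)
  }
  cells <- vc[inside]
  if (!length(cells)) stop("MCP region contains no non-missing cells")
  background_region("mcp", cells, polygon = hull, lineage = occ$lineage[1])
}

is_collinear <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 3) return(TRUE)
  p1 <- pts[1, ]
  for (i in 3:nrow(pts)) {
    cr <- (pts[2, 1] - p1[1]) * (pts[i, 2] - p1[2]) -
          (pts[2, 2] - p1[2]) * (pts[i, 1] - p1[1])
    if (abs(cr) > tol) return(FALSE)
  }
  TRUE
}

# Half-plane membership test for a convex polygon (chull returns clockwise
# order). Points on the boundary count as inside.
in_convex_hull <- function(pts, hull, tol = 1e-9) {
  n <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  # orientation of the hull (chull gives clockwise, but do not rely on it)
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  s <- if (area2 >= 0) 1 else -1
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (hull[j, 1] - hull[i, 1]) * (pts[, 2] - hull[i, 2]) -
          (hull[j, 2] - hull[i, 2]) * (pts[, 1] - hull[i, 1])
    inside <- inside & (s * cr >= -tol)
  }
  inside
}

#' Suitability-threshold background region
#'
#' The region is every cell whose logistic habitat suitability is strictly
#' greater than `tau` (the conventional 0.5 and 0.75 thresholds are on the
#' \[0, 1\] logistic view, not the raw sum-to-one view). By construction the
#' `tau = 0.75` region is nested inside the `tau = 0.5` region of the same
#' surface.
#'
#' @param surface a [suitability_surface][predict_surface].
#' @param tau suitability threshold in \[0, 1); cells must exceed it strictly.
#' @return a `background_region` with method `"thresh<100 tau>"`.
#' @export
threshold_region <- function(surface, tau = 0.5) {
  log_v <- as.vector(t(surface$logistic))
  cells <- which(!is.na(log_v) & log_v > tau)
  if (!length(cells))
    stop(sprintf("no cell has logistic suitability > %.2f; lower tau", tau))
  method <- paste0("thresh", format(round(tau * 100)))
  background_region(method, cells,
                    lineage = surface$model$lineage %||% NA_character_)
}
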