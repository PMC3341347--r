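## Plot geometry in local Cartesian metres. A polygon is a 2-column
## (x, y) matrix of vertices of a simple ring; it need not be closed.

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3)
    stop("polygon must be an (x, y) matrix with >= 3 vertices",
         call. = FALSE)
  ## drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  storage.mode(poly) <- "double"
  colnames(poly) <- c("x", "y")
  poly
}

#' Area of a plot polygon
#' @param poly 2-column (x, y) vertex matrix, metres.
#' @return Area in square metres.
#' @export
polygon_area <- function(poly) {
  p <- as_polygon(poly)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Test whether points lie inside a plot polygon
#' @param xy `n x 2` matrix of point coordinates, metres.
#' @param poly 2-column vertex matrix.
#' @return Logical vector.
#' @export
in_plot <- function(xy, poly) {
  p <- as_polygon(poly)
  xy <- matrix(as.numeric(xy), ncol = 2)
  bnd <- list(x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]))
  mgcv::in.out(cbind(bnd$x, bnd$y), xy)
}

#' Distance from points to the nearest plot edge
#'
#' Minimum Euclidean distance from each point to the polygon boundary
#' (for a seedling inside the plot, the minimum dispersal distance an
#' immigrant seed must have covered).
#'
#' @inheritParams in_plot
#' @return Numeric vector of distances in metres.
#' @export
edge_distance <- function(xy, poly) {
  p <- as_polygon(poly)
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(p)
  d2 <- rep(Inf, nrow(xy))
  for (s in seq_len(n)) {
    a <- p[s, ]; b <- p[if (s == n) 1 else s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) /
      max(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    dx <- xy[, 1] - (a[1] + t * ab[1])
    dy <- xy[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

## uniform points inside a polygon by rejection from the bounding box
runif_in_polygon <- function(n, poly) {
  p <- as_polygon(poly)
  out <- matrix(NA_real_, n, 2)
  got <- 0
  while (got < n) {
    m <- max(2 * (n - got), 16)
    cand <- cbind(runif(m, min(p[, 1]), max(p[, 1])),
                  runif(m, min(p[, 2]), max(p[, 2])))
    keep <- in_plot(cand, p)
    take <- min(sum(keep), n - got)
    if (take > 0)
      out[(got + 1):(got + take), ] <- cand[which(keep)[seq_len(take)], ,
                                            drop = FALSE]
    got <- got + take
  }
  colnames(out) <- c("x", "y")
  out
}

#' Grid of virtual out-of-plot parents
#'
#' Dispersal from outside the mapped stand is integrated over a regular
#' grid of virtual parent locations tiling the annulus between the plot
#' boundary and a cutoff radius. Both stands are assumed to sit in
#' continuous forest, so each cell carries the expected number of trees
#' (in-plot density times cell area) and the in-plot mean fecundity.
#'
#' @param poly Plot polygon, 2-column (x, y) matrix in metres.
#' @param density_ha In-plot adult density, trees per hectare.
#' @param mean_fecundity In-plot mean fecundity, seeds per year.
#' @param cutoff Outer integration radius beyond the plot edge, metres.
#' @param spacing Grid cell side, metres (<= 10 m resolves the kernels at
#'   the scales of interest; coarser grids are admissible for the smooth
#'   far field and are used in the scaled-down examples).
#' @param warn_mean_distance If non-`NULL`, an expected seed dispersal
#'   distance (m); a warning is issued when `cutoff` < 2 times it (tail
#'   truncation).
#' @return Data frame of class `"exterior_grid"` with columns `x`, `y`,
#'   `count` (expected trees per cell) and `fec` (mean fecundity), plus
#'   attribute `spacing`.
#' @export
build_exterior_grid <- function(poly, density_ha, mean_fecundity,
                                cutoff = 500, spacing = 10,
                                warn_mean_distance = NULL) {
  p <- as_polygon(poly)
  if (polygon_area(p) <= 0) stop("polygon has zero area", call. = FALSE)
  if (!is.null(warn_mean_distance) && cutoff < 2 * warn_mean_distance)
    warning("exterior cutoff is < 2x the expected seed dispersal ",
            "distance; the immigrant tail is truncated")
  xs <- seq(min(p[, 1]) - cutoff + spacing / 2,
            max(p[, 1]) + cutoff, by = spacing)
  ys <- seq(min(p[, 2]) - cutoff + spacing / 2,
            max(p[, 2]) + cutoff, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  g <- g[!in_plot(as.matrix(g), p), , drop = FALSE]
  g <- g[edge_distance(as.matrix(g), p) <= cutoff, , drop = FALSE]
  g$count <- density_ha / 1e4 * spacing^2
  g$fec <- mean_fecundity
  rownames(g) <- NULL
  structure(g, spacing = spacing, cutoff = cutoff,
            class = c("exterior_grid", "data.frame"))
}
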