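#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise vertex order in the package's coordinate
#' algebra (the shoelace sign convention; note `y` points down in display
#' terms, which does not affect any of the geometry).
#'
#' @param p a polygon: list with numeric `x`, `y` vertex vectors, implicitly
#'   closed.
#' @return Signed area.
#' @export
poly_area <- function(p) {
  x <- p$x; y <- p$y
  sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
}

.reverse_poly <- function(p) list(x = rev(p$x), y = rev(p$y))

.ccw <- function(p) if (poly_area(p) < 0) .reverse_poly(p) else p

#' Convex hull of a 2-D point set
#'
#' Returns the minimal convex polygon containing all points, with vertices
#' in counter-clockwise order. Degenerate inputs (fewer than three distinct
#' points, or all points collinear) are inflated to a thin rectangle of
#' half-width `pad` around the point/segment so that containment and
#' boundary-distance queries remain well defined; cluster expansion passes
#' `pad = eps / 4`.
#'
#' @param x,y point coordinates (or `x` a 2-column matrix / data.frame).
#' @param pad half-width used to inflate degenerate hulls.
#' @return A polygon (list with `x`, `y`) with positive signed area.
#' @export
convex_hull <- function(x, y = NULL, pad = 0.25) {
  if (is.null(y)) {
    m <- as.matrix(x)
    x <- m[, 1L]; y <- m[, 2L]
  }
  if (!length(x)) stop("convex hull of an empty point set")
  stopifnot(length(x) == length(y), pad > 0)
  pts <- unique(cbind(as.numeric(x), as.numeric(y)))
  if (nrow(pts) >= 3L) {
    idx <- grDevices::chull(pts[, 1L], pts[, 2L])
    hull <- list(x = pts[idx, 1L], y = pts[idx, 2L])
    if (abs(poly_area(hull)) > 1e-9) return(.ccw(hull))
  }
  .inflate_degenerate(pts[, 1L], pts[, 2L], pad)
}

# thin rectangle around a (possibly zero-length) segment covering all points
.inflate_degenerate <- function(x, y, pad) {
  if (length(x) == 1L || (max(x) == min(x) && max(y) == min(y))) {
    cx <- x[1L]; cy <- y[1L]
    return(list(x = c(cx - pad, cx + pad, cx + pad, cx - pad),
                y = c(cy - pad, cy - pad, cy + pad, cy + pad)))
  }
  # principal direction: the two most separated points
  i <- which.max((x - x[1L])^2 + (y - y[1L])^2)
  d2 <- (x - x[i])^2 + (y - y[i])^2
  j <- which.max(d2)
  ux <- x[i] - x[j]; uy <- y[i] - y[j]
  len <- sqrt(ux^2 + uy^2)
  ux <- ux / len; uy <- uy / len
  nx <- -uy; ny <- ux
  t <- (x - x[j]) * ux + (y - y[j]) * uy   # projections along the segment
  t0 <- min(t) - pad; t1 <- max(t) + pad
  corner <- function(tt, ss) c(x[j] + tt * ux + ss * nx,
                               y[j] + tt * uy + ss * ny)
  c1 <- corner(t0, -pad); c2 <- corner(t1, -pad)
  c3 <- corner(t1, pad);  c4 <- corner(t0, pad)
  .ccw(list(x = c(c1[1L], c2[1L], c3[1L], c4[1L]),
            y = c(c1[2L], c2[2L], c3[2L], c4[2L])))
}

#' Polygon set (cluster boundary) constructor
#'
#' A cluster boundary is a list of rings: outer shells with positive signed
#' area (counter-clockwise) and, for ring-shaped regions, hole rings with
#' negative signed area. Tracking holes keeps the boundary equal to the
#' exact union of the primitive-cluster hulls, which is what makes the
#' leading-point skip test sound: a filled-in (hole-free) cover would be
#' larger than the true union and would skip queries whose neighbourhood
#' reaches into uncovered gaps. The empty set is a valid boundary.
#'
#' @param rings list of polygons (each a list with `x`, `y`), orientation
#'   meaningful (positive area = shell, negative = hole).
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(rings = list()) {
  structure(rings, class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  areas <- vapply(x, poly_area, 0)
  cat(sprintf("<polygon_set: %d shell(s), %d hole(s), area %.3f>\n",
              sum(areas > 0), sum(areas < 0), sum(areas)))
  invisible(x)
}

#' Union a polygon into a cluster boundary
#'
#' Region semantics: the result covers exactly `region(ps) | region(poly)`.
#' Overlapping shells merge into one; a disjoint polygon is appended as a
#' new shell; gaps enclosed by a ring of hulls become hole rings (negative
#' signed area) rather than being filled in.
#'
#' @param ps a [polygon_set()] (may be empty).
#' @param poly a polygon (list with `x`, `y`).
#' @return The updated [polygon_set()].
#' @export
union_into <- function(ps, poly) {
  poly <- .ccw(poly)
  if (!length(ps)) return(polygon_set(list(poly)))
  out <- polyclip::polyclip(unclass(ps), poly, op = "union",
                            fillA = "nonzero", fillB = "nonzero")
  structure(out, class = "polygon_set")
}

#' Point-in-boundary test
#'
#' TRUE iff the point lies inside or on the covered region, with even-odd
#' parity across rings (so points inside a hole are outside the region);
#' points on an edge or vertex count as inside.
#'
#' @param ps a [polygon_set()].
#' @param x,y point coordinates (vectorized).
#' @return Logical vector.
#' @export
ps_contains <- function(ps, x, y) {
  if (!length(ps)) return(rep(FALSE, length(x)))
  parity <- integer(length(x))
  on_edge <- rep(FALSE, length(x))
  for (sh in ps) {
    pip <- sp::point.in.polygon(x, y, sh$x, sh$y)
    parity <- parity + (pip > 0)
    on_edge <- on_edge | pip >= 2
  }
  parity %% 2L == 1L | on_edge
}

#' Distance from a point to the boundary edges
#'
#' Euclidean distance to the nearest edge segment of any shell (0 for points
#' on an edge). Used by the leading-point test: members deeper inside the
#' boundary than the band width cannot change the cluster shape.
#'
#' @param ps a non-empty [polygon_set()].
#' @param x,y point coordinates (vectorized).
#' @return Numeric vector of distances.
#' @export
boundary_distance <- function(ps, x, y) {
  if (!length(ps)) stop("boundary_distance on an empty polygon set")
  d2 <- rep(Inf, length(x))
  for (sh in ps) {
    ax <- sh$x; ay <- sh$y
    bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    for (k in seq_along(x)) {
      t <- ((x[k] - ax) * ex + (y[k] - ay) * ey) / pmax(len2, 1e-300)
      t <- pmin(pmax(t, 0), 1)
      dk <- (x[k] - (ax + t * ex))^2 + (y[k] - (ay + t * ey))^2
      m <- min(dk)
      if (m < d2[k]) d2[k] <- m
    }
  }
  sqrt(d2)
}

# distance of ONE point to the boundary (hot path in cluster expansion)
.boundary_dist1 <- function(edges, x, y) {
  t <- ((x - edges$ax) * edges$ex + (y - edges$ay) * edges$ey) / edges$len2
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt(min((x - (edges$ax + t * edges$ex))^2 +
           (y - (edges$ay + t * edges$ey))^2))
}

# precompute edge arrays for repeated .boundary_dist1 calls
.edge_table <- function(ps) {
  ax <- ay <- bx <- by <- numeric(0)
  for (sh in ps) {
    ax <- c(ax, sh$x); ay <- c(ay, sh$y)
    bx <- c(bx, c(sh$x[-1L], sh$x[1L])); by <- c(by, c(sh$y[-1L], sh$y[1L]))
  }
  ex <- bx - ax; ey <- by - ay
  list(ax = ax, ay = ay, ex = ex, ey = ey, len2 = pmax(ex^2 + ey^2, 1e-300))
}

#' Export a polygon set as WKT
#'
#' @param ps a [polygon_set()].
#' @return A WKT `POLYGON`/`MULTIPOLYGON` string (or `"MULTIPOLYGON EMPTY"`).
#' @export
ps_as_wkt <- function(ps) {
  if (!length(ps)) return("MULTIPOLYGON EMPTY")
  ring <- function(p) {
    xs <- c(p$x, p$x[1L]); ys <- c(p$y, p$y[1L])
    paste0("((", paste(sprintf("%g %g", xs, ys), collapse = ", "), "))")
  }
  paste0("MULTIPOLYGON (", paste(vapply(ps, ring, ""), collapse = ", "), ")")
}

#' Export a polygon set as a vertex table
#'
#' @param ps a [polygon_set()].
#' @return A `data.frame` with columns `shell`, `vertex`, `x`, `y`.
#' @export
ps_as_df <- function(ps) {
  if (!length(ps))
    return(data.frame(shell = integer(), vertex = integer(),
                      x = numeric(), y = numeric()))
  do.call(rbind, lapply(seq_along(ps), function(i) {
    data.frame(shell = i, vertex = seq_along(ps[[i]]$x),
               x = ps[[i]]$x, y = ps[[i]]$y)
  }))
}
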