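#' Primitive cluster around a core point
#'
#' The unit of boundary-based cluster growth: a core point, its
#' eps-neighbourhood, and the convex hull (in pixel coordinates) enclosing
#' all of them. Returns `NULL` when the point is not core, i.e. its
#' neighbourhood holds fewer than `minpts` points.
#'
#' @param i index of the candidate core point.
#' @param points the point table the index was built on.
#' @param index a [points_index()].
#' @return `NULL`, or a list of class `primitive_cluster` with `core`
#'   (index), `members` (indices, core first), `hull` (polygon).
#' @export
primitive_cluster <- function(i, points, index) {
  nb <- index$query(i)
  if (length(nb) < index$params$minpts) return(NULL)
  members <- c(i, nb)
  pad <- max(index$reach / 4, 1e-6)
  hull <- convex_hull(points$x[members], points$y[members], pad = pad)
  structure(list(core = i, members = members, hull = hull),
            class = "primitive_cluster")
}

#' Leading-point test
#'
#' A cluster member is *leading* unless it lies inside the cluster boundary
#' at more than the band width from its edges; only then is its full
#' neighbourhood provably covered and its region query skippable. Points
#' outside the boundary (possible when they were labelled through a
#' degenerate hull that contributed no area) are always leading. The band
#' width is `eps` for spatial metrics and [spatial_reach()]`(eps)` for the
#' normalized distance (a conservative spatial projection of the 5-D
#' neighbourhood).
#'
#' @param gamma the cluster boundary, a [polygon_set()].
#' @param x,y coordinates of the member point.
#' @param band band width in pixels.
#' @return Logical: `TRUE` if the point's query must be fired.
#' @export
is_leading <- function(gamma, x, y, band) {
  if (!length(gamma)) return(TRUE)
  boundary_distance(gamma, x, y) <= band | !ps_contains(gamma, x, y)
}

# Convex hull without degeneracy inflation: NULL when the points are
# (nearly) collinear and the hull has no genuine area.
.true_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(NULL)
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull <- list(x = pts[idx, 1L], y = pts[idx, 2L])
  if (abs(poly_area(hull)) < 1e-9) return(NULL)
  .ccw(hull)
}

# Mutable clustering state shared by fdbld_expand calls.
#' Create FDBLD clustering state
#'
#' @param points point table from [image_to_points()].
#' @param params a [cluster_params()].
#' @param dims image dimensions `c(width, height)` (required for
#'   `metric = "nd"`).
#' @param skip enable the leading-point skip test; with `skip = FALSE` the
#'   algorithm degenerates to DBSCAN with identical output.
#' @return An environment holding labels, query bookkeeping and per-cluster
#'   boundaries; consumed by [fdbld_expand()] and [fdbld_cluster()].
#' @export
fdbld_state <- function(points, params, dims = NULL, skip = TRUE) {
  index <- points_index(points, params, dims)
  st <- new.env(parent = emptyenv())
  st$points <- points
  st$index <- index
  st$params <- params
  st$skip <- isTRUE(skip)
  st$band <- index$reach       # eps for spatial metrics, spatial_reach for nd
  st$pad <- max(index$reach / 4, 1e-6)
  st$labels <- integer(index$n)
  st$queried <- logical(index$n)
  st$fired <- 0L
  st$skipped <- 0L
  st$clusters <- list()
  st
}

#' Expand one cluster from a seed point
#'
#' Fires the seed's region query; returns `FALSE` if the seed is not core
#' (no labels change). Otherwise creates a new cluster from the seed's
#' primitive cluster and grows it: pending boundary pixels are processed
#' LIFO (depth-first, deterministic), each is tested with [is_leading()]
#' against the current boundary, leading points get a region query, and
#' every successful (core) query unions its primitive-cluster hull into the
#' boundary and labels the newly found members. Non-leading pixels are
#' dropped from the list without a query; depth-first order means the
#' boundary has typically grown well past early-discovered pixels by the
#' time they are popped, which is what retires most interior queries.
#'
#' @param seed index of an unlabelled point.
#' @param state an [fdbld_state()].
#' @return Logical: whether a cluster was created.
#' @export
fdbld_expand <- function(seed, state) {
  if (state$labels[seed] != 0L) stop("seed is already labelled")
  pts <- state$points
  minpts <- state$params$minpts
  query <- state$index$query

  if (!state$queried[seed]) {
    nb <- query(seed)
    state$queried[seed] <- TRUE
    state$fired <- state$fired + 1L
    if (length(nb) < minpts) return(FALSE)
  } else {
    return(FALSE)  # queried before and found non-core
  }

  k <- length(state$clusters) + 1L
  members <- c(seed, nb)
  # Only hulls with genuine area enter the boundary: a true convex hull of
  # an eps-neighbourhood lies inside the core's eps-disc, so every point
  # covered by the boundary is provably labelled. Degenerate (collinear)
  # neighbourhoods contribute no area, which merely reduces skipping.
  gamma <- polygon_set()
  hull0 <- .true_hull(pts$x[members], pts$y[members])
  if (!is.null(hull0)) gamma <- union_into(gamma, hull0)
  edges <- .edge_table(gamma)

  newm <- members[state$labels[members] == 0L]
  state$labels[newm] <- k
  # Pending boundary pixels, processed LIFO: depth-first expansion lets the
  # boundary grow past early-discovered pixels before they are popped, so
  # the leading-point test can actually retire them without a query.
  stack <- newm[!state$queried[newm]]
  top <- length(stack)

  while (top > 0L) {
    j <- stack[top]; top <- top - 1L
    if (state$queried[j]) next
    # skip only pixels strictly inside the boundary at more than the band
    # width from its edges: a member can sit OUTSIDE gamma (labelled via a
    # degenerate hull that was never unioned), and for such a point a large
    # distance to the polygon means far outside, not deep inside
    if (state$skip && length(edges$ax) &&
        .boundary_dist1(edges, pts$x[j], pts$y[j]) > state$band + 1e-7 &&
        ps_contains(gamma, pts$x[j], pts$y[j])) {
      state$skipped <- state$skipped + 1L
      next
    }
    nbj <- query(j)
    state$queried[j] <- TRUE
    state$fired <- state$fired + 1L
    if (length(nbj) < minpts) next
    memj <- c(j, nbj)
    hullj <- .true_hull(pts$x[memj], pts$y[memj])
    if (!is.null(hullj)) {
      gamma <- union_into(gamma, hullj)
      edges <- .edge_table(gamma)
    }
    add <- nbj[state$labels[nbj] == 0L]
    if (length(add)) {
      state$labels[add] <- k
      grow <- add[!state$queried[add]]
      if (length(grow)) {
        if (top + length(grow) > length(stack))
          length(stack) <- max(2L * length(stack), top + length(grow))
        stack[top + seq_along(grow)] <- grow
        top <- top + length(grow)
      }
    }
  }

  state$clusters[[k]] <- list(id = k, seed = seed, gamma = gamma)
  TRUE
}

#' Boundary-based density clustering (FDBLD)
#'
#' Scans points in row-major order; each unlabelled point seeds a
#' [fdbld_expand()] attempt. Points never claimed by a cluster are noise.
#' In spatial (binary-image) mode the labelling is identical to [dbscan()]
#' up to cluster-id permutation; in normalized-distance mode the hull-based
#' skip test is a conservative spatial projection and any residual
#' disagreement with DBSCAN can be measured (and removed with
#' `skip = FALSE`).
#'
#' @inheritParams fdbld_state
#' @return A list of class `fdbld_result`: `labels` (0 = noise),
#'   `n_clusters`, `clusters` (list with per-cluster `id`, `seed`, `gamma`
#'   boundary and `size`), and `stats` (queries `fired`, `skipped`, `total`
#'   points).
#' @export
fdbld_cluster <- function(points, params, dims = NULL, skip = TRUE) {
  st <- fdbld_state(points, params, dims, skip)
  for (i in seq_len(st$index$n)) {
    if (st$labels[i] != 0L || st$queried[i]) next
    fdbld_expand(i, st)
  }
  clusters <- lapply(st$clusters, function(cl) {
    cl$size <- sum(st$labels == cl$id)
    cl
  })
  structure(list(labels = st$labels,
                 n_clusters = length(clusters),
                 clusters = clusters,
                 stats = list(fired = st$fired, skipped = st$skipped,
                              total = st$index$n)),
            class = "fdbld_result")
}

#' @export
print.fdbld_result <- function(x, ...) {
  cat(sprintf(
    "<fdbld_result: %d cluster(s), %d point(s), %d noise; queries fired %d, skipped %d>\n",
    x$n_clusters, x$stats$total, sum(x$labels == 0L),
    x$stats$fired, x$stats$skipped))
  invisible(x)
}
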