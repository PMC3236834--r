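#' Clustering parameters
#'
#' @param eps neighbourhood radius in the units of the chosen metric
#'   (pixels for `euclidean`/`manhattan`; a unitless value in `(0, 1)` is
#'   typical for the normalized distance).
#' @param minpts minimum number of neighbours (the query point itself is
#'   excluded from its own neighbourhood, so a point is core iff at least
#'   `minpts` *other* points lie within `eps`).
#' @param metric `"nd"`, `"euclidean"` or `"manhattan"`.
#' @param weights an [nd_weights()] object (used when `metric = "nd"`).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(eps, minpts,
                           metric = c("nd", "euclidean", "manhattan"),
                           weights = nd_weights()) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(eps), eps > 0,
            is.numeric(minpts), minpts >= 1)
  if (metric == "nd") stopifnot(inherits(weights, "nd_weights"))
  structure(list(eps = eps, minpts = as.integer(minpts),
                 metric = metric, weights = weights),
            class = "cluster_params")
}

#' @export
print.cluster_params <- function(x, ...) {
  cat(sprintf("<cluster_params: metric=%s eps=%g minpts=%d>\n",
              x$metric, x$eps, x$minpts))
  invisible(x)
}

# Spatial radius that is guaranteed to contain an eps-ball of the metric.
.metric_reach <- function(params, dims) {
  switch(params$metric,
         euclidean = params$eps,
         manhattan = params$eps,   # |dx|+|dy| <= eps implies sqrt(dx^2+dy^2) <= eps
         nd = spatial_reach(params$eps, dims, params$weights))
}

#' Build a neighbour-query index over a point set
#'
#' Buckets points on a uniform spatial grid whose cell size equals the
#' metric's spatial reach, so a region query only inspects the 3 x 3 block
#' of cells around the query point. Returns a closure `query(i)` yielding
#' the indices of all points `j != i` with `dist(i, j) <= eps`, in
#' deterministic row-major order.
#'
#' @param points point table from [image_to_points()].
#' @param params a [cluster_params()].
#' @param dims image dimensions `c(width, height)`; required for the
#'   normalized distance, optional otherwise (inferred from the points).
#' @return A list with `query(i)`, `n`, `params`, `dims`, `reach`.
#' @export
points_index <- function(points, params, dims = NULL) {
  n <- nrow(points)
  stopifnot(n >= 1L)
  if (is.null(dims)) {
    if (params$metric == "nd")
      stop("dims = c(width, height) is required for the normalized distance")
    dims <- c(max(points$x) + 1, max(points$y) + 1)
  }
  reach <- .metric_reach(params, dims)
  cell <- max(reach, 1)
  cx <- floor(points$x / cell); cy <- floor(points$y / cell)
  ncx <- max(cx) - min(cx) + 1L; ncy <- max(cy) - min(cy) + 1L
  key <- (cx - min(cx)) + ncx * (cy - min(cy)) + 1L
  buckets <- vector("list", ncx * ncy)
  sp <- split(seq_len(n), key)
  buckets[as.integer(names(sp))] <- sp
  x <- points$x; y <- points$y
  r <- points$r; g <- points$g; b <- points$b
  eps <- params$eps
  minx <- min(cx); miny <- min(cy)

  gather <- function(i) {
    ci <- cx[i] - minx; yi <- cy[i] - miny
    ks <- integer(0)
    for (dy in -1:1) {
      ry <- yi + dy
      if (ry < 0 || ry >= ncy) next
      for (dx in -1:1) {
        rx <- ci + dx
        if (rx < 0 || rx >= ncx) next
        ks <- c(ks, rx + ncx * ry + 1L)
      }
    }
    unlist(buckets[ks], use.names = FALSE)
  }

  query <-
    if (params$metric == "euclidean") {
      e2 <- eps^2
      function(i) {
        cand <- gather(i)
        d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
        out <- cand[d2 <= e2 & cand != i]
        sort(out)
      }
    } else if (params$metric == "manhattan") {
      function(i) {
        cand <- gather(i)
        d <- abs(x[cand] - x[i]) + abs(y[cand] - y[i])
        sort(cand[d <= eps & cand != i])
      }
    } else {
      w <- params$weights
      cnorm <- .ND_COLOR_NORM * w$w1
      snorm <- (dims[1L]^2 + dims[2L]^2) * w$w2
      e2 <- eps^2
      function(i) {
        cand <- gather(i)
        d2 <- (w$w3 * (r[cand] - r[i])^2 + w$w4 * (g[cand] - g[i])^2 +
               w$w5 * (b[cand] - b[i])^2) / cnorm +
              ((x[cand] - x[i])^2 + (y[cand] - y[i])^2) / snorm
        sort(cand[d2 <= e2 & cand != i])
      }
    }

  list(query = query, n = n, params = params, dims = dims, reach = reach)
}

#' Region query: the eps-neighbourhood of a point
#'
#' All points within `eps` of point `i` under the index's metric, excluding
#' the query point itself.
#'
#' @param i point index (row of the point table the index was built on).
#' @param index an index from [points_index()].
#' @return Integer vector of neighbour indices in row-major order.
#' @export
region_query <- function(i, index) index$query(i)

#' Reference DBSCAN clustering
#'
#' Textbook DBSCAN over a pixel point set with any of the package's metrics.
#' A point is core iff its eps-neighbourhood (query point excluded) holds at
#' least `minpts` points; clusters are maximal density-connected sets; all
#' other points are noise. Seeds are scanned in row-major order and cluster
#' expansion uses a FIFO queue, so the labelling is deterministic; border
#' points reachable from two clusters go to the cluster whose expansion
#' reaches them first.
#'
#' @param points point table from [image_to_points()].
#' @param params a [cluster_params()].
#' @param dims image dimensions `c(width, height)` (required for
#'   `metric = "nd"`).
#' @return A list of class `dbscan_result`: `labels` (integer per point;
#'   0 = noise, clusters numbered from 1), `n_clusters`, `is_core` (logical).
#' @export
dbscan <- function(points, params, dims = NULL) {
  idx <- points_index(points, params, dims)
  n <- idx$n
  labels <- integer(n)       # 0 unvisited
  noise <- logical(n)
  is_core <- logical(n)
  minpts <- params$minpts
  k <- 0L
  queue <- integer(n)
  for (i in seq_len(n)) {
    if (labels[i] != 0L || noise[i]) next
    nb <- idx$query(i)
    if (length(nb) < minpts) { noise[i] <- TRUE; next }
    k <- k + 1L
    labels[i] <- k
    is_core[i] <- TRUE
    fresh <- nb[labels[nb] == 0L]
    expandable <- fresh[!noise[fresh]]
    labels[fresh] <- k
    noise[fresh] <- FALSE
    qlen <- length(expandable)
    queue[seq_len(qlen)] <- expandable
    head <- 1L
    while (head <= qlen) {
      j <- queue[head]; head <- head + 1L
      nbj <- idx$query(j)
      if (length(nbj) < minpts) next
      is_core[j] <- TRUE
      add <- nbj[labels[nbj] == 0L]
      if (length(add)) {
        # previously-noise points become border members but are not expanded
        expandable <- add[!noise[add]]
        labels[add] <- k
        noise[add] <- FALSE
        if (length(expandable)) {
          queue[qlen + seq_along(expandable)] <- expandable
          qlen <- qlen + length(expandable)
        }
      }
    }
  }
  structure(list(labels = labels, n_clusters = k, is_core = is_core),
            class = "dbscan_result")
}

#' @export
print.dbscan_result <- function(x, ...) {
  cat(sprintf("<dbscan_result: %d cluster(s), %d point(s), %d noise>\n",
              x$n_clusters, length(x$labels), sum(x$labels == 0L)))
  invisible(x)
}

#' Core/border/noise status of each point
#'
#' Core: at least `minpts` neighbours. Border: non-core but within `eps` of
#' some core point. Noise: neither.
#'
#' @inheritParams dbscan
#' @return Character vector (`"core"`, `"border"`, `"noise"`) per point.
#' @export
core_status <- function(points, params, dims = NULL) {
  idx <- points_index(points, params, dims)
  n <- idx$n
  deg <- integer(n)
  nbs <- vector("list", n)
  for (i in seq_len(n)) {
    nbs[[i]] <- idx$query(i)
    deg[i] <- length(nbs[[i]])
  }
  core <- deg >= params$minpts
  status <- rep("noise", n)
  status[core] <- "core"
  for (i in which(!core)) {
    if (any(core[nbs[[i]]])) status[i] <- "border"
  }
  status
}
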