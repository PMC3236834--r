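# Shared fixtures and independent oracles for the test suite.

# flat-gray image of given size (all channels equal to `value`)
flat_image <- function(w, h, value = 0L) {
  m <- matrix(as.integer(value), h, w)
  rgb_image(m, m, m)
}

# random binary mask as a matrix
random_binary <- function(w, h, density, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(stats::runif(w * h) < density), h, w)
}

# point table for a binary image (spatial clustering input)
binary_points <- function(m) {
  h <- nrow(m); w <- ncol(m)
  image_to_points(flat_image(w, h), binary_mask(m))
}

# random colour image built from flat rectangles over a flat background,
# optionally with per-channel gaussian noise
random_color_image <- function(w = 32, h = 32, nrect = 3, noise = 0,
                               seed = NULL, min_color_sep = 0) {
  if (!is.null(seed)) set.seed(seed)
  # optionally enforce pairwise colour separation so that clusters are
  # guaranteed colour-homogeneous (regions cannot chain through colour)
  cols <- matrix(sample(0:255, 3, replace = TRUE), ncol = 3)
  while (nrow(cols) < nrect + 1L) {
    cand <- sample(0:255, 3, replace = TRUE)
    if (min_color_sep == 0 ||
        all(sqrt(colSums((t(cols) - cand)^2)) >= min_color_sep))
      cols <- rbind(cols, cand)
  }
  ch <- lapply(1:3, function(i) matrix(cols[1L, i], h, w))
  for (k in seq_len(nrect)) {
    x0 <- sample(seq_len(w), 1); x1 <- sample(x0:w, 1)
    y0 <- sample(seq_len(h), 1); y1 <- sample(y0:h, 1)
    col <- cols[k + 1L, ]
    for (i in 1:3) ch[[i]][y0:y1, x0:x1] <- col[i]
  }
  clamp <- function(m) {
    if (noise > 0) m <- m + matrix(stats::rnorm(w * h, 0, noise), h, w)
    matrix(as.integer(pmin(pmax(round(m), 0), 255)), h, w)
  }
  rgb_image(clamp(ch[[1]]), clamp(ch[[2]]), clamp(ch[[3]]))
}

# scalar reference distance (plain arithmetic, independent of the package's
# vectorized implementations)
ref_nd <- function(p, q, dims, w1 = 2, w2 = 2, w3 = 1, w4 = 1, w5 = 1) {
  col2 <- (w3 * (p$r - q$r)^2 + w4 * (p$g - q$g)^2 + w5 * (p$b - q$b)^2) /
    (3 * 255^2)
  sp2 <- ((p$x - q$x)^2 + (p$y - q$y)^2) / (dims[1]^2 + dims[2]^2)
  sqrt(col2 / w1 + sp2 / w2)
}

# Brute-force DBSCAN oracle: full pairwise distance matrix, textbook scan
# (row-major seeds, FIFO expansion). Independent of the package's grid index
# and boundary machinery; shares only the conventions (neighbourhood
# excludes the query point, closed <= eps ball).
oracle_dbscan <- function(pts, eps, minpts, metric = "euclidean",
                          dims = NULL, w = list(w1 = 2, w2 = 2, w3 = 1,
                                                w4 = 1, w5 = 1)) {
  n <- nrow(pts)
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(cbind(pts$x, pts$y))),
    manhattan = as.matrix(stats::dist(cbind(pts$x, pts$y),
                                      method = "manhattan")),
    nd = {
      col2 <- (w$w3 * outer(pts$r, pts$r, "-")^2 +
               w$w4 * outer(pts$g, pts$g, "-")^2 +
               w$w5 * outer(pts$b, pts$b, "-")^2) / (3 * 255^2)
      sp2 <- (outer(pts$x, pts$x, "-")^2 + outer(pts$y, pts$y, "-")^2) /
        (dims[1]^2 + dims[2]^2)
      sqrt(col2 / w$w1 + sp2 / w$w2)
    })
  nb <- lapply(seq_len(n), function(i) {
    out <- which(D[i, ] <= eps)
    out[out != i]
  })
  labels <- integer(n); noise <- logical(n); k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || noise[i]) next
    if (length(nb[[i]]) < minpts) { noise[i] <- TRUE; next }
    k <- k + 1L
    labels[i] <- k
    fresh <- nb[[i]][labels[nb[[i]]] == 0L]
    expandable <- fresh[!noise[fresh]]
    labels[fresh] <- k; noise[fresh] <- FALSE
    queue <- expandable; head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (length(nb[[j]]) < minpts) next
      add <- nb[[j]][labels[nb[[j]]] == 0L]
      if (length(add)) {
        expandable <- add[!noise[add]]
        labels[add] <- k; noise[add] <- FALSE
        if (length(expandable)) queue <- c(queue, expandable)
      }
    }
  }
  labels
}

# TRUE when two labelings define the same partition-with-noise
# (noise matches exactly; clusters match up to id permutation)
same_clustering <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ta <- paste(a, b); length(unique(ta[a != 0L])) ==
    length(unique(a[a != 0L])) &&
    length(unique(ta[a != 0L])) == length(unique(b[b != 0L]))
}

# naive per-pixel confusion loop (oracle for count_pixels)
naive_counts <- function(ab, mb) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(ab$height)) for (j in seq_len(ab$width)) {
    a <- ab$fg[i, j] == 1L; m <- mb$fg[i, j] == 1L
    if (a && m) tp <- tp + 1L
    else if (a) fp <- fp + 1L
    else if (m) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
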