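#' Weights for the normalized colour-spatial distance
#'
#' The normalized distance (ND) combines a colour block and a spatial block
#' under reciprocal block weights `w1` (colour) and `w2` (spatial) that must
#' satisfy `1/w1 + 1/w2 = 1`, so the two blocks form a convex combination.
#' With the default `w1 = w2 = 2` colour and position contribute equally.
#' `w3`, `w4`, `w5` weight the R, G and B channels individually (all 1 by
#' default); raising one makes differences in that channel count more.
#'
#' @param w1 block weight for the colour term (> 0).
#' @param w2 block weight for the spatial term (> 0).
#' @param w3,w4,w5 per-channel weights for R, G, B (>= 0).
#' @return An object of class `nd_weights`.
#' @export
nd_weights <- function(w1 = 2, w2 = 2, w3 = 1, w4 = 1, w5 = 1) {
  if (!is.numeric(w1) || !is.numeric(w2) || w1 <= 0 || w2 <= 0)
    stop("block weights w1 and w2 must be positive")
  if (abs(1 / w1 + 1 / w2 - 1) > 1e-9)
    stop("block weights must satisfy 1/w1 + 1/w2 = 1 (got 1/",
         w1, " + 1/", w2, " = ", 1 / w1 + 1 / w2, ")")
  if (any(c(w3, w4, w5) < 0)) stop("channel weights must be non-negative")
  structure(list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, w5 = w5),
            class = "nd_weights")
}

# RGB channel normalization constant: three channels of range 255.
.ND_COLOR_NORM <- 3 * 255^2

.as_pt <- function(p) {
  # accept a one-row data.frame, a named list, or a named vector
  if (is.data.frame(p)) p <- as.list(p)
  p
}

#' Euclidean pixel distance
#'
#' Plain spatial Euclidean distance between two pixels, ignoring colour.
#'
#' @param p,q pixel points: named lists / one-row data.frames with `x`, `y`.
#' @return Non-negative distance (vectorized over coordinates).
#' @export
px_euclidean <- function(p, q) {
  p <- .as_pt(p); q <- .as_pt(q)
  sqrt((p$x - q$x)^2 + (p$y - q$y)^2)
}

#' Manhattan pixel distance
#'
#' City-block spatial distance `|dx| + |dy|`; the metric used by the binary
#' baseline clustering mode.
#'
#' @inheritParams px_euclidean
#' @return Non-negative distance.
#' @export
px_manhattan <- function(p, q) {
  p <- .as_pt(p); q <- .as_pt(q)
  abs(p$x - q$x) + abs(p$y - q$y)
}

#' Normalized colour-spatial pixel distance
#'
#' The joint metric that lets density clustering work directly on colour
#' images. For pixels `p`, `q` in an image of width `w` and height `h`:
#' \deqn{d(p,q) = \sqrt{\frac{1}{w_1}\,\frac{w_3\Delta R^2 + w_4\Delta G^2 +
#'   w_5\Delta B^2}{3\cdot 255^2} + \frac{1}{w_2}\,
#'   \frac{\Delta x^2 + \Delta y^2}{w^2 + h^2}}}
#' The colour block is normalized by the RGB channel constant `3 * 255^2`;
#' the spatial block by the squared image diagonal `w^2 + h^2`, so each block
#' lies in `[0, 1)` and, with default weights, the whole distance is below 1
#' for any pixel pair inside the image.
#'
#' @param p,q pixel points with fields `x`, `y`, `r`, `g`, `b`.
#' @param dims image dimensions `c(width, height)`.
#' @param w an [nd_weights()] object.
#' @return Non-negative distance (vectorized).
#' @export
normalized_distance <- function(p, q, dims, w = nd_weights()) {
  stopifnot(inherits(w, "nd_weights"), length(dims) == 2L, all(dims >= 1))
  p <- .as_pt(p); q <- .as_pt(q)
  if (any(p$x < 0 | p$x >= dims[1L] | p$y < 0 | p$y >= dims[2L] |
          q$x < 0 | q$x >= dims[1L] | q$y < 0 | q$y >= dims[2L]))
    stop("pixel coordinates outside image dimensions")
  col2 <- (w$w3 * (p$r - q$r)^2 + w$w4 * (p$g - q$g)^2 +
           w$w5 * (p$b - q$b)^2) / .ND_COLOR_NORM
  sp2 <- ((p$x - q$x)^2 + (p$y - q$y)^2) / (dims[1L]^2 + dims[2L]^2)
  sqrt(col2 / w$w1 + sp2 / w$w2)
}

#' Normalized distance for multispectral pixels
#'
#' Generalizes [normalized_distance()] to `n` channels: the colour block
#' becomes `sum_k w_k * dC_k^2 / normalizer`. With `n = 3`, channel range
#' 255, unit channel weights and `normalizer = 3 * 255^2` it reduces exactly
#' to the RGB normalized distance.
#'
#' @param u,v lists with `channels` (numeric vectors of equal length) and
#'   coordinates `x`, `y`.
#' @param dims image dimensions `c(width, height)`.
#' @param w1,w2 block weights, `1/w1 + 1/w2 = 1`.
#' @param wk per-channel weights (recycled to the number of channels).
#' @param normalizer positive normalization constant for the channel block;
#'   defaults to `n * 255^2` (n channels of 8-bit range).
#' @return Non-negative distance.
#' @export
multispectral_distance <- function(u, v, dims, w1 = 2, w2 = 2, wk = 1,
                                   normalizer = NULL) {
  if (abs(1 / w1 + 1 / w2 - 1) > 1e-9)
    stop("block weights must satisfy 1/w1 + 1/w2 = 1")
  cu <- u$channels; cv <- v$channels
  if (length(cu) != length(cv))
    stop("channel count mismatch: ", length(cu), " vs ", length(cv))
  n <- length(cu)
  if (n < 1L) stop("at least one channel required")
  wk <- rep_len(wk, n)
  if (is.null(normalizer)) normalizer <- n * 255^2
  if (normalizer <= 0) stop("normalizer must be positive")
  col2 <- sum(wk * (cu - cv)^2) / normalizer
  sp2 <- ((u$x - v$x)^2 + (u$y - v$y)^2) / (dims[1L]^2 + dims[2L]^2)
  sqrt(col2 / w1 + sp2 / w2)
}

#' Conservative spatial radius of a normalized-distance ball
#'
#' Any pixel within normalized distance `eps` of a query pixel lies within
#' Euclidean spatial distance `eps * sqrt(w2 * (width^2 + height^2))` of it,
#' because the spatial block alone already contributes
#' `(dx^2 + dy^2) / (w2 (w^2 + h^2))` to the squared distance. The bound is
#' what lets the clusterers restrict ND region queries to a spatial window,
#' and sets the leading-point band width in ND mode.
#'
#' @param eps normalized-distance radius (> 0).
#' @param dims image dimensions `c(width, height)`.
#' @param w an [nd_weights()] object (only `w2` is used).
#' @return Spatial radius in pixels.
#' @export
spatial_reach <- function(eps, dims, w = nd_weights()) {
  stopifnot(eps > 0, inherits(w, "nd_weights"))
  eps * sqrt(w$w2 * (dims[1L]^2 + dims[2L]^2))
}
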