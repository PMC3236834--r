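#' Convert an RGB image to luminance
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, returned as a
#' real-valued matrix indexed like the channel matrices.
#'
#' @param img an [rgb_image()].
#' @return Numeric matrix of luminance values in `[0, 255]`.
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  0.299 * img$r + 0.587 * img$g + 0.114 * img$b
}

#' Intermeans (iterative two-means) automatic threshold
#'
#' Starting from the global mean, repeatedly sets the threshold to the
#' midpoint of the means of the two classes it induces (`gray <= T` vs
#' `gray > T`) until the threshold moves by less than `tol` gray levels.
#' This is the classic iterative-selection thresholding used to binarize a
#' lesion image before spatial-only clustering.
#'
#' @param gray numeric matrix (or vector) of gray levels.
#' @param tol convergence tolerance in gray levels.
#' @param max_iter iteration cap.
#' @return A list of class `intermeans_result` with `threshold`,
#'   `iterations`, `converged` and `degenerate` (TRUE when one class is
#'   empty at every threshold, i.e. a constant image).
#' @export
intermeans_threshold <- function(gray, tol = 0.5, max_iter = 200L) {
  v <- as.numeric(gray)
  if (!length(v)) stop("at least one pixel required")
  if (anyNA(v)) stop("gray levels must not contain NA")
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    return(structure(list(threshold = rng[1L], iterations = 1L,
                          converged = TRUE, degenerate = TRUE),
                     class = "intermeans_result"))
  }
  t_cur <- mean(v)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (!length(lo) || !length(hi)) break  # threshold drifted past the data
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) {
      # return t_cur, not t_new: the update from t_cur is < tol by this
      # very test, so the reported threshold is a fixed point of the
      # iteration to within the tolerance
      converged <- TRUE
      break
    }
    t_cur <- t_new
  }
  structure(list(threshold = t_cur, iterations = it,
                 converged = converged, degenerate = FALSE),
            class = "intermeans_result")
}

#' @export
print.intermeans_result <- function(x, ...) {
  cat(sprintf("<intermeans threshold %.3f after %d iteration(s)%s%s>\n",
              x$threshold, x$iterations,
              if (x$converged) "" else " (not converged)",
              if (x$degenerate) " (degenerate: constant image)" else ""))
  invisible(x)
}

#' Binarize a gray image at a threshold
#'
#' Foreground is the dark class, `gray <= T`: in dermoscopy the lesion is
#' darker than the surrounding skin, so thresholding marks lesion candidate
#' pixels as foreground. Ties at exactly `T` go to the dark class so the
#' lesion never loses boundary pixels.
#'
#' @param gray numeric matrix of gray levels (e.g. from [to_gray()]).
#' @param threshold gray-level cut, e.g. from [intermeans_threshold()].
#' @return A [binary_mask()] with `foreground = "dark"`.
#' @export
binarize <- function(gray, threshold) {
  stopifnot(is.matrix(gray), is.numeric(threshold), length(threshold) == 1L)
  binary_mask((gray <= threshold) * 1L, foreground = "dark")
}
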