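#' Confusion counts between automatic and manual masks
#'
#' Pixel-wise confusion between a predicted (automatic border, AB) and a
#' ground-truth (manual border, MB) lesion mask: `tp` foreground in both,
#' `fp` only in AB, `fn` only in MB, `tn` in neither.
#'
#' @param ab predicted [binary_mask()].
#' @param mb ground-truth [binary_mask()] of the same dimensions.
#' @return A list of class `eval_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
count_pixels <- function(ab, mb) {
  stopifnot(inherits(ab, "binary_mask"), inherits(mb, "binary_mask"))
  if (ab$width != mb$width || ab$height != mb$height)
    stop("mask dimensions differ: ", ab$width, "x", ab$height,
         " vs ", mb$width, "x", mb$height)
  a <- ab$fg == 1L; m <- mb$fg == 1L
  structure(list(tp = sum(a & m), fp = sum(a & !m),
                 fn = sum(!a & m), tn = sum(!a & !m)),
            class = "eval_counts")
}

#' Precision and recall from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`. A zero
#' denominator yields `NA` rather than 0, so an empty prediction is reported
#' as undefined precision instead of being silently rewarded.
#'
#' @param counts an [count_pixels()] result.
#' @return List with `precision` and `recall` (each in `[0, 1]` or `NA`).
#' @export
precision_recall <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  pr <- if (counts$tp + counts$fp == 0) NA_real_ else
    counts$tp / (counts$tp + counts$fp)
  rc <- if (counts$tp + counts$fn == 0) NA_real_ else
    counts$tp / (counts$tp + counts$fn)
  list(precision = pr, recall = rc)
}

#' XOR border error
#'
#' The standard lesion-segmentation error measure: the symmetric difference
#' between the automatic (AB) and manual (MB) masks relative to the manual
#' lesion area, as a percentage:
#' `BE = 100 * |AB xor MB| / |MB| = 100 * (fp + fn) / (tp + fn)`.
#' Zero iff the masks agree exactly; can exceed 100 when the prediction
#' overshoots a small lesion.
#'
#' @inheritParams count_pixels
#' @return Border error in percent (scalar).
#' @export
border_error <- function(ab, mb) {
  counts <- count_pixels(ab, mb)
  denom <- counts$tp + counts$fn
  if (denom == 0) stop("manual mask has no foreground: border error undefined")
  100 * (counts$fp + counts$fn) / denom
}

#' Full evaluation report for a mask pair
#'
#' @inheritParams count_pixels
#' @return List with `counts`, `precision`, `recall` and `border_error`
#'   (percent; `NA` when the manual mask is empty).
#' @export
evaluate_masks <- function(ab, mb) {
  counts <- count_pixels(ab, mb)
  pr <- precision_recall(counts)
  be <- if (counts$tp + counts$fn == 0) NA_real_ else
    100 * (counts$fp + counts$fn) / (counts$tp + counts$fn)
  list(counts = counts, precision = pr$precision, recall = pr$recall,
       border_error = be)
}
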