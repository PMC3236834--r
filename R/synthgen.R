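#' Phantom configuration
#'
#' Parameters of a dermoscopy-like synthetic image: a roughly uniform
#' skin-coloured background with per-channel Gaussian sensor noise, one
#' darker lesion blob with an irregular star-shaped outline and a blurred
#' ("fuzzy") border, and optionally dark hair-like strokes running from the
#' lesion interior to an image edge. The exact pre-blur lesion shape is kept
#' as ground truth, so all measured segmentation error is attributable to
#' the segmentation itself.
#'
#' @param seed integer RNG seed; every phantom is fully determined by its
#'   configuration.
#' @param width,height image size in pixels (at least 32 x 32).
#' @param skin,lesion base RGB colours (length-3 integer vectors, 0-255).
#' @param noise_sd per-channel Gaussian noise standard deviation in gray
#'   levels.
#' @param fuzziness Gaussian blur sigma (pixels) applied to the lesion
#'   border.
#' @param irregularity amplitude of the radial harmonics deforming the
#'   lesion outline, 0 (disc) to about 0.4.
#' @param radius_frac range of the mean lesion radius as a fraction of the
#'   smaller image dimension.
#' @param hair_count number of hair strokes.
#' @param hair_darkness 0-1; how dark the hair strokes are.
#' @return A list of class `phantom_config`. Includes the derived `contrast`
#'   field: mean luminance gap between skin and lesion divided by
#'   `noise_sd`.
#' @export
phantom_config <- function(seed = 1L, width = 80L, height = 80L,
                           skin = c(224L, 172L, 138L),
                           lesion = c(96L, 56L, 48L),
                           noise_sd = 8, fuzziness = 1.5,
                           irregularity = 0.25,
                           radius_frac = c(0.22, 0.30),
                           hair_count = 0L, hair_darkness = 0.8) {
  stopifnot(width >= 32L, height >= 32L,
            length(skin) == 3L, length(lesion) == 3L,
            all(c(skin, lesion) >= 0), all(c(skin, lesion) <= 255),
            noise_sd >= 0, fuzziness >= 0,
            irregularity >= 0, irregularity <= 0.45,
            length(radius_frac) == 2L, all(radius_frac > 0),
            radius_frac[1L] <= radius_frac[2L],
            hair_count >= 0, hair_darkness >= 0, hair_darkness <= 1)
  lum <- function(ch) sum(c(0.299, 0.587, 0.114) * ch)
  structure(list(seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height),
                 skin = as.integer(skin), lesion = as.integer(lesion),
                 noise_sd = noise_sd, fuzziness = fuzziness,
                 irregularity = irregularity, radius_frac = radius_frac,
                 hair_count = as.integer(hair_count),
                 hair_darkness = hair_darkness,
                 contrast = if (noise_sd > 0)
                   abs(lum(skin) - lum(lesion)) / noise_sd else Inf),
            class = "phantom_config")
}

# star-shaped radius function r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k))
.shape_impl <- function(cfg) {
  w <- cfg$width; h <- cfg$height
  r0 <- stats::runif(1, cfg$radius_frac[1L], cfg$radius_frac[2L]) * min(w, h)
  cx <- w / 2 + stats::runif(1, -0.05, 0.05) * w
  cy <- h / 2 + stats::runif(1, -0.05, 0.05) * h
  ks <- 2:8
  a <- cfg$irregularity * stats::runif(length(ks), -1, 1) / ks
  phi <- stats::runif(length(ks), 0, 2 * pi)
  # keep the blob strictly interior: max radius below half the span minus margin
  rmax_allowed <- min(cx, cy, w - cx, h - cy) - 3
  amp <- sum(abs(a))
  if (r0 * (1 + amp) > rmax_allowed && amp > 0) {
    a <- a * max(0, (rmax_allowed / r0 - 1)) / amp
  }
  r0 <- min(r0, rmax_allowed)
  px <- rep.int(0:(w - 1L), h) + 0.5
  py <- rep(0:(h - 1L), each = w) + 0.5
  theta <- atan2(py - cy, px - cx)
  rad <- sqrt((px - cx)^2 + (py - cy)^2)
  rtheta <- r0 * (1 + colSums(a * sin(outer(ks, theta) + phi)))
  m <- matrix(as.integer(rad <= rtheta), nrow = h, ncol = w, byrow = TRUE)
  binary_mask(m, foreground = "lesion")
}

#' Generate the ground-truth lesion shape
#'
#' Draws the star-shaped lesion region of a phantom: a disc of mean radius
#' `r0` deformed by random low-order radial harmonics scaled by
#' `irregularity`. The shape is fully interior to the image and its area is
#' a moderate fraction of the image.
#'
#' @param cfg a [phantom_config()].
#' @return A [binary_mask()] (the exact ground truth used by
#'   [render_phantom()]).
#' @export
make_lesion_shape <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  .shape_impl(cfg)
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# separable Gaussian blur as banded-matrix products (no padding artefacts:
# kernel rows renormalized at the borders)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in -rad:rad) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1L & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + rad + 1L]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Render a phantom image with ground truth
#'
#' Draws the lesion in the lesion colour over the skin background, blurs the
#' transition by `fuzziness` (border fuzz is a property of the image, not of
#' the ground truth), optionally adds dark hair strokes from the lesion
#' interior out to an image edge, and finally adds per-channel Gaussian
#' noise. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return A list with `image` ([rgb_image()]), `mask` (the exact pre-blur
#'   [binary_mask()] ground truth) and `config`.
#' @export
render_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  truth <- .shape_impl(cfg)
  w <- cfg$width; h <- cfg$height
  alpha <- .gauss_blur(truth$fg * 1.0, cfg$fuzziness)
  chans <- lapply(1:3, function(ci) {
    cfg$skin[ci] * (1 - alpha) + cfg$lesion[ci] * alpha
  })
  if (cfg$hair_count > 0L) {
    fgidx <- which(truth$fg == 1L, arr.ind = TRUE)
    hair_col <- (1 - cfg$hair_darkness) * cfg$skin
    px <- rep.int(0:(w - 1L), h) + 0.5
    py <- rep(0:(h - 1L), each = w) + 0.5
    for (s in seq_len(cfg$hair_count)) {
      src <- fgidx[sample.int(nrow(fgidx), 1L), ]
      x0 <- src[2L] - 0.5; y0 <- src[1L] - 0.5
      side <- sample.int(4L, 1L)
      x1 <- switch(side, stats::runif(1, 0, w), w, stats::runif(1, 0, w), 0)
      y1 <- switch(side, 0, stats::runif(1, 0, h), h, stats::runif(1, 0, h))
      width_px <- stats::runif(1, 0.8, 1.6)
      ex <- x1 - x0; ey <- y1 - y0
      len2 <- max(ex^2 + ey^2, 1e-12)
      t <- pmin(pmax(((px - x0) * ex + (py - y0) * ey) / len2, 0), 1)
      d <- sqrt((px - (x0 + t * ex))^2 + (py - (y0 + t * ey))^2)
      cover <- pmin(pmax(width_px / 2 + 0.5 - d, 0), 1)  # anti-aliased stroke
      cover_m <- matrix(cover, nrow = h, ncol = w, byrow = TRUE)
      for (ci in 1:3)
        chans[[ci]] <- chans[[ci]] * (1 - cover_m) + hair_col[ci] * cover_m
    }
  }
  if (cfg$noise_sd > 0) {
    for (ci in 1:3)
      chans[[ci]] <- chans[[ci]] +
        matrix(stats::rnorm(w * h, 0, cfg$noise_sd), h, w)
  }
  clamp <- function(m) matrix(as.integer(pmin(pmax(round(m), 0), 255)), h, w)
  list(image = rgb_image(clamp(chans[[1L]]), clamp(chans[[2L]]),
                         clamp(chans[[3L]])),
       mask = truth, config = cfg)
}

#' Generate a suite of phantoms
#'
#' `n` phantoms with per-item seeds `base_seed + i - 1`, under a difficulty
#' preset: `"easy"` (strong lesion/skin contrast), `"low-contrast"` (lesion
#' colour pulled towards skin and more noise, the hard case for
#' thresholding-based pipelines) or `"hairy"` (easy contrast plus dark hair
#' strokes crossing the lesion out to the image edge). The returned manifest
#' contains every configuration, sufficient for exact regeneration.
#'
#' @param n number of phantoms.
#' @param base_seed seed of the first phantom.
#' @param difficulty `"easy"`, `"low-contrast"` or `"hairy"`.
#' @param ... overrides forwarded to [phantom_config()].
#' @return A list of class `phantom_suite`: `items` (each with `image`,
#'   `mask`, `config`) and `manifest` (a `data.frame` of scalar settings).
#' @export
make_suite <- function(n, base_seed = 1L,
                       difficulty = c("easy", "low-contrast", "hairy"), ...) {
  stopifnot(n >= 1L)
  difficulty <- match.arg(difficulty)
  # The low-contrast preset keeps a moderate chromatic lesion/skin gap but
  # almost no luminance gap (violaceous lesion): the case where a gray-level
  # threshold carries little information while colour still separates.
  preset <- switch(difficulty,
    "easy" = list(),
    "low-contrast" = list(lesion = c(190L, 160L, 185L)),
    "hairy" = list(hair_count = 2L)
  )
  overrides <- list(...)
  items <- lapply(seq_len(n), function(i) {
    args <- c(list(seed = base_seed + i - 1L), overrides, preset)
    args <- args[!duplicated(names(args))]  # explicit overrides beat presets
    do.call(render_phantom, list(do.call(phantom_config, args)))
  })
  manifest <- do.call(rbind, lapply(items, function(it) {
    cfg <- it$config
    data.frame(seed = cfg$seed, width = cfg$width, height = cfg$height,
               skin = paste(cfg$skin, collapse = ";"),
               lesion = paste(cfg$lesion, collapse = ";"),
               noise_sd = cfg$noise_sd, fuzziness = cfg$fuzziness,
               irregularity = cfg$irregularity,
               hair_count = cfg$hair_count,
               hair_darkness = cfg$hair_darkness,
               difficulty = difficulty)
  }))
  structure(list(items = items, manifest = manifest,
                 difficulty = difficulty, base_seed = base_seed),
            class = "phantom_suite")
}

#' @export
print.phantom_suite <- function(x, ...) {
  cat(sprintf("<phantom_suite: %d %s phantom(s), base seed %d>\n",
              length(x$items), x$difficulty, x$base_seed))
  invisible(x)
}
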