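test_that("worked distance values match hand computation", {
  # 3-4-5 triangle and friends
  expect_equal(px_euclidean(list(x = 0, y = 0), list(x = 3, y = 4)), 5)
  expect_equal(px_euclidean(list(x = 0, y = 0), list(x = 1, y = 1)), sqrt(2))
  expect_equal(px_manhattan(list(x = 0, y = 0), list(x = 2, y = 3)), 5)
  expect_equal(px_manhattan(list(x = 5, y = 1), list(x = 1, y = 5)), 8)

  dims <- c(100, 100)
  black0 <- list(x = 0, y = 0, r = 0, g = 0, b = 0)
  white99 <- list(x = 99, y = 99, r = 255, g = 255, b = 255)
  # opposite corners, black vs white: colour block saturates at 1/2,
  # spatial block is (99^2+99^2)/(2*20000)
  expect_equal(normalized_distance(black0, white99, dims),
               sqrt(0.5 + 0.5 * (99^2 + 99^2) / 20000), tolerance = 1e-12)
  expect_equal(normalized_distance(black0, white99, dims), 0.99501,
               tolerance = 1e-5)
  # same position, pure red vs black: sqrt(255^2 / (2 * 3 * 255^2)) = sqrt(1/6)
  red <- list(x = 5, y = 5, r = 255, g = 0, b = 0)
  blk <- list(x = 5, y = 5, r = 0, g = 0, b = 0)
  expect_equal(normalized_distance(red, blk, dims), sqrt(1 / 6),
               tolerance = 1e-12)
  expect_equal(normalized_distance(red, blk, dims), 0.40825, tolerance = 1e-5)
  expect_equal(normalized_distance(red, red, dims), 0)
})

test_that("all metrics satisfy metric axioms on random triples", {
  set.seed(101)
  dims <- c(64, 48)
  rp <- function(n) data.frame(
    x = sample(0:(dims[1] - 1), n, TRUE), y = sample(0:(dims[2] - 1), n, TRUE),
    r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
    b = sample(0:255, n, TRUE))
  n <- 2000
  a <- rp(n); b <- rp(n); c <- rp(n)
  metrics <- list(
    eu = function(p, q) px_euclidean(p, q),
    ma = function(p, q) px_manhattan(p, q),
    nd = function(p, q) normalized_distance(p, q, dims),
    ms = function(p, q) mapply(function(i, j) multispectral_distance(
      list(channels = c(p$r[i], p$g[i], p$b[i]), x = p$x[i], y = p$y[i]),
      list(channels = c(q$r[j], q$g[j], q$b[j]), x = q$x[j], y = q$y[j]),
      dims), seq_len(nrow(p)), seq_len(nrow(q))))
  for (nm in names(metrics)) {
    d <- metrics[[nm]]
    idx <- if (nm == "ms") 1:100 else seq_len(n)  # scalar metric is slower
    ai <- a[idx, ]; bi <- b[idx, ]; ci <- c[idx, ]
    dab <- d(ai, bi); dba <- d(bi, ai); dac <- d(ai, ci); dcb <- d(ci, bi)
    expect_true(all(dab >= 0), info = nm)
    expect_equal(dab, dba, info = nm)
    expect_equal(d(ai, ai), rep(0, length(idx)), info = nm)
    expect_true(all(dab <= dac + dcb + 1e-9), info = nm)
  }
})

test_that("normalized distance with default weights is bounded by 1", {
  set.seed(7)
  dims <- c(100, 100)
  n <- 5000
  p <- data.frame(x = sample(0:99, n, TRUE), y = sample(0:99, n, TRUE),
                  r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
                  b = sample(0:255, n, TRUE))
  q <- p[sample(n), ]
  expect_true(all(normalized_distance(p, q, dims) < 1))
})

test_that("distance increases monotonically in each |delta|", {
  dims <- c(50, 50)
  base <- list(x = 10, y = 10, r = 100, g = 100, b = 100)
  d0 <- normalized_distance(base, list(x = 12, y = 10, r = 110, g = 100,
                                       b = 100), dims)
  d_more_sp <- normalized_distance(base, list(x = 14, y = 10, r = 110,
                                              g = 100, b = 100), dims)
  d_more_col <- normalized_distance(base, list(x = 12, y = 10, r = 130,
                                               g = 100, b = 100), dims)
  expect_gt(d_more_sp, d0)
  expect_gt(d_more_col, d0)
})

test_that("weight constraint is enforced, not renormalized", {
  expect_error(nd_weights(w1 = 2, w2 = 3), "1/w1")
  expect_error(nd_weights(w1 = 0, w2 = 2), "positive")
  expect_error(nd_weights(w1 = -1, w2 = 2), "positive")
  # a valid non-default pair: 1/1.5 + 1/3 = 1
  w <- nd_weights(w1 = 1.5, w2 = 3)
  expect_equal(w$w1, 1.5)
  # colour-heavier weighting increases colour contribution
  dims <- c(50, 50)
  p <- list(x = 0, y = 0, r = 0, g = 0, b = 0)
  q <- list(x = 0, y = 0, r = 60, g = 0, b = 0)
  expect_gt(normalized_distance(p, q, dims, w),
            normalized_distance(p, q, dims))
})

test_that("multispectral distance reduces to RGB case and handles n = 1", {
  set.seed(21)
  dims <- c(40, 30)
  for (i in 1:100) {
    p <- list(x = sample(0:39, 1), y = sample(0:29, 1),
              r = sample(0:255, 1), g = sample(0:255, 1), b = sample(0:255, 1))
    q <- list(x = sample(0:39, 1), y = sample(0:29, 1),
              r = sample(0:255, 1), g = sample(0:255, 1), b = sample(0:255, 1))
    expect_equal(
      multispectral_distance(
        list(channels = c(p$r, p$g, p$b), x = p$x, y = p$y),
        list(channels = c(q$r, q$g, q$b), x = q$x, y = q$y), dims),
      normalized_distance(p, q, dims), tolerance = 1e-12)
  }
  # n = 1 grayscale worked value: sqrt(0.5 * 128^2 / 255^2)
  g1 <- list(channels = 0, x = 3, y = 3)
  g2 <- list(channels = 128, x = 3, y = 3)
  expect_equal(multispectral_distance(g1, g2, dims, normalizer = 255^2),
               sqrt(0.5 * 128^2 / 255^2), tolerance = 1e-12)
  expect_equal(multispectral_distance(g1, g2, dims, normalizer = 255^2),
               0.35495, tolerance = 1e-4)
  expect_equal(multispectral_distance(g1, g1, dims), 0)
  expect_error(multispectral_distance(g1, list(channels = c(1, 2), x = 0,
                                               y = 0), dims), "mismatch")
})

test_that("spatial reach bounds the spatial extent of ND eps-balls", {
  dims <- c(100, 100)
  expect_equal(spatial_reach(0.05, dims), 10)
  expect_lt(spatial_reach(1e-9, dims), 1e-6)
  # brute force: no pair within eps may exceed the spatial reach
  set.seed(33)
  n <- 400
  p <- data.frame(x = sample(0:99, n, TRUE), y = sample(0:99, n, TRUE),
                  r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
                  b = sample(0:255, n, TRUE))
  q <- data.frame(x = sample(0:99, n, TRUE), y = sample(0:99, n, TRUE),
                  r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
                  b = sample(0:255, n, TRUE))
  for (eps in c(0.02, 0.05, 0.2)) {
    d <- normalized_distance(p, q, dims)
    sp <- sqrt((p$x - q$x)^2 + (p$y - q$y)^2)
    expect_true(all(sp[d <= eps] <= spatial_reach(eps, dims) + 1e-9))
  }
})
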