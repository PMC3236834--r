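test_that("convex hull matches a brute-force extremality oracle", {
  # unit square corners + centre
  h <- convex_hull(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  expect_equal(length(h$x), 4L)
  expect_gt(poly_area(h), 0)
  expect_equal(poly_area(h), 1)

  set.seed(5)
  for (rep in 1:10) {
    x <- sample(0:30, 20, TRUE); y <- sample(0:30, 20, TRUE)
    h <- convex_hull(x, y)
    # every input point inside or on the hull
    expect_true(all(sp::point.in.polygon(x, y, h$x, h$y) > 0))
    # brute-force: a point is a hull vertex iff it is not strictly inside
    # the triangle of any other three points
    pts <- unique(cbind(x, y))
    inside_some_triangle <- function(px, py) {
      n <- nrow(pts)
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        tri <- pts[c(i, j, k), ]
        if ((px %in% tri[, 1] && py %in% tri[, 2] &&
             any(tri[, 1] == px & tri[, 2] == py))) next
        if (abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
                (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])) < 1e-12)
          next
        if (sp::point.in.polygon(px, py, tri[, 1], tri[, 2]) == 1) return(TRUE)
      }
      FALSE
    }
    verts <- unique(cbind(h$x, h$y))
    for (v in seq_len(nrow(verts)))
      expect_false(inside_some_triangle(verts[v, 1], verts[v, 2]))
  }
})

test_that("degenerate hulls inflate to thin rectangles covering the input", {
  h <- convex_hull(c(0, 1, 2), c(0, 1, 2), pad = 0.25)  # collinear
  expect_equal(length(h$x), 4L)
  expect_gt(poly_area(h), 0)
  expect_true(all(sp::point.in.polygon(c(0, 1, 2), c(0, 1, 2),
                                       h$x, h$y) > 0))
  hp <- convex_hull(3, 4, pad = 0.5)  # single point
  expect_equal(poly_area(hp), 1)
  expect_true(sp::point.in.polygon(3, 4, hp$x, hp$y) > 0)
  expect_error(convex_hull(numeric(0), numeric(0)), "empty")
})

test_that("union_into has exact region semantics", {
  sq <- function(x0, y0, s) list(x = c(x0, x0 + s, x0 + s, x0),
                                 y = c(y0, y0, y0 + s, y0 + s))
  # identity on empty set
  g <- union_into(polygon_set(), sq(0, 0, 1))
  expect_equal(length(g), 1L)
  expect_equal(poly_area(g[[1]]), 1)
  # half-overlapping unit squares -> single shell of area 1.5
  g2 <- union_into(g, sq(0.5, 0, 1))
  expect_equal(length(g2), 1L)
  expect_equal(sum(vapply(g2, poly_area, 0)), 1.5, tolerance = 1e-6)
  # rasterization oracle at 0.1-pixel resolution
  gx <- seq(0.05, 1.95, by = 0.1); gy <- seq(0.05, 0.95, by = 0.1)
  grid <- expand.grid(x = gx, y = gy)
  covered <- ps_contains(g2, grid$x, grid$y)
  ref <- (grid$x <= 1 | grid$x >= 0.5) & grid$x <= 1.5
  expect_equal(mean(covered), mean(ref), tolerance = 0.02)
  # disjoint squares stay separate shells
  g3 <- union_into(g, sq(3, 0, 1))
  expect_equal(length(g3), 2L)
  expect_equal(sum(vapply(g3, poly_area, 0)), 2, tolerance = 1e-6)
})

test_that("union_into is idempotent and never shrinks the region", {
  set.seed(9)
  sq <- function(x0, y0, s) list(x = c(x0, x0 + s, x0 + s, x0),
                                 y = c(y0, y0, y0 + s, y0 + s))
  g <- polygon_set()
  probe <- expand.grid(x = seq(0, 12, by = 0.5), y = seq(0, 12, by = 0.5))
  was_inside <- rep(FALSE, nrow(probe))
  for (i in 1:8) {
    g <- union_into(g, sq(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0.5, 2)))
    now <- ps_contains(g, probe$x, probe$y)
    expect_true(all(now[was_inside]))   # monotone growth
    was_inside <- now
  }
  area_before <- sum(vapply(g, poly_area, 0))
  for (sh in unclass(g)) g <- union_into(g, sh)  # re-union its own shells
  expect_equal(sum(vapply(g, poly_area, 0)), area_before, tolerance = 1e-6)
})

test_that("a ring of hulls leaves a hole rather than filling it", {
  sq <- function(x0, y0, s) list(x = c(x0, x0 + s, x0 + s, x0),
                                 y = c(y0, y0, y0 + s, y0 + s))
  g <- polygon_set()
  # frame of four 1 x 3 rectangles around the empty square (1,1)-(2,2)
  for (r in list(list(0, 0, 3, 1), list(0, 2, 3, 3), list(0, 0, 1, 3),
                 list(2, 0, 3, 3))) {
    g <- union_into(g, list(x = c(r[[1]], r[[3]], r[[3]], r[[1]]),
                            y = c(r[[2]], r[[2]], r[[4]], r[[4]])))
  }
  expect_false(ps_contains(g, 1.5, 1.5))       # hole centre stays outside
  expect_true(ps_contains(g, 0.5, 0.5))
  areas <- vapply(g, poly_area, 0)
  expect_true(any(areas < 0))                  # an explicit hole ring exists
  expect_equal(sum(areas), 8, tolerance = 1e-6)
  # boundary distance sees the hole edges
  expect_equal(boundary_distance(g, 1.5, 1.5), 0.5, tolerance = 1e-6)
})

test_that("containment counts boundary points as inside", {
  g <- polygon_set(list(list(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))))
  expect_true(ps_contains(g, 1, 1))
  expect_false(ps_contains(g, 3, 3))
  expect_true(ps_contains(g, 0, 0))   # vertex
  expect_true(ps_contains(g, 1, 0))   # edge midpoint
})

test_that("boundary distance agrees with dense edge sampling", {
  g <- polygon_set(list(list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))))
  expect_equal(boundary_distance(g, 5, 5), 5)
  expect_equal(boundary_distance(g, 5, 0), 0)
  expect_error(boundary_distance(polygon_set(), 1, 1), "empty")
  set.seed(23)
  tsamp <- seq(0, 1, length.out = 4001)
  ex <- c(10 * tsamp, rep(10, 4001), 10 * (1 - tsamp), rep(0, 4001))
  ey <- c(rep(0, 4001), 10 * tsamp, rep(10, 4001), 10 * (1 - tsamp))
  for (i in 1:50) {
    px <- runif(1, -3, 13); py <- runif(1, -3, 13)
    ref <- min(sqrt((ex - px)^2 + (ey - py)^2))
    got <- boundary_distance(g, px, py)
    expect_lte(got, ref + 1e-9)       # sampling can only overestimate
    expect_lt(ref - got, 2e-3)        # 2.5e-3 sample spacing on the edges
  }
})

test_that("hull of points inside a disc stays within the disc", {
  # underpins the skip-test soundness in spatial mode
  set.seed(31)
  for (rep in 1:100) {
    cx <- runif(1, 0, 20); cy <- runif(1, 0, 20); eps <- runif(1, 1, 4)
    ang <- runif(12, 0, 2 * pi); rad <- eps * sqrt(runif(12))
    x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
    h <- convex_hull(x, y, pad = eps / 4)
    if (abs(poly_area(h)) < 1e-9) next
    # all hull vertices (hence the hull) within the closed disc
    expect_true(all(sqrt((h$x - cx)^2 + (h$y - cy)^2) <= eps + 1e-9))
  }
})

test_that("polygon sets export to WKT and vertex tables", {
  g <- polygon_set(list(list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))))
  expect_match(ps_as_wkt(g), "^MULTIPOLYGON \\(\\(\\(0 0")
  expect_equal(ps_as_wkt(polygon_set()), "MULTIPOLYGON EMPTY")
  df <- ps_as_df(g)
  expect_equal(nrow(df), 4L)
  expect_named(df, c("shell", "vertex", "x", "y"))
})
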