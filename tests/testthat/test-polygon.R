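test_that("bresenham_line traces expected pixels", {
  expect_equal(bresenham_line(c(0, 0), c(0, 3)),
               cbind(c(0, 0, 0, 0), 0:3), ignore_attr = TRUE)
  expect_equal(bresenham_line(c(0, 0), c(3, 3)),
               cbind(0:3, 0:3), ignore_attr = TRUE)
  seg <- bresenham_line(c(0, 0), c(2, 5))
  expect_equal(seg[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(seg[nrow(seg), ], c(2, 5), ignore_attr = TRUE)
  expect_true(all(abs(diff(seg[, 1])) <= 1) && all(abs(diff(seg[, 2])) <= 1))
})

test_that("empty polygon list rasterizes to an all-zero canvas", {
  expect_equal(rasterize_mask(polygon_mask(list(), c(6, 7))),
               matrix(FALSE, 6, 7))
})

test_that("axis-aligned square matches the point-in-polygon brute force", {
  pm <- polygon_mask(list(rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2))), c(12, 12))
  r <- rasterize_mask(pm)
  expect_equal(sum(r), 49)                       # closed 7x7 block
  expect_equal(r, oracle_rasterize(pm))
})

test_that("a square with an inner square hole yields the annulus", {
  pm <- polygon_mask(list(rbind(c(1, 1), c(1, 10), c(10, 10), c(10, 1)),
                          rbind(c(4, 4), c(4, 7), c(7, 7), c(7, 4))), c(12, 12))
  r <- rasterize_mask(pm)
  expect_equal(r, oracle_rasterize(pm))
  expect_false(r[6, 6])                          # inside the hole
  expect_true(r[2, 2])                           # in the ring
  # a polygon inside the hole re-fills (3-level nesting, strict parity)
  pm3 <- polygon_mask(c(pm$polygons, list(rbind(c(5, 5), c(5, 6), c(6, 6), c(6, 5)))),
                      c(12, 12))
  r3 <- rasterize_mask(pm3)
  expect_equal(r3, oracle_rasterize(pm3))
  expect_true(r3[6, 6])
})

test_that("degenerate polygons are skipped and out-of-canvas vertices clipped with warnings", {
  pm <- polygon_mask(list(rbind(c(0, 0), c(0, 3))), c(5, 5))
  expect_warning(r <- rasterize_mask(pm), "fewer than 3")
  expect_equal(sum(r), 0)
  pm2 <- polygon_mask(list(rbind(c(-2, -2), c(-2, 8), c(8, 8), c(8, -2))), c(6, 6))
  expect_warning(r2 <- rasterize_mask(pm2), "clip")
  expect_true(all(r2))                           # canvas fully covered
})

test_that("rasterization equals the even-odd brute force on random polygon scenes", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    side <- sample(c(16, 32, 64), 1)
    polys <- lapply(seq_len(n), function(i) {
      v <- sample(3:8, 1)
      cbind(runif(v, 0, side - 1), runif(v, 0, side - 1))
    })
    pm <- polygon_mask(polys, c(side, side))
    expect_equal(suppressWarnings(rasterize_mask(pm)), oracle_rasterize(pm))
  }
})

test_that("polygonize -> rasterize is the identity on binary rasters", {
  expect_length(polygonize(matrix(FALSE, 8, 8))$polygons, 0)
  # filled square: a single polygon that round-trips
  sq <- matrix(FALSE, 12, 12); sq[3:9, 3:9] <- TRUE
  pz <- polygonize(sq)
  expect_length(pz$polygons, 1)
  expect_equal(unname(suppressWarnings(rasterize_mask(pz))), sq)
  # square annulus: outer polygon plus hole polygon
  an <- matrix(FALSE, 20, 20); an[4:16, 4:16] <- TRUE; an[8:12, 8:12] <- FALSE
  pz2 <- polygonize(an)
  expect_gte(length(pz2$polygons), 2)
  expect_equal(unname(suppressWarnings(rasterize_mask(pz2))), an)
  # random smoothed blobs, speckle, single pixels
  set.seed(32)
  for (rep in 1:8) {
    m <- matrix(rnorm(40 * 40), 40)
    m <- EBImage::imageData(EBImage::gblur(m, sample(2:4, 1))) > runif(1, -0.02, 0.05)
    pz3 <- polygonize(m)
    expect_equal(unname(suppressWarnings(rasterize_mask(pz3))), unname(m))
  }
  px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE; px[1, 9] <- TRUE
  expect_equal(unname(suppressWarnings(rasterize_mask(polygonize(px)))), px)
})
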