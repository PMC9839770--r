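test_that("component labelling matches the propagation oracle on random masks", {
  set.seed(21)
  for (k in 1:40) {
    m <- random_mask(sample(4:16, 1), sample(4:16, 1), p = runif(1, 0.1, 0.5))
    got <- find_components(m)
    want <- oracle_components(m)
    expect_length(got, length(want))
    got_sets <- lapply(got, function(co)
      co$pixels[order(co$pixels[, 2], co$pixels[, 1]), , drop = FALSE])
    ord <- order(vapply(got_sets, function(p) min(p[, 2]) * 1e6 + min(p[, 1]), 0))
    want_ord <- order(vapply(want, function(p) min(p[, 2]) * 1e6 + min(p[, 1]), 0))
    for (i in seq_along(want))
      expect_equal(got_sets[[ord[i]]], want[[want_ord[i]]], ignore_attr = TRUE)
  }
})

test_that("component geometry fields follow from the pixel set", {
  m <- matrix(0L, 8, 8)
  m[3:5, 3:5] <- 1L
  comps <- find_components(m)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$centroid, c(4, 4))
  expect_equal(comps[[1]]$area, 9)
  expect_equal(comps[[1]]$bbox, c(3, 3, 5, 5))

  expect_length(find_components(matrix(0L, 5, 5)), 0)

  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_length(find_components(diagm), 1)     # 8-connectivity joins diagonals
})

test_that("crop windows centre the rounded centroid and clamp by shifting", {
  w <- make_crop_window(c(6, 6), 4L, c(10L, 10L))
  expect_equal(c(w$row, w$col, w$height, w$width), c(4, 4, 4, 4))

  w0 <- make_crop_window(c(1, 1), 4L, c(10L, 10L))
  expect_equal(c(w0$row, w0$col), c(1, 1))

  wf <- make_crop_window(c(5, 5), 64L, c(10L, 10L))
  expect_equal(c(wf$row, wf$col, wf$height, wf$width), c(1, 1, 10, 10))

  # rounded centroid always falls inside the window
  set.seed(12)
  for (k in 1:50) {
    H <- sample(8:40, 1); W <- sample(8:40, 1)
    ctr <- c(runif(1, 1, H), runif(1, 1, W))
    s <- sample(2:20, 1)
    w <- make_crop_window(ctr, s, c(H, W))
    expect_gte(w$row, 1); expect_gte(w$col, 1)
    expect_lte(w$row + w$height - 1, H); expect_lte(w$col + w$width - 1, W)
    rc <- floor(ctr + 0.5)
    expect_true(rc[1] >= w$row && rc[1] <= w$row + w$height - 1)
    expect_true(rc[2] >= w$col && rc[2] <= w$col + w$width - 1)
  }
})

test_that("each lesion yields one crop that fully contains it", {
  m <- matrix(0L, 40, 40)
  m[4:6, 5:7] <- 1L
  m[30:33, 20:24] <- 1L
  img <- matrix(runif(1600), 40, 40)
  crops <- ccs_sample_pair(img, m, crop_size = 10L)
  expect_length(crops, 2)
  for (cr in crops) {
    expect_equal(dim(cr$image), c(10, 10))
    expect_equal(dim(cr$image), dim(cr$mask))
  }
  expect_equal(sum(vapply(crops, function(cr) sum(cr$mask), 0L)), sum(m))

  expect_length(ccs_sample_pair(img, matrix(0L, 40, 40)), 0)

  big <- matrix(0L, 300, 300); big[100:102, 150:152] <- 1L
  cr <- ccs_sample_pair(matrix(0.5, 300, 300), big, crop_size = 10L)
  expect_length(cr, 1)
  expect_equal(dim(cr[[1]]$mask), c(10, 10))
  expect_equal(sum(cr[[1]]$mask), 9)
})

test_that("oversized components enlarge the window instead of truncating", {
  m <- matrix(0L, 60, 60)
  m[10:35, 12:20] <- 1L                        # 26 px tall > crop_size
  cr <- ccs_sample_pair(matrix(0, 60, 60), m, crop_size = 16L)
  expect_length(cr, 1)
  expect_equal(sum(cr[[1]]$mask), sum(m))
  expect_gte(cr[[1]]$window$height, 26)
})

test_that("dataset sampling preserves order, ids and every foreground pixel", {
  cfg <- tiny_synth_config(seed = 13)
  d <- generate_dataset(12, cfg)
  crops <- ccs_sample_dataset(d, crop_size = 24L)
  expect_equal(length(crops),
               sum(vapply(d, function(e) length(find_components(e$mask)), 0L)))
  expect_identical(crops, ccs_sample_dataset(d, crop_size = 24L))
  # reconstruct: every source foreground pixel appears in >= 1 crop mask
  for (e in d) {
    covered <- matrix(0L, 64, 64)
    for (cr in crops[vapply(crops, function(x) x$id, "") == e$id]) {
      w <- cr$window
      rows <- w$row:(w$row + w$height - 1); cols <- w$col:(w$col + w$width - 1)
      covered[rows, cols] <- covered[rows, cols] | cr$mask
    }
    expect_true(all(covered[e$mask == 1L] == 1L))
  }
})

test_that("mismatched image and mask shapes are rejected", {
  expect_error(ccs_sample_pair(matrix(0, 5, 5), matrix(0L, 4, 4)), "differ")
})
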