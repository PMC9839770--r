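test_that("generation is bit-reproducible from (seed, draw_index)", {
  cfg <- tiny_synth_config(seed = 9)
  a <- generate_radiograph(cfg, 3L)
  b <- generate_radiograph(cfg, 3L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  # and independent of surrounding RNG use
  set.seed(999); runif(10)
  d <- generate_radiograph(cfg, 3L)
  expect_identical(d$mask, a$mask)
})

test_that("a zero-lesion range yields an all-background mask", {
  cfg <- synthetic_config(height = 64, width = 64, lesions_range = c(0L, 0L),
                          seed = 2)
  e <- generate_radiograph(cfg, 0L)
  expect_equal(sum(e$mask), 0L)
})

test_that("default frames carry the stated foreground-fraction regime", {
  cfg <- synthetic_config(seed = 31)       # 300x300, 1-3 lesions of side ~10
  fr <- vapply(0:29, function(i) mean(generate_radiograph(cfg, i)$mask), 0)
  expect_true(all(fr >= 2e-4 & fr <= 1e-2))
})

test_that("components correspond one-to-one with placed lesions and stay small", {
  cfg <- tiny_synth_config(seed = 17)
  d <- generate_dataset(25, cfg)
  for (e in d) {
    comps <- find_components(e$mask)
    expect_gte(length(comps), 1)
    expect_lte(length(comps), 3)
    for (co in comps) {
      side <- max(co$bbox[3] - co$bbox[1], co$bbox[4] - co$bbox[2]) + 1
      expect_lte(side, 64 / 4)
      expect_gte(co$area, 4)
    }
  }
})

test_that("datasets are deterministic in n and seed", {
  cfg <- tiny_synth_config(seed = 5)
  expect_length(generate_dataset(0, cfg), 0)
  a <- generate_dataset(6, cfg)
  b <- generate_dataset(6, cfg)
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
  # first n draws are a prefix of a longer dataset
  c10 <- generate_dataset(10, cfg)
  expect_identical(c10[[4]]$image$pixels, a[[4]]$image$pixels)
})

test_that("lesion pixels are darker than their unlesioned surroundings", {
  cfg <- synthetic_config(height = 64, width = 64, noise_sd = 0, seed = 23)
  e <- generate_radiograph(cfg, 1L)
  comps <- find_components(e$mask)
  for (co in comps) {
    inside <- mean(e$image$pixels[co$pixels])
    ring <- c(max(1, co$bbox[1] - 2), max(1, co$bbox[2] - 2),
              min(64, co$bbox[3] + 2), min(64, co$bbox[4] + 2))
    box <- e$image$pixels[ring[1]:ring[3], ring[2]:ring[4]]
    boxmask <- e$mask[ring[1]:ring[3], ring[2]:ring[4]]
    expect_lt(inside, mean(box[boxmask == 0L]))
  }
})

test_that("written datasets round-trip through the image/mask loaders", {
  cfg <- tiny_synth_config(seed = 7, n = 48L)
  d <- generate_dataset(3, cfg)
  root <- withr::local_tempdir()
  man <- write_synthetic_dataset(d, root)
  expect_equal(nrow(man), 3)
  expect_equal(man$fg_pixels, vapply(d, function(e) sum(e$mask), 0L))
  back <- load_image_mask_dataset(file.path(root, "images"),
                                  file.path(root, "masks"))
  expect_length(back, 3)
  for (i in 1:3) expect_identical(back[[i]]$mask, d[[i]]$mask)
})
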