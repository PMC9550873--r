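test_that("patch probabilities refill their footprints, averaging overlaps", {
  one <- data.frame(row = 0L, col = 0L, size = 2L, probability = 0.7)
  pm <- assemble_probability_map(one, c(4, 4))
  expect_equal(pm$values[1:2, 1:2], matrix(0.7, 2, 2))
  expect_equal(sum(pm$values), 4 * 0.7)

  two <- data.frame(row = c(0L, 1L), col = c(0L, 1L), size = c(2L, 2L),
                    probability = c(0.4, 0.8))
  pm2 <- assemble_probability_map(two, c(4, 4))
  expect_equal(pm2$values[2, 2], 0.6)
  expect_equal(pm2$values[1, 1], 0.4)
  expect_equal(pm2$values[3, 3], 0.8)
  # values stay within the input probability range over covered pixels
  covered <- pm2$values[pm2$tissue_mask]
  expect_true(all(covered >= 0.4 & covered <= 0.8))

  empty <- assemble_probability_map(
    data.frame(row = integer(0), col = integer(0), size = integer(0),
               probability = numeric(0)), c(4, 4))
  expect_true(all(empty$values == 0))
})

test_that("assembly validates probabilities, footprints and tissue", {
  bad_p <- data.frame(row = 0L, col = 0L, size = 2L, probability = 1.2)
  expect_error(assemble_probability_map(bad_p, c(4, 4)), "\\[0, 1\\]")
  oob <- data.frame(row = 3L, col = 0L, size = 2L, probability = 0.5)
  expect_error(assemble_probability_map(oob, c(4, 4)), "out of bounds")
  # non-tissue pixels forced to exactly zero
  one <- data.frame(row = 0L, col = 0L, size = 4L, probability = 0.9)
  tis <- matrix(FALSE, 4, 4); tis[1:2, ] <- TRUE
  pm <- assemble_probability_map(one, c(4, 4), tissue_mask = tis)
  expect_true(all(pm$values[3:4, ] == 0))
  expect_true(all(pm$values[1:2, ] == 0.9))
})

test_that("non-overlapping round trip recovers per-patch probabilities", {
  set.seed(13)
  probs <- runif(16)
  grid <- expand.grid(col = seq(0L, 24L, 8L), row = seq(0L, 24L, 8L))
  preds <- data.frame(row = grid$row, col = grid$col, size = 8L,
                      probability = probs)
  pm <- assemble_probability_map(preds, c(32, 32))
  for (i in seq_len(16)) {
    block <- pm$values[preds$row[i] + 1:8, preds$col[i] + 1:8]
    expect_equal(mean(block), probs[i])
    expect_equal(max(block) - min(block), 0)
  }
})

test_that("rendering maps 1 to pure red, 0 to pure blue, linearly between", {
  v <- matrix(c(0, 1, 0.25, 0.5), 2, 2)
  hm <- render_heatmap(v)
  expect_equal(hm[1, 1, ], c(0, 0, 1))   # p = 0: blue
  expect_equal(hm[2, 1, ], c(1, 0, 0))   # p = 1: red
  expect_equal(hm[1, 2, ], c(0.25, 0, 0.75))
})

test_that("overlay blending is exact at the alpha extremes", {
  s <- generate_slide(synthetic_slide_spec(16, 16, seed = 3))
  v <- matrix(runif(16 * 16), 16, 16)
  expect_identical(render_overlay(v, s$image, alpha = 0), s$image)
  expect_identical(render_overlay(v, s$image, alpha = 1), render_heatmap(v))
  expect_error(render_overlay(v, s$image, alpha = 1.2), "\\[0, 1\\]")
  expect_error(render_overlay(matrix(0.5, 8, 8), s$image, alpha = 0.5),
               "match")
})

test_that("maps survive the 16-bit quantized write/read round trip", {
  dir <- withr::local_tempdir()
  pm <- assemble_probability_map(
    data.frame(row = 0L, col = 0L, size = 8L, probability = 0.437),
    c(8, 8), slide_id = "s1", downsample = 2)
  path <- file.path(dir, "map.tif")
  write_probability_map(pm, path)
  back <- read_probability_map(path)
  expect_lt(max(abs(back$values - pm$values)), 1 / 65535)
  expect_identical(back$tissue_mask, pm$tissue_mask)
  expect_identical(back$slide_id, "s1")
  expect_identical(as.numeric(back$downsample), 2)
})
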