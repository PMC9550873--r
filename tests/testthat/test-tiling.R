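test_that("tissue rule classifies white, pink and mixed patches", {
  expect_equal(tissue_fraction(white_patch(8)), 0)
  expect_equal(tissue_fraction(pink_patch(8)), 1)
  half <- white_patch(8); half[, 1:4, ] <- pink_patch(8)[, 1:4, ]
  expect_equal(tissue_fraction(half), 0.5)
})

test_that("non-overlapping tiling enumerates the full grid row-major", {
  img <- pink_patch(256)
  m <- tile_slide(img, patch_size = 64, stride = 64, slide_id = "s")
  expect_identical(nrow(m), 16L)
  expect_true(all(m$label == "UNLABELED"))
  # row-major: row changes slower than col
  expect_identical(m$row[1:5], c(0L, 0L, 0L, 0L, 64L))
  expect_identical(anyDuplicated(m[, c("row", "col")]), 0L)

  one <- tile_slide(pink_patch(64), patch_size = 64, slide_id = "s")
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$row, one$col), c(0L, 0L))
})

test_that("mask overlap at the cutoff splits malignant from non-malignant", {
  img <- pink_patch(128)
  mask <- matrix(0, 128, 128); mask[, 1:64] <- 1  # left half tumor
  m <- tile_slide(img, mask, patch_size = 64, stride = 64,
                  overlap_cutoff = 0.5, slide_id = "s")
  expect_identical(sum(m$label == "MALIGNANT"), 2L)
  expect_identical(sum(m$label == "NON_MALIGNANT"), 2L)
  expect_true(all(m$label[m$col == 0] == "MALIGNANT"))
})

test_that("labels and tissue fractions agree with a per-patch oracle", {
  s <- generate_slide(synthetic_slide_spec(64, 64, tumor_fraction = 0.5,
                                           seed = 21))
  m <- tile_slide(s$image, s$tumor_mask, patch_size = 16, stride = 16,
                  tissue_threshold = 0, slide_id = "s")
  expect_identical(nrow(m), 16L)
  for (i in seq_len(nrow(m))) {
    p <- extract_patch(s$image, m$row[i], m$col[i], 16)
    expect_equal(m$tissue_fraction[i], tissue_fraction(p))
    ov <- mean(s$tumor_mask[m$row[i] + 1:16, m$col[i] + 1:16])
    expect_identical(m$label[i],
                     if (ov >= 0.5) "MALIGNANT" else "NON_MALIGNANT")
  }
})

test_that("patches reassemble the covered region bit-exactly", {
  s <- generate_slide(synthetic_slide_spec(64, 64, tumor_fraction = 0.3,
                                           seed = 9))
  m <- tile_slide(s$image, patch_size = 16, stride = 16,
                  tissue_threshold = 0, slide_id = "s")
  rebuilt <- array(NA_real_, dim(s$image))
  for (i in seq_len(nrow(m))) {
    ri <- m$row[i] + 1:16; ci <- m$col[i] + 1:16
    rebuilt[ri, ci, ] <- extract_patch(s$image, m$row[i], m$col[i], 16)
  }
  expect_identical(rebuilt, s$image)
})

test_that("degenerate tiling inputs warn or error as contracted", {
  expect_warning(m <- tile_slide(pink_patch(16), patch_size = 32),
                 "smaller than patch_size")
  expect_identical(nrow(m), 0L)
  expect_error(tile_slide(pink_patch(32), patch_size = 32, stride = 0),
               "stride")
  expect_error(tile_slide(pink_patch(32), patch_size = 0), "patch_size")
  expect_error(tile_slide(pink_patch(64), mask = matrix(0, 8, 8),
                          patch_size = 32), "dimensions")
})

test_that("manifest summaries add up, including the dataset-scale partition", {
  # archive-scale four-way split: pre-aggregated counts must reproduce the total
  partition <- data.frame(
    split = c("pretrain", "train", "val", "test"),
    label = "ALL",
    n = c(422168, 69807, 1973, 30359))
  s <- summarize_manifest(partition)
  expect_identical(attr(s, "total"), 524307)

  expect_identical(attr(summarize_manifest(list()), "total"), 0)

  m <- tile_slide(pink_patch(128), patch_size = 32, slide_id = "s")
  m$split <- rep(c("train", "test"), c(12, 4))
  s2 <- summarize_manifest(m)
  expect_identical(attr(s2, "total"), 16)
  expect_identical(sum(s2$n[s2$split == "train"]), 12)
})
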