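test_that("identical specs produce bit-identical slides", {
  sp <- synthetic_slide_spec(96, 96, tumor_fraction = 0.3, seed = 11)
  a <- generate_slide(sp)
  b <- generate_slide(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$tumor_mask, b$tumor_mask)
  expect_identical(a$tissue_mask, b$tissue_mask)
})

test_that("tumor_fraction zero gives an empty tumor mask and NM label", {
  s <- generate_slide(synthetic_slide_spec(64, 64, tumor_fraction = 0, seed = 3))
  expect_false(any(s$tumor_mask))
  expect_identical(s$label, "NM")
})

test_that("masks are contained and intensities are ordered on every seed", {
  for (seed in 1:6) {
    s <- generate_slide(synthetic_slide_spec(96, 96, tumor_fraction = 0.4,
                                             seed = seed))
    expect_true(all(!s$tumor_mask | s$tissue_mask))
    expect_identical(dim(s$image)[1:2], dim(s$tumor_mask))
    expect_identical(s$label, if (any(s$tumor_mask)) "MM" else "NM")
    normal <- s$tissue_mask & !s$tumor_mask
    m3 <- function(m) mean(s$image[array(m, dim(s$image))])
    expect_lt(m3(s$tumor_mask), m3(normal))
    expect_lt(m3(normal), m3(!s$tissue_mask))
  }
})

test_that("achieved tumor fraction tracks the request within 0.1", {
  for (seed in 1:20) {
    s <- generate_slide(synthetic_slide_spec(256, 256, tumor_fraction = 0.3,
                                             n_tumor_blobs = 3, seed = seed))
    achieved <- sum(s$tumor_mask) / sum(s$tissue_mask)
    expect_lt(abs(achieved - 0.3), 0.1)
  }
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_slide_spec(0, 64), "positive")
  expect_error(synthetic_slide_spec(64, -1), "positive")
  expect_error(synthetic_slide_spec(64, 64, tumor_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_slide_spec(64, 64, nuclei_density_normal = -2),
               "non-negative")
})

test_that("generate_dataset honors counts, splits and determinism", {
  tmpl <- synthetic_slide_spec(64, 64, tumor_fraction = 0.4)
  empty <- generate_dataset(0, 0, 0, tmpl, seed = 1)
  expect_identical(nrow(empty$manifest), 0L)

  ds <- generate_dataset(4, 2, 2, tmpl, seed = 7)
  expect_identical(nrow(ds$manifest), 8L)
  expect_identical(sum(ds$manifest$split == "pretrain"), 4L)
  expect_true(all(is.na(ds$manifest$label[ds$manifest$split == "pretrain"])))
  expect_identical(sum(ds$manifest$label == "MM", na.rm = TRUE), 2L)
  # labeled slides keep exact masks; MM slides actually contain tumor
  for (id in ds$manifest$slide_id[which(ds$manifest$label == "MM")])
    expect_true(any(ds$slides[[id]]$tumor_mask))

  ds2 <- generate_dataset(4, 2, 2, tmpl, seed = 7)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$slides[[1]]$image, ds2$slides[[1]]$image)

  expect_error(generate_dataset(-1, 0, 0, tmpl), "non-negative")
})

test_that("written datasets round-trip through PNG and CSV", {
  dir <- withr::local_tempdir()
  tmpl <- synthetic_slide_spec(64, 64, tumor_fraction = 0.4)
  ds <- generate_dataset(1, 1, 1, tmpl, seed = 5, dir = dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 3L)
  expect_true(all(file.exists(man$path)))
  id <- man$slide_id[man$label == "MM" & !is.na(man$label)]
  img <- png::readPNG(file.path(dir, paste0(id, ".png")))
  expect_equal(dim(img), c(64, 64, 3))
  mask <- png::readPNG(file.path(dir, paste0(id, "_mask.png"))) > 0.5
  expect_identical(mask, ds$slides[[id]]$tumor_mask)
})
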