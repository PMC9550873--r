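test_that("binarization follows the >= threshold rule exactly", {
  v <- matrix(c(0.5, 0.49, 0, 1), 2, 2)
  m <- binarize(v, 0.5)
  expect_identical(m[1, 1], 255L)
  expect_identical(m[2, 1], 0L)
  expect_identical(m[2, 2], 255L)
  expect_true(all(unclass(m) %in% c(0L, 255L)))
  expect_true(all(unclass(binarize(matrix(0, 3, 3))) == 0L))
  expect_error(binarize(v, 1.5), "\\[0, 1\\]")
  for (seed in 1:3) {
    v <- random_blob_map(20, 20, 3, seed)
    expect_true(all(unclass(binarize(v)) %in% c(0L, 255L)))
  }
})

test_that("a solid square has the textbook region properties", {
  v <- matrix(0, 30, 30); v[11:20, 6:15] <- 1
  r <- find_regions(binarize(v), v)
  expect_identical(nrow(r), 1L)
  expect_equal(r$area, 100)
  expect_equal(r$perimeter, 40)
  expect_equal(r$solidity, 1)
  expect_equal(r$eccentricity, 0)
  expect_equal(r$mean_probability, 1)
  expect_equal(r$major_axis_length, 4 * sqrt(mean((0:9 - 4.5)^2)))
})

test_that("connectivity is 8-way and empty masks give empty results", {
  d <- matrix(0, 4, 4); d[1, 1] <- 1; d[2, 2] <- 1
  expect_identical(nrow(find_regions(binarize(d))), 1L)
  four <- matrix(0, 4, 4); four[1, 1] <- 1; four[1, 3] <- 1
  expect_identical(nrow(find_regions(binarize(four))), 2L)
  expect_identical(nrow(find_regions(binarize(matrix(0, 4, 4)))), 0L)
  expect_error(find_regions(binarize(matrix(0, 4, 4)), matrix(0, 3, 3)),
               "match")
})

test_that("region properties match the brute-force oracle on random masks", {
  for (seed in 1:6) {
    v <- random_blob_map(40, 40, 4, seed)
    reg <- find_regions(binarize(v), v)
    orc <- oracle_regions(v >= 0.5, v)
    expect_identical(nrow(reg), length(orc))
    # order-free comparison keyed by area then perimeter
    key <- function(a, p) order(a, p)
    io <- key(reg$area, reg$perimeter)
    oo <- key(sapply(orc, `[[`, "area"), sapply(orc, `[[`, "perimeter"))
    for (f in c("area", "perimeter", "major_axis_length", "eccentricity",
                "solidity", "mean_probability")) {
      expect_equal(reg[[f]][io], sapply(orc, `[[`, f)[oo],
                   tolerance = 1e-9, label = paste(f, "seed", seed))
    }
  }
})

test_that("the 31-entry summary matches the oracle entry by entry", {
  # worked example: one unit-probability 10x10 block in a 100x100 tissue map
  v <- matrix(0, 100, 100); v[41:50, 41:50] <- 1
  fv <- extract_features(v)
  expect_identical(length(fv), 31L)
  expect_identical(names(fv), feature_schema())
  expect_equal(unname(fv), oracle_features(v), tolerance = 1e-9)
  expect_equal(unname(fv["n_regions"]), 1)
  expect_equal(unname(fv["tumor_to_tissue_ratio"]), 0.01)
  expect_equal(unname(fv["largest_region_area"]), 100)
  expect_equal(unname(fv["positive_pixel_count"]), 100)
  expect_equal(unname(fv["region_area_mean"]), 100)
  expect_equal(unname(fv[c("region_area_variance", "region_area_skewness",
                           "region_area_kurtosis")]), c(0, 0, 0))

  for (seed in 7:12) {
    v <- random_blob_map(48, 48, 5, seed)
    expect_equal(unname(extract_features(v)), oracle_features(v),
                 tolerance = 1e-9, label = paste("map seed", seed))
  }
})

test_that("features are translation invariant and monotone under new regions", {
  v <- matrix(0, 60, 60); v[6:13, 6:17] <- 0.9; v[7, 7] <- 0.6
  shifted <- matrix(0, 60, 60); shifted[26:33, 36:47] <- 0.9; shifted[27, 37] <- 0.6
  expect_equal(extract_features(v), extract_features(shifted),
               tolerance = 1e-12)
  with_extra <- v; with_extra[40:44, 40:44] <- 1
  a <- extract_features(v); b <- extract_features(with_extra)
  expect_gt(b["n_regions"], a["n_regions"])
  expect_gt(b["positive_pixel_count"], a["positive_pixel_count"])
  expect_gt(b["tumor_to_tissue_ratio"], a["tumor_to_tissue_ratio"])
})

test_that("edge cases: empty map, empty tissue, downsample correction", {
  z <- extract_features(matrix(0, 10, 10))
  expect_identical(length(z), 31L)
  expect_true(all(z == 0))
  v <- matrix(1, 4, 4)
  expect_error(extract_features(v, tissue_mask = matrix(FALSE, 4, 4)),
               "tissue mask is empty")
  # a downsampled map reports areas x factor^2 and lengths x factor
  pm <- assemble_probability_map(
    data.frame(row = 1L, col = 1L, size = 4L, probability = 1),
    c(8, 8), tissue_mask = matrix(TRUE, 8, 8), downsample = 4)
  fv <- extract_features(pm)
  expect_equal(unname(fv["largest_region_area"]), 16 * 16)
  expect_equal(unname(fv["region_perimeter_mean"]), 16 * 4)
  expect_equal(unname(fv["largest_region_major_axis"]),
               4 * 4 * sqrt(mean((0:3 - 1.5)^2)))
  expect_equal(unname(fv["tumor_to_tissue_ratio"]), 16 / 64)
})
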