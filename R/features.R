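# Morphological summarization of a probability map: threshold to a binary
# mask, find 8-connected tumor regions, and compute the fixed 31-feature
# vector used for slide-level classification.
#
# Conventions (fixed so an exact oracle exists): 8-connected components;
# perimeter = number of unit edges between a region pixel and a
# non-region/outside pixel; ellipse axes/eccentricity from second central
# moments of pixel centers; solidity = area / area of the convex hull of
# the pixel squares; population variance, Fisher skewness, excess kurtosis,
# with 0 where the list is too short for the statistic to be defined.

#' Threshold a probability map into a 0/255 binary mask
#'
#' Pixels with value greater than or equal to the threshold become 255,
#' all others 0.
#'
#' @param map a `"probability_map"` or a numeric matrix in `[0, 1]`.
#' @param threshold threshold in `[0, 1]` (default 0.5).
#' @return Integer matrix over `{0, 255}` of class `"binary_mask"`, with
#'   the threshold stored as an attribute.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop_invalid("threshold must be a scalar in [0, 1]")
  v <- if (inherits(map, "probability_map")) map$values else map
  check_probability(v, "map values")
  m <- matrix(ifelse(v >= threshold, 255L, 0L), nrow(v), ncol(v))
  structure(m, class = "binary_mask", threshold = threshold)
}

# 8-connected labeling of the foreground of a logical matrix. Components
# come from the pixel-adjacency graph (igraph); labels are renumbered in
# first-encounter (column-major) order so output is deterministic.
label_components8 <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  nfg <- sum(fg)
  lab <- matrix(0L, H, W)
  if (nfg == 0L) return(lab)
  vid <- matrix(0L, H, W)
  vid[fg] <- seq_len(nfg)
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- 1L:(H - dr)
    c1 <- if (dc >= 0L) 1L:(W - dc) else (1L - dc):W
    a <- vid[r1, c1, drop = FALSE]
    b <- vid[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- rbind(a[sel], b[sel])
  }
  memb <- if (length(edges) == 0L) seq_len(nfg) else {
    g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                            n = nfg, directed = FALSE)
    igraph::components(g)$membership
  }
  first_seen <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first_seen]] <- seq_len(sum(first_seen))
  lab[fg] <- renum[memb]
  lab
}

# Shoelace area of the convex hull of the pixel *squares* of the given
# pixel centers (each pixel contributes its four corners).
hull_area_pixels <- function(r, c) {
  pr <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pc <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  h <- grDevices::chull(pc, pr)
  x <- pc[h]; y <- pr[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Find connected tumor regions of a binary mask
#'
#' Labels the 8-connected components of the 255-valued pixels and computes
#' per-region properties under the package's fixed conventions (see the
#' comments at the top of this file).
#'
#' @param mask a [binarize()] result (or 0/255 matrix).
#' @param map optional source `"probability_map"` (or matrix) with matching
#'   dimensions; when given, each region's `mean_probability` is the mean
#'   map value over its pixels.
#' @return A data.frame with one row per region: `region`, `area`,
#'   `perimeter`, `major_axis_length`, `eccentricity`, `solidity`,
#'   `mean_probability`; the label matrix is attached as attribute
#'   `"labels"`.
#' @export
find_regions <- function(mask, map = NULL) {
  fg <- unclass(mask) != 0
  vals <- NULL
  if (!is.null(map)) {
    vals <- if (inherits(map, "probability_map")) map$values else map
    if (!all(dim(vals) == dim(fg)))
      stop_invalid("map dimensions must match the mask")
  }
  lab <- label_components8(fg)
  k <- max(lab)
  if (k == 0L) {
    out <- data.frame(region = integer(0), area = numeric(0),
                      perimeter = numeric(0), major_axis_length = numeric(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      mean_probability = numeric(0))
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  H <- nrow(fg)
  r <- ((idx - 1L) %% H) + 1L
  c0 <- ((idx - 1L) %/% H) + 1L

  area <- as.vector(rowsum(rep(1, length(l)), l))

  # Unit-edge perimeter: distinct regions are never 4-adjacent under
  # 8-connectivity, so boundary edges are exactly edges to background or to
  # the outside of the grid.
  fgp <- matrix(FALSE, H + 2L, ncol(fg) + 2L)
  fgp[2:(H + 1L), 2:(ncol(fg) + 1L)] <- fg
  ri <- r + 1L; ci <- c0 + 1L
  nb <- (!fgp[cbind(ri - 1L, ci)]) + (!fgp[cbind(ri + 1L, ci)]) +
        (!fgp[cbind(ri, ci - 1L)]) + (!fgp[cbind(ri, ci + 1L)])
  perim <- as.vector(rowsum(as.numeric(nb), l))

  mr <- as.vector(rowsum(r, l)) / area
  mc <- as.vector(rowsum(c0, l)) / area
  mrr <- as.vector(rowsum(r^2, l)) / area - mr^2
  mcc <- as.vector(rowsum(c0^2, l)) / area - mc^2
  mrc <- as.vector(rowsum(r * c0, l)) / area - mr * mc
  tr2 <- (mrr + mcc) / 2
  d <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
  l1 <- tr2 + d; l2 <- pmax(tr2 - d, 0)
  major <- 4 * sqrt(pmax(l1, 0))
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)

  solidity <- vapply(seq_len(k), function(i) {
    sel <- l == i
    area[i] / hull_area_pixels(r[sel], c0[sel])
  }, numeric(1))

  mean_prob <- if (is.null(vals)) rep(NA_real_, k)
               else as.vector(rowsum(vals[idx], l)) / area

  out <- data.frame(region = seq_len(k), area = area, perimeter = perim,
                    major_axis_length = major, eccentricity = ecc,
                    solidity = pmin(solidity, 1), mean_probability = mean_prob)
  attr(out, "labels") <- lab
  out
}

# max / mean / population variance / Fisher skewness / excess kurtosis,
# with 0 where the statistic is undefined (short list or zero variance).
stat5 <- function(x) {
  n <- length(x)
  if (n == 0L) return(c(max = 0, mean = 0, variance = 0,
                        skewness = 0, kurtosis = 0))
  m <- mean(x); m2 <- mean((x - m)^2)
  c(max = max(x), mean = m,
    variance = if (n < 2L) 0 else m2,
    skewness = if (n < 3L || m2 == 0) 0 else mean((x - m)^3) / m2^1.5,
    kurtosis = if (n < 4L || m2 == 0) 0 else mean((x - m)^4) / m2^2 - 3)
}

#' Names of the 31 heatmap features, in fixed order
#'
#' @return Character vector of length 31.
#' @export
feature_schema <- function() {
  c("n_regions", "tumor_to_tissue_ratio", "largest_region_area",
    "largest_region_major_axis", "largest_region_mean_probability",
    "positive_pixel_count",
    paste0("pixel_prob_", c("max", "mean", "variance", "skewness", "kurtosis")),
    paste0("region_area_", c("max", "mean", "variance", "skewness", "kurtosis")),
    paste0("region_perimeter_", c("max", "mean", "variance", "skewness", "kurtosis")),
    paste0("region_eccentricity_", c("max", "mean", "variance", "skewness", "kurtosis")),
    paste0("region_solidity_", c("max", "mean", "variance", "skewness", "kurtosis")))
}

#' Compute the 31-feature morphological summary of a probability map
#'
#' Thresholds the map (unless a mask is supplied), finds 8-connected tumor
#' regions, and returns the fixed-order feature vector: region count,
#' tumor-to-tissue area ratio, largest-region descriptors, positive pixel
#' count, and five-number statistics (max, mean, variance, skewness,
#' kurtosis) of per-pixel probabilities, region areas, perimeters,
#' eccentricities and solidities. When the map object carries a
#' `downsample` factor, areas are corrected by its square and lengths by
#' the factor. All entries are 0 when no region exists.
#'
#' @param map a `"probability_map"` or numeric matrix in `[0, 1]`.
#' @param mask optional precomputed [binarize()] mask.
#' @param tissue_mask optional logical matrix; defaults to the map's own
#'   tissue mask (or all pixels for a bare matrix).
#' @param threshold binarization threshold used when `mask` is missing.
#' @return Named numeric vector of length 31 (see [feature_schema()]).
#' @export
extract_features <- function(map, mask = NULL, tissue_mask = NULL,
                             threshold = 0.5) {
  is_pm <- inherits(map, "probability_map")
  vals <- if (is_pm) map$values else map
  dsf <- if (is_pm) map$downsample else 1
  if (is.null(tissue_mask))
    tissue_mask <- if (is_pm) map$tissue_mask
                   else matrix(TRUE, nrow(vals), ncol(vals))
  if (is.null(mask)) mask <- binarize(vals, threshold)
  if (!all(dim(unclass(mask)) == dim(vals)))
    stop_invalid("mask dimensions must match the map")

  out <- stats::setNames(numeric(31L), feature_schema())
  fg <- unclass(mask) != 0
  npos <- sum(fg)
  if (npos == 0L) return(out)
  n_tissue <- sum(tissue_mask != 0)
  if (n_tissue == 0L)
    stop_invalid("tumor pixels present but tissue mask is empty")

  reg <- find_regions(mask, vals)
  areas <- reg$area * dsf^2
  perims <- reg$perimeter * dsf
  big <- which.max(reg$area)

  out["n_regions"] <- nrow(reg)
  out["tumor_to_tissue_ratio"] <- npos / n_tissue
  out["largest_region_area"] <- areas[big]
  out["largest_region_major_axis"] <- reg$major_axis_length[big] * dsf
  out["largest_region_mean_probability"] <- reg$mean_probability[big]
  out["positive_pixel_count"] <- npos * dsf^2
  out[7:11] <- stat5(vals[fg])
  out[12:16] <- stat5(areas)
  out[17:21] <- stat5(perims)
  out[22:26] <- stat5(reg$eccentricity)
  out[27:31] <- stat5(reg$solidity)
  out
}
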