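# Window-sliding decomposition of a slide into fixed-size square patches,
# with background filtering and patch labeling from an annotation mask.
# Coordinates are 0-based, row-major; a patch footprint is the half-open
# block [row, row+size) x [col, col+size).

#' Classify pixels of an RGB image as tissue
#'
#' A pixel counts as tissue when its RGB mean is below 220/255 (not
#' near-white) or its HSV saturation exceeds 0.07. This is the usual cheap
#' background filter for slide images with a bright background.
#'
#' @param image RGB array `(H, W, 3)` with values in `[0, 1]`.
#' @return Logical `(H, W)` matrix, `TRUE` for tissue pixels.
#' @export
tissue_pixels <- function(image) {
  image <- as_image(image)
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  mean_rgb <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  mean_rgb < 220 / 255 | sat > 0.07
}

#' Fraction of tissue pixels in a patch
#'
#' @param patch_pixels RGB patch array.
#' @return Fraction of pixels classified as tissue, in `[0, 1]`.
#' @export
tissue_fraction <- function(patch_pixels) {
  mean(tissue_pixels(patch_pixels))
}

# Summed-area table supporting O(1) block sums; returns a closure over
# half-open 0-based blocks.
block_sums <- function(m) {
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S, deparse.level = 0))
  function(r0, c0, size) {
    S[cbind(r0 + size + 1L, c0 + size + 1L)] -
      S[cbind(r0 + 1L, c0 + size + 1L)] -
      S[cbind(r0 + size + 1L, c0 + 1L)] +
      S[cbind(r0 + 1L, c0 + 1L)]
  }
}

#' Cut a slide into a manifest of fixed-size patches
#'
#' Enumerates patches row-major over the grid `{0, stride, 2*stride, ...}`
#' wherever the full square footprint fits, drops patches whose tissue
#' fraction is below `tissue_threshold`, and assigns labels from an
#' optional annotation mask: `MALIGNANT` when at least `overlap_cutoff` of
#' the footprint overlaps the mask, else `NON_MALIGNANT`; `UNLABELED` when
#' no mask is supplied.
#'
#' @param image RGB slide array `(H, W, 3)` in `[0, 1]`.
#' @param mask optional logical/0-1 tumor annotation matrix `(H, W)`.
#' @param patch_size square patch side in pixels (default 256).
#' @param stride grid step in pixels, `1 <= stride <= patch_size`
#'   (default `patch_size`: non-overlapping).
#' @param tissue_threshold minimum tissue fraction to keep a patch.
#' @param overlap_cutoff mask-overlap fraction at which a patch is labeled
#'   malignant (default 0.5).
#' @param slide_id identifier recorded in the manifest.
#' @return A `tile_manifest`: data.frame with columns `slide_id`, `row`,
#'   `col`, `size`, `label`, `tissue_fraction`, plus attributes
#'   `slide_dims`, `patch_size`, `stride`. An image smaller than
#'   `patch_size` yields an empty manifest with a warning.
#' @export
tile_slide <- function(image, mask = NULL, patch_size = 256L,
                       stride = patch_size, tissue_threshold = 0.1,
                       overlap_cutoff = 0.5, slide_id = "slide") {
  image <- as_image(image)
  if (patch_size < 1L) stop_invalid("patch_size must be >= 1")
  if (stride < 1L) stop_invalid("stride must be >= 1")
  if (stride > patch_size) stop_invalid("stride must not exceed patch_size")
  H <- dim(image)[1]; W <- dim(image)[2]
  empty <- function() {
    structure(data.frame(slide_id = character(0), row = integer(0),
                         col = integer(0), size = integer(0),
                         label = character(0), tissue_fraction = numeric(0)),
              class = c("tile_manifest", "data.frame"),
              slide_dims = c(H, W), patch_size = patch_size, stride = stride)
  }
  if (H < patch_size || W < patch_size) {
    warning("image (", H, "x", W, ") smaller than patch_size ", patch_size,
            "; returning an empty manifest")
    return(empty())
  }
  rows0 <- seq(0L, H - patch_size, by = stride)
  cols0 <- seq(0L, W - patch_size, by = stride)
  grid <- expand.grid(col = cols0, row = rows0)  # row-major order
  grid <- grid[, c("row", "col")]

  tsum <- block_sums(tissue_pixels(image) * 1)
  tf <- tsum(grid$row, grid$col, patch_size) / patch_size^2

  if (!is.null(mask)) {
    if (!all(dim(mask)[1:2] == c(H, W)))
      stop_invalid("mask dimensions must match the image")
    msum <- block_sums((mask != 0) * 1)
    ov <- msum(grid$row, grid$col, patch_size) / patch_size^2
    label <- ifelse(ov >= overlap_cutoff, "MALIGNANT", "NON_MALIGNANT")
  } else {
    label <- rep("UNLABELED", nrow(grid))
  }

  keep <- tf >= tissue_threshold
  out <- data.frame(slide_id = slide_id, row = as.integer(grid$row[keep]),
                    col = as.integer(grid$col[keep]),
                    size = as.integer(patch_size),
                    label = label[keep], tissue_fraction = tf[keep])
  rownames(out) <- NULL
  structure(out, class = c("tile_manifest", "data.frame"),
            slide_dims = c(H, W), patch_size = patch_size, stride = stride)
}

#' Extract one patch from a slide image
#'
#' @param image RGB slide array.
#' @param row,col 0-based top-left corner of the patch.
#' @param size square patch side in pixels.
#' @return The `(size, size, 3)` patch array.
#' @export
extract_patch <- function(image, row, col, size) {
  image <- as_image(image)
  if (row < 0 || col < 0 || row + size > dim(image)[1] ||
      col + size > dim(image)[2])
    stop_invalid("patch footprint out of bounds")
  image[(row + 1L):(row + size), (col + 1L):(col + size), , drop = FALSE]
}

# Stack all manifest patches of one slide into an (N, size, size, 3) array.
manifest_patches <- function(image, manifest) {
  if (nrow(manifest) == 0L) stop_invalid("empty manifest")
  size <- manifest$size[1]
  out <- array(0, c(nrow(manifest), size, size, 3L))
  for (i in seq_len(nrow(manifest)))
    out[i, , , ] <- extract_patch(image, manifest$row[i], manifest$col[i], size)
  out
}

#' Tabulate patch counts by split and label
#'
#' Accepts one manifest, a list of manifests, or any data.frame with
#' `label` and optional `split` / `n` columns (`n` gives pre-aggregated
#' counts; rows without it count once each).
#'
#' @param manifests manifest(s) to tabulate.
#' @return A data.frame with columns `split`, `label`, `n`, one row per
#'   combination, with attribute `total` equal to `sum(n)` (also shown by
#'   the print method). The grand total always equals the sum of the
#'   per-split, per-label counts.
#' @export
summarize_manifest <- function(manifests) {
  if (is.data.frame(manifests)) manifests <- list(manifests)
  if (length(manifests) == 0L)
    manifests <- list(data.frame(label = character(0)))
  rows <- lapply(manifests, function(m) {
    m <- as.data.frame(m)
    data.frame(
      split = if ("split" %in% names(m)) as.character(m$split)
              else rep("all", nrow(m)),
      label = if ("label" %in% names(m)) as.character(m$label)
              else rep("UNLABELED", nrow(m)),
      n = if ("n" %in% names(m)) as.numeric(m$n) else rep(1, nrow(m)))
  })
  long <- do.call(rbind, rows)
  if (nrow(long) == 0L) {
    out <- data.frame(split = character(0), label = character(0),
                      n = numeric(0))
  } else {
    out <- stats::aggregate(n ~ split + label, data = long, FUN = sum)
    out <- out[order(out$split, out$label), ]
    rownames(out) <- NULL
  }
  structure(out, total = sum(out$n), class = c("manifest_summary",
                                               "data.frame"))
}

#' @export
print.manifest_summary <- function(x, ...) {
  print.data.frame(x, ...)
  cat("Total patches:", format(attr(x, "total"), big.mark = ","), "\n")
  invisible(x)
}
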