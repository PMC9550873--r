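# Assembly of patch-level malignancy probabilities into a slide-aligned
# single-channel probability map, and its red-blue rendering / overlay.

#' Assemble a slide probability map from patch predictions
#'
#' Each pixel of the map becomes the arithmetic mean of the probabilities
#' of all patch footprints covering it (patches replicate their probability
#' over their footprint); pixels covered by no patch are 0. When a tissue
#' mask is supplied, non-tissue pixels are forced to exactly 0.
#'
#' @param predictions data.frame with columns `row`, `col`, `size`,
#'   `probability` (0-based top-left corners, probabilities in `[0, 1]`).
#' @param slide_dims integer `c(H, W)` of the slide (at the map's scale).
#' @param tissue_mask optional logical `(H, W)` matrix; when omitted, the
#'   covered area is taken as tissue.
#' @param slide_id identifier stored in the map.
#' @param downsample scale factor of the map relative to the native slide
#'   (recorded so area/length features can be scale-corrected downstream).
#' @return An object of class `"probability_map"`: `values` (`H x W` in
#'   `[0, 1]`), `tissue_mask`, `slide_id`, `downsample`.
#' @export
assemble_probability_map <- function(predictions, slide_dims,
                                     tissue_mask = NULL, slide_id = "slide",
                                     downsample = 1) {
  H <- slide_dims[1]; W <- slide_dims[2]
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  if (nrow(predictions) > 0L) {
    check_probability(predictions$probability)
    for (i in seq_len(nrow(predictions))) {
      r <- predictions$row[i]; c0 <- predictions$col[i]
      s <- predictions$size[i]
      if (r < 0 || c0 < 0 || r + s > H || c0 + s > W)
        stop_invalid("patch footprint out of bounds at row ", r, ", col ", c0)
      ri <- (r + 1L):(r + s); ci <- (c0 + 1L):(c0 + s)
      acc[ri, ci] <- acc[ri, ci] + predictions$probability[i]
      cnt[ri, ci] <- cnt[ri, ci] + 1L
    }
  }
  vals <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0)
  if (is.null(tissue_mask)) tissue_mask <- cnt > 0L
  else {
    if (!all(dim(tissue_mask) == c(H, W)))
      stop_invalid("tissue_mask dimensions must match slide_dims")
    tissue_mask <- tissue_mask != 0
    vals[!tissue_mask] <- 0
  }
  structure(list(values = vals, tissue_mask = tissue_mask,
                 slide_id = slide_id, downsample = downsample),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("Probability map ", x$slide_id, ": ", nrow(x$values), "x",
      ncol(x$values), ", downsample ", x$downsample, ", max p = ",
      signif(max(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Render a probability map as a blue-to-red heatmap
#'
#' Linear colormap: probability 0 is pure blue, 1 is pure red (higher
#' malignancy shows hotter).
#'
#' @param map a [assemble_probability_map()] result or a plain `[0,1]`
#'   matrix.
#' @return RGB array `(H, W, 3)` in `[0, 1]`.
#' @export
render_heatmap <- function(map) {
  v <- if (inherits(map, "probability_map")) map$values else map
  check_probability(v, "map values")
  array(c(v, matrix(0, nrow(v), ncol(v)), 1 - v), c(dim(v), 3L))
}

#' Alpha-blend a rendered heatmap over the slide image
#'
#' @param map probability map (or matrix) for the slide.
#' @param slide_image RGB slide array with matching height/width.
#' @param alpha blend weight of the heatmap in `[0, 1]`; 0 returns the
#'   slide unchanged, 1 the pure heatmap.
#' @return RGB array `(H, W, 3)`.
#' @export
render_overlay <- function(map, slide_image, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop_invalid("alpha must be a scalar in [0, 1]")
  hm <- render_heatmap(map)
  slide_image <- as_image(slide_image)
  if (!all(dim(hm) == dim(slide_image)))
    stop_invalid("slide image dimensions must match the map")
  (1 - alpha) * slide_image + alpha * hm
}

#' Write / read a probability map as a 16-bit TIFF with a JSON sidecar
#'
#' Values are quantized to `round(65535 * p) / 65535`; the sidecar records
#' `slide_id` and `downsample`, and the tissue mask goes to a companion
#' single-channel PNG.
#'
#' @param map a `"probability_map"`.
#' @param path output TIFF path (sidecar at `<path>.json`, mask at
#'   `<path>_tissue.png`).
#' @return `write_probability_map()`: the path, invisibly;
#'   `read_probability_map()`: the restored `"probability_map"`.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  tiff::writeTIFF(map$values, path, bits.per.sample = 16L)
  png::writePNG(map$tissue_mask * 1, paste0(path, "_tissue.png"))
  jsonlite::write_json(list(slide_id = map$slide_id,
                            downsample = map$downsample),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vals <- tiff::readTIFF(path)
  mask <- png::readPNG(paste0(path, "_tissue.png")) > 0.5
  structure(list(values = vals, tissue_mask = mask,
                 slide_id = meta$slide_id, downsample = meta$downsample),
            class = "probability_map")
}
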