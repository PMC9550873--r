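# The two augmentation distributions used for self-supervised pretraining:
# T  — random horizontal flip;
# T' — random horizontal flip followed by Gaussian blur.

#' Augmentation distribution specification
#'
#' @param distribution `"T"` (random horizontal flip) or `"T_PRIME"`
#'   (random horizontal flip, then Gaussian blur with sigma drawn uniformly
#'   from `blur_sigma_range`).
#' @param flip_probability probability of the horizontal flip, in `[0, 1]`.
#' @param blur_sigma_range length-2 numeric, blur sigma bounds in pixels
#'   (ignored for `"T"`). Both bounds must be non-negative.
#' @param seed optional integer; when given, [augment()] draws its random
#'   choices under this seed without disturbing the caller's RNG stream.
#' @return An object of class `"augmentation_spec"`.
#' @export
augmentation_spec <- function(distribution = c("T", "T_PRIME"),
                              flip_probability = 0.5,
                              blur_sigma_range = c(0.1, 2),
                              seed = NULL) {
  distribution <- match.arg(distribution)
  check_probability(flip_probability, "flip_probability")
  if (length(blur_sigma_range) != 2L || any(blur_sigma_range < 0))
    stop_invalid("blur_sigma_range must be two non-negative values")
  if (blur_sigma_range[1] > blur_sigma_range[2])
    stop_invalid("blur_sigma_range must be increasing")
  structure(list(distribution = distribution,
                 flip_probability = flip_probability,
                 blur_sigma_range = blur_sigma_range,
                 seed = seed),
            class = "augmentation_spec")
}

#' Flip an image horizontally
#'
#' @param image RGB array `(H, W, 3)` or matrix.
#' @return The mirrored image.
#' @export
hflip <- function(image) {
  if (is.matrix(image)) image[, rev(seq_len(ncol(image))), drop = FALSE]
  else image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
}

# 1-D Gaussian kernel, truncated at 3 sigma and renormalized to sum 1 so
# blurring conserves total intensity away from borders.
gaussian_kernel1d <- function(sigma) {
  if (sigma < 0) stop_invalid("sigma must be non-negative")
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable blur of one channel matrix with reflect padding.
blur_matrix <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  ridx <- c(pmin(r:1 + 1L, H), 1:H, pmax(H - seq_len(r), 1L))
  out <- matrix(0, H, W)
  pad <- m[ridx, , drop = FALSE]
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + H - 1L), , drop = FALSE]
  cidx <- c(pmin(r:1 + 1L, W), 1:W, pmax(W - seq_len(r), 1L))
  pad <- out[, cidx, drop = FALSE]
  out2 <- matrix(0, H, W)
  for (i in seq_along(k)) out2 <- out2 + k[i] * pad[, i:(i + W - 1L), drop = FALSE]
  out2
}

#' Gaussian blur of an RGB image
#'
#' Separable convolution with a 3-sigma-truncated, renormalized Gaussian
#' kernel and reflect padding, so a centered impulse keeps its total mass.
#'
#' @param image RGB array `(H, W, 3)` or a single-channel matrix.
#' @param sigma standard deviation in pixels; `0` is the identity.
#' @return Blurred image of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  k <- gaussian_kernel1d(sigma)
  if (is.matrix(image)) return(blur_matrix(image, k))
  for (ch in seq_len(dim(image)[3]))
    image[, , ch] <- blur_matrix(image[, , ch], k)
  image
}

#' Draw an augmented view of an image
#'
#' Applies the spec's distribution: `T` flips horizontally with
#' `flip_probability`; `T_PRIME` does the same and then blurs with a sigma
#' drawn uniformly from `blur_sigma_range`.
#'
#' @param image RGB array `(H, W, 3)`.
#' @param spec an [augmentation_spec()].
#' @return The augmented image (same dimensions as the input).
#' @export
augment <- function(image, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  with_seed(spec$seed, {
    if (stats::runif(1) < spec$flip_probability) image <- hflip(image)
    if (spec$distribution == "T_PRIME") {
      sigma <- stats::runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
      image <- gaussian_blur(image, sigma)
    }
    image
  })
}
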