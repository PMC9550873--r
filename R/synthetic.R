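# Seeded generator of histology-like slides with exact ground-truth masks.
# Slides are white-background images carrying pink-textured "tissue" blobs
# sprinkled with dark elliptical nuclei; "tumor" blobs inside the tissue are
# darker purple with a higher nuclear density. The generator is the stand-in
# dataset that makes the whole pipeline testable without real slides.

#' Specification of one synthetic slide
#'
#' @param width,height slide dimensions in pixels (positive).
#' @param tumor_fraction requested tumor area as a fraction of tissue area,
#'   in `[0, 1]`.
#' @param n_tissue_blobs,n_tumor_blobs numbers of elliptical blobs.
#' @param nuclei_density_normal,nuclei_density_tumor expected nuclei per
#'   100x100 px of normal tissue / tumor.
#' @param seed integer seed; identical specs produce bit-identical slides.
#' @return An object of class `"synthetic_slide_spec"`.
#' @export
synthetic_slide_spec <- function(width, height, tumor_fraction = 0,
                                 n_tissue_blobs = 3L, n_tumor_blobs = 3L,
                                 nuclei_density_normal = 10,
                                 nuclei_density_tumor = 40,
                                 seed = 0L) {
  if (!is.numeric(width) || !is.numeric(height) || width < 1 || height < 1)
    stop_invalid("width and height must be positive")
  check_probability(tumor_fraction, "tumor_fraction")
  if (nuclei_density_normal < 0 || nuclei_density_tumor < 0)
    stop_invalid("nuclei densities must be non-negative")
  structure(list(width = as.integer(width), height = as.integer(height),
                 tumor_fraction = tumor_fraction,
                 n_tissue_blobs = as.integer(n_tissue_blobs),
                 n_tumor_blobs = as.integer(n_tumor_blobs),
                 nuclei_density_normal = nuclei_density_normal,
                 nuclei_density_tumor = nuclei_density_tumor,
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Rasterize a filled rotated ellipse into a logical (H, W) matrix.
ellipse_mask <- function(H, W, r0, c0, a, b, phi) {
  rr <- pmax(1L, floor(r0 - max(a, b))):pmin(H, ceiling(r0 + max(a, b)))
  cc <- pmax(1L, floor(c0 - max(a, b))):pmin(W, ceiling(c0 + max(a, b)))
  if (length(rr) == 0L || length(cc) == 0L) return(NULL)
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- (dr * cos(phi) + dc * sin(phi)) / a
  v <- (-dr * sin(phi) + dc * cos(phi)) / b
  list(rows = rr, cols = cc, inside = u^2 + v^2 <= 1)
}

paint_mask <- function(mask, em) {
  if (is.null(em)) return(mask)
  mask[em$rows, em$cols] <- mask[em$rows, em$cols] | em$inside
  mask
}

# Scatter n small dark nuclei at random pixels of `region`; returns the
# updated image.
scatter_nuclei <- function(image, region, n, color, jitter = 10 / 255) {
  idx <- which(region)
  if (n < 1L || length(idx) == 0L) return(image)
  H <- nrow(region); W <- ncol(region)
  centers <- sample(idx, n, replace = TRUE)
  r0 <- ((centers - 1L) %% H) + 1L
  c0 <- ((centers - 1L) %/% H) + 1L
  a <- stats::runif(n, 1, 2.5)
  b <- a * stats::runif(n, 0.6, 1)
  phi <- stats::runif(n, 0, pi)
  for (i in seq_len(n)) {
    em <- ellipse_mask(H, W, r0[i], c0[i], a[i], b[i], phi[i])
    if (is.null(em)) next
    sel <- em$inside & region[em$rows, em$cols]
    if (!any(sel)) next
    for (ch in 1:3) {
      plane <- image[em$rows, em$cols, ch]
      plane[sel] <- pmin(pmax(color[ch] +
        stats::runif(sum(sel), -jitter, jitter), 0), 1)
      image[em$rows, em$cols, ch] <- plane
    }
  }
  image
}

#' Generate one synthetic histology-like slide
#'
#' Renders a white background, pink tissue blobs with sparse dark nuclei,
#' and (when `tumor_fraction > 0`) darker purple tumor blobs confined to the
#' tissue, at a higher nuclear density. Masks are pixel-exact; the slide
#' label is `"MM"` when any tumor pixel exists, else `"NM"`. Output is a
#' deterministic function of the spec (including its seed).
#'
#' @param spec a [synthetic_slide_spec()].
#' @return An object of class `"synthetic_slide"`: `image` (`H x W x 3` in
#'   `[0, 1]`), `tumor_mask` and `tissue_mask` (logical `H x W`,
#'   tumor subset of tissue), `label`, and the `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    tissue <- matrix(FALSE, H, W)
    for (i in seq_len(spec$n_tissue_blobs)) {
      em <- ellipse_mask(H, W,
                         r0 = stats::runif(1, 0.25 * H, 0.75 * H),
                         c0 = stats::runif(1, 0.25 * W, 0.75 * W),
                         a = stats::runif(1, 0.18, 0.32) * min(H, W),
                         b = stats::runif(1, 0.18, 0.32) * min(H, W),
                         phi = stats::runif(1, 0, pi))
      tissue <- paint_mask(tissue, em)
    }
    tissue_area <- sum(tissue)

    tumor <- matrix(FALSE, H, W)
    if (spec$tumor_fraction > 0 && spec$n_tumor_blobs > 0L && tissue_area > 0L) {
      target <- spec$tumor_fraction * tissue_area
      per_blob <- target / spec$n_tumor_blobs
      add_blob <- function(tumor, area) {
        idx <- which(tissue)
        center <- idx[sample.int(length(idx), 1L)]
        r0 <- ((center - 1L) %% H) + 1L
        c0 <- ((center - 1L) %/% H) + 1L
        aspect <- stats::runif(1, 0.55, 1)
        a <- sqrt(area / (pi * aspect))
        em <- ellipse_mask(H, W, r0, c0, a, a * aspect, stats::runif(1, 0, pi))
        if (!is.null(em)) {
          em$inside <- em$inside & tissue[em$rows, em$cols]
          tumor <- paint_mask(tumor, em)
        }
        tumor
      }
      for (i in seq_len(spec$n_tumor_blobs)) tumor <- add_blob(tumor, per_blob)
      # Clipping against tissue and blob overlap can undershoot the request;
      # top up with small blobs until close (bounded loop keeps determinism).
      it <- 0L
      while (sum(tumor) / tissue_area < spec$tumor_fraction - 0.02 && it < 60L) {
        deficit <- target - sum(tumor)
        tumor <- add_blob(tumor, min(deficit, per_blob))
        it <- it + 1L
      }
    }

    image <- array(rep(matrix(stats::runif(H * W, 245, 255) / 255, H, W), 3L),
                   c(H, W, 3L))
    jit <- function(n) stats::runif(n, -10, 10) / 255
    normal <- tissue & !tumor
    base_tissue <- c(230, 180, 200) / 255
    base_tumor <- c(150, 90, 160) / 255
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[normal] <- pmin(pmax(base_tissue[ch] + jit(sum(normal)), 0), 1)
      plane[tumor] <- pmin(pmax(base_tumor[ch] + jit(sum(tumor)), 0), 1)
      image[, , ch] <- plane
    }
    n_norm <- stats::rpois(1, spec$nuclei_density_normal * sum(normal) / 1e4)
    n_tum <- stats::rpois(1, spec$nuclei_density_tumor * sum(tumor) / 1e4)
    image <- scatter_nuclei(image, normal, n_norm, c(60, 40, 90) / 255)
    image <- scatter_nuclei(image, tumor, n_tum, c(40, 20, 60) / 255)

    structure(list(image = image, tumor_mask = tumor, tissue_mask = tissue,
                   label = if (any(tumor)) "MM" else "NM", spec = spec),
              class = "synthetic_slide")
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("Synthetic slide ", x$spec$width, "x", x$spec$height, ", label ",
      x$label, ", tumor/tissue = ",
      signif(sum(x$tumor_mask) / max(sum(x$tissue_mask), 1L), 3), "\n", sep = "")
  invisible(x)
}

#' Generate a seeded collection of synthetic slides with a manifest
#'
#' Emulates the structure of a slide archive split into an unlabeled
#' pretraining pool and labeled malignant/non-malignant slides. About one
#' third of the unlabeled slides contain tumor (hidden ground truth; the
#' manifest records neither label nor mask for them). Labeled malignant
#' slides jitter the template's tumor fraction by a factor in `[0.6, 1.4]`
#' (clipped to `[0.05, 0.6]`) to emulate case heterogeneity.
#'
#' @param n_unlabeled,n_labeled_mm,n_labeled_nm slide counts (>= 0).
#' @param spec_template a [synthetic_slide_spec()]; its `tumor_fraction` is
#'   the template for malignant slides.
#' @param seed integer seed; per-slide seeds are drawn once from this
#'   stream, so identical calls give identical collections.
#' @param labeled_split split name recorded for the labeled slides
#'   (unlabeled slides are always `"pretrain"`).
#' @param dir optional directory; when given, slides and masks are written
#'   as PNG and the manifest as CSV.
#' @return List with `slides` (named list of [generate_slide()] outputs) and
#'   `manifest` (data.frame: `slide_id`, `path`, `split`, `label`,
#'   `mask_path`; `NA` label/mask for unlabeled slides).
#' @export
generate_dataset <- function(n_unlabeled, n_labeled_mm, n_labeled_nm,
                             spec_template, seed = 0L,
                             labeled_split = "train", dir = NULL) {
  if (n_unlabeled < 0 || n_labeled_mm < 0 || n_labeled_nm < 0)
    stop_invalid("slide counts must be non-negative")
  stopifnot(inherits(spec_template, "synthetic_slide_spec"))
  n_total <- n_unlabeled + n_labeled_mm + n_labeled_nm
  if (n_total == 0L)
    return(list(slides = list(),
                manifest = data.frame(slide_id = character(0),
                                      path = character(0),
                                      split = character(0),
                                      label = character(0),
                                      mask_path = character(0))))
  seeds <- with_seed(seed, sample.int(2147483646L, n_total))
  mm_jit <- with_seed(derive_seed(seed, "generate"),
                      stats::runif(max(n_labeled_mm, 1L), 0.6, 1.4))

  make_spec <- function(frac, s) {
    sp <- spec_template
    sp$tumor_fraction <- frac
    sp$seed <- s
    sp
  }
  slides <- list(); rows <- list()
  k <- 0L
  for (i in seq_len(n_unlabeled)) {
    k <- k + 1L
    frac <- if (i %% 3L == 0L) spec_template$tumor_fraction else 0
    id <- sprintf("pretrain_%03d", i)
    slides[[id]] <- generate_slide(make_spec(frac, seeds[k]))
    rows[[k]] <- data.frame(slide_id = id, path = NA_character_,
                            split = "pretrain", label = NA_character_,
                            mask_path = NA_character_)
  }
  for (i in seq_len(n_labeled_mm)) {
    k <- k + 1L
    frac <- min(max(spec_template$tumor_fraction * mm_jit[i], 0.05), 0.6)
    id <- sprintf("%s_mm_%03d", labeled_split, i)
    slides[[id]] <- generate_slide(make_spec(frac, seeds[k]))
    rows[[k]] <- data.frame(slide_id = id, path = NA_character_,
                            split = labeled_split, label = "MM",
                            mask_path = NA_character_)
  }
  for (i in seq_len(n_labeled_nm)) {
    k <- k + 1L
    id <- sprintf("%s_nm_%03d", labeled_split, i)
    slides[[id]] <- generate_slide(make_spec(0, seeds[k]))
    rows[[k]] <- data.frame(slide_id = id, path = NA_character_,
                            split = labeled_split, label = "NM",
                            mask_path = NA_character_)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$slide_id[i]
      p <- file.path(dir, paste0(id, ".png"))
      png::writePNG(slides[[id]]$image, p)
      manifest$path[i] <- p
      if (!is.na(manifest$label[i])) {
        mp <- file.path(dir, paste0(id, "_mask.png"))
        png::writePNG(slides[[id]]$tumor_mask * 1, mp)
        manifest$mask_path[i] <- mp
      }
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(slides = slides, manifest = manifest)
}
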