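# Shared fixtures built in code at test time.

# Flat-color RGB patch.
solid_patch <- function(size, rgb) {
  array(rep(rgb, each = size * size), c(size, size, 3L))
}

white_patch <- function(size = 32L) solid_patch(size, c(1, 1, 1))
pink_patch <- function(size = 32L) solid_patch(size, c(230, 180, 200) / 255)

# Labeled tumor/normal patches cut from synthetic slides.
fixture_labeled_patches <- function(n_mm_slides, n_nm_slides, seed,
                                    patch_size = 32L) {
  tmpl <- synthetic_slide_spec(128, 128, 0.5, n_tumor_blobs = 2)
  ds <- generate_dataset(0, n_mm_slides, n_nm_slides, tmpl, seed = seed)
  xs <- list(); labs <- character(0)
  for (id in names(ds$slides)) {
    s <- ds$slides[[id]]
    m <- tile_slide(s$image, mask = s$tumor_mask, patch_size = patch_size,
                    slide_id = id)
    if (nrow(m) == 0L) next
    xs[[id]] <- sslheat:::manifest_patches(s$image, m)
    labs <- c(labs, m$label)
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  x <- array(0, c(n, patch_size, patch_size, 3L))
  i <- 0L
  for (a in xs) {
    k <- dim(a)[1]
    x[(i + 1L):(i + k), , , ] <- a
    i <- i + k
  }
  list(x = x, labels = labs)
}

# Unlabeled pretraining patches.
fixture_unlabeled_patches <- function(n_slides, seed, patch_size = 32L,
                                      max_patches = Inf) {
  tmpl <- synthetic_slide_spec(128, 128, 0.5, n_tumor_blobs = 2)
  ds <- generate_dataset(n_slides, 0, 0, tmpl, seed = seed)
  xs <- list()
  for (id in names(ds$slides)) {
    s <- ds$slides[[id]]
    m <- tile_slide(s$image, patch_size = patch_size, slide_id = id)
    if (nrow(m) > 0L) xs[[id]] <- sslheat:::manifest_patches(s$image, m)
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  x <- array(0, c(n, patch_size, patch_size, 3L))
  i <- 0L
  for (a in xs) {
    k <- dim(a)[1]
    x[(i + 1L):(i + k), , , ] <- a
    i <- i + k
  }
  x[seq_len(min(n, max_patches)), , , , drop = FALSE]
}

# One seeded pretraining-ablation run: pretrain on up to 500 unlabeled
# patches, then fine-tune the three classifier variants on a scarce
# balanced labeled set (15+15 train, 15+15 validation) and return their
# validation accuracies. The labeled budget sits in the regime where every
# variant trains but labels are scarce enough for pretraining to matter.
ablation_run <- function(seed) {
  up <- fixture_unlabeled_patches(32, seed = seed, max_patches = 500)
  lp <- fixture_labeled_patches(18, 12, seed = seed + 1000L)
  set.seed(seed)
  mm <- which(lp$labels == "MALIGNANT")
  nm <- which(lp$labels == "NON_MALIGNANT")
  tr <- c(sample(mm, 15), sample(nm, 15))
  va <- c(sample(setdiff(mm, tr), 15), sample(setdiff(nm, tr), 15))
  enc <- pretrained_encoder(pretrain(up, byol_config(epochs = 2L, seed = seed)))
  one <- function(mode, e) {
    cfg <- classifier_config(mode, epochs = 40L, batch_size = 20L, seed = seed)
    clf <- train_classifier(e, lp$x[tr, , , ], lp$labels[tr],
                            lp$x[va, , , ], lp$labels[va], cfg)
    pr <- predict_patches(clf, lp$x[va, , , ])
    mean((pr >= 0.5) == (lp$labels[va] == "MALIGNANT"))
  }
  c(ssl_linear = one("SSL_LINEAR", enc),
    no_pretrain = one("NO_PRETRAIN", NULL),
    frozen = one("FROZEN", enc))
}

# Small pipeline configuration for fast end-to-end tests.
tiny_pipeline_config <- function(out_dir, seed) {
  pipeline_config(out_dir = out_dir, seed = seed,
                  n_pretrain = 6L, n_train_mm = 3L, n_train_nm = 3L,
                  n_val_mm = 1L, n_val_nm = 1L, n_test_mm = 2L,
                  n_test_nm = 2L, slide_width = 96L, slide_height = 96L,
                  byol_epochs = 1L, classifier_epochs = 8L,
                  classifier_batch_size = 16L, forest_ntree = 25L)
}
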