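# Orchestration of the four-stage pipeline: self-supervised pretraining,
# patch-level fine-tuning, heatmap/feature extraction, and slide-level
# diagnosis. Stages communicate only through files under the configured
# output directory, so each stage is independently re-runnable; a stage is
# skipped when its artifacts already exist under an identical config hash
# (the hash chains in the upstream stage hashes, so changing a parameter
# only invalidates the stages at and after the first one that uses it).

#' Pipeline configuration
#'
#' Global seed fan-out: every stage derives its own seed via
#' [derive_seed()] with a fixed per-stage offset.
#'
#' @param out_dir directory for all stage artifacts.
#' @param seed global integer seed.
#' @param n_pretrain unlabeled pretraining slides.
#' @param n_train_mm,n_train_nm,n_val_mm,n_val_nm,n_test_mm,n_test_nm
#'   labeled slide counts per split and class.
#' @param slide_width,slide_height,tumor_fraction,n_tissue_blobs,n_tumor_blobs
#'   synthetic slide geometry (see [synthetic_slide_spec()]).
#' @param patch_size,stride,tissue_threshold,overlap_cutoff tiling
#'   parameters (see [tile_slide()]).
#' @param byol_epochs,byol_batch_size,byol_lr,byol_tau,proj_dim pretraining
#'   parameters (see [byol_config()]).
#' @param classifier_mode,classifier_epochs,classifier_lr,classifier_momentum,classifier_batch_size,classifier_class_weights
#'   patch-classifier parameters (see [classifier_config()]); inverse
#'   class-frequency loss weights are on by default because slide-level
#'   annotation yields far fewer malignant than non-malignant patches.
#' @param feature_threshold heatmap binarization threshold.
#' @param forest_ntree trees in the slide-level forest.
#' @param decision_threshold slide-level vote-fraction threshold.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("sslheat_"), seed = 0L,
                            n_pretrain = 40L,
                            n_train_mm = 8L, n_train_nm = 8L,
                            n_val_mm = 2L, n_val_nm = 2L,
                            n_test_mm = 8L, n_test_nm = 8L,
                            slide_width = 128L, slide_height = 128L,
                            tumor_fraction = 0.5,
                            n_tissue_blobs = 3L, n_tumor_blobs = 2L,
                            patch_size = 32L, stride = 32L,
                            tissue_threshold = 0.1, overlap_cutoff = 0.5,
                            byol_epochs = 2L, byol_batch_size = 64L,
                            byol_lr = 3e-4, byol_tau = 0.996,
                            proj_dim = 64L,
                            classifier_mode = "SSL_LINEAR",
                            classifier_epochs = 25L, classifier_lr = 0.01,
                            classifier_momentum = 0.9,
                            classifier_batch_size = 32L,
                            classifier_class_weights = TRUE,
                            feature_threshold = 0.5,
                            forest_ntree = 100L,
                            decision_threshold = 0.5) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

PIPELINE_STAGES <- c("generate", "tile", "pretrain", "train_patch",
                     "predict_patch", "heatmap", "features", "train_slide",
                     "predict_slide", "evaluate")

# Which config fields each stage consumes (hash inputs).
stage_fields <- function(stage) {
  switch(stage,
    generate = c("seed", "n_pretrain", "n_train_mm", "n_train_nm", "n_val_mm",
                 "n_val_nm", "n_test_mm", "n_test_nm", "slide_width",
                 "slide_height", "tumor_fraction", "n_tissue_blobs",
                 "n_tumor_blobs"),
    tile = c("patch_size", "stride", "tissue_threshold", "overlap_cutoff"),
    pretrain = c("byol_epochs", "byol_batch_size", "byol_lr", "byol_tau",
                 "proj_dim"),
    train_patch = c("classifier_mode", "classifier_epochs", "classifier_lr",
                    "classifier_momentum", "classifier_batch_size",
                    "classifier_class_weights"),
    predict_patch = character(0),
    heatmap = character(0),
    features = c("feature_threshold"),
    train_slide = c("forest_ntree"),
    predict_slide = c("decision_threshold"),
    evaluate = character(0))
}

stage_deps <- function(stage, config = NULL) {
  deps <- switch(stage,
    generate = character(0), tile = "generate", pretrain = "tile",
    train_patch = c("tile", "pretrain"), predict_patch = c("tile", "train_patch"),
    heatmap = "predict_patch", features = c("heatmap", "tile"),
    train_slide = "features", predict_slide = c("train_slide", "features"),
    evaluate = c("predict_patch", "predict_slide", "tile"))
  # The fine-tuning stage needs the pretraining checkpoint only when a
  # pretrained mode is configured.
  if (stage == "train_patch" && !is.null(config) &&
      config$classifier_mode == "NO_PRETRAIN")
    deps <- setdiff(deps, "pretrain")
  deps
}

config_hash <- function(config, stage) {
  chain <- ""
  for (dep in stage_deps(stage, config)) chain <- paste0(chain, config_hash(config, dep))
  payload <- jsonlite::toJSON(config[stage_fields(stage)], auto_unbox = TRUE)
  f <- tempfile()
  writeLines(paste0(chain, payload), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

stage_done <- function(config, stage) {
  marker <- file.path(stage_dir(config, stage), ".hash")
  file.exists(marker) && readLines(marker, n = 1L) == config_hash(config, stage)
}

require_stage <- function(config, stage) {
  if (!stage_done(config, stage))
    stop(structure(class = c("sslheat_dependency_error", "error", "condition"),
                   list(message = paste0("stage '", stage, "' artifacts missing",
                                         " or stale under ",
                                         stage_dir(config, stage),
                                         "; run run_stage(\"", stage, "\", config) first"),
                        call = sys.call(-1))))
}

mark_done <- function(config, stage) {
  writeLines(config_hash(config, stage),
             file.path(stage_dir(config, stage), ".hash"))
}

# Read slides referenced by the generate-stage manifest; returns the
# manifest with images/masks attached in-memory.
load_slides <- function(config, splits = NULL) {
  man <- utils::read.csv(file.path(stage_dir(config, "generate"), "manifest.csv"),
                         stringsAsFactors = FALSE)
  if (!is.null(splits)) man <- man[man$split %in% splits, ]
  slides <- lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(man$path[i])
    mask <- if (!is.na(man$mask_path[i])) png::readPNG(man$mask_path[i]) > 0.5
            else NULL
    list(image = img, mask = mask, label = man$label[i],
         slide_id = man$slide_id[i], split = man$split[i])
  })
  names(slides) <- man$slide_id
  slides
}

load_patch_manifest <- function(config) {
  utils::read.csv(file.path(stage_dir(config, "tile"), "patches.csv"),
                  stringsAsFactors = FALSE)
}

# Stack the patches of the given manifest rows, reading each slide once.
gather_patches <- function(config, rows) {
  slides <- load_slides(config)
  size <- rows$size[1]
  out <- array(0, c(nrow(rows), size, size, 3L))
  for (sid in unique(rows$slide_id)) {
    img <- slides[[sid]]$image
    sel <- which(rows$slide_id == sid)
    for (i in sel)
      out[i, , , ] <- extract_patch(img, rows$row[i], rows$col[i], size)
  }
  out
}

#' Run one pipeline stage
#'
#' Stages: `generate`, `tile`, `pretrain`, `train_patch`, `predict_patch`,
#' `heatmap`, `features`, `train_slide`, `predict_slide`, `evaluate`. Each
#' writes its artifacts under `config$out_dir/<stage>/` together with a
#' config-hash marker; a stage whose prerequisites are missing raises a
#' dependency error naming the missing stage, and a stage whose artifacts
#' are already current is skipped.
#'
#' @param stage_name one of the stage names above.
#' @param config a [pipeline_config()].
#' @param force rerun even when artifacts are current.
#' @return The stage directory, invisibly.
#' @export
run_stage <- function(stage_name, config, force = FALSE) {
  stage_name <- match.arg(stage_name, PIPELINE_STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  for (dep in stage_deps(stage_name, config))
    require_stage(config, dep)
  if (!force && stage_done(config, stage_name))
    return(invisible(stage_dir(config, stage_name)))
  dir <- stage_dir(config, stage_name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- get(paste0("stage_", stage_name), mode = "function")
  fn(config, dir)
  mark_done(config, stage_name)
  invisible(dir)
}

stage_generate <- function(config, dir) {
  sd <- derive_seed(config$seed, "generate")
  tmpl <- synthetic_slide_spec(config$slide_width, config$slide_height,
                               config$tumor_fraction,
                               config$n_tissue_blobs, config$n_tumor_blobs)
  parts <- list(
    generate_dataset(config$n_pretrain, 0L, 0L, tmpl, seed = sd, dir = dir),
    generate_dataset(0L, config$n_train_mm, config$n_train_nm, tmpl,
                     seed = sd + 1L, labeled_split = "train", dir = dir),
    generate_dataset(0L, config$n_val_mm, config$n_val_nm, tmpl,
                     seed = sd + 2L, labeled_split = "val", dir = dir),
    generate_dataset(0L, config$n_test_mm, config$n_test_nm, tmpl,
                     seed = sd + 3L, labeled_split = "test", dir = dir))
  manifest <- do.call(rbind, lapply(parts, `[[`, "manifest"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
}

stage_tile <- function(config, dir) {
  slides <- load_slides(config)
  rows <- lapply(slides, function(s) {
    m <- tile_slide(s$image, mask = s$mask, patch_size = config$patch_size,
                    stride = config$stride,
                    tissue_threshold = config$tissue_threshold,
                    overlap_cutoff = config$overlap_cutoff,
                    slide_id = s$slide_id)
    if (nrow(m) == 0L) return(NULL)
    m$split <- s$split
    as.data.frame(m)
  })
  patches <- do.call(rbind, rows)
  rownames(patches) <- NULL
  utils::write.csv(patches, file.path(dir, "patches.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(summarize_manifest(patches)),
                   file.path(dir, "patch_counts.csv"), row.names = FALSE)
}

stage_pretrain <- function(config, dir) {
  pm <- load_patch_manifest(config)
  pm <- pm[pm$split == "pretrain", ]
  if (nrow(pm) == 0L) stop_invalid("no pretraining patches survived tiling")
  x <- gather_patches(config, pm)
  cfg <- byol_config(batch_size = config$byol_batch_size,
                     epochs = config$byol_epochs, lr = config$byol_lr,
                     tau = config$byol_tau, proj_dim = config$proj_dim,
                     seed = derive_seed(config$seed, "pretrain"))
  state <- pretrain(x, cfg)
  saveRDS(state, file.path(dir, "byol_state.rds"))
  utils::write.csv(state$log, file.path(dir, "loss_log.csv"), row.names = FALSE)
}

stage_train_patch <- function(config, dir) {
  pm <- load_patch_manifest(config)
  tr <- pm[pm$split == "train", ]
  va <- pm[pm$split == "val", ]
  enc <- if (config$classifier_mode == "NO_PRETRAIN") NULL else
    pretrained_encoder(readRDS(file.path(stage_dir(config, "pretrain"),
                                         "byol_state.rds")))
  cfg <- classifier_config(mode = config$classifier_mode,
                           learning_rate = config$classifier_lr,
                           momentum = config$classifier_momentum,
                           epochs = config$classifier_epochs,
                           batch_size = config$classifier_batch_size,
                           class_weights = config$classifier_class_weights,
                           seed = derive_seed(config$seed, "train_patch"))
  clf <- train_classifier(enc, gather_patches(config, tr), tr$label,
                          gather_patches(config, va), va$label, cfg)
  saveRDS(clf, file.path(dir, "classifier.rds"))
  utils::write.csv(clf$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
}

stage_predict_patch <- function(config, dir) {
  pm <- load_patch_manifest(config)
  pm <- pm[pm$split != "pretrain", ]
  clf <- readRDS(file.path(stage_dir(config, "train_patch"), "classifier.rds"))
  pm$probability <- predict_patches(clf, gather_patches(config, pm))
  utils::write.csv(pm[, c("slide_id", "row", "col", "size", "split",
                          "label", "probability")],
                   file.path(dir, "predictions.csv"), row.names = FALSE)
}

stage_heatmap <- function(config, dir) {
  preds <- utils::read.csv(file.path(stage_dir(config, "predict_patch"),
                                     "predictions.csv"),
                           stringsAsFactors = FALSE)
  slides <- load_slides(config, splits = c("train", "val", "test"))
  for (sid in names(slides)) {
    s <- slides[[sid]]
    p <- preds[preds$slide_id == sid, ]
    pmap <- assemble_probability_map(p, dim(s$image)[1:2],
                                     tissue_mask = tissue_pixels(s$image),
                                     slide_id = sid)
    write_probability_map(pmap, file.path(dir, paste0(sid, ".tif")))
    png::writePNG(render_heatmap(pmap),
                  file.path(dir, paste0(sid, "_heatmap.png")))
    png::writePNG(render_overlay(pmap, s$image, alpha = 0.5),
                  file.path(dir, paste0(sid, "_overlay.png")))
  }
}

stage_features <- function(config, dir) {
  man <- utils::read.csv(file.path(stage_dir(config, "generate"), "manifest.csv"),
                         stringsAsFactors = FALSE)
  man <- man[man$split != "pretrain", ]
  rows <- lapply(seq_len(nrow(man)), function(i) {
    pmap <- read_probability_map(file.path(stage_dir(config, "heatmap"),
                                           paste0(man$slide_id[i], ".tif")))
    fv <- extract_features(pmap, threshold = config$feature_threshold)
    cbind(data.frame(slide_id = man$slide_id[i], split = man$split[i],
                     label = man$label[i]),
          as.data.frame(as.list(fv)))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "features.csv"),
                   row.names = FALSE)
}

stage_train_slide <- function(config, dir) {
  ft <- utils::read.csv(file.path(stage_dir(config, "features"), "features.csv"),
                        stringsAsFactors = FALSE)
  tr <- ft[ft$split %in% c("train", "val"), ]
  model <- train_slide_model(tr, tr$label, ntree = config$forest_ntree,
                             seed = derive_seed(config$seed, "train_slide"))
  saveRDS(model, file.path(dir, "slide_model.rds"))
}

stage_predict_slide <- function(config, dir) {
  ft <- utils::read.csv(file.path(stage_dir(config, "features"), "features.csv"),
                        stringsAsFactors = FALSE)
  te <- ft[ft$split == "test", ]
  model <- readRDS(file.path(stage_dir(config, "train_slide"),
                             "slide_model.rds"))
  out <- predict_slides(model, te, threshold = config$decision_threshold)
  out$truth <- te$label
  utils::write.csv(out, file.path(dir, "slide_predictions.csv"),
                   row.names = FALSE)
}

stage_evaluate <- function(config, dir) {
  preds <- utils::read.csv(file.path(stage_dir(config, "predict_patch"),
                                     "predictions.csv"),
                           stringsAsFactors = FALSE)
  pt <- preds[preds$split == "test", ]
  patch_metrics <- NULL
  if (nrow(pt) > 0L && length(unique(pt$label)) == 2L) {
    cm <- confusion(pt$label, ifelse(pt$probability >= 0.5,
                                     "MALIGNANT", "NON_MALIGNANT"))
    patch_metrics <- metrics(cm)
    patch_metrics$auc <- roc_auc(pt$label, pt$probability)$auc
  }
  sp <- utils::read.csv(file.path(stage_dir(config, "predict_slide"),
                                  "slide_predictions.csv"),
                        stringsAsFactors = FALSE)
  slide_metrics <- NULL
  if (nrow(sp) > 0L && length(unique(sp$truth)) == 2L) {
    cm <- confusion(sp$truth, sp$label)
    slide_metrics <- metrics(cm)
    slide_metrics$auc <- roc_auc(sp$truth, sp$probability)$auc
  }
  report <- list(patch = unclass(patch_metrics), slide = unclass(slide_metrics))
  jsonlite::write_json(report, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full pipeline end to end on generated fixtures
#'
#' Generates a seeded synthetic dataset, runs every stage in order, and
#' returns the evaluation report. Two calls with the same seed produce
#' identical artifacts and metrics.
#'
#' @param seed global integer seed.
#' @param config optional [pipeline_config()]; when omitted, the default
#'   demo-scale configuration is used with this seed.
#' @return List with `patch` and `slide` metric sets (accuracy, balanced
#'   accuracy, sensitivity, specificity, kappa as computed by [metrics()],
#'   plus `auc`), the `config`, and `out_dir`.
#' @export
demo <- function(seed = 0L, config = NULL) {
  if (is.null(config)) config <- pipeline_config(seed = as.integer(seed))
  for (st in PIPELINE_STAGES) run_stage(st, config)
  report <- jsonlite::read_json(file.path(stage_dir(config, "evaluate"),
                                          "metrics.json"), simplifyVector = TRUE)
  c(report, list(config = config, out_dir = config$out_dir))
}
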