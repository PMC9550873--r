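# Patch-level malignancy classifier: a pretrained encoder plus a linear
# head, fine-tuned with momentum SGD and two-class cross-entropy.
# Modes: SSL_LINEAR fine-tunes pretrained encoder + head; NO_PRETRAIN
# trains from random encoder weights; FROZEN trains the head only.

#' Patch classifier configuration
#'
#' @param mode `"SSL_LINEAR"` (pretrained encoder, all weights fine-tuned),
#'   `"NO_PRETRAIN"` (random encoder initialization) or `"FROZEN"`
#'   (pretrained encoder held fixed; only the linear head trains).
#' @param learning_rate SGD learning rate (default `0.01`).
#' @param momentum SGD momentum (default `0.9`).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param class_weights if `TRUE`, weight the cross-entropy by inverse class
#'   frequency of the training set.
#' @param encoder_channels encoder block channels, used only for
#'   `NO_PRETRAIN` initialization.
#' @param seed integer seed for initialization and shuffling.
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(mode = c("SSL_LINEAR", "NO_PRETRAIN", "FROZEN"),
                              learning_rate = 0.01, momentum = 0.9,
                              epochs = 10L, batch_size = 64L,
                              class_weights = FALSE,
                              encoder_channels = c(8L, 16L, 32L, 64L),
                              seed = 0L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights,
                 encoder_channels = as.integer(encoder_channels),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Encode patch labels to class index: 1 = NON_MALIGNANT, 2 = MALIGNANT.
patch_label_index <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 2L, 1L))
  labels <- as.character(labels)
  bad <- !labels %in% c("MALIGNANT", "NON_MALIGNANT")
  if (any(bad)) stop_invalid("labels must be MALIGNANT or NON_MALIGNANT")
  ifelse(labels == "MALIGNANT", 2L, 1L)
}

classifier_forward_probs <- function(encoder, head, x) {
  y <- encoder_forward(encoder, x, keep_cache = FALSE)$y
  softmax_rows(head_forward(head, y))
}

balanced_accuracy_from_labels <- function(truth_idx, prob_mal, threshold = 0.5) {
  pred <- ifelse(prob_mal >= threshold, 2L, 1L)
  sen <- if (any(truth_idx == 2L)) mean(pred[truth_idx == 2L] == 2L) else NA_real_
  spe <- if (any(truth_idx == 1L)) mean(pred[truth_idx == 1L] == 1L) else NA_real_
  mean(c(sen, spe), na.rm = TRUE)
}

#' Train the patch-level malignancy classifier
#'
#' Attaches a linear two-class head to the encoder representation and
#' trains with momentum SGD on softmax cross-entropy. Model selection keeps
#' the epoch with the best validation balanced accuracy (ties broken in
#' favor of the earlier epoch).
#'
#' @param encoder pretrained encoder weights (required for `SSL_LINEAR` and
#'   `FROZEN`; must be `NULL` for `NO_PRETRAIN`, which never reads a
#'   checkpoint).
#' @param patches training patches, `(N, H, W, 3)` array or list.
#' @param labels training labels, `"MALIGNANT"` / `"NON_MALIGNANT"`; both
#'   classes must be present.
#' @param val_patches,val_labels validation set used for model selection;
#'   when omitted, the final epoch is kept.
#' @param config a [classifier_config()].
#' @return An object of class `"patch_classifier"` holding the encoder, the
#'   head, the config, the patch size seen in training, and a per-epoch
#'   history (`epoch`, `train_loss`, `val_b_acc`).
#' @export
train_classifier <- function(encoder = NULL, patches, labels,
                             val_patches = NULL, val_labels = NULL,
                             config = classifier_config()) {
  x <- as_patch_array(patches)
  yidx <- patch_label_index(labels)
  if (length(yidx) != dim(x)[1])
    stop_invalid("labels must match the number of patches")
  if (length(unique(yidx)) < 2L)
    stop_invalid("training set must contain both classes")
  if (config$mode %in% c("SSL_LINEAR", "FROZEN") && is.null(encoder))
    stop_invalid("mode ", config$mode, " requires pretrained encoder weights")
  if (config$mode == "NO_PRETRAIN" && !is.null(encoder))
    stop_invalid("NO_PRETRAIN must not be given pretrained weights")

  set.seed(config$seed)
  if (config$mode == "NO_PRETRAIN")
    encoder <- encoder_init(dim(x)[4], config$encoder_channels)
  frozen <- config$mode == "FROZEN"
  head <- head_init(encoder_out_dim(encoder))

  cw <- NULL
  if (isTRUE(config$class_weights)) {
    freq <- tabulate(yidx, nbins = 2L)
    cw <- sum(freq) / (2 * pmax(freq, 1L))
  }

  has_val <- !is.null(val_patches)
  if (has_val) {
    xv <- as_patch_array(val_patches)
    yv <- patch_label_index(val_labels)
  }

  params <- if (frozen) list(head = head) else list(encoder = encoder, head = head)
  opt <- sgd_init(params)
  n <- dim(x)[1]
  best <- list(b_acc = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_b_acc = numeric(0))

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- x[idx, , , , drop = FALSE]
      enc_now <- if (frozen) encoder else params$encoder
      ef <- encoder_forward(enc_now, xb, keep_cache = !frozen)
      logits <- head_forward(params$head, ef$y)
      ce <- cross_entropy(logits, yidx[idx], cw)
      gh <- list(W = crossprod(ef$y, ce$dlogits), b = colSums(ce$dlogits))
      grads <- if (frozen) list(head = gh) else {
        dy <- ce$dlogits %*% t(params$head$W)
        list(encoder = encoder_backward(enc_now, ef$cache, dy), head = gh)
      }
      upd <- sgd_step(params, grads, opt, config$learning_rate, config$momentum)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
    }
    vb <- NA_real_
    if (has_val) {
      enc_now <- if (frozen) encoder else params$encoder
      pv <- classifier_forward_probs(enc_now, params$head, xv)[, 2L]
      vb <- balanced_accuracy_from_labels(yv, pv)
      if (vb > best$b_acc) best <- list(b_acc = vb, params = params, epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_b_acc = vb))
  }
  if (has_val && best$epoch > 0L) params <- best$params

  structure(list(encoder = if (frozen) encoder else params$encoder,
                 head = params$head, config = config,
                 patch_size = dim(x)[2], history = history,
                 best_epoch = if (has_val) best$epoch else config$epochs,
                 frozen = frozen),
            class = "patch_classifier")
}

#' Predict per-patch malignancy probabilities
#'
#' @param classifier a trained [train_classifier()] model.
#' @param patches `(N, H, W, 3)` array or list of patches, same spatial size
#'   as the training patches.
#' @return Numeric vector of malignancy probabilities in `[0, 1]` (the
#'   malignant-class component of the two-class softmax).
#' @export
predict_patches <- function(classifier, patches) {
  stopifnot(inherits(classifier, "patch_classifier"))
  x <- as_patch_array(patches)
  if (dim(x)[2] != classifier$patch_size || dim(x)[3] != classifier$patch_size)
    stop_invalid("patch size ", dim(x)[2], "x", dim(x)[3],
                 " does not match training size ", classifier$patch_size)
  classifier_forward_probs(classifier$encoder, classifier$head, x)[, 2L]
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("Patch classifier (", x$config$mode, "), best epoch ",
      x$best_epoch, "\n", sep = "")
  invisible(x)
}
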