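# Bootstrap (online/target) self-supervised pretraining.
#
# Two augmented views of each patch are fed through an online network
# (encoder -> projector -> predictor, weights theta) and a target network
# (encoder -> projector, weights xi). The loss is the mean squared error
# between the L2-normalized online prediction and target projection,
# symmetrized over the two views. Gradients flow only through the online
# branch; the target is an exponential moving average of the online weights.

#' Normalized-MSE bootstrap loss between a prediction and a target projection
#'
#' Computes `|| p/||p|| - z'/||z'|| ||^2 = 2 - 2 cos(p, z')`, bounded in
#' `[0, 4]`.
#'
#' @param p prediction vector (online branch), nonzero and finite.
#' @param z_prime target projection vector, nonzero and finite.
#' @return Scalar loss.
#' @export
byol_loss <- function(p, z_prime) {
  if (length(p) != length(z_prime))
    stop_invalid("p and z_prime must have equal length")
  if (any(!is.finite(p)) || any(!is.finite(z_prime)))
    stop_invalid("inputs must be finite")
  np <- sqrt(sum(p^2)); nz <- sqrt(sum(z_prime^2))
  if (np == 0 || nz == 0)
    stop_invalid("degenerate input: zero-norm vector")
  2 - 2 * sum(p * z_prime) / (np * nz)
}

#' Symmetrized bootstrap loss over the two views
#'
#' The two augmented views swap roles between the online and target
#' branches: the total loss is
#' `byol_loss(p(v), z'(v')) + byol_loss(p(v'), z'(v))`, bounded in `[0, 8]`.
#'
#' @param outputs_v,outputs_v_prime lists with elements `p` (online
#'   prediction for that view) and `z_target` (target projection for that
#'   view).
#' @return Scalar loss.
#' @export
symmetric_loss <- function(outputs_v, outputs_v_prime) {
  byol_loss(outputs_v$p, outputs_v_prime$z_target) +
    byol_loss(outputs_v_prime$p, outputs_v$z_target)
}

#' Exponential-moving-average update of the target weights
#'
#' `xi_new = tau * xi + (1 - tau) * theta_part`, elementwise over a
#' parameter tree. `tau = 1` freezes the target; `tau = 0` copies the
#' online weights.
#'
#' @param theta_part online weights (the encoder + projector part).
#' @param xi target weights, same structure as `theta_part`.
#' @param tau decay in `[0, 1]`.
#' @return Updated target weights.
#' @export
ema_update <- function(theta_part, xi, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop_invalid("tau must be a scalar in [0, 1]")
  tree_map2(function(th, x) tau * x + (1 - tau) * th, theta_part, xi)
}

#' Pretraining configuration
#'
#' @param batch_size patches per optimization step.
#' @param epochs passes over the unlabeled set.
#' @param lr Adam learning rate (default `3e-4`).
#' @param tau EMA decay of the target network (default `0.996`, constant).
#' @param proj_dim projector/predictor output dimension.
#' @param proj_hidden hidden width of projector/predictor (default
#'   `4 * proj_dim`).
#' @param encoder_channels channels of the four encoder blocks.
#' @param flip_probability,blur_sigma_range augmentation parameters shared
#'   by the two view distributions.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation draws.
#' @param max_steps optional cap on total optimization steps.
#' @return A list of class `"byol_config"`.
#' @export
byol_config <- function(batch_size = 64L, epochs = 2L, lr = 3e-4, tau = 0.996,
                        proj_dim = 64L, proj_hidden = NULL,
                        encoder_channels = c(8L, 16L, 32L, 64L),
                        flip_probability = 0.5, blur_sigma_range = c(0.1, 2),
                        seed = 0L, max_steps = Inf) {
  if (is.null(proj_hidden)) proj_hidden <- 4L * proj_dim
  if (tau < 0 || tau > 1) stop_invalid("tau must lie in [0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, tau = tau,
                 proj_dim = as.integer(proj_dim),
                 proj_hidden = as.integer(proj_hidden),
                 encoder_channels = as.integer(encoder_channels),
                 flip_probability = flip_probability,
                 blur_sigma_range = blur_sigma_range,
                 seed = as.integer(seed), max_steps = max_steps),
            class = "byol_config")
}

# Coerce a list of (H,W,3) images into a batch array (N,H,W,3).
as_patch_array <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 4L) return(patches)
  if (is.list(patches) && length(patches) > 0L) {
    d <- dim(patches[[1]])
    out <- array(0, c(length(patches), d))
    for (i in seq_along(patches)) out[i, , , ] <- patches[[i]]
    return(out)
  }
  stop_invalid("patches must be a non-empty list of images or an (N,H,W,C) array")
}

augment_batch <- function(x, flip_prob, blur_range = NULL) {
  n <- dim(x)[1]
  flips <- stats::runif(n) < flip_prob
  sigmas <- if (!is.null(blur_range))
    stats::runif(n, blur_range[1], blur_range[2]) else NULL
  for (i in seq_len(n)) {
    img <- x[i, , , ]
    if (flips[i]) img <- hflip(img)
    if (!is.null(sigmas)) img <- gaussian_blur(img, sigmas[i])
    x[i, , , ] <- img
  }
  x
}

# Batched loss: rows of P against rows of Z (targets, treated as constant).
# Returns per-sample losses and dLoss/dP for the *sum* of per-sample losses.
byol_loss_batch <- function(P, Z) {
  np <- sqrt(rowSums(P^2)); nz <- sqrt(rowSums(Z^2))
  if (any(np == 0) || any(nz == 0))
    stop_invalid("degenerate input: zero-norm vector")
  Phat <- P / np; Zhat <- Z / nz
  s <- rowSums(Phat * Zhat)
  dP <- -2 * (Zhat - s * Phat) / np
  list(loss = 2 - 2 * s, dP = dP)
}

# Forward online branch with caches: encoder -> projector -> predictor.
online_forward <- function(net, x) {
  ef <- encoder_forward(net$encoder, x, keep_cache = TRUE)
  pf <- mlp_forward(net$projector, ef$y, keep_cache = TRUE)
  qf <- mlp_forward(net$predictor, pf$out, keep_cache = TRUE)
  list(y = ef$y, z = pf$out, p = qf$out,
       cache = list(enc = ef$cache, proj = pf$cache, pred = qf$cache))
}

# Backprop dLoss/dp through predictor, projector, encoder.
online_backward <- function(net, fwd, dp) {
  qb <- mlp_backward(net$predictor, fwd$cache$pred, dp)
  pb <- mlp_backward(net$projector, fwd$cache$proj, qb$dx)
  eb <- encoder_backward(net$encoder, fwd$cache$enc, pb$dx)
  list(encoder = eb, projector = pb$grads, predictor = qb$grads)
}

target_forward <- function(net, x) {
  ef <- encoder_forward(net$encoder, x, keep_cache = FALSE)
  mlp_forward(net$projector, ef$y, keep_cache = FALSE)$out
}

#' Self-supervised pretraining of the patch encoder
#'
#' Runs the bootstrap online/target procedure on unlabeled patches: per
#' step, each patch in the batch is augmented under the two view
#' distributions, the symmetrized normalized-MSE loss is minimized with
#' Adam over the online weights only, and the target weights are updated as
#' an EMA of the online weights. The target network is initialized as a
#' copy of the online encoder + projector.
#'
#' @param patches unlabeled patches: list of `(H, W, 3)` arrays or a single
#'   `(N, H, W, 3)` array, values in `[0, 1]`; `H`, `W` divisible by 16.
#' @param config a [byol_config()].
#' @return An object of class `"byol_state"`: `online` (encoder, projector,
#'   predictor weights), `target` (encoder, projector), `tau`, `step`, the
#'   per-step loss `log`, and the config. Extract the pretrained encoder
#'   with [pretrained_encoder()].
#' @export
pretrain <- function(patches, config = byol_config()) {
  x <- as_patch_array(patches)
  n <- dim(x)[1]
  if (n < 1L) stop_invalid("need at least one patch")
  set.seed(config$seed)
  online <- list(
    encoder = encoder_init(dim(x)[4], config$encoder_channels),
    projector = mlp_init(config$encoder_channels[length(config$encoder_channels)],
                         config$proj_hidden, config$proj_dim),
    predictor = mlp_init(config$proj_dim, config$proj_hidden, config$proj_dim))
  target <- list(encoder = online$encoder, projector = online$projector)
  opt <- adam_init(online)
  step <- 0L
  log <- list(step = integer(0), loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      if (step >= config$max_steps) break
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- x[idx, , , , drop = FALSE]
      v <- augment_batch(xb, config$flip_probability)
      vp <- augment_batch(xb, config$flip_probability, config$blur_sigma_range)

      f1 <- online_forward(online, v)
      f2 <- online_forward(online, vp)
      z_t_v <- target_forward(target, v)
      z_t_vp <- target_forward(target, vp)

      l1 <- byol_loss_batch(f1$p, z_t_vp)
      l2 <- byol_loss_batch(f2$p, z_t_v)
      loss <- mean(l1$loss) + mean(l2$loss)

      g1 <- online_backward(online, f1, l1$dP / length(idx))
      g2 <- online_backward(online, f2, l2$dP / length(idx))
      grads <- tree_add(g1, g2)

      upd <- adam_step(online, grads, opt, config$lr)
      online <- upd$params; opt <- upd$state

      target$encoder <- ema_update(online$encoder, target$encoder, config$tau)
      target$projector <- ema_update(online$projector, target$projector, config$tau)

      step <- step + 1L
      log$step <- c(log$step, step)
      log$loss <- c(log$loss, loss)
    }
    if (step >= config$max_steps) break
  }
  structure(list(online = online, target = target, tau = config$tau,
                 step = step,
                 log = data.frame(step = log$step, loss = log$loss),
                 config = config),
            class = "byol_state")
}

#' Extract the pretrained online encoder from a pretraining state
#'
#' @param state a `"byol_state"` from [pretrain()].
#' @return The online encoder weights.
#' @export
pretrained_encoder <- function(state) {
  stopifnot(inherits(state, "byol_state"))
  state$online$encoder
}

#' @export
print.byol_state <- function(x, ...) {
  cat("Bootstrap pretraining state:", x$step, "steps, tau =", x$tau, "\n")
  if (nrow(x$log) > 0)
    cat("  loss:", signif(x$log$loss[1], 4), "->",
        signif(x$log$loss[nrow(x$log)], 4), "\n")
  invisible(x)
}
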