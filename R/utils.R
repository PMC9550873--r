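#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the previous state, so seeded helpers do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Seed fan-out rule used across the pipeline: each named stage gets a
#' fixed integer offset, mixed with the global seed by a
#' multiply-and-reduce step modulo 2^31 - 1 so derived seeds stay valid
#' 32-bit R integers and distinct stages get uncorrelated streams.
#'
#' @param seed global integer seed.
#' @param stage stage name (see names of the internal offset table) or an
#'   integer offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 1L, tile = 2L, pretrain = 3L, train_patch = 4L,
               predict_patch = 5L, heatmap = 6L, features = 7L,
               train_slide = 8L, predict_slide = 9L, evaluate = 10L,
               augment = 11L)
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer((as.numeric(seed) * 48271 + off * 2654435) %% 2147483647)
}

# internal argument checks ---------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(class = c("sslheat_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_probability <- function(x, what = "probability") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_invalid(what, " must lie in [0, 1]")
  invisible(x)
}

# Canonical label constants: patch level and slide level.
PATCH_LABELS <- c("MALIGNANT", "NON_MALIGNANT", "UNLABELED")
SLIDE_LABELS <- c("MM", "NM")

# image helpers --------------------------------------------------------------

# Images are numeric arrays dim c(H, W, 3) with values in [0, 1];
# masks are logical or 0/1 matrices dim c(H, W).
as_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop_invalid("expected an RGB image array (H x W x 3)")
  x
}
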