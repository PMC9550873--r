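# Slide-level diagnosis: a random forest over the 31-feature heatmap
# summaries. The forest itself comes from the randomForest package
# (bootstrap-aggregated CART trees); this module owns the schema handling,
# validation, and the vote-fraction probability contract.

#' Train the random-forest slide classifier
#'
#' Fits a bootstrap-aggregated decision-tree ensemble on one 31-feature row
#' per slide. Columns are matched by schema name, never by position. The
#' out-of-bag error estimate is kept in the returned object.
#'
#' @param feature_table data.frame or matrix with exactly the 31 columns of
#'   [feature_schema()] (any order; extra columns `slide_id`/`label` are
#'   ignored).
#' @param labels slide labels, `"MM"` / `"NM"`; at least two slides per
#'   class.
#' @param ntree number of trees (default 100).
#' @param mtry features tried per split (default `floor(sqrt(31))`).
#' @param seed integer seed; fixed seed gives a reproducible forest.
#' @return An object of class `"slide_model"` wrapping the forest, the
#'   schema, and the out-of-bag confusion.
#' @export
train_slide_model <- function(feature_table, labels, ntree = 100L,
                              mtry = floor(sqrt(31)), seed = 0L) {
  x <- as_feature_matrix(feature_table)
  y <- factor(ifelse(as_binary01(labels) == 1L, "MM", "NM"),
              levels = c("NM", "MM"))
  if (length(y) != nrow(x))
    stop_invalid("labels must match the number of slides")
  if (any(table(y) < 2L))
    stop_invalid("need at least two slides per class")
  if (all(apply(x, 2, function(col) length(unique(col))) == 1L))
    stop_invalid("degenerate feature table: every feature is constant")
  fit <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry))
  structure(list(forest = fit, schema = feature_schema(),
                 oob_error = fit$err.rate[ntree, "OOB"],
                 ntree = ntree, seed = seed),
            class = "slide_model")
}

# Validate and order feature columns by schema name.
as_feature_matrix <- function(feature_table) {
  ft <- as.data.frame(feature_table)
  ft <- ft[, !(names(ft) %in% c("slide_id", "label", "split")), drop = FALSE]
  schema <- feature_schema()
  missing <- setdiff(schema, names(ft))
  extra <- setdiff(names(ft), schema)
  if (length(missing) || length(extra))
    stop(structure(class = c("sslheat_schema_error", "error", "condition"),
                   list(message = paste0(
                     "feature schema mismatch",
                     if (length(missing)) paste0("; missing: ",
                       paste(missing, collapse = ", ")),
                     if (length(extra)) paste0("; unexpected: ",
                       paste(extra, collapse = ", "))),
                     call = sys.call(-1))))
  as.matrix(ft[, schema, drop = FALSE])
}

#' Predict slide-level malignancy from feature vectors
#'
#' @param model a [train_slide_model()] fit.
#' @param feature_table feature rows with the 31 schema columns (any
#'   order); a `slide_id` column, when present, is carried through.
#' @param threshold decision threshold on the malignant vote fraction
#'   (default 0.5).
#' @return data.frame with `slide_id`, `probability` (fraction of trees
#'   voting malignant) and `label` (`"MM"` iff `probability >= threshold`).
#' @export
predict_slides <- function(model, feature_table, threshold = 0.5) {
  stopifnot(inherits(model, "slide_model"))
  x <- as_feature_matrix(feature_table)
  prob <- stats::predict(model$forest, x, type = "prob")[, "MM"]
  ids <- if (is.data.frame(feature_table) && "slide_id" %in% names(feature_table))
    as.character(feature_table$slide_id) else as.character(seq_len(nrow(x)))
  data.frame(slide_id = ids, probability = as.numeric(prob),
             label = ifelse(prob >= threshold, "MM", "NM"),
             row.names = NULL)
}

#' @export
print.slide_model <- function(x, ...) {
  cat("Slide-level random forest:", x$ntree, "trees, OOB error",
      signif(x$oob_error, 3), "\n")
  invisible(x)
}
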