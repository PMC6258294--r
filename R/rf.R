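#' Random forest configuration
#'
#' Defaults follow the study design for this problem: 501 trees and 6
#' candidate features per split over the 105-feature schema.
#'
#' @param n_trees number of trees.
#' @param candidates_per_split features sampled as candidates at each split
#'   (mtry).
#' @param seed RNG seed.
#' @return list of class \code{rf_config}.
#' @export
rf_config <- function(n_trees = 501L, candidates_per_split = 6L, seed = 1L) {
  stopifnot(n_trees >= 1, candidates_per_split >= 1,
            candidates_per_split <= 105)
  structure(list(n_trees = as.integer(n_trees),
                 candidates_per_split = as.integer(candidates_per_split),
                 seed = as.integer(seed)),
            class = "rf_config")
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Train the random forest classifier
#'
#' Breiman-style random forest (Gini split criterion) on the 105-feature
#' model schema, via the randomForest package. Importance bookkeeping is
#' always enabled so \code{rf_importance} can be computed afterwards.
#'
#' @param features numeric matrix over \code{model_feature_names()} columns.
#' @param labels binary vector (1 = positive).
#' @param config \code{rf_config}.
#' @return list of class \code{rf_model} wrapping the randomForest fit.
#' @importFrom randomForest randomForest importance
#' @export
train_random_forest <- function(features, labels, config = rf_config()) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (!identical(colnames(features), model_feature_names())) {
    stop("features must use the 105-column model schema")
  }
  y <- factor(labels, levels = c(0, 1))
  fit <- with_seed(config$seed,
    randomForest::randomForest(x = features, y = y,
                               ntree = config$n_trees,
                               mtry = config$candidates_per_split,
                               importance = TRUE))
  structure(list(fit = fit, config = config), class = "rf_model")
}

#' Positive-class probabilities from the random forest
#' @param object \code{rf_model}.
#' @param features numeric matrix over the model schema.
#' @param ... unused.
#' @return numeric vector of positive-class vote fractions.
#' @export
predict.rf_model <- function(object, features, ...) {
  unname(stats::predict(object$fit, features, type = "prob")[, "1"])
}

#' Random forest feature importance with top-10\% flags
#'
#' Mean decrease accuracy (out-of-bag permutation importance, averaged over
#' trees) and mean decrease Gini (total split-impurity reduction), with the
#' top 10\% of features (ceil(0.10 * n) = 11 of 105) flagged under each
#' criterion.
#'
#' @param model \code{rf_model} trained with importance enabled.
#' @param top_fraction fraction flagged per criterion (default 0.10).
#' @return data.frame with \code{feature}, \code{mean_decrease_accuracy},
#'   \code{mean_decrease_gini}, \code{top_accuracy}, \code{top_gini}, sorted
#'   by decreasing Gini importance.
#' @export
rf_importance <- function(model, top_fraction = 0.10) {
  imp <- randomForest::importance(model$fit)
  if (!all(c("MeanDecreaseAccuracy", "MeanDecreaseGini") %in% colnames(imp))) {
    stop("model was not trained with importance bookkeeping")
  }
  n_top <- ceiling(top_fraction * nrow(imp))
  mda <- imp[, "MeanDecreaseAccuracy"]
  mdg <- imp[, "MeanDecreaseGini"]
  out <- data.frame(
    feature = rownames(imp),
    mean_decrease_accuracy = unname(mda),
    mean_decrease_gini = unname(mdg),
    top_accuracy = rank(-mda, ties.method = "first") <= n_top,
    top_gini = rank(-mdg, ties.method = "first") <= n_top,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$mean_decrease_gini), , drop = FALSE]
}
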