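#' Extract the baseline feature vector from segment summaries
#'
#' Deterministic, fixed-length feature mapping used by the training-based
#' classifiers: per-channel mean, SD, min, max and slope, segment duration,
#' a one-hot room encoding, and the clock time of the segment start encoded
#' as sine/cosine (so midnight wraps continuously). Missing values are
#' imputed with 0 and flagged in a per-channel mask column.
#'
#' @param summaries Segment summary table ([segment_summaries()]).
#' @param rooms Character vector fixing the room one-hot order (default:
#'   the rooms of [default_rooms()]).
#' @return Numeric feature `data.table`, one row per segment, columns in a
#'   documented fixed order.
#' @export
extract_features <- function(summaries, rooms = default_rooms()$room) {
  n <- nrow(summaries)
  out <- list()
  for (ch in CHANNELS) {
    for (st in c("mean", "sd", "min", "max", "slope")) {
      col <- paste0(ch, "_", st)
      v <- summaries[[col]]
      if (is.null(v)) v <- rep(NA_real_, n)
      out[[col]] <- v
    }
  }
  out$duration_min <- summaries$duration_min
  for (rm in rooms) {
    out[[paste0("room_", rm)]] <- as.numeric(summaries$room == rm)
  }
  ang <- summaries$clock_start_h / 24 * 2 * pi
  out$clock_sin <- sin(ang)
  out$clock_cos <- cos(ang)
  ft <- as.data.table(out)
  for (ch in CHANNELS) {
    cols <- paste0(ch, "_", c("mean", "sd", "min", "max", "slope"))
    miss <- rowSums(is.na(as.matrix(ft[, cols, with = FALSE]))) > 0
    ft[[paste0(ch, "_missing")]] <- as.numeric(miss)
  }
  for (col in names(ft)) ft[[col]][is.na(ft[[col]])] <- 0
  ft
}

#' Train a Gaussian naive Bayes classifier
#'
#' Assumes feature independence within a class: per class and feature a
#' Gaussian likelihood (sample mean and variance, floored at `var_floor`),
#' combined with class priors estimated from the label frequencies.
#' Prediction maximizes the posterior probability.
#'
#' @param x Numeric feature matrix or data.frame (rows = instances).
#' @param y Class labels (>= 2 distinct classes required).
#' @param var_floor Lower bound on per-feature variance.
#' @return An `adl_nb` model object.
#' @export
nb_train <- function(x, y, var_floor = 1e-6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("nb_train needs >= 2 classes")
  y <- droplevels(y)
  classes <- levels(y)
  means <- vars <- matrix(0, nrow = length(classes), ncol = ncol(x),
                          dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    means[cl, ] <- colMeans(xc)
    v <- apply(xc, 2, var)
    v[is.na(v)] <- 0
    vars[cl, ] <- pmax(v, var_floor)
  }
  structure(list(classes = classes,
                 prior = as.numeric(table(y)[classes]) / length(y),
                 means = means, vars = vars),
            class = "adl_nb")
}

#' Predict with a Gaussian naive Bayes model
#'
#' @param model An `adl_nb` model.
#' @param x Feature matrix / data.frame.
#' @param type `"class"` (default) for the maximum-posterior label,
#'   `"posterior"` for the normalized posterior matrix (rows sum to 1).
#' @return Character vector of labels, or a posterior matrix.
#' @export
nb_predict <- function(model, x, type = c("class", "posterior")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  logpost <- matrix(0, nrow = nrow(x), ncol = length(model$classes),
                    dimnames = list(NULL, model$classes))
  for (k in seq_along(model$classes)) {
    ll <- dnorm(x, mean = matrix(model$means[k, ], nrow(x), ncol(x),
                                 byrow = TRUE),
                sd = matrix(sqrt(model$vars[k, ]), nrow(x), ncol(x),
                            byrow = TRUE), log = TRUE)
    logpost[, k] <- rowSums(ll) + log(model$prior[k])
  }
  if (type == "class") {
    return(model$classes[max.col(logpost, ties.method = "first")])
  }
  sweep_max <- apply(logpost, 1, max)
  p <- exp(logpost - sweep_max)
  p / rowSums(p)
}

#' Majority vote with smallest-class-index tie break
#'
#' @param votes Character matrix: rows = instances, columns = per-tree (or
#'   per-model) votes.
#' @param classes Class levels; ties are broken toward the smallest index
#'   in this order.
#' @return Character vector of winning labels.
#' @keywords internal
majority_vote <- function(votes, classes) {
  apply(votes, 1, function(v) {
    counts <- table(factor(v, levels = classes))
    classes[which.max(counts)] # which.max takes the first (smallest index)
  })
}

#' Train a random forest classifier
#'
#' Grows `n_trees` unpruned decision trees, each on a bootstrap sample of
#' the data with a random subset of `ceiling(sqrt(p))` features tried at
#' every split (delegated to the randomForest package, whose algorithm is
#' exactly this contract). Prediction is a majority vote over the trees'
#' individual votes with ties broken toward the smallest class index;
#' deterministic under `seed`.
#'
#' @param x Feature matrix / data.frame.
#' @param y Class labels (>= 2 classes).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param mtry Features tried per split (default `ceiling(sqrt(p))`).
#' @return An `adl_rf` model object (wraps the fitted forest).
#' @export
rf_train <- function(x, y, n_trees = 100, seed = 1L, mtry = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("rf_train needs >= 2 classes")
  x <- as.data.frame(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(x)))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                    mtry = mtry, replace = TRUE)
  structure(list(forest = fit, classes = levels(y), n_trees = n_trees),
            class = "adl_rf")
}

#' Predict with a random forest model
#'
#' @param model An `adl_rf` model.
#' @param x Feature matrix / data.frame.
#' @return Character vector of majority-vote labels (ties toward the
#'   smallest class index).
#' @export
rf_predict <- function(model, x) {
  pred <- predict(model$forest, newdata = as.data.frame(x),
                  predict.all = TRUE)
  votes <- matrix(as.character(pred$individual),
                  nrow = nrow(as.data.frame(x)))
  majority_vote(votes, model$classes)
}

#' Out-of-bag error of a random forest model
#' @param model An `adl_rf` model.
#' @return OOB error rate (fraction misclassified).
#' @export
rf_oob_error <- function(model) {
  as.numeric(tail(model$forest$err.rate[, "OOB"], 1))
}
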