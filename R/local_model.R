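# Per-query local random-forest regression: for each query molecule a
# neighbourhood of the k nearest training molecules (weighted Euclidean
# distance in sigma_p space) is retrieved and one forest per property is
# fitted on that neighbourhood only. Forests come from the ranger package.

#' Default random-forest settings
#'
#' Robust small-sample defaults for the 100-molecule neighbourhoods:
#' 300 trees, unrestricted depth, square-root feature sampling.
#'
#' @param num_trees Number of trees.
#' @param mtry Features sampled per split (default `floor(sqrt(16)) = 4`).
#' @param min_node_size Minimum terminal node size.
#' @return A list of forest parameters.
#' @export
forest_params <- function(num_trees = 300L, mtry = NULL,
                          min_node_size = 5L) {
  list(num_trees = as.integer(num_trees), mtry = mtry,
       min_node_size = as.integer(min_node_size))
}

#' Weighted Euclidean distance between descriptor vectors
#'
#' \deqn{d(a, b) = \sqrt{\sum_i w_i (a_i - b_i)^2}} — a metric for strictly
#' positive weights. Uniform weights are the default throughout (per-position
#' weights are accepted everywhere a distance is taken).
#'
#' @param a,b Numeric descriptor vectors of equal length.
#' @param w Non-negative weights, not all zero (default uniform).
#' @return Non-negative scalar.
#' @export
weighted_distance <- function(a, b, w = rep(1, length(a))) {
  if (length(a) != length(b) || length(w) != length(a)) {
    hel_error("descriptor vectors and weights must have equal length",
              "dimension_error")
  }
  if (any(w < 0) || !any(w > 0) || any(!is.finite(w))) {
    hel_error("weights must be finite, non-negative, not all zero",
              "value_error")
  }
  sqrt(sum(w * (a - b)^2))
}

# distances from one query vector to every row of a feature matrix
distances_to_pool <- function(qvec, feats, w) {
  if (ncol(feats) != length(qvec) || length(w) != length(qvec)) {
    hel_error("feature dimension mismatch", "dimension_error")
  }
  sqrt(colSums(w * (t(feats) - qvec)^2))
}

#' Retrieve the k nearest neighbours of a query molecule
#'
#' The query itself (matched by canonical name) is excluded from its own
#' neighbourhood. Distance ties are broken by canonical name order, so
#' retrieval is fully deterministic.
#'
#' @param query A [helicene()].
#' @param pool A `helicene_dataset`.
#' @param k Neighbourhood size (default 100, a size that performs well
#'   across properties at typical dataset scales; tune per case if needed).
#' @param w Distance weights over the 16 positions.
#' @param sigma Descriptor table.
#' @return The k nearest rows of `pool` (a `helicene_dataset`) with an
#'   attached numeric attribute `distances`, non-decreasing.
#' @export
nearest_neighbours <- function(query, pool, k = 100L,
                               w = rep(1, N_POSITIONS),
                               sigma = sigma_table()) {
  qname <- format_name(query)
  keep <- pool$name != qname
  if (sum(keep) < k) {
    hel_error(sprintf("pool has only %d candidate neighbours, need k = %d",
                      sum(keep), k), "insufficient_pool_error")
  }
  sub <- as.data.frame(pool)[keep, , drop = FALSE]
  occ <- as.matrix(sub[, paste0("pos", 1:16)])
  feats <- matrix(sigma[occ], nrow = nrow(sub))
  if (anyNA(feats)) {
    hel_error("pool contains codes absent from the descriptor table",
              "descriptor_table_error")
  }
  d <- distances_to_pool(encode(query, sigma), feats, w)
  ord <- order(d, sub$name)[seq_len(k)]
  out <- new_dataset(sub[ord, , drop = FALSE], attr(pool, "provenance"))
  attr(out, "distances") <- d[ord]
  out
}

fit_forest <- function(x, y, fp, seed) {
  if (stats::var(y) == 0 || all(apply(x, 2, stats::var) == 0)) {
    # degenerate neighbourhood: constant target or constant features
    return(structure(list(mean = mean(y)), class = "constant_model"))
  }
  ranger::ranger(
    x = x, y = y,
    num.trees = fp$num_trees,
    mtry = fp$mtry %||% max(1L, floor(sqrt(ncol(x)))),
    min.node.size = fp$min_node_size,
    seed = seed, num.threads = 1L
  )
}

predict_forest <- function(fit, xnew) {
  if (inherits(fit, "constant_model")) {
    return(rep(fit$mean, nrow(xnew)))
  }
  stats::predict(fit, data = xnew, num.threads = 1L)$predictions
}

#' Fit a local model at a query and predict its properties
#'
#' Retrieves the query's k nearest training neighbours and fits one random
#' forest per requested property on the neighbourhood's descriptor/property
#' pairs. A constant-property or constant-feature neighbourhood degrades
#' gracefully to the neighbourhood mean. Predicted `g_abs` is clamped to
#' the physical bound [-2, 2].
#'
#' @param query A [helicene()].
#' @param pool Training `helicene_dataset`.
#' @param k Neighbourhood size.
#' @param w Distance weights.
#' @param fp Forest parameters ([forest_params()]).
#' @param seed Integer seed for the forest fits.
#' @param properties Property names to predict (default all nine).
#' @return Named numeric vector of predictions.
#' @export
fit_predict_local <- function(query, pool, k = 100L,
                              w = rep(1, N_POSITIONS),
                              fp = forest_params(), seed = 1L,
                              properties = PROPERTY_NAMES) {
  nb <- nearest_neighbours(query, pool, k, w)
  x <- dataset_features(nb)
  qx <- matrix(encode(query), nrow = 1,
               dimnames = list(NULL, colnames(x)))
  preds <- vapply(properties, function(p) {
    fit <- fit_forest(x, nb[[p]], fp, derive_seed(seed, p))
    predict_forest(fit, qx)
  }, numeric(1))
  if ("g_abs" %in% properties) {
    preds[["g_abs"]] <- max(-2, min(2, preds[["g_abs"]]))
  }
  preds
}

#' Fit one global model on the full pool and predict many queries
#'
#' The baseline the local protocol is compared against: a single forest per
#' property trained on all available data.
#'
#' @param pool Training `helicene_dataset` (non-empty).
#' @param queries List of [helicene()] objects.
#' @param fp Forest parameters.
#' @param seed Integer seed.
#' @param properties Property names to predict.
#' @return Matrix of predictions, one row per query.
#' @export
fit_predict_global <- function(pool, queries, fp = forest_params(),
                               seed = 1L, properties = PROPERTY_NAMES) {
  stopifnot(nrow(pool) >= 2)
  x <- dataset_features(pool)
  qx <- do.call(rbind, lapply(queries, encode))
  colnames(qx) <- colnames(x)
  preds <- sapply(properties, function(p) {
    fit <- fit_forest(x, pool[[p]], fp, derive_seed(seed, p))
    predict_forest(fit, qx)
  })
  preds <- matrix(preds, nrow = length(queries),
                  dimnames = list(NULL, properties))
  if ("g_abs" %in% properties) {
    preds[, "g_abs"] <- pmax(-2, pmin(2, preds[, "g_abs"]))
  }
  preds
}

#' Build a cached molecule -> predicted properties function
#'
#' Wraps [fit_predict_local()] as a predictor closure for the search
#' algorithms, memoising by canonical name (the GA revisits candidates).
#'
#' @inheritParams fit_predict_local
#' @param pool Training `helicene_dataset`.
#' @return Function `(helicene) -> named numeric vector`.
#' @export
make_local_predictor <- function(pool, k = 100L, w = rep(1, N_POSITIONS),
                                 fp = forest_params(), seed = 1L,
                                 properties = PROPERTY_NAMES) {
  cache <- new.env(parent = emptyenv())
  function(mol) {
    nm <- format_name(mol)
    hit <- get0(nm, envir = cache)
    if (!is.null(hit)) return(hit)
    p <- fit_predict_local(mol, pool, k, w, fp, seed, properties)
    assign(nm, p, envir = cache)
    p
  }
}

#' Prediction-error report with robust outlier flagging
#'
#' Computes MAE and RMSE per property and flags outliers as residuals
#' deviating from the median residual by more than 2.5 times the scaled
#' median absolute deviation (MAD x 1.4826, the normal-consistency scaling).
#'
#' @param predictions Numeric matrix (or data frame), one column per
#'   property, one row per case.
#' @param truths Matrix of the same shape with the reference values.
#' @param names Optional case names for the residual table.
#' @param mad_multiplier Outlier threshold in scaled-MAD units (default 2.5).
#' @return A list of class `eval_report`: `metrics` (data frame with
#'   property, MAE, RMSE, outlier fraction) and `residuals` (long table with
#'   an `outlier` flag).
#' @export
evaluate_predictions <- function(predictions, truths, names = NULL,
                                 mad_multiplier = 2.5) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (!all(dim(predictions) == dim(truths)) || nrow(predictions) < 2) {
    hel_error("predictions and truths must have equal shape, >= 2 rows",
              "dimension_error")
  }
  props <- colnames(predictions) %||% paste0("p", seq_len(ncol(predictions)))
  names <- names %||% as.character(seq_len(nrow(predictions)))
  resid_tables <- lapply(seq_along(props), function(j) {
    r <- predictions[, j] - truths[, j]
    med <- stats::median(r)
    smad <- 1.4826 * stats::median(abs(r - med))
    out <- abs(r - med) > mad_multiplier * smad
    data.frame(property = props[j], name = names,
               predicted = predictions[, j], true = truths[, j],
               residual = r, outlier = out, stringsAsFactors = FALSE)
  })
  residuals <- do.call(rbind, resid_tables)
  metrics <- do.call(rbind, lapply(resid_tables, function(tb) {
    data.frame(property = tb$property[1],
               mae = mean(abs(tb$residual)),
               rmse = sqrt(mean(tb$residual^2)),
               outlier_fraction = mean(tb$outlier),
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, residuals = residuals),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Run the held-out local-model evaluation protocol
#'
#' Splits a dataset (default 80/20), fits a local model per test molecule on
#' its k nearest training neighbours, and returns the [evaluate_predictions()]
#' report over the test set.
#'
#' @param ds A `helicene_dataset`.
#' @param k Neighbourhood size.
#' @param test_fraction Held-out fraction.
#' @param w Distance weights.
#' @param fp Forest parameters.
#' @param seed Integer seed (drives the split and the fits).
#' @param properties Properties to evaluate.
#' @param split_seed Optional separate seed for the split (defaults to `seed`).
#' @return An `eval_report`.
#' @export
evaluate_local_protocol <- function(ds, k = 100L, test_fraction = 0.2,
                                    w = rep(1, N_POSITIONS),
                                    fp = forest_params(), seed = 1L,
                                    properties = PROPERTY_NAMES,
                                    split_seed = NULL) {
  parts <- split_dataset(ds, test_fraction, split_seed %||% seed)
  train <- parts$train
  test <- parts$test
  if (nrow(train) < k + 1L) {
    hel_error("training pool smaller than the neighbourhood size",
              "insufficient_pool_error")
  }
  # same retrieval rule as nearest_neighbours (self-exclusion by name,
  # distance then canonical-name tie-break), on precomputed matrices
  feats <- dataset_features(train)
  tfeats <- t(feats)
  props <- as.matrix(as.data.frame(train)[, properties, drop = FALSE])
  qfeats <- dataset_features(test)
  preds <- matrix(NA_real_, nrow(test), length(properties),
                  dimnames = list(NULL, properties))
  for (i in seq_len(nrow(test))) {
    d <- sqrt(colSums(w * (tfeats - qfeats[i, ])^2))
    keep <- train$name != test$name[i]
    idx <- which(keep)[order(d[keep], train$name[keep])[seq_len(k)]]
    x <- feats[idx, , drop = FALSE]
    qx <- qfeats[i, , drop = FALSE]
    qseed <- derive_seed(seed, paste0("q", i))
    preds[i, ] <- vapply(properties, function(p) {
      fit <- fit_forest(x, props[idx, p], fp, derive_seed(qseed, p))
      predict_forest(fit, qx)
    }, numeric(1))
  }
  if ("g_abs" %in% properties) {
    preds[, "g_abs"] <- pmax(-2, pmin(2, preds[, "g_abs"]))
  }
  truths <- as.matrix(as.data.frame(test)[, properties, drop = FALSE])
  evaluate_predictions(preds, truths, names = test$name)
}
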