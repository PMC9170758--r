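# Cross-validation: plain k-fold with a fixed configuration, and nested
# k-fold with inner grid search for hyperparameter selection.

#' Plain k-fold cross-validation with a fixed configuration
#'
#' Samples are split into `k` random folds; for each fold a fresh model is
#' trained on the remaining folds (with a small carved-out validation split
#' driving early stopping) and scored on the held-out fold. The out-of-fold
#' predictions over all folds are pooled into one score vector — the pooled
#' vector, not per-fold averages, is what [evaluate_cv()] reports.
#'
#' @param samples data.frame with `sequence` and `label` columns.
#' @param config A [model_config()]; its seed is re-derived per fold.
#' @param k Fold count.
#' @param seed Seed for the fold assignment and per-fold training.
#' @param val_fraction Fraction of each training portion held out for early
#'   stopping (default 0.1; 0 disables early stopping).
#' @param keep_models Keep the per-fold trained models in the result.
#' @return Object of class `cv_result`: `scores` (pooled out-of-fold),
#'   `labels`, `fold`, `chosen` (NULL here), `models` (if kept).
#' @export
cross_validate <- function(samples, config, k = 10L, seed = 1L,
                           val_fraction = 0.1, keep_models = FALSE) {
  stopifnot(inherits(config, "model_config"))
  n <- nrow(samples)
  fa <- make_folds(n, k, seed)
  scores <- rep(NA_real_, n)
  models <- if (keep_models) vector("list", k) else NULL

  for (i in seq_len(k)) {
    test_idx <- which(fa$fold == i)
    train_idx <- which(fa$fold != i)
    cfg <- config
    cfg$seed <- as.integer((seed %% 1000003L) * 1000L + i)
    split <- .carve_validation(train_idx, val_fraction, cfg$seed,
                               samples$label[train_idx])
    fit <- train_model(cfg, samples[split$train, , drop = FALSE],
                       if (length(split$val)) samples[split$val, , drop = FALSE])
    scores[test_idx] <- predict(fit, samples$sequence[test_idx])
    if (keep_models) models[[i]] <- fit
  }
  structure(list(scores = scores, labels = as.integer(samples$label),
                 fold = fa$fold, chosen = NULL, models = models,
                 k = k, seed = seed),
            class = "cv_result")
}

# Split a training index set into train/validation, stratified by label so
# early stopping always sees both classes.
.carve_validation <- function(train_idx, val_fraction, seed, labels) {
  if (val_fraction <= 0) return(list(train = train_idx, val = integer()))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  val <- integer()
  for (cl in unique(labels)) {
    i <- train_idx[labels == cl]
    n_val <- max(1L, round(length(i) * val_fraction))
    val <- c(val, sample(i, n_val))
  }
  list(train = setdiff(train_idx, val), val = val)
}

#' Nested cross-validation with inner grid search
#'
#' For each outer fold, an inner k-fold cross-validation over the outer
#' training portion scores every hyperparameter combination in the grid by
#' mean inner validation AUC; the best combination is then refit on the full
#' merged outer training portion and scored on the untouched outer test
#' fold. No outer-test sample ever enters an inner training or selection
#' step.
#'
#' @param samples data.frame with `sequence` and `label` columns.
#' @param grid Named list of candidate values per tuned `model_config` field,
#'   e.g. `list(learning_rate = c(0.1, 0.01), dropout_p = c(0.25, 0.5))`.
#' @param config Base [model_config()] supplying the untuned fields.
#' @param k_outer,k_inner Fold counts (10 and 10 by default).
#' @param seed Master seed; all fold assignments and trainings derive from it.
#' @param val_fraction Early-stopping split carved from each refit, as in
#'   [cross_validate()].
#' @return A `cv_result` whose `chosen` element is a data.frame of the
#'   hyperparameters selected in each outer fold and whose `audit` element
#'   records, per outer fold, the outer test indices and every inner training
#'   index set (so the absence of selection leakage is checkable).
#' @export
nested_cv <- function(samples, grid, config = model_config(),
                      k_outer = 10L, k_inner = 10L, seed = 1L,
                      val_fraction = 0.1) {
  stopifnot(inherits(config, "model_config"))
  if (!is.list(grid) || length(grid) == 0L ||
      any(!nzchar(names(grid))) || any(vapply(grid, length, 1L) == 0L)) {
    stop("grid must be a non-empty named list with at least one value per field")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  n <- nrow(samples)
  fa <- make_folds(n, k_outer, seed)
  scores <- rep(NA_real_, n)
  chosen <- vector("list", k_outer)
  audit <- vector("list", k_outer)

  for (o in seq_len(k_outer)) {
    test_idx <- which(fa$fold == o)
    tr_idx <- which(fa$fold != o)
    fi <- make_folds(length(tr_idx), k_inner,
                     as.integer((seed %% 1000003L) * 100L + o))
    audit[[o]] <- list(test_idx = test_idx,
                       inner_train = lapply(seq_len(k_inner),
                                            function(j) tr_idx[fi$fold != j]))

    mean_auc <- numeric(nrow(combos))
    for (g in seq_len(nrow(combos))) {
      cfg <- .apply_combo(config, combos[g, , drop = FALSE])
      aucs <- numeric(k_inner)
      for (j in seq_len(k_inner)) {
        inner_val <- tr_idx[fi$fold == j]
        inner_train <- tr_idx[fi$fold != j]
        cfg$seed <- as.integer((seed %% 100003L) * 1000L + o * 37L + j)
        fit <- train_model(cfg, samples[inner_train, , drop = FALSE],
                           samples[inner_val, , drop = FALSE])
        aucs[j] <- roc_auc(predict(fit, samples$sequence[inner_val]),
                           samples$label[inner_val])
      }
      mean_auc[g] <- mean(aucs)
    }
    best <- which.max(mean_auc)
    chosen[[o]] <- cbind(fold = o, combos[best, , drop = FALSE],
                         mean_inner_auc = mean_auc[best])

    # all the outer-training data merged for the final per-fold refit
    cfg <- .apply_combo(config, combos[best, , drop = FALSE])
    cfg$seed <- as.integer((seed %% 1000003L) * 1000L + o)
    split <- .carve_validation(tr_idx, val_fraction, cfg$seed,
                               samples$label[tr_idx])
    fit <- train_model(cfg, samples[split$train, , drop = FALSE],
                       if (length(split$val)) samples[split$val, , drop = FALSE])
    scores[test_idx] <- predict(fit, samples$sequence[test_idx])
  }
  structure(list(scores = scores, labels = as.integer(samples$label),
                 fold = fa$fold,
                 chosen = do.call(rbind, chosen),
                 audit = audit,
                 models = NULL, k = k_outer, seed = seed),
            class = "cv_result")
}

.apply_combo <- function(config, combo) {
  for (nm in names(combo)) {
    if (!nm %in% names(config)) stop("unknown hyperparameter in grid: ", nm)
    config[[nm]] <- combo[[nm]]
  }
  # re-validate the architecture arithmetic after substitution
  config$dims <- feature_map_dims(config)
  config
}
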