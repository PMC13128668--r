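# Hyperparameter grid enumeration, stratified k-fold cross-validation, and
# best-configuration selection by mean MCC.

#' The default hyperparameter grid
#'
#' The eight axes with their candidate values; the Cartesian product holds
#' 1,296 configurations.
#'
#' @return Named list of axis values in the documented axis order
#'   (kernel_size, n_filters, n_layers, n_units, dropout, learning_rate,
#'   max_epochs, batch_size).
#' @export
default_grid <- function() {
  list(kernel_size = c(7L, 9L),
       n_filters = c(8L, 16L),
       n_layers = c(1L, 2L, 3L),
       n_units = list(512L, 1024L, "input_dim"),
       dropout = c(0.1, 0.2),
       learning_rate = c(1e-3, 1e-5),
       max_epochs = c(10L, 20L, 30L),
       batch_size = c(32L, 64L, 128L))
}

#' A reduced grid for desk-scale runs
#'
#' Eight configurations exercising the same code paths as the full search:
#' the published kernel, filter count, units rule, dropout, and learning
#' rate, crossed over layer depth, epoch budget and batch size.
#'
#' @return Named list of axis values.
#' @export
reduced_grid <- function() {
  list(kernel_size = 7L,
       n_filters = 8L,
       n_layers = c(1L, 2L),
       n_units = list("input_dim"),
       dropout = 0.2,
       learning_rate = 1e-3,
       max_epochs = c(10L, 20L),
       batch_size = c(32L, 64L))
}

#' Enumerate a hyperparameter grid
#'
#' Deterministic lexicographic enumeration over the axes in the documented
#' axis order (earlier axes vary slowest).
#'
#' @param grid Named list of axis values, as [default_grid()].
#' @param patience,seed Carried into every configuration.
#' @return List of [model_config()] objects.
#' @export
enumerate_grid <- function(grid = default_grid(), patience = 5L, seed = 1L) {
  axes <- c("kernel_size", "n_filters", "n_layers", "n_units", "dropout",
            "learning_rate", "max_epochs", "batch_size")
  stopifnot(setequal(names(grid), axes))
  lens <- vapply(grid[axes], length, integer(1))
  if (any(lens == 0L)) stop("empty grid axis: ",
                            paste(axes[lens == 0L], collapse = ", "))
  idx <- expand.grid(rev(lapply(lens, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(axes)), drop = FALSE]  # first axis slowest
  names(idx) <- axes
  lapply(seq_len(nrow(idx)), function(r) {
    val <- function(ax) {
      v <- grid[[ax]][[idx[r, ax]]]
      v
    }
    model_config(kernel_size = val("kernel_size"),
                 n_filters = val("n_filters"),
                 n_layers = val("n_layers"),
                 n_units = val("n_units"),
                 dropout = val("dropout"),
                 learning_rate = val("learning_rate"),
                 max_epochs = val("max_epochs"),
                 batch_size = val("batch_size"),
                 patience = patience, seed = seed)
  })
}

#' Stratified k-fold split
#'
#' Partitions the samples into `k` validation folds, stratified by class so
#' fold class counts differ by at most one; identical for identical seeds.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Seed for the (scoped) shuffling RNG.
#' @return List of `k` lists with integer `train` and `val` index vectors.
#' @export
kfold_split <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("fewer samples than folds")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  counts <- table(labels)
  if (any(counts < k)) {
    warning("class(es) with fewer than k samples: some folds will hold 0/1 ",
            "of: ", paste(names(counts)[counts < k], collapse = ", "))
  }
  fold_of <- integer(n)
  with_local_seed(combine_seed(seed, 104729L), {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), val = which(fold_of == f))
  })
}

#' Prepare a training-data bundle
#'
#' Computes, once, every per-sequence input the search needs: the
#' physicochemical descriptor matrix, the sequence-level embedding matrix,
#' and the residue-embedding array. Feature processing (z-score, ANOVA,
#' PCA) is deliberately NOT done here -- it is refit inside every
#' cross-validation fold on that fold's training rows.
#'
#' @param seqs Named character vector of validated sequences.
#' @param labels Character labels parallel to `seqs`.
#' @param embedder A `prohl_embedder`.
#' @param dconf A [descriptor_config()].
#' @param cache Optional embedding cache.
#' @return A `prohl_training_data` list.
#' @export
prepare_training_data <- function(seqs, labels, embedder,
                                  dconf = descriptor_config(), cache = NULL) {
  stopifnot(length(seqs) == length(labels),
            all(labels %in% label_levels()))
  x_phys <- encode_physchem(seqs, dconf)
  bundles <- embed_sequences(seqs, embedder, cache)
  inputs <- bundles_to_inputs(bundles)
  structure(list(ids = names(seqs), labels = labels,
                 y = as.numeric(labels == LABEL_LONG),
                 x_phys = x_phys, x_seq = inputs$xseq, ximg = inputs$ximg,
                 dconf = dconf, embedder_spec = embedder$spec),
            class = "prohl_training_data")
}

#' Cross-validate one configuration
#'
#' For each fold, the feature state (z-score, ANOVA mask, PCA basis) is
#' refit on the fold's training rows only, a fresh network is trained (the
#' fold's validation rows drive early stopping), and the six metrics are
#' evaluated on the validation rows. Fold means and standard errors (from
#' the k fold values) are reported.
#'
#' @param config A [model_config()].
#' @param data A [prepare_training_data()] bundle.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param feature_cfg A [feature_config()].
#' @param folds Optional precomputed folds from [kfold_split()] (so several
#'   configurations or ablation conditions share identical folds).
#' @return A `prohl_cv_result`: per-fold metric data frame plus `mean` and
#'   `se` per metric.
#' @export
cross_validate <- function(config, data, k = 10L, seed = 1L,
                           feature_cfg = feature_config(), folds = NULL) {
  stopifnot(inherits(data, "prohl_training_data"))
  if (is.null(folds)) folds <- kfold_split(data$labels, k, seed)
  fold_metrics <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$val
    state <- fit_feature_state(data$x_phys, data$x_seq, data$labels,
                               feature_cfg, train_idx = tr)
    feats <- apply_feature_state(state, data$x_phys, data$x_seq)
    model <- train_model(data$ximg[, , tr, drop = FALSE],
                         feats[tr, , drop = FALSE], data$y[tr],
                         data$ximg[, , va, drop = FALSE],
                         feats[va, , drop = FALSE], data$y[va],
                         config)
    pred <- predict_model(model, data$ximg[, , va, drop = FALSE],
                          feats[va, , drop = FALSE])
    m <- compute_metrics(confusion_counts(data$labels[va],
                                          pred$predicted_class))
    fold_metrics[[f]] <- as.data.frame(as.list(m))
  }
  fm <- do.call(rbind, fold_metrics)
  fm$fold <- seq_len(nrow(fm))
  structure(list(config = config,
                 fold_metrics = fm,
                 mean = colMeans(fm[, c("ACC", "SEN", "SPE", "PPV", "NPV", "MCC")]),
                 se = apply(fm[, c("ACC", "SEN", "SPE", "PPV", "NPV", "MCC")],
                            2L, stats::sd) / sqrt(nrow(fm))),
            class = "prohl_cv_result")
}

#' Select the best configuration by mean MCC
#'
#' Ties broken by enumeration order (first wins); failed configurations
#' (`NULL` entries) are excluded.
#'
#' @param cv_results List of `prohl_cv_result` (or `NULL` for failures), in
#'   enumeration order.
#' @return List with the winning `config`, its `cv` result, and its `index`.
#' @export
select_best <- function(cv_results) {
  ok <- !vapply(cv_results, is.null, logical(1))
  if (!any(ok)) stop("all configurations failed")
  mccs <- rep(-Inf, length(cv_results))
  mccs[ok] <- vapply(cv_results[ok], function(r) unname(r$mean["MCC"]),
                     numeric(1))
  best <- which.max(mccs)  # which.max returns the first maximum
  list(config = cv_results[[best]]$config, cv = cv_results[[best]],
       index = best)
}

#' Grid search with cross-validation
#'
#' Cross-validates every configuration on identical folds and selects the
#' one with the highest mean MCC. A configuration whose training fails is
#' recorded as failed and excluded from selection.
#'
#' @param configs List of configurations from [enumerate_grid()].
#' @param data A [prepare_training_data()] bundle.
#' @param k,seed,feature_cfg As in [cross_validate()].
#' @param verbose Print per-configuration progress.
#' @return List with `best` (see [select_best()]), `results`, and a summary
#'   data frame `table` (one row per configuration with mean/SE of all six
#'   metrics and MCC rank).
#' @export
grid_search <- function(configs, data, k = 10L, seed = 1L,
                        feature_cfg = feature_config(), verbose = FALSE) {
  folds <- kfold_split(data$labels, k, seed)
  results <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    results[[i]] <- tryCatch(
      cross_validate(configs[[i]], data, k, seed, feature_cfg, folds = folds),
      error = function(e) {
        message("configuration ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (verbose && !is.null(results[[i]])) {
      message(sprintf("config %d/%d: mean MCC %.3f", i, length(configs),
                      results[[i]]$mean["MCC"]))
    }
  }
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    base <- data.frame(index = i,
                       kernel_size = cfg$kernel_size,
                       n_filters = cfg$n_filters,
                       n_layers = cfg$n_layers,
                       n_units = as.character(cfg$n_units),
                       dropout = cfg$dropout,
                       learning_rate = cfg$learning_rate,
                       max_epochs = cfg$max_epochs,
                       batch_size = cfg$batch_size,
                       failed = is.null(results[[i]]),
                       stringsAsFactors = FALSE)
    if (is.null(results[[i]])) {
      for (mn in c("ACC", "SEN", "SPE", "PPV", "NPV", "MCC")) {
        base[[paste0("mean_", mn)]] <- NA_real_
        base[[paste0("se_", mn)]] <- NA_real_
      }
    } else {
      for (mn in c("ACC", "SEN", "SPE", "PPV", "NPV", "MCC")) {
        base[[paste0("mean_", mn)]] <- unname(results[[i]]$mean[mn])
        base[[paste0("se_", mn)]] <- unname(results[[i]]$se[mn])
      }
    }
    base
  })
  tab <- do.call(rbind, rows)
  tab$rank <- rank(-tab$mean_MCC, ties.method = "first", na.last = "keep")
  list(best = select_best(results), results = results, table = tab)
}
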