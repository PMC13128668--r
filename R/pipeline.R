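# End-to-end convenience layer: train a classifier from sequences and
# labels, predict on new sequences, and round-trip the trained artifact
# through a plain-text directory.

embedder_info <- function(embedder) {
  if (identical(embedder$spec$name, "synthetic")) {
    list(type = "synthetic", seed = embedder$seed,
         d_local = embedder$spec$d_local, d_global = embedder$spec$d_global,
         L_padded = embedder$spec$L_padded, signal_map = embedder$signal_map)
  } else {
    list(type = "pretrained", path = attr(embedder, "path"),
         spec = unclass(embedder$spec))
  }
}

embedder_from_info <- function(info) {
  if (identical(info$type, "synthetic")) {
    synthetic_embedder(info$seed, info$d_local, info$d_global, info$L_padded,
                       info$signal_map)
  } else {
    pretrained_embedder(info$path)
  }
}

#' Train a half-life classifier end to end
#'
#' Splits the labelled set into a training portion and a stratified
#' early-stopping validation portion, fits the feature state (z-score,
#' ANOVA selection, PCA) on the training portion only, trains the network,
#' and returns a self-contained classifier.
#'
#' @param seqs Named character vector of validated sequences.
#' @param labels Character labels parallel to `seqs`.
#' @param embedder A `prohl_embedder`.
#' @param config A [model_config()].
#' @param dconf,fconf Descriptor and feature-processing configurations.
#' @param val_fraction Fraction held out for early stopping (stratified).
#' @param seed Split seed.
#' @return A `prohl_classifier`.
#' @export
prohl_train <- function(seqs, labels, embedder, config = model_config(),
                        dconf = descriptor_config(), fconf = feature_config(),
                        val_fraction = 0.15, seed = 1L) {
  data <- prepare_training_data(seqs, labels, embedder, dconf)
  k <- max(2L, round(1 / val_fraction))
  fold <- kfold_split(data$labels, k = k, seed = seed)[[1L]]
  state <- fit_feature_state(data$x_phys, data$x_seq, data$labels, fconf,
                             train_idx = fold$train)
  feats <- apply_feature_state(state, data$x_phys, data$x_seq)
  model <- train_model(data$ximg[, , fold$train, drop = FALSE],
                       feats[fold$train, , drop = FALSE], data$y[fold$train],
                       data$ximg[, , fold$val, drop = FALSE],
                       feats[fold$val, , drop = FALSE], data$y[fold$val],
                       config)
  structure(list(model = model, feature_state = state, dconf = dconf,
                 fconf = fconf, embedder_info = embedder_info(embedder),
                 seed = as.integer(seed)),
            class = "prohl_classifier")
}

#' Predict stability classes for new sequences
#'
#' Validates each record against the prediction contract (standard residues,
#' length 50-1655); invalid records yield a per-record error note while the
#' batch continues. A probability of exactly 0.5 is classed long-lived.
#'
#' @param classifier A `prohl_classifier`.
#' @param seqs Named character vector of query sequences.
#' @param embedder Optional embedder; by default reconstructed from the
#'   classifier's stored embedder description.
#' @return Data frame `id`, `probability_long_lived`, `predicted_class`,
#'   `note` (`NA` for clean records).
#' @export
prohl_predict <- function(classifier, seqs, embedder = NULL) {
  stopifnot(inherits(classifier, "prohl_classifier"))
  if (is.null(embedder)) embedder <- embedder_from_info(classifier$embedder_info)
  report <- validate_for_prediction(seqs, collect = TRUE)
  out <- data.frame(id = names(seqs),
                    probability_long_lived = NA_real_,
                    predicted_class = NA_character_,
                    note = report$reason,
                    stringsAsFactors = FALSE)
  ok <- report$ok
  if (any(ok)) {
    good <- seqs[ok]
    x_phys <- encode_physchem(good, classifier$dconf)
    inputs <- bundles_to_inputs(embed_sequences(good, embedder))
    feats <- apply_feature_state(classifier$feature_state, x_phys, inputs$xseq)
    pred <- predict_model(classifier$model, inputs$ximg, feats)
    out$probability_long_lived[ok] <- pred$probability_long_lived
    out$predicted_class[ok] <- pred$predicted_class
  }
  out
}

#' Save a trained classifier to a plain-text directory
#'
#' Writes `classifier.json` (all weights, feature state, and configuration,
#' serialized losslessly enough for prediction-identical round trips) plus
#' a human-readable `training_log.tsv`.
#'
#' @param classifier A `prohl_classifier`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "prohl_classifier"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  payload <- classifier
  payload$model$log <- NULL
  json <- jsonlite::serializeJSON(payload, digits = 17)
  writeLines(json, file.path(path, "classifier.json"))
  utils::write.table(classifier$model$log, file.path(path, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path Directory containing `classifier.json`.
#' @return A `prohl_classifier`.
#' @export
load_classifier <- function(path) {
  f <- file.path(path, "classifier.json")
  if (!file.exists(f)) stop("no classifier.json under ", path)
  cls <- jsonlite::unserializeJSON(paste(readLines(f), collapse = "\n"))
  stopifnot(inherits(cls, "prohl_classifier"))
  cls
}
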