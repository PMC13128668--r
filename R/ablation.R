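# Leave-one-group-out ablation of the four physicochemical descriptor
# groups, plus the all-groups-removed condition. Embeddings always remain
# in the model; only descriptor columns are dropped, and everything
# downstream (z-score, ANOVA, PCA, network width via the "input_dim" units
# rule) is refit per fold under identical folds and seed.

#' The standard ablation plan
#'
#' Condition 0 is the full model (empty exclusion), followed by each single
#' descriptor group and the all-groups-removed condition.
#'
#' @return List of conditions, each `list(name, exclude)`.
#' @export
ablation_plan <- function() {
  groups <- descriptor_group_levels()
  c(list(list(name = "none", exclude = character(0))),
    lapply(groups, function(g) list(name = g, exclude = g)),
    list(list(name = "all_groups", exclude = groups)))
}

# drop the columns of the excluded groups from a training-data bundle
exclude_groups <- function(data, exclude) {
  if (length(exclude) == 0L) return(data)
  bad <- setdiff(exclude, descriptor_group_levels())
  if (length(bad)) stop("unknown descriptor group(s): ",
                        paste(bad, collapse = ", "))
  groups <- attr(data$x_phys, "groups")
  keep <- !(groups %in% exclude)
  x <- data$x_phys[, keep, drop = FALSE]
  attr(x, "groups") <- groups[keep]
  data$x_phys <- x
  data
}

#' Run a leave-one-group-out ablation
#'
#' Cross-validates the fixed base configuration under every condition of
#' the plan, reusing identical folds and seed, with no re-search of
#' hyperparameters per condition (the `"input_dim"` units rule re-resolves
#' to each condition's reduced width).
#'
#' @param data A [prepare_training_data()] bundle.
#' @param config The base [model_config()].
#' @param k,seed,feature_cfg As in [cross_validate()].
#' @param plan Conditions from [ablation_plan()].
#' @return A `prohl_ablation_report` data frame: one row per condition with
#'   `condition`, `excluded`, `mean_MCC`, `se_MCC`, and `delta_MCC` versus
#'   the baseline (condition `"none"`).
#' @export
run_ablation <- function(data, config, k = 10L, seed = 1L,
                         feature_cfg = feature_config(),
                         plan = ablation_plan()) {
  stopifnot(inherits(data, "prohl_training_data"))
  folds <- kfold_split(data$labels, k, seed)
  rows <- lapply(plan, function(cond) {
    cv <- cross_validate(config, exclude_groups(data, cond$exclude), k, seed,
                         feature_cfg, folds = folds)
    data.frame(condition = cond$name,
               excluded = paste(cond$exclude, collapse = "+"),
               mean_MCC = unname(cv$mean["MCC"]),
               se_MCC = unname(cv$se["MCC"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- out$mean_MCC[out$condition == "none"]
  if (length(base) != 1L) stop("the plan must contain the baseline condition")
  out$delta_MCC <- out$mean_MCC - base
  class(out) <- c("prohl_ablation_report", class(out))
  out
}

#' Format an ablation report for output
#'
#' @param report A report from [run_ablation()].
#' @return Data frame sorted by `delta_MCC` ascending (most damaging
#'   exclusion first).
#' @export
format_ablation <- function(report) {
  out <- as.data.frame(report)[order(report$delta_MCC), , drop = FALSE]
  rownames(out) <- NULL
  out
}
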