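# Fit-and-apply feature processing: z-score normalization and ANOVA
# selection of the physicochemical block, PCA reduction of sequence-level
# embeddings. State is fitted on training rows only and frozen; applying it
# never refits, which is what makes per-fold refitting leak-free.

#' Feature-processing configuration
#'
#' @param anova_alpha Keep a physicochemical feature iff its two-class ANOVA
#'   p-value is `<= anova_alpha` (default 0.01).
#' @param pca_variance Retain the smallest number of principal components
#'   whose cumulative explained variance reaches this fraction (default
#'   0.95).
#' @return A `prohl_feature_config` list.
#' @export
feature_config <- function(anova_alpha = 0.01, pca_variance = 0.95) {
  stopifnot(anova_alpha > 0, anova_alpha < 1,
            pca_variance > 0, pca_variance <= 1)
  structure(list(anova_alpha = anova_alpha, pca_variance = pca_variance),
            class = "prohl_feature_config")
}

#' Fit per-column z-score statistics
#'
#' @param x Numeric matrix (rows = samples).
#' @return List with `mean`, `sd` (sample convention, n-1), and `keep`
#'   (FALSE for zero-variance columns, which are force-dropped downstream).
#' @export
fit_zscore <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L) stop("z-score fit needs >= 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  list(mean = mu, sd = sdv, keep = sdv > 0)
}

apply_zscore <- function(stats, x) {
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, ifelse(stats$keep, stats$sd, 1), "/")
}

#' Two-class ANOVA feature selection
#'
#' One-way ANOVA F-test per feature between the two classes; for two groups
#' the F statistic with (1, n-2) degrees of freedom equals the square of the
#' pooled two-sample t statistic. A feature is kept iff its p-value is at
#' most `alpha`.
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels Two-class label vector (each class needs >= 2 samples).
#' @param alpha Significance threshold.
#' @return List with `F`, `p`, and logical `keep` per column.
#' @export
anova_select <- function(x, labels, alpha = 0.01) {
  cls <- unique(labels)
  if (length(cls) != 2L) stop("exactly two classes are required")
  g1 <- labels == cls[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  n <- n1 + n2
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  m <- colMeans(x)
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2L, m1, "-")^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2L, m2, "-")^2)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  keep <- !is.na(p) & p <= alpha
  list(F = f, p = p, keep = keep)
}

#' Fit a PCA basis retaining a target variance fraction
#'
#' Centres but does not rescale the input (embedding coordinates are already
#' on one scale) and keeps the smallest number of components whose
#' cumulative explained-variance fraction reaches `variance`.
#'
#' @param x Numeric matrix (rows = samples).
#' @param variance Retained variance fraction in `(0, 1]`.
#' @return List with `center`, orthonormal `rotation`
#'   (columns = components), and per-component `explained` fractions.
#' @export
fit_pca <- function(x, variance = 0.95) {
  if (is.null(dim(x)) || nrow(x) < 2L) stop("PCA fit needs >= 2 rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) stop("degenerate (rank-0) input to PCA")
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance - 1e-12)[1L]
  list(center = pc$center,
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)])
}

#' Fit the frozen feature-processing state
#'
#' Fits z-score statistics and the ANOVA selection mask on the
#' physicochemical block and the PCA basis on the sequence-level embedding
#' block, using only the rows in `train_idx`. Rows outside `train_idx` never
#' influence the state (the leakage guard property).
#'
#' @param x_phys Physicochemical descriptor matrix (samples x features),
#'   with column names.
#' @param x_seq Sequence-level embedding matrix (samples x d_global).
#' @param labels Two-class labels, parallel to the rows.
#' @param config A [feature_config()].
#' @param train_idx Row indices to fit on (default: all rows).
#' @return A `prohl_feature_state`.
#' @export
fit_feature_state <- function(x_phys, x_seq, labels,
                              config = feature_config(), train_idx = NULL) {
  stopifnot(inherits(config, "prohl_feature_config"),
            nrow(x_phys) == nrow(x_seq), nrow(x_phys) == length(labels))
  if (is.null(train_idx)) train_idx <- seq_len(nrow(x_phys))
  xp <- x_phys[train_idx, , drop = FALSE]
  xs <- x_seq[train_idx, , drop = FALSE]
  y <- labels[train_idx]
  zs <- fit_zscore(xp)
  sel <- list(F = rep(NA_real_, ncol(xp)), p = rep(NA_real_, ncol(xp)),
              keep = rep(FALSE, ncol(xp)))
  if (any(zs$keep)) {
    zsub <- apply_zscore(zs, xp)[, zs$keep, drop = FALSE]
    a <- anova_select(zsub, y, config$anova_alpha)
    sel$F[zs$keep] <- a$F
    sel$p[zs$keep] <- a$p
    sel$keep[zs$keep] <- a$keep
  }
  pca <- fit_pca(xs, config$pca_variance)
  structure(list(phys_names = colnames(x_phys),
                 phys_groups = attr(x_phys, "groups"),
                 zscore = zs, anova = sel, pca = pca, config = config),
            class = "prohl_feature_state")
}

#' Apply a fitted feature state
#'
#' Transforms new samples using training statistics only: z-scores and
#' mask-selects the physicochemical block, projects the embedding block
#' onto the fitted PCA basis, and concatenates the two.
#'
#' @param state A `prohl_feature_state`.
#' @param x_phys,x_seq Matrices with the same columns as at fit time.
#' @return Numeric matrix with column provenance in attribute
#'   `"provenance"` (`"phys"` or `"embedding"` per column).
#' @export
apply_feature_state <- function(state, x_phys, x_seq) {
  stopifnot(inherits(state, "prohl_feature_state"))
  if (!identical(colnames(x_phys), state$phys_names)) {
    bad <- c(setdiff(state$phys_names, colnames(x_phys)),
             setdiff(colnames(x_phys), state$phys_names))
    stop("physicochemical columns do not match the fitted state: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  keep <- state$anova$keep
  z <- apply_zscore(state$zscore, x_phys)[, keep, drop = FALSE]
  pcs <- sweep(x_seq, 2L, state$pca$center, "-") %*% state$pca$rotation
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  out <- cbind(z, pcs)
  attr(out, "provenance") <- c(rep("phys", ncol(z)),
                               rep("embedding", ncol(pcs)))
  out
}

#' Checksum of a fitted feature state
#'
#' Order-sensitive fingerprint of every fitted statistic; two states with
#' the same checksum were fitted on the same data with the same
#' configuration.
#'
#' @param state A `prohl_feature_state`.
#' @return Integer checksum.
#' @export
state_checksum <- function(state) {
  fingerprint(list(state$zscore, state$anova, state$pca,
                   unclass(state$config)))
}

#' Feature-selection report
#'
#' @param state A `prohl_feature_state`.
#' @return Data frame listing every physicochemical feature, its group, its
#'   ANOVA p-value, and whether it was kept.
#' @export
feature_report <- function(state) {
  data.frame(feature = state$phys_names,
             group = state$phys_groups,
             p_value = state$anova$p,
             kept = state$anova$keep,
             stringsAsFactors = FALSE)
}
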