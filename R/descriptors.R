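# The four physicochemical descriptor families, each tagged with its
# ablation group:
#   GAPPED_KMER         - CKSAAP, composition of k-spaced amino-acid pairs
#   GROUPED_COMPOSITION - DDE, dipeptide deviation from expected mean
#   PHYSCHEM_PROPERTY   - CTD, composition / transition / distribution
#   SEQUENCE_ORDER      - Moran autocorrelation and the sequence-order
#                         coupling number
#
# Masked residues (X) take part in no descriptor term: pairs or positions
# involving X are skipped and denominators count only valid terms.

#' The four descriptor ablation groups
#'
#' @return Character vector of the group tags, in canonical order.
#' @export
descriptor_group_levels <- function() {
  c("GAPPED_KMER", "GROUPED_COMPOSITION", "PHYSCHEM_PROPERTY", "SEQUENCE_ORDER")
}

# residue indices into aa_alphabet(); NA for masked X
aa_index <- function(sequence) {
  match(strsplit(sequence, "")[[1]], aa_alphabet())
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each gap `g` in `0..max_gap` and each ordered residue pair `(a, b)`,
#' the frequency of positions `i` with `seq[i] = a` and `seq[i + g + 1] = b`,
#' normalised by the number of pairs at that gap, so each gap block sums
#' to 1.
#'
#' @param sequence A single sequence.
#' @param max_gap Largest gap (default 5, giving 6 blocks of 400 features).
#' @return Named numeric vector of length `400 * (max_gap + 1)`.
#' @export
cksaap <- function(sequence, max_gap = 5L) {
  idx <- aa_index(sequence)
  L <- length(idx)
  if (L <= max_gap + 1L) stop("sequence too short for gap ", max_gap)
  aa <- aa_alphabet()
  pair_names <- as.vector(t(outer(aa, aa, paste0)))  # AA, AC, ..., YY
  out <- numeric(0)
  for (g in 0:max_gap) {
    i1 <- idx[seq_len(L - g - 1L)]
    i2 <- idx[seq.int(g + 2L, L)]
    valid <- !is.na(i1) & !is.na(i2)
    counts <- tabulate((i1[valid] - 1L) * 20L + i2[valid], nbins = 400L)
    denom <- sum(valid)
    block <- if (denom > 0) counts / denom else numeric(400L)
    names(block) <- paste0("CKSAAP.g", g, ".", pair_names)
    out <- c(out, block)
  }
  out
}

#' Dipeptide deviation from expected mean (DDE)
#'
#' For each dipeptide `(a, b)`: the observed frequency `Dc` is standardized
#' against its codon-usage expectation `Tm = (Ca/61)(Cb/61)` with variance
#' `Tv = Tm (1 - Tm) / N` where `N` is the number of dipeptides, yielding
#' `(Dc - Tm) / sqrt(Tv)`.
#'
#' @param sequence A single sequence (length >= 2).
#' @return Named numeric vector of length 400.
#' @export
dde <- function(sequence) {
  idx <- aa_index(sequence)
  L <- length(idx)
  if (L < 2L) stop("DDE requires length >= 2")
  aa <- aa_alphabet()
  i1 <- idx[seq_len(L - 1L)]
  i2 <- idx[seq.int(2L, L)]
  valid <- !is.na(i1) & !is.na(i2)
  n_pairs <- sum(valid)
  if (n_pairs == 0L) stop("no valid dipeptides in sequence")
  dc <- tabulate((i1[valid] - 1L) * 20L + i2[valid], nbins = 400L) / n_pairs
  cc <- codon_counts() / 61
  tm <- as.vector(t(outer(cc, cc)))  # a-major order matching pair names
  tv <- tm * (1 - tm) / n_pairs
  out <- (dc - tm) / sqrt(tv)
  names(out) <- paste0("DDE.", as.vector(t(outer(aa, aa, paste0))))
  out
}

#' Composition / transition / distribution (CTD)
#'
#' For each of the seven physicochemical attributes of [ctd_attributes()],
#' with the alphabet partitioned into three classes: the three class
#' fractions (composition), the three between-class adjacent-pair
#' frequencies (transition), and, per class, the positions of the first,
#' 25th-, 50th-, 75th-percentile, and last residue of that class as a
#' percentage of sequence length (0 when the class is absent)
#' (distribution).
#'
#' @param sequence A single sequence (length >= 2).
#' @return Named numeric vector of length 147 (7 x 21).
#' @export
ctd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2L) stop("CTD requires length >= 2")
  attrs <- ctd_attributes()
  out <- numeric(0)
  for (an in names(attrs)) {
    cls <- rep(NA_integer_, L)
    for (k in 1:3) cls[chars %in% attrs[[an]][[k]]] <- k
    n_valid <- sum(!is.na(cls))
    comp <- if (n_valid > 0) tabulate(cls, 3L) / n_valid else numeric(3L)
    a <- cls[seq_len(L - 1L)]
    b <- cls[seq.int(2L, L)]
    ok <- !is.na(a) & !is.na(b)
    np <- sum(ok)
    lo <- pmin(a[ok], b[ok])
    hi <- pmax(a[ok], b[ok])
    trans <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
               sum(lo == 2 & hi == 3))
    trans <- if (np > 0) trans / np else numeric(3L)
    dist <- numeric(0)
    for (k in 1:3) {
      pos <- which(cls == k)
      n <- length(pos)
      d <- if (n == 0L) numeric(5L) else
        pos[c(1L, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)] / L * 100
      names(d) <- paste0("CTD.", an, ".dist.c", k, ".",
                         c("first", "p25", "p50", "p75", "last"))
      dist <- c(dist, d)
    }
    names(comp) <- paste0("CTD.", an, ".comp.c", 1:3)
    names(trans) <- paste0("CTD.", an, ".trans.", c("c1c2", "c1c3", "c2c3"))
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Moran autocorrelation
#'
#' For each property scale (standardized to zero mean and unit population
#' variance over the 20 residues) and each lag `d`, the normalised lag-`d`
#' autocovariance of the property profile along the sequence:
#' `I(d) = mean over i of (P_i - Pbar)(P_{i+d} - Pbar) / mean of
#' (P_i - Pbar)^2`, with `Pbar` the sequence mean of the profile. A
#' zero-variance profile (e.g. a homopolymer) yields 0 for all lags.
#'
#' @param sequence A single sequence.
#' @param n_lag Number of lags (default 30; requires length > `n_lag`).
#' @param scales Property matrix as from [aa_property_scales()].
#' @return Named numeric vector of length `nrow(scales) * n_lag`.
#' @export
moran <- function(sequence, n_lag = 30L, scales = aa_property_scales()) {
  idx <- aa_index(sequence)
  L <- length(idx)
  if (n_lag >= L) stop("n_lag must be smaller than the sequence length")
  zscales <- t(apply(scales, 1, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }))
  out <- numeric(0)
  for (pn in rownames(zscales)) {
    prof <- zscales[pn, ][idx]
    valid <- !is.na(prof)
    vals <- numeric(n_lag)
    if (sum(valid) > 0) {
      pbar <- mean(prof[valid])
      dev <- prof - pbar
      den <- mean(dev[valid]^2)
      if (den > 0) {
        for (d in seq_len(n_lag)) {
          a <- dev[seq_len(L - d)]
          b <- dev[seq.int(d + 1L, L)]
          ok <- !is.na(a) & !is.na(b)
          if (any(ok)) vals[d] <- mean(a[ok] * b[ok]) / den
        }
      }
    }
    names(vals) <- paste0("MORAN.", pn, ".lag", seq_len(n_lag))
    out <- c(out, vals)
  }
  out
}

#' Sequence-order coupling numbers (SOCN)
#'
#' `tau_d = sum over i of dist(seq[i], seq[i+d])^2` for `d` in `1..n_lag`,
#' with `dist` a pairwise physicochemical distance between residues.
#'
#' @param sequence A single sequence.
#' @param n_lag Number of lags (default 30; requires length > `n_lag`).
#' @param dist_matrix Symmetric residue distance matrix as from
#'   [aa_distance_matrix()].
#' @return Named numeric vector of length `n_lag`.
#' @export
socn <- function(sequence, n_lag = 30L, dist_matrix = aa_distance_matrix()) {
  idx <- aa_index(sequence)
  L <- length(idx)
  if (n_lag >= L) stop("n_lag must be smaller than the sequence length")
  d2 <- dist_matrix^2
  out <- numeric(n_lag)
  for (d in seq_len(n_lag)) {
    a <- idx[seq_len(L - d)]
    b <- idx[seq.int(d + 1L, L)]
    ok <- !is.na(a) & !is.na(b)
    out[d] <- sum(d2[cbind(a[ok], b[ok])])
  }
  names(out) <- paste0("SOCN.lag", seq_len(n_lag))
  out
}

#' Descriptor configuration
#'
#' @param max_gap CKSAAP maximum gap.
#' @param moran_nlag,socn_nlag Lag counts for the sequence-order family.
#' @param scales Moran property scales.
#' @param dist_matrix SOCN residue distance matrix.
#' @return A `prohl_descriptor_config` list.
#' @export
descriptor_config <- function(max_gap = 5L, moran_nlag = 30L, socn_nlag = 30L,
                              scales = aa_property_scales(),
                              dist_matrix = aa_distance_matrix()) {
  stopifnot(max_gap >= 0, moran_nlag >= 1, socn_nlag >= 1)
  structure(list(max_gap = as.integer(max_gap),
                 moran_nlag = as.integer(moran_nlag),
                 socn_nlag = as.integer(socn_nlag),
                 scales = scales, dist_matrix = dist_matrix),
            class = "prohl_descriptor_config")
}

#' Encode sequences as physicochemical descriptor matrices
#'
#' Concatenates the four descriptor families in canonical order (CKSAAP,
#' DDE, CTD, Moran, SOCN; alphabetical residue order within families,
#' ascending gap/lag) and tags every feature with its ablation group.
#'
#' @param seqs Named character vector of sequences.
#' @param config A [descriptor_config()].
#' @return Numeric matrix (sequences x features) with an attribute
#'   `"groups"`: a character vector over [descriptor_group_levels()]
#'   parallel to the columns.
#' @export
encode_physchem <- function(seqs, config = descriptor_config()) {
  stopifnot(inherits(config, "prohl_descriptor_config"))
  encode_one <- function(s) {
    c(cksaap(s, config$max_gap),
      dde(s),
      ctd(s),
      moran(s, config$moran_nlag, config$scales),
      socn(s, config$socn_nlag, config$dist_matrix))
  }
  rows <- lapply(seqs, encode_one)
  x <- do.call(rbind, rows)
  rownames(x) <- names(seqs)
  groups <- descriptor_groups(config)
  stopifnot(identical(colnames(x), names(groups)))
  attr(x, "groups") <- unname(groups)
  x
}

#' Group tag per descriptor feature
#'
#' @param config A [descriptor_config()].
#' @return Named character vector: feature name -> ablation group.
#' @export
descriptor_groups <- function(config = descriptor_config()) {
  probe <- strrep(paste(aa_alphabet(), collapse = ""), 4)  # 80-mer covering all residues
  v <- c(
    stats::setNames(rep("GAPPED_KMER", 400L * (config$max_gap + 1L)),
                    names(cksaap(probe, config$max_gap))),
    stats::setNames(rep("GROUPED_COMPOSITION", 400L), names(dde(probe))),
    stats::setNames(rep("PHYSCHEM_PROPERTY", 147L), names(ctd(probe))),
    stats::setNames(rep("SEQUENCE_ORDER",
                        nrow(config$scales) * config$moran_nlag),
                    names(moran(probe, config$moran_nlag, config$scales))),
    stats::setNames(rep("SEQUENCE_ORDER", config$socn_nlag),
                    names(socn(probe, config$socn_nlag, config$dist_matrix)))
  )
  v
}
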