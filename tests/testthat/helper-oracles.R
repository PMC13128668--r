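# Independent brute-force oracles used to check the descriptor, alignment,
# and metric implementations. Deliberately written in the most literal way
# (per-position loops, paste/table counting) rather than sharing any code
# with the package.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# quadratic-time global aligner, match = 1 / mismatch = 0 / gap = 0
oracle_align_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- max(D[i, j] + (x[i] == y[j]),
                               D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

oracle_cksaap <- function(sequence, max_gap = 5L) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  pair_levels <- as.vector(t(outer(AA, AA, paste0)))
  out <- numeric(0)
  for (g in 0:max_gap) {
    pairs <- paste0(chars[1:(L - g - 1)], chars[(g + 2):L])
    counts <- table(factor(pairs, levels = pair_levels))
    block <- as.numeric(counts) / (L - g - 1)
    names(block) <- paste0("CKSAAP.g", g, ".", pair_levels)
    out <- c(out, block)
  }
  out
}

oracle_dde <- function(sequence) {
  codons <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
              K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
              T = 4, V = 4, W = 1, Y = 2)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  pair_levels <- as.vector(t(outer(AA, AA, paste0)))
  pairs <- paste0(chars[1:(L - 1)], chars[2:L])
  dc <- as.numeric(table(factor(pairs, levels = pair_levels))) / (L - 1)
  out <- numeric(400)
  k <- 0
  for (a in AA) {
    for (b in AA) {
      k <- k + 1
      tm <- (codons[[a]] / 61) * (codons[[b]] / 61)
      tv <- tm * (1 - tm) / (L - 1)
      out[k] <- (dc[k] - tm) / sqrt(tv)
    }
  }
  names(out) <- paste0("DDE.", pair_levels)
  out
}

oracle_ctd_groups <- list(
  hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  vdw_volume = c("GASCTPD", "NVEQIL", "MHKFRYW"),
  polarity = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondary_structure = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_accessibility = c("ALFCGIVW", "RKQEND", "MSPTHY"))

oracle_ctd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (an in names(oracle_ctd_groups)) {
    sets <- lapply(oracle_ctd_groups[[an]], function(s) strsplit(s, "")[[1]])
    cls <- vapply(chars, function(ch) which(vapply(sets, function(s) ch %in% s,
                                                   logical(1))), integer(1))
    comp <- vapply(1:3, function(k) sum(cls == k) / L, numeric(1))
    trans <- numeric(3)
    for (i in 1:(L - 1)) {
      pr <- sort(c(cls[i], cls[i + 1]))
      if (pr[1] == 1 && pr[2] == 2) trans[1] <- trans[1] + 1
      if (pr[1] == 1 && pr[2] == 3) trans[2] <- trans[2] + 1
      if (pr[1] == 2 && pr[2] == 3) trans[3] <- trans[3] + 1
    }
    trans <- trans / (L - 1)
    dist <- numeric(0)
    for (k in 1:3) {
      pos <- which(cls == k)
      n <- length(pos)
      d <- if (n == 0) rep(0, 5) else
        pos[c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)] / L * 100
      dist <- c(dist, d)
    }
    out <- c(out, comp, trans, dist)
  }
  unname(out)
}

oracle_moran <- function(sequence, n_lag, scales) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (pn in rownames(scales)) {
    v <- scales[pn, ]
    z <- (v - mean(v)) / sqrt(sum((v - mean(v))^2) / length(v))
    prof <- z[chars]
    pbar <- mean(prof)
    den <- sum((prof - pbar)^2) / L
    vals <- numeric(n_lag)
    if (den > 0) {
      for (d in 1:n_lag) {
        s <- 0
        for (i in 1:(L - d)) s <- s + (prof[i] - pbar) * (prof[i + d] - pbar)
        vals[d] <- (s / (L - d)) / den
      }
    }
    out <- c(out, vals)
  }
  unname(out)
}

oracle_socn <- function(sequence, n_lag, dist_matrix) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(n_lag)
  for (d in 1:n_lag) {
    s <- 0
    for (i in 1:(L - d)) s <- s + dist_matrix[chars[i], chars[i + d]]^2
    out[d] <- s
  }
  out
}

oracle_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den > 0) num / den else 0
  mccd <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(ACC = (tp + tn) / (tp + tn + fp + fn),
    SEN = div(tp, tp + fn),
    SPE = div(tn, tn + fp),
    PPV = div(tp, tp + fp),
    NPV = div(tn, tn + fn),
    MCC = if (mccd > 0) (tp * tn - fp * fn) / sqrt(mccd) else 0)
}
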