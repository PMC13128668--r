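# Length filtering and greedy identity-based redundancy reduction of
# training sets.

#' Drop sequences shorter than a minimum length
#'
#' @param seqs Named character vector of sequences.
#' @param min_length Minimum retained length (default 50, the shortest
#'   protein the classifier accepts).
#' @return The retained sequences, input order preserved.
#' @export
length_filter <- function(seqs, min_length = 50L) {
  seqs[nchar(seqs) >= min_length]
}

#' Pairwise sequence identity
#'
#' Identity between two sequences: the number of identical residues in an
#' optimal global alignment under pure identity maximisation (match = 1,
#' mismatch = 0, gap = 0 -- i.e. the longest common subsequence), divided by
#' the length of the shorter sequence. Symmetric and in `[0, 1]`.
#'
#' @param a,b Sequences (single strings).
#' @return Identity fraction.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("identity of an empty sequence is undefined")
  lcs_length_cpp(a, b) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of sequences
#'
#' Greedy incremental clustering in the style of CD-HIT, without the k-mer
#' prefilter (exact alignment is affordable at desk scale): sequences are
#' sorted longest-first (ties broken by id), and each sequence joins the
#' first existing cluster whose representative is at least `identity_cutoff`
#' identical to it, otherwise it founds a new cluster. The representative of
#' a cluster is therefore always its longest member, and the result does not
#' depend on input order.
#'
#' @param seqs Named character vector of sequences.
#' @param identity_cutoff Identity threshold in `(0, 1]` (default 0.5).
#' @return Data frame with columns `cluster` (1-based index in creation
#'   order), `representative_id`, `member_id`.
#' @export
greedy_cluster <- function(seqs, identity_cutoff = 0.5) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1)
  if (length(seqs) == 0L) {
    return(data.frame(cluster = integer(0), representative_id = character(0),
                      member_id = character(0), stringsAsFactors = FALSE))
  }
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  rep_idx <- integer(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- 0L
    for (k in seq_along(rep_idx)) {
      if (pairwise_identity(seqs[[rep_idx[k]]], seqs[[i]]) >= identity_cutoff) {
        placed <- k
        break
      }
    }
    if (placed == 0L) {
      rep_idx <- c(rep_idx, i)
      placed <- length(rep_idx)
    }
    assignment[i] <- placed
  }
  data.frame(cluster = assignment,
             representative_id = names(seqs)[rep_idx][assignment],
             member_id = names(seqs),
             stringsAsFactors = FALSE)[order(assignment), , drop = FALSE]
}

#' Representative sequences of a clustering
#'
#' @param clusters Data frame from [greedy_cluster()].
#' @param seqs The clustered sequences.
#' @return Named character vector of one representative per cluster, in
#'   cluster order.
#' @export
cluster_representatives <- function(clusters, seqs) {
  reps <- clusters$representative_id[!duplicated(clusters$cluster)]
  seqs[reps]
}

#' Write a cluster table as TSV
#'
#' @param clusters Data frame from [greedy_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
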