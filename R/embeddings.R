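# Residue-level and sequence-level protein representations behind a
# pluggable embedder contract.
#
# The synthetic embedder makes the whole pipeline runnable and testable with
# no model download: its output is a deterministic hash-seeded function of
# sequence content, so it carries no generalisable sequence structure beyond
# an optional planted signal (a stated shift of the first sequence-vector
# coordinate when a motif is present). The pretrained adapter reads
# embeddings exported to plain-text files by an external language-model run.

#' Embedder specification
#'
#' @param name Embedder name.
#' @param d_local Residue-level embedding dimension.
#' @param d_global Sequence-level embedding dimension.
#' @param L_padded Fixed padded sequence length (default 1655, the longest
#'   accepted protein).
#' @return A `prohl_embedder_spec` list.
#' @export
embedder_spec <- function(name, d_local, d_global, L_padded = 1655L) {
  stopifnot(d_local >= 1, d_global >= 1, L_padded >= 1)
  structure(list(name = name, d_local = as.integer(d_local),
                 d_global = as.integer(d_global),
                 L_padded = as.integer(L_padded)),
            class = "prohl_embedder_spec")
}

#' Deterministic synthetic embedder
#'
#' Embeddings are drawn from a pseudo-random stream seeded by
#' `(seed, hash(sequence))`, so the same sequence always maps to the same
#' bundle (content-addressed, independent of record id) and different
#' sequences collide with negligible probability. Because each sequence's
#' embedding is an arbitrary function of the whole sequence, the synthetic
#' embedder deliberately carries no learnable sequence signal of its own;
#' `signal_map` plants one of known effect size for recovery tests.
#'
#' @param seed Integer seed.
#' @param d_local,d_global,L_padded Dimensions, see [embedder_spec()].
#' @param signal_map Optional `list(pattern =, effect =)`: sequences
#'   matching the regular expression `pattern` have `effect` added to the
#'   first coordinate of their sequence-level vector.
#' @return A `prohl_embedder`.
#' @export
synthetic_embedder <- function(seed = 1L, d_local = 128L, d_global = 512L,
                               L_padded = 1655L, signal_map = NULL) {
  spec <- embedder_spec("synthetic", d_local, d_global, L_padded)
  if (!is.null(signal_map)) {
    stopifnot(is.character(signal_map$pattern), is.numeric(signal_map$effect))
  }
  embed_one <- function(sequence) {
    L <- nchar(sequence)
    with_local_seed(combine_seed(seed, prohl_hash(sequence)), {
      rm_full <- matrix(0, nrow = spec$d_local, ncol = spec$L_padded)
      rm_full[, seq_len(L)] <- stats::rnorm(spec$d_local * L)
      sv <- stats::rnorm(spec$d_global)
      if (!is.null(signal_map) && grepl(signal_map$pattern, sequence)) {
        sv[1L] <- sv[1L] + signal_map$effect
      }
      list(residue_matrix = rm_full, sequence_vector = sv, true_length = L)
    })
  }
  structure(list(spec = spec, seed = as.integer(seed),
                 signal_map = signal_map, embed_one = embed_one),
            class = "prohl_embedder")
}

#' Adapter for externally computed (pretrained) embeddings
#'
#' Reads per-sequence embeddings exported by an external protein
#' language-model run into a directory containing `spec.json` (fields
#' `name`, `d_local`, `d_global`, `L_padded`) and, per sequence, plain-text
#' files `<hash>.residue.tsv` (d_local rows x true-length columns) and
#' `<hash>.sequence.tsv` (one row of d_global values), where `<hash>` is the
#' package's content hash of the sequence. No network access and no silent
#' fallback: a missing directory or missing sequence file is an error with
#' instructions.
#'
#' @param path Directory of exported embeddings.
#' @return A `prohl_embedder`.
#' @export
pretrained_embedder <- function(path) {
  if (!dir.exists(path) || !file.exists(file.path(path, "spec.json"))) {
    stop("no exported embeddings at '", path, "'. Export them from your ",
         "language-model environment as spec.json plus <hash>.residue.tsv ",
         "and <hash>.sequence.tsv per sequence (see ?pretrained_embedder), ",
         "or use synthetic_embedder() for a self-contained run.")
  }
  sj <- jsonlite::read_json(file.path(path, "spec.json"), simplifyVector = TRUE)
  spec <- embedder_spec(sj$name, sj$d_local, sj$d_global, sj$L_padded)
  embed_one <- function(sequence) {
    h <- prohl_hash(sequence)
    rf <- file.path(path, paste0(h, ".residue.tsv"))
    sf <- file.path(path, paste0(h, ".sequence.tsv"))
    if (!file.exists(rf) || !file.exists(sf)) {
      stop("no exported embedding for a sequence with content hash ", h,
           " under '", path, "'; re-export embeddings for the full input set.")
    }
    rm_true <- as.matrix(utils::read.table(rf, sep = "\t"))
    sv <- as.numeric(utils::read.table(sf, sep = "\t"))
    stopifnot(nrow(rm_true) == spec$d_local, length(sv) == spec$d_global)
    L <- ncol(rm_true)
    rm_full <- matrix(0, nrow = spec$d_local, ncol = spec$L_padded)
    rm_full[, seq_len(L)] <- rm_true
    list(residue_matrix = rm_full, sequence_vector = sv, true_length = L)
  }
  structure(list(spec = spec, seed = NA_integer_, signal_map = NULL,
                 embed_one = embed_one),
            class = "prohl_embedder")
}

#' Create an in-memory embedding cache
#'
#' Content-addressed: the cache key is the sequence itself, so the same
#' sequence hits the same entry regardless of its record id.
#'
#' @return An environment usable as the `cache` argument of
#'   [embed_sequences()].
#' @export
new_embedding_cache <- function() new.env(parent = emptyenv())

#' Embed sequences
#'
#' @param seqs Named character vector of validated sequences.
#' @param embedder A `prohl_embedder`.
#' @param cache Optional cache from [new_embedding_cache()].
#' @return Named list of embedding bundles, each
#'   `list(residue_matrix, sequence_vector, true_length)` with the residue
#'   matrix zero-padded to `d_local x L_padded`.
#' @export
embed_sequences <- function(seqs, embedder, cache = NULL) {
  stopifnot(inherits(embedder, "prohl_embedder"))
  too_long <- nchar(seqs) > embedder$spec$L_padded
  if (any(too_long)) {
    stop("sequences longer than L_padded = ", embedder$spec$L_padded, ": ",
         paste(names(seqs)[too_long], collapse = ", "))
  }
  out <- lapply(seqs, function(s) {
    if (!is.null(cache)) {
      hit <- get0(s, envir = cache, inherits = FALSE)
      if (!is.null(hit)) return(hit)
    }
    b <- embedder$embed_one(s)
    if (!is.null(cache)) assign(s, b, envir = cache)
    b
  })
  names(out) <- names(seqs)
  out
}
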