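# FASTA / label-table input and output, sequence validation, and the
# half-life labelling rule.

LABEL_SHORT <- "short_lived"
LABEL_LONG <- "long_lived"

label_levels <- function() c(LABEL_SHORT, LABEL_LONG)

#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA file into a named character vector.
#' Record ids are the header text up to the first whitespace and must be
#' unique. Sequences are uppercased and a terminal stop character (`*`) is
#' stripped. In strict mode (the default) any residue outside the 20-letter
#' standard alphabet is an error; with `strict = FALSE` the conventional
#' ambiguity letters (B, J, O, U, X, Z) are mapped to `X` (descriptor terms
#' involving `X` are skipped downstream). Gap characters are always an error.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-standard residues instead of masking them to `X`.
#' @return Named character vector of sequences (possibly empty), in file
#'   order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: line ", first, " precedes any '>' header: ",
         substr(lines[first], 1, 40))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- ids
  validate_sequences(seqs, strict = strict)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then re-reading a validated set of
#' sequences is the identity.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate sequences against the standard amino-acid alphabet
#'
#' @param seqs Named character vector.
#' @param strict Error on non-standard residues; otherwise map the ambiguity
#'   letters B, J, O, U, Z (and keep X) to `X`.
#' @return The validated (possibly masked) sequences.
#' @export
validate_sequences <- function(seqs, strict = TRUE) {
  if (length(seqs) == 0L) return(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by id")
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  if (any(grepl("[-.]", seqs))) {
    stop("gap characters in sequence for id: ",
         paste(names(seqs)[grepl("[-.]", seqs)], collapse = ", "))
  }
  ok_strict <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), seqs)
  if (all(ok_strict)) return(seqs)
  if (strict) {
    stop("non-standard residues in sequence for id: ",
         paste(names(seqs)[!ok_strict], collapse = ", "),
         " (use strict = FALSE to mask B/J/O/U/X/Z to X)")
  }
  masked <- chartr(paste(non_standard_residues(), collapse = ""),
                   strrep("X", length(non_standard_residues())), seqs)
  still_bad <- !grepl(paste0("^[X", paste(aa_alphabet(), collapse = ""), "]+$"), masked)
  if (any(still_bad)) {
    stop("unrecognised characters in sequence for id: ",
         paste(names(seqs)[still_bad], collapse = ", "))
  }
  masked
}

#' Validate sequences for prediction
#'
#' Prediction input must consist of standard amino acids with length in
#' `[min_len, max_len]` (defaults 50 and 1655).
#'
#' @param seqs Named character vector of sequences.
#' @param min_len,max_len Inclusive length bounds.
#' @param collect If `TRUE`, return a per-record data frame with columns
#'   `id`, `ok`, `reason` instead of erroring, so batch prediction can skip
#'   invalid records and continue.
#' @return The unchanged sequences (or the per-record report).
#' @export
validate_for_prediction <- function(seqs, min_len = 50L, max_len = 1655L,
                                    collect = FALSE) {
  ids <- names(seqs)
  len <- nchar(seqs)
  alpha_ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"), seqs)
  reason <- rep(NA_character_, length(seqs))
  reason[!alpha_ok] <- "non-standard residue"
  reason[alpha_ok & len < min_len] <- sprintf("length %d < %d", len[alpha_ok & len < min_len], min_len)
  reason[alpha_ok & len > max_len] <- sprintf("length %d > %d", len[alpha_ok & len > max_len], max_len)
  ok <- is.na(reason)
  if (collect) {
    return(data.frame(id = ids, ok = ok, reason = reason,
                      stringsAsFactors = FALSE))
  }
  if (!all(ok)) {
    bad <- paste0(ids[!ok], " (", reason[!ok], ")")
    stop("rejected for prediction: ", paste(bad, collapse = "; "))
  }
  seqs
}

#' Assign stability classes from half-life values
#'
#' A protein is short-lived iff its half-life is strictly below the
#' threshold (default 60 minutes, i.e. "less than one hour"); exactly at
#' the threshold is long-lived.
#'
#' @param half_life_minutes Non-negative numeric vector of half-lives, in
#'   minutes.
#' @param threshold_minutes Positive threshold.
#' @return Character vector over `"short_lived"` / `"long_lived"`.
#' @export
assign_label <- function(half_life_minutes, threshold_minutes = 60) {
  stopifnot(is.numeric(half_life_minutes), threshold_minutes > 0)
  if (any(is.na(half_life_minutes)) || any(half_life_minutes < 0)) {
    stop("half-life values must be non-negative and non-missing")
  }
  ifelse(half_life_minutes < threshold_minutes, LABEL_SHORT, LABEL_LONG)
}

#' Read a two-column label table
#'
#' Reads a tab-separated table of `id` and either a numeric half-life or a
#' class name (`short_lived` / `long_lived`); a header row is detected and
#' skipped. Numeric and class values may not be mixed. When `ids` is given,
#' every label id must occur in it.
#'
#' @param path Path to the TSV file.
#' @param ids Optional character vector of known sequence ids (e.g. from the
#'   accompanying FASTA) to resolve against.
#' @param unit Unit of numeric half-life values, `"minutes"` or `"hours"`.
#' @param threshold_minutes Labelling threshold passed to [assign_label()].
#' @return Data frame with columns `id`, `half_life` (minutes, `NA` when the
#'   table held classes), and `label`.
#' @export
read_labels <- function(path, ids = NULL, unit = c("minutes", "hours"),
                        threshold_minutes = 60) {
  unit <- match.arg(unit)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) != 2L) stop("label table must have exactly two columns")
  is_class <- raw[[2L]] %in% label_levels()
  is_num <- !is.na(suppressWarnings(as.numeric(raw[[2L]])))
  if (nrow(raw) > 0L && !is_class[1L] && !is_num[1L]) {
    raw <- raw[-1L, , drop = FALSE]  # header row
    is_class <- is_class[-1L]
    is_num <- is_num[-1L]
  }
  if (nrow(raw) == 0L) stop("label table is empty")
  if (!all(is_class | is_num)) {
    stop("unrecognised label values: ",
         paste(unique(raw[[2L]][!(is_class | is_num)]), collapse = ", "))
  }
  if (any(is_class) && any(is_num)) {
    stop("label table mixes numeric half-lives and class names")
  }
  if (anyDuplicated(raw[[1L]])) {
    stop("duplicate ids in label table: ",
         paste(unique(raw[[1L]][duplicated(raw[[1L]])]), collapse = ", "))
  }
  if (!is.null(ids)) {
    missing <- setdiff(raw[[1L]], ids)
    if (length(missing)) {
      stop("label ids absent from the sequence set: ",
           paste(missing, collapse = ", "))
    }
  }
  if (all(is_num)) {
    hl <- as.numeric(raw[[2L]])
    if (unit == "hours") hl <- hl * 60
    if (any(hl < 0)) stop("negative half-life values in label table")
    data.frame(id = raw[[1L]], half_life = hl,
               label = assign_label(hl, threshold_minutes),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = raw[[1L]], half_life = NA_real_, label = raw[[2L]],
               stringsAsFactors = FALSE)
  }
}

#' Write a prediction table
#'
#' @param predictions Data frame with columns `id`, `probability_long_lived`,
#'   `predicted_class` (and optionally `note`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
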