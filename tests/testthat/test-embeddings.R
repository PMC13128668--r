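test_that("the synthetic embedder is deterministic and content-addressed", {
  emb <- synthetic_embedder(seed = 7L, d_local = 8L, d_global = 12L,
                            L_padded = 100L)
  s <- random_seq(60)
  b1 <- embed_sequences(c(x = s), emb)[[1]]
  b2 <- embed_sequences(c(renamed = s), emb)[[1]]
  expect_identical(b1, b2)  # id plays no role
  expect_identical(dim(b1$residue_matrix), c(8L, 100L))
  expect_equal(b1$true_length, 60L)
  expect_true(all(b1$residue_matrix[, 61:100] == 0))  # padding contract
  expect_true(sum(b1$residue_matrix[, 1:60] != 0) > 0)
  # bit-identical across a fresh embedder with the same seed
  emb2 <- synthetic_embedder(seed = 7L, d_local = 8L, d_global = 12L,
                             L_padded = 100L)
  expect_identical(embed_sequences(c(x = s), emb2)[[1]], b1)
  # and independent of the ambient RNG state
  set.seed(999)
  expect_identical(embed_sequences(c(x = s), emb)[[1]], b1)
})

test_that("different sequences get different vectors (collision check)", {
  set.seed(21)
  seqs <- setNames(unique(replicate(300, random_seq(55))), NULL)
  names(seqs) <- paste0("s", seq_along(seqs))
  emb <- synthetic_embedder(seed = 1L, d_local = 4L, d_global = 8L,
                            L_padded = 60L)
  vecs <- vapply(embed_sequences(seqs, emb), function(b)
    paste(format(b$sequence_vector, digits = 15), collapse = ","), "")
  expect_equal(anyDuplicated(vecs), 0L)
})

test_that("the signal map shifts the first coordinate by the stated effect", {
  set.seed(31)
  n <- 500
  plain <- setNames(replicate(n, random_seq(60)), paste0("p", 1:n))
  with_motif <- setNames(vapply(replicate(n, random_seq(60)), function(s) {
    paste0(substr(s, 1, 30), "WWW", substr(s, 34, 60))
  }, ""), paste0("m", 1:n))
  emb <- synthetic_embedder(seed = 5L, d_local = 4L, d_global = 8L,
                            L_padded = 70L,
                            signal_map = list(pattern = "WWW", effect = 2.0))
  first <- function(bs) vapply(bs, function(b) b$sequence_vector[1], 0)
  a <- first(embed_sequences(with_motif, emb))
  b <- first(embed_sequences(plain[!grepl("WWW", plain)], emb))
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - 2.0), 3 * se)
})

test_that("the cache is a content-addressed hit and records are length-checked", {
  emb <- synthetic_embedder(seed = 2L, d_local = 4L, d_global = 6L,
                            L_padded = 80L)
  cache <- new_embedding_cache()
  s <- random_seq(70)
  b1 <- embed_sequences(c(a = s), emb, cache)[[1]]
  # poison the embedder: a cache hit must not recompute
  emb_broken <- emb
  emb_broken$embed_one <- function(sequence) stop("recomputed")
  expect_identical(embed_sequences(c(b = s), emb_broken, cache)[[1]], b1)
  expect_error(embed_sequences(c(x = random_seq(81)), emb), "L_padded")
})

test_that("the pretrained adapter reads exported matrices and fails loudly", {
  expect_error(pretrained_embedder(file.path(tempdir(), "nope")),
               "synthetic_embedder")
  dir <- withr::local_tempdir()
  writeLines(jsonlite::toJSON(list(name = "exported", d_local = 3,
                                   d_global = 4, L_padded = 20),
                              auto_unbox = TRUE),
             file.path(dir, "spec.json"))
  s <- "ACDEFGHIKLMNPQR"
  h <- prohl:::prohl_hash(s)
  write.table(matrix(1:45 / 10, nrow = 3), file.path(dir, paste0(h, ".residue.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(t(c(1, 2, 3, 4)), file.path(dir, paste0(h, ".sequence.tsv")),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  emb <- pretrained_embedder(dir)
  b <- embed_sequences(c(q = s), emb)[[1]]
  expect_identical(dim(b$residue_matrix), c(3L, 20L))
  expect_equal(b$sequence_vector, c(1, 2, 3, 4))
  expect_true(all(b$residue_matrix[, 16:20] == 0))
  expect_error(embed_sequences(c(q = "ACDEFGHIKLMNPQRS"), emb), "content hash")
})
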