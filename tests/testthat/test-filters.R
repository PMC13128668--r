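test_that("length filtering keeps the 50-residue boundary and order", {
  seqs <- c(a = strrep("A", 49), b = strrep("C", 50), d = strrep("D", 80))
  expect_identical(names(length_filter(seqs)), c("b", "d"))
  expect_length(length_filter(character(0)), 0L)
  set.seed(1)
  many <- setNames(replicate(50, random_seq(sample(50:120, 1))),
                   paste0("s", 1:50))
  expect_identical(length_filter(many), many)
})

test_that("pairwise identity matches the quadratic aligner oracle", {
  s <- random_seq(60)
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity(strrep("A", 60), strrep("C", 60)), 0.0)
  expect_error(pairwise_identity("", s), "empty")

  # two fixed 60-mers differing at exactly 30 positions, no indel advantage:
  # alternate two disjoint alphabets so off-position matches cannot align
  a <- strrep("AC", 30)
  b <- paste0(strrep("A", 30), strrep("D", 30))
  expect_equal(oracle_align_score(a, b) / 60, 0.5)
  expect_equal(pairwise_identity(a, b), oracle_align_score(a, b) / 60)

  set.seed(42)
  for (i in 1:20) {
    x <- random_seq(sample(20:70, 1))
    y <- random_seq(sample(20:70, 1))
    expect_equal(pairwise_identity(x, y),
                 oracle_align_score(x, y) / min(nchar(x), nchar(y)))
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
})

test_that("greedy clustering merges identical and 60%-identical sequences", {
  s <- random_seq(80)
  cl <- greedy_cluster(c(a = s, b = s))
  expect_equal(max(cl$cluster), 1L)
  expect_identical(unique(cl$representative_id), "a")  # id tie-break

  # mutate 40% of positions: identity >= 0.5 by the oracle, same cluster
  set.seed(7)
  chars <- strsplit(s, "")[[1]]
  idx <- sample(80, 32)
  chars[idx] <- vapply(chars[idx], function(ch) sample(setdiff(AA, ch), 1), "")
  mut <- paste(chars, collapse = "")
  expect_gte(oracle_align_score(s, mut) / 80, 0.5)
  longer <- paste0(s, "AAAAA")
  cl2 <- greedy_cluster(c(m = mut, orig = longer))
  expect_equal(max(cl2$cluster), 1L)
  expect_identical(unique(cl2$representative_id), "orig")  # longest member
})

test_that("mutually dissimilar sequences stay singletons and clusters partition", {
  set.seed(11)
  seqs <- setNames(replicate(8, random_seq(60)), paste0("s", 1:8))
  ids <- combn(8, 2)
  pid <- apply(ids, 2, function(p) {
    oracle_align_score(seqs[[p[1]]], seqs[[p[2]]]) / 60
  })
  expect_true(all(pid < 0.5))
  cl <- greedy_cluster(seqs)
  expect_equal(max(cl$cluster), 8L)
  expect_setequal(cl$member_id, names(seqs))
  expect_false(anyDuplicated(cl$member_id) > 0)
})

test_that("clustering is invariant to input order", {
  set.seed(3)
  base <- replicate(6, random_seq(sample(55:90, 1)))
  fam <- unlist(lapply(base, function(s) {
    chars <- strsplit(s, "")[[1]]
    i <- sample(length(chars), round(length(chars) * 0.3))
    chars[i] <- sample(AA, length(i), replace = TRUE)
    c(s, paste(chars, collapse = ""))
  }))
  names(fam) <- paste0("q", seq_along(fam))
  a <- greedy_cluster(fam)
  b <- greedy_cluster(rev(fam))
  a <- a[order(a$member_id), ]
  b <- b[order(b$member_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
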