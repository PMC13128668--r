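test_that("CKSAAP counts spaced pairs and normalises each gap block", {
  v <- cksaap("AAAA", max_gap = 0L)
  expect_equal(unname(v["CKSAAP.g0.AA"]), 1.0)
  expect_equal(sum(v), 1.0)

  v1 <- cksaap("ACAC", max_gap = 1L)
  expect_equal(unname(v1["CKSAAP.g1.AA"]), 0.5)
  expect_equal(unname(v1["CKSAAP.g1.CC"]), 0.5)

  set.seed(5)
  s <- random_seq(80)
  v5 <- cksaap(s, 5L)
  for (g in 0:5) {
    expect_equal(sum(v5[grepl(paste0("\\.g", g, "\\."), names(v5))]), 1,
                 tolerance = 1e-12)
  }
  expect_error(cksaap("ACD", max_gap = 5L), "too short")
})

test_that("CKSAAP gap-0 residue marginals are shuffle-invariant", {
  set.seed(8)
  s <- random_seq(120)
  chars <- strsplit(s, "")[[1]]
  shuf <- paste(sample(chars), collapse = "")
  marg <- function(v) {
    g0 <- v[grepl("\\.g0\\.", names(v))]
    first <- factor(substr(sub(".*\\.g0\\.", "", names(g0)), 1, 1), levels = AA)
    out <- tapply(g0, first, sum)
    ifelse(is.na(out), 0, out)
  }
  # first-residue marginals of the gap-0 block are the amino-acid
  # composition over positions 1..L-1, which a shuffle changes by at most
  # the one boundary residue (1/(L-1) per letter)
  expect_lte(max(abs(marg(cksaap(s, 0L)) - marg(cksaap(shuf, 0L)))),
             1 / 119 + 1e-12)
})

test_that("DDE standardizes dipeptide counts against codon expectation", {
  set.seed(9)
  s <- random_seq(100)
  expect_equal(dde(s), oracle_dde(s), tolerance = 1e-12)
  # a dipeptide that never occurs scores -Tm / sqrt(Tv)
  s2 <- paste(rep("AC", 40), collapse = "")  # no WW anywhere
  v <- dde(s2)
  tm <- (1 / 61)^2
  tv <- tm * (1 - tm) / 79
  expect_equal(unname(v["DDE.WW"]), -tm / sqrt(tv))
  expect_error(dde("A"), "length")
})

test_that("CTD compositions sum to one and homopolymers have no transitions", {
  v <- ctd(strrep("A", 30))
  expect_equal(unname(v["CTD.hydrophobicity.comp.c2"]), 1.0)  # A is neutral
  expect_true(all(v[grepl("trans", names(v))] == 0))
  set.seed(10)
  s <- random_seq(60)
  v2 <- ctd(s)
  for (an in names(oracle_ctd_groups)) {
    expect_equal(sum(v2[grepl(paste0(an, "\\.comp"), names(v2))]), 1,
                 tolerance = 1e-12)
  }
})

test_that("Moran autocorrelation matches its definition and degenerates to 0", {
  expect_true(all(moran(strrep("A", 60), n_lag = 10L) == 0))
  # strictly alternating sequence: lag-1 autocorrelation approaches -1
  alt <- strrep("AW", 100)
  v <- moran(alt, n_lag = 2L)
  expect_lt(unname(v["MORAN.hydropathy.lag1"]), -0.95)
  # a property constant on the two residues degenerates to 0, not NaN
  expect_equal(unname(v["MORAN.net_charge.lag1"]), 0)
  expect_error(moran("ACDEF", n_lag = 5L), "n_lag")
})

test_that("SOCN is non-negative and zero for homopolymers", {
  expect_true(all(socn(strrep("W", 50), n_lag = 10L) == 0))
  set.seed(11)
  s <- random_seq(70)
  expect_true(all(socn(s, 30L) >= 0))
  expect_error(socn(s, 70L), "n_lag")
})

test_that("each descriptor family matches its brute-force oracle", {
  set.seed(123)
  scales <- aa_property_scales()
  dmat <- aa_distance_matrix()
  for (i in 1:5) {
    s <- random_seq(sample(50:150, 1))
    expect_equal(cksaap(s, 5L), oracle_cksaap(s, 5L), tolerance = 1e-12)
    expect_equal(dde(s), oracle_dde(s), tolerance = 1e-12)
    expect_equal(unname(ctd(s)), oracle_ctd(s), tolerance = 1e-12)
    expect_equal(unname(moran(s, 30L, scales)),
                 unname(oracle_moran(s, 30L, scales)), tolerance = 1e-12)
    expect_equal(unname(socn(s, 30L, dmat)), oracle_socn(s, 30L, dmat),
                 tolerance = 1e-12)
  }
})

test_that("the combined encoding is deterministic with a documented layout", {
  set.seed(14)
  seqs <- setNames(replicate(3, random_seq(60)), c("a", "b", "c"))
  x <- encode_physchem(seqs)
  expect_equal(ncol(x), 2400 + 400 + 147 + 8 * 30 + 30)
  groups <- attr(x, "groups")
  expect_setequal(unique(groups), descriptor_group_levels())
  expect_true(all(table(groups) > 0))
  expect_true(all(is.finite(x)))
  x2 <- encode_physchem(seqs)
  expect_identical(x, x2)
  # identical sequences map to identical rows
  y <- encode_physchem(c(p = seqs[["a"]], q = seqs[["a"]]))
  expect_equal(unname(y[1, ]), unname(y[2, ]))
})

test_that("masked residues take part in no descriptor term", {
  v <- cksaap("AXAXA", max_gap = 1L)
  expect_equal(unname(v["CKSAAP.g1.AA"]), 1.0)  # only valid gap-1 pairs
  expect_equal(sum(v[grepl("g0", names(v))]), 0)  # no valid adjacent pair
})
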