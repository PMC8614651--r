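test_that("count_codons drops the stop and is additive under pooling", {
  cds <- make_cds("ATGAAAAAATAA")
  cnt <- count_codons(cds)
  expect_equal(cnt[["ATG"]], 1L)
  expect_equal(cnt[["AAA"]], 2L)
  expect_equal(sum(cnt), length(cds$codons) - 1L)
  expect_false(any(names(cnt) %in% c("TAA", "TAG", "TGA")))
  pooled <- pool_counts(cnt, cnt)
  expect_equal(as.numeric(pooled), 2 * as.numeric(cnt))
})

test_that("family homozygosity matches the hand-evaluated formula", {
  # two-fold family with counts {3, 1}: F = (4 * (9/16 + 1/16) - 1) / 3 = 0.5
  counts <- cubscan:::as_codon_counts(c(TTT = 3, TTC = 1))
  expect_equal(cubscan:::family_homozygosity(counts, c("TTT", "TTC")), 0.5)
  # n < 2 is unusable
  counts1 <- cubscan:::as_codon_counts(c(TTT = 1))
  expect_true(is.na(cubscan:::family_homozygosity(counts1, c("TTT", "TTC"))))
})

test_that("ENC attains 20 under maximal bias and 61 under equal usage", {
  one_per_aa <- vapply(synonymous_families(), `[`, "", 1)
  maximal <- stats::setNames(rep(100, 20), one_per_aa)
  expect_equal(enc_observed(maximal), 20)
  equal_use <- stats::setNames(rep(1000, 61), sense_codons())
  expect_equal(enc_observed(equal_use), 61)
})

test_that("ENC handles missing degeneracy classes as documented", {
  # only a two-fold family observed: 4- and 6-fold classes missing -> NA
  expect_warning(v <- enc_observed(c(TTT = 5, TTC = 5)), "undefined")
  expect_true(is.na(v))
  # no family with >= 2 codons at all -> error
  expect_error(enc_observed(c(TTT = 1)), "undefined")
})

test_that("ENC missing 3-fold class is imputed from the 2- and 4-fold means", {
  counts <- random_count_table()
  counts[synonymous_families()[["I"]]] <- 0
  imputed <- enc_observed(counts)
  expect_true(is.finite(imputed))
  expect_equal(imputed, oracle_enc(counts))
})

test_that("ENC matches an independent oracle on random count tables", {
  set.seed(101)
  for (i in 1:40) {
    counts <- random_count_table(lambda = sample(c(0.5, 2, 10), 1))
    got <- suppressWarnings(enc_observed(counts))
    want <- oracle_enc(counts)
    expect_equal(got, want, tolerance = 1e-9, info = paste("table", i))
  }
})

test_that("skewing a uniform family never increases ENC", {
  counts <- stats::setNames(rep(60, 61), sense_codons())
  fam <- synonymous_families()[["A"]]  # fourfold alanine family
  prev <- enc_observed(counts)
  for (shift in seq(10, 50, by = 10)) {
    skewed <- counts
    skewed[fam] <- c(60 + 3 * shift, 60 - shift, 60 - shift, 60 - shift)
    cur <- enc_observed(skewed)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("ENC is scale invariant for large counts", {
  set.seed(7)
  counts <- stats::setNames(stats::rpois(61, 1000), sense_codons())
  expect_equal(enc_observed(counts), enc_observed(counts * 5),
               tolerance = 0.05)
})

test_that("expected ENC follows the GC3 null curve", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  expect_equal(enc_expected(0), 31)
  # s^2 + (1-s)^2 is symmetric about 0.5
  s <- c(0.1, 0.25, 0.4)
  expect_equal(enc_expected(s) - s, enc_expected(1 - s) - (1 - s))
  expect_error(enc_expected(1.2), "0, 1")
  expect_error(enc_expected(-0.1), "0, 1")
})

test_that("the ENC ratio has the documented sign convention", {
  expect_equal(enc_ratio(50, 50), 0)
  expect_equal(enc_ratio(50, 60), 1 / 6)
  expect_equal(enc_ratio(61, 60.5), -0.5 / 60.5)
  expect_error(enc_ratio(50, 0), "non-zero")
})

test_that("RSCU matches hand-derived values and classifies by threshold", {
  r <- rscu(c(TTT = 3, TTC = 1))
  expect_equal(r$rscu[["TTT"]], 1.5)
  expect_equal(r$rscu[["TTC"]], 0.5)
  expect_equal(r$class[["TTT"]], "preferred")
  expect_equal(r$class[["TTC"]], "rare")
  r2 <- rscu(c(GCA = 8))
  expect_equal(r2$rscu[["GCA"]], 4)
  expect_equal(r2$class[["GCA"]], "over_represented")
  # boundary cases: exactly 1.6 is preferred, not over-represented
  r3 <- rscu(c(TTT = 8, TTC = 2))  # 8 / 5 = 1.6
  expect_equal(r3$rscu[["TTT"]], 1.6)
  expect_equal(r3$class[["TTT"]], "preferred")
  r4 <- rscu(c(TTT = 5, TTC = 5))
  expect_equal(r4$class[["TTT"]], "unbiased")
})

test_that("uniform usage gives RSCU 1 everywhere; unobserved families give 0", {
  uniform <- stats::setNames(rep(12, 61), sense_codons())
  r <- rscu(uniform)
  expect_equal(unname(r$rscu), rep(1, 59))
  zeroed <- uniform
  zeroed[synonymous_families()[["L"]]] <- 0
  expect_equal(unname(rscu(zeroed)$rscu[synonymous_families()[["L"]]]),
               rep(0, 6))
})

test_that("observed-family RSCU sums equal family size", {
  set.seed(55)
  fams <- synonymous_families()
  for (i in 1:25) {
    counts <- random_count_table(2)
    r <- rscu(counts)
    for (aa in names(fams)) {
      fam <- fams[[aa]]
      if (length(fam) < 2 || sum(counts[fam]) == 0) next
      expect_equal(sum(r$rscu[fam]), length(fam), tolerance = 1e-9)
    }
  }
})

test_that("RSCU agrees with seqinr's implementation on a real-shaped CDS", {
  set.seed(12)
  ds <- generate_dataset(generator_config(1, length_codons = 400,
                                          gc3_target = 0.6, seed = 12))
  cds <- ds$sequences[[1]]
  ours <- rscu(count_codons(cds))$rscu
  ref <- seqinr::uco(seqinr::s2c(tolower(cds$sequence)), index = "rscu")
  names(ref) <- toupper(names(ref))
  shared <- intersect(names(ours), names(ref))
  comparable <- shared[is.finite(ref[shared])]
  expect_gt(length(comparable), 50)
  expect_equal(ours[comparable], ref[comparable], tolerance = 1e-9)
})
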