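test_that("generated sequences are valid CDS by construction", {
  ds <- generate_dataset(generator_config(10, length_codons = 150, seed = 2))
  expect_length(ds$sequences, 10)
  expect_equal(nrow(ds$rejected), 0)
  for (s in ds$sequences) {
    res <- validate_cds(s$seq_id, s$sequence, s$group)
    expect_s3_class(res, "coding_sequence")
  }
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(5, length_codons = 120, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(lapply(a$sequences, `[[`, "sequence"),
                   lapply(b$sequences, `[[`, "sequence"))
  c_ <- generate_dataset(generator_config(5, length_codons = 120, seed = 100))
  expect_false(identical(lapply(a$sequences, `[[`, "sequence"),
                         lapply(c_$sequences, `[[`, "sequence")))
})

test_that("realised GC3 tracks the target closely at CDS-scale lengths", {
  ds <- generate_dataset(generator_config(40, length_codons = 710,
                                          gc3_target = 0.55,
                                          gc3_halfwidth = 0, seed = 13))
  gc3 <- vapply(ds$sequences, function(s) composition_profile(s)$gc3, 0)
  expect_gte(mean(abs(gc3 - 0.55) <= 0.02), 0.95)
  ds2 <- generate_dataset(generator_config(20, length_codons = 710,
                                           gc3_target = 0.4,
                                           gc3_halfwidth = 0, seed = 14))
  gc3_2 <- vapply(ds2$sequences, function(s) composition_profile(s)$gc3, 0)
  expect_gte(mean(abs(gc3_2 - 0.4) <= 0.02), 0.95)
})

test_that("zero bias yields near-uniform synonymous usage and high ENC", {
  ds <- generate_dataset(generator_config(2, length_codons = 2000,
                                          gc3_target = NA, bias_strength = 0,
                                          seed = 3))
  counts <- count_codons(ds$sequences[[1]])
  expect_gt(enc_observed(counts), 57)
  r <- rscu(counts)
  expect_lt(max(abs(r$rscu - 1)), 0.35)
})

test_that("extreme bias collapses each family to one codon and ENC to 20", {
  ds <- generate_dataset(generator_config(2, length_codons = 1500,
                                          gc3_target = NA,
                                          bias_strength = 60, seed = 4))
  counts <- count_codons(ds$sequences[[1]])
  expect_equal(enc_observed(counts), 20)
  fams <- synonymous_families()
  for (aa in names(fams)) {
    expect_lte(sum(counts[fams[[aa]]] > 0), 1)
  }
})

test_that("infeasible GC3 targets raise a constraint-naming error", {
  cfg <- generator_config(1, length_codons = 100, gc3_target = 0.015,
                          gc3_halfwidth = 0, seed = 1)
  expect_error(generate_dataset(cfg), "infeasible")
  expect_error(generator_config(1, gc3_target = 1.2), "gc3_target")
  expect_error(generator_config(1, gc3_target = NA, regime = "mutation"),
               "mutation regime")
})

test_that("regimes separate on the neutrality slope", {
  mut <- generate_dataset(generator_config(50, gc3_target = 0.5,
                                           gc3_halfwidth = 0.15,
                                           regime = "mutation", seed = 11))
  sel <- generate_dataset(generator_config(50, gc3_target = 0.5,
                                           gc3_halfwidth = 0.15,
                                           regime = "selection", seed = 11))
  slope_of <- function(ds) {
    ct <- composition_table(ds)
    neutrality_fit(ct$p3, ct$p12)$slope
  }
  expect_lt(abs(slope_of(mut) - 1), 0.1)
  expect_lt(abs(slope_of(sel)), 0.1)
})

test_that("the four-group panel lands on its GC3 targets", {
  panel <- generate_regime_panel(20, seed = 5)
  expect_setequal(panel$groups, c("fish", "bird", "reptile", "mammal"))
  ct <- composition_table(panel)
  means <- tapply(ct$gc3, ct$group, mean)
  targets <- c(fish = 0.632, bird = 0.453, reptile = 0.434, mammal = 0.490)
  for (g in names(targets)) {
    expect_lt(abs(means[[g]] - targets[[g]]), 0.03)
  }
  expect_gt(means[["fish"]], max(means[c("bird", "reptile", "mammal")]))
  lens <- tapply(ct$length_nt, ct$group, mean)
  expect_true(all(lens > 2000 & lens < 2400))
})
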