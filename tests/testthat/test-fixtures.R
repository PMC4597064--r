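# Synthetic generator: determinism, internal consistency, planted structure.

test_that("generation is deterministic under a fixed seed", {
  b1 <- generate_bundle(fixture_config(seed = 77, n_variants = 25L))
  b2 <- generate_bundle(fixture_config(seed = 77, n_variants = 25L))
  expect_identical(b1$w, b2$w)
  expect_identical(b1$rv, b2$rv)
  expect_identical(b1$m, b2$m)
  expect_identical(b1$r, b2$r)
  b3 <- generate_bundle(fixture_config(seed = 78, n_variants = 25L))
  expect_false(identical(b1$w, b3$w))
})

test_that("drawn VAFs are reproduced exactly by the VAF formula", {
  b <- generate_bundle(fixture_config(seed = 4, n_variants = 50L))
  trv <- round(b$w$dna_depth * b$w$dna_allelic_freq / 100)
  expect_equal(compute_vaf(trv, b$w$dna_depth - trv), b$w$dna_allelic_freq)
})

test_that("no RNA mirroring means no RNA-expressed glyphs downstream", {
  b <- generate_bundle(fixture_config(seed = 10, n_variants = 30L,
                                      fraction_rna_expressed = 0))
  expect_equal(nrow(b$rv), 0L)
  w_hat <- distinct_mutations(integrate_bundle(b))
  expect_true(all(w_hat$glyph == 1L))
})

test_that("planted silenced TSGs pass the filter with zero counts", {
  b <- generate_bundle(fixture_config(seed = 12, n_variants = 20L,
                                      n_tsg_silenced = 5L))
  tsg <- tsg_methylation_table(b$m, b$h, b$k)
  expect_equal(length(unique(tsg$gene_symbol[tsg$silenced])), 5L)
  # the expressed-TSG control is reported but not silenced
  expect_true(any(!tsg$silenced))
  expect_error(generate_bundle(fixture_config(n_tsg_silenced = 99L)),
               "TSG pool")
})

test_that("worked-example bundles encode the paired case study faithfully", {
  bp <- mm_case_bundle("presentation")
  br <- mm_case_bundle("relapse")
  expect_equal(nrow(bp$w), 5L)
  expect_equal(nrow(br$w), 8L)
  # relapse carries over the presentation DNA changes for shared genes
  shared <- intersect(bp$w$gene_symbol, br$w$gene_symbol)
  expect_equal(br$w$dna_change[match(shared, br$w$gene_symbol)],
               bp$w$dna_change[match(shared, bp$w$gene_symbol)])
  # copy numbers as tabulated: MYC amplified in both samples
  myc_cn <- function(b) b$c$copy_number[b$c$chromosome == "8"]
  expect_equal(myc_cn(bp), 3L)
  expect_equal(myc_cn(br), 3L)
  # methylation probes carry the printed beta precision
  expect_equal(bp$m$avg_beta[bp$m$target_id == "cg26370022"], 0.6804651)
})
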