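# Visualizations: the TSV data export is the tested contract; images are
# smoke-tested for existence only.

test_that("genomic overview places variants inside scaled chromosome bands", {
  len <- grch37_chromosome_lengths()
  mid1 <- as.integer(len[["1"]] / 2)
  w <- wes_variants("1", mid1, 100L, 40, "g1", "G1", "c.1A>C", NA,
                    "MODERATE", "e")
  spec <- plot_spec(tempfile(fileext = ".png"))
  export <- read_relation(plot_genomic_overview(w, spec))
  # chr1 is the first band: x = (position) / genome length
  expect_equal(export$x, mid1 / sum(as.numeric(len)), tolerance = 1e-9)
  expect_equal(export$vaf, 40)
  expect_true(file.exists(spec$path))

  # empty relation renders axes only, no error
  spec2 <- plot_spec(tempfile(fileext = ".png"))
  expect_no_error(plot_genomic_overview(wes_variants(), spec2))
  expect_true(file.exists(spec2$path))

  # smoke: 200 variants render
  b <- generate_bundle(fixture_config(seed = 2, n_variants = 200L))
  spec3 <- plot_spec(tempfile(fileext = ".svg"))
  expect_no_error(plot_genomic_overview(b$w, spec3))
})

test_that("paired scatter export encodes shared and unique variants", {
  w1 <- filter_wes(mm_case_bundle("presentation")$w)
  w2 <- filter_wes(mm_case_bundle("relapse")$w)
  pc <- paired_compare(w1, w2)
  spec <- plot_spec(tempfile(fileext = ".png"))
  export <- read_relation(plot_paired_scatter(pc$common, pc$unique1,
                                              pc$unique2,
                                              mm_case_bundle("presentation")$k,
                                              spec))
  shared <- export[export$set == "shared", ]
  expect_equal(nrow(shared), 5L)
  expect_setequal(shared$x, w1$dna_allelic_freq)
  expect_equal(shared$y,
               w2$dna_allelic_freq[match(shared$gene_symbol, w2$gene_symbol)])
  only2 <- export[export$set == "sample2_only", ]
  expect_true(all(only2$x == 0))
  expect_setequal(only2$gene_symbol, c("KRAS", "MTOR", "MLL3"))

  # identical samples lie on the diagonal; disjoint samples on the axes
  self <- paired_compare(w1, w1)
  sp <- plot_spec(tempfile(fileext = ".png"))
  e2 <- read_relation(plot_paired_scatter(self$common, self$unique1,
                                          self$unique2, NULL, sp))
  expect_equal(e2$x, e2$y)
})

test_that("KDE-scatter export matches the glyph partition of the mutations", {
  b <- mm_case_bundle("presentation")
  an <- clonal_analysis(b)
  spec <- plot_spec(tempfile(fileext = ".png"))
  export <- read_relation(plot_kde_scatter(an$w_hat, an$curve, b$k, spec))
  expect_equal(sum(export$glyph == 2L), sum(an$w_hat$glyph == 2L))
  expect_equal(sum(export$glyph == 2L), 3L)
  expect_equal(nrow(export), nrow(an$w_hat))

  # all-WES data: zero star glyphs
  b0 <- generate_bundle(fixture_config(seed = 10, n_variants = 30L,
                                       fraction_rna_expressed = 0))
  an0 <- clonal_analysis(b0)
  sp0 <- plot_spec(tempfile(fileext = ".png"))
  e0 <- read_relation(plot_kde_scatter(an0$w_hat, an0$curve, b0$k, sp0))
  expect_equal(sum(e0$glyph == 2L), 0L)

  # show_kg_only hides unlabelled points
  spk <- plot_spec(tempfile(fileext = ".png"), show_kg_only = TRUE)
  ek <- read_relation(plot_kde_scatter(an$w_hat, an$curve, b$k, spk))
  expect_true(all(ek$labelled))
})

test_that("plot method on the analysis object writes image plus export", {
  b <- mm_case_bundle("presentation")
  an <- clonal_analysis(b)
  p <- tempfile(fileext = ".png")
  plot(an, path = p)
  expect_true(file.exists(p))
  expect_true(file.exists(sub("\\.png$", "_data.tsv", p)))
})
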