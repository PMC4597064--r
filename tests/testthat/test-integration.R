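# Integration pipeline: filtering, the join stages, glyph logic, derived
# tables, paired comparison.

test_that("VAF/depth filter bounds are inclusive", {
  w <- wes_variants(rep("1", 5), 1:5 * 100L,
                    dna_depth = c(20L, 19L, 1000L, 1001L, 50L),
                    dna_allelic_freq = c(4, 50, 50, 50, 3.9),
                    ensembl_gene_id = paste0("g", 1:5),
                    gene_symbol = paste0("G", 1:5),
                    dna_change = "c.1A>C", amino_acid_change = NA,
                    effect_impact = "MODERATE", experiment_id = "e")
  out <- filter_wes(w)
  expect_setequal(out$gene_symbol, c("G1", "G3"))   # boundary rows retained
})

test_that("stage I keeps only MODERATE/HIGH and outer-joins methylation", {
  w <- wes_variants(c("1", "1"), c(100L, 200L), c(50L, 60L), c(30, 40),
                    c("gA", "gB"), c("A", "B"), "c.1A>C", NA,
                    c("LOW", "MODERATE"), "e")
  m <- methylation_probes("cg1", 0.5, "Promoter Associated", "Island",
                          "gC", "me")
  I <- build_I(w, m)
  expect_equal(I$gene_symbol, "B")        # LOW dropped
  expect_true(is.na(I$target_id))         # unmethylated gene: null probe fields
})

test_that("stages J and D keep strictly positive expression evidence", {
  rv <- rna_variants("1", 100L, "g1", 30L, 50, "r")
  r <- transcript_quants(c("t1", "t2", "t3"), c("g1", "g1", "g1"),
                         c(0, 2.5, 1.1), "r")
  expect_equal(nrow(build_J(rv, r)), 2L)  # fpkm=0 excluded, 2 positive
  h0 <- gene_counts("g1", 0L, "r")
  h1 <- gene_counts("g1", 1L, "r")
  expect_equal(nrow(build_D(rv, h0)), 0L)
  expect_equal(nrow(build_D(rv, h1)), 1L)
})

test_that("glyphs separate WES-only from RNA-expressed mutations", {
  b <- mm_case_bundle("presentation")
  integrated <- integrate_bundle(b)
  w_hat <- distinct_mutations(integrated)
  glyph_of <- function(sym) unique(w_hat$glyph[w_hat$gene_symbol == sym])
  expect_equal(glyph_of("MYC"), 2L)
  expect_equal(glyph_of("SETD2"), 2L)
  expect_equal(glyph_of("TET2"), 2L)
  expect_equal(glyph_of("DNA2"), 1L)
  expect_equal(glyph_of("TNFRSF11A"), 1L)
  expect_true(all(w_hat$glyph %in% c(1L, 2L)))
})

test_that("integration never loses a variant and dedup collapses transcript fanout", {
  b <- mm_case_bundle("relapse")
  w_f <- filter_wes(b$w)
  keep <- w_f[w_f$effect_impact %in% c("MODERATE", "HIGH"), ]
  integrated <- integrate_bundle(b)
  w_hat <- distinct_mutations(integrated)
  key <- function(x) unique(paste(x$chromosome, x$position))
  expect_setequal(key(w_hat), key(keep))
  expect_equal(nrow(w_hat), nrow(keep))   # one row per mutation after dedup
  # MYC matched by two transcripts yet appears once
  expect_equal(sum(w_hat$gene_symbol == "MYC"), 1L)
})

test_that("copy number is attached by segment containment, NA outside segments", {
  w <- wes_variants(c("1", "2"), c(500L, 500L), c(50L, 50L), c(30, 30),
                    c("g1", "g2"), c("A", "B"), "c.1A>C", NA, "MODERATE", "e")
  cseg <- cnv_segments("1", 1L, 1000L, 3L, "e")
  I <- build_I(w, methylation_probes())
  integ <- build_integrated(I, build_J(rna_variants(), transcript_quants()),
                            build_D(rna_variants(), gene_counts()), cseg)
  expect_equal(integ$copy_number[integ$gene_symbol == "A"], 3L)
  expect_true(is.na(integ$copy_number[integ$gene_symbol == "B"]))
})

test_that("transcripts_for returns the locus transcript set, empty for WES-only", {
  b <- mm_case_bundle("presentation")
  integrated <- integrate_bundle(b)
  w_hat <- distinct_mutations(integrated)
  myc <- transcripts_for(w_hat[w_hat$gene_symbol == "MYC", ], integrated)
  expect_setequal(myc$ensembl_transcript_id,
                  c("ENST00000377970", "ENST00000524013"))
  expect_setequal(myc$fpkm, c(42, 58))
  dna2 <- transcripts_for(w_hat[w_hat$gene_symbol == "DNA2", ], integrated)
  expect_equal(nrow(dna2), 0L)
})

test_that("key-gene and RNA tables reproduce the worked-example shapes", {
  bp <- mm_case_bundle("presentation")
  ip <- integrate_bundle(bp)
  kg <- key_gene_table(distinct_mutations(ip), bp$k)
  expect_equal(nrow(kg), 5L)
  expect_setequal(kg$gene_symbol[kg$rna_mutation], c("MYC", "SETD2", "TET2"))
  expect_equal(nrow(key_gene_table(distinct_mutations(ip), gene_list())), 0L)

  br <- mm_case_bundle("relapse")
  rt <- rna_table(integrate_bundle(br))
  expect_equal(nrow(rt), 8L)
  expect_equal(sum(rt$gene_symbol == "MTOR"), 2L)
  # no RNA evidence at all: empty table
  b0 <- bp
  b0$rv <- rna_variants()
  expect_equal(nrow(rna_table(integrate_bundle(b0))), 0L)
})

test_that("TSG methylation table applies all three criteria and the silenced flag", {
  b <- mm_case_bundle("presentation")
  tsg <- tsg_methylation_table(b$m, b$h, b$k)
  expect_setequal(unique(tsg$gene_symbol[tsg$silenced]),
                  c("BRCA1", "CEBPA", "MSH2", "SOCS1"))
  expect_true(all(tsg$avg_beta >= 0.25))
  # boundary: beta just below threshold excluded
  m2 <- methylation_probes("cg_low", 0.249, "Promoter Associated", "Island",
                           "ENSG00000012048", "METH_P")
  expect_equal(nrow(tsg_methylation_table(m2, b$h, b$k)), 0L)
  # annotation matching is case-insensitive after trimming
  m3 <- methylation_probes("cg_up", 0.5, " PROMOTER ASSOCIATED ", "ISLAND",
                           "ENSG00000012048", "METH_P")
  expect_equal(nrow(tsg_methylation_table(m3, b$h, b$k)), 1L)
  # output is a subset of the input probes
  expect_true(all(tsg$target_id %in% b$m$target_id))
})

test_that("integrated-relation methylation route only reports mutated genes", {
  b <- mm_case_bundle("presentation")
  integrated <- integrate_bundle(b)
  lit <- tsg_methylation_integrated(integrated, b$k)
  # no key-gene mutation has probes in this fixture: empty
  expect_equal(nrow(lit), 0L)
  # give MYC a probe and it appears
  b$m <- rbind(b$m, methylation_probes("cg_myc", 0.4, "Promoter Associated",
                                       "Island", "ENSG00000136997", "METH_P"))
  lit2 <- tsg_methylation_integrated(integrate_bundle(b), b$k)
  expect_equal(unique(lit2$gene_symbol), "MYC")
})

test_that("paired comparison partitions loci into shared and unique sets", {
  w1 <- filter_wes(mm_case_bundle("presentation")$w)
  w2 <- filter_wes(mm_case_bundle("relapse")$w)
  pc <- paired_compare(w1, w2)
  expect_equal(nrow(pc$common), 5L)
  expect_equal(nrow(pc$unique1), 0L)
  expect_setequal(pc$unique2$gene_symbol, c("KRAS", "MTOR", "MLL3"))
  expect_equal(nrow(pc$common) + nrow(pc$unique1),
               length(unique(paste(w1$chromosome, w1$position))))
  # identical samples: no unique variants; disjoint: no shared
  self <- paired_compare(w1, w1)
  expect_equal(nrow(self$unique1) + nrow(self$unique2), 0L)
  disj <- paired_compare(w1, pc$unique2)
  expect_equal(nrow(disj$common), 0L)
  # shared relation carries both samples' VAF
  expect_equal(sort(pc$common$dna_allelic_freq_2),
               sort(w2$dna_allelic_freq[w2$gene_symbol %in% pc$common$gene_symbol]))
})
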