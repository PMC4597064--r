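# Relational operators: null semantics, outer-join preservation, set
# algebra, distinct projection.

test_that("left outer join preserves every left tuple and nulls unmatched rows", {
  left <- data.frame(id = 1:3, g = c("a", "b", NA), stringsAsFactors = FALSE)
  right <- data.frame(g = c("a", "a"), v = c(10, 20), stringsAsFactors = FALSE)
  out <- left_outer_join(left, right, by = "g")
  expect_setequal(unique(out$id), 1:3)
  expect_equal(nrow(out), 4L)              # id 1 matched twice, 2 and 3 unmatched
  expect_true(all(is.na(out$v[out$id %in% 2:3])))
  # NA key never matches, even if right held an NA key
  right_na <- rbind(right, data.frame(g = NA, v = 99))
  out2 <- left_outer_join(left, right_na, by = "g")
  expect_true(all(is.na(out2$v[out2$id == 3L])))

  # empty left preserves emptiness
  expect_equal(nrow(left_outer_join(left[0, ], right, by = "g")), 0L)
  # 1 left tuple, no match: one all-null row
  one <- left_outer_join(left[2, ], right, by = "g")
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$v))
})

test_that("equi join returns only matching pairs and rejects unknown attributes", {
  a <- data.frame(k = c("x", "y"), p = 1:2, stringsAsFactors = FALSE)
  b <- data.frame(k = c("z", "w"), q = 3:4, stringsAsFactors = FALSE)
  expect_equal(nrow(equi_join(a, b, by = "k")), 0L)
  # self-join on a unique key keeps cardinality
  expect_equal(nrow(equi_join(a, a, by = "k")), nrow(a))
  expect_error(equi_join(a, b, by = "nope"), "unknown attribute")
  expect_error(left_outer_join(a, b, by = c(k = "nope")), "unknown attribute")
})

test_that("equi join cardinality is the sum of per-key products", {
  set.seed(3)
  rv <- data.frame(gene = sample(c("g1", "g2", "g3"), 7, replace = TRUE),
                   pos = 1:7, stringsAsFactors = FALSE)
  r <- data.frame(gene = sample(c("g1", "g2", "g3"), 5, replace = TRUE),
                  tx = paste0("t", 1:5), stringsAsFactors = FALSE)
  out <- equi_join(rv, r, by = "gene")
  expected <- sum(sapply(c("g1", "g2", "g3"), function(g) {
    sum(rv$gene == g) * sum(r$gene == g)
  }))
  expect_equal(nrow(out), expected)
})

test_that("intersection and difference partition the distinct keys", {
  for (seed in 1:25) {
    pr <- random_keyed_pair(seed)
    keys <- c("chromosome", "position")
    i <- intersect_on(pr$a, pr$b, keys)
    d <- difference_on(pr$a, pr$b, keys)
    ka <- paste(pr$a$chromosome, pr$a$position)
    expect_equal(nrow(i) + nrow(d), length(unique(ka)),
                 info = paste("seed", seed))
  }
  a <- data.frame(chromosome = "1", position = 5, stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_on(a, a, c("chromosome", "position"))), 1L)
  expect_equal(nrow(difference_on(a, a, c("chromosome", "position"))), 0L)
})

test_that("distinct projection collapses duplicates and survives float noise", {
  rel <- data.frame(g = c("a", "a"), x = c(1, 1) + c(0, 1e-14),
                    extra = c("p", "q"), stringsAsFactors = FALSE)
  expect_equal(nrow(project_distinct(rel, c("g", "x"))), 1L)
  expect_equal(nrow(project_distinct(rel, c("g", "x", "extra"))), 2L)
  one <- project_distinct(rel[1, ], c("g", "x"))
  expect_equal(nrow(one), 1L)
})

test_that("join operators agree with the nested-loop oracle on random inputs", {
  for (seed in 1:40) {
    pr <- random_keyed_pair(seed, n_max = 25L)
    mf <- key_match_fun(c("chromosome", "position"), c("chromosome", "position"))
    expect_same_rel(
      left_outer_join(pr$a, pr$b, by = c("chromosome", "position")),
      oracle_left_join(pr$a, pr$b, mf)
    )
    expect_same_rel(
      equi_join(pr$a, pr$b, by = c("chromosome", "position")),
      oracle_inner_join(pr$a, pr$b, mf)
    )
  }
})

test_that("typed constructors validate domains and normalize chromosomes", {
  expect_equal(normalize_chromosome(c("chr1", "CHRX", "22")), c("1", "X", "22"))
  expect_error(normalize_chromosome("chr25"), "unknown chromosome")
  expect_error(wes_variants("1", 10, 50, 120, "g", "G", "c.1A>C", NA,
                            "MODERATE", "e"))      # VAF > 100
  expect_error(wes_variants("1", 10, 50, 20, "g", "G", "c.1A>C", NA,
                            "SEVERE", "e"))        # bad impact
  expect_error(cnv_segments(c("1", "1"), c(1L, 50L), c(100L, 60L),
                            c(2L, 3L), "e"),
               "overlapping")
  expect_error(methylation_probes(c("cg1", "cg1"), c(0.5, 0.6), "P", "I",
                                  "g", "e"),
               "duplicate")
})
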