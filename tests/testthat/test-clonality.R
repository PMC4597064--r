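# Clonality statistics: VAF arithmetic, diversity indices, bandwidth
# selection, weighted KDE.

test_that("VAF formula and error cases", {
  expect_equal(compute_vaf(0, 50), 0)
  expect_equal(compute_vaf(50, 50), 50)
  expect_equal(compute_vaf(31, 69), 31)
  expect_equal(compute_vaf(25, 75), 25)
  expect_error(compute_vaf(0, 0), "undefined VAF")
  expect_error(compute_vaf(-1, 5), "non-negative")
})

test_that("abundance multiplies VAF, depth and copy number with diploid default", {
  expect_equal(abundance(0, 100, 2), 0)
  expect_equal(abundance(31, 207, 3), 19251)
  expect_equal(abundance(10, 50, NA), abundance(10, 50, 2))
  expect_error(abundance(10, 0, 2), "positive")
})

test_that("Shannon diversity: bounds, uniform case, invariances", {
  expect_equal(shannon_diversity(7), 0)
  expect_equal(shannon_diversity(rep(3.2, 4)), log(4))
  set.seed(9)
  for (i in 1:20) {
    a <- stats::runif(sample(2:30, 1), 0, 100)
    s <- shannon_diversity(a)
    expect_gte(s, 0)
    expect_lte(s, log(length(a)) + 1e-12)
    expect_equal(s, shannon_diversity(sample(a)))        # permutation
    expect_equal(s, shannon_diversity(a * 17.3))         # scale invariance
  }
  expect_equal(shannon_diversity(c(0, 5, 0, 5)), log(2)) # zeros contribute nothing
  expect_error(shannon_diversity(c(0, 0)), "zero")
  expect_error(shannon_diversity(numeric()), "no abundances")
})

test_that("companion diversity indices take standard values", {
  expect_equal(simpson_diversity(rep(1, 4)), 0.75)
  expect_equal(berger_parker(c(1, 3)), 0.75)
})

test_that("plug-in bandwidth is location invariant and scale equivariant", {
  set.seed(21)
  x <- stats::rnorm(120, 40, 8)
  h <- plugin_bandwidth(x)
  expect_equal(as.numeric(plugin_bandwidth(x + 13.7)), as.numeric(h))
  expect_equal(as.numeric(plugin_bandwidth(2.5 * x)), 2.5 * as.numeric(h),
               tolerance = 1e-10)
  expect_equal(attr(h, "method"), "plugin")
})

test_that("plug-in bandwidth matches the binned reference selector", {
  set.seed(200)
  x <- stats::rnorm(200)
  h <- as.numeric(plugin_bandwidth(x))
  ref <- KernSmooth::dpik(x, scalest = "minim")
  expect_equal(h, ref, tolerance = 5e-3)        # 3 significant figures
  set.seed(201)
  y <- stats::rnorm(200, 50, 12)
  expect_equal(as.numeric(plugin_bandwidth(y)),
               KernSmooth::dpik(y, scalest = "minim"), tolerance = 5e-3)
})

test_that("degenerate samples fall back without crashing", {
  h <- plugin_bandwidth(rep(42, 3))
  expect_equal(attr(h, "method"), "fallback")
  expect_gte(as.numeric(h), 0.5)                # documented floor
  h2 <- plugin_bandwidth(c(1, 2))
  expect_equal(attr(h2, "method"), "fallback")
  expect_gt(as.numeric(h2), 0)
})

test_that("weighted KDE: closed form, weight cancellation, oracle agreement", {
  # single point: density at the point is 1/(h sqrt(2 pi))
  h <- 2.5
  cv <- weighted_kde(30, weights = 1, h = h, grid = c(30))
  expect_equal(cv$density, 1 / (h * sqrt(2 * pi)))
  # equal weights cancel: identical to the unweighted estimator
  set.seed(5)
  x <- stats::runif(40, 10, 90)
  g <- seq(0, 100, length.out = 101)
  cw <- weighted_kde(x, weights = rep(7, 40), h = 3, grid = g)
  cu <- weighted_kde(x, weights = NULL, h = 3, grid = g)
  expect_equal(cw$density, cu$density, tolerance = 1e-14)
  # pointwise double-loop oracle
  w <- sample(1:4, 40, replace = TRUE)
  cv2 <- weighted_kde(x, weights = w, h = 3, grid = g)
  expect_equal(cv2$density, oracle_wkde(x, w, 3, g), tolerance = 1e-12)
  expect_error(weighted_kde(x, weights = w[-1], h = 3), "lengths")
  expect_error(weighted_kde(x, weights = w, h = 0), "positive")
})

test_that("KDE is a convex combination of kernels with unit mass", {
  set.seed(31)
  x <- c(stats::rnorm(80, 30, 4), stats::rnorm(80, 60, 4))
  w <- sample(1:3, 160, replace = TRUE)
  h <- as.numeric(plugin_bandwidth(x))
  cv <- weighted_kde(x, w, h = h)
  expect_true(all(cv$density >= 0))
  expect_lte(max(cv$density), 1 / (h * sqrt(2 * pi)) + 1e-12)
  expect_gte(kde_integral(cv), 0.98)
  expect_lte(kde_integral(cv), 1.02)
})

test_that("per-sample metrics count mutations and key genes", {
  b <- mm_case_bundle("presentation")
  w_hat <- distinct_mutations(integrate_bundle(b))
  met <- calculate_metrics(w_hat, b$k)
  expect_equal(met$n_mutations, 5L)
  expect_equal(met$n_key_genes, 5L)
  expect_equal(met$sdi,
               shannon_diversity(abundance(w_hat$dna_allelic_freq,
                                           w_hat$dna_depth, w_hat$copy_number)))
  expect_error(calculate_metrics(w_hat[0, ], b$k), "no mutations")
  f <- tempfile(fileext = ".json")
  write_metrics(met, "WES_P", f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$N, 5L)
  expect_equal(rep$KG, 5L)
})
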