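# ---------------------------------------------------------------------------
# Clonality statistics: variant allele frequency, per-mutation abundance,
# Shannon diversity of the abundance distribution, and a copy-number-weighted
# Gaussian kernel density of VAFs with a data-derived plug-in bandwidth.
# ---------------------------------------------------------------------------

#' Variant allele frequency from read counts
#'
#' VAF in percent: 100 * TRV / (TRV + TRR), where TRV and TRR are the read
#' counts supporting the variant and the reference allele.
#'
#' @param trv variant-supporting read count (>= 0).
#' @param trr reference-supporting read count (>= 0).
#' @return numeric vector of VAF percent values in [0, 100].
#' @export
compute_vaf <- function(trv, trr) {
  if (any(trv < 0 | trr < 0, na.rm = TRUE)) stop("read counts must be non-negative")
  tot <- trv + trr
  if (any(tot == 0, na.rm = TRUE)) {
    stop("undefined VAF: TRV + TRR = 0 for ", sum(tot == 0, na.rm = TRUE), " record(s)")
  }
  100 * trv / tot
}

#' Per-mutation abundance
#'
#' The abundance of a mutation treated as a molecular species is the product
#' VAF * DP * CN.  A missing copy number (no overlapping segment) is taken
#' as diploid (CN = 2).
#'
#' @param vaf VAF in percent.
#' @param dp read depth (> 0).
#' @param cn integer copy number, NA for unknown.
#' @return numeric abundance vector (non-negative).
#' @export
abundance <- function(vaf, dp, cn = NA_integer_) {
  if (any(dp <= 0, na.rm = TRUE)) stop("depth must be positive")
  cn <- ifelse(is.na(cn), 2, cn)
  vaf * dp * cn
}

#' Shannon diversity index of clone abundances
#'
#' SDI = -sum_i p(i) ln p(i) in nats, where p(i) is the relative abundance
#' of clone i.  Zero-abundance entries carry no information and contribute
#' nothing; at least one abundance must be strictly positive.
#'
#' @param abundances non-negative abundance values, one per clone/mutation.
#' @return Shannon diversity in nats; 0 for a single clone.
#' @export
shannon_diversity <- function(abundances) {
  if (!length(abundances)) stop("no abundances supplied")
  if (any(abundances < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  a <- abundances[!is.na(abundances) & abundances > 0]
  if (!length(a)) stop("all abundances are zero: diversity undefined")
  p <- a / sum(a)
  -sum(p * log(p))
}

#' Simpson diversity index (1 - sum p^2)
#'
#' Provided as an optional companion to [shannon_diversity()]; not used by
#' the default metrics.
#' @inheritParams shannon_diversity
#' @return Simpson index in [0, 1).
#' @export
simpson_diversity <- function(abundances) {
  a <- abundances[!is.na(abundances) & abundances > 0]
  if (!length(a)) stop("all abundances are zero: diversity undefined")
  p <- a / sum(a)
  1 - sum(p^2)
}

#' Berger-Parker dominance index (max p)
#'
#' @inheritParams shannon_diversity
#' @return dominance of the most abundant clone, in (0, 1].
#' @export
berger_parker <- function(abundances) {
  a <- abundances[!is.na(abundances) & abundances > 0]
  if (!length(a)) stop("all abundances are zero: diversity undefined")
  max(a) / sum(a)
}

# Derivatives of the standard normal density at 0 used by the plug-in
# selector: K^(4)(0) = 3/sqrt(2*pi), K^(6)(0) = -15/sqrt(2*pi).
.psi_hat <- function(x, g, r) {
  n <- length(x)
  d <- outer(x, x, "-") / g
  h4 <- switch(as.character(r),
    "4" = d^4 - 6 * d^2 + 3,
    "6" = d^6 - 15 * d^4 + 45 * d^2 - 15,
    stop("unsupported derivative order")
  )
  sum(stats::dnorm(d) * h4) / (n^2 * g^(r + 1))
}

#' Two-stage direct plug-in bandwidth for a Gaussian kernel
#'
#' Data-derived univariate bandwidth selector in the Sheather-Jones /
#' Wand-Jones direct plug-in family: the eighth-derivative density
#' functional is taken at its normal-scale value, then the sixth- and
#' fourth-derivative functionals are estimated with kernel estimators at
#' their asymptotically optimal pilot bandwidths, and the final bandwidth is
#' h = (1 / (2 sqrt(pi) psi4 n))^(1/5).  The scale estimate is
#' min(sd, IQR/1.349).
#'
#' The selector runs on the raw (unweighted) values; copy-number weights
#' enter the density estimate, not the bandwidth.  With fewer than
#' `min_n` distinct values, or when the plug-in numerics degenerate (zero
#' scale or a non-positive curvature functional), the selector falls back
#' to Silverman's rule with a floor of `floor_h`.
#'
#' @param values numeric sample (VAF percent in the pipeline, but any scale
#'   works: the selector is location invariant and scale equivariant).
#' @param min_n minimum number of distinct values for the plug-in path.
#' @param floor_h smallest bandwidth ever returned (VAF percent units).
#' @return positive bandwidth, with attribute `"method"` set to
#'   `"plugin"` or `"fallback"`.
#' @export
plugin_bandwidth <- function(values, min_n = 5L, floor_h = 0.5) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0L) stop("no values supplied")
  fallback <- function() {
    s <- stats::sd(x)
    iqr <- stats::IQR(x)
    sc <- if (n >= 2L) min(s, iqr / 1.349) else 0
    if (!is.finite(sc) || sc <= 0) sc <- if (is.finite(s) && s > 0) s else 0
    h <- if (sc > 0) 0.9 * sc * n^(-1 / 5) else 0
    h <- max(h, floor_h)
    attr(h, "method") <- "fallback"
    h
  }
  if (length(unique(x)) < min_n) return(fallback())
  sc <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(sc) || sc <= 0) return(fallback())
  psi8 <- 105 / (32 * sqrt(pi) * sc^9)
  g1 <- (2 * (15 / sqrt(2 * pi)) / (psi8 * n))^(1 / 9)
  psi6 <- .psi_hat(x, g1, 6L)
  if (!is.finite(psi6) || psi6 >= 0) return(fallback())
  g2 <- (-2 * (3 / sqrt(2 * pi)) / (psi6 * n))^(1 / 7)
  psi4 <- .psi_hat(x, g2, 4L)
  if (!is.finite(psi4) || psi4 <= 0) return(fallback())
  h <- (1 / (2 * sqrt(pi) * psi4 * n))^(1 / 5)
  attr(h, "method") <- "plugin"
  h
}

#' Copy-number-weighted Gaussian kernel density estimate
#'
#' f_hat(x) = sum_i w_i K((x_i - x)/h) / (h * sum_i w_i) with K the standard
#' normal density.  With all weights equal this reduces exactly to the
#' classical unweighted estimator (1/(n h)) sum_i K((x_i - x)/h).  In the
#' clonality pipeline x_i are VAF percent values and w_i the copy numbers of
#' the segments the mutations lie in (missing CN = 2).
#'
#' @param values sample values (VAF percent).
#' @param weights positive weights, one per value; NULL for unweighted.
#' @param h positive bandwidth.
#' @param grid evaluation points; default 512 equally spaced on [0, 100].
#' @return object of class `kde_curve`: list with `grid`, `density`,
#'   `bandwidth`, `n`, `weights_used`.
#' @export
weighted_kde <- function(values, weights = NULL, h,
                         grid = seq(0, 100, length.out = 512L)) {
  x <- as.numeric(values)
  if (!length(x)) stop("no values supplied")
  if (anyNA(x)) stop("NA values in sample")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("bandwidth must be a positive scalar")
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) {
    stop("weights and values have different lengths")
  }
  if (any(is.na(weights) | weights <= 0)) stop("weights must be positive")
  # column j of the kernel matrix is K((x_i - grid_j)/h)
  km <- stats::dnorm(outer(x, grid, "-") / h)
  dens <- as.numeric(crossprod(km, weights)) / (h * sum(weights))
  structure(
    list(grid = grid, density = dens, bandwidth = as.numeric(h),
         n = length(x), weights_used = !is.null(weights) && length(unique(weights)) > 1L),
    class = "kde_curve"
  )
}

#' @export
print.kde_curve <- function(x, ...) {
  cat(sprintf("Weighted Gaussian KDE: n = %d, h = %.4g, grid [%g, %g] x %d%s\n",
              x$n, x$bandwidth, min(x$grid), max(x$grid), length(x$grid),
              if (x$weights_used) ", copy-number weighted" else ""))
  invisible(x)
}

#' Local maxima of a KDE curve
#'
#' Interior grid points strictly higher than both neighbours; used to count
#' apparent clonal modes.
#'
#' @param curve a `kde_curve`.
#' @return numeric vector of grid positions of the modes.
#' @export
kde_modes <- function(curve) {
  d <- curve$density
  n <- length(d)
  if (n < 3L) return(numeric())
  i <- 2:(n - 1L)
  idx <- i[d[i] > d[i - 1L] & d[i] > d[i + 1L]]
  curve$grid[idx]
}

#' Trapezoidal integral of a KDE curve over its grid
#'
#' @param curve a `kde_curve`.
#' @return approximate integral (close to 1 when the grid covers the mass).
#' @export
kde_integral <- function(curve) {
  g <- curve$grid
  d <- curve$density
  sum(diff(g) * (d[-1] + d[-length(d)]) / 2)
}

#' Per-sample clonality metrics
#'
#' Computes, from a deduplicated mutation relation (see
#' [distinct_mutations()]), the mutation count N, the number of key genes
#' mutated, and the Shannon diversity index over per-mutation abundances
#' VAF * DP * CN.
#'
#' @param w_hat deduplicated mutation relation with columns
#'   `dna_allelic_freq`, `dna_depth`, `copy_number`, `gene_symbol`.
#' @param key_genes gene list relation ([gene_list()]) or NULL.
#' @return object of class `clonality_metrics`: list with `n_mutations`,
#'   `n_key_genes`, `sdi`.
#' @export
calculate_metrics <- function(w_hat, key_genes = NULL) {
  if (!nrow(w_hat)) stop("no mutations: metrics undefined")
  ab <- abundance(w_hat$dna_allelic_freq, w_hat$dna_depth, w_hat$copy_number)
  kg <- 0L
  if (!is.null(key_genes) && nrow(key_genes)) {
    kg_syms <- key_genes$gene_symbol[!is.na(key_genes$gene_symbol)]
    is_kg <- w_hat$gene_symbol %in% kg_syms
    if (!is.null(w_hat$ensembl_gene_id)) {
      is_kg <- is_kg | w_hat$ensembl_gene_id %in% key_genes$ensembl_gene_id
    }
    kg <- length(unique(w_hat$gene_symbol[is_kg]))
  }
  structure(
    list(n_mutations = nrow(w_hat), n_key_genes = kg,
         sdi = shannon_diversity(ab)),
    class = "clonality_metrics"
  )
}

#' @export
print.clonality_metrics <- function(x, ...) {
  cat(sprintf("N = %d mutations, KG = %d key genes, SDI = %.4f nats\n",
              x$n_mutations, x$n_key_genes, x$sdi))
  invisible(x)
}

#' Serialize clonality metrics to a small JSON report
#'
#' @param metrics a `clonality_metrics` object.
#' @param experiment_id experiment label included in the report.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_metrics <- function(metrics, experiment_id, path) {
  jsonlite::write_json(
    list(experiment = experiment_id, N = metrics$n_mutations,
         KG = metrics$n_key_genes, SDI = metrics$sdi),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
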