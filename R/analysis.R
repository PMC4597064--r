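# ---------------------------------------------------------------------------
# One-call clonality analysis of a bundle: filter, integrate, deduplicate,
# compute diversity metrics and the copy-number-weighted VAF density.
# Returned as a classed object with print/summary/plot methods.
# ---------------------------------------------------------------------------

#' Clonality analysis of one sample
#'
#' Runs the full pipeline on a bundle: VAF/depth filtering, the
#' multi-omic integration joins, deduplication to one row per mutation,
#' abundance-weighted Shannon diversity, and the copy-number-weighted
#' Gaussian KDE of VAF with a two-stage direct plug-in bandwidth.
#'
#' @param bundle a [dataset_bundle()].
#' @param settings [filter_settings()].
#' @param key_genes gene list for labelling/metrics; defaults to
#'   `bundle$k`.
#' @param grid KDE evaluation grid (default 512 points on [0, 100]).
#' @return object of class `clonal_analysis` with elements `integrated`,
#'   `w_hat`, `metrics`, `curve`, `settings`, `key_genes`.
#' @export
clonal_analysis <- function(bundle, settings = filter_settings(),
                            key_genes = bundle$k,
                            grid = seq(0, 100, length.out = 512L)) {
  integrated <- integrate_bundle(bundle, settings)
  w_hat <- distinct_mutations(integrated)
  if (!nrow(w_hat)) stop("no mutations pass the filter settings")
  metrics <- calculate_metrics(w_hat, key_genes)
  h <- plugin_bandwidth(w_hat$dna_allelic_freq)
  weights <- ifelse(is.na(w_hat$copy_number), 2, w_hat$copy_number)
  weights[weights <= 0] <- 2
  curve <- weighted_kde(w_hat$dna_allelic_freq, weights, h = h, grid = grid)
  structure(list(integrated = integrated, w_hat = w_hat, metrics = metrics,
                 curve = curve, settings = settings, key_genes = key_genes),
            class = "clonal_analysis")
}

#' @export
print.clonal_analysis <- function(x, ...) {
  cat("Integrative clonality analysis\n")
  cat(sprintf("  mutations (N):        %d\n", x$metrics$n_mutations))
  cat(sprintf("  key genes (KG):       %d\n", x$metrics$n_key_genes))
  cat(sprintf("  Shannon diversity:    %.4f nats\n", x$metrics$sdi))
  cat(sprintf("  KDE bandwidth (h):    %.4g VAF points [%s]\n",
              x$curve$bandwidth, attr(x$curve$bandwidth, "method") %||% "plugin"))
  cat(sprintf("  RNA-expressed:        %d of %d mutations\n",
              sum(x$w_hat$glyph == 2L), nrow(x$w_hat)))
  invisible(x)
}

#' @export
summary.clonal_analysis <- function(object, ...) {
  x <- object
  modes <- kde_modes(x$curve)
  out <- list(
    n_mutations = x$metrics$n_mutations,
    n_key_genes = x$metrics$n_key_genes,
    sdi = x$metrics$sdi,
    bandwidth = x$curve$bandwidth,
    n_modes = length(modes),
    mode_vafs = modes,
    n_rna_expressed = sum(x$w_hat$glyph == 2L),
    kde_integral = kde_integral(x$curve)
  )
  class(out) <- "summary.clonal_analysis"
  out
}

#' @export
print.summary.clonal_analysis <- function(x, ...) {
  cat(sprintf("N = %d, KG = %d, SDI = %.4f nats\n", x$n_mutations,
              x$n_key_genes, x$sdi))
  cat(sprintf("KDE: h = %.4g, %d mode(s) at VAF %s, grid integral %.4f\n",
              x$bandwidth, x$n_modes,
              paste(sprintf("%.1f", x$mode_vafs), collapse = ", "),
              x$kde_integral))
  cat(sprintf("RNA-expressed mutations: %d\n", x$n_rna_expressed))
  invisible(x)
}

#' @export
plot.clonal_analysis <- function(x, path = tempfile(fileext = ".png"),
                                 title = "Clonality analysis", ...) {
  spec <- plot_spec(path, title = title, opacity = x$settings$opacity,
                    show_kg_only = x$settings$show_kg_only, ...)
  plot_kde_scatter(x$w_hat, x$curve, x$key_genes, spec)
  invisible(path)
}
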