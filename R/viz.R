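# ---------------------------------------------------------------------------
# The three standard visualizations, rendered with base graphics to PNG or
# SVG.  Every plot also writes a machine-readable TSV of the plotted
# coordinates ("<image>_data.tsv"): the export, not the pixels, is the
# tested contract.
# ---------------------------------------------------------------------------

#' Plot specification
#'
#' @param path output image path; format inferred from the extension
#'   (".png" or ".svg").
#' @param title plot title.
#' @param width,height image size in pixels.
#' @param opacity point opacity, fraction in (0, 1].
#' @param label_genes gene symbols to annotate (key genes).
#' @param show_kg_only hide points whose gene is not labelled.
#' @return list of class `plot_spec`.
#' @export
plot_spec <- function(path, title = "", width = 900, height = 600,
                      opacity = 0.5, label_genes = character(),
                      show_kg_only = FALSE) {
  if (opacity <= 0 || opacity > 1) stop("opacity must be in (0, 1]")
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "svg")) stop("unsupported image format: ", fmt)
  structure(list(path = path, title = title, width = width, height = height,
                 opacity = opacity, label_genes = label_genes,
                 show_kg_only = isTRUE(show_kg_only), format = fmt),
            class = "plot_spec")
}

.open_device <- function(spec) {
  if (spec$format == "svg") {
    grDevices::svg(spec$path, width = spec$width / 96, height = spec$height / 96)
  } else {
    grDevices::png(spec$path, width = spec$width, height = spec$height,
                   res = 96)
  }
}

.export_path <- function(spec) {
  paste0(tools::file_path_sans_ext(spec$path), "_data.tsv")
}

.alpha <- function(col, opacity) {
  grDevices::adjustcolor(col, alpha.f = opacity)
}

# log-spaced depth -> color index on a continuous palette
.depth_colors <- function(depth, n = 64L) {
  pal <- grDevices::hcl.colors(n, "viridis")
  if (!length(depth)) return(character())
  ld <- log10(depth)
  rng <- range(ld)
  idx <- if (diff(rng) == 0) rep(1L, length(ld)) else {
    pmin(n, 1L + floor((ld - rng[1]) / diff(rng) * (n - 1L) + 0.5))
  }
  pal[idx]
}

# nudge overlapping labels apart vertically (simple collision resolution)
.place_labels <- function(x, y, labels, yrange) {
  if (!length(x)) return(invisible())
  ord <- order(x)
  ynudge <- y
  step <- 0.04 * diff(yrange)
  for (i in seq_along(ord)[-1]) {
    a <- ord[i - 1L]; b <- ord[i]
    if (abs(x[b] - x[a]) < 4 && abs(ynudge[b] - ynudge[a]) < step) {
      ynudge[b] <- ynudge[a] + step
    }
  }
  graphics::text(x, ynudge, labels, pos = 3, cex = 0.75, xpd = NA)
}

#' Genomic mutational overview
#'
#' One point per variant: the x-axis is the genome laid out as 24
#' chromosome bands (1-22, X, Y) scaled by GRCh37 chromosome length, with
#' the variant placed at its fractional position inside its band; y is VAF
#' percent; color encodes read depth on a log scale.
#'
#' @param w WES variant relation (chromosome labels normalized).
#' @param spec a [plot_spec()].
#' @return path of the data export, invisibly.
#' @export
plot_genomic_overview <- function(w, spec) {
  len <- grch37_chromosome_lengths()
  bad <- setdiff(unique(w$chromosome), names(len))
  if (length(bad)) stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  offsets <- c(0, cumsum(as.numeric(len)))[seq_along(len)]
  names(offsets) <- names(len)
  total <- sum(as.numeric(len))
  x <- (offsets[w$chromosome] + w$position) / total
  cols <- .depth_colors(w$dna_depth)

  export <- data.frame(chromosome = w$chromosome, position = w$position,
                       x = as.numeric(x), vaf = w$dna_allelic_freq,
                       depth = w$dna_depth, color = cols,
                       stringsAsFactors = FALSE)
  write_relation(export, .export_path(spec))

  .open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 100), xaxt = "n",
                 xlab = "chromosome", ylab = "VAF (%)", main = spec$title)
  mids <- (offsets + as.numeric(len) / 2) / total
  graphics::abline(v = offsets[-1] / total, col = "grey85")
  graphics::axis(1, at = mids, labels = names(len), cex.axis = 0.6, tick = FALSE)
  if (nrow(w)) {
    graphics::points(x, w$dna_allelic_freq, pch = 16,
                     col = .alpha(cols, spec$opacity), cex = 0.7)
  }
  invisible(.export_path(spec))
}

#' Paired-sample VAF scatter plot
#'
#' Shared variants at (VAF in sample 1, VAF in sample 2); sample-unique
#' variants on their own axis with the other coordinate at 0.  Three
#' colors distinguish shared / first-only / second-only; genes on the
#' label list are annotated.
#'
#' @param common,unique1,unique2 output of [paired_compare()].
#' @param k gene list used for labelling (or NULL).
#' @param spec a [plot_spec()].
#' @return path of the data export, invisibly.
#' @export
plot_paired_scatter <- function(common, unique1, unique2, k = NULL, spec) {
  lab_syms <- unique(c(spec$label_genes,
                       if (!is.null(k)) k$gene_symbol[!is.na(k$gene_symbol)]))
  mk <- function(rel, x, y, set) {
    data.frame(x = x, y = y, set = rep(set, length.out = max(0L, nrow(rel))),
               gene_symbol = if (nrow(rel)) rel$gene_symbol else character(),
               stringsAsFactors = FALSE)
  }
  export <- rbind(
    mk(common, common$dna_allelic_freq, common$dna_allelic_freq_2, "shared"),
    mk(unique1, unique1$dna_allelic_freq, rep(0, nrow(unique1)), "sample1_only"),
    mk(unique2, rep(0, nrow(unique2)), unique2$dna_allelic_freq, "sample2_only")
  )
  export$labelled <- export$gene_symbol %in% lab_syms
  if (spec$show_kg_only) export <- export[export$labelled, , drop = FALSE]
  write_relation(export, .export_path(spec))

  cols <- c(shared = "#2166ac", sample1_only = "#1b7837", sample2_only = "#b2182b")
  .open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "VAF sample 1 (%)", ylab = "VAF sample 2 (%)",
                 main = spec$title)
  graphics::abline(0, 1, col = "grey80", lty = 2)
  if (nrow(export)) {
    graphics::points(export$x, export$y, pch = 16,
                     col = .alpha(cols[export$set], spec$opacity), cex = 0.8)
    lab <- export[export$labelled, , drop = FALSE]
    .place_labels(lab$x, lab$y, lab$gene_symbol, c(0, 100))
  }
  graphics::legend("topleft", legend = c("shared", "sample 1 only", "sample 2 only"),
                   col = cols, pch = 16, bty = "n", cex = 0.8)
  invisible(.export_path(spec))
}

#' KDE-plus-scatter panel
#'
#' Upper panel: copy-number-weighted Gaussian kernel density of VAF.
#' Lower panel: depth-vs-VAF scatter of the deduplicated mutations, with a
#' circle glyph for WES-only mutations and a star for mutations also found
#' in RNA; labelled genes annotated; shared x-axis on [0, 100].
#'
#' @param w_hat deduplicated mutation relation ([distinct_mutations()]).
#' @param curve a `kde_curve` ([weighted_kde()]).
#' @param k gene list used for labelling (or NULL).
#' @param spec a [plot_spec()].
#' @return path of the data export, invisibly.
#' @export
plot_kde_scatter <- function(w_hat, curve, k = NULL, spec) {
  lab_syms <- unique(c(spec$label_genes,
                       if (!is.null(k)) k$gene_symbol[!is.na(k$gene_symbol)]))
  export <- data.frame(
    vaf = w_hat$dna_allelic_freq, depth = w_hat$dna_depth,
    glyph = w_hat$glyph, gene_symbol = w_hat$gene_symbol,
    labelled = w_hat$gene_symbol %in% lab_syms,
    stringsAsFactors = FALSE
  )
  if (spec$show_kg_only) export <- export[export$labelled, , drop = FALSE]
  write_relation(export, .export_path(spec))

  .open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, nrow = 2), heights = c(1, 1.6))
  graphics::par(mar = c(0.5, 4, 3, 1))
  graphics::plot(curve$grid, curve$density, type = "l", col = "#2166ac",
                 lwd = 2, xaxt = "n", xlab = "", ylab = "density",
                 xlim = c(0, 100), main = spec$title)
  graphics::mtext(sprintf("h = %.3g", curve$bandwidth), side = 3, line = -1.2,
                  adj = 0.98, cex = 0.7)
  graphics::par(mar = c(4, 4, 0.5, 1))
  ymax <- if (nrow(export)) max(export$depth) * 1.1 else 1
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(0, ymax),
                 xlab = "VAF (%)", ylab = "depth")
  if (nrow(export)) {
    circ <- export$glyph == 1L
    graphics::points(export$vaf[circ], export$depth[circ], pch = 21,
                     bg = .alpha("#2166ac", spec$opacity), col = "#2166ac",
                     cex = 0.9)
    graphics::points(export$vaf[!circ], export$depth[!circ], pch = 8,
                     col = .alpha("#b2182b", min(1, spec$opacity + 0.3)),
                     cex = 1.1)
    lab <- export[export$labelled, , drop = FALSE]
    .place_labels(lab$vaf, lab$depth, lab$gene_symbol, c(0, ymax))
  }
  graphics::legend("topright", legend = c("WES only", "WES + RNA"),
                   pch = c(21, 8), col = c("#2166ac", "#b2182b"),
                   pt.bg = c("#2166ac", NA), bty = "n", cex = 0.8)
  invisible(.export_path(spec))
}
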