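# ---------------------------------------------------------------------------
# Multi-omic integration: the six-stage join pipeline that combines WES
# variants with methylation, RNA-expressed variants, transcript expression,
# gene counts and copy number into one integrated relation, plus the derived
# tables (deduplicated mutation relation, key-gene table, RNA transcript
# table, TSG methylation table, paired-sample comparison).
# ---------------------------------------------------------------------------

#' Filter settings for the variant pipeline
#'
#' Defaults follow the standard somatic retention criteria: VAF >= 4%,
#' 20 <= DP <= 1000, methylation threshold 25%, scatter opacity 50%.
#'
#' @param min_vaf,max_vaf VAF bounds in percent (inclusive).
#' @param min_depth,max_depth depth bounds in reads (inclusive).
#' @param min_meth minimum methylation percent for the TSG table.
#' @param opacity scatter plot point opacity, fraction in (0, 1].
#' @param show_kg_only hide non-key-gene points in plots.
#' @return list of class `filter_settings`.
#' @export
filter_settings <- function(min_vaf = 4, max_vaf = 100, min_depth = 20,
                            max_depth = 1000, min_meth = 25, opacity = 0.5,
                            show_kg_only = FALSE) {
  if (min_vaf > max_vaf) stop("min_vaf > max_vaf")
  if (min_depth > max_depth) stop("min_depth > max_depth")
  if (opacity <= 0 || opacity > 1) stop("opacity must be in (0, 1]")
  structure(list(min_vaf = min_vaf, max_vaf = max_vaf, min_depth = min_depth,
                 max_depth = max_depth, min_meth = min_meth, opacity = opacity,
                 show_kg_only = isTRUE(show_kg_only)),
            class = "filter_settings")
}

#' Retain variants by VAF and depth
#'
#' Keeps rows with min_vaf <= AF <= max_vaf and min_depth <= DP <= max_depth,
#' all bounds inclusive.
#'
#' @param w WES variant relation.
#' @param s [filter_settings()].
#' @return filtered relation.
#' @export
filter_wes <- function(w, s = filter_settings()) {
  keep <- w$dna_allelic_freq >= s$min_vaf & w$dna_allelic_freq <= s$max_vaf &
    w$dna_depth >= s$min_depth & w$dna_depth <= s$max_depth
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Methylation columns renamed so they never clash with gene-count columns
# downstream; meth_gene_id keeps the probe's own gene annotation.
.meth_sel <- function(m) {
  data.frame(target_id = m$target_id, avg_beta = m$avg_beta,
             regulatory_feature = m$regulatory_feature,
             relation_to_cpg_island = m$relation_to_cpg_island,
             meth_gene_id = m$ensembl_gene_id,
             stringsAsFactors = FALSE)
}

#' Stage I: impact-restricted variants joined to methylation
#'
#' Selects MODERATE/HIGH-impact variants and left-outer-joins the
#' methylation relation on the gene identifier.
#'
#' @param w WES variant relation (already VAF/depth filtered).
#' @param m methylation probe relation.
#' @return relation with W columns plus nullable probe columns.
#' @export
build_I <- function(w, m) {
  sel <- w[w$effect_impact %in% c("MODERATE", "HIGH"), , drop = FALSE]
  left_outer_join(sel, .meth_sel(m), by = c(ensembl_gene_id = "meth_gene_id"))
}

#' Stage J: RNA variants joined to expressed transcripts
#'
#' Equi-joins RNA variants to transcript quantifications on the gene
#' identifier, keeping transcripts with FPKM strictly > 0.
#'
#' @param rv RNA variant relation.
#' @param r transcript quantification relation.
#' @return relation with RV columns plus transcript columns.
#' @export
build_J <- function(rv, r) {
  r_pos <- r[!is.na(r$fpkm) & r$fpkm > 0, , drop = FALSE]
  out <- equi_join(rv, r_pos, by = "ensembl_gene_id")
  out[, c("chromosome", "position", "ensembl_gene_id", "rna_depth",
          "rna_allelic_freq", "ensembl_transcript_id", "fpkm"), drop = FALSE]
}

#' Stage D: RNA variants joined to genes with nonzero raw counts
#'
#' Equi-joins RNA variants to the gene-count relation on the gene
#' identifier, keeping counts strictly > 0.
#'
#' @param rv RNA variant relation.
#' @param h gene count relation.
#' @return relation with RV columns plus `count`.
#' @export
build_D <- function(rv, h) {
  h_pos <- h[!is.na(h$count) & h$count > 0, , drop = FALSE]
  out <- equi_join(rv, h_pos, by = "ensembl_gene_id")
  out[, c("chromosome", "position", "ensembl_gene_id", "rna_depth",
          "rna_allelic_freq", "count"), drop = FALSE]
}

#' Build the integrated relation
#'
#' Chains the remaining pipeline stages: L = I left-joined to J on
#' (chromosome, position); N = L left-joined to D on (chromosome,
#' position); the result left-joined to the CNV segments by containment
#' (chromosome equal, Start <= Position <= Stop).  A glyph column is
#' computed per record: 2 (WES_PLUS_RNA) when the RNA variant join matched
#' and the gene has expression support (transcript FPKM > 0 or raw count
#' > 0), otherwise 1 (WES_ONLY).
#'
#' @param I,J,D outputs of [build_I()], [build_J()], [build_D()].
#' @param c_seg CNV segment relation.
#' @return integrated relation; one row per (variant x matching probe x
#'   matching transcript) combination, with nullable RNA/expression/CN
#'   columns and an integer `glyph`.
#' @export
build_integrated <- function(I, J, D, c_seg) {
  j_sel <- J[, c("chromosome", "position", "rna_depth", "rna_allelic_freq",
                 "ensembl_transcript_id", "fpkm"), drop = FALSE]
  L <- left_outer_join(I, j_sel, by = c("chromosome", "position"),
                       suffix = ".j")
  d_sel <- data.frame(chromosome = D$chromosome, position = D$position,
                      d_rna_depth = D$rna_depth,
                      d_rna_allelic_freq = D$rna_allelic_freq,
                      count = D$count, stringsAsFactors = FALSE)
  N <- left_outer_join(L, d_sel, by = c("chromosome", "position"),
                       suffix = ".d")
  # RNA evidence may arrive via either join; coalesce the RV fields
  N$rna_depth <- ifelse(is.na(N$rna_depth), N$d_rna_depth, N$rna_depth)
  N$rna_allelic_freq <- ifelse(is.na(N$rna_allelic_freq),
                               N$d_rna_allelic_freq, N$rna_allelic_freq)
  N$d_rna_depth <- NULL
  N$d_rna_allelic_freq <- NULL

  # Containment join on the distinct loci: with non-overlapping segments a
  # locus matches at most one segment, anything else is a data integrity
  # error surfaced here.
  c_sel <- c_seg[, c("chromosome", "start", "stop", "copy_number"), drop = FALSE]
  loci <- project_distinct(N, c("chromosome", "position"))
  hits <- left_outer_join(
    loci, c_sel, by = "chromosome",
    predicate = function(l, r) l$position >= r$start & l$position <= r$stop,
    suffix = ".c"
  )
  lkey <- paste(hits$chromosome, hits$position, sep = "\r")
  if (anyDuplicated(lkey)) {
    dup <- unique(lkey[duplicated(lkey)])
    stop("variant overlaps more than one CNV segment at ",
         paste(sub("\r", ":", dup), collapse = ", "))
  }
  out <- N
  out$copy_number <- hits$copy_number[match(paste(N$chromosome, N$position, sep = "\r"), lkey)]
  has_rna <- !is.na(out$rna_depth)
  has_expr <- (!is.na(out$fpkm) & out$fpkm > 0) | (!is.na(out$count) & out$count > 0)
  out$glyph <- ifelse(has_rna & has_expr, 2L, 1L)
  out
}

#' Run the full integration pipeline for one sample
#'
#' Convenience wrapper: VAF/depth filtering, then the I/J/D stages, then the
#' integrated relation.
#'
#' @param bundle a [dataset_bundle()].
#' @param s [filter_settings()].
#' @return integrated relation.
#' @export
integrate_bundle <- function(bundle, s = filter_settings()) {
  w <- filter_wes(bundle$w, s)
  I <- build_I(w, bundle$m)
  J <- build_J(bundle$rv, bundle$r)
  D <- build_D(bundle$rv, bundle$h)
  build_integrated(I, J, D, bundle$c)
}

.WHAT_COLS <- c("chromosome", "position", "dna_depth", "copy_number",
                "dna_change", "amino_acid_change", "dna_allelic_freq",
                "gene_symbol", "glyph")

#' Deduplicated mutation relation (scatter-plot relation)
#'
#' Distinct projection of the integrated relation onto (chromosome,
#' position, DP, CN, DNA change, AA change, VAF, gene symbol, glyph): one
#' row per mutation regardless of how many probes/transcripts matched it.
#'
#' @param integrated output of [build_integrated()].
#' @return deduplicated relation.
#' @export
distinct_mutations <- function(integrated) {
  project_distinct(integrated, .WHAT_COLS)
}

#' Expressed transcripts at one mutation's locus
#'
#' Distinct (gene symbol, transcript, FPKM) rows of the integrated relation
#' at the locus of `w_hat_row`; empty for mutations without RNA evidence.
#'
#' @param w_hat_row single row of [distinct_mutations()] output (or any list
#'   with `chromosome` and `position`).
#' @param integrated the integrated relation.
#' @return relation with columns gene_symbol, ensembl_transcript_id, fpkm.
#' @export
transcripts_for <- function(w_hat_row, integrated) {
  sel <- integrated[integrated$chromosome == w_hat_row$chromosome[1L] &
                      integrated$position == w_hat_row$position[1L] &
                      !is.na(integrated$ensembl_transcript_id), , drop = FALSE]
  project_distinct(sel, c("gene_symbol", "ensembl_transcript_id", "fpkm"))
}

#' Key-gene summary table
#'
#' Restricts the deduplicated mutation relation to genes in the key-gene
#' list and emits one summary row per variant: gene, DNA change, AA change,
#' CN, DP, AF, an RNA-expressed flag, and the gene classification.
#'
#' @param w_hat output of [distinct_mutations()].
#' @param k key-gene list ([gene_list()]).
#' @return summary relation ordered by gene symbol.
#' @export
key_gene_table <- function(w_hat, k) {
  kg_syms <- k$gene_symbol[!is.na(k$gene_symbol)]
  sel <- w_hat[w_hat$gene_symbol %in% kg_syms, , drop = FALSE]
  out <- data.frame(
    gene_symbol = sel$gene_symbol,
    dna_change = sel$dna_change,
    amino_acid_change = sel$amino_acid_change,
    copy_number = sel$copy_number,
    dna_depth = sel$dna_depth,
    dna_allelic_freq = sel$dna_allelic_freq,
    rna_mutation = sel$glyph == 2L,
    stringsAsFactors = FALSE
  )
  out$classification <- k$classification[match(out$gene_symbol, k$gene_symbol)]
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RNA transcript table
#'
#' Distinct (gene symbol, RNA depth, RNA AF, FPKM, transcript) rows of the
#' integrated relation: one row per expressed-mutation transcript.
#'
#' @param integrated the integrated relation.
#' @return relation shaped like the per-sample mRNA expression tables.
#' @export
rna_table <- function(integrated) {
  sel <- integrated[!is.na(integrated$ensembl_transcript_id), , drop = FALSE]
  out <- project_distinct(sel, c("gene_symbol", "rna_depth",
                                 "rna_allelic_freq", "fpkm",
                                 "ensembl_transcript_id"))
  rownames(out) <- NULL
  out
}

#' TSG methylation table
#'
#' Methylation probes of tumor-suppressor genes passing all three
#' criteria -- average beta >= min_meth/100, "Promoter Associated"
#' regulatory feature, CpG "Island" -- each joined to the gene's raw RNA
#' read count (0 when the gene is absent from the count relation).  The
#' `silenced` flag marks probes of genes with zero counts.  Operates on the
#' methylation relation directly so unmutated TSGs are reported too; see
#' [tsg_methylation_integrated()] for the variant restricted to mutated key
#' genes.
#'
#' String matching of the annotation fields is case-insensitive after
#' trimming.
#'
#' @param m methylation probe relation.
#' @param h gene count relation.
#' @param genes gene list; rows with classification "TSG" are used.
#' @param s [filter_settings()] (supplies min_meth, in percent).
#' @return relation with one row per passing probe.
#' @export
tsg_methylation_table <- function(m, h, genes, s = filter_settings()) {
  tsg <- genes[!is.na(genes$classification) &
                 toupper(genes$classification) == "TSG", , drop = FALSE]
  norm <- function(x) tolower(trimws(x))
  keep <- !is.na(m$ensembl_gene_id) & m$ensembl_gene_id %in% tsg$ensembl_gene_id &
    !is.na(m$avg_beta) & m$avg_beta >= s$min_meth / 100 &
    !is.na(m$regulatory_feature) & norm(m$regulatory_feature) == "promoter associated" &
    !is.na(m$relation_to_cpg_island) & norm(m$relation_to_cpg_island) == "island"
  sel <- m[keep, , drop = FALSE]
  cnt <- h$count[match(sel$ensembl_gene_id, h$ensembl_gene_id)]
  cnt[is.na(cnt)] <- 0L
  out <- data.frame(
    target_id = sel$target_id,
    avg_beta = sel$avg_beta,
    gene_symbol = tsg$gene_symbol[match(sel$ensembl_gene_id, tsg$ensembl_gene_id)],
    ensembl_gene_id = sel$ensembl_gene_id,
    rna_read_count = cnt,
    classification = tsg$classification[match(sel$ensembl_gene_id, tsg$ensembl_gene_id)],
    regulatory_feature = sel$regulatory_feature,
    relation_to_cpg_island = sel$relation_to_cpg_island,
    silenced = cnt == 0L,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_symbol, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation of mutated key genes (integrated-relation route)
#'
#' The literal projection: the integrated relation equi-joined to the gene
#' list, projected distinct onto (target id, beta, gene symbol, annotation
#' fields, gene id, count).  Only mutated genes can appear here, since the
#' integrated relation is rooted in the WES variants.
#'
#' @param integrated the integrated relation.
#' @param k gene list.
#' @return distinct probe rows for mutated genes in `k`.
#' @export
tsg_methylation_integrated <- function(integrated, k) {
  j <- equi_join(integrated, k[, "ensembl_gene_id", drop = FALSE],
                 by = "ensembl_gene_id")
  sel <- j[!is.na(j$target_id), , drop = FALSE]
  project_distinct(sel, c("target_id", "avg_beta", "gene_symbol",
                          "regulatory_feature", "relation_to_cpg_island",
                          "ensembl_gene_id", "count"))
}

#' Paired-sample comparison of mutation relations
#'
#' Partitions two samples' variants on the (chromosome, position) key into
#' shared and sample-unique sets.  The shared relation carries both
#' samples' VAF and depth (suffix `_2` for the second sample).
#'
#' @param w1,w2 WES variant relations (typically VAF/depth filtered).
#' @return list with elements `common`, `unique1`, `unique2`.
#' @export
paired_compare <- function(w1, w2) {
  keys <- c("chromosome", "position")
  common <- intersect_on(w1, w2, keys)
  if (nrow(common)) {
    w2_dedup <- w2[!duplicated(.key_string(w2, keys)), , drop = FALSE]
    idx <- match(.key_string(common, keys), .key_string(w2_dedup, keys))
    common$dna_allelic_freq_2 <- w2_dedup$dna_allelic_freq[idx]
    common$dna_depth_2 <- w2_dedup$dna_depth[idx]
  } else {
    common$dna_allelic_freq_2 <- numeric()
    common$dna_depth_2 <- integer()
  }
  list(common = common,
       unique1 = difference_on(w1, w2, keys),
       unique2 = difference_on(w2, w1, keys))
}
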