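# ---------------------------------------------------------------------------
# DatasetBundle: the in-memory container holding one sample's eight
# relations, plus directory-level serialization (VCFs + TSV tables + a JSON
# manifest) used by the generator, the CLI and the round-trip tests.
# ---------------------------------------------------------------------------

#' Bundle the per-sample relations
#'
#' Groups the WES variant (W), methylation (M), copy-number (C), gene count
#' (H), RNA variant (RV), transcript quantification (R) relations and the
#' experiment metadata (P) for one sample.  Each member relation must carry
#' a single experiment identifier; the identifiers may differ across
#' modalities (the DNA/RNA/methylation pairing is what the metadata
#' records).  A key-gene list may ride along as `k`.
#'
#' @param w,m,c,h,rv,r member relations (see [wes_variants()] and friends).
#' @param meta [experiment_meta()] relation.
#' @param k optional [gene_list()].
#' @return object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(w = wes_variants(), m = methylation_probes(),
                           c = cnv_segments(), h = gene_counts(),
                           rv = rna_variants(), r = transcript_quants(),
                           meta = experiment_meta(), k = NULL) {
  for (nm in c("w", "m", "c", "h", "rv", "r")) {
    rel <- get(nm)
    if (nrow(rel) && length(unique(rel$experiment_id)) > 1L) {
      stop("relation '", nm, "' mixes experiment ids: ",
           paste(unique(rel$experiment_id), collapse = ", "))
    }
  }
  structure(list(w = w, m = m, c = c, h = h, rv = rv, r = r,
                 meta = meta, k = k),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("Multi-omic dataset bundle\n")
  cat(sprintf("  WES variants:     %5d\n", nrow(x$w)))
  cat(sprintf("  RNA variants:     %5d\n", nrow(x$rv)))
  cat(sprintf("  Transcripts:      %5d\n", nrow(x$r)))
  cat(sprintf("  Gene counts:      %5d\n", nrow(x$h)))
  cat(sprintf("  Methyl. probes:   %5d\n", nrow(x$m)))
  cat(sprintf("  CNV segments:     %5d\n", nrow(x$c)))
  if (!is.null(x$k)) cat(sprintf("  Listed genes:     %5d\n", nrow(x$k)))
  invisible(x)
}

# --- fixture VCF writers ----------------------------------------------------
# These emit plain-text VCFs whose allele-support counts reproduce the
# relation exactly when DP * VAF / 100 is an integer (which the synthetic
# generator guarantees by construction).  SNVs only; ref/alt bases are
# synthesized as A>C since the relations do not carry alleles.

.vcf_escape_counts <- function(depth, vaf) {
  trv <- as.integer(round(depth * vaf / 100))
  list(trv = trv, trr = depth - trv)
}

#' Write a W relation as a Strelka-dialect somatic VCF
#'
#' Tier-count genotype encoding (AU/CU/GU/TU) with NORMAL and TUMOR
#' columns and one ANN annotation entry per variant-gene row.
#'
#' @param w [wes_variants()] relation.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_wes_vcf <- function(w, path) {
  hdr <- c(
    "##fileformat=VCFv4.1",
    "##source=strelka",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A tier1,tier2 counts\">",
    "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C tier1,tier2 counts\">",
    "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G tier1,tier2 counts\">",
    "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T tier1,tier2 counts\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t")
  )
  body <- character()
  if (nrow(w)) {
    # one VCF record per locus; annotations for all gene rows at the locus
    key <- paste(w$chromosome, w$position, sep = "\r")
    ord <- order(match(w$chromosome, .CHROMOSOMES), w$position)
    w <- w[ord, , drop = FALSE]
    key <- key[ord]
    body <- vapply(split(seq_len(nrow(w)), factor(key, levels = unique(key))),
                   function(idx) {
      first <- w[idx[1L], ]
      cnt <- .vcf_escape_counts(first$dna_depth, first$dna_allelic_freq)
      ann <- paste(vapply(idx, function(i) {
        paste("C", "variant", w$effect_impact[i], w$gene_symbol[i],
              w$ensembl_gene_id[i], "transcript", "", "", "",
              w$dna_change[i],
              ifelse(is.na(w$amino_acid_change[i]), "", w$amino_acid_change[i]),
              sep = "|")
      }, character(1)), collapse = ",")
      # ref A counts go to AU, alt C counts to CU ("tier1,tier2")
      tumor <- sprintf("%d:%d,%d:%d,%d:0,0:0,0", first$dna_depth,
                       cnt$trr, cnt$trr, cnt$trv, cnt$trv)
      normal <- sprintf("%d:%d,%d:0,0:0,0:0,0", first$dna_depth,
                        first$dna_depth, first$dna_depth)
      paste(first$chromosome, first$position, ".", "A", "C", ".", "PASS",
            paste0("ANN=", ann), "DP:AU:CU:GU:TU", normal, tumor, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an RV relation as a GATK-dialect VCF
#'
#' Allelic-depth genotype encoding (GT:AD:DP) with a GENEID INFO tag.
#'
#' @param rv [rna_variants()] relation.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rna_vcf <- function(rv, path) {
  hdr <- c(
    "##fileformat=VCFv4.1",
    "##source=HaplotypeCaller",
    "##INFO=<ID=GENEID,Number=1,Type=String,Description=\"Ensembl gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE", sep = "\t")
  )
  body <- character()
  if (nrow(rv)) {
    ord <- order(match(rv$chromosome, .CHROMOSOMES), rv$position)
    rv <- rv[ord, , drop = FALSE]
    cnt <- .vcf_escape_counts(rv$rna_depth, rv$rna_allelic_freq)
    body <- paste(rv$chromosome, rv$position, ".", "A", "C", ".", "PASS",
                  ifelse(is.na(rv$ensembl_gene_id), ".",
                         paste0("GENEID=", rv$ensembl_gene_id)),
                  "GT:AD:DP",
                  sprintf("0/1:%d,%d:%d", cnt$trr, cnt$trv, rv$rna_depth),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a bundle as a directory of standard files
#'
#' Emits `wes.vcf` (Strelka dialect), `rna.vcf` (GATK dialect), `cnv.tsv`,
#' `counts.tsv` (htseq-count style, with summary rows), `fpkm.tsv`
#' (tracking style), `methylation.tsv`, `genes.tsv`, `meta.tsv` and a
#' `manifest.json` recording the experiment ids (and, for generated
#' bundles, the seed and configuration).
#'
#' @param bundle a [dataset_bundle()].
#' @param dir output directory (created if needed).
#' @param manifest_extra named list merged into the manifest.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir, manifest_extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_wes_vcf(bundle$w, fp("wes.vcf"))
  write_rna_vcf(bundle$rv, fp("rna.vcf"))
  write_relation(data.frame(chromosome = bundle$c$chromosome,
                            start = bundle$c$start, stop = bundle$c$stop,
                            copy_number = bundle$c$copy_number),
                 fp("cnv.tsv"))
  cnt_lines <- c(paste(bundle$h$ensembl_gene_id, bundle$h$count, sep = "\t"),
                 "__no_feature\t0", "__ambiguous\t0", "__not_aligned\t0")
  writeLines(cnt_lines, fp("counts.tsv"))
  write_relation(data.frame(tracking_id = bundle$r$ensembl_transcript_id,
                            gene_id = bundle$r$ensembl_gene_id,
                            FPKM = bundle$r$fpkm),
                 fp("fpkm.tsv"))
  write_relation(data.frame(target_id = bundle$m$target_id,
                            avg_beta = bundle$m$avg_beta,
                            regulatory_feature = bundle$m$regulatory_feature,
                            relation_to_cpg_island = bundle$m$relation_to_cpg_island,
                            ensembl_gene_id = bundle$m$ensembl_gene_id),
                 fp("methylation.tsv"))
  if (!is.null(bundle$k)) write_relation(bundle$k, fp("genes.tsv"))
  write_relation(bundle$meta, fp("meta.tsv"))
  ids <- function(rel) if (nrow(rel)) unique(rel$experiment_id) else NA
  manifest <- c(list(
    experiments = list(wes = ids(bundle$w), rna = ids(bundle$rv),
                       methylation = ids(bundle$m))
  ), manifest_extra)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a [dataset_bundle()].
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  manifest <- jsonlite::read_json(fp("manifest.json"))
  ex <- manifest$experiments
  id_or <- function(x, fallback) if (is.null(x)) fallback else as.character(x)
  wes_id <- id_or(ex$wes, "WES")
  rna_id <- id_or(ex$rna, "RNA")
  meth_id <- id_or(ex$methylation, "METH")
  k <- if (file.exists(fp("genes.tsv"))) read_gene_list(fp("genes.tsv")) else NULL
  dataset_bundle(
    w = read_wes_vcf(fp("wes.vcf"), wes_id),
    m = read_methylation(fp("methylation.tsv"), meth_id),
    c = read_cnv(fp("cnv.tsv"), wes_id),
    h = read_counts(fp("counts.tsv"), rna_id),
    rv = read_rna_vcf(fp("rna.vcf"), rna_id),
    r = read_fpkm(fp("fpkm.tsv"), rna_id),
    meta = if (file.exists(fp("meta.tsv"))) read_meta(fp("meta.tsv"))
           else experiment_meta(),
    k = k
  )
}
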