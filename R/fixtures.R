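# ---------------------------------------------------------------------------
# Synthetic multi-omic data generation with planted clonal structure, and
# the packaged worked example: a paired presentation/relapse multiple
# myeloma case with key-gene, transcript and TSG-methylation tables.
# ---------------------------------------------------------------------------

# Built-in pool of tumor suppressor genes used by the generator's silenced
# TSG construct (identifiers are canonical Ensembl gene ids).
.TSG_POOL <- data.frame(
  gene_symbol = c("AXIN1", "BRCA1", "CDKN2A", "CEBPA", "MEN1", "MSH2",
                  "PTCH1", "RUNX1", "SOCS1", "RB1", "TP53", "VHL"),
  ensembl_gene_id = c("ENSG00000103126", "ENSG00000012048", "ENSG00000147889",
                      "ENSG00000245848", "ENSG00000133895", "ENSG00000095002",
                      "ENSG00000185920", "ENSG00000159216", "ENSG00000185338",
                      "ENSG00000139687", "ENSG00000141510", "ENSG00000134086"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic bundle generator
#'
#' The defaults describe a mid-sized exome study sample: about a hundred
#' retained somatic mutations in two clones (a clonal cluster near 45% VAF
#' and a subclonal cluster near 20%), per-clone VAF spread of 3 points,
#' depths uniform over 30-300x around a 100x design, roughly a third of
#' mutations detectable in RNA, a few percent of mutated genes on the
#' key-gene list, and a handful of promoter-methylated, transcriptionally
#' silenced TSGs.
#'
#' @param seed integer RNG seed (Mersenne-Twister via [set.seed()]).
#' @param n_variants number of somatic variants.
#' @param clone_centers VAF percent centers of the planted clones.
#' @param clone_weights mixing fractions, summing to 1.
#' @param vaf_sd within-clone VAF standard deviation (percent).
#' @param depth_range inclusive integer depth range.
#' @param fraction_rna_expressed fraction of variants mirrored into the RNA
#'   relations (variant, expressed transcripts, positive gene count).
#' @param n_tsg_silenced number of silenced TSGs planted (passing
#'   methylation criteria with zero count).
#' @param cnv_profile data.frame(chromosome, start, stop, copy_number);
#'   default is diploid genome-wide with chromosome 8 trisomic and
#'   chromosome 13 monosomic.
#' @param key_gene_fraction fraction of mutated genes put on the key-gene
#'   list.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_variants = 100L,
                           clone_centers = c(20, 45),
                           clone_weights = c(0.5, 0.5), vaf_sd = 3,
                           depth_range = c(30L, 300L),
                           fraction_rna_expressed = 0.3,
                           n_tsg_silenced = 4L,
                           cnv_profile = NULL,
                           key_gene_fraction = 0.05) {
  if (abs(sum(clone_weights) - 1) > 1e-9) stop("clone_weights must sum to 1")
  if (length(clone_weights) != length(clone_centers)) {
    stop("clone_centers and clone_weights lengths differ")
  }
  if (any(clone_centers <= 0 | clone_centers >= 100)) {
    stop("clone_centers must lie in (0, 100)")
  }
  if (is.null(cnv_profile)) {
    len <- grch37_chromosome_lengths()
    cnv_profile <- data.frame(
      chromosome = names(len), start = 1L, stop = as.integer(len),
      copy_number = ifelse(names(len) == "8", 3L,
                           ifelse(names(len) == "13", 1L, 2L)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 clone_centers = clone_centers, clone_weights = clone_weights,
                 vaf_sd = vaf_sd, depth_range = as.integer(depth_range),
                 fraction_rna_expressed = fraction_rna_expressed,
                 n_tsg_silenced = as.integer(n_tsg_silenced),
                 cnv_profile = cnv_profile,
                 key_gene_fraction = key_gene_fraction),
            class = "fixture_config")
}

# truncated normal on (lo, hi) by resampling
.rtruncnorm <- function(n, mean, sd, lo = 0.5, hi = 99.5) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate a synthetic multi-omic bundle with planted clonal structure
#'
#' Draws per-clone VAFs from truncated normals around the configured
#' centers, uniform integer depths, and back-computes variant-supporting
#' read counts so that [compute_vaf()] reproduces the stored VAF exactly.
#' A configured fraction of variants is mirrored into the RNA relations
#' (RNA variant at the same locus, one or two expressed transcripts,
#' positive raw gene count), creating mixed WES-only / WES-plus-RNA glyph
#' populations downstream.  `n_tsg_silenced` tumor suppressor genes are
#' given promoter-island probes with beta above threshold and a zero read
#' count; two additional TSGs are planted that fail the criteria (one
#' expressed, one off-island probe) to exercise the filters.
#'
#' Deterministic for a fixed seed.
#'
#' @param cfg a [fixture_config()].
#' @return a [dataset_bundle()] with the key-gene/TSG list in `$k`.
#' @export
generate_bundle <- function(cfg = fixture_config()) {
  if (cfg$n_tsg_silenced > nrow(.TSG_POOL) - 2L) {
    stop("n_tsg_silenced exceeds the built-in TSG pool (",
         nrow(.TSG_POOL) - 2L, " usable genes)")
  }
  set.seed(cfg$seed)
  n <- cfg$n_variants
  len <- grch37_chromosome_lengths()

  clone <- sample.int(length(cfg$clone_centers), n, replace = TRUE,
                      prob = cfg$clone_weights)
  vaf0 <- .rtruncnorm(n, cfg$clone_centers[clone], cfg$vaf_sd)
  depth <- sample(seq(cfg$depth_range[1L], cfg$depth_range[2L]), n,
                  replace = TRUE)
  trv <- pmax(1L, as.integer(round(depth * vaf0 / 100)))
  vaf <- compute_vaf(trv, depth - trv)

  chrom <- sample(names(len), n, replace = TRUE, prob = len)
  pos <- vapply(chrom, function(ch) sample.int(len[[ch]], 1L), integer(1))
  gene_id <- sprintf("ENSGSIM%05d", seq_len(n))
  gene_sym <- sprintf("SIMG%d", seq_len(n))
  impact <- sample(c("MODERATE", "HIGH", "LOW", "MODIFIER"), n,
                   replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  has_aa <- impact %in% c("MODERATE", "HIGH")

  w <- wes_variants(
    chromosome = chrom, position = pos, dna_depth = depth,
    dna_allelic_freq = vaf, ensembl_gene_id = gene_id,
    gene_symbol = gene_sym,
    dna_change = sprintf("c.%dA>C", sample.int(5000L, n, replace = TRUE)),
    amino_acid_change = ifelse(has_aa, sprintf("p.Ala%dThr", seq_len(n)),
                               NA_character_),
    effect_impact = impact, experiment_id = "WES_SIM"
  )

  # RNA mirror: chosen variants appear as RNA variants with expressed
  # transcripts and a positive raw count for their gene
  expressed <- which(stats::runif(n) < cfg$fraction_rna_expressed)
  rna_depth <- sample(10:200, length(expressed), replace = TRUE)
  rna_trv <- pmax(1L, as.integer(round(rna_depth * vaf[expressed] / 100)))
  rv <- rna_variants(
    chromosome = chrom[expressed], position = pos[expressed],
    ensembl_gene_id = gene_id[expressed], rna_depth = rna_depth,
    rna_allelic_freq = compute_vaf(rna_trv, rna_depth - rna_trv),
    experiment_id = "RNA_SIM"
  )
  n_tx <- sample(1:2, length(expressed), replace = TRUE)
  tx_gene <- rep(expressed, n_tx)
  r <- transcript_quants(
    ensembl_transcript_id = sprintf("ENSTSIM%05d", seq_along(tx_gene)),
    ensembl_gene_id = gene_id[tx_gene],
    fpkm = round(stats::runif(length(tx_gene), 0.5, 80), 2),
    experiment_id = "RNA_SIM"
  )

  # TSG construct: silenced genes pass all three criteria with count 0;
  # one expressed TSG and one off-island probe are planted as controls
  tsg_n <- cfg$n_tsg_silenced
  tsg <- .TSG_POOL[seq_len(tsg_n + 2L), , drop = FALSE]
  silenced <- tsg[seq_len(tsg_n), , drop = FALSE]
  n_probe <- sample(1:3, tsg_n, replace = TRUE)
  probe_gene <- rep.int(seq_len(tsg_n), n_probe)
  m <- methylation_probes(
    target_id = sprintf("cg%08d", sample.int(99999999L, length(probe_gene) + 2L)),
    avg_beta = c(round(stats::runif(length(probe_gene), 0.26, 0.95), 7),
                 0.55, 0.62),
    regulatory_feature = c(rep("Promoter Associated", length(probe_gene) + 1L),
                           "Unclassified"),
    relation_to_cpg_island = c(rep("Island", length(probe_gene) + 1L),
                               "N_Shore"),
    ensembl_gene_id = c(silenced$ensembl_gene_id[probe_gene],
                        tsg$ensembl_gene_id[tsg_n + 1L],
                        tsg$ensembl_gene_id[tsg_n + 2L]),
    experiment_id = "METH_SIM"
  )

  h <- gene_counts(
    ensembl_gene_id = c(gene_id[expressed], silenced$ensembl_gene_id,
                        tsg$ensembl_gene_id[tsg_n + 1L]),
    count = c(sample(1:500, length(expressed), replace = TRUE),
              rep(0L, tsg_n), 37L),
    experiment_id = "RNA_SIM"
  )

  n_kg <- max(0L, round(cfg$key_gene_fraction * n))
  kg_idx <- if (n_kg) sample.int(n, n_kg) else integer()
  k <- gene_list(
    ensembl_gene_id = c(gene_id[kg_idx], tsg$ensembl_gene_id),
    gene_symbol = c(gene_sym[kg_idx], tsg$gene_symbol),
    classification = c(rep("Driver", n_kg), rep("TSG", nrow(tsg)))
  )

  cseg <- cnv_segments(
    chromosome = cfg$cnv_profile$chromosome, start = cfg$cnv_profile$start,
    stop = cfg$cnv_profile$stop, copy_number = cfg$cnv_profile$copy_number,
    experiment_id = "WES_SIM"
  )
  meta <- experiment_meta(
    patient_id = rep("SIM-PAT", 3),
    experiment_id = c("WES_SIM", "RNA_SIM", "METH_SIM"),
    experiment_description = c("whole exome sequencing", "RNA-seq",
                               "450K methylation array"),
    sample_type = rep("synthetic tumor", 3)
  )
  dataset_bundle(w = w, m = m, c = cseg, h = h, rv = rv, r = r,
                 meta = meta, k = k)
}

# --- packaged worked example ------------------------------------------------

.MM_KEY_GENES <- data.frame(
  gene_symbol = c("DNA2", "MYC", "SETD2", "TET2", "TNFRSF11A",
                  "KRAS", "MTOR", "MLL3"),
  ensembl_gene_id = c("ENSG00000138346", "ENSG00000136997", "ENSG00000181555",
                      "ENSG00000168769", "ENSG00000141655", "ENSG00000133703",
                      "ENSG00000198793", "ENSG00000055609"),
  chromosome = c("10", "8", "3", "4", "18", "12", "1", "7"),
  # synthetic loci inside each gene's approximate GRCh37 span
  position = c(70226000L, 128750500L, 47100500L, 106156500L, 60022000L,
               25398284L, 11190000L, 151900000L),
  dna_change = c("c.146delG", "c.226G>A", "c.7085A>G", "c.2725C>T",
                 "c.1097C>T", "c.183A>C", "c.6016G>C", "c.944G>A"),
  amino_acid_change = c(NA, "p.Ala76Thr", "p.Gln2362Arg", "p.Gln909*",
                        "p.Pro366Leu", "p.Gln61His", "p.Val2006Leu",
                        "p.Gly315Asp"),
  effect_impact = c("HIGH", "MODERATE", "MODERATE", "HIGH", "MODERATE",
                    "MODERATE", "MODERATE", "MODERATE"),
  classification = c("DNA repair", "Amp oncogene + VUS", "HMT", "Oncogene",
                     "Bone remodelling", "Oncogene", "Oncogene", "HMT"),
  stringsAsFactors = FALSE
)

.MM_TSGS <- .TSG_POOL[.TSG_POOL$gene_symbol %in%
                        c("AXIN1", "BRCA1", "CDKN2A", "CEBPA", "MEN1",
                          "MSH2", "PTCH1", "RUNX1", "SOCS1"), ]

.mm_wes <- function(sample) {
  g <- .MM_KEY_GENES
  if (sample == "presentation") {
    sel <- 1:5
    dp <- c(82L, 207L, 94L, 117L, 244L)
    af <- c(17, 31, 24, 24, 14)
    id <- "WES_P"
  } else {
    sel <- 1:8
    dp <- c(70L, 257L, 105L, 129L, 283L, 175L, 69L, 392L)
    af <- c(38, 33, 35, 36, 15, 4, 23, 4)
    id <- "WES_R"
  }
  wes_variants(
    chromosome = g$chromosome[sel], position = g$position[sel],
    dna_depth = dp, dna_allelic_freq = af,
    ensembl_gene_id = g$ensembl_gene_id[sel], gene_symbol = g$gene_symbol[sel],
    dna_change = g$dna_change[sel], amino_acid_change = g$amino_acid_change[sel],
    effect_impact = g$effect_impact[sel], experiment_id = id
  )
}

.mm_cnv <- function(sample) {
  g <- .MM_KEY_GENES
  if (sample == "presentation") {
    sel <- 1:5
    cn <- c(1L, 3L, 1L, 3L, 3L)
    id <- "WES_P"
  } else {
    sel <- 1:8
    cn <- c(3L, 3L, 2L, 3L, 3L, 3L, 1L, 1L)
    id <- "WES_R"
  }
  cnv_segments(
    chromosome = g$chromosome[sel],
    start = g$position[sel] - 1000000L, stop = g$position[sel] + 1000000L,
    copy_number = cn, experiment_id = id
  )
}

.mm_rna <- function(sample) {
  g <- .MM_KEY_GENES
  gid <- function(sym) g$ensembl_gene_id[match(sym, g$gene_symbol)]
  pos <- function(sym) g$position[match(sym, g$gene_symbol)]
  chr <- function(sym) g$chromosome[match(sym, g$gene_symbol)]
  if (sample == "presentation") {
    id <- "RNA_P"
    syms <- c("MYC", "SETD2", "TET2")
    dp <- c(192L, 25L, 6L)
    af <- c(100, 50, 50)
    tx <- data.frame(
      sym = c("MYC", "MYC", "SETD2", "SETD2", "TET2", "TET2"),
      transcript = c("ENST00000377970", "ENST00000524013", "ENST00000409792",
                     "ENST00000431180", "ENST00000380013", "ENST00000265149"),
      fpkm = c(42, 58, 9.5, 2.2, 2.0, 1.2),
      stringsAsFactors = FALSE
    )
  } else {
    id <- "RNA_R"
    syms <- c("MYC", "SETD2", "MTOR")
    dp <- c(100L, 29L, 20L)
    af <- c(100, 50, 50)
    tx <- data.frame(
      sym = c("MYC", "MYC", "SETD2", "SETD2", "SETD2", "SETD2", "MTOR", "MTOR"),
      transcript = c("ENST00000377970", "ENST00000524013", "ENST00000409792",
                     "ENST00000431180", "ENST00000445387", "CUFF.29743.3",
                     "ENST00000361445", "ENST00000376838"),
      fpkm = c(24, 55, 3.2, 1.5, 1.2, 9.4, 4.7, 2.2),
      stringsAsFactors = FALSE
    )
  }
  list(
    rv = rna_variants(chromosome = chr(syms), position = pos(syms),
                      ensembl_gene_id = gid(syms), rna_depth = dp,
                      rna_allelic_freq = af, experiment_id = id),
    r = transcript_quants(ensembl_transcript_id = tx$transcript,
                          ensembl_gene_id = gid(tx$sym), fpkm = tx$fpkm,
                          experiment_id = id),
    mut_counts = gene_counts(gid(syms), dp, id)
  )
}

.mm_meth <- function(sample) {
  tid <- function(sym) .MM_TSGS$ensembl_gene_id[match(sym, .MM_TSGS$gene_symbol)]
  if (sample == "presentation") {
    id <- "METH_P"
    probes <- data.frame(
      target_id = c("cg27549619", "cg26370022", "cg11529738", "cg24900425",
                    "cg13601799", "cg01437571", "cg00976692", "cg14803009",
                    "cg22866426", "cg27003951"),
      avg_beta = c(0.3934072, 0.6804651, 0.7789396, 0.9020266, 0.2905587,
                   0.3243266, 0.291538, 0.3387372, 0.4628801, 0.2562254),
      sym = c("AXIN1", "BRCA1", "BRCA1", "BRCA1", "CDKN2A", "CEBPA", "MEN1",
              "MSH2", "RUNX1", "SOCS1"),
      stringsAsFactors = FALSE
    )
    counts <- data.frame(
      sym = c("AXIN1", "BRCA1", "CDKN2A", "CEBPA", "MEN1", "MSH2", "RUNX1",
              "SOCS1"),
      count = c(4L, 0L, 13L, 0L, 8L, 0L, 1L, 0L),
      stringsAsFactors = FALSE
    )
  } else {
    id <- "METH_R"
    probes <- data.frame(
      target_id = c("cg27549619", "cg02086790", "cg26370022", "cg24900425",
                    "cg11529738", "cg13601799", "cg00976692", "cg14803009",
                    "cg22073802", "cg22866426", "cg17339910", "cg04004558",
                    "cg27003951"),
      avg_beta = c(0.443731, 0.4921295, 0.6747859, 0.8910863, 0.7637555,
                   0.467826, 0.293402, 0.4267139, 0.2875548, 0.5251715,
                   0.399428, 0.2809271, 0.2598022),
      sym = c("AXIN1", "AXIN1", "BRCA1", "BRCA1", "BRCA1", "CDKN2A", "MEN1",
              "MSH2", "PTCH1", "RUNX1", "RUNX1", "SOCS1", "SOCS1"),
      stringsAsFactors = FALSE
    )
    counts <- data.frame(
      sym = c("AXIN1", "BRCA1", "CDKN2A", "MEN1", "MSH2", "PTCH1", "RUNX1",
              "SOCS1"),
      count = c(0L, 0L, 38L, 0L, 0L, 23L, 0L, 0L),
      stringsAsFactors = FALSE
    )
  }
  list(
    m = methylation_probes(
      target_id = probes$target_id, avg_beta = probes$avg_beta,
      regulatory_feature = "Promoter Associated",
      relation_to_cpg_island = "Island",
      ensembl_gene_id = tid(probes$sym), experiment_id = id
    ),
    tsg_counts = gene_counts(tid(counts$sym), counts$count,
                             if (sample == "presentation") "RNA_P" else "RNA_R")
  )
}

#' Worked-example multiple myeloma bundle (presentation or relapse)
#'
#' A paired serial-sample case study encoded as relations: key-gene somatic
#' mutations with copy number, depth and allelic frequency; the
#' RNA-expressed subset with per-transcript FPKM (including one
#' assembler-novel transcript in the relapse); and promoter-island TSG
#' methylation probes with raw RNA read counts.  The presentation sample
#' carries five mutated key genes, three of them RNA-expressed; the relapse
#' gains KRAS, MTOR and MLL3.  Loci are synthetic positions inside each
#' gene's approximate GRCh37 span.
#'
#' @param sample "presentation" or "relapse".
#' @return a [dataset_bundle()] with the key-gene/TSG list in `$k`.
#' @export
mm_case_bundle <- function(sample = c("presentation", "relapse")) {
  sample <- match.arg(sample)
  rna <- .mm_rna(sample)
  meth <- .mm_meth(sample)
  h <- rbind(rna$mut_counts, meth$tsg_counts)
  k <- gene_list(
    ensembl_gene_id = c(.MM_KEY_GENES$ensembl_gene_id,
                        .MM_TSGS$ensembl_gene_id),
    gene_symbol = c(.MM_KEY_GENES$gene_symbol, .MM_TSGS$gene_symbol),
    classification = c(.MM_KEY_GENES$classification,
                       rep("TSG", nrow(.MM_TSGS)))
  )
  suff <- if (sample == "presentation") "P" else "R"
  year <- if (sample == "presentation") "2010" else "2013"
  meta <- experiment_meta(
    patient_id = rep("MM-01", 3),
    experiment_id = paste0(c("WES_", "RNA_", "METH_"), suff),
    experiment_description = c("whole exome sequencing", "RNA-seq",
                               "450K methylation array"),
    sample_type = rep(sample, 3),
    sample_collection_date = rep(paste0(year, "-01-01"), 3)
  )
  dataset_bundle(w = .mm_wes(sample), m = meth$m, c = .mm_cnv(sample),
                 h = h, rv = rna$rv, r = rna$r, meta = meta, k = k)
}
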