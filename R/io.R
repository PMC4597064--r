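# ---------------------------------------------------------------------------
# Readers converting standard bioinformatics files into the typed relations,
# and the canonical tab-separated writer for any relation.  VCF parsing goes
# through vcfR; the two supported somatic dialects differ only in how allele
# support is encoded (Strelka tier counts AU/CU/GU/TU vs. GATK allelic
# depths AD).
# ---------------------------------------------------------------------------

# Split a multi-entry INFO annotation (ANN=...) into per-alternate records.
# ANN subfields (SnpEff 4.x): allele | annotation | impact | gene_name |
# gene_id | feature_type | feature_id | ... | HGVS.c (10) | HGVS.p (11).
.parse_ann <- function(info) {
  ann <- sub(".*(?:^|;)ANN=([^;]*).*", "\\1", info)
  if (identical(ann, info) || !nzchar(ann)) return(NULL)
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  do.call(rbind, lapply(fields, function(f) {
    f <- c(f, rep("", max(0, 11 - length(f))))
    data.frame(allele = f[1], impact = f[3], gene_symbol = f[4],
               gene_id = f[5], hgvs_c = f[10], hgvs_p = f[11],
               stringsAsFactors = FALSE)
  }))
}

.detect_dialect <- function(vcf) {
  meta <- vcf@meta
  if (any(grepl("strelka", meta, ignore.case = TRUE)) ||
      any(grepl("ID=AU", meta))) return("strelka")
  if (any(grepl("ID=AD", meta))) return("gatk")
  stop("cannot detect VCF dialect: no Strelka tier counts (AU) and no ",
       "allelic depths (AD) declared in the header")
}

# Allele support (TRV, TRR) for one record under each dialect.  Strelka
# SNV records carry per-base tier counts "tier1,tier2"; the first tier is
# used.  GATK records carry AD = ref,alt[,alt2...].
.allele_support <- function(dialect, format, sample_field, ref, alt, alt_index) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  vals <- strsplit(sample_field, ":", fixed = TRUE)[[1]]
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }
  tier1 <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]][1])
  if (dialect == "strelka") {
    counts <- c(A = get("AU"), C = get("CU"), G = get("GU"), T = get("TU"))
    if (anyNA(counts)) return(c(trv = NA_integer_, trr = NA_integer_))
    c(trv = tier1(counts[[alt]]), trr = tier1(counts[[ref]]))
  } else {
    ad <- get("AD")
    if (is.na(ad)) return(c(trv = NA_integer_, trr = NA_integer_))
    parts <- as.integer(strsplit(ad, ",", fixed = TRUE)[[1]])
    c(trv = parts[alt_index + 1L], trr = parts[1L])
  }
}

# Shared VCF ingestion: one output row per (record, alternate, annotated
# gene).  Multi-allelic records are split.  Returns a data.frame with
# chromosome, position, trv, trr, depth, and (when annotated) impact/gene
# fields.  `sample_col` selects the genotype column (tumor sample).
.read_vcf_records <- function(path, sample_col = NULL, need_ann = FALSE,
                              dialect = "auto") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || !nrow(fix)) {
    return(data.frame(chromosome = character(), position = integer(),
                      trv = integer(), trr = integer(), depth = integer(),
                      impact = character(), gene_symbol = character(),
                      gene_id = character(), hgvs_c = character(),
                      hgvs_p = character(), stringsAsFactors = FALSE))
  }
  gt <- vcf@gt
  if (is.null(gt) || !ncol(gt)) stop("VCF has no genotype columns: ", path)
  samples <- colnames(gt)[-1L]
  if (is.null(sample_col)) {
    sample_col <- if ("TUMOR" %in% samples) "TUMOR" else samples[length(samples)]
  }
  if (!sample_col %in% samples) {
    stop("sample column '", sample_col, "' not present in ", path)
  }
  if (identical(dialect, "auto")) dialect <- .detect_dialect(vcf)
  if (!dialect %in% c("strelka", "gatk")) stop("unknown VCF dialect: ", dialect)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- fix[i, "INFO"]
    ann <- if (need_ann) .parse_ann(info) else NULL
    if (need_ann && is.null(ann)) {
      stop("missing ANN annotation at ", fix[i, "CHROM"], ":", fix[i, "POS"])
    }
    fmt <- gt[i, 1L]
    sf <- gt[i, sample_col]
    per_alt <- lapply(seq_along(alts), function(ai) {
      sup <- .allele_support(dialect, fmt, sf, ref, alts[ai], ai)
      base <- data.frame(chromosome = fix[i, "CHROM"],
                         position = as.integer(fix[i, "POS"]),
                         trv = sup[["trv"]], trr = sup[["trr"]],
                         stringsAsFactors = FALSE)
      if (is.null(ann)) return(base)
      a <- ann[ann$allele == alts[ai] | !nzchar(ann$allele), , drop = FALSE]
      if (!nrow(a)) return(NULL)
      # keep the highest-impact annotation per gene
      a$rank <- match(a$impact, .IMPACT_LEVELS)
      a <- a[order(a$gene_id, -a$rank), , drop = FALSE]
      a <- a[!duplicated(a$gene_id), , drop = FALSE]
      cbind(base[rep(1L, nrow(a)), , drop = FALSE],
            a[, c("impact", "gene_symbol", "gene_id", "hgvs_c", "hgvs_p"),
              drop = FALSE])
    })
    rows[[i]] <- do.call(rbind, per_alt)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an annotated somatic WES VCF into the W relation
#'
#' Accepts Strelka-style (tier counts) or GATK-style (allelic depths)
#' genotype encodings, auto-detected from the header unless forced.  VAF is
#' computed as 100 * TRV / (TRV + TRR); records with TRV + TRR = 0 are
#' skipped with a warning.  One row is produced per (position, alternate,
#' annotated gene), keeping the highest-impact annotation per gene.
#' Gzip-compressed input is supported.
#'
#' @param path VCF file (optionally .gz).
#' @param experiment_id experiment identifier stamped on every row.
#' @param sample which genotype column to use; default the TUMOR column if
#'   present, else the last.
#' @param dialect "auto", "strelka" or "gatk".
#' @return a [wes_variants()] relation.
#' @export
read_wes_vcf <- function(path, experiment_id, sample = NULL, dialect = "auto") {
  rec <- .read_vcf_records(path, sample_col = sample, need_ann = TRUE,
                           dialect = dialect)
  if (!nrow(rec)) return(wes_variants())
  zero <- !is.na(rec$trv) & !is.na(rec$trr) & (rec$trv + rec$trr) == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with no allele-supporting reads skipped")
    rec <- rec[!zero, , drop = FALSE]
  }
  if (anyNA(rec$trv) || anyNA(rec$trr)) {
    stop("allele support counts missing in ", path)
  }
  wes_variants(
    chromosome = rec$chromosome,
    position = rec$position,
    dna_depth = rec$trv + rec$trr,
    dna_allelic_freq = compute_vaf(rec$trv, rec$trr),
    ensembl_gene_id = rec$gene_id,
    gene_symbol = rec$gene_symbol,
    dna_change = rec$hgvs_c,
    amino_acid_change = ifelse(nzchar(rec$hgvs_p), rec$hgvs_p, NA_character_),
    effect_impact = rec$impact,
    experiment_id = experiment_id
  )
}

#' Read an RNA-seq variant VCF into the RV relation
#'
#' Same dialect handling as [read_wes_vcf()]; annotation is optional and
#' only the gene id is taken from it when present (an `GENEID=` INFO tag or
#' the ANN gene field).
#'
#' @inheritParams read_wes_vcf
#' @return an [rna_variants()] relation.
#' @export
read_rna_vcf <- function(path, experiment_id, sample = NULL, dialect = "auto") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || !nrow(fix)) return(rna_variants())
  rec <- .read_vcf_records(path, sample_col = sample, need_ann = FALSE,
                           dialect = dialect)
  # gene id: prefer a GENEID INFO tag, else the first ANN gene
  info <- fix[, "INFO"]
  gid <- ifelse(grepl("(^|;)GENEID=", info),
                sub(".*(?:^|;)GENEID=([^;]*).*", "\\1", info), NA_character_)
  ann_gid <- vapply(info, function(x) {
    a <- .parse_ann(x)
    if (is.null(a) || !nrow(a)) NA_character_ else a$gene_id[1L]
  }, character(1), USE.NAMES = FALSE)
  gid <- ifelse(is.na(gid), ann_gid, gid)
  key <- paste(fix[, "CHROM"], fix[, "POS"], sep = "\r")
  rec$gene <- gid[match(paste(rec$chromosome, rec$position, sep = "\r"), key)]
  zero <- !is.na(rec$trv) & !is.na(rec$trr) & (rec$trv + rec$trr) == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with no allele-supporting reads skipped")
    rec <- rec[!zero, , drop = FALSE]
  }
  if (!nrow(rec)) return(rna_variants())
  rna_variants(
    chromosome = rec$chromosome,
    position = rec$position,
    ensembl_gene_id = rec$gene,
    rna_depth = rec$trv + rec$trr,
    rna_allelic_freq = compute_vaf(rec$trv, rec$trr),
    experiment_id = experiment_id
  )
}

.open_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read an htseq-count style two-column gene count table
#'
#' Tab-separated gene id / count rows; trailing summary rows whose ids
#' begin with a double underscore (e.g. __no_feature) are excluded.
#'
#' @param path count file (optionally .gz).
#' @param experiment_id experiment identifier.
#' @return a [gene_counts()] relation.
#' @export
read_counts <- function(path, experiment_id) {
  lines <- .open_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_counts())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed count line ", bad[1L], " in ", path)
  ids <- vapply(parts, `[`, character(1), 1L)
  counts <- vapply(parts, `[`, character(1), 2L)
  keep <- !startsWith(ids, "__")
  ids <- ids[keep]; counts <- counts[keep]
  num <- suppressWarnings(as.numeric(counts))
  if (anyNA(num) || any(num != floor(num))) {
    stop("non-integer count at line ", which(keep)[which(is.na(num) | num != floor(num))[1L]],
         " in ", path)
  }
  gene_counts(ids, as.integer(num), experiment_id)
}

#' Read a Cufflinks isoform tracking table into the R relation
#'
#' Requires columns `tracking_id` (transcript), `gene_id`, and `FPKM`
#' (case-insensitive); assembler-novel ids are accepted verbatim.
#'
#' @param path tracking file (optionally .gz).
#' @param experiment_id experiment identifier.
#' @return a [transcript_quants()] relation.
#' @export
read_fpkm <- function(path, experiment_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) return(transcript_quants())
  pick <- function(cands) {
    i <- match(tolower(cands), tolower(names(df)))
    i <- i[!is.na(i)][1]
    if (is.na(i) || is.null(i)) stop("missing column (one of ",
                                     paste(cands, collapse = "/"), ") in ", path)
    df[[i]]
  }
  fpkm <- as.numeric(pick(c("FPKM")))
  if (any(is.na(fpkm) | fpkm < 0)) stop("negative or missing FPKM in ", path)
  transcript_quants(
    ensembl_transcript_id = as.character(pick(c("tracking_id", "transcript_id"))),
    ensembl_gene_id = as.character(pick(c("gene_id"))),
    fpkm = fpkm,
    experiment_id = experiment_id
  )
}

#' Read a CNV segment table into the C relation
#'
#' Expects columns chromosome/chr, start/probe_start, stop/end, and
#' copy_number/CN (case-insensitive).  Segments are sorted and overlap
#' within a chromosome is rejected.
#'
#' @param path segment table (optionally .gz).
#' @param experiment_id experiment identifier.
#' @return a [cnv_segments()] relation.
#' @export
read_cnv <- function(path, experiment_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) return(cnv_segments())
  pick <- function(cands) {
    i <- match(tolower(cands), tolower(names(df)))
    i <- i[!is.na(i)][1]
    if (is.na(i) || is.null(i)) stop("missing column (one of ",
                                     paste(cands, collapse = "/"), ") in ", path)
    df[[i]]
  }
  cnv_segments(
    chromosome = pick(c("chromosome", "chr")),
    start = as.integer(pick(c("start", "probe_start"))),
    stop = as.integer(pick(c("stop", "end", "probe_end"))),
    copy_number = as.integer(pick(c("copy_number", "cn", "copy.number"))),
    experiment_id = experiment_id
  )
}

#' Read an Illumina 450K probe export into the M relation
#'
#' Requires columns for the probe id (TargetID), average beta, gene id,
#' regulatory feature and relation to CpG island (names matched
#' case-insensitively, dots/spaces/underscores interchangeable).  Beta is
#' parsed as a fraction and validated to [0, 1]; rows without a gene id are
#' kept with NA.
#'
#' @param path probe table (optionally .gz).
#' @param experiment_id experiment identifier.
#' @return a [methylation_probes()] relation.
#' @export
read_methylation <- function(path, experiment_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) return(methylation_probes())
  canon <- function(x) gsub("[._ -]", "", tolower(x))
  pick <- function(cands, required = TRUE) {
    i <- match(canon(cands), canon(names(df)))
    i <- i[!is.na(i)][1]
    if (is.na(i) || is.null(i)) {
      if (required) stop("missing column (one of ",
                         paste(cands, collapse = "/"), ") in ", path)
      return(NULL)
    }
    df[[i]]
  }
  beta <- as.numeric(pick(c("avg_beta", "avgbeta", "beta")))
  if (any(is.na(beta) | beta < 0 | beta > 1)) {
    stop("beta value outside [0, 1] in ", path)
  }
  gid <- pick(c("ensembl_gene_id", "ensembl geneid", "gene_id"))
  gid[!nzchar(trimws(gid))] <- NA_character_
  methylation_probes(
    target_id = as.character(pick(c("target_id", "targetid"))),
    avg_beta = beta,
    regulatory_feature = as.character(pick(c("regulatory_feature"))),
    relation_to_cpg_island = as.character(pick(c("relation_to_cpg_island",
                                                 "relation to ucsc cpg island"))),
    ensembl_gene_id = as.character(gid),
    experiment_id = experiment_id
  )
}

#' Read a gene list (one id per line, or tabular with classification)
#'
#' @param path list file: either one gene id per line, or a tab-separated
#'   table with columns ensembl_gene_id, optionally gene_symbol and
#'   classification (with header).
#' @return a [gene_list()] relation, deduplicated on gene id.
#' @export
read_gene_list <- function(path) {
  lines <- .open_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_list())
  if (grepl("\t", lines[1L]) && grepl("ensembl_gene_id", lines[1L])) {
    df <- utils::read.delim(textConnection(lines), stringsAsFactors = FALSE)
    gene_list(df$ensembl_gene_id,
              if ("gene_symbol" %in% names(df)) df$gene_symbol else NA_character_,
              if ("classification" %in% names(df)) df$classification else NA_character_)
  } else {
    gene_list(trimws(lines))
  }
}

#' Read an experiment metadata table into the P relation
#'
#' @param path tab-separated table with the P columns (header required).
#' @return an [experiment_meta()] relation.
#' @export
read_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c("patient_id", "experiment_id", "experiment_description",
            "sample_type", "sample_description", "experiment_date",
            "sample_collection_date")
  for (col in setdiff(cols, names(df))) df[[col]] <- NA_character_
  do.call(experiment_meta, as.list(df[, cols, drop = FALSE]))
}

#' Write any relation as a canonical tab-separated file
#'
#' Header row, NA encoded as empty fields, reals at 10 significant digits,
#' stable column order.  Re-reading with [read_relation()] reproduces an
#' equal relation.
#'
#' @param rel data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_relation <- function(rel, path) {
  out <- rel
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(signif(out[[j]], 10), digits = 10,
                                 format = "g"))
    }
    if (is.logical(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), NA, out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write relation to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a canonical tab-separated relation dump
#'
#' Inverse of [write_relation()]: empty fields become NA.  Column types are
#' inferred; supply `coerce` (a relation constructor) to re-impose the
#' typed schema.
#'
#' @param path file written by [write_relation()].
#' @param coerce optional constructor (e.g. [wes_variants]) applied to the
#'   columns.
#' @return data.frame.
#' @export
read_relation <- function(path, coerce = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  if (!is.null(coerce)) df <- do.call(coerce, as.list(df))
  df
}
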