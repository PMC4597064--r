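# ---------------------------------------------------------------------------
# Typed in-memory relations.
#
# Each relation is a plain data.frame with a fixed column set; the
# constructors below validate domains and normalize chromosome labels so the
# integration pipeline can be written as a literal chain of relational
# operators.  NULL is represented by NA and never satisfies an equality
# predicate (standard relational semantics).
# ---------------------------------------------------------------------------

.CHROMOSOMES <- c(as.character(1:22), "X", "Y")

.IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

#' Normalize chromosome labels
#'
#' Strips any "chr" prefix (case-insensitively) and validates labels against
#' the human nuclear chromosome set 1-22, X, Y.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
  bad <- !is.na(x) & !(x %in% .CHROMOSOMES)
  if (any(bad)) {
    stop("unknown chromosome label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}


# When the leading field is empty, force every argument to length zero so
# scalar defaults do not fabricate rows.
.empty_args <- function(args, lead) {
  if (length(args[[lead]]) == 0L) lapply(args, function(x) x[0]) else args
}

.stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
}

#' WES somatic variant relation (W)
#'
#' One row per DNA-level somatic mutation with read depth, allelic
#' frequency (percent), gene annotation and predicted impact class.
#'
#' @param chromosome chromosome labels ("1".."22", "X", "Y"; "chr" prefixes
#'   are stripped).
#' @param position 1-based genomic coordinate.
#' @param dna_depth total read depth (DP), positive integer.
#' @param dna_allelic_freq variant allele frequency in percent, 0-100.
#' @param ensembl_gene_id,gene_symbol gene annotation.
#' @param dna_change HGVS c. description.
#' @param amino_acid_change HGVS p. description (may be NA).
#' @param effect_impact one of MODIFIER, LOW, MODERATE, HIGH.
#' @param experiment_id experiment identifier.
#' @return data.frame with the ten W columns.
#' @export
wes_variants <- function(chromosome = character(), position = integer(),
                         dna_depth = integer(), dna_allelic_freq = numeric(),
                         ensembl_gene_id = character(), gene_symbol = character(),
                         dna_change = character(), amino_acid_change = character(),
                         effect_impact = character(), experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "chromosome")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  w <- data.frame(
    chromosome = normalize_chromosome(chromosome),
    position = as.integer(position),
    dna_depth = as.integer(dna_depth),
    dna_allelic_freq = as.numeric(dna_allelic_freq),
    ensembl_gene_id = as.character(ensembl_gene_id),
    gene_symbol = as.character(gene_symbol),
    dna_change = as.character(dna_change),
    amino_acid_change = as.character(amino_acid_change),
    effect_impact = as.character(effect_impact),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(w)) {
    stopifnot(all(w$position >= 1L), all(w$dna_depth > 0L),
              all(w$dna_allelic_freq >= 0 & w$dna_allelic_freq <= 100))
    if (!all(w$effect_impact %in% .IMPACT_LEVELS)) {
      stop("effect_impact must be one of ", paste(.IMPACT_LEVELS, collapse = "/"))
    }
  }
  w
}

#' Methylation probe relation (M)
#'
#' Illumina HM450K probe rows with average beta value (fraction in [0,1]),
#' regulatory-feature and CpG-island annotation.  Vendor exports print one
#' combined annotation column; it is carried here as the two fields that
#' the filtering criteria actually use.
#'
#' @param target_id probe identifier (cg-prefixed).
#' @param avg_beta methylation fraction in [0,1].
#' @param regulatory_feature e.g. "Promoter Associated".
#' @param relation_to_cpg_island e.g. "Island".
#' @param ensembl_gene_id annotated gene (may be NA).
#' @param experiment_id experiment identifier.
#' @return data.frame with the six M columns.
#' @export
methylation_probes <- function(target_id = character(), avg_beta = numeric(),
                               regulatory_feature = character(),
                               relation_to_cpg_island = character(),
                               ensembl_gene_id = character(),
                               experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "target_id")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  m <- data.frame(
    target_id = as.character(target_id),
    avg_beta = as.numeric(avg_beta),
    regulatory_feature = as.character(regulatory_feature),
    relation_to_cpg_island = as.character(relation_to_cpg_island),
    ensembl_gene_id = as.character(ensembl_gene_id),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(m)) {
    stopifnot(all(m$avg_beta >= 0 & m$avg_beta <= 1))
    if (anyDuplicated(m[, c("target_id", "experiment_id")])) {
      stop("duplicate target_id within one experiment")
    }
  }
  m
}

#' Copy-number segment relation (C)
#'
#' Closed genomic intervals [start, stop] with an integer copy number;
#' segments of one experiment must not overlap within a chromosome.
#'
#' @param chromosome,start,stop interval (1-based, inclusive).
#' @param copy_number non-negative integer copy number.
#' @param experiment_id experiment identifier.
#' @return data.frame with the five C columns, sorted by chromosome/start.
#' @export
cnv_segments <- function(chromosome = character(), start = integer(),
                         stop = integer(), copy_number = integer(),
                         experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "chromosome")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  cc <- data.frame(
    chromosome = normalize_chromosome(chromosome),
    start = as.integer(start),
    stop = as.integer(stop),
    copy_number = as.integer(copy_number),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(cc)) {
    stopifnot(all(cc$start <= cc$stop), all(cc$copy_number >= 0L))
    cc <- cc[order(match(cc$chromosome, .CHROMOSOMES), cc$start), , drop = FALSE]
    rownames(cc) <- NULL
    for (grp in split(cc, list(cc$experiment_id, cc$chromosome), drop = TRUE)) {
      if (nrow(grp) > 1L && any(grp$start[-1L] <= grp$stop[-nrow(grp)])) {
        i <- which(grp$start[-1L] <= grp$stop[-nrow(grp)])[1L]
        stop(sprintf("overlapping CNV segments on chromosome %s: [%d,%d] and [%d,%d]",
                     grp$chromosome[1L], grp$start[i], grp$stop[i],
                     grp$start[i + 1L], grp$stop[i + 1L]))
      }
    }
  }
  cc
}

#' Gene raw-count relation (H)
#'
#' @param ensembl_gene_id gene identifier.
#' @param count raw (unnormalized) read count, non-negative integer.
#' @param experiment_id experiment identifier.
#' @return data.frame with the three H columns.
#' @export
gene_counts <- function(ensembl_gene_id = character(), count = integer(),
                        experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "ensembl_gene_id")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  h <- data.frame(
    ensembl_gene_id = as.character(ensembl_gene_id),
    count = as.integer(count),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(h)) {
    stopifnot(all(h$count >= 0L))
    if (anyDuplicated(h[, c("ensembl_gene_id", "experiment_id")])) {
      stop("duplicate gene within one experiment in count relation")
    }
  }
  h
}

#' RNA variant relation (RV)
#'
#' @param chromosome,position locus (1-based).
#' @param ensembl_gene_id gene identifier.
#' @param rna_depth RNA read depth, positive integer.
#' @param rna_allelic_freq RNA variant allele frequency in percent.
#' @param experiment_id experiment identifier.
#' @return data.frame with the six RV columns.
#' @export
rna_variants <- function(chromosome = character(), position = integer(),
                         ensembl_gene_id = character(), rna_depth = integer(),
                         rna_allelic_freq = numeric(), experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "chromosome")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  rv <- data.frame(
    chromosome = normalize_chromosome(chromosome),
    position = as.integer(position),
    ensembl_gene_id = as.character(ensembl_gene_id),
    rna_depth = as.integer(rna_depth),
    rna_allelic_freq = as.numeric(rna_allelic_freq),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(rv)) {
    stopifnot(all(rv$position >= 1L), all(rv$rna_depth > 0L),
              all(rv$rna_allelic_freq >= 0 & rv$rna_allelic_freq <= 100))
  }
  rv
}

#' Transcript quantification relation (R)
#'
#' Isoform-level FPKM; assembler-novel transcript ids (e.g. CUFF.n.m) are
#' accepted verbatim.
#'
#' @param ensembl_transcript_id transcript identifier.
#' @param ensembl_gene_id gene identifier.
#' @param fpkm non-negative expression value.
#' @param experiment_id experiment identifier.
#' @return data.frame with the four R columns.
#' @export
transcript_quants <- function(ensembl_transcript_id = character(),
                              ensembl_gene_id = character(),
                              fpkm = numeric(), experiment_id = character()) {
  .a <- .empty_args(mget(names(formals())), "ensembl_transcript_id")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  r <- data.frame(
    ensembl_transcript_id = as.character(ensembl_transcript_id),
    ensembl_gene_id = as.character(ensembl_gene_id),
    fpkm = as.numeric(fpkm),
    experiment_id = as.character(experiment_id),
    stringsAsFactors = FALSE
  )
  if (nrow(r)) stopifnot(all(r$fpkm >= 0))
  r
}

#' Gene list relation (K)
#'
#' Key genes (cancer drivers and variants of uncertain significance) or
#' tumor suppressor genes, optionally with symbol and classification.
#'
#' @param ensembl_gene_id gene identifiers, unique.
#' @param gene_symbol optional symbols (NA when absent).
#' @param classification optional class labels (e.g. "TSG", "Oncogene").
#' @return data.frame with the three K columns.
#' @export
gene_list <- function(ensembl_gene_id = character(),
                      gene_symbol = NA_character_,
                      classification = NA_character_) {
  .a <- .empty_args(mget(names(formals())), "ensembl_gene_id")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  k <- data.frame(
    ensembl_gene_id = as.character(ensembl_gene_id),
    gene_symbol = as.character(gene_symbol),
    classification = as.character(classification),
    stringsAsFactors = FALSE
  )
  k <- k[!duplicated(k$ensembl_gene_id), , drop = FALSE]
  rownames(k) <- NULL
  k
}

#' Experiment metadata relation (P)
#'
#' @param patient_id,experiment_id identifiers (experiment_id unique).
#' @param experiment_description,sample_type,sample_description free text.
#' @param experiment_date,sample_collection_date dates as ISO strings.
#' @return data.frame with the seven P columns.
#' @export
experiment_meta <- function(patient_id = character(), experiment_id = character(),
                            experiment_description = NA_character_,
                            sample_type = NA_character_,
                            sample_description = NA_character_,
                            experiment_date = NA_character_,
                            sample_collection_date = NA_character_) {
  .a <- .empty_args(mget(names(formals())), "patient_id")
  for (.nm in names(.a)) assign(.nm, .a[[.nm]])
  p <- data.frame(
    patient_id = as.character(patient_id),
    experiment_id = as.character(experiment_id),
    experiment_description = as.character(experiment_description),
    sample_type = as.character(sample_type),
    sample_description = as.character(sample_description),
    experiment_date = as.character(experiment_date),
    sample_collection_date = as.character(sample_collection_date),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(p$experiment_id)) stop("experiment_id must be unique")
  p
}

# ---------------------------------------------------------------------------
# Generic relational operators.
# ---------------------------------------------------------------------------

.check_attrs <- function(rel, attrs, side) {
  missing <- setdiff(attrs, names(rel))
  if (length(missing)) {
    stop("schema error: unknown attribute(s) in ", side, " relation: ",
         paste(missing, collapse = ", "))
  }
}

# Composite key as a character vector; rows with any NA key component get NA
# (so they never match: null never equals null in a join predicate).
.key_string <- function(rel, keys) {
  if (!nrow(rel)) return(character())
  cols <- lapply(keys, function(k) rel[[k]])
  any_na <- Reduce(`|`, lapply(cols, is.na))
  key <- do.call(paste, c(cols, sep = "\r"))
  key[any_na] <- NA_character_
  key
}

# Identity key for deduplication: NA is a regular (distinct) value here, so
# (1, NA) and (2, NA) stay two different tuples.
.id_string <- function(rel, keys) {
  if (!nrow(rel)) return(character())
  cols <- lapply(keys, function(k) {
    x <- rel[[k]]
    ifelse(is.na(x), "\x01NA\x01", as.character(x))
  })
  do.call(paste, c(cols, sep = "\r"))
}

#' Left-outer join of two relations
#'
#' Every left tuple appears at least once; unmatched left tuples carry NA in
#' all right-hand attributes.  Matching is by equality on `by` (named vector
#' or plain names; names = left attributes, values = right attributes); an
#' optional `predicate` function further restricts candidate pairs (used for
#' interval containment).  NA key values never match.
#'
#' @param left,right data.frames.
#' @param by equality keys; named character vector maps left names to right
#'   names, unnamed means same name on both sides.  May be NULL when only a
#'   predicate is used (cross-candidates; keep relations small).
#' @param predicate optional function(left_rows, right_rows) returning a
#'   logical vector over candidate pairs, evaluated vectorized.
#' @param suffix suffix appended to right-hand columns that clash with left
#'   column names.
#' @return data.frame with left columns followed by right columns.
#' @export
left_outer_join <- function(left, right, by = NULL, predicate = NULL,
                            suffix = ".y") {
  join_impl(left, right, by, predicate, suffix, outer = TRUE)
}

#' Equi-join (inner) of two relations
#'
#' Only matching tuple pairs are returned; NA keys never match.
#' Arguments as in [left_outer_join()].
#'
#' @inheritParams left_outer_join
#' @return data.frame with left columns followed by right columns.
#' @export
equi_join <- function(left, right, by, predicate = NULL, suffix = ".y") {
  join_impl(left, right, by, predicate, suffix, outer = FALSE)
}

join_impl <- function(left, right, by, predicate, suffix, outer) {
  if (!is.null(by)) {
    lk <- if (is.null(names(by))) by else ifelse(names(by) == "", by, names(by))
    rk <- unname(by)
    .check_attrs(left, lk, "left")
    .check_attrs(right, rk, "right")
  } else {
    lk <- rk <- character()
  }
  rcols <- names(right)
  out_rcols <- ifelse(rcols %in% names(left), paste0(rcols, suffix), rcols)

  empty_right <- right[0, , drop = FALSE]
  names(empty_right) <- out_rcols

  if (!nrow(left)) {
    out <- cbind(left, empty_right)
    rownames(out) <- NULL
    return(out)
  }

  if (length(lk)) {
    lkey <- .key_string(left, lk)
    rkey <- .key_string(right, rk)
    match_list <- if (nrow(right)) split(seq_len(nrow(right)), rkey) else list()
    cand <- lapply(lkey, function(k) {
      if (is.na(k)) integer() else match_list[[k]] %||% integer()
    })
  } else {
    cand <- rep(list(seq_len(nrow(right))), nrow(left))
  }

  li <- rep.int(seq_len(nrow(left)), lengths(cand))
  ri <- unlist(cand, use.names = FALSE)
  if (!is.null(predicate) && length(li)) {
    keep <- predicate(left[li, , drop = FALSE], right[ri, , drop = FALSE])
    keep[is.na(keep)] <- FALSE
    li <- li[keep]
    ri <- ri[keep]
  }

  if (outer) {
    unmatched <- setdiff(seq_len(nrow(left)), unique(li))
    res_l <- left[c(li, unmatched), , drop = FALSE]
    rpart <- right[ri, , drop = FALSE]
    if (length(unmatched)) {
      na_block <- right[rep(NA_integer_, length(unmatched)), , drop = FALSE]
      rpart <- rbind(rpart, na_block)
    }
  } else {
    res_l <- left[li, , drop = FALSE]
    rpart <- right[ri, , drop = FALSE]
  }
  names(rpart) <- out_rcols
  out <- cbind(res_l, rpart)
  rownames(out) <- NULL
  # keep deterministic order: left row order, then candidate order
  if (outer) {
    ord <- order(c(li, setdiff(seq_len(nrow(left)), unique(li))))
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersection on common attributes
#'
#' Tuples of `a` whose key combination also occurs in `b`, deduplicated on
#' the keys (first occurrence of each key kept).  NA keys never match.
#'
#' @param a,b data.frames.
#' @param keys attribute names present in both relations.
#' @return data.frame, subset of `a`, one row per matching key.
#' @export
intersect_on <- function(a, b, keys) {
  .check_attrs(a, keys, "first")
  .check_attrs(b, keys, "second")
  ka <- .key_string(a, keys)
  kb <- .key_string(b, keys)
  keep <- !is.na(ka) & ka %in% kb[!is.na(kb)] & !duplicated(.id_string(a, keys))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Set difference on common attributes
#'
#' Tuples of `a` whose key combination does not occur in `b`, deduplicated
#' on the keys.  NA keys in `a` are kept (they match nothing in `b`).
#'
#' @inheritParams intersect_on
#' @return data.frame, subset of `a`, one row per non-matching key.
#' @export
difference_on <- function(a, b, keys) {
  .check_attrs(a, keys, "first")
  .check_attrs(b, keys, "second")
  ka <- .key_string(a, keys)
  kb <- .key_string(b, keys)
  keep <- (is.na(ka) | !(ka %in% kb[!is.na(kb)])) & !duplicated(.id_string(a, keys))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct projection
#'
#' Projects onto `attributes` and collapses duplicate rows over the full
#' projected set to one.  Real-valued columns are compared after rounding to
#' 10 significant digits so float noise does not defeat deduplication; NA
#' compares equal to NA for the purpose of row identity (projection
#' semantics, not join semantics).
#'
#' @param rel data.frame.
#' @param attributes column names to keep.
#' @return data.frame with distinct projected rows, input order preserved.
#' @export
project_distinct <- function(rel, attributes) {
  .check_attrs(rel, attributes, "projected")
  out <- rel[, attributes, drop = FALSE]
  if (!nrow(out)) return(out)
  cmp <- out
  for (j in seq_along(cmp)) {
    if (is.double(cmp[[j]])) cmp[[j]] <- signif(cmp[[j]], 10)
  }
  out <- out[!duplicated(cmp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
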