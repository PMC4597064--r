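# Independent naive oracles used across the suite.  These deliberately use
# row-by-row nested loops and base primitives only, so they share no code
# path with the package's vectorized operators.

# canonical form for relation comparison: all columns as character, rows
# sorted over every column
canon_rel <- function(df) {
  if (!nrow(df)) return(df[order(names(df))])
  out <- df[, order(names(df)), drop = FALSE]
  chr <- as.data.frame(lapply(out, function(x) {
    x <- if (is.double(x)) signif(x, 10) else x
    ifelse(is.na(x), "<NA>", as.character(x))
  }), stringsAsFactors = FALSE)
  ord <- do.call(order, chr)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_same_rel <- function(actual, expected) {
  a <- canon_rel(actual)
  e <- canon_rel(expected)
  expect_identical(names(a), names(e))
  expect_equal(nrow(a), nrow(e))
  for (cl in names(a)) {
    av <- a[[cl]]
    ev <- e[[cl]]
    # a text round-trip may re-infer "20" as integer; compare as text then
    if (is.character(av) != is.character(ev)) {
      av <- as.character(av)
      ev <- as.character(ev)
    }
    expect_equal(av, ev, tolerance = 1e-9)
  }
}

# nested-loop left outer join oracle; match_fun(l_row, r_row) -> TRUE/FALSE
oracle_left_join <- function(left, right, match_fun, suffix = ".y") {
  rcols <- names(right)
  out_rcols <- ifelse(rcols %in% names(left), paste0(rcols, suffix), rcols)
  rows <- list()
  for (i in seq_len(nrow(left))) {
    hit <- FALSE
    for (j in seq_len(nrow(right))) {
      if (isTRUE(match_fun(left[i, , drop = FALSE], right[j, , drop = FALSE]))) {
        rp <- right[j, , drop = FALSE]
        names(rp) <- out_rcols
        rows[[length(rows) + 1L]] <- cbind(left[i, , drop = FALSE], rp)
        hit <- TRUE
      }
    }
    if (!hit) {
      rp <- right[NA_integer_, , drop = FALSE]
      names(rp) <- out_rcols
      rows[[length(rows) + 1L]] <- cbind(left[i, , drop = FALSE], rp)
    }
  }
  if (!length(rows)) {
    rp <- right[0, , drop = FALSE]
    names(rp) <- out_rcols
    return(cbind(left[0, , drop = FALSE], rp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_inner_join <- function(left, right, match_fun, suffix = ".y") {
  rcols <- names(right)
  out_rcols <- ifelse(rcols %in% names(left), paste0(rcols, suffix), rcols)
  rows <- list()
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      if (isTRUE(match_fun(left[i, , drop = FALSE], right[j, , drop = FALSE]))) {
        rp <- right[j, , drop = FALSE]
        names(rp) <- out_rcols
        rows[[length(rows) + 1L]] <- cbind(left[i, , drop = FALSE], rp)
      }
    }
  }
  if (!length(rows)) {
    rp <- right[0, , drop = FALSE]
    names(rp) <- out_rcols
    return(cbind(left[0, , drop = FALSE], rp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# equality over named key pairs with NA-never-matches semantics
key_match_fun <- function(lk, rk) {
  function(l, r) {
    for (t in seq_along(lk)) {
      lv <- l[[lk[t]]]
      rv <- r[[rk[t]]]
      if (is.na(lv) || is.na(rv) || lv != rv) return(FALSE)
    }
    TRUE
  }
}

# monolithic nested-loop oracle for the whole integration pipeline:
# returns the expected deduplicated mutation relation for a bundle
oracle_pipeline <- function(bundle, s = filter_settings()) {
  w <- bundle$w
  rows <- list()
  for (i in seq_len(nrow(w))) {
    if (!(w$dna_allelic_freq[i] >= s$min_vaf && w$dna_allelic_freq[i] <= s$max_vaf &&
          w$dna_depth[i] >= s$min_depth && w$dna_depth[i] <= s$max_depth)) next
    if (!w$effect_impact[i] %in% c("MODERATE", "HIGH")) next
    # copy number by containment
    cn <- NA_integer_
    for (j in seq_len(nrow(bundle$c))) {
      if (bundle$c$chromosome[j] == w$chromosome[i] &&
          w$position[i] >= bundle$c$start[j] && w$position[i] <= bundle$c$stop[j]) {
        cn <- bundle$c$copy_number[j]
        break
      }
    }
    # RNA variant at the same locus
    rv_hit <- FALSE
    rv_gene <- character()
    for (j in seq_len(nrow(bundle$rv))) {
      if (bundle$rv$chromosome[j] == w$chromosome[i] &&
          bundle$rv$position[j] == w$position[i]) {
        rv_hit <- TRUE
        rv_gene <- c(rv_gene, bundle$rv$ensembl_gene_id[j])
      }
    }
    # expression support for any gene of the matching RNA variants
    expr <- FALSE
    for (g in rv_gene) {
      if (is.na(g)) next
      if (any(bundle$r$ensembl_gene_id == g & bundle$r$fpkm > 0)) expr <- TRUE
      if (any(bundle$h$ensembl_gene_id == g & bundle$h$count > 0)) expr <- TRUE
    }
    glyph <- if (rv_hit && expr) 2L else 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = w$chromosome[i], position = w$position[i],
      dna_depth = w$dna_depth[i], copy_number = cn,
      dna_change = w$dna_change[i], amino_acid_change = w$amino_acid_change[i],
      dna_allelic_freq = w$dna_allelic_freq[i], gene_symbol = w$gene_symbol[i],
      glyph = glyph, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), position = integer(),
               dna_depth = integer(), copy_number = integer(),
               dna_change = character(), amino_acid_change = character(),
               dna_allelic_freq = numeric(), gene_symbol = character(),
               glyph = integer(), stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

# direct double-loop weighted KDE oracle
oracle_wkde <- function(values, weights, h, grid) {
  sapply(grid, function(g) {
    acc <- 0
    for (i in seq_along(values)) {
      acc <- acc + weights[i] * stats::dnorm((values[i] - g) / h)
    }
    acc / (h * sum(weights))
  })
}

# small random relation pair with NA keys for operator property tests
random_keyed_pair <- function(seed, n_max = 50L) {
  set.seed(seed)
  mk <- function(n) {
    data.frame(
      chromosome = sample(c("1", "2", "X", NA), n, replace = TRUE),
      position = sample(c(1:6, NA), n, replace = TRUE),
      val = round(stats::runif(n), 3),
      stringsAsFactors = FALSE
    )
  }
  list(a = mk(sample.int(n_max, 1)), b = mk(sample.int(n_max, 1)))
}
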