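# ---------------------------------------------------------------------------
# Local, file-backed query engine over an aggregated store: search by
# chromosomal position, dbSNP ID or gene symbol (against a user-supplied
# BED/GFF interval file), with allele / genotype frequency display.
# All queries are read-only.
# ---------------------------------------------------------------------------

norm_chrom <- function(x) sub("^chr", "", as.character(x))

# assemble the displayed result for a set of record row indices
build_query_result <- function(store, idx, matched_term = NULL,
                               intervals = NULL, ref_freqs = NULL) {
  if (is.character(intervals)) intervals <- load_gene_intervals(intervals)
  r <- store$records[idx]
  n <- store$n_samples
  res <- data.table(
    chrom = r$chrom, pos = r$pos, id = r$id, ref = r$ref, alt = r$alt,
    blurred = r$blurred, carrier_count = r$carrier_count, n_samples = n,
    carrier_freq = r$carrier_count / n,
    het_freq = ifelse(r$blurred, NA_real_, r$het_count / n),
    hom_freq = ifelse(r$blurred, NA_real_, r$hom_count / n),
    # alt alleles: het carriers contribute 1, hom carriers 2, over 2n
    allele_freq = ifelse(r$blurred, NA_real_,
                         (r$het_count + 2 * r$hom_count) / (2 * n)),
    trait_summary = r$trait_summary,
    contact = r$contact)
  # genotype frequencies are never reported for blurred records
  res[blurred == TRUE, carrier_freq := NA_real_]
  cls <- store$classes
  res[, hpo_terms := vapply(r$class_tokens, function(ct) {
    if (!nzchar(ct)) return("")
    hp <- cls$hpo_present[match(strsplit(ct, ",", fixed = TRUE)[[1]],
                                cls$class_id)]
    paste(sort(unique(unlist(strsplit(hp[nzchar(hp) & !is.na(hp)], ";",
                                      fixed = TRUE)))), collapse = ";")
  }, character(1))]
  if (!is.null(matched_term)) res[, matched_term := matched_term]
  if (!is.null(intervals)) {
    hits <- vapply(seq_len(nrow(res)), function(i) {
      j <- which(norm_chrom(intervals$chrom) == norm_chrom(res$chrom[i]) &
                   intervals$start <= res$pos[i] &
                   intervals$end >= res$pos[i])
      if (length(j)) paste(sort(unique(intervals$gene[j])), collapse = ";")
      else NA_character_
    }, character(1))
    res[, within_gene := !is.na(hits)]
    res[, gene := hits]
  }
  if (!is.null(ref_freqs)) {
    kk <- snv_key(res$chrom, res$pos, res$ref, res$alt)
    res[, ref_freq := ref_freqs$freq[match(kk, snv_key(
      ref_freqs$chrom, ref_freqs$pos, ref_freqs$ref, ref_freqs$alt))]]
  }
  setattr(res, "class", c("snv_query_result", class(res)))
  res[]
}

#' @export
print.snv_query_result <- function(x, ...) {
  if (!nrow(x)) {
    cat("no matching SNVs\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s:%d %s>%s", x$chrom[i], x$pos[i], x$ref[i], x$alt[i]))
    if (x$id[i] != ".") cat(sprintf(" (%s)", x$id[i]))
    if (x$blurred[i]) {
      cat(sprintf("  BLURRED  carriers=%d/%d  contact: %s\n",
                  x$carrier_count[i], x$n_samples[i], x$contact[i]))
    } else {
      cat(sprintf("  carriers=%d/%d (freq %.3f)  allele freq %.3f\n",
                  x$carrier_count[i], x$n_samples[i], x$carrier_freq[i],
                  x$allele_freq[i]))
    }
  }
  invisible(x)
}

#' Query an aggregated store by chromosomal position
#'
#' Returns every alternate allele recorded at the locus. An absent locus
#' yields an empty result, not an error. Blurred records are returned
#' with the submitter contact but no genotype frequencies.
#'
#' @param store an [snv_store()].
#' @param position string `"chrom:pos"`, e.g. `"chr1:13272"` (the `chr`
#'   prefix is optional and ignored for matching).
#' @param ... passed to the result builder (`intervals`, `ref_freqs`).
#' @return a `snv_query_result` data.table.
#' @export
query_position <- function(store, position, ...) {
  if (!grepl("^[^:]+:[0-9]+$", position))
    stop_snvblur(sprintf("malformed position '%s' (expected chrom:pos)",
                         position), "snvblur_usage")
  p <- strsplit(position, ":", fixed = TRUE)[[1]]
  idx <- which(norm_chrom(store$records$chrom) == norm_chrom(p[1]) &
                 store$records$pos == as.integer(p[2]))
  build_query_result(store, idx, matched_term = if (length(idx))
    rep(position, length(idx)) else NULL, ...)
}

#' Query an aggregated store by dbSNP ID
#'
#' Exact match on the VCF ID column; the `"."` sentinel never matches.
#'
#' @param store an [snv_store()].
#' @param rsid dbSNP identifier, e.g. `"rs6605067"`.
#' @param ... passed to the result builder.
#' @return a `snv_query_result` data.table.
#' @export
query_rsid <- function(store, rsid, ...) {
  idx <- if (identical(rsid, ".")) integer() else
    which(store$records$id == rsid)
  build_query_result(store, idx, matched_term = if (length(idx))
    rep(rsid, length(idx)) else NULL, ...)
}

#' Load gene intervals from a BED or GFF file
#'
#' Normalizes both formats to a closed containment test on VCF
#' coordinates: a position hits a BED interval when
#' `start <= pos < end` (the half-open test applied to the printed BED
#' coordinates), and a GFF/GTF interval when `start <= pos <= end`
#' (1-based closed, per that format). GFF files are parsed through
#' `rtracklayer` when available.
#'
#' @param path BED or GFF/GTF file.
#' @return `data.table` with columns `chrom`, `start`, `end`, `gene`;
#'   `start`/`end` are stored so that a hit is `start <= pos <= end`.
#' @export
load_gene_intervals <- function(path) {
  if (!file.exists(path))
    stop_snvblur(sprintf("cannot read interval file '%s'", path),
                 "snvblur_io")
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    dt <- fread(path, header = FALSE)
    return(data.table(chrom = as.character(dt[[1]]),
                      start = as.integer(dt[[2]]),
                      end = as.integer(dt[[3]]) - 1L,
                      gene = if (ncol(dt) >= 4) as.character(dt[[4]])
                      else NA_character_))
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    mc <- as.data.frame(gr)
    name_col <- intersect(c("name", "Name", "gene_name", "gene_id", "ID"),
                          names(mc))
    gene <- if (length(name_col)) as.character(mc[[name_col[1]]])
            else rep(NA_character_, length(gr))
    return(data.table(chrom = as.character(mc$seqnames),
                      start = mc$start, end = mc$end, gene = gene))
  }
  # minimal GFF fallback: columns 1 (chrom), 4/5 (1-based closed), 9 (attrs)
  dt <- fread(path, header = FALSE, sep = "\t")
  gene <- sub('.*(?:gene_name[= ]"?|Name=|ID=)([^";]+).*', "\\1",
              as.character(dt[[9]]))
  data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[4]]),
             end = as.integer(dt[[5]]), gene = gene)
}

#' Query an aggregated store by gene symbol
#'
#' Returns every SNV whose position falls inside any interval annotated
#' with the symbol. An unknown symbol yields an empty result with a
#' warning.
#'
#' @param store an [snv_store()].
#' @param symbol gene symbol as annotated in the interval file.
#' @param intervals path of a BED/GFF file, or a table from
#'   [load_gene_intervals()].
#' @param ... passed to the result builder.
#' @return a `snv_query_result` data.table.
#' @export
query_gene <- function(store, symbol, intervals, ...) {
  iv <- if (is.character(intervals)) load_gene_intervals(intervals)
        else as.data.table(intervals)
  iv <- iv[!is.na(gene) & gene == symbol]
  if (!nrow(iv)) {
    warning(sprintf("gene symbol '%s' not found in interval file", symbol))
    return(build_query_result(store, integer(), ...))
  }
  r <- store$records
  idx <- which(vapply(seq_len(nrow(r)), function(i)
    any(norm_chrom(iv$chrom) == norm_chrom(r$chrom[i]) &
          iv$start <= r$pos[i] & iv$end >= r$pos[i]), logical(1)))
  build_query_result(store, idx, matched_term = if (length(idx))
    rep(symbol, length(idx)) else NULL, intervals = iv, ...)
}

#' Combined search over mixed term types
#'
#' Classifies each term by syntax - `chrom:pos` positions, `rs` IDs,
#' gene symbols - runs the corresponding single-term queries, and
#' returns their de-duplicated union, each record annotated with the
#' terms that matched it.
#'
#' @param store an [snv_store()].
#' @param terms character vector of search terms.
#' @param intervals interval file or table (required for symbol terms).
#' @param ... passed to the result builder.
#' @return a `snv_query_result` data.table.
#' @export
combined_search <- function(store, terms, intervals = NULL, ...) {
  terms <- unique(terms)
  if (is.character(intervals)) intervals <- load_gene_intervals(intervals)
  parts <- lapply(terms, function(t) {
    if (grepl("^[^:]+:[0-9]+$", t)) {
      query_position(store, t, intervals = if (is.null(intervals)) NULL
                     else intervals, ...)
    } else if (grepl("^rs[0-9]+$", t)) {
      query_rsid(store, t, intervals = if (is.null(intervals)) NULL
                 else intervals, ...)
    } else if (grepl("^[A-Za-z][A-Za-z0-9._-]*$", t)) {
      if (is.null(intervals))
        stop_snvblur(sprintf(
          "term '%s' looks like a gene symbol but no interval file was supplied",
          t), "snvblur_usage")
      query_gene(store, t, intervals, ...)
    } else {
      stop_snvblur(sprintf("cannot classify search term '%s'", t),
                   "snvblur_usage")
    }
  })
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (!length(parts))
    return(build_query_result(store, integer(), ...))
  all <- rbindlist(parts, fill = TRUE)
  all[, key := snv_key(chrom, pos, ref, alt)]
  merged <- all[, c(.SD[1],
                    .(matched_term = paste(unique(matched_term),
                                           collapse = ";"))),
                by = key, .SDcols = setdiff(names(all),
                                            c("key", "matched_term"))]
  merged[, key := NULL]
  setattr(merged, "class", c("snv_query_result", class(merged)))
  merged[]
}

#' Read a user-supplied reference allele-frequency table
#'
#' External population frequencies (e.g. exported from public variant
#' servers) keyed by `chrom, pos, ref, alt` with a numeric `freq`
#' column, as tab-separated text. No network access is performed.
#'
#' @param path TSV file with header `chrom pos ref alt freq` (extra
#'   columns preserved).
#' @return a `data.table`.
#' @export
read_reference_freqs <- function(path) {
  dt <- fread(path)
  need <- c("chrom", "pos", "ref", "alt", "freq")
  if (!all(need %in% names(dt)))
    stop_snvblur(sprintf("reference table must have columns: %s",
                         paste(need, collapse = ", ")), "snvblur_format")
  dt[, chrom := as.character(chrom)]
  dt
}
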