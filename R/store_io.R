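# ---------------------------------------------------------------------------
# The aggregated store and its sites-only VCF dialect.
#
# All genotype information lives in INFO (sub-samples are not fixed-width
# columns and blurred rows have no genotypes), under these keys:
#
#   GBN       total samples in the set
#   GBCAR     carrier count (samples with >= 1 alt allele)
#   GBHET     het carrier count          (unblurred only)
#   GBHOM     hom-alt carrier count      (unblurred only)
#   GBTRAIT   trait labels with counts, label|n (percent-encoded labels)
#   GBSUBS    comma list sub_id|H / sub_id|A    (unblurred only)
#   GBCLASS   phenotype-class tokens of the listed sub-samples
#   GBBLUR    flag: record blurred (locus + trait + contact only)
#   GBCONTACT percent-encoded submitter contact  (blurred records)
#
# Cohort-level metadata (phenotype classes, released tuples, the
# sub-sample -> class map, threshold echo) is carried in ##GB* meta-lines.
# ---------------------------------------------------------------------------

DIALECT_VERSION <- "1.0"

#' Construct an aggregated store
#'
#' The shareable result of aggregation: one record per SNV, either
#' carrying sub-sample genotype linkage (common variants) or blurred down
#' to locus + trait + submitter contact (rare variants). Nothing in a
#' store references a sample id.
#'
#' @param records `data.table` with columns `chrom,pos,id,ref,alt,blurred,
#'   carrier_count,het_count,hom_count,trait_summary,subs,class_tokens,
#'   contact`.
#' @param n_samples cohort size.
#' @param factor,median_count,threshold the rare-variant rule echo:
#'   `threshold = factor * median_count`.
#' @param classes `data.table` of phenotype classes
#'   (`class_id,n_members,hpo_present,hpo_absent`).
#' @param tuples `data.table` of released attribute tuples with counts.
#' @param sub_class `data.table` mapping `sub_id` to `class_id`.
#' @param contact submitter contact string.
#' @return object of class `snv_store`.
#' @export
snv_store <- function(records, n_samples, factor, median_count, threshold,
                      classes, tuples, sub_class, contact) {
  records <- as.data.table(records)
  if (nrow(records)) {
    records <- records[snv_order(records)]
    keys <- snv_key(records$chrom, records$pos, records$ref, records$alt)
    if (anyDuplicated(keys))
      stop_snvblur("duplicate SNV keys in store", "snvblur_invariant")
    bad <- records$blurred &
      (nzchar(records$subs) | !is.na(records$het_count) |
         !is.na(records$hom_count))
    if (any(bad))
      stop_snvblur("blurred record carries genotype/sub-sample linkage",
                   "snvblur_invariant")
    if (any(records$blurred & is.na(records$contact)))
      stop_snvblur("blurred record without contact", "snvblur_invariant")
    ub <- records[blurred == FALSE]
    if (nrow(ub)) {
      nsubs <- ifelse(nzchar(ub$subs),
                      lengths(strsplit(ub$subs, ",", fixed = TRUE)), 0L)
      if (!all(nsubs == ub$carrier_count))
        stop_snvblur("unblurred record: |sub_calls| != carrier count",
                     "snvblur_invariant")
      if (!all(ub$het_count + ub$hom_count == ub$carrier_count))
        stop_snvblur("unblurred record: het + hom != carrier count",
                     "snvblur_invariant")
    }
  }
  if (abs(threshold - factor * median_count) > 1e-9)
    stop_snvblur("threshold echo != factor * median", "snvblur_invariant")
  structure(list(records = records, n_samples = as.integer(n_samples),
                 factor = factor, median_count = median_count,
                 threshold = threshold,
                 classes = as.data.table(classes),
                 tuples = as.data.table(tuples),
                 sub_class = as.data.table(sub_class),
                 contact = contact),
            class = "snv_store")
}

#' @export
print.snv_store <- function(x, ...) {
  nb <- sum(x$records$blurred)
  cat(sprintf(paste0(
    "<snv_store> %d SNV records from %d samples\n",
    "  blurred: %d (%.1f%%)   threshold: %s = %s x median %s\n"),
    nrow(x$records), x$n_samples, nb,
    if (nrow(x$records)) 100 * nb / nrow(x$records) else 0,
    format(x$threshold), format(x$factor), format(x$median_count)))
  invisible(x)
}

empty_records <- function() {
  data.table(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), blurred = logical(),
             carrier_count = integer(), het_count = integer(),
             hom_count = integer(), trait_summary = character(),
             subs = character(), class_tokens = character(),
             contact = character())
}

#' Write an aggregated store as a sites-only VCF
#'
#' Produces a valid VCF 4.2 file in the GB* INFO dialect described above,
#' records sorted by (chrom, pos, ref, alt). Blurred records carry
#' `GBBLUR` and `GBCONTACT` but no `GBSUBS`; unblurred records carry
#' `GBSUBS` and never any sample id.
#'
#' @param store an [snv_store()].
#' @param path output file.
#' @export
write_aggregated_vcf <- function(store, path) {
  stopifnot(inherits(store, "snv_store"))
  r <- store$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=snvblur",
    sprintf("##GBDIALECT=%s", DIALECT_VERSION),
    sprintf("##GBNSAMPLES=%d", store$n_samples),
    sprintf("##GBFACTOR=%s", num_fmt(store$factor)),
    sprintf("##GBMEDIAN=%s", num_fmt(store$median_count)),
    sprintf("##GBTHRESHOLD=%s", num_fmt(store$threshold)),
    sprintf("##GBCONTACTGLOBAL=%s", pct_encode(store$contact)))
  if (nrow(store$classes))
    hdr <- c(hdr, sprintf("##GBCLASSDEF=%s|n=%d|hpo_present=%s|hpo_absent=%s",
                          store$classes$class_id, store$classes$n_members,
                          store$classes$hpo_present, store$classes$hpo_absent))
  if (nrow(store$tuples))
    hdr <- c(hdr, sprintf(
      "##GBTUPLE=trait=%s|hpo_present=%s|hpo_absent=%s|gender=%s|platform=%s|enrichment=%s|n=%d",
      pct_encode(store$tuples$trait), store$tuples$hpo_present,
      store$tuples$hpo_absent, store$tuples$gender,
      pct_encode(store$tuples$platform), pct_encode(store$tuples$enrichment),
      store$tuples$n))
  if (nrow(store$sub_class))
    hdr <- c(hdr, sprintf("##GBSUBCLASS=%s|%s",
                          store$sub_class$sub_id, store$sub_class$class_id))
  hdr <- c(hdr,
    '##INFO=<ID=GBN,Number=1,Type=Integer,Description="Total samples in the aggregated set">',
    '##INFO=<ID=GBCAR,Number=1,Type=Integer,Description="Number of carrier samples">',
    '##INFO=<ID=GBHET,Number=1,Type=Integer,Description="Heterozygous carrier count">',
    '##INFO=<ID=GBHOM,Number=1,Type=Integer,Description="Homozygous-alt carrier count">',
    '##INFO=<ID=GBTRAIT,Number=.,Type=String,Description="Trait labels with carrier counts, label|n (percent-encoded)">',
    '##INFO=<ID=GBSUBS,Number=.,Type=String,Description="Sub-sample genotypes, sub_id|H or sub_id|A">',
    '##INFO=<ID=GBCLASS,Number=.,Type=String,Description="Phenotype-class tokens of the listed sub-samples">',
    '##INFO=<ID=GBBLUR,Number=0,Type=Flag,Description="Record blurred: genotype and sub-sample linkage removed">',
    '##INFO=<ID=GBCONTACT,Number=1,Type=String,Description="Submitter contact (percent-encoded)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- character()
  if (nrow(r)) {
    info <- ifelse(
      r$blurred,
      paste0("GBBLUR;GBN=", store$n_samples, ";GBCAR=", r$carrier_count,
             ";GBTRAIT=", r$trait_summary, ";GBCONTACT=",
             pct_encode(r$contact)),
      paste0("GBN=", store$n_samples, ";GBCAR=", r$carrier_count,
             ";GBHET=", r$het_count, ";GBHOM=", r$hom_count,
             ";GBTRAIT=", r$trait_summary, ";GBSUBS=", r$subs,
             ifelse(nzchar(r$class_tokens),
                    paste0(";GBCLASS=", r$class_tokens), "")))
    body <- paste(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".", info,
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_get <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- which(m > 0)
  if (length(hit)) {
    s <- regmatches(info, m)   # matched substrings only, in order
    out[hit] <- sub(pat, "\\1", s, perl = TRUE)
  }
  out
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info, perl = TRUE)
}

parse_meta_value <- function(lines, key) {
  hit <- startsWith(lines, paste0("##", key, "="))
  if (!any(hit)) return(NULL)
  sub(paste0("^##", key, "="), "", lines[hit])
}

#' Read an aggregated VCF back into a store
#'
#' Inverse of [write_aggregated_vcf()]: `read_aggregated_vcf(
#' write_aggregated_vcf(s))` reproduces `s` field-exactly.
#'
#' @param path file in the GB* dialect.
#' @return an [snv_store()].
#' @export
read_aggregated_vcf <- function(path) {
  if (!file.exists(path))
    stop_snvblur(sprintf("cannot read '%s'", path), "snvblur_io")
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "##")]
  if (is.null(parse_meta_value(hdr, "GBDIALECT")))
    stop_snvblur("missing GB dialect meta-lines (not an aggregated VCF?)",
                 "snvblur_format")
  n_samples <- as.integer(parse_meta_value(hdr, "GBNSAMPLES"))
  factor <- as.numeric(parse_meta_value(hdr, "GBFACTOR"))
  med <- as.numeric(parse_meta_value(hdr, "GBMEDIAN"))
  thr <- as.numeric(parse_meta_value(hdr, "GBTHRESHOLD"))
  contact <- pct_decode(parse_meta_value(hdr, "GBCONTACTGLOBAL"))

  cls <- parse_meta_value(hdr, "GBCLASSDEF") %||% character()
  classes <- if (length(cls)) {
    p <- tstrsplit(cls, "|", fixed = TRUE)
    data.table(class_id = p[[1]],
               n_members = as.integer(sub("^n=", "", p[[2]])),
               hpo_present = sub("^hpo_present=", "", p[[3]]),
               hpo_absent = sub("^hpo_absent=", "", p[[4]]))
  } else data.table(class_id = character(), n_members = integer(),
                    hpo_present = character(), hpo_absent = character())

  tup <- parse_meta_value(hdr, "GBTUPLE") %||% character()
  tuples <- if (length(tup)) {
    p <- tstrsplit(tup, "|", fixed = TRUE)
    data.table(trait = pct_decode(sub("^trait=", "", p[[1]])),
               hpo_present = sub("^hpo_present=", "", p[[2]]),
               hpo_absent = sub("^hpo_absent=", "", p[[3]]),
               gender = sub("^gender=", "", p[[4]]),
               platform = pct_decode(sub("^platform=", "", p[[5]])),
               enrichment = pct_decode(sub("^enrichment=", "", p[[6]])),
               n = as.integer(sub("^n=", "", p[[7]])))
  } else data.table(trait = character(), hpo_present = character(),
                    hpo_absent = character(), gender = character(),
                    platform = character(), enrichment = character(),
                    n = integer())

  sc <- parse_meta_value(hdr, "GBSUBCLASS") %||% character()
  sub_class <- if (length(sc)) {
    p <- tstrsplit(sc, "|", fixed = TRUE)
    data.table(sub_id = p[[1]], class_id = p[[2]])
  } else data.table(sub_id = character(), class_id = character())

  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  records <- empty_records()
  if (length(body)) {
    f <- tstrsplit(body, "\t", fixed = TRUE)
    if (length(f) < 8L)
      stop_snvblur("malformed aggregated VCF body", "snvblur_format")
    info <- f[[8]]
    blurred <- info_flag(info, "GBBLUR")
    subs <- info_get(info, "GBSUBS")
    subs[is.na(subs)] <- ""
    ctk <- info_get(info, "GBCLASS")
    ctk[is.na(ctk)] <- ""
    records <- data.table(
      chrom = f[[1]], pos = as.integer(f[[2]]), id = f[[3]],
      ref = f[[4]], alt = f[[5]], blurred = blurred,
      carrier_count = as.integer(info_get(info, "GBCAR")),
      het_count = as.integer(info_get(info, "GBHET")),
      hom_count = as.integer(info_get(info, "GBHOM")),
      trait_summary = info_get(info, "GBTRAIT"),
      subs = subs, class_tokens = ctk,
      contact = pct_decode(info_get(info, "GBCONTACT")))
  }
  snv_store(records, n_samples, factor, med, thr, classes, tuples,
            sub_class, contact)
}

#' Validate an aggregated VCF file
#'
#' Consistency / corruption check of a file claiming to be in the
#' aggregated dialect. All problems are report entries, never errors:
#' missing dialect meta-lines, malformed lines, blurred records that
#' still carry genotypes or sub-sample linkage, carrier counts that do
#' not match the listed genotypes, duplicate SNV keys, and unsorted
#' records. An empty report means the file is dialect-conformant.
#'
#' @param path file to check.
#' @return a `data.frame` (class `snv_validation_report`) with columns
#'   `class`, `line`, `message`.
#' @export
validate_aggregated_vcf <- function(path) {
  viol <- list()
  add <- function(class, line, message)
    viol[[length(viol) + 1L]] <<- data.frame(class = class, line = line,
                                             message = message)
  if (!file.exists(path)) {
    add("missing-meta", 0L, sprintf("file '%s' not readable", path))
    return(finish_report(viol))
  }
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- which(startsWith(lines, "##"))
  hdr <- lines[hdr_idx]
  if (!any(startsWith(hdr, "##fileformat=VCF")))
    add("missing-meta", 1L, "no ##fileformat meta-line")
  if (is.null(parse_meta_value(hdr, "GBDIALECT")))
    add("missing-meta", 1L, "no ##GBDIALECT meta-line")
  if (!any(startsWith(lines, "#CHROM")))
    add("missing-meta", 1L, "no #CHROM header line")
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  keys_seen <- character()
  prev <- NULL
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      add("malformed-line", i, "fewer than 8 tab-separated fields")
      next
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L ||
        !f[4] %in% c("A", "C", "G", "T") ||
        !f[5] %in% c("A", "C", "G", "T") || f[4] == f[5]) {
      add("malformed-line", i, "bad POS/REF/ALT (SNV expected)")
      next
    }
    info <- f[8]
    blur <- info_flag(info, "GBBLUR")
    subs <- info_get(info, "GBSUBS")
    car <- suppressWarnings(as.integer(info_get(info, "GBCAR")))
    het <- suppressWarnings(as.integer(info_get(info, "GBHET")))
    hom <- suppressWarnings(as.integer(info_get(info, "GBHOM")))
    if (blur) {
      if (!is.na(subs))
        add("blurred-with-linkage", i,
            "blurred record still lists sub-sample genotypes")
      if (!is.na(het) || !is.na(hom))
        add("blurred-with-genotype", i,
            "blurred record still carries genotype counts")
      if (is.na(info_get(info, "GBCONTACT")))
        add("malformed-line", i, "blurred record without GBCONTACT")
    } else {
      nsub <- if (is.na(subs) || !nzchar(subs)) 0L else
        length(strsplit(subs, ",", fixed = TRUE)[[1]])
      if (is.na(car) || nsub != car)
        add("count-mismatch", i, sprintf(
          "GBCAR=%s but %d sub-sample genotypes listed",
          as.character(car), nsub))
      if (!is.na(het) && !is.na(hom) && !is.na(car) && het + hom != car)
        add("count-mismatch", i,
            sprintf("GBHET+GBHOM=%d but GBCAR=%d", het + hom, car))
    }
    k <- snv_key(f[1], pos, f[4], f[5])
    if (k %in% keys_seen)
      add("duplicate-key", i, sprintf("duplicate SNV key %s", k))
    keys_seen <- c(keys_seen, k)
    cur <- list(chrom = f[1], pos = pos, ref = f[4], alt = f[5])
    if (!is.null(prev)) {
      o <- snv_order(data.table(chrom = c(prev$chrom, cur$chrom),
                                pos = c(prev$pos, cur$pos),
                                ref = c(prev$ref, cur$ref),
                                alt = c(prev$alt, cur$alt)))
      if (!identical(o, 1:2))
        add("unsorted", i, "record out of (chrom, pos, ref, alt) order")
    }
    prev <- cur
  }
  finish_report(viol)
}

finish_report <- function(viol) {
  rep <- if (length(viol)) do.call(rbind, viol) else
    data.frame(class = character(), line = integer(), message = character())
  class(rep) <- c("snv_validation_report", "data.frame")
  rep
}

#' @export
print.snv_validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("aggregated VCF OK: no violations\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] line %d: %s\n", x$class[i], x$line[i],
                  x$message[i]))
  }
  invisible(x)
}

#' Write a validation report as text or JSON
#'
#' @param report result of [validate_aggregated_vcf()].
#' @param path output file.
#' @param format `"text"` or `"json"`.
#' @export
write_validation_report <- function(report, path,
                                    format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(unclass(report)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(utils::capture.output(print(report)), path)
  }
  invisible(path)
}
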