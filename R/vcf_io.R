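#' Read SNV genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) into a sparse call table:
#' one call per sample x site with at least one alternate allele.
#' Multi-allelic lines are split into one SNV per alternate allele; a
#' genotype referencing allele *j* makes the sample a carrier of that
#' alternate only. Indels, symbolic alleles and `*` are skipped and
#' counted, never an error: the data model is SNVs only. Phased
#' separators (`|`) are treated as unphased.
#'
#' @param path VCF file.
#' @param sample_id_override optional; replaces the (single) sample column
#'   name. Only allowed for single-sample files.
#' @return an [snv_cohort()] whose samples carry metadata stubs (id only);
#'   attach real metadata via [read_ini()] / [read_cohort()].
#' @export
read_vcf <- function(path, sample_id_override = NULL) {
  if (!file.exists(path))
    stop_snvblur(sprintf("cannot read VCF '%s'", path), "snvblur_io")
  hdr <- scan_vcf_header(path)
  if (!hdr$has_chrom_line)
    stop_snvblur(sprintf("'%s': no #CHROM header line", path),
                 "snvblur_format")
  sample_ids <- hdr$samples
  if (!is.null(sample_id_override)) {
    if (length(sample_ids) != 1L)
      stop_snvblur("sample_id_override requires a single-sample VCF",
                   "snvblur_validation")
    sample_ids <- as.character(sample_id_override)
  }

  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  n_row <- nrow(fix)
  skip <- c(indel = 0L, symbolic = 0L, malformed = 0L)

  sites <- data.table(site_id = integer(), chrom = character(),
                      pos = integer(), id = character(),
                      ref = character(), alt = character())
  calls <- data.table(site_id = integer(), sample_id = character(),
                      zygosity = character())

  if (n_row > 0L) {
    if (length(sample_ids) > 0L) {
      fmt <- gt[, "FORMAT"]
      if (any(is.na(fmt)) ||
          !all(vapply(strsplit(fmt, ":", fixed = TRUE),
                      function(f) "GT" %in% f, logical(1))))
        stop_snvblur(sprintf("'%s': GT missing from FORMAT", path),
                     "snvblur_format")
    }
    ref <- toupper(fix[, "REF"])
    alts <- strsplit(toupper(fix[, "ALT"]), ",", fixed = TRUE)
    # GT is always the first colon-field per VCF spec
    gtm <- if (length(sample_ids))
      sub(":.*$", "", gt[, -1L, drop = FALSE]) else NULL
    if (!is.null(gtm)) dim(gtm) <- c(n_row, length(sample_ids))

    out_sites <- vector("list", n_row)
    out_calls <- vector("list", n_row)
    next_id <- 0L
    for (i in seq_len(n_row)) {
      if (nchar(ref[i]) != 1L || !ref[i] %in% c("A", "C", "G", "T")) {
        skip[if (grepl("^[ACGTN]+$", ref[i])) "indel" else "malformed"] <-
          skip[if (grepl("^[ACGTN]+$", ref[i])) "indel" else "malformed"] + 1L
        next
      }
      a <- alts[[i]]
      snv <- a %in% c("A", "C", "G", "T") & a != ref[i]
      if (any(!snv)) {
        sym <- grepl("^<|\\*", a[!snv])
        skip["symbolic"] <- skip["symbolic"] + sum(sym)
        skip["indel"] <- skip["indel"] + sum(!sym)
      }
      if (!any(snv)) next
      alleles <- if (is.null(gtm)) NULL else
        lapply(strsplit(gtm[i, ], "[/|]"),
               function(x) suppressWarnings(as.integer(x)))
      for (j in which(snv)) {
        next_id <- next_id + 1L
        out_sites[[next_id]] <- list(
          site_id = next_id, chrom = as.character(fix[i, "CHROM"]),
          pos = as.integer(fix[i, "POS"]),
          id = as.character(fix[i, "ID"] %||% "."),
          ref = ref[i], alt = a[j])
        if (!is.null(alleles)) {
          nj <- vapply(alleles, function(al) sum(al == j, na.rm = TRUE),
                       integer(1))
          car <- which(nj >= 1L)
          if (length(car))
            out_calls[[next_id]] <- data.table(
              site_id = next_id, sample_id = sample_ids[car],
              zygosity = ifelse(nj[car] >= 2L, "hom_alt", "het"))
        }
      }
    }
    if (next_id > 0L) {
      sites <- rbindlist(out_sites[seq_len(next_id)])
      cl <- out_calls[seq_len(next_id)]
      cl <- cl[!vapply(cl, is.null, logical(1))]
      if (length(cl)) calls <- rbindlist(cl)
    }
  }
  sites$id[is.na(sites$id)] <- "."
  stubs <- lapply(sample_ids, function(s)
    structure(list(sample_id = s, status = NA_character_,
                   trait = NA_character_, hpo_present = character(),
                   hpo_absent = character(), gender = NA_character_,
                   platform = NA_character_, enrichment = NA_character_,
                   pi = NA_character_, contact = NULL,
                   contact_release = FALSE), class = "sample_meta"))
  snv_cohort(stubs, sites, calls, skip)
}

scan_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  has_chrom <- FALSE
  samples <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) break
    if (startsWith(line, "##")) next
    if (startsWith(line, "#CHROM")) {
      has_chrom <- TRUE
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) >= 10L) samples <- f[-(1:9)]
    }
    break
  }
  list(has_chrom_line = has_chrom, samples = samples)
}

# ---------------------------------------------------------------------------
# INI metadata dialect
#
#   [global]            trait, pi, contact_name, contact_affiliation,
#                       contact_email, contact_release
#   [sample:<ID>]       vcf, status, gender, platform, enrichment,
#                       hpo_present, hpo_absent  (HPO lists ';'-separated)
#
# Global keys act as defaults a sample section may override.
# ---------------------------------------------------------------------------

#' Read sample metadata from an INI file
#'
#' @param path INI file with a `[global]` section and one `[sample:<ID>]`
#'   section per sample (see Details in the package vignette).
#' @return named list of [sample_meta()] objects, in file order. Each
#'   element additionally carries a `vcf` attribute when the section names
#'   a genotype file.
#' @export
read_ini <- function(path) {
  if (!file.exists(path))
    stop_snvblur(sprintf("cannot read INI '%s'", path), "snvblur_io")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, ";")]
  section <- NA_character_
  sections <- list()
  order_ids <- character()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(sections[[section]])) {
        sections[[section]] <- list()
        order_ids <- c(order_ids, section)
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section))
        stop_snvblur(sprintf("INI key outside any section: '%s'", ln),
                     "snvblur_format")
      k <- trimws(sub("=.*$", "", ln))
      v <- trimws(sub("^[^=]*=", "", ln))
      sections[[section]][[k]] <- v
    } else {
      stop_snvblur(sprintf("malformed INI line: '%s'", ln), "snvblur_format")
    }
  }
  g <- sections[["global"]] %||% list()
  samp_sections <- order_ids[startsWith(order_ids, "sample:")]
  out <- list()
  for (sec in samp_sections) {
    sid <- sub("^sample:", "", sec)
    s <- sections[[sec]]
    get <- function(key) s[[key]] %||% g[[key]]
    hpo_split <- function(x) {
      if (is.null(x) || !nzchar(x)) character()
      else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    }
    status <- get("status")
    if (is.null(status))
      stop_snvblur(sprintf("sample '%s': status is mandatory", sid),
                   "snvblur_validation")
    trait <- get("trait")
    if (is.null(trait) || !nzchar(trait))
      stop_snvblur(sprintf("sample '%s': trait is mandatory", sid),
                   "snvblur_validation")
    cn <- get("contact_name"); ca <- get("contact_affiliation")
    ce <- get("contact_email")
    if (is.null(cn) || is.null(ca) || is.null(ce))
      stop_snvblur(sprintf("sample '%s': contact is mandatory", sid),
                   "snvblur_validation")
    m <- sample_meta(
      sample_id = sid, status = status, trait = trait,
      hpo_present = hpo_split(get("hpo_present")),
      hpo_absent = hpo_split(get("hpo_absent")),
      gender = get("gender") %||% NA_character_,
      platform = get("platform") %||% NA_character_,
      enrichment = get("enrichment") %||% NA_character_,
      pi = get("pi") %||% NA_character_,
      contact = list(name = cn, affiliation = ca, email = ce),
      contact_release = tolower(get("contact_release") %||% "false") %in%
        c("true", "1", "yes"))
    if (!is.null(s$vcf)) attr(m, "vcf") <- s$vcf
    out[[sid]] <- m
  }
  out
}

#' Write sample metadata to an INI file
#'
#' Inverse of [read_ini()]: the written file parses back to an equal list
#' of metadata records. Shared contact / PI / trait values are hoisted
#' into `[global]` only when identical across all samples.
#'
#' @param samples list of [sample_meta()] objects.
#' @param path output file.
#' @export
write_ini <- function(samples, path) {
  lines <- "[global]"
  for (m in samples) validate_sample_meta(m)
  out_opt <- function(key, val) {
    if (is.null(val) || (length(val) == 1 && is.na(val))) character()
    else sprintf("%s = %s", key, val)
  }
  for (m in samples) {
    lines <- c(lines, "", sprintf("[sample:%s]", m$sample_id))
    v <- attr(m, "vcf")
    lines <- c(lines,
      out_opt("vcf", v),
      sprintf("status = %s", m$status),
      sprintf("trait = %s", m$trait),
      out_opt("gender", m$gender),
      out_opt("platform", m$platform),
      out_opt("enrichment", m$enrichment),
      out_opt("pi", m$pi),
      if (length(m$hpo_present))
        sprintf("hpo_present = %s", paste(m$hpo_present, collapse = ";"))
      else character(),
      if (length(m$hpo_absent))
        sprintf("hpo_absent = %s", paste(m$hpo_absent, collapse = ";"))
      else character(),
      sprintf("contact_name = %s", m$contact$name),
      sprintf("contact_affiliation = %s", m$contact$affiliation),
      sprintf("contact_email = %s", m$contact$email),
      sprintf("contact_release = %s",
              if (m$contact_release) "true" else "false"))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_snvblur(sprintf("cannot write INI '%s'", path), "snvblur_io")
  invisible(path)
}

#' Read a full cohort (metadata + genotypes)
#'
#' Reads the INI metadata file, then each sample's VCF. VCF paths come
#' from the per-sample `vcf` INI key (resolved relative to the INI file)
#' unless `vcf_paths` supplies them by sample id.
#'
#' @param ini_path metadata file, see [read_ini()].
#' @param vcf_paths optional named character vector `sample_id -> path`.
#' @return an [snv_cohort()].
#' @export
read_cohort <- function(ini_path, vcf_paths = NULL) {
  samples <- read_ini(ini_path)
  base <- dirname(ini_path)
  sites <- data.table(site_id = integer(), chrom = character(),
                      pos = integer(), id = character(),
                      ref = character(), alt = character())
  calls_list <- list()
  skip <- c(indel = 0L, symbolic = 0L, malformed = 0L)
  key_index <- new.env(parent = emptyenv())
  next_id <- 0L
  all_sites <- list()
  for (m in samples) {
    p <- if (!is.null(vcf_paths) && m$sample_id %in% names(vcf_paths))
      vcf_paths[[m$sample_id]] else attr(m, "vcf")
    if (is.null(p))
      stop_snvblur(sprintf("no VCF path for sample '%s'", m$sample_id),
                   "snvblur_validation")
    if (!file.exists(p)) p <- file.path(base, p)
    one <- read_vcf(p, sample_id_override = m$sample_id)
    skip <- skip + one$skip_stats
    if (!nrow(one$sites)) next
    keys <- cohort_keys(one)
    gid <- integer(length(keys))
    for (i in seq_along(keys)) {
      hit <- key_index[[keys[i]]]
      if (is.null(hit)) {
        next_id <- next_id + 1L
        key_index[[keys[i]]] <- next_id
        gid[i] <- next_id
        all_sites[[next_id]] <- one$sites[i]
      } else gid[i] <- hit
    }
    if (nrow(one$calls)) {
      cc <- copy(one$calls)
      cc[, site_id := gid[match(site_id, one$sites$site_id)]]
      calls_list[[length(calls_list) + 1L]] <- cc
    }
  }
  if (length(all_sites)) {
    sites <- rbindlist(all_sites)
    sites[, site_id := seq_len(.N)]
  }
  calls <- if (length(calls_list)) rbindlist(calls_list) else
    data.table(site_id = integer(), sample_id = character(),
               zygosity = character())
  snv_cohort(samples, sites, calls, skip)
}
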