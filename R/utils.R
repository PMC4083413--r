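#' @import data.table
#' @importFrom stats median rexp rbinom runif setNames ave
#' @importFrom utils URLencode URLdecode
NULL

.datatable.aware <- TRUE

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "site_id", "sample_id", "sub_id", "zygosity", "chrom",
  "pos", "ref", "alt", "id", "blurred", "carrier_count", "het_count",
  "hom_count", "trait_summary", "subs", "contact", "count", "key",
  "class_id", "trait", "n_members", "size", "shared", "containment",
  "jaccard", "is_own", "n_sites", "k", "het", "hom", "N", "label", "n",
  "class_tokens", "hpo_terms", "matched_term", "within_gene", "gene",
  "ref_freq", "carrier_freq", "freq", "start", "end"
))

#' Canonical string key for an SNV locus
#'
#' Builds the `chrom:pos:ref:alt` identity string used everywhere
#' downstream: two variant records are the same SNV iff their keys match.
#'
#' @param chrom chromosome name as printed in the VCF.
#' @param pos 1-based position.
#' @param ref,alt single upper-case bases.
#' @return character vector of keys.
#' @export
snv_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# numeric-aware chromosome rank: 1..22 < X < Y < MT < everything else (alpha)
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(x))
  r <- n
  r[x %in% c("X", "x")] <- 23
  r[x %in% c("Y", "y")] <- 24
  r[x %in% c("MT", "M", "mt")] <- 25
  bad <- is.na(r)
  if (any(bad)) {
    extra <- sort(unique(x[bad]))
    r[bad] <- 25 + match(x[bad], extra)
  }
  r
}

# order for aggregated records: (chrom, pos, ref, alt)
snv_order <- function(dt) {
  order(chrom_rank(dt$chrom), dt$pos, dt$ref, dt$alt, method = "radix")
}

# percent-encode a string so it is safe inside a VCF INFO value
# (no ';' ',' '=' '|' or whitespace survive)
pct_encode <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    s <- URLencode(s, reserved = TRUE)
    # URLencode leaves !*'() unescaped; they are INFO-safe, keep them
    s
  }, character(1), USE.NAMES = FALSE)
}

pct_decode <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

# exact-round-trip numeric formatting for header echo lines
num_fmt <- function(x) sprintf("%.17g", x)

# random 128-bit hex token drawn from the *R* RNG so that sub-sample ids
# are reproducible under a seed (required for byte-identical output)
rng_token <- function(n = 1L) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    paste(sample(hex, 32L, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_snvblur <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "snvblur_error")))
}
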