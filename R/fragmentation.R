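# ---------------------------------------------------------------------------
# Step 2 of aggregation: fragmentation of the SNV data.
#
# Each sample's calls are split into sub-samples of deliberately unequal
# size: if sub-samples were near-equal, a group of linked sub-samples
# could be recognized by its size signature and the sample reconstructed.
# Per sample, a weight vector is drawn once from the flat (symmetric,
# concentration 1) law on the probability simplex - all weight vectors
# equally likely - and every SNV is then assigned independently with
# those weights. Sub-sample ids are random 128-bit tokens carrying no
# information about the source sample. The secret sample <-> sub-sample
# map lives only in an encrypted, password-protected linkage file.
# ---------------------------------------------------------------------------

#' Fragmentation configuration
#'
#' @param n_subsamples sub-samples per sample (default 5).
#' @param weight_law identifier of the weight-generating law; only
#'   `"flat_simplex"` is implemented.
#' @param seed optional RNG seed applied by [aggregate_cohort()].
#' @export
fragmentation_config <- function(n_subsamples = 5L,
                                 weight_law = "flat_simplex", seed = NULL) {
  n_subsamples <- as.integer(n_subsamples)
  if (is.na(n_subsamples) || n_subsamples < 1L)
    stop_snvblur("n_subsamples must be >= 1", "snvblur_validation")
  if (!identical(weight_law, "flat_simplex"))
    stop_snvblur(sprintf("unknown weight law '%s'", weight_law),
                 "snvblur_validation")
  structure(list(n_subsamples = n_subsamples, weight_law = weight_law,
                 seed = seed), class = "fragmentation_config")
}

# flat law on the simplex: normalized iid Exp(1) draws
draw_weights <- function(k) {
  e <- rexp(k)
  e / sum(e)
}

#' Fragment one sample's calls into sub-samples
#'
#' @param calls `data.table` with columns `site_id`, `zygosity` (one
#'   sample's calls).
#' @param config a [fragmentation_config()].
#' @return list of sub-samples, each `list(sub_id, calls)`; empty
#'   sub-samples are dropped. Consumes the R RNG stream (seed it for
#'   reproducibility).
#' @export
fragment_sample <- function(calls, config = fragmentation_config()) {
  calls <- as.data.table(calls)
  k <- config$n_subsamples
  sub_ids <- rng_token(k)
  if (!nrow(calls)) return(list())
  w <- draw_weights(k)
  assign <- sample.int(k, nrow(calls), replace = TRUE, prob = w)
  out <- lapply(seq_len(k), function(j) {
    cj <- calls[assign == j]
    if (!nrow(cj)) NULL else list(sub_id = sub_ids[j], calls = cj)
  })
  out[!vapply(out, is.null, logical(1))]
}

# fragment every sample; returns the sub-sample call table plus the
# linkage records (sample -> sub-samples with their full call lists)
fragment_cohort <- function(cohort, config = fragmentation_config()) {
  frag <- list()
  linkage <- list()
  keys_all <- cohort_keys(cohort)
  calls <- copy(cohort$calls)
  setkey(calls, sample_id)
  for (m in cohort$samples) {
    sc <- calls[.(m$sample_id), nomatch = NULL]
    subs <- fragment_sample(sc[, .(site_id, zygosity)], config)
    rec_subs <- lapply(subs, function(s) list(
      sub_id = s$sub_id,
      keys = keys_all[match(s$calls$site_id, cohort$sites$site_id)],
      zygosity = s$calls$zygosity))
    linkage[[length(linkage) + 1L]] <- list(
      sample_id = m$sample_id, trait = m$trait,
      subs = rec_subs)
    for (s in subs)
      frag[[length(frag) + 1L]] <- data.table(
        site_id = s$calls$site_id, sample_id = m$sample_id,
        sub_id = s$sub_id, zygosity = s$calls$zygosity)
  }
  calls <- if (length(frag)) rbindlist(frag) else
    data.table(site_id = integer(), sample_id = character(),
               sub_id = character(), zygosity = character())
  list(calls = calls, linkage = linkage)
}

# ---------------------------------------------------------------------------
# Encrypted linkage file.
#
# Authenticated password-based symmetric encryption (encrypt-then-MAC):
# bcrypt PBKDF stretches the passphrase into independent AES-256-CBC and
# HMAC-SHA256 keys; the MAC covers magic, header and ciphertext, so a
# wrong passphrase or a single flipped bit fails authentication before
# any plaintext is produced. Scheme and KDF parameters are recorded in a
# plaintext JSON header.
# ---------------------------------------------------------------------------

LINKAGE_MAGIC <- charToRaw("SNVLNK01")
LINKAGE_SCHEME <- "AES-256-CBC+HMAC-SHA256"
LINKAGE_KDF <- "bcrypt-pbkdf"
LINKAGE_KDF_ROUNDS <- 16L

derive_keys <- function(passphrase, salt, rounds) {
  km <- openssl::bcrypt_pbkdf(passphrase, salt, rounds, 64L)
  list(enc = km[1:32], mac = km[33:64])
}

#' Encrypt the sample/sub-sample linkage
#'
#' Serializes the linkage records (sample id, trait, per-sub-sample call
#' lists) to JSON and encrypts them under a passphrase. Only the holder
#' of the passphrase - the submitter - can recover the mapping; it is
#' needed to honour consent withdrawal via [remove_sample()].
#'
#' @param records list of linkage records (from aggregation).
#' @param passphrase non-empty string.
#' @return raw vector: the linkage file content.
#' @export
encrypt_linkage <- function(records, passphrase) {
  if (!is.character(passphrase) || !nzchar(passphrase))
    stop_snvblur("passphrase must be non-empty", "snvblur_validation")
  payload <- charToRaw(as.character(jsonlite::toJSON(
    records, auto_unbox = TRUE, digits = NA)))
  salt <- openssl::rand_bytes(16L)
  iv <- openssl::rand_bytes(16L)
  keys <- derive_keys(passphrase, salt, LINKAGE_KDF_ROUNDS)
  ct <- openssl::aes_cbc_encrypt(payload, keys$enc, iv)
  header <- charToRaw(as.character(jsonlite::toJSON(list(
    scheme = LINKAGE_SCHEME, kdf = LINKAGE_KDF,
    rounds = LINKAGE_KDF_ROUNDS,
    salt = jsonlite::base64_enc(salt), iv = jsonlite::base64_enc(iv)),
    auto_unbox = TRUE)))
  hlen <- writeBin(length(header), raw(), size = 4L, endian = "little")
  mac <- openssl::sha256(c(LINKAGE_MAGIC, hlen, header, as.raw(ct)),
                         key = keys$mac)
  c(LINKAGE_MAGIC, hlen, header, as.raw(ct), as.raw(mac))
}

#' Decrypt a linkage file
#'
#' Inverse of [encrypt_linkage()]. A wrong passphrase or any tampering
#' fails authentication with no partial output.
#'
#' @param ciphertext raw vector as produced by [encrypt_linkage()].
#' @param passphrase the submitter's passphrase.
#' @return the list of linkage records.
#' @export
decrypt_linkage <- function(ciphertext, passphrase) {
  if (!is.character(passphrase) || !nzchar(passphrase))
    stop_snvblur("passphrase must be non-empty", "snvblur_validation")
  n <- length(ciphertext)
  if (n < length(LINKAGE_MAGIC) + 4L + 32L ||
      !identical(ciphertext[seq_along(LINKAGE_MAGIC)], LINKAGE_MAGIC))
    stop_snvblur("not a linkage file (bad magic bytes)", "snvblur_format")
  off <- length(LINKAGE_MAGIC)
  hlen <- readBin(ciphertext[(off + 1L):(off + 4L)], integer(),
                  size = 4L, endian = "little")
  if (hlen <= 0L || off + 4L + hlen + 32L > n)
    stop_snvblur("corrupt linkage header", "snvblur_format")
  header <- jsonlite::fromJSON(rawToChar(
    ciphertext[(off + 4L + 1L):(off + 4L + hlen)]))
  if (!identical(header$scheme, LINKAGE_SCHEME))
    stop_snvblur(sprintf("unsupported scheme '%s'", header$scheme),
                 "snvblur_format")
  ct <- ciphertext[(off + 4L + hlen + 1L):(n - 32L)]
  mac_stored <- ciphertext[(n - 31L):n]
  keys <- derive_keys(passphrase, jsonlite::base64_dec(header$salt),
                      as.integer(header$rounds))
  mac <- as.raw(openssl::sha256(ciphertext[1:(n - 32L)], key = keys$mac))
  if (!identical(mac, mac_stored))
    stop_snvblur("authentication failed: wrong passphrase or tampered file",
                 "snvblur_auth")
  payload <- openssl::aes_cbc_decrypt(
    ct, keys$enc, jsonlite::base64_dec(header$iv))
  jsonlite::fromJSON(rawToChar(payload), simplifyVector = FALSE)
}
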