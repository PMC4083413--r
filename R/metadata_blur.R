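# ---------------------------------------------------------------------------
# Step 1 of aggregation: metadata ambiguity inspection.
#
# A patient could be re-identified through a unique combination of the
# released attributes (trait, HPO sets, gender, platform, enrichment), so
# no released attribute combination may be unique: every combination must
# be shared by at least k samples (k-anonymity, default k = 2). Where a
# combination falls short, attributes are suppressed (set to unknown) for
# all members of the violating group, in a fixed priority order that keeps
# the clinically informative HPO terms longest.
# ---------------------------------------------------------------------------

UNKNOWN <- "unknown"

#' Group samples into phenotype classes
#'
#' Samples with an identical set of HPO terms (both the present and the
#' explicitly absent set) form one phenotype class; classes partition the
#' cohort. Class ordering is deterministic: by sorted member ids.
#'
#' @param samples list of [sample_meta()] objects.
#' @return list of classes, each `list(class_id, member_ids, hpo_present,
#'   hpo_absent)`.
#' @export
build_phenotype_classes <- function(samples) {
  keys <- vapply(samples, function(m)
    paste(paste(m$hpo_present, collapse = ";"),
          paste(m$hpo_absent, collapse = ";"), sep = "||"), character(1))
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  groups <- split(ids, keys)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, character(1), 1L))]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    member <- groups[[i]]
    m <- samples[[match(member[1], ids)]]
    out[[i]] <- list(class_id = sprintf("C%d", i), member_ids = member,
                     hpo_present = m$hpo_present, hpo_absent = m$hpo_absent)
  }
  out
}

#' Project a sample onto its released attribute tuple
#'
#' The combination of attributes a third party would actually see for a
#' sample: trait, the two HPO sets, gender, platform and enrichment, with
#' unset or suppressed attributes shown as `"unknown"`. Sample id, status
#' and contact are not part of the tuple.
#'
#' @param sample a [sample_meta()].
#' @return named character vector of length 6.
#' @export
released_tuple <- function(sample) {
  un <- function(x) if (is.na(x) || !nzchar(x)) UNKNOWN else x
  c(trait = sample$trait,
    hpo_present = if (length(sample$hpo_present))
      paste(sample$hpo_present, collapse = ";") else UNKNOWN,
    hpo_absent = if (length(sample$hpo_absent))
      paste(sample$hpo_absent, collapse = ";") else UNKNOWN,
    gender = un(sample$gender),
    platform = un(sample$platform),
    enrichment = un(sample$enrichment))
}

tuple_strings <- function(samples) {
  vapply(samples, function(m) paste(released_tuple(m), collapse = "\r"),
         character(1))
}

#' Suppress metadata until every released tuple is k-anonymous
#'
#' Greedy suppression: while some released attribute combination occurs
#' fewer than `k` times, take the smallest violating group (ties broken
#' by tuple string) and delete, for all its members, the first attribute
#' in the priority order enrichment -> platform -> gender -> HPO sets
#' that still carries information. Trait and status are never suppressed;
#' if a trait itself occurs fewer than `k` times the cohort cannot be
#' released and an error is raised.
#'
#' @param samples list of [sample_meta()] objects.
#' @param k anonymity parameter, integer >= 2.
#' @return `list(samples = <suppressed copies>, log = <data.frame with
#'   sample_id, attribute, reason>)`.
#' @export
suppress_metadata <- function(samples, k = 2L) {
  if (k < 2L)
    stop_snvblur("k must be >= 2", "snvblur_validation")
  if (length(samples) < k)
    stop_snvblur(sprintf(
      "cohort of %d samples cannot be released with k = %d",
      length(samples), k), "snvblur_validation")
  for (m in samples) validate_sample_meta(m)
  samples <- lapply(samples, identity)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  log <- list()
  repeat {
    ts <- tuple_strings(samples)
    tab <- table(ts)
    bad <- names(tab)[tab < k]
    if (!length(bad)) break
    # smallest violating group; deterministic tie-break on tuple string
    bad <- bad[order(tab[bad], bad)]
    grp <- which(ts == bad[1])
    m0 <- samples[[grp[1]]]
    pick <- function(m) {
      if (!is.na(m$enrichment)) "enrichment"
      else if (!is.na(m$platform)) "platform"
      else if (!is.na(m$gender)) "gender"
      else if (length(m$hpo_present) || length(m$hpo_absent)) "hpo"
      else NA_character_
    }
    has_attr <- function(m, a) switch(a,
      enrichment = !is.na(m$enrichment),
      platform = !is.na(m$platform),
      gender = !is.na(m$gender),
      hpo = length(m$hpo_present) > 0 || length(m$hpo_absent) > 0)
    attrib <- pick(m0)
    if (is.na(attrib)) {
      # the violating group is already reduced to its bare trait; its
      # trait-peers must shed the same attributes too, or the group can
      # never merge with anything and the cohort cannot be released
      traits <- vapply(samples, `[[`, character(1), "trait")
      peers <- which(traits == m0$trait)
      for (a in c("enrichment", "platform", "gender", "hpo")) {
        hit <- peers[vapply(samples[peers], has_attr, logical(1), a)]
        if (length(hit)) { attrib <- a; grp <- hit; break }
      }
      if (is.na(attrib))
        stop_snvblur(sprintf(
          "cannot anonymize: trait '%s' occurs fewer than %d times",
          m0$trait, k), "snvblur_validation")
    }
    for (i in grp) {
      if (attrib == "hpo") {
        samples[[i]]$hpo_present <- character()
        samples[[i]]$hpo_absent <- character()
      } else {
        samples[[i]][[attrib]] <- NA_character_
      }
      log[[length(log) + 1L]] <- data.frame(
        sample_id = ids[i], attribute = attrib,
        reason = sprintf("released tuple shared by %d < %d samples",
                         length(grp), k))
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(sample_id = character(), attribute = character(),
               reason = character())
  list(samples = samples, log = log)
}

#' Write a suppression log as JSON lines
#'
#' @param log the `log` component of [suppress_metadata()].
#' @param path output file; one JSON object per deletion.
#' @export
write_suppression_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i)
    as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
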