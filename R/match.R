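#' Match variants between the two resources
#'
#' Identifies variant x disease records shared by the curated resource and
#' the clinical repository using shared identifiers, with join precedence
#' dbSNP rsid > transcript-level HGVS > protein-level HGVS (accession plus
#' protein change).  A record matched by a higher-precedence key is not
#' re-matched by a lower one.  Duplicate identities on one side are logged
#' and all duplicate combinations are paired, flagged `ambiguous`.  Output
#' order is deterministic (gene, position, condition) and invariant under
#' shuffling of the inputs.
#'
#' @param uniprot_set Curated-resource records: a `"parsed_table"` from
#'   [read_uniprot_table()] or its `records` data frame.
#' @param clinvar_set Clinical-repository records: a `"parsed_table"` from
#'   [read_clinvar_table()] or its `records` data frame.
#' @return A data frame of class `"matched_pairs"`, one row per matched
#'   (variant, condition/disease) combination, carrying the classification,
#'   star status and disease-model columns needed downstream plus
#'   `match_key` and `ambiguous`.
#' @seealso [apply_study_filters()]
#' @export
match_variants <- function(uniprot_set, clinvar_set) {
  u <- .records_of(uniprot_set)
  cv <- .records_of(clinvar_set)
  u$.uid <- seq_len(nrow(u))
  cv$.cid <- seq_len(nrow(cv))

  ukeys <- .match_keys(u)
  ckeys <- .match_keys(cv)

  matched_u <- rep(FALSE, nrow(u))
  matched_c <- rep(FALSE, nrow(cv))
  pairs <- list()
  for (stage in c("RSID", "HGVS_C", "HGVS_P")) {
    uk <- ukeys[[stage]]
    ck <- ckeys[[stage]]
    ui <- which(!matched_u & !is.na(uk))
    ci <- which(!matched_c & !is.na(ck))
    if (!length(ui) || !length(ci)) next
    m <- merge(data.frame(key = uk[ui], .uid = u$.uid[ui],
                          stringsAsFactors = FALSE),
               data.frame(key = ck[ci], .cid = cv$.cid[ci],
                          stringsAsFactors = FALSE),
               by = "key")
    if (!nrow(m)) next
    dup_u <- duplicated(uk[ui]) | duplicated(uk[ui], fromLast = TRUE)
    dup_c <- duplicated(ck[ci]) | duplicated(ck[ci], fromLast = TRUE)
    dup_keys <- unique(c(uk[ui][dup_u], ck[ci][dup_c]))
    if (length(dup_keys)) {
      message("match_variants: ", length(dup_keys),
              " duplicated ", stage, " identit(ies); ",
              "all combinations paired and flagged ambiguous")
    }
    m$match_key <- stage
    m$ambiguous <- m$key %in% dup_keys
    pairs[[stage]] <- m
    matched_u[m$.uid] <- TRUE
    matched_c[m$.cid] <- TRUE
  }

  if (!length(pairs)) {
    out <- .empty_pairs()
  } else {
    m <- do.call(rbind, pairs)
    out <- data.frame(
      uniprot_row = m$.uid, clinvar_row = m$.cid,
      match_key = m$match_key, ambiguous = m$ambiguous,
      gene_symbol = u$gene_symbol[m$.uid],
      protein_accession = u$protein_accession[m$.uid],
      hgvs_p = u$hgvs_p[m$.uid], rsid = u$rsid[m$.uid],
      ref_aa = u$ref_aa[m$.uid], position = u$position[m$.uid],
      alt_aa = u$alt_aa[m$.uid],
      uniprot_class = u$uniprot_class[m$.uid],
      disease_name = u$disease_name[m$.uid],
      is_mendelian = u$is_mendelian[m$.uid],
      condition = cv$condition[m$.cid],
      aggregate_class = cv$aggregate_class[m$.cid],
      review_stars = cv$review_stars[m$.cid],
      stringsAsFactors = FALSE)
    out$is_missense <- !is.na(out$ref_aa) & !is.na(out$alt_aa) &
      out$ref_aa != out$alt_aa
    out <- out[order(out$gene_symbol, out$position, out$condition,
                     out$match_key, out$uniprot_row, out$clinvar_row), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("matched_pairs", class(out))
  out
}

.records_of <- function(x) {
  if (inherits(x, "parsed_table")) x$records else as.data.frame(x)
}

.match_keys <- function(df) {
  rs <- .normalize_rsid(df$rsid)
  rs[!.valid_rsid(rs)] <- NA_character_
  hc <- .normalize_hgvs(df$hgvs_c)
  hp <- .normalize_hgvs(df$hgvs_p)
  acc <- df$protein_accession
  hp_key <- ifelse(is.na(hp) | is.na(acc) | acc == "", NA_character_,
                   paste0(acc, ":", hp))
  list(RSID = rs, HGVS_C = hc, HGVS_P = hp_key)
}

.empty_pairs <- function() {
  data.frame(uniprot_row = integer(), clinvar_row = integer(),
             match_key = character(), ambiguous = logical(),
             gene_symbol = character(), protein_accession = character(),
             hgvs_p = character(), rsid = character(),
             ref_aa = character(), position = integer(),
             alt_aa = character(), uniprot_class = character(),
             disease_name = character(), is_mendelian = logical(),
             condition = character(), aggregate_class = character(),
             review_stars = integer(), is_missense = logical(),
             stringsAsFactors = FALSE)
}

#' Apply the study inclusion filters
#'
#' Retains matched pairs that are (a) missense substitutions, (b) reported
#' in clinical-repository records with 2-star review status, and (c)
#' associated with a Mendelian disease (variants found in multifactorial
#' disorders are excluded).  Each excluded pair is attributed to exactly
#' one filter, the first failing one in the fixed order
#' missense -> review stars -> Mendelian, so that the retained count plus
#' the exclusion counts always equals the input count.
#'
#' @param pairs A `"matched_pairs"` data frame from [match_variants()].
#' @return A list of class `"filtered_pairs"` with elements `pairs` (the
#'   retained pairs), `exclusions` (named integer vector of per-filter
#'   counts) and `n_input`.
#' @export
apply_study_filters <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  fail_missense <- !pairs$is_missense
  fail_stars <- !fail_missense &
    (is.na(pairs$review_stars) | pairs$review_stars != 2L)
  fail_mend <- !fail_missense & !fail_stars & !pairs$is_mendelian
  keep <- !(fail_missense | fail_stars | fail_mend)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(pairs = out,
                 exclusions = c(missense = sum(fail_missense),
                                review_stars = sum(fail_stars),
                                mendelian = sum(fail_mend)),
                 n_input = nrow(pairs)),
            class = "filtered_pairs")
}

#' @export
print.filtered_pairs <- function(x, ...) {
  cat("<filtered_pairs> retained ", nrow(x$pairs), " of ", x$n_input,
      " pair(s)\n  excluded: ",
      paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
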