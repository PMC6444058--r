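#' ACMG-AMP evidence codes
#'
#' The 28 coded criteria of the ACMG-AMP framework.  Polarity and default
#' strength are determined by the code prefix: PVS = very strong
#' pathogenic, PS = strong, PM = moderate, PP = supporting; BA = stand-alone
#' benign, BS = strong benign, BP = supporting benign.
#'
#' @return Data frame with columns `code`, `polarity`, `default_strength`.
#' @export
acmg_codes <- function() {
  grp <- function(prefix, n, polarity, strength) {
    data.frame(code = paste0(prefix, seq_len(n)), polarity = polarity,
               default_strength = strength, stringsAsFactors = FALSE)
  }
  rbind(grp("PVS", 1, "PATHOGENIC", "VERY_STRONG"),
        grp("PS", 4, "PATHOGENIC", "STRONG"),
        grp("PM", 6, "PATHOGENIC", "MODERATE"),
        grp("PP", 5, "PATHOGENIC", "SUPPORTING"),
        grp("BA", 1, "BENIGN", "STAND_ALONE"),
        grp("BS", 4, "BENIGN", "STRONG"),
        grp("BP", 7, "BENIGN", "SUPPORTING"))
}

#' Create an evidence assignment
#'
#' One applied ACMG-AMP criterion: the code, the strength at which it is
#' applied (default: the code's default strength) and a provenance note.
#' Strengths may only be changed through [adjust_strength()], which
#' requires a justification.
#'
#' @param code An ACMG-AMP code, e.g. `"PM2"`.
#' @param strength Optional applied strength (one of
#'   [evidence_strengths()]); when it differs from the code's default a
#'   non-empty `justification` is required.
#' @param justification Free-text reason.
#' @param source Citation or identifier backing the evidence.
#' @return A one-row data frame with columns `code`, `polarity`,
#'   `default_strength`, `applied_strength`, `justification`, `source`.
#'   Rows `rbind()` into an evidence list for [combine_evidence()].
#' @examples
#' rbind(evidence_assignment("BS1"),
#'       evidence_assignment("BS2", "SUPPORTING", "penetrance is not 100%"))
#' @export
evidence_assignment <- function(code, strength = NULL, justification = "",
                                source = "") {
  codes <- acmg_codes()
  i <- match(toupper(code), codes$code)
  if (is.na(i)) {
    stop("unknown ACMG evidence code ", sQuote(code), call. = FALSE)
  }
  a <- data.frame(code = codes$code[i], polarity = codes$polarity[i],
                  default_strength = codes$default_strength[i],
                  applied_strength = codes$default_strength[i],
                  justification = justification, source = source,
                  stringsAsFactors = FALSE)
  if (!is.null(strength) && !is.na(strength) && nzchar(strength)) {
    a <- adjust_strength(a, strength, justification)
  }
  a
}

.normalize_strength <- function(x) {
  key <- toupper(gsub("[ \\-]+", "_", trimws(x)))
  key[key == "STANDALONE"] <- "STAND_ALONE"
  key
}

#' Adjust the applied strength of an evidence assignment
#'
#' Professional judgment may up- or down-weight a criterion (for example,
#' applying BS2 only as supporting evidence when penetrance is incomplete),
#' but never flip its polarity, and every change must carry a
#' justification.  The code's default strength is retained for the report.
#'
#' @param a A one-row evidence assignment from [evidence_assignment()].
#' @param new_strength One of [evidence_strengths()].  `STAND_ALONE` is
#'   only valid for benign-polarity codes.
#' @param justification Non-empty free text when the strength changes.
#' @return The modified assignment.
#' @export
adjust_strength <- function(a, new_strength, justification) {
  stopifnot(is.data.frame(a), nrow(a) == 1L)
  ns <- .normalize_strength(new_strength)
  if (ns %in% c("PATHOGENIC", "BENIGN")) {
    stop("polarity of an evidence code is immutable; ", a$code,
         " stays ", a$polarity, call. = FALSE)
  }
  if (!(ns %in% evidence_strengths())) {
    stop("unknown strength ", sQuote(new_strength), "; expected one of ",
         paste(evidence_strengths(), collapse = ", "), call. = FALSE)
  }
  if (ns == "STAND_ALONE" && a$polarity != "BENIGN") {
    stop("STAND_ALONE strength is reserved for benign-polarity evidence",
         call. = FALSE)
  }
  if (ns != a$applied_strength &&
      (missing(justification) || !nzchar(trimws(justification)))) {
    stop("changing the strength of ", a$code,
         " requires a non-empty justification", call. = FALSE)
  }
  a$applied_strength <- ns
  if (!missing(justification) && nzchar(trimws(justification))) {
    a$justification <- justification
  }
  a
}

# combining rules ----------------------------------------------------------

.rules_env <- new.env(parent = emptyenv())

#' The shipped combining-rule table
#'
#' The ACMG-AMP combining rules, frozen as package data
#' (`extdata/acmg_rules.tsv`) so that the engine and its tests pin the same
#' table.  Each row gives a target class and the minimum counts of
#' pathogenic very-strong / strong / moderate / supporting and benign
#' stand-alone / strong / supporting evidence that fire the rule.
#'
#' @return Data frame with columns `rule`, `class`, `pvs`, `ps`, `pm`,
#'   `pp`, `ba`, `bs`, `bp`.
#' @export
acmg_rule_table <- function() {
  if (is.null(.rules_env$rules)) {
    path <- system.file("extdata", "acmg_rules.tsv", package = "varconcord")
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    for (col in c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")) {
      df[[col]] <- as.integer(df[[col]])
    }
    .rules_env$rules <- df
  }
  .rules_env$rules
}

#' Classify from evidence-strength counts
#'
#' Vectorized core of the engine: given the number of applied evidence
#' items in each polarity x strength stratum, fires every combining rule
#' whose minimum counts are met and resolves the five-tier class.
#' Pathogenic wins over likely pathogenic and benign over likely benign
#' when both fire on the same side; if rules fire on both sides the result
#' is `VUS` with `conflicting = TRUE`.  A `VUS` that fires no rule is also
#' flagged conflicting when evidence of both polarities is present
#' (conflicting evidence without a resolving rule).
#'
#' @param pvs,ps,pm,pp Counts of pathogenic very-strong, strong, moderate
#'   and supporting evidence.
#' @param ba,bs,bp Counts of benign stand-alone, strong and supporting
#'   evidence.
#' @return Data frame with columns `classification`, `conflicting` and
#'   `fired` (comma-separated rule ids).
#' @export
classify_evidence_counts <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                                     ba = 0, bs = 0, bp = 0) {
  n <- max(lengths(list(pvs, ps, pm, pp, ba, bs, bp)))
  counts <- cbind(pvs = rep_len(pvs, n), ps = rep_len(ps, n),
                  pm = rep_len(pm, n), pp = rep_len(pp, n),
                  ba = rep_len(ba, n), bs = rep_len(bs, n),
                  bp = rep_len(bp, n))
  rules <- acmg_rule_table()
  need <- as.matrix(rules[c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")])
  # fired[i, r]: does evidence vector i meet every minimum of rule r?
  fired <- matrix(TRUE, n, nrow(rules))
  for (k in seq_len(ncol(need))) {
    fired <- fired & outer(counts[, k], need[, k], `>=`)
  }
  p_fire <- rowSums(fired[, rules$class == "PATHOGENIC", drop = FALSE]) > 0
  lp_fire <- rowSums(fired[, rules$class == "LIKELY_PATHOGENIC",
                           drop = FALSE]) > 0
  b_fire <- rowSums(fired[, rules$class == "BENIGN", drop = FALSE]) > 0
  lb_fire <- rowSums(fired[, rules$class == "LIKELY_BENIGN",
                           drop = FALSE]) > 0
  path_side <- p_fire | lp_fire
  ben_side <- b_fire | lb_fire
  cls <- rep("VUS", n)
  cls[path_side & !ben_side] <- ifelse(p_fire[path_side & !ben_side],
                                       "PATHOGENIC", "LIKELY_PATHOGENIC")
  cls[ben_side & !path_side] <- ifelse(b_fire[ben_side & !path_side],
                                       "BENIGN", "LIKELY_BENIGN")
  has_path <- rowSums(counts[, c("pvs", "ps", "pm", "pp"), drop = FALSE]) > 0
  has_ben <- rowSums(counts[, c("ba", "bs", "bp"), drop = FALSE]) > 0
  conflicting <- (path_side & ben_side) |
    (!path_side & !ben_side & has_path & has_ben)
  fired_ids <- apply(fired, 1L, function(f) {
    paste(rules$rule[f], collapse = ",")
  })
  data.frame(classification = cls, conflicting = conflicting,
             fired = fired_ids, stringsAsFactors = FALSE)
}

# strengths outside the rule vocabulary are mapped to the nearest stratum
# the rules know: pathogenic side has no stand-alone stratum (counted as
# very strong); the benign side has no very-strong or moderate stratum
# (counted as strong and supporting respectively)
.count_strata <- function(evidence) {
  path <- evidence$polarity == "PATHOGENIC"
  s <- evidence$applied_strength
  c(pvs = sum(path & s %in% c("VERY_STRONG", "STAND_ALONE")),
    ps = sum(path & s == "STRONG"),
    pm = sum(path & s == "MODERATE"),
    pp = sum(path & s == "SUPPORTING"),
    ba = sum(!path & s == "STAND_ALONE"),
    bs = sum(!path & s %in% c("VERY_STRONG", "STRONG")),
    bp = sum(!path & s %in% c("MODERATE", "SUPPORTING")))
}

#' Combine evidence into a five-tier classification
#'
#' Deduplicates the evidence by code (criteria are counted once however
#' often they are cited), tallies the applied strengths by polarity and
#' resolves the ACMG-AMP combining rules via
#' [classify_evidence_counts()].  An empty evidence list yields `VUS`
#' (no criteria met).
#'
#' @param evidence Evidence data frame (rows from
#'   [evidence_assignment()]), or `NULL`/empty.
#' @return A list of class `"acmg_classification"` with elements
#'   `classification`, `fired_rules`, `conflicting`, `evidence` (the
#'   deduplicated assignments) and `counts`.
#' @examples
#' combine_evidence(rbind(evidence_assignment("PVS1"),
#'                        evidence_assignment("PS1")))$classification
#' @export
combine_evidence <- function(evidence = NULL) {
  if (is.null(evidence) || nrow(evidence) == 0L) {
    evidence <- evidence_assignment("PM2")[0L, ]
  }
  dup <- duplicated(evidence$code)
  if (any(dup)) {
    message("combine_evidence: dropping ", sum(dup),
            " duplicated evidence code(s): ",
            paste(unique(evidence$code[dup]), collapse = ", "))
    evidence <- evidence[!dup, , drop = FALSE]
  }
  counts <- .count_strata(evidence)
  res <- classify_evidence_counts(counts["pvs"], counts["ps"], counts["pm"],
                                  counts["pp"], counts["ba"], counts["bs"],
                                  counts["bp"])
  fired <- if (nzchar(res$fired)) strsplit(res$fired, ",")[[1L]] else
    character(0)
  structure(list(classification = res$classification,
                 fired_rules = fired,
                 conflicting = res$conflicting,
                 evidence = evidence, counts = counts),
            class = "acmg_classification")
}

.display_class <- c(PATHOGENIC = "Pathogenic",
                    LIKELY_PATHOGENIC = "Likely pathogenic",
                    VUS = "Uncertain significance",
                    LIKELY_BENIGN = "Likely benign",
                    BENIGN = "Benign")

#' @export
print.acmg_classification <- function(x, ...) {
  cat("<acmg_classification> ", .display_class[[x$classification]],
      if (x$conflicting) " (conflicting evidence)", "\n",
      "  evidence: ",
      if (nrow(x$evidence)) paste(x$evidence$code, collapse = ", ") else
        "none", "\n", sep = "")
  invisible(x)
}

#' Render a classification report
#'
#' Produces a deterministic plain-text report: final class, conflict flag,
#' fired combining rules and, for every evidence item, its code, polarity,
#' default versus applied strength, justification and source.
#' [parse_report()] recovers the classification and conflict flag from the
#' rendered text.
#'
#' @param r An `"acmg_classification"` from [combine_evidence()].
#' @return A single string (embedded newlines).
#' @export
render_report <- function(r) {
  stopifnot(inherits(r, "acmg_classification"))
  ev <- r$evidence
  lines <- c(
    "ACMG-AMP classification report",
    paste0("Classification: ", .display_class[[r$classification]]),
    paste0("Conflicting evidence: ", if (r$conflicting) "yes" else "no"),
    paste0("Fired rules: ",
           if (length(r$fired_rules)) paste(r$fired_rules, collapse = ", ")
           else "none"),
    paste0("Evidence items: ", nrow(ev)))
  if (nrow(ev) == 0L) {
    lines <- c(lines, "  (no criteria met)")
  } else {
    lines <- c(lines, sprintf(
      "  %s [%s] default=%s applied=%s | %s | %s",
      ev$code, ev$polarity, ev$default_strength, ev$applied_strength,
      ifelse(nzchar(ev$justification), ev$justification, "-"),
      ifelse(nzchar(ev$source), ev$source, "-")))
  }
  paste(lines, collapse = "\n")
}

#' @rdname render_report
#' @param text A rendered report string.
#' @return For `parse_report()`: list with `classification` and
#'   `conflicting`.
#' @export
parse_report <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  cls_line <- sub("^Classification: ", "",
                  grep("^Classification: ", lines, value = TRUE)[1L])
  cls <- names(.display_class)[match(cls_line, .display_class)]
  if (is.na(cls)) stop("cannot parse classification from report",
                       call. = FALSE)
  conf <- grepl("yes$", grep("^Conflicting evidence: ", lines,
                             value = TRUE)[1L])
  list(classification = cls, conflicting = conf)
}

# accept either full assignment rows or bare code/strength/justification
# rows (as written by the profile generator) and return assignment rows
.as_evidence <- function(df) {
  if (is.null(df) || nrow(df) == 0L ||
      all(c("polarity", "applied_strength") %in% names(df))) {
    return(df)
  }
  just <- if (is.null(df$justification)) rep("", nrow(df)) else
    ifelse(is.na(df$justification), "", df$justification)
  src <- if (is.null(df$source)) rep("", nrow(df)) else
    ifelse(is.na(df$source), "", df$source)
  str <- if (is.null(df$strength)) rep(NA_character_, nrow(df)) else
    df$strength
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    evidence_assignment(df$code[i], str[i], just[i], src[i])
  }))
}

#' Read an evidence table
#'
#' Reads a structured tab-separated evidence file with columns `code`,
#' `strength` (empty for the code's default), `justification`, `source`
#' and optionally `variant_id` (for per-variant profile files).
#'
#' @param path Path to the tab-separated evidence file.
#' @return Evidence data frame ready for [combine_evidence()]; with a
#'   `variant_id` column when the file has one (see
#'   [classify_profiles()]).
#' @export
read_evidence_table <- function(path) {
  raw <- .read_tsv(path)
  if (nrow(raw) == 0L) return(evidence_assignment("PM2")[0L, ])
  stopifnot("code" %in% names(raw))
  just <- if (is.null(raw$justification)) rep("", nrow(raw)) else
    ifelse(is.na(raw$justification), "", raw$justification)
  src <- if (is.null(raw$source)) rep("", nrow(raw)) else
    ifelse(is.na(raw$source), "", raw$source)
  str <- if (is.null(raw$strength)) rep(NA_character_, nrow(raw)) else
    raw$strength
  out <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    evidence_assignment(raw$code[i], str[i], just[i], src[i])
  }))
  if (!is.null(raw$variant_id)) out <- cbind(variant_id = raw$variant_id, out)
  out
}

#' Classify per-variant evidence profiles
#'
#' Applies [combine_evidence()] to each variant's evidence rows.  Variants
#' listed in `variant_ids` but absent from `profiles` are classified from
#' an empty profile (`VUS`, no criteria met).
#'
#' @param profiles Evidence data frame with a `variant_id` column.
#' @param variant_ids Optional character vector of all variants to
#'   classify.
#' @return Data frame with one row per variant: `variant_id`,
#'   `classification`, `conflicting`, `fired_rules`, `n_evidence`.
#' @export
classify_profiles <- function(profiles, variant_ids = NULL) {
  ids <- unique(c(as.character(variant_ids),
                  as.character(profiles$variant_id)))
  res <- lapply(ids, function(id) {
    ev <- profiles[profiles$variant_id == id, , drop = FALSE]
    ev$variant_id <- NULL
    ev <- .as_evidence(ev)
    r <- combine_evidence(ev)
    data.frame(variant_id = id, classification = r$classification,
               conflicting = r$conflicting,
               fired_rules = paste(r$fired_rules, collapse = ","),
               n_evidence = nrow(r$evidence), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
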