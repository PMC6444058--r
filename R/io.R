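#' Shipped file dialects
#'
#' Both table readers are driven by a column map ("dialect") so that files
#' with different headers can be read without rewriting them.  Three presets
#' ship with the package:
#'
#' * `"humsavar-2017"` — curated-resource variant table: one row per
#'   variant x disease with a three-class interpretation.
#' * `"clinvar-submissions-2017"` — clinical-repository table with one row
#'   per submitter; rows are grouped by variant x condition and the
#'   review-star status is computed from the submissions.
#' * `"clinvar-summary-2017"` — pre-aggregated clinical-repository table
#'   with one row per variant x condition and an explicit review-status
#'   column (integer stars 0-4 or the repository's status phrases).
#'
#' A dialect is a list with elements `type`, `columns` (map from logical
#' field to file column name) and `required` (logical fields whose columns
#' must be present).  Pass a modified copy to the readers for custom files.
#'
#' @param name Preset name, or a dialect list which is validated and
#'   returned unchanged.
#' @return A dialect list.
#' @examples
#' io_dialect("humsavar-2017")$columns$protein_change
#' @export
io_dialect <- function(name) {
  if (is.list(name)) {
    stopifnot(all(c("type", "columns", "required") %in% names(name)))
    return(name)
  }
  switch(name,
    "humsavar-2017" = list(
      name = name, type = "uniprot",
      columns = list(gene_symbol = "gene", protein_accession = "accession",
                     protein_change = "variant", classification = "category",
                     rsid = "dbsnp", hgvs_c = "hgvs_c",
                     disease_name = "disease", omim_id = "omim",
                     inheritance = "inheritance", prevalence = "prevalence",
                     penetrance = "penetrance",
                     carrier_frequency = "carrier_frequency",
                     is_mendelian = "mendelian"),
      required = c("gene_symbol", "protein_accession", "protein_change",
                   "classification")),
    "clinvar-submissions-2017" = list(
      name = name, type = "clinvar_submissions",
      columns = list(gene_symbol = "gene", protein_accession = "accession",
                     protein_change = "variant", rsid = "dbsnp",
                     hgvs_c = "hgvs_c", condition = "condition",
                     submitter = "submitter", classification = "classification",
                     criteria_provided = "criteria_provided",
                     expert_panel = "expert_panel",
                     practice_guideline = "practice_guideline"),
      required = c("gene_symbol", "protein_change", "condition", "submitter",
                   "classification", "criteria_provided")),
    "clinvar-summary-2017" = list(
      name = name, type = "clinvar_aggregate",
      columns = list(gene_symbol = "gene", protein_accession = "accession",
                     protein_change = "variant", rsid = "dbsnp",
                     hgvs_c = "hgvs_c", condition = "condition",
                     classification = "clinical_significance",
                     review_status = "review_status"),
      required = c("gene_symbol", "protein_change", "condition",
                   "classification", "review_status")),
    stop("unknown dialect ", sQuote(name), "; shipped presets: ",
         "humsavar-2017, clinvar-submissions-2017, clinvar-summary-2017",
         call. = FALSE)
  )
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(data.frame())
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

# pull a logical field from the raw table; NA column if unmapped/absent
.field <- function(raw, dialect, field) {
  col <- dialect$columns[[field]]
  if (is.null(col) || !(col %in% names(raw))) {
    return(rep(NA_character_, nrow(raw)))
  }
  raw[[col]]
}

.check_required <- function(raw, dialect) {
  cols <- unlist(dialect$columns[dialect$required], use.names = FALSE)
  missing <- setdiff(cols, names(raw))
  if (length(missing)) {
    stop("configuration error: dialect ",
         sQuote(dialect$name %||% "custom"),
         " requires column(s) missing from the file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a curated-resource variant table
#'
#' Reads a humsavar-style tab-separated table into one record per row.
#' Malformed rows (unparseable protein change, unknown category label, no
#' usable identifier) are not dropped silently: they are collected into a
#' rejects table with a `reason` column, so that every input row appears
#' exactly once in either the records or the rejects.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param dialect Dialect name or list, see [io_dialect()].
#' @return A list of class `"parsed_table"` with elements `records`
#'   (data frame, one row per accepted variant x disease) and `rejects`
#'   (original columns plus `row` and `reason`).
#' @seealso [read_clinvar_table()], [write_uniprot_table()]
#' @export
read_uniprot_table <- function(path, dialect = "humsavar-2017") {
  dialect <- io_dialect(dialect)
  raw <- .read_tsv(path)
  if (nrow(raw) == 0L) return(.parsed_table(.empty_uniprot(), raw))
  .check_required(raw, dialect)

  pc <- .parse_protein_changes(.field(raw, dialect, "protein_change"))
  cls <- normalize_uniprot_label(.field(raw, dialect, "classification"),
                                 error = FALSE)
  rsid <- .normalize_rsid(.field(raw, dialect, "rsid"))
  rsid_given <- !is.na(rsid)
  rsid[!.valid_rsid(rsid)] <- NA_character_
  hgvs_c <- .normalize_hgvs(.field(raw, dialect, "hgvs_c"))
  acc <- trimws(.field(raw, dialect, "protein_accession"))
  hgvs_p <- ifelse(pc$ok, paste0("p.", pc$ref_aa, pc$position, pc$alt_aa),
                   NA_character_)

  pen <- .parse_fraction(.field(raw, dialect, "penetrance"))
  if (anyNA(pen)) {
    message(sum(is.na(pen)),
            " row(s) without penetrance; assuming full penetrance (1.0)")
    pen[is.na(pen)] <- 1
  }
  mend <- .parse_flag(.field(raw, dialect, "is_mendelian"), default = TRUE)

  records <- data.frame(
    gene_symbol = trimws(.field(raw, dialect, "gene_symbol")),
    protein_accession = acc,
    rsid = rsid, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    ref_aa = pc$ref_aa, position = pc$position, alt_aa = pc$alt_aa,
    uniprot_class = cls,
    disease_name = .field(raw, dialect, "disease_name"),
    omim_id = .field(raw, dialect, "omim_id"),
    inheritance = .normalize_inheritance(.field(raw, dialect, "inheritance")),
    prevalence = .parse_fraction(.field(raw, dialect, "prevalence")),
    penetrance = pen,
    carrier_frequency =
      .parse_fraction(.field(raw, dialect, "carrier_frequency")),
    is_mendelian = mend,
    source = "UNIPROT",
    stringsAsFactors = FALSE)

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(cls)] <- "unknown or missing variant category label"
  reason[!pc$ok] <- paste0("malformed protein change: ",
                           pc$reason[!pc$ok])
  no_identity <- is.na(rsid) & is.na(hgvs_c) &
    (is.na(hgvs_p) | is.na(acc) | acc == "")
  reason[is.na(reason) & no_identity] <-
    "no usable identifier (needs rsid, hgvs_c, or accession + protein change)"
  bad_rsid <- rsid_given & is.na(rsid)
  reason[is.na(reason) & bad_rsid] <- "malformed dbSNP identifier"

  keep <- is.na(reason)
  rejects <- cbind(row = which(!keep), raw[!keep, , drop = FALSE],
                   reason = reason[!keep])
  .parsed_table(records[keep, , drop = FALSE], rejects)
}

.empty_uniprot <- function() {
  data.frame(gene_symbol = character(), protein_accession = character(),
             rsid = character(), hgvs_c = character(), hgvs_p = character(),
             ref_aa = character(), position = integer(),
             alt_aa = character(), uniprot_class = character(),
             disease_name = character(), omim_id = character(),
             inheritance = character(), prevalence = numeric(),
             penetrance = numeric(), carrier_frequency = numeric(),
             is_mendelian = logical(), source = character(),
             stringsAsFactors = FALSE)
}

.parsed_table <- function(records, rejects) {
  rownames(records) <- NULL
  if (!is.null(rejects)) rownames(rejects) <- NULL
  structure(list(records = records, rejects = rejects),
            class = "parsed_table")
}

#' @export
print.parsed_table <- function(x, ...) {
  cat("<parsed_table> ", nrow(x$records), " record(s), ",
      NROW(x$rejects), " rejected row(s)\n", sep = "")
  invisible(x)
}

#' Compute a review-star status from submissions
#'
#' Implements the 0-4 star review-status scale of the clinical repository:
#' 4 stars for practice-guideline records, 3 for expert-panel records,
#' 2 for concordant interpretations by at least two submitters with
#' assertion criteria, 1 for at least one submitter with criteria, and
#' 0 otherwise.  Concordance for the 2-star level is judged at the
#' harmonized bucket level (pathogenic with likely pathogenic counts as
#' concordant), mirroring the equivalence classes used throughout the
#' concordance analysis.
#'
#' @param classifications Character vector of five-tier classifications
#'   (canonical tokens or synonyms), one per submission.
#' @param criteria_provided Logical vector: did the submission provide
#'   assertion criteria?
#' @param expert_panel,practice_guideline Record-level flags.
#' @param submitters Optional character vector of submitter names; when
#'   given, the 2-star rule counts distinct submitters.
#' @return Integer star status in `0:4`.
#' @examples
#' compute_review_status(c("Pathogenic", "Likely pathogenic"), c(TRUE, TRUE))
#' compute_review_status("Benign", FALSE)
#' @export
compute_review_status <- function(classifications, criteria_provided,
                                  expert_panel = FALSE,
                                  practice_guideline = FALSE,
                                  submitters = NULL) {
  if (isTRUE(practice_guideline)) return(4L)
  if (isTRUE(expert_panel)) return(3L)
  if (length(classifications) == 0L) return(0L)
  stopifnot(length(criteria_provided) == length(classifications))
  cls <- normalize_acmg_label(classifications)
  crit <- which(criteria_provided)
  if (length(crit) == 0L) return(0L)
  n_sub <- if (is.null(submitters)) length(crit) else
    length(unique(submitters[crit]))
  concordant <- length(unique(harmonize_class(cls[crit]))) == 1L
  if (n_sub >= 2L && concordant) 2L else 1L
}

# bucket-concordant submissions get the modal five-tier label; ties break
# toward the more severe tier; bucket-discordant records get NA
.aggregate_classification <- function(classifications) {
  if (length(classifications) == 0L) return(NA_character_)
  cls <- normalize_acmg_label(classifications)
  if (length(unique(harmonize_class(cls))) > 1L) return(NA_character_)
  tab <- table(factor(cls, levels = .acmg_severity))
  names(tab)[which.max(tab)]
}

#' Read a clinical-repository variant table
#'
#' Reads either a per-submission table (rows grouped by variant x condition,
#' review stars computed via [compute_review_status()]) or a pre-aggregated
#' table with an explicit review-status column.  Unknown classification
#' labels raise a parse error listing the accepted labels; rows with a
#' malformed protein change and no other identifier go to the rejects table.
#'
#' @inheritParams read_uniprot_table
#' @return A list of class `"parsed_table"`: `records` has one row per
#'   variant x condition with `review_stars`, `aggregate_class` (NA when the
#'   submissions disagree at bucket level), `n_submissions` and
#'   `n_criteria_submitters`; `rejects` as in [read_uniprot_table()].
#' @export
read_clinvar_table <- function(path, dialect = "clinvar-submissions-2017") {
  dialect <- io_dialect(dialect)
  raw <- .read_tsv(path)
  if (nrow(raw) == 0L) return(.parsed_table(.empty_clinvar(), raw))
  .check_required(raw, dialect)

  pc <- .parse_protein_changes(.field(raw, dialect, "protein_change"))
  rsid <- .normalize_rsid(.field(raw, dialect, "rsid"))
  rsid[!.valid_rsid(rsid)] <- NA_character_
  hgvs_c <- .normalize_hgvs(.field(raw, dialect, "hgvs_c"))
  acc <- trimws(.field(raw, dialect, "protein_accession"))
  hgvs_p <- ifelse(pc$ok, paste0("p.", pc$ref_aa, pc$position, pc$alt_aa),
                   NA_character_)
  # hard error on unknown labels (lists accepted labels)
  cls <- normalize_acmg_label(.field(raw, dialect, "classification"))
  condition <- trimws(.field(raw, dialect, "condition"))

  no_identity <- is.na(rsid) & is.na(hgvs_c) &
    (is.na(hgvs_p) | is.na(acc) | acc == "")
  reason <- rep(NA_character_, nrow(raw))
  reason[no_identity] <-
    "no usable identifier (needs rsid, hgvs_c, or accession + protein change)"
  keep <- is.na(reason)
  rejects <- cbind(row = which(!keep), raw[!keep, , drop = FALSE],
                   reason = reason[!keep])

  base <- data.frame(
    gene_symbol = trimws(.field(raw, dialect, "gene_symbol")),
    protein_accession = acc, rsid = rsid, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    ref_aa = pc$ref_aa, position = pc$position, alt_aa = pc$alt_aa,
    condition = condition, classification = cls,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  if (dialect$type == "clinvar_aggregate") {
    stars <- .parse_review_status(.field(raw, dialect, "review_status")[keep])
    records <- cbind(base[setdiff(names(base), "classification")],
                     data.frame(n_submissions = NA_integer_,
                                n_criteria_submitters = NA_integer_,
                                expert_panel = stars == 3L,
                                practice_guideline = stars == 4L,
                                review_stars = stars,
                                aggregate_class = base$classification,
                                source = "CLINVAR",
                                stringsAsFactors = FALSE))
    return(.parsed_table(records, rejects))
  }

  crit <- .parse_flag(.field(raw, dialect, "criteria_provided")[keep],
                      default = FALSE)
  panel <- .parse_flag(.field(raw, dialect, "expert_panel")[keep],
                       default = FALSE)
  guide <- .parse_flag(.field(raw, dialect, "practice_guideline")[keep],
                       default = FALSE)
  submitter <- trimws(.field(raw, dialect, "submitter")[keep])

  key <- paste(base$gene_symbol, base$protein_accession, base$rsid,
               base$hgvs_c, base$hgvs_p, base$condition, sep = "\r")
  groups <- split(seq_len(nrow(base)), factor(key, levels = unique(key)))
  records <- do.call(rbind, lapply(groups, function(i) {
    first <- i[1L]
    data.frame(
      base[first, setdiff(names(base), "classification"), drop = FALSE],
      n_submissions = length(i),
      n_criteria_submitters = length(unique(submitter[i][crit[i]])),
      expert_panel = any(panel[i]),
      practice_guideline = any(guide[i]),
      review_stars = compute_review_status(
        base$classification[i], crit[i],
        expert_panel = any(panel[i]),
        practice_guideline = any(guide[i]),
        submitters = submitter[i]),
      aggregate_class = .aggregate_classification(base$classification[i]),
      source = "CLINVAR",
      stringsAsFactors = FALSE)
  }))
  attr(records, "submissions") <- cbind(
    base[c("gene_symbol", "hgvs_p", "condition", "classification")],
    submitter = submitter, criteria_provided = crit)
  .parsed_table(records, rejects)
}

.empty_clinvar <- function() {
  data.frame(gene_symbol = character(), protein_accession = character(),
             rsid = character(), hgvs_c = character(), hgvs_p = character(),
             ref_aa = character(), position = integer(),
             alt_aa = character(), condition = character(),
             n_submissions = integer(), n_criteria_submitters = integer(),
             expert_panel = logical(), practice_guideline = logical(),
             review_stars = integer(), aggregate_class = character(),
             source = character(), stringsAsFactors = FALSE)
}

.parse_review_status <- function(x) {
  key <- .squash(x)
  out <- rep(NA_integer_, length(x))
  ints <- grepl("^[0-4]$", key)
  out[ints] <- as.integer(key[ints])
  map <- c("no assertion criteria provided" = 0L,
           "criteria provided, single submitter" = 1L,
           "criteria provided, conflicting interpretations" = 1L,
           "criteria provided, multiple submitters, no conflicts" = 2L,
           "reviewed by expert panel" = 3L,
           "practice guideline" = 4L)
  # the phrases contain commas; match on the squashed text
  phr <- match(gsub(",", "", key), gsub(",", "", .squash(names(map))))
  out[!ints & !is.na(phr)] <- unname(map[phr[!ints & !is.na(phr)]])
  if (anyNA(out)) {
    stop("unrecognized review status value(s): ",
         paste(sQuote(unique(x[is.na(out)])), collapse = ", "),
         "; expected an integer 0-4 or a standard status phrase",
         call. = FALSE)
  }
  out
}

#' Write variant tables
#'
#' Inverse of the readers: serializes a records data frame back to the
#' tab-separated dialect, so that a write-then-read round trip reproduces
#' the records.  `write_clinvar_table()` writes the pre-aggregated
#' (`"clinvar-summary-2017"`) dialect.
#'
#' @param records Records data frame (the `records` element of a
#'   [read_uniprot_table()] / [read_clinvar_table()] result).
#' @param path Output path.
#' @param dialect Dialect name or list.
#' @return The path, invisibly.
#' @export
write_uniprot_table <- function(records, path, dialect = "humsavar-2017") {
  dialect <- io_dialect(dialect)
  cols <- dialect$columns
  out <- data.frame(a = records$gene_symbol, stringsAsFactors = FALSE)
  names(out) <- cols$gene_symbol
  out[[cols$protein_accession]] <- records$protein_accession
  out[[cols$protein_change]] <- records$hgvs_p
  out[[cols$classification]] <- records$uniprot_class
  out[[cols$rsid]] <- records$rsid
  out[[cols$hgvs_c]] <- records$hgvs_c
  out[[cols$disease_name]] <- records$disease_name
  out[[cols$omim_id]] <- records$omim_id
  out[[cols$inheritance]] <- records$inheritance
  out[[cols$prevalence]] <- .fmt_num(records$prevalence)
  out[[cols$penetrance]] <- .fmt_num(records$penetrance)
  out[[cols$carrier_frequency]] <- .fmt_num(records$carrier_frequency)
  out[[cols$is_mendelian]] <- ifelse(records$is_mendelian, "yes", "no")
  .write_tsv(out, path)
  invisible(path)
}

#' @rdname write_uniprot_table
#' @export
write_clinvar_table <- function(records, path,
                                dialect = "clinvar-summary-2017") {
  dialect <- io_dialect(dialect)
  cols <- dialect$columns
  out <- data.frame(a = records$gene_symbol, stringsAsFactors = FALSE)
  names(out) <- cols$gene_symbol
  out[[cols$protein_accession]] <- records$protein_accession
  out[[cols$protein_change]] <- records$hgvs_p
  out[[cols$rsid]] <- records$rsid
  out[[cols$hgvs_c]] <- records$hgvs_c
  out[[cols$condition]] <- records$condition
  out[[cols$classification]] <- records$aggregate_class
  out[[cols$review_status]] <- records$review_stars
  .write_tsv(out, path)
  invisible(path)
}

.fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                               format(x, scientific = FALSE, trim = TRUE,
                                      digits = 15))

#' Write a rejects report
#'
#' @param parsed A `"parsed_table"` result.
#' @param path Output path for the tab-separated rejects report (original
#'   columns plus `row` and `reason`).
#' @return The path, invisibly.
#' @export
write_rejects_report <- function(parsed, path) {
  stopifnot(inherits(parsed, "parsed_table"))
  .write_tsv(parsed$rejects, path)
  invisible(path)
}
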