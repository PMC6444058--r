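#' Harmonize five-tier classes to three-class buckets
#'
#' The two resources are compared on the three-class scale: `PATHOGENIC`
#' and `LIKELY_PATHOGENIC` map to `DISEASE`, `BENIGN` and `LIKELY_BENIGN`
#' map to `POLYMORPHISM`, and `VUS` maps to `UNCLASSIFIED`.  Inputs already
#' on the three-class scale pass through unchanged, so the function is
#' total over both vocabularies.
#'
#' @param x Character vector of five-tier (or three-class) tokens;
#'   synonyms accepted as in [normalize_acmg_label()].
#' @return Character vector of [uniprot_classes()] tokens.
#' @examples
#' harmonize_class(c("LIKELY_BENIGN", "VUS", "Pathogenic"))
#' @export
harmonize_class <- function(x) {
  out <- rep(NA_character_, length(x))
  idx <- x %in% uniprot_classes()
  out[idx] <- x[idx]
  five <- normalize_acmg_label(x[!idx])
  map <- c(PATHOGENIC = "DISEASE", LIKELY_PATHOGENIC = "DISEASE",
           BENIGN = "POLYMORPHISM", LIKELY_BENIGN = "POLYMORPHISM",
           VUS = "UNCLASSIFIED")
  out[!idx] <- unname(map[five])
  out
}

#' Construct or validate a 3x3 contingency table
#'
#' @param counts 3x3 numeric matrix of non-negative counts, rows indexed by
#'   the original (curated-resource) bucket and columns by the harmonized
#'   comparison bucket.  Unnamed dimensions are assumed to follow the
#'   [uniprot_classes()] order; named dimensions are reordered.
#' @return An integer matrix of class `"contingency_table"`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("contingency table must be 3x3", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("contingency table cells must be non-negative integers",
         call. = FALSE)
  }
  buckets <- uniprot_classes()
  if (!is.null(rownames(counts)) && setequal(rownames(counts), buckets)) {
    counts <- counts[buckets, , drop = FALSE]
  }
  if (!is.null(colnames(counts)) && setequal(colnames(counts), buckets)) {
    counts <- counts[, buckets, drop = FALSE]
  }
  dimnames(counts) <- list(original = buckets, comparison = buckets)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Cross-classify matched pairs into a contingency table
#'
#' Cell (i, j) counts the matched pairs whose curated-resource bucket is i
#' and whose harmonized clinical-repository bucket is j; the grand total is
#' the number of pairs.  A pair missing either classification raises an
#' error naming the pair.
#'
#' @param pairs A `"matched_pairs"` / `"filtered_pairs"` object or a data
#'   frame with columns `uniprot_class` and `aggregate_class`.
#' @return A `"contingency_table"`.
#' @export
build_contingency <- function(pairs) {
  if (inherits(pairs, "filtered_pairs")) pairs <- pairs$pairs
  pairs <- as.data.frame(pairs)
  miss <- is.na(pairs$uniprot_class) | is.na(pairs$aggregate_class)
  if (any(miss)) {
    lab <- paste(pairs$gene_symbol[miss], pairs$hgvs_p[miss],
                 pairs$condition[miss], sep = ":")
    stop("pair(s) missing a classification: ",
         paste(utils::head(lab, 5L), collapse = "; "),
         if (sum(miss) > 5L) " ...", call. = FALSE)
  }
  buckets <- uniprot_classes()
  tab <- table(factor(pairs$uniprot_class, levels = buckets),
               factor(harmonize_class(pairs$aggregate_class),
                      levels = buckets))
  contingency_table(unclass(tab))
}

#' Per-category concordance
#'
#' For one bucket, concordance is the number of interpretations common to
#' both resources divided by the number of interpretations in either
#' resource, times 100: `100 * d / (row_total + col_total - d)` where `d`
#' is the bucket's diagonal cell.  An empty union (both marginals zero) is
#' undefined and raises an error.  The value is returned unrounded;
#' [round_half_up()] gives the printed integer percentage.
#'
#' @param t A `"contingency_table"` (or plain 3x3 matrix).
#' @param bucket One of [uniprot_classes()].
#' @return Unrounded percentage.
#' @examples
#' t1 <- contingency_table(rbind(c(1328, 111, 94),
#'                               c(46, 2328, 128),
#'                               c(55, 81, 115)))
#' category_concordance(t1, "POLYMORPHISM")   # 86.41...
#' @export
category_concordance <- function(t, bucket) {
  t <- contingency_table(t)
  bucket <- match.arg(bucket, uniprot_classes())
  d <- t[bucket, bucket]
  union <- sum(t[bucket, ]) + sum(t[, bucket]) - d
  if (union == 0) {
    stop("concordance undefined for bucket ", bucket,
         ": no interpretations in either resource", call. = FALSE)
  }
  100 * d / union
}

#' Overall concordance report
#'
#' Overall concordance is 100 times the trace of the contingency table
#' divided by its grand total; per-category concordances use the
#' union-denominator formula of [category_concordance()] (categories with
#' an empty union are reported as `NA`).
#'
#' @param t A `"contingency_table"` (or plain 3x3 matrix).
#' @return A list of class `"concordance_report"` with `n_total`,
#'   `n_agree`, `overall` and `per_category` (all percentages unrounded).
#' @export
overall_concordance <- function(t) {
  t <- contingency_table(t)
  n_total <- sum(t)
  if (n_total == 0) stop("empty contingency table", call. = FALSE)
  n_agree <- sum(diag(t))
  per <- vapply(uniprot_classes(), function(b) {
    union <- sum(t[b, ]) + sum(t[, b]) - t[b, b]
    if (union == 0) NA_real_ else 100 * t[b, b] / union
  }, numeric(1))
  structure(list(n_total = n_total, n_agree = n_agree,
                 overall = 100 * n_agree / n_total, per_category = per),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_agree, " of ", x$n_total,
      " interpretations agree (", round_half_up(x$overall), "%)\n",
      sep = "")
  for (b in names(x$per_category)) {
    cat(sprintf("  %-13s %s%%\n", tolower(b),
                ifelse(is.na(x$per_category[[b]]), "NA",
                       round_half_up(x$per_category[[b]]))))
  }
  invisible(x)
}

#' Build a re-curation transition table
#'
#' Cross-classifies each variant's original bucket against its bucket
#' after re-curation.  Five-tier re-curated classes are harmonized to
#' buckets.  Both inputs must carry the same identities: an identity
#' present on one side only raises an error naming it.
#'
#' @param before,after Data frames with an identity column (`id_col`) and a
#'   class column: `bucket`, `uniprot_class` or (five-tier) `acmg_class`,
#'   looked up in that order.
#' @param id_col Name of the shared identity column (default
#'   `"variant_id"`).
#' @return A `"contingency_table"` with rows = original bucket, columns =
#'   re-curated bucket.
#' @export
build_transition <- function(before, after, id_col = "variant_id") {
  b_id <- before[[id_col]]
  a_id <- after[[id_col]]
  if (anyDuplicated(b_id) || anyDuplicated(a_id)) {
    stop("duplicate identities in transition input", call. = FALSE)
  }
  lost <- c(setdiff(b_id, a_id), setdiff(a_id, b_id))
  if (length(lost)) {
    stop("unmatched identit(ies) between before and after sets: ",
         paste(utils::head(lost, 5L), collapse = ", "),
         if (length(lost) > 5L) " ...", call. = FALSE)
  }
  buckets <- uniprot_classes()
  bb <- .bucket_col(before)
  aa <- .bucket_col(after)[match(b_id, a_id)]
  tab <- table(factor(bb, levels = buckets), factor(aa, levels = buckets))
  contingency_table(unclass(tab))
}

.bucket_col <- function(df) {
  for (col in c("bucket", "uniprot_class", "acmg_class")) {
    if (!is.null(df[[col]])) return(harmonize_class(df[[col]]))
  }
  stop("no class column found (expected bucket, uniprot_class or acmg_class)",
       call. = FALSE)
}

#' Project concordance after full re-curation
#'
#' Combines the observed agreement rate `a = trace / total` of a
#' contingency table with the outcome rates measured on the re-curated
#' samples: the fraction of concordant interpretations confirmed on
#' re-curation (`retained_rate`) and the fraction of discordant
#' interpretations whose conflict was solved (`resolved_rate`).  The
#' projected agreement is `100 * (a * retained_rate +
#' (1 - a) * resolved_rate)`, an estimate of the concordance to be
#' expected once every shared variant has been re-curated.
#'
#' @param t A `"contingency_table"` (or plain 3x3 matrix).
#' @param retained_rate,resolved_rate Fractions in `[0, 1]`.
#' @return Unrounded projected percentage.
#' @export
project_concordance <- function(t, retained_rate, resolved_rate) {
  t <- contingency_table(t)
  stopifnot(retained_rate >= 0, retained_rate <= 1,
            resolved_rate >= 0, resolved_rate <= 1)
  a <- sum(diag(t)) / sum(t)
  100 * (a * retained_rate + (1 - a) * resolved_rate)
}

# fixture-format helpers ---------------------------------------------------

#' Read / write a contingency table fixture
#'
#' The text format is tab-separated with a leading row-label column; column
#' labels may be bucket tokens or the conventional five-tier pairs
#' (`P_LP`, `B_LB`, `VUS`).  `Total` rows/columns, if present, are dropped
#' and the remaining cells revalidated.
#'
#' @param path Path to the tab-separated table.
#' @return A `"contingency_table"`.
#' @export
read_contingency <- function(path) {
  raw <- .read_tsv(path)
  labels <- toupper(trimws(raw[[1L]]))
  keep_r <- labels != "TOTAL"
  mat <- as.matrix(raw[keep_r, -1L, drop = FALSE])
  cn <- toupper(trimws(colnames(mat)))
  keep_c <- cn != "TOTAL"
  mat <- mat[, keep_c, drop = FALSE]
  cn <- cn[keep_c]
  storage.mode(mat) <- "numeric"
  colmap <- c(P_LP = "DISEASE", `P/LP` = "DISEASE", DISEASE = "DISEASE",
              B_LB = "POLYMORPHISM", `B/LB` = "POLYMORPHISM",
              POLYMORPHISM = "POLYMORPHISM",
              VUS = "UNCLASSIFIED", UNCLASSIFIED = "UNCLASSIFIED")
  if (!all(cn %in% names(colmap)) || !all(labels[keep_r] %in% colmap)) {
    stop("unrecognized contingency table labels in ", path, call. = FALSE)
  }
  rownames(mat) <- unname(colmap[labels[keep_r]])
  colnames(mat) <- unname(colmap[cn])
  contingency_table(mat)
}

#' @rdname read_contingency
#' @param t A `"contingency_table"`.
#' @export
write_contingency <- function(t, path) {
  t <- contingency_table(t)
  df <- data.frame(bucket = rownames(t), unclass(t), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Expand a contingency table into matched-pair records
#'
#' Deterministically materializes one synthetic matched pair per counted
#' interpretation: cell (i, j) with count n yields n pairs whose curated
#' bucket is i and whose harmonized repository class is the representative
#' five-tier label of j.  Running [build_contingency()] on the result
#' recovers the input table exactly, which makes printed count tables
#' usable as pipeline inputs.
#'
#' @param t A `"contingency_table"` (or plain 3x3 matrix).
#' @return A `"matched_pairs"` data frame of `sum(t)` rows.
#' @export
expand_contingency_pairs <- function(t) {
  t <- contingency_table(t)
  rep5 <- c(DISEASE = "PATHOGENIC", POLYMORPHISM = "BENIGN",
            UNCLASSIFIED = "VUS")
  rows <- list()
  k <- 0L
  for (i in rownames(t)) {
    for (j in colnames(t)) {
      n <- t[i, j]
      if (n == 0L) next
      idx <- k + seq_len(n)
      rows[[paste(i, j)]] <- data.frame(
        uniprot_row = idx, clinvar_row = idx,
        match_key = "RSID", ambiguous = FALSE,
        gene_symbol = sprintf("GENE%05d", idx),
        protein_accession = sprintf("P%05d", idx),
        hgvs_p = "p.Ala2Val", rsid = sprintf("rs9%08d", idx),
        ref_aa = "Ala", position = 2L, alt_aa = "Val",
        uniprot_class = i,
        disease_name = sprintf("Synthetic disorder %05d", idx),
        is_mendelian = TRUE,
        condition = sprintf("Synthetic disorder %05d", idx),
        aggregate_class = rep5[[j]], review_stars = 2L,
        is_missense = TRUE, stringsAsFactors = FALSE)
      k <- k + n
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("matched_pairs", class(out))
  out
}
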