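#' Classification vocabularies
#'
#' The curated protein resource uses a three-class scheme
#' (disease / polymorphism / unclassified); the clinical repository uses the
#' five-tier ACMG-AMP scheme (pathogenic, likely pathogenic, uncertain
#' significance, likely benign, benign).  All package functions exchange the
#' upper-case tokens returned by these accessors.
#'
#' @return Character vector of the canonical class tokens.
#' @examples
#' uniprot_classes()
#' acmg_classes()
#' @export
uniprot_classes <- function() c("DISEASE", "POLYMORPHISM", "UNCLASSIFIED")

#' @rdname uniprot_classes
#' @export
acmg_classes <- function() {
  c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS", "LIKELY_BENIGN", "BENIGN")
}

#' @rdname uniprot_classes
#' @export
inheritance_modes <- function() {
  c("AUTOSOMAL_DOMINANT", "AUTOSOMAL_RECESSIVE", "X_LINKED")
}

#' @rdname uniprot_classes
#' @export
evidence_strengths <- function() {
  c("SUPPORTING", "MODERATE", "STRONG", "VERY_STRONG", "STAND_ALONE")
}

# severity order used for deterministic tie-breaks (most severe first)
.acmg_severity <- c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                    "LIKELY_BENIGN", "BENIGN")

.squash <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ _\\-]+", " ", x)
}

.acmg_synonyms <- c(
  "pathogenic"                        = "PATHOGENIC",
  "p"                                 = "PATHOGENIC",
  "likely pathogenic"                 = "LIKELY_PATHOGENIC",
  "lp"                                = "LIKELY_PATHOGENIC",
  "benign"                            = "BENIGN",
  "b"                                 = "BENIGN",
  "likely benign"                     = "LIKELY_BENIGN",
  "lb"                                = "LIKELY_BENIGN",
  "uncertain significance"            = "VUS",
  "of uncertain significance"         = "VUS",
  "variant of uncertain significance" = "VUS",
  "uncertain"                         = "VUS",
  "vus"                               = "VUS"
)

.uniprot_synonyms <- c(
  "disease"         = "DISEASE",
  "disease causing" = "DISEASE",
  "polymorphism"    = "POLYMORPHISM",
  "unclassified"    = "UNCLASSIFIED"
)

#' Normalize classification labels
#'
#' Maps free-text classification labels (case- and punctuation-insensitive
#' synonyms such as `"Likely benign"`, `"likely_benign"` or `"LB"`) onto the
#' canonical tokens of [acmg_classes()] / [uniprot_classes()].
#'
#' @param x Character vector of labels.
#' @param error If `TRUE` (default) an unknown label raises an error listing
#'   the accepted labels; otherwise it becomes `NA`.
#' @return Character vector of canonical tokens.
#' @examples
#' normalize_acmg_label(c("Likely benign", "PATHOGENIC", "vus"))
#' normalize_uniprot_label("Disease")
#' @export
normalize_acmg_label <- function(x, error = TRUE) {
  key <- .squash(x)
  # canonical tokens themselves are accepted in any case
  key[key == "likely pathogenic"] <- "likely pathogenic"
  out <- unname(.acmg_synonyms[key])
  bad <- !is.na(x) & x != "" & is.na(out)
  if (error && any(bad)) {
    stop("unknown classification label(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         "; accepted labels (case-insensitive): ",
         paste(unique(names(.acmg_synonyms)), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname normalize_acmg_label
#' @export
normalize_uniprot_label <- function(x, error = TRUE) {
  out <- unname(.uniprot_synonyms[.squash(x)])
  bad <- !is.na(x) & x != "" & is.na(out)
  if (error && any(bad)) {
    stop("unknown variant category label(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         "; accepted labels (case-insensitive): ",
         paste(unique(names(.uniprot_synonyms)), collapse = ", "),
         call. = FALSE)
  }
  out
}

.normalize_inheritance <- function(x) {
  key <- .squash(x)
  map <- c("ad" = "AUTOSOMAL_DOMINANT",
           "autosomal dominant" = "AUTOSOMAL_DOMINANT",
           "dominant" = "AUTOSOMAL_DOMINANT",
           "ar" = "AUTOSOMAL_RECESSIVE",
           "autosomal recessive" = "AUTOSOMAL_RECESSIVE",
           "recessive" = "AUTOSOMAL_RECESSIVE",
           "xl" = "X_LINKED",
           "x linked" = "X_LINKED")
  unname(map[key])
}

.parse_flag <- function(x, default = NA) {
  key <- .squash(x)
  out <- rep(default, length(x))
  out[key %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[key %in% c("no", "n", "false", "f", "0")] <- FALSE
  as.logical(out)
}

# accepts "0.0005", "5e-4" and ratio notation "1/90"
.parse_fraction <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  ratio <- grepl("^[0-9.eE+-]+\\s*/\\s*[0-9.eE+-]+$", x)
  out[ratio] <- vapply(strsplit(x[ratio], "/"), function(p) {
    as.numeric(p[1]) / as.numeric(p[2])
  }, numeric(1))
  plain <- !ratio & grepl("^[0-9.eE+-]+$", x)
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  out
}

#' Describe a disease model
#'
#' Bundles the disease-level quantities that drive allele-frequency evidence:
#' inheritance mode, population prevalence, penetrance and (for recessive
#' conditions) the carrier frequency, plus the flag marking the disorder as
#' Mendelian (non-Mendelian, multifactorial disorders are excluded from the
#' concordance study filters and from ACMG classification).
#'
#' @param name Disease name.
#' @param inheritance One of [inheritance_modes()] (synonyms such as `"AD"`
#'   are accepted).
#' @param omim_id Optional OMIM accession.
#' @param prevalence Optional disease prevalence in `(0, 1]`; ratio strings
#'   such as `"1/30000"` are accepted.
#' @param penetrance Penetrance in `(0, 1]`.  When missing it defaults to
#'   1 (full penetrance) with a message.
#' @param carrier_frequency Optional carrier frequency (recessive diseases).
#' @param is_mendelian Logical, default `TRUE`.
#' @return A list of class `"disease_model"`.
#' @examples
#' disease_model("Greig cephalopolysyndactyly syndrome", "AD",
#'               omim_id = "175700", prevalence = 1e-6, penetrance = 0.9)
#' @export
disease_model <- function(name, inheritance, omim_id = NA_character_,
                          prevalence = NA_real_, penetrance = NA_real_,
                          carrier_frequency = NA_real_, is_mendelian = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  inh <- .normalize_inheritance(inheritance)
  if (is.na(inh)) {
    stop("unknown inheritance mode ", sQuote(inheritance),
         "; expected one of ", paste(inheritance_modes(), collapse = ", "),
         call. = FALSE)
  }
  if (is.character(prevalence)) prevalence <- .parse_fraction(prevalence)
  if (is.character(carrier_frequency)) {
    carrier_frequency <- .parse_fraction(carrier_frequency)
  }
  if (is.na(penetrance)) {
    message("penetrance not given for ", sQuote(name),
            "; assuming full penetrance (1.0)")
    penetrance <- 1
  }
  if (!is.na(prevalence) && (prevalence <= 0 || prevalence > 1)) {
    stop("prevalence must lie in (0, 1]", call. = FALSE)
  }
  if (penetrance <= 0 || penetrance > 1) {
    stop("penetrance must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, omim_id = omim_id, inheritance = inh,
                 prevalence = prevalence, penetrance = penetrance,
                 carrier_frequency = carrier_frequency,
                 is_mendelian = isTRUE(is_mendelian)),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("<disease_model> ", x$name,
      if (!is.na(x$omim_id)) paste0(" (OMIM ", x$omim_id, ")"), "\n",
      "  inheritance: ", x$inheritance,
      "  mendelian: ", x$is_mendelian, "\n", sep = "")
  cat(sprintf("  prevalence: %s  penetrance: %g  carrier frequency: %s\n",
              format(x$prevalence), x$penetrance, format(x$carrier_frequency)))
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used throughout the package for printed percentages
#' (base `round()` rounds half to even, which does not match the usual
#' "half up" convention for reported integer percentages).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(86.41, 24.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * trunc(abs(x) * f + 0.5) / f
}
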