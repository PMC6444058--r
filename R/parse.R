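# three-letter codes of the 20 standard amino acids
.aa3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

#' Parse an HGVS-style protein change
#'
#' Parses a protein-level substitution token of the form `p.<Ref><Pos><Alt>`
#' with three-letter amino-acid codes, e.g. `"p.Ile808Met"`.  Only missense
#' substitutions are accepted: synonymous tokens (identical reference and
#' alternate residues) and anything not matching the pattern raise a parse
#' error naming the offending token.
#'
#' @param token Character scalar, e.g. `"p.Ile808Met"`.
#' @return A list of class `"protein_change"` with fields `ref_aa`,
#'   `position`, `alt_aa`.  `format()` recovers the original token.
#' @examples
#' pc <- parse_protein_change("p.Ile808Met")
#' pc$position
#' format(pc)
#' @export
parse_protein_change <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  parsed <- .parse_protein_changes(token)
  if (!parsed$ok) {
    stop("malformed protein change token ", sQuote(token), ": ",
         parsed$reason, call. = FALSE)
  }
  structure(list(ref_aa = parsed$ref_aa, position = parsed$position,
                 alt_aa = parsed$alt_aa),
            class = "protein_change")
}

#' @rdname parse_protein_change
#' @param x A `"protein_change"` object.
#' @param ... Unused.
#' @export
format.protein_change <- function(x, ...) {
  paste0("p.", x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change>", format(x), "\n")
  invisible(x)
}

# vectorized worker shared with the table readers; never throws
.parse_protein_changes <- function(tokens) {
  tokens <- trimws(tokens)
  n <- length(tokens)
  out <- data.frame(ref_aa = NA_character_, position = NA_integer_,
                    alt_aa = NA_character_, ok = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  pat <- "^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$"
  hit <- !is.na(tokens) & grepl(pat, tokens)
  out$reason[!hit] <- "expected p.<Ref><Pos><Alt> with 3-letter codes"
  if (any(hit)) {
    out$ref_aa[hit] <- sub(pat, "\\1", tokens[hit])
    out$position[hit] <- as.integer(sub(pat, "\\2", tokens[hit]))
    out$alt_aa[hit] <- sub(pat, "\\3", tokens[hit])
  }
  bad_aa <- hit & (!(out$ref_aa %in% .aa3) | !(out$alt_aa %in% .aa3))
  out$reason[bad_aa] <- "unknown amino-acid code"
  syn <- hit & !bad_aa & out$ref_aa == out$alt_aa
  out$reason[syn] <- "not a missense substitution (ref == alt)"
  zero <- hit & !bad_aa & !syn & out$position < 1L
  out$reason[zero] <- "position must be >= 1"
  out$ok <- hit & !bad_aa & !syn & !zero
  out
}

# normalized identity keys -------------------------------------------------

.normalize_rsid <- function(x) {
  x <- tolower(trimws(x))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

.valid_rsid <- function(x) !is.na(x) & grepl("^rs[0-9]+$", x)

# HGVS comparison is exact-string after removing whitespace; transcript
# versions are significant (a versioned mismatch is no match)
.normalize_hgvs <- function(x) {
  x <- gsub("[[:space:]]+", "", x)
  x[is.na(x) | x == ""] <- NA_character_
  x
}
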