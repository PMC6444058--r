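#' Maximum credible population allele frequency
#'
#' The highest population allele frequency compatible with the variant
#' causing a disease of the given prevalence:
#' `prevalence * allelic_heterogeneity * genotypic_contribution /
#' penetrance`.  For autosomal-dominant diseases the default genotypic
#' contribution is 1/2 (one of the two alleles of a heterozygote).  For
#' recessive diseases with a known carrier frequency, frequency evidence
#' compares against the carrier allele frequency directly (see
#' [frequency_evidence()]); the prevalence-derived product returned here is
#' then interpreted on the carrier-allele scale.
#'
#' @param d A [disease_model()].
#' @param allelic_heterogeneity Fraction of the disease's pathogenic
#'   alleles attributable to this variant, in `(0, 1]` (default 1).
#' @param genotypic_contribution Fraction in `(0, 1]`; default 1/2 for
#'   autosomal-dominant inheritance, 1 otherwise.
#' @return The threshold frequency, or `NA_real_` (with a message) when
#'   the disease model has no prevalence — callers must then not fire
#'   BS1/BA1 from a prevalence-derived threshold.
#' @examples
#' gcps <- disease_model("GCPS", "AD", prevalence = 1e-6, penetrance = 1)
#' max_credible_af(gcps)   # 5e-7
#' @export
max_credible_af <- function(d, allelic_heterogeneity = 1,
                            genotypic_contribution = NULL) {
  stopifnot(inherits(d, "disease_model"))
  if (is.na(d$prevalence)) {
    message("max_credible_af: no prevalence for ", sQuote(d$name),
            "; frequency threshold unavailable")
    return(NA_real_)
  }
  if (is.null(genotypic_contribution)) {
    genotypic_contribution <-
      if (d$inheritance == "AUTOSOMAL_DOMINANT") 0.5 else 1
  }
  stopifnot(allelic_heterogeneity > 0, allelic_heterogeneity <= 1,
            genotypic_contribution > 0, genotypic_contribution <= 1)
  d$prevalence * allelic_heterogeneity * genotypic_contribution /
    d$penetrance
}

#' Create a population observation
#'
#' @param dataset Dataset label, e.g. `"ExAC r0.3"`.
#' @param allele_frequency Observed allele frequency in `[0, 1]`.
#' @param allele_count Optional allele count.
#' @param homozygote_count Homozygote count (default 0); must not exceed
#'   the allele count.
#' @param healthy_adult_observed Was the variant observed in a healthy
#'   adult in the state relevant to the inheritance pattern (homozygous
#'   for recessive, heterozygous for dominant, hemizygous for X-linked)?
#' @return One-row data frame; rows `rbind()` into an observation set.
#' @export
population_observation <- function(dataset, allele_frequency,
                                   allele_count = NA_integer_,
                                   homozygote_count = 0L,
                                   healthy_adult_observed = FALSE) {
  stopifnot(allele_frequency >= 0, allele_frequency <= 1)
  if (!is.na(allele_count) && homozygote_count > allele_count) {
    stop("homozygote_count cannot exceed allele_count", call. = FALSE)
  }
  data.frame(dataset = dataset, allele_frequency = allele_frequency,
             allele_count = allele_count,
             homozygote_count = homozygote_count,
             healthy_adult_observed = healthy_adult_observed,
             stringsAsFactors = FALSE)
}

#' Derive frequency-based evidence
#'
#' Turns population observations plus a disease model into ACMG-AMP
#' frequency criteria, using the maximum observed allele frequency across
#' datasets:
#'
#' * `BA1` (stand-alone benign) when the frequency exceeds the stand-alone
#'   cutoff (default 5%).
#' * `BS1` ("allele frequency is greater than expected for disorder") when
#'   the frequency exceeds the disease-specific threshold: the supplied
#'   `threshold`, else the carrier allele frequency
#'   (`carrier_frequency / 2`) for recessive diseases with a known carrier
#'   frequency, else [max_credible_af()] from the prevalence.
#' * `BS2` when the variant was observed in a healthy adult in the state
#'   relevant to the inheritance pattern.
#' * `PM2` ("absent from controls, or at extremely low frequency if
#'   recessive") when the frequency is below the extremely-low cutoff
#'   (the carrier-scale threshold for recessive diseases with a known
#'   carrier frequency, else `pm2_cutoff`), does not exceed the BS1
#'   threshold, and — for recessive diseases — no homozygote is reported.
#'
#' `BS1` and `PM2` are mutually exclusive by construction.  When no
#' threshold can be derived (no prevalence, no carrier frequency) only the
#' BA1/PM2 logic is active and a message is logged.
#'
#' @param obs Observation set (rows from [population_observation()]).
#' @param d A [disease_model()].
#' @param threshold Optional explicit frequency threshold overriding the
#'   derived one.
#' @param ba1_cutoff Stand-alone benign cutoff (default 0.05).
#' @param pm2_cutoff "Extremely low" frequency cutoff used when no
#'   carrier-scale threshold applies (default 1e-4).
#' @return Evidence data frame (possibly 0 rows) for
#'   [combine_evidence()].
#' @export
frequency_evidence <- function(obs, d, threshold = NULL, ba1_cutoff = 0.05,
                               pm2_cutoff = 1e-4) {
  stopifnot(is.data.frame(obs), nrow(obs) >= 1L,
            inherits(d, "disease_model"))
  bad <- !is.na(obs$allele_count) &
    obs$homozygote_count > obs$allele_count
  if (any(bad)) stop("homozygote_count exceeds allele_count", call. = FALSE)
  imax <- which.max(obs$allele_frequency)
  fmax <- obs$allele_frequency[imax]
  where <- obs$dataset[imax]
  recessive <- d$inheritance == "AUTOSOMAL_RECESSIVE"
  carrier_scale <- recessive && !is.na(d$carrier_frequency)
  if (is.null(threshold)) {
    threshold <- if (carrier_scale) d$carrier_frequency / 2 else
      suppressMessages(max_credible_af(d))
  }
  if (is.na(threshold)) {
    message("frequency_evidence: no frequency threshold derivable for ",
            sQuote(d$name), "; only BA1/PM2 logic active")
  }

  ev <- list()
  if (fmax > ba1_cutoff) {
    ev$ba1 <- evidence_assignment(
      "BA1", justification = sprintf(
        "allele frequency %.3g in %s exceeds the %.3g stand-alone cutoff",
        fmax, where, ba1_cutoff),
      source = where)
  } else if (!is.na(threshold) && fmax > threshold) {
    ev$bs1 <- evidence_assignment(
      "BS1", justification = sprintf(
        "allele frequency %.3g in %s is greater than expected for %s (threshold %.3g)",
        fmax, where, d$name, threshold),
      source = where)
  }
  if (any(obs$healthy_adult_observed)) {
    state <- switch(d$inheritance,
                    AUTOSOMAL_RECESSIVE = "homozygous",
                    AUTOSOMAL_DOMINANT = "heterozygous",
                    X_LINKED = "hemizygous")
    ev$bs2 <- evidence_assignment(
      "BS2", justification = paste0(
        "observed ", state, " in a healthy adult individual"),
      source = paste(unique(obs$dataset[obs$healthy_adult_observed]),
                     collapse = ", "))
  }
  low_cut <- if (carrier_scale) d$carrier_frequency / 2 else pm2_cutoff
  hom_total <- sum(obs$homozygote_count, na.rm = TRUE)
  if (fmax < low_cut && (is.na(threshold) || fmax <= threshold) &&
      (!recessive || hom_total == 0L) && is.null(ev$ba1) &&
      is.null(ev$bs1)) {
    ev$pm2 <- evidence_assignment(
      "PM2", justification = sprintf(
        "allele frequency %.3g in %s is below the extremely-low cutoff %.3g%s",
        fmax, where, low_cut,
        if (recessive) " and no homozygote is reported" else ""),
      source = paste(unique(obs$dataset), collapse = ", "))
  }
  if (length(ev)) do.call(rbind, unname(ev)) else
    evidence_assignment("PM2")[0L, ]
}

#' Computational predictor consensus
#'
#' Computational evidence is taken into account only when the three
#' predictors agree: all deleterious yields PP3 (supporting pathogenic),
#' all tolerated yields BP4 (supporting benign); any disagreement or
#' unknown verdict yields no evidence.
#'
#' @param polyphen,sift,mutation_taster Verdicts: `"DELETERIOUS"`,
#'   `"TOLERATED"` or `"UNKNOWN"` (synonyms `"damaging"`, `"benign"`
#'   accepted, case-insensitive).
#' @return A one-row evidence data frame, or `NULL` when discordant.
#' @examples
#' computational_consensus("deleterious", "deleterious", "deleterious")
#' @export
computational_consensus <- function(polyphen, sift, mutation_taster) {
  norm <- function(x) {
    key <- .squash(x)
    map <- c(deleterious = "DELETERIOUS", damaging = "DELETERIOUS",
             "probably damaging" = "DELETERIOUS",
             tolerated = "TOLERATED", benign = "TOLERATED",
             neutral = "TOLERATED", unknown = "UNKNOWN")
    out <- unname(map[key])
    if (is.na(out)) stop("unknown predictor verdict ", sQuote(x),
                         call. = FALSE)
    out
  }
  v <- vapply(list(polyphen, sift, mutation_taster), norm, character(1))
  if (all(v == "DELETERIOUS")) {
    evidence_assignment("PP3", justification =
      "PolyPhen, SIFT and MutationTaster concordantly predict a deleterious effect")
  } else if (all(v == "TOLERATED")) {
    evidence_assignment("BP4", justification =
      "PolyPhen, SIFT and MutationTaster concordantly predict a tolerated change")
  } else {
    NULL
  }
}

#' Functional-assay evidence
#'
#' Well-established functional studies yield PS3 (damaging effect) or BS3
#' (no damaging effect) — but only when the assay reflects the biological
#' environment of the disease.  Evidence from assays without a clear
#' mechanistic link to the disease, or with equivocal results, is
#' disregarded (with a message).
#'
#' @param assay_effect `"DAMAGING"`, `"NO_EFFECT"` or `"EQUIVOCAL"`.
#' @param assay_reflects_biology Does the assay reflect the biological
#'   environment relevant to the disease?
#' @param source Citation for the assay.
#' @return A one-row evidence data frame, or `NULL` when disregarded.
#' @export
functional_evidence <- function(assay_effect, assay_reflects_biology,
                                source = "") {
  effect <- toupper(gsub("[ \\-]+", "_", trimws(assay_effect)))
  if (!effect %in% c("DAMAGING", "NO_EFFECT", "EQUIVOCAL")) {
    stop("unknown assay effect ", sQuote(assay_effect), call. = FALSE)
  }
  if (!isTRUE(assay_reflects_biology) || effect == "EQUIVOCAL") {
    message("functional_evidence: assay disregarded (",
            if (!isTRUE(assay_reflects_biology))
              "does not reflect the biological environment" else
              "equivocal result", ")")
    return(NULL)
  }
  if (effect == "DAMAGING") {
    evidence_assignment("PS3", justification =
      "well-established functional studies show a damaging effect",
      source = source)
  } else {
    evidence_assignment("BS3", justification =
      "well-established functional studies show no damaging effect",
      source = source)
  }
}
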