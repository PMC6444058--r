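#' Synthetic-study generator configuration
#'
#' Describes a synthetic paired-resource study with known ground truth.
#' The defaults reproduce the statistical structure of the global
#' comparison of the two resources: bucket mixture proportional to the
#' curated-resource marginals (1533 / 2502 / 251 of 4286), overall
#' concordance 0.88, and a discordance kernel proportional to the
#' off-diagonal structure of the observed contingency table.  The star
#' distribution and Mendelian fraction are not constrained by the
#' comparison (which conditions on 2-star Mendelian records); their
#' defaults are chosen to exercise every filter.
#'
#' @param seed Integer seed; a fixed seed makes the generator output
#'   byte-identical.
#' @param n_variants Number of synthetic variants (default 4286).
#' @param bucket_mixture Length-3 fractions (disease, polymorphism,
#'   unclassified) summing to 1.
#' @param concordance_target Probability that the repository bucket equals
#'   the curated bucket.
#' @param discord_kernel 3x3 row-stochastic matrix with zero diagonal;
#'   row i gives the distribution of the discordant repository bucket for
#'   curated bucket i.
#' @param star_distribution Length-5 fractions for star levels 0-4,
#'   summing to 1.
#' @param mendelian_fraction Fraction of variants linked to Mendelian
#'   diseases.
#' @param evidence_templates Per-bucket evidence-template library: a named
#'   list (buckets) of lists of character vectors of ACMG codes.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_variants = 4286L,
                             bucket_mixture = c(1533, 2502, 251) / 4286,
                             concordance_target = 0.88,
                             discord_kernel = default_discord_kernel(),
                             star_distribution =
                               c(0.15, 0.35, 0.40, 0.07, 0.03),
                             mendelian_fraction = 0.9,
                             evidence_templates =
                               default_evidence_templates()) {
  chk_mix <- function(x, len, what) {
    if (length(x) != len || any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop("config error: ", what, " must be ", len,
           " non-negative fractions summing to 1", call. = FALSE)
    }
  }
  chk_mix(bucket_mixture, 3L, "bucket_mixture")
  chk_mix(star_distribution, 5L, "star_distribution")
  stopifnot(concordance_target >= 0, concordance_target <= 1,
            mendelian_fraction >= 0, mendelian_fraction <= 1,
            n_variants >= 1)
  discord_kernel <- as.matrix(discord_kernel)
  if (!all(dim(discord_kernel) == c(3L, 3L)) ||
      any(diag(discord_kernel) != 0) ||
      any(abs(rowSums(discord_kernel) - 1) > 1e-9)) {
    stop("config error: discord_kernel must be 3x3 row-stochastic with ",
         "a zero diagonal", call. = FALSE)
  }
  buckets <- uniprot_classes()
  dimnames(discord_kernel) <- list(buckets, buckets)
  names(bucket_mixture) <- buckets
  names(star_distribution) <- as.character(0:4)
  stopifnot(setequal(names(evidence_templates), buckets))
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 bucket_mixture = bucket_mixture,
                 concordance_target = concordance_target,
                 discord_kernel = discord_kernel,
                 star_distribution = star_distribution,
                 mendelian_fraction = mendelian_fraction,
                 evidence_templates = evidence_templates),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_discord_kernel <- function() {
  k <- rbind(c(0, 111, 94),
             c(46, 0, 128),
             c(55, 81, 0))
  k / rowSums(k)
}

#' @rdname generator_config
#' @export
default_evidence_templates <- function() {
  list(DISEASE = list(c("PVS1", "PS1"), c("PS3", "PM1", "PM2", "PP3")),
       POLYMORPHISM = list("BA1", c("BS1", "BS2")),
       UNCLASSIFIED = list(character(0), c("PM2", "PM3", "BS3")))
}

# run expr under the config seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate paired resource tables with known ground truth
#'
#' Draws a curated-resource bucket per variant from the bucket mixture;
#' with probability `concordance_target` the repository bucket matches
#' (five-tier label drawn uniformly within the bucket), otherwise it is
#' drawn from the discordance kernel.  Repository submissions are
#' fabricated to realize the drawn star level (two concordant
#' criteria-providing submitters for 2 stars, one with / without criteria
#' for 1 / 0 stars, panel flags for 3-4 stars).  All latent assignments are
#' recorded in the truth table.
#'
#' @param cfg A [generator_config()].
#' @return List of class `"synthetic_tables"`: `uniprot` (curated-resource
#'   records), `clinvar_submissions` (per-submitter rows), `truth` (latent
#'   assignments), `config`.
#' @seealso [write_synthetic_tables()], [generate_evidence_profiles()]
#' @export
generate_paired_tables <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_variants
    buckets <- uniprot_classes()
    idx <- seq_len(n)
    variant_id <- sprintf("VAR%06d", idx)
    ref <- sample(.aa3, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.aa3, r), 1L),
                  character(1))
    position <- sample(1:999, n, replace = TRUE)
    hgvs_p <- paste0("p.", ref, position, alt)

    u_bucket <- sample(buckets, n, replace = TRUE,
                       prob = cfg$bucket_mixture)
    concordant <- stats::runif(n) < cfg$concordance_target
    c_bucket <- u_bucket
    if (any(!concordant)) {
      c_bucket[!concordant] <- vapply(u_bucket[!concordant], function(b) {
        sample(buckets, 1L, prob = cfg$discord_kernel[b, ])
      }, character(1))
    }
    five <- function(b) switch(b,
      DISEASE = sample(c("PATHOGENIC", "LIKELY_PATHOGENIC"), 1L),
      POLYMORPHISM = sample(c("BENIGN", "LIKELY_BENIGN"), 1L),
      UNCLASSIFIED = "VUS")
    stars <- sample(0:4, n, replace = TRUE, prob = cfg$star_distribution)
    mendelian <- stats::runif(n) < cfg$mendelian_fraction
    inheritance <- sample(c("AUTOSOMAL_DOMINANT", "AUTOSOMAL_RECESSIVE",
                            "X_LINKED"), n, replace = TRUE,
                          prob = c(0.5, 0.45, 0.05))
    disease <- sprintf("Synthetic disorder %06d", idx)

    uniprot <- data.frame(
      gene_symbol = sprintf("GENE%06d", idx),
      protein_accession = sprintf("P%06d", idx),
      rsid = sprintf("rs9%08d", idx),
      hgvs_c = NA_character_, hgvs_p = hgvs_p,
      ref_aa = ref, position = position, alt_aa = alt,
      uniprot_class = u_bucket, disease_name = disease,
      omim_id = sprintf("6%05d", idx %% 1e5),
      inheritance = inheritance,
      prevalence = signif(10^stats::runif(n, -6, -3.5), 3),
      penetrance = 1,
      carrier_frequency = ifelse(inheritance == "AUTOSOMAL_RECESSIVE",
                                 signif(10^stats::runif(n, -3, -1.5), 3),
                                 NA_real_),
      is_mendelian = mendelian, source = "UNIPROT",
      stringsAsFactors = FALSE)

    subs <- lapply(idx, function(i) {
      b <- c_bucket[i]
      s <- stars[i]
      n_sub <- if (s == 2L) 2L else 1L
      data.frame(
        gene_symbol = uniprot$gene_symbol[i],
        protein_accession = uniprot$protein_accession[i],
        hgvs_p = hgvs_p[i], rsid = uniprot$rsid[i],
        condition = disease[i],
        submitter = paste0("LAB_", seq_len(n_sub)),
        classification = vapply(seq_len(n_sub), function(k) five(b),
                                character(1)),
        criteria_provided = s >= 1L,
        expert_panel = s == 3L, practice_guideline = s == 4L,
        stringsAsFactors = FALSE)
    })
    clinvar_submissions <- do.call(rbind, subs)

    truth <- data.frame(variant_id = variant_id,
                        uniprot_bucket = u_bucket,
                        clinvar_bucket = c_bucket,
                        concordant = concordant,
                        review_stars = stars,
                        is_mendelian = mendelian,
                        stringsAsFactors = FALSE)
    structure(list(uniprot = uniprot,
                   clinvar_submissions = clinvar_submissions,
                   truth = truth, config = cfg),
              class = "synthetic_tables")
  })
}

#' Generate per-variant evidence profiles from the truth table
#'
#' Each variant receives an evidence profile drawn from its latent class's
#' template library: benign-latent variants get frequency-based benign
#' codes, pathogenic-latent variants get pathogenic code sets, and
#' uncertain-latent variants get either no evidence or the conflicting
#' frequency / in-trans / functional triple.  The templates are designed
#' so that [combine_evidence()] recovers the latent bucket for
#' template-pure profiles.
#'
#' @param cfg A [generator_config()].
#' @param truth Truth table from [generate_paired_tables()].
#' @return Evidence-profile data frame (`variant_id`, `code`, `strength`,
#'   `justification`, `source`) for [classify_profiles()]; variants whose
#'   template is empty are absent.
#' @export
generate_evidence_profiles <- function(cfg, truth) {
  stopifnot(inherits(cfg, "generator_config"),
            all(c("variant_id", "clinvar_bucket") %in% names(truth)))
  .with_seed(cfg$seed + 1L, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      tpl <- cfg$evidence_templates[[truth$clinvar_bucket[i]]]
      codes <- tpl[[sample.int(length(tpl), 1L)]]
      if (!length(codes)) return(NULL)
      data.frame(variant_id = truth$variant_id[i], code = codes,
                 strength = NA_character_,
                 justification = "synthetic template evidence",
                 source = "synthetic", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(variant_id = character(),
                                        code = character(),
                                        strength = character(),
                                        justification = character(),
                                        source = character(),
                                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Write synthetic tables in the reader dialects
#'
#' Serializes a [generate_paired_tables()] result as three tab-separated
#' files — `uniprot.tsv` (humsavar dialect), `clinvar.tsv` (per-submission
#' dialect) and `truth.tsv` — readable by [read_uniprot_table()] and
#' [read_clinvar_table()].
#'
#' @param x A `"synthetic_tables"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic_tables <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(uniprot = file.path(dir, "uniprot.tsv"),
             clinvar = file.path(dir, "clinvar.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_uniprot_table(x$uniprot, paths["uniprot"])
  cs <- x$clinvar_submissions
  out <- data.frame(gene = cs$gene_symbol, accession = cs$protein_accession,
                    variant = cs$hgvs_p, dbsnp = cs$rsid, hgvs_c = NA,
                    condition = cs$condition, submitter = cs$submitter,
                    classification = cs$classification,
                    criteria_provided = ifelse(cs$criteria_provided,
                                               "yes", "no"),
                    expert_panel = ifelse(cs$expert_panel, "yes", "no"),
                    practice_guideline = ifelse(cs$practice_guideline,
                                                "yes", "no"),
                    stringsAsFactors = FALSE)
  .write_tsv(out, paths["clinvar"])
  .write_tsv(x$truth, paths["truth"])
  invisible(paths)
}
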