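# shared helpers: fixture paths and independent oracles

fixture <- function(name) {
  path <- system.file("extdata", name, package = "varconcord")
  stopifnot(nzchar(path))
  path
}

# Independent direct encoding of the ACMG-AMP combining rules, written as
# explicit boolean clauses over strength counts (the implementation instead
# matches minimum-count rows of the shipped rule file).
oracle_classify <- function(pvs, ps, pm, pp, ba, bs, bp) {
  P <- (pvs >= 1 & ps >= 1) | (pvs >= 1 & pm >= 2) |
    (pvs >= 1 & pm >= 1 & pp >= 1) | (pvs >= 1 & pp >= 2) |
    (ps >= 2) |
    (ps >= 1 & pm >= 3) | (ps >= 1 & pm >= 2 & pp >= 2) |
    (ps >= 1 & pm >= 1 & pp >= 4)
  LP <- (pvs >= 1 & pm >= 1) | (ps >= 1 & pm >= 1 & pm <= 2) |
    (ps >= 1 & pp >= 2) | (pm >= 3) | (pm >= 2 & pp >= 2) |
    (pm >= 1 & pp >= 4)
  B <- (ba >= 1) | (bs >= 2)
  LB <- (bs >= 1 & bp >= 1) | (bp >= 2)
  pside <- P | LP
  bside <- B | LB
  cls <- rep("VUS", length(pside))
  cls[pside & !bside] <- ifelse(P[pside & !bside],
                                "PATHOGENIC", "LIKELY_PATHOGENIC")
  cls[bside & !pside] <- ifelse(B[bside & !pside],
                                "BENIGN", "LIKELY_BENIGN")
  conflicting <- (pside & bside) |
    (!pside & !bside & (pvs + ps + pm + pp) > 0 & (ba + bs + bp) > 0)
  data.frame(classification = cls, conflicting = conflicting,
             stringsAsFactors = FALSE)
}

# build an evidence data frame realizing given per-stratum counts using
# distinct default-strength codes
evidence_from_counts <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                                 ba = 0, bs = 0, bp = 0) {
  pick <- function(codes, k) if (k > 0) codes[seq_len(k)] else character(0)
  codes <- c(pick("PVS1", pvs), pick(paste0("PS", 1:4), ps),
             pick(paste0("PM", 1:6), pm), pick(paste0("PP", 1:5), pp),
             pick("BA1", ba), pick(paste0("BS", 1:4), bs),
             pick(paste0("BP", 1:7), bp))
  if (!length(codes)) return(NULL)
  do.call(rbind, lapply(codes, evidence_assignment))
}

acmg_rank <- c(BENIGN = 1, LIKELY_BENIGN = 2, VUS = 3,
               LIKELY_PATHOGENIC = 4, PATHOGENIC = 5)

# brute-force tally oracle: explicit double loop over pairs
brute_contingency <- function(u_bucket, c_class) {
  buckets <- uniprot_classes()
  m <- matrix(0L, 3, 3, dimnames = list(buckets, buckets))
  cb <- harmonize_class(c_class)
  for (i in seq_along(u_bucket)) {
    m[u_bucket[i], cb[i]] <- m[u_bucket[i], cb[i]] + 1L
  }
  m
}

# brute-force matcher: nested loops with explicit stage bookkeeping
brute_match <- function(u, cv) {
  key_of <- function(df, i, stage) {
    rs <- tolower(trimws(df$rsid[i]))
    if (!is.na(rs) && !grepl("^rs[0-9]+$", rs)) rs <- NA
    switch(stage,
           RSID = rs,
           HGVS_C = gsub("[[:space:]]", "", df$hgvs_c[i]),
           HGVS_P = if (is.na(df$hgvs_p[i]) || is.na(df$protein_accession[i]))
             NA_character_ else
               paste0(df$protein_accession[i], ":",
                      gsub("[[:space:]]", "", df$hgvs_p[i])))
  }
  used_u <- rep(FALSE, nrow(u))
  used_c <- rep(FALSE, nrow(cv))
  pairs <- list()
  for (stage in c("RSID", "HGVS_C", "HGVS_P")) {
    new_u <- logical(nrow(u))
    new_c <- logical(nrow(cv))
    for (i in seq_len(nrow(u))) {
      if (used_u[i]) next
      ku <- key_of(u, i, stage)
      if (is.na(ku) || ku == "") next
      for (j in seq_len(nrow(cv))) {
        if (used_c[j]) next
        kc <- key_of(cv, j, stage)
        if (!is.na(kc) && kc == ku) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
          new_u[i] <- TRUE
          new_c[j] <- TRUE
        }
      }
    }
    used_u <- used_u | new_u
    used_c <- used_c | new_c
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# minimal curated/repository record frames for matcher tests
make_uniprot_records <- function(n, rsid = sprintf("rs%d", seq_len(n)),
                                 hgvs_c = NA, hgvs_p = "p.Ala2Val",
                                 accession = sprintf("P%05d", seq_len(n)),
                                 uniprot_class = "DISEASE",
                                 is_mendelian = TRUE) {
  data.frame(gene_symbol = sprintf("G%03d", seq_len(n)),
             protein_accession = accession, rsid = rsid,
             hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             ref_aa = "Ala", position = seq_len(n), alt_aa = "Val",
             uniprot_class = uniprot_class,
             disease_name = sprintf("D%03d", seq_len(n)),
             is_mendelian = is_mendelian, stringsAsFactors = FALSE)
}

make_clinvar_records <- function(n, rsid = sprintf("rs%d", seq_len(n)),
                                 hgvs_c = NA, hgvs_p = "p.Ala2Val",
                                 accession = sprintf("P%05d", seq_len(n)),
                                 aggregate_class = "PATHOGENIC",
                                 review_stars = 2L) {
  data.frame(gene_symbol = sprintf("G%03d", seq_len(n)),
             protein_accession = accession, rsid = rsid,
             hgvs_c = hgvs_c, hgvs_p = hgvs_p,
             condition = sprintf("D%03d", seq_len(n)),
             aggregate_class = aggregate_class,
             review_stars = review_stars, stringsAsFactors = FALSE)
}

# full synthetic pipeline: generate, serialize, re-read, match, filter,
# and measure the overall concordance of the surviving pairs
simulated_concordance <- function(cfg) {
  dir <- withr::local_tempdir()
  tabs <- generate_paired_tables(cfg)
  paths <- write_synthetic_tables(tabs, dir)
  u <- suppressMessages(read_uniprot_table(paths[["uniprot"]]))
  cv <- suppressMessages(read_clinvar_table(paths[["clinvar"]]))
  pairs <- match_variants(u, cv)
  filtered <- apply_study_filters(pairs)
  kept <- filtered$pairs[!is.na(filtered$pairs$aggregate_class), ,
                         drop = FALSE]
  report <- overall_concordance(build_contingency(kept))
  list(report = report, filtered = filtered, tabs = tabs)
}
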