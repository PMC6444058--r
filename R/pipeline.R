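#' Run the full comparison pipeline
#'
#' Orchestrates match -> filter -> contingency -> concordance (and
#' optionally per-variant ACMG classification) as one reproducible run.
#' The configuration is a YAML file or an equivalent list:
#'
#' ```yaml
#' uniprot: { path: uniprot.tsv, dialect: humsavar-2017 }
#' clinvar: { path: clinvar.tsv, dialect: clinvar-submissions-2017 }
#' evidence_profiles: profiles.tsv      # optional
#' out_dir: results
#' thresholds: { ba1_cutoff: 0.05, pm2_cutoff: 1.0e-4 }
#' ```
#'
#' Outputs written under `out_dir`: `matched_pairs.tsv`,
#' `exclusions.tsv`, `contingency.tsv`, `concordance.tsv`, optionally
#' `classifications.tsv`, plus `manifest.yaml` recording the configuration
#' snapshot, input digests, tool version, per-stage record counts and
#' output digests.  Empty inputs abort before any output is written.
#'
#' @param config Path to a YAML configuration file, or a list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return The run manifest (list of class `"run_manifest"`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$uniprot),
            !is.null(config$clinvar))
  cfg_in <- function(x) if (is.list(x)) x else list(path = x)
  u_cfg <- cfg_in(config$uniprot)
  c_cfg <- cfg_in(config$clinvar)
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no out_dir given", call. = FALSE)
  thresholds <- utils::modifyList(list(ba1_cutoff = 0.05, pm2_cutoff = 1e-4),
                                  config$thresholds %||% list())

  u <- read_uniprot_table(u_cfg$path, u_cfg$dialect %||% "humsavar-2017")
  cv <- read_clinvar_table(c_cfg$path,
                           c_cfg$dialect %||% "clinvar-submissions-2017")
  if (nrow(u$records) == 0L || nrow(cv$records) == 0L) {
    stop("pipeline stage 'read' failed: empty input table(s); ",
         "no outputs written", call. = FALSE)
  }

  pairs <- match_variants(u, cv)
  filtered <- apply_study_filters(pairs)
  usable <- !is.na(filtered$pairs$aggregate_class)
  if (any(!usable)) {
    message("run_pipeline: dropping ", sum(!usable),
            " pair(s) with bucket-discordant submissions")
  }
  kept <- filtered$pairs[usable, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("pipeline stage 'filter' failed: no pairs survive the study ",
         "filters; no outputs written", call. = FALSE)
  }
  tab <- build_contingency(kept)
  report <- overall_concordance(tab)

  classifications <- NULL
  if (!is.null(config$evidence_profiles)) {
    profiles <- read_evidence_table(config$evidence_profiles)
    classifications <- classify_profiles(profiles)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matched_pairs = file.path(out_dir, "matched_pairs.tsv"),
             exclusions = file.path(out_dir, "exclusions.tsv"),
             contingency = file.path(out_dir, "contingency.tsv"),
             concordance = file.path(out_dir, "concordance.tsv"))
  .write_tsv(as.data.frame(pairs), paths["matched_pairs"])
  .write_tsv(data.frame(filter = names(filtered$exclusions),
                        excluded = as.integer(filtered$exclusions)),
             paths["exclusions"])
  write_contingency(tab, paths["contingency"])
  .write_tsv(data.frame(
    quantity = c("n_total", "n_agree", "overall_percent",
                 paste0(tolower(names(report$per_category)), "_percent")),
    value = c(report$n_total, report$n_agree,
              round_half_up(report$overall, 2),
              round_half_up(report$per_category, 2))),
    paths["concordance"])
  if (!is.null(classifications)) {
    paths["classifications"] <- file.path(out_dir, "classifications.tsv")
    .write_tsv(classifications, paths["classifications"])
  }

  manifest <- structure(list(
    tool = "varconcord",
    version = as.character(utils::packageVersion("varconcord")),
    config = list(uniprot = u_cfg, clinvar = c_cfg,
                  evidence_profiles = config$evidence_profiles,
                  thresholds = thresholds, out_dir = out_dir),
    input_digests = list(
      uniprot = unname(tools::md5sum(u_cfg$path)),
      clinvar = unname(tools::md5sum(c_cfg$path))),
    counts = list(
      uniprot_records = nrow(u$records),
      uniprot_rejects = NROW(u$rejects),
      clinvar_records = nrow(cv$records),
      clinvar_rejects = NROW(cv$rejects),
      matched_pairs = nrow(pairs),
      exclusions = as.list(filtered$exclusions),
      analyzed_pairs = nrow(kept),
      classified_variants = NROW(classifications)),
    concordance = list(n_agree = report$n_agree,
                       overall_percent = round_half_up(report$overall, 4)),
    outputs = as.list(vapply(paths, function(p) unname(tools::md5sum(p)),
                             character(1)))),
    class = "run_manifest")
  yaml::write_yaml(unclass(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> varconcord", x$version, "\n")
  cat("  pairs:", x$counts$matched_pairs,
      " analyzed:", x$counts$analyzed_pairs,
      " overall concordance:", x$concordance$overall_percent, "%\n")
  invisible(x)
}
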