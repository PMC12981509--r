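#' Pipeline commands
#'
#' Thin end-to-end commands wiring the package modules together the way the
#' `umni` command-line script drives them. Every command writes its outputs
#' plus a plain-text run manifest (`manifest.json` with the package
#' version, the seed, and an md5 of the canonicalized configuration) into
#' `out_dir`; reruns with an identical manifest produce byte-identical
#' outputs.
#'
#' @name umni_pipeline
NULL

write_manifest <- function(out_dir, command, config, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "umni",
    version = as.character(utils::packageVersion("umni")),
    command = command,
    seed = seed,
    config = config,
    config_md5 = md5
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a complete offline fixture set
#'
#' Writes a synthetic registry (TSV), disease profiles (CSV), and a paired
#' expert/second-rater score set (CSV) produced under the given seed —
#' every input the downstream commands need, with no network access.
#'
#' @param out_dir Output directory.
#' @param n_diseases Number of synthetic diseases (default 40).
#' @param seed Integer seed.
#' @param rates Rater disagreement rates (see [mock_rate()]).
#' @return Invisibly, a named list of the written paths.
#' @export
umni_simulate <- function(out_dir, n_diseases = 40L, seed = 1L,
                          rates = c("1" = 0.2045, "2" = 0.0545)) {
  config <- list(command = "simulate", n_diseases = n_diseases,
                 rates = as.list(rates))
  reg <- gen_registry(n_diseases)
  profiles <- gen_profiles(n_diseases, seed = seed)
  pair <- gen_rater_pair(n_diseases, seed = seed + 1L, rates = rates)
  write_manifest(out_dir, "simulate", config, seed)
  paths <- list(
    registry = file.path(out_dir, "registry.tsv"),
    profiles = file.path(out_dir, "profiles.csv"),
    expert = file.path(out_dir, "expert_scores.csv"),
    second = file.path(out_dir, "llm_scores.csv")
  )
  write_registry_tsv(reg, paths$registry)
  write_profiles_csv(profiles, paths$profiles)
  write_score_csv(pair$expert, paths$expert)
  write_score_csv(pair$second, paths$second)
  invisible(paths)
}

#' Score diseases end to end
#'
#' Rates every disease (rubric rater over a profile table, or a
#' mock-perturbed variant of those rubric scores), audits the scores,
#' aggregates them into weighted composites with rank and top-percent, and
#' writes the composite CSV plus a histogram summary.
#'
#' @param profiles_csv Path to a disease-profile CSV.
#' @param out_dir Output directory.
#' @param rubric_json Optional rubric JSON (default: the built-in rubric).
#' @param weights_json Optional weight-scheme JSON (default: the built-in
#'   weights).
#' @param rater `"rubric"` for deterministic rubric scores, `"mock"` to
#'   perturb them with `rates`.
#' @param rates Mock-rater disagreement rates.
#' @param seed Integer seed.
#' @param bins Histogram bins.
#' @return Invisibly, a list with `composite`, `summary`, and `violations`.
#' @export
umni_score <- function(profiles_csv, out_dir, rubric_json = NULL,
                       weights_json = NULL, rater = c("rubric", "mock"),
                       rates = c("1" = 0.2045, "2" = 0.0545),
                       seed = 1L, bins = 15L) {
  rater <- match.arg(rater)
  profiles <- read_profiles_csv(profiles_csv)
  rubric <- if (is.null(rubric_json)) default_rubric() else read_rubric_json(rubric_json)
  weights <- if (is.null(weights_json)) default_weights() else read_weights_json(weights_json)
  config <- list(command = "score", profiles = basename(profiles_csv),
                 rubric = if (is.null(rubric_json)) "default" else basename(rubric_json),
                 weights = if (is.null(weights_json)) "default" else basename(weights_json),
                 rater = rater, rates = as.list(rates), bins = bins)
  scores <- score_profiles(profiles, rubric)
  if (rater == "mock") {
    scores <- mock_rate(scores, rates = rates, seed = seed, rater = "mock")
  }
  violations <- validate_scores(scores)
  if (nrow(violations)) {
    stop_umni("score audit found ", nrow(violations), " invalid cell(s)")
  }
  composite <- composite_scores(scores, weights)
  summary <- distribution_summary(composite$total_score, bins = bins)
  write_manifest(out_dir, "score", config, seed)
  write_score_csv(scores, file.path(out_dir, "scores.csv"))
  write_composite_csv(composite, file.path(out_dir, "composite.csv"))
  write_histogram_csv(summary, file.path(out_dir, "histogram.csv"))
  invisible(list(composite = composite, summary = summary,
                 violations = violations))
}

#' Agreement report between two score files
#'
#' Computes the per-criterion agreement report (moments, gates, Spearman
#' with bootstrap interval, errors, Wilcoxon) between an expert score CSV
#' and a candidate rater score CSV, and writes the report plus a gate
#' failure log.
#'
#' @param expert_csv,rater_csv Paths to aligned score CSVs.
#' @param out_dir Output directory.
#' @param resamples Bootstrap resamples per criterion.
#' @param seed Integer seed.
#' @return Invisibly, the `agreement_report` data frame.
#' @export
umni_agree <- function(expert_csv, rater_csv, out_dir, resamples = 1000L,
                       seed = 1L) {
  expert <- read_score_csv(expert_csv, rater_id = "expert")
  rater <- read_score_csv(rater_csv, rater_id = "rater")
  config <- list(command = "agree", expert = basename(expert_csv),
                 rater = basename(rater_csv), resamples = resamples)
  report <- agreement_report(expert, rater, resamples = resamples, seed = seed)
  write_manifest(out_dir, "agree", config, seed)
  utils::write.csv(report, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  failures <- report[report$gate_mean == "fail" | report$gate_sd == "fail",
                     c("criterion", "mean_diff", "sd_diff", "gate_mean", "gate_sd")]
  utils::write.csv(failures, file.path(out_dir, "gate_failures.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(report)
}

#' Factor suite over a score file
#'
#' Runs Bartlett, KMO, parallel analysis, and (when the data are
#' factorable) maximum-likelihood EFA with dominant-loading grouping on a
#' score CSV, writing the full factor report.
#'
#' @param scores_csv Path to a score CSV with at least `p + 1` complete
#'   rows.
#' @param out_dir Output directory.
#' @param n_sim Parallel-analysis simulations.
#' @param seed Integer seed.
#' @param rotation EFA rotation.
#' @return Invisibly, the `factor_report`.
#' @export
umni_factors <- function(scores_csv, out_dir, n_sim = 1000L, seed = 1L,
                         rotation = "promax") {
  m <- read_score_csv(scores_csv)
  config <- list(command = "factors", scores = basename(scores_csv),
                 n_sim = n_sim, rotation = rotation)
  report <- factor_report(m, n_sim = n_sim, seed = seed, rotation = rotation)
  write_manifest(out_dir, "factors", config, seed)
  write_factor_report(report, out_dir)
  invisible(report)
}

#' Reconcile two expert score files
#'
#' Tabulates the disagreement histogram between two raters, applies the
#' mediation rule (mean for differences of at most one point, mediator
#' verbatim above that), and writes the consensus matrix, the mediation
#' log, and the disagreement table.
#'
#' @param a_csv,b_csv Paths to the two expert score CSVs.
#' @param mediator_csv Path to the mediator's score CSV (may be omitted
#'   when no difference exceeds one point).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (the command itself
#'   is deterministic).
#' @return Invisibly, a list with `consensus`, `log`, and `table`.
#' @export
umni_reconcile <- function(a_csv, b_csv, mediator_csv = NULL, out_dir,
                           seed = 1L) {
  a <- read_score_csv(a_csv, rater_id = "expert_a")
  b <- read_score_csv(b_csv, rater_id = "expert_b")
  med <- if (is.null(mediator_csv)) NULL else read_score_csv(mediator_csv, "mediator")
  config <- list(command = "reconcile", a = basename(a_csv), b = basename(b_csv),
                 mediator = if (is.null(mediator_csv)) NA else basename(mediator_csv))
  tab <- diff_histogram(a, b)
  res <- mediate(a, b, med)
  write_manifest(out_dir, "reconcile", config, seed)
  cons <- data.frame(disease_id = rownames(res$consensus), res$consensus,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(cons, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(res$log, file.path(out_dir, "mediation_log.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(
    data.frame(abs_diff = names(tab$counts), count = tab$counts,
               percent = tab$percent),
    file.path(out_dir, "disagreement_table.csv"),
    row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"
  )
  invisible(list(consensus = res$consensus, log = res$log, table = tab))
}
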