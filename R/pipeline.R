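# The two-stage workflow.
#
# Stage 1 (cohort): build per-variant cluster models from the cohort's own
# intensities, call, compute metrics, flag under a ruleset, recluster the
# flagged variants (dropping those zeroed), run the QC cascade, and write a
# custom JSON cluster file from the surviving, repaired models.
#
# Stage 2 (independent samples): call a fresh cohort once with the custom
# cluster file and once with its own default (built-from-data) models, run
# the same QC on both call sets, and compare the surviving variant sets.

#' Stage 1: build, flag, recluster, QC, emit a custom cluster file
#'
#' @param bundle A `sim_bundle` (or any list with `intensities`,
#'   `variant_meta`, `sample_meta`, `error_registry`).
#' @param out_dir Output directory for artifacts (NULL for none).
#' @param ruleset A `ruleset` used for flagging and repair decisions.
#' @param caller_cfg A [caller_config()].
#' @param qc_cfg A [qc_config()].
#' @return List with `models` (repaired `cluster_model_set` excluding zeroed
#'   variants), `calls`, `metrics`, `flags` (`flag_report`),
#'   `recluster_status` (data frame), `qc` (`qc_report`),
#'   `surviving_variants`.
#' @export
run_stage1 <- function(bundle, out_dir = NULL,
                       ruleset = builtin_ruleset("adjusted"),
                       caller_cfg = caller_config(),
                       qc_cfg = qc_config()) {
  models <- bundle_models(bundle, caller_cfg)
  calls <- call_genotypes(bundle$intensities, models)
  metrics <- variant_metrics_table(calls, bundle$intensities, models)
  flags <- apply_ruleset(metrics, ruleset)

  flagged <- unique(flags$hits$variant_id)
  status <- data.frame(variant_id = flagged,
                       status = NA_character_, stringsAsFactors = FALSE)
  g <- unclass_geno(calls)
  for (i in seq_along(flagged)) {
    vid <- flagged[i]
    v <- match(vid, rownames(g))
    res <- recluster_variant(bundle$intensities$theta[v, ],
                             bundle$intensities$r[v, ],
                             models$models[[vid]],
                             flags$hits$rule_id[flags$hits$variant_id == vid],
                             ruleset, caller_cfg)
    status$status[i] <- res$status
    if (res$status != "unchanged") {
      models$models[[vid]] <- res$model
      g[v, ] <- res$calls
    }
  }
  calls <- new_genotype_matrix(g)
  zeroed <- status$variant_id[status$status == "zeroed"]
  keep <- setdiff(rownames(g), zeroed)

  qc <- run_qc(new_genotype_matrix(g[keep, , drop = FALSE]),
               bundle$variant_meta[match(keep, bundle$variant_meta$variant_id),
                                   , drop = FALSE],
               declared_sex = bundle$sample_meta$sex, config = qc_cfg)
  surviving <- qc$surviving_variants
  out_models <- structure(
    list(models = models$models[surviving], config = models$config),
    class = "cluster_model_set")

  res <- list(models = out_models, calls = calls, metrics = metrics,
              flags = flags, recluster_status = status, qc = qc,
              surviving_variants = surviving)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flags$hits, file.path(out_dir, "flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summarize_flags(flags),
                       file.path(out_dir, "flag_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(status, file.path(out_dir, "recluster_status.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_cluster_json(out_models, file.path(out_dir, "cluster_file.json"))
    jsonlite::write_json(list(
      samples_excluded = qc$samples_excluded,
      variants_excluded = qc$variants_excluded,
      dim_before = qc$dim_before, dim_after = qc$dim_after),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
    write_run_log(file.path(out_dir, "run_log.yaml"), "stage1",
                  bundle, ruleset, caller_cfg, qc_cfg)
  }
  res
}

#' Stage 2: call an independent cohort with custom vs default cluster files
#'
#' @param bundle A fresh cohort `sim_bundle`.
#' @param custom_models A `cluster_model_set` (e.g. stage 1 output or
#'   [read_cluster_json()]); variants absent from it fall back to the
#'   cohort's own built models.
#' @param out_dir Output directory for artifacts (NULL for none).
#' @param ruleset,caller_cfg,qc_cfg As in [run_stage1()].
#' @return List with `venn` (counts shared/unique_custom/unique_default),
#'   `custom`, `default` (each: `calls`, `qc`, `surviving_variants`).
#' @export
run_stage2 <- function(bundle, custom_models, out_dir = NULL,
                       ruleset = builtin_ruleset("adjusted"),
                       caller_cfg = caller_config(),
                       qc_cfg = qc_config()) {
  if (is.null(custom_models)) {
    stop("stage 2 requires a custom cluster file (cluster_model_set)")
  }
  default_models <- bundle_models(bundle, caller_cfg)
  vids <- rownames(bundle$intensities$theta)
  merged <- default_models
  shared_ids <- intersect(vids, names(custom_models$models))
  merged$models[shared_ids] <- custom_models$models[shared_ids]

  eval_arm <- function(models) {
    calls <- call_genotypes(bundle$intensities, models)
    qc <- run_qc(calls, bundle$variant_meta,
                 declared_sex = bundle$sample_meta$sex, config = qc_cfg)
    list(calls = calls, qc = qc, surviving_variants = qc$surviving_variants)
  }
  custom <- eval_arm(merged)
  default <- eval_arm(default_models)
  venn <- compare_variant_sets(custom$surviving_variants,
                               default$surviving_variants)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      shared = unname(venn$counts["shared"]),
      unique_custom = unname(venn$counts["unique_a"]),
      unique_default = unname(venn$counts["unique_b"])),
      file.path(out_dir, "venn_counts.json"), auto_unbox = TRUE, digits = NA)
    write_run_log(file.path(out_dir, "run_log.yaml"), "stage2",
                  bundle, ruleset, caller_cfg, qc_cfg)
  }
  list(venn = venn, custom = custom, default = default)
}

write_run_log <- function(path, stage, bundle, ruleset, caller_cfg, qc_cfg) {
  yaml::write_yaml(list(
    stage = stage,
    seed = bundle$config$seed %||% NA,
    n_samples = ncol(bundle$intensities$theta),
    n_variants = nrow(bundle$intensities$theta),
    ruleset = ruleset$name,
    caller_config = lapply(unclass(caller_cfg), function(x)
      if (is.numeric(x) && length(x) > 1) as.list(x) else x),
    qc_config = unclass(qc_cfg)), path)
}

#' Run the two-stage pipeline end to end on simulated cohorts
#'
#' Convenience wrapper: simulates a discovery cohort, runs stage 1 to derive
#' a custom cluster file, simulates an independent cohort (different
#' substream of the same seed), and runs stage 2 against it.
#'
#' @param stage1_config,stage2_config [sim_config()] objects for the two
#'   cohorts.
#' @param out_dir Output directory (artifacts under `stage1/` and `stage2/`),
#'   or NULL.
#' @param ruleset,caller_cfg,qc_cfg Shared settings.
#' @return List with `stage1` and `stage2` results.
#' @export
run_pipeline <- function(stage1_config, stage2_config, out_dir = NULL,
                         ruleset = builtin_ruleset("adjusted"),
                         caller_cfg = caller_config(),
                         qc_cfg = qc_config()) {
  b1 <- simulate_dataset(stage1_config)
  s1 <- run_stage1(b1, if (!is.null(out_dir)) file.path(out_dir, "stage1"),
                   ruleset, caller_cfg, qc_cfg)
  b2 <- simulate_dataset(stage2_config)
  s2 <- run_stage2(b2, s1$models,
                   if (!is.null(out_dir)) file.path(out_dir, "stage2"),
                   ruleset, caller_cfg, qc_cfg)
  list(stage1 = s1, stage2 = s2)
}
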