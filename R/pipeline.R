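## End-to-end orchestration: simulate or ingest a cohort, compute the
## behavior matrix, fit the phenotype classifier, characterize structure and
## write a reproducible report bundle.

#' Run the full phenotyping pipeline
#'
#' In `"simulate"` mode a synthetic cohort is generated from `sim`
#' (deterministically, from its seed) and pushed through indexing, scoring
#' and structure analysis; in `"files"` mode the event log is read from the
#' three CSV inputs. Outputs written to `out_dir`:
#'
#' * `behavior_matrix.csv` — animals x indices (all variants);
#' * `aud_results.csv` — per-animal flags, AUD index, AUD score, class;
#' * `report.json` — cohort-level results: prone fraction, AUD-index
#'   distribution, criterion thresholds, independence-null expectation, and
#'   per-group Spearman/PCA structure;
#' * `run_manifest.json` — config echo, seed, package version and input
#'   checksums;
#' * in simulate mode additionally `events.csv`, `registry.csv`,
#'   `schedule.csv` and `truth.csv`.
#'
#' Identical configuration and seed produce byte-identical bundles.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] (simulate mode).
#' @param events,schedule,registry input CSV paths (files mode).
#' @param q,k scoring parameters, see [aud_phenotype()].
#' @param behaviors behavior columns used for scoring.
#' @param lick_volume_ul microlitres per lick for the consumption index.
#' @param occurrence which occurrence of each scored phase to use, see
#'   [build_behavior_matrix()].
#' @param write_events logical; in simulate mode, also write the simulated
#'   CSV inputs and latent truth (default `TRUE`).
#' @return Invisibly, a list with `log`, `truth` (or `NULL`), `matrix`,
#'   `fit`, `structure`, `report` and `paths`.
#' @export
run_pipeline <- function(mode = c("simulate", "files"),
                         out_dir,
                         sim = sim_config(),
                         events = NULL, schedule = NULL, registry = NULL,
                         q = 0.35, k = 2L,
                         behaviors = .behaviors,
                         lick_volume_ul = DEFAULT_LICK_VOLUME_UL,
                         occurrence = list(),
                         write_events = TRUE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  checksums <- NULL
  if (mode == "simulate") {
    cohort <- .with_stage("simulate", simulate_cohort(sim))
    log <- cohort$log
    truth <- cohort$truth
    if (write_events) {
      write_event_log(log, out_dir)
      data.table::fwrite(truth, file.path(out_dir, "truth.csv"))
    }
  } else {
    if (is.null(events) || is.null(schedule) || is.null(registry)) {
      stop_audcage("files mode needs events, schedule and registry paths",
                   "audcage_config_error")
    }
    log <- .with_stage("read", read_event_log(events, schedule, registry))
    checksums <- as.list(tools::md5sum(c(events, schedule, registry)))
    names(checksums) <- c("events", "schedule", "registry")
  }

  occ <- utils::modifyList(
    list(motivation = 1L, extinction = 1L, cue_relapse = 1L,
         alcohol_relapse = 1L, persistence = 1L), occurrence)
  bm <- .with_stage("indices",
                    build_behavior_matrix(log, lick_volume_ul = lick_volume_ul,
                                          occurrence = occ))
  fit <- .with_stage("scoring",
                     aud_phenotype(bm, q = q, k = k, behaviors = behaviors))
  struct <- .with_stage("structure",
                        phenotype_structure(bm, fit$class, behaviors = behaviors))

  results <- as.data.frame(fit)
  paths <- c(
    behavior_matrix = file.path(out_dir, "behavior_matrix.csv"),
    aud_results = file.path(out_dir, "aud_results.csv"),
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  data.table::fwrite(as.data.frame(bm), paths[["behavior_matrix"]])
  data.table::fwrite(results, paths[["aud_results"]])

  report <- list(
    n_animals = nrow(log$registry),
    n_scored = fit$n,
    excluded = as.list(attr(bm, "excluded")),
    q = q, k = as.integer(k),
    behaviors = behaviors,
    n_prone = sum(fit$class == "prone"),
    n_resistant = sum(fit$class == "resistant"),
    prone_fraction = mean(fit$class == "prone"),
    independence_null_fraction = independence_null(q, length(behaviors), k),
    criterion_thresholds = as.list(fit$thresholds),
    aud_index_distribution = as.list(stats::setNames(
      as.integer(table(factor(fit$index, levels = 0:length(behaviors)))),
      paste0("crit_", 0:length(behaviors)))),
    structure = .structure_to_list(struct)
  )
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  manifest <- list(
    package = "audcage",
    version = as.character(utils::packageVersion("audcage")),
    mode = mode,
    q = q, k = as.integer(k),
    behaviors = behaviors,
    lick_volume_ul = lick_volume_ul,
    occurrence = occ,
    seed = if (mode == "simulate") sim$seed else NULL,
    sim_config = if (mode == "simulate") .config_to_list(sim) else NULL,
    input_checksums = checksums
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  invisible(list(log = log, truth = truth, matrix = bm, fit = fit,
                 structure = struct, report = report, paths = paths))
}

.structure_to_list <- function(struct) {
  lapply(unclass(struct), function(el) {
    if (is.null(el$spearman)) return(list(n = el$n))
    list(
      n = el$n,
      spearman_r = as.data.frame(el$spearman$r),
      spearman_p = as.data.frame(el$spearman$p),
      mean_offdiag_r = mean(el$spearman$r[upper.tri(el$spearman$r)]),
      pca_loadings = as.data.frame(el$pca$loadings),
      explained_variance = el$pca$explained_variance
    )
  })
}

.config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$schedule <- as.data.frame(out$schedule)
  out$ladder <- unclass(out$ladder)
  out
}

## rethrow stage errors with the stage name prepended, preserving the
## original condition class
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    e$message <- paste0("stage '", stage, "': ", conditionMessage(e))
    stop(e)
  })
}
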