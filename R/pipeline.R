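#' Pipeline configuration
#'
#' Collects the knobs of the simulate -> extract -> compare -> evaluate ->
#' report pipeline. A seed is mandatory for simulation; everything else has
#' the packaged defaults.
#'
#' @param seed Integer master seed (required for [run_simulate()]).
#' @param n_noncm,n_cm Cohort sizes.
#' @param params_noncm,params_cm [group_params()] for the two groups.
#' @param sparc [sparc_config()].
#' @param grid SVM cost grid.
#' @param mode Tuning mode, `"paper_faithful"` or `"nested"`.
#' @param kernel SVM kernel.
#' @param normalization `"fold"` or `"global"`.
#' @param rho Across-shape correlation of participant latent factors.
#' @return An object of class `cm_config`.
#' @export
pipeline_config <- function(seed = NULL, n_noncm = 66, n_cm = 38,
                            params_noncm = default_group_params("nonCM"),
                            params_cm = default_group_params("CM"),
                            sparc = sparc_config(),
                            grid = c(0.1, 1, 10, 100),
                            mode = "paper_faithful", kernel = "radial",
                            normalization = "fold", rho = 0.3) {
  structure(list(seed = seed, n_noncm = n_noncm, n_cm = n_cm,
                 params_noncm = params_noncm, params_cm = params_cm,
                 sparc = sparc, grid = grid, mode = mode, kernel = kernel,
                 normalization = normalization, rho = rho),
            class = "cm_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `n_noncm`, `n_cm`, `mode`, `kernel`,
#' `normalization`, `grid`, `rho`, `sparc` (sub-keys as in
#' [sparc_config()]) and `groups` (per group, per shape:
#' `duration`/`pressure`/`roughness` triples `[median, q1, q3]`
#' overriding the packaged defaults).
#'
#' @param path YAML file path.
#' @return A `cm_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- do.call(sparc_config, y$sparc %||% list())
  pars <- list(nonCM = default_group_params("nonCM"),
               CM = default_group_params("CM"))
  for (g in names(y$groups %||% list())) {
    for (s in names(y$groups[[g]])) {
      for (q in names(y$groups[[g]][[s]]))
        pars[[g]]$shapes[[s]][[q]] <- as.numeric(y$groups[[g]][[s]][[q]])
    }
  }
  pipeline_config(seed = y$seed, n_noncm = y$n_noncm %||% 66,
                  n_cm = y$n_cm %||% 38, params_noncm = pars$nonCM,
                  params_cm = pars$CM, sparc = sp,
                  grid = as.numeric(y$grid %||% c(0.1, 1, 10, 100)),
                  mode = y$mode %||% "paper_faithful",
                  kernel = y$kernel %||% "radial",
                  normalization = y$normalization %||% "fold",
                  rho = y$rho %||% 0.3)
}

log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Simulate a cohort and write it to disk
#'
#' Writes one recording CSV + JSON sidecar per tracing, `manifest.csv`,
#' `participants.csv` and a `provenance.json` (config hash, seed, package
#' version).
#'
#' @param config A `cm_config` with a non-`NULL` seed.
#' @param out_dir Destination directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "cm_config"))
  if (is.null(config$seed)) stop_validation("config must carry a seed")
  t0 <- Sys.time()
  cohort <- simulate_cohort(config$params_noncm, config$params_cm,
                            config$n_noncm, config$n_cm,
                            seed = config$seed, rho = config$rho)
  write_cohort(cohort, out_dir)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         n_recordings = length(cohort$recordings),
         package_version = as.character(utils::packageVersion("cmscreen"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  log_msg("simulate: %d recordings -> %s (%.1f s)",
          length(cohort$recordings), out_dir,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out_dir)
}

#' Extract features from a cohort directory
#'
#' One feature row per valid recording; recordings failing validation (or
#' flagged multi-stroke) are skipped with a logged reason, or trimmed to
#' their longest stroke when `keep_longest_stroke = TRUE`.
#'
#' @param cohort_dir Directory written by [run_simulate()]/[write_cohort()].
#' @param out_csv Destination feature CSV.
#' @param sparc [sparc_config()].
#' @param keep_longest_stroke Trim multi-stroke recordings instead of
#'   skipping them.
#' @return The feature data.frame, invisibly.
#' @export
run_extract <- function(cohort_dir, out_csv, sparc = sparc_config(),
                        keep_longest_stroke = FALSE) {
  manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop_validation("empty cohort")
  rows <- list()
  skipped <- 0
  for (p in manifest$path) {
    row <- tryCatch({
      rec <- read_recording(file.path(cohort_dir, p))
      v <- validate_recording(rec)
      if (v$multi_stroke) {
        if (keep_longest_stroke) rec <- keep_longest_stroke(rec)
        else stop_validation("multi-stroke recording")
      } else if (!v$ok) stop_validation("%s", v$violations[1])
      extract_features(rec, cfg = sparc)
    }, error = function(e) {
      log_msg("extract: skipping %s (%s)", p, conditionMessage(e))
      NULL
    })
    if (is.null(row)) skipped <- skipped + 1 else
      rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) stop_validation("no valid recordings")
  features <- do.call(rbind, rows)
  write_features(features, out_csv)
  log_msg("extract: %d rows (%d skipped) -> %s", nrow(features), skipped,
          out_csv)
  invisible(features)
}

#' Group-comparison report from a feature CSV
#'
#' Writes the feature comparison table as CSV and Markdown (one row per
#' shape x feature, medians/IQRs per group, Mann-Whitney p). The Markdown
#' footnote notes that p-values are uncorrected.
#'
#' @param features_csv Feature CSV path.
#' @param out_prefix Output path prefix (writes `<prefix>.csv`,
#'   `<prefix>.md`).
#' @return The comparison data.frame, invisibly.
#' @export
run_compare <- function(features_csv, out_prefix) {
  ct <- comparison_table(read_features(features_csv))
  utils::write.csv(ct, paste0(out_prefix, ".csv"), row.names = FALSE)
  md <- c("| Shape | Feature | non-CM median (IQR) | CM median (IQR) | p |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %.1f (%.1f-%.1f) | %.1f (%.1f-%.1f) | %.3g%s |",
                  ct$shape, ct$feature, ct$noncm_median, ct$noncm_q1,
                  ct$noncm_q3, ct$cm_median, ct$cm_q1, ct$cm_q3,
                  ct$p_value, ifelse(ct$significant, " *", "")),
          "", "Mann-Whitney U, two-sided, uncorrected; * p < 0.05.")
  writeLines(md, paste0(out_prefix, ".md"))
  invisible(ct)
}

#' Evaluate the screening models from a feature CSV
#'
#' Runs [cm_screen()] and serializes the full results (per model: shapes,
#' hyperparameters, mode, AUC, ROC vertices, operating point,
#' per-participant scores) to JSON.
#'
#' @param features_csv Feature CSV path.
#' @param config A `cm_config`.
#' @param out_json Destination JSON path.
#' @return The `cm_screen` fit, invisibly.
#' @export
run_evaluate <- function(features_csv, config = pipeline_config(),
                         out_json = "results.json") {
  features <- read_features(features_csv)
  fit <- cm_screen(features, grid = config$grid, mode = config$mode,
                   kernel = config$kernel,
                   normalization = config$normalization)
  out <- lapply(fit$results, function(r) list(
    shapes = r$model$shapes, mode = r$mode,
    hyperparams = r$hyperparams, normalization = r$normalization,
    auc = r$auc, operating_point = r$operating_point,
    roc = r$roc,
    scores = stats::setNames(as.list(r$scores), r$participant_id),
    labels = stats::setNames(as.list(as.character(r$labels)),
                             r$participant_id)))
  jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  log_msg("evaluate: %d models -> %s (best %s, AUC %.3f)",
          length(fit$results), out_json, fit$best, max(fit$table$auc))
  invisible(fit)
}

#' Markdown report and ROC CSVs from a results JSON
#'
#' One table row per model (sensitivity, specificity, AUC; best model in
#' bold) plus one `roc_<model>.csv` (`fpr,tpr,threshold`) per model.
#'
#' @param results_json JSON written by [run_evaluate()].
#' @param out_md Destination Markdown path.
#' @param roc_dir Directory for ROC CSVs (default: along `out_md`).
#' @return `out_md`, invisibly.
#' @export
run_report <- function(results_json, out_md, roc_dir = dirname(out_md)) {
  res <- jsonlite::read_json(results_json, simplifyVector = TRUE)
  if (length(res) == 0) stop_validation("malformed results: no models")
  aucs <- vapply(res, function(r) r$auc, numeric(1))
  best <- names(res)[which.max(aucs)]
  lines <- c("# Screening model report", "",
             sprintf("Mode: %s; normalization: %s.", res[[1]]$mode,
                     res[[1]]$normalization), "",
             "| Model | Sensitivity | Specificity | AUC |",
             "|---|---|---|---|")
  for (nm in names(res)) {
    r <- res[[nm]]
    lab <- if (nm == best) sprintf("**%s**", nm) else nm
    lines <- c(lines, sprintf("| %s | %.2f | %.2f | %.2f |", lab,
                              r$operating_point$sensitivity,
                              r$operating_point$specificity, r$auc))
    roc <- as.data.frame(r$roc)
    utils::write.csv(roc, file.path(roc_dir,
                                    sprintf("roc_%s.csv",
                                            gsub("\\+", "_", nm))),
                     row.names = FALSE)
  }
  lines <- c(lines, "", sprintf("Best model by AUC: **%s** (%.2f).", best,
                                max(aucs)))
  writeLines(lines, out_md)
  invisible(out_md)
}
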