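# Orchestration of the full analysis: simulate -> extract -> screen ->
# classify -> report, from a single declarative configuration, with every
# source of randomness derived from one master seed.

#' Pipeline configuration
#'
#' A single declarative object driving [run_pipeline()]. The input is either
#' a synthetic [cohort_spec()] or a directory containing NIfTI volumes and a
#' lesion table as written by [write_cohort()].
#'
#' @param spec a [cohort_spec()] for a synthetic run (ignored when
#'   `input_dir` is given).
#' @param input_dir directory with `<id>_T2.nii.gz`, `<id>_ADC.nii.gz` and
#'   `lesions.csv`.
#' @param scheme grouping scheme, `"three"` (default) or `"five"` (Gleason
#'   Grade Groups).
#' @param modes feature modes to extract; subset of
#'   `c("mean", "T2", "ADC")`. The first is the primary analysis table.
#' @param alpha family-wise significance level for the univariate screen.
#' @param n_trees,n_folds random-forest parameters, see [rf_config()].
#' @param n_train,n_test balanced hold-out sizes, see [holdout_rf()].
#' @param seed master seed for classification randomness (the synthetic
#'   cohort uses `spec$seed`).
#' @param out_dir output directory for the report bundle.
#' @param write_volumes also write the synthetic NIfTI volumes into
#'   `out_dir/cohort`? (Default `FALSE`; the feature tables are the record.)
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), input_dir = NULL,
                            scheme = c("three", "five"),
                            modes = c("mean", "T2", "ADC"),
                            alpha = 0.05, n_trees = 500L, n_folds = 5L,
                            n_train = 40L, n_test = 20L, seed = 1L,
                            out_dir = "radiomics_run",
                            write_volumes = FALSE) {
  scheme <- match.arg(scheme)
  modes <- match.arg(modes, several.ok = TRUE)
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  structure(
    list(spec = spec, input_dir = input_dir, scheme = scheme, modes = modes,
         alpha = alpha, n_trees = as.integer(n_trees),
         n_folds = as.integer(n_folds), n_train = as.integer(n_train),
         n_test = as.integer(n_test), seed = as.integer(seed),
         out_dir = out_dir, write_volumes = isTRUE(write_volumes)),
    class = "pipeline_config"
  )
}

# re-derive group labels under a grouping scheme from the stored score strings
set_group_scheme <- function(patients, scheme) {
  lapply(patients, function(p) {
    p$lesion <- lesion_record(p$lesion$patient_id, p$lesion$centroid,
                              p$lesion$gleason_score, scheme)
    p
  })
}

#' Read a cohort directory
#'
#' Loads every patient listed in `lesions.csv` from a directory of paired
#' `<id>_T2.nii.gz` / `<id>_ADC.nii.gz` volumes (the layout written by
#' [write_cohort()]).
#'
#' @param dir cohort directory.
#' @param scheme grouping scheme for [gleason_to_group()].
#' @return List of patients in the shape expected by [cohort_features()].
#' @export
read_cohort <- function(dir, scheme = c("three", "five")) {
  scheme <- match.arg(scheme)
  lesions <- read_lesion_table(file.path(dir, "lesions.csv"), scheme)
  lapply(lesions, function(les) {
    t2_path <- file.path(dir, paste0(les$patient_id, "_T2.nii.gz"))
    adc_path <- file.path(dir, paste0(les$patient_id, "_ADC.nii.gz"))
    structure(
      list(patient_id = les$patient_id,
           t2_volume = read_volume(t2_path, "T2"),
           adc_volume = read_volume(adc_path, "ADC"),
           lesion = les,
           true_group = les$group),
      class = "synthetic_patient")
  })
}

#' Write / read a feature table CSV
#'
#' The on-disk dialect is `patient_id, group`, then the 41 canonical feature
#' columns; the scaling state is recorded in a comment header line.
#'
#' @param tab a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(tab, path) {
  con <- file(path, "w")
  writeLines(sprintf("# radiomic feature table; scaled=%s",
                     isTRUE(attr(tab, "scaled"))), con)
  write.csv(as.data.frame(tab), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  first <- readLines(path, n = 1L)
  scaled <- grepl("scaled=TRUE", first, fixed = TRUE)
  tab <- read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  feature_table(as.matrix(tab[, setdiff(names(tab),
                                        c("patient_id", "group"))]),
                tab$patient_id, tab$group, scaled = scaled)
}

#' Run the full radiomic pipeline
#'
#' Executes every stage in order — simulate (or load), extract features per
#' mode, univariate screen, one-vs-rest classification (cross-validated and
#' held-out) with permutation importance, report — and writes a reproducible
#' bundle under `cfg$out_dir`:
#' \describe{
#'   \item{`features_<mode>.csv`}{per-mode feature tables.}
#'   \item{`univariate.csv`, `group_summary.csv`}{screen outputs.}
#'   \item{`classification.json`}{per-task CV and hold-out metrics.}
#'   \item{`importance.csv`}{features x tasks normalized permutation
#'     importance (primary mode).}
#'   \item{`roc_<task>.csv`, `confusion_<task>.csv`}{ROC points and pooled
#'     confusion matrices.}
#'   \item{`modality_comparison.csv`}{hold-out metrics per modality (when
#'     all of mean/T2/ADC are extracted).}
#'   \item{`summary.txt`, `MANIFEST.json`}{human-readable summary and a
#'     manifest stamped with the config hash and seeds.}
#' }
#' Outputs are pure functions of the configuration: a rerun with the same
#' config produces byte-identical tabular outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return An object of class `radiomic_run` with elements `tables`,
#'   `screen`, `cv`, `holdout`, `importance`, `modality`, `files`,
#'   `config_hash`, invisibly writable via the bundle.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character(0)

  # -- stage: simulate / load ------------------------------------------------
  patients <- withCallingHandlers(
    if (is.null(cfg$input_dir)) generate_cohort(cfg$spec)
    else read_cohort(cfg$input_dir, cfg$scheme),
    error = function(e) stop("stage simulate/load failed: ",
                             conditionMessage(e), call. = FALSE))
  if (cfg$scheme != "three") patients <- set_group_scheme(patients, cfg$scheme)
  if (cfg$write_volumes && is.null(cfg$input_dir)) {
    write_cohort(patients, file.path(out, "cohort"), overwrite = TRUE)
  }

  # -- stage: extract --------------------------------------------------------
  tables <- list()
  for (mode in cfg$modes) {
    tables[[mode]] <- tryCatch(
      cohort_features(patients, mode),
      error = function(e) stop("stage extract (", mode, ") failed: ",
                               conditionMessage(e), call. = FALSE))
    f <- file.path(out, sprintf("features_%s.csv", mode))
    write_feature_table(tables[[mode]], f)
    files <- c(files, f)
  }
  primary <- tables[[cfg$modes[1]]]

  # -- stage: screen ---------------------------------------------------------
  scr <- screen_features(primary, alpha = cfg$alpha)
  f1 <- file.path(out, "univariate.csv")
  write.csv(scr$table, f1, row.names = FALSE)
  f2 <- file.path(out, "group_summary.csv")
  write.csv(scr$group_summary, f2, row.names = FALSE)
  files <- c(files, f1, f2)

  # -- stage: classify -------------------------------------------------------
  rfc <- rf_config(cfg$n_trees, cfg$n_folds, seed = cfg$seed)
  targets <- sort(unique(primary$group))
  cv <- list(); ho <- list(); imp <- NULL
  can_holdout <- all(vapply(targets, function(tg) {
    n_pos <- sum(primary$group == tg)
    n_pos >= (cfg$n_train + cfg$n_test) %/% 2 &&
      nrow(primary) - n_pos >= (cfg$n_train + cfg$n_test) %/% 2
  }, logical(1)))
  for (tg in targets) {
    key <- paste0("G", tg)
    cv[[key]] <- crossval_rf(primary, tg, rfc)
    imp <- cbind(imp, permutation_importance(cv[[key]]))
    if (can_holdout) ho[[key]] <- holdout_rf(primary, tg, cfg$n_train,
                                             cfg$n_test, rfc)
    fr <- file.path(out, sprintf("roc_G%s.csv", tg))
    write.csv(roc_points(cv[[key]]$oof_scores, cv[[key]]$labels), fr,
              row.names = FALSE)
    fc <- file.path(out, sprintf("confusion_G%s.csv", tg))
    write.csv(as.data.frame(cv[[key]]$confusion), fc)
    files <- c(files, fr, fc)
  }
  colnames(imp) <- paste0("G", targets, "-vs-rest")
  f3 <- file.path(out, "importance.csv")
  write.csv(data.frame(feature = rownames(imp), imp, check.names = FALSE),
            f3, row.names = FALSE)
  files <- c(files, f3)

  modality <- NULL
  if (all(c("mean", "T2", "ADC") %in% names(tables)) && can_holdout) {
    modality <- run_modality_comparison(tables[c("mean", "T2", "ADC")], rfc,
                                        cfg$n_train, cfg$n_test)
    f4 <- file.path(out, "modality_comparison.csv")
    write.csv(modality$metrics, f4, row.names = FALSE)
    files <- c(files, f4)
  }

  metrics_json <- list(
    seed = cfg$seed,
    tasks = lapply(cv, function(z) {
      entry <- list(task = z$task,
                    cv_mean = as.list(z$mean_metrics),
                    cv_folds = z$fold_metrics)
      h <- ho[[paste0("G", z$target)]]
      if (!is.null(h)) entry$holdout <- h$metrics
      entry
    })
  )
  f5 <- file.path(out, "classification.json")
  jsonlite::write_json(metrics_json, f5, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f5)

  # -- stage: report ---------------------------------------------------------
  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)

  f6 <- file.path(out, "summary.txt")
  sink(f6)
  cat("Radiomic pipeline run\n")
  cat("config hash:", config_hash, " master seed:", cfg$seed, "\n")
  cat("defaults in effect: Ng=32, ROI 21x21x3, GLCM 13 directions distance 1",
      "symmetric, GLSZM 26-connected, Holm families: separate,",
      sprintf("RF %d trees / %d folds\n", cfg$n_trees, cfg$n_folds))
  cat("\n")
  print(scr)
  cat("\n")
  for (z in cv) print(z)
  if (length(ho)) { cat("\n"); for (z in ho) print(z) }
  sink()
  files <- c(files, f6)

  manifest <- list(config_hash = config_hash, seed = cfg$seed,
                   scheme = cfg$scheme, modes = cfg$modes,
                   files = basename(files))
  f7 <- file.path(out, "MANIFEST.json")
  jsonlite::write_json(manifest, f7, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f7)

  structure(
    list(tables = tables, screen = scr, cv = cv, holdout = ho,
         importance = imp, modality = modality, files = files,
         config_hash = config_hash, cfg = cfg),
    class = "radiomic_run"
  )
}

#' @export
print.radiomic_run <- function(x, ...) {
  cat("Radiomic pipeline run (config", substr(x$config_hash, 1, 8), ")\n")
  cat("Outputs in", x$cfg$out_dir, ":", length(x$files), "files\n\n")
  print(x$screen)
  cat("\n")
  for (z in x$cv) print(z)
  invisible(x)
}
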