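#' Run the full subtyping analysis as a staged, file-based pipeline
#'
#' Executes the configured stages in order, each reading only the files
#' earlier stages wrote into `outdir`, so any stage can be re-run or
#' audited standalone. A JSON run manifest (config snapshot, master seed,
#' derived per-stage seeds, package version, input digests, per-stage
#' outputs and wall-clock) fully determines re-execution.
#'
#' Stages: `simulate` (synthetic cohort; or ingestion of `matrix_path` /
#' `clinical_path` / `series_path` when `data: files`), `cluster`
#' (consensus BMF + Ward cut), `diagnose_k` (K-range diagnostics),
#' `enrich` (per-cluster Fisher/BH table), `train` (subtype classifier),
#' `survival` (staging, evolving flags, KM/log-rank/Cox/C-index),
#' `report` (markdown summary).
#'
#' @param config path to a YAML/JSON config file, or an equivalent named
#'   list. Recognized fields: `data` ("synthetic"/"files"), `stages`,
#'   `n_patients`, `n_subtypes`, `K`, `n_runs`, `K_range`,
#'   `matrix_path`, `clinical_path`, `series_path`, `search_iters`.
#' @param outdir artifact directory (created).
#' @param seed master seed; every stochastic stage uses a seed derived
#'   from it.
#' @param verbose log stage progress.
#' @return `outdir`, invisibly; the manifest is at
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config, outdir = "smm_run", seed = 1L, verbose = TRUE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  defaults <- list(data = "synthetic", n_patients = 214L, n_subtypes = 6L,
                   K = 6L, n_runs = 100L, K_range = 2:8, search_iters = 10L,
                   stages = c("simulate", "cluster", "enrich", "train",
                              "survival", "report"))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  known <- c("simulate", "cluster", "diagnose_k", "enrich", "train",
             "survival", "report")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- stats::setNames(
    vapply(seq_along(known), function(i) derive_seed(seed, 9000L + i), 1L), known)
  manifest <- list(config = cfg, seed = seed, stage_seeds = as.list(stage_seeds),
                   package_version = as.character(utils::packageVersion("smmsubtype")),
                   inputs = list(), stages = list())
  path_of <- function(f) file.path(outdir, f)

  for (stage in cfg$stages) {
    t0 <- Sys.time()
    smm_log(sprintf("[%s] running", stage), verbose = verbose)
    outputs <- switch(
      stage,
      simulate = {
        if (identical(cfg$data, "files")) {
          for (p in c(cfg$matrix_path, cfg$clinical_path, cfg$series_path)) {
            if (!is.null(p)) {
              manifest$inputs[[p]] <- unname(tools::md5sum(p))
            }
          }
          X <- read_alteration_matrix(cfg$matrix_path)
          write_alteration_matrix(X, path_of("alteration_matrix.tsv"))
          if (!is.null(cfg$clinical_path)) {
            file.copy(cfg$clinical_path, path_of("clinical.csv"), overwrite = TRUE)
          }
          if (!is.null(cfg$series_path)) {
            file.copy(cfg$series_path, path_of("biomarker_series.csv"), overwrite = TRUE)
          }
        } else {
          cohort <- generate_cohort(cohort_config(
            n_patients = cfg$n_patients, n_subtypes = cfg$n_subtypes,
            seed = stage_seeds[["simulate"]]))
          write_cohort(cohort, outdir)
          utils::write.table(
            data.frame(patient_id = names(cohort$true_labels),
                       subtype = unname(cohort$true_labels)),
            path_of("true_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        }
        c("alteration_matrix.tsv", "clinical.csv", "biomarker_series.csv")
      },
      cluster = {
        X <- read_alteration_matrix(path_of("alteration_matrix.tsv"))
        fit <- bmf_subtype(X, K = cfg$K, n_runs = cfg$n_runs,
                           seed = stage_seeds[["cluster"]])
        utils::write.table(
          data.frame(patient_id = names(fit$labels), K = cfg$K,
                     label = unname(fit$labels)),
          path_of("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(fit$consensus$consensus, path_of("consensus.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)
        c("labels.tsv", "consensus.tsv")
      },
      diagnose_k = {
        X <- read_alteration_matrix(path_of("alteration_matrix.tsv"))
        diag <- k_diagnostics(X, K_range = cfg$K_range, n_runs = cfg$n_runs,
                              seed = stage_seeds[["diagnose_k"]])
        sel <- select_k(diag)
        utils::write.table(diag$summary, path_of("k_diagnostics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(K_selected = sel$K, rationale = sel$rationale),
                             path_of("k_selection.json"), auto_unbox = TRUE,
                             digits = NA, dataframe = "rows")
        c("k_diagnostics.tsv", "k_selection.json")
      },
      enrich = {
        X <- read_alteration_matrix(path_of("alteration_matrix.tsv"))
        lab <- utils::read.table(path_of("labels.tsv"), header = TRUE, sep = "\t")
        enr <- enrich_clusters(X, lab$label)
        write_enrichment(enr, path_of("enrichment.tsv"))
        "enrichment.tsv"
      },
      train = {
        X <- read_alteration_matrix(path_of("alteration_matrix.tsv"))
        lab <- utils::read.table(path_of("labels.tsv"), header = TRUE, sep = "\t")
        model <- train_subtype_classifier(X, lab$label,
                                          seed = stage_seeds[["train"]],
                                          search_iters = cfg$search_iters)
        save_subtype_model(model, path_of("subtype_model.rds"))
        pred <- predict(model, X)
        write_predictions(pred, path_of("predictions.tsv"))
        jsonlite::write_json(list(cv_accuracy_mean = model$cv_accuracy_mean,
                                  cv_accuracy_sd = model$cv_accuracy_sd),
                             path_of("classifier_cv.json"), auto_unbox = TRUE,
                             digits = NA)
        c("subtype_model.rds", "predictions.tsv", "classifier_cv.json")
      },
      survival = {
        cl <- read_clinical_table(path_of("clinical.csv"))
        ser <- read_biomarker_series(path_of("biomarker_series.csv"))
        st <- stage_20_2_20(cl$m_protein_baseline, cl$flc_ratio, cl$bmpc_percent)
        cl$clinical_stage <- st$stage
        evo <- detect_evolving_cohort(ser)
        cl <- merge(cl[setdiff(names(cl), c("emp", "ehb"))], evo,
                    by = "patient_id", sort = FALSE)
        km <- km_fit(cl$ttp_months, cl$progressed, cl$risk_group)
        lr <- logrank_test(cl$ttp_months, cl$progressed, cl$risk_group)
        base <- cox_fit(data.frame(clinical_stage = cl$clinical_stage),
                        cl$ttp_months, cl$progressed)
        ext <- cox_fit(data.frame(clinical_stage = cl$clinical_stage,
                                  genetic_risk = factor(cl$risk_group,
                                    levels = c("low", "intermediate", "high"))),
                       cl$ttp_months, cl$progressed)
        cmp <- compare_cox_models(base, ext)
        assoc <- biomarker_association(cl$emp, cl$risk_group)
        utils::write.table(km$curves, path_of("km_curves.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(ext$table, path_of("cox_summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(
          km_medians = km$medians, logrank = lr,
          model_comparison = cmp[c("lr_chisq", "df", "p", "c_base",
                                   "c_extended", "delta_c")],
          emp_association = assoc[c("odds_ratio", "ci_low", "ci_high", "p")]),
          path_of("survival_summary.json"), auto_unbox = TRUE, digits = NA,
          dataframe = "rows")
        c("km_curves.tsv", "cox_summary.tsv", "survival_summary.json")
      },
      report = {
        pipeline_report(outdir)
        "report.md"
      }
    )
    manifest$stages[[stage]] <- list(
      outputs = as.list(outputs),
      seconds = as.numeric(Sys.time() - t0, units = "secs"))
  }
  jsonlite::write_json(manifest, path_of("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(outdir)
}

#' Summarize a completed pipeline run
#'
#' Pure re-formatting of existing artifacts (no recomputation): cluster
#' sizes, top enriched features per cluster, K diagnostics when present,
#' risk-group KM medians and the model comparison, written as
#' `report.md` in the run directory. Re-invocation yields identical files.
#'
#' @param dir a [run_pipeline()] artifact directory.
#' @return path to `report.md`, invisibly.
#' @export
pipeline_report <- function(dir) {
  need <- c("labels.tsv", "enrichment.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing pipeline artifact(s): ", paste(missing, collapse = ", "))
  }
  lines <- c("# Subtyping run report", "")
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t")
  sizes <- table(lab$label)
  lines <- c(lines, "## Cluster sizes", "",
             sprintf("- cluster %s: %d patients", names(sizes), as.integer(sizes)), "")
  enr <- utils::read.table(file.path(dir, "enrichment.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  lines <- c(lines, "## Top enriched features per cluster", "")
  for (k in sort(unique(enr$cluster))) {
    d <- enr[enr$cluster == k & enr$enriched, , drop = FALSE]
    top <- utils::head(d$feature, 5L)
    lines <- c(lines, sprintf("- cluster %d: %s", k,
                              if (length(top)) paste(top, collapse = ", ")
                              else "(none at q < 0.1)"))
  }
  lines <- c(lines, "")
  kd_path <- file.path(dir, "k_diagnostics.tsv")
  if (file.exists(kd_path)) {
    kd <- utils::read.table(kd_path, header = TRUE, sep = "\t")
    lines <- c(lines, "## K diagnostics", "",
               paste(utils::capture.output(print(kd, row.names = FALSE)),
                     collapse = "\n"), "")
  }
  sv_path <- file.path(dir, "survival_summary.json")
  if (file.exists(sv_path)) {
    sv <- jsonlite::read_json(sv_path, simplifyVector = TRUE)
    med <- sv$km_medians
    lines <- c(lines, "## Survival by genetic risk group", "",
               sprintf("- %s: median TTP %.1f months", med$group, med$median),
               sprintf("- log-rank chi-square %.2f (p = %.2g)",
                       sv$logrank$chisq, sv$logrank$p),
               sprintf("- C-index: clinical %.3f vs clinical+genetic %.3f (LR p = %.2g)",
                       sv$model_comparison$c_base, sv$model_comparison$c_extended,
                       sv$model_comparison$p), "")
  }
  cv_path <- file.path(dir, "classifier_cv.json")
  if (file.exists(cv_path)) {
    cv <- jsonlite::read_json(cv_path, simplifyVector = TRUE)
    lines <- c(lines, "## Classifier", "",
               sprintf("- CV accuracy %.3f (sd %.3f)", cv$cv_accuracy_mean,
                       cv$cv_accuracy_sd), "")
  }
  out <- file.path(dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
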