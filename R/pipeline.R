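# End-to-end orchestration: simulate -> label -> extract -> train ->
# report, with on-disk artifacts between stages so any stage can be rerun
# from its upstream outputs.

#' Run the shock-prediction pipeline
#'
#' Executes the requested stage(s) against a synthetic cohort and writes
#' stage artifacts under `out_dir`: a cohort manifest and exclusion log,
#' a windows manifest, the feature table (CSV with a JSON catalog
#' sidecar), the mutual-information selection, per-model evaluation
#' reports, the importance ranking of the best model and the
#' logistic-confirmation odds-ratio table. Every artifact set carries a
#' config sidecar (with seed and config hash), making a run reproducible
#' from its sidecar alone.
#'
#' Patients are processed one at a time (simulate, label, extract,
#' discard), so cohort size is bounded by time rather than memory.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param command One of `simulate`+labeling (`"label"`), `"extract"`,
#'   `"train"`, `"report"` or `"all"`. Downstream commands require the
#'   upstream artifacts in `out_dir`.
#' @param k Number of features kept by the selection step.
#' @param seed Seed for the modeling stages (splitting, learners,
#'   bootstrap); the generator uses `config$seed`.
#' @param lactate_op `">="` or `">"`, the lactate-threshold comparison.
#' @param scenario_preference `"1"` or `"2"`.
#' @param n_boot Bootstrap replicates for the evaluation stage.
#' @param progress Log per-patient progress.
#' @return Invisible list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, command = "all",
                         k = 65, seed = 1L, lactate_op = ">=",
                         scenario_preference = "1", n_boot = 1000,
                         progress = FALSE) {
  command <- match.arg(command,
                       c("all", "label", "extract", "train", "report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_meta <- list(seed = config$seed, model_seed = seed, k = k,
                   lactate_op = lactate_op,
                   scenario_preference = scenario_preference,
                   n_patients = config$n_patients,
                   shock_fraction = config$shock_fraction,
                   config_hash = .config_hash(config))
  jsonlite::write_json(cfg_meta, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list()

  if (command %in% c("all", "label", "extract")) {
    manifest <- list(); excl <- list(); feats <- list(); winlist <- list()
    for (i in seq_len(config$n_patients)) {
      sim <- simulate_patient(config, i)
      if (progress) message("patient ", i, "/", config$n_patients)
      lab <- label_record(sim$record, lactate_op = lactate_op,
                          scenario_preference = scenario_preference)
      chk <- apply_exclusions(list(list(record = sim$record,
                                        event = lab$event,
                                        windows = lab$windows)))
      excl[[i]] <- chk$log
      manifest[[i]] <- data.frame(
        patient_id = sim$record$patient_id,
        shock_truth = sim$truth$shock,
        onset_truth = if (isTRUE(sim$truth$shock)) sim$truth$onset
                      else NA_real_,
        onset_detected = if (!is.null(lab$event)) lab$event$onset
                         else NA_real_,
        included = nrow(chk$log) && chk$log$status[1] == "included")
      if (length(chk$included)) {
        winlist[[i]] <- lab$windows
        if (command != "label")
          feats[[i]] <- extract_cohort_features(chk$included)
      }
    }
    manifest <- do.call(rbind, manifest)
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, excl), file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    windows <- do.call(rbind, winlist)
    write.csv(windows, file.path(out_dir, "windows.csv"),
              row.names = FALSE)
    res$manifest <- manifest
    res$windows <- windows
    if (command != "label") {
      features <- do.call(rbind, feats)
      write.csv(features, file.path(out_dir, "features.csv"),
                row.names = FALSE)
      write_catalog_manifest(shock_catalog(),
                             file.path(out_dir, "catalog.json"))
      res$features <- features
    }
  }
  if (command %in% c("label", "extract")) return(invisible(res))

  if (command %in% c("train", "report") && is.null(res$features)) {
    fp <- file.path(out_dir, "features.csv")
    if (!file.exists(fp))
      stop("missing upstream artifact: ", fp, " (run 'extract' first)")
    res$features <- read.csv(fp)
  }

  res <- c(res, .train_and_report(res$features, out_dir, k = k,
                                  seed = seed, n_boot = n_boot))
  invisible(res)
}

# Modeling stages on an extracted feature table.
.train_and_report <- function(features, out_dir, k = 65, seed = 1L,
                              n_boot = 1000) {
  cat <- shock_catalog()
  feat_cols <- cat$all
  meta_cols <- setdiff(names(features), feat_cols)
  # drop features with too few observed values to impute, then complete
  obs <- colSums(!is.na(features[feat_cols]))
  usable <- feat_cols[obs >= 2]
  imputed <- impute_chained(features[usable], seed = seed)
  tab <- cbind(features[meta_cols], imputed)

  split <- patient_split(unique(tab$patient_id), seed = seed)
  tab$set <- split[tab$patient_id]
  stopifnot(!anyNA(tab$set))
  train <- tab[tab$set == "train", ]
  val <- tab[tab$set == "validation", ]
  test <- tab[tab$set == "test", ]

  ranking <- mutual_information_rank(train[usable], train$label)
  feats <- select_top_k(ranking, min(k, nrow(ranking)))
  write.csv(data.frame(rank = seq_along(feats), feature = feats),
            file.path(out_dir, "selection.csv"), row.names = FALSE)

  bench <- fit_models(train, val, feats, seed = seed)
  bench <- build_weighted_ensemble(bench)

  reports <- lapply(bench$models, evaluate_model, rows = test,
                    n_boot = n_boot, seed = seed)
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$model,
               accuracy_pct = 100 * r$metrics["accuracy"],
               sensitivity_pct = 100 * r$metrics["sensitivity"],
               specificity_pct = 100 * r$metrics["specificity"],
               auc = r$metrics["auc"], row.names = NULL)))
  write.csv(summary, file.path(out_dir, "model_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r)
      list(model = r$model, metrics = as.list(r$metrics),
           ci = list(lower = as.list(ci <- r$ci[1, ]),
                     upper = as.list(r$ci[2, ])),
           confusion = as.vector(r$confusion))),
    file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)

  best <- summary$model[which.max(summary$auc)]
  best_model <- bench$models[[best]]
  imp <- importance_report(best_model, test, feats = feats, seed = seed)
  write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)

  ors <- logistic_confirmation(tab, head(feats, 20))
  write.csv(ors, file.path(out_dir, "odds_ratios.csv"), row.names = FALSE)

  list(split = split, ranking = ranking, selected = feats, bench = bench,
       reports = reports, summary = summary, best_model = best,
       importance = imp, odds_ratios = ors)
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "drift")],
                        auto_unbox = TRUE, digits = 10)
  s <- paste0(s, jsonlite::toJSON(unclass(config$drift), auto_unbox = TRUE,
                                  digits = 10))
  # small rolling hash; avoids a digest dependency
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
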