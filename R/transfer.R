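## Transfer of fused loadings (and comparator feature sets) to downstream
## binary classification of diagnosis pairs and carrier status.

#' Default pairwise classification tasks
#'
#' The three diagnosis pairs macro-averaged in the metric battery, plus
#' carrier status.
#'
#' @return named list; each element has `label` (phenotype column) and
#'   `classes` (negative, positive) or NULL for a binary column.
#' @export
default_tasks <- function() {
  list(
    CN_vs_MCI = list(label = "diagnosis", classes = c("CN", "MCI_SCD")),
    CN_vs_mild = list(label = "diagnosis", classes = c("CN", "mild")),
    MCI_vs_mild = list(label = "diagnosis", classes = c("MCI_SCD", "mild")),
    carrier = list(label = "carrier", classes = NULL)
  )
}

#' Run the transfer-classification study
#'
#' For each feature set and each binary task, fits an L1-logistic
#' classifier on the training split (lambda by stratified inner CV),
#' reports cross-validated training metrics and held-out test metrics with
#' bootstrap confidence intervals, and records the selected features.
#' Diagnosis metrics are macro-averaged over the three pairwise tasks.
#' Loadings-like feature sets are harmonized across scanners first
#' (harmonization fit on the training split only, applied everywhere).
#' Tasks with an empty class in a split are reported as skipped, never
#' dropped silently.
#'
#' @param dataset a `multimodal_dataset`.
#' @param model a fitted `fusion_model` (or NULL to evaluate only
#'   `feature_sets`).
#' @param split a [grouped_split()] assignment.
#' @param feature_sets optional named list of `feature_set` objects; by
#'   default the fused loadings plus [build_comparators()].
#' @param tasks task list as in [default_tasks()].
#' @param B bootstrap resamples for the test-metric confidence intervals.
#' @param seed integer seed.
#' @param harmonize harmonize every multivariate feature set across
#'   `scanner` before classification (demographics are left untouched).
#' @param n_components comparator decomposition size.
#' @param cv_metrics also compute cross-validated training metrics (out-of
#'   -fold predictions on the training split); disable for quick studies.
#' @return object of class `classification_report`.
#' @export
run_transfer_study <- function(dataset, model = NULL, split,
                               feature_sets = NULL,
                               tasks = default_tasks(),
                               B = 500, seed = 1, harmonize = TRUE,
                               n_components = 10, cv_metrics = TRUE) {
  pheno <- dataset$pheno
  train <- which(split$split == "train")
  test <- which(split$split == "test")

  if (is.null(feature_sets)) {
    feature_sets <- build_comparators(dataset, split,
                                      n_components = n_components,
                                      seed = seed)
    if (!is.null(model)) {
      Z_all <- project_subjects(model, dataset$X)
      feature_sets <- c(list(fused_loadings = new_feature_set(
        "fused_loadings", Z_all,
        list(K = model$K, source = "ridge projection of fitted maps"))),
        feature_sets)
    }
  }

  ## scanner harmonization, fit on training rows only; if a scanner level
  ## is entirely absent from the training split, fall back to fitting on
  ## all subjects (with a warning) so held-out subjects stay adjustable
  if (harmonize) {
    fit_rows <- train
    if (!all(unique(pheno$scanner) %in% pheno$scanner[train])) {
      warning("scanner level absent from the training split; ",
              "harmonization fit on all subjects")
      fit_rows <- seq_len(nrow(pheno))
    }
    for (nm in names(feature_sets)) {
      if (nm == "demographics") next
      fs <- feature_sets[[nm]]
      cm <- fit_combat(fs$matrix[fit_rows, , drop = FALSE],
                       pheno$scanner[fit_rows])
      fs$matrix <- apply_combat(cm, fs$matrix, pheno$scanner)
      fs$provenance$harmonized <- "scanner (EB location-scale)"
      feature_sets[[nm]] <- fs
    }
  }

  results <- list()
  for (fs_name in names(feature_sets)) {
    fs <- feature_sets[[fs_name]]
    task_out <- list()
    for (task_name in names(tasks)) {
      tk <- tasks[[task_name]]
      lab <- pheno[[tk$label]]
      if (is.null(tk$classes)) {
        keep <- !is.na(lab)
        y <- as.integer(lab)
      } else {
        keep <- lab %in% tk$classes
        y <- as.integer(lab == tk$classes[2])
      }
      tr <- intersect(which(keep), train)
      te <- intersect(which(keep), test)
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
        task_out[[task_name]] <- list(skipped = TRUE,
                                      reason = "empty class in a split")
        next
      }
      fit <- fit_lasso_logistic(fs$matrix[tr, , drop = FALSE], y[tr],
                                seed = seed)
      ## cross-validated training metrics from out-of-fold predictions
      cvm <- NULL
      if (cv_metrics) {
        kf <- max(3L, min(5L, min(table(y[tr]))))
        fold <- stratified_folds(y[tr], kf, seed + 17L)
        cv_scores <- numeric(length(tr))
        cv_ok <- TRUE
        for (f in seq_len(kf)) {
          in_f <- fold == f
          if (length(unique(y[tr][!in_f])) < 2) { cv_ok <- FALSE; break }
          fcv <- fit_lasso_logistic(fs$matrix[tr[!in_f], , drop = FALSE],
                                    y[tr][!in_f], seed = seed + f)
          cv_scores[in_f] <- predict(fcv, fs$matrix[tr[in_f], , drop = FALSE])
        }
        cvm <- if (cv_ok) evaluate_binary(cv_scores, y[tr]) else NULL
      }
      test_scores <- predict(fit, fs$matrix[te, , drop = FALSE])
      test_metrics <- evaluate_binary(test_scores, y[te])
      ci <- list(
        auroc = bootstrap_ci("auroc", test_scores, y[te], B = B, seed = seed),
        auprc = bootstrap_ci("auprc", test_scores, y[te], B = B, seed = seed)
      )
      task_out[[task_name]] <- list(
        skipped = FALSE, n_train = length(tr), n_test = length(te),
        selected = fit$selected,
        selected_names = colnames(fs$matrix)[fit$selected],
        lambda = fit$lambda,
        cv_metrics = cvm, test_metrics = test_metrics,
        test_ci = ci, test_scores = test_scores, test_labels = y[te])
    }
    diag_tasks <- setdiff(names(tasks), "carrier")
    done <- Filter(function(t) !isTRUE(task_out[[t]]$skipped), diag_tasks)
    macro <- if (length(done)) {
      macro_average(lapply(task_out[done], `[[`, "test_metrics"))
    } else NULL
    results[[fs_name]] <- list(tasks = task_out, macro_test = macro)
  }
  structure(list(feature_sets = names(feature_sets), results = results,
                 tasks = tasks, B = B, seed = seed,
                 harmonized = harmonize),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report:", length(x$results), "feature sets x",
      length(x$tasks), "tasks\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    mac <- if (!is.null(r$macro_test))
      sprintf("macro AUROC %.3f", r$macro_test[["auroc"]]) else "macro n/a"
    carrier <- r$tasks$carrier
    carr <- if (!is.null(carrier) && !isTRUE(carrier$skipped))
      sprintf(", carrier AUROC %.3f", carrier$test_metrics[["auroc"]]) else ""
    cat(sprintf("  %-18s %s%s\n", nm, mac, carr))
  }
  invisible(x)
}

#' Write a classification report to JSON and a Table-2-shaped TSV
#'
#' @param report a `classification_report`.
#' @param json_path,tsv_path output files (either may be NULL).
#' @return invisibly, the summary data.frame written to `tsv_path`.
#' @export
write_classification_report <- function(report, json_path = NULL,
                                        tsv_path = NULL) {
  rows <- list()
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    for (tn in names(r$tasks)) {
      tk <- r$tasks[[tn]]
      if (isTRUE(tk$skipped)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_set = nm, task = tn, skipped = TRUE,
          auroc = NA, auroc_lo = NA, auroc_hi = NA, auprc = NA,
          balanced_accuracy_cv = NA)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = nm, task = tn, skipped = FALSE,
        auroc = tk$test_metrics[["auroc"]],
        auroc_lo = tk$test_ci$auroc[["lower"]],
        auroc_hi = tk$test_ci$auroc[["upper"]],
        auprc = tk$test_metrics[["auprc"]],
        balanced_accuracy_cv = if (is.null(tk$cv_metrics)) NA else
          tk$cv_metrics[["balanced_accuracy"]])
    }
    if (!is.null(r$macro_test)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = nm, task = "macro_diagnosis", skipped = FALSE,
        auroc = r$macro_test[["auroc"]], auroc_lo = NA, auroc_hi = NA,
        auprc = r$macro_test[["auprc"]], balanced_accuracy_cv = NA)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tsv_path)) data.table::fwrite(tab, tsv_path, sep = "\t")
  if (!is.null(json_path)) {
    slim <- lapply(report$results, function(r) {
      list(macro_test = as.list(r$macro_test),
           tasks = lapply(r$tasks, function(tk) {
             if (isTRUE(tk$skipped)) return(tk)
             tk$test_scores <- NULL; tk$test_labels <- NULL
             tk$cv_metrics <- as.list(tk$cv_metrics)
             tk$test_metrics <- as.list(tk$test_metrics)
             tk
           }))
    })
    jsonlite::write_json(slim, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(tab)
}
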