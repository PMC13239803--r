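## End-to-end pipeline orchestration: simulate/ingest -> split -> fit ->
## project -> harmonize -> threshold -> classify -> validate, each stage
## writing plain-text artifacts plus a manifest line with a checksum.

.known_stage_keys <- list(
  simulate = c("N", "M", "features_m", "K_true", "sparsity", "snr",
               "n_sites", "n_scanners", "beta_support", "target_mean",
               "target_sd", "target_r2", "carrier_component",
               "carrier_slope", "carrier_prevalence", "batch_gamma_sd",
               "batch_delta_sd", "csf_fraction", "csf_r_abeta",
               "csf_r_ptau", "seed"),
  dataset = c("dir"),
  split = c("fractions", "seed"),
  fit = c("K", "gamma", "lambda1", "lr", "lr_decay", "batch_size", "epochs",
          "patience", "seed"),
  threshold = c("mmthresh"),
  classify = c("B", "n_components", "seed"),
  validate = c("component")
)
.stochastic_stages <- c("simulate", "split", "fit", "classify")

#' Validate a pipeline configuration
#'
#' Rejects unknown stages or keys and requires an explicit seed for every
#' stochastic stage that is present.
#'
#' @param config nested list, or path to a YAML file with the same shape.
#' @return the validated config (class `run_config`), invisibly usable by
#'   [run_pipeline()].
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(.known_stage_keys))
  if (length(unknown)) {
    stop("unknown config stage(s): ", paste(unknown, collapse = ", "))
  }
  for (stage in names(config)) {
    bad <- setdiff(names(config[[stage]]), .known_stage_keys[[stage]])
    if (length(bad)) {
      stop("unknown key(s) in stage '", stage, "': ",
           paste(bad, collapse = ", "))
    }
    if (stage %in% .stochastic_stages &&
        is.null(config[[stage]][["seed"]])) {
      stop("stage '", stage, "' is stochastic and needs an explicit seed")
    }
  }
  if (is.null(config$simulate) && is.null(config$dataset)) {
    stop("config needs either a 'simulate' or a 'dataset' stage")
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing every artifact as
#' plain text (TSV/JSON) under `out_dir` along with `manifest.tsv`
#' (stage, file, md5 checksum, seed). Re-running an unchanged config
#' reproduces the checksums of all deterministic artifacts. A stage
#' failure halts the run with the stage name attached.
#'
#' @param config a config accepted by [validate_config()].
#' @param out_dir output directory.
#' @return invisible list with the main in-memory artifacts (dataset,
#'   split, model, loadings, screen, report) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path, seed = NA) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), seed = seed)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- data ----------------------------------------------------------
  dataset <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(simulation_config, config$simulate)
      ds <- generate_dataset(cfg)
      write_dataset(ds, file.path(out_dir, "dataset"))
      ds
    } else {
      read_dataset(config$dataset$dir)
    }
  })
  for (f in list.files(file.path(out_dir, "dataset"), full.names = TRUE)) {
    note("simulate", f, config$simulate$seed %||% NA)
  }

  ## --- split ---------------------------------------------------------
  split <- run_stage("split", {
    fr <- config$split$fractions %||% c(train = 0.7, val = 0.15, test = 0.15)
    fr <- stats::setNames(as.numeric(fr),
                          names(fr) %||% c("train", "val", "test"))
    grouped_split(dataset$pheno$site, fr, seed = config$split$seed)
  })
  sp_path <- file.path(out_dir, "split.tsv")
  data.table::fwrite(data.frame(subject_id = dataset$pheno$subject_id,
                                split = as.character(split$split)),
                     sp_path, sep = "\t")
  note("split", sp_path, config$split$seed)

  ## --- fit + project --------------------------------------------------
  fitcfg <- config$fit
  ctl <- fusion_control(
    gamma = fitcfg$gamma %||% 1, lambda1 = fitcfg$lambda1 %||% 1e-3,
    lr = fitcfg$lr %||% 0.02, batch_size = fitcfg$batch_size %||% 64,
    epochs = fitcfg$epochs %||% 2000, patience = fitcfg$patience %||% 50,
    seed = fitcfg$seed)
  model <- run_stage("fit",
                     fit_fusion(dataset, split, K = fitcfg$K, control = ctl))
  mdir <- file.path(out_dir, "model")
  write_fusion_model(model, mdir)
  for (f in list.files(mdir, full.names = TRUE)) note("fit", f, fitcfg$seed)

  loadings <- run_stage("project", project_subjects(model, dataset$X))
  ld_path <- file.path(out_dir, "loadings.tsv")
  data.table::fwrite(cbind(data.frame(subject_id = rownames(loadings)),
                           as.data.frame(loadings)), ld_path, sep = "\t")
  note("project", ld_path)

  ## --- harmonize ------------------------------------------------------
  train <- which(split$split == "train")
  harm <- run_stage("harmonize", {
    fit_rows <- train
    if (!all(unique(dataset$pheno$scanner) %in%
             dataset$pheno$scanner[train])) {
      warning("scanner level absent from the training split; ",
              "harmonization fit on all subjects")
      fit_rows <- seq_len(nrow(dataset$pheno))
    }
    cm <- fit_combat(loadings[fit_rows, , drop = FALSE],
                     dataset$pheno$scanner[fit_rows])
    apply_combat(cm, loadings, dataset$pheno$scanner)
  })
  hz_path <- file.path(out_dir, "loadings_harmonized.tsv")
  data.table::fwrite(cbind(data.frame(subject_id = rownames(loadings)),
                           as.data.frame(harm)), hz_path, sep = "\t")
  note("harmonize", hz_path)

  ## --- threshold ------------------------------------------------------
  mm <- config$threshold$mmthresh %||% 0.5
  masks <- run_stage("threshold", {
    lapply(seq_along(model$S), function(m) {
      apply(model$S[[m]], 2L, function(col) {
        threshold_map(fit_mixture(col), mmthresh = mm)$mask
      })
    })
  })
  for (m in seq_along(masks)) {
    mp <- file.path(out_dir, paste0("mask_", model$modalities[m], ".tsv"))
    data.table::fwrite(as.data.frame(masks[[m]] * 1L), mp, sep = "\t")
    note("threshold", mp)
  }

  ## --- classify -------------------------------------------------------
  report <- run_stage("classify", {
    ds2 <- dataset
    run_transfer_study(ds2, model, split,
                       B = config$classify$B %||% 500,
                       seed = config$classify$seed %||% 1,
                       n_components = config$classify$n_components %||% 10)
  })
  rp_json <- file.path(out_dir, "classification_report.json")
  rp_tsv <- file.path(out_dir, "classification_table.tsv")
  write_classification_report(report, rp_json, rp_tsv)
  note("classify", rp_json, config$classify$seed %||% 1)
  note("classify", rp_tsv, config$classify$seed %||% 1)

  ## --- validate -------------------------------------------------------
  screen <- run_stage("validate",
                      correlation_screen(harm, dataset$pheno$target))
  sc_path <- file.path(out_dir, "correlation_screen.tsv")
  data.table::fwrite(as.data.frame(screen), sc_path, sep = "\t")
  note("validate", sc_path)

  man <- do.call(rbind, manifest)
  data.table::fwrite(man, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(list(dataset = dataset, split = split, model = model,
                 loadings = loadings, harmonized = harm, masks = masks,
                 report = report, screen = screen, manifest = man))
}

#' Write a fitted fusion model as a plain-text bundle
#'
#' JSON metadata plus one TSV per matrix; [read_fusion_model()] restores
#' numerically identical matrices.
#'
#' @param model a `fusion_model`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fusion_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, path) {
    ## %.17g round-trips IEEE doubles exactly (bit-identical read-back)
    m <- as.matrix(m)
    ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    data.table::fwrite(data.table::as.data.table(ch), path, sep = "\t")
  }
  wr(model$Z, file.path(dir, "Z.tsv"))
  for (i in seq_along(model$S)) {
    wr(model$S[[i]], file.path(dir, paste0("S_", model$modalities[i], ".tsv")))
    wr(rbind(center = model$std[[i]]$center, scale = model$std[[i]]$scale),
       file.path(dir, paste0("std_", model$modalities[i], ".tsv")))
  }
  wr(do.call(rbind, model$W), file.path(dir, "W.tsv"))
  wr(rbind(c(model$b0, model$beta)), file.path(dir, "head.tsv"))
  num17 <- function(v) sprintf("%.17g", v)  # exact numeric round trip
  meta <- list(
    K = model$K, modalities = model$modalities, P = model$P,
    a_m = num17(model$a_m),
    train_rownames = rownames(model$Z),
    degenerate = model$degenerate,
    init_loss = model$init_loss, final_loss = model$final_loss,
    best_epoch = model$best_epoch,
    control = lapply(unclass(model$control), function(v)
      if (is.numeric(v)) num17(v) else v)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fusion model bundle written by [write_fusion_model()]
#' @param dir bundle directory.
#' @return a `fusion_model` (training history is not round-tripped).
#' @export
read_fusion_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  rd <- function(path) unname(as.matrix(data.table::fread(path)))
  Z <- rd(file.path(dir, "Z.tsv"))
  rownames(Z) <- meta$train_rownames
  colnames(Z) <- paste0("C", seq_len(meta$K))
  S <- lapply(meta$modalities, function(m)
    rd(file.path(dir, paste0("S_", m, ".tsv"))))
  Wmat <- rd(file.path(dir, "W.tsv"))
  W <- lapply(seq_len(nrow(Wmat)), function(i) Wmat[i, ])
  head_v <- as.vector(rd(file.path(dir, "head.tsv")))
  std <- lapply(meta$modalities, function(m) {
    sm <- rd(file.path(dir, paste0("std_", m, ".tsv")))
    list(center = sm[1, ], scale = sm[2, ])
  })
  names(std) <- meta$modalities
  ctl_args <- meta$control[intersect(names(formals(fusion_control)),
                                     names(meta$control))]
  ctl_args <- lapply(ctl_args, function(v)
    if (is.character(v)) as.numeric(v) else v)
  ctl_args <- ctl_args[!vapply(ctl_args, function(v)
    length(v) == 0 || all(is.na(v)), logical(1))]
  ctl <- do.call(fusion_control, ctl_args)
  structure(list(Z = Z, S = S, W = W, beta = head_v[-1], b0 = head_v[1],
                 K = meta$K, std = std, a_m = as.numeric(meta$a_m),
                 modalities = meta$modalities, P = meta$P,
                 train_idx = NULL, val_idx = NULL, history = NULL,
                 init_loss = meta$init_loss, final_loss = meta$final_loss,
                 best_epoch = meta$best_epoch,
                 degenerate = meta$degenerate, control = ctl),
            class = "fusion_model")
}
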