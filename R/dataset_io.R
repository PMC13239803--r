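#' Write a multimodal dataset bundle to a directory
#'
#' One TSV per modality (first column `subject_id`, then one column per
#' feature), a phenotype TSV, and — when ground truth is present and
#' `with_truth` is TRUE — a JSON sidecar with the generating parameters.
#'
#' @param dataset a `multimodal_dataset`.
#' @param dir output directory (created if missing).
#' @param with_truth write the ground-truth JSON sidecar if available.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, with_truth = TRUE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(dataset$X)) {
    dt <- data.table::data.table(subject_id = rownames(dataset$X[[m]]))
    dt <- cbind(dt, data.table::as.data.table(dataset$X[[m]]))
    data.table::fwrite(dt, file.path(dir, paste0("modality_", m, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(dataset$pheno, file.path(dir, "phenotype.tsv"),
                     sep = "\t")
  if (with_truth && !is.null(dataset$truth)) {
    tr <- dataset$truth
    payload <- list(
      loadings_true = unname(tr$loadings_true),
      maps_true = lapply(tr$maps_true, unname),
      modality_weights_true = unname(tr$modality_weights_true),
      beta_true = tr$beta_true,
      noise_sd_per_modality = tr$noise_sd_per_modality,
      empirical_snr = tr$empirical_snr,
      batch_gamma = lapply(tr$batch_gamma, function(g)
        list(levels = rownames(g), values = unname(g))),
      batch_delta = lapply(tr$batch_delta, function(g)
        list(levels = rownames(g), values = unname(g))),
      carrier_component_index = tr$carrier_component_index,
      carrier_intercept = tr$carrier_intercept,
      target_noise_sd = tr$target_noise_sd,
      target_r_ceiling = tr$target_r_ceiling
    )
    jsonlite::write_json(payload, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a multimodal dataset bundle written by [write_dataset()]
#'
#' @param dir bundle directory.
#' @return a `multimodal_dataset` (with `truth` if the sidecar is present;
#'   matrix-valued truth fields are restored, dimension names on truth
#'   matrices are not).
#' @export
read_dataset <- function(dir) {
  mod_files <- sort(list.files(dir, pattern = "^modality_.*\\.tsv$"))
  if (!length(mod_files)) stop("no modality TSVs found in ", dir)
  pheno <- as.data.frame(data.table::fread(file.path(dir, "phenotype.tsv")))
  X <- list()
  for (f in mod_files) {
    m <- sub("^modality_(.*)\\.tsv$", "\\1", f)
    dt <- data.table::fread(file.path(dir, f))
    mat <- as.matrix(dt[, -1])
    rownames(mat) <- dt[[1]]
    if (!identical(rownames(mat), pheno$subject_id)) {
      stop("subject order mismatch between ", f, " and phenotype.tsv")
    }
    X[[m]] <- mat
  }
  ## restore the canonical modality order if recognizable
  canon <- c("GM", "CT", "PSA", "AMY", "TAU")
  if (all(names(X) %in% canon)) X <- X[intersect(canon, names(X))]
  truth <- NULL
  tf <- file.path(dir, "ground_truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = FALSE)
    as_mat <- function(x) do.call(rbind, lapply(x, function(r)
      unlist(r, use.names = FALSE)))
    as_num <- function(x) unlist(x, use.names = FALSE)
    truth <- list(
      loadings_true = as_mat(tj$loadings_true),
      maps_true = lapply(tj$maps_true, as_mat),
      modality_weights_true = as_mat(tj$modality_weights_true),
      beta_true = as_num(tj$beta_true),
      noise_sd_per_modality = as_num(tj$noise_sd_per_modality),
      empirical_snr = as_num(tj$empirical_snr),
      batch_gamma = lapply(tj$batch_gamma, function(g) {
        v <- as_mat(g$values); rownames(v) <- as_num(g$levels); v
      }),
      batch_delta = lapply(tj$batch_delta, function(g) {
        v <- as_mat(g$values); rownames(v) <- as_num(g$levels); v
      }),
      carrier_component_index = tj$carrier_component_index,
      carrier_intercept = tj$carrier_intercept,
      target_noise_sd = tj$target_noise_sd,
      target_r_ceiling = tj$target_r_ceiling
    )
  }
  structure(list(X = X, pheno = pheno, truth = truth, config = NULL),
            class = "multimodal_dataset")
}
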