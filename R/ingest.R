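## Optional ingestion of voxel/vertex-wise NIfTI volumes into the
## pipeline's subjects-by-features matrix form, and export back.

#' Ingest per-subject NIfTI volumes into a modality matrix
#'
#' Reads one volume per subject, checks that all grids match, applies an
#' inclusion mask and returns one row per subject and one column per
#' in-mask voxel. Feature IDs encode the linear voxel index so a matrix
#' row can be exported back into a volume.
#'
#' @param paths character vector of NIfTI file paths (one per subject).
#' @param mask logical/0-1 array matching the volume grid, or a path to a
#'   mask volume; NULL keeps every voxel.
#' @return matrix with rownames from file names and colnames `vox<index>`;
#'   the mask and grid dimensions are attached as attributes.
#' @export
ingest_neuro_volumes <- function(paths, mask = NULL) {
  vols <- lapply(paths, function(p) {
    v <- tryCatch(RNifti::readNifti(p),
                  error = function(e) stop("unreadable volume: ", p))
    as.array(v)
  })
  dims <- lapply(vols, dim)
  ref <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], ref)) {
      stop("grid mismatch between ", paths[1], " (", paste(ref, collapse = "x"),
           ") and ", paths[i], " (", paste(dims[[i]], collapse = "x"), ")")
    }
  }
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  if (is.null(mask)) mask <- array(TRUE, ref)
  if (!identical(dim(mask), ref)) stop("mask dimensions do not match volumes")
  keep <- which(as.logical(mask))
  X <- t(vapply(vols, function(v) as.vector(v)[keep], numeric(length(keep))))
  rownames(X) <- basename(paths)
  colnames(X) <- paste0("vox", keep)
  attr(X, "grid_dim") <- ref
  attr(X, "mask_index") <- keep
  X
}

#' Export one matrix row back into a NIfTI volume
#'
#' Inverse of [ingest_neuro_volumes()] for a single subject: in-mask
#' voxels receive the row's values, everything else `fill`.
#'
#' @param values numeric vector (one matrix row) aligned with the mask.
#' @param grid_dim integer volume dimensions.
#' @param mask_index linear indices of in-mask voxels.
#' @param path output NIfTI path.
#' @param fill value for out-of-mask voxels.
#' @return `path`, invisibly.
#' @export
export_neuro_volume <- function(values, grid_dim, mask_index, path,
                                fill = 0) {
  vol <- array(fill, grid_dim)
  vol[mask_index] <- values
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
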