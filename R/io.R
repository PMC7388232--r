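#' Persist voxel fields, deformations and models
#'
#' Fields and fitted models are serialized with R's native format (RDS),
#' which round-trips every attribute including attached signed distances.
#' Voxel fields can additionally be exported to NIfTI (a standard 3D volume
#' format readable by most imaging toolchains) when the \pkg{RNifti}
#' package is available.
#'
#' @param x A \code{vox_field}, \code{deformation_field},
#'   \code{average_model}, \code{elastic_pca} or \code{cultivar_model}.
#' @param path Output path (\code{.rds}, or \code{.nii}/\code{.nii.gz} for
#'   voxel-field export).
#' @return \code{path}, invisibly.
#' @export
write_field <- function(x, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!inherits(x, "vox_field"))
      stop("write_field: NIfTI export supports vox_field objects")
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("write_field: the RNifti package is required for NIfTI export")
    n <- x$grid$n
    img <- array(x$values, dim = c(n, n, n))
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = rep(x$grid$h, 3)), path)
  } else {
    saveRDS(x, path)
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("read_field: the RNifti package is required for NIfTI import")
    img <- RNifti::readNifti(path)
    n <- dim(img)[1]
    vals <- as.numeric(img)
    kind <- if (all(vals %in% c(0, 1))) "occupancy" else "signed_distance"
    vox_field(vals, grid3(n), kind = kind)
  } else {
    readRDS(path)
  }
}
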