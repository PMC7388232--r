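#' Five scalar shape traits of a root
#'
#' Root length (vertical extent along the z growth axis), width (maximal
#' horizontal extent), surface area, volume, and complexity (surface /
#' volume). The mesh path uses exact triangle-mesh area and enclosed volume;
#' the voxel path uses interface-face area and node-count volume. The path
#' used is recorded in \code{attr(,"path")}.
#'
#' @param shape A \code{tri_mesh} or an occupancy \code{vox_field}.
#' @return Named numeric vector \code{length, width, surface, volume,
#'   complexity}.
#' @export
compute_traits <- function(shape) {
  if (inherits(shape, "tri_mesh")) {
    bb <- mesh_bbox(shape)
    len <- unname(bb[2, 3] - bb[1, 3])
    wid <- unname(max(bb[2, 1] - bb[1, 1], bb[2, 2] - bb[1, 2]))
    surf <- mesh_area(shape)
    vol <- mesh_volume(shape)
    path <- "mesh"
  } else if (inherits(shape, "vox_field")) {
    if (shape$kind != "occupancy")
      stop("compute_traits: voxel input must be an occupancy field")
    mask <- shape$values > 0.5
    if (!any(mask)) stop("compute_traits: empty shape")
    n <- shape$grid$n
    h <- shape$grid$h
    xyz <- grid_nodes(shape$grid)[mask, , drop = FALSE]
    len <- diff(range(xyz[, 3])) + h
    wid <- max(diff(range(xyz[, 1])), diff(range(xyz[, 2]))) + h
    a <- array(mask, dim = c(n, n, n))
    faces <- sum(a[1:(n - 1), , ] != a[2:n, , ]) +
             sum(a[, 1:(n - 1), ] != a[, 2:n, ]) +
             sum(a[, , 1:(n - 1)] != a[, , 2:n])
    surf <- faces * h^2
    vol <- sum(mask) * h^3
    path <- "voxel"
  } else {
    stop("compute_traits: expected a tri_mesh or vox_field")
  }
  if (vol <= 0) stop("compute_traits: degenerate shape (zero volume)")
  out <- c(length = len, width = wid, surface = surf, volume = vol,
           complexity = surf / vol)
  attr(out, "path") <- path
  out
}

#' Euclidean PCA of the five-trait baseline
#'
#' Standardizes each trait to zero mean and unit variance and
#' eigendecomposes the correlation matrix — the simplified comparison
#' baseline for the elastic shape PCA. Constant trait columns are dropped
#' with a warning.
#'
#' @param traits Matrix or data frame with one row per sample and the five
#'   trait columns.
#' @return A \code{trait_pca} object: \code{scores}, \code{loadings},
#'   \code{variances} (summing to the number of retained traits),
#'   \code{center}, \code{scale}, \code{kept}.
#' @export
trait_pca <- function(traits) {
  X <- as.matrix(traits)
  if (nrow(X) < 3) stop("trait_pca: need at least 3 samples")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("trait_pca: dropping constant trait(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variances = pc$sdev^2, center = ctr, scale = sds,
                 kept = colnames(X)),
            class = "trait_pca")
}

#' Project new samples into a fitted trait-PCA space
#'
#' @param pca A \code{trait_pca}.
#' @param traits New trait rows.
#' @return Score matrix.
#' @export
trait_scores <- function(pca, traits) {
  X <- as.matrix(traits)[, pca$kept, drop = FALSE]
  Z <- scale(X, center = pca$center, scale = pca$scale)
  Z %*% pca$loadings
}

# nearest-centroid classification in the leading trait-PCA components
trait_nearest_centroid <- function(pca, train_labels, test_traits,
                                   n_comp = 2L) {
  n_comp <- min(n_comp, ncol(pca$scores))
  tr <- pca$scores[, seq_len(n_comp), drop = FALSE]
  centroids <- rowsum(tr, train_labels) / as.numeric(table(train_labels))
  te <- trait_scores(pca, test_traits)[, seq_len(n_comp), drop = FALSE]
  d2 <- outer(rowSums(te^2), rowSums(centroids^2), "+") -
        2 * te %*% t(centroids)
  rownames(centroids)[apply(d2, 1, which.min)]
}
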