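#' Train a cultivar model from an ensemble of shapes
#'
#' Builds the class average, its elastic PCA and the pieces the extended
#' Mahalanobis distance needs: the training displacements spanning the class
#' subspace \eqn{U_j}, the Hessian metric \eqn{g_j}, the retained modes and
#' variances, the truncation \eqn{M_j} and the residual regularization
#' \eqn{\beta}.
#'
#' @param label Class label.
#' @param ensemble List of volume-normalized occupancy \code{vox_field}s.
#' @param params \code{elastic_params}.
#' @param M Mahalanobis truncation (default 13, capped at the number of
#'   retained modes).
#' @param beta Residual regularization weight (default 1e-5).
#' @param match_iter Per-level iteration cap for all matching solves of
#'   this model, including later embeddings (default 300).
#' @param ... Passed to \code{\link{elastic_average}}.
#' @return A \code{cultivar_model}.
#' @export
cultivar_model <- function(label, ensemble, params = elastic_params(),
                           M = 13L, beta = 1e-5, match_iter = 300L, ...) {
  if (beta <= 0) stop("cultivar_model: beta must be > 0")
  avg <- elastic_average(ensemble, params, match_iter = match_iter, ...)
  pca <- elastic_pca(avg, match_iter = match_iter)
  M <- as.integer(min(M, pca$n_retained))
  if (M < 1L) stop("cultivar_model: no retained modes")
  Umat <- sapply(pca$displacements, as_column)
  G <- gram_matrix(pca$displacements, pca$metric) * length(pca$displacements)
  structure(list(label = label, average = avg, pca = pca,
                 metric = pca$metric, M = M, beta = beta,
                 U = Umat, G = G, params = params,
                 match_iter = as.integer(match_iter)),
            class = "cultivar_model")
}

#' @export
print.cultivar_model <- function(x, ...) {
  cat(sprintf("<cultivar_model> '%s': %d training shapes, M=%d, beta=%g\n",
              x$label, ncol(x$U), x$M, x$beta))
  invisible(x)
}

#' Embed a shape as a displacement relative to a class average
#'
#' The shape is matched to the class average in the same direction as the
#' training matches (shape onto average), the boundary stress of the
#' deformation is evaluated on the average surface, converted to a
#' displacement through the class's equilibrium solve, and centered with the
#' training mean — the identical path that produced the training
#' displacements, so a training sample embeds onto (approximately) its own
#' training displacement.
#'
#' @param shape Volume-normalized occupancy \code{vox_field} on the model's
#'   grid.
#' @param model A \code{cultivar_model}.
#' @param recenter Centroid-align the shape first (default TRUE, matching
#'   the averaging gauge).
#' @return A \code{deformation_field}; the underlying \code{match_result}
#'   is attached as \code{attr(,"match")}.
#' @export
embed_shape <- function(shape, model, recenter = TRUE) {
  stopifnot(inherits(model, "cultivar_model"))
  if (shape$grid$n != model$average$average$grid$n)
    stop("embed_shape: grid mismatch for class '", model$label, "'")
  if (recenter) shape <- recenter_field(shape)
  mi <- if (is.null(model$match_iter)) 300L else model$match_iter
  mr <- tryCatch(
    match_shapes(shape, model$average$average, model$params,
                 max_iter = mi),
    error = function(e)
      stop("embed_shape: matching against class '", model$label,
           "' failed: ", conditionMessage(e)))
  trac <- boundary_stress(mr$deformation, model$average)
  u <- stress_to_displacement(trac, model$metric)
  u <- deformation_field(u$displacement - model$pca$mean_displacement,
                         u$grid)
  attr(u, "match") <- mr
  u
}

#' Classical truncated Mahalanobis distance (squared)
#'
#' \eqn{m_j^2(u) = \sum_{k \le M} g_j(u, w_k^j)^2 / \lambda_k^j} over the
#' class's g-orthonormal modes; deviations along dominant modes are
#' penalized least, and any displacement g-orthogonal to the retained modes
#' scores zero.
#'
#' @param u Displacement (\code{deformation_field} or vector).
#' @param model A \code{cultivar_model}.
#' @param M Truncation (default the model's \code{M}).
#' @return Non-negative scalar.
#' @export
mahalanobis_sq <- function(u, model, M = model$M) {
  stopifnot(inherits(model, "cultivar_model"))
  if (M > model$pca$n_retained)
    stop("mahalanobis_sq: M exceeds the retained modes")
  uv <- as_column(u)
  Hu <- as.numeric(model$metric$H %*% uv)
  proj <- as.numeric(crossprod(model$pca$modes[, seq_len(M), drop = FALSE],
                               Hu))
  sum(proj^2 / model$pca$variances[model$pca$retained][seq_len(M)])
}

#' Extended Mahalanobis distance (squared) with residual regularization
#'
#' \eqn{d_j^2(u) = m_j^2(P_j u) + \frac{1}{\beta} g_j(u - P_j u, u - P_j u)}
#' where \eqn{P_j} is the g-orthogonal projection onto the span of the
#' class's training displacements (computed through the training Gram system
#' with a pseudo-inverse cutoff for rank deficiency).
#'
#' @param u Displacement (\code{deformation_field} or vector).
#' @param model A \code{cultivar_model}.
#' @return List: \code{total}, \code{mahalanobis}, \code{residual}.
#' @export
extended_distance_sq <- function(u, model) {
  stopifnot(inherits(model, "cultivar_model"))
  uv <- as_column(u)
  Hu <- as.numeric(model$metric$H %*% uv)
  b <- as.numeric(crossprod(model$U, Hu))
  eg <- eigen(model$G, symmetric = TRUE)
  pos <- eg$values > 1e-10 * max(eg$values, .Machine$double.eps)
  coef <- eg$vectors[, pos, drop = FALSE] %*%
    ((crossprod(eg$vectors[, pos, drop = FALSE], b)) / eg$values[pos])
  Pu <- as.numeric(model$U %*% coef)
  res <- uv - Pu
  mah <- mahalanobis_sq(Pu, model)
  rg <- as.numeric(res %*% (model$metric$H %*% res))
  rg <- max(rg, 0)
  list(total = mah + rg / model$beta, mahalanobis = mah,
       residual = rg / model$beta)
}

#' Classify a shape against a set of cultivar models
#'
#' Embeds the shape against every model independently, computes all extended
#' Mahalanobis distances and assigns the label of the minimal one; exact
#' ties go to the lowest class index.
#'
#' @param shape Volume-normalized occupancy \code{vox_field}.
#' @param models List of \code{cultivar_model}s on a common grid.
#' @return A \code{classification_result}: \code{label}, \code{distances}
#'   (per-class totals), \code{parts} (Mahalanobis and residual parts), and
#'   \code{average_only} (the baseline matching objectives, see
#'   \code{\link{average_only_distance}}).
#' @export
classify_shape <- function(shape, models) {
  if (length(models) < 2) stop("classify_shape: need at least 2 models")
  labels <- vapply(models, `[[`, "", "label")
  dists <- numeric(length(models))
  avg_only <- numeric(length(models))
  parts <- vector("list", length(models))
  for (j in seq_along(models)) {
    u <- embed_shape(shape, models[[j]])
    dd <- extended_distance_sq(u, models[[j]])
    dists[j] <- dd$total
    parts[[j]] <- dd
    avg_only[j] <- attr(u, "match")$objective
  }
  names(dists) <- labels
  names(avg_only) <- labels
  best <- which.min(dists)  # which.min already takes the first on ties
  structure(list(label = labels[best], distances = dists, parts = parts,
                 average_only = avg_only,
                 average_only_label = labels[which.min(avg_only)]),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> assigned '%s'\n", x$label))
  print(signif(x$distances, 4))
  invisible(x)
}

#' Average-only baseline distance
#'
#' Ignores the principal modes: the distance of a shape to a class is the
#' converged total matching objective (elastic energy plus mismatch penalty)
#' between the class average and the shape.
#'
#' @param shape Volume-normalized occupancy \code{vox_field}.
#' @param model A \code{cultivar_model} (or \code{average_model}).
#' @param recenter Centroid-align the shape first (default TRUE).
#' @return Non-negative scalar.
#' @export
average_only_distance <- function(shape, model, recenter = TRUE) {
  avg <- if (inherits(model, "cultivar_model")) model$average else model
  stopifnot(inherits(avg, "average_model"))
  if (recenter) shape <- recenter_field(shape)
  mi <- if (inherits(model, "cultivar_model") && !is.null(model$match_iter))
    model$match_iter else 300L
  match_shapes(shape, avg$average, avg$params, max_iter = mi)$objective
}

#' Confusion matrix and per-class rates
#'
#' @param predicted Character vector of assigned labels.
#' @param truth Character vector of true labels (same length).
#' @param levels Optional label ordering.
#' @return List: \code{counts} (rows = truth, columns = assigned),
#'   \code{rates} (row-normalized), \code{accuracy}.
#' @export
confusion_matrix <- function(predicted, truth, levels = NULL) {
  if (length(predicted) != length(truth))
    stop("confusion_matrix: length mismatch between predictions and labels")
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, levels = levels),
                  factor(predicted, levels = levels))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  rates <- sweep(counts, 1, pmax(rs, 1), "/")
  list(counts = counts, rates = rates,
       accuracy = sum(diag(counts)) / max(sum(counts), 1))
}
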