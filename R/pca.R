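#' Boundary stress representative of a matching deformation
#'
#' Replaces the nonlinear deformation \eqn{\phi_i : O_i \to \bar O} by its
#' linear representative: the traction
#' \deqn{\sigma_i = W'((D\phi_i^{-1})^{-1})\,(\det D\phi_i^{-1})\,
#'       (D\phi_i^{-1})^{-T}\,\nu}
#' evaluated on the average surface with outward normal \eqn{\nu}. With
#' \eqn{F = D\phi_i} at the preimage \eqn{x = \phi_i^{-1}(y)} this equals
#' \eqn{\sigma_i(y) = \det(F)^{-1} W'(F) F^T \nu(y)}; the preimage is found
#' by fixed-point iteration on the displacement, avoiding an explicit global
#' inverse. Surface samples are the centers of grid cells crossed by the
#' average interface; normals come from the gradient of the average's signed
#' distance; per-sample area weights use the interface delta approximation
#' \eqn{|\nabla\chi_s| h^3}.
#'
#' @param phi A \code{deformation_field} mapping an input onto the average.
#' @param average An \code{average_model} (or an occupancy \code{vox_field}
#'   with attached signed distance).
#' @return A \code{surface_traction}: \code{points}, \code{normals},
#'   \code{tractions}, \code{weights}.
#' @export
boundary_stress <- function(phi, average) {
  chi <- average_field(average)
  stopifnot(inherits(phi, "deformation_field"))
  n <- chi$grid$n
  if (phi$grid$n != n) stop("boundary_stress: grid mismatch")
  surf <- average_surface(chi)
  # evaluate half a voxel inside the surface: the preimage then sits in
  # interior cells where the det barrier was enforced, keeping the
  # interpolated gradient well-conditioned
  pts_in <- surf$points - 0.5 * chi$grid$h * surf$normals
  pre <- cpp_invert_disp(phi$displacement, n, pts_in, 10L)
  Fs <- cpp_def_grad_at(phi$displacement, n, pre)
  np <- nrow(surf$points)
  trac <- matrix(0, np, 3)
  pars <- if (inherits(average, "average_model")) average$params
          else elastic_params()
  clamped <- 0L
  sv_lo <- 0.05
  sv_hi <- 20
  for (q in seq_len(np)) {
    F <- matrix(Fs[q, ], 3, 3, byrow = TRUE)
    # interpolated gradients near partially occupied boundary cells can
    # degenerate (the det barrier holds at cell centers only); repair
    # orientation and truly extreme principal stretches via the signed SVD,
    # absorbing reflections into the rotation factors
    sv <- svd(F)
    U <- sv$u %*% diag(c(1, 1, det(sv$u)))
    V <- sv$v %*% diag(c(1, 1, det(sv$v)))
    s <- sv$d
    s[3] <- s[3] * det(sv$u) * det(sv$v)
    if (any(s < sv_lo) || any(s > sv_hi)) {
      clamped <- clamped + 1L
      F <- U %*% diag(pmin(pmax(s, sv_lo), sv_hi)) %*% t(V)
    }
    d <- det(F)
    P <- pk_stress(F, pars)
    trac[q, ] <- (P %*% (t(F) %*% surf$normals[q, ])) / d
  }
  if (clamped > 0.5 * np)
    stop("boundary_stress: ill-conditioned deformation gradients at ",
         clamped, " of ", np, " surface samples")
  # robust winsorization: a single runaway sample would otherwise inject a
  # spurious rank-one mode into the downstream PCA
  mags <- sqrt(rowSums(trac^2))
  cap <- 10 * stats::median(mags)
  if (is.finite(cap) && cap > 0) {
    over <- mags > cap
    if (any(over)) trac[over, ] <- trac[over, ] * (cap / mags[over])
  }
  structure(list(points = surf$points, normals = surf$normals,
                 tractions = trac, weights = surf$weights, grid = chi$grid),
            class = "surface_traction")
}

average_field <- function(average) {
  if (inherits(average, "average_model")) average$average
  else if (inherits(average, "vox_field")) average
  else stop("expected an average_model or vox_field")
}

# surface sample points (interface cell centers), outward normals from the
# signed distance gradient, and area weights |grad chi_s| h^3
average_surface <- function(chi) {
  n <- chi$grid$n
  h <- chi$grid$h
  sdf <- field_sdf_values(chi)
  a <- array(sdf, dim = c(n, n, n))
  lo <- 1:(n - 1); hi <- 2:n
  cmin <- pmin(a[lo, lo, lo], a[hi, lo, lo], a[lo, hi, lo], a[hi, hi, lo],
               a[lo, lo, hi], a[hi, lo, hi], a[lo, hi, hi], a[hi, hi, hi])
  cmax <- pmax(a[lo, lo, lo], a[hi, lo, lo], a[lo, hi, lo], a[hi, hi, lo],
               a[lo, lo, hi], a[hi, lo, hi], a[lo, hi, hi], a[hi, hi, hi])
  iface <- which(cmin < 0 & cmax >= 0)
  if (!length(iface)) stop("average_surface: no interface cells")
  centers <- grid_cell_centers(chi$grid)[iface, , drop = FALSE]
  # outward normal = -grad(d)/|grad d| under positive-inside convention
  eps_pts <- function(dim, s) {
    p <- centers
    p[, dim] <- p[, dim] + s * h / 2
    pmin(pmax(p, 0), 1)
  }
  g <- sapply(1:3, function(dim)
    (cpp_resample(sdf, n, eps_pts(dim, 1), 0) -
     cpp_resample(sdf, n, eps_pts(dim, -1), 0)) / h)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm < 1e-12] <- 1
  normals <- -g / nrm
  s <- if (chi$sign_convention == "negative_inside") -1 else 1
  if (s < 0) normals <- -normals
  # interface delta: |grad chi_s| at the cell center
  chis <- smooth_chi_values(sdf, chi$grid, chi$sign_convention)
  gs <- sapply(1:3, function(dim)
    (cpp_resample(chis, n, eps_pts(dim, 1), 0) -
     cpp_resample(chis, n, eps_pts(dim, -1), 0)) / h)
  weights <- sqrt(rowSums(gs^2)) * h^3
  list(points = centers, normals = normals, weights = weights,
       cells = iface)
}

#' Displacement induced by a boundary traction on the average
#'
#' Solves the linearized elastic equilibrium on the average body: the energy
#' Hessian at the identity applied to \eqn{u} balances the boundary load,
#' with the six-dimensional infinitesimal-rigid-motion kernel projected out
#' of load and solution. The load distributes each traction sample (times
#' its area weight) to the corner nodes of its interface cell.
#'
#' @param traction A \code{surface_traction}.
#' @param metric An \code{elastic_metric} assembled on the average.
#' @return A \code{deformation_field} holding the displacement.
#' @export
stress_to_displacement <- function(traction, metric) {
  stopifnot(inherits(traction, "surface_traction"),
            inherits(metric, "elastic_metric"))
  n <- metric$n
  if (traction$grid$n != n) stop("stress_to_displacement: grid mismatch")
  N <- n^3
  load <- numeric(3 * N)
  h <- metric$grid$h
  pts <- traction$points
  ci <- pmin(pmax(floor(pts[, 1] / h), 0), n - 2)
  cj <- pmin(pmax(floor(pts[, 2] / h), 0), n - 2)
  ck <- pmin(pmax(floor(pts[, 3] / h), 0), n - 2)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (a in 1:8) {
    nid <- (ci + corners[a, 1]) + n * (cj + corners[a, 2]) +
           n^2 * (ck + corners[a, 3]) + 1L
    for (p in 1:3) {
      idx <- nid + N * (p - 1L)
      add <- traction$tractions[, p] * traction$weights / 8
      agg <- rowsum(add, idx)
      load[as.integer(rownames(agg))] <-
        load[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  deformation_field(solve_equilibrium(metric, load), metric$grid)
}

#' Center a set of displacement fields
#'
#' Subtracts the mean displacement from each field so the set sums to zero,
#' mirroring the centered data matrix of vector-space PCA.
#'
#' @param displacements List of \code{deformation_field}s (or matrices).
#' @return List of centered fields with the mean in \code{attr(,"mean")}.
#' @export
center_displacements <- function(displacements) {
  if (length(displacements) < 2)
    stop("center_displacements: need at least 2 displacements")
  mats <- lapply(displacements, function(u)
    if (inherits(u, "deformation_field")) u$displacement else u)
  mean_u <- Reduce(`+`, mats) / length(mats)
  out <- lapply(displacements, function(u) {
    if (inherits(u, "deformation_field"))
      deformation_field(u$displacement - mean_u, u$grid)
    else u - mean_u
  })
  attr(out, "mean") <- mean_u
  out
}

# coerce a displacement (deformation_field / matrix / vector) to a column
as_column <- function(u) {
  if (inherits(u, "deformation_field")) as.numeric(u$displacement)
  else as.numeric(u)
}

# evaluate the metric: elastic_metric object, "euclidean", or a function
metric_dot <- function(metric) {
  if (inherits(metric, "elastic_metric"))
    function(U) crossprod(U, as.matrix(metric$H %*% U))
  else if (identical(metric, "euclidean"))
    function(U) crossprod(U)
  else if (is.function(metric))
    function(U) {
      m <- ncol(U)
      G <- matrix(0, m, m)
      for (i in 1:m) for (j in i:m)
        G[i, j] <- G[j, i] <- metric(U[, i], U[, j])
      G
    }
  else stop("unsupported metric")
}

#' Gram matrix of displacements under a metric
#'
#' \eqn{C_{ij} = \frac{1}{m} g(u_i, u_j)}; symmetric positive semi-definite.
#'
#' @param displacements List of displacement fields (or numeric vectors for
#'   a Euclidean surrogate).
#' @param metric An \code{elastic_metric}, \code{"euclidean"}, or a function
#'   \code{(u, v) -> scalar}.
#' @return An \code{m x m} matrix.
#' @export
gram_matrix <- function(displacements, metric) {
  m <- length(displacements)
  if (m < 2) stop("gram_matrix: need at least 2 displacements")
  U <- sapply(displacements, as_column)
  G <- metric_dot(metric)(U)
  C <- as.matrix(G) / m
  (C + t(C)) / 2
}

#' Principal modes of shape variation from a Gram matrix
#'
#' Spectral decomposition \eqn{C = Q \Lambda Q^T} of the Gram matrix; the
#' modes are assembled from the displacements as
#' \eqn{w_j \propto \sum_i q_j^i u_i} and rescaled to be g-orthonormal
#' (so that the classifier identity \eqn{m_j^2(w_k) = 1/\lambda_k} holds
#' exactly). Modes with \eqn{\lambda_j < 10^{-12}\lambda_1} are dropped.
#'
#' @param displacements List of displacement fields or numeric vectors
#'   (centered; see \code{\link{center_displacements}}).
#' @param metric Metric as in \code{\link{gram_matrix}}.
#' @param drop_tol Relative eigenvalue cutoff (default 1e-12).
#' @return A \code{pca_model}: \code{gram}, \code{variances} (sorted
#'   descending), \code{Q}, \code{modes} (columns, g-orthonormal),
#'   \code{n_retained}.
#' @export
principal_modes <- function(displacements, metric, drop_tol = 1e-12) {
  m <- length(displacements)
  U <- sapply(displacements, as_column)
  C <- gram_matrix(displacements, metric)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- which(lam > drop_tol * max(lam, .Machine$double.eps))
  modes <- matrix(0, nrow(U), length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    # g(sum q_i u_i, same) = m * lambda_j  =>  normalize by sqrt(m lambda_j)
    modes[, jj] <- (U %*% eg$vectors[, j]) / sqrt(m * lam[j])
  }
  structure(list(gram = C, variances = lam, Q = eg$vectors, modes = modes,
                 retained = keep, n_retained = length(keep)),
            class = "pca_model")
}

#' Elastic PCA of an averaged ensemble
#'
#' Full path from an \code{average_model} to principal modes: boundary
#' stresses of the matching deformations, stress-induced displacements of
#' the average, centering, Gram matrix under the Hessian metric, and the
#' spectral decomposition.
#'
#' @param average An \code{average_model}.
#' @param center Center the displacements before the Gram matrix (default
#'   TRUE).
#' @param rematch Re-match every input against the final average from a
#'   cold start before computing tractions (default TRUE). The alternating
#'   minimization warm-starts its matches, so their solutions carry the
#'   optimization path of the alternation; unseen shapes are embedded by
#'   cold-start matches, and training and test displacements must come from
#'   the identical protocol or protocol differences masquerade as shape
#'   variation along the weakest modes.
#' @param match_iter Per-level iteration cap for the re-matching solves
#'   (default 300).
#' @return An \code{elastic_pca} object: the \code{pca_model} fields plus
#'   \code{average}, \code{metric}, \code{displacements} (centered),
#'   \code{mean_displacement}, \code{tractions}.
#' @export
elastic_pca <- function(average, center = TRUE, rematch = TRUE,
                        match_iter = 300L) {
  stopifnot(inherits(average, "average_model"))
  metric <- elastic_metric(average$average, average$params)
  deformations <- if (rematch && !is.null(average$inputs)) {
    lapply(average$inputs, function(chi)
      match_shapes(chi, average$average, average$params,
                   max_iter = match_iter)$deformation)
  } else {
    average$deformations
  }
  tractions <- lapply(deformations, boundary_stress,
                      average = average)
  disps <- lapply(tractions, stress_to_displacement, metric = metric)
  if (center) {
    disps <- center_displacements(disps)
    mean_u <- attr(disps, "mean")
  } else {
    mean_u <- matrix(0, average$average$grid$n^3, 3)
  }
  pm <- principal_modes(disps, metric)
  out <- c(pm, list(average = average, metric = metric,
                    displacements = disps, mean_displacement = mean_u,
                    tractions = tractions))
  class(out) <- c("elastic_pca", "pca_model")
  out
}

#' @export
print.pca_model <- function(x, ...) {
  v <- x$variances[seq_len(min(5, length(x$variances)))]
  cat(sprintf("<%s> %d modes retained; leading variances: %s\n",
              class(x)[1], x$n_retained,
              paste(signif(v, 3), collapse = ", ")))
  invisible(x)
}

#' Render a principal mode as a displaced surface mesh
#'
#' Extracts the average surface by marching tetrahedra and displaces its
#' vertices by \code{amplitude * w_j}. Amplitudes are commonly chosen as
#' multiples of \eqn{\sqrt{\lambda_j}}.
#'
#' @param average An \code{average_model} (or occupancy field).
#' @param mode A mode: an \code{n^3 x 3} matrix, a mode column index plus a
#'   \code{pca_model} in \code{pca}, or a \code{deformation_field}.
#' @param amplitude Signed scalar amplitude.
#' @param pca Optional \code{pca_model} when \code{mode} is an index.
#' @return A \code{tri_mesh}; warns when the amplitude is large enough to
#'   risk local self-intersection (displacement above 3 voxel spacings).
#' @export
render_mode <- function(average, mode, amplitude = 0, pca = NULL) {
  chi <- average_field(average)
  n <- chi$grid$n
  if (is.numeric(mode) && length(mode) == 1 && !is.null(pca))
    mode <- matrix(pca$modes[, mode], ncol = 3)
  if (inherits(mode, "deformation_field")) mode <- mode$displacement
  if (!is.matrix(mode)) mode <- matrix(mode, ncol = 3)
  sdf <- field_sdf_values(chi)
  mt <- cpp_marching_tets(sdf, n, 0)
  verts <- mt$vertices
  if (!nrow(verts)) stop("render_mode: empty surface")
  up <- sapply(1:3, function(p) cpp_resample(mode[, p], n, verts, 0))
  if (abs(amplitude) * max(abs(up)) > 3 * chi$grid$h)
    warning("render_mode: amplitude may cause local self-intersection")
  tri_mesh(verts + amplitude * up, mt$faces + 1L)
}
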