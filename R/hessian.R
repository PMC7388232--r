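# Linearized elasticity on the occupied region: Hessian of the hyperelastic
# energy at the identity, its kernel (infinitesimal rigid motions) and the
# equilibrium solver used to convert boundary stresses into displacements.
#
# Expanding W(I + G) to second order gives the quadratic density
#   Q(G) = mu |sym G|^2 + (lam/2) (tr G)^2,
# i.e. classical linear elasticity; the associated bilinear form
#   g(u, v) = int_O [ 2 mu eps(u):eps(v) + lam div u div v ] dx
# is assembled with trilinear elements and full 2x2x2 Gauss quadrature
# (single-point quadrature would admit spurious hourglass modes in its
# kernel). Degrees of freedom are ordered component-blocked: all x, then all
# y, then all z displacements, matching as.numeric() of an n^3 x 3 matrix.

trilinear_shape_grads <- function(h) {
  gp <- (c(-1, 1) / sqrt(3) + 1) / 2
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  out <- vector("list", 8)
  q <- 1L
  for (gz in gp) for (gy in gp) for (gx in gp) {
    g <- matrix(0, 8, 3)
    for (a in 1:8) {
      cx <- corners[a, 1]; cy <- corners[a, 2]; cz <- corners[a, 3]
      wx <- if (cx) gx else 1 - gx
      wy <- if (cy) gy else 1 - gy
      wz <- if (cz) gz else 1 - gz
      g[a, ] <- c((if (cx) 1 else -1) * wy * wz,
                  wx * (if (cy) 1 else -1) * wz,
                  wx * wy * (if (cz) 1 else -1)) / h
    }
    out[[q]] <- g
    q <- q + 1L
  }
  out
}

# 24 x 24 element matrix of the linearized density on an h-cell; local dof
# ordering a + 8*(p-1) for corner a, component p
elasticity_element_matrix <- function(h, mu, lam) {
  grads <- trilinear_shape_grads(h)
  E0 <- matrix(0, 24, 24)
  w <- h^3 / 8
  for (g in grads) {
    B_eps <- matrix(0, 9, 24)   # vectorized sym(e_p x gradN_a)
    B_div <- numeric(24)
    for (p in 1:3) for (a in 1:8) {
      la <- a + 8 * (p - 1)
      Gm <- matrix(0, 3, 3)
      Gm[p, ] <- g[a, ]
      E <- (Gm + t(Gm)) / 2
      B_eps[, la] <- as.numeric(E)
      B_div[la] <- g[a, p]
    }
    E0 <- E0 + w * (2 * mu * crossprod(B_eps) + lam * tcrossprod(B_div))
  }
  E0
}

#' Elastic metric induced by the energy Hessian at the average
#'
#' Assembles the Hessian of the hyperelastic energy at the identity over the
#' occupied region of a shape. The resulting bilinear form is the natural
#' scalar product on surface displacements; its kernel is exactly the
#' six-dimensional space of infinitesimal rigid motions (translations and
#' linearized rotations), which the equilibrium solver projects out.
#'
#' @param chi Occupancy \code{vox_field} of the (average) shape.
#' @param params \code{elastic_params} supplying \code{mu}, \code{lam}.
#' @return An \code{elastic_metric} object holding the sparse Hessian, the
#'   active degrees of freedom and a lazily computed factorization.
#' @export
elastic_metric <- function(chi, params = elastic_params()) {
  stopifnot(inherits(chi, "vox_field"))
  n <- chi$grid$n
  N <- n^3
  wc <- cell_average(chi$values, n)
  occ <- which(wc > 0)
  E0 <- elasticity_element_matrix(chi$grid$h, params$mu, params$lam)
  nc <- n - 1L
  ck <- (occ - 1L) %/% (nc^2)
  cj <- ((occ - 1L) %/% nc) %% nc
  ci <- (occ - 1L) %% nc
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  nodes <- matrix(0L, length(occ), 8)
  for (a in 1:8)
    nodes[, a] <- (ci + corners[a, 1]) + n * (cj + corners[a, 2]) +
                  n^2 * (ck + corners[a, 3]) + 1L
  wocc <- wc[occ]
  ilist <- vector("list", 576)
  jlist <- vector("list", 576)
  xlist <- vector("list", 576)
  q <- 1L
  for (p in 1:3) for (a in 1:8) {
    la <- a + 8 * (p - 1)
    gi <- nodes[, a] + N * (p - 1L)
    for (r in 1:3) for (b in 1:8) {
      lb <- b + 8 * (r - 1)
      if (E0[la, lb] == 0) next
      ilist[[q]] <- gi
      jlist[[q]] <- nodes[, b] + N * (r - 1L)
      xlist[[q]] <- wocc * E0[la, lb]
      q <- q + 1L
    }
  }
  H <- Matrix::sparseMatrix(i = unlist(ilist[seq_len(q - 1)]),
                            j = unlist(jlist[seq_len(q - 1)]),
                            x = unlist(xlist[seq_len(q - 1)]),
                            dims = c(3 * N, 3 * N))
  active_nodes <- sort(unique(as.integer(nodes)))
  active_dofs <- c(active_nodes, active_nodes + N, active_nodes + 2L * N)
  # orthonormal basis of infinitesimal rigid motions on the active nodes
  coords <- grid_nodes(chi$grid)[active_nodes, , drop = FALSE]
  cen <- colMeans(coords)
  xc <- sweep(coords, 2, cen)
  na <- length(active_nodes)
  R <- matrix(0, 3 * na, 6)
  one <- rep(1, na)
  R[seq_len(na), 1] <- one
  R[na + seq_len(na), 2] <- one
  R[2 * na + seq_len(na), 3] <- one
  # rotations about x, y, z
  R[na + seq_len(na), 4] <- -xc[, 3]; R[2 * na + seq_len(na), 4] <- xc[, 2]
  R[seq_len(na), 5] <- xc[, 3]; R[2 * na + seq_len(na), 5] <- -xc[, 1]
  R[seq_len(na), 6] <- -xc[, 2]; R[na + seq_len(na), 6] <- xc[, 1]
  R <- qr.Q(qr(R))
  structure(list(H = H, n = n, grid = chi$grid, params = params,
                 active_nodes = active_nodes, active_dofs = active_dofs,
                 rigid = R, cache = new.env(parent = emptyenv())),
            class = "elastic_metric")
}

#' Hessian-induced scalar product of two displacement fields
#'
#' \eqn{g(u,v) = u^T H v} with \eqn{H} the linearized-elasticity Hessian over
#' the occupied region; symmetric, positive semi-definite, and zero whenever
#' either argument is an infinitesimal rigid motion.
#'
#' @param u,v \code{deformation_field}s (or \code{n^3 x 3} matrices) on the
#'   metric's grid.
#' @param metric An \code{elastic_metric}.
#' @return Scalar.
#' @export
metric_g <- function(u, v, metric) {
  stopifnot(inherits(metric, "elastic_metric"))
  uu <- displacement_vector(u, metric)
  vv <- displacement_vector(v, metric)
  as.numeric(uu %*% (metric$H %*% vv))
}

displacement_vector <- function(u, metric) {
  if (inherits(u, "deformation_field")) {
    if (u$grid$n != metric$n) stop("metric_g: grid mismatch")
    u <- u$displacement
  }
  if (is.matrix(u)) {
    if (nrow(u) != metric$n^3 || ncol(u) != 3) stop("metric_g: bad shape")
    u <- as.numeric(u)
  }
  if (length(u) != 3 * metric$n^3) stop("metric_g: bad length")
  u
}

metric_factor <- function(metric) {
  if (!is.null(metric$cache$chol)) return(metric$cache$chol)
  ad <- metric$active_dofs
  K <- metric$H[ad, ad]
  ridge <- 1e-10 * mean(Matrix::diag(K))
  metric$cache$ridge <- ridge
  metric$cache$chol <- Matrix::Cholesky(
    K + ridge * Matrix::Diagonal(length(ad)), LDL = FALSE, perm = TRUE)
  metric$cache$chol
}

# solve H u = load on the active dofs with the rigid kernel projected out of
# both load and solution
solve_equilibrium <- function(metric, load) {
  stopifnot(length(load) == 3 * metric$n^3)
  ad <- metric$active_dofs
  b <- load[ad]
  R <- metric$rigid
  b <- b - R %*% crossprod(R, b)
  ch <- metric_factor(metric)
  x <- as.numeric(Matrix::solve(ch, b))
  x <- x - as.numeric(R %*% crossprod(R, x))
  u <- numeric(3 * metric$n^3)
  u[ad] <- x
  matrix(u, ncol = 3)
}
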