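#' Hyperelastic model parameters
#'
#' The polyconvex energy density
#' \deqn{W(F) = \bar W(\|F\|_F, \det F), \quad
#'       \bar W(a,d) = \frac{\mu}{2} a^2 + \frac{\lambda}{4} d^2 -
#'       (\mu + \frac{\lambda}{2}) \log d - \frac{3\mu}{2} -
#'       \frac{\lambda}{4}}
#' is minimal (= 0) at rigid motions and blows up as \eqn{\det F \to 0^+},
#' penalizing local self-interpenetration. \code{gamma} weights the occupancy
#' mismatch penalty of the shape-matching functional.
#'
#' @param mu Shear-like stiffness (> 0, default 1).
#' @param lam Compression-like stiffness (> 0, default 1).
#' @param gamma Mismatch penalty weight (> 0, default 50).
#' @return An \code{elastic_params} object.
#' @export
elastic_params <- function(mu = 1, lam = 1, gamma = 50) {
  if (mu <= 0 || lam <= 0 || gamma <= 0)
    stop("elastic_params: mu, lam and gamma must be > 0")
  structure(list(mu = mu, lam = lam, gamma = gamma),
            class = "elastic_params")
}

#' Hyperelastic energy density
#'
#' Evaluates \eqn{W(F)} for a 3x3 deformation gradient; returns \code{+Inf}
#' when \eqn{\det F \le 0} (the log barrier).
#'
#' @param F A 3x3 matrix.
#' @param params \code{elastic_params}.
#' @return Non-negative scalar (or \code{Inf}).
#' @export
energy_density <- function(F, params = elastic_params()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  d <- det(F)
  if (d <= 0) return(Inf)
  a2 <- sum(F^2)
  mu <- params$mu
  lam <- params$lam
  mu / 2 * a2 + lam / 4 * d^2 - (mu + lam / 2) * log(d) - 3 * mu / 2 - lam / 4
}

#' First Piola-Kirchhoff stress
#'
#' The derivative \eqn{\partial W / \partial F = \mu F +
#' (\frac{\lambda}{2}\det F - (\mu + \frac{\lambda}{2}) / \det F)\,
#' \mathrm{cof}\,F}; zero at rigid motions.
#'
#' @param F A 3x3 matrix with \eqn{\det F > 0}.
#' @param params \code{elastic_params}.
#' @return A 3x3 matrix.
#' @export
pk_stress <- function(F, params = elastic_params()) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  d <- det(F)
  if (d <= 0)
    stop("pk_stress: singular deformation (det F <= 0)")
  cof <- d * t(solve(F))
  params$mu * F + (params$lam / 2 * d - (params$mu + params$lam / 2) / d) * cof
}

#' Displacement field on a grid
#'
#' The deformation is \eqn{\phi(x) = x + u(x)} with \eqn{u} trilinear per
#' cell; an all-zero displacement is the identity.
#'
#' @param displacement \code{n^3 x 3} matrix of nodal displacements.
#' @param grid A \code{grid3}.
#' @return A \code{deformation_field} object.
#' @export
deformation_field <- function(displacement, grid) {
  displacement <- as.matrix(displacement)
  storage.mode(displacement) <- "double"
  if (nrow(displacement) != grid$n^3 || ncol(displacement) != 3L)
    stop("deformation_field: displacement must be n^3 x 3")
  if (any(!is.finite(displacement)))
    stop("deformation_field: displacement must be finite")
  structure(list(displacement = displacement, grid = grid),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %d^3 nodes, sup|u| = %.4g\n", x$grid$n,
              max(abs(x$displacement))))
  invisible(x)
}

# identity deformation on a grid
identity_deformation <- function(grid)
  deformation_field(matrix(0, grid$n^3, 3), grid)

#' Elastic energy of a deformation over a reference shape
#'
#' Cell-center quadrature of \eqn{W(D\phi)} weighted by the cell-averaged
#' reference occupancy, with per-cell multilinear deformation gradients.
#' Returns \code{+Inf} when \eqn{\det D\phi \le 0} on an occupied cell.
#'
#' @param phi A \code{deformation_field}.
#' @param chi_ref Occupancy \code{vox_field} on the same grid.
#' @param params \code{elastic_params}.
#' @return Non-negative scalar (or \code{Inf} with attribute
#'   \code{"barrier"}).
#' @export
deformation_energy <- function(phi, chi_ref, params = elastic_params()) {
  stopifnot(inherits(phi, "deformation_field"), inherits(chi_ref, "vox_field"))
  if (phi$grid$n != chi_ref$grid$n)
    stop("deformation_energy: grid mismatch")
  n <- phi$grid$n
  w <- cell_average(chi_ref$values, n)
  res <- cpp_match_objgrad(phi$displacement, n, w, numeric(n^3),
                           numeric(n^3), params$mu, params$lam, 1, FALSE)
  out <- if (res$barrier) Inf else res$elastic
  attr(out, "barrier") <- res$barrier
  out
}

#' Occupancy mismatch penalty of a deformation
#'
#' \eqn{\gamma \int (\chi_{mov} - \chi_{fix}\circ\phi)^2 dx} by mass-lumped
#' nodal quadrature; \eqn{\chi_{fix}\circ\phi} is evaluated by trilinear
#' interpolation and reads 0 outside the unit cube. By default both fields
#' are mollified over a 1.5-voxel interface band (gradient methods need a
#' differentiable surrogate of the binary masks); \code{smooth = FALSE} uses
#' the hard masks.
#'
#' @param phi A \code{deformation_field}.
#' @param chi_moving,chi_fixed Occupancy fields on the same grid.
#' @param gamma Penalty weight.
#' @param smooth Mollify the masks (default TRUE).
#' @return Non-negative scalar.
#' @export
mismatch_penalty <- function(phi, chi_moving, chi_fixed, gamma = 50,
                             smooth = TRUE) {
  stopifnot(inherits(phi, "deformation_field"))
  n <- phi$grid$n
  if (chi_moving$grid$n != n || chi_fixed$grid$n != n)
    stop("mismatch_penalty: grid mismatch")
  if (smooth) {
    ref <- smoothed_occupancy(chi_moving)$values
    fix <- smoothed_occupancy(chi_fixed)$values
  } else {
    ref <- chi_moving$values
    fix <- chi_fixed$values
  }
  res <- cpp_match_objgrad(phi$displacement, n, numeric((n - 1)^3), ref, fix,
                           1, 1, gamma, FALSE)
  res$mismatch
}

#' Elastic shape matching by penalty minimization
#'
#' Minimizes \eqn{\int_{O_{mov}} W(D\phi)\,dx + \gamma\int (\chi_{mov} -
#' \chi_{fix}\circ\phi)^2 dx} over deformations \eqn{\phi} of the moving
#' shape onto the fixed one, by limited-memory BFGS with Armijo backtracking
#' inside a coarse-to-fine cascade (nested grid halvings, prolongation by
#' trilinear interpolation). The masks are mollified over a 1.5-voxel band
#' for the penalty term. When a warm start \code{init} is supplied the
#' cascade is skipped and optimization runs at the finest level only.
#'
#' @param chi_moving,chi_fixed Occupancy \code{vox_field}s on a common grid
#'   with positive volumes.
#' @param params \code{elastic_params}.
#' @param init Optional initial \code{deformation_field} (warm start).
#' @param levels Cascade levels (default 3, limited by the grid size).
#' @param max_iter Iteration cap per level (default 300).
#' @param rel_tol Relative objective-decrease stopping tolerance (1e-6).
#' @param background Optional weak elastic weight applied during
#'   optimization in a narrow band outside the moving body (default 0, i.e.
#'   off). The matching functional leaves exterior space free to deform, so
#'   minimizers concentrate stretch in a thin boundary layer; a soft
#'   surrounding medium spreads the deformation volumetrically at roughly
#'   twice the cost. Reported energies and objectives always use the
#'   body-only density.
#' @return A \code{match_result}: \code{deformation},
#'   \code{elastic_energy}, \code{mismatch}, \code{objective},
#'   \code{converged}, \code{iterations}, \code{trace}.
#' @export
match_shapes <- function(chi_moving, chi_fixed, params = elastic_params(),
                         init = NULL, levels = 3L, max_iter = 300L,
                         rel_tol = 1e-6, background = 0) {
  stopifnot(inherits(chi_moving, "vox_field"), inherits(chi_fixed, "vox_field"))
  n <- chi_moving$grid$n
  if (chi_fixed$grid$n != n) stop("match_shapes: grid mismatch")
  if (field_volume(chi_moving) <= 0 || field_volume(chi_fixed) <= 0)
    stop("match_shapes: both shapes must have positive volume")
  sdf_m <- field_sdf_values(chi_moving)
  sdf_f <- field_sdf_values(chi_fixed)

  level_data <- function(nl, sm, sf) {
    g <- grid3(nl)
    w <- cell_average(as.numeric(sm > 0), nl)
    # soft surrounding medium: weak stiffness within ~5 voxels of either
    # body, used by the optimizer only
    if (background > 0) {
      near <- cell_average(as.numeric(pmax(sm, sf) > -5 * g$h), nl)
      w_opt <- pmax(w, background * as.numeric(near > 0))
    } else {
      w_opt <- w
    }
    list(n = nl, w = w, w_opt = w_opt,
         ref = smooth_chi_values(sm, g),
         fix = smooth_chi_values(sf, g))
  }
  # scale a warm start back toward identity until it clears the det barrier
  # (prolongation can push cells that only the finer mask resolves past it)
  make_feasible <- function(ld, disp) {
    for (try in 1:40) {
      res <- cpp_match_objgrad(disp, ld$n, ld$w_opt, ld$ref, ld$fix,
                               params$mu, params$lam, params$gamma, FALSE)
      if (!res$barrier) return(disp)
      disp <- 0.7 * disp
    }
    matrix(0, nrow(disp), 3)
  }
  run_level <- function(ld, disp) {
    cpp_match_lbfgs(make_feasible(ld, disp), ld$n, ld$w_opt, ld$ref, ld$fix,
                    params$mu, params$lam, params$gamma, max_iter, rel_tol,
                    6L)
  }

  if (is.null(init)) {
    # build the nested level hierarchy (finest first)
    ns <- n
    sms <- list(sdf_m)
    sfs <- list(sdf_f)
    while (length(ns) < levels &&
           (tail_n <- (ns[length(ns)] - 1L) %/% 2L + 1L) >= 9L) {
      sms <- c(sms, list(restrict_values(sms[[length(sms)]], ns[length(ns)])))
      sfs <- c(sfs, list(restrict_values(sfs[[length(sfs)]], ns[length(ns)])))
      ns <- c(ns, tail_n)
    }
    disp <- matrix(0, ns[length(ns)]^3, 3)
    total_iter <- 0L
    conv <- TRUE
    tr <- NULL
    for (l in rev(seq_along(ns))) {
      opt <- run_level(level_data(ns[l], sms[[l]], sfs[[l]]), disp)
      disp <- opt$disp
      total_iter <- total_iter + opt$iterations
      tr <- opt$trace
      if (l > 1) {  # prolong to the next finer level
        nf <- ns[l - 1]
        fine_nodes <- grid_nodes(grid3(nf))
        disp <- cbind(cpp_resample(disp[, 1], ns[l], fine_nodes, 0),
                      cpp_resample(disp[, 2], ns[l], fine_nodes, 0),
                      cpp_resample(disp[, 3], ns[l], fine_nodes, 0))
      }
      conv <- opt$converged
    }
  } else {
    stopifnot(inherits(init, "deformation_field"), init$grid$n == n)
    opt <- run_level(level_data(n, sdf_m, sdf_f), init$displacement)
    disp <- opt$disp
    total_iter <- opt$iterations
    conv <- opt$converged
    tr <- opt$trace
  }

  ld <- level_data(n, sdf_m, sdf_f)
  final <- cpp_match_objgrad(disp, n, ld$w, ld$ref, ld$fix, params$mu,
                             params$lam, params$gamma, FALSE)
  if (final$barrier)
    stop("match_shapes: deformation hit the det barrier at the finest level")
  structure(list(deformation = deformation_field(disp, grid3(n)),
                 elastic_energy = final$elastic, mismatch = final$mismatch,
                 objective = final$obj, converged = conv,
                 iterations = total_iter, trace = tr),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("<match_result> objective=%.5g (elastic=%.5g, ",
                     "mismatch=%.5g), %d iterations, converged=%s\n"),
              x$objective, x$elastic_energy, x$mismatch, x$iterations,
              x$converged))
  invisible(x)
}
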