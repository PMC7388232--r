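#' Elastic shape average of an ensemble
#'
#' Jointly minimizes
#' \deqn{\sum_i \int_{O_i} W(D\phi_i)\,dx +
#'       \gamma \int (\chi_i - \bar\chi\circ\phi_i)^2 dx}
#' over the average occupancy \eqn{\bar\chi} and one matching deformation per
#' input, by alternating minimization: (a) with \eqn{\bar\chi} fixed, every
#' \eqn{\phi_i} is updated by \code{\link{match_shapes}} (warm-started after
#' the first sweep); (b) with the \eqn{\phi_i} fixed, \eqn{\bar\chi} is
#' updated by thresholding the mean of the inputs pulled back through the
#' current deformations (approximate inverses by fixed-point iteration),
#' after which a clean signed distance is re-extracted. The average is only
#' defined up to rigid motion, so inputs are centroid-aligned first and the
#' average centroid is pinned to the domain center (gauge fixing); no
#' rotational gauge is applied since root shapes are generated and scanned
#' upright.
#'
#' If an alternation fails to decrease the total objective the previous
#' iterate is kept, so the recorded objective trace is non-increasing.
#'
#' @param ensemble List of at least 2 volume-normalized occupancy
#'   \code{vox_field}s on a common grid.
#' @param params \code{elastic_params}.
#' @param max_outer Maximal alternations (default 20).
#' @param outer_tol Relative objective-decrease stopping tolerance (1e-4).
#' @param match_iter Per-match iteration cap (default 300).
#' @param recenter_inputs Centroid-align the inputs first (default TRUE).
#' @param init_level Threshold applied to the voxelwise mean of the
#'   smoothed inputs for the initial average (default 0.35). A majority
#'   threshold of 0.5 erases thin shared structures (apex tips jitter by a
#'   voxel or two across samples, pushing the mean below one half), and the
#'   alternation cannot regrow structure outside the current average — the
#'   matches have already folded every input's tip into the tipless blob.
#'   A sub-majority initial level keeps such structures alive; subsequent
#'   alternations prune whatever the ensemble does not support.
#' @return An \code{average_model}: \code{average} (occupancy field with
#'   signed distance), \code{deformations} (one per input),
#'   \code{elastic_energies}, \code{mismatches}, \code{objective_trace},
#'   \code{inputs} (the aligned inputs), \code{params}.
#' @export
elastic_average <- function(ensemble, params = elastic_params(),
                            max_outer = 20L, outer_tol = 1e-4,
                            match_iter = 300L, recenter_inputs = TRUE,
                            init_level = 0.35) {
  if (length(ensemble) < 2L)
    stop("elastic_average: need at least 2 shapes")
  n <- ensemble[[1]]$grid$n
  for (f in ensemble) {
    if (!inherits(f, "vox_field") || f$kind != "occupancy")
      stop("elastic_average: ensemble must contain occupancy fields")
    if (f$grid$n != n) stop("elastic_average: inconsistent grids")
  }
  grid <- ensemble[[1]]$grid
  m <- length(ensemble)
  if (recenter_inputs)
    ensemble <- lapply(ensemble, recenter_field)

  # initialization: thresholded voxelwise mean of the smoothed inputs,
  # projected to the ensemble's median volume. The sub-majority threshold
  # inflates the mask slightly, and the vote update below is a fixed point
  # wherever the matches already fit well, so without the volume projection
  # the inflation would never recede.
  vol_target <- stats::median(vapply(ensemble, field_volume, 0))
  smooth_inputs <- lapply(ensemble, function(f) smoothed_occupancy(f)$values)
  input_sdfs <- lapply(ensemble, field_sdf_values)
  mean_field <- Reduce(`+`, smooth_inputs) / m
  avg <- rescale_to_volume(field_from_level(mean_field, grid, init_level),
                           vol_target)

  phis <- vector("list", m)
  trace <- numeric(0)
  best_total <- Inf
  best <- NULL
  nodes <- grid_nodes(grid)
  for (outer in seq_len(max_outer)) {
    # (a) update all matching deformations against the current average
    for (i in seq_len(m)) {
      init <- if (outer > 1) phis[[i]]$deformation else NULL
      phis[[i]] <- match_shapes(ensemble[[i]], avg, params, init = init,
                                max_iter = match_iter)
    }
    total <- sum(vapply(phis, `[[`, 0, "objective"))
    if (total < best_total - 1e-15) {
      best_total <- total
      best <- list(avg = avg, phis = phis)
      trace <- c(trace, total)
    } else {
      # the chi-update overshot; keep the best iterate and stop
      break
    }
    rel_dec <- if (length(trace) >= 2)
      (trace[length(trace) - 1] - total) / max(abs(total), 1e-12) else Inf
    if (outer == max_outer || rel_dec <= outer_tol) break

    # (b) update the average: mean of inputs pulled back through phi_i,
    # evaluated in the gauge of the mean deformation. Pulling back through
    # phi_i alone is a fixed point wherever the matches already fit (the
    # mismatch term cannot prefer the zero-deformation representative), so
    # the new average is read off at phibar(z) = z + mean displacement:
    # common deformation content moves into the average itself and the
    # per-input deformations center at the identity.
    ubar <- Reduce(`+`, lapply(phis, function(p)
      p$deformation$displacement)) / m
    pts <- pmin(pmax(nodes + ubar, 0), 1)
    # the vote resamples signed distances (not the clamped occupancy
    # surrogates): linear near the boundary, so sub-voxel interfaces
    # survive repeated resampling, and the mean-of-SDF zero level is the
    # classical signed-distance shape average
    acc <- numeric(grid$n^3)
    for (i in seq_len(m)) {
      pre <- cpp_invert_disp(phis[[i]]$deformation$displacement, n, pts, 10L)
      acc <- acc + cpp_resample(input_sdfs[[i]], n, pmin(pmax(pre, 0), 1),
                                -1)
    }
    acc <- acc / m
    if (max(acc) <= 0 || min(acc) > 0)
      stop("elastic_average: degenerate average (no interface)")
    avg <- field_from_level(acc, grid, 0)
    avg <- recenter_field(avg)
  }
  if (is.null(best))
    stop("elastic_average: no successful alternation; objective trace ",
         "could not be established")

  structure(list(average = best$avg,
                 deformations = lapply(best$phis, `[[`, "deformation"),
                 elastic_energies = vapply(best$phis, `[[`, 0,
                                           "elastic_energy"),
                 mismatches = vapply(best$phis, `[[`, 0, "mismatch"),
                 objective_trace = trace,
                 inputs = ensemble,
                 params = params),
            class = "average_model")
}

# occupancy field (with sdf) from the level set {values > level}
field_from_level <- function(values, grid, level) {
  mask <- values > level
  if (!any(mask) || all(mask))
    stop("field_from_level: degenerate level set")
  sdf <- cpp_sdf_from_field(values, grid$n, level)
  out <- vox_field(as.numeric(mask), grid, kind = "occupancy")
  attr(out, "sdf") <- sdf
  out
}

#' @export
print.average_model <- function(x, ...) {
  cat(sprintf(paste0("<average_model> %d inputs on a %d^3 grid, total ",
                     "objective %.5g (%d alternations)\n"),
              length(x$deformations), x$average$grid$n,
              utils::tail(x$objective_trace, 1), length(x$objective_trace)))
  invisible(x)
}
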