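#' Regular computational grid on the unit cube
#'
#' Nodes sit at coordinates \code{(i*h, j*h, k*h)} for 0-based indices
#' \code{i,j,k < n} with spacing \code{h = 1/(n-1)}. Odd \code{n >= 9} supports
#' the coarse-to-fine halving used by the matching optimizer.
#'
#' @param n Number of nodes per axis (odd, at least 9). The production default
#'   is 129; 33 is a practical desk-scale resolution.
#' @return An object of class \code{grid3} with elements \code{n} and \code{h}.
#' @export
grid3 <- function(n = 33L) {
  n <- as.integer(n)
  if (is.na(n) || n < 9L || n %% 2L == 0L)
    stop("grid3: `n` must be an odd integer >= 9, got ", n)
  structure(list(n = n, h = 1 / (n - 1)), class = "grid3")
}

#' @export
print.grid3 <- function(x, ...) {
  cat(sprintf("<grid3> %d^3 nodes on [0,1]^3, h = %.6g\n", x$n, x$h))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid A \code{grid3}.
#' @return An \code{n^3 x 3} matrix of node coordinates, x-index fastest.
#' @export
grid_nodes <- function(grid) {
  ax <- seq(0, 1, length.out = grid$n)
  cbind(
    x = rep(ax, times = grid$n^2),
    y = rep(rep(ax, each = grid$n), times = grid$n),
    z = rep(ax, each = grid$n^2)
  )
}

#' Cell-center coordinates of a grid
#'
#' @param grid A \code{grid3}.
#' @return An \code{(n-1)^3 x 3} matrix of cell centers.
#' @export
grid_cell_centers <- function(grid) {
  nc <- grid$n - 1L
  ax <- (seq_len(nc) - 0.5) * grid$h
  cbind(
    x = rep(ax, times = nc^2),
    y = rep(rep(ax, each = nc), times = nc),
    z = rep(ax, each = nc^2)
  )
}

# next coarser nested grid (every second node)
coarsen_grid <- function(grid) grid3((grid$n - 1L) %/% 2L + 1L)

#' Scalar field on a regular grid
#'
#' Container for nodal scalar data: signed distances, hard occupancy masks
#' (0/1) and smoothed occupancy surrogates. Occupancy fields produced by the
#' voxelization pipeline carry the regularized signed distance along in
#' \code{attr(, "sdf")}, which downstream code uses for resampling, surface
#' normals and interface smoothing.
#'
#' @param values Numeric vector or 3D array of length \code{n^3} (x fastest).
#' @param grid A \code{grid3}.
#' @param kind One of \code{"signed_distance"}, \code{"occupancy"},
#'   \code{"smoothed_occupancy"}.
#' @param sign_convention Sign convention of associated signed distances;
#'   \code{"positive_inside"} (default) or \code{"negative_inside"}.
#' @return A \code{vox_field} object.
#' @export
vox_field <- function(values, grid, kind = c("signed_distance", "occupancy",
                                             "smoothed_occupancy"),
                      sign_convention = c("positive_inside",
                                          "negative_inside")) {
  kind <- match.arg(kind)
  sign_convention <- match.arg(sign_convention)
  values <- as.numeric(values)
  if (length(values) != grid$n^3)
    stop("vox_field: values length ", length(values), " != n^3 = ", grid$n^3)
  if (any(!is.finite(values))) stop("vox_field: values must be finite")
  if (kind == "occupancy" && !all(values %in% c(0, 1)))
    stop("vox_field: occupancy values must be 0/1")
  if (kind == "signed_distance" && max(abs(values)) > sqrt(3) + 1e-9)
    stop("vox_field: |signed distance| exceeds the domain diameter sqrt(3)")
  structure(list(values = values, grid = grid, kind = kind,
                 sign_convention = sign_convention),
            class = "vox_field")
}

#' @export
print.vox_field <- function(x, ...) {
  cat(sprintf("<vox_field> kind=%s, %d^3 nodes", x$kind, x$grid$n))
  if (x$kind == "occupancy")
    cat(sprintf(", volume=%.5g", field_volume(x)))
  cat("\n")
  invisible(x)
}

#' Voxel-measured volume of an occupancy field
#'
#' Volume is the interior node count times \code{h^3}.
#'
#' @param chi An occupancy \code{vox_field}.
#' @return Scalar volume.
#' @export
field_volume <- function(chi) {
  stopifnot(inherits(chi, "vox_field"))
  sum(chi$values > 0.5) * chi$grid$h^3
}

#' Centroid of an occupancy field
#'
#' @param chi An occupancy \code{vox_field}.
#' @return Length-3 numeric vector.
#' @export
field_centroid <- function(chi) {
  idx <- chi$values > 0.5
  if (!any(idx)) stop("field_centroid: empty occupancy field")
  colMeans(grid_nodes(chi$grid)[idx, , drop = FALSE])
}

# interface band half-width used to mollify hard masks for the penalty term
smoothing_band <- function(grid) 1.5 * grid$h

# smoothed occupancy from a signed distance: clamp(1/2 + d/(2w), 0, 1) for
# the positive-inside convention
smooth_chi_values <- function(sdf_values, grid,
                              sign_convention = "positive_inside") {
  w <- smoothing_band(grid)
  s <- if (sign_convention == "positive_inside") 1 else -1
  pmin(pmax(0.5 + s * sdf_values / (2 * w), 0), 1)
}

# smoothed occupancy field for a voxelized shape (requires attached sdf, or
# reconstructs one from the mask interface)
smoothed_occupancy <- function(chi) {
  stopifnot(inherits(chi, "vox_field"))
  sdf <- attr(chi, "sdf")
  if (is.null(sdf))
    sdf <- cpp_sdf_from_field(chi$values, chi$grid$n, 0.5)
  vals <- smooth_chi_values(sdf, chi$grid, chi$sign_convention)
  out <- vox_field(vals, chi$grid, kind = "smoothed_occupancy",
                   sign_convention = chi$sign_convention)
  attr(out, "sdf") <- sdf
  out
}

# signed distance values attached to (or reconstructed for) an occupancy field
field_sdf_values <- function(chi) {
  sdf <- attr(chi, "sdf")
  if (is.null(sdf)) sdf <- cpp_sdf_from_field(chi$values, chi$grid$n, 0.5)
  sdf
}

# mean of the 8 corner values per cell, as an (n-1)^3 vector (x fastest)
cell_average <- function(values, n) {
  a <- array(values, dim = c(n, n, n))
  lo <- 1:(n - 1); hi <- 2:n
  (a[lo, lo, lo] + a[hi, lo, lo] + a[lo, hi, lo] + a[hi, hi, lo] +
   a[lo, lo, hi] + a[hi, lo, hi] + a[lo, hi, hi] + a[hi, hi, hi]) / 8
}

# value of a nodal field at cell centers (equals the 8-corner mean for
# trilinear interpolation)
cell_center_values <- function(values, n) cell_average(values, n)

# restrict a nodal field to the next coarser nested grid
restrict_values <- function(values, n) {
  a <- array(values, dim = c(n, n, n))
  idx <- seq(1L, n, by = 2L)
  as.numeric(a[idx, idx, idx])
}

#' Dice overlap between two occupancy fields
#'
#' \code{2|A n B| / (|A| + |B|)}; 1 for identical masks.
#'
#' @param a,b Occupancy \code{vox_field}s on the same grid.
#' @return Scalar in \[0,1\].
#' @export
dice_overlap <- function(a, b) {
  stopifnot(a$grid$n == b$grid$n)
  ma <- a$values > 0.5
  mb <- b$values > 0.5
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}
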