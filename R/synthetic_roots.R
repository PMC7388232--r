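#' Parameters of a synthetic tap root
#'
#' A tap-root-like solid inside the unit cube: a rounded crown on top, a
#' tapering body of profile
#' \code{r(z) = max_radius * (1 - z/body_length)^taper_exponent} (depth
#' \code{z} measured downward from the crown), and \code{n_apices} tapered
#' conical tips emanating from the lower body. Band-limited radial roughness
#' emulates surface furrows.
#'
#' @param body_length Body length as a fraction of the unit cube.
#' @param max_radius Maximal body radius (fraction, < 0.5).
#' @param taper_exponent Positive exponent shaping the radius profile; 1 is a
#'   straight cone, > 1 a fuller body with a slimmer tip ("dull" for large
#'   values combined with short apices).
#' @param n_apices Number of branch tips (integer >= 1).
#' @param apex_length Length of the apex cones beyond their attachment
#'   (fraction).
#' @param apex_angle Tilt of side apices from the vertical, radians. A single
#'   apex is always axis-aligned.
#' @param roughness_amp Amplitude of the radial surface roughness (fraction,
#'   < \code{max_radius}).
#' @param roughness_freq Roughness frequency in cycles per unit length.
#' @param size Overall isotropic size factor multiplying all linear
#'   dimensions. Plants of one shape type vary in size with growth
#'   conditions largely independently of their shape, so ensembles spread
#'   this factor separately from the shape parameters.
#' @param seed Integer seed; the generated mesh is a pure function of the
#'   parameters including the seed.
#' @return A validated \code{root_params} object.
#' @export
root_params <- function(body_length = 0.55, max_radius = 0.13,
                        taper_exponent = 1.4, n_apices = 1L,
                        apex_length = 0.15, apex_angle = 0.45,
                        roughness_amp = 0.006, roughness_freq = 6,
                        size = 1, seed = 1L) {
  p <- list(body_length = body_length, max_radius = max_radius,
            taper_exponent = taper_exponent, n_apices = as.integer(n_apices),
            apex_length = apex_length, apex_angle = apex_angle,
            roughness_amp = roughness_amp, roughness_freq = roughness_freq,
            size = size, seed = as.integer(seed))
  validate_root_params(p)
  structure(p, class = "root_params")
}

# apply the isotropic size factor to all linear dimensions
scale_root_params <- function(p) {
  s <- p$size
  p$body_length <- s * p$body_length
  p$max_radius <- s * p$max_radius
  p$apex_length <- s * p$apex_length
  p$roughness_amp <- s * p$roughness_amp
  p$size <- 1
  p
}

validate_root_params <- function(p) {
  if (is.null(p$size) || p$size <= 0 || p$size > 1.5)
    stop("root_params: size must be in (0, 1.5]")
  if (p$max_radius >= 0.5)
    stop("root_params: max_radius must be < 0.5 (violated: ", p$max_radius, ")")
  if (p$n_apices < 1L)
    stop("root_params: n_apices must be >= 1 (violated: ", p$n_apices, ")")
  if (p$roughness_amp >= p$max_radius)
    stop("root_params: roughness_amp must be < max_radius (violated: ",
         p$roughness_amp, ")")
  if (p$body_length <= 0 || p$max_radius <= 0 || p$taper_exponent <= 0 ||
      p$apex_length < 0 || p$apex_angle < 0 || p$roughness_amp < 0 ||
      p$roughness_freq <= 0)
    stop("root_params: all size parameters must be positive")
  p <- scale_root_params(p)
  if (p$body_length + p$apex_length >= 0.95)
    stop("root_params: body_length + apex_length must be < 1 with margin ",
         ">= 0.05 (violated: ", p$body_length + p$apex_length, ")")
  # total vertical extent incl. the rounded crown and roughness must fit the
  # unit cube with the 0.05 margin
  if (0.5 * p$max_radius + p$body_length + p$apex_length +
      2 * p$roughness_amp >= 0.9)
    stop("root_params: crown + body + apex exceed the domain margin ",
         "(total vertical extent >= 0.9)")
  invisible(p)
}

# evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Lehmer-style integer hash for reproducible per-sample seeds; stays < 2^31
seed_hash <- function(seed, index) {
  m <- 2147483647
  s <- (((seed %% m) * 16807) %% m + (index * 69621) %% m) %% m
  as.integer(s + 1)
}

# crown cap height
crown_height <- function(p) 0.5 * p$max_radius

# analytic radius profile of the axisymmetric body incl. crown, depth s
# (s < 0 inside the crown cap, 0 <= s <= body_length in the body)
body_profile <- function(p, s) {
  ch <- crown_height(p)
  r <- numeric(length(s))
  crown <- s < 0 & s >= -ch
  body <- s >= 0 & s <= p$body_length
  r[crown] <- p$max_radius * sqrt(pmax(0, 1 - (s[crown] / ch)^2))
  r[body] <- p$max_radius * (1 - s[body] / p$body_length)^p$taper_exponent
  r
}

# apex cone geometry: attachment depth, base radius, axis directions
apex_geometry <- function(p, azimuth_offset = 0) {
  za <- 0.78 * p$body_length
  rb <- max(0.45 * p$max_radius,
            0.9 * body_profile(p, za))
  k <- p$n_apices
  if (k == 1L) {
    dirs <- matrix(c(0, 0, 1), 1)  # straight down (depth axis)
  } else {
    az <- azimuth_offset + 2 * pi * (seq_len(k) - 1) / k
    a <- p$apex_angle
    dirs <- cbind(sin(a) * cos(az), sin(a) * sin(az), rep(cos(a), k))
  }
  len <- (p$body_length - za) / pmax(dirs[, 3], 0.2) + p$apex_length
  list(za = za, rb = rb, dirs = dirs, len = len)
}

# union inside-test in shape coordinates (x, y, depth s); vectorized over rows
root_inside <- function(p, apx, pts) {
  x <- pts[, 1]; y <- pts[, 2]; s <- pts[, 3]
  horiz <- sqrt(x^2 + y^2)
  inside <- horiz <= body_profile(p, s) & s >= -crown_height(p) &
            s <= p$body_length
  for (k in seq_len(nrow(apx$dirs))) {
    d <- apx$dirs[k, ]
    qx <- x; qy <- y; qs <- s - apx$za
    t <- qx * d[1] + qy * d[2] + qs * d[3]
    ax <- qx - t * d[1]; ay <- qy - t * d[2]; as_ <- qs - t * d[3]
    rad <- sqrt(ax^2 + ay^2 + as_^2)
    ok <- t >= 0 & t <= apx$len[k] & rad <= apx$rb * (1 - t / apx$len[k])
    inside <- inside | ok
  }
  inside
}

#' Generate one synthetic tap-root mesh
#'
#' The surface is constructed as a radial graph over a subdivided icosphere:
#' along each ray from an interior center the outermost boundary crossing of
#' the implicit body-and-apices union is located by bisection. Radial graphs
#' are embedded by construction, so the mesh is watertight, consistently
#' oriented and free of self-intersections. Seeded band-limited plane waves
#' add radial roughness.
#'
#' @param params A \code{root_params} object.
#' @param subdiv Icosphere subdivision level of the direction set (default 3,
#'   1280 faces).
#' @return A watertight \code{tri_mesh} inside \code{[0.05, 0.95]^3}.
#' @export
generate_root <- function(params, subdiv = 3L) {
  stopifnot(inherits(params, "root_params"))
  validate_root_params(params)
  p <- scale_root_params(unclass(params))
  with_seed(p$seed, {
    # apices sit at canonical azimuths: specimens are presented in a fixed
    # orientation (as a scanning mount would), so ensembles do not carry a
    # rotational orbit that the statistics would otherwise have to span
    azoff <- 0
    nwave <- 6L
    wdir <- matrix(stats::rnorm(3 * nwave), nwave, 3)
    wdir <- wdir / sqrt(rowSums(wdir^2))
    wamp <- stats::runif(nwave, 0.5, 1)
    wph <- stats::runif(nwave, 0, 2 * pi)
  })
  apx <- apex_geometry(p, azoff)

  # ray-cast the union surface over the sphere of directions
  sphere <- icosphere(subdiv)
  dirs <- sphere$vertices
  ch <- crown_height(p)
  smax <- max(p$body_length, apx$za + apx$len * apx$dirs[, 3])
  tmax <- sqrt(max(p$max_radius, apx$rb)^2 + (ch + smax)^2) + 1e-6
  center <- c(0, 0, 0.3 * p$body_length)  # on the axis, inside the wide body

  nd <- nrow(dirs)
  nsteps <- 160L
  ts <- seq(0, tmax, length.out = nsteps)
  # coarse march along all rays at once, then vectorized bisection refinement
  big <- cbind(center[1] + rep(dirs[, 1], each = nsteps) * ts,
               center[2] + rep(dirs[, 2], each = nsteps) * ts,
               center[3] + rep(dirs[, 3], each = nsteps) * ts)
  ins <- matrix(root_inside(p, apx, big), nrow = nsteps)
  last_in <- vapply(seq_len(nd), function(v) max(which(ins[, v])), 1L)
  lo <- ts[last_in]
  hi <- ifelse(last_in < nsteps, ts[pmin(last_in + 1L, nsteps)], tmax)
  for (q in 1:30) {
    mid <- (lo + hi) / 2
    mp <- cbind(center[1] + mid * dirs[, 1], center[2] + mid * dirs[, 2],
                center[3] + mid * dirs[, 3])
    isin <- root_inside(p, apx, mp)
    lo <- ifelse(isin, mid, lo)
    hi <- ifelse(isin, hi, mid)
  }
  rho <- (lo + hi) / 2

  # band-limited radial roughness, evaluated at the unperturbed surface
  if (p$roughness_amp > 0) {
    surf <- sweep(dirs * rho, 2, center, "+")
    eta <- rep(0, nrow(surf))
    for (w in seq_len(nrow(wdir)))
      eta <- eta + wamp[w] *
        cos(2 * pi * p$roughness_freq * (surf %*% wdir[w, ]) + wph[w])
    eta <- eta / sum(wamp)
    rho <- pmax(rho + p$roughness_amp * as.numeric(eta), 0.2 * rho)
  }

  verts <- sweep(dirs * rho, 2, center, "+")
  # map shape coordinates (x, y, depth) into the unit cube, depth downward
  smin <- -ch - p$roughness_amp
  shi <- smax + p$roughness_amp
  zmid <- (smin + shi) / 2
  cube <- cbind(0.5 + verts[, 1], 0.5 + verts[, 2],
                0.5 - (verts[, 3] - zmid))
  if (min(cube) < 0.05 - 1e-9 || max(cube) > 0.95 + 1e-9)
    stop("generate_root: shape exceeds [0.05, 0.95]^3; reduce sizes ",
         "(bounding box ", paste(round(range(cube), 3), collapse = ".."), ")")
  # depth axis points down, so flipping z reverses orientation; reorder faces
  tri_mesh(cube, sphere$faces[, c(1, 3, 2)])
}

#' Specification of a labeled synthetic root class
#'
#' Emulates a cultivar: a mean parameter set plus per-parameter spreads from
#' which \code{n_samples} roots are drawn.
#'
#' @param name Class label.
#' @param param_means A \code{root_params} object (its \code{seed} field is
#'   ignored; see \code{seed}).
#' @param param_sds Named list of non-negative spreads for any of
#'   \code{body_length, max_radius, taper_exponent, n_apices, apex_length,
#'   apex_angle, roughness_amp, roughness_freq}; omitted fields are fixed.
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer class seed; per-sample seeds are derived from it by an
#'   integer hash, so generation is reproducible and order-independent.
#' @return A \code{class_spec} object.
#' @export
class_spec <- function(name, param_means, param_sds = list(),
                       n_samples = 35L, seed = 1L) {
  stopifnot(inherits(param_means, "root_params"))
  if (n_samples < 2L) stop("class_spec: n_samples must be >= 2")
  if (length(param_sds) && any(unlist(param_sds) < 0))
    stop("class_spec: spreads must be non-negative")
  bad <- setdiff(names(param_sds),
                 c("body_length", "max_radius", "taper_exponent", "n_apices",
                   "apex_length", "apex_angle", "roughness_amp",
                   "roughness_freq", "size"))
  if (length(bad)) stop("class_spec: unknown spread field(s): ",
                        paste(bad, collapse = ", "))
  structure(list(name = as.character(name), param_means = param_means,
                 param_sds = param_sds, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "class_spec")
}

# draw one valid parameter set around the class means (truncated: re-drawn
# until the invariants hold)
draw_root_params <- function(spec, sample_seed) {
  means <- spec$param_means
  sds <- spec$param_sds
  result <- with_seed(sample_seed, {
    found <- NULL
    for (try in 1:200) {
      p <- unclass(means)
      for (f in names(sds)) {
        if (f == "n_apices") {
          p[[f]] <- max(1L, as.integer(round(stats::rnorm(1, means[[f]],
                                                          sds[[f]]))))
        } else {
          p[[f]] <- stats::rnorm(1, means[[f]], sds[[f]])
        }
      }
      p$roughness_amp <- max(0, p$roughness_amp)
      p$seed <- sample_seed
      ok <- tryCatch({
        validate_root_params(p)
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        found <- structure(p, class = "root_params")
        break
      }
    }
    found
  })
  if (is.null(result))
    stop("draw_root_params: could not draw valid parameters for class '",
         spec$name, "' within 200 tries (spreads too large)")
  result
}

#' Generate a labeled ensemble of synthetic roots
#'
#' @param spec A \code{class_spec}.
#' @param subdiv Icosphere subdivision passed to \code{\link{generate_root}}.
#' @return List with \code{meshes} (list of \code{tri_mesh}), \code{labels},
#'   and \code{params} (the per-sample \code{root_params}).
#' @export
generate_ensemble <- function(spec, subdiv = 3L) {
  stopifnot(inherits(spec, "class_spec"))
  params <- lapply(seq_len(spec$n_samples), function(i)
    draw_root_params(spec, seed_hash(spec$seed, i)))
  meshes <- lapply(params, generate_root, subdiv = subdiv)
  list(meshes = meshes, labels = rep(spec$name, spec$n_samples),
       params = params)
}

#' Generate a train/test benchmark from several classes
#'
#' Per class, \code{holdout_per_class} samples are moved to the test set by a
#' seeded uniform draw without replacement; the rest form the training set.
#'
#' @param specs List of \code{class_spec}s.
#' @param holdout_per_class Held-out samples per class (may be 0).
#' @param seed Integer seed of the split.
#' @param subdiv Icosphere subdivision for mesh generation.
#' @return List with \code{train} and \code{test}, each holding
#'   \code{meshes}, \code{labels} and \code{params}.
#' @export
generate_benchmark <- function(specs, holdout_per_class, seed = 1L,
                               subdiv = 3L) {
  if (holdout_per_class >= min(vapply(specs, `[[`, 1L, "n_samples")))
    stop("generate_benchmark: holdout_per_class must be smaller than every ",
         "class size")
  train <- list(meshes = list(), labels = character(), params = list())
  test <- list(meshes = list(), labels = character(), params = list())
  for (ci in seq_along(specs)) {
    ens <- generate_ensemble(specs[[ci]], subdiv = subdiv)
    m <- specs[[ci]]$n_samples
    hold <- if (holdout_per_class > 0)
      with_seed(seed_hash(seed, ci), sample.int(m, holdout_per_class))
    else integer()
    keep <- setdiff(seq_len(m), hold)
    train$meshes <- c(train$meshes, ens$meshes[keep])
    train$labels <- c(train$labels, ens$labels[keep])
    train$params <- c(train$params, ens$params[keep])
    test$meshes <- c(test$meshes, ens$meshes[hold])
    test$labels <- c(test$labels, ens$labels[hold])
    test$params <- c(test$params, ens$params[hold])
  }
  list(train = train, test = test)
}

#' Write an ensemble to disk with a JSON manifest
#'
#' Meshes are written as binary little-endian PLY; the manifest records file
#' names, class labels, seeds and the full per-sample parameters.
#'
#' @param ensemble Result of \code{\link{generate_ensemble}} or one half of a
#'   \code{\link{generate_benchmark}} split.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ensemble$meshes)
  files <- sprintf("root_%03d.ply", seq_len(n))
  for (i in seq_len(n))
    write_mesh(ensemble$meshes[[i]], file.path(dir, files[i]))
  manifest <- list(
    n_samples = n,
    samples = lapply(seq_len(n), function(i) list(
      file = files[i], label = ensemble$labels[i],
      seed = ensemble$params[[i]]$seed,
      params = unclass(ensemble$params[[i]])))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
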