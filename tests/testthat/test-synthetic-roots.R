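test_that("generated roots are watertight, bounded and deterministic", {
  p <- root_params(seed = 11L)
  m1 <- generate_root(p)
  m2 <- generate_root(p)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_true(is_watertight(m1))
  expect_gt(mesh_volume(m1), 0)
  bb <- mesh_bbox(m1)
  expect_true(min(bb) >= 0.05 - 1e-9 && max(bb) <= 0.95 + 1e-9)
})

test_that("axisymmetric parameters give a surface of revolution", {
  p <- root_params(roughness_amp = 0, n_apices = 1L, taper_exponent = 1,
                   body_length = 0.5, apex_length = 0.15, max_radius = 0.12,
                   seed = 3L)
  m <- generate_root(p, subdiv = 4L)
  v <- m$vertices
  horiz <- sqrt((v[, 1] - 0.5)^2 + (v[, 2] - 0.5)^2)
  # side-facing vertices in the upper body must match the analytic profile
  # union (body cone vs apex cone, whichever is wider)
  ztop <- max(v[, 3])
  # depth is measured from the crown-body junction, one crown-cap height
  # below the mesh top
  depth <- ztop - v[, 3] - elastroot:::crown_height(p)
  apx <- elastroot:::apex_geometry(p)
  prof_body <- elastroot:::body_profile(p, depth)
  prof_apex <- pmax(0, apx$rb * (1 - (depth - apx$za) / apx$len)) *
    (depth >= apx$za)
  prof <- pmax(prof_body, prof_apex)
  # test away from the body/apex junction, where the union silhouette has a
  # radial jump that rays from the interior center cut across
  sel <- depth > 0.1 & depth < apx$za - 0.03 & horiz > 0.02
  expect_true(sum(sel) > 100)
  expect_lt(max(abs(horiz[sel] - prof[sel])), 0.01)
})

test_that("apex length drives the bounding-box height", {
  short <- generate_root(root_params(body_length = 0.5, apex_length = 0.1,
                                     seed = 5L))
  long <- generate_root(root_params(body_length = 0.5, apex_length = 0.3,
                                    seed = 5L))
  h_short <- diff(range(short$vertices[, 3]))
  h_long <- diff(range(long$vertices[, 3]))
  expect_gt(h_long, h_short)
})

test_that("enclosed volume is non-decreasing in max_radius", {
  radii <- c(0.08, 0.10, 0.13, 0.16)
  vols <- vapply(radii, function(r)
    mesh_volume(generate_root(root_params(max_radius = r, seed = 9L))), 0)
  expect_true(all(diff(vols) > 0))
})

test_that("parameter invariants are enforced by name", {
  expect_error(root_params(max_radius = 0.6), "max_radius")
  expect_error(root_params(n_apices = 0), "n_apices")
  expect_error(root_params(roughness_amp = 0.2, max_radius = 0.1),
               "roughness_amp")
  expect_error(root_params(body_length = 0.7, apex_length = 0.3),
               "body_length")
})

test_that("ensembles are reproducible and degenerate spreads collapse", {
  spec0 <- class_spec("zero", root_params(), param_sds = list(),
                      n_samples = 3L, seed = 2L)
  ens <- generate_ensemble(spec0)
  # all-zero spreads: identical parameters up to the per-sample seed, but
  # identical geometry requires identical seeds too, so compare parameters
  expect_true(all(vapply(ens$params, `[[`, 0, "body_length") ==
                  ens$params[[1]]$body_length))

  spec <- class_spec("a", root_params(),
                     param_sds = list(body_length = 0.02), n_samples = 4L,
                     seed = 7L)
  e1 <- generate_ensemble(spec)
  e2 <- generate_ensemble(spec)
  expect_identical(e1$meshes[[3]]$vertices, e2$meshes[[3]]$vertices)
  expect_false(identical(e1$meshes[[1]]$vertices, e1$meshes[[2]]$vertices))
})

test_that("apex-count classes differ geometrically at the tips", {
  p1 <- root_params(n_apices = 1L, apex_angle = 0.5, seed = 21L)
  p3 <- root_params(n_apices = 3L, apex_angle = 0.5, seed = 21L)
  one <- generate_root(p1, subdiv = 4L)
  three <- generate_root(p3, subdiv = 4L)
  # vertices below the main body belong to the apex cones; tilted multiple
  # apices sit laterally off-axis while a single apex hugs the axis
  tip_lateral <- function(m, p) {
    v <- m$vertices
    depth <- max(v[, 3]) - v[, 3]
    deep <- depth > p$body_length
    expect_gt(sum(deep), 5)
    mean(sqrt((v[deep, 1] - 0.5)^2 + (v[deep, 2] - 0.5)^2))
  }
  expect_gt(tip_lateral(three, p3), tip_lateral(one, p1) * 1.3)
})

test_that("benchmark split is seeded and sized correctly", {
  specs <- lapply(1:2, function(i)
    class_spec(paste0("c", i),
               root_params(n_apices = i, seed = i),
               param_sds = list(body_length = 0.02),
               n_samples = 6L, seed = 10L + i))
  b1 <- generate_benchmark(specs, 2L, seed = 5L)
  b2 <- generate_benchmark(specs, 2L, seed = 5L)
  expect_equal(length(b1$train$meshes), 8L)
  expect_equal(length(b1$test$meshes), 4L)
  expect_identical(b1$test$labels, b2$test$labels)
  expect_identical(b1$test$meshes[[1]]$vertices,
                   b2$test$meshes[[1]]$vertices)
  b0 <- generate_benchmark(specs, 0L, seed = 5L)
  expect_equal(length(b0$test$meshes), 0L)
  expect_equal(length(b0$train$meshes), 12L)
  expect_error(generate_benchmark(specs, 6L), "holdout")
})

test_that("ensembles persist with a faithful JSON manifest", {
  spec <- class_spec("m", root_params(), param_sds = list(),
                     n_samples = 2L, seed = 3L)
  ens <- generate_ensemble(spec)
  dir <- tempfile()
  write_ensemble(ens, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_samples, 2L)
  m <- read_mesh(file.path(dir, man$samples$file[1]))
  expect_equal(nrow(m$vertices), nrow(ens$meshes[[1]]$vertices))
})
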