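test_that("averaging identical shapes returns the shape with zero energy", {
  g <- grid3(33L)
  chi <- voxelize_mesh(generate_root(root_params(seed = 7L)), g)
  am <- elastic_average(list(chi, chi, chi))
  expect_gt(dice_overlap(am$average, elastroot:::recenter_field(chi)), 0.99)
  expect_lt(sum(am$elastic_energies), 1e-3)
  for (phi in am$deformations)
    expect_lt(mean(abs(phi$displacement)), g$h)
})

test_that("averaging equal spheres at different centers preserves the
           radius", {
  g <- grid3(33L)
  r <- 0.2
  ca <- voxelize_mesh(icosphere(3, r, c(0.44, 0.5, 0.5)), g)
  cb <- voxelize_mesh(icosphere(3, r, c(0.56, 0.5, 0.5)), g)
  am <- elastic_average(list(ca, cb))
  r_eff <- (3 * field_volume(am$average) / (4 * pi))^(1 / 3)
  expect_equal(r_eff, r, tolerance = 2 * g$h)
  cen <- field_centroid(am$average)
  expect_equal(as.numeric(cen), c(0.5, 0.5, 0.5), tolerance = 2 * g$h)
})

test_that("the average beats any single input as a summary", {
  ens <- small_root_ensemble()
  am <- small_average()
  params <- elastic_params()
  total_avg <- sum(vapply(seq_along(ens), function(i)
    match_shapes(ens[[i]], am$average, params)$objective, 0))
  # the alternation is a local scheme, so allow a modest optimization gap
  for (j in c(1, 3)) {
    cand <- elastroot:::recenter_field(ens[[j]])
    total_j <- sum(vapply(seq_along(ens), function(i)
      match_shapes(ens[[i]], cand, params)$objective, 0))
    expect_lte(total_avg, total_j * 1.10)
  }
})

test_that("the objective trace is non-increasing and inputs validated", {
  am <- small_average()
  expect_true(all(diff(am$objective_trace) <= 0))
  g17 <- grid3(17L)
  bad <- voxelize_mesh(sphere_mesh(0.3, subdiv = 2L), g17)
  expect_error(elastic_average(list(bad)), "at least 2")
  expect_error(elastic_average(list(bad, small_root_ensemble()[[1]])),
               "grids")
})

test_that("ensemble order does not change the average materially", {
  ens <- small_root_ensemble()[1:3]
  a1 <- elastic_average(ens)
  a2 <- elastic_average(rev(ens))
  expect_gt(dice_overlap(a1$average, a2$average), 0.98)
})

test_that("translating all inputs together leaves the gauge-fixed average
           unchanged", {
  g <- grid3(33L)
  mk <- function(dx) list(
    voxelize_mesh(icosphere(3, 0.18, c(0.45 + dx, 0.5, 0.5)), g),
    voxelize_mesh(icosphere(3, 0.21, c(0.55 + dx, 0.5, 0.5)), g))
  a0 <- elastic_average(mk(0))
  a1 <- elastic_average(mk(3 * g$h))
  expect_gt(dice_overlap(a0$average, a1$average), 0.99)
})
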