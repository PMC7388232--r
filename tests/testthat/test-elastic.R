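test_that("energy density reproduces closed-form values and invariances", {
  expect_identical(energy_density(diag(3)), 0)
  expect_equal(energy_density(2 * diag(3)),
               Wbar_oracle(sqrt(12), 8), tolerance = 1e-12)
  expect_equal(energy_density(2 * diag(3)), 17.13083688, tolerance = 1e-7)
  set.seed(1)
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    expect_lt(abs(energy_density(R)), 1e-12)
  }
  # log barrier: density diverges monotonically as det -> 0+
  barr <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(d)
    energy_density(diag(c(d, 1, 1))), 0)
  expect_true(all(diff(barr) > 0))
  expect_gt(barr[4], 25)
  expect_identical(energy_density(diag(c(-1, 1, 1))), Inf)
  # convexity of a -> Wbar(a, d) along rays
  a <- seq(0.5, 4, length.out = 50)
  w <- Wbar_oracle(a, 1)
  expect_true(all(diff(diff(w)) > -1e-12))
})

test_that("stress matches the analytic derivative and finite differences", {
  expect_equal(pk_stress(diag(3)), matrix(0, 3, 3), tolerance = 1e-14)
  expect_equal(pk_stress(2 * diag(3)), 17.25 * diag(3), tolerance = 1e-12)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  expect_lt(max(abs(pk_stress(R))), 1e-12)
  expect_error(pk_stress(diag(c(-1, 1, 1))), "singular")
  set.seed(42)
  for (i in 1:20) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
    if (det(F) <= 0.05) next
    P <- pk_stress(F)
    eps <- 1e-6
    fd <- matrix(0, 3, 3)
    for (p in 1:3) for (q in 1:3) {
      Fp <- F; Fp[p, q] <- Fp[p, q] + eps
      Fm <- F; Fm[p, q] <- Fm[p, q] - eps
      fd[p, q] <- (energy_density(Fp) - energy_density(Fm)) / (2 * eps)
    }
    expect_lt(max(abs(P - fd)) / max(abs(P)), 1e-5)
  }
})

test_that("deformation energy vanishes for rigid motions and tracks the
           affine closed form", {
  chi <- sphere_chi_33()
  g <- chi$grid
  idd <- elastroot:::identity_deformation(g)
  expect_equal(deformation_energy(idd, chi), 0, tolerance = 1e-15,
               ignore_attr = TRUE)
  tr <- deformation_field(matrix(rep(c(0.02, -0.01, 0.03), each = g$n^3),
                                 g$n^3, 3), g)
  expect_equal(deformation_energy(tr, chi), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # uniform dilation about the centroid: constant-gradient closed form
  s <- 1.08
  nodes <- grid_nodes(g)
  aff <- deformation_field((s - 1) * sweep(nodes, 2, c(0.5, 0.5, 0.5)), g)
  V <- sum(elastroot:::cell_average(chi$values, g$n)) * g$h^3
  expect_equal(as.numeric(deformation_energy(aff, chi)),
               V * Wbar_oracle(s * sqrt(3), s^3), tolerance = 0.01)
  # inverted cells inside the body trip the barrier
  bad <- deformation_field(-1.2 * sweep(nodes, 2, c(0.5, 0.5, 0.5)), g)
  expect_identical(as.numeric(deformation_energy(bad, chi)), Inf)
})

test_that("mismatch penalty identities on hard and smoothed masks", {
  g <- grid3(17L)
  n <- g$n
  idd <- elastroot:::identity_deformation(g)
  chi <- voxelize_mesh(sphere_mesh(0.25, subdiv = 2L), g)
  expect_equal(mismatch_penalty(idd, chi, chi), 0, tolerance = 1e-12)

  # two disjoint single-node blobs: hand-counted nodal quadrature
  iA <- 5 + n * 8 + n^2 * 8 + 1
  iB <- 12 + n * 8 + n^2 * 8 + 1
  blobA <- numeric(n^3); blobA[iA] <- 1
  blobB <- numeric(n^3); blobB[iB] <- 1
  fa <- vox_field(blobA, g, "occupancy")
  fb <- vox_field(blobB, g, "occupancy")
  got <- mismatch_penalty(idd, fa, fb, gamma = 50, smooth = FALSE)
  expect_equal(got, 50 * 2 * g$h^3, tolerance = 1e-12)

  # mapping everything outside the domain integrates the moving mask alone
  off <- deformation_field(matrix(rep(c(5, 0, 0), each = n^3), n^3, 3), g)
  smoothed <- elastroot:::smoothed_occupancy(chi)$values
  expect_equal(mismatch_penalty(off, chi, chi, gamma = 50),
               50 * sum(smoothed^2) * g$h^3, tolerance = 1e-10)
})

test_that("matching objective gradient agrees with finite differences", {
  g <- grid3(17L)
  n <- g$n
  chiA <- voxelize_mesh(sphere_mesh(0.22, subdiv = 2L), g)
  chiB <- voxelize_mesh(sphere_mesh(0.26, subdiv = 2L), g)
  w <- elastroot:::cell_average(chiA$values, n)
  ref <- elastroot:::smooth_chi_values(attr(chiA, "sdf"), g)
  fix <- elastroot:::smooth_chi_values(attr(chiB, "sdf"), g)
  set.seed(7)
  disp <- matrix(rnorm(3 * n^3, 0, 0.004), n^3, 3)
  res <- elastroot:::cpp_match_objgrad(disp, n, w, ref, fix, 1, 1, 50, TRUE)
  eps <- 1e-6
  set.seed(8)
  idx <- sample.int(3 * n^3, 40)
  # the interpolated mismatch term is only piecewise smooth: skip probes
  # whose warped position sits within FD reach of a cell face, where the
  # one-sided derivatives legitimately differ
  nodes <- grid_nodes(g)
  warped <- nodes + disp
  tested <- 0
  for (q in idx) {
    node <- ((q - 1) %% n^3) + 1
    frac <- (warped[node, ] / g$h) %% 1
    if (min(frac, 1 - frac) < 50 * eps / g$h) next
    tested <- tested + 1
    dp <- disp; dp[q] <- dp[q] + eps
    dm <- disp; dm[q] <- dm[q] - eps
    fp <- elastroot:::cpp_match_objgrad(dp, n, w, ref, fix, 1, 1, 50, FALSE)
    fm <- elastroot:::cpp_match_objgrad(dm, n, w, ref, fix, 1, 1, 50, FALSE)
    fd <- (fp$obj - fm$obj) / (2 * eps)
    expect_equal(as.numeric(res$grad)[q], fd,
                 tolerance = max(1e-5, 1e-4 * abs(fd)))
  }
  expect_gt(tested, 15)
})

test_that("matching identical shapes stays at the identity", {
  g <- grid3(33L)
  chi <- sphere_chi_33()
  mr <- match_shapes(chi, chi)
  expect_lt(max(abs(mr$deformation$displacement)), g$h)
  idd <- elastroot:::identity_deformation(g)
  base <- mismatch_penalty(idd, chi, chi)
  expect_lte(mr$objective, base + 1e-6)
})

test_that("matching recovers an integer-voxel translation", {
  g <- grid3(33L)
  t_vox <- 3L
  ca <- voxelize_mesh(icosphere(3, 0.22, c(0.45, 0.5, 0.5)), g)
  cb <- voxelize_mesh(icosphere(3, 0.22, c(0.45 + t_vox * g$h, 0.5, 0.5)), g)
  mr <- match_shapes(ca, cb)
  inside <- ca$values > 0.5
  md <- colMeans(mr$deformation$displacement[inside, ])
  expect_equal(md, c(t_vox * g$h, 0, 0), tolerance = g$h,
               ignore_attr = TRUE)
  expect_lt(mr$elastic_energy, 1e-3)
})

test_that("objective decreases monotonically and rigid shifts leave it
           unchanged", {
  g <- grid3(33L)
  ca <- voxelize_mesh(icosphere(3, 0.20, c(0.48, 0.5, 0.5)), g)
  cb <- voxelize_mesh(icosphere(3, 0.23, c(0.52, 0.5, 0.5)), g)
  mr <- match_shapes(ca, cb)
  expect_true(all(diff(mr$trace) <= 1e-12))
  # repeatability: the solve has no hidden entropy
  mr_rep <- match_shapes(ca, cb)
  expect_identical(mr_rep$objective, mr$objective)
  # rigid invariance of the discretized functional: translating both
  # fields AND the converged deformation by the same voxel vector leaves
  # the objective value unchanged to rounding. (The optimizer itself is
  # only deterministic, not translation-equivariant: exact translates
  # change the floating-point summation order, and on this non-convex
  # landscape lowest-bit differences can select different basins.)
  roll_vals <- function(vals, k, fill) {
    n <- 33L
    a <- array(vals, rep(n, 3))
    b <- array(fill, rep(n, 3))
    b[, (1 + k):n, ] <- a[, 1:(n - k), ]
    as.numeric(b)
  }
  roll_field <- function(chi, k) {
    out <- vox_field(roll_vals(chi$values, k, 0), chi$grid, "occupancy")
    attr(out, "sdf") <- roll_vals(attr(chi, "sdf"), k,
                                  min(attr(chi, "sdf")))
    out
  }
  ca2 <- roll_field(ca, 4L)
  cb2 <- roll_field(cb, 4L)
  disp2 <- sapply(1:3, function(p)
    roll_vals(mr$deformation$displacement[, p], 4L, 0))
  obj_of <- function(chi_m, chi_f, disp) {
    sm <- elastroot:::field_sdf_values(chi_m)
    sf <- elastroot:::field_sdf_values(chi_f)
    r <- elastroot:::cpp_match_objgrad(
      disp, 33L, elastroot:::cell_average(as.numeric(sm > 0), 33L),
      elastroot:::smooth_chi_values(sm, g),
      elastroot:::smooth_chi_values(sf, g), 1, 1, 50, FALSE)
    r$obj
  }
  expect_equal(obj_of(ca2, cb2, disp2),
               obj_of(ca, cb, mr$deformation$displacement),
               tolerance = 1e-10)
})

test_that("growing a sphere onto a larger one is no costlier than the
           affine dilation", {
  g <- grid3(33L)
  ca <- voxelize_mesh(sphere_mesh(0.20), g)
  cb <- voxelize_mesh(sphere_mesh(0.22), g)
  mr <- match_shapes(ca, cb)
  s <- 0.22 / 0.20
  V <- sum(elastroot:::cell_average(ca$values, g$n)) * g$h^3
  affine_obj <- V * Wbar_oracle(s * sqrt(3), s^3)
  # the affine dilation is a feasible competitor with near-zero mismatch,
  # so the minimizer's total objective cannot exceed it by more than the
  # residual mismatch of the affine map itself
  expect_lt(mr$objective, affine_obj * 1.10 + 5e-4)
  expect_lt(mr$mismatch, 5e-4)
})
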