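test_that("sphere traits match the analytic surface, volume and
           complexity", {
  m <- sphere_mesh(0.3)
  tr <- compute_traits(m)
  expect_equal(tr[["surface"]], 4 * pi * 0.3^2, tolerance = 0.02)
  expect_equal(tr[["volume"]], 4 / 3 * pi * 0.3^3, tolerance = 0.02)
  expect_equal(tr[["complexity"]], 3 / 0.3, tolerance = 0.04)
  expect_identical(attr(tr, "path"), "mesh")
  expect_equal(tr[["complexity"]], tr[["surface"]] / tr[["volume"]],
               tolerance = 1e-12)
})

test_that("ellipsoid extents give length along z and width across x/y", {
  s <- icosphere(3, 1, c(0, 0, 0))
  ell <- tri_mesh(sweep(s$vertices, 2, c(0.1, 0.1, 0.3), "*"),
                  s$faces)
  ell$vertices <- sweep(ell$vertices, 2, c(0.5, 0.5, 0.5), "+")
  tr <- compute_traits(ell)
  expect_equal(tr[["length"]], 0.6, tolerance = 1e-3)
  expect_equal(tr[["width"]], 0.2, tolerance = 1e-3)
})

test_that("voxel-path traits approximate the mesh path", {
  chi <- sphere_chi_33()
  tr <- compute_traits(chi)
  expect_identical(attr(tr, "path"), "voxel")
  expect_equal(tr[["volume"]], 4 / 3 * pi * 0.3^3, tolerance = 0.05)
  expect_equal(tr[["length"]], 0.6, tolerance = 3 * chi$grid$h)
  # voxel interface area overestimates a smooth surface (staircase), but
  # stays within the standard 1.5x factor
  expect_gt(tr[["surface"]], 4 * pi * 0.3^2 * 0.9)
  expect_lt(tr[["surface"]], 4 * pi * 0.3^2 * 1.6)
})

test_that("traits are invariant under rigid translation", {
  m1 <- generate_root(root_params(seed = 13L))
  m2 <- tri_mesh(sweep(m1$vertices, 2, c(0.03, -0.02, 0.01), "+"),
                 m1$faces)
  expect_equal(compute_traits(m1), compute_traits(m2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("trait PCA standardizes, drops constants and sums variances", {
  set.seed(2)
  X <- cbind(length = rnorm(20, 0.5, 0.1), width = rnorm(20, 0.2, 0.02),
             surface = rnorm(20, 0.5, 0.05), volume = rnorm(20, 0.01, 0.002),
             complexity = rnorm(20, 50, 5))
  tp <- trait_pca(X)
  expect_equal(sum(tp$variances), 5, tolerance = 1e-10)
  sc <- trait_scores(tp, X)
  expect_equal(sc, tp$scores, tolerance = 1e-10, ignore_attr = TRUE)
  X2 <- X
  X2[, "width"] <- 0.2
  expect_warning(tp2 <- trait_pca(X2), "constant")
  expect_equal(sum(tp2$variances), 4, tolerance = 1e-10)
  # duplicated sample set gives the identical score cloud
  tp3 <- trait_pca(rbind(X, X))
  expect_equal(abs(tp3$scores[1:20, 1]), abs(tp3$scores[21:40, 1]),
               tolerance = 1e-10)
})

test_that("an ensemble varying only in length loads entirely on length", {
  # the other traits are constant, so they are dropped and the single
  # retained direction is the length axis
  len <- seq(0.3, 0.7, length.out = 15)
  X <- cbind(length = len, width = 0.2, surface = 0.5, volume = 0.01,
             complexity = 50)
  expect_warning(tp <- trait_pca(X), "constant")
  expect_gte(abs(tp$loadings["length", 1]), 0.9)
})

test_that("nearest-centroid scoring in trait space recovers separated
           classes", {
  # classes differ coherently in length, surface and volume (as real size
  # morphs do), so the leading standardized component captures the split
  set.seed(6)
  mkX <- function(mu, k) cbind(length = rnorm(k, mu, 0.02),
                               width = rnorm(k, 0.2, 0.01),
                               surface = rnorm(k, 1.2 * mu, 0.03),
                               volume = rnorm(k, 0.02 * mu, 0.001),
                               complexity = rnorm(k, 50, 1))
  Xtr <- rbind(mkX(0.4, 10), mkX(0.7, 10))
  lab <- rep(c("a", "b"), each = 10)
  tp <- trait_pca(Xtr)
  pred <- elastroot:::trait_nearest_centroid(tp, lab,
                                             rbind(mkX(0.4, 5), mkX(0.7, 5)))
  expect_identical(pred, rep(c("a", "b"), each = 5))
})
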