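test_that("the Mahalanobis identity m^2(w_k) = 1/lambda_k holds for every
           retained mode", {
  mA <- tiny_models()$mA
  lam <- mA$pca$variances[mA$pca$retained]
  for (k in seq_len(mA$M)) {
    wk <- matrix(mA$pca$modes[, k], ncol = 3)
    expect_equal(mahalanobis_sq(wk, mA), 1 / lam[k],
                 tolerance = 1e-8 / lam[k])
  }
  expect_identical(mahalanobis_sq(matrix(0, 33^3, 3), mA), 0)
  expect_error(mahalanobis_sq(matrix(0, 33^3, 3), mA,
                              M = mA$pca$n_retained + 1L), "retained")
})

test_that("the extended distance decomposes along the training subspace", {
  mA <- tiny_models()$mA
  # u inside U_j: residual vanishes, total is the Mahalanobis part
  u_in <- mA$pca$displacements[[2]]
  dd <- extended_distance_sq(u_in, mA)
  expect_lt(dd$residual, 1e-6 * dd$total)
  expect_equal(dd$total, mahalanobis_sq(u_in, mA) + dd$residual,
               tolerance = 1e-8)
  # u orthogonal to U_j (rigid motions are g-orthogonal to everything):
  # total = g(u, u) / beta
  N <- 33^3
  nodes <- grid_nodes(grid3(33L))
  xc <- sweep(nodes, 2, c(0.5, 0.5, 0.5))
  u_perp <- cbind(-xc[, 2], xc[, 1], 0) + 0.5
  gu <- metric_g(u_perp, u_perp, mA$metric)
  dd2 <- extended_distance_sq(u_perp, mA)
  expect_equal(dd2$total, gu / mA$beta, tolerance = 1e-8 * max(1, gu / mA$beta))
  expect_lt(dd2$mahalanobis, 1e-8)
})

test_that("projection onto the training span is idempotent and the distance
           shrinks with beta", {
  mA <- tiny_models()$mA
  set.seed(9)
  u <- matrix(rnorm(3 * 33^3, 0, 0.005), 33^3, 3)
  project <- function(u) {
    uv <- as.numeric(u)
    b <- as.numeric(crossprod(mA$U, as.numeric(mA$metric$H %*% uv)))
    eg <- eigen(mA$G, symmetric = TRUE)
    pos <- eg$values > 1e-10 * max(eg$values)
    coef <- eg$vectors[, pos] %*% (crossprod(eg$vectors[, pos], b) /
                                   eg$values[pos])
    matrix(as.numeric(mA$U %*% coef), ncol = 3)
  }
  Pu <- project(u)
  PPu <- project(Pu)
  num <- metric_g(Pu - PPu, Pu - PPu, mA$metric)
  den <- max(metric_g(Pu, Pu, mA$metric), 1e-12)
  expect_lt(num / den, 1e-10)
  # d^2 non-increasing in beta
  m2 <- mA
  ds <- vapply(c(1e-6, 1e-5, 1e-3, 1e-1), function(b) {
    m2$beta <- b
    extended_distance_sq(u, m2)$total
  }, 0)
  expect_true(all(diff(ds) <= 1e-9))
  # beta -> Inf limit: only the projected Mahalanobis part remains
  m2$beta <- 1e12
  expect_equal(extended_distance_sq(u, m2)$total, mahalanobis_sq(Pu, mA),
               tolerance = 1e-6)
})

test_that("class averages and training samples classify to their own
           class", {
  tm <- tiny_models()
  models <- list(tm$mA, tm$mB)
  rA <- classify_shape(tm$mA$average$average, models)
  expect_identical(rA$label, "A")
  rB <- classify_shape(tm$mB$average$average, models)
  expect_identical(rB$label, "B")
  # a class average embeds into its own model at near-zero distance
  uAA <- embed_shape(tm$mA$average$average, tm$mA, recenter = FALSE)
  raw <- uAA$displacement + tm$mA$pca$mean_displacement
  expect_lt(sqrt(metric_g(raw, raw, tm$mA$metric)), 1e-3)
})

test_that("training samples embed onto their own training displacements", {
  tm <- tiny_models()
  u <- embed_shape(tm$sA[[1]], tm$mA)
  ut <- tm$mA$pca$displacements[[1]]
  diff <- u$displacement - ut$displacement
  rel <- sqrt(metric_g(diff, diff, tm$mA$metric) /
              max(metric_g(ut, ut, tm$mA$metric), 1e-300))
  expect_lt(rel, 0.1)
})

test_that("average-only distances are near zero at the average and grow
           with shape difference", {
  tm <- tiny_models()
  d0 <- average_only_distance(tm$mA$average$average, tm$mA,
                              recenter = FALSE)
  expect_lt(d0, 1e-3)
  g <- grid3(33L)
  avg_sphere <- elastic_average(list(
    voxelize_mesh(sphere_mesh(0.2), g), voxelize_mesh(sphere_mesh(0.2), g)))
  ds <- vapply(c(0.20, 0.22, 0.24), function(r)
    match_shapes(voxelize_mesh(sphere_mesh(r), g), avg_sphere$average,
                 avg_sphere$params)$objective, 0)
  expect_true(all(diff(ds) > 0))
})

test_that("classification validates its inputs", {
  tm <- tiny_models()
  expect_error(classify_shape(tm$sA[[1]], list(tm$mA)), "at least 2")
  g17 <- grid3(17L)
  wrong_grid <- voxelize_mesh(sphere_mesh(0.3, subdiv = 2L), g17)
  expect_error(embed_shape(wrong_grid, tm$mA), "grid mismatch")
})

test_that("confusion matrices count and normalize correctly", {
  truth <- c("a", "a", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "a")
  cm <- confusion_matrix(pred, truth)
  expect_equal(sum(cm$counts), 5)
  expect_equal(rowSums(cm$counts), c(a = 2, b = 2, c = 1))
  expect_equal(cm$accuracy, 3 / 5)
  expect_equal(rowSums(cm$rates), c(a = 1, b = 1, c = 1))
  perfect <- confusion_matrix(truth, truth)
  expect_equal(perfect$counts, diag(c(2, 2, 1)), ignore_attr = TRUE)
  all_first <- confusion_matrix(rep("a", 5), truth)
  expect_equal(sum(all_first$counts[, "a"]), 5)
  expect_error(confusion_matrix(pred[1:3], truth), "length")
})
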