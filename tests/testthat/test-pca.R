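test_that("the Hessian metric annihilates infinitesimal rigid motions", {
  chi <- sphere_chi_33()
  met <- elastic_metric(chi)
  N <- chi$grid$n^3
  nodes <- grid_nodes(chi$grid)
  xc <- sweep(nodes, 2, c(0.5, 0.5, 0.5))
  for (u in list(matrix(rep(c(1, 0, 0), each = N), N, 3),
                 matrix(rep(c(0, -1, 2), each = N), N, 3),
                 cbind(-xc[, 2], xc[, 1], 0),
                 cbind(0, -xc[, 3], xc[, 2])))
    expect_lt(abs(metric_g(u, u, met)), 1e-10)
})

test_that("the metric is a symmetric positive semi-definite bilinear form", {
  chi <- sphere_chi_33()
  met <- elastic_metric(chi)
  N <- chi$grid$n^3
  set.seed(3)
  u <- matrix(rnorm(3 * N, 0, 0.01), N, 3)
  v <- matrix(rnorm(3 * N, 0, 0.01), N, 3)
  w <- matrix(rnorm(3 * N, 0, 0.01), N, 3)
  expect_gt(metric_g(u, u, met), 0)
  expect_lt(abs(metric_g(u, v, met) - metric_g(v, u, met)), 1e-12)
  a <- 1.7; b <- -0.4
  expect_equal(metric_g(a * u + b * w, v, met),
               a * metric_g(u, v, met) + b * metric_g(w, v, met),
               tolerance = 1e-10)
})

test_that("Gram matrix and modes reproduce direct covariance PCA under a
           Euclidean surrogate metric", {
  set.seed(11)
  m <- 6; d <- 40
  X <- matrix(rnorm(m * d), d, m) %*% diag(c(5, 3, 2, 1, 0.5, 0.2))
  X <- sweep(X, 1, rowMeans(X))  # centered data
  disp <- lapply(seq_len(m), function(i) X[, i])
  C <- gram_matrix(disp, "euclidean")
  expect_equal(C, crossprod(X) / m, tolerance = 1e-12)
  expect_true(isSymmetric(C))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  pm <- principal_modes(disp, "euclidean")
  # direct covariance route
  cov_eig <- eigen(X %*% t(X) / m, symmetric = TRUE)
  k <- pm$n_retained
  expect_equal(pm$variances[seq_len(k)], cov_eig$values[seq_len(k)],
               tolerance = 1e-8)
  # same principal subspace: projectors agree
  W <- pm$modes
  U <- cov_eig$vectors[, seq_len(k)]
  Wn <- apply(W, 2, function(x) x / sqrt(sum(x^2)))
  expect_lt(max(abs(Wn %*% t(Wn) - U %*% t(U))), 1e-6)
  # centered data: smallest eigenvalue collapses
  expect_lt(min(pm$variances), 1e-10 * max(pm$variances))
  # custom metric function route agrees
  C2 <- gram_matrix(disp, function(u, v) sum(u * v))
  expect_equal(C2, C, tolerance = 1e-12)
})

test_that("rank-one and antisymmetric displacement sets give the printed
           Gram structure", {
  u <- rnorm(30)
  C1 <- gram_matrix(list(u, u, u), "euclidean")
  ev <- eigen(C1, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2], 1e-10 * ev[1])
  C2 <- gram_matrix(list(u, -u), "euclidean")
  expect_equal(C2, sum(u^2) / 2 * matrix(c(1, -1, -1, 1), 2),
               tolerance = 1e-12)
})

test_that("displacement centering removes the mean exactly", {
  g <- grid3(9L)
  set.seed(5)
  ds <- lapply(1:4, function(i)
    deformation_field(matrix(rnorm(3 * g$n^3, 0, 0.01), g$n^3, 3), g))
  cd <- center_displacements(ds)
  total <- Reduce(`+`, lapply(cd, `[[`, "displacement"))
  expect_lt(max(abs(total)), 1e-12)
  cd2 <- center_displacements(cd)
  expect_equal(cd2[[2]]$displacement, cd[[2]]$displacement,
               tolerance = 1e-14)
  all_equal <- center_displacements(list(ds[[1]], ds[[1]], ds[[1]]))
  expect_lt(max(abs(all_equal[[1]]$displacement)), 1e-14)
})

test_that("identity and translation deformations induce zero traction", {
  chi <- sphere_chi_33()
  g <- chi$grid
  idd <- elastroot:::identity_deformation(g)
  tr0 <- boundary_stress(idd, chi)
  expect_lt(max(abs(tr0$tractions)), 1e-10)
  expect_equal(sqrt(rowSums(tr0$normals^2)), rep(1, nrow(tr0$normals)),
               tolerance = 1e-6)
  shift <- deformation_field(matrix(rep(c(0.03, 0.01, -0.02),
                                        each = g$n^3), g$n^3, 3), g)
  tr1 <- boundary_stress(shift, chi)
  expect_lt(max(abs(tr1$tractions)), 1e-8)
})

test_that("uniform dilation induces constant-magnitude radial traction on a
           spherical average", {
  chi <- sphere_chi_33()
  g <- chi$grid
  s <- 1.06
  nodes <- grid_nodes(g)
  # phi maps the input onto the average: the input is the average shrunk by
  # 1/s, so the gradient of phi at the preimage is s I
  aff <- deformation_field((s - 1) * sweep(nodes, 2, c(0.5, 0.5, 0.5)), g)
  tr <- boundary_stress(aff, chi)
  P <- pk_stress(s * diag(3))
  expected_mag <- abs(P[1, 1] * s / s^3)  # |det|^-1 P F^T on a unit normal
  mags <- sqrt(rowSums(tr$tractions^2))
  expect_equal(stats::median(mags), expected_mag, tolerance = 0.1)
  # tractions align with the outward normal (expansion pulls outward)
  align <- rowSums(tr$tractions * tr$normals) / pmax(mags, 1e-12)
  expect_gt(stats::median(abs(align)), 0.99)
})

test_that("the equilibrium solve is linear and kernel-free", {
  chi <- sphere_chi_33()
  met <- elastic_metric(chi)
  idd <- elastroot:::identity_deformation(chi$grid)
  surf <- boundary_stress(idd, chi)
  u0 <- stress_to_displacement(surf, met)
  expect_lt(max(abs(u0$displacement)), 1e-10)
  # constant radial traction: radial displacement with small angular spread
  surf$tractions <- surf$normals * 0.01
  u1 <- stress_to_displacement(surf, met)
  vals <- sapply(1:3, function(p)
    elastroot:::cpp_resample(u1$displacement[, p], chi$grid$n, surf$points,
                             0))
  radial <- rowSums(vals * surf$normals)
  expect_lt(stats::sd(radial) / abs(mean(radial)), 0.1)
  # scaling the traction scales the displacement
  surf$tractions <- surf$normals * 0.03
  u3 <- stress_to_displacement(surf, met)
  expect_equal(u3$displacement, 3 * u1$displacement, tolerance = 1e-8)
  # the solution is orthogonal to the rigid kernel
  expect_lt(abs(sum(u1$displacement[met$active_nodes, 1])) /
            sum(abs(u1$displacement[met$active_nodes, 1])), 1e-6)
})

test_that("elastic PCA on a root ensemble yields g-orthonormal modes and a
           balanced traction set", {
  ep <- small_pca()
  k <- min(3, ep$n_retained)
  for (j in seq_len(k)) for (l in seq_len(k)) {
    got <- metric_g(matrix(ep$modes[, j], ncol = 3),
                    matrix(ep$modes[, l], ncol = 3), ep$metric)
    expect_equal(got, as.numeric(j == l), tolerance = 1e-6)
  }
  expect_true(all(diff(ep$variances) <= 1e-12))
  expect_lt(min(ep$variances), 1e-10 * max(ep$variances))  # centered
  # the average balances the ensemble: net traction small vs magnitudes
  net <- Reduce(`+`, lapply(ep$tractions, function(t)
    colSums(t$tractions * t$weights)))
  mean_mag <- mean(vapply(ep$tractions, function(t)
    sum(sqrt(rowSums(t$tractions^2)) * t$weights), 0))
  expect_lt(sqrt(sum(net^2)), 0.5 * mean_mag)
})

test_that("mode rendering is linear in the amplitude", {
  ep <- small_pca()
  am <- ep$average
  m0 <- render_mode(am, 1, 0, pca = ep)
  expect_true(nrow(m0$vertices) > 100)
  lam1 <- sqrt(ep$variances[1])
  mp <- render_mode(am, 1, lam1, pca = ep)
  mm <- render_mode(am, 1, -lam1, pca = ep)
  m2 <- render_mode(am, 1, 2 * lam1, pca = ep)
  dp <- mp$vertices - m0$vertices
  dm <- mm$vertices - m0$vertices
  expect_equal(dp, -dm, tolerance = 1e-10)
  expect_equal(m2$vertices - m0$vertices, 2 * dp, tolerance = 1e-10)
})
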