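# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

sphere_mesh <- function(r = 0.3, center = c(0.5, 0.5, 0.5), subdiv = 3L)
  icosphere(subdiv, r, center)

# axis-aligned box as a 12-triangle mesh
box_mesh <- function(lo = c(0.3, 0.35, 0.25), hi = c(0.7, 0.65, 0.75)) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = lo
    c(5, 6, 7), c(6, 8, 7),   # z = hi
    c(1, 2, 5), c(2, 6, 5),   # y = lo
    c(3, 7, 4), c(4, 7, 8),   # y = hi
    c(1, 5, 3), c(3, 5, 7),   # x = lo
    c(2, 4, 6), c(4, 8, 6))   # x = hi
  tri_mesh(v, f)
}

sphere_chi_33 <- function()
  fixture("sphere_chi_33", function()
    voxelize_mesh(sphere_mesh(0.3), grid3(33L)))

small_root_ensemble <- function() {
  fixture("small_root_ensemble", function() {
    g <- grid3(33L)
    shapes <- lapply(1:5, function(i)
      voxelize_mesh(generate_root(root_params(
        body_length = 0.5 + 0.015 * (i %% 3), apex_length = 0.1 + 0.01 * i,
        seed = 40 + i)), g))
    vol <- stats::median(vapply(shapes, field_volume, 0))
    lapply(shapes, rescale_to_volume, target_volume = vol)
  })
}

small_average <- function()
  fixture("small_average", function() elastic_average(small_root_ensemble()))

small_pca <- function()
  fixture("small_pca", function() elastic_pca(small_average()))

# a tiny two-class training setup shared by classifier and acceptance tests
tiny_models <- function() {
  fixture("tiny_models", function() {
    g <- grid3(33L)
    mk <- function(n_ap, al, seedbase, k) lapply(seq_len(k), function(i)
      voxelize_mesh(generate_root(root_params(
        n_apices = n_ap, apex_length = al,
        body_length = 0.5 + 0.01 * (i %% 3), seed = seedbase + i)), g))
    sA <- mk(1L, 0.10, 100, 5)
    sB <- mk(2L, 0.22, 200, 5)
    vol <- stats::median(vapply(c(sA, sB), field_volume, 0))
    sA <- lapply(sA, rescale_to_volume, target_volume = vol)
    sB <- lapply(sB, rescale_to_volume, target_volume = vol)
    list(mA = cultivar_model("A", sA), mB = cultivar_model("B", sB),
         sA = sA, sB = sB)
  })
}
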