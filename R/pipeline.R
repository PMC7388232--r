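#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with production
#' defaults (\code{n = 129}, \eqn{\mu = \lambda = 1}, \eqn{\gamma = 50},
#' \eqn{\sigma = 0.01}, \eqn{\epsilon = 10^{-4}}, \eqn{\beta = 10^{-5}},
#' \eqn{M = 13}) and a desk-scale \code{"test"} profile at \code{n = 33}.
#'
#' @param profile \code{"test"} (n = 33, default) or \code{"production"}
#'   (n = 129).
#' @param n Grid nodes per axis (overrides the profile).
#' @param mu,lam,gamma Elastic and penalty parameters.
#' @param sigma_reg,epsilon Signed-distance regularization parameters.
#' @param beta,M Classifier regularization and truncation.
#' @param levels Matching cascade levels.
#' @param match_iter Per-level iteration cap for every matching solve in
#'   the pipeline (default 150 in the test profile, 300 in the production
#'   profile; the objective decrease beyond 150 fine-level iterations is
#'   orders of magnitude below the class separation scale).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param n_samples Samples per class.
#' @param holdout_per_class Held-out test samples per class.
#' @param subdiv Mesh subdivision of the generator.
#' @param target_volume Common volume for normalization, or \code{"auto"}
#'   (median of the voxelized ensemble).
#' @param unscaled_pca Also run the per-class PCA without volume
#'   normalization (for the rescaling-stability report; default TRUE).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(profile = c("test", "production"), n = NULL, mu = 1,
                            lam = 1, gamma = 50, sigma_reg = 0.01,
                            epsilon = 1e-4, beta = 1e-5, M = 13L,
                            levels = 3L, seed = 1L, n_samples = 35L,
                            holdout_per_class = 5L, subdiv = 3L,
                            target_volume = "auto", unscaled_pca = TRUE,
                            match_iter = NULL) {
  profile <- match.arg(profile)
  if (is.null(n)) n <- if (profile == "production") 129L else 33L
  if (is.null(match_iter))
    match_iter <- if (profile == "production") 300L else 150L
  cfg <- list(profile = profile, n = as.integer(n), mu = mu, lam = lam,
              gamma = gamma, sigma_reg = sigma_reg, epsilon = epsilon,
              beta = beta, M = as.integer(M), levels = as.integer(levels),
              seed = as.integer(seed), n_samples = as.integer(n_samples),
              holdout_per_class = as.integer(holdout_per_class),
              subdiv = as.integer(subdiv), target_volume = target_volume,
              unscaled_pca = isTRUE(unscaled_pca),
              match_iter = as.integer(match_iter))
  num <- unlist(cfg[c("n", "mu", "lam", "gamma", "sigma_reg", "epsilon",
                      "beta", "M", "levels", "n_samples", "subdiv",
                      "match_iter")])
  if (any(num <= 0)) stop("pipeline_config: numeric fields must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#' @param config A \code{pipeline_config}.
#' @param path JSON file path.
#' @return \code{path} / the restored \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Default four-class synthetic benchmark
#'
#' Four root classes in the vocabulary of sugar-beet cultivar variation:
#' a multi-apex class, a long-apex class, a dull (strongly tapered,
#' short-apex) class, and a slim elongated single-apex class. Spreads are
#' chosen so classes overlap in simple size traits while differing in apex
#' structure and taper.
#'
#' @param n_samples Samples per class.
#' @param seed Master seed; per-class seeds are derived by hashing.
#' @return List of four \code{class_spec}s.
#' @export
default_benchmark_specs <- function(n_samples = 35L, seed = 1L) {
  # within-class spreads: shape attributes vary at most a third of any
  # between-class difference in the class-defining attribute, while the
  # independent size factor (12% linear CV, emulating environmental size
  # variation) dwarfs them all so uniform scaling dominates the raw data
  sds_common <- list(body_length = 0.02, max_radius = 0.008,
                     taper_exponent = 0.12, apex_length = 0.02,
                     apex_angle = 0.04, size = 0.12)
  mk <- function(name, means, extra_sds = list(), idx) {
    class_spec(name, means, utils::modifyList(sds_common, extra_sds),
               n_samples = n_samples, seed = seed_hash(seed, 100 + idx))
  }
  # four cultivar-like archetypes differing in apex count, apex length and
  # taper: a full-bodied double apex, an overall conical root ending in a
  # long apex, a blunt barrel with hardly any apex, and a slim elongated
  # single-apex form
  list(
    mk("multiapex",
       root_params(body_length = 0.50, max_radius = 0.13,
                   taper_exponent = 1.0, n_apices = 2L, apex_length = 0.16,
                   apex_angle = 0.55, roughness_amp = 0.006),
       list(), 1),
    mk("longapex",
       root_params(body_length = 0.42, max_radius = 0.15,
                   taper_exponent = 2.0, n_apices = 1L, apex_length = 0.28,
                   roughness_amp = 0.006),
       list(), 2),
    mk("dull",
       root_params(body_length = 0.58, max_radius = 0.15,
                   taper_exponent = 3.2, n_apices = 1L, apex_length = 0.04,
                   roughness_amp = 0.006),
       list(), 3),
    mk("slim",
       root_params(body_length = 0.63, max_radius = 0.115,
                   taper_exponent = 1.0, n_apices = 1L, apex_length = 0.16,
                   roughness_amp = 0.006),
       list(), 4)
  )
}

#' Run the full benchmark pipeline
#'
#' Generate a labeled synthetic benchmark, voxelize and volume-normalize all
#' shapes, compute per-class elastic averages and PCAs, classify the
#' held-out shapes with the extended Mahalanobis distance and the
#' average-only baseline, run the five-trait Euclidean-PCA baseline, and
#' (optionally) repeat the per-class PCA without volume normalization to
#' report rescaling stability of the variance spectrum.
#'
#' @param config A \code{pipeline_config}.
#' @param specs Optional list of \code{class_spec}s (default
#'   \code{\link{default_benchmark_specs}} under the config seed).
#' @param verbose Log stage progress and timings (default TRUE).
#' @return A \code{pipeline_report}; see Details. Key fields:
#'   \code{accuracy}, \code{accuracy_average_only}, \code{accuracy_traits},
#'   \code{confusion}, \code{binomial_p}, \code{models},
#'   \code{variances}, \code{variance_ratio_agreement}, \code{timings}.
#' @export
run_pipeline <- function(config = pipeline_config(), specs = NULL,
                         verbose = TRUE) {
  t_all <- proc.time()[3]
  timings <- c()
  log_stage <- function(name, t0) {
    el <- proc.time()[3] - t0
    timings[[name]] <<- el
    if (verbose) message(sprintf("[%s] %.1fs", name, el))
  }
  grid <- grid3(config$n)
  params <- elastic_params(config$mu, config$lam, config$gamma)
  reg <- regularization_params(config$sigma_reg, config$epsilon)
  if (is.null(specs))
    specs <- default_benchmark_specs(config$n_samples, config$seed)
  labels_all <- vapply(specs, `[[`, "", "name")

  t0 <- proc.time()[3]
  bench <- generate_benchmark(specs, config$holdout_per_class, config$seed,
                              subdiv = config$subdiv)
  log_stage("generate", t0)

  t0 <- proc.time()[3]
  # volume normalization happens on the surface, before voxelization, so
  # that thin apices of small specimens survive the grid
  vols <- vapply(c(bench$train$meshes, bench$test$meshes), mesh_volume, 0)
  target <- if (identical(config$target_volume, "auto"))
    stats::median(vols) else config$target_volume
  vox_train <- lapply(bench$train$meshes, function(m)
    voxelize_mesh(rescale_mesh_to_volume(m, target), grid, reg))
  vox_test <- lapply(bench$test$meshes, function(m)
    voxelize_mesh(rescale_mesh_to_volume(m, target), grid, reg))
  log_stage("voxelize", t0)

  if (length(specs) < 2) {
    if (verbose) message("single class: classification stage skipped")
    models <- lapply(labels_all, function(lb) {
      idx <- bench$train$labels == lb
      cultivar_model(lb, vox_train[idx], params, M = config$M,
                     beta = config$beta, match_iter = config$match_iter)
    })
    return(structure(list(config = config, benchmark = bench,
                          models = models, classification = NULL,
                          accuracy = NA_real_, timings = timings),
                     class = "pipeline_report"))
  }

  t0 <- proc.time()[3]
  models <- lapply(labels_all, function(lb) {
    idx <- bench$train$labels == lb
    cultivar_model(lb, vox_train[idx], params, M = config$M,
                   beta = config$beta, match_iter = config$match_iter)
  })
  log_stage("train", t0)

  # classification of the held-out shapes
  t0 <- proc.time()[3]
  results <- lapply(vox_test, classify_shape, models = models)
  predicted <- vapply(results, `[[`, "", "label")
  predicted_avg <- vapply(results, `[[`, "", "average_only_label")
  truth <- bench$test$labels
  conf <- confusion_matrix(predicted, truth, levels = labels_all)
  conf_avg <- confusion_matrix(predicted_avg, truth, levels = labels_all)
  n_test <- length(truth)
  binom <- if (n_test > 0)
    stats::binom.test(sum(predicted == truth), n_test,
                      p = 1 / length(labels_all),
                      alternative = "greater")$p.value else NA_real_
  log_stage("classify", t0)

  # five-trait Euclidean baseline on the original meshes
  t0 <- proc.time()[3]
  traits_train <- t(sapply(bench$train$meshes, compute_traits))
  traits_test <- t(sapply(bench$test$meshes, compute_traits))
  tp <- trait_pca(traits_train)
  trait_pred <- trait_nearest_centroid(tp, bench$train$labels, traits_test)
  conf_traits <- confusion_matrix(trait_pred, truth, levels = labels_all)
  log_stage("traits", t0)

  # variance spectra with vs without volume normalization
  variances <- lapply(models, function(mo)
    mo$pca$variances[mo$pca$retained])
  names(variances) <- labels_all
  ratio_agreement <- NULL
  variances_unscaled <- NULL
  if (config$unscaled_pca) {
    t0 <- proc.time()[3]
    vox_raw_train <- lapply(bench$train$meshes, voxelize_mesh, grid = grid,
                            reg = reg)
    pca_unscaled <- lapply(labels_all, function(lb) {
      idx <- bench$train$labels == lb
      elastic_pca(elastic_average(vox_raw_train[idx], params,
                                  match_iter = config$match_iter),
                  match_iter = config$match_iter)
    })
    variances_unscaled <- lapply(pca_unscaled, function(p)
      p$variances[p$retained])
    names(variances_unscaled) <- labels_all
    ratio_agreement <- mapply(function(lam, lamt) {
      # scaled lambda_k corresponds to unscaled lambda-tilde_k (the dominant
      # unscaled mode absorbs uniform scaling): compare consecutive ratios
      # lambda_{k-1}/lambda_k vs tilde_{k-1}/tilde_k for k > 1
      kmax <- min(length(lam) - 1, length(lamt) - 2, 4)
      if (kmax < 2) return(NA_real_)
      r_scaled <- lam[seq_len(kmax - 1)] / lam[2:kmax]
      r_unscaled <- lamt[1 + seq_len(kmax - 1)] / lamt[1 + (2:kmax)]
      max(abs(r_scaled / r_unscaled - 1))
    }, variances, variances_unscaled)
    log_stage("unscaled_pca", t0)
  }

  timings[["total"]] <- proc.time()[3] - t_all
  structure(list(config = config, specs = specs, benchmark = bench,
                 target_volume = target, models = models,
                 results = results, predicted = predicted, truth = truth,
                 confusion = conf, accuracy = conf$accuracy,
                 confusion_average_only = conf_avg,
                 accuracy_average_only = conf_avg$accuracy,
                 confusion_traits = conf_traits,
                 accuracy_traits = conf_traits$accuracy,
                 binomial_p = binom, trait_pca = tp,
                 variances = variances,
                 variances_unscaled = variances_unscaled,
                 variance_ratio_agreement = ratio_agreement,
                 timings = timings),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$classification) || !is.na(x$accuracy)) {
    cat(sprintf("  extended-Mahalanobis accuracy: %.3f\n", x$accuracy))
    cat(sprintf("  average-only baseline:        %.3f\n",
                x$accuracy_average_only))
    cat(sprintf("  trait-PCA baseline:           %.3f\n", x$accuracy_traits))
    cat(sprintf("  one-sided binomial p (vs %.2f): %.4g\n",
                1 / nrow(x$confusion$counts), x$binomial_p))
    cat("  confusion (rows = truth):\n")
    print(x$confusion$counts)
  }
  invisible(x)
}
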