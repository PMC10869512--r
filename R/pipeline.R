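#' Default pipeline configuration
#'
#' Defaults reproduce the full-scale study conditions: 21 families with 5
#' morphological variants each, 100 probe placements per model, a
#' 400-unit-per-family balanced tensor, ranks 1-19 with 4 restarts. The
#' `families`, `variants`, `probes_per_model` and `quota` fields scale the
#' problem down for desk-size runs.
#'
#' @param families Character vector of archetype families (default: all 21).
#' @param variants Morphological variants per family.
#' @param probes_per_model Probe placements per model.
#' @param quota Canonical units retained per family.
#' @param sigma Extracellular conductivity, S/m.
#' @param noise A [noise_config()].
#' @param R_range Candidate ranks for selection.
#' @param R_fixed Optional fixed rank (skips rank selection).
#' @param n_restarts Restarts per rank.
#' @param tol,max_iter Decomposition stopping parameters.
#' @param me_threshold ME dendrogram cut (normalized distance); `NA` selects
#'   the largest threshold yielding `me_classes` classes.
#' @param me_classes Target ME class count when `me_threshold` is `NA`.
#' @param n_boot_cca,n_per_model Bootstrapped-CCA parameters.
#' @param n_boot_centroids Centroid bootstrap draws.
#' @param run_exclusion Run the leave-one-out ME exclusion analysis.
#' @param normalize_units Normalize each unit's waveforms by its maximum
#'   amplitude before feature extraction (see [normalize_units()]); on by
#'   default so prevalences describe waveform composition rather than
#'   absolute magnitude.
#' @return A validated `pipeline_config` list.
#' @export
default_config <- function(families = archetype_table()$family,
                           variants = 5L, probes_per_model = 100L,
                           quota = 400L, sigma = 0.3,
                           noise = noise_config(),
                           R_range = 1:19, R_fixed = NULL, n_restarts = 4L,
                           tol = 1e-6, max_iter = 500L,
                           me_threshold = NA_real_, me_classes = 6L,
                           n_boot_cca = 1000L, n_per_model = 50L,
                           n_boot_centroids = 1000L,
                           run_exclusion = FALSE, normalize_units = TRUE) {
  cfg <- list(families = families, variants = as.integer(variants),
              probes_per_model = as.integer(probes_per_model),
              quota = as.integer(quota), sigma = sigma, noise = noise,
              R_range = R_range, R_fixed = R_fixed,
              n_restarts = as.integer(n_restarts), tol = tol,
              max_iter = as.integer(max_iter),
              me_threshold = me_threshold, me_classes = as.integer(me_classes),
              n_boot_cca = as.integer(n_boot_cca),
              n_per_model = as.integer(n_per_model),
              n_boot_centroids = as.integer(n_boot_centroids),
              run_exclusion = isTRUE(run_exclusion),
              normalize_units = isTRUE(normalize_units))
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema check run before any computation; violations raise a
#' configuration error naming the field.
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  bad <- function(field, why) {
    abort(paste0("invalid config field '", field, "': ", why),
          class = "eap_config_error")
  }
  known <- archetype_table()$family
  if (length(cfg$families) < 1) bad("families", "must name >= 1 family")
  if (!all(cfg$families %in% known)) {
    bad("families", paste("unknown:",
        paste(setdiff(cfg$families, known), collapse = ", ")))
  }
  if (cfg$variants < 1) bad("variants", "must be >= 1")
  if (cfg$probes_per_model < 1) bad("probes_per_model", "must be >= 1")
  if (cfg$quota < 1) bad("quota", "must be >= 1")
  if (cfg$sigma <= 0) bad("sigma", "must be > 0")
  if (cfg$n_restarts < 2) bad("n_restarts", "must be >= 2")
  if (!is.null(cfg$R_fixed) && cfg$R_fixed < 1) bad("R_fixed", "must be >= 1")
  if (!is.na(cfg$me_threshold) &&
      (cfg$me_threshold <= 0 || cfg$me_threshold > 1)) {
    bad("me_threshold", "must lie in (0, 1]")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys override the [default_config()] fields.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  noise_args <- raw$noise
  raw$noise <- NULL
  cfg <- do.call(default_config, c(raw,
    if (!is.null(noise_args)) list(noise = do.call(noise_config, noise_args))))
  cfg
}

# deterministic per-stage child seeds derived from one base seed
stage_seed <- function(base_seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, balance = 37L, demix = 53L,
               order = 67L, analysis = 79L, hierarchy = 97L, cca = 113L)
  (as.integer(base_seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate the labeled single-unit dataset
#'
#' For every (family, variant): builds the morphology and current
#' templates, runs the detectability scan, samples probe placements within
#' the detectability limit, simulates the 64-channel raw recordings and
#' preprocesses them into noisy, median-shifted unit recordings.
#'
#' @param cfg A [default_config()].
#' @param seed Integer base seed.
#' @return List: `units` (list of `unit_recording`), `morphologies` (list),
#'   `detectability` (tibble family/variant/limit/undetectable).
#' @export
simulate_dataset <- function(cfg, seed = 0L) {
  units <- list()
  morphs <- list()
  detect <- list()
  sim_seed <- stage_seed(seed, "simulate")
  k <- 0L
  for (fam in cfg$families) {
    for (v in seq_len(cfg$variants)) {
      k <- k + 1L
      morph <- build_archetype_morphology(fam, variant_seed = v)
      templates <- generate_current_templates(morph)
      scan <- detectability_scan(morph, templates, sigma = cfg$sigma,
                                 seed = sim_seed + k)
      detect[[k]] <- tibble(family = fam, variant = v, limit = scan$limit,
                            undetectable = scan$undetectable)
      morphs[[paste(fam, v)]] <- morph
      if (scan$undetectable || !is.finite(scan$limit) || scan$limit <= 10) {
        next
      }
      placements <- sample_probes(morph, scan$limit,
                                  n_locations = cfg$probes_per_model,
                                  seed = sim_seed + 1000L + k)
      pre_seed <- stage_seed(seed, "preprocess") + 1000L * k
      for (p in seq_len(nrow(placements))) {
        raw <- simulate_unit(morph, templates, placements[p, ],
                             sigma = cfg$sigma)
        old <- .Random.seed_save()
        set.seed((pre_seed + p) %% .Machine$integer.max)
        units[[length(units) + 1L]] <- preprocess_unit(raw, cfg$noise)
        .Random.seed_restore(old)
      }
    }
  }
  list(units = units, morphologies = morphs,
       detectability = dplyr::bind_rows(detect))
}

#' Run the end-to-end demixing pipeline
#'
#' simulate -> preprocess -> center/balance -> Haar features -> rank
#' selection (or fixed rank) -> non-negative CP -> importance ordering ->
#' family classification, EI clustering benchmark, morphometrics + CCA,
#' distance scaling -> ME hierarchy (optional exclusion analysis). Fully
#' reproducible from (config, seed); per-stage child seeds are derived from
#' the base seed so stages can be rerun in isolation.
#'
#' @param cfg A [default_config()].
#' @param seed Integer base seed.
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV and the run summary as JSON.
#' @return A `pipeline_result` list (tensor metadata, demix model,
#'   diagnostics, analysis reports, hierarchy).
#' @export
run_pipeline <- function(cfg = default_config(), seed = 0L, out_dir = NULL) {
  validate_config(cfg)
  sim <- simulate_dataset(cfg, seed)
  centered <- center_units(sim$units)
  bal <- balance_dataset(centered, cfg$quota,
                         seed = stage_seed(seed, "balance"), strict = FALSE)
  X <- bal$X
  meta <- bal$meta
  if (isTRUE(cfg$normalize_units)) X <- normalize_units(X)
  Ft <- build_feature_tensor(X)

  if (is.null(cfg$R_fixed)) {
    rs <- select_rank(Ft, meta$family, R_range = cfg$R_range,
                      n_restarts = cfg$n_restarts,
                      base_seed = stage_seed(seed, "demix"), tol = cfg$tol,
                      max_iter = cfg$max_iter)
    R_star <- rs$R_star
    model <- rs$fits[[as.character(R_star)]]
    rank_diag <- rs$diagnostics
  } else {
    R_star <- as.integer(cfg$R_fixed)
    res <- ncp_restarts(Ft, R_star, n_restarts = cfg$n_restarts,
                        base_seed = stage_seed(seed, "demix"), tol = cfg$tol,
                        max_iter = cfg$max_iter)
    model <- res$best
    errs <- vapply(res$fits, function(m) m$reconstruction_error, numeric(1))
    sims <- vapply(res$fits[-which.min(errs)], function(m)
      as.numeric(decomposition_similarity(res$best, m)), numeric(1))
    rank_diag <- tibble(R = R_star, mean_similarity = mean(sims),
                        best_error = model$reconstruction_error,
                        candidate = NA, accuracy = NA_real_)
  }
  ord <- order_sources(model, meta$family,
                       seed = stage_seed(seed, "order"))
  model <- ord$model

  # supervised + unsupervised analyses over the unit prevalences
  a_seed <- stage_seed(seed, "analysis")
  family_report <- rf_classify(model$prevalence, meta$family, seed = a_seed)
  ei_labels <- family_ei_class(meta$family)
  ei_cluster <- if (length(unique(ei_labels)) == 2L) {
    clustering_benchmark(model$prevalence, ei_labels, seed = a_seed)
  } else NULL

  m_tab <- morphometric_table(sim$morphologies)
  cca <- lapply(seq_len(model$R), function(r) {
    bootstrap_cca(m_tab, model$prevalence, meta, r,
                  n_boot = cfg$n_boot_cca, n_per_model = cfg$n_per_model,
                  seed = stage_seed(seed, "cca") + r)
  })
  scaling <- distance_scaling(model$prevalence, meta)

  centroids <- bootstrap_centroids(model$prevalence, meta$family,
                                   n_boot = cfg$n_boot_centroids,
                                   seed = stage_seed(seed, "hierarchy"))
  thr <- cfg$me_threshold
  if (is.na(thr)) {
    thr <- threshold_for_classes(centroids,
                                 min(cfg$me_classes, nrow(centroids)))
    if (is.na(thr)) thr <- 0.45
  }
  hier <- build_hierarchy(centroids, thr)
  exclusion <- if (cfg$run_exclusion && hier$n_me_classes >= 2L) {
    exclusion_analysis(X, meta, model, hier,
                       seed = stage_seed(seed, "hierarchy") + 1L,
                       tol = cfg$tol, max_iter = cfg$max_iter)
  } else NULL

  result <- structure(list(
    config = cfg, seed = seed, meta = meta, X_dim = dim(X),
    detectability = sim$detectability,
    centering_summary = attr(centered, "centering_summary"),
    model = model, R_star = R_star, rank_diagnostics = rank_diag,
    importance = ord$importance,
    family_report = family_report, ei_cluster = ei_cluster,
    morphometrics = m_tab, cca = cca, scaling = scaling,
    centroids = centroids, hierarchy = hier, exclusion = exclusion),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  units:", x$X_dim[3], " families:", length(unique(x$meta$family)),
      "\n")
  cat("  selected rank:", x$R_star, " rel. error:",
      signif(x$model$reconstruction_error, 4), "\n")
  cat("  family classification (holdout):",
      sprintf("%.1f%%", 100 * x$family_report$holdout_accuracy), "\n")
  if (!is.null(x$ei_cluster)) {
    cat("  EI clustering accuracy:",
        paste(sprintf("%s %.1f%%", x$ei_cluster$method,
                      100 * x$ei_cluster$accuracy), collapse = ", "), "\n")
  }
  cat("  ME classes:", x$hierarchy$n_me_classes, "\n")
  invisible(x)
}

#' Write the pipeline artifacts as CSV/JSON
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(result$meta, "unit_meta.csv")
  wcsv(result$detectability, "detectability.csv")
  wcsv(result$rank_diagnostics, "rank_diagnostics.csv")
  wcsv(as.data.frame(result$model$spatial), "spatial_sources.csv")
  wcsv(as.data.frame(result$model$temporal), "temporal_sources.csv")
  wcsv(as.data.frame(result$model$prevalence), "prevalences.csv")
  wcsv(result$morphometrics, "morphometrics.csv")
  wcsv(result$scaling$fits, "distance_scaling.csv")
  wcsv(as.data.frame(result$centroids), "centroids.csv")
  if (!is.null(result$ei_cluster)) wcsv(result$ei_cluster, "ei_clustering.csv")
  summary <- list(
    seed = result$seed, n_units = result$X_dim[3], R_star = result$R_star,
    reconstruction_error = result$model$reconstruction_error,
    family_holdout_accuracy = result$family_report$holdout_accuracy,
    n_me_classes = result$hierarchy$n_me_classes,
    me_assignment = as.list(result$hierarchy$me_assignment))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Desk-scale configuration for the excitatory/inhibitory benchmark
#'
#' A reduced study configuration for the EI clustering and classification
#' benchmark: four apical-bearing excitatory archetypes against four
#' inhibitory archetypes, two morphological variants each, 30 probe
#' placements per model balanced at 40 units per family, and the four-source
#' demix model. Noise averaging uses 50 draws; the averaged-and-rescaled
#' noise has the same law for any draw count, so this only saves time.
#'
#' @return A validated `pipeline_config`.
#' @export
ei_benchmark_config <- function() {
  default_config(
    families = c("thick_tufted_pyr_a", "tufted_pyr_l4", "untufted_pyr_a",
                 "small_pyr_l2", "large_basket", "bitufted", "martinotti",
                 "neurogliaform"),
    variants = 2L, probes_per_model = 30L, quota = 40L,
    noise = noise_config(n_avg = 50L), R_fixed = 4L, n_restarts = 4L,
    max_iter = 300L, n_boot_cca = 30L, n_per_model = 20L,
    n_boot_centroids = 100L, me_classes = 4L)
}

#' Excitatory/inhibitory class of each archetype family
#'
#' @param families Character vector of family names.
#' @return Character vector of `"E"`/`"I"` labels.
#' @export
family_ei_class <- function(families) {
  tab <- archetype_table()
  setNames(tab$class, tab$family)[families]
}

#' Synthetic benchmark feature tensor with planted sources
#'
#' Builds a non-negative S x W x N tensor as the sum of `n_sources` planted
#' rank-1 components — distinct spatial bumps and multiresolution temporal
#' motifs for the signal sources plus one pervasive flat "noise" source
#' loaded on every unit — with unit prevalences structured by family (each
#' signal motif dominates one family) and a small additive noise floor.
#' Planted factor collinearity is kept below 0.5. Used for rank-recovery
#' and restart-similarity benchmarks.
#'
#' @param S,W,N Tensor dimensions.
#' @param n_sources Planted components (default 4: 3 signal + 1 noise).
#' @param noise Relative amplitude of the additive noise floor (default
#'   0.01).
#' @param seed Integer seed.
#' @return List: `F` (the tensor), `factors` (list of spatial/temporal/
#'   prevalence matrices), `labels` (family per unit).
#' @export
simulate_benchmark_tensor <- function(S = 31L, W = 128L, N = 180L,
                                      n_sources = 4L, noise = 0.01,
                                      seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n_signal <- n_sources - 1L
  ch <- seq_len(S)
  centers <- seq(6, S - 5, length.out = n_signal)
  widths <- seq(2.5, 5, length.out = n_signal)
  spatial <- vapply(seq_len(n_signal), function(r)
    exp(-(ch - centers[r])^2 / (2 * widths[r]^2)), numeric(S))
  spatial <- cbind(spatial, rep(1, S) / sqrt(S))        # pervasive noise source

  temporal <- matrix(0, W, n_sources)
  starts <- floor(seq(2, W / 2, length.out = n_signal))
  for (r in seq_len(n_signal)) {
    idx <- starts[r]:(starts[r] + 7L)
    temporal[idx, r] <- runif(8, 0.5, 1)
  }
  tail_len <- max(2L, W %/% 4L)                            # fine-scale tail
  temporal[(W - tail_len + 1L):W, n_sources] <- runif(tail_len, 0.3, 0.6)

  labels <- rep(paste0("fam", seq_len(n_signal)), length.out = N)
  prevalence <- matrix(runif(N * n_sources, 0, 0.15), N, n_sources)
  for (r in seq_len(n_signal)) {
    m <- labels == paste0("fam", r)
    prevalence[m, r] <- prevalence[m, r] + runif(sum(m), 0.8, 1.2)
  }
  prevalence[, n_sources] <- runif(N, 0.6, 1.0)          # pervasive loading

  Ft <- array(0, dim = c(S, W, N))
  for (r in seq_len(n_sources)) {
    Ft <- Ft + outer(outer(spatial[, r], temporal[, r]), prevalence[, r])
  }
  scale <- mean(Ft[Ft > 0])
  Ft <- pmax(Ft + array(rnorm(length(Ft), 0, noise * scale), dim = dim(Ft)),
             0)
  list(F = Ft,
       factors = list(spatial = spatial, temporal = temporal,
                      prevalence = prevalence),
       labels = labels)
}
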