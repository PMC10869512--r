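test_that("random-forest classification separates what is separable", {
  set.seed(41)
  n <- 100
  labels <- rep(c("A", "B"), each = n / 2)
  sep <- cbind(ifelse(labels == "A", 0, 10) + rnorm(n, 0, 0.1), rnorm(n))
  grid <- list(max_depth = c(4, 0), num_trees = c(100))
  rep1 <- rf_classify(sep, labels, grid = grid, seed = 1)
  expect_equal(rep1$holdout_accuracy, 1)
  expect_true(all(rep1$gini_importances >= 0))
  expect_equal(sum(rep1$gini_importances), 1, tolerance = 1e-9)
  expect_equal(sum(rep1$confusion), 20)

  # shuffled labels: holdout accuracy within the binomial band of chance
  set.seed(42)
  shuf <- sample(labels)
  rep2 <- rf_classify(sep, shuf, grid = grid, seed = 2)
  band <- qbinom(c(0.025, 0.975), 20, 0.5) / 20
  expect_gte(rep2$holdout_accuracy, band[1] - 1e-9)
  expect_lte(rep2$holdout_accuracy, band[2] + 1e-9)

  # duplicating an informative feature barely moves the holdout accuracy
  rep3 <- rf_classify(cbind(sep, sep[, 1]), labels, grid = grid, seed = 1)
  expect_lte(abs(rep3$holdout_accuracy - rep1$holdout_accuracy), 0.02)

  expect_error(rf_classify(sep, rep("A", n), grid = grid),
               class = "eap_usage_error")
  expect_error(rf_classify(sep[1:3, ], c("A", "A", "B"), grid = grid),
               class = "eap_stratification_error")
})

test_that("baseline waveform features match hand-computed examples", {
  dt <- 5.6 / 128
  # triangle-like waveform: trough -60 at +0.175 ms, peak +20 at +1.575 ms
  t_rel <- (seq_len(128) - 33) * dt
  wf <- numeric(128)
  trough_i <- 33 + 4   # +0.175 ms
  peak_i <- 33 + 36    # +1.575 ms
  wf[trough_i] <- -60
  wf[peak_i] <- 20
  # linear flanks so the half-width crossings are well defined
  wf[trough_i - 1] <- -30; wf[trough_i + 1] <- -30
  unit <- list(waveforms = rbind(matrix(0, 15, 128), wf, matrix(0, 15, 128)),
               spike_index = 33L, dt = dt)
  bf <- baseline_features(unit)
  expect_equal(bf$peak_to_trough_duration, (peak_i - trough_i) * dt,
               tolerance = 1e-9)
  expect_equal(bf$peak_to_trough_duration, 1.4, tolerance = 1e-9)
  expect_equal(bf$peak_to_trough_ratio, 20 / 60, tolerance = 1e-9)
  # repolarization slope: 30 us after the trough, linear flank -30/-60
  # interpolated at 0.686 of a sample -> value -60 + 30 * (0.03 / dt)
  v30 <- -60 + 30 * (0.030 / dt)
  expect_equal(bf$repolarization_slope, (v30 - -60) / 0.030,
               tolerance = 1e-6)

  # spread rule: amplitudes 100/20/10/5 at 0/10/20/30 um, threshold 12%
  wfs <- matrix(0, 31, 128)
  wfs[16, 40] <- -100
  wfs[17, 40] <- -20
  wfs[18, 40] <- -10
  wfs[19, 40] <- -5
  u2 <- list(waveforms = wfs, spike_index = 33L, dt = dt)
  expect_equal(baseline_features(u2)$spread, 10)

  # velocity: troughs at +0.1/+0.2/+0.3 ms at 10/20/30 um above and the
  # mirror below; slopes all 100 um/ms, total = 200
  wf3 <- matrix(0, 31, 128)
  wf3[, 33] <- -1          # co-timed troughs elsewhere: excluded by the guard
  wf3[16, 33] <- -50
  offs <- c(0.1, 0.2, 0.3) / dt
  for (k in 1:3) {
    wf3[16 + k, ] <- 0
    wf3[16 - k, ] <- 0
    wf3[16 + k, round(33 + offs[k])] <- -30
    wf3[16 - k, round(33 + offs[k])] <- -30
  }
  u3 <- list(waveforms = wf3, spike_index = 33L, dt = dt)
  bf3 <- baseline_features(u3)
  slope_exp <- abs(median(c(10, 20, 30) / (round(33 + offs) - 33) / dt))
  expect_equal(bf3$propagation_velocity_above, slope_exp, tolerance = 1e-9)
  expect_equal(bf3$total_propagation_velocity, 2 * slope_exp,
               tolerance = 1e-9)

  # time-shift equivariance: durations unchanged
  sh <- cbind(unit$waveforms[, 5:128], matrix(0, 31, 4))
  bf_sh <- baseline_features(list(waveforms = sh, spike_index = 29L,
                                  dt = dt))
  expect_equal(bf_sh$peak_to_trough_duration, bf$peak_to_trough_duration,
               tolerance = 1e-9)
})

test_that("bootstrapped CCA recovers a planted linear relation and rejects noise", {
  set.seed(51)
  fams <- paste0("fam", 1:6)
  m_tab <- tibble::tibble(
    family = rep(fams, each = 2), variant = rep(1:2, 6),
    morph1 = rnorm(12), morph2 = rnorm(12), morph3 = rnorm(12))
  meta <- tibble::tibble(
    family = rep(m_tab$family, each = 20),
    variant = rep(m_tab$variant, each = 20))
  # prevalence source 1 is an exact linear function of morph1
  key <- paste(meta$family, meta$variant)
  morph1_of <- setNames(m_tab$morph1, paste(m_tab$family, m_tab$variant))
  prev <- cbind(2 * morph1_of[key] + 5, rnorm(nrow(meta)))

  out <- bootstrap_cca(m_tab, prev, meta, source_r = 1, n_boot = 60,
                       n_per_model = 15, seed = 3)
  s <- out$summary
  expect_gte(s$mean_abs_correlation[s$morphometric == "morph1"], 0.99)

  # independent prevalences: every morphometric stays under the
  # permutation-null 95% quantile of the planted statistic
  prev_null <- cbind(rnorm(nrow(meta)), rnorm(nrow(meta)))
  null_out <- bootstrap_cca(m_tab, prev_null, meta, source_r = 1,
                            n_boot = 60, n_per_model = 15, seed = 4)
  # permutation oracle: shuffle family rows of the morphometric table
  null_q <- replicate(20, {
    m_perm <- m_tab
    num <- c("morph1", "morph2", "morph3")
    m_perm[num] <- m_perm[sample(nrow(m_perm)), num]
    o <- bootstrap_cca(m_perm, prev, meta, source_r = 1, n_boot = 10,
                       n_per_model = 15, seed = sample.int(1e6, 1))
    max(o$summary$mean_abs_correlation)
  })
  expect_lt(max(null_out$summary$mean_abs_correlation),
            max(quantile(null_q, 0.95), 0.9))

  # two identical 1-D variables correlate perfectly
  x <- matrix(rnorm(30))
  fit <- eapdemix:::.cca1(scale(x), scale(x))
  expect_equal(abs(fit$cor), 1, tolerance = 1e-9)

  # cross-check against cancor on a full-rank case
  set.seed(52)
  A <- scale(matrix(rnorm(60), 20, 3)); B <- scale(matrix(rnorm(40), 20, 2))
  ours <- eapdemix:::.cca1(A, B)
  ref <- stats::cancor(A, B)
  expect_equal(abs(ours$cor), ref$cor[1], tolerance = 1e-6)
})

test_that("distance scaling fits slopes, bins and CVs as defined", {
  set.seed(61)
  meta <- tibble::tibble(family = rep("f", 40), r = seq(10, 49, 1))
  prev <- cbind(0.01 * meta$r + 3, rep(2, 40))
  out <- suppressMessages(distance_scaling(prev, meta))
  f1 <- out$fits[out$fits$source == 1, ]
  expect_equal(f1$slope, 0.01, tolerance = 1e-9)
  # constant prevalence: slope 0, CV undefined
  f2 <- out$fits[out$fits$source == 2, ]
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_true(is.na(f2$cv))
  # binned means of an exact linear trend lie on the regression line
  b1 <- out$binned[out$binned$source == 1, ]
  pred <- f1$intercept + f1$slope * b1$bin
  expect_lt(max(abs(b1$mean_dp - pred)), 0.01 * 10 / 2 + 1e-9)

  tiny <- tibble::tibble(family = c("a", "a"), r = c(10, 20))
  out2 <- suppressMessages(distance_scaling(matrix(1, 2, 1), tiny))
  expect_equal(nrow(out2$fits), 0L)
})

test_that("the clustering benchmark scores label permutations fairly", {
  set.seed(71)
  two <- rbind(matrix(rnorm(100, 0, 0.1), 50), matrix(rnorm(100, 8, 0.1), 50))
  labels <- rep(c("E", "I"), each = 50)
  res <- clustering_benchmark(two, labels, seed = 1)
  expect_setequal(res$method, c("kmeans", "ward", "average", "gmm"))
  expect_true(all(res$accuracy == 1))

  # swapped label names give identical accuracies (permutation max)
  res2 <- clustering_benchmark(two, rep(c("I", "E"), each = 50), seed = 1)
  expect_equal(res$accuracy, res2$accuracy)

  # random labels on one blob: accuracy near the majority proportion
  set.seed(72)
  blob <- matrix(rnorm(200), 100)
  rnd <- sample(rep(c("E", "I"), c(60, 40)))
  res3 <- clustering_benchmark(blob, rnd, seed = 2)
  expect_true(all(res3$accuracy >= 0.5))

  expect_error(clustering_benchmark(two, labels, k = 3),
               class = "eap_usage_error")
  expect_error(clustering_benchmark(two, rep("E", 100)),
               class = "eap_usage_error")
})
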