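test_that("non-negative CP recovers a planted rank-1 tensor", {
  r1 <- rank1_tensor()
  m <- ncp_bcd(r1$F, 1, seed = 3)
  expect_lte(m$reconstruction_error, 1e-6)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cosine(m$spatial[, 1], r1$s), 0.9999)
  expect_gte(cosine(m$temporal[, 1], r1$w), 0.9999)
  expect_gte(cosine(m$prevalence[, 1], r1$n), 0.9999)
  # normalization convention: unit-norm spatial and temporal columns
  expect_equal(sum(m$spatial[, 1]^2), 1, tolerance = 1e-9)
  expect_equal(sum(m$temporal[, 1]^2), 1, tolerance = 1e-9)

  z <- ncp_bcd(array(0, dim = c(3, 4, 5)), 2, seed = 1)
  expect_equal(z$reconstruction_error, 0)
  expect_equal(z$spatial, matrix(0, 3, 2))

  expect_error(ncp_bcd(array(-1, dim = c(2, 2, 2)), 1),
               class = "eap_input_error")
  expect_error(ncp_bcd(r1$F, 0), class = "eap_usage_error")
})

test_that("BCD keeps factors non-negative with a monotone objective", {
  set.seed(9)
  Ft <- array(abs(rnorm(6 * 8 * 10)), dim = c(6, 8, 10))
  m <- ncp_bcd(Ft, 3, seed = 2, max_iter = 60)
  expect_true(all(m$spatial >= 0) && all(m$temporal >= 0) &&
                all(m$prevalence >= 0))
  expect_true(all(diff(m$error_history) <= 1e-8))

  # best-of-restarts error is non-increasing in the rank
  e1 <- min(vapply(ncp_restarts(Ft, 1, 3, base_seed = 5)$fits,
                   function(x) x$reconstruction_error, numeric(1)))
  e2 <- min(vapply(ncp_restarts(Ft, 2, 3, base_seed = 5)$fits,
                   function(x) x$reconstruction_error, numeric(1)))
  expect_gte(e1, e2 - 1e-9)
})

test_that("planted four-source tensors are recovered component-wise", {
  bt <- simulate_benchmark_tensor(S = 20, W = 64, N = 60, noise = 0.01,
                                  seed = 8)
  fit <- ncp_restarts(bt$F, 4, n_restarts = 4, base_seed = 3,
                      max_iter = 300)$best
  # match fitted to planted components and check per-mode cosines
  planted <- structure(list(R = 4L, spatial = bt$factors$spatial,
                            temporal = bt$factors$temporal,
                            prevalence = bt$factors$prevalence),
                       class = "demix_model")
  sim <- decomposition_similarity(planted, fit)
  match <- attr(sim, "matching")
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (r in 1:4) {
    expect_gte(cosine(bt$factors$spatial[, r], fit$spatial[, match[r]]),
               0.95)
    expect_gte(cosine(bt$factors$temporal[, r], fit$temporal[, match[r]]),
               0.95)
    expect_gte(cosine(bt$factors$prevalence[, r],
                      fit$prevalence[, match[r]]), 0.95)
  }
})

test_that("decomposition similarity is permutation/scale invariant and matches the exhaustive oracle", {
  bt <- simulate_benchmark_tensor(S = 12, W = 32, N = 30, seed = 4)
  m <- ncp_bcd(bt$F, 4, seed = 1, max_iter = 150)
  expect_equal(as.numeric(decomposition_similarity(m, m)), 1,
               tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$spatial <- m$spatial[, perm]
  mp$temporal <- m$temporal[, perm]
  mp$prevalence <- m$prevalence[, perm] %*% diag(c(2, 3, 0.5, 7))
  expect_equal(as.numeric(decomposition_similarity(m, mp)), 1,
               tolerance = 1e-9)

  # replacing one factor column by an orthogonal vector lowers the score
  mo <- m
  v <- numeric(nrow(m$spatial))
  v[which.min(m$spatial[, 1])] <- 1
  v <- v - m$spatial[, 1] * sum(v * m$spatial[, 1])
  mo$spatial[, 1] <- abs(v)
  expect_lt(as.numeric(decomposition_similarity(m, mo)), 1)

  # agreement with the exhaustive-permutation oracle for R <= 5
  set.seed(6)
  for (R in 2:5) {
    a <- ncp_bcd(bt$F, R, seed = 10, max_iter = 40)
    b <- ncp_bcd(bt$F, R, seed = 11, max_iter = 40)
    expect_equal(as.numeric(decomposition_similarity(a, b)),
                 similarity_oracle(a, b), tolerance = 1e-10)
  }

  a2 <- ncp_bcd(bt$F, 2, seed = 1, max_iter = 20)
  expect_error(decomposition_similarity(m, a2), class = "eap_usage_error")
})

test_that("the Hungarian assignment solves small assignment problems exactly", {
  set.seed(7)
  for (n in 2:6) {
    cost <- matrix(runif(n * n), n, n)
    got <- hungarian_assignment(cost)
    perms <- gtools_permutations(n)
    best <- min(vapply(seq_len(nrow(perms)), function(i)
      sum(cost[cbind(seq_len(n), perms[i, ])]), numeric(1)))
    expect_equal(sum(cost[cbind(seq_len(n), got)]), best, tolerance = 1e-12)
  }
})

test_that("rank selection recovers the planted source count", {
  bt <- simulate_benchmark_tensor(S = 20, W = 64, N = 90, noise = 0.01,
                                  seed = 13)
  rs <- select_rank(bt$F, bt$labels, R_range = 1:6, n_restarts = 4,
                    base_seed = 17, max_iter = 250)
  expect_equal(rs$R_star, 4L)
  expect_false(rs$flagged)
  sim4 <- rs$diagnostics$mean_similarity[rs$diagnostics$R == 4]
  expect_gt(sim4, 0.99)

  # exactly rank-1 tensor: similarity 1 at R = 1
  r1 <- rank1_tensor(6, 8, 10)
  rs1 <- select_rank(r1$F, rep(c("a", "b"), 5), R_range = 1L,
                     n_restarts = 3, base_seed = 2)
  expect_equal(rs1$diagnostics$mean_similarity[1], 1, tolerance = 1e-6)

  expect_error(select_rank(bt$F, bt$labels, R_range = 1:2, n_restarts = 1),
               class = "eap_usage_error")
})

test_that("sources are ordered by random-forest importance", {
  set.seed(31)
  n <- 120
  labels <- rep(c("fam1", "fam2"), each = n / 2)
  # feature 2 separates the families perfectly, feature 1 is pure noise
  prev <- cbind(runif(n), ifelse(labels == "fam1", 0, 1) + rnorm(n, 0, 0.01))
  model <- structure(list(R = 2L, spatial = diag(2), temporal = diag(2),
                          prevalence = prev, component_scales = c(1, 1)),
                     class = "demix_model")
  out <- order_sources(model, labels, seed = 5)
  expect_equal(out$order, c(2L, 1L))
  expect_gt(out$importance[1], out$importance[2])
  expect_equal(out$model$prevalence[, 1], prev[, 2])

  # permuting input columns leaves the ordered factor content unchanged
  model2 <- model
  model2$prevalence <- prev[, c(2, 1)]
  out2 <- order_sources(model2, labels, seed = 5)
  expect_equal(out2$model$prevalence[, 1], prev[, 2])

  expect_error(order_sources(model, rep("one", n)),
               class = "eap_usage_error")
})
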