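# shared fixtures, built in code and cached for the test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# minimal two-compartment morphology: soma + one basal dendrite
two_comp_morphology <- function(dend_len = 100, dend_radius = 1) {
  segs <- dplyr::bind_rows(
    tibble::tibble(id = 0L, parent_id = NA_integer_,
                   px = 0, py = -5, pz = 0, dx = 0, dy = 5, dz = 0,
                   prox_radius = 5, dist_radius = 5, domain = "soma"),
    tibble::tibble(id = 1L, parent_id = 0L,
                   px = 0, py = 5, pz = 0, dx = 0, dy = 5 + dend_len, dz = 0,
                   prox_radius = dend_radius, dist_radius = dend_radius,
                   domain = "basal"))
  structure(list(segments = segs, family = "two_comp", variant = 0L,
                 soma_center = c(0, 0, 0)), class = "morphology")
}

# a synthetic canonical center waveform: quiet pre-spike, trough just after
# the spike sample, later positive peak
canonical_waveform <- function(trough = -60, peak = 25, trough_t = 0.15,
                               peak_t = 1.0, dt = 5.6 / 128) {
  t_rel <- (seq_len(128) - 33) * dt
  w <- trough * exp(-(t_rel - trough_t)^2 / (2 * 0.1^2)) +
    peak * exp(-(t_rel - peak_t)^2 / (2 * 0.45^2))
  w - median(w)
}

# small simulated dataset shared across tests: 4 families, 1 variant,
# 14 probes each, light noise averaging; balanced at 8 units/family
small_dataset <- function() {
  fixture("small_dataset", function() {
    cfg <- default_config(
      families = c("thick_tufted_pyr_a", "small_pyr_l2",
                   "large_basket", "martinotti"),
      variants = 1, probes_per_model = 14, quota = 8,
      noise = noise_config(n_avg = 20), R_fixed = 3, n_restarts = 2,
      n_boot_cca = 10, n_per_model = 10, n_boot_centroids = 30,
      me_classes = 2)
    sim <- simulate_dataset(cfg, seed = 42)
    cen <- suppressMessages(center_units(sim$units))
    bal <- balance_dataset(cen, cfg$quota, seed = 7, strict = FALSE)
    list(cfg = cfg, sim = sim, centered = cen, X = bal$X, meta = bal$meta)
  })
}

# planted rank-1 outer product tensor
rank1_tensor <- function(S = 5, W = 6, N = 7, seed = 2) {
  set.seed(seed)
  s <- runif(S, 0.2, 1); w <- runif(W, 0.2, 1); n <- runif(N, 0.2, 1)
  list(F = outer(outer(s, w), n), s = s, w = w, n = n)
}

# exhaustive-permutation oracle for decomposition similarity (R <= 5)
similarity_oracle <- function(a, b, modes = c("spatial", "temporal",
                                              "prevalence")) {
  R <- a$R
  cos_col <- function(M) {
    nrm <- sqrt(colSums(M^2)); nrm[nrm == 0] <- 1
    sweep(M, 2, nrm, "/")
  }
  M <- matrix(1, R, R)
  for (mode in modes) {
    M <- M * crossprod(cos_col(a[[mode]]), cos_col(b[[mode]]))
  }
  perms <- gtools_permutations(R)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    sc <- mean(M[cbind(seq_len(R), perms[i, ])])
    if (sc > best) best <- sc
  }
  best
}

# all permutations of 1..n (tiny n)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
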