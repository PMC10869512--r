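# symmetric pseudo-inverse square root via eigendecomposition
.pinv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  U <- e$vectors[, keep, drop = FALSE]
  U %*% diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(U)
}

# single-component linear CCA on column-standardized matrices; returns the
# canonical weights, scores and correlation
.cca1 <- function(X, Y, tol = 1e-10) {
  n <- nrow(X)
  Cxx <- crossprod(X) / n
  Cyy <- crossprod(Y) / n
  Cxy <- crossprod(X, Y) / n
  Wx <- .pinv_sqrt(Cxx, tol)
  Wy <- .pinv_sqrt(Cyy, tol)
  K <- Wx %*% Cxy %*% Wy
  sv <- svd(K, nu = 1, nv = 1)
  a <- drop(Wx %*% sv$u)
  b <- drop(Wy %*% sv$v)
  xs <- drop(X %*% a)
  ys <- drop(Y %*% b)
  r <- suppressWarnings(cor(xs, ys))
  list(xw = a, yw = b, xscore = xs, yscore = ys, cor = r)
}

# population-variance (ddof = 0) column standardization; zero-variance
# columns are reported back
.standardize <- function(M) {
  mu <- colMeans(M)
  sdv <- sqrt(colMeans(sweep(M, 2, mu)^2))
  zero <- sdv <= 0
  sdv[zero] <- 1
  list(Z = sweep(sweep(M, 2, mu), 2, sdv, "/"), zero = zero)
}

#' Bootstrapped canonical correlation of morphometrics and prevalences
#'
#' Per bootstrap iteration: one model (variant) is sampled per family; the
#' morphometric matrix M (families x morphometrics) is populated from those
#' models, and the prevalence matrix P (families x n_per_model) from
#' `n_per_model` unit prevalences of source `source_r` sampled with
#' replacement from each selected model's units. Both are standardized
#' (zero mean, unit population variance per column; zero-variance columns
#' dropped with a message), a single-component linear CCA is fitted, and
#' the Pearson correlation between each morphometric and the canonical
#' covariate (prevalence-side score) is recorded.
#'
#' @param m_table Morphometric table from [morphometric_table()] (columns
#'   `family`, `variant` plus numeric morphometrics).
#' @param prevalences N x R prevalence matrix.
#' @param unit_meta Tibble aligned to prevalence rows with `family` and
#'   `variant`.
#' @param source_r Source (column of `prevalences`) to analyze.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param n_per_model Prevalence samples per model (default 50).
#' @param seed Integer seed.
#' @return List: `correlations` (tibble iteration x morphometric, long),
#'   `summary` (per-morphometric mean and 2.5/97.5% quantiles of the
#'   correlation), `canonical_correlation` (per-iteration vector).
#' @export
bootstrap_cca <- function(m_table, prevalences, unit_meta, source_r,
                          n_boot = 1000L, n_per_model = 50L, seed = 0L) {
  fams <- sort(intersect(unique(m_table$family), unique(unit_meta$family)))
  dropped_fams <- setdiff(unique(m_table$family), fams)
  if (length(dropped_fams) > 0) {
    inform(paste("families without units skipped in CCA:",
                 paste(dropped_fams, collapse = ", ")))
  }
  if (length(fams) < 2L) abort("need at least two families",
                               class = "eap_usage_error")
  num_cols <- names(m_table)[vapply(m_table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "variant")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  # pre-index units by (family, variant)
  key <- paste(unit_meta$family, unit_meta$variant)
  unit_idx <- split(seq_len(nrow(unit_meta)), key)

  cors <- matrix(NA_real_, n_boot, length(num_cols),
                 dimnames = list(NULL, num_cols))
  can_cor <- numeric(n_boot)
  dropped <- character(0)
  for (b in seq_len(n_boot)) {
    Mrows <- matrix(NA_real_, length(fams), length(num_cols))
    Prows <- matrix(NA_real_, length(fams), n_per_model)
    for (fi in seq_along(fams)) {
      sub <- m_table[m_table$family == fams[fi], , drop = FALSE]
      pick <- sub[sample(nrow(sub), 1L), ]
      Mrows[fi, ] <- as.numeric(pick[1, num_cols])
      uk <- paste(pick$family, pick$variant)
      units <- unit_idx[[uk]]
      if (is.null(units)) units <- which(unit_meta$family == fams[fi])
      Prows[fi, ] <- prevalences[sample(units, n_per_model, replace = TRUE),
                                 source_r]
    }
    Mrows[is.na(Mrows)] <- 0
    sm <- .standardize(Mrows)
    sp <- .standardize(Prows)
    dropped <- union(dropped, num_cols[sm$zero])
    fit <- .cca1(sm$Z[, !sm$zero, drop = FALSE], sp$Z)
    can_cor[b] <- fit$cor
    covariate <- fit$yscore
    keep <- which(!sm$zero)
    for (j in seq_along(keep)) {
      cors[b, keep[j]] <- suppressWarnings(cor(sm$Z[, keep[j]], covariate))
    }
  }
  if (length(dropped) > 0) {
    inform(paste("zero-variance morphometric columns dropped in some draws:",
                 paste(dropped, collapse = ", ")))
  }
  long <- as_tibble(cors) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "morphometric",
                        values_to = "correlation")
  summary <- long |>
    dplyr::group_by(.data$morphometric) |>
    dplyr::summarise(
      mean_correlation = mean(.data$correlation, na.rm = TRUE),
      mean_abs_correlation = mean(abs(.data$correlation), na.rm = TRUE),
      lo = quantile(.data$correlation, 0.025, na.rm = TRUE),
      hi = quantile(.data$correlation, 0.975, na.rm = TRUE),
      .groups = "drop")
  list(correlations = long, summary = summary,
       canonical_correlation = can_cor)
}

#' Prevalence scaling with recording distance
#'
#' Per family and source: the unit at the smallest radial distance is the
#' reference; the change in prevalence of every other unit relative to the
#' reference is regressed (OLS) on the change in radial distance, with
#' means in 10 um distance bins and the coefficient of variation of the
#' prevalence change (sd / |mean|, `NA` when the mean vanishes). Families
#' with fewer than 3 units are skipped.
#'
#' @param prevalences N x R prevalence matrix.
#' @param unit_meta Tibble aligned to rows with `family` and `r` (um).
#' @param bin_width Bin width for the binned means, um.
#' @return List: `fits` (tibble family x source: slope, intercept, cv, n),
#'   `binned` (tibble of binned mean prevalence changes), `pooled_cv`
#'   (per-source CV pooled over families).
#' @export
distance_scaling <- function(prevalences, unit_meta, bin_width = 10) {
  R <- ncol(prevalences)
  fits <- list()
  binned <- list()
  for (fam in sort(unique(unit_meta$family))) {
    rows <- which(unit_meta$family == fam)
    if (length(rows) < 3L) {
      inform(paste0("family ", fam, " has < 3 units; skipped"))
      next
    }
    rr <- unit_meta$r[rows]
    ref <- rows[which.min(rr)]
    d <- rr - unit_meta$r[ref]
    for (src in seq_len(R)) {
      dp <- prevalences[rows, src] - prevalences[ref, src]
      fit <- lm(dp ~ d)
      mu <- mean(dp)
      fits[[length(fits) + 1L]] <- tibble(
        family = fam, source = src,
        slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
        cv = if (abs(mu) < 1e-12) NA_real_ else sd(dp) / abs(mu),
        n = length(rows))
      bin <- floor(d / bin_width) * bin_width + bin_width / 2
      bt <- tibble(family = fam, source = src, d = d, dp = dp, bin = bin) |>
        dplyr::group_by(.data$family, .data$source, .data$bin) |>
        dplyr::summarise(mean_dp = mean(.data$dp), n = dplyr::n(),
                         .groups = "drop")
      binned[[length(binned) + 1L]] <- bt
    }
  }
  fits <- dplyr::bind_rows(fits)
  pooled <- if (nrow(fits) > 0) {
    fits |>
      dplyr::group_by(.data$source) |>
      dplyr::summarise(mean_cv = mean(.data$cv, na.rm = TRUE),
                       .groups = "drop")
  } else {
    tibble(source = integer(), mean_cv = numeric())
  }
  list(fits = fits, binned = dplyr::bind_rows(binned), pooled_cv = pooled)
}
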