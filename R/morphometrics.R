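# children lookup: list mapping segment id -> integer row indices of children
.children_index <- function(segs) {
  idx <- split(seq_len(nrow(segs)), factor(segs$parent_id,
                                           levels = segs$id))
  idx
}

# walk from a stem row to its first branch point (>= 2 children) or terminal;
# returns the distal Y there
.first_branch_y <- function(segs, children, row) {
  repeat {
    kids <- children[[as.character(segs$id[row])]]
    if (is.null(kids) || length(kids) == 0L) return(segs$dy[row])  # terminal
    if (length(kids) >= 2L) return(segs$dy[row])                   # branch
    row <- kids[1]
  }
}

# all terminal rows in the subtree rooted at `row` (inclusive)
.subtree_terminals <- function(segs, children, row) {
  out <- integer(0)
  stack <- row
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- children[[as.character(segs$id[cur])]]
    if (is.null(kids) || length(kids) == 0L) out <- c(out, cur)
    else stack <- c(stack, kids)
  }
  out
}

#' Stem and terminal morphometrics of one model
#'
#' Computes the proximal-geometry features used as canonical-correlation
#' targets: soma height along Y and its midpoint; stems (segments whose
#' parent is the soma) with their cross-sectional area CSA = pi (d/2)^2 at
#' the proximal end; upper/lower division of stems by attachment Y relative
#' to the soma midpoint (exact midpoint attaches upper); per-stem proximal
#' Y and the Y of the first branch point (an unbranched stem's terminal
#' counts as its first branch); per-domain terminal Y locations; and the
#' CSA aggregates per domain and division.
#'
#' @param morph A `morphology`.
#' @return A `morphometrics` object: list with `features` (one-row tibble
#'   of scalar morphometrics), `stems` (per-stem tibble) and `terminals`
#'   (per-terminal tibble).
#' @export
compute_morphometrics <- function(morph) {
  segs <- morph$segments
  soma_rows <- which(segs$domain == "soma")
  if (length(soma_rows) == 0) abort("morphology has no soma",
                                    class = "eap_integrity_error")
  soma_ids <- segs$id[soma_rows]
  soma_y <- c(segs$py[soma_rows], segs$dy[soma_rows])
  soma_height <- max(soma_y) - min(soma_y)
  soma_mid <- (max(soma_y) + min(soma_y)) / 2

  children <- .children_index(segs)
  stem_rows <- which(segs$parent_id %in% soma_ids)
  csa <- pi * segs$prox_radius[stem_rows]^2
  division <- ifelse(segs$py[stem_rows] >= soma_mid, "upper", "lower")
  stems <- tibble(
    id = segs$id[stem_rows], domain = segs$domain[stem_rows],
    csa = csa, division = division, y_prox = segs$py[stem_rows],
    y_dist = vapply(stem_rows, function(r)
      .first_branch_y(segs, children, r), numeric(1)))

  term_list <- lapply(seq_along(stem_rows), function(k) {
    trows <- .subtree_terminals(segs, children, stem_rows[k])
    tibble(domain = segs$domain[trows], y_term = segs$dy[trows],
           stem_division = stems$division[k])
  })
  terminals <- dplyr::bind_rows(term_list)

  dsum <- function(domain, div = NULL) {
    m <- stems$domain == domain
    if (!is.null(div)) m <- m & stems$division == div
    sum(stems$csa[m])
  }
  tmean <- function(domain, div) {
    m <- terminals$domain == domain & terminals$stem_division == div
    if (!any(m)) NA_real_ else mean(terminals$y_term[m])
  }
  ais <- stems[stems$domain == "ais", ]
  features <- tibble(
    family = morph$family, variant = morph$variant,
    soma_height_y = soma_height,
    n_stems = nrow(stems),
    total_stem_csa = sum(stems$csa),
    basal_n_stems = sum(stems$domain == "basal"),
    basal_total_csa = dsum("basal"),
    basal_upper_csa = dsum("basal", "upper"),
    basal_lower_csa = dsum("basal", "lower"),
    basal_terminal_y_upper = tmean("basal", "upper"),
    basal_terminal_y_lower = tmean("basal", "lower"),
    apical_upper_csa = dsum("apical", "upper"),
    apical_lower_csa = dsum("apical", "lower"),
    axon_stem_csa = if (nrow(ais)) ais$csa[1] else 0,
    axon_division = if (nrow(ais)) ais$division[1] else NA_character_)

  structure(list(features = features, stems = stems, terminals = terminals),
            class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat("<morphometrics>", x$features$family, "variant", x$features$variant,
      "-", x$features$n_stems, "stems, total CSA",
      signif(x$features$total_stem_csa, 4), "um^2\n")
  invisible(x)
}

#' Morphometric table for a set of models
#'
#' @param morphs List of `morphology` objects.
#' @return Tibble: one row per model, scalar morphometrics as columns.
#' @export
morphometric_table <- function(morphs) {
  dplyr::bind_rows(lapply(morphs, function(m) compute_morphometrics(m)$features))
}

#' Density profile of a morphological feature along the probe (Y) axis
#'
#' Pools the requested per-stem or per-domain feature across models and
#' returns a unit-area histogram over Y: `first_branch` uses per-stem
#' first-branch locations, `terminal` the terminal distal Y locations, and
#' `max_extent` the extreme distal Y of any segment of the domain, for the
#' upper and lower divisions separately.
#'
#' @param morphs List of `morphology` objects.
#' @param domain Domain to profile (`"basal"`, `"apical"`, `"ais"`).
#' @param feature One of `"first_branch"`, `"terminal"`, `"max_extent"`.
#' @param bins Numeric vector of Y bin edges, um.
#' @return Tibble: `y_mid`, `density` (integrates to 1 over the bins);
#'   attribute `"empty"` set when no model contributes.
#' @export
domain_density_profile <- function(morphs, domain,
                                   feature = c("terminal", "first_branch",
                                               "max_extent"),
                                   bins = seq(-320, 320, by = 20)) {
  feature <- match.arg(feature)
  vals <- numeric(0)
  for (m in morphs) {
    segs <- m$segments
    if (!any(segs$domain == domain)) {
      inform(paste0("model ", m$family, "/", m$variant, " lacks domain ",
                    domain, "; skipped"))
      next
    }
    mm <- compute_morphometrics(m)
    v <- switch(feature,
      first_branch = mm$stems$y_dist[mm$stems$domain == domain],
      terminal = mm$terminals$y_term[mm$terminals$domain == domain],
      max_extent = {
        y <- segs$dy[segs$domain == domain]
        c(max(y), min(y))
      })
    vals <- c(vals, v)
  }
  mids <- (head(bins, -1) + tail(bins, -1)) / 2
  if (length(vals) == 0) {
    out <- tibble(y_mid = mids, density = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  h <- graphics::hist(pmin(pmax(vals, min(bins)), max(bins)),
                      breaks = bins, plot = FALSE)
  out <- tibble(y_mid = mids, density = h$density)
  attr(out, "empty") <- FALSE
  out
}
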