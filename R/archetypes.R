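#' Archetype library of cortical neuron-type families
#'
#' Returns the built-in table of 21 neuron-type family archetypes: 11
#' excitatory pyramidal-like archetypes (with apical trunks of varying
#' caliber, length and orientation) and 10 inhibitory interneuron-like
#' archetypes (basket-, bitufted-, bipolar-, Martinotti-, chandelier-like,
#' ...). Each row parameterizes the simplified labeled geometry built by
#' [build_archetype_morphology()]: stem counts and diameters, trunk and
#' branch lengths, apical presence/orientation, soma radius and axon
#' direction. All lengths are in micrometers.
#'
#' @return A tibble with one row per family archetype.
#' @export
archetype_table <- function() {
  E <- function(family, soma_r, n_basal, basal_diam, basal_len,
                apical_diam, trunk_len, n_tuft, apical_orient = "up") {
    tibble(
      family = family, class = "E", soma_radius = soma_r,
      n_basal = n_basal, basal_diam = basal_diam, basal_len = basal_len,
      basal_orient = "radial", has_apical = TRUE,
      apical_diam = apical_diam, trunk_len = trunk_len, n_tuft = n_tuft,
      apical_orient = apical_orient, axon_dir = "down"
    )
  }
  I <- function(family, soma_r, n_basal, basal_diam, basal_len,
                basal_orient = "radial", axon_dir = "down") {
    tibble(
      family = family, class = "I", soma_radius = soma_r,
      n_basal = n_basal, basal_diam = basal_diam, basal_len = basal_len,
      basal_orient = basal_orient, has_apical = FALSE,
      apical_diam = NA_real_, trunk_len = NA_real_, n_tuft = 0L,
      apical_orient = NA_character_, axon_dir = axon_dir
    )
  }
  dplyr::bind_rows(
    # --- excitatory families -------------------------------------------------
    # trunk_len is the distance to the first apical branch point; the tuft
    # branches extend well beyond it (see build_archetype_morphology)
    E("thick_tufted_pyr_a", 10, 6, 3.0, 180, 6.0, 100, 6),
    E("thick_tufted_pyr_b", 10, 6, 3.0, 200, 5.5, 90, 5),
    E("tufted_pyr_l4",       9, 5, 2.5, 160, 4.0, 80, 4),
    E("tufted_pyr_l6",       9, 5, 2.5, 170, 3.5, 90, 3),
    E("slender_tufted_pyr",  8, 5, 2.0, 160, 2.5, 80, 3),
    E("untufted_pyr_a",      8, 5, 2.0, 150, 2.5, 70, 0),
    E("untufted_pyr_b",      8, 4, 2.0, 150, 2.2, 60, 0),
    E("star_pyr",            8, 6, 2.2, 150, 2.0, 50, 2),
    E("small_pyr_l2",        7, 4, 1.8, 130, 2.2, 60, 2),
    E("small_pyr_l3",        7, 4, 1.8, 140, 2.4, 70, 2),
    E("inverted_pyr",        8, 5, 2.0, 150, 2.5, 80, 3, apical_orient = "down"),
    # --- inhibitory families -------------------------------------------------
    I("large_basket",       8, 7, 1.8, 160),
    I("small_basket",       6, 5, 1.2, 100),
    I("nest_basket",        7, 6, 1.5, 130),
    I("bitufted",           7, 4, 1.6, 170, basal_orient = "both"),
    I("bipolar",            6, 2, 1.4, 190, basal_orient = "both"),
    I("double_bouquet",     6, 4, 1.3, 160, basal_orient = "both", axon_dir = "down"),
    I("martinotti",         7, 5, 1.5, 150, axon_dir = "up"),
    I("chandelier",         7, 6, 1.4, 140),
    I("neurogliaform",      6, 8, 1.0, 90),
    I("descending_basket",  7, 6, 1.6, 150, axon_dir = "down")
  )
}

#' Look up one archetype by family name
#' @param family Character family name from [archetype_table()].
#' @return One-row tibble of archetype parameters.
#' @export
archetype_spec <- function(family) {
  tab <- archetype_table()
  row <- tab[tab$family == family, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown archetype family: '", family, "'"),
          class = "eap_config_error")
  }
  row
}

# unit vector helpers ---------------------------------------------------------
.unit <- function(v) v / sqrt(sum(v^2))

.new_segment <- function(id, parent_id, prox, dist, r_prox, r_dist, domain) {
  tibble(
    id = as.integer(id), parent_id = as.integer(parent_id),
    px = prox[1], py = prox[2], pz = prox[3],
    dx = dist[1], dy = dist[2], dz = dist[3],
    prox_radius = r_prox, dist_radius = r_dist, domain = domain
  )
}

#' Build one seeded morphological variant of an archetype
#'
#' Constructs a connected, domain-labeled tree (soma, AIS, basal and
#' optionally apical dendrites) from the named archetype. The soma sits at
#' the origin with the Y axis as the cortical-depth axis (+Y superficial).
#' The AIS is two equal-length, equal-diameter segments. Variants of the
#' same family differ only through seeded geometric jitter (lengths and
#' diameters within ~10% and 5%, plus angular jitter); the topology and
#' segment count are fixed by the archetype.
#'
#' @param family Archetype family name (see [archetype_table()]).
#' @param variant_seed Integer seed controlling the geometric jitter.
#' @return A `morphology` object: list with `segments` (tibble), `family`,
#'   `variant`, `soma_center`.
#' @export
build_archetype_morphology <- function(family, variant_seed = 0L) {
  spec <- archetype_spec(family)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(variant_seed))

  jlen <- function(x) x * runif(1, 0.9, 1.1)
  jdiam <- function(x) {
    d <- x * runif(1, 0.95, 1.05)
    if (d <= 0) abort("jitter produced non-positive diameter",
                      class = "eap_construction_error")
    d
  }

  segs <- list()
  r_s <- jlen(spec$soma_radius)
  # soma: one vertical segment spanning the soma sphere along Y
  segs[[1]] <- .new_segment(0L, NA_integer_,
                            c(0, -r_s, 0), c(0, r_s, 0), r_s, r_s, "soma")
  next_id <- 1L
  add <- function(parent_id, prox, dist, r_prox, r_dist, domain) {
    seg <- .new_segment(next_id, parent_id, prox, dist, r_prox, r_dist, domain)
    segs[[length(segs) + 1L]] <<- seg
    next_id <<- next_id + 1L
    seg
  }

  # AIS: two equal compartments leaving the soma pole given by axon_dir
  ais_half <- jlen(12.5)
  ais_r <- jdiam(1.5) / 2
  ax_sign <- if (spec$axon_dir == "up") 1 else -1
  a0 <- c(0, ax_sign * r_s, 0)
  tilt <- .unit(c(runif(1, -0.15, 0.15), ax_sign, runif(1, -0.15, 0.15)))
  a1 <- a0 + tilt * ais_half
  a2 <- a1 + tilt * ais_half
  s_ais1 <- add(0L, a0, a1, ais_r, ais_r, "ais")
  add(s_ais1$id, a1, a2, ais_r, ais_r, "ais")

  # basal stems: stem compartment to first branch, then two daughters
  n_basal <- spec$n_basal
  stem_dirs <- vector("list", n_basal)
  for (k in seq_len(n_basal)) {
    base_angle <- 2 * pi * (k - 1) / n_basal + runif(1, -0.3, 0.3)
    if (spec$basal_orient == "both") {
      # alternate up- and down-oriented trunks (bitufted/bipolar-like)
      ys <- if (k %% 2 == 1) 1 else -1
      dir <- .unit(c(0.35 * cos(base_angle), ys * 1.2, 0.35 * sin(base_angle)))
    } else {
      y_tilt <- runif(1, -0.45, 0.45)
      dir <- .unit(c(cos(base_angle), y_tilt, sin(base_angle)))
    }
    stem_dirs[[k]] <- dir
  }
  for (k in seq_len(n_basal)) {
    dir <- stem_dirs[[k]]
    len <- jlen(spec$basal_len)
    r0 <- jdiam(spec$basal_diam) / 2
    p0 <- dir * r_s                      # attachment on the soma surface
    p1 <- p0 + dir * (0.4 * len)
    stem <- add(0L, p0, p1, r0, 0.7 * r0, "basal")
    for (b in 1:2) {
      perp <- .unit(c(-dir[3], runif(1, -0.4, 0.4), dir[1]))
      bdir <- .unit(dir + (if (b == 1) 0.8 else -0.8) * perp)
      p2 <- p1 + bdir * (0.6 * len)
      add(stem$id, p1, p2, 0.7 * r0, 0.4 * r0, "basal")
    }
  }

  # apical trunk + tuft for excitatory archetypes
  if (isTRUE(spec$has_apical)) {
    ap_sign <- if (spec$apical_orient == "down") -1 else 1
    tdir <- .unit(c(runif(1, -0.08, 0.08), ap_sign, runif(1, -0.08, 0.08)))
    tlen <- jlen(spec$trunk_len)
    r0 <- jdiam(spec$apical_diam) / 2
    p0 <- c(0, ap_sign * r_s, 0)
    p1 <- p0 + tdir * tlen
    trunk <- add(0L, p0, p1, r0, 0.6 * r0, "apical")
    n_tuft <- spec$n_tuft
    if (n_tuft >= 1) {
      # tuft/oblique branches leave the first branch point and extend well
      # past it toward the distal terminals
      for (b in seq_len(n_tuft)) {
        ang <- 2 * pi * (b - 1) / n_tuft + runif(1, -0.3, 0.3)
        bdir <- .unit(c(0.8 * cos(ang), ap_sign * 1.0, 0.8 * sin(ang)))
        p2 <- p1 + bdir * jlen(2.2 * tlen)
        add(trunk$id, p1, p2, 0.6 * r0, 0.3 * r0, "apical")
      }
    } else {
      # untufted: the trunk continues unbranched to its terminal
      p2 <- p1 + tdir * jlen(1.8 * tlen)
      add(trunk$id, p1, p2, 0.6 * r0, 0.3 * r0, "apical")
    }
  }

  morph <- structure(
    list(
      segments = dplyr::bind_rows(segs),
      family = family,
      variant = as.integer(variant_seed),
      soma_center = c(0, 0, 0)
    ),
    class = "morphology"
  )
  validate_morphology(morph)
  morph
}

#' Validate a morphology object
#'
#' Checks the structural invariants: positive radii, a single tree rooted at
#' the soma, known domain labels, and exactly two equal-length equal-diameter
#' AIS compartments when an AIS is present.
#'
#' @param morph A `morphology`.
#' @return `morph`, invisibly; errors on violation.
#' @export
validate_morphology <- function(morph) {
  s <- morph$segments
  stopifnot(is.data.frame(s), nrow(s) >= 1)
  if (any(s$prox_radius <= 0) || any(s$dist_radius <= 0)) {
    abort("non-positive segment radius", class = "eap_construction_error")
  }
  if (!all(s$domain %in% c("soma", "ais", "basal", "apical"))) {
    abort("unknown segment domain label", class = "eap_construction_error")
  }
  roots <- which(is.na(s$parent_id))
  if (length(roots) != 1L || s$domain[roots] != "soma") {
    abort("morphology must be a single tree rooted at the soma",
          class = "eap_construction_error")
  }
  non_root <- s[!is.na(s$parent_id), ]
  if (nrow(non_root) > 0 && !all(non_root$parent_id %in% s$id)) {
    abort("dangling parent reference", class = "eap_construction_error")
  }
  ais <- s[s$domain == "ais", ]
  if (nrow(ais) > 0) {
    if (nrow(ais) != 2L) abort("AIS must have exactly two compartments",
                               class = "eap_construction_error")
    len <- sqrt((ais$dx - ais$px)^2 + (ais$dy - ais$py)^2 + (ais$dz - ais$pz)^2)
    if (abs(diff(len)) > 1e-6 || abs(diff(ais$prox_radius)) > 1e-9) {
      abort("AIS compartments must have equal length and diameter",
            class = "eap_construction_error")
    }
  }
  invisible(morph)
}

#' @export
print.morphology <- function(x, ...) {
  cat("<morphology> family:", x$family, " variant:", x$variant,
      " segments:", nrow(x$segments), "\n")
  print(table(x$segments$domain))
  invisible(x)
}

# segment lengths (um)
segment_lengths <- function(morph) {
  s <- morph$segments
  sqrt((s$dx - s$px)^2 + (s$dy - s$py)^2 + (s$dz - s$pz)^2)
}

# lateral (frustum) membrane area per segment, um^2
segment_areas <- function(morph) {
  s <- morph$segments
  len <- segment_lengths(morph)
  slant <- sqrt(len^2 + (s$prox_radius - s$dist_radius)^2)
  pi * (s$prox_radius + s$dist_radius) * slant
}

# path distance (um) from the soma to each segment midpoint, following parents
segment_path_distances <- function(morph) {
  s <- morph$segments
  len <- segment_lengths(morph)
  idx <- setNames(seq_len(nrow(s)), s$id)
  out <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    d <- len[i] / 2
    p <- s$parent_id[i]
    while (!is.na(p)) {
      j <- idx[[as.character(p)]]
      if (s$domain[j] != "soma") d <- d + len[j]
      p <- s$parent_id[j]
    }
    out[i] <- d
  }
  out
}

# RNG bookkeeping: save/restore the global seed so seeded builders do not
# disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
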