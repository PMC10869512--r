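test_that("NeuroML writer and reader round-trip a morphology", {
  morph <- build_archetype_morphology("bitufted", 2)
  path <- withr::local_tempfile(fileext = ".nml")
  write_neuroml(morph, path)
  back <- read_neuroml_morphology(path)
  expect_equal(back$segments$id, morph$segments$id)
  expect_equal(back$segments$parent_id, morph$segments$parent_id)
  expect_equal(back$segments$domain, morph$segments$domain)
  expect_equal(back$segments$px, morph$segments$px, tolerance = 1e-5)
  expect_equal(back$segments$prox_radius, morph$segments$prox_radius,
               tolerance = 1e-5)
  expect_equal(back$family, "bitufted")

  # minimal two-segment fixture written by hand
  p2 <- withr::local_tempfile(fileext = ".nml")
  writeLines(c(
    '<neuroml><cell id="mini_0"><morphology id="m">',
    '<segment id="0"><proximal x="0" y="-4" z="0" diameter="8"/>',
    '<distal x="0" y="4" z="0" diameter="8"/></segment>',
    '<segment id="1"><parent segment="0"/>',
    '<proximal x="0" y="4" z="0" diameter="2"/>',
    '<distal x="0" y="60" z="0" diameter="2"/></segment>',
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    '<segmentGroup id="dendrite_group"><member segment="1"/></segmentGroup>',
    '</morphology></cell></neuroml>'), p2)
  mini <- read_neuroml_morphology(p2)
  expect_equal(nrow(mini$segments), 2L)
  expect_equal(mini$segments$parent_id[2], 0L)
  expect_equal(mini$segments$domain, c("soma", "basal"))

  # a segment without a resolvable group names its id
  p3 <- withr::local_tempfile(fileext = ".nml")
  writeLines(c(
    '<neuroml><cell id="bad_0"><morphology id="m">',
    '<segment id="0"><proximal x="0" y="0" z="0" diameter="8"/>',
    '<distal x="0" y="4" z="0" diameter="8"/></segment>',
    '<segmentGroup id="soma_group"><member segment="0"/></segmentGroup>',
    '<segment id="7"><parent segment="0"/>',
    '<proximal x="0" y="4" z="0" diameter="2"/>',
    '<distal x="0" y="9" z="0" diameter="2"/></segment>',
    '</morphology></cell></neuroml>'), p3)
  expect_error(read_neuroml_morphology(p3), "segment 7")

  p4 <- withr::local_tempfile(fileext = ".nml")
  writeLines("<neuroml><cell>", p4)
  expect_error(read_neuroml_morphology(p4), class = "eap_parse_error")
})

test_that("stem morphometrics follow the CSA and first-branch rules", {
  # single basal stem with proximal diameter 2 um -> CSA = pi
  segs <- dplyr::bind_rows(
    tibble::tibble(id = 0L, parent_id = NA_integer_, px = 0, py = -5, pz = 0,
                   dx = 0, dy = 5, dz = 0, prox_radius = 5, dist_radius = 5,
                   domain = "soma"),
    tibble::tibble(id = 1L, parent_id = 0L, px = 0, py = 2, pz = 0,
                   dx = 0, dy = 80, dz = 0, prox_radius = 1, dist_radius = 1,
                   domain = "basal"))
  m <- structure(list(segments = segs, family = "fix", variant = 0L,
                      soma_center = c(0, 0, 0)), class = "morphology")
  mm <- compute_morphometrics(m)
  expect_equal(mm$features$basal_total_csa, pi, tolerance = 1e-12)
  expect_equal(mm$features$n_stems, 1L)
  expect_equal(mm$features$soma_height_y, 10)
  # unbranched stem: first branch = terminal; attachment above the midpoint
  expect_equal(mm$stems$y_prox, 2)
  expect_equal(mm$stems$y_dist, 80)
  expect_equal(mm$stems$division, "upper")
  expect_equal(mm$features$basal_upper_csa, pi, tolerance = 1e-12)
  expect_equal(mm$features$basal_lower_csa, 0)

  no_soma <- m
  no_soma$segments$domain <- c("basal", "basal")
  expect_error(compute_morphometrics(no_soma),
               class = "eap_integrity_error")
})

test_that("mirroring a morphology in Y swaps the upper and lower fields", {
  morph <- build_archetype_morphology("thick_tufted_pyr_a", 4)
  mirror <- morph
  mirror$segments$py <- -morph$segments$py
  mirror$segments$dy <- -morph$segments$dy
  a <- compute_morphometrics(morph)$features
  b <- compute_morphometrics(mirror)$features
  expect_equal(a$basal_upper_csa, b$basal_lower_csa, tolerance = 1e-9)
  expect_equal(a$basal_lower_csa, b$basal_upper_csa, tolerance = 1e-9)
  expect_equal(a$apical_upper_csa, b$apical_lower_csa, tolerance = 1e-9)
  expect_equal(a$basal_terminal_y_upper, -b$basal_terminal_y_lower,
               tolerance = 1e-9)
  expect_equal(a$total_stem_csa, b$total_stem_csa, tolerance = 1e-9)
  # upper/lower CSAs partition the total
  expect_equal(a$basal_upper_csa + a$basal_lower_csa, a$basal_total_csa,
               tolerance = 1e-9)
})

test_that("domain density profiles are unit-area histograms over Y", {
  segs <- dplyr::bind_rows(
    tibble::tibble(id = 0L, parent_id = NA_integer_, px = 0, py = -5, pz = 0,
                   dx = 0, dy = 5, dz = 0, prox_radius = 5, dist_radius = 5,
                   domain = "soma"),
    tibble::tibble(id = 1L, parent_id = 0L, px = 0, py = 5, pz = 0,
                   dx = 0, dy = 35, dz = 0, prox_radius = 2, dist_radius = 1,
                   domain = "apical"))
  m1 <- structure(list(segments = segs, family = "a", variant = 0L,
                       soma_center = c(0, 0, 0)), class = "morphology")
  m2 <- m1
  m2$segments$py[2] <- -5
  m2$segments$dy[2] <- -35

  bins <- seq(-60, 60, by = 20)
  prof <- domain_density_profile(list(m1), "apical", "terminal", bins)
  expect_equal(sum(prof$density * 20), 1, tolerance = 1e-12)
  expect_equal(prof$y_mid[prof$density > 0], 30)  # bin (20, 40]

  both <- domain_density_profile(list(m1, m2), "apical", "terminal", bins)
  expect_equal(sum(both$density > 0), 2L)
  expect_equal(both$density[both$y_mid == 30], both$density[both$y_mid == -30])

  none <- suppressMessages(
    domain_density_profile(list(m1), "basal", "terminal", bins))
  expect_true(attr(none, "empty"))
  expect_equal(sum(none$density), 0)
})
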