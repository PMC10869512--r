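# mapping between internal domain labels and NeuroML segment-group names
.domain_to_group <- c(soma = "soma_group", ais = "axon_group",
                      basal = "dendrite_group", apical = "apical_dendrite_group")

.group_to_domain <- function(name) {
  n <- tolower(name)
  if (grepl("soma", n)) return("soma")
  if (grepl("axon|ais", n)) return("ais")
  if (grepl("apical", n)) return("apical")
  if (grepl("basal|dend", n)) return("basal")
  NA_character_
}

#' Write a morphology as a minimal NeuroML v2 file
#'
#' Emits `segment` elements with `proximal`/`distal` coordinates and
#' diameters plus one `segmentGroup` per morphological domain
#' (`soma_group`, `axon_group`, `dendrite_group`,
#' `apical_dendrite_group`).
#'
#' @param morph A `morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_neuroml <- function(morph, path) {
  s <- morph$segments
  doc <- xml2::xml_new_root("neuroml",
                            xmlns = "http://www.neuroml.org/schema/neuroml2")
  cell <- xml2::xml_add_child(doc, "cell",
                              id = paste0(morph$family, "_", morph$variant))
  mo <- xml2::xml_add_child(cell, "morphology",
                            id = paste0("morph_", morph$family))
  fmt <- function(x) sprintf("%.6f", x)
  for (i in seq_len(nrow(s))) {
    seg <- xml2::xml_add_child(mo, "segment", id = as.character(s$id[i]),
                               name = paste0(s$domain[i], "_", s$id[i]))
    if (!is.na(s$parent_id[i])) {
      xml2::xml_add_child(seg, "parent", segment = as.character(s$parent_id[i]))
    }
    xml2::xml_add_child(seg, "proximal", x = fmt(s$px[i]), y = fmt(s$py[i]),
                        z = fmt(s$pz[i]), diameter = fmt(2 * s$prox_radius[i]))
    xml2::xml_add_child(seg, "distal", x = fmt(s$dx[i]), y = fmt(s$dy[i]),
                        z = fmt(s$dz[i]), diameter = fmt(2 * s$dist_radius[i]))
  }
  for (dom in unique(s$domain)) {
    grp <- xml2::xml_add_child(mo, "segmentGroup", id = .domain_to_group[[dom]])
    for (id in s$id[s$domain == dom]) {
      xml2::xml_add_child(grp, "member", segment = as.character(id))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a minimal NeuroML v2 morphology
#'
#' Parses `segment` elements (proximal/distal coordinates and diameters,
#' parent links) and `segmentGroup` memberships; group names are mapped to
#' the four morphological domains (soma / axon-AIS / basal / apical). A
#' segment with no resolvable domain is an error naming its id, as is a
#' root segment lacking a proximal point.
#'
#' @param path NeuroML XML file.
#' @param family,variant Optional metadata overrides (defaults parsed from
#'   the cell id when possible).
#' @return A `morphology`.
#' @export
read_neuroml_morphology <- function(path, family = NULL, variant = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed NeuroML XML: ", conditionMessage(e)),
          class = "eap_parse_error")
  })
  xml2::xml_ns_strip(doc)
  seg_nodes <- xml2::xml_find_all(doc, ".//segment")
  if (length(seg_nodes) == 0) abort("no segment elements found",
                                    class = "eap_parse_error")
  # domain per segment id from the groups
  dom_map <- new.env(parent = emptyenv())
  for (grp in xml2::xml_find_all(doc, ".//segmentGroup")) {
    dom <- .group_to_domain(xml2::xml_attr(grp, "id"))
    if (is.na(dom)) {
      abort(paste0("unknown segment group: ",
                   xml2::xml_attr(grp, "id")), class = "eap_parse_error")
    }
    for (m in xml2::xml_find_all(grp, ".//member")) {
      assign(xml2::xml_attr(m, "segment"), dom, envir = dom_map)
    }
  }
  num_attr <- function(node, a) as.numeric(xml2::xml_attr(node, a))
  rows <- lapply(seg_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    parent <- xml2::xml_find_first(node, "./parent")
    parent_id <- if (inherits(parent, "xml_missing")) NA_integer_ else
      as.integer(xml2::xml_attr(parent, "segment"))
    prox <- xml2::xml_find_first(node, "./proximal")
    dist <- xml2::xml_find_first(node, "./distal")
    if (inherits(prox, "xml_missing") && is.na(parent_id)) {
      abort(paste0("root segment ", id, " lacks a proximal point"),
            class = "eap_parse_error")
    }
    if (inherits(dist, "xml_missing")) {
      abort(paste0("segment ", id, " lacks a distal point"),
            class = "eap_parse_error")
    }
    dom <- if (exists(id, envir = dom_map)) get(id, envir = dom_map) else
      NA_character_
    if (is.na(dom)) abort(paste0("segment ", id, " has no domain group"),
                          class = "eap_parse_error")
    tibble(
      id = as.integer(id), parent_id = parent_id,
      px = num_attr(prox, "x"), py = num_attr(prox, "y"),
      pz = num_attr(prox, "z"),
      dx = num_attr(dist, "x"), dy = num_attr(dist, "y"),
      dz = num_attr(dist, "z"),
      prox_radius = num_attr(prox, "diameter") / 2,
      dist_radius = num_attr(dist, "diameter") / 2,
      domain = dom)
  })
  cell_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//cell"), "id")
  if (is.null(family)) {
    family <- if (!is.na(cell_id)) sub("_[0-9]+$", "", cell_id) else "unknown"
  }
  if (is.null(variant)) {
    v <- if (!is.na(cell_id)) sub("^.*_([0-9]+)$", "\\1", cell_id) else NA
    variant <- if (!is.na(suppressWarnings(as.integer(v))))
      as.integer(v) else 0L
  }
  morph <- structure(
    list(segments = dplyr::bind_rows(rows), family = family,
         variant = variant, soma_center = c(0, 0, 0)),
    class = "morphology")
  validate_morphology(morph)
  morph
}
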