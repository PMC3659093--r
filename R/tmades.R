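#' @name tmades
#' @title TMA Data Exchange Specification (TMA DES) import and export
#' @description
#' The TMA DES is the pathology-informatics community's XML format for
#' sharing tissue microarray data. The toolkit writes every internal field
#' that has a DES tag equivalent under that tag (`block_identifier`,
#' `block_core_size`, `block_core_spacing`, `slide_identifier`,
#' `core_histo-repository_donor-block`,
#' `core_results_percent-tissue-staining`, `core_results_tissue-intensity`)
#' and everything without one (coordinates, slice number, position-used
#' flags, Allred components, HER2 and binary results) as extension elements
#' in the `cg:` project namespace, so that standard-compliant consumers can
#' read the shared subset while nothing is lost on round trip.
NULL

TMADES_EXT_NS <- "urn:tmakit:tmades-extension"

# structural elements of the DES document tree
TMADES_STRUCTURAL <- c("tma", "header", "block", "slide", "core")
# Table-vocabulary DES CDE tags the toolkit emits
TMADES_CDE_TAGS <- c("block_identifier", "block_core_size",
                     "block_core_spacing", "slide_identifier",
                     "core_histo-repository_donor-block",
                     "core_results_percent-tissue-staining",
                     "core_results_tissue-intensity")

# per-system routing of score fields to DES tags; unlisted fields go to the
# extension namespace as cg:{system-specific name}
des_field_tag <- function(system, field) {
  if (system == "percentage" && field == "percent") {
    return("core_results_percent-tissue-staining")
  }
  if (system == "intensity-0-3" && field == "intensity") {
    return("core_results_tissue-intensity")
  }
  ext <- switch(paste(system, field),
                "allred intensity" = "allred_intensity",
                "allred proportion" = "allred_proportion",
                "allred total" = "allred_total",
                "her2-ihc her2" = "her2_ihc",
                "binary result" = "binary_result",
                paste0("field_", field))
  paste0("cg:", ext)
}

des_tag_field <- function(tag, system) {
  switch(tag,
         "core_results_percent-tissue-staining" = "percent",
         "core_results_tissue-intensity" = "intensity",
         "allred_intensity" = "intensity",
         "allred_proportion" = "proportion",
         "allred_total" = "total",
         "her2_ihc" = "her2",
         "binary_result" = "result",
         sub("^field_", "", tag))
}

#' Export a marker collection as a TMA DES document
#'
#' Serialises every slide registered under `(study, marker)` — layout
#' geometry, donor linkage, and the latest score of each core by each scorer
#' — as a TMA DES XML document. An empty collection yields a header-only
#' document with a warning.
#'
#' @param store A `tma_store`.
#' @param study_id,marker Collection to export.
#' @param path Optional output file path.
#' @param date ISO-8601 export timestamp (inject a fixed one for
#'   deterministic output).
#' @return An `xml2::xml_document` (invisibly when `path` is given).
#' @export
export_tmades <- function(store, study_id, marker, path = NULL,
                          date = iso_now()) {
  stopifnot(inherits(store, "tma_store"))
  doc <- xml2::xml_new_root("tma", "xmlns:cg" = TMADES_EXT_NS)
  header <- xml2::xml_add_child(doc, "header")
  xml2::xml_add_child(header, "cg:origin", "tmakit")
  xml2::xml_add_child(header, "cg:date", date)
  xml2::xml_add_child(header, "cg:generator",
                      paste0("tmakit ", as.character(utils::packageVersion("tmakit"))))
  xml2::xml_add_child(header, "cg:study", study_id)
  xml2::xml_add_child(header, "cg:marker", marker)

  maps <- store_slidemaps(store, study_id, marker)
  if (!length(maps)) {
    warning("collection ", study_id, "/", marker,
            " holds no slides; exporting header only", call. = FALSE)
  }
  docs <- marker_docs(store, study_id, marker)
  for (map in maps) {
    blk <- xml2::xml_add_child(doc, "block")
    b <- map$block
    xml2::xml_add_child(blk, "block_identifier", b$block_id)
    xml2::xml_add_child(blk, "block_core_size", num_str(b$core_diameter))
    xml2::xml_add_child(blk, "block_core_spacing", num_str(b$core_spacing))
    xml2::xml_add_child(blk, "cg:slice_number", as.character(b$slice_number))
    xml2::xml_add_child(blk, "cg:columns", as.character(b$n_cols))
    xml2::xml_add_child(blk, "cg:rows", as.character(b$n_rows))
    slide <- xml2::xml_add_child(blk, "slide")
    xml2::xml_add_child(slide, "slide_identifier", map$slide_id)
    xml2::xml_add_child(slide, "cg:marker", map$marker_name)
    p <- map$positions
    for (i in seq_len(nrow(p))) {
      core <- xml2::xml_add_child(slide, "core")
      xml2::xml_add_child(core, "cg:x", as.character(p$x[i]))
      xml2::xml_add_child(core, "cg:y", as.character(p$y[i]))
      xml2::xml_add_child(core, "cg:position_used",
                          tolower(as.character(p$used[i])))
      xml2::xml_add_child(core, "cg:kind", p$kind[i])
      if (p$kind[i] == "tissue") {
        xml2::xml_add_child(core, "core_histo-repository_donor-block",
                            p$donor_block_id[i])
      }
      for (d in docs) {
        if (d$slide_id != map$slide_id) next
        for (r in latest_scores(d$scores)) {
          if (r$x != p$x[i] || r$y != p$y[i]) next
          sc <- xml2::xml_add_child(core, "cg:score", scorer = r$scorer,
                                    system = d$template$system,
                                    record_version = as.character(r$record_version),
                                    timestamp = r$timestamp, status = r$status)
          for (f in names(r$values)) {
            xml2::xml_add_child(sc, des_field_tag(d$template$system, f),
                                as.character(r$values[[f]]))
          }
        }
      }
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

ns_uri <- function(node) xml2::xml_find_chr(node, "string(namespace-uri(.))")

#' Check TMA DES schema conformance of an exported document
#'
#' Verifies the export invariant: every element is either one of the DES
#' structural elements (`tma`, `header`, `block`, `slide`, `core`), a DES
#' CDE tag from the supported vocabulary, or carries the project extension
#' namespace.
#'
#' @param x A path, XML string or `xml2::xml_document`.
#' @return `TRUE`, or a character vector naming the offending elements.
#' @export
tmades_conformant <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  nodes <- xml2::xml_find_all(doc, "//*")
  bad <- character()
  for (node in nodes) {
    uri <- ns_uri(node)
    name <- xml2::xml_name(node)
    ok <- identical(uri, TMADES_EXT_NS) ||
      (!nzchar(uri) && name %in% c(TMADES_STRUCTURAL, TMADES_CDE_TAGS))
    if (!ok) bad <- c(bad, name)
  }
  if (length(bad)) unique(bad) else TRUE
}

#' Import a TMA DES document
#'
#' Maps recognised DES tags and project extension elements back to internal
#' slidemaps and score records. Unrecognised vendor elements are preserved
#' as opaque annotations (element name plus text) and logged; a core without
#' coordinates is returned in `unplaced` with a warning; a slide without a
#' `slide_identifier` is an error.
#'
#' @param x A path, XML string or `xml2::xml_document`.
#' @return A list with `slidemaps` (list of [slidemap()]), `scores` (list of
#'   [score_record()]s), `systems` (named character vector: scorer ->
#'   system), `annotations` (data frame of unrecognised elements), and
#'   `unplaced` (data frame of cores lacking coordinates).
#' @export
import_tmades <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "tma") {
    stop_tma("parse error at /: expected tma, found %s", xml2::xml_name(root))
  }
  ext1 <- function(node, local) {
    xml2::xml_find_first(node, sprintf(
      "./*[local-name()='%s' and namespace-uri()='%s']", local, TMADES_EXT_NS))
  }
  ext_txt <- function(node, local, default = NA_character_) {
    n <- ext1(node, local)
    if (inherits(n, "xml_missing")) default else xml2::xml_text(n)
  }
  plain1 <- function(node, local) {
    xml2::xml_find_first(node, sprintf(
      "./*[local-name()='%s' and namespace-uri()='']", local))
  }
  plain_txt <- function(node, local, default = NA_character_) {
    n <- plain1(node, local)
    if (inherits(n, "xml_missing")) default else xml2::xml_text(n)
  }

  slidemaps <- list()
  scores <- list()
  systems <- character()
  annotations <- data.frame(element = character(), text = character(),
                            stringsAsFactors = FALSE)
  unplaced <- data.frame(slide_id = character(), donor_block_id = character(),
                         stringsAsFactors = FALSE)
  known_core_children <- c("x", "y", "position_used", "kind", "score")

  for (blk in xml2::xml_find_all(root, "./*[local-name()='block']")) {
    for (slide in xml2::xml_find_all(blk, "./*[local-name()='slide']")) {
      slide_id <- plain_txt(slide, "slide_identifier")
      if (is.na(slide_id) || !nzchar(slide_id)) {
        stop_tma("parse error: slide without <slide_identifier>")
      }
      marker <- ext_txt(slide, "marker", "")
      n_cols <- as.integer(ext_txt(blk, "columns", "1"))
      n_rows <- as.integer(ext_txt(blk, "rows", "1"))
      block <- recipient_block(
        block_id = plain_txt(blk, "block_identifier", slide_id),
        n_cols = n_cols, n_rows = n_rows,
        core_diameter = as.numeric(plain_txt(blk, "block_core_size", "0.6")),
        core_spacing = as.numeric(plain_txt(blk, "block_core_spacing", "1")),
        slice_number = as.integer(ext_txt(blk, "slice_number", "1"))
      )
      pos <- list()
      for (core in xml2::xml_find_all(slide, "./*[local-name()='core']")) {
        donor <- plain_txt(core, "core_histo-repository_donor-block", "")
        cx <- suppressWarnings(as.integer(ext_txt(core, "x")))
        cy <- suppressWarnings(as.integer(ext_txt(core, "y")))
        if (is.na(cx) || is.na(cy)) {
          warning("core on slide '", slide_id,
                  "' lacks coordinates; imported as unplaced", call. = FALSE)
          unplaced <- rbind(unplaced, data.frame(
            slide_id = slide_id, donor_block_id = donor,
            stringsAsFactors = FALSE))
          next
        }
        kind <- ext_txt(core, "kind",
                        if (nzchar(donor)) "tissue" else "empty")
        pos <- c(pos, list(core_position(cx, cy, donor_block_id = donor,
                                         kind = kind)))
        for (child in xml2::xml_find_all(core, "./*")) {
          local <- xml2::xml_name(child)
          uri <- ns_uri(child)
          if (identical(uri, TMADES_EXT_NS) && local %in% known_core_children) {
            next
          }
          if (!nzchar(uri) && local == "core_histo-repository_donor-block") next
          if (!identical(uri, TMADES_EXT_NS) || local != "score") {
            message("retaining unrecognised element <", local, "> as annotation")
            annotations <- rbind(annotations, data.frame(
              element = local, text = xml2::xml_text(child),
              stringsAsFactors = FALSE))
            next
          }
        }
        for (sc in xml2::xml_find_all(core, sprintf(
          "./*[local-name()='score' and namespace-uri()='%s']", TMADES_EXT_NS))) {
          system <- xml2::xml_attr(sc, "system")
          scorer <- xml2::xml_attr(sc, "scorer")
          systems[scorer] <- system
          values <- list()
          for (v in xml2::xml_find_all(sc, "./*")) {
            field <- des_tag_field(xml2::xml_name(v), system)
            s <- xml2::xml_text(v)
            n <- suppressWarnings(as.numeric(s))
            values[[field]] <- if (!is.na(n) && grepl("^-?[0-9.]+$", s)) n else s
          }
          status <- xml2::xml_attr(sc, "status")
          scores <- c(scores, list(score_record(
            slide_id, cx, cy, scorer = scorer, marker = marker,
            values = values, timestamp = xml2::xml_attr(sc, "timestamp"),
            record_version = as.integer(xml2::xml_attr(sc, "record_version")),
            status = if (is.na(status)) "scored" else status)))
        }
      }
      slidemaps <- c(slidemaps, list(slidemap(slide_id, block, pos, marker)))
    }
  }
  list(slidemaps = slidemaps, scores = scores, systems = systems,
       annotations = annotations, unplaced = unplaced)
}
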