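STORE_NS <- "urn:tmakit:store"

#' Open (or create) a hierarchical TMA study store
#'
#' The store is a directory tree of XML documents mirroring the
#' study -> marker -> scorer -> slide collection hierarchy: slide documents
#' live at `{root}/{study}/{marker}/{scorer}/{slide_id}.xml`, the shared
#' slidemap for a slide at `{root}/{study}/{marker}/{slide_id}.slidemap.xml`,
#' and advisory access grants in `{root}/permissions.xml`. The documents are
#' the sole source of truth — closing and reopening a store changes nothing.
#'
#' @param root Root directory (created if absent).
#' @return An object of class `tma_store`.
#' @export
study_store <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  structure(list(root = normalizePath(root)), class = "tma_store")
}

#' @export
print.tma_store <- function(x, ...) {
  cat(sprintf("<tma_store at %s: studies [%s]>\n", x$root,
              paste(store_studies(x), collapse = ", ")))
  invisible(x)
}

perm_path <- function(store) file.path(store$root, "permissions.xml")

read_grants <- function(store) {
  p <- perm_path(store)
  if (!file.exists(p)) {
    return(data.frame(scorer = character(), study = character(),
                      marker = character(), stringsAsFactors = FALSE))
  }
  nodes <- xml2::xml_find_all(xml2::read_xml(p), ".//*[local-name()='grant']")
  data.frame(scorer = xml2::xml_attr(nodes, "scorer"),
             study = xml2::xml_attr(nodes, "study"),
             marker = xml2::xml_attr(nodes, "marker"),
             stringsAsFactors = FALSE)
}

write_grants <- function(store, grants) {
  doc <- xml2::xml_new_root("permissions", xmlns = STORE_NS)
  for (i in seq_len(nrow(grants))) {
    xml2::xml_add_child(doc, "grant", scorer = grants$scorer[i],
                        study = grants$study[i], marker = grants$marker[i])
  }
  xml2::write_xml(doc, perm_path(store))
  invisible(store)
}

#' @rdname study_store
#' @param store A `tma_store`.
#' @param study_id Study identifier (path-safe).
#' @export
create_study <- function(store, study_id) {
  stopifnot(inherits(store, "tma_store"))
  assert_path_safe(study_id, "study_id")
  path <- file.path(store$root, study_id)
  if (dir.exists(path)) stop_tma("study '%s' already exists", study_id)
  dir.create(path)
  invisible(store)
}

#' @rdname study_store
#' @param marker Marker (stain) collection name (path-safe).
#' @export
add_marker <- function(store, study_id, marker) {
  stopifnot(inherits(store, "tma_store"))
  assert_path_safe(study_id, "study_id")
  assert_path_safe(marker, "marker")
  study_path <- file.path(store$root, study_id)
  if (!dir.exists(study_path)) stop_tma("study '%s' does not exist", study_id)
  path <- file.path(study_path, marker)
  if (dir.exists(path)) stop_tma("marker '%s' already exists in study '%s'",
                                 marker, study_id)
  dir.create(path)
  invisible(store)
}

#' Grant a scorer access to a (study, marker) collection
#'
#' Grants are advisory permissions enforced by the library API: a scorer may
#' open and write slide documents only under granted `(study, marker)` pairs.
#' Granting creates the scorer's collection directory.
#'
#' @param store A `tma_store`.
#' @param scorer Scorer username (path-safe).
#' @param study_id,marker The collection being granted.
#' @return The store, invisibly.
#' @export
grant_scorer <- function(store, scorer, study_id, marker) {
  stopifnot(inherits(store, "tma_store"))
  assert_path_safe(scorer, "scorer")
  marker_path <- file.path(store$root, study_id, marker)
  if (!dir.exists(marker_path)) {
    stop_tma("collection %s/%s does not exist", study_id, marker)
  }
  grants <- read_grants(store)
  if (!any(grants$scorer == scorer & grants$study == study_id &
           grants$marker == marker)) {
    grants <- rbind(grants, data.frame(scorer = scorer, study = study_id,
                                       marker = marker, stringsAsFactors = FALSE))
    write_grants(store, grants)
  }
  dir.create(file.path(marker_path, scorer), showWarnings = FALSE)
  invisible(store)
}

#' @rdname grant_scorer
#' @export
has_grant <- function(store, scorer, study_id, marker) {
  grants <- read_grants(store)
  any(grants$scorer == scorer & grants$study == study_id &
      grants$marker == marker)
}

#' @rdname study_store
#' @export
store_studies <- function(store) {
  dirs <- sort(list.dirs(store$root, recursive = FALSE, full.names = FALSE))
  dirs[!startsWith(dirs, "_")]  # underscore names are reserved, not studies
}

#' @rdname study_store
#' @export
store_markers <- function(store, study_id) {
  sort(list.dirs(file.path(store$root, study_id), recursive = FALSE,
                 full.names = FALSE))
}

slidemap_path <- function(store, study, marker, slide_id) {
  file.path(store$root, study, marker, paste0(slide_id, ".slidemap.xml"))
}

#' Register a slidemap in a marker collection
#'
#' Stores the slide's layout once per `(study, marker)`; scorer documents
#' reference it by path and checksum rather than duplicating it.
#'
#' @param store A `tma_store`.
#' @param study_id,marker Target collection.
#' @param map A [slidemap()].
#' @return The slidemap file path, invisibly.
#' @export
add_slidemap <- function(store, study_id, marker, map) {
  stopifnot(inherits(store, "tma_store"), inherits(map, "tma_slidemap"))
  marker_path <- file.path(store$root, study_id, marker)
  if (!dir.exists(marker_path)) {
    stop_tma("collection %s/%s does not exist", study_id, marker)
  }
  path <- slidemap_path(store, study_id, marker, map$slide_id)
  write_slidemap_xml(map, path)
  invisible(path)
}

store_slidemaps <- function(store, study, marker) {
  files <- list.files(file.path(store$root, study, marker),
                      pattern = "\\.slidemap\\.xml$", full.names = TRUE)
  stats::setNames(lapply(files, parse_slidemap_xml),
                  sub("\\.slidemap\\.xml$", "", basename(files)))
}

# ---------------------------------------------------------------------------
# Score form templates

#' Build a score form template from a slidemap
#'
#' The template lists every used position of the slide with one empty slot
#' per field of the scoring system — the structure a scoring form is
#' generated from. Marker cores are listed but flagged so forms can skip
#' them; gaps are omitted.
#'
#' @param map A [slidemap()].
#' @param system A [scoring_system()].
#' @return An object of class `tma_score_template` with fields `slide_id`,
#'   `marker`, `system`, `fields` and `entries` (data frame of used
#'   positions).
#' @export
make_score_template <- function(map, system) {
  stopifnot(inherits(map, "tma_slidemap"), inherits(system, "tma_scoring_system"))
  used <- map$positions[map$positions$used, , drop = FALSE]
  entries <- data.frame(x = used$x, y = used$y,
                        donor_block_id = used$donor_block_id,
                        kind = used$kind,
                        image = core_filename(map$slide_id, used$x, used$y),
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(
    list(slide_id = map$slide_id, marker = map$marker_name,
         system = system$name, fields = names(system$fields),
         entries = entries),
    class = "tma_score_template"
  )
}

template_to_xml <- function(parent, tpl) {
  node <- xml2::xml_add_child(parent, "template", system = tpl$system)
  for (f in tpl$fields) xml2::xml_add_child(node, "slot", field = f)
  for (i in seq_len(nrow(tpl$entries))) {
    e <- xml2::xml_add_child(node, "entry",
                             x = as.character(tpl$entries$x[i]),
                             y = as.character(tpl$entries$y[i]),
                             kind = tpl$entries$kind[i],
                             image = tpl$entries$image[i])
    if (nzchar(tpl$entries$donor_block_id[i])) {
      xml2::xml_attr(e, "donor") <- tpl$entries$donor_block_id[i]
    }
  }
  invisible(node)
}

template_from_xml <- function(node, slide_id, marker) {
  slots <- xml2::xml_find_all(node, "./*[local-name()='slot']")
  entries <- xml2::xml_find_all(node, "./*[local-name()='entry']")
  donor <- xml2::xml_attr(entries, "donor")
  donor[is.na(donor)] <- ""
  structure(
    list(slide_id = slide_id, marker = marker,
         system = xml2::xml_attr(node, "system"),
         fields = xml2::xml_attr(slots, "field"),
         entries = data.frame(
           x = as.integer(xml2::xml_attr(entries, "x")),
           y = as.integer(xml2::xml_attr(entries, "y")),
           donor_block_id = donor,
           kind = xml2::xml_attr(entries, "kind"),
           image = xml2::xml_attr(entries, "image"),
           stringsAsFactors = FALSE)),
    class = "tma_score_template"
  )
}

#' Write / read a score form template as a standalone XML document
#'
#' @param tpl A `tma_score_template`.
#' @param path Optional output path.
#' @return For the writer, an `xml2::xml_document`; for the parser, a
#'   `tma_score_template`.
#' @export
write_template_xml <- function(tpl, path = NULL) {
  doc <- xml2::xml_new_root("scoreFormTemplate", xmlns = STORE_NS)
  xml2::xml_add_child(doc, "slide_identifier", tpl$slide_id)
  xml2::xml_add_child(doc, "marker", tpl$marker)
  template_to_xml(doc, tpl)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @rdname write_template_xml
#' @param x A path, XML string or document.
#' @export
parse_template_xml <- function(x) {
  root <- xml2::xml_root(if (inherits(x, "xml_document")) x else xml2::read_xml(x))
  f1 <- function(tag) xml2::xml_find_first(root, sprintf("./*[local-name()='%s']", tag))
  sid <- f1("slide_identifier")
  if (inherits(sid, "xml_missing")) {
    stop_tma("parse error at /scoreFormTemplate: missing <slide_identifier>")
  }
  mk <- f1("marker")
  template_from_xml(f1("template"), xml2::xml_text(sid),
                    if (inherits(mk, "xml_missing")) "" else xml2::xml_text(mk))
}

# ---------------------------------------------------------------------------
# Slide documents

doc_path <- function(store, study, marker, scorer, slide_id) {
  file.path(store$root, study, marker, scorer, paste0(slide_id, ".xml"))
}

score_to_xml <- function(parent, r) {
  node <- xml2::xml_add_child(parent, "score",
                              x = as.character(r$x), y = as.character(r$y),
                              record_version = as.character(r$record_version),
                              timestamp = r$timestamp, status = r$status)
  for (f in names(r$values)) {
    xml2::xml_add_child(node, "value", as.character(r$values[[f]]), field = f)
  }
  if (!is.null(r$note)) xml2::xml_add_child(node, "note", r$note)
  invisible(node)
}

score_from_xml <- function(node, slide_id, scorer, marker) {
  vals <- xml2::xml_find_all(node, "./*[local-name()='value']")
  values <- lapply(xml2::xml_text(vals), function(s) {
    n <- suppressWarnings(as.numeric(s))
    if (!is.na(n) && grepl("^-?[0-9.]+$", s)) n else s
  })
  names(values) <- xml2::xml_attr(vals, "field")
  note_node <- xml2::xml_find_first(node, "./*[local-name()='note']")
  score_record(
    slide_id = slide_id, x = as.integer(xml2::xml_attr(node, "x")),
    y = as.integer(xml2::xml_attr(node, "y")), scorer = scorer, marker = marker,
    values = values, timestamp = xml2::xml_attr(node, "timestamp"),
    record_version = as.integer(xml2::xml_attr(node, "record_version")),
    status = xml2::xml_attr(node, "status"),
    note = if (!inherits(note_node, "xml_missing")) xml2::xml_text(note_node)
  )
}

read_slide_doc <- function(path) {
  root <- xml2::xml_root(xml2::read_xml(path))
  f1 <- function(tag) xml2::xml_find_first(root, sprintf("./*[local-name()='%s']", tag))
  txt <- function(tag) {
    n <- f1(tag)
    if (inherits(n, "xml_missing")) stop_tma("slide document '%s' lacks <%s>", path, tag)
    xml2::xml_text(n)
  }
  slide_id <- txt("slide_identifier")
  scorer <- txt("scorer"); marker <- txt("marker")
  ref <- f1("slidemapRef")
  tpl <- template_from_xml(f1("template"), slide_id, marker)
  score_nodes <- xml2::xml_find_all(root,
    ".//*[local-name()='scores']/*[local-name()='score']")
  list(slide_id = slide_id, study = txt("study"), marker = marker,
       scorer = scorer, template = tpl,
       slidemap_href = xml2::xml_attr(ref, "href"),
       slidemap_checksum = xml2::xml_attr(ref, "checksum"),
       scores = lapply(score_nodes, score_from_xml, slide_id = slide_id,
                       scorer = scorer, marker = marker))
}

write_slide_doc <- function(doc, path) {
  root <- xml2::xml_new_root("slideDocument", xmlns = STORE_NS)
  xml2::xml_add_child(root, "slide_identifier", doc$slide_id)
  xml2::xml_add_child(root, "study", doc$study)
  xml2::xml_add_child(root, "marker", doc$marker)
  xml2::xml_add_child(root, "scorer", doc$scorer)
  xml2::xml_add_child(root, "slidemapRef", href = doc$slidemap_href,
                      checksum = doc$slidemap_checksum)
  template_to_xml(root, doc$template)
  scores <- xml2::xml_add_child(root, "scores")
  for (r in doc$scores) score_to_xml(scores, r)
  xml2::write_xml(root, path)
  invisible(path)
}

#' Open a slide document for a scorer
#'
#' Checks the scorer's grant and returns the scorer's document for the
#' slide, creating it on first open from the registered slidemap and a fresh
#' score form template.
#'
#' @param store A `tma_store`.
#' @param study_id,marker Collection holding the slide.
#' @param scorer Scorer username (must hold a grant).
#' @param slide_id Slide identifier (its slidemap must be registered).
#' @param system The [scoring_system()] for the form (default Allred).
#' @return The slide document (a list; see Details), invisibly.
#' @export
open_slide <- function(store, study_id, marker, scorer, slide_id,
                       system = builtin_systems()[["allred"]]) {
  stopifnot(inherits(store, "tma_store"))
  if (!has_grant(store, scorer, study_id, marker)) {
    stop_tma("permission error: scorer '%s' has no grant on %s/%s",
             scorer, study_id, marker)
  }
  path <- doc_path(store, study_id, marker, scorer, slide_id)
  if (file.exists(path)) return(invisible(read_slide_doc(path)))
  smap_path <- slidemap_path(store, study_id, marker, slide_id)
  if (!file.exists(smap_path)) {
    stop_tma("no slidemap registered for slide '%s' in %s/%s",
             slide_id, study_id, marker)
  }
  map <- parse_slidemap_xml(smap_path)
  doc <- list(slide_id = slide_id, study = study_id, marker = marker,
              scorer = scorer,
              template = make_score_template(map, system),
              slidemap_href = file.path("..", basename(smap_path)),
              slidemap_checksum = digest::digest(file = smap_path, algo = "sha1"),
              scores = list())
  dir.create(dirname(path), showWarnings = FALSE)
  write_slide_doc(doc, path)
  invisible(doc)
}

#' Record a score in the store
#'
#' Validates the record against the slide document's scoring system and
#' appends it with the next `record_version` for its core. The document is
#' left unchanged when validation fails or the scorer holds no grant.
#'
#' @param store A `tma_store`.
#' @param study_id Study collection.
#' @param record A [score_record()] (its `scorer` and `marker` locate the
#'   document; any supplied `record_version` is replaced by the next one).
#' @param system Scoring system used if the slide must be opened first.
#' @param registry CDE registry for validation.
#' @return The appended record (with its assigned version), invisibly.
#' @export
record_score <- function(store, study_id, record,
                         system = builtin_systems()[["allred"]],
                         registry = load_default_cdes()) {
  stopifnot(inherits(store, "tma_store"), inherits(record, "tma_score"))
  scorer <- record$scorer; marker <- record$marker
  if (!has_grant(store, scorer, study_id, marker)) {
    stop_tma("permission error: scorer '%s' has no grant on %s/%s",
             scorer, study_id, marker)
  }
  path <- doc_path(store, study_id, marker, scorer, record$slide_id)
  if (!file.exists(path)) {
    open_slide(store, study_id, marker, scorer, record$slide_id, system)
  }
  doc <- read_slide_doc(path)
  systems <- builtin_systems(registry)
  sys <- systems[[doc$template$system]] %||% system
  res <- validate_score(sys, registry, record)
  if (!res$valid) stop_tma("score rejected: %s", res$message)
  prev <- vapply(doc$scores, function(r) {
    if (r$x == record$x && r$y == record$y) r$record_version else 0L
  }, 0L)
  record$record_version <- if (length(prev)) max(prev, 0L) + 1L else 1L
  doc$scores <- c(doc$scores, list(record))
  write_slide_doc(doc, path)
  invisible(record)
}

#' Latest scores in a scorer's slide document
#'
#' @param store A `tma_store`.
#' @param study_id,marker,scorer,slide_id Document coordinates.
#' @return A list of [score_record()]s, one per scored core (highest
#'   version), or an empty list when the document does not exist.
#' @export
slide_scores <- function(store, study_id, marker, scorer, slide_id) {
  path <- doc_path(store, study_id, marker, scorer, slide_id)
  if (!file.exists(path)) return(list())
  latest_scores(read_slide_doc(path)$scores)
}

marker_docs <- function(store, study, marker, scorer = NULL) {
  base <- file.path(store$root, study, marker)
  scorers <- if (is.null(scorer)) {
    sort(list.dirs(base, recursive = FALSE, full.names = FALSE))
  } else scorer
  paths <- unlist(lapply(scorers, function(s) {
    list.files(file.path(base, s), pattern = "\\.xml$", full.names = TRUE)
  }))
  lapply(paths, read_slide_doc)
}

#' Export latest scores as a table
#'
#' One row per `(core, scorer)` with a recorded score, carrying the donor
#' block identifier from the slidemap so every row links back to the patient
#' tissue it came from. Suitable for import into spreadsheet or statistics
#' software.
#'
#' @param store A `tma_store`.
#' @param study_id,marker Collection to export.
#' @param scorer A single scorer, or `NULL` for all scorers.
#' @return A data frame with columns `study`, `marker`, `scorer`,
#'   `slide_id`, `x`, `y`, `donor_block_id`, one column per score field, and
#'   `timestamp`. Header-only (zero rows) when nothing is scored.
#' @export
export_table <- function(store, study_id, marker, scorer = NULL) {
  stopifnot(inherits(store, "tma_store"))
  docs <- marker_docs(store, study_id, marker, scorer)
  maps <- store_slidemaps(store, study_id, marker)
  all_fields <- unique(unlist(lapply(docs, function(d) d$template$fields)))
  base_cols <- c("study", "marker", "scorer", "slide_id", "x", "y",
                 "donor_block_id")
  empty <- as.data.frame(c(
    stats::setNames(list(character(), character(), character(), character(),
                         integer(), integer(), character()), base_cols),
    stats::setNames(rep(list(character()), length(all_fields)), all_fields),
    list(timestamp = character())), stringsAsFactors = FALSE)
  rows <- list()
  for (d in docs) {
    map <- maps[[d$slide_id]]
    for (r in latest_scores(d$scores)) {
      donor <- if (!is.null(map)) {
        pos <- core_at(map, r$x, r$y)
        if (is.null(pos)) "" else pos$donor_block_id
      } else ""
      row <- data.frame(study = d$study, marker = d$marker, scorer = d$scorer,
                        slide_id = d$slide_id, x = r$x, y = r$y,
                        donor_block_id = donor, stringsAsFactors = FALSE)
      for (f in all_fields) {
        row[[f]] <- if (f %in% names(r$values)) as.character(r$values[[f]])
                    else NA_character_
      }
      row$timestamp <- r$timestamp
      rows <- c(rows, list(row))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$scorer, out$slide_id, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find every core from one donor block
#'
#' Scans the whole store for tissue cores punched from the given donor block
#' — i.e. all of one patient's cores, across studies and markers — together
#' with the latest scores each core has received.
#'
#' @param store A `tma_store`.
#' @param donor_block_id Donor block identifier.
#' @return A data frame with columns `study`, `marker`, `slide_id`, `x`, `y`
#'   and a list-column `scores` (per-core list of latest [score_record()]s
#'   across scorers); zero rows for an unknown donor.
#' @export
query_by_donor <- function(store, donor_block_id) {
  stopifnot(inherits(store, "tma_store"))
  out <- data.frame(study = character(), marker = character(),
                    slide_id = character(), x = integer(), y = integer(),
                    stringsAsFactors = FALSE)
  out$scores <- list()
  for (study in store_studies(store)) {
    for (marker in store_markers(store, study)) {
      maps <- store_slidemaps(store, study, marker)
      docs <- marker_docs(store, study, marker)
      for (map in maps) {
        hits <- map$positions[map$positions$kind == "tissue" &
                              map$positions$donor_block_id == donor_block_id, ,
                              drop = FALSE]
        for (i in seq_len(nrow(hits))) {
          latest <- list()
          for (d in docs) {
            if (d$slide_id != map$slide_id) next
            for (r in latest_scores(d$scores)) {
              if (r$x == hits$x[i] && r$y == hits$y[i]) {
                latest <- c(latest, list(r))
              }
            }
          }
          row <- data.frame(study = study, marker = marker,
                            slide_id = map$slide_id,
                            x = hits$x[i], y = hits$y[i],
                            stringsAsFactors = FALSE)
          row$scores <- list(latest)
          out <- rbind(out, row)
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}
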