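#' Value domains for Common Data Elements
#'
#' A value domain constrains the values a data element may take. Four kinds
#' are supported: `enumerated` (a fixed code list with meanings),
#' `integer-range` and `real-range` (closed intervals, optionally stepped),
#' and `free-text` (optionally pattern-constrained strings).
#'
#' @param kind One of `"enumerated"`, `"integer-range"`, `"real-range"`,
#'   `"free-text"`.
#' @param codes Character vector of permitted codes (enumerated only).
#' @param meanings Character vector of code meanings, recycled to match
#'   `codes`; defaults to the codes themselves.
#' @param min,max Inclusive bounds (range kinds only).
#' @param step Optional step from `min` (range kinds only).
#' @param pattern Optional regular expression a free-text value must match in
#'   full.
#' @return An object of class `tma_value_domain`.
#' @examples
#' value_domain("integer-range", min = 0, max = 3)
#' value_domain("enumerated", codes = c("positive", "negative"))
#' @export
value_domain <- function(kind = c("enumerated", "integer-range", "real-range", "free-text"),
                         codes = NULL, meanings = NULL,
                         min = NULL, max = NULL, step = NULL,
                         pattern = NULL) {
  kind <- match.arg(kind)
  vd <- list(kind = kind)
  if (kind == "enumerated") {
    if (is.null(codes) || length(codes) < 1L) {
      stop_tma("enumerated domain needs at least one code")
    }
    codes <- as.character(codes)
    if (anyDuplicated(codes)) stop_tma("enumerated domain codes must be distinct")
    if (is.null(meanings)) meanings <- codes
    meanings <- rep_len(as.character(meanings), length(codes))
    vd$codes <- codes
    vd$meanings <- meanings
  } else if (kind %in% c("integer-range", "real-range")) {
    if (is.null(min) || is.null(max)) stop_tma("range domain needs min and max")
    min <- as.numeric(min); max <- as.numeric(max)
    if (min > max) stop_tma("range domain requires min <= max (got %g > %g)", min, max)
    vd$min <- min
    vd$max <- max
    if (!is.null(step)) {
      step <- as.numeric(step)
      if (step <= 0) stop_tma("step must be positive")
      vd$step <- step
    }
  } else {
    if (!is.null(pattern)) vd$pattern <- as.character(pattern)
  }
  structure(vd, class = "tma_value_domain")
}

#' Define a Common Data Element
#'
#' A Common Data Element (CDE) is a metadata definition: a name, an informal
#' definition of meaning and usage, a value domain, units of measurement, and
#' a list of alternative names under which the element is known in other
#' vocabularies (for TMA work, notably the tag names of the pathology
#' informatics TMA Data Exchange Specification).
#'
#' @param identifier Opaque unique identifier within a registry.
#' @param name Human-readable element name (non-empty).
#' @param definition Free-text definition.
#' @param domain A [value_domain()].
#' @param units Units of measurement, or `""`.
#' @param alternative_names Character vector of alternative names.
#' @return An object of class `tma_cde`.
#' @export
cde_definition <- function(identifier, name, definition = "", domain,
                           units = "", alternative_names = character()) {
  assert_nonempty_string(identifier, "identifier")
  assert_nonempty_string(name, "name")
  if (!inherits(domain, "tma_value_domain")) {
    stop_tma("domain must be a value_domain()")
  }
  alternative_names <- as.character(alternative_names)
  if (anyDuplicated(alternative_names)) {
    stop_tma("alternative names of a CDE must be distinct")
  }
  structure(
    list(identifier = identifier, name = name,
         definition = as.character(definition), domain = domain,
         units = as.character(units),
         alternative_names = alternative_names),
    class = "tma_cde"
  )
}

#' Create an empty CDE registry
#'
#' A registry holds CDE definitions keyed by identifier, with lookup by name
#' and by alternative name. Lookups are case-sensitive and exact.
#'
#' @return An object of class `tma_registry`.
#' @seealso [register_cde()], [load_default_cdes()]
#' @export
cde_registry <- function() {
  structure(list(cdes = list()), class = "tma_registry")
}

#' @export
length.tma_registry <- function(x) length(x$cdes)

#' @export
print.tma_registry <- function(x, ...) {
  cat(sprintf("<tma_registry: %d data elements>\n", length(x$cdes)))
  invisible(x)
}

#' Register a CDE
#'
#' Adds a definition to the registry. Identifiers, names and alternative
#' names must all be unique across the registry; a collision is rejected with
#' an error naming the colliding key.
#'
#' @param registry A [cde_registry()].
#' @param cde A [cde_definition()].
#' @return The updated registry.
#' @export
register_cde <- function(registry, cde) {
  stopifnot(inherits(registry, "tma_registry"), inherits(cde, "tma_cde"))
  if (cde$identifier %in% names(registry$cdes)) {
    stop_tma("duplicate CDE identifier '%s'", cde$identifier)
  }
  existing_names <- vapply(registry$cdes, `[[`, "", "name")
  if (cde$name %in% existing_names) {
    stop_tma("duplicate CDE name '%s'", cde$name)
  }
  existing_alt <- unlist(lapply(registry$cdes, `[[`, "alternative_names"),
                         use.names = FALSE)
  clash <- intersect(cde$alternative_names, existing_alt)
  if (length(clash)) {
    stop_tma("duplicate alternative name '%s'", clash[[1L]])
  }
  registry$cdes[[cde$identifier]] <- cde
  registry
}

#' Look up a CDE by identifier, name or alternative name
#'
#' @param registry A [cde_registry()].
#' @param key Identifier, exact name, or exact alternative name.
#' @return The matching `tma_cde`, or `NULL` when absent.
#' @export
cde_lookup <- function(registry, key) {
  stopifnot(inherits(registry, "tma_registry"))
  assert_nonempty_string(key, "key")
  hit <- registry$cdes[[key]]
  if (!is.null(hit)) return(hit)
  for (cde in registry$cdes) {
    if (identical(cde$name, key) || key %in% cde$alternative_names) return(cde)
  }
  NULL
}

#' Validate a value against a CDE's value domain
#'
#' Membership is checked against the element's value domain: code lists for
#' enumerated domains, closed (optionally stepped) intervals for ranges, and
#' an optional full-match pattern for free text. An out-of-domain value is a
#' result, not an error.
#'
#' @param cde A [cde_definition()].
#' @param value A scalar value.
#' @return A [validation_result()].
#' @examples
#' reg <- load_default_cdes()
#' validate_value(cde_lookup(reg, "Allred Intensity Score"), 4)
#' @export
validate_value <- function(cde, value) {
  stopifnot(inherits(cde, "tma_cde"))
  if (length(value) != 1L || is.na(value)) {
    return(validation_result(FALSE, sprintf(
      "'%s' expects a single non-missing value", cde$name)))
  }
  d <- cde$domain
  switch(d$kind,
    "enumerated" = {
      if (as.character(value) %in% d$codes) validation_result(TRUE)
      else validation_result(FALSE, sprintf(
        "'%s' must be one of {%s}, got '%s'", cde$name,
        paste(d$codes, collapse = ", "), as.character(value)))
    },
    "integer-range" = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v) || v != round(v)) {
        validation_result(FALSE, sprintf("'%s' must be an integer", cde$name))
      } else if (v < d$min || v > d$max) {
        validation_result(FALSE, sprintf(
          "'%s' must lie in [%g, %g], got %g", cde$name, d$min, d$max, v))
      } else if (!is.null(d$step) && ((v - d$min) %% d$step) != 0) {
        validation_result(FALSE, sprintf(
          "'%s' must step by %g from %g", cde$name, d$step, d$min))
      } else validation_result(TRUE)
    },
    "real-range" = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v)) {
        validation_result(FALSE, sprintf("'%s' must be numeric", cde$name))
      } else if (v < d$min || v > d$max) {
        validation_result(FALSE, sprintf(
          "'%s' must lie in [%g, %g], got %g", cde$name, d$min, d$max, v))
      } else if (!is.null(d$step) && ((v - d$min) %% d$step) != 0) {
        validation_result(FALSE, sprintf(
          "'%s' must step by %g from %g", cde$name, d$step, d$min))
      } else validation_result(TRUE)
    },
    "free-text" = {
      v <- as.character(value)
      if (!is.null(d$pattern) &&
          !grepl(paste0("^(?:", d$pattern, ")$"), v, perl = TRUE)) {
        validation_result(FALSE, sprintf(
          "'%s' must match pattern '%s'", cde$name, d$pattern))
      } else validation_result(TRUE)
    }
  )
}

# ---------------------------------------------------------------------------
# Built-in CDE set

#' Load the built-in TMA Common Data Element set
#'
#' Returns a registry holding the toolkit's sixteen TMA data elements: the
#' layout elements describing a recipient block and its core positions, and
#' the scoring elements for the supported immunohistochemistry scoring
#' systems (Allred, percentage staining, HER2 IHC, binary). Where a TMA Data
#' Exchange Specification (TMA DES) tag name exists for an element, it is
#' recorded as an alternative name, so `cde_lookup(reg, "block_identifier")`
#' resolves the recipient-block identifier element.
#'
#' @return A `tma_registry` with 16 CDEs.
#' @examples
#' reg <- load_default_cdes()
#' length(reg)
#' cde_lookup(reg, "slide_identifier")$name
#' @export
load_default_cdes <- function() {
  reg <- cde_registry()
  add <- function(reg, id, name, def, domain, units = "", alt = character()) {
    register_cde(reg, cde_definition(id, name, def, domain, units, alt))
  }
  reg <- add(reg, "CG-TMA-01", "Donor Tissue Block Identifier",
    "Identifier of the donor tissue block from which a core was taken; links a core back to the patient's tissue block without storing patient details.",
    value_domain("free-text"), alt = "core_histo-repository_donor-block")
  reg <- add(reg, "CG-TMA-02", "Tissue Microarray Recipient Block Identifier",
    "Identifier of the recipient block into which donor cores are arrayed.",
    value_domain("free-text"), alt = "block_identifier")
  reg <- add(reg, "CG-TMA-03", "Tissue Microarray Recipient Block Core Diameter",
    "Diameter of the cylindrical cores in the recipient block.",
    value_domain("real-range", min = 0.05, max = 10), units = "mm",
    alt = "block_core_size")
  reg <- add(reg, "CG-TMA-04", "Tissue Microarray Recipient Block Core Spacing",
    "Centre-to-centre spacing of adjacent cores in the recipient block.",
    value_domain("real-range", min = 0.05, max = 20), units = "mm",
    alt = "block_core_spacing")
  reg <- add(reg, "CG-TMA-05", "Tissue Microarray Recipient Block Core Position Used",
    "Indicates a gap in the recipient block where a core has not been inserted.",
    value_domain("enumerated", codes = c("true", "false"),
                 meanings = c("core present", "gap")))
  reg <- add(reg, "CG-TMA-06", "Tissue Microarray Recipient Block Slice Number",
    "Serial section number cut from the recipient block; adjacent slice numbers identify near-identical sections.",
    value_domain("integer-range", min = 1, max = 10000))
  reg <- add(reg, "CG-TMA-07", "Tissue Microarray Recipient Block x coordinate",
    "1-based column index of a core within the recipient block array.",
    value_domain("integer-range", min = 1, max = 10000))
  reg <- add(reg, "CG-TMA-08", "Tissue Microarray Recipient Block y coordinate",
    "1-based row index of a core within the recipient block array.",
    value_domain("integer-range", min = 1, max = 10000))
  reg <- add(reg, "CG-TMA-09", "Tissue Microarray Slide Identifier",
    "Identifier of one slide sectioned from a recipient block.",
    value_domain("free-text"), alt = "slide_identifier")
  reg <- add(reg, "CG-TMA-10", "Tissue Microarray Core Element Identifier",
    "Unique identifier of a core within a recipient block.",
    value_domain("free-text"))
  reg <- add(reg, "CG-TMA-11", "Allred Intensity Score",
    "Staining intensity component of the Allred score: 0 none, 1 weak, 2 intermediate, 3 strong.",
    value_domain("integer-range", min = 0, max = 3))
  reg <- add(reg, "CG-TMA-12", "Allred Proportion Score",
    "Proportion-of-stained-cells component of the Allred score, on the 0-5 logarithmic bin scale.",
    value_domain("integer-range", min = 0, max = 5))
  reg <- add(reg, "CG-TMA-13", "Allred Score for ER status",
    "Composite Allred score (intensity plus proportion); 0 or 2-8. Totals of 3 or more are classified oestrogen-receptor positive.",
    value_domain("integer-range", min = 0, max = 8))
  reg <- add(reg, "CG-TMA-14", "Percentage tissue staining",
    "Percentage of tissue within the core that is stained.",
    value_domain("real-range", min = 0, max = 100), units = "%",
    alt = "core_results_percent-tissue-staining")
  reg <- add(reg, "CG-TMA-15", "HER2 status by immunohistochemistry",
    "HER2 immunohistochemistry category.",
    value_domain("enumerated", codes = c("0", "1+", "2+", "3+"),
                 meanings = c("negative", "negative", "equivocal", "positive")))
  reg <- add(reg, "CG-TMA-16", "Binary biomarker staining result",
    "Binary value indicating whether the tissue is positively or negatively stained for a particular marker.",
    value_domain("enumerated", codes = c("positive", "negative")))
  reg
}

# ---------------------------------------------------------------------------
# XML serialization (project dialect, ISO/IEC 11179-flavoured)

REGISTRY_NS <- "urn:tmakit:registry"

domain_to_xml <- function(parent, d) {
  vd <- xml2::xml_add_child(parent, "valueDomain", kind = d$kind)
  if (d$kind == "enumerated") {
    for (i in seq_along(d$codes)) {
      xml2::xml_add_child(vd, "value", d$meanings[[i]], code = d$codes[[i]])
    }
  } else if (d$kind %in% c("integer-range", "real-range")) {
    rng <- xml2::xml_add_child(vd, "range",
                               min = num_str(d$min),
                               max = num_str(d$max))
    if (!is.null(d$step)) xml2::xml_attr(rng, "step") <- num_str(d$step)
  } else if (!is.null(d$pattern)) {
    xml2::xml_add_child(vd, "pattern", d$pattern)
  }
  invisible(vd)
}

domain_from_xml <- function(node, path) {
  kind <- xml2::xml_attr(node, "kind")
  if (is.na(kind)) stop_tma("parse error at %s/valueDomain: missing 'kind'", path)
  if (kind == "enumerated") {
    vals <- xml2::xml_find_all(node, "./*[local-name()='value']")
    if (!length(vals)) {
      stop_tma("parse error at %s/valueDomain: enumerated domain with no values", path)
    }
    value_domain("enumerated",
                 codes = xml2::xml_attr(vals, "code"),
                 meanings = xml2::xml_text(vals))
  } else if (kind %in% c("integer-range", "real-range")) {
    rng <- xml2::xml_find_first(node, "./*[local-name()='range']")
    if (inherits(rng, "xml_missing")) {
      stop_tma("parse error at %s/valueDomain: missing range element", path)
    }
    step <- xml2::xml_attr(rng, "step")
    value_domain(kind,
                 min = as.numeric(xml2::xml_attr(rng, "min")),
                 max = as.numeric(xml2::xml_attr(rng, "max")),
                 step = if (!is.na(step)) as.numeric(step))
  } else if (kind == "free-text") {
    pat <- xml2::xml_find_first(node, "./*[local-name()='pattern']")
    value_domain("free-text",
                 pattern = if (!inherits(pat, "xml_missing")) xml2::xml_text(pat))
  } else {
    stop_tma("parse error at %s/valueDomain: unknown kind '%s'", path, kind)
  }
}

#' Serialize a CDE registry to XML
#'
#' Writes the registry in the toolkit's metadata-registry dialect
#' (`metadataRegistry`/`dataElement` elements with `name`, `definition`,
#' `unit`, `alternativeName` and `valueDomain` children), UTF-8 encoded.
#'
#' @param registry A `tma_registry`.
#' @param path Optional file path; when given, the document is written there.
#' @return An `xml2::xml_document` (invisibly when `path` is given).
#' @seealso [parse_registry()]
#' @export
serialize_registry <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "tma_registry"))
  doc <- xml2::xml_new_root("metadataRegistry", xmlns = REGISTRY_NS)
  for (cde in registry$cdes) {
    el <- xml2::xml_add_child(doc, "dataElement", identifier = cde$identifier)
    xml2::xml_add_child(el, "name", cde$name)
    xml2::xml_add_child(el, "definition", cde$definition)
    xml2::xml_add_child(el, "unit", cde$units)
    for (alt in cde$alternative_names) {
      xml2::xml_add_child(el, "alternativeName", alt)
    }
    domain_to_xml(el, cde$domain)
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Parse a CDE registry from XML
#'
#' Inverse of [serialize_registry()]: `parse_registry(serialize_registry(r))`
#' reproduces `r` field for field. Malformed documents and missing mandatory
#' fields raise errors naming the offending element path.
#'
#' @param x A file path, XML string, or `xml2::xml_document`.
#' @return A `tma_registry`.
#' @export
parse_registry <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "metadataRegistry") {
    stop_tma("parse error at /: expected metadataRegistry, found %s",
             xml2::xml_name(root))
  }
  reg <- cde_registry()
  els <- xml2::xml_find_all(root, "./*[local-name()='dataElement']")
  for (i in seq_along(els)) {
    el <- els[[i]]
    path <- sprintf("/metadataRegistry/dataElement[%d]", i)
    identifier <- xml2::xml_attr(el, "identifier")
    if (is.na(identifier) || !nzchar(identifier)) {
      stop_tma("parse error at %s: missing identifier attribute", path)
    }
    get1 <- function(tag) {
      xml2::xml_find_first(el, sprintf("./*[local-name()='%s']", tag))
    }
    name_node <- get1("name")
    if (inherits(name_node, "xml_missing") || !nzchar(xml2::xml_text(name_node))) {
      stop_tma("parse error at %s/name: missing or empty name", path)
    }
    dom_node <- get1("valueDomain")
    if (inherits(dom_node, "xml_missing")) {
      stop_tma("parse error at %s/valueDomain: missing value domain", path)
    }
    def_node <- get1("definition")
    unit_node <- get1("unit")
    alts <- xml2::xml_find_all(el, "./*[local-name()='alternativeName']")
    cde <- cde_definition(
      identifier = identifier,
      name = xml2::xml_text(name_node),
      definition = if (inherits(def_node, "xml_missing")) "" else xml2::xml_text(def_node),
      domain = domain_from_xml(dom_node, path),
      units = if (inherits(unit_node, "xml_missing")) "" else xml2::xml_text(unit_node),
      alternative_names = xml2::xml_text(alts)
    )
    reg <- register_cde(reg, cde)
  }
  reg
}
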