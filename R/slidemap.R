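#' Describe a TMA recipient block
#'
#' The recipient block is the arrayed paraffin block that donor cores are
#' punched into. Its geometry (grid size, core diameter and spacing) and the
#' serial slice number of the section on a slide are the layout metadata the
#' toolkit tracks.
#'
#' @param block_id Block identifier (non-empty string).
#' @param n_cols,n_rows Grid dimensions (positive integers).
#' @param core_diameter Core diameter in mm (> 0).
#' @param core_spacing Centre-to-centre core spacing in mm (> 0).
#' @param slice_number Serial section number (positive integer).
#' @return An object of class `tma_recipient_block`.
#' @export
recipient_block <- function(block_id, n_cols, n_rows,
                            core_diameter = 0.6, core_spacing = 1.0,
                            slice_number = 1L) {
  assert_nonempty_string(block_id, "block_id")
  n_cols <- assert_count(n_cols, "n_cols")
  n_rows <- assert_count(n_rows, "n_rows")
  slice_number <- assert_count(slice_number, "slice_number")
  if (!is.numeric(core_diameter) || core_diameter <= 0) {
    stop_tma("core_diameter must be > 0")
  }
  if (!is.numeric(core_spacing) || core_spacing <= 0) {
    stop_tma("core_spacing must be > 0")
  }
  structure(
    list(block_id = block_id, n_cols = n_cols, n_rows = n_rows,
         core_diameter = as.numeric(core_diameter),
         core_spacing = as.numeric(core_spacing),
         slice_number = slice_number),
    class = "tma_recipient_block"
  )
}

CORE_KINDS <- c("tissue", "marker", "empty")

#' Construct one core position record
#'
#' One cell of a recipient-block grid. `used` is derived from `kind`: gaps
#' (`"empty"`) are unused, tissue and orientation-marker cores are used, and
#' a tissue core must name its donor block.
#'
#' @param x,y 1-based column and row indices.
#' @param donor_block_id Donor block identifier (tissue cores only).
#' @param kind `"tissue"`, `"marker"` or `"empty"`.
#' @return A list with fields `x`, `y`, `donor_block_id`, `kind`, `used`.
#' @export
core_position <- function(x, y, donor_block_id = "", kind = "tissue") {
  x <- assert_count(x, "x"); y <- assert_count(y, "y")
  if (!kind %in% CORE_KINDS) stop_tma("kind must be one of %s",
                                      paste(CORE_KINDS, collapse = ", "))
  if (kind == "tissue" && !nzchar(donor_block_id)) {
    stop_tma("a tissue core at (%d, %d) needs a donor_block_id", x, y)
  }
  if (kind != "tissue") donor_block_id <- ""
  list(x = x, y = y, donor_block_id = donor_block_id,
       kind = kind, used = kind != "empty")
}

positions_df <- function(pos_list) {
  if (!length(pos_list)) {
    return(data.frame(x = integer(), y = integer(),
                      donor_block_id = character(), kind = character(),
                      used = logical(), stringsAsFactors = FALSE))
  }
  data.frame(
    x = vapply(pos_list, `[[`, 0L, "x"),
    y = vapply(pos_list, `[[`, 0L, "y"),
    donor_block_id = vapply(pos_list, `[[`, "", "donor_block_id"),
    kind = vapply(pos_list, `[[`, "", "kind"),
    used = vapply(pos_list, `[[`, TRUE, "used"),
    stringsAsFactors = FALSE
  )
}

#' Construct a slidemap
#'
#' A slidemap binds a slide identifier and stain (marker) name to a recipient
#' block layout: the grid of core positions linking array coordinates
#' `(x, y)` (x = column, y = row, both 1-based, origin top-left) to donor
#' block identifiers. Positions of kind `"marker"` are orientation cores;
#' `"empty"` marks a gap where no core was inserted.
#'
#' @param slide_id Slide identifier (non-empty).
#' @param block A [recipient_block()].
#' @param positions A data frame with columns `x`, `y`, `donor_block_id`,
#'   `kind`, `used`, or a list of position records.
#' @param marker_name Stain/biomarker assessed on this slide.
#' @return An object of class `tma_slidemap`.
#' @export
slidemap <- function(slide_id, block, positions, marker_name = "") {
  assert_nonempty_string(slide_id, "slide_id")
  stopifnot(inherits(block, "tma_recipient_block"))
  if (!is.data.frame(positions)) positions <- positions_df(positions)
  if (nrow(positions)) {
    if (any(positions$x < 1 | positions$x > block$n_cols |
            positions$y < 1 | positions$y > block$n_rows)) {
      bad <- which(positions$x < 1 | positions$x > block$n_cols |
                   positions$y < 1 | positions$y > block$n_rows)[1L]
      stop_tma("core at (%d, %d) lies outside the %dx%d grid",
               positions$x[bad], positions$y[bad], block$n_cols, block$n_rows)
    }
    key <- paste(positions$x, positions$y)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop_tma("duplicate core position at (%s)", sub(" ", ", ", dup))
    }
    bad_kind <- !positions$kind %in% CORE_KINDS
    if (any(bad_kind)) stop_tma("unknown core kind '%s'", positions$kind[bad_kind][1L])
    if (any(positions$kind == "tissue" & !nzchar(positions$donor_block_id))) {
      stop_tma("tissue cores must carry a donor_block_id")
    }
    positions$used <- positions$kind != "empty"
    positions <- positions[order(positions$y, positions$x), , drop = FALSE]
    rownames(positions) <- NULL
  }
  structure(
    list(slide_id = slide_id, block = block, positions = positions,
         marker_name = as.character(marker_name)),
    class = "tma_slidemap"
  )
}

#' @export
print.tma_slidemap <- function(x, ...) {
  cat(sprintf("<tma_slidemap '%s' (%s): %dx%d grid, %d positions (%d used)>\n",
              x$slide_id, if (nzchar(x$marker_name)) x$marker_name else "no marker",
              x$block$n_cols, x$block$n_rows,
              nrow(x$positions), sum(x$positions$used)))
  invisible(x)
}

#' Build a slidemap from a tabular layout
#'
#' Converts the grid-of-cells layout convention used in spreadsheet layout
#' files into a slidemap: cell `(row r, column c)` becomes the position
#' `(x = c, y = r)`. An empty cell is a gap (`kind = "empty"`), the sentinel
#' `"MARKER"` (case-insensitive) is an orientation core, and any other string
#' is a donor block identifier. The same donor identifier may appear in
#' several cells (replicate cores).
#'
#' @param rows A character matrix, a data frame of character cells, or a list
#'   of equal-length character vectors (one per grid row).
#' @param block A [recipient_block()]; the grid must fit within it.
#' @param slide_id Slide identifier.
#' @param marker_name Stain name for the slide.
#' @return A [slidemap()].
#' @examples
#' blk <- recipient_block("B1", 3, 3)
#' cells <- matrix(c("D1", "D2", "D3", "", "MARKER", "D4", "D5", "D5", "D6"),
#'                 nrow = 3, byrow = TRUE)
#' parse_layout_table(cells, blk, "S1", "ER")
#' @export
parse_layout_table <- function(rows, block, slide_id, marker_name = "") {
  stopifnot(inherits(block, "tma_recipient_block"))
  if (is.data.frame(rows)) {
    rows <- as.matrix(rows)
    rows[] <- as.character(rows)
  }
  if (is.list(rows) && !is.matrix(rows)) {
    widths <- lengths(rows)
    if (length(unique(widths)) > 1L) {
      bad <- which(widths != widths[1L])[1L]
      stop_tma("ragged layout: row %d has %d cells, expected %d",
               bad, widths[bad], widths[1L])
    }
    rows <- do.call(rbind, lapply(rows, as.character))
  }
  if (!is.matrix(rows)) stop_tma("rows must be a matrix, data frame or list of rows")
  mode(rows) <- "character"
  rows[is.na(rows)] <- ""
  nr <- nrow(rows); nc <- ncol(rows)
  if (nc > block$n_cols || nr > block$n_rows) {
    stop_tma("layout grid %dx%d exceeds block dimensions %dx%d",
             nc, nr, block$n_cols, block$n_rows)
  }
  pos <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      cell <- trimws(rows[r, c])
      k <- k + 1L
      pos[[k]] <- if (!nzchar(cell)) {
        core_position(c, r, kind = "empty")
      } else if (toupper(cell) == "MARKER") {
        core_position(c, r, kind = "marker")
      } else {
        core_position(c, r, donor_block_id = cell, kind = "tissue")
      }
    }
  }
  slidemap(slide_id, block, pos, marker_name)
}

#' Read a layout CSV into a slidemap
#'
#' One CSV file describes one block: each row of cells is one array row, per
#' the [parse_layout_table()] conventions. Ragged rows are an error naming
#' the offending row.
#'
#' @param path CSV file path.
#' @param block A [recipient_block()].
#' @param slide_id Slide identifier.
#' @param marker_name Stain name.
#' @param header Whether the first line is a header to skip.
#' @return A [slidemap()].
#' @export
read_layout_csv <- function(path, block, slide_id, marker_name = "",
                            header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_tma("layout file '%s' has no data rows", path)
  cells <- lapply(lines, function(l) scan(text = l, what = "", sep = ",",
                                          quiet = TRUE, strip.white = TRUE,
                                          blank.lines.skip = FALSE))
  widths <- lengths(cells)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop_tma("ragged layout in '%s': row %d has %d cells, expected %d",
             path, bad + if (header) 1L else 0L, widths[bad], widths[1L])
  }
  parse_layout_table(cells, block, slide_id, marker_name)
}

#' Render a slidemap back to its layout table
#'
#' Inverse of [parse_layout_table()] on cell contents: tissue cells hold the
#' donor block identifier, marker cells the sentinel `"MARKER"`, gaps and
#' unmapped positions the empty string.
#'
#' @param map A [slidemap()].
#' @return A character matrix of `n_rows` x `n_cols` cells.
#' @export
layout_table <- function(map) {
  stopifnot(inherits(map, "tma_slidemap"))
  out <- matrix("", nrow = map$block$n_rows, ncol = map$block$n_cols)
  p <- map$positions
  for (i in seq_len(nrow(p))) {
    out[p$y[i], p$x[i]] <- switch(p$kind[i],
                                  tissue = p$donor_block_id[i],
                                  marker = "MARKER",
                                  empty = "")
  }
  out
}

#' Retrieve the core position at grid coordinates
#'
#' @param map A [slidemap()].
#' @param x,y 1-based column and row indices; must lie within the block grid.
#' @return The position record (a list with `x`, `y`, `donor_block_id`,
#'   `kind`, `used`), or `NULL` when the map carries no entry at `(x, y)`.
#' @export
core_at <- function(map, x, y) {
  stopifnot(inherits(map, "tma_slidemap"))
  x <- assert_count(x, "x"); y <- assert_count(y, "y")
  if (x > map$block$n_cols || y > map$block$n_rows) {
    stop_tma("(%d, %d) is outside the %dx%d grid (coordinates are 1-based)",
             x, y, map$block$n_cols, map$block$n_rows)
  }
  i <- which(map$positions$x == x & map$positions$y == y)
  if (!length(i)) return(NULL)
  as.list(map$positions[i, , drop = FALSE])
}

#' Index tissue cores by donor block
#'
#' Builds the donor-to-core index that lets all cores punched from one donor
#' block (i.e. one patient's tissue) be found across slides stained for
#' different biomarkers.
#'
#' @param maps A [slidemap()] or a list of them.
#' @return A data frame with columns `donor_block_id`, `slide_id`, `x`, `y`,
#'   one row per tissue core.
#' @export
donor_index <- function(maps) {
  if (inherits(maps, "tma_slidemap")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    p <- m$positions[m$positions$kind == "tissue", , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(donor_block_id = p$donor_block_id, slide_id = m$slide_id,
               x = p$x, y = p$y, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(donor_block_id = character(), slide_id = character(),
                      x = integer(), y = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$donor_block_id, out$slide_id, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Slidemap XML dialect. Element names reuse the TMA DES tag vocabulary of the
# built-in CDE set (slide_identifier, block_identifier, block_core_size,
# block_core_spacing, core_histo-repository_donor-block) for interoperability.

SLIDEMAP_NS <- "urn:tmakit:slidemap"

#' Write a slidemap as XML
#'
#' @param map A [slidemap()].
#' @param path Optional output file path.
#' @return An `xml2::xml_document` (invisibly when `path` is given).
#' @seealso [parse_slidemap_xml()]
#' @export
write_slidemap_xml <- function(map, path = NULL) {
  stopifnot(inherits(map, "tma_slidemap"))
  doc <- xml2::xml_new_root("slidemap", xmlns = SLIDEMAP_NS)
  xml2::xml_add_child(doc, "slide_identifier", map$slide_id)
  xml2::xml_add_child(doc, "marker", map$marker_name)
  blk <- xml2::xml_add_child(doc, "recipientBlock")
  b <- map$block
  xml2::xml_add_child(blk, "block_identifier", b$block_id)
  xml2::xml_add_child(blk, "block_core_size", num_str(b$core_diameter),
                      unit = "mm")
  xml2::xml_add_child(blk, "block_core_spacing", num_str(b$core_spacing),
                      unit = "mm")
  xml2::xml_add_child(blk, "columns", as.character(b$n_cols))
  xml2::xml_add_child(blk, "rows", as.character(b$n_rows))
  xml2::xml_add_child(blk, "sliceNumber", as.character(b$slice_number))
  cores <- xml2::xml_add_child(doc, "cores")
  p <- map$positions
  for (i in seq_len(nrow(p))) {
    core <- xml2::xml_add_child(cores, "core",
                                x = as.character(p$x[i]),
                                y = as.character(p$y[i]),
                                kind = p$kind[i],
                                used = tolower(as.character(p$used[i])))
    if (p$kind[i] == "tissue") {
      xml2::xml_add_child(core, "core_histo-repository_donor-block",
                          p$donor_block_id[i])
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Parse a slidemap from XML
#'
#' Inverse of [write_slidemap_xml()]. Coordinates outside the declared grid
#' and duplicate positions are parse errors; a missing `sliceNumber` defaults
#' to 1 with a warning.
#'
#' @param x A file path, XML string, or `xml2::xml_document`.
#' @return A [slidemap()].
#' @export
parse_slidemap_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "slidemap") {
    stop_tma("parse error at /: expected slidemap, found %s", xml2::xml_name(root))
  }
  f1 <- function(node, tag) xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", tag))
  txt <- function(node, tag, path) {
    n <- f1(node, tag)
    if (inherits(n, "xml_missing")) stop_tma("parse error at %s: missing <%s>", path, tag)
    xml2::xml_text(n)
  }
  slide_id <- txt(root, "slide_identifier", "/slidemap")
  marker_node <- f1(root, "marker")
  marker <- if (inherits(marker_node, "xml_missing")) "" else xml2::xml_text(marker_node)
  blk_node <- f1(root, "recipientBlock")
  if (inherits(blk_node, "xml_missing")) {
    stop_tma("parse error at /slidemap: missing <recipientBlock>")
  }
  slice_node <- f1(blk_node, "sliceNumber")
  if (inherits(slice_node, "xml_missing")) {
    warning("slidemap '", slide_id, "': missing sliceNumber, defaulting to 1",
            call. = FALSE)
    slice <- 1L
  } else {
    slice <- as.integer(xml2::xml_text(slice_node))
  }
  block <- recipient_block(
    block_id = txt(blk_node, "block_identifier", "/slidemap/recipientBlock"),
    n_cols = as.integer(txt(blk_node, "columns", "/slidemap/recipientBlock")),
    n_rows = as.integer(txt(blk_node, "rows", "/slidemap/recipientBlock")),
    core_diameter = as.numeric(txt(blk_node, "block_core_size", "/slidemap/recipientBlock")),
    core_spacing = as.numeric(txt(blk_node, "block_core_spacing", "/slidemap/recipientBlock")),
    slice_number = slice
  )
  core_nodes <- xml2::xml_find_all(root, ".//*[local-name()='cores']/*[local-name()='core']")
  pos <- vector("list", length(core_nodes))
  for (i in seq_along(core_nodes)) {
    node <- core_nodes[[i]]
    cx <- as.integer(xml2::xml_attr(node, "x"))
    cy <- as.integer(xml2::xml_attr(node, "y"))
    if (is.na(cx) || is.na(cy)) {
      stop_tma("parse error at /slidemap/cores/core[%d]: missing x/y attribute", i)
    }
    kind <- xml2::xml_attr(node, "kind")
    if (is.na(kind)) kind <- "tissue"
    donor_node <- f1(node, "core_histo-repository_donor-block")
    donor <- if (inherits(donor_node, "xml_missing")) "" else xml2::xml_text(donor_node)
    pos[[i]] <- core_position(cx, cy, donor_block_id = donor, kind = kind)
  }
  tryCatch(
    slidemap(slide_id, block, pos, marker),
    error = function(e) stop_tma("parse error in /slidemap/cores: %s", conditionMessage(e))
  )
}
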