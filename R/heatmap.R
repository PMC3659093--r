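#' Heatmap rendering specification
#'
#' Colour conventions for the slide heatmap: score values map to colours (the
#' 0-3 intensity legend by default: 0 pale yellow, 1 intense yellow, 2 pale
#' blue, 3 intense blue), marker cores are grey, no-tumour cores pink,
#' unscored cells white, and the current position is outlined in black.
#' Values of systems beyond the 0-3 legend (e.g. Allred totals, percentages)
#' interpolate linearly between the pale-yellow and intense-blue endpoints
#' over `domain_range`.
#'
#' @param colour_map Named list mapping score values (as strings) to RGB
#'   integer triples.
#' @param marker_colour,no_tumour_colour,unscored_colour,current_outline_colour
#'   RGB integer triples.
#' @param cell_px Cell edge in pixels (>= 4).
#' @param domain_range Numeric `c(min, max)` of admissible score values.
#' @return An object of class `tma_heatmap_spec`.
#' @export
heatmap_spec <- function(colour_map = list(
                           "0" = c(255L, 255L, 204L),  # pale yellow
                           "1" = c(255L, 215L, 0L),    # intense yellow
                           "2" = c(173L, 216L, 230L),  # pale blue
                           "3" = c(0L, 0L, 205L)),     # intense blue
                         marker_colour = c(128L, 128L, 128L),
                         no_tumour_colour = c(255L, 192L, 203L),
                         unscored_colour = c(255L, 255L, 255L),
                         current_outline_colour = c(0L, 0L, 0L),
                         cell_px = 16L,
                         domain_range = c(0, 3)) {
  cell_px <- assert_count(cell_px, "cell_px", min = 4L)
  check_rgb <- function(v, what) {
    if (!is.numeric(v) || length(v) != 3L || any(v < 0) || any(v > 255)) {
      stop_tma("%s must be an RGB triple in 0..255", what)
    }
    as.integer(v)
  }
  colour_map <- lapply(colour_map, check_rgb, what = "colour_map entry")
  if (!is.numeric(domain_range) || length(domain_range) != 2L ||
      domain_range[1] > domain_range[2]) {
    stop_tma("domain_range must be c(min, max) with min <= max")
  }
  structure(
    list(colour_map = colour_map,
         marker_colour = check_rgb(marker_colour, "marker_colour"),
         no_tumour_colour = check_rgb(no_tumour_colour, "no_tumour_colour"),
         unscored_colour = check_rgb(unscored_colour, "unscored_colour"),
         current_outline_colour = check_rgb(current_outline_colour,
                                            "current_outline_colour"),
         cell_px = cell_px, domain_range = as.numeric(domain_range)),
    class = "tma_heatmap_spec"
  )
}

#' Map a score value or cell status to its heatmap colour
#'
#' @param value Score value (ignored when `status` is given).
#' @param spec A [heatmap_spec()].
#' @param status Optional cell status: `"marker"`, `"no_tumour"` or
#'   `"unscored"`.
#' @return An RGB integer triple.
#' @examples
#' score_to_colour(3, heatmap_spec())           # intense blue
#' score_to_colour(status = "marker", spec = heatmap_spec())
#' @export
score_to_colour <- function(value = NULL, spec = heatmap_spec(), status = NULL) {
  stopifnot(inherits(spec, "tma_heatmap_spec"))
  if (!is.null(status)) {
    return(switch(status,
                  marker = spec$marker_colour,
                  no_tumour = spec$no_tumour_colour,
                  unscored = spec$unscored_colour,
                  stop_tma("unknown cell status '%s'", status)))
  }
  if (is.null(value)) stop_tma("either value or status must be supplied")
  key <- as.character(value)
  if (key %in% names(spec$colour_map)) return(spec$colour_map[[key]])
  v <- suppressWarnings(as.numeric(value))
  rng <- spec$domain_range
  if (is.na(v) || v < rng[1] || v > rng[2]) {
    stop_tma("score value '%s' lies outside the domain [%g, %g]",
             as.character(value), rng[1], rng[2])
  }
  # linear interpolation between the legend endpoints
  lo <- c(255, 255, 204); hi <- c(0, 0, 205)
  t <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  as.integer(round_half_up(lo + (hi - lo) * t))
}

latest_by_cell <- function(scores) {
  scores <- latest_scores(scores)
  if (!length(scores)) return(list())
  keys <- vapply(scores, function(r) paste(r$x, r$y), "")
  stats::setNames(scores, keys)
}

#' Render a slide heatmap
#'
#' Draws one uniformly coloured cell per grid position: marker cores grey,
#' no-tumour cores pink, scored cores coloured by the latest recorded value
#' of `field`, everything else the unscored colour. When `current` is given,
#' that cell's border pixels are overdrawn with the current-position outline
#' colour (the "black square" progress cursor).
#'
#' @param map A [slidemap()].
#' @param scores A list of [score_record()]s for the slide (all versions;
#'   the latest per core wins).
#' @param current Optional `c(x, y)` of the core currently being scored.
#' @param spec A [heatmap_spec()].
#' @param field Which score field drives the colour (default `"intensity"`).
#' @return An object of class `tma_heatmap`: `pixels` (integer RGB array),
#'   `svg` (SVG text), and `cells` (per-cell colour/class table).
#' @export
render_heatmap <- function(map, scores = list(), current = NULL,
                           spec = heatmap_spec(), field = "intensity") {
  stopifnot(inherits(map, "tma_slidemap"))
  nc <- map$block$n_cols; nr <- map$block$n_rows
  cp <- spec$cell_px
  if (!is.null(current)) {
    if (length(current) != 2L || current[1] < 1 || current[1] > nc ||
        current[2] < 1 || current[2] > nr) {
      stop_tma("current position (%s) is outside the %dx%d grid",
               paste(current, collapse = ", "), nc, nr)
    }
  }
  by_cell <- latest_by_cell(scores)
  cells <- data.frame(x = integer(), y = integer(), class = character(),
                      value = character(), stringsAsFactors = FALSE)
  px <- array(0L, dim = c(nr * cp, nc * cp, 3L))
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      pos <- core_at(map, x, y)
      rec <- by_cell[[paste(x, y)]]
      if (!is.null(pos) && pos$kind == "marker") {
        cls <- "marker"; val <- ""
        col <- score_to_colour(status = "marker", spec = spec)
      } else if (!is.null(rec) && rec$status == "no_tumour") {
        cls <- "no_tumour"; val <- ""
        col <- score_to_colour(status = "no_tumour", spec = spec)
      } else if (!is.null(rec) && field %in% names(rec$values)) {
        cls <- "scored"; val <- as.character(rec$values[[field]])
        col <- score_to_colour(rec$values[[field]], spec)
      } else {
        cls <- "unscored"; val <- ""
        col <- score_to_colour(status = "unscored", spec = spec)
      }
      rr <- ((y - 1L) * cp + 1L):(y * cp)
      cc <- ((x - 1L) * cp + 1L):(x * cp)
      for (ch in 1:3) px[rr, cc, ch] <- col[ch]
      cells <- rbind(cells, data.frame(x = x, y = y, class = cls, value = val,
                                       stringsAsFactors = FALSE))
    }
  }
  if (!is.null(current)) {
    cx <- as.integer(current[1]); cy <- as.integer(current[2])
    rr <- ((cy - 1L) * cp + 1L):(cy * cp)
    cc <- ((cx - 1L) * cp + 1L):(cx * cp)
    oc <- spec$current_outline_colour
    for (ch in 1:3) {
      px[rr[1], cc, ch] <- oc[ch]; px[rr[cp], cc, ch] <- oc[ch]
      px[rr, cc[1], ch] <- oc[ch]; px[rr, cc[cp], ch] <- oc[ch]
    }
  }
  structure(
    list(pixels = px, cells = cells,
         svg = heatmap_svg(cells, spec, nc, nr, current)),
    class = "tma_heatmap"
  )
}

heatmap_svg <- function(cells, spec, n_cols, n_rows, current) {
  cp <- spec$cell_px
  rgbhex <- function(col) sprintf("#%02x%02x%02x", col[1], col[2], col[3])
  rects <- vapply(seq_len(nrow(cells)), function(i) {
    col <- switch(cells$class[i],
                  marker = spec$marker_colour,
                  no_tumour = spec$no_tumour_colour,
                  unscored = spec$unscored_colour,
                  scored = score_to_colour(cells$value[i], spec))
    sprintf('  <rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
            (cells$x[i] - 1L) * cp, (cells$y[i] - 1L) * cp, cp, cp, rgbhex(col))
  }, "")
  cursor <- if (!is.null(current)) {
    sprintf(paste0('  <rect x="%d" y="%d" width="%d" height="%d" fill="none" ',
                   'stroke="%s" stroke-width="1"/>'),
            (as.integer(current[1]) - 1L) * cp, (as.integer(current[2]) - 1L) * cp,
            cp, cp, rgbhex(spec$current_outline_colour))
  } else character()
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                  n_cols * cp, n_rows * cp),
          rects, cursor, "</svg>"),
        collapse = "\n")
}

#' Write a rendered heatmap to PNG and/or SVG
#'
#' @param heatmap A `tma_heatmap` from [render_heatmap()].
#' @param png_path,svg_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_heatmap <- function(heatmap, png_path = NULL, svg_path = NULL) {
  stopifnot(inherits(heatmap, "tma_heatmap"))
  if (!is.null(png_path)) png::writePNG(heatmap$pixels / 255, target = png_path)
  if (!is.null(svg_path)) writeLines(heatmap$svg, svg_path)
  invisible(c(png_path, svg_path))
}

#' Compare two scorers' heatmaps for discrepancies
#'
#' Side-by-side comparison of two users' scores on the same slide, the review
#' mode used to investigate discrepant scores and slide defects. A cell is
#' *compared* when both scorers have scored it (latest versions), and
#' *discrepant* when their values for `field` differ (or their no-tumour
#' statuses disagree).
#'
#' @param map A [slidemap()].
#' @param scores_a,scores_b Score record lists for the two scorers.
#' @param field Field compared (default `"intensity"`).
#' @return An object of class `tma_discrepancy`: `cells` (data frame of
#'   compared cells with `value_a`, `value_b`, `discrepant`), `n_compared`,
#'   `n_discrepant`.
#' @export
compare_scorers <- function(map, scores_a, scores_b, field = "intensity") {
  stopifnot(inherits(map, "tma_slidemap"))
  a <- latest_by_cell(scores_a)
  b <- latest_by_cell(scores_b)
  common <- intersect(names(a), names(b))
  cell_value <- function(rec) {
    if (rec$status == "no_tumour") "no_tumour"
    else as.character(rec$values[[field]] %||% NA_character_)
  }
  rows <- lapply(common, function(k) {
    ra <- a[[k]]; rb <- b[[k]]
    va <- cell_value(ra); vb <- cell_value(rb)
    data.frame(x = ra$x, y = ra$y, value_a = va, value_b = vb,
               discrepant = !identical(va, vb), stringsAsFactors = FALSE)
  })
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = integer(), y = integer(), value_a = character(),
               value_b = character(), discrepant = logical(),
               stringsAsFactors = FALSE)
  cells <- cells[order(cells$y, cells$x), , drop = FALSE]
  rownames(cells) <- NULL
  structure(
    list(cells = cells, n_compared = nrow(cells),
         n_discrepant = sum(cells$discrepant)),
    class = "tma_discrepancy"
  )
}

#' @export
print.tma_discrepancy <- function(x, ...) {
  cat(sprintf("<tma_discrepancy: %d of %d compared cells discrepant>\n",
              x$n_discrepant, x$n_compared))
  invisible(x)
}

#' Render a discrepancy report as a heatmap
#'
#' A third heatmap highlighting disagreement: compared cells are drawn green
#' when the two scorers agree and red when they differ; uncompared cells stay
#' in the unscored colour and marker cores grey.
#'
#' @param map A [slidemap()].
#' @param report A `tma_discrepancy` from [compare_scorers()].
#' @param spec A [heatmap_spec()].
#' @param agree_colour,discrepant_colour RGB triples.
#' @return A `tma_heatmap`-style object with `pixels` and `cells`.
#' @export
render_discrepancy <- function(map, report, spec = heatmap_spec(),
                               agree_colour = c(144L, 238L, 144L),
                               discrepant_colour = c(220L, 20L, 60L)) {
  stopifnot(inherits(map, "tma_slidemap"), inherits(report, "tma_discrepancy"))
  nc <- map$block$n_cols; nr <- map$block$n_rows
  cp <- spec$cell_px
  px <- array(0L, dim = c(nr * cp, nc * cp, 3L))
  key <- paste(report$cells$x, report$cells$y)
  cells <- data.frame(x = integer(), y = integer(), class = character(),
                      stringsAsFactors = FALSE)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      pos <- core_at(map, x, y)
      i <- match(paste(x, y), key)
      if (!is.null(pos) && pos$kind == "marker") {
        cls <- "marker"; col <- spec$marker_colour
      } else if (!is.na(i)) {
        if (report$cells$discrepant[i]) {
          cls <- "discrepant"; col <- as.integer(discrepant_colour)
        } else {
          cls <- "agree"; col <- as.integer(agree_colour)
        }
      } else {
        cls <- "uncompared"; col <- spec$unscored_colour
      }
      rr <- ((y - 1L) * cp + 1L):(y * cp)
      cc <- ((x - 1L) * cp + 1L):(x * cp)
      for (ch in 1:3) px[rr, cc, ch] <- col[ch]
      cells <- rbind(cells, data.frame(x = x, y = y, class = cls,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(pixels = px, cells = cells, svg = NULL), class = "tma_heatmap")
}
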