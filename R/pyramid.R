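#' Number of Deep Zoom pyramid levels
#'
#' A Deep Zoom pyramid stores an image at every power-of-two scale from the
#' full resolution down to 1x1, each level obtained from the next by halving
#' with ceiling dimensions. The number of levels is
#' `ceil(log2(max(width, height))) + 1`; level index 0 is the 1x1 level and
#' the top index is full resolution.
#'
#' @param width,height Source image dimensions (>= 1).
#' @return Integer level count.
#' @examples
#' num_pyramid_levels(1024, 768)  # 11
#' @export
num_pyramid_levels <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) || width < 1 || height < 1) {
    stop_tma("width and height must be >= 1")
  }
  # integer halving avoids log2 floating-point edge cases at exact powers of 2
  m <- max(as.integer(width), as.integer(height))
  levels <- 1L
  while (m > 1L) {
    m <- (m + 1L) %/% 2L
    levels <- levels + 1L
  }
  levels
}

#' Dimensions of one pyramid level
#'
#' Applies ceiling halving `(max_level - level)` times to the full-size
#' dimensions, where `max_level = num_pyramid_levels(w, h) - 1`.
#'
#' @param width,height Full-resolution dimensions.
#' @param level Level index in `0..max_level`.
#' @return Integer vector `c(w, h)` of the level's dimensions.
#' @export
level_dimensions <- function(width, height, level) {
  max_level <- num_pyramid_levels(width, height) - 1L
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > max_level) {
    stop_tma("level must lie in 0..%d", max_level)
  }
  w <- as.integer(width); h <- as.integer(height)
  for (i in seq_len(max_level - as.integer(level))) {
    w <- (w + 1L) %/% 2L
    h <- (h + 1L) %/% 2L
  }
  c(w, h)
}

#' Halve an image by 2x2 box averaging
#'
#' Each output pixel is the mean of the 2x2 input block it covers, rounded
#' half-up to 8 bits; at odd edges the mean runs over the available pixels
#' only (ceiling dimensions). Flat fields are preserved exactly.
#'
#' @param pixels An `H x W x 3` integer pixel array.
#' @return The `ceil(H/2) x ceil(W/2) x 3` downsampled array.
#' @export
downsample_box2 <- function(pixels) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  gr <- ceiling(seq_len(h) / 2)
  gc <- ceiling(seq_len(w) / 2)
  nr <- max(gr); nc <- max(gc)
  cnt <- tabulate(gr, nr) %o% tabulate(gc, nc)
  out <- array(0L, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    m <- matrix(pixels[, , ch], h, w)
    s <- rowsum(m, gr, reorder = TRUE)
    s <- t(rowsum(t(s), gc, reorder = TRUE))
    out[, , ch] <- as.integer(round_half_up(s / cnt))
  }
  out
}

#' Compute one pyramid level's image
#'
#' @param pixels Full-resolution `H x W x 3` array.
#' @param level Level index (0 = 1x1, top = full resolution).
#' @return The level's pixel array.
#' @export
pyramid_level_image <- function(pixels, level) {
  d <- dim(pixels)
  max_level <- num_pyramid_levels(d[2], d[1]) - 1L
  if (level < 0 || level > max_level) stop_tma("level must lie in 0..%d", max_level)
  for (i in seq_len(max_level - as.integer(level))) {
    pixels <- downsample_box2(pixels)
  }
  pixels
}

DZI_NS <- "http://schemas.microsoft.com/deepzoom/2008"

pyramid_descriptor <- function(width, height, tile_size = 254L, overlap = 1L,
                               format = "jpeg") {
  tile_size <- assert_count(tile_size, "tile_size")
  if (!is.numeric(overlap) || overlap < 0) stop_tma("overlap must be >= 0")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         tile_size = tile_size, overlap = as.integer(overlap),
         format = format,
         max_level = num_pyramid_levels(width, height) - 1L),
    class = "tma_pyramid"
  )
}

#' @export
print.tma_pyramid <- function(x, ...) {
  cat(sprintf("<tma_pyramid %dx%d, %d levels, tiles %d+%d overlap, %s>\n",
              x$width, x$height, x$max_level + 1L, x$tile_size, x$overlap,
              x$format))
  invisible(x)
}

# inclusive pixel range (1-based) of tile `idx` (0-based) along an axis of
# length `extent`, with overlap extension where a neighbouring tile exists
tile_range <- function(idx, extent, tile_size, overlap) {
  n_tiles <- ceiling(extent / tile_size)
  lo <- idx * tile_size + 1L - if (idx > 0L) overlap else 0L
  hi <- min((idx + 1L) * tile_size, extent) +
    if (idx < n_tiles - 1L) overlap else 0L
  c(max(1L, lo), min(extent, hi))
}

write_tile <- function(pixels, path, format, quality) {
  if (format == "png") {
    png::writePNG(pixels / 255, target = path)
  } else {
    jpeg::writeJPEG(pixels / 255, target = path, quality = quality / 100)
  }
}

read_tile <- function(path, format) {
  raw <- if (format == "png") png::readPNG(path) else jpeg::readJPEG(path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  px <- round_half_up(raw[, , 1:3, drop = FALSE] * 255)
  storage.mode(px) <- "integer"
  px
}

#' Build a Deep Zoom pyramid for one image
#'
#' Writes a DZI descriptor (`{name}.dzi`) and the tile tree
#' (`{name}_files/{level}/{col}_{row}.{ext}`) compatible with standard Deep
#' Zoom viewers. Every level from full resolution down to 1x1 is tiled into
#' `ceil(w/tile_size) x ceil(h/tile_size)` tiles; tiles extend `overlap`
#' pixels past their nominal edge wherever a neighbouring tile exists.
#' Downsampling between levels is 2x2 box averaging ([downsample_box2()]).
#'
#' @param image A [core_image()] or a raw `H x W x 3` pixel array.
#' @param out_dir Output directory.
#' @param name Pyramid name (defaults to the core's export filename stem).
#' @param tile_size Tile edge in pixels (Deep Zoom convention: 254).
#' @param overlap Tile overlap in pixels (convention: 1).
#' @param format Tile codec, `"jpeg"` or `"png"` (PNG tiles are lossless).
#' @param quality JPEG tile quality, 1-100.
#' @return A `tma_pyramid` descriptor with `dzi_path` and `files_dir` fields.
#' @export
build_pyramid <- function(image, out_dir, name = NULL, tile_size = 254L,
                          overlap = 1L, format = c("jpeg", "png"),
                          quality = 85) {
  format <- match.arg(format)
  if (inherits(image, "tma_core_image")) {
    if (is.null(name)) {
      name <- sprintf("%s_%d_%d_%d", image$slide_id, image$x, image$y,
                      image$version)
    }
    pixels <- image$pixels
  } else {
    pixels <- image
    if (is.null(name)) name <- "image"
  }
  d <- dim(pixels)
  desc <- pyramid_descriptor(d[2], d[1], tile_size, overlap, format)
  files_dir <- file.path(out_dir, paste0(name, "_files"))
  dir.create(files_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") "png" else "jpg"

  level_px <- pixels
  for (level in desc$max_level:0) {
    ld <- dim(level_px)
    lw <- ld[2]; lh <- ld[1]
    lev_dir <- file.path(files_dir, level)
    dir.create(lev_dir, showWarnings = FALSE)
    for (col in 0:(ceiling(lw / tile_size) - 1L)) {
      xr <- tile_range(col, lw, tile_size, desc$overlap)
      for (row in 0:(ceiling(lh / tile_size) - 1L)) {
        yr <- tile_range(row, lh, tile_size, desc$overlap)
        tile <- level_px[yr[1]:yr[2], xr[1]:xr[2], , drop = FALSE]
        write_tile(tile, file.path(lev_dir, sprintf("%d_%d.%s", col, row, ext)),
                   format, quality)
      }
    }
    if (level > 0L) level_px <- downsample_box2(level_px)
  }

  doc <- xml2::xml_new_root("Image", xmlns = DZI_NS,
                            TileSize = as.character(desc$tile_size),
                            Overlap = as.character(desc$overlap),
                            Format = if (format == "png") "png" else "jpg")
  xml2::xml_add_child(doc, "Size",
                      Width = as.character(desc$width),
                      Height = as.character(desc$height))
  dzi_path <- file.path(out_dir, paste0(name, ".dzi"))
  xml2::write_xml(doc, dzi_path)
  desc$dzi_path <- dzi_path
  desc$files_dir <- files_dir
  desc
}

#' Read a DZI descriptor
#'
#' @param path Path to a `.dzi` file.
#' @return A `tma_pyramid` descriptor.
#' @export
read_dzi <- function(path) {
  root <- xml2::xml_root(xml2::read_xml(path))
  if (xml2::xml_name(root) != "Image") {
    stop_tma("parse error at /: expected Image, found %s", xml2::xml_name(root))
  }
  size <- xml2::xml_find_first(root, "./*[local-name()='Size']")
  if (inherits(size, "xml_missing")) stop_tma("parse error at /Image: missing Size")
  fmt <- xml2::xml_attr(root, "Format")
  desc <- pyramid_descriptor(
    width = as.integer(xml2::xml_attr(size, "Width")),
    height = as.integer(xml2::xml_attr(size, "Height")),
    tile_size = as.integer(xml2::xml_attr(root, "TileSize")),
    overlap = as.integer(xml2::xml_attr(root, "Overlap")),
    format = if (identical(fmt, "png")) "png" else "jpeg"
  )
  desc$dzi_path <- path
  desc$files_dir <- file.path(dirname(path),
                              paste0(sub("\\.dzi$", "", basename(path)), "_files"))
  desc
}

#' Reassemble one pyramid level from its tiles
#'
#' Reads every tile of a level, crops the overlap margins, and stitches the
#' nominal tile extents back into the level image. With PNG tiles this
#' reproduces the level image pixel-exactly.
#'
#' @param desc A `tma_pyramid` descriptor with a `files_dir` (from
#'   [build_pyramid()] or [read_dzi()]).
#' @param level Level index.
#' @return The reassembled `H x W x 3` integer pixel array.
#' @export
read_pyramid_level <- function(desc, level) {
  stopifnot(inherits(desc, "tma_pyramid"))
  ld <- level_dimensions(desc$width, desc$height, level)
  lw <- ld[1]; lh <- ld[2]
  out <- array(0L, dim = c(lh, lw, 3L))
  ext <- if (desc$format == "png") "png" else "jpg"
  ts <- desc$tile_size; ov <- desc$overlap
  for (col in 0:(ceiling(lw / ts) - 1L)) {
    xr <- tile_range(col, lw, ts, ov)
    nominal_x <- c(col * ts + 1L, min((col + 1L) * ts, lw))
    for (row in 0:(ceiling(lh / ts) - 1L)) {
      yr <- tile_range(row, lh, ts, ov)
      nominal_y <- c(row * ts + 1L, min((row + 1L) * ts, lh))
      tile <- read_tile(file.path(desc$files_dir, level,
                                  sprintf("%d_%d.%s", col, row, ext)),
                        desc$format)
      # crop the overlap margin: nominal extent relative to the tile origin
      rx <- (nominal_x[1] - xr[1] + 1L):(nominal_x[2] - xr[1] + 1L)
      ry <- (nominal_y[1] - yr[1] + 1L):(nominal_y[2] - yr[1] + 1L)
      out[nominal_y[1]:nominal_y[2], nominal_x[1]:nominal_x[2], ] <-
        tile[ry, rx, , drop = FALSE]
    }
  }
  out
}

#' Batch-convert a directory of core images to Deep Zoom pyramids
#'
#' Converts every parseable core image in `in_dir` (JPEG or PNG, named per
#' the export convention) into a pyramid under `out_dir`. Files whose names
#' do not match the convention are skipped with a logged message. Re-running
#' on the same input reproduces the same manifest.
#'
#' @param in_dir Directory of core images.
#' @param out_dir Output directory for pyramids.
#' @param tile_size,overlap,format,quality Passed to [build_pyramid()].
#' @return A manifest data frame with columns `slide_id`, `x`, `y`,
#'   `version`, `source`, `descriptor`.
#' @export
batch_convert <- function(in_dir, out_dir, tile_size = 254L, overlap = 1L,
                          format = c("jpeg", "png"), quality = 85) {
  format <- match.arg(format)
  files <- sort(list.files(in_dir, pattern = "\\.(jpe?g|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  manifest <- data.frame(slide_id = character(), x = integer(), y = integer(),
                         version = integer(), source = character(),
                         descriptor = character(), stringsAsFactors = FALSE)
  if (!length(files)) {
    warning("no core images found in '", in_dir, "'", call. = FALSE)
    return(manifest)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_skipped <- 0L
  for (f in files) {
    id <- tryCatch(parse_core_filename(f), error = function(e) NULL)
    if (is.null(id)) {
      message("skipping unparseable core filename: ", basename(f))
      n_skipped <- n_skipped + 1L
      next
    }
    img <- read_core_image(f)
    desc <- build_pyramid(img, out_dir, tile_size = tile_size,
                          overlap = overlap, format = format, quality = quality)
    manifest <- rbind(manifest, data.frame(
      slide_id = id$slide_id, x = id$x, y = id$y, version = id$version,
      source = basename(f), descriptor = desc$dzi_path,
      stringsAsFactors = FALSE))
  }
  message(sprintf("converted %d image(s), skipped %d", nrow(manifest), n_skipped))
  manifest
}
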