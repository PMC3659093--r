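#' Construct a core image
#'
#' Wraps an 8-bit RGB pixel array together with the identity of the core it
#' depicts: the slide it came from, its grid coordinates, and an export
#' version number (scanners may re-export a core after re-scanning).
#'
#' @param pixels An `H x W x 3` integer array with values 0-255.
#' @param slide_id Slide identifier (non-empty).
#' @param x,y 1-based grid coordinates.
#' @param version Positive integer export version.
#' @return An object of class `tma_core_image`.
#' @export
core_image <- function(pixels, slide_id, x, y, version = 1L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_tma("pixels must be an H x W x 3 array")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) stop_tma("image must be at least 1x1")
  if (min(pixels) < 0 || max(pixels) > 255) stop_tma("pixel values must lie in 0..255")
  storage.mode(pixels) <- "integer"
  assert_nonempty_string(slide_id, "slide_id")
  structure(
    list(pixels = pixels, slide_id = slide_id,
         x = assert_count(x, "x"), y = assert_count(y, "y"),
         version = assert_count(version, "version")),
    class = "tma_core_image"
  )
}

#' @export
print.tma_core_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tma_core_image %s at (%d, %d) v%d: %dx%d px>\n",
              x$slide_id, x$x, x$y, x$version, d[2], d[1]))
  invisible(x)
}

#' Compose the export filename for a core image
#'
#' The scanner-export naming convention encodes the core's identity in the
#' filename: `{slide_id}_{x}_{y}_{version}.JPEG`.
#'
#' @param slide_id Slide identifier (may itself contain underscores).
#' @param x,y Grid coordinates.
#' @param version Export version.
#' @param ext File extension (default `"JPEG"`).
#' @return The filename string.
#' @export
core_filename <- function(slide_id, x, y, version = 1L, ext = "JPEG") {
  assert_nonempty_string(slide_id, "slide_id")
  sprintf("%s_%d_%d_%d.%s", slide_id, as.integer(x), as.integer(y),
          as.integer(version), ext)
}

#' Parse a core-image export filename
#'
#' Inverts the `{slide_id}_{x}_{y}_{version}` naming convention. Parsing is
#' right-anchored: the last three underscore-separated tokens before the
#' extension are read (right to left) as version, y, x, and everything to
#' their left is the slide identifier — so slide identifiers containing
#' underscores round-trip correctly.
#'
#' @param name A filename ending in `.JPEG`, `.jpeg`, `.jpg` or `.png` (any
#'   case); directories are ignored.
#' @return A list with `slide_id`, `x`, `y`, `version`.
#' @examples
#' parse_core_filename("TRIAL_A_10_4_2.jpeg")
#' @export
parse_core_filename <- function(name) {
  assert_nonempty_string(name, "name")
  base <- basename(name)
  m <- regmatches(base, regexpr("\\.(jpe?g|png)$", base, ignore.case = TRUE))
  if (!length(m)) stop_tma("'%s' does not end in a recognised image extension", base)
  stem <- substr(base, 1L, nchar(base) - nchar(m))
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (length(tokens) < 4L) {
    stop_tma("'%s' does not match the slideID_x_y_version naming pattern", base)
  }
  tail3 <- tokens[(length(tokens) - 2L):length(tokens)]
  if (!all(grepl("^[0-9]+$", tail3))) {
    stop_tma("'%s': trailing tokens '%s' are not all numeric", base,
             paste(tail3, collapse = "_"))
  }
  slide_id <- paste(tokens[seq_len(length(tokens) - 3L)], collapse = "_")
  if (!nzchar(slide_id)) {
    stop_tma("'%s' has an empty slide identifier", base)
  }
  list(slide_id = slide_id,
       x = as.integer(tail3[1L]), y = as.integer(tail3[2L]),
       version = as.integer(tail3[3L]))
}

# nearest-neighbour resample to w x h (deterministic, codec-free)
resize_pixels <- function(pixels, w, h) {
  d <- dim(pixels)
  src_r <- pmin(d[1], floor((seq_len(h) - 0.5) * d[1] / h) + 1L)
  src_c <- pmin(d[2], floor((seq_len(w) - 0.5) * d[2] / w) + 1L)
  out <- pixels[src_r, src_c, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Export a core image as JPEG
#'
#' Writes the image under the export naming convention, scaled to the export
#' resolution. The default scale of 0.70 reproduces the 70%-resolution
#' export used for manual scoring: each axis is scaled linearly
#' (round-half-up, minimum 1 pixel). JPEG quality is a separate knob.
#'
#' @param image A [core_image()].
#' @param out_dir Output directory (created if absent).
#' @param scale Linear scale factor applied to width and height.
#' @param quality JPEG quality, 1-100.
#' @return The output file path, invisibly.
#' @examples
#' img <- generate_synthetic_core(synthetic_core_spec(size_px = 40), "S1", 2, 3)
#' export_core_image(img, tempdir())
#' @export
export_core_image <- function(image, out_dir, scale = 0.70, quality = 85) {
  stopifnot(inherits(image, "tma_core_image"))
  if (!is.numeric(scale) || scale <= 0) stop_tma("scale must be > 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(image$pixels)
  h <- max(1L, as.integer(round_half_up(scale * d[1])))
  w <- max(1L, as.integer(round_half_up(scale * d[2])))
  px <- if (w == d[2] && h == d[1]) image$pixels else resize_pixels(image$pixels, w, h)
  path <- file.path(out_dir, core_filename(image$slide_id, image$x, image$y,
                                           image$version))
  jpeg::writeJPEG(px / 255, target = path, quality = quality / 100)
  invisible(path)
}

#' Read a core image from disk
#'
#' Reads a JPEG or PNG core image and recovers the core identity from its
#' filename.
#'
#' @param path Image file path named per the export convention.
#' @return A [core_image()].
#' @export
read_core_image <- function(path) {
  id <- parse_core_filename(path)
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    jpeg::readJPEG(path)
  }
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- round_half_up(raw * 255)
  storage.mode(px) <- "integer"
  core_image(px, id$slide_id, id$x, id$y, id$version)
}

#' Write a core image as PNG (lossless)
#'
#' @param image A [core_image()].
#' @param out_dir Output directory.
#' @return The output file path, invisibly.
#' @export
write_core_png <- function(image, out_dir) {
  stopifnot(inherits(image, "tma_core_image"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, core_filename(image$slide_id, image$x, image$y,
                                           image$version, ext = "png"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Assemble thumbnails into a virtual-slide montage
#'
#' Places core thumbnails on a grid according to their array coordinates,
#' producing the array view of a slide — or a "virtual TMA" when the entries
#' are drawn from several physical slides (e.g. cores selected across studies
#' for joint review).
#'
#' @param entries A list of entries, each a list with `x`, `y` and `pixels`
#'   (an RGB array; resized to `cell_px` as needed).
#' @param cell_px Square cell size in pixels.
#' @param n_cols,n_rows Montage grid dimensions.
#' @param background RGB vector used for cells without an entry.
#' @return An integer `n_rows*cell_px x n_cols*cell_px x 3` pixel array.
#' @export
assemble_virtual_slide <- function(entries, cell_px, n_cols, n_rows,
                                   background = c(255L, 255L, 255L)) {
  cell_px <- assert_count(cell_px, "cell_px")
  n_cols <- assert_count(n_cols, "n_cols")
  n_rows <- assert_count(n_rows, "n_rows")
  out <- array(0L, dim = c(n_rows * cell_px, n_cols * cell_px, 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(background[ch])
  seen <- character()
  for (e in entries) {
    ex <- assert_count(e$x, "entry x"); ey <- assert_count(e$y, "entry y")
    if (ex > n_cols || ey > n_rows) {
      stop_tma("entry at (%d, %d) is outside the %dx%d montage grid",
               ex, ey, n_cols, n_rows)
    }
    key <- paste(ex, ey)
    if (key %in% seen) stop_tma("duplicate montage entry at (%d, %d)", ex, ey)
    seen <- c(seen, key)
    px <- e$pixels
    if (inherits(px, "tma_core_image")) px <- px$pixels
    d <- dim(px)
    if (d[1] != cell_px || d[2] != cell_px) px <- resize_pixels(px, cell_px, cell_px)
    rr <- ((ey - 1L) * cell_px + 1L):(ey * cell_px)
    cc <- ((ex - 1L) * cell_px + 1L):(ex * cell_px)
    out[rr, cc, ] <- px
  }
  storage.mode(out) <- "integer"
  out
}
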