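#' Specify a synthetic stained-core image
#'
#' The synthetic generator emulates one scanned TMA core: a circular tissue
#' disc centred on a neutral background, with a controllable fraction of the
#' disc covered by stained cell clusters whose colour darkens with staining
#' intensity (a crude stand-in for DAB/haematoxylin IHC appearance).
#'
#' @param size_px Side length of the square image in pixels.
#' @param disc_radius_fraction Disc radius as a fraction of half the image
#'   side, in (0, 1].
#' @param stain_intensity Integer staining intensity, 0 (unstained) to 3
#'   (strong).
#' @param stained_fraction Target fraction of the disc area covered by
#'   stained clusters, in \[0, 1\].
#' @param background_grey Background grey level, 0-255.
#' @param seed Integer seed; the generated image is a deterministic function
#'   of the spec.
#' @return An object of class `tma_core_spec`.
#' @export
synthetic_core_spec <- function(size_px = 256L, disc_radius_fraction = 0.9,
                                stain_intensity = 2L, stained_fraction = 0.5,
                                background_grey = 235L, seed = 1L) {
  size_px <- assert_count(size_px, "size_px")
  if (!is.numeric(disc_radius_fraction) || disc_radius_fraction <= 0 ||
      disc_radius_fraction > 1) {
    stop_tma("disc_radius_fraction must lie in (0, 1]")
  }
  if (!stain_intensity %in% 0:3) stop_tma("stain_intensity must be an integer in 0..3")
  if (!is.numeric(stained_fraction) || stained_fraction < 0 || stained_fraction > 1) {
    stop_tma("stained_fraction must lie in [0, 1]")
  }
  if (!background_grey %in% 0:255) stop_tma("background_grey must be an integer in 0..255")
  structure(
    list(size_px = size_px,
         disc_radius_fraction = as.numeric(disc_radius_fraction),
         stain_intensity = as.integer(stain_intensity),
         stained_fraction = as.numeric(stained_fraction),
         background_grey = as.integer(background_grey),
         seed = as.integer(seed)),
    class = "tma_core_spec"
  )
}

# unstained tissue tone: pale eosin pink
TISSUE_TONE <- c(230L, 205L, 210L)
# fully stained tone at intensity 3: dark DAB brown
STAIN_TONE <- c(94L, 61L, 34L)

#' Generate a synthetic core image
#'
#' Renders the image described by a [synthetic_core_spec()]: pixels outside
#' the centred disc are the flat background grey; pixels inside are the
#' unstained tissue tone except where stained clusters fall. Clusters are
#' random discs whose combined area approximates `stained_fraction` of the
#' tissue disc; their colour interpolates from the tissue tone (intensity 0)
#' to a dark brown (intensity 3). The output is a deterministic function of
#' the spec, including its seed.
#'
#' @param spec A [synthetic_core_spec()].
#' @param slide_id,x,y,version Identity of the core the image depicts.
#' @return A [core_image()].
#' @examples
#' img <- generate_synthetic_core(synthetic_core_spec(size_px = 64, seed = 7))
#' dim(img$pixels)
#' @export
generate_synthetic_core <- function(spec, slide_id = "SYN", x = 1L, y = 1L,
                                    version = 1L) {
  stopifnot(inherits(spec, "tma_core_spec"))
  n <- spec$size_px
  cx <- (n + 1) / 2
  radius <- spec$disc_radius_fraction * n / 2
  xs <- matrix(rep(seq_len(n), each = n), nrow = n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), nrow = n)  # row index
  dist2 <- (xs - cx)^2 + (ys - cx)^2
  disc <- dist2 <= radius^2

  stained <- matrix(FALSE, n, n)
  if (spec$stained_fraction > 0 && any(disc)) {
    with_seed(spec$seed, {
      n_clusters <- max(1L, as.integer(round(12 * spec$stained_fraction)))
      # cluster radius chosen so the union area is ~ stained_fraction of the disc
      r_c <- sqrt(spec$stained_fraction * radius^2 / n_clusters)
      theta <- stats::runif(n_clusters, 0, 2 * pi)
      rho <- radius * sqrt(stats::runif(n_clusters))
      ccx <- cx + rho * cos(theta)
      ccy <- cx + rho * sin(theta)
      for (k in seq_len(n_clusters)) {
        stained <- stained | ((xs - ccx[k])^2 + (ys - ccy[k])^2 <= r_c^2)
      }
    })
    stained <- stained & disc
  }

  w <- spec$stain_intensity / 3
  stain_rgb <- round_half_up(TISSUE_TONE + (STAIN_TONE - TISSUE_TONE) * w)
  px <- array(0L, dim = c(n, n, 3L))
  for (ch in 1:3) {
    plane <- matrix(spec$background_grey, n, n)
    plane[disc] <- TISSUE_TONE[ch]
    plane[stained] <- stain_rgb[ch]
    px[, , ch] <- plane
  }
  storage.mode(px) <- "integer"
  core_image(px, slide_id = slide_id, x = x, y = y, version = version)
}
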