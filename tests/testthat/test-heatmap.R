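ts0 <- "2013-05-01T00:00:00Z"

test_that("score values and statuses map to the legend colours", {
  spec <- heatmap_spec()
  expect_identical(score_to_colour(0, spec), c(255L, 255L, 204L))  # pale yellow
  expect_identical(score_to_colour(1, spec), c(255L, 215L, 0L))    # intense yellow
  expect_identical(score_to_colour(2, spec), c(173L, 216L, 230L))  # pale blue
  expect_identical(score_to_colour(3, spec), c(0L, 0L, 205L))      # intense blue
  expect_identical(score_to_colour(status = "marker", spec = spec),
                   c(128L, 128L, 128L))                            # grey
  expect_identical(score_to_colour(status = "no_tumour", spec = spec),
                   c(255L, 192L, 203L))                            # pink
  expect_identical(score_to_colour(status = "unscored", spec = spec),
                   c(255L, 255L, 255L))                            # white default
  expect_error(score_to_colour(4, spec), "outside the domain")
  expect_error(score_to_colour(-1, spec), "outside the domain")
})

test_that("values beyond the 0-3 legend interpolate between the endpoints", {
  spec8 <- heatmap_spec(colour_map = list(), domain_range = c(0, 8))
  expect_identical(score_to_colour(0, spec8), c(255L, 255L, 204L))
  expect_identical(score_to_colour(8, spec8), c(0L, 0L, 205L))
  mid <- score_to_colour(4, spec8)
  expect_true(all(mid <= c(255, 255, 205) & mid >= c(0, 0, 204)))
  expect_error(score_to_colour(9, spec8), "outside the domain")
})

test_that("heatmap dimensions and colour-class partition hold on random slides", {
  set.seed(31)
  for (i in 1:8) {
    map <- random_slidemap()
    spec <- heatmap_spec(cell_px = sample(4:12, 1))
    tissue <- map$positions[map$positions$kind == "tissue", , drop = FALSE]
    scores <- lapply(seq_len(nrow(tissue)), function(j) {
      score_record(map$slide_id, tissue$x[j], tissue$y[j], "u", map$marker_name,
                   values = list(intensity = sample(0:3, 1)), timestamp = ts0)
    })
    hm <- render_heatmap(map, scores, spec = spec)
    expect_identical(dim(hm$pixels),
                     c(map$block$n_rows * spec$cell_px,
                       map$block$n_cols * spec$cell_px, 3L))
    expect_identical(nrow(hm$cells), map$block$n_rows * map$block$n_cols)
    expect_identical(sum(table(hm$cells$class)),
                     as.integer(map$block$n_rows * map$block$n_cols))
  }
})

test_that("an all-unscored slide renders uniform except marker cells", {
  map <- make_map3()
  hm <- render_heatmap(map, list())
  expect_setequal(unique(hm$cells$class), c("unscored", "marker"))
  expect_identical(sum(hm$cells$class == "marker"), 1L)
})

test_that("one core scored 3 paints exactly cell_px^2 intense-blue pixels", {
  map <- make_map3()
  spec <- heatmap_spec(cell_px = 16)
  scores <- list(score_record("S1", 3, 1, "u", "ER",
                              values = list(intensity = 3), timestamp = ts0))
  hm <- render_heatmap(map, scores, spec = spec)
  blue <- hm$pixels[, , 1] == 0L & hm$pixels[, , 2] == 0L &
    hm$pixels[, , 3] == 205L
  expect_identical(sum(blue), 16L * 16L)
})

test_that("the latest record version wins and the current cell gets an outline", {
  map <- make_map3()
  spec <- heatmap_spec(cell_px = 8)
  scores <- list(
    score_record("S1", 1, 1, "u", "ER", values = list(intensity = 0),
                 timestamp = ts0, record_version = 1),
    score_record("S1", 1, 1, "u", "ER", values = list(intensity = 3),
                 timestamp = ts0, record_version = 2))
  hm <- render_heatmap(map, scores, current = c(2, 2), spec = spec)
  expect_identical(hm$cells$value[hm$cells$x == 1 & hm$cells$y == 1], "3")
  # the current (marker) cell's border is black, its interior still grey
  cc <- hm$pixels[9:16, 9:16, ]
  expect_identical(unname(cc[1, 1, ]), c(0L, 0L, 0L))
  expect_identical(unname(cc[4, 4, ]), c(128L, 128L, 128L))
  expect_error(render_heatmap(map, scores, current = c(9, 9)), "outside")
})

test_that("no-tumour status renders pink rather than a score colour", {
  map <- make_map3()
  scores <- list(score_record("S1", 1, 1, "u", "ER", status = "no_tumour",
                              timestamp = ts0))
  hm <- render_heatmap(map, scores)
  expect_identical(hm$cells$class[hm$cells$x == 1 & hm$cells$y == 1],
                   "no_tumour")
})

test_that("PNG and SVG outputs agree with the rendered raster", {
  map <- make_map3()
  hm <- render_heatmap(map, list(), spec = heatmap_spec(cell_px = 4))
  png_path <- withr::local_tempfile(fileext = ".png")
  svg_path <- withr::local_tempfile(fileext = ".svg")
  write_heatmap(hm, png_path, svg_path)
  back <- png::readPNG(png_path)
  expect_identical(dim(back)[1:2], dim(hm$pixels)[1:2])
  expect_identical(max(abs(round(back * 255) - hm$pixels)), 0)
  svg <- readLines(svg_path)
  expect_identical(sum(grepl("<rect", svg)), 9L)
})

test_that("scorer comparison counts intersections and discrepancies symmetrically", {
  map <- make_map3()
  mk <- function(x, y, v, scorer) {
    score_record("S1", x, y, scorer, "ER", values = list(intensity = v),
                 timestamp = ts0)
  }
  cells <- expand.grid(x = 1:3, y = 1:3)
  cells <- cells[!(cells$x == 1 & cells$y == 2) &
                 !(cells$x == 2 & cells$y == 2), ]  # skip gap and marker
  vals <- c(0, 1, 2, 3, 0, 1, 2)
  a <- mapply(mk, cells$x, cells$y, vals, "pathA", SIMPLIFY = FALSE)
  b <- mapply(mk, cells$x, cells$y, vals, "pathB", SIMPLIFY = FALSE)
  same <- compare_scorers(map, a, b)
  expect_identical(same$n_compared, 7L)
  expect_identical(same$n_discrepant, 0L)

  b2 <- b
  b2[[3]] <- mk(cells$x[3], cells$y[3], 3, "pathB")
  diff1 <- compare_scorers(map, a, b2)
  expect_identical(diff1$n_discrepant, 1L)
  # symmetric up to swapping the value columns
  rev <- compare_scorers(map, b2, a)
  expect_identical(rev$n_discrepant, diff1$n_discrepant)
  expect_identical(rev$cells$value_a, diff1$cells$value_b)
  expect_identical(rev$cells$value_b, diff1$cells$value_a)
  # missing cores shrink the comparison to the intersection
  partial <- compare_scorers(map, a, b[1:4])
  expect_identical(partial$n_compared, 4L)
  # the report renders as a third heatmap
  hm <- render_discrepancy(map, diff1)
  expect_identical(sum(hm$cells$class == "discrepant"), 1L)
  expect_identical(sum(hm$cells$class == "agree"), 6L)
})
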