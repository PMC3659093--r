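# Shared fixtures and independent oracles for the suite.

make_block <- function(n_cols = 3L, n_rows = 3L, id = "B1", ...) {
  recipient_block(id, n_cols, n_rows, ...)
}

# canonical 3x3 fixture: one gap at (1,2), one marker core at (2,2),
# donor DB7 replicated at (1,1) and (3,3)
make_map3 <- function(slide_id = "S1", marker = "ER") {
  cells <- matrix(c("DB7", "DB2", "DB3",
                    "",    "MARKER", "DB4",
                    "DB5", "DB6", "DB7"),
                  nrow = 3, byrow = TRUE)
  parse_layout_table(cells, make_block(), slide_id, marker)
}

# --- independent Deep Zoom oracles ----------------------------------------

# level count by literal repeated halving until 1x1
oracle_num_levels <- function(w, h) {
  n <- 1L
  while (w > 1L || h > 1L) {
    w <- ceiling(w / 2); h <- ceiling(h / 2)
    n <- n + 1L
  }
  n
}

# dims of every level, top (full size) first, by the same halving
oracle_level_dims <- function(w, h) {
  dims <- list(c(w, h))
  while (w > 1L || h > 1L) {
    w <- ceiling(w / 2); h <- ceiling(h / 2)
    dims <- c(dims, list(c(w, h)))
  }
  dims
}

# brute-force 2x2 box-mean halving (naive loops; rounding half-up)
oracle_downsample <- function(px) {
  d <- dim(px)
  nh <- ceiling(d[1] / 2); nw <- ceiling(d[2] / 2)
  out <- array(0L, dim = c(nh, nw, 3L))
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      ri <- (2 * i - 1):min(2 * i, d[1])
      cj <- (2 * j - 1):min(2 * j, d[2])
      for (ch in 1:3) {
        out[i, j, ch] <- as.integer(floor(mean(px[ri, cj, ch]) + 0.5))
      }
    }
  }
  out
}

random_pixels <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3L))
}

# --- randomized-instance generators ----------------------------------------

random_domain <- function() {
  kind <- sample(c("enumerated", "integer-range", "real-range", "free-text"), 1)
  switch(kind,
    "enumerated" = value_domain("enumerated",
      codes = paste0("c", seq_len(sample(1:4, 1))),
      meanings = paste0("meaning ", seq_len(sample(1:4, 1)))[1]),
    "integer-range" = {
      lo <- sample(-5:5, 1)
      value_domain("integer-range", min = lo, max = lo + sample(0:10, 1))
    },
    "real-range" = {
      lo <- stats::runif(1, -10, 10)
      value_domain("real-range", min = lo, max = lo + stats::runif(1, 0, 50))
    },
    "free-text" = value_domain("free-text",
      pattern = if (stats::runif(1) < 0.5) "[A-Z]+[0-9]*"))
}

random_registry <- function(n_cdes = sample(1:4, 1)) {
  reg <- cde_registry()
  for (i in seq_len(n_cdes)) {
    reg <- register_cde(reg, cde_definition(
      identifier = sprintf("ID-%d", i),
      name = sprintf("Element %d", i),
      definition = sample(c("", "a definition with <xml> & specials"), 1),
      domain = random_domain(),
      units = sample(c("", "mm", "%"), 1),
      alternative_names = if (stats::runif(1) < 0.5)
        sprintf("alt_%d_%d", i, seq_len(sample(1:2, 1))) else character()))
  }
  reg
}

random_slidemap <- function(slide_id = "S1") {
  nc <- sample(1:4, 1); nr <- sample(1:4, 1)
  cells <- matrix(sample(c("", "MARKER", paste0("DB", 1:3)),
                         nc * nr, replace = TRUE),
                  nrow = nr, ncol = nc)
  parse_layout_table(cells, make_block(nc, nr,
                                       core_diameter = stats::runif(1, 0.1, 2),
                                       core_spacing = stats::runif(1, 0.5, 3),
                                       slice_number = sample(1:20, 1)),
                     slide_id, marker_name = sample(c("ER", "PR", "HER2"), 1))
}

expect_same_registry <- function(a, b) {
  expect_identical(names(a$cdes), names(b$cdes))
  for (id in names(a$cdes)) {
    expect_identical(unclass(a$cdes[[id]]), unclass(b$cdes[[id]]))
  }
}

expect_same_slidemap <- function(a, b) {
  expect_identical(a$slide_id, b$slide_id)
  expect_identical(a$marker_name, b$marker_name)
  expect_equal(unclass(a$block), unclass(b$block))
  expect_identical(a$positions, b$positions)
}

# small populated store used by store/tmades/cli tests
make_demo_store <- function(root, markers = c("ER", "PR"),
                            scorers = c("path1", "path2"),
                            timestamp = "2013-05-01T09:00:00Z") {
  store <- study_store(root)
  create_study(store, "BCAC")
  registry <- load_default_cdes()
  sys <- builtin_systems(registry)[["intensity-0-3"]]
  for (mk in markers) {
    add_marker(store, "BCAC", mk)
    map <- make_map3(slide_id = paste0("S-", mk), marker = mk)
    add_slidemap(store, "BCAC", mk, map)
    for (sc in scorers) {
      grant_scorer(store, sc, "BCAC", mk)
      open_slide(store, "BCAC", mk, sc, map$slide_id, sys)
    }
  }
  store
}
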