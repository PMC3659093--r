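ts0 <- "2013-05-01T00:00:00Z"

populate_scores <- function(store, marker = "ER", slide = paste0("S-", marker)) {
  sys <- builtin_systems()[["intensity-0-3"]]
  map <- make_map3(slide, marker)
  tissue <- map$positions[map$positions$kind == "tissue", ]
  for (i in seq_len(nrow(tissue))) {
    record_score(store, "BCAC",
      score_record(slide, tissue$x[i], tissue$y[i], "path1", marker,
                   values = list(intensity = (i - 1) %% 4), timestamp = ts0),
      sys)
  }
  invisible(map)
}

test_that("exported documents use DES tags where Table-vocabulary equivalents exist", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  populate_scores(store)
  doc <- export_tmades(store, "BCAC", "ER", date = ts0)
  txt <- as.character(doc)
  expect_match(txt, "<block_identifier>B1</block_identifier>")
  expect_match(txt, "<block_core_size>")
  expect_match(txt, "<block_core_spacing>")
  expect_match(txt, "<slide_identifier>S-ER</slide_identifier>")
  expect_match(txt, "<core_histo-repository_donor-block>DB7<")
  # intensity scores from the generic 0-3 system use the general DES tag
  expect_match(txt, "<core_results_tissue-intensity>")
  # fields with no DES equivalent travel in the extension namespace
  expect_match(txt, "<cg:x>")
  expect_match(txt, "<cg:slice_number>")
  expect_match(txt, "<cg:position_used>")
})

test_that("Allred component fields export as extension elements, not DES tags", {
  root <- withr::local_tempdir()
  store <- study_store(root)
  create_study(store, "BCAC")
  add_marker(store, "BCAC", "ER")
  add_slidemap(store, "BCAC", "ER", make_map3("S-ER", "ER"))
  grant_scorer(store, "path1", "BCAC", "ER")
  sys <- builtin_systems()[["allred"]]
  open_slide(store, "BCAC", "ER", "path1", "S-ER", sys)
  record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER",
                 values = list(intensity = 2, proportion = 4, total = 6),
                 timestamp = ts0), sys)
  txt <- as.character(export_tmades(store, "BCAC", "ER", date = ts0))
  expect_match(txt, "<cg:allred_intensity>2</cg:allred_intensity>")
  expect_match(txt, "<cg:allred_proportion>4</cg:allred_proportion>")
  expect_match(txt, "<cg:allred_total>6</cg:allred_total>")
  expect_no_match(txt, "core_results_tissue-intensity")
})

test_that("every emitted element is a DES tag, a structural tag, or cg-namespaced", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  populate_scores(store)
  doc <- export_tmades(store, "BCAC", "ER", date = ts0)
  expect_true(isTRUE(tmades_conformant(doc)))
})

test_that("export then import reproduces geometry, donor linkage and latest scores", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  map <- populate_scores(store)
  path <- withr::local_tempfile(fileext = ".xml")
  export_tmades(store, "BCAC", "ER", path = path, date = ts0)
  imp <- import_tmades(path)
  expect_identical(length(imp$slidemaps), 1L)
  expect_same_slidemap(imp$slidemaps[[1]], map)
  latest <- slide_scores(store, "BCAC", "ER", "path1", "S-ER")
  expect_identical(length(imp$scores), length(latest))
  key <- function(r) paste(r$x, r$y)
  got <- imp$scores[order(vapply(imp$scores, key, ""))]
  want <- latest[order(vapply(latest, key, ""))]
  for (i in seq_along(want)) {
    expect_identical(got[[i]]$values$intensity, want[[i]]$values$intensity)
    expect_identical(got[[i]]$scorer, want[[i]]$scorer)
  }
  expect_identical(unname(imp$systems["path1"]), "intensity-0-3")
})

test_that("round trip holds on randomized stores", {
  set.seed(41)
  sys <- builtin_systems()[["intensity-0-3"]]
  for (trial in 1:6) {
    root <- withr::local_tempdir()
    store <- study_store(root)
    create_study(store, "ST")
    add_marker(store, "ST", "M")
    map <- random_slidemap(sprintf("RS-%d", trial))
    map$marker_name <- "M"
    add_slidemap(store, "ST", "M", map)
    grant_scorer(store, "u1", "ST", "M")
    open_slide(store, "ST", "M", "u1", map$slide_id, sys)
    tissue <- map$positions[map$positions$kind == "tissue", , drop = FALSE]
    vals <- if (nrow(tissue)) sample(0:3, nrow(tissue), replace = TRUE)
    for (i in seq_len(nrow(tissue))) {
      record_score(store, "ST",
        score_record(map$slide_id, tissue$x[i], tissue$y[i], "u1", "M",
                     values = list(intensity = vals[i]), timestamp = ts0), sys)
    }
    imp <- import_tmades(export_tmades(store, "ST", "M", date = ts0))
    expect_same_slidemap(imp$slidemaps[[1]], map)
    expect_identical(length(imp$scores), nrow(tissue))
    got <- vapply(imp$scores, function(r) r$values$intensity, 0)
    key <- vapply(imp$scores, function(r) paste(r$x, r$y), "")
    want_key <- paste(tissue$x, tissue$y)
    expect_identical(got[match(want_key, key)], as.numeric(vals))
  }
})

test_that("unknown vendor elements are retained as annotations and logged", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  populate_scores(store)
  txt <- as.character(export_tmades(store, "BCAC", "ER", date = ts0))
  hacked <- sub("<core>", "<core><vendor_field>opaque</vendor_field>", txt)
  expect_message(imp <- import_tmades(hacked), "vendor_field")
  expect_identical(imp$annotations$element, "vendor_field")
  expect_identical(imp$annotations$text, "opaque")
})

test_that("cores without coordinates import as unplaced with a warning", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  populate_scores(store)
  txt <- as.character(export_tmades(store, "BCAC", "ER", date = ts0))
  hacked <- sub("<cg:x>1</cg:x>\\s*<cg:y>1</cg:y>", "", txt)
  expect_warning(imp <- import_tmades(hacked), "unplaced")
  expect_identical(nrow(imp$unplaced), 1L)
  expect_identical(length(imp$slidemaps[[1]]$positions$x), 8L)
})

test_that("a slide without an identifier is a parse error; empty collections warn", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  txt <- as.character(export_tmades(store, "BCAC", "ER", date = ts0))
  hacked <- gsub("<slide_identifier>S-ER</slide_identifier>", "", txt)
  expect_error(import_tmades(hacked), "slide_identifier")
  add_marker(store, "BCAC", "KI67")
  expect_warning(doc <- export_tmades(store, "BCAC", "KI67", date = ts0),
                 "header only")
  expect_identical(length(xml2::xml_find_all(doc, "//*[local-name()='block']")), 0L)
})
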