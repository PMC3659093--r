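ts0 <- "2013-05-01T00:00:00Z"

test_that("study/marker/scorer hierarchy and grants govern writes", {
  root <- withr::local_tempdir()
  store <- study_store(root)
  create_study(store, "BCAC")
  expect_error(create_study(store, "BCAC"), "already exists")
  add_marker(store, "BCAC", "ER")
  add_marker(store, "BCAC", "PR")
  expect_error(add_marker(store, "NOPE", "ER"), "does not exist")
  map <- make_map3(slide_id = "S1", marker = "ER")
  add_slidemap(store, "BCAC", "ER", map)
  add_slidemap(store, "BCAC", "PR", make_map3("S1", "PR"))

  grant_scorer(store, "path1", "BCAC", "ER")
  grant_scorer(store, "path1", "BCAC", "PR")
  expect_true(has_grant(store, "path1", "BCAC", "ER"))
  expect_false(has_grant(store, "path2", "BCAC", "ER"))
  sys <- builtin_systems()[["intensity-0-3"]]
  rec <- score_record("S1", 1, 1, "path1", "ER",
                      values = list(intensity = 2), timestamp = ts0)
  record_score(store, "BCAC", rec, sys)
  # same scorer granted two markers: both writable
  record_score(store, "BCAC",
               score_record("S1", 1, 1, "path1", "PR",
                            values = list(intensity = 1), timestamp = ts0), sys)
  # ungranted scorer is refused
  expect_error(record_score(store, "BCAC",
    score_record("S1", 1, 1, "path2", "ER", values = list(intensity = 2),
                 timestamp = ts0), sys), "permission")
  expect_identical(length(slide_scores(store, "BCAC", "ER", "path1", "S1")), 1L)
})

test_that("score templates list used positions with one slot per system field", {
  map <- make_map3()
  systems <- builtin_systems()
  tpl <- make_score_template(map, systems[["allred"]])
  expect_identical(nrow(tpl$entries), 8L)  # 9 cells minus 1 gap
  expect_identical(sum(tpl$entries$kind == "tissue"), 7L)
  expect_identical(sum(tpl$entries$kind == "marker"), 1L)
  expect_identical(tpl$fields, c("intensity", "proportion", "total"))
  # template XML round trip is the identity
  back <- parse_template_xml(write_template_xml(tpl))
  expect_equal(unclass(back), unclass(tpl))
  path <- withr::local_tempfile(fileext = ".xml")
  write_template_xml(tpl, path)
  expect_equal(unclass(parse_template_xml(path)), unclass(tpl))
})

test_that("re-scoring appends versions and invalid scores leave the document unchanged", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  sys <- builtin_systems()[["intensity-0-3"]]
  r1 <- record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER", values = list(intensity = 1),
                 timestamp = ts0), sys)
  expect_identical(r1$record_version, 1L)
  r2 <- record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER", values = list(intensity = 3),
                 timestamp = ts0), sys)
  expect_identical(r2$record_version, 2L)
  latest <- slide_scores(store, "BCAC", "ER", "path1", "S-ER")
  expect_identical(length(latest), 1L)
  expect_identical(latest[[1]]$values$intensity, 3)

  doc_file <- file.path(root, "BCAC", "ER", "path1", "S-ER.xml")
  before <- readBin(doc_file, "raw", file.size(doc_file))
  expect_error(record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER", values = list(intensity = 4),
                 timestamp = ts0), sys), "rejected")
  after <- readBin(doc_file, "raw", file.size(doc_file))
  expect_identical(before, after)
})

test_that("store contents are plain documents that survive reopening byte-identically", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  sys <- builtin_systems()[["intensity-0-3"]]
  record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER", values = list(intensity = 2),
                 timestamp = ts0), sys)
  files <- sort(list.files(root, recursive = TRUE))
  sums <- tools::md5sum(file.path(root, files))
  reopened <- study_store(root)
  expect_identical(store_studies(reopened), "BCAC")
  expect_identical(sort(list.files(root, recursive = TRUE)), files)
  expect_identical(tools::md5sum(file.path(root, files)), sums)
  # reads do not mutate the tree
  export_table(reopened, "BCAC", "ER")
  query_by_donor(reopened, "DB7")
  expect_identical(tools::md5sum(file.path(root, files)), sums)
})

test_that("randomized grant sets never allow writes outside granted collections", {
  set.seed(37)
  for (trial in 1:5) {
    root <- withr::local_tempdir()
    store <- study_store(root)
    create_study(store, "ST")
    markers <- c("ER", "PR", "HER2")
    for (mk in markers) {
      add_marker(store, "ST", mk)
      add_slidemap(store, "ST", mk, make_map3(paste0("S-", mk), mk))
    }
    sys <- builtin_systems()[["intensity-0-3"]]
    scorers <- c("u1", "u2")
    granted <- expand.grid(scorer = scorers, marker = markers,
                           stringsAsFactors = FALSE)
    granted$ok <- stats::runif(nrow(granted)) < 0.5
    for (i in seq_len(nrow(granted))) {
      if (granted$ok[i]) grant_scorer(store, granted$scorer[i], "ST", granted$marker[i])
    }
    for (i in seq_len(nrow(granted))) {
      rec <- score_record(paste0("S-", granted$marker[i]), 1, 1,
                          granted$scorer[i], granted$marker[i],
                          values = list(intensity = 1), timestamp = ts0)
      if (granted$ok[i]) {
        expect_silent(record_score(store, "ST", rec, sys))
      } else {
        expect_error(record_score(store, "ST", rec, sys), "permission")
        expect_false(dir.exists(file.path(root, "ST", granted$marker[i],
                                          granted$scorer[i])))
      }
    }
  }
})

test_that("export_table links every scored core to its donor block", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  sys <- builtin_systems()[["intensity-0-3"]]
  # header-only before any score exists
  empty <- export_table(store, "BCAC", "ER")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("study", "marker", "scorer", "slide_id", "x", "y",
                    "donor_block_id", "timestamp") %in% names(empty)))
  record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path1", "ER", values = list(intensity = 2),
                 timestamp = ts0), sys)
  record_score(store, "BCAC",
    score_record("S-ER", 3, 3, "path1", "ER", values = list(intensity = 0),
                 timestamp = ts0), sys)
  tab <- export_table(store, "BCAC", "ER")
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$donor_block_id, "DB7")  # both replicate cores
  # two scorers on the same core: one row each in "all" mode
  record_score(store, "BCAC",
    score_record("S-ER", 1, 1, "path2", "ER", values = list(intensity = 3),
                 timestamp = ts0), sys)
  all_mode <- export_table(store, "BCAC", "ER")
  expect_identical(nrow(all_mode), 3L)
  expect_identical(nrow(export_table(store, "BCAC", "ER", scorer = "path2")), 1L)
  # row count equals a direct document scan
  docs <- list.files(file.path(root, "BCAC", "ER"), pattern = "\\.xml$",
                     recursive = TRUE)
  docs <- docs[grepl("/", docs)]
  n_pairs <- 0L
  for (d in docs) {
    doc <- xml2::read_xml(file.path(root, "BCAC", "ER", d))
    sc <- xml2::xml_find_all(doc, ".//*[local-name()='score']")
    n_pairs <- n_pairs + length(unique(paste(xml2::xml_attr(sc, "x"),
                                             xml2::xml_attr(sc, "y"))))
  }
  expect_identical(nrow(all_mode), n_pairs)
})

test_that("query_by_donor spans markers and lists replicate cores separately", {
  root <- withr::local_tempdir()
  store <- make_demo_store(root)
  sys <- builtin_systems()[["intensity-0-3"]]
  for (mk in c("ER", "PR")) {
    record_score(store, "BCAC",
      score_record(paste0("S-", mk), 1, 1, "path1", mk,
                   values = list(intensity = 2), timestamp = ts0), sys)
  }
  res <- query_by_donor(store, "DB7")
  # DB7 sits at (1,1) and (3,3) on both the ER and PR slides
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$marker), c("ER", "PR"))
  scored <- res[res$x == 1 & res$y == 1, ]
  expect_identical(vapply(scored$scores, length, 0L), c(1L, 1L))
  # brute-force oracle: direct scan over the layout tables
  brute <- sum(layout_table(make_map3()) == "DB7") * 2L
  expect_identical(nrow(res), brute)
  expect_identical(nrow(query_by_donor(store, "UNKNOWN")), 0L)
})
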