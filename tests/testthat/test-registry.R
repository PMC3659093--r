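test_that("registration makes a CDE retrievable by id, name and alternative names", {
  reg <- cde_registry()
  cde <- cde_definition("X1", "Percent stained", "how much tissue stains",
                        value_domain("real-range", min = 0, max = 100),
                        units = "%", alternative_names = c("pct", "percent"))
  reg <- register_cde(reg, cde)
  expect_identical(cde_lookup(reg, "X1"), cde)
  expect_identical(cde_lookup(reg, "Percent stained"), cde)
  expect_identical(cde_lookup(reg, "pct"), cde)
  expect_identical(cde_lookup(reg, "percent"), cde)
  expect_null(cde_lookup(reg, "PERCENT STAINED"))  # lookups are case-sensitive
})

test_that("duplicate identifiers, names and alternative names are rejected by key", {
  reg <- cde_registry()
  a <- cde_definition("A", "First", domain = value_domain("free-text"),
                      alternative_names = "block_identifier")
  reg <- register_cde(reg, a)
  expect_error(register_cde(reg, cde_definition("A", "Other",
    domain = value_domain("free-text"))), "identifier 'A'")
  expect_error(register_cde(reg, cde_definition("B", "First",
    domain = value_domain("free-text"))), "name 'First'")
  expect_error(register_cde(reg, cde_definition("B", "Second",
    domain = value_domain("free-text"),
    alternative_names = "block_identifier")), "block_identifier")
})

test_that("registering into the loaded default set preserves existing entries", {
  reg <- load_default_cdes()
  reg <- register_cde(reg, cde_definition("STUDY-1", "Study-specific score",
    domain = value_domain("integer-range", min = 0, max = 10)))
  expect_identical(length(reg), 17L)
  expect_identical(cde_lookup(reg, "Study-specific score")$identifier, "STUDY-1")
  expect_identical(cde_lookup(reg, "slide_identifier")$name,
                   "Tissue Microarray Slide Identifier")
})

test_that("the default set has 16 elements with the expected DES alternative names", {
  reg <- load_default_cdes()
  expect_identical(length(reg), 16L)
  expect_true("block_identifier" %in%
    cde_lookup(reg, "Tissue Microarray Recipient Block Identifier")$alternative_names)
  expect_true("core_results_percent-tissue-staining" %in%
    cde_lookup(reg, "Percentage tissue staining")$alternative_names)
  expect_true("core_histo-repository_donor-block" %in%
    cde_lookup(reg, "Donor Tissue Block Identifier")$alternative_names)
  expect_true("block_core_size" %in%
    cde_lookup(reg, "Tissue Microarray Recipient Block Core Diameter")$alternative_names)
  # the position-used flag has no DES equivalent
  gap <- cde_lookup(reg, "Tissue Microarray Recipient Block Core Position Used")
  expect_identical(gap$alternative_names, character(0))
})

test_that("value validation matches brute-force domain membership", {
  reg <- load_default_cdes()
  intensity <- cde_lookup(reg, "Allred Intensity Score")
  for (v in -5:8) {
    expect_identical(validate_value(intensity, v)$valid, v %in% 0:3,
                     info = paste("intensity", v))
  }
  expect_false(validate_value(intensity, 1.5)$valid)
  pct <- cde_lookup(reg, "Percentage tissue staining")
  expect_true(validate_value(pct, 45.0)$valid)
  expect_false(validate_value(pct, 101)$valid)
  expect_false(validate_value(pct, -0.1)$valid)
  binary <- cde_lookup(reg, "Binary biomarker staining result")
  expect_true(validate_value(binary, "positive")$valid)
  expect_false(validate_value(binary, "maybe")$valid)
  her2 <- cde_lookup(reg, "HER2 status by immunohistochemistry")
  expect_true(validate_value(her2, "2+")$valid)
  expect_false(validate_value(her2, "4+")$valid)
})

test_that("stepped and pattern domains validate correctly", {
  stepped <- cde_definition("S", "Even score",
    domain = value_domain("integer-range", min = 0, max = 8, step = 2))
  expect_true(validate_value(stepped, 6)$valid)
  expect_false(validate_value(stepped, 5)$valid)
  coded <- cde_definition("P", "Accession",
    domain = value_domain("free-text", pattern = "[A-Z]{2}[0-9]+"))
  expect_true(validate_value(coded, "AB12")$valid)
  expect_false(validate_value(coded, "ab12")$valid)
  expect_false(validate_value(coded, "AB12-extra")$valid)
})

test_that("registry XML round trip is the identity, including the default set", {
  reg <- load_default_cdes()
  expect_same_registry(parse_registry(serialize_registry(reg)), reg)

  path <- withr::local_tempfile(fileext = ".xml")
  serialize_registry(reg, path)
  expect_same_registry(parse_registry(path), reg)

  set.seed(101)
  for (i in 1:25) {
    r <- random_registry()
    expect_same_registry(parse_registry(serialize_registry(r)), r)
  }
})

test_that("malformed registry XML yields parse errors naming the element path", {
  no_name <- paste0(
    '<metadataRegistry xmlns="urn:tmakit:registry">',
    '<dataElement identifier="A"><definition>d</definition>',
    '<valueDomain kind="free-text"/></dataElement></metadataRegistry>')
  expect_error(parse_registry(no_name), "dataElement\\[1\\]/name")
  no_domain <- paste0(
    '<metadataRegistry xmlns="urn:tmakit:registry">',
    '<dataElement identifier="A"><name>n</name></dataElement></metadataRegistry>')
  expect_error(parse_registry(no_domain), "valueDomain")
  expect_error(parse_registry("<wrongRoot/>"), "metadataRegistry")
})

test_that("a hand-written single-CDE document parses to a registry of size 1", {
  xml <- paste0(
    '<metadataRegistry xmlns="urn:tmakit:registry">',
    '<dataElement identifier="H1"><name>Handmade</name>',
    '<definition>written by hand</definition><unit>mm</unit>',
    '<alternativeName>hm</alternativeName>',
    '<valueDomain kind="integer-range"><range min="1" max="9"/></valueDomain>',
    '</dataElement></metadataRegistry>')
  reg <- parse_registry(xml)
  expect_identical(length(reg), 1L)
  cde <- cde_lookup(reg, "hm")
  expect_identical(cde$name, "Handmade")
  expect_identical(cde$domain$min, 1)
  expect_true(validate_value(cde, 9)$valid)
})
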