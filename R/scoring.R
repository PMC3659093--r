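#' Allred composite score
#'
#' The Allred system scores oestrogen-receptor immunohistochemistry as the
#' sum of an intensity component (0-3) and a proportion component (0-5, a
#' logarithmic bin of the fraction of stained cells). The components are
#' coupled: no staining means both are 0, any staining means both are
#' positive, so a total of 1 cannot occur and totals span `{0} U [2, 8]`.
#'
#' @param intensity Integer intensity component, 0-3.
#' @param proportion Integer proportion component, 0-5.
#' @return `intensity + proportion`.
#' @examples
#' allred_total(3, 5)  # 8
#' @export
allred_total <- function(intensity, proportion) {
  if (length(intensity) != length(proportion)) {
    stop_tma("intensity and proportion must have equal length")
  }
  if (!all(intensity %in% 0:3)) stop_tma("intensity must be an integer in 0..3")
  if (!all(proportion %in% 0:5)) stop_tma("proportion must be an integer in 0..5")
  mixed <- (intensity == 0) != (proportion == 0)
  if (any(mixed)) {
    i <- which(mixed)[1L]
    stop_tma(paste0("intensity %d with proportion %d violates the Allred ",
                    "coupling rule (components are both zero or both positive)"),
             intensity[i], proportion[i])
  }
  as.integer(intensity + proportion)
}

#' Classify ER status from an Allred total
#'
#' Totals of 2 and 3 are the borderline scores that separate
#' oestrogen-receptor negative from positive tumours: a total of at most 2 is
#' negative, 3 or more is positive.
#'
#' @param total Allred total in `{0} U [2, 8]` (1 is unreachable under the
#'   component coupling rule and raises an error).
#' @return `"negative"` or `"positive"` (vectorised).
#' @examples
#' classify_er_status(c(0, 2, 3, 8))
#' @export
classify_er_status <- function(total) {
  if (!all(total %in% c(0L, 2:8))) {
    bad <- total[!total %in% c(0L, 2:8)][1L]
    stop_tma("Allred total must lie in {0} U [2, 8], got %s", format(bad))
  }
  ifelse(total <= 2, "negative", "positive")
}

#' Define a scoring system
#'
#' A scoring system is an ordered set of named fields, each bound to a CDE
#' whose value domain constrains the entered values, plus optional derived
#' fields whose values must satisfy a derivation rule (e.g. the Allred total
#' is the sum of its components).
#'
#' @param name System name.
#' @param fields Named character vector: `field_name = CDE identifier/name`.
#' @param derived_fields Named character vector: `field_name = rule id`.
#'   Supported rules: `"allred_total"`.
#' @return An object of class `tma_scoring_system`.
#' @export
scoring_system <- function(name, fields, derived_fields = character()) {
  assert_nonempty_string(name, "name")
  if (!length(fields) || is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop_tma("fields must be a named character vector")
  }
  if (anyDuplicated(names(fields))) stop_tma("field names must be unique")
  structure(
    list(name = name, fields = fields, derived_fields = derived_fields),
    class = "tma_scoring_system"
  )
}

# derivation rules: each returns a validation_result given the values map
DERIVATION_RULES <- list(
  allred_total = function(values) {
    i <- as.numeric(values[["intensity"]])
    p <- as.numeric(values[["proportion"]])
    t <- as.numeric(values[["total"]])
    if ((i == 0) != (p == 0)) {
      return(validation_result(FALSE, sprintf(
        "intensity %g with proportion %g violates the Allred coupling rule", i, p)))
    }
    if (t != i + p) {
      return(validation_result(FALSE, sprintf(
        "Allred total %g does not equal intensity %g + proportion %g", t, i, p)))
    }
    validation_result(TRUE)
  }
)

#' Built-in scoring systems
#'
#' Returns the toolkit's standard scoring systems, each with its fields bound
#' to the built-in CDE set: `allred` (intensity 0-3 + proportion 0-5 +
#' derived total), `intensity-0-3` (the plain staining-intensity scale used
#' for heatmap colouring), `percentage` (0-100% tissue staining), `her2-ihc`
#' (categories 0/1+/2+/3+), and `binary` (positive/negative).
#'
#' @param registry The CDE registry to bind against (default the built-in set).
#' @return A named list of [scoring_system()] objects.
#' @export
builtin_systems <- function(registry = load_default_cdes()) {
  systems <- list(
    "allred" = scoring_system("allred",
      fields = c(intensity = "Allred Intensity Score",
                 proportion = "Allred Proportion Score",
                 total = "Allred Score for ER status"),
      derived_fields = c(total = "allred_total")),
    "intensity-0-3" = scoring_system("intensity-0-3",
      fields = c(intensity = "Allred Intensity Score")),
    "percentage" = scoring_system("percentage",
      fields = c(percent = "Percentage tissue staining")),
    "her2-ihc" = scoring_system("her2-ihc",
      fields = c(her2 = "HER2 status by immunohistochemistry")),
    "binary" = scoring_system("binary",
      fields = c(result = "Binary biomarker staining result"))
  )
  for (sys in systems) {
    for (ref in sys$fields) {
      if (is.null(cde_lookup(registry, ref))) {
        stop_tma("scoring system '%s' references unknown CDE '%s'", sys$name, ref)
      }
    }
  }
  systems
}

#' Construct a score record
#'
#' One scorer's values for one core under one scoring system. Records are
#' immutable and versioned: re-scoring a core appends a record with a higher
#' `record_version` rather than overwriting, preserving an audit trail. A
#' status of `"no_tumour"` marks a core with no scoreable tumour tissue and
#' carries no field values.
#'
#' @param slide_id,x,y Core reference.
#' @param scorer Scorer username.
#' @param marker Stain name.
#' @param values Named list of field values (empty for `no_tumour`).
#' @param timestamp ISO-8601 timestamp; supply a fixed clock for
#'   reproducible pipelines.
#' @param record_version Positive integer version.
#' @param status `"scored"` or `"no_tumour"`.
#' @param note Optional free-text note, carried opaquely.
#' @return An object of class `tma_score`.
#' @export
score_record <- function(slide_id, x, y, scorer, marker, values = list(),
                         timestamp = iso_now(), record_version = 1L,
                         status = c("scored", "no_tumour"), note = NULL) {
  status <- match.arg(status)
  assert_nonempty_string(slide_id, "slide_id")
  assert_nonempty_string(scorer, "scorer")
  if (!is_iso_timestamp(timestamp)) {
    stop_tma("timestamp must be ISO-8601 (YYYY-MM-DDThh:mm:ssZ), got '%s'",
             as.character(timestamp))
  }
  if (status == "scored" && !length(values)) {
    stop_tma("a scored record needs at least one field value")
  }
  structure(
    list(slide_id = slide_id, x = assert_count(x, "x"), y = assert_count(y, "y"),
         scorer = scorer, marker = as.character(marker),
         values = as.list(values), timestamp = timestamp,
         record_version = assert_count(record_version, "record_version"),
         status = status, note = note),
    class = "tma_score"
  )
}

#' @export
print.tma_score <- function(x, ...) {
  vals <- if (x$status == "no_tumour") "no tumour"
          else paste(names(x$values), unlist(x$values), sep = "=", collapse = ", ")
  cat(sprintf("<tma_score %s (%d,%d) %s/%s v%d: %s>\n",
              x$slide_id, x$x, x$y, x$scorer, x$marker, x$record_version, vals))
  invisible(x)
}

#' Validate a score record against a scoring system
#'
#' A record is valid when every system field is present, every value lies in
#' its CDE's value domain, no unknown fields appear, and all derived-field
#' rules hold. `no_tumour` records carry no values and are always valid.
#'
#' @param system A [scoring_system()].
#' @param registry The CDE registry resolving the system's fields.
#' @param record A [score_record()].
#' @return A [validation_result()].
#' @examples
#' reg <- load_default_cdes()
#' sys <- builtin_systems(reg)[["allred"]]
#' rec <- score_record("S1", 1, 1, "path1", "ER",
#'                     values = list(intensity = 2, proportion = 4, total = 6),
#'                     timestamp = "2013-05-01T00:00:00Z")
#' validate_score(sys, reg, rec)
#' @export
validate_score <- function(system, registry, record) {
  stopifnot(inherits(system, "tma_scoring_system"),
            inherits(registry, "tma_registry"),
            inherits(record, "tma_score"))
  if (record$status == "no_tumour") return(validation_result(TRUE))
  unknown <- setdiff(names(record$values), names(system$fields))
  if (length(unknown)) {
    return(validation_result(FALSE, sprintf(
      "unknown field(s) for system '%s': %s", system$name,
      paste(unknown, collapse = ", "))))
  }
  missing <- setdiff(names(system$fields), names(record$values))
  if (length(missing)) {
    return(validation_result(FALSE, sprintf(
      "missing field(s) for system '%s': %s", system$name,
      paste(missing, collapse = ", "))))
  }
  for (fname in names(system$fields)) {
    cde <- cde_lookup(registry, system$fields[[fname]])
    if (is.null(cde)) {
      return(validation_result(FALSE, sprintf(
        "field '%s' references unknown CDE '%s'", fname, system$fields[[fname]])))
    }
    res <- validate_value(cde, record$values[[fname]])
    if (!res$valid) {
      return(validation_result(FALSE, sprintf("field '%s': %s", fname, res$message)))
    }
  }
  for (fname in names(system$derived_fields)) {
    rule <- DERIVATION_RULES[[system$derived_fields[[fname]]]]
    if (is.null(rule)) {
      return(validation_result(FALSE, sprintf(
        "unknown derivation rule '%s'", system$derived_fields[[fname]])))
    }
    res <- rule(record$values)
    if (!res$valid) return(res)
  }
  validation_result(TRUE)
}

# ---------------------------------------------------------------------------
# CSV interchange: long format, one row per (record, field)

SCORE_CSV_COLS <- c("slide_id", "x", "y", "scorer", "marker", "field", "value",
                    "timestamp", "record_version", "status")

#' Write score records to CSV
#'
#' Long format: one row per field of each record, with columns `slide_id, x,
#' y, scorer, marker, field, value, timestamp, record_version, status`.
#' `no_tumour` records emit a single row with an empty field.
#'
#' @param records A list of [score_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (r$status == "no_tumour" || !length(r$values)) {
      data.frame(slide_id = r$slide_id, x = r$x, y = r$y, scorer = r$scorer,
                 marker = r$marker, field = "", value = "",
                 timestamp = r$timestamp, record_version = r$record_version,
                 status = r$status, stringsAsFactors = FALSE)
    } else {
      data.frame(slide_id = r$slide_id, x = r$x, y = r$y, scorer = r$scorer,
                 marker = r$marker, field = names(r$values),
                 value = vapply(r$values, function(v) as.character(v), ""),
                 timestamp = r$timestamp, record_version = r$record_version,
                 status = r$status, stringsAsFactors = FALSE)
    }
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character()), length(SCORE_CSV_COLS)),
                                  SCORE_CSV_COLS))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read score records from CSV
#'
#' Inverse of [write_scores_csv()]; rows are grouped back into one record per
#' `(slide_id, x, y, scorer, marker, record_version)`.
#'
#' @param path CSV path.
#' @return A list of [score_record()]s.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  need <- setdiff(c("slide_id", "x", "y", "scorer", "marker", "field", "value",
                    "timestamp"), names(df))
  if (length(need)) {
    stop_tma("score CSV '%s' is missing column(s): %s", path,
             paste(need, collapse = ", "))
  }
  if (is.null(df$record_version)) df$record_version <- 1L
  if (is.null(df$status)) df$status <- "scored"
  if (!nrow(df)) return(list())
  key <- paste(df$slide_id, df$x, df$y, df$scorer, df$marker, df$record_version,
               sep = "\r")
  lapply(split(seq_len(nrow(df)), key)[unique(key)], function(idx) {
    g <- df[idx, , drop = FALSE]
    vals <- if (g$status[1L] == "no_tumour") list() else {
      v <- as.list(g$value)
      names(v) <- g$field
      # numeric-looking values come back numeric so domain checks behave
      lapply(v, function(s) {
        n <- suppressWarnings(as.numeric(s))
        if (!is.na(n) && grepl("^-?[0-9.]+$", s)) n else s
      })
    }
    score_record(g$slide_id[1L], g$x[1L], g$y[1L], g$scorer[1L], g$marker[1L],
                 values = vals, timestamp = g$timestamp[1L],
                 record_version = g$record_version[1L], status = g$status[1L])
  })
}

#' Keep only the latest version of each score
#'
#' @param records A list of [score_record()]s.
#' @return The subset holding, for each `(slide_id, x, y, scorer, marker)`,
#'   the record with the highest `record_version`.
#' @export
latest_scores <- function(records) {
  if (!length(records)) return(list())
  key <- vapply(records, function(r)
    paste(r$slide_id, r$x, r$y, r$scorer, r$marker, sep = "\r"), "")
  keep <- lapply(split(seq_along(records), key)[unique(key)], function(idx) {
    vers <- vapply(records[idx], `[[`, 0L, "record_version")
    records[[idx[which.max(vers)]]]
  })
  unname(keep)
}
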