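# ILPD-dialect CSV reading and writing.
#
# The UCI distribution is a headerless comma-separated file in the column order
# Age, Gender, TB, DB, Alkphos, Sgpt, Sgot, TP, ALB, A/G, Selector. Mirrors of
# the file differ in header presence and Gender capitalisation, so the reader
# takes an explicit column-order spec and parses Gender case-insensitively.

#' Read an ILPD-dialect CSV into a cohort
#'
#' Reads a comma-separated file in the UCI ILPD column order (or any reordering
#' given via `columns`). The raw Selector codes (1 = liver patient, 2 =
#' non-patient) are preserved; recoding to 0/1 is a separate, auditable step
#' ([recode_target()]). Blank cells are treated as missing and are only legal
#' in the A/G-ratio column. A trailing `provenance` column (written by
#' [write_cohort_csv()]) is picked up when present.
#'
#' @param path file path.
#' @param columns column-order spec: character vector naming, in file order,
#'   the standard fields `age`, `sex`, the eight biomarkers, `disease`.
#' @param header `"auto"` (detect a header line by a non-numeric age field),
#'   `"none"`, or `"present"`.
#' @param name cohort label.
#' @return A [new_cohort()] with `provenance = "original"` (unless stored in
#'   the file) and the target still un-recoded.
#' @export
read_ilpd_csv <- function(path, columns = ILPD_COLUMNS,
                          header = c("auto", "none", "present"),
                          name = "dataset1") {
  header <- match.arg(header)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty file: ", path)

  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- trimws(fields[[1]])
  has_header <- switch(header,
    none = FALSE, present = TRUE,
    auto = is.na(suppressWarnings(as.numeric(first[[match("age", columns)]]))))
  row_offset <- 0L
  if (has_header) {
    fields <- fields[-1]
    row_offset <- 1L
    if (!length(fields)) stop("parse error: header-only file: ", path)
  }

  ncol_expected <- length(columns)
  has_prov <- all(lengths(fields) == ncol_expected + 1L)
  if (!has_prov && any(lengths(fields) != ncol_expected)) {
    bad <- which(lengths(fields) != ncol_expected)[1]
    stop(sprintf("parse error at row %d: expected %d fields, found %d",
                 bad + row_offset, ncol_expected, lengths(fields)[bad]))
  }

  n <- length(fields)
  mat <- matrix("", nrow = n, ncol = ncol_expected + has_prov)
  for (i in seq_len(n)) mat[i, ] <- trimws(fields[[i]])

  parse_numeric_col <- function(col_name, allow_missing = FALSE) {
    raw <- mat[, match(col_name, columns)]
    out <- suppressWarnings(as.numeric(raw))
    blank <- !nzchar(raw) | toupper(raw) == "NA"
    bad <- which(is.na(out) & !blank)
    if (length(bad)) {
      stop(sprintf("parse error at row %d: non-numeric value '%s' in column %s",
                   bad[1] + row_offset, raw[bad[1]], col_name))
    }
    if (!allow_missing && any(blank)) {
      stop(sprintf("parse error at row %d: missing value in column %s",
                   which(blank)[1] + row_offset, col_name))
    }
    out[blank] <- NA_real_
    out
  }

  sex_raw <- tolower(mat[, match("sex", columns)])
  unknown <- which(!sex_raw %in% SEX_LEVELS)
  if (length(unknown)) {
    stop(sprintf("validation error at row %d: unknown Gender token '%s'",
                 unknown[1] + row_offset, mat[unknown[1], match("sex", columns)]))
  }

  selector <- parse_numeric_col("disease")
  if (!all(selector %in% c(1, 2))) {
    bad <- which(!selector %in% c(1, 2))[1]
    stop(sprintf("validation error at row %d: Selector value %s outside {1, 2}",
                 bad + row_offset, selector[bad]))
  }

  records <- data.frame(
    age = parse_numeric_col("age"),
    sex = factor(sex_raw, levels = SEX_LEVELS),
    stringsAsFactors = FALSE
  )
  for (b in biomarker_names()) {
    records[[b]] <- parse_numeric_col(b, allow_missing = (b == "ag_ratio"))
  }
  records$disease <- selector
  records$provenance <- if (has_prov) {
    prov <- tolower(mat[, ncol_expected + 1L])
    if (!all(prov %in% PROVENANCE_LEVELS)) {
      stop("validation error: unknown provenance token in trailing column")
    }
    prov
  } else "original"

  new_cohort(records, name = name, recoded = FALSE)
}

#' Write a cohort as an ILPD-dialect CSV
#'
#' Writes the cohort back in the UCI column order, headerless, with blank cells
#' for missing A/G ratios. By default a trailing `provenance` column is
#' appended so balanced datasets can be inspected externally; `strict_uci =
#' TRUE` drops it (re-reading then defaults provenance to `"original"`). If the
#' target has been recoded, Selector codes are reconstructed (1 = diseased,
#' 2 = healthy) so the file stays in dialect; a re-read followed by
#' [recode_target()] reproduces the labels.
#'
#' Values are written with 17 significant digits so that write-then-read is the
#' identity on doubles.
#'
#' @param cohort a cohort.
#' @param path output path.
#' @param strict_uci drop the provenance column.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, strict_uci = FALSE) {
  validate_cohort(cohort)
  if (!nrow(cohort)) stop("refusing to write an empty cohort")
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else formatC(x, digits = 17, format = "g")
    }, character(1))
    out
  }
  selector <- if (is_recoded(cohort)) ifelse(cohort$disease == 1, 1, 2) else cohort$disease
  cols <- list(
    age = fmt(cohort$age),
    sex = ifelse(cohort$sex == "male", "Male", "Female")
  )
  for (b in biomarker_names()) cols[[b]] <- fmt(cohort[[b]])
  cols$disease <- fmt(selector)
  mat <- do.call(cbind, cols[ILPD_COLUMNS])
  if (!strict_uci) mat <- cbind(mat, as.character(cohort$provenance))
  ok <- tryCatch({
    writeLines(apply(mat, 1, paste, collapse = ","), con = path)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}
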