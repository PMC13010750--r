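#' Describe one source table
#'
#' @param path CSV file path.
#' @param id_column Name of the patient-identifier column in the file.
#' @param columns Optional named character vector mapping file column names
#'   to record field names (e.g. `c(AUXU500R = "right_air_500")`). Columns
#'   not mentioned (other than the id) are ignored with a warning. `NULL`
#'   keeps all columns under their file names.
#' @param na_strings Cell values treated as missing. Default empty cells and
#'   the common NHANES-style sentinel codes "." and "NA".
#' @return Object of class `table_spec`.
#' @export
table_spec <- function(path, id_column = "patient_id", columns = NULL,
                       na_strings = c("", ".", "NA")) {
  structure(list(path = path, id_column = id_column, columns = columns,
                 na_strings = na_strings),
            class = "table_spec")
}

read_one_table <- function(spec) {
  if (!file.exists(spec$path)) stop("file not found: ", spec$path, call. = FALSE)
  df <- utils::read.csv(spec$path, stringsAsFactors = FALSE,
                        na.strings = spec$na_strings, check.names = FALSE)
  if (!spec$id_column %in% names(df)) {
    stop("id column '", spec$id_column, "' absent from ", spec$path, call. = FALSE)
  }
  dup <- df[[spec$id_column]][duplicated(df[[spec$id_column]])]
  if (length(dup) > 0) {
    stop("duplicate patient identifier(s) in ", spec$path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!is.null(spec$columns)) {
    missing <- setdiff(names(spec$columns), names(df))
    if (length(missing) > 0) {
      stop("mapped column(s) absent from ", spec$path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ignored <- setdiff(names(df), c(spec$id_column, names(spec$columns)))
    if (length(ignored) > 0) {
      warning("ignoring unmapped column(s) in ", spec$path, ": ",
              paste(ignored, collapse = ", "), call. = FALSE)
    }
    df <- df[, c(spec$id_column, names(spec$columns)), drop = FALSE]
    names(df) <- c("patient_id", unname(spec$columns))
  } else {
    names(df)[names(df) == spec$id_column] <- "patient_id"
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read and inner-join NHANES-style source tables
#'
#' Each table is read, optionally renamed through its column mapping, and
#' the tables are inner-joined on the patient identifier: only identifiers
#' present in every table yield a record.
#'
#' @param specs List of [table_spec()]s (a single spec may be passed bare).
#' @return Data frame of merged patient records, ordered by identifier.
#' @export
read_and_merge <- function(specs) {
  if (inherits(specs, "table_spec")) specs <- list(specs)
  tables <- lapply(specs, read_one_table)
  merged <- Reduce(function(a, b) merge(a, b, by = "patient_id"), tables)
  merged <- merged[order(merged$patient_id), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Complete-case filter on audiometric thresholds
#'
#' Retains only records carrying all 14 air-conduction thresholds; every
#' excluded record is logged with its missing fields.
#'
#' @param records Data frame of patient records.
#' @return List with `records` (retained) and `excluded` (data frame:
#'   patient_id, missing_fields).
#' @export
complete_case_filter <- function(records) {
  req <- all_air_cols()
  missing_cols <- setdiff(req, names(records))
  present <- intersect(req, names(records))
  miss <- lapply(seq_len(nrow(records)), function(i) {
    m <- present[is.na(as.numeric(records[i, present]))]
    c(m, missing_cols)
  })
  drop <- vapply(miss, length, 0L) > 0
  excluded <- data.frame(
    patient_id = records$patient_id[drop],
    missing_fields = vapply(miss[drop], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  retained <- records[!drop, , drop = FALSE]
  rownames(retained) <- NULL
  list(records = retained, excluded = excluded)
}

LABEL_COLS <- c("hl_type", "severity", "laterality", "treatment")

#' Write (and read back) a labeled cohort CSV
#'
#' One row per patient in stable column order: the raw record columns, the
#' four semantic label columns, then any SNOMED concept-id columns. The file
#' round-trips losslessly through [read_labeled_csv()].
#'
#' @param records Cohort data frame.
#' @param labels Label data frame from [label_cohort()] (trace column is
#'   dropped on write).
#' @param path Output path.
#' @param annotations Optional annotated table from [annotate_labels()]
#'   supplying `*_snomed` columns; when `NULL` they are derived from the
#'   shipped mapping.
#' @return `path` invisibly; `read_labeled_csv()` returns the table.
#' @export
write_labeled_csv <- function(records, labels, path, annotations = NULL) {
  if (nrow(records) != nrow(labels)) {
    stop("records and labels differ in length", call. = FALSE)
  }
  lab <- labels[, intersect(LABEL_COLS, names(labels)), drop = FALSE]
  if (is.null(annotations)) annotations <- annotate_labels(lab)
  snomed_cols <- grep("_snomed$", names(annotations), value = TRUE)
  out <- cbind(records, lab, annotations[, snomed_cols, drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labeled_csv
#' @export
read_labeled_csv <- function(path) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  classes <- stats::setNames(rep(NA, ncol(header)), names(header))
  classes[grepl("_snomed$", names(header))] <- "character"
  classes[names(header) == "patient_id"] <- "character"
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = classes)
  sn <- grepl("_snomed$", names(df))
  df[sn][is.na(df[sn])] <- ""
  df
}
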