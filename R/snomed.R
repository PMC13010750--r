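#' The shipped SNOMED CT mapping table
#'
#' Two-way lookup between internal label vocabularies and SNOMED CT concept
#' identifiers, shipped as an editable tab-separated file. Only concepts
#' with an authoritative code carry one (`status = "asserted"`); entries for
#' which no code is asserted are retained with an empty `concept_id` and
#' marked `provisional` rather than invented.
#'
#' @param path Optional path to an alternative mapping file.
#' @return Data frame: internal_label, concept_id, preferred_term, status.
#' @export
snomed_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snomed_map.tsv", package = "audisem")
  }
  map <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("internal_label", "concept_id", "preferred_term")
  if (!all(needed %in% names(map))) {
    stop("mapping file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  coded <- map$concept_id[nzchar(map$concept_id)]
  if (any(!grepl("^[0-9]+$", coded))) {
    stop("concept ids must be non-empty digit strings", call. = FALSE)
  }
  if (anyDuplicated(map$internal_label)) {
    stop("at most one concept per internal label", call. = FALSE)
  }
  map
}

#' Map an internal label to its SNOMED CT concept
#'
#' @param label An internal vocabulary value (e.g. `"sensorineural"`).
#' @param mapping Mapping table from [snomed_mapping()].
#' @return A list of class `snomed_concept` (`concept_id`, `preferred_term`,
#'   `mapped_label`), or `NULL` for labels deliberately shipped without a
#'   code.
#' @export
to_snomed <- function(label, mapping = snomed_mapping()) {
  known <- unique(c(TYPE_LEVELS, SEVERITY_LEVELS, LATERALITY_LEVELS,
                    TREATMENT_LEVELS, mapping$internal_label))
  if (length(label) != 1L || !label %in% known) {
    stop("unknown vocabulary value: ", label, call. = FALSE)
  }
  i <- match(label, mapping$internal_label)
  if (is.na(i) || !nzchar(mapping$concept_id[i])) return(NULL)
  structure(list(concept_id = mapping$concept_id[i],
                 preferred_term = mapping$preferred_term[i],
                 mapped_label = label),
            class = "snomed_concept")
}

#' Annotate a labeled table with SNOMED CT concept-id columns
#'
#' Adds one `<column>_snomed` column per label column found; cells whose
#' label has no asserted code stay empty, and no row or existing cell is
#' ever changed or reordered.
#'
#' @param labeled Data frame containing at least one of the label columns
#'   `hl_type`, `severity`, `laterality`, `treatment`.
#' @param mapping Mapping table from [snomed_mapping()].
#' @param columns Label columns to annotate; defaults to those present.
#' @return The input table with appended concept-id columns.
#' @export
annotate_labels <- function(labeled, mapping = snomed_mapping(),
                            columns = intersect(c("hl_type", "severity",
                                                  "laterality", "treatment"),
                                                names(labeled))) {
  if (length(columns) == 0 || !all(columns %in% names(labeled))) {
    stop("labeled table lacks the label column(s): ",
         paste(setdiff(columns, names(labeled)), collapse = ", "), call. = FALSE)
  }
  lookup <- stats::setNames(mapping$concept_id, mapping$internal_label)
  for (col in columns) {
    code <- unname(lookup[as.character(labeled[[col]])])
    code[is.na(code)] <- ""
    labeled[[paste0(col, "_snomed")]] <- code
  }
  labeled
}
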