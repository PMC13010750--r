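TURTLE_CLASS <- list(
  hl_type = c(normal = "Hearing_Normal", conductive = "Conductive_HL",
              sensorineural = "Sensorineural_HL", mixed = "Mixed_HL"),
  severity = c(normal = "Normal_Severity", mild = "Mild_HL", moderate = "Moderate_HL",
               severe = "Severe_HL", profound = "Profound_HL"),
  laterality = c(normal = "Laterality_Normal", bilateral = "Bilateral",
                 unilateral_left = "Unilateral_Left", unilateral_right = "Unilateral_Right"),
  treatment = c(monitoring = "Monitoring", hearing_aid = "Hearing_Aid",
                cochlear_implant_evaluation = "Cochlear_Implant_Evaluation",
                surgical_evaluation = "Surgical_Evaluation",
                auditory_rehabilitation = "Auditory_Rehabilitation")
)

#' Export labeled patients as RDF Turtle
#'
#' Serializes one named individual per patient with exactly one class
#' assertion per labeled dimension (type, severity, laterality, treatment),
#' data-property triples for age, comorbidity flags and the air-conduction
#' thresholds, and a `snomedCode` annotation for every dimension whose label
#' carries an asserted SNOMED CT concept id (labels without a code are
#' retained as class assertions but get no code annotation). The output is
#' plain Turtle parseable by any standard RDF library.
#'
#' @param records Cohort data frame.
#' @param labels Labels from [label_cohort()] (aligned row order).
#' @param path Output `.ttl` path.
#' @param mapping SNOMED mapping table from [snomed_mapping()].
#' @return `path`, invisibly.
#' @export
export_turtle <- function(records, labels, path, mapping = snomed_mapping()) {
  if (nrow(records) != nrow(labels)) {
    stop("records and labels differ in length", call. = FALSE)
  }
  base <- "http://example.org/hearing-loss#"
  lines <- c(
    paste0("@prefix hl: <", base, "> ."),
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    ""
  )
  code_of <- stats::setNames(mapping$concept_id, mapping$internal_label)
  for (i in seq_len(nrow(records))) {
    subj <- paste0("hl:", records$patient_id[i])
    classes <- vapply(names(TURTLE_CLASS), function(dim) {
      paste0("hl:", TURTLE_CLASS[[dim]][[labels[[dim]][i]]])
    }, "")
    stmts <- c(paste0(subj, " a ", paste(classes, collapse = " , ")))
    stmts <- c(stmts, sprintf("%s hl:age \"%d\"^^xsd:integer", subj,
                              as.integer(records$age[i])))
    for (fl in intersect(COMORBIDITY_FLAGS, names(records))) {
      stmts <- c(stmts, sprintf("%s hl:%s \"%s\"^^xsd:boolean", subj, fl,
                                tolower(as.character(records[[fl]][i]))))
    }
    for (col in all_air_cols()) {
      stmts <- c(stmts, sprintf("%s hl:%s \"%g\"^^xsd:decimal", subj, col,
                                records[[col]][i]))
    }
    for (dim in names(TURTLE_CLASS)) {
      code <- code_of[labels[[dim]][i]]
      if (!is.na(code) && nzchar(code)) {
        stmts <- c(stmts, sprintf("%s hl:snomedCode \"%s\"", subj, code))
      }
    }
    lines <- c(lines, paste0(stmts, " ."), "")
  }
  writeLines(lines, path)
  invisible(path)
}
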