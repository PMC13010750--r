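#' Feature-derivation configuration
#'
#' Holds the tunable clinical conventions used when deriving per-ear
#' quantities from raw thresholds.
#'
#' @param pta_freqs Frequencies (Hz) entering the pure-tone average.
#'   Default is the standard four-frequency PTA (0.5/1/2/4 kHz).
#' @param hl_cutoff Hearing-loss cutoff in dB HL: an ear "has loss" when its
#'   PTA exceeds this value. Default 25.
#' @param abg_threshold Mean air-bone gap (dB) at or above which an ear shows
#'   conductive evidence. Default 15.
#' @param bone_normal_max Largest bone-conduction PTA (dB HL) still considered
#'   normal; above it the ear shows sensorineural evidence. Default 25.
#' @param severity_cutoffs Named increasing upper band edges (dB HL) for
#'   normal/mild/moderate/severe; PTAs strictly above the last edge are
#'   profound. Default `c(normal = 25, mild = 40, moderate = 70, severe = 90)`
#'   so that a PTA exceeding 90 dB HL is profound.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(pta_freqs = c(500, 1000, 2000, 4000),
                           hl_cutoff = 25,
                           abg_threshold = 15,
                           bone_normal_max = 25,
                           severity_cutoffs = c(normal = 25, mild = 40,
                                                moderate = 70, severe = 90)) {
  if (!all(pta_freqs %in% AIR_FREQS)) {
    stop("pta_freqs must be drawn from the seven standard frequencies: ",
         paste(AIR_FREQS, collapse = ", "))
  }
  if (length(severity_cutoffs) != 4L ||
      !identical(names(severity_cutoffs), c("normal", "mild", "moderate", "severe"))) {
    stop("severity_cutoffs must be named normal/mild/moderate/severe")
  }
  if (any(diff(severity_cutoffs) <= 0)) {
    stop("severity_cutoffs must be strictly increasing")
  }
  structure(list(pta_freqs = as.numeric(pta_freqs),
                 hl_cutoff = as.numeric(hl_cutoff),
                 abg_threshold = as.numeric(abg_threshold),
                 bone_normal_max = as.numeric(bone_normal_max),
                 severity_cutoffs = severity_cutoffs),
            class = "feature_config")
}

#' Pure-tone average
#'
#' Arithmetic mean of air- (or bone-) conduction thresholds over a frequency
#' set, in dB HL.
#'
#' @param thresholds Named numeric vector, names are frequencies in Hz.
#' @param freqs Frequencies to average over.
#' @return Mean threshold in dB HL.
#' @export
pure_tone_average <- function(thresholds, freqs) {
  keys <- as.character(freqs)
  present <- keys %in% names(thresholds) & !is.na(thresholds[keys])
  if (!all(present)) {
    stop("missing threshold at frequency ", paste(keys[!present], collapse = ", "),
         " Hz", call. = FALSE)
  }
  mean(as.numeric(thresholds[keys]))
}

#' Mean air-bone gap
#'
#' Per-frequency gap `max(air - bone, 0)` averaged over `freqs`. Negative
#' per-frequency gaps are clamped to zero (measurement noise).
#'
#' @param air,bone Named numeric threshold vectors (names = Hz).
#' @param freqs Frequencies to average over.
#' @return Mean gap in dB, always >= 0.
#' @export
air_bone_gap <- function(air, bone, freqs) {
  keys <- as.character(freqs)
  for (m in list(air = air, bone = bone)) {
    present <- keys %in% names(m) & !is.na(m[keys])
    if (!all(present)) {
      stop("missing threshold at frequency ", paste(keys[!present], collapse = ", "),
           " Hz", call. = FALSE)
    }
  }
  mean(pmax(as.numeric(air[keys]) - as.numeric(bone[keys]), 0))
}

#' Band a PTA into a severity label
#'
#' Bands partition the whole line: normal up to the first cutoff, then mild,
#' moderate, severe, and profound strictly above the last cutoff (so a PTA
#' of exactly 90 dB HL is severe, 91 is profound under the defaults).
#'
#' @param pta Numeric PTA(s) in dB HL.
#' @param config A [feature_config()].
#' @return Character vector of severity labels.
#' @export
severity_band <- function(pta, config = feature_config()) {
  cut_points <- c(-Inf, config$severity_cutoffs, Inf)
  SEVERITY_LEVELS[findInterval(pta, cut_points, left.open = TRUE)]
}

extract_map <- function(record, cols, freqs) {
  v <- vapply(cols, function(col) {
    x <- record[[col]]
    if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  }, 0)
  names(v) <- as.character(freqs)
  v[!is.na(v)]
}

#' Derive per-ear clinical features
#'
#' Computes the pure-tone average, high-frequency PTA, air-bone gap (when
#' bone conduction is present) and the evidence predicates consumed by the
#' rule engine for one ear of one patient record.
#'
#' Conductive evidence: mean air-bone gap at or above `abg_threshold`; when
#' bone conduction is absent, an abnormal tympanogram together with an
#' elevated PTA stands in. Sensorineural evidence: bone-conduction PTA above
#' `bone_normal_max`; when bone conduction is absent and the tympanogram is
#' normal or missing, an elevated air PTA defaults to sensorineural evidence
#' (the most prevalent adult etiology).
#'
#' @param record One patient record (one-row data frame or named list).
#' @param side `"left"` or `"right"`.
#' @param config A [feature_config()].
#' @return A list of class `ear_features` with fields `pta`, `hf_pta`,
#'   `abg` (NA when bone absent), `has_loss`, `ear_severity`,
#'   `conductive_evidence`, `sensorineural_evidence`.
#' @export
ear_profile <- function(record, side = c("left", "right"), config = feature_config()) {
  side <- match.arg(side)
  record <- as.list(record)
  air <- extract_map(record, air_cols(side), AIR_FREQS)
  pta <- pure_tone_average(air, config$pta_freqs)
  hf <- pure_tone_average(air, c(3000, 4000, 6000))

  bcols <- bone_cols(side)
  have_bone_cols <- all(bcols %in% names(record))
  bone <- if (have_bone_cols) extract_map(record, bcols, BONE_FREQS) else numeric(0)
  bone_present <- all(as.character(config$pta_freqs) %in% names(bone))

  tcol <- paste0(side, "_tymp_abnormal")
  tymp <- if (tcol %in% names(record)) record[[tcol]] else NA
  tymp_present <- !is.na(tymp)

  has_loss <- pta > config$hl_cutoff

  if (bone_present) {
    abg <- air_bone_gap(air, bone, config$pta_freqs)
    bone_pta <- pure_tone_average(bone, config$pta_freqs)
    conductive <- abg >= config$abg_threshold
    sensorineural <- bone_pta > config$bone_normal_max
  } else {
    abg <- NA_real_
    conductive <- tymp_present && isTRUE(tymp) && has_loss
    sensorineural <- (!tymp_present && has_loss) ||
      (tymp_present && !isTRUE(tymp) && has_loss)
  }

  structure(list(pta = pta,
                 hf_pta = hf,
                 abg = abg,
                 has_loss = has_loss,
                 ear_severity = severity_band(pta, config),
                 conductive_evidence = conductive,
                 sensorineural_evidence = sensorineural),
            class = "ear_features")
}

#' Per-ear features for a whole cohort
#'
#' Vectorized companion of [ear_profile()]: one row per patient with
#' left/right PTAs, air-bone gaps, evidence flags, plus the patient-level
#' aggregates (`worse_pta`, `conductive_any`, `sensorineural_any`,
#' `has_loss_any`) that the rule base conditions on.
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param config A [feature_config()].
#' @return Data frame of engine-ready features, one row per patient.
#' @export
cohort_ear_features <- function(cohort, config = feature_config()) {
  n <- nrow(cohort)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    l <- ear_profile(cohort[i, ], "left", config)
    r <- ear_profile(cohort[i, ], "right", config)
    out[[i]] <- data.frame(
      left_pta = l$pta, right_pta = r$pta,
      left_hf_pta = l$hf_pta, right_hf_pta = r$hf_pta,
      left_abg = l$abg, right_abg = r$abg,
      left_has_loss = l$has_loss, right_has_loss = r$has_loss,
      left_conductive_evidence = l$conductive_evidence,
      right_conductive_evidence = r$conductive_evidence,
      left_sensorineural_evidence = l$sensorineural_evidence,
      right_sensorineural_evidence = r$sensorineural_evidence
    )
  }
  feats <- do.call(rbind, out)
  feats$worse_pta <- pmax(feats$left_pta, feats$right_pta)
  feats$conductive_any <- feats$left_conductive_evidence | feats$right_conductive_evidence
  feats$sensorineural_any <- feats$left_sensorineural_evidence | feats$right_sensorineural_evidence
  feats$has_loss_any <- feats$left_has_loss | feats$right_has_loss
  rownames(feats) <- NULL
  feats
}

#' Model feature vector for one record
#'
#' Deterministic, stably named vector of raw model inputs: age, the six
#' comorbidity flags, the 14 air-conduction thresholds and (when present)
#' the two tympanometry flags. When `include_semantic` is given, the listed
#' semantic label columns are appended as categorical values.
#'
#' @param record One patient record.
#' @param config A [feature_config()] (reserved for derived variants).
#' @param include_semantic Optional named character vector of semantic labels
#'   (e.g. `c(Has_Severity = "mild", Has_Laterality = "bilateral")`).
#' @return Named character/numeric vector (as a named list) in stable order.
#' @export
feature_vector <- function(record, config = feature_config(), include_semantic = NULL) {
  record <- as.list(record)
  cols <- c("age", COMORBIDITY_FLAGS, all_air_cols())
  missing <- setdiff(cols, names(record))
  if (length(missing) > 0 || anyNA(unlist(record[cols], use.names = FALSE))) {
    bad <- c(missing, cols[vapply(record[intersect(cols, names(record))], function(x) any(is.na(x)), TRUE)])
    stop("incomplete record: missing ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  v <- record[cols]
  for (tc in c("left_tymp_abnormal", "right_tymp_abnormal")) {
    if (tc %in% names(record) && !is.na(record[[tc]])) v[[tc]] <- as.integer(record[[tc]])
  }
  if (!is.null(include_semantic)) {
    v <- c(v, as.list(include_semantic))
  }
  v
}

#' Model feature table for a cohort
#'
#' Cohort-level version of [feature_vector()]: a data frame with one row per
#' patient, flags encoded as 0/1 integers and semantic columns (if supplied)
#' as factors.
#'
#' @param cohort Cohort data frame.
#' @param config A [feature_config()].
#' @param semantic Optional data frame of semantic feature columns (same row
#'   order as `cohort`), e.g. severity and laterality labels.
#' @return Data frame of model inputs.
#' @export
feature_table <- function(cohort, config = feature_config(), semantic = NULL) {
  cols <- c("age", COMORBIDITY_FLAGS, all_air_cols())
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    stop("incomplete cohort: missing ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- cohort[, cols, drop = FALSE]
  for (fl in COMORBIDITY_FLAGS) x[[fl]] <- as.integer(x[[fl]])
  for (tc in c("left_tymp_abnormal", "right_tymp_abnormal")) {
    if (tc %in% names(cohort)) x[[tc]] <- as.integer(cohort[[tc]])
  }
  if (anyNA(x)) stop("incomplete cohort: missing values in model inputs", call. = FALSE)
  if (!is.null(semantic)) {
    stopifnot(nrow(semantic) == nrow(cohort))
    vocab <- list(TYPE_LEVELS, SEVERITY_LEVELS, LATERALITY_LEVELS, TREATMENT_LEVELS)
    for (nm in names(semantic)) {
      vals <- as.character(semantic[[nm]])
      hit <- vapply(vocab, function(v) all(vals %in% v), TRUE)
      # keep the clinical level order (severity is ordinal) rather than alphabetical
      lv <- if (any(hit)) intersect(vocab[[which(hit)[1]]], unique(vals)) else sort(unique(vals))
      x[[nm]] <- factor(vals, levels = lv)
    }
  }
  rownames(x) <- NULL
  x
}

#' Read/write a feature configuration file
#'
#' Plain-text `key = value` format; frequencies are comma-separated Hz,
#' thresholds are in dB HL.
#'
#' @param config A [feature_config()].
#' @param path File path.
#' @return `read_feature_config()` returns a `feature_config`;
#'   `write_feature_config()` returns `path` invisibly.
#' @export
write_feature_config <- function(config, path) {
  lines <- c(
    paste0("pta_freqs = ", paste(config$pta_freqs, collapse = ",")),
    paste0("hl_cutoff = ", config$hl_cutoff),
    paste0("abg_threshold = ", config$abg_threshold),
    paste0("bone_normal_max = ", config$bone_normal_max),
    paste0("severity_cutoffs = ", paste(config$severity_cutoffs, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_config
#' @export
read_feature_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get_num <- function(key) as.numeric(strsplit(vals[match(key, keys)], ",")[[1]])
  sev <- get_num("severity_cutoffs")
  names(sev) <- c("normal", "mild", "moderate", "severe")
  feature_config(pta_freqs = get_num("pta_freqs"),
                 hl_cutoff = get_num("hl_cutoff"),
                 abg_threshold = get_num("abg_threshold"),
                 bone_normal_max = get_num("bone_normal_max"),
                 severity_cutoffs = sev)
}
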