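# Shared fixtures built in code: small cohorts with known generative truth.

air_cols <- function(side) {
  paste0(side, "_air_", c(500, 1000, 2000, 3000, 4000, 6000, 8000))
}
all_air_cols <- function() c(air_cols("left"), air_cols("right"))
SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe", "profound")

default_flags <- function() {
  list(diabetes = FALSE, hypertension = FALSE, cardiovascular = FALSE,
       noise_exposure = FALSE, smoking = FALSE, alcohol = FALSE)
}

# Assemble one patient record from an audiogram produced by sample_audiogram().
record_from_audiogram <- function(id, a, age = 50, sex = "female",
                                  ethnicity = "white") {
  row <- c(list(patient_id = id, age = age, sex = sex, ethnicity = ethnicity),
           default_flags(),
           stats::setNames(as.list(a$left_air), paste0("left_air_", names(a$left_air))),
           stats::setNames(as.list(a$right_air), paste0("right_air_", names(a$right_air))))
  if (!is.null(a$left_bone)) {
    row <- c(row,
             stats::setNames(as.list(a$left_bone), paste0("left_bone_", names(a$left_bone))),
             stats::setNames(as.list(a$right_bone), paste0("right_bone_", names(a$right_bone))))
  }
  row$left_tymp_abnormal <- a$left_tymp_abnormal
  row$right_tymp_abnormal <- a$right_tymp_abnormal
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Cohort with fully prescribed per-patient truth (types/severities/lateralities
# recycled to a common length), deterministic per seed.
build_cohort <- function(types, severities, lateralities, config, seed = 1L) {
  n <- max(length(types), length(severities), length(lateralities))
  types <- rep_len(types, n)
  severities <- rep_len(severities, n)
  lateralities <- rep_len(lateralities, n)
  affected <- c(normal = "none", bilateral = "both",
                unilateral_left = "left", unilateral_right = "right")
  lateralities[types == "normal"] <- "normal"
  severities[types == "normal"] <- "normal"
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      a <- sample_audiogram(types[i], severities[i], affected[[lateralities[i]]], config)
      record_from_audiogram(sprintf("T%03d", i), a)
    })
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = data.frame(patient_id = cohort$patient_id, true_type = types,
                          true_severity = ifelse(types == "normal", "normal", severities),
                          true_laterality = ifelse(types == "normal", "normal", lateralities),
                          stringsAsFactors = FALSE))
}

# Flat-audiogram record: every air (and bone) threshold at `level` dB HL in
# both ears; bone equal to air so there is no air-bone gap.
flat_record <- function(id, level) {
  freqs <- c(500, 1000, 2000, 3000, 4000, 6000, 8000)
  bfreqs <- c(500, 1000, 2000, 4000)
  a <- list(left_air = stats::setNames(rep(level, 7), freqs),
            right_air = stats::setNames(rep(level, 7), freqs),
            left_bone = stats::setNames(rep(level, 4), bfreqs),
            right_bone = stats::setNames(rep(level, 4), bfreqs),
            left_tymp_abnormal = FALSE, right_tymp_abnormal = FALSE)
  record_from_audiogram(id, a)
}

# Random complete records spanning both evidence pathways (bone present or
# absent, tympanometry present or absent), for oracle-equivalence sweeps.
random_records <- function(n, seed = 1L) {
  freqs <- c(500, 1000, 2000, 3000, 4000, 6000, 8000)
  bfreqs <- c(500, 1000, 2000, 4000)
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      mk <- function(k) round(stats::runif(k, -10, 120))
      has_bone <- stats::runif(1) < 0.7
      tymp <- sample(c(NA, TRUE, FALSE), 2, replace = TRUE)
      a <- list(left_air = stats::setNames(mk(7), freqs),
                right_air = stats::setNames(mk(7), freqs),
                left_bone = stats::setNames(if (has_bone) mk(4) else rep(NA_real_, 4), bfreqs),
                right_bone = stats::setNames(if (has_bone) mk(4) else rep(NA_real_, 4), bfreqs),
                left_tymp_abnormal = tymp[1], right_tymp_abnormal = tymp[2])
      record_from_audiogram(sprintf("R%05d", i), a)
    })
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

# Straight-line labeling of one record: the non-engine reimplementation of
# the four classification decisions, used as the oracle for the rule engine.
straightline_labels <- function(record, config = feature_config()) {
  l <- ear_profile(record, "left", config)
  r <- ear_profile(record, "right", config)
  ty <- classify_type(l, r)
  sv <- classify_severity(l, r, config, hl_type = ty)
  lt <- classify_laterality(l, r)
  tx <- recommend_treatment(list(hl_type = ty, severity = sv, laterality = lt))
  list(hl_type = ty, severity = sv, laterality = lt, treatment = tx)
}
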