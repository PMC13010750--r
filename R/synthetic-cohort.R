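#' Synthetic cohort configuration
#'
#' Defines the generative conditions for an NHANES-style audiometric cohort:
#' the mixture of hearing-loss types, the severity and laterality mixtures
#' among affected patients, measurement noise, audiometer quantization and
#' comorbidity prevalences.
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Integer seed; identical config + seed reproduce the cohort
#'   byte-identically.
#' @param type_mix Proportions over normal/conductive/sensorineural/mixed,
#'   summing to 1.
#' @param severity_mix Proportions over mild/moderate/severe/profound for
#'   affected ears. (Mixed-type patients cannot present as "mild": with a
#'   total loss of at most 40 dB HL there is no room for both a >= 20 dB
#'   air-bone gap and an elevated bone-conduction PTA, so for those patients
#'   the mixture is renormalized over moderate/severe/profound.)
#' @param laterality_mix Proportions over bilateral/unilateral_left/
#'   unilateral_right for affected patients.
#' @param noise_sd Gaussian measurement noise SD in dB added to every
#'   threshold before quantization. Default 5 (typical test-retest spread).
#' @param quantization_step Audiometer resolution in dB. Default 5.
#' @param comorbidity_prevalences Named per-flag Bernoulli probabilities.
#' @param missing_rate Fraction of audiometric cells blanked afterwards by
#'   [inject_missingness()]; stored here for pipeline convenience.
#' @param bone_conduction Generate bone-conduction thresholds at the PTA
#'   frequencies? NHANES itself lacks them; the default keeps them so the
#'   air-bone-gap evidence pathway is exercised.
#' @param tymp_abnormal_prob Probability that a conductive or mixed ear shows
#'   an abnormal tympanogram. Default 0.95.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          type_mix = c(normal = 0.40, conductive = 0.15,
                                       sensorineural = 0.35, mixed = 0.10),
                          severity_mix = c(mild = 0.45, moderate = 0.35,
                                           severe = 0.12, profound = 0.08),
                          laterality_mix = c(bilateral = 0.60,
                                             unilateral_left = 0.20,
                                             unilateral_right = 0.20),
                          noise_sd = 5,
                          quantization_step = 5,
                          comorbidity_prevalences = c(diabetes = 0.12,
                                                      hypertension = 0.35,
                                                      cardiovascular = 0.08,
                                                      noise_exposure = 0.25,
                                                      smoking = 0.20,
                                                      alcohol = 0.55),
                          missing_rate = 0,
                          bone_conduction = TRUE,
                          tymp_abnormal_prob = 0.95) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0) {
    stop("n_patients must be a single non-negative count", call. = FALSE)
  }
  check_mix <- function(mix, expected, what) {
    if (!identical(sort(names(mix)), sort(expected)) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-9) {
      stop(what, " must be non-negative proportions over {",
           paste(expected, collapse = ", "), "} summing to 1", call. = FALSE)
    }
    mix[expected]
  }
  type_mix <- check_mix(type_mix, c("normal", "conductive", "sensorineural", "mixed"),
                        "type_mix")
  severity_mix <- check_mix(severity_mix, c("mild", "moderate", "severe", "profound"),
                            "severity_mix")
  laterality_mix <- check_mix(laterality_mix,
                              c("bilateral", "unilateral_left", "unilateral_right"),
                              "laterality_mix")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (quantization_step <= 0) stop("quantization_step must be > 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]", call. = FALSE)
  if (!identical(sort(names(comorbidity_prevalences)), sort(COMORBIDITY_FLAGS))) {
    stop("comorbidity_prevalences must name the six flags", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 type_mix = type_mix,
                 severity_mix = severity_mix,
                 laterality_mix = laterality_mix,
                 noise_sd = noise_sd,
                 quantization_step = quantization_step,
                 comorbidity_prevalences = comorbidity_prevalences[COMORBIDITY_FLAGS],
                 missing_rate = missing_rate,
                 bone_conduction = isTRUE(bone_conduction),
                 tymp_abnormal_prob = tymp_abnormal_prob),
            class = "cohort_config")
}

quantize <- function(x, step) round(x / step) * step

clamp_db <- function(x) pmin(pmax(x, -10), 120)

# Severity band interiors for the noise-free PTA target, kept >= 3 dB away
# from the band edges so that 5 dB quantization (which can move a
# four-frequency PTA by at most 2.5 dB) cannot cross a boundary.
severity_target_range <- function(severity) {
  switch(severity,
         mild     = c(28, 37),
         moderate = c(44, 67),
         severe   = c(74, 87),
         profound = c(94, 106),
         stop("unknown severity: ", severity))
}

# Audiogram shapes: sensorineural and mixed ears slope upward above 2 kHz
# (high-frequency loss); conductive ears are flat. Offsets over the PTA
# frequencies average to zero so the target PTA is preserved.
SHAPE_SLOPING <- c(`500` = -10, `1000` = -5, `2000` = 3, `3000` = 8,
                   `4000` = 12, `6000` = 15, `8000` = 18)
SHAPE_FLAT <- c(`500` = 2, `1000` = 0, `2000` = -1, `3000` = -1,
                `4000` = -1, `6000` = 0, `8000` = 1)

normal_ear_air <- function() {
  stats::setNames(sample(c(0, 5, 10, 15), length(AIR_FREQS), replace = TRUE),
                  as.character(AIR_FREQS))
}

affected_ear_air <- function(true_type, true_severity) {
  rng <- severity_target_range(true_severity)
  if (true_type == "mixed") rng[1] <- max(rng[1], 48)
  target <- stats::runif(1, rng[1], rng[2])
  shape <- if (true_type == "conductive") SHAPE_FLAT else SHAPE_SLOPING
  # per-patient audiogram configuration variability; mean-centered over the
  # PTA frequencies so the target PTA (and its severity band) is preserved
  jitter <- stats::runif(length(AIR_FREQS), -10, 10)
  names(jitter) <- as.character(AIR_FREQS)
  pf <- as.character(c(500, 1000, 2000, 4000))
  jitter[pf] <- jitter[pf] - mean(jitter[pf])
  stats::setNames(target + shape[as.character(AIR_FREQS)] + jitter,
                  as.character(AIR_FREQS))
}

ear_bone <- function(air, true_type) {
  a <- air[as.character(BONE_FREQS)]
  bone <- switch(true_type,
    normal = a,
    sensorineural = a,
    conductive = pmin(pmax(a - sample(seq(25, 40, by = 5), 1), 0), 20),
    mixed = {
      pta <- mean(air[as.character(c(500, 1000, 2000, 4000))])
      gaps <- c(20, 25, 30)
      gap <- sample(rep(gaps[gaps <= pta - 28], 2L), 1L)
      a - gap
    })
  stats::setNames(bone, as.character(BONE_FREQS))
}

#' Sample one patient's audiogram from its generative truth
#'
#' Produces per-ear air-conduction maps (7 frequencies), bone-conduction
#' maps (4 PTA frequencies) and tympanometry flags consistent with the true
#' type/severity: sensorineural ears slope upward at high frequencies with
#' air ~ bone; conductive ears are flat with normal bone and an air-bone gap
#' of at least 20 dB; mixed ears show both patterns; unaffected/normal ears
#' have all thresholds at or below 20 dB HL. Noise and quantization from
#' `config` are applied last. Uses the current RNG stream.
#'
#' @param true_type One of normal/conductive/sensorineural/mixed.
#' @param true_severity One of mild/moderate/severe/profound (ignored for
#'   normal type).
#' @param affected `"none"`, `"left"`, `"right"` or `"both"`.
#' @param config A [cohort_config()].
#' @return List with `left_air`, `right_air`, `left_bone`, `right_bone`
#'   (NULL when bone generation is off), `left_tymp_abnormal`,
#'   `right_tymp_abnormal`.
#' @export
sample_audiogram <- function(true_type, true_severity, affected, config) {
  stopifnot(true_type %in% TYPE_LEVELS,
            affected %in% c("none", "left", "right", "both"))
  if (true_type == "normal") affected <- "none"
  one_ear <- function(is_affected) {
    type <- if (is_affected) true_type else "normal"
    air <- if (is_affected) affected_ear_air(true_type, true_severity) else normal_ear_air()
    bone <- if (config$bone_conduction) ear_bone(air, type) else NULL
    tymp <- if (type %in% c("conductive", "mixed")) {
      stats::runif(1) < config$tymp_abnormal_prob
    } else FALSE
    noisy <- function(v) {
      if (is.null(v)) return(NULL)
      v <- v + stats::rnorm(length(v), 0, config$noise_sd)
      clamp_db(quantize(v, config$quantization_step))
    }
    list(air = noisy(air), bone = noisy(bone), tymp = tymp)
  }
  left <- one_ear(affected %in% c("left", "both"))
  right <- one_ear(affected %in% c("right", "both"))
  list(left_air = left$air, right_air = right$air,
       left_bone = left$bone, right_bone = right$bone,
       left_tymp_abnormal = left$tymp, right_tymp_abnormal = right$tymp)
}

#' Generate a synthetic NHANES-style cohort with known truth
#'
#' Samples patient-level generative truth (type, severity, laterality) from
#' the configured mixtures, then audiograms, demographics and comorbidity
#' flags. The same config and seed reproduce the output exactly.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (data frame, one row per patient) and `truth`
#'   (data frame: patient_id, true_type, true_severity, true_laterality).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  empty_truth <- data.frame(patient_id = character(0), true_type = character(0),
                            true_severity = character(0), true_laterality = character(0),
                            stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(cohort = empty_cohort(config), truth = empty_truth))
  }
  withr::with_seed(config$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    types <- sample(names(config$type_mix), n, replace = TRUE, prob = config$type_mix)
    sev_for <- function(type) {
      if (type == "normal") return("normal")
      mix <- config$severity_mix
      if (type == "mixed") {
        mix <- mix[c("moderate", "severe", "profound")]
        if (sum(mix) == 0) mix[] <- c(1, 0, 0)
      }
      sample(names(mix), 1L, prob = mix)
    }
    severities <- vapply(types, sev_for, "", USE.NAMES = FALSE)
    lats <- ifelse(types == "normal", "normal",
                   sample(names(config$laterality_mix), n, replace = TRUE,
                          prob = config$laterality_mix))
    affected <- c(normal = "none", bilateral = "both",
                  unilateral_left = "left", unilateral_right = "right")[lats]

    age <- sample(20:85, n, replace = TRUE)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    ethnicity <- sample(c("mexican_american", "other_hispanic", "white",
                          "black", "asian", "other"), n, replace = TRUE)
    flags <- lapply(config$comorbidity_prevalences,
                    function(p) stats::runif(n) < p)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      a <- sample_audiogram(types[i], severities[i], affected[[i]], config)
      row <- c(list(patient_id = ids[i], age = age[i], sex = sex[i],
                    ethnicity = ethnicity[i]),
               lapply(flags, `[[`, i),
               stats::setNames(as.list(a$left_air), air_cols("left")),
               stats::setNames(as.list(a$right_air), air_cols("right")))
      if (config$bone_conduction) {
        row <- c(row,
                 stats::setNames(as.list(a$left_bone), bone_cols("left")),
                 stats::setNames(as.list(a$right_bone), bone_cols("right")))
      }
      row$left_tymp_abnormal <- a$left_tymp_abnormal
      row$right_tymp_abnormal <- a$right_tymp_abnormal
      rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    truth <- data.frame(patient_id = ids, true_type = types,
                        true_severity = severities, true_laterality = lats,
                        stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}

empty_cohort <- function(config) {
  cols <- c("patient_id", "age", "sex", "ethnicity", COMORBIDITY_FLAGS,
            all_air_cols(),
            if (config$bone_conduction) c(bone_cols("left"), bone_cols("right")),
            "left_tymp_abnormal", "right_tymp_abnormal")
  df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  df$patient_id <- character(0)
  df
}

#' Blank a random fraction of audiometric cells
#'
#' Each air- and bone-conduction cell is independently blanked (set to NA)
#' with probability `rate`; demographics, flags and tympanometry are never
#' touched. Deterministic per seed.
#'
#' @param cohort Cohort data frame.
#' @param rate Fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return The cohort with some audiometric cells set to NA.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop("rate must be in [0, 1]", call. = FALSE)
  }
  cols <- intersect(c(all_air_cols(), bone_cols("left"), bone_cols("right")),
                    names(cohort))
  if (rate == 0 || nrow(cohort) == 0L) return(cohort)
  withr::with_seed(as.integer(seed), {
    for (col in cols) {
      blank <- stats::runif(nrow(cohort)) < rate
      cohort[[col]][blank] <- NA_real_
    }
  })
  cohort
}
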