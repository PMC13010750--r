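ef <- function(pta = 10, cond = FALSE, sens = FALSE, cutoff = 25) {
  structure(list(pta = pta, hf_pta = pta, abg = if (cond) 30 else 0,
                 has_loss = pta > cutoff, ear_severity = severity_band(pta),
                 conductive_evidence = cond, sensorineural_evidence = sens),
            class = "ear_features")
}

test_that("type classification follows the patient-level evidence table", {
  expect_identical(classify_type(ef(60, cond = TRUE), ef(60, sens = TRUE)), "mixed")
  expect_identical(classify_type(ef(60, cond = TRUE, sens = TRUE), ef(10)), "mixed")
  expect_identical(classify_type(ef(10), ef(10)), "normal")
  expect_identical(classify_type(ef(50, cond = TRUE), ef(10)), "conductive")
  expect_identical(classify_type(ef(50, sens = TRUE), ef(10)), "sensorineural")
  # loss without any evidence defaults to sensorineural
  expect_identical(classify_type(ef(50), ef(10)), "sensorineural")
})

test_that("severity uses the worse ear with a strict reading of 'exceeds 90'", {
  expect_identical(classify_severity(ef(91, sens = TRUE), ef(10)), "profound")
  expect_identical(classify_severity(ef(90, sens = TRUE), ef(10)), "severe")
  expect_identical(classify_severity(ef(10), ef(10)), "normal")
  expect_identical(classify_severity(ef(30, sens = TRUE), ef(55, sens = TRUE)),
                   "moderate")
  # consistency clamp against the type label
  expect_identical(classify_severity(ef(20, cond = TRUE), ef(10), hl_type = "conductive"),
                   "mild")
  expect_identical(classify_severity(ef(10), ef(10), hl_type = "normal"), "normal")
})

test_that("laterality reflects which ears have loss", {
  expect_identical(classify_laterality(ef(50, sens = TRUE), ef(50, sens = TRUE)),
                   "bilateral")
  expect_identical(classify_laterality(ef(50, sens = TRUE), ef(10)), "unilateral_left")
  expect_identical(classify_laterality(ef(10), ef(50, sens = TRUE)), "unilateral_right")
  expect_identical(classify_laterality(ef(10), ef(10)), "normal")
})

test_that("treatment recommendation implements the decision table", {
  tx <- function(ty, sv, lt) {
    recommend_treatment(list(hl_type = ty, severity = sv, laterality = lt))
  }
  expect_identical(tx("sensorineural", "profound", "bilateral"),
                   "cochlear_implant_evaluation")
  expect_identical(tx("sensorineural", "severe", "bilateral"),
                   "cochlear_implant_evaluation")
  expect_identical(tx("sensorineural", "severe", "unilateral_left"), "hearing_aid")
  expect_identical(tx("sensorineural", "mild", "bilateral"), "hearing_aid")
  expect_identical(tx("conductive", "moderate", "unilateral_left"),
                   "surgical_evaluation")
  expect_identical(tx("mixed", "severe", "bilateral"), "surgical_evaluation")
  expect_identical(tx("normal", "normal", "normal"), "monitoring")
  expect_error(recommend_treatment(list(hl_type = "normal")), "inferred")
})

test_that("apply_rule_base labels every dimension with a sound trace", {
  rules <- default_rule_base()
  lookup <- stats::setNames(
    lapply(rules$rules, function(r) r[c("dimension", "assign", "kind")]),
    vapply(rules$rules, `[[`, "", "id")
  )
  g <- build_cohort(c("normal", "conductive", "sensorineural", "mixed"),
                    c("normal", "moderate", "profound", "severe"),
                    c("normal", "bilateral", "bilateral", "unilateral_left"),
                    cohort_config(1, seed = 1, noise_sd = 0), seed = 8)
  labs <- label_cohort(g$cohort)
  dim_col <- c(type = "hl_type", severity = "severity",
               laterality = "laterality", treatment = "treatment")
  for (i in seq_len(nrow(labs))) {
    trace <- labs$trace[[i]]
    expect_gt(length(trace), 0)
    for (dim in names(dim_col)) {
      asserting <- vapply(trace, function(id) {
        r <- lookup[[id]]
        r$kind == "assign" && r$dimension == dim &&
          r$assign == labs[[dim_col[[dim]]]][i]
      }, TRUE)
      expect_true(any(asserting))
    }
  }
  # the noise-free conductive/moderate/bilateral patient gets the full tuple
  expect_identical(unlist(labs[2, c("hl_type", "severity", "laterality", "treatment")],
                          use.names = FALSE),
                   c("conductive", "moderate", "bilateral", "surgical_evaluation"))
  # record independence: permuting the cohort permutes the labels
  perm <- c(3, 1, 4, 2)
  labs_perm <- label_cohort(g$cohort[perm, ])
  expect_identical(labs_perm$hl_type, labs$hl_type[perm])
  # missing audiometric data is rejected, mirroring the complete-case policy
  broken <- g$cohort
  broken$right_air_4000[1] <- NA
  expect_error(label_cohort(broken), "4000")
})

test_that("rule engine agrees with the straight-line reimplementation", {
  recs <- random_records(10000, seed = 33)
  engine <- label_cohort(recs)
  oracle <- lapply(seq_len(nrow(recs)), function(i) straightline_labels(recs[i, ]))
  expect_identical(engine$hl_type, vapply(oracle, `[[`, "", "hl_type"))
  expect_identical(engine$severity, vapply(oracle, `[[`, "", "severity"))
  expect_identical(engine$laterality, vapply(oracle, `[[`, "", "laterality"))
  expect_identical(engine$treatment, vapply(oracle, `[[`, "", "treatment"))
})

test_that("severity inference is monotone in the air thresholds", {
  recs <- random_records(60, seed = 21)
  labs <- label_cohort(recs)
  cols <- all_air_cols()
  withr::with_seed(13, {
    for (i in seq_len(nrow(recs))) {
      bumped <- recs[i, ]
      bumped[cols] <- pmin(as.numeric(bumped[cols]) + sample(0:20, 14, TRUE), 120)
      after <- apply_rule_base(bumped)
      expect_gte(match(after$severity, SEVERITY_LEVELS),
                 match(labs$severity[i], SEVERITY_LEVELS))
    }
  })
})

test_that("the shipped rule base sweeps clean on the full synthetic grid", {
  v <- validate_rule_base(default_rule_base())
  expect_true(v$exhaustive)
  expect_true(v$exclusive)
  expect_length(v$unreachable_rules, 0)
  expect_identical(v$n_grid, 121L * 121L * 16L)
})

test_that("defective rule bases are reported, not masked", {
  rules <- default_rule_base()
  ids <- vapply(rules$rules, `[[`, "", "id")
  # drop every severity rule except profound -> gaps below 90 dB
  crippled <- rule_base(rules$rules[!(ids %in% c("sev_normal", "sev_severe",
                                                 "sev_moderate", "sev_mild"))])
  v1 <- validate_rule_base(crippled, by = 5)
  expect_false(v1$exhaustive)
  expect_true("severity" %in% names(v1$exhaustiveness_violations))

  # contradictory equal-priority type rules -> exclusivity violation
  clash <- rule_base(c(rules$rules, list(
    rule("type_clash", "type", 1L, "conductive_any & sensorineural_any", "conductive")
  )))
  v2 <- validate_rule_base(clash, by = 5)
  expect_false(v2$exclusive)
  expect_identical(v2$exclusivity_violations[[1]]$dimension, "type")
})

test_that("rule bases round-trip through the text format", {
  rules <- default_rule_base()
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_rule_base(rules, p1)
  back <- read_rule_base(p1)
  expect_equal(back, rules)
  write_rule_base(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(rule("bad", "type", 1L, "system('ls')", "normal"), "not allowed")
  expect_error(rule("bad", "type", 1L, "conductive_any", "blue"), "vocabulary")
})
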