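freqs4 <- c(500, 1000, 2000, 4000)

test_that("pure-tone average is the arithmetic mean and names missing data", {
  flat <- stats::setNames(rep(40, 7), c(500, 1000, 2000, 3000, 4000, 6000, 8000))
  expect_equal(pure_tone_average(flat, freqs4), 40)
  expect_equal(pure_tone_average(c(`500` = 20, `1000` = 30, `2000` = 40, `4000` = 50),
                                 freqs4), 35)
  expect_error(pure_tone_average(c(`500` = 20, `1000` = 30, `4000` = 50), freqs4),
               "2000")
})

test_that("air-bone gap averages per-frequency clamped differences", {
  mk <- function(v) stats::setNames(rep(v, 4), freqs4)
  expect_equal(air_bone_gap(mk(30), mk(30), freqs4), 0)
  expect_equal(air_bone_gap(mk(45), mk(15), freqs4), 30)
  expect_equal(air_bone_gap(mk(10), mk(20), freqs4), 0)
  expect_error(air_bone_gap(mk(30)[-1], mk(30), c(500, freqs4[-1])), "500")
})

test_that("severity bands partition the PTA axis with strict 'exceeds' edges", {
  expect_identical(severity_band(c(-10, 25, 26, 40, 41, 70, 71, 90, 91, 120)),
                   c("normal", "normal", "mild", "mild", "moderate", "moderate",
                     "severe", "severe", "profound", "profound"))
  # monotone and total over the clinical range
  pta <- seq(-10, 120, by = 0.5)
  idx <- match(severity_band(pta), c("normal", "mild", "moderate", "severe", "profound"))
  expect_true(all(diff(idx) >= 0))
  expect_false(anyNA(idx))
})

test_that("ear_profile derives evidence predicates as documented", {
  quiet <- flat_record("q", 10)
  quiet$left_bone_500 <- NA  # knock out bone -> tympanometry pathway
  quiet[paste0("left_bone_", freqs4)] <- NA
  l <- ear_profile(quiet, "left")
  expect_false(l$has_loss)
  expect_false(l$conductive_evidence)
  expect_false(l$sensorineural_evidence)
  expect_identical(l$ear_severity, "normal")

  deaf <- flat_record("d", 95)
  d <- ear_profile(deaf, "left")
  expect_identical(d$ear_severity, "profound")

  # conductive pattern: air 45, bone 15 -> gap 30 >= 15, bone PTA 15 <= 25
  cond <- flat_record("c", 45)
  cond[c(paste0("left_bone_", freqs4))] <- 15
  ce <- ear_profile(cond, "left")
  expect_equal(ce$abg, 30)
  expect_true(ce$conductive_evidence)
  expect_false(ce$sensorineural_evidence)

  # no bone, abnormal tympanogram, elevated PTA -> conductive pathway
  tymp <- flat_record("t", 45)
  tymp[paste0("left_bone_", freqs4)] <- NA
  tymp$left_tymp_abnormal <- TRUE
  te <- ear_profile(tymp, "left")
  expect_true(te$conductive_evidence)
  expect_false(te$sensorineural_evidence)

  # no bone, normal tympanogram, elevated PTA -> sensorineural default
  tymp$left_tymp_abnormal <- FALSE
  tn <- ear_profile(tymp, "left")
  expect_false(tn$conductive_evidence)
  expect_true(tn$sensorineural_evidence)

  expect_error(ear_profile(within(quiet, rm(left_air_2000)), "left"), "2000")
})

test_that("PTA and ear_profile are monotone and pure", {
  base <- flat_record("m", 30)
  p1 <- ear_profile(base, "left")
  expect_identical(p1, ear_profile(base, "left"))
  withr::with_seed(4, {
    for (i in 1:25) {
      bumped <- base
      bump <- sample(0:15, 7, replace = TRUE)
      bumped[air_cols("left")] <- as.numeric(bumped[air_cols("left")]) + bump
      p2 <- ear_profile(bumped, "left")
      expect_gte(p2$pta, p1$pta)
      expect_gte(match(p2$ear_severity, SEVERITY_LEVELS),
                 match(p1$ear_severity, SEVERITY_LEVELS))
    }
  })
})

test_that("feature vectors are deterministic with stable semantic extension", {
  rec <- flat_record("f", 10)
  v1 <- feature_vector(rec)
  expect_identical(v1, feature_vector(rec))
  expect_true(all(unlist(v1[all_air_cols()]) == 10))
  v2 <- feature_vector(rec, include_semantic = c(Has_Severity = "mild",
                                                 Has_Laterality = "bilateral"))
  expect_identical(length(v2) - length(v1), 2L)
  incomplete <- rec
  incomplete$left_air_500 <- NA
  expect_error(feature_vector(incomplete), "incomplete")
})

test_that("feature configuration round-trips through its text format", {
  cfg <- feature_config(pta_freqs = c(500, 1000, 2000, 3000),
                        hl_cutoff = 20, abg_threshold = 10,
                        bone_normal_max = 20,
                        severity_cutoffs = c(normal = 20, mild = 35,
                                             moderate = 65, severe = 85))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_feature_config(cfg, path)
  expect_equal(read_feature_config(path), cfg)
  expect_error(feature_config(severity_cutoffs = c(normal = 40, mild = 25,
                                                   moderate = 70, severe = 90)),
               "increasing")
})
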