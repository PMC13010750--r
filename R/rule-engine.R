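#' Declarative rules and rule bases
#'
#' A rule asserts one label on one dimension (type, severity, laterality or
#' treatment) when its condition holds. Conditions are vectorized logical
#' expressions over named per-patient features (`left_pta`, `worse_pta`,
#' `conductive_any`, ...) and over labels already inferred (`hl_type`,
#' `severity`, `laterality`, `treatment`), restricted to comparisons,
#' boolean connectives and parentheses. Within a dimension, rules fire in
#' priority order and the first match wins. Rules of kind `"annotation"`
#' never assign; they only record eligibility in the inference trace.
#'
#' @param id Unique rule identifier.
#' @param dimension One of type/severity/laterality/treatment.
#' @param priority Integer; lower fires first within its dimension.
#' @param condition Condition expression as a character string.
#' @param assign Label asserted when the condition holds.
#' @param kind `"assign"` (default) or `"annotation"`.
#' @param description Human-readable intent.
#' @return An object of class `hl_rule`.
#' @export
rule <- function(id, dimension, priority, condition, assign,
                 kind = c("assign", "annotation"), description = "") {
  kind <- match.arg(kind)
  dims <- list(type = TYPE_LEVELS, severity = SEVERITY_LEVELS,
               laterality = LATERALITY_LEVELS, treatment = TREATMENT_LEVELS)
  if (!dimension %in% names(dims)) {
    stop("dimension must be one of ", paste(names(dims), collapse = ", "), call. = FALSE)
  }
  if (!assign %in% dims[[dimension]]) {
    stop("label '", assign, "' is not in the ", dimension, " vocabulary", call. = FALSE)
  }
  expr <- parse_condition(condition)
  structure(list(id = id, dimension = dimension, priority = as.integer(priority),
                 condition = condition, expr = expr, assign = assign,
                 kind = kind, description = description),
            class = "hl_rule")
}

ALLOWED_CONDITION_OPS <- c("&", "|", "!", "(", "==", "!=", ">", "<", ">=", "<=")

parse_condition <- function(condition) {
  expr <- tryCatch(parse(text = condition, keep.source = FALSE)[[1]],
                   error = function(e) stop("unparsable condition: ", condition,
                                            call. = FALSE))
  check <- function(e) {
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% ALLOWED_CONDITION_OPS) {
        stop("operator '", op, "' not allowed in rule conditions", call. = FALSE)
      }
      for (a in as.list(e)[-1]) check(a)
    } else if (!(is.name(e) || is.numeric(e) || is.character(e) || is.logical(e))) {
      stop("invalid token in condition: ", deparse(e), call. = FALSE)
    }
  }
  check(expr)
  expr
}

#' Assemble a rule base
#'
#' @param rules List of [rule()] objects; at least one per dimension.
#' @param version Version tag string.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(rules, version = "1") {
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate rule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  dims <- vapply(rules, `[[`, "", "dimension")
  missing <- setdiff(c("type", "severity", "laterality", "treatment"), dims)
  if (length(missing) > 0) {
    stop("rule base lacks rules for dimension(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(rules = rules, version = version), class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base> version", x$version, "-", length(x$rules), "rules\n")
  for (r in x$rules) {
    cat(sprintf("  [%s/%d] %s: %s -> %s\n", r$dimension, r$priority, r$id,
                r$condition, r$assign))
  }
  invisible(x)
}

#' The shipped default rule base
#'
#' Eighteen rules realizing the four clinical rule families: hearing-loss
#' type (mixed when both conductive and sensorineural evidence are present
#' in the same patient), severity by worse-ear pure-tone average (profound
#' strictly above 90 dB HL), laterality by which ears have loss (bilateral
#' when both do), and treatment recommendation (cochlear-implant evaluation
#' for bilateral severe-to-profound sensorineural loss; limited hearing-aid
#' benefit is not measurable in these data and is noted, not conditioned
#' on). Loaded from the editable rules file shipped with the package.
#'
#' @return A `rule_base`.
#' @export
default_rule_base <- function() {
  read_rule_base(system.file("extdata", "hearing_rules.txt", package = "audisem"))
}

# Vectorized forward chaining over a feature data frame. Returns the label
# data frame, per-record traces, and per-rule match/fire bookkeeping used by
# validate_rule_base().
infer_labels <- function(features, rules, collect_matches = FALSE,
                         collect_traces = !collect_matches) {
  n <- nrow(features)
  dims <- c("type", "severity", "laterality", "treatment")
  label_col <- c(type = "hl_type", severity = "severity",
                 laterality = "laterality", treatment = "treatment")
  labels <- data.frame(hl_type = rep(NA_character_, n), severity = NA_character_,
                       laterality = NA_character_, treatment = NA_character_,
                       stringsAsFactors = FALSE)
  rl <- rules$rules
  order_idx <- order(match(vapply(rl, `[[`, "", "dimension"), dims),
                     vapply(rl, `[[`, 0L, "priority"))
  traces <- vector("list", n)
  for (i in seq_len(n)) traces[[i]] <- character(0)
  fired_by <- matrix(FALSE, n, length(rl),
                     dimnames = list(NULL, vapply(rl, `[[`, "", "id")))
  matched <- if (collect_matches) fired_by else NULL

  eval_rule <- function(r) {
    env <- c(as.list(features), as.list(labels))
    val <- tryCatch(eval(r$expr, envir = env, enclos = baseenv()),
                    error = function(e) stop("rule '", r$id, "' failed to evaluate: ",
                                             conditionMessage(e), call. = FALSE))
    v <- rep_len(as.logical(val), n)
    v & !is.na(v)
  }

  repeat {
    changed <- FALSE
    for (ri in order_idx) {
      r <- rl[[ri]]
      if (r$kind != "assign") next
      col <- label_col[[r$dimension]]
      open <- is.na(labels[[col]])
      if (!any(open)) next
      hit <- eval_rule(r)
      if (collect_matches) matched[, r$id] <- matched[, r$id] | hit
      fire <- open & hit
      if (any(fire)) {
        labels[[col]][fire] <- r$assign
        fired_by[fire, r$id] <- TRUE
        if (collect_traces) {
          for (i in which(fire)) traces[[i]] <- c(traces[[i]], r$id)
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (ri in order_idx) {
    r <- rl[[ri]]
    if (r$kind != "annotation") next
    hit <- eval_rule(r)
    if (collect_matches) matched[, r$id] <- matched[, r$id] | hit
    fired_by[hit, r$id] <- TRUE
    if (collect_traces) {
      for (i in which(hit)) traces[[i]] <- c(traces[[i]], r$id)
    }
  }
  list(labels = labels, traces = traces, fired_by = fired_by, matched = matched)
}

#' Label one patient record by forward chaining
#'
#' Derives per-ear features from the record, then fires the rule base to
#' fixpoint in priority order within each dimension. Every fired rule id is
#' recorded in the inference trace.
#'
#' @param record One complete patient record (one-row data frame or list).
#' @param rules A [rule_base()]; default [default_rule_base()].
#' @param config A [feature_config()].
#' @return Object of class `semantic_labels`: list with `hl_type`,
#'   `severity`, `laterality`, `treatment` and `trace`.
#' @export
apply_rule_base <- function(record, rules = default_rule_base(),
                            config = feature_config()) {
  feats <- cohort_ear_features(as.data.frame(as.list(record),
                                             stringsAsFactors = FALSE), config)
  res <- infer_labels(feats, rules)
  lab <- res$labels[1, ]
  if (anyNA(lab)) {
    stop("rule base failed to label dimension(s): ",
         paste(names(lab)[is.na(unlist(lab))], collapse = ", "), call. = FALSE)
  }
  structure(list(hl_type = lab$hl_type, severity = lab$severity,
                 laterality = lab$laterality, treatment = lab$treatment,
                 trace = res$traces[[1]]),
            class = "semantic_labels")
}

#' Label a whole cohort
#'
#' Vectorized [apply_rule_base()]: one row of labels per patient plus a
#' `trace` list column.
#'
#' @param cohort Cohort data frame with complete audiometric columns.
#' @param rules A [rule_base()].
#' @param config A [feature_config()].
#' @return Data frame: patient_id, hl_type, severity, laterality, treatment,
#'   trace (list column of fired rule ids).
#' @export
label_cohort <- function(cohort, rules = default_rule_base(),
                         config = feature_config()) {
  feats <- cohort_ear_features(cohort, config)
  res <- infer_labels(feats, rules)
  if (anyNA(res$labels)) {
    stop("rule base left some patients unlabeled; run validate_rule_base()",
         call. = FALSE)
  }
  out <- cbind(data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE),
               res$labels)
  out$trace <- I(res$traces)
  out
}

#' Straight-line type classification
#'
#' Independent (non-engine) implementation of the type decision: mixed when
#' both conductive and sensorineural evidence occur in the same patient,
#' conductive or sensorineural when only one kind occurs, normal when no ear
#' has loss or evidence. Hearing loss without any evidence flag defaults to
#' sensorineural (most prevalent adult etiology).
#'
#' @param left,right `ear_features` for each ear (see [ear_profile()]).
#' @return Type label.
#' @export
classify_type <- function(left, right) {
  conductive_any <- left$conductive_evidence || right$conductive_evidence
  sensorineural_any <- left$sensorineural_evidence || right$sensorineural_evidence
  has_loss_any <- left$has_loss || right$has_loss
  if (conductive_any && sensorineural_any) return("mixed")
  if (conductive_any) return("conductive")
  if (sensorineural_any || has_loss_any) return("sensorineural")
  "normal"
}

#' Straight-line severity classification
#'
#' Patient severity is the band of the worse (larger) ear PTA. When
#' `hl_type` is supplied the label is made consistent with it: a non-normal
#' type is never graded "normal" (clamped to mild), and a normal type is
#' always "normal".
#'
#' @param left,right `ear_features`.
#' @param config A [feature_config()].
#' @param hl_type Optional type label for consistency clamping.
#' @return Severity label.
#' @export
classify_severity <- function(left, right, config = feature_config(), hl_type = NULL) {
  band <- severity_band(max(left$pta, right$pta), config)
  if (!is.null(hl_type)) {
    if (hl_type == "normal") return("normal")
    if (band == "normal") return("mild")
  }
  band
}

#' Straight-line laterality classification
#'
#' Bilateral when both ears have loss, unilateral when one does, normal when
#' neither does.
#'
#' @param left,right `ear_features`.
#' @return Laterality label.
#' @export
classify_laterality <- function(left, right) {
  if (left$has_loss && right$has_loss) return("bilateral")
  if (left$has_loss) return("unilateral_left")
  if (right$has_loss) return("unilateral_right")
  "normal"
}

#' Straight-line treatment recommendation
#'
#' Decision table over the already-inferred labels: bilateral severe or
#' profound sensorineural loss -> cochlear-implant evaluation; conductive or
#' mixed loss -> surgical evaluation; remaining sensorineural loss ->
#' hearing aid; normal hearing -> monitoring. Hearing-aid and
#' cochlear-implant cases are additionally eligible for auditory
#' rehabilitation (flagged in the engine trace).
#'
#' @param labels List with `hl_type`, `severity`, `laterality` already set.
#' @param record The patient record (unused by the default table; kept so
#'   user rule bases may condition on history).
#' @return Treatment label.
#' @export
recommend_treatment <- function(labels, record = NULL) {
  need <- c("hl_type", "severity", "laterality")
  vals <- labels[need]
  if (any(vapply(vals, is.null, TRUE)) || anyNA(unlist(vals))) {
    stop("type, severity and laterality must be inferred before treatment",
         call. = FALSE)
  }
  if (labels$hl_type == "normal") return("monitoring")
  if (labels$hl_type %in% c("conductive", "mixed")) return("surgical_evaluation")
  if (labels$severity %in% c("severe", "profound") && labels$laterality == "bilateral") {
    return("cochlear_implant_evaluation")
  }
  "hearing_aid"
}

#' Validate a rule base by brute-force sweep
#'
#' Sweeps a synthetic grid of per-ear features (PTA 0-120 dB HL in `by`-dB
#' steps per ear crossed with all 16 evidence-flag combinations) and checks
#' exhaustiveness (every grid point labeled in every dimension),
#' exclusivity (no grid point where two equal-priority rules of one
#' dimension assert different labels) and reachability (rules that never
#' fire anywhere on the grid).
#'
#' @param rules A [rule_base()].
#' @param config A [feature_config()] (sets the hearing-loss cutoff used to
#'   derive `has_loss` on the grid).
#' @param by Grid step in dB. Default 1.
#' @return List of class `rule_validation`: `exhaustive`, `exclusive`,
#'   `n_grid`, `exhaustiveness_violations`, `exclusivity_violations`,
#'   `unreachable_rules`.
#' @export
validate_rule_base <- function(rules, config = feature_config(), by = 1) {
  ptas <- seq(0, 120, by = by)
  flag <- c(FALSE, TRUE)
  grid <- expand.grid(left_pta = ptas, right_pta = ptas,
                      left_conductive_evidence = flag,
                      right_conductive_evidence = flag,
                      left_sensorineural_evidence = flag,
                      right_sensorineural_evidence = flag,
                      KEEP.OUT.ATTRS = FALSE)
  grid$left_has_loss <- grid$left_pta > config$hl_cutoff
  grid$right_has_loss <- grid$right_pta > config$hl_cutoff
  grid$left_hf_pta <- grid$left_pta
  grid$right_hf_pta <- grid$right_pta
  grid$left_abg <- ifelse(grid$left_conductive_evidence, config$abg_threshold + 10, 0)
  grid$right_abg <- ifelse(grid$right_conductive_evidence, config$abg_threshold + 10, 0)
  grid$worse_pta <- pmax(grid$left_pta, grid$right_pta)
  grid$conductive_any <- grid$left_conductive_evidence | grid$right_conductive_evidence
  grid$sensorineural_any <- grid$left_sensorineural_evidence | grid$right_sensorineural_evidence
  grid$has_loss_any <- grid$left_has_loss | grid$right_has_loss

  res <- infer_labels(grid, rules, collect_matches = TRUE)

  exh <- lapply(names(res$labels), function(col) which(is.na(res$labels[[col]])))
  names(exh) <- names(res$labels)
  exh <- exh[vapply(exh, length, 0L) > 0]

  rl <- rules$rules
  ids <- vapply(rl, `[[`, "", "id")
  excl <- list()
  for (dim in unique(vapply(rl, `[[`, "", "dimension"))) {
    in_dim <- which(vapply(rl, `[[`, "", "dimension") == dim &
                      vapply(rl, `[[`, "", "kind") == "assign")
    prios <- vapply(rl[in_dim], `[[`, 0L, "priority")
    for (p in unique(prios[duplicated(prios)])) {
      tied <- in_dim[prios == p]
      labs <- vapply(rl[tied], `[[`, "", "assign")
      if (length(unique(labs)) < 2) next
      m <- res$matched[, ids[tied], drop = FALSE]
      conflict <- rowSums(m) >= 2
      # conflict only when the tied matching rules assert different labels
      bad <- which(conflict & apply(m, 1, function(z) length(unique(labs[z])) > 1))
      if (length(bad) > 0) {
        excl[[length(excl) + 1]] <- list(dimension = dim, priority = p,
                                         rules = ids[tied], n_points = length(bad))
      }
    }
  }
  unreachable <- ids[colSums(res$fired_by) == 0]
  structure(list(exhaustive = length(exh) == 0,
                 exclusive = length(excl) == 0,
                 n_grid = nrow(grid),
                 exhaustiveness_violations = exh,
                 exclusivity_violations = excl,
                 unreachable_rules = unreachable),
            class = "rule_validation")
}

#' @export
print.rule_validation <- function(x, ...) {
  cat("<rule_validation> grid points:", x$n_grid, "\n",
      "exhaustive:", x$exhaustive, " exclusive:", x$exclusive, "\n",
      "unreachable rules:",
      if (length(x$unreachable_rules) == 0) "none" else paste(x$unreachable_rules, collapse = ", "),
      "\n")
  invisible(x)
}
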