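kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1L) {
    for (j in 2:k) {
      if (all(d2 == 0)) {
        stop("fewer distinct points than clusters (k = ", k, ")", call. = FALSE)
      }
      nxt <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[nxt, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

#' Fit K-Means with k-means++ seeding and restarts
#'
#' Standard Lloyd iterations (via [stats::kmeans()]) started from k-means++
#' initial centers, repeated over `restarts` independent initializations;
#' the model with the lowest inertia (total within-cluster sum of squares)
#' is kept. Deterministic for a given seed.
#'
#' @param features Numeric matrix/data frame of (already standardized)
#'   feature vectors, one row per record.
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts. Default 10.
#' @return Object of class `cluster_model`: `k`, `centroids`,
#'   `assignments`, `inertia`, `seed`.
#' @export
fit_kmeans <- function(features, k, seed = 1L, restarts = 10L) {
  x <- as.matrix(features)
  if (nrow(x) == 0L) stop("empty feature matrix", call. = FALSE)
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  if (k < 1L || k > nrow(x)) stop("k must be in [1, n]", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(k = as.integer(k),
                   centroids = unname(best$centers),
                   assignments = unname(best$cluster),
                   inertia = best$tot.withinss,
                   seed = as.integer(seed)),
              class = "cluster_model")
  })
}

#' Per-k clustering diagnostics (elbow and silhouette)
#'
#' Fits K-Means for every k in `k_range` under shared seeding and reports
#' inertia (for elbow inspection) and mean silhouette width.
#'
#' @param features Standardized feature matrix.
#' @param k_range Integer vector of candidate k, each in `[2, n - 1]`.
#' @param seed Integer seed shared across k.
#' @param restarts Restarts per k.
#' @return Data frame: k, inertia, silhouette.
#' @export
k_diagnostics <- function(features, k_range, seed = 1L, restarts = 10L) {
  x <- as.matrix(features)
  if (any(k_range < 2L) || any(k_range > nrow(x) - 1L)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  d <- stats::dist(x)
  rows <- lapply(k_range, function(k) {
    m <- fit_kmeans(x, k, seed = seed, restarts = restarts)
    sil <- cluster::silhouette(m$assignments, d)
    data.frame(k = k, inertia = m$inertia,
               silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, rows)
}

# Exact optimal one-to-one assignment between clusters and labels by
# exhaustive permutation search on the contingency table (k is at most 5 in
# this pipeline, so enumeration is exact and instant).
best_assignment <- function(tab) {
  k <- nrow(tab)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_score <- -1
  for (p in perms(seq_len(ncol(tab)))) {
    score <- sum(tab[cbind(seq_len(k), p[seq_len(k)])])
    if (score > best_score) {
      best_score <- score
      best <- p
    }
  }
  list(perm = best, score = best_score)
}

#' Name clusters after reference labels
#'
#' Builds the cluster-by-label contingency table and assigns each cluster a
#' clinical name. When the numbers of clusters and distinct labels match
#' (and are at most 8), the one-to-one assignment maximizing agreement is
#' found exactly; otherwise each cluster falls back to its majority label
#' (which may duplicate or drop labels, reported with a warning).
#'
#' @param model A `cluster_model` from [fit_kmeans()].
#' @param reference_labels Character vector of reference labels, one per
#'   clustered record.
#' @return List of class `cluster_mapping`: `mapping` (cluster index ->
#'   label), `agreement` (fraction of records whose mapped label matches the
#'   reference), `labels` (mapped per-record labels).
#' @export
map_clusters_to_labels <- function(model, reference_labels) {
  if (length(reference_labels) != length(model$assignments)) {
    stop("reference labels and cluster assignments differ in length", call. = FALSE)
  }
  ref <- as.character(reference_labels)
  tab <- table(cluster = factor(model$assignments, levels = seq_len(model$k)),
               label = ref)
  if (model$k == ncol(tab) && model$k <= 8L) {
    asg <- best_assignment(unclass(tab))
    mapping <- colnames(tab)[asg$perm]
  } else {
    mapping <- colnames(tab)[max.col(unclass(tab), ties.method = "first")]
    warning("clusters and labels differ in number; using per-cluster majority labels",
            call. = FALSE)
  }
  if (anyDuplicated(mapping) || length(unique(ref)) > length(unique(mapping))) {
    warning("cluster naming is degenerate: duplicated or missing labels (",
            paste(mapping, collapse = ", "), ")", call. = FALSE)
  }
  mapped <- mapping[model$assignments]
  list(mapping = stats::setNames(mapping, seq_len(model$k)),
       agreement = mean(mapped == ref),
       labels = mapped)
}

standardize <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  scale(x[, keep, drop = FALSE])
}

#' Cluster-derived labels for a whole cohort
#'
#' Reproduces the unsupervised baseline: three independent K-Means
#' segmentations — type (k = 4) on thresholds plus gap/tympanometry
#' features, severity (k = 5) on PTA features, laterality (k = 4) on
#' per-ear PTAs and their difference — each standardized, clustered, and
#' named against the rule-engine labels of the same records, then merged
#' into one table.
#'
#' @param cohort Cohort data frame.
#' @param config A [feature_config()].
#' @param seed Integer seed.
#' @param rules Rule base used to derive the reference labels for cluster
#'   naming.
#' @param restarts K-Means restarts per task.
#' @return Data frame: patient_id, km_type, km_severity, km_laterality, with
#'   per-task agreement rates in `attr(, "agreement")`.
#' @export
kmeans_label_cohort <- function(cohort, config = feature_config(), seed = 1L,
                                rules = default_rule_base(), restarts = 10L) {
  feats <- cohort_ear_features(cohort, config)
  ref <- infer_labels(feats, rules)$labels
  raw <- feature_table(cohort, config)

  tymp_cols <- intersect(c("left_tymp_abnormal", "right_tymp_abnormal"), names(raw))
  abg <- cbind(left_abg = ifelse(is.na(feats$left_abg), 0, feats$left_abg),
               right_abg = ifelse(is.na(feats$right_abg), 0, feats$right_abg))
  task_features <- list(
    type = cbind(left_pta = feats$left_pta, right_pta = feats$right_pta,
                 left_hf = feats$left_hf_pta, right_hf = feats$right_hf_pta,
                 abg,
                 if (length(tymp_cols) > 0) as.matrix(raw[, tymp_cols, drop = FALSE])),
    severity = cbind(left_pta = feats$left_pta, right_pta = feats$right_pta,
                     worse_pta = feats$worse_pta,
                     left_hf = feats$left_hf_pta, right_hf = feats$right_hf_pta),
    laterality = cbind(left_pta = feats$left_pta, right_pta = feats$right_pta,
                       diff = feats$left_pta - feats$right_pta)
  )
  task_k <- c(type = 4L, severity = 5L, laterality = 4L)
  task_ref <- list(type = ref$hl_type, severity = ref$severity,
                   laterality = ref$laterality)

  out <- data.frame(patient_id = cohort$patient_id, stringsAsFactors = FALSE)
  agreement <- numeric(0)
  for (task in names(task_k)) {
    x <- standardize(task_features[[task]])
    model <- fit_kmeans(x, task_k[[task]], seed = seed, restarts = restarts)
    mapped <- map_clusters_to_labels(model, task_ref[[task]])
    out[[paste0("km_", task)]] <- mapped$labels
    agreement[task] <- mapped$agreement
  }
  attr(out, "agreement") <- agreement
  out
}
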