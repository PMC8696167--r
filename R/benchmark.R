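# Four-metric evaluation of enrichment pipelines: sensitivity (Storey),
# prioritization (median target rank), specificity (FPR deviation under
# phenotype permutation) and reproducibility (overlap AUC across
# disjoint subject subsets), plus normalization and ranking across
# method combinations.

#' Sensitivity: estimated proportion of truly alternative gene sets
#'
#' Storey's estimator of the proportion of true nulls pi0 on the
#' collected gene set p-values: `pi0(lambda) = mean(p > lambda) /
#' (1 - lambda)` is evaluated on the grid lambda = 0.05, 0.10, ..., 0.95
#' and smoothed with a natural cubic smoothing spline (3 df); the
#' estimate is the smoother's value at the largest lambda, clipped to
#' `[0, 1]`. Sensitivity is `1 - pi0`.
#'
#' @param set_pvalues p-values of all analysed gene sets (one run);
#'   at least ~20 recommended. With fewer, a single-lambda (0.5)
#'   estimate is used with a warning.
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivity_storey <- function(set_pvalues) {
  check_pvalues(set_pvalues, "gene set p-values")
  m <- length(set_pvalues)
  if (m < 20) {
    warnf("only %d p-values: falling back to the single-lambda (0.5) pi0 estimate", m)
    pi0 <- mean(set_pvalues > 0.5) / 0.5
    return(1 - min(max(pi0, 0), 1))
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(set_pvalues > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  1 - min(max(pi0, 0), 1)
}

#' Prioritization: median rank of the target gene sets
#'
#' Sets are ranked ascending by p-value (rank 1 = most significant;
#' average ranks on ties); the metric is the median rank of the target
#' sets, so lower is better and `(|targets| + 1) / 2` is the best
#' achievable value.
#'
#' @param results a `gsa_result`/`gsa_results` data frame with columns
#'   `set_id` and `p` (one combination at a time), or a named numeric
#'   vector of set p-values.
#' @param targets character vector of target set ids.
#' @return median rank (numeric).
#' @export
prioritization <- function(results, targets) {
  p <- as_set_pvalues(results)
  if (!length(targets)) stopf("targets must be nonempty")
  found <- intersect(targets, names(p))
  if (!length(found)) stopf("none of the target sets was scored")
  rk <- rank(p, ties.method = "average")
  unname(median(rk[found]))
}

# Accept a named p vector, or any data frame with set_id + p.
as_set_pvalues <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stopf("set p-values must be named by set id")
    return(x)
  }
  if (is.data.frame(x) && all(c("set_id", "p") %in% names(x))) {
    if (anyDuplicated(x$set_id)) {
      stopf("results contain several rows per set; pass a single combination")
    }
    return(stats::setNames(x$p, x$set_id))
  }
  stopf("cannot extract set p-values from a %s", class(x)[1])
}

#' Permute the paired phenotype of a study
#'
#' The only label permutation consistent with the paired design: each
#' subject's tumour/normal labels are swapped with probability 1/2,
#' preserving the pairing.
#'
#' @param study a [paired_study()].
#' @param seed integer seed.
#' @return a new `paired_study` with permuted condition labels.
#' @export
permute_phenotype <- function(study, seed) {
  stopifnot(inherits(study, "paired_study"))
  swap <- with_seed(seed, rbinom(length(study$subjects), 1, 0.5) == 1)
  normal <- study$normal
  tumor <- study$tumor
  normal[swap, ] <- study$tumor[swap, , drop = FALSE]
  tumor[swap, ] <- study$normal[swap, , drop = FALSE]
  paired_study(normal, tumor)
}

#' Specificity: deviation of the false-positive rate from its nominal level
#'
#' Reruns a full analysis pipeline on phenotype-permuted copies of the
#' study (per-subject tumour/normal swaps). For each permutation the
#' false-positive rate is the fraction of gene sets significant at
#' `alpha`; the metric is the absolute deviation of the mean FPR from
#' `alpha`. Pipeline failures in individual permutations are recorded
#' and skipped.
#'
#' @param pipeline a function `(study, seed) -> set p-values` (named
#'   vector, or data frame with `set_id` and `p`). It must be
#'   deterministic given its seed.
#' @param study a [paired_study()].
#' @param n_label_perms number of phenotype permutations (default 50).
#' @param alpha nominal significance level (default 0.05).
#' @param seed master integer seed.
#' @return list with `fpr_mean`, `deviation` (`|fpr_mean - alpha|`),
#'   `fpr` (per-permutation rates) and `n_failed`.
#' @export
specificity_fpr <- function(pipeline, study, n_label_perms = 50, alpha = 0.05,
                            seed) {
  stopifnot(is.function(pipeline), n_label_perms >= 1)
  fpr <- rep(NA_real_, n_label_perms)
  for (i in seq_len(n_label_perms)) {
    perm_seed <- derive_seed(seed, paste0("phenoperm", i))
    fpr[i] <- tryCatch({
      p <- as_set_pvalues(pipeline(permute_phenotype(study, perm_seed),
                                   derive_seed(seed, paste0("pipeline", i))))
      mean(p < alpha)
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(fpr))
  if (n_failed == n_label_perms) stopf("pipeline failed in every permutation")
  if (n_failed > 0) warnf("pipeline failed in %d of %d permutations; skipped", n_failed, n_label_perms)
  m <- mean(fpr, na.rm = TRUE)
  list(fpr_mean = m, deviation = abs(m - alpha), fpr = fpr, n_failed = n_failed)
}

#' Reproducibility: overlap AUC across disjoint subject subsets
#'
#' Splits the subject pairs into disjoint subsets (default five subsets
#' of 14 pairs), runs the pipeline on each, and, for every cutoff c in
#' the grid, computes the fraction `|common top-c sets across all
#' subsets| / c`. The metric is the trapezoidal mean of that overlap
#' function over the cutoff grid, which lies in `[0, 1]`: identical
#' rankings give 1, unrelated rankings give ~0.
#'
#' @inheritParams specificity_fpr
#' @param n_subsets number of disjoint subsets (5 or 6 in typical use).
#' @param subset_size subject pairs per subset (default 14).
#' @param cutoffs top-c grid; defaults to `seq(5, 50, by = 5)` clipped
#'   to the number of scored sets.
#' @return list with `auc`, `overlap` (per-cutoff fractions) and
#'   `cutoffs`.
#' @export
reproducibility_auc <- function(pipeline, study, n_subsets = 5, subset_size = 14,
                                cutoffs = seq(5, 50, by = 5), seed) {
  stopifnot(is.function(pipeline), n_subsets >= 2)
  need <- n_subsets * subset_size
  if (need > length(study$subjects)) {
    stopf("need %d subject pairs for %d disjoint subsets of %d; study has %d",
          need, n_subsets, subset_size, length(study$subjects))
  }
  shuffled <- with_seed(derive_seed(seed, "subsets"),
                        sample(study$subjects, need))
  groups <- split(shuffled, rep(seq_len(n_subsets), each = subset_size))
  rankings <- lapply(seq_len(n_subsets), function(i) {
    p <- as_set_pvalues(pipeline(subset_study(study, groups[[i]]),
                                 derive_seed(seed, paste0("subset", i))))
    names(p)[order(p, names(p), method = "radix")]  # ties broken by set id
  })
  n_sets <- min(lengths(rankings))
  cutoffs <- sort(unique(pmin(cutoffs, n_sets)))
  overlap <- vapply(cutoffs, function(cc) {
    length(Reduce(intersect, lapply(rankings, head, cc))) / cc
  }, numeric(1))
  auc <- if (length(cutoffs) == 1) overlap else {
    sum(diff(cutoffs) * (head(overlap, -1) + overlap[-1]) / 2) /
      (max(cutoffs) - min(cutoffs))
  }
  list(auc = auc, overlap = overlap, cutoffs = cutoffs)
}

#' Normalize benchmark metrics and rank method combinations
#'
#' Each metric is oriented so that lower is better (sensitivity and
#' reproducibility are inverted), then min-max normalized across the
#' supplied reports (best observed -> 0, worst -> 1; a metric constant
#' across reports normalizes to 0 with a warning). The overall score is
#' the sum of the four normalized metrics; combinations are ranked
#' ascending. A descriptive k-means clustering of the normalized metric
#' vectors (k chosen by average silhouette width) is attached when
#' enough reports are available.
#'
#' @param reports data frame with one row per combination: a
#'   `combination` id column plus `sensitivity`, `prioritization`,
#'   `specificity_deviation`, `reproducibility_auc`.
#' @param cluster attach k-means cluster labels (default TRUE).
#' @param seed seed for the k-means restarts.
#' @return the reports with normalized metric columns (`norm_*`),
#'   `overall_score`, `overall_rank` and (optionally) `cluster`.
#' @export
normalize_and_rank <- function(reports, cluster = TRUE, seed = 1) {
  metrics <- c("sensitivity", "prioritization", "specificity_deviation",
               "reproducibility_auc")
  miss <- setdiff(c("combination", metrics), names(reports))
  if (length(miss)) stopf("reports: missing column(s) %s", paste(miss, collapse = ", "))
  if (nrow(reports) < 2) stopf("need at least 2 reports to normalize")
  lower_better <- c(sensitivity = FALSE, prioritization = TRUE,
                    specificity_deviation = TRUE, reproducibility_auc = FALSE)
  norm <- sapply(metrics, function(mt) {
    x <- reports[[mt]]
    if (!lower_better[mt]) x <- -x
    rng <- range(x)
    if (diff(rng) == 0) {
      warnf("metric '%s' is constant across reports; normalized to 0", mt)
      rep(0, length(x))
    } else {
      (x - rng[1]) / diff(rng)
    }
  })
  norm <- matrix(norm, nrow = nrow(reports),
                 dimnames = list(reports$combination, paste0("norm_", metrics)))
  out <- cbind(reports, as.data.frame(norm, row.names = NULL))
  out$overall_score <- rowSums(norm)
  out$overall_rank <- rank(out$overall_score, ties.method = "average")
  if (cluster && nrow(out) >= 4) {
    ks <- 2:min(6, nrow(out) - 1)
    sil <- vapply(ks, function(k) {
      cl <- with_seed(derive_seed(seed, paste0("kmeans", k)),
                      kmeans(norm, centers = k, nstart = 10))
      if (length(unique(cl$cluster)) < 2) return(-Inf)
      mean(cluster::silhouette(cl$cluster, dist(norm))[, "sil_width"])
    }, numeric(1))
    best_k <- ks[which.max(sil)]
    out$cluster <- with_seed(derive_seed(seed, paste0("kmeans", best_k)),
                             kmeans(norm, centers = best_k, nstart = 10))$cluster
  }
  out <- out[order(out$overall_rank), ]
  rownames(out) <- NULL
  class(out) <- c("gsa_benchmark", "data.frame")
  out
}

#' @export
print.gsa_benchmark <- function(x, ...) {
  cat("GSA benchmark ranking (lower overall score = better):\n")
  print.data.frame(x[c("combination", "sensitivity", "prioritization",
                       "specificity_deviation", "reproducibility_auc",
                       "overall_score", "overall_rank")],
                   digits = 3, row.names = FALSE)
  invisible(x)
}
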