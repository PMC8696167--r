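# Six competitive gene set analysis algorithms on gene-level (or, for
# GSEA-SNP, SNP-level) association p-values.

#' Valid enrichment algorithm names
#'
#' @return character vector of the six supported algorithms.
#' @export
gsa_algorithms <- function() {
  c("gsea", "gsea_snp", "igsea4gwas", "magenta75", "ora", "cerno")
}

#' Build a ranked list from ids and p-values
#'
#' Units (genes or SNPs) are ranked by `r = -log10(p)`, descending, so
#' the most significant unit comes first. Ties are broken by id in
#' lexical order -- a stable, documented rule that keeps permutation
#' nulls reproducible.
#'
#' @param ids character vector of unit ids.
#' @param p matching p-values in (0, 1]; clamped at 1e-300 before the log.
#' @return data frame (`id`, `p`, `r`) sorted for enrichment scanning.
#' @export
ranked_list <- function(ids, p) {
  stopifnot(length(ids) == length(p), !anyDuplicated(ids))
  check_pvalues(p)
  r <- -log10(clamp_p(p, hi = 1))
  o <- order(-r, ids, method = "radix")
  structure(data.frame(id = ids[o], p = p[o], r = r[o], stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# Core enrichment-score scan. r: non-negative rank metric in list order;
# member: logical, same length. Returns the signed deviation of maximum
# magnitude. NA when the set's total rank mass is zero (degenerate under
# permutation; callers decide whether that is an error).
es_stat <- function(r, member) {
  n <- length(r)
  nh <- sum(member)
  nr <- sum(abs(r[member]))
  if (nr <= 0) return(NA_real_)
  hit <- numeric(n)
  hit[member] <- abs(r[member]) / nr
  dev <- cumsum(hit) - cumsum(!member) / (n - nh)
  dev[es_extremum(dev)]
}

# First position whose deviation magnitude is within numerical tolerance
# of the maximum -- a documented tie-break that keeps the extremum stable
# under reordering of floating-point sums.
es_extremum <- function(dev, tol = 1e-12) {
  a <- abs(dev)
  which(a >= max(a) - tol)[1]
}

#' Running enrichment score of a gene set on a ranked list
#'
#' Walks the ranked list accumulating the hit profile (rank-weighted,
#' normalised by the set's total rank mass) against the miss profile
#' (uniform steps of `1 / (N - N_H)`); the enrichment score ES is the
#' signed value of `P_hit - P_miss` at the position of maximum absolute
#' deviation. Both profiles end at 1, so ES lies in `[-1, 1]`.
#'
#' @param ranked a [ranked_list()].
#' @param set character vector of member ids; must intersect the list
#'   and not cover it entirely.
#' @return list with `es`, `position` (1-based index of the extremum),
#'   `p_hit` and `p_miss` (full profiles).
#' @export
running_enrichment_score <- function(ranked, set) {
  stopifnot(inherits(ranked, "ranked_list"))
  member <- ranked$id %in% set
  nh <- sum(member)
  n <- nrow(ranked)
  if (nh < 1 || nh >= n) stopf("need 1 <= |set intersect universe| < N (got %d of %d)", nh, n)
  nr <- sum(abs(ranked$r[member]))
  if (nr <= 0) stopf("degenerate set: every member has zero rank metric")
  hit <- numeric(n)
  hit[member] <- abs(ranked$r[member]) / nr
  p_hit <- cumsum(hit)
  p_miss <- cumsum(!member) / (n - nh)
  dev <- p_hit - p_miss
  i <- es_extremum(dev)
  list(es = dev[i], position = i, p_hit = p_hit, p_miss = p_miss)
}

# Intersect a collection with the universe and apply the minimum-size
# filter. Returns list(sets = list of member vectors, dropped = names).
restrict_sets <- function(sets, universe, min_size, max_frac = 1, verbose = FALSE) {
  inter <- lapply(sets, function(s) intersect(s, universe))
  keep <- lengths(inter) >= min_size & lengths(inter) <= max_frac * length(universe)
  if (any(!keep)) {
    vlog(verbose, "dropped %d set(s) below min size %d (or covering the universe)",
         sum(!keep), min_size)
  }
  list(sets = inter[keep], dropped = names(sets)[!keep])
}

finish_result <- function(df, algorithm, integration = NA_character_, ld = NA) {
  df$p_adj <- p.adjust(df$p, method = "BH")
  df <- df[c("set_id", "statistic", "p", "p_adj", "set_size", "n_hits")]
  attr(df, "algorithm") <- algorithm
  attr(df, "integration") <- integration
  attr(df, "ld") <- ld
  class(df) <- c("gsa_result", "data.frame")
  df
}

#' @export
print.gsa_result <- function(x, ...) {
  if (!all(c("set_id", "p", "p_adj") %in% names(x))) {
    return(print.data.frame(x, ...))
  }
  cat(sprintf("gsa_result [%s%s]: %d sets; %d with p < 0.05 (%d after BH)\n",
              attr(x, "algorithm"),
              if (!is.na(attr(x, "integration"))) paste0(", ", attr(x, "integration"),
                if (isTRUE(attr(x, "ld"))) "+LD" else "") else "",
              nrow(x), sum(x$p < 0.05), sum(x$p_adj < 0.05)))
  invisible(x)
}

# Shared label-permutation ES machinery for GSEA and GSEA-SNP.
# r: rank metric in ranked order; members: list of logical vectors.
es_permutation_test <- function(r, members, n_perm, seed) {
  n <- length(r)
  obs <- vapply(members, function(m) es_stat(r, m), numeric(1))
  perm <- matrix(NA_real_, n_perm, length(members))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      for (s in seq_along(members)) perm[b, s] <- es_stat(r, members[[s]][idx])
    }
  })
  summarise_signed_perms(obs, perm)
}

# Same-sign permutation summary: p compares |observed| against same-sign
# permuted magnitudes (add-one convention); NES divides the observed
# statistic by the mean magnitude of same-sign permuted statistics.
summarise_signed_perms <- function(obs, perm) {
  n_sets <- length(obs)
  p <- nes <- rep(NA_real_, n_sets)
  for (s in seq_len(n_sets)) {
    o <- obs[s]
    if (is.na(o)) next
    col <- perm[, s]
    col <- col[!is.na(col)]
    same <- if (o >= 0) col[col > 0] else col[col < 0]
    if (!length(same)) {
      p[s] <- 1
      nes[s] <- NA_real_
    } else {
      p[s] <- (sum(abs(same) >= abs(o)) + 1) / (length(same) + 1)
      nes[s] <- o / mean(abs(same))
    }
  }
  list(obs = obs, p = p, nes = nes)
}

#' GSEA on integrated gene scores
#'
#' Ranks genes by `-log10(p)`, scans each set's running enrichment score
#' and assesses it against a gene-label permutation null: each replicate
#' randomly reassigns genes to ranks (one shared permutation per
#' replicate across sets). The normalised enrichment score NES divides
#' the observed ES by the mean magnitude of same-direction permuted ES;
#' the p-value compares magnitudes within the same direction, with the
#' add-one convention.
#'
#' @param scores `gene_scores` data frame (see [integrate_genes()]).
#' @param sets a [gene_set_collection()] (or named list).
#' @param n_perm permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param min_size minimum set size after intersection with the scored
#'   universe (default 5).
#' @return `gsa_result` data frame: `set_id`, `statistic` (NES), `p`,
#'   `p_adj` (BH), `set_size` (after intersection), `n_hits` (= set
#'   size). The observed ES per set is kept in the `es` attribute.
#' @export
gsea <- function(scores, sets, n_perm = 1000, seed, min_size = 5) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  rl <- ranked_list(scores$gene_id, scores$p)
  rs <- restrict_sets(sets, rl$id, min_size, max_frac = 1 - 1e-9)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  members <- lapply(rs$sets, function(s) rl$id %in% s)
  res <- es_permutation_test(rl$r, members, n_perm, seed)
  out <- data.frame(set_id = names(rs$sets), statistic = res$nes, p = res$p,
                    set_size = lengths(rs$sets), n_hits = lengths(rs$sets),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- finish_result(out, "gsea")
  attr(out, "es") <- stats::setNames(res$obs, names(rs$sets))
  out
}

#' GSEA-SNP: enrichment on the SNP-level ranked list
#'
#' Skips gene integration entirely: the ranked list is over SNPs
#' (`r = -log10(p_SNP)`), a SNP belongs to a set when it maps to any
#' member gene, and the null permutes SNP labels. ES/NES/p machinery is
#' identical to [gsea()].
#'
#' @param associations `snp_association` data frame.
#' @param map a `snp_gene_map`.
#' @inheritParams gsea
#' @return `gsa_result` as in [gsea()]; `set_size`/`n_hits` count SNPs.
#' @export
gsea_snp <- function(associations, map, sets, n_perm = 1000, seed, min_size = 5) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  ok <- !is.na(associations$p_value)
  rl <- ranked_list(associations$snp_id[ok], associations$p_value[ok])
  snp_sets <- lapply(sets, function(genes) {
    unique(map$map$snp_id[map$map$gene_id %in% genes])
  })
  names(snp_sets) <- names(sets)
  rs <- restrict_sets(snp_sets, rl$id, min_size, max_frac = 1 - 1e-9)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  members <- lapply(rs$sets, function(s) rl$id %in% s)
  res <- es_permutation_test(rl$r, members, n_perm, seed)
  out <- data.frame(set_id = names(rs$sets), statistic = res$nes, p = res$p,
                    set_size = lengths(rs$sets), n_hits = lengths(rs$sets),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- finish_result(out, "gsea_snp")
  attr(out, "es") <- stats::setNames(res$obs, names(rs$sets))
  out
}

#' i-GSEA4GWAS: SNP-label permutation with significance reweighting
#'
#' Two changes relative to [gsea()]: the null permutes SNP labels (each
#' replicate shuffles the SNP p-values over SNP slots and re-runs the
#' gene integration before rescoring), and the statistic is the
#' significance-proportion-based enrichment score
#' `SPES = ES * (k / K)`, where a gene counts as significant when at
#' least one of its SNPs lies in the top `top_snp_fraction` of all SNPs
#' by association p-value, `k` is the significant fraction within the
#' set and `K` in the whole scored universe.
#'
#' @inheritParams gsea_snp
#' @param method,ld integration method and LD flag used to collapse SNP
#'   p-values to genes (re-applied in every permutation round).
#' @param top_snp_fraction fraction of top SNPs defining "significant"
#'   genes (default 0.05).
#' @return `gsa_result` with `statistic` = SPES.
#' @export
igsea4gwas <- function(associations, map, sets, method = "minimum", ld = FALSE,
                       n_perm = 1000, seed, top_snp_fraction = 0.05, min_size = 5) {
  if (!(top_snp_fraction > 0 && top_snp_fraction < 1)) {
    stopf("top_snp_fraction must lie in (0, 1)")
  }
  if (n_perm < 100) stopf("n_perm must be >= 100")
  ok <- !is.na(associations$p_value)
  p_snp <- stats::setNames(associations$p_value[ok], associations$snp_id[ok])
  m <- map$map[map$map$snp_id %in% names(p_snp), , drop = FALSE]
  if (!nrow(m)) stopf("no mapped SNP carries an association result")
  idx <- split(match(m$snp_id, names(p_snp)), m$gene_id)
  genes <- names(idx)
  n_top <- max(1L, ceiling(top_snp_fraction * length(p_snp)))

  score_once <- function(pv) {
    pg <- integrate_fast(pv, idx, method, ld)
    p_use <- if (ld) pg$p_corr else pg$p
    rl <- ranked_list(genes, p_use)
    top <- rank(pv, ties.method = "first") <= n_top
    sig_gene <- vapply(idx, function(i) any(top[i]), logical(1))
    list(rl = rl, sig = stats::setNames(sig_gene, genes))
  }

  obs <- score_once(p_snp)
  rs <- restrict_sets(sets, genes, min_size, max_frac = 1 - 1e-9)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  members_of <- function(rl) lapply(rs$sets, function(s) rl$id %in% s)
  big_k <- mean(obs$sig)
  if (big_k == 0) {
    stopf("no gene maps to the top %.0f%% of SNPs; K = 0 makes SPES undefined (provide more SNPs)",
          100 * top_snp_fraction)
  }
  spes_of <- function(sc, members) {
    vapply(seq_along(rs$sets), function(s) {
      es <- es_stat(sc$rl$r, members[[s]])
      kk <- mean(sc$sig[rs$sets[[s]]])
      bk <- mean(sc$sig)
      if (is.na(es) || bk == 0) NA_real_ else es * (kk / bk)
    }, numeric(1))
  }
  obs_members <- members_of(obs$rl)
  obs_spes <- spes_of(obs, obs_members)
  perm <- matrix(NA_real_, n_perm, length(rs$sets))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pv <- stats::setNames(p_snp[sample.int(length(p_snp))], names(p_snp))
      sc <- score_once(pv)
      perm[b, ] <- spes_of(sc, members_of(sc$rl))
    }
  })
  res <- summarise_signed_perms(obs_spes, perm)
  out <- data.frame(set_id = names(rs$sets), statistic = obs_spes, p = res$p,
                    set_size = lengths(rs$sets), n_hits = lengths(rs$sets),
                    stringsAsFactors = FALSE, row.names = NULL)
  finish_result(out, "igsea4gwas", method, ld)
}

#' MAGENTA with a 75th-percentile cutoff
#'
#' The observed statistic is the leading-edge fraction: the number of
#' set members whose gene p-value falls strictly below the global
#' cutoff, the stated percentile of all gene p-values. The null draws
#' `n_perm` mock sets of identical size uniformly without replacement
#' from the scored universe and counts how often a mock leading-edge
#' fraction is at least the observed one (add-one convention).
#'
#' @inheritParams gsea
#' @param percentile percentile (0-100) of all gene p-values used as
#'   the cutoff; default 75.
#' @return `gsa_result` with `statistic` = leading-edge count and
#'   `n_hits` = the same count.
#' @export
magenta75 <- function(scores, sets, n_perm = 1000, seed, percentile = 75,
                      min_size = 5) {
  if (!(percentile > 0 && percentile < 100)) stopf("percentile must lie in (0, 100)")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  p <- stats::setNames(scores$p, scores$gene_id)
  n <- length(p)
  cutoff <- unname(quantile(p, percentile / 100))
  rs <- restrict_sets(sets, names(p), min_size)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  if (any(lengths(rs$sets) > n)) stopf("set larger than the scored universe")
  below <- p < cutoff
  n_perm <- as.integer(n_perm)
  rows <- with_seed(seed, {
    lapply(seq_along(rs$sets), function(s) {
      size <- length(rs$sets[[s]])
      obs <- sum(below[rs$sets[[s]]])
      mock <- vapply(seq_len(n_perm),
                     function(b) sum(below[sample.int(n, size)]), integer(1))
      c(obs = obs, p = (sum(mock >= obs) + 1) / (n_perm + 1))
    })
  })
  out <- data.frame(set_id = names(rs$sets),
                    statistic = vapply(rows, `[[`, 0, "obs"),
                    p = vapply(rows, `[[`, 0, "p"),
                    set_size = lengths(rs$sets),
                    n_hits = as.integer(vapply(rows, `[[`, 0, "obs")),
                    stringsAsFactors = FALSE, row.names = NULL)
  finish_result(out, "magenta75")
}

#' Over-representation analysis (hypergeometric test)
#'
#' Genes with working p-value below `deg_alpha` form the
#' "differentially associated" list; each set is tested for
#' over-representation of that list by the upper-tail hypergeometric
#' probability of observing at least the actual overlap. The sample
#' odds ratio of the 2x2 table is reported as the statistic.
#'
#' @inheritParams gsea
#' @param deg_alpha significance threshold defining the gene list
#'   (default 0.05).
#' @return `gsa_result` with `statistic` = odds ratio and `n_hits` =
#'   overlap count.
#' @export
ora <- function(scores, sets, deg_alpha = 0.05, min_size = 5) {
  if (!(deg_alpha > 0 && deg_alpha < 1)) stopf("deg_alpha must lie in (0, 1)")
  universe <- scores$gene_id
  n <- length(universe)
  deg <- universe[scores$p < deg_alpha]
  rs <- restrict_sets(sets, universe, min_size)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  if (!length(deg)) warnf("zero significant genes at alpha = %g: all ORA p-values are 1", deg_alpha)
  rows <- lapply(rs$sets, function(s) {
    m <- length(s)
    x <- length(intersect(s, deg))
    pval <- if (length(deg)) {
      phyper(x - 1, length(deg), n - length(deg), m, lower.tail = FALSE)
    } else 1
    a <- x; b <- m - x; cc <- length(deg) - x; d <- n - length(deg) - b
    or <- (a * d) / (b * cc)
    c(or = or, p = pval, x = x)
  })
  out <- data.frame(set_id = names(rs$sets),
                    statistic = vapply(rows, `[[`, 0, "or"),
                    p = vapply(rows, `[[`, 0, "p"),
                    set_size = lengths(rs$sets),
                    n_hits = as.integer(vapply(rows, `[[`, 0, "x")),
                    stringsAsFactors = FALSE, row.names = NULL)
  finish_result(out, "ora")
}

#' CERNO: analytic rank-based set test
#'
#' Genes are ranked 1..N ascending by p-value (rank 1 = most
#' significant; ties take average ranks). For each set, Fisher's
#' integration is applied to the relative ranks:
#' `F = -2 * sum(log(rank_g / N))`, referred to the upper tail of a
#' chi-square distribution with `2 * N_H` degrees of freedom. No
#' permutations are needed.
#'
#' @inheritParams gsea
#' @return `gsa_result` with `statistic` = CERNO F.
#' @export
cerno <- function(scores, sets, min_size = 5) {
  universe <- scores$gene_id
  n <- length(universe)
  if (n < 2) stopf("universe must contain at least 2 genes")
  rk <- stats::setNames(rank(scores$p, ties.method = "average"), universe)
  rs <- restrict_sets(sets, universe, min_size)
  if (!length(rs$sets)) stopf("no set survives the size filter")
  rows <- lapply(rs$sets, function(s) {
    f <- -2 * sum(log(rk[s] / n))
    c(f = f, p = pchisq(f, df = 2 * length(s), lower.tail = FALSE))
  })
  out <- data.frame(set_id = names(rs$sets),
                    statistic = vapply(rows, `[[`, 0, "f"),
                    p = vapply(rows, `[[`, 0, "p"),
                    set_size = lengths(rs$sets),
                    n_hits = lengths(rs$sets),
                    stringsAsFactors = FALSE, row.names = NULL)
  finish_result(out, "cerno")
}

#' Run every algorithm x integration x LD combination
#'
#' Integrates once per (integration, LD) combination, then runs each
#' requested algorithm, collecting everything into one tidy long-format
#' table. GSEA-SNP consumes SNP-level p-values directly, so it runs once
#' and is tagged with integration `"none"`. BH adjustment is applied
#' within each combination. Every combination draws its own seed from
#' the master seed via [derive_seed()].
#'
#' @param associations `snp_association` data frame.
#' @param map a `snp_gene_map`.
#' @param sets a [gene_set_collection()].
#' @param algorithms subset of [gsa_algorithms()].
#' @param integrations subset of [integration_methods()].
#' @param ld logical vector of LD-correction settings to cross.
#' @param n_perm permutations for the permutation-based algorithms.
#' @param seed master integer seed.
#' @param deg_alpha,percentile,top_snp_fraction,min_size passed through
#'   to the individual algorithms.
#' @param verbose log one line per combination.
#' @return data frame of class `gsa_results` with columns `algorithm`,
#'   `integration`, `ld`, `set_id`, `statistic`, `p`, `p_adj`,
#'   `set_size`, `n_hits`.
#' @export
run_gsa_all <- function(associations, map, sets,
                        algorithms = gsa_algorithms(),
                        integrations = integration_methods(),
                        ld = c(FALSE, TRUE),
                        n_perm = 1000, seed,
                        deg_alpha = 0.05, percentile = 75,
                        top_snp_fraction = 0.05, min_size = 5,
                        verbose = FALSE) {
  bad <- setdiff(algorithms, gsa_algorithms())
  if (length(bad)) {
    stopf("unknown algorithm(s): %s; valid names are %s",
          paste(bad, collapse = ", "), paste(gsa_algorithms(), collapse = ", "))
  }
  out <- list()
  tidy <- function(res, algorithm, integration, ld_flag) {
    cbind(data.frame(algorithm = algorithm, integration = integration,
                     ld = ld_flag, stringsAsFactors = FALSE),
          as.data.frame(res))
  }
  for (int in integrations) {
    for (l in ld) {
      combo <- sprintf("%s/%s", int, if (l) "ld" else "nold")
      scores <- integrate_genes(associations, map, int, l)
      for (alg in setdiff(algorithms, "gsea_snp")) {
        vlog(verbose, "running %s on %s", alg, combo)
        s <- derive_seed(seed, paste(alg, combo))
        res <- switch(alg,
          gsea = gsea(scores, sets, n_perm, s, min_size),
          igsea4gwas = igsea4gwas(associations, map, sets, int, l, n_perm, s,
                                  top_snp_fraction, min_size),
          magenta75 = magenta75(scores, sets, n_perm, s, percentile, min_size),
          ora = ora(scores, sets, deg_alpha, min_size),
          cerno = cerno(scores, sets, min_size))
        out[[paste(alg, combo)]] <- tidy(res, alg, int, l)
      }
    }
  }
  if ("gsea_snp" %in% algorithms) {
    vlog(verbose, "running gsea_snp (integration-free)")
    res <- gsea_snp(associations, map, sets, n_perm,
                    derive_seed(seed, "gsea_snp"), min_size)
    out[["gsea_snp"]] <- tidy(res, "gsea_snp", "none", FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gsa_results", "data.frame")
  res
}

#' @export
print.gsa_results <- function(x, ...) {
  if (!all(c("algorithm", "integration", "ld", "set_id") %in% names(x))) {
    return(print.data.frame(x, ...))  # column subset: plain printing
  }
  combos <- unique(x[c("algorithm", "integration", "ld")])
  cat(sprintf("gsa_results: %d rows over %d combination(s), %d set(s)\n",
              nrow(x), nrow(combos), length(unique(x$set_id))))
  invisible(x)
}
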