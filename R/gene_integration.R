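# Collapse per-SNP association p-values to per-gene p-values (minimum /
# Fisher / Stouffer) with an optional fixed-exponent LD correction.

#' Minimum p-value integration
#'
#' The most common SNP-to-gene collapse: the gene inherits its best
#' SNP's p-value. No multiplicity adjustment is applied here; see
#' [ld_correct()].
#'
#' @param p_values vector of k p-values in (0, 1].
#' @return the minimum.
#' @export
combine_minimum <- function(p_values) {
  check_pvalues(p_values)
  min(p_values)
}

#' Fisher probability integration
#'
#' `F = -2 * sum(log(p_i))`, referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. At k = 1 the combined
#' p-value equals the input exactly.
#'
#' @param p_values vector of k p-values in (0, 1]; values below 1e-300
#'   are clamped before the log.
#' @return list with `statistic` (F) and `p` (combined p-value).
#' @examples
#' combine_fisher(c(0.05, 0.05))  # F = 11.98, p ~ 0.0175
#' @export
combine_fisher <- function(p_values) {
  check_pvalues(p_values)
  k <- length(p_values)
  f <- -2 * sum(log(clamp_p(p_values, hi = 1)))
  list(statistic = f, p = pchisq(f, df = 2 * k, lower.tail = FALSE))
}

#' Stouffer (z-transformation) integration
#'
#' `Z_i = qnorm(p_i)`, `Z_gene = sum(Z_i) / sqrt(k)`; the combined
#' p-value is the lower normal tail `pnorm(Z_gene)`, so small input
#' p-values map to small output p-values and k = 1 is an identity.
#'
#' @param p_values vector of k p-values; values are clamped to
#'   `[1e-300, 1 - 1e-16]` before the normal quantile transform.
#' @return list with `statistic` (Z_gene) and `p` (combined p-value).
#' @examples
#' combine_stouffer(c(0.0228, 0.0228))  # Z ~ -2.83, p ~ 0.0023
#' @export
combine_stouffer <- function(p_values) {
  check_pvalues(p_values)
  k <- length(p_values)
  z <- sum(qnorm(clamp_p(p_values))) / sqrt(k)
  list(statistic = z, p = pnorm(z))
}

#' Linkage disequilibrium correction of a gene-level p-value
#'
#' Dunn-Sidak-style correction with the exponent halved,
#' `p_corr = 1 - (1 - p_gene)^((k + 1) / 2)`, reflecting that roughly
#' half of within-gene SNPs are in strong LD and so the effective number
#' of independent tests is about `(k + 1) / 2`. Identity at k = 1;
#' always `p_corr >= p_gene`. The exponent is used literally (no
#' rounding for even k).
#'
#' @param p_gene combined gene-level p-value in (0, 1].
#' @param k number of SNPs integrated for the gene (>= 1).
#' @return corrected p-value.
#' @examples
#' ld_correct(0.01, 3)  # 1 - 0.99^2 = 0.0199
#' @export
ld_correct <- function(p_gene, k) {
  check_pvalues(p_gene, "p_gene")
  if (any(k < 1)) stopf("k must be >= 1")
  1 - (1 - p_gene)^((k + 1) / 2)
}

# Vectorised integration used by both integrate_genes() and the
# i-GSEA4GWAS permutation loop: p is the per-SNP p-value vector, idx a
# list (one element per gene) of indices into p.
integrate_fast <- function(p, idx, method, ld = FALSE) {
  p <- clamp_p(p, hi = 1)
  k <- lengths(idx)
  res <- switch(
    method,
    minimum = list(statistic = rep(NA_real_, length(idx)),
                   p = vapply(idx, function(i) min(p[i]), numeric(1))),
    fisher = {
      f <- -2 * vapply(idx, function(i) sum(log(p[i])), numeric(1))
      list(statistic = f, p = pchisq(f, df = 2 * k, lower.tail = FALSE))
    },
    stouffer = {
      pz <- clamp_p(p)  # qnorm needs the upper clamp too
      z <- vapply(idx, function(i) sum(qnorm(pz[i])), numeric(1)) / sqrt(k)
      list(statistic = z, p = pnorm(z))
    },
    stopf("unknown integration method '%s'; use one of %s", method,
          paste(integration_methods(), collapse = ", ")))
  res$p <- clamp_p(res$p, hi = 1)
  if (ld) res$p_corr <- 1 - (1 - res$p)^((k + 1) / 2) else res$p_corr <- rep(NA_real_, length(idx))
  res$k <- k
  res
}

#' Integration method names
#'
#' @return `c("minimum", "fisher", "stouffer")`.
#' @export
integration_methods <- function() c("minimum", "fisher", "stouffer")

#' Integrate per-SNP p-values into per-gene scores
#'
#' For every gene in the map, combines the association p-values of its
#' mapped SNPs with the chosen method and, when `ld = TRUE`, applies
#' [ld_correct()] with that gene's SNP count k. A SNP mapped to several
#' genes contributes to each of them. Genes none of whose SNPs carry an
#' association result are omitted with a warning.
#'
#' @param associations `snp_association` data frame (see
#'   [associate_all()]).
#' @param map a `snp_gene_map` (see [map_snps_to_genes()]).
#' @param method `"minimum"`, `"fisher"` or `"stouffer"`.
#' @param ld apply the LD correction?
#' @return data frame of class `gene_scores` with columns `gene_id`,
#'   `method`, `k`, `statistic`, `p_gene`, `ld`, `p_corr`, `p` (the
#'   working p-value: `p_corr` when `ld`, else `p_gene`).
#' @export
integrate_genes <- function(associations, map, method = integration_methods(),
                            ld = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(map, "snp_gene_map"), is_flag(ld))
  ok <- !is.na(associations$p_value)
  pv <- stats::setNames(associations$p_value[ok], associations$snp_id[ok])
  m <- map$map[map$map$snp_id %in% names(pv), , drop = FALSE]
  dropped <- setdiff(unique(map$map$gene_id), unique(m$gene_id))
  if (length(dropped)) {
    warnf("%d gene(s) omitted: no association results for their SNPs", length(dropped))
  }
  if (!nrow(m)) stopf("no (SNP, gene) pair carries an association result")
  idx <- split(match(m$snp_id, names(pv)), m$gene_id)
  res <- integrate_fast(pv, idx, method, ld)
  out <- data.frame(gene_id = names(idx), method = method, k = res$k,
                    statistic = res$statistic, p_gene = res$p, ld = ld,
                    p_corr = res$p_corr,
                    p = if (ld) res$p_corr else res$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("gene_scores: %d genes, %s integration%s; %d with p < 0.05\n",
              nrow(x), x$method[1], if (x$ld[1]) " + LD correction" else "",
              sum(x$p < 0.05)))
  invisible(x)
}

#' Write / read gene scores as TSV
#'
#' @param scores `gene_scores` data frame (for writing) or file path
#'   (for reading).
#' @param path output file.
#' @return path / `gene_scores` data frame.
#' @export
write_gene_scores <- function(scores, path) {
  write_tsv(scores, path)
}

#' @rdname write_gene_scores
#' @export
read_gene_scores <- function(path) {
  df <- require_cols(read_tsv(path), c("gene_id", "p_gene"), path)
  if (is.null(df$method)) df$method <- "unknown"
  if (is.null(df$k)) df$k <- NA_integer_
  if (is.null(df$statistic)) df$statistic <- NA_real_
  if (is.null(df$ld)) df$ld <- FALSE
  if (is.null(df$p_corr)) df$p_corr <- NA_real_
  if (is.null(df$p)) df$p <- ifelse(df$ld, df$p_corr, df$p_gene)
  out <- df[c("gene_id", "method", "k", "statistic", "p_gene", "ld", "p_corr", "p")]
  class(out) <- c("gene_scores", "data.frame")
  out
}
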