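# SNP quality control (MAF / HWE) and window-based SNP-to-gene mapping.

#' Minor allele frequency of a genotype vector
#'
#' Genotypes are coded as copies of the alternate allele (0/1/2); missing
#' calls are excluded from the denominator. The frequency is folded, so
#' the result never exceeds 0.5 and is invariant under swapping the
#' allele coding (`g -> 2 - g`).
#'
#' @param genotypes vector with values in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @examples
#' snp_maf(c(0, 0, 1, 2))  # 0.375
#' @export
snp_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) stopf("all genotypes missing: MAF undefined for this SNP")
  if (!all(g %in% 0:2)) stopf("genotype codes must be 0, 1, 2 or NA")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Goodness-of-fit test (1 df) of observed genotype counts against the
#' proportions expected under HWE at the allele frequency estimated from
#' the same counts. Monomorphic SNPs carry no testable departure and
#' return p = 1.
#'
#' @param counts length-3 vector `(n_AA, n_AB, n_BB)` of genotype counts
#'   (0, 1, 2 alternate alleles respectively).
#' @return p-value.
#' @examples
#' hwe_test(c(25, 50, 25))  # exactly at HWE: p = 1
#' hwe_test(c(50, 0, 50))   # complete heterozygote deficit
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0)) {
    stopf("counts must be 3 non-negative genotype counts (n_AA, n_AB, n_BB)")
  }
  n <- sum(counts)
  if (n == 0) stopf("no genotype calls: HWE undefined")
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (f == 0 || f == 1) return(1)
  expected <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  chi2 <- sum((counts - expected)^2 / expected)
  unname(pchisq(chi2, df = 1, lower.tail = FALSE))
}

genotype_counts <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Filter SNPs on minor allele frequency and Hardy-Weinberg equilibrium
#'
#' A SNP is removed when its MAF falls below `maf_min` (strictly) or,
#' among those passing the MAF rule, when its HWE p-value falls below
#' `hwe_alpha` (strictly); boundary values are retained. Each removal is
#' recorded with the first failing rule.
#'
#' By default HWE is evaluated on the normal-condition genotypes only --
#' case-condition (tumour) genotypes can violate HWE for somatic rather
#' than technical reasons; set `hwe_samples = "all"` to pool both
#' conditions. MAF is always computed on all samples.
#'
#' @param study a [paired_study()].
#' @param maf_min MAF threshold in (0, 1); default 0.05.
#' @param hwe_alpha HWE significance threshold in (0, 1); default 0.05.
#' @param hwe_samples `"normal"` (default) or `"all"`.
#' @return An object of class `snp_qc`: a data frame with one row per
#'   input SNP (`snp_id`, `maf`, `hwe_p`, `status`, `reason`), in input
#'   order. `retained_snps()` extracts the surviving ids.
#' @export
filter_snps <- function(study, maf_min = 0.05, hwe_alpha = 0.05,
                        hwe_samples = c("normal", "all")) {
  stopifnot(inherits(study, "paired_study"))
  hwe_samples <- match.arg(hwe_samples)
  if (!(maf_min > 0 && maf_min < 1)) stopf("maf_min must lie in (0, 1)")
  if (!(hwe_alpha > 0 && hwe_alpha < 1)) stopf("hwe_alpha must lie in (0, 1)")
  if (!length(study$snp_ids)) {
    warnf("empty study: no SNPs to filter")
    return(structure(data.frame(snp_id = character(), maf = numeric(),
                                hwe_p = numeric(), status = character(),
                                reason = character(), stringsAsFactors = FALSE),
                     class = c("snp_qc", "data.frame")))
  }
  res <- lapply(study$snp_ids, function(s) {
    g_all <- c(study$normal[, s], study$tumor[, s])
    g_hwe <- if (hwe_samples == "normal") study$normal[, s] else g_all
    maf <- tryCatch(snp_maf(g_all), error = function(e) NA_real_)
    hwe <- tryCatch(hwe_test(genotype_counts(g_hwe)), error = function(e) NA_real_)
    if (is.na(maf)) {
      c(maf = NA, hwe = hwe, status = "removed_maf", reason = "all calls missing")
    } else if (maf < maf_min) {
      c(maf = maf, hwe = hwe, status = "removed_maf",
        reason = sprintf("MAF %.4f < %.4f", maf, maf_min))
    } else if (is.na(hwe) || hwe < hwe_alpha) {
      c(maf = maf, hwe = hwe, status = "removed_hwe",
        reason = sprintf("HWE p %.3g < %.3g", hwe, hwe_alpha))
    } else {
      c(maf = maf, hwe = hwe, status = "retained", reason = "")
    }
  })
  out <- data.frame(
    snp_id = study$snp_ids,
    maf = as.numeric(vapply(res, `[[`, "", "maf")),
    hwe_p = as.numeric(vapply(res, `[[`, "", "hwe")),
    status = vapply(res, `[[`, "", "status"),
    reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE)
  class(out) <- c("snp_qc", "data.frame")
  out
}

#' Extract retained SNP ids from a QC table
#'
#' @param qc result of [filter_snps()].
#' @return character vector of SNP ids with status `"retained"`.
#' @export
retained_snps <- function(qc) {
  stopifnot(inherits(qc, "snp_qc"))
  qc$snp_id[qc$status == "retained"]
}

#' @export
print.snp_qc <- function(x, ...) {
  tab <- table(factor(x$status, c("retained", "removed_maf", "removed_hwe")))
  cat(sprintf("SNP QC: %d in -> %d retained (%d removed by MAF, %d by HWE)\n",
              nrow(x), tab["retained"], tab["removed_maf"], tab["removed_hwe"]))
  invisible(x)
}

#' Map SNPs to genes by genomic window
#'
#' A SNP maps to a gene when it lies on the same chromosome within the
#' closed window `[start - flank, end + flank]` (1-based, inclusive at
#' both boundaries). A SNP may map to zero, one or several genes; each
#' overlapping gene counts it towards its SNP count `k`. Strand never
#' affects the result because the window is symmetric.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos` (see
#'   [read_snp_table()]).
#' @param genes data frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (see [read_gene_table()]).
#' @param flank window half-extension in bases; default 5000 (5 kb
#'   upstream and downstream).
#' @return An object of class `snp_gene_map`: list with `map` (data
#'   frame `snp_id`, `gene_id`, one row per incidence pair), `unmapped`
#'   (SNP ids hitting no window; excluded from integration) and `k`
#'   (named integer vector of per-gene SNP counts).
#' @export
map_snps_to_genes <- function(snps, genes, flank = 5000) {
  if (flank < 0) stopf("flank must be >= 0")
  for (col in c("snp_id", "chrom", "pos")) {
    if (is.null(snps[[col]])) stopf("snps: missing column '%s'", col)
  }
  for (col in c("gene_id", "chrom", "start", "end")) {
    if (is.null(genes[[col]])) stopf("genes: missing column '%s'", col)
  }
  if (nrow(snps) && nrow(genes)) {
    gr_snp <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
    gr_gene <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(1, genes$start - flank), genes$end + flank))
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene, ignore.strand = TRUE)
    map <- data.frame(
      snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  } else {
    map <- data.frame(snp_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  }
  k <- table(map$gene_id)
  structure(list(map = map,
                 unmapped = setdiff(snps$snp_id, map$snp_id),
                 k = stats::setNames(as.integer(k), names(k))),
            class = "snp_gene_map")
}

#' @export
print.snp_gene_map <- function(x, ...) {
  cat(sprintf("snp_gene_map: %d (SNP, gene) pairs over %d genes; %d unmapped SNPs\n",
              nrow(x$map), length(x$k), length(x$unmapped)))
  invisible(x)
}

#' Write / read a SNP-to-gene map as TSV
#'
#' @param map a `snp_gene_map` (for writing) or file path (for reading).
#' @param path output file.
#' @return `write_snp_gene_map` returns the path; `read_snp_gene_map`
#'   returns a `snp_gene_map` (with an empty `unmapped` slot, which is
#'   not representable in the two-column file).
#' @export
write_snp_gene_map <- function(map, path) {
  stopifnot(inherits(map, "snp_gene_map"))
  write_tsv(map$map, path)
}

#' @rdname write_snp_gene_map
#' @export
read_snp_gene_map <- function(path) {
  df <- require_cols(read_tsv(path), c("snp_id", "gene_id"), path)
  k <- table(df$gene_id)
  structure(list(map = df[c("snp_id", "gene_id")], unmapped = character(),
                 k = stats::setNames(as.integer(k), names(k))),
            class = "snp_gene_map")
}
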