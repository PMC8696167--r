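# Per-SNP association between genotype and paired phenotype via an exact
# multinomial symmetry test (Bowker-type extension of McNemar's test)
# with a Monte Carlo null.

#' Tabulate paired genotype transitions for one SNP
#'
#' Builds the 3x3 table of subjects with genotype i in the normal
#' condition and genotype j in the tumour condition. Subjects with a
#' missing call in either condition are dropped for this SNP.
#'
#' @param study a [paired_study()].
#' @param snp_id SNP identifier present in the study.
#' @return 3x3 integer matrix with dimnames `0:2` (normal x tumour).
#' @export
transition_table <- function(study, snp_id) {
  stopifnot(inherits(study, "paired_study"))
  if (!snp_id %in% study$snp_ids) stopf("SNP '%s' not present in study", snp_id)
  a <- study$normal[, snp_id]
  b <- study$tumor[, snp_id]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stopf("SNP '%s': all subjects have a missing call", snp_id)
  tab <- table(factor(a[keep], levels = 0:2), factor(b[keep], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3, dimnames = list(normal = 0:2, tumor = 0:2))
  m
}

#' Bowker-type symmetry statistic of a 3x3 transition table
#'
#' Sum over unordered genotype pairs i < j with any discordance of
#' `(n_ij - n_ji)^2 / (n_ij + n_ji)`. Zero iff the table is symmetric in
#' its discordant pairs; pairs with no discordant subjects contribute
#' nothing (and no degrees of freedom).
#'
#' @param table 3x3 count matrix (normal x tumour), e.g. from
#'   [transition_table()].
#' @return non-negative statistic.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- 8; m[2, 1] <- 2
#' symmetry_statistic(m)  # (8 - 2)^2 / 10 = 3.6
#' @export
symmetry_statistic <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(3, 3)), all(table >= 0))
  s <- 0
  for (i in 1:2) {
    for (j in (i + 1):3) {
      d <- table[i, j] + table[j, i]
      if (d > 0) s <- s + (table[i, j] - table[j, i])^2 / d
    }
  }
  s
}

discordant_pairs <- function(table) {
  d <- c(table[1, 2] + table[2, 1], table[1, 3] + table[3, 1],
         table[2, 3] + table[3, 2])
  d[d > 0]
}

#' Monte Carlo exact symmetry test for one transition table
#'
#' Tests marginal homogeneity of the paired genotype distribution. The
#' null keeps each unordered pair's total discordance fixed and
#' redistributes it as Binomial(n_ij + n_ji, 1/2) -- the exact
#' conditional null of the symmetry hypothesis; diagonal (concordant)
#' cells are ancillary and stay fixed. The p-value uses the add-one
#' convention `(b + 1) / (n_perm + 1)` and is therefore never exactly 0.
#'
#' @param table 3x3 transition table.
#' @param n_perm number of Monte Carlo replicates (default 1e5).
#' @param seed integer seed; the caller's RNG state is not disturbed.
#' @return list with `statistic`, `p_value`, `n_effective` (subjects in
#'   the table) and `n_perm`.
#' @export
mc_symmetry_test <- function(table, n_perm = 1e5, seed) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  stat <- symmetry_statistic(table)
  d <- discordant_pairs(table)
  n_eff <- sum(table)
  if (!length(d)) {
    return(list(statistic = 0, p_value = 1, n_effective = n_eff, n_perm = 0L))
  }
  n_perm <- as.integer(n_perm)
  p <- with_seed(seed, {
    x <- matrix(rbinom(n_perm * length(d), size = rep(d, each = n_perm), prob = 0.5),
                nrow = n_perm)
    dm <- matrix(d, n_perm, length(d), byrow = TRUE)
    rep_stat <- rowSums((2 * x - dm)^2 / dm)
    (sum(rep_stat >= stat) + 1) / (n_perm + 1)
  })
  list(statistic = stat, p_value = p, n_effective = n_eff, n_perm = n_perm)
}

#' Associate every SNP with the paired phenotype
#'
#' Runs [mc_symmetry_test()] per SNP. Each SNP draws its own RNG stream
#' from the master seed via [derive_seed()] keyed on the SNP id, so
#' results are independent of execution order. SNP-level failures (e.g.
#' all calls missing) are returned as flagged rows, not errors.
#'
#' @param study a [paired_study()].
#' @param snp_ids SNPs to test (default: all in the study; normally the
#'   QC-retained list).
#' @param n_perm Monte Carlo replicates per SNP (default 1e5).
#' @param seed master integer seed.
#' @param verbose log progress every 500 SNPs.
#' @return data frame of class `snp_association` with columns `snp_id`,
#'   `statistic`, `p_value`, `n_effective`, `note`.
#' @export
associate_all <- function(study, snp_ids = study$snp_ids, n_perm = 1e5, seed,
                          verbose = FALSE) {
  stopifnot(inherits(study, "paired_study"))
  if (!length(snp_ids)) stopf("no SNPs to test")
  rows <- vector("list", length(snp_ids))
  for (i in seq_along(snp_ids)) {
    s <- snp_ids[i]
    rows[[i]] <- tryCatch({
      r <- mc_symmetry_test(transition_table(study, s),
                            n_perm = n_perm, seed = derive_seed(seed, s))
      data.frame(snp_id = s, statistic = r$statistic, p_value = r$p_value,
                 n_effective = r$n_effective, note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(snp_id = s, statistic = NA_real_, p_value = NA_real_,
                 n_effective = 0L, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    if (verbose && i %% 500 == 0) vlog(TRUE, "associated %d / %d SNPs", i, length(snp_ids))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("snp_association", "data.frame")
  out
}

#' @export
print.snp_association <- function(x, ...) {
  ok <- !is.na(x$p_value)
  cat(sprintf("snp_association: %d SNPs (%d failed); %d with p < 0.05\n",
              nrow(x), sum(!ok), sum(x$p_value[ok] < 0.05)))
  invisible(x)
}

#' Write / read SNP association results as TSV
#'
#' @param assoc a `snp_association` data frame (for writing) or a file
#'   path (for reading).
#' @param path output file.
#' @return path / `snp_association` data frame.
#' @export
write_association <- function(assoc, path) {
  write_tsv(assoc, path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  df <- require_cols(read_tsv(path), c("snp_id", "p_value"), path)
  if (is.null(df$statistic)) df$statistic <- NA_real_
  if (is.null(df$n_effective)) df$n_effective <- NA_integer_
  if (is.null(df$note)) df$note <- ""
  ok <- !is.na(df$p_value)
  if (any(df$p_value[ok] <= 0 | df$p_value[ok] > 1)) {
    stopf("%s: p_value must lie in (0, 1]", path)
  }
  out <- df[c("snp_id", "statistic", "p_value", "n_effective", "note")]
  class(out) <- c("snp_association", "data.frame")
  out
}
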