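# Independent oracles used to cross-check the package implementations.

# Brute-force enrichment score: walk every prefix of the ranked list,
# accumulating the hit and miss profiles directly, and keep the first
# deviation of maximum magnitude.
# Ties in |deviation| (within 1e-12) resolve to the earliest prefix, the
# same documented convention the package uses.
brute_es <- function(r, member) {
  n <- length(r)
  nh <- sum(member)
  nr <- sum(abs(r[member]))
  ph <- pm <- 0
  devs <- numeric(n)
  for (i in seq_len(n)) {
    if (member[i]) ph <- ph + abs(r[i]) / nr else pm <- pm + 1 / (n - nh)
    devs[i] <- ph - pm
  }
  devs[which(abs(devs) >= max(abs(devs)) - 1e-12)[1]]
}

# Explicit combinatorial upper-tail hypergeometric sum:
# P(overlap >= x) for a set of size m drawn from N genes of which K are
# significant.
ora_oracle <- function(N, K, m, x) {
  xs <- x:min(m, K)
  sum(choose(K, xs) * choose(N - K, m - xs)) / choose(N, m)
}

# Hand-built paired study from genotype vectors (one element per SNP,
# each a subjects-long vector); tumour defaults to a copy of normal.
tiny_study <- function(normal_cols, tumor_cols = normal_cols) {
  normal <- do.call(cbind, normal_cols)
  tumor <- do.call(cbind, tumor_cols)
  colnames(normal) <- colnames(tumor) <- names(normal_cols)
  rownames(normal) <- rownames(tumor) <- sprintf("S%02d", seq_len(nrow(normal)))
  paired_study(normal, tumor)
}

# 3x3 transition table from off-diagonal counts.
tab3 <- function(n01 = 0, n10 = 0, n02 = 0, n20 = 0, n12 = 0, n21 = 0,
                 diag = c(0, 0, 0)) {
  m <- diag(diag)
  m[1, 2] <- n01; m[2, 1] <- n10
  m[1, 3] <- n02; m[3, 1] <- n20
  m[2, 3] <- n12; m[3, 2] <- n21
  dimnames(m) <- list(normal = 0:2, tumor = 0:2)
  m
}

# Gene scores data frame from a named p-value vector (enough structure
# for the enrichment algorithms).
scores_from_p <- function(p, method = "minimum", ld = FALSE) {
  out <- data.frame(gene_id = names(p), method = method, k = 1L,
                    statistic = NA_real_, p_gene = unname(p), ld = ld,
                    p_corr = NA_real_, p = unname(p), stringsAsFactors = FALSE)
  class(out) <- c("gene_scores", "data.frame")
  out
}

read_tsv_for_test <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
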