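# End-to-end orchestration: QC -> mapping -> paired association ->
# integration -> enrichment, plus a closure factory used by the
# benchmark metrics.

#' Run the full SNP gene-set-analysis pipeline
#'
#' Convenience wrapper chaining [filter_snps()], [map_snps_to_genes()],
#' [associate_all()] and [run_gsa_all()] under one master seed. Stage
#' seeds are derived with [derive_seed()], so any stage rerun in
#' isolation with the same master seed reproduces its output exactly.
#'
#' @param study a [paired_study()].
#' @param snps SNP table (`snp_id`, `chrom`, `pos`).
#' @param genes gene annotation table.
#' @param sets a [gene_set_collection()].
#' @param integrations,ld integration methods and LD settings to cross
#'   (passed to [run_gsa_all()]).
#' @param algorithms subset of [gsa_algorithms()].
#' @param maf_min,hwe_alpha,flank QC and mapping parameters.
#' @param assoc_n_perm Monte Carlo permutations per SNP association
#'   test.
#' @param enrich_n_perm permutations for permutation-based enrichment
#'   algorithms.
#' @param min_size,deg_alpha,percentile,top_snp_fraction enrichment
#'   parameters.
#' @param seed master integer seed.
#' @param verbose log per-stage counts.
#' @return list of class `gsa_pipeline`: `qc`, `map`, `assoc`,
#'   `results` (tidy `gsa_results`), `params`.
#' @export
gsa_pipeline <- function(study, snps, genes, sets,
                         integrations = "stouffer", ld = TRUE,
                         algorithms = gsa_algorithms(),
                         maf_min = 0.05, hwe_alpha = 0.05, flank = 5000,
                         assoc_n_perm = 1e5, enrich_n_perm = 1000,
                         min_size = 5, deg_alpha = 0.05, percentile = 75,
                         top_snp_fraction = 0.05, seed, verbose = FALSE) {
  qc <- filter_snps(study, maf_min, hwe_alpha)
  kept <- retained_snps(qc)
  vlog(verbose, "QC: %d of %d SNPs retained", length(kept), nrow(qc))
  if (!length(kept)) stopf("no SNP survives QC")
  map <- map_snps_to_genes(snps[snps$snp_id %in% kept, , drop = FALSE],
                           genes, flank)
  vlog(verbose, "mapping: %d (SNP, gene) pairs over %d genes; %d SNPs unmapped",
       nrow(map$map), length(map$k), length(map$unmapped))
  mapped <- intersect(kept, unique(map$map$snp_id))
  assoc <- associate_all(study, mapped, n_perm = assoc_n_perm,
                         seed = derive_seed(seed, "assoc"))
  vlog(verbose, "association: %d SNPs tested, %d with p < 0.05",
       nrow(assoc), sum(assoc$p_value < 0.05, na.rm = TRUE))
  results <- run_gsa_all(assoc, map, sets, algorithms = algorithms,
                         integrations = integrations, ld = ld,
                         n_perm = enrich_n_perm,
                         seed = derive_seed(seed, "enrich"),
                         deg_alpha = deg_alpha, percentile = percentile,
                         top_snp_fraction = top_snp_fraction,
                         min_size = min_size, verbose = verbose)
  structure(list(qc = qc, map = map, assoc = assoc, results = results,
                 params = list(integrations = integrations, ld = ld,
                               algorithms = algorithms, maf_min = maf_min,
                               hwe_alpha = hwe_alpha, flank = flank,
                               assoc_n_perm = assoc_n_perm,
                               enrich_n_perm = enrich_n_perm,
                               min_size = min_size, deg_alpha = deg_alpha,
                               percentile = percentile,
                               top_snp_fraction = top_snp_fraction,
                               seed = seed)),
            class = "gsa_pipeline")
}

#' @export
print.gsa_pipeline <- function(x, ...) {
  cat("gsa_pipeline run\n")
  print(x$qc)
  print(x$map)
  print(x$assoc)
  print(x$results)
  invisible(x)
}

#' Build a single-combination pipeline closure for benchmarking
#'
#' Returns a function `(study, seed) -> named vector of set p-values`
#' that runs QC, mapping, association and one enrichment algorithm for
#' one (integration, LD) combination -- the callable shape
#' [specificity_fpr()] and [reproducibility_auc()] expect. The
#' association stage is fully rerun on every call (the conservative
#' choice for phenotype-permutation specificity); lower `assoc_n_perm`
#' for speed.
#'
#' @inheritParams gsa_pipeline
#' @param algorithm one of [gsa_algorithms()].
#' @param integration one of [integration_methods()] (ignored by
#'   `gsea_snp`).
#' @return a function `(study, seed)`.
#' @export
make_pipeline <- function(snps, genes, sets, algorithm = "cerno",
                          integration = "stouffer", ld = TRUE,
                          maf_min = 0.05, hwe_alpha = 0.05, flank = 5000,
                          assoc_n_perm = 1000, enrich_n_perm = 200,
                          min_size = 5, deg_alpha = 0.05, percentile = 75,
                          top_snp_fraction = 0.05) {
  if (!algorithm %in% gsa_algorithms()) {
    stopf("unknown algorithm '%s'; valid names are %s", algorithm,
          paste(gsa_algorithms(), collapse = ", "))
  }
  force(list(snps, genes, sets, integration, ld))
  function(study, seed) {
    qc <- filter_snps(study, maf_min, hwe_alpha)
    kept <- retained_snps(qc)
    if (!length(kept)) stopf("no SNP survives QC")
    map <- map_snps_to_genes(snps[snps$snp_id %in% kept, , drop = FALSE],
                             genes, flank)
    mapped <- intersect(kept, unique(map$map$snp_id))
    assoc <- associate_all(study, mapped, n_perm = assoc_n_perm,
                           seed = derive_seed(seed, "assoc"))
    res <- if (algorithm == "gsea_snp") {
      gsea_snp(assoc, map, sets, enrich_n_perm, derive_seed(seed, "enrich"),
               min_size)
    } else if (algorithm == "igsea4gwas") {
      igsea4gwas(assoc, map, sets, integration, ld, enrich_n_perm,
                 derive_seed(seed, "enrich"), top_snp_fraction, min_size)
    } else {
      scores <- integrate_genes(assoc, map, integration, ld)
      switch(algorithm,
             gsea = gsea(scores, sets, enrich_n_perm,
                         derive_seed(seed, "enrich"), min_size),
             magenta75 = magenta75(scores, sets, enrich_n_perm,
                                   derive_seed(seed, "enrich"), percentile,
                                   min_size),
             ora = ora(scores, sets, deg_alpha, min_size),
             cerno = cerno(scores, sets, min_size))
    }
    stats::setNames(res$p, res$set_id)
  }
}
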