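# Seeded generator of paired GWAS studies with controllable within-gene
# LD, effect sizes and spiked target gene sets. Every other module is
# testable against this generator without external data.

#' Configuration for the synthetic paired GWAS generator
#'
#' Defaults emulate the scale of a matched tumour/normal SNP-array
#' study: 83 subject pairs, a KEGG-sized collection of 341 gene sets of
#' which 54 are phenotype targets. The genotype model draws, per gene, a
#' latent multivariate-normal vector with exchangeable correlation
#' `ld_rho` and thresholds it at the Hardy-Weinberg genotype boundaries
#' of a per-SNP allele frequency, which induces within-gene LD while
#' keeping marginal genotype frequencies at HWE. Tumour genotypes start
#' as copies of the normal ones; SNPs in effect genes are shifted one
#' genotype step towards more alternate alleles with probability
#' `effect_size` (creating the marginal asymmetry the paired test
#' targets), all other SNPs get a small symmetric discordance
#' `noise`.
#'
#' @param n_pairs subject pairs (default 83).
#' @param n_genes genes (default 300).
#' @param snps_per_gene length-2 integer range of SNPs per gene.
#' @param ld_rho within-gene latent correlation in `[0, 1)`.
#' @param maf_range length-2 range of per-SNP alternate-allele
#'   frequencies (folded MAF is drawn uniformly in this range).
#' @param n_sets gene sets (default 341).
#' @param n_target_sets target (spiked) sets (default 54).
#' @param genes_per_set length-2 range of genes per set.
#' @param n_effect_genes genes carrying associated SNPs (default 60).
#' @param causal_fraction fraction of an effect gene's SNPs that carry
#'   the shift (at least one); association signals within a gene are
#'   typically asymmetric -- driven by one or a few causal variants --
#'   rather than spread over every SNP (default 0.5).
#' @param effect_size per-subject probability of the asymmetric tumour
#'   genotype shift for causal SNPs (0 = global null; default 0.4).
#' @param noise per-subject probability of a symmetric one-step shift
#'   for non-associated SNPs (default 0.02).
#' @param target_enrichment fraction of each target set's genes drawn
#'   from the effect genes (default 0.8).
#' @param n_intergenic_snps SNPs placed outside every gene window
#'   (default 10), exercising the unmapped-SNP path.
#' @param missing_rate per-call probability of a missing genotype
#'   (default 0).
#' @param seed master seed for the whole simulation.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 83L, n_genes = 300L, snps_per_gene = c(1L, 10L),
                       ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       n_sets = 341L, n_target_sets = 54L,
                       genes_per_set = c(5L, 25L), n_effect_genes = 60L,
                       causal_fraction = 0.5, effect_size = 0.4, noise = 0.02,
                       target_enrichment = 0.8, n_intergenic_snps = 10L,
                       missing_rate = 0, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene), ld_rho = ld_rho,
              maf_range = maf_range, n_sets = as.integer(n_sets),
              n_target_sets = as.integer(n_target_sets),
              genes_per_set = as.integer(genes_per_set),
              n_effect_genes = as.integer(n_effect_genes),
              causal_fraction = causal_fraction,
              effect_size = effect_size, noise = noise,
              target_enrichment = target_enrichment,
              n_intergenic_snps = as.integer(n_intergenic_snps),
              missing_rate = missing_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_pairs < 1 || n_genes < 1 || n_sets < 1) stopf("counts must be positive")
    if (!(ld_rho >= 0 && ld_rho < 1)) stopf("ld_rho must lie in [0, 1)")
    if (length(snps_per_gene) != 2 || snps_per_gene[1] < 1 ||
        snps_per_gene[1] > snps_per_gene[2]) stopf("snps_per_gene must be an increasing range >= 1")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) stopf("maf_range must lie within (0, 0.5]")
    if (n_target_sets > n_sets) stopf("target sets must be a subset of all sets")
    if (n_effect_genes > n_genes) stopf("effect genes exceed total genes")
    if (genes_per_set[2] > n_genes) stopf("genes_per_set exceeds available genes")
    if (causal_fraction <= 0 || causal_fraction > 1) stopf("causal_fraction must lie in (0, 1]")
    if (effect_size < 0 || effect_size > 1 || noise < 0 || noise > 1 ||
        target_enrichment < 0 || target_enrichment > 1 ||
        missing_rate < 0 || missing_rate >= 1) stopf("probabilities must lie in [0, 1]")
  })
  structure(cfg, class = "sim_config")
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()] (for writing) or file path (for
#'   reading).
#' @param path output file.
#' @return path / `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate a paired genotype study with within-gene LD
#'
#' See [sim_config()] for the generative model. Genes are laid out on
#' four chromosomes with SNPs 500 bp apart inside the gene body and
#' >= 5 kb of clear space between gene windows, so the default mapping
#' flank reproduces the intended SNP-gene structure exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `study` (a [paired_study()]),
#'   `snps` (SNP table), `genes` (gene annotations), `truth` (list with
#'   per-SNP `snp` flags, per-gene `gene` flags) and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    k_g <- sample_from(seq(config$snps_per_gene[1], config$snps_per_gene[2]),
                       n_genes, replace = TRUE)
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 4L + 1L)
    # per-chromosome layout: gene i starts 15 kb after the previous end
    start <- integer(n_genes)
    end <- integer(n_genes)
    cursor <- stats::setNames(rep(1L, 4), paste0("chr", 1:4))
    for (i in seq_len(n_genes)) {
      start[i] <- cursor[chrom[i]] + 15000L
      end[i] <- start[i] + k_g[i] * 500L
      cursor[chrom[i]] <- end[i]
    }
    genes <- data.frame(gene_id = gene_ids, chrom = chrom, start = start,
                        end = end, strand = rep(c("+", "-"), length.out = n_genes),
                        stringsAsFactors = FALSE)
    effect_genes <- sort(sample_from(gene_ids, config$n_effect_genes))

    snp_rows <- list()
    normal_cols <- list()
    n <- config$n_pairs
    for (i in seq_len(n_genes)) {
      k <- k_g[i]
      f <- runif(k, config$maf_range[1], config$maf_range[2])
      w <- rnorm(n)
      z <- sqrt(config$ld_rho) * matrix(w, n, k) +
        sqrt(1 - config$ld_rho) * matrix(rnorm(n * k), n, k)
      u <- pnorm(z)
      c0 <- matrix((1 - f)^2, n, k, byrow = TRUE)
      c1 <- matrix((1 - f)^2 + 2 * f * (1 - f), n, k, byrow = TRUE)
      geno <- (u > c0) + (u > c1)
      ids <- sprintf("rs%04d_%02d", i, seq_len(k))
      causal <- rep(FALSE, k)
      if (gene_ids[i] %in% effect_genes) {
        n_causal <- max(1L, round(config$causal_fraction * k))
        causal[sample.int(k, n_causal)] <- TRUE
      }
      snp_rows[[i]] <- data.frame(
        snp_id = ids, chrom = chrom[i],
        pos = start[i] + (seq_len(k) - 1L) * 500L + 250L,
        gene_id = gene_ids[i], associated = causal,
        stringsAsFactors = FALSE)
      colnames(geno) <- ids
      normal_cols[[i]] <- geno
    }
    # intergenic SNPs: far beyond the last window on chr1
    if (config$n_intergenic_snps > 0) {
      k <- config$n_intergenic_snps
      f <- runif(k, config$maf_range[1], config$maf_range[2])
      u <- matrix(runif(n * k), n, k)
      c0 <- matrix((1 - f)^2, n, k, byrow = TRUE)
      c1 <- matrix((1 - f)^2 + 2 * f * (1 - f), n, k, byrow = TRUE)
      geno <- (u > c0) + (u > c1)
      ids <- sprintf("rsX%04d", seq_len(k))
      colnames(geno) <- ids
      snp_rows[[n_genes + 1]] <- data.frame(
        snp_id = ids, chrom = "chr1",
        pos = max(end[chrom == "chr1"]) + 50000L + seq_len(k) * 1000L,
        gene_id = NA_character_, associated = FALSE, stringsAsFactors = FALSE)
      normal_cols[[n_genes + 1]] <- geno
    }
    snps <- do.call(rbind, snp_rows)
    normal <- do.call(cbind, normal_cols)
    rownames(normal) <- sprintf("P%03d", seq_len(n))

    # tumour condition: asymmetric one-step shifts for associated SNPs,
    # small symmetric discordance elsewhere
    tumor <- normal
    assoc_cols <- which(snps$associated)
    for (j in assoc_cols) {
      shift <- runif(n) < config$effect_size
      tumor[shift, j] <- pmin(tumor[shift, j] + 1, 2)
    }
    for (j in setdiff(seq_len(ncol(tumor)), assoc_cols)) {
      flip <- runif(n) < config$noise
      if (any(flip)) {
        step <- sample(c(-1, 1), sum(flip), replace = TRUE)
        tumor[flip, j] <- pmin(pmax(tumor[flip, j] + step, 0), 2)
      }
    }
    if (config$missing_rate > 0) {
      normal[matrix(runif(length(normal)) < config$missing_rate,
                    nrow(normal))] <- NA
      tumor[matrix(runif(length(tumor)) < config$missing_rate,
                   nrow(tumor))] <- NA
    }
    structure(list(
      study = paired_study(normal, tumor),
      snps = snps[c("snp_id", "chrom", "pos")],
      genes = genes,
      truth = list(snp = snps[c("snp_id", "gene_id", "associated")],
                   gene = data.frame(gene_id = gene_ids,
                                     effect = gene_ids %in% effect_genes,
                                     stringsAsFactors = FALSE)),
      config = config), class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("sim_study: %d pairs, %d SNPs in %d genes ",
                     "(%d effect genes, %d associated SNPs)\n"),
              length(x$study$subjects), nrow(x$snps), nrow(x$genes),
              sum(x$truth$gene$effect), sum(x$truth$snp$associated)))
  invisible(x)
}

#' Simulate a gene set collection with spiked target sets
#'
#' Target sets draw a configurable fraction of their members from the
#' effect genes (the spike); background sets draw uniformly from all
#' genes. Overlap between sets is permitted, as in real pathway
#' collections.
#'
#' @param config a [sim_config()].
#' @param gene_ids universe of gene ids (typically `sim$genes$gene_id`).
#' @param truth the `truth` element of a [simulate_study()] result.
#' @return a [gene_set_collection()] with the `targets` attribute set.
#' @export
simulate_gene_sets <- function(config, gene_ids, truth) {
  stopifnot(inherits(config, "sim_config"))
  effect <- intersect(truth$gene$gene_id[truth$gene$effect], gene_ids)
  others <- setdiff(gene_ids, effect)
  with_seed(derive_seed(config$seed, "gene_sets"), {
    sizes <- sample_from(seq(config$genes_per_set[1], config$genes_per_set[2]),
                         config$n_sets, replace = TRUE)
    set_names <- sprintf("GS%04d", seq_len(config$n_sets))
    target_ids <- sort(sample_from(set_names, config$n_target_sets))
    sets <- lapply(seq_len(config$n_sets), function(i) {
      size <- sizes[i]
      if (set_names[i] %in% target_ids) {
        n_eff <- min(round(config$target_enrichment * size), length(effect))
        c(sample_from(effect, n_eff),
          sample_from(others, size - n_eff))
      } else {
        sample_from(gene_ids, size)
      }
    })
    gene_set_collection(
      stats::setNames(sets, set_names),
      description = stats::setNames(
        ifelse(set_names %in% target_ids, "target", "background"), set_names),
      targets = target_ids)
  })
}

#' A small deterministic fixture study
#'
#' A tiny bundled simulation (30 pairs, 40 genes, < 200 SNPs, 15 sets of
#' which 2 are strongly spiked targets) regenerated from a fixed
#' internal seed, for unit tests and examples. Guaranteed to contain at
#' least one gene with a single SNP (k = 1 identity path) and one with
#' k >= 5.
#'
#' @return list as [simulate_study()] plus a `sets` element.
#' @export
small_fixture <- function() {
  cfg <- sim_config(n_pairs = 30L, n_genes = 40L, snps_per_gene = c(1L, 6L),
                    ld_rho = 0.5, maf_range = c(0.1, 0.5), n_sets = 15L,
                    n_target_sets = 2L, genes_per_set = c(5L, 10L),
                    n_effect_genes = 12L, causal_fraction = 1,
                    effect_size = 0.5, noise = 0.01,
                    target_enrichment = 1, n_intergenic_snps = 5L,
                    seed = 424242L)
  sim <- simulate_study(cfg)
  sim$sets <- simulate_gene_sets(cfg, sim$genes$gene_id, sim$truth)
  sim
}

#' Write all simulation artifacts to a directory
#'
#' Emits the genotype TSV, SNP and gene annotation TSVs, truth table,
#' config YAML and (when sets are present) the GMT, plus a provenance
#' sidecar for the genotype table.
#'
#' @param sim result of [simulate_study()] (optionally with a `sets`
#'   element) .
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_study(sim$study, file.path(dir, "genotypes.tsv"))
  write_tsv(sim$snps, file.path(dir, "snps.tsv"))
  write_tsv(sim$genes, file.path(dir, "genes.tsv"))
  write_tsv(sim$truth$snp, file.path(dir, "truth_snps.tsv"))
  write_tsv(sim$truth$gene, file.path(dir, "truth_genes.tsv"))
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  if (!is.null(sim$sets)) write_gmt(sim$sets, file.path(dir, "sets.gmt"))
  write_provenance(file.path(dir, "genotypes.tsv"), sim$config$seed,
                   unclass(sim$config))
  invisible(dir)
}
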