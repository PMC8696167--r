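test_that("configuration validation rejects infeasible settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_effect_genes = 500, n_genes = 100), "exceed")
  expect_error(sim_config(n_target_sets = 400, n_sets = 341), "subset")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(causal_fraction = 0), "causal_fraction")
  cfg <- sim_config(n_pairs = 10)
  tmp <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, tmp)
  expect_equal(read_sim_config(tmp), cfg)
})

test_that("normal-condition genotypes respect HWE and the MAF range", {
  cfg <- sim_config(n_pairs = 200, n_genes = 150, snps_per_gene = c(1, 3),
                    ld_rho = 0.5, maf_range = c(0.2, 0.5), n_sets = 5,
                    n_target_sets = 0, genes_per_set = c(3, 5),
                    n_effect_genes = 0, effect_size = 0, noise = 0,
                    n_intergenic_snps = 0, seed = 123)
  sim <- simulate_study(cfg)
  hwe_p <- apply(sim$study$normal, 2, function(g) hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2))))
  rej <- mean(hwe_p < 0.05)
  n <- length(hwe_p)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
  maf <- apply(sim$study$normal, 2, snp_maf)
  expect_gt(min(maf), 0.1)  # drawn in [0.2, 0.5]; sampling noise bounded
})

test_that("the LD knob controls within-gene genotype correlation", {
  base <- list(n_pairs = 300, n_genes = 40, snps_per_gene = c(4, 4),
               maf_range = c(0.3, 0.5), n_sets = 5, n_target_sets = 0,
               genes_per_set = c(3, 5), n_effect_genes = 0, effect_size = 0,
               noise = 0, n_intergenic_snps = 0, seed = 321)
  mean_r2 <- function(rho) {
    sim <- simulate_study(do.call(sim_config, c(base, ld_rho = rho)))
    per_gene <- split(sim$truth$snp$snp_id, sim$truth$snp$gene_id)
    mean(vapply(per_gene, function(ids) {
      cc <- cor(sim$study$normal[, ids])
      mean(cc[upper.tri(cc)]^2)
    }, numeric(1)))
  }
  expect_lt(mean_r2(0), 0.02)
  expect_gt(mean_r2(0.9), 0.3)
})

test_that("the effect knob concentrates small association p-values on causal SNPs", {
  cfg <- sim_config(n_pairs = 83, n_genes = 60, snps_per_gene = c(1, 4),
                    ld_rho = 0.3, maf_range = c(0.2, 0.5), n_sets = 5,
                    n_target_sets = 0, genes_per_set = c(3, 5),
                    n_effect_genes = 20, effect_size = 0.4, noise = 0.05,
                    n_intergenic_snps = 0, seed = 55)
  sim <- simulate_study(cfg)
  assoc <- associate_all(sim$study, n_perm = 300, seed = 56)
  flagged <- sim$truth$snp$associated[match(assoc$snp_id, sim$truth$snp$snp_id)]
  expect_gt(sum(flagged), 5)
  w <- wilcox.test(assoc$p_value[flagged], assoc$p_value[!flagged],
                   alternative = "less")
  expect_lt(w$p.value, 1e-6)
})

test_that("a null generator yields uniform association behaviour", {
  cfg <- sim_config(n_pairs = 60, n_genes = 80, snps_per_gene = c(1, 2),
                    ld_rho = 0, maf_range = c(0.2, 0.5), n_sets = 5,
                    n_target_sets = 0, genes_per_set = c(3, 5),
                    n_effect_genes = 0, effect_size = 0, noise = 0.3,
                    n_intergenic_snps = 0, seed = 66)
  sim <- simulate_study(cfg)
  assoc <- associate_all(sim$study, n_perm = 400, seed = 67)
  expect_lte(mean(assoc$p_value < 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / nrow(assoc)))
})

test_that("gene set simulation spikes targets with effect genes", {
  cfg <- sim_config(n_genes = 300, n_sets = 341, n_target_sets = 54,
                    genes_per_set = c(5, 25), n_effect_genes = 60,
                    target_enrichment = 1, seed = 2)
  sim <- simulate_study(cfg)
  sets <- simulate_gene_sets(cfg, sim$genes$gene_id, sim$truth)
  expect_length(sets, 341)
  targets <- attr(sets, "targets")
  expect_length(targets, 54)
  effect <- sim$truth$gene$gene_id[sim$truth$gene$effect]
  # enrichment fraction 1: every target-set gene is an effect gene
  # (up to the size of the effect pool)
  for (t in targets[1:10]) {
    expect_gte(mean(sets[[t]] %in% effect), min(1, 60 / length(sets[[t]])))
  }
  bg <- setdiff(names(sets), targets)
  expect_lt(mean(unlist(sets[bg]) %in% effect), 0.5)
})

test_that("the bundled fixture is reproducible and structurally rich", {
  f1 <- small_fixture()
  f2 <- small_fixture()
  expect_identical(f1, f2)
  expect_lte(nrow(f1$snps), 200)
  expect_lte(nrow(f1$genes), 50)
  expect_lte(length(f1$sets), 20)
  k <- table(f1$truth$snp$gene_id)
  expect_true(any(k == 1))   # single-SNP gene exercises identity paths
  expect_true(any(k >= 5))
  expect_length(attr(f1$sets, "targets"), 2)
})

test_that("simulation artifacts round-trip through the plain-text writers", {
  fx <- small_fixture()
  dir <- tempfile("simout")
  write_simulation(fx, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genotypes.tsv", "snps.tsv", "genes.tsv", "sets.gmt",
           "config.yaml", "truth_snps.tsv", "genotypes.tsv.provenance.json")))))
  study <- read_genotype_study(file.path(dir, "genotypes.tsv"))
  expect_equal(study$normal, fx$study$normal)
  expect_equal(study$tumor, fx$study$tumor)
  expect_equal(read_snp_table(file.path(dir, "snps.tsv")), fx$snps,
               ignore_attr = TRUE)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_equal(lapply(sets, sort), lapply(fx$sets, sort), ignore_attr = TRUE)
})
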