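test_that("running enrichment score reproduces the worked prefix walk", {
  rl <- ranked_list(paste0("g", 1:5), 10^-c(3, 2, 1, 1, 1))
  r <- running_enrichment_score(rl, c("g1", "g3"))
  expect_equal(r$es, 0.75)
  expect_equal(r$position, 1)
  # full prefix deviations: 0.75, 0.417, 0.667, 0.333, 0
  expect_equal(r$p_hit - r$p_miss,
               c(0.75, 0.75 - 1 / 3, 1 - 1 / 3, 1 - 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(r$p_hit[5], 1)
  expect_equal(r$p_miss[5], 1)
  expect_error(running_enrichment_score(rl, paste0("g", 1:5)), "< N")
  rl2 <- ranked_list(c("a", "b"), c(0.01, 1))
  expect_error(running_enrichment_score(rl2, "b"), "degenerate")
})

test_that("enrichment score equals the brute-force prefix scan", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    ids <- sprintf("g%02d", 1:n)
    rl <- ranked_list(ids, runif(n, 1e-6, 1))
    nh <- sample(1:(n - 1), 1)
    set <- sample(ids, nh)
    if (sum(abs(rl$r[rl$id %in% set])) == 0) next
    r <- running_enrichment_score(rl, set)
    expect_equal(r$es, brute_es(rl$r, rl$id %in% set), tolerance = 1e-12)
    expect_gte(r$es, -1); expect_lte(r$es, 1)
  }
})

test_that("ranked lists sort by significance with lexical tie-break", {
  rl <- ranked_list(c("b", "a", "c"), c(0.5, 0.5, 0.01))
  expect_equal(rl$id, c("c", "a", "b"))
  expect_error(ranked_list(c("a", "a"), c(0.1, 0.2)))
})

test_that("GSEA finds a spiked set and is seed-deterministic", {
  set.seed(53)
  ids <- sprintf("g%03d", 1:60)
  p <- runif(60, 0.05, 1)
  spike <- sample(ids, 8)
  p[ids %in% spike] <- 1e-6
  sc <- scores_from_p(setNames(p, ids))
  sets <- c(list(SPIKE = spike),
            lapply(setNames(1:10, paste0("BG", 1:10)),
                   function(i) sample(ids, 8)))
  r1 <- gsea(sc, sets, n_perm = 200, seed = 6)
  expect_equal(r1$set_id[which.min(r1$p)], "SPIKE")
  expect_true(all(r1$p >= 1 / 201 & r1$p <= 1))
  expect_true(all(r1$p_adj >= r1$p))
  r2 <- gsea(sc, sets, n_perm = 200, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$p, gsea(sc, sets, n_perm = 200, seed = 7)$p))
})

test_that("GSEA-SNP degenerates to GSEA when every gene has exactly one SNP", {
  set.seed(59)
  ids <- sprintf("u%03d", 1:40)
  p <- runif(40)
  assoc <- data.frame(snp_id = ids, statistic = 1, p_value = p,
                      n_effective = 10L, note = "")
  map <- structure(list(map = data.frame(snp_id = ids, gene_id = ids),
                        unmapped = character(),
                        k = setNames(rep(1L, 40), ids)),
                   class = "snp_gene_map")
  sets <- lapply(setNames(1:6, paste0("S", 1:6)), function(i) sample(ids, 7))
  rs <- gsea_snp(assoc, map, sets, n_perm = 150, seed = 8)
  # minimum integration without LD leaves p and ids untouched, so the
  # two ranked universes coincide and the machinery must agree exactly
  sc <- integrate_genes(assoc, map, "minimum")
  rg <- gsea(sc, sets, n_perm = 150, seed = 8)
  expect_equal(rs$statistic, rg$statistic)
  expect_equal(rs$p, rg$p)
})

test_that("i-GSEA4GWAS reweights by significance fractions and stays in bounds", {
  set.seed(61)
  n_gene <- 40
  gene_ids <- sprintf("g%03d", 1:n_gene)
  snp_ids <- sprintf("r%03d", 1:(2 * n_gene))
  gene_of <- rep(gene_ids, each = 2)
  p <- runif(2 * n_gene, 0.01, 1)
  spike_genes <- gene_ids[1:8]
  p[gene_of %in% spike_genes] <- runif(16, 1e-6, 1e-4)
  assoc <- data.frame(snp_id = snp_ids, statistic = 1, p_value = p,
                      n_effective = 10L, note = "")
  map <- structure(list(map = data.frame(snp_id = snp_ids, gene_id = gene_of),
                        unmapped = character(),
                        k = setNames(rep(2L, n_gene), gene_ids)),
                   class = "snp_gene_map")
  sets <- c(list(SPIKE = spike_genes),
            lapply(setNames(1:8, paste0("B", 1:8)),
                   function(i) sample(gene_ids, 8)))
  r <- igsea4gwas(assoc, map, sets, method = "minimum", ld = FALSE,
                  n_perm = 100, seed = 10)
  expect_equal(r$set_id[which.min(r$p)], "SPIKE")
  expect_true(all(r$p >= 1 / 101 & r$p <= 1))
  r2 <- igsea4gwas(assoc, map, sets, method = "minimum", ld = FALSE,
                   n_perm = 100, seed = 10)
  expect_identical(r, r2)
  expect_error(igsea4gwas(assoc, map, sets, top_snp_fraction = 1.5, seed = 1),
               "top_snp_fraction")
})

test_that("MAGENTA75 counts the leading edge below the global percentile cutoff", {
  p <- c(0.01, 0.2, 0.6, 0.9, seq(0.05, 1, length.out = 16))
  names(p) <- sprintf("g%02d", seq_along(p))
  sc <- scores_from_p(p)
  cutoff <- quantile(p, 0.75)
  set <- names(p)[1:4]
  r <- magenta75(sc, list(S1 = set, S2 = names(p)[5:10]), n_perm = 200,
                 seed = 12, min_size = 4)
  expect_equal(r$statistic[r$set_id == "S1"], sum(p[set] < cutoff))
  expect_true(all(r$p >= 1 / 201 & r$p <= 1))
  # set equal to the whole universe: mock always matches, p must be 1
  rall <- magenta75(sc, list(ALL = names(p)), n_perm = 100, seed = 13,
                    min_size = 4)
  expect_equal(rall$p, 1)
})

test_that("ORA equals the closed-form hypergeometric upper tail", {
  # universe 20, set 5, 4 significant genes, overlap 3 -> 155/4845
  p <- rep(0.5, 20); names(p) <- sprintf("g%02d", 1:20)
  p[c("g01", "g02", "g03", "g04")] <- 0.01
  set <- c("g01", "g02", "g03", "g05", "g06")
  r <- ora(scores_from_p(p), list(S = set))
  expect_equal(r$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(r$n_hits, 3L)
  # zero overlap: upper tail at 0 is 1
  r0 <- ora(scores_from_p(p), list(S = sprintf("g%02d", 10:17)))
  expect_equal(r0$p, 1)
  # no significant genes at all: warned, p = 1
  pz <- setNames(rep(0.9, 20), names(p))
  expect_warning(rz <- ora(scores_from_p(pz), list(S = set)), "zero significant")
  expect_equal(rz$p, 1)
})

test_that("CERNO matches Fisher integration of relative ranks", {
  p <- c(g1 = 0.01, g2 = 0.02, g3 = 0.3, g4 = 0.4)
  r <- cerno(scores_from_p(p), list(S = c("g1", "g2")), min_size = 2)
  expect_equal(r$statistic, -2 * (log(0.25) + log(0.5)), tolerance = 1e-12)
  expect_equal(r$p, pchisq(r$statistic, df = 4, lower.tail = FALSE))
  # the worst-ranked singleton has F = 0, p = 1
  r2 <- cerno(scores_from_p(p), list(S = "g4"), min_size = 1)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  # set = universe: statistic depends only on N (degenerate-case guard)
  rall1 <- cerno(scores_from_p(p), list(S = names(p)), min_size = 4)
  p_other <- c(g1 = 0.9, g2 = 0.5, g3 = 0.001, g4 = 0.2)
  rall2 <- cerno(scores_from_p(p_other), list(S = names(p_other)), min_size = 4)
  expect_equal(rall1$statistic, rall2$statistic)
  # ties take average ranks
  ptie <- c(a = 0.2, b = 0.2, c = 0.8, d = 0.9)
  rt <- cerno(scores_from_p(ptie), list(S = c("a", "b")), min_size = 2)
  expect_equal(rt$statistic, -4 * log(1.5 / 4), tolerance = 1e-12)
})

test_that("CERNO p-values are uniform under a random universe", {
  set.seed(71)
  pvals <- replicate(300, {
    p <- setNames(runif(50), sprintf("g%02d", 1:50))
    cerno(scores_from_p(p), list(S = sample(names(p), 8)))$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("run_gsa_all produces the full tidy grid deterministically", {
  fx <- small_fixture()
  qc <- filter_snps(fx$study)
  map <- map_snps_to_genes(fx$snps[fx$snps$snp_id %in% retained_snps(qc), ],
                           fx$genes)
  assoc <- associate_all(fx$study,
                         intersect(retained_snps(qc), unique(map$map$snp_id)),
                         n_perm = 200, seed = 14)
  res <- run_gsa_all(assoc, map, fx$sets,
                     algorithms = c("cerno", "ora", "gsea_snp"),
                     integrations = c("minimum", "stouffer"),
                     ld = c(FALSE, TRUE), n_perm = 100, seed = 15)
  combos <- unique(res[c("algorithm", "integration", "ld")])
  expect_equal(nrow(combos), 2 * 2 * 2 + 1)  # gsea_snp runs once
  expect_setequal(names(res), c("algorithm", "integration", "ld", "set_id",
                                "statistic", "p", "p_adj", "set_size", "n_hits"))
  res2 <- run_gsa_all(assoc, map, fx$sets,
                      algorithms = c("cerno", "ora", "gsea_snp"),
                      integrations = c("minimum", "stouffer"),
                      ld = c(FALSE, TRUE), n_perm = 100, seed = 15)
  expect_identical(res, res2)
  expect_error(run_gsa_all(assoc, map, fx$sets, algorithms = "camera", seed = 1),
               "cerno")
})
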