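test_that("Storey sensitivity separates null, alternative and mixed collections", {
  set.seed(81)
  expect_equal(sensitivity_storey(rep(1e-8, 50)), 1, tolerance = 1e-6)
  expect_lte(sensitivity_storey(runif(341)), 0.15)
  mix <- c(runif(500), rbeta(500, 0.05, 1) * 1e-3)
  expect_lt(abs(sensitivity_storey(mix) - 0.5), 0.1)
  expect_warning(s <- sensitivity_storey(runif(10)), "single-lambda")
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("prioritization is the median rank of target sets", {
  p <- setNames((1:10) / 100, paste0("S", 1:10))
  expect_equal(prioritization(p, c("S2", "S5", "S8")), 5)
  # all targets on top: best achievable value (t + 1) / 2
  expect_equal(prioritization(p, paste0("S", 1:4)), 2.5)
  expect_equal(prioritization(p, "S10"), 10)
  expect_error(prioritization(p, character()), "nonempty")
  expect_error(prioritization(p, "nope"), "none of the target")
  # random scores: expected median near (N + 1) / 2
  set.seed(83)
  meds <- replicate(200, prioritization(setNames(runif(21), paste0("S", 1:21)),
                                        c("S3", "S9", "S17")))
  expect_lt(abs(mean(meds) - 11), 1.5)
})

test_that("phenotype permutation swaps whole subjects and preserves pairing", {
  fx <- small_fixture()
  perm <- permute_phenotype(fx$study, seed = 99)
  expect_identical(perm$subjects, fx$study$subjects)
  swapped <- perm$normal[, 1] != fx$study$normal[, 1] |
    perm$normal[, 2] != fx$study$normal[, 2]
  # swapped subjects carry the tumour genotypes in the normal slot
  expect_true(any(rowSums(perm$normal != fx$study$normal, na.rm = TRUE) > 0))
  i <- which(rowSums(perm$normal != fx$study$normal, na.rm = TRUE) > 0)[1]
  expect_equal(perm$normal[i, ], fx$study$tumor[i, ])
  expect_equal(perm$tumor[i, ], fx$study$normal[i, ])
  expect_identical(permute_phenotype(fx$study, 99), perm)
})

test_that("specificity deviation reflects the pipeline's null behaviour", {
  fx <- small_fixture()
  uniform_pipe <- function(study, seed) {
    set.seed(seed)
    setNames(runif(400), paste0("S", 1:400))
  }
  r <- specificity_fpr(uniform_pipe, fx$study, n_label_perms = 20, seed = 7)
  expect_lt(r$deviation, 0.02)
  anti_pipe <- function(study, seed) setNames(rep(0.001, 50), paste0("S", 1:50))
  r2 <- specificity_fpr(anti_pipe, fx$study, n_label_perms = 5, seed = 7)
  expect_equal(r2$fpr_mean, 1)
  expect_equal(r2$deviation, 0.95)
  r3 <- specificity_fpr(uniform_pipe, fx$study, n_label_perms = 20, seed = 7)
  expect_identical(r, r3)
  # failing permutations are skipped with a warning, not fatal
  flaky <- local({
    calls <- 0
    function(study, seed) {
      calls <<- calls + 1
      if (calls %% 3 == 0) stop("boom")
      setNames(runif(100), paste0("S", 1:100))
    }
  })
  expect_warning(r4 <- specificity_fpr(flaky, fx$study, n_label_perms = 6, seed = 1),
                 "skipped")
  expect_equal(r4$n_failed, 2)
})

test_that("reproducibility AUC spans identical to unrelated rankings", {
  fx <- small_fixture()
  same_pipe <- function(study, seed) setNames((1:200) / 1000, sprintf("S%03d", 1:200))
  r <- reproducibility_auc(same_pipe, fx$study, n_subsets = 3, subset_size = 8,
                           cutoffs = c(5, 10, 20), seed = 5)
  expect_equal(r$auc, 1)
  rand_pipe <- function(study, seed) {
    set.seed(seed); setNames(runif(200), sprintf("S%03d", 1:200))
  }
  r2 <- reproducibility_auc(rand_pipe, fx$study, n_subsets = 3, subset_size = 8,
                            cutoffs = c(5, 10, 20), seed = 5)
  expect_lt(r2$auc, 0.1)
  expect_identical(reproducibility_auc(rand_pipe, fx$study, n_subsets = 3,
                                       subset_size = 8, cutoffs = c(5, 10, 20),
                                       seed = 5), r2)
  expect_error(reproducibility_auc(same_pipe, fx$study, n_subsets = 5,
                                   subset_size = 14, seed = 1),
               "need 70 subject pairs")
})

test_that("normalization orients, scales and ranks combinations", {
  reports <- data.frame(
    combination = c("best", "mid", "worst"),
    sensitivity = c(0.9, 0.5, 0.1),
    prioritization = c(5, 20, 60),
    specificity_deviation = c(0.01, 0.05, 0.3),
    reproducibility_auc = c(0.8, 0.5, 0.2))
  r <- normalize_and_rank(reports, cluster = FALSE)
  expect_equal(r$combination[r$overall_rank == 1], "best")
  expect_equal(r$norm_sensitivity[r$combination == "best"], 0)
  expect_equal(r$norm_sensitivity[r$combination == "worst"], 1)
  # two identical reports tie
  r2 <- normalize_and_rank(reports[c(1, 1, 3), ], cluster = FALSE)
  expect_equal(r2$overall_rank[1:2], c(1.5, 1.5))
  # rank order invariant to per-metric rescaling
  reports2 <- reports; reports2$prioritization <- reports2$prioritization * 10
  r3 <- normalize_and_rank(reports2, cluster = FALSE)
  expect_equal(r3$overall_rank[order(r3$combination)],
               r$overall_rank[order(r$combination)])
  const <- reports; const$reproducibility_auc <- 0.5
  expect_warning(r4 <- normalize_and_rank(const, cluster = FALSE), "constant")
  expect_true(all(r4$norm_reproducibility_auc == 0))
  # clustering attaches a label per combination when requested
  many <- do.call(rbind, lapply(1:3, function(i) {
    x <- reports; x$combination <- paste0(x$combination, i)
    x$sensitivity <- x$sensitivity + i / 100; x
  }))
  r5 <- normalize_and_rank(many, cluster = TRUE, seed = 2)
  expect_true(!is.null(r5$cluster) && length(unique(r5$cluster)) >= 2)
})
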