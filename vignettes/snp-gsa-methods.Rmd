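---
title: "Methods: gene set analysis for paired-design GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene set analysis for paired-design GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`snpgsa` implements competitive gene set analysis (GSA) for genome-wide
association data from *paired* designs — the same subject contributes a
genotype under two conditions, typically matched normal and tumour
tissue. The pipeline has five stages, each usable on its own:

1. **Variant QC** — minor allele frequency (MAF) and Hardy–Weinberg
   equilibrium (HWE) filters; window-based SNP-to-gene assignment.
2. **Paired association** — an exact multinomial symmetry test of the
   3×3 genotype transition table per SNP (a McNemar extension), with a
   Monte Carlo null.
3. **Gene integration** — collapsing per-SNP p-values to one per-gene
   p-value by the minimum, Fisher or Stouffer method, optionally with a
   linkage-disequilibrium (LD) dependency correction.
4. **Enrichment** — six competitive algorithms: GSEA, GSEA-SNP,
   i-GSEA4GWAS, MAGENTA75, ORA and CERNO.
5. **Benchmark** — four metrics (sensitivity, prioritization,
   specificity, reproducibility) comparing algorithm × integration × LD
   combinations, driven by a seeded synthetic-data generator.

This vignette records the statistical model behind each stage, the
parameters that matter, and the design choices made where conventions
genuinely diverge.

# Paired association testing

For each SNP the genotype calls (0/1/2 copies of the alternate allele)
of the two conditions form a 3×3 transition table $n_{ij}$. Under the
null hypothesis of marginal homogeneity — the condition does not shift
genotypes — discordant pairs are exchangeable, and the Bowker-type
statistic

$$T = \sum_{i<j,\; n_{ij}+n_{ji}>0} \frac{(n_{ij}-n_{ji})^2}{n_{ij}+n_{ji}}$$

is zero exactly when the table is symmetric. Rather than relying on the
asymptotic chi-square (unreliable at the small discordance counts paired
tissue studies produce), `mc_symmetry_test()` uses the exact conditional
null: each unordered pair's total discordance $n_{ij}+n_{ji}$ is held
fixed and redistributed as Binomial$(n_{ij}+n_{ji}, 1/2)$; diagonal
cells are ancillary. With discordance confined to a single genotype
pair, this reduces analytically to the two-sided exact binomial test —
a closed-form oracle the test suite uses for convergence checks.

Two conventions worth noting:

* p-values use the add-one estimator $(b+1)/(m+1)$, so they are never
  exactly zero and are mildly conservative;
* each SNP draws its RNG stream from the master seed hashed with its
  rsID (`derive_seed()`), so per-SNP results do not depend on the order
  (or parallelisation) of execution.

No covariate adjustment is offered: in a matched-pair design, subject-
level covariates are balanced by construction.

# SNP-to-gene integration

A gene $g$ with $k$ mapped SNPs (window: gene body ± 5 kb by default,
closed 1-based intervals, strand-blind; a SNP may fall in several
windows and then counts for each gene) gets one p-value by one of:

* **minimum**: $p_g = \min_i p_i$ — the field's most common choice;
  favours genes with many SNPs because no multiplicity control is
  applied;
* **Fisher**: $F_g = -2\sum_i \ln p_i \sim \chi^2_{2k}$;
* **Stouffer**: $Z_g = \sum_i \Phi^{-1}(p_i)/\sqrt{k} \sim N(0,1)$,
  with $p_g = \Phi(Z_g)$.

The Stouffer tail convention deserves a note: the z-transformation is
stated via the inverse normal CDF of the p-values themselves, which
maps small p-values to large negative scores. Taking the *lower* normal
tail of $Z_g$ is the only reading under which $k=1$ is an identity and
small inputs give small outputs; it is what `combine_stouffer()` does.
Inputs are clamped to $[10^{-300}, 1-10^{-16}]$ before the log/quantile
transforms; the upper clamp is applied only where the quantile function
needs it, so `combine_fisher(1)` still returns a statistic of exactly 0.

## LD correction

SNP p-values within a gene are positively dependent through linkage
disequilibrium, so all three combiners are anticonservative to some
degree. Instead of estimating $r^2$/D′ from genotypes, the package uses
a fixed-exponent Dunn–Šidák-style correction,

$$p_{corr} = 1 - (1 - p_g)^{(k+1)/2},$$

reflecting the empirical rule of thumb that roughly half the SNPs in a
gene are in strong LD, which makes $(k+1)/2$ an effective number of
independent tests. The exponent is used literally (no rounding at even
$k$); $k=1$ is an identity and $p_{corr} \ge p_g$ always, so applying
the correction can only reduce significant-gene counts. Its practical
appeal is that it needs nothing beyond the rsID and the association
p-value — no genotype matrix at integration time.

# Enrichment algorithms

All six algorithms test the competitive null: the gene set is no more
associated with the phenotype than the genes outside it.

**GSEA** ranks genes by $r_j = -\log_{10} p_j$ (descending; ties broken
by id in lexical order so permutations are reproducible) and scans the
running difference between the rank-weighted hit profile
$P_{hit}(S,i) = \sum_{g_j \in S,\, j \le i} |r_j| / N_R$ (with
$N_R = \sum_{g_j\in S} |r_j|$) and the uniform miss profile
$P_{miss}(S,i) = \sum_{g_j \notin S,\, j\le i} 1/(N - N_H)$. The
enrichment score ES is the signed deviation of maximum magnitude; when
two prefixes tie in magnitude within $10^{-12}$ the earlier one is
taken — a documented tie-break that keeps the extremum stable under
floating-point reordering. The null permutes gene labels; NES divides
the observed ES by the mean magnitude of same-direction permuted ES,
and the p-value compares magnitudes within the same direction (add-one
convention). Sets whose intersection with the scored universe falls
below `min_size` (default 5) are dropped — small sets make the
hypergeometric and chi-square machinery of the analytic methods
degenerate, and the same filter is applied everywhere for
comparability.

**GSEA-SNP** skips integration: SNPs are the ranked units, a SNP
belongs to a set when it maps into any member gene, and SNP labels are
permuted. **i-GSEA4GWAS** also permutes SNP labels but re-runs the
gene integration each round, and replaces NES by
$SPES = ES \cdot k/K$, where $k$ (resp. $K$) is the fraction of set
(resp. all) genes having at least one SNP among the top 5% of SNP
p-values. The permutation loop re-integrates naively each round; a
shortcut exists for minimum integration, but a single code path is
easier to verify and is affordable at the problem sizes this package
targets.

**MAGENTA75** counts set genes with $p$ strictly below the 75th
percentile of all gene p-values (the leading-edge fraction) and
compares the count against mock sets of identical size drawn uniformly
without replacement. **ORA** thresholds genes at `deg_alpha` (default
0.05 — a conventional choice, configurable) and applies the upper-tail
hypergeometric test. **CERNO** transforms ascending p-value ranks:
$F_S = -2 \sum_{g\in S}\ln(\mathrm{rank}_g/N) \sim \chi^2_{2N_H}$, with
average ranks on ties (ties are consequential for an analytic test).
Benjamini–Hochberg adjustment is applied across sets within each
algorithm × integration × LD combination; raw p-values are always
retained.

# Benchmark metrics

* **Sensitivity** = $1 - \hat\pi_0$ over all collected set p-values of
  a run, with $\hat\pi_0$ estimated on the λ-grid 0.05…0.95 and
  smoothed by a cubic smoothing spline (3 df), evaluated at λ = 0.95
  and clipped to $[0,1]$. Below 20 p-values the estimator falls back to
  the single-λ (0.5) estimate with a warning.
* **Prioritization** = median rank (ascending by p; average ranks on
  ties) of the target sets; $(|T|+1)/2$ is the best achievable value
  and $(N+1)/2$ the random expectation.
* **Specificity** = $|\overline{FPR} - 0.05|$ where each of 50 (by
  default) phenotype permutations swaps every subject's tumour/normal
  labels with probability ½ — the only label permutation consistent
  with pairing — and reruns the *full* pipeline including the
  association stage (the conservative reading; reduce `assoc_n_perm`
  in the pipeline closure for a faster approximation).
* **Reproducibility** = the trapezoidal mean over a top-$c$ cutoff grid
  (default $c = 5, 10, \dots, 50$) of the fraction of sets common to
  the top-$c$ lists of disjoint subject subsets (default five subsets
  of 14 pairs). Identical rankings give 1; unrelated rankings give
  nearly 0. The overlap function and its normalisation are not uniquely
  fixed by convention, so this definition is isolated in
  `reproducibility_auc()` where an alternative can be swapped in.

`normalize_and_rank()` orients each metric so lower is better
(sensitivity and reproducibility are inverted), min–max normalises
across the supplied combinations, sums the four normalised metrics and
ranks. The optional k-means clustering (k by average silhouette width)
is descriptive only.

# The synthetic-data generator

`simulate_study()` emulates the structure of a matched tumour/normal
SNP-array cohort at configurable scale; the defaults mirror a typical
study of this kind: 83 subject pairs and a KEGG-sized collection of 341
gene sets with 54 phenotype-relevant targets.

* **Genotypes with LD.** Per gene, a latent Gaussian vector with
  exchangeable correlation `ld_rho` is thresholded at the
  Hardy–Weinberg boundaries of a per-SNP allele frequency drawn from
  `maf_range`. Marginal genotype frequencies therefore sit exactly at
  HWE (verified by the suite at the nominal 5% rejection rate) while
  within-gene genotypes correlate — the feature that makes the LD
  correction consequential. Between-gene LD and realistic human LD maps
  are deliberately out of scope.
* **Effects.** Tumour genotypes start as copies of the normal ones. In
  each of `n_effect_genes` effect genes, a `causal_fraction` of SNPs
  (default 0.5, at least one — association signals within a gene are
  typically driven by one or a few variants, which is also what makes
  the minimum method competitive in practice) receive an *asymmetric*
  one-step shift towards more alternate alleles with per-subject
  probability `effect_size`. This targets exactly the marginal
  asymmetry the symmetry test measures. All other SNPs get a small
  symmetric discordance `noise` (default 0.02), emulating call
  discordance between paired specimens.
* **Gene sets.** Target sets draw `target_enrichment` (default 0.8) of
  their members from the effect genes; background sets draw uniformly;
  overlap between sets is allowed, as in real pathway collections.

What passing tests on this generator do *not* show: behaviour under
population structure, copy-number artefacts of tumour tissue, realistic
block-structured LD, or annotation error — the generator's LD is
exchangeable within genes and zero between them, and its effect model
is a clean marginal shift.

# Numerical and design choices

* **Threshold semantics** follow the usual filter wording: MAF below
  the threshold is removed (≥ retained); HWE p below α is removed;
  MAGENTA's leading edge counts p strictly below the cutoff.
* **HWE filtering** uses the normal-condition genotypes by default
  (`hwe_samples = "all"` to pool): tumour genotypes can violate HWE for
  somatic rather than technical reasons, and filtering on them would
  discard real signal.
* **A SNP failing both filters** is counted under the first failing
  rule (MAF), so the QC report partitions the input.
* **Permutation p-values** everywhere use the add-one convention and
  hence lie in $[1/(m+1), 1]$.
* **Degenerate inputs**: sets whose members all carry zero rank mass
  are errors in `running_enrichment_score()` and are skipped inside
  permutation loops; ORA with zero significant genes returns p = 1
  with a warning; a monomorphic SNP has HWE p = 1 by definition.
* **Problem sizes.** The shipped test-suite and acceptance-script runs
  use deliberately desk-sized simulations (tens of subject pairs,
  hundreds of genes and SNPs, 80–200 sets, reduced Monte Carlo depths);
  all sizes are parameters, and the defaults of `sim_config()` /
  `associate_all()` (83 pairs, 100 000 permutations) reflect the
  full-scale study conditions.

# Known limitations

* The LD correction's exponent $(k+1)/2$ encodes a fixed "half the
  SNPs are in high LD" assumption; when true LD is much stronger (the
  generator's ρ = 0.8, say) it undercorrects the Fisher method relative
  to the minimum method, and when SNPs are independent it overcorrects.
* i-GSEA4GWAS is the slowest algorithm (per-permutation
  re-integration); its permutation depth is the first thing to reduce
  on large inputs.
* Storey's estimator is noisy below a few hundred set p-values; the
  sensitivity metric should be read comparatively, not absolutely.
* GSEA-SNP inherits gene-size bias through SNP-level set membership:
  large genes contribute more SNPs. That is a property of the method,
  not of this implementation.
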