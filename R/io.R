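# Plain-text interchange: TSV tables for genotypes / SNPs / genes /
# associations / gene scores, and GMT for gene set collections. These are
# deliberately minimal formats -- the enrichment stage needs nothing more
# than rsIDs with association p-values plus a gene map.

#' Construct a paired genotype study
#'
#' Holds genotype calls (0/1/2 copies of the alternate allele, `NA` for
#' missing) for the same subjects under two paired conditions, e.g.
#' matched normal and tumour tissue.
#'
#' @param normal,tumor numeric matrices, subjects x SNPs, values in
#'   `{0, 1, 2, NA}`. Dimnames give subject ids and SNP ids.
#' @param subjects,snp_ids optional character vectors overriding the
#'   dimnames of `normal`.
#' @return An object of class `paired_study` with elements `subjects`,
#'   `snp_ids`, `normal`, `tumor`.
#' @examples
#' g <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
#' paired_study(g, g)
#' @export
paired_study <- function(normal, tumor, subjects = rownames(normal),
                         snp_ids = colnames(normal)) {
  normal <- as.matrix(normal)
  tumor <- as.matrix(tumor)
  if (!all(dim(normal) == dim(tumor))) {
    stopf("normal and tumor matrices must have identical dimensions (paired design)")
  }
  if (is.null(subjects)) subjects <- sprintf("S%d", seq_len(nrow(normal)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(normal)))
  if (anyDuplicated(snp_ids)) stopf("SNP ids must be unique within a study")
  if (anyDuplicated(subjects)) stopf("subject ids must be unique")
  for (m in list(normal, tumor)) {
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% 0:2)) {
      stopf("genotype codes must be 0, 1, 2 or NA")
    }
  }
  dimnames(normal) <- dimnames(tumor) <- list(subjects, snp_ids)
  structure(list(subjects = subjects, snp_ids = snp_ids,
                 normal = normal, tumor = tumor),
            class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf("paired_study: %d subject pairs x %d SNPs (%.1f%% missing calls)\n",
              length(x$subjects), length(x$snp_ids),
              100 * mean(is.na(x$normal) | is.na(x$tumor))))
  invisible(x)
}

# Keep a subset of subject pairs (used by the reproducibility benchmark).
subset_study <- function(study, subjects) {
  stopifnot(inherits(study, "paired_study"))
  missing <- setdiff(subjects, study$subjects)
  if (length(missing)) stopf("unknown subjects: %s", paste(missing, collapse = ", "))
  paired_study(study$normal[subjects, , drop = FALSE],
               study$tumor[subjects, , drop = FALSE])
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a table as tab-separated text
#'
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  }
  df
}

#' Read a SNP table (snp_id, chrom, pos)
#'
#' @param path TSV file with header columns `snp_id`, `chrom`, `pos`
#'   (1-based position).
#' @return data frame of SNP records.
#' @export
read_snp_table <- function(path) {
  df <- require_cols(read_tsv(path), c("snp_id", "chrom", "pos"), path)
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos) || any(df$pos < 1)) stopf("%s: pos must be integers >= 1", path)
  if (anyDuplicated(df$snp_id)) stopf("%s: duplicated snp_id", path)
  df[c("snp_id", "chrom", "pos")]
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `start`,
#'   `end` and optionally `strand` (`+`, `-` or `unknown`); coordinates
#'   are 1-based, fully closed.
#' @return data frame of gene annotations.
#' @export
read_gene_table <- function(path) {
  df <- require_cols(read_tsv(path), c("gene_id", "chrom", "start", "end"), path)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end) || any(df$start > df$end)) {
    stopf("%s: need integer start <= end", path)
  }
  if (is.null(df$strand)) df$strand <- "unknown"
  df$strand[!df$strand %in% c("+", "-")] <- "unknown"
  df[c("gene_id", "chrom", "start", "end", "strand")]
}

#' Read gene features from a GFF3 file
#'
#' Thin adapter over [rtracklayer::import()] keeping only `gene`-type
#' features; the `ID` (or `gene_id`) attribute becomes the gene id.
#'
#' @param path GFF3 file.
#' @return data frame in the same layout as [read_gene_table()].
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("read_gff_genes() needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else as.character(gr$ID)
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = ifelse(as.character(GenomicRanges::strand(gr)) %in% c("+", "-"),
                             as.character(GenomicRanges::strand(gr)), "unknown"),
             stringsAsFactors = FALSE)
}

#' Read a paired genotype matrix
#'
#' Expects one row per subject x condition: a `subject` column, a
#' `condition` column with exactly two levels, and one column per SNP
#' with genotype codes 0/1/2 (NA = missing call).
#'
#' @param path TSV file.
#' @param normal_level,tumor_level which condition level is treated as
#'   the reference (normal) and which as the case (tumour) condition.
#' @return A [paired_study()].
#' @export
read_genotype_study <- function(path, normal_level = "normal",
                                tumor_level = "tumor") {
  df <- require_cols(read_tsv(path), c("subject", "condition"), path)
  lev <- unique(df$condition)
  if (length(lev) != 2) stopf("%s: condition must have exactly 2 levels, found %d", path, length(lev))
  if (!all(c(normal_level, tumor_level) %in% lev)) {
    stopf("%s: condition levels are (%s); expected '%s' and '%s'",
          path, paste(lev, collapse = ", "), normal_level, tumor_level)
  }
  snp_cols <- setdiff(names(df), c("subject", "condition"))
  if (!length(snp_cols)) stopf("%s: no SNP columns", path)
  pick <- function(level) {
    sub <- df[df$condition == level, , drop = FALSE]
    if (anyDuplicated(sub$subject)) stopf("%s: duplicated subject within condition '%s'", path, level)
    m <- as.matrix(sub[snp_cols])
    storage.mode(m) <- "double"
    rownames(m) <- sub$subject
    m
  }
  normal <- pick(normal_level)
  tumor <- pick(tumor_level)
  common <- intersect(rownames(normal), rownames(tumor))
  if (length(common) < nrow(normal) || length(common) < nrow(tumor)) {
    stopf("%s: every subject needs both conditions (paired design)", path)
  }
  paired_study(normal[common, , drop = FALSE], tumor[common, , drop = FALSE])
}

#' Write a paired genotype study to TSV
#'
#' Inverse of [read_genotype_study()].
#'
#' @param study a [paired_study()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_study <- function(study, path) {
  stopifnot(inherits(study, "paired_study"))
  block <- function(m, level) {
    data.frame(subject = rownames(m), condition = level, m,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  write_tsv(rbind(block(study$normal, "normal"), block(study$tumor, "tumor")), path)
}

#' Read a gene set collection from a GMT file
#'
#' Standard Broad dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicated members
#' within a set are dropped with a warning.
#'
#' @param path GMT file.
#' @return A named list of character vectors of class
#'   `gene_set_collection`; set descriptions are kept in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stopf("%s: line %d has %d field(s); GMT needs name, description and >= 1 member",
          path, bad[1], lengths(fields)[bad[1]])
  }
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_)) stopf("%s: duplicated set name '%s'", path, names_[duplicated(names_)][1])
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, 0L) > 0)
  if (ndup > 0) {
    warnf("%s: %d set(s) contain duplicated members; deduplicated", path, ndup)
    sets <- lapply(sets, unique)
  }
  gene_set_collection(stats::setNames(sets, names_), description = stats::setNames(desc, names_))
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param description optional named character vector of set descriptions.
#' @param targets optional character vector of set names flagged as
#'   target (truly phenotype-relevant) sets.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL, targets = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stopf("sets must be named")
  if (any(lengths(sets) < 1)) stopf("every set needs at least one member")
  if (!is.null(targets) && length(setdiff(targets, names(sets)))) {
    stopf("target ids absent from the collection: %s",
          paste(setdiff(targets, names(sets)), collapse = ", "))
  }
  structure(lapply(sets, as.character),
            description = description, targets = targets,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x), min(lengths(x)), max(lengths(x)),
              if (!is.null(attr(x, "targets"))) {
                sprintf(", %d flagged as targets", length(attr(x, "targets")))
              } else ""))
  invisible(x)
}

#' Write a gene set collection to GMT
#'
#' @param sets a `gene_set_collection` (or named list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON provenance sidecar next to a result file
#'
#' Records the package version, master seed and resolved parameters so a
#' result table can be regenerated exactly.
#'
#' @param path the result file the sidecar describes (sidecar is
#'   `<path>.provenance.json`).
#' @param seed master seed used.
#' @param params named list of resolved parameters.
#' @return sidecar path, invisibly.
#' @export
write_provenance <- function(path, seed, params = list()) {
  side <- paste0(path, ".provenance.json")
  jsonlite::write_json(
    list(tool = "snpgsa", version = as.character(packageVersion("snpgsa")),
         seed = seed, params = params),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
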