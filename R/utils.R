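# Internal helpers: error formatting, seeding, p-value hygiene.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate expr under a fixed, version-stable RNG state; the caller's RNG
# state is untouched afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  expr
}

#' Derive a reproducible child seed from a master seed and a key
#'
#' Stochastic stages (per-SNP Monte Carlo tests, per-combination
#' permutation nulls, benchmark resampling) each draw their own seed from
#' the run's master seed and a string key naming the stage. The derivation
#' is a deterministic string hash, so results do not depend on the order
#' in which stages execute.
#'
#' @param master integer master seed.
#' @param key character scalar (or vector, collapsed) identifying the
#'   consumer, e.g. an rsID or `"gsea/stouffer/ld"`.
#' @return An integer seed in `[0, 2^31)`.
#' @examples
#' derive_seed(42, "rs123") == derive_seed(42, "rs123")
#' derive_seed(42, "rs123") != derive_seed(42, "rs124")
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master))
  h <- 5381
  for (ch in utf8ToInt(paste(as.character(key), collapse = "\r"))) {
    h <- (h * 33 + ch) %% 2147483629
  }
  as.integer((h * 31 + as.numeric(master)) %% 2147483629)
}

# Clamp p-values away from 0 (and optionally 1) before log/quantile
# transforms; leaves values unchanged at any realistic precision.
clamp_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) {
  pmin(pmax(p, lo), hi)
}

check_pvalues <- function(p, what = "p-values", allow_zero = FALSE) {
  if (length(p) == 0) stopf("empty list of %s", what)
  if (anyNA(p)) stopf("%s contain NA", what)
  lo <- if (allow_zero) p < 0 else p <= 0
  if (any(lo) || any(p > 1)) stopf("%s must lie in (0, 1]", what)
  invisible(p)
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

vlog <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

# sample() that never expands a length-1 vector into 1:x.
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
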