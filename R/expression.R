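#' Centered log-ratio transform of an expression table
#'
#' Maps each sample's relative abundances (e.g. TPM) to unconstrained clr
#' space: `x -> ln(x') - mean(ln(x'))`, where `x'` is the zero-replaced
#' column. Every clr column sums to zero, and the transform is invariant to
#' rescaling a sample (so TPM, fractions and raw proportional counts all give
#' the same result).
#'
#' @param expr A data frame with a `transcript_id` column, optional `class`
#'   and `species` columns, and one numeric column per sample.
#' @param zero_policy How zeros are replaced before taking logs:
#'   `"multiplicative"` (default) replaces zeros by half the smallest nonzero
#'   value in that sample; `"pseudocount"` adds `pseudocount` to every value.
#' @param pseudocount Pseudocount used when `zero_policy = "pseudocount"`.
#' @return A tibble of the same shape with clr-transformed sample columns.
#' @examples
#' expr <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
#'                        s1 = c(1, exp(1), exp(2)))
#' clr_transform(expr)$s1  # -1, 0, 1
#' @export
clr_transform <- function(expr, zero_policy = c("multiplicative", "pseudocount"),
                          pseudocount = 0.5) {
  assert_expression(expr)
  zero_policy <- match.arg(zero_policy)
  out <- tibble::as_tibble(expr)
  for (col in expr_sample_cols(out)) {
    out[[col]] <- clr_vec(out[[col]], zero_policy, pseudocount)
  }
  out
}

clr_vec <- function(x, zero_policy = "multiplicative", pseudocount = 0.5) {
  if (all(x == 0)) {
    stop("all-zero sample column: composition undefined", call. = FALSE)
  }
  if (zero_policy == "multiplicative") {
    if (any(x == 0)) x[x == 0] <- 0.5 * min(x[x > 0])
  } else {
    x <- x + pseudocount
  }
  lx <- log(x)
  lx - mean(lx)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample TMM scaling factors for a raw count table (used here
#' for small-RNA libraries). The reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean across samples. Per
#' sample, M-values (log2 count-fraction ratios versus the reference) and
#' A-values (mean log2 abundance) are computed over genes nonzero in both
#' libraries, doubly trimmed (`trim_m` from each tail of M, `trim_a` of A),
#' and combined with inverse asymptotic-binomial-variance precision weights:
#' `factor = 2^(weighted mean M)`. Factors are rescaled to geometric mean 1.
#'
#' Trimming is by value quantiles rather than ranks, so heavily tied
#' M-values (e.g. many genes with identical counts in both libraries) keep
#' their whole tie group instead of being split arbitrarily.
#'
#' @param counts Data frame with `transcript_id` (or first id column) and one
#'   numeric raw-count column per sample, or a numeric matrix.
#' @param trim_m Fraction trimmed from each tail of the M-value distribution.
#' @param trim_a Fraction trimmed from each tail of the A-value distribution.
#' @return A tibble with columns `sample_id` and `factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  mat <- if (is.data.frame(counts)) {
    as.matrix(counts[expr_sample_cols(counts)])
  } else {
    as.matrix(counts)
  }
  if (ncol(mat) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  if (any(mat < 0)) stop("counts must be non-negative", call. = FALSE)
  nz <- mat > 0
  if (any(colSums(nz) == 0L)) {
    stop("sample with no nonzero counts", call. = FALSE)
  }
  shared <- crossprod(nz)
  if (any(shared[upper.tri(shared)] == 0L)) {
    stop("a pair of samples shares no nonzero genes", call. = FALSE)
  }
  lib <- colSums(mat)
  f75 <- apply(mat, 2, function(x) pctl(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(mat[, j], mat[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / geometric_mean(f)
  tibble::tibble(
    sample_id = colnames(mat) %||% paste0("sample", seq_len(ncol(mat))),
    factor = unname(f)
  )
}

tmm_pair_factor <- function(x, ref, N, Nr, trim_m, trim_a) {
  keep <- x > 0 & ref > 0
  x <- x[keep]; ref <- ref[keep]
  M <- log2((x / N) / (ref / Nr))
  A <- 0.5 * log2((x / N) * (ref / Nr))
  # value-quantile double trim (keeps whole tie groups)
  in_m <- M >= pctl(M, trim_m) & M <= pctl(M, 1 - trim_m)
  in_a <- A >= pctl(A, trim_a) & A <= pctl(A, 1 - trim_a)
  sel <- in_m & in_a
  if (!any(sel)) sel <- in_m
  w <- 1 / ((N - x) / (N * x) + (Nr - ref) / (Nr * ref))
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

#' Filter transcripts by a minimum TPM across individuals
#'
#' Retains transcripts whose TPM is strictly greater than `threshold` in all
#' individuals of each species (default) or of at least one species
#' (`scope = "any_species"`). A transcript with TPM exactly equal to the
#' threshold in any required individual is removed. Applied to nontoxins
#' before the null expression band is built.
#'
#' @param expr Expression table (TPM) with sample columns.
#' @param samples Optional data frame with `sample_id` and `species` mapping
#'   sample columns to species; if `NULL`, all samples are treated as one
#'   species.
#' @param threshold TPM threshold (default 1).
#' @param scope `"each_species"` (default) requires the threshold in every
#'   individual of every species; `"any_species"` in every individual of at
#'   least one species.
#' @return The filtered expression tibble.
#' @export
filter_min_tpm <- function(expr, samples = NULL, threshold = 1,
                           scope = c("each_species", "any_species")) {
  assert_expression(expr)
  scope <- match.arg(scope)
  smp <- expr_sample_cols(expr)
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = smp, species = "all")
  }
  samples <- samples[samples$sample_id %in% smp, , drop = FALSE]
  mat <- as.matrix(expr[samples$sample_id])
  by_species <- split(seq_len(nrow(samples)), samples$species)
  ok_per_species <- vapply(by_species, function(idx) {
    matrixStats_rowAll(mat[, idx, drop = FALSE] > threshold)
  }, logical(nrow(mat)))
  ok_per_species <- matrix(ok_per_species, nrow = nrow(mat))
  keep <- if (scope == "each_species") {
    rowSums(ok_per_species) == ncol(ok_per_species)
  } else {
    rowSums(ok_per_species) >= 1L
  }
  tibble::as_tibble(expr[keep, , drop = FALSE])
}

matrixStats_rowAll <- function(m) rowSums(m) == ncol(m)

#' Rescale sample columns to TPM (columns sum to one million)
#'
#' @param expr Expression table with non-negative sample columns.
#' @return The rescaled tibble.
#' @export
scale_to_tpm <- function(expr) {
  assert_expression(expr)
  out <- tibble::as_tibble(expr)
  for (col in expr_sample_cols(out)) {
    s <- sum(out[[col]])
    if (s == 0) stop("all-zero sample column", call. = FALSE)
    out[[col]] <- out[[col]] / s * 1e6
  }
  out
}
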