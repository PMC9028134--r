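# Internal helpers shared across modules.

# Sample columns of an expression tibble = everything that is not metadata.
expr_meta_cols <- c("transcript_id", "class", "species")

# Numeric columns that are not metadata: works for transcript, ortholog and
# miRNA tables alike (id columns are character, values numeric).
expr_sample_cols <- function(expr) {
  cand <- setdiff(names(expr), expr_meta_cols)
  cand[vapply(expr[cand], is.numeric, logical(1))]
}

assert_expression <- function(expr, nonneg = TRUE) {
  if (!is.data.frame(expr)) {
    stop("expression input must be a data frame", call. = FALSE)
  }
  if (!"transcript_id" %in% names(expr)) {
    stop("expression input must have a `transcript_id` column", call. = FALSE)
  }
  smp <- expr_sample_cols(expr)
  if (length(smp) == 0L) {
    stop("expression input has no sample columns", call. = FALSE)
  }
  vals <- as.matrix(expr[smp])
  if (!is.numeric(vals)) {
    stop("sample columns must be numeric", call. = FALSE)
  }
  if (nonneg && any(vals < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  invisible(expr)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Quantiles throughout the package use the linear-interpolation definition
# (type 7), e.g. the 99th percentile of |residuals| for the null band.
pctl <- function(x, p) stats::quantile(x, probs = p, type = 7, names = FALSE)

# Sequence-string helpers (kept base-R: callers work on short vectors).
dna_complement <- function(x) chartr("ACGTUacgtu", "TGCAATGCAA", x)

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

as_dna <- function(x) chartr("Uu", "Tt", toupper(x))
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

geometric_mean <- function(x) exp(mean(log(x)))
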