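# Spectral-count proteome integration: EUSC normalization, clr-space
# transcriptome-proteome correlation, and per-toxin translation efficiency.

#' Normalize exclusive unique spectral counts
#'
#' Scales each sample column to fractions of its total (columns sum to 1).
#'
#' @param table Data frame `transcript_id` (plus optional metadata) and one
#'   raw EUSC column per sample.
#' @return The tibble with sample columns replaced by fractions.
#' @export
normalize_eusc <- function(table) {
  out <- tibble::as_tibble(table)
  for (cc in expr_sample_cols(out)) {
    s <- sum(out[[cc]])
    if (s == 0) stop("all-zero proteome sample", call. = FALSE)
    out[[cc]] <- out[[cc]] / s
  }
  out
}

#' Correlate transcriptome and proteome abundances
#'
#' Computes Spearman's rank correlation (average ranks on ties), Pearson's
#' correlation, and the ordinary-least-squares best-fit line of protein clr
#' on transcript clr over shared toxins. An orthogonal (total least squares)
#' line is available with `line = "orthogonal"`.
#'
#' @param transcript_clr,protein_clr Tibbles `transcript_id`, `clr` (one
#'   species each), or numeric vectors aligned by position.
#' @param line `"ols"` (default) or `"orthogonal"`.
#' @return An object of class `omics_correlation`: `rho`, `r`, `slope`,
#'   `intercept`, `n`, `line`, and the joined `data`.
#' @export
correlate_omics <- function(transcript_clr, protein_clr,
                            line = c("ols", "orthogonal")) {
  line <- match.arg(line)
  if (is.data.frame(transcript_clr)) {
    joined <- dplyr::inner_join(
      tibble::as_tibble(transcript_clr)[c("transcript_id", "clr")],
      tibble::as_tibble(protein_clr)[c("transcript_id", "clr")],
      by = "transcript_id", suffix = c("_transcript", "_protein"))
    x <- joined$clr_transcript
    y <- joined$clr_protein
  } else {
    x <- transcript_clr
    y <- protein_clr
    joined <- tibble::tibble(clr_transcript = x, clr_protein = y)
  }
  if (length(x) < 3L) stop("need at least 3 shared toxins", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance on one axis: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  r <- stats::cor(x, y, method = "pearson")
  if (line == "ols") {
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    intercept <- fit$coefficients[1]
  } else {
    tls <- orthogonal_fit(tibble::tibble(x = x, y = y))
    slope <- tls$slope
    intercept <- tls$intercept
  }
  structure(
    list(rho = rho, r = r, slope = unname(slope),
         intercept = unname(intercept), n = length(x), line = line,
         data = joined),
    class = "omics_correlation"
  )
}

#' @export
print.omics_correlation <- function(x, ...) {
  cat(sprintf(
    "Transcriptome-proteome correlation: rho = %.2f, R = %.2f, %s fit y = %.2f x + %.2f (n = %d)\n",
    x$rho, x$r, x$line, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Per-toxin translation efficiency
#'
#' `te = clr(protein) - clr(transcript)` for every toxin shared by both
#' tables. The low-TE set is the lowest `te_quantile` of toxins; adding a
#' constant to either clr vector shifts all te values equally and leaves
#' the low-TE ranking unchanged.
#'
#' @param transcript_clr,protein_clr Tibbles `transcript_id`, `clr`.
#' @param species Optional species label carried into the result.
#' @param te_quantile Low-TE quantile (default 0.25).
#' @return A tibble `transcript_id`, `species`, `te`, `low_te`.
#' @export
translation_efficiency <- function(transcript_clr, protein_clr,
                                   species = NA_character_,
                                   te_quantile = 0.25) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(transcript_clr)[c("transcript_id", "clr")],
    tibble::as_tibble(protein_clr)[c("transcript_id", "clr")],
    by = "transcript_id", suffix = c("_transcript", "_protein"))
  te <- joined$clr_protein - joined$clr_transcript
  cut <- pctl(te, te_quantile)
  tibble::tibble(transcript_id = joined$transcript_id, species = species,
                 te = te, low_te = te <= cut)
}

#' Clr values of one proteome or transcriptome sample
#'
#' Convenience: extracts one sample column and returns `transcript_id`,
#' `clr` suitable for [correlate_omics()] and [translation_efficiency()].
#'
#' @param table Abundance table (`transcript_id` + sample columns).
#' @param sample Sample column name; defaults to the only sample column.
#' @param ... Passed to [clr_transform()].
#' @return A tibble `transcript_id`, `clr`.
#' @export
sample_clr <- function(table, sample = NULL, ...) {
  smp <- expr_sample_cols(table)
  sample <- sample %||% smp[1]
  cl <- clr_transform(table[c("transcript_id", sample)], ...)
  tibble::tibble(transcript_id = cl$transcript_id, clr = cl[[sample]])
}
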