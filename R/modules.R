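# Weighted coexpression module detection: variance-trend filtering,
# soft-threshold Pearson adjacency, topological overlap, average-linkage
# clustering with a static cut. A deliberately transparent stack faithful to
# the stated parameters (beta = 10, Pearson, minimum module size 1).

#' Coexpression configuration
#'
#' @param beta Soft-threshold exponent for the adjacency (default 10).
#' @param min_module_size Modules smaller than this are merged into the
#'   nearest module by eigengene correlation (default 1 = keep all).
#' @param variance_filter_keep Cap on transcripts kept by [vst_filter()]: a
#'   count, a fraction (< 1) of the input, or `NULL` to keep every
#'   transcript above the variance trend.
#' @param cut_height Static cut height on the 1 - TOM dissimilarity tree
#'   (default 0.25).
#' @return A list of class `coexpression_config`.
#' @export
coexpression_config <- function(beta = 10, min_module_size = 1,
                                variance_filter_keep = NULL,
                                cut_height = 0.25) {
  stopifnot(beta >= 1, min_module_size >= 1, cut_height > 0)
  structure(list(beta = beta, min_module_size = min_module_size,
                 variance_filter_keep = variance_filter_keep,
                 cut_height = cut_height),
            class = "coexpression_config")
}

#' Variance-stabilizing transform and variance-trend filter
#'
#' Transforms TPM to `log2(TPM + 1)`, fits a locally weighted (lowess) trend
#' of per-transcript variance against mean expression, and keeps transcripts
#' whose variance exceeds the trend. (Near-)constant transcripts are always
#' dropped. When `variance_filter_keep` is a count k, the top k transcripts
#' by trend residual are kept instead, which makes the filter idempotent.
#'
#' @param expr Expression table (TPM or already-transformed values; set
#'   `transform = FALSE` to skip the log step).
#' @param config A [coexpression_config()].
#' @param transform Apply `log2(x + 1)` (default TRUE).
#' @return The filtered, transformed expression tibble.
#' @export
vst_filter <- function(expr, config = coexpression_config(), transform = TRUE) {
  assert_expression(expr, nonneg = transform)
  smp <- expr_sample_cols(expr)
  if (length(smp) < 3L) warning("fewer than 3 samples: variance trend is coarse")
  out <- tibble::as_tibble(expr)
  if (transform) for (cc in smp) out[[cc]] <- log2(out[[cc]] + 1)
  mat <- as.matrix(out[smp])
  v <- apply(mat, 1, stats::var)
  m <- rowMeans(mat)
  if (max(v) < 1e-12) stop("constant expression matrix", call. = FALSE)
  keep <- v > 1e-12
  resid <- rep(-Inf, length(v))
  if (sum(keep) >= 3L) {
    tr <- stats::lowess(m[keep], v[keep], f = 2 / 3)
    fitted <- stats::approx(tr$x, tr$y, xout = m[keep], rule = 2, ties = mean)$y
    resid[keep] <- v[keep] - fitted
  } else {
    resid[keep] <- v[keep]
  }
  k <- config$variance_filter_keep
  sel <- if (is.null(k)) {
    keep & resid > 0
  } else {
    if (k < 1) k <- ceiling(k * nrow(out))
    k <- min(k, sum(keep))
    ord <- order(resid, decreasing = TRUE)
    seq_along(resid) %in% ord[seq_len(k)] & keep
  }
  out[sel, , drop = FALSE]
}

# Unsigned topological overlap matrix from an adjacency with zero diagonal.
tom_similarity <- function(adj) {
  diag(adj) <- 0
  L <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' Detect coexpression modules
#'
#' Adjacency is `|pearson r|^beta` between transcripts; similarity is the
#' unsigned topological overlap; modules come from average-linkage
#' hierarchical clustering of `1 - TOM` cut statically at
#' `config$cut_height`. Modules smaller than `min_module_size` are merged
#' into the module whose eigengene (first principal component of member
#' profiles) correlates best with theirs. Module ids are ordered by
#' decreasing size.
#'
#' @param expr Filtered, transformed expression tibble (from
#'   [vst_filter()]).
#' @param config A [coexpression_config()].
#' @return An object of class `module_set`: `assignment` (tibble
#'   `transcript_id`, `module`), `config`, `n_samples`.
#' @export
detect_modules <- function(expr, config = coexpression_config()) {
  assert_expression(expr, nonneg = FALSE)  # input is log/clr scale
  smp <- expr_sample_cols(expr)
  if (nrow(expr) < 2L) stop("need at least 2 transcripts", call. = FALSE)
  if (length(smp) < 8L) {
    warning("module detection below 8 samples: correlations are coarse")
  }
  mat <- t(as.matrix(expr[smp]))
  colnames(mat) <- expr$transcript_id
  adj <- abs(stats::cor(mat, method = "pearson"))^config$beta
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = config$cut_height)
  cl <- merge_small_modules(cl, mat, config$min_module_size)
  # relabel by decreasing size, stable within ties
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- relabel[as.character(cl)]
  structure(
    list(assignment = tibble::tibble(transcript_id = expr$transcript_id,
                                     module = as.integer(cl)),
         config = config, n_samples = length(smp)),
    class = "module_set"
  )
}

merge_small_modules <- function(cl, mat, min_size) {
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0L || length(sizes) <= 1L) break
    eigengene <- function(ids) {
      sub <- mat[, ids, drop = FALSE]
      if (ncol(sub) == 1L) return(scale(sub)[, 1])
      stats::prcomp(scale(sub))$x[, 1]
    }
    eg <- lapply(split(colnames(mat), cl), eigengene)
    target <- small[which.min(sizes[small])]
    others <- setdiff(names(eg), target)
    r <- vapply(others, function(o) abs(stats::cor(eg[[target]], eg[[o]])),
                numeric(1))
    cl[cl == target] <- others[which.max(r)]
  }
  cl
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(sprintf("Coexpression modules: %d modules over %d transcripts (%d samples)\n",
              length(sizes), nrow(x$assignment), x$n_samples))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate modules with toxin content and transcription factors
#'
#' @param modules A `module_set` from [detect_modules()].
#' @param classes Tibble `transcript_id`, `class` (family label or
#'   `"nontoxin"`).
#' @param tf_list Character vector of transcript ids flagged as
#'   transcription factors.
#' @return A tibble, one row per module: `module`, `n_members`, `n_toxin`,
#'   `n_nontoxin`, `toxin_families` (comma-separated), `tf_members`
#'   (comma-separated), `has_toxin`.
#' @export
annotate_modules <- function(modules, classes, tf_list = character(0)) {
  stopifnot(inherits(modules, "module_set"))
  joined <- dplyr::left_join(modules$assignment, tibble::as_tibble(classes),
                             by = "transcript_id")
  joined$class[is.na(joined$class)] <- "nontoxin"
  joined |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_toxin = sum(.data$class != "nontoxin"),
      n_nontoxin = sum(.data$class == "nontoxin"),
      toxin_families = paste(sort(unique(.data$class[.data$class != "nontoxin"])),
                             collapse = ","),
      tf_members = paste(sort(.data$transcript_id[.data$transcript_id %in% tf_list]),
                         collapse = ","),
      .groups = "drop") |>
    dplyr::mutate(has_toxin = .data$n_toxin > 0) |>
    dplyr::arrange(.data$module)
}
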