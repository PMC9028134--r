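# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname orthogonal_fit
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy venom_tls
#' @export
tidy.venom_tls <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @rdname orthogonal_fit
#' @method glance venom_tls
#' @export
glance.venom_tls <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, n = x$n)
}

#' @rdname build_null_band
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy null_band
#' @export
tidy.null_band <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept", "half_width"),
                 estimate = c(x$fit$slope, x$fit$intercept, x$half_width))
}

#' @rdname build_null_band
#' @method glance null_band
#' @export
glance.null_band <- function(x, ...) {
  tibble::tibble(slope = x$fit$slope, intercept = x$fit$intercept,
                 half_width = x$half_width, probs = x$probs,
                 n_null = x$n_null)
}

#' @rdname compare_groups
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy dnds_comparison
#' @export
tidy.dnds_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$metrics), function(m) {
    pm <- x$metrics[[m]]
    tibble::tibble(metric = m, statistic = pm$statistic,
                   p_value = pm$p_value, threshold = pm$threshold,
                   n_flagged = length(pm$flagged))
  }))
}

#' @rdname compare_groups
#' @method glance dnds_comparison
#' @export
glance.dnds_comparison <- function(x, ...) {
  tibble::tibble(n_toxin = x$n_toxin, n_nontoxin = x$n_nontoxin,
                 omega_p = x$metrics$omega$p_value,
                 n_positive_selection = length(x$positive_selection))
}

#' @rdname detect_modules
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) x$assignment

#' @rdname detect_modules
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  sizes <- table(x$assignment$module)
  tibble::tibble(n_modules = length(sizes),
                 n_transcripts = nrow(x$assignment),
                 largest_module = max(sizes),
                 n_samples = x$n_samples)
}

#' @rdname correlate_omics
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy omics_correlation
#' @export
tidy.omics_correlation <- function(x, ...) {
  tibble::tibble(term = c("rho", "r", "slope", "intercept"),
                 estimate = c(x$rho, x$r, x$slope, x$intercept))
}

#' @rdname correlate_omics
#' @method glance omics_correlation
#' @export
glance.omics_correlation <- function(x, ...) {
  tibble::tibble(rho = x$rho, r = x$r, slope = x$slope,
                 intercept = x$intercept, n = x$n, line = x$line)
}

#' @rdname rbh_pairs
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy rbh_result
#' @export
tidy.rbh_result <- function(x, ...) x$pairs

#' @rdname rbh_pairs
#' @method glance rbh_result
#' @export
glance.rbh_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), n_unpaired = nrow(x$unpaired))
}
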