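#' Orthogonal (total least squares) best-fit line
#'
#' Fits the line through the centroid along the first principal axis of the
#' 2x2 covariance of `(x, y)`; residuals are signed perpendicular distances.
#' For an isotropic degenerate cloud (equal eigenvalues, zero covariance) the
#' tie is broken toward slope 1 with a warning.
#'
#' @param points Data frame with numeric columns `x` and `y` (clr values).
#' @return An object of class `venom_tls` with elements `slope`, `intercept`,
#'   `center` and `n`.
#' @export
orthogonal_fit <- function(points) {
  x <- points$x
  y <- points$y
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  cv <- stats::cov(cbind(x, y))
  if (sum(diag(cv)) < .Machine$double.eps) {
    stop("zero total variance: orthogonal fit undefined", call. = FALSE)
  }
  eg <- eigen(cv, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-12 * sum(abs(eg$values))) {
    warning("isotropic point cloud; breaking tie toward slope 1")
    v <- c(1, 1) / sqrt(2)
  } else {
    v <- eg$vectors[, 1]
  }
  if (abs(v[1]) < .Machine$double.eps) {
    stop("orthogonal fit is vertical; axes carry no shared signal", call. = FALSE)
  }
  slope <- v[2] / v[1]
  center <- c(x = mean(x), y = mean(y))
  structure(
    list(slope = slope, intercept = center[["y"]] - slope * center[["x"]],
         center = center, n = length(x)),
    class = "venom_tls"
  )
}

#' @export
print.venom_tls <- function(x, ...) {
  cat(sprintf("Orthogonal best-fit line: y = %.4f x + %.4f (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

# Signed perpendicular distance of points from a venom_tls line.
orthogonal_residuals <- function(fit, x, y) {
  (y - (fit$intercept + fit$slope * x)) / sqrt(1 + fit$slope^2)
}

#' Build the nontoxin null expression band
#'
#' Fits the orthogonal best-fit line to nontoxin clr pairs and takes the 99th
#' percentile (linear interpolation) of the absolute orthogonal residuals as
#' the band half-width. Toxins falling outside this band are later called
#' expression outliers. Intended inputs are nontoxins that survived the
#' minimum-TPM filter.
#'
#' @param nontoxin_points Data frame with columns `x` and `y`: paired clr
#'   values of nontoxins (two individuals, or two species means).
#' @param probs Percentile defining the band (default 0.99).
#' @param residuals `"absolute"` (default) takes the percentile of
#'   \code{|residual|}; `"signed"` uses two one-sided quantiles at
#'   `(1 - probs)/2` and `1 - (1 - probs)/2`.
#' @return An object of class `null_band`: the `venom_tls` fit plus
#'   `half_width` (clr units) and `n_null`.
#' @export
build_null_band <- function(nontoxin_points, probs = 0.99,
                            residuals = c("absolute", "signed")) {
  residuals <- match.arg(residuals)
  if (nrow(nontoxin_points) < 3L) {
    stop("need at least 3 nontoxin points to build a null band", call. = FALSE)
  }
  if (nrow(nontoxin_points) < 50L) {
    warning("fewer than 50 nontoxins: null band will be unstable")
  }
  fit <- orthogonal_fit(nontoxin_points)
  res <- orthogonal_residuals(fit, nontoxin_points$x, nontoxin_points$y)
  if (residuals == "absolute") {
    lo <- hi <- pctl(abs(res), probs)
  } else {
    a <- (1 - probs) / 2
    lo <- -pctl(res, a)
    hi <- pctl(res, 1 - a)
  }
  structure(
    list(fit = fit, half_width = max(lo, hi), lower = lo, upper = hi,
         probs = probs, residuals = residuals, n_null = nrow(nontoxin_points)),
    class = "null_band"
  )
}

#' @export
print.null_band <- function(x, ...) {
  cat(sprintf(
    "Nontoxin null band: slope %.3f, intercept %.3f, half-width %.4f clr (%d nontoxins, %.0f%% band)\n",
    x$fit$slope, x$fit$intercept, x$half_width, x$n_null, 100 * x$probs))
  invisible(x)
}

#' Call expression outliers against a null band
#'
#' Computes each toxin's signed orthogonal residual from the band's best-fit
#' line and flags it when the residual magnitude exceeds the band half-width.
#' `direction` records which axis is higher: `"y"` for residual > 0 (the
#' y-axis individual/species), `"x"` otherwise.
#'
#' @param band A `null_band`.
#' @param toxin_points Data frame with `x`, `y` and an id column
#'   (`transcript_id` or `ortholog_id`); extra columns are carried through.
#' @return A tibble with `x`, `y`, `residual`, `half_width`, `is_outlier`,
#'   `direction` added.
#' @export
call_outliers <- function(band, toxin_points) {
  stopifnot(inherits(band, "null_band"))
  out <- tibble::as_tibble(toxin_points)
  res <- orthogonal_residuals(band$fit, out$x, out$y)
  out$residual <- res
  out$half_width <- band$half_width
  out$is_outlier <- if (band$residuals == "absolute") {
    abs(res) > band$half_width
  } else {
    res > band$upper | res < -band$lower
  }
  out$direction <- ifelse(res > 0, "y", ifelse(res < 0, "x", "none"))
  attr(out, "band") <- band
  class(out) <- c("outlier_calls", class(out))
  out
}

#' Intraspecific expression divergence of toxins
#'
#' Runs the full intraspecific outlier analysis for one species: clr
#' transform, minimum-TPM filter on nontoxins, nontoxin null band over the
#' two individuals, and toxin outlier calls.
#'
#' @param expr TPM expression table with `transcript_id`, `class` and exactly
#'   two sample columns (the species' two individuals).
#' @param threshold Minimum TPM applied to nontoxins (default 1).
#' @param probs Band percentile (default 0.99).
#' @param ... Passed to [clr_transform()].
#' @return A tibble of toxin outlier calls (see [call_outliers()]), with the
#'   `null_band` attached as attribute `"band"`.
#' @export
intraspecific_divergence <- function(expr, threshold = 1, probs = 0.99, ...) {
  assert_expression(expr)
  smp <- expr_sample_cols(expr)
  if (length(smp) != 2L) {
    stop("intraspecific analysis expects exactly 2 individuals", call. = FALSE)
  }
  nontoxin <- expr[expr$class == "nontoxin", , drop = FALSE]
  nontoxin <- filter_min_tpm(nontoxin, threshold = threshold)
  toxin <- expr[expr$class != "nontoxin", , drop = FALSE]
  # clr on the full filtered composition so both groups share the geometry
  comp <- clr_transform(dplyr::bind_rows(nontoxin, toxin), ...)
  pts <- tibble::tibble(
    transcript_id = comp$transcript_id,
    class = comp$class,
    x = comp[[smp[1]]],
    y = comp[[smp[2]]]
  )
  band <- build_null_band(pts[pts$class == "nontoxin", ], probs = probs)
  call_outliers(band, pts[pts$class != "nontoxin", ])
}

#' Interspecific expression divergence of toxin orthologs
#'
#' Axes are per-species mean clr values (arithmetic mean over individuals,
#' i.e. geometric mean of abundances), joined across species through the
#' one-to-one ortholog pairing. The null band is built from nontoxin
#' orthologs; toxin orthologs are then called against it. Unpaired
#' transcripts are skipped.
#'
#' @param expr_a,expr_b Per-species TPM tables (`transcript_id`, `class`,
#'   one column per individual).
#' @param pairs Data frame with `id_a`, `id_b`: one-to-one ortholog pairs
#'   (ids in `expr_a` and `expr_b` respectively).
#' @param threshold Minimum TPM applied to nontoxins within each species.
#' @param probs Band percentile (default 0.99).
#' @param ... Passed to [clr_transform()].
#' @return A tibble of toxin-ortholog calls with columns `id_a`, `id_b`,
#'   `class`, `x` (species A mean clr), `y` (species B), `residual`,
#'   `is_outlier`, `direction` (`"y"` = higher in species B).
#' @export
interspecific_divergence <- function(expr_a, expr_b, pairs, threshold = 1,
                                     probs = 0.99, ...) {
  mean_clr <- function(expr) {
    nontoxin <- filter_min_tpm(expr[expr$class == "nontoxin", , drop = FALSE],
                               threshold = threshold)
    keep <- dplyr::bind_rows(nontoxin, expr[expr$class != "nontoxin", , drop = FALSE])
    cl <- clr_transform(keep, ...)
    tibble::tibble(
      transcript_id = cl$transcript_id,
      class = cl$class,
      value = rowMeans(as.matrix(cl[expr_sample_cols(cl)]))
    )
  }
  a <- mean_clr(expr_a)
  b <- mean_clr(expr_b)
  joined <- dplyr::inner_join(
    dplyr::inner_join(tibble::as_tibble(pairs[c("id_a", "id_b")]), a,
                      by = c(id_a = "transcript_id")),
    b, by = c(id_b = "transcript_id"), suffix = c("_a", "_b")
  )
  n_skipped <- nrow(pairs) - nrow(joined)
  if (n_skipped > 0) {
    message(n_skipped, " ortholog pair(s) skipped (filtered or missing expression)")
  }
  pts <- tibble::tibble(
    id_a = joined$id_a, id_b = joined$id_b, class = joined$class_a,
    x = joined$value_a, y = joined$value_b
  )
  band <- build_null_band(pts[pts$class == "nontoxin", c("x", "y")], probs = probs)
  call_outliers(band, pts[pts$class != "nontoxin", ])
}
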