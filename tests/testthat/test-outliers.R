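test_that("orthogonal fit recovers exact and noisy lines", {
  pts <- tibble::tibble(x = c(-2, 0, 1, 3), y = c(-2, 0, 1, 3))
  f <- orthogonal_fit(pts)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(unname(venomdelta:::orthogonal_residuals(f, pts$x, pts$y)),
               rep(0, 4))

  set.seed(3)
  x <- rnorm(100)
  noisy <- tibble::tibble(x = x + rnorm(100, 0, 0.01),
                          y = 2 * x + 1 + rnorm(100, 0, 0.01))
  f2 <- orthogonal_fit(noisy)
  expect_lt(abs(f2$slope - 2), 2e-2)
})

test_that("axis swap inverts the slope", {
  set.seed(4)
  pts <- tibble::tibble(x = rnorm(50), y = rnorm(50) * 0.3 + rnorm(50))
  f <- orthogonal_fit(pts)
  f_swap <- orthogonal_fit(tibble::tibble(x = pts$y, y = pts$x))
  expect_equal(f_swap$slope, 1 / f$slope, tolerance = 1e-9)
})

test_that("isotropic clouds fall back to slope 1 with a warning", {
  pts <- tibble::tibble(x = c(-1, 1, 0, 0), y = c(0, 0, -1, 1))
  expect_warning(f <- orthogonal_fit(pts), "isotropic")
  expect_equal(f$slope, 1)
})

test_that("null band half-width follows the interpolated 99th percentile", {
  # residual magnitudes 1..100 (each planted as a +/- pair so the fit stays
  # on y = x) against a wide x spread: interpolated 99th percentile = 99.01
  t <- rep(seq(-1, 1, length.out = 100) * 1e7, each = 2)
  disp <- as.vector(rbind(1:100, -(1:100))) * sqrt(2)
  y <- t + disp
  band <- build_null_band(tibble::tibble(x = t, y = y))
  expect_equal(band$half_width, 99.01, tolerance = 1e-4)
  # homogeneity: scaling the cloud scales the half-width
  band2 <- build_null_band(tibble::tibble(x = 3 * t, y = 3 * y))
  expect_equal(band2$half_width, 3 * band$half_width, tolerance = 1e-4)
  # perfectly collinear nontoxins give a zero-width band
  collinear <- build_null_band(tibble::tibble(x = t, y = 2 * t),
                               residuals = "absolute")
  expect_equal(collinear$half_width, 0)
})

test_that("outlier calls flag by band exceedance with direction", {
  t <- seq(1, 10, length.out = 100)
  band <- build_null_band(tibble::tibble(x = t, y = t + rep(c(-0.1, 0.1), 50)))
  toxins <- tibble::tibble(transcript_id = c("on", "hi", "lo"),
                           x = c(5, 5, 5), y = c(5, 8, 2))
  calls <- call_outliers(band, toxins)
  expect_false(calls$is_outlier[calls$transcript_id == "on"])
  expect_true(all(calls$is_outlier[calls$transcript_id %in% c("hi", "lo")]))
  expect_equal(calls$direction[calls$transcript_id == "hi"], "y")
  expect_equal(calls$direction[calls$transcript_id == "lo"], "x")
  # monotonicity: pushing a flagged toxin further out keeps it flagged
  further <- call_outliers(band, tibble::tibble(transcript_id = "hi",
                                                x = 5, y = 12))
  expect_true(further$is_outlier)
  expect_gt(abs(further$residual), abs(calls$residual[calls$transcript_id == "hi"]))
})

test_that("flag set is invariant under axis relabeling", {
  set.seed(9)
  t <- rnorm(300)
  pts <- tibble::tibble(x = t + rnorm(300, 0, 0.2), y = t + rnorm(300, 0, 0.2))
  tox <- tibble::tibble(transcript_id = sprintf("t%d", 1:20),
                        x = rnorm(20), y = rnorm(20))
  flags <- call_outliers(build_null_band(pts), tox)$is_outlier
  flags_swapped <- call_outliers(
    build_null_band(tibble::tibble(x = pts$y, y = pts$x)),
    tibble::tibble(transcript_id = tox$transcript_id, x = tox$y, y = tox$x)
  )$is_outlier
  expect_identical(flags, flags_swapped)
})

test_that("identical species profiles yield no interspecific outliers", {
  set.seed(10)
  vals <- rlnorm(120, 4, 1.5)
  expr_a <- tibble::tibble(
    transcript_id = c(sprintf("n%03d_A", 1:100), sprintf("x%02d_A", 1:20)),
    class = c(rep("nontoxin", 100), rep("SVMP", 20)),
    A_1 = vals + 2, A_2 = vals + 2)
  expr_b <- expr_a
  expr_b$transcript_id <- sub("_A$", "_B", expr_b$transcript_id)
  names(expr_b)[3:4] <- c("B_1", "B_2")
  pairs <- tibble::tibble(id_a = expr_a$transcript_id,
                          id_b = expr_b$transcript_id)
  calls <- interspecific_divergence(expr_a, expr_b, pairs)
  expect_false(any(calls$is_outlier))

  # one ortholog shifted by +3 clr in species B: exactly that one flagged
  shifted <- expr_b
  k <- which(shifted$transcript_id == "x01_B")
  shifted$B_1[k] <- shifted$B_1[k] * exp(3)
  shifted$B_2[k] <- shifted$B_2[k] * exp(3)
  calls2 <- interspecific_divergence(expr_a, shifted, pairs)
  expect_equal(calls2$id_b[calls2$is_outlier], "x01_B")
  expect_equal(calls2$direction[calls2$is_outlier], "y")
})

test_that("planted interspecific shifts of >= 2 clr are recalled", {
  set.seed(12)
  shifts <- tibble::tibble(
    transcript_id = sprintf("SVMP-%d", 1:40),
    species = rep(c("A", "B"), 20),
    fold_change = exp(runif(40, 2, 3)))
  cfg <- cohort_config(
    n_nontoxin_orthologs = 1000,
    toxin_family_plan = c(SVMP = 40, CTL = 21),
    planted_expression_shifts = shifts,
    with_sequences = FALSE, with_proteome = FALSE, with_mirna = FALSE,
    rng_seed = 12)
  co <- generate_cohort(cfg)
  calls <- interspecific_divergence(co$expression$A, co$expression$B,
                                    co$ortholog_truth)
  planted <- paste0(shifts$transcript_id, "_A")
  recall <- mean(planted %in% calls$id_a[calls$is_outlier])
  expect_gte(recall, 0.9)
})
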