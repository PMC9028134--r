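test_that("clr transform matches closed forms and handles zeros", {
  e <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                      s1 = c(1, 1, 1, 1))
  expect_equal(clr_transform(e)$s1, rep(0, 4))

  e2 <- tibble::tibble(transcript_id = c("a", "b", "c"),
                       s1 = c(1, exp(1), exp(2)))
  expect_equal(clr_transform(e2)$s1, c(-1, 0, 1))

  # zero replacement: half the smallest nonzero value
  e3 <- tibble::tibble(transcript_id = c("a", "b", "c"), s1 = c(0, 2, 8))
  lx <- log(c(1, 2, 8))
  expect_equal(clr_transform(e3)$s1, lx - mean(lx))
  e4 <- tibble::tibble(transcript_id = c("a", "b"), s1 = c(0, 0))
  expect_error(clr_transform(e4), "all-zero")
})

test_that("clr obeys zero-sum, scale invariance and rank preservation", {
  set.seed(11)
  for (rep in 1:20) {
    expr <- random_expr(n = 50, k = 3, zero_frac = ifelse(rep %% 2, 0, 0.05))
    cl <- clr_transform(expr)
    for (s in c("s1", "s2", "s3")) {
      expect_lt(abs(sum(cl[[s]])), 1e-9 * 50)
      expect_equal(rank(cl[[s]]), rank(replace(expr[[s]], expr[[s]] == 0,
                                               min(expr[[s]][expr[[s]] > 0]) / 2)))
    }
    scaled <- expr
    for (s in c("s1", "s2", "s3")) scaled[[s]] <- scaled[[s]] * 10
    expect_equal(as.matrix(clr_transform(scaled)[c("s1", "s2", "s3")]),
                 as.matrix(cl[c("s1", "s2", "s3")]))
  }
})

test_that("TMM factors are 1 for identical or purely rescaled libraries", {
  set.seed(5)
  counts <- tibble::tibble(transcript_id = sprintf("g%04d", 1:800),
                           a = rpois(800, 50))
  counts$b <- counts$a
  f <- tmm_factors(counts)
  expect_equal(f$factor, c(1, 1), tolerance = 1e-12)
  counts$b <- counts$a * 2L
  f2 <- tmm_factors(counts)
  expect_equal(f2$factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM recovers a planted composition bias within 5% of the oracle", {
  set.seed(7)
  base <- rpois(1050, 100) + 1L
  b <- base
  up <- 1:50                      # 50 genes 10-fold up only in sample b
  b[up] <- b[up] * 10L
  counts <- tibble::tibble(transcript_id = sprintf("g%04d", seq_along(base)),
                           a = base, b = b)
  f <- tmm_factors(counts)
  oracle <- oracle_tmm_factor(counts$b, counts$a)
  # factors are reported rescaled to geometric mean 1
  expect_equal(f$factor[2] / f$factor[1], oracle, tolerance = 0.05)
  # closed form: unshifted genes share M = log2(sum(a)/sum(b)) exactly and
  # survive the trim, so the factor is the library-fraction ratio itself
  expect_equal(f$factor[2] / f$factor[1], sum(counts$a) / sum(counts$b),
               tolerance = 0.05)
  # gene order must not matter
  perm <- sample(nrow(counts))
  f_perm <- tmm_factors(counts[perm, ])
  expect_equal(f_perm$factor, f$factor, tolerance = 1e-12)
})

test_that("TMM agrees with edgeR on tie-free heterogeneous libraries", {
  set.seed(15)
  mu <- rlnorm(600, 5, 1.3)
  counts <- tibble::tibble(
    transcript_id = sprintf("g%04d", 1:600),
    a = rpois(600, mu) + 1L,
    b = rpois(600, mu * rlnorm(600, 0, 0.25)) + 1L)
  f <- tmm_factors(counts)
  fe <- edgeR::calcNormFactors(as.matrix(counts[c("a", "b")]), method = "TMM")
  fe <- fe / exp(mean(log(fe)))
  expect_equal(f$factor, unname(fe), tolerance = 0.02)
})

test_that("TMM rejects samples sharing no expressed genes", {
  counts <- tibble::tibble(transcript_id = c("g1", "g2"),
                           a = c(10L, 0L), b = c(0L, 10L))
  expect_error(tmm_factors(counts), "shares no nonzero")
})

test_that("minimum-TPM filter removes boundary values and is idempotent", {
  expr <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    class = "nontoxin",
    i1 = c(1.0, 5.0, 0.5), i2 = c(5.0, 5.0, 3.0))
  kept <- filter_min_tpm(expr, threshold = 1)
  expect_equal(kept$transcript_id, "t2")   # TPM exactly 1 is removed
  expect_identical(filter_min_tpm(kept, threshold = 1), kept)

  # all above threshold: identity; threshold 0 on positive values: identity
  hi <- tibble::tibble(transcript_id = c("a", "b"), i1 = c(2, 3), i2 = c(4, 5))
  expect_identical(filter_min_tpm(hi, threshold = 1), hi)
  expect_identical(filter_min_tpm(expr, threshold = 0),
                   expr[expr$i1 > 0 & expr$i2 > 0, ])
})

test_that("minimum-TPM filter respects species scope", {
  expr <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    A_1 = c(5, 5), A_2 = c(5, 5), B_1 = c(0.5, 5), B_2 = c(5, 5))
  samples <- tibble::tibble(sample_id = c("A_1", "A_2", "B_1", "B_2"),
                            species = c("A", "A", "B", "B"))
  expect_equal(filter_min_tpm(expr, samples)$transcript_id, "t2")
  expect_equal(filter_min_tpm(expr, samples, scope = "any_species")$transcript_id,
               c("t1", "t2"))
})

test_that("TPM rescaling makes sample columns sum to one million", {
  expr <- random_expr(30, 2)
  tpm <- scale_to_tpm(expr)
  expect_equal(sum(tpm$s1), 1e6)
  expect_equal(sum(tpm$s2), 1e6)
})
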