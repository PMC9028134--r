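test_that("variance filter drops constant transcripts and keeps blocks", {
  set.seed(61)
  sim <- simulate_coexpression(n_modules = 2, module_size = 10, n_noise = 0,
                               n_samples = 10, within_sd = 0.1)
  flat <- tibble::tibble(transcript_id = sprintf("flat%d", 1:5), class = "nontoxin")
  for (s in venomdelta:::expr_sample_cols(sim$expr)) flat[[s]] <- 7
  expr <- dplyr::bind_rows(sim$expr, flat)
  filt <- vst_filter(expr, coexpression_config(variance_filter_keep = 20),
                     transform = FALSE)
  expect_setequal(filt$transcript_id, sim$expr$transcript_id)
})

test_that("variance filter with a count cap is idempotent", {
  set.seed(62)
  sim <- simulate_coexpression(n_modules = 3, module_size = 8, n_noise = 30,
                               n_samples = 10)
  cfg <- coexpression_config(variance_filter_keep = 25)
  once <- vst_filter(sim$expr, cfg, transform = FALSE)
  twice <- vst_filter(once, cfg, transform = FALSE)
  expect_identical(dplyr::arrange(once, transcript_id),
                   dplyr::arrange(twice, transcript_id))
  expect_error(vst_filter(dplyr::mutate(sim$expr,
                                        dplyr::across(dplyr::where(is.numeric), ~0)),
                          cfg, transform = FALSE),
               "constant")
})

perfect_blocks <- function(n_samples = 10) {
  p1 <- seq(-1, 1, length.out = n_samples)
  p2 <- rep(c(1, -1), length.out = n_samples)
  expr <- tibble::tibble(transcript_id = sprintf("t%02d", 1:20))
  vals <- rbind(
    t(sapply(seq(0.5, 5, length.out = 10), function(a) 3 + a * p1)),
    t(sapply(seq(0.5, 5, length.out = 10), function(a) 3 + a * p2)))
  for (j in seq_len(n_samples)) expr[[sprintf("s%02d", j)]] <- vals[, j]
  expr
}

test_that("perfect two-block designs give exactly two modules", {
  expr <- perfect_blocks()
  mods <- suppressWarnings(detect_modules(expr))
  assign <- mods$assignment
  expect_equal(length(unique(assign$module)), 2)
  expect_equal(length(unique(assign$module[1:10])), 1)
  expect_equal(length(unique(assign$module[11:20])), 1)

  # a much larger beta cannot change a 0/1 correlation structure
  mods2 <- suppressWarnings(
    detect_modules(expr, coexpression_config(beta = 30)))
  expect_equal(oracle_ari(assign$module, mods2$assignment$module), 1)
})

test_that("module content is invariant under transcript reordering", {
  set.seed(63)
  sim <- simulate_coexpression(n_modules = 3, module_size = 8, n_noise = 10)
  m1 <- suppressWarnings(detect_modules(sim$expr))
  perm <- sample(nrow(sim$expr))
  m2 <- suppressWarnings(detect_modules(sim$expr[perm, ]))
  j <- dplyr::inner_join(m1$assignment, m2$assignment, by = "transcript_id")
  expect_equal(oracle_ari(j$module.x, j$module.y), 1)
  # partition property: every transcript appears exactly once
  expect_setequal(m1$assignment$transcript_id, sim$expr$transcript_id)
  expect_false(any(duplicated(m1$assignment$transcript_id)))
})

test_that("planted five-profile cohorts are recovered", {
  set.seed(64)
  aris <- replicate(5, {
    sim <- simulate_coexpression(n_modules = 5, module_size = 10,
                                 n_noise = 50, n_samples = 12)
    mods <- suppressWarnings(detect_modules(sim$expr))
    planted <- sim$truth[sim$truth$module > 0, ]
    j <- dplyr::inner_join(planted, mods$assignment, by = "transcript_id")
    oracle_ari(j$module.x, j$module.y)
  })
  expect_gte(mean(aris), 0.9)
})

test_that("module annotation links toxins and transcription factors", {
  set.seed(65)
  sim <- simulate_coexpression(n_modules = 2, module_size = 8, n_noise = 5,
                               toxins_per_module = 2, tfs_per_module = 2)
  mods <- suppressWarnings(detect_modules(sim$expr))
  tf_ids <- sim$truth$transcript_id[sim$truth$is_tf]
  rep <- annotate_modules(mods, sim$truth[c("transcript_id", "class")], tf_ids)
  expect_true(all(c("n_toxin", "tf_members", "has_toxin") %in% names(rep)))
  # no TFs given: all TF lists empty
  rep0 <- annotate_modules(mods, sim$truth[c("transcript_id", "class")])
  expect_true(all(rep0$tf_members == ""))
  # each planted module's TFs sit in the module holding its toxins
  j <- dplyr::inner_join(sim$truth, mods$assignment, by = "transcript_id")
  for (m in 1:2) {
    tox_mod <- j$module.y[j$module.x == m & j$class != "nontoxin"]
    tf_mod <- j$module.y[j$module.x == m & j$is_tf]
    expect_true(all(tf_mod == tox_mod[1]))
    row <- rep[rep$module == tox_mod[1], ]
    expect_true(row$has_toxin)
    expect_true(all(strsplit(row$tf_members, ",")[[1]] %in% tf_ids))
  }
})
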