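test_that("site counts match hand-enumerated codons", {
  expect_equal(ng86_sites("TTT")$s, 1 / 3)   # only TTC is synonymous
  expect_equal(ng86_sites("TGG")$s, 0)       # Trp: no synonymous change
  expect_error(ng86_sites("TAA"), "stop")
  # every sense codon sums to 3 sites
  all_s <- ng86_sites(venomdelta:::sense_codons())
  expect_equal(all_s$s + all_s$n, rep(3, 61))
})

test_that("pathway-averaged differences conserve the Hamming distance", {
  expect_equal(unlist(ng86_differences("TTT", "TTT")[c("sd", "nd")]),
               c(sd = 0, nd = 0))
  expect_equal(unlist(ng86_differences("TTT", "TTC")[c("sd", "nd")]),
               c(sd = 1, nd = 0))
  set.seed(21)
  cods <- venomdelta:::sense_codons()
  a <- sample(cods, 100, replace = TRUE)
  b <- sample(cods, 100, replace = TRUE)
  d <- ng86_differences(a, b)
  hamming <- mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b)
  expect_equal(d$sd + d$nd, unname(hamming))
})

test_that("differences match the exhaustive pathway oracle on random pairs", {
  set.seed(22)
  cods <- venomdelta:::sense_codons()
  a <- sample(cods, 150, replace = TRUE)
  b <- sample(cods, 150, replace = TRUE)
  d <- ng86_differences(a, b)
  for (i in seq_len(150)) {
    o <- oracle_diffs(a[i], b[i])
    expect_equal(d$sd[i], unname(o["sd"]))
    expect_equal(d$nd[i], unname(o["nd"]))
  }
})

test_that("pairwise estimates behave at the identical and small-p limits", {
  seq100 <- strrep("TTTGCA", 50)
  same <- pairwise_dnds(list(seq_a = seq100, seq_b = seq100))
  expect_equal(same$dS, 0)
  expect_equal(same$dN, 0)
  expect_true(is.na(same$omega))
  expect_equal(same$filter_flag, "undefined")
  expect_equal(same$S_sites + same$N_sites, 3 * same$n_codons, tolerance = 1e-6)

  # 300 TTT codons with one synonymous change: pS = 0.01, JC within 1%
  a <- strrep("TTT", 300)
  b <- paste0("TTC", strrep("TTT", 299))
  est <- pairwise_dnds(list(seq_a = a, seq_b = b))
  expect_equal(est$pS, 0.01)
  expect_equal(est$dS, est$pS, tolerance = 0.01)
})

test_that("pairwise estimates are symmetric and pool over concatenation", {
  set.seed(23)
  anc <- random_cds(200)
  ev <- evolve_ortholog_pair(anc, 0.06, 0.5)
  ab <- pairwise_dnds(list(seq_a = ev$cds_a, seq_b = ev$cds_b))
  ba <- pairwise_dnds(list(seq_a = ev$cds_b, seq_b = ev$cds_a))
  expect_equal(ab[c("S_sites", "N_sites", "Sd", "Nd", "dS", "dN", "omega")],
               ba[c("S_sites", "N_sites", "Sd", "Nd", "dS", "dN", "omega")])

  ev2 <- evolve_ortholog_pair(random_cds(150), 0.04, 1.5)
  cat1 <- pairwise_dnds(list(seq_a = paste0(ev$cds_a, ev2$cds_a),
                             seq_b = paste0(ev$cds_b, ev2$cds_b)))
  part2 <- pairwise_dnds(list(seq_a = ev2$cds_a, seq_b = ev2$cds_b))
  expect_equal(cat1$Sd, ab$Sd + part2$Sd)
  expect_equal(cat1$Nd, ab$Nd + part2$Nd)
  expect_equal(cat1$S_sites, ab$S_sites + part2$S_sites)
})

test_that("dS-range filtering flags exactly the out-of-range pairs", {
  res <- tibble::tibble(
    id_a = sprintf("p%d", 1:4), id_b = sprintf("q%d", 1:4),
    dS = c(0.0005, 0.05, 0.15, 0.10), dN = 0.01, omega = 1,
    filter_flag = "pass")
  out <- filter_ds_range(res)
  expect_equal(out$filter_flag,
               c("ds_too_low", "pass", "ds_too_high", "pass"))
})

test_that("group comparison separates planted toxin and nontoxin omegas", {
  set.seed(24)
  n_tox <- 30; n_ntx <- 80
  sim_class <- function(n, omega_mean, cls) {
    rows <- lapply(seq_len(n), function(i) {
      ev <- evolve_ortholog_pair(random_cds(200), runif(1, 0.03, 0.08),
                                 rgamma(1, 2, scale = omega_mean / 2))
      out <- pairwise_dnds(list(seq_a = ev$cds_a, seq_b = ev$cds_b))
      out$id_a <- sprintf("%s_%d", cls, i)
      out$class <- cls
      out
    })
    dplyr::bind_rows(rows)
  }
  res <- filter_ds_range(dplyr::bind_rows(
    sim_class(n_tox, 0.8, "SVMP"), sim_class(n_ntx, 0.15, "nontoxin")))
  cmp <- compare_groups(res)
  expect_lt(cmp$metrics$omega$p_value, 0.01)
  expect_true(all(cmp$positive_selection %in% res$id_a[res$class == "SVMP"]))
  flagged <- cmp$metrics$omega$flagged
  thr <- cmp$metrics$omega$threshold
  tox_pass <- res[res$class == "SVMP" & res$filter_flag == "pass" &
                    !is.na(res$omega), ]
  expect_setequal(flagged, tox_pass$id_a[tox_pass$omega > thr])
})

test_that("identical class distributions give a null comparison", {
  set.seed(25)
  vals <- runif(40, 0.02, 0.09)
  res <- tibble::tibble(
    id_a = sprintf("x%d", 1:40), id_b = sprintf("y%d", 1:40),
    dS = vals, dN = vals * 0.3, omega = rep(0.3, 40),
    filter_flag = "pass",
    class = rep(c("CTL", "nontoxin"), each = 20))
  res$dS <- rep(res$dS[1:20], 2)  # identical distributions in both groups
  res$dN <- rep(res$dN[1:20], 2)
  cmp <- compare_groups(res)
  expect_gt(cmp$metrics$dS$p_value, 0.9)
  expect_length(cmp$positive_selection, 0)
})
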