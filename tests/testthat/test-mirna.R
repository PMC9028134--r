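mk_mirna <- function(n = 5, seed = 70) {
  venomdelta:::with_rng(seed, tibble::tibble(
    mirna_id = sprintf("mir-%02d", seq_len(n)),
    seq = replicate(n, paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                             collapse = ""))))
}

test_that("quantification assigns exact and near matches and conserves reads", {
  ref <- mk_mirna(5)
  dna <- venomdelta:::as_dna(ref$seq)
  mismatched <- dna[2]
  substr(mismatched, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                        substr(mismatched, 10, 10))[1]
  reads <- c(rep(dna[1], 7), rep(mismatched, 3),
             rep(paste(rep("ACGT", 5), collapse = ""), 2))  # 20-nt nonmatch
  q <- collapse_and_quantify(reads, ref)
  expect_equal(q$counts$count[1], 7)
  expect_equal(q$counts$count[2], 3)          # 1 mismatch accepted
  expect_equal(sum(q$unassigned$count), 2)
  expect_equal(sum(q$counts$count) + sum(q$unassigned$count), q$total)
  expect_error(collapse_and_quantify(reads, ref[0, ]), "empty")
})

test_that("planted proportions are recovered exactly at zero mismatches", {
  ref <- mk_mirna(10, seed = 71)
  planted <- c(50, 40, 30, 25, 20, 15, 10, 5, 4, 1)
  reads <- tibble::tibble(seq = venomdelta:::as_dna(ref$seq), count = planted)
  q <- collapse_and_quantify(reads, ref, max_mismatch = 0)
  expect_equal(q$counts$count, planted)
  expect_equal(nrow(q$unassigned), 0)
})

test_that("end-trimmed reads still map within the 2-nt flexibility", {
  ref <- mk_mirna(3, seed = 72)
  dna <- venomdelta:::as_dna(ref$seq)
  trimmed <- substr(dna[1], 2, 21)   # 20 nt, one nt lost at each end
  q <- collapse_and_quantify(trimmed, ref, max_mismatch = 0)
  expect_equal(q$counts$count[1], 1)
})

test_that("duplex detection requires the 2-nt overhang signature", {
  venomdelta:::with_rng(73, {
    mature <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                    collapse = "")
    star_core <- venomdelta:::dna_revcomp(substr(mature, 1, 20))
    star <- paste0(star_core, "CA")      # 2-nt 3' overhang on each strand
    bad <- paste0(venomdelta:::dna_revcomp(substr(mature, 1, 18)), "ACGT")
    other <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                   collapse = "")
    collapsed <- tibble::tibble(seq = c(mature, star, other),
                                count = c(120, 30, 50))
    hits <- detect_novel_duplex(collapsed, min_count = 5)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$candidate_seq, mature)
    expect_equal(hits$star_seq, star)
    # a 4-nt overhang violates the rule
    collapsed4 <- tibble::tibble(seq = c(mature, bad), count = c(120, 30))
    expect_equal(nrow(detect_novel_duplex(collapsed4, min_count = 5)), 0)
    # nothing complementary: empty result
    expect_equal(nrow(detect_novel_duplex(
      tibble::tibble(seq = c(mature, other), count = c(10, 10)))), 0)
  })
})

test_that("seed scan types planted sites and ignores empty UTRs", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_equal(nrow(seed_scan(m, "ACGUA")), 0)   # UTR shorter than 6
  expect_equal(nrow(seed_scan(m, strrep("C", 50))), 0)
  for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    site <- venomdelta:::seed_site_sequence(m, ty)
    # flank with G: neither an A1 anchor nor this miRNA's m8 complement (C)
    utr <- paste0(strrep("G", 20), site, strrep("G", 20))
    hit <- seed_scan(m, utr)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$site_type, ty)
    expect_gte(hit$start, 19)
    expect_lte(hit$end, 20 + nchar(site) + 1)
  }
})

test_that("seed scan equals the brute-force window oracle on random UTRs", {
  venomdelta:::with_rng(74, {
    for (i in 1:25) {
      m <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                 collapse = "")
      utr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                   collapse = "")
      got <- seed_scan(m, utr)
      want <- oracle_seed_scan(m, utr)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$site_type, vapply(want, `[[`, "", "type"))
      }
    }
  })
})

test_that("DNA and RNA encodings give identical sites", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  site <- venomdelta:::seed_site_sequence(m, "8mer")
  utr_dna <- paste0(strrep("G", 15), site, strrep("T", 15))
  utr_rna <- chartr("T", "U", utr_dna)
  m_dna <- chartr("U", "T", m)
  expect_identical(seed_scan(m, utr_dna), seed_scan(m_dna, utr_rna))
})

test_that("candidate integration applies the conjunction of all rules", {
  mirna_expr <- tibble::tibble(mirna_id = c("mir-hi", "mir-lo"),
                               log2_ratio = c(2, 0.2))
  sites <- tibble::tibble(
    mirna_id = c("mir-hi", "mir-hi", "mir-lo"),
    transcript_id = c("tox-low", "tox-high", "tox-low2"),
    start = 0L, end = 8L, site_type = "8mer", duplex_score = 50)
  te <- tibble::tibble(transcript_id = c("tox-low", "tox-low2", "tox-high",
                                         "tox-mid", "tox-top"),
                       te = c(-2, -1.8, 2, 0.5, 1))
  out <- integrate_candidates(mirna_expr, sites, te)
  expect_equal(out$mirna_id, "mir-hi")
  expect_equal(out$toxin_id, "tox-low")   # high-TE target excluded
  # toxin with low TE but no site is never reported
  expect_false("tox-low2" %in% out$toxin_id)
  # no miRNA over the ratio threshold: empty
  expect_equal(nrow(integrate_candidates(mirna_expr, sites, te,
                                         expr_ratio_min = 3)), 0)
  # monotone nonincreasing in both thresholds
  loose <- integrate_candidates(mirna_expr, sites, te,
                                expr_ratio_min = 0.1, te_quantile = 0.9)
  expect_true(all(paste(out$mirna_id, out$toxin_id) %in%
                    paste(loose$mirna_id, loose$toxin_id)))
  expect_gte(nrow(loose), nrow(out))
})
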