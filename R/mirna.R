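# Genome-free miRNA toolkit: collapse-and-count quantification against a
# mature reference, duplex-rule novel-miRNA candidates, canonical seed-site
# scanning on 3'UTRs, and integration with translation efficiency.

collapse_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("seq", "count") %in% names(reads)))
    out <- stats::aggregate(count ~ seq, data = data.frame(
      seq = as_dna(reads$seq), count = reads$count), FUN = sum)
  } else {
    tab <- table(as_dna(reads))
    out <- data.frame(seq = names(tab), count = as.integer(tab))
  }
  tibble::as_tibble(out[order(-out$count, out$seq), ])
}

# Best ungapped match of a read against one mature with +/- 2 nt end
# flexibility. Returns c(mismatch, overhang) or NULL when no placement fits.
read_vs_mature <- function(read, mature, max_mismatch, end_flex = 2L) {
  rl <- nchar(read); ml <- nchar(mature)
  rs <- strsplit(read, "", fixed = TRUE)[[1]]
  ms <- strsplit(mature, "", fixed = TRUE)[[1]]
  best <- NULL
  for (off in -end_flex:end_flex) {
    # read position i aligns to mature position i + off
    i1 <- max(1L, 1L - off)
    i2 <- min(rl, ml - off)
    if (i2 < i1) next
    overhang <- (i1 - 1L) + (rl - i2)
    if (overhang > end_flex) next
    mm <- sum(rs[i1:i2] != ms[(i1 + off):(i2 + off)])
    if (mm > max_mismatch) next
    cand <- c(mismatch = mm, overhang = overhang)
    if (is.null(best) || cand[1] < best[1] ||
        (cand[1] == best[1] && cand[2] < best[2])) {
      best <- cand
    }
  }
  best
}

#' Collapse small-RNA reads and quantify known miRNAs
#'
#' Identical reads are collapsed; each collapsed read is assigned to a
#' reference mature miRNA when it matches full-length with at most
#' `max_mismatch` mismatches and at most 2 nt of end flexibility. Ambiguous
#' reads go to the best match (fewest mismatches, then least overhang); ties
#' are split equally. Reads outside 18-26 nt or matching nothing fall into
#' the unassigned bin, so assigned + unassigned counts always equal the
#' total.
#'
#' @param reads Character vector of read sequences, or a pre-collapsed data
#'   frame with `seq` and `count`.
#' @param reference Data frame with `mirna_id` and `seq` (mature miRNAs,
#'   18-26 nt).
#' @param max_mismatch Maximum mismatches against a mature (default 1).
#' @return An object of class `mirna_quant`: `counts` (tibble `mirna_id`,
#'   `count`), `unassigned` (tibble `seq`, `count`), `total`.
#' @export
collapse_and_quantify <- function(reads, reference, max_mismatch = 1) {
  if (nrow(reference) == 0L) stop("empty mature miRNA reference", call. = FALSE)
  ref_seq <- as_dna(reference$seq)
  collapsed <- collapse_reads(reads)
  counts <- stats::setNames(rep(0, nrow(reference)), reference$mirna_id)
  unassigned <- list()
  for (i in seq_len(nrow(collapsed))) {
    rd <- collapsed$seq[i]
    ct <- collapsed$count[i]
    if (nchar(rd) < 18L || nchar(rd) > 26L) {
      unassigned[[length(unassigned) + 1L]] <- collapsed[i, ]
      next
    }
    hits <- lapply(ref_seq, read_vs_mature, read = rd,
                   max_mismatch = max_mismatch)
    ok <- !vapply(hits, is.null, logical(1))
    if (!any(ok)) {
      unassigned[[length(unassigned) + 1L]] <- collapsed[i, ]
      next
    }
    score <- vapply(hits[ok], function(h) h[1] * 10 + h[2], numeric(1))
    idx <- which(ok)[score == min(score)]
    counts[idx] <- counts[idx] + ct / length(idx)
  }
  structure(
    list(counts = tibble::tibble(mirna_id = reference$mirna_id,
                                 count = unname(counts)),
         unassigned = if (length(unassigned)) dplyr::bind_rows(unassigned)
                      else tibble::tibble(seq = character(), count = numeric()),
         total = sum(collapsed$count)),
    class = "mirna_quant"
  )
}

#' @export
print.mirna_quant <- function(x, ...) {
  cat(sprintf("miRNA quantification: %.1f of %.1f reads assigned to %d matures (%d unassigned sequences)\n",
              sum(x$counts$count), x$total, sum(x$counts$count > 0),
              nrow(x$unassigned)))
  invisible(x)
}

# Is miRNA base b1 paired with opposite-strand base b2 (DNA space)?
wc_pair <- function(b1, b2) {
  (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A") |
  (b1 == "C" & b2 == "G") | (b1 == "G" & b2 == "C")
}

gu_pair <- function(b1, b2) {
  (b1 == "G" & b2 == "T") | (b1 == "T" & b2 == "G")
}

#' Detect putative novel miRNAs from read duplexes
#'
#' Among abundant collapsed reads unassigned to known matures, reports pairs
#' whose reverse-complement hybridization leaves exactly a 2-nt 3' overhang
#' on each strand (the Dicer signature) with at least `min_paired` paired
#' positions (G:U wobble allowed). The candidate mature is the more abundant
#' member of the duplex.
#'
#' @param collapsed Data frame `seq`, `count` of collapsed unassigned reads.
#' @param min_count Minimum count for both duplex members (default 5).
#' @param min_paired Minimum paired positions in the duplex region
#'   (default 14).
#' @return A tibble `candidate_seq`, `star_seq`, `candidate_count`,
#'   `star_count`, `n_paired`.
#' @export
detect_novel_duplex <- function(collapsed, min_count = 5, min_paired = 14) {
  cand <- collapsed[collapsed$count >= min_count, , drop = FALSE]
  out <- list()
  n <- nrow(cand)
  if (n >= 2L) {
    seqs <- as_dna(cand$seq)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s1 <- seqs[i]; s2 <- seqs[j]
        if (nchar(s1) != nchar(s2)) next
        L <- nchar(s1)
        if (L <= 2L) next
        # 2-nt 3' overhang each: positions 1..L-2 of each strand pair
        # antiparallel with the other's 1..L-2 region
        a <- strsplit(substr(s1, 1L, L - 2L), "", fixed = TRUE)[[1]]
        b <- rev(strsplit(substr(s2, 1L, L - 2L), "", fixed = TRUE)[[1]])
        paired <- sum(wc_pair(a, b) | gu_pair(a, b))
        if (paired < min_paired) next
        hi <- if (cand$count[i] >= cand$count[j]) i else j
        lo <- if (hi == i) j else i
        out[[length(out) + 1L]] <- tibble::tibble(
          candidate_seq = seqs[hi], star_seq = seqs[lo],
          candidate_count = cand$count[hi], star_count = cand$count[lo],
          n_paired = paired)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(candidate_seq = character(), star_seq = character(),
                   candidate_count = numeric(), star_count = numeric(),
                   n_paired = integer())
  }
}

#' Scan a 3'UTR for canonical miRNA seed sites
#'
#' Finds matches of the reverse complement of miRNA positions 2-7 on the UTR
#' and types each site: extended by a perfect match opposite position 8
#' (7mer-m8), an A opposite position 1 (7mer-A1), both (8mer), neither
#' (6mer). The duplex score pairs the full miRNA gaplessly against the UTR
#' around the site: +5 per Watson-Crick pair, +2 per G:U pair. DNA and RNA
#' encodings of the same sequences give identical sites.
#'
#' @param mirna_seq Mature miRNA sequence (5'->3', RNA or DNA alphabet).
#' @param utr_seq 3'UTR sequence (5'->3').
#' @param mirna_id,transcript_id Optional ids carried into the result.
#' @return A tibble `mirna_id`, `transcript_id`, `start`, `end` (0-based,
#'   half-open on the UTR), `site_type`, `duplex_score`. Empty when the UTR
#'   is shorter than 6 nt or has no seed match.
#' @export
seed_scan <- function(mirna_seq, utr_seq, mirna_id = NA_character_,
                      transcript_id = NA_character_) {
  m <- as_dna(mirna_seq)
  u <- as_dna(utr_seq)
  L <- nchar(u)
  empty <- tibble::tibble(mirna_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          site_type = character(), duplex_score = numeric())
  if (L < 6L || nchar(m) < 8L) return(empty)
  core6 <- dna_revcomp(substr(m, 2, 7))
  m8_comp <- dna_complement(substr(m, 8, 8))
  us <- strsplit(u, "", fixed = TRUE)[[1]]
  ms <- strsplit(m, "", fixed = TRUE)[[1]]
  rows <- list()
  for (p0 in 0:(L - 6L)) {            # 0-based start of the 6mer core
    if (substr(u, p0 + 1L, p0 + 6L) != core6) next
    has_m8 <- p0 >= 1L && us[p0] == m8_comp
    has_a1 <- (p0 + 6L) < L && us[p0 + 7L] == "A"
    site_type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    start <- p0 - (has_m8)
    end <- p0 + 6L + (has_a1)
    # gapless duplex: miRNA position i (1-based) opposite UTR 1-based
    # position p0 + 8 - i (antiparallel)
    score <- 0
    for (i in seq_along(ms)) {
      ui <- p0 + 8L - i
      if (ui < 1L || ui > L) next
      if (wc_pair(ms[i], us[ui])) score <- score + 5
      else if (gu_pair(ms[i], us[ui])) score <- score + 2
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mirna_id = mirna_id, transcript_id = transcript_id,
      start = as.integer(start), end = as.integer(end),
      site_type = site_type, duplex_score = score)
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty
}

#' Scan many miRNAs against many 3'UTRs
#'
#' @param matures Data frame `mirna_id`, `seq`.
#' @param utrs Data frame `transcript_id`, `seq`.
#' @return Row-bound [seed_scan()] results.
#' @export
scan_targets <- function(matures, utrs) {
  rows <- list()
  for (i in seq_len(nrow(matures))) {
    for (j in seq_len(nrow(utrs))) {
      rows[[length(rows) + 1L]] <- seed_scan(
        matures$seq[i], utrs$seq[j],
        mirna_id = matures$mirna_id[i],
        transcript_id = utrs$transcript_id[j])
    }
  }
  dplyr::bind_rows(rows)
}

#' TMM-normalized miRNA expression
#'
#' Scales raw miRNA counts to counts-per-million adjusted by TMM factors.
#'
#' @param counts Tibble `mirna_id` plus one raw-count column per library.
#' @param ... Passed to [tmm_factors()].
#' @return The tibble with sample columns replaced by TMM-CPM values.
#' @export
mirna_normalize <- function(counts, ...) {
  smp <- expr_sample_cols(counts)
  fac <- tmm_factors(counts, ...)
  out <- tibble::as_tibble(counts)
  for (cc in smp) {
    eff <- sum(out[[cc]]) * fac$factor[fac$sample_id == cc]
    out[[cc]] <- out[[cc]] / eff * 1e6
  }
  out
}

#' Integrate miRNA expression, target sites and translation efficiency
#'
#' Emits (miRNA, toxin) regulatory candidates where the miRNA's
#' between-species log2 expression ratio is at least `expr_ratio_min`, the
#' toxin's translation efficiency falls in the lowest `te_quantile` of
#' toxins, and at least one seed site links the pair.
#'
#' @param mirna_expr Tibble `mirna_id`, `log2_ratio` (species of interest
#'   over the other, TMM-normalized).
#' @param sites [scan_targets()] output (`mirna_id`, `transcript_id`, ...).
#' @param te Tibble `transcript_id`, `te` (clr units, see
#'   [translation_efficiency()]).
#' @param expr_ratio_min Minimum miRNA log2 ratio (default 1).
#' @param te_quantile Low-TE quantile of toxins (default 0.25).
#' @return A tibble `mirna_id`, `toxin_id`, `log2_ratio`, `te`, `n_sites`.
#' @export
integrate_candidates <- function(mirna_expr, sites, te,
                                 expr_ratio_min = 1, te_quantile = 0.25) {
  te <- tibble::as_tibble(te)
  te_cut <- pctl(te$te, te_quantile)
  low_te <- te[te$te <= te_cut, , drop = FALSE]
  hi_mirna <- mirna_expr[mirna_expr$log2_ratio >= expr_ratio_min, , drop = FALSE]
  if (nrow(hi_mirna) == 0L || nrow(low_te) == 0L || nrow(sites) == 0L) {
    return(tibble::tibble(mirna_id = character(), toxin_id = character(),
                          log2_ratio = numeric(), te = numeric(),
                          n_sites = integer()))
  }
  site_counts <- sites |>
    dplyr::count(.data$mirna_id, .data$transcript_id, name = "n_sites")
  out <- hi_mirna |>
    dplyr::inner_join(site_counts, by = "mirna_id") |>
    dplyr::inner_join(low_te[c("transcript_id", "te")], by = "transcript_id") |>
    dplyr::transmute(mirna_id = .data$mirna_id, toxin_id = .data$transcript_id,
                     log2_ratio = .data$log2_ratio, te = .data$te,
                     n_sites = .data$n_sites)
  dplyr::arrange(out, dplyr::desc(.data$log2_ratio), .data$toxin_id)
}
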