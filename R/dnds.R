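# Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
# correction. Site and pathway tables over the 61 sense codons are built once
# and cached; pairwise estimation is then a table lookup per codon column.

.dnds_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  # Standard code; Biostrings::GENETIC_CODE uses "*" for stops.
  Biostrings::GENETIC_CODE
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

is_stop_codon <- function(codon) {
  unname(genetic_code()[codon] == "*")
}

#' Expected synonymous and nonsynonymous sites of a codon (NG86)
#'
#' For each of the three codon positions, the synonymous fraction is the
#' number of synonymous single-nucleotide changes divided by the number of
#' changes that do not create a stop codon; the nonsynonymous fraction is its
#' complement, so `s + n = 3` for every sense codon.
#'
#' @param codon Character vector of sense codons (DNA alphabet).
#' @return A tibble with columns `codon`, `s`, `n`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3
#' @export
ng86_sites <- function(codon) {
  codon <- as_dna(codon)
  if (any(is_stop_codon(codon))) {
    stop("stop codon has no defined site counts", call. = FALSE)
  }
  tab <- ng86_site_table()
  tibble::tibble(codon = codon,
                 s = unname(tab[codon, "s"]),
                 n = unname(tab[codon, "n"]))
}

ng86_site_table <- function() {
  if (!is.null(.dnds_cache$sites)) return(.dnds_cache$sites)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- sense_codons()
  tab <- matrix(0, nrow = length(codons), ncol = 2,
                dimnames = list(codons, c("s", "n")))
  for (cd in codons) {
    aa <- gc[[cd]]
    chars <- strsplit(cd, "", fixed = TRUE)[[1]]
    s_total <- 0
    for (pos in 1:3) {
      alts <- setdiff(bases, chars[pos])
      mut <- vapply(alts, function(b) {
        tmp <- chars; tmp[pos] <- b; paste(tmp, collapse = "")
      }, character(1))
      mut_aa <- gc[mut]
      valid <- mut_aa != "*"
      if (!any(valid)) next  # cannot happen for sense codons, kept defensive
      s_total <- s_total + sum(mut_aa[valid] == aa) / sum(valid)
    }
    tab[cd, "s"] <- s_total
    tab[cd, "n"] <- 3 - s_total
  }
  .dnds_cache$sites <- tab
  tab
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Differences are averaged over all orderings of the differing positions
#' (1, 2 or 6 pathways); each mutational step is classified synonymous or
#' nonsynonymous, pathways passing through a stop codon are excluded, and if
#' every pathway is blocked all are included (with a message). Always
#' `sd + nd` equals the nucleotide Hamming distance of the codons.
#'
#' @param codon_a,codon_b Sense codons (DNA alphabet), recycled to a common
#'   length.
#' @return A tibble with columns `codon_a`, `codon_b`, `sd`, `nd`.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- as_dna(codon_a)
  codon_b <- as_dna(codon_b)
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n)
  codon_b <- rep_len(codon_b, n)
  if (any(is_stop_codon(codon_a)) || any(is_stop_codon(codon_b))) {
    stop("stop codons are not allowed", call. = FALSE)
  }
  tabs <- ng86_diff_tables()
  sd <- nd <- numeric(n)
  for (i in seq_len(n)) {
    sd[i] <- tabs$sd[codon_a[i], codon_b[i]]
    nd[i] <- tabs$nd[codon_a[i], codon_b[i]]
  }
  tibble::tibble(codon_a = codon_a, codon_b = codon_b, sd = sd, nd = nd)
}

# Enumerate pathways for one codon pair. Returns c(sd, nd).
ng86_pair_diff <- function(ca, cb) {
  gc <- genetic_code()
  a <- strsplit(ca, "", fixed = TRUE)[[1]]
  b <- strsplit(cb, "", fixed = TRUE)[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(diff_pos),
    "2" = list(diff_pos, rev(diff_pos)),
    "3" = {
      p <- diff_pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  classify <- function(order) {
    cur <- a
    sd <- nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") return(NULL)  # pathway through a stop codon
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, classify)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # all pathways blocked by stops: fall back to including them
    classify_all <- function(order) {
      cur <- a
      sd <- nd <- 0
      for (pos in order) {
        nxt <- cur
        nxt[pos] <- b[pos]
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(perms, classify_all)
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

ng86_diff_tables <- function() {
  if (!is.null(.dnds_cache$diff)) return(.dnds_cache$diff)
  codons <- sense_codons()
  k <- length(codons)
  sd <- nd <- matrix(0, k, k, dimnames = list(codons, codons))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      v <- ng86_pair_diff(codons[i], codons[j])
      sd[i, j] <- v[["sd"]]
      nd[i, j] <- v[["nd"]]
    }
  }
  .dnds_cache$diff <- list(sd = sd, nd = nd)
  .dnds_cache$diff
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log1p(-4 * p / 3))
}

#' Pairwise dN/dS for a gap-free codon alignment
#'
#' Site counts are averaged across the two sequences; difference counts are
#' pathway-averaged per codon column; proportions are Jukes-Cantor corrected
#' (`d = -3/4 ln(1 - 4p/3)`). `omega = dN/dS` is flagged `"undefined"` when
#' `dS = 0` or either proportion reaches the correction's 3/4 ceiling.
#'
#' @param alignment A `codon_alignment` (see [codon_align()]), or a list with
#'   elements `seq_a` and `seq_b`: equal-length, gap-free, in-frame
#'   nucleotide strings.
#' @return A one-row tibble: `id_a`, `id_b`, `n_codons`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `filter_flag`.
#' @export
pairwise_dnds <- function(alignment) {
  ca <- split_codons(as_dna(alignment$seq_a))
  cb <- split_codons(as_dna(alignment$seq_b))
  if (length(ca) != length(cb)) stop("sequences differ in codon length", call. = FALSE)
  if (length(ca) < 1L) stop("empty alignment", call. = FALSE)
  stab <- ng86_site_table()
  dtab <- ng86_diff_tables()
  S <- (sum(stab[ca, "s"]) + sum(stab[cb, "s"])) / 2
  N <- (sum(stab[ca, "n"]) + sum(stab[cb, "n"])) / 2
  idx <- cbind(match(ca, rownames(dtab$sd)), match(cb, colnames(dtab$sd)))
  Sd <- sum(dtab$sd[idx])
  Nd <- sum(dtab$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  flag <- if (is.na(dS) || is.na(dN) || dS == 0) "undefined" else "pass"
  tibble::tibble(
    id_a = alignment$id_a %||% NA_character_,
    id_b = alignment$id_b %||% NA_character_,
    n_codons = length(ca),
    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
    filter_flag = flag
  )
}

#' Flag ortholog pairs outside the usable dS range
#'
#' Pairs with `dS < ds_min` are flagged `"ds_too_low"` (tiny dS inflates
#' omega); pairs with `dS > ds_max` are flagged `"ds_too_high"` (putative
#' misidentified orthologs). Downstream group comparisons use pass-flagged
#' pairs only.
#'
#' @param results Tibble of [pairwise_dnds()] rows.
#' @param ds_min,ds_max dS bounds (defaults 0.001 and 0.10).
#' @return The tibble with `filter_flag` updated.
#' @export
filter_ds_range <- function(results, ds_min = 0.001, ds_max = 0.10) {
  out <- tibble::as_tibble(results)
  pass <- out$filter_flag == "pass"
  out$filter_flag[pass & out$dS < ds_min] <- "ds_too_low"
  out$filter_flag[pass & out$dS > ds_max] <- "ds_too_high"
  out
}

#' Compare substitution-rate distributions of toxins and nontoxins
#'
#' For each metric (dS, dN, omega), runs a two-sample Wilcoxon test of toxins
#' versus nontoxins over pass-flagged pairs, computes the 95th-percentile
#' threshold on the nontoxin distribution (linear interpolation; optionally
#' pooled), and lists the toxins above it. Toxins with omega > 1 are reported
#' as positive-selection candidates.
#'
#' @param results [pairwise_dnds()] tibble with a `class` column (toxin
#'   family label or `"nontoxin"`).
#' @param probs Threshold percentile (default 0.95).
#' @param threshold_on `"nontoxins"` (default) or `"pooled"`.
#' @param paired Use the signed-rank (paired) Wilcoxon variant; default FALSE
#'   (rank-sum).
#' @return An object of class `dnds_comparison` with per-metric test results,
#'   thresholds and flagged toxin ids.
#' @export
compare_groups <- function(results, probs = 0.95,
                           threshold_on = c("nontoxins", "pooled"),
                           paired = FALSE) {
  threshold_on <- match.arg(threshold_on)
  if (!"class" %in% names(results)) stop("results need a `class` column", call. = FALSE)
  res <- results[results$filter_flag == "pass", , drop = FALSE]
  res$group <- ifelse(res$class == "nontoxin", "nontoxin", "toxin")
  if (length(unique(res$group)) < 2L ||
      any(table(res$group) < 2L)) {
    stop("need at least 2 pass-flagged pairs per class", call. = FALSE)
  }
  metrics <- c(dS = "dS", dN = "dN", omega = "omega")
  per_metric <- lapply(metrics, function(m) {
    tox <- res[[m]][res$group == "toxin"]
    ntx <- res[[m]][res$group == "nontoxin"]
    tox_id <- res$id_a[res$group == "toxin"]
    keep <- !is.na(tox)
    tox <- tox[keep]; tox_id <- tox_id[keep]
    ntx <- ntx[!is.na(ntx)]
    wt <- stats::wilcox.test(tox, ntx, paired = paired, exact = FALSE)
    thr_base <- if (threshold_on == "nontoxins") ntx else c(tox, ntx)
    thr <- pctl(thr_base, probs)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         threshold = thr, flagged = tox_id[tox > thr])
  })
  tox_pass <- res[res$group == "toxin", , drop = FALSE]
  structure(
    list(metrics = per_metric,
         positive_selection = tox_pass$id_a[!is.na(tox_pass$omega) & tox_pass$omega > 1],
         n_toxin = sum(res$group == "toxin"),
         n_nontoxin = sum(res$group == "nontoxin"),
         probs = probs, threshold_on = threshold_on, paired = paired),
    class = "dnds_comparison"
  )
}

#' @export
print.dnds_comparison <- function(x, ...) {
  cat(sprintf("Toxin vs nontoxin substitution rates (%d toxins, %d nontoxins)\n",
              x$n_toxin, x$n_nontoxin))
  for (m in names(x$metrics)) {
    pm <- x$metrics[[m]]
    cat(sprintf("  %-5s W = %.1f, p = %.3g, %.0fth pctl = %.4f, %d toxin(s) above\n",
                m, pm$statistic, pm$p_value, 100 * x$probs, pm$threshold,
                length(pm$flagged)))
  }
  cat(sprintf("  omega > 1 (positive-selection candidates): %d\n",
              length(x$positive_selection)))
  invisible(x)
}
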