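# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_SENSE <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

# NG86 sites by direct mutation enumeration: per position, synonymous
# fraction among non-stop single-nucleotide changes; n = 3 - s.
oracle_sites <- function(codon) {
  aa <- ORACLE_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in ORACLE_BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ORACLE_CODE[[mut]] == "*") next
      valid <- valid + 1
      if (ORACLE_CODE[[mut]] == aa) syn <- syn + 1
    }
    s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# All permutations of a small vector (recursive, base R).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged differences by exhaustive enumeration.
oracle_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  walk <- function(order, skip_stops) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (skip_stops && ORACLE_CODE[[nxt]] == "*") return(NULL)
      if (ORACLE_CODE[[cur]] == ORACLE_CODE[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null), lapply(oracle_perms(pos), walk, skip_stops = TRUE))
  if (length(paths) == 0L) {
    paths <- lapply(oracle_perms(pos), walk, skip_stops = FALSE)
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Doubly trimmed, precision-weighted mean of M-values computed from the
# definition via explicit sorting (sample x vs reference ref).
oracle_tmm_factor <- function(x, ref, trim_m = 0.30, trim_a = 0.05) {
  N <- sum(x); Nr <- sum(ref)
  keep <- x > 0 & ref > 0
  x <- x[keep]; ref <- ref[keep]
  M <- log2((x / N) / (ref / Nr))
  A <- 0.5 * log2((x / N) * (ref / Nr))
  qwin <- function(v, p) {
    s <- sort(v)
    lo <- s[1 + (length(s) - 1) * p]          # interpolated quantile bounds
    hi <- s[1 + (length(s) - 1) * (1 - p)]
    h_lo <- 1 + (length(s) - 1) * p
    lo <- s[floor(h_lo)] + (h_lo - floor(h_lo)) * (s[ceiling(h_lo)] - s[floor(h_lo)])
    h_hi <- 1 + (length(s) - 1) * (1 - p)
    hi <- s[floor(h_hi)] + (h_hi - floor(h_hi)) * (s[ceiling(h_hi)] - s[floor(h_hi)])
    v >= lo & v <= hi
  }
  sel <- qwin(M, trim_m) & qwin(A, trim_a)
  if (!any(sel)) sel <- qwin(M, trim_m)
  prec <- 1 / ((N - x) / (N * x) + (Nr - ref) / (Nr * ref))
  2^(stats::weighted.mean(M[sel], prec[sel]))
}

# Seed-site scan by per-window pattern check.
oracle_seed_scan <- function(mirna, utr) {
  to_dna <- function(s) chartr("Uu", "Tt", toupper(s))
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  m <- to_dna(mirna); u <- to_dna(utr)
  core <- rc(substr(m, 2, 7))
  m8c <- chartr("ACGT", "TGCA", substr(m, 8, 8))
  hits <- list()
  if (nchar(u) < 6) return(hits)
  for (i in 1:(nchar(u) - 5)) {
    if (substr(u, i, i + 5) != core) next
    m8 <- i > 1 && substr(u, i - 1, i - 1) == m8c
    a1 <- i + 6 <= nchar(u) && substr(u, i + 6, i + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else if (a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1L]] <- list(p0 = i - 1L, type = type)
  }
  hits
}

# Adjusted Rand index between two labelings over planted-module members.
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small random composition matrix for property tests.
random_expr <- function(n = 40, k = 3, zero_frac = 0) {
  m <- matrix(rlnorm(n * k, 2, 1), n, k)
  if (zero_frac > 0) m[sample(length(m), ceiling(zero_frac * length(m)))] <- 0
  out <- tibble::tibble(transcript_id = sprintf("t%03d", seq_len(n)))
  for (j in seq_len(k)) out[[paste0("s", j)]] <- m[, j]
  out
}
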