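# Forward simulation of an ortholog pair at controlled dS and omega.
# Substitutions are proposed as uniform random single-nucleotide changes and
# filtered through an acceptance scheme that targets the requested dN/dS
# ratio; realized event counts are recorded so downstream recovery tests can
# compare estimates against realized, not nominal, values.

#' Generate a random in-frame coding sequence
#'
#' Starts with ATG and draws the remaining codons uniformly from the sense
#' codons (no internal stops).
#'
#' @param n_codons Number of codons (>= 2).
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2)
  body <- sample(setdiff(sense_codons(), "ATG"), n_codons - 1L, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

#' Evolve a descendant ortholog pair from an ancestral CDS
#'
#' Each branch proposes uniform random single-nucleotide changes; proposals
#' creating a stop codon are rejected outright, nonsynonymous proposals are
#' accepted with probability `min(1, target_omega)` and synonymous proposals
#' with probability `min(1, 1 / max(target_omega, 1))`. A branch stops once
#' its target number of accepted synonymous events is reached, chosen so the
#' expected pairwise dS matches `target_ds` (after inverting the Jukes-Cantor
#' correction). With `target_ds = 0` both descendants equal the ancestor.
#'
#' @param ancestral_cds In-frame CDS (no internal stops, >= 30 codons).
#' @param target_ds Target pairwise synonymous rate (substitutions/site).
#'   Refused when the implied synonymous proportion reaches 0.74, where the
#'   downstream distance correction degenerates.
#' @param target_omega Target dN/dS ratio (>= 0).
#' @return A list: `cds_a`, `cds_b`, `counts` (tibble `branch`, `syn`,
#'   `nonsyn` of accepted events), `realized_omega` (from accepted counts and
#'   ancestral site counts; `NA` when no synonymous events).
#' @export
evolve_ortholog_pair <- function(ancestral_cds, target_ds, target_omega) {
  ancestral_cds <- as_dna(ancestral_cds)
  codons <- split_codons(ancestral_cds)
  if (length(codons) < 30L) stop("ancestor must have >= 30 codons", call. = FALSE)
  if (any(is_stop_codon(codons))) stop("ancestor contains a stop codon", call. = FALSE)
  if (target_ds < 0) stop("target_ds must be >= 0", call. = FALSE)
  if (target_omega < 0) stop("target_omega must be >= 0", call. = FALSE)
  p_s <- 0.75 * (1 - exp(-4 * target_ds / 3))
  if (p_s >= 0.74) {
    stop("target_ds implies a synonymous proportion >= 0.74; ",
         "the Jukes-Cantor correction is undefined there", call. = FALSE)
  }
  sites <- ng86_site_table()
  S_anc <- sum(sites[codons, "s"])
  N_anc <- sum(sites[codons, "n"])
  counts <- tibble::tibble(branch = c("a", "b"), syn = 0L, nonsyn = 0L)
  if (target_ds == 0) {
    return(list(cds_a = ancestral_cds, cds_b = ancestral_cds,
                counts = counts, realized_omega = NA_real_))
  }
  k_total <- p_s * S_anc
  k_a <- stats::rbinom(1L, size = round(k_total), prob = 0.5)
  k_b <- round(k_total) - k_a
  acc_syn <- min(1, 1 / max(target_omega, 1))
  acc_non <- min(1, target_omega)
  run_branch <- function(codons, k_syn) {
    gc <- genetic_code()
    bases <- c("A", "C", "G", "T")
    syn <- 0L; non <- 0L
    guard <- 0L
    max_prop <- 5000L * max(1L, k_syn)
    while (syn < k_syn && guard < max_prop) {
      guard <- guard + 1L
      ci <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      old <- codons[ci]
      chars <- strsplit(old, "", fixed = TRUE)[[1]]
      alt <- sample(setdiff(bases, chars[pos]), 1L)
      chars[pos] <- alt
      new <- paste(chars, collapse = "")
      if (gc[[new]] == "*") next
      is_syn <- gc[[new]] == gc[[old]]
      p_acc <- if (is_syn) acc_syn else acc_non
      if (p_acc < 1 && stats::runif(1L) > p_acc) next
      codons[ci] <- new
      if (is_syn) syn <- syn + 1L else non <- non + 1L
    }
    list(codons = codons, syn = syn, nonsyn = non)
  }
  br_a <- run_branch(codons, k_a)
  br_b <- run_branch(codons, k_b)
  counts$syn <- c(br_a$syn, br_b$syn)
  counts$nonsyn <- c(br_a$nonsyn, br_b$nonsyn)
  syn_tot <- sum(counts$syn)
  non_tot <- sum(counts$nonsyn)
  realized_omega <- if (syn_tot > 0) {
    (non_tot / N_anc) / (syn_tot / S_anc)
  } else NA_real_
  list(cds_a = paste(br_a$codons, collapse = ""),
       cds_b = paste(br_b$codons, collapse = ""),
       counts = counts, realized_omega = realized_omega)
}
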