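# Reciprocal-best-hit orthology and protein-guided codon alignment.
# Alignments are global protein alignments (BLOSUM62, affine gaps
# open 10 / extend 1) computed with Biostrings.

translate_cds <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(as_dna(s))))
  }, character(1), USE.NAMES = FALSE)
}

assert_cds <- function(cds) {
  stopifnot(is.data.frame(cds),
            all(c("transcript_id", "seq") %in% names(cds)))
  bad_len <- nchar(cds$seq) %% 3L != 0L
  if (any(bad_len)) {
    stop("CDS length not divisible by 3: ",
         paste(cds$transcript_id[bad_len], collapse = ", "), call. = FALSE)
  }
  prot <- translate_cds(cds$seq)
  if (any(grepl("\\*", sub("\\*$", "", prot)))) {
    stop("internal stop codon in CDS", call. = FALSE)
  }
  invisible(prot)
}

protein_score_matrix <- function(prot_a, prot_b) {
  pa <- Biostrings::AAStringSet(prot_a)
  sc <- matrix(NA_real_, length(prot_a), length(prot_b))
  for (j in seq_along(prot_b)) {
    sc[, j] <- Biostrings::pairwiseAlignment(
      pattern = pa, subject = Biostrings::AAString(prot_b[j]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  }
  sc
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Scores global protein alignments between all cross-species sequence pairs
#' within the same class partition (toxins against toxins, nontoxins against
#' nontoxins) and keeps a pair iff each member is the other's best hit. Ties
#' are broken by lexicographic transcript id. Sequences left unpaired are
#' reported as putative duplication/loss candidates.
#'
#' @param cds_a,cds_b Data frames with `transcript_id`, `seq` (CDS) and
#'   optionally `class` (`"nontoxin"` or a toxin family label).
#' @return An object of class `rbh_result`: `pairs` (tibble `id_a`, `id_b`,
#'   `class`, `score`) and `unpaired` (tibble `transcript_id`, `species`).
#' @export
rbh_pairs <- function(cds_a, cds_b) {
  if (nrow(cds_a) == 0L || nrow(cds_b) == 0L) {
    stop("empty sequence set", call. = FALSE)
  }
  prot_a <- assert_cds(cds_a)
  prot_b <- assert_cds(cds_b)
  part_a <- if ("class" %in% names(cds_a)) {
    ifelse(cds_a$class == "nontoxin", "nontoxin", "toxin")
  } else rep("all", nrow(cds_a))
  part_b <- if ("class" %in% names(cds_b)) {
    ifelse(cds_b$class == "nontoxin", "nontoxin", "toxin")
  } else rep("all", nrow(cds_b))
  pairs <- list()
  for (part in intersect(unique(part_a), unique(part_b))) {
    ia <- which(part_a == part)
    ib <- which(part_b == part)
    # lexicographic order makes which.max's first-match tie-break lexicographic
    ia <- ia[order(cds_a$transcript_id[ia])]
    ib <- ib[order(cds_b$transcript_id[ib])]
    sc <- protein_score_matrix(prot_a[ia], prot_b[ib])
    best_b_for_a <- apply(sc, 1, which.max)
    best_a_for_b <- apply(sc, 2, which.max)
    mutual <- which(best_a_for_b[best_b_for_a] == seq_along(ia))
    if (length(mutual)) {
      pairs[[part]] <- tibble::tibble(
        id_a = cds_a$transcript_id[ia[mutual]],
        id_b = cds_b$transcript_id[ib[best_b_for_a[mutual]]],
        class = if ("class" %in% names(cds_a)) cds_a$class[ia[mutual]] else NA_character_,
        score = sc[cbind(mutual, best_b_for_a[mutual])]
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  unpaired <- dplyr::bind_rows(
    tibble::tibble(transcript_id = setdiff(cds_a$transcript_id, pairs$id_a),
                   species = "a"),
    tibble::tibble(transcript_id = setdiff(cds_b$transcript_id, pairs$id_b),
                   species = "b")
  )
  structure(list(pairs = pairs, unpaired = unpaired), class = "rbh_result")
}

#' @export
print.rbh_result <- function(x, ...) {
  cat(sprintf("RBH orthology: %d pairs, %d unpaired (duplication/loss candidates)\n",
              nrow(x$pairs), nrow(x$unpaired)))
  invisible(x)
}

#' Protein-guided codon alignment of an ortholog pair
#'
#' Globally aligns the translated proteins, back-threads the alignment onto
#' the nucleotide sequences, and drops every codon column with a gap in
#' either protein. The result is a gap-free, in-frame paired codon alignment
#' ready for [pairwise_dnds()].
#'
#' @param cds_a,cds_b In-frame CDS nucleotide strings (no internal stops).
#' @param id_a,id_b Optional sequence ids carried into the result.
#' @return An object of class `codon_alignment`: `seq_a`, `seq_b` (equal
#'   length, gap-free), `id_a`, `id_b`, `n_codons`, `n_dropped`.
#' @export
codon_align <- function(cds_a, cds_b, id_a = NULL, id_b = NULL) {
  cds_a <- as_dna(cds_a); cds_b <- as_dna(cds_b)
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(prot_a), subject = Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1]]
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  ia <- ib <- 0L
  keep_a <- keep_b <- character(0)
  dropped <- 0L
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"
    gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) {
      dropped <- dropped + 1L
    } else {
      keep_a <- c(keep_a, cod_a[ia])
      keep_b <- c(keep_b, cod_b[ib])
    }
  }
  structure(
    list(seq_a = paste(keep_a, collapse = ""),
         seq_b = paste(keep_b, collapse = ""),
         id_a = id_a, id_b = id_b,
         n_codons = length(keep_a), n_dropped = dropped),
    class = "codon_alignment"
  )
}

#' Pairwise dN/dS for a table of ortholog pairs
#'
#' Convenience wrapper: codon-aligns each RBH pair and runs
#' [pairwise_dnds()], returning one row per pair with the class label
#' attached.
#'
#' @param pairs Tibble with `id_a`, `id_b` and optionally `class` (e.g. from
#'   [rbh_pairs()]`$pairs`).
#' @param cds_a,cds_b Per-species CDS tables (`transcript_id`, `seq`).
#' @param align Run the protein-guided codon alignment per pair (default).
#'   Set `FALSE` when the sequences are already codon-aligned and gap-free
#'   (e.g. indel-free simulated orthologs) to skip the alignment step.
#' @return A tibble of [pairwise_dnds()] rows with a `class` column.
#' @export
dnds_for_pairs <- function(pairs, cds_a, cds_b, align = TRUE) {
  seq_a <- cds_a$seq[match(pairs$id_a, cds_a$transcript_id)]
  seq_b <- cds_b$seq[match(pairs$id_b, cds_b$transcript_id)]
  if (anyNA(seq_a) || anyNA(seq_b)) stop("pair id missing from CDS table", call. = FALSE)
  rows <- purrr::pmap(
    list(seq_a, seq_b, pairs$id_a, pairs$id_b),
    function(sa, sb, ia, ib) {
      aln <- if (align) codon_align(sa, sb, ia, ib) else
        list(seq_a = sa, seq_b = sb, id_a = ia, id_b = ib)
      pairwise_dnds(aln)
    }
  )
  out <- dplyr::bind_rows(rows)
  if ("class" %in% names(pairs)) out$class <- pairs$class
  out
}
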