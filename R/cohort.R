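# Synthetic two-species, four-individual venom-gland cohort with recorded
# ground truth for every downstream stage: log-normal ortholog expression
# with planted interspecific fold-changes, codon sequences diverged at
# planted dS/omega, pooled spectral counts with planted translation-
# efficiency offsets, and small-RNA counts with planted 3'UTR seed sites.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the study design the package targets: 2 species x 2
#' individuals, ~50 toxin orthologs in named venom families plus 3500
#' nontoxin orthologs, log-normal expression with a toxin abundance bonus,
#' within-species log-scale noise of 0.3, toxin/nontoxin omega means of
#' 0.67 and 0.2, and dS in the 0.01-0.09 range.
#'
#' @param species Two species labels.
#' @param n_individuals Individuals per species.
#' @param n_nontoxin_orthologs Number of nontoxin ortholog pairs.
#' @param toxin_family_plan Named integer vector: isoforms per toxin family.
#' @param expr_log_mean,expr_log_sd Log-normal baseline expression
#'   parameters (natural-log scale).
#' @param toxin_log_bonus Added to toxin baselines (venom glands are toxin
#'   dominated).
#' @param individual_noise_sd Within-species log-scale noise.
#' @param family_profile Optional named list (per species) of named toxin
#'   family percentage targets; toxin baselines are rescaled per species so
#'   expected family sums match.
#' @param planted_expression_shifts Tibble `transcript_id` (ortholog id),
#'   `species`, `fold_change` (> 0).
#' @param dnds_plan Tibble `transcript_id`, `target_ds`, `target_omega`
#'   overriding the class defaults for named orthologs.
#' @param toxin_omega_mean,nontoxin_omega_mean Mean omega drawn for
#'   unplanted toxins/nontoxins (gamma, shape 2).
#' @param ds_range Range of pairwise dS drawn for unplanted orthologs.
#' @param cds_codon_range,utr_len_range Length ranges for generated CDS
#'   (codons) and 3'UTRs (nt).
#' @param proteome_depth Total spectral counts per proteome sample.
#' @param te_offsets Tibble `transcript_id`, `species` (NA = both),
#'   `offset` (clr units) of planted translation-efficiency offsets.
#' @param te_noise_sd Clr-scale noise between transcript and protein
#'   composition.
#' @param mirna_plan Tibble `mirna_id`, `seq` (RNA, NA = random 22-mer),
#'   `count_a`, `count_b`, `targets` (list column of toxin ortholog ids),
#'   `site_type` (one of 8mer, 7mer-m8, 7mer-A1, 6mer).
#' @param n_background_mirnas Extra untargeted miRNAs with similar counts in
#'   both species.
#' @param n_tf Number of nontoxins flagged as transcription factors.
#' @param with_sequences,with_proteome,with_mirna Stage toggles; switching a
#'   stage off skips generating its data (for expression-only studies).
#' @param rng_seed Integer seed; the cohort is byte-identical for a fixed
#'   seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(species = c("A", "B"),
                          n_individuals = 2,
                          n_nontoxin_orthologs = 3500,
                          toxin_family_plan = c(
                            CTL = 12, SVMP = 12, SVSP = 8, BPP = 4,
                            `VEGF-F` = 3, PLA2 = 2, LAO = 3, CRISP = 3,
                            NGF = 1, HYAL = 2),
                          expr_log_mean = 3, expr_log_sd = 1.5,
                          toxin_log_bonus = 4,
                          individual_noise_sd = 0.3,
                          family_profile = NULL,
                          planted_expression_shifts = NULL,
                          dnds_plan = NULL,
                          toxin_omega_mean = 0.67,
                          nontoxin_omega_mean = 0.2,
                          ds_range = c(0.01, 0.09),
                          cds_codon_range = c(120, 400),
                          utr_len_range = c(150, 400),
                          proteome_depth = 2e5,
                          te_offsets = NULL,
                          te_noise_sd = 0.5,
                          mirna_plan = NULL,
                          n_background_mirnas = 20,
                          n_tf = 5,
                          with_sequences = TRUE,
                          with_proteome = TRUE,
                          with_mirna = TRUE,
                          rng_seed = 1L) {
  stopifnot(length(species) == 2L, n_individuals >= 1,
            n_nontoxin_orthologs >= 0, all(toxin_family_plan >= 0),
            individual_noise_sd >= 0, expr_log_sd >= 0,
            proteome_depth >= 0, te_noise_sd >= 0)
  empty_shifts <- tibble::tibble(transcript_id = character(),
                                 species = character(), fold_change = numeric())
  empty_dnds <- tibble::tibble(transcript_id = character(),
                               target_ds = numeric(), target_omega = numeric())
  empty_te <- tibble::tibble(transcript_id = character(),
                             species = character(), offset = numeric())
  empty_mirna <- tibble::tibble(mirna_id = character(), seq = character(),
                                count_a = numeric(), count_b = numeric(),
                                targets = list(), site_type = character())
  cfg <- list(
    species = species, n_individuals = n_individuals,
    n_nontoxin_orthologs = n_nontoxin_orthologs,
    toxin_family_plan = toxin_family_plan,
    expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
    toxin_log_bonus = toxin_log_bonus,
    individual_noise_sd = individual_noise_sd,
    family_profile = family_profile,
    planted_expression_shifts = tibble::as_tibble(planted_expression_shifts %||% empty_shifts),
    dnds_plan = tibble::as_tibble(dnds_plan %||% empty_dnds),
    toxin_omega_mean = toxin_omega_mean,
    nontoxin_omega_mean = nontoxin_omega_mean,
    ds_range = ds_range, cds_codon_range = cds_codon_range,
    utr_len_range = utr_len_range,
    proteome_depth = proteome_depth,
    te_offsets = tibble::as_tibble(te_offsets %||% empty_te),
    te_noise_sd = te_noise_sd,
    mirna_plan = tibble::as_tibble(mirna_plan %||% empty_mirna),
    n_background_mirnas = n_background_mirnas,
    n_tf = n_tf,
    with_sequences = with_sequences,
    with_proteome = with_proteome,
    with_mirna = with_mirna,
    rng_seed = as.integer(rng_seed)
  )
  if (any(cfg$planted_expression_shifts$fold_change <= 0)) {
    stop("fold-changes must be > 0", call. = FALSE)
  }
  if (any(cfg$dnds_plan$target_ds < 0)) {
    stop("target dS must be >= 0", call. = FALSE)
  }
  bad_site <- setdiff(cfg$mirna_plan$site_type,
                      c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  if (length(bad_site)) {
    stop("unknown site type: ", paste(bad_site, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Uniform draw from an integer range; safe for degenerate ranges (sample()
# would otherwise treat a scalar as 1:x).
sample_range <- function(range, n) {
  v <- seq(range[1], range[2])
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

cohort_ortholog_ids <- function(config) {
  fam <- config$toxin_family_plan
  fam <- fam[fam > 0]
  toxin_ids <- unlist(lapply(names(fam), function(f) {
    paste0(f, "-", seq_len(fam[[f]]))
  }), use.names = FALSE)
  toxin_class <- rep(names(fam), fam)
  ntx_ids <- if (config$n_nontoxin_orthologs > 0) {
    sprintf("NTX%05d", seq_len(config$n_nontoxin_orthologs))
  } else character(0)
  tibble::tibble(
    ortholog_id = c(toxin_ids, ntx_ids),
    class = c(toxin_class, rep("nontoxin", length(ntx_ids)))
  )
}

check_planted_ids <- function(ids, declared, what) {
  missing <- setdiff(ids, declared)
  if (length(missing)) {
    stop("configuration error: ", what, " references undeclared transcript(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Generate a synthetic two-species cohort
#'
#' Deterministic for a fixed `rng_seed`. The returned `truth` element records
#' every planted effect with its realized value: realized log2 expression
#' ratios of planted shifts, realized synonymous/nonsynonymous event counts
#' and realized omega per ortholog, planted translation-efficiency offsets,
#' and planted miRNA target sites.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort` with elements `samples`,
#'   `expression` (per-species TPM tibbles), `ortholog_expression` (ortholog
#'   by all-sample TPM), `cds`, `utr3`, `ortholog_truth`, `proteome`,
#'   `mirna`, `tf_ids`, and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_rng(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  orth <- cohort_ortholog_ids(config)
  n <- nrow(orth)
  declared <- orth$ortholog_id
  check_planted_ids(config$planted_expression_shifts$transcript_id, declared,
                    "planted_expression_shifts")
  check_planted_ids(config$dnds_plan$transcript_id, declared, "dnds_plan")
  check_planted_ids(config$te_offsets$transcript_id, declared, "te_offsets")
  check_planted_ids(unlist(config$mirna_plan$targets), declared, "mirna_plan")
  sp <- config$species
  samples <- tidyr::expand_grid(species = sp,
                                individual = seq_len(config$n_individuals))
  samples$sample_id <- paste0(samples$species, "_", samples$individual)
  samples <- tibble::as_tibble(samples[c("sample_id", "species", "individual")])

  ## --- expression ---------------------------------------------------------
  base <- stats::rnorm(n, config$expr_log_mean, config$expr_log_sd)
  base[orth$class != "nontoxin"] <- base[orth$class != "nontoxin"] +
    config$toxin_log_bonus
  # per-species log-mean matrix
  mu <- matrix(base, nrow = n, ncol = 2, dimnames = list(orth$ortholog_id, sp))
  if (!is.null(config$family_profile)) {
    for (s in names(config$family_profile)) {
      tgt <- config$family_profile[[s]]
      tox <- orth$class != "nontoxin"
      tot <- sum(exp(mu[tox, s]))
      for (f in names(tgt)) {
        memb <- orth$class == f
        if (!any(memb)) next
        cur <- sum(exp(mu[memb, s]))
        mu[memb, s] <- mu[memb, s] + log(tgt[[f]] / 100 * tot / cur)
      }
      rest <- tox & !(orth$class %in% names(tgt))
      rest_share <- (100 - sum(unlist(tgt))) / 100
      if (any(rest) && rest_share > 0) {
        cur <- sum(exp(mu[rest, s]))
        mu[rest, s] <- mu[rest, s] + log(rest_share * tot / cur)
      }
    }
  }
  shifts <- config$planted_expression_shifts
  for (i in seq_len(nrow(shifts))) {
    mu[shifts$transcript_id[i], shifts$species[i]] <-
      mu[shifts$transcript_id[i], shifts$species[i]] + log(shifts$fold_change[i])
  }
  # log expression before compositional closure; realized planted effects
  # are recorded on this scale (clr and TPM analyses are closure-invariant)
  lraw <- matrix(0, n, nrow(samples),
                 dimnames = list(orth$ortholog_id, samples$sample_id))
  tpm <- lraw
  for (j in seq_len(nrow(samples))) {
    lraw[, j] <- mu[, samples$species[j]] +
      stats::rnorm(n, 0, config$individual_noise_sd)
    v <- exp(lraw[, j])
    tpm[, j] <- v / sum(v) * 1e6
  }
  ortholog_expression <- dplyr::bind_cols(
    orth, tibble::as_tibble(tpm))
  names(ortholog_expression)[1] <- "ortholog_id"

  sp_means <- vapply(sp, function(s) {
    rowMeans(lraw[, samples$sample_id[samples$species == s], drop = FALSE])
  }, numeric(n))
  realized_shifts <- shifts
  if (nrow(shifts)) {
    other <- vapply(shifts$species, function(s) setdiff(sp, s)[1], character(1))
    realized_shifts$realized_log2_ratio <-
      (sp_means[cbind(shifts$transcript_id, shifts$species)] -
         sp_means[cbind(shifts$transcript_id, other)]) / log(2)
  } else {
    realized_shifts$realized_log2_ratio <- numeric(0)
  }

  per_species_expr <- lapply(sp, function(s) {
    cols <- samples$sample_id[samples$species == s]
    out <- tibble::tibble(
      transcript_id = paste0(orth$ortholog_id, "_", s),
      class = orth$class)
    for (cc in cols) out[[cc]] <- tpm[, cc]
    out
  })
  names(per_species_expr) <- sp

  ortholog_truth <- tibble::tibble(
    ortholog_id = orth$ortholog_id,
    id_a = paste0(orth$ortholog_id, "_", sp[1]),
    id_b = paste0(orth$ortholog_id, "_", sp[2]),
    class = orth$class
  )

  ## --- sequences ----------------------------------------------------------
  cds <- utr3 <- NULL
  dnds_truth <- NULL
  if (config$with_sequences) {
    n_cod <- sample_range(config$cds_codon_range, n)
    ds <- stats::runif(n, config$ds_range[1], config$ds_range[2])
    om_mean <- ifelse(orth$class == "nontoxin",
                      config$nontoxin_omega_mean, config$toxin_omega_mean)
    om <- stats::rgamma(n, shape = 2, scale = om_mean / 2)
    plan <- config$dnds_plan
    if (nrow(plan)) {
      idx <- match(plan$transcript_id, orth$ortholog_id)
      ds[idx] <- plan$target_ds
      om[idx] <- plan$target_omega
    }
    seq_a <- seq_b <- character(n)
    syn_events <- nonsyn_events <- integer(n)
    realized_omega <- numeric(n)
    for (i in seq_len(n)) {
      anc <- random_cds(n_cod[i])
      ev <- evolve_ortholog_pair(anc, ds[i], om[i])
      seq_a[i] <- ev$cds_a
      seq_b[i] <- ev$cds_b
      syn_events[i] <- sum(ev$counts$syn)
      nonsyn_events[i] <- sum(ev$counts$nonsyn)
      realized_omega[i] <- ev$realized_omega
    }
    cds <- lapply(seq_along(sp), function(k) {
      tibble::tibble(
        transcript_id = paste0(orth$ortholog_id, "_", sp[k]),
        species = sp[k], class = orth$class,
        seq = if (k == 1) seq_a else seq_b)
    })
    names(cds) <- sp
    dnds_truth <- tibble::tibble(
      ortholog_id = orth$ortholog_id, class = orth$class,
      target_ds = ds, target_omega = om,
      syn_events = syn_events, nonsyn_events = nonsyn_events,
      realized_omega = realized_omega)

    utr_len <- sample_range(config$utr_len_range, n)
    utr_seq <- vapply(utr_len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(utr_seq) <- orth$ortholog_id
    utr3 <- list()
  }

  ## --- miRNAs and planted 3'UTR sites -------------------------------------
  mirna <- NULL
  mirna_sites_truth <- NULL
  if (config$with_mirna) {
    plan <- config$mirna_plan
    plan$seq <- vapply(seq_len(nrow(plan)), function(i) {
      if (!is.na(plan$seq[i])) as_rna(plan$seq[i])
      else paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
    }, character(1))
    bg_n <- config$n_background_mirnas
    bg <- tibble::tibble(
      mirna_id = sprintf("mir-bg-%02d", seq_len(bg_n)),
      seq = vapply(seq_len(bg_n), function(i) {
        paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
      }, character(1)),
      count_a = stats::rpois(bg_n, 200),
      count_b = stats::rpois(bg_n, 200),
      targets = replicate(bg_n, character(0), simplify = FALSE),
      site_type = NA_character_)
    all_mirna <- dplyr::bind_rows(plan, bg)
    matures <- tibble::tibble(mirna_id = all_mirna$mirna_id,
                              family = sub("-[0-9]+$", "", all_mirna$mirna_id),
                              seq = all_mirna$seq)
    counts <- tibble::tibble(mirna_id = all_mirna$mirna_id)
    counts[[paste0(sp[1], "_sRNA")]] <- all_mirna$count_a
    counts[[paste0(sp[2], "_sRNA")]] <- all_mirna$count_b
    reads <- lapply(seq_along(sp), function(k) {
      cnt <- if (k == 1) all_mirna$count_a else all_mirna$count_b
      tibble::tibble(seq = as_dna(all_mirna$seq), count = cnt)[cnt > 0, ]
    })
    names(reads) <- sp
    mirna <- list(matures = matures, counts = counts, reads = reads)

    if (config$with_sequences && nrow(plan)) {
      # scrub chance seed-core matches of planted miRNAs from non-target
      # UTRs so the planted target map is the complete ground truth
      for (i in seq_len(nrow(plan))) {
        core <- seed_site_sequence(plan$seq[i], "6mer")
        non_targets <- setdiff(orth$ortholog_id, plan$targets[[i]])
        for (tid in non_targets) {
          for (pass in 1:5) {
            hit <- regexpr(core, utr_seq[[tid]], fixed = TRUE)
            if (hit < 0) break
            pos <- hit + 2L
            old <- substr(utr_seq[[tid]], pos, pos)
            substr(utr_seq[[tid]], pos, pos) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          }
        }
      }
      site_rows <- list()
      for (i in seq_len(nrow(plan))) {
        site <- seed_site_sequence(plan$seq[i], plan$site_type[i])
        for (tid in plan$targets[[i]]) {
          L <- nchar(utr_seq[[tid]])
          w <- nchar(site)
          pos <- sample.int(L - w + 1L, 1L)
          substr(utr_seq[[tid]], pos, pos + w - 1L) <- site
          site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
            mirna_id = plan$mirna_id[i], ortholog_id = tid,
            site_type = plan$site_type[i], start = pos - 1L, end = pos + w - 1L)
        }
      }
      mirna_sites_truth <- dplyr::bind_rows(site_rows)
    }
  }
  if (config$with_sequences) {
    utr3 <- lapply(sp, function(s) {
      tibble::tibble(transcript_id = paste0(orth$ortholog_id, "_", s),
                     species = s, class = orth$class,
                     seq = unname(utr_seq))
    })
    names(utr3) <- sp
  }

  ## --- proteome ------------------------------------------------------------
  proteome <- NULL
  te_truth <- NULL
  if (config$with_proteome) {
    tox <- orth$class != "nontoxin" & orth$class != "BPP"
    proteome <- lapply(sp, function(s) {
      expr_s <- tibble::tibble(
        transcript_id = paste0(orth$ortholog_id[tox], "_", s),
        class = orth$class[tox])
      expr_s$pooled <- exp(sp_means[tox, s])
      off <- config$te_offsets
      off <- off[is.na(off$species) | off$species == s, , drop = FALSE]
      off_vec <- stats::rnorm(sum(tox), 0, config$te_noise_sd)
      names(off_vec) <- orth$ortholog_id[tox]
      if (nrow(off)) {
        off_vec[off$transcript_id] <- off_vec[off$transcript_id] + off$offset
      }
      counts <- simulate_proteome(
        expr_s[c("transcript_id", "class", "pooled")],
        te_offsets = tibble::tibble(
          transcript_id = expr_s$transcript_id, offset = unname(off_vec)),
        depth = config$proteome_depth)
      counts$species <- s
      counts
    })
    names(proteome) <- sp
    te_truth <- config$te_offsets
  }

  tf_ids <- if (config$n_tf > 0 && config$n_nontoxin_orthologs >= config$n_tf) {
    sample(orth$ortholog_id[orth$class == "nontoxin"], config$n_tf)
  } else character(0)

  structure(
    list(
      config = config, samples = samples,
      expression = per_species_expr,
      ortholog_expression = ortholog_expression,
      cds = cds, utr3 = utr3,
      ortholog_truth = ortholog_truth,
      proteome = proteome, mirna = mirna, tf_ids = tf_ids,
      truth = list(
        planted_shifts = realized_shifts,
        dnds = dnds_truth,
        te_offsets = te_truth,
        mirna_sites = mirna_sites_truth
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %s vs %s, %d individuals each, %d orthologs (%d toxin, %d nontoxin)\n",
    x$config$species[1], x$config$species[2], x$config$n_individuals,
    nrow(x$ortholog_truth),
    sum(x$ortholog_truth$class != "nontoxin"),
    sum(x$ortholog_truth$class == "nontoxin")))
  invisible(x)
}

# 5'->3' UTR site sequence matched by a miRNA (RNA) for a canonical type.
seed_site_sequence <- function(mirna_seq, site_type) {
  m <- as_dna(mirna_seq)
  core6 <- dna_revcomp(substr(m, 2, 7))
  m8 <- dna_complement(substr(m, 8, 8))
  switch(site_type,
         "6mer" = core6,
         "7mer-m8" = paste0(m8, core6),
         "7mer-A1" = paste0(core6, "A"),
         "8mer" = paste0(m8, core6, "A"),
         stop("unknown site type: ", site_type, call. = FALSE))
}

#' Simulate a spectral-count proteome from toxin expression
#'
#' Per sample, spectral counts are drawn multinomially from the composition
#' proportional to `exp(clr(TPM) + offset)`. BPP transcripts are excluded
#' (their precursor is processed into peptides and escapes shotgun
#' proteomics); nontoxin rows are not allowed.
#'
#' @param expression Toxin expression table (`transcript_id`, optional
#'   `class`, sample columns).
#' @param te_offsets Tibble `transcript_id`, `offset` (clr units); missing
#'   transcripts default to 0.
#' @param depth Total spectral counts per sample (>= 0).
#' @return A tibble `transcript_id`, `class` (if present) and one
#'   spectral-count column per input sample.
#' @export
simulate_proteome <- function(expression, te_offsets = NULL, depth = 1e5) {
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  expr <- tibble::as_tibble(expression)
  if ("class" %in% names(expr)) {
    if (any(expr$class == "nontoxin")) {
      stop("proteome simulation expects toxin transcripts only", call. = FALSE)
    }
    if (any(expr$class == "BPP")) {
      expr <- expr[expr$class != "BPP", , drop = FALSE]
    }
  }
  smp <- expr_sample_cols(expr)
  off <- rep(0, nrow(expr))
  if (!is.null(te_offsets) && nrow(te_offsets)) {
    m <- match(expr$transcript_id, te_offsets$transcript_id)
    off[!is.na(m)] <- te_offsets$offset[m[!is.na(m)]]
  }
  out <- expr[intersect(names(expr), expr_meta_cols)]
  for (cc in smp) {
    w <- exp(clr_vec(expr[[cc]]) + off)
    out[[cc]] <- if (depth == 0) {
      rep(0L, nrow(expr))
    } else {
      as.integer(stats::rmultinom(1, size = depth, prob = w / sum(w)))
    }
  }
  tibble::as_tibble(out)
}

#' Simulate a planted coexpression design
#'
#' Generates `n_modules` sample profiles and, per module, members that track
#' their profile with independent noise, plus uncorrelated noise transcripts.
#' Used to validate module detection on more samples than the 4-sample
#' cohort provides.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Members per module.
#' @param n_noise Number of uncorrelated transcripts.
#' @param n_samples Number of samples.
#' @param within_sd Member noise around the module profile (profiles have
#'   unit spread; 0.1 gives within-module correlations near 0.99).
#' @param toxins_per_module Leading members of each module labeled as toxins
#'   (families recycled from common venom families).
#' @param tfs_per_module Members per module flagged as transcription
#'   factors.
#' @return A list: `expr` (expression tibble on a log2-like scale) and
#'   `truth` (tibble `transcript_id`, `module`, `class`, `is_tf`).
#' @export
simulate_coexpression <- function(n_modules = 5, module_size = 10,
                                  n_noise = 50, n_samples = 12,
                                  within_sd = 0.1, toxins_per_module = 2,
                                  tfs_per_module = 0) {
  fams <- c("PLA2", "SVMP", "SVSP", "CTL", "LAO")
  rows <- list()
  vals <- list()
  for (m in seq_len(n_modules)) {
    profile <- stats::rnorm(n_samples)
    profile <- (profile - mean(profile)) / stats::sd(profile)
    for (k in seq_len(module_size)) {
      id <- sprintf("M%d_t%02d", m, k)
      cls <- if (k <= toxins_per_module) fams[(m - 1) %% length(fams) + 1] else "nontoxin"
      is_tf <- cls == "nontoxin" && k > toxins_per_module &&
        (k - toxins_per_module) <= tfs_per_module
      rows[[id]] <- tibble::tibble(transcript_id = id, module = m,
                                   class = cls, is_tf = is_tf)
      vals[[id]] <- 5 + profile + stats::rnorm(n_samples, 0, within_sd)
    }
  }
  for (k in seq_len(n_noise)) {
    id <- sprintf("noise_t%03d", k)
    rows[[id]] <- tibble::tibble(transcript_id = id, module = 0L,
                                 class = "nontoxin", is_tf = FALSE)
    vals[[id]] <- 5 + stats::rnorm(n_samples)
  }
  truth <- dplyr::bind_rows(rows)
  mat <- do.call(rbind, vals)
  colnames(mat) <- sprintf("s%02d", seq_len(n_samples))
  expr <- dplyr::bind_cols(
    tibble::tibble(transcript_id = truth$transcript_id, class = truth$class),
    tibble::as_tibble(mat))
  list(expr = expr, truth = truth)
}
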