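# Pipeline orchestration: run every stage in dependency order on a synthetic
# cohort (or user-supplied tables), collect a machine-readable comparative
# report, and write intermediate TSVs.

#' Per-species toxin family composition
#'
#' Family percentages of total toxin expression, computed per sample and
#' averaged over the individuals of each species.
#'
#' @param expr Expression table (TPM) with `class` labels.
#' @param samples Optional tibble `sample_id`, `species`; defaults to one
#'   species covering all samples.
#' @return A tibble `species`, `family`, `pct` (percentages sum to 100 per
#'   species).
#' @export
compose_family_summary <- function(expr, samples = NULL) {
  assert_expression(expr)
  if (!"class" %in% names(expr)) stop("expression needs a `class` column", call. = FALSE)
  tox <- expr[expr$class != "nontoxin", , drop = FALSE]
  if (nrow(tox) == 0L) stop("no toxin transcripts", call. = FALSE)
  smp <- expr_sample_cols(tox)
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = smp, species = "all")
  }
  long <- tox |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample_id",
                        values_to = "tpm") |>
    dplyr::inner_join(samples, by = "sample_id")
  long |>
    dplyr::group_by(.data$species, .data$sample_id) |>
    dplyr::mutate(sample_total = sum(.data$tpm)) |>
    dplyr::group_by(.data$species, .data$sample_id, .data$class) |>
    dplyr::summarise(pct = 100 * sum(.data$tpm) / .data$sample_total[1],
                     .groups = "drop") |>
    dplyr::group_by(.data$species, family = .data$class) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop") |>
    dplyr::arrange(.data$species, dplyr::desc(.data$pct))
}

#' Run the full comparative pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order: family composition,
#' intraspecific and interspecific expression outliers, ortholog dN/dS with
#' dS-range filtering and the toxin-vs-nontoxin comparison, coexpression
#' modules, miRNA quantification/targets/integration, and proteome
#' correlation with translation efficiency. Stages whose inputs were not
#' generated (e.g. `with_proteome = FALSE`) are skipped and omitted from the
#' report. Fully deterministic given the cohort seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param params Optional list of per-stage parameter blocks: `outliers`
#'   (`threshold`, `probs`), `dnds` (`ds_min`, `ds_max`, `rbh_toxins` — a
#'   logical: verify toxin orthology by reciprocal best hit), `modules`
#'   (arguments of [coexpression_config()]; the variance filter is capped at
#'   200 transcripts unless overridden), `mirna` (`max_mismatch`,
#'   `expr_ratio_min`, `te_quantile`).
#' @param out_dir Optional directory for intermediate TSVs and
#'   `report.json`.
#' @return The comparative report: a list of tibbles and summaries (class
#'   `venom_report`).
#' @export
run_pipeline <- function(cohort, params = list(), out_dir = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sp <- cohort$config$species
  p_out <- params$outliers %||% list()
  p_dnds <- params$dnds %||% list()
  p_mod <- params$modules %||% list()
  p_mir <- params$mirna %||% list()
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("venomdelta")),
    rng_seed = cohort$config$rng_seed,
    species = sp,
    params = params
  ))

  ## composition + outliers
  fam <- lapply(sp, function(s) {
    out <- compose_family_summary(cohort$expression[[s]])
    out$species <- s
    out[c("species", "family", "pct")]
  })
  report$family_composition <- dplyr::bind_rows(fam)

  report$intraspecific_outliers <- dplyr::bind_rows(lapply(sp, function(s) {
    calls <- intraspecific_divergence(
      cohort$expression[[s]],
      threshold = p_out$threshold %||% 1,
      probs = p_out$probs %||% 0.99)
    calls$species <- s
    tibble::as_tibble(calls)
  }))

  inter <- interspecific_divergence(
    cohort$expression[[sp[1]]], cohort$expression[[sp[2]]],
    cohort$ortholog_truth,
    threshold = p_out$threshold %||% 1, probs = p_out$probs %||% 0.99)
  report$interspecific_outliers <- tibble::as_tibble(inter)
  report$ortholog_count <- nrow(cohort$ortholog_truth)

  ## sequence evolution
  if (!is.null(cohort$cds)) {
    if (isTRUE(p_dnds$rbh_toxins %||% TRUE)) {
      tox_a <- cohort$cds[[sp[1]]]
      tox_a <- tox_a[tox_a$class != "nontoxin", ]
      tox_b <- cohort$cds[[sp[2]]]
      tox_b <- tox_b[tox_b$class != "nontoxin", ]
      rbh <- rbh_pairs(tox_a, tox_b)
      truth_tox <- cohort$ortholog_truth[cohort$ortholog_truth$class != "nontoxin", ]
      report$rbh_toxin_recovery <- mean(
        paste(truth_tox$id_a, truth_tox$id_b) %in%
          paste(rbh$pairs$id_a, rbh$pairs$id_b))
    }
    dnds <- dnds_for_pairs(cohort$ortholog_truth,
                           cohort$cds[[sp[1]]], cohort$cds[[sp[2]]],
                           align = FALSE)
    dnds <- filter_ds_range(dnds,
                            ds_min = p_dnds$ds_min %||% 0.001,
                            ds_max = p_dnds$ds_max %||% 0.10)
    report$dnds <- dnds
    cmp <- compare_groups(dnds)
    report$dnds_comparison <- list(
      omega_p = cmp$metrics$omega$p_value,
      dS_p = cmp$metrics$dS$p_value,
      dN_p = cmp$metrics$dN$p_value,
      mean_toxin_omega = mean(dnds$omega[dnds$class != "nontoxin" &
                                           dnds$filter_flag == "pass"], na.rm = TRUE),
      positive_selection = cmp$positive_selection)
  }

  ## coexpression modules on the 4-sample ortholog matrix; the variance
  ## filter is capped so the network stays at CEMiTool-like size
  if (is.null(p_mod$variance_filter_keep)) p_mod$variance_filter_keep <- 200
  mod_cfg <- do.call(coexpression_config, p_mod)
  filt <- tryCatch({
    expr4 <- cohort$ortholog_expression
    names(expr4)[1] <- "transcript_id"
    suppressWarnings(vst_filter(expr4, mod_cfg))
  }, error = function(e) NULL)
  if (!is.null(filt) && nrow(filt) >= 2L) {
    mods <- suppressWarnings(detect_modules(filt, mod_cfg))
    report$modules <- annotate_modules(
      mods, cohort$ortholog_expression[c("ortholog_id", "class")] |>
        stats::setNames(c("transcript_id", "class")),
      tf_list = cohort$tf_ids)
    report$module_assignment <- mods$assignment
  }

  ## miRNA chain
  if (!is.null(cohort$mirna)) {
    quant <- lapply(sp, function(s) {
      collapse_and_quantify(cohort$mirna$reads[[s]], cohort$mirna$matures,
                            max_mismatch = p_mir$max_mismatch %||% 1)
    })
    names(quant) <- sp
    counts <- tibble::tibble(mirna_id = cohort$mirna$matures$mirna_id)
    for (s in sp) counts[[s]] <- quant[[s]]$counts$count
    norm <- mirna_normalize(counts)
    report$mirna_counts <- norm
    if (!is.null(cohort$utr3) && !is.null(cohort$proteome)) {
      eps <- 0.5
      cands <- lapply(sp, function(s) {
        other <- setdiff(sp, s)
        ratio <- tibble::tibble(
          mirna_id = norm$mirna_id,
          log2_ratio = log2((norm[[s]] + eps) / (norm[[other]] + eps)))
        utr_s <- cohort$utr3[[s]]
        utr_s <- utr_s[utr_s$class != "nontoxin" & utr_s$class != "BPP", ]
        sites <- scan_targets(cohort$mirna$matures, utr_s)
        te <- pipeline_te(cohort, s)
        out <- integrate_candidates(ratio, sites, te,
                                    expr_ratio_min = p_mir$expr_ratio_min %||% 1,
                                    te_quantile = p_mir$te_quantile %||% 0.25)
        if (nrow(out)) out$species <- s
        out
      })
      report$mirna_candidates <- dplyr::bind_rows(cands)
    }
  }

  ## proteome integration
  if (!is.null(cohort$proteome)) {
    report$omics_correlation <- dplyr::bind_rows(lapply(sp, function(s) {
      cc <- correlate_omics(pipeline_transcript_clr(cohort, s),
                            pipeline_protein_clr(cohort, s))
      tibble::tibble(species = s, rho = cc$rho, r = cc$r,
                     slope = cc$slope, intercept = cc$intercept, n = cc$n)
    }))
    report$translation_efficiency <- dplyr::bind_rows(lapply(sp, function(s) {
      pipeline_te(cohort, s)
    }))
  }

  class(report) <- c("venom_report", "list")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Species-level toxin transcript clr (BPP excluded, matching the proteome).
pipeline_transcript_clr <- function(cohort, s) {
  expr <- cohort$expression[[s]]
  tox <- expr[expr$class != "nontoxin" & expr$class != "BPP", , drop = FALSE]
  smp <- expr_sample_cols(tox)
  pooled <- tibble::tibble(transcript_id = tox$transcript_id,
                           pooled = rowMeans(log(as.matrix(tox[smp]))))
  pooled$pooled <- exp(pooled$pooled)
  sample_clr(pooled, "pooled")
}

pipeline_protein_clr <- function(cohort, s) {
  prot <- cohort$proteome[[s]]
  keep <- prot[c("transcript_id", "pooled")]
  sample_clr(keep, "pooled")
}

pipeline_te <- function(cohort, s, te_quantile = 0.25) {
  translation_efficiency(pipeline_transcript_clr(cohort, s),
                         pipeline_protein_clr(cohort, s),
                         species = s, te_quantile = te_quantile)
}

#' @export
print.venom_report <- function(x, ...) {
  cat("Comparative venom-gland report\n")
  cat(sprintf("  orthologs: %s\n", x$ortholog_count %||% "n/a"))
  if (!is.null(x$interspecific_outliers)) {
    cat(sprintf("  interspecific toxin outliers: %d of %d\n",
                sum(x$interspecific_outliers$is_outlier),
                nrow(x$interspecific_outliers)))
  }
  if (!is.null(x$dnds_comparison)) {
    cat(sprintf("  mean toxin omega: %.2f (omega>1: %d; toxin-vs-nontoxin p = %.2g)\n",
                x$dnds_comparison$mean_toxin_omega,
                length(x$dnds_comparison$positive_selection),
                x$dnds_comparison$omega_p))
  }
  if (!is.null(x$omics_correlation)) {
    for (i in seq_len(nrow(x$omics_correlation))) {
      cat(sprintf("  %s transcriptome-proteome: rho = %.2f, R = %.2f\n",
                  x$omics_correlation$species[i], x$omics_correlation$rho[i],
                  x$omics_correlation$r[i]))
    }
  }
  invisible(x)
}

#' Write a comparative report to disk
#'
#' Tabular elements become TSVs; the whole report is serialized to
#' `report.json` (deterministic: no timestamps).
#'
#' @param report A `venom_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    el <- report[[nm]]
    if (is.data.frame(el)) {
      utils::write.table(el, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the pipeline from a YAML configuration
#'
#' The configuration holds a `simulate` block (arguments of
#' [cohort_config()]), optional per-stage parameter blocks, and an optional
#' `out_dir`. A `seed` entry (or the `seed` argument) overrides the
#' simulate block's `rng_seed`.
#'
#' @param config Path to a YAML file, or an equivalent list.
#' @param seed Optional integer overriding the configured seed.
#' @param out_dir Optional output directory overriding the configured one.
#' @return The `venom_report`.
#' @export
run_pipeline_config <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sim <- config$simulate
  if (is.null(sim)) stop("config needs a `simulate` block", call. = FALSE)
  sim$rng_seed <- seed %||% config$seed %||% sim$rng_seed %||% 1L
  cohort <- generate_cohort(parse_simulate_block(sim))
  run_pipeline(cohort, params = config$params %||% list(),
               out_dir = out_dir %||% config$out_dir)
}

#' Build a cohort configuration from a parsed YAML `simulate` block
#'
#' Converts the nested-list representation of plan tables
#' (`planted_expression_shifts`, `te_offsets`, `dnds_plan`, `mirna_plan`,
#' `toxin_family_plan`) into the tibbles [cohort_config()] expects.
#'
#' @param sim A named list, typically `yaml::read_yaml(path)$simulate`.
#' @return A validated `cohort_config`.
#' @export
parse_simulate_block <- function(sim) {
  if (!is.null(sim$planted_expression_shifts)) {
    sim$planted_expression_shifts <-
      dplyr::bind_rows(lapply(sim$planted_expression_shifts, tibble::as_tibble))
  }
  if (!is.null(sim$te_offsets)) {
    sim$te_offsets <- dplyr::bind_rows(lapply(sim$te_offsets, function(x) {
      x$species <- x$species %||% NA_character_
      tibble::as_tibble(x)
    }))
  }
  if (!is.null(sim$dnds_plan)) {
    sim$dnds_plan <- dplyr::bind_rows(lapply(sim$dnds_plan, tibble::as_tibble))
  }
  if (!is.null(sim$mirna_plan)) {
    sim$mirna_plan <- dplyr::bind_rows(lapply(sim$mirna_plan, function(x) {
      tibble::tibble(mirna_id = x$mirna_id, seq = x$seq %||% NA_character_,
                     count_a = x$count_a, count_b = x$count_b,
                     targets = list(unlist(x$targets)),
                     site_type = x$site_type)
    }))
  }
  if (!is.null(sim$toxin_family_plan)) {
    sim$toxin_family_plan <- unlist(sim$toxin_family_plan)
  }
  do.call(cohort_config, sim)
}

#' Write cohort inputs to disk in standard formats
#'
#' CDS, 3'UTR and mature-miRNA FASTA, expression/proteome/annotation TSVs,
#' and the ground-truth record as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta <- function(df, path) {
    if (is.null(df)) return(invisible(NULL))
    x <- Biostrings::DNAStringSet(stats::setNames(as_dna(df$seq), df$transcript_id))
    Biostrings::writeXStringSet(x, path)
  }
  for (s in names(cohort$expression)) {
    utils::write.table(cohort$expression[[s]],
                       file.path(dir, paste0("expression_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cohort$cds)) {
      write_fasta(cohort$cds[[s]], file.path(dir, paste0("cds_", s, ".fasta")))
      write_fasta(cohort$utr3[[s]], file.path(dir, paste0("utr3_", s, ".fasta")))
    }
    if (!is.null(cohort$proteome)) {
      utils::write.table(cohort$proteome[[s]],
                         file.path(dir, paste0("proteome_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(cohort$ortholog_truth, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$mirna)) {
    m <- cohort$mirna$matures
    x <- Biostrings::RNAStringSet(stats::setNames(as_rna(m$seq), m$mirna_id))
    Biostrings::writeXStringSet(x, file.path(dir, "mirna_matures.fasta"))
    utils::write.table(cohort$mirna$counts, file.path(dir, "mirna_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
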