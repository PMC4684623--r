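# End-to-end pipeline driver: simulate/load -> spectrum -> motif ->
# associate -> methylation -> report.

#' Pipeline configuration
#'
#' Either supply a [sim_config()] via `sim` (the cohort is generated) or a
#' directory of cohort TSVs via `input_dir` (see [read_cohort_dir()]).
#'
#' @param sim optional `sim_config` for synthetic input.
#' @param input_dir optional directory of cohort tables.
#' @param outdir optional output directory for intermediate TSVs.
#' @param genes genes to analyse (association + clinical stages).
#' @param group_by grouping for spectrum pooling and TCW tests.
#' @param stratify_by stratification for the burden-expression association.
#' @param burden burden definition: `"ct_ga"` or `"total"`.
#' @param background optional `background_composition` (or TSV path) for
#'   the motif stage; defaults to the simulator's configured background
#'   when simulating, otherwise the motif stage is skipped.
#' @param tss optional TSS annotation data.frame for the methylation stage.
#' @param seed root seed (overrides `sim$seed` when simulating).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, outdir = NULL,
                            genes = c("APOBEC3B", "APOBEC3C"),
                            group_by = "cn_state",
                            stratify_by = "er_status",
                            burden = "ct_ga",
                            background = NULL, tss = NULL, seed = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("supply either 'sim' (a sim_config) or 'input_dir'")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    stop("'sim' must be a sim_config")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  if (is.character(background) && length(background) == 1L) {
    background <- read_background_tsv(background)
  }
  structure(
    list(sim = sim, input_dir = input_dir, outdir = outdir, genes = genes,
         group_by = group_by, stratify_by = stratify_by, burden = burden,
         background = background, tss = tss, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation or loading, cohort summary,
#' mutation-spectrum counting, motif excess-rate and TCW enrichment tests
#' grouped by `group_by`, stratified burden-expression association and
#' clinical contrasts per gene, and promoter methylation comparison between
#' the first two methylation tracks. Stages whose inputs are absent are
#' skipped with a notice. Deterministic given configuration and seed
#' (timestamps live only in `provenance$generated_at`).
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` with sections `cohort_summary`,
#'   `spectrum`, `motif_excess`, `tcw_tests`, `associations`, `clinical`,
#'   `methylation`, `skipped` and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config")
  }
  skipped <- character()
  notice <- function(stage, why) {
    message("stage '", stage, "' skipped: ", why)
    c(skipped, sprintf("%s: %s", stage, why))
  }

  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    cohort <- simulate_cohort(sim_cfg)
    metadata <- cohort$metadata
    expression <- cohort$expression
    variants <- cohort$variants
    methylation <- cohort$methylation
    background <- config$background %||% background_composition(
      c_freqs = sim_cfg$background_trinuc_freqs$C,
      t_freqs = sim_cfg$background_trinuc_freqs$T,
      provenance = "simulator configuration"
    )
    tss <- config$tss %||% synthetic_tss(sim_cfg)
  } else {
    tables <- read_cohort_dir(config$input_dir)
    metadata <- tables$metadata
    expression <- tables$expression
    variants <- tables$variants
    methylation <- tables$methylation
    background <- config$background
    bg_path <- file.path(config$input_dir, "background.tsv")
    if (is.null(background) && file.exists(bg_path)) {
      background <- read_background_tsv(bg_path)
    }
    tss <- config$tss
    tss_path <- file.path(config$input_dir, "tss.bed")
    if (is.null(tss) && file.exists(tss_path)) {
      tss <- read_tss_bed(tss_path)
    }
  }

  out <- list(cohort_summary = NULL, spectrum = NULL, motif_excess = NULL,
              tcw_tests = NULL, associations = NULL, clinical = NULL,
              methylation = NULL)

  out$cohort_summary <- summarize_cohort(metadata)

  ann <- NULL
  if (!is.null(variants) && nrow(variants)) {
    exome_meta <- metadata[metadata$tissue == "tumor" &
                             !is.na(metadata$has_exome) & metadata$has_exome, ,
                           drop = FALSE]
    if (!nrow(exome_meta)) exome_meta <- metadata
    out$spectrum <- count_spectrum(variants, exome_meta,
                                   group_by = config$group_by)
    ann <- annotate_variants(variants)
    grp <- exome_meta[[config$group_by]][match(ann$sample,
                                               exome_meta$sample_id)]
    grp <- as.character(grp)
    levels <- setdiff(sort(unique(grp[!is.na(grp)])), "unknown")
    if (!is.null(background)) {
      out$motif_excess <- lapply(stats::setNames(levels, levels), function(l) {
        motif_excess_table(ann[!is.na(grp) & grp == l, , drop = FALSE],
                           background)
      })
    } else {
      skipped <- notice("motif_excess", "no background composition available")
    }
    if (length(levels) >= 2) {
      pairs <- utils::combn(levels, 2)
      tests <- list()
      for (k in seq_len(ncol(pairs))) {
        la <- pairs[1, k]
        lb <- pairs[2, k]
        va <- ann[!is.na(grp) & grp == la, , drop = FALSE]
        vb <- ann[!is.na(grp) & grp == lb, , drop = FALSE]
        key <- paste0(la, "_vs_", lb)
        tests[[paste0(key, "_allC")]] <-
          tcw_enrichment_test(va, vb, labels = c(la, lb))
        tests[[paste0(key, "_CG_CT")]] <-
          tcw_enrichment_test(va, vb, classes = c("C>G", "C>T"),
                              labels = c(la, lb))
      }
      out$tcw_tests <- tests
    } else {
      skipped <- notice("tcw_tests", "fewer than 2 groups with variants")
    }
  } else {
    skipped <- notice("spectrum", "no variant table")
    skipped <- notice("motif_excess", "no variant table")
    skipped <- notice("tcw_tests", "no variant table")
  }

  if (!is.null(expression) && !is.null(out$spectrum)) {
    genes <- intersect(config$genes, rownames(expression))
    out$associations <- lapply(stats::setNames(genes, genes), function(g) {
      associate_burden_expression(out$spectrum, expression, g, metadata,
                                  stratify_by = config$stratify_by,
                                  burden = config$burden)
    })
    out$clinical <- lapply(stats::setNames(genes, genes), function(g) {
      tryCatch(clinical_association(expression, g, metadata),
               error = function(e) {
                 message("clinical association for ", g, " skipped: ",
                         conditionMessage(e))
                 NULL
               })
    })
  } else {
    skipped <- notice("associations", "expression and spectrum both required")
  }

  if (!is.null(methylation) && length(methylation) >= 2 && !is.null(tss)) {
    cts <- names(methylation)[1:2]
    profiles <- lapply(methylation[cts], function(sites) {
      sites <- filter_sites(sites)
      profs <- lapply(seq_len(nrow(tss)), function(i) {
        bin_methylation_profile(sites, tss$tss[i],
                                strand = tss$strand[i],
                                chrom = tss$chrom[i], gene = tss$gene[i])
      })
      stats::setNames(profs, tss$gene)
    })
    out$methylation <- list(
      cell_types = cts,
      comparison = compare_promoter_methylation(profiles[[1]], profiles[[2]])
    )
  } else {
    skipped <- notice("methylation", "needs two methylation tracks and a TSS set")
  }

  prov_config <- config
  prov_config$outdir <- NULL
  report <- structure(
    list(
      cohort_summary = out$cohort_summary, spectrum = out$spectrum,
      motif_excess = out$motif_excess, tcw_tests = out$tcw_tests,
      associations = out$associations, clinical = out$clinical,
      methylation = out$methylation, skipped = skipped,
      provenance = list(
        package_version = as.character(utils::packageVersion("apobecsig")),
        config_hash = hash_object(prov_config),
        seed = config$seed,
        generated_at = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "run_report"
  )

  if (!is.null(config$outdir)) {
    write_report_tables(report, config$outdir)
  }
  report
}

write_report_tables <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$cohort_summary$table, file.path(outdir, "cohort_summary.tsv"))
  if (!is.null(report$spectrum)) {
    write_tsv(as.data.frame(report$spectrum),
              file.path(outdir, "spectrum_per_sample.tsv"))
    if (!is.null(report$spectrum$group_freqs)) {
      write_tsv(report$spectrum$group_freqs,
                file.path(outdir, "spectrum_group_freqs.tsv"))
    }
  }
  if (!is.null(report$motif_excess)) {
    tab <- do.call(rbind, lapply(names(report$motif_excess), function(g) {
      cbind(group = g, report$motif_excess[[g]])
    }))
    write_tsv(tab, file.path(outdir, "motif_excess.tsv"))
  }
  if (!is.null(report$tcw_tests)) {
    tab <- do.call(rbind, lapply(names(report$tcw_tests), function(k) {
      t <- report$tcw_tests[[k]]
      data.frame(contrast = k, classes = paste(t$classes, collapse = ","),
                 odds_ratio = t$odds_ratio, p = t$p,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(tab, file.path(outdir, "tcw_tests.tsv"))
  }
  if (!is.null(report$associations)) {
    tab <- do.call(rbind, lapply(names(report$associations), function(g) {
      cbind(gene = g, report$associations[[g]]$summary)
    }))
    write_tsv(tab, file.path(outdir, "associations.tsv"))
  }
  if (!is.null(report$methylation)) {
    write_tsv(report$methylation$comparison,
              file.path(outdir, "methylation_comparison.tsv"))
  }
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("apobecsig run report\n")
  cat(sprintf("  seed %d, config %s, package %s\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8),
              x$provenance$package_version))
  sections <- c("cohort_summary", "spectrum", "motif_excess", "tcw_tests",
                "associations", "clinical", "methylation")
  for (s in sections) {
    cat(sprintf("  %-16s %s\n", s, if (is.null(x[[s]])) "skipped" else "ok"))
  }
  if (length(x$skipped)) {
    cat("  notices:\n")
    for (s in x$skipped) cat("   -", s, "\n")
  }
  invisible(x)
}
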