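# Stratified burden-expression association and clinical contrasts.

#' Associate mutation burden with gene expression, per stratum
#'
#' For each stratum (e.g. ER status or copy-number state) computes the
#' Spearman correlation between a gene's expression and the per-sample
#' mutation burden - either the C>T/G>A count or the total SNV count - plus
#' a tricube local-linear smooth and an ordinary least-squares line for
#' plotting. Rank-based inference makes the result invariant to whether
#' expression enters as RPKM or log2 RPKM.
#'
#' @param spectrum a `spectrum_table` from [count_spectrum()].
#' @param expr gene x sample RPKM matrix.
#' @param gene gene identifier.
#' @param metadata sample metadata.
#' @param stratify_by metadata column defining strata (default
#'   `"er_status"`).
#' @param burden `"ct_ga"` (C>T/G>A count, default) or `"total"`.
#' @param span smoothing span for [loess_smooth()].
#' @param min_n strata smaller than this are skipped with a warning.
#' @param include_unknown include the `"unknown"` stratum level.
#' @return object of class `burden_association`: list with `summary`
#'   (stratum, n, rho, p), `curves` (per-stratum smooth) and `lines`
#'   (per-stratum least-squares intercept/slope).
#' @export
associate_burden_expression <- function(spectrum, expr, gene, metadata,
                                        stratify_by = "er_status",
                                        burden = c("ct_ga", "total"),
                                        span = 0.75, min_n = 3L,
                                        include_unknown = FALSE) {
  burden <- match.arg(burden)
  if (!inherits(spectrum, "spectrum_table")) {
    stop("spectrum must be a spectrum_table")
  }
  if (!gene %in% rownames(expr)) stop("gene not found in expression matrix: ", gene)
  metadata <- validate_metadata(metadata)
  check_columns(metadata, stratify_by, "metadata")
  burden_vec <- if (burden == "ct_ga") {
    spectrum$counts[, "C>T"]
  } else {
    spectrum$totals
  }
  common <- Reduce(intersect, list(names(burden_vec), colnames(expr),
                                   metadata$sample_id))
  if (!length(common)) stop("no samples shared by spectrum, expression and metadata")
  strata <- as.character(metadata[[stratify_by]][match(common, metadata$sample_id)])
  levels <- unique(strata)
  if (!include_unknown) levels <- setdiff(levels, "unknown")
  summary_rows <- list()
  curves <- list()
  lines <- list()
  for (s in sort(levels)) {
    ids <- common[strata == s]
    if (length(ids) < min_n) {
      warning(sprintf("stratum %s has fewer than %d samples; skipped", s, min_n))
      next
    }
    x <- expr[gene, ids]
    y <- burden_vec[ids]
    sr <- spearman_rho(x, y)
    fit <- stats::lm(y ~ x)
    curves[[s]] <- loess_smooth(x, y, span = span)
    lines[[s]] <- stats::coef(fit)
    summary_rows[[s]] <- data.frame(
      stratum = s, n = length(ids), rho = sr$rho, p = sr$p,
      stringsAsFactors = FALSE
    )
  }
  if (!length(summary_rows)) stop("no stratum had enough samples")
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  structure(
    list(summary = summary, curves = curves, lines = lines,
         gene = gene, burden = burden, stratify_by = stratify_by),
    class = "burden_association"
  )
}

#' @export
print.burden_association <- function(x, ...) {
  cat(sprintf("Burden (%s) vs %s expression, stratified by %s\n",
              if (x$burden == "ct_ga") "C>T/G>A" else "total SNVs",
              x$gene, x$stratify_by))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Clinical associations of gene expression
#'
#' Vital-status contrast (alive vs deceased, two-sided rank-sum with group
#' medians) and the stage trend as a Spearman correlation of expression with
#' ordinal tumor stage (I = 1 ... IV = 4). Samples with level `"unknown"`
#' are excluded from the respective analysis; normals are excluded
#' throughout.
#'
#' @param expr gene x sample RPKM matrix.
#' @param gene gene identifier.
#' @param metadata sample metadata with `vital_status` and `stage`.
#' @return list with components `vital` (n and median per group, p) and
#'   `stage` (n, rho, p).
#' @export
clinical_association <- function(expr, gene, metadata) {
  if (!gene %in% rownames(expr)) stop("gene not found in expression matrix: ", gene)
  metadata <- validate_metadata(metadata)
  meta <- metadata[metadata$tissue == "tumor", , drop = FALSE]
  common <- intersect(meta$sample_id, colnames(expr))
  meta <- meta[match(common, meta$sample_id), ]
  vals <- expr[gene, common]

  vital <- meta$vital_status
  alive <- vals[vital == "alive"]
  dead <- vals[vital == "deceased"]
  if (!length(alive) || !length(dead)) {
    stop("need both alive and deceased samples for the vital-status contrast")
  }
  vt <- wilcoxon_rank_sum(alive, dead)

  stage_num <- match(meta$stage, c("I", "II", "III", "IV"))
  keep <- !is.na(stage_num)
  if (length(unique(stage_num[keep])) < 2L) {
    stop("need at least 2 distinct stages for the stage trend")
  }
  st <- spearman_rho(stage_num[keep], vals[keep])

  list(
    gene = gene,
    vital = list(
      n_alive = length(alive), n_deceased = length(dead),
      median_alive = stats::median(alive), median_deceased = stats::median(dead),
      p = vt$p
    ),
    stage = list(n = sum(keep), rho = st$rho, p = st$p)
  )
}
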