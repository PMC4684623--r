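# Gene expression quantification (RPKM) and cohort summaries.

ER_LEVELS <- c("positive", "negative", "unknown")
CN_LEVELS <- c("0", "1", "2", "unknown")
TISSUE_LEVELS <- c("tumor", "normal")
VITAL_LEVELS <- c("alive", "deceased", "unknown")
STAGE_LEVELS <- c("I", "II", "III", "IV", "unknown")

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = reads * 1e9 / (transcript_length_bp * total_mapped_reads)`.
#' Read counts are assumed to be pre-filtered (e.g. mapping quality >= 30);
#' alignment and filtering happen upstream of this package.
#'
#' @param read_count non-negative read count(s) for the feature.
#' @param transcript_length feature length in bp (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return numeric RPKM, zero iff `read_count` is zero.
#' @examples
#' compute_rpkm(1000, 1000, 1e6)  # 1000
#' compute_rpkm(50, 2500, 2e7)   # 1
#' @export
compute_rpkm <- function(read_count, transcript_length, total_mapped) {
  if (any(!is.finite(transcript_length)) || any(transcript_length <= 0)) {
    stop("transcript_length must be positive")
  }
  if (any(!is.finite(total_mapped)) || any(total_mapped <= 0)) {
    stop("total_mapped must be positive")
  }
  if (any(read_count < 0, na.rm = TRUE)) stop("read_count must be non-negative")
  read_count * 1e9 / (transcript_length * total_mapped)
}

#' RPKM matrix from a count matrix and feature lengths
#'
#' @param counts gene x sample matrix of read counts (rownames = genes).
#' @param lengths named vector of feature lengths in bp covering all genes.
#' @param total_mapped per-sample library sizes; defaults to the column sums
#'   of `counts`.
#' @return gene x sample numeric matrix of RPKM values.
#' @export
rpkm_matrix <- function(counts, lengths, total_mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("lengths missing for gene(s): ", paste(missing, collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (length(total_mapped) != ncol(counts)) {
    stop("total_mapped must have one entry per sample")
  }
  out <- counts * 1e9 / outer(len, total_mapped)
  dimnames(out) <- dimnames(counts)
  out
}

#' Log2 display layer for an RPKM matrix
#'
#' `log2(RPKM + pseudocount)`. Display/plotting only: all inference in the
#' package is rank-based and invariant to this transform.
#'
#' @param rpkm RPKM matrix or vector.
#' @param pseudocount added before the log (default 1).
#' @export
log2_rpkm <- function(rpkm, pseudocount = 1) {
  log2(rpkm + pseudocount)
}

validate_metadata <- function(metadata) {
  check_columns(metadata, c("sample_id", "er_status", "tissue"), "metadata")
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata sample_id values must be unique")
  }
  check_levels(metadata$er_status, ER_LEVELS, "metadata$er_status")
  check_levels(metadata$tissue, TISSUE_LEVELS, "metadata$tissue")
  if (!"cn_state" %in% names(metadata)) metadata$cn_state <- "unknown"
  metadata$cn_state <- as.character(metadata$cn_state)
  check_levels(metadata$cn_state, CN_LEVELS, "metadata$cn_state")
  if (!"vital_status" %in% names(metadata)) metadata$vital_status <- "unknown"
  check_levels(metadata$vital_status, VITAL_LEVELS, "metadata$vital_status")
  if (!"stage" %in% names(metadata)) metadata$stage <- "unknown"
  check_levels(metadata$stage, STAGE_LEVELS, "metadata$stage")
  if (!"has_exome" %in% names(metadata)) metadata$has_exome <- NA
  metadata$has_exome <- as.logical(metadata$has_exome)
  metadata
}

#' Compare expression of one gene between phenotype groups
#'
#' Performs a two-sided Wilcoxon rank-sum test for every pair of grouping
#' levels, after excluding samples whose level is `"unknown"`. Medians are
#' reported on the RPKM scale.
#'
#' @param expr gene x sample RPKM matrix.
#' @param gene gene identifier (must be a row of `expr`).
#' @param metadata sample metadata with `sample_id` and the grouping column.
#' @param grouping name of the metadata column to contrast (e.g.
#'   `"er_status"`, `"tissue"`, `"cn_state"`).
#' @return data.frame with one row per contrast: the two levels, group
#'   sizes, group medians, and the rank-sum p-value.
#' @export
compare_expression_groups <- function(expr, gene, metadata, grouping = "er_status") {
  if (!gene %in% rownames(expr)) stop("gene not found in expression matrix: ", gene)
  metadata <- validate_metadata(metadata)
  check_columns(metadata, grouping, "metadata")
  common <- intersect(metadata$sample_id, colnames(expr))
  meta <- metadata[match(common, metadata$sample_id), ]
  vals <- expr[gene, common]
  grp <- as.character(meta[[grouping]])
  keep <- grp != "unknown" & !is.na(grp)
  vals <- vals[keep]
  grp <- grp[keep]
  levels <- unique(grp)
  if (length(levels) < 2L) {
    stop("fewer than 2 non-'unknown' groups available for grouping ", sQuote(grouping))
  }
  pairs <- utils::combn(sort(levels), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    la <- pairs[1, k]
    lb <- pairs[2, k]
    va <- vals[grp == la]
    vb <- vals[grp == lb]
    if (!length(va) || !length(vb)) {
      stop("group empty after excluding 'unknown': ", if (!length(va)) la else lb)
    }
    test <- wilcoxon_rank_sum(va, vb)
    data.frame(
      group_a = la, group_b = lb,
      n_a = length(va), n_b = length(vb),
      median_a = stats::median(va), median_b = stats::median(vb),
      p = test$p, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cohort summary table
#'
#' Per-category counts and percentages (half-up rounded to one decimal, the
#' printed table style) for ER status, APOBEC3B copy-number state and
#' exome-sequencing availability, split by tumor/normal tissue, plus the
#' number of germline-deletion carriers (CN0 + CN1) among tumors.
#'
#' @param metadata sample metadata (see [validate_metadata] columns).
#' @return object of class `cohort_summary`: list with `table` (category,
#'   level, tumor/normal counts and percentages), `n_tumor`, `n_normal` and
#'   `deletion_carriers`.
#' @export
summarize_cohort <- function(metadata) {
  meta <- as.data.frame(metadata)
  if (nrow(meta)) {
    meta <- validate_metadata(meta)
  } else {
    meta <- data.frame(
      sample_id = character(), er_status = character(), tissue = character(),
      cn_state = character(), vital_status = character(), stage = character(),
      has_exome = logical(), stringsAsFactors = FALSE
    )
  }
  tumors <- meta[meta$tissue == "tumor", , drop = FALSE]
  normals <- meta[meta$tissue == "normal", , drop = FALSE]
  count_block <- function(df, values, levels) {
    counts <- vapply(levels, function(l) sum(values == l, na.rm = TRUE), numeric(1))
    total <- nrow(df)
    pct <- if (total > 0) round_half_up(100 * counts / total, 1) else rep(NA_real_, length(levels))
    list(count = counts, pct = pct)
  }
  categories <- list(
    er_status = ER_LEVELS,
    cn_state = CN_LEVELS,
    has_exome = c("yes", "no")
  )
  rows <- lapply(names(categories), function(cat) {
    levels <- categories[[cat]]
    tvals <- if (cat == "has_exome") {
      ifelse(is.na(tumors$has_exome), NA, ifelse(tumors$has_exome, "yes", "no"))
    } else {
      as.character(tumors[[cat]])
    }
    nvals <- if (cat == "has_exome") {
      ifelse(is.na(normals$has_exome), NA, ifelse(normals$has_exome, "yes", "no"))
    } else {
      as.character(normals[[cat]])
    }
    tb <- count_block(tumors, tvals, levels)
    nb <- count_block(normals, nvals, levels)
    data.frame(
      category = cat, level = levels,
      tumor_count = tb$count, tumor_pct = tb$pct,
      normal_count = nb$count, normal_pct = nb$pct,
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  deletion <- if (nrow(tumors)) {
    sum(tumors$cn_state %in% c("0", "1"))
  } else {
    0L
  }
  structure(
    list(
      table = table,
      n_tumor = nrow(tumors),
      n_normal = nrow(normals),
      deletion_carriers = deletion
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d tumors, %d normals\n", x$n_tumor, x$n_normal))
  print(x$table, row.names = FALSE)
  cat(sprintf("Germline-deletion carriers among tumors (CN0 + CN1): %d\n",
              x$deletion_carriers))
  invisible(x)
}
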