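# TSV/BED readers and writers. All tabular formats are header-bearing TSV
# with documented columns; missing values are serialized as "NA".

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read sample metadata TSV
#'
#' Expected columns: `sample_id`, `er_status`, `tissue`, and optionally
#' `cn_state`, `vital_status`, `stage`, `has_exome`. Categorical levels are
#' validated and offending values named in errors.
#'
#' @param path TSV path.
#' @return validated metadata data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- read_tsv(path, colClasses = NA)
  if ("cn_state" %in% names(df)) df$cn_state <- as.character(df$cn_state)
  validate_metadata(df)
}

#' Write sample metadata TSV
#' @param metadata metadata data.frame.
#' @param path output path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write_tsv(validate_metadata(metadata), path)
}

#' Read a MAF-like somatic variant TSV
#'
#' Expected columns: `sample`, `chrom`, `pos` (1-based), `ref`, `alt`, and
#' optionally `context` (+ strand 3-mer centered on `pos`).
#'
#' @param path TSV path.
#' @return variant data.frame.
#' @export
read_variants_tsv <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("sample", "chrom", "pos", "ref", "alt"), "variant table")
  if (!is.numeric(df$pos)) stop("variant pos column must be numeric (1-based)")
  df
}

#' Write a MAF-like somatic variant TSV
#' @param variants variant data.frame.
#' @param path output path.
#' @export
write_variants_tsv <- function(variants, path) {
  check_columns(variants, c("sample", "chrom", "pos", "ref", "alt"),
                "variant table")
  write_tsv(variants, path)
}

#' Read a gene x sample expression TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene") stop("expression table must start with a 'gene' column")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  storage.mode(mat) <- "double"
  mat
}

#' Write a gene x sample expression TSV
#' @param expr matrix with gene rownames.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a bedGraph-like CpG methylation TSV
#'
#' Expected columns: `chrom`, `pos` (1-based), `methylated`, `total`.
#'
#' @param path TSV path.
#' @return CpG site data.frame.
#' @export
read_cpg_tsv <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("chrom", "pos", "methylated", "total"), "CpG table")
  df
}

#' Write a bedGraph-like CpG methylation TSV
#' @param sites CpG site data.frame.
#' @param path output path.
#' @export
write_cpg_tsv <- function(sites, path) {
  check_columns(sites, c("chrom", "pos", "methylated", "total"), "CpG table")
  write_tsv(sites, path)
}

#' Read TSS annotations from a BED6 file
#'
#' Headerless BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`,
#' 0-based half-open). The TSS is `start + 1` for plus-strand and `end` for
#' minus-strand features. Strand is required.
#'
#' @param path BED6 path.
#' @return data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BED6 file with a strand column required")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  check_levels(df$strand, c("+", "-"), "BED strand")
  data.frame(
    gene = df$name, chrom = df$chrom,
    tss = ifelse(df$strand == "+", df$start + 1L, df$end),
    strand = df$strand, stringsAsFactors = FALSE
  )
}

# headerless BED3 for territories
read_bed3 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs chrom/start/end columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  df[, 1:3]
}

#' Read a background trinucleotide composition TSV
#'
#' Expected columns: `center` (C or T), `motif`, `freq`.
#'
#' @param path TSV path.
#' @return `background_composition`.
#' @export
read_background_tsv <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("center", "motif", "freq"), "background table")
  cset <- df[df$center == "C", ]
  tset <- df[df$center == "T", ]
  background_composition(
    c_freqs = stats::setNames(cset$freq, cset$motif),
    t_freqs = if (nrow(tset)) stats::setNames(tset$freq, tset$motif) else NULL,
    provenance = "supplied"
  )
}

#' Write a background trinucleotide composition TSV
#' @param background `background_composition`.
#' @param path output path.
#' @export
write_background_tsv <- function(background, path) {
  df <- data.frame(
    center = c(rep("C", 16), if (!is.null(background$t_freqs)) rep("T", 16)),
    motif = c(names(background$c_freqs), names(background$t_freqs)),
    freq = c(unname(background$c_freqs), unname(background$t_freqs)),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes `metadata.tsv`, `expression.tsv`, `variants.tsv`, one
#' `methylation_<celltype>.tsv` per cell type, `tss.bed`,
#' `truth_samples.tsv` and `truth_params.txt`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param tss optional TSS annotation to write alongside.
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, tss = NULL) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("cohort must be a synthetic_cohort")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(cohort$expression)) {
    write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  }
  if (!is.null(cohort$variants)) {
    write_variants_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  }
  if (!is.null(cohort$methylation)) {
    for (ct in names(cohort$methylation)) {
      write_cpg_tsv(cohort$methylation[[ct]],
                    file.path(dir, paste0("methylation_", ct, ".tsv")))
    }
  }
  if (!is.null(tss)) {
    bed <- data.frame(
      chrom = tss$chrom,
      start = ifelse(tss$strand == "+", tss$tss - 1L, tss$tss - 1L),
      end = ifelse(tss$strand == "+", tss$tss, tss$tss),
      name = tss$gene, score = 0L, strand = tss$strand
    )
    utils::write.table(bed, file.path(dir, "tss.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(cohort$truth$config)) {
    write_background_tsv(
      background_composition(
        cohort$truth$config$background_trinuc_freqs$C,
        cohort$truth$config$background_trinuc_freqs$T,
        provenance = "simulator configuration"
      ),
      file.path(dir, "background.tsv")
    )
  }
  if (!is.null(cohort$truth$samples)) {
    write_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"))
  }
  writeLines(deparse(cohort$truth[c("slopes", "target_rho",
                                    "apobec3c_er_neg_rho")]),
             file.path(dir, "truth_params.txt"))
  invisible(dir)
}

#' Read cohort tables from a directory with cross-file validation
#'
#' Loads whichever of `metadata.tsv`, `expression.tsv`, `variants.tsv` and
#' `methylation_*.tsv` are present, enforces sample-ID consistency between
#' the files, and reports row counts as messages.
#'
#' @param dir directory written by [write_cohort()] (or hand-assembled with
#'   the same layout).
#' @return list with `metadata`, `expression`, `variants`, `methylation`.
#' @export
read_cohort_dir <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("metadata.tsv not found in ", dir)
  metadata <- read_metadata_tsv(meta_path)
  message(nrow(metadata), " metadata rows")
  out <- list(metadata = metadata, expression = NULL, variants = NULL,
              methylation = NULL)
  expr_path <- file.path(dir, "expression.tsv")
  if (file.exists(expr_path)) {
    out$expression <- read_expression_tsv(expr_path)
    alien <- setdiff(colnames(out$expression), metadata$sample_id)
    if (length(alien)) {
      stop("expression samples absent from metadata: ",
           paste(utils::head(alien, 5), collapse = ", "))
    }
    message(ncol(out$expression), " expression samples")
  }
  var_path <- file.path(dir, "variants.tsv")
  if (file.exists(var_path)) {
    out$variants <- read_variants_tsv(var_path)
    alien <- setdiff(unique(out$variants$sample), metadata$sample_id)
    if (length(alien)) {
      stop("variant samples absent from metadata: ",
           paste(utils::head(alien, 5), collapse = ", "))
    }
    message(nrow(out$variants), " variant rows")
  }
  meth_paths <- list.files(dir, pattern = "^methylation_.*\\.tsv$",
                           full.names = TRUE)
  if (length(meth_paths)) {
    out$methylation <- lapply(meth_paths, read_cpg_tsv)
    names(out$methylation) <- sub("^methylation_(.*)\\.tsv$", "\\1",
                                  basename(meth_paths))
  }
  out
}
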