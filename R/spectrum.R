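# Strand-collapsed mutation spectra and trinucleotide contexts.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# the 16 pyrimidine-centered motifs for each center base, 5'->3'
C_MOTIFS <- as.vector(outer(DNA_BASES, DNA_BASES,
                            function(a, b) paste0(a, "C", b)))
T_MOTIFS <- as.vector(outer(DNA_BASES, DNA_BASES,
                            function(a, b) paste0(a, "T", b)))
TCW_MOTIFS <- c("TCA", "TCT")

#' Paired labels for the six substitution classes
#'
#' @return named character vector mapping the pyrimidine-reference class
#'   labels to their conventional paired form (e.g. `"C>T"` -> `"C>T/G>A"`).
#' @export
substitution_pair_labels <- function() {
  c(`C>A` = "C>A/G>T", `C>G` = "C>G/G>C", `C>T` = "C>T/G>A",
    `T>A` = "T>A/A>T", `T>C` = "T>C/A>G", `T>G` = "T>G/A>C")
}

#' Classify a base substitution into one of six strand-collapsed classes
#'
#' Purine-reference substitutions are mapped to their reverse-complement
#' pyrimidine-reference class, so exactly six classes (C>A, C>G, C>T, T>A,
#' T>C, T>G) cover all 12 ordered base pairs.
#'
#' @param ref,alt reference and alternate bases (A/C/G/T), vectorised.
#' @return character vector of class labels.
#' @examples
#' classify_substitution("G", "A")  # "C>T"
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  bad <- !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES)
  if (any(bad)) {
    stop("non-ACGT allele(s): ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, complement_bases(ref), ref)
  alt2 <- ifelse(purine, complement_bases(alt), alt)
  paste0(ref2, ">", alt2)
}

#' Collapse a trinucleotide context to its pyrimidine-centered form
#'
#' When the reference base is a purine the context is reverse-complemented
#' (and the class collapsed accordingly), so the returned motif always has a
#' C or T center. `is_tcw` flags motifs TCA/TCT with a mutated C - the
#' preferred APOBEC deamination context (W = A or T).
#'
#' @param context 3-mer on the + strand centered on the variant position.
#' @param ref,alt reference and alternate bases; the context's middle base
#'   must equal `ref`.
#' @return data.frame with columns `motif`, `class`, `is_tcw`.
#' @examples
#' pyrimidine_context("TGA", "G", "A")  # motif TCA, class C>T, TCW
#' @export
pyrimidine_context <- function(context, ref, alt) {
  context <- toupper(as.character(context))
  ref <- toupper(as.character(ref))
  n <- length(context)
  if (length(ref) != n || length(alt) != n) {
    stop("context, ref and alt must have equal length")
  }
  ok_ctx <- !is.na(context) & nchar(context) == 3L &
    !grepl("[^ACGT]", context)
  if (any(!ok_ctx & !is.na(context))) {
    stop("malformed 3-mer context(s): ",
         paste(unique(context[!ok_ctx & !is.na(context)]), collapse = ", "))
  }
  mism <- ok_ctx & substr(context, 2, 2) != ref
  if (any(mism)) {
    stop("context middle base does not match ref for: ",
         paste(unique(paste0(context[mism], "/", ref[mism])), collapse = ", "))
  }
  cls <- classify_substitution(ref, alt)
  purine <- ref %in% c("A", "G")
  motif <- ifelse(purine, revcomp3(context), context)
  motif[!ok_ctx] <- NA_character_
  data.frame(
    motif = motif,
    class = cls,
    is_tcw = !is.na(motif) & substr(cls, 1, 1) == "C" & motif %in% TCW_MOTIFS,
    stringsAsFactors = FALSE
  )
}

#' Extract the + strand trinucleotide context at a position
#'
#' @param chrom chromosome name(s), vectorised with `pos`.
#' @param pos 1-based position(s); both flanking bases must lie inside the
#'   sequence, otherwise an error is raised.
#' @param reference named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @return uppercase 3-mers; windows containing a non-ACGT base (e.g. N)
#'   return `NA` with a warning - such variants stay in class counts but are
#'   excluded from motif analysis.
#' @export
extract_context <- function(chrom, pos, reference) {
  seqs <- load_reference(reference)
  chrom <- as.character(chrom)
  missing <- setdiff(unique(chrom), names(seqs))
  if (length(missing)) {
    stop("reference is missing sequence(s): ", paste(missing, collapse = ", "))
  }
  lens <- nchar(seqs)[chrom]
  if (any(pos < 2 | pos > lens - 1)) {
    bad <- which(pos < 2 | pos > lens - 1)[1]
    stop(sprintf("position %s:%d lies at a sequence edge (no full 3-mer window)",
                 chrom[bad], pos[bad]))
  }
  ctx <- toupper(substr(seqs[chrom], pos - 1, pos + 1))
  hasN <- grepl("[^ACGT]", ctx)
  if (any(hasN)) {
    warning(sum(hasN), " context window(s) contain non-ACGT bases; ",
            "returned as NA (excluded from motif analysis)")
    ctx[hasN] <- NA_character_
  }
  unname(ctx)
}

# accept DNAStringSet, named character, or FASTA path
load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else if (is.character(reference) && length(reference) == 1L &&
             is.null(names(reference)) && file.exists(reference)) {
    out <- as.character(Biostrings::readDNAStringSet(reference))
  } else if (is.character(reference)) {
    out <- reference
  } else {
    stop("reference must be a DNAStringSet, a named character vector, or a FASTA path")
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("reference sequences must be named")
  }
  # FASTA headers may carry descriptions; keep the first word
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Annotate somatic variants with class, collapsed motif and TCW flag
#'
#' @param variants data.frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `context` (+ strand 3-mer centered on `pos`).
#' @param reference optional reference sequences used to fill in missing
#'   contexts via [extract_context()].
#' @return the input with added columns `class`, `motif`, `is_tcw`.
#' @export
annotate_variants <- function(variants, reference = NULL) {
  check_columns(variants, c("sample", "chrom", "pos", "ref", "alt"), "variants")
  variants <- as.data.frame(variants)
  if (!"context" %in% names(variants)) variants$context <- NA_character_
  need <- is.na(variants$context)
  if (any(need)) {
    if (is.null(reference)) {
      if (all(need)) {
        stop("variants carry no context and no reference was supplied")
      }
    } else {
      variants$context[need] <- extract_context(
        variants$chrom[need], variants$pos[need], reference
      )
    }
  }
  ann <- pyrimidine_context(variants$context, variants$ref, variants$alt)
  variants$class <- ann$class
  variants$motif <- ann$motif
  variants$is_tcw <- ann$is_tcw
  variants
}

#' Per-sample mutation spectrum over the six substitution classes
#'
#' Counts each sample's variants in the six strand-collapsed classes,
#' derives relative frequencies, summarises the per-sample burden (total
#' SNVs and C>T/G>A mutations, mean and SD), and optionally pools counts by
#' a metadata grouping such as copy-number state or ER status.
#'
#' Records with multi-base or non-ACGT alleles are dropped with a message;
#' duplicate records (same sample, chrom, pos, alt) are deduplicated with a
#' warning. Samples present in `metadata` but without variants contribute
#' zero counts.
#'
#' @param variants variant data.frame (`sample`, `chrom`, `pos`, `ref`, `alt`).
#' @param metadata optional sample metadata defining the sample universe and
#'   grouping columns.
#' @param group_by optional metadata column for pooled group frequencies.
#' @param unknown_sample what to do with variants whose sample is absent
#'   from `metadata`: `"error"` (default) or `"drop"` with a warning.
#' @return object of class `spectrum_table`: list with `counts` (sample x 6
#'   matrix), `totals`, `freqs`, `burden_summary`, `group_freqs`, `dropped`.
#' @export
count_spectrum <- function(variants, metadata = NULL, group_by = NULL,
                           unknown_sample = c("error", "drop")) {
  unknown_sample <- match.arg(unknown_sample)
  check_columns(variants, c("sample", "chrom", "pos", "ref", "alt"), "variants")
  variants <- as.data.frame(variants)
  n0 <- nrow(variants)
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    toupper(variants$ref) %in% DNA_BASES & toupper(variants$alt) %in% DNA_BASES &
    toupper(variants$ref) != toupper(variants$alt)
  n_nonsnv <- sum(!snv)
  if (n_nonsnv) {
    message(n_nonsnv, " non-SNV record(s) dropped from the spectrum")
    variants <- variants[snv, , drop = FALSE]
  }
  key <- paste(variants$sample, variants$chrom, variants$pos, variants$alt)
  n_dup <- sum(duplicated(key))
  if (n_dup) {
    warning(n_dup, " duplicate variant record(s) removed")
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    samples <- metadata$sample_id
    alien <- setdiff(unique(variants$sample), samples)
    if (length(alien)) {
      msg <- paste("variant(s) reference unknown sample(s):",
                   paste(alien, collapse = ", "))
      if (unknown_sample == "error") stop(msg)
      warning(msg, " - dropped")
      variants <- variants[variants$sample %in% samples, , drop = FALSE]
    }
  } else {
    samples <- sort(unique(variants$sample))
  }
  cls <- if (nrow(variants)) {
    classify_substitution(variants$ref, variants$alt)
  } else {
    character()
  }
  counts <- table(
    factor(variants$sample, levels = samples),
    factor(cls, levels = SUB_CLASSES)
  )
  counts <- matrix(as.numeric(counts), nrow = length(samples),
                   dimnames = list(samples, SUB_CLASSES))
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals > 0, totals, NA_real_)
  burden_summary <- data.frame(
    statistic = c("total_snvs", "ct_ga"),
    pooled_count = c(sum(totals), sum(counts[, "C>T"])),
    mean = c(mean(totals), mean(counts[, "C>T"])),
    sd = c(stats::sd(totals), stats::sd(counts[, "C>T"])),
    stringsAsFactors = FALSE
  )
  group_freqs <- NULL
  if (!is.null(group_by)) {
    if (is.null(metadata)) stop("group_by requires metadata")
    check_columns(metadata, group_by, "metadata")
    grp <- as.character(metadata[[group_by]][match(samples, metadata$sample_id)])
    pooled <- rowsum(counts, grp)
    gtot <- rowSums(pooled)
    gf <- pooled / ifelse(gtot > 0, gtot, NA_real_)
    group_freqs <- data.frame(
      group = rep(rownames(pooled), times = ncol(pooled)),
      class = rep(colnames(pooled), each = nrow(pooled)),
      count = as.vector(pooled),
      freq = as.vector(gf),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      counts = counts, totals = totals, freqs = freqs,
      burden_summary = burden_summary, group_freqs = group_freqs,
      dropped = c(non_snv = n_nonsnv, duplicates = n_dup)
    ),
    class = "spectrum_table"
  )
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("Mutation spectrum: %d samples, %d SNVs\n",
              nrow(x$counts), sum(x$totals)))
  print(x$burden_summary, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.spectrum_table <- function(x, ...) {
  df <- data.frame(sample = rownames(x$counts), x$counts,
                   total = x$totals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
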