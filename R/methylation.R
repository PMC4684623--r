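# TSS-centered CpG methylation profiles in 100-bp bins.

#' Filter CpG sites by read depth
#'
#' Keeps sites supported by at least `min_reads` total reads (default 4, the
#' conventional bisulfite depth cutoff); the number of dropped sites is
#' reported as a message and stored in the `dropped` attribute.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `methylated`,
#'   `total`.
#' @param min_reads minimum total read depth (inclusive).
#' @return the filtered data.frame.
#' @export
filter_sites <- function(sites, min_reads = 4) {
  check_columns(sites, c("chrom", "pos", "methylated", "total"), "sites")
  if (any(sites$methylated > sites$total, na.rm = TRUE) ||
      any(sites$methylated < 0 | sites$total < 0, na.rm = TRUE)) {
    stop("methylated counts must lie in [0, total]")
  }
  keep <- !is.na(sites$total) & sites$total >= min_reads
  out <- sites[keep, , drop = FALSE]
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " CpG site(s) below depth ", min_reads, " dropped")
  attr(out, "dropped") <- n_drop
  out
}

#' Binned methylation profile around a transcription start site
#'
#' Averages per-site methylation ratios within 100 contiguous half-open
#' 100-bp bins spanning TSS - 5 kb to TSS + 5 kb. Bin 1 is always the 5'
#' end of the gene: for minus-strand genes the genomic bin order is
#' reversed. The TSS itself falls in the first downstream bin (bin 51 for a
#' plus-strand gene). Bins without qualifying sites are NA, never 0.
#'
#' @param sites depth-filtered CpG sites (see [filter_sites()]).
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param chrom optional chromosome; when given, sites on other chromosomes
#'   are ignored.
#' @param gene optional gene label carried through to the output.
#' @param flank half-width of the profiled window in bp (default 5000).
#' @param bin_width bin width in bp (default 100).
#' @param proximal half-width of the proximal-promoter summary region
#'   (default 500).
#' @return object of class `methylation_profile`: list with `bins` (bin
#'   index in gene orientation, genomic bin, genomic start/end, mean ratio,
#'   site count), `proximal` (site-level mean/median/n over TSS +/-
#'   `proximal`), and the call parameters.
#' @export
bin_methylation_profile <- function(sites, tss, strand = c("+", "-"),
                                    chrom = NULL, gene = NULL,
                                    flank = 5000L, bin_width = 100L,
                                    proximal = 500L) {
  strand <- match.arg(strand)
  check_columns(sites, c("chrom", "pos", "methylated", "total"), "sites")
  if (flank %% bin_width != 0) stop("flank must be a multiple of bin_width")
  if (!is.null(chrom)) sites <- sites[sites$chrom == chrom, , drop = FALSE]
  n_bins <- as.integer(2 * flank / bin_width)
  offset <- sites$pos - (tss - flank)
  inside <- offset >= 0 & offset < 2 * flank
  sites <- sites[inside, , drop = FALSE]
  offset <- offset[inside]
  genomic_bin <- offset %/% bin_width + 1L
  ratio <- sites$methylated / sites$total
  mean_by_bin <- rep(NA_real_, n_bins)
  n_by_bin <- integer(n_bins)
  if (nrow(sites)) {
    agg_mean <- tapply(ratio, genomic_bin, mean)
    agg_n <- tapply(ratio, genomic_bin, length)
    idx <- as.integer(names(agg_mean))
    mean_by_bin[idx] <- as.numeric(agg_mean)
    n_by_bin[idx] <- as.integer(agg_n)
  }
  genomic_start <- tss - flank + (seq_len(n_bins) - 1L) * bin_width
  oriented <- if (strand == "+") seq_len(n_bins) else rev(seq_len(n_bins))
  bins <- data.frame(
    bin = seq_len(n_bins),
    genomic_bin = oriented,
    genomic_start = genomic_start[oriented],
    genomic_end = genomic_start[oriented] + bin_width,
    mean_ratio = mean_by_bin[oriented],
    n_sites = n_by_bin[oriented]
  )
  prox <- abs(sites$pos - tss) <= proximal & sites$pos >= tss - proximal &
    sites$pos < tss + proximal
  prox_ratio <- ratio[prox]
  structure(
    list(
      gene = gene, tss = tss, strand = strand, chrom = chrom,
      flank = flank, bin_width = bin_width, proximal_halfwidth = proximal,
      bins = bins,
      proximal = list(
        mean = if (length(prox_ratio)) mean(prox_ratio) else NA_real_,
        median = if (length(prox_ratio)) stats::median(prox_ratio) else NA_real_,
        n_sites = length(prox_ratio)
      )
    ),
    class = "methylation_profile"
  )
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("Methylation profile%s: TSS %d (%s), %d bins of %d bp, %d covered\n",
              if (is.null(x$gene)) "" else paste0(" for ", x$gene),
              x$tss, x$strand, nrow(x$bins), x$bin_width,
              sum(!is.na(x$bins$mean_ratio))))
  cat(sprintf("proximal +/-%d bp: mean %.3f, median %.3f over %d sites\n",
              x$proximal_halfwidth, x$proximal$mean, x$proximal$median,
              x$proximal$n_sites))
  invisible(x)
}

# proximal-promoter bins of a profile, in gene orientation
proximal_bins <- function(profile) {
  b <- profile$bins
  lo <- profile$tss - profile$proximal_halfwidth
  hi <- profile$tss + profile$proximal_halfwidth
  b[b$genomic_start >= lo & b$genomic_end <= hi, , drop = FALSE]
}

#' Compare proximal-promoter methylation between two profiles
#'
#' Pairs the TSS +/- 0.5 kb bins covered in both profiles and applies the
#' Wilcoxon signed-rank test to the per-bin differences
#' (`profile_b - profile_a`). When both single profiles and named lists of
#' profiles (one per gene) are supplied, the comparison is run per gene.
#'
#' @param profile_a,profile_b `methylation_profile` objects, or named lists
#'   of them keyed by gene.
#' @param genes optional subset of gene names (list input only).
#' @return for single profiles, a list with `n_bins`, `differences`, `p`,
#'   `median_a`, `median_b` and a `note` when all differences are zero (the
#'   signed-rank test is then undefined and `p` is NA). For lists, a
#'   data.frame with one row per gene.
#' @export
compare_promoter_methylation <- function(profile_a, profile_b, genes = NULL) {
  if (inherits(profile_a, "methylation_profile")) {
    if (!inherits(profile_b, "methylation_profile")) {
      stop("profile_b must be a methylation_profile")
    }
    return(compare_promoter_single(profile_a, profile_b))
  }
  if (!is.list(profile_a) || !is.list(profile_b)) {
    stop("supply two methylation_profile objects or two named lists of them")
  }
  shared <- intersect(names(profile_a), names(profile_b))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (!length(shared)) stop("no shared genes between the two profile sets")
  rows <- lapply(shared, function(g) {
    cmp <- compare_promoter_single(profile_a[[g]], profile_b[[g]])
    data.frame(gene = g, n_bins = cmp$n_bins, p = cmp$p,
               median_a = cmp$median_a, median_b = cmp$median_b,
               note = cmp$note %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

compare_promoter_single <- function(a, b) {
  pa <- proximal_bins(a)
  pb <- proximal_bins(b)
  m <- merge(pa[, c("genomic_bin", "mean_ratio")],
             pb[, c("genomic_bin", "mean_ratio")],
             by = "genomic_bin", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$mean_ratio_a) & !is.na(m$mean_ratio_b), , drop = FALSE]
  if (!nrow(m)) stop("no shared covered bins in the proximal region")
  d <- m$mean_ratio_b - m$mean_ratio_a
  if (all(d == 0)) {
    return(list(n_bins = nrow(m), differences = d, p = NA_real_,
                median_a = stats::median(m$mean_ratio_a),
                median_b = stats::median(m$mean_ratio_b),
                note = "no nonzero differences; profiles identical on shared bins"))
  }
  test <- wilcoxon_signed_rank(d)
  list(n_bins = nrow(m), differences = d, p = test$p,
       median_a = stats::median(m$mean_ratio_a),
       median_b = stats::median(m$mean_ratio_b),
       note = NULL)
}
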