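# Background-normalized trinucleotide motif excess rates and TCW enrichment.

C_CLASSES <- c("C>A", "C>G", "C>T")

#' Construct a background trinucleotide composition
#'
#' @param c_freqs named frequencies over the 16 C-centered motifs.
#' @param t_freqs optional named frequencies over the 16 T-centered motifs.
#' @param provenance free-text provenance tag (`"supplied"` or
#'   `"computed from FASTA+BED"`).
#' @return object of class `background_composition`.
#' @export
background_composition <- function(c_freqs, t_freqs = NULL,
                                   provenance = "supplied") {
  c_freqs <- check_motif_freqs(c_freqs, C_MOTIFS, "c_freqs")
  if (!is.null(t_freqs)) {
    t_freqs <- check_motif_freqs(t_freqs, T_MOTIFS, "t_freqs")
  }
  structure(
    list(c_freqs = c_freqs, t_freqs = t_freqs, provenance = provenance),
    class = "background_composition"
  )
}

check_motif_freqs <- function(f, motifs, name) {
  if (is.null(names(f))) stop(sprintf("'%s' must be named by motif", name))
  missing <- setdiff(motifs, names(f))
  if (length(missing)) {
    stop(sprintf("'%s' is missing motif(s): %s", name,
                 paste(missing, collapse = ", ")))
  }
  f <- f[motifs]
  check_prob_vector(f, name, tol = 1e-9)
}

#' Background composition from a reference territory
#'
#' Counts every overlapping 3-mer whose center base falls inside the
#' supplied territory; G- and A-centered 3-mers are reverse-complemented
#' into the C- and T-centered tallies (strand collapse), and each 16-vector
#' is normalized to frequencies. 3-mers containing non-ACGT bases are
#' ignored. Centers whose flanking base would fall outside the sequence are
#' skipped.
#'
#' @param reference reference sequences (named character,
#'   `Biostrings::DNAStringSet`, or FASTA path).
#' @param territory data.frame with columns `chrom`, `start`, `end`
#'   (BED-style: 0-based half-open), or a path to a headerless BED file.
#' @return `background_composition` with provenance
#'   `"computed from FASTA+BED"`.
#' @export
background_from_territory <- function(reference, territory) {
  seqs <- load_reference(reference)
  if (is.character(territory) && length(territory) == 1L) {
    territory <- read_bed3(territory)
  }
  check_columns(territory, c("chrom", "start", "end"), "territory")
  if (!nrow(territory)) stop("empty territory")
  missing <- setdiff(unique(territory$chrom), names(seqs))
  if (length(missing)) {
    stop("territory references missing sequence(s): ",
         paste(missing, collapse = ", "))
  }
  lens <- nchar(seqs)
  tally <- NULL
  for (i in seq_len(nrow(territory))) {
    chrom <- territory$chrom[i]
    start0 <- territory$start[i]
    end0 <- territory$end[i]
    if (is.na(start0) || is.na(end0) || start0 < 0 || end0 > lens[chrom] ||
        start0 >= end0) {
      stop(sprintf("territory interval out of bounds: %s:%d-%d", chrom,
                   start0, end0))
    }
    # centers are 1-based positions (start0+1)..end0; the 3-mers of the
    # padded window [start0, end0+1] are exactly the 3-mers centered there
    wstart <- max(start0, 1L)
    wend <- min(end0 + 1L, lens[chrom])
    if (wend - wstart + 1L < 3L) next
    win <- Biostrings::DNAStringSet(substr(seqs[chrom], wstart, wend))
    tf <- Biostrings::trinucleotideFrequency(win, simplify.as = "collapsed")
    tally <- if (is.null(tally)) tf else tally + tf
  }
  if (is.null(tally)) stop("territory contains no full 3-mer windows")
  c_counts <- structure(numeric(16), names = C_MOTIFS)
  t_counts <- structure(numeric(16), names = T_MOTIFS)
  for (m in names(tally)) {
    center <- substr(m, 2, 2)
    if (center == "C") {
      c_counts[m] <- c_counts[m] + tally[[m]]
    } else if (center == "G") {
      c_counts[revcomp3(m)] <- c_counts[revcomp3(m)] + tally[[m]]
    } else if (center == "T") {
      t_counts[m] <- t_counts[m] + tally[[m]]
    } else {
      t_counts[revcomp3(m)] <- t_counts[revcomp3(m)] + tally[[m]]
    }
  }
  if (sum(c_counts) == 0) stop("territory contains no C- or G-centered 3-mers")
  background_composition(
    c_freqs = c_counts / sum(c_counts),
    t_freqs = if (sum(t_counts) > 0) t_counts / sum(t_counts) else NULL,
    provenance = "computed from FASTA+BED"
  )
}

#' Expected motif occurrences under the background composition
#'
#' The "mean occurrence" of each motif for a substitution class is the
#' analytic expectation `class_total * background_frequency(motif)`, so the
#' expected counts sum exactly to the class total.
#'
#' @param class_total pooled number of mutations in the class (`N >= 0`).
#' @param background a `background_composition`.
#' @return named numeric vector of expected counts over the 16 C-centered
#'   motifs.
#' @export
expected_motif_counts <- function(class_total, background) {
  if (!inherits(background, "background_composition")) {
    stop("background must be a background_composition")
  }
  if (length(class_total) != 1L || is.na(class_total) || class_total < 0) {
    stop("class_total must be a single non-negative count")
  }
  class_total * background$c_freqs
}

#' Excess rate of observed over expected occurrences
#'
#' `(observed - expected) / expected`; undefined (NA with a warning) when
#' the expected count is not positive.
#'
#' @param observed observed count(s).
#' @param expected expected ("mean") occurrence(s).
#' @return numeric excess rate(s) in `[-1, Inf)`.
#' @examples
#' excess_rate(30, 20)  # 0.5
#' @export
excess_rate <- function(observed, expected) {
  out <- (observed - expected) / expected
  bad <- !is.na(expected) & expected <= 0
  if (any(bad)) {
    warning(sum(bad), " excess rate(s) undefined (expected <= 0); returned NA")
    out[bad] <- NA_real_
  }
  out
}

#' Motif excess-rate table for a group of C-centered mutations
#'
#' For each of the three C-centered substitution classes, tallies the
#' group's pooled mutations over the 16 C-centered motifs, computes expected
#' counts from the background composition with the class's pooled total, and
#' derives the excess rate. Classes with no mutations yield NA rows.
#'
#' @param variants annotated variants (see [annotate_variants()]); rows with
#'   missing motifs are excluded.
#' @param background a `background_composition`.
#' @param permutation also report a permutation-mean expectation
#'   (`expected_perm`) from `n_perm` seeded multinomial draws as a
#'   cross-check of the analytic expectation.
#' @param n_perm,perm_seed permutation draws and seed.
#' @return data.frame with 48 rows: `class`, `motif`, `observed`,
#'   `expected`, `excess_rate`, `is_tcw` (and optionally `expected_perm`).
#' @export
motif_excess_table <- function(variants, background, permutation = FALSE,
                               n_perm = 1000, perm_seed = 1) {
  if (!inherits(background, "background_composition")) {
    stop("background must be a background_composition")
  }
  check_columns(variants, c("class", "motif"), "variants (annotate first)")
  v <- variants[variants$class %in% C_CLASSES & !is.na(variants$motif), ,
                drop = FALSE]
  rows <- lapply(C_CLASSES, function(cl) {
    motifs <- v$motif[v$class == cl]
    n_cl <- length(motifs)
    observed <- as.numeric(table(factor(motifs, levels = C_MOTIFS)))
    if (n_cl == 0) {
      expected <- rep(NA_real_, 16)
      exc <- rep(NA_real_, 16)
      observed <- rep(NA_real_, 16)
    } else {
      expected <- unname(expected_motif_counts(n_cl, background))
      exc <- (observed - expected) / expected
      exc[expected <= 0] <- NA_real_
    }
    data.frame(
      class = cl, motif = C_MOTIFS, observed = observed,
      expected = expected, excess_rate = exc,
      is_tcw = C_MOTIFS %in% TCW_MOTIFS,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (permutation) {
    out$expected_perm <- NA_real_
    for (cl in C_CLASSES) {
      n_cl <- sum(v$class == cl)
      if (n_cl == 0) next
      pm <- with_seed(perm_seed, {
        draws <- stats::rmultinom(n_perm, n_cl, background$c_freqs)
        rowMeans(draws)
      })
      out$expected_perm[out$class == cl] <- unname(pm)
    }
  }
  out
}

#' TCW enrichment test between two groups of mutations
#'
#' Builds the 2x2 table of TCW vs non-TCW C-centered mutation counts pooled
#' per group (rows = groups, columns = TCW / non-TCW) and applies the
#' two-sided Fisher's exact test. By default all three C-centered classes
#' are pooled; restrict to the APOBEC-preferred outcomes with
#' `classes = c("C>G", "C>T")`.
#'
#' @param variants_a,variants_b annotated variants for the two groups.
#' @param classes which C-centered classes to pool.
#' @param labels group labels for reporting.
#' @return object of class `tcw_test`: list with `table`, `odds_ratio`, `p`,
#'   `classes`, `labels`, `degenerate`.
#' @export
tcw_enrichment_test <- function(variants_a, variants_b,
                                classes = C_CLASSES,
                                labels = c("group_a", "group_b")) {
  classes <- match.arg(classes, C_CLASSES, several.ok = TRUE)
  cell <- function(v, lab) {
    check_columns(v, c("class", "motif", "is_tcw"), "variants (annotate first)")
    v <- v[v$class %in% classes & !is.na(v$motif), , drop = FALSE]
    if (!nrow(v)) {
      stop("group ", lab, " has no C-centered mutations in the selected classes")
    }
    c(tcw = sum(v$is_tcw), non_tcw = sum(!v$is_tcw))
  }
  ca <- cell(variants_a, labels[1])
  cb <- cell(variants_b, labels[2])
  tab <- rbind(ca, cb)
  dimnames(tab) <- list(labels, c("TCW", "non-TCW"))
  ft <- fisher_exact_2x2(tab)
  structure(
    list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
         classes = classes, labels = labels, degenerate = ft$degenerate),
    class = "tcw_test"
  )
}

#' @export
print.tcw_test <- function(x, ...) {
  cat("TCW enrichment (Fisher's exact test), classes:",
      paste(x$classes, collapse = " "), "\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, two-sided p = %.3g\n", x$odds_ratio, x$p))
  if (x$degenerate) cat("note: a table cell is zero; odds ratio may be 0/Inf\n")
  invisible(x)
}
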