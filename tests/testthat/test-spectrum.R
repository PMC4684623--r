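# Substitution classification, strand collapse and spectrum counting.

test_that("classify_substitution covers all 12 ordered pairs with complement symmetry", {
  expect_equal(classify_substitution("C", "T"), "C>T")
  expect_equal(classify_substitution("G", "A"), "C>T")
  expect_equal(classify_substitution("T", "G"), "T>G")
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seen <- character()
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      cls <- classify_substitution(r, a)
      expect_match(cls, "^[CT]>[ACGT]$")
      expect_equal(cls, classify_substitution(comp[[r]], comp[[a]]))
      seen <- c(seen, cls)
    }
  }
  expect_setequal(unique(seen), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_error(classify_substitution("C", "C"), "differ")
  expect_error(classify_substitution("N", "A"), "non-ACGT")
})

test_that("pyrimidine_context collapses purine strands and flags TCW", {
  res <- pyrimidine_context("ACA", "C", "T")
  expect_equal(res$motif, "ACA")
  expect_equal(res$class, "C>T")
  expect_false(res$is_tcw)

  res <- pyrimidine_context("TGA", "G", "A")
  expect_equal(res$motif, "TCA")
  expect_equal(res$class, "C>T")
  expect_true(res$is_tcw)

  res <- pyrimidine_context("TCT", "C", "G")
  expect_equal(res$motif, "TCT")
  expect_equal(res$class, "C>G")
  expect_true(res$is_tcw)

  # T-centered motifs are never TCW even in W contexts
  expect_false(pyrimidine_context("TTA", "T", "C")$is_tcw)
  expect_error(pyrimidine_context("ACA", "G", "A"), "middle base")
  expect_error(pyrimidine_context("AC", "C", "T"), "malformed")
})

test_that("strand collapse is an involution: collapsing a collapsed motif is a no-op", {
  v <- random_variants(100, seed = 3)
  ann <- pyrimidine_context(v$context, v$ref, v$alt)
  expect_true(all(substr(ann$motif, 2, 2) %in% c("C", "T")))
  # re-collapse from the pyrimidine representation
  alt_pyr <- substr(ann$class, 3, 3)
  again <- pyrimidine_context(ann$motif, substr(ann$class, 1, 1), alt_pyr)
  expect_equal(again$motif, ann$motif)
  expect_equal(again$class, ann$class)
})

test_that("extract_context indexes correctly and honours edges and Ns", {
  ref <- c(seqA = "AACGT", seqB = "ANCGT")
  expect_equal(extract_context("seqA", 3, ref), "ACG")
  expect_equal(extract_context("seqA", 2, ref), "AAC")
  expect_error(extract_context("seqA", 1, ref), "edge")
  expect_error(extract_context("seqA", 5, ref), "edge")
  expect_warning(ctx <- extract_context("seqB", 2, ref), "non-ACGT")
  expect_true(is.na(ctx))
  expect_error(extract_context("nope", 3, ref), "missing sequence")
})

test_that("count_spectrum tallies match a naive oracle and handle edge cases", {
  v <- data.frame(
    sample = "s1", chrom = "chr1", pos = 1:3,
    ref = c("C", "G", "T"), alt = c("T", "A", "A"),
    stringsAsFactors = FALSE
  )
  sp <- count_spectrum(v)
  expect_equal(unname(sp$counts["s1", "C>T"]), 2)
  expect_equal(unname(sp$counts["s1", "T>A"]), 1)
  expect_equal(unname(sp$freqs["s1", "C>T"]), 2 / 3)
  expect_equal(sum(sp$counts["s1", ]), sp$totals[["s1"]])

  # 200-variant fixture equals an independent naive tally
  v2 <- random_variants(200, seed = 7)
  sp2 <- count_spectrum(v2)
  oracle <- oracle_class_tally(v2$ref, v2$alt)
  expect_equal(colSums(sp2$counts), oracle)
  expect_equal(rowSums(sp2$freqs), setNames(rep(1, nrow(sp2$freqs)),
                                            rownames(sp2$freqs)))

  # empty variant set: zero totals, NA frequencies
  sp3 <- count_spectrum(v2[0, ], metadata = data.frame(
    sample_id = "s1", er_status = "positive", tissue = "tumor",
    stringsAsFactors = FALSE
  ))
  expect_equal(unname(sp3$totals), 0)
  expect_true(all(is.na(sp3$freqs)))
})

test_that("count_spectrum validates samples, dedupes, and pools groups", {
  meta <- data.frame(
    sample_id = c("s1", "s2"), er_status = "positive", tissue = "tumor",
    cn_state = c("0", "2"), stringsAsFactors = FALSE
  )
  v <- data.frame(
    sample = c("s1", "s1", "s2", "sX"), chrom = "chr1",
    pos = c(10, 10, 11, 12), ref = "C", alt = "T",
    stringsAsFactors = FALSE
  )
  expect_error(suppressWarnings(count_spectrum(v, meta)), "unknown sample")
  warns <- capture_warnings(
    sp <- count_spectrum(v, meta, group_by = "cn_state",
                         unknown_sample = "drop")
  )
  expect_true(any(grepl("duplicate", warns)))
  expect_true(any(grepl("unknown", warns)))
  expect_equal(sum(sp$counts), 2)  # dedup removed one, sX dropped
  gf <- sp$group_freqs
  expect_equal(sum(gf$count[gf$class == "C>T"]), 2)
  # group pooled counts equal the sum of member samples' counts
  expect_equal(gf$count[gf$group == "0" & gf$class == "C>T"],
               unname(sp$counts["s1", "C>T"]))

  # non-SNV records dropped with a message
  v3 <- data.frame(sample = "s1", chrom = "chr1", pos = 1,
                   ref = "CT", alt = "C", stringsAsFactors = FALSE)
  expect_message(sp3 <- count_spectrum(rbind(v[1, ], v3), meta,
                                       unknown_sample = "drop"),
                 "non-SNV")
  expect_equal(sum(sp3$counts), 1)
})

test_that("annotate_variants fills contexts from a reference and flags motifs", {
  ref <- c(chr1 = "TTGACCTCAT")
  v <- data.frame(
    sample = "s1", chrom = "chr1", pos = c(4, 8),
    ref = c("A", "C"), alt = c("G", "T"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_variants(v, ref)
  expect_equal(ann$context, c("GAC", "TCA"))
  expect_equal(ann$motif, c("GTC", "TCA"))  # GAC reverse-complemented
  expect_equal(ann$class, c("T>C", "C>T"))
  expect_equal(ann$is_tcw, c(FALSE, TRUE))
  expect_error(annotate_variants(v), "no reference")
})
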