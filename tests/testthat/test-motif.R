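# Background composition, excess rates and TCW enrichment.

test_that("background_from_territory counts and collapses 3-mers", {
  bg <- background_from_territory(c(s = "TCATCA"),
                                  data.frame(chrom = "s", start = 0, end = 6))
  expect_equal(unname(bg$c_freqs["TCA"]), 1)
  expect_equal(sum(bg$c_freqs), 1)
  # T-centered tally: ATC directly plus CAT collapsed to ATG
  expect_equal(unname(bg$t_freqs["ATC"]), 0.5)
  expect_equal(unname(bg$t_freqs["ATG"]), 0.5)

  # single G-centered 3-mer collapses to TCA
  bg2 <- background_from_territory(c(s = "TGA"),
                                   data.frame(chrom = "s", start = 0, end = 3))
  expect_equal(unname(bg2$c_freqs["TCA"]), 1)

  expect_error(
    background_from_territory(c(s = "TCATCA"),
                              data.frame(chrom = "s", start = 0, end = 0)[0, ]),
    "empty territory"
  )
  expect_error(
    background_from_territory(c(s = "TCA"),
                              data.frame(chrom = "s", start = 0, end = 9)),
    "out of bounds"
  )
  # N bases are ignored by the tally
  bg3 <- background_from_territory(c(s = "TCANNNACG"),
                                   data.frame(chrom = "s", start = 0, end = 9))
  expect_equal(sum(bg3$c_freqs > 0), 2)  # TCA and ACG only
})

test_that("expected counts are proportional with exact mass conservation", {
  uni <- background_composition(
    setNames(rep(1 / 16, 16), apobecsig:::C_MOTIFS)
  )
  expect_equal(unname(expected_motif_counts(160, uni)), rep(10, 16))
  expect_equal(sum(expected_motif_counts(50, uni)), 50)
  expect_equal(unname(expected_motif_counts(0, uni)), rep(0, 16))
  skew <- setNames(rep(0.8 / 15, 16), apobecsig:::C_MOTIFS)
  skew["TCA"] <- 0.2
  bg <- background_composition(skew / sum(skew))
  expect_equal(unname(expected_motif_counts(50, bg)["TCA"]), 10,
               tolerance = 1e-9)
})

test_that("excess_rate follows the (observed - expected)/expected formula", {
  expect_equal(excess_rate(30, 20), 0.5)
  expect_equal(excess_rate(20, 20), 0)
  expect_equal(excess_rate(0, 20), -1)
  expect_warning(e <- excess_rate(5, 0), "undefined")
  expect_true(is.na(e))
})

test_that("motif_excess_table equals a brute-force tally and conserves class totals", {
  v <- random_variants(300, seed = 13)
  ann <- annotate_variants(v)
  uni <- background_composition(
    setNames(rep(1 / 16, 16), apobecsig:::C_MOTIFS)
  )
  tab <- motif_excess_table(ann, uni)
  expect_equal(nrow(tab), 48)
  for (cl in c("C>A", "C>G", "C>T")) {
    sub <- tab[tab$class == cl, ]
    oracle <- oracle_motif_tally(ann$class, ann$motif, cl)
    n_cl <- sum(oracle)
    if (n_cl == 0) {
      expect_true(all(is.na(sub$excess_rate)))
      next
    }
    expect_equal(setNames(sub$observed, sub$motif), oracle[sub$motif])
    expect_equal(sum(sub$expected), n_cl)
    expect_equal(sum(sub$observed), n_cl)
    expect_equal(sub$excess_rate, (sub$observed - sub$expected) / sub$expected)
  }
  # a class with no mutations yields NA rows
  ann_ct <- ann[ann$class != "C>A", ]
  tab2 <- motif_excess_table(ann_ct, uni)
  expect_true(all(is.na(tab2$excess_rate[tab2$class == "C>A"])))
})

test_that("excess rates are invariant to doubling counts and territory together", {
  v <- random_variants(150, seed = 17)
  ann <- annotate_variants(v)
  bg <- background_from_territory(
    c(s = paste(rep("ACGTCATTCCGGA", 10), collapse = "")),
    data.frame(chrom = "s", start = 0, end = 130)
  )
  t1 <- motif_excess_table(ann, bg)
  # doubled observations: replicate every variant
  ann2 <- rbind(ann, ann)
  # doubled territory: the same interval listed twice doubles every tally
  bg2 <- background_from_territory(
    c(s = paste(rep("ACGTCATTCCGGA", 10), collapse = "")),
    data.frame(chrom = "s", start = c(0, 0), end = c(130, 130))
  )
  expect_equal(bg2$c_freqs, bg$c_freqs)
  t2 <- motif_excess_table(ann2, bg2)
  expect_equal(t2$excess_rate, t1$excess_rate, tolerance = 1e-12)
})

test_that("permutation mean expectation agrees with the analytic expectation", {
  v <- random_variants(400, seed = 19)
  ann <- annotate_variants(v)
  uni <- background_composition(
    setNames(rep(1 / 16, 16), apobecsig:::C_MOTIFS)
  )
  tab <- motif_excess_table(ann, uni, permutation = TRUE, n_perm = 2000,
                            perm_seed = 3)
  ok <- !is.na(tab$expected)
  # Monte-Carlo mean within 4 SEs of the analytic expectation
  se <- sqrt(tab$expected[ok] * (1 - 1 / 16) / 2000)
  expect_true(all(abs(tab$expected_perm[ok] - tab$expected[ok]) <
                    4 * pmax(se, 1e-6) + 1e-9))
})

test_that("tcw_enrichment_test builds the right table and Fisher p", {
  mk <- function(n_tcw, n_non, sample = "s") {
    data.frame(
      sample = sample, chrom = "chr1", pos = seq_len(n_tcw + n_non),
      ref = "C", alt = "T",
      class = "C>T",
      motif = c(rep("TCA", n_tcw), rep("ACA", n_non)),
      is_tcw = c(rep(TRUE, n_tcw), rep(FALSE, n_non)),
      stringsAsFactors = FALSE
    )
  }
  res <- tcw_enrichment_test(mk(5, 5), mk(5, 5))
  expect_equal(res$p, 1)
  expect_equal(res$odds_ratio, 1)
  expect_equal(as.vector(res$table), c(5, 5, 5, 5))

  res2 <- tcw_enrichment_test(mk(10, 0), mk(0, 10))
  expect_equal(res2$p, 2 / choose(20, 10))
  expect_true(res2$degenerate)

  res3 <- tcw_enrichment_test(mk(3, 1), mk(1, 3))
  expect_equal(res3$p, 34 / 70)

  # class restriction drops C>A mutations from the table
  va <- mk(4, 4)
  va$class[1] <- "C>A"
  r_all <- tcw_enrichment_test(va, mk(4, 4))
  r_cgct <- tcw_enrichment_test(va, mk(4, 4), classes = c("C>G", "C>T"))
  expect_equal(sum(r_all$table[1, ]), 8)
  expect_equal(sum(r_cgct$table[1, ]), 7)

  expect_error(tcw_enrichment_test(mk(1, 1)[0, ], mk(1, 1)),
               "no C-centered")
})

test_that("TCW Fisher test is calibrated under the simulator null", {
  # 5% +/- 2% rejections at alpha = 0.05 over 1000 null group pairs of
  # equal size (10 + 10 samples, no signature)
  cfg <- sim_config(n_tumor = 20, n_normal = 0, exome_fraction = 1,
                    signature_baseline = 0, apobec3c_er_neg_rho = 0)
  rej <- vapply(1:1000, function(s) {
    c2 <- cfg
    c2$seed <- 100000L + s
    co <- simulate_cohort(c2, include = c("expression", "variants"))
    ann <- annotate_variants(co$variants)
    ids <- unique(co$metadata$sample_id)
    ga <- ann[ann$sample %in% ids[1:10], ]
    gb <- ann[ann$sample %in% ids[11:20], ]
    tcw_enrichment_test(ga, gb)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
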