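# Synthetic cohort generator: determinism, configured moments, null
# behaviour and forced edge cases.

test_that("sim_config validates probability vectors and moments", {
  expect_error(sim_config(er_fractions = c(positive = 0.5, negative = 0.5,
                                           unknown = 0.1)),
               "sum to 1")
  expect_error(sim_config(burden_mean = -1), "positive")
  expect_error(sim_config(burden_mean = 60, burden_sd = 5), "overdispersion")
  expect_error(sim_config(n_tumor = -1), "non-negative")
  expect_error(sim_config(target_rho = c(0.3, 0, 0)), "named")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  # method-of-moments NB size reproduces the configured SD
  expect_equal(sqrt(cfg$burden_mean + cfg$burden_mean^2 / cfg$burden_size),
               cfg$burden_sd)
})

test_that("identical config and seed give byte-identical cohorts and files", {
  cfg <- sim_config(n_tumor = 40, n_normal = 4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d1 <- tempfile("cohort1_")
  d2 <- tempfile("cohort2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seed changes the cohort
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(simulate_cohort(cfg2)$variants, a$variants))
})

test_that("with zero signature weight the TCW share matches the background", {
  cfg <- sim_config(n_tumor = 120, n_normal = 0, exome_fraction = 1,
                    signature_baseline = 0, apobec3c_er_neg_rho = 0,
                    seed = 31)
  co <- simulate_cohort(cfg, include = c("expression", "variants"))
  ann <- annotate_variants(co$variants)
  cmut <- ann[substr(ann$class, 1, 1) == "C", ]
  p_bg <- sum(cfg$background_trinuc_freqs$C[c("TCA", "TCT")])
  n <- nrow(cmut)
  obs <- mean(cmut$is_tcw)
  # binomial Monte-Carlo bound from the configuration
  expect_lt(abs(obs - p_bg), 3 * sqrt(p_bg * (1 - p_bg) / n))
  # truth records a zero signature probability everywhere
  expect_true(all(co$truth$samples$p_signature == 0))
})

test_that("CN0 samples sit exactly at the expression floor", {
  cfg <- sim_config(n_tumor = 150, n_normal = 0, cn0_floor = 0, seed = 17,
                    target_rho = c(positive = 0, negative = 0, unknown = 0))
  co <- simulate_cohort(cfg, include = "expression")
  cn0 <- co$metadata$sample_id[co$metadata$cn_state == "0"]
  expect_gt(length(cn0), 0)
  expect_equal(unname(co$expression["APOBEC3B", cn0]),
               rep(0, length(cn0)))
  # nonzero floor applies verbatim
  cfg2 <- sim_config(n_tumor = 150, n_normal = 0, seed = 17,
                     target_rho = c(positive = 0, negative = 0, unknown = 0))
  co2 <- simulate_cohort(cfg2, include = "expression")
  expect_equal(unname(co2$expression["APOBEC3B", cn0]),
               rep(0.05, length(cn0)))
  # CN1 expression sits between CN0 and CN2 on average
  m <- tapply(log2(co2$expression["APOBEC3B", ]), co2$metadata$cn_state, mean)
  expect_lt(m[["0"]], m[["1"]])
  expect_lt(m[["1"]], m[["2"]])
})

test_that("burden moments match the configuration at n = 5000", {
  cfg <- sim_config(n_tumor = 5000, n_normal = 0, exome_fraction = 1,
                    signature_baseline = 0, apobec3c_er_neg_rho = 0,
                    seed = 2)
  co <- simulate_cohort(cfg, include = c("expression", "variants"))
  sp <- count_spectrum(co$variants, co$metadata)
  m <- sp$burden_summary$mean[sp$burden_summary$statistic == "total_snvs"]
  s <- sp$burden_summary$sd[sp$burden_summary$statistic == "total_snvs"]
  expect_lt(abs(m - 57.9) / 57.9, 0.05)
  expect_lt(abs(s - 50.9) / 50.9, 0.05)
})

test_that("every variant belongs to a known sample and contexts are consistent", {
  cfg <- sim_config(n_tumor = 50, n_normal = 5, seed = 8)
  co <- simulate_cohort(cfg)
  expect_true(all(co$variants$sample %in% co$metadata$sample_id))
  # context middle base equals ref for every emitted record
  expect_true(all(substr(co$variants$context, 2, 2) == co$variants$ref))
  # both strands represented
  expect_true(any(co$variants$ref %in% c("G", "A")))
  expect_true(any(co$variants$ref %in% c("C", "T")))
  # positions unique within the cohort (no accidental duplicate records)
  expect_false(anyDuplicated(co$variants[, c("sample", "chrom", "pos")]) > 0)
})

test_that("methylation simulator honours forced beta shapes and depth moments", {
  tss_df <- data.frame(gene = "g", chrom = "c", tss = 50000L, strand = "+",
                       stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 4)
  cfg$meth_params$cell_types <- list(
    zero = list(promoter = c(0, 1), flank = c(7, 3)),
    strong = list(promoter = c(8, 2), flank = c(7, 3))
  )
  meth <- simulate_methylation(cfg, tss_df)
  promoter <- function(df) df[df$pos >= 50000 - 500 & df$pos < 50000 + 500, ]
  # promoter shape (0, 1) forces ratio 0 at every site
  expect_true(all(promoter(meth$zero)$methylated == 0))
  # promoter mean 0.8 recovered within 3 SEs over the simulated sites
  ps <- promoter(meth$strong)
  ratios <- ps$methylated / ps$total
  # site-level variance from the beta-binomial moments
  a <- 8; b <- 2
  mu <- a / (a + b)
  v_beta <- a * b / ((a + b)^2 * (a + b + 1))
  v_site <- v_beta + mean(1 / ps$total) * mu * (1 - mu) * (1 - v_beta / (mu * (1 - mu)))
  expect_gt(nrow(ps), 15)
  expect_lt(abs(mean(ratios) - mu), 3 * sqrt(v_site / nrow(ps)))
  # determinism
  expect_identical(simulate_methylation(cfg, tss_df),
                   simulate_methylation(cfg, tss_df))
  expect_error(simulate_methylation(cfg, tss_df[0, ]), "non-empty")
})

test_that("calibration is deterministic, cached, and independent of run seed", {
  cfg1 <- sim_config(n_tumor = 30, seed = 1)
  cfg2 <- sim_config(n_tumor = 30, seed = 777)
  s1 <- calibrate_signature_slope(cfg1, "positive")
  s2 <- calibrate_signature_slope(cfg2, "positive")
  expect_identical(s1, s2)
  expect_gt(s1, 0)
  expect_identical(calibrate_signature_slope(cfg1, "negative"), 0)
  # unattainable target errors rather than silently saturating
  cfg3 <- sim_config(target_rho = c(positive = 0.9, negative = 0,
                                    unknown = 0))
  expect_error(calibrate_signature_slope(cfg3, "positive"),
               "not achievable")
})
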