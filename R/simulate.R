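# Synthetic breast-cancer cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: an
# ER-stratified tumor cohort with APOBEC3B germline copy-number states,
# negative-binomial exome mutation burdens, a TCW-concentrated C>T/C>G
# signature whose per-sample intensity is coupled to APOBEC3B expression in
# configurable strata, and promoter CpG methylation tracks.

# fixed internal seed for link calibration: calibration must be a
# deterministic function of the configuration, independent of the run seed
CALIBRATION_SEED <- 104729L
.calibration_cache <- new.env(parent = emptyenv())

default_background_trinucs <- function() {
  # genome-like composition with CpG depletion (NCG / TCG rare), normalized
  c_raw <- c(
    ACA = 0.105, ACC = 0.075, ACG = 0.020, ACT = 0.075,
    CCA = 0.090, CCC = 0.060, CCG = 0.020, CCT = 0.080,
    GCA = 0.080, GCC = 0.070, GCG = 0.020, GCT = 0.070,
    TCA = 0.090, TCC = 0.060, TCG = 0.015, TCT = 0.090
  )
  t_raw <- c(
    ATA = 0.100, ATC = 0.060, ATG = 0.090, ATT = 0.110,
    CTA = 0.060, CTC = 0.080, CTG = 0.120, CTT = 0.100,
    GTA = 0.050, GTC = 0.050, GTG = 0.080, GTT = 0.070,
    TTA = 0.070, TTC = 0.080, TTG = 0.080, TTT = 0.120
  )
  list(C = c_raw / sum(c_raw), T = t_raw / sum(t_raw))
}

default_expr_params <- function() {
  # log2 RPKM location/scale per ER stratum (positive, negative, unknown),
  # plus a tumor-vs-normal shift and clinical effects on the log2 scale
  list(
    APOBEC3B = list(
      mean_log2 = c(positive = 2.0, negative = 3.5, unknown = 2.0),
      sd_log2 = 1.0, normal_shift = -1.5, stage_slope = 0.15,
      vital_shift = 0.3
    ),
    APOBEC3C = list(
      mean_log2 = c(positive = 3.0, negative = 4.0, unknown = 3.0),
      sd_log2 = 0.8, normal_shift = 0.5, stage_slope = -0.15,
      vital_shift = -0.3
    ),
    APOBEC3G = list(
      mean_log2 = c(positive = 2.5, negative = 2.5, unknown = 2.5),
      sd_log2 = 0.8, normal_shift = 0, stage_slope = 0, vital_shift = 0
    ),
    APOBEC1 = list(
      mean_log2 = c(positive = -2, negative = -2, unknown = -2),
      sd_log2 = 0.5, normal_shift = 0, stage_slope = 0, vital_shift = 0
    )
  )
}

default_meth_params <- function() {
  list(
    spacing = 50L,       # bp between consecutive CpG sites
    depth_mean = 30,     # Poisson mean read depth per site
    cell_types = list(
      # ER- breast cancer line and normal mammary epithelium style tracks:
      # low promoter methylation, high flanking methylation
      HCC1954 = list(promoter = c(2, 8), flank = c(7, 3)),
      HMEC = list(promoter = c(1, 9), flank = c(7, 3))
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions of the emulated cohort: 915
#' tumors and 85 adjacent normals, ER+ : ER- : unknown = 72.6 : 21.4 : 6.0,
#' copy-number states 28/162/597/128 (CN0/CN1/CN2/unknown), exome data for
#' 82% of tumors, per-exome burden 57.9 +/- 50.9 (negative binomial by
#' method of moments), and an APOBEC signature (C>T or C>G in TCA/TCT)
#' whose per-sample probability follows a logistic link in standardized
#' log2 APOBEC3B expression, calibrated per stratum to the target Spearman
#' correlations (ER+ 0.32, ER- 0).
#'
#' @param n_tumor,n_normal cohort sizes.
#' @param er_fractions,cn_fractions tumor ER-status and APOBEC3B
#'   copy-number probabilities (must sum to 1).
#' @param er_fractions_normal,cn_fractions_normal same for normal tissues.
#' @param exome_fraction probability a tumor has exome (variant) data.
#' @param burden_mean,burden_sd moments of the per-exome SNV count; the
#'   negative-binomial size is `mean^2 / (sd^2 - mean)` (requires
#'   `sd^2 > mean`).
#' @param signature_baseline APOBEC-signature probability at stratum-mean
#'   expression (logistic intercept); 0 disables the signature entirely.
#' @param target_rho named per-stratum target Spearman correlation between
#'   log2 APOBEC3B expression and C>T/G>A burden; realized by calibrating
#'   the logistic slope (see [calibrate_signature_slope()]).
#' @param signature_slopes optional named per-stratum logistic slopes that
#'   bypass calibration.
#' @param sig_class_freqs substitution-class mix of signature mutations.
#' @param sig_motif_freqs motif mix of signature mutations (TCW).
#' @param background_class_freqs six-class mix of background mutations.
#' @param background_trinuc_freqs list with elements `C` and `T`: motif
#'   frequencies per center base for background mutations.
#' @param cn_expression_effect multiply expected APOBEC3B expression by
#'   copy/2 (CN unknown treated as 2 copies).
#' @param cn0_floor APOBEC3B RPKM assigned to CN0 samples (homozygous
#'   deletion); default 0.05 keeps log-scale plots finite.
#' @param apobec3c_er_neg_rho target Spearman correlation between APOBEC3C
#'   expression and C>T/G>A burden in ER- tumors (Gaussian-copula
#'   coupling; a descriptive target, not a mechanism).
#' @param stage_fractions,vital_fractions tumor stage and vital-status
#'   probabilities.
#' @param expr_params per-gene expression model parameters (see
#'   `default_expr_params()` in the package source).
#' @param meth_params CpG track parameters: `spacing`, `depth_mean`, and
#'   per-cell-type beta shapes for promoter and flank regions.
#' @param seed root RNG seed; all components draw from deterministic child
#'   streams.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(n_tumor = 915L,
                       n_normal = 85L,
                       er_fractions = c(positive = 664, negative = 196,
                                        unknown = 55) / 915,
                       cn_fractions = c(`0` = 28, `1` = 162, `2` = 597,
                                        unknown = 128) / 915,
                       er_fractions_normal = c(positive = 67, negative = 15,
                                               unknown = 3) / 85,
                       cn_fractions_normal = c(`0` = 2, `1` = 17, `2` = 66,
                                               unknown = 0) / 85,
                       exome_fraction = 750 / 915,
                       burden_mean = 57.9,
                       burden_sd = 50.9,
                       signature_baseline = 0.2,
                       target_rho = c(positive = 0.32, negative = 0,
                                      unknown = 0.32),
                       signature_slopes = NULL,
                       sig_class_freqs = c(`C>T` = 2 / 3, `C>G` = 1 / 3),
                       sig_motif_freqs = c(TCA = 0.5, TCT = 0.5),
                       background_class_freqs = c(`C>A` = 0.11, `C>G` = 0.09,
                                                  `C>T` = 0.25, `T>A` = 0.09,
                                                  `T>C` = 0.30, `T>G` = 0.16),
                       background_trinuc_freqs = default_background_trinucs(),
                       cn_expression_effect = TRUE,
                       cn0_floor = 0.05,
                       apobec3c_er_neg_rho = -0.26,
                       stage_fractions = c(I = 0.17, II = 0.45, III = 0.25,
                                           IV = 0.04, unknown = 0.09),
                       vital_fractions = c(alive = 0.86, deceased = 0.12,
                                           unknown = 0.02),
                       expr_params = default_expr_params(),
                       meth_params = default_meth_params(),
                       seed = 1L) {
  if (n_tumor < 0 || n_normal < 0) stop("cohort sizes must be non-negative")
  if (burden_mean <= 0) stop("burden_mean must be positive")
  if (burden_sd^2 <= burden_mean) {
    stop("burden_sd^2 must exceed burden_mean (negative-binomial overdispersion)")
  }
  er_fractions <- check_prob_vector(er_fractions, "er_fractions", ER_LEVELS)
  cn_fractions <- check_prob_vector(cn_fractions, "cn_fractions", CN_LEVELS)
  er_fractions_normal <- check_prob_vector(er_fractions_normal,
                                           "er_fractions_normal", ER_LEVELS)
  cn_fractions_normal <- check_prob_vector(cn_fractions_normal,
                                           "cn_fractions_normal", CN_LEVELS)
  stage_fractions <- check_prob_vector(stage_fractions, "stage_fractions",
                                       STAGE_LEVELS)
  vital_fractions <- check_prob_vector(vital_fractions, "vital_fractions",
                                       VITAL_LEVELS)
  sig_class_freqs <- check_prob_vector(sig_class_freqs, "sig_class_freqs")
  if (!all(names(sig_class_freqs) %in% c("C>T", "C>G"))) {
    stop("signature mutations must be C>T or C>G")
  }
  sig_motif_freqs <- check_prob_vector(sig_motif_freqs, "sig_motif_freqs")
  if (!all(names(sig_motif_freqs) %in% TCW_MOTIFS)) {
    stop("signature motifs must be TCW (TCA/TCT)")
  }
  background_class_freqs <- check_prob_vector(background_class_freqs,
                                              "background_class_freqs",
                                              SUB_CLASSES)
  background_trinuc_freqs$C <- check_motif_freqs(background_trinuc_freqs$C,
                                                 C_MOTIFS,
                                                 "background_trinuc_freqs$C")
  background_trinuc_freqs$T <- check_motif_freqs(background_trinuc_freqs$T,
                                                 T_MOTIFS,
                                                 "background_trinuc_freqs$T")
  if (signature_baseline < 0 || signature_baseline > 1) {
    stop("signature_baseline must be in [0, 1]")
  }
  if (exome_fraction < 0 || exome_fraction > 1) {
    stop("exome_fraction must be in [0, 1]")
  }
  if (cn0_floor < 0) stop("cn0_floor must be non-negative")
  if (is.null(names(target_rho))) {
    stop("target_rho must be named by ER stratum")
  }
  target_rho <- target_rho[ER_LEVELS]
  names(target_rho) <- ER_LEVELS
  target_rho[is.na(target_rho)] <- 0
  if (any(abs(target_rho) >= 1)) stop("target_rho values must lie in (-1, 1)")
  if (!"APOBEC3B" %in% names(expr_params)) {
    stop("expr_params must include APOBEC3B")
  }
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
      er_fractions = er_fractions, cn_fractions = cn_fractions,
      er_fractions_normal = er_fractions_normal,
      cn_fractions_normal = cn_fractions_normal,
      exome_fraction = exome_fraction,
      burden_mean = burden_mean, burden_sd = burden_sd,
      burden_size = burden_mean^2 / (burden_sd^2 - burden_mean),
      signature_baseline = signature_baseline,
      target_rho = target_rho, signature_slopes = signature_slopes,
      sig_class_freqs = sig_class_freqs, sig_motif_freqs = sig_motif_freqs,
      background_class_freqs = background_class_freqs,
      background_trinuc_freqs = background_trinuc_freqs,
      cn_expression_effect = cn_expression_effect, cn0_floor = cn0_floor,
      apobec3c_er_neg_rho = apobec3c_er_neg_rho,
      stage_fractions = stage_fractions, vital_fractions = vital_fractions,
      expr_params = expr_params, meth_params = meth_params,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# per-sample expected log2 expression for one gene given metadata rows
gene_mean_log2 <- function(gp, meta) {
  mu <- gp$mean_log2[meta$er_status]
  mu <- mu + ifelse(meta$tissue == "normal", gp$normal_shift %||% 0, 0)
  stage_num <- match(meta$stage, c("I", "II", "III", "IV"))
  mu <- mu + ifelse(is.na(stage_num) | meta$tissue == "normal", 0,
                    (gp$stage_slope %||% 0) * (stage_num - 2))
  mu <- mu + ifelse(meta$vital_status == "deceased" & meta$tissue == "tumor",
                    gp$vital_shift %||% 0, 0)
  unname(mu)
}

# copy-number multiplier on the log2 scale for APOBEC3B (unknown ~ 2 copies)
cn_log2_shift <- function(cn_state) {
  ifelse(cn_state == "1", log2(0.5), 0)
}

# draw per-sample burden and signature allocation for tumors; used both by
# the cohort generator and by the link calibration so the two agree in
# distribution
draw_signature_counts <- function(config, log2_a3b, stratum, slopes) {
  n <- length(log2_a3b)
  p <- numeric(n)
  b0 <- config$signature_baseline
  if (b0 > 0 && b0 < 1) {
    for (s in unique(stratum)) {
      idx <- stratum == s
      z <- log2_a3b[idx]
      zstd <- if (length(z) > 1 && stats::sd(z) > 0) {
        (z - mean(z)) / stats::sd(z)
      } else {
        rep(0, length(z))
      }
      p[idx] <- stats::plogis(stats::qlogis(b0) + slopes[[s]] * zstd)
    }
  } else if (b0 >= 1) {
    p[] <- 1
  }
  burden <- stats::rnbinom(n, mu = config$burden_mean, size = config$burden_size)
  n_sig <- stats::rbinom(n, burden, p)
  list(p = p, burden = burden, n_signature = n_sig)
}

# marginal C>T/G>A count given burden and signature split (lean path shared
# with calibration; the full generator realises the same distribution
# mutation by mutation)
ctga_counts <- function(config, burden, n_sig) {
  p_sig_ct <- if ("C>T" %in% names(config$sig_class_freqs)) {
    config$sig_class_freqs[["C>T"]]
  } else {
    0
  }
  p_bg_ct <- config$background_class_freqs[["C>T"]]
  stats::rbinom(length(burden), n_sig, p_sig_ct) +
    stats::rbinom(length(burden), burden - n_sig, p_bg_ct)
}

#' Calibrate the signature-link slope for a target Spearman correlation
#'
#' Solves for the logistic-link slope that makes the Spearman correlation
#' between log2 APOBEC3B expression and C>T/G>A burden match the per-stratum
#' target, by root-finding on a Monte-Carlo estimate (4000 internal samples,
#' fixed internal seed, common random numbers across slope evaluations).
#' Deterministic given the configuration and independent of the run seed;
#' results are cached on a configuration hash.
#'
#' @param config a `sim_config`.
#' @param stratum ER stratum (`"positive"`, `"negative"`, `"unknown"`).
#' @param target target Spearman correlation; 0 returns slope 0.
#' @param n_cal internal Monte-Carlo sample size.
#' @return the calibrated slope (numeric scalar).
#' @export
calibrate_signature_slope <- function(config, stratum,
                                      target = config$target_rho[[stratum]],
                                      n_cal = 4000L) {
  if (target == 0) return(0)
  if (config$signature_baseline <= 0 || config$signature_baseline >= 1) {
    stop("cannot calibrate a correlation target with signature_baseline at 0 or 1")
  }
  key <- hash_object(list(
    stratum = stratum, target = target, n_cal = n_cal,
    burden = c(config$burden_mean, config$burden_sd),
    baseline = config$signature_baseline,
    sig_cls = config$sig_class_freqs, bg_cls = config$background_class_freqs,
    expr = config$expr_params$APOBEC3B,
    cn = config$cn_fractions, cn_eff = config$cn_expression_effect,
    floor = config$cn0_floor,
    stage = config$stage_fractions, vital = config$vital_fractions
  ))
  cached <- .calibration_cache[[key]]
  if (!is.null(cached)) return(cached)
  rho_at <- function(slope) {
    with_seed(CALIBRATION_SEED, {
      meta <- data.frame(
        er_status = stratum,
        tissue = "tumor",
        cn_state = sample(CN_LEVELS, n_cal, replace = TRUE,
                          prob = config$cn_fractions),
        stage = sample(STAGE_LEVELS, n_cal, replace = TRUE,
                       prob = config$stage_fractions),
        vital_status = sample(VITAL_LEVELS, n_cal, replace = TRUE,
                              prob = config$vital_fractions),
        stringsAsFactors = FALSE
      )
      gp <- config$expr_params$APOBEC3B
      mu <- gene_mean_log2(gp, meta)
      if (config$cn_expression_effect) mu <- mu + cn_log2_shift(meta$cn_state)
      z <- stats::rnorm(n_cal, mu, gp$sd_log2)
      if (config$cn_expression_effect) {
        z[meta$cn_state == "0"] <- log2(max(config$cn0_floor,
                                            .Machine$double.xmin))
      }
      slopes <- stats::setNames(rep(list(slope), 1), stratum)
      draws <- draw_signature_counts(config, z, meta$er_status, slopes)
      y <- ctga_counts(config, draws$burden, draws$n_signature)
      stats::cor(z, y, method = "spearman")
    })
  }
  lower <- if (target > 0) 0 else -12
  upper <- if (target > 0) 12 else 0
  f <- function(s) rho_at(s) - target
  f_hi <- if (target > 0) f(upper) else f(lower)
  if ((target > 0 && f_hi < 0) || (target < 0 && f_hi > 0)) {
    stop(sprintf("target correlation %.3f not achievable in stratum %s",
                 target, stratum))
  }
  slope <- stats::uniroot(f, c(lower, upper), tol = 0.01)$root
  .calibration_cache[[key]] <- slope
  slope
}

resolve_slopes <- function(config) {
  out <- list()
  for (s in ER_LEVELS) {
    out[[s]] <- if (!is.null(config$signature_slopes)) {
      if (s %in% names(config$signature_slopes)) {
        config$signature_slopes[[s]]
      } else {
        0
      }
    } else if (config$signature_baseline > 0 && config$signature_baseline < 1 &&
               config$target_rho[[s]] != 0) {
      calibrate_signature_slope(config, s)
    } else {
      0
    }
  }
  out
}

#' Default synthetic TSS annotation for the simulator genes
#'
#' Places the configured genes on a single synthetic chromosome, 20 kb
#' apart, with alternating strands (so minus-strand bin flipping is
#' exercised).
#'
#' @param config a `sim_config`.
#' @return data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
synthetic_tss <- function(config) {
  genes <- names(config$expr_params)
  data.frame(
    gene = genes,
    chrom = "chr22",
    tss = 39e6 + (seq_along(genes) - 1L) * 20000L,
    strand = rep(c("+", "-"), length.out = length(genes)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a breast-cancer cohort with known ground truth
#'
#' Generates sample metadata, a gene x sample RPKM matrix, somatic SNVs
#' with trinucleotide contexts, and per-cell-type CpG methylation tables,
#' using deterministic child RNG streams derived from `config$seed` in this
#' order: (1) metadata, (2) expression, (3) variants, (4) methylation,
#' (5) APOBEC3C copula coupling. Identical configurations and seeds yield
#' byte-identical cohorts.
#'
#' @param config a [sim_config()].
#' @param include which components to generate (any of `"expression"`,
#'   `"variants"`, `"methylation"`); metadata is always generated. Variants
#'   require expression (the signature link needs it).
#' @param tss TSS annotation for the methylation component; defaults to
#'   [synthetic_tss()].
#' @return object of class `synthetic_cohort`: list with `metadata`,
#'   `expression`, `variants`, `methylation` and `truth` (per-sample
#'   signature probabilities, calibrated slopes, targets, config).
#' @export
simulate_cohort <- function(config,
                            include = c("expression", "variants", "methylation"),
                            tss = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  include <- match.arg(include, several.ok = TRUE)
  if ("variants" %in% include && !"expression" %in% include) {
    stop("the variant component requires the expression component")
  }
  n_t <- config$n_tumor
  n_n <- config$n_normal

  metadata <- with_seed(child_seed(config$seed, 1L), {
    tumor <- data.frame(
      sample_id = sprintf("T%04d", seq_len(n_t)),
      tissue = "tumor",
      er_status = sample(ER_LEVELS, n_t, replace = TRUE,
                         prob = config$er_fractions),
      cn_state = sample(CN_LEVELS, n_t, replace = TRUE,
                        prob = config$cn_fractions),
      stage = sample(STAGE_LEVELS, n_t, replace = TRUE,
                     prob = config$stage_fractions),
      vital_status = sample(VITAL_LEVELS, n_t, replace = TRUE,
                            prob = config$vital_fractions),
      has_exome = stats::runif(n_t) < config$exome_fraction,
      stringsAsFactors = FALSE
    )
    if (n_n > 0) {
      normal <- data.frame(
        sample_id = sprintf("N%04d", seq_len(n_n)),
        tissue = rep("normal", n_n),
        er_status = sample(ER_LEVELS, n_n, replace = TRUE,
                           prob = config$er_fractions_normal),
        cn_state = sample(CN_LEVELS, n_n, replace = TRUE,
                          prob = config$cn_fractions_normal),
        stage = rep("unknown", n_n),
        vital_status = rep("unknown", n_n),
        has_exome = rep(FALSE, n_n),
        stringsAsFactors = FALSE
      )
      rbind(tumor, normal)
    } else {
      tumor
    }
  })

  expression <- NULL
  mean_log2 <- NULL
  if ("expression" %in% include) {
    genes <- names(config$expr_params)
    mean_log2 <- vapply(genes, function(g) {
      gene_mean_log2(config$expr_params[[g]], metadata)
    }, numeric(nrow(metadata)))
    mean_log2 <- t(mean_log2)  # gene x sample
    dimnames(mean_log2) <- list(genes, metadata$sample_id)
    if (config$cn_expression_effect) {
      mean_log2["APOBEC3B", ] <- mean_log2["APOBEC3B", ] +
        cn_log2_shift(metadata$cn_state)
    }
    expression <- with_seed(child_seed(config$seed, 2L), {
      sds <- vapply(genes, function(g) config$expr_params[[g]]$sd_log2,
                    numeric(1))
      noise <- matrix(stats::rnorm(length(mean_log2)), nrow(mean_log2))
      2^(mean_log2 + noise * sds)
    })
    dimnames(expression) <- dimnames(mean_log2)
    if (config$cn_expression_effect) {
      expression["APOBEC3B", metadata$cn_state == "0"] <- config$cn0_floor
    }
  }

  variants <- NULL
  truth_samples <- NULL
  slopes <- NULL
  if ("variants" %in% include) {
    slopes <- resolve_slopes(config)
    exome <- metadata$tissue == "tumor" & metadata$has_exome
    ids <- metadata$sample_id[exome]
    strata <- metadata$er_status[exome]
    log2_a3b <- log2(pmax(expression["APOBEC3B", ids], .Machine$double.xmin))
    res <- with_seed(child_seed(config$seed, 3L), {
      draws <- draw_signature_counts(config, log2_a3b, strata, slopes)
      list(draws = draws, variants = build_variant_table(config, ids, draws))
    })
    variants <- res$variants
    truth_samples <- data.frame(
      sample = ids, p_signature = res$draws$p, burden = res$draws$burden,
      n_signature = res$draws$n_signature, stringsAsFactors = FALSE
    )
  }

  methylation <- NULL
  if ("methylation" %in% include) {
    if (is.null(tss)) tss <- synthetic_tss(config)
    methylation <- with_seed(child_seed(config$seed, 4L), {
      simulate_methylation_impl(config, tss)
    })
  }

  if (!is.null(variants) && config$apobec3c_er_neg_rho != 0 &&
      "APOBEC3C" %in% rownames(expression)) {
    expression <- with_seed(child_seed(config$seed, 5L), {
      couple_apobec3c(config, metadata, expression, mean_log2, variants)
    })
  }

  structure(
    list(
      metadata = metadata,
      expression = expression,
      variants = variants,
      methylation = methylation,
      truth = list(
        samples = truth_samples,
        slopes = slopes,
        target_rho = config$target_rho,
        apobec3c_er_neg_rho = config$apobec3c_er_neg_rho,
        config = config
      )
    ),
    class = "synthetic_cohort"
  )
}

# emit one variant row per mutation; signature mutations are C>T/C>G in TCW
# contexts, background mutations follow the configured class and motif
# frequencies; half the rows are reported on the purine strand to exercise
# strand collapse downstream
build_variant_table <- function(config, ids, draws) {
  n_sig <- draws$n_signature
  n_bg <- draws$burden - n_sig
  total <- sum(draws$burden)
  if (total == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      context = character(), stringsAsFactors = FALSE))
  }
  sample_col <- c(rep(ids, n_sig), rep(ids, n_bg))
  k_sig <- sum(n_sig)
  k_bg <- sum(n_bg)
  cls_sig <- if (k_sig) {
    sample(names(config$sig_class_freqs), k_sig, replace = TRUE,
           prob = config$sig_class_freqs)
  } else {
    character()
  }
  motif_sig <- if (k_sig) {
    sample(names(config$sig_motif_freqs), k_sig, replace = TRUE,
           prob = config$sig_motif_freqs)
  } else {
    character()
  }
  cls_bg <- if (k_bg) {
    sample(SUB_CLASSES, k_bg, replace = TRUE,
           prob = config$background_class_freqs)
  } else {
    character()
  }
  motif_bg <- character(k_bg)
  is_c <- substr(cls_bg, 1, 1) == "C"
  if (any(is_c)) {
    motif_bg[is_c] <- sample(C_MOTIFS, sum(is_c), replace = TRUE,
                             prob = config$background_trinuc_freqs$C)
  }
  if (any(!is_c)) {
    motif_bg[!is_c] <- sample(T_MOTIFS, sum(!is_c), replace = TRUE,
                              prob = config$background_trinuc_freqs$T)
  }
  cls <- c(cls_sig, cls_bg)
  motif <- c(motif_sig, motif_bg)
  ref_pyr <- substr(cls, 1, 1)
  alt_pyr <- substr(cls, 3, 3)
  flip <- stats::runif(total) < 0.5
  ref <- ifelse(flip, complement_bases(ref_pyr), ref_pyr)
  alt <- ifelse(flip, complement_bases(alt_pyr), alt_pyr)
  context <- ifelse(flip, revcomp3(motif), motif)
  pos <- sample.int(1073741824L, total, replace = FALSE)
  out <- data.frame(
    sample = sample_col, chrom = "chr1", pos = pos, ref = ref, alt = alt,
    context = context, stringsAsFactors = FALSE
  )
  out <- out[order(out$sample, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaussian-copula coupling of APOBEC3C expression to C>T/G>A burden ranks
# in ER- tumors; rho_latent = 2 sin(pi * rho_s / 6) targets the requested
# Spearman correlation
couple_apobec3c <- function(config, metadata, expression, mean_log2, variants) {
  target <- config$apobec3c_er_neg_rho
  idx <- metadata$tissue == "tumor" & metadata$er_status == "negative" &
    metadata$has_exome
  ids <- metadata$sample_id[idx]
  if (length(ids) < 3) return(expression)
  is_ct <- classify_substitution(variants$ref, variants$alt) == "C>T"
  y <- vapply(ids, function(s) sum(variants$sample == s & is_ct), numeric(1))
  u <- rank(y, ties.method = "average") / (length(y) + 1)
  zb <- stats::qnorm(u)
  zb <- (zb - mean(zb)) / max(stats::sd(zb), .Machine$double.eps)
  r_lat <- 2 * sin(pi * target / 6)
  eps <- stats::rnorm(length(ids))
  znew <- r_lat * zb + sqrt(1 - r_lat^2) * eps
  gp <- config$expr_params$APOBEC3C
  expression["APOBEC3C", ids] <- 2^(mean_log2["APOBEC3C", ids] +
                                      gp$sd_log2 * znew)
  expression
}

#' Simulate CpG methylation tables around gene TSSs
#'
#' Places CpG sites at the configured spacing across TSS +/- 5 kb for each
#' gene and cell type; each site's read depth is Poisson and its methylated
#' count is binomial with a beta-drawn ratio, using the promoter beta shapes
#' within +/- 0.5 kb of the TSS and the flank shapes elsewhere. Beta shape 0
#' in the first (second) position forces ratio 0 (1) exactly. Sites with
#' zero sampled depth are omitted.
#'
#' @param config a [sim_config()] (uses `meth_params` and `seed`).
#' @param tss_annotations data.frame with columns `gene`, `chrom`, `tss`,
#'   `strand` (non-empty).
#' @return named list (one per cell type) of data.frames with columns
#'   `chrom`, `pos`, `methylated`, `total`.
#' @export
simulate_methylation <- function(config, tss_annotations) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  with_seed(child_seed(config$seed, 4L), {
    simulate_methylation_impl(config, tss_annotations)
  })
}

simulate_methylation_impl <- function(config, tss_annotations) {
  mp <- config$meth_params
  if (is.null(tss_annotations) || !nrow(tss_annotations)) {
    stop("TSS annotation set must be non-empty")
  }
  check_columns(tss_annotations, c("gene", "chrom", "tss", "strand"),
                "tss_annotations")
  if (mp$spacing <= 0 || mp$depth_mean <= 0) {
    stop("methylation spacing and depth must be positive")
  }
  draw_beta <- function(n, shape) {
    if (shape[1] == 0) return(rep(0, n))
    if (shape[2] == 0) return(rep(1, n))
    stats::rbeta(n, shape[1], shape[2])
  }
  lapply(mp$cell_types, function(ct) {
    per_gene <- lapply(seq_len(nrow(tss_annotations)), function(i) {
      tss <- tss_annotations$tss[i]
      pos <- seq(tss - 5000L, tss + 5000L - 1L, by = mp$spacing)
      depth <- stats::rpois(length(pos), mp$depth_mean)
      promoter <- pos >= tss - 500L & pos < tss + 500L
      ratio <- numeric(length(pos))
      ratio[promoter] <- draw_beta(sum(promoter), ct$promoter)
      ratio[!promoter] <- draw_beta(sum(!promoter), ct$flank)
      meth <- stats::rbinom(length(pos), depth, ratio)
      keep <- depth > 0
      data.frame(
        chrom = tss_annotations$chrom[i], pos = pos[keep],
        methylated = meth[keep], total = depth[keep],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_gene)
    rownames(out) <- NULL
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d tumors, %d normals\n",
              sum(x$metadata$tissue == "tumor"),
              sum(x$metadata$tissue == "normal")))
  if (!is.null(x$expression)) {
    cat(sprintf("expression: %d genes x %d samples\n",
                nrow(x$expression), ncol(x$expression)))
  }
  if (!is.null(x$variants)) {
    cat(sprintf("variants: %d somatic SNVs in %d samples\n",
                nrow(x$variants), length(unique(x$variants$sample))))
  }
  if (!is.null(x$methylation)) {
    cat(sprintf("methylation: %s\n", paste(names(x$methylation), collapse = ", ")))
  }
  invisible(x)
}
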