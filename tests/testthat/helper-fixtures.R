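# Shared fixtures, built in code.

# metadata reproducing the printed cohort composition: 915 tumors
# (ER+ 664 / ER- 196 / unknown 55; CN 28/162/597/128; exome 750 yes / 165
# no) and 85 adjacent normals (ER 67/15/3; CN 2/17/66/0). Category
# assignments are marginal, so their joint arrangement is arbitrary.
published_cohort_metadata <- function() {
  tumor <- data.frame(
    sample_id = sprintf("T%04d", 1:915),
    tissue = "tumor",
    er_status = rep(c("positive", "negative", "unknown"), c(664, 196, 55)),
    cn_state = rep(c("0", "1", "2", "unknown"), c(28, 162, 597, 128)),
    vital_status = "unknown",
    stage = "unknown",
    has_exome = rep(c(TRUE, FALSE), c(750, 165)),
    stringsAsFactors = FALSE
  )
  normal <- data.frame(
    sample_id = sprintf("N%04d", 1:85),
    tissue = "normal",
    er_status = rep(c("positive", "negative", "unknown"), c(67, 15, 3)),
    cn_state = rep(c("0", "1", "2"), c(2, 17, 66)),
    vital_status = "unknown",
    stage = "unknown",
    has_exome = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(tumor, normal)
}

# random SNV table with pyrimidine- and purine-strand records
random_variants <- function(n, samples = c("S1", "S2", "S3"), seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  left <- sample(bases, n, replace = TRUE)
  right <- sample(bases, n, replace = TRUE)
  data.frame(
    sample = sample(samples, n, replace = TRUE),
    chrom = "chr1",
    pos = sample.int(1e6, n),
    ref = ref,
    alt = unname(alt),
    context = paste0(left, ref, right),
    stringsAsFactors = FALSE
  )
}

# small flat CpG site table builder
cpg_sites <- function(pos, methylated, total, chrom = "chrT") {
  data.frame(chrom = chrom, pos = pos, methylated = methylated,
             total = total, stringsAsFactors = FALSE)
}
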