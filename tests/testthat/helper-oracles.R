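# Independent brute-force oracles used to check the package implementations.
# These deliberately use different algorithms/data structures than the
# package code (recursive list permutations, bitmask subset scans, direct
# factorial formulas, lm()-based weighted fits).

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# two-sided exact Spearman p by full permutation enumeration
oracle_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(cor(rx, ry))
  vals <- vapply(oracle_perms(ry), function(p) cor(rx, p), numeric(1))
  mean(abs(vals) >= obs - 1e-9)
}

# two-sided exact rank-sum p by bitmask scan over group assignments
oracle_ranksum_p <- function(a, b) {
  N <- length(a) + length(b)
  na <- length(a)
  r <- rank(c(a, b))
  mu <- na * (N + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  ws <- numeric(0)
  for (m in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(m))[1:N]
    if (sum(bits) == na) ws <- c(ws, sum(r[bits == 1L]))
  }
  mean(abs(ws - mu) >= obs - 1e-9)
}

# two-sided exact signed-rank p by bitmask scan over sign patterns
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- sum(r) / 2
  obs <- abs(sum(r[d > 0]) - mu)
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    vs[m + 1L] <- sum(r[bits == 1L])
  }
  mean(abs(vs - mu) >= obs - 1e-9)
}

# two-sided Fisher p by direct hypergeometric formula over all tables with
# the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  m1 <- a + b; m2 <- cc + dd; k <- a + cc
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# direct tricube weighted-least-squares fit at each point via lm()
oracle_loess_fit <- function(x, y, span) {
  n <- length(x)
  q <- floor(span * n)
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  vapply(seq_len(n), function(i) {
    d <- abs(xo - xo[i])
    h <- sort(d)[q]
    if (h == 0) return(mean(yo[d == 0]))
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    if (sum(w > 0) < 2 || length(unique(xo[w > 0])) < 2) {
      return(sum(w * yo) / sum(w))
    }
    fit <- lm(yo ~ xo, weights = w)
    unname(predict(fit, data.frame(xo = xo[i])))
  }, numeric(1))
}

# naive six-class tally with an explicit complement map
oracle_class_tally <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- setNames(numeric(6), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (r %in% c("A", "G")) {
      r <- comp[[r]]; a <- comp[[a]]
    }
    key <- paste0(r, ">", a)
    out[key] <- out[key] + 1
  }
  out
}

# naive motif tally over C-centered classes
oracle_motif_tally <- function(class, motif, cls) {
  motifs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            function(a, b) paste0(a, "C", b)))
  out <- setNames(numeric(16), motifs)
  for (i in seq_along(class)) {
    if (!is.na(motif[i]) && class[i] == cls) out[motif[i]] <- out[motif[i]] + 1
  }
  out
}
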