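# Rank-based statistical primitives.
#
# Each test switches between an exhaustive-enumeration exact mode at small
# sample sizes and the classical large-sample approximation above a
# configurable crossover; ties always get average (mid) ranks and the
# approximations carry the usual tie corrections.

.perm_cache <- new.env(parent = emptyenv())
.spearman_cache <- new.env(parent = emptyenv())

# all permutations of 1..k as a k! x k integer matrix (cached; k <= 9)
all_permutations <- function(k) {
  key <- as.character(k)
  cached <- .perm_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (k == 1L) {
    out <- matrix(1L, 1L, 1L)
  } else {
    q <- all_permutations(k - 1L)
    m <- nrow(q)
    out <- matrix(0L, m * k, k)
    for (j in seq_len(k)) {
      left <- if (j > 1L) q[, 1:(j - 1L), drop = FALSE] else NULL
      right <- if (j < k) q[, j:(k - 1L), drop = FALSE] else NULL
      out[((j - 1L) * m + 1L):(j * m), ] <- cbind(left, matrix(k, m, 1L), right)
    }
  }
  .perm_cache[[key]] <- out
  out
}

# permutation values of S = sum(rx * ry[perm]); chunked on the first
# position for n = 10 so the index matrix for 9 elements is reused
spearman_perm_stats <- function(rx, ry) {
  n <- length(rx)
  if (n <= 9L) {
    P <- all_permutations(n)
    as.vector(matrix(ry[P], nrow(P), n) %*% rx)
  } else {
    P <- all_permutations(n - 1L)
    out <- vector("list", n)
    for (f in seq_len(n)) {
      rest <- ry[-f]
      out[[f]] <- rx[1L] * ry[f] +
        as.vector(matrix(rest[P], nrow(P), n - 1L) %*% rx[-1L])
    }
    unlist(out, use.names = FALSE)
  }
}

# tabulated null distribution of S, cached on the rank multisets (the
# distribution depends on the two rank vectors only through their multisets)
spearman_null_distribution <- function(rx, ry) {
  key <- paste(c(sort(rx), "|", sort(ry)), collapse = ",")
  cached <- .spearman_cache[[key]]
  if (!is.null(cached)) return(cached)
  s <- round(spearman_perm_stats(rx, ry), 6)
  tab <- table(s)
  out <- list(values = as.numeric(names(tab)), counts = as.numeric(tab))
  .spearman_cache[[key]] <- out
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks. The
#' two-sided p-value uses exhaustive permutation enumeration for
#' `n <= exact_limit` and the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom above it.
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are dropped.
#' @param exact_limit largest n for which the exact permutation null is
#'   enumerated (default 10).
#' @return list with elements `rho`, `p`, `n` and `method`. A constant input
#'   vector yields `rho = NA` with a warning (the correlation is undefined).
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_rho <- function(x, y, exact_limit = 10L) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observation pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    dist <- spearman_null_distribution(rx, ry)
    centre <- n * mean(rx) * mean(ry)
    s_obs <- sum(rx * ry)
    p <- sum(dist$counts[abs(dist$values - centre) >= abs(s_obs - centre) - 1e-8]) /
      sum(dist$counts)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration over all `choose(n, n_a)` group assignments when the
#' pooled sample has at most `exact_limit` observations and no ties;
#' otherwise the normal approximation with tie correction and a 0.5
#' continuity correction. The two-sided exact p-value is
#' `P(|W - E W| >= |W_obs - E W|)` under the permutation null.
#'
#' @param a,b numeric vectors (NAs dropped); both must be non-empty.
#' @param exact_limit largest pooled size for exact enumeration (default 12).
#' @return list with elements `W` (rank sum of `a`), `p`, `n`, `method`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a)
  nb <- length(b)
  N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (N <= exact_limit && !ties) {
    idx <- utils::combn(N, na)
    Wall <- colSums(matrix(r[idx], nrow(idx)))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-8)
    method <- "exact enumeration"
  } else {
    tt <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  list(W = W, p = p, n = c(na, nb), method = method)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Accepts either a vector of differences or two paired vectors. Zero
#' differences are removed first; with at most `exact_limit` nonzero
#' differences all `2^n` sign patterns are enumerated (ties in the absolute
#' differences get mid-ranks and the enumeration is still exhaustive),
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x differences, or the first member of each pair when `y` is given.
#' @param y optional second member of each pair.
#' @param exact_limit largest number of nonzero differences for exact
#'   enumeration (default 12).
#' @return list with `V` (positive-rank sum), `p`, `n`, `n_zero_dropped`,
#'   `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p  # 0.25
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n), KEEP.OUT.ATTRS = FALSE))
    Vall <- as.vector(signs %*% r)
    p <- mean(abs(Vall - mu) >= abs(V - mu) - 1e-8)
    method <- "exact sign enumeration"
  } else {
    tt <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- max(0, abs(V - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(V = V, p = p, n = n, n_zero_dropped = n_zero, method = method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing all hypergeometric table probabilities not
#' exceeding the observed table's probability (with the conventional
#' `1 + 1e-7` relative tolerance for floating-point ties). The reported odds
#' ratio is the sample odds ratio `ad / bc`.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return list with `odds_ratio`, `p`, `table` and `degenerate` (TRUE when
#'   any cell is zero, in which case the odds ratio may be 0, Inf or NaN).
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p  # 34/70
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("cells must be non-negative integers")
  }
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; dd <- m[2, 2]
  if (a + b == 0 || cc + dd == 0 || a + cc == 0 || b + dd == 0) {
    stop("table has a zero margin")
  }
  k <- a + cc
  xs <- max(0, k - (cc + dd)):min(k, a + b)
  dens <- stats::dhyper(xs, a + b, cc + dd, k)
  p <- sum(dens[dens <= dens[xs == a] * (1 + 1e-7)])
  list(
    odds_ratio = (a * dd) / (b * cc),
    p = min(p, 1),
    table = m,
    degenerate = any(m == 0)
  )
}

#' Tricube-weighted local linear smoother
#'
#' Fits a weighted least-squares line in a tricube-weighted neighbourhood of
#' each observation (the nearest `floor(span * n)` points) and evaluates it
#' at that observation, i.e. first-degree LOESS without robustness
#' iterations. Deterministic given the inputs and span; exactly reproduces
#' any globally linear signal.
#'
#' @param x,y numeric vectors; incomplete pairs dropped; `n >= 5` required.
#' @param span fraction of points in each local window, in (0, 1].
#' @return data.frame with columns `x` (sorted) and `fitted`.
#' @export
loess_smooth <- function(x, y, span = 0.75) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("x and y must be numeric vectors of equal length")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  q <- floor(span * n)
  if (q < 3L) stop("span too small: local windows would contain fewer than 3 points")
  ord <- order(x)
  xo <- x[ord]
  yo <- y[ord]
  fitted <- vapply(seq_len(n), function(i) {
    d <- abs(xo - xo[i])
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      w <- as.numeric(d == 0)
    } else {
      w <- (1 - pmin(d / h, 1)^3)^3
    }
    sw <- sum(w)
    xm <- sum(w * xo) / sw
    ym <- sum(w * yo) / sw
    sxx <- sum(w * (xo - xm)^2)
    if (sxx < 1e-12 * max(1, abs(xm))^2) return(ym)
    beta <- sum(w * (xo - xm) * (yo - ym)) / sxx
    ym + beta * (xo[i] - xm)
  }, numeric(1))
  data.frame(x = xo, fitted = fitted)
}
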