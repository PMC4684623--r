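# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_bases <- function(x) {
  out <- unname(DNA_COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  out
}

# reverse complement of 3-mers, vectorised; anything that is not a clean
# ACGT 3-mer comes back NA
revcomp3 <- function(x) {
  out <- paste0(
    DNA_COMPLEMENT[substr(x, 3, 3)],
    DNA_COMPLEMENT[substr(x, 2, 2)],
    DNA_COMPLEMENT[substr(x, 1, 1)]
  )
  bad <- is.na(x) | nchar(x) != 3L | grepl("NA", out, fixed = TRUE)
  out[bad] <- NA_character_
  out
}

# half-up rounding as printed in cohort summary tables (base round() is
# round-half-even, which would turn e.g. 0.25 into 0.2)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic per-component child seeds from one root seed; stream order
# is documented in ?simulate_cohort
child_seed <- function(seed, stream) {
  as.integer(((as.double(seed) %% 2147483399) * 48271 + 331 * stream) %% 2147483647)
}

# stable content hash of an R object (text-serialised, md5)
hash_object <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(x, control = c("exact")), f)
  unname(tools::md5sum(f))
}

check_prob_vector <- function(p, name, levels = NULL, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("'%s' must be a non-negative probability vector without NA", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 within %g (got %.12f)", name, tol, sum(p)),
         call. = FALSE)
  }
  if (!is.null(levels)) {
    if (is.null(names(p)) || !setequal(names(p), levels) || length(p) != length(levels)) {
      stop(sprintf("'%s' must be named with levels: %s", name,
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    p <- p[levels]
  }
  p
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad)) {
    stop(sprintf("%s contains unknown level(s): %s (allowed: %s)", what,
                 paste(sQuote(bad), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
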