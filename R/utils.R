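#' @keywords internal
"_PACKAGE"

## Derive a reproducible integer sub-seed from a master seed and a stage tag,
## so every stage draws from its own named stream. Kept < 2^31.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483647)
}

## Evaluate expr under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Column standard deviations with the sample (N-1) convention.
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu)^2) / (n - 1))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5)
}

stopifnot_aligned <- function(n, ...) {
  lens <- vapply(list(...), NROW, integer(1))
  if (any(lens != n)) {
    stop(sprintf("inputs not aligned: expected %d subjects, got %s",
                 n, paste(lens, collapse = ", ")))
  }
  invisible(TRUE)
}
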