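#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their `seed` argument
# through here so that user session RNG state is never disturbed.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("'seed' must be a single non-missing integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage seed from a master seed; kept strictly below 2^31
#' @noRd
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9973) %% 2147483647)
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stopf("'%s' must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  }
  as.integer(x)
}

#' @noRd
check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  as.numeric(x)
}

#' @noRd
check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("'%s' must be a numeric matrix", name)
  if (anyNA(x)) stopf("'%s' contains missing values", name)
  x
}

# two-sided p-value for a Pearson correlation via the exact t transform,
# n - 2 degrees of freedom; |r| = 1 maps to p = 0
#' @noRd
cor_pvalue <- function(r, n) {
  if (n < 3L) return(rep(NA_real_, length(r)))
  p <- rep(NA_real_, length(r))
  ok <- is.finite(r)
  rr <- pmin(pmax(r[ok], -1), 1)
  t <- abs(rr) * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[ok][abs(rr) >= 1] <- 0
  p
}
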