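# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Population-SD z-scoring of matrix rows: each row centred, then divided by
## sqrt(mean((x - mean)^2)). Zero-variance rows map to all-zero rows.
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  cent <- m - mu
  sd_pop <- sqrt(rowMeans(cent^2))
  zero <- sd_pop < .Machine$double.eps
  sd_pop[zero] <- 1
  z <- cent / sd_pop
  if (any(zero)) z[zero, ] <- 0
  z
}

zscore_cols <- function(m) {
  t(zscore_rows(t(as.matrix(m))))
}

## One Dirichlet draw per row of `alpha` (n x k matrix, or a vector recycled
## to n rows).
rdirichlet <- function(n, alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, n, length(alpha), byrow = TRUE)
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow(alpha), ncol(alpha))
  g / pmax(rowSums(g), .Machine$double.xmin)
}

## Euclidean cross-distances between the rows of a (m x f) and b (n x f).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be numeric in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
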