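# Independent brute-force oracles used to cross-check the implementation.

## Per-cell loop summation of index S-scores (vs the matrix product).
bf_sscores <- function(z, sets) {
  cells <- colnames(z)
  out <- matrix(NA_real_, length(cells), length(sets),
                dimnames = list(cells, names(sets)))
  for (i in seq_along(cells)) {
    for (j in names(sets)) {
      members <- intersect(sets[[j]], rownames(z))
      out[i, j] <- sum(z[members, i])
    }
  }
  out
}

## Benjamini-Hochberg step-up q-values written directly from the formula:
## q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

## Delaunay edges by the empty-circumcircle test: a triangle belongs to the
## triangulation iff no other point lies strictly inside its circumcircle.
## Assumes points in general position (no duplicates / cocircular quads).
bf_delaunay_edges <- function(x, y, tol = 1e-9) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (cmb in utils::combn(n, 3, simplify = FALSE)) {
    i <- cmb[1]; j <- cmb[2]; k <- cmb[3]
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    if (abs(d) < 1e-12) next                       # collinear triple
    s <- c(x[i]^2 + y[i]^2, x[j]^2 + y[j]^2, x[k]^2 + y[k]^2)
    ux <- (s[1] * (y[j] - y[k]) + s[2] * (y[k] - y[i]) + s[3] * (y[i] - y[j])) / d
    uy <- (s[1] * (x[k] - x[j]) + s[2] * (x[i] - x[k]) + s[3] * (x[j] - x[i])) / d
    r <- sqrt((x[i] - ux)^2 + (y[i] - uy)^2)
    others <- setdiff(seq_len(n), cmb)
    dist_others <- sqrt((x[others] - ux)^2 + (y[others] - uy)^2)
    if (all(dist_others > r * (1 - tol))) {
      edges <- rbind(edges, t(utils::combn(sort(cmb), 2)))
    }
  }
  unique(edges)
}

edge_key <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "-")
}

## Exhaustive search for the best b-knot continuous segmented fit, using
## lm() and explicit enumeration (independent of the package's search).
bf_best_knots <- function(y, b, min_seg) {
  n <- length(y)
  x <- seq_len(n)
  if (b == 0) {
    return(list(knots = integer(0), rss = sum(resid(lm(y ~ x))^2)))
  }
  cand <- seq.int(min_seg, n - min_seg)
  best <- NULL
  best_rss <- Inf
  for (cmb in utils::combn(cand, b, simplify = FALSE)) {
    if (b > 1 && any(diff(cmb) < min_seg)) next
    d <- data.frame(y = y, x = x)
    for (q in seq_along(cmb)) d[[paste0("h", q)]] <- pmax(x - cmb[q], 0)
    fit <- lm(y ~ ., data = d)
    rss <- sum(resid(fit)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- cmb
    }
  }
  list(knots = best, rss = best_rss)
}

## Small dense toy count matrix with gene names.
toy_counts <- function(values, genes, cells = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- cells %||% paste0("c", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
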