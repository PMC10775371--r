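#' Within-spot co-occurrence score
#'
#' `C(k1, k2) = (k1 + k2) * exp(-3 * (k1 - k2)^2)` on two cell-type
#' proportions within one spot: high when both types are abundant and
#' balanced (close to the `k1 = k2` axis), and at most 2 (at
#' `k1 = k2 = 1`). Symmetric in its arguments. Vectorized.
#'
#' @param k1,k2 proportions in `[0, 1]`.
#' @return numeric score(s) in `[0, 2]`.
#' @export
cooccurrence_score <- function(k1, k2) {
  stop_if_not_scalar_prob(k1, "k1")
  stop_if_not_scalar_prob(k2, "k2")
  (k1 + k2) * exp(-3 * (k1 - k2)^2)
}

validate_spot_table <- function(table, group_col = "group", tol = 1e-6) {
  stopifnot(is.data.frame(table))
  meta <- c("spot_id", "x", "y", group_col)
  absent <- setdiff(meta, names(table))
  if (length(absent)) stop("spot table lacks column(s): ", paste(absent, collapse = ", "))
  types <- setdiff(names(table), meta)
  types <- types[vapply(table[types], is.numeric, TRUE)]
  if (nrow(table)) {
    p <- as.matrix(table[types])
    if (any(p < -tol) || any(p > 1 + tol)) stop("proportions must lie in [0, 1]")
    if (any(abs(rowSums(p) - 1) > tol)) {
      stop("spot proportions must sum to 1 (tolerance ", tol, ")")
    }
  }
  types
}

#' Score co-occurrence for all cell-type pairs and compare groups
#'
#' Computes the co-occurrence score `C` for every unordered cell-type pair
#' in every spot, summarizes per group by the mean over spots, and reports
#' the group differential (first comparison group minus second) with a
#' label-permutation p-value.
#'
#' @param table spot proportion data.frame: `spot_id`, `x`, `y`, the group
#'   column, plus one proportion column per cell type (rows sum to 1).
#'   Spots are expected to be QC-gated upstream (spots are gated
#'   identically to cells; see [gate_cells()]).
#' @param group_col name of the group-label column.
#' @param compare length-2 character vector of group levels,
#'   disease/comparison group first; defaults to the two levels in order
#'   of appearance.
#' @param n_perm label permutations for the p-value (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @return list of class `"cooccurrence_result"`: `per_spot` (long
#'   data.frame of C values), `group_means` (pair x group), `differential`
#'   (pair, difference, permutation p-value). Tables with fewer than two
#'   cell types yield empty results.
#' @export
spot_cooccurrence <- function(table, group_col = "group", compare = NULL,
                              n_perm = 1000, seed = 1L) {
  types <- validate_spot_table(table, group_col)
  if (length(types) < 2) {
    return(structure(list(per_spot = data.frame(), group_means = data.frame(),
                          differential = data.frame()),
                     class = "cooccurrence_result"))
  }
  groups <- as.character(table[[group_col]])
  if (is.null(compare)) compare <- unique(groups)
  if (length(compare) != 2) stop("`compare` must name exactly two groups")
  n_g <- c(sum(groups == compare[1]), sum(groups == compare[2]))
  if (any(n_g == 0)) {
    stop("group with 0 spots: ", compare[which(n_g == 0)[1]],
         "; differential undefined")
  }
  p <- as.matrix(table[types])
  pairs <- utils::combn(types, 2)
  cmat <- apply(pairs, 2, function(pr) cooccurrence_score(p[, pr[1]], p[, pr[2]]))
  cmat <- matrix(cmat, nrow = nrow(table))
  pair_id <- paste(pairs[1, ], pairs[2, ], sep = ":")
  colnames(cmat) <- pair_id

  keep <- groups %in% compare
  g1 <- groups[keep] == compare[1]
  csub <- cmat[keep, , drop = FALSE]
  m1 <- colMeans(csub[g1, , drop = FALSE])
  m2 <- colMeans(csub[!g1, , drop = FALSE])
  diff_obs <- m1 - m2

  p_perm <- rep(NA_real_, length(diff_obs))
  if (n_perm > 0) {
    exceed <- numeric(length(diff_obs))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        sh <- sample(g1)
        d <- colMeans(csub[sh, , drop = FALSE]) - colMeans(csub[!sh, , drop = FALSE])
        exceed <- exceed + (abs(d) >= abs(diff_obs) - 1e-15)
      }
    })
    p_perm <- (1 + exceed) / (n_perm + 1)
  }

  per_spot <- data.frame(spot_id = rep(table$spot_id, times = ncol(cmat)),
                         group = rep(groups, times = ncol(cmat)),
                         type1 = rep(pairs[1, ], each = nrow(table)),
                         type2 = rep(pairs[2, ], each = nrow(table)),
                         C = as.vector(cmat))
  gm <- data.frame(type1 = pairs[1, ], type2 = pairs[2, ],
                   mean_1 = m1, mean_2 = m2, row.names = NULL)
  names(gm)[3:4] <- paste0("mean_", compare)
  structure(list(per_spot = per_spot,
                 group_means = gm,
                 differential = data.frame(type1 = pairs[1, ], type2 = pairs[2, ],
                                           difference = unname(diff_obs),
                                           p_value = p_perm, row.names = NULL),
                 compare = compare),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  if (!nrow(x$differential)) {
    cat("co-occurrence result: no cell-type pairs\n")
    return(invisible(x))
  }
  cat(sprintf("co-occurrence differential (%s - %s), top pairs:\n",
              x$compare[1], x$compare[2]))
  d <- x$differential[order(-abs(x$differential$difference)), ]
  print(utils::head(d, 10), row.names = FALSE)
  invisible(x)
}

#' Within-spot cell-type correlation matrix
#'
#' Pearson correlation between cell-type proportion columns across spots.
#' Zero-variance types give `NA` rows/columns.
#'
#' @param table spot proportion data.frame (>= 3 spots).
#' @param group_col group column name (only used to locate type columns).
#' @return type x type correlation matrix.
#' @export
within_spot_correlation <- function(table, group_col = "group") {
  types <- validate_spot_table(table, group_col)
  if (nrow(table) < 3) stop("need at least 3 spots")
  p <- as.matrix(table[types])
  rho <- suppressWarnings(stats::cor(p, method = "pearson"))
  zero_var <- apply(p, 2, function(v) stats::sd(v) == 0)
  rho[zero_var, ] <- NA_real_
  rho[, zero_var] <- NA_real_
  rho
}

#' Spot adjacency from coordinates
#'
#' Two spots are adjacent when their distance is at most `factor` times
#' the median nearest-neighbor distance — on a regular hexagonal grid this
#' captures the 6 packed neighbors while tolerating missing spots.
#'
#' @param x,y spot coordinates.
#' @param factor multiple of the median nearest-neighbor distance.
#' @return two-column integer matrix of adjacent spot index pairs (i < j).
#' @export
spot_adjacency <- function(x, y, factor = 1.5) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  idx <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Next-spot (neighbor) cell-type correlation matrix
#'
#' For every ordered pair of adjacent spots `(a, b)` and every type pair
#' `(t, u)`, correlates the proportion of `t` in spot `a` with the
#' proportion of `u` in neighbor `b` (Pearson, over all ordered adjacent
#' pairs; both directions are included, so the matrix is symmetric).
#' Isolated spots drop out; an entirely isolated table is an error.
#'
#' @param table spot proportion data.frame.
#' @param adjacency optional adjacency pairs from [spot_adjacency()];
#'   computed from the coordinates when `NULL`.
#' @param group_col group column name.
#' @param factor passed to [spot_adjacency()].
#' @return type x type correlation matrix (`NA` where a side has zero
#'   variance).
#' @export
next_spot_correlation <- function(table, adjacency = NULL, group_col = "group",
                                  factor = 1.5) {
  types <- validate_spot_table(table, group_col)
  if (is.null(adjacency)) adjacency <- spot_adjacency(table$x, table$y, factor)
  if (nrow(adjacency) == 0) stop("no adjacent spots (all spots isolated)")
  a <- c(adjacency[, 1], adjacency[, 2])    # ordered pairs, both directions
  b <- c(adjacency[, 2], adjacency[, 1])
  p <- as.matrix(table[types])
  rho <- suppressWarnings(stats::cor(p[a, , drop = FALSE], p[b, , drop = FALSE],
                                     method = "pearson"))
  za <- apply(p[a, , drop = FALSE], 2, function(v) stats::sd(v) == 0)
  zb <- apply(p[b, , drop = FALSE], 2, function(v) stats::sd(v) == 0)
  rho[za, ] <- NA_real_
  rho[, zb] <- NA_real_
  rho
}
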