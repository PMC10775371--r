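#' Build Delaunay cell-contact graphs
#'
#' Per tissue, builds the Delaunay triangulation of the segmented-cell
#' coordinates and keeps its unique edges with Euclidean lengths as
#' potential cell-cell interactions. Cells labeled `"Unknown"` (or `NA`)
#' are excluded before triangulation; duplicate coordinates are
#' deduplicated with a warning; tissues with fewer than 3 usable cells or
#' with all cells collinear are skipped with a warning.
#'
#' @param cells data.frame with columns `x`, `y`, `cell_type`, and
#'   optionally `cell_id`, `tissue_id` (single tissue assumed when absent)
#'   and `condition`.
#' @return named list of `"cell_graph"` objects (one per tissue), each with
#'   `cells` (data.frame) and `edges` (data.frame `from`, `to`, `length`;
#'   indices into `cells`). Single-tissue input still returns a length-1
#'   list.
#' @export
build_delaunay <- function(cells) {
  stopifnot(is.data.frame(cells), all(c("x", "y", "cell_type") %in% names(cells)))
  if (!"tissue_id" %in% names(cells)) cells$tissue_id <- "tissue1"
  if (!"cell_id" %in% names(cells)) cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
  unknown <- is.na(cells$cell_type) | cells$cell_type == "Unknown"
  if (any(unknown)) {
    message("excluding ", sum(unknown), " Unknown/unlabeled cell(s) before triangulation")
    cells <- cells[!unknown, , drop = FALSE]
  }
  out <- list()
  for (tis in unique(cells$tissue_id)) {
    sub <- cells[cells$tissue_id == tis, , drop = FALSE]
    dup <- duplicated(sub[, c("x", "y")])
    if (any(dup)) {
      warning("tissue '", tis, "': ", sum(dup),
              " duplicate coordinate(s) removed", call. = FALSE)
      sub <- sub[!dup, , drop = FALSE]
    }
    if (nrow(sub) < 3 || collinear(sub$x, sub$y)) {
      warning("tissue '", tis, "' skipped: fewer than 3 non-collinear cells",
              call. = FALSE)
      next
    }
    tri <- deldir::deldir(sub$x, sub$y, suppressMsge = TRUE)
    e <- tri$delsgs
    from <- pmin(e$ind1, e$ind2)
    to <- pmax(e$ind1, e$ind2)
    keep <- !duplicated(cbind(from, to)) & from != to
    edges <- data.frame(from = from[keep], to = to[keep])
    edges$length <- sqrt((sub$x[edges$from] - sub$x[edges$to])^2 +
                           (sub$y[edges$from] - sub$y[edges$to])^2)
    rownames(sub) <- NULL
    out[[tis]] <- structure(list(cells = sub, edges = edges, tissue_id = tis),
                            class = "cell_graph")
  }
  out
}

collinear <- function(x, y, tol = 1e-9) {
  if (length(x) < 3) return(TRUE)
  m <- cbind(x - mean(x), y - mean(y))
  sv <- svd(m, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Prune improbably long graph edges
#'
#' Removes edges strictly longer than the tissue's own `percentile`-th
#' edge-length quantile (linear-interpolation quantile); thresholds are
#' computed per tissue. `percentile = 100` is the identity.
#'
#' @param graph a `"cell_graph"` or list of them (from [build_delaunay()]).
#' @param percentile edge-length percentile in `(0, 100]` (default 99).
#' @return pruned graph(s) of the same shape; each graph carries the
#'   threshold as attribute `"prune_threshold"`.
#' @export
prune_edges <- function(graph, percentile = 99) {
  if (!inherits(graph, "cell_graph")) {
    return(lapply(graph, prune_edges, percentile = percentile))
  }
  if (nrow(graph$edges) == 0) stop("graph has no edges")
  thr <- stats::quantile(graph$edges$length, percentile / 100, type = 7, names = FALSE)
  graph$edges <- graph$edges[graph$edges$length <= thr, , drop = FALSE]
  rownames(graph$edges) <- NULL
  attr(graph, "prune_threshold") <- thr
  graph
}

#' Cell-type interaction matrix from contact graphs
#'
#' `a[i, j]` counts the graph edges whose endpoint types are `{i, j}`,
#' aggregated over all supplied tissues (e.g. all tissues of one
#' condition). Same-type edges fill the diagonal (counted once); the
#' matrix is symmetric by construction.
#'
#' @param graphs a `"cell_graph"` or list of them.
#' @param types optional type universe for the matrix dimensions.
#' @return symmetric type x type integer matrix with attribute
#'   `"n_edges"`.
#' @export
interaction_matrix <- function(graphs, types = NULL) {
  if (inherits(graphs, "cell_graph")) graphs <- list(graphs)
  seen <- unique(unlist(lapply(graphs, function(g) g$cells$cell_type)))
  if (is.null(types)) types <- sort(seen)
  if (length(setdiff(seen, types))) {
    stop("cell type(s) outside the given universe: ",
         paste(setdiff(seen, types), collapse = ", "))
  }
  a <- matrix(0, length(types), length(types), dimnames = list(types, types))
  n_edges <- 0L
  for (g in graphs) {
    if (any(is.na(g$cells$cell_type) | g$cells$cell_type == "Unknown")) {
      stop("graph contains Unknown/unlabeled cells; exclude them first")
    }
    t1 <- g$cells$cell_type[g$edges$from]
    t2 <- g$cells$cell_type[g$edges$to]
    n_edges <- n_edges + length(t1)
    for (e in seq_along(t1)) {
      a[t1[e], t2[e]] <- a[t1[e], t2[e]] + 1
      if (t1[e] != t2[e]) a[t2[e], t1[e]] <- a[t2[e], t1[e]] + 1
    }
  }
  attr(a, "n_edges") <- n_edges
  a
}

#' Column-normalize an interaction matrix
#'
#' Divides each column by its sum; zero columns stay zero (every nonzero
#' column of the result sums to 1).
#'
#' @param m interaction matrix.
#' @return column-normalized matrix.
#' @export
normalize_interactions <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

#' Disease/healthy interaction fold-change matrix
#'
#' Pads both matrices to the union of their type universes, column-
#' normalizes each (after an optional pseudocount on the raw counts), and
#' divides elementwise: `FC = disease / healthy`. FC above 1 marks
#' interactions more pronounced in diseased tissue. Entries with a zero
#' healthy denominator are reported as `NA` (flagged in `undefined`)
#' rather than infinity. When the FC matrix is complete, a hierarchical
#' clustering order (Euclidean distance) is attached as ordering metadata.
#'
#' @param healthy,disease raw interaction matrices
#'   ([interaction_matrix()]).
#' @param pseudocount constant added to the raw counts before
#'   normalization for users wanting dense output (default 0).
#' @return list of class `"interaction_fc"`: `fc`, `healthy_norm`,
#'   `disease_norm`, `undefined` (logical mask), and `cluster_order`
#'   (or `NULL`).
#' @export
normalize_and_fold_change <- function(healthy, disease, pseudocount = 0) {
  types <- sort(union(colnames(healthy), colnames(disease)))
  pad <- function(m) {
    out <- matrix(0, length(types), length(types), dimnames = list(types, types))
    out[rownames(m), colnames(m)] <- m
    out + pseudocount
  }
  h <- normalize_interactions(pad(healthy))
  d <- normalize_interactions(pad(disease))
  fc <- d / h
  undefined <- h == 0
  fc[undefined] <- NA_real_
  order <- NULL
  if (!anyNA(fc) && ncol(fc) >= 2) {
    order <- stats::hclust(stats::dist(fc, method = "euclidean"))$order
  }
  structure(list(fc = fc, healthy_norm = h, disease_norm = d,
                 undefined = undefined, cluster_order = order),
            class = "interaction_fc")
}

#' @export
print.interaction_fc <- function(x, ...) {
  cat("interaction fold-change matrix (disease / healthy), ",
      ncol(x$fc), " types, ", sum(x$undefined), " undefined entries\n", sep = "")
  print(round(x$fc, 3))
  invisible(x)
}
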