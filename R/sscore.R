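#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a common total (`scale_total`) and then
#' `log1p`-transformed. Cells with zero total counts (which QC gating
#' should have removed) become all-zero columns with a warning.
#'
#' @param counts genes x cells raw count matrix (sparse or dense).
#' @param scale_total per-cell target total after scaling.
#' @return matrix of the same shape (sparse stays sparse).
#' @export
lognormalize <- function(counts, scale_total = 1e4) {
  total <- Matrix::colSums(counts)
  zero <- total == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count cell(s); their normalized rows are all zero",
            call. = FALSE)
    total[zero] <- 1
  }
  scaled <- counts %*% Matrix::Diagonal(x = scale_total / total)
  dimnames(scaled) <- dimnames(counts)
  log1p(scaled)
}

#' Convert expression to per-gene Z-scores
#'
#' Every gene (row) is standardized across cells to mean 0 and SD 1, using
#' the population SD (divide by n). Zero-variance genes map to all-zero
#' rows rather than being dropped, preserving gene-index membership counts.
#'
#' @param m genes x cells matrix, normally log-normalized.
#' @param sd_type `"population"` (default) or `"sample"` SD.
#' @return dense genes x cells matrix of Z-scores.
#' @export
zscore_genes <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  z <- zscore_rows(m)
  if (sd_type == "sample") {
    n <- ncol(m)
    if (n > 1) z <- z * sqrt((n - 1) / n)
  }
  z
}

#' Build a gene-index encoding matrix from gene sets
#'
#' Encodes a named list of gene sets as a binary genes x indices matrix
#' `E`, with `E[g, j] = 1` iff gene `g` belongs to index `j`.
#'
#' @param sets named list of character vectors.
#' @return binary integer matrix (genes x indices).
#' @export
catalog_from_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  e <- matrix(0L, length(genes), length(sets), dimnames = list(genes, names(sets)))
  for (j in names(sets)) e[unique(sets[[j]]), j] <- 1L
  e
}

#' Compute index S-scores
#'
#' Multiplies the per-gene Z-score matrix by a binary gene x index encoding
#' matrix: the S-score of index `j` in cell `i` is the sum of cell `i`'s
#' Z-scores over the member genes of `j`. Genes are aligned by name (inner
#' join), so gene order is irrelevant; indices with no member gene present
#' in the data are dropped with a warning.
#'
#' @param z genes x cells Z-score matrix (see [zscore_genes()]).
#' @param catalog genes x indices binary encoding matrix
#'   ([catalog_from_sets()]) or a named list of gene sets.
#' @return cells x indices S-score matrix with attribute `"n_genes_used"`
#'   (member genes present in the data, per index).
#' @export
compute_sscores <- function(z, catalog) {
  if (is.list(catalog)) catalog <- catalog_from_sets(catalog)
  if (is.null(rownames(z)) || is.null(rownames(catalog))) {
    stop("both Z matrix and catalog need gene rownames")
  }
  shared <- intersect(rownames(z), rownames(catalog))
  if (!length(shared)) {
    stop("no genes shared between data and catalog '",
         paste(utils::head(colnames(catalog), 3), collapse = ","), "...'")
  }
  e <- catalog[shared, , drop = FALSE]
  used <- colSums(e != 0)
  if (any(used == 0)) {
    warning("dropping ", sum(used == 0), " index(es) with no member gene present: ",
            paste(utils::head(colnames(e)[used == 0], 5), collapse = ", "),
            call. = FALSE)
    e <- e[, used > 0, drop = FALSE]
    used <- used[used > 0]
  }
  s <- as.matrix(Matrix::crossprod(z[shared, , drop = FALSE], e))
  attr(s, "n_genes_used") <- used
  s
}

#' Score a Type I interferon-stimulated gene signature
#'
#' Convenience wrapper around [compute_sscores()] with a one-index catalog:
#' the per-cell score is the sum of Z-scores over the supplied
#' interferon-stimulated genes (e.g. a user's 21-gene ISG list). When cell
#' labels are supplied, per-label mean scores are attached.
#'
#' @param z genes x cells Z-score matrix.
#' @param genes character vector of signature genes (>= 1 present in data).
#' @param cell_labels optional per-cell labels (length `ncol(z)`).
#' @return numeric per-cell score; with labels, attribute `"by_label"`
#'   holds per-label means.
#' @export
score_ifn_signature <- function(z, genes, cell_labels = NULL) {
  s <- compute_sscores(z, list(IFN_I = genes))
  score <- stats::setNames(s[, "IFN_I"], rownames(s))
  if (!is.null(cell_labels)) {
    stopifnot(length(cell_labels) == length(score))
    attr(score, "by_label") <- vapply(split(score, cell_labels), mean, 0)
  }
  score
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, "", 1))
}

#' Crosstab S-score clusters against prior labels
#'
#' Hook comparing a clustering computed on S-scores (by any external
#' community-detection routine) with prior annotations. The embedding and
#' clustering algorithms themselves are deliberately not re-implemented
#' here; any per-cell cluster vector is accepted.
#'
#' @param sscore_clusters per-cell cluster ids from the S-score space.
#' @param prior_labels per-cell prior annotations.
#' @return contingency table (clusters x prior labels).
#' @export
crosstab_clusters <- function(sscore_clusters, prior_labels) {
  stopifnot(length(sscore_clusters) == length(prior_labels))
  table(sscore_cluster = sscore_clusters, prior = prior_labels)
}
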