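#' Quality-control thresholds
#'
#' Per-cell gates on a raw count matrix. Defaults are the study gates:
#' below 15% mitochondrial reads, below 50% ribosomal reads, below 5%
#' hemoglobin-gene reads, at least 10 detected genes and at least 100 total
#' counts. Percent gates are strict upper bounds (a cell exactly at 15%
#' mitochondrial reads is removed); count gates are inclusive lower bounds.
#'
#' @param max_mito_pct,max_ribo_pct,max_hb_pct percent upper bounds in
#'   `[0, 100]`.
#' @param min_genes,min_counts inclusive lower bounds (non-negative).
#' @return list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(max_mito_pct = 15, max_ribo_pct = 50, max_hb_pct = 5,
                          min_genes = 10, min_counts = 100) {
  pcts <- c(max_mito_pct, max_ribo_pct, max_hb_pct)
  if (any(!is.finite(pcts)) || any(pcts < 0) || any(pcts > 100)) {
    stop("percent thresholds must lie in [0, 100]")
  }
  if (min_genes < 0 || min_counts < 0) stop("count thresholds must be >= 0")
  structure(list(max_mito_pct = max_mito_pct, max_ribo_pct = max_ribo_pct,
                 max_hb_pct = max_hb_pct, min_genes = min_genes,
                 min_counts = min_counts),
            class = "qc_thresholds")
}

#' Default gene-class detection for real data
#'
#' Mitochondrial genes by the `MT-` symbol prefix, ribosomal by `RPS`/`RPL`,
#' hemoglobin by an explicit symbol list. Synthetic fixtures instead carry
#' their gene classes explicitly.
#'
#' @param genes character vector of gene symbols.
#' @return list with `mito`, `ribo`, `hb` character vectors.
#' @export
default_gene_classes <- function(genes) {
  hb_list <- c("HBA1", "HBA2", "HBB", "HBD", "HBE1",
               "HBG1", "HBG2", "HBM", "HBQ1", "HBZ")
  list(mito = grep("^MT-", genes, value = TRUE),
       ribo = grep("^RP[SL]", genes, value = TRUE),
       hb   = intersect(hb_list, genes))
}

#' Compute per-cell QC metrics
#'
#' For each cell: total counts, number of detected genes (count > 0), and
#' the percentage of counts falling in each gene class
#' (`100 * class_counts / total_counts`). Cells with zero total counts get
#' 0% for every class (they fail the minimum-count gate instead of raising
#' a division error).
#'
#' @param counts genes x cells count matrix (sparse or dense), or a
#'   [synth_expression()] object (its carried gene classes are used).
#' @param gene_classes list of character vectors (`mito`, `ribo`, `hb`);
#'   defaults to [default_gene_classes()] on the rownames. Genes missing
#'   from the matrix are allowed and warned about.
#' @return data.frame of class `"qc_report"`: `cell_id`, `total_counts`,
#'   `n_genes`, `pct_mito`, `pct_ribo`, `pct_hb`.
#' @export
compute_qc_metrics <- function(counts, gene_classes = NULL) {
  if (inherits(counts, "synth_expression")) {
    if (is.null(gene_classes)) gene_classes <- counts$gene_classes
    counts <- counts$counts
  }
  if (is.null(rownames(counts))) stop("count matrix must have gene rownames")
  if (is.null(gene_classes)) gene_classes <- default_gene_classes(rownames(counts))
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  pct <- function(class_genes) {
    missing <- setdiff(class_genes, rownames(counts))
    if (length(missing)) {
      warning(length(missing), " gene-class gene(s) absent from matrix: ",
              paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    present <- intersect(class_genes, rownames(counts))
    cls <- if (length(present)) {
      Matrix::colSums(counts[present, , drop = FALSE])
    } else {
      rep(0, length(total))
    }
    ifelse(total > 0, 100 * cls / total, 0)
  }
  rep <- data.frame(cell_id = colnames(counts) %||% as.character(seq_along(total)),
                    total_counts = as.numeric(total),
                    n_genes = as.numeric(n_genes),
                    pct_mito = pct(gene_classes$mito %||% character(0)),
                    pct_ribo = pct(gene_classes$ribo %||% character(0)),
                    pct_hb   = pct(gene_classes$hb %||% character(0)))
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Gate cells on QC metrics
#'
#' Retains cells with `pct_mito < max_mito_pct`, `pct_ribo < max_ribo_pct`,
#' `pct_hb < max_hb_pct`, `n_genes >= min_genes` and
#' `total_counts >= min_counts`; a cell fails iff at least one rule fails.
#' Spot tables are gated identically to cells. Column order of the matrix
#' is preserved.
#'
#' @param counts genes x cells count matrix or [synth_expression()] object.
#' @param report a [compute_qc_metrics()] report for the same matrix
#'   (recomputed when `NULL`).
#' @param thresholds a [qc_thresholds()].
#' @param gene_classes passed to [compute_qc_metrics()] when recomputing.
#' @return list of class `"qc_gate"`: `counts` (filtered matrix), `retained`
#'   (logical per cell), `report`, and `exclusions` (per-rule failure tally,
#'   with multiplicity).
#' @export
gate_cells <- function(counts, report = NULL, thresholds = qc_thresholds(),
                       gene_classes = NULL) {
  synth <- NULL
  if (inherits(counts, "synth_expression")) {
    synth <- counts
    if (is.null(gene_classes)) gene_classes <- synth$gene_classes
    counts <- synth$counts
  }
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (is.null(report)) report <- compute_qc_metrics(counts, gene_classes)
  if (nrow(report) != ncol(counts)) {
    stop("QC report has ", nrow(report), " cells but matrix has ", ncol(counts))
  }
  fail <- cbind(mito = report$pct_mito >= thresholds$max_mito_pct,
                ribo = report$pct_ribo >= thresholds$max_ribo_pct,
                hb = report$pct_hb >= thresholds$max_hb_pct,
                low_genes = report$n_genes < thresholds$min_genes,
                low_counts = report$total_counts < thresholds$min_counts)
  retained <- rowSums(fail) == 0
  if (!any(retained)) warning("all cells removed by QC gates", call. = FALSE)
  out <- list(counts = counts[, retained, drop = FALSE],
              retained = retained,
              report = report,
              exclusions = data.frame(rule = colnames(fail),
                                      n_failed = colSums(fail)))
  if (!is.null(synth)) out$cells <- synth$cells[retained, , drop = FALSE]
  class(out) <- "qc_gate"
  out
}

#' @export
print.qc_gate <- function(x, ...) {
  cat(sprintf("QC gate: %d / %d cells retained\n",
              sum(x$retained), length(x$retained)))
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}
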