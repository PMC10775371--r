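#' Per-patient cell-type proportion table
#'
#' Cross-tabulates cells by patient and annotation, then row-normalizes so
#' every patient row sums to 1; types absent in a patient get 0. Patients
#' with zero cells are dropped with a warning.
#'
#' @param cells data.frame with one row per cell.
#' @param patient_col,type_col column names of the patient and annotation
#'   labels.
#' @param group_col optional column with the patient-level group label
#'   (e.g. diagnosis); must be constant within patient.
#' @return list of class `"proportion_table"`: `proportions` (patients x
#'   types matrix), `n_cells` (per patient), and `groups` (named character
#'   or `NULL`).
#' @export
proportion_table <- function(cells, patient_col = "patient",
                             type_col = "cell_type", group_col = NULL) {
  stopifnot(is.data.frame(cells),
            all(c(patient_col, type_col) %in% names(cells)))
  if (anyNA(cells[[patient_col]]) || anyNA(cells[[type_col]])) {
    stop("every cell needs a patient and a type label")
  }
  tab <- table(cells[[patient_col]], cells[[type_col]])
  n_cells <- rowSums(tab)
  if (any(n_cells == 0)) {
    warning("dropping ", sum(n_cells == 0), " patient(s) with 0 cells",
            call. = FALSE)
    tab <- tab[n_cells > 0, , drop = FALSE]
    n_cells <- n_cells[n_cells > 0]
  }
  props <- sweep(unclass(tab), 1, n_cells, "/")
  groups <- NULL
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(cells))
    map <- unique(cells[, c(patient_col, group_col)])
    if (anyDuplicated(map[[patient_col]])) {
      stop("group label must be constant within patient")
    }
    groups <- stats::setNames(as.character(map[[group_col]]),
                              as.character(map[[patient_col]]))
    groups <- groups[rownames(props)]
  }
  structure(list(proportions = props, n_cells = n_cells, groups = groups),
            class = "proportion_table")
}

#' Test cell-type proportion differences between groups
#'
#' Per cell type, a two-sided two-sample t-test (Welch by default) between
#' the per-patient proportions of the two groups, followed by
#' Benjamini-Hochberg correction across all tested types (one family per
#' call); q-values below 0.05 are flagged significant. Types with zero
#' variance in both groups get p = 1 with a warning.
#'
#' @param ptab a [proportion_table()] (or a patients x types matrix).
#' @param groups per-patient group labels (taken from `ptab` when `NULL`).
#' @param compare length-2 character vector, comparison group first; fold
#'   change is `mean(compare[1]) / mean(compare[2])`. Defaults to the two
#'   levels in order of appearance.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param alpha q-value significance threshold.
#' @return data.frame of class `"proportion_test"`: per type the group
#'   means, fold change, t statistic, `p_value`, BH `q_value` and
#'   `significant` flag.
#' @export
test_proportions <- function(ptab, groups = NULL, compare = NULL,
                             var_equal = FALSE, alpha = 0.05) {
  props <- if (inherits(ptab, "proportion_table")) ptab$proportions else as.matrix(ptab)
  if (is.null(groups) && inherits(ptab, "proportion_table")) groups <- ptab$groups
  if (is.null(groups)) stop("per-patient group labels are required")
  if (!is.null(names(groups)) && !is.null(rownames(props))) {
    groups <- groups[rownames(props)]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(props))
  if (is.null(compare)) compare <- unique(groups)
  if (length(compare) != 2) stop("`compare` must name exactly two groups")
  i1 <- groups == compare[1]
  i2 <- groups == compare[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("both groups need at least 2 patients")

  res <- lapply(colnames(props), function(ty) {
    a <- props[i1, ty]
    b <- props[i2, ty]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      warning("type '", ty, "' has zero variance in both groups; p = 1",
              call. = FALSE)
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                     error = function(e) list(statistic = 0, p.value = 1))
    }
    data.frame(cell_type = ty, mean_1 = mean(a), mean_2 = mean(b),
               fold_change = mean(a) / mean(b),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  res <- do.call(rbind, res)
  names(res)[2:3] <- paste0("mean_", compare)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < alpha
  class(res) <- c("proportion_test", "data.frame")
  attr(res, "compare") <- compare
  res
}
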