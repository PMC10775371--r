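#' @name tacit
#' @title Signature-based cell-type annotation of multiplex marker tables
#'
#' @description
#' TACIT assigns cell types to segmented cells from multiplex imaging using
#' a marker x cell-type signature matrix. Per cell type it: (1) groups
#' cells into many small seed clusters of z-normalized marker profiles;
#' (2) ranks the seed clusters by their median Cell Type Relevance (CTR)
#' score, the dot product of a cell's z-scored intensities with the type's
#' signature column; (3) fits segmented linear regressions with up to three
#' breakpoints to the ranked median curve, choosing the breakpoint count by
#' AIC; (4) labels clusters below the lowest breakpoint the low-relevance
#' group (LRG) and above the highest the high-relevance group (HRG); and
#' (5) sets the CTR cutoff to the value minimizing LRG/HRG classification
#' error. Cells passing a cutoff are marked in a binary cell-type matrix
#' (CTM); deeper-granularity subtypes are AND-gated on single-marker
#' positivity, and cells with multiple identities are resolved by majority
#' vote among their k nearest "clean" neighbors in the space of the
#' relevant markers.
NULL

## --- signature matrix -------------------------------------------------

validate_signature <- function(signature) {
  if (!is.matrix(signature) || is.null(rownames(signature)) ||
      is.null(colnames(signature))) {
    stop("signature must be a matrix with marker rownames and cell-type colnames")
  }
  if (any(signature < 0) || any(signature != round(signature))) {
    stop("signature entries must be non-negative integers (0/1/granularity level)")
  }
  empty <- colSums(signature >= 1) == 0
  if (any(empty)) {
    stop("signature column(s) with no defining marker: ",
         paste(colnames(signature)[empty], collapse = ", "))
  }
  invisible(signature)
}

#' Identify parent types of deeper-granularity signature columns
#'
#' A column with any entry >= 2 is a subtype; its parent is the column
#' without level->=2 entries whose defining markers equal the subtype's
#' level-1 markers (e.g. a T-cell column for CD4/CD8 subtypes). `NA` when
#' no such column exists.
#'
#' @param signature validated signature matrix.
#' @return named character vector, subtype -> parent type (or `NA`).
#' @export
signature_parents <- function(signature) {
  subs <- colnames(signature)[apply(signature >= 2, 2, any)]
  base_cols <- setdiff(colnames(signature), subs)
  out <- stats::setNames(rep(NA_character_, length(subs)), subs)
  for (sub in subs) {
    l1 <- rownames(signature)[signature[, sub] == 1]
    for (p in base_cols) {
      if (setequal(rownames(signature)[signature[, p] >= 1], l1)) {
        out[sub] <- p
        break
      }
    }
  }
  out
}

## --- step 0: z-normalization and CTR ----------------------------------

#' Z-normalize marker intensities
#'
#' Standardizes every marker column to mean 0 and SD 1 (population SD).
#' Zero-variance markers become all-zero columns with a warning.
#'
#' @param table data.frame with one row per cell (metadata columns
#'   `cell_id`, `x`, `y`, `tissue_id`, `condition` are ignored) or a
#'   numeric cells x markers matrix.
#' @param markers optional marker subset/order to use.
#' @return dense cells x markers matrix of z-scores (rownames = cell ids
#'   when available).
#' @export
znormalize_intensities <- function(table, markers = NULL) {
  if (is.data.frame(table)) {
    meta <- intersect(c("cell_id", "x", "y", "tissue_id", "condition"),
                      names(table))
    cols <- markers %||% setdiff(names(table), meta)
    absent <- setdiff(cols, names(table))
    if (length(absent)) {
      stop("marker column(s) absent: ", paste(absent, collapse = ", "))
    }
    bad <- cols[!vapply(table[cols], is.numeric, TRUE)]
    if (length(bad)) stop("non-numeric marker column: ", paste(bad, collapse = ", "))
    m <- as.matrix(table[cols])
    if ("cell_id" %in% names(table)) rownames(m) <- table$cell_id
  } else {
    m <- as.matrix(table)
    if (!is.numeric(m)) stop("intensity matrix must be numeric")
    if (!is.null(markers)) m <- m[, markers, drop = FALSE]
  }
  if (nrow(m) == 0) return(m)
  sds <- apply(m, 2, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(sds < .Machine$double.eps)) {
    warning("zero-variance marker(s) mapped to zero: ",
            paste(colnames(m)[sds < .Machine$double.eps], collapse = ", "),
            call. = FALSE)
  }
  zscore_cols(m)
}

#' Compute Cell Type Relevance (CTR) scores
#'
#' `CTR = Z %*% binarized(signature)`: the CTR of a cell for a type is the
#' sum of the cell's marker z-scores over the type's defining markers (any
#' signature level >= 1 counts; levels >= 2 gate deconvolution later, not
#' scoring). Markers are aligned by name.
#'
#' @param z cells x markers z-score matrix.
#' @param signature marker x cell-type signature matrix.
#' @return cells x cell-types CTR matrix.
#' @export
compute_ctr <- function(z, signature) {
  validate_signature(signature)
  shared <- intersect(colnames(z), rownames(signature))
  if (!length(shared)) stop("no markers shared between intensities and signature")
  b <- (signature[shared, , drop = FALSE] >= 1) * 1
  z[, shared, drop = FALSE] %*% b
}

## --- step 1: seed clustering ------------------------------------------

#' Seed-cluster cells on z-normalized intensities
#'
#' Groups cells into `k = round(1 / target_fraction)` k-means clusters
#' (default: clusters averaging 0.5% of cells each) on the full marker
#' panel, with a fixed seed for determinism.
#'
#' @param z cells x markers z-score matrix.
#' @param target_fraction target mean cluster size as a fraction of cells.
#' @param seed RNG seed.
#' @return integer cluster label per cell, attribute `"k"`.
#' @export
seed_cluster <- function(z, target_fraction = 0.005, seed = 1L) {
  n <- nrow(z)
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must lie in (0, 1]")
  }
  if (n < 1) stop("no cells to cluster")
  k <- as.integer(round(1 / target_fraction))
  if (k > n) {
    warning("fewer cells than requested clusters; using k = ", n, call. = FALSE)
    k <- as.integer(n)
  }
  if (k == n) return(structure(seq_len(n), k = n))
  fit <- with_seed(seed, stats::kmeans(z, centers = k, iter.max = 100L, nstart = 1L))
  structure(unname(fit$cluster), k = k)
}

## --- step 3: segmented regression with AIC selection ------------------

#' Fit breakpoints to a ranked curve by segmented regression
#'
#' Fits continuous piecewise-linear (segmented) regressions of the sorted
#' curve on its rank for `b = 0..max_bp` breakpoints, searching integer
#' breakpoint ranks (exhaustively when the combination count allows,
#' otherwise by a coarse grid followed by iterative joint local refinement
#' down to step 1), subject to a minimum segment length. The model is
#' chosen by AIC `n*ln(RSS/n) + 2p` with `p = 2 + 2b`; ties go to fewer
#' breakpoints, so a noiseless straight line selects `b = 0`.
#'
#' @param curve numeric vector indexed by rank; in the annotation pipeline
#'   this is the ascending-sorted cluster-median CTR curve, but any noisy
#'   realization of a piecewise-linear trend over ranks is accepted.
#' @param max_bp maximum number of breakpoints (0-3).
#' @param min_seg minimum points per segment; default
#'   `max(3, ceiling(0.02 * n))`.
#' @return object of class `"breakpoint_fit"`: chosen `breakpoints`
#'   (integer ranks), `n_breakpoints`, per-model `aic` and `rss`, `fitted`
#'   values, and `flagged = TRUE` when the curve is too short for any
#'   breakpoint.
#' @export
fit_breakpoints <- function(curve, max_bp = 3, min_seg = NULL) {
  y <- as.numeric(curve)
  n <- length(y)
  if (n < 4) stop("curve too short to fit (need >= 4 points)")
  if (anyNA(y)) stop("curve must not contain NA")
  if (max_bp < 0 || max_bp > 3) stop("max_bp must be in 0..3")
  if (is.null(min_seg)) min_seg <- max(3L, as.integer(ceiling(0.02 * n)))
  min_seg <- as.integer(min_seg)
  x <- seq_len(n)

  rss_knots <- function(knots) {
    X <- cbind(1, x)
    for (kn in knots) X <- cbind(X, pmax(x - kn, 0))
    sum(.lm.fit(X, y)$residuals^2)
  }

  cand <- if (n - min_seg >= min_seg) seq.int(min_seg, n - min_seg) else integer(0)
  max_b <- min(max_bp, max(0L, n %/% min_seg - 1L))
  flagged <- max_bp > 0 && max_b < 1L

  search_knots <- function(b) {
    if (b == 0L) return(list(knots = integer(0), rss = rss_knots(integer(0))))
    spacing_ok <- function(m) {       # m: b x ncombo matrix of knot columns
      ok <- rep(TRUE, ncol(m))
      if (b > 1) for (j in seq_len(b - 1)) ok <- ok & (m[j + 1, ] - m[j, ] >= min_seg)
      ok
    }
    if (choose(length(cand), b) <= 60000) {
      combos <- utils::combn(cand, b)
      combos <- combos[, spacing_ok(combos), drop = FALSE]
      rssv <- apply(combos, 2, rss_knots)
      i <- which.min(rssv)
      return(list(knots = as.integer(combos[, i]), rss = rssv[i]))
    }
    ## coarse grid, then joint local refinement with shrinking window
    step <- max(1L, as.integer(ceiling(length(cand) / 40)))
    grid <- unique(c(seq.int(min_seg, n - min_seg, by = step), n - min_seg))
    combos <- utils::combn(grid, b)
    combos <- combos[, spacing_ok(combos), drop = FALSE]
    if (ncol(combos) == 0) {          # sparse grid missed all feasible combos
      combos <- matrix(min_seg * seq_len(b), ncol = 1)
    }
    rssv <- apply(combos, 2, rss_knots)
    i <- which.min(rssv)
    best <- as.integer(combos[, i]); best_rss <- rssv[i]
    w <- step
    repeat {
      offs <- seq.int(-w, w)
      cc <- as.matrix(expand.grid(lapply(best, function(kn) kn + offs)))
      ok <- cc[, 1] >= min_seg & cc[, b] <= n - min_seg
      if (b > 1) for (j in seq_len(b - 1)) ok <- ok & (cc[, j + 1] - cc[, j] >= min_seg)
      cc <- cc[ok, , drop = FALSE]
      rssv <- apply(cc, 1, rss_knots)
      i <- which.min(rssv)
      if (rssv[i] < best_rss - 1e-12) {
        best <- as.integer(cc[i, ]); best_rss <- rssv[i]
      } else if (w == 1L) {
        break
      } else {
        w <- max(1L, w %/% 2L)
      }
    }
    list(knots = best, rss = best_rss)
  }

  models <- lapply(0:max_b, search_knots)
  names(models) <- as.character(0:max_b)
  rss_floor <- n * 1e-12
  aic <- vapply(seq_along(models), function(i) {
    b <- i - 1L
    n * log(max(models[[i]]$rss, rss_floor) / n) + 2 * (2 + 2 * b)
  }, 0)
  names(aic) <- names(models)
  chosen <- min(which(aic <= min(aic) + 1e-8))   # ties -> fewest breakpoints
  knots <- models[[chosen]]$knots
  X <- cbind(1, x)
  for (kn in knots) X <- cbind(X, pmax(x - kn, 0))
  fit <- .lm.fit(X, y)
  structure(list(curve = y, n = n, min_seg = min_seg,
                 models = models, aic = aic,
                 rss = vapply(models, `[[`, 0, "rss"),
                 n_breakpoints = chosen - 1L,
                 breakpoints = knots,
                 fitted = y - fit$residuals,
                 flagged = flagged),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("Segmented fit on %d ranks: %d breakpoint(s)%s\n", x$n,
              x$n_breakpoints,
              if (x$n_breakpoints) paste0(" at ", paste(x$breakpoints, collapse = ", "))
              else ""))
  cat("AIC by model: ", paste(sprintf("b=%s %.2f", names(x$aic), x$aic),
                              collapse = "; "), "\n")
  invisible(x)
}

## --- step 4: LRG / HRG ------------------------------------------------

#' Split ranked clusters into low/high relevance groups
#'
#' LRG: clusters ranking at or below the lowest breakpoint (a cluster
#' exactly at a breakpoint rank joins the lower side); HRG: clusters
#' ranking strictly above the highest breakpoint; clusters between remain
#' unassigned. With 0 breakpoints the type is non-separable and no cutoff
#' can be derived.
#'
#' @param fit a [fit_breakpoints()] result.
#' @return list: `lrg`, `hrg`, `middle` (integer ranks), `separable`.
#' @export
classify_lrg_hrg <- function(fit) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  n <- fit$n
  if (fit$n_breakpoints == 0) {
    return(list(lrg = integer(0), hrg = integer(0), middle = seq_len(n),
                separable = FALSE))
  }
  lo <- min(fit$breakpoints)
  hi <- max(fit$breakpoints)
  lrg <- seq_len(lo)
  hrg <- seq.int(hi + 1L, n)
  list(lrg = lrg, hrg = hrg,
       middle = setdiff(seq_len(n), c(lrg, hrg)), separable = TRUE)
}

## --- step 5: cutoff ---------------------------------------------------

#' Find the score cutoff minimizing LRG/HRG classification error
#'
#' Scans candidate cutoffs at the midpoints between consecutive distinct
#' sorted score values; the classification error of cutoff `c` is
#' `(# HRG cells with score < c + # LRG cells with score >= c) / n`.
#' Returns the error-minimizing cutoff (the lowest such value on ties).
#'
#' @param values per-cell scores of cells in LRG or HRG clusters.
#' @param membership `"LRG"`/`"HRG"` per value.
#' @return numeric cutoff with attribute `"error"` (the achieved error).
#' @export
find_cutoff <- function(values, membership) {
  membership <- as.character(membership)
  stopifnot(length(values) == length(membership),
            all(membership %in% c("LRG", "HRG")))
  lrg <- sort(values[membership == "LRG"])
  hrg <- sort(values[membership == "HRG"])
  if (!length(lrg) || !length(hrg)) stop("both LRG and HRG must be non-empty")
  n <- length(values)
  v <- sort(unique(values))
  if (length(v) < 2) {
    cutoff <- v[1]
    return(structure(cutoff, error = (sum(hrg < cutoff) + sum(lrg >= cutoff)) / n))
  }
  cands <- (v[-1] + v[-length(v)]) / 2
  err <- (findInterval(cands, hrg) + (length(lrg) - findInterval(cands, lrg))) / n
  i <- which.min(err)                 # first minimum = lowest candidate
  structure(cands[i], error = err[i])
}

#' Assign primary cell types from CTR cutoffs
#'
#' `CTM[i, t] = 1` iff `CTR[i, t] >= cutoff_t` (inclusive at the cutoff).
#' Types without a derivable cutoff (`NA`) get an all-zero column.
#'
#' @param ctr cells x types CTR matrix.
#' @param cutoffs named numeric vector of per-type cutoffs (`NA` allowed).
#' @return binary integer cells x types matrix (CTM).
#' @export
assign_primary <- function(ctr, cutoffs) {
  ctr <- as.matrix(ctr)
  if (is.null(colnames(ctr))) stop("CTR matrix needs cell-type colnames")
  if (all(is.na(cutoffs))) stop("need a cutoff for at least one type")
  ctm <- matrix(0L, nrow(ctr), ncol(ctr), dimnames = dimnames(ctr))
  for (ty in colnames(ctr)) {
    ct <- if (ty %in% names(cutoffs)) cutoffs[[ty]] else NA_real_
    if (!is.na(ct)) ctm[, ty] <- as.integer(ctr[, ty] >= ct)
  }
  ctm
}

## Shared machinery: derive a positivity cutoff for any per-cell score
## (a CTR column, or a single marker for granularity gating) from seed
## clusters: sorted cluster medians -> breakpoints -> LRG/HRG -> cutoff.
derive_score_cutoff <- function(score, clusters, max_bp = 3, min_seg = NULL) {
  med <- tapply(score, clusters, stats::median)
  ord <- order(med)
  fit <- fit_breakpoints(as.numeric(med[ord]), max_bp = max_bp, min_seg = min_seg)
  grp <- classify_lrg_hrg(fit)
  if (!grp$separable) return(list(cutoff = NA_real_, error = NA_real_, fit = fit))
  cl_sorted <- names(med)[ord]
  memb <- rep(NA_character_, length(score))
  memb[as.character(clusters) %in% cl_sorted[grp$lrg]] <- "LRG"
  memb[as.character(clusters) %in% cl_sorted[grp$hrg]] <- "HRG"
  sel <- !is.na(memb)
  cut <- find_cutoff(score[sel], memb[sel])
  list(cutoff = as.numeric(cut), error = attr(cut, "error"), fit = fit)
}

## --- granularity refinement and mixed-identity resolution -------------

#' Refine deeper-granularity subtypes by single-marker AND-gating
#'
#' For each subtype column (signature level >= 2), the positivity cutoff of
#' each of its level-marker(s) is derived exactly like a CTR cutoff
#' (seed-cluster medians, breakpoints, LRG/HRG error minimization) on that
#' single marker, and the subtype column is set to
#' `parent-type membership AND marker-positive` (inclusive `>=` at the
#' cutoff; with several level markers, all must be positive). A subtype
#' with a non-separable marker is zeroed with a warning.
#'
#' @param ctm binary cells x types matrix from [assign_primary()].
#' @param z cells x markers z-score matrix.
#' @param signature signature matrix with level >= 2 entries.
#' @param clusters seed-cluster labels from [seed_cluster()].
#' @param max_bp,min_seg passed to [fit_breakpoints()].
#' @param parents subtype -> parent map; default [signature_parents()].
#'   Subtypes without an identifiable parent gate their own CTM column.
#' @return updated CTM.
#' @export
refine_granularity <- function(ctm, z, signature, clusters, max_bp = 3,
                               min_seg = NULL, parents = NULL) {
  validate_signature(signature)
  if (is.null(parents)) parents <- signature_parents(signature)
  if (!length(parents)) return(ctm)
  cutoff_cache <- new.env(parent = emptyenv())
  marker_cutoff <- function(m) {
    if (!is.null(cutoff_cache[[m]])) return(cutoff_cache[[m]])
    val <- derive_score_cutoff(z[, m], clusters, max_bp, min_seg)$cutoff
    cutoff_cache[[m]] <- val
    val
  }
  for (sub in names(parents)) {
    lvl_markers <- rownames(signature)[signature[, sub] >= 2]
    lvl_markers <- intersect(lvl_markers, colnames(z))
    pos <- rep(TRUE, nrow(ctm))
    for (m in lvl_markers) {
      ct <- marker_cutoff(m)
      if (is.na(ct)) {
        warning("marker '", m, "' non-separable; subtype '", sub, "' zeroed",
                call. = FALSE)
        pos <- rep(FALSE, nrow(ctm))
        break
      }
      pos <- pos & (z[, m] >= ct)
    }
    parent_member <- if (!is.na(parents[[sub]])) {
      ctm[, parents[[sub]]] > 0
    } else {
      ctm[, sub] > 0
    }
    ctm[, sub] <- as.integer(parent_member & pos)
  }
  ctm
}

#' Resolve mixed cell identities by KNN among clean cells
#'
#' Cells positive for a parent type and any of its subtypes first have the
#' redundant parent bit cleared. Cells then positive for exactly one type
#' are "clean" and keep that label; cells positive for none become
#' `"Unknown"`. Each remaining mixed cell is projected onto the union of
#' the defining markers of its contending types and reassigned to the
#' majority label among its `k` nearest clean cells of those types
#' (Euclidean distance); a tied vote goes to the label of the single
#' nearest neighbor. Contending types with no clean cell are excluded with
#' a warning; if no clean cells exist at all, mixed cells become
#' `"Unknown"`.
#'
#' @param ctm binary cells x types matrix (after [refine_granularity()]).
#' @param z cells x markers z-score matrix.
#' @param signature signature matrix (defines the relevant markers).
#' @param k number of neighbors.
#' @param parents subtype -> parent map; default [signature_parents()].
#' @return character vector of final per-cell labels (possibly `"Unknown"`).
#' @export
resolve_mixed <- function(ctm, z, signature, k = 15, parents = NULL) {
  validate_signature(signature)
  if (is.null(parents)) parents <- signature_parents(signature)
  for (p in unique(parents[!is.na(parents)])) {
    subs <- names(parents)[!is.na(parents) & parents == p]
    has_sub <- rowSums(ctm[, subs, drop = FALSE] > 0) > 0
    ctm[has_sub, p] <- 0L
  }
  types <- colnames(ctm)
  nmem <- rowSums(ctm > 0)
  labels <- rep("Unknown", nrow(ctm))
  clean <- which(nmem == 1)
  labels[clean] <- types[max.col(ctm[clean, , drop = FALSE], ties.method = "first")]
  mixed <- which(nmem >= 2)
  if (!length(mixed)) {
    names(labels) <- rownames(ctm)
    return(labels)
  }
  if (!length(clean)) {
    warning("no clean cells; all mixed cells labeled Unknown", call. = FALSE)
    names(labels) <- rownames(ctm)
    return(labels)
  }
  pattern <- apply(ctm[mixed, , drop = FALSE] > 0, 1, function(r) {
    paste(types[r], collapse = "\r")
  })
  for (pat in unique(pattern)) {
    contending <- strsplit(pat, "\r", fixed = TRUE)[[1]]
    cells <- mixed[pattern == pat]
    have_clean <- contending[contending %in% labels[clean]]
    missing <- setdiff(contending, have_clean)
    if (length(missing)) {
      warning("no clean cells for type(s) ", paste(missing, collapse = ", "),
              "; excluded from KNN for ", length(cells), " mixed cell(s)",
              call. = FALSE)
    }
    if (!length(have_clean)) next     # stays Unknown
    feats <- rownames(signature)[rowSums(signature[, contending, drop = FALSE] >= 1) > 0]
    feats <- intersect(feats, colnames(z))
    cand <- clean[labels[clean] %in% have_clean]
    d <- cross_dist(z[cells, feats, drop = FALSE], z[cand, feats, drop = FALSE])
    kk <- min(k, length(cand))
    for (i in seq_along(cells)) {
      ord <- order(d[i, ])
      votes <- labels[cand[ord[seq_len(kk)]]]
      tab <- table(votes)
      winners <- names(tab)[tab == max(tab)]
      labels[cells[i]] <- if (length(winners) == 1) winners else labels[cand[ord[1]]]
    }
  }
  names(labels) <- rownames(ctm)
  labels
}

## --- end-to-end wrapper ------------------------------------------------

#' Run the full TACIT annotation pipeline
#'
#' Z-normalization, CTR scoring, seed clustering, per-type breakpoint
#' cutoff derivation, primary assignment, granularity AND-gating, and KNN
#' resolution of mixed identities. Deterministic at a fixed seed.
#'
#' @param intensities marker-intensity table (see
#'   [znormalize_intensities()]).
#' @param signature marker x cell-type signature matrix.
#' @param target_fraction seed-cluster mean size fraction (default 0.005).
#' @param max_bp maximum breakpoints (default 3).
#' @param min_seg minimum segment length for [fit_breakpoints()].
#' @param k neighbors for [resolve_mixed()].
#' @param seed RNG seed for the seed clustering.
#' @return list of class `"tacit_result"`: `labels`, `ctm`, `ctr`,
#'   `cutoffs`, per-type `fits`, `clusters`, `z`.
#' @export
tacit_annotate <- function(intensities, signature, target_fraction = 0.005,
                           max_bp = 3, min_seg = NULL, k = 15, seed = 1L) {
  validate_signature(signature)
  avail <- if (is.data.frame(intensities)) names(intensities) else colnames(intensities)
  use <- intersect(rownames(signature), avail)
  if (!length(use)) stop("no markers shared between intensities and signature")
  z <- znormalize_intensities(intensities, markers = use)
  ctr <- compute_ctr(z, signature)
  clusters <- seed_cluster(z, target_fraction = target_fraction, seed = seed)
  cutoffs <- stats::setNames(rep(NA_real_, ncol(ctr)), colnames(ctr))
  fits <- vector("list", ncol(ctr))
  names(fits) <- colnames(ctr)
  for (ty in colnames(ctr)) {
    res <- derive_score_cutoff(ctr[, ty], clusters, max_bp, min_seg)
    fits[[ty]] <- res$fit
    cutoffs[ty] <- res$cutoff
    if (is.na(res$cutoff)) {
      warning("cell type '", ty, "' is non-separable (0 breakpoints); ",
              "its assignments are zeroed", call. = FALSE)
    }
  }
  parents <- signature_parents(signature)
  ctm <- assign_primary(ctr, cutoffs)
  ctm <- refine_granularity(ctm, z, signature, clusters, max_bp = max_bp,
                            min_seg = min_seg, parents = parents)
  labels <- resolve_mixed(ctm, z, signature, k = k, parents = parents)
  structure(list(labels = labels, ctm = ctm, ctr = ctr, cutoffs = cutoffs,
                 fits = fits, clusters = clusters, z = z),
            class = "tacit_result")
}

#' @export
print.tacit_result <- function(x, ...) {
  cat("TACIT annotation of", length(x$labels), "cells\n")
  print(sort(table(x$labels), decreasing = TRUE))
  invisible(x)
}
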