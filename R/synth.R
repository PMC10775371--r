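#' Synthetic-data configuration
#'
#' Bundles the parameters of the synthetic fixture generators. The defaults
#' describe the study conditions the generators emulate: two clinical groups
#' (`"SjD"` and `"nonSjD"`) with balanced patients, a negative-binomial
#' count background (mean 1, dispersion 0.5), cell-type marker genes
#' elevated in their own type, explicit mitochondrial / ribosomal /
#' hemoglobin gene lists for QC gating, and one disease-enriched cell type
#' (`"Tex"`, 4.75-fold over a 0.03 baseline frequency).
#'
#' @param seed integer RNG seed; all generator randomness flows through it.
#' @param n_patients_per_group patients per clinical group.
#' @param n_cells_per_patient cells drawn per patient.
#' @param n_genes total genes in the expression fixture (must cover the
#'   marker and QC gene lists; the remainder are background genes).
#' @param cell_types named list of character vectors: marker genes per type.
#' @param marker_effect unitless effect size. For expression counts the
#'   marker-gene NB mean is multiplied by `1 + marker_effect`; for marker
#'   intensity tables defining markers are drawn from `Normal(marker_effect, 1)`.
#' @param noise_sd residual noise SD used by curve fixtures.
#' @param qc_violation_rates named fractions (`mito`, `ribo`, `hb`,
#'   `low_genes`, `low_counts`) of cells planted to violate each QC rule.
#' @param shifted_type cell type whose frequency differs between groups.
#' @param shift_factor fold-change of `shifted_type` frequency in `"SjD"`
#'   relative to `"nonSjD"`; `1` gives a null (no group effect) fixture.
#' @param baseline_freq optional named baseline type frequencies
#'   (`"nonSjD"`); defaults to 0.03 for `shifted_type` and uniform rest.
#' @param patient_concentration Dirichlet concentration controlling
#'   patient-to-patient variability of type composition (larger = less).
#'
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients_per_group = 5L,
                         n_cells_per_patient = 500L,
                         n_genes = 300L,
                         cell_types = default_cell_types(),
                         marker_effect = 2.5,
                         noise_sd = 1,
                         qc_violation_rates = c(mito = 0, ribo = 0, hb = 0,
                                                low_genes = 0, low_counts = 0),
                         shifted_type = "Tex",
                         shift_factor = 4.75,
                         baseline_freq = NULL,
                         patient_concentration = 200) {
  stopifnot(length(cell_types) >= 2, !is.null(names(cell_types)))
  counts <- c(n_patients_per_group, n_cells_per_patient, n_genes)
  if (any(counts < 1)) stop("patient/cell/gene counts must be positive")
  stop_if_not_scalar_prob(qc_violation_rates, "qc_violation_rates")
  kinds <- c("mito", "ribo", "hb", "low_genes", "low_counts")
  rates <- stats::setNames(rep(0, length(kinds)), kinds)
  if (length(qc_violation_rates)) {
    unknown <- setdiff(names(qc_violation_rates), kinds)
    if (length(unknown)) stop("unknown qc_violation_rates: ",
                              paste(unknown, collapse = ", "))
    rates[names(qc_violation_rates)] <- qc_violation_rates
  }
  qc_genes <- unlist(synth_qc_gene_classes(), use.names = FALSE)
  overlap <- intersect(unlist(cell_types, use.names = FALSE), qc_genes)
  if (length(overlap)) {
    stop("marker genes overlap QC gene classes: ", paste(overlap, collapse = ", "))
  }
  if (!shifted_type %in% names(cell_types)) {
    stop("`shifted_type` must be one of the configured cell types")
  }
  if (is.null(baseline_freq)) {
    k <- length(cell_types)
    baseline_freq <- stats::setNames(rep((1 - 0.03) / (k - 1), k), names(cell_types))
    baseline_freq[shifted_type] <- 0.03
  }
  baseline_freq <- baseline_freq / sum(baseline_freq)
  structure(list(seed = as.integer(seed),
                 n_patients_per_group = as.integer(n_patients_per_group),
                 n_cells_per_patient = as.integer(n_cells_per_patient),
                 n_genes = as.integer(n_genes),
                 cell_types = cell_types,
                 marker_effect = marker_effect,
                 noise_sd = noise_sd,
                 qc_violation_rates = rates,
                 shifted_type = shifted_type,
                 shift_factor = shift_factor,
                 baseline_freq = baseline_freq,
                 patient_concentration = patient_concentration),
            class = "synth_config")
}

#' Default cell types of the expression fixture
#'
#' Eight salivary-gland populations with three marker genes each, mirroring
#' the tissue's main compartments (seromucous and mucous acini, ducts,
#' lymphocyte subsets, fibroblasts).
#' @return named list of marker-gene character vectors.
#' @export
default_cell_types <- function() {
  list(SMAC       = c("PRR4", "CST3", "MUC7"),
       Mucous     = c("MUC5B", "BPIFB2", "PIP"),
       Duct       = c("KRT19", "WFDC2", "KRT5"),
       Tex        = c("CD8A", "GZMK", "PDCD1"),
       Tc         = c("CD8B", "GZMB", "PRF1"),
       Th         = c("CD4", "IL7R", "CD40LG"),
       B          = c("CD79A", "MS4A1", "CD19"),
       Fibroblast = c("COL1A1", "COL3A1", "PDGFRA"))
}

## Explicit QC gene lists carried inside every expression fixture, so gating
## tests never depend on symbol-prefix heuristics.
synth_qc_gene_classes <- function() {
  list(mito = paste0("MT-G", sprintf("%02d", 1:10)),
       ribo = c(paste0("RPS", 1:10), paste0("RPL", 1:10)),
       hb   = c("HBB", "HBA1", "HBA2", "HBD", "HBG1"))
}

#' Generate a synthetic sparse expression matrix with ground truth
#'
#' Draws a genes x cells count matrix from a negative-binomial background
#' (mean 1, dispersion 0.5; hemoglobin genes at mean 0.2 so clean cells
#' clear the strict hemoglobin gate) with each type's marker genes elevated
#' by `1 + marker_effect`. Patients are balanced across the `"SjD"` and
#' `"nonSjD"` groups; the configured `shifted_type` frequency is multiplied
#' by `shift_factor` in `"SjD"`. A configured fraction of cells is planted
#' to violate each QC rule, each violating exactly one rule and each cell at
#' most one.
#'
#' @param config a [synth_config()].
#' @return list of class `"synth_expression"` with elements `counts`
#'   (dgCMatrix, genes x cells), `cells` (data.frame: `cell_id`, `patient`,
#'   `group`, `true_type`, `planted_violation`), `genes` (data.frame:
#'   `gene`, `class`), `gene_classes` (explicit mito/ribo/hb lists) and
#'   `truth` (shifted type, shift factor, per-patient type frequencies).
#' @export
synth_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, synth_expression_impl(config))
}

synth_expression_impl <- function(config) {
  classes <- synth_qc_gene_classes()
  marker_genes <- unlist(config$cell_types, use.names = FALSE)
  core <- c(marker_genes, unlist(classes, use.names = FALSE))
  if (anyDuplicated(core)) stop("duplicated gene symbols in configuration")
  n_filler <- config$n_genes - length(core)
  if (n_filler < 10) {
    stop("n_genes too small: need at least ", length(core) + 10, " genes")
  }
  genes <- c(core, sprintf("BG%04d", seq_len(n_filler)))
  gene_class <- rep("background", length(genes))
  names(gene_class) <- genes
  for (cls in names(classes)) gene_class[classes[[cls]]] <- cls
  for (ty in names(config$cell_types)) {
    gene_class[config$cell_types[[ty]]] <- paste0("marker:", ty)
  }

  groups <- c("SjD", "nonSjD")
  n_pat <- config$n_patients_per_group
  patients <- sprintf("P%02d", seq_len(2L * n_pat))
  pat_group <- rep(groups, each = n_pat)

  ## group-level type frequencies, then per-patient Dirichlet jitter
  p0 <- config$baseline_freq
  p1 <- p0
  p1[config$shifted_type] <- p1[config$shifted_type] * config$shift_factor
  p1 <- p1 / sum(p1)
  types <- names(config$cell_types)
  pat_freq <- t(vapply(seq_along(patients), function(i) {
    base <- if (pat_group[i] == "SjD") p1 else p0
    drop(rdirichlet(1, config$patient_concentration * base))
  }, numeric(length(types))))
  colnames(pat_freq) <- types
  rownames(pat_freq) <- patients

  n_cells <- 2L * n_pat * config$n_cells_per_patient
  cell_pat <- rep(patients, each = config$n_cells_per_patient)
  cell_grp <- rep(pat_group, each = config$n_cells_per_patient)
  cell_type <- unlist(lapply(seq_along(patients), function(i) {
    sample(types, config$n_cells_per_patient, replace = TRUE, prob = pat_freq[i, ])
  }), use.names = FALSE)

  ## NB background: mean 1 (hb genes 0.2), dispersion 0.5 => size = 2
  base_mu <- rep(1, length(genes))
  names(base_mu) <- genes
  base_mu[classes$hb] <- 0.2
  size <- 2
  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes, sprintf("C%05d", seq_len(n_cells))))
  for (ty in types) {
    idx <- which(cell_type == ty)
    if (!length(idx)) next
    mu <- base_mu
    mu[config$cell_types[[ty]]] <- mu[config$cell_types[[ty]]] * (1 + config$marker_effect)
    counts[, idx] <- stats::rnbinom(length(genes) * length(idx), size = size,
                                    mu = rep(mu, times = length(idx)))
  }

  ## plant QC violations on disjoint cells, one rule per cell
  rates <- config$qc_violation_rates
  n_violate <- round(rates * n_cells)
  if (sum(n_violate) > n_cells) stop("qc_violation_rates sum to more than one cell each")
  victim <- if (sum(n_violate) > 0) sample(n_cells, sum(n_violate)) else integer(0)
  violation <- rep("none", n_cells)
  filler <- setdiff(genes, c(marker_genes, unlist(classes, use.names = FALSE)))
  at <- 0L
  for (kind in names(n_violate)) {
    if (n_violate[[kind]] == 0) next
    cells_k <- victim[at + seq_len(n_violate[[kind]])]
    at <- at + n_violate[[kind]]
    violation[cells_k] <- kind
    for (j in cells_k) {
      tot <- sum(counts[, j])
      if (kind == "mito") {
        have <- sum(counts[classes$mito, j])
        add <- max(1, ceiling((0.30 * tot - have) / 0.70))
        counts[classes$mito[1], j] <- counts[classes$mito[1], j] + add
      } else if (kind == "ribo") {
        have <- sum(counts[classes$ribo, j])
        add <- max(1, ceiling((0.60 * tot - have) / 0.40))
        counts[classes$ribo[1], j] <- counts[classes$ribo[1], j] + add
      } else if (kind == "hb") {
        have <- sum(counts[classes$hb, j])
        add <- max(1, ceiling((0.10 * tot - have) / 0.90))
        counts[classes$hb[1], j] <- counts[classes$hb[1], j] + add
      } else if (kind == "low_genes") {
        counts[, j] <- 0L
        counts[filler[1:5], j] <- 30L        # 5 genes, 150 counts
      } else if (kind == "low_counts") {
        counts[, j] <- 0L
        counts[filler[1:30], j] <- 1L        # 30 genes, 30 counts
      }
    }
  }

  structure(list(
    counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                     "generalMatrix"), "CsparseMatrix"),
    cells = data.frame(cell_id = colnames(counts), patient = cell_pat,
                       group = cell_grp, true_type = cell_type,
                       planted_violation = violation),
    genes = data.frame(gene = genes, class = unname(gene_class)),
    gene_classes = classes,
    truth = list(shifted_type = config$shifted_type,
                 shift_factor = config$shift_factor,
                 patient_freq = pat_freq,
                 patient_group = stats::setNames(pat_group, patients))),
    class = "synth_expression")
}

#' Generate a synthetic multiplex marker-intensity table
#'
#' For every cell of true type `t`, markers with signature value >= 1 in
#' column `t` are drawn from `Normal(marker_effect, 1)` and all other
#' markers from `Normal(0, 1)`. Hierarchy markers (signature value >= 2)
#' are therefore elevated only in the correct subtype. Cells are generated
#' only for leaf types (signature columns that are not the parent of a
#' deeper-granularity column); 2-D coordinates are drawn from type-specific
#' Gaussian blobs so neighborhood analysis has planted spatial structure.
#'
#' @param config a [synth_config()] (supplies `marker_effect` and the seed).
#' @param signature marker x cell-type signature matrix (see
#'   [read_signature()]); entries 0/1/level.
#' @param n_cells number of cells (default 5000). `0` yields an empty table.
#' @param blob_sd SD of the coordinate blobs (same units as coordinates).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list of class `"synth_markers"`: `table` (data.frame `cell_id`,
#'   `x`, `y`, one column per marker) and `truth` (data.frame `cell_id`,
#'   `true_type`).
#' @export
synth_marker_table <- function(config, signature, n_cells = 5000L,
                               blob_sd = 1.5, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), is.matrix(signature))
  validate_signature(signature)
  with_seed(seed, {
    parents <- signature_parents(signature)
    leaves <- setdiff(colnames(signature), stats::setNames(parents, NULL))
    markers <- rownames(signature)
    if (n_cells == 0L) {
      tab <- data.frame(cell_id = character(0), x = numeric(0), y = numeric(0))
      for (m in markers) tab[[m]] <- numeric(0)
      return(structure(list(table = tab,
                            truth = data.frame(cell_id = character(0),
                                               true_type = character(0))),
                       class = "synth_markers"))
    }
    true_type <- sample(leaves, n_cells, replace = TRUE)
    inten <- matrix(stats::rnorm(n_cells * length(markers)), n_cells, length(markers),
                    dimnames = list(NULL, markers))
    for (ty in leaves) {
      idx <- which(true_type == ty)
      def <- markers[signature[, ty] >= 1]
      if (length(idx) && length(def)) {
        inten[idx, def] <- inten[idx, def] + config$marker_effect
      }
    }
    ## type-clustered blobs on a circle
    ang <- 2 * pi * (match(true_type, leaves) - 1) / length(leaves)
    radius <- 5 * sqrt(length(leaves))
    x <- radius * cos(ang) + stats::rnorm(n_cells, sd = blob_sd)
    y <- radius * sin(ang) + stats::rnorm(n_cells, sd = blob_sd)
    cell_id <- sprintf("M%05d", seq_len(n_cells))
    tab <- data.frame(cell_id = cell_id, x = x, y = y)
    tab <- cbind(tab, as.data.frame(inten))
    structure(list(table = tab,
                   truth = data.frame(cell_id = cell_id, true_type = true_type)),
              class = "synth_markers")
  })
}

#' Generate a synthetic spot x cell-type proportion table
#'
#' Spots sit on a hexagonal grid (unit pitch by default). Per-spot
#' proportions are Dirichlet draws; in the disease group a fraction of
#' spots ("foci") has the concentrations of each planted pair jointly
#' boosted, planting within-spot colocalization, while the control group
#' boosts the same types separately (so marginal abundances stay
#' comparable but the types do not co-occur).
#'
#' @param types character vector of cell-type names (>= 2).
#' @param n_spots_per_group spots per group.
#' @param planted_pairs list of length-2 character vectors to colocalize in
#'   the disease group; `list()` plants nothing (null fixture).
#' @param boost multiplicative Dirichlet-concentration boost in focus spots.
#' @param focus_frac fraction of spots that are foci.
#' @param base_conc baseline Dirichlet concentration per type.
#' @param groups length-2 character vector, disease group first.
#' @param pitch hexagonal grid pitch (platform units).
#' @param seed RNG seed.
#' @return list of class `"synth_spots"`: `table` (data.frame `spot_id`,
#'   `x`, `y`, `group`, one proportion column per type; rows sum to 1) and
#'   `truth` (planted pairs, per-spot focus flag).
#' @export
synth_spot_table <- function(types = names(default_cell_types()),
                             n_spots_per_group = 200L,
                             planted_pairs = list(c("Tex", "SMAC")),
                             boost = 4, focus_frac = 0.3, base_conc = 1,
                             groups = c("SjD", "nonSjD"),
                             pitch = 1, seed = 1L) {
  if (length(types) < 2) stop("need at least 2 cell types")
  for (p in planted_pairs) {
    if (!all(p %in% types)) stop("planted pair refers to unknown types")
  }
  stopifnot(length(groups) == 2)
  with_seed(seed, {
    grid <- hex_grid(n_spots_per_group, pitch)
    tabs <- list(); focus_flags <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      n <- n_spots_per_group
      alpha <- matrix(base_conc, n, length(types), dimnames = list(NULL, types))
      is_focus <- stats::runif(n) < focus_frac
      if (length(planted_pairs)) {
        for (p in planted_pairs) {
          if (gi == 1) {                      # disease: joint boost
            alpha[is_focus, p] <- alpha[is_focus, p] * boost
          } else {                            # control: separate boosts
            half <- is_focus & (seq_len(n) %% 2 == 0)
            alpha[half, p[1]] <- alpha[half, p[1]] * boost
            alpha[is_focus & !half, p[2]] <- alpha[is_focus & !half, p[2]] * boost
          }
        }
      }
      props <- rdirichlet(n, alpha)
      colnames(props) <- types
      tabs[[g]] <- cbind(data.frame(spot_id = sprintf("%s_S%04d", g, seq_len(n)),
                                    x = grid$x, y = grid$y, group = g),
                         as.data.frame(props))
      focus_flags[[g]] <- is_focus
    }
    structure(list(table = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
                   truth = list(planted_pairs = planted_pairs,
                                focus = focus_flags)),
              class = "synth_spots")
  })
}

## First n spots of a hexagonally packed grid with the given pitch.
hex_grid <- function(n, pitch = 1) {
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  row <- rep(seq_len(nrow) - 1L, each = ncol)[seq_len(n)]
  col <- rep(seq_len(ncol) - 1L, times = nrow)[seq_len(n)]
  data.frame(x = pitch * (col + 0.5 * (row %% 2)),
             y = pitch * row * sqrt(3) / 2)
}

#' Generate a ranked piecewise-linear curve with known breakpoints
#'
#' Continuous piecewise-linear mean evaluated at ranks `1..n_points`, plus
#' `Normal(0, noise_sd)` noise. The fixture for breakpoint-recovery tests.
#'
#' @param n_points curve length.
#' @param breakpoints 0-3 strictly increasing integer ranks inside
#'   `(1, n_points)`.
#' @param slopes one slope per segment (`length(breakpoints) + 1`).
#' @param intercept mean value at rank 0.
#' @param noise_sd noise SD.
#' @param seed RNG seed.
#' @return list: `y` (observed), `mean`, `x` (ranks), `breakpoints`, `slopes`.
#' @export
synth_piecewise_curve <- function(n_points, breakpoints = integer(0), slopes = 1,
                                  intercept = 0, noise_sd = 0, seed = 1L) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) > 3) stop("at most 3 breakpoints supported")
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing")
  }
  if (length(breakpoints) && (min(breakpoints) <= 1 || max(breakpoints) >= n_points)) {
    stop("breakpoints must lie strictly inside (1, n_points)")
  }
  if (length(slopes) != length(breakpoints) + 1) {
    stop("need one slope per segment: length(slopes) == length(breakpoints) + 1")
  }
  x <- seq_len(n_points)
  mu <- intercept + slopes[1] * x
  if (length(breakpoints)) {
    for (j in seq_along(breakpoints)) {
      mu <- mu + (slopes[j + 1] - slopes[j]) * pmax(x - breakpoints[j], 0)
    }
  }
  y <- with_seed(seed, mu + stats::rnorm(n_points, sd = noise_sd))
  list(x = x, y = y, mean = mu, breakpoints = breakpoints, slopes = slopes)
}

#' Example marker x cell-type signature matrix
#'
#' Nine columns over 16 markers: eight base populations plus a two-level
#' T-cell hierarchy (a `Tcell` parent defined by CD3-complex markers, with
#' `Th` and `Tc` subtypes split at granularity level 2 by CD4 and CD8A).
#' @return integer matrix, markers in rows, cell types in columns.
#' @export
example_signature <- function() {
  markers <- c("CD3D", "CD3E", "CD2", "CD4", "CD8A",
               "CD19", "CD20", "CD79A", "NKG7", "GNLY", "NCAM1",
               "CD68", "CD163", "LYZ",
               "COL1A1", "PDGFRA", "PECAM1", "VWF", "EPCAM", "KRT8")
  types <- c("Tcell", "Th", "Tc", "B", "NK", "Macrophage",
             "Fibroblast", "Endothelial", "Epithelial")
  s <- matrix(0L, length(markers), length(types),
              dimnames = list(markers, types))
  s[c("CD3D", "CD3E", "CD2"), "Tcell"] <- 1L
  s[c("CD3D", "CD3E", "CD2"), "Th"] <- 1L
  s["CD4", "Th"] <- 2L
  s[c("CD3D", "CD3E", "CD2"), "Tc"] <- 1L
  s["CD8A", "Tc"] <- 2L
  s[c("CD19", "CD20", "CD79A"), "B"] <- 1L
  s[c("NKG7", "GNLY", "NCAM1"), "NK"] <- 1L
  s[c("CD68", "CD163", "LYZ"), "Macrophage"] <- 1L
  s[c("COL1A1", "PDGFRA"), "Fibroblast"] <- 1L
  s[c("PECAM1", "VWF"), "Endothelial"] <- 1L
  s[c("EPCAM", "KRT8"), "Epithelial"] <- 1L
  s
}
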