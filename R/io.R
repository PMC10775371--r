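#' Read a sparse expression matrix with annotations
#'
#' Matrix-market counts plus tab-separated cell and gene annotation tables
#' (first column = identifier). Gzipped files are accepted. Dimensions are
#' cross-checked: rows of the matrix must match the gene table, columns
#' the cell table.
#'
#' @param mtx_path matrix-market file (`.mtx` or `.mtx.gz`), genes x cells.
#' @param cells_path,genes_path TSV annotation tables with headers.
#' @return list of class `"expression_set"`: `counts` (dgCMatrix with
#'   dimnames), `cells`, `genes`.
#' @export
read_expression <- function(mtx_path, cells_path, genes_path) {
  con <- if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else file(mtx_path)
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) {
                  stop("malformed matrix-market file '", mtx_path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop(sprintf(paste0("dimension mismatch: '%s' is %d x %d but '%s' has %d ",
                        "genes and '%s' has %d cells"),
                 mtx_path, nrow(m), ncol(m), genes_path, nrow(genes),
                 cells_path, nrow(cells)))
  }
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(genes[[1]], cells[[1]])
  structure(list(counts = m, cells = cells, genes = genes),
            class = "expression_set")
}

#' Write a sparse expression matrix with annotations
#'
#' Inverse of [read_expression()]: matrix-market counts plus cell and gene
#' TSVs in `dir`.
#'
#' @param counts genes x cells matrix (or [synth_expression()] object).
#' @param dir output directory (created if needed).
#' @param cells,genes annotation data.frames; derived from dimnames when
#'   `NULL`.
#' @return invisibly, the three file paths.
#' @export
write_expression <- function(counts, dir, cells = NULL, genes = NULL) {
  if (inherits(counts, "synth_expression")) {
    if (is.null(cells)) cells <- counts$cells
    if (is.null(genes)) genes <- counts$genes
    counts <- counts$counts
  }
  if (is.null(cells)) cells <- data.frame(cell_id = colnames(counts))
  if (is.null(genes)) genes <- data.frame(gene = rownames(counts))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "cells.tsv", "genes.tsv"))
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), paths[1])
  write_tsv(cells, paths[2])
  write_tsv(genes, paths[3])
  invisible(paths)
}

#' Read a marker x cell-type signature matrix from TSV
#'
#' Markers in rows (first column), cell types in columns; entries 0/1 or
#' an integer granularity level >= 2.
#'
#' @param path TSV file.
#' @return validated integer signature matrix.
#' @export
read_signature <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  validate_signature(m)
  m
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' One object carrying every stage toggle and tunable parameter of
#' [run_pipeline()], with the study defaults (QC gates 15/50/5/10/100,
#' 0.5% seed clusters, up to 3 breakpoints, KNN k = 15, 99th-percentile
#' edge pruning, q < 0.05). Unknown keys are rejected by normal argument
#' matching; a JSON config file can be loaded with
#' [read_pipeline_config()].
#'
#' @param seed global RNG seed.
#' @param outdir output directory.
#' @param stages character subset of
#'   `c("expression", "qc", "proportions", "sscore", "tacit",
#'   "cooccurrence", "neighborhood")`.
#' @param synth a [synth_config()] for the generated inputs.
#' @param qc a [qc_thresholds()].
#' @param scale_total log-normalization target total.
#' @param n_marker_cells cells in the marker-intensity fixture.
#' @param target_fraction,max_bp,knn_k TACIT parameters.
#' @param percentile edge-pruning percentile.
#' @param n_perm permutations for co-occurrence differentials.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("glandmap_run_"),
                            stages = c("expression", "qc", "proportions",
                                       "sscore", "tacit", "cooccurrence",
                                       "neighborhood"),
                            synth = NULL, qc = qc_thresholds(),
                            scale_total = 1e4, n_marker_cells = 2000L,
                            target_fraction = 0.005, max_bp = 3, knn_k = 15,
                            percentile = 99, n_perm = 1000) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(synth)) synth <- synth_config(seed = seed)
  stopifnot(inherits(synth, "synth_config"), inherits(qc, "qc_thresholds"))
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 synth = synth, qc = qc, scale_total = scale_total,
                 n_marker_cells = as.integer(n_marker_cells),
                 target_fraction = target_fraction, max_bp = max_bp,
                 knn_k = knn_k, percentile = percentile, n_perm = n_perm),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Top-level keys map to [pipeline_config()] arguments (unknown keys are
#' an error); `synth` and `qc` sub-objects map to [synth_config()] and
#' [qc_thresholds()].
#'
#' @param path JSON file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(pipeline_config, raw)
}

#' Run the end-to-end pipeline on synthetic fixtures
#'
#' Generates the configured synthetic inputs and executes the enabled
#' stages in dependency order (expression -> QC -> proportions / S-scores;
#' marker table -> TACIT -> neighborhood graphs; spot table ->
#' co-occurrence), writing every result as plain text under
#' `config$outdir` and a JSON run manifest (package version, config,
#' output file MD5 hashes, per-stage timings, collected warnings).
#' Output files are byte-identical across runs at a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  warnings <- character(0)
  outputs <- character(0)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings <<- c(warnings, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(d, file) {
    path <- file.path(config$outdir, file)
    write_tsv(d, path)
    outputs <<- c(outputs, path)
    path
  }

  state <- new.env(parent = emptyenv())
  if ("expression" %in% config$stages) {
    run_stage("expression", function() {
      state$expr <- synth_expression(config$synth)
      outputs <<- c(outputs, write_expression(state$expr,
                                              file.path(config$outdir, "expression")))
    })
  }
  if ("qc" %in% config$stages && !is.null(state$expr)) {
    run_stage("qc", function() {
      state$gate <- gate_cells(state$expr, thresholds = config$qc)
      emit(state$gate$report, "qc_report.tsv")
      emit(state$gate$exclusions, "qc_exclusions.tsv")
    })
  }
  if ("proportions" %in% config$stages && !is.null(state$gate)) {
    run_stage("proportions", function() {
      ptab <- proportion_table(state$gate$cells, patient_col = "patient",
                               type_col = "true_type", group_col = "group")
      res <- test_proportions(ptab, compare = c("SjD", "nonSjD"))
      emit(cbind(patient = rownames(ptab$proportions),
                 as.data.frame(ptab$proportions)), "proportions.tsv")
      emit(as.data.frame(res), "proportion_tests.tsv")
    })
  }
  if ("sscore" %in% config$stages && !is.null(state$gate)) {
    run_stage("sscore", function() {
      z <- zscore_genes(lognormalize(state$gate$counts, config$scale_total))
      s <- compute_sscores(z, config$synth$cell_types)
      emit(cbind(cell_id = rownames(s), as.data.frame(s)), "sscores.tsv")
    })
  }
  if ("tacit" %in% config$stages) {
    run_stage("tacit", function() {
      sig <- example_signature()
      state$markers <- synth_marker_table(config$synth, sig,
                                          n_cells = config$n_marker_cells,
                                          seed = config$seed)
      state$tacit <- tacit_annotate(state$markers$table, sig,
                                    target_fraction = config$target_fraction,
                                    max_bp = config$max_bp, k = config$knn_k,
                                    seed = config$seed)
      emit(data.frame(cell_id = state$markers$table$cell_id,
                      x = state$markers$table$x, y = state$markers$table$y,
                      label = unname(state$tacit$labels)), "tacit_labels.tsv")
      emit(data.frame(cell_type = names(state$tacit$cutoffs),
                      cutoff = unname(state$tacit$cutoffs)), "tacit_cutoffs.tsv")
    })
  }
  if ("neighborhood" %in% config$stages && !is.null(state$tacit)) {
    run_stage("neighborhood", function() {
      ## two pseudo-tissues from independent marker draws: healthy vs disease
      sig <- example_signature()
      healthy <- synth_marker_table(config$synth, sig,
                                    n_cells = config$n_marker_cells,
                                    seed = config$seed + 1000L)
      mk_cells <- function(mk) {
        data.frame(cell_id = mk$table$cell_id, x = mk$table$x, y = mk$table$y,
                   cell_type = mk$truth$true_type)
      }
      gh <- prune_edges(build_delaunay(mk_cells(healthy)), config$percentile)
      gd <- prune_edges(build_delaunay(mk_cells(state$markers)), config$percentile)
      fc <- normalize_and_fold_change(interaction_matrix(gh),
                                      interaction_matrix(gd))
      emit(cbind(cell_type = rownames(fc$fc), as.data.frame(fc$fc)),
           "interaction_fc.tsv")
    })
  }
  if ("cooccurrence" %in% config$stages) {
    run_stage("cooccurrence", function() {
      state$spots <- synth_spot_table(seed = config$seed)
      cooc <- spot_cooccurrence(state$spots$table, compare = c("SjD", "nonSjD"),
                                n_perm = config$n_perm, seed = config$seed)
      emit(state$spots$table, "spots.tsv")
      emit(cooc$differential, "cooccurrence_differential.tsv")
    })
  }

  manifest <- list(package = "glandmap",
                   version = as.character(utils::packageVersion("glandmap")),
                   seed = config$seed,
                   stages = config$stages,
                   config_hash = hash_object(config[setdiff(names(config), "outdir")]),
                   outputs = file_hashes(outputs, config$outdir),
                   timings = timings,
                   warnings = warnings)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## MD5 of an R object via its serialization to a temp file.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

file_hashes <- function(paths, base) {
  paths <- unique(paths)
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), sub("^/*", "", sub(base, "", names(h), fixed = TRUE)))
}
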