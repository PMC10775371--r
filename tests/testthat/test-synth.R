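test_that("synthetic expression is deterministic and ground-truthed", {
  cfg <- synth_config(seed = 42, n_patients_per_group = 2,
                      n_cells_per_patient = 50)
  a <- synth_expression(cfg)
  b <- synth_expression(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  # every cell has exactly one truth record
  expect_identical(nrow(a$cells), ncol(a$counts))
  expect_false(anyNA(a$cells$true_type))
  # patients balanced across the two groups
  expect_equal(as.vector(table(unique(a$cells[c("patient", "group")])$group)),
               c(2L, 2L))
})

test_that("violation-free fixtures pass the QC gate completely", {
  cfg <- synth_config(seed = 7, n_patients_per_group = 2,
                      n_cells_per_patient = 100)
  ex <- synth_expression(cfg)
  g <- gate_cells(ex)
  expect_true(all(g$retained))
})

test_that("planted QC violations hit exactly their own rule", {
  cfg <- synth_config(seed = 3, n_patients_per_group = 2,
                      n_cells_per_patient = 100,
                      qc_violation_rates = c(mito = 0.05, ribo = 0.05,
                                             hb = 0.05, low_genes = 0.05,
                                             low_counts = 0.05))
  ex <- synth_expression(cfg)
  g <- gate_cells(ex)
  expect_identical(ex$cells$planted_violation != "none", !g$retained)
  # each planted kind fails its own rule
  rep <- g$report
  thr <- qc_thresholds()
  expect_true(all(rep$pct_mito[ex$cells$planted_violation == "mito"] >= thr$max_mito_pct))
  expect_true(all(rep$pct_ribo[ex$cells$planted_violation == "ribo"] >= thr$max_ribo_pct))
  expect_true(all(rep$pct_hb[ex$cells$planted_violation == "hb"] >= thr$max_hb_pct))
  expect_true(all(rep$n_genes[ex$cells$planted_violation == "low_genes"] < thr$min_genes))
  expect_true(all(rep$total_counts[ex$cells$planted_violation == "low_counts"] < thr$min_counts))
})

test_that("marker-set / QC-class overlap is a configuration error", {
  expect_error(synth_config(cell_types = list(A = c("HBB", "X1"), B = "X2")),
               "overlap")
})

test_that("marker tables elevate exactly the defining markers", {
  sig <- example_signature()
  cfg <- synth_config(seed = 5, marker_effect = 3)
  mk <- synth_marker_table(cfg, sig, n_cells = 2000, seed = 5)
  expect_identical(nrow(mk$table), nrow(mk$truth))
  # cells only of leaf types
  expect_false(any(mk$truth$true_type == "Tcell"))
  # defining markers sit near marker_effect, others near 0
  tc <- mk$truth$true_type == "Tc"
  expect_gt(mean(mk$table$CD8A[tc]), 2.5)
  expect_lt(abs(mean(mk$table$CD4[tc])), 0.3)        # hierarchy marker of Th
  expect_lt(abs(mean(mk$table$CD8A[!tc])), 0.3)
  # type-clustered coordinates: within-type spread far below global spread
  xy <- cbind(mk$table$x, mk$table$y)
  within <- mean(unlist(tapply(seq_len(nrow(xy)), mk$truth$true_type, function(i) {
    apply(xy[i, ], 2, sd)
  })))
  expect_lt(within, 0.25 * mean(apply(xy, 2, sd)))
})

test_that("empty marker table is allowed", {
  mk <- synth_marker_table(synth_config(), example_signature(), n_cells = 0)
  expect_identical(nrow(mk$table), 0L)
  expect_identical(nrow(mk$truth), 0L)
})

test_that("spot tables are simplex-valued and deterministic", {
  sp <- synth_spot_table(n_spots_per_group = 60, seed = 9)
  types <- setdiff(names(sp$table), c("spot_id", "x", "y", "group"))
  p <- as.matrix(sp$table[types])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  sp2 <- synth_spot_table(n_spots_per_group = 60, seed = 9)
  expect_identical(sp$table, sp2$table)
  # single spot per group degenerates gracefully
  one <- synth_spot_table(n_spots_per_group = 1, seed = 1)
  expect_identical(nrow(one$table), 2L)
  expect_equal(rowSums(as.matrix(one$table[types])), c(1, 1), tolerance = 1e-9)
})

test_that("planted colocalization raises disease co-occurrence across seeds", {
  diffs <- vapply(1:20, function(s) {
    sp <- synth_spot_table(n_spots_per_group = 80,
                           planted_pairs = list(c("Tex", "SMAC")), seed = s)
    co <- spot_cooccurrence(sp$table, compare = c("SjD", "nonSjD"), n_perm = 0)
    d <- co$differential
    d$difference[d$type1 == "SMAC" & d$type2 == "Tex" |
                   d$type1 == "Tex" & d$type2 == "SMAC"]
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("null spot tables show no systematic group differential", {
  diffs <- vapply(1:20, function(s) {
    sp <- synth_spot_table(n_spots_per_group = 80, planted_pairs = list(),
                           seed = s)
    co <- spot_cooccurrence(sp$table, compare = c("SjD", "nonSjD"), n_perm = 0)
    mean(co$differential$difference)
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("piecewise curves are exact without noise and validated", {
  cv <- synth_piecewise_curve(10, integer(0), slopes = 2, intercept = 1)
  expect_equal(cv$y, 1 + 2 * (1:10))
  cv2 <- synth_piecewise_curve(200, c(50, 150), c(0, 1, 0), noise_sd = 0)
  expect_equal(cv2$y, cv2$mean)
  # kinks where planted: second differences nonzero only at breakpoints
  kinks <- which(abs(diff(diff(cv2$y))) > 1e-9) + 1
  expect_identical(as.integer(kinks), c(50L, 150L))
  expect_error(synth_piecewise_curve(100, c(60, 40), c(1, 1, 1)),
               "strictly increasing")
  expect_error(synth_piecewise_curve(100, c(1, 50), c(1, 1, 1)), "inside")
  expect_error(synth_piecewise_curve(100, 50, 1), "one slope per segment")
})
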