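test_that("the co-occurrence score matches its closed form", {
  expect_equal(cooccurrence_score(0, 0), 0)
  expect_equal(cooccurrence_score(0.5, 0.5), 1)
  expect_equal(cooccurrence_score(1, 0), exp(-3))
  expect_equal(cooccurrence_score(1, 1), 2)
  expect_error(cooccurrence_score(1.2, 0), "\\[0, 1\\]")
  expect_error(cooccurrence_score(0.5, -0.1), "\\[0, 1\\]")
})

test_that("the score is symmetric, bounded and maximized on the diagonal", {
  g <- seq(0, 1, length.out = 101)
  cmat <- outer(g, g, cooccurrence_score)
  expect_equal(cmat, t(cmat))
  expect_true(all(cmat >= 0 & cmat <= 2))
  # along the diagonal C(a, a) = 2a, increasing
  expect_equal(diag(cmat), 2 * g)
  # for fixed sum s, the maximum over the grid sits at the balanced split
  for (i in seq(3, 199, by = 14)) {             # antidiagonals i = row + col
    idx <- which(row(cmat) + col(cmat) == i + 1, arr.ind = TRUE)
    vals <- cmat[idx]
    best <- idx[which.max(vals), ]
    expect_lte(abs(best[1] - best[2]), 1)       # balanced within grid step
  }
})

test_that("spot co-occurrence summarizes pairs per group", {
  # constant table: types A and B each 0.5 in every spot
  tab <- data.frame(spot_id = paste0("s", 1:8), x = 1:8, y = 0,
                    group = rep(c("d", "h"), each = 4),
                    A = 0.5, B = 0.5)
  res <- spot_cooccurrence(tab, compare = c("d", "h"), n_perm = 0)
  expect_equal(res$group_means$mean_d, 1)
  expect_equal(res$group_means$mean_h, 1)
  expect_equal(res$differential$difference, 0)
  # single-type table -> empty result
  one <- data.frame(spot_id = "s", x = 0, y = 0, group = "d", A = 1)
  expect_identical(nrow(spot_cooccurrence(one)$differential), 0L)
  # missing group errors
  expect_error(spot_cooccurrence(tab, compare = c("d", "zz"), n_perm = 0),
               "0 spots")
  # malformed proportions error
  bad <- tab; bad$A <- 0.9
  expect_error(spot_cooccurrence(bad, n_perm = 0), "sum to 1")
})

test_that("planted colocalized pair has the largest positive differential", {
  hits <- vapply(1:25, function(s) {
    sp <- synth_spot_table(n_spots_per_group = 120,
                           planted_pairs = list(c("Tex", "SMAC")), seed = s)
    d <- spot_cooccurrence(sp$table, compare = c("SjD", "nonSjD"),
                           n_perm = 0)$differential
    top <- d[which.max(d$difference), ]
    top$difference > 0 && setequal(c(top$type1, top$type2), c("Tex", "SMAC"))
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("permutation p-values are small for planted pairs, null otherwise", {
  sp <- synth_spot_table(n_spots_per_group = 120,
                         planted_pairs = list(c("Tex", "SMAC")), seed = 5)
  res <- spot_cooccurrence(sp$table, compare = c("SjD", "nonSjD"),
                           n_perm = 200, seed = 1)
  d <- res$differential
  planted <- d$type1 %in% c("Tex", "SMAC") & d$type2 %in% c("Tex", "SMAC")
  expect_lt(d$p_value[planted], 0.05)
})

test_that("within-spot correlations are Pearson on proportion columns", {
  # compositional two-type table: rho = -1
  tab <- data.frame(spot_id = paste0("s", 1:5), x = 1:5, y = 0, group = "g",
                    A = c(0.1, 0.3, 0.5, 0.7, 0.9))
  tab$B <- 1 - tab$A
  rho <- within_spot_correlation(tab)
  expect_equal(rho["A", "B"], -1)
  # perfectly co-varying types
  tab3 <- data.frame(spot_id = paste0("s", 1:6), x = 1:6, y = 0, group = "g",
                     A = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3))
  tab3$B <- tab3$A
  tab3$C <- 1 - 2 * tab3$A
  expect_equal(within_spot_correlation(tab3)["A", "B"], 1)
  # matches the textbook formula on a random Dirichlet fixture
  sp <- synth_spot_table(n_spots_per_group = 50, planted_pairs = list(), seed = 2)
  types <- setdiff(names(sp$table), c("spot_id", "x", "y", "group"))
  rho2 <- within_spot_correlation(sp$table)
  p <- as.matrix(sp$table[types])
  manual <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(rho2[1, 2], manual(p[, 1], p[, 2]), tolerance = 1e-10)
  # zero-variance column -> NA entries
  tabz <- data.frame(spot_id = paste0("s", 1:4), x = 1:4, y = 0, group = "g",
                     A = 0.5, B = c(0.2, 0.3, 0.2, 0.3),
                     C = c(0.3, 0.2, 0.3, 0.2))
  expect_true(all(is.na(within_spot_correlation(tabz)["A", ])))
  expect_error(within_spot_correlation(tab[1:2, ]), "at least 3")
})

test_that("hexagonal interior spots have six neighbors", {
  sp <- synth_spot_table(n_spots_per_group = 100, seed = 1)
  one_group <- sp$table[sp$table$group == "SjD", ]
  adj <- spot_adjacency(one_group$x, one_group$y)
  deg <- tabulate(c(adj[, 1], adj[, 2]), nbins = nrow(one_group))
  # interior spot of a 10 x 10 hex block
  interior <- which(one_group$x > 2 & one_group$x < 7 &
                      one_group$y > 2 & one_group$y < 6)
  expect_true(all(deg[interior] == 6))
})

test_that("next-spot correlations detect planted spatial gradients", {
  grid <- expand.grid(x = 1:8, y = 1:8)
  a <- (grid$x + grid$y) / 32                   # smooth gradient of type A
  tab <- data.frame(spot_id = paste0("s", seq_len(nrow(grid))),
                    x = grid$x, y = grid$y, group = "g",
                    A = a, B = 1 - a)
  nxt <- next_spot_correlation(tab)
  expect_gt(nxt["A", "A"], 0.5)
  # identical proportions everywhere -> undefined, reported missing
  tabc <- tab; tabc$A <- 0.4; tabc$B <- 0.6
  expect_true(all(is.na(next_spot_correlation(tabc))))
  # an empty adjacency (every spot isolated) -> error
  expect_error(next_spot_correlation(tab, adjacency = matrix(integer(0), 0, 2)),
               "isolated")
})
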