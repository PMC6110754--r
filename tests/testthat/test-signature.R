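test_that("size factors remove per-sample depth differences", {
  set.seed(71)
  base <- matrix(stats::rpois(200, 50), nrow = 20)
  scaled <- sweep(base, 2, c(1, 2, 4, 1, 3, 1, 2, 1, 5, 1), "*")
  v <- vst_transform(scaled)
  v0 <- vst_transform(base)
  # depth scaling is removed up to the global geometric-mean factor
  expect_lt(max(abs(sweep(v, 1, rowMeans(v)) - sweep(v0, 1, rowMeans(v0)))),
            0.35)
  # a doubled copy of the same sample maps onto identical columns
  two <- cbind(a = base[, 1], b = 2L * base[, 1])
  vt <- vst_transform(two)
  expect_equal(vt[, "a"], vt[, "b"], ignore_attr = TRUE)
})

test_that("constant count matrices transform to a constant", {
  m <- matrix(7, nrow = 4, ncol = 3)
  expect_true(all(vst_transform(m) == log2(8)))
})

test_that("size factors follow the median-of-ratios hand example", {
  m <- matrix(c(100, 10, 200, 20), nrow = 2)
  v <- vst_transform(m)
  sf <- attr(v, "size_factors")
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(v[1, 1], v[1, 2])
  expect_equal(v[2, 1], v[2, 2])
})

test_that("total-count fallback engages when no gene is always nonzero", {
  m <- matrix(c(5, 0, 0, 6), nrow = 2)
  expect_warning(v <- vst_transform(m), "total-count")
  expect_equal(dim(v), c(2L, 2L))
  expect_error(vst_transform(matrix(c(1, -1), 1)), "non-negative")
  expect_error(vst_transform(matrix(c(1, 0, 0, 0), 2)), "nonzero gene")
})

test_that("differential expression selects planted genes and only them", {
  # identical groups: nothing selected
  set.seed(81)
  null_m <- matrix(stats::rnorm(100 * 12, 8, 0.3), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  de0 <- differential_expression(null_m, rep(c(TRUE, FALSE), each = 6))
  expect_equal(sum(de0$selected), 0L)

  # a +1 log2 gene is excluded by the fold-change floor regardless of p
  m1 <- null_m
  m1[1, 1:6] <- m1[1, 1:6] + 1
  de1 <- differential_expression(m1, rep(c(TRUE, FALSE), each = 6))
  expect_false(de1$selected[1])
  expect_lt(de1$p_value[1], 0.01)

  # planted +4 log2 genes in generator counts all pass
  cfg <- small_config(seed = 82)
  sim <- simulate_mutations(cfg)
  counts <- simulate_expression(sim$sample_sheet, cfg)
  des <- training_design(sim$sample_sheet)
  vst <- vst_transform(counts)[, des$case_id]
  de <- differential_expression(vst, des$role == "tumor")
  expect_true(all(de$selected[de$gene %in%
                                cfg$activation_spec$genes]))
  expect_false(any(de$selected[de$gene %in% cfg$batch_spec$genes]))
  expect_error(differential_expression(null_m, c(TRUE, rep(FALSE, 11))),
               "2 samples per group")
})

test_that("false discoveries stay near the nominal FDR on null matrices", {
  set.seed(83)
  any_hit <- vapply(1:40, function(i) {
    m <- matrix(stats::rnorm(200 * 10, 8, 0.5), nrow = 200)
    de <- differential_expression(m, rep(c(TRUE, FALSE), each = 5),
                                  lfc_min = 0)
    any(de$q_value < 0.05)
  }, logical(1))
  # BH under the complete null: P(any rejection) <= alpha
  expect_lte(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("tumor-type bias ranking orders by |d_r| with stable ties", {
  m <- rbind(flat = c(1, 1, 1, 1),
             b_big = c(5, 5, 1, 1),
             a_small = c(1.2, 1.2, 1, 1))
  types <- c("LUAD", "LUAD", "LUSC", "LUSC")
  rk <- tumor_type_bias_rank(m, rownames(m), types)
  expect_equal(rk$gene, c("flat", "a_small", "b_big"))
  expect_equal(rk$abs_d_r, c(0, 0.2, 4))
  expect_equal(rk$rank, 1:3)
  # invariance to sample order
  perm <- c(3, 1, 4, 2)
  rk2 <- tumor_type_bias_rank(m[, perm], rownames(m), types[perm])
  expect_equal(rk2$gene, rk$gene)
  expect_equal(abs(rk2$d_r), abs(rk$d_r))
  # ties broken by gene name
  m2 <- rbind(zz = c(1, 1, 0, 0), aa = c(1, 1, 0, 0))
  expect_equal(tumor_type_bias_rank(m2, rownames(m2), types)$gene,
               c("aa", "zz"))
  expect_error(tumor_type_bias_rank(m, rownames(m), rep("LUAD", 4)),
               "two tumor types")
})

test_that("batch-effect genes rank after activation genes", {
  cfg <- small_config(seed = 84)
  sim <- simulate_mutations(cfg)
  counts <- simulate_expression(sim$sample_sheet, cfg)
  des <- training_design(sim$sample_sheet)
  vst <- vst_transform(counts)[, des$case_id]
  tum <- des$role == "tumor"
  cand <- c(cfg$activation_spec$genes, cfg$batch_spec$genes)
  rk <- tumor_type_bias_rank(vst[, tum], cand, des$tumor_type[tum])
  act_ranks <- rk$rank[rk$gene %in% cfg$activation_spec$genes]
  bat_ranks <- rk$rank[rk$gene %in% cfg$batch_spec$genes]
  expect_lt(max(act_ranks), min(bat_ranks))
})

test_that("the machine-learning score follows the hand geometry", {
  x <- cbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  is_tumor <- c(FALSE, FALSE, TRUE, TRUE)
  res <- mls_score(x, is_tumor, clusters = c(1, 1, 2, 2))
  expect_equal(res$l_inter, 10)
  expect_equal(res$l_intra, 1)
  expect_equal(res$score, 10)
  # scale invariance of the ratio
  res2 <- mls_score(3.7 * x, is_tumor, c(1, 1, 2, 2))
  expect_equal(res2$score, 10)
  # all points identical: sentinel Inf
  res3 <- mls_score(matrix(1, 2, 4), is_tumor, c(1, 1, 2, 2))
  expect_equal(res3$l_inter, 0)
  expect_identical(res3$score, Inf)
  # singleton clusters are excluded from the intra average
  res4 <- mls_score(x, is_tumor, clusters = c(1, 2, 3, 3))
  expect_equal(res4$l_intra, 1)
  expect_error(mls_score(x, rep(TRUE, 4), c(1, 1, 2, 2)), "non-empty")
})

test_that("sequential selection peaks where the informative genes end", {
  # five signal genes with growing effect, then three noise genes;
  # |d_r| ranking is driven by a small planted type bias that increases
  # along the intended order.
  set.seed(91)
  n_per <- 8
  labels <- rep(c(FALSE, TRUE), each = n_per)  # normals then tumors
  types <- rep(rep(c("LUAD", "LUSC"), each = n_per / 2), 2)
  effects <- c(0.5, 0.5, 0.5, 0.5, 4)
  sig <- t(sapply(seq_along(effects), function(i) {
    stats::rnorm(2 * n_per, 0, 0.01) + effects[i] * labels +
      0.02 * i * (types == "LUAD")
  }))
  noise <- t(sapply(1:3, function(i) {
    stats::rnorm(2 * n_per, 0, 0.01) + 0.4 * (i + 3) * (types == "LUAD")
  }))
  m <- rbind(sig, noise)
  rownames(m) <- sprintf("g%d", 1:8)
  rk <- tumor_type_bias_rank(m[, labels], rownames(m), types[labels])
  expect_equal(rk$gene, rownames(m))
  tr <- sequential_signature_selection(m, rk, labels, k_max = 8)
  expect_equal(tr$selected_k, 5L)
  expect_true(all(sprintf("g%d", 1:5) %in% tr$genes))
  expect_gte(tr$trace$mls[tr$trace$k == 5],
             tr$trace$mls[tr$trace$k == 2])
})

test_that("duplicating one informative gene keeps the trace non-decreasing", {
  set.seed(92)
  base <- stats::rnorm(12, 0, 0.1) + 4 * rep(c(0, 1), each = 6)
  m <- matrix(rep(base, each = 10), nrow = 10,
              dimnames = list(sprintf("d%02d", 1:10), NULL))
  rk <- data.frame(gene = rownames(m), d_r = 0, abs_d_r = 0, rank = 1:10)
  tr <- sequential_signature_selection(m, rk, rep(c(FALSE, TRUE),
                                                  each = 6))
  expect_true(all(diff(tr$trace$mls) >= -1e-9))
})

test_that("selection trace bounds and determinism hold", {
  set.seed(93)
  m <- matrix(stats::rnorm(5 * 10, 0, 1) +
                4 * rep(rep(c(0, 1), each = 5), each = 5), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), NULL))
  rk <- data.frame(gene = rownames(m), d_r = 0, abs_d_r = 0, rank = 1:5)
  labels <- rep(c(FALSE, TRUE), each = 5)
  tr2 <- sequential_signature_selection(m, rk, labels, k_max = 2)
  expect_equal(nrow(tr2$trace), 1L)
  expect_equal(tr2$selected_k, 2L)
  expect_warning(trx <- sequential_signature_selection(m, rk, labels,
                                                       k_max = 10),
                 "truncated")
  expect_identical(trx$trace,
                   sequential_signature_selection(
                     m, rk, labels, k_max = 5)$trace)
  expect_error(sequential_signature_selection(m, rk[1, ], labels),
               "two ranked genes")
})

test_that("derived signatures draw from planted genes and never from batch genes", {
  cfg <- small_config(seed = 94)
  sim <- simulate_mutations(cfg)
  counts <- simulate_expression(sim$sample_sheet, cfg)
  des <- training_design(sim$sample_sheet)
  sig <- derive_signature(counts, des)
  expect_true(all(sig$signature$gene %in% cfg$activation_spec$genes))
  expect_equal(length(intersect(sig$signature$gene,
                                cfg$batch_spec$genes)), 0L)
  expect_equal(sig$trace$selected_k, length(sig$signature$gene))
  # deterministic end to end
  sig2 <- derive_signature(counts, des)
  expect_identical(sig$signature, sig2$signature)
})

test_that("a zero activation effect yields no selected genes", {
  cfg <- small_config(seed = 95,
                      activation_spec = list(genes = c("AKR1B10", "AKR1B15",
                                                       "GPX2", "TXNRD1",
                                                       "GCLM", "GCLC"),
                                             log2_effect = 0,
                                             fraction = 0.4))
  sim <- simulate_mutations(cfg)
  counts <- simulate_expression(sim$sample_sheet, cfg)
  des <- training_design(sim$sample_sheet)
  vst <- vst_transform(counts)[, des$case_id]
  de <- differential_expression(vst, des$role == "tumor")
  expect_equal(sum(de$selected), 0L)
})
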