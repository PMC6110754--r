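maf_row <- function(case, gene = "NFE2L2", pos = 1000L, ref = "C",
                    alt = "A", cls = "Missense_Mutation",
                    hgvsp = "p.R34G", type = "LUSC") {
  data.frame(Tumor_Sample_Barcode = paste0(case, "-01A"),
             tumor_type = type, Hugo_Symbol = gene, Chromosome = "chr1",
             Start_Position = pos, Reference_Allele = ref,
             Tumor_Seq_Allele2 = alt, Variant_Classification = cls,
             HGVSp_Short = hgvsp, stringsAsFactors = FALSE)
}

test_that("consensus filter keeps only multiply-called records", {
  r <- maf_row("TCGA-01-0001")
  calls <- list(MuSE = r, MuTect2 = r[0, ], SomaticSniper = r[0, ],
                VarScan2 = r[0, ])
  expect_equal(nrow(merge_caller_calls(calls, min_callers = 2)), 0L)
  expect_equal(nrow(merge_caller_calls(calls, min_callers = 1)), 1L)

  two <- list(MuSE = r, MuTect2 = r)
  cons <- merge_caller_calls(two, min_callers = 2)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_callers, 2L)
  expect_equal(cons$callers, "MuSE;MuTect2")
  expect_equal(cons$case_id, "TCGA-01-0001")
  expect_equal(cons$variant_class, "missense")
  expect_equal(cons$protein_pos, 34L)

  expect_warning(merge_caller_calls(list(MuSE = rbind(r, r),
                                         MuTect2 = r)),
                 "deduplicated")
  expect_error(merge_caller_calls(list(Strelka = r)), "unknown")
})

test_that("raising min_callers never adds records", {
  sim <- simulate_mutations(small_config(seed = 21))
  sizes <- vapply(1:4, function(k)
    nrow(merge_caller_calls(sim$per_caller, min_callers = k)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # min_callers = 1 recovers every unique key across callers
  all_keys <- unique(unlist(lapply(sim$per_caller, function(tab)
    paste(tab$Tumor_Sample_Barcode, tab$Hugo_Symbol, tab$Chromosome,
          tab$Start_Position, tab$Reference_Allele, tab$Tumor_Seq_Allele2))))
  expect_equal(sizes[1], length(all_keys))
})

test_that("consensus at full concordance equals the planted truth exactly", {
  cfg <- small_config(seed = 22, caller_concordance = 1, spurious_rate = 2)
  sim <- simulate_mutations(cfg)
  cons <- merge_caller_calls(sim$per_caller, min_callers = 2)
  key <- function(df) paste(df$Tumor_Sample_Barcode, df$Hugo_Symbol,
                            df$Start_Position, df$Reference_Allele,
                            df$Tumor_Seq_Allele2)
  expect_setequal(key(cons), key(sim$truth))
  expect_true(all(cons$n_callers == 4L))
})

test_that("substitutions classify as transition or transversion", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_equal(classify_substitution("T", "C"), "transition")
  # strand-flip invariance over all 12 ordered pairs
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) for (a in setdiff(names(comp), r))
    expect_equal(classify_substitution(r, a),
                 classify_substitution(comp[[r]], comp[[a]]))
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "A, C, G, T")
})

test_that("protein-change strings parse to residue, position and class", {
  p <- parse_protein_change(c("p.R34G", "p.R34*", "p.D29H", "p.E82fs",
                              "", "p.T80T"))
  expect_equal(p$ref_aa, c("R", "R", "D", "E", NA, "T"))
  expect_equal(p$protein_pos, c(34L, 34L, 29L, 82L, NA, 80L))
  expect_equal(p$alt_aa, c("G", "*", "H", "fs", NA, "T"))
  expect_equal(p$variant_class,
               c("missense", "nonsense", "missense", "frameshift", NA,
                 "silent"))
  expect_message(p2 <- parse_protein_change(c("p.R34G", "garbage")),
                 "malformed")
  expect_equal(attr(p2, "n_malformed"), 1L)
  expect_true(is.na(p2$protein_pos[2]))
})

test_that("mutant case sets are unique, filtered and warn on unknown genes", {
  empty <- make_consensus(character(0), "NFE2L2", integer(0))
  expect_equal(mutant_case_sets(empty, "NFE2L2"), character(0))

  cons <- make_consensus(c("A", "A", "B", "C"), "NFE2L2", c(34, 80, 34, 12),
                         variant_class = c("missense", "missense",
                                           "missense", "silent"))
  expect_setequal(mutant_case_sets(cons, "NFE2L2"), c("A", "B"))
  expect_setequal(mutant_case_sets(cons, "NFE2L2",
                                   nonsynonymous_only = FALSE),
                  c("A", "B", "C"))
  expect_warning(out <- mutant_case_sets(cons, "KEAP1"), "not present")
  expect_equal(out, character(0))
})

test_that("exact overlap test matches hand enumeration and brute force", {
  res <- overlap_test(5L, 4L, 10L, observed = 4L)
  expect_equal(res$p_value, 5 / 210)
  expect_equal(res$expected, 2)

  # disjoint sets: k = 0 gives p = 1
  expect_equal(overlap_test(c("a", "b"), c("c", "d"), 10L)$p_value, 1)

  # exact mode equals full subset-pair enumeration on a small universe
  for (k in 0:3)
    expect_equal(overlap_test(3L, 3L, 8L, observed = k)$p_value,
                 brute_overlap_p(8, 3, 3, k))

  expect_error(overlap_test(20L, 4L, 10L, observed = 2L), "universe")
})

test_that("Monte-Carlo overlap p converges to the exact tail", {
  exact <- overlap_test(6L, 5L, 15L, observed = 3L)$p_value
  mc <- overlap_test(6L, 5L, 15L, observed = 3L, mode = "montecarlo",
                     m = 4000L, seed = 9L)
  expect_lt(abs(mc$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 4000))
})

test_that("case burden counts events and substitution classes", {
  cons <- data.frame(case_id = c("A", "A", "A"),
                     Reference_Allele = c("A", "C", "A"),
                     Tumor_Seq_Allele2 = c("G", "A", "-"),
                     stringsAsFactors = FALSE)
  b <- case_burden(cons, case_ids = c("A", "B"))
  expect_equal(b$n_total, c(3L, 0L))
  expect_equal(b$n_transition, c(1L, 0L))
  expect_equal(b$n_transversion, c(1L, 0L))
})

test_that("pooled transition fraction follows the configured odds", {
  cfg <- small_config(seed = 23, n_cases = 300L, ts_tv_ratio = 2,
                      caller_concordance = 1, spurious_rate = 0)
  sim <- simulate_mutations(cfg)
  cons <- merge_caller_calls(sim$per_caller)
  b <- case_burden(cons)
  ts <- sum(b$n_transition); tv <- sum(b$n_transversion)
  expect_lt(abs(ts / (ts + tv) - 2 / 3),
            3 * sqrt(2 / 3 * 1 / 3 / (ts + tv)))
})

test_that("burden comparison uses the exact Mann-Whitney distribution", {
  burden <- data.frame(case_id = letters[1:6], n_total = c(10, 11, 12,
                                                           1, 2, 3),
                       n_transition = 0L, n_transversion = 0L)
  res <- burden_comparison(burden, activated = rep(c(TRUE, FALSE),
                                                   each = 3),
                           tumor_type = rep("LUSC", 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$median_active, 11)
  expect_equal(res$p_value, exact_mw_p(c(10, 11, 12), c(1, 2, 3)))

  same <- data.frame(case_id = letters[1:8],
                     n_total = rep(c(4, 7, 9, 2), 2),
                     n_transition = 0L, n_transversion = 0L)
  res2 <- burden_comparison(same, activated = rep(c(TRUE, FALSE), each = 4),
                            tumor_type = rep("LUSC", 8))
  expect_gt(res2$p_value, 0.9)

  expect_warning(burden_comparison(burden, activated = rep(TRUE, 6),
                                   tumor_type = rep("LUSC", 6)),
                 "skipped")
})

test_that("shifted burden is detected with high power", {
  set.seed(31)
  hits <- vapply(1:5, function(i) {
    x <- stats::rpois(40, 30)  # active: +50%
    y <- stats::rpois(40, 20)
    burden <- data.frame(case_id = sprintf("c%02d", 1:80),
                         n_total = c(x, y), n_transition = 0L,
                         n_transversion = 0L)
    burden_comparison(burden, activated = rep(c(TRUE, FALSE), each = 40),
                      tumor_type = rep("LUSC", 80))$p_value < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("Pearson correlation with Fisher-transform p matches oracles", {
  r1 <- pearson_fisher_test(1:5, 2 * (1:5))
  expect_equal(r1$r, 1)
  expect_equal(r1$p_value, 0)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- pearson_fisher_test(x, y)
  expect_equal(res$r, stats::cor(x, y))
  expect_equal(res$r, 0.8)
  expect_equal(res$p_value, 2 * stats::pnorm(-atanh(0.8) * sqrt(2)))

  expect_warning(bad <- pearson_fisher_test(rep(1, 5), 1:5),
                 "zero variance")
  expect_true(is.na(bad$r))
  expect_error(pearson_fisher_test(1:3, 1:3), "at least 4")
})

test_that("activation correlates with transversion burden on planted data", {
  set.seed(41)
  n_types <- 20
  tv <- stats::rpois(n_types, 40)
  act <- stats::plogis((tv - 40) / 8) + stats::rnorm(n_types, 0, 0.05)
  ts <- stats::rpois(n_types, 30)
  res <- activation_mutation_correlation(act, tv, ts)
  expect_gt(res$transversion$r, 0)
  expect_lt(res$transversion$p_value, 0.05)
})
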