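# NB-Wald differential expression, size factors and signature derivation.

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(rpois(200, 20) + 1, 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  # identical samples -> all factors 1
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))
  # B = 2A elementwise -> (1/sqrt(2), sqrt(2))
  two <- cbind(A = m[, 1], B = 2L * m[, 1])
  expect_equal(unname(estimate_size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # invariance under gene permutation
  perm <- sample(nrow(m))
  expect_equal(estimate_size_factors(m), estimate_size_factors(m[perm, ]))
  # all-zero sample is rejected by name
  bad <- m; bad[, 2] <- 0L
  expect_error(estimate_size_factors(bad), "s2")
})

test_that("Wald statistics are N(0,1) on label-permuted null data", {
  p0 <- cytokine_program("null", up_genes = integer(), log2fc_up = 0)
  gb <- generate_bulk(list(p0), n_genes = 3000L, seed = 21L)
  de <- nb_wald_de(gb$bulk, "null")
  w <- de$wald_stat[!is.na(de$p_adj)]
  ks <- suppressWarnings(stats::ks.test(w, "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lt(abs(median(de$log2fc, na.rm = TRUE)), 0.05)
})

test_that("BH adjustment respects its bounds and monotonicity", {
  p0 <- cytokine_program("null", up_genes = 1:20, log2fc_up = 1)
  gb <- generate_bulk(list(p0), n_genes = 500L, seed = 3L)
  de <- nb_wald_de(gb$bulk, "null")
  ok <- !is.na(de$p_adj)
  expect_true(all(de$p_adj[ok] >= de$p[ok]))
  expect_true(all(de$p_adj[ok] >= 0 & de$p_adj[ok] <= 1))
  o <- order(de$p[ok])
  expect_true(!is.unsorted(de$p_adj[ok][o]))
})

test_that("NB-Wald estimates agree with an established NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  p <- cytokine_program("TNF", up_genes = 1:30, down_genes = 31:60,
                        log2fc_up = 1.5, log2fc_down = 1.5)
  gb <- generate_bulk(list(p), n_genes = 400L, seed = 13L)
  de <- nb_wald_de(gb$bulk, "TNF")
  sel <- gb$bulk$condition %in% c("TNF", "control")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    gb$bulk$counts[, sel],
    S4Vectors::DataFrame(condition = factor(gb$bulk$condition[sel],
                                            levels = c("control", "TNF"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(de$log2fc) & !is.na(res$log2FoldChange) & de$base_mean > 5
  expect_gt(cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.98)
  # size factors match the reference implementation exactly
  expect_equal(unname(estimate_size_factors(gb$bulk$counts[, sel])),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
  # significance calls agree on the planted fixture
  called_ours <- de$gene[!is.na(de$p_adj) & de$p_adj < 0.05]
  called_ref <- rownames(res)[!is.na(res$padj) & res$padj < 0.05]
  jaccard <- length(intersect(called_ours, called_ref)) /
    length(union(called_ours, called_ref))
  expect_gt(jaccard, 0.8)
})

test_that("signature derivation thresholds nest and empty results warn", {
  p <- cytokine_program("TNF", up_genes = 1:40, down_genes = 41:80)
  gb <- generate_bulk(list(p), n_genes = 600L, seed = 17L)
  de <- nb_wald_de(gb$bulk, "TNF")
  s05 <- derive_signature(de, 0.05)
  s01 <- derive_signature(de, 0.01)
  expect_true(all(s01$up %in% s05$up))
  expect_true(all(s01$down %in% s05$down))
  expect_true(all(startsWith(s05$provenance, "condition=TNF")))

  de_null <- de
  de_null$p_adj[!is.na(de_null$p_adj)] <- 1
  expect_warning(s0 <- derive_signature(de_null), "empty")
  expect_length(c(s0$up, s0$down), 0)
})

test_that("signature derivation commutes with gene relabeling", {
  p <- cytokine_program("TNF", up_genes = 1:30)
  gb <- generate_bulk(list(p), n_genes = 300L, seed = 19L)
  de <- nb_wald_de(gb$bulk, "TNF")
  sig <- derive_signature(de)
  relabel <- setNames(paste0("X_", de$gene), de$gene)
  de2 <- de
  de2$gene <- unname(relabel[de$gene])
  sig2 <- derive_signature(de2)
  expect_setequal(sig2$up, unname(relabel[sig$up]))
  expect_setequal(sig2$down, unname(relabel[sig$down]))
})

test_that("cell-type restriction keeps exactly the exclusive genes", {
  sig <- gene_signature("s", up = c("g1", "g2", "g3"), down = c("g4", "g5"))
  tab <- rbind(g1 = c(FLS = 10, Tcell = 1, B = 0.5),
               g2 = c(5, 4, 6),      # not exclusive
               g3 = c(8, 0, 0),
               g4 = c(6, 2, 1))      # g5 absent
  expect_warning(r <- restrict_signature(sig, tab, "FLS", 2), "absent")
  expect_setequal(r$up, c("g1", "g3"))
  expect_setequal(r$down, "g4")
  # ratio 0 keeps everything present
  expect_warning(r0 <- restrict_signature(sig, tab, "FLS", 0), "absent")
  expect_setequal(c(r0$up, r0$down), c("g1", "g2", "g3", "g4"))
})

test_that("dll4_shift reports no dampening for identical tables and recovers planted attenuation", {
  p <- cytokine_program("TNF", up_genes = 1:40, down_genes = 41:80)
  gb <- generate_bulk(list(p), n_genes = 600L, seed = 23L,
                      combinations = list(list(programs = "TNF",
                                               name = "TNF+DLL4",
                                               effect_scale = 0.5)))
  de_alone <- nb_wald_de(gb$bulk, "TNF")
  sig <- derive_signature(de_alone)
  same <- dll4_shift(de_alone, de_alone, sig)
  expect_equal(same$median_paired_diff, 0)
  expect_false(same$dampening)

  de_dll4 <- nb_wald_de(gb$bulk, "TNF+DLL4")
  shift <- dll4_shift(de_alone, de_dll4, sig)
  expect_lt(abs(shift$median_abs_ratio - 0.5), 0.12)
  expect_true(shift$dampening)
  # both directions report shrinkage as positive
  expect_gt(shift$median_shrink_up, 0)
  expect_gt(shift$median_shrink_down, 0)
  # too few shared genes is an error
  tiny <- gene_signature("tiny", up = gene_ids(1:3))
  expect_error(dll4_shift(de_alone, de_dll4, tiny), "fewer than 5")
})
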