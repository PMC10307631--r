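# QC filtering, normalization, signature scoring, hurdle DE, HVG selection
# and cluster merging.

make_qc_fixture <- function() {
  # 10 cells x 6 genes (one mitochondrial); 3 planted failures:
  # two low-depth cells and one 25%-mito cell. Two boundary cells sit
  # exactly at the thresholds and must be kept.
  g <- c(gene_ids(1:5), "MT-1")
  m <- matrix(0L, 10, 6, dimnames = list(sprintf("c%02d", 1:10), g))
  m[1, 1:5] <- 400L                      # 2000 total, no mito
  m[2, 1:5] <- 300L                      # 1500 total
  m[3, ] <- c(rep(205L, 5), 0L)          # 1025 total
  m[4, ] <- c(rep(204L, 4), 208L, 0L)    # exactly 1024, kept (strict <)
  m[5, 1:5] <- 100L                      # 500 total: low depth
  m[6, 1] <- 900L                        # 900 total: low depth
  m[7, ] <- c(rep(240L, 5), 400L)        # 1600 total, 25% mito: removed
  m[8, ] <- c(rep(240L, 5), 300L)        # exactly 20% mito, kept (strict >)
  m[9, 1:5] <- 500L
  m[10, 1:5] <- 600L
  m
}

test_that("QC filter honors both rules and their exact boundaries", {
  m <- make_qc_fixture()
  qc <- qc_filter_cells(m)
  expect_equal(qc$report$n_removed_libsize, 2L)
  expect_equal(qc$report$n_removed_mito, 1L)
  expect_setequal(rownames(qc$counts),
                  c("c01", "c02", "c03", "c04", "c08", "c09", "c10"))
  expect_true("c04" %in% rownames(qc$counts))  # exactly 1024 molecules kept
  expect_true("c08" %in% rownames(qc$counts))  # exactly 20% mito kept
  # permissive thresholds are the identity
  qc0 <- qc_filter_cells(m, mito_max = 1, libsize_min = 0L)
  expect_identical(qc0$counts, m)
  expect_error(qc_filter_cells(m, libsize_min = 10000L), "no cells")
})

test_that("normalization matches its closed form and is scale-invariant", {
  m <- matrix(0L, 3, 4, dimnames = list(paste0("c", 1:3), gene_ids(1:4)))
  m[1, 2] <- 7L
  m[2, ] <- c(10L, 20L, 30L, 40L)
  m[3, ] <- 2L * m[2, ]
  x <- normalize_log(m)
  expect_equal(x[1, 2], log1p(1e5))
  # doubling all counts of a cell leaves its normalized vector unchanged
  expect_equal(x[2, ], x[3, ])
  # expm1 then rescale recovers count proportions
  prop <- expm1(x[2, ]) / sum(expm1(x[2, ]))
  expect_equal(unname(prop), c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-10)
  # spatial mode scales to the median total
  xm <- normalize_log(m, scale = "median")
  expect_equal(attr(xm, "scale_factor"), median(rowSums(m)))
  m[1, ] <- 0L
  expect_error(normalize_log(m), "c1")
})

test_that("an all-gene signature scores exactly zero before the final z", {
  sc <- fixture_sc()
  expr <- normalize_log(sc$counts)
  sig_all <- gene_signature("all", up = colnames(expr))
  s <- suppressWarnings(score_signature(expr, sig_all, final_z = FALSE))
  expect_lt(max(abs(s)), 1e-8)
})

test_that("a constant matrix yields zero scores with a warning", {
  m <- matrix(5, 30, 40, dimnames = list(paste0("c", 1:30), gene_ids(1:40)))
  sig <- gene_signature("s", up = gene_ids(1:5))
  w <- capture_warnings(s <- score_signature(m, sig, n_ctrl = 3L))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(s == 0))
})

test_that("signature scores separate planted program cells by > 1 z-unit", {
  sc <- fixture_sc()
  expr <- normalize_log(sc$counts)
  sig <- gene_signature("prog", up = gene_ids(1:50))
  s <- suppressWarnings(score_signature(expr, sig, seed = 3L))
  st <- sc$truth$state_of_cell[names(s)]
  expect_gt(mean(s[st == "act"]) - mean(s[st == "rest"]), 1)
})

test_that("scores are invariant to gene and observation order at fixed seed", {
  sc <- fixture_sc()
  expr <- as.matrix(normalize_log(sc$counts))[1:100, ]
  sig <- gene_signature("prog", up = gene_ids(c(3, 10, 25)),
                        down = gene_ids(c(60, 61)))
  s1 <- suppressWarnings(score_signature(expr, sig, n_ctrl = 10L, seed = 5L))
  gperm <- sample(ncol(expr))
  s2 <- suppressWarnings(score_signature(expr[, gperm], sig, n_ctrl = 10L,
                                         seed = 5L))
  expect_equal(s1, s2)
  operm <- sample(nrow(expr))
  s3 <- suppressWarnings(score_signature(expr[operm, ], sig, n_ctrl = 10L,
                                         seed = 5L))
  expect_equal(s1[names(s3)], s3, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("down genes lower the score of cells expressing them", {
  sc <- fixture_sc()
  expr <- normalize_log(sc$counts)
  sig_dn <- gene_signature("prog_dn", down = gene_ids(1:50))
  s <- suppressWarnings(score_signature(expr, sig_dn, seed = 3L))
  st <- sc$truth$state_of_cell[names(s)]
  expect_lt(mean(s[st == "act"]) - mean(s[st == "rest"]), -1)
})

test_that("hurdle DE finds nothing on a random split of homogeneous cells", {
  st <- list(state_spec("a", 200L), state_spec("b", 200L))
  sc <- generate_single_cell(st, n_genes = 300L, seed = 31L,
                             low_depth_frac = 0, high_mito_frac = 0)
  expr <- normalize_log(sc$counts)
  groups <- with_seed(1L, sample(rep(c("g1", "g2"), each = 200L)))
  de <- hurdle_de(expr, groups)
  expect_equal(sum(de$p_bonf < 0.05), 0L)
})

test_that("hurdle DE recovers a planted 4x program with high sensitivity", {
  sc <- fixture_sc()
  expr <- normalize_log(sc$counts)
  st <- sc$truth$state_of_cell[rownames(expr)]
  de <- hurdle_de(expr, st)
  hits <- de$gene[de$p_bonf < 0.05]
  expect_gte(mean(gene_ids(1:50) %in% hits), 0.8)
  # genes detected nowhere are absent from the output
  expect_true(all(de$gene %in% colnames(expr)[Matrix::colSums(expr > 0) >= 5]))
})

test_that("hurdle null p-values are uniform or super-uniform", {
  st <- list(state_spec("a", 150L), state_spec("b", 150L))
  sc <- generate_single_cell(st, n_genes = 500L, seed = 37L,
                             low_depth_frac = 0, high_mito_frac = 0)
  expr <- normalize_log(sc$counts)
  groups <- with_seed(2L, sample(rep(c("g1", "g2"), each = 150L)))
  de <- hurdle_de(expr, groups)
  # super-uniform: empirical CDF at q never exceeds q by more than noise
  qs <- c(0.01, 0.05, 0.1, 0.25, 0.5)
  emp <- vapply(qs, function(q) mean(de$p <= q), 0)
  expect_true(all(emp <= qs + 2 * sqrt(qs * (1 - qs) / nrow(de))))
})

test_that("HVG selection prefers planted variable genes and ignores batch labels", {
  p <- cytokine_program("prog", up_genes = 1:30, log2fc_up = 2)
  states <- list(state_spec("rest", 150L),
                 state_spec("act", 150L, programs = list(p)))
  sc <- generate_single_cell(states, n_genes = 400L, seed = 41L,
                             low_depth_frac = 0, high_mito_frac = 0)
  expr <- normalize_log(sc$counts)
  hv <- select_hvgs(expr, n_top = 60L)
  expect_gte(mean(gene_ids(1:30) %in% hv), 0.8)
  # constant gene never selected
  e2 <- cbind(as.matrix(expr), CONSTANT = rep(1, nrow(expr)))
  hv2 <- select_hvgs(e2, n_top = 60L)
  expect_false("CONSTANT" %in% hv2)
  # invariant to batch label permutation
  b <- rep(c("x", "y"), length.out = nrow(expr))
  hv3 <- select_hvgs(expr, batches = b, n_top = 60L)
  hv4 <- select_hvgs(expr, batches = rev(b), n_top = 60L)
  expect_setequal(hv3, hv4)
  # masked genes are excluded
  expect_false(any(startsWith(hv, "MT-")))
  expect_warning(select_hvgs(expr, n_top = 10000L), "n_top")
})

test_that("cluster merging recovers planted two-program block structure", {
  pa <- cytokine_program("A", up_genes = 1:40, log2fc_up = 3)
  pb <- cytokine_program("B", up_genes = 41:80, log2fc_up = 3)
  states <- list(state_spec("a", 160L, programs = list(pa)),
                 state_spec("b", 160L, programs = list(pb)))
  sc <- generate_single_cell(states, n_genes = 400L, seed = 43L,
                             low_depth_frac = 0, high_mito_frac = 0)
  expr <- normalize_log(sc$counts)
  st <- sc$truth$state_of_cell[rownames(expr)]
  # split each state into two clusters
  clusters <- paste0(st, rep(1:2, length.out = length(st)))
  hv <- select_hvgs(expr, n_top = 100L)
  merged <- cluster_state_merge(expr, clusters, hv)
  expect_equal(merged$n_states, 2L)
  expect_equal(unname(merged$map["a1"]), unname(merged$map["a2"]))
  expect_equal(unname(merged$map["b1"]), unname(merged$map["b2"]))
  expect_false(merged$map[["a1"]] == merged$map[["b1"]])
  # correlation matrix is symmetric with unit diagonal
  expect_equal(merged$cor, t(merged$cor))
  expect_equal(unname(diag(merged$cor)), rep(1, 4))
  # a duplicated cluster correlates at 1 and merges
  dup <- cluster_state_merge(
    rbind(expr, expr[clusters == "a1", ]),
    c(clusters, rep("a1bis", sum(clusters == "a1"))), hv)
  expect_equal(dup$cor["a1", "a1bis"], 1, tolerance = 1e-12)
  expect_equal(unname(dup$map["a1"]), unname(dup$map["a1bis"]))
})
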