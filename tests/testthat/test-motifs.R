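# Motif accessibility deviations: expectation model, background matching,
# z-scores against a brute-force oracle, expression gating, ranking.

test_that("expected counts match the hand-computed toy example and conserve totals", {
  # 3 peaks x 2 cells, motif = {p1, p2}: T = 3, d = (2, 2), D = 4 -> E = 1.5
  X <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), c("c1", "c2")))
  M <- matrix(c(1, 1, 0), 1, 3, dimnames = list("m1", rownames(X)))
  pm <- peak_matrix(X)
  mm <- motif_match(M, list(m1 = "TF1"))
  E <- expected_counts(pm, mm)
  expect_equal(unname(E["m1", ]), c(1.5, 1.5))
  expect_equal(sum(E["m1", ]), 3)
  # a homogeneous all-ones matrix has zero raw deviation
  X1 <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
  pm1 <- peak_matrix(X1, gc = rep(0.5, 4))
  mm1 <- motif_match(matrix(c(1, 1, 0, 0), 1, 4,
                            dimnames = list("m1", rownames(X1))),
                     list(m1 = "TF1"))
  bg1 <- suppressWarnings(sample_backgrounds(pm1, n_background = 4L, seed = 1L))
  dev1 <- compute_deviations(pm1, mm1, bg1)
  expect_lt(max(abs(dev1$raw)), 1e-12)
})

test_that("deviation z-scores match the brute-force oracle to 1e-10", {
  at <- generate_atac(n_peaks = 60L, n_cells = 25L, n_motifs = 6L, seed = 8L)
  bg <- sample_backgrounds(at$peaks, n_background = 20L, seed = 3L)
  dev <- compute_deviations(at$peaks, at$motifs, bg)
  oracle <- oracle_deviations(at$peaks$binary, at$motifs$match, bg)
  expect_lt(max(abs(dev$raw - oracle$raw), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(dev$z - oracle$z), na.rm = TRUE), 1e-10)
  # conservation: per-motif raw deviations sum to zero
  expect_lt(max(abs(rowSums(dev$raw, na.rm = TRUE))), 1e-8)
})

test_that("self-backgrounds collapse the deviation against its own expectation", {
  at <- generate_atac(n_peaks = 50L, n_cells = 20L, n_motifs = 3L, seed = 12L)
  self_bg <- matrix(rep(seq_len(50L), 10L), 50L, 10L)
  attr(self_bg, "seed") <- 0L
  dev <- compute_deviations(at$peaks, at$motifs, self_bg)
  # background deviations equal the observed one exactly: the numerator is
  # zero, so the z-score is either numerically ~0 or undefined (zero
  # background sd)
  expect_true(all(is.na(dev$z) | abs(dev$z) < 1e-6))
})

test_that("background sampling respects covariate structure", {
  # two well-separated covariate clusters: backgrounds stay within-cluster
  n <- 200L
  gc <- c(runif(n / 2, 0.2, 0.3), runif(n / 2, 0.7, 0.8))
  at <- generate_atac(n_peaks = n, n_cells = 80L, gc = gc, gc_slope = 4,
                      seed = 21L)
  bg <- sample_backgrounds(at$peaks, n_background = 25L, seed = 4L)
  cluster <- rep(1:2, each = n / 2)
  same <- mean(cluster[as.vector(bg)] ==
                 cluster[rep(seq_len(n), times = 25L)])
  expect_gte(same, 0.99)
  # identical covariates: degenerate covariance falls back with a warning
  at2 <- generate_atac(n_peaks = 80L, n_cells = 40L, gc = rep(0.5, 80L),
                       seed = 22L)
  expect_warning(bg2 <- sample_backgrounds(at2$peaks, n_background = 10L,
                                           seed = 5L),
                 "degenerate|rank")
  # seeded determinism
  b1 <- sample_backgrounds(at$peaks, n_background = 10L, seed = 9L)
  b2 <- sample_backgrounds(at$peaks, n_background = 10L, seed = 9L)
  expect_identical(b1, b2)
})

test_that("null deviations are calibrated under permuted labels", {
  at <- generate_atac(n_peaks = 250L, n_cells = 120L, n_motifs = 10L,
                      seed = 31L)
  bg <- sample_backgrounds(at$peaks, n_background = 50L, seed = 6L)
  dev <- compute_deviations(at$peaks, at$motifs, bg)
  mu <- rowMeans(dev$z, na.rm = TRUE)
  sdv <- apply(dev$z, 1L, sd, na.rm = TRUE)
  ok <- !rownames(dev$z) %in% dev$flagged
  expect_true(all(abs(mu[ok]) < 0.25))
  expect_true(all(sdv[ok] > 0.8 & sdv[ok] < 1.3))
})

test_that("expression gate honors the strict >20% boundary", {
  z <- matrix(rnorm(300), 3, 100,
              dimnames = list(paste0("m", 1:3), paste0("c", 1:100)))
  dev <- structure(list(z = z, flagged = character()),
                   class = "deviation_result")
  mm <- motif_match(matrix(1, 3, 5, dimnames = list(paste0("m", 1:3), NULL)),
                    list(m1 = "TF1", m2 = "TF2", m3 = "TF3"))
  states <- rep("s1", 100L)
  expr <- matrix(0L, 100L, 3L,
                 dimnames = list(paste0("c", 1:100), c("TF1", "TF2", "TF4")))
  expr[1:21, "TF1"] <- 1L   # 21% detection: passes strict > 0.2
  expr[1:20, "TF2"] <- 1L   # exactly 20%: does not pass
  expect_warning(gate <- expression_gate(dev, mm, expr, states), "no TF")
  expect_true("m1" %in% gate$s1)
  expect_false("m2" %in% gate$s1)
  expect_false("m3" %in% gate$s1)  # TF absent from matrix -> dropped
  # min_frac = 0 admits every motif whose TF is present and detected
  gate0 <- suppressWarnings(expression_gate(dev, mm, expr, states,
                                            min_frac = 0))
  expect_setequal(gate0$s1, c("m1", "m2"))
  # raising min_frac never admits a new motif
  gate_hi <- suppressWarnings(expression_gate(dev, mm, expr, states,
                                              min_frac = 0.5))
  expect_true(all(gate_hi$s1 %in% gate0$s1))
})

test_that("motif ranking matches exact rank-sum enumeration and caps at n_top", {
  # 4 vs 4 cells with distinct values: U equals direct pair counting
  x <- c(9.1, 7.3, 5.2, 8.4); y <- c(1.1, 3.9, 2.5, 6.6)
  z <- matrix(c(x, y, rnorm(8)), 2, 8, byrow = TRUE,
              dimnames = list(c("mA", "mB"), paste0("c", 1:8)))
  dev <- structure(list(z = z, flagged = character()),
                   class = "deviation_result")
  states <- rep(c("s1", "s2"), each = 4L)
  rk <- rank_motifs(dev, states, n_top = 6L)
  u <- oracle_wilcoxon_u(x, y)
  n1 <- 4; n2 <- 4
  z_exp <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(rk$score[rk$state == "s1" & rk$motif == "mA"], z_exp,
               tolerance = 1e-12)
  # indicator motif is maximally separated and ranks first
  at <- generate_atac(n_peaks = 200L, n_cells = 100L, n_motifs = 8L,
                      motif_activity = {
                        a <- matrix(0, 8, 2); a[3, 2] <- 3; a
                      }, seed = 41L)
  bg <- sample_backgrounds(at$peaks, n_background = 30L, seed = 7L)
  dev2 <- compute_deviations(at$peaks, at$motifs, bg)
  rk2 <- rank_motifs(dev2, at$state_of_cell, n_top = 6L)
  expect_equal(rk2$motif[rk2$state == "B" & rk2$rank == 1L], "motif_03")
  expect_true(all(table(rk2$state) <= 6L))
})
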