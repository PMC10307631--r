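# Single-cell / spot normalization, QC, signature scoring, hurdle-model DE,
# preranked GSEA and cluster-to-state merging.
#
# Matrix orientation throughout the analysis layer: observations (cells or
# spots) in rows, genes in columns.

default_gene_mask <- function(genes) {
  genes[startsWith(genes, "MT-") | startsWith(genes, "RPS") |
          startsWith(genes, "RPL") | genes == "MALAT1"]
}

#' Quality-control cell filter
#'
#' Removes cells whose mitochondrial fraction exceeds `mito_max` (strict
#' `>`: a cell at exactly the threshold is kept) or whose library size falls
#' below `libsize_min` (strict `<`: a cell with exactly `libsize_min`
#' molecules is kept). Mitochondrial genes are identified by name prefix.
#'
#' @param counts Raw counts, cells x genes, with gene names.
#' @param mito_max Maximum mitochondrial fraction (default 0.20).
#' @param libsize_min Minimum library size (default 1024 molecules).
#' @param mito_prefix Gene-name prefix marking mitochondrial genes.
#' @return List with `counts` (filtered) and `report` (removed barcodes per
#'   rule and totals).
#' @export
qc_filter_cells <- function(counts, mito_max = 0.2, libsize_min = 1024L,
                            mito_prefix = "MT-") {
  assert_count_matrix(counts, "cell counts")
  tot <- row_sums(counts)
  mgenes <- startsWith(colnames(counts), mito_prefix)
  mfrac <- if (any(mgenes)) row_sums(counts[, mgenes, drop = FALSE]) / pmax(tot, 1)
           else numeric(nrow(counts))
  bad_mito <- mfrac > mito_max
  bad_depth <- tot < libsize_min
  keep <- !(bad_mito | bad_depth)
  if (!any(keep)) stop_validation("no cells survive QC filtering")
  report <- list(
    n_input = nrow(counts), n_kept = sum(keep),
    n_removed_mito = sum(bad_mito), n_removed_libsize = sum(bad_depth),
    removed_mito = rownames(counts)[bad_mito],
    removed_libsize = rownames(counts)[bad_depth],
    mito_max = mito_max, libsize_min = libsize_min)
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Library-size normalization with log transform
#'
#' `x = ln(1 + s * c / total)` per cell, with scale `s` either a fixed
#' target (100,000 molecules for single cells) or the median of per-cell
#' totals (the spatial convention).
#'
#' @param counts Raw counts, cells x genes.
#' @param scale `"fixed"` or `"median"`.
#' @param scale_factor Target sum when `scale = "fixed"`.
#' @return Normalized matrix (same class/sparsity) with attributes
#'   `scale_factor` and `normalized = TRUE`.
#' @export
normalize_log <- function(counts, scale = c("fixed", "median"),
                          scale_factor = 1e5) {
  scale <- match.arg(scale)
  tot <- row_sums(counts)
  if (any(tot == 0))
    stop_validation(sprintf("observation '%s' has zero total counts",
                            rownames(counts)[which(tot == 0)[1L]] %||%
                              as.character(which(tot == 0)[1L])))
  s <- if (scale == "fixed") scale_factor else median(tot)
  if (inherits(counts, "dgCMatrix")) {
    out <- Matrix::Diagonal(x = s / tot) %*% counts
    out@x <- log1p(out@x)
    out <- as(out, "CsparseMatrix")
    dimnames(out) <- dimnames(counts)
  } else {
    out <- log1p(sweep(as.matrix(counts), 1L, tot / s, "/"))
  }
  attr(out, "scale_factor") <- s
  attr(out, "normalized") <- TRUE
  out
}

# gene-wise z-score of a dense columns-subset; sd 0 -> 0
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

#' Score a directed gene signature on cells or spots
#'
#' The normalized matrix is gene-wise z-scored; genes are binned into
#' `n_bins` expression bins by mean expression; each signature gene draws
#' `n_ctrl` control genes from the non-signature members of its bin (when a
#' bin has no non-signature gene, the whole bin's mean is used, which makes
#' the score exactly zero for an all-gene signature). The per-observation
#' score is mean(z of up genes) - mean(z of their controls), minus the same
#' contrast for down genes, and the score column is finally z-scored.
#'
#' @param expr Normalized matrix from [normalize_log()], cells x genes.
#' @param sig A [gene_signature()].
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes sampled per signature gene (default 50).
#' @param seed Seed for control sampling.
#' @param final_z Apply the final column z-score (disable to inspect raw
#'   control-subtracted scores).
#' @return Numeric per-observation score vector with attribute `method`
#'   recording the parameters.
#' @export
score_signature <- function(expr, sig, n_bins = 25L, n_ctrl = 50L,
                            seed = 1L, final_z = TRUE) {
  genes <- colnames(expr)
  sig_up <- sort(intersect(sig$up, genes))
  sig_down <- sort(intersect(sig$down, genes))
  if (!length(sig_up) && !length(sig_down))
    stop_validation(sprintf("no gene of signature '%s' present in matrix", sig$name))
  mu <- col_means(expr)
  rk <- rank(mu, ties.method = "first")
  bin <- ceiling(rk / (length(genes) / n_bins))
  names(bin) <- genes
  in_sig <- genes %in% c(sig_up, sig_down)

  # canonical ordering makes control draws invariant to input gene order
  ord <- order(genes)
  pools <- split(genes[ord], bin[ord])
  pick_controls <- function(sgenes) {
    # one control set per signature gene; reference term averages the
    # per-gene control means, which makes an all-gene signature score
    # exactly zero (each gene's reference is then its whole bin's mean)
    lapply(sgenes, function(g) {
      pool <- setdiff(pools[[as.character(bin[g])]], c(sig_up, sig_down))
      if (!length(pool)) {
        pools[[as.character(bin[g])]]          # deterministic full bin
      } else if (length(pool) < n_ctrl) {
        warning("expression bin smaller than n_ctrl; sampling with replacement")
        sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl)
      }
    })
  }
  with_seed(seed, {
    ctrl_up <- if (length(sig_up)) pick_controls(sig_up) else list()
    ctrl_down <- if (length(sig_down)) pick_controls(sig_down) else list()
  })
  need <- unique(c(sig_up, sig_down, unlist(ctrl_up), unlist(ctrl_down)))
  z <- zscore_cols(as_dense(expr[, need, drop = FALSE]))
  term <- function(sgenes, ctrl) {
    if (!length(sgenes)) return(0)
    ref <- vapply(ctrl, function(cs) rowMeans(z[, cs, drop = FALSE]),
                  numeric(nrow(z)))
    rowMeans(z[, sgenes, drop = FALSE]) - rowMeans(matrix(ref, nrow = nrow(z)))
  }
  score <- term(sig_up, ctrl_up) - term(sig_down, ctrl_down)
  if (final_z) {
    s <- sd(score)
    if (!is.finite(s) || s == 0) {
      warning("degenerate scores (zero variance); returning zeros")
      score <- rep(0, length(score))
    } else {
      score <- (score - mean(score)) / s
    }
  }
  names(score) <- rownames(expr)
  attr(score, "method") <- list(signature = sig$name, n_bins = n_bins,
                                n_ctrl = n_ctrl, seed = seed,
                                final_z = final_z)
  score
}

#' Score several signatures into a matrix
#'
#' @param expr Normalized matrix, cells x genes.
#' @param signatures List of [gene_signature()] objects.
#' @inheritParams score_signature
#' @return Observations x signatures score matrix.
#' @export
score_signatures <- function(expr, signatures, n_bins = 25L, n_ctrl = 50L,
                             seed = 1L, final_z = TRUE) {
  out <- vapply(signatures, function(s)
    score_signature(expr, s, n_bins, n_ctrl, seed, final_z),
    numeric(nrow(expr)))
  colnames(out) <- vapply(signatures, `[[`, "", "name")
  rownames(out) <- rownames(expr)
  out
}

# ridge-penalized logistic IRLS fallback for separated fits
ridge_logistic <- function(X, y, lambda = 1e-2, n_iter = 50L) {
  b <- rep(0, ncol(X))
  for (it in seq_len(n_iter)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% b)
  p <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(coef = b, dev = -2 * sum(y * log(p) + (1 - y) * log(1 - p)))
}

logistic_dev <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  sep <- !fit$converged || any(abs(fit$coefficients) > 15, na.rm = TRUE)
  if (sep) {
    f <- ridge_logistic(X, y)
    list(dev = f$dev, coef = f$coef, flagged = TRUE)
  } else {
    list(dev = fit$deviance, coef = fit$coefficients, flagged = FALSE)
  }
}

#' Hurdle-model single-cell differential expression
#'
#' Two-part model per gene: a logistic regression of detection (x > 0) on
#' condition + cngeneson, and a Gaussian regression of positive
#' log-expression on the same design, where cngeneson is the z-scored
#' number of detected genes per cell (the cellular detection rate). The
#' hurdle p-value combines the two likelihood-ratio components as a
#' chi-square with 2 degrees of freedom (1 when the continuous part is not
#' estimable). Bonferroni correction is applied over tested genes; genes
#' detected in fewer than `min_cells` cells overall are skipped.
#'
#' @param expr Normalized log matrix, cells x genes.
#' @param groups Two-level factor/character/logical per cell.
#' @param min_cells Minimum detected cells for a gene to be tested.
#' @param mask Optional gene ids to exclude (defaults to the standard
#'   mito/ribosomal/MALAT1 mask).
#' @return `data.frame` of class `de_sc_table` with `gene`, `coef_cont`
#'   (condition coefficient, continuous part), `coef_disc` (logit part),
#'   `chisq`, `df`, `p`, `p_bonf`, `flagged`.
#' @export
hurdle_de <- function(expr, groups, min_cells = 5L, mask = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop_validation("groups must have exactly two levels")
  if (any(table(groups) < 20L))
    stop_validation("each group must contain at least 20 cells")
  if (is.null(mask)) mask <- default_gene_mask(colnames(expr))
  x <- as_dense(expr)
  det_all <- x > 0
  cng <- drop(scale(rowSums(det_all)))
  if (all(!is.finite(cng))) cng <- rep(0, nrow(x))
  cond <- as.numeric(groups == levels(groups)[2L])
  X1 <- cbind(intercept = 1, condition = cond, cngeneson = cng)
  X0 <- X1[, c(1L, 3L), drop = FALSE]
  test_genes <- setdiff(colnames(x)[colSums(det_all) >= min_cells], mask)
  res <- lapply(test_genes, function(g) {
    y <- x[, g]
    d <- as.numeric(y > 0)
    f1 <- logistic_dev(X1, d)
    f0 <- logistic_dev(X0, d)
    chi_d <- max(f0$dev - f1$dev, 0)
    # continuous part on detected cells
    di <- d > 0
    chi_c <- 0; df_c <- 0L; coef_c <- NA_real_
    if (sum(di) >= 4L && length(unique(cond[di])) == 2L) {
      yy <- y[di]
      fit1 <- lm.fit(X1[di, , drop = FALSE], yy)
      fit0 <- lm.fit(X0[di, , drop = FALSE], yy)
      rss1 <- sum(fit1$residuals^2); rss0 <- sum(fit0$residuals^2)
      if (rss1 > 0) {
        chi_c <- sum(di) * log(rss0 / rss1)
        df_c <- 1L
        coef_c <- fit1$coefficients[["condition"]]
      }
    }
    df <- 1L + df_c
    chi <- chi_d + chi_c
    data.frame(gene = g, coef_cont = coef_c,
               coef_disc = unname(f1$coef[2L]),
               chisq = chi, df = df,
               p = pchisq(chi, df = df, lower.tail = FALSE),
               flagged = f1$flagged || f0$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(gene = character(), coef_cont = numeric(),
                                      coef_disc = numeric(), chisq = numeric(),
                                      df = integer(), p = numeric(),
                                      flagged = logical())
  out$p_bonf <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  class(out) <- c("de_sc_table", "data.frame")
  out
}

# enrichment score of one gene set from hit positions in a ranked list.
# absr: |rank statistic| sorted in ranking order; hits: sorted positions.
es_from_hits <- function(absr, hits, N) {
  m <- length(hits)
  nr <- sum(absr[hits])
  miss_w <- 1 / (N - m)
  if (nr == 0) return(0)
  cumhit <- cumsum(absr[hits]) / nr
  after <- cumhit - (hits - seq_len(m)) * miss_w     # just after each hit
  before <- c(0, cumhit[-m]) - (hits - 1L - (seq_len(m) - 1L)) * miss_w
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight =
#' |rank statistic|, exponent 1) with a gene-label permutation null:
#' normalized ES divides by the mean |null ES| of matching sign, and the
#' permutation p-value uses the matching-sign tail with +1 smoothing.
#' BH correction is applied across gene sets.
#'
#' When `stats` is a DE table, ranks are `-log(p) * log2fc`.
#'
#' @param stats Named numeric rank statistic, or a `de_table` /
#'   `de_sc_table`.
#' @param gene_sets Named list of character gene-id sets.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Seed for the permutation null.
#' @param min_size Sets with fewer ranked members are skipped with a
#'   warning.
#' @return `data.frame` of class `gsea_result` with `pathway`, `es`, `nes`,
#'   `p`, `p_adj`, `size`.
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 2000L, seed = 1L,
                           min_size = 5L) {
  if (inherits(stats, "data.frame")) {
    lfc <- if ("log2fc" %in% names(stats)) stats$log2fc else stats$coef_cont
    p <- pmax(stats$p, 1e-300)
    stats <- setNames(-log(p) * lfc, stats$gene)
  }
  stats <- stats[is.finite(stats)]
  # stable ordering: decreasing statistic, ties broken by gene id
  ord <- order(-stats, names(stats), method = "radix")
  s <- stats[ord]
  genes <- names(s)
  N <- length(s)
  absr <- abs(s)
  keep <- vapply(gene_sets, function(gs) sum(gs %in% genes) >= min_size, TRUE)
  if (any(!keep))
    warning(sprintf("%d gene set(s) with fewer than %d ranked members skipped",
                    sum(!keep), min_size))
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets))
    return(structure(data.frame(pathway = character(), es = numeric(),
                                nes = numeric(), p = numeric(),
                                p_adj = numeric(), size = integer()),
                     class = c("gsea_result", "data.frame")))
  res <- with_seed(seed, lapply(names(gene_sets), function(nm) {
    hits <- sort(match(intersect(gene_sets[[nm]], genes), genes))
    m <- length(hits)
    es <- es_from_hits(absr, hits, N)
    null_es <- vapply(seq_len(n_perm), function(b)
      es_from_hits(absr, sort(sample.int(N, m)), N), 0)
    same <- null_es[sign(null_es) == sign(es)]
    if (!length(same)) same <- null_es
    nes <- if (mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
    pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(pathway = nm, es = es, nes = nes, p = pval, size = m,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[, c("pathway", "es", "nes", "p", "p_adj", "size")]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Select highly variable genes across batches
#'
#' Per batch, the normalized dispersion of each gene is the z-score (within
#' mean-expression bins) of variance/mean of the log data. A gene "passes"
#' in a batch when it ranks in that batch's top `n_top` by normalized
#' dispersion; genes are ranked by the number of passing batches, ties
#' broken by median normalized dispersion.
#'
#' @param expr Normalized log matrix, cells x genes.
#' @param batches Per-cell batch labels (single batch if `NULL`).
#' @param n_top Number of genes to return.
#' @param n_bins Mean-expression bins for dispersion normalization.
#' @param mask Gene ids to exclude (default standard mask).
#' @return Character vector of gene ids.
#' @export
select_hvgs <- function(expr, batches = NULL, n_top = 500L, n_bins = 20L,
                        mask = NULL) {
  if (nrow(expr) < 2L) stop_validation("at least two observations required")
  if (is.null(batches)) batches <- rep("all", nrow(expr))
  if (is.null(mask)) mask <- default_gene_mask(colnames(expr))
  genes <- setdiff(colnames(expr), mask)
  if (n_top > length(genes)) {
    warning("n_top exceeds number of genes; returning all")
    n_top <- length(genes)
  }
  disp_z <- function(sub) {
    mu <- col_means(sub)
    v <- col_vars(sub)
    d <- ifelse(mu > 0, v / mu, 0)
    bin <- ceiling(rank(mu, ties.method = "first") / (length(mu) / n_bins))
    z <- d
    for (b in unique(bin)) {
      i <- bin == b
      s <- sd(d[i])
      z[i] <- if (is.finite(s) && s > 0) (d[i] - mean(d[i])) / s else 0
    }
    z
  }
  zmat <- vapply(unique(batches), function(b)
    disp_z(expr[batches == b, genes, drop = FALSE]), numeric(length(genes)))
  zmat <- matrix(zmat, nrow = length(genes))
  rownames(zmat) <- genes
  pass <- apply(zmat, 2L, function(z)
    rank(-z, ties.method = "first") <= n_top)
  pass <- matrix(pass, nrow = length(genes))
  n_pass <- rowSums(pass)
  med_z <- apply(zmat, 1L, median)
  ord <- order(-n_pass, -med_z, genes, method = "radix")
  genes[ord][seq_len(n_top)]
}

#' Merge clusters into states by mean-expression correlation
#'
#' Computes the Pearson correlation matrix of per-cluster mean expression
#' over highly variable genes and groups clusters by average-linkage
#' hierarchical clustering cut at correlation `linkage_threshold`.
#'
#' @param expr Normalized log matrix, cells x genes.
#' @param clusters Per-cell cluster labels.
#' @param hvgs Gene ids used for the correlation.
#' @param linkage_threshold Correlation at which the dendrogram is cut
#'   (default 0.7).
#' @return List with `map` (cluster -> state label), `cor` (cluster
#'   correlation matrix), `n_states`.
#' @export
cluster_state_merge <- function(expr, clusters, hvgs,
                                linkage_threshold = 0.7) {
  clusters <- as.character(clusters)
  cl <- unique(clusters)
  if (length(cl) < 2L) stop_validation("at least two clusters required")
  small <- names(which(table(clusters) < 3L))
  if (length(small))
    warning(sprintf("cluster(s) with fewer than 3 cells kept: %s",
                    paste(small, collapse = ", ")))
  hvgs <- intersect(hvgs, colnames(expr))
  means <- t(vapply(cl, function(k)
    col_means(expr[clusters == k, hvgs, drop = FALSE]),
    numeric(length(hvgs))))
  cm <- stats::cor(t(means))
  dimnames(cm) <- list(cl, cl)
  hc <- hclust(stats::as.dist(1 - cm), method = "average")
  grp <- cutree(hc, h = 1 - linkage_threshold)
  map <- setNames(sprintf("state_%d", grp), cl)
  list(map = map, cor = cm, n_states = length(unique(grp)))
}
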