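# Bulk stimulation differential expression and signature derivation.
#
# The DE core is a negative-binomial Wald test: median-of-ratios size
# factors, gene-wise dispersion MLE shrunk toward a parametric a/mu + b
# trend (log-normal prior, MAP estimate), then a Wald test on the condition
# coefficient of a two-group NB GLM with log link and log-size-factor
# offsets. Genes below a mean-normalized-count floor are excluded from the
# BH family (independent filtering).

#' Construct a bulk count container
#'
#' @param counts Genes x samples nonnegative integer matrix.
#' @param condition Per-sample condition label; a `"control"` level (or the
#'   `control` argument of downstream calls) must exist.
#' @param replicate Per-sample replicate index.
#' @return An object of class `bulk_counts`.
#' @export
bulk_counts <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  assert_count_matrix(counts, "bulk counts")
  if (length(condition) != ncol(counts))
    stop_validation("one condition label per sample required")
  tab <- table(condition)
  if (any(tab < 2L))
    stop_validation(sprintf("condition '%s' has fewer than 2 replicates",
                            names(tab)[which(tab < 2L)[1L]]))
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  structure(list(counts = counts, condition = as.character(condition),
                 replicate = as.integer(replicate)),
            class = "bulk_counts")
}

#' @export
print.bulk_counts <- function(x, ...) {
  cat(sprintf("bulk_counts: %d genes x %d samples; conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes
#' (those with a positive geometric mean across samples) of the ratio
#' count / geometric mean.
#'
#' @param counts Genes x samples matrix.
#' @return Named positive numeric vector, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop_validation(sprintf("sample '%s' has all-zero counts",
                            colnames(counts)[which(tot == 0)[1L]] %||%
                              as.character(which(tot == 0)[1L])))
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use))
    stop_validation("no gene has positive counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(cnt) exp(median(log(cnt) - lg[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stop_validation("degenerate size factor; check for samples sharing no expressed genes")
  sf
}

# vectorized Newton solve of per-group NB means on the log scale.
# y: genes x samples, sf: sample size factors, alpha: per-gene dispersion.
# returns list(eta = log fitted group mean on the normalized scale, info =
# Fisher information of eta).
nb_group_fit <- function(y, sf, alpha, n_iter = 25L) {
  G <- nrow(y)
  q0 <- rowSums(y) / sum(sf)
  eta <- log(pmax(q0, 1e-8))
  sfm <- matrix(sf, G, length(sf), byrow = TRUE)
  for (it in seq_len(n_iter)) {
    mu <- exp(eta) * sfm
    w <- 1 + alpha * mu
    f <- rowSums((y - mu) / w)
    fp <- -rowSums(mu * (1 + alpha * y) / w^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 2), -2)
    eta <- eta - step
    eta <- pmax(eta, -25)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(eta) * sfm
  info <- rowSums(mu / (1 + alpha * mu))
  conv <- abs(rowSums((y - mu) / (1 + alpha * mu))) <
    1e-4 * (1 + rowSums(y))
  list(eta = eta, info = info, converged = conv)
}

nb_loglik <- function(y, mu, alpha) {
  size <- 1 / pmax(alpha, 1e-12)
  rowSums(dnbinom(y, size = matrix(size, nrow(y), ncol(y)), mu = mu, log = TRUE))
}

# profile log-likelihood of dispersion alpha (per-gene), maximizing group
# means at each alpha on a log-alpha grid; optional log-normal prior.
nb_dispersion_grid <- function(yc, yt, sfc, sft, grid_log_alpha,
                               prior_mean = NULL, prior_var = NULL) {
  G <- nrow(yc)
  best_ll <- rep(-Inf, G)
  if (!is.matrix(grid_log_alpha))
    grid_log_alpha <- matrix(grid_log_alpha, G, length(grid_log_alpha),
                             byrow = TRUE)
  npts <- ncol(grid_log_alpha)
  best <- grid_log_alpha[, 1L]
  for (j in seq_len(npts)) {
    la <- grid_log_alpha[, j]
    a <- exp(la)
    fc <- nb_group_fit(yc, sfc, a)
    ft <- nb_group_fit(yt, sft, a)
    muc <- exp(fc$eta) * matrix(sfc, G, length(sfc), byrow = TRUE)
    mut <- exp(ft$eta) * matrix(sft, G, length(sft), byrow = TRUE)
    # Cox-Reid adjusted profile likelihood: penalize by half the log
    # determinant of the per-group Fisher information, which removes most
    # of the downward ML bias of the dispersion at small sample sizes
    ll <- rowSums(dnbinom(yc, size = 1 / a, mu = muc, log = TRUE)) +
          rowSums(dnbinom(yt, size = 1 / a, mu = mut, log = TRUE)) -
          0.5 * (log(pmax(fc$info, 1e-12)) + log(pmax(ft$info, 1e-12)))
    if (!is.null(prior_mean)) ll <- ll - (la - prior_mean)^2 / (2 * prior_var)
    gain <- ll > best_ll
    gain[!is.finite(ll)] <- FALSE
    best[gain] <- la[gain]
    best_ll[gain] <- ll[gain]
  }
  best
}

#' Negative-binomial Wald differential expression
#'
#' Tests one condition against the control using a per-gene NB GLM (log
#' link, design intercept + condition indicator, log size-factor offsets).
#' Gene-wise dispersions are profiled by maximum likelihood, a parametric
#' trend `a / mu + b` is fitted across genes, and gene-wise estimates are
#' shrunk toward the trend via a log-normal prior (MAP). Genes whose mean
#' normalized count falls below `min_mean` are reported with `p_adj = NA`
#' and excluded from the BH family.
#'
#' @param bulk A [bulk_counts()] object.
#' @param condition Condition label to test.
#' @param control Control condition label.
#' @param min_mean Independent-filtering floor on mean normalized counts.
#' @param lfc_shrink If `TRUE`, add a `log2fc_shrunk` column: the posterior
#'   mean under a zero-centered normal prior on the condition coefficient
#'   (ridge-style shrinkage; the Wald test itself always uses the MLE).
#' @return A `data.frame` of class `de_table` with columns `gene`,
#'   `base_mean`, `log2fc`, `se`, `wald_stat`, `p`, `p_adj`, `dispersion`,
#'   `converged` (and `log2fc_shrunk` if requested).
#' @export
nb_wald_de <- function(bulk, condition, control = "control", min_mean = 1,
                       lfc_shrink = FALSE) {
  if (!inherits(bulk, "bulk_counts")) stop_validation("bulk must be a bulk_counts object")
  if (!condition %in% bulk$condition)
    stop_validation(sprintf("condition '%s' not present", condition))
  if (!control %in% bulk$condition)
    stop_validation(sprintf("control condition '%s' not present", control))
  sel <- bulk$condition %in% c(condition, control)
  y <- bulk$counts[, sel, drop = FALSE]
  grp <- bulk$condition[sel] == condition
  sf <- estimate_size_factors(y)
  yc <- y[, !grp, drop = FALSE]; yt <- y[, grp, drop = FALSE]
  sfc <- sf[!grp]; sft <- sf[grp]
  G <- nrow(y)
  m <- ncol(y)
  base_mean <- rowMeans(sweep(y, 2L, sf, "/"))
  nonzero <- base_mean > 0

  # stage 1: coarse gene-wise dispersion MLE
  coarse <- seq(log(1e-6), log(4), length.out = 30L)
  la_mle <- rep(NA_real_, G)
  la_mle[nonzero] <- nb_dispersion_grid(yc[nonzero, , drop = FALSE],
                                        yt[nonzero, , drop = FALSE],
                                        sfc, sft, coarse)
  disp_mle <- exp(la_mle)

  # stage 2: parametric trend a/mu + b on well-expressed genes
  fit_ok <- nonzero & base_mean >= min_mean & is.finite(disp_mle) &
    disp_mle > 1e-6 & disp_mle < 4
  trend <- tryCatch({
    d <- disp_mle[fit_ok]; bm <- base_mean[fit_ok]
    for (it in 1:3) {
      X <- cbind(1, 1 / bm)
      cf <- lm.fit(X, d)$coefficients
      pred <- pmax(cf[1L] + cf[2L] / bm, 1e-8)
      r <- d / pred
      keep <- r > 1e-3 & r < 15      # trim dispersion outliers, refit
      d <- d[keep]; bm <- bm[keep]
    }
    cf <- pmax(cf, 0)
    if (cf[1L] <= 0 && cf[2L] <= 0) stop("flat")
    cf
  }, error = function(e) c(median(disp_mle[fit_ok], na.rm = TRUE) %||% 0.1, 0))
  disp_trend <- pmax(trend[1L] + trend[2L] / pmax(base_mean, 1e-8), 1e-8)

  # stage 3: prior width = spread of log residuals minus expected sampling
  # variance of the log dispersion MLE (trigamma((m - 2) / 2))
  lr <- log(disp_mle[fit_ok]) - log(disp_trend[fit_ok])
  samp_var <- trigamma(max((m - 2) / 2, 0.5))
  prior_var <- max(mad(lr, na.rm = TRUE)^2 - samp_var, 0.0625)

  # stage 4: MAP dispersion on a fine grid around the trend
  offsets <- seq(-6, 6, length.out = 40L)
  la_map <- rep(NA_real_, G)
  idx <- which(nonzero)
  grid <- outer(log(disp_trend[idx]), offsets, `+`)
  la_map[idx] <- nb_dispersion_grid(yc[idx, , drop = FALSE],
                                    yt[idx, , drop = FALSE], sfc, sft, grid,
                                    prior_mean = log(disp_trend[idx]),
                                    prior_var = prior_var)
  disp <- exp(la_map)
  disp[!nonzero] <- NA_real_

  # stage 5: Wald test at the MAP dispersion
  log2fc <- se <- wald <- p <- rep(NA_real_, G)
  conv <- rep(FALSE, G)
  a <- disp[idx]
  fc <- nb_group_fit(yc[idx, , drop = FALSE], sfc, a)
  ft <- nb_group_fit(yt[idx, , drop = FALSE], sft, a)
  log2fc[idx] <- (ft$eta - fc$eta) / log(2)
  se[idx] <- sqrt(1 / fc$info + 1 / ft$info) / log(2)
  wald[idx] <- log2fc[idx] / se[idx]
  p[idx] <- 2 * pnorm(-abs(wald[idx]))
  conv[idx] <- fc$converged & ft$converged

  tested <- nonzero & base_mean >= min_mean & conv & is.finite(p)
  p_adj <- rep(NA_real_, G)
  p_adj[tested] <- p.adjust(p[tested], method = "BH")

  out <- data.frame(gene = rownames(y), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald_stat = wald,
                    p = p, p_adj = p_adj, dispersion = disp,
                    converged = conv, stringsAsFactors = FALSE)
  if (lfc_shrink) {
    # normal-normal posterior mean: ridge shrinkage of the MLE toward zero
    ok <- is.finite(log2fc) & is.finite(se)
    b <- log2fc[ok]
    prior_sd <- max(quantile(abs(b), 0.95, na.rm = TRUE) / qnorm(0.975), 0.25)
    out$log2fc_shrunk <- NA_real_
    out$log2fc_shrunk[ok] <- b * prior_sd^2 / (prior_sd^2 + se[ok]^2)
  }
  attr(out, "condition") <- condition
  attr(out, "control") <- control
  class(out) <- c("de_table", "data.frame")
  out
}

#' Construct a directed gene signature
#'
#' @param name Signature label.
#' @param up,down Disjoint character gene-id sets.
#' @param provenance Free-text provenance (condition, thresholds).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           provenance = "") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop_validation("up and down gene sets must be disjoint")
  if (!length(up) && !length(down))
    warning(sprintf("signature '%s' is empty", name))
  structure(list(name = name, up = up, down = down, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down\n  provenance: %s\n",
              x$name, length(x$up), length(x$down), x$provenance))
  invisible(x)
}

#' Derive a cytokine-response signature from a DE table
#'
#' Genes up- or down-regulated at adjusted p below `alpha` define the
#' directed signature.
#'
#' @param de A `de_table`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param name Optional signature name; defaults to the tested condition.
#' @return A [gene_signature()].
#' @export
derive_signature <- function(de, alpha = 0.05, name = NULL) {
  if (!nrow(de)) stop_validation("empty DE table")
  name <- name %||% attr(de, "condition") %||% "signature"
  sig_rows <- !is.na(de$p_adj) & de$p_adj < alpha
  up <- de$gene[sig_rows & de$log2fc > 0]
  down <- de$gene[sig_rows & de$log2fc < 0]
  prov <- sprintf("condition=%s vs %s; p_adj<%g", name,
                  attr(de, "control") %||% "control", alpha)
  suppressWarnings(sig <- gene_signature(name, up, down, prov))
  if (!length(up) && !length(down))
    warning(sprintf("no genes pass p_adj < %g; empty signature", alpha))
  sig
}

#' Restrict a signature to genes exclusively expressed by a cell type
#'
#' Keeps a gene if its mean expression in the target cell type is at least
#' `exclusivity_ratio` times the maximum mean expression among all other
#' cell types.
#'
#' @param sig A [gene_signature()].
#' @param expr_by_celltype Genes x cell-types mean-expression matrix.
#' @param target Target cell-type column.
#' @param exclusivity_ratio Positive real (e.g. 2 demands 2x exclusivity).
#' @return Restricted [gene_signature()].
#' @export
restrict_signature <- function(sig, expr_by_celltype, target,
                               exclusivity_ratio = 2) {
  if (!target %in% colnames(expr_by_celltype))
    stop_validation(sprintf("target cell type '%s' not in table", target))
  keep_gene <- function(genes) {
    present <- genes %in% rownames(expr_by_celltype)
    if (any(!present))
      warning(sprintf("%d signature gene(s) absent from expression table dropped",
                      sum(!present)))
    g <- genes[present]
    if (!length(g)) return(character())
    tgt <- expr_by_celltype[g, target]
    oth <- expr_by_celltype[g, setdiff(colnames(expr_by_celltype), target),
                            drop = FALSE]
    g[tgt >= exclusivity_ratio * apply(oth, 1L, max)]
  }
  up <- keep_gene(sig$up)
  down <- keep_gene(sig$down)
  suppressWarnings(gene_signature(
    paste0(sig$name, "_", target, "_restricted"), up, down,
    sprintf("%s; restricted to %s at ratio %g", sig$provenance, target,
            exclusivity_ratio)))
}

#' Paired fold-change shift under co-stimulation (DLL4 dampening)
#'
#' Pairs each signature gene's log2 fold change under cytokine-alone and
#' cytokine-plus-DLL4 stimulation and summarizes the shift toward zero
#' ("dampening"): for up genes shrinkage = lfc_alone - lfc_with, for down
#' genes shrinkage = lfc_with - lfc_alone, so shrinkage is positive when the
#' response magnitude is attenuated in either direction.
#'
#' @param de_alone,de_with_dll4 `de_table`s sharing the signature genes.
#' @param sig A [gene_signature()].
#' @param use_shrunk Use `log2fc_shrunk` columns when present.
#' @return List of class `dll4_shift` with per-gene pairs, per-direction
#'   median shrinkage and Wilcoxon signed-rank p, the median |lfc| ratio,
#'   and a `dampening` flag (both directions shrink).
#' @export
dll4_shift <- function(de_alone, de_with_dll4, sig, use_shrunk = FALSE) {
  col <- if (use_shrunk && "log2fc_shrunk" %in% names(de_alone)) "log2fc_shrunk"
         else "log2fc"
  genes <- c(sig$up, sig$down)
  a <- setNames(de_alone[[col]], de_alone$gene)[genes]
  b <- setNames(de_with_dll4[[col]], de_with_dll4$gene)[genes]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 5L)
    stop_validation("fewer than 5 signature genes shared between the two DE tables")
  genes <- genes[ok]; a <- a[ok]; b <- b[ok]
  dir_up <- genes %in% sig$up
  shrink <- ifelse(dir_up, a - b, b - a)
  wtest <- function(x) {
    if (length(x) < 5L || all(x == 0)) return(NA_real_)
    suppressWarnings(wilcox.test(x, mu = 0)$p.value)
  }
  ratio <- median(abs(b) / pmax(abs(a), 1e-8))
  med_up <- if (any(dir_up)) median(shrink[dir_up]) else NA_real_
  med_down <- if (any(!dir_up)) median(shrink[!dir_up]) else NA_real_
  structure(list(
    pairs = data.frame(gene = genes, log2fc_alone = a, log2fc_with_dll4 = b,
                       direction = ifelse(dir_up, "up", "down"),
                       shrinkage = shrink, stringsAsFactors = FALSE,
                       row.names = NULL),
    median_paired_diff = median(b - a),
    median_shrink_up = med_up, median_shrink_down = med_down,
    p_up = wtest(shrink[dir_up]), p_down = wtest(shrink[!dir_up]),
    median_abs_ratio = ratio,
    dampening = isTRUE(med_up > 0) && (is.na(med_down) || med_down > 0)),
    class = "dll4_shift")
}

#' @export
print.dll4_shift <- function(x, ...) {
  cat(sprintf(paste0("dll4_shift: %d paired genes; median |lfc| ratio %.3f\n",
                     "  shrinkage up %.3f (p=%.3g), down %.3f (p=%.3g); dampening: %s\n"),
              nrow(x$pairs), x$median_abs_ratio, x$median_shrink_up, x$p_up,
              x$median_shrink_down, x$p_down, x$dampening))
  invisible(x)
}
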