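# chromVAR-style motif accessibility deviations with matched background
# peaks, expression gating and per-state Wilcoxon ranking.
#
# Definition used throughout: the expected accessibility of motif m in cell
# i is E_mi = T_m * d_i / D (motif total x cell depth fraction); the raw
# deviation is the fractional excess (obs - E) / E, mean-centered across
# cells per motif so that deviations sum to zero by construction. The same
# statistic computed on matched background peak sets yields the z-score
# z = (raw - mean_bg) / sd_bg.

#' Construct a peak accessibility container
#'
#' @param binary Peaks x cells matrix in \{0, 1\}.
#' @param peak_coords BED-style data frame (`chrom`, `start`, `end`,
#'   optional `name`), 0-based half-open.
#' @param gc Per-peak GC fraction in `[0, 1]`.
#' @return Object of class `peak_matrix`.
#' @export
peak_matrix <- function(binary, peak_coords = NULL, gc = NULL) {
  v <- if (inherits(binary, "sparseMatrix")) binary@x else as.numeric(binary)
  if (length(v) && !all(v %in% c(0, 1)))
    stop_validation("accessibility matrix must be binary")
  if (any(col_sums(binary) == 0))
    stop_validation("all-zero cell present; filter cells upstream")
  if (!is.null(gc)) {
    if (length(gc) != nrow(binary)) stop_validation("one gc value per peak required")
    if (any(!is.finite(gc)) || any(gc < 0 | gc > 1))
      stop_validation("gc must be finite and in [0, 1]")
  }
  structure(list(binary = binary, peak_coords = peak_coords, gc = gc),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d peaks x %d cells (density %.3f)\n",
              nrow(x$binary), ncol(x$binary),
              sum(x$binary) / length(x$binary)))
  invisible(x)
}

#' Construct a motif-to-peak match container
#'
#' @param match Motifs x peaks binary matrix.
#' @param motif_to_tf Named list mapping each motif to >= 1 TF gene id.
#' @return Object of class `motif_match`.
#' @export
motif_match <- function(match, motif_to_tf) {
  if (is.null(rownames(match))) rownames(match) <- names(motif_to_tf)
  missing <- setdiff(rownames(match), names(motif_to_tf))
  if (length(missing))
    stop_validation(sprintf("motif(s) without TF mapping: %s",
                            paste(head(missing, 3L), collapse = ", ")))
  if (any(lengths(motif_to_tf[rownames(match)]) == 0))
    stop_validation("every motif must map to at least one TF gene id")
  structure(list(match = match, motif_to_tf = motif_to_tf),
            class = "motif_match")
}

#' Depth-proportional expected motif accessibility
#'
#' `E[m, i] = T_m * d_i / D` where `T_m` is the total accessible count in
#' motif-m peaks over all cells, `d_i` the cell total and `D` the grand
#' total. Columns of the result sum to `T_m` exactly.
#'
#' @param pm A [peak_matrix()].
#' @param mm A [motif_match()].
#' @return Motifs x cells matrix of expectations.
#' @export
expected_counts <- function(pm, mm) {
  X <- pm$binary
  M <- mm$match
  if (ncol(M) != nrow(X)) stop_validation("motif and peak dimensions disagree")
  d <- col_sums(X)
  D <- sum(d)
  if (D == 0) stop_validation("empty accessibility matrix")
  Tm <- as.numeric(M %*% row_sums(X))
  E <- outer(Tm, d / D)
  dimnames(E) <- list(rownames(M), colnames(X))
  E
}

centered_fractional_deviation <- function(obs, E) {
  dev <- (obs - E) / E
  dev[!is.finite(dev)] <- NA_real_
  sweep(dev, 1L, rowMeans(dev), "-")
}

#' Sample GC/accessibility-matched background peaks
#'
#' Peaks are placed in the 2-D space of z-scored GC and z-scored log mean
#' accessibility; for each peak, `n_background` backgrounds are sampled
#' with replacement from its Mahalanobis-nearest neighborhood (the nearest
#' `window` quantile of peaks, floored at 25 to keep small panels stable).
#' A degenerate covariate covariance triggers a rank-based fallback with a
#' warning.
#'
#' @param pm A [peak_matrix()] with `gc`.
#' @param n_background Background draws per peak (default 50).
#' @param seed Seed.
#' @param window Neighborhood quantile (default 0.02).
#' @return Peaks x n_background integer index matrix with attribute `seed`.
#' @export
sample_backgrounds <- function(pm, n_background = 50L, seed = 1L,
                               window = 0.02) {
  if (is.null(pm$gc)) stop_validation("peak_matrix lacks gc covariate")
  X <- pm$binary
  P <- nrow(X)
  if (P < n_background) stop_validation("need at least n_background peaks")
  acc <- log(row_sums(X) / ncol(X) + 1 / (2 * ncol(X)))
  zs <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  Z <- cbind(zs(pm$gc), zs(acc))
  S <- stats::cov(Z)
  degenerate <- !is.finite(det(S)) || det(S) < 1e-12
  if (degenerate) {
    warning("degenerate covariate covariance; falling back to rank-based matching")
    Z <- cbind(rank(pm$gc), rank(acc)) / P
    W <- Z
  } else {
    # whitening turns Mahalanobis distance into Euclidean distance
    W <- Z %*% solve(chol(S))
  }
  k <- max(ceiling(window * P), min(P, 25L))
  out <- matrix(0L, P, n_background)
  with_seed(seed, {
    chunk <- 512L
    for (start in seq(1L, P, by = chunk)) {
      idx <- start:min(start + chunk - 1L, P)
      d2 <- outer(rowSums(W[idx, , drop = FALSE]^2), rowSums(W^2), `+`) -
        2 * W[idx, , drop = FALSE] %*% t(W)
      for (r in seq_along(idx)) {
        nb <- order(d2[r, ])[seq_len(k)]
        out[idx[r], ] <- nb[sample.int(k, n_background, replace = TRUE)]
      }
    }
  })
  attr(out, "seed") <- seed
  attr(out, "k") <- k
  out
}

#' Compute motif deviations and background z-scores
#'
#' Raw deviation = mean-centered fractional excess over the
#' depth-proportional expectation; for each background replicate the same
#' statistic is computed with every motif peak replaced by its matched
#' background peak, and `z = (raw - mean_bg) / sd_bg`.
#'
#' @param pm A [peak_matrix()].
#' @param mm A [motif_match()].
#' @param backgrounds Index matrix from [sample_backgrounds()] on the same
#'   peaks.
#' @return Object of class `deviation_result` with `raw` and `z`
#'   (motifs x cells), `n_background`, `background_seed`, `flagged` motifs
#'   (zero background sd or empty motif).
#' @export
compute_deviations <- function(pm, mm, backgrounds) {
  X <- pm$binary
  M <- mm$match
  if (nrow(backgrounds) != nrow(X))
    stop_validation("backgrounds were not computed on this peak matrix")
  E <- expected_counts(pm, mm)
  obs <- as.matrix(M %*% X)
  raw <- centered_fractional_deviation(obs, E)
  B <- ncol(backgrounds)
  d <- col_sums(X); D <- sum(d); rs <- row_sums(X)
  sum_bg <- matrix(0, nrow(M), ncol(X))
  sumsq_bg <- matrix(0, nrow(M), ncol(X))
  Msp <- as(M, "CsparseMatrix")
  for (b in seq_len(B)) {
    # selection matrix: peak p -> its b-th background peak (multiset-aware)
    Pb <- Matrix::sparseMatrix(i = seq_len(nrow(X)), j = backgrounds[, b],
                               x = 1, dims = c(nrow(X), nrow(X)))
    Mb <- Msp %*% Pb
    obs_b <- as.matrix(Mb %*% X)
    T_b <- as.numeric(Mb %*% rs)
    E_b <- outer(T_b, d / D)
    dev_b <- centered_fractional_deviation(obs_b, E_b)
    sum_bg <- sum_bg + dev_b
    sumsq_bg <- sumsq_bg + dev_b^2
  }
  mean_bg <- sum_bg / B
  sd_bg <- sqrt(pmax(sumsq_bg / B - mean_bg^2, 0) * B / (B - 1))
  z <- (raw - mean_bg) / sd_bg
  zero_sd <- rowSums(sd_bg == 0, na.rm = TRUE) > 0
  empty <- as.numeric(M %*% rs) == 0
  z[which(sd_bg == 0)] <- NA_real_
  flagged <- rownames(M)[zero_sd | empty]
  dimnames(z) <- dimnames(raw) <- list(rownames(M), colnames(X))
  structure(list(raw = raw, z = z, n_background = B,
                 background_seed = attr(backgrounds, "seed"),
                 flagged = flagged),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("deviation_result: %d motifs x %d cells; %d backgrounds; %d flagged\n",
              nrow(x$z), ncol(x$z), x$n_background, length(x$flagged)))
  invisible(x)
}

#' Gate motifs by TF expression per state
#'
#' A motif is admitted for a state iff any of its mapped TF genes is
#' detected (raw count > 0) in strictly more than `min_frac` of that
#' state's cells. Motifs whose TFs are absent from the expression matrix
#' are dropped everywhere with a warning.
#'
#' @param dev A `deviation_result`.
#' @param mm A [motif_match()].
#' @param expr Raw counts, cells x genes (cells aligned with `dev`
#'   columns).
#' @param states Per-cell state labels.
#' @param min_frac Detection-fraction gate (default 0.2, strict `>`).
#' @return Named list: state -> admitted motif ids.
#' @export
expression_gate <- function(dev, mm, expr, states, min_frac = 0.2) {
  if (length(states) != ncol(dev$z))
    stop_validation("one state label per cell required")
  lv <- unique(as.character(states))
  for (s in lv) if (!sum(states == s)) stop_validation("state with zero cells")
  motifs <- rownames(dev$z)
  tf <- mm$motif_to_tf[motifs]
  present <- vapply(tf, function(g) any(g %in% colnames(expr)), TRUE)
  if (any(!present))
    warning(sprintf("%d motif(s) with no TF present in expression matrix excluded",
                    sum(!present)))
  out <- lapply(lv, function(s) {
    cells <- which(states == s)
    admitted <- vapply(motifs, function(m) {
      if (!present[[m]]) return(FALSE)
      g <- intersect(tf[[m]], colnames(expr))
      frac <- col_means(expr[cells, g, drop = FALSE] > 0)
      any(frac > min_frac)
    }, TRUE)
    motifs[admitted]
  })
  names(out) <- lv
  out
}

# tie-corrected normal-approximation Wilcoxon rank-sum score
wilcoxon_score <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sig2 <= 0) return(list(score = 0, p = 1, U = U))
  z <- (U - n1 * n2 / 2) / sqrt(sig2)
  list(score = z, p = 2 * pnorm(-abs(z)), U = U)
}

#' Rank motifs per state by one-vs-rest Wilcoxon on deviation z-scores
#'
#' For each state, every gated motif's z-scores in the state's cells are
#' compared with all other cells by a tie-corrected
#' normal-approximation Wilcoxon rank-sum test; BH correction is applied
#' across motifs within the state and the top `n_top` motifs by score are
#' returned.
#'
#' @param dev A `deviation_result`.
#' @param states Per-cell state labels (>= 2 states).
#' @param gate Optional named list from [expression_gate()]; default all
#'   unflagged motifs for every state.
#' @param n_top Motifs reported per state (default 6).
#' @return `data.frame` with `state`, `motif`, `score`, `p`, `p_adj`,
#'   `rank`.
#' @export
rank_motifs <- function(dev, states, gate = NULL, n_top = 6L) {
  states <- as.character(states)
  lv <- unique(states)
  if (length(lv) < 2L) stop_validation("at least two states required")
  usable <- setdiff(rownames(dev$z), dev$flagged)
  res <- lapply(lv, function(s) {
    motifs <- if (is.null(gate)) usable else intersect(gate[[s]], usable)
    motifs <- motifs[vapply(motifs, function(m) !anyNA(dev$z[m, ]), TRUE)]
    if (!length(motifs)) return(NULL)
    inb <- states == s
    stats <- lapply(motifs, function(m)
      wilcoxon_score(dev$z[m, inb], dev$z[m, !inb]))
    df <- data.frame(state = s, motif = motifs,
                     score = vapply(stats, `[[`, 0, "score"),
                     p = vapply(stats, `[[`, 0, "p"),
                     stringsAsFactors = FALSE)
    df$p_adj <- p.adjust(df$p, method = "BH")
    df <- df[order(-df$score, df$motif), , drop = FALSE]
    df <- head(df, n_top)
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
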