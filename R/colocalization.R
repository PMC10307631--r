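# Spot-level colocalization of signature scores and topic proportions, and
# hex-neighborhood dampening contrasts.

#' Construct aligned per-spot scores
#'
#' @param scores Spots x columns numeric matrix (signature scores and/or
#'   topic proportions), rownames = barcodes.
#' @param coords Data frame with `barcode`, `array_row`, `array_col` (axial
#'   hex coordinates).
#' @param sample Per-spot sample label (single sample if `NULL`).
#' @return Object of class `spot_scores`.
#' @export
spot_scores <- function(scores, coords, sample = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stop_validation("scores must carry barcodes as rownames")
  if (!all(rownames(scores) %in% coords$barcode))
    stop_validation("every score barcode must appear in coords")
  coords <- coords[match(rownames(scores), coords$barcode), , drop = FALSE]
  if (is.null(sample)) sample <- rep("sample1", nrow(scores))
  key <- paste(sample, coords$array_row, coords$array_col)
  if (anyDuplicated(key))
    stop_validation("spot coordinates must be unique within a sample")
  structure(list(scores = scores, coords = coords,
                 sample = as.character(sample)),
            class = "spot_scores")
}

#' @export
print.spot_scores <- function(x, ...) {
  cat(sprintf("spot_scores: %d spots x %d columns (%d sample(s))\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$sample))))
  invisible(x)
}

#' Pearson correlation of scores across spots
#'
#' @param ss A [spot_scores()].
#' @param combine_samples Correlate across all spots combined (`TRUE`) or
#'   return one matrix per sample.
#' @return Symmetric correlation matrix with unit diagonal (or a named list
#'   of them). Zero-variance columns yield `NA` rows/columns with a
#'   warning.
#' @export
correlate_spotwise <- function(ss, combine_samples = TRUE) {
  one <- function(m) {
    if (nrow(m) < 10L) stop_validation("at least 10 spots required")
    v <- apply(m, 2L, var)
    if (any(v == 0))
      warning(sprintf("zero-variance column(s): %s",
                      paste(colnames(m)[v == 0], collapse = ", ")))
    cm <- suppressWarnings(cor(m))
    diag(cm) <- 1
    cm
  }
  if (combine_samples) return(one(ss$scores))
  lapply(split.data.frame(ss$scores, ss$sample), one)
}

# axial hex neighbors: the six adjacent axial cells
hex_neighbor_offsets <- cbind(dr = c(0, 0, 1, -1, 1, -1),
                              dc = c(1, -1, 0, 0, -1, 1))

#' Indices of hex-adjacent spots
#'
#' @param coords Data frame with `array_row`, `array_col` in axial hex
#'   convention.
#' @param of Integer indices whose neighbors are wanted.
#' @param sample Optional per-spot sample labels; adjacency never crosses
#'   samples.
#' @return Integer indices of spots adjacent to (and not in) `of`.
#' @export
hex_neighbors <- function(coords, of, sample = NULL) {
  if (is.null(sample)) sample <- rep("s", nrow(coords))
  key <- paste(sample, coords$array_row, coords$array_col)
  nb_keys <- unlist(lapply(of, function(i)
    paste(sample[i],
          coords$array_row[i] + hex_neighbor_offsets[, "dr"],
          coords$array_col[i] + hex_neighbor_offsets[, "dc"])))
  setdiff(which(key %in% nb_keys), of)
}

# Jonckheere-Terpstra statistic for ordered groups (ties count 1/2)
jt_statistic <- function(values, group_idx) {
  J <- 0
  ng <- length(group_idx)
  for (i in seq_len(ng - 1L)) for (j in seq.int(i + 1L, ng)) {
    xi <- values[group_idx[[i]]]; xj <- values[group_idx[[j]]]
    r <- rank(c(xi, xj))
    U <- sum(r[seq_along(xi)]) - length(xi) * (length(xi) + 1) / 2
    J <- J + (length(xi) * length(xj) - U)   # count pairs xi < xj
  }
  J
}

#' Neighborhood contrast around high-scoring anchor spots
#'
#' Partitions spots into anchor-high (anchor score at or above the
#' `quantile` threshold), adjacent (hex neighbors of anchor-high spots that
#' are not themselves anchor-high) and distal (all others), and tests the
#' ordered contrast of the response score across the three groups with a
#' Monte-Carlo Jonckheere-Terpstra permutation test (two-sided).
#'
#' @param ss A [spot_scores()].
#' @param anchor_signature,response_signature Column names in `ss$scores`.
#' @param quantile Anchor threshold quantile, strictly in (0, 1)
#'   (default 0.9).
#' @param n_perm Monte-Carlo permutations (default 999).
#' @param seed Seed for the permutation test.
#' @return List of class `neighborhood_contrast` with per-group means and
#'   sizes, the JT statistic, and the permutation p-value.
#' @export
neighborhood_contrast <- function(ss, anchor_signature, response_signature,
                                  quantile = 0.9, n_perm = 999L, seed = 1L) {
  if (quantile <= 0 || quantile >= 1)
    stop_validation("quantile must lie strictly in (0, 1); the partition is degenerate otherwise")
  a <- ss$scores[, anchor_signature]
  y <- ss$scores[, response_signature]
  thr <- stats::quantile(a, quantile)
  high <- which(a >= thr)
  adj <- hex_neighbors(ss$coords, high, ss$sample)
  distal <- setdiff(seq_along(a), c(high, adj))
  groups <- list(high = high, adjacent = adj, distal = distal)
  sizes <- lengths(groups)
  if (any(sizes < 5L))
    stop_validation(sprintf("group(s) with fewer than 5 spots: %s",
                            paste(names(sizes)[sizes < 5L], collapse = ", ")))
  obs <- jt_statistic(y, groups)
  lab <- rep.int(seq_along(groups), sizes)
  pooled <- y[unlist(groups)]
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    pl <- sample(lab)
    jt_statistic(pooled, split(seq_along(pl), pl))
  }, 0))
  p <- min(1, 2 * min((1 + sum(null >= obs)) / (1 + n_perm),
                      (1 + sum(null <= obs)) / (1 + n_perm)))
  means <- vapply(groups, function(i) mean(y[i]), 0)
  structure(list(group_means = means, group_sizes = sizes,
                 jt_statistic = obs, p = p,
                 quantile = quantile,
                 monotone_increasing = all(diff(means) > 0),
                 monotone_decreasing = all(diff(means) < 0)),
            class = "neighborhood_contrast")
}

#' @export
print.neighborhood_contrast <- function(x, ...) {
  cat(sprintf(paste0("neighborhood_contrast: means high %.3f / adjacent %.3f",
                     " / distal %.3f (n = %d/%d/%d); JT p = %.4g\n"),
              x$group_means[1L], x$group_means[2L], x$group_means[3L],
              x$group_sizes[1L], x$group_sizes[2L], x$group_sizes[3L], x$p))
  invisible(x)
}
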