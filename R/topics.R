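# Grade-of-membership (LDA) topic models for spatial spot counts: gene
# filtering, collapsed-Gibbs fitting, Bayes-factor model selection and
# Poisson-KL marker extraction.

#' Filter genes by spot detection
#'
#' Keeps a gene iff it is detected in at least `min_spots` spots (a gene in
#' exactly `min_spots` spots is kept) and in at most `max_frac` of spots.
#'
#' @param counts Spots x genes raw counts.
#' @param min_spots Minimum detected spots (default 10).
#' @param max_frac Maximum detected fraction (default 0.95).
#' @return List with `counts` (filtered) and `report` (removals per rule).
#' @export
filter_spot_genes <- function(counts, min_spots = 10L, max_frac = 0.95) {
  assert_count_matrix(counts, "spot counts")
  det <- col_sums(counts > 0)
  low <- det < min_spots
  high <- det > max_frac * nrow(counts)
  keep <- !(low | high)
  if (sum(keep) < 2L) stop_validation("fewer than 2 genes survive filtering")
  list(counts = counts[, keep, drop = FALSE],
       report = list(n_input = ncol(counts), n_kept = sum(keep),
                     n_removed_low = sum(low), n_removed_high = sum(high),
                     removed_low = colnames(counts)[low],
                     removed_high = colnames(counts)[high],
                     min_spots = min_spots, max_frac = max_frac))
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Topic-gene probabilities `theta` and spot-topic proportions `omega` are
#' posterior means over post-burn-in thinned Gibbs samples. `loglik` is the
#' training log-likelihood of the count matrix under the posterior-mean
#' parameters (multinomial coefficients omitted; they cancel between models
#' on the same data).
#'
#' @param counts Spots x genes raw counts (filtered).
#' @param K Number of topics (>= 2).
#' @param seed Integer seed.
#' @param n_iter Total Gibbs sweeps (default 1000).
#' @param burnin Burn-in sweeps (default `n_iter / 2`).
#' @param thin Thinning interval (default 10).
#' @param alpha Symmetric Dirichlet prior on omega (default `1 / K`).
#' @param beta Symmetric Dirichlet prior on theta (default 0.1).
#' @return Object of class `topic_model` with `theta` (K x genes), `omega`
#'   (spots x K), `K`, `loglik`, `loglik_trace`, `n_tokens`, `seed`.
#' @export
fit_topic_model <- function(counts, K, seed = 1L, n_iter = 1000L,
                            burnin = floor(n_iter / 2), thin = 10L,
                            alpha = 1 / K, beta = 0.1) {
  if (K < 2L) stop_validation("K must be >= 2")
  assert_count_matrix(counts, "spot counts")
  cnt <- as_dense(counts)
  storage.mode(cnt) <- "integer"
  fit <- with_seed(seed, .lda_gibbs_cpp(cnt, as.integer(K), alpha, beta,
                                        as.integer(n_iter),
                                        as.integer(burnin),
                                        as.integer(thin)))
  theta <- fit$theta
  omega <- fit$omega
  dimnames(theta) <- list(sprintf("topic_%d", seq_len(K)), colnames(counts))
  dimnames(omega) <- list(rownames(counts), rownames(theta))
  mix <- omega %*% theta
  ll <- sum(cnt * log(pmax(mix, 1e-300)))
  if (!is.finite(ll)) stop_flscape("non-finite likelihood after sampling")
  structure(list(theta = theta, omega = omega, K = as.integer(K),
                 loglik = ll, loglik_trace = fit$loglik_trace,
                 n_tokens = fit$n_tokens, n_samples = fit$n_samples,
                 alpha = alpha, beta = beta, seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: K = %d; %d spots x %d genes; loglik = %.1f (%d samples)\n",
              x$K, nrow(x$omega), ncol(x$theta), x$loglik, x$n_samples))
  invisible(x)
}

#' Select the number of topics by approximate Bayes factor
#'
#' For each K, the log Bayes factor against the K = 1 multinomial null is
#' approximated BIC-style as `2 * (loglik_K - loglik_1) - (df_K - df_1) *
#' log(N_tokens)` with `df_K = K (G - 1) + S (K - 1)`. The selected K
#' maximizes the approximation; ties go to the smallest K.
#'
#' @param counts Spots x genes raw counts (filtered).
#' @param K_range Integer candidates, each in `[2, 20]`.
#' @param seed Integer seed (each K fit gets a derived seed).
#' @param ... Passed to [fit_topic_model()] (e.g. `n_iter`).
#' @return List with `K` (selected), `table` (per-K loglik, df, log_bf) and
#'   `fits` (the fitted models, named by K).
#' @export
select_K <- function(counts, K_range = 2:6, seed = 1L, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (any(K_range < 2L | K_range > 20L))
    stop_validation("K_range must lie within [2, 20]")
  cnt <- as_dense(counts)
  S <- nrow(cnt); G <- ncol(cnt)
  N <- sum(cnt)
  pg <- colSums(cnt) / N
  ll1 <- sum(t(cnt) * log(pmax(pg, 1e-300)))
  df1 <- G - 1
  fits <- lapply(K_range, function(K)
    fit_topic_model(counts, K, seed = derive_seed(seed, "topics") + K, ...))
  names(fits) <- as.character(K_range)
  ll <- vapply(fits, `[[`, 0, "loglik")
  df <- K_range * (G - 1) + S * (K_range - 1)
  log_bf <- 2 * (ll - ll1) - (df - df1) * log(N)
  best <- K_range[which.max(log_bf)]  # which.max returns the first maximum
  list(K = best,
       table = data.frame(K = K_range, loglik = ll, df = df, log_bf = log_bf,
                          row.names = NULL),
       fits = fits)
}

#' Extract per-topic marker genes by Poisson-KL score
#'
#' The score of gene g for topic k is the smallest Kullback-Leibler
#' divergence `KL(Poisson(theta_kg) || Poisson(theta_k'g)) = theta_k'g -
#' theta_kg + theta_kg * log(theta_kg / theta_k'g)` over all other topics
#' k' — discriminability against the nearest competitor. Genes are ranked
#' descending within topic.
#'
#' @param tm A `topic_model` (K >= 2).
#' @param n_top Genes per topic (default 30).
#' @param eps Probability floor applied to theta (default 1e-12).
#' @return Object of class `topic_markers`: named list of data frames
#'   (`gene`, `score`), scores nonincreasing.
#' @export
extract_top_genes <- function(tm, n_top = 30L, eps = 1e-12) {
  theta <- pmax(tm$theta, eps)
  K <- nrow(theta)
  if (K < 2L) stop_validation("K must be >= 2")
  out <- lapply(seq_len(K), function(k) {
    others <- theta[-k, , drop = FALSE]
    tk <- theta[k, ]
    kl <- sweep(others, 2L, tk, function(o, t) o - t + t * log(t / o))
    score <- apply(kl, 2L, min)
    ord <- order(-score, colnames(theta), method = "radix")
    head(data.frame(gene = colnames(theta)[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL), n_top)
  })
  names(out) <- rownames(theta)
  structure(out, class = "topic_markers")
}

#' @export
print.topic_markers <- function(x, ...) {
  for (k in names(x))
    cat(sprintf("%s: %s ...\n", k, paste(head(x[[k]]$gene, 5L), collapse = ", ")))
  invisible(x)
}
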