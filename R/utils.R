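# Internal utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not perturb the
#' caller's RNG stream. All stochastic operations in the package route their
#' `seed` argument through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_flscape <- function(msg, class = "flscape_error", ...) {
  stop(errorCondition(msg, class = c(class, "flscape_error"), ...))
}

stop_validation <- function(msg, ...) {
  stop_flscape(msg, class = "flscape_validation_error", ...)
}

stop_missing_input <- function(msg, ...) {
  stop_flscape(msg, class = "flscape_missing_input", ...)
}

assert_count_matrix <- function(x, what = "counts") {
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop_validation(sprintf("%s must be a matrix", what))
  v <- if (inherits(x, "sparseMatrix")) x@x else as.numeric(x)
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop_validation(sprintf("%s must contain nonnegative integers", what))
  invisible(TRUE)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# column means / variances that work for base and Matrix classes
col_means <- function(x) {
  if (inherits(x, "sparseMatrix")) Matrix::colMeans(x) else colMeans(x)
}
row_sums <- function(x) {
  if (inherits(x, "sparseMatrix")) Matrix::rowSums(x) else rowSums(x)
}
col_sums <- function(x) {
  if (inherits(x, "sparseMatrix")) Matrix::colSums(x) else colSums(x)
}
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- col_means(x)
  sq <- if (inherits(x, "sparseMatrix")) Matrix::colSums(x^2) else colSums(x^2)
  (sq - n * mu^2) / (n - 1)
}

#' All permutations of 1..n (n <= 9)
#' @keywords internal
all_permutations <- function(n) {
  if (n > 9L) stop_validation("permutation enumeration limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' Natural-log JSD in `[0, log 2]`; arguments are renormalized defensively.
#'
#' @param p,q Nonnegative numeric vectors of equal length.
#' @return Scalar divergence.
#' @export
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Match estimated topics to reference topics
#'
#' Resolves label switching by exhaustive permutation search (K <= 8)
#' minimizing the summed Jensen-Shannon divergence between matched rows of
#' the topic-gene matrices.
#'
#' @param theta_hat Estimated topics x genes matrix (rows sum to 1).
#' @param theta_ref Reference topics x genes matrix.
#' @return Integer permutation `perm` such that `theta_hat[perm[k], ]`
#'   matches `theta_ref[k, ]`, with attribute `"jsd"` holding per-topic
#'   divergences after matching.
#' @export
match_topics <- function(theta_hat, theta_ref) {
  K <- nrow(theta_ref)
  if (nrow(theta_hat) != K)
    stop_validation("topic matrices must have the same number of rows")
  d <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    d[i, j] <- js_divergence(theta_hat[i, ], theta_ref[j, ])
  perms <- all_permutations(K)
  costs <- apply(perms, 1L, function(p) sum(d[cbind(p, seq_len(K))]))
  best <- perms[which.min(costs), ]
  structure(best, jsd = d[cbind(best, seq_len(K))])
}

# stage-seed fan-out: one user seed -> reproducible per-stage seeds < 2^31
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, bulk = 23L, signatures = 31L, score = 47L,
            scde = 59L, gsea = 67L, motifs = 79L, topics = 89L,
            colocalize = 97L, misc = 101L)
  k <- offs[[stage]] %||% 113L
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}
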