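# Synthetic data generators with planted ground truth.
#
# Each generator is seed-deterministic and returns the dataset together with
# a `synthetic_truth` record (planted DE sets, cell states, mixing
# proportions, motif activities) so every downstream stage can be tested
# without external downloads. Negative-binomial counts use the
# mean/dispersion parameterization Var = mu + alpha * mu^2 with a constant
# dispersion per dataset.

#' Define a cytokine response program
#'
#' A directed gene set with planted effect sizes, standing for the
#' transcriptional program a cytokine induces in stimulated fibroblasts.
#' Gene identities are integer indices into the simulated gene universe.
#'
#' @param name Program label (e.g. `"TNF"`).
#' @param up_genes,down_genes Integer gene indices (disjoint).
#' @param log2fc_up,log2fc_down Positive effect sizes in log2 units applied
#'   to up-/down-regulated genes respectively.
#' @return An object of class `cytokine_program`.
#' @export
cytokine_program <- function(name, up_genes = integer(), down_genes = integer(),
                             log2fc_up = 2, log2fc_down = 2) {
  up_genes <- as.integer(up_genes)
  down_genes <- as.integer(down_genes)
  if (length(intersect(up_genes, down_genes)))
    stop_validation(sprintf("program '%s': up and down gene sets overlap", name))
  if (!is.finite(log2fc_up) || !is.finite(log2fc_down) ||
      log2fc_up < 0 || log2fc_down < 0)
    stop_validation(sprintf("program '%s': effect sizes must be finite and >= 0", name))
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes,
                 log2fc_up = log2fc_up, log2fc_down = log2fc_down),
            class = "cytokine_program")
}

#' Define a synthetic cell state
#'
#' A fibroblast state is a weighted combination of cytokine programs acting
#' multiplicatively on a baseline expression profile.
#'
#' @param name State label (e.g. `"resting_lining"`).
#' @param n_cells Number of cells to simulate for this state.
#' @param programs List of `cytokine_program` objects.
#' @param weights Numeric in `[0, 1]`, one per program.
#' @param baseline_mean Optional per-gene relative expression; defaults to a
#'   shared log-normal baseline drawn by the generator.
#' @return An object of class `state_spec`.
#' @export
state_spec <- function(name, n_cells, programs = list(), weights = NULL,
                       baseline_mean = NULL) {
  if (n_cells < 1L) stop_validation(sprintf("state '%s': n_cells must be >= 1", name))
  if (is.null(weights)) weights <- rep(1, length(programs))
  if (length(weights) != length(programs))
    stop_validation("one weight per program required")
  if (any(weights < 0 | weights > 1))
    stop_validation("program weights must lie in [0, 1]")
  if (!is.null(baseline_mean) && any(baseline_mean < 0))
    stop_validation("baseline_mean must be nonnegative")
  structure(list(name = name, n_cells = as.integer(n_cells),
                 programs = programs, weights = weights,
                 baseline_mean = baseline_mean),
            class = "state_spec")
}

gene_universe <- function(n_genes, n_mito = 0L) {
  n_reg <- n_genes - n_mito
  c(sprintf("G%05d", seq_len(n_reg)),
    if (n_mito > 0L) sprintf("MT-%d", seq_len(n_mito)))
}

new_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "synthetic_truth")
}

#' Simulate bulk cytokine-stimulation counts
#'
#' Generates a genes x samples negative-binomial count table with one control
#' condition, one condition per program, and one per requested combination.
#' Planted genes have mean `baseline * 2^(signed log2fc)`; combinations sum
#' program effects in log2 space, optionally rescaled (e.g. to emulate
#' DLL4-style attenuation).
#'
#' @param programs List of `cytokine_program` objects.
#' @param n_replicates Replicates per condition (>= 2; stimulations are run
#'   in triplicate by default).
#' @param n_genes Number of genes.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param baseline_mean Scalar or per-gene baseline mean counts; default
#'   log-normal around 100.
#' @param combinations Optional list; each element a list with fields
#'   `programs` (character names), optional `name`, optional `effect_scale`
#'   multiplying all log2 effects of the combination.
#' @param size_factor_sd Log-normal sd of per-sample depth factors.
#' @param seed Integer seed.
#' @return List with `bulk` (a [bulk_counts()] object) and `truth`
#'   (`synthetic_truth` with `de_genes_by_condition`).
#' @export
generate_bulk <- function(programs, n_replicates = 3L, n_genes = 2000L,
                          dispersion = 0.05, baseline_mean = NULL,
                          combinations = list(), size_factor_sd = 0.1,
                          seed = 1L) {
  if (n_replicates < 2L) stop_validation("n_replicates must be >= 2")
  for (p in programs) {
    if (!inherits(p, "cytokine_program")) stop_validation("programs must be cytokine_program objects")
    if (length(c(p$up_genes, p$down_genes)) &&
        max(c(p$up_genes, p$down_genes)) > n_genes)
      stop_validation(sprintf("program '%s' references gene index > n_genes", p$name))
  }
  pnames <- vapply(programs, `[[`, "", "name")
  with_seed(seed, {
    genes <- gene_universe(n_genes)
    if (is.null(baseline_mean)) {
      baseline_mean <- rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    } else {
      baseline_mean <- rep_len(baseline_mean, n_genes)
    }
    # condition -> signed log2 effect per gene
    cond_effects <- list(control = numeric(n_genes))
    truth_sets <- list()
    add_condition <- function(name, members, scale = 1) {
      eff <- numeric(n_genes)
      up_all <- integer(); down_all <- integer()
      for (p in members) {
        eff[p$up_genes] <- eff[p$up_genes] + scale * p$log2fc_up
        eff[p$down_genes] <- eff[p$down_genes] - scale * p$log2fc_down
        up_all <- union(up_all, p$up_genes)
        down_all <- union(down_all, p$down_genes)
      }
      if (length(intersect(up_all, down_all)))
        stop_validation(sprintf("condition '%s': a gene is both up- and down-regulated", name))
      cond_effects[[name]] <<- eff
      truth_sets[[name]] <<- list(
        up = genes[up_all][abs(eff[up_all]) > 0],
        down = genes[down_all][abs(eff[down_all]) > 0])
    }
    for (p in programs) add_condition(p$name, list(p))
    for (cmb in combinations) {
      members <- programs[match(cmb$programs, pnames)]
      if (anyNA(match(cmb$programs, pnames)))
        stop_validation("combination references unknown program")
      nm <- cmb$name %||% paste(cmb$programs, collapse = "+")
      add_condition(nm, members, scale = cmb$effect_scale %||% 1)
    }
    conds <- names(cond_effects)
    n_samples <- length(conds) * n_replicates
    condition <- rep(conds, each = n_replicates)
    replicate <- rep(seq_len(n_replicates), times = length(conds))
    sf <- rlnorm(n_samples, 0, size_factor_sd)
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(genes,
                                     paste(condition, replicate, sep = "_")))
    for (j in seq_len(n_samples)) {
      mu <- baseline_mean * 2^cond_effects[[condition[j]]] * sf[j]
      counts[, j] <- if (dispersion < 1e-12) rpois(n_genes, mu)
                     else rnbinom(n_genes, size = 1 / dispersion, mu = mu)
    }
    bulk <- bulk_counts(counts, condition = condition, replicate = replicate)
    truth <- new_truth(seed, de_genes_by_condition = truth_sets,
                       baseline_mean = setNames(baseline_mean, genes),
                       dispersion = dispersion, size_factors = sf)
    list(bulk = bulk, truth = truth)
  })
}

#' Simulate multi-state single-cell counts
#'
#' Cells x genes sparse negative-binomial counts. Per-cell library sizes are
#' log-normal (median ~6,000 molecules, matching typical snRNA-seq depth);
#' cytokine programs act multiplicatively on the per-state expression
#' profile. Mitochondrial genes carry the reserved prefix `MT-` and occupy
#' the last `n_mito` gene slots so QC fractions are computable from names
#' alone. Optional planted QC failures: low-depth cells (library size drawn
#' well below 1,024) and high-mito cells (mitochondrial share raised to
#' `high_mito_target`).
#'
#' @param states List of `state_spec` objects (>= 2 unless
#'   `allow_single_state`).
#' @param n_genes Total genes including `n_mito` mitochondrial genes.
#' @param seed Integer seed.
#' @param dispersion NB dispersion.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param n_mito Number of reserved mitochondrial genes.
#' @param mito_frac Baseline mitochondrial expression share.
#' @param low_depth_frac,high_mito_frac Fractions of planted QC-failing cells.
#' @param low_depth_mean Mean library size of planted low-depth cells.
#' @param high_mito_target Mitochondrial share of planted high-mito cells.
#' @param allow_single_state Permit a single state (null simulations).
#' @return List with `counts` (dgCMatrix, cells x genes), `truth`
#'   (`synthetic_truth` with `state_of_cell`, `qc_low_depth`, `qc_high_mito`,
#'   `program_genes`).
#' @export
generate_single_cell <- function(states, n_genes = 2000L, seed = 1L,
                                 dispersion = 0.3,
                                 libsize_meanlog = log(6000),
                                 libsize_sdlog = 0.3,
                                 n_mito = 10L, mito_frac = 0.05,
                                 low_depth_frac = 0.05,
                                 high_mito_frac = 0.05,
                                 low_depth_mean = 400,
                                 high_mito_target = 0.4,
                                 allow_single_state = FALSE) {
  if (length(states) < 2L && !allow_single_state)
    stop_validation("at least two states required")
  for (s in states) {
    if (!inherits(s, "state_spec")) stop_validation("states must be state_spec objects")
    if (s$n_cells == 0L) stop_validation(sprintf("state '%s' has n_cells = 0", s$name))
    for (p in s$programs)
      if (length(c(p$up_genes, p$down_genes)) &&
          max(c(p$up_genes, p$down_genes)) > n_genes - n_mito)
        stop_validation("program genes must not hit reserved mitochondrial slots")
  }
  with_seed(seed, {
    genes <- gene_universe(n_genes, n_mito)
    n_reg <- n_genes - n_mito
    base <- rlnorm(n_reg, 0, 1)
    base <- base / sum(base) * (1 - mito_frac)
    mito_p <- if (n_mito > 0L) {
      m <- rlnorm(n_mito, 0, 0.5); m / sum(m) * mito_frac
    } else numeric()
    n_cells <- sum(vapply(states, `[[`, 0L, "n_cells"))
    state_of_cell <- rep(vapply(states, `[[`, "", "name"),
                         vapply(states, `[[`, 0L, "n_cells"))
    lib <- rlnorm(n_cells, libsize_meanlog, libsize_sdlog)
    n_low <- round(low_depth_frac * n_cells)
    n_hi <- round(high_mito_frac * n_cells)
    flagged <- sample.int(n_cells, n_low + n_hi)
    low_idx <- flagged[seq_len(n_low)]
    hi_idx <- setdiff(flagged, low_idx)
    if (n_low) lib[low_idx] <- pmin(rlnorm(n_low, log(low_depth_mean), 0.3), 1000)
    # per-state gene profiles
    profiles <- lapply(states, function(s) {
      b <- if (is.null(s$baseline_mean)) base
           else {
             bb <- rep_len(s$baseline_mean, n_reg)
             bb / sum(bb) * (1 - mito_frac)
           }
      mult <- rep(1, n_reg)
      for (k in seq_along(s$programs)) {
        p <- s$programs[[k]]; w <- s$weights[k]
        mult[p$up_genes] <- mult[p$up_genes] * 2^(w * p$log2fc_up)
        mult[p$down_genes] <- mult[p$down_genes] * 2^(-w * p$log2fc_down)
      }
      pr <- b * mult
      pr <- pr / sum(pr) * (1 - mito_frac)
      c(pr, mito_p)
    })
    names(profiles) <- vapply(states, `[[`, "", "name")
    prof_mat <- do.call(rbind, profiles)  # states x genes
    pcell <- prof_mat[match(state_of_cell, rownames(prof_mat)), , drop = FALSE]
    if (length(hi_idx)) {
      # raise mito share to the target for planted high-mito cells
      mi <- seq.int(n_reg + 1L, n_genes)
      for (i in hi_idx) {
        p <- pcell[i, ]
        p[mi] <- p[mi] / sum(p[mi]) * high_mito_target
        p[seq_len(n_reg)] <- p[seq_len(n_reg)] / sum(p[seq_len(n_reg)]) *
          (1 - high_mito_target)
        pcell[i, ] <- p
      }
    }
    mu <- pcell * lib
    cnt <- matrix(rnbinom(length(mu), size = 1 / dispersion, mu = as.numeric(mu)),
                  nrow = n_cells, ncol = n_genes)
    dimnames(cnt) <- list(sprintf("cell%05d", seq_len(n_cells)), genes)
    counts <- as(as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix"), "dMatrix")
    program_genes <- lapply(states, function(s)
      lapply(s$programs, function(p)
        list(up = genes[p$up_genes], down = genes[p$down_genes])))
    truth <- new_truth(seed,
                       state_of_cell = setNames(state_of_cell, rownames(cnt)),
                       qc_low_depth = rownames(cnt)[sort(low_idx)],
                       qc_high_mito = rownames(cnt)[sort(hi_idx)],
                       program_genes = program_genes)
    list(counts = counts, truth = truth)
  })
}

#' Build well-separated topic-gene distributions
#'
#' Each topic shares a flat baseline and strongly up-weights its own disjoint
#' marker block, giving identifiable topics for recovery experiments.
#'
#' @param K Number of topics.
#' @param n_genes Number of genes.
#' @param n_markers Markers per topic.
#' @param strength Multiplicative enrichment of markers.
#' @param seed Optional seed for mild baseline jitter.
#' @return K x n_genes matrix with rows summing to 1; marker indices in
#'   attribute `"markers"`.
#' @export
make_separated_topics <- function(K, n_genes, n_markers = 20L, strength = 30,
                                  seed = NULL) {
  if (K * n_markers > n_genes)
    stop_validation("K * n_markers must not exceed n_genes")
  f <- function() {
    base <- rlnorm(n_genes, 0, 0.2)
    theta <- matrix(rep(base, each = K), K, n_genes, byrow = FALSE)
    markers <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- seq.int((k - 1L) * n_markers + 1L, k * n_markers)
      theta[k, idx] <- theta[k, idx] * strength
      markers[[k]] <- idx
    }
    theta <- theta / rowSums(theta)
    colnames(theta) <- sprintf("G%05d", seq_len(n_genes))
    rownames(theta) <- sprintf("topic_%d", seq_len(K))
    structure(theta, markers = markers)
  }
  if (is.null(seed)) f() else with_seed(seed, f())
}

# axial hex grid covering approximately square area; neighbors are the six
# adjacent axial cells
hex_grid <- function(n_spots) {
  side <- ceiling(sqrt(n_spots))
  r <- rep(seq_len(side) - 1L, each = side)[seq_len(n_spots)]
  q <- rep(seq_len(side) - 1L, times = side)[seq_len(n_spots)]
  data.frame(barcode = sprintf("spot%05d", seq_len(n_spots)),
             array_row = r, array_col = q, stringsAsFactors = FALSE)
}

#' Simulate spatial transcriptomics spots
#'
#' Per spot, topic proportions omega ~ Dirichlet(alpha) and counts ~
#' Multinomial(depth, t(theta) %*% omega); coordinates lie on an axial hex
#' grid (Visium-like geometry, six neighbors per interior spot).
#'
#' @param theta_true Topics x genes probability matrix (rows sum to 1).
#' @param n_spots Number of spots.
#' @param depth Scalar or per-spot sequencing depth (>0; totals are exact).
#' @param alpha Dirichlet concentration vector, length K, strictly positive.
#' @param seed Integer seed.
#' @return List with `counts` (dgCMatrix spots x genes), `coords`
#'   (barcode/array_row/array_col data frame), `truth` (with `omega_true`,
#'   `theta_true`).
#' @export
generate_spatial <- function(theta_true, n_spots = 2000L, depth = 2000L,
                             alpha = NULL, seed = 1L) {
  K <- nrow(theta_true)
  rs <- rowSums(theta_true)
  if (any(abs(rs - 1) > 1e-8)) stop_validation("theta_true rows must sum to 1")
  if (any(depth <= 0)) stop_validation("depth must be positive")
  if (is.null(alpha)) alpha <- rep(0.5, K)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (any(alpha <= 0)) stop_validation("alpha must be strictly positive")
  depth <- rep_len(as.integer(depth), n_spots)
  with_seed(seed, {
    g <- matrix(rgamma(n_spots * K, shape = rep(alpha, each = n_spots)),
                n_spots, K)
    zero <- rowSums(g) == 0          # numerically degenerate alpha -> one-hot
    if (any(zero)) {
      for (i in which(zero)) g[i, sample.int(K, 1L)] <- 1
    }
    omega <- g / rowSums(g)
    cnt <- matrix(0L, n_spots, ncol(theta_true))
    for (i in seq_len(n_spots)) {
      p <- as.numeric(crossprod(theta_true, omega[i, ]))
      cnt[i, ] <- rmultinom(1L, depth[i], p)[, 1L]
    }
    coords <- hex_grid(n_spots)
    dimnames(cnt) <- list(coords$barcode, colnames(theta_true))
    rownames(omega) <- coords$barcode
    colnames(omega) <- rownames(theta_true)
    truth <- new_truth(seed, omega_true = omega, theta_true = theta_true)
    list(counts = as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix"),
         coords = coords, truth = truth)
  })
}

#' Simulate a binarized peak x cell accessibility matrix
#'
#' Bernoulli accessibility with logit = peak intercept (GC-dependent) +
#' per-cell depth offset + sum of motif effects for the cell's state. The
#' peak GC covariate both shapes the intercept and is reported, so background
#' matching on GC is exercised downstream.
#'
#' @param n_peaks,n_cells Dimensions.
#' @param states Character state label per cell, or a named integer vector of
#'   cells per state.
#' @param n_motifs Number of motifs when `motif_matrix` is not supplied.
#' @param motif_matrix Optional motifs x peaks binary matrix.
#' @param motif_activity Optional motifs x states effect matrix (logit
#'   units); default all zero.
#' @param gc Optional per-peak GC fraction in `[0, 1]`.
#' @param base_logit Baseline accessibility logit.
#' @param gc_slope Effect of centered GC on the peak intercept.
#' @param depth_sd SD of per-cell depth offsets.
#' @param match_prob Peak-level motif match probability for the random
#'   default motif matrix.
#' @param seed Integer seed.
#' @return List with `peaks` (a [peak_matrix()]), `motifs` (a
#'   [motif_match()]), `state_of_cell`, and `truth` (with `motif_activity`).
#' @export
generate_atac <- function(n_peaks = 500L, n_cells = 300L, states = NULL,
                          n_motifs = 20L, motif_matrix = NULL,
                          motif_activity = NULL, gc = NULL,
                          base_logit = -2, gc_slope = 1.5, depth_sd = 0.5,
                          match_prob = 0.1, seed = 1L) {
  if (is.null(states)) states <- c(A = ceiling(n_cells / 2),
                                   B = floor(n_cells / 2))
  state_of_cell <- if (is.character(states)) states
                   else rep(names(states), states)
  n_cells <- length(state_of_cell)
  state_levels <- unique(state_of_cell)
  with_seed(seed, {
    if (is.null(gc)) gc <- runif(n_peaks, 0.3, 0.7)
    if (any(gc < 0 | gc > 1)) stop_validation("gc must lie in [0, 1]")
    if (is.null(motif_matrix)) {
      motif_matrix <- matrix(rbinom(n_motifs * n_peaks, 1L, match_prob),
                             n_motifs, n_peaks)
    }
    n_motifs <- nrow(motif_matrix)
    rownames(motif_matrix) <- rownames(motif_matrix) %||%
      sprintf("motif_%02d", seq_len(n_motifs))
    if (any(rowSums(motif_matrix) == 0))
      warning("motif with no matched peaks kept; its deviations are undefined downstream")
    if (is.null(motif_activity)) {
      motif_activity <- matrix(0, n_motifs, length(state_levels))
    }
    dimnames(motif_activity) <- list(rownames(motif_matrix), state_levels)
    intercept <- base_logit + gc_slope * (gc - mean(gc)) + rnorm(n_peaks, 0, 0.25)
    depth_off <- rnorm(n_cells, 0, depth_sd)
    # logit[p, i] = intercept_p + depth_i + sum_m activity[m, state_i] match[m, p]
    state_idx <- match(state_of_cell, state_levels)
    eff_ps <- crossprod(motif_matrix, motif_activity)  # peaks x states
    logit <- outer(intercept, depth_off, `+`) + eff_ps[, state_idx, drop = FALSE]
    x <- matrix(rbinom(length(logit), 1L, stats::plogis(logit)),
                n_peaks, n_cells)
    dimnames(x) <- list(sprintf("peak%05d", seq_len(n_peaks)),
                        sprintf("cell%05d", seq_len(n_cells)))
    keep <- colSums(x) > 0
    if (!all(keep)) {
      message(sprintf("dropping %d all-zero cell(s)", sum(!keep)))
      x <- x[, keep, drop = FALSE]
      state_of_cell <- state_of_cell[keep]
      depth_off <- depth_off[keep]
    }
    coords <- data.frame(chrom = "chr1",
                         start = (seq_len(n_peaks) - 1L) * 1000L,
                         end = (seq_len(n_peaks) - 1L) * 1000L + 500L,
                         name = rownames(x), gc = gc,
                         stringsAsFactors = FALSE)
    pm <- peak_matrix(as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
                      peak_coords = coords, gc = gc)
    colnames(motif_matrix) <- rownames(x)
    mm <- motif_match(
      as(Matrix::Matrix(motif_matrix, sparse = TRUE), "CsparseMatrix"),
      motif_to_tf = setNames(as.list(paste0("TF-", rownames(motif_matrix))),
                             rownames(motif_matrix)))
    truth <- new_truth(seed, motif_activity = motif_activity,
                       state_of_cell = setNames(state_of_cell, colnames(x)),
                       depth_offset = depth_off)
    list(peaks = pm, motifs = mm,
         state_of_cell = setNames(state_of_cell, colnames(x)), truth = truth)
  })
}
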