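# Shared fixtures, built once per test run.

fixture_programs <- function(n_sig = 40L, lfc = 2) {
  list(
    cytokine_program("TNF", up_genes = seq_len(n_sig),
                     down_genes = n_sig + seq_len(n_sig),
                     log2fc_up = lfc, log2fc_down = lfc),
    cytokine_program("IFNG", up_genes = 2L * n_sig + seq_len(n_sig),
                     down_genes = 3L * n_sig + seq_len(n_sig),
                     log2fc_up = lfc, log2fc_down = lfc))
}

# two-state single-cell dataset with a planted 4x (log2fc = 2) program
fixture_sc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- cytokine_program("prog", up_genes = 1:50, log2fc_up = 2)
      states <- list(state_spec("rest", 200L),
                     state_spec("act", 200L, programs = list(p)))
      cache <<- generate_single_cell(states, n_genes = 800L, seed = 42L,
                                     low_depth_frac = 0, high_mito_frac = 0)
    }
    cache
  }
})

gene_ids <- function(i) sprintf("G%05d", i)
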