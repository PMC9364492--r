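# Study-condition runs shared by the acceptance tests: computed once per test
# session and cached, since several criteria read different statistics off
# the same seeded experiment.
.study_cache <- new.env(parent = emptyenv())

study_pipeline <- function() {
  if (is.null(.study_cache$pipeline)) {
    .study_cache$pipeline <- run_pipeline(pipeline_config(verbose = FALSE))
  }
  .study_cache$pipeline
}

# Diploid mechanism control: identical conditions minus subgenome divergence
# (single subgenome, no heterozygosity, so introduced errors isolate the
# voting mechanism itself).
study_diploid_control <- function() {
  if (is.null(.study_cache$diploid)) {
    g <- make_subgenomes(150000, divergence = 0,
                         block_model = c(conserved = 5000, divergent = 5000),
                         n_subgenomes = 1, seed = 42)
    r <- simulate_long_reads(g, depth = 30, profile = ont_profile(),
                             seed = 44)
    cr <- correct_reads(r, g)
    .study_cache$diploid <- list(
      genome = g, reads = r,
      account = correction_accounting(r, cr, g))
  }
  .study_cache$diploid
}
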