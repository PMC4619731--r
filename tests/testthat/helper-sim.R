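# Reference simulation at the validation scale (8 samples in 3 unequal
# condition groups, 20k fragments each), built once per test session and
# shared by the conservation / recovery / bias tests.
.sim_cache <- new.env(parent = emptyenv())

get_reference_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    dir <- file.path(tempdir(), "spliceGaps-refsim")
    cfg <- toy_sim_config(n_fragments = 20000L, seed = 1L)
    .sim_cache$sim <- simulate_reads(cfg, dir)
    .sim_cache$groups <- merge_groups(
      .sim_cache$sim$sheet, paste0(cfg$model$chrom, ":1-", cfg$chrom_len))
  }
  list(sim = .sim_cache$sim, groups = .sim_cache$groups)
}
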