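# The scaled-down density sweep shared by the acceptance checks: a smoke
# version of the full protocol (6 x 6 mm domains, 4 realisations per
# density, 13 stimulus sites, 600 ms horizon) sized to run on one CPU
# within the test-suite budget. Computed lazily once per test session.
.sweep_cache <- new.env(parent = emptyenv())

get_desk_sweep <- function() {
  if (is.null(.sweep_cache$res)) {
    proto <- desk_protocol(n_rows = 60, n_cols = 60,
                           rho = c(0.40, 0.44, 0.48, 0.52, 0.56, 0.60),
                           realisations = 4L,
                           config = sim_config(t_max = 600,
                                               stop_on_reentry = FALSE))
    .sweep_cache$res <- run_protocol(proto, keep_sim_data = TRUE)
  }
  .sweep_cache$res
}
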