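# Shared coarse meshes / settings for tests that integrate in time, and a
# per-session cache so expensive runs are computed once per test run.

coarse_grading <- list(h_axis = 40e-6, h_interface = 2e-7,
                       h_boundary = 2e-7, ratio = 1.9)

run_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = env)) assign(key, force(expr), envir = env)
    get(key, envir = env)
  }
})

coarse_model <- function(...) {
  ps <- ref_ps(...)
  fem_model(ps, build_mesh(ps, grading = coarse_grading))
}
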