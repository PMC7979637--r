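# Reference parameter sets and randomized-but-reproducible point states
# used by the property-style tests.

ref_ps <- function(...) {
  load_parameters(c(list(preset = "reference"), list(...)))
}

# A random dilute point state (concentrations, potentials, pressure and
# their radial gradients) vectorized over n points. Water concentrations
# stay near 1/v_w and ion concentrations well below them, as in the
# physical regime.
random_point_state <- function(n, ps, seed = 1) {
  set.seed(seed)
  m <- sum(vapply(ps$species, `[[`, logical(1), "mobile"))
  Cw0 <- 1 / ps$v_w
  rmat <- function(lo, hi) matrix(stats::runif(n * m, lo, hi), n, m)
  list(
    Cw  = Cw0 * stats::runif(n, 0.5, 3.5),
    Cwe = Cw0 * stats::runif(n, 0.3, 1.5),
    Ci  = rmat(1, 300), Ce = rmat(1, 300),
    psi = stats::runif(n, -0.1, 0.1), psie = stats::runif(n, -0.1, 0.1),
    pw  = stats::runif(n, -200, 200),
    g_pw  = stats::runif(n, -1e6, 1e6),
    g_psi = stats::runif(n, -1e3, 1e3), g_psie = stats::runif(n, -1e3, 1e3),
    g_Cw  = stats::runif(n, -1e8, 1e8), g_Cwe = stats::runif(n, -1e8, 1e8),
    g_Ci  = rmat(-1e6, 1e6), g_Ce = rmat(-1e6, 1e6)
  )
}

random_kin <- function(n, seed = 1) {
  set.seed(seed + 1000)
  F_rr <- stats::runif(n, 0.7, 1.6)
  F_tt <- stats::runif(n, 0.7, 1.6)
  F_zz <- stats::runif(n, 0.7, 1.6)
  kinematics1d(F_rr, F_tt, F_zz)
}
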