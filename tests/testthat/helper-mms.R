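# Manufactured-solution machinery for the zero-mobile-species subsystem
# (u, p_w, psi, psi_e, C_w^e coupled through the volumetric constraint,
# plane stress, Darcy/fixed-ion water fluxes and transmembrane osmosis).
# Strong-form sources are obtained by Richardson numerical differentiation
# of the pointwise constitutive laws at the manufactured fields.

num_deriv <- function(f, x, h) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

mms_problem <- function() {
  sp <- list(species_spec("Px", +1, FALSE, 20, 10),
             species_spec("Pn", -1, FALSE, 20, 10))
  ps <- ref_ps(species = sp, include_polarization = FALSE, eps_scale = 1,
               D_w_m = 1e-10)
  dc <- derive_constants(ps)
  Rcl <- ps$R_cl
  f <- list(
    u    = function(R) 0.02 * Rcl * (R / Rcl - (R / Rcl)^3 / 3),
    pw   = function(R) 30 * cos(pi * R / (2 * Rcl)),
    psi  = function(R) 0.01 * cos(pi * R / (2 * Rcl)),
    psie = function(R) 0.005 * (1 - (R / Rcl)^2),
    Cwe  = function(R) (1 + 0.05 * cos(pi * R / (2 * Rcl))) / ps$v_w
  )
  h0 <- 1e-3 * Rcl

  kin_at <- function(R) {
    du <- num_deriv(f$u, R, h0)
    F_rr <- 1 + du
    F_tt <- 1 + f$u(R) / R
    Fzz <- plane_stress_condense(F_rr, F_tt, f$pw(R), 0, 0, dc, ps)
    kinematics1d(F_rr, F_tt, Fzz)
  }
  J_at <- function(R) { k <- kin_at(R); k$J }
  Cw_at <- function(R) water_from_constraint(J_at(R), f$Cwe(R), ps)
  empty <- function(R) matrix(0, length(R), 0)
  state_at <- function(R) list(
    Cw = Cw_at(R), Cwe = f$Cwe(R),
    Ci = empty(R), Ce = empty(R),
    g_pw = num_deriv(f$pw, R, h0),
    g_psi = num_deriv(f$psi, R, h0), g_psie = num_deriv(f$psie, R, h0),
    g_Cw = num_deriv(Cw_at, R, h0), g_Cwe = num_deriv(f$Cwe, R, h0),
    g_Ci = empty(R), g_Ce = empty(R))

  Prr_at <- function(R) nominal_stress(kin_at(R), 0, 0, f$pw(R), dc, ps)$P[, "rr"]
  Ptt_at <- function(R) nominal_stress(kin_at(R), 0, 0, f$pw(R), dc, ps)$P[, "tt"]
  Jw_ic_at <- function(R) ic_fluxes(state_at(R), kin_at(R), ps)$Jw
  Jw_ec_at <- function(R) ec_fluxes(state_at(R), kin_at(R), ps)$Jw
  D_at  <- function(R) electric_displacement(kin_at(R), num_deriv(f$psi, R, h0), ps)
  De_at <- function(R) electric_displacement(kin_at(R), num_deriv(f$psie, R, h0), ps)
  Jwm_at <- function(R) transmembrane_water_flux(
    list(Cw = Cw_at(R), Cwe = f$Cwe(R), Cosm_ic = 40, Cosm_ec = 20), ps)

  av <- dc$area_per_volume
  src <- function(R) {
    divr <- function(g) num_deriv(g, R, h0) + g(R) / R
    cbind(
      -(num_deriv(Prr_at, R, h0) + (Prr_at(R) - Ptt_at(R)) / R),
      divr(Jw_ic_at) + av * Jwm_at(R),
      divr(D_at),
      divr(De_at),
      divr(Jw_ec_at) - av * Jwm_at(R))
  }
  list(ps = ps, dc = dc, fields = f, src = src)
}

# Solve the steady manufactured problem on a uniform n-element mesh and
# return the max scaled nodal error over all five fields.
mms_error <- function(prob, n) {
  ps <- prob$ps
  mesh <- build_mesh(ps, n_elements = n)
  nn <- mesh$n_nodes
  exact <- vapply(prob$fields, function(g) g(pmax(mesh$nodes, 1e-12)), numeric(nn))
  exact[1, 1] <- 0
  model <- fem_model(ps, mesh, mms = list(
    source = prob$src,
    dirichlet = data.frame(node = nn, field = 1:5, value = exact[nn, ])))
  x0 <- as.vector(t(exact))
  sol <- newton_solve(model, x0, x0, dt = Inf,
                      solver_settings(newton_tol = 1e-11, max_newton = 20))
  stopifnot(sol$converged)
  Xs <- matrix(sol$x, nn, 5, byrow = TRUE)
  max(abs(Xs - exact) %*% diag(1 / model$fscale))
}
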