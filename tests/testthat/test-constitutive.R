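test_that("volumetric constraint inversion is exact and round-trips", {
  ps <- ref_ps()
  vw <- ps$v_w
  # undeformed reference
  expect_equal(water_from_constraint(1, 1 / vw, ps), 1 / vw)
  # hand-inverted swollen state: J = 1 + 0.695 * 2.5 with EC undeformed
  expect_equal(water_from_constraint(2.7375, 1 / vw, ps), 3.5 / vw,
               tolerance = 1e-12)
  # round-trip through the forward constraint
  set.seed(42)
  Cw <- stats::runif(50, 0.3, 4) / vw
  Cwe <- stats::runif(50, 0.3, 4) / vw
  J <- 1 + ps$Phi0_ic * (vw * Cw - 1) + ps$Phi0_ec * (vw * Cwe - 1)
  expect_equal(water_from_constraint(J, Cwe, ps), Cw, tolerance = 1e-13)
  expect_error(water_from_constraint(1e-6, 1e-9, ps), "collapse")
})

test_that("water chemical potential matches the osmotic + pressure form", {
  ps <- ref_ps()
  expect_equal(chemical_potential_water(0, 1 / ps$v_w, 0, ps), 0)
  # benchmark initial state: -R T C0 v_w
  mu0 <- chemical_potential_water(300, 1 / ps$v_w, 0, ps)
  expect_equal(mu0, -13.9184, tolerance = 1e-4)
  # equal concentration ratios and pressure give equal potentials
  expect_equal(chemical_potential_water(300, 1 / ps$v_w, 50, ps),
               chemical_potential_water(600, 2 / ps$v_w, 50, ps))
  expect_error(chemical_potential_water(300, -1, 0, ps), "positive")
})

test_that("electrochemical potential vanishes at ln-1 and Nernst equilibria", {
  ps <- ref_ps()
  expect_equal(electrochemical_potential_ion(100, 100, 3, 0, ps), 0)
  # potassium at the Nernst potential equilibrates the two sides
  psiN <- nernst_potential("K", ps = ps)
  expect_equal(1000 * psiN, -89.0156, tolerance = 1e-3)
  mu_ic <- electrochemical_potential_ion(140, 1 / ps$v_w, 1, psiN, ps)
  mu_ec <- electrochemical_potential_ion(5, 1 / ps$v_w, 1, 0, ps)
  expect_equal(mu_ic, mu_ec, tolerance = 1e-10)
})

test_that("mobility matrices are symmetric, correctly scaled and positive definite", {
  ps <- ref_ps()
  kin <- kinematics1d(1.2, 1.1, 0.95)
  st <- list(Cw = 1 / ps$v_w, Cwe = 1 / ps$v_w,
             Ci = c(10, 140, 10), Ce = c(145, 5, 110))
  M <- mobility_matrices(st, kin, ps)
  expect_identical(M$M_ic, t(M$M_ic))
  expect_identical(M$M_ec, t(M$M_ec))
  RT <- ps$R_gas * ps$T
  expect_equal(M$M_ec[1, 1], ps$D_w_ec * st$Cwe * kin$Cinv_rr / RT)
  expect_equal(M$M_ec[1, 2], ps$D_w_ec * st$Ce[1] * kin$Cinv_rr / RT)

  # zero diffusivities give zero matrices
  ps0 <- ref_ps(D_w_ic = 0, D_w_ec = 0,
                species = lapply(default_species(), function(s) {
                  s$D_ic <- s$D_ec <- 0; s
                }))
  M0 <- mobility_matrices(st, kin, ps0)
  expect_true(all(M0$M_ic == 0) && all(M0$M_ec == 0))

  # positive definiteness on 100 random positive states (Cholesky succeeds)
  for (k in 1:100) {
    set.seed(k)
    stk <- list(Cw = stats::runif(1, 0.3, 4) / ps$v_w,
                Cwe = stats::runif(1, 0.3, 4) / ps$v_w,
                Ci = stats::runif(3, 0.1, 400),
                Ce = stats::runif(3, 0.1, 400))
    kk <- kinematics1d(stats::runif(1, 0.6, 1.8), stats::runif(1, 0.6, 1.8),
                       stats::runif(1, 0.6, 1.8))
    Mk <- mobility_matrices(stk, kk, ps)
    expect_no_error(chol(Mk$M_ic))
    expect_no_error(chol(Mk$M_ec))
  }
})

test_that("explicit fluxes equal the mobility/potential route on random states", {
  ps <- ref_ps()
  st <- random_point_state(50, ps, seed = 7)
  kin <- random_kin(50, seed = 7)
  for (space in c("ic", "ec")) {
    a <- if (space == "ic") ic_fluxes(st, kin, ps) else ec_fluxes(st, kin, ps)
    b <- fluxes_via_potentials(st, kin, ps, space)
    expect_equal(a$Jw, b$Jw, tolerance = 1e-10)
    expect_equal(a$Ji, b$Ji, tolerance = 1e-10)
  }
})

test_that("zero gradients give zero fluxes and limits reduce correctly", {
  ps <- ref_ps()
  st <- random_point_state(5, ps, seed = 3)
  for (g in grep("^g_", names(st), value = TRUE)) st[[g]] <- st[[g]] * 0
  kin <- random_kin(5, seed = 3)
  fl <- ic_fluxes(st, kin, ps)
  expect_true(all(fl$Jw == 0) && all(fl$Ji == 0))

  # immobile water: ion fluxes reduce to Nernst-Planck electro-diffusion
  ps_nw <- ref_ps(D_w_ic = 0)
  st2 <- random_point_state(10, ps, seed = 4)
  fl2 <- ic_fluxes(st2, random_kin(10, seed = 4), ps_nw)
  kin2 <- random_kin(10, seed = 4)
  RT <- ps$R_gas * ps$T
  z <- c(1, 1, -1); Di <- rep(1e-12, 3)
  np <- -sweep(st2$g_Ci - (st2$Ci / st2$Cw) * st2$g_Cw +
                 sweep(st2$Ci, 2, z, `*`) * (ps$F / RT * st2$g_psi),
               2, Di, `*`) * kin2$Cinv_rr
  expect_true(all(fl2$Jw == 0))
  expect_equal(fl2$Ji, np, tolerance = 1e-12)

  # no ions at all: Darcy-like water flux proportional to -grad p_w
  ps_d <- param_set(species = list())
  std <- list(Cw = 1 / ps$v_w, Cwe = 1 / ps$v_w,
              Ci = matrix(0, 1, 0), Ce = matrix(0, 1, 0),
              g_pw = 2e5, g_psi = 1e3, g_psie = 1e3,
              g_Cw = 1e7, g_Cwe = 1e7,
              g_Ci = matrix(0, 1, 0), g_Ce = matrix(0, 1, 0))
  kind <- kinematics1d(1, 1, 1)
  fld <- ic_fluxes(std, kind, ps_d)
  expect_equal(fld$Jw,
               -ps_d$D_w_ic * ps$v_w * std$Cw / (ps$R_gas * ps$T) * std$g_pw)
})

test_that("stress decomposition matches the independent Cauchy formula", {
  ps <- ref_ps()
  dc <- derive_constants(ps)
  # reference state is stress-free
  k0 <- kinematics1d(1, 1, 1)
  s0 <- nominal_stress(k0, 0, 0, 0, dc, ps)
  expect_true(all(abs(s0$P) < 1e-12) && abs(s0$p_total) < 1e-12)

  # isotropic swelling with the matching pressure is in total equilibrium
  lam <- 1.398894
  kin <- kinematics1d(lam, lam, lam)
  pw <- (dc$lame_G * (lam^2 - 1) + dc$lame_lambda * log(lam^3)) / lam^3
  st <- nominal_stress(kin, 0, 0, pw, dc, ps)
  expect_true(all(abs(st$sigma) < 1e-10 * ps$E))

  # random diagonal states: sigma agrees with the direct current-frame form
  set.seed(11)
  for (k in 1:20) {
    kk <- kinematics1d(stats::runif(1, 0.6, 1.8), stats::runif(1, 0.6, 1.8),
                       stats::runif(1, 0.6, 1.8))
    D <- stats::runif(1, -1e-4, 1e-4); De <- stats::runif(1, -1e-4, 1e-4)
    pwk <- stats::runif(1, -300, 300)
    s <- nominal_stress(kk, D, De, pwk, dc, ps)
    b <- c(kk$F_rr, kk$F_tt, kk$F_zz)^2
    d <- kk$F_rr * D / kk$J; de <- kk$F_rr * De / kk$J
    ep2 <- 2 * ps$eps0 * ps$eps_r
    sig <- (dc$lame_G * (b - 1) + dc$lame_lambda * log(kk$J)) / kk$J - pwk +
      (2 * c(d^2, 0, 0) - d^2) / ep2 + (2 * c(de^2, 0, 0) - de^2) / ep2
    expect_equal(unname(s$sigma[1, ]), sig, tolerance = 1e-10)
    expect_equal(s$p_total, -sum(sig) / 3, tolerance = 1e-10)
  }
})

test_that("electric displacement follows the deformed-dielectric law", {
  ps <- ref_ps(eps_scale = 1)
  k0 <- kinematics1d(1, 1, 1)
  expect_equal(electric_displacement(k0, 0, ps), 0)
  g <- 1e4
  expect_equal(electric_displacement(k0, g, ps, scaled = FALSE),
               -ps$eps0 * ps$eps_r * g)
  # J = 2 with F_rr = 2 halves the reference-frame value
  k2 <- kinematics1d(2, 2, 0.5)
  expect_equal(electric_displacement(k2, g, ps, scaled = FALSE),
               -0.5 * ps$eps0 * ps$eps_r * g)
})

test_that("dissipation rate is non-negative for law-generated fluxes", {
  ps <- ref_ps()
  st <- random_point_state(200, ps, seed = 21)
  kin <- random_kin(200, seed = 21)
  st$in_region <- rep(FALSE, 200)
  st$Cosm_ic <- rowSums(st$Ci) + 140
  st$Cosm_ec <- rowSums(st$Ce) + 40
  fl <- list(Jw_ic = ic_fluxes(st, kin, ps)$Jw,
             Ji_ic = ic_fluxes(st, kin, ps)$Ji,
             Jw_ec = ec_fluxes(st, kin, ps)$Jw,
             Ji_ec = ec_fluxes(st, kin, ps)$Ji)
  mem <- list(Jw_m = transmembrane_water_flux(st, ps),
              Ji_m = transmembrane_ion_flux(st, ps))
  d <- dissipation_rate(st, kin, fl, mem, ps)
  scale <- max(abs(d))
  expect_true(all(d >= -1e-10 * scale))

  # hand-flipping the transmembrane water flux can break the inequality
  st1 <- st
  st1$Cosm_ic <- st1$Cosm_ic + 500      # strong osmotic imbalance
  mem_bad <- list(Jw_m = -transmembrane_water_flux(st1, ps),
                  Ji_m = transmembrane_ion_flux(st1, ps) * 0)
  fl0 <- lapply(fl, function(x) x * 0)
  names(fl0) <- names(fl)
  d_bad <- dissipation_rate(st1, kin, fl0, mem_bad, ps)
  expect_true(any(d_bad < 0))
})
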