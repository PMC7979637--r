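test_that("open-boundary steady state reproduces the closed-form swelling", {
  ps <- ref_ps()
  s <- open_boundary_steady(ps)
  # bath equality of current concentrations and the Donnan-fixed water content
  expect_equal(unname(s$c_i), c(145, 5, 110))
  expect_equal(s$water_ratio_ic, 3.5)                # (Cw - Cw0)/Cw0 = 2.5
  expect_equal(s$osm_ratio_ic, 3.5)                  # (C - C0)/C0 = 2.5
  expect_equal(s$J, 2.7375)
  expect_equal(s$lambda_s, 2.7375^(1 / 3))
  expect_equal(s$u_frac, 0.39889, tolerance = 1e-4)  # ~0.4 R_cl, u linear in R
  expect_equal(s$psi, 0); expect_equal(s$psie, 0)
  expect_equal(s$osm_ratio_ec, 1); expect_equal(s$water_ratio_ec, 1)

  # the uniform p_w equilibrates the isotropically swollen network
  dc <- derive_constants(ps)
  kin <- kinematics1d(s$lambda_s, s$lambda_s, s$lambda_s)
  st <- nominal_stress(kin, 0, 0, s$pw, dc, ps)
  expect_true(all(abs(st$sigma) < 1e-10 * ps$E))
})

test_that("open-boundary steady state has zero transmembrane fluxes", {
  ps <- ref_ps()
  s <- open_boundary_steady(ps)
  st <- list(Cw = s$C_w, Cwe = s$C_w_e,
             Cosm_ic = sum(s$C_i) + 140, Cosm_ec = sum(s$C_i_e) + 40,
             Ci = matrix(s$C_i, 1), Ce = matrix(s$C_i_e, 1),
             psi = 0, psie = 0, in_region = FALSE)
  # zero up to round-off of the osmotic balance (flux scale ~ 1e5 mol/m^2/s
  # per unit concentration imbalance)
  expect_lt(abs(transmembrane_water_flux(st, ps)), 1e-6)
  fl <- transmembrane_ion_flux(st, ps)
  expect_true(all(abs(fl) < 1e-18))
})

test_that("no driving force means no deformation", {
  # no fixed ions, identical IC and EC initial concentrations
  sp <- list(species_spec("Na", 1, TRUE, 100, 100, 1e-12, 1e-9, 1e-18),
             species_spec("Cl", -1, TRUE, 100, 100, 1e-12, 1e-9, 5e-17))
  ps <- ref_ps(species = sp)
  s <- open_boundary_steady(ps)
  expect_equal(s$J, 1); expect_equal(s$u_frac, 0)
  expect_equal(s$water_ratio_ic, 1)
})

test_that("sealed steady state matches conservation + Donnan closure", {
  ps <- ref_ps(tj_sealed = TRUE)
  s <- sealed_steady(ps)
  expect_equal(s$osm_ratio_ec, 0.287180, tolerance = 1e-5)
  expect_equal(s$osm_ratio_ic, 1.005128, tolerance = 1e-5)
  expect_equal(s$water_ratio_ic, 1.005128, tolerance = 1e-5)
  # current concentrations equalize across the membrane (r = 1 emerges)
  expect_equal(s$r, 1, tolerance = 1e-9)
  expect_equal(unname(s$c_i), unname(s$c_i_e), tolerance = 1e-9)

  # exact conservation of reference totals
  P0 <- ps$Phi0_ic; P0e <- ps$Phi0_ec
  expect_equal(P0 * unname(s$C_i) + P0e * unname(s$C_i_e),
               P0 * c(10, 140, 10) + P0e * c(145, 5, 110), tolerance = 1e-12)
  expect_equal(P0 * s$C_w + P0e * s$C_w_e, (P0 + P0e) / ps$v_w,
               tolerance = 1e-9)
  # electroneutrality in both spaces (fixed anions included)
  z <- c(1, 1, -1)
  expect_equal(sum(z * s$C_i) - 140, 0, tolerance = 1e-9)
  expect_equal(sum(z * s$C_i_e) - 40, 0, tolerance = 1e-9)
})

test_that("a vanishing EC reservoir leaves the IC state at its initial values", {
  ps <- ref_ps(Phi0_ec = 1e-7)
  s <- sealed_steady(ps)
  expect_equal(unname(s$C_i), c(10, 140, 10), tolerance = 1e-4)
  expect_equal(s$water_ratio_ic, 1, tolerance = 1e-5)
})

test_that("Nernst potentials match the closed-form arithmetic", {
  ps <- ref_ps()
  expect_equal(1000 * nernst_potential("K", ps = ps), -89.0156, tolerance = 1e-3)
  expect_equal(1000 * nernst_potential("Cl", ps = ps), -64.0567, tolerance = 1e-3)
  expect_equal(nernst_potential("Na", list(Ci = 50, Cw = 1, Ce = 50, Cwe = 1),
                                ps), 0)
})

test_that("Donnan equilibrium closed form agrees with a brute-force grid search", {
  ps <- ref_ps()
  bath <- c(Na = 145, K = 5, Cl = 150); z <- c(1, 1, -1)
  # zero fixed charge: bath recovered, zero potential
  d0 <- donnan_state(0, bath, z, ps)
  expect_equal(d0$psi, 0)
  expect_equal(d0$conc, bath)
  # negative fixed charge: negative potential, cation accumulation
  dn <- donnan_state(-100, bath, z, ps)
  expect_lt(dn$psi, 0)
  expect_gt(dn$conc[["Na"]], bath[["Na"]])
  # grid-search oracle on the electroneutrality residual over x
  xs <- seq(0.5, 3, by = 1e-6)
  resid <- sum(bath[z > 0]) * xs - sum(bath[z < 0]) / xs + (-100)
  x_grid <- xs[which.min(abs(resid))]
  expect_equal(dn$x, x_grid, tolerance = 1e-6)
})
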