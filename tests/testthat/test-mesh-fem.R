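test_that("mesh construction places nodes as requested", {
  ps <- ref_ps()
  m4 <- build_mesh(ps, n_elements = 4)
  expect_equal(m4$nodes, ps$R_cl * c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(m4$nodes[m4$i_interface], ps$R_cl / 2)

  mg <- build_mesh(ps, grading = list(h_axis = 25e-6, h_interface = 1e-7,
                                      h_boundary = 1e-7, ratio = 1.5))
  expect_true(all(diff(mg$nodes) > 0))
  expect_equal(mg$nodes[1], 0)
  expect_equal(mg$nodes[mg$n_nodes], ps$R_cl)
  expect_true(any(mg$nodes == ps$R_cl / 2))
  # graded: smallest elements hug the interface and the outer boundary
  h <- diff(mg$nodes)
  expect_lt(h[mg$n_elements], 2e-7)
  expect_gt(max(h), 1e-5)
  expect_error(build_mesh(ps, n_elements = 2), ">= 4")
})

test_that("kinematics evaluation handles the axis limit", {
  ps <- ref_ps()
  mesh <- build_mesh(ps, n_elements = 8)
  k0 <- kinematics_at(mesh, rep(0, mesh$n_nodes), c(0, 1e-4, 4e-4))
  expect_equal(k0$F_rr, rep(1, 3)); expect_equal(k0$F_tt, rep(1, 3))
  a <- 0.07
  kl <- kinematics_at(mesh, a * mesh$nodes, c(0, 1e-4, 2.5e-4))
  expect_equal(kl$F_rr, rep(1 + a, 3))
  expect_equal(kl$F_tt, rep(1 + a, 3))
})

test_that("plane-stress condensation matches a bisection oracle", {
  ps <- ref_ps(); dc <- derive_constants(ps)
  expect_equal(plane_stress_condense(1, 1, 0, 0, 0, dc, ps), 1)

  # equibiaxial stretch contracts laterally; compare against uniroot on
  # the zz Cauchy stress assembled independently
  Fzz <- plane_stress_condense(1.2, 1.2, 0, 0, 0, dc, ps)
  expect_lt(Fzz, 1)
  szz <- function(x) nominal_stress(kinematics1d(1.2, 1.2, x),
                                    0, 0, 0, dc, ps)$sigma[, "zz"]
  root <- uniroot(szz, c(0.5, 1), tol = 1e-14)$root
  expect_equal(Fzz, root, tolerance = 1e-9)
  expect_lt(abs(szz(Fzz)), 1e-10 * ps$E)

  # isotropic swollen state with matching pressure: condensation is isotropic
  lam <- 1.398894
  pw <- (dc$lame_G * (lam^2 - 1) + dc$lame_lambda * log(lam^3)) / lam^3
  expect_equal(plane_stress_condense(lam, lam, pw, 0, 0, dc, ps), lam,
               tolerance = 1e-9)
})

test_that("the electroneutral initial state is a discrete equilibrium up to membrane exchange", {
  ps <- ref_ps()
  mesh <- build_mesh(ps, n_elements = 12)
  model <- fem_model(ps, mesh)
  x0 <- initial_state(model)
  asm <- assemble(model, x0, x0, dt = 1, want_jacobian = FALSE)
  R <- matrix(asm$r, model$nn, model$nf, byrow = TRUE)
  # Gauss rows vanish (electroneutral start), as do mechanics/water rows
  expect_true(all(abs(R[, c(1, 3, 4)]) < 1e-20))
  expect_true(all(abs(R[, c(2, 5)]) < 1e-12))
  # ion rows carry only the (nonzero) transmembrane electro-diffusion
  expect_gt(max(abs(R[, 6:11])), 0)

  # with sealed TJs and no membrane transport the state is a full equilibrium
  ps_eq <- ref_ps(tj_sealed = TRUE, D_w_m = 0,
                  species = lapply(default_species(), function(s) {
                    s$D_m <- 0; s$D_m_in <- 0; s
                  }))
  model_eq <- fem_model(ps_eq, build_mesh(ps_eq, n_elements = 12))
  asm_eq <- assemble(model_eq, initial_state(model_eq), initial_state(model_eq),
                     dt = 1, want_jacobian = FALSE)
  expect_true(all(abs(asm_eq$r) < 1e-18))
})

test_that("axis regularity: linear displacement fields produce finite residuals", {
  ps <- ref_ps()
  model <- fem_model(ps, build_mesh(ps, n_elements = 12))
  x <- initial_state(model)
  X <- matrix(x, model$nn, model$nf, byrow = TRUE)
  X[, 1] <- 0.05 * model$mesh$nodes        # u proportional to R
  x <- as.vector(t(X))
  asm <- assemble(model, x, initial_state(model), dt = 1, want_jacobian = FALSE)
  expect_true(all(is.finite(asm$r)))
  qp <- asm$qp
  expect_true(all(abs(qp$F_tt - 1.05) < 1e-12))
})

test_that("assembled Jacobian matches a global finite-difference Jacobian", {
  ps <- ref_ps()
  mesh <- build_mesh(ps, n_elements = 6)
  model <- fem_model(ps, mesh)
  x0 <- initial_state(model)
  # deterministic smooth perturbation, kept feasible
  X <- matrix(x0, model$nn, model$nf, byrow = TRUE)
  wob <- sin(seq_len(model$nn))
  X[, 1] <- 1e-6 * model$mesh$nodes * wob
  X[, 2] <- 5 * wob
  X[, 3] <- -0.01 + 1e-3 * wob
  X[, 4] <- 1e-3 * wob
  X[, 5] <- X[, 5] * (1 + 0.01 * wob)
  X[, 6:11] <- X[, 6:11] * (1 + 0.02 * wob)
  x <- as.vector(t(X))
  asm <- assemble(model, x, x0, dt = 0.5)
  Jd <- as.matrix(asm$J)
  cols <- seq(1, model$ndof, by = 3)
  for (j in cols) {
    h <- 3e-6 * model$xscale[j]
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    fd <- (assemble(model, xp, x0, 0.5, want_jacobian = FALSE)$r -
             assemble(model, xm, x0, 0.5, want_jacobian = FALSE)$r) / (2 * h)
    denom <- max(abs(Jd[, j]), 1e-8 / model$xscale[j])
    expect_lt(max(abs(fd - Jd[, j])) / denom, 1e-5)
  }
})

test_that("open-boundary essential conditions reduce to bath values at zero pressure", {
  ps <- ref_ps()
  model <- fem_model(ps, build_mesh(ps, n_elements = 8))
  nn <- model$nn
  x0 <- initial_state(model)
  asm <- assemble(model, x0, x0, dt = 1, want_jacobian = FALSE)
  # boundary rows are satisfied by the initial state (pw = 0 -> bath values)
  i_bnd <- (nn - 1) * model$nf + c(4L, 5L, 9L, 10L, 11L)
  expect_true(all(abs(asm$r[i_bnd]) < 1e-12))

  # raising the boundary pressure lowers the equilibrium boundary C_w^e
  X <- matrix(x0, nn, model$nf, byrow = TRUE)
  X[nn, 2] <- 500
  asm2 <- assemble(model, as.vector(t(X)), x0, dt = 1, want_jacobian = FALSE)
  r_cwe <- asm2$r[(nn - 1) * model$nf + 5L]
  # residual = Cwe - g(pw); g decreases with pw so the residual turns positive
  expect_gt(r_cwe, 0)
})

test_that("manufactured smooth solution converges at second order", {
  prob <- mms_problem()
  errs <- vapply(c(8, 16, 32), function(n) mms_error(prob, n), numeric(1))
  rates <- log2(errs[-length(errs)] / errs[-1])
  expect_gt(min(rates), 1.6)
  expect_lt(errs[3], errs[1] / 8)
})
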