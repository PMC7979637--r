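#' Axisymmetric diagonal kinematics
#'
#' In the 1-D axisymmetric benchmark the deformation gradient is diagonal:
#' radial stretch `F_rr = 1 + du/dR`, hoop stretch `F_tt = 1 + u/R`, and an
#' out-of-plane stretch `F_zz` set by plane stress. All arguments vectorize.
#'
#' @param F_rr,F_tt,F_zz diagonal stretches (> 0).
#' @return list with `F_rr`, `F_tt`, `F_zz`, volume ratio `J`, areal
#'   Jacobian `J_a = F_rr F_tt`, and `Cinv_rr = 1/F_rr^2` (radial component
#'   of the inverse right Cauchy-Green tensor).
#' @export
kinematics1d <- function(F_rr, F_tt, F_zz = 1) {
  if (any(F_rr <= 0) || any(F_tt <= 0) || any(F_zz <= 0))
    stop("stretches must be positive")
  list(F_rr = F_rr, F_tt = F_tt, F_zz = F_zz,
       J = F_rr * F_tt * F_zz, J_a = F_rr * F_tt, Cinv_rr = 1 / F_rr^2)
}

#' IC water concentration from the volumetric constraint
#'
#' Solid network, water and ions are incompressible, so the volume ratio
#' is tied to the water contents:
#' `J = 1 + Phi0_ic (v_w Cw_ic - 1) + Phi0_ec (v_w Cw_ec - 1)`.
#' This inverts that constraint for the IC water concentration, which is
#' thereby eliminated from the list of independent fields (the water
#' pressure takes its place as the Lagrange multiplier of the constraint).
#'
#' @param J volume ratio (> 0).
#' @param Cw_ec EC water concentration \[mol m^-3 reference\].
#' @param ps a [param_set()].
#' @return IC water concentration \[mol m^-3 reference\].
#' @export
water_from_constraint <- function(J, Cw_ec, ps) {
  if (any(J <= 0)) stop("volume ratio must be positive")
  Cw <- 1 / ps$v_w +
    (J - 1 - ps$Phi0_ec * (ps$v_w * Cw_ec - 1)) / (ps$Phi0_ic * ps$v_w)
  if (any(Cw <= 0))
    stop("nonphysical collapse: IC water concentration <= 0")
  Cw
}

#' Chemical potential of water
#'
#' `mu_w = -R T C_osm / C_w + v_w p_w`: the osmotic pressure of the
#' dissolved species (mobile *and* fixed) plus the mechanical water
#' pressure. Shared by the IC and EC spaces with their own concentrations;
#' the water pressure field is common to both.
#'
#' @param C_osm osmotic concentration, mobile + fixed \[mol m^-3\].
#' @param Cw water concentration \[mol m^-3\] (> 0).
#' @param pw water pressure \[Pa\].
#' @param ps a [param_set()].
#' @return chemical potential \[J mol^-1\].
#' @export
chemical_potential_water <- function(C_osm, Cw, pw, ps) {
  if (any(Cw <= 0)) stop("water concentration must be positive")
  -ps$R_gas * ps$T * C_osm / Cw + ps$v_w * pw
}

#' Electrochemical potential of an ion
#'
#' `mu~_i = R T ln(C_i / C_w) + F z_i psi` (ideal dilute solution).
#'
#' @param Ci ion concentration \[mol m^-3\] (> 0).
#' @param Cw water concentration \[mol m^-3\] (> 0).
#' @param z valence.
#' @param psi electric potential \[V\].
#' @param ps a [param_set()].
#' @return electrochemical potential \[J mol^-1\].
#' @export
electrochemical_potential_ion <- function(Ci, Cw, z, psi, ps) {
  if (any(Ci <= 0) || any(Cw <= 0)) stop("concentrations must be positive")
  ps$R_gas * ps$T * log(Ci / Cw) + ps$F * z * psi
}

# Mobility matrix of one space for a single material point:
# (1+m) x (1+m), water first, then the mobile ions.
.mob_matrix <- function(Dw, Di, Cw, Ci, Cinv, RT) {
  m <- length(Ci)
  M <- matrix(0, 1 + m, 1 + m)
  M[1, 1] <- Dw * Cw
  if (m > 0) {
    M[1, -1] <- M[-1, 1] <- Dw * Ci
    M[-1, -1] <- Dw * outer(Ci, Ci) / Cw
    diag(M)[-1] <- (Dw * Ci / Cw + Di) * Ci
  }
  M * Cinv / RT
}

#' Onsager mobility matrices
#'
#' Builds the symmetric IC and EC mobility matrices coupling the water
#' chemical-potential gradient and the electrochemical-potential gradients
#' of all mobile ions (cross-diffusion: electro-osmosis and convection live
#' in the off-diagonal water-ion entries). In 1-D the tensor factor
#' `C^-1` reduces to the scalar `Cinv_rr`. The matrices are positive
#' definite for positive diffusivities and concentrations.
#'
#' @param state point state: list with `Cw`, `Cwe` (water concentrations)
#'   and `Ci`, `Ce` (named vectors of mobile-ion concentrations).
#' @param kin [kinematics1d()] at the same point.
#' @param ps a [param_set()].
#' @return `list(M_ic, M_ec)` of `(1+m) x (1+m)` matrices
#'   \[mol^2 J^-1 m^-1 s^-1\].
#' @export
mobility_matrices <- function(state, kin, ps) {
  if (any(c(state$Cw, state$Cwe, state$Ci, state$Ce) <= 0))
    stop("concentrations must be positive")
  mob <- .mobile(ps)
  RT <- ps$R_gas * ps$T
  list(
    M_ic = .mob_matrix(ps$D_w_ic, .spec_vec(mob, "D_ic"),
                       state$Cw, state$Ci, kin$Cinv_rr, RT),
    M_ec = .mob_matrix(ps$D_w_ec, .spec_vec(mob, "D_ec"),
                       state$Cwe, state$Ce, kin$Cinv_rr, RT)
  )
}

# Core flux kernel of one space, vectorized over points. Ci and g_Ci are
# n x m matrices (mobile species in columns), everything else length n.
# C_fix is the (uniform, constant) total fixed-species concentration.
.space_fluxes <- function(Dw, Di, z, C_fix, Cinv, Cw, Ci,
                          g_pw, g_psi, g_Cw, g_Ci, ps) {
  if (any(Cw <= 0)) stop("water concentration must be positive")
  RT <- ps$R_gas * ps$T
  Ci <- as.matrix(Ci); g_Ci <- as.matrix(g_Ci)
  zC <- drop(Ci %*% z)
  Jw <- -Dw * Cinv * (ps$v_w * Cw / RT * g_pw +
                        ps$F / RT * zC * g_psi +
                        C_fix / Cw * g_Cw)
  conv <- (Ci / Cw) * Jw
  mig  <- sweep(Ci, 2, z, `*`) * (ps$F / RT * g_psi)
  diff <- g_Ci - (Ci / Cw) * g_Cw
  Ji <- conv - sweep(diff + mig, 2, Di, `*`) * Cinv
  list(Jw = Jw, Ji = Ji)
}

#' Intracellular fluxes (gap junctions)
#'
#' Nominal radial water and ion fluxes in the IC space. The water flux
#' combines pressure-driven (Darcy), electro-osmotic and fixed-ion
#' osmotic terms; the ion fluxes combine convection with water,
#' Fickian diffusion and migration. With `D_w = 0` the ion fluxes reduce
#' to standard Nernst-Planck electro-diffusion; with no ions the water
#' flux reduces to a Darcy flux.
#'
#' @param state point state: `Cw` (IC water), `Ci` (n x m mobile-ion
#'   matrix), gradients `g_pw`, `g_psi`, `g_Cw`, `g_Ci` (material radial
#'   derivatives).
#' @param kin [kinematics1d()].
#' @param ps a [param_set()]; `gj_open = FALSE` zeroes all IC diffusivities.
#' @return `list(Jw, Ji)` with `Jw` length n and `Ji` n x m
#'   \[mol m^-2 s^-1\].
#' @export
ic_fluxes <- function(state, kin, ps) {
  mob <- .mobile(ps)
  .space_fluxes(ps$D_w_ic, .spec_vec(mob, "D_ic"), .spec_vec(mob, "z"),
                sum(.spec_vec(.fixed(ps), "C0_ic")), kin$Cinv_rr,
                state$Cw, state$Ci,
                state$g_pw, state$g_psi, state$g_Cw, state$g_Ci, ps)
}

#' Extracellular fluxes (intercellular clefts)
#'
#' Same structure as [ic_fluxes()] with the EC water concentration,
#' potential and diffusivities.
#'
#' @inheritParams ic_fluxes
#' @export
ec_fluxes <- function(state, kin, ps) {
  mob <- .mobile(ps)
  .space_fluxes(ps$D_w_ec, .spec_vec(mob, "D_ec"), .spec_vec(mob, "z"),
                sum(.spec_vec(.fixed(ps), "C0_ec")), kin$Cinv_rr,
                state$Cwe, state$Ce,
                state$g_pw, state$g_psie, state$g_Cwe, state$g_Ce, ps)
}

#' Fluxes through the mobility-matrix route
#'
#' Evaluates the same IC or EC fluxes as [ic_fluxes()] / [ec_fluxes()]
#' but through the independent route: assemble the chemical-potential
#' gradients by the chain rule and apply the Onsager mobility matrices.
#' Used as a cross-check oracle; the two routes agree to round-off.
#'
#' @param state,kin,ps as in [ic_fluxes()].
#' @param space `"ic"` or `"ec"`.
#' @return `list(Jw, Ji)`.
#' @export
fluxes_via_potentials <- function(state, kin, ps, space = c("ic", "ec")) {
  space <- match.arg(space)
  mob <- .mobile(ps)
  z <- .spec_vec(mob, "z")
  RT <- ps$R_gas * ps$T
  if (space == "ic") {
    Dw <- ps$D_w_ic; Di <- .spec_vec(mob, "D_ic")
    Cw <- state$Cw; Ci <- as.matrix(state$Ci)
    C_fix <- sum(.spec_vec(.fixed(ps), "C0_ic"))
    g_pw <- state$g_pw; g_psi <- state$g_psi
    g_Cw <- state$g_Cw; g_Ci <- as.matrix(state$g_Ci)
  } else {
    Dw <- ps$D_w_ec; Di <- .spec_vec(mob, "D_ec")
    Cw <- state$Cwe; Ci <- as.matrix(state$Ce)
    C_fix <- sum(.spec_vec(.fixed(ps), "C0_ec"))
    g_pw <- state$g_pw; g_psi <- state$g_psie
    g_Cw <- state$g_Cwe; g_Ci <- as.matrix(state$g_Ce)
  }
  g_mut <- RT * (g_Ci / Ci - g_Cw / Cw) + outer(ps$F * g_psi, z)
  C_osm <- rowSums(Ci) + C_fix
  g_mu_w <- -RT * (rowSums(g_Ci) * Cw - C_osm * g_Cw) / Cw^2 + ps$v_w * g_pw
  Jw <- -Dw / RT * kin$Cinv_rr * (Cw * g_mu_w + rowSums(Ci * g_mut))
  Ji <- (Ci / Cw) * Jw - sweep(Ci * g_mut, 2, Di, `*`) / RT * kin$Cinv_rr
  list(Jw = Jw, Ji = Ji)
}

#' Nominal stress, Cauchy stress and pressure split
#'
#' Diagonal components (rr, tt, zz) of the four additive stress
#' contributions: compressible neo-Hookean network stress, water-pressure
#' eigenstress `-p_w J F^-T`, and the IC and EC Maxwell polarization
#' stresses of the radial electric displacements. Also returns the Cauchy
#' map `sigma = J^-1 P F^T` and the pressure decomposition
#' `p = p_mec + p_w + p_pol + p_pol_e` (positive if compressive).
#'
#' @param kin [kinematics1d()].
#' @param D_ic,D_ec radial nominal electric displacements \[C m^-2\]
#'   (physical, unscaled).
#' @param pw water pressure \[Pa\].
#' @param dc [derive_constants()].
#' @param ps a [param_set()].
#' @return list with matrices `P_mec`, `P_w`, `P_pol_ic`, `P_pol_ec`,
#'   `P`, `sigma` (n x 3, columns rr/tt/zz) and vectors `p_mec`, `p_w`,
#'   `p_pol`, `p_pol_e`, `p_total`.
#' @export
nominal_stress <- function(kin, D_ic = 0, D_ec = 0, pw = 0, dc, ps) {
  G <- dc$lame_G; la <- dc$lame_lambda
  Fd <- cbind(rr = kin$F_rr, tt = kin$F_tt, zz = kin$F_zz)
  J <- kin$J; lnJ <- log(J)
  P_mec <- G * (Fd - 1 / Fd) + la * lnJ / Fd
  P_w <- -pw * J / Fd
  epd <- 2 * ps$eps0 * ps$eps_r
  pol_part <- function(D) {
    # radial reference D: P_pol_rr = F_rr D^2/(2 eps J),
    # P_pol_tt/zz = -F_rr^2 D^2/(2 eps J F_tt/zz)
    cbind(rr = kin$F_rr * D^2 / (epd * J),
          tt = -kin$F_rr^2 * D^2 / (epd * J * kin$F_tt),
          zz = -kin$F_rr^2 * D^2 / (epd * J * kin$F_zz))
  }
  P_pol_ic <- pol_part(D_ic)
  P_pol_ec <- pol_part(D_ec)
  P <- P_mec + P_w + P_pol_ic + P_pol_ec
  sigma <- P * Fd / J
  d2 <- (kin$F_rr * D_ic / J)^2
  de2 <- (kin$F_rr * D_ec / J)^2
  trb <- kin$F_rr^2 + kin$F_tt^2 + kin$F_zz^2
  p_mec <- -(G * (trb / 3 - 1) + la * lnJ) / J
  p_pol <- d2 / (3 * epd)
  p_pol_e <- de2 / (3 * epd)
  list(P_mec = P_mec, P_w = P_w, P_pol_ic = P_pol_ic, P_pol_ec = P_pol_ec,
       P = P, sigma = sigma,
       p_mec = p_mec, p_w = pw + numeric(length(J)),
       p_pol = p_pol, p_pol_e = p_pol_e,
       p_total = p_mec + pw + p_pol + p_pol_e)
}

#' Nominal electric displacement
#'
#' `D = -eps0 eps_r J Cinv_rr dpsi/dR` (radial component). The `scaled`
#' flag applies the Gauss-law permittivity regularization factor
#' `ps$eps_scale`; the unscaled (physical) value feeds the polarization
#' stresses.
#'
#' @param kin [kinematics1d()].
#' @param grad_psi material radial potential gradient \[V m^-1\].
#' @param ps a [param_set()].
#' @param scaled apply `eps_scale`?
#' @return radial nominal electric displacement \[C m^-2\].
#' @export
electric_displacement <- function(kin, grad_psi, ps, scaled = TRUE) {
  eps <- ps$eps0 * ps$eps_r * (if (scaled) ps$eps_scale else 1)
  -eps * kin$J * kin$Cinv_rr * grad_psi
}

#' Local dissipation rate
#'
#' Left-hand side of the reduced dissipation inequality: the negative of
#' flux times potential-gradient for both spaces, plus the
#' membrane-exchange terms weighted by the membrane area per unit cell
#' volume. Non-negative whenever the fluxes derive from the (positive
#' semi-definite) mobility laws; used as a runtime diagnostic.
#'
#' @param state point state with concentrations, potentials, pressure and
#'   their gradients (see [ic_fluxes()]), including `psi`, `psie`, `pw`.
#' @param kin [kinematics1d()].
#' @param fluxes `list(Jw_ic, Ji_ic, Jw_ec, Ji_ec)`.
#' @param membrane_fluxes `list(Jw_m, Ji_m)` from the membrane module.
#' @param ps a [param_set()].
#' @return dissipation rate \[W m^-3\], vectorized over points.
#' @export
dissipation_rate <- function(state, kin, fluxes, membrane_fluxes, ps) {
  mob <- .mobile(ps)
  z <- .spec_vec(mob, "z")
  RT <- ps$R_gas * ps$T
  C_fix_ic <- sum(.spec_vec(.fixed(ps), "C0_ic"))
  C_fix_ec <- sum(.spec_vec(.fixed(ps), "C0_ec"))
  Ci <- as.matrix(state$Ci); Ce <- as.matrix(state$Ce)
  g_Ci <- as.matrix(state$g_Ci); g_Ce <- as.matrix(state$g_Ce)

  g_mut_ic <- RT * (g_Ci / Ci - state$g_Cw / state$Cw) + outer(ps$F * state$g_psi, z)
  g_mut_ec <- RT * (g_Ce / Ce - state$g_Cwe / state$Cwe) + outer(ps$F * state$g_psie, z)
  Cosm_ic <- rowSums(Ci) + C_fix_ic
  Cosm_ec <- rowSums(Ce) + C_fix_ec
  g_mu_w_ic <- -RT * (rowSums(g_Ci) * state$Cw - Cosm_ic * state$g_Cw) / state$Cw^2 +
    ps$v_w * state$g_pw
  g_mu_w_ec <- -RT * (rowSums(g_Ce) * state$Cwe - Cosm_ec * state$g_Cwe) / state$Cwe^2 +
    ps$v_w * state$g_pw

  bulk <- -(fluxes$Jw_ic * g_mu_w_ic + rowSums(as.matrix(fluxes$Ji_ic) * g_mut_ic) +
              fluxes$Jw_ec * g_mu_w_ec + rowSums(as.matrix(fluxes$Ji_ec) * g_mut_ec))

  mu_w_ic <- chemical_potential_water(Cosm_ic, state$Cw, state$pw, ps)
  mu_w_ec <- chemical_potential_water(Cosm_ec, state$Cwe, state$pw, ps)
  mut_ic <- RT * log(Ci / state$Cw) + outer(ps$F * state$psi, z)
  mut_ec <- RT * log(Ce / state$Cwe) + outer(ps$F * state$psie, z)
  av <- 2 / ps$R_c
  mem <- -av * (membrane_fluxes$Jw_m * (mu_w_ec - mu_w_ic) +
                  rowSums(as.matrix(membrane_fluxes$Ji_m) * (mut_ec - mut_ic)))
  bulk + mem
}
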