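#' Transmembrane water flux (aquaporins)
#'
#' Osmotic water exchange between the IC and EC spaces at one material
#' point, positive from IC to EC:
#' `Jw_m = -D_w^m (Cw + Cwe) / (2 T_m) * (Cwe C - Cw C^e) / (Cw Cwe)`,
#' where `C` and `C^e` are the osmotic concentrations (mobile + fixed).
#' Because the water pressure field is shared by the two spaces, the
#' driving force contains no pressure jump: transmembrane water transport
#' is purely osmotic. Vanishes at osmotic equilibrium
#' (`C/Cw = C^e/Cwe`), in particular in the reference initial state.
#'
#' @param state list with `Cw`, `Cwe` (water concentrations) and
#'   `Cosm_ic`, `Cosm_ec` (osmotic concentrations, mobile + fixed), all
#'   vectorized \[mol m^-3\].
#' @param ps a [param_set()].
#' @return flux \[mol m^-2 s^-1\], positive IC to EC.
#' @export
transmembrane_water_flux <- function(state, ps) {
  Cw <- state$Cw; Cwe <- state$Cwe
  if (any(Cw <= 0) || any(Cwe <= 0)) stop("water concentrations must be positive")
  -ps$D_w_m * (Cw + Cwe) / (2 * ps$T_m) *
    (Cwe * state$Cosm_ic - Cw * state$Cosm_ec) / (Cw * Cwe)
}

#' Transmembrane ion fluxes (ion channels)
#'
#' Electro-diffusive exchange through ion channels, positive IC to EC:
#' `Ji_m = -D_i^m (Ci + Cie)/(2 T_m) [ ln((Cie/Ci)(Cw/Cwe)) - F z_i psi_m / (R T) ]`
#' with `psi_m = psi - psi_e` the membrane potential. This is the
#' finite-strain counterpart of the Goldman-Hodgkin-Katz flux law; it
#' vanishes when the membrane potential equals the species' Nernst
#' potential. The sodium transmembrane diffusivity may differ between the
#' channel-overexpressing core and the outer annulus (`in_region`).
#'
#' @param state list with `Cw`, `Cwe`, `Ci`, `Ce` (n x m matrices of
#'   mobile-ion concentrations), `psi`, `psie`, and optionally
#'   `in_region` (logical, selects the core transmembrane diffusivities).
#' @param ps a [param_set()].
#' @return n x m matrix of fluxes \[mol m^-2 s^-1\], positive IC to EC.
#' @export
transmembrane_ion_flux <- function(state, ps) {
  mob <- .mobile(ps)
  z <- .spec_vec(mob, "z")
  Ci <- as.matrix(state$Ci); Ce <- as.matrix(state$Ce)
  if (any(Ci <= 0) || any(Ce <= 0) || any(state$Cw <= 0) || any(state$Cwe <= 0))
    stop("concentrations must be positive")
  n <- nrow(Ci)
  in_region <- if (is.null(state$in_region)) rep(FALSE, n) else state$in_region
  Dm_out <- .spec_vec(mob, "D_m")
  Dm_in  <- .spec_vec(mob, "D_m_in")
  Dm <- matrix(Dm_out, n, length(mob), byrow = TRUE)
  if (any(in_region))
    Dm[in_region, ] <- matrix(Dm_in, sum(in_region), length(mob), byrow = TRUE)
  psi_m <- state$psi - state$psie
  force <- log((Ce / Ci) * (state$Cw / state$Cwe)) -
    outer(ps$F / (ps$R_gas * ps$T) * psi_m, z)
  -Dm * (Ci + Ce) / (2 * ps$T_m) * force
}

#' Membrane / tight-junction capacitor displacement
#'
#' The cluster boundary acts as a thin parallel-plate capacitor against
#' the bath (held at zero potential): `D = eps0 eps_r^m psi / T_m` for
#' the cell membranes, `D = eps0 eps_r^tj psi_e / T_tj` for the
#' tight-junction belt. Used as the natural boundary condition of the
#' Gauss laws at the outer radius.
#'
#' @param psi_boundary boundary potential \[V\].
#' @param ps a [param_set()].
#' @param which `"membrane"` or `"tj"`.
#' @return electric displacement \[C m^-2\].
#' @export
membrane_capacitor_displacement <- function(psi_boundary, ps,
                                            which = c("membrane", "tj")) {
  which <- match.arg(which)
  if (which == "membrane") ps$eps0 * ps$eps_r_m * psi_boundary / ps$T_m
  else ps$eps0 * ps$eps_r_tj * psi_boundary / ps$T_tj
}

#' Goldman-Hodgkin-Katz resting potential
#'
#' Classical GHK voltage for monovalent ions, with the transmembrane
#' diffusivities playing the role of relative permeabilities:
#' `psi_m = (R T / F) ln[(sum_cat P C^ec + sum_an P C^ic) /
#'                      (sum_cat P C^ic + sum_an P C^ec)]`.
#' A validation helper only: the simulator never uses it in the dynamics.
#' Invariant under uniform scaling of all permeabilities; reduces to the
#' Nernst potential when a single species is permeant.
#'
#' @param ps a [param_set()].
#' @param region `"out"` or `"in"`: which region's transmembrane
#'   diffusivities to use (sodium differs between them).
#' @param Ci,Ce optional named vectors of IC/EC concentrations overriding
#'   the initial ones \[mol m^-3\].
#' @return membrane potential \[V\].
#' @export
ghk_resting_potential <- function(ps, region = c("out", "in"),
                                  Ci = NULL, Ce = NULL) {
  region <- match.arg(region)
  mob <- .mobile(ps)
  z <- .spec_vec(mob, "z")
  if (any(abs(z) != 1))
    stop("GHK voltage equation implemented for monovalent ions only")
  P <- if (region == "in") .spec_vec(mob, "D_m_in") else .spec_vec(mob, "D_m")
  if (all(P == 0)) stop("at least one species must be membrane-permeant")
  if (is.null(Ci)) Ci <- .spec_vec(mob, "C0_ic")
  if (is.null(Ce)) Ce <- .spec_vec(mob, "C0_ec")
  cat_i <- z > 0
  num <- sum(P[cat_i] * Ce[cat_i]) + sum(P[!cat_i] * Ci[!cat_i])
  den <- sum(P[cat_i] * Ci[cat_i]) + sum(P[!cat_i] * Ce[!cat_i])
  ps$R_gas * ps$T / ps$F * log(num / den)
}
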