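#' Closed-form steady state with a permeable boundary
#'
#' With gap junctions, no tight junctions, no pumps and a compliant
#' network (water pressure negligible against the osmotic pressures),
#' the cluster equilibrates with the bath: every mobile ion's *current*
#' concentration equals its bath value in both spaces and both potentials
#' vanish. The impermeant intracellular anion then fixes the IC water
#' content through electroneutrality,
#' `sum_mobile z_i C_i^{e,0} - C_A / (v_w C_w) = 0`,
#' the volumetric constraint gives the (uniform) swelling `J` with the EC
#' space undeformed, and traction-free plane-stress equilibrium of the
#' isotropically swollen disc gives the stretch `lambda_s = J^{1/3}` and
#' the uniform water pressure `p_w = [G(lambda_s^2 - 1) + lambda ln J]/J`.
#' The displacement is linear in R, so `u(R_cl) = 2 u(R_cl/2)`.
#'
#' Computed analytically, independently of the PDE solver, so it can
#' serve as its verification target.
#'
#' @param ps a [param_set()] with `tj_sealed = FALSE`.
#' @return object of class `steady_state`: current and reference
#'   concentrations, `J`, `lambda_s`, `pw`, osmotic and water ratios,
#'   `u_frac = u(R_cl)/R_cl`, `psi`, `psie`.
#' @export
open_boundary_steady <- function(ps) {
  stopifnot(inherits(ps, "param_set"))
  if (ps$tj_sealed) stop("open_boundary_steady requires tj_sealed = FALSE")
  dc <- derive_constants(ps)
  mob <- .mobile(ps); fix <- .fixed(ps)
  z <- .spec_vec(mob, "z")
  c_bath <- .spec_vec(mob, "C0_ec")       # bath = initial EC, current volume
  zA <- .spec_vec(fix, "z"); CA <- .spec_vec(fix, "C0_ic")
  zsum <- sum(z * c_bath)
  qA <- sum(zA * CA)
  # zsum + qA/(v_w C_w) = 0  =>  v_w C_w = -qA / zsum
  if (length(fix) == 0L || qA == 0) {
    vC <- 1
  } else {
    vC <- -qA / zsum
    if (!is.finite(vC) || vC <= 0)
      stop("fixed-anion charge signs make IC electroneutrality insoluble")
  }
  Cw <- vC / ps$v_w
  Ci <- c_bath * vC                        # reference IC concentrations
  names(Ci) <- vapply(mob, `[[`, character(1), "name")
  C_osm <- sum(Ci) + sum(CA)
  Cwe <- 1 / ps$v_w                        # EC undeformed
  Ce <- c_bath
  names(Ce) <- names(Ci)
  J <- 1 + ps$Phi0_ic * (vC - 1)
  lam <- J^(1/3)
  pw <- (dc$lame_G * (lam^2 - 1) + dc$lame_lambda * log(J)) / J
  C0 <- dc$C0_osm_ic
  structure(list(
    c_i = c_bath, c_i_e = c_bath,
    C_i = Ci, C_i_e = Ce, C_w = Cw, C_w_e = Cwe,
    J = J, lambda_s = lam, pw = pw,
    osm_ratio_ic = if (C0 > 0) C_osm / C0 else NA_real_,
    osm_ratio_ec = 1,
    water_ratio_ic = vC, water_ratio_ec = 1,
    u_frac = lam - 1, psi = 0, psie = 0,
    kind = "open_boundary"
  ), class = "steady_state")
}

#' Closed-form steady state with a sealed (tight-junction) boundary
#'
#' With tight junctions nothing is exchanged with the bath, so the
#' per-species reference totals `Phi0 C_i + Phi0^e C_i^e` and the water
#' total are conserved; at steady state the membrane exchange is in
#' equilibrium (a Donnan condition, `c_i^e = c_i r^{z_i}` with
#' `r = exp(F psi_m / (R T))`, and equal current osmolarities), and each
#' space is electroneutral. The resulting nonlinear system (solved by a
#' safeguarded Newton with numerical Jacobian) yields, for the reference
#' parameters, `r = 1`: the current IC and EC concentrations coincide and
#' `J = 1` pointwise, the cluster globally undeformed.
#'
#' @param ps a [param_set()] (the `tj_sealed` flag is not consulted; the
#'   oracle describes the sealed configuration by construction).
#' @return object of class `steady_state` with the same fields as
#'   [open_boundary_steady()] plus `psi_m` and `r`.
#' @export
sealed_steady <- function(ps) {
  stopifnot(inherits(ps, "param_set"))
  mob <- .mobile(ps); fix <- .fixed(ps)
  m <- length(mob)
  if (m == 0L) stop("sealed_steady needs at least one mobile species")
  z <- .spec_vec(mob, "z")
  C0i <- .spec_vec(mob, "C0_ic"); C0e <- .spec_vec(mob, "C0_ec")
  CA <- sum(.spec_vec(fix, "C0_ic") * -.spec_vec(fix, "z"))   # IC fixed (-) charge
  CAe <- sum(.spec_vec(fix, "C0_ec") * -.spec_vec(fix, "z"))
  OA <- sum(.spec_vec(fix, "C0_ic")); OAe <- sum(.spec_vec(fix, "C0_ec"))
  P0 <- ps$Phi0_ic; P0e <- ps$Phi0_ec
  Ti <- P0 * C0i + P0e * C0e

  # unknowns x = (C_i (m), C_i^e (m), v_w C_w, v_w C_w^e, r)
  fres <- function(x) {
    Ci <- x[1:m]; Ce <- x[m + 1:m]; vC <- x[2 * m + 1]
    vCe <- x[2 * m + 2]; r <- x[2 * m + 3]
    ci <- Ci / vC; ce <- Ce / vCe
    c(P0 * Ci + P0e * Ce - Ti,
      ce - ci * r^z,
      P0 * vC + P0e * vCe - (P0 + P0e),
      sum(z * Ci) - CA,
      (sum(ci) + OA / vC) - (sum(ce) + OAe / vCe))
  }
  x <- c(C0i, C0e, 1, 1, 1)
  ok <- FALSE
  for (it in 1:200) {
    r0 <- fres(x)
    Jm <- vapply(seq_along(x), function(j) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xm <- x; xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (fres(xp) - fres(xm)) / (2 * h)
    }, numeric(length(x)))
    dx <- tryCatch(solve(Jm, -r0), error = function(e) NULL)
    if (is.null(dx)) break
    a <- 1
    while (a > 1e-8 && any((x + a * dx)[1:(2 * m + 2)] <= 0)) a <- a / 2
    x <- x + a * dx
    if (max(abs(a * dx) / pmax(abs(x), 1e-10)) < 1e-13) { ok <- TRUE; break }
  }
  if (!ok && max(abs(fres(x))) > 1e-8 * max(1, sum(Ti)))
    stop("sealed steady-state system did not converge")

  Ci <- x[1:m]; Ce <- x[m + 1:m]
  vC <- x[2 * m + 1]; vCe <- x[2 * m + 2]; r <- x[2 * m + 3]
  names(Ci) <- names(Ce) <- vapply(mob, `[[`, character(1), "name")
  dc <- derive_constants(ps)
  psi_m <- ps$R_gas * ps$T / ps$F * log(r)
  structure(list(
    c_i = Ci / vC, c_i_e = Ce / vCe,
    C_i = Ci, C_i_e = Ce,
    C_w = vC / ps$v_w, C_w_e = vCe / ps$v_w,
    J = 1, lambda_s = 1, pw = 0,
    osm_ratio_ic = (sum(Ci) + OA) / dc$C0_osm_ic,
    osm_ratio_ec = (sum(Ce) + OAe) / dc$C0_osm_ec,
    water_ratio_ic = vC, water_ratio_ec = vCe,
    u_frac = 0, psi = NA_real_, psie = NA_real_,
    psi_m = psi_m, r = r, kind = "sealed"
  ), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>", x$kind, "\n")
  cat("  osmotic ratios IC/EC:", signif(x$osm_ratio_ic, 6), "/",
      signif(x$osm_ratio_ec, 6), "\n")
  cat("  water ratios  IC/EC:", signif(x$water_ratio_ic, 6), "/",
      signif(x$water_ratio_ec, 6), "\n")
  cat("  J =", signif(x$J, 6), " u(R_cl)/R_cl =", signif(x$u_frac, 6),
      " p_w =", signif(x$pw, 6), "Pa\n")
  invisible(x)
}

#' Nernst equilibrium potential of one species
#'
#' `psi = (R T / (z F)) ln[(C_i^e / C_w^e) / (C_i / C_w)]`: the membrane
#' potential at which the species' transmembrane electrochemical driving
#' force vanishes.
#'
#' @param species name of a mobile species in `ps`.
#' @param state optional list with `Ci`, `Cw`, `Ce`, `Cwe` (defaults to
#'   the initial state of `ps`).
#' @param ps a [param_set()].
#' @return potential \[V\].
#' @export
nernst_potential <- function(species, state = NULL, ps) {
  mob <- .mobile(ps)
  nm <- vapply(mob, `[[`, character(1), "name")
  i <- match(species, nm)
  if (is.na(i)) stop("unknown mobile species '", species, "'")
  s <- mob[[i]]
  if (s$z == 0) stop("Nernst potential undefined for z = 0")
  if (is.null(state))
    state <- list(Ci = s$C0_ic, Cw = 1 / ps$v_w, Ce = s$C0_ec, Cwe = 1 / ps$v_w)
  ps$R_gas * ps$T / (s$z * ps$F) *
    log((state$Ce / state$Cwe) / (state$Ci / state$Cw))
}

#' Gibbs-Donnan equilibrium against a bath
#'
#' Equilibrium partitioning of monovalent mobile ions between a bath and
#' a compartment containing an impermeant fixed charge: equal
#' electrochemical potentials plus local electroneutrality. With
#' `x = exp(-F psi / (R T))`, cations partition as `c = c_bath x` and
#' anions as `c = c_bath / x`, and electroneutrality gives the closed form
#' `x = (-Q + sqrt(Q^2 + 4 P N)) / (2 P)` with `P`, `N` the total bath
#' cation/anion concentrations and `Q` the signed fixed-charge
#' concentration. A negative fixed charge yields `psi < 0` and cation
#' accumulation.
#'
#' @param fixed_charge signed fixed-charge concentration `z_f c_f`
#'   \[mol m^-3 current\].
#' @param bath named vector of bath concentrations \[mol m^-3\].
#' @param z valences of the bath species (monovalent), matching `bath`.
#' @param ps a [param_set()] (for T and physical constants).
#' @return list with `psi` \[V\] and `conc`, the equilibrium compartment
#'   concentrations.
#' @export
donnan_state <- function(fixed_charge, bath, z, ps) {
  if (any(abs(z) != 1)) stop("Donnan helper implemented for monovalent ions only")
  P <- sum(bath[z > 0]); N <- sum(bath[z < 0])
  if (P <= 0 || N <= 0) stop("bath must contain both cations and anions")
  Q <- fixed_charge
  x <- (-Q + sqrt(Q^2 + 4 * P * N)) / (2 * P)
  psi <- -ps$R_gas * ps$T / ps$F * log(x)
  conc <- bath
  conc[z > 0] <- bath[z > 0] * x
  conc[z < 0] <- bath[z < 0] / x
  list(psi = psi, conc = conc, x = x)
}
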