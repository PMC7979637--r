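# Galerkin discretization of the coupled balance laws on the 1-D
# axisymmetric reference domain: momentum for u, IC water balance written
# for p_w (C_w eliminated through the volumetric constraint), EC water
# balance for C_w^e, IC/EC mass balances for every mobile ion, and the two
# Gauss laws for psi and psi^e. Linear elements, 2-point Gauss quadrature,
# axisymmetric measure R dR; backward-Euler time terms. The element
# Jacobian blocks are computed by central differences of the vectorized
# element residual.

#' Plane-stress out-of-plane stretch
#'
#' Solves, per point, for `F_zz` such that the total out-of-plane Cauchy
#' stress vanishes:
#' `G(F_zz^2 - 1) + lambda ln J - J p_w - F_rr^2 (D^2 + De^2)/(2 eps0 eps_r J) = 0`
#' with `J = J_a F_zz`. Safeguarded Newton (step limiting plus bisection
#' fallback); the root satisfies `|sigma_zz| <= 1e-10 E`.
#'
#' @param F_rr,F_tt in-plane stretches.
#' @param pw water pressure \[Pa\].
#' @param D_ic,D_ec radial nominal electric displacements \[C m^-2\].
#' @param dc [derive_constants()].
#' @param ps a [param_set()].
#' @return `F_zz` (vectorized); `NaN` entries signal step rejection.
#' @export
plane_stress_condense <- function(F_rr, F_tt, pw, D_ic = 0, D_ec = 0, dc, ps) {
  if (any(F_rr <= 0) || any(F_tt <= 0)) stop("in-plane stretches must be positive")
  Ja <- F_rr * F_tt
  polc <- F_rr^2 * (D_ic^2 + D_ec^2) / (2 * ps$eps0 * ps$eps_r)
  .solve_Fzz(dc$lame_G, dc$lame_lambda, Ja, pw, polc, ps$E)
}

# g(x) = G (x^2 - 1) + la ln(Ja x) - Ja x q - polc/(Ja x); tolerance on
# J*sigma_zz relative to the Young modulus.
.solve_Fzz <- function(G, la, Ja, q, polc, E, x0 = NULL) {
  n <- length(Ja)
  x <- if (is.null(x0)) rep(1, n) else x0
  gfun <- function(x) G * (x^2 - 1) + la * log(Ja * x) - Ja * x * q - polc / (Ja * x)
  # converge to round-off, then one polishing step, so the root is a smooth
  # function of its inputs (the element Jacobian differentiates through it)
  tol <- 1e-13 * E
  polish <- FALSE
  for (it in 1:100) {
    g <- gfun(x)
    gp <- 2 * G * x + la / x - Ja * q + polc / (Ja * x^2)
    dx <- -g / gp
    dx[!is.finite(dx)] <- 0
    dx <- pmax(pmin(dx, 0.5 * x), -0.5 * x)
    x <- x + dx
    if (all(abs(g) <= tol * pmax(Ja * x, 1))) {
      if (polish) return(x)
      polish <- TRUE
    }
  }
  g <- gfun(x)
  bad <- abs(g) > tol * pmax(Ja * x, 1)
  if (any(bad)) {
    for (i in which(bad)) {
      f1 <- function(xx) G * (xx^2 - 1) + la * log(Ja[i] * xx) -
        Ja[i] * xx * (if (length(q) > 1) q[i] else q) -
        (if (length(polc) > 1) polc[i] else polc) / (Ja[i] * xx)
      lo <- 1e-6; hi <- 1e3
      if (!is.finite(f1(lo)) || !is.finite(f1(hi)) || f1(lo) * f1(hi) > 0) {
        x[i] <- NaN
      } else {
        x[i] <- stats::uniroot(f1, c(lo, hi), tol = 1e-15)$root
      }
    }
  }
  x
}

# ---------------------------------------------------------------------------

#' Build a finite-element model
#'
#' Precomputes the degree-of-freedom layout, quadrature data, field
#' scalings and boundary-condition plan for a parameter set and mesh.
#' Per node the unknowns are `u`, `p_w`, `psi`, `psi_e`, `C_w^e` and the
#' IC and EC concentrations of each mobile species; the IC water
#' concentration is not an unknown (eliminated through the volumetric
#' constraint in favour of `p_w`).
#'
#' @param ps a [param_set()].
#' @param mesh a [build_mesh()] mesh.
#' @param mms optional manufactured-solution hook: list with `source`, a
#'   `function(R)` returning an `length(R) x n_fields` matrix of strong-form
#'   sources, and `dirichlet`, a data.frame with columns `node`, `field`,
#'   `value` of extra essential conditions. Testing machinery.
#' @return object of class `fem_model`.
#' @export
fem_model <- function(ps, mesh, mms = NULL) {
  dc <- derive_constants(ps)
  mob <- .mobile(ps); fix <- .fixed(ps)
  m <- length(mob)
  nf <- 5L + 2L * m
  nn <- mesh$n_nodes; ne <- mesh$n_elements
  nodes <- mesh$nodes
  n1 <- seq_len(ne); n2 <- n1 + 1L
  h <- diff(nodes)
  xi <- c(-1, 1) / sqrt(3)
  qa <- (1 - xi) / 2; qb <- (1 + xi) / 2
  Rq <- c(qa[1] * nodes[n1] + qb[1] * nodes[n2],
          qa[2] * nodes[n1] + qb[2] * nodes[n2])
  wq <- rep(h / 2, 2)
  in_region <- Rq < mesh$R_interface

  field_names <- c("u", "pw", "psi", "psie", "Cwe",
                   paste0("C_", vapply(mob, `[[`, character(1), "name")),
                   paste0("Ce_", vapply(mob, `[[`, character(1), "name")))
  Cscale <- max(dc$C0_osm_ic, dc$C0_osm_ec, 1)
  fscale <- c(ps$R_cl, ps$E, ps$R_gas * ps$T / ps$F, ps$R_gas * ps$T / ps$F,
              1 / ps$v_w, rep(Cscale, 2 * m))

  gidx <- matrix(0L, ne, 2L * nf)
  for (f in seq_len(nf)) {
    gidx[, f] <- (n1 - 1L) * nf + f
    gidx[, nf + f] <- (n2 - 1L) * nf + f
  }

  structure(list(
    ps = ps, dc = dc, mesh = mesh, mms = mms,
    m = m, nf = nf, nn = nn, ne = ne, ndof = nn * nf,
    n1 = n1, n2 = n2, h = h, qa = qa, qb = qb, Rq = Rq, wq = wq,
    in_region = in_region, gidx = gidx,
    z = .spec_vec(mob, "z"),
    D_ic = .spec_vec(mob, "D_ic"), D_ec = .spec_vec(mob, "D_ec"),
    Dm_out = .spec_vec(mob, "D_m"), Dm_in = .spec_vec(mob, "D_m_in"),
    C0_ic = .spec_vec(mob, "C0_ic"), C0_ec = .spec_vec(mob, "C0_ec"),
    OA_ic = sum(.spec_vec(fix, "C0_ic")), OA_ec = sum(.spec_vec(fix, "C0_ec")),
    qfix_ic = sum(.spec_vec(fix, "z") * .spec_vec(fix, "C0_ic")),
    qfix_ec = sum(.spec_vec(fix, "z") * .spec_vec(fix, "C0_ec")),
    field_names = field_names, fscale = fscale,
    xscale = rep(fscale, nn)
  ), class = "fem_model")
}

#' Initial state vector
#'
#' Reference configuration: zero displacement, zero water pressure, zero
#' potentials, all concentrations at their initial (Table-of-parameters)
#' values, EC water at `1/v_w`.
#'
#' @param model a [fem_model()].
#' @return numeric state vector (node-major).
#' @export
initial_state <- function(model) {
  v <- c(0, 0, 0, 0, 1 / model$ps$v_w, model$C0_ic, model$C0_ec)
  rep(v, model$nn)
}

# nodal matrix (nn x nf) from the flat vector and back
.as_nodal <- function(model, x) matrix(x, model$nn, model$nf, byrow = TRUE)
.dof <- function(model, node, field) (node - 1L) * model$nf + field

# Evaluate all quadrature-point quantities from local element values.
# loc: ne x 2nf (node-1 fields, node-2 fields). Returns a list of
# 2ne-vectors / 2ne x m matrices, or ok = FALSE on infeasible kinematics.
.qp_eval <- function(model, loc) {
  ps <- model$ps; dc <- model$dc
  ne <- model$ne; nf <- model$nf; m <- model$m
  qa <- model$qa; qb <- model$qb; h <- model$h; Rq <- model$Rq
  v1 <- loc[, seq_len(nf), drop = FALSE]
  v2 <- loc[, nf + seq_len(nf), drop = FALSE]
  val <- function(f) c(qa[1] * v1[, f] + qb[1] * v2[, f],
                       qa[2] * v1[, f] + qb[2] * v2[, f])
  grd <- function(f) rep((v2[, f] - v1[, f]) / h, 2)
  vals <- function(fs) vapply(fs, val, numeric(2 * ne))
  grds <- function(fs) vapply(fs, grd, numeric(2 * ne))

  u <- val(1); du <- grd(1)
  F_rr <- 1 + du; F_tt <- 1 + u / Rq
  if (any(F_rr <= 0) || any(F_tt <= 0)) return(list(ok = FALSE))
  Ja <- F_rr * F_tt
  pw <- val(2); g_pw <- grd(2)
  psi <- val(3); g_psi <- grd(3)
  psie <- val(4); g_psie <- grd(4)
  Cwe <- val(5); g_Cwe <- grd(5)
  iC <- 5L + seq_len(m); iCe <- 5L + m + seq_len(m)
  Ci <- if (m) vals(iC) else matrix(0, 2 * ne, 0)
  g_Ci <- if (m) grds(iC) else matrix(0, 2 * ne, 0)
  Ce <- if (m) vals(iCe) else matrix(0, 2 * ne, 0)
  g_Ce <- if (m) grds(iCe) else matrix(0, 2 * ne, 0)
  if (any(Cwe <= 0) || (m && (any(Ci <= 0) || any(Ce <= 0))))
    return(list(ok = FALSE))

  # current electric displacements: d = -eps0 eps_r grad(psi)/F_rr is
  # independent of F_zz, so plane stress closes with q = p_w + p_pol(zz)
  ep <- ps$eps0 * ps$eps_r
  d_ic <- -ep * g_psi / F_rr
  d_ec <- -ep * g_psie / F_rr
  q <- pw + if (ps$include_polarization) (d_ic^2 + d_ec^2) / (2 * ep) else 0
  Fzz <- .solve_Fzz(dc$lame_G, dc$lame_lambda, Ja, q, 0, ps$E)
  if (any(!is.finite(Fzz))) return(list(ok = FALSE))
  J <- Ja * Fzz
  Cinv <- 1 / F_rr^2

  Cw <- 1 / ps$v_w +
    (J - 1 - ps$Phi0_ec * (ps$v_w * Cwe - 1)) / (ps$Phi0_ic * ps$v_w)
  if (any(Cw <= 0)) return(list(ok = FALSE))
  # gradient of the eliminated C_w via the in-element Gauss-point difference
  # of J (exact for linear variation) and the constraint's chain rule
  dRq <- Rq[ne + seq_len(ne)] - Rq[seq_len(ne)]
  g_J <- rep((J[ne + seq_len(ne)] - J[seq_len(ne)]) / dRq, 2)
  g_Cw <- (g_J - ps$Phi0_ec * ps$v_w * g_Cwe) / (ps$Phi0_ic * ps$v_w)

  list(ok = TRUE, u = u, F_rr = F_rr, F_tt = F_tt, Fzz = Fzz, Ja = Ja, J = J,
       Cinv = Cinv, pw = pw, g_pw = g_pw, psi = psi, g_psi = g_psi,
       psie = psie, g_psie = g_psie, Cwe = Cwe, g_Cwe = g_Cwe,
       Ci = Ci, g_Ci = g_Ci, Ce = Ce, g_Ce = g_Ce,
       Cw = Cw, g_Cw = g_Cw, d_ic = d_ic, d_ec = d_ec)
}

# Element residual contributions (ne x 2nf) for the current local values,
# given precomputed previous-step qp fields and dt (Inf for steady).
.elem_residual <- function(model, loc, prevq, dt) {
  ps <- model$ps; dc <- model$dc
  ne <- model$ne; nf <- model$nf; m <- model$m
  q <- .qp_eval(model, loc)
  if (!q$ok) return(matrix(NaN, ne, 2 * nf))
  Rq <- model$Rq; wq <- model$wq; h <- model$h
  qa <- model$qa; qb <- model$qb
  RT <- ps$R_gas * ps$T
  av <- dc$area_per_volume
  idt <- if (is.finite(dt)) 1 / dt else 0

  # fluxes in the two spaces (explicit electro-diffusion/convection forms)
  fl_ic <- .space_fluxes(ps$D_w_ic, model$D_ic, model$z, model$OA_ic,
                         q$Cinv, q$Cw, q$Ci, q$g_pw, q$g_psi, q$g_Cw, q$g_Ci, ps)
  fl_ec <- .space_fluxes(ps$D_w_ec, model$D_ec, model$z, model$OA_ec,
                         q$Cinv, q$Cwe, q$Ce, q$g_pw, q$g_psie, q$g_Cwe, q$g_Ce, ps)

  # transmembrane exchange
  mst <- list(Cw = q$Cw, Cwe = q$Cwe,
              Cosm_ic = rowSums(q$Ci) + model$OA_ic,
              Cosm_ec = rowSums(q$Ce) + model$OA_ec,
              Ci = q$Ci, Ce = q$Ce, psi = q$psi, psie = q$psie,
              in_region = model$in_region)
  Jwm <- transmembrane_water_flux(mst, ps)
  Jim <- if (m) transmembrane_ion_flux(mst, ps) else matrix(0, 2 * ne, 0)

  # stresses (polarization with physical permittivity)
  kin <- list(F_rr = q$F_rr, F_tt = q$F_tt, F_zz = q$Fzz, J = q$J,
              J_a = q$Ja, Cinv_rr = q$Cinv)
  D_ic_phys <- q$d_ic * q$J / q$F_rr
  D_ec_phys <- q$d_ec * q$J / q$F_rr
  if (!ps$include_polarization) D_ic_phys <- D_ec_phys <- 0
  st <- nominal_stress(kin, D_ic_phys, D_ec_phys, q$pw, dc, ps)
  P_rr <- st$P[, "rr"]; P_tt <- st$P[, "tt"]

  # Gauss-law displacements with the regularized permittivity
  epg <- ps$eps0 * ps$eps_r * ps$eps_scale
  Dg  <- -epg * q$J * q$Cinv * q$g_psi
  Dge <- -epg * q$J * q$Cinv * q$g_psie
  rho_ic <- ps$Phi0_ic * ps$F * (drop(q$Ci %*% model$z) + model$qfix_ic)
  rho_ec <- ps$Phi0_ec * ps$F * (drop(q$Ce %*% model$z) + model$qfix_ec)

  src <- if (!is.null(model$mms)) model$mms$source(Rq) else NULL

  i1 <- seq_len(ne); i2 <- ne + i1
  # contributions of a row with N-weighted integrand S and B-weighted FB:
  # node a gets sum_q w (N_a S + B_a FB), B_1 = -1/h, B_2 = +1/h, w = h/2
  pair <- function(S, FB) {
    n1c <- wq[i1] * (qa[1] * S[i1]) + wq[i2] * (qa[2] * S[i2]) -
      (FB[i1] + FB[i2]) / 2
    n2c <- wq[i1] * (qb[1] * S[i1]) + wq[i2] * (qb[2] * S[i2]) +
      (FB[i1] + FB[i2]) / 2
    cbind(n1c, n2c)
  }

  out <- matrix(0, ne, 2 * nf)
  put <- function(out, f, S, FB) {
    if (!is.null(src)) S <- S - Rq * src[, f]
    p <- pair(S, FB)
    out[, f] <- out[, f] + p[, 1]
    out[, nf + f] <- out[, nf + f] + p[, 2]
    out
  }

  # momentum: integrand B_a P_rr R + N_a P_tt
  out <- put(out, 1L, P_tt, Rq * P_rr)
  # IC water balance (p_w row): Phi0 dCw/dt + Div Jw = -av Jwm
  out <- put(out, 2L,
             Rq * (ps$Phi0_ic * (q$Cw - prevq$Cw) * idt + av * Jwm),
             -Rq * fl_ic$Jw)
  # IC Gauss law
  out <- put(out, 3L, -Rq * rho_ic, -Rq * Dg)
  # EC Gauss law
  out <- put(out, 4L, -Rq * rho_ec, -Rq * Dge)
  # EC water balance
  out <- put(out, 5L,
             Rq * (ps$Phi0_ec * (q$Cwe - prevq$Cwe) * idt - av * Jwm),
             -Rq * fl_ec$Jw)
  for (k in seq_len(m)) {
    out <- put(out, 5L + k,
               Rq * (ps$Phi0_ic * (q$Ci[, k] - prevq$Ci[, k]) * idt + av * Jim[, k]),
               -Rq * fl_ic$Ji[, k])
    out <- put(out, 5L + m + k,
               Rq * (ps$Phi0_ec * (q$Ce[, k] - prevq$Ce[, k]) * idt - av * Jim[, k]),
               -Rq * fl_ec$Ji[, k])
  }
  attr(out, "qp") <- q
  attr(out, "fluxes") <- list(ic = fl_ic, ec = fl_ec, Jwm = Jwm, Jim = Jim)
  out
}

.local_values <- function(model, x) {
  X <- .as_nodal(model, x)
  cbind(X[model$n1, , drop = FALSE], X[model$n2, , drop = FALSE])
}

#' Assemble residual and Jacobian
#'
#' Computes the global Galerkin residual for a backward-Euler step from
#' `x_prev` to `x` over `dt` (use `dt = Inf` for a steady solve), the
#' sparse Jacobian (element blocks by central finite differences of the
#' element residual, plus analytic boundary rows), and applies the
#' boundary conditions selected by the parameter set: axis `u = 0`;
#' traction-free outer boundary; IC zero-flux; membrane-capacitor natural
#' condition on the IC Gauss law; and either bath chemical/electrical
#' equilibrium (no tight junctions: essential conditions on `psi_e`,
#' `C_w^e`, `C_i^e` at the boundary, pressure-coupled) or EC zero-flux
#' with the TJ-capacitor natural condition (sealed).
#'
#' @param model a [fem_model()].
#' @param x,x_prev current and previous state vectors.
#' @param dt time step \[s\] or `Inf`.
#' @param want_jacobian assemble the sparse Jacobian?
#' @return object of class `assembled_system`: `r` (residual), `J`
#'   (`dgCMatrix` or `NULL`), `ok`, and the quadrature cache `qp`.
#' @export
assemble <- function(model, x, x_prev, dt, want_jacobian = TRUE) {
  ps <- model$ps; nf <- model$nf; m <- model$m
  nn <- model$nn; ndof <- model$ndof
  loc <- .local_values(model, x)
  prevq <- .qp_eval(model, .local_values(model, x_prev))
  if (!isTRUE(prevq$ok)) stop("previous state is kinematically infeasible")

  rloc <- .elem_residual(model, loc, prevq, dt)
  qp <- attr(rloc, "qp"); fluxes <- attr(rloc, "fluxes")
  ok <- all(is.finite(rloc))

  r <- numeric(ndof)
  for (j in seq_len(2 * nf)) {
    idx <- model$gidx[, j]
    r[idx] <- r[idx] + rloc[, j]
  }

  X <- .as_nodal(model, x)
  Rcl <- ps$R_cl
  # natural boundary terms at R = R_cl (membrane / TJ capacitors)
  psi_b <- X[nn, 3L]; psie_b <- X[nn, 4L]
  r[.dof(model, nn, 3L)] <- r[.dof(model, nn, 3L)] +
    Rcl * membrane_capacitor_displacement(psi_b, ps, "membrane")
  if (ps$tj_sealed)
    r[.dof(model, nn, 4L)] <- r[.dof(model, nn, 4L)] +
      Rcl * membrane_capacitor_displacement(psie_b, ps, "tj")

  # essential rows
  dir_rows <- .dirichlet_rows(model, X)
  for (d in dir_rows) r[d$row] <- d$res

  Jmat <- NULL
  if (want_jacobian) {
    nl <- 2 * nf
    ii <- jj <- vv <- vector("list", nl)
    for (j in seq_len(nl)) {
      f <- if (j <= nf) j else j - nf
      hstep <- 3e-6 * model$fscale[f]
      lp <- loc; lp[, j] <- lp[, j] + hstep
      lm <- loc; lm[, j] <- lm[, j] - hstep
      dblock <- (.elem_residual(model, lp, prevq, dt) -
                   .elem_residual(model, lm, prevq, dt)) / (2 * hstep)
      ii[[j]] <- as.vector(model$gidx)
      jj[[j]] <- rep(model$gidx[, j], nl)
      vv[[j]] <- as.vector(dblock)
    }
    ii <- unlist(ii); jj <- unlist(jj); vv <- unlist(vv)
    keep <- vv != 0 & is.finite(vv)
    ii <- ii[keep]; jj <- jj[keep]; vv <- vv[keep]
    # natural capacitor terms
    ii <- c(ii, .dof(model, nn, 3L)); jj <- c(jj, .dof(model, nn, 3L))
    vv <- c(vv, Rcl * ps$eps0 * ps$eps_r_m / ps$T_m)
    if (ps$tj_sealed) {
      ii <- c(ii, .dof(model, nn, 4L)); jj <- c(jj, .dof(model, nn, 4L))
      vv <- c(vv, Rcl * ps$eps0 * ps$eps_r_tj / ps$T_tj)
    }
    # essential rows: wipe and set analytic entries
    drows <- vapply(dir_rows, `[[`, numeric(1), "row")
    keep <- !(ii %in% drows)
    ii <- ii[keep]; jj <- jj[keep]; vv <- vv[keep]
    for (d in dir_rows) {
      ii <- c(ii, rep(d$row, length(d$cols)))
      jj <- c(jj, d$cols)
      vv <- c(vv, d$ders)
    }
    Jmat <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
  }

  structure(list(r = r, J = Jmat, ok = ok && all(is.finite(r)),
                 qp = qp, fluxes = fluxes, prevq = prevq, dt = dt),
            class = "assembled_system")
}

# Essential (Dirichlet) rows: list of (row, res, cols, ders).
.dirichlet_rows <- function(model, X) {
  ps <- model$ps; nn <- model$nn; m <- model$m
  RT <- ps$R_gas * ps$T
  out <- list(list(row = .dof(model, 1L, 1L), res = X[1L, 1L],
                   cols = .dof(model, 1L, 1L), ders = 1))
  if (!is.null(model$mms) && !is.null(model$mms$dirichlet)) {
    dd <- model$mms$dirichlet
    for (k in seq_len(nrow(dd))) {
      out[[length(out) + 1L]] <- list(
        row = .dof(model, dd$node[k], dd$field[k]),
        res = X[dd$node[k], dd$field[k]] - dd$value[k],
        cols = .dof(model, dd$node[k], dd$field[k]), ders = 1)
    }
    return(out)
  }
  if (!ps$tj_sealed) {
    # bath equilibrium at the open boundary: psi_e = 0, and the chemical
    # equilibrium conditions written for C_w^e (pressure-coupled) and C_i^e
    out[[length(out) + 1L]] <- list(row = .dof(model, nn, 4L), res = X[nn, 4L],
                                    cols = .dof(model, nn, 4L), ders = 1)
    pw_b <- X[nn, 2L]; Cwe_b <- X[nn, 5L]
    Ce_b <- if (m) X[nn, 5L + m + seq_len(m)] else numeric(0)
    Ce_tot <- sum(Ce_b) + model$OA_ec
    Ce0_osm <- model$dc$C0_osm_ec
    den <- ps$v_w * (RT * Ce0_osm + pw_b)
    out[[length(out) + 1L]] <- list(
      row = .dof(model, nn, 5L),
      res = Cwe_b - RT * Ce_tot / den,
      cols = c(.dof(model, nn, 5L), .dof(model, nn, 2L),
               if (m) .dof(model, nn, 5L + m + seq_len(m))),
      ders = c(1, RT * Ce_tot * ps$v_w / den^2, rep(-RT / den, m)))
    for (k in seq_len(m)) {
      out[[length(out) + 1L]] <- list(
        row = .dof(model, nn, 5L + m + k),
        res = X[nn, 5L + m + k] - ps$v_w * model$C0_ec[k] * Cwe_b,
        cols = c(.dof(model, nn, 5L + m + k), .dof(model, nn, 5L)),
        ders = c(1, -ps$v_w * model$C0_ec[k]))
    }
  }
  out
}

#' Conservation and dissipation diagnostics
#'
#' Reference totals of water and each mobile species over the cluster
#' (`Phi0 int C R dR + Phi0^e int C^e R dR`, same quadrature as the
#' scheme, so sealed-boundary totals are discrete invariants), the free
#' charge of each space, and the integrated dissipation rate, which must
#' be non-negative along any trajectory generated by the mobility laws.
#'
#' @param model a [fem_model()].
#' @param asm an [assemble()] result (its quadrature cache is reused).
#' @return list with `water_total`, `species_totals`, `charge_ic`,
#'   `charge_ec`, `dissipation`.
#' @export
fem_diagnostics <- function(model, asm) {
  q <- asm$qp; ps <- model$ps
  wR <- model$wq * model$Rq
  species <- if (model$m)
    colSums(wR * (ps$Phi0_ic * q$Ci + ps$Phi0_ec * q$Ce)) else numeric(0)
  names(species) <- if (model$m) model$field_names[5L + seq_len(model$m)]
  water <- sum(wR * (ps$Phi0_ic * q$Cw + ps$Phi0_ec * q$Cwe))
  charge_ic <- sum(wR * ps$Phi0_ic * (drop(q$Ci %*% model$z) + model$qfix_ic))
  charge_ec <- sum(wR * ps$Phi0_ec * (drop(q$Ce %*% model$z) + model$qfix_ec))
  st <- list(Cw = q$Cw, Cwe = q$Cwe, Ci = q$Ci, Ce = q$Ce,
             psi = q$psi, psie = q$psie, pw = q$pw,
             g_pw = q$g_pw, g_psi = q$g_psi, g_psie = q$g_psie,
             g_Cw = q$g_Cw, g_Cwe = q$g_Cwe, g_Ci = q$g_Ci, g_Ce = q$g_Ce)
  kin <- list(Cinv_rr = q$Cinv)
  fl <- list(Jw_ic = asm$fluxes$ic$Jw, Ji_ic = asm$fluxes$ic$Ji,
             Jw_ec = asm$fluxes$ec$Jw, Ji_ec = asm$fluxes$ec$Ji)
  mem <- list(Jw_m = asm$fluxes$Jwm, Ji_m = asm$fluxes$Jim)
  diss <- sum(wR * dissipation_rate(st, kin, fl, mem, ps))
  list(water_total = water, species_totals = species,
       charge_ic = charge_ic, charge_ec = charge_ec, dissipation = diss)
}
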