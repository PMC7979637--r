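# Physical constants (SI): Faraday [C/mol], gas constant [J/(mol K)],
# vacuum permittivity [F/m].
.phys <- list(
  F     = 96485.33212,
  R_gas = 8.31446261815,
  eps0  = 8.8541878128e-12
)

#' Define one ionic species
#'
#' A species carries its valence, its initial molar concentrations per unit
#' *reference* volume of the intracellular (IC) and extracellular (EC)
#' spaces, and three diffusivities: within IC water (through gap
#' junctions), within EC water (intercellular clefts), and across the cell
#' membrane (ion channels). Fixed (impermeant) species such as the
#' cytoplasmic macro-anion are modelled with `mobile = FALSE` and zero
#' diffusivities, so that the osmotic and free-charge sums need no special
#' casing.
#'
#' @param name species label, e.g. `"Na"`.
#' @param z integer valence.
#' @param mobile logical; `FALSE` for impermeant species whose reference
#'   concentrations are constant in time.
#' @param C0_ic,C0_ec initial IC/EC concentrations \[mol m^-3 reference\].
#' @param D_ic,D_ec,D_m IC, EC and transmembrane diffusivities \[m^2 s^-1\].
#' @param D_m_in transmembrane diffusivity inside the channel-overexpressing
#'   core region; defaults to `D_m` (no region dependence).
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, z, mobile = TRUE,
                         C0_ic = 0, C0_ec = 0,
                         D_ic = 0, D_ec = 0, D_m = 0, D_m_in = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  z <- as.numeric(z)
  if (C0_ic < 0 || C0_ec < 0) stop("species '", name, "': concentrations must be >= 0")
  if (!mobile && (D_ic != 0 || D_ec != 0 || D_m != 0))
    stop("species '", name, "': immobile species must have zero diffusivities")
  if (any(c(D_ic, D_ec, D_m) < 0)) stop("species '", name, "': diffusivities must be >= 0")
  if (is.null(D_m_in)) D_m_in <- D_m
  structure(list(name = name, z = z, mobile = isTRUE(mobile),
                 C0_ic = C0_ic, C0_ec = C0_ec,
                 D_ic = D_ic, D_ec = D_ec, D_m = D_m, D_m_in = D_m_in),
            class = "species_spec")
}

#' Reference species set
#'
#' Sodium, potassium and chloride (the ions dominating animal-cell
#' bioelectricity) plus a fixed monovalent anion representing charged
#' proteins and nucleic acids. Initial concentrations make both spaces
#' electroneutral and give equal initial osmotic concentrations of
#' 300 mol/m^3. The transmembrane sodium diffusivity is ten times larger
#' in the cluster core, emulating sodium-channel overexpression.
#'
#' @param gj_open logical; when `FALSE` the IC diffusivities are zero
#'   (gap junctions absent or closed).
#' @return list of [species_spec()] objects.
#' @export
default_species <- function(gj_open = TRUE) {
  D_i <- if (gj_open) 1e-12 else 0
  list(
    species_spec("Na", +1, TRUE, C0_ic = 10,  C0_ec = 145,
                 D_ic = D_i, D_ec = 1e-9, D_m = 1e-18, D_m_in = 1e-17),
    species_spec("K",  +1, TRUE, C0_ic = 140, C0_ec = 5,
                 D_ic = D_i, D_ec = 1e-9, D_m = 5e-18),
    species_spec("Cl", -1, TRUE, C0_ic = 10,  C0_ec = 110,
                 D_ic = D_i, D_ec = 1e-9, D_m = 5e-17),
    species_spec("A",  -1, FALSE, C0_ic = 140, C0_ec = 40)
  )
}

.unit_factors <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "K" = 1,
  "m^3/mol" = 1, "m3/mol" = 1, "cm^3/mol" = 1e-6, "cm3/mol" = 1e-6, "L/mol" = 1e-3,
  "m^2/s" = 1, "m2/s" = 1,
  "mol/m^3" = 1, "mol/m3" = 1, "mM" = 1, "M" = 1e3,
  "V" = 1, "mV" = 1e-3, "-" = 1
)

# Accept either a bare number or a "value unit" string ("500 um", "0.4 kPa").
.parse_quantity <- function(x, key) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(parts[1]))
    if (!is.na(val) && length(parts) == 1L) return(val)
    if (!is.na(val) && length(parts) == 2L) {
      f <- .unit_factors[parts[2]]
      if (is.na(f)) stop("unknown unit tag '", parts[2], "' for key '", key, "'")
      return(val * unname(f))
    }
  }
  stop("cannot parse value for key '", key, "'")
}

#' Build a parameter set
#'
#' All values are SI internally (m, s, Pa, K, mol m^-3, V). Defaults are
#' the benchmark reference set for an animal-cell cluster.
#'
#' @param R_c reference cell radius \[m\].
#' @param T_m membrane thickness \[m\].
#' @param R_cl reference cluster radius \[m\].
#' @param Phi0_ic,Phi0_ec initial IC/EC porosities.
#' @param T absolute temperature \[K\].
#' @param eps_r,eps_r_m,eps_r_tj relative permittivities of the aqueous
#'   solutions, the cell membrane and the tight-junction (TJ) complex.
#' @param T_tj TJ thickness \[m\].
#' @param v_w water molar volume \[m^3 mol^-1\].
#' @param E,nu Young modulus \[Pa\] and Poisson ratio of the solid network.
#' @param D_w_ic,D_w_ec,D_w_m IC, EC and transmembrane water diffusivities
#'   \[m^2 s^-1\].
#' @param species list of [species_spec()].
#' @param region_boundary reference radius separating the
#'   channel-overexpressing core from the outer annulus \[m\];
#'   default `R_cl/2`.
#' @param gj_open gap junctions present? When `FALSE` all IC diffusivities
#'   (water and ions) are forced to zero.
#' @param tj_sealed tight junctions sealing the cluster boundary?
#' @param eps_scale regularization factor applied to the solution relative
#'   permittivity in the Gauss laws only; thickens the (nanometric) charged
#'   boundary layers to a mesh-resolvable width. Steady bulk fields are
#'   insensitive to it (see the methods vignette).
#' @param include_polarization include the (tiny) Maxwell polarization
#'   stresses in the stress balance?
#' @return object of class `param_set`.
#' @export
param_set <- function(R_c = 5e-6, T_m = 5e-9, R_cl = 500e-6,
                      Phi0_ic = 0.695, Phi0_ec = 0.005,
                      T = 310, eps_r = 80, eps_r_m = 3, eps_r_tj = 30,
                      T_tj = 500e-9, v_w = 18e-6,
                      E = 400, nu = 0.3,
                      D_w_ic = 1e-9, D_w_ec = 1e-7, D_w_m = 1e-8,
                      species = NULL,
                      region_boundary = NULL,
                      gj_open = TRUE, tj_sealed = FALSE,
                      eps_scale = 3e4, include_polarization = TRUE) {
  if (is.null(species)) species <- default_species(gj_open = gj_open)
  if (is.null(region_boundary)) region_boundary <- R_cl / 2
  ps <- structure(list(
    R_c = R_c, T_m = T_m, R_cl = R_cl,
    Phi0_ic = Phi0_ic, Phi0_ec = Phi0_ec,
    T = T, eps_r = eps_r, eps_r_m = eps_r_m, eps_r_tj = eps_r_tj,
    T_tj = T_tj, v_w = v_w, E = E, nu = nu,
    D_w_ic = D_w_ic, D_w_ec = D_w_ec, D_w_m = D_w_m,
    species = species, region_boundary = region_boundary,
    gj_open = isTRUE(gj_open), tj_sealed = isTRUE(tj_sealed),
    eps_scale = eps_scale, include_polarization = isTRUE(include_polarization),
    F = .phys$F, R_gas = .phys$R_gas, eps0 = .phys$eps0
  ), class = "param_set")
  if (!ps$gj_open) {
    ps$D_w_ic <- 0
    ps$species <- lapply(ps$species, function(s) { s$D_ic <- 0; s })
  }
  .validate_param_set(ps)
  ps
}

.validate_param_set <- function(ps) {
  pos <- c("R_c", "T_m", "R_cl", "T", "eps_r", "eps_r_m", "eps_r_tj",
           "T_tj", "v_w", "E", "eps_scale")
  for (k in pos) if (!is.numeric(ps[[k]]) || ps[[k]] <= 0)
    stop("parameter '", k, "' must be positive")
  nonneg <- c("D_w_ic", "D_w_ec", "D_w_m")
  for (k in nonneg) if (ps[[k]] < 0) stop("parameter '", k, "' must be >= 0")
  if (!(ps$Phi0_ec > 0 && ps$Phi0_ic > 0 && ps$Phi0_ic + ps$Phi0_ec < 1))
    stop("porosities must satisfy 0 < Phi0_ec, 0 < Phi0_ic, Phi0_ic + Phi0_ec < 1")
  if (ps$Phi0_ec >= ps$Phi0_ic)
    stop("EC porosity must be much smaller than IC porosity (closely packed cells)")
  if (!(ps$nu > 0 && ps$nu < 0.5)) stop("Poisson ratio must lie in (0, 0.5)")
  if (!(ps$region_boundary > 0 && ps$region_boundary < ps$R_cl))
    stop("region_boundary must lie inside (0, R_cl)")
  if (!all(vapply(ps$species, inherits, logical(1), "species_spec")))
    stop("species must be a list of species_spec objects")
  nm <- vapply(ps$species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate species names")
  invisible(ps)
}

#' Load a parameter set from a configuration
#'
#' The configuration is a flat key-value document: a YAML or JSON file
#' path, or a named list. A `preset: reference` entry selects the
#' benchmark defaults; any other key overrides the corresponding
#' [param_set()] argument. Scalar values may carry unit tags as strings
#' (`R_cl: "500 um"`, `E: "0.4 kPa"`, `v_w: "18 cm^3/mol"`); they are
#' converted to SI on load. Species are overridden through a `species`
#' block: a list of per-species named lists understood by
#' [species_spec()].
#'
#' @param config file path or named list.
#' @return a `param_set`.
#' @export
load_parameters <- function(config = list(preset = "reference")) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  preset <- config$preset
  config$preset <- NULL
  if (!is.null(preset) && !identical(preset, "reference"))
    stop("unknown preset '", preset, "'")
  if (is.null(preset) && length(config) == 0L)
    stop("config must name a preset or supply parameter values")

  args <- list()
  known <- names(formals(param_set))
  quantity_keys <- setdiff(known, c("species", "gj_open", "tj_sealed",
                                    "include_polarization"))
  for (k in names(config)) {
    if (!k %in% known) stop("unknown configuration key '", k, "'")
    v <- config[[k]]
    args[[k]] <- if (k %in% quantity_keys) .parse_quantity(v, k) else v
  }
  if (!is.null(args$species)) {
    if (!is.list(args$species)) stop("species must be a list")
    args$species <- lapply(args$species, function(s) {
      if (inherits(s, "species_spec")) return(s)
      do.call(species_spec, s)
    })
  }
  # gj_open gating of IC diffusivities is applied inside param_set()
  do.call(param_set, args)
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> cluster radius", x$R_cl * 1e6, "um; cell radius",
      x$R_c * 1e6, "um\n")
  cat("  porosities IC/EC:", x$Phi0_ic, "/", x$Phi0_ec,
      " T =", x$T, "K  E =", x$E, "Pa  nu =", x$nu, "\n")
  cat("  gap junctions:", if (x$gj_open) "open" else "absent/closed",
      " tight junctions:", if (x$tj_sealed) "sealed" else "absent", "\n")
  cat("  species:", paste(vapply(x$species, function(s)
    sprintf("%s(z=%+d%s)", s$name, as.integer(s$z),
            if (s$mobile) "" else ", fixed"), character(1)), collapse = " "), "\n")
  invisible(x)
}

# Convenience extractors used throughout the package.
.mobile <- function(ps) Filter(function(s) s$mobile, ps$species)
.fixed  <- function(ps) Filter(function(s) !s$mobile, ps$species)
.spec_vec <- function(sp, field) vapply(sp, `[[`, numeric(1), field)

#' Derived model constants
#'
#' Lame parameters of the compressible neo-Hookean network, the initial
#' water concentration 1/v_w implied by incompressibility of all
#' constituents, the membrane area per unit cell volume 2/R_c of a
#' circular reference cell, and the initial osmotic concentrations
#' (mobile plus fixed species).
#'
#' @param ps a [param_set()].
#' @return object of class `derived_constants` with fields `lame_lambda`,
#'   `lame_G` \[Pa\], `Cw0` \[mol m^-3\], `area_per_volume` \[m^-1\],
#'   `C0_osm_ic`, `C0_osm_ec` \[mol m^-3\].
#' @export
derive_constants <- function(ps) {
  stopifnot(inherits(ps, "param_set"))
  out <- structure(list(
    lame_lambda = ps$E * ps$nu / ((1 + ps$nu) * (1 - 2 * ps$nu)),
    lame_G = ps$E / (2 * (1 + ps$nu)),
    Cw0 = 1 / ps$v_w,
    area_per_volume = 2 / ps$R_c,
    C0_osm_ic = sum(.spec_vec(ps$species, "C0_ic")),
    C0_osm_ec = sum(.spec_vec(ps$species, "C0_ec"))
  ), class = "derived_constants")
  out
}

#' Validate the initial state of a parameter set
#'
#' Checks that (a) both spaces are initially electroneutral, which the
#' zero initial potentials require; (b) the initial IC and EC osmotic
#' concentrations are equal, so the initial transmembrane water flux
#' vanishes; and (c) the solutions are dilute.
#'
#' @param ps a [param_set()].
#' @param diluteness_tol maximum allowed ratio of osmotic to water
#'   concentration (default 0.02).
#' @return a report list with fields `charge_ic`, `charge_ec`,
#'   `osm_ic`, `osm_ec`, `osmotic_balanced`, `diluteness`, `dilute`.
#'   Errors if either space violates electroneutrality.
#' @export
validate_initial_state <- function(ps, diluteness_tol = 0.02) {
  stopifnot(inherits(ps, "param_set"))
  z  <- .spec_vec(ps$species, "z")
  ci <- .spec_vec(ps$species, "C0_ic")
  ce <- .spec_vec(ps$species, "C0_ec")
  q_ic <- sum(z * ci); q_ec <- sum(z * ce)
  scale <- max(1, sum(abs(ci)), sum(abs(ce)))
  if (abs(q_ic) > 1e-9 * scale || abs(q_ec) > 1e-9 * scale)
    stop(sprintf(
      "initial electroneutrality violated (IC charge %.6g, EC charge %.6g mol/m^3); a zero initial potential would be inconsistent",
      q_ic, q_ec))
  osm_ic <- sum(ci); osm_ec <- sum(ce)
  dil <- max(osm_ic, osm_ec) * ps$v_w
  list(charge_ic = q_ic, charge_ec = q_ec,
       osm_ic = osm_ic, osm_ec = osm_ec,
       osmotic_balanced = isTRUE(abs(osm_ic - osm_ec) <= 1e-9 * scale),
       diluteness = dil, dilute = dil <= diluteness_tol)
}
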