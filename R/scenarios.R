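# Scenario registry, profile extraction, sweep driver and export.

#' Define a simulation scenario
#'
#' The three named scenarios reproduce the benchmark configurations:
#' `"noGJ_noTJ"` (gap junctions closed, boundary open to the bath),
#' `"GJ_noTJ"` (gap junctions open, boundary open) and `"GJ_TJ"`
#' (gap junctions open, tight junctions sealing the boundary).
#'
#' @param name one of `"noGJ_noTJ"`, `"GJ_noTJ"`, `"GJ_TJ"`, or
#'   `"custom"`.
#' @param overrides named list of [param_set()] overrides (merged on top
#'   of the scenario's GJ/TJ flags).
#' @param t_max time horizon \[s\].
#' @param output_times snapshot times \[s\].
#' @param n_elements uniform mesh size when `grading` is `NULL`.
#' @param grading mesh grading spec for [build_mesh()]; the default
#'   refines the axis, interface and outer boundary.
#' @param settings [solver_settings()].
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("GJ_noTJ", "noGJ_noTJ", "GJ_TJ", "custom"),
                          overrides = list(), t_max = 600,
                          output_times = c(60, 600),
                          n_elements = NULL, grading = NULL,
                          settings = solver_settings()) {
  name <- match.arg(name)
  flags <- switch(name,
                  noGJ_noTJ = list(gj_open = FALSE, tj_sealed = FALSE),
                  GJ_noTJ   = list(gj_open = TRUE,  tj_sealed = FALSE),
                  GJ_TJ     = list(gj_open = TRUE,  tj_sealed = TRUE),
                  custom    = list())
  cfg <- c(list(preset = "reference"), flags)
  cfg[names(overrides)] <- overrides
  if (is.null(grading) && is.null(n_elements))
    grading <- list(h_axis = 25e-6, h_interface = 5e-8,
                    h_boundary = 5e-8, ratio = 1.7)
  structure(list(name = name, config = cfg, t_max = t_max,
                 output_times = output_times, n_elements = n_elements,
                 grading = grading, settings = settings),
            class = "scenario_spec")
}

#' Run a scenario
#'
#' Builds the parameter set, mesh and model, integrates to `t_max` (or
#' steadiness, whichever first), and attaches tidy radial profiles for
#' every snapshot. With `out_dir` set, writes `profiles.csv` (long
#' format: time, R, field, value), `diagnostics.json` and the fully
#' resolved configuration `config.json` (sufficient to re-run the
#' scenario bit-identically).
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional output directory.
#' @return a `scenario_result` with elements `profiles` (data.frame),
#'   `log`, `steady`, plus the raw snapshots.
#' @export
run_scenario <- function(spec, out_dir = NULL) {
  ps <- load_parameters(spec$config)
  mesh <- if (is.null(spec$grading)) build_mesh(ps, spec$n_elements)
  else build_mesh(ps, grading = spec$grading)
  model <- fem_model(ps, mesh)
  res <- if (spec$t_max > 0)
    run_to_steady(model, settings = spec$settings, t_max = spec$t_max,
                  output_times = spec$output_times)
  else {
    x0 <- initial_state(model)
    structure(list(times = 0, snapshots = list(x0), log = NULL,
                   steady = FALSE, t_end = 0, x_end = x0, model = model),
              class = "scenario_result")
  }
  res$spec <- spec
  res$profiles <- do.call(rbind, lapply(seq_along(res$times), function(i)
    cbind(time = res$times[i], state_profiles(model, res$snapshots[[i]]))))
  if (!is.null(out_dir)) export_profiles(res, out_dir)
  res
}

#' Nodal radial profiles of all primary and derived fields
#'
#' Extracts the nodal unknowns and reconstructs the derived fields:
#' membrane potential, IC water concentration (via the volumetric
#' constraint), volume ratio `J`, areal Jacobian `J_a`, and the relative
#' osmotic/water concentrations. Element gradients are averaged onto
#' nodes for the kinematic reconstruction.
#'
#' @param model a [fem_model()].
#' @param x state vector.
#' @return data.frame with one row per node.
#' @export
state_profiles <- function(model, x) {
  ps <- model$ps; dc <- model$dc
  X <- .as_nodal(model, x)
  nodes <- model$mesh$nodes; nn <- model$nn; m <- model$m
  u <- X[, 1L]
  du <- diff(u) / diff(nodes)
  du_node <- c(du[1], (du[-1] + du[-length(du)]) / 2, du[length(du)])
  F_rr <- 1 + du_node
  F_tt <- c(F_rr[1], 1 + u[-1] / nodes[-1])
  g_psi <- diff(X[, 3L]) / diff(nodes)
  g_psi_node <- c(g_psi[1], (g_psi[-1] + g_psi[-length(g_psi)]) / 2,
                  g_psi[length(g_psi)])
  g_psie <- diff(X[, 4L]) / diff(nodes)
  g_psie_node <- c(g_psie[1], (g_psie[-1] + g_psie[-length(g_psie)]) / 2,
                   g_psie[length(g_psie)])
  ep <- ps$eps0 * ps$eps_r
  d_ic <- -ep * g_psi_node / F_rr
  d_ec <- -ep * g_psie_node / F_rr
  q <- X[, 2L] + if (ps$include_polarization) (d_ic^2 + d_ec^2) / (2 * ep) else 0
  Fzz <- .solve_Fzz(dc$lame_G, dc$lame_lambda, F_rr * F_tt, q, 0, ps$E)
  J <- F_rr * F_tt * Fzz
  Cw <- 1 / ps$v_w +
    (J - 1 - ps$Phi0_ec * (ps$v_w * X[, 5L] - 1)) / (ps$Phi0_ic * ps$v_w)
  Ci <- X[, 5L + seq_len(m), drop = FALSE]
  Ce <- X[, 5L + m + seq_len(m), drop = FALSE]
  osm_ic <- rowSums(Ci) + model$OA_ic
  osm_ec <- rowSums(Ce) + model$OA_ec
  out <- data.frame(R = nodes, R_rel = nodes / ps$R_cl,
                    u = u, pw = X[, 2L], psi = X[, 3L], psie = X[, 4L],
                    psim = X[, 3L] - X[, 4L],
                    Cw = Cw, Cwe = X[, 5L], J = J, Ja = F_rr * F_tt,
                    osm_ic = osm_ic, osm_ec = osm_ec,
                    osm_ratio_ic = osm_ic / dc$C0_osm_ic,
                    osm_ratio_ec = osm_ec / dc$C0_osm_ec,
                    water_ratio_ic = Cw * ps$v_w,
                    water_ratio_ec = X[, 5L] * ps$v_w)
  for (k in seq_len(m)) {
    out[[model$field_names[5L + k]]] <- Ci[, k]
    out[[model$field_names[5L + m + k]]] <- Ce[, k]
  }
  out
}

#' Run a one-parameter sweep
#'
#' Repeats a scenario for each value of one parameter and summarizes:
#' the half-radius displacement at the final time, the membrane-potential
#' extrema, and the IC/EC osmotic-ratio ranges. Per-point failures are
#' recorded and the sweep continues.
#'
#' @param spec a [scenario_spec()].
#' @param param name of the [param_set()] argument to sweep.
#' @param values numeric vector of values.
#' @return list with `results` (one `scenario_result` or `NULL` per
#'   value) and `summary` (data.frame).
#' @export
run_sweep <- function(spec, param, values) {
  results <- vector("list", length(values))
  rows <- list()
  for (i in seq_along(values)) {
    sp <- spec
    sp$config[[param]] <- values[i]
    res <- tryCatch(run_scenario(sp), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(value = values[i], ok = FALSE,
                              u_half = NA, u_boundary = NA, pw_max = NA,
                              psim_min = NA, psim_max = NA,
                              osm_ic_max = NA, osm_ec_min = NA)
      next
    }
    results[[i]] <- res
    pr <- res$profiles[res$profiles$time == max(res$profiles$time), ]
    ihalf <- which.min(abs(pr$R - res$model$ps$region_boundary))
    rows[[i]] <- data.frame(value = values[i], ok = TRUE,
                            u_half = pr$u[ihalf], u_boundary = pr$u[nrow(pr)],
                            pw_max = max(pr$pw),
                            psim_min = min(pr$psim), psim_max = max(pr$psim),
                            osm_ic_max = max(pr$osm_ratio_ic),
                            osm_ec_min = min(pr$osm_ratio_ec))
  }
  list(param = param, values = values, results = results,
       summary = do.call(rbind, rows))
}

#' Export scenario results
#'
#' Writes tidy long-format CSV profiles (`time, R, field, value`),
#' per-step diagnostics and the resolved configuration as JSON, and
#' optionally one plot per field (field against `R/R_cl`, one line per
#' snapshot time; needs ggplot2).
#'
#' @param result a `scenario_result` from [run_scenario()].
#' @param out_dir output directory (created if missing).
#' @param format `"csv"`.
#' @param plots logical; write PNG panels?
#' @return invisibly, the paths written.
#' @export
export_profiles <- function(result, out_dir, format = "csv", plots = FALSE) {
  if (!identical(format, "csv")) stop("unknown format '", format, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pr <- result$profiles
  idv <- c("time", "R", "R_rel")
  long <- do.call(rbind, lapply(setdiff(names(pr), idv), function(f)
    data.frame(time = pr$time, R = pr$R, field = f, value = pr[[f]])))
  status <- if (isTRUE(result$steady)) "steady"
  else if (result$t_end >= (result$spec$t_max %||% Inf)) "complete"
  else "aborted"
  paths <- file.path(out_dir, c("profiles.csv", "diagnostics.json", "config.json"))
  utils::write.csv(long, paths[1], row.names = FALSE)
  diag <- list(status = status, steady = isTRUE(result$steady),
               t_end = result$t_end)
  if (!is.null(result$log)) diag$log <- result$log
  jsonlite::write_json(diag, paths[2], dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(result$spec))
    jsonlite::write_json(list(config = result$spec$config,
                              t_max = result$spec$t_max,
                              output_times = result$spec$output_times,
                              grading = result$spec$grading,
                              n_elements = result$spec$n_elements),
                         paths[3], auto_unbox = TRUE, digits = NA)
  if (plots) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
      stop("plots require ggplot2")
    for (f in setdiff(names(pr), idv)) {
      dd <- data.frame(R_rel = pr$R_rel, value = pr[[f]],
                       time = factor(pr$time))
      gg <- ggplot2::ggplot(dd, ggplot2::aes(x = R_rel, y = value,
                                             colour = time)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = expression(R / R^cl), y = f, colour = "t [s]")
      p <- file.path(out_dir, paste0("profile_", f, ".png"))
      ggplot2::ggsave(p, gg, width = 5, height = 4, dpi = 120)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-import exported profiles
#'
#' Reads a `profiles.csv` written by [export_profiles()] back into the
#' wide per-node data.frame layout.
#'
#' @param path path to `profiles.csv`.
#' @return data.frame.
#' @export
import_profiles <- function(path) {
  long <- utils::read.csv(path)
  wide <- stats::reshape(long, idvar = c("time", "R"), timevar = "field",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$time, wide$R), ]
}
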