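#' Graded 1-D radial reference mesh
#'
#' Builds a mesh of 2-node elements on `[0, R_cl]` with a node placed
#' exactly at the core/annulus interface (`ps$region_boundary`), so the
#' transmembrane-diffusivity discontinuity never straddles an element.
#' Without a grading spec the mesh is uniform with `n_elements` elements
#' (the nearest interior node is snapped onto the interface). With a
#' grading spec, each of the two subdomains is meshed with element sizes
#' growing geometrically away from its refined ends: the axis, the
#' interface (material discontinuity) and the outer boundary (charged
#' boundary layer under the membrane capacitor).
#'
#' @param ps a [param_set()].
#' @param n_elements number of elements for a uniform mesh (>= 4).
#' @param grading `NULL`, or a list with target element sizes `h_axis`,
#'   `h_interface`, `h_boundary` \[m\] and growth `ratio` (> 1).
#' @return object of class `mesh1d`: `nodes` (strictly increasing,
#'   starting at 0 and ending at `R_cl`), `n_nodes`, `n_elements`,
#'   `i_interface`, `R_interface`.
#' @export
build_mesh <- function(ps, n_elements = 48, grading = NULL) {
  Rb <- ps$region_boundary; Rcl <- ps$R_cl
  if (is.null(grading)) {
    if (n_elements < 4) stop("n_elements must be >= 4")
    nodes <- seq(0, Rcl, length.out = n_elements + 1)
    i <- which.min(abs(nodes - Rb))
    if (i == 1L || i == length(nodes)) stop("interface falls on the domain boundary")
    nodes[i] <- Rb
  } else {
    g <- grading
    stopifnot(is.list(g), g$ratio > 1)
    nodes <- c(.geom_segment(0, Rb, g$h_axis, g$h_interface, g$ratio),
               .geom_segment(Rb, Rcl, g$h_interface, g$h_boundary, g$ratio)[-1])
  }
  if (any(diff(nodes) <= 0)) stop("grading produced non-monotone nodes")
  structure(list(nodes = nodes, n_nodes = length(nodes),
                 n_elements = length(nodes) - 1L,
                 i_interface = which(nodes == Rb)[1], R_interface = Rb),
            class = "mesh1d")
}

# Mesh [a, b] with target sizes ha at a and hb at b, growing geometrically
# (ratio r) from each end; sizes then rescaled so the segment closes exactly.
.geom_segment <- function(a, b, ha, hb, r) {
  L <- b - a
  sl <- ha; sr <- hb; left <- ha; right <- hb
  sizes_l <- c(); sizes_r <- c()
  repeat {
    if (sum(sizes_l) + sum(sizes_r) >= L) break
    if (sl <= sr) { sizes_l <- c(sizes_l, sl); sl <- sl * r }
    else          { sizes_r <- c(sizes_r, sr); sr <- sr * r }
    if (length(sizes_l) + length(sizes_r) > 10000)
      stop("grading produced too many elements")
  }
  s <- c(sizes_l, rev(sizes_r))
  s <- s * L / sum(s)
  a + cumsum(c(0, s))
}

#' @export
print.mesh1d <- function(x, ...) {
  h <- diff(x$nodes)
  cat("<mesh1d>", x$n_elements, "elements on [0,", max(x$nodes) * 1e6,
      "um]; h in [", signif(min(h) * 1e6, 3), ",", signif(max(h) * 1e6, 3),
      "] um; interface node", x$i_interface, "\n")
  invisible(x)
}

#' Evaluate kinematics from a nodal displacement field
#'
#' Radial stretch `F_rr = 1 + du/dR` (elementwise constant for linear
#' elements) and hoop stretch `F_tt = 1 + u/R`, with the axis limit
#' `F_tt -> F_rr` as `R -> 0`.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param u nodal displacements \[m\] (`u[1]` must be 0).
#' @param R query reference radii \[m\].
#' @return list of vectors `F_rr`, `F_tt` at the query radii.
#' @export
kinematics_at <- function(mesh, u, R) {
  stopifnot(length(u) == mesh$n_nodes)
  if (abs(u[1]) > 0) stop("u(0) = 0 must hold on the axis")
  nodes <- mesh$nodes
  du <- diff(u) / diff(nodes)
  el <- pmin(pmax(findInterval(R, nodes, rightmost.closed = TRUE), 1L),
             mesh$n_elements)
  uq <- u[el] + du[el] * (R - nodes[el])
  F_rr <- 1 + du[el]
  F_tt <- ifelse(R > 1e-12 * max(nodes), 1 + uq / R, F_rr)
  if (any(F_rr <= 0) || any(F_tt <= 0)) stop("nonpositive stretch")
  list(F_rr = F_rr, F_tt = F_tt)
}
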