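# Substrate models: mesh + fibers + conductivities + cell-model scalings +
# fibrosis + structural modifications (decoupled edges, ablated triangles).

#' Construct a substrate model directly from its fields
#'
#' Most users call [build_substrate()]; this constructor is the low-level
#' assembly point (also used for test sheets).
#'
#' @param mesh `la_mesh`.
#' @param fibers `fiber_field` (or NULL for isotropic).
#' @param d_l,d_t per-triangle (or scalar) longitudinal / transverse
#'   diffusion coefficients (mm^2/ms).
#' @param cell_params `cell_model_params`.
#' @param apd_scale,excitability_scale per-vertex (or scalar) positive
#'   scalings.
#' @param fibrosis optional `fibrosis_map`.
#' @param decoupled_edges k x 2 matrix of vertex pairs carrying no flux.
#' @param ablated integer vector of ablated triangle indices.
#' @param provenance free-form list recorded for reproducibility.
#' @return object of class `substrate`.
#' @export
new_substrate <- function(mesh, fibers = NULL, d_l = 0.2, d_t = 0.05,
                          cell_params = cell_model_params(),
                          apd_scale = 1, excitability_scale = 1,
                          fibrosis = NULL, decoupled_edges = NULL,
                          ablated = integer(0), provenance = list()) {
  m <- n_triangles(mesh); n <- n_vertices(mesh)
  expand <- function(x, len) if (length(x) == 1) rep(x, len) else x
  d_l <- expand(d_l, m); d_t <- expand(d_t, m)
  apd_scale <- expand(apd_scale, n)
  excitability_scale <- expand(excitability_scale, n)
  stopifnot(length(d_l) == m, length(d_t) == m,
            all(is.finite(apd_scale)), all(apd_scale > 0),
            all(excitability_scale >= 0))
  if (any(d_t > d_l + 1e-12)) stop("transverse conductivity exceeds longitudinal")
  if (is.null(fibers)) {
    dirs <- matrix(rep(c(1, 0, 0), each = m), m, 3)
    nrm <- triangle_normals(mesh$vertices, mesh$triangles)
    dirs <- normalize_rows(dirs - nrm * rowSums(dirs * nrm))
    fibers <- structure(list(directions = dirs, variant = "isotropic"),
                        class = "fiber_field")
  }
  if (!is.null(decoupled_edges) && nrow(decoupled_edges) > 0) {
    decoupled_edges <- cbind(pmin(decoupled_edges[, 1], decoupled_edges[, 2]),
                             pmax(decoupled_edges[, 1], decoupled_edges[, 2]))
    if (any(decoupled_edges < 1) || any(decoupled_edges > n))
      stop("decoupled edge references invalid vertex")
  }
  if (length(ablated) && (any(ablated < 1) || any(ablated > m)))
    stop("ablated triangle index out of range")
  structure(list(mesh = mesh, fibers = fibers, d_l = d_l, d_t = d_t,
                 cell_params = cell_params, apd_scale = apd_scale,
                 excitability_scale = excitability_scale,
                 fibrosis = fibrosis,
                 decoupled_edges = decoupled_edges,
                 ablated = as.integer(ablated),
                 provenance = provenance),
            class = "substrate")
}

#' Deterministic hash of a substrate (used as cache key)
#' @param substrate a `substrate`
#' @return character digest
#' @export
substrate_hash <- function(substrate) {
  digest::digest(list(substrate$mesh$vertices, substrate$mesh$triangles,
                      substrate$fibers$directions, substrate$d_l,
                      substrate$d_t, unclass(substrate$cell_params),
                      substrate$apd_scale, substrate$excitability_scale,
                      substrate$decoupled_edges, substrate$ablated))
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate> %d vertices, %d triangles, %d decoupled edges, %d ablated, fibers=%s\n",
              n_vertices(x$mesh), n_triangles(x$mesh),
              if (is.null(x$decoupled_edges)) 0L else nrow(x$decoupled_edges),
              length(x$ablated), x$fibers$variant))
  invisible(x)
}

#' Map image intensity ratio to a conductivity scaling
#'
#' Rule-based conduction slowing in enhanced tissue: scaling 1 for
#' IIR <= 1.22 (threshold inclusive on the healthy side), falling linearly
#' to `floor` at `ceiling`, constant beyond.  A custom rule is a two-column
#' matrix of (iir, scaling) knots and must be monotone non-increasing.
#'
#' @param iir per-vertex IIR values.
#' @param rule two-column knot matrix; default
#'   `rbind(c(1.22, 1), c(1.6, 0.3))`.
#' @param mesh optional `la_mesh`; when given, returns per-triangle scalings
#'   (mean of the triangle's vertex scalings) instead of per-vertex.
#' @return numeric scalings in (0, 1].
#' @export
iir_to_conductivity <- function(iir, rule = NULL, mesh = NULL) {
  if (is.null(rule)) rule <- rbind(c(IIR_THRESHOLD, 1), c(1.6, 0.3))
  rule <- as.matrix(rule)
  if (is.unsorted(rule[, 1])) stop("rule knots must have increasing iir")
  if (any(diff(rule[, 2]) > 1e-12))
    stop("non-monotone rule: scaling must be non-increasing in iir")
  s <- approx(rule[, 1], rule[, 2], xout = iir, rule = 2)$y
  if (!is.null(mesh)) {
    tri <- mesh$triangles
    s <- (s[tri[, 1]] + s[tri[, 2]] + s[tri[, 3]]) / 3
  }
  s
}

#' Select interstitial (zero-flux) edges from a fibrosis map
#'
#' Each interior mesh edge whose mean endpoint IIR exceeds 1.22 is decoupled
#' independently with probability `p(iir)`; the default density rule rises
#' linearly from 0 at IIR 1.22 to `p_max` at IIR 1.6.  A connectivity
#' post-check re-couples a spanning subset if the selection would split the
#' excitable tissue into more than one component.
#'
#' @param mesh `la_mesh`.
#' @param fibrosis `fibrosis_map`.
#' @param seed integer seed.
#' @param p_max maximal decoupling probability (at/beyond IIR 1.6).
#' @param density_rule optional function iir -> probability in \[0,1\]
#'   overriding the default linear rule.
#' @return k x 2 matrix of decoupled vertex pairs.
#' @export
decouple_interstitial_edges <- function(mesh, fibrosis, seed, p_max = 0.5,
                                        density_rule = NULL) {
  me <- mesh_edges(mesh$triangles)
  interior <- me$count == 2
  e <- me$edges[interior, , drop = FALSE]
  iir_e <- (fibrosis$iir[e[, 1]] + fibrosis$iir[e[, 2]]) / 2
  p <- if (is.null(density_rule)) {
    pmin(p_max, pmax(0, (iir_e - IIR_THRESHOLD) / (1.6 - IIR_THRESHOLD) * p_max))
  } else {
    vapply(iir_e, density_rule, numeric(1))
  }
  if (any(p < 0 | p > 1)) stop("density rule must map iir to [0,1]")
  p[iir_e <= IIR_THRESHOLD] <- 0
  sel <- with_seed(child_seed(seed, "interstitial"), runif(length(p)) < p)
  dec <- e[sel, , drop = FALSE]
  if (nrow(dec) == 0) return(dec)
  # connectivity repair: keep the mesh one excitable component
  keep <- rbind(e[!sel, , drop = FALSE],
                me$edges[me$count == 1, , drop = FALSE])
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_vertices(mesh) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    recouple <- logical(nrow(dec))
    memb <- comp$membership
    for (r in seq_len(nrow(dec))) {
      a <- memb[dec[r, 1]]; b <- memb[dec[r, 2]]
      if (a != b) {
        recouple[r] <- TRUE
        memb[memb == b] <- a
      }
    }
    dec <- dec[!recouple, , drop = FALSE]
  }
  dec
}

#' Build one stress-test substrate variant
#'
#' Realizes the four fibrosis-type variants on a common mesh/fibrosis input:
#' \describe{
#'   \item{combination}{interstitial edge decoupling + IIR-based conductivity
#'     scaling + ionic remodeling (APD shortening at fibrotic vertices).}
#'   \item{conduction_only}{conductivity scaling + ionic remodeling, no
#'     decoupling.}
#'   \item{interstitial}{edge decoupling only.}
#'   \item{none}{homogeneous healthy substrate.}
#' }
#'
#' @param mesh `la_mesh`.
#' @param fibrosis_map `fibrosis_map`.
#' @param fiber_variant fiber variant id passed to [generate_fibers()], or a
#'   ready `fiber_field`.
#' @param fibrosis_type one of `"combination"`, `"conduction_only"`,
#'   `"interstitial"`, `"none"`.
#' @param seed integer seed (controls interstitial edge selection).
#' @param conductivity list with `d_l` and `d_t` (healthy values, mm^2/ms);
#'   default from [calibrate_cv()] at the mesh resolution.
#' @param apd_remodel APD scaling applied at fibrotic vertices (default
#'   0.85).
#' @param erp_scale global APD scaling implementing the ERP variants.
#' @param cell_params `cell_model_params`.
#' @return a `substrate`.
#' @export
build_substrate <- function(mesh, fibrosis_map, fiber_variant = "fiber_A",
                            fibrosis_type = c("combination", "conduction_only",
                                              "interstitial", "none"),
                            seed = 1, conductivity = NULL,
                            apd_remodel = 0.85, erp_scale = 1,
                            cell_params = cell_model_params()) {
  fibrosis_type <- match.arg(fibrosis_type)
  fibers <- if (inherits(fiber_variant, "fiber_field")) fiber_variant else
    generate_fibers(mesh, fiber_variant)
  if (is.null(conductivity)) {
    conductivity <- calibrate_cv(0.5, anisotropy_ratio = 2,
                                 resolution = mesh$resolution %||% 2,
                                 cell_params = cell_params)
  }
  n <- n_vertices(mesh)
  apd <- rep(erp_scale, n)
  d_l <- rep(conductivity$d_l, n_triangles(mesh))
  d_t <- rep(conductivity$d_t, n_triangles(mesh))
  dec <- NULL
  if (fibrosis_type %in% c("combination", "conduction_only")) {
    sc <- iir_to_conductivity(fibrosis_map$iir, mesh = mesh)
    d_l <- d_l * sc; d_t <- d_t * sc
    apd[fibrosis_map$iir > IIR_THRESHOLD] <-
      apd[fibrosis_map$iir > IIR_THRESHOLD] * apd_remodel
  }
  if (fibrosis_type %in% c("combination", "interstitial")) {
    dec <- decouple_interstitial_edges(mesh, fibrosis_map, seed)
  }
  new_substrate(mesh, fibers, d_l = d_l, d_t = d_t,
                cell_params = cell_params, apd_scale = apd,
                excitability_scale = 1, fibrosis = fibrosis_map,
                decoupled_edges = dec,
                provenance = list(seed = seed, fibrosis_type = fibrosis_type,
                                  fiber_variant = fibers$variant,
                                  erp_scale = erp_scale,
                                  apd_remodel = apd_remodel,
                                  conductivity = conductivity[c("d_l", "d_t")]))
}
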