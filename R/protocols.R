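# AF initiation (phase-distribution seeding) and simulated pulmonary vein
# isolation.

# canonical seed directions (unit-sphere frame): posterior wall x2,
# anterior wall, appendage-base analogue
.map_dirs <- function(variant) {
  base <- rbind(c(0.00, 0.85, 0.45),
                c(0.10, 0.95, -0.30),
                c(0.20, -0.45, 0.85),
                c(-0.70, 0.10, -0.65))
  rot_z <- function(m, deg) {
    th <- deg * pi / 180
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    m %*% t(R)
  }
  m <- switch(variant,
              map_A = base,
              map_B = rot_z(base, 35),
              map_C = rot_z(base, -35),
              stop("unknown initiation map variant: ", variant))
  normalize_rows(m)
}

#' Construct an AF initiation map
#'
#' A set of phase-singularity seed locations with alternating chirality.
#' `map_A` places four seeds at fixed anatomical landmark analogues
#' (posterior wall x2, anterior wall, appendage base); `map_B`/`map_C` use
#' the same count at placements rotated about the long axis by +/-35
#' degrees.  Seeds are snapped to the nearest vertex outside PV ostium
#' boundary neighbourhoods.
#'
#' @param mesh an `la_mesh`.
#' @param variant `"map_A"`, `"map_B"` or `"map_C"`.
#' @param core_radius rotor core radius (mm) used for the pairwise
#'   separation invariant.
#' @return object of class `initiation_map`: data.frame `seeds` (vertex,
#'   chirality), `variant`, `core_radius`.
#' @export
initiation_map <- function(mesh, variant = c("map_A", "map_B", "map_C"),
                           core_radius = 5) {
  variant <- match.arg(variant)
  dirs <- .map_dirs(variant)
  ctr <- colMeans(mesh$vertices)
  vdir <- normalize_rows(sweep(mesh$vertices, 2, ctr))
  # keep clear of all boundary loops
  bl <- unlist(mesh$boundary_loops)
  dbound <- geodesic_from(mesh, bl)
  ok <- dbound > 1.5 * (mesh$resolution %||% 2)
  verts <- integer(nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    score <- vdir %*% dirs[k, ]
    score[!ok] <- -Inf
    verts[k] <- which.max(score)
  }
  seeds <- data.frame(vertex = verts,
                      chirality = rep(c(1L, -1L), length.out = length(verts)))
  d <- as.matrix(stats::dist(mesh$vertices[verts, , drop = FALSE]))
  diag(d) <- Inf
  if (min(d) < 2 * core_radius)
    warning("initiation seeds closer than 2 x core radius; boundary-adjacent annihilation possible")
  structure(list(seeds = seeds, variant = variant,
                 core_radius = core_radius), class = "initiation_map")
}

# orthonormal tangent frame at a vertex (e1, e2, n right-handed)
vertex_frame <- function(mesh, v) {
  inc <- which(mesh$triangles[, 1] == v | mesh$triangles[, 2] == v |
                 mesh$triangles[, 3] == v)
  nrm <- triangle_normals(mesh$vertices, mesh$triangles[inc, , drop = FALSE])
  n <- colSums(nrm); n <- n / sqrt(sum(n^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - n * sum(ref * n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

#' Build an AF-initiating state by phase-distribution seeding
#'
#' Assigns each vertex the phase sum of `atan2` angles about every seed
#' (computed in the seed's tangent frame, weighted by chirality) and maps
#' the phase onto a recorded single-cell limit cycle, producing an initial
#' state that contains one phase singularity per seed at t = 0.
#'
#' @param substrate a `substrate`.
#' @param map an `initiation_map`.
#' @param cycle_length pacing cycle length (ms) of the limit cycle used for
#'   the phase-to-state mapping; default 1000 / 6 Hz target rate.
#' @return state list(v, h) usable as `initial_state` in [simulate()].
#' @export
seed_phase_distribution <- function(substrate, map, cycle_length = 1000 / 6) {
  stopifnot(inherits(map, "initiation_map"))
  if (nrow(map$seeds) < 1) stop("initiation map must contain at least one seed")
  mesh <- substrate$mesh
  if (length(substrate$ablated)) {
    abl_verts <- unique(as.vector(mesh$triangles[substrate$ablated, ]))
    if (any(map$seeds$vertex %in% abl_verts))
      stop("initiation seed lies inside an ablated region")
  }
  phi <- numeric(n_vertices(mesh))
  for (k in seq_len(nrow(map$seeds))) {
    v0 <- map$seeds$vertex[k]
    fr <- vertex_frame(mesh, v0)
    rel <- sweep(mesh$vertices, 2, mesh$vertices[v0, ])
    phi <- phi + map$seeds$chirality[k] *
      atan2(rel %*% fr$e2, rel %*% fr$e1)
  }
  phi <- wrap_pi(phi)
  lc <- cell_limit_cycle(substrate$cell_params, cl = cycle_length)
  idx <- 1 + floor(((phi + pi) / (2 * pi)) * length(lc$phase))
  idx[idx > length(lc$phase)] <- length(lc$phase)
  st <- list(v = lc$v[idx], h = lc$h[idx])
  attr(st, "phase") <- phi   # the geometric phase field realised at t = 0
  st
}

#' Build a pulmonary vein isolation lesion set
#'
#' Ablates every triangle whose centroid geodesic distance to the nearest
#' PV junction (ostium boundary loop) lies in `[d, d + width]`, forming a
#' closed wide-area circumferential band per vein (left and right pairs may
#' merge when bands overlap).  Fails with "incomplete encirclement" if any
#' PV antrum remains graph-connected to the atrial body after removal.
#'
#' @param mesh an `la_mesh`.
#' @param d band inner distance from the PV junction (mm); baseline 5,
#'   size variant 10.
#' @param width band width (mm); must be at least twice the edge length.
#' @param size_variant label recorded on the lesion (`"baseline"` or
#'   `"variant"`).
#' @return object of class `lesion_set`: `triangles`, `d`, `width`,
#'   `size_variant`.
#' @export
build_pvi_lesion <- function(mesh, d = 5, width = NULL,
                             size_variant = "baseline") {
  if (d <= 0) stop("d must be > 0")
  h <- mesh$resolution %||% 2
  width <- width %||% max(5, 2.5 * h)
  if (width < 2 * h)
    stop("width must be at least 2 x edge length")
  tri <- mesh$triangles
  cd <- (mesh$dist_pv[tri[, 1]] + mesh$dist_pv[tri[, 2]] +
           mesh$dist_pv[tri[, 3]]) / 3
  abl <- which(cd >= d & cd <= d + width)
  lesion <- structure(list(triangles = abl, d = d, width = width,
                           size_variant = size_variant),
                      class = "lesion_set")
  chk <- check_isolation(mesh, lesion)
  if (!isTRUE(chk))
    stop(sprintf("incomplete encirclement: %s remains connected to the body",
                 paste(chk, collapse = ", ")))
  lesion
}

# TRUE when every PV antrum is graph-disconnected from the body across the
# lesion; otherwise the offending PV names
check_isolation <- function(mesh, lesion) {
  tri <- mesh$triangles
  keep <- setdiff(seq_len(nrow(tri)), lesion$triangles)
  sub <- tri[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    rbind(sub[, c(1, 2)], sub[, c(2, 3)], sub[, c(3, 1)]), directed = FALSE)
  if (igraph::vcount(g) < n_vertices(mesh))
    g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  body_far <- unique(as.vector(tri[mesh$region == "body", ]))
  body_far <- body_far[mesh$dist_pv[body_far] > lesion$d + lesion$width + 1]
  bad <- character(0)
  for (pv in paste0("pv", 1:4)) {
    pvv <- unique(as.vector(tri[mesh$region == pv, ]))
    pvv <- pvv[mesh$dist_pv[pvv] < lesion$d - 0.5]
    if (length(pvv) == 0) next
    if (any(memb[pvv] %in% memb[body_far])) bad <- c(bad, pv)
  }
  if (length(bad)) bad else TRUE
}

#' Inject a conduction gap into a lesion (test API)
#'
#' Centres a gap on one lesion triangle and removes every lesion triangle
#' whose centroid lies within `radius` of it.  A band two or more elements
#' thick cannot be bridged by restoring a single triangle (its vertices
#' still only couple within one band row), so the gap radius defaults to
#' the band width to guarantee a transmural conducting channel.
#'
#' @param lesion a `lesion_set`.
#' @param mesh the `la_mesh` the lesion was built on.
#' @param index which lesion triangle to centre the gap on.
#' @param radius gap radius (mm); default the lesion band width.
#' @return modified `lesion_set` with a `gap` field listing the removed
#'   triangles.
#' @export
inject_lesion_gap <- function(lesion, mesh, index = 1, radius = NULL) {
  radius <- radius %||% lesion$width
  tri <- mesh$triangles
  cen <- (mesh$vertices[tri[, 1], , drop = FALSE] +
            mesh$vertices[tri[, 2], , drop = FALSE] +
            mesh$vertices[tri[, 3], , drop = FALSE]) / 3
  t0 <- lesion$triangles[index]
  d <- sqrt(rowSums(sweep(cen[lesion$triangles, , drop = FALSE],
                          2, cen[t0, ])^2))
  drop <- lesion$triangles[d <= radius]
  lesion$triangles <- setdiff(lesion$triangles, drop)
  lesion$gap <- drop
  lesion
}

#' Apply an ablation lesion to a substrate
#'
#' Ablated triangles get zero conductivity and their interior vertices are
#' excluded from reaction updates; all other fields are untouched and the
#' input substrate is not mutated.
#'
#' @param substrate a `substrate`.
#' @param lesion a `lesion_set` (or integer triangle indices).
#' @return new `substrate` with the lesion applied.
#' @export
apply_ablation <- function(substrate, lesion) {
  tris <- if (inherits(lesion, "lesion_set")) lesion$triangles else
    as.integer(lesion)
  if (length(tris) && (min(tris) < 1 || max(tris) > n_triangles(substrate$mesh)))
    stop("lesion references invalid triangles")
  out <- substrate
  out$ablated <- sort(union(substrate$ablated, tris))
  out$provenance$lesion <- if (inherits(lesion, "lesion_set"))
    lesion[c("d", "width", "size_variant")] else list(custom = TRUE)
  out
}
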