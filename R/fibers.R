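# Rule-based fiber fields.
#
# Stand-ins for DT-MRI-derived fiber maps: fiber_A follows a smoothed
# circumferential rule about the long (mitral) axis; other variants are
# fiber_A rotated in-plane by a fixed angle.  Directions are unit vectors
# tangent to their triangle.

.fiber_rotations <- c(fiber_A = 0, fiber_B = 60, fiber_C = -60)

#' Generate a rule-based fiber field
#'
#' `fiber_A` projects the circumferential direction about the mitral axis
#' onto each triangle plane and smooths it over neighbouring triangles.
#' `fiber_B` / `fiber_C` rotate `fiber_A` in-plane by +60 / -60 degrees
#' (configurable), giving globally distinct fields on the same mesh.
#' On a flat sheet the rule degenerates to a constant direction.
#'
#' @param mesh an `la_mesh`.
#' @param variant `"fiber_A"`, `"fiber_B"` or `"fiber_C"`.
#' @param rotation_deg in-plane rotation (degrees) applied for variants
#'   other than `fiber_A`; sign taken from the variant's default.
#' @param smoothing_iters rounds of neighbour averaging.
#' @return object of class `fiber_field`: `directions` (m x 3 unit vectors,
#'   tangent), `variant`.
#' @export
generate_fibers <- function(mesh, variant = c("fiber_A", "fiber_B", "fiber_C"),
                            rotation_deg = NULL, smoothing_iters = 10) {
  variant <- match.arg(variant)
  nrm <- triangle_normals(mesh$vertices, mesh$triangles)
  m <- nrow(nrm)
  axis <- .mitral_dir()
  d <- cross3(matrix(axis, m, 3, byrow = TRUE), nrm)
  # degenerate where the normal is parallel to the axis: fall back to a
  # fixed reference direction projected onto the plane
  bad <- vec_norm(d) < 1e-6
  if (any(bad)) {
    ref <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    nb <- nrm[bad, , drop = FALSE]
    d[bad, ] <- ref - nb * rowSums(ref * nb)
  }
  d <- normalize_rows(d)

  if (smoothing_iters > 0 && m > 1) {
    adj <- triangle_adjacency(mesh)
    for (it in seq_len(smoothing_iters)) {
      s <- d + adj %*% d
      # reproject to tangent plane and renormalize
      s <- s - nrm * rowSums(as.matrix(s) * nrm)
      d <- normalize_rows(as.matrix(s))
    }
  }

  theta <- .fiber_rotations[[variant]]
  if (!is.null(rotation_deg)) theta <- rotation_deg * sign(theta)
  if (theta != 0) {
    th <- theta * pi / 180
    perp <- cross3(nrm, d)
    d <- normalize_rows(d * cos(th) + perp * sin(th))
  }
  structure(list(directions = d, variant = variant), class = "fiber_field")
}

# triangle-triangle adjacency over shared edges (sparse 0/1 matrix)
triangle_adjacency <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(tri)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tid <- rep(seq_len(m), 3)
  grp <- split(tid, key)
  pairs <- do.call(rbind, lapply(grp[lengths(grp) == 2], function(p)
    c(p[1], p[2])))
  Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                       j = c(pairs[, 2], pairs[, 1]),
                       x = 0.5, dims = c(m, m))
}

# signed in-plane angle between two tangent fields (degrees, per triangle)
fiber_angle_difference <- function(mesh, fa, fb) {
  nrm <- triangle_normals(mesh$vertices, mesh$triangles)
  a <- fa$directions; b <- fb$directions
  s <- rowSums(cross3(a, b) * nrm)
  c_ <- rowSums(a * b)
  atan2(s, c_) * 180 / pi
}
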