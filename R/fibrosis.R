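# Fibrosis substrate synthesis.
#
# Late-gadolinium enhancement is summarised per vertex as the image
# intensity ratio (IIR, voxel intensity / blood-pool mean).  Vertices with
# IIR > 1.22 are called fibrotic.  The synthetic field is a spatially
# correlated Gaussian random field (white noise smoothed over the vertex
# graph), rank-mapped onto an IIR scale so that the fibrotic fraction equals
# the requested burden exactly up to ties.

#' Image intensity ratio threshold defining fibrosis
#' @export
IIR_THRESHOLD <- 1.22

#' Generate a per-vertex fibrosis (IIR) map
#'
#' @param mesh an `la_mesh`.
#' @param seed integer seed.
#' @param burden target fraction of vertices with IIR above 1.22, in
#'   \[0, 1\].
#' @param correlation_length spatial scale (mm) of the fibrotic patches.
#' @param iir_range range of the produced IIR values (dimensionless).
#' @return object of class `fibrosis_map`: list with `iir` (per vertex),
#'   `burden` (realized fraction), `correlation_length`, `seed`.
#' @export
generate_fibrosis <- function(mesh, seed, burden = 0.2,
                              correlation_length = 8,
                              iir_range = c(0.8, 1.8)) {
  stopifnot(inherits(mesh, "la_mesh"))
  if (burden < 0 || burden > 1) stop("burden must be in [0, 1]")
  n <- n_vertices(mesh)
  with_seed(child_seed(seed, "fibrosis"), {
    z <- rnorm(n)
    # graph smoothing: k rounds of 1-ring averaging gives a correlation
    # scale ~ sqrt(k) edge lengths
    me <- mesh_edges(mesh$triangles)
    h <- mean(vec_norm(mesh$vertices[me$edges[, 1], , drop = FALSE] -
                         mesh$vertices[me$edges[, 2], , drop = FALSE]))
    k <- max(1, round((correlation_length / h)^2 / 2))
    A <- Matrix::sparseMatrix(i = c(me$edges[, 1], me$edges[, 2]),
                              j = c(me$edges[, 2], me$edges[, 1]),
                              x = 1, dims = c(n, n))
    deg <- Matrix::rowSums(A)
    for (it in seq_len(k)) {
      z <- 0.5 * z + 0.5 * as.vector(A %*% z) / deg
    }
    # rank map onto the IIR scale with exactly `burden` above threshold
    u <- rank(z, ties.method = "first") / n
    ustar <- 1 - burden
    iir <- numeric(n)
    lo <- u <= ustar
    if (ustar > 0)
      iir[lo] <- iir_range[1] +
        (IIR_THRESHOLD - iir_range[1]) * u[lo] / ustar
    if (ustar < 1)
      iir[!lo] <- IIR_THRESHOLD +
        (iir_range[2] - IIR_THRESHOLD) * (u[!lo] - ustar) / (1 - ustar)
    structure(list(iir = iir, burden = mean(iir > IIR_THRESHOLD),
                   correlation_length = correlation_length, seed = seed),
              class = "fibrosis_map")
  })
}

#' @export
print.fibrosis_map <- function(x, ...) {
  cat(sprintf("<fibrosis_map> %d vertices, burden %.3f (IIR > %.2f)\n",
              length(x$iir), x$burden, IIR_THRESHOLD))
  invisible(x)
}
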