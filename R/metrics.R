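# Imaging-derived area metrics (the Figure-3-style block of the patient
# signature).

# visual fibrosis score bins on the fibrotic area fraction
.visual_breaks <- c(0.10, 0.20, 0.35)
.visual_levels <- c("healthy", "mild", "moderate", "severe")

#' Imaging metrics of a mesh + fibrosis map
#'
#' Areas are triangle-area sums in cm^2.  A triangle is fibrotic iff the
#' mean of its vertex IIR values exceeds 1.22; PV areas restrict to the
#' four antral regions.  The ordinal visual fibrosis score bins the global
#' fibrotic area fraction at 10 / 20 / 35 %.
#'
#' @param mesh an `la_mesh`.
#' @param fibrosis_map a `fibrosis_map`.
#' @return object of class `imaging_metrics`: `total_area`, `pv_area`,
#'   `fibrosis_area`, `pv_fibrosis_area` (cm^2), `visual_score` (ordered
#'   factor) and `visual_code` (0-3).
#' @export
imaging_metrics <- function(mesh, fibrosis_map) {
  tri <- mesh$triangles
  areas <- triangle_areas(mesh$vertices, tri) / 100
  iir_t <- (fibrosis_map$iir[tri[, 1]] + fibrosis_map$iir[tri[, 2]] +
              fibrosis_map$iir[tri[, 3]]) / 3
  fib <- iir_t > IIR_THRESHOLD
  pv <- mesh$region %in% paste0("pv", 1:4)
  total <- sum(areas)
  fib_area <- sum(areas[fib])
  frac <- fib_area / total
  code <- findInterval(frac, .visual_breaks)
  structure(list(total_area = total,
                 pv_area = sum(areas[pv]),
                 fibrosis_area = fib_area,
                 pv_fibrosis_area = sum(areas[fib & pv]),
                 visual_score = factor(.visual_levels[code + 1],
                                       levels = .visual_levels,
                                       ordered = TRUE),
                 visual_code = code),
            class = "imaging_metrics")
}

#' @export
print.imaging_metrics <- function(x, ...) {
  cat(sprintf("<imaging_metrics> total %.1f cm^2, pv %.1f, fibrosis %.1f, pv fibrosis %.1f, visual %s\n",
              x$total_area, x$pv_area, x$fibrosis_area, x$pv_fibrosis_area,
              as.character(x$visual_score)))
  invisible(x)
}
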