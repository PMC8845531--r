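# Phase maps and phase-singularity (PS) detection.
#
# Phase is the angle of the per-vertex Hilbert-transform analytic signal of
# mean-subtracted Vm (parameter-free, method tag "hilbert").  A PS is a
# vertex whose one-ring has winding number +/-1: the sum of wrapped phase
# differences along the ring's opposite directed edges (traversed
# counterclockwise with respect to the outward normal) divided by 2 pi.

#' Wrap angles to (-pi, pi]
#' @param x angles (radians)
#' @return wrapped angles
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Compute a phase map from a transmembrane-potential movie
#'
#' @param movie a `vm_movie` (duration >= 1 s for sensible detrending).
#' @param min_sd vertices whose Vm standard deviation falls below this (mV)
#'   are flagged phase-undefined and excluded from PS detection.
#' @return object of class `phase_map`: `phase` (frames x vertices,
#'   radians in (-pi, pi]), `times`, `undefined` (logical per vertex),
#'   `mesh`, `method`.
#' @export
compute_phase <- function(movie, min_sd = 0.5) {
  stopifnot(inherits(movie, "vm_movie"))
  if (max(movie$times) < 1000)
    warning("movie shorter than 1 s; phase estimates may be poor")
  x <- movie$vm
  f <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colMeans(xc^2))
  undefined <- sds < min_sd
  X <- mvfft(xc)
  mask <- numeric(f)
  if (f %% 2 == 0) {
    mask[1] <- 1; mask[f / 2 + 1] <- 1
    mask[2:(f / 2)] <- 2
  } else {
    mask[1] <- 1
    mask[2:((f + 1) / 2)] <- 2
  }
  z <- mvfft(X * mask, inverse = TRUE) / f
  ph <- atan2(Im(z), Re(z))
  ph[, undefined] <- NA_real_
  structure(list(phase = ph, times = movie$times, undefined = undefined,
                 mesh = movie$mesh, method = "hilbert"),
            class = "phase_map")
}

.ring_cache <- new.env(parent = emptyenv())

# opposite directed edges of each interior vertex's one-ring: for triangle
# (a,b,c) in CCW order, vertex a owns edge b->c.  Summing wrapped phase
# differences over these edges equals the ring winding integral.
vertex_ring_edges <- function(mesh) {
  key <- digest::digest(mesh$triangles)
  hit <- .ring_cache[[key]]
  if (!is.null(hit)) return(hit)
  tri <- mesh$triangles
  owner <- c(tri[, 1], tri[, 2], tri[, 3])
  from <- c(tri[, 2], tri[, 3], tri[, 1])
  to <- c(tri[, 3], tri[, 1], tri[, 2])
  bverts <- unique(unlist(trace_boundary_loops(tri)))
  interior <- !(owner %in% bverts)
  out <- list(owner = owner[interior], from = from[interior],
              to = to[interior],
              interior_vertices = setdiff(seq_len(nrow(mesh$vertices)),
                                          bverts))
  .ring_cache[[key]] <- out
  out
}

#' Detect phase singularities at one time point
#'
#' Computes the winding number of every interior vertex's one-ring with
#' each pairwise phase difference wrapped to (-pi, pi]; vertices with
#' |winding| = 1 are reported with their topological charge.
#'
#' @param phase a `phase_map`, or a numeric vector of per-vertex phases
#'   (then `mesh` must be supplied).
#' @param t time (ms) of the frame to analyse (nearest frame used);
#'   ignored for vector input.
#' @param mesh mesh for vector input.
#' @param dedupe a singular point interior to a triangle lies inside the
#'   one-ring polygon of each of that triangle's vertices, so the raw
#'   winding criterion flags a small cluster of adjacent vertices per
#'   rotor.  With `dedupe = TRUE` (default) edge-connected clusters of
#'   equal charge are merged into a single observation (first vertex kept);
#'   `dedupe = FALSE` returns the raw per-vertex winding detections.
#' @return data.frame with columns `time`, `vertex`, `charge`.
#' @export
detect_phase_singularities <- function(phase, t = 0, mesh = NULL,
                                       dedupe = TRUE) {
  if (inherits(phase, "phase_map")) {
    fi <- which.min(abs(phase$times - t))
    phi <- phase$phase[fi, ]
    mesh <- phase$mesh
    tm <- phase$times[fi]
  } else {
    phi <- as.numeric(phase)
    if (is.null(mesh)) stop("mesh required for vector phase input")
    tm <- t
  }
  re <- vertex_ring_edges(mesh)
  contrib <- wrap_pi(phi[re$to] - phi[re$from])
  w <- rowsum(contrib, re$owner)
  wn <- round(w / (2 * pi))
  ok <- !is.na(wn) & abs(wn) >= 1
  vs <- as.integer(rownames(w))[ok]
  ch <- as.integer(sign(wn[ok]))
  if (dedupe && length(vs) > 1) {
    me <- mesh_edges(mesh$triangles)
    e <- me$edges[me$edges[, 1] %in% vs & me$edges[, 2] %in% vs, ,
                  drop = FALSE]
    if (nrow(e) > 0) {
      # merge adjacent detections of equal charge
      chmap <- setNames(ch, vs)
      same <- chmap[as.character(e[, 1])] == chmap[as.character(e[, 2])]
      ei <- cbind(match(e[same, 1], vs), match(e[same, 2], vs))
      parent <- seq_along(vs)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(ei))) {
        a <- find(ei[r, 1]); b <- find(ei[r, 2])
        if (a != b) parent[b] <- a
      }
      memb <- vapply(seq_along(vs), find, integer(1))
      keep <- !duplicated(memb)
      vs <- vs[keep]; ch <- ch[keep]
    }
  }
  data.frame(time = rep(tm, length(vs)), vertex = vs, charge = ch)
}

#' Detect phase singularities in every frame of a phase map
#' @param phase a `phase_map`
#' @param times optional subset of frame times (ms)
#' @return data.frame (time, vertex, charge) over all frames
#' @export
track_phase_singularities <- function(phase, times = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  times <- times %||% phase$times
  do.call(rbind, lapply(times, function(t)
    detect_phase_singularities(phase, t)))
}

#' Summarise phase-singularity observations
#'
#' @param observations data.frame (time, vertex, charge) from
#'   [track_phase_singularities()].
#' @param mesh the `la_mesh` the observations live on.
#' @param window numeric length-2 analysis window (ms); frames outside are
#'   ignored.  Frames inside the window with no observations count as zero.
#' @param frame_times the full set of analysed frame times (ms), needed to
#'   count empty frames; defaults to the distinct times in `observations`.
#' @return list with `mean_count`, `ps_area_cm2`, `pv_ps_area_cm2`.
#' @export
ps_statistics <- function(observations, mesh, window = NULL,
                          frame_times = NULL) {
  frame_times <- frame_times %||% sort(unique(observations$time))
  if (!is.null(window)) {
    frame_times <- frame_times[frame_times >= window[1] &
                                 frame_times <= window[2]]
    observations <- observations[observations$time >= window[1] &
                                   observations$time <= window[2], ,
                                 drop = FALSE]
  }
  if (length(frame_times) == 0 || nrow(observations) == 0)
    return(list(mean_count = 0, ps_area_cm2 = 0, pv_ps_area_cm2 = 0))
  counts <- table(factor(observations$time, levels = frame_times))
  mean_count <- mean(as.numeric(counts))
  tri <- mesh$triangles
  areas <- triangle_areas(mesh$vertices, tri)
  vs <- unique(observations$vertex)
  visited <- which(tri[, 1] %in% vs | tri[, 2] %in% vs | tri[, 3] %in% vs)
  ps_area <- sum(areas[visited]) / 100
  pv_area <- sum(areas[visited][mesh$region[visited] %in%
                                  paste0("pv", 1:4)]) / 100
  list(mean_count = mean_count, ps_area_cm2 = ps_area,
       pv_ps_area_cm2 = pv_area)
}
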